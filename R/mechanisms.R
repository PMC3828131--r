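MECHANISM_CLASSES <- c("charge", "cation_pi", "pi_pi", "size", "hbond",
                       "other_hydrophobic", "other_hydrophilic", "other_mixed")

#' Physicochemical annotations of the 20 standard amino acids
#'
#' Fixed constants used by the covariation mechanism classifier: side-chain
#' volume (Angstrom^3, Zamyatnin-style standard values), formal charge at
#' neutral pH (+1 for K and R, -1 for D and E, histidine treated as
#' uncharged), cation and aromatic flags for cation-pi / pi-pi detection
#' (cations K and R; aromatics F, W and Y), side-chain hydrogen-bond donor
#' and acceptor capability, and a binary hydropathy label (hydrophobic:
#' A, V, L, I, M, F, W, C, P, G). Every default can be overridden by passing
#' a modified copy of this table to the classifier.
#'
#' @return Data frame with one row per residue (rownames = one-letter code)
#'   and columns `volume`, `charge`, `cation`, `aromatic`, `donor`,
#'   `acceptor`, `hydrophobic`.
#' @export
residue_annotations <- function() {
  volume <- c(A = 88.6, C = 108.5, D = 111.1, E = 138.4, F = 189.9,
              G = 60.1, H = 153.2, I = 166.7, K = 168.6, L = 166.7,
              M = 162.9, N = 114.1, P = 112.7, Q = 143.8, R = 173.4,
              S = 89.0, T = 116.1, V = 140.0, W = 227.8, Y = 193.6)
  charge <- setNames(rep(0, 20), AA20)
  charge[c("K", "R")] <- 1
  charge[c("D", "E")] <- -1
  cation <- AA20 %in% c("K", "R")
  aromatic <- AA20 %in% c("F", "W", "Y")
  donor <- AA20 %in% c("R", "K", "W", "N", "Q", "H", "S", "T", "Y")
  acceptor <- AA20 %in% c("D", "E", "N", "Q", "H", "S", "T", "Y")
  hydrophobic <- AA20 %in% c("A", "V", "L", "I", "M", "F", "W", "C", "P", "G")
  data.frame(volume = volume[AA20], charge = charge[AA20], cation = cation,
             aromatic = aromatic, donor = donor, acceptor = acceptor,
             hydrophobic = hydrophobic, row.names = AA20)
}

#' Phi correlation of a residue pair at two alignment columns
#'
#' The phi coefficient of the two binary row indicators "residue at column i
#' equals x" and "residue at column j equals y", i.e. the 2x2 contingency
#' correlation. Defined as 0 when either indicator is constant.
#'
#' @param aln [Alignment]; columns `i` and `j` gap-free.
#' @param i,j Column indices.
#' @param x,y One-letter residue codes.
#' @return Phi in \[-1, 1\].
#' @export
pair_phi <- function(aln, i, j, x, y) {
  stopifnot(inherits(aln, "Alignment"))
  check_ungapped(aln, i)
  check_ungapped(aln, j)
  u <- aln$mat[, i] == x
  v <- aln$mat[, j] == y
  phi_from_counts(sum(u & v), sum(u), sum(v), length(u))
}

phi_from_counts <- function(n11, r1, c1, n) {
  denom <- sqrt(r1) * sqrt(n - r1) * sqrt(c1) * sqrt(n - c1)
  if (denom == 0) return(0)
  n00 <- n - r1 - c1 + n11
  n10 <- r1 - n11
  n01 <- c1 - n11
  (n11 * n00 - n10 * n01) / denom
}

# phi coefficients for every residue combination observed at two columns,
# computed in one pass from the joint contingency table
phi_table <- function(aln, i, j) {
  tab <- table(factor(aln$mat[, i]), factor(aln$mat[, j]))
  n <- sum(tab)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  phi <- tab
  for (a in seq_along(rs)) {
    for (b in seq_along(cs)) {
      phi[a, b] <- phi_from_counts(tab[a, b], rs[a], cs[b], n)
    }
  }
  list(phi = unclass(phi), counts = unclass(tab))
}

#' Pair-transition score between two residue pairs
#'
#' Scores the transition from residue pair (x, y) to (a, b) at a covarying
#' position pair (i, j) as `phi(x,y) + phi(a,b) - phi(x,b) - phi(a,y)`: a
#' transition is significant when it highly favours the two observed pairs
#' and highly disfavours the cross pairs (x,b) and (a,y).
#'
#' @inheritParams pair_phi
#' @param a,b Residues of the second pair.
#' @return The PT score (finite; symmetric under swapping the two pairs).
#' @export
transition_score <- function(aln, i, j, x, y, a, b) {
  pair_phi(aln, i, j, x, y) + pair_phi(aln, i, j, a, b) -
    pair_phi(aln, i, j, x, b) - pair_phi(aln, i, j, a, y)
}

#' Classify a pair transition into a covariation mechanism
#'
#' Assigns the first matching class in the fixed priority order charge,
#' cation-pi, pi-pi, size, hydrogen bonding, other (hydrophobic), other
#' (hydrophilic), other (mixed):
#' \describe{
#'   \item{charge}{one pair carries opposite charges and the transition
#'     either swaps the signs or moves to an uncharged pair; also fires when
#'     the transition avoids like charges in the cross pairs (x,b) or (a,y).}
#'   \item{cation_pi}{exactly one of the two pairs combines a cation with an
#'     aromatic residue.}
#'   \item{pi_pi}{exactly one pair is aromatic-aromatic.}
#'   \item{size}{one position shrinks by at least `size_threshold` cubic
#'     Angstrom (a methyl group, 18 by default) while the other grows by at
#'     least the same amount.}
#'   \item{hbond}{exactly one pair combines a side-chain donor with an
#'     acceptor.}
#'   \item{other_*}{fallback by the hydropathy composition of the four
#'     residues: all hydrophobic, all hydrophilic, or mixed.}
#' }
#'
#' @param x,y Residues of the first pair (positions i and j).
#' @param a,b Residues of the second pair.
#' @param annotations Annotation table, see [residue_annotations()].
#' @param size_threshold Volume change (cubic Angstrom) defining a size
#'   transition; default 18.
#' @return One of `"charge"`, `"cation_pi"`, `"pi_pi"`, `"size"`, `"hbond"`,
#'   `"other_hydrophobic"`, `"other_hydrophilic"`, `"other_mixed"`.
#' @export
classify_transition <- function(x, y, a, b, annotations = residue_annotations(),
                                size_threshold = 18) {
  res <- c(x, y, a, b)
  if (!all(res %in% rownames(annotations))) {
    stop("unannotated residue(s): ",
         paste(setdiff(res, rownames(annotations)), collapse = ", "))
  }
  ch <- annotations[res, "charge"]
  vol <- annotations[res, "volume"]
  cat_ <- annotations[res, "cation"]
  aro <- annotations[res, "aromatic"]
  don <- annotations[res, "donor"]
  acc <- annotations[res, "acceptor"]
  hyd <- annotations[res, "hydrophobic"]

  opp1 <- ch[1] * ch[2] == -1
  opp2 <- ch[3] * ch[4] == -1
  swapped <- opp1 && opp2 && ch[3] == -ch[1] && ch[4] == -ch[2]
  unch1 <- ch[1] == 0 && ch[2] == 0
  unch2 <- ch[3] == 0 && ch[4] == 0
  like_cross <- (ch[1] != 0 && ch[1] == ch[4]) || (ch[2] != 0 && ch[2] == ch[3])
  if ((opp1 && (swapped || unch2)) || (opp2 && (swapped || unch1)) ||
      like_cross) {
    return("charge")
  }

  catpi1 <- (cat_[1] && aro[2]) || (cat_[2] && aro[1])
  catpi2 <- (cat_[3] && aro[4]) || (cat_[4] && aro[3])
  if (xor(catpi1, catpi2)) return("cation_pi")

  if (xor(aro[1] && aro[2], aro[3] && aro[4])) return("pi_pi")

  d1 <- vol[3] - vol[1]
  d2 <- vol[4] - vol[2]
  if ((d1 >= size_threshold && d2 <= -size_threshold) ||
      (d1 <= -size_threshold && d2 >= size_threshold)) {
    return("size")
  }

  hb1 <- (don[1] && acc[2]) || (don[2] && acc[1])
  hb2 <- (don[3] && acc[4]) || (don[4] && acc[3])
  if (xor(hb1, hb2)) return("hbond")

  if (all(hyd)) return("other_hydrophobic")
  if (!any(hyd)) return("other_hydrophilic")
  "other_mixed"
}

#' Top-scoring pair transitions at covarying position pairs
#'
#' For each covarying position pair, candidate transitions are enumerated
#' between the residue pairs actually observed at the two columns (observed
#' at least once; this grounds the phi estimates and bounds the search), the
#' PT score of every unordered candidate is computed, and the `n`
#' highest-scoring transitions are returned with their mechanism class. Ties
#' in PT are broken lexicographically on (x, y, a, b). A position pair with
#' fewer than two distinct observed residue pairs yields no records.
#'
#' @param aln [Alignment].
#' @param pairs Non-empty [pair_set()] of position pairs.
#' @param n Number of transitions to keep per position pair (default 10).
#' @param annotations,size_threshold Passed to [classify_transition()].
#' @return Data frame of `TransitionRecord`s: columns `i`, `j`, `from_x`,
#'   `from_y`, `to_a`, `to_b`, `score`, `mechanism`.
#' @export
top_transitions <- function(aln, pairs, n = 10,
                            annotations = residue_annotations(),
                            size_threshold = 18) {
  stopifnot(inherits(aln, "Alignment"), inherits(pairs, "CovaryingPairSet"))
  if (nrow(pairs$pairs) == 0) stop("empty position pair set")
  out <- list()
  for (r in seq_len(nrow(pairs$pairs))) {
    i <- pairs$pairs[r, 1]
    j <- pairs$pairs[r, 2]
    check_ungapped(aln, i)
    check_ungapped(aln, j)
    pt <- phi_table(aln, i, j)
    obs <- which(pt$counts > 0, arr.ind = TRUE)
    obs <- obs[order(rownames(pt$counts)[obs[, 1]],
                     colnames(pt$counts)[obs[, 2]]), , drop = FALSE]
    if (nrow(obs) < 2) next
    cmb <- combn(nrow(obs), 2)
    xs <- rownames(pt$phi)[obs[cmb[1, ], 1]]
    ys <- colnames(pt$phi)[obs[cmb[1, ], 2]]
    as_ <- rownames(pt$phi)[obs[cmb[2, ], 1]]
    bs <- colnames(pt$phi)[obs[cmb[2, ], 2]]
    score <- pt$phi[cbind(xs, ys)] + pt$phi[cbind(as_, bs)] -
      pt$phi[cbind(xs, bs)] - pt$phi[cbind(as_, ys)]
    ord <- order(-score, xs, ys, as_, bs)
    take <- head(ord, n)
    mech <- vapply(take, function(t) {
      classify_transition(xs[t], ys[t], as_[t], bs[t], annotations,
                          size_threshold)
    }, character(1))
    out[[length(out) + 1L]] <- data.frame(
      i = i, j = j, from_x = xs[take], from_y = ys[take],
      to_a = as_[take], to_b = bs[take], score = unname(score[take]),
      mechanism = mech, row.names = NULL, stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(i = integer(0), j = integer(0), from_x = character(0),
                      from_y = character(0), to_a = character(0),
                      to_b = character(0), score = numeric(0),
                      mechanism = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Distribution of covariation mechanisms
#'
#' @param records Transition records from [top_transitions()].
#' @return Named numeric vector of class fractions over the eight mechanism
#'   classes, summing to 1.
#' @export
mechanism_distribution <- function(records) {
  if (NROW(records) == 0) stop("no transition records: distribution undefined")
  counts <- table(factor(records$mechanism, levels = MECHANISM_CLASSES))
  setNames(as.numeric(counts) / sum(counts), MECHANISM_CLASSES)
}

#' Majority mechanism per position pair
#'
#' Each position pair is assigned the most common mechanism among its top
#' transitions; ties go to the higher-priority class (the earlier class in
#' the fixed priority order).
#'
#' @param records Transition records from [top_transitions()].
#' @return Data frame with columns `i`, `j`, `mechanism`.
#' @export
pair_mechanisms <- function(records) {
  if (NROW(records) == 0) {
    return(data.frame(i = integer(0), j = integer(0),
                      mechanism = character(0), stringsAsFactors = FALSE))
  }
  key <- paste(records$i, records$j, sep = ":")
  res <- lapply(split(records, key), function(d) {
    counts <- table(factor(d$mechanism, levels = MECHANISM_CLASSES))
    win <- MECHANISM_CLASSES[which.max(counts)]  # which.max: first = priority
    data.frame(i = d$i[1], j = d$j[1], mechanism = win,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$i, out$j), , drop = FALSE]
}

#' Percent overlap between two sources for each covariation mechanism
#'
#' Position pairs from two sources (e.g. natural and designed sequences) are
#' each labelled with their majority mechanism; for every class m the percent
#' overlap `100 * 2 C_m / (A_m + B_m)` is computed, where A_m and B_m are the
#' position pairs assigned class m in each source and C_m those assigned m in
#' both. Classes absent from both sources are undefined (`NA`).
#'
#' @param a,b Transition records (from [top_transitions()]) for the two
#'   sources over a shared position-pair universe.
#' @return Named numeric vector of per-class percent overlaps.
#' @export
mechanism_overlap <- function(a, b) {
  ma <- pair_mechanisms(a)
  mb <- pair_mechanisms(b)
  ka <- split(paste(ma$i, ma$j, sep = ":"),
              factor(ma$mechanism, levels = MECHANISM_CLASSES))
  kb <- split(paste(mb$i, mb$j, sep = ":"),
              factor(mb$mechanism, levels = MECHANISM_CLASSES))
  out <- setNames(rep(NA_real_, length(MECHANISM_CLASSES)), MECHANISM_CLASSES)
  for (m in MECHANISM_CLASSES) {
    A <- length(ka[[m]])
    B <- length(kb[[m]])
    if (A + B == 0) next
    C <- length(intersect(ka[[m]], kb[[m]]))
    out[m] <- 100 * 2 * C / (A + B)
  }
  out
}
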