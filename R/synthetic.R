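#' Background amino-acid frequencies
#'
#' Natural-protein background composition (Robinson-Robinson style
#' frequencies), normalized to sum to 1; the default source distribution for
#' background columns of synthetic alignments.
#'
#' @return Named numeric vector over the 20 standard residues.
#' @export
aa_background <- function() {
  f <- c(A = 0.078, R = 0.051, N = 0.045, D = 0.054, C = 0.019,
         Q = 0.043, E = 0.063, G = 0.074, H = 0.022, I = 0.051,
         L = 0.090, K = 0.057, M = 0.022, F = 0.039, P = 0.052,
         S = 0.071, T = 0.058, W = 0.011, Y = 0.032, V = 0.066)
  f <- f[AA20]
  f / sum(f)
}

COUPLING_STATES <- list(
  charge_swap = list(c("R", "E"), c("D", "R")),
  size_comp = list(c("I", "A"), c("V", "V")),
  hbond = list(c("A", "P"), c("S", "S"))
)

#' Define a planted covarying column pair
#'
#' A planted pair couples two columns through a two-state model: each
#' sequence carries either the first or the second residue-pair state. The
#' named mechanisms use canonical states (charge swap RE/DR, size
#' compensation IA/VV, hydrogen bonding AP/SS); `generic_two_state` takes
#' arbitrary states.
#'
#' @param i,j Column indices of the pair.
#' @param mechanism One of `"charge_swap"`, `"size_comp"`, `"hbond"`,
#'   `"generic_two_state"`.
#' @param states For `generic_two_state`: list of two length-2 character
#'   vectors, the residue pairs of the two states.
#' @return List describing the planted pair.
#' @export
planted_pair <- function(i, j,
                         mechanism = c("charge_swap", "size_comp", "hbond",
                                       "generic_two_state"),
                         states = NULL) {
  mechanism <- match.arg(mechanism)
  if (mechanism == "generic_two_state") {
    if (is.null(states) || length(states) != 2 ||
        !all(lengths(states) == 2)) {
      stop("generic_two_state requires `states`: a list of two residue pairs")
    }
  } else {
    states <- COUPLING_STATES[[mechanism]]
  }
  if (i == j) stop("a planted pair needs two distinct columns")
  list(i = as.integer(min(i, j)), j = as.integer(max(i, j)),
       mechanism = mechanism, states = states)
}

#' Specification of a synthetic alignment
#'
#' Bundles and validates the generator parameters. Defaults are the
#' package's standard study conditions: 500 sequences by 50 columns,
#' natural background composition, balanced two-state coupling, 5%
#' per-position substitution noise at planted positions, no redundancy.
#'
#' @param n_seq Number of sequences.
#' @param n_col Number of columns.
#' @param background Amino-acid distribution for background columns.
#' @param planted_pairs List of [planted_pair()] objects with disjoint
#'   position support.
#' @param state_balance Fraction of sequences in the first coupled state,
#'   in (0, 1).
#' @param noise Per-position substitution probability at planted positions,
#'   in \[0, 0.5).
#' @param redundancy Fraction of sequences that are duplicates of other
#'   sequences, in \[0, 1).
#' @param seed Integer master seed; every sub-stream derives from it.
#' @return Object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(n_seq = 500, n_col = 50,
                           background = aa_background(),
                           planted_pairs = list(), state_balance = 0.5,
                           noise = 0.05, redundancy = 0, seed = 1) {
  stopifnot(n_seq >= 2, n_col >= 2)
  if (state_balance <= 0 || state_balance >= 1) {
    stop("state_balance must lie in (0, 1)")
  }
  if (noise < 0 || noise >= 0.5) stop("noise must lie in [0, 0.5)")
  if (redundancy < 0 || redundancy >= 1) stop("redundancy must lie in [0, 1)")
  pos <- unlist(lapply(planted_pairs, function(p) c(p$i, p$j)))
  if (anyDuplicated(pos)) {
    stop("planted pairs must have disjoint position support")
  }
  if (length(pos) && max(pos) > n_col) {
    stop("planted position ", max(pos), " exceeds n_col = ", n_col)
  }
  if (!is.null(names(background))) background <- background[AA20]
  background <- background / sum(background)
  structure(list(n_seq = n_seq, n_col = n_col, background = background,
                 planted_pairs = planted_pairs,
                 state_balance = state_balance, noise = noise,
                 redundancy = redundancy, seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' Generate a synthetic alignment with planted covariation
#'
#' Background columns are i.i.d. draws from the background distribution; at
#' each planted pair every sequence adopts one of the two coupled states by a
#' Bernoulli(`state_balance`) draw, after which substitution noise is applied
#' independently at each planted position (replacement drawn from the
#' background). If `redundancy > 0`, that fraction of the output rows are
#' verbatim duplicates of other rows. Output is deterministic for a fixed
#' seed.
#'
#' @param spec [synthetic_spec()].
#' @return [Alignment] of `spec$n_seq` sequences.
#' @export
generate_alignment <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  with_seed(spec$seed, {
    n_dup <- round(spec$redundancy * spec$n_seq)
    n_base <- spec$n_seq - n_dup
    mat <- matrix(sample(AA20, n_base * spec$n_col, replace = TRUE,
                         prob = spec$background),
                  nrow = n_base, ncol = spec$n_col)
    for (p in spec$planted_pairs) {
      state1 <- runif(n_base) < spec$state_balance
      mat[state1, p$i] <- p$states[[1]][1]
      mat[state1, p$j] <- p$states[[1]][2]
      mat[!state1, p$i] <- p$states[[2]][1]
      mat[!state1, p$j] <- p$states[[2]][2]
      for (col in c(p$i, p$j)) {
        hit <- runif(n_base) < spec$noise
        if (any(hit)) {
          mat[hit, col] <- sample(AA20, sum(hit), replace = TRUE,
                                  prob = spec$background)
        }
      }
    }
    rows <- apply(mat, 1, paste, collapse = "")
    ids <- sprintf("syn%04d", seq_len(n_base))
    if (n_dup > 0) {
      src <- sample.int(n_base, n_dup, replace = TRUE)
      rows <- c(rows, rows[src])
      ids <- c(ids, sprintf("syn%04d_dup%03d", src, seq_len(n_dup)))
    }
    Alignment(ids, rows)
  })
}

#' Generate two alignments with controlled planted-pair overlap
#'
#' Produces two independently realized alignments whose planted position
#' pairs overlap in exactly `round(shared_fraction * n_pairs)` pairs: the
#' shared pairs keep the positions and mechanism of the first alignment's
#' spec, and each non-shared pair of the second alignment is moved to the
#' lowest-numbered free columns (keeping its mechanism). The second
#' alignment's sequences use an independent sub-stream of the master seed.
#'
#' @param spec [synthetic_spec()] for the first alignment.
#' @param shared_fraction Fraction of planted pairs shared, in \[0, 1\].
#' @return List with `a`, `b` ([Alignment]s), and `planted_a`, `planted_b`
#'   (the two planted-pair lists).
#' @export
generate_alignment_pair <- function(spec, shared_fraction) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  if (shared_fraction < 0 || shared_fraction > 1) {
    stop("shared_fraction must lie in [0, 1]")
  }
  m <- length(spec$planted_pairs)
  n_shared <- round(shared_fraction * m)
  planted_a <- spec$planted_pairs
  used <- unlist(lapply(planted_a, function(p) c(p$i, p$j)))
  free <- setdiff(seq_len(spec$n_col), used)
  planted_b <- planted_a
  if (m > n_shared) {
    for (k in seq.int(n_shared + 1L, m)) {
      if (length(free) < 2) {
        stop("not enough free columns to relocate non-shared planted pairs")
      }
      planted_b[[k]]$i <- free[1]
      planted_b[[k]]$j <- free[2]
      free <- free[-(1:2)]
    }
  }
  spec_b <- spec
  spec_b$planted_pairs <- planted_b
  spec_b$seed <- spec$seed + 1L
  list(a = generate_alignment(spec), b = generate_alignment(spec_b),
       planted_a = planted_a, planted_b = planted_b)
}

unit_vec <- function(v) v / sqrt(sum(v^2))

random_unit <- function() unit_vec(rnorm(3))

#' Generate a toy protein structure with planted contacts
#'
#' Builds a backbone-like chain of pseudo-residues (N, CA, C, CB heavy
#' atoms) along a self-avoiding correlated random walk with a 3.8 Angstrom
#' CA-CA step, then relocates the second residue of each planted pair next
#' to the first so that the pair's minimum heavy-atom distance is below 6
#' Angstrom. Deterministic for a fixed seed.
#'
#' @param n_col Number of residues (alignment columns).
#' @param planted_pairs List of [planted_pair()] objects (or any list of
#'   `list(i =, j =)`); pairs are made spatially proximal.
#' @param seed Integer seed.
#' @return [structure_model()] with positions `1:n_col`.
#' @export
generate_structure <- function(n_col, planted_pairs = list(), seed = 1) {
  stopifnot(n_col >= 2)
  pos <- unlist(lapply(planted_pairs, function(p) c(p$i, p$j)))
  if (length(pos) && (max(pos) > n_col || anyDuplicated(pos))) {
    stop("planted pairs must fit in n_col with disjoint support")
  }
  with_seed(seed, {
    ca <- matrix(NA_real_, n_col, 3)
    ca[1, ] <- c(0, 0, 0)
    dir <- random_unit()
    for (k in 2:n_col) {
      placed <- FALSE
      for (try in 1:200) {
        cand_dir <- unit_vec(0.6 * dir + 0.4 * random_unit())
        cand <- ca[k - 1, ] + 3.8 * cand_dir
        prev <- ca[seq_len(k - 2), , drop = FALSE]
        if (nrow(prev) == 0 ||
            min(sqrt(rowSums(sweep(prev, 2, cand)^2))) > 4.0) {
          ca[k, ] <- cand
          dir <- cand_dir
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("self-avoiding walk failed; geometry infeasible")
    }
    atoms <- vector("list", n_col)
    for (k in seq_len(n_col)) {
      u1 <- random_unit()
      u2 <- unit_vec(u1 + 0.8 * random_unit())
      n_at <- ca[k, ] - 1.46 * u1
      c_at <- ca[k, ] + 1.52 * u2
      cb_at <- virtual_cb(n_at, ca[k, ], c_at)
      atoms[[k]] <- data.frame(
        pos = k, res_name = "ALA",
        atom = c("N", "CA", "C", "CB"),
        element = c("N", "C", "C", "C"),
        x = c(n_at[1], ca[k, 1], c_at[1], cb_at[1]),
        y = c(n_at[2], ca[k, 2], c_at[2], cb_at[2]),
        z = c(n_at[3], ca[k, 3], c_at[3], cb_at[3]),
        chain = "A", stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, atoms)
    for (p in planted_pairs) {
      sel <- df$pos == p$j
      old_ca <- as.numeric(df[df$pos == p$j & df$atom == "CA",
                              c("x", "y", "z")])
      target <- as.numeric(df[df$pos == p$i & df$atom == "CA",
                              c("x", "y", "z")]) + 4.5 * random_unit()
      shift <- target - old_ca
      df$x[sel] <- df$x[sel] + shift[1]
      df$y[sel] <- df$y[sel] + shift[2]
      df$z[sel] <- df$z[sel] + shift[3]
    }
    structure_model(df)
  })
}

#' Generate a conformational ensemble of toy structures
#'
#' Takes the [generate_structure()] model as the base conformation and adds
#' independent isotropic Gaussian jitter (SD `jitter` Angstrom per
#' coordinate) to every atom of every member.
#'
#' @inheritParams generate_structure
#' @param n_models Ensemble size.
#' @param jitter Per-coordinate Gaussian SD in Angstrom; 0 gives identical
#'   members.
#' @return List of [structure_model()] objects.
#' @export
generate_structure_ensemble <- function(n_col, planted_pairs = list(),
                                        n_models = 10, jitter = 0.5,
                                        seed = 1) {
  base <- generate_structure(n_col, planted_pairs, seed = seed)
  with_seed(seed + 1L, {
    lapply(seq_len(n_models), function(m) {
      df <- base$atoms
      df$x <- df$x + rnorm(nrow(df), sd = jitter)
      df$y <- df$y + rnorm(nrow(df), sd = jitter)
      df$z <- df$z + rnorm(nrow(df), sd = jitter)
      structure_model(df)
    })
  })
}
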