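# integer-encode an alignment: 1..20 over AA20, NA for gaps
encode_alignment <- function(aln) {
  m <- match(aln$mat, AA20)
  dim(m) <- dim(aln$mat)
  m
}

check_ungapped <- function(aln, i) {
  if (any(aln$mat[, i] == GAP)) {
    stop("column ", i, " contains gap characters; covariation statistics ",
         "are defined for ungapped columns only")
  }
}

entropy_from_counts <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Shannon entropy of an alignment column
#'
#' Entropy in bits, `-sum_x P_x log2 P_x`, where `P_x` is the raw frequency
#' (counts / number of sequences, no pseudocounts) of amino acid `x` at the
#' column. The `0 * log 0 = 0` convention applies.
#'
#' @param aln [Alignment].
#' @param i Column index (1-based); the column must be gap-free.
#' @return Entropy in bits, in \[0, log2(20)\].
#' @export
column_entropy <- function(aln, i) {
  stopifnot(inherits(aln, "Alignment"))
  check_ungapped(aln, i)
  entropy_from_counts(tabulate(match(aln$mat[, i], AA20), nbins = 20L))
}

#' Joint Shannon entropy of two alignment columns
#'
#' `-sum_{x,y} P_{x,y} log2 P_{x,y}` over residue pairs read row-wise, in bits.
#'
#' @param aln [Alignment].
#' @param i,j Distinct gap-free column indices.
#' @return Joint entropy in bits.
#' @export
joint_entropy <- function(aln, i, j) {
  stopifnot(inherits(aln, "Alignment"))
  if (i == j) stop("i and j must differ; use column_entropy() for a single column")
  check_ungapped(aln, i)
  check_ungapped(aln, j)
  ci <- match(aln$mat[, i], AA20)
  cj <- match(aln$mat[, j], AA20)
  entropy_from_counts(tabulate((ci - 1L) * 20L + cj, nbins = 400L))
}

#' Mutual information between two alignment columns
#'
#' `MI(i, j) = H(i) + H(j) - H(i, j)` in bits; tiny negative values from
#' floating-point cancellation are clamped to zero.
#'
#' @inheritParams joint_entropy
#' @return MI in bits, `0 <= MI <= min(H(i), H(j))`.
#' @export
mutual_information <- function(aln, i, j) {
  mi <- column_entropy(aln, i) + column_entropy(aln, j) - joint_entropy(aln, i, j)
  max(mi, 0)
}

#' Mutual information matrix over a set of ungapped columns
#'
#' @param aln [Alignment].
#' @param columns Integer vector of gap-free columns (default: all, via
#'   [ungapped_columns()]).
#' @return Symmetric matrix of MI values (bits) with zero diagonal; dimnames
#'   carry the original column indices.
#' @export
mi_matrix <- function(aln, columns = ungapped_columns(aln)) {
  stopifnot(inherits(aln, "Alignment"))
  for (i in columns) check_ungapped(aln, i)
  code <- encode_alignment(aln)[, columns, drop = FALSE]
  m <- length(columns)
  h <- vapply(seq_len(m), function(k) {
    entropy_from_counts(tabulate(code[, k], nbins = 20L))
  }, numeric(1))
  mi <- matrix(0, m, m, dimnames = list(columns, columns))
  if (m >= 2) {
    for (a in seq_len(m - 1L)) {
      base <- (code[, a] - 1L) * 20L
      for (b in seq.int(a + 1L, m)) {
        hj <- entropy_from_counts(tabulate(base + code[, b], nbins = 400L))
        mi[a, b] <- mi[b, a] <- max(h[a] + h[b] - hj, 0)
      }
    }
  }
  attr(mi, "H") <- setNames(h, columns)
  mi
}

#' Average-product correction of a mutual information matrix
#'
#' Subtracts the background mutual information expected from per-column noise
#' and shared ancestry: `MIp(i,j) = MI(i,j) - mean_i * mean_j / mean`, where
#' `mean_i` is the mean MI of column i with all other columns and `mean` is
#' the overall off-diagonal mean. If the overall mean is zero the correction
#' is defined as zero and `MIp == 0` everywhere.
#'
#' @param mi Square symmetric MI matrix over at least 3 columns.
#' @return Symmetric MIp matrix with zero diagonal.
#' @export
apc_correction <- function(mi) {
  stopifnot(is.matrix(mi), nrow(mi) == ncol(mi))
  n <- nrow(mi)
  if (n < 3) {
    stop("APC is undefined for fewer than 3 columns (got ", n, ")")
  }
  if (max(abs(mi - t(mi))) > 1e-9) stop("MI matrix must be symmetric")
  diag(mi) <- 0
  mbar_i <- rowSums(mi) / (n - 1)
  mbar <- sum(mi) / (n * (n - 1))
  if (mbar == 0) {
    mip <- matrix(0, n, n, dimnames = dimnames(mi))
    return(mip)
  }
  mip <- mi - outer(mbar_i, mbar_i) / mbar
  diag(mip) <- 0
  mip
}

#' Doubly column-normalized covariation score (Zpx)
#'
#' For each pair (i, j) the MIp value is converted to two z-scores, one
#' within column i and one within column j (off-diagonal entries only,
#' population SD); the z-scores are multiplied and the final score is the
#' signed square root: `Zpx = sign(z_i z_j) * sqrt(|z_i z_j|)`. A column with
#' zero SD contributes a z-score of 0.
#'
#' @param mip Symmetric MIp matrix from [apc_correction()].
#' @return Symmetric Zpx matrix with zero diagonal.
#' @export
zpx_matrix <- function(mip) {
  stopifnot(is.matrix(mip), nrow(mip) == ncol(mip), nrow(mip) >= 3)
  n <- nrow(mip)
  z <- matrix(0, n, n, dimnames = dimnames(mip))
  for (i in seq_len(n)) {
    v <- mip[i, -i]
    mu <- mean(v)
    s <- pop_sd(v)
    if (s > 0) z[i, ] <- (mip[i, ] - mu) / s
  }
  prod <- z * t(z)
  out <- sign(prod) * sqrt(abs(prod))
  diag(out) <- 0
  out
}

#' Full covariation analysis of an alignment
#'
#' Computes per-column entropies, the MI matrix over ungapped columns, the
#' average-product-corrected MIp and the final Zpx score, plus the mean and
#' population SD of Zpx over all unordered column pairs (used by the
#' covarying-pair threshold).
#'
#' @param aln [Alignment].
#' @param columns Gap-free columns to analyse (default all ungapped); at
#'   least 3 are required.
#' @return An object of class `CovariationResult`: list with `columns`, `H`,
#'   `MI`, `MIp`, `Zpx`, `mean_zpx`, `sd_zpx`.
#' @export
covariation <- function(aln, columns = ungapped_columns(aln)) {
  if (length(columns) < 3) {
    stop("covariation analysis requires at least 3 ungapped columns, got ",
         length(columns))
  }
  mi <- mi_matrix(aln, columns)
  h <- attr(mi, "H")
  attr(mi, "H") <- NULL
  mip <- apc_correction(mi)
  zpx <- zpx_matrix(mip)
  vals <- zpx[upper.tri(zpx)]
  structure(
    list(columns = as.integer(columns), H = h, MI = mi, MIp = mip, Zpx = zpx,
         mean_zpx = mean(vals), sd_zpx = pop_sd(vals)),
    class = "CovariationResult"
  )
}

#' @export
print.CovariationResult <- function(x, ...) {
  cat("CovariationResult over", length(x$columns), "ungapped columns\n")
  cat(sprintf("  Zpx: mean %.4f, sd %.4f, max %.4f\n",
              x$mean_zpx, x$sd_zpx, max(x$Zpx[upper.tri(x$Zpx)])))
  invisible(x)
}

#' Construct a set of covarying column pairs
#'
#' @param pairs Two-column integer matrix of unordered column pairs (each row
#'   i < j, 1-based alignment columns).
#' @param columns The column universe the pairs are drawn from.
#' @param threshold,k Optional Zpx threshold and SD multiplier that produced
#'   the set.
#' @return Object of class `CovaryingPairSet`.
#' @export
pair_set <- function(pairs, columns, threshold = NA_real_, k = NA_real_) {
  pairs <- matrix(as.integer(pairs), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  if (nrow(pairs)) {
    swap <- pairs[, 1] > pairs[, 2]
    pairs[swap, ] <- pairs[swap, c(2, 1)]
    if (any(pairs[, 1] == pairs[, 2])) stop("pairs must have i != j")
    if (!all(pairs %in% columns)) {
      stop("pair indices outside the column universe")
    }
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
    pairs <- pairs[!duplicated(pair_key(pairs)), , drop = FALSE]
  }
  structure(list(pairs = pairs, columns = as.integer(columns),
                 threshold = threshold, k = k),
            class = "CovaryingPairSet")
}

pair_key <- function(pairs) {
  if (is.null(dim(pairs))) pairs <- matrix(pairs, ncol = 2)
  paste(pairs[, 1], pairs[, 2], sep = ":")
}

#' @export
print.CovaryingPairSet <- function(x, ...) {
  cat("CovaryingPairSet:", nrow(x$pairs), "pairs over",
      length(x$columns), "columns")
  if (!is.na(x$threshold)) {
    cat(sprintf(" (Zpx >= %.4f, mean + %g SD)", x$threshold, x$k))
  }
  cat("\n")
  invisible(x)
}

#' Select highly covarying column pairs
#'
#' A pair is highly covarying if its Zpx is at least `k` standard deviations
#' above the mean Zpx (inclusive), mean and population SD taken over all
#' unordered off-diagonal pairs within the analysed columns. A flat score
#' landscape (SD of Zpx equal to 0) carries no signal and yields the empty
#' set.
#'
#' @param result [covariation()] result.
#' @param k SD multiplier (default 2).
#' @return A [pair_set()] with the threshold recorded.
#' @export
top_covarying_pairs <- function(result, k = 2) {
  stopifnot(inherits(result, "CovariationResult"))
  ut <- which(upper.tri(result$Zpx), arr.ind = TRUE)
  if (nrow(ut) < 2) {
    stop("need at least 2 eligible column pairs to set a threshold")
  }
  vals <- result$Zpx[ut]
  thr <- result$mean_zpx + k * result$sd_zpx
  if (result$sd_zpx == 0) {
    sel <- integer(0)
  } else {
    sel <- which(vals >= thr)
  }
  pairs <- cbind(result$columns[ut[sel, 1]], result$columns[ut[sel, 2]])
  pair_set(pairs, result$columns, threshold = thr, k = k)
}

#' Restrict a pair set to a smaller column universe
#'
#' Keeps only pairs whose two columns both lie in `columns`; used to place
#' two pair sets on a shared sample space before overlap statistics.
#'
#' @param set [pair_set()].
#' @param columns New column universe.
#' @return A [pair_set()] over `columns`.
#' @export
restrict_pairs <- function(set, columns) {
  stopifnot(inherits(set, "CovaryingPairSet"))
  keep <- set$pairs[, 1] %in% columns & set$pairs[, 2] %in% columns
  pair_set(set$pairs[keep, , drop = FALSE], columns,
           threshold = set$threshold, k = set$k)
}
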