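AA19 <- setdiff(AA20, "C")

#' Amino acid pair propensities at covarying positions
#'
#' For every unordered residue pair (x, y), the propensity
#' `PP(x, y) = f_obs(x, y) / f_exp(x, y)` compares the observed frequency of
#' the pair, pooled over all sequences and all supplied covarying position
#' pairs, with the frequency expected from the pooled single-residue
#' frequencies under independence. Position pairs are unordered, so
#' observations are symmetrized and the expected frequency is
#' `2 f(x) f(y)` for x != y and `f(x)^2` on the diagonal. Observations
#' containing cysteine are dropped before any normalization (cysteine rarely
#' appears in designed sequences and would distort the table). Cells with
#' zero expected frequency are undefined (`NA`) and excluded from z-scoring;
#' z-scores are computed over the defined cells of the table (upper triangle
#' including the diagonal, population SD).
#'
#' @param aln [Alignment] with gap-free columns at all pair positions.
#' @param pairs Non-empty [pair_set()] of covarying position pairs.
#' @param expected_from `"pairs"` (default) computes single-residue
#'   frequencies from the covarying positions themselves; `"alignment"` uses
#'   all ungapped columns of the alignment.
#' @return Object of class `PropensityTable`: list with 19x19 symmetric
#'   matrices `counts`, `pp`, `z`, the single-residue frequencies `f`, and
#'   `n_obs`.
#' @export
pair_propensity <- function(aln, pairs, expected_from = c("pairs", "alignment")) {
  stopifnot(inherits(aln, "Alignment"), inherits(pairs, "CovaryingPairSet"))
  expected_from <- match.arg(expected_from)
  if (nrow(pairs$pairs) == 0) {
    stop("empty covarying pair set: propensities are undefined")
  }
  counts <- matrix(0, 19, 19, dimnames = list(AA19, AA19))
  singles <- setNames(numeric(19), AA19)
  n_obs <- 0L
  for (r in seq_len(nrow(pairs$pairs))) {
    i <- pairs$pairs[r, 1]
    j <- pairs$pairs[r, 2]
    check_ungapped(aln, i)
    check_ungapped(aln, j)
    x <- aln$mat[, i]
    y <- aln$mat[, j]
    keep <- x != "C" & y != "C"
    x <- x[keep]
    y <- y[keep]
    n_obs <- n_obs + length(x)
    for (s in seq_along(x)) {
      counts[x[s], y[s]] <- counts[x[s], y[s]] + 1
      if (x[s] != y[s]) counts[y[s], x[s]] <- counts[y[s], x[s]] + 1
      singles[x[s]] <- singles[x[s]] + 1
      singles[y[s]] <- singles[y[s]] + 1
    }
  }
  if (n_obs == 0) stop("all pair observations contained cysteine")
  f_obs <- counts / n_obs
  if (expected_from == "pairs") {
    f <- singles / sum(singles)
  } else {
    cols <- ungapped_columns(aln)
    tab <- tabulate(match(aln$mat[, cols], AA20), nbins = 20L)
    names(tab) <- AA20
    tab <- tab[AA19]
    f <- tab / sum(tab)
  }
  f_exp <- 2 * outer(f, f)
  diag(f_exp) <- f^2
  pp <- ifelse(f_exp > 0, f_obs / f_exp, NA_real_)
  ut <- upper.tri(pp, diag = TRUE)
  vals <- pp[ut & !is.na(pp)]
  z <- matrix(NA_real_, 19, 19, dimnames = list(AA19, AA19))
  if (length(vals) >= 2 && pop_sd(vals) > 0) {
    z[] <- (pp - mean(vals)) / pop_sd(vals)
    z[is.na(pp)] <- NA_real_
  }
  structure(list(counts = counts, pp = pp, z = z, f = f, n_obs = n_obs),
            class = "PropensityTable")
}

#' @export
print.PropensityTable <- function(x, ...) {
  ut <- upper.tri(x$pp, diag = TRUE)
  def <- sum(!is.na(x$pp[ut]))
  cat("PropensityTable:", x$n_obs, "pair observations,",
      def, "of", sum(ut), "cells defined\n")
  top <- which(x$pp == max(x$pp, na.rm = TRUE), arr.ind = TRUE)[1, ]
  cat(sprintf("  top propensity: %s-%s (PP = %.2f)\n",
              AA19[top[1]], AA19[top[2]], max(x$pp, na.rm = TRUE)))
  invisible(x)
}

#' Correlation between two propensity tables
#'
#' Pearson correlation of the z-scored propensities over cells defined in
#' both tables (unordered residue pairs; upper triangle including the
#' diagonal).
#'
#' @param a,b [pair_propensity()] tables over the same alphabet.
#' @return Pearson r.
#' @export
propensity_correlation <- function(a, b) {
  stopifnot(inherits(a, "PropensityTable"), inherits(b, "PropensityTable"))
  ut <- upper.tri(a$z, diag = TRUE)
  mutual <- ut & !is.na(a$z) & !is.na(b$z)
  if (sum(mutual) < 3) {
    stop("fewer than 3 mutually defined cells; correlation is undefined")
  }
  cor(a$z[mutual], b$z[mutual])
}
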