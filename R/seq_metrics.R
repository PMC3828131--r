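#' Native sequence recovery of a designed alignment
#'
#' Mean percent identity of each designed row to the native sequence (e.g.
#' the sequence of the crystal structure used as design input). A position
#' counts as recovered when the row carries the same, non-gap, residue as the
#' native sequence; the denominator is the alignment length.
#'
#' @param designed [Alignment] of designed sequences.
#' @param native Native sequence (string or character vector) of length
#'   `n_col`.
#' @return Mean percent identity in \[0, 100\].
#' @export
sequence_recovery <- function(designed, native) {
  stopifnot(inherits(designed, "Alignment"))
  if (is.character(native) && length(native) == 1) {
    native <- strsplit(toupper(native), "")[[1]]
  }
  if (length(native) != designed$n_col) {
    stop("native sequence length (", length(native),
         ") does not match alignment columns (", designed$n_col, ")")
  }
  hits <- sweep(designed$mat, 2, native, FUN = "==") & designed$mat != GAP
  mean(rowSums(hits) / designed$n_col) * 100
}

#' Per-column entropy profile
#'
#' [column_entropy()] applied to every ungapped column; columns containing a
#' gap are reported as `NA` (entropy with gaps is undefined under the
#' package's strict ungapped-column convention).
#'
#' @param aln [Alignment].
#' @return Numeric vector of length `n_col`, entropy in bits or `NA`.
#' @export
entropy_profile <- function(aln) {
  stopifnot(inherits(aln, "Alignment"))
  out <- rep(NA_real_, aln$n_col)
  for (i in ungapped_columns(aln)) out[i] <- column_entropy(aln, i)
  out
}

# Jensen-Shannon divergence in bits, normalized to [0, 1]
js_divergence <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    keep <- a > 0
    sum(a[keep] * log2(a[keep] / b[keep]))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

column_freqs <- function(aln, i) {
  tabulate(match(aln$mat[, i], AA20), nbins = 20L) / aln$n_seq
}

#' Profile similarity between two alignments
#'
#' Column-wise comparison of amino-acid frequency profiles as the product of
#' two scores: the estimated probability that the two column distributions
#' share a source distribution, instantiated as `1 - JS(p, q)`, and the prior
#' informativeness of that source, instantiated as `JS(m, background)` with
#' `m = (p + q) / 2`; JS is the Jensen-Shannon divergence in bits, bounded by
#' 1. A column scores high iff the two profiles agree with each other and
#' differ from the background. The value returned is the mean score over
#' mutually ungapped columns. This is a JS-divergence instantiation of the
#' two-factor profile-similarity description and is not calibrated against
#' any external implementation.
#'
#' @param a,b [Alignment] objects with equal `n_col`, columns paired by
#'   index.
#' @param background Reference amino-acid distribution (named or ordered as
#'   the 20 standard residues); default uniform.
#' @return Mean per-column score in \[0, 1\].
#' @export
profile_similarity <- function(a, b, background = rep(1 / 20, 20)) {
  stopifnot(inherits(a, "Alignment"), inherits(b, "Alignment"))
  if (a$n_col != b$n_col) {
    stop("alignments must share a column frame (", a$n_col, " vs ", b$n_col, ")")
  }
  if (!is.null(names(background))) background <- background[AA20]
  background <- background / sum(background)
  cols <- intersect(ungapped_columns(a), ungapped_columns(b))
  if (length(cols) == 0) {
    stop("no mutually ungapped columns between the two alignments")
  }
  scores <- vapply(cols, function(i) {
    p <- column_freqs(a, i)
    q <- column_freqs(b, i)
    (1 - js_divergence(p, q)) * js_divergence((p + q) / 2, background)
  }, numeric(1))
  mean(scores)
}
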