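check_same_universe <- function(a, b) {
  stopifnot(inherits(a, "CovaryingPairSet"), inherits(b, "CovaryingPairSet"))
  if (!identical(a$columns, b$columns)) {
    stop("pair sets are drawn from different column universes; ",
         "restrict both to a shared set of columns first (see restrict_pairs)")
  }
}

#' Percent overlap between two sets of covarying pairs
#'
#' The covariation similarity `100 * 2C / (A + B)`, where A and B are the two
#' set sizes and C the number of shared pairs. Symmetric in its arguments;
#' defined as 0 when both sets are empty.
#'
#' @param a,b [pair_set()] objects over the same column universe.
#' @return Percent overlap in \[0, 100\].
#' @export
overlap_similarity <- function(a, b) {
  check_same_universe(a, b)
  A <- nrow(a$pairs)
  B <- nrow(b$pairs)
  if (A + B == 0) return(0)
  C <- length(intersect(pair_key(a$pairs), pair_key(b$pairs)))
  100 * 2 * C / (A + B)
}

#' Hypergeometric significance of pair-set overlap
#'
#' Upper-tail probability `P(X >= C)` of observing at least the actual
#' overlap when `|b|` pairs are drawn without replacement from a universe of
#' `universe` pairs of which `|a|` are marked; the observed count is included
#' in the tail (standard enrichment convention).
#'
#' @param a,b [pair_set()] objects over the same column universe.
#' @param universe Number of eligible column pairs; defaults to all unordered
#'   pairs of the shared column universe.
#' @return P-value in (0, 1\].
#' @export
overlap_pvalue <- function(a, b, universe = NULL) {
  check_same_universe(a, b)
  if (is.null(universe)) universe <- choose(length(a$columns), 2)
  A <- nrow(a$pairs)
  B <- nrow(b$pairs)
  C <- length(intersect(pair_key(a$pairs), pair_key(b$pairs)))
  if (length(union(pair_key(a$pairs), pair_key(b$pairs))) > universe) {
    stop("universe (", universe, ") smaller than the union of the two sets")
  }
  phyper(C - 1, A, universe - A, B, lower.tail = FALSE)
}

#' Overlap report for two covarying pair sets
#'
#' @inheritParams overlap_pvalue
#' @return Object of class `OverlapReport`: list with `n_a`, `n_b`,
#'   `n_overlap`, `percent_overlap`, `p_value`, `universe`.
#' @export
overlap_report <- function(a, b, universe = NULL) {
  check_same_universe(a, b)
  if (is.null(universe)) universe <- choose(length(a$columns), 2)
  C <- length(intersect(pair_key(a$pairs), pair_key(b$pairs)))
  structure(
    list(n_a = nrow(a$pairs), n_b = nrow(b$pairs), n_overlap = C,
         percent_overlap = overlap_similarity(a, b),
         p_value = overlap_pvalue(a, b, universe),
         universe = universe),
    class = "OverlapReport"
  )
}

#' @export
print.OverlapReport <- function(x, ...) {
  cat(sprintf(
    "Overlap: %d of A=%d, B=%d pairs shared (%.1f%%), p = %.3g (universe %d)\n",
    x$n_overlap, x$n_a, x$n_b, x$percent_overlap, x$p_value, x$universe))
  invisible(x)
}

#' Split covarying pairs into sequence-near and sequence-far subsets
#'
#' "Near" pairs are separated by `cutoff` residues or fewer in sequence
#' (inclusive); the rest are "far".
#'
#' @param set [pair_set()].
#' @param cutoff Sequence-separation cutoff in residues (default 10).
#' @return List with `near` and `far`, both [pair_set()] objects.
#' @export
split_near_far <- function(set, cutoff = 10) {
  stopifnot(inherits(set, "CovaryingPairSet"))
  sep <- set$pairs[, 2] - set$pairs[, 1]
  near <- sep <= cutoff
  list(
    near = pair_set(set$pairs[near, , drop = FALSE], set$columns,
                    threshold = set$threshold, k = set$k),
    far = pair_set(set$pairs[!near, , drop = FALSE], set$columns,
                   threshold = set$threshold, k = set$k)
  )
}

#' Classify pairs as shared or specific to one set
#'
#' Set algebra on two covarying pair sets: `overlap` holds pairs in both,
#' `a_specific` pairs only in the first and `b_specific` pairs only in the
#' second; the three sets are disjoint and their union is the union of the
#' inputs.
#'
#' @param a,b [pair_set()] objects over the same column universe (for the
#'   natural-versus-designed comparison, `a` is the natural set).
#' @return Object of class `PairClassification`: list with `overlap`,
#'   `a_specific`, `b_specific` ([pair_set()] objects).
#' @export
classify_pairs <- function(a, b) {
  check_same_universe(a, b)
  ka <- pair_key(a$pairs)
  kb <- pair_key(b$pairs)
  structure(
    list(
      overlap = pair_set(a$pairs[ka %in% kb, , drop = FALSE], a$columns),
      a_specific = pair_set(a$pairs[!(ka %in% kb), , drop = FALSE], a$columns),
      b_specific = pair_set(b$pairs[!(kb %in% ka), , drop = FALSE], b$columns)
    ),
    class = "PairClassification"
  )
}

#' @export
print.PairClassification <- function(x, ...) {
  cat("PairClassification: overlap", nrow(x$overlap$pairs),
      "| a-specific", nrow(x$a_specific$pairs),
      "| b-specific", nrow(x$b_specific$pairs), "\n")
  invisible(x)
}
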