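#' Construct a validated multiple sequence alignment
#'
#' An `Alignment` is the substrate of every sequence statistic in the package:
#' a set of equal-length rows over the 20 standard amino acids plus the gap
#' symbol `-`. Rows are case-normalized to upper case and `.` gaps (Stockholm
#' convention) are rewritten as `-`.
#'
#' @param ids Character vector of unique sequence identifiers.
#' @param rows Character vector of aligned sequences, same length as `ids`.
#' @return An object of class `Alignment` with components `ids`, `rows`,
#'   `mat` (character matrix, one row per sequence), `n_seq` and `n_col`.
#' @examples
#' aln <- Alignment(c("s1", "s2"), c("AC-D", "ACWD"))
#' aln$n_col
#' @export
Alignment <- function(ids, rows) {
  if (!is.character(ids) || !is.character(rows) || length(ids) != length(rows)) {
    stop("`ids` and `rows` must be character vectors of equal length")
  }
  if (length(rows) < 1) {
    stop("an alignment requires at least 1 sequence")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  rows <- toupper(gsub(".", GAP, rows, fixed = TRUE))
  len <- nchar(rows)
  if (length(unique(len)) != 1L) {
    stop("alignment rows have unequal lengths (",
         paste(sort(unique(len)), collapse = ", "),
         "); sequences must share one column frame")
  }
  if (len[1] < 2) {
    stop("an alignment requires at least 2 columns, got ", len[1])
  }
  mat <- matrix(unlist(strsplit(rows, "", fixed = TRUE), use.names = FALSE),
                nrow = length(rows), byrow = TRUE)
  bad <- !(mat %in% c(AA20, GAP))
  if (any(bad)) {
    hit <- which(matrix(bad, nrow = nrow(mat)), arr.ind = TRUE)[1, ]
    stop("character '", mat[hit[1], hit[2]], "' outside the amino-acid ",
         "alphabet in sequence '", ids[hit[1]], "', column ", hit[2])
  }
  structure(
    list(ids = ids, rows = rows, mat = mat,
         n_seq = length(rows), n_col = unname(len[1])),
    class = "Alignment"
  )
}

#' @export
print.Alignment <- function(x, ...) {
  cat("Alignment:", x$n_seq, "sequences x", x$n_col, "columns\n")
  gaps <- sum(x$mat == GAP)
  cat("  gap content:", sprintf("%.1f%%", 100 * gaps / length(x$mat)),
      "| ungapped columns:", length(ungapped_columns(x)), "\n")
  invisible(x)
}

#' Read a multiple sequence alignment from FASTA or Stockholm
#'
#' Parsing is delegated to [Biostrings::readAAMultipleAlignment()]; the result
#' is validated and normalized (`.` to `-`, upper case) into an [Alignment].
#'
#' @param path Path to an alignment file.
#' @param format `"fasta"` or `"stockholm"`.
#' @return An [Alignment].
#' @export
read_alignment <- function(path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty input file: ", path)
  msa <- tryCatch(
    Biostrings::readAAMultipleAlignment(path, format = format),
    error = function(e) {
      stop("failed to parse '", path, "' as ", format, ": ",
           conditionMessage(e), call. = FALSE)
    }
  )
  rows <- as.character(Biostrings::unmasked(msa))
  if (length(rows) == 0) stop("empty input: no sequences in ", path)
  Alignment(ids = names(rows), rows = unname(rows))
}

#' Write an alignment to a FASTA file
#'
#' @param aln An [Alignment].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "Alignment"))
  xs <- Biostrings::AAStringSet(setNames(aln$rows, aln$ids))
  Biostrings::writeXStringSet(xs, filepath = path)
  invisible(path)
}

#' Remove sequences with uncommon insertions or deletions
#'
#' Drops every sequence that has (a) a gap at a column where at least
#' `occupancy` of the reference sequences are non-gap, or (b) an amino acid at
#' a column where at least `occupancy` of the reference sequences are gapped.
#' With the defaults this is the 90% gap-occupancy rule used to clean seed
#' alignments before covariation analysis; the reference is typically the
#' alignment itself.
#'
#' @param aln [Alignment] to filter.
#' @param reference [Alignment] defining column occupancy (default: `aln`).
#' @param occupancy Fraction of reference sequences, inclusive threshold
#'   (default 0.9).
#' @return The surviving subset of `aln`, in input order, with an attribute
#'   `"removed"` (data frame of `id`, `reason`) retrievable via
#'   [removed_sequences()].
#' @export
filter_gapped_sequences <- function(aln, reference = aln, occupancy = 0.9) {
  stopifnot(inherits(aln, "Alignment"), inherits(reference, "Alignment"))
  if (aln$n_col != reference$n_col) {
    stop("column-count mismatch: alignment has ", aln$n_col,
         " columns, reference has ", reference$n_col)
  }
  ref_gap <- colMeans(reference$mat == GAP)
  must_occupy <- which(1 - ref_gap >= occupancy)
  must_gap <- which(ref_gap >= occupancy)

  reasons <- character(aln$n_seq)
  for (s in seq_len(aln$n_seq)) {
    g <- aln$mat[s, ] == GAP
    bad_gap <- must_occupy[g[must_occupy]]
    bad_res <- must_gap[!g[must_gap]]
    if (length(bad_gap)) {
      reasons[s] <- paste0("gap at conserved column ", bad_gap[1])
    } else if (length(bad_res)) {
      reasons[s] <- paste0("residue at gapped column ", bad_res[1])
    }
  }
  keep <- reasons == ""
  out <- Alignment(aln$ids[keep], aln$rows[keep])
  attr(out, "removed") <- data.frame(id = aln$ids[!keep],
                                     reason = reasons[!keep],
                                     stringsAsFactors = FALSE)
  out
}

#' Pairwise sequence identity over an alignment column frame
#'
#' Identity is the fraction of columns at which the two rows carry the same
#' amino acid; columns gapped in both rows are excluded from numerator and
#' denominator, and gap-versus-residue columns count as mismatches.
#'
#' @param a,b Aligned sequences (strings or character vectors) of equal length.
#' @return Identity in \[0, 1\].
#' @export
sequence_identity <- function(a, b) {
  if (is.character(a) && length(a) == 1) a <- strsplit(a, "")[[1]]
  if (is.character(b) && length(b) == 1) b <- strsplit(b, "")[[1]]
  stopifnot(length(a) == length(b))
  both_gap <- a == GAP & b == GAP
  denom <- sum(!both_gap)
  if (denom == 0) return(1)
  sum(a == b & !both_gap) / denom
}

#' Remove redundant sequences by greedy identity clustering
#'
#' Sequences are scanned in input order; a sequence is kept iff its identity
#' (see [sequence_identity()]) to every previously kept sequence is below
#' `identity_threshold`. The threshold is inclusive: identity exactly at the
#' threshold is redundant. With the default 0.8 this removes sequences with
#' 80% redundancy or greater. Greedy first-seen clustering is deterministic
#' and order-stable; the result depends on input order, which is documented
#' behaviour.
#'
#' @param aln [Alignment].
#' @param identity_threshold Fraction in (0, 1\], default 0.8.
#' @return Filtered [Alignment] with a `"removed"` attribute.
#' @export
redundancy_filter <- function(aln, identity_threshold = 0.8) {
  stopifnot(inherits(aln, "Alignment"))
  if (!is.numeric(identity_threshold) || length(identity_threshold) != 1 ||
      identity_threshold <= 0 || identity_threshold > 1) {
    stop("`identity_threshold` must be a single number in (0, 1], got ",
         identity_threshold)
  }
  kept <- integer(0)
  reasons <- character(aln$n_seq)
  for (s in seq_len(aln$n_seq)) {
    redundant_to <- 0L
    for (k in kept) {
      if (sequence_identity(aln$mat[s, ], aln$mat[k, ]) >= identity_threshold) {
        redundant_to <- k
        break
      }
    }
    if (redundant_to > 0L) {
      reasons[s] <- paste0("identity >= ", identity_threshold,
                           " to ", aln$ids[redundant_to])
    } else {
      kept <- c(kept, s)
    }
  }
  out <- Alignment(aln$ids[kept], aln$rows[kept])
  attr(out, "removed") <- data.frame(id = aln$ids[reasons != ""],
                                     reason = reasons[reasons != ""],
                                     stringsAsFactors = FALSE)
  out
}

#' Report sequences removed by a filtering step
#'
#' @param aln An [Alignment] returned by [filter_gapped_sequences()] or
#'   [redundancy_filter()].
#' @return Data frame with columns `id` and `reason` (empty if none removed).
#' @export
removed_sequences <- function(aln) {
  r <- attr(aln, "removed")
  if (is.null(r)) {
    r <- data.frame(id = character(0), reason = character(0),
                    stringsAsFactors = FALSE)
  }
  r
}

#' Columns eligible for covariation analysis
#'
#' A column is eligible iff it contains no gap character in any sequence, the
#' strictest reading of "ungapped position"; this guarantees that every
#' frequency denominator equals the number of sequences.
#'
#' @param aln [Alignment].
#' @return Strictly increasing integer vector of 1-based column indices.
#' @export
ungapped_columns <- function(aln) {
  stopifnot(inherits(aln, "Alignment"))
  which(colSums(aln$mat == GAP) == 0L)
}
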