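# Small in-code fixture builders shared across test files.

make_aln <- function(rows, ids = sprintf("s%d", seq_along(rows))) {
  Alignment(ids, rows)
}

# gap-free random alignment over a reduced alphabet (collisions on purpose)
random_small_aln <- function(n_seq, n_col, alphabet = c("A", "D", "K", "W")) {
  make_aln(apply(matrix(sample(alphabet, n_seq * n_col, replace = TRUE),
                        n_seq, n_col), 1, paste, collapse = ""))
}

write_temp_fasta <- function(rows, ids = sprintf("s%d", seq_along(rows))) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(as.vector(rbind(paste0(">", ids), rows)), path)
  path
}

random_pair_subset <- function(universe_pairs, size) {
  universe_pairs[sample.int(nrow(universe_pairs), size), , drop = FALSE]
}

# all unordered pairs of 1..m as a 2-column matrix
all_pairs <- function(m) {
  t(combn(m, 2))
}
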