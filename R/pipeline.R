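#' Configuration of the comparison pipeline
#'
#' All thresholds of the end-to-end comparison with their standard defaults:
#' covarying-pair threshold at mean + 2 SD of Zpx, near/far sequence
#' separation 10 residues, burial radius 8 Angstrom with bins 0-8 / 9-14 /
#' >14, interface cutoff 6 Angstrom, size-transition threshold 18 cubic
#' Angstrom, top 10 transitions per pair, redundancy identity 0.8 and gap
#' occupancy 0.9.
#'
#' @param k SD multiplier for the covarying-pair threshold.
#' @param near_cutoff Near/far sequence separation (residues, inclusive).
#' @param burial_radius C-beta neighbourhood radius (Angstrom).
#' @param interface_cutoff Interface/active-site contact cutoff (Angstrom).
#' @param size_threshold Size-transition volume change (cubic Angstrom).
#' @param top_n Transitions kept per covarying pair.
#' @param identity_threshold Redundancy filter threshold.
#' @param occupancy Gap-occupancy filter threshold.
#' @param filter_natural Apply gap and redundancy filtering to the natural
#'   alignment before analysis (designed sequences are used as given).
#' @param background Background distribution for profile similarity.
#' @param annotations Residue annotation table for the mechanism classifier.
#' @return Named list of class `comparison_config`.
#' @export
comparison_config <- function(k = 2, near_cutoff = 10, burial_radius = 8,
                              interface_cutoff = 6, size_threshold = 18,
                              top_n = 10, identity_threshold = 0.8,
                              occupancy = 0.9, filter_natural = TRUE,
                              background = rep(1 / 20, 20),
                              annotations = residue_annotations()) {
  structure(list(k = k, near_cutoff = near_cutoff,
                 burial_radius = burial_radius,
                 interface_cutoff = interface_cutoff,
                 size_threshold = size_threshold, top_n = top_n,
                 identity_threshold = identity_threshold,
                 occupancy = occupancy, filter_natural = filter_natural,
                 background = background, annotations = annotations),
            class = "comparison_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

summarize_covariation <- function(aln_in, aln, cov, set) {
  list(n_seq_input = aln_in$n_seq, n_seq = aln$n_seq, n_col = aln$n_col,
       n_ungapped = length(cov$columns), mean_zpx = cov$mean_zpx,
       sd_zpx = cov$sd_zpx, threshold = set$threshold,
       n_covarying = nrow(set$pairs))
}

pairs_df <- function(set) {
  data.frame(i = set$pairs[, 1], j = set$pairs[, 2])
}

#' Run the full natural-versus-designed covariation comparison
#'
#' Executes the pipeline end to end: optional filtering of the natural
#' alignment (gap-occupancy rule against itself, then greedy redundancy
#' removal), covariation analysis and covarying-pair selection for both
#' alignments, restriction of both pair sets to the columns ungapped in both
#' (the shared sample space), overlap statistics with hypergeometric
#' significance, pair classification (overlap / natural-specific /
#' design-specific), near-versus-far overlap breakdown, profile similarity,
#' amino acid pair propensities at overlap pairs with their correlation,
#' mechanism classification of top transitions with per-class overlap, and,
#' when a structure is supplied, burial context and minimum heavy-atom
#' distances per classification set. All numbers in the report are
#' recomputable by calling the underlying exported functions directly.
#'
#' @param natural [Alignment] of natural homologs.
#' @param designed [Alignment] of designed sequences over the same column
#'   frame.
#' @param structure Optional [structure_model()] mapped to alignment
#'   columns; when `NULL` the structural sections are omitted.
#' @param partner_atoms Optional n x 3 matrix of binding-partner heavy-atom
#'   coordinates for interface flags.
#' @param native Optional native sequence for sequence recovery of the
#'   designed set.
#' @param config [comparison_config()].
#' @return Nested list of class `ComparisonReport`; detail tables (pairs,
#'   transitions, propensities, context) sit under `$tables`.
#' @export
run_comparison <- function(natural, designed, structure = NULL,
                           partner_atoms = NULL, native = NULL,
                           config = comparison_config()) {
  stopifnot(inherits(natural, "Alignment"), inherits(designed, "Alignment"))
  if (natural$n_col != designed$n_col) {
    stop("alignments must share a column frame: ", natural$n_col, " vs ",
         designed$n_col, " columns")
  }
  nat_in <- natural
  removed <- NULL
  if (config$filter_natural) {
    natural <- stage("filter", {
      a <- filter_gapped_sequences(natural, natural, config$occupancy)
      b <- redundancy_filter(a, config$identity_threshold)
      removed <- rbind(removed_sequences(a), removed_sequences(b))
      attr(b, "removed") <- removed
      b
    })
  }

  cov_nat <- stage("covariation (natural)", covariation(natural))
  cov_des <- stage("covariation (designed)", covariation(designed))
  set_nat <- stage("thresholding", top_covarying_pairs(cov_nat, config$k))
  set_des <- stage("thresholding", top_covarying_pairs(cov_des, config$k))

  shared_cols <- intersect(cov_nat$columns, cov_des$columns)
  universe <- choose(length(shared_cols), 2)
  set_nat_s <- restrict_pairs(set_nat, shared_cols)
  set_des_s <- restrict_pairs(set_des, shared_cols)

  ovl <- stage("comparison", overlap_report(set_nat_s, set_des_s, universe))
  cls <- stage("comparison", classify_pairs(set_nat_s, set_des_s))

  near_far <- stage("comparison", {
    nf_nat <- split_near_far(set_nat_s, config$near_cutoff)
    nf_des <- split_near_far(set_des_s, config$near_cutoff)
    list(
      near = list(n_a = nrow(nf_nat$near$pairs),
                  n_b = nrow(nf_des$near$pairs),
                  percent_overlap = overlap_similarity(nf_nat$near,
                                                       nf_des$near)),
      far = list(n_a = nrow(nf_nat$far$pairs),
                 n_b = nrow(nf_des$far$pairs),
                 percent_overlap = overlap_similarity(nf_nat$far,
                                                      nf_des$far))
    )
  })

  prof_sim <- stage("profile similarity",
                    profile_similarity(natural, designed, config$background))
  recovery <- if (!is.null(native)) {
    stage("sequence recovery", sequence_recovery(designed, native))
  } else {
    NULL
  }

  overlap_set <- cls$overlap
  propensity <- NULL
  prop_tables <- NULL
  if (nrow(overlap_set$pairs) > 0) {
    prop_tables <- stage("propensity", list(
      natural = pair_propensity(natural, overlap_set),
      designed = pair_propensity(designed, overlap_set)))
    pn <- prop_tables$natural
    pd <- prop_tables$designed
    propensity <- list(
      r = tryCatch(propensity_correlation(pn, pd),
                   error = function(e) NA_real_),
      n_cells = sum(!is.na(pn$z) & !is.na(pd$z) &
                      upper.tri(pn$z, diag = TRUE)))
  }

  mechanisms <- NULL
  trans_tables <- NULL
  if (nrow(overlap_set$pairs) > 0) {
    trans_tables <- stage("mechanisms", list(
      natural = top_transitions(natural, overlap_set, config$top_n,
                                config$annotations, config$size_threshold),
      designed = top_transitions(designed, overlap_set, config$top_n,
                                 config$annotations, config$size_threshold)))
    tn <- trans_tables$natural
    td <- trans_tables$designed
    mechanisms <- list(
      natural_distribution = if (NROW(tn)) as.list(mechanism_distribution(tn)),
      designed_distribution = if (NROW(td)) as.list(mechanism_distribution(td)),
      class_overlap = as.list(mechanism_overlap(tn, td)))
  }

  struct <- NULL
  context_tab <- NULL
  if (!is.null(structure)) {
    counts <- stage("structure context",
                    cb_neighbor_counts(structure, config$burial_radius))
    burial <- burial_class(counts)
    iface <- if (!is.null(partner_atoms)) {
      stage("structure context",
            interface_positions(structure, partner_atoms,
                                config$interface_cutoff))
    }
    context_tab <- data.frame(
      position = structure$positions, cb_count = unname(counts),
      burial = unname(burial),
      interface = if (is.null(iface)) NA else unname(iface))
    struct <- stage("structure context", {
      dist_summary <- lapply(
        list(overlap = cls$overlap, nature_specific = cls$a_specific,
             design_specific = cls$b_specific),
        function(s) {
          if (nrow(s$pairs) == 0) return(list(n = 0, median_distance = NA))
          d <- vapply(seq_len(nrow(s$pairs)), function(r) {
            tryCatch(min_heavy_atom_distance(structure, s$pairs[r, 1],
                                             s$pairs[r, 2]),
                     error = function(e) NA_real_)
          }, numeric(1))
          list(n = nrow(s$pairs),
               median_distance = stats::median(d, na.rm = TRUE))
        })
      list(pair_distances = dist_summary,
           burial_fractions = as.list(table(factor(
             burial, levels = c("exposed", "intermediate", "buried"))) /
               sum(!is.na(burial))))
    })
  }

  report <- list(
    natural = summarize_covariation(nat_in, natural, cov_nat, set_nat),
    designed = summarize_covariation(designed, designed, cov_des, set_des),
    universe = universe,
    overlap = unclass(ovl),
    classification = list(
      overlap = pairs_df(cls$overlap),
      nature_specific = pairs_df(cls$a_specific),
      design_specific = pairs_df(cls$b_specific)
    ),
    near_far = near_far,
    profile_similarity = prof_sim,
    sequence_recovery = recovery,
    propensity = propensity,
    mechanisms = mechanisms,
    structure = struct
  )
  report$tables <- list(
    removed = removed,
    covariation = list(natural = cov_nat, designed = cov_des),
    pair_sets = list(natural = set_nat_s, designed = set_des_s),
    propensity = prop_tables,
    transitions = trans_tables,
    context = context_tab
  )
  class(report) <- "ComparisonReport"
  report
}

#' @export
print.ComparisonReport <- function(x, ...) {
  cat("ComparisonReport\n")
  cat(sprintf("  natural:  %d seqs, %d covarying pairs\n",
              x$natural$n_seq, x$natural$n_covarying))
  cat(sprintf("  designed: %d seqs, %d covarying pairs\n",
              x$designed$n_seq, x$designed$n_covarying))
  cat(sprintf("  overlap: %.1f%% (p = %.3g)\n",
              x$overlap$percent_overlap, x$overlap$p_value))
  invisible(x)
}

tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a comparison report to disk
#'
#' Emits `report.json` (the report without the detail tables, 1-based column
#' indices throughout) plus TSVs: `pairs.tsv` (every covarying pair with its
#' Zpx in both alignments and its classification), `transitions.tsv`,
#' `propensity.tsv`, `context.tsv` and `removed.tsv` where the corresponding
#' stage ran. Output is byte-identical across runs on identical input.
#'
#' @param report [run_comparison()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "ComparisonReport"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- report$tables
  json <- unclass(report)
  json$tables <- NULL
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       na = "null")

  sets <- tabs$pair_sets
  cov <- tabs$covariation
  all_pairs <- rbind(
    cbind(report$classification$overlap, class = "overlap"),
    cbind(report$classification$nature_specific, class = "nature_specific"),
    cbind(report$classification$design_specific, class = "design_specific"))
  if (nrow(all_pairs)) {
    zn <- cov$natural$Zpx
    zd <- cov$designed$Zpx
    all_pairs$zpx_natural <- zn[cbind(match(all_pairs$i, cov$natural$columns),
                                      match(all_pairs$j, cov$natural$columns))]
    all_pairs$zpx_designed <- zd[cbind(match(all_pairs$i, cov$designed$columns),
                                       match(all_pairs$j, cov$designed$columns))]
    all_pairs <- all_pairs[order(all_pairs$i, all_pairs$j), ]
  }
  tsv(all_pairs, file.path(dir, "pairs.tsv"))

  if (!is.null(tabs$transitions)) {
    tr <- rbind(cbind(tabs$transitions$natural, source = "natural"),
                cbind(tabs$transitions$designed, source = "designed"))
    tsv(tr, file.path(dir, "transitions.tsv"))
  }
  if (!is.null(tabs$propensity)) {
    long <- function(tab, source) {
      ut <- which(upper.tri(tab$pp, diag = TRUE), arr.ind = TRUE)
      data.frame(source = source, x = rownames(tab$pp)[ut[, 1]],
                 y = colnames(tab$pp)[ut[, 2]], pp = tab$pp[ut],
                 z = tab$z[ut])
    }
    tsv(rbind(long(tabs$propensity$natural, "natural"),
              long(tabs$propensity$designed, "designed")),
        file.path(dir, "propensity.tsv"))
  }
  if (!is.null(tabs$context)) {
    tsv(tabs$context, file.path(dir, "context.tsv"))
  }
  if (!is.null(tabs$removed) && nrow(tabs$removed)) {
    tsv(tabs$removed, file.path(dir, "removed.tsv"))
  }
  invisible(dir)
}
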