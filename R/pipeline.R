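# End-to-end orchestration: distances -> guide tree -> both delimiters ->
# reconciliation -> run report.

#' Run the full delimitation pipeline
#'
#' Computes the K2P matrix, builds (or accepts) a rooted guide tree, runs
#' the barcode-gap partitioner (best-ranked partition, plus the partition
#' at the `t_low` divergence guide) and the PTP delimiter (ML search,
#' optionally the bPTP MCMC), reconciles the two partitions, and returns
#' the species-hypothesis table with a self-contained run report.
#'
#' @param aln A [dna_alignment()] (or path to a FASTA file).
#' @param meta Metadata data.frame (or path to a TSV file).
#' @param guide_tree Optional externally built tree (`phylo` or newick
#'   path); when supplied it is preferred over the internal NJ tree and
#'   midpoint-rooted if unrooted.
#' @param config A [delim_config()].
#' @param seed Master seed for the stochastic stages (PTP restarts,
#'   MCMC), expanded deterministically per stage.
#' @return Object of class `delim_run`: list with `table`
#'   (`species_hypothesis_table`), `report`, `distances`, `guide_tree`,
#'   `partitions` (gap_best, gap_at_t_low, ptp_ml, truth-free), `gap_ranking`,
#'   `ptp_fit`, and `bptp_fit` (NULL unless `config$mcmc`).
#' @export
delim_run <- function(aln, meta, guide_tree = NULL, config = delim_config(),
                      seed = 1L) {
  if (is.character(aln)) aln <- read_fasta(aln)
  if (is.character(meta))
    meta <- read_metadata(meta, aln, extra_regions = config$extra_regions)
  stopifnot(inherits(aln, "dna_alignment"))
  if (!setequal(meta$id, aln$ids))
    stop("metadata does not cover the alignment specimens")
  warnings_seen <- character()
  wh <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  D <- k2p_matrix(aln, saturation_cap = config$saturation_cap)
  if (is.character(guide_tree)) guide_tree <- read_guide_tree(guide_tree)
  tree_source <- if (is.null(guide_tree)) "nj_midpoint" else "external"
  if (is.null(guide_tree)) {
    guide_tree <- if (n_seq(aln) == 2L) {
      h <- D$d[1L, 2L] / 2
      ape::read.tree(text = sprintf("(%s:%.12f,%s:%.12f);",
                                    aln$ids[1L], h, aln$ids[2L], h))
    } else midpoint_root(nj_tree(D))
  } else {
    guide_tree <- check_guide_tree(guide_tree)
    if (!ape::is.rooted(guide_tree)) guide_tree <- midpoint_root(guide_tree)
    if (!setequal(guide_tree$tip.label, aln$ids))
      stop("guide tree leaves do not match the alignment specimens")
  }

  if (n_seq(aln) == 2L) {
    # degenerate two-specimen path: a single pairwise distance, no sweep
    p <- partition_at_threshold(D, config$t_low)
    sc <- data.frame(rank = 1L, threshold = config$t_low,
                     n_otus = n_otus(p), gap_width = NA_real_,
                     relative_gap = NA_real_)
    ranking <- structure(list(scores = sc, partitions = list(p),
                              no_barcode_gap = TRUE), class = "gap_ranking")
  } else {
    ranking <- wh(rank_partitions(D, gap_floor = config$gap_floor))
  }
  p_gap <- best_partition(ranking)
  p_gap_tlow <- partition_at_threshold(D, config$t_low)
  ptp_fit <- wh(ptp_ml_search(guide_tree, restarts = config$restarts,
                              seed = seed * 1000L + 1L))
  p_ptp <- ptp_fit$partition
  bptp_fit <- NULL
  if (isTRUE(config$mcmc))
    bptp_fit <- wh(bptp_mcmc(guide_tree, generations = config$generations,
                             burnin_fraction = config$burnin_fraction,
                             seed = seed * 1000L + 2L))
  table <- wh(reconcile(p_gap, p_ptp, guide_tree, D, meta, config))
  flags <- table(unlist(table$hypotheses$flags))
  report <- structure(list(
    n_specimens = n_seq(aln), alignment_length = aln$length,
    tree_source = tree_source, seed = seed,
    otu_counts = list(gap_best = n_otus(p_gap),
                      gap_at_t_low = n_otus(p_gap_tlow),
                      ptp_ml = ptp_fit$n_species,
                      bptp_posterior_mode = if (!is.null(bptp_fit))
                        bptp_fit$posterior_mode_n else NA_integer_),
    no_barcode_gap = ranking$no_barcode_gap,
    final_species = nrow(table$hypotheses),
    flag_tally = as.list(flags),
    settings = unclass(config)[c("t_low", "t_strong", "gap_floor",
                                 "saturation_cap", "restarts", "mcmc",
                                 "generations", "burnin_fraction")],
    warnings = warnings_seen), class = "delim_report")
  structure(list(table = table, report = report, distances = D,
                 guide_tree = guide_tree,
                 partitions = list(gap_best = p_gap,
                                   gap_at_t_low = p_gap_tlow,
                                   ptp_ml = p_ptp,
                                   final = table_partition(table)),
                 gap_ranking = ranking, ptp_fit = ptp_fit,
                 bptp_fit = bptp_fit),
            class = "delim_run")
}

#' @export
print.delim_report <- function(x, ...) {
  cat("Delimitation run: ", x$n_specimens, " specimens x ",
      x$alignment_length, " bp (guide tree: ", x$tree_source, ")\n",
      "  OTUs - gap best: ", x$otu_counts$gap_best,
      "; gap@", sprintf("%.3f", x$settings$t_low), ": ",
      x$otu_counts$gap_at_t_low,
      "; PTP ML: ", x$otu_counts$ptp_ml,
      if (!is.na(x$otu_counts$bptp_posterior_mode))
        paste0("; bPTP mode: ", x$otu_counts$bptp_posterior_mode) else "",
      "\n  Final species hypotheses: ", x$final_species, "\n", sep = "")
  if (length(x$flag_tally)) {
    cat("  Flags:", paste(names(x$flag_tally), unlist(x$flag_tally),
                          sep = "=", collapse = ", "), "\n")
  }
  if (length(x$warnings)) cat("  Warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' @export
print.delim_run <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Pairwise divergence summary between hypotheses (and between labels)
#'
#' For every pair of species hypotheses, and every pair of morphospecies
#' labels, the min/mean/max K2P distance in percent (the scale at which
#' barcoding studies report divergences).
#'
#' @param table A `species_hypothesis_table` (or an [otu_partition()]).
#' @param D Distance input.
#' @param meta Metadata (required to summarize by label when `table` is a
#'   partition; optional otherwise).
#' @return List with data.frames `by_otu` and (if labels are available)
#'   `by_label`, columns `min_pct`, `mean_pct`, `max_pct`.
#' @export
summarize_divergences <- function(table, D, meta = NULL) {
  m <- as_dist_matrix(D)
  if (inherits(table, "species_hypothesis_table")) {
    groups <- setNames(table$hypotheses$members, table$hypotheses$otu_id)
    labels <- setNames(table$hypotheses$labels, table$hypotheses$otu_id)
    label_groups <- split(
      unlist(groups), unlist(labels))
  } else {
    p <- table
    groups <- setNames(otu_members(p), paste0("OTU", seq_len(n_otus(p))))
    label_groups <- if (!is.null(meta))
      split(meta$id, meta$species) else NULL
  }
  pair_summary <- function(gs) {
    if (length(gs) < 2L) return(NULL)
    cmb <- combn(names(gs), 2L)
    do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
      a <- gs[[cmb[1L, i]]]; b <- gs[[cmb[2L, i]]]
      sub <- m[a, b, drop = FALSE]
      data.frame(group1 = cmb[1L, i], group2 = cmb[2L, i],
                 min_pct = 100 * min(sub), mean_pct = 100 * mean(sub),
                 max_pct = 100 * max(sub))
    }))
  }
  out <- list(by_otu = pair_summary(groups))
  if (!is.null(label_groups)) out$by_label <- pair_summary(label_groups)
  out
}

#' Write all pipeline artifacts
#'
#' Writes the distance matrices, guide tree, partitions, gap ranking,
#' species table and the run report (JSON) under a stable filename
#' scheme.
#'
#' @param run A `delim_run`.
#' @param dir Output directory.
#' @export
write_delim_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_distances(run$distances, file.path(dir, "distances.phylip.tsv"),
                  file.path(dir, "distances.long.tsv"))
  write_guide_tree(run$guide_tree, file.path(dir, "guide_tree.nwk"))
  for (nm in names(run$partitions))
    write_partition(run$partitions[[nm]],
                    file.path(dir, paste0("partition_", nm, ".tsv")))
  write_gap_ranking(run$gap_ranking, file.path(dir, "gap_ranking.tsv"))
  write_species_table(run$table, file.path(dir, "species_hypotheses.tsv"),
                      file.path(dir, "species_hypotheses.json"))
  rep <- run$report
  jsonlite::write_json(unclass(rep), file.path(dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
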