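# Integrative reconciliation of the two delimiters: congruence, divergence
# thresholds, sympatry/allopatry merging over regions, misidentification
# flagging, and type-locality name assignment.

#' Reconciliation configuration
#'
#' @param t_low Divergence guide in substitutions/site (default 0.03, the
#'   3% COI threshold commonly applied to sibling marine fishes).
#' @param t_strong Strong-evidence divergence override: allopatric sister
#'   OTUs at or above this K2P divergence are retained as distinct even
#'   without sympatry (default 0.055).
#' @param gap_floor Passed to [rank_partitions()].
#' @param saturation_cap Passed to [k2p_matrix()].
#' @param restarts Random restarts for the greedy PTP search.
#' @param mcmc Run the bPTP MCMC in [delim_run()] (default FALSE; the ML
#'   partition drives reconciliation either way).
#' @param generations,burnin_fraction bPTP MCMC settings (defaults 500000
#'   and 0.10).
#' @param morphology_overrides Optional data.frame with columns `id1`,
#'   `id2`, `decision` (`"distinct"` or `"conspecific"`); `id1`/`id2` are
#'   specimen ids, one from each candidate OTU of a pair. Represents
#'   strong morphological evidence from specimen examination.
#' @param extra_regions Additional region codes beyond [REGION_CODES].
#' @return A list of class `delim_config`.
#' @export
delim_config <- function(t_low = 0.03, t_strong = 0.055, gap_floor = 0.005,
                         saturation_cap = 1.0, restarts = 20L, mcmc = FALSE,
                         generations = 500000L, burnin_fraction = 0.1,
                         morphology_overrides = NULL,
                         extra_regions = character()) {
  stopifnot(t_low > 0, t_low <= t_strong)
  structure(list(t_low = t_low, t_strong = t_strong, gap_floor = gap_floor,
                 saturation_cap = saturation_cap, restarts = restarts,
                 mcmc = mcmc, generations = generations,
                 burnin_fraction = burnin_fraction,
                 morphology_overrides = morphology_overrides,
                 extra_regions = extra_regions),
            class = "delim_config")
}

otu_set_keys <- function(p) {
  vapply(otu_members(p), function(m) paste(sort(m), collapse = "\r"),
         character(1L))
}

#' Congruent OTUs and conflict blocks between two partitions
#'
#' An OTU is congruent when exactly the same member set occurs in both
#' partitions; such OTUs are potentially supported species. The remaining
#' specimens fall into conflict blocks: connected components of the union
#' of the non-identical OTUs across the two partitions.
#'
#' @param pA,pB [otu_partition()]s over the same specimen set.
#' @return List with `congruent` (list of member-id vectors) and `blocks`
#'   (list of member-id vectors needing resolution).
#' @export
congruent_core <- function(pA, pB) {
  if (!setequal(names(pA), names(pB))) {
    diff <- c(setdiff(names(pA), names(pB)), setdiff(names(pB), names(pA)))
    stop("partitions cover different specimens: ", paste(diff, collapse = ", "))
  }
  kA <- otu_set_keys(pA); kB <- otu_set_keys(pB)
  congruent <- lapply(intersect(kA, kB),
                      function(k) strsplit(k, "\r", fixed = TRUE)[[1L]])
  in_congruent <- unlist(congruent)
  rest <- setdiff(names(pA), in_congruent)
  if (!length(rest)) return(list(congruent = congruent, blocks = list()))
  # union-find over specimens linked by co-membership in either partition
  ids <- rest
  lab <- seq_along(ids)
  find <- function(i) { while (lab[i] != i) { lab[i] <<- lab[lab[i]]; i <- lab[i] }; i }
  link_groups <- function(p) {
    for (grp in split(ids, unclass(p)[ids])) {
      if (length(grp) < 2L) next
      a <- find(match(grp[1L], ids))
      for (g in grp[-1L]) { b <- find(match(g, ids)); if (a != b) lab[b] <<- a }
    }
  }
  link_groups(pA); link_groups(pB)
  roots <- vapply(seq_along(ids), find, numeric(1L))
  blocks <- unname(split(ids, roots))
  list(congruent = congruent, blocks = blocks)
}

region_set <- function(meta, ids) {
  r <- unique(unlist(meta$region[match(ids, meta$id)]))
  setdiff(r, NA)
}

#' Sympatry status of two region sets
#'
#' Sympatric iff the region sets intersect after excluding `UNKNOWN`;
#' `"unknown"` when either set is empty after that exclusion (an unknown
#' region never counts as overlapping anything).
#'
#' @param r1,r2 Character vectors of region codes.
#' @return `"sympatric"`, `"allopatric"` or `"unknown"`.
#' @export
sympatric_status <- function(r1, r2) {
  r1 <- setdiff(r1, "UNKNOWN"); r2 <- setdiff(r2, "UNKNOWN")
  if (!length(r1) || !length(r2)) return("unknown")
  if (length(intersect(r1, r2))) "sympatric" else "allopatric"
}

min_inter_distance <- function(m, ids1, ids2) {
  sub <- m[ids1, ids2, drop = FALSE]
  c(min = min(sub), mean = mean(sub), max = max(sub))
}

morph_decision <- function(overrides, ids1, ids2) {
  if (is.null(overrides) || !nrow(overrides)) return(NA_character_)
  hit <- (overrides$id1 %in% ids1 & overrides$id2 %in% ids2) |
         (overrides$id1 %in% ids2 & overrides$id2 %in% ids1)
  if (!any(hit)) return(NA_character_)
  d <- unique(overrides$decision[hit])
  if (length(d) > 1L) stop("conflicting morphology overrides for one pair")
  d
}

#' Resolve one conflict block into species hypotheses
#'
#' Agglomerative pass over sister sub-OTU pairs read off the guide tree
#' restricted to the block, evaluated cherry-first. For each sister pair:
#' strong morphological evidence wins (distinct keeps the split,
#' conspecific merges); otherwise sympatric pairs are kept split
#' (`retained_sympatric`), allopatric pairs below `t_strong` minimum K2P
#' are merged (`merged_allopatric`, flagged `tentative`), allopatric
#' pairs at or above `t_strong` are kept (`strong_divergence_retained`),
#' and pairs with unknown region status are kept but flagged `tentative`.
#' Passes repeat until no merge applies.
#'
#' @param members Specimen ids of the block.
#' @param sub Partition supplying the candidate sub-OTUs (restricted to
#'   the block automatically).
#' @param guide_tree Rooted guide tree containing the block members.
#' @param D Distance input (see [as_dist_matrix()] accepted forms).
#' @param meta Metadata data.frame (for regions).
#' @param config A [delim_config()].
#' @return List of hypothesis descriptors: `members`, `regions`, `flags`.
#' @export
resolve_conflict_block <- function(members, sub, guide_tree, D, meta, config) {
  m <- as_dist_matrix(D)
  p <- restrict_partition(sub, members)
  groups <- lapply(otu_members(p), function(g)
    list(members = g, regions = region_set(meta, g), flags = character()))
  if (length(groups) == 1L) return(groups)
  tr <- ape::keep.tip(guide_tree, members)
  non_mono <- vapply(groups, function(g)
    length(g$members) > 1L && length(g$members) < length(members) &&
      !ape::is.monophyletic(tr, g$members), logical(1L))
  if (any(non_mono))
    warning("non-monophyletic OTU in conflict block; evaluated by ",
            "nearest-ancestor grouping")
  decided <- character()
  repeat {
    merged_this_pass <- FALSE
    pairs <- sister_group_pairs(tr, groups)
    for (pr in pairs) {
      g1 <- groups[[pr[1L]]]; g2 <- groups[[pr[2L]]]
      key <- paste(sort(c(paste(sort(g1$members), collapse = ","),
                          paste(sort(g2$members), collapse = ","))),
                   collapse = "|")
      if (key %in% decided) next
      dv <- min_inter_distance(m, g1$members, g2$members)
      morph <- morph_decision(config$morphology_overrides,
                              g1$members, g2$members)
      status <- sympatric_status(g1$regions, g2$regions)
      if (identical(morph, "distinct")) {
        decided <- c(decided, key)
      } else if (identical(morph, "conspecific")) {
        groups[[pr[1L]]] <- merge_groups(g1, g2, character())
        groups[[pr[2L]]] <- NULL
        merged_this_pass <- TRUE
        break
      } else if (status == "sympatric") {
        groups[[pr[1L]]]$flags <- union(g1$flags, "retained_sympatric")
        groups[[pr[2L]]]$flags <- union(g2$flags, "retained_sympatric")
        decided <- c(decided, key)
      } else if (status == "allopatric" && dv["min"] < config$t_strong) {
        groups[[pr[1L]]] <- merge_groups(g1, g2,
                                         c("merged_allopatric", "tentative"))
        groups[[pr[2L]]] <- NULL
        merged_this_pass <- TRUE
        break
      } else if (status == "allopatric") {
        groups[[pr[1L]]]$flags <- union(g1$flags, "strong_divergence_retained")
        groups[[pr[2L]]]$flags <- union(g2$flags, "strong_divergence_retained")
        decided <- c(decided, key)
      } else {  # unknown region status: keep split, flag tentative
        groups[[pr[1L]]]$flags <- union(g1$flags, "tentative")
        groups[[pr[2L]]]$flags <- union(g2$flags, "tentative")
        decided <- c(decided, key)
      }
    }
    if (!merged_this_pass) break
    if (length(groups) == 1L) break
  }
  groups
}

merge_groups <- function(g1, g2, flags) {
  fl <- setdiff(union(union(g1$flags, g2$flags), flags), "retained_sympatric")
  list(members = c(g1$members, g2$members),
       regions = union(g1$regions, g2$regions), flags = fl)
}

# indices of group pairs that are sisters on the tree: internal nodes
# whose descendant leaves span exactly two current groups, shallowest
# (fewest leaves) first
sister_group_pairs <- function(tr, groups) {
  ntip <- length(tr$tip.label)
  gidx <- integer(ntip)
  for (i in seq_along(groups))
    gidx[match(groups[[i]]$members, tr$tip.label)] <- i
  if (ntip == 2L) {
    if (length(unique(gidx)) == 2L) return(list(sort(unique(gidx))))
    return(list())
  }
  desc <- tip_descendants(tr)
  out <- list()
  sizes <- integer()
  for (v in seq_along(desc)) {
    gs <- unique(gidx[desc[[v]]])
    if (length(gs) == 2L) {
      out[[length(out) + 1L]] <- sort(gs)
      sizes <- c(sizes, length(desc[[v]]))
    }
  }
  if (!length(out)) return(list())
  out <- out[order(sizes)]
  out[!duplicated(vapply(out, paste, character(1L), collapse = "-"))]
}

# list over internal nodes of tip indices below each (postorder fill)
tip_descendants <- function(tr) {
  ntip <- length(tr$tip.label)
  tr2 <- stats::reorder(tr, "postorder")
  desc <- rep(list(integer()), tr$Nnode)
  for (e in seq_len(nrow(tr2$edge))) {
    par <- tr2$edge[e, 1L] - ntip
    ch <- tr2$edge[e, 2L]
    desc[[par]] <- c(desc[[par]],
                     if (ch <= ntip) ch else desc[[ch - ntip]])
  }
  desc
}

#' Flag morphospecies-name incongruence
#'
#' Marks hypotheses containing more than one morphospecies label
#' (`name_incongruent`) and hypotheses sharing a label with another
#' hypothesis (`label polyphyletic`, also reported per label).
#'
#' @param table A `species_hypothesis_table`.
#' @return The table with updated flags and a `name_report` element.
#' @export
flag_name_incongruence <- function(table) {
  hy <- table$hypotheses
  multi_label <- vapply(hy$labels, function(l) length(unique(l)) > 1L,
                        logical(1L))
  all_labels <- unique(unlist(hy$labels))
  label_otus <- lapply(all_labels, function(lb)
    which(vapply(hy$labels, function(l) lb %in% l, logical(1L))))
  poly <- all_labels[lengths(label_otus) > 1L]
  poly_otu <- sort(unique(unlist(label_otus[lengths(label_otus) > 1L])))
  for (i in seq_len(nrow(hy))) {
    if (multi_label[i] || i %in% poly_otu)
      hy$flags[[i]] <- union(hy$flags[[i]], "name_incongruent")
  }
  table$hypotheses <- hy
  table$name_report <- list(
    multi_label_otus = hy$otu_id[multi_label],
    polyphyletic_labels = data.frame(
      label = poly,
      n_otus = lengths(label_otus)[match(poly, all_labels)]))
  table
}

#' Assign species names from labels and type-locality membership
#'
#' Within each hypothesis: if exactly one candidate label has a
#' type-locality member, that label is assigned (basis `type_locality`);
#' otherwise the majority label is assigned (basis `majority_label`);
#' ties or no labels give `"unassigned"`.
#'
#' @param table A `species_hypothesis_table`.
#' @param meta Metadata data.frame.
#' @return The table with `assigned_name` and `name_basis` filled in.
#' @export
assign_names <- function(table, meta) {
  hy <- table$hypotheses
  for (i in seq_len(nrow(hy))) {
    ids <- hy$members[[i]]
    rows <- meta[match(ids, meta$id), , drop = FALSE]
    tl_labels <- unique(rows$species[rows$type_locality & !is.na(rows$species)])
    if (length(tl_labels) == 1L) {
      hy$assigned_name[i] <- tl_labels
      hy$name_basis[i] <- "type_locality"
      next
    }
    tab <- sort(table(rows$species[!is.na(rows$species)]), decreasing = TRUE)
    if (length(tab) && (length(tab) == 1L || tab[1L] > tab[2L])) {
      hy$assigned_name[i] <- names(tab)[1L]
      hy$name_basis[i] <- "majority_label"
    } else {
      hy$assigned_name[i] <- "unassigned"
      hy$name_basis[i] <- "none"
    }
  }
  table$hypotheses <- hy
  table
}

#' Reconcile two delimiter partitions into a species-hypothesis table
#'
#' Congruent OTUs pass through unchanged (flag `congruent`); each
#' conflict block is resolved by [resolve_conflict_block()] using the
#' sub-OTUs of the finer partition within the block; morphospecies-name
#' incongruence is flagged and names are assigned from type-locality
#' membership or majority labels. The output member sets always partition
#' the input specimen set.
#'
#' @param p_gap,p_ptp [otu_partition()]s from the two delimiters (same
#'   specimen set).
#' @param guide_tree Rooted guide tree over all specimens.
#' @param D Distance input.
#' @param meta Metadata data.frame.
#' @param config A [delim_config()].
#' @return Object of class `species_hypothesis_table`: list with
#'   `hypotheses` (data.frame with list columns `members`, `labels`,
#'   `regions`, `flags`), `name_report` and `provenance`.
#' @export
reconcile <- function(p_gap, p_ptp, guide_tree, D, meta,
                      config = delim_config()) {
  m <- as_dist_matrix(D)
  core <- congruent_core(p_gap, p_ptp)
  hyp <- lapply(core$congruent, function(ids)
    list(members = ids, regions = region_set(meta, ids),
         flags = "congruent"))
  for (block in core$blocks) {
    nA <- length(unique(unclass(p_gap)[block]))
    nB <- length(unique(unclass(p_ptp)[block]))
    finer <- if (nA > nB) p_gap else p_ptp
    hyp <- c(hyp, resolve_conflict_block(block, finer, guide_tree, m,
                                         meta, config))
  }
  all_members <- unlist(lapply(hyp, `[[`, "members"))
  if (anyDuplicated(all_members) || !setequal(all_members, names(p_gap)))
    stop("internal error: reconciled hypotheses do not partition the ",
         "specimen set")
  # order hypotheses by guide-tree leaf order for stable output
  first_leaf <- vapply(hyp, function(h)
    min(match(h$members, guide_tree$tip.label)), numeric(1L))
  hyp <- hyp[order(first_leaf)]
  hy <- data.frame(otu_id = sprintf("H%03d", seq_along(hyp)),
                   n_members = vapply(hyp, function(h) length(h$members),
                                      integer(1L)),
                   stringsAsFactors = FALSE)
  hy$members <- lapply(hyp, `[[`, "members")
  hy$labels <- lapply(hyp, function(h)
    meta$species[match(h$members, meta$id)])
  hy$regions <- lapply(hyp, `[[`, "regions")
  hy$flags <- lapply(hyp, `[[`, "flags")
  hy$assigned_name <- NA_character_
  hy$name_basis <- NA_character_
  # divergence to nearest other hypothesis (by minimum K2P)
  hy$div_min <- hy$div_mean <- hy$div_max <- NA_real_
  if (nrow(hy) > 1L) {
    for (i in seq_len(nrow(hy))) {
      best <- NULL
      for (j in seq_len(nrow(hy))[-i]) {
        dv <- min_inter_distance(m, hy$members[[i]], hy$members[[j]])
        if (is.null(best) || dv["min"] < best["min"]) best <- dv
      }
      hy$div_min[i] <- best["min"]; hy$div_mean[i] <- best["mean"]
      hy$div_max[i] <- best["max"]
    }
  }
  out <- structure(list(hypotheses = hy,
                        provenance = list(config = config,
                                          n_specimens = length(p_gap),
                                          gap_otus = n_otus(p_gap),
                                          ptp_otus = n_otus(p_ptp))),
                   class = "species_hypothesis_table")
  out <- flag_name_incongruence(out)
  assign_names(out, meta)
}

#' @export
print.species_hypothesis_table <- function(x, ...) {
  hy <- x$hypotheses
  cat("Species hypotheses: ", nrow(hy), " (from ",
      x$provenance$gap_otus, " gap OTUs / ", x$provenance$ptp_otus,
      " PTP OTUs over ", x$provenance$n_specimens, " specimens)\n", sep = "")
  df <- data.frame(otu_id = hy$otu_id, n = hy$n_members,
                   name = hy$assigned_name,
                   flags = vapply(hy$flags, paste, character(1L),
                                  collapse = ";"))
  print(head(df, 12L), row.names = FALSE)
  if (nrow(df) > 12L) cat("... and", nrow(df) - 12L, "more\n")
  invisible(x)
}

#' Final partition implied by a species-hypothesis table
#' @param table A `species_hypothesis_table`.
#' @return An [otu_partition()] with method `"reconciled"`.
#' @export
table_partition <- function(table) {
  hy <- table$hypotheses
  assign <- unlist(lapply(seq_len(nrow(hy)), function(i)
    setNames(rep(i, length(hy$members[[i]])), hy$members[[i]])))
  otu_partition(assign, method = "reconciled")
}

#' Write a species-hypothesis table
#'
#' @param table A `species_hypothesis_table`.
#' @param path Output TSV path.
#' @param json_path Optional JSON path including provenance.
#' @export
write_species_table <- function(table, path, json_path = NULL) {
  hy <- table$hypotheses
  flat <- data.frame(
    otu_id = hy$otu_id, n_members = hy$n_members,
    members = vapply(hy$members, paste, character(1L), collapse = ","),
    labels = vapply(hy$labels, function(l)
      paste(unique(l), collapse = ","), character(1L)),
    regions = vapply(hy$regions, paste, character(1L), collapse = ","),
    flags = vapply(hy$flags, paste, character(1L), collapse = ";"),
    assigned_name = hy$assigned_name, name_basis = hy$name_basis,
    div_min = hy$div_min, div_mean = hy$div_mean, div_max = hy$div_max)
  write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(hypotheses = flat,
                              provenance = table$provenance[c("n_specimens",
                                                              "gap_otus",
                                                              "ptp_otus")]),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
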