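# Barcode-gap OTU partitioner: single-linkage threshold sweep over the
# distance distribution, recursive refinement, and gap-based ranking.

# connected components of the graph linking pairs with d <= t
# (iterative min-label propagation; exact and dependency-free)
components_leq <- function(m, t) {
  n <- nrow(m)
  adj <- m <= t
  diag(adj) <- TRUE
  lab <- seq_len(n)
  repeat {
    new <- vapply(seq_len(n), function(i) min(lab[adj[i, ]]), numeric(1L))
    if (identical(new, lab)) break
    lab <- new
  }
  as.integer(lab)
}

#' Single-linkage partition at a distance threshold
#'
#' OTUs are the connected components of the graph linking every specimen
#' pair with `d <= t` (single-linkage closure). Saturated pairs, if any,
#' participate at their cap value.
#'
#' @param D A `k2p_matrix`, `dist`, or square symmetric matrix.
#' @param t Threshold in substitutions/site (>= 0).
#' @return An [otu_partition()] with method `"gap"`.
#' @export
partition_at_threshold <- function(D, t) {
  stopifnot(t >= 0)
  m <- as_dist_matrix(D)
  otu_partition(setNames(components_leq(m, t), rownames(m)), method = "gap")
}

#' Candidate thresholds from the distance distribution
#'
#' Midpoints between consecutive distinct sorted pairwise distances
#' (saturated pairs excluded from the sweep). Every candidate separates at
#' least one pair of distances.
#'
#' @param D A `k2p_matrix`, `dist`, or square symmetric matrix.
#' @return Increasing numeric vector of candidate thresholds.
#' @export
candidate_thresholds <- function(D) {
  m <- as_dist_matrix(D)
  vals <- sort(unique(pair_values(m, saturated_keys(D))))
  if (length(vals) == 0L) stop("need at least one pairwise distance")
  if (length(vals) == 1L) {
    message("all pairwise distances equal; single degenerate candidate")
    return(vals)
  }
  (vals[-1L] + vals[-length(vals)]) / 2
}

# upper-triangle distance values, dropping saturated pairs
pair_values <- function(m, sat_keys = character()) {
  idx <- which(upper.tri(m), arr.ind = TRUE)
  v <- m[idx]
  if (length(sat_keys)) {
    keys <- paste(pmin(rownames(m)[idx[, 1L]], rownames(m)[idx[, 2L]]),
                  pmax(rownames(m)[idx[, 1L]], rownames(m)[idx[, 2L]]),
                  sep = "\r")
    v <- v[!(keys %in% sat_keys)]
  }
  v
}

# gap statistics of a partition against the full matrix; saturated pairs
# are excluded from the statistics (they still took part in clustering).
gap_stats <- function(p, m, sat_keys = character()) {
  idx <- which(upper.tri(m), arr.ind = TRUE)
  same <- unclass(p)[rownames(m)[idx[, 1L]]] == unclass(p)[rownames(m)[idx[, 2L]]]
  v <- m[idx]
  if (length(sat_keys)) {
    keys <- paste(pmin(rownames(m)[idx[, 1L]], rownames(m)[idx[, 2L]]),
                  pmax(rownames(m)[idx[, 1L]], rownames(m)[idx[, 2L]]),
                  sep = "\r")
    keep <- !(keys %in% sat_keys)
    same <- same[keep]; v <- v[keep]
  }
  max_within <- if (any(same)) max(v[same]) else 0
  min_between <- if (any(!same)) min(v[!same]) else NA_real_
  gap <- min_between - max_within
  thr <- (max_within + min_between) / 2
  list(max_within = max_within, min_between = min_between,
       gap_width = gap, threshold = thr,
       relative_gap = if (!is.na(thr) && thr > 0) gap / thr else NA_real_)
}

partition_key <- function(p) paste(unclass(p), collapse = ",")

#' Rank candidate barcode-gap partitions
#'
#' Sweeps the candidate thresholds, computes the single-linkage partition
#' at each, scores every distinct partition by its barcode gap (smallest
#' between-OTU distance minus largest within-OTU distance), recursively
#' refines OTUs whose internal distance distribution shows a wider gap
#' than the parent partition's, and returns the candidates ranked by gap
#' width (widest first). The relative gap (gap width over the gap-center
#' threshold) is reported alongside.
#'
#' When no candidate reaches `gap_floor` the result is flagged
#' `no_barcode_gap` and the single-OTU partition is ranked first (with the
#' all-singleton partition also included), since a gap narrower than
#' typical intraspecific variation is no evidence of species structure.
#'
#' @param D A `k2p_matrix`, `dist`, or square symmetric matrix (>= 3
#'   specimens).
#' @param gap_floor Minimum gap width (substitutions/site) to count as a
#'   barcode gap; default 0.005.
#' @param refine Recursively refine OTUs with wider internal gaps.
#' @param max_depth Maximum refinement depth.
#' @return An object of class `gap_ranking`: list with `scores` (data
#'   frame: rank, threshold, n_otus, gap_width, relative_gap),
#'   `partitions` (list of [otu_partition()] in rank order) and
#'   `no_barcode_gap` flag.
#' @export
rank_partitions <- function(D, gap_floor = 0.005, refine = TRUE, max_depth = 3L) {
  m <- as_dist_matrix(D)
  if (nrow(m) < 3L) stop("need at least 3 specimens")
  sat <- saturated_keys(D)
  cands <- candidate_thresholds(D)

  seen <- new.env(parent = emptyenv())
  entries <- list()
  add_entry <- function(p) {
    key <- partition_key(p)
    if (!is.null(seen[[key]])) return(invisible(NULL))
    seen[[key]] <- TRUE
    st <- gap_stats(p, m, sat)
    if (is.na(st$gap_width)) return(invisible(NULL))  # 1-OTU: no between pairs
    entries[[length(entries) + 1L]] <<- c(list(partition = p), st,
                                          list(n_otus = n_otus(p)))
    invisible(NULL)
  }
  for (t in cands) add_entry(partition_at_threshold(m, t))

  if (refine && length(entries)) {
    # refine the best sweep partitions: replace any OTU whose internal
    # distances show a wider gap than the parent's by its best internal
    # sub-partition, and rescore the combined partition globally
    refine_one <- function(entry, depth) {
      if (depth > max_depth) return(invisible(NULL))
      p <- entry$partition
      for (mem in otu_members(p)) {
        if (length(mem) < 3L) next
        sub_m <- m[mem, mem, drop = FALSE]
        sub_vals <- unique(pair_values(sub_m, sat))
        if (length(sub_vals) < 2L) next
        sub_rank <- rank_partitions(sub_m, gap_floor = gap_floor,
                                    refine = FALSE)
        if (sub_rank$no_barcode_gap) next
        best_sub <- sub_rank$partitions[[1L]]
        if (sub_rank$scores$gap_width[1L] <= entry$gap_width) next
        combined <- unclass(p)
        combined[mem] <- n_otus(p) + unclass(best_sub)[mem]
        cp <- otu_partition(combined, method = "gap")
        key <- partition_key(cp)
        if (!is.null(seen[[key]])) next
        add_entry(cp)
        refine_one(entries[[length(entries)]], depth + 1L)
      }
      invisible(NULL)
    }
    for (e in entries[order(-vapply(entries, `[[`, numeric(1L), "gap_width"))][
      seq_len(min(10L, length(entries)))]) refine_one(e, 1L)
  }

  no_gap <- length(entries) == 0L ||
    max(vapply(entries, `[[`, numeric(1L), "gap_width")) < gap_floor
  if (no_gap) {
    ids <- rownames(m)
    one <- otu_partition(setNames(rep(1L, length(ids)), ids), method = "gap")
    singletons <- otu_partition(setNames(seq_along(ids), ids), method = "gap")
    extra <- list(c(list(partition = one), gap_stats(one, m, sat),
                    list(n_otus = 1L)),
                  c(list(partition = singletons), gap_stats(singletons, m, sat),
                    list(n_otus = length(ids))))
    # the 1-OTU partition leads; scored candidates follow
    entries <- c(extra[1L], entries, extra[2L])
    ord <- seq_along(entries)
  } else {
    ord <- order(-vapply(entries, `[[`, numeric(1L), "gap_width"),
                 vapply(entries, `[[`, numeric(1L), "n_otus"),
                 vapply(entries, function(e) e$threshold %||% Inf, numeric(1L)))
  }
  entries <- entries[ord]
  scores <- data.frame(
    rank = seq_along(entries),
    threshold = vapply(entries, function(e) e$threshold %||% NA_real_, numeric(1L)),
    n_otus = vapply(entries, `[[`, numeric(1L), "n_otus"),
    gap_width = vapply(entries, function(e) e$gap_width %||% NA_real_, numeric(1L)),
    relative_gap = vapply(entries, function(e) e$relative_gap %||% NA_real_,
                          numeric(1L)))
  structure(list(scores = scores,
                 partitions = lapply(entries, `[[`, "partition"),
                 no_barcode_gap = no_gap),
            class = "gap_ranking")
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' @export
print.gap_ranking <- function(x, ...) {
  cat("Barcode-gap ranking: ", nrow(x$scores), " candidate partition(s)",
      if (x$no_barcode_gap) " [no barcode gap]" else "", "\n", sep = "")
  print(head(x$scores, 5L), row.names = FALSE)
  invisible(x)
}

#' Best barcode-gap partition
#' @param ranking A `gap_ranking` from [rank_partitions()].
#' @return The rank-1 [otu_partition()].
#' @export
best_partition <- function(ranking) {
  stopifnot(inherits(ranking, "gap_ranking"))
  ranking$partitions[[1L]]
}

#' Write a gap ranking as TSV
#' @param ranking A `gap_ranking`.
#' @param path Output path.
#' @export
write_gap_ranking <- function(ranking, path) {
  write.table(ranking$scores, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
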