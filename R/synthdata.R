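# Ground-truth generator: Yule species tree, within-species coalescent
# subtrees, K80 sequence evolution, region assignment with a
# sister-sympatry probability, and misidentification (label) noise.

#' Simulation configuration
#'
#' @param n_species Number of true species.
#' @param birth_rate Per-lineage speciation rate of the Yule species tree
#'   (only the tree shape matters; depths are rescaled by `mu`).
#' @param pop_scale Within-species coalescent depth as a fraction of the
#'   species-tree depth (must be < 1; the within/between depth contrast is
#'   what the delimiters exploit).
#' @param n_per_species Specimens sampled per species.
#' @param seq_length Alignment length in bp (default 615, a typical
#'   trimmed COI barcode).
#' @param kappa Transition/transversion rate ratio of the K80 model
#'   (default 4, typical for fish COI).
#' @param mu Root-to-tip depth of the species tree in expected
#'   substitutions/site (default 0.075, giving between-species K2P
#'   divergences spanning roughly 1-15%).
#' @param regions_per_species Regions drawn per species from the 8-code
#'   vocabulary.
#' @param p_sympatric_sisters Probability that sister species share a
#'   region (default 1: by default sisters are simulated sympatric, the
#'   regime in which the sympatry criterion is informative; allopatric
#'   sisters are deliberately lumped by the reconciliation rule).
#' @param mislabel_rate Fraction of specimens given another species'
#'   morphospecies label (emulating database misidentifications).
#' @param max_depth_ratio Upper bound on the within/between depth ratio:
#'   the species tree is conditioned (by redrawing) on every split being
#'   at least `pop_scale / max_depth_ratio` of the root depth, so that
#'   the coalescent depth of any species is at most this fraction of its
#'   divergence from its closest relative (default 0.1). `NULL` disables
#'   the conditioning.
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_species = 5L, birth_rate = 1, pop_scale = 0.02,
                       n_per_species = 6L, seq_length = 615L, kappa = 4,
                       mu = 0.075, regions_per_species = 1L,
                       p_sympatric_sisters = 1, mislabel_rate = 0,
                       max_depth_ratio = 0.1, seed = NULL) {
  stopifnot(n_species >= 1L, birth_rate > 0, n_per_species >= 1L,
            seq_length > 0L, kappa > 0, mu > 0, regions_per_species >= 1L,
            p_sympatric_sisters >= 0, p_sympatric_sisters <= 1,
            mislabel_rate >= 0, mislabel_rate < 1)
  if (!is.null(max_depth_ratio) && pop_scale / max_depth_ratio >= 1)
    stop("pop_scale / max_depth_ratio >= 1: no species tree can satisfy ",
         "the requested depth contrast")
  if (pop_scale >= 1)
    stop("pop_scale >= 1: expected within-species divergence would ",
         "exceed between-species divergence; no delimiter can work there")
  if (pop_scale <= 0) stop("pop_scale must be positive")
  structure(as.list(environment()), class = "sim_config")
}

# K80 transition probabilities for one branch of length b (expected
# substitutions/site), rate-normalized so alpha + 2 beta = 1
k80_probs <- function(b, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * b)
  e2 <- exp(-2 * (alpha + beta) * b)
  c(same = 0.25 + 0.25 * e1 + 0.5 * e2,
    ts   = 0.25 + 0.25 * e1 - 0.5 * e2,
    tv   = 0.25 - 0.25 * e1)  # each of the two transversion targets
}

# evolve integer-coded sequences (1=A 2=C 3=G 4=T) down a tree
sim_k80_sequences <- function(tr, seq_length, kappa) {
  ntip <- length(tr$tip.label)
  nnode <- tr$Nnode
  seqs <- matrix(NA_integer_, ntip + nnode, seq_length)
  root <- ntip + 1L
  seqs[root, ] <- sample.int(4L, seq_length, replace = TRUE)
  tr2 <- stats::reorder(tr, "cladewise")  # parents before children
  ts_of <- c(3L, 4L, 1L, 2L)             # A<->G, C<->T
  tv1_of <- c(2L, 1L, 2L, 1L)            # one transversion target
  tv2_of <- c(4L, 3L, 4L, 3L)            # the other
  for (e in seq_len(nrow(tr2$edge))) {
    par <- tr2$edge[e, 1L]; ch <- tr2$edge[e, 2L]
    pr <- k80_probs(tr2$edge.length[e], kappa)
    parent_seq <- seqs[par, ]
    u <- runif(seq_length)
    child <- parent_seq
    is_ts <- u >= pr["same"] & u < pr["same"] + pr["ts"]
    is_tv1 <- u >= pr["same"] + pr["ts"] & u < pr["same"] + pr["ts"] + pr["tv"]
    is_tv2 <- u >= pr["same"] + pr["ts"] + pr["tv"]
    child[is_ts] <- ts_of[parent_seq[is_ts]]
    child[is_tv1] <- tv1_of[parent_seq[is_tv1]]
    child[is_tv2] <- tv2_of[parent_seq[is_tv2]]
    seqs[ch, ] <- child
  }
  out <- seqs[seq_len(ntip), , drop = FALSE]
  rownames(out) <- tr$tip.label
  out
}

tree_depth <- function(tr) max(ape::node.depth.edgelength(tr))

#' Simulate a barcode dataset with known species truth
#'
#' Yule species tree (depth rescaled to `mu` substitutions/site) with a
#' scaled coalescent subtree grafted at each tip (depth
#' `pop_scale * mu`), K80 sequence evolution over the resulting gene
#' tree, per-species region assignment with a sister-sympatry
#' probability, and misidentification noise applied last. Fully
#' reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return Object of class `barcode_sim`: list with `alignment`
#'   (a [dna_alignment()]), `meta` (metadata data.frame in the
#'   [read_metadata()] schema), and `truth` (list: `partition`
#'   ([otu_partition()] of the true species), `species_tree`,
#'   `gene_tree`, `true_labels`, `config`).
#' @export
simulate_barcodes <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  k <- config$n_species
  sp_names <- sprintf("sp%02d", seq_len(k))
  # species tree, rescaled so root-to-tip depth = mu
  if (k == 1L) {
    sp_tree <- NULL
  } else if (k == 2L) {
    sp_tree <- ape::read.tree(text = sprintf("(%s:%f,%s:%f);", sp_names[1L],
                                             config$mu, sp_names[2L], config$mu))
  } else {
    min_frac <- if (is.null(config$max_depth_ratio)) 0 else
      config$pop_scale / config$max_depth_ratio
    for (try in seq_len(10000L)) {
      sp_tree <- ape::rphylo(k, birth = config$birth_rate, death = 0)
      depth <- tree_depth(sp_tree)
      node_h <- depth - ape::node.depth.edgelength(sp_tree)[(k + 1L):(k + sp_tree$Nnode)]
      if (min(node_h) >= min_frac * depth) break
      sp_tree <- NULL
    }
    if (is.null(sp_tree))
      stop("could not draw a species tree satisfying max_depth_ratio; ",
           "relax it or lower pop_scale")
    sp_tree$tip.label <- sp_names
    sp_tree$edge.length <- sp_tree$edge.length * config$mu / tree_depth(sp_tree)
  }
  # graft a coalescent subtree (depth pop_scale * mu) at each species tip
  sub_depth <- config$pop_scale * config$mu
  gene_tree <- sp_tree
  for (sp in sp_names) {
    tips <- paste0(sp, "_", sprintf("%02d", seq_len(config$n_per_species)))
    if (config$n_per_species == 1L) {
      if (!is.null(gene_tree))
        gene_tree$tip.label[gene_tree$tip.label == sp] <- tips
      else gene_tree <- ape::read.tree(text = paste0("(", tips, ":0);"))
      next
    }
    sub <- ape::rcoal(config$n_per_species, tip.label = tips)
    if (is.null(gene_tree)) {
      sub$edge.length <- sub$edge.length * sub_depth / tree_depth(sub)
      gene_tree <- sub
      next
    }
    w <- which(gene_tree$tip.label == sp)
    pend <- gene_tree$edge.length[gene_tree$edge[, 2L] == w]
    # cap the coalescent depth at the species stem so within-species
    # coalescence always completes before the split (no incomplete
    # lineage sorting by construction; the truth stays well-defined)
    d_i <- min(sub_depth, 0.9 * pend)
    sub$edge.length <- sub$edge.length * d_i / tree_depth(sub)
    gene_tree$edge.length[gene_tree$edge[, 2L] == w] <- pend - d_i
    gene_tree <- ape::bind.tree(gene_tree, sub, where = w, position = 0)
  }
  ids <- sort(gene_tree$tip.label)
  true_sp <- sub("_[0-9]+$", "", ids)
  # sequences
  enc <- sim_k80_sequences(gene_tree, config$seq_length, config$kappa)
  chars <- c("A", "C", "G", "T")
  seqs <- apply(enc[ids, , drop = FALSE], 1L, function(r)
    paste(chars[r], collapse = ""))
  aln <- dna_alignment(setNames(seqs, ids))
  # regions per species; cherries share a region with prob p_sympatric_sisters
  sp_regions <- lapply(seq_len(k), function(i)
    sample(REGION_CODES, min(config$regions_per_species,
                             length(REGION_CODES))))
  names(sp_regions) <- sp_names
  if (!is.null(sp_tree) && k > 1L) {
    for (v in seq_len(sp_tree$Nnode) + k) {
      ch <- sp_tree$edge[sp_tree$edge[, 1L] == v, 2L]
      if (all(ch <= k)) {  # cherry: both children are species tips
        a <- sp_tree$tip.label[ch[1L]]; b <- sp_tree$tip.label[ch[2L]]
        if (runif(1L) < config$p_sympatric_sisters) {
          sp_regions[[b]][1L] <- sp_regions[[a]][1L]
        } else {
          pool <- setdiff(REGION_CODES, sp_regions[[a]])
          sp_regions[[b]] <- sample(pool, min(length(sp_regions[[b]]),
                                              length(pool)))
        }
        sp_regions[[b]] <- unique(sp_regions[[b]])
      }
    }
  }
  true_labels <- paste("Simulus", true_sp)
  observed <- true_labels
  n <- length(ids)
  if (config$mislabel_rate > 0 && k > 1L) {
    hit <- which(runif(n) < config$mislabel_rate)
    for (i in hit)
      observed[i] <- paste("Simulus",
                           sample(setdiff(sp_names, true_sp[i]), 1L))
  }
  first_of_sp <- !duplicated(true_sp)
  meta <- data.frame(id = ids, species = observed,
                     locality = paste0("sim:",
                                       vapply(sp_regions[true_sp], `[[`,
                                              character(1L), 1L)),
                     stringsAsFactors = FALSE)
  meta$region <- unname(sp_regions[true_sp])
  meta$type_locality <- first_of_sp
  meta$source <- "synthetic"
  truth <- list(
    partition = otu_partition(setNames(match(true_sp, sp_names), ids),
                              method = "truth"),
    species_tree = sp_tree, gene_tree = gene_tree,
    true_labels = setNames(true_labels, ids),
    species_regions = sp_regions, config = config)
  structure(list(alignment = aln, meta = meta, truth = truth),
            class = "barcode_sim")
}

#' @export
print.barcode_sim <- function(x, ...) {
  cat("Simulated barcode dataset: ", n_seq(x$alignment), " specimens, ",
      x$truth$config$n_species, " true species, ", x$alignment$length,
      " bp\n", sep = "")
  invisible(x)
}

#' Write simulation artifacts to a directory
#'
#' Emits `alignment.fasta`, `metadata.tsv`, `truth.json`,
#' `species_tree.nwk` and `gene_tree.nwk`.
#'
#' @param sim A `barcode_sim`.
#' @param dir Output directory (created if absent).
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$alignment, file.path(dir, "alignment.fasta"))
  write_metadata(sim$meta, file.path(dir, "metadata.tsv"))
  if (!is.null(sim$truth$species_tree))
    write_guide_tree(sim$truth$species_tree, file.path(dir, "species_tree.nwk"))
  write_guide_tree(sim$truth$gene_tree, file.path(dir, "gene_tree.nwk"))
  cfg <- sim$truth$config
  jsonlite::write_json(
    list(true_partition = as.list(setNames(as.integer(sim$truth$partition),
                                           names(sim$truth$partition))),
         true_labels = as.list(sim$truth$true_labels),
         species_regions = sim$truth$species_regions,
         config = cfg[!vapply(cfg, is.null, logical(1L))]),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement computed from the contingency table of the
#' two partitions; 1 for identical partitions, approximately 0 for
#' independent ones.
#'
#' @param p1,p2 [otu_partition()]s (or named vectors) over the same
#'   specimens.
#' @return Numeric in `[-1, 1]`.
#' @export
adjusted_rand <- function(p1, p2) {
  stopifnot(setequal(names(p1), names(p2)))
  a <- unclass(p1)[names(p1)]
  b <- unclass(p2)[names(p1)]
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Score a delimitation against the simulation truth
#'
#' @param estimated,truth [otu_partition()]s over the same specimens.
#' @return List with `exact_count_match`, `adjusted_rand`,
#'   `split_errors` (true species spread over >1 estimated OTU) and
#'   `merge_errors` (estimated OTUs containing >1 true species).
#' @export
score_recovery <- function(estimated, truth) {
  stopifnot(setequal(names(estimated), names(truth)))
  e <- unclass(estimated)[names(truth)]
  t <- unclass(truth)
  tab <- table(t, e)
  list(exact_count_match = n_otus(estimated) == n_otus(truth),
       adjusted_rand = adjusted_rand(estimated, truth),
       split_errors = sum(rowSums(tab > 0) > 1L),
       merge_errors = sum(colSums(tab > 0) > 1L))
}
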