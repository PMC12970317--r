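test_that("simulation is exactly reproducible from its seed", {
  cfg <- sim_config(seed = 99L)
  s1 <- simulate_barcodes(cfg)
  s2 <- simulate_barcodes(cfg)
  expect_identical(as.character(s1$alignment), as.character(s2$alignment))
  expect_identical(s1$meta, s2$meta)
  expect_identical(ape::write.tree(s1$truth$gene_tree),
                   ape::write.tree(s2$truth$gene_tree))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_sim(s1, d1); write_sim(s2, d2)
  expect_identical(readLines(file.path(d1, "alignment.fasta")),
                   readLines(file.path(d2, "alignment.fasta")))
  expect_identical(readLines(file.path(d1, "metadata.tsv")),
                   readLines(file.path(d2, "metadata.tsv")))
})

test_that("a single simulated species stays shallow", {
  sim <- simulate_barcodes(sim_config(n_species = 1L, n_per_species = 8L,
                                      seed = 4L))
  expect_equal(n_otus(sim$truth$partition), 1L)
  D <- k2p_matrix(sim$alignment)
  expect_lt(max(D$d), 0.02)
})

test_that("depth contrast shows up as a between/within K2P ratio", {
  sim <- simulate_barcodes(sim_config(seed = 23L))
  D <- k2p_matrix(sim$alignment)
  t <- unclass(sim$truth$partition)
  idx <- which(upper.tri(D$d), arr.ind = TRUE)
  same <- t[D$ids[idx[, 1L]]] == t[D$ids[idx[, 2L]]]
  v <- D$d[idx]
  expect_gte(mean(v[!same]) / mean(v[same]), 10)
})

test_that("divergence grows monotonically with tree-path separation", {
  sim <- simulate_barcodes(sim_config(n_species = 4L, seed = 31L))
  D <- k2p_matrix(sim$alignment)
  paths <- ape::cophenetic.phylo(sim$truth$gene_tree)[D$ids, D$ids]
  idx <- which(upper.tri(D$d), arr.ind = TRUE)
  bins <- cut(paths[idx], breaks = c(0, 0.01, 0.05, 0.1, Inf))
  means <- tapply(D$d[idx], bins, mean)
  means <- means[!is.na(means)]
  expect_true(all(diff(means) > 0))
  # zero separation -> identical sequences
  z <- which(paths < 1e-12 & upper.tri(paths), arr.ind = TRUE)
  if (nrow(z)) expect_true(all(D$d[z] == 0))
})

test_that("transition/transversion proportions match the K80 expectation", {
  # independent oracle: P(t) and Q(t) from the matrix exponential of the
  # normalized K80 rate matrix
  kappa <- 4
  beta <- 1 / (kappa + 2); alpha <- kappa * beta
  R <- matrix(beta, 4, 4)
  R[1, 3] <- R[3, 1] <- R[2, 4] <- R[4, 2] <- alpha
  diag(R) <- 0; diag(R) <- -rowSums(R)
  t_tot <- 0.1
  Pm <- as.matrix(Matrix::expm(R * t_tot))
  exp_P <- Pm[1, 3]            # transition probability
  exp_Q <- Pm[1, 2] + Pm[1, 4] # transversion probability
  set.seed(55)
  tr <- ape::read.tree(text = sprintf("(A:%f,B:%f);", t_tot / 2, t_tot / 2))
  enc <- barcodelim:::sim_k80_sequences(tr, 60000L, kappa)
  cnt <- count_site_pairs(c("A", "C", "G", "T")[enc[1L, ]],
                          c("A", "C", "G", "T")[enc[2L, ]])
  expect_lt(abs(cnt$P - exp_P), 0.005)
  expect_lt(abs(cnt$Q - exp_Q), 0.005)
  # and the K2P estimator recovers the generating distance
  expect_lt(abs(k2p(cnt) - t_tot), 0.01)
})

test_that("sister species share a region exactly as often as requested", {
  shared <- function(p_sym, seeds) {
    vapply(seeds, function(s) {
      sim <- simulate_barcodes(sim_config(n_species = 2L, n_per_species = 2L,
                                          seq_length = 30L,
                                          p_sympatric_sisters = p_sym,
                                          seed = s))
      r <- sim$truth$species_regions
      length(intersect(r[["sp01"]], r[["sp02"]])) > 0L
    }, logical(1L))
  }
  expect_true(all(shared(1, 1:10)))
  expect_false(any(shared(0, 1:10)))
})

test_that("mislabeling rewires labels without touching the truth", {
  sim <- simulate_barcodes(sim_config(mislabel_rate = 0.3, seed = 77L))
  wrong <- sim$meta$species != unname(sim$truth$true_labels[sim$meta$id])
  expect_gt(mean(wrong), 0.05)
  expect_lt(mean(wrong), 0.6)
  expect_equal(n_otus(sim$truth$partition), 5L)
  # wrong labels always belong to another simulated species
  expect_true(all(sim$meta$species %in% sim$truth$true_labels))
})

test_that("impossible parameter combinations are refused", {
  expect_error(sim_config(pop_scale = 1.2), "pop_scale")
  expect_error(sim_config(pop_scale = 0.5, max_depth_ratio = 0.1),
               "depth contrast")
  expect_error(sim_config(mislabel_rate = 1), "mislabel_rate")
})

test_that("adjusted Rand matches an independent implementation", {
  ids <- paste0("x", 1:12)
  p1 <- otu_partition(setNames(rep(1:3, each = 4L), ids))
  expect_equal(adjusted_rand(p1, p1), 1)
  singletons <- otu_partition(setNames(1:12, ids))
  lump <- otu_partition(setNames(rep(1L, 12L), ids))
  expect_lte(adjusted_rand(singletons, lump), 0)
  set.seed(66)
  for (i in 1:20) {
    a <- otu_partition(setNames(sample(1:4, 12L, TRUE), ids))
    b <- otu_partition(setNames(sample(1:4, 12L, TRUE), ids))
    expect_equal(adjusted_rand(a, b),
                 mclust::adjustedRandIndex(unclass(a), unclass(b)[ids]),
                 tolerance = 1e-12)
  }
})

test_that("split and merge errors count lattice moves", {
  ids <- paste0("y", 1:6)
  truth <- otu_partition(setNames(c(1, 1, 1, 2, 2, 2), ids), "truth")
  est_split <- otu_partition(setNames(c(1, 1, 2, 3, 3, 3), ids))
  sc <- score_recovery(est_split, truth)
  expect_false(sc$exact_count_match)
  expect_equal(sc$split_errors, 1L)
  expect_equal(sc$merge_errors, 0L)
  est_merge <- otu_partition(setNames(rep(1L, 6L), ids))
  sc2 <- score_recovery(est_merge, truth)
  expect_equal(sc2$merge_errors, 1L)
  expect_equal(sc2$split_errors, 0L)
  sc3 <- score_recovery(truth, truth)
  expect_true(sc3$exact_count_match)
  expect_equal(sc3$adjusted_rand, 1)
})
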