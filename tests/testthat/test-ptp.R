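test_that("PTP log-likelihood matches the closed form", {
  # one class, two edges of length 1: lambda_hat = 1, loglik = -2
  tr <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(ptp_loglik(tr)$loglik, -2)

  # 4-leaf tree with both classes: independent re-derivation
  tr4 <- ape::read.tree(text = "((A:0.01,B:0.02):0.5,(C:0.015,D:0.025):0.6);")
  root <- 5L  # ntip + 1
  got <- ptp_loglik(tr4, speciation_nodes = root)
  b_s <- c(0.5, 0.6)                      # edges below the root
  b_c <- c(0.01, 0.02, 0.015, 0.025)      # edges inside the two species
  lam_s <- length(b_s) / sum(b_s)
  lam_c <- length(b_c) / sum(b_c)
  want <- sum(log(lam_s) - lam_s * b_s) + sum(log(lam_c) - lam_c * b_c)
  expect_equal(got$loglik, want, tolerance = 1e-12)
  expect_equal(got$lambda_s, lam_s)
  expect_equal(got$lambda_c, lam_c)
  expect_equal(got$n_species, 2L)

  # invalid (not ancestrally closed) speciation sets are rejected
  expect_error(ptp_loglik(tr4, speciation_nodes = 6L), "ancestrally closed")
})

test_that("log-likelihood depends only on edge lengths and classes", {
  tr <- ape::read.tree(text = "((A:0.01,B:0.02):0.5,(C:0.015,D:0.025):0.6);")
  tr2 <- tr
  tr2$tip.label <- c("W", "X", "Y", "Z")
  expect_equal(ptp_loglik(tr, 5L)$loglik, ptp_loglik(tr2, 5L)$loglik)
})

test_that("ML search separates two deep clades and matches the exhaustive oracle", {
  sim <- simulate_barcodes(sim_config(n_species = 2L, n_per_species = 4L,
                                      seed = 5L))
  tr <- midpoint_root(ape::unroot(sim$truth$gene_tree))
  fit <- ptp_ml_search(tr, method = "exhaustive")
  expect_equal(fit$n_species, 2L)
  expect_equal(adjusted_rand(fit$partition, sim$truth$partition), 1)
  greedy <- ptp_ml_search(tr, method = "greedy", seed = 2L)
  expect_equal(greedy$loglik, fit$loglik, tolerance = 1e-9)
  expect_equal(unclass(greedy$partition), unclass(fit$partition))
})

test_that("one-species null wins on a single coalescent cluster", {
  set.seed(12)
  for (i in 1:5) {
    tr <- ape::rcoal(8L)
    tr$edge.length <- tr$edge.length * 0.0015 /
      max(ape::node.depth.edgelength(tr))
    fit <- ptp_ml_search(tr, method = "exhaustive")
    expect_equal(fit$n_species, 1L)
  }
})

test_that("greedy equals exhaustive across random trees", {
  set.seed(13)
  for (i in 1:20) {
    tr <- ape::rcoal(sample(5:12, 1L))
    tr$edge.length <- tr$edge.length * runif(1L, 0.05, 0.3) /
      max(ape::node.depth.edgelength(tr))
    ex <- ptp_ml_search(tr, method = "exhaustive")
    gr <- ptp_ml_search(tr, method = "greedy", seed = i)
    expect_equal(gr$loglik, ex$loglik, tolerance = 1e-9)
  }
})

test_that("the state space enumeration counts ancestrally closed sets", {
  # balanced 4-leaf tree: internal nodes root,a,b; valid sets are
  # {}, {r}, {r,a}, {r,b}, {r,a,b} -> 5 states
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  states <- barcodelim:::enumerate_states(barcodelim:::ptp_prepare(tr))
  expect_equal(length(states), 5L)
  # caterpillar 5-leaf: g(v) = 1 + prod(children) along the path = 5 states
  tr2 <- ape::read.tree(text = "(((((A:1,B:1):1,C:1):1,D:1):1,E:1):1,F:1);")
  states2 <- barcodelim:::enumerate_states(barcodelim:::ptp_prepare(tr2))
  expect_equal(length(states2), 6L)
  # every enumerated state is ancestrally closed
  prep <- barcodelim:::ptp_prepare(tr2)
  for (s in states2) {
    if (!length(s)) next
    par <- prep$parent[s]
    expect_true(all(par == 0L | par %in% s | par == prep$root & prep$root %in% s))
  }
})

test_that("star trees degrade to one species with a warning", {
  tr <- ape::read.tree(text = "((A:0,B:0):0,(C:0,D:0):0);")
  expect_warning(fit <- ptp_ml_search(tr), "star")
  expect_equal(fit$n_species, 1L)
})

test_that("bPTP recovers deep clades with high support and is reproducible", {
  sim <- simulate_barcodes(sim_config(n_species = 2L, n_per_species = 4L,
                                      seed = 5L))
  tr <- midpoint_root(ape::unroot(sim$truth$gene_tree))
  fit <- suppressWarnings(bptp_mcmc(tr, generations = 20000L, seed = 9L))
  expect_equal(fit$posterior_mode_n, 2L)
  expect_equal(n_otus(fit$ml_partition), 2L)
  expect_true(all(fit$support >= 0.9))
  fit2 <- suppressWarnings(bptp_mcmc(tr, generations = 20000L, seed = 9L))
  expect_identical(fit$n_species_trace, fit2$n_species_trace)
  expect_identical(fit$support, fit2$support)
})

test_that("MCMC visit frequencies match the stationary distribution on a flat tree", {
  # all edges equal: states of equal likelihood must be visited equally
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  prep <- barcodelim:::ptp_prepare(tr)
  states <- barcodelim:::enumerate_states(prep)
  lls <- vapply(states, function(s) ptp_loglik(tr, s)$loglik, numeric(1L))
  post <- exp(lls - max(lls)); post <- post / sum(post)
  # theoretical distribution of n_species = |S| + 1
  ns <- vapply(states, length, integer(1L)) + 1L
  want <- vapply(sort(unique(ns)), function(k) sum(post[ns == k]), numeric(1L))
  fit <- suppressWarnings(bptp_mcmc(tr, generations = 100000L,
                                    burnin_fraction = 0.2, seed = 4L))
  trace <- fit$n_species_trace[-(1:20000)]
  got <- vapply(sort(unique(ns)), function(k) mean(trace == k), numeric(1L))
  expect_lt(max(abs(got - want)), 0.05)
})
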