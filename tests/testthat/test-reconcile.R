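p_of <- function(ids, groups, method = "ptp") {
  otu_partition(setNames(groups, ids), method = method)
}

test_that("congruent cores and conflict blocks follow set algebra", {
  ids <- c("A", "B", "C")
  pA <- p_of(ids, c(1, 1, 2), "gap")
  pB <- p_of(ids, c(1, 2, 3), "ptp")
  res <- congruent_core(pA, pB)
  expect_equal(res$congruent, list("C"))
  expect_equal(lapply(res$blocks, sort), list(c("A", "B")))

  # identical partitions: everything congruent
  res2 <- congruent_core(pA, pA)
  expect_equal(length(res2$congruent), 2L)
  expect_equal(res2$blocks, list())

  # nested coarse/fine (the typical gap-vs-PTP pattern): blocks are
  # exactly the coarse OTUs that the finer method splits
  ids6 <- paste0("s", 1:6)
  coarse <- p_of(ids6, c(1, 1, 1, 2, 2, 3), "gap")
  fine <- p_of(ids6, c(1, 1, 2, 3, 3, 4), "ptp")
  res3 <- congruent_core(coarse, fine)
  expect_equal(lapply(res3$blocks, sort), list(c("s1", "s2", "s3")))
  expect_setequal(vapply(res3$congruent, paste, character(1L),
                         collapse = ","),
                  c("s4,s5", "s6"))

  # cross-cutting OTUs coalesce into one block
  pX <- p_of(ids, c(1, 1, 2))
  pY <- p_of(ids, c(1, 2, 2))
  expect_equal(lapply(congruent_core(pX, pY)$blocks, sort),
               list(c("A", "B", "C")))

  expect_error(congruent_core(pA, p_of(c("A", "B", "Z"), c(1, 2, 3))),
               "different specimens.*Z")
})

test_that("sympatry predicate excludes UNKNOWN and detects overlap", {
  expect_equal(sympatric_status("SAS", c("ECS", "SCS")), "allopatric")
  expect_equal(sympatric_status("SCS", c("SCS", "IO")), "sympatric")
  expect_equal(sympatric_status("UNKNOWN", "IO"), "unknown")
  expect_equal(sympatric_status(c("UNKNOWN", "GC"), c("GC", "BP")), "sympatric")
  expect_equal(sympatric_status(character(), "IO"), "unknown")
})

scenario <- function(div, r1, r2, t_strong = 0.055, overrides = NULL) {
  g1 <- c("a1", "a2"); g2 <- c("b1", "b2")
  m <- block_matrix(list(g1, g2),
                    between = matrix(c(0, div, div, 0), 2, 2), w = 0.002)
  tr <- two_group_tree(g1, g2, div = div)
  meta <- toy_meta(c(g1, g2), rep(c("Sp one", "Sp two"), each = 2L),
                   rep(c(r1, r2), each = 2L))
  sub <- p_of(c(g1, g2), c(1, 1, 2, 2))
  cfg <- delim_config(t_strong = t_strong, morphology_overrides = overrides)
  resolve_conflict_block(c(g1, g2), sub, tr, m, meta, cfg)
}

test_that("allopatric sisters below the strong-divergence override merge", {
  # the 1.52% allopatric case: one species
  got <- scenario(0.0152, "CWP", "IO")
  expect_equal(length(got), 1L)
  expect_true(all(c("merged_allopatric", "tentative") %in% got[[1L]]$flags))
  expect_setequal(got[[1L]]$members, c("a1", "a2", "b1", "b2"))
})

test_that("allopatric sisters above the override are retained", {
  # the 5.73% transatlantic case: two species despite allopatry
  got <- scenario(0.0573, "GC", "TEA")
  expect_equal(length(got), 2L)
  expect_true(all(vapply(got, function(g)
    "strong_divergence_retained" %in% g$flags, logical(1L))))
})

test_that("sympatric sisters are retained regardless of shallow divergence", {
  got <- scenario(0.02, "SCS", "SCS")
  expect_equal(length(got), 2L)
  expect_true(all(vapply(got, function(g)
    "retained_sympatric" %in% g$flags, logical(1L))))
})

test_that("unknown regions block merging and mark the outcome tentative", {
  got <- scenario(0.02, "UNKNOWN", "UNKNOWN")
  expect_equal(length(got), 2L)
  expect_true(all(vapply(got, function(g) "tentative" %in% g$flags,
                         logical(1L))))
})

test_that("morphological overrides outrank the geographic rule", {
  ov_distinct <- data.frame(id1 = "a1", id2 = "b1", decision = "distinct")
  got <- scenario(0.0152, "CWP", "IO", overrides = ov_distinct)
  expect_equal(length(got), 2L)  # shallow allopatric pair kept split
  ov_con <- data.frame(id1 = "a1", id2 = "b1", decision = "conspecific")
  got2 <- scenario(0.02, "SCS", "SCS", overrides = ov_con)
  expect_equal(length(got2), 1L)  # sympatric pair merged on morphology
})

test_that("a three-OTU complex merges allopatric pair then keeps the sympatric survivor", {
  # undosquamis-style: O1 (ECS) and O2 (IO) allopatric at 3.6% -> merge;
  # the merged group is sympatric with O3 (ECS) -> two species remain
  g1 <- c("u1", "u2"); g2 <- c("u3", "u4"); g3 <- c("u5", "u6")
  bet <- matrix(c(0, .036, .07,
                  .036, 0, .07,
                  .07, .07, 0), 3, 3)
  m <- block_matrix(list(g1, g2, g3), between = bet, w = 0.003)
  tr <- ape::read.tree(text = paste0(
    "(((u1:0.002,u2:0.002):0.016,(u3:0.002,u4:0.002):0.016):0.017,",
    "(u5:0.002,u6:0.002):0.033);"))
  meta <- toy_meta(c(g1, g2, g3),
                   rep(c("S complexa", "S complexa", "S alia"), each = 2L),
                   rep(c("ECS", "IO", "ECS"), each = 2L))
  sub <- p_of(c(g1, g2, g3), rep(1:3, each = 2L))
  got <- resolve_conflict_block(c(g1, g2, g3), sub, tr, m, meta,
                                delim_config())
  expect_equal(length(got), 2L)
  merged <- got[[which(vapply(got, function(g) length(g$members) == 4L,
                              logical(1L)))]]
  expect_true("merged_allopatric" %in% merged$flags)
  expect_true("retained_sympatric" %in%
                unlist(lapply(got, `[[`, "flags")))
})

test_that("name incongruence is flagged in both directions", {
  ids <- paste0("n", 1:6)
  pA <- p_of(ids, c(1, 1, 2, 2, 3, 3), "gap")
  meta <- toy_meta(ids, c("X a", "Y b",        # mixed labels in one OTU
                          "Y b", "Y b",        # label Y spans OTUs 1 and 2
                          "Z c", "Z c"),       # clean
                   rep("SCS", 6L))
  tr <- two_group_tree(ids[1:3], ids[4:6], div = 0.08)
  m <- block_matrix(list(ids[1:2], ids[3:4], ids[5:6]),
                    between = matrix(c(0, .06, .09, .06, 0, .09,
                                       .09, .09, 0), 3, 3))
  tab <- reconcile(pA, pA, tr, m, meta)
  hy <- tab$hypotheses
  flagged <- vapply(hy$flags, function(f) "name_incongruent" %in% f,
                    logical(1L))
  expect_equal(sum(flagged), 2L)   # OTU with X+Y, and both OTUs sharing Y
  expect_false(flagged[3L])
  expect_equal(tab$name_report$polyphyletic_labels$label, "Y b")
  expect_equal(tab$name_report$polyphyletic_labels$n_otus, 2L)
})

test_that("names come from type localities, then majority, then stay open", {
  ids <- paste0("t", 1:6)
  p <- p_of(ids, c(1, 1, 1, 2, 2, 3))
  # OTU1: mixed labels, one type-locality member -> its label wins
  # OTU2: single label, no type locality -> majority
  # OTU3: tie between two labels -> unassigned
  meta <- toy_meta(ids, c("Saurida tumbil", "S other", "S other",
                          "S single", "S single", "S tie"),
                   rep("IO", 6L),
                   type_locality = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  # make OTU3 a genuine two-label tie by a second member
  ids7 <- c(ids, "t7")
  p <- p_of(ids7, c(1, 1, 1, 2, 2, 3, 3))
  meta <- toy_meta(ids7, c("Saurida tumbil", "S other", "S other",
                           "S single", "S single", "S tie", "S braid"),
                   rep("IO", 7L),
                   type_locality = c(TRUE, rep(FALSE, 6L)))
  tr <- two_group_tree(ids7[1:3], ids7[4:7], div = 0.08)
  m <- block_matrix(list(ids7[1:3], ids7[4:5], ids7[6:7]),
                    between = matrix(c(0, .07, .07, .07, 0, .03,
                                       .07, .03, 0), 3, 3))
  tab <- reconcile(p, p, tr, m, meta)
  hy <- tab$hypotheses
  expect_equal(hy$assigned_name[1L], "Saurida tumbil")
  expect_equal(hy$name_basis[1L], "type_locality")
  expect_equal(hy$assigned_name[2L], "S single")
  expect_equal(hy$name_basis[2L], "majority_label")
  expect_equal(hy$assigned_name[3L], "unassigned")
  expect_equal(hy$name_basis[3L], "none")
})

test_that("reconcile passes identical partitions through unchanged", {
  ids <- paste0("q", 1:6)
  p <- p_of(ids, c(1, 1, 2, 2, 3, 3))
  meta <- toy_meta(ids, rep(c("A a", "B b", "C c"), each = 2L),
                   rep("", 6L))  # no region data
  tr <- two_group_tree(ids[1:4], ids[5:6], div = 0.08)
  m <- block_matrix(list(ids[1:2], ids[3:4], ids[5:6]),
                    between = matrix(c(0, .05, .08, .05, 0, .08,
                                       .08, .08, 0), 3, 3))
  tab <- reconcile(p, p, tr, m, meta)
  expect_equal(nrow(tab$hypotheses), 3L)
  expect_equal(adjusted_rand(table_partition(tab), p), 1)
  expect_true(all(vapply(tab$hypotheses$flags, function(f)
    "congruent" %in% f, logical(1L))))
})

test_that("raising the strong-divergence override only ever merges more", {
  # allopatric ladder at 2% / 4% / 8%
  ids <- paste0("L", 1:8)
  gs <- split(ids, rep(1:4, each = 2L))
  bet <- matrix(c(0, .02, .04, .08,
                  .02, 0, .04, .08,
                  .04, .04, 0, .08,
                  .08, .08, .08, 0), 4, 4)
  m <- block_matrix(gs, between = bet, w = 0.002)
  tr <- ape::read.tree(text = paste0(
    "((((L1:.001,L2:.001):.009,(L3:.001,L4:.001):.009):.01,",
    "(L5:.001,L6:.001):.02):.02,(L7:.001,L8:.001):.04);"))
  meta <- toy_meta(ids, paste("Sp", rep(1:4, each = 2L)),
                   rep(c("GC", "BP", "TEA", "IO"), each = 2L))
  p1 <- p_of(ids, rep(1L, 8L), "gap")
  p4 <- p_of(ids, rep(1:4, each = 2L), "ptp")
  counts <- vapply(c(0.01, 0.03, 0.05, 0.09), function(ts)
    nrow(reconcile(p1, p4, tr, m, meta,
                   delim_config(t_low = 0.01, t_strong = ts))$hypotheses),
    numeric(1L))
  expect_equal(counts, c(4, 3, 2, 1))
  expect_true(all(diff(counts) <= 0))
})

test_that("with one shared region no merging ever happens", {
  sim <- simulate_barcodes(sim_config(n_species = 3L, n_per_species = 4L,
                                      regions_per_species = 1L, seed = 14L))
  sim$meta$region <- rep(list("SCS"), nrow(sim$meta))
  D <- k2p_matrix(sim$alignment)
  tr <- midpoint_root(suppressMessages(nj_tree(D)))
  p_fine <- ptp_ml_search(tr, seed = 1L)$partition
  p_coarse <- otu_partition(setNames(rep(1L, n_seq(sim$alignment)),
                                     sim$alignment$ids), "gap")
  tab <- reconcile(p_coarse, p_fine, tr, D, sim$meta)
  expect_equal(nrow(tab$hypotheses), n_otus(p_fine))
})

test_that("reconciled tables always partition the specimens", {
  for (s in 15:17) {
    sim <- simulate_barcodes(sim_config(seed = s))
    run <- suppressMessages(suppressWarnings(
      delim_run(sim$alignment, sim$meta, seed = s)))
    final <- run$partitions$final
    expect_setequal(names(final), sim$alignment$ids)
    expect_equal(sum(run$table$hypotheses$n_members), n_seq(sim$alignment))
  }
})
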