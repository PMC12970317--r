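# Poisson tree processes (PTP) delimiter.
#
# Branch lengths (substitutions) are modeled as draws from one of two
# exponential processes: speciation (between-species) and coalescent
# (within-species). A delimitation is encoded by the set S of internal
# "speciation nodes", constrained to be ancestrally closed (a node can be
# a speciation node only if its parent is). Edges whose parent node is in
# S are speciation-class; the species are the maximal subtrees whose
# internal edges are all coalescent-class. S = {} is the one-species
# state; any non-empty S contains the root. For a binary tree,
# n_species = |S| + 1. Class rates are profiled analytically
# (lambda_hat = 1/mean branch length in class).

# --- tree bookkeeping -------------------------------------------------

ptp_prepare <- function(tr, min_branch = 1e-3) {
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  if (!ape::is.rooted(tr)) stop("PTP requires a rooted tree")
  if (!ape::is.binary(tr)) {
    message("polytomy resolved arbitrarily with zero-length edges")
    tr <- ape::multi2di(tr, random = FALSE)
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  ntip <- length(tr$tip.label)
  b <- tr$edge.length
  # floor at the resolution of barcode-scale data (~half a substitution
  # on a 600-bp locus): the exponential density is undefined at zero mean
  # and near-zero estimated branches (identical haplotypes, clamped NJ
  # lengths) otherwise let one class's rate diverge, which drives
  # spurious oversplitting
  b[b < min_branch] <- min_branch
  root <- ntip + 1L
  # children of each internal node (list indexed by node - ntip)
  kids <- split(tr$edge[, 2L], factor(tr$edge[, 1L], levels = root:(ntip + tr$Nnode)))
  parent <- integer(ntip + tr$Nnode)
  parent[tr$edge[, 2L]] <- tr$edge[, 1L]
  # edge indices leading to the children of each internal node
  child_edges <- split(seq_len(nrow(tr$edge)),
                       factor(tr$edge[, 1L], levels = root:(ntip + tr$Nnode)))
  # internal-node-indexed helpers for fast move generation: parent's
  # internal index (0 for root) and the internal children of each node
  nnode <- tr$Nnode
  internal <- root:(ntip + nnode)
  parent_int <- ifelse(parent[internal] == 0L, 0L, parent[internal] - ntip)
  int_kids <- lapply(kids, function(k) k[k > ntip] - ntip)
  list(tree = tr, ntip = ntip, root = root, b = b, total = sum(b),
       n_edges = length(b), kids = kids, parent = parent,
       child_edges = child_edges, edge = tr$edge,
       parent_int = parent_int, int_kids = int_kids)
}

# log-likelihood from class aggregates (n_s, sum_s) speciation,
# (n_c, sum_c) coalescent; empty class => single-class likelihood
ll_from_sums <- function(n_s, sum_s, n_c, sum_c) {
  ll <- 0
  if (n_s > 0L) ll <- ll + n_s * log(n_s / sum_s) - n_s
  if (n_c > 0L) ll <- ll + n_c * log(n_c / sum_c) - n_c
  ll
}

state_sums <- function(prep, S) {
  # S: logical over internal nodes (index = node - ntip)
  sp_edge <- S[prep$edge[, 1L] - prep$ntip]
  n_s <- sum(sp_edge)
  sum_s <- sum(prep$b[sp_edge])
  list(n_s = n_s, sum_s = sum_s, n_c = prep$n_edges - n_s,
       sum_c = prep$total - sum_s)
}

#' PTP log-likelihood of an edge classification
#'
#' Sum over classes of the profiled exponential log-density
#' `n log(n/sum_b) - n` with `lambda_hat = n/sum_b`; if one class is
#' empty the likelihood is the single-class one.
#'
#' @param tr Rooted binary `phylo` tree.
#' @param speciation_nodes Integer vector of internal node numbers (ape
#'   numbering, root = ntip+1) forming an ancestrally closed set; the
#'   edges below these nodes are speciation-class.
#' @return List with `loglik`, `lambda_s`, `lambda_c`, `n_species`.
#' @export
ptp_loglik <- function(tr, speciation_nodes = integer()) {
  prep <- ptp_prepare(tr)
  S <- logical(prep$tree$Nnode)
  if (length(speciation_nodes)) {
    idx <- speciation_nodes - prep$ntip
    if (any(idx < 1L | idx > prep$tree$Nnode))
      stop("speciation_nodes must be internal node numbers")
    S[idx] <- TRUE
    par <- prep$parent[speciation_nodes]
    bad <- par != 0L & !S[pmax(par - prep$ntip, 1L)]
    if (any(bad)) stop("speciation node set is not ancestrally closed")
  }
  sums <- state_sums(prep, S)
  list(loglik = ll_from_sums(sums$n_s, sums$sum_s, sums$n_c, sums$sum_c),
       lambda_s = if (sums$n_s > 0) sums$n_s / sums$sum_s else NA_real_,
       lambda_c = if (sums$n_c > 0) sums$n_c / sums$sum_c else NA_real_,
       n_species = sum(S) + 1L)
}

# partition of tips implied by state S (logical over internal nodes):
# species = components connected by coalescent edges
state_partition <- function(prep, S) {
  lab <- seq_len(prep$ntip + prep$tree$Nnode)
  find <- function(i) { while (lab[i] != i) { lab[i] <<- lab[lab[i]]; i <- lab[i] }; i }
  coal <- !S[prep$edge[, 1L] - prep$ntip]
  for (e in which(coal)) {
    a <- find(prep$edge[e, 1L]); bb <- find(prep$edge[e, 2L])
    if (a != bb) lab[a] <- bb
  }
  roots <- vapply(seq_len(prep$ntip), find, numeric(1L))
  otu_partition(setNames(match(roots, unique(roots)), prep$tree$tip.label),
                method = "ptp")
}

# count of speciation-class internal children per internal node
sp_child_counts <- function(prep, S) {
  vapply(prep$int_kids, function(k) sum(S[k]), integer(1L))
}

# legal moves from state S (internal indices): add v (not in S, parent in
# S or v is root), remove v (in S, no child of v in S); `nsc` is the
# speciation-child count vector, maintained incrementally by callers
legal_moves <- function(prep, S, nsc = sp_child_counts(prep, S)) {
  par_ok <- prep$parent_int == 0L | S[pmax(prep$parent_int, 1L)]
  which((!S & par_ok) | (S & nsc == 0L)) + prep$ntip
}

# delta in class sums from flipping node v (its child edges change class)
flip_sums <- function(prep, sums, S, v) {
  es <- prep$child_edges[[v - prep$ntip]]
  db <- sum(prep$b[es])
  k <- length(es)
  if (!S[v - prep$ntip]) {  # add: child edges coalescent -> speciation
    list(n_s = sums$n_s + k, sum_s = sums$sum_s + db,
         n_c = sums$n_c - k, sum_c = sums$sum_c - db)
  } else {
    list(n_s = sums$n_s - k, sum_s = sums$sum_s - db,
         n_c = sums$n_c + k, sum_c = sums$sum_c + db)
  }
}

# enumerate all ancestrally closed speciation-node sets (logical matrices
# are wasteful; return list of integer node vectors)
enumerate_states <- function(prep) {
  rec <- function(v) {
    # choices for the subtree at internal node v, given parent in S:
    # v not in S -> {}, or v in S plus any combination below
    k <- prep$kids[[v - prep$ntip]]
    k <- k[k > prep$ntip]
    below <- list(integer())
    for (child in k) {
      ch <- rec(child)
      below <- unlist(lapply(below, function(a) lapply(ch, function(b) c(a, b))),
                      recursive = FALSE)
    }
    c(list(integer()), lapply(below, function(s) c(v, s)))
  }
  rec(prep$root)
}

#' Maximum-likelihood PTP partition
#'
#' For trees with up to `exhaustive_max` leaves the search enumerates all
#' valid speciation-node sets; above that a greedy hill-climb (best
#' single add/remove move until no improvement) is run from deterministic
#' starts (one-species, all-speciation) plus `restarts` random starts.
#'
#' @param tr Rooted `phylo` tree (binarized if needed).
#' @param method `"auto"`, `"exhaustive"` or `"greedy"`.
#' @param restarts Random restarts for the greedy search.
#' @param exhaustive_max Leaf-count limit for exhaustive enumeration.
#' @param null_alpha Significance level of the likelihood-ratio test of
#'   the two-rate model against the single-rate (one species) null; when
#'   the best partition does not beat the null at this level the
#'   one-species partition is returned (chi-square, 1 df). `NULL`
#'   disables the test.
#' @param seed Optional RNG seed for the random restarts.
#' @return Object of class `ptp_fit`: list with `partition`
#'   ([otu_partition()]), `speciation_nodes`, `loglik`, `lambda_s`,
#'   `lambda_c`, `n_species`, `method`.
#' @export
ptp_ml_search <- function(tr, method = c("auto", "exhaustive", "greedy"),
                          restarts = 20L, exhaustive_max = 12L,
                          null_alpha = 0.05, seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  prep <- ptp_prepare(tr)
  if (prep$ntip < 2L) stop("need at least 2 leaves")
  if (all(prep$tree$edge.length <= 0)) {
    warning("star-like tree with zero total length: one-species partition")
    S <- logical(prep$tree$Nnode)
    return(ptp_result(prep, S, "degenerate"))
  }
  if (method == "auto")
    method <- if (prep$ntip <= exhaustive_max) "exhaustive" else "greedy"

  if (method == "exhaustive") {
    states <- enumerate_states(prep)
    best <- NULL; best_ll <- -Inf
    for (s in states) {
      S <- logical(prep$tree$Nnode)
      S[s - prep$ntip] <- TRUE
      sums <- state_sums(prep, S)
      ll <- ll_from_sums(sums$n_s, sums$sum_s, sums$n_c, sums$sum_c)
      if (ll > best_ll + 1e-12 ||
          (abs(ll - best_ll) <= 1e-12 && !is.null(best) && sum(S) < sum(best))) {
        best <- S; best_ll <- ll
      }
    }
    return(ptp_result(prep, lrt_guard(prep, best, best_ll, null_alpha),
                      "exhaustive"))
  }

  climb <- function(S) {
    sums <- state_sums(prep, S)
    ll <- ll_from_sums(sums$n_s, sums$sum_s, sums$n_c, sums$sum_c)
    repeat {
      moves <- legal_moves(prep, S)
      if (!length(moves)) break
      lls <- vapply(moves, function(v) {
        ns <- flip_sums(prep, sums, S, v)
        ll_from_sums(ns$n_s, ns$sum_s, ns$n_c, ns$sum_c)
      }, numeric(1L))
      i <- which.max(lls)
      if (lls[i] <= ll + 1e-12) break
      v <- moves[i]
      sums <- flip_sums(prep, sums, S, v)
      S[v - prep$ntip] <- !S[v - prep$ntip]
      ll <- lls[i]
    }
    list(S = S, ll = ll)
  }
  random_state <- function() {
    S <- logical(prep$tree$Nnode)
    p <- runif(1L)
    # top-down: include each internal node with prob p given parent in S
    for (v in prep$root:(prep$ntip + prep$tree$Nnode)) {
      par <- prep$parent[v]
      if (par == 0L || S[par - prep$ntip]) S[v - prep$ntip] <- runif(1L) < p
    }
    S
  }
  starts <- c(list(logical(prep$tree$Nnode), rep(TRUE, prep$tree$Nnode)),
              replicate(restarts, random_state(), simplify = FALSE))
  best <- NULL; best_ll <- -Inf
  for (S0 in starts) {
    res <- climb(S0)
    if (res$ll > best_ll + 1e-12 ||
        (abs(res$ll - best_ll) <= 1e-12 && !is.null(best) &&
         sum(res$S) < sum(best))) {
      best <- res$S; best_ll <- res$ll
    }
  }
  ptp_result(prep, lrt_guard(prep, best, best_ll, null_alpha), "greedy")
}

# likelihood-ratio guard against the single-rate null: without it the
# two-class ML essentially never returns one species (any length
# heterogeneity buys a positive gain for the extra rate)
lrt_guard <- function(prep, S, ll, null_alpha) {
  if (is.null(null_alpha) || !any(S)) return(S)
  null_sums <- state_sums(prep, logical(prep$tree$Nnode))
  null_ll <- ll_from_sums(null_sums$n_s, null_sums$sum_s,
                          null_sums$n_c, null_sums$sum_c)
  if (2 * (ll - null_ll) < stats::qchisq(1 - null_alpha, df = 1L))
    return(logical(prep$tree$Nnode))
  S
}

ptp_result <- function(prep, S, method) {
  sums <- state_sums(prep, S)
  structure(list(
    partition = state_partition(prep, S),
    speciation_nodes = which(S) + prep$ntip,
    loglik = ll_from_sums(sums$n_s, sums$sum_s, sums$n_c, sums$sum_c),
    lambda_s = if (sums$n_s > 0) sums$n_s / sums$sum_s else NA_real_,
    lambda_c = if (sums$n_c > 0) sums$n_c / sums$sum_c else NA_real_,
    n_species = sum(S) + 1L, method = method), class = "ptp_fit")
}

#' @export
print.ptp_fit <- function(x, ...) {
  cat("PTP ML fit (", x$method, "): ", x$n_species, " species, loglik ",
      sprintf("%.3f", x$loglik), "\n", sep = "")
  invisible(x)
}

#' Bayesian PTP (bPTP) MCMC over delimitations
#'
#' Metropolis sampler over valid speciation-node sets with uniform prior
#' and single-node flip proposals (Hastings-corrected for the differing
#' numbers of legal moves). Reports the maximum-likelihood partition
#' encountered, the posterior distribution of the species count, and the
#' posterior support of each OTU of the ML partition (the fraction of
#' post-burn-in samples in which exactly that member set is a species).
#'
#' @param tr Rooted `phylo` tree.
#' @param generations MCMC generations (default 500000).
#' @param burnin_fraction Fraction of generations discarded (default 0.1).
#' @param thin Store a full partition sample every `thin` generations
#'   (default keeps ~1000 samples).
#' @param seed RNG seed; the chain is reproducible given the seed.
#' @return Object of class `bptp_fit`: list with `ml_partition`,
#'   `ml_loglik`, `support` (per-OTU posterior support of the ML
#'   partition), `n_species_trace`, `posterior_mean_n`,
#'   `posterior_mode_n`, `acceptance_rate`, `settings`.
#' @export
bptp_mcmc <- function(tr, generations = 500000L, burnin_fraction = 0.1,
                      thin = NULL, seed = NULL) {
  stopifnot(generations >= 1L, burnin_fraction >= 0, burnin_fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  prep <- ptp_prepare(tr)
  if (is.null(thin)) thin <- max(1L, generations %/% 1000L)
  nnode <- prep$tree$Nnode
  S <- logical(nnode)
  nsc <- sp_child_counts(prep, S)
  # per-node child-edge count and summed child-edge length, for O(1) flips
  kv <- lengths(prep$child_edges)
  dbv <- vapply(prep$child_edges, function(es) sum(prep$b[es]), numeric(1L))
  parent_int <- prep$parent_int
  n_s <- 0; sum_s <- 0; n_c <- prep$n_edges; sum_c <- prep$total
  llf <- function(ns, ss, nc, sc)
    (if (ns > 0) ns * log(ns / ss) - ns else 0) +
    (if (nc > 0) nc * log(nc / sc) - nc else 0)
  ll <- llf(n_s, sum_s, n_c, sum_c)
  best_S <- S; best_ll <- ll
  n_trace <- integer(generations)
  n_cur <- 1L
  samples <- list()
  accepted <- 0L
  burn <- floor(generations * burnin_fraction)
  log_us <- log(runif(generations))  # pre-drawn acceptance variates
  root_mask <- parent_int == 0L
  parent_fix <- ifelse(root_mask, 1L, parent_int)
  n_moves <- function() {
    (!S & (root_mask | S[parent_fix])) | (S & nsc == 0L)
  }
  for (g in seq_len(generations)) {
    mv <- which(n_moves())
    vi <- mv[sample.int(length(mv), 1L)]
    add <- !S[vi]
    d_n <- if (add) kv[vi] else -kv[vi]
    d_b <- if (add) dbv[vi] else -dbv[vi]
    ns2 <- n_s + d_n; ss2 <- sum_s + d_b
    nc2 <- n_c - d_n; sc2 <- sum_c - d_b
    new_ll <- llf(ns2, ss2, nc2, sc2)
    S[vi] <- add
    pv <- parent_int[vi]
    if (pv > 0L) nsc[pv] <- nsc[pv] + if (add) 1L else -1L
    n_back <- sum(n_moves())
    # q(x->y) = 1/|moves(x)|; accept with ll ratio times |moves(x)|/|moves(y)|
    if (log_us[g] < new_ll - ll + log(length(mv)) - log(n_back)) {
      n_s <- ns2; sum_s <- ss2; n_c <- nc2; sum_c <- sc2
      ll <- new_ll; accepted <- accepted + 1L
      n_cur <- sum(S) + 1L
      if (ll > best_ll) { best_ll <- ll; best_S <- S }
    } else {  # revert
      if (pv > 0L) nsc[pv] <- nsc[pv] - if (add) 1L else -1L
      S[vi] <- !add
    }
    n_trace[g] <- n_cur
    if (g > burn && g %% thin == 0L)
      samples[[length(samples) + 1L]] <- which(S)
  }
  acc <- accepted / generations
  if (acc < 0.01 || acc > 0.99)
    warning(sprintf("possible non-mixing: acceptance rate %.3f", acc))
  ml_part <- state_partition(prep, best_S)
  # per-OTU posterior support of the ML partition
  ml_sets <- lapply(otu_members(ml_part), sort)
  support <- numeric(length(ml_sets))
  if (length(samples)) {
    for (s in samples) {
      Ss <- logical(prep$tree$Nnode); Ss[s] <- TRUE
      sets <- lapply(otu_members(state_partition(prep, Ss)), sort)
      keys <- vapply(sets, paste, character(1L), collapse = "\r")
      support <- support +
        vapply(ml_sets, paste, character(1L), collapse = "\r") %in% keys
    }
    support <- support / length(samples)
  }
  post <- n_trace[(burn + 1L):generations]
  structure(list(
    ml_partition = ml_part, ml_loglik = best_ll,
    support = setNames(support, paste0("OTU", seq_along(support))),
    n_species_trace = n_trace,
    posterior_mean_n = mean(post),
    posterior_mode_n = as.integer(names(which.max(table(post)))),
    acceptance_rate = acc,
    settings = list(generations = generations, thin = thin,
                    burnin_fraction = burnin_fraction, seed = seed)),
    class = "bptp_fit")
}

#' @export
print.bptp_fit <- function(x, ...) {
  cat("bPTP: ML partition with ", n_otus(x$ml_partition),
      " species (loglik ", sprintf("%.3f", x$ml_loglik),
      "); posterior mode ", x$posterior_mode_n,
      ", mean ", sprintf("%.2f", x$posterior_mean_n),
      "; acceptance ", sprintf("%.2f", x$acceptance_rate), "\n", sep = "")
  invisible(x)
}
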