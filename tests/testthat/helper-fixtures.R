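# Fixture builders shared across the test files. Everything is generated
# in code; no stored data.

# toy 6-specimen matrix: two tight clusters (within <= 0.01) separated by
# >= 0.08, labels a1..a3 / b1..b3
two_cluster_matrix <- function() {
  ids <- c("a1", "a2", "a3", "b1", "b2", "b3")
  m <- matrix(0.09, 6, 6, dimnames = list(ids, ids))
  within <- matrix(c(0, .008, .010,
                     .008, 0, .006,
                     .010, .006, 0), 3, 3)
  m[1:3, 1:3] <- within
  m[4:6, 4:6] <- within
  m[5, 6] <- m[6, 5] <- 0.004
  diag(m) <- 0
  m[1, 4] <- m[4, 1] <- 0.08
  m
}

# metadata frame for hand-built cases: one row per id
toy_meta <- function(ids, species, regions, type_locality = FALSE) {
  data.frame(id = ids, species = species,
             locality = "", stringsAsFactors = FALSE) |>
    within({
      region <- lapply(strsplit(regions, ",", fixed = TRUE), trimws)
      type_locality <- rep_len(type_locality, length(ids))
      source <- "novel"
    })
}

# a cherry-pair guide tree over two groups of ids, with the two groups as
# sister clades at divergence `div`
two_group_tree <- function(g1, g2, div = 0.05, within = 0.002) {
  clade <- function(ids) {
    if (length(ids) == 1L) return(sprintf("%s:%.6f", ids, div / 2))
    inner <- paste(sprintf("%s:%.6f", ids, within), collapse = ",")
    sprintf("(%s):%.6f", inner, div / 2 - within)
  }
  ape::read.tree(text = paste0("(", clade(g1), ",", clade(g2), ");"))
}

# block-structured distance matrix: within-group `w`, between groups from
# the `between` matrix (indexed by group)
block_matrix <- function(groups, between, w = 0.005) {
  ids <- unlist(groups)
  g_of <- rep(seq_along(groups), lengths(groups))
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i == j) next
    m[i, j] <- if (g_of[i] == g_of[j]) w else between[g_of[i], g_of[j]]
  }
  m
}

# random tree with uniform branch lengths; the induced cophenetic matrix
# is additive by construction
random_additive_matrix <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- runif(nrow(tr$edge), 0.01, 0.2)
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

# random distances from points on a line (positive, distinct-ish)
random_point_matrix <- function(n) {
  x <- sort(runif(n, 0, 0.2))
  m <- abs(outer(x, x, "-"))
  ids <- paste0("t", seq_len(n))
  dimnames(m) <- list(ids, ids)
  m
}

# independent brute-force connected components (DFS) of the d <= t graph
components_oracle <- function(m, t) {
  n <- nrow(m)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[[1L]]; stack <- stack[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      stack <- c(stack, which(m[v, ] <= t & is.na(comp)))
    }
  }
  setNames(comp, rownames(m))
}

# random IUPAC-ish sequence pair with controlled divergence and noise
random_seq_pair <- function(len = 600L) {
  bases <- c("A", "C", "G", "T")
  a <- sample(bases, len, replace = TRUE)
  b <- a
  nmut <- rbinom(1L, len, 0.08)
  pos <- sample.int(len, nmut)
  b[pos] <- sample(bases, nmut, replace = TRUE)
  # sprinkle gaps/N/ambiguities into both
  for (v in c("a", "b")) {
    s <- get(v)
    idx <- sample.int(len, rbinom(1L, len, 0.03))
    s[idx] <- sample(c("-", "N", "R", "Y"), length(idx), replace = TRUE)
    assign(v, s)
  }
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

# closed-form K2P evaluated independently (explicit column scan + formula)
k2p_oracle <- function(sa, sb) {
  a <- strsplit(sa, "")[[1L]]; b <- strsplit(sb, "")[[1L]]
  n <- 0L; ts <- 0L; tv <- 0L
  pur <- c("A", "G"); pyr <- c("C", "T")
  for (i in seq_along(a)) {
    if (!(a[i] %in% c(pur, pyr)) || !(b[i] %in% c(pur, pyr))) next
    n <- n + 1L
    if (a[i] == b[i]) next
    same_class <- (a[i] %in% pur) == (b[i] %in% pur)
    if (same_class) ts <- ts + 1L else tv <- tv + 1L
  }
  P <- ts / n; Q <- tv / n
  list(n = n, ts = ts, tv = tv,
       d = -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q))
}
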