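# Kimura two-parameter (K2P) pairwise distances.
#
# Only unambiguous A/C/G/T columns shared by both sequences are compared
# (pairwise deletion); ambiguity codes, gaps and N are excluded per pair.

# Integer encoding A=1 C=2 G=3 T=4 (U treated as T); everything else NA.
encode_nt <- function(chars) {
  code <- match(chars, c("A", "C", "G", "T"))
  code[chars == "U"] <- 4L
  code
}

encode_alignment <- function(aln) {
  mat <- matrix(encode_nt(aln$seq), nrow = nrow(aln$seq))
  rownames(mat) <- aln$ids
  mat
}

#' Count comparable site pairs between two aligned sequences
#'
#' Tallies transitions (A<->G, C<->T) and transversions over the columns
#' where both sequences carry an unambiguous A/C/G/T (pairwise deletion of
#' gaps, N and ambiguity codes).
#'
#' @param seq_a,seq_b Equal-length nucleotide strings (or character
#'   vectors of single bases).
#' @param ids Optional pair of labels used in error messages.
#' @return An object of class `site_pair_counts`: list with `n_compared`,
#'   `transitions`, `transversions`, and the proportions `P` and `Q`.
#' @export
count_site_pairs <- function(seq_a, seq_b, ids = c("seq_a", "seq_b")) {
  a <- if (length(seq_a) == 1L) strsplit(toupper(seq_a), "")[[1L]] else toupper(seq_a)
  b <- if (length(seq_b) == 1L) strsplit(toupper(seq_b), "")[[1L]] else toupper(seq_b)
  if (length(a) != length(b))
    stop("sequences have unequal lengths (", length(a), " vs ", length(b), ")")
  site_pair_counts_int(encode_nt(a), encode_nt(b), ids)
}

# core on integer-encoded sequences (1..4 or NA)
site_pair_counts_int <- function(a, b, ids = c("seq_a", "seq_b")) {
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n == 0L)
    stop("no comparable sites between '", ids[1L], "' and '", ids[2L], "'")
  x <- a[ok]; y <- b[ok]
  diff <- x != y
  # transition partner: A<->G (1<->3), C<->T (2<->4)
  ts <- sum(diff & (((x + 1L) %% 4L) + 1L == y))
  tv <- sum(diff) - ts
  structure(list(n_compared = n, transitions = ts, transversions = tv,
                 P = ts / n, Q = tv / n, ids = ids),
            class = "site_pair_counts")
}

#' @export
print.site_pair_counts <- function(x, ...) {
  cat("Site pairs: n =", x$n_compared, " transitions =", x$transitions,
      " transversions =", x$transversions,
      sprintf(" (P = %.4f, Q = %.4f)\n", x$P, x$Q))
  invisible(x)
}

#' Kimura two-parameter distance
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` where `P` and `Q` are the
#' observed transition and transversion proportions. Saturated pairs
#' (either log argument non-positive) raise a condition of class
#' `k2p_saturation`.
#'
#' @param counts A `site_pair_counts` object, or the transition proportion
#'   `P` when `Q` is given.
#' @param Q Transversion proportion (only when `counts` is numeric `P`).
#' @return Distance in substitutions per site (>= 0).
#' @export
k2p <- function(counts, Q = NULL) {
  if (inherits(counts, "site_pair_counts")) {
    P <- counts$P; Q <- counts$Q
  } else {
    P <- counts
    if (is.null(Q)) stop("supply Q with a numeric P")
  }
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (any(w1 <= 0 | w2 <= 0))
    stop(structure(class = c("k2p_saturation", "error", "condition"),
                   list(message = sprintf(
                     "K2P distance undefined (saturation): P = %.4f, Q = %.4f", P, Q),
                     call = sys.call(-1L))))
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' K2P distance matrix for an alignment
#'
#' All pairwise K2P distances under pairwise deletion. Saturated pairs
#' (and pairs with no comparable sites) are assigned the cap value so the
#' matrix stays finite for clustering, and are listed in the
#' `$saturated` element so downstream threshold sweeps can exclude them.
#'
#' @param aln A `dna_alignment`.
#' @param saturation_cap Distance assigned to saturated/incomparable
#'   pairs (default 1.0 substitutions/site).
#' @return An object of class `k2p_matrix`: list with `ids`, `d` (square
#'   symmetric matrix), `P`, `Q`, `n_compared` matrices, and `saturated`
#'   (2-column matrix of offending id pairs, possibly empty).
#' @export
k2p_matrix <- function(aln, saturation_cap = 1.0) {
  stopifnot(inherits(aln, "dna_alignment"))
  n <- n_seq(aln)
  if (n < 2L) stop("need at least 2 sequences")
  enc <- encode_alignment(aln)
  d <- Pm <- Qm <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  nm <- matrix(aln$length, n, n, dimnames = list(aln$ids, aln$ids))
  sat <- list()
  for (i in seq_len(n - 1L)) {
    ai <- enc[i, ]
    for (j in (i + 1L):n) {
      cnt <- tryCatch(site_pair_counts_int(ai, enc[j, ], aln$ids[c(i, j)]),
                      error = function(e) e)
      if (inherits(cnt, "error")) {
        d[i, j] <- d[j, i] <- saturation_cap
        nm[i, j] <- nm[j, i] <- 0
        sat[[length(sat) + 1L]] <- aln$ids[c(i, j)]
        next
      }
      Pm[i, j] <- Pm[j, i] <- cnt$P
      Qm[i, j] <- Qm[j, i] <- cnt$Q
      nm[i, j] <- nm[j, i] <- cnt$n_compared
      dij <- tryCatch(k2p(cnt), k2p_saturation = function(e) NA_real_)
      if (is.na(dij)) {
        d[i, j] <- d[j, i] <- saturation_cap
        sat[[length(sat) + 1L]] <- aln$ids[c(i, j)]
      } else d[i, j] <- d[j, i] <- dij
    }
  }
  if (length(sat))
    message(length(sat), " saturated/incomparable pair(s) capped at ",
            saturation_cap)
  structure(list(ids = aln$ids, d = d, P = Pm, Q = Qm, n_compared = nm,
                 saturated = do.call(rbind, c(sat, list(matrix(character(), 0, 2)))),
                 saturation_cap = saturation_cap),
            class = "k2p_matrix")
}

#' @export
print.k2p_matrix <- function(x, ...) {
  off <- x$d[upper.tri(x$d)]
  cat("K2P distance matrix: ", length(x$ids), " specimens; d in [",
      sprintf("%.4f", min(off)), ", ", sprintf("%.4f", max(off)), "]; ",
      nrow(x$saturated), " saturated pair(s)\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.k2p_matrix <- function(x, ...) x$d

# Accept a k2p_matrix, dist, or plain symmetric matrix.
as_dist_matrix <- function(D) {
  if (inherits(D, "k2p_matrix")) return(D$d)
  if (inherits(D, "dist")) return(as.matrix(D))
  if (is.matrix(D)) {
    if (is.null(rownames(D))) {
      lab <- paste0("t", seq_len(nrow(D)))
      dimnames(D) <- list(lab, lab)
    }
    return(D)
  }
  stop("cannot interpret distance input of class ", class(D)[1L])
}

# id pairs excluded from gap statistics (saturated), as a "i|j" key set
saturated_keys <- function(D) {
  if (!inherits(D, "k2p_matrix") || nrow(D$saturated) == 0L) return(character())
  apply(D$saturated, 1L, function(p) paste(sort(p), collapse = "\r"))
}

#' Write a distance matrix
#'
#' Writes the square matrix in tab-delimited PHYLIP-like form
#' (`path`), and optionally a long-form per-pair table
#' (`id1, id2, n_compared, P, Q, d`) when `long_path` is given.
#'
#' @param D A `k2p_matrix`.
#' @param path Output path for the square matrix.
#' @param long_path Optional output path for the long form.
#' @export
write_distances <- function(D, path, long_path = NULL) {
  stopifnot(inherits(D, "k2p_matrix"))
  con <- file(path, "w")
  writeLines(as.character(length(D$ids)), con)
  for (i in seq_along(D$ids))
    writeLines(paste(c(D$ids[i], sprintf("%.8f", D$d[i, ])), collapse = "\t"), con)
  close(con)
  if (!is.null(long_path)) {
    idx <- which(upper.tri(D$d), arr.ind = TRUE)
    long <- data.frame(id1 = D$ids[idx[, 1L]], id2 = D$ids[idx[, 2L]],
                       n_compared = D$n_compared[idx],
                       P = D$P[idx], Q = D$Q[idx], d = D$d[idx])
    write.table(long, long_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
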