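# Guide-tree construction: neighbor joining from the K2P matrix and
# midpoint rooting. An externally built (e.g. ML) tree can be supplied to
# the pipeline instead; NJ is the no-dependency default.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ on the K2P matrix. Negative estimated branch lengths are
#' clamped to zero (the number clamped is reported with a message).
#'
#' @param D A `k2p_matrix`, `dist`, or square symmetric matrix.
#' @return An unrooted binary `phylo` tree whose leaf set equals the
#'   matrix ids.
#' @export
nj_tree <- function(D) {
  m <- as_dist_matrix(D)
  if (nrow(m) < 3L)
    stop("need at least 3 taxa for NJ; for 2 taxa split the single ",
         "distance over a one-edge tree")
  if (any(!is.finite(m))) stop("distance matrix has non-finite entries")
  tr <- ape::nj(m)
  neg <- sum(tr$edge.length < 0)
  if (neg > 0) {
    message(neg, " negative NJ branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path, the
#' documented default rooting for the PTP delimiter when no externally
#' rooted tree is supplied.
#'
#' @param tr An (unrooted) `phylo` tree with >= 2 leaves.
#' @return A rooted binary `phylo` tree.
#' @export
midpoint_root <- function(tr) {
  if (length(tr$tip.label) < 2L) stop("need >= 2 leaves")
  if (length(tr$tip.label) == 2L) {
    # split the leaf-to-leaf path evenly
    h <- sum(tr$edge.length) / 2
    return(ape::read.tree(text = sprintf("(%s:%.12f,%s:%.12f);",
                                         tr$tip.label[1L], h,
                                         tr$tip.label[2L], h)))
  }
  out <- phangorn::midpoint(tr)
  if (!ape::is.binary(out)) out <- ape::multi2di(out, random = FALSE)
  out$edge.length[is.na(out$edge.length)] <- 0
  out
}

#' Leaf-to-leaf path-length matrix
#'
#' @param tr A `phylo` tree with branch lengths.
#' @return Square matrix of pairwise path lengths, ordered by tip label.
#' @export
path_length_matrix <- function(tr) {
  m <- ape::cophenetic.phylo(tr)
  m[order(rownames(m)), order(colnames(m)), drop = FALSE]
}
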