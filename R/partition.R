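# OTU partitions: the common currency of the delimiters.

#' Construct an OTU partition
#'
#' @param assignment Named vector (names = specimen ids) of OTU labels;
#'   labels are recoded to contiguous integer indices starting at 1, in
#'   order of first appearance.
#' @param method One of `"gap"`, `"ptp"`, `"reconciled"`, `"truth"`.
#' @return Named integer vector of class `otu_partition` with attribute
#'   `method`.
#' @export
otu_partition <- function(assignment, method = c("gap", "ptp", "reconciled", "truth")) {
  method <- match.arg(method)
  if (is.null(names(assignment)) || anyDuplicated(names(assignment)))
    stop("assignment must be uniquely named by specimen id")
  idx <- match(assignment, unique(assignment))
  structure(setNames(idx, names(assignment)), method = method,
            class = "otu_partition")
}

#' Number of OTUs in a partition
#' @param p An `otu_partition`.
#' @export
n_otus <- function(p) length(unique(unclass(p)))

#' OTU member lists
#' @param p An `otu_partition`.
#' @return List of character vectors of specimen ids, one per OTU.
#' @export
otu_members <- function(p) {
  unname(split(names(p), unclass(p)))[order(unique(unclass(p)))]
}

#' @export
print.otu_partition <- function(x, ...) {
  cat("OTU partition (", attr(x, "method"), "): ", length(x),
      " specimens in ", n_otus(x), " OTUs\n", sep = "")
  invisible(x)
}

#' Restrict a partition to a subset of specimens
#' @param p An `otu_partition`.
#' @param ids Specimen ids to keep.
#' @export
restrict_partition <- function(p, ids) {
  stopifnot(all(ids %in% names(p)))
  otu_partition(unclass(p)[ids], method = attr(p, "method"))
}

#' Write a partition as TSV (specimen_id, otu)
#' @param p An `otu_partition`.
#' @param path Output path.
#' @export
write_partition <- function(p, path) {
  write.table(data.frame(specimen_id = names(p), otu = as.integer(p)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
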