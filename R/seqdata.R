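# Domain types and I/O: alignments, specimen metadata, region codes, trees.

# IUPAC nucleotide alphabet plus gap/missing, as stored (interpretation of
# ambiguity codes is deferred to the distance layer).
IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-", "?")

#' Biogeographic region vocabulary
#'
#' The closed set of region codes used by the sympatry/allopatry predicate:
#' Greater Caribbean (GC), Brazilian provinces (BP), tropical East Atlantic
#' (TEA), East China Sea (ECS), South China Sea (SCS), Sahul Shelf and
#' Australia (SAS), Central West Pacific (CWP) and Indian Ocean (IO).
#' Additional codes can be declared per run via the `extra_regions`
#' argument of the readers and [delim_config()]; the sentinel `UNKNOWN`
#' never counts as overlapping any region.
#'
#' @format Character vector of 8 region codes.
#' @export
REGION_CODES <- c("GC", "BP", "TEA", "ECS", "SCS", "SAS", "CWP", "IO")

#' Construct a barcode alignment
#'
#' @param seqs Named character vector of equal-length nucleotide sequences
#'   (names are specimen ids), or a character matrix with one row per
#'   specimen and one column per site.
#' @return An object of class `dna_alignment`: a list with elements `ids`,
#'   `seq` (character matrix, rows = specimens, uppercase) and `length`.
#' @export
dna_alignment <- function(seqs) {
  if (is.matrix(seqs)) {
    mat <- toupper(seqs)
    ids <- rownames(mat)
  } else {
    if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
      stop("sequences must be named by specimen id")
    ids <- names(seqs)
    lens <- nchar(seqs)
    if (any(lens == 0L)) stop("empty sequence for id '", ids[lens == 0L][1L], "'")
    if (length(unique(lens)) != 1L) {
      bad <- which(lens != lens[1L])[1L]
      stop("alignment error: record ", bad, " ('", ids[bad], "') has length ",
           lens[bad], ", expected ", lens[1L])
    }
    mat <- matrix(unlist(strsplit(toupper(seqs), "", fixed = TRUE)),
                  nrow = length(seqs), byrow = TRUE)
    rownames(mat) <- ids
  }
  if (is.null(ids)) stop("sequences must be named by specimen id")
  if (anyDuplicated(ids))
    stop("duplicate specimen id: '", ids[duplicated(ids)][1L], "'")
  if (ncol(mat) == 0L) stop("alignment has zero columns")
  bad <- !(mat %in% IUPAC_CHARS)
  if (any(bad)) {
    ij <- which(matrix(bad, nrow(mat)), arr.ind = TRUE)[1L, ]
    stop("invalid character '", mat[ij[1L], ij[2L]], "' in sequence '",
         ids[ij[1L]], "' at column ", ij[2L])
  }
  structure(list(ids = ids, seq = mat, length = ncol(mat)),
            class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("Barcode alignment: ", length(x$ids), " sequences x ", x$length,
      " bp\n", sep = "")
  invisible(x)
}

#' @export
as.character.dna_alignment <- function(x, ...) {
  setNames(apply(x$seq, 1L, paste, collapse = ""), x$ids)
}

#' Number of sequences in an alignment
#' @param x A `dna_alignment`.
#' @export
n_seq <- function(x) length(x$ids)

#' Read an aligned FASTA file
#'
#' Specimen ids are taken from the first whitespace-delimited token of each
#' header line; sequences are uppercased. All records must have identical
#' length (the file is an alignment, not raw reads).
#'
#' @param path Path to a FASTA file.
#' @return A [dna_alignment()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("no sequences in ", path)
  ids <- vapply(strsplit(names(dna), "[ \t]+"), `[[`, character(1L), 1L)
  seqs <- vapply(as.character(dna), paste, character(1L), collapse = "")
  names(seqs) <- ids
  dna_alignment(seqs)
}

#' Write an alignment to FASTA
#'
#' @param aln A `dna_alignment`.
#' @param path Output path.
#' @export
write_fasta <- function(aln, path) {
  seqs <- as.character(aln)
  writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)), path)
  invisible(path)
}

#' Parse a region field into a set of region codes
#'
#' A specimen may be recorded from several regions; codes are separated by
#' commas. Empty or missing fields become `"UNKNOWN"`.
#'
#' @param x Character vector of raw region fields.
#' @param extra_regions Additional codes to accept beyond [REGION_CODES].
#' @return A list of character vectors of validated codes.
#' @export
parse_regions <- function(x, extra_regions = character()) {
  vocab <- c(REGION_CODES, extra_regions, "UNKNOWN")
  lapply(x, function(field) {
    if (is.na(field) || !nzchar(trimws(field))) return("UNKNOWN")
    codes <- toupper(trimws(strsplit(field, ",", fixed = TRUE)[[1L]]))
    codes <- codes[nzchar(codes)]
    bad <- setdiff(codes, vocab)
    if (length(bad))
      stop("unknown region code(s): ", paste(bad, collapse = ", "),
           " (declare via extra_regions if intended)")
    unique(codes)
  })
}

#' Read a specimen metadata table
#'
#' Tab-delimited UTF-8 with a header; required columns `id`, `species`,
#' `locality`, `region`, `type_locality` (an optional `source` column is
#' kept if present). Missing regions become `UNKNOWN`; missing
#' `type_locality` becomes `FALSE`. When `aln` is supplied, metadata rows
#' whose id is absent from the alignment are dropped with a warning, and
#' alignment ids without metadata receive default rows (the join is total
#' over alignment ids).
#'
#' @param path Path to the TSV file.
#' @param aln Optional `dna_alignment` to join against.
#' @param extra_regions Additional region codes to accept.
#' @return A data.frame with columns `id`, `species`, `locality`, `region`
#'   (list column of code sets), `type_locality`, `source`.
#' @export
read_metadata <- function(path, aln = NULL, extra_regions = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = "character", na.strings = c("NA", ""))
  need <- c("id", "species", "locality", "region", "type_locality")
  miss <- setdiff(c("id", "species"), names(raw))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  for (col in setdiff(need, names(raw))) raw[[col]] <- NA_character_
  if (anyDuplicated(raw$id))
    stop("duplicate metadata id: '", raw$id[duplicated(raw$id)][1L], "'")
  meta <- data.frame(id = raw$id, species = raw$species,
                     locality = ifelse(is.na(raw$locality), "", raw$locality),
                     stringsAsFactors = FALSE)
  meta$region <- parse_regions(raw$region, extra_regions)
  tl <- raw$type_locality
  meta$type_locality <- !is.na(tl) & tl %in% c("1", "TRUE", "true", "T", "yes")
  meta$source <- if ("source" %in% names(raw))
    ifelse(is.na(raw$source), "novel", raw$source) else "novel"
  if (!is.null(aln)) {
    extra <- setdiff(meta$id, aln$ids)
    if (length(extra)) {
      warning("metadata id(s) absent from alignment, skipped: ",
              paste(extra, collapse = ", "))
      meta <- meta[!meta$id %in% extra, , drop = FALSE]
    }
    missing_ids <- setdiff(aln$ids, meta$id)
    if (length(missing_ids)) {
      fill <- data.frame(id = missing_ids, species = "unknown",
                         locality = "", stringsAsFactors = FALSE)
      fill$region <- rep(list("UNKNOWN"), length(missing_ids))
      fill$type_locality <- FALSE
      fill$source <- "novel"
      meta <- rbind(meta, fill)
    }
    meta <- meta[match(aln$ids, meta$id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  meta
}

#' Write a specimen metadata table
#'
#' @param meta Metadata data.frame as produced by [read_metadata()] or
#'   [simulate_barcodes()].
#' @param path Output TSV path.
#' @export
write_metadata <- function(meta, path) {
  out <- data.frame(id = meta$id, species = meta$species,
                    locality = meta$locality,
                    region = vapply(meta$region, paste, character(1L),
                                    collapse = ","),
                    type_locality = as.integer(meta$type_locality),
                    source = meta$source, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a guide tree from a newick file
#'
#' Polytomies are accepted and resolved arbitrarily into zero-length edges
#' (with a message), since the PTP delimiter requires a binary tree.
#' Negative branch lengths are rejected.
#'
#' @param path Path to a newick file.
#' @return A binary `phylo` tree.
#' @export
read_guide_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick in ", path)
  check_guide_tree(tr)
}

#' Validate (and binarize) a guide tree
#' @param tr A `phylo` object.
#' @return The validated, binary tree.
#' @export
check_guide_tree <- function(tr) {
  if (is.null(tr$tip.label) || anyNA(tr$tip.label) || any(tr$tip.label == ""))
    stop("tree has unlabeled leaves")
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop("tree has negative branch lengths")
  if (!ape::is.binary(tr)) {
    message("polytomy resolved arbitrarily with zero-length edges")
    tr <- ape::multi2di(tr, random = FALSE)
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  tr
}

#' Write a tree to newick
#' @param tr A `phylo` object.
#' @param path Output path.
#' @export
write_guide_tree <- function(tr, path) {
  ape::write.tree(tr, file = path, digits = 12)
  invisible(path)
}
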