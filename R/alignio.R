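#' Read a single-region alignment
#'
#' Reads a pre-aligned region from FASTA, NEXUS (DATA block) or relaxed
#' sequential PHYLIP into a one-region \code{\link{AlignmentSet}}. Input is
#' case-insensitive; \code{.} gaps are normalized to \code{-}; sequences are
#' validated against the alphabet \code{A,C,G,T,-,N}. Ragged alignments and
#' duplicated ids are rejected with the offending sample named.
#'
#' @param path file path.
#' @param format one of \code{"fasta"}, \code{"nexus"}, \code{"phylip"};
#'   guessed from the extension when missing.
#' @param region region name (defaults to the file base name).
#' @return an \code{AlignmentSet} with one region.
#' @export
readAlignment <- function(path, format = c("auto", "fasta", "nexus", "phylip"),
                          region = NULL) {
  stopifnot(file.exists(path))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      fa = , fas = , fasta = , fna = "fasta",
      nex = , nexus = , nxs = "nexus",
      phy = , phylip = "phylip",
      "fasta")
  }
  seqs <- switch(format,
    fasta = {
      x <- Biostrings::readBStringSet(path)
      stats::setNames(as.character(x), names(x))
    },
    nexus = {
      x <- ape::read.nexus.data(path)
      vapply(x, function(s) paste(s, collapse = ""), character(1L))
    },
    phylip = {
      x <- ape::read.dna(path, format = "sequential", as.character = TRUE)
      apply(x, 1L, paste, collapse = "")
    })
  if (is.null(region)) region <- tools::file_path_sans_ext(basename(path))
  .alignmentFromStrings(seqs, region)
}

.alignmentFromStrings <- function(seqs, region) {
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every sequence needs a sample id")
  ids <- sub("\\s.*$", "", trimws(ids))  # id = first token of the header
  if (anyDuplicated(ids))
    stop("duplicated sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  w <- nchar(seqs)
  if (length(unique(w)) > 1L) {
    off <- ids[w != w[1L]][1L]
    stop(sprintf("ragged alignment: sample '%s' has length %d, expected %d",
                 off, w[ids == off][1L], w[1L]))
  }
  m <- matrix(toupper(unlist(strsplit(unname(seqs), ""), use.names = FALSE)),
              nrow = length(seqs), byrow = TRUE, dimnames = list(ids, NULL))
  m[m == "."] <- "-"
  bad <- !(m %in% ALN_ALPHABET)
  dim(bad) <- dim(m)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("unknown symbol '%s' at sample '%s', column %d",
                 m[idx[1L], idx[2L]], ids[idx[1L]], idx[2L]))
  }
  new("AlignmentSet", regions = stats::setNames(list(m), region))
}

#' Build an AlignmentSet from in-memory sequences
#'
#' @param seqs named character vector of equal-length gapped sequences.
#' @param region region name.
#' @export
alignmentSet <- function(seqs, region = "region1") .alignmentFromStrings(seqs, region)

#' Write one region of an alignment
#'
#' @param aln an \code{AlignmentSet}.
#' @param path output path.
#' @param format \code{"fasta"}, \code{"nexus"} or \code{"phylip"}.
#' @param region region to write (default: the concatenation if several).
#' @export
writeAlignment <- function(aln, path, format = c("fasta", "nexus", "phylip"),
                           region = NULL) {
  format <- match.arg(format)
  m <- if (is.null(region)) as.matrix(aln) else aln@regions[[region]]
  seqs <- apply(m, 1L, paste, collapse = "")
  switch(format,
    fasta = {
      x <- Biostrings::BStringSet(seqs)
      Biostrings::writeXStringSet(x, path)
    },
    nexus = ape::write.nexus.data(strsplit(seqs, ""), path,
                                  interleaved = FALSE),
    phylip = {
      con <- file(path, "w")
      on.exit(close(con))
      writeLines(sprintf("%d %d", nrow(m), ncol(m)), con)
      writeLines(sprintf("%s  %s", rownames(m), seqs), con)
    })
  invisible(path)
}

#' Concatenate single- or multi-region alignment sets
#'
#' All inputs must carry identical sample sets; samples are reordered to the
#' first input's order. Region offsets into the concatenated matrix are
#' recoverable with \code{\link{regionOffsets}}; total length is the sum of
#' region lengths.
#'
#' @param ... \code{AlignmentSet} objects (or a single list of them).
#' @return a multi-region \code{AlignmentSet}.
#' @export
concatenateRegions <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1L]]) && !is(xs[[1L]], "AlignmentSet"))
    xs <- xs[[1L]]
  stopifnot(length(xs) >= 1L, all(vapply(xs, is, TRUE, "AlignmentSet")))
  ids <- sampleIDs(xs[[1L]])
  regs <- list()
  for (x in xs) {
    if (!setequal(sampleIDs(x), ids)) {
      d1 <- setdiff(ids, sampleIDs(x)); d2 <- setdiff(sampleIDs(x), ids)
      stop("sample sets differ: missing {",
           paste(d1, collapse = ","), "}, extra {",
           paste(d2, collapse = ","), "}")
    }
    for (rn in names(x@regions)) {
      if (rn %in% names(regs)) stop("duplicated region name '", rn, "'")
      regs[[rn]] <- x@regions[[rn]][ids, , drop = FALSE]
    }
  }
  new("AlignmentSet", regions = regs)
}

#' @describeIn readAlignment sample identifiers, in order.
#' @param x an \code{AlignmentSet}.
#' @export
sampleIDs <- function(x) rownames(x@regions[[1L]])

#' Aligned length of each region (columns)
#' @param x an \code{AlignmentSet}.
#' @export
regionLengths <- function(x) vapply(x@regions, ncol, integer(1L))

#' 1-based start offset of each region in the concatenated matrix
#' @param x an \code{AlignmentSet}.
#' @export
regionOffsets <- function(x) {
  len <- regionLengths(x)
  stats::setNames(cumsum(c(1L, len[-length(len)])), names(len))
}

#' Convert a region-local column to a concatenated column
#' @param x an \code{AlignmentSet}.
#' @param region region name.
#' @param column 1-based region-local column(s).
#' @export
toConcatenated <- function(x, region, column)
  unname(regionOffsets(x)[region]) + as.integer(column) - 1L

#' @export
setMethod("as.matrix", "AlignmentSet", function(x, ...) {
  do.call(cbind, unname(x@regions))
})

setMethod("show", "AlignmentSet", function(object) {
  len <- regionLengths(object)
  cat(sprintf("AlignmentSet: %d samples, %d region(s), %d columns total\n",
              length(sampleIDs(object)), length(len), sum(len)))
  for (rn in names(len)) cat(sprintf("  %s: %d bp\n", rn, len[rn]))
})

#' Read a sample-to-population map
#'
#' Three-column tab-separated text: sample, species, population (header
#' optional, detected from the literal first line
#' \code{sample\\tspecies\\tpopulation}). Populations must nest within
#' species.
#'
#' @param path TSV path.
#' @return data.frame with columns \code{sample}, \code{species},
#'   \code{population}.
#' @export
readSampleMap <- function(path) {
  first <- readLines(path, n = 1L)
  hasHeader <- identical(tolower(strsplit(first, "\t")[[1L]][1L]), "sample")
  df <- utils::read.table(path, sep = "\t", header = hasHeader,
                          stringsAsFactors = FALSE,
                          col.names = c("sample", "species", "population"))
  validateSampleMap(df)
}

#' Validate a sample map (optionally against an alignment)
#' @param map data.frame with sample/species/population columns.
#' @param aln optional \code{AlignmentSet}; every alignment sample must have
#'   exactly one map entry.
#' @export
validateSampleMap <- function(map, aln = NULL) {
  stopifnot(all(c("sample", "species", "population") %in% names(map)))
  if (anyDuplicated(map$sample))
    stop("duplicated sample(s) in map: ",
         paste(unique(map$sample[duplicated(map$sample)]), collapse = ", "))
  sp <- tapply(map$species, map$population, function(s) length(unique(s)))
  if (any(sp > 1L))
    stop("population(s) span several species: ",
         paste(names(sp)[sp > 1L], collapse = ", "))
  if (!is.null(aln)) {
    miss <- setdiff(sampleIDs(aln), map$sample)
    if (length(miss))
      stop("alignment sample(s) missing from map: ",
           paste(miss, collapse = ", "))
  }
  map
}
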