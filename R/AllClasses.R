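#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

ALN_ALPHABET <- c("A", "C", "G", "T", "-", "N")

#' Multi-region sequence alignment set
#'
#' An \code{AlignmentSet} holds one or more pre-aligned plastid regions as
#' character matrices (rows = samples, columns = 1-based alignment positions)
#' over the alphabet \code{A,C,G,T,-,N}. All regions carry the same samples in
#' the same order; per-region column offsets into the concatenated matrix are
#' derived, so region-local and concatenated coordinates are interconvertible.
#'
#' @slot regions named list of character matrices, one per region.
#' @export
setClass("AlignmentSet", representation(regions = "list"))

setValidity("AlignmentSet", function(object) {
  regs <- object@regions
  if (length(regs) == 0L) return("AlignmentSet needs at least one region")
  if (is.null(names(regs)) || anyDuplicated(names(regs)))
    return("regions must be uniquely named")
  ids <- rownames(regs[[1L]])
  for (rn in names(regs)) {
    m <- regs[[rn]]
    if (!is.matrix(m) || !is.character(m))
      return(sprintf("region '%s' is not a character matrix", rn))
    if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
      return(sprintf("region '%s' has missing or duplicated sample ids", rn))
    if (!identical(rownames(m), ids))
      return(sprintf("sample ids of region '%s' differ from region '%s'",
                     rn, names(regs)[1L]))
    bad <- !(m %in% ALN_ALPHABET)
    dim(bad) <- dim(m)
    if (any(bad)) {
      idx <- which(bad, arr.ind = TRUE)[1L, ]
      return(sprintf(
        "region '%s': unknown symbol '%s' (sample %s, column %d)",
        rn, m[idx[1L], idx[2L]], rownames(m)[idx[1L]], idx[2L]))
    }
  }
  TRUE
})

#' Catalog of typed mutational events
#'
#' Each event is a substitution (single column), an indel (one unique
#' \code{(start, end)} gap span = one unordered event) or a microsatellite
#' (motif repeat-count character over a declared column window). The
#' per-sample character states for every event are stored alongside, so
#' haplotype calling and event distances never re-scan the alignment.
#'
#' @slot events data.frame with columns \code{id, kind, region, start, end,
#'   cstart, cend, motif} (region-local and concatenated 1-based inclusive
#'   spans).
#' @slot states character matrix, samples x events; substitutions hold the
#'   base (or \code{"-"} when deleted, \code{"N"} when ambiguous), indels
#'   \code{"0"/"1"/"?"}, microsatellites the integer repeat count.
#' @slot alignLength integer, total concatenated columns.
#' @slot excludedColumns integer vector of concatenated columns excluded from
#'   per-site statistics (indel spans and microsatellite windows).
#' @export
setClass("VariantCatalog",
         representation(events = "data.frame", states = "matrix",
                        alignLength = "integer", excludedColumns = "integer"))

setValidity("VariantCatalog", function(object) {
  ev <- object@events
  need <- c("id", "kind", "region", "start", "end", "cstart", "cend", "motif")
  if (!all(need %in% names(ev))) return("events is missing required columns")
  if (nrow(ev)) {
    if (!all(ev$kind %in% c("substitution", "indel", "microsatellite")))
      return("unknown event kind")
    if (any(ev$cstart < 1L) || any(ev$cend > object@alignLength))
      return("event span outside alignment bounds")
    if (any(ev$kind == "substitution" & ev$cend != ev$cstart))
      return("substitution events must span exactly one column")
    key <- paste(ev$kind, ev$cstart, ev$cend)
    if (anyDuplicated(key))
      return("two events of the same kind share an identical span")
    if (!identical(colnames(object@states), ev$id))
      return("states columns must match event ids")
  }
  TRUE
})

#' Haplotype-by-population count table
#'
#' Extends \code{SummarizedExperiment}: rows are haplotypes (rowData carries
#' the event-state key and a representative sample), columns are populations
#' (colData carries \code{species} and the sample size \code{n}); the single
#' assay \code{counts} holds integer haplotype counts per population. The full
#' per-individual assignment, any ambiguous samples and the generating
#' \code{VariantCatalog} live in \code{metadata()}.
#'
#' @export
setClass("HaplotypeTable", contains = "SummarizedExperiment")

setValidity("HaplotypeTable", function(object) {
  a <- SummarizedExperiment::assays(object)
  if (!"counts" %in% names(a)) return("assay 'counts' is required")
  cnt <- a[["counts"]]
  if (any(cnt < 0) || any(cnt != round(cnt))) return("counts must be non-negative integers")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("species", "n") %in% names(cd)))
    return("colData needs 'species' and 'n'")
  if (!isTRUE(all(colSums(cnt) == cd$n)))
    return("column sums must equal population sample sizes n")
  TRUE
})

#' Statistical-parsimony haplotype network
#'
#' @slot graph igraph object; observed haplotype nodes carry per-species
#'   counts, inferred median nodes are flagged \code{type = "median"}; edges
#'   are labelled with the ordered mutational events separating endpoints.
#' @slot limit integer connection limit (steps) applied during construction.
#' @slot confidence numeric confidence level behind the limit.
#' @slot constraint character, \code{"substitutions"} (homoplasy-free
#'   substitutions, free indels/microsatellites) or \code{"none"}.
#' @export
setClass("HaploNetwork",
         representation(graph = "ANY", limit = "integer",
                        confidence = "numeric", constraint = "character"))

#' Parsimony character matrix
#'
#' Variable nucleotide columns (states A,C,G,T; gaps as missing) plus, under
#' simple indel coding, appended binary presence/absence characters. Carries
#' per-character minimum steps \code{m} (observed states - 1) and maximum
#' steps \code{g} (non-missing taxa - modal state frequency).
#'
#' @slot chars character matrix, taxa x characters ("?" = missing).
#' @slot info data.frame per character: \code{type} ("nuc"/"indel"),
#'   \code{column} (concatenated alignment column, NA for indel characters),
#'   \code{m}, \code{g}, \code{informative}.
#' @slot gapMode character, \code{"missing"} or \code{"sic"}.
#' @export
setClass("CharacterMatrix",
         representation(chars = "matrix", info = "data.frame",
                        gapMode = "character"))

setValidity("CharacterMatrix", function(object) {
  if (nrow(object@info) != ncol(object@chars))
    return("info must describe every character")
  if (any(object@info$m > object@info$g)) return("m must not exceed g")
  TRUE
})
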