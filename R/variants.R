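#' Declare a microsatellite window
#'
#' @param motif repeat motif, e.g. \code{"TA"}.
#' @param region region name the window lives in.
#' @param start,end 1-based region-local columns of the window (inclusive).
#' @param indelColumns optional region-local columns inside the window that
#'   are scored as separate single-base indel events (and dropped from repeat
#'   counting), for alignments where a window also carries point indels.
#' @export
microsatWindow <- function(motif, region, start, end, indelColumns = integer()) {
  stopifnot(nchar(motif) >= 1L, end >= start)
  list(motif = toupper(motif), region = region, start = as.integer(start),
       end = as.integer(end), indelColumns = as.integer(indelColumns))
}

.autoDetectMicrosat <- function(aln, minRepeats = 4L) {
  out <- list()
  for (rn in names(aln@regions)) {
    m <- aln@regions[[rn]]
    hits <- list()
    for (i in seq_len(nrow(m))) {
      s <- paste(m[i, ], collapse = "")
      mt <- gregexpr("([ACGT]{2})\\1{3,}", s, perl = TRUE)[[1L]]
      if (mt[1L] == -1L) next
      for (k in seq_along(mt)) {
        st <- mt[k]; len <- attr(mt, "match.length")[k]
        motif <- substr(s, st, st + 1L)
        hits[[length(hits) + 1L]] <- c(motif = motif, start = st,
                                       end = st + len - 1L)
      }
    }
    if (!length(hits)) next
    h <- do.call(rbind, hits)
    for (motif in unique(h[, "motif"])) {
      sel <- h[, "motif"] == motif
      reps <- (as.integer(h[sel, "end"]) - as.integer(h[sel, "start"]) + 1L) /
        nchar(motif)
      if (max(reps) < minRepeats) next
      out[[length(out) + 1L]] <- microsatWindow(
        motif, rn, min(as.integer(h[sel, "start"])),
        max(as.integer(h[sel, "end"])))
    }
  }
  out
}

.gapRuns <- function(rowChars) {
  r <- rle(rowChars == "-")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

.countRepeats <- function(chars, motif) {
  s <- paste(chars[chars != "-"], collapse = "")
  if (grepl("N", s, fixed = TRUE)) return(NA_integer_)
  mt <- gregexpr(sprintf("(%s)+", motif), s)[[1L]]
  if (mt[1L] == -1L) return(0L)
  max(attr(mt, "match.length")) %/% nchar(motif)
}

#' Scan an alignment into a catalog of mutational events
#'
#' Every polymorphic column is assigned to exactly one typed event:
#' substitutions at single columns; contiguous gap runs with identical start
#' and end across the samples bearing them form one indel event (runs with
#' distinct endpoints are distinct events; nested gaps score the contained
#' span as missing); columns inside a declared microsatellite window
#' contribute only to that window's repeat-count event, except columns
#' declared as in-window single-base indels, which stay separate indel
#' events.
#'
#' @param aln an \code{\link{AlignmentSet}} (regions are scanned on the
#'   concatenated coordinate system).
#' @param microsat list of \code{\link{microsatWindow}} declarations,
#'   \code{"auto"} to detect runs of a 2-mer motif with >= 4 repeats, or
#'   \code{NULL}.
#' @return a \code{\link{VariantCatalog}}.
#' @export
scanVariableSites <- function(aln, microsat = NULL) {
  stopifnot(is(aln, "AlignmentSet"))
  if (identical(microsat, "auto")) microsat <- .autoDetectMicrosat(aln)
  if (is.null(microsat)) microsat <- list()
  M <- as.matrix(aln)
  L <- ncol(M)
  n <- nrow(M)
  ids <- rownames(M)
  off <- regionOffsets(aln)
  lens <- regionLengths(aln)
  regionOf <- rep(names(lens), lens)

  # microsatellite windows in concatenated coordinates
  msat <- lapply(microsat, function(w) {
    w$cstart <- toConcatenated(aln, w$region, w$start)
    w$cend <- toConcatenated(aln, w$region, w$end)
    w$cindel <- if (length(w$indelColumns))
      toConcatenated(aln, w$region, w$indelColumns) else integer()
    w
  })
  inWindow <- rep(FALSE, L)
  for (w in msat) inWindow[w$cstart:w$cend] <- TRUE
  windowIndelCols <- unlist(lapply(msat, `[[`, "cindel"))
  inWindow[windowIndelCols] <- FALSE  # exception columns scanned normally

  # indel events: unique (start,end) gap spans outside windows
  runsBySample <- lapply(seq_len(n), function(i) {
    r <- .gapRuns(M[i, ])
    if (!nrow(r)) return(r)
    keep <- !vapply(seq_len(nrow(r)), function(k)
      all(inWindow[r[k, "start"]:r[k, "end"]]), logical(1L))
    r[keep, , drop = FALSE]
  })
  allRuns <- unique(do.call(rbind, c(runsBySample, list(matrix(0L, 0L, 2L,
    dimnames = list(NULL, c("start", "end")))))))
  if (nrow(allRuns) > 1L) {
    o <- order(allRuns[, 1L], allRuns[, 2L])
    allRuns <- allRuns[o, , drop = FALSE]
    for (a in seq_len(nrow(allRuns) - 1L)) for (b in (a + 1L):nrow(allRuns)) {
      sa <- allRuns[a, ]; sb <- allRuns[b, ]
      if (sb[1L] <= sa[2L] && sb[2L] > sa[2L] && sb[1L] > sa[1L])
        warning(sprintf(
          "partially overlapping indel spans %d-%d and %d-%d kept as distinct events",
          sa[1L], sa[2L], sb[1L], sb[2L]))
    }
  }

  events <- list(); states <- list()
  addEvent <- function(id, kind, cstart, cend, motif, st) {
    events[[length(events) + 1L]] <<- data.frame(
      id = id, kind = kind, region = regionOf[cstart],
      start = cstart - off[regionOf[cstart]] + 1L,
      end = cend - off[regionOf[cend]] + 1L,
      cstart = cstart, cend = cend, motif = motif,
      stringsAsFactors = FALSE)
    states[[id]] <<- st
  }

  if (nrow(allRuns)) for (k in seq_len(nrow(allRuns))) {
    s <- allRuns[k, "start"]; e <- allRuns[k, "end"]
    st <- vapply(seq_len(n), function(i) {
      r <- runsBySample[[i]]
      if (nrow(r) && any(r[, 1L] == s & r[, 2L] == e)) return("1")
      if (nrow(r) && any(r[, 1L] <= s & r[, 2L] >= e)) return("?")
      "0"
    }, character(1L))
    addEvent(sprintf("i%d_%d", s, e), "indel", s, e, NA_character_, st)
  }

  # substitution events: columns with >= 2 distinct bases, outside windows
  for (j in which(!inWindow)) {
    bases <- unique(M[, j])
    bases <- bases[bases %in% c("A", "C", "G", "T")]
    if (length(bases) >= 2L)
      addEvent(sprintf("s%d", j), "substitution", j, j, NA_character_, M[, j])
  }

  for (w in msat) {
    cols <- setdiff(w$cstart:w$cend, w$cindel)
    st <- vapply(seq_len(n), function(i) {
      cnt <- .countRepeats(M[i, cols], w$motif)
      if (is.na(cnt)) "N" else as.character(cnt)
    }, character(1L))
    addEvent(sprintf("m%d", w$cstart), "microsatellite", w$cstart, w$cend,
             w$motif, st)
  }

  if (length(events)) {
    ev <- do.call(rbind, events)
    # keep only variable events (>= 2 distinct resolvable states)
    variable <- vapply(ev$id, function(id) {
      st <- states[[id]]
      length(unique(st[!st %in% c("N", "?")])) >= 2L
    }, logical(1L))
    ev <- ev[variable, , drop = FALSE]
    states <- states[ev$id]
  }
  if (length(events) && nrow(ev)) {
    kindOrder <- match(ev$kind, c("substitution", "indel", "microsatellite"))
    o <- order(ev$cstart, kindOrder, ev$cend)
    ev <- ev[o, , drop = FALSE]
    rownames(ev) <- NULL
    stm <- do.call(cbind, states)[, ev$id, drop = FALSE]
    rownames(stm) <- ids
  } else {
    ev <- data.frame(id = character(), kind = character(), region = character(),
                     start = integer(), end = integer(), cstart = integer(),
                     cend = integer(), motif = character(),
                     stringsAsFactors = FALSE)
    stm <- matrix(character(), nrow = n, ncol = 0L, dimnames = list(ids, NULL))
  }
  excluded <- sort(unique(c(
    unlist(lapply(which(ev$kind != "substitution"), function(k)
      ev$cstart[k]:ev$cend[k])),
    unlist(lapply(msat, function(w) w$cstart:w$cend)))))
  new("VariantCatalog", events = ev, states = stm, alignLength = L,
      excludedColumns = as.integer(excluded))
}

#' Event alleles observed in a catalog
#' @param catalog a \code{VariantCatalog}.
#' @return list of character vectors of observed states per event.
#' @export
eventAlleles <- function(catalog) {
  lapply(stats::setNames(seq_len(nrow(catalog@events)), catalog@events$id),
         function(k) {
           st <- catalog@states[, k]
           sort(unique(st[!st %in% c("N", "?")]))
         })
}

setMethod("show", "VariantCatalog", function(object) {
  tb <- table(factor(object@events$kind,
                     c("substitution", "indel", "microsatellite")))
  cat(sprintf(
    "VariantCatalog: %d events (%d substitutions, %d indels, %d microsatellites) over %d columns\n",
    nrow(object@events), tb[1L], tb[2L], tb[3L], object@alignLength))
})

#' Collapse individuals into haplotypes
#'
#' Two individuals share a haplotype iff their event-state vectors are
#' identical. Haplotypes are numbered \code{H01, H02, ...} by first
#' occurrence in sample order. Samples with an unresolvable state (an
#' \code{N} at an event column or inside a microsatellite window) are
#' assigned \code{"ambiguous"}, excluded from counts, and reported via a
#' message.
#'
#' @param catalog a \code{\link{VariantCatalog}}.
#' @param map sample map data.frame (see \code{\link{readSampleMap}}).
#' @return a \code{\link{HaplotypeTable}}.
#' @export
callHaplotypes <- function(catalog, map) {
  st <- catalog@states
  map <- validateSampleMap(map)
  ids <- rownames(st)
  miss <- setdiff(ids, map$sample)
  if (length(miss)) stop("samples missing from map: ",
                         paste(miss, collapse = ", "))
  map <- map[match(ids, map$sample), , drop = FALSE]
  ambiguous <- if (ncol(st)) rowSums(st == "N") > 0L else rep(FALSE, nrow(st))
  if (any(ambiguous))
    message("excluding ", sum(ambiguous), " ambiguous sample(s): ",
            paste(ids[ambiguous], collapse = ", "))
  keep <- !ambiguous
  key <- if (ncol(st)) apply(st[keep, , drop = FALSE], 1L, paste,
                             collapse = "|") else rep("", sum(keep))
  uk <- unique(key)
  hap <- sprintf("H%02d", match(key, uk))
  pops <- unique(map$population)
  counts <- table(factor(hap, levels = sprintf("H%02d", seq_along(uk))),
                  factor(map$population[keep], levels = pops))
  counts <- matrix(as.integer(counts), nrow = length(uk),
                   dimnames = dimnames(counts))
  species <- map$species[match(pops, map$population)]
  rep1 <- ids[keep][match(sprintf("H%02d", seq_along(uk)), hap)]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(stateKey = uk, representative = rep1,
                                   row.names = rownames(counts)),
    colData = S4Vectors::DataFrame(species = species,
                                   n = as.integer(colSums(counts)),
                                   row.names = pops))
  S4Vectors::metadata(se) <- list(
    assignments = data.frame(sample = ids[keep], haplotype = hap,
                             species = map$species[keep],
                             population = map$population[keep],
                             stringsAsFactors = FALSE),
    ambiguous = ids[ambiguous],
    catalog = catalog)
  new("HaplotypeTable", se)
}

#' Haplotype counts matrix (haplotypes x populations)
#' @param ht a \code{HaplotypeTable}.
#' @export
haplotypeCounts <- function(ht) SummarizedExperiment::assay(ht, "counts")

#' Per-individual haplotype assignments
#' @param ht a \code{HaplotypeTable}.
#' @export
haplotypeAssignments <- function(ht) S4Vectors::metadata(ht)$assignments

#' Catalog stored with a haplotype table
#' @param ht a \code{HaplotypeTable}.
#' @export
haplotypeCatalog <- function(ht) S4Vectors::metadata(ht)$catalog

#' Haplotype counts aggregated by species
#' @param ht a \code{HaplotypeTable}.
#' @export
speciesCounts <- function(ht) {
  cnt <- haplotypeCounts(ht)
  sp <- SummarizedExperiment::colData(ht)$species
  t(rowsum(t(cnt), sp))
}

#' Summarize haplotype sharing between species
#'
#' @param ht a \code{HaplotypeTable}.
#' @return list with per-species detected totals and integer percentages of
#'   the overall haplotype count, the number shared by more than one species,
#'   per-species exclusives, and the per-haplotype per-population counts.
#' @export
summarizeSharing <- function(ht) {
  sc <- speciesCounts(ht)
  present <- sc > 0L
  total <- nrow(sc)
  detected <- colSums(present)
  shared <- sum(rowSums(present) >= 2L)
  exclusive <- vapply(colnames(present), function(s)
    sum(present[, s] & rowSums(present) == 1L), integer(1L))
  list(total = total, detected = detected,
       percent = round(100 * detected / total),
       shared = shared, exclusive = exclusive,
       counts = haplotypeCounts(ht))
}

#' Write haplotype representative sequences as FASTA
#'
#' One record per haplotype (its first-observed individual's concatenated
#' sequence), matching the one-sequence-per-haplotype deposition style.
#'
#' @param ht a \code{HaplotypeTable}.
#' @param aln the \code{AlignmentSet} the haplotypes were called from.
#' @param path output FASTA path.
#' @export
haplotypeFasta <- function(ht, aln, path) {
  reps <- SummarizedExperiment::rowData(ht)$representative
  M <- as.matrix(aln)[reps, , drop = FALSE]
  seqs <- apply(M, 1L, paste, collapse = "")
  names(seqs) <- rownames(ht)
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}
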