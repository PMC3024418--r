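#' Simulation configuration for the island/mainland design
#'
#' Defaults emulate the two-species sampling design the package targets: one
#' island species sampled as a single population (n = 54) and one mainland
#' species sampled as five populations of 20, two plastid regions of 858 and
#' 701 aligned columns, variation from point substitutions, 1-43 bp indels
#' and a TA dinucleotide microsatellite bounded between 6 and 15 repeats,
#' and an island deme with a several-fold larger effective size than the
#' mainland demes so that island diversity exceeds mainland diversity while
#' a recent species split leaves ancestral haplotypes shared across species.
#' Times and deme sizes are in coalescent units of one reference deme size;
#' event rates are per lineage per unit time.
#'
#' @param islandN island sample size.
#' @param mainlandN per-population mainland sample sizes.
#' @param regionLengths named region lengths (columns).
#' @param rateSub,rateIndel,rateMsat per-class mutation rates.
#' @param msatBounds repeat-count bounds (clamping).
#' @param msatStart ancestral repeat count.
#' @param msatWindowStart first column of the microsatellite window in
#'   region 1 (width = 2 * upper repeat bound).
#' @param indelMaxLen,indelLenP indel span length: 1 + geometric(p), capped.
#' @param islandSize,mainlandDemeSize,ancestralSize,mainlandAncSize deme
#'   sizes (reference units).
#' @param mainlandSplitTime,speciesSplitTime merger times (backwards).
#' @export
simConfig <- function(islandN = 54L, mainlandN = rep(20L, 5L),
                      regionLengths = c(trnS_trnG = 858L, trnL_trnF = 701L),
                      rateSub = 0.175, rateIndel = 0.06, rateMsat = 0.12,
                      msatBounds = c(6L, 15L), msatStart = 10L,
                      msatWindowStart = 381L,
                      indelMaxLen = 43L, indelLenP = 0.35,
                      islandSize = 6, mainlandDemeSize = 0.4,
                      ancestralSize = 2.5, mainlandAncSize = 0.4,
                      mainlandSplitTime = 0.15, speciesSplitTime = 0.8) {
  cfg <- list(islandN = as.integer(islandN),
              mainlandN = as.integer(mainlandN),
              regionLengths = regionLengths, rateSub = rateSub,
              rateIndel = rateIndel, rateMsat = rateMsat,
              msatBounds = as.integer(msatBounds),
              msatStart = as.integer(msatStart),
              msatWindowStart = as.integer(msatWindowStart),
              indelMaxLen = as.integer(indelMaxLen), indelLenP = indelLenP,
              islandSize = islandSize, mainlandDemeSize = mainlandDemeSize,
              ancestralSize = ancestralSize, mainlandAncSize = mainlandAncSize,
              mainlandSplitTime = mainlandSplitTime,
              speciesSplitTime = speciesSplitTime)
  stopifnot(all(unlist(cfg[c("rateSub", "rateIndel", "rateMsat")]) >= 0),
            cfg$islandN >= 1L, all(cfg$mainlandN >= 1L),
            cfg$msatBounds[1L] >= 1L, cfg$msatBounds[2L] <= 50L,
            cfg$msatBounds[1L] <= cfg$msatStart,
            cfg$msatStart <= cfg$msatBounds[2L])
  class(cfg) <- "SimConfig"
  cfg
}

#' Structured-coalescent genealogy
#'
#' Backward-in-time coalescent across demes with scheduled deme mergers and
#' no migration otherwise (plastid, non-recombining). Within a deme of size
#' \eqn{N} holding \eqn{k} lineages, pairs coalesce at rate
#' \eqn{k(k-1)/(2N)}.
#'
#' @param tipDemes character vector: deme of each tip (names = tip labels).
#' @param demeSizes named numeric deme sizes.
#' @param mergers list of \code{list(time=, from=, to=, size=)} events,
#'   sorted by time.
#' @return list: \code{tree} (ape phylo with branch lengths), \code{depth}.
#' @export
simulateGenealogy <- function(tipDemes, demeSizes, mergers = list()) {
  ids <- names(tipDemes)
  stopifnot(!is.null(ids), all(tipDemes %in% names(demeSizes)))
  nwk <- as.list(ids)
  birth <- rep(0, length(ids))
  deme <- unname(tipDemes)
  size <- demeSizes
  t <- 0
  mi <- 1L
  mergers <- mergers[order(vapply(mergers, `[[`, numeric(1L), "time"))]
  while (length(nwk) > 1L) {
    ks <- table(factor(deme, names(size)))
    rates <- as.numeric(ks * (ks - 1L)) / (2 * as.numeric(size))
    total <- sum(rates)
    tNext <- if (total > 0) t + stats::rexp(1L, total) else Inf
    if (mi <= length(mergers) && mergers[[mi]]$time <= tNext) {
      ev <- mergers[[mi]]
      deme[deme %in% ev$from] <- ev$to
      size <- size[!(names(size) %in% ev$from)]
      size[ev$to] <- ev$size
      t <- ev$time
      mi <- mi + 1L
      next
    }
    if (!is.finite(tNext)) stop("lineages cannot coalesce: disconnected demes")
    t <- tNext
    dsel <- sample.int(length(rates), 1L, prob = rates / total)
    inD <- which(deme == names(size)[dsel])
    pick <- sort(sample(inD, 2L))
    a <- pick[1L]; b <- pick[2L]
    nwk[[a]] <- sprintf("(%s:%.10f,%s:%.10f)", nwk[[a]], t - birth[a],
                        nwk[[b]], t - birth[b])
    birth[a] <- t
    nwk <- nwk[-b]; birth <- birth[-b]; deme <- deme[-b]
  }
  tree <- ape::read.tree(text = paste0(nwk[[1L]], ";"))
  list(tree = tree, depth = t)
}

# descendant tip indices per edge (rows of tree$edge)
.edgeDescendants <- function(tree) {
  nt <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- i
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  lapply(seq_len(nrow(tree$edge)), function(e) desc[[tree$edge[e, 2L]]])
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate a full island/mainland dataset with known truth
#'
#' Draws a structured-coalescent genealogy for the configured design, places
#' substitution events on unique free columns (infinite sites), indel events
#' as single non-overlapping spans (so downstream simple indel coding is
#' unambiguous), and microsatellite +/-1 repeat steps clamped to the bounds
#' but recorded as repeat counts, then emits gapped alignments per region, a
#' sample map and a truth record (genealogy, per-individual true haplotypes,
#' event list, realized h and pi per grouping).
#'
#' @param seed RNG seed (all randomness derives from it).
#' @param cfg a \code{\link{simConfig}}.
#' @return list: \code{aln} (\code{AlignmentSet}), \code{map} (data.frame),
#'   \code{microsat} (window declaration for
#'   \code{\link{scanVariableSites}}), \code{truth}, \code{seed}, \code{cfg}.
#' @export
simulateIslandMainland <- function(seed, cfg = simConfig()) {
  set.seed(seed)
  nM <- length(cfg$mainlandN)
  tipDemes <- c(rep("Island", cfg$islandN),
                rep(sprintf("M%d", seq_len(nM)), cfg$mainlandN))
  names(tipDemes) <- c(sprintf("I%03d", seq_len(cfg$islandN)),
                       unlist(lapply(seq_len(nM), function(d)
                         sprintf("M%d_%02d", d, seq_len(cfg$mainlandN[d])))))
  demeSizes <- c(Island = cfg$islandSize,
                 stats::setNames(rep(cfg$mainlandDemeSize, nM),
                                 sprintf("M%d", seq_len(nM))))
  mergers <- list(
    list(time = cfg$mainlandSplitTime, from = sprintf("M%d", seq_len(nM)),
         to = "ML", size = cfg$mainlandAncSize),
    list(time = cfg$speciesSplitTime, from = c("Island", "ML"),
         to = "ANC", size = cfg$ancestralSize))
  gen <- simulateGenealogy(tipDemes, demeSizes, mergers)
  tree <- gen$tree
  n <- length(tree$tip.label)
  edgeLen <- tree$edge.length
  B <- sum(edgeLen)
  desc <- .edgeDescendants(tree)

  lens <- cfg$regionLengths
  L <- sum(lens)
  off <- cumsum(c(1L, lens[-length(lens)]))
  wWidth <- 2L * cfg$msatBounds[2L]
  wStart <- cfg$msatWindowStart
  wCols <- wStart:(wStart + wWidth - 1L)   # region 1, also concatenated
  stopifnot(max(wCols) <= lens[1L])

  blocked <- rep(FALSE, L)
  blocked[wCols] <- TRUE

  events <- list()
  # indel events first (spans must not overlap each other or the window)
  nIndel <- stats::rpois(1L, cfg$rateIndel * B)
  for (k in seq_len(nIndel)) {
    for (try in seq_len(1000L)) {
      len <- min(1L + stats::rgeom(1L, cfg$indelLenP), cfg$indelMaxLen)
      reg <- sample.int(length(lens), 1L, prob = lens)
      if (len > lens[reg]) next
      s <- sample.int(lens[reg] - len + 1L, 1L) + off[reg] - 1L
      span <- s:(s + len - 1L)
      if (any(blocked[span])) next
      blocked[span] <- TRUE
      eIdx <- sample.int(length(edgeLen), 1L, prob = edgeLen)
      events[[length(events) + 1L]] <- list(kind = "indel", cstart = s,
                                            cend = s + len - 1L,
                                            carriers = desc[[eIdx]])
      break
    }
  }
  # substitutions on unique free columns
  nSub <- stats::rpois(1L, cfg$rateSub * B)
  free <- which(!blocked)
  if (nSub > length(free))
    stop("more substitution events than available columns; raise region ",
         "lengths or lower rateSub")
  subCols <- sort(sample(free, nSub))
  bases <- c("A", "C", "G", "T")
  for (k in seq_len(nSub)) {
    eIdx <- sample.int(length(edgeLen), 1L, prob = edgeLen)
    events[[length(events) + 1L]] <- list(kind = "substitution",
                                          cstart = subCols[k],
                                          cend = subCols[k],
                                          carriers = desc[[eIdx]])
  }
  # microsatellite stepwise moves, applied in time order along each path
  nStep <- stats::rpois(1L, cfg$rateMsat * B)
  repCounts <- rep(cfg$msatStart, n)
  if (nStep > 0L) {
    stepEdge <- sample.int(length(edgeLen), nStep, replace = TRUE,
                           prob = edgeLen)
    stepDir <- sample(c(-1L, 1L), nStep, replace = TRUE)
    stepPos <- stats::runif(nStep)
    nodeDepth <- ape::node.depth.edgelength(tree)  # root-to-node distance
    stepTime <- nodeDepth[tree$edge[stepEdge, 1L]] +
      stepPos * edgeLen[stepEdge]
    for (i in seq_len(n)) {
      onPath <- which(vapply(stepEdge, function(e) i %in% desc[[e]],
                             logical(1L)))
      if (!length(onPath)) next
      r <- cfg$msatStart
      for (sstep in onPath[order(stepTime[onPath])])
        r <- .clamp(r + stepDir[sstep], cfg$msatBounds[1L],
                    cfg$msatBounds[2L])
      repCounts[i] <- r
    }
  }

  # emit alignment
  root <- sample(bases, L, replace = TRUE)
  M <- matrix(rep(root, each = n), nrow = n,
              dimnames = list(tree$tip.label, NULL))
  for (ev in events) {
    if (ev$kind == "substitution") {
      alt <- sample(setdiff(bases, root[ev$cstart]), 1L)
      M[ev$carriers, ev$cstart] <- alt
    } else {
      M[ev$carriers, ev$cstart:ev$cend] <- "-"
    }
  }
  motifChars <- strsplit("TA", "")[[1L]]
  for (i in seq_len(n)) {
    rep_i <- repCounts[i]
    filled <- rep(motifChars, rep_i)
    M[i, wCols] <- c(filled, rep("-", wWidth - length(filled)))
  }

  regs <- lapply(seq_along(lens), function(r)
    M[, off[r]:(off[r] + lens[r] - 1L), drop = FALSE])
  names(regs) <- names(lens)
  ord <- names(tipDemes)            # restore sampling order (tree reorders)
  regs <- lapply(regs, function(m) m[ord, , drop = FALSE])
  aln <- new("AlignmentSet", regions = regs)

  map <- data.frame(sample = ord,
                    species = ifelse(startsWith(ord, "I"), "island_sp",
                                     "mainland_sp"),
                    population = unname(tipDemes[ord]),
                    stringsAsFactors = FALSE)

  truth <- .truthRecord(tree, events, repCounts, cfg, aln, map, wCols)
  list(aln = aln, map = map,
       microsat = list(microsatWindow("TA", names(lens)[1L], wStart,
                                      wStart + wWidth - 1L)),
       truth = truth, seed = seed, cfg = cfg)
}

# realized-truth bookkeeping, computed from the event lists and, for pi,
# directly from the emitted matrix by pair enumeration (independent of the
# estimator code path)
.truthRecord <- function(tree, events, repCounts, cfg, aln, map, wCols) {
  n <- length(tree$tip.label)
  stateM <- matrix("0", n, length(events))
  for (k in seq_along(events)) stateM[events[[k]]$carriers, k] <- "1"
  varying <- apply(stateM, 2L, function(s) length(unique(s)) > 1L)
  msVar <- length(unique(repCounts)) > 1L
  key <- paste(apply(stateM[, varying, drop = FALSE], 1L, paste,
                     collapse = ""), repCounts, sep = "|")
  names(key) <- tree$tip.label
  key <- key[map$sample]
  hapID <- sprintf("T%02d", match(key, unique(key)))
  groups <- list(island = map$sample[map$species == "island_sp"],
                 mainland = map$sample[map$species == "mainland_sp"])
  for (p in unique(map$population))
    groups[[p]] <- map$sample[map$population == p]
  hTrue <- vapply(groups, function(g)
    unname(haplotypeDiversity(table(hapID[match(g, map$sample)]))["h"]),
    numeric(1L))
  indelCols <- unlist(lapply(events, function(e)
    if (e$kind == "indel") e$cstart:e$cend else integer()))
  piTrue <- vapply(groups, function(g)
    .directPi(as.matrix(aln), g, c(wCols, indelCols)), numeric(1L))
  list(tree = ape::write.tree(tree),
       nEvents = sum(varying) + as.integer(msVar),
       events = data.frame(
         kind = vapply(events, `[[`, character(1L), "kind"),
         cstart = vapply(events, function(e) as.integer(e$cstart), integer(1L)),
         cend = vapply(events, function(e) as.integer(e$cend), integer(1L)),
         varying = varying),
       repCounts = stats::setNames(repCounts, tree$tip.label),
       haplotype = stats::setNames(hapID, map$sample),
       h = hTrue, pi = piTrue)
}

# straightforward all-pairs pi on ACGT-only columns (truth-side oracle)
.directPi <- function(M, samples, dropCols = integer()) {
  M <- M[samples, setdiff(seq_len(ncol(M)), dropCols), drop = FALSE]
  keep <- apply(M, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
  M <- M[, keep, drop = FALSE]
  n <- nrow(M)
  if (ncol(M) == 0L) return(0)
  tot <- 0
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n)
    tot <- tot + sum(M[a, ] != M[b, ])
  tot / choose(n, 2L) / ncol(M)
}

#' Write a simulated dataset to disk
#'
#' FASTA per region, the sample map as TSV, the genealogy as newick and the
#' truth record as JSON.
#'
#' @param sim result of \code{\link{simulateIslandMainland}}.
#' @param dir output directory (created).
#' @export
writeSimulatedDataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rn in names(sim$aln@regions))
    writeAlignment(sim$aln, file.path(dir, paste0(rn, ".fasta")), "fasta",
                   region = rn)
  utils::write.table(sim$map, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(sim$truth$tree, file.path(dir, "genealogy.nwk"))
  jsonlite::write_json(sim$truth[c("nEvents", "h", "pi", "haplotype")],
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
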