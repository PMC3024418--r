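#' Run the full haplotype analysis pipeline
#'
#' Orchestrates every stage on either file inputs (pre-aligned regions plus
#' a sample map) or a simulated dataset: variant scan, haplotype calling,
#' per-group diversity with rarefaction, the Snn permutation test, the
#' neutrality tests with the observed mismatch distribution, the
#' statistical-parsimony network and the parsimony analysis of the
#' haplotype matrix (gaps-as-missing and simple indel coding). Deterministic
#' given \code{seed}. When \code{outDir} is given, per-stage tables, network
#' files and a machine-readable JSON summary are written.
#'
#' @param alignments named character vector of alignment paths (one per
#'   region), or \code{NULL} when \code{sim} is given.
#' @param sampleMap path to the sample map TSV (ignored with \code{sim}).
#' @param sim optional result of \code{\link{simulateIslandMainland}}.
#' @param microsat microsatellite declarations (see
#'   \code{\link{scanVariableSites}}); taken from \code{sim} when present.
#' @param rarefyTo rarefaction subsample size (individuals).
#' @param permutations Snn Monte-Carlo permutation count.
#' @param confidence network connection-limit confidence.
#' @param seed seed for every randomized stage (recorded in the report).
#' @param outDir optional output directory.
#' @param searchStarts random-addition replicates for the parsimony search.
#' @return the report list (also serialized as JSON when \code{outDir} is
#'   set).
#' @export
runPipeline <- function(alignments = NULL, sampleMap = NULL, sim = NULL,
                        microsat = NULL, rarefyTo = 50L, permutations = 1000L,
                        confidence = 0.95, seed = 1L, outDir = NULL,
                        searchStarts = 5L) {
  stages <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  if (!is.null(sim)) {
    aln <- sim$aln; map <- sim$map
    if (is.null(microsat)) microsat <- sim$microsat
  } else {
    stopifnot(!is.null(alignments), !is.null(sampleMap))
    sets <- lapply(names(alignments), function(rn)
      readAlignment(alignments[[rn]], region = rn))
    aln <- stages("alignio", concatenateRegions(sets))
    map <- stages("alignio", readSampleMap(sampleMap))
  }
  validateSampleMap(map, aln)
  catalog <- stages("variants", scanVariableSites(aln, microsat))
  ht <- stages("variants", callHaplotypes(catalog, map))
  sharing <- summarizeSharing(ht)
  div <- stages("diversity", diversityReport(ht, aln))
  sc <- speciesCounts(ht)
  rare <- stages("diversity", {
    lapply(stats::setNames(colnames(sc), colnames(sc)), function(s) {
      N <- sum(sc[, s])
      rarefyRichness(sc[, s], min(rarefyTo, N))
    })
  })
  snn <- stages("popstructure", {
    idm <- individualDistanceMatrix(ht, grouping = "species")
    snnTest(idm$d, idm$localities, K = permutations, seed = seed)
  })
  asg <- haplotypeAssignments(ht)
  neut <- stages("neutrality", {
    lapply(stats::setNames(colnames(sc), colnames(sc)), function(s)
      neutralityTests(aln, catalog, asg$sample[asg$species == s],
                      reps = 1000L, seed = seed))
  })
  net <- stages("network", buildHaploNetwork(ht, confidence = confidence))
  pars <- stages("parsimony", {
    reps <- SummarizedExperiment::rowData(ht)$representative
    M <- as.matrix(aln)[reps, , drop = FALSE]
    rownames(M) <- rownames(ht)
    lapply(stats::setNames(c("missing", "sic"), c("missing", "sic")),
           function(gm) {
             cm <- characterMatrix(M, gapMode = gm)
             if (nrow(ht) >= 4L && ncol(cm@chars) > 0L)
               c(heuristicSearch(cm, nStarts = searchStarts, seed = seed),
                 list(nVariable = ncol(cm@chars),
                      nInformative = sum(cm@info$informative),
                      nIndelChars = sum(cm@info$type == "indel")))
             else list(tree = NULL, nVariable = ncol(cm@chars),
                       nInformative = sum(cm@info$informative),
                       nIndelChars = sum(cm@info$type == "indel"))
           })
  })
  report <- list(
    seed = seed,
    n = nrow(map),
    nHaplotypes = nrow(ht),
    sharing = sharing[c("total", "detected", "percent", "shared",
                        "exclusive")],
    diversity = div,
    rarefaction = rare,
    snn = snn,
    neutrality = lapply(neut, function(x)
      x[setdiff(names(x), c("summary", "mismatch"))]),
    network = list(limit = net@limit,
                   components = igraph::components(net@graph)$no,
                   edges = networkEdges(net)),
    parsimony = lapply(pars, function(p)
      p[intersect(names(p),
                  c("nVariable", "nInformative", "nIndelChars", "bound",
                    "boundAttained", "nBest"))]),
    parsimonyScores = lapply(pars, function(p)
      if (!is.null(p$score)) p$score[c("L", "CI", "CIexc", "RI")] else NULL))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(div, file.path(outDir, "diversity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(catalog@events, file.path(outDir, "variants.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cbind(haplotype = rownames(ht), haplotypeCounts(ht)),
                       file.path(outDir, "haplotypes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeNetwork(net, file.path(outDir, "network.graphml"), "graphml")
    writeNetwork(net, file.path(outDir, "network.tsv"), "tsv")
    for (s in names(neut))
      utils::write.table(neut[[s]]$mismatch,
                         file.path(outDir, sprintf("mismatch_%s.tsv", s)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(pars$missing$tree))
      ape::write.tree(pars$missing$tree, file.path(outDir, "tree_missing.nwk"))
    if (!is.null(pars$sic$tree))
      ape::write.tree(pars$sic$tree, file.path(outDir, "tree_sic.nwk"))
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

#' Structural check of a pipeline report
#'
#' Verifies the report against the shipped JSON schema's field list
#' (\code{inst/schema/report-schema.json}).
#'
#' @param report a \code{\link{runPipeline}} result (or a parsed JSON copy).
#' @return TRUE (invisibly) or an error naming missing fields.
#' @export
checkReport <- function(report) {
  schema <- jsonlite::read_json(system.file("schema", "report-schema.json",
                                            package = "HaploPop"))
  need <- names(schema$properties)
  miss <- setdiff(need, names(report))
  if (length(miss)) stop("report is missing fields: ",
                         paste(miss, collapse = ", "))
  invisible(TRUE)
}
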