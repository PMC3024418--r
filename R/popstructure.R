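.stateMatrix <- function(ht) {
  keys <- SummarizedExperiment::rowData(ht)$stateKey
  catalog <- haplotypeCatalog(ht)
  if (nrow(catalog@events) == 0L)
    return(matrix(character(), nrow = length(keys), ncol = 0L,
                  dimnames = list(rownames(ht), NULL)))
  m <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  dimnames(m) <- list(rownames(ht), catalog@events$id)
  m
}

#' Pairwise event distance between haplotypes
#'
#' Number of mutational events at which two haplotypes differ: substitutions
#' always (missing states from a deletion or \code{N} are skipped); indels
#' and microsatellites per configuration. A microsatellite difference counts
#' as one event regardless of the repeat-count gap unless
#' \code{microsatStepwise}.
#'
#' @param ht a \code{HaplotypeTable}.
#' @param includeIndels,includeMicrosat include those event classes.
#' @param microsatStepwise count \eqn{|\Delta repeats|} instead of 1.
#' @return symmetric numeric matrix over haplotypes.
#' @export
pairwiseEventDistance <- function(ht, includeIndels = TRUE,
                                  includeMicrosat = TRUE,
                                  microsatStepwise = FALSE) {
  st <- .stateMatrix(ht)
  ev <- haplotypeCatalog(ht)@events
  H <- nrow(st)
  d <- matrix(0, H, H, dimnames = list(rownames(st), rownames(st)))
  if (H < 2L || ncol(st) == 0L) return(d)
  for (k in seq_len(ncol(st))) {
    kind <- ev$kind[k]
    if (kind == "indel" && !includeIndels) next
    if (kind == "microsatellite" && !includeMicrosat) next
    s <- st[, k]
    contrib <- switch(kind,
      substitution = {
        ok <- s %in% c("A", "C", "G", "T")
        outer(ok, ok, "&") & outer(s, s, "!=")
      },
      indel = {
        ok <- s %in% c("0", "1")
        outer(ok, ok, "&") & outer(s, s, "!=")
      },
      microsatellite = {
        r <- suppressWarnings(as.numeric(s))
        ok <- !is.na(r)
        dd <- abs(outer(r, r, "-"))
        if (!microsatStepwise) dd <- (dd > 0) + 0
        dd[!outer(ok, ok, "&")] <- 0
        dd
      })
    d <- d + contrib
  }
  d
}

#' Distance matrix over individuals
#'
#' Expands the haplotype-level event distances to all assigned individuals.
#'
#' @inheritParams pairwiseEventDistance
#' @param samples optional subset of sample ids.
#' @return list with the matrix \code{d} and the matching \code{localities}
#'   taken from the grouping column.
#' @param grouping \code{"population"} or \code{"species"} localities.
#' @export
individualDistanceMatrix <- function(ht, grouping = c("population", "species"),
                                     samples = NULL, includeIndels = TRUE,
                                     includeMicrosat = TRUE,
                                     microsatStepwise = FALSE) {
  grouping <- match.arg(grouping)
  asg <- haplotypeAssignments(ht)
  if (!is.null(samples)) asg <- asg[asg$sample %in% samples, , drop = FALSE]
  hd <- pairwiseEventDistance(ht, includeIndels, includeMicrosat,
                              microsatStepwise)
  idx <- match(asg$haplotype, rownames(hd))
  d <- hd[idx, idx, drop = FALSE]
  dimnames(d) <- list(asg$sample, asg$sample)
  list(d = d, localities = asg[[grouping]])
}

#' Hudson's Snn nearest-neighbour statistic
#'
#' For each individual, the fraction of its nearest neighbours (all
#' individuals at minimal distance, self excluded) that belong to its own
#' locality; ties contribute fractionally. Snn is the mean over individuals.
#'
#' @param d symmetric distance matrix over individuals.
#' @param localities locality label per individual (>= 2 distinct).
#' @export
snnStatistic <- function(d, localities) {
  if (length(unique(localities)) < 2L)
    stop("Snn needs at least two localities")
  A <- .snnWeights(d)
  .snnFromWeights(A, as.integer(factor(localities)))
}

.snnWeights <- function(d) {
  n <- nrow(d)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d[i, ]; di[i] <- Inf
    nn <- which(di == min(di))
    A[i, nn] <- 1 / length(nn)
  }
  A
}

.snnFromWeights <- function(A, lab) {
  g <- max(lab)
  V <- matrix(0, ncol(A), g)
  V[cbind(seq_along(lab), lab)] <- 1
  P <- A %*% V
  mean(P[cbind(seq_along(lab), lab)])
}

.multisetPermutations <- function(counts) {
  # all distinct arrangements of labels 1..g with the given multiplicities
  g <- length(counts)
  n <- sum(counts)
  out <- list()
  rec <- function(prefix, left) {
    if (length(prefix) == n) { out[[length(out) + 1L]] <<- prefix; return() }
    for (l in seq_len(g)) if (left[l] > 0L) {
      left[l] <- left[l] - 1L
      rec(c(prefix, l), left)
      left[l] <- left[l] + 1L
    }
  }
  rec(integer(), counts)
  out
}

#' Permutation test of geographic subdivision with Snn
#'
#' The null is produced by reassigning locality labels at random while
#' preserving locality sizes. When the number of distinct label arrangements
#' is at most \code{exhaustiveLimit}, all arrangements are enumerated and
#' the p-value is the exact fraction with \eqn{Snn \ge} observed; otherwise
#' Monte-Carlo with \eqn{p = (1 + \#\{Snn_{perm} \ge Snn_{obs}\})/(K+1)}
#' (never exactly zero).
#'
#' @inheritParams snnStatistic
#' @param K Monte-Carlo permutation count.
#' @param seed RNG seed (recorded in the result).
#' @param exhaustiveLimit arrangement-count bound for exact enumeration.
#' @return list: \code{snn}, \code{p}, \code{K} (arrangements or draws),
#'   \code{method}, \code{seed}.
#' @export
snnTest <- function(d, localities, K = 1000L, seed = NULL,
                    exhaustiveLimit = 10000L) {
  stopifnot(K >= 1L)
  lab <- as.integer(factor(localities))
  if (max(lab) < 2L) stop("Snn needs at least two localities")
  A <- .snnWeights(d)
  obs <- .snnFromWeights(A, lab)
  counts <- tabulate(lab)
  nArr <- exp(lgamma(sum(counts) + 1) - sum(lgamma(counts + 1)))
  if (nArr <= exhaustiveLimit) {
    perms <- .multisetPermutations(counts)
    vals <- vapply(perms, function(p) .snnFromWeights(A, p), numeric(1L))
    return(list(snn = obs, p = mean(vals >= obs - 1e-12),
                K = length(perms), method = "exhaustive", seed = NA_integer_))
  }
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  set.seed(seed)
  ge <- 0L
  for (k in seq_len(K)) {
    v <- .snnFromWeights(A, sample(lab))
    if (v >= obs - 1e-12) ge <- ge + 1L
  }
  list(snn = obs, p = (1 + ge) / (K + 1), K = K,
       method = "monte-carlo", seed = seed)
}

#' Write a distance matrix
#' @param d matrix.
#' @param path output path.
#' @param format \code{"tsv"} (square, with header) or \code{"phylip"}.
#' @export
writeDistanceMatrix <- function(d, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(d, path, sep = "\t", quote = FALSE, col.names = NA)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(d)), con)
    writeLines(sprintf("%-10s %s", rownames(d),
                       apply(d, 1L, function(r) paste(format(r, digits = 6),
                                                      collapse = " "))), con)
  }
  invisible(path)
}
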