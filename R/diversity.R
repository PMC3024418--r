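#' Nei's unbiased haplotype (gene) diversity
#'
#' \eqn{h = n(1 - \sum p_i^2)/(n - 1)} with the sampling variance
#' \eqn{V(h) = \frac{2}{n(n-1)}\{2(n-2)[\sum p_i^3 - (\sum p_i^2)^2] +
#' \sum p_i^2 - (\sum p_i^2)^2\}}. Equivalent to the probability that two
#' individuals drawn without replacement carry different haplotypes.
#'
#' @param counts integer vector of per-haplotype counts (zeros allowed).
#' @return named numeric: \code{h}, \code{sd}, \code{n}, \code{S_obs}.
#' @export
haplotypeDiversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2L) stop("haplotype diversity is undefined for n < 2")
  p <- counts / n
  s2 <- sum(p^2); s3 <- sum(p^3)
  h <- n * (1 - s2) / (n - 1)
  v <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  c(h = h, sd = sqrt(max(v, 0)), n = n, S_obs = length(counts))
}

.maskedColumns <- function(aln, catalog = NULL, samples = NULL) {
  M <- as.matrix(aln)
  if (!is.null(samples)) M <- M[samples, , drop = FALSE]
  keep <- rep(TRUE, ncol(M))
  if (!is.null(catalog) && length(catalog@excludedColumns))
    keep[catalog@excludedColumns] <- FALSE
  ok <- apply(M, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
  M[, keep & ok, drop = FALSE]
}

# per-column pairwise-difference bookkeeping over a base-only matrix
.columnPairDiffs <- function(M) {
  n <- nrow(M)
  vapply(seq_len(ncol(M)), function(j) {
    cnt <- tabulate(factor(M[, j], c("A", "C", "G", "T")), 4L)
    (choose(n, 2L) - sum(choose(cnt, 2L)))
  }, numeric(1L))
}

#' Nucleotide diversity per site
#'
#' \eqn{\pi} = average number of pairwise differences per counted site over
#' all \eqn{C(n,2)} sequence pairs. Counted sites exclude indel spans and
#' microsatellite windows (when a catalog is given) and any column that is
#' not pure \code{A/C/G/T} in the selected samples (complete deletion, so a
#' column containing \code{N} or a gap is never counted). The reported SD is
#' the square root of the total (stochastic + sampling) variance of Nei
#' (1987, eq. 10.7): \eqn{V(\pi) = \frac{n+1}{3(n-1)}\frac{\pi}{L} +
#' \frac{2(n^2+n+3)}{9n(n-1)}\pi^2}.
#'
#' @param aln an \code{AlignmentSet}.
#' @param catalog optional \code{VariantCatalog} used to exclude indel and
#'   microsatellite columns.
#' @param samples optional sample ids restricting the computation.
#' @return named numeric: \code{pi}, \code{sd}, \code{n}, \code{L},
#'   \code{kbar} (mean pairwise differences, absolute).
#' @export
nucleotideDiversity <- function(aln, catalog = NULL, samples = NULL) {
  M <- .maskedColumns(aln, catalog, samples)
  n <- nrow(M)
  if (n < 2L) stop("nucleotide diversity needs at least 2 sequences")
  L <- ncol(M)
  if (L == 0L) stop("no countable sites after masking")
  kbar <- sum(.columnPairDiffs(M)) / choose(n, 2L)
  pi <- kbar / L
  v <- (n + 1) / (3 * (n - 1)) * pi / L +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  c(pi = pi, sd = sqrt(v), n = n, L = L, kbar = kbar)
}

#' Individual-based rarefaction of haplotype richness
#'
#' Hurlbert's expectation \eqn{E[S(n')] = \sum_i [1 - C(N-N_i,n')/C(N,n')]}
#' with the Heck et al. variance, via \code{vegan::rarefy}; normal-
#' approximation confidence intervals at the requested levels.
#'
#' @param counts per-haplotype counts.
#' @param nprime subsample size(s), each between 1 and \code{sum(counts)}.
#' @param conf confidence level(s).
#' @return data.frame with \code{nprime}, \code{expected}, \code{se} and a
#'   lower/upper column pair per confidence level.
#' @export
rarefyRichness <- function(counts, nprime, conf = c(0.95, 0.99)) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (any(nprime < 1L) || any(nprime > N))
    stop("nprime must lie in [1, ", N, "]")
  out <- data.frame(nprime = as.integer(nprime))
  r <- vapply(nprime, function(k) {
    # vegan warns about singleton-heavy counts; expected for haplotype data
    e <- suppressWarnings(vegan::rarefy(matrix(counts, nrow = 1L),
                                        sample = k, se = TRUE))
    c(e[1L], e[2L])
  }, numeric(2L))
  out$expected <- r[1L, ]
  out$se <- r[2L, ]
  for (cl in conf) {
    z <- stats::qnorm(1 - (1 - cl) / 2)
    out[[sprintf("lower%g", 100 * cl)]] <- out$expected - z * out$se
    out[[sprintf("upper%g", 100 * cl)]] <- out$expected + z * out$se
  }
  out
}

#' One-sample t comparison of per-population statistics to a reference
#'
#' @param values per-population statistic values (k >= 2, nonzero spread).
#' @param reference the single reference value.
#' @return named numeric: \code{t}, \code{df}, \code{p} (two-tailed),
#'   \code{mean}.
#' @export
compareDiversityT <- function(values, reference) {
  if (length(values) < 2L) stop("need at least two values")
  if (stats::sd(values) == 0) stop("zero variance: t is undefined")
  tt <- stats::t.test(values, mu = reference)
  c(t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, mean = mean(values))
}

#' Expected waiting time for a single substitution
#'
#' Given a per-site yearly substitution-rate interval and the number of
#' counted (noncoding) sites, the expected time to one substitution is
#' \eqn{1/(\mu L)} years; the fast rate gives the short waiting time.
#'
#' @param rateLow,rateHigh substitutions/site/year, \code{rateLow <= rateHigh}.
#' @param L number of counted sites.
#' @return list with full-precision \code{yearsFast}, \code{yearsSlow} and
#'   2-significant-figure \code{rounded}.
#' @export
substitutionWaitingTime <- function(rateLow, rateHigh, L) {
  stopifnot(rateLow > 0, rateHigh >= rateLow, L > 0)
  fast <- 1 / (rateHigh * L)
  slow <- 1 / (rateLow * L)
  list(yearsFast = fast, yearsSlow = slow,
       rounded = c(yearsFast = signif(fast, 2L), yearsSlow = signif(slow, 2L)))
}

#' Per-group diversity report
#'
#' Computes h (with SD), pi (with SD) and observed haplotype richness for
#' each population and each species of a haplotype table, plus the
#' species-level pooled and mean-of-population summaries (both reported,
#' explicitly labelled, since they differ in general).
#'
#' @param ht a \code{HaplotypeTable}.
#' @param aln the \code{AlignmentSet} the table was called from.
#' @return data.frame keyed by \code{level} ("population", "species_pooled")
#'   and \code{group}.
#' @export
diversityReport <- function(ht, aln) {
  catalog <- haplotypeCatalog(ht)
  asg <- haplotypeAssignments(ht)
  cnt <- haplotypeCounts(ht)
  rows <- list()
  addRow <- function(level, group, counts, samples) {
    hv <- haplotypeDiversity(counts)
    pv <- nucleotideDiversity(aln, catalog, samples)
    rows[[length(rows) + 1L]] <<- data.frame(
      level = level, group = group, n = unname(hv["n"]),
      S_obs = unname(hv["S_obs"]), h = unname(hv["h"]),
      h_sd = unname(hv["sd"]), pi = unname(pv["pi"]), pi_sd = unname(pv["sd"]),
      stringsAsFactors = FALSE)
  }
  for (p in colnames(cnt))
    addRow("population", p, cnt[, p], asg$sample[asg$population == p])
  sc <- speciesCounts(ht)
  for (s in colnames(sc))
    addRow("species_pooled", s, sc[, s], asg$sample[asg$species == s])
  do.call(rbind, rows)
}
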