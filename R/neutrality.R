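#' Segregating-site summary
#'
#' Counts over the masked (substitution-only, complete-deletion) columns of
#' an alignment: segregating sites \code{S}, total mutations \code{eta}
#' (alleles - 1 per column), singleton mutations \code{eta_s} (variant state
#' carried by exactly one sequence), mean pairwise differences \code{kbar}
#' (absolute, not per site) and the harmonic sums \code{a1}, \code{a2}.
#'
#' @inheritParams nucleotideDiversity
#' @return list of the quantities above plus \code{n} and \code{L}.
#' @export
siteSummary <- function(aln, catalog = NULL, samples = NULL) {
  M <- .maskedColumns(aln, catalog, samples)
  n <- nrow(M)
  stopifnot(n >= 2L)
  S <- 0L; eta <- 0L; etaS <- 0L
  for (j in seq_len(ncol(M))) {
    cnt <- sort(tabulate(factor(M[, j], c("A", "C", "G", "T")), 4L),
                decreasing = TRUE)
    cnt <- cnt[cnt > 0L]
    if (length(cnt) < 2L) next
    S <- S + 1L
    eta <- eta + length(cnt) - 1L
    etaS <- etaS + sum(cnt[-1L] == 1L)
  }
  kbar <- if (ncol(M)) sum(.columnPairDiffs(M)) / choose(n, 2L) else 0
  i <- seq_len(n - 1L)
  list(n = n, L = ncol(M), S = S, eta = eta, eta_s = etaS, kbar = kbar,
       a1 = sum(1 / i), a2 = sum(1 / i^2))
}

#' Tajima's D
#'
#' \eqn{D = (\bar k - S/a_1)/\sqrt{e_1 S + e_2 S(S-1)}} with Tajima's (1989)
#' constants. Undefined (flagged) when \eqn{S = 0}.
#'
#' @param n sequences.
#' @param S segregating sites.
#' @param kbar mean pairwise differences (absolute).
#' @return list: \code{D}, \code{evaluable}.
#' @export
tajimasD <- function(n, S, kbar) {
  if (S < 1L || n < 4L) return(list(D = NA_real_, evaluable = FALSE))
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- (kbar - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  list(D = D, evaluable = TRUE)
}

#' Approximate p-value for Tajima's D (beta approximation)
#'
#' Tajima's smooth approximation: D rescaled to its theoretical range
#' \eqn{[D_{min}, D_{max}]} is treated as Beta with mean 0 and variance 1 on
#' that range; two-sided p.
#'
#' @param D the statistic.
#' @param n sequences.
#' @export
tajimaPvalue <- function(D, n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e2 <- c2 / (a1^2 + a2)
  dmin <- (2 / n - 1 / a1) / sqrt(e2)
  dmax <- (n / (2 * (n - 1)) - 1 / a1) / sqrt(e2)
  m <- (0 - dmin) / (dmax - dmin)
  v <- 1 / (dmax - dmin)^2
  k <- m * (1 - m) / v - 1
  al <- m * k; be <- (1 - m) * k
  x <- (D - dmin) / (dmax - dmin)
  x <- min(max(x, 1e-12), 1 - 1e-12)
  2 * min(stats::pbeta(x, al, be), 1 - stats::pbeta(x, al, be))
}

#' Fu and Li's D* and F* (no outgroup)
#'
#' Contrasts the singleton count with the total mutation count (D*) and the
#' mean pairwise difference (F*), with the corrected published variance
#' coefficients. Undefined (flagged) when \eqn{S = 0}.
#'
#' @param n sequences.
#' @param eta total mutations.
#' @param eta_s singleton mutations.
#' @param kbar mean pairwise differences.
#' @return list: \code{Dstar}, \code{Fstar}, \code{evaluable}.
#' @export
fuLiDstarFstar <- function(n, eta, eta_s, kbar) {
  if (eta < 1L || n < 4L)
    return(list(Dstar = NA_real_, Fstar = NA_real_, evaluable = FALSE))
  i <- seq_len(n - 1L)
  an <- sum(1 / i); bn <- sum(1 / i^2)
  an1 <- an + 1 / n
  cn <- 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (3 / 2 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * bn + an^2 * dn -
           2 * (n * an * (an + 1)) / (n - 1)^2) / (an^2 + bn)
  uD <- (n / (n - 1)) * (an - n / (n - 1)) - vD
  Dstar <- ((n / (n - 1)) * eta - an * eta_s) /
    sqrt(uD * eta + vD * eta^2)
  vF <- (dn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) -
           (2 / (n - 1)) * (4 * bn - 6 + 8 / n)) / (an^2 + bn)
  uF <- (n / (n - 1) + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
           2 * ((n + 1) / (n - 1)^2) * (an1 - 2 * n / (n + 1))) / an - vF
  Fstar <- (kbar - ((n - 1) / n) * eta_s) / sqrt(uF * eta + vF * eta^2)
  list(Dstar = Dstar, Fstar = Fstar, evaluable = TRUE)
}

# Kingman coalescent branch table: one row per non-root branch with the
# number of descendant leaves and the branch length (coalescent units).
.simCoalBranches <- function(n) {
  size <- rep(1L, n)
  len <- rep(0, n)
  outSize <- integer(2L * (n - 1L)); outLen <- numeric(2L * (n - 1L))
  pos <- 0L
  k <- n
  while (k > 1L) {
    t <- stats::rexp(1L, k * (k - 1L) / 2)
    len <- len + t
    pick <- sample.int(k, 2L)
    for (p in pick) {
      pos <- pos + 1L
      outSize[pos] <- size[p]; outLen[pos] <- len[p]
    }
    size[pick[1L]] <- size[pick[1L]] + size[pick[2L]]
    len[pick[1L]] <- 0
    size <- size[-pick[2L]]; len <- len[-pick[2L]]
    k <- k - 1L
  }
  list(size = outSize, len = outLen)
}

#' Simulate neutral-coalescent site summaries (sequence-free)
#'
#' Standard Kingman coalescent for a panmictic sample; mutations placed on
#' branches proportionally to length under the infinite-sites model, either
#' a Poisson number at rate \eqn{\theta/2} per unit branch length
#' (\code{theta}) or exactly \code{S} (fixed-S null, used for critical
#' values). Only the summaries needed by the neutrality statistics are
#' returned.
#'
#' @param n sample size.
#' @param theta scaled mutation rate (mutually exclusive with \code{S}).
#' @param S fixed mutation count.
#' @param reps replicates.
#' @param seed RNG seed.
#' @return data.frame with \code{S}, \code{eta}, \code{eta_s}, \code{kbar}.
#' @export
simulateNeutralSummaries <- function(n, theta = NULL, S = NULL, reps = 1000L,
                                     seed = NULL) {
  stopifnot(xor(is.null(theta), is.null(S)))
  if (!is.null(seed)) set.seed(seed)
  out <- matrix(0, reps, 4L,
                dimnames = list(NULL, c("S", "eta", "eta_s", "kbar")))
  denom <- n * (n - 1L)
  for (r in seq_len(reps)) {
    br <- .simCoalBranches(n)
    M <- if (!is.null(theta)) stats::rpois(1L, theta / 2 * sum(br$len)) else S
    if (M > 0L) {
      idx <- sample.int(length(br$len), M, replace = TRUE, prob = br$len)
      sz <- br$size[idx]
      out[r, ] <- c(M, M, sum(sz == 1L | sz == n - 1L),
                    sum(2 * sz * (n - sz)) / denom)
    }
  }
  as.data.frame(out)
}

#' Simulation-based two-sided p-value for a neutrality statistic
#'
#' Fixed-S coalescent null at the observed number of mutations; empirical
#' two-sided p with the +1 correction.
#'
#' @param observed observed statistic value.
#' @param statistic \code{"D"}, \code{"Dstar"} or \code{"Fstar"}.
#' @param n sample size.
#' @param S observed mutation count conditioned on.
#' @param reps null replicates.
#' @param seed RNG seed.
#' @export
neutralityPvalue <- function(observed, statistic = c("D", "Dstar", "Fstar"),
                             n, S, reps = 1000L, seed = NULL) {
  statistic <- match.arg(statistic)
  sim <- simulateNeutralSummaries(n, S = S, reps = reps, seed = seed)
  null <- vapply(seq_len(reps), function(r) {
    switch(statistic,
      D = tajimasD(n, sim$S[r], sim$kbar[r])$D,
      Dstar = fuLiDstarFstar(n, sim$eta[r], sim$eta_s[r], sim$kbar[r])$Dstar,
      Fstar = fuLiDstarFstar(n, sim$eta[r], sim$eta_s[r], sim$kbar[r])$Fstar)
  }, numeric(1L))
  null <- null[is.finite(null)]
  lo <- (1 + sum(null <= observed)) / (length(null) + 1)
  hi <- (1 + sum(null >= observed)) / (length(null) + 1)
  min(1, 2 * min(lo, hi))
}

#' Observed mismatch distribution
#'
#' Histogram of pairwise difference counts over all \eqn{C(n,2)} pairs of
#' the selected sequences (masked substitution columns).
#'
#' @inheritParams nucleotideDiversity
#' @return data.frame with \code{differences} and \code{pairs};
#'   \code{sum(pairs) == choose(n, 2)}.
#' @export
mismatchDistribution <- function(aln, catalog = NULL, samples = NULL) {
  M <- .maskedColumns(aln, catalog, samples)
  n <- nrow(M)
  stopifnot(n >= 2L)
  key <- apply(M, 1L, paste, collapse = "")
  uk <- unique(key)
  U <- M[match(uk, key), , drop = FALSE]
  cnt <- as.integer(table(factor(key, uk)))
  u <- length(uk)
  dU <- matrix(0L, u, u)
  if (u > 1L) for (j in seq_len(ncol(U)))
    dU <- dU + outer(U[, j], U[, j], "!=")
  maxd <- max(dU)
  pairs <- integer(maxd + 1L)
  for (a in seq_len(u)) {
    pairs[1L] <- pairs[1L] + choose(cnt[a], 2L)
    if (a < u) for (b in (a + 1L):u)
      pairs[dU[a, b] + 1L] <- pairs[dU[a, b] + 1L] + cnt[a] * cnt[b]
  }
  data.frame(differences = 0:maxd, pairs = as.integer(round(pairs)))
}

#' Full neutrality-test report for a sample group
#'
#' @inheritParams nucleotideDiversity
#' @param pvalues compute p-values (beta approximation for D,
#'   fixed-S simulation for D*/F*).
#' @param reps,seed simulation settings for the D*/F* p-values.
#' @export
neutralityTests <- function(aln, catalog = NULL, samples = NULL,
                            pvalues = TRUE, reps = 1000L, seed = NULL) {
  ss <- siteSummary(aln, catalog, samples)
  td <- tajimasD(ss$n, ss$S, ss$kbar)
  fl <- fuLiDstarFstar(ss$n, ss$eta, ss$eta_s, ss$kbar)
  res <- list(summary = ss, D = td$D, Dstar = fl$Dstar, Fstar = fl$Fstar,
              evaluable = td$evaluable && fl$evaluable,
              mismatch = mismatchDistribution(aln, catalog, samples))
  if (pvalues && res$evaluable) {
    res$p_D <- tajimaPvalue(td$D, ss$n)
    res$p_Dstar <- neutralityPvalue(fl$Dstar, "Dstar", ss$n, ss$eta,
                                    reps, seed)
    res$p_Fstar <- neutralityPvalue(fl$Fstar, "Fstar", ss$n, ss$eta,
                                    reps, if (is.null(seed)) NULL else seed + 1L)
  }
  res
}
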