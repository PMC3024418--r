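# Independent oracles and small fixture builders used across the suite.
# These deliberately use naive enumeration, never the package's code paths.

aln2 <- function(...) alignmentSet(c(...), region = "r1")

# probability two draws without replacement differ (pair enumeration)
oracleH <- function(counts) {
  pool <- rep(seq_along(counts), counts)
  pairs <- utils::combn(length(pool), 2L)
  mean(pool[pairs[1L, ]] != pool[pairs[2L, ]])
}

# all integer partitions of n (as count vectors)
allPartitions <- function(n, max = n) {
  if (n == 0L) return(list(integer()))
  out <- list()
  for (k in seq_len(min(n, max)))
    for (rest in allPartitions(n - k, k))
      out[[length(out) + 1L]] <- c(k, rest)
  out
}

# mean pairwise differences per site over explicit sequence strings
oraclePi <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  keep <- apply(m, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- m[, keep, drop = FALSE]
  pairs <- utils::combn(nrow(m), 2L)
  d <- vapply(seq_len(ncol(pairs)), function(k)
    sum(m[pairs[1L, k], ] != m[pairs[2L, k], ]), numeric(1L))
  mean(d) / ncol(m)
}

# exhaustive expected richness of subsamples of size k
oracleRarefy <- function(counts, k) {
  pool <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(pool), k)
  mean(apply(subs, 2L, function(ix) length(unique(pool[ix]))))
}

# exhaustive Fitch: minimize changes over all internal-state assignments
oracleFitch <- function(tree, cm) {
  chars <- cm@chars
  total <- 0L
  nTip <- length(tree$tip.label)
  nInt <- tree$Nnode
  for (j in seq_len(ncol(chars))) {
    col <- chars[tree$tip.label, j]
    states <- unique(col[col != "?"])
    if (length(states) < 2L) next
    grids <- do.call(expand.grid,
                     c(rep(list(states), nInt), stringsAsFactors = FALSE))
    best <- Inf
    for (g in seq_len(nrow(grids))) {
      assign <- c(col, unlist(grids[g, ]))
      cost <- 0L
      for (e in seq_len(nrow(tree$edge))) {
        a <- assign[tree$edge[e, 1L]]; b <- assign[tree$edge[e, 2L]]
        if (a != "?" && b != "?" && a != b) cost <- cost + 1L
      }
      best <- min(best, cost)
    }
    total <- total + best
  }
  total
}

# second, independent transcription of the parsimony-probability model:
# transition-matrix power for the visible-difference chain + direct posterior
oracleParsProb <- function(j, m, maxExtra = 30L) {
  hmax <- j + maxExtra
  sz <- hmax + 2L
  P <- matrix(0, sz, sz)
  for (k in 0:hmax) {
    P[k + 1L, k + 2L] <- (m - k) / m
    P[k + 1L, k + 1L] <- (k / m) * (2 / 3)
    if (k > 0L) P[k + 1L, k] <- (k / m) * (1 / 3)
  }
  v <- numeric(sz); v[1L] <- 1
  lik <- numeric(hmax + 1L)
  lik[1L] <- as.numeric(j == 0L)
  for (h in seq_len(hmax)) {
    v <- as.numeric(v %*% P)
    lik[h + 1L] <- v[j + 1L]
  }
  theta <- j
  prior <- (1 / (1 + theta)) * (theta / (1 + theta))^(0:hmax)
  post <- prior * lik
  post[j + 1L] / sum(post[(j + 1L):(hmax + 1L)])
}

# one-deme coalescent dataset: pairwise event-count distances (for Snn nulls)
simFlatDistances <- function(n, theta) {
  demes <- stats::setNames(rep("D", n), sprintf("t%02d", seq_len(n)))
  g <- simulateGenealogy(demes, c(D = 1))
  tree <- g$tree
  desc <- HaploPop:::.edgeDescendants(tree)
  B <- sum(tree$edge.length)
  M <- stats::rpois(1L, theta / 2 * B)
  d <- matrix(0L, n, n)
  if (M > 0L) {
    eIdx <- sample.int(length(desc), M, replace = TRUE,
                       prob = tree$edge.length)
    for (e in eIdx) {
      x <- rep(0L, n); x[desc[[e]]] <- 1L
      d <- d + outer(x, x, "!=")
    }
  }
  ord <- match(sprintf("t%02d", seq_len(n)), tree$tip.label)
  d[ord, ord]
}

# tiny haplotype table straight from sequences (one population per group)
htFromSeqs <- function(seqs, populations, species = populations,
                       microsat = NULL) {
  aln <- alignmentSet(seqs, region = "r1")
  catalog <- scanVariableSites(aln, microsat)
  map <- data.frame(sample = names(seqs), species = species,
                    population = populations, stringsAsFactors = FALSE)
  list(aln = aln, catalog = catalog, ht = callHaplotypes(catalog, map))
}
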