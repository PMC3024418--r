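#' Probability that j observed differences are parsimonious
#'
#' Probability that two sequences of \code{m} sites observed to differ at
#' \code{j} sites are separated by exactly \code{j} mutations (no
#' superimposed, parallel or back mutation). The mutation count is given a
#' geometric prior from the pairwise coalescent (mean equal to the observed
#' difference count, the pairwise moment estimate of theta); the number of
#' visibly differing sites after h mutations follows a Markov chain in which
#' a hit on a currently matching site always creates a difference and a hit
#' on a currently differing site reverts it with probability 1/3
#' (Jukes-Cantor-type states). The returned value is the posterior
#' probability of no superimposed hits given j visible differences.
#'
#' @param j observed differences (>= 1).
#' @param m aligned sites.
#' @param maxExtra how many extra mutations beyond j to integrate over.
#' @export
parsimonyProbability <- function(j, m, maxExtra = 30L) {
  stopifnot(j >= 1L, m >= j)
  theta <- j
  pH <- function(h) (1 / (1 + theta)) * (theta / (1 + theta))^h
  hmax <- j + maxExtra
  # DP over number of visibly differing sites, one mutation at a time
  p <- numeric(hmax + 2L)   # index k+1 = k differing sites
  p[1L] <- 1
  lik <- numeric(hmax + 1L) # lik[h+1] = P(j visible | h mutations)
  lik[1L] <- as.numeric(j == 0L)
  for (h in seq_len(hmax)) {
    k <- 0:hmax
    up <- (m - k) / m
    stay <- (k / m) * (2 / 3)
    down <- (k / m) * (1 / 3)
    np <- numeric(hmax + 2L)
    np[2:(hmax + 2L)] <- p[1:(hmax + 1L)] * up[1:(hmax + 1L)]
    np[1:(hmax + 1L)] <- np[1:(hmax + 1L)] + p[1:(hmax + 1L)] * stay[1:(hmax + 1L)]
    np[1:(hmax)] <- np[1:(hmax)] + p[2:(hmax + 1L)] * down[2:(hmax + 1L)]
    p <- np
    lik[h + 1L] <- p[j + 1L]
  }
  h <- j:hmax
  post <- pH(h) * lik[h + 1L]
  post[1L] / sum(post)
}

#' Statistical-parsimony connection limit
#'
#' The largest number of steps \code{j} whose parsimony probability
#' (\code{\link{parsimonyProbability}}) still reaches the confidence level;
#' at least 1.
#'
#' @param L aligned sites.
#' @param confidence confidence level in (0, 1).
#' @param maxSteps scan bound.
#' @return integer limit.
#' @export
connectionLimit <- function(L, confidence = 0.95, maxSteps = 200L) {
  stopifnot(L > 0L, confidence > 0, confidence < 1)
  limit <- 1L
  for (j in seq_len(min(maxSteps, L))) {
    if (parsimonyProbability(j, L) >= confidence) limit <- j else break
  }
  limit
}

#' Build the statistical-parsimony haplotype network
#'
#' Minimum-spanning-network construction: candidate haplotype pairs are
#' processed in nondecreasing event distance; at each distance level every
#' pair not already connected at a smaller distance is a candidate, and all
#' co-minimal alternatives are retained (network, not tree). An edge is
#' skipped when (a) its distance exceeds the connection limit, or (b) under
#' the substitution constraint one of its substitution events (same event,
#' same unordered state pair) already labels an accepted edge, which would
#' force that substitution to arise more than once. Indel and microsatellite
#' events are exempt from (b) (homoplasy allowed). Multi-step edges
#' materialize intermediate median nodes in the exported graph. Haplotypes
#' left unconnected are reported as separate components.
#'
#' @param ht a \code{\link{HaplotypeTable}}.
#' @param limit integer connection limit; when \code{NULL}, computed from the
#'   alignment length at \code{confidence}.
#' @param constraint \code{"substitutions"} (the homoplasy-free-substitution
#'   constraint) or \code{"none"}.
#' @param confidence confidence for the computed limit.
#' @param microsatStepwise passed to \code{\link{pairwiseEventDistance}}.
#' @return a \code{\link{HaploNetwork}}.
#' @export
buildHaploNetwork <- function(ht, limit = NULL,
                              constraint = c("substitutions", "none"),
                              confidence = 0.95, microsatStepwise = FALSE) {
  constraint <- match.arg(constraint)
  if (nrow(ht) == 0L) stop("empty haplotype table")
  st <- .stateMatrix(ht)
  ev <- haplotypeCatalog(ht)@events
  d <- pairwiseEventDistance(ht, microsatStepwise = microsatStepwise)
  H <- nrow(d)
  if (is.null(limit))
    limit <- connectionLimit(haplotypeCatalog(ht)@alignLength, confidence)
  limit <- as.integer(limit)

  diffEvents <- function(a, b) {
    if (ncol(st) == 0L) return(character())
    ks <- which(st[a, ] != st[b, ])
    keep <- vapply(ks, function(k) {
      sa <- st[a, k]; sb <- st[b, k]
      switch(ev$kind[k],
        substitution = all(c(sa, sb) %in% c("A", "C", "G", "T")),
        indel = all(c(sa, sb) %in% c("0", "1")),
        microsatellite = !anyNA(suppressWarnings(as.numeric(c(sa, sb)))))
    }, logical(1L))
    ev$id[ks[keep]]
  }

  comp <- seq_len(H)                     # union-find by relabel
  usedSub <- character()                 # "event|state1|state2" keys
  edges <- list()
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  if (nrow(pairs)) {
    pd <- d[pairs]
    o <- order(pd, pairs[, 1L], pairs[, 2L])
    pairs <- pairs[o, , drop = FALSE]; pd <- pd[o]
    for (lev in unique(pd)) {
      if (lev > limit) break
      sel <- which(pd == lev)
      compBefore <- comp                 # connectivity from smaller distances
      for (q in sel) {
        a <- pairs[q, 1L]; b <- pairs[q, 2L]
        if (compBefore[a] == compBefore[b]) next
        evts <- diffEvents(a, b)
        if (constraint == "substitutions") {
          subs <- evts[ev$kind[match(evts, ev$id)] == "substitution"]
          keys <- vapply(subs, function(e) {
            k <- match(e, ev$id)
            paste(c(e, sort(c(st[a, k], st[b, k]))), collapse = "|")
          }, character(1L))
          if (any(keys %in% usedSub)) next
          usedSub <- c(usedSub, keys)
        }
        edges[[length(edges) + 1L]] <-
          list(a = a, b = b, d = lev, events = evts)
        comp[comp == comp[b]] <- comp[a]
      }
    }
  }

  cnt <- speciesCounts(ht)
  g <- igraph::make_empty_graph(n = H, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = rownames(d))
  g <- igraph::set_vertex_attr(g, "type", value = "observed")
  g <- igraph::set_vertex_attr(g, "frequency", value = rowSums(cnt))
  for (s in colnames(cnt))
    g <- igraph::set_vertex_attr(g, paste0("n_", s), value = cnt[, s])
  medianCount <- 0L
  for (e in edges) {
    if (e$d <= 1L) {
      g <- igraph::add_edges(g, c(e$a, e$b),
                             attr = list(events = paste(e$events,
                                                        collapse = ",")))
    } else {
      prev <- e$a
      for (s in seq_len(e$d - 1L)) {
        medianCount <- medianCount + 1L
        g <- igraph::add_vertices(g, 1L, attr = list(
          name = sprintf("mv%d", medianCount), type = "median",
          frequency = 0))
        mid <- igraph::vcount(g)
        g <- igraph::add_edges(g, c(prev, mid), attr = list(
          events = if (length(e$events) >= s) e$events[s] else ""))
        prev <- mid
      }
      g <- igraph::add_edges(g, c(prev, e$b), attr = list(
        events = if (length(e$events) >= e$d) e$events[e$d] else ""))
    }
  }
  net <- new("HaploNetwork", graph = g, limit = limit,
             confidence = confidence, constraint = constraint)
  attr(net@graph, "edgeTable") <- edges
  net
}

#' Accepted haplotype-to-haplotype edges of a network
#'
#' @param net a \code{HaploNetwork}.
#' @return data.frame with haplotype endpoints, step count and event labels
#'   (median nodes collapsed).
#' @export
networkEdges <- function(net) {
  edges <- attr(net@graph, "edgeTable")
  nm <- igraph::vertex_attr(net@graph, "name")
  if (!length(edges))
    return(data.frame(from = character(), to = character(), steps = integer(),
                      events = character(), stringsAsFactors = FALSE))
  data.frame(
    from = nm[vapply(edges, function(e) as.integer(e$a), integer(1L))],
    to = nm[vapply(edges, function(e) as.integer(e$b), integer(1L))],
    steps = vapply(edges, function(e) as.integer(e$d), integer(1L)),
    events = vapply(edges, function(e) paste(e$events, collapse = ","),
                    character(1L)),
    stringsAsFactors = FALSE)
}

setMethod("show", "HaploNetwork", function(object) {
  g <- object@graph
  obs <- sum(igraph::vertex_attr(g, "type") == "observed")
  cat(sprintf(
    "HaploNetwork: %d haplotypes, %d median nodes, %d edges; limit %d steps (%.0f%%), constraint '%s'\n",
    obs, igraph::vcount(g) - obs, igraph::ecount(g), object@limit,
    100 * object@confidence, object@constraint))
  comp <- igraph::components(g)$no
  if (comp > 1L) cat(sprintf("  %d unconnected subnetworks\n", comp))
})

#' Export a haplotype network
#'
#' Graph as GraphML or DOT (via igraph), node attribute table as TSV
#' (haplotype, total and per-species counts).
#'
#' @param net a \code{HaploNetwork}.
#' @param path output path.
#' @param format \code{"graphml"}, \code{"dot"} or \code{"tsv"}.
#' @export
writeNetwork <- function(net, path, format = c("graphml", "dot", "tsv")) {
  format <- match.arg(format)
  g <- net@graph
  if (format == "tsv") {
    at <- igraph::vertex_attr(g)
    utils::write.table(as.data.frame(at), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    igraph::write_graph(g, path, format = format)
  }
  invisible(path)
}
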