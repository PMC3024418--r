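#' Simple indel coding
#'
#' Converts alignment gaps into binary presence/absence characters: each gap
#' with a unique \code{(start, end)} span becomes one character; a taxon
#' whose own gap strictly contains another taxon's span is scored missing
#' (\code{"?"}) for the contained span's character. Characters are ordered by
#' \code{(start, end)}; output is invariant under taxon reordering.
#'
#' @param M character matrix (taxa x columns) over \code{A,C,G,T,-,N}.
#' @return list: \code{chars} (taxa x characters, \code{"0"/"1"/"?"}),
#'   \code{spans} (data.frame start/end).
#' @export
simpleIndelCoding <- function(M) {
  n <- nrow(M)
  runs <- lapply(seq_len(n), function(i) .gapRuns(M[i, ]))
  spans <- unique(do.call(rbind, runs))
  if (is.null(spans) || nrow(spans) == 0L)
    return(list(chars = matrix(character(), n, 0L,
                               dimnames = list(rownames(M), NULL)),
                spans = data.frame(start = integer(), end = integer())))
  spans <- spans[order(spans[, 1L], spans[, 2L]), , drop = FALSE]
  chars <- matrix("0", n, nrow(spans),
                  dimnames = list(rownames(M),
                                  sprintf("indel%d_%d", spans[, 1L],
                                          spans[, 2L])))
  for (i in seq_len(n)) {
    r <- runs[[i]]
    if (!nrow(r)) next
    for (k in seq_len(nrow(spans))) {
      s <- spans[k, 1L]; e <- spans[k, 2L]
      if (any(r[, 1L] == s & r[, 2L] == e)) chars[i, k] <- "1"
      else if (any(r[, 1L] <= s & r[, 2L] >= e)) chars[i, k] <- "?"
    }
  }
  list(chars = chars, spans = data.frame(start = spans[, 1L],
                                         end = spans[, 2L]))
}

.charStats <- function(col) {
  obs <- col[col != "?"]
  cnt <- table(obs)
  states <- length(cnt)
  m <- max(states - 1L, 0L)
  g <- if (states) length(obs) - max(cnt) else 0L
  informative <- sum(cnt >= 2L) >= 2L
  c(m = m, g = g, informative = informative)
}

#' Build a parsimony character matrix from an alignment
#'
#' Variable nucleotide columns (states \code{A,C,G,T}; gaps and \code{N}
#' become missing \code{"?"}) plus, under \code{gapMode = "sic"}, the simple
#' indel coding binary characters appended after the nucleotide block.
#' Invariant columns are dropped but counted in the attributes.
#'
#' @param M character matrix (taxa x aligned columns), e.g.
#'   \code{as.matrix(aln)}.
#' @param gapMode \code{"missing"} or \code{"sic"}.
#' @return a \code{\link{CharacterMatrix}}; \code{metadata} entries
#'   \code{nVariable}, \code{nInformative}, \code{nIndelChars} summarize the
#'   character accounting.
#' @export
characterMatrix <- function(M, gapMode = c("missing", "sic")) {
  gapMode <- match.arg(gapMode)
  stopifnot(is.matrix(M), !is.null(rownames(M)))
  nuc <- M
  nuc[!(nuc %in% c("A", "C", "G", "T"))] <- "?"
  variable <- vapply(seq_len(ncol(nuc)), function(j)
    length(unique(nuc[nuc[, j] != "?", j])) >= 2L, logical(1L))
  cols <- which(variable)
  chars <- nuc[, cols, drop = FALSE]
  colnames(chars) <- sprintf("nuc%d", cols)
  info <- data.frame(type = rep("nuc", length(cols)), column = cols)
  if (gapMode == "sic") {
    sic <- simpleIndelCoding(M)
    if (ncol(sic$chars)) {
      chars <- cbind(chars, sic$chars)
      info <- rbind(info, data.frame(type = rep("indel", ncol(sic$chars)),
                                     column = NA_integer_, row.names = NULL))
    }
  }
  st <- t(vapply(seq_len(ncol(chars)), function(j) .charStats(chars[, j]),
                 numeric(3L)))
  info$m <- as.integer(st[, 1L])
  info$g <- as.integer(st[, 2L])
  info$informative <- st[, 3L] == 1
  rownames(info) <- colnames(chars)
  cm <- new("CharacterMatrix", chars = chars, info = info, gapMode = gapMode)
  cm
}

setMethod("show", "CharacterMatrix", function(object) {
  inf <- object@info
  cat(sprintf(
    "CharacterMatrix (%s): %d taxa, %d variable characters (%d informative, %d uninformative), %d indel characters\n",
    object@gapMode, nrow(object@chars), ncol(object@chars),
    sum(inf$informative), sum(!inf$informative), sum(inf$type == "indel")))
})

# ---- Fitch engine over a nested-list tree representation -------------------
# A tree is either a taxon index (leaf) or a list of >= 2 subtrees. States
# are bitmasks; "?" = union of all observed states for the character, so
# missing data never force steps.

.encodeChars <- function(cm) {
  chars <- cm@chars
  enc <- matrix(0L, nrow(chars), ncol(chars), dimnames = dimnames(chars))
  full <- integer(ncol(chars))
  for (j in seq_len(ncol(chars))) {
    lev <- sort(unique(chars[chars[, j] != "?", j]))
    bit <- stats::setNames(bitwShiftL(1L, seq_along(lev) - 1L), lev)
    f <- sum(bit)
    if (f == 0L) f <- 1L
    v <- ifelse(chars[, j] == "?", f, bit[chars[, j]])
    enc[, j] <- as.integer(v)
    full[j] <- as.integer(f)
  }
  list(enc = enc, full = full)
}

.fitchRec <- function(node, enc) {
  if (!is.list(node))
    return(list(set = enc[node, ], steps = integer(ncol(enc))))
  r <- .fitchRec(node[[1L]], enc)
  set <- r$set; steps <- r$steps
  for (k in 2L:length(node)) {
    r <- .fitchRec(node[[k]], enc)
    steps <- steps + r$steps
    inter <- bitwAnd(set, r$set)
    zero <- inter == 0L
    set <- ifelse(zero, bitwOr(set, r$set), inter)
    steps <- steps + zero
  }
  list(set = set, steps = steps)
}

.phyloToNested <- function(tree) {
  tipIdx <- seq_along(tree$tip.label)
  build <- function(node) {
    if (node <= length(tipIdx)) return(node)
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    lapply(kids, build)
  }
  build(length(tipIdx) + 1L)
}

#' Fitch parsimony length of a tree
#'
#' Fitch optimization for unordered characters; \code{"?"} (missing)
#' contributes no forced steps. Works on binary trees (a basal trichotomy
#' from an unrooted tree is handled exactly).
#'
#' @param tree an \code{ape} \code{phylo} whose tip labels are the matrix
#'   taxa.
#' @param cm a \code{\link{CharacterMatrix}}.
#' @return list: total length \code{L} and per-character steps \code{steps}.
#' @export
fitchLength <- function(tree, cm) {
  taxa <- rownames(cm@chars)
  if (!setequal(tree$tip.label, taxa))
    stop("tree tips and matrix taxa differ: ",
         paste(union(setdiff(tree$tip.label, taxa),
                     setdiff(taxa, tree$tip.label)), collapse = ", "))
  e <- .encodeChars(cm)
  enc <- e$enc[tree$tip.label, , drop = FALSE]
  if (ncol(enc) == 0L) return(list(L = 0L, steps = integer()))
  nested <- .phyloToNested(tree)
  r <- .fitchRec(nested, enc)
  list(L = sum(r$steps), steps = stats::setNames(r$steps, colnames(enc)))
}

#' Lower bound on tree length
#'
#' \eqn{\sum_i m_i}, the sum over characters of (observed states - 1); no
#' tree can be shorter, and a tree attaining it is certified globally
#' optimal (CI = 1).
#'
#' @param cm a \code{CharacterMatrix}.
#' @export
parsimonyBound <- function(cm) sum(cm@info$m)

#' Tree length and homoplasy indices
#'
#' \code{CI} = \eqn{\sum m_i/\sum s_i} over variable characters, \code{CIexc}
#' excluding parsimony-uninformative characters, \code{RI} =
#' \eqn{(\sum g_i - \sum s_i)/(\sum g_i - \sum m_i)} (flagged undefined when
#' \eqn{\sum g = \sum m}).
#'
#' @inheritParams fitchLength
#' @return list: \code{L}, \code{CI}, \code{CIexc}, \code{RI},
#'   \code{RIdefined}, per-character \code{steps}.
#' @export
treeIndices <- function(tree, cm) {
  f <- fitchLength(tree, cm)
  inf <- cm@info
  v <- inf$m > 0L
  ci <- if (sum(f$steps[v]) > 0) sum(inf$m[v]) / sum(f$steps[v]) else 1
  e <- v & inf$informative
  ciexc <- if (sum(f$steps[e]) > 0) sum(inf$m[e]) / sum(f$steps[e]) else 1
  sg <- sum(inf$g); sm <- sum(inf$m)
  riDef <- sg > sm
  ri <- if (riDef) (sg - sum(f$steps)) / (sg - sm) else NA_real_
  list(L = f$L, CI = ci, CIexc = ciexc, RI = ri, RIdefined = riDef,
       steps = f$steps)
}

# ---- tree search on the nested representation ------------------------------
# Unrooted trees over taxa 1..n are represented rooted on the pendant edge of
# the first taxon in `order`: tree = list(leaf, S). Attachment positions are
# all nodes of S (including S itself), one per unrooted edge.

.nodePaths <- function(node, prefix = integer()) {
  out <- list(prefix)
  if (is.list(node))
    for (k in seq_along(node))
      out <- c(out, .nodePaths(node[[k]], c(prefix, k)))
  out
}

.getAt <- function(tree, path) {
  for (k in path) tree <- tree[[k]]
  tree
}

.replaceAt <- function(tree, path, value) {
  if (!length(path)) return(value)
  tree[[path[1L]]] <- .replaceAt(tree[[path[1L]]], path[-1L], value)
  tree
}

.insertLeaf <- function(S, path, leaf)
  .replaceAt(S, path, list(.getAt(S, path), leaf))

.deleteLeaf <- function(S, leaf) {
  # returns S with the leaf spliced out (parent replaced by sibling)
  splice <- function(node) {
    if (!is.list(node)) return(if (identical(node, leaf)) NULL else node)
    kids <- lapply(node, splice)
    drop <- vapply(kids, is.null, logical(1L))
    kids <- kids[!drop]
    if (length(kids) == 1L) kids[[1L]] else kids
  }
  splice(S)
}

.scoreNested <- function(S, leaf1, enc) {
  r <- .fitchRec(list(leaf1, S), enc)
  sum(r$steps)
}

.canonical <- function(node, taxa) {
  if (!is.list(node)) return(taxa[node])
  paste0("(", paste(sort(vapply(node, .canonical, character(1L), taxa)),
                    collapse = ","), ")")
}

.nestedToNewick <- function(S, leaf1, taxa) {
  rec <- function(node) {
    if (!is.list(node)) return(taxa[node])
    paste0("(", paste(vapply(node, rec, character(1L)), collapse = ","), ")")
  }
  paste0("(", taxa[leaf1], ",", rec(S), ");")
}

.randomAddition <- function(enc, ord) {
  leaf1 <- ord[1L]
  S <- if (length(ord) >= 3L) list(ord[2L], ord[3L]) else ord[2L]
  if (length(ord) >= 4L) for (i in 4L:length(ord)) {
    paths <- .nodePaths(S)
    best <- NULL; bestL <- Inf
    for (p in paths) {
      cand <- .insertLeaf(S, p, ord[i])
      L <- .scoreNested(cand, leaf1, enc)
      if (L < bestL) { bestL <- L; best <- cand }
    }
    S <- best
  }
  list(S = S, leaf1 = leaf1, L = .scoreNested(S, leaf1, enc))
}

.leafSPR <- function(S, leaf1, enc, bound) {
  L <- .scoreNested(S, leaf1, enc)
  repeat {
    if (L <= bound) break
    improved <- FALSE
    leaves <- setdiff(unlist(S), integer())
    for (lf in leaves) {
      S2 <- .deleteLeaf(S, lf)
      if (!is.list(S2)) next
      for (p in .nodePaths(S2)) {
        cand <- .insertLeaf(S2, p, lf)
        Lc <- .scoreNested(cand, leaf1, enc)
        if (Lc < L) { S <- cand; L <- Lc; improved <- TRUE; break }
      }
      if (improved) break
    }
    if (!improved) break
  }
  list(S = S, L = L)
}

#' Heuristic parsimony search
#'
#' Random stepwise addition followed by leaf-reinsertion (leaf-SPR) hill
#' climbing, repeated over \code{nStarts} random addition sequences; stops
#' early when the parsimony bound is attained (which certifies global
#' optimality). Distinct best trees are counted by canonical newick up to
#' \code{maxTrees}.
#'
#' @param cm a \code{\link{CharacterMatrix}} with >= 4 taxa.
#' @param nStarts random addition replicates.
#' @param seed RNG seed (recorded).
#' @param maxTrees cap on stored distinct best trees.
#' @return list: \code{tree} (ape phylo), \code{score}
#'   (\code{\link{treeIndices}} of the best tree), \code{nBest},
#'   \code{bound}, \code{boundAttained}, \code{seed}.
#' @export
heuristicSearch <- function(cm, nStarts = 10L, seed = NULL,
                            maxTrees = 10000L) {
  taxa <- rownames(cm@chars)
  stopifnot(length(taxa) >= 4L)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  set.seed(seed)
  e <- .encodeChars(cm)
  enc <- e$enc
  bound <- parsimonyBound(cm)
  bestL <- Inf; bestSet <- character(); bestTree <- NULL
  for (s in seq_len(nStarts)) {
    ord <- sample.int(length(taxa))
    ra <- .randomAddition(enc, ord)
    hc <- .leafSPR(ra$S, ra$leaf1, enc, bound)
    # re-root representation on taxon 1 for canonical comparison
    nwk <- .nestedToNewick(hc$S, ra$leaf1, taxa)
    tr <- ape::read.tree(text = nwk)
    if (hc$L < bestL) {
      bestL <- hc$L; bestTree <- tr
      bestSet <- character()
    }
    if (hc$L == bestL && length(bestSet) < maxTrees) {
      key <- .canonicalPhylo(tr)
      bestSet <- union(bestSet, key)
    }
    if (bestL <= bound) break
  }
  list(tree = bestTree, score = treeIndices(bestTree, cm), nBest = length(bestSet),
       bound = bound, boundAttained = bestL <= bound, seed = seed)
}

.canonicalPhylo <- function(tree) {
  # canonical string of the unrooted topology: root at the alphabetically
  # first tip's pendant edge, sort children recursively
  tips <- sort(tree$tip.label)
  t1 <- tips[1L]
  idx <- match(tree$tip.label, tree$tip.label)
  nested <- .phyloToNested(tree)
  # relabel leaves by tip name, splice out t1, canonicalize the rest
  S <- .deleteLeaf(.relabel(nested, tree$tip.label), t1)
  canon <- function(node) {
    if (!is.list(node)) return(node)
    paste0("(", paste(sort(vapply(node, canon, character(1L))),
                      collapse = ","), ")")
  }
  paste0(t1, "|", canon(S))
}

.relabel <- function(node, labels) {
  if (!is.list(node)) return(labels[node])
  lapply(node, .relabel, labels)
}

#' Exhaustive parsimony search
#'
#' Enumerates every unrooted binary topology (by sequential insertion) and
#' returns the minimum Fitch length; feasible for up to ~8 taxa.
#'
#' @param cm a \code{CharacterMatrix} with 4-8 taxa.
#' @return list: \code{L}, \code{nTrees} enumerated, \code{tree} (one best,
#'   ape phylo).
#' @export
exhaustiveSearch <- function(cm) {
  taxa <- rownames(cm@chars)
  n <- length(taxa)
  stopifnot(n >= 4L, n <= 8L)
  enc <- .encodeChars(cm)$enc
  trees <- list(list(2L, 3L))
  if (n >= 4L) for (i in 4L:n) {
    trees <- unlist(lapply(trees, function(S)
      lapply(.nodePaths(S), function(p) .insertLeaf(S, p, i))),
      recursive = FALSE)
  }
  Ls <- vapply(trees, .scoreNested, numeric(1L), leaf1 = 1L, enc = enc)
  best <- which.min(Ls)
  list(L = min(Ls), nTrees = length(trees),
       tree = ape::read.tree(text = .nestedToNewick(trees[[best]], 1L, taxa)))
}

#' Write a character matrix as NEXUS
#'
#' DATA block with symbols \code{A C G T 0 1} and \code{?} for missing, so
#' the appended binary indel-coding characters travel with the nucleotide
#' block.
#'
#' @param cm a \code{CharacterMatrix}.
#' @param path output path.
#' @export
writeCharacterMatrixNexus <- function(cm, path) {
  m <- cm@chars
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#NEXUS", "BEGIN DATA;",
               sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(m), ncol(m)),
               "  FORMAT SYMBOLS=\"A C G T 0 1\" MISSING=? GAP=-;",
               "  MATRIX"), con)
  writeLines(sprintf("    %-12s %s", rownames(m),
                     apply(m, 1L, paste, collapse = "")), con)
  writeLines(c("  ;", "END;"), con)
  invisible(path)
}
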