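test_that("the parsimony probability agrees with an independent transcription", {
  for (j in c(1L, 3L, 8L, 14L)) {
    expect_equal(parsimonyProbability(j, 1559L), oracleParsProb(j, 1559L),
                 tolerance = 1e-10, label = paste("j =", j))
    expect_equal(parsimonyProbability(j, 600L), oracleParsProb(j, 600L),
                 tolerance = 1e-10)
  }
  # and the resulting limits agree
  oLimit <- function(m, conf) {
    l <- 1L
    for (j in 1:100) if (oracleParsProb(j, m) >= conf) l <- j else break
    l
  }
  expect_identical(connectionLimit(1559L, 0.95), oLimit(1559L, 0.95))
  expect_identical(connectionLimit(858L, 0.95), oLimit(858L, 0.95))
})

test_that("connection limits behave sensibly", {
  expect_identical(connectionLimit(1559L, 0.95), connectionLimit(1559L, 0.95))
  # lower confidence can only raise the limit
  expect_gte(connectionLimit(1559L, 0.50), connectionLimit(1559L, 0.95))
  # longer alignments allow more steps at the same confidence
  expect_gte(connectionLimit(2000L, 0.95), connectionLimit(500L, 0.95))
  expect_gte(connectionLimit(100L, 0.99), 1L)
})

test_that("a three-haplotype chain excludes the redundant long edge", {
  r <- htFromSeqs(c(a = "AAAAAA", b = "CAAAAA", c = "CAACAA"),
                  populations = rep("p1", 3L))
  net <- buildHaploNetwork(r$ht)
  ed <- networkEdges(net)
  expect_identical(nrow(ed), 2L)
  expect_true(all(ed$steps == 1L))
  # path A-B-C, no direct A-C edge
  pairs <- paste(ed$from, ed$to)
  expect_false("H01 H03" %in% pairs || "H03 H01" %in% pairs)
})

test_that("a single haplotype yields a single node and no edges", {
  r <- htFromSeqs(c(a = "ACGT", b = "ACGT"), populations = c("p1", "p1"))
  net <- buildHaploNetwork(r$ht)
  expect_equal(igraph::vcount(net@graph), 1L)
  expect_equal(igraph::ecount(net@graph), 0L)
})

test_that("indel homoplasy is allowed while substitutions stay single-origin", {
  # A=(s0,i0) B=(s0,i1) C=(s1,i0) D=(s1,i1): the same indel separates A-B
  # and C-D; the same substitution separates A-C and B-D
  r <- htFromSeqs(c(A = "ATTGGTTA", B = "ATT--TTA",
                    C = "CTTGGTTA", D = "CTT--TTA"),
                  populations = rep("p1", 4L))
  net <- buildHaploNetwork(r$ht, constraint = "substitutions")
  ed <- networkEdges(net)
  expect_identical(nrow(ed), 3L)
  kinds <- haplotypeCatalog(r$ht)@events
  indelID <- kinds$id[kinds$kind == "indel"]
  # both indel edges retained, only one substitution edge
  expect_identical(sum(ed$events == indelID), 2L)
  # removing the constraint never decreases the edge count
  edFree <- networkEdges(buildHaploNetwork(r$ht, constraint = "none"))
  expect_gte(nrow(edFree), nrow(ed))
})

test_that("multi-step edges materialize median nodes", {
  r <- htFromSeqs(c(a = "AAAAAA", b = "CCAAAA"), populations = c("p1", "p1"))
  net <- buildHaploNetwork(r$ht, limit = 5L)
  types <- igraph::vertex_attr(net@graph, "type")
  expect_identical(sum(types == "median"), 1L)
  expect_equal(igraph::ecount(net@graph), 2L)
  expect_identical(networkEdges(net)$steps, 2L)
})

test_that("haplotypes beyond the connection limit stay unconnected", {
  r <- htFromSeqs(c(a = "AAAAAA", b = "CCCAAA"), populations = c("p1", "p1"))
  net <- buildHaploNetwork(r$ht, limit = 2L)
  expect_equal(igraph::components(net@graph)$no, 2L)
})

test_that("network path lengths never undercut pairwise event distances", {
  set.seed(31)
  for (rep in 1:6) {
    n <- 8L
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C"), 12L, TRUE, prob = c(0.75, 0.25)),
            collapse = ""), "")
    names(seqs) <- sprintf("s%d", seq_len(n))
    r <- htFromSeqs(seqs, populations = rep("p1", n))
    if (nrow(r$ht) < 2L) next
    net <- buildHaploNetwork(r$ht, limit = 50L, constraint = "none")
    ed <- networkEdges(net)
    if (!nrow(ed)) next
    g <- igraph::graph_from_data_frame(ed[, c("from", "to")],
                                       directed = FALSE,
                                       vertices = rownames(r$ht))
    igraph::E(g)$weight <- ed$steps
    sp <- igraph::distances(g)
    d <- pairwiseEventDistance(r$ht)
    reach <- is.finite(sp)
    expect_true(all(sp[reach] >= d[rownames(sp), colnames(sp)][reach] - 1e-9))
  }
})

test_that("networks export as GraphML, DOT and node tables", {
  r <- htFromSeqs(c(a = "AAAA", b = "CAAA", c = "CAAC"),
                  populations = rep("p1", 3L))
  net <- buildHaploNetwork(r$ht)
  f1 <- withr::local_tempfile(fileext = ".graphml")
  writeNetwork(net, f1, "graphml")
  expect_gt(file.size(f1), 0)
  g2 <- igraph::read_graph(f1, format = "graphml")
  expect_equal(igraph::vcount(g2), igraph::vcount(net@graph))
  f2 <- withr::local_tempfile(fileext = ".dot")
  writeNetwork(net, f2, "dot")
  expect_gt(file.size(f2), 0)
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeNetwork(net, f3, "tsv")
  tab <- utils::read.table(f3, sep = "\t", header = TRUE)
  expect_true("frequency" %in% names(tab))
})
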