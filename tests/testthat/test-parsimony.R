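mkmat <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- names(seqs)
  m
}

test_that("simple indel coding follows the span/containment rules", {
  # one taxon with gap 5-7, others ungapped -> one 1/0 character
  m1 <- mkmat(c(t1 = "ACGT---ACG", t2 = "ACGTTTTACG", t3 = "ACGTTTTACG"))
  s1 <- simpleIndelCoding(m1)
  expect_identical(ncol(s1$chars), 1L)
  expect_identical(unname(s1$chars[, 1L]), c("1", "0", "0"))
  # gaps 5-7 and 5-9: two characters; the 5-9 taxon is "?" for 5-7
  m2 <- mkmat(c(t1 = "ACGT---ACG", t2 = "ACGT-----G", t3 = "ACGTTTTACG"))
  s2 <- simpleIndelCoding(m2)
  expect_identical(ncol(s2$chars), 2L)
  expect_identical(unname(s2$chars[, "indel5_7"]), c("1", "?", "0"))
  expect_identical(unname(s2$chars[, "indel5_9"]), c("0", "1", "0"))
  # identical spans share one character
  m3 <- mkmat(c(t1 = "AC--T", t2 = "AC--T", t3 = "ACGTT"))
  s3 <- simpleIndelCoding(m3)
  expect_identical(ncol(s3$chars), 1L)
  expect_identical(unname(s3$chars[, 1L]), c("1", "1", "0"))
})

test_that("indel coding is invariant under taxon reordering", {
  m <- mkmat(c(t1 = "A--GT--A", t2 = "A--GTTTA", t3 = "AC-GT--A",
               t4 = "ACCGTTTA"))
  s <- simpleIndelCoding(m)
  ord <- c(3L, 1L, 4L, 2L)
  s2 <- simpleIndelCoding(m[ord, ])
  expect_identical(s2$chars[rownames(m), ], s$chars)
})

test_that("character matrices carry min/max steps and informativeness", {
  m <- mkmat(c(t1 = "AAGA-", t2 = "ACGA-", t3 = "ACTAT", t4 = "AATAT"))
  cm <- characterMatrix(m, "missing")
  # column 1 invariant, dropped; columns 2 and 3 variable
  expect_identical(ncol(cm@chars), 2L)
  expect_identical(cm@info$m, c(1L, 1L))
  expect_identical(cm@info$g, c(2L, 2L))
  expect_true(all(cm@info$informative))
  cmSic <- characterMatrix(m, "sic")
  expect_identical(sum(cmSic@info$type == "indel"), 1L)
  # three-state column has minimum two steps
  m2 <- mkmat(c(t1 = "A", t2 = "C", t3 = "G", t4 = "C"))
  expect_identical(parsimonyBound(characterMatrix(m2, "missing")), 2L)
})

test_that("Fitch length matches hand counts and ignores missing data", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  cm1 <- characterMatrix(mkmat(c(A = "A", B = "A", C = "C", D = "C")),
                         "missing")
  expect_identical(fitchLength(tr, cm1)$L, 1L)
  cm2 <- characterMatrix(mkmat(c(A = "A", B = "C", C = "A", D = "C")),
                         "missing")
  expect_identical(fitchLength(tr, cm2)$L, 2L)
  # a character observed in one taxon only is all-missing after masking
  cm3 <- characterMatrix(mkmat(c(A = "A-", B = "AA", C = "A-", D = "A-")),
                         "missing")
  expect_identical(fitchLength(tr, cm3)$L, 0L)
  expect_error(fitchLength(ape::read.tree(text = "((A,B),(C,X));"), cm1),
               "differ")
})

test_that("Fitch equals the exhaustive assignment oracle on small trees", {
  set.seed(37)
  for (rep in 1:6) {
    n <- sample(4:6, 1L)
    taxa <- sprintf("t%d", seq_len(n))
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "-"), 6L, TRUE), collapse = ""), "")
    names(seqs) <- taxa
    cm <- characterMatrix(mkmat(seqs), "missing")
    if (ncol(cm@chars) == 0L) next
    tr <- ape::rtree(n, tip.label = sample(taxa))
    expect_equal(fitchLength(tr, cm)$L, oracleFitch(tr, cm),
                     label = sprintf("rep %d", rep))
  }
})

test_that("Fitch agrees with an established implementation", {
  skip_if_not_installed("phangorn")
  set.seed(41)
  for (rep in 1:4) {
    n <- 8L
    taxa <- sprintf("t%d", seq_len(n))
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), 12L, TRUE), collapse = ""), "")
    names(seqs) <- taxa
    cm <- characterMatrix(mkmat(seqs), "missing")
    tr <- ape::rtree(n, tip.label = taxa)
    pd <- phangorn::phyDat(mkmat(seqs), type = "DNA")
    expect_identical(fitchLength(tr, cm)$L,
                     as.integer(phangorn::parsimony(tr, pd, method = "fitch")))
  }
})

test_that("tree indices reproduce hand computations", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  # homoplasy-free two-character matrix
  cmGood <- characterMatrix(mkmat(c(A = "AA", B = "AA", C = "CA", D = "CC")),
                            "missing")
  iGood <- treeIndices(tr, cmGood)
  expect_equal(iGood$CI, 1)
  expect_equal(iGood$RI, 1)
  # single informative character conflicting with the tree: s=2, m=1, g=2
  cmBad <- characterMatrix(mkmat(c(A = "A", B = "C", C = "A", D = "C")),
                           "missing")
  iBad <- treeIndices(tr, cmBad)
  expect_equal(iBad$CI, 0.5)
  expect_equal(iBad$RI, 0)
  # with no uninformative characters CIexc equals CI
  expect_equal(iBad$CIexc, iBad$CI)
  # CI weakly decreases as homoplasic characters are added
  cmMix <- characterMatrix(mkmat(c(A = "AA", B = "CA", C = "AC", D = "CC")),
                           "missing")
  expect_lte(treeIndices(tr, cmMix)$CI, iGood$CI)
})

test_that("RI undefined is flagged when max steps equal min steps", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  # only a singleton character: g == m
  cm <- characterMatrix(mkmat(c(A = "A", B = "A", C = "A", D = "C")),
                        "missing")
  i <- treeIndices(tr, cm)
  expect_false(i$RIdefined)
})

test_that("heuristic search certifies the bound on compatible characters", {
  # nested clade structure: perfect phylogeny, bound attainable
  seqs <- c(t1 = "AAAAA", t2 = "CAAAA", t3 = "CCAAA", t4 = "CCCAA",
            t5 = "CCCCA", t6 = "CCCCC")
  cm <- characterMatrix(mkmat(seqs), "missing")
  r <- heuristicSearch(cm, nStarts = 3L, seed = 5L)
  expect_true(r$boundAttained)
  expect_identical(r$score$L, parsimonyBound(cm))
  expect_equal(r$score$CI, 1)
})

test_that("heuristic search matches exhaustive search on 5-taxon matrices", {
  set.seed(43)
  for (rep in 1:5) {
    taxa <- sprintf("t%d", 1:5)
    seqs <- vapply(1:5, function(i)
      paste(sample(c("A", "C"), 8L, TRUE), collapse = ""), "")
    names(seqs) <- taxa
    cm <- characterMatrix(mkmat(seqs), "missing")
    if (ncol(cm@chars) == 0L) next
    ex <- exhaustiveSearch(cm)
    expect_identical(ex$nTrees, 15L)
    hs <- heuristicSearch(cm, nStarts = 5L, seed = rep)
    expect_equal(hs$score$L, ex$L, label = sprintf("rep %d", rep))
    expect_gte(hs$score$L, parsimonyBound(cm))
  }
})

test_that("search is reproducible under a fixed seed", {
  set.seed(47)
  seqs <- vapply(1:7, function(i)
    paste(sample(c("A", "C", "G"), 10L, TRUE), collapse = ""), "")
  names(seqs) <- sprintf("t%d", 1:7)
  cm <- characterMatrix(mkmat(seqs), "missing")
  r1 <- heuristicSearch(cm, nStarts = 2L, seed = 99L)
  r2 <- heuristicSearch(cm, nStarts = 2L, seed = 99L)
  expect_identical(r1$score$L, r2$score$L)
  expect_identical(ape::write.tree(r1$tree), ape::write.tree(r2$tree))
})

test_that("character matrices export as NEXUS with binary symbols", {
  m <- mkmat(c(t1 = "AC--T", t2 = "ACGTT", t3 = "CCGTT"))
  cm <- characterMatrix(m, "sic")
  f <- withr::local_tempfile(fileext = ".nex")
  writeCharacterMatrixNexus(cm, f)
  txt <- readLines(f)
  expect_true(any(grepl("SYMBOLS=\"A C G T 0 1\"", txt)))
  expect_true(any(grepl("NTAX=3", txt)))
})
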