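test_that("substitutions, indels and microsatellites are typed correctly", {
  # one differing column -> one substitution with both alleles
  a <- aln2(s1 = "AACGT", s2 = "AAAGT")
  cat1 <- scanVariableSites(a)
  expect_identical(nrow(cat1@events), 1L)
  expect_identical(cat1@events$kind, "substitution")
  expect_identical(cat1@events$cstart, 3L)
  expect_identical(eventAlleles(cat1)[[1L]], c("A", "C"))

  # a 43-column gap run is ONE indel event, not 43
  gap <- paste(rep("-", 43L), collapse = "")
  base <- paste(rep("A", 50L), collapse = "")
  withGap <- paste0("AAA", gap, paste(rep("A", 4L), collapse = ""))
  cat2 <- scanVariableSites(aln2(s1 = base, s2 = withGap))
  expect_identical(nrow(cat2@events), 1L)
  expect_identical(cat2@events$kind, "indel")
  expect_identical(cat2@events$cend - cat2@events$cstart + 1L, 43L)

  # declared TA window: repeat counts 6 vs 8, one event
  w <- 16L  # window width: up to 8 repeats
  s6 <- paste0("GG", strrep("TA", 6L), "----", "CC")
  s8 <- paste0("GG", strrep("TA", 8L), "CC")
  cat3 <- scanVariableSites(aln2(s1 = s6, s2 = s8),
                            list(microsatWindow("TA", "r1", 3L, 2L + w)))
  expect_identical(nrow(cat3@events), 1L)
  expect_identical(cat3@events$kind, "microsatellite")
  expect_setequal(eventAlleles(cat3)[[1L]], c("6", "8"))
})

test_that("gap runs with distinct endpoints are distinct events; nesting scores missing", {
  # spans 4-6 and 4-8 in different taxa
  a <- aln2(s1 = "ACGTTTTTCA", s2 = "ACG---TTCA", s3 = "ACG-----CA")
  cat <- scanVariableSites(a)
  ind <- cat@events[cat@events$kind == "indel", ]
  expect_identical(nrow(ind), 2L)
  st <- cat@states[, ind$id[ind$cend == 6L]]
  expect_identical(unname(st), c("0", "1", "?"))  # container scored missing
})

test_that("haplotype calling groups identical event-state vectors", {
  r <- htFromSeqs(c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT"),
                  populations = rep("p1", 4L))
  expect_identical(nrow(r$ht), 1L)
  expect_identical(unname(haplotypeCounts(r$ht)[1L, 1L]), 4L)

  r2 <- htFromSeqs(c(a = "AACC", b = "AACC", c = "CACC"),
                   populations = rep("p1", 3L))
  expect_identical(nrow(r2$ht), 2L)
  expect_identical(unname(sort(haplotypeCounts(r2$ht)[, 1L],
                               decreasing = TRUE)), c(2L, 1L))

  # repeat-count-only difference separates haplotypes; cross-check by
  # direct ungapped string comparison
  s6 <- paste0("GG", strrep("TA", 6L), "----")
  s8 <- paste0("GG", strrep("TA", 8L))
  r3 <- htFromSeqs(c(a = s6, b = s8, c = s8), populations = rep("p1", 3L),
                   microsat = list(microsatWindow("TA", "r1", 3L, 18L)))
  expect_identical(nrow(r3$ht), 2L)
  ungapped <- vapply(c(s6, s8, s8), function(s) gsub("-", "", s), "")
  expect_identical(length(unique(ungapped)), 2L)
})

test_that("ambiguous (N) individuals are excluded from counts with a report", {
  expect_message(
    r <- htFromSeqs(c(a = "AACC", b = "AACC", c = "CACC", d = "NACC"),
                    populations = rep("p1", 4L)),
    "ambiguous sample")
  expect_identical(S4Vectors::metadata(r$ht)$ambiguous, "d")
  expect_identical(sum(haplotypeCounts(r$ht)), 3L)
  expect_identical(unname(SummarizedExperiment::colData(r$ht)$n), 3L)
})

test_that("sharing report does set arithmetic on species presence", {
  # A = {H1, H2}, B = {H2, H3}
  r <- htFromSeqs(c(a1 = "AAAA", a2 = "AACA", b1 = "AACA", b2 = "AACC"),
                  populations = c("pA", "pA", "pB", "pB"),
                  species = c("A", "A", "B", "B"))
  sh <- summarizeSharing(r$ht)
  expect_identical(sh$total, 3L)
  expect_identical(sh$shared, 1L)
  expect_identical(unname(sh$exclusive[c("A", "B")]), c(1L, 1L))
  expect_identical(sh$total, sh$shared + sum(sh$exclusive))
})

test_that("haplotype partition is invariant under sample reordering", {
  set.seed(7)
  base <- strsplit("ACGTACGTACGTACGT", "")[[1L]]
  seqs <- vapply(1:8, function(i) {
    s <- base
    if (i %% 2L == 0L) s[3L] <- "T"
    if (i %% 3L == 0L) s[10L] <- "A"
    paste(s, collapse = "")
  }, "")
  names(seqs) <- sprintf("s%d", 1:8)
  part <- function(sq) {
    r <- htFromSeqs(sq, populations = rep("p1", length(sq)))
    a <- haplotypeAssignments(r$ht)
    split(a$sample, a$haplotype)
  }
  p1 <- part(seqs)
  p2 <- part(seqs[sample(8L)])
  canon <- function(p) unname(lapply(p, sort)[order(vapply(p, function(x)
    sort(x)[1L], ""))])
  expect_identical(canon(p1), canon(p2))
})

test_that("concatenated regions never yield fewer haplotypes than one region", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 6L
    m1 <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C"), 8L, TRUE), collapse = ""), "")
    m2 <- vapply(seq_len(n), function(i)
      paste(sample(c("G", "T"), 8L, TRUE), collapse = ""), "")
    names(m1) <- names(m2) <- sprintf("s%d", seq_len(n))
    a1 <- alignmentSet(m1, "rA"); a2 <- alignmentSet(m2, "rB")
    cc <- concatenateRegions(a1, a2)
    map <- data.frame(sample = names(m1), species = "sp", population = "p1")
    nHap <- function(a) nrow(callHaplotypes(scanVariableSites(a), map))
    expect_gte(nHap(cc), max(nHap(a1), nHap(a2)))
  }
})

test_that("haplotype representatives export as one FASTA record each", {
  r <- htFromSeqs(c(a = "AACC", b = "AACC", c = "CACC"),
                  populations = rep("p1", 3L))
  f <- withr::local_tempfile(fileext = ".fasta")
  haplotypeFasta(r$ht, r$aln, f)
  x <- Biostrings::readBStringSet(f)
  expect_identical(names(x), rownames(r$ht))
  expect_identical(as.character(x[["H01"]]), "AACC")
})
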