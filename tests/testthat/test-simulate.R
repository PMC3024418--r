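smallCfg <- function(...) {
  simConfig(islandN = 10L, mainlandN = rep(5L, 2L),
            regionLengths = c(rA = 300L, rB = 200L), msatWindowStart = 101L,
            ...)
}

test_that("identical config and seed give byte-identical datasets", {
  s1 <- simulateIslandMainland(77L, smallCfg())
  s2 <- simulateIslandMainland(77L, smallCfg())
  expect_identical(as.matrix(s1$aln), as.matrix(s2$aln))
  expect_identical(s1$truth, s2$truth)
  expect_false(identical(as.matrix(s1$aln),
                         as.matrix(simulateIslandMainland(78L, smallCfg())$aln)))
})

test_that("zero rates give a monomorphic sample with h = 0", {
  s <- simulateIslandMainland(3L, smallCfg(rateSub = 0, rateIndel = 0,
                                           rateMsat = 0))
  expect_identical(s$truth$nEvents, 0L)
  expect_true(all(s$truth$h == 0))
  expect_identical(length(unique(s$truth$haplotype)), 1L)
  catalog <- scanVariableSites(s$aln, s$microsat)
  expect_identical(nrow(catalog@events), 0L)
})

test_that("pairwise coalescence in one deme is exponential with mean 1", {
  set.seed(51)
  depths <- replicate(3000, {
    simulateGenealogy(c(a = "D", b = "D"), c(D = 1))$depth
  })
  expect_equal(mean(depths), 1, tolerance = 0.05)
  expect_equal(stats::var(depths), 1, tolerance = 0.12)
})

test_that("deep splits with no migration give reciprocal monophyly", {
  set.seed(53)
  mono <- replicate(60, {
    tips <- c(stats::setNames(rep("A", 5L), sprintf("a%d", 1:5)),
              stats::setNames(rep("B", 5L), sprintf("b%d", 1:5)))
    g <- simulateGenealogy(tips, c(A = 1, B = 1),
                           list(list(time = 50, from = c("A", "B"),
                                     to = "R", size = 1)))
    ape::is.monophyletic(g$tree, sprintf("a%d", 1:5))
  })
  expect_gte(mean(mono), 0.97)
})

test_that("emitted datasets validate and round-trip through the caller", {
  for (seed in c(101L, 202L, 303L)) {
    s <- simulateIslandMainland(seed, smallCfg())
    expect_true(validObject(s$aln))
    expect_silent(validateSampleMap(s$map, s$aln))
    expect_identical(unname(regionLengths(s$aln)), c(300L, 200L))
    catalog <- scanVariableSites(s$aln, s$microsat)
    # catalog recovers exactly the realized mutational events
    expect_identical(nrow(catalog@events), s$truth$nEvents)
    # haplotype calling reproduces the true partition
    ht <- callHaplotypes(catalog, s$map)
    called <- haplotypeAssignments(ht)
    truthHap <- s$truth$haplotype[called$sample]
    tab <- table(called$haplotype, truthHap)
    expect_true(all(rowSums(tab > 0L) == 1L) && all(colSums(tab > 0L) == 1L))
    # microsatellite repeat counts stay within the configured bounds
    expect_true(all(s$truth$repCounts >= 6L & s$truth$repCounts <= 15L))
  }
})

test_that("one substitution on a branch splits the sample in two", {
  cfg <- smallCfg(rateIndel = 0, rateMsat = 0, rateSub = 0.004)
  found <- FALSE
  for (seed in 1:40) {
    s <- simulateIslandMainland(seed, cfg)
    if (s$truth$nEvents == 1L) {
      expect_identical(length(unique(s$truth$haplotype)), 2L)
      carriers <- sum(s$truth$haplotype !=
                        s$truth$haplotype[[1L]])
      expect_gte(min(carriers, 20L - carriers), 1L)
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("truth statistics are recomputable from the emitted sequences", {
  s <- simulateIslandMainland(11L, smallCfg())
  catalog <- scanVariableSites(s$aln, s$microsat)
  ht <- callHaplotypes(catalog, s$map)
  asg <- haplotypeAssignments(ht)
  isl <- asg$sample[asg$species == "island_sp"]
  cnt <- table(asg$haplotype[asg$species == "island_sp"])
  expect_equal(unname(haplotypeDiversity(cnt)["h"]),
               unname(s$truth$h["island"]), tolerance = 1e-12)
  expect_equal(unname(nucleotideDiversity(s$aln, catalog, isl)["pi"]),
               unname(s$truth$pi["island"]), tolerance = 1e-12)
})

test_that("simulated datasets write out as plain-text files", {
  s <- simulateIslandMainland(5L, smallCfg())
  d <- withr::local_tempdir()
  writeSimulatedDataset(s, d)
  expect_true(all(file.exists(file.path(d, c("rA.fasta", "rB.fasta",
                                             "samples.tsv", "genealogy.nwk",
                                             "truth.json")))))
  back <- readAlignment(file.path(d, "rA.fasta"), "fasta", region = "rA")
  expect_identical(as.matrix(back), s$aln@regions$rA)
})

test_that("the preset reproduces the island/mainland diversity contrast", {
  share <- logical(100)
  win <- logical(100)
  for (r in 1:100) {
    tr <- simulateIslandMainland(60000L + r)$truth
    hap <- tr$haplotype
    isl <- startsWith(names(hap), "I")
    share[r] <- length(intersect(hap[isl], hap[!isl])) >= 1L
    win[r] <- tr$h["island"] > tr$h["mainland"]
  }
  expect_gte(mean(share), 0.80)
  expect_gte(mean(win), 0.85)
})

test_that("with equal deme sizes the diversity contrast disappears", {
  cfgEq <- simConfig(islandSize = 0.4, mainlandSplitTime = 0.001)
  win <- vapply(1:100, function(r) {
    tr <- simulateIslandMainland(70000L + r, cfgEq)$truth
    tr$h["island"] > tr$h["mainland"]
  }, logical(1L))
  expect_gte(mean(win), 0.35)
  expect_lte(mean(win), 0.65)
})
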