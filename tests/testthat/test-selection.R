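test_that("substitution classes are strand-symmetric over all 12 ordered pairs", {
  expect_equal(classifySNV("A", "G"), "AT>GC")
  expect_equal(classifySNV("T", "C"), "AT>GC")
  expect_equal(classifySNV("C", "T"), "GC>AT")
  expect_equal(classifySNV("A", "T"), "AT>TA")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (r in c("A", "C", "G", "T")) {
    for (a in setdiff(c("A", "C", "G", "T"), r)) {
      expect_equal(classifySNV(r, a),
                   classifySNV(comp[[r]], comp[[a]]))
    }
  }
  expect_error(classifySNV("A", "A"))
})

test_that("synonymous status translates the affected codon on either strand", {
  # + strand: ATG GGA TAA -> codon2 third base A>G is Gly>Gly
  g <- organelleGenome("plastid", paste0("CC", "ATGGGATGA", "CC"),
    annotation = GenomicRanges::GRanges("genome",
      IRanges::IRanges(3, 11), strand = "+",
      feature = "CDS", geneId = "g1", segment = 1L))
  expect_equal(synonymousStatus(g, 8, "G"), "synonymous")    # GGA>GGG
  expect_equal(synonymousStatus(g, 3, "G"), "nonsynonymous") # ATG>GTG
  expect_equal(synonymousStatus(g, 1, "G"), "not_CDS")
  # - strand: genomic GGAGGC read as GCCTCC; genomic G>A at the codon-1
  # third position (genomic pos 7) is GCC>GCT, synonymous
  gm <- organelleGenome("plastid", "AAAGGAGGCTTT",
    annotation = GenomicRanges::GRanges("genome",
      IRanges::IRanges(4, 9), strand = "-",
      feature = "CDS", geneId = "g1", segment = 1L))
  expect_equal(synonymousStatus(gm, 7, "A"), "synonymous")
  expect_equal(synonymousStatus(gm, 9, "T"), "nonsynonymous")
  # intron-split CDS concatenates exons for codon phase
  g2 <- organelleGenome("plastid", "AAAGGATTTGGCAAA",
    annotation = GenomicRanges::GRanges("genome",
      IRanges::IRanges(c(4, 7, 10), c(6, 9, 12)), strand = "+",
      feature = c("CDS", "intron", "CDS"), geneId = "g2",
      segment = c(1L, NA, 2L)))
  expect_equal(synonymousStatus(g2, 12, "T"), "synonymous")  # GGC>GGT
  expect_equal(synonymousStatus(g2, 8, "A"), "not_CDS")      # intron
})

test_that("permutation p-value matches exact enumeration on a 2-codon CDS", {
  # CDS GGA GGC: for GC>AT the eligible sites are the five G/C positions,
  # of which only the codon-2 third base (GGC>GGT) is synonymous
  g <- organelleGenome("plastid", "AAAGGAGGCTTT",
    annotation = GenomicRanges::GRanges("genome",
      IRanges::IRanges(4, 9), strand = "+",
      feature = "CDS", geneId = "g1", segment = 1L))
  cc <- data.frame(genomeId = "plastid", class = "GC>AT", count = 1)
  pExact <- 1 / 5
  r <- permutationTestSynonymous(list(plastid = g), cc, observedSyn = 1,
                                 nPerm = 10000, seed = 5)
  mcse <- sqrt(pExact * (1 - pExact) / 10000)
  expect_lt(abs(r$pValue - pExact), 3 * mcse)
  # degenerate null: every eligible placement synonymous -> p = 1
  gd <- organelleGenome("plastid", "GGAGGAGGA",
    annotation = GenomicRanges::GRanges("genome",
      IRanges::IRanges(1, 9), strand = "+",
      feature = "CDS", geneId = "g1", segment = 1L))
  ccd <- data.frame(genomeId = "plastid", class = "AT>GC", count = 2)
  expect_equal(permutationTestSynonymous(list(plastid = gd), ccd, 2,
                                         nPerm = 500, seed = 6)$pValue, 1)
  # observed 0 is never exceeded -> p = 1
  expect_equal(permutationTestSynonymous(list(plastid = g), cc, 0,
                                         nPerm = 500, seed = 7)$pValue, 1)
  # a class with no eligible site errors out by name
  ggOnly <- organelleGenome("plastid", "GGGGGGGGG",
    annotation = GenomicRanges::GRanges("genome",
      IRanges::IRanges(1, 9), strand = "+",
      feature = "CDS", geneId = "g1", segment = 1L))
  expect_error(permutationTestSynonymous(list(plastid = ggOnly),
    data.frame(genomeId = "plastid", class = "AT>GC", count = 1), 1,
    nPerm = 100, seed = 8), "AT>GC")
})

test_that("permutation p-values are reproducible and super-uniform under the null", {
  set.seed(81)
  ref <- makeSyntheticReference("plastid", 3000L, genicFraction = 0.6,
                                seed = 82)
  cc <- data.frame(genomeId = "plastid", class = c("AT>GC", "GC>AT"),
                   count = c(3, 2))
  r1 <- permutationTestSynonymous(list(plastid = ref), cc, 2, 500, seed = 9)
  r2 <- permutationTestSynonymous(list(plastid = ref), cc, 2, 500, seed = 9)
  expect_identical(r1$pValue, r2$pValue)
  # draw observed synonymous counts from the null mechanism, re-test,
  # and check P(p <= q) <= q + Monte-Carlo slack
  elig <- organelleMA:::cdsEligibility(ref)
  pSyn <- vapply(cc$class, function(k) {
    s <- elig[[paste0("syn.", k)]]
    mean(s[!is.na(s)])
  }, numeric(1))
  nRep <- 150
  ps <- vapply(seq_len(nRep), function(i) {
    obs <- rbinom(1, 3, pSyn[1]) + rbinom(1, 2, pSyn[2])
    permutationTestSynonymous(list(plastid = ref), cc, obs, 300,
                              seed = 100 + i)$pValue
  }, numeric(1))
  for (q in c(0.05, 0.5)) {
    expect_lte(mean(ps <= q), q + 3 * sqrt(q * (1 - q) / nRep))
  }
})

test_that("dispersion statistic matches its formula and points the right way", {
  # equal counts: variance < mean, statistic negative, p > 0.5
  d <- dispersionTest(rep(4, 10))
  expect_lt(d$statistic, 0)
  expect_gt(d$pValue, 0.5)
  expect_error(dispersionTest(rep(0, 5)), "zero")
  # brute-force recomputation on random count vectors
  set.seed(91)
  for (i in 1:100) {
    y <- rpois(sample(5:40, 1), runif(1, 0.5, 10))
    if (mean(y) == 0) next
    d <- dispersionTest(y)
    m <- mean(y)
    zBrute <- sum((y - m)^2 - y) / (m * sqrt(2 * length(y)))
    expect_equal(d$statistic, zBrute)
    expect_equal(d$pValue, pnorm(zBrute, lower.tail = FALSE))
  }
  # overdispersed counts are flagged
  set.seed(92)
  y <- rnbinom(50, size = 1, mu = 5)
  expect_lt(dispersionTest(y)$pValue, 0.05)
})

test_that("variant location summary counts features and synonymous changes", {
  g <- organelleGenome("plastid", paste0("CC", "ATGGGATGA", "CC",
                                         strrep("A", 7)),
    annotation = GenomicRanges::GRanges("genome",
      IRanges::IRanges(3, 11), strand = "+",
      feature = "CDS", geneId = "g1", segment = 1L))
  v <- rbind(
    variantRow("plastid", 8L, ref = "A", alt = "G"),    # CDS synonymous
    variantRow("plastid", 3L, ref = "A", alt = "G"),    # CDS nonsynonymous
    variantRow("plastid", 15L, ref = "A", alt = "G"))   # intergenic
  out <- genicFractionSummary(v, list(plastid = g))
  expect_equal(out$n[out$feature == "CDS"], 2L)
  expect_equal(out$synonymous[out$feature == "CDS"], 1L)
  expect_equal(out$n[out$feature == "intergenic"], 1L)
  empty <- genicFractionSummary(v[0, ], list(plastid = g))
  expect_true(all(empty$n == 0))
})

test_that("spectrum summary reports class counts, fractions, and GC balance", {
  v <- rbind(variantRow("plastid", 1L, ref = "A", alt = "G", altCount = 100),
             variantRow("plastid", 2L, ref = "T", alt = "C", altCount = 50),
             variantRow("plastid", 3L, ref = "G", alt = "A", altCount = 100))
  sm <- spectrumSummary(v)
  expect_equal(sm$byClass$n[sm$byClass$class == "AT>GC"], 2)
  expect_equal(sm$transitionFraction, 1.0)
  expect_equal(sm$gcGainWeighted, 1.5)
  expect_equal(sm$gcLossWeighted, 1.0)
  expect_true(all(spectrumSummary(v[0, ])$byClass$n == 0))
})

test_that("planted spectra are recovered within multinomial error", {
  ref <- makeSyntheticReference("plastid", 5000L, seed = 93)
  lines <- lineMetadata(nWT = 0, nMutant = 20, mutantGenerations = 7L)
  cfg <- simulationConfig(
    snvRate = c(mitochondrial = 2e-4, plastid = 2e-4),
    hpIndelRate = 0, dinucIndelRate = 0,
    mnvRate = c(mitochondrial = 0, plastid = 0))
  truth <- simulatePedigreeMutations(ref, lines, cfg, seed = 94)
  frac <- mean(truth$class == "AT>GC")
  n <- nrow(truth)
  expect_gt(n, 80)
  expect_lt(abs(frac - 0.83), 3 * sqrt(0.83 * 0.17 / n))
})

test_that("two-group count comparison supports the selectable tests", {
  set.seed(95)
  x <- rpois(20, 7)
  y <- rpois(20, 3.4)
  for (tst in c("wilcoxon", "t", "poisson")) {
    out <- compareLineCounts(x, y, tst)
    expect_lt(out$pValue, 0.05)
    expect_gt(out$meanX, out$meanY)
  }
})
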