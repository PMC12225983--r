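test_that("zero rates give an empty truth ledger for every line", {
  refs <- tinyRefPair()
  cfg <- simulationConfig(snvRate = c(mitochondrial = 0, plastid = 0),
                          mnvRate = c(mitochondrial = 0, plastid = 0),
                          hpIndelRate = 0, dinucIndelRate = 0)
  truth <- simulatePedigreeMutations(refs$mitochondrial, lineMetadata(),
                                     cfg, seed = 1)
  expect_equal(nrow(truth), 0L)
})

test_that("planted SNV counts follow the Poisson expectation", {
  ref <- makeSyntheticReference("mitochondrial", 4000L, seed = 5)
  lines <- lineMetadata(nWT = 0, nMutant = 1, mutantGenerations = 5L)
  r <- 2e-4  # per bp per generation, inflated for a countable toy
  cfg <- simulationConfig(snvRate = c(mitochondrial = r, plastid = r),
                          mnvRate = c(mitochondrial = 0, plastid = 0),
                          hpIndelRate = 0, dinucIndelRate = 0)
  set.seed(42)
  counts <- replicate(200, nrow(simulatePedigreeMutations(ref, lines, cfg)))
  lambda <- r * reducedLength(ref) * 5
  se <- sqrt(lambda / 200)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})

test_that("a bottleneck of one copy sorts every heteroplasmy to 0 or 1", {
  ref <- makeSyntheticReference("plastid", 3000L, seed = 6)
  lines <- lineMetadata(nWT = 0, nMutant = 4, mutantGenerations = 6L)
  cfg <- simulationConfig(snvRate = c(mitochondrial = 1e-4, plastid = 1e-4),
                          bottleneck = c(mitochondrial = 1, plastid = 1),
                          hpIndelRate = 0, dinucIndelRate = 0,
                          mnvRate = c(mitochondrial = 0, plastid = 0))
  truth <- simulatePedigreeMutations(ref, lines, cfg, seed = 9)
  born_before_last <- truth$originGen < 6L
  expect_true(all(truth$finalFreq[born_before_last] %in% c(0, 1)))
  expect_equal(truth$lost, truth$finalFreq == 0)
})

test_that("heteroplasmic sorting is unbiased (mean final frequency ~ initial)", {
  ref <- makeSyntheticReference("plastid", 3000L, seed = 6)
  lines <- lineMetadata(nWT = 0, nMutant = 30, mutantGenerations = 7L)
  cfg <- simulationConfig(snvRate = c(mitochondrial = 2e-4, plastid = 2e-4),
                          bottleneck = c(mitochondrial = 30, plastid = 30),
                          hpIndelRate = 0, dinucIndelRate = 0,
                          mnvRate = c(mitochondrial = 0, plastid = 0),
                          initialFreq = 0.5)
  truth <- simulatePedigreeMutations(ref, lines, cfg, seed = 10)
  expect_gt(nrow(truth), 80)
  se <- sd(truth$finalFreq) / sqrt(nrow(truth))
  expect_lt(abs(mean(truth$finalFreq) - 0.5), 3 * se)
})

test_that("identical seed and config reproduce the experiment exactly", {
  refs <- tinyRefPair()
  lines <- lineMetadata(nWT = 2, nMutant = 2)
  ex1 <- simulateExperiment(lines, refs, seed = 77)
  ex2 <- simulateExperiment(lines, refs, seed = 77)
  expect_identical(ex1$truth, ex2$truth)
  expect_identical(siteTable(ex1$tables$plastid[[1]]),
                   siteTable(ex2$tables$plastid[[1]]))
  expect_identical(indelTable(ex1$tables$mitochondrial[[3]]),
                   indelTable(ex2$tables$mitochondrial[[3]]))
})

test_that("count synthesis reflects planted frequencies and the error model", {
  ref <- organelleGenome("plastid", randomSeq(200, gc = 0.5))
  lines <- lineMetadata(nWT = 0, nMutant = 1, mutantGenerations = 1L)
  cfg <- simulationConfig(errorRate = 0, fixedDepth = TRUE,
                          meanDepth = 1000)
  # frequency-1 SNV with zero error: alt count equals depth
  truth <- data.frame(lineId = lines$lineId[1], genomeId = "plastid",
                      pos = 50L, ref = "?", alt = "A", type = "SNV",
                      class = "GC>AT", originGen = 1L, initFreq = 1,
                      finalFreq = 1, lost = FALSE,
                      stringsAsFactors = FALSE)
  s <- strsplit(as.character(genomeSequence(ref)), "")[[1]]
  truth$ref <- s[50]
  if (truth$ref == "A") truth$alt <- "G"
  tab <- synthesizeCounts(ref, truth, lines, cfg, seed = 3)[[1]]
  st <- siteTable(tab)
  expect_equal(st[[truth$alt]][50], 1000)
  expect_equal(st$depth[50], 1000)
  # frequency-0.5 SNV at constant depth 1000: binomial 99.9% interval
  truth$finalFreq <- 0.5
  tab <- synthesizeCounts(ref, truth, lines, cfg, seed = 4)[[1]]
  f <- siteTable(tab)[[truth$alt]][50] / 1000
  expect_lt(abs(f - 0.5), 3.3 * sqrt(0.25 / 1000))
})

test_that("numt contamination dilutes raw mitochondrial frequencies as expected", {
  nm <- IRanges::IRanges(1, 200)
  S4Vectors::mcols(nm)$copies <- 1L
  ref <- organelleGenome("mitochondrial", randomSeq(200), numtMap = nm)
  lines <- lineMetadata(nWT = 0, nMutant = 1, mutantGenerations = 1L)
  cfg <- simulationConfig(errorRate = 0, fixedDepth = TRUE, meanDepth = 80,
                          nuclearCoverage = 20)
  s <- strsplit(as.character(genomeSequence(ref)), "")[[1]]
  truth <- data.frame(lineId = lines$lineId[1], genomeId = "mitochondrial",
                      pos = 100L, ref = s[100],
                      alt = setdiff(c("A", "C", "G", "T"), s[100])[1],
                      type = "SNV", class = "AT>GC", originGen = 1L,
                      initFreq = 1, finalFreq = 1, lost = FALSE,
                      stringsAsFactors = FALSE)
  # copies 1, nuclear coverage 20, organelle depth 80, frequency 1:
  # expected raw frequency 80 / 100 = 0.8
  set.seed(11)
  fs <- replicate(40, {
    tab <- synthesizeCounts(ref, truth, lines, cfg)[[1]]
    st <- siteTable(tab)
    st[[truth$alt]][100] / st$depth[100]
  })
  expect_lt(abs(mean(fs) - 0.8), 0.02)
  # depth at every site gained ~20 numt reads
  tab <- synthesizeCounts(ref, truth, lines, cfg, seed = 12)[[1]]
  expect_gt(mean(siteTable(tab)$depth), 95)
})

test_that("fixtures round-trip and are byte-stable under a fixed seed", {
  refs <- tinyRefPair()
  lines <- lineMetadata(nWT = 2, nMutant = 2)
  ex <- simulateExperiment(lines, refs, seed = 3)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeFixture(d1, ex)
  writeFixture(d2, simulateExperiment(lines, refs, seed = 3))
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    if (grepl("gff3$", f)) next  # carries a date comment line
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  fx <- readFixture(d1)
  expect_equal(as.character(genomeSequence(fx$refs$mitochondrial)),
               as.character(genomeSequence(refs$mitochondrial)))
  expect_equal(IRanges::start(excludedRepeats(fx$refs$plastid)),
               IRanges::start(excludedRepeats(refs$plastid)))
  expect_equal(S4Vectors::mcols(numtMap(fx$refs$mitochondrial))$copies,
               S4Vectors::mcols(numtMap(refs$mitochondrial))$copies)
  expect_equal(fx$truth, ex$truth, ignore_attr = TRUE)
  expect_equal(siteTable(fx$tables$plastid[["M1-1"]]),
               siteTable(ex$tables$plastid[["M1-1"]]),
               ignore_attr = TRUE)
  expect_equal(indelTable(fx$tables$mitochondrial[["M2-1"]]),
               indelTable(ex$tables$mitochondrial[["M2-1"]]),
               ignore_attr = TRUE)
  ann1 <- annotationTrack(fx$refs$plastid)
  ann2 <- annotationTrack(refs$plastid)
  expect_equal(IRanges::start(ann1), IRanges::start(ann2))
  expect_equal(S4Vectors::mcols(ann1)$feature,
               S4Vectors::mcols(ann2)$feature)
})
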