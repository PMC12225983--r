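test_that("background profile is the per-allele mean across WT lines", {
  s <- strrep("A", 10)
  wt <- lapply(1:3, function(i)
    manualTable(paste0("W", i), "plastid", s, depth = 100,
                alt = data.frame(pos = 4L, base = "G",
                                 count = c(10L, 20L, 30L)[i])))
  names(wt) <- paste0("W", 1:3)
  bg <- computeBackground(wt)
  expect_equal(unname(bg$snv[4, "G"]), 0.2)
  expect_equal(unname(bg$snv[5, "G"]), 0)
  expect_equal(bg$nWT, 3L)
  expect_error(computeBackground(list()), "WT")
  # all-zero WT counts give a zero background
  wt0 <- lapply(wt, function(x)
    manualTable(lineId(x), "plastid", s, depth = 100))
  expect_true(all(computeBackground(wt0)$snv == 0))
})

test_that("candidate gates: frequency, depth, and background fold", {
  s <- strrep("A", 10)
  bg <- computeBackground(list(manualTable("W1", "plastid", s, 100)))
  # depth gate: 49x fails even at 90% frequency
  t1 <- manualTable("M1", "plastid", s, 49,
                    alt = data.frame(pos = 3L, base = "T", count = 44L))
  expect_equal(nrow(callCandidates(t1, bg)), 0L)
  # frequency gate at exactly 20%
  t2 <- manualTable("M1", "plastid", s, 100,
                    alt = data.frame(pos = c(3L, 5L), base = "T",
                                     count = c(19L, 20L)))
  v <- callCandidates(t2, bg)
  expect_equal(v$pos, 5L)
  expect_equal(v$rawFreq, 0.20)
  # background fold: freq 0.25 vs bg 0.10 fails, 0.31 passes
  wtbg <- manualTable("W1", "plastid", s, 100,
                      alt = data.frame(pos = 7L, base = "C", count = 10L))
  bg2 <- computeBackground(list(wtbg))
  t3 <- manualTable("M1", "plastid", s, 100,
                    alt = data.frame(pos = 7L, base = "C", count = 25L))
  expect_equal(nrow(callCandidates(t3, bg2)), 0L)
  t4 <- manualTable("M1", "plastid", s, 100,
                    alt = data.frame(pos = 7L, base = "C", count = 31L))
  expect_equal(nrow(callCandidates(t4, bg2)), 1L)
})

test_that("indel candidates are keyed by position, type, and allele", {
  s <- strrep("A", 12)
  bg <- computeBackground(list(manualTable("W1", "plastid", s, 100)))
  ind <- data.frame(pos = c(4L, 4L), type = c("ins", "del"),
                    allele = c("AA", "1"), count = c(30L, 10L),
                    stringsAsFactors = FALSE)
  tb <- manualTable("M1", "plastid", s, 100, indels = ind)
  v <- callCandidates(tb, bg)
  expect_equal(nrow(v), 1L)
  expect_equal(v$klass, "insertion")
  expect_equal(v$alt, "AA")
  expect_equal(v$rawFreq, 0.3)
})

test_that("raising thresholds never adds a call; lowering minFreq adds only low-frequency calls", {
  refs <- tinyRefPair()
  ex <- simulateExperiment(lineMetadata(nWT = 3, nMutant = 3), refs,
                           cfg = simulationConfig(
                             snvRate = c(mitochondrial = 2e-5,
                                         plastid = 2e-5)),
                           seed = 21)
  wt <- ex$lines$lineId[ex$lines$genotype == "WT"]
  bg <- computeBackground(ex$tables$plastid[wt])
  tb <- ex$tables$plastid[["M1-1"]]
  key <- function(v) paste(v$pos, v$klass, v$alt, v$ref)
  base <- callCandidates(tb, bg)
  for (args in list(list(minFreq = 0.3), list(minDepth = 400),
                    list(bgFold = 5))) {
    strict <- do.call(callCandidates, c(list(tb, bg), args))
    expect_true(all(key(strict) %in% key(base)))
  }
  loose <- callCandidates(tb, bg, minFreq = 0.10)
  added <- loose[!key(loose) %in% key(base), , drop = FALSE]
  expect_true(all(added$rawFreq >= 0.10 & added$rawFreq < 0.20))
})

test_that("excluded-repeat calls are removed with inclusive boundaries", {
  g <- organelleGenome("plastid", randomSeq(100),
                       excludedRepeats = IRanges::IRanges(40, 60))
  v <- rbind(variantRow("plastid", pos = 40L), variantRow("plastid", 50L),
             variantRow("plastid", 60L), variantRow("plastid", 61L),
             variantRow("plastid", 39L))
  out <- excludeRepeatCopies(v, g)
  expect_equal(sort(out$pos), c(39L, 61L))
  # brute-force membership oracle on a random variant set
  set.seed(31)
  pos <- sample(100, 50, replace = TRUE)
  vr <- do.call(rbind, lapply(pos, function(p) variantRow("plastid", p)))
  out <- excludeRepeatCopies(vr, g)
  expect_equal(out$pos, pos[!(pos >= 40 & pos <= 60)])
})

test_that("artefact contexts are excluded on either strand", {
  set.seed(41)
  s <- randomSeq(200)
  g <- organelleGenome("mitochondrial", s)
  x <- strsplit(s, "")[[1]]
  mkv <- function(p) variantRow("mitochondrial", p, ref = x[p],
                                alt = setdiff(c("A", "C", "G", "T"), x[p])[1])
  v <- do.call(rbind, lapply(c(30L, 60L, 90L, 120L, 150L, 50L, 80L, 110L,
                               140L, 170L), mkv))
  # plant the alt context of the first five variants inside artefact
  # junction sequences (one of them reverse-complemented)
  ctx <- vapply(1:5, function(i)
    organelleMA:::variantContext(v[i, ], g, 20L), character(1))
  ctx[3] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(ctx[3])))
  artefacts <- paste0(randomSeq(15), ctx, randomSeq(15))
  expect_equal(nrow(excludeStructuralArtifacts(v, character(), g)), 10L)
  out <- excludeStructuralArtifacts(v, artefacts, g)
  expect_equal(sort(out$pos), sort(v$pos[6:10]))
})

test_that("nuclear coverage estimation is (total - organelle) / genome size", {
  expect_equal(estimateNuclearCoverage(1.5e8, 1.5e8, 1.5e8), 0)
  expect_equal(estimateNuclearCoverage(3.0e8, 1.5e8, 1.5e8), 1.0)
  expect_equal(estimateNuclearCoverage(1e9, 2e8, 1.35e8),
               (1e9 - 2e8) / 1.35e8)
  expect_error(estimateNuclearCoverage(1e8, 2e8, 1.35e8), "exceed")
})

test_that("numt correction implements the subtract-and-recompute rule", {
  nm <- IRanges::IRanges(1, 50)
  S4Vectors::mcols(nm)$copies <- 1L
  g <- organelleGenome("mitochondrial", randomSeq(100), numtMap = nm)
  # alt 40, ref 60, depth 100, expected numt reads 20 -> 40/80 = 0.50
  v <- variantRow("mitochondrial", 10L, depth = 100, altCount = 40)
  out <- correctNumtFrequency(v, g, nuclearCoverage = 20)
  expect_equal(out$corrFreq, 0.5)
  expect_equal(out$rawFreq, 0.4)
  # clamping: alt 80, ref 20, expected 30 -> 80/80 = 1.0
  v2 <- variantRow("mitochondrial", 10L, depth = 100, altCount = 80)
  expect_equal(correctNumtFrequency(v2, g, 30)$corrFreq, 1.0)
  # pass-through outside the numt map and for zero coverage
  v3 <- variantRow("mitochondrial", 90L, depth = 100, altCount = 40)
  expect_equal(correctNumtFrequency(v3, g, 20)$corrFreq, 0.4)
  expect_equal(correctNumtFrequency(v, g, 0)$corrFreq, 0.4)
  # correction never lowers a frequency and never exceeds 1
  set.seed(51)
  for (i in 1:50) {
    depth <- sample(50:500, 1)
    altC <- sample(seq_len(depth), 1)
    vv <- variantRow("mitochondrial", sample(100, 1), depth = depth,
                     altCount = altC)
    cc <- correctNumtFrequency(vv, g, runif(1, 0, 60))
    expect_gte(cc$corrFreq, cc$rawFreq)
    expect_lte(cc$corrFreq, 1.0)
  }
  # degenerate coverage: flagged uncorrectable, frequency kept raw
  v4 <- variantRow("mitochondrial", 10L, depth = 100, altCount = 0)
  v4$rawFreq <- 0; v4$corrFreq <- 0
  out4 <- correctNumtFrequency(v4, g, nuclearCoverage = 1000)
  expect_true(out4$uncorrectable)
  expect_equal(out4$corrFreq, 0)
})

test_that("adjacent SNVs merge into MNVs with mean frequency, per line", {
  v <- rbind(
    variantRow("plastid", 10L, ref = "A", alt = "G", lineId = "M1",
               altCount = 40),
    variantRow("plastid", 11L, ref = "C", alt = "T", lineId = "M1",
               altCount = 60),
    variantRow("plastid", 11L, ref = "C", alt = "T", lineId = "M2"),
    variantRow("plastid", 20L, lineId = "M1"),
    variantRow("plastid", 22L, lineId = "M1"))
  out <- mergeMNV(v)
  mnv <- out[out$klass == "MNV", , drop = FALSE]
  expect_equal(nrow(mnv), 1L)
  expect_equal(mnv$lineId, "M1")
  expect_equal(mnv$ref, "AC")
  expect_equal(mnv$alt, "GT")
  expect_equal(mnv$rawFreq, 0.5)
  # the other line's SNV and the non-adjacent pair stay SNVs
  expect_equal(sum(out$klass == "SNV"), 3L)
  # insertion co-located with an SNV becomes a replacement MNV
  v2 <- rbind(variantRow("plastid", 10L, ref = "A", alt = "G"),
              variantRow("plastid", 10L, ref = "", alt = "T",
                         klass = "insertion"))
  out2 <- mergeMNV(v2)
  expect_equal(out2$klass, "MNV")
  expect_equal(out2$alt, "GT")
})

test_that("homoplasmy labels use 98% (plastid) and strictly >90% (mitochondrial)", {
  v <- rbind(variantRow("plastid", 1L), variantRow("plastid", 2L),
             variantRow("mitochondrial", 3L), variantRow("mitochondrial", 4L),
             variantRow("plastid", 5L))
  v$corrFreq <- c(0.98, 0.979, 0.90, 0.905, 0.50)
  z <- labelZygosity(v)$zygosity
  expect_equal(z, c("homoplasmic_candidate", "heteroplasmic",
                    "heteroplasmic", "homoplasmic_candidate",
                    "heteroplasmic"))
})

test_that("the full cascade is deterministic and empty on WT-only data", {
  refs <- tinyRefPair()
  lines <- lineMetadata(nWT = 4, nMutant = 0)
  ex <- simulateExperiment(lines, refs, seed = 61)
  v <- callPipeline(ex$tables$mitochondrial, ex$lines, ex$refs$mitochondrial,
                    readStats = ex$readStats)
  expect_equal(nrow(v), 0L)
  # determinism on a mutant fixture
  ex2 <- simulateExperiment(lineMetadata(nWT = 3, nMutant = 3), refs,
                            seed = 62)
  v1 <- callPipeline(ex2$tables$plastid, ex2$lines, ex2$refs$plastid,
                     readStats = ex2$readStats)
  v2 <- callPipeline(ex2$tables$plastid, ex2$lines, ex2$refs$plastid,
                     readStats = ex2$readStats)
  expect_identical(v1, v2)
})

test_that("the cascade recovers planted variants on a mutant fixture", {
  refs <- tinyRefPair()
  cfg <- simulationConfig(snvRate = c(mitochondrial = 3e-5, plastid = 3e-5))
  ex <- simulateExperiment(lineMetadata(nWT = 4, nMutant = 6), refs,
                           cfg = cfg, seed = 63)
  v <- rbind(
    callPipeline(ex$tables$mitochondrial, ex$lines, ex$refs$mitochondrial,
                 readStats = ex$readStats),
    callPipeline(ex$tables$plastid, ex$lines, ex$refs$plastid,
                 readStats = ex$readStats))
  wt <- ex$lines$lineId[ex$lines$genotype == "WT"]
  expect_equal(sum(v$lineId %in% wt), 0L)
  m <- matchCallsToTruth(v, ex$truth)
  hi <- m$truth$finalFreq >= 0.4
  expect_true(sum(hi) > 0)
  expect_equal(sum(m$truth$recovered[hi]), sum(hi))
  expect_equal(m$nFalse, 0L)
})
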