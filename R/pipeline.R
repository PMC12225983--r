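#' Background-normalized variant-frequency heatmap matrix
#'
#' One row per distinct passing variant allele (genome, position, allele),
#' one column per line; the value is the line's raw variant frequency
#' minus the mean WT background frequency at that position/allele, floored
#' at zero. Lines without a passing call at a site are zero. When no WT
#' variant passes filtering, the WT columns are all zero — the "empty WT
#' panel" appearance of an MA-line heatmap.
#'
#' @param variants Variant data.frame from [callPipeline()].
#' @param lineIds Column order (default: lines present in `variants`).
#' @return Numeric matrix with informative dimnames.
#' @export
buildHeatmap <- function(variants, lineIds = NULL) {
  if (is.null(lineIds)) lineIds <- unique(variants$lineId)
  key <- paste(variants$genomeId, variants$pos, variants$klass,
               variants$alt, sep = ":")
  rows <- unique(key)
  m <- matrix(0, nrow = length(rows), ncol = length(lineIds),
              dimnames = list(rows, lineIds))
  if (nrow(variants)) {
    val <- pmax(variants$rawFreq - variants$bgMean, 0)
    m[cbind(match(key, rows), match(variants$lineId, lineIds))] <- val
  }
  m
}

#' Run the full analysis pipeline on a synthetic experiment
#'
#' Orchestrates simulate -> call -> rates -> selection tests -> indel
#' analysis, optionally persisting every intermediate product (fixture
#' files, variant TSV/VCF, rate and test reports, heatmap matrix, summary
#' JSON) under `outdir`. All randomness flows from `seed`; two runs with
#' the same configuration and seed produce identical summaries.
#'
#' @param lines Line metadata ([lineMetadata()]).
#' @param refs Optional reference pair (generated when NULL).
#' @param cfg A [simulationConfig()].
#' @param seed Root seed (default `cfg$seed`).
#' @param outdir Output directory, or NULL to skip writing files.
#' @param artefactSeqs Character vector of artefact sequences for the
#'   exclusion filter.
#' @param minFreq,minDepth,bgFold,flankK Calling thresholds.
#' @param nPerm Permutations for the synonymous-enrichment test.
#' @return List with `experiment`, `variants`, `rates` (per genome),
#'   `spectrum`, `dispersion`, `permutation`, `indelSummary`, `heatmap`,
#'   `summary` (the JSON-ready summary list).
#' @export
runPipeline <- function(lines = lineMetadata(), refs = NULL,
                        cfg = simulationConfig(), seed = cfg$seed,
                        outdir = NULL, artefactSeqs = character(),
                        minFreq = 0.20, minDepth = 50L, bgFold = 3.0,
                        flankK = 20L, nPerm = 10000L) {
  ex <- simulateExperiment(lines, refs, cfg, seed = seed)
  if (!is.null(outdir)) writeFixture(file.path(outdir, "fixture"), ex)

  variants <- do.call(rbind, lapply(names(ex$refs), function(g) {
    callPipeline(ex$tables[[g]], ex$lines, ex$refs[[g]],
                 artefactSeqs = artefactSeqs, readStats = ex$readStats,
                 minFreq = minFreq, minDepth = minDepth, bgFold = bgFold,
                 flankK = flankK)
  }))
  mut <- ex$lines[ex$lines$genotype == "msh1", , drop = FALSE]
  N <- totalGenerations(mut)
  mutV <- variants[variants$lineId %in% mut$lineId, , drop = FALSE]

  rates <- lapply(ex$refs, function(ref) {
    g <- genomeId(ref)
    v <- mutV[mutV$genomeId == g, , drop = FALSE]
    list(snv = snvRate(v, reducedLength(ref), N),
         indel = indelRate(v, reducedLength(ref), N),
         spectrum = spectrumRates(v, ref, N))
  })

  perLine <- vapply(mut$lineId, function(ln)
    sum(mutV$lineId == ln & mutV$klass == "SNV"), numeric(1))
  dispersion <- if (sum(perLine) > 0) dispersionTest(perLine) else NULL

  # observed CDS substitutions by genome and class, for the permutation test
  cdsSnv <- do.call(rbind, lapply(names(ex$refs), function(g) {
    v <- mutV[mutV$genomeId == g & mutV$klass == "SNV", , drop = FALSE]
    if (!nrow(v)) return(NULL)
    feat <- as.character(classifyPosition(ex$refs[[g]], v$pos))
    v <- v[feat == "CDS", , drop = FALSE]
    if (!nrow(v)) return(NULL)
    v$class <- classifySNV(v$ref, v$alt)
    v$syn <- vapply(seq_len(nrow(v)), function(i)
      synonymousStatus(ex$refs[[g]], v$pos[i], v$alt[i]), character(1))
    v
  }))
  permutation <- NULL
  if (!is.null(cdsSnv) && nrow(cdsSnv)) {
    cc <- aggregate(list(count = cdsSnv$pos),
                    by = list(genomeId = cdsSnv$genomeId,
                              class = cdsSnv$class), FUN = length)
    permutation <- permutationTestSynonymous(
      ex$refs, cc, sum(cdsSnv$syn == "synonymous"), nPerm = nPerm,
      seed = seed + 1L)
  }

  indelSummary <- indelBiasSummary(mutV)
  heatmap <- buildHeatmap(variants, ex$lines$lineId)
  genic <- genicFractionSummary(mutV, ex$refs)
  spectrum <- spectrumSummary(mutV)

  summary <- list(
    seed = seed,
    thresholds = list(minFreq = minFreq, minDepth = minDepth,
                      bgFold = bgFold, flankK = flankK),
    nLines = nrow(ex$lines), nMutantGenerations = N,
    calls = list(
      total = nrow(variants),
      wt = sum(variants$lineId %in%
                 ex$lines$lineId[ex$lines$genotype == "WT"]),
      byGenome = lapply(split(mutV$klass, mutV$genomeId), table)),
    rates = lapply(rates, function(r) list(
      snvMu = r$snv$mu, snvV = r$snv$V,
      indelMu = r$indel$mu, indelCount = r$indel$V)),
    dispersionP = if (is.null(dispersion)) NA else dispersion$pValue,
    permutationP = if (is.null(permutation)) NA else permutation$pValue,
    transitionFraction = spectrum$transitionFraction,
    heatmapDims = dim(heatmap))

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    writeVariantTable(variants, file.path(outdir, "variants.tsv"))
    writeVariantVCF(variants, file.path(outdir, "variants.vcf"))
    write.table(genic, file.path(outdir, "genic_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(indelSummary$byContext,
                file.path(outdir, "indel_context.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(site = rownames(heatmap), heatmap,
                           check.names = FALSE),
                file.path(outdir, "heatmap.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_json(summary, file.path(outdir, "summary.json"),
               auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  }

  list(experiment = ex, variants = variants, rates = rates,
       spectrum = spectrum, genic = genic, dispersion = dispersion,
       permutation = permutation, indelSummary = indelSummary,
       heatmap = heatmap, summary = summary)
}

#' Match variant calls against a truth ledger
#'
#' A planted mutation is recovered when a call of the same line and genome
#' overlaps its position (SNVs additionally require the alternate allele,
#' possibly as part of a merged MNV; indels require matching type and
#' length/sequence). Calls matching no planted mutation are false
#' positives.
#'
#' @param variants Variant data.frame.
#' @param truth Truth ledger from [simulatePedigreeMutations()].
#' @return List with `truth` (ledger plus `recovered` column), `nFalse`
#'   (false-positive calls), `falseCalls`.
#' @export
matchCallsToTruth <- function(variants, truth) {
  matched <- rep(FALSE, nrow(variants))
  recovered <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    t <- truth[i, ]
    cand <- which(variants$lineId == t$lineId &
                    variants$genomeId == t$genomeId & !matched)
    hit <- integer()
    if (t$type %in% c("SNV", "MNV")) {
      span <- t$pos:(t$pos + nchar(t$ref) - 1L)
      for (j in cand) {
        if (variants$klass[j] %in% c("SNV", "MNV") &&
            any(variants$pos[j]:variants$end[j] %in% span)) {
          hit <- j; break
        }
      }
    } else if (t$type == "insertion") {
      hit <- cand[variants$klass[cand] == "insertion" &
                    variants$pos[cand] == t$pos &
                    variants$alt[cand] == t$alt][1]
    } else {
      hit <- cand[variants$klass[cand] == "deletion" &
                    variants$pos[cand] == t$pos &
                    variants$ref[cand] == as.character(nchar(t$ref))][1]
    }
    hit <- hit[!is.na(hit)]
    if (length(hit)) {
      matched[hit] <- TRUE
      recovered[i] <- TRUE
    }
  }
  truth$recovered <- recovered
  list(truth = truth, nFalse = sum(!matched),
       falseCalls = variants[!matched, , drop = FALSE])
}
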