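#' Compute the WT background error profile
#'
#' For every position and alternate allele (and every distinct indel
#' allele), the mean variant frequency across all WT lines. Low-complexity
#' regions such as long homopolymers produce elevated error frequencies in
#' every sample; candidate variants are later required to exceed a multiple
#' of this background, which is what empties the WT panels of a heatmap.
#'
#' Per-line frequency is count/depth, taken as 0 where depth is 0. The
#' profile is per-allele (not summed non-reference): a true variant in one
#' WT line then cannot mask a different alternate allele at the same site.
#'
#' @param wtTables List of [SiteCounts-class] from WT lines of one genome.
#' @return A `BackgroundProfile`: list with `genomeId`, `snv` (positions x
#'   4 matrix of mean frequencies), `indel` (data.frame `pos`, `type`,
#'   `allele`, `meanFreq`), `nWT`.
#' @export
computeBackground <- function(wtTables) {
  if (!length(wtTables)) stop("background is undefined without WT lines")
  gid <- unique(vapply(wtTables, genomeId, character(1)))
  stopifnot(length(gid) == 1L)
  bases <- c("A", "C", "G", "T")
  n <- length(wtTables)
  tab0 <- siteTable(wtTables[[1]])
  L <- nrow(tab0)
  snv <- matrix(0, nrow = L, ncol = 4L, dimnames = list(NULL, bases))
  indelAcc <- list()
  for (tb in wtTables) {
    tab <- siteTable(tb)
    stopifnot(nrow(tab) == L)
    d <- tab$depth
    for (b in bases) {
      f <- ifelse(d > 0, tab[[b]] / d, 0)
      snv[, b] <- snv[, b] + f
    }
    ind <- indelTable(tb)
    if (nrow(ind)) {
      dp <- d[match(ind$pos, tab$pos)]
      indelAcc[[length(indelAcc) + 1L]] <- data.frame(
        pos = ind$pos, type = ind$type, allele = ind$allele,
        freq = ifelse(dp > 0, ind$count / dp, 0), stringsAsFactors = FALSE)
    }
  }
  snv <- snv / n
  # the profile is defined for alternate alleles; the reference-base slot
  # is not a background and is kept at zero
  snv[cbind(seq_len(L), match(tab0$ref, bases))] <- 0
  indel <- data.frame(pos = integer(), type = character(),
                      allele = character(), meanFreq = numeric(),
                      stringsAsFactors = FALSE)
  if (length(indelAcc)) {
    acc <- do.call(rbind, indelAcc)
    key <- paste(acc$pos, acc$type, acc$allele)
    tot <- rowsum(acc$freq, key)
    first <- !duplicated(key)
    indel <- data.frame(pos = acc$pos[first], type = acc$type[first],
                        allele = acc$allele[first],
                        meanFreq = tot[key[first], 1] / n,
                        stringsAsFactors = FALSE)
  }
  structure(list(genomeId = gid, snv = snv, indel = indel, nWT = n),
            class = "BackgroundProfile")
}

#' Call candidate variants from one count table
#'
#' Threshold-based candidate detection: a (position, allele) pair is
#' emitted when its raw frequency is at least `minFreq`, the depth is at
#' least `minDepth`, and the frequency is at least `bgFold` times the WT
#' background mean for that allele (a zero background leaves only the
#' frequency and depth gates). Multiple alternate alleles at one site may
#' each be emitted. Indel alleles are keyed by left-aligned position and
#' inserted sequence / deleted length.
#'
#' @param table A [SiteCounts-class].
#' @param bg A `BackgroundProfile` from [computeBackground()].
#' @param minFreq Minimum raw variant frequency (default 0.20).
#' @param minDepth Minimum coverage depth (default 50).
#' @param bgFold Required fold over the WT background mean (default 3).
#' @return Variant data.frame with columns `lineId`, `genomeId`, `pos`,
#'   `end`, `ref`, `alt`, `klass` (SNV/insertion/deletion), `depth`,
#'   `altCount`, `rawFreq`, `bgMean`, `corrFreq`, `uncorrectable`.
#' @export
callCandidates <- function(table, bg, minFreq = 0.20, minDepth = 50L,
                           bgFold = 3.0) {
  stopifnot(minFreq > 0, minFreq <= 1, minDepth >= 1, bgFold >= 1)
  stopifnot(genomeId(table) == bg$genomeId)
  tab <- siteTable(table)
  bases <- c("A", "C", "G", "T")
  rows <- list()
  d <- tab$depth
  for (b in bases) {
    cnt <- tab[[b]]
    f <- ifelse(d > 0, cnt / d, 0)
    bgm <- bg$snv[, b]
    hit <- which(tab$ref != b & d >= minDepth & f >= minFreq &
                   f >= bgFold * bgm)
    if (length(hit))
      rows[[length(rows) + 1L]] <- data.frame(
        pos = tab$pos[hit], end = tab$pos[hit], ref = tab$ref[hit],
        alt = b, klass = "SNV", depth = d[hit], altCount = cnt[hit],
        rawFreq = f[hit], bgMean = bgm[hit], stringsAsFactors = FALSE)
  }
  ind <- indelTable(table)
  if (nrow(ind)) {
    dp <- d[match(ind$pos, tab$pos)]
    f <- ifelse(dp > 0, ind$count / dp, 0)
    key <- paste(ind$pos, ind$type, ind$allele)
    bgKey <- paste(bg$indel$pos, bg$indel$type, bg$indel$allele)
    bgm <- bg$indel$meanFreq[match(key, bgKey)]
    bgm[is.na(bgm)] <- 0
    hit <- which(dp >= minDepth & f >= minFreq & f >= bgFold * bgm)
    if (length(hit)) {
      isIns <- ind$type[hit] == "ins"
      dlen <- rep(0L, length(hit))
      dlen[!isIns] <- as.integer(ind$allele[hit][!isIns])
      rows[[length(rows) + 1L]] <- data.frame(
        pos = ind$pos[hit],
        end = ind$pos[hit] + pmax(dlen - 1L, 0L),
        ref = ifelse(isIns, "", ind$allele[hit]),
        alt = ifelse(isIns, ind$allele[hit], ""),
        klass = ifelse(isIns, "insertion", "deletion"),
        depth = dp[hit], altCount = ind$count[hit], rawFreq = f[hit],
        bgMean = bgm[hit], stringsAsFactors = FALSE)
    }
  }
  v <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pos = integer(), end = integer(), ref = character(),
               alt = character(), klass = character(), depth = integer(),
               altCount = numeric(), rawFreq = numeric(), bgMean = numeric(),
               stringsAsFactors = FALSE)
  v <- cbind(lineId = rep(lineId(table), nrow(v)),
             genomeId = rep(genomeId(table), nrow(v)), v,
             stringsAsFactors = FALSE)
  v$corrFreq <- v$rawFreq
  v$uncorrectable <- rep(FALSE, nrow(v))
  v <- v[order(v$pos, v$klass, v$alt), , drop = FALSE]
  rownames(v) <- NULL
  v
}

#' Remove calls inside excluded repeat copies
#'
#' Large organelle repeats interconvert by recombination and gene
#' conversion; calls in one copy of each repeat pair are removed so
#' variants are not double-counted (matching the reduced genome length used
#' as the rate denominator).
#'
#' @param variants Variant data.frame (see [callCandidates()]).
#' @param ref An [OrganelleGenome-class].
#' @return The surviving variants.
#' @export
excludeRepeatCopies <- function(variants, ref) {
  if (!nrow(variants)) return(variants)
  drop <- overlapsAny(IRanges(variants$pos, pmax(variants$end, variants$pos)),
                      excludedRepeats(ref))
  out <- variants[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

variantContext <- function(v, ref, k) {
  s <- as.character(genomeSequence(ref))
  L <- nchar(s)
  p <- v$pos
  refLen <- nchar(v$ref)
  if (v$klass == "insertion") {
    left <- substr(s, max(1L, p - k + 1L), p)
    right <- substr(s, p + 1L, min(L, p + k))
    paste0(left, v$alt, right)
  } else if (v$klass == "deletion") {
    left <- substr(s, max(1L, p - k), p - 1L)
    right <- substr(s, p + refLen, min(L, p + refLen + k - 1L))
    paste0(left, right)
  } else {
    left <- substr(s, max(1L, p - k), p - 1L)
    right <- substr(s, p + refLen, min(L, p + refLen + k - 1L))
    paste0(left, v$alt, right)
  }
}

#' Exclude structural-rearrangement and numt artefacts
#'
#' Reads from rearranged genomes (recombination between small imperfect
#' repeats) or from the numt can masquerade as de novo variants when mapped
#' to the reference. A variant is excluded when its alt-containing context
#' (k bp of reference flank on each side with the alternate allele
#' substituted) occurs exactly within any supplied artefact sequence, on
#' either strand.
#'
#' @param variants Variant data.frame.
#' @param artefactSeqs Character vector of artefact (junction / numt)
#'   sequences; empty vector leaves the variants unchanged.
#' @param ref An [OrganelleGenome-class].
#' @param k Flank length in bp (default 20, minimum 8).
#' @return The surviving variants.
#' @export
excludeStructuralArtifacts <- function(variants, artefactSeqs, ref, k = 20L) {
  stopifnot(k >= 8L)
  if (!nrow(variants) || !length(artefactSeqs)) return(variants)
  haystack <- c(artefactSeqs,
                as.character(reverseComplement(DNAStringSet(artefactSeqs))))
  drop <- vapply(seq_len(nrow(variants)), function(i) {
    ctx <- variantContext(variants[i, ], ref, k)
    any(vapply(haystack, function(h) grepl(ctx, h, fixed = TRUE),
               logical(1)))
  }, logical(1))
  out <- variants[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Estimate average nuclear genome coverage
#'
#' Coverage of the nuclear genome inferred from the read bases that did not
#' map to the organelle genomes, divided by the nuclear genome size. Used
#' to predict the number of numt-derived reads at each mitochondrial locus.
#'
#' @param totalReadBases Total sequenced bases for the line.
#' @param organelleMappedBases Bases mapped to the organelle genomes.
#' @param nuclearGenomeSize Nuclear genome size in bp.
#' @return Fold coverage (numeric).
#' @examples
#' estimateNuclearCoverage(1.5e8, 0, 1.5e8)  # 1x
#' @export
estimateNuclearCoverage <- function(totalReadBases, organelleMappedBases,
                                    nuclearGenomeSize) {
  stopifnot(nuclearGenomeSize > 0)
  if (any(organelleMappedBases > totalReadBases))
    stop("organelle-mapped bases exceed total read bases")
  (totalReadBases - organelleMappedBases) / nuclearGenomeSize
}

#' Correct mitochondrial variant frequencies for numt-derived reads
#'
#' The nuclear numt is nearly identical to the mitochondrial genome, so
#' even a homoplasmic mitochondrial variant still yields reference-allele
#' reads derived from the nuclear copy. The expected number of
#' nuclear-derived reads (`nuclearCoverage * copies`) is subtracted from
#' both the reference-allele count and the total coverage, and the variant
#' frequency is recalculated (capped at 1). The correction can only raise a
#' frequency. Plastid variants, indels, and sites with zero numt copies
#' pass through unchanged; a site whose corrected coverage would be
#' non-positive is flagged `uncorrectable` and keeps its raw frequency.
#'
#' @param variants Variant data.frame.
#' @param ref An [OrganelleGenome-class].
#' @param nuclearCoverage Fold nuclear coverage for this line (see
#'   [estimateNuclearCoverage()]); may be a single value or one per row.
#' @return Variants with `corrFreq` (and `uncorrectable`) updated.
#' @examples
#' v <- data.frame(lineId = "M1", genomeId = "mitochondrial", pos = 5L,
#'   end = 5L, ref = "A", alt = "G", klass = "SNV", depth = 100,
#'   altCount = 40, rawFreq = 0.4, bgMean = 0, corrFreq = 0.4,
#'   uncorrectable = FALSE)
#' nm <- IRanges::IRanges(1, 10); S4Vectors::mcols(nm)$copies <- 1L
#' g <- organelleGenome("mitochondrial", strrep("ACGTT", 4), numtMap = nm)
#' correctNumtFrequency(v, g, nuclearCoverage = 20)$corrFreq  # 0.5
#' @export
correctNumtFrequency <- function(variants, ref, nuclearCoverage) {
  if (!nrow(variants)) return(variants)
  stopifnot(all(nuclearCoverage >= 0))
  cp <- numtCopiesVector(ref)
  apply_to <- which(variants$genomeId == "mitochondrial" &
                      variants$klass %in% c("SNV", "MNV") &
                      cp[variants$pos] > 0)
  if (!length(apply_to)) return(variants)
  nc <- rep_len(nuclearCoverage, nrow(variants))
  for (i in apply_to) {
    expectedNumt <- nc[i] * cp[variants$pos[i]]
    refCount <- variants$depth[i] - variants$altCount[i]
    totalPrime <- variants$depth[i] - min(expectedNumt, refCount)
    if (totalPrime <= 0) {
      variants$uncorrectable[i] <- TRUE
      next
    }
    variants$corrFreq[i] <- min(variants$altCount[i] / totalPrime, 1.0)
  }
  variants
}

#' Merge adjacent substitutions into multi-nucleotide variants
#'
#' Within one line and genome, SNVs at adjacent positions are merged into a
#' single MNV whose raw/corrected frequencies are the means of the member
#' frequencies; an insertion co-located with an SNV at the same position
#' becomes a replacement-type MNV (single base pair replaced by a longer
#' allele). Members are removed from the SNV pool so MNVs are counted once.
#'
#' @param variants Variant data.frame.
#' @return Variants with merged MNV rows (`klass` "MNV").
#' @export
mergeMNV <- function(variants) {
  if (!nrow(variants)) return(variants)
  out <- list()
  for (grp in split(variants,
                    paste(variants$lineId, variants$genomeId))) {
    snv <- grp[grp$klass == "SNV", , drop = FALSE]
    other <- grp[grp$klass != "SNV", , drop = FALSE]
    used <- rep(FALSE, nrow(snv))
    if (nrow(snv) > 1L) {
      snv <- snv[order(snv$pos), , drop = FALSE]
      runGrp <- cumsum(c(1L, diff(snv$pos) != 1L))
      for (g in unique(runGrp)) {
        idx <- which(runGrp == g)
        if (length(idx) < 2L) next
        m <- snv[idx[1], , drop = FALSE]
        m$end <- snv$pos[idx[length(idx)]]
        m$ref <- paste(snv$ref[idx], collapse = "")
        m$alt <- paste(snv$alt[idx], collapse = "")
        m$klass <- "MNV"
        m$depth <- round(mean(snv$depth[idx]))
        m$altCount <- mean(snv$altCount[idx])
        m$rawFreq <- mean(snv$rawFreq[idx])
        m$bgMean <- mean(snv$bgMean[idx])
        m$corrFreq <- mean(snv$corrFreq[idx])
        m$uncorrectable <- any(snv$uncorrectable[idx])
        used[idx] <- TRUE
        out[[length(out) + 1L]] <- m
      }
    }
    snvLeft <- snv[!used, , drop = FALSE]
    # replacement-type MNV: insertion at the same position as an SNV
    if (nrow(snvLeft) && nrow(other)) {
      dropSnv <- integer()
      dropOther <- integer()
      for (i in which(other$klass == "insertion")) {
        j <- setdiff(which(snvLeft$pos == other$pos[i]), dropSnv)
        if (length(j) >= 1L) {
          j <- j[1]
          m <- snvLeft[j, , drop = FALSE]
          m$klass <- "MNV"
          m$alt <- paste0(m$alt, other$alt[i])
          m$rawFreq <- mean(c(m$rawFreq, other$rawFreq[i]))
          m$corrFreq <- mean(c(m$corrFreq, other$corrFreq[i]))
          m$altCount <- mean(c(m$altCount, other$altCount[i]))
          out[[length(out) + 1L]] <- m
          dropSnv <- c(dropSnv, j)
          dropOther <- c(dropOther, i)
        }
      }
      if (length(dropSnv)) snvLeft <- snvLeft[-dropSnv, , drop = FALSE]
      if (length(dropOther)) other <- other[-dropOther, , drop = FALSE]
    }
    out[[length(out) + 1L]] <- snvLeft
    out[[length(out) + 1L]] <- other
  }
  res <- do.call(rbind, out)
  res <- res[order(res$lineId, res$genomeId, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Label candidate homoplasmy
#'
#' Plastid variants at a corrected frequency of at least 0.98 are labelled
#' homoplasmic candidates; mitochondrial variants require a corrected
#' frequency strictly above 0.90 (the numt correction is approximate, so
#' the mitochondrial cutoff is more conservative). Everything else is
#' heteroplasmic. For indels the frequencies at homopolymers are too noisy
#' for the label to mean much; it is applied mechanically and should not be
#' interpreted.
#'
#' @param variants Variant data.frame with `corrFreq` set.
#' @return Variants with a `zygosity` column added.
#' @export
labelZygosity <- function(variants) {
  z <- rep("heteroplasmic", nrow(variants))
  pl <- variants$genomeId == "plastid" & variants$corrFreq >= 0.98
  mt <- variants$genomeId == "mitochondrial" & variants$corrFreq > 0.90
  z[pl | mt] <- "homoplasmic_candidate"
  variants$zygosity <- z
  variants
}

#' Run the full variant-calling cascade
#'
#' Composition of the filtering steps in order: candidate thresholds
#' (frequency, depth, WT background fold) -> excluded-repeat removal ->
#' structural/numt artefact exclusion -> numt frequency correction
#' (mitochondrial SNVs) -> MNV merging -> homoplasmy labelling -> indel
#' context assignment. The WT background is computed from the WT lines'
#' tables and applied to every line, including the WT lines themselves.
#'
#' @param tables List of [SiteCounts-class] for one genome (all lines).
#' @param lines Line metadata ([lineMetadata()]); used to identify WT lines.
#' @param ref The genome's [OrganelleGenome-class].
#' @param artefactSeqs Character vector of artefact sequences (may be
#'   empty).
#' @param nuclearCoverage Named per-line nuclear coverage, a single value,
#'   or NULL to derive it from `readStats`.
#' @param readStats Optional data.frame (`lineId`, `totalReadBases`,
#'   `mitoMappedBases`, `plastidMappedBases`).
#' @param minFreq,minDepth,bgFold Calling thresholds (defaults 0.20, 50, 3).
#' @param flankK Artefact-context flank length (default 20).
#' @return Combined variant data.frame across lines, with `zygosity` and
#'   `context` columns.
#' @export
callPipeline <- function(tables, lines, ref, artefactSeqs = character(),
                         nuclearCoverage = NULL, readStats = NULL,
                         minFreq = 0.20, minDepth = 50L, bgFold = 3.0,
                         flankK = 20L) {
  wtIds <- lines$lineId[lines$genotype == "WT"]
  bg <- computeBackground(tables[intersect(names(tables), wtIds)])
  if (is.null(nuclearCoverage)) {
    if (!is.null(readStats)) {
      org <- readStats$mitoMappedBases + readStats$plastidMappedBases
      nuclearCoverage <- setNames(
        estimateNuclearCoverage(readStats$totalReadBases, org,
                                nuclearGenomeSize(ref)),
        readStats$lineId)
    } else nuclearCoverage <- 0
  }
  res <- lapply(names(tables), function(ln) {
    v <- callCandidates(tables[[ln]], bg, minFreq, minDepth, bgFold)
    v <- excludeRepeatCopies(v, ref)
    v <- excludeStructuralArtifacts(v, artefactSeqs, ref, flankK)
    nc <- if (length(nuclearCoverage) > 1L) nuclearCoverage[[ln]]
          else nuclearCoverage
    v <- correctNumtFrequency(v, ref, nc)
    v
  })
  v <- do.call(rbind, res)
  v <- mergeMNV(v)
  v <- labelZygosity(v)
  v$context <- assignIndelContext(v, ref)
  rownames(v) <- NULL
  v
}
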