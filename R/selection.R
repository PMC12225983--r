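#' Classify a substitution into its strand-symmetric class
#'
#' Groups each of the 12 ordered base substitutions into one of six
#' strand-symmetric classes (A>G and its complement T>C are both AT>GC,
#' etc.), so spectra do not depend on which strand the reference reports.
#'
#' @param ref,alt Reference and alternate bases (vectors of single
#'   characters in A/C/G/T; `ref != alt`).
#' @return Character vector of classes, e.g. `"AT>GC"`.
#' @examples
#' classifySNV("A", "G")  # "AT>GC"
#' classifySNV("T", "C")  # "AT>GC"
#' @export
classifySNV <- function(ref, alt) {
  stopifnot(all(ref %in% c("A", "C", "G", "T")),
            all(alt %in% c("A", "C", "G", "T")), all(ref != alt))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # canonical representative: purine-pair notation via the A/G strand
  key <- ifelse(ref %in% c("A", "G"),
                paste0(ref, ">", alt),
                paste0(comp[ref], ">", comp[alt]))
  map <- c("A>G" = "AT>GC", "A>C" = "AT>CG", "A>T" = "AT>TA",
           "G>A" = "GC>AT", "G>T" = "GC>TA", "G>C" = "GC>CG")
  unname(map[key])
}

isTransition <- function(klass) klass %in% c("AT>GC", "GC>AT")

# Concatenated coding sequence and genomic-position map for one CDS gene.
# Segments are stored in transcription order in the `segment` column; minus
# strand genes are reverse-complemented.
codingMap <- function(ref, geneId) {
  ann <- annotationTrack(ref)
  cds <- ann[mcols(ann)$feature == "CDS" & mcols(ann)$geneId == geneId]
  cds <- cds[order(mcols(cds)$segment)]
  strand <- as.character(GenomicRanges::strand(cds))[1]
  s <- strsplit(as.character(genomeSequence(ref)), "")[[1]]
  pos <- unlist(lapply(seq_along(cds), function(i) {
    p <- start(cds)[i]:end(cds)[i]
    if (strand == "-") rev(p) else p
  }))
  base <- s[pos]
  if (strand == "-") base <- c(A = "T", C = "G", G = "C", T = "A")[base]
  list(pos = pos, base = unname(base), strand = strand)
}

#' Synonymous or nonsynonymous status of a substitution
#'
#' Translates the affected codon on the coding strand before and after the
#' substitution using the standard genetic code (plant organelle genes use
#' the standard code). Positions outside protein-coding sequence return
#' `"not_CDS"`.
#'
#' @param ref An [OrganelleGenome-class] with CDS annotation.
#' @param pos Genomic position (scalar).
#' @param altBase Alternate base at `pos` on the genomic (reference) strand.
#' @return `"synonymous"`, `"nonsynonymous"`, or `"not_CDS"`.
#' @export
synonymousStatus <- function(ref, pos, altBase) {
  ann <- annotationTrack(ref)
  cds <- ann[mcols(ann)$feature == "CDS"]
  hit <- which(start(cds) <= pos & end(cds) >= pos)
  if (!length(hit)) return("not_CDS")
  gid <- mcols(cds)$geneId[hit[1]]
  cm <- codingMap(ref, gid)
  i <- match(pos, cm$pos)
  codonIdx <- (i - 1L) %/% 3L
  codon <- cm$base[codonIdx * 3L + 1:3]
  altCoding <- if (cm$strand == "-")
    c(A = "T", C = "G", G = "C", T = "A")[altBase] else altBase
  codonAlt <- codon
  codonAlt[(i - 1L) %% 3L + 1L] <- unname(altCoding)
  aaRef <- GENETIC_CODE[paste(codon, collapse = "")]
  aaAlt <- GENETIC_CODE[paste(codonAlt, collapse = "")]
  if (is.na(aaRef) || is.na(aaAlt)) stop("codon contains non-ACGT base")
  if (aaRef == aaAlt) "synonymous" else "nonsynonymous"
}

# For every CDS site of a genome: genomic position, reference pair
# ("AT"/"GC"), and whether the substitution induced by each mutation class
# is synonymous. This is the eligibility table driving the permutation test.
cdsEligibility <- function(ref) {
  ann <- annotationTrack(ref)
  genes <- unique(mcols(ann)$geneId[mcols(ann)$feature == "CDS"])
  rows <- list()
  for (g in genes) {
    cm <- codingMap(ref, g)
    n <- length(cm$pos)
    if (n < 3L) next
    codons <- matrix(cm$base[seq_len(n - n %% 3L)], ncol = 3L, byrow = TRUE)
    aaRef <- GENETIC_CODE[paste0(codons[, 1], codons[, 2], codons[, 3])]
    df <- data.frame(pos = cm$pos[seq_len(nrow(codons) * 3L)],
                     codingBase = cm$base[seq_len(nrow(codons) * 3L)],
                     stringsAsFactors = FALSE)
    df$codon <- rep(seq_len(nrow(codons)), each = 3L)
    df$offset <- rep(1:3, nrow(codons))
    for (k in MUTATION_CLASSES) {
      src <- strsplit(substr(k, 1, 2), "")[[1]]
      eligible <- df$codingBase %in% src
      alt <- snvAltForClass(k, df$codingBase)
      syn <- rep(NA, nrow(df))
      idx <- which(eligible)
      if (length(idx)) {
        codAlt <- codons[df$codon[idx], , drop = FALSE]
        codAlt[cbind(seq_along(idx), df$offset[idx])] <- alt[idx]
        aaAlt <- GENETIC_CODE[paste0(codAlt[, 1], codAlt[, 2], codAlt[, 3])]
        syn[idx] <- aaAlt == aaRef[df$codon[idx]]
      }
      df[[paste0("syn.", k)]] <- syn
    }
    rows[[length(rows) + 1L]] <- df
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  # drop sites inside excluded repeats: no calls can arise there
  out[!overlapsAny(IRanges(out$pos, out$pos), excludedRepeats(ref)), ,
      drop = FALSE]
}

#' Spectrum-preserving permutation test for synonymous-site enrichment
#'
#' Keeps the number and strand-symmetric type of the observed CDS
#' substitutions fixed but randomizes their positions uniformly over the
#' eligible CDS sites of their own genome (sites whose reference pair
#' matches the class source; the substituted base follows from the class
#' and the site's base). Each permutation yields a total synonymous count
#' pooled across genomes; the one-tailed p-value is the frequency of
#' permutations with a count greater than or equal to the observed number
#' of synonymous substitutions. A small p would indicate an enrichment of
#' synonymous variants, i.e. selection against amino-acid-changing
#' mutations.
#'
#' @param refs Named list of [OrganelleGenome-class] objects.
#' @param classCounts data.frame with columns `genomeId`, `class`, `count`:
#'   the observed CDS substitutions per genome and class.
#' @param observedSyn Observed total synonymous count.
#' @param nPerm Number of permutations (default 10000).
#' @param seed Optional seed.
#' @return List of class `PermutationResult`: `observedSynonymous`,
#'   `nPerm`, `nullCounts` (table of the null distribution), `pValue`,
#'   `pLabel` (`"< 1/nPerm"` when no permutation reached the observed
#'   count), `seed`.
#' @export
permutationTestSynonymous <- function(refs, classCounts, observedSyn,
                                      nPerm = 10000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(c("genomeId", "class", "count") %in% names(classCounts)))
  classCounts <- classCounts[classCounts$count > 0, , drop = FALSE]
  nullSyn <- integer(nPerm)
  for (g in unique(classCounts$genomeId)) {
    elig <- cdsEligibility(refs[[g]])
    cc <- classCounts[classCounts$genomeId == g, , drop = FALSE]
    for (i in seq_len(nrow(cc))) {
      k <- cc$class[i]
      syn <- elig[[paste0("syn.", k)]]
      syn <- syn[!is.na(syn)]
      if (!length(syn))
        stop(sprintf("no eligible CDS sites for class %s in %s genome",
                     k, g))
      draws <- matrix(sample(syn, nPerm * cc$count[i], replace = TRUE),
                      nrow = nPerm)
      nullSyn <- nullSyn + as.integer(rowSums(draws))
    }
  }
  p <- mean(nullSyn >= observedSyn)
  structure(list(observedSynonymous = observedSyn, nPerm = nPerm,
                 nullCounts = table(nullSyn), pValue = p,
                 pLabel = if (p == 0) sprintf("< %g", 1 / nPerm)
                          else format(p),
                 seed = seed),
            class = "PermutationResult")
}

#' @export
print.PermutationResult <- function(x, ...) {
  cat(sprintf("Permutation test (n = %d): observed synonymous = %d, P = %s\n",
              x$nPerm, x$observedSynonymous, x$pLabel))
  invisible(x)
}

#' Poisson overdispersion test on per-line variant counts
#'
#' Cameron-Trivedi score test for overdispersion under a
#' variance-proportional-to-mean alternative (`var = (1 + a) * mean`),
#' the default of the AER `dispersiontest`:
#' `z = sum((y - ybar)^2 - y) / (ybar * sqrt(2 n))`, compared to a
#' standard normal, one-sided for `a > 0`. Also reports the
#' auxiliary-regression formulation (`t` statistic of the intercept-only
#' regression of `((y - ybar)^2 - y) / (ybar * sqrt(2))`) as a
#' cross-check. MA lines whose counts are consistent with a Poisson
#' distribution behaved as independent accumulators of mutations.
#'
#' @param counts Per-line variant counts (length >= 2, not all zero).
#' @return List of class `DispersionResult`: `counts`, `mean`, `variance`,
#'   `statistic`, `statisticAux`, `pValue` (one-sided, overdispersion).
#' @export
dispersionTest <- function(counts) {
  stopifnot(length(counts) >= 2)
  m <- mean(counts)
  if (m == 0) stop("dispersion is undefined when all counts are zero")
  n <- length(counts)
  z <- sum((counts - m)^2 - counts) / (m * sqrt(2 * n))
  # studentized intercept-only auxiliary regression (equivalent to the
  # lm t statistic); NaN when the aux responses are constant
  aux <- ((counts - m)^2 - counts) / (m * sqrt(2))
  zAux <- if (sd(aux) > 0) sqrt(n) * mean(aux) / sd(aux) else NaN
  structure(list(counts = counts, mean = m, variance = var(counts),
                 statistic = z, statisticAux = zAux,
                 pValue = pnorm(z, lower.tail = FALSE)),
            class = "DispersionResult")
}

#' @export
print.DispersionResult <- function(x, ...) {
  cat(sprintf("Overdispersion test: mean = %.3g, var = %.3g, z = %.3f, one-sided P = %.3g\n",
              x$mean, x$variance, x$statistic, x$pValue))
  invisible(x)
}

#' Variant counts by genomic feature class
#'
#' Tabulates SNVs (and MNVs) by the feature class of their position (CDS,
#' rRNA, tRNA, intron, intergenic), with a synonymous sub-count for CDS
#' SNVs, per genome. Comparing the genic fraction of variants with the
#' genic fraction of the genome is a coarse test for selection during MA
#' propagation.
#'
#' @param variants Variant data.frame.
#' @param refs Named list of [OrganelleGenome-class].
#' @return data.frame with columns `genomeId`, `feature`, `n`,
#'   `synonymous` (NA outside CDS).
#' @export
genicFractionSummary <- function(variants, refs) {
  feats <- c("CDS", "rRNA", "tRNA", "intron", "intergenic")
  out <- list()
  for (g in names(refs)) {
    v <- variants[variants$genomeId == g &
                    variants$klass %in% c("SNV", "MNV"), , drop = FALSE]
    cls <- if (nrow(v)) as.character(classifyPosition(refs[[g]], v$pos))
           else character()
    nSyn <- 0L
    snvCds <- which(cls == "CDS" & v$klass == "SNV")
    for (i in snvCds)
      if (synonymousStatus(refs[[g]], v$pos[i], v$alt[i]) == "synonymous")
        nSyn <- nSyn + 1L
    cnt <- table(factor(cls, levels = feats))
    out[[g]] <- data.frame(genomeId = g, feature = feats,
                           n = as.integer(cnt),
                           synonymous = ifelse(feats == "CDS", nSyn, NA),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mutation-spectrum summary
#'
#' Per-class SNV counts and fractions, the transition fraction, and the
#' frequency-weighted GC-gaining vs GC-losing sums.
#'
#' @param variants Variant data.frame (SNV rows are used).
#' @return List with `byClass` (data.frame `class`, `n`, `fraction`,
#'   `weighted`), `transitionFraction`, `gcGainWeighted`, `gcLossWeighted`.
#' @export
spectrumSummary <- function(variants) {
  snv <- variants[variants$klass == "SNV", , drop = FALSE]
  kl <- if (nrow(snv)) classifySNV(snv$ref, snv$alt) else character()
  n <- vapply(MUTATION_CLASSES, function(k) sum(kl == k), numeric(1))
  w <- vapply(MUTATION_CLASSES, function(k) sum(snv$corrFreq[kl == k]),
              numeric(1))
  tot <- sum(n)
  byClass <- data.frame(class = MUTATION_CLASSES, n = unname(n),
                        fraction = unname(if (tot > 0) n / tot else n * 0),
                        weighted = unname(w), stringsAsFactors = FALSE)
  list(byClass = byClass,
       transitionFraction = if (tot > 0)
         sum(n[c("AT>GC", "GC>AT")]) / tot else NA_real_,
       gcGainWeighted = unname(w["AT>GC"] + w["AT>CG"]),
       gcLossWeighted = unname(w["GC>AT"] + w["GC>TA"]))
}

#' Two-sample comparison of per-line variant counts
#'
#' Generic utility for comparing per-line counts between two groups (for
#' example nuclear SNV counts in mutant vs WT lines). The test is
#' selectable since different count comparisons warrant different
#' assumptions.
#'
#' @param x,y Numeric count vectors for the two groups.
#' @param test `"wilcoxon"` (default), `"t"`, or `"poisson"` (Poisson GLM
#'   Wald test on a group effect).
#' @return List with `meanX`, `meanY`, `pValue`, `test`.
#' @export
compareLineCounts <- function(x, y, test = c("wilcoxon", "t", "poisson")) {
  test <- match.arg(test)
  p <- switch(test,
    wilcoxon = wilcox.test(x, y, exact = FALSE)$p.value,
    t = t.test(x, y)$p.value,
    poisson = {
      df <- data.frame(n = c(x, y),
                       grp = rep(c("x", "y"), c(length(x), length(y))))
      fit <- glm(n ~ grp, family = "poisson", data = df)
      coef(summary(fit))["grpy", "Pr(>|z|)"]
    })
  list(meanX = mean(x), meanY = mean(y), pValue = p, test = test)
}
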