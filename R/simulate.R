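#' Simulation configuration for synthetic MA experiments
#'
#' Bundles every parameter of the synthetic-data generator: mutation input
#' (per-class SNV rates, MNV rate, per-locus homopolymer and dinucleotide
#' indel rates with insertion/deletion bias), heteroplasmic sorting
#' (per-generation transmission bottleneck per organelle), the sequencing
#' model (depth distribution, base error rate, homopolymer error inflation),
#' and the numt contamination model (nuclear coverage).
#'
#' Defaults are set to the conditions of an *msh1*-type MA experiment:
#' total SNV rates of 6.1e-7 (mitochondrial) and 3.2e-6 (plastid) per bp per
#' generation, spectra dominated by AT>GC and GC>AT transitions (plastid
#' strongly GC-biased, mitochondrial GC-neutral), deletion-biased A/T and
#' insertion-biased G/C homopolymer indels, a smaller plastid than
#' mitochondrial bottleneck (faster plastid sorting), and wild-type rates of
#' zero. Sequencing-error rates at a homopolymer of length `len` are
#' inflated to `errorRate * hpErrorFactor * (len - hpMinLen + 1)^hpErrorExponent`,
#' capped at `hpErrorCap`, with fraction `indelErrorFraction` of that rate
#' manifesting as length-1 indel errors at the run.
#'
#' @param snvRate Named total SNV rate per bp per generation for mutant
#'   lines, per genome.
#' @param snvSpectrum List of per-genome named class weights over the six
#'   strand-symmetric classes (normalized internally).
#' @param mnvRate Named MNV rate per bp per generation.
#' @param hpIndelRate Homopolymer indel rate per locus per generation.
#' @param dinucIndelRate Dinucleotide-repeat indel rate per locus per
#'   generation.
#' @param insBias Probability that a repeat-locus mutation is an insertion,
#'   by run class.
#' @param indelLengthProbs Probabilities of 1..4 repeat-unit changes.
#' @param initialFreq Heteroplasmic frequency at which a new germline
#'   mutation enters.
#' @param bottleneck Named per-generation variance-effective bottleneck size
#'   (organelle genome copies) per genome.
#' @param wtSnvRate,wtHpIndelRate Rates applied to WT lines (default 0).
#' @param meanDepth,depthDispersion,fixedDepth Sequencing depth model:
#'   negative binomial with mean `meanDepth` and size `depthDispersion`, or
#'   constant `meanDepth` when `fixedDepth = TRUE`.
#' @param errorRate Baseline per-base sequencing error rate.
#' @param hpErrorFactor,hpErrorExponent,hpErrorCap,hpMinLen,indelErrorFraction
#'   Homopolymer error-inflation model (see Description).
#' @param nuclearCoverage Mean nuclear genome coverage; numt-derived
#'   reference reads are added to mitochondrial tables at
#'   `nuclearCoverage * copies` expected reads per site.
#' @param founderFreq Frequency at which an optional shared founder mutation
#'   is planted (see [simulatePedigreeMutations()]).
#' @param seed Root random seed.
#' @return A list of class `SimulationConfig`.
#' @export
simulationConfig <- function(
    snvRate = c(mitochondrial = 6.1e-7, plastid = 3.2e-6),
    snvSpectrum = list(
      mitochondrial = c("AT>GC" = 0.47, "GC>AT" = 0.43, "AT>CG" = 0.02,
                        "GC>TA" = 0.04, "AT>TA" = 0.02, "GC>CG" = 0.02),
      plastid = c("AT>GC" = 0.83, "GC>AT" = 0.08, "AT>CG" = 0.02,
                  "GC>TA" = 0.03, "AT>TA" = 0.02, "GC>CG" = 0.02)),
    mnvRate = c(mitochondrial = 1.2e-8, plastid = 6.4e-8),
    hpIndelRate = 2e-3,
    dinucIndelRate = 5e-5,
    insBias = c("A/T" = 0.35, "G/C" = 0.60),
    indelLengthProbs = c(0.90, 0.06, 0.03, 0.01),
    initialFreq = 0.5,
    bottleneck = c(mitochondrial = 50, plastid = 20),
    wtSnvRate = c(mitochondrial = 0, plastid = 0),
    wtHpIndelRate = 0,
    meanDepth = 500,
    depthDispersion = 8,
    fixedDepth = FALSE,
    errorRate = 0.002,
    hpErrorFactor = 20,
    hpErrorExponent = 1,
    hpErrorCap = 0.4,
    hpMinLen = 5L,
    indelErrorFraction = 0.8,
    nuclearCoverage = 40,
    founderFreq = 0.143,
    seed = 1L) {
  cfg <- as.list(environment())
  cfg$snvSpectrum <- lapply(cfg$snvSpectrum, function(w) {
    stopifnot(all(names(w) %in% MUTATION_CLASSES), all(w >= 0))
    w[MUTATION_CLASSES] / sum(w)
  })
  stopifnot(all(cfg$snvRate >= 0), all(cfg$mnvRate >= 0),
            cfg$hpIndelRate >= 0, cfg$dinucIndelRate >= 0,
            cfg$initialFreq >= 0, cfg$initialFreq <= 1,
            all(cfg$bottleneck >= 1),
            sum(cfg$indelLengthProbs) > 0)
  cfg$indelLengthProbs <- cfg$indelLengthProbs / sum(cfg$indelLengthProbs)
  class(cfg) <- "SimulationConfig"
  cfg
}

#' MA line metadata
#'
#' Builds the per-line metadata table for an experiment: line identifier,
#' genotype (WT or msh1), founder family, and the number of homozygous
#' generations contributing mutations. Defaults mirror a design with 22
#' msh1 lines (18 lines at 7 generations and 4 at 6, i.e. 150 mutant
#' generations) from three founder families, and 20 WT control lines at 8
#' generations each.
#'
#' @param nWT Number of WT lines.
#' @param nMutant Number of msh1 mutant lines.
#' @param wtGenerations Generations per WT line.
#' @param mutantGenerations Vector of generations recycled over mutant lines
#'   (default: 18 sevens then 4 sixes).
#' @param nFamilies Founder families per genotype.
#' @return data.frame with columns `lineId`, `genotype`, `founder`,
#'   `generations`.
#' @examples
#' lines <- lineMetadata()
#' sum(lines$generations[lines$genotype == "msh1"])  # 150
#' @export
lineMetadata <- function(nWT = 20L, nMutant = 22L, wtGenerations = 8L,
                         mutantGenerations = c(rep(7L, 18L), rep(6L, 4L)),
                         nFamilies = 3L) {
  mutantGenerations <- rep_len(mutantGenerations, nMutant)
  mk <- function(prefix, n, gens, genotype) {
    if (n == 0L)
      return(data.frame(lineId = character(), genotype = character(),
                        founder = character(), generations = integer(),
                        stringsAsFactors = FALSE))
    fam <- paste0(prefix, rep_len(seq_len(nFamilies), n))
    data.frame(
      lineId = paste0(fam, "-", stats::ave(seq_len(n), fam, FUN = seq_along)),
      genotype = genotype, founder = fam, generations = gens,
      stringsAsFactors = FALSE)
  }
  rbind(mk("W", nWT, wtGenerations, "WT"),
        mk("M", nMutant, mutantGenerations, "msh1"))
}

#' Generate a synthetic organelle reference genome
#'
#' Random reference with the hallmarks the analysis depends on: a nucleotide
#' composition matching the organelle (GC-neutral mitochondrial vs AT-rich
#' plastid, which yields abundant A/T homopolymers), one excluded
#' large-repeat interval, a gene annotation covering a configurable genic
#' fraction (CDS with occasional introns, rRNA, tRNA), and, for
#' mitochondrial genomes, a numt copy map covering most of the genome at one
#' copy plus a smaller two-copy region.
#'
#' @param genomeId "mitochondrial" or "plastid".
#' @param length Genome length in bp (defaults: 50 kb mitochondrial,
#'   20 kb plastid).
#' @param gcContent GC fraction (defaults 0.45 / 0.35).
#' @param genicFraction Target fraction of the genome covered by genes
#'   (defaults 0.10 / 0.59).
#' @param repeatFraction Fraction covered by the excluded repeat interval.
#' @param numt Add the default numt map (mitochondrial only).
#' @param nuclearGenomeSize Nuclear genome size in bp.
#' @param seed Optional seed (set only when non-NULL).
#' @return An [OrganelleGenome-class].
#' @export
makeSyntheticReference <- function(genomeId,
                                   length = if (genomeId == "mitochondrial") 50000L else 20000L,
                                   gcContent = if (genomeId == "mitochondrial") 0.45 else 0.35,
                                   genicFraction = if (genomeId == "mitochondrial") 0.10 else 0.59,
                                   repeatFraction = 0.05,
                                   numt = genomeId == "mitochondrial",
                                   nuclearGenomeSize = 1.35e8,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- as.integer(length)
  p <- c((1 - gcContent) / 2, gcContent / 2, gcContent / 2, (1 - gcContent) / 2)
  s <- sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = p)
  repW <- max(0L, as.integer(L * repeatFraction))
  er <- if (repW > 0) IRanges(as.integer(L * 0.08), width = repW) else IRanges()
  ann <- makeSyntheticAnnotation(genomeId, s, er, genicFraction)
  nm <- IRanges()
  if (numt) {
    nm <- IRanges(c(1L, as.integer(L * 0.70)),
                  c(as.integer(L * 0.55), as.integer(L * 0.80)))
    mcols(nm)$copies <- c(1L, 2L)
  }
  organelleGenome(genomeId, paste(s, collapse = ""),
                  excludedRepeats = er, numtMap = nm,
                  nuclearGenomeSize = nuclearGenomeSize, annotation = ann)
}

# Place non-overlapping genes outside the excluded repeat until the target
# genic fraction is reached. CDS genes occasionally carry one intron; the
# two CDS segments keep a concatenated length divisible by 3.
makeSyntheticAnnotation <- function(genomeId, s, er, genicFraction) {
  L <- length(s)
  target <- genicFraction * L
  rows <- list()
  cursor <- 2L
  genic <- 0
  gene <- 0L
  exStart <- if (length(er)) start(er)[1] else Inf
  exEnd <- if (length(er)) end(er)[1] else -Inf
  while (genic < target && cursor < L - 2500L) {
    cursor <- cursor + sample(30:400, 1L)
    feat <- sample(c("CDS", "rRNA", "tRNA"), 1L, prob = c(0.6, 0.2, 0.2))
    glen <- switch(feat,
                   CDS = 3L * sample(60:400, 1L),
                   rRNA = sample(300:1200, 1L),
                   tRNA = sample(70:90, 1L))
    intron <- feat == "CDS" && runif(1) < 0.3
    ilen <- if (intron) sample(80:300, 1L) else 0L
    span <- glen + ilen
    # skip past the excluded repeat rather than overlapping it
    if (cursor <= exEnd && cursor + span - 1L >= exStart)
      cursor <- exEnd + sample(30:200, 1L)
    if (cursor + span - 1L > L) break
    gene <- gene + 1L
    gid <- sprintf("%s_g%03d", substr(genomeId, 1, 2), gene)
    strand <- sample(c("+", "-"), 1L)
    if (intron) {
      l1 <- 3L * sample(20L:(glen %/% 3L - 20L), 1L)
      seg1 <- c(cursor, cursor + l1 - 1L)
      intr <- c(seg1[2] + 1L, seg1[2] + ilen)
      seg2 <- c(intr[2] + 1L, cursor + span - 1L)
      ord <- if (strand == "+") 1:2 else 2:1
      rows[[length(rows) + 1L]] <- data.frame(
        start = c(seg1[1], intr[1], seg2[1]),
        end = c(seg1[2], intr[2], seg2[2]),
        feature = c("CDS", "intron", "CDS"),
        geneId = gid, strand = strand,
        segment = c(ord[1], NA, ord[2]), stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        start = cursor, end = cursor + span - 1L, feature = feat,
        geneId = gid, strand = strand,
        segment = ifelse(feat == "CDS", 1L, NA), stringsAsFactors = FALSE)
    }
    genic <- genic + span
    cursor <- cursor + span
  }
  if (!length(rows)) return(GRanges())
  df <- do.call(rbind, rows)
  GRanges(seqnames = "genome",
          ranges = IRanges(df$start, df$end),
          strand = df$strand,
          feature = df$feature, geneId = df$geneId, segment = df$segment)
}

## ---- mutation input and heteroplasmic sorting -------------------------

snvAltForClass <- function(klass, refBase) {
  to <- list(
    "AT>GC" = c(A = "G", T = "C"), "AT>CG" = c(A = "C", T = "G"),
    "AT>TA" = c(A = "T", T = "A"), "GC>AT" = c(G = "A", C = "T"),
    "GC>TA" = c(G = "T", C = "A"), "GC>CG" = c(G = "C", C = "G"))
  unname(to[[klass]][refBase])
}

# Neutral drift of heteroplasmic frequencies: per generation, binomial
# resampling of nGen organelle copies. Unbiased (martingale), absorbing at
# 0 and 1.
driftFrequencies <- function(freq, nGenerations, bottleneck) {
  maxT <- if (length(nGenerations)) max(nGenerations) else 0L
  if (maxT < 1L) return(freq)
  for (t in seq_len(maxT)) {
    act <- which(nGenerations >= t & freq > 0 & freq < 1)
    if (length(act))
      freq[act] <- rbinom(length(act), bottleneck, freq[act]) / bottleneck
  }
  freq
}

#' Simulate germline mutations along MA line pedigrees
#'
#' For each line and homozygous generation, draws new mutations — SNVs per
#' strand-symmetric class (Poisson with mean rate x reduced genome length),
#' MNVs at adjacent positions, and repeat-locus indels (per homopolymer or
#' dinucleotide locus) — at the genotype's configured rates. Each new
#' heteroplasmy enters at `cfg$initialFreq` and then drifts by binomial
#' transmission-bottleneck resampling each remaining generation until
#' fixation or loss. Frequency-0 entries are retained and marked `lost`.
#'
#' Optionally a founder mutation shared within each mutant family can be
#' planted (`plantFounder = TRUE`): one SNV per family, present in every
#' line of the family at `cfg$founderFreq` before generation 1, sorting
#' independently in each line thereafter — the pattern expected for a
#' heteroplasmy already present in a common F2 ancestor.
#'
#' @param ref An [OrganelleGenome-class].
#' @param lines Line metadata, see [lineMetadata()].
#' @param cfg A [simulationConfig()].
#' @param plantFounder Plant one shared founder SNV per mutant family.
#' @param seed Optional seed (set only when non-NULL).
#' @return The truth ledger: data.frame with columns `lineId`, `genomeId`,
#'   `pos`, `ref`, `alt`, `type` (SNV/MNV/insertion/deletion), `class`
#'   (mutation class, NA for indels), `originGen`, `finalFreq`, `lost`.
#' @export
simulatePedigreeMutations <- function(ref, lines, cfg = simulationConfig(),
                                      plantFounder = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gid <- genomeId(ref)
  s <- strsplit(as.character(genomeSequence(ref)), "")[[1]]
  incl <- includedMask(ref)
  G <- reducedLength(ref)
  posPair <- list("AT" = which(incl & s %in% c("A", "T")),
                  "GC" = which(incl & s %in% c("G", "C")))
  runs <- findHomopolymers(ref, cfg$hpMinLen)
  dinucs <- findDinucleotideRepeats(ref)
  adjOK <- which(incl & c(incl[-1], FALSE))   # pos and pos+1 both included
  spectrum <- cfg$snvSpectrum[[gid]]
  out <- list()

  addRow <- function(lineId, pos, refA, altA, type, klass, gen, f0) {
    out[[length(out) + 1L]] <<- data.frame(
      lineId = lineId, genomeId = gid, pos = pos, ref = refA, alt = altA,
      type = type, class = klass, originGen = gen, initFreq = f0,
      finalFreq = f0, stringsAsFactors = FALSE)
  }

  if (plantFounder) {
    fams <- unique(lines$founder[lines$genotype == "msh1"])
    for (fam in fams) {
      pool <- c(posPair$AT, posPair$GC)
      p <- pool[sample.int(length(pool), 1L)]
      pair <- if (s[p] %in% c("A", "T")) "AT" else "GC"
      klass <- paste0(pair, ">", setdiff(c("AT", "GC"), pair)[1])
      # founder SNVs default to the transition class of the site's pair
      klass <- if (pair == "AT") "AT>GC" else "GC>AT"
      alt <- snvAltForClass(klass, s[p])
      for (ln in lines$lineId[lines$founder == fam])
        addRow(ln, p, s[p], alt, "SNV", klass, 0L, cfg$founderFreq)
    }
  }

  for (i in seq_len(nrow(lines))) {
    ln <- lines$lineId[i]
    gens <- lines$generations[i]
    mut <- lines$genotype[i] == "msh1"
    totalRate <- if (mut) cfg$snvRate[[gid]] else cfg$wtSnvRate[[gid]]
    mnvRate <- if (mut) cfg$mnvRate[[gid]] else 0
    hpRate <- if (mut) cfg$hpIndelRate else cfg$wtHpIndelRate
    dnRate <- if (mut) cfg$dinucIndelRate else 0
    usedPos <- integer()
    usedLoci <- integer()   # row indices into runs
    usedDinuc <- integer()
    for (g in seq_len(gens)) {
      # SNVs per class
      for (k in MUTATION_CLASSES) {
        lam <- totalRate * spectrum[[k]] * G
        n <- if (lam > 0) rpois(1L, lam) else 0L
        if (n == 0L) next
        pool <- posPair[[substr(k, 1, 2)]]
        for (j in seq_len(n)) {
          p <- pool[sample.int(length(pool), 1L)]
          tries <- 0L
          while (p %in% usedPos && tries < 50L) {
            p <- pool[sample.int(length(pool), 1L)]; tries <- tries + 1L
          }
          if (p %in% usedPos) next
          usedPos <- c(usedPos, p)
          addRow(ln, p, s[p], snvAltForClass(k, s[p]), "SNV", k, g,
                 cfg$initialFreq)
        }
      }
      # MNVs: two substitutions at adjacent positions
      nm <- if (mnvRate > 0) rpois(1L, mnvRate * G) else 0L
      for (j in seq_len(nm)) {
        p <- adjOK[sample.int(length(adjOK), 1L)]
        if (p %in% usedPos || (p + 1L) %in% usedPos) next
        usedPos <- c(usedPos, p, p + 1L)
        alt1 <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
        alt2 <- sample(setdiff(c("A", "C", "G", "T"), s[p + 1L]), 1L)
        addRow(ln, p, paste0(s[p], s[p + 1L]), paste0(alt1, alt2),
               "MNV", NA_character_, g, cfg$initialFreq)
      }
      # homopolymer indels, per locus
      if (hpRate > 0 && nrow(runs)) {
        hits <- which(runif(nrow(runs)) < hpRate)
        hits <- setdiff(hits, usedLoci)
        for (h in hits) {
          usedLoci <- c(usedLoci, h)
          kl <- runs$klass[h]
          ins <- runif(1) < cfg$insBias[[kl]]
          u <- sample.int(length(cfg$indelLengthProbs), 1L,
                          prob = cfg$indelLengthProbs)
          if (!ins) u <- min(u, runs$length[h])
          if (ins) {
            addRow(ln, runs$start[h], "", strrep(runs$base[h], u),
                   "insertion", NA_character_, g, cfg$initialFreq)
          } else {
            addRow(ln, runs$start[h], strrep(runs$base[h], u), "",
                   "deletion", NA_character_, g, cfg$initialFreq)
          }
        }
      }
      # dinucleotide-repeat indels, per locus (whole units)
      if (dnRate > 0 && nrow(dinucs)) {
        hits <- which(runif(nrow(dinucs)) < dnRate)
        hits <- setdiff(hits, usedDinuc)
        for (h in hits) {
          usedDinuc <- c(usedDinuc, h)
          ins <- runif(1) < 0.5
          u <- sample.int(2L, 1L, prob = c(0.9, 0.1))
          if (!ins) u <- min(u, dinucs$units[h])
          if (ins) {
            addRow(ln, dinucs$start[h], "", strrep(dinucs$unit[h], u),
                   "insertion", NA_character_, g, cfg$initialFreq)
          } else {
            addRow(ln, dinucs$start[h], strrep(dinucs$unit[h], u), "",
                   "deletion", NA_character_, g, cfg$initialFreq)
          }
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(lineId = character(), genomeId = character(),
                      pos = integer(), ref = character(), alt = character(),
                      type = character(), class = character(),
                      originGen = integer(), initFreq = numeric(),
                      finalFreq = numeric(), lost = logical(),
                      stringsAsFactors = FALSE))
  }
  truth <- do.call(rbind, out)
  gensOf <- setNames(lines$generations, lines$lineId)
  nT <- gensOf[truth$lineId] - truth$originGen
  truth$finalFreq <- driftFrequencies(truth$initFreq, nT,
                                      cfg$bottleneck[[gid]])
  truth$lost <- truth$finalFreq == 0
  rownames(truth) <- NULL
  truth
}

## ---- count synthesis ---------------------------------------------------

# Per-position sequencing-error rates: list(snv=, indel=) vectors of genome
# length; indel errors are concentrated at the leftmost position of each
# homopolymer run.
siteErrorRates <- function(ref, cfg) {
  L <- length(genomeSequence(ref))
  snv <- rep(cfg$errorRate, L)
  indel <- numeric(L)
  runs <- rawRuns(as.character(genomeSequence(ref)))
  runs <- runs[runs$length >= cfg$hpMinLen, , drop = FALSE]
  for (i in seq_len(nrow(runs))) {
    rate <- min(cfg$errorRate * cfg$hpErrorFactor *
                  (runs$length[i] - cfg$hpMinLen + 1)^cfg$hpErrorExponent,
                cfg$hpErrorCap)
    idx <- runs$start[i]:(runs$start[i] + runs$length[i] - 1L)
    snv[idx] <- (1 - cfg$indelErrorFraction) * rate
    indel[runs$start[i]] <- cfg$indelErrorFraction * rate
  }
  list(snv = snv, indel = indel, runs = runs)
}

numtCopiesVector <- function(ref) {
  L <- length(genomeSequence(ref))
  cp <- numeric(L)
  nm <- numtMap(ref)
  for (i in seq_along(nm))
    cp[start(nm)[i]:end(nm)[i]] <- cp[start(nm)[i]:end(nm)[i]] + mcols(nm)$copies[i]
  cp
}

#' Synthesize per-site allele-count tables
#'
#' Emulates the per-site count compilation downstream of read mapping. For
#' every position: depth is drawn from the configured model; reads carrying
#' a planted mutation are drawn binomially at its final heteroplasmic
#' frequency; per-base sequencing errors are added, with rates inflated at
#' homopolymer runs (mostly as length-1 indel observations at the run's
#' leftmost position); and, for mitochondrial genomes, numt-derived
#' reference-allele reads are added to both the reference count and the
#' depth (Poisson with mean `nuclearCoverage * copies`).
#'
#' @param ref An [OrganelleGenome-class].
#' @param truth Truth ledger from [simulatePedigreeMutations()] (same
#'   genome).
#' @param lines Line metadata; one table is produced per line.
#' @param cfg A [simulationConfig()].
#' @param seed Optional seed (set only when non-NULL).
#' @return Named list of [SiteCounts-class], one per line.
#' @export
synthesizeCounts <- function(ref, truth, lines, cfg = simulationConfig(),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gid <- genomeId(ref)
  s <- strsplit(as.character(genomeSequence(ref)), "")[[1]]
  L <- length(s)
  err <- siteErrorRates(ref, cfg)
  numtLambda <- if (gid == "mitochondrial")
    cfg$nuclearCoverage * numtCopiesVector(ref) else numeric(L)
  bases <- c("A", "C", "G", "T")
  refIdx <- match(s, bases)
  truth <- truth[truth$genomeId == gid, , drop = FALSE]

  lapply(setNames(lines$lineId, lines$lineId), function(ln) {
    depth <- if (cfg$fixedDepth) rep(as.integer(cfg$meanDepth), L)
             else rnbinom(L, size = cfg$depthDispersion, mu = cfg$meanDepth)
    cmat <- matrix(0L, nrow = L, ncol = 4L, dimnames = list(NULL, bases))
    for (b in seq_len(4L)) {
      e <- rbinom(L, depth, pmin(err$snv / 3, 1))
      e[refIdx == b] <- 0L
      cmat[, b] <- e
    }
    tl <- truth[truth$lineId == ln & truth$finalFreq > 0, , drop = FALSE]
    indelRows <- list()
    for (j in seq_len(nrow(tl))) {
      f <- tl$finalFreq[j]
      p <- tl$pos[j]
      if (tl$type[j] == "SNV") {
        cmat[p, tl$alt[j]] <- cmat[p, tl$alt[j]] + rbinom(1L, depth[p], f)
      } else if (tl$type[j] == "MNV") {
        a <- strsplit(tl$alt[j], "")[[1]]
        for (o in seq_along(a))
          cmat[p + o - 1L, a[o]] <- cmat[p + o - 1L, a[o]] +
            rbinom(1L, depth[p + o - 1L], f)
      } else if (tl$type[j] == "insertion") {
        indelRows[[length(indelRows) + 1L]] <- data.frame(
          pos = p, type = "ins", allele = tl$alt[j],
          count = rbinom(1L, depth[p], f), stringsAsFactors = FALSE)
      } else {
        indelRows[[length(indelRows) + 1L]] <- data.frame(
          pos = p, type = "del", allele = as.character(nchar(tl$ref[j])),
          count = rbinom(1L, depth[p], f), stringsAsFactors = FALSE)
      }
    }
    # homopolymer indel sequencing errors (length-1 ins and del at each run)
    hpPos <- which(err$indel > 0)
    if (length(hpPos)) {
      delE <- rbinom(length(hpPos), depth[hpPos], pmin(err$indel / 2, 1))
      insE <- rbinom(length(hpPos), depth[hpPos], pmin(err$indel / 2, 1))
      nz <- delE > 0L
      if (any(nz))
        indelRows[[length(indelRows) + 1L]] <- data.frame(
          pos = hpPos[nz], type = "del", allele = "1", count = delE[nz],
          stringsAsFactors = FALSE)
      nz <- insE > 0L
      if (any(nz))
        indelRows[[length(indelRows) + 1L]] <- data.frame(
          pos = hpPos[nz], type = "ins", allele = s[hpPos[nz]],
          count = insE[nz], stringsAsFactors = FALSE)
    }
    # reference reads fill the remaining depth; numt reads (reference
    # allele) are then added to both the reference count and the depth
    other <- rowSums(cmat)
    refReads <- pmax(depth - other, 0L)
    if (any(numtLambda > 0)) {
      add <- rpois(L, numtLambda)
      refReads <- refReads + add
      depth <- pmax(depth, other) + add
    } else {
      depth <- pmax(depth, other)
    }
    cmat[cbind(seq_len(L), refIdx)] <- refReads
    indels <- if (length(indelRows)) do.call(rbind, indelRows)
              else emptyIndelFrame()
    if (nrow(indels)) {
      key <- paste(indels$pos, indels$type, indels$allele)
      agg <- rowsum(indels$count, key)
      first <- !duplicated(key)
      indels <- indels[first, , drop = FALSE]
      indels$count <- agg[paste(indels$pos, indels$type, indels$allele), 1]
      indels <- indels[order(indels$pos, indels$type, indels$allele), ,
                       drop = FALSE]
      rownames(indels) <- NULL
    }
    siteCounts(ln, gid,
               data.frame(pos = seq_len(L), ref = s, depth = depth,
                          A = cmat[, 1], C = cmat[, 2], G = cmat[, 3],
                          T = cmat[, 4], stringsAsFactors = FALSE),
               indels)
  })
}

#' Simulate a complete MA-line experiment
#'
#' End-to-end generator: builds (or accepts) the mitochondrial/plastid
#' reference pair, simulates pedigree mutations per genome, synthesizes
#' per-line count tables, and derives per-line read statistics consistent
#' with the configured nuclear coverage. All randomness flows from `seed`.
#'
#' @param lines Line metadata ([lineMetadata()]).
#' @param refs Optional named list of [OrganelleGenome-class]
#'   (`mitochondrial`, `plastid`); generated when NULL.
#' @param cfg A [simulationConfig()].
#' @param seed Root seed (default `cfg$seed`).
#' @param plantFounder Plant shared founder SNVs, see
#'   [simulatePedigreeMutations()].
#' @return List with elements `refs`, `lines`, `truth` (combined ledger),
#'   `tables` (list per genome of per-line [SiteCounts-class]),
#'   `readStats` (data.frame), `cfg`.
#' @examples
#' ex <- simulateExperiment(lineMetadata(nWT = 2, nMutant = 2),
#'   refs = list(
#'     mitochondrial = makeSyntheticReference("mitochondrial", 4000, seed = 1),
#'     plastid = makeSyntheticReference("plastid", 2000, seed = 2)),
#'   seed = 99)
#' nrow(ex$truth)
#' @export
simulateExperiment <- function(lines = lineMetadata(),
                               refs = NULL,
                               cfg = simulationConfig(),
                               seed = cfg$seed,
                               plantFounder = FALSE) {
  set.seed(seed)
  if (is.null(refs)) {
    refs <- list(
      mitochondrial = makeSyntheticReference("mitochondrial"),
      plastid = makeSyntheticReference("plastid"))
  }
  truth <- list()
  tables <- list()
  for (g in names(refs)) {
    truth[[g]] <- simulatePedigreeMutations(refs[[g]], lines, cfg,
                                            plantFounder = plantFounder)
    tables[[g]] <- synthesizeCounts(refs[[g]], truth[[g]], lines, cfg)
  }
  truth <- do.call(rbind, c(truth, make.row.names = FALSE))
  nucBases <- cfg$nuclearCoverage *
    nuclearGenomeSize(refs[[1]])
  readStats <- data.frame(
    lineId = lines$lineId,
    totalReadBases = NA_real_,
    mitoMappedBases = vapply(lines$lineId, function(ln) {
      if ("mitochondrial" %in% names(tables))
        sum(as.numeric(siteTable(tables$mitochondrial[[ln]])$depth)) else 0
    }, numeric(1)),
    plastidMappedBases = vapply(lines$lineId, function(ln) {
      if ("plastid" %in% names(tables))
        sum(as.numeric(siteTable(tables$plastid[[ln]])$depth)) else 0
    }, numeric(1)),
    stringsAsFactors = FALSE)
  readStats$totalReadBases <- readStats$mitoMappedBases +
    readStats$plastidMappedBases + nucBases
  rownames(readStats) <- NULL
  list(refs = refs, lines = lines, truth = truth, tables = tables,
       readStats = readStats, cfg = cfg)
}
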