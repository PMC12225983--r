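#' Reduced genome length
#'
#' Genome length after removing the excluded large-repeat copies. This is the
#' number of positions eligible for variant calling and the `G` denominator
#' of every mutation-rate estimate.
#'
#' @param x An [OrganelleGenome-class].
#' @return Reduced length in bp.
#' @examples
#' g <- organelleGenome("plastid", strrep("ACGT", 250),
#'   excludedRepeats = IRanges::IRanges(1, 200))
#' reducedLength(g)  # 800
#' @rdname reducedLength
#' @export
setMethod("reducedLength", "OrganelleGenome", function(x) {
  length(x@sequence) - sum(width(x@excludedRepeats))
})

#' Logical mask of positions eligible for calling
#'
#' TRUE at positions outside every excluded repeat interval.
#'
#' @param ref An [OrganelleGenome-class].
#' @return Logical vector of genome length.
#' @export
includedMask <- function(ref) {
  L <- length(genomeSequence(ref))
  keep <- rep(TRUE, L)
  er <- excludedRepeats(ref)
  for (i in seq_along(er)) keep[start(er)[i]:end(er)[i]] <- FALSE
  keep
}

#' Base-pair composition of the reduced genome
#'
#' Counts A/T and G/C base pairs over the included (non-repeat) positions.
#' A site is an AT pair or a GC pair regardless of strand, matching the
#' strand-symmetric mutation classes (AT>GC etc.), so the result is
#' invariant under reverse complementation.
#'
#' @param ref An [OrganelleGenome-class].
#' @return Named numeric vector `c(AT = ..., GC = ...)`; the two entries sum
#'   to [reducedLength()].
#' @examples
#' basePairComposition(organelleGenome("plastid", "AATTGGCC"))
#' @export
basePairComposition <- function(ref) {
  b <- strsplit(as.character(genomeSequence(ref)), "")[[1]][includedMask(ref)]
  at <- sum(b == "A" | b == "T")
  c(AT = at, GC = length(b) - at)
}

runClass <- function(base) ifelse(base %in% c("A", "T"), "A/T", "G/C")

# All maximal single-base runs of the raw sequence (no exclusion filtering).
rawRuns <- function(seqchar) {
  r <- rle(strsplit(seqchar, "")[[1]])
  ends <- cumsum(r$lengths)
  data.frame(base = r$values,
             start = ends - r$lengths + 1L,
             length = r$lengths,
             stringsAsFactors = FALSE)
}

#' Find homopolymer runs
#'
#' Maximal single-nucleotide runs of at least `minLen` bp whose full span
#' lies outside the excluded repeats. Homopolymers are both replication
#' slippage hotspots (indel mutations) and sequencing-error hotspots, so
#' this track drives the indel-context assignment and the error model of
#' the simulator.
#'
#' @param ref An [OrganelleGenome-class].
#' @param minLen Minimum run length in bp (default 5; runs of 5 bp or longer
#'   are the conventional slippage-prone class).
#' @return data.frame with columns `base`, `start`, `length`, `klass`
#'   ("A/T" or "G/C"), sorted by start.
#' @examples
#' findHomopolymers(organelleGenome("plastid", "GGAAAAAGG"), minLen = 5)
#' @export
findHomopolymers <- function(ref, minLen = 5L) {
  stopifnot(minLen >= 2L)
  runs <- rawRuns(as.character(genomeSequence(ref)))
  runs <- runs[runs$length >= minLen, , drop = FALSE]
  if (nrow(runs)) {
    ir <- IRanges(runs$start, width = runs$length)
    keep <- !overlapsAny(ir, excludedRepeats(ref))
    runs <- runs[keep, , drop = FALSE]
  }
  runs$klass <- runClass(runs$base)
  rownames(runs) <- NULL
  runs
}

#' Find tandem dinucleotide repeat arrays
#'
#' Maximal tandem arrays of a 2-mer whose two bases differ, with at least
#' `minUnits` full units. Arrays are reported in canonical (leftmost) phase;
#' a partial trailing unit extends the reported span but not the unit count.
#' Arrays overlapping excluded repeats are dropped.
#'
#' @param ref An [OrganelleGenome-class].
#' @param minUnits Minimum number of full units (default 3).
#' @return data.frame with columns `unit` (2-mer at the array start),
#'   `start`, `end` (span including any partial unit), `units`.
#' @examples
#' findDinucleotideRepeats(organelleGenome("plastid", "CATATATAC"))
#' @export
findDinucleotideRepeats <- function(ref, minUnits = 3L) {
  stopifnot(minUnits >= 2L)
  s <- strsplit(as.character(genomeSequence(ref)), "")[[1]]
  L <- length(s)
  out <- data.frame(unit = character(), start = integer(), end = integer(),
                    units = integer(), stringsAsFactors = FALSE)
  if (L >= 4L) {
    # period-2 indicator: TRUE at i when s[i] == s[i+2]
    m <- s[seq_len(L - 2L)] == s[3L:L]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- which(r$values)
    for (k in sel) {
      a <- starts[k]
      b <- ends[k] + 2L            # span guaranteed period-2
      if (s[a] == s[a + 1L]) next  # homopolymer, not a dinucleotide array
      units <- (b - a + 1L) %/% 2L
      if (units < minUnits) next
      out <- rbind(out, data.frame(
        unit = paste0(s[a], s[a + 1L]), start = a, end = b,
        units = units, stringsAsFactors = FALSE))
    }
  }
  if (nrow(out)) {
    keep <- !overlapsAny(IRanges(out$start, out$end), excludedRepeats(ref))
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Classify a genome position by annotated feature
#'
#' Returns the feature class covering a position: CDS, rRNA, tRNA, intron,
#' or intergenic for positions covered by no annotation record. CDS takes
#' precedence over intron (intron-within-gene nesting). Positions inside an
#' excluded repeat are classified but flagged by attribute `excluded`
#' (variant calls there are removed upstream).
#'
#' @param ref An [OrganelleGenome-class].
#' @param pos 1-based position (vectorized).
#' @return Character vector of feature classes with attribute `excluded`.
#' @export
classifyPosition <- function(ref, pos) {
  L <- length(genomeSequence(ref))
  stopifnot(all(pos >= 1L), all(pos <= L))
  ann <- annotationTrack(ref)
  res <- rep("intergenic", length(pos))
  if (length(ann)) {
    prec <- c(CDS = 1L, rRNA = 2L, tRNA = 3L, intron = 4L)
    hits <- findOverlaps(IRanges(pos, pos), IRanges(start(ann), end(ann)))
    if (length(hits)) {
      feat <- mcols(ann)$feature[subjectHits(hits)]
      qh <- queryHits(hits)
      best <- tapply(feat, qh, function(f) f[which.min(prec[f])])
      res[as.integer(names(best))] <- unlist(best)
    }
  }
  attr(res, "excluded") <- overlapsAny(IRanges(pos, pos), excludedRepeats(ref))
  res
}

#' Homopolymer profile of the reduced genome
#'
#' Counts of homopolymer runs by class (A/T vs G/C) and length over the
#' included portion of the genome, plus the A/T : G/C run-count ratio. In
#' AT-rich plastid genomes this ratio is large, which is what makes their
#' overall indel spectrum deletion-biased (A/T runs are deletion-prone).
#'
#' @param ref An [OrganelleGenome-class].
#' @param minLen Minimum run length (default 5).
#' @return List with `byLength` (data.frame klass, length, n), `byClass`
#'   (named counts), and `ratioATGC` (A/T count / G/C count; Inf when no
#'   G/C runs).
#' @export
homopolymerGenomeProfile <- function(ref, minLen = 5L) {
  runs <- findHomopolymers(ref, minLen)
  byLength <- as.data.frame(table(klass = runs$klass, length = runs$length),
                            stringsAsFactors = FALSE)
  names(byLength)[3] <- "n"
  byLength$length <- as.integer(byLength$length)
  byClass <- c("A/T" = sum(runs$klass == "A/T"),
               "G/C" = sum(runs$klass == "G/C"))
  list(byLength = byLength[byLength$n > 0, , drop = FALSE],
       byClass = byClass,
       ratioATGC = unname(byClass[1] / byClass[2]))
}
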