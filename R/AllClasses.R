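#' OrganelleGenome: an organelle reference genome with its analysis tracks
#'
#' Container for one organelle reference sequence together with the interval
#' tracks needed for variant calling and rate estimation: the large repeat
#' copies excluded from calling and from the rate denominator, the numt copy
#' map (mitochondrial genomes only; number of copies of each region present
#' in the nuclear numt insertion), the gene annotation, and the nuclear
#' genome size used to convert read counts into nuclear coverage.
#'
#' Coordinates are 1-based and inclusive throughout, matching how organelle
#' genome positions are conventionally printed. Genomes are treated as
#' linear; features spanning the circular origin are not merged.
#'
#' @slot genomeId "mitochondrial" or "plastid".
#' @slot sequence A [Biostrings::DNAString] (A/C/G/T only).
#' @slot excludedRepeats [IRanges::IRanges] of repeat copies removed from
#'   calling and from the reduced genome length.
#' @slot numtMap [IRanges::IRanges] with an integer metadata column `copies`;
#'   empty for plastid genomes.
#' @slot nuclearGenomeSize Nuclear genome size in bp.
#' @slot annotation [GenomicRanges::GRanges] with metadata columns `feature`
#'   (CDS, rRNA, tRNA, intron), `geneId`, `segment` (1-based order of CDS
#'   segments along the coding sequence, in transcription order).
#'
#' @seealso [organelleGenome()], [reducedLength()], [basePairComposition()],
#'   [findHomopolymers()]
#' @exportClass OrganelleGenome
setClass("OrganelleGenome",
  representation(
    genomeId = "character",
    sequence = "DNAString",
    excludedRepeats = "IRanges",
    numtMap = "IRanges",
    nuclearGenomeSize = "numeric",
    annotation = "GRanges"
  )
)

setValidity("OrganelleGenome", function(object) {
  msg <- character()
  if (!object@genomeId %in% GENOME_IDS)
    msg <- c(msg, sprintf("genomeId must be one of: %s",
                          paste(GENOME_IDS, collapse = ", ")))
  L <- length(object@sequence)
  if (L == 0L) msg <- c(msg, "sequence must be non-empty")
  s <- as.character(object@sequence)
  if (grepl("[^ACGT]", s)) msg <- c(msg, "sequence must contain only A/C/G/T")
  er <- object@excludedRepeats
  if (length(er)) {
    if (min(start(er)) < 1L || max(end(er)) > L)
      msg <- c(msg, "excludedRepeats must lie within [1, genome length]")
    if (length(reduce(er)) != length(er) || sum(width(reduce(er))) != sum(width(er)))
      msg <- c(msg, "excludedRepeats intervals must not overlap")
  }
  if (L - sum(width(er)) <= 0L)
    msg <- c(msg, "reduced genome length must be positive")
  nm <- object@numtMap
  if (length(nm)) {
    if (object@genomeId != "mitochondrial")
      msg <- c(msg, "numtMap must be empty for non-mitochondrial genomes")
    cp <- mcols(nm)$copies
    if (is.null(cp) || any(cp < 0))
      msg <- c(msg, "numtMap must carry a non-negative 'copies' column")
  }
  if (length(object@nuclearGenomeSize) != 1L || object@nuclearGenomeSize <= 0)
    msg <- c(msg, "nuclearGenomeSize must be a single positive number")
  ann <- object@annotation
  if (length(ann)) {
    feat <- mcols(ann)$feature
    if (is.null(feat) || !all(feat %in% c("CDS", "rRNA", "tRNA", "intron")))
      msg <- c(msg, "annotation features must be CDS/rRNA/tRNA/intron")
    cds <- ann[feat == "CDS"]
    if (length(cds)) {
      tot <- tapply(width(cds), mcols(cds)$geneId, sum)
      if (any(tot %% 3L != 0L))
        msg <- c(msg, "concatenated CDS length must be divisible by 3 for every gene")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an OrganelleGenome
#'
#' @param genomeId "mitochondrial" or "plastid".
#' @param sequence A [Biostrings::DNAString] or character scalar (A/C/G/T).
#' @param excludedRepeats [IRanges::IRanges] of excluded repeat copies
#'   (default: none).
#' @param numtMap [IRanges::IRanges] with metadata column `copies`
#'   (default: none).
#' @param nuclearGenomeSize Nuclear genome size in bp (default 1.35e8,
#'   approximately the *A. thaliana* nuclear genome).
#' @param annotation [GenomicRanges::GRanges] annotation (default: none).
#' @return An [OrganelleGenome-class] object.
#' @examples
#' g <- organelleGenome("plastid", "ACGTACGTAAGGCC")
#' reducedLength(g)
#' @export
organelleGenome <- function(genomeId, sequence,
                            excludedRepeats = IRanges(),
                            numtMap = IRanges(),
                            nuclearGenomeSize = 1.35e8,
                            annotation = GRanges()) {
  if (is.character(sequence)) sequence <- DNAString(sequence)
  if (length(numtMap) && is.null(mcols(numtMap)$copies))
    stop("numtMap must carry a 'copies' metadata column")
  new("OrganelleGenome",
      genomeId = genomeId, sequence = sequence,
      excludedRepeats = excludedRepeats, numtMap = numtMap,
      nuclearGenomeSize = nuclearGenomeSize, annotation = annotation)
}

#' SiteCounts: per-site allele counts for one MA line and one genome
#'
#' Pileup-style count table holding, for every genome position, the read
#' depth and per-base allele counts, plus indel observations keyed by
#' left-aligned position and allele (inserted sequence for insertions,
#' deleted length for deletions). The depth at a row may exceed the sum of
#' recorded base counts (unrecorded reads are allowed).
#'
#' @slot lineId MA line identifier.
#' @slot genomeId "mitochondrial" or "plastid".
#' @slot counts data.frame with columns `pos`, `ref`, `depth`,
#'   `A`, `C`, `G`, `T`; positions strictly increasing.
#' @slot indels data.frame with columns `pos`, `type` ("ins"/"del"),
#'   `allele` (inserted sequence, or deleted length as character), `count`.
#'
#' @seealso [siteCounts()], [synthesizeCounts()], [computeBackground()]
#' @exportClass SiteCounts
setClass("SiteCounts",
  representation(
    lineId = "character",
    genomeId = "character",
    counts = "data.frame",
    indels = "data.frame"
  )
)

setValidity("SiteCounts", function(object) {
  msg <- character()
  cc <- object@counts
  need <- c("pos", "ref", "depth", "A", "C", "G", "T")
  if (!all(need %in% names(cc)))
    msg <- c(msg, paste("counts must have columns:", paste(need, collapse = ", ")))
  else {
    if (is.unsorted(cc$pos, strictly = TRUE))
      msg <- c(msg, "counts$pos must be strictly increasing")
    if (any(cc$depth < cc$A + cc$C + cc$G + cc$T))
      msg <- c(msg, "depth must be >= sum of base counts at every position")
  }
  ii <- object@indels
  needI <- c("pos", "type", "allele", "count")
  if (!all(needI %in% names(ii)))
    msg <- c(msg, paste("indels must have columns:", paste(needI, collapse = ", ")))
  else if (nrow(ii) && !all(ii$type %in% c("ins", "del")))
    msg <- c(msg, "indel type must be 'ins' or 'del'")
  if (length(msg)) msg else TRUE
})

emptyIndelFrame <- function() {
  data.frame(pos = integer(), type = character(), allele = character(),
             count = integer(), stringsAsFactors = FALSE)
}

#' Construct a SiteCounts table
#'
#' @param lineId MA line identifier.
#' @param genomeId "mitochondrial" or "plastid".
#' @param counts data.frame with columns `pos`, `ref`, `depth`, `A`, `C`,
#'   `G`, `T`.
#' @param indels data.frame with columns `pos`, `type`, `allele`, `count`
#'   (default: none).
#' @return A [SiteCounts-class] object.
#' @export
siteCounts <- function(lineId, genomeId, counts, indels = emptyIndelFrame()) {
  new("SiteCounts", lineId = lineId, genomeId = genomeId,
      counts = counts, indels = indels)
}

## ---- generics and accessors -------------------------------------------

#' @rdname OrganelleGenome-class
#' @param x,object An object.
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))
#' @rdname OrganelleGenome-class
#' @export
setGeneric("genomeSequence", function(x) standardGeneric("genomeSequence"))
#' @rdname OrganelleGenome-class
#' @export
setGeneric("excludedRepeats", function(x) standardGeneric("excludedRepeats"))
#' @rdname OrganelleGenome-class
#' @export
setGeneric("numtMap", function(x) standardGeneric("numtMap"))
#' @rdname OrganelleGenome-class
#' @export
setGeneric("annotationTrack", function(x) standardGeneric("annotationTrack"))
#' @rdname OrganelleGenome-class
#' @export
setGeneric("nuclearGenomeSize", function(x) standardGeneric("nuclearGenomeSize"))
#' @rdname OrganelleGenome-class
#' @export
setGeneric("reducedLength", function(x) standardGeneric("reducedLength"))

#' @rdname SiteCounts-class
#' @param x An object.
#' @export
setGeneric("lineId", function(x) standardGeneric("lineId"))
#' @rdname SiteCounts-class
#' @export
setGeneric("siteTable", function(x) standardGeneric("siteTable"))
#' @rdname SiteCounts-class
#' @export
setGeneric("indelTable", function(x) standardGeneric("indelTable"))

#' @rdname OrganelleGenome-class
setMethod("genomeId", "OrganelleGenome", function(x) x@genomeId)
#' @rdname OrganelleGenome-class
setMethod("genomeSequence", "OrganelleGenome", function(x) x@sequence)
#' @rdname OrganelleGenome-class
setMethod("excludedRepeats", "OrganelleGenome", function(x) x@excludedRepeats)
#' @rdname OrganelleGenome-class
setMethod("numtMap", "OrganelleGenome", function(x) x@numtMap)
#' @rdname OrganelleGenome-class
setMethod("annotationTrack", "OrganelleGenome", function(x) x@annotation)
#' @rdname OrganelleGenome-class
setMethod("nuclearGenomeSize", "OrganelleGenome", function(x) x@nuclearGenomeSize)

#' @rdname SiteCounts-class
setMethod("genomeId", "SiteCounts", function(x) x@genomeId)
#' @rdname SiteCounts-class
setMethod("lineId", "SiteCounts", function(x) x@lineId)
#' @rdname SiteCounts-class
setMethod("siteTable", "SiteCounts", function(x) x@counts)
#' @rdname SiteCounts-class
setMethod("indelTable", "SiteCounts", function(x) x@indels)

#' @rdname OrganelleGenome-class
setMethod("show", "OrganelleGenome", function(object) {
  cat(sprintf("OrganelleGenome: %s, %d bp (reduced %d bp)\n",
              object@genomeId, length(object@sequence),
              reducedLength(object)))
  cat(sprintf("  excluded repeats: %d interval(s), %d bp\n",
              length(object@excludedRepeats),
              sum(width(object@excludedRepeats))))
  cat(sprintf("  numt map: %d interval(s)\n", length(object@numtMap)))
  cat(sprintf("  annotation: %d feature record(s)\n",
              length(object@annotation)))
})

#' @rdname SiteCounts-class
setMethod("show", "SiteCounts", function(object) {
  cat(sprintf("SiteCounts: line %s, %s genome, %d position(s), %d indel allele(s)\n",
              object@lineId, object@genomeId,
              nrow(object@counts), nrow(object@indels)))
})
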