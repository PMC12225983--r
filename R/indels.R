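#' Assign repeat context to indel calls
#'
#' An indel is in homopolymer context when it is a whole-number expansion
#' or contraction of a single-nucleotide run of at least `minLen` bp (the
#' inserted/deleted sequence is a repetition of the run base and the
#' left-aligned position lies at or within the run); in dinucleotide
#' context when it changes a tandem dinucleotide array by whole units; and
#' `"other"` otherwise. Homopolymer context takes precedence. The
#' assignment depends only on run membership, so it is invariant under
#' shifting an indel within its run (left-alignment normalization).
#'
#' @param variants Variant data.frame (non-indel rows get NA).
#' @param ref An [OrganelleGenome-class].
#' @param minLen Minimum homopolymer length (default 5).
#' @param minUnits Minimum dinucleotide units (default 3).
#' @return Character vector: `"A/T_homopolymer"`, `"G/C_homopolymer"`,
#'   `"dinucleotide"`, `"other"`, or NA for non-indels.
#' @export
assignIndelContext <- function(variants, ref, minLen = 5L, minUnits = 3L) {
  runs <- findHomopolymers(ref, minLen)
  dinucs <- findDinucleotideRepeats(ref, minUnits)
  n <- nrow(variants)
  out <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    kl <- variants$klass[i]
    if (!kl %in% c("insertion", "deletion")) next
    p <- variants$pos[i]
    allele <- if (kl == "insertion") variants$alt[i] else variants$ref[i]
    # deletions synthesized from count tables carry only a length; recover
    # the deleted bases from the reference
    if (kl == "deletion" && grepl("^[0-9]+$", allele)) {
      len <- as.integer(allele)
      allele <- substr(as.character(genomeSequence(ref)), p, p + len - 1L)
    }
    alen <- nchar(allele)
    out[i] <- "other"
    if (alen == 0L) next
    achars <- unique(strsplit(allele, "")[[1]])
    # homopolymer: single-base allele repetition, position at/within a run
    if (length(achars) == 1L) {
      hit <- runs[runs$base == achars &
                    p >= runs$start - (kl == "insertion") &
                    p <= runs$start + runs$length - 1L, , drop = FALSE]
      if (nrow(hit)) {
        out[i] <- paste0(hit$klass[1], "_homopolymer")
        next
      }
    }
    # dinucleotide: whole units of a 2-mer with differing bases
    if (alen %% 2L == 0L && alen >= 2L) {
      u <- substr(allele, 1, 2)
      u2 <- strsplit(u, "")[[1]]
      wholeUnits <- u2[1] != u2[2] &&
        allele == strrep(u, alen / 2L)
      if (wholeUnits) {
        hit <- dinucs[p >= dinucs$start - (kl == "insertion") &
                        p <= dinucs$end, , drop = FALSE]
        # the allele unit must be a rotation of the array unit
        ok <- vapply(seq_len(nrow(hit)), function(j) {
          au <- hit$unit[j]
          u %in% c(au, paste0(substr(au, 2, 2), substr(au, 1, 1)))
        }, logical(1))
        if (any(ok)) out[i] <- "dinucleotide"
      }
    }
  }
  out
}

#' Insertion/deletion bias by repeat context
#'
#' Tabulates insertions vs deletions per context class and genome, plus
#' the indel length distribution (1, 2, 3, >3 bp). A/T homopolymers are
#' typically deletion-biased and G/C homopolymers insertion-biased, and
#' the balance of the two run classes in a genome shapes its overall indel
#' spectrum.
#'
#' @param variants Variant data.frame with a `context` column (from
#'   [assignIndelContext()] or [callPipeline()]).
#' @return List with `byContext` (data.frame `genomeId`, `context`,
#'   `insertions`, `deletions`) and `byLength` (data.frame `genomeId`,
#'   `lengthClass`, `n`).
#' @export
indelBiasSummary <- function(variants) {
  ind <- variants[variants$klass %in% c("insertion", "deletion"), ,
                  drop = FALSE]
  ctxLevels <- c("A/T_homopolymer", "G/C_homopolymer", "dinucleotide",
                 "other")
  genomes <- if (nrow(ind)) unique(ind$genomeId) else character()
  byContext <- do.call(rbind, lapply(genomes, function(g) {
    v <- ind[ind$genomeId == g, , drop = FALSE]
    data.frame(genomeId = g, context = ctxLevels,
               insertions = vapply(ctxLevels, function(cx)
                 sum(v$context == cx & v$klass == "insertion"), numeric(1)),
               deletions = vapply(ctxLevels, function(cx)
                 sum(v$context == cx & v$klass == "deletion"), numeric(1)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(byContext))
    byContext <- data.frame(genomeId = character(), context = character(),
                            insertions = numeric(), deletions = numeric(),
                            stringsAsFactors = FALSE)
  len <- nchar(ifelse(ind$klass == "insertion", ind$alt, ind$ref))
  numeric_allele <- ind$klass == "deletion" & grepl("^[0-9]+$", ind$ref)
  len[numeric_allele] <- as.integer(ind$ref[numeric_allele])
  # deletions from count tables may store length directly in end - pos + 1
  len[ind$klass == "deletion" & ind$ref == ""] <-
    (ind$end - ind$pos + 1L)[ind$klass == "deletion" & ind$ref == ""]
  lengthClass <- cut(len, c(0, 1, 2, 3, Inf),
                     labels = c("1", "2", "3", ">3"))
  byLength <- do.call(rbind, lapply(genomes, function(g) {
    tt <- table(lengthClass[ind$genomeId == g])
    data.frame(genomeId = g, lengthClass = names(tt), n = as.integer(tt),
               stringsAsFactors = FALSE)
  }))
  if (is.null(byLength))
    byLength <- data.frame(genomeId = character(), lengthClass = character(),
                           n = integer(), stringsAsFactors = FALSE)
  rownames(byContext) <- NULL
  list(byContext = byContext, byLength = byLength)
}
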