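#' @title Fixture input/output
#' @description Readers and writers for the plain-text experiment bundle:
#' FASTA references (Biostrings), GFF3 annotation and BED repeat intervals
#' (rtracklayer), the 4-column numt copy map, pileup-style per-line count
#' tables, line metadata, truth ledger, and read statistics. A fixture
#' written with a fixed seed is byte-stable, so complete experiments can be
#' round-tripped for testing.
#' @name fixture-io
NULL

indelString <- function(ind) {
  if (!nrow(ind)) return(".")
  paste(paste(ind$type, ind$allele, ind$count, sep = ":"), collapse = ";")
}

#' Write one pileup-style count table
#'
#' Columns: `genome`, `pos`, `ref`, `depth`, `A`, `C`, `G`, `T`, `indels`
#' (semicolon-joined `ins:SEQ:count` / `del:LEN:count`, `.` when none).
#'
#' @param x A [SiteCounts-class].
#' @param path Output TSV path.
#' @export
writeCountTable <- function(x, path) {
  tab <- siteTable(x)
  ind <- indelTable(x)
  indCol <- rep(".", nrow(tab))
  if (nrow(ind)) {
    sp <- split(ind, ind$pos)
    indCol[match(as.integer(names(sp)), tab$pos)] <-
      vapply(sp, indelString, character(1))
  }
  out <- data.frame(genome = genomeId(x), tab, indels = indCol,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read one pileup-style count table
#'
#' @param path TSV path written by [writeCountTable()].
#' @param lineId Line identifier to attach.
#' @return A [SiteCounts-class].
#' @export
readCountTable <- function(path, lineId) {
  raw <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "integer", "character",
                                   "integer", "integer", "integer",
                                   "integer", "integer", "character"))
  counts <- raw[, c("pos", "ref", "depth", "A", "C", "G", "T")]
  has <- which(raw$indels != ".")
  indels <- emptyIndelFrame()
  if (length(has)) {
    parts <- strsplit(raw$indels[has], ";", fixed = TRUE)
    n <- lengths(parts)
    fields <- strsplit(unlist(parts), ":", fixed = TRUE)
    indels <- data.frame(
      pos = rep(raw$pos[has], n),
      type = vapply(fields, `[`, character(1), 1L),
      allele = vapply(fields, `[`, character(1), 2L),
      count = as.integer(vapply(fields, `[`, character(1), 3L)),
      stringsAsFactors = FALSE)
  }
  siteCounts(lineId, raw$genome[1], counts, indels)
}

writeNumtMap <- function(ref, path) {
  nm <- numtMap(ref)
  df <- data.frame(chrom = genomeId(ref), start = start(nm) - 1L,
                   end = end(nm), copies = mcols(nm)$copies)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

readNumtMap <- function(path) {
  if (!file.exists(path) || file.size(path) == 0) return(IRanges())
  df <- read.table(path, sep = "\t",
                   col.names = c("chrom", "start", "end", "copies"))
  nm <- IRanges(df$start + 1L, df$end)
  mcols(nm)$copies <- as.integer(df$copies)
  nm
}

writeAnnotation <- function(ref, path) {
  ann <- annotationTrack(ref)
  mcols(ann)$type <- mcols(ann)$feature
  mcols(ann)$ID <- paste0(mcols(ann)$geneId, ".", seq_along(ann))
  phase <- rep(NA_integer_, length(ann))
  isCds <- mcols(ann)$feature == "CDS"
  for (g in unique(mcols(ann)$geneId[isCds])) {
    idx <- which(isCds & mcols(ann)$geneId == g)
    idx <- idx[order(mcols(ann)$segment[idx])]
    prior <- c(0L, cumsum(width(ann)[idx]))[seq_along(idx)]
    phase[idx] <- (3L - prior %% 3L) %% 3L
  }
  mcols(ann)$phase <- phase
  rtracklayer::export(ann, path, format = "GFF3")
}

readAnnotation <- function(path) {
  if (!file.exists(path)) return(GRanges())
  ann <- rtracklayer::import(path, format = "GFF3")
  keep <- as.character(mcols(ann)$type) %in% c("CDS", "rRNA", "tRNA", "intron")
  ann <- ann[keep]
  seg <- mcols(ann)$segment
  if (is.null(seg)) seg <- rep(NA_character_, length(ann))
  gr <- GRanges(seqnames = "genome",
                ranges = IRanges(start(ann), end(ann)),
                strand = GenomicRanges::strand(ann),
                feature = as.character(mcols(ann)$type),
                geneId = as.character(mcols(ann)$geneId),
                segment = suppressWarnings(as.integer(seg)))
  gr
}

#' Write a complete synthetic experiment to plain-text files
#'
#' Emits, per genome: `<genome>.fasta`, `<genome>.gff3`,
#' `<genome>.repeats.bed`, and (mitochondrial) `mitochondrial.numt.tsv`;
#' plus `counts/<line>.<genome>.tsv` pileup tables, `lines.tsv`,
#' `truth.tsv`, `read_stats.tsv`, and `meta.json`. Deterministic given the
#' experiment (same seed twice gives identical files).
#'
#' @param dir Output directory (created if needed).
#' @param experiment List from [simulateExperiment()].
#' @return `dir`, invisibly.
#' @export
writeFixture <- function(dir, experiment) {
  dir.create(file.path(dir, "counts"), recursive = TRUE,
             showWarnings = FALSE)
  for (g in names(experiment$refs)) {
    ref <- experiment$refs[[g]]
    ss <- DNAStringSet(as.character(genomeSequence(ref)))
    names(ss) <- g
    writeXStringSet(ss, file.path(dir, paste0(g, ".fasta")))
    if (length(annotationTrack(ref)))
      writeAnnotation(ref, file.path(dir, paste0(g, ".gff3")))
    er <- excludedRepeats(ref)
    bed <- data.frame(chrom = g, start = start(er) - 1L, end = end(er))
    write.table(bed, file.path(dir, paste0(g, ".repeats.bed")),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    if (length(numtMap(ref)))
      writeNumtMap(ref, file.path(dir, paste0(g, ".numt.tsv")))
    for (ln in names(experiment$tables[[g]]))
      writeCountTable(experiment$tables[[g]][[ln]],
                      file.path(dir, "counts", paste0(ln, ".", g, ".tsv")))
  }
  write.table(experiment$lines, file.path(dir, "lines.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(experiment$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(experiment$readStats, file.path(dir, "read_stats.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(
    genomes = names(experiment$refs),
    nuclearGenomeSize = nuclearGenomeSize(experiment$refs[[1]]),
    seed = experiment$cfg$seed)
  write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a fixture directory back into memory
#'
#' @param dir Directory written by [writeFixture()].
#' @return List with `refs`, `lines`, `truth`, `tables`, `readStats`.
#' @export
readFixture <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  lines <- read.table(file.path(dir, "lines.tsv"), header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)
  truthPath <- file.path(dir, "truth.tsv")
  truth <- read.table(truthPath, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE,
                      colClasses = c(ref = "character",
                                     alt = "character",
                                     class = "character"))
  truth$ref[is.na(truth$ref)] <- ""
  truth$alt[is.na(truth$alt)] <- ""
  readStats <- read.table(file.path(dir, "read_stats.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  refs <- list()
  tables <- list()
  for (g in meta$genomes) {
    ss <- readDNAStringSet(file.path(dir, paste0(g, ".fasta")))
    bedPath <- file.path(dir, paste0(g, ".repeats.bed"))
    er <- IRanges()
    if (file.exists(bedPath) && file.size(bedPath) > 0) {
      bed <- read.table(bedPath, sep = "\t",
                        col.names = c("chrom", "start", "end"))
      er <- IRanges(bed$start + 1L, bed$end)
    }
    refs[[g]] <- organelleGenome(
      g, as.character(ss[[1]]), excludedRepeats = er,
      numtMap = readNumtMap(file.path(dir, paste0(g, ".numt.tsv"))),
      nuclearGenomeSize = meta$nuclearGenomeSize,
      annotation = readAnnotation(file.path(dir, paste0(g, ".gff3"))))
    tables[[g]] <- list()
    for (ln in lines$lineId) {
      p <- file.path(dir, "counts", paste0(ln, ".", g, ".tsv"))
      if (file.exists(p)) tables[[g]][[ln]] <- readCountTable(p, ln)
    }
  }
  list(refs = refs, lines = lines, truth = truth, tables = tables,
       readStats = readStats)
}

#' Write a variant table as TSV
#'
#' @param variants Variant data.frame from [callPipeline()].
#' @param path Output path.
#' @export
writeVariantTable <- function(variants, path) {
  write.table(variants, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write variants as a minimal VCF-like file
#'
#' One record per call with CHROM set to the genome, and INFO fields
#' carrying line, raw and corrected frequency, depth, zygosity label and
#' repeat context. Empty REF/ALT alleles (pure insertions/deletions keyed
#' by left-aligned position) are written as `.`; this is a light-weight
#' interchange format, not a spec-complete VCF.
#'
#' @param variants Variant data.frame.
#' @param path Output path.
#' @export
writeVariantVCF <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2-minimal",
    "##INFO=<ID=LINE,Number=1,Type=String,Description=\"MA line\">",
    "##INFO=<ID=RAW_AF,Number=1,Type=Float,Description=\"Raw variant frequency\">",
    "##INFO=<ID=CORR_AF,Number=1,Type=Float,Description=\"Numt-corrected frequency\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##INFO=<ID=ZYG,Number=1,Type=String,Description=\"Zygosity label\">",
    "##INFO=<ID=CTX,Number=1,Type=String,Description=\"Indel repeat context\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    info <- sprintf("LINE=%s;RAW_AF=%.4f;CORR_AF=%.4f;DP=%d;ZYG=%s;CTX=%s",
                    v$lineId, v$rawFreq, v$corrFreq, as.integer(v$depth),
                    if (is.null(v$zygosity)) "." else v$zygosity,
                    if (is.null(v$context) || is.na(v$context)) "."
                    else v$context)
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                       v$genomeId, v$pos,
                       ifelse(nzchar(v$ref), v$ref, "."),
                       ifelse(nzchar(v$alt), v$alt, "."), info), con)
  }
  invisible(path)
}
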