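# Shared builders for small in-code fixtures.

tinyRefPair <- function(seed = 11) {
  list(
    mitochondrial = makeSyntheticReference("mitochondrial", 6000L,
                                           seed = seed),
    plastid = makeSyntheticReference("plastid", 4000L, seed = seed + 1L))
}

# A SiteCounts table where every position is pure reference at `depth`,
# except for the alt observations in `alt` (data.frame pos, base, count)
# and optional indel rows.
manualTable <- function(lineId, genomeId, seqstr, depth, alt = NULL,
                        indels = NULL) {
  s <- strsplit(seqstr, "")[[1]]
  cc <- data.frame(pos = seq_along(s), ref = s, depth = as.integer(depth),
                   A = 0L, C = 0L, G = 0L, T = 0L,
                   stringsAsFactors = FALSE)
  for (b in c("A", "C", "G", "T")) cc[[b]] <- ifelse(s == b, cc$depth, 0L)
  if (!is.null(alt)) {
    for (i in seq_len(nrow(alt))) {
      p <- alt$pos[i]
      cc[p, alt$base[i]] <- cc[p, alt$base[i]] + alt$count[i]
      cc[p, s[p]] <- cc[p, s[p]] - alt$count[i]
    }
  }
  if (is.null(indels)) indels <- organelleMA:::emptyIndelFrame()
  siteCounts(lineId, genomeId, cc, indels)
}

variantRow <- function(genomeId = "mitochondrial", pos = 5L, ref = "A",
                       alt = "G", klass = "SNV", depth = 100,
                       altCount = 40, lineId = "M1", bgMean = 0) {
  end <- pos
  if (klass == "deletion") end <- pos + nchar(ref) - 1L
  data.frame(lineId = lineId, genomeId = genomeId, pos = pos, end = end,
             ref = ref, alt = alt, klass = klass, depth = depth,
             altCount = altCount, rawFreq = altCount / depth,
             bgMean = bgMean, corrFreq = altCount / depth,
             uncorrectable = FALSE, stringsAsFactors = FALSE)
}

randomSeq <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Independent regex oracle for homopolymer runs of length >= minLen.
regexRuns <- function(seqstr, minLen) {
  out <- list()
  for (b in c("A", "C", "G", "T")) {
    m <- gregexpr(sprintf("%s{%d,}", b, minLen), seqstr)[[1]]
    if (m[1] != -1L)
      out[[b]] <- data.frame(base = b, start = as.integer(m),
                             length = attr(m, "match.length"),
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(base = character(), start = integer(),
                      length = integer(), stringsAsFactors = FALSE))
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Brute-force dinucleotide-array oracle: every start x phase candidate,
# kept only if maximal (cannot extend the period-2 span leftwards).
bruteDinucs <- function(seqstr, minUnits) {
  x <- strsplit(seqstr, "")[[1]]
  L <- length(x)
  res <- list()
  for (i in seq_len(max(L - 3L, 0L))) {
    if (x[i] == x[i + 1L]) next
    k <- 1L
    while (i + 2L * k + 1L <= L && x[i + 2L * k] == x[i] &&
           x[i + 2L * k + 1L] == x[i + 1L]) k <- k + 1L
    if (k < minUnits) next
    e <- i + 2L * k - 1L
    if (e + 1L <= L && x[e + 1L] == x[e - 1L]) e <- e + 1L
    # maximality: the period-2 span must not extend to i-1
    if (i > 1L && x[i - 1L] == x[i + 1L]) next
    res[[length(res) + 1L]] <- data.frame(
      unit = paste0(x[i], x[i + 1L]), start = i, end = e, units = k,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(unit = character(), start = integer(),
                      end = integer(), units = integer(),
                      stringsAsFactors = FALSE))
  out
}
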