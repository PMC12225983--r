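#' Total generations across MA lines
#'
#' The `N` of every rate estimate: the sum over lines of the number of
#' homozygous generations contributing mutations.
#'
#' @param lines Line metadata ([lineMetadata()]) or a numeric vector of
#'   per-line generation counts.
#' @return Total generations (numeric).
#' @examples
#' totalGenerations(c(rep(7, 18), rep(6, 4)))    # 150
#' totalGenerations(c(rep(25, 107), rep(8, 20))) # 2835
#' @export
totalGenerations <- function(lines) {
  g <- if (is.data.frame(lines)) lines$generations else lines
  stopifnot(length(g) > 0, all(g >= 1))
  sum(g)
}

rateEstimate <- function(V, G, N, mode,
                         mu = V / (G * N),
                         variantClass = "SNV") {
  structure(list(V = V, G = G, N = N, mu = mu, mode = mode,
                 variantClass = variantClass),
            class = "RateEstimate")
}

#' @export
print.RateEstimate <- function(x, ...) {
  cat(sprintf("%s %s rate: mu = %s per bp per generation (V = %.4g, G = %d, N = %d)\n",
              x$mode, x$variantClass, formatRate(x$mu), x$V,
              as.integer(x$G), as.integer(x$N)))
  invisible(x)
}

#' Format a mutation rate in scientific notation
#'
#' @param mu Rate(s), per bp per generation.
#' @param digits Significant figures (default 2).
#' @return Character, e.g. `"4.8e-06"`.
#' @export
formatRate <- function(mu, digits = 2) {
  formatC(signif(mu, digits), format = "e", digits = digits - 1)
}

#' Frequency-weighted SNV mutation rate
#'
#' `mu = V / (G * N)` where `V` is the sum of corrected heteroplasmic
#' frequencies over SNVs (and MNVs, each counted once at its frequency).
#' Weighting by frequency makes the estimator target the
#' transmission-effective substitution rate: a heteroplasmy transmitted at
#' frequency f contributes f, which under neutral sorting equals its
#' fixation probability.
#'
#' @param variants Variant data.frame with `klass` and `corrFreq` columns.
#' @param G Reduced genome length in bp.
#' @param N Total generations ([totalGenerations()]).
#' @return A `RateEstimate` (mode "weighted").
#' @export
snvRate <- function(variants, G, N) {
  stopifnot(G > 0, N > 0)
  sel <- variants$klass %in% c("SNV", "MNV")
  rateEstimate(V = sum(variants$corrFreq[sel]), G = G, N = N,
               mode = "weighted")
}

#' Unweighted indel mutation rate
#'
#' `mu = count / (G * N)`. Indel frequencies at homopolymers are too noisy
#' to weight by, so raw counts are used; the estimate is an upper count of
#' events but may still underestimate the true rate (multiple hits at one
#' locus in one line are not separable).
#'
#' @param indelCount Number of indel calls (or a variant data.frame, in
#'   which case insertion/deletion rows are counted).
#' @param G Reduced genome length in bp.
#' @param N Total generations.
#' @return A `RateEstimate` (mode "unweighted").
#' @examples
#' formatRate(indelRate(258, 357025, 150)$mu)  # "4.8e-06"
#' @export
indelRate <- function(indelCount, G, N) {
  stopifnot(G > 0, N > 0)
  if (is.data.frame(indelCount))
    indelCount <- sum(indelCount$klass %in% c("insertion", "deletion"))
  rateEstimate(V = indelCount, G = G, N = N, mode = "unweighted",
               variantClass = "indel")
}

#' Poisson zero-observation upper bound on the mutation rate
#'
#' When an experiment observes no mutations, the smallest rate that would
#' still have yielded probability `1 - alpha` of at least one observation
#' (Poisson model, expectation `mu * G * N`) is
#' `mu = ln(1/alpha) / (G * N)`.
#'
#' @param G Reduced genome length in bp.
#' @param N Total generations (pooled over experiments).
#' @param alpha Allowed probability of observing zero mutations
#'   (default 0.05).
#' @return A `RateEstimate` (mode "upper_bound").
#' @examples
#' formatRate(wtUpperBound(357025, 2835)$mu, 1)  # "3e-09"
#' @export
wtUpperBound <- function(G, N, alpha = 0.05) {
  stopifnot(G > 0, N > 0, alpha > 0, alpha <= 1)
  rateEstimate(V = log(1 / alpha), G = G, N = N, mode = "upper_bound")
}

#' Rate implied by a single homoplasmic variant
#'
#' The rate that one fixed (frequency 1) variant would have corresponded
#' to: `1 / (G * N)`. A reference point for interpreting experiments with
#' zero observations.
#'
#' @param G Reduced genome length in bp.
#' @param N Total generations.
#' @return A `RateEstimate` (mode "single_variant").
#' @export
singleVariantRate <- function(G, N) {
  stopifnot(G > 0, N > 0)
  rateEstimate(V = 1, G = G, N = N, mode = "single_variant")
}

#' Per-class mutation rates normalized by base-pair composition
#'
#' For each of the six strand-symmetric classes,
#' `mu_c = sum(frequencies of class-c SNVs) / (pairs_c * N)` where
#' `pairs_c` is the number of AT or GC base pairs (matching the class
#' source) in the reduced genome. Normalizing by pair counts removes the
#' effect of biased nucleotide composition when comparing spectra between
#' genomes.
#'
#' @param variants Variant data.frame (SNV rows are used; their class is
#'   derived from ref/alt via [classifySNV()]).
#' @param ref An [OrganelleGenome-class].
#' @param N Total generations.
#' @return data.frame with columns `class`, `V` (summed frequency),
#'   `pairs`, `mu`.
#' @export
spectrumRates <- function(variants, ref, N) {
  stopifnot(N > 0)
  comp <- basePairComposition(ref)
  snv <- variants[variants$klass == "SNV", , drop = FALSE]
  kl <- if (nrow(snv)) classifySNV(snv$ref, snv$alt) else character()
  V <- vapply(MUTATION_CLASSES,
              function(k) sum(snv$corrFreq[kl == k]), numeric(1))
  pairs <- ifelse(startsWith(MUTATION_CLASSES, "AT"), comp["AT"], comp["GC"])
  mu <- ifelse(V == 0, 0, V / (pairs * N))  # a genome may lack one pair type
  data.frame(class = MUTATION_CLASSES, V = unname(V),
             pairs = unname(pairs), mu = unname(mu),
             stringsAsFactors = FALSE)
}
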