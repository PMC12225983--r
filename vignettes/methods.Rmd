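---
title: "Measuring organelle germline mutation rates from MA-line count data"
author: "organelleMA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring organelle germline mutation rates from MA-line count data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organelleMA)
```

# The problem

Plant mitochondrial and plastid genomes normally mutate extremely slowly,
in part because of plant-specific organelle-targeted DNA repair (the MSH1
pathway). Mutation-accumulation (MA) experiments quantify germline mutation
rates directly: lines are propagated by single-seed descent so that drift,
not selection, governs the fate of new mutations, and resequencing after
several generations reveals the mutations that accumulated. In organelle
genomes the observable unit is a *heteroplasmy* — a variant present in some
fraction of the cell's many genome copies — whose frequency drifts between
generations under transmission bottlenecks until it fixes or is lost.

`organelleMA` implements the full computational path from per-site
allele-count tables (pileup counts, one table per line per organelle
genome) to mutation rates, spectra, indel-context summaries, and selection
diagnostics, together with a synthetic-data generator that produces
complete MA experiments with known ground truth.

# The variant-calling cascade

Calling is deliberately threshold-based; there are no genotype
likelihoods. For each line and each (position, allele) pair:

1. **Candidate gates.** Raw variant frequency ≥ `minFreq` (default 0.20),
   depth ≥ `minDepth` (default 50×), and frequency ≥ `bgFold` (default 3)
   times the *wild-type background* — the mean frequency of that allele
   across all WT lines (`computeBackground()`). The high frequency cutoff
   guards against vegetative (somatic) mutations and sequencing error; the
   background rule removes systematic error at low-complexity sites, where
   every sample shows elevated frequencies. The background is per-allele
   rather than summed over non-reference alleles — the stricter reading —
   so a genuine variant in one WT line cannot shadow a different allele.
   WT lines are called against the self-inclusive WT mean.
2. **Repeat-copy exclusion.** Organelle genomes carry large repeats that
   interconvert by recombination; calls in one copy of each pair are
   removed, and the genome length used in rates is reduced accordingly.
3. **Artefact exclusion.** Reads spanning structural-rearrangement
   junctions (or derived from the nuclear copy of mitochondrial DNA, the
   *numt*) can mimic de novo variants. A variant is dropped when its
   alt-substituted context (`flankK` = 20 bp of flank each side) occurs
   exactly in any supplied artefact sequence, either strand. Exact
   matching of a 20-mer context is deterministic and dependency-free;
   users screening real data against imperfect homology should pre-screen
   externally and pass the junction sequences as a blocklist.
4. **Numt frequency correction.** Mitochondrial reads include
   numt-derived molecules that always match the reference allele, biasing
   frequencies downward. With nuclear coverage `c` (estimated from
   non-organelle read bases over the nuclear genome size) and `k` numt
   copies of the locus, `c*k` expected reference reads are subtracted from
   the reference count and the total, and the frequency is recalculated
   (capped at 1). The correction can only raise a frequency. It is applied
   after the candidate gates, i.e. the 20% threshold applies to the raw
   frequency — consistent with the filtering order of the protocol this
   package follows; the alternative (threshold on corrected frequencies)
   can be explored by lowering `minFreq` and filtering afterwards.
5. **MNV merging.** Adjacent same-line substitutions merge into one
   multi-nucleotide variant at the mean of the member frequencies, as does
   an insertion co-located with a substitution (replacement-type MNV).
   Members leave the SNV pool so nothing is double-counted. The mean is a
   convention; members of a true MNV have essentially equal frequencies.
6. **Homoplasmy labels.** Plastid calls at ≥ 98% corrected frequency, and
   mitochondrial calls strictly above 90%, are labelled homoplasmic
   candidates; the mitochondrial cutoff is more conservative because the
   numt correction is approximate. Indel calls receive the label
   mechanically but it should not be interpreted — indel frequencies at
   homopolymers are dominated by sequencing noise.

Indel alleles are keyed by left-aligned position (the leftmost position of
the repeat run they modify) and by inserted sequence or deleted length.
Left alignment is a convention; context assignment is invariant to shifts
within the run.

# Rate estimation

All rates are per base pair per generation:

$$\mu = \frac{V}{G \times N}$$

with `G` the *reduced* genome length (repeat copies removed) and `N` the
total homozygous generations summed over lines (`totalGenerations()`).

For SNVs, `V` is the sum of corrected heteroplasmic frequencies
(`snvRate()`); an MNV counts once at its frequency. Weighting by frequency
makes the estimator target the *transmission-effective* rate: under
neutral drift a heteroplasmy's frequency is a martingale and equals its
fixation probability, so a mutation entering the germline at frequency
$f_0$ contributes $f_0$ in expectation. In the simulator this means the
weighted estimator recovers `eventRate * initialFreq`, which is what the
acceptance checks assert (with a single-copy bottleneck so that sorting is
complete and the called and planted weighted sums coincide).

For indels `V` is the raw call count (`indelRate()`): frequencies at
homopolymers are too noisy to weight by. The resulting rate can err in
both directions — unweighted heteroplasmies inflate it, unobservable
multiple hits at one locus and variants lost in homopolymer noise deflate
it.

For an experiment that observed *zero* mutations, `wtUpperBound()` gives
the smallest rate that would still have produced at least one mutation
with probability $1-\alpha$ under a Poisson model:
$\mu = \ln(1/\alpha)/(G N)$, and `singleVariantRate()` gives the rate a
single homoplasmic variant would have implied, $1/(GN)$.

Spectrum rates (`spectrumRates()`) divide each strand-symmetric class's
weighted count by the number of AT or GC base pairs of the reduced genome
(`basePairComposition()`), removing composition bias when comparing
genomes; the six classes conserve the total weighted count.

# Selection diagnostics

**Synonymous-site permutation test** (`permutationTestSynonymous()`).
Selection against deleterious amino-acid changes would enrich the observed
CDS variants for synonymous changes. The test keeps the number and
strand-symmetric type of the observed CDS substitutions fixed and
randomizes their positions uniformly over the eligible CDS sites of their
own genome — sites whose reference pair matches the class source; the
substituted base then follows from the class and the site's coding-strand
base, so the permuted data have exactly the observed spectrum. Each of
`nPerm` permutations (default 10,000) yields a pooled synonymous count;
the one-tailed p-value is the frequency of permutations at or above the
observed count. Uniform placement over eligible sites is the only reading
that preserves mutation type; placements are independent, so the null is
a sum of binomials and can be enumerated exactly on toy genes — which is
how the implementation is tested. The p-value is the plain permutation
frequency (no +1 correction); a zero is reported as "< 1/nPerm".
Intron-containing genes are handled by concatenating CDS segments in
transcription order (the `segment` annotation column).

**Overdispersion across lines** (`dispersionTest()`). If lines accumulate
mutations independently at a constant rate, per-line counts are Poisson.
The Cameron–Trivedi score test against `var = (1+a)*mean` uses
$z = \sum_i[(y_i-\bar y)^2 - y_i]\,/\,(\bar y\sqrt{2n})$, standard normal
under the null, one-sided for overdispersion; the studentized
auxiliary-regression statistic is reported as a cross-check. At n = 22
lines the test's type-I error at nominal 0.05 measures ~0.04–0.05 and
power against variance = 3× mean exceeds 0.9 (both recomputed by the test
suite and the acceptance script).

**Genic fractions** (`genicFractionSummary()`). Counts of variants by
feature class (CDS/rRNA/tRNA/intron/intergenic) with a synonymous
sub-count; proportional representation of genic sequence among variants is
the coarse signature of effective neutrality during MA propagation.

# Homopolymer indel analysis

Homopolymers (single-nucleotide runs; default minimum 5 bp, the
conventional slippage-prone length, configurable since a length spectrum
is often wanted) are both mutational and sequencing-error hotspots.
`assignIndelContext()` classes each indel as an A/T- or G/C-homopolymer
expansion/contraction (whole repetitions of the run base, position within
the run), a whole-unit dinucleotide-array change, or "other"; homopolymer
takes precedence, and a mixed-sequence insertion inside a run is "other"
because it is not an expansion of the repeat. `indelBiasSummary()`
tabulates insertions vs deletions per context and genome —
deletion-biased A/T runs and insertion-biased G/C runs, combined with a
genome's run composition, shape its overall indel spectrum — and
`homopolymerGenomeProfile()` gives the genome-wide run counts those
comparisons are normalized against.

# The synthetic-data generator

`simulateExperiment()` produces what the analysis consumes — count
tables — without simulating reads or alignment. Per genome and line:

* **Mutation input.** SNVs per strand-symmetric class arise Poisson with
  mean `rate_class × G` per generation, placed uniformly on eligible
  (non-repeat, matching-pair) sites; MNVs at adjacent positions;
  repeat-locus indels per homopolymer/dinucleotide locus per generation
  with class-specific insertion bias and mostly single-unit lengths.
  Defaults are the msh1-mutant conditions: total SNV rates 6.1e-7
  (mitochondrial) and 3.2e-6 (plastid) per bp per generation; spectra
  dominated by transitions with a strongly GC-biased plastid (83% AT→GC)
  and a GC-neutral mitochondrion (47% AT→GC / 43% GC→AT); per-locus
  homopolymer indel rate 2e-3 per generation with insertion probabilities
  0.35 (A/T) and 0.60 (G/C); dinucleotide-locus rate 5e-5, set so the
  dinucleotide share of called indels stays near the few-percent level
  seen in real data given the relative abundance of arrays in random
  sequence. WT rates default to zero.
* **Heteroplasmic sorting.** A new mutation enters at `initialFreq`
  (default 0.5 — the generator models germline transmission of an already
  established heteroplasmy; real initial frequencies are unknown and the
  parameter is exposed) and each subsequent generation is resampled
  binomially with an organelle-specific bottleneck (defaults 50
  mitochondrial, 20 plastid: order-of-magnitude placeholders expressing
  that plastid sorting is faster; they are *not* estimates). Drift is
  unbiased and absorbs at 0 and 1; lost mutations stay in the truth
  ledger flagged `lost`.
* **Sequencing model.** Depth is negative binomial (mean 500, size 8;
  a fixed-depth mode exists for deterministic tests); base error rate
  0.2% per site spread over the three non-reference bases. At a
  homopolymer of length L the error rate inflates to
  `errorRate × 20 × (L − 4)`, capped at 0.4, with 80% of it emitted as
  length-1 indel observations at the run's leftmost position — a
  deliberately simple saturating stand-in for the steep error growth at
  long runs. Because the inflation is deterministic per site, WT lines
  share it, which is exactly the situation the 3-fold background rule is
  designed to neutralize.
* **Numt contamination.** For mitochondrial tables, Poisson
  `nuclearCoverage × copies` reference-allele reads are added to both the
  reference count and the depth over the numt intervals (default map: one
  single-copy region covering ~55% of the genome plus a small two-copy
  region). Default nuclear coverage 40, keeping the nuclear:organelle
  coverage ratio in the range typical of total-DNA plant sequencing at
  the default organelle depth.
* **References.** `makeSyntheticReference()` draws random genomes at the
  organelles' GC contents (45% mitochondrial / 35% plastid — AT-richness
  is what makes plastid A/T homopolymers abundant), one excluded repeat
  interval (5%), and an annotation covering the genomes' genic fractions
  (10% / 59%) with CDS (occasionally intron-split), rRNA and tRNA genes.
  Default lengths are 50 kb and 20 kb: large enough for hundreds of
  repeat loci and realistic background structure, small enough that a
  42-line experiment synthesizes in a few seconds.

What the generator does **not** emulate: read-level artefacts
(mapping bias, strand effects, base-quality structure), true numt
paralogy (numts are modelled as frequency dilution, not mismapped
variant reads), structural rearrangements (the artefact filter is
exercised with planted junction sequences instead), circular-origin
features, and selection within the organelle population. Tests passing on
synthetic data therefore validate the *computational* pipeline — filter
logic, estimator calibration, test statistics — not the upstream mapping
choices a real study must make.

# Numerical and design choices

* Coordinates are 1-based inclusive everywhere; BED input/output converts
  at the boundary. Genomes are treated as linear; runs or arrays spanning
  the circular origin are not merged (a documented limitation).
* Dinucleotide arrays are reported in leftmost phase counting full units
  only; a partial trailing unit extends the span, not the count.
* Expected numt reads are subtracted as real numbers (the correction is
  an expectation, not a read count); a site whose corrected coverage
  would be ≤ 0 is flagged uncorrectable and keeps its raw frequency.
* Ties among multiple passing alleles at one site: all are reported.
* All randomness flows from one root seed; per-stage seeds are derived by
  fixed offsets so stages re-run independently and byte-identically
  (fixtures written twice from the same seed have identical checksums).
* Degenerate inputs error early and explicitly: empty WT sets (the
  background rule is undefined), all-zero counts in the dispersion test,
  permutation classes with no eligible CDS site (named in the message).

# Problem sizes used by the checks

The test suite and the acceptance script size their simulations for a
single CPU: 50 replicate 20-line WT experiments for the null check; 25
(suite) / 20 (script) replicate full 42-line experiments on the 50 + 20 kb
reference pair for recovery and false positives; 200 truth-level pedigree
replicates with a single-copy bottleneck for weighted-rate recovery,
pooled across the two genomes (the pooled estimate has ~3× the event count
of the mitochondrial genome alone, tightening the Monte-Carlo check
without changing its 3-standard-error criterion); 2,000 replicates for
dispersion-test calibration; 1,000 random 10-kb sequences against the
regex homopolymer oracle.

# Known limitations

* The threshold cascade has no statistical error model; sensitivity near
  the 20% cutoff is sharp, and mitochondrial variants whose raw frequency
  is diluted below it by numt reads are missed by design (the threshold
  precedes the correction).
* The homoplasmy labels are heuristics on frequency, not genotype calls.
* Indel rates are unweighted counts; multiple hits at one locus within a
  line are invisible.
* The permutation test conditions on the observed spectrum and placement
  eligibility only; it does not model codon usage or site-specific
  mutability.
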