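---
title: "Modelling and detecting biallelic somatic mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and detecting biallelic somatic mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biallelic)
```

## The problem

Tumour phylogenetics and essentially all somatic variant interpretation
rest on the infinite sites assumption: each genomic position mutates at
most once in a lineage's history. In hypermutated tumours this assumption
breaks. When both parental alleles of a site acquire the same substitution
independently (a *biallelic parallel* mutation) the variant allele
frequency roughly doubles, mimicking a copy-number gain or an early clonal
event; two different substitutions at one site form a *biallelic
divergent* mutation, which most consensus callers mishandle; second hits
on an already mutated allele produce *back* (reference-restoring) and
*forward* mutations that silently erase or rewrite evidence.

This package provides the full modelling and detection stack for these
events in bulk tumour sequencing data: two simulators that estimate how
many violations a tumour's mutation burden should produce, a
VAF (variant allele frequency)-based caller for parallel mutations with a
purity- and copy-number-aware beta-binomial test, a read-backed phasing
caller, closed-form collision estimators, and a synthetic-cohort
generator that makes the whole pipeline testable without access to
protected patient genomes.

## Mutation representation

Substitutions are classed into the standard 96 trinucleotide channels:
six pyrimidine substitutions (C>A, C>G, C>T, T>A, T>C, T>G) by 16 flank
combinations, with purine-centred events reverse-complemented onto the
pyrimidine strand. The channel order (substitution-major, then 5′ flank
A/C/G/T, then 3′ flank A/C/G/T) is frozen and used for all spectrum
serialisation. A `context_genome` couples reference sequences with
callable intervals and precomputes, per chromosome, the positions and
context class of every callable site; contexts containing N and
chromosome-edge bases are excluded from both abundance counts and
sampling.

## The uniform permutation simulator

One replicate resamples a sample's catalog in three hierarchical steps
and then scatters the mutations over both parental copies of the callable
genome:

1. **Burden.** `n ~ Poisson(λ)`, `λ ~ Gamma(rate r, shape β)` with the
   Gamma's mode at the observed burden and standard deviation
   `σ = 0.05 × n_obs`. We solve both constraints exactly:
   `r = (n + √(n² + 4σ²)) / (2σ²)`, `β = 1 + n·r`. At the default
   coefficient of variation the difference from any nearby
   parameterisation is O(σ²/n²) and immaterial.
2. **Chromosomes.** The burden is divided by a Dirichlet-multinomial
   with parameter `α = observed per-chromosome counts + 1`.
3. **Spectrum.** Each chromosome draws channel probabilities from a
   Dirichlet whose parameter adds the chromosome's observed channel
   counts to a pseudocount `ψ = (overall counts + 1) × (2/3) / n_obs` —
   a weak prior anchored on the sample's overall spectrum (the 2/3
   scale is exposed as a package constant).

Mutations are then placed one at a time: a position and allele are
proposed uniformly; the proposal is accepted with probability
proportional to the spectrum mass of its *current* trinucleotide class
divided by the class's reference abundance (`π_c / f_c`). Because
acceptance consults the current, possibly already mutated, trinucleotide,
the simulator naturally produces back and forward mutations, and a
mutated site whose new context carries no spectrum mass simply leaves the
mutable set. Each repeat hit at a locus is classified against the current
allelic state: other allele and same resulting base — parallel; other
allele, different base — divergent; same allele restoring the reference —
back; same allele, third state — forward. A locus whose hits have all
been reverted by back mutation is reference again, and a later hit there
counts as a fresh first hit. Re-drawing the identical state (a "no-op")
cannot occur, because substitution channels always change the current
base.

For speed the implementation processes proposals in vectorised batches:
proposals that cannot interact with any mutated position are accepted in
bulk, while proposals at or adjacent to mutated positions, or duplicated
within a batch, go through an exact sequential path. Position duplicates
are handled exactly in proposal order; a proposal merely *flanking* a hit
accepted earlier in the same batch sees the batch-start overlay — a
distortion of order hit-density that vanishes at genomic scales and does
not touch same-locus collision accounting. Rejection attempts are capped
(10⁶ per mutation) so spectra concentrated on absent contexts fail loudly
rather than spin.

Each replicate records per-class violation counts, per-channel parallel
and divergent spectra, and `n_colliding` — the number of mutations at
multi-hit loci. The latter exists because the closed-form birthday
expectation (below) counts every mutation involved in a collision,
whereas the per-class counts tally classified events (a two-hit locus is
one parallel event but two colliding mutations); comparisons against the
closed form must use the matching statistic.

## The neighbour resampling simulator

Positionally clustered mutational processes collide more often than a
uniform model predicts. The neighbour model therefore keeps one "allele"
as a random half (⌈n/2⌉) of the sample's own non-driver mutations and
draws the other half without replacement from pooled mutations of
*representative* samples: same histology, mutation-spectrum cosine
similarity ≥ 0.9 to the target. A sample qualifies only when its pool
holds at least half its burden. Any same-position pair across the two
allele sets is a violation — same alternate allele: parallel; different:
divergent (for indels, parallel requires the identical inserted or
deleted sequence). Back and forward mutations cannot arise. Duplicate
positions drawn within one allele set are discarded and redrawn, because
the model defines only cross-allele events. Driver mutations never enter
the pool, and resampled records are treated as single events, which
slightly underestimates the true violation count when inputs are
themselves biallelic.

## Closed-form estimators

Scattering `n` mutations over `N` positions is a birthday problem: the
expected number of mutations sharing a locus with at least one other is
`n − n(1 − 1/N)^(n−1) ≈ n²/N`. `fit_c_type()` summarises a tumour type's
deviation from this law as the through-origin regression coefficient of
simulated violations on `m²/N`; `effective_genome_size()` converts the
ratio of the two simulators' expectations into the genome size a uniform
process would need to produce the observed collision rate
(`N_eff = N_callable × E_uniform / E_neighbour`). The effective-size
formula is a reconstruction from the inverse-proportionality of
collisions in `N` and is labelled as such in its output. For the birthday
formulas the genome size is always the callable locus count supplied by
the data, never a hard-coded constant; on single-channel toy genomes the
appropriate collision space is the `2N` diploid allelic sites, because a
mutated site leaves the mutable set.

## VAF-based detection of parallel mutations

Read counts at phased heterozygous SNPs are modelled as
`V ~ Bin(n, p)`, `p ~ Beta(BAF_seg·ω, (1−BAF_seg)·ω)`, where `BAF_seg`
is the segment's mean phased B-allele frequency (input contract:
haplotype blocks already flipped so `BAF_seg ≥ 0.5`, as Battenberg-style
pipelines emit) and `ω ∈ [50, 1000]` is a sample-specific concentration —
a pseudo-coverage capturing over-dispersion. `ω` is calibrated so the
robust slope of the QQ plot of the SNPs' two-sided p-values equals 1,
searched on a 40-point log grid with local root refinement. Two details
are deliberate:

* The calibration uses *mid-p* two-sided values. For discrete counts the
  plain doubled-tail p-value is conservative, which deflates the QQ slope
  and would bias `ω` upward; the mid-p correction removes that bias.
  Candidate testing and all guard checks use the conservative doubled
  tail.
* The robust slope is a Theil–Sen median-of-pairwise-slopes on the
  −log10 quantile pairs, excluding ties at p = 1 and deterministically
  thinned to 500 evenly spaced order statistics. At high concentrations
  (ω ≳ 600) read counts at depth ~60 are nearly binomial and the slope
  surface flattens, so calibration there is intrinsically noisy — a
  limitation of the QQ-slope criterion itself, not of the search.

The maximal allele frequency a major-allele-confined variant can reach is
the segment BAF corrected for the major-allele contribution of admixed
normal cells:
`BAF_som = BAF_seg − (1−ρ) / ((2(1−ρ) + ρΨ_t)·2^logR_seg)`,
with purity ρ and tumour ploidy Ψ_t; values below 0.05 are conservatively
raised back to `BAF_seg`. Candidate SNVs are tested one-sided
(`P(V ≥ v)`) against `BAF_som`; sites whose *minimal attainable* p-value
(the tail at `v = n`) is not below 0.001 are removed as unpowered — that
reading is the only one that excludes low-coverage and `BAF_som ≈ 1`
sites, which is the filter's stated purpose. Benjamini–Hochberg
correction runs over the tested (post-filter, powered) sites and
candidates require `q ≤ 0.1`.

The filter cascade removes: (i) SNVs at known heterozygous germline SNPs;
(ii) SNVs in regions of common structural variation; (iv) SNVs with two
or more heterozygous SNPs within 25 bp (mapping-bias risk); (v) SNVs in
loss-of-heterozygosity segments, which are untestable by either approach
(in males, only the X pseudoautosomal regions are considered).
Candidates additionally face a flanking-SNP guard (iii): the nearest
heterozygous SNP on each side must not be a BAF or logR outlier on its
segment — per-SNP two-sided p > 0.001 and Fisher-combined p > 0.01, with
logR outliers judged against a Gaussian centred on the segment median
with a MAD-based, consistency-adjusted standard deviation. The guard uses
the two nearest flanks (configurable); with missing flanks the candidate
is untestable rather than failed. T/B-cell receptor loci, indel proximity
(−10 to +25 bp around the variant) and liftover failure are attached as
non-removing flags. Sample-level QC excludes a sample whose final
p-values show a robust QQ slope above 1 (under-estimated purity inflates
every test) and, when simulator summaries are supplied, samples in which
both simulators expect zero biallelic events. Every input SNV exits the
pipeline in exactly one state: removed (with a filter id), untested (with
a reason), not-significant, or parallel-candidate.

Divergent candidates arrive as two-ALT records and pass a separate rule:
germline posterior below −1 (log10) for *both* alternates and at least 19
high-quality reads in the matched normal.

## Phasing-based detection

A heterozygous SNP within 700 bp of a somatic SNV lets read pairs assign
the variant to haplotypes. Pairs are counted only when both reads map
with quality ≥ 20, the phased positions have base quality ≥ 25, the pair
is proper, unclipped, not a duplicate, carries no indel or vendor-fail
flag, and shows fewer than 2 mismatches in a read and 3 in the pair
(mismatches exclude the phased positions themselves, since the variant is
not an artefact). A parallel call requires ≥ 2 Ref-Alt and ≥ 2 Alt-Alt
pairs, each above 10% of the four-cell total (the denominator includes
all four SNP×SNV classes; pairs uninformative at one position are not
counted), and a SNP whose own BAF is not a segment outlier (two-sided
p > 0.001) — the latter guards against a post-gain mutation of the in-cis
SNP allele. An SNV with several informative SNPs is parallel if any pair
calls it. Note the fraction rule caps strict monotonicity: an extra
Alt-Alt read can dilute the Ref-Alt fraction through the 10% floor at the
boundary.

Precision of the VAF caller is judged as the fraction of its calls,
restricted to *phaseable* SNVs (SNP informative on both alleles, ≥ 4
reads reporting the SNV), confirmed by phasing; recall as the fraction of
phasing hits recovered by VAF. The total parallel burden is extrapolated
from the phaseable subset with
`n_viol ~ Bin(n_tested, P ~ Beta(n_par + 0.001, n_single + 0.001))`,
reporting the posterior-predictive mean and 2.5/97.5 percentiles. The
near-zero prior makes the interval degenerate when no phaseable hit is
seen, so calibration statements are restricted to the reporting
population of samples with ≥ 10,000 phaseable SNVs — the same threshold
used for cohort-level performance summaries.

## The synthetic cohort generator

The generator inverts the detection model so that planted truth flows
through to read counts. Reference chromosomes are i.i.d. bases at a
configurable GC content; catalogs draw channels from a requested spectrum
and positions uniformly within context classes (one mutation per locus);
planted parallel events are emitted as ordinary single records — their
biallelic nature lives only in the truth manifest and in the generated
counts — while divergent events carry two ALT alleles. Observations
follow the caller's own model: depth is Poisson around a copy-number-
scaled mean (`logR` consistent with the purity/ploidy conventions of the
caller), SNP and SNV counts are beta-binomial with a configurable true
concentration, and the expected VAF of a variant on `k` copies in an
(n_maj, n_min) segment is `ρk / (2(1−ρ) + ρ(n_maj+n_min))`. Defaults
encode the benchmark conditions used throughout the tests: purity 0.9,
mean depth 80, ω = 300, heterozygous SNPs every ~1.5 kb, segments cycling
2+1/2+2 states, single SNVs at multiplicity 1 (a typical late clonal
event) and planted parallel events clonal on all copies of both alleles;
a late-parallel mode (multiplicity 2) exists to demonstrate the VAF
caller's documented blind spot. Phased evidence draws pair classes from
the planted allele configuration with a symmetric per-position error
rate.

What the generator does *not* emulate bounds what green tests prove:
mapping artefacts, strand- and position-dependent sequencing error,
GC-coverage waves, subclonal structure and copy-number mis-segmentation
are absent, so passing spike-in recovery demonstrates correctness of the
statistical machinery under its own assumptions, not robustness to real
data pathologies — that is what the filter cascade and guards are for,
and they are exercised by constructed trap fixtures instead.

## Numerical choices and scales

Beta-binomial pmfs are computed in log space via `lchoose`/`lbeta` and
summed exactly (tests require 1e-12 agreement with an independent
recurrence oracle up to depth 200). Two-sided p-values double the smaller
tail, capped at 1. Replicate seeds derive deterministically from the run
seed, so replicates are reproducible and order-independent. Segment
assignment is 1-based inclusive with boundary ties going to the left
segment. BED input is converted from 0-based half-open on load and back
on write.

Simulation sizes in the tests and analysis scripts (e.g. 1,000 replicates
for birthday agreement on a 10⁴-locus toy, 10⁴ replicates for the
squared-spectrum check on a two-channel toy, 300 replicates per sample in
the demonstration cohort) were chosen as the smallest scales at which the
Monte-Carlo standard errors are well below the effect sizes being
checked; the study-scale default of 1,000 replicates per sample is kept
as the package default.

## Known limitations

* The VAF caller is blind to parallel events with multiplicity below the
  major copy number and in LOH regions; phasing covers the former but not
  the latter.
* ω calibration is unreliable above ~600 at typical depths (flat QQ-slope
  surface); the clamp at 1,000 marks effectively binomial samples.
* Neighbour resampling treats input records as single events,
  underestimating violations when inputs are already biallelic.
* The squared-spectrum prediction uses the abundance-corrected form
  `p²/f` (the collision-probability derivation); the raw `p²` variant is
  available behind a toggle for comparison.
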