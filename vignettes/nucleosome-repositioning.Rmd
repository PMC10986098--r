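---
title: "Estimating nucleosome spacing and repositioning from MNase fragment maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating nucleosome spacing and repositioning from MNase fragment maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrlkit)
```

## The measurement model

Paired-end sequencing of MNase-protected chromatin (or of cell-free DNA)
yields fragment intervals whose boundaries are set by nuclease cuts in
linker DNA. Throughout the package a fragment is the triple
(chromosome, start, end) in 0-based half-open coordinates; its *dyad* —
the presumed nucleosome centre — is `start + floor(length / 2)`. Two
assumptions underlie everything downstream:

1. *Fragment length encodes particle type.* Core particles protect
   ~147 bp, chromatosomes (core plus linker histone) ~160–180 bp,
   subnucleosomal particles less, dinucleosomes ~300+ bp. Analyses that
   target mono-nucleosomes therefore restrict to a length band, by
   default `[120, 180)` bp. Bands are lower-inclusive, upper-exclusive so
   the canonical 20-bp fractionation bins (100–120, …, 180–200) are
   disjoint and partition `[100, 200)`: the conventional notation is
   ambiguous at shared endpoints and an exact, testable rule is needed.
2. *Regular spacing leaves a periodic signature in dyad distances.* In a
   phased array with repeat length $L$, dyad pairs sit near distances
   $L, 2L, 3L, \dots$ The distribution of all pairwise dyad–dyad
   distances up to $D = 2000$ bp (the *phaseogram*) therefore oscillates
   with period $L$.

## The NRL estimator

`estimate_nrl()` composes the full pipeline:

size-band filter → optional region restriction (a fragment participates
when its dyad lies inside a region, so distances reflect intra-region
spacing) → per-chromosome read cap → dyad track → stacked-position
filter → phaseogram → peak detection → regression.

Parameters, with defaults and the reasons for them:

| parameter | default | role |
|---|---|---|
| `size_band` | `[120, 180)` bp | mono-nucleosome band; dinucleosomes would add half-period harmonics |
| `max_distance` | 2,000 bp | ~10 repeat lengths; beyond this, phasing has decayed in real chromatin |
| `stack_cutoff` | 50 dyads/bp | positions with *more* than this many co-centred fragments are removed entirely (not capped): extreme pileups are amplification/mapping artefacts, and removal is reported to be insensitive to the exact cutoff, which the tests verify on synthetic data |
| `max_reads` | 4×10⁷ per chromosome | keeps pair counting tractable on deep samples; subsampling is uniform without replacement under an explicit seed (the scheme is otherwise unconstrained, so a reproducible one was fixed) |
| `min_pairs` | 10⁴ | a chromosome enters the genome average only with this many weighted pairs; thinner curves are dominated by noise |
| `smooth_halfwidth` | 10 bp | centred moving average (21-bp window) before peak picking |
| `min_separation` | 100 bp | well below any plausible NRL; suppresses ripple after smoothing. On conflict the higher peak wins; exact ties go to the leftmost |
| `min_rel_prominence` | 0.15 | see below |
| `max_peaks` | 10 | peaks used in the regression, leftmost first |

Distance 0 (co-located dyads) is tallied but excluded from the normalised
curve: it measures stacking, not spacing. Each chromosome's curve is
normalised to unit mass before an *unweighted* average across
chromosomes, so one large chromosome cannot dominate the genome estimate.

The NRL is the slope of OLS of peak position on peak order with a free
intercept. The intercept absorbs a constant offset of the whole peak
train (e.g. from linker asymmetry or envelope tilt), which would bias a
through-origin slope; R² is reported so callers can gate fit quality.
Degenerate inputs fail loudly: fewer than three detected peaks, or no
chromosome passing `min_pairs`, abort with a clear message rather than
returning an unusable estimate.

### Why a prominence gate

Automatic peak picking must decide which local maxima of the smoothed
curve are phasing peaks. Where the phased signal has decayed (large
distances), sampling fluctuations and weak long-range structure still
produce local maxima; if those entered the regression the peak indices
`k` would no longer be consecutive multiples and the slope would be
badly corrupted. Peaks are therefore required to have topographic
prominence at least `min_rel_prominence` (default 0.15) of the most
prominent peak. On synthetic data the two populations are well
separated — genuine array peaks keep relative prominence ≳ 0.23 down to
the fifth harmonic, while tail ripple stays ≲ 0.09 — and a damped-cosine
curve retains all ten harmonics above the gate. Interactive protocols
resolve this step by manual curation; the gate is this package's declared
automatic replacement, and its value is logged with every estimate.

### Paired comparison

`compare_paired_nrl()` pairs per-sample estimates by patient (plus any
extra key columns such as assay), takes differences
`condition_a − condition_b`, and applies a paired two-sided t test
(`stats::t.test`). Zero-variance differences are reported as degenerate
with no p-value instead of an infinite statistic.

## Discrete repositioning calls

All matching uses bedtools `intersect` fraction semantics: the integer
overlap (half-open intervals; abutment is zero) is compared with `>=` to
the *unrounded* real threshold `f × length` — 0.99 × 150 = 148.5, so a
149-bp overlap qualifies and no rounding rule is needed.

* **stable** — reproduced at `f = 0.99` of the fragment's own length
  (non-reciprocal) in ≥ 1 other patient of the same condition and assay.
  Assays are not pooled by default: whether pooling is appropriate
  depends on the experiment, so it is left to the caller.
* **common / shifted** — computed independently from the stable reference
  set: common needs a 0.99 non-reciprocal match in the other condition;
  shifted needs *no* reciprocal 0.80 match. Fragments whose best overlap
  falls between 80% and 99% carry neither label — the definitions imply
  a gap, and the classes are deliberately not a partition.
* **gained / lost** — zero-overlap (not even 1 bp) against every stable
  fragment of the other condition, symmetric under swapping conditions.

Interval queries run on IRanges; the package's tests require exact
agreement with a brute-force all-pairs oracle on random inputs, so the
indexed path is an optimisation, never a semantic change.

## Aggregate profiles

Occupancy profiles accumulate per-bp fragment coverage in
`[centre − flank, centre + flank]` (default flank 2,000 bp) over all
features, reverse minus-strand windows when strand is present, then
optionally normalise to fragments-per-million (using the sample depth
*before* any restriction) and smooth (10-bp default). Feature centres use
the same floor-midpoint rule as dyads for cross-module consistency.
Profiles are summed over features by default — summation makes mass
conservation an exactly testable property — with a per-feature-average
flag for the familiar normalised shape. ChIP profiles are
input-normalised by pointwise ratio, masking offsets whose input is ~0
(masked values propagate through averaging as available-case means, not
as zeros). Methylation profiles sum per-CpG beta values at each offset
over all (CpG, feature) pairs with no normalisation: the output is in
arbitrary units and linear in beta by construction.

## Enrichment

The chance model for `fisher_enrichment()` is length-preserving uniform
re-placement of each query interval on its own chromosome (rejection
sampling against an optional exclusion set), pooled over 10 shuffles by
default. Same-chromosome placement was chosen over genome-wide relocation
because chromosome composition differs; an analytic bp-overlap model is
the main alternative, and interval-count semantics were preferred here
because the query sets are discrete nucleosome calls. The p-value is the
standard two-sided Fisher exact test (sum of all tables at most as
probable as the observed one) on the pooled 2×2 table; the fold uses the
raw pooled random rate. Zero random overlap reports an infinite fold with
the p-value from the degenerate table.

## The synthetic cohort generator

The generator produces the structure the analyses assume, with known
truth, so every stage can be validated end to end:

* **Arrays.** Each chromosome is tiled with phased arrays spanning
  1,000 bp (≈ 6 nucleosomes at the default spacing), separated by gaps
  drawn uniformly from `[300, 900]` bp. Randomised gaps prevent spurious
  long-range coherence between arrays. Normal-condition dyads sit at
  `anchor + k·L_normal` plus shared Gaussian jitter (sd 10 bp, rounded
  half-away-from-zero — a fixed rule so reruns are byte-identical).
* **Conditions.** The tumour map re-spaces each array at
  `L_tumour = L_normal − 7` about the array centre. Centre anchoring
  bounds the per-locus drift at ±2.5 spacings × Δ (≈ 17 bp), so conserved
  loci remain recognisably the same nucleosome — which is what makes
  gained/lost/shifted truth well defined per locus — while the spacing
  signal carries the full Δ. The 7-bp default sits in the middle of the
  range the paired-tissue comparison is designed to detect.
* **Events.** Per locus: lost (5%) removes the tumour copy; shifted (5%)
  displaces it by 30–60% of 147 bp with random sign (≥ 25% guarantees a
  reciprocal-0.80 failure); gained loci (5%) are placed in inter-array
  gaps with ≥ 274 bp clearance from both maps so the zero-overlap rule is
  satisfiable by construction. Patients reproduce each base position
  exactly with probability 0.9, else deviate by ≤ 3 bp.
* **Fragments.** Poisson(20) fragments per nucleosome per sample; lengths
  from a four-component mixture — subnucleosomal (130 ± 10, 15%), core
  (147 ± 7, 45%), chromatosome (168 ± 8, 20%), dinucleosome
  (320 ± 20, 20%) — matching the ~80:20 mono/di abundance the wet
  protocol targets; mono centres jitter around the dyad with sd 5 bp;
  dinucleosome fragments span adjacent dyads. Lengths are clipped at
  50 bp to avoid degenerate intervals.
* **Methylation.** CpGs (real CG dinucleotides when sequence is
  generated) within 74 bp of a retained dyad draw beta ~ N(0.8, 0.1),
  near shifted dyads N(0.2, 0.1), background uniform — reproducing the
  qualitative contrast between retained and repositioned nucleosomes.

Everything is a pure function of the configuration: stage-specific seeds
are derived deterministically from the master seed, and the cohort
manifest records MD5 checksums.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data: sequence-dependent nucleosome affinity and
MNase sequence bias; mappability artefacts; realistic chromosome counts
or coordinates; mixed cell populations and tumour purity; phasing decay
around boundaries rather than hard array edges; patient-to-patient
biological heterogeneity beyond small positional noise. Parameter
recovery here demonstrates correctness of the estimators under their own
model, not robustness to everything real tissue does.

## Validation scale and numerical notes

The shipped tests validate: phaseogram counting against O(n²)
enumeration (100 random tracks, ≤ 5,000 dyads); spacing recovery within
2 bp for true L ∈ {180, 190, 200} on two 5-Mb chromosomes with ≥ 10⁵
fragments; the paired 7-bp shortening over three patients (and a flat
Δ = 0 null); classification against a brute-force oracle (100 seeds) and
against planted truth (recall ≥ 0.9 gained/lost, ≥ 0.8 shifted);
the exact test against direct hypergeometric enumeration (to 10⁻⁹) and a
null fold calibration within 1 ± 0.2; profile mass conservation; and
byte-identical reruns of every stochastic stage. These problem sizes keep
the whole suite to a few minutes on a single core while leaving each
statistic comfortably above its noise floor.

Remaining numerical conventions, chosen once and fixed: dyads and feature
centres floor the midpoint (symmetric alternatives shift phaseograms by
≤ 1 bp but break exact tests); per-gene fragment density counts a
fragment by dyad membership so each fragment counts exactly once;
"running 10-kb window" GC classification uses non-overlapping tiles
(the final partial tile is kept when ≥ half a window, all-N tiles are
unlabelled, and N bases are excluded from both numerator and
denominator); region families follow the published definitions exactly
(TSS ± 5,000 windows from stranded TSSs, gene bodies with
1 kb < length < 200 kb strict, ± 1,000 bp padding clipped at chromosome
ends, top/bottom-3,000 selection by score).

## Limitations

The estimator reports a single genome-wide (or region-restricted) NRL
per sample; it does not model mixtures of spacings within a region set.
The classification is two-condition; multi-condition designs require
repeated pairwise runs. The enrichment chance model keeps chromosome
identity, so it cannot detect enrichment *of* chromosomes. The package
deliberately stops upstream of read mapping: BAM/CRAM handling, duplicate
marking and mappability correction are out of scope, and fragment BEDs
are taken as given.
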