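# nrlkit

Nucleosome repeat length (NRL) estimation and discrete nucleosome
repositioning analysis for paired-end MNase-derived fragment maps —
MNase-seq, MNase-assisted histone ChIP-seq, or cell-free DNA fragment
intervals supplied as BED.

## What it is for

Micrococcal nuclease (and the endogenous nucleases that generate cfDNA)
cut chromatin in linker DNA, so the protected fragments that get sequenced
trace nucleosome positions. Two kinds of chromatin change are of interest
when comparing paired samples (e.g. tumour versus adjacent normal tissue
from the same patient):

* **global spacing changes** — the average centre-to-centre distance
  between neighbouring nucleosomes (the NRL) can shrink or grow by a few
  base pairs genome-wide;
* **discrete repositioning** — individual nucleosomes that are stably
  positioned across patients can be retained, shifted, gained or lost
  between conditions.

`nrlkit` implements both analyses as composable, tibble-in/tibble-out
functions, plus the surrounding machinery: fragment-size fractionation,
aggregate occupancy and DNA-methylation profiles around genomic features,
interval enrichment against a chance model, and a synthetic-data generator
with ground truth used to validate every stage.

## The statistics at the core

**NRL from a dyad-distance phaseogram.** Each fragment is reduced to its
dyad (midpoint, `start + floor(length/2)`). For dyad positions on each
chromosome, the frequency of pairwise dyad–dyad distances `d = 1..2000` bp
is computed at single-bp resolution (all pairs, weighted by per-position
multiplicity), normalised per chromosome and averaged. Phased nucleosome
arrays make this curve oscillate with period equal to the NRL: peaks sit
near `p_k ≈ k·NRL`. Peaks are detected on the smoothed curve (local maxima
with a minimum separation and a prominence gate) and the NRL is the slope
of the ordinary least-squares regression of `p_k` on `k` with free
intercept. Filters mirror the established protocol: fragments in the
120–180 bp mono-nucleosome band, positions with more than 50 stacked
dyads discarded, at most 40 million reads per chromosome. Paired
conditions are compared with a paired two-sided t test on per-patient NRL
values.

**Discrete classification.** With fragment sets from several patients in
two conditions, a fragment is *stable* when reproduced at ≥ 99% of its
length in at least one other patient (bedtools `-u -f 0.99` semantics).
Between the conditions of one patient, a stable reference fragment is
*common* when matched at ≥ 99% in the other condition, *shifted* when it
has no reciprocal 80% match there (`-f 0.80 -r -v`), and *lost* when it
overlaps no stable fragment of the other condition by even one base pair;
*gained* is the symmetric zero-overlap call in the other direction.

**Enrichment.** Fold enrichment of a query interval set in an annotation
is the observed overlap rate over the rate in length-preserving,
same-chromosome random placements (pooled over shuffles), with a
two-sided Fisher exact test on the pooled 2×2 table.

## Worked example

Generate a three-patient paired cohort (true NRL 193 bp normal, 186 bp
tumour) and estimate the NRL of one sample:

```r
library(nrlkit)

cohort <- generate_cohort(synthetic_config(seed = 1, with_sequence = FALSE))
frags  <- dplyr::filter(cohort$fragments, patient == "P1")

est <- frags |>
  dplyr::filter(condition == "normal") |>
  estimate_nrl(phaseogram_config(seed = 1))
est
#> <nrl_estimate> NRL = 194.2 bp (5 peaks, R² = 1)
glance(est)
#> # A tibble: 1 × 5
#>     nrl intercept r_squared n_peaks n_fragments
#>   <dbl>     <dbl>     <dbl>   <int>       <int>
#> 1  194.     -1.60     1.000       5       39774
```

The estimate lands within ~1 bp of the planted 193 bp spacing.
`autoplot(est)` shows the peak-order regression, and
`autoplot(est$phaseogram)` the oscillating distance curve. Running all six
samples through `run_end_to_end()` yields the per-sample table, the paired
comparison, per-patient classification and recovery of the planted events:

```r
report <- run_end_to_end(cohort = cohort)
report$nrl_table        # 6 per-sample NRL estimates
report$comparison       # paired t test, normal - tumour
report$class_recovery   # recall/precision against planted truth
```

On this cohort the paired mean difference is ~7.6 bp (all three patients
positive) and gained/lost planted events are recovered with recall ≥ 0.97
at precision 1.0.

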