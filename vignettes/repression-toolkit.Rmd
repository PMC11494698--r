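---
title: "Quantifying and designing plant transcriptional repression motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and designing plant transcriptional repression motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(represskit)
```

## The problem

Short peptide motifs of the EAR family (canonical patterns `LxLxL` and
`DLNxxP`) turn plant transcription factors into repressors, largely by
recruiting the TOPLESS corepressor. Characterizing such motifs at scale is
done with a transient reporter assay: each candidate motif is fused to the
Gal4 DNA-binding domain, co-infiltrated into *Nicotiana benthamiana* leaves
with a GFP reporter under a Gal4-responsive promoter, and read out as leaf
fluorescence. The Gal4 domain alone sets the no-repression baseline; the
engineered 12-residue SRDX motif is the standard strong-repressor control.

`represskit` implements the complete computational side of such a study:

1. **Quantification** of plate-reader fluorescence into per-construct
   repression summaries relative to the Gal4 baseline.
2. **Sequence analysis**: canonical-pattern scanning with exact enrichment
   tests, length-strength analysis, and rank-based post-hoc comparisons.
3. **n-gram classification**: amino-acid 2/3/4-grams tallied per strength
   quartile and labelled strong, moderate, or weak.
4. **SynEAR generation**: synthetic repression motifs assembled from
   classified grams in four predicted strength classes.
5. **Prediction evaluation**: accuracy-maximizing ordinal binning, a
   confusion matrix, and permutation and random-guessing null models.
6. A **synthetic-data module** that simulates the assay (and a qPCR
   ΔΔCq fixture) with known ground truth, so every stage runs and is
   testable without wet-lab data.

The numbered scripts under `analysis/` run these stages in order from a
single master seed; this vignette explains the models and the design
choices behind them.

## Quantification model

The assay produces a long table of fluorescence reads: per construct,
3 plants (biological replicates) × 8 leaf disks (technical replicates).
Technical replicates are averaged first, so each plant contributes one
biological value; construct summaries are computed over biological values
only:

- `mean_fluor` — mean of the per-plant values;
- `sem` — sample standard deviation over plants divided by √n (undefined
  and reported as `NA` with a single plant);
- `relative_gfp` — `mean_fluor` divided by the Gal4 control's mean;
- `is_repressor` — `relative_gfp ≤ 0.5`, i.e. at least 50% GFP reduction.
  The boundary is included so the rule is deterministic.

Constructs with `relative_gfp > 1` (apparent activators) are retained and
flagged, never classified as repressors. For comparisons across libraries
measured in different experiments, `normalize_cross_library()` applies the
affine two-anchor map that sends Gal4 to 0 and SRDX to 1; scores above 1
(stronger than SRDX) and below 0 (activation) are meaningful and kept.
Since the anchors are library-specific means, the Gal4 reference is always
computed within the library being normalized, never globally.

qPCR relative expression uses the ΔΔCq model with amplification efficiency
fixed at exactly 2 (no efficiency calibration): per sample,
`ΔCq = Cq_target − Cq_reference`, expression `2^(−ΔCq)`, rescaled so the
wild-type mean is exactly 1.

## n-gram classification

Constructs (controls excluded) are ranked by repression strength
`1 − relative_gfp` and split into four near-equal quartiles, Q1 strongest;
a remainder goes to the stronger quartiles first, and ties break by
construct id so the partition is deterministic. Every sequence is
decomposed into all overlapping 2-, 3- and 4-grams and tallied per
quartile. Representation is measured as a ratio of frequencies rather than
raw counts — within-quartile frequency (count over the quartile's total
grams of the same length) divided by the pooled frequency — because the
quartiles' total sequence lengths differ, and only frequencies are
scale-free. The class rules:

- **strong**: at least 2× over-represented in Q1 (`ratio ≥ 2`) *and*
  under-represented in Q4 (`ratio < 1`);
- **weak**: the mirror image (`ratio_Q4 ≥ 2`, `ratio_Q1 < 1`);
- **moderate**: within ±25% of the pooled frequency in *all four*
  quartiles;
- everything else, including grams whose ratios are undefined because a
  quartile has no grams of that length, is unclassified.

No pseudocounts are used; degenerate quartiles produce `NA` ratios and a
warning rather than an imputed value. Tallying is per occurrence (one per
start position, overlaps allowed), not per construct.

## SynEAR generation

Synthetic motifs are assembled per predicted class by drawing grams
uniformly from the class's set and concatenating until the target length
is reached; the final gram is truncated so the length is exact (truncation
guarantees termination; rejection sampling would not). Target lengths for
the weak, moderate and strong classes are drawn from the empirical length
list of the natural library; the *strongest* class — strong grams with a
longer length distribution, reflecting the observed length-strength
relationship in natural EARs — uses `round(1.5 × natural length)`. The
factor is exposed in `synear_spec()`. Gram sampling is uniform rather than
frequency-weighted (the simplest reading of random concatenation;
weighting can be layered on by repeating grams in the set). Duplicate
sequences are regenerated within a bounded retry budget; a class that
cannot reach its requested count (e.g. a single-gram class) returns a
partial library with a warning rather than failing the run.

## Prediction evaluation

Measured repression is continuous, so observed classes require three
thresholds. `optimize_thresholds()` maximizes binning accuracy against the
predicted classes by exhaustive search over cut positions between
consecutive sorted distinct values (plus outer caps). This search provably
contains a global optimum — accuracy only changes when a threshold crosses
a data value — and is deterministic, with ties broken toward the
lexicographically smallest cut triple; degenerate solutions with empty
classes are allowed. Because candidates are value midpoints, the achieved
accuracy depends on the observations only through their ranks.

Binning is half-open: a value exactly at a threshold goes to the upper
class. The confusion matrix is predicted × observed over the four classes;
accuracy is its normalized trace. Two null models are run with the fitted
thresholds held fixed:

- **Permutation null** — observed class labels are shuffled uniformly;
  its closed-form mean is `Σ_c n_pred(c)·n_obs(c)/n²`.
- **Random-guessing bootstrap** — n independent uniform guesses over the
  four classes per run; mean accuracy 0.25 regardless of the observed
  label distribution, with per-run SD `√(0.25·0.75/n)`.

Each null reports its mean and SD, the percentage of null runs the real
accuracy outperforms, an empirical two-tailed p-value with the +1
correction (`2·min((k_ge+1)/(N+1), (k_le+1)/(N+1))`, capped at 1), and a
normal-approximation two-tailed p-value. Both p-value conventions are
reported because neither alone is canonical. Evaluation operates on
per-construct means; evaluating at replicate level would shrink the null
SDs by roughly the root of the replicate count.

## Sequence similarity

Percent identity uses Needleman–Wunsch global alignment (match +1,
mismatch −1, one point per gap column, no free end gaps) via `Biostrings`,
with identity defined as identical aligned columns over the *full*
alignment length including gap columns — the most conservative common
denominator, which can only lower identities. Co-optimal alignments can
differ in identity; the reported value is the one attained by the
alignment the aligner returns, and the test suite checks it against the
set of optima by exhaustive enumeration on short sequences.

## The synthetic-data model

The generator is the package's stand-in for the wet lab, and its defaults
define the study conditions used throughout the tests and the acceptance
script: 84 natural-library motifs plus Gal4/SRDX controls, 80 SynEARs (20
per class), 3 plants × 8 disks, planted effect size 0.3, and log-scale
biological and technical noise SDs of 0.05.

A `ground_truth_model` plants three disjoint gram sets: *strong* grams
(each occurrence contributes −0.3 to a latent effect sum), *weak* grams
(+0.3), and two *neutral family dipeptides* with no effect. A motif's true
repression strength maps the latent sum through a bounded logistic link
onto `[−0.6, 1]` (fraction of GFP reduction; negative values are
activation; a motif with no planted grams sits at 0.2). The link's scale
(0.6 latent units) is set so a handful of gram occurrences traverses the
assay's observed dynamic range, from ~50% activation to >90% repression.
Simulated fluorescence is
`exp(baseline + log(1 − strength) + bio + tech)` with lognormal noise at
the plant and disk levels (fluorescence is positive and heteroskedastic,
so multiplicative noise is the natural model); at zero noise the
quantification recovers `relative_gfp = 1 − true_strength` exactly.

Motif composition is a polarized mixture: 35% repressor-type motifs
(tokens are strong grams with probability 0.8, else background residues
at natural amino-acid frequencies), 35% activator-type (same with weak
grams), 30% inert (background only). Polarization matters because the
classifier reads per-quartile *frequencies*: if strong and weak constructs
had the same planted-gram density, the frequency ratios would carry no
signal regardless of effect size. The neutral dipeptides are added to
every motif in a deterministic, roughly length-proportional dose
(alternating over the set in short motifs), inserted at token boundaries
so assembly units stay intact. They emulate family-typical residue content
shared across strength levels — which is exactly what the ±25% "moderate"
band can legitimately detect; without them, no gram reaches the band's
count requirements at n = 84 and the moderate class is empty.

What the generator deliberately does **not** emulate:

- the real library's *repressor fraction* (53/84 in a library mined for
  putative repressors): the balanced mixture yields ~10–30 repressors of
  84, so headline repressor counts are not comparable;
- a built-in length-strength correlation: length amplifies planted effects
  symmetrically in both directions, so the library-wide rank correlation
  is near zero rather than positive;
- canonical-motif content: random sequences rarely contain `LxLxL` or
  `DLNxxP`, so the dual-motif enrichment test is usually degenerate on
  simulated data (the scripts narrate this);
- plate, edge or leaf-position effects, Agrobacterium titer, and plasmid
  copy number.

Passing tests on this generator therefore demonstrate that the *methods*
are correct (oracle equivalence, closed-form moments, parameter recovery,
determinism), not that the biological effect sizes of any particular real
dataset are reproduced.

## Numerical choices and degenerate inputs

- All randomness flows from one master seed via `fanout_seeds()`; seeded
  functions restore the caller's RNG state.
- Repressor threshold inclusive at exactly 0.5; binning half-open with the
  boundary going up; quartile remainders to the stronger quartiles; all
  ties broken by id — every boundary rule is deterministic.
- The exact 2×2 test sums hypergeometric point probabilities with a
  `1 + 1e-7` relative guard (the standard protection against floating
  ties); the two-sided value uses the minimum-likelihood convention.
- The Dunn test applies the standard rank tie correction
  `Σ(t³−t)/(12(N−1))`; groups with fewer than two values are excluded with
  a warning; with identical values in all groups the statistic is
  undefined (0/0) and propagates as `NaN` rather than being masked.
- `true_strength = 1` would send `log(1 − s)` to −∞; reads are clamped at
  a configurable fraction of baseline (default 10⁻⁴) and flagged.
- An empty quartile yields `NA` ratios, a warning, and unclassified grams
  — never a silent pseudocount.

## Worked example

```{r example}
res <- run_pipeline(seed = 1, n_perm = 1000, n_boot = 1000)
rec <- strong_gram_recovery(res$ngram_table, res$model)
rec$recovered / rec$eligible
res$eval
```

The permutation and bootstrap null means sit at ~25%, the planted strong
grams are recovered, and the model accuracy exceeds both nulls' 95th
percentiles — the behaviour the acceptance suite checks over many seeds.

## Problem sizes

The test suite and `scripts/acceptance.R` run the pipeline at the study
scale described above (84 + 80 constructs, 1000 + 1000 null iterations),
with ten independent seeds for the recovery properties; brute-force oracle
comparisons use instances of at most 12 values (threshold search, Dunn),
margins of at most 30 (exact 2×2 enumeration) and sequences of at most 6
residues (alignment enumeration), the sizes at which exhaustive
enumeration is itself trustworthy.

## Known limitations

- The moderate gram class is intrinsically small at n = 84; single-gram
  classes can exhaust the uniqueness retry budget and return a partial
  SynEAR library (with a warning and an `incomplete` attribute).
- Identity percentages depend on the alignment convention; with a
  different denominator (e.g. shorter-sequence length) values can be
  higher. The scheme here is fixed and documented.
- ΔΔCq assumes perfect doubling per cycle; no efficiency calibration is
  performed.
- The threshold search is exhaustive over `O(m³)` cut triples; for the
  library sizes involved (m ≤ ~250 distinct values) this is inexpensive,
  but it is not intended for thousands of constructs.
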