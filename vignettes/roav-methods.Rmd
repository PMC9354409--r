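---
title: "Scoring aroma contributions with relative odor activity values"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring aroma contributions with relative odor activity values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roavtools)
```

## The problem

A fermentation headspace contains dozens of volatiles, but perceived aroma is
not proportional to abundance: humans detect some compounds at nanogram
levels and others not at all. Untargeted GC-MS gives peak areas; deciding
which compounds actually drive an aroma, and how two strains differ in their
key contributors, requires weighting abundance by human odor detection
thresholds. `roavtools` implements that analysis for identified-compound
tables — peak picking, spectral matching, and quantitation are upstream of
this package — together with the complementary electronic-nose view of the
same samples.

The bundled example data are the volatile profiles of two
*Geotrichum candidum* strains (a wild dairy-type isolate and a mutagenized
derivative) fermented in potato dextrose broth, with the uninoculated medium
as blank control.

## Relative content

Within one sample group, a compound's **relative content** is its share of
the summed peak areas:

$$X_i = \frac{A_i}{\sum_j A_j} \times 100\,\%$$

over the detected compounds of that group. `relative_content()` performs
this normalization per group; non-detections (`NA`, written `-` in files)
stay missing and are excluded from the denominator. The operation is
idempotent and invariant to rescaling a group's areas by any positive
constant, which the test suite checks by property.

Published relative-content tables are rounded to two decimals, so their
columns rarely sum to exactly 100. The validator therefore warns rather than
errors when a group's sum deviates from 100 beyond `sum_tol` (default 0.5).
The bundled transcription deviates by up to ~3 (its printed class totals
confirm the columns were typeset that way), so `geotrichum_peaks()` loads it
with `sum_tol = 3.5`; the deviation is a property of the source table, not
of the arithmetic here.

## Detection thresholds

Thresholds come in three syntaxes: a point value (`3`), an interval
(`3–5`), and an approximate value (`≈2.2`). All three survive a
read–write–read round trip. Two conventions matter:

* **Units.** Thresholds are published in µg/L (aqueous solutions) and µg/kg
  (food matrices). For dilute aqueous fermentation broths (density ≈ 1 kg/L)
  the magnitudes are numerically equivalent, and mixed-unit tables can only
  be scored under that equivalence; `normalize_threshold()` makes the
  convention explicit and auditable.
* **Name matching** is exact after case folding and whitespace collapsing.
  No fuzzy matching: a silent join to the wrong compound corrupts every
  downstream score, whereas a loud `NULL` is visible.

### Inferring unknown ester thresholds

Short-chain ester thresholds vary systematically with carbon-chain length,
so an ester without a literature threshold can be bracketed between
structurally adjacent esters. The choice of reference homologs is a
judgement call — structural analogy, not carbon count alone (a same-carbon
compound can be a threshold outlier and be deliberately passed over) — so
`roavtools` ships the bracket map as *curated data*, not as an algorithm:
five formula rules (C6H10O2 → 3–5 µg/L, C7H12O2 → 1–3 µg/L, C9H16O2 →
2–2.2 µg/L, C7H14O2 → ≈3 µg/L, C9H18O2 → ≈2.2 µg/L) that callers can extend.
`infer_threshold()` refuses formulas absent from the map (`roav_no_bracket`
error) rather than guessing; reproducibility beats coverage here.

## ROAV scoring

The **relative odor activity value** of compound $A$ in a group is

$$\mathrm{ROAV}_A = \frac{C_A}{C_{stan}} \cdot \frac{T_{stan}}{T_A} \times 100$$

where $C$ is relative content, $T$ the detection threshold, and *stan* the
**reference compound**: the detected compound maximizing $C/T$, i.e. the
strongest contributor to the overall aroma, which scores exactly 100.
ROAV is a within-sample ranking device — it needs no absolute
quantitation because the unknown conversion from relative content to
concentration cancels in the ratio.

Implementation decisions:

* **Reference selection** (`select_reference()`) considers only compounds
  with point-like thresholds (point or approx): an interval-threshold
  reference could not pin the scale to a single 100. Ties prefer `point`
  over `approx` entries, then alphabetical order.
* **Interval thresholds** propagate to ROAV intervals with swapped
  endpoints (ROAV is anti-monotone in $T$): a 3–5 µg/L threshold yields a
  score printed `2.42–1.45`. Classification and ranking use the *upper*
  endpoint `roav_high` (the score at the lower threshold bound) — the
  compound's maximal plausible contribution.
* **Classes scored.** Scoring covers esters, alcohols, and aldehydes by
  default; the `other` class (hydrocarbons such as benzene, and alkanes
  generally) has detection thresholds so high that it cannot contribute
  perceptible odor and is excluded from ROAV tables, while still counting
  toward detection totals.
* **No silent drops.** Detected compounds without any known or inferable
  threshold stay in the table with `NA` ROAV and class `potential`.

### Classification bins

The OAV convention calls a compound a likely aroma contributor above 1, a
modifier between 0.1 and 1, and sub-perceptual below 0.1. Published ROAV
tables in this domain, however, routinely list scores of 0.01–0.06 among
the modified compounds, which is only consistent with a lower
potential/modified boundary. `roav_bins()` therefore defaults to
`key_min = 1`, `potential_max = 0.01`, and both boundaries are arguments,
so the conventional 0.1 bound is one call away. Classification always uses
unrounded scores; the two-decimal rendering is display-only.

The bundled tables carry a handful of internal inconsistencies typical of
typeset tables (one ROAV that recomputes 0.04 higher than printed; two
borderline compounds whose printed class contradicts their printed score).
`roavtools` reports what the formula gives from the printed inputs and does
not special-case those rows.

## Comparing strains

`compare_key_compounds()` separates two questions that are easy to
conflate:

* **Detection difference** — `unique_key_a/b`: key in one strain and *not
  detected* in the other. These compounds can explain a genuinely different
  aroma character (here: two fruity esters unique to the wild strain
  versus phenylethyl alcohol, rose-like floral, unique to the mutant).
* **Classification difference** — `downshifted_a/b`: key in one strain but
  detected at sub-key ROAV in the other; a difference of degree.

With `shared_key` these partition each strain's key set, the comparison is
exactly symmetric under swapping inputs, and comparing tables classified
under different bins is refused. `aroma_note_summary()` aggregates the
free-text odor descriptors of each key set by token frequency (comma-split,
lowercased, missing → `unlabeled`) — deliberately a description, not a
score, since no odor ontology is attached.

## Electronic-nose analysis

A 10-sensor metal-oxide array (PEN3 layout, `pen3_sensors`) gives one
response vector per measurement; replicates per group form the analysis
matrix.

* **PCA** (`enose_pca()`) is mean-centered covariance PCA: the sensors share
  a response scale, so correlation scaling would discard real magnitude
  information (`use_correlation = TRUE` is available). Explained ratios are
  eigenvalue shares of total variance; component signs are fixed so each
  axis's largest-magnitude loading is positive.
* **LDA** (`enose_lda()`) solves the generalized eigenproblem of
  between-group versus within-group scatter, with a relative ridge
  (`1e-8 × trace(S_W)` on the diagonal) so few-replicate and zero-noise
  matrices stay solvable. At most `groups − 1` axes exist; explained ratios
  are eigenvalue proportions and sum to 1 over the full axis set. The tests
  check both PCA and LDA against independent oracles (direct
  eigendecomposition; a whitening-based solve; `MASS::lda` proportions).
* **Radar and ratios.** `radar_profile()` is the per-sensor group mean;
  `response_ratio()` divides it by the blank-control mean, the standard way
  to express fermentation-induced response; `strong_responders()` flags
  sensors above a documented heuristic cutoff (ratio > 2).

The study that motivated this package printed near-total first-axis
dominance (PC1 ≈ 99.9%) for its sensor data, but the underlying raw
matrices are unpublished, so those percentages cannot be recomputed and are
treated as qualitative context. The package's claims about its ordination
code are therefore property-based: oracle equivalence, ratio normalization,
and recovery of group structure planted by the simulator.

## The synthetic-data generator

`simulate_peak_table()` and `simulate_sensor_matrix()` generate data with
the statistical structure the analysis assumes, plus a ground-truth record,
so every stage is testable without external data.

* **Peak areas** are log-normal (the standard heavy-tailed model for
  chromatographic intensities), one base area per compound, with per-group
  multiplicative log-normal noise (`noise_sd`, default 0.25; 0 makes groups
  identical).
* **Strain-unique compounds** are planted by presence masks — not by
  thresholding noise — so ground truth is unambiguous. Planted compounds
  get boosted abundance (×20) and a low point threshold (0.5 µg/L), making
  them key by construction; they are always esters, the class strain-unique
  markers belong to in fermentation volatiles.
* **Thresholds** are log-uniform over 0.1–316 µg/L, with 20% missing and
  15% known only as ±50% intervals, mirroring the coverage of real
  threshold compilations.
* **Sensor data** are group means plus i.i.d. Gaussian noise truncated at
  zero. The default means emulate the reported fermentation pattern: strong
  W1W/W1S/W2S/W2W/W5S responses, with strain W1W means at 5.15× and 4.27×
  the blank.
* **Ground truth** is computed from the noiseless configuration by direct
  arithmetic in the generator, independent of the scoring code path it
  validates.

What the simulator does *not* emulate: retention behavior, co-elution,
censoring of low areas (missingness in real tables is
abundance-dependent), inter-sensor correlation of e-nose noise, and sensor
drift. Passing recovery tests therefore demonstrate correctness of the
scoring pipeline under the stated model, not robustness to those artifacts.

A single integer seed drives one documented random stream
(`withr::with_seed`), so identical configurations give identical bundles.

## Numerical and degenerate-input conventions

* Ties in `top_compounds()` and in ROAV ranking break by ascending compound
  name; reference-selection ties prefer point entries, then names.
* Scores are classified unrounded; files render two decimals and `-` for
  missing.
* All-missing or all-zero groups, constant sensor matrices, single-group
  LDA, zero blank means, inverted threshold intervals, and infeasible
  uniqueness configurations raise named errors early.
* Pipeline runs (`run_aroma_pipeline()`) validate every input path before
  writing anything, and identical inputs produce byte-identical outputs.

## Problem sizes

The test suite runs entirely on the bundled 38-compound tables, simulated
30-compound tables, and 18-row sensor matrices; the zero-noise recovery
property is swept over 20 seeds and the noise-degradation property over 12
seeds at three noise levels. These sizes keep the whole suite under a
minute while exercising every code path; all scale linearly if enlarged.

## Limitations

* ROAV inherits the limits of relative content: it ranks contributors
  within a sample but does not compare absolute intensity across samples.
* The µg/kg ≡ µg/L equivalence is an approximation that degrades for
  non-aqueous or fat-rich matrices.
* Threshold values are matrix- and panel-dependent; a different threshold
  compilation can reorder borderline compounds. Keep `source` tags in
  threshold files.
* Odor-note aggregation is token counting over free text; synonyms
  ("fruity" vs "pineapple") are not unified.
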