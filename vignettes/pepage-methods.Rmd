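---
title: "Methods and design notes for the pepage pipeline"
author: "pepage authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for the pepage pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepage)
```

# Scope and model

`pepage` implements the desk side of a CE-MS urinary peptidomics aging
study: everything downstream of the deconvolved per-sample peptide list
(mass in Da, CE migration time in min, signal amplitude in arbitrary
units).  Spectral acquisition, charge deconvolution and peptide
sequencing are instrument- and vendor-side concerns and are out of
scope; so is image segmentation for the histology quantities, whose
operations here consume already-measured areas.

The statistical model underneath the pipeline is deliberately modest:

* Amplitudes are treated as log-normal.  Screening uses only ranks, so
  this matters mainly for the synthetic-data generator and for the
  classifier's `log2(1 + a)` feature transform.
* Group comparisons are two-sample location problems handled by the
  Wilcoxon rank-sum statistic, standardized with the tie-corrected
  variance so peptides with different missingness patterns share a
  common |Z| scale.
* Multiplicity across peptides is controlled family-wise by the
  Westfall–Young maxT step-down permutation method, which uses the
  joint permutation distribution of the |Z| vector and therefore
  benefits from the strong inter-peptide correlation typical of urinary
  collagen fragments.
* The age model is a single soft-margin RBF-kernel hyperplane; the
  score is the signed kernel-space Euclidean distance to it.

# Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `ppm_low` / `ppm_high` | 50 / 150 | ppm | mass-match windows below 4 kDa / above 6 kDa; linear ramp between (so 100 ppm at 5 kDa) |
| `mig_tol_min_low` / `mig_tol_min_high` | 1.0 / 2.5 | min | migration-time window at the start / end of the run; CE drift grows with migration time, so the stated 1–2.5 min range is spread linearly across the run |
| `presence_threshold` | 0.3 | fraction | master peptides seen in fewer than 30 % of samples are dropped; no published rule exists, so it is explicit configuration |
| `C`, `gamma` | 3.2, 0.008 | — | published soft-margin cost and RBF width of the mouse aging model |
| `alpha`, `min_comparisons` | 0.05, 2 | — | a peptide enters the consensus panel when its adjusted p is below α in at least 2 of the 3 pairwise age comparisons |
| `n_permutations` | 10 000 | — | Monte-Carlo permutations per comparison; full enumeration of C(26,13) label assignments is infeasible, so permutation p values are declared Monte-Carlo and seeded |

# The synthetic-cohort generator

`generate_cohort()` is first-class, tested code, not a fixture.  It
emulates the reference study design: 3 age groups × 13 animals (optionally
crossed with treatment arms), a master list of 200 peptides plus 5
internal standards spread evenly across the migration range, and it
records ground truth (affected peptide ids, per-age mean log2
amplitudes, per-sample warp coefficients, per-sample intensity factors)
so every stage can be scored against what was planted.

Choices where no published value exists, fixed once:

* **Amplitudes** — log-normal; per-peptide baselines log2 ~ N(10, 2),
  per-observation log2 noise sd 1.0, per-sample global intensity factor
  log2 sd 0.5.  These give the factor-two-ish within-group spread and
  sample-to-sample loading differences a peptidomics practitioner would
  recognize.
* **Planted effect** — `effect_log2fc = 2` per age step on 10 peptides,
  a strong biomarker-scale effect (4-fold per step, 16-fold young to
  old).
* **Migration warp** — a smooth monotone quadratic per sample,
  t′ = t + s·(u₀ + u₁x + u₂x²) with x the position in the run and
  u ~ U(−1, 1), s = 1 min.  Quadratic because CE drift is smooth but
  not affine, monotone so alignment is well-posed, and bounded (≤ ~3
  min) so internal-standard alignment has something real — but
  invertible — to undo.
* **Dropout** — missing-at-random at rate 0.2 per non-standard peptide
  per sample; an intensity-dependent mode (low-amplitude observations
  preferentially lost, same marginal rate) exists for stress tests.
  Standards are never dropped.
* **Mass jitter** — 10 ppm sd per observation, well inside the 50 ppm
  window but enough to exercise the tolerance logic.
* **Treated arms** — optional `treated_like` redirects the affected
  peptides of treated samples to another age group's means.  This is
  the construction behind the "treated old animals score young"
  direction checks.

What the generator does **not** emulate: correlated peptide families
(each peptide's noise is independent), amplitude-dependent mass
accuracy, electrospray suppression, batch effects, chemical noise, or
any real biological covariance between the planted markers.  Passing
tests on synthetic cohorts therefore demonstrate correctness of the
algorithms under the stated model, not performance on real urine.

# Numerical and algorithmic choices

**Standard detection.** Reference standards are located in a raw
profile by mass window, disambiguated by migration-time proximity: with
10 ppm jitter inside a 50 ppm window, an unrelated co-massed peptide at
an arbitrary time would otherwise occasionally win the mass-closest
vote and break anchor monotonicity.  Fewer than two detected standards
is an error that lists what was found.

**Alignment.** Monotone piecewise-linear time interpolation through the
(detected, reference) anchor pairs, end-segment slopes extrapolated
beyond the outermost anchors.  Amplitude normalization is one global
factor per sample — the median of reference/detected standard amplitude
ratios — deliberately not per-peptide.

**Matching.** Single-linkage semantics: master peptides are the
connected components of the graph whose edges are observation pairs
within both tolerances.  The implementation sweeps in ascending mass
with a union-find structure (only neighbours within the widest possible
window are examined) and is validated against a brute-force all-pairs
oracle on instances up to 30 observations.  The ppm window is anchored
at the *smaller* of the two masses (conservative, and symmetric enough
at these tolerances); the migration tolerance is evaluated at the
midpoint of the two times.  Within a cluster each sample contributes at
most one observation — closest in mass to the amplitude-weighted
consensus, ties broken by time then by local id; losers are counted in
a `dropped_duplicates` attribute so observation counts always
reconcile.  Master ids are assigned in ascending consensus-mass order,
so they are stable across reruns and sample reorderings.

**maxT.** One permutation stream per comparison, keyed only to the
seed and the group sizes — shared across peptides, which is what makes
the step-down maxima valid.  Adjusted p values carry +1 smoothing in
numerator and denominator (never exactly 0) and are made monotone by a
cumulative maximum down the |Z| ordering; adjusted p never falls below
raw p.  The whole computation is vectorized as a rank-matrix ×
permutation-indicator product, with missingness handled by indicator
matrices, so hundreds of null-cohort replicates run in seconds.
Peptides with fewer than two non-missing values in either group of a
comparison cannot be tested; they keep Z = 0, p = 1 and a
`testable = FALSE` flag rather than failing the whole screen.

**Classifier.** Missing amplitudes are explicit (`NA`) through the
screening stage but imputed as 0 at the classifier stage, *before* the
`log2(1 + a)` transform — an unobserved peptide and a truly absent one
are equivalent evidence to the model.  Training uses the extreme age
groups only (youngest vs oldest in the declared order); all other
samples, including intermediate ages and treated arms, are scored post
hoc.  A single scalar score with intermediate values for the middle
age group implies a single hyperplane, which is what this scheme
yields; the kernel is RBF, as implied by the presence of a γ value.
Scores divide the decision value by the kernel-space weight norm
√(αᵀKα), so "Euclidean distance to the hyperplane" is honored in
feature space; raw decision values are available via `raw = TRUE`.
Training rows are sorted by sample id before fitting, making the fit
invariant to the caller's sample order (libsvm is order-sensitive only
through its input order).  The KKT margin condition holds to libsvm's
termination tolerance (~1e-3 on decision values), which is the
tolerance the margin tests use.

**Take-one-out.** Greedy backward elimination with CV folds fixed once
per run (leave-one-out when the smaller class has ≤ 15 samples, else
5-fold stratified, seeded).  Each round applies the best tentative
single-peptide drop as long as CV accuracy does not decrease — a drop
that leaves accuracy unchanged is still taken (a redundant duplicate
should go), ties broken by dropping the lowest master id — and stops
when every drop would strictly decrease accuracy or one peptide
remains.  Consequently the panel never grows and final CV accuracy is
never below the initial panel's.  Accuracy (not AUC) is the evaluated
criterion.

**Two-way ANOVA.** Type II sums of squares for unbalanced data (equal
to the sequential decomposition when balanced), interaction included;
Tukey HSD runs over the age × treatment cell means using the
studentized-range distribution, with the `*`/`**`/`***` flag
convention at 0.05/0.01/0.001.  Degenerate inputs follow conventions:
a constant response reports F = 0, p = 1; an (almost) perfect fit falls
back to the sequential decomposition, where Type II solvers refuse a
zero residual.

**Glomerular volume.** Per-animal summaries default to the mean of
per-glomerulus volumes (`mean_of_volumes`); applying the Weibel formula
to the mean area is available as `volume_of_mean`, since the
aggregation order is a genuine modelling choice with no published rule.

**qPCR.** The contamination bracket 1 − 1/2^(Ct_RT⁻ − Ct_gene) is 1
when the RT⁻ control is absent (no detectable genomic signal) and 0
when Ct_RT⁻ equals the gene Ct; Ct_RT⁻ below the gene Ct violates the
signal model and is an error.

# Problem sizes used by the test and acceptance suites

The suites run the study-scale conditions where they are the point, and
smaller cohorts where only correctness is at stake: family-wise error
is calibrated on 200 null cohorts of 13 vs 13 samples × 100 peptides at
2 000 permutations; screening recovery on 50 cohorts at the full
design (3 × 13 samples, 200 peptides, 10 planted, 10 000
permutations); score monotonicity on 100 two-arm cohorts of 60
peptides; matcher-vs-oracle agreement on 100 random instances of up to
30 observations; exhaustive maxT enumeration on 3-vs-3 toys (all 20
assignments).  `scripts/acceptance.R` recomputes all of these from
scratch and writes the measured rates.

# Known limitations

* The maxT screen's power at these sample sizes is bounded by the rank
  statistic itself: a peptide observed in, say, 7 vs 7 samples after
  dropout cannot exceed |Z| ≈ 3.1 even under complete separation,
  while the null maximum over ~200 peptides sits near that level.
  Single-age-step effects therefore go undetected for a nontrivial
  fraction of planted peptides; the young-vs-old comparison, spanning
  two steps, recovers almost all of them.  The acceptance script
  reports both the consensus-panel recall and the per-pair union
  recall so the gap is visible.
* Master ids are reproducible within this pipeline but are not the
  opaque peptide ids of any external database; the packaged annotation
  table treats those as external labels.
* The normalization scheme (piecewise-linear time map + median
  amplitude ratio) is this package's own stated stand-in for
  proprietary calibration software; it is not a claim about what any
  vendor tool computes.
* The published 40-peptide mouse panel and its per-group scores depend
  on the original animals and are not reproducible from code; the
  packaged sequence table carries the 12 sequenced fragments only for
  annotation-consistency checks.
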