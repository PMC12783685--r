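---
title: "Methods: activity detection and MoA classification for live-cell embedding screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activity detection and MoA classification for live-cell embedding screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapscreen)
```

# The data model

`mapscreen` operates on *profile tables*: one row per imaged field of view
(FOV), carrying nine reserved metadata columns (`Metadata_plate`,
`Metadata_replica`, `Metadata_well`, `Metadata_fov`,
`Metadata_timepoint_h`, `Metadata_compound`, `Metadata_dose_uM`,
`Metadata_moa`, `Metadata_role`) and D numeric embedding features. A
*replica* is one complete experimental run — seeding, dosing and imaging
all plates at all timepoints — while technical *replicates* are multiple
wells of the same treatment. A *measurement* is one plate imaged at one
timepoint. Plate identifiers are shared across replicas (the same
randomization plate re-run), which matters below: statistics grouped by
(plate, timepoint) pool replicas, so replica-level technical structure
survives per-measurement normalization and must be removed by an explicit
batch-integration step.

DMSO wells are the negative controls (`Metadata_role =
"negative_control"`, dose stored as missing); everything downstream is
defined relative to them.

# Normalization

## Robust per-measurement scaling

`mad_robustize()` centres and scales every feature within each
measurement by that measurement's DMSO wells:
\[ x' = \frac{x - \mathrm{median}_{DMSO}}{c \cdot \mathrm{MAD}_{DMSO}}, \qquad c = 1.4826, \]
where \(c\) makes the MAD a consistent estimator of the standard
deviation under normality. After this step the DMSO wells of every
measurement have per-feature median exactly 0 and scaled MAD exactly 1
(the test suite asserts both to 1e-9). If a feature's DMSO MAD is exactly
zero — constant controls, common in degenerate test data — the feature is
centred but left unscaled (division by 1) and a warning names it;
dividing by a tiny estimated scale would explode near-constant features.

## Batch integration over replica and FOV

The embedding normalization family is:

| method | per-measurement step | integration covariates |
|---|---|---|
| `mad` | MAD robustize | — |
| `mad_harmony` | MAD robustize | replica |
| `mad_harmony_fov` | MAD robustize | replica + FOV |

The order is fixed: MAD per measurement, concatenate all measurements,
then one global integration pass. `harmony_correct()` is the package's
batch integrator, an iterative soft-clustering mixture-model method:

1. profiles are soft-assigned to `nclust` clusters by cosine-distance
   soft k-means (width `sigma = 0.1`), with the assignment multiplied by
   a diversity penalty \((E/O)^\theta\) per covariate block
   (`theta = 2`) that rewards clusters mixing batches in proportion to
   their global frequencies;
2. within each cluster, features are ridge-regressed (`lambda = 1`, the
   intercept unpenalised) on the one-hot covariate design, and the
   assignment-weighted batch component is subtracted from every profile.

The alternation stops when the RMS of the applied correction falls below
`tol = 0.01` times the RMS of the feature matrix, or after `max_iter =
20` rounds (a warning reports non-convergence and the best iterate is
returned). The integration runs on the feature matrix directly, not on a
PCA reduction: the features are already a learned embedding of moderate
dimension, and keeping the original axes lets the per-measurement MAD
semantics survive. FOV is treated as a categorical covariate with
plate-agnostic levels, so FOV 1 means "first imaged position" everywhere.
`kmeans` initialisation is seeded through the package's keyed RNG
streams, making the whole pipeline deterministic given `seed`.

`covariate_probe_accuracy()` quantifies residual batch structure: the
k-fold cross-validated accuracy of a multinomial ridge probe predicting a
covariate from the features, usually on DMSO wells only. Held-out
accuracy is essential here — an in-sample linear probe on tens of wells
and dozens of features decodes batch labels even from pure noise.

# Phenotypic activity: mAP-ES

Activity of a (compound, dose, timepoint) condition is measured by a
retrieval experiment on well-level profiles (FOV rows are
median-aggregated per well after normalization; the median is robust and
matches the package's per-image aggregation default, with the mean
selectable). One *resample* draws:

- a query well of the condition, uniformly among wells with enough
  eligible positives;
- `n_pos = 3` wells of the same treatment from a *different plate and a
  different replica* than the query (the strongest batch contrast);
- `n_neg = 31` DMSO wells from the query's own measurement (the weakest
  batch contrast);

ranks the 34 candidates by cosine similarity to the query (negative
Euclidean selectable; exact ties are broken by a seeded shuffle before a
stable sort, so tied candidates are ordered uniformly at random), and
records the average precision of the ranked labels. `n_resamples = 1000`
such values form the condition's mAP distribution. The DMSO *null*
repeats the same scheme with DMSO playing the treatment role, stratified
per timepoint and pooled over plates and replicas (DMSO has no dose, and
per-timepoint stratification keeps the null matched to the condition's
imaging time).

The mAP effect size is Cohen's d with the pooled standard deviation —
the standard two-sample definition — and a condition is called active at
`mAP-ES >= 0.8`. Degenerate inputs are handled explicitly: zero pooled SD
yields a signed infinity with a warning rather than an error, and
conditions whose wells span fewer than two replicas are *skipped* with an
explicit status instead of producing an unsupported estimate.

Because the negative controls define the null, technical structure that
survives normalization inflates the null rather than the effect size —
that is the point of the metric. The test suite verifies the machinery
end to end: AP equals a brute-force precision-at-k oracle on all 20
arrangements of 3 positives among 6 candidates; the null mean matches a
Monte-Carlo random-ranking oracle when the generator produces pure
isotropic noise; and the logged resampling draws respect the plate and
replica constraints exactly.

# Nuclei-count baseline and % Inhibition

Counts are Z-transformed per measurement against DMSO count statistics
(`z = (count − mean_DMSO) / sd_DMSO`). A condition is count-active when
the 95% percentile-bootstrap confidence interval for the *median* of all
its normalized FOV-level counts — pooled across wells, plates and
replicas, without prior aggregation — lies entirely below zero. The
percentile method with `n_boot = 10000` by default is the simplest
bootstrap consistent with a median target; both the method's coverage
(95% ± 3% at n = 40 over 500 simulations) and its degenerate behaviour
(constant data gives a zero-width interval) are asserted in the tests.
`inhibition_effect()` implements
\(\%\,\mathrm{Inhibition} = 100\,(\overline{m}_{DMSO} - m_{cpd})/\overline{m}_{DMSO}\)
for count or confluency metrics.

The contrast between the two activity definitions is itself tested: on a
fixture whose treatment moves the embedding but not the counts, mAP-ES
calls conditions active while the count CI rule does not; when the
generator also suppresses counts, both call activity.

# MoA classification

For every (dose, timepoint) condition a linear probe — multinomial
logistic regression with L2 penalty (`lambda = 1e-3`), features
standardized on the training split only — is trained on the wells of
compounds called active at that condition, plus all DMSO wells at the
timepoint as an explicit "DMSO" class, so weakly acting compounds can be
predicted vehicle-like. The ridge fit runs along a short descending
penalty path ending at the target `lambda`; coordinate descent needs the
warm starts to converge at small penalties. Per-compound class
probabilities are the average of the probe's softmax over the compound's
wells; `incremental_aggregate()` then averages per-condition rows with
uniform weights (configurable) over all conditions whose dose rank does
not exceed a cut-off, each included dose contributing all its timepoints.
Predictions are made for every compound at every condition regardless of
that compound's own activity call — the activity filter applies to
training only.

Cross-validation splits *by compound*, stratified by MoA, so replicate
wells of one compound never straddle train and test; with fewer
compounds per class than folds the assignment is best-effort with a
warning. A holdout mode (train on one compound set, predict another)
falls out of `predict_conditions()` directly. Classifiers are compared
with McNemar's test on discordant pairs, \((b-c)^2/(b+c)\) against
\(\chi^2_1\) without continuity correction, switching to the exact
two-sided binomial test when \(b + c < 25\).

# Self-supervised objectives at desk scale

The loss functions that produce batch-robust embeddings are provided as
pure functions, testable without any training loop. `center_bank()` keeps
one teacher-centering vector *per experimental batch*, EMA-updated
(`momentum = 0.9`); `dino_cross_batch_loss()` centres each teacher row by
its own batch's center before sharpening (`teacher_temp = 0.04`,
`student_temp = 0.1` — conventional distillation defaults; only the
learning schedule of a full training run is out of scope here).
`barlow_twins_loss()` standardizes both views per feature over the batch
(population SD, with a 1e-12 floor so degenerate toy batches do not
divide by zero) and penalises the cross-correlation matrix's deviation
from identity with off-diagonal weight `lambda = 0.5` — strong
decorrelation. `combined_loss()` applies the 1:1 ratio.
`sample_cross_batch_crops()` expresses the augmentation contract: two
global crops from two *distinct* replicas of the same condition, three
local crops per global source, and a focal plane drawn uniformly per crop
from the available z-planes, so natural focal variation replaces
artificial blur. Identities asserted in the tests include the uniform
cross-entropy value \(\ln 4\), the Gibbs lower bound with its equality
case, softmax shift invariance, the closed-form Barlow values on
engineered correlation matrices, and chi-square uniformity of the plane
draws.

# The synthetic generator

`generate_dataset()` emulates the study design, not its imagery. The
feature vector of record \(r\) is
\[ x_r = e(d_r, t_r)\,E_c\,u_c + b_{plate} + b_{replica} + b_{replica,fov} + \varepsilon_r, \qquad
   e(d, t) = \frac{d^h}{d^h + EC_{50}^h}\cdot\frac{t}{t_{max}}, \]
with per-compound maximal effect \(E_c \sim U(emax_{lo}, emax_{hi})\),
unit directions \(u_c\) drawn around a per-MoA direction
(`direction_jitter = 0.2` controls within-class spread), batch offsets
drawn once per level from isotropic Gaussians (`sigma_plate = 0.5`,
`sigma_replica = 1`, `sigma_fov = 0.5` — replica effects dominate, as a
full re-run perturbs more than a plate), and i.i.d. noise
(`sigma_noise = 1`). DMSO rows have the treatment term zeroed. Nuclei
counts are \(\mathrm{Poisson}(count_{base}(1 - \kappa\, e(d,t)))\) with
`count_base = 150` per FOV and maximal fractional inhibition
`kappa = 0.6`. Ground truth marks a condition active when
\(E_c\,e(d,t) \ge \sigma_{noise}/2\) — a stated detectability margin, so
truth labels are in principle recoverable.

Default design: 10 MoA × 3 compounds, 2 plates with shared layouts, 3
replicas, 2 wells per (compound, dose) per plate, 32 DMSO wells per
plate, 4 FOV, doses 0.156/0.625/2.5/10 µM, timepoints 4–20 h, D = 64.
This scales the study's shape (eight 384-well plates, seven replicas,
~190 compounds) down to sizes that generate in seconds while preserving
every structural property the pipeline relies on: enough replicas for
cross-replica positives (at least 3, since positives must avoid both the
query's plate and replica), enough DMSO wells per measurement for 31
negatives, and batch offsets at all three levels. All draws come from
keyed child streams (a rolling hash of purpose and level identifiers
folded with the master seed), so adding compounds does not shift
unrelated draws and fixtures are stable across platforms via R's default
Mersenne-Twister.

What the generator does *not* emulate: images (no optics or z-plane
rendering), non-additive or feature-correlated batch effects, compound
similarity structure beyond MoA clustering, dose-dependent toxicity
shapes other than the Hill × ramp form, plate-position (edge) effects,
and temporal autocorrelation of the live imaging. Tests passing on this
generator therefore demonstrate correctness of the pipeline's statistics
under its own model assumptions, not performance on real screens.

# Study conditions used by the tests and the acceptance script

Fixture sizes are the package's own choices, balancing statistical
resolution against runtime:

- *Mixed screen* (normalization, batch probes): 2 MoA × 3 compounds, 2
  plates, 3 replicas, 2 doses, 2 timepoints, D = 16.
- *Strong-effect screen* (activity recovery): 4 MoA × 3 compounds,
  doses 2.5/10 µM, timepoints 16/20 h, `emax_range = (5, 7)` so every
  condition's effect magnitude is at least \(3\sigma_{noise}\); 32 DMSO
  wells per plate support the full 3/31/1000 scheme.
- *Zero-effect screen* (null calibration): `emax_range = (0, 0)`, 3
  compounds × 96 wells each. The calibration check compares a compound's
  resampled mAP distribution to the null with a Kolmogorov–Smirnov test;
  both distributions are *conditional* on the realized wells, so the
  marginal-law identity only becomes visible once each condition has
  enough wells — hence the unusually high well count for this fixture.
- *MoA screen* (classification recovery): 10 MoA × 3 compounds, 3
  doses, 2 timepoints, `direction_jitter = 0.1`, `emax_range = (5, 7)`.
- Bootstrap coverage: 500 simulations of n = 40 standard normals,
  `n_boot = 1000`.

`scripts/acceptance.R` re-runs all of the above from scratch under a
caller-supplied master seed and writes the measured quantities (null
false-positive fraction and KS p-value, strong-effect sensitivity,
replica-probe accuracies before and after integration, count-contrast
fractions, % inhibition, bootstrap coverage, cross-validated MoA
accuracy/F1/top-3, and the closed-form loss identities) as JSON.

# Known limitations

- The batch integrator assumes additive, cluster-wise linear batch
  effects; multiplicative or strongly nonlinear batch structure would
  call for a different correction model.
- The mAP-ES null is stratified per timepoint but pooled over plates;
  plate-specific nulls would need many more DMSO wells per plate than
  the scaled-down designs carry.
- With few wells per condition, the resampled mAP distribution is
  strongly conditional on the realized wells; mAP-ES remains usable (the
  null has the same character) but distribution-shape comparisons
  against the null are then dominated by conditioning, as described
  above.
- The count baseline's percentile bootstrap slightly undercovers at
  small n, making the "CI below zero" rule mildly anticonservative —
  visible as occasional false positives in zero-count-effect fixtures.
- Linear probes test linear separability only, by design; the DMSO class
  absorbs weak phenotypes, so per-class F1 for weakly active MoAs
  depends on the activity filter's sensitivity upstream.
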