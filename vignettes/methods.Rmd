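---
title: "Methods: severity grading, whale-optimization feature selection, and stacking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: severity grading, whale-optimization feature selection, and stacking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdseverity)
```

## The problem

Serum 25-hydroxyvitamin D (25-OH-D) is the clinical measure of vitamin D
status, but the blood test is expensive enough that population-wide
screening is discouraged. `vdseverity` implements a non-invasive
alternative: grade the **severity of vitamin D deficiency** into four
clinical levels from questionnaire answers alone — demographics, diet,
lifestyle, environment and season — without measuring serum. The severity
grades follow the standard serum bands:

| Level | Label | Serum band (ng/mL) |
|---|---|---|
| 1 | Optimal | above 30 |
| 2 | Suboptimal | 20–30 |
| 3 | Inadequate | 10–20 |
| 4 | Extremely Inadequate | below 10 |

Band boundaries use one consistent convention: Optimal is strictly above
30; every other band is closed at its lower bound and open at the top, so
30 and 20 grade Suboptimal and 10 grades Inadequate
(`assign_severity()`).

The toolkit has three scientific components: a synthetic cohort simulator,
wrapper feature selection by an improved (memetic) binary whale
optimization algorithm, and an out-of-fold stacking classifier with a
softmax meta-model, plus the preprocessing and evaluation machinery around
them.

## The synthetic cohort generator

Real questionnaire cohorts of this kind are private, so the package ships
a simulator whose defaults emulate the reference study conditions: 512
records with class proportions 21.88 / 26.17 / 26.95 / 25.00 percent
(counts 112/134/138/128 under exact-count sampling), fourteen
questionnaire fields with fixed categorical vocabularies, a continuous
11-item food-diversity score, season, and a latent serum value.

The latent model is additive:

$$\mathrm{serum}_i = \mu_{\mathrm{season}(i)} +
  s \sum_j w_j \, \sigma_j \, c_j(x_{ij}) + \varepsilon_i,\qquad
  \varepsilon_i \sim N(0, \sigma_\varepsilon^2)$$

* $\mu_{\mathrm{season}}$ — per-season baselines, default 12.5 (winter),
  18.5 (spring), 22.0 (summer), 15.0 (fall) ng/mL from the structured
  seasonal summary (`seasonal_preset("table")`). An alternative
  `"narrative"` preset (11.33/16.38/22.55/16.56) is exposed because both
  sets are reported; the structured table is the default.
* $w_j$ — non-negative effect weights, defaulting to the reported
  feature-importance percentages (family relationship 15, exercise 12,
  calcium 11, age 10, sun exposure 9, milk 9, health issues 9, BMI 8,
  financial stress 6, fish 5, food-diversity score 5, gender 2), rescaled
  to sum to one. Geographic location and air-quality band carry weight 0;
  they are the two fields beyond the twelve with reported importances, and
  they act as built-in noise features.
* $\sigma_j \in \{+1,-1\}$ — effect directions: age, BMI, financial
  stress and health issues lower serum; diet, exercise, sun exposure and a
  happy family environment raise it.
* $c_j$ — centered category codes scaled to $[-1, 1]$ (ordered
  vocabularies keep their order; the food-diversity score is centered at
  its scale midpoint 5.5).
* $s$ — the overall questionnaire effect amplitude `effect_scale`
  (ng/mL), default 30.
* $\sigma_\varepsilon$ — residual noise `noise_sd`, default 0.5 ng/mL.

Severity is assigned from the latent serum, so serum/severity consistency
holds for every generated row by construction.

**Why `effect_scale = 30` and `noise_sd = 0.5`.** The reported class
distribution places about a quarter of the cohort above 30 ng/mL and a
quarter below 10 ng/mL, which requires the marginal serum distribution to
span all four bands; with seasonal baselines between 12.5 and 22 ng/mL the
questionnaire effects must carry most of that spread. An amplitude of 30
ng/mL gives a marginal spread (SD ≈ 8–9 ng/mL) under which every class has
comfortable probability mass, so exact-count sampling by per-class
rejection is cheap. The residual noise of 0.5 ng/mL makes severity almost
a deterministic function of the questionnaire answers (the noiseless
predictor grades about 96% of rows correctly in a large-sample check),
i.e. the default cohort is deliberately *highly separable*: it exercises
the pipeline's ceiling, not the ambiguity of real questionnaire data.

**What the simulator does not emulate.** Real cohorts have correlated
questionnaire answers (diet with financial stress, exercise with BMI),
informative missingness, measurement error in the serum assay,
non-additive effects, and far weaker feature–serum relationships. The
generator samples fields independently and uniformly and adds effects
linearly. Tests passing on this cohort therefore demonstrate correctness
of the machinery and attainability of high accuracy under separable
conditions — not expected performance on real questionnaire data.

**Seasonal spread caveat.** The configured per-season SDs (1.5–2.0 ng/mL)
set the seasonal baseline description and the reference preset for
seasonal normalization; the realized within-season spread is larger
(≈ 8 ng/mL) because the questionnaire effects add variance. The two
constraints — a narrow within-season spread and a class distribution
spanning all four bands — cannot hold simultaneously, and the package
resolves the conflict in favour of the class structure, which the
classification task requires. For the same reason no within-season
z-scoring can reproduce the reported per-season "normalized" summary
values (e.g. winter −0.75 ± 1.50): a within-group z-score has mean 0 and
SD 1 by construction. That summary is treated as a documented
inconsistency, not as ground truth.

**Exact counts.** With `exact_counts = TRUE` the per-class targets are the
largest-remainder allocation of `n * proportions` (ties toward the lower
severity level), filled by per-class rejection sampling; the fill loop
fails loudly if a class is unreachable under the configured latent model.

`inject_missingness()` masks an expected fraction of cells completely at
random (never the severity label) as a fixture for imputation.

## Preprocessing chain

* **Chained-equation imputation** (`impute_chained()`): categorical gaps
  take the column mode (ties toward the lexicographically first
  category); continuous gaps are initialized at the column mean and
  refined by iterated least-squares regression on all other columns until
  the largest change drops below `impute_tolerance` (default 1e-6) or
  `impute_max_sweeps` (default 20). This is deliberately a
  single-imputation variant — one completed table feeds the downstream
  pipeline, so multiple imputed datasets and pooling rules are out of
  scope. Observed cells are never altered.
* **IQR outlier handling** (`cap_outliers_iqr()`): fences at
  `Q1 − 1.5·IQR` and `Q3 + 1.5·IQR` with quantiles by linear interpolation
  (R type 7 — stated because the fences depend on the convention); values
  outside are capped to the nearer fence or removed. Capping is
  idempotent.
* **Z-score standardization** (`zscore_standardize()`): population
  (n-denominator) SD, stated for exactness; constant columns are an error
  advising exclusion.
* **Category aggregation** (`aggregate_bins()`): raw calcium scores map to
  the reporting bands `>16`, `1–15`, `0–7`, checked in that printed order,
  so the 1–7 overlap resolves to `1–15` and only 0 lands in `0–7`;
  milk/fish frequency answers collapse to yes/no.
* **Encoding** (`encode_features()`): ordered fields become integer codes
  preserving order (sun exposure Never→0 … Always→4); binary fields become
  0/1; season is one-hot (its effect on serum is not monotone in any
  category order, so an ordinal code would misrepresent it). The encoding
  map is invertible (`decode_features()`).
* **SMOTE-NC** (`smote_nc_balance()`): minority classes are oversampled to
  the majority count. Distances between same-class rows are Euclidean over
  continuous columns plus one squared median-of-continuous-SDs penalty per
  mismatching categorical column (the original nominal-continuous
  formulation; the method's source names no metric). Synthetic rows
  interpolate continuous features between a sample and one of its
  `k = 5` nearest same-class neighbours and take neighbour-majority
  categories. Balancing is applied to the *training partition only*,
  after the split, to avoid leakage; the ordering is a package decision
  since the source pipeline does not state it.

## Feature selection: memetic binary whale optimization

Wrapper selection scores a feature mask $B$ by

$$f(B) = w \cdot \mathrm{acc}_{CV}(B) + (1 - w)\left(1 -
  \frac{|B|}{n}\right),$$

with $\mathrm{acc}_{CV}$ the stratified 3-fold accuracy of a
decision-tree wrapper classifier on the masked columns and $w = 0.9$ (the
accuracy/sparsity trade-off weight is a package default; only the
existence of the trade-off is prescribed). The fold assignment is derived
once from the configuration seed, so a mask always maps to the same
fitness and results are reproducible; evaluations are cached. The empty
mask scores 0 and any empty mask arising during search is repaired by
setting one uniformly random bit.

The global search is canonical whale optimization over a continuous
relaxation: `a` decays linearly 2→0, `A = 2a·r1 − a`, `C = 2·r2`, spiral
parameter `l ~ U(−1,1)`; each whale takes the logarithmic-spiral move with
probability `switch_probability` (default 0.5) and otherwise the
encircling move — toward the best whale when `|A| < 1`, toward a random
whale (exploration) otherwise. These coefficient definitions are the
standard ones; the source algorithm names the phases but never defines the
symbols. Positions binarize through the increasing sigmoid
$S(x) = 1/(1+e^{-x})$ (bit set when `S(x) > rand`). The printed transfer
in the source is the *decreasing* $1/(1+e^{x})$, which inverts the meaning
of "high position → include"; the standard form is the default and the
printed variant stays available via `transfer = "printed"`.

Design choices worth calling out:

* **Best-mask anchor.** When a new best mask is found, the "best position"
  that other whales encircle is set to $\pm 4$ per bit, i.e. a position
  whose sigmoid regenerates the best mask with probability ≈ 0.982 per
  bit. Without this, exploitation contracts toward an arbitrary continuous
  point whose binarization need not resemble the best mask at all, and the
  search loses its optimum half the time on small benchmarks.
* **Simulated-annealing refinement** (`sa_refine()`): single-bit flips
  accepted by the Boltzmann rule $P = \min(1, e^{-\Delta f / T})$ with
  $\Delta f = f_{\mathrm{current}} - f_{\mathrm{proposed}}$, so
  improvements ($\Delta f \le 0$) are always accepted — this sign
  convention makes "worse accepted with probability < 1" literally true.
  The printed acceptance expression is dimensionally ambiguous
  ($e^{-\Delta T}$); dividing by the temperature is the reading consistent
  with cooling semantics. Temperature cools geometrically
  ($T \leftarrow \alpha T$, default $\alpha = 0.9$) and the best visited
  state is returned. The default start temperature is **0.02**, matched to
  the scale of realistic fitness differences: cross-validated accuracies
  on a few hundred rows differ by ~0.01, so a start temperature of 1 would
  accept almost every worsening move and degrade the refinement to a
  random walk.
* **Refinement schedule**: once per whale at the end of the global search
  (the literal reading of the algorithm); per-iteration refinement is
  available via `sa_mode = "each"`.
* **Termination**: `max_iterations` (default 50) or 15 iterations without
  improvement ("convergence" is otherwise unquantified).
* The best-so-far is updated only on strict improvement, so the fitness
  trajectory is nondecreasing by construction.

On an 8-feature benchmark (three informative features, 120 rows) the
search with population 16 and 40 iterations recovers the exhaustive
optimum over all 255 nonempty masks in 10 of 10 seeded runs; with 3
informative + 17 noise features its selected masks overlap the informative
set (Jaccard ≈ 0.5–0.6 averaged over 10 seeds) far above equal-size random
masks (≈ 0.09). These problem sizes — 120–150 rows, 8–20 features, 10
seeds — are the package's chosen benchmark scale.

## Stacking classifier

`fit_stacking()` follows the standard out-of-fold recipe: stratified
k-fold (default 5) out-of-fold class-probability predictions from each
base model form the meta-feature matrix (width `n_base × K` in probability
mode, one label code per model in label mode), a softmax meta-classifier
is fitted on it, and the base models are refit on all training rows for
deployment. The default trio is RF / SVM / GB (the operative algorithm
statement); the wider set {RF, SVM, GB, NB, KNN, XGB, DT} is available.

* The **softmax meta-model**
  $P(y = k \mid x) = \exp(\beta_k^\top x) / \sum_j \exp(\beta_j^\top x)$
  is fitted in-package by L2-penalized maximum likelihood (penalty 1.0 on
  coefficients, intercepts unpenalized) with analytic gradients under
  BFGS from a zero start — deterministic to machine precision. Probability
  mode is the default meta representation: the softmax acts on
  real-valued inputs and class probabilities carry more signal than hard
  labels.
* **SVM probabilities** are produced by a deterministic calibration: each
  pairwise decision value is squashed through a sigmoid whose slope is a
  quarter of the median training margin for that pair, the soft votes are
  accumulated per class, and the totals pass through a softmax. This
  tracks the pairwise voting rule of the underlying fit while avoiding its
  internally randomized Platt scaling, whose results are not reproducible
  under an R seed. The linear kernel is the default: the severity bands
  are thresholds on an additive score, so the Bayes boundary is close to
  linear in the encoded features.
* **GB and XGB** are both gradient-boosted trees (single-threaded, seeded)
  with classic shallow-tree settings for GB (depth 3, learning rate 0.1,
  200 rounds) and faster/deeper settings for XGB (depth 6, rate 0.3, 60
  rounds). **KNN** class probabilities are neighbour-class proportions on
  train-standardized features. Ties in the final argmax break toward the
  lower severity level.
* The outer evaluation split is stratified; every seed is logged in the
  returned objects.

On the default synthetic cohort (512 rows, fixed seeds) the full pipeline
— per-fold SMOTE-NC balancing, encoding, training-statistics
standardization, stacking — reaches ≈ 0.92 mean accuracy under 10-fold
cross-validation, against a majority-class floor of 0.27 and a noiseless
ceiling of ≈ 0.96. The reference study reports 99.4% on its private
cohort; that number is not reproducible from a simulator and is not a
package claim.

## Evaluation conventions

* Per-class "accuracy" is **one-vs-rest accuracy** `(TP+TN)/n`; the
  reference tables never define it, and in most of their rows the printed
  accuracy equals recall, so recall is reported alongside for comparison.
* Zero-denominator metric cells are reported as 0 with an explicit
  `zero_division` flag rather than `NaN`, keeping tabular output stable.
* Correlation reports are Pearson, with the redundant upper triangle
  masked (lower triangle retained) and `|corr| > 0.25` flagged; zero-
  variance columns yield undefined (`NA`) correlations, not zeros.
* Seasonal normalization is a within-season z-score (population SD), with
  an option to standardize against reference seasonal parameters instead
  of empirical ones.
* Cross-validation is stratified; `k = n` degrades gracefully to
  leave-one-out.

## Numerical choices and degenerate inputs

* Positions are clamped to $[-10, 10]$ before binarization; the sigmoid is
  saturated there and unbounded spiral excursions would otherwise overflow
  `exp`.
* Softmax computations subtract the row maximum before exponentiating.
* Quantiles are type 7; SDs are population SDs wherever a z-score law is
  asserted to 1e-9.
* Single-feature selection problems return the only valid mask `[1]` with
  a warning; single-class labels, all-missing columns, constant columns,
  singleton season groups and singleton SMOTE classes are errors with
  actionable messages.
* All randomness flows from named sub-seeds derived from one master seed
  (`derive_seed()`), so changing one stage's configuration does not shift
  another stage's stream.

## Limitations

* The simulator's independence and linearity assumptions make the default
  cohort easier than real questionnaire data; accuracy numbers on it are
  upper bounds of machinery quality, not clinical performance estimates.
* The reported per-season normalized summary cannot be reproduced by any
  within-season z-scoring and is not asserted anywhere.
* The wrapper fitness uses a single decision tree for speed; subsets
  optimal for a tree wrapper need not be optimal for the stacking
  classifier downstream.
* Severity grading of the generator is exactly threshold-consistent;
  assay measurement error on real serum values would blur labels near
  band boundaries.
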