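---
title: "Models and methods: CC diet-challenge phenotype analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: CC diet-challenge phenotype analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccorganotrait)
```

## The setting

Collaborative Cross (CC) lines are recombinant inbred mouse strains:
animals within a line are genetic replicates, animals across lines sample a
broad range of genetic backgrounds. A diet-challenge study places replicate
animals of each line and sex on either a standard chow diet (CHD) or a
high-fat diet (HFD) for 12 weeks, recording body weight bi-weekly, glucose
tolerance (IPGTT) at weeks 6 and 12, and terminal liver, spleen and heart
weights. The within/between-line layout turns ordinary one-way ANOVA into a
genetics instrument: between-line variance estimates genetic variance,
within-line variance estimates environmental variance, and their ratio is
the broad-sense heritability of each trait under each diet.

No per-animal data from such studies is bundled here. The package instead
ships a generative model of such a cohort, and validates the analysis
machinery by parameter recovery: traits simulated at a known heritability
must be estimated back at that heritability, classifiers run on permuted
labels must calibrate to chance, and every closed-form statistic must agree
with an independent brute-force oracle.

## The generative model

All trait families share one structure: an additive linear predictor with
line, sex, diet and line x diet effects plus residual noise. Line effects
are drawn once per line per trait family and shared by all that line's
animals — this is what creates the between-line variance component. Across
trait families the line effects are drawn independently (genetic
correlation zero) by default, because the real inter-organ genetic
correlation is undocumented; this is the main realism limitation (below).

**Body weight** (raw grams). Animal $i$ has intercept
$\beta_{0i} = \mu_0 + s\,[\mathrm{male}] + \ell_{L(i)} + a_i$ and growth
rate
$\beta_{1i} = r + g_{L(i)} + b_i + [\mathrm{HFD}]\,(r_{\mathrm{hfd}} + h_{L(i)})$,
with weekly reading
$BW_i(w) = \beta_{0i} + \beta_{1i} w + \varepsilon_{iw}$. Diet enters only
through the slope, so the arms coincide in expectation at week 0 — the
week the challenge diet starts. Non-positive readings are rejected and the
measurement noise redrawn (with default parameters this never triggers).
The week-12 minus week-0 difference, ΔBW, is then
$12(r + r_\mathrm{hfd}[\mathrm{HFD}] + g_{L} + b_i)$ plus two measurement
errors, which makes its implied heritability
$(12\sigma_{g})^2 / \big((12\sigma_{g})^2 + (12\sigma_{b})^2 + 2\sigma_m^2\big)$
— this is what `implied_h2(params, "dbw")` computes.

**IPGTT glucose** (mg/dL). Fasting glucose is linear-additive; each test
draws the gamma-pulse curve
$$\mathrm{glucose}(t) = \mathrm{fasting} + A\,\frac{t}{\tau}\,
e^{1 - t/\tau} + \varepsilon_t .$$
The pulse rises from exactly `fasting` at $t=0$ to an exact peak
$\mathrm{fasting} + A$ at $t=\tau$, then clears monotonically — the shape
of a glucose bolus being absorbed and cleared, with closed-form landmarks
that make exact tests possible. HFD animals have both $A$ and $\tau$
multiplied by the clearance-slowing factor (default 1.35), which raises and
right-shifts the curve, hence a larger area under it. The two test weeks
are drawn from the same distribution; progressive deterioration between
week 6 and week 12 is not modelled.

**Organ weights** (grams). Linear-additive on the log scale — effects are
log-ratios and weights are guaranteed positive, matching the right skew of
weight data; `mu` is the median weight of a chow-fed female.

### Default parameters

Defaults describe a plausible mid-sized mouse cohort; they were chosen once
and are not tuned to reproduce any published table.

| family | parameter | default | meaning |
|---|---|---|---|
| bw | `mu0` | 21 g | female week-0 weight |
| bw | `sex_effect` | 4 g | male intercept shift |
| bw | `growth` / `growth_hfd` | 0.55 / +0.45 g/wk | chow growth; HFD increment |
| bw | `sigma_line`, `sigma_line_growth` | 1.8 g, 0.12 g/wk | line effects (intercept, slope) |
| bw | `sigma_int_growth` | 0.10 g/wk | line x diet slope effect |
| bw | `sigma_animal`, `sigma_animal_growth`, `sigma_meas` | 1.3 g, 0.08 g/wk, 0.3 g | within-line variation |
| glucose | `fasting_mu`, `sex_effect`, `diet_effect` | 100, +8, +15 mg/dL | fasting level |
| glucose | `peak_amplitude` (A), `time_to_peak` (τ) | 180 mg/dL, 30 min | pulse shape |
| glucose | `hfd_clearance_mult` | 1.35 | HFD inflation of A and τ |
| glucose | `sigma_line`, `sigma_line_amp`, `sigma_animal`, `sigma_meas` | 8, 15, 10, 5 | variance components |
| liver | `mu`; effects (log) | 1.30 g; sex +0.10, diet +0.18 | ~+10% male, ~+20% HFD |
| liver | `sigma_line`, `sigma_int`, `sigma_e` (log) | 0.15, 0.06, 0.10 | implied H² ≈ 0.69 |
| spleen | `mu`; effects | 0.09 g; −0.05, +0.10 | |
| spleen | sigmas | 0.12, 0.08, 0.15 | implied H² ≈ 0.39 |
| heart | `mu`; effects | 0.15 g; +0.08, −0.03 | percent heart falls on HFD mainly via BW |
| heart | sigmas | 0.08, 0.04, 0.10 | implied H² ≈ 0.39 |

With these values the estimated heritabilities across all sex x diet strata
span roughly 0.2–0.75 — the requirement was that strata fall inside the
0.1–0.8 band typical of line-replicate studies, without targeting any
specific published cell. The glucose variance components were set after a
first inspection showed the initial choice implied an AUC heritability
above that band; the division between line-level and animal-level variance
was rebalanced before any test expectations were frozen.

### What the generator does *not* emulate

A green test establishes that the estimators and protocols are correct on
data satisfying the model's assumptions — not that real cohorts satisfy
them. Deliberately absent: genetic correlation between trait families
(liver line effects are independent of body-weight line effects, which is
why the shipped regression grids are near zero — the features carry no
information about organ weight beyond the shared diet/sex structure);
cage, batch and litter effects; food-intake, insulin and histology
measurements; mortality and dropout; non-Gaussian residuals;
week-6-to-week-12 progression of glucose intolerance.

## Derived traits

* **AUC**: trapezoid rule over all adjacent timepoint pairs from 0 to
  180 min, $\sum (t_{k+1}-t_k)(y_k + y_{k+1})/2$ — total AUC, not the
  baseline-subtracted variant. Curves must span the full design window;
  missing interior points are tolerated (the trapezoids just widen), a
  missing endpoint is an error, keeping the integration window fixed
  across animals.
* **ΔBW** = BW(final week) − BW(week 0); may be negative.
* **Percent organ weight** = organ / final BW × 100 ("adjusted weight").
* **Group Δorgan/ΔBW**: per (line, sex) cell,
  (mean organ HFD − mean organ CHD) / (mean ΔBW HFD − mean ΔBW CHD). This
  is a group-mean contrast, not a per-animal trait; a zero denominator is
  flagged rather than returned as ±Inf. The denominator is the difference
  in mean *ΔBW* (weight change), the quantity the contrast is expressed
  against in this literature.

## Heritability and CVg

From the one-way layout with $a$ lines and $n_i$ animals per line:
$MSB = SSB/(a-1)$, $MSW = SSW/(N-a)$, and the unbalanced correction
$n_0 = (N - \sum n_i^2/N)/(a-1)$, so that $E[MSB] = V_e + n_0 V_g$.
Method-of-moments extraction gives $V_e = MSW$ and
$V_g = \max(0, (MSB - MSW)/n_0)$ — negative moment estimates are clamped
to zero, the standard convention for line-replicate panels — and
$H^2 = V_g/(V_g+V_e)$, undefined (flagged) when both components vanish.

Choices worth making explicit:

* **CVg** uses the sample SD of per-line means divided by the overall
  animal-level mean — the literal "SD among the lines" — rather than
  $\sqrt{V_g}$. The two differ: the SD of line means includes a
  $V_e/\tilde n$ sampling component. The literal reading was kept because
  it is what the quantity's name says; it is mildly upward-biased as an
  estimate of $\sqrt{V_g}/\mu$ at small within-line replication.
* **Which AUC row**: the heritability table analyses the final (week-12)
  AUC, the terminal glucose-tolerance measurement; week 6 remains available
  as a column and can be passed via `trait_cols`.
* **Ratio traits** (ΔLW/ΔBW, ΔSW/ΔBW, one row per sex, diets pooled): an
  ANOVA needs an animal-level quantity, so these rows use per-animal
  organ-weight/ΔBW. Animals with ΔBW ≤ 0 are excluded (the ratio explodes
  near zero) and the excluded count is recorded in the row's `flags`. This
  is an interpretation — a group-level contrast has no within-line
  replication to feed an ANOVA — and is flagged as such in the output.
* Strata that fail preconditions (single line, all-singleton lines, zero
  variance) appear in the table with `NA` values and a reason in `flags`,
  never silently dropped.

The estimator's finite-sample behaviour is quantified in the acceptance
suite: at 8 lines x 10 animals the mean estimate over 200 replicates is
within 0.04 of the simulated truth across H² ∈ {0, 0.3, 0.6, 0.9}
(tolerance 0.10); at 200 lines x 50 animals within 0.02. The residual bias
at 8 lines is real — a ratio of noisy variance components plus the
zero-clamp — and is why single-study heritability values from 8-line
panels carry substantial uncertainty.

## Correlations and diet contrasts

Pearson matrices are computed pairwise-complete per stratum (sex x diet,
optionally a single line), so one missing measurement does not delete a
mouse from unrelated cells; cells with fewer than 3 complete pairs or zero
variance are flagged-undefined and rendered grey in heatmaps. On complete
cases the matrix is positive semidefinite (property-tested). Heatmaps span
a fixed [−1, 1] blue-white-red key with no clustering, so identical input
gives identical output.

Diet contrasts use Welch's unequal-variance t-test: design cells range from
3 to 14 animals per arm, so the equal-variance assumption is not worth
making. When variances and group sizes are equal, Welch reduces to
Student's t (asserted to 1e-8). Stars follow the three-level convention
`*` p<0.05, `**` p<0.01, `***` p<0.001; where the source conventions
disagree on the number of thresholds, the three-level form is used
throughout. No multiple-testing correction is applied by default, matching
per-panel testing practice; `contrast_table(..., adjust = "BH")` switches
the stars to Benjamini-Hochberg adjusted p-values. The star procedure's
type-I error is verified at 5% ± 1% by a 10,000-replicate null simulation.

## Classification and regression protocols

Labels: percent organ weight strictly above its 70th percentile
(linear-interpolation quantile, R type 7; ties label 0) — computed within
the modelled subset, i.e. per line in per-line mode, since "the data" being
classified is that line's animals. Features (default set): sex and diet
0/1-encoded, initial and final body weight, AUC at weeks 6 and 12. The
alternative `table-caption` feature set drops final body weight and maps
the notion of an "initial organ weight" — impossible, as organs are
weighed only at sacrifice — to initial body weight.

Protocol: stratified 4-fold cross-validation (stratification is a
documented deviation from an unspecified original: at 18–35 animals and 30%
positives, unstratified folds are frequently single-class and unscorable),
scored by held-out ROC-AUC with midrank tie handling, averaged over
scorable folds; unscorable folds are recorded. Pooled-prediction AUC was
considered and not implemented — the mean-over-folds convention is the one
reported. Model families:

* decision tree — CART, Gini impurity, fully grown (minsplit 2);
* random forest — 100 such trees on bootstrap resamples with
  $\lfloor\sqrt p\rfloor$ features per split, scores averaged;
* Gaussian naive Bayes — per-class feature means/variances with a small
  variance floor, 0/1 categoricals treated as Gaussian (the standard
  shortcut);
* kNN — k = 5, Euclidean distance on raw features, score = fraction of
  positive neighbours. Features are deliberately not rescaled; with the
  default feature set the AUC columns dominate the metric, which mirrors
  naive use of these tools and is part of why kNN columns are erratic.

The tree engine is compiled (Rcpp) with an internal xorshift RNG seeded
from R, so results are identical across platforms regardless of R's RNG
state. Every stochastic stage draws its seed from the global seed via a
labelled mixing function (`child_seed`), and all package functions restore
the caller's RNG state — a permutation loop around
`run_classification_cv()` behaves as expected.

Regression: linear (least squares; collinear columns dropped) and kNN
(k = 5) over 100 random 70/30 splits, scored by held-out R² about the
*test-set* mean (so R² < 0 means worse than the mean predictor). The raw
mean is reported alongside the floored score `max(0, mean)`; the floored
value is the table-comparable one — an all-zero row means "no model beat
the mean", not "R² was exactly zero on every split".

Cells that cannot be scored — a single class, a line reduced to one
sex x diet group, degenerate labels, too few animals — are flagged with a
reason and kept in the grid.

## Numerical and interface choices

* Cohort values are rounded to 4 decimals at generation; the CSV
  interchange format then round-trips exactly (`read(write(x))`
  identical), and fixed seeds give byte-identical files across runs.
* CSV outputs stay plain (no comment headers), for interoperability; the
  association between each output file and the configuration that produced
  it lives in `manifest.json` (config echo, config md5, per-file md5).
* The IPGTT schedule defaults to weeks {6, 12} — the weeks the downstream
  analyses use — and is configurable in `study_design()`; sampling minutes
  default to 0/15/30/60/120/180 and must start at 0.
* Degenerate inputs error early with context (mouse id, row/column of a
  malformed CSV) rather than propagating NaN.

## Known limitations

* Zero cross-trait genetic correlation makes organ-weight regression
  intentionally hard; do not read the near-zero default grids as a
  property of real data.
* The heritability point estimator is biased toward the interior at 8
  lines (≈ ±0.04); no confidence intervals are provided.
* Gaussian naive Bayes on 0/1 features is a model misspecification
  accepted for fidelity to common practice.
* The per-line 70th-percentile labelling re-draws the threshold per line;
  grids across lines therefore classify *relative* extremeness, not a
  common absolute cut.
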