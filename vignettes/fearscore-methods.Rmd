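---
title: "Methods: quantifying fear intensity and its encoding in sweat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying fear intensity and its encoding in sweat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fearscore)
```

## The scientific problem

Sweat-donation studies of human chemical communication need two
quantifications that univariate statistics handle poorly. First, *how
afraid was each donor?* A fear state expresses itself jointly across skin
conductance (tonic level, µS; phasic response count), heart rate (bpm),
respiratory rate (breaths/min), armpit sweat mass (mg per 75 cm² pad) and
self-reported feelings; no single endpoint is reliable on its own. Second,
*is that intensity encoded in the sweat?* A photo-ionization detector
(PID) ionizes the volatile molecules a pad releases and outputs a current
(mV) proportional to their concentration, so per-trial PID responses
quantify the chemical signal a receiver could in principle decode.

`fearscore` implements the encoder-side chain: questionnaire clustering →
outlier handling and collinearity screening → PLS-DA classification →
composite fear score and intensity categories → dose–response statistics →
PID quantification and decay modelling, plus a synthetic-data generator
that reproduces the statistical structure this chain assumes.

## Questionnaire clustering

Twenty affect items (0–5 ratings) are highly correlated within circumplex
neighbourhoods (r > 0.7 for, e.g., fearful/nervous/tense), which would
destabilize regression coefficients if entered individually. The package
embeds items by metric multidimensional scaling of the dissimilarity
`d = 1 − r` and groups them into the four arousal × valence quadrants
(HA+, HA−, LA−, LA+). The MDS is stress-majorizing (SMACOF updates) with a
classical-scaling start, convergence when the normalized stress improves
by less than 1e−6, and a 300-iteration cap; the partition is initialized
by seeded k-means on the embedding and refined so every item joins the
group with whose centroid rating profile it correlates best. Only the
*assignment* is consumed downstream, so any stress-minimizing metric MDS
would serve equally.

A cluster score is the **mean** of its member items, keeping scores on the
0–5 rating scale and giving the composite score terms the magnitude the
reference weight equation implies (group means of ~0.6–1.2 arise only with
rating-scale means; a `sum` variant is available via `score_method`). The
direct arousal and valence ratings are deliberately *excluded* from the
default predictor set: they are near-linear combinations of the cluster
scores and inflate variance inflation factors (VIFs) well beyond the
usual acceptability bounds, as `include_arousal_valence = TRUE` plus
`compute_vif()` demonstrates.

## Outliers and collinearity

Extreme cases underweight in PLS-DA, so each predictor is Winsorized
within condition (fear and neutral separately, since outlier rates differ
by condition): values beyond `median ± 2.5 × MAD` are replaced by the
bound. The MAD is scaled by the normal-consistency constant 1.4826; the
outlier-detection literature behind the 2.5 rule uses the scaled form, and
the `constant` argument exposes the unscaled alternative. Bounds are
computed once from the input, making the operation idempotent. A zero MAD
with non-constant data (more than half the values identical) leaves the
vector unmodified with a warning rather than dividing by zero.
`compute_vif()`/`drop_high_vif()` implement the usual
`VIF = 1/(1 − R²)` screen with iterative removal of the worst predictor;
perfect collinearity reports as an infinite VIF rather than an error.

## PLS-DA, diagnostics and the composite fear score

The classifier is PLS1 on a dummy-coded label (fear = 1, neutral = 0,
decision threshold 0.5) rather than two-column PLS2 — for two classes the
decisions coincide and the coefficient vector is simpler. Predictors are
autoscaled internally; coefficients are back-transformed to raw units
because the composite fear score is defined on raw scores. NIPALS computes
weights, scores and loadings with X- and y-deflation; for a univariate
response the weight vector has the closed form `w ∝ X'y`, and successive
score vectors are orthogonal to machine precision. With as many components
as the predictor rank the solution collapses to ordinary least squares;
the test suite checks both identities and verifies prediction-level
agreement with an independent PLS implementation (mixOmics) to 1e−6.

The component count is not a free lunch: the package selects it by
maximizing leave-one-out Q² (`Q² = 1 − PRESS/SS_tot`), capped at 5 —
standard chemometrics practice when a cross-validated goodness of
prediction is the headline diagnostic. R² is the in-sample fraction of
response variance explained. VIP scores use the y-variance-weighted form
with `mean(VIP²) = 1`; their confidence intervals come from a seeded
percentile bootstrap (default B = 1000) resampling donors within class,
as the reference figures show intervals without naming a method.

The composite fear score is the classification function evaluated on
fear-condition raw (Winsorized) predictors:
`CFS = b₀ + Σ bⱼ xⱼ`. It is exactly linear, so intensity *ranks* — all
that the categorization consumes — are invariant to any increasing
transform. The shipped reference weight fixture (intercept −0.096, SCL
0.053/µS, SCR 0.024/response, HR 0.002/bpm, RR 0.012/(breaths/min), sweat
0.348, HA− 0.095, HA+ 0.060, LA− −0.071, LA+ −0.080) enters sweat in
**grams**: 0.348 × 0.16 g ≈ 0.056 is consistent with composite scores of
0.6–1.2, whereas mg units would let sweat dwarf every other term. The
original report does not state the unit, so `cfs_weights()` records it
explicitly and `compute_cfs()` converts `sweat_mg` columns as needed.

## Intensity categories and their validation

Donors are ranked by CFS and split into equal thirds (low/medium/high);
ties break by donor order. When n is not divisible by 3 the sizes differ
by at most one (remainder 1 → middle group; remainder 2 → the outer
groups) with a warning. Leave-one-out cross-validation repeats the whole
chain without each donor: refit PLS-DA on the remaining donors (both
conditions), re-derive weights, re-score and re-tertile, then place the
held-out donor. Because tertiles are defined only on the retained donors,
the held-out case needs a decision rule: the default takes the *midpoints
between adjacent groups' boundary scores* — the natural decision
boundaries of a rank split — and a nearest-group-mean rule is available
via `rule = "nearest"`. Two further choices are fixed for stability and
noted here: the item→cluster assignment is derived once from the full
table (one donor cannot move it materially), and the component count is
selected once on the full data and reused across folds (per-fold
reselection is defensible but makes folds incommensurable). Per-category
accuracies are tested against the chance proportion 1/3 with the exact
binomial upper tail `P(X ≥ k)`.

## Dose–response statistics

Endpoint distributions in such studies are generally non-normal, so paired
fear-vs-neutral contrasts use the Wilcoxon signed-rank test with the
tie-corrected normal approximation (zeros discarded, mid-ranks, no
continuity correction; Z is positive when fear exceeds neutral). The
intensity→sweat trend uses a linear-contrast one-way ANOVA with weights
(−1, 0, +1) across the ordered categories — the report names only "linear
contrast", and equally spaced centred weights are the textbook choice —
with `F = SS_contrast/MS_within` on (1, N − k) degrees of freedom and
`η² = SS_contrast/SS_total`. Correlations are Spearman with the
t-approximation p-value (Pearson by flag); the correlation table behind
the heat map uses the same method throughout. No multiple-testing
correction is applied, matching the analysis the package reimplements;
users combining many endpoints should correct downstream.

## PID quantification and decay

A trial's response is the mean signal over the stimulus-on window minus
the mean over a pre-onset baseline window — the simplest robust reduction,
exactly invariant to constant offsets, and the generator's square-pulse
construction makes the noiseless round trip exact. First-exposure
responses are regressed on pad weight (mg), emotion (fear = 1) and
freshness (first use = 1) by ordinary least squares. Decay over a session
is fit by nonlinear least squares for `A e^(−kt)` and
`A₁e^(−k₁t) + A₂e^(−k₂t)` (t in minutes; no offset term — the reference
analysis names the family, not the parameterization, and an offset is
degenerate with the slow component over a 30-min window). Parameters are
kept positive by log-parameterization; Levenberg–Marquardt runs from ≥ 20
starts on a log-spaced rate grid (10^−2.5–10 min⁻¹), for the
bi-exponential additionally from perturbations and embeddings of the mono
solution so the nested model can never score below it. `k₁ > k₂` by
convention; R² is computed on the original scale; if every start fails the
best-effort parameters are returned with `converged = FALSE`. Trials
flagged as post-break rebound (volatiles re-accumulating in the headspace
during a pause) are excluded from fitting by default.

## What the synthetic generator emulates — and what it does not

`simulate_donors()` draws all 25 variables from a multivariate normal on a
latent scale and then discretizes: items are rounded and clipped to 0–5,
physiological values clipped at 0, SCR counts rounded. Its defaults are
*calibrated configuration, not ground truth* — the study report prints
only summary values, and the defaults were chosen once so that the
generated data reproduce the printed ensemble:

* **Condition means.** Sweat 95 mg (fear; the average of the printed
  intensity-group means 47.19/77.19/160.31 mg) vs 28 mg (neutral);
  the remaining endpoints are physiologically plausible round numbers
  (SCL 4.5 vs 1.5 µS, SCR 24 vs 8 per session, HR 76 vs 70 bpm, RR 17 vs
  14 breaths/min; HA− items 3.0 vs 0.5, LA+ items 1.0 vs 3.5 on the 0–5
  scale).
* **Condition SDs.** Chosen for consistency with the reference CFS
  equation: the printed coefficients times plausible endpoint SDs must
  leave composite-score noise small enough to yield the printed
  within-group SDs (0.06–0.10). Larger SDs would be incompatible with
  those numbers.
* **Latent intensity.** One hidden multiplier per donor scales *all*
  fear-condition effects jointly (scaling, not shifting, so intensity
  tertiles differ on every endpoint at once). It is
  `floor + Gamma excess` with mean 1, SD 0.35 and floor 0.5: donor
  studies screen out non-responders at intake and exclude donors whose
  fear-condition response resembles calm, so the retained donors' weakest
  response is about half the average — visible in the short lower tail of
  the printed composite-score distribution — and the gamma excess gives
  the right-skew implied by the wider high-intensity group (SD 0.10 vs
  0.06).
* **Correlation structure.** Residual correlation 0.3 between any two
  variables, raised to 0.8 within an item cluster. In the fear condition
  the shared intensity factor adds correlation on top, bringing observed
  cross-variable correlations to the moderate ~0.5 level the discriminant
  analysis is chosen to tolerate. (A residual of 0.5 would push observed
  fear-condition correlations to ~0.65–0.75, stronger than reported.)
* **Arousal/valence.** Derived from the item clusters plus rating noise,
  reproducing the multicollinearity they introduce as predictors.

With these defaults the pipeline reproduces, without further tuning:
100% fear-vs-neutral training accuracy (modal over seeds), R² ≈ 0.80–0.89
and Q² ≈ 0.71–0.84 across seeds (printed values 0.79 and 0.76), CFS
tertile means ≈ 0.65/0.88/1.20 (printed 0.63/0.88/1.17), and held-out
intensity categorization well above the 33.3% chance level.

`simulate_pid_trace()` adds square-pulse responses on Gaussian sensor
noise; per-trial amplitude follows a bi-exponential envelope (defaults
A₁ = 25 mV, k₁ = 0.35 min⁻¹, A₂ = 8 mV, k₂ = 0.02 min⁻¹) times weight,
emotion and freshness multipliers (neutral 0.5×, second use 0.55×,
mirroring the reported median ratios of ~0.49 and ~0.52). The default
schedule is 35 trials over ~30 min, i.e. a per-pad mean inter-trial time
of 51 s: the olfactometer's 12.5-s interval refers to openings across its
four randomized channels, so a single pad is presented roughly every
fourth opening. An optional mid-session break reproduces the headspace
rebound artefact.

The generator does **not** emulate raw waveforms (pulse, respiration,
GSR traces), olfactometer valve dynamics, non-Gaussian endpoint skew
beyond clipping/discretization, missing data, or session/order effects.
Passing tests therefore show that the *pipeline* behaves correctly on data
with the assumed structure — not that real recordings satisfy those
assumptions.

## Numerical choices and degenerate inputs

Tie-breaks: tertile ties by donor order; VIF removal ties by first
maximum. Zero variance: constant items are an error naming the item;
constant predictors cannot be autoscaled and error. MDS convergence
1e−6 stress improvement / 300 iterations; NIPALS stops with an error if
the residual response is orthogonal to X. Degenerate generator configs
(all SDs and the intensity spread zero) reproduce the configured means
exactly, which pins the generator's arithmetic in tests. Winsorization of
a vector it has already processed is a no-op. The decay fitter treats
`A₂ = 0` data correctly because the mono solution is embedded among the
bi-exponential starts.

## Problem sizes

The test and acceptance runs use the study-scale n = 36 donors × 2
conditions for classification, LOO-CV and dose–response checks; moment and
correlation convergence use 1000–2000 donors; structural parameter
recovery (latent intensity vs CFS rank, Spearman ρ > 0.8) uses 200 donors
so the check measures the generative structure rather than small-sample
noise; PID fits use the default 35-trial session. The full suite runs in
well under a minute on one core.

## Known limitations

* The reference CFS weight fixture is faithful only up to the stated unit
  ambiguities (sweat g vs mg; cluster means vs sums), which are resolved
  by explicit, recorded conventions.
* Exact reproduction of the original Q² is not attempted: the original
  software's cross-validation scheme and component count are unreported.
* The LOO-CV held-out categorization rule is underdetermined by the
  source description; both implemented rules are reasonable readings.
* Real-data headline figures that depend on the archived raw dataset
  (Winsorized fractions of 3.03%/2.78%, the F₁,₃₅ = 24.85 contrast, the
  ρ = 0.60 CFS–sweat correlation) are covered structurally by the
  property suite, not numerically.
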