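# fearscore

Quantifying how intensely sweat donors experienced fear — and whether that
intensity is encoded in the volatiles their sweat emits.

In sweat-donation studies of chemical emotion communication, male donors
watch fear-inducing versus calm-neutral film clips while armpit sweat and
psychophysiology are recorded. A single endpoint (heart rate, sweat mass,
self-reported fear) is an unreliable readout of the fear state, so the
encoder-side analysis is multivariate: physiological endpoints and
questionnaire ratings are combined by two-class partial least-squares
discriminant analysis (PLS-DA) into a *composite fear score* (CFS) that
ranks donors by experienced fear intensity. On the encoding side, a
photo-ionization detector (PID) counts the volatile molecules a sweat pad
gives off, trial after trial, as an olfactometer presents it repeatedly.
`fearscore` implements that whole pipeline as a tested R package, together
with a synthetic-data generator so every stage runs without access to raw
study data.

## The model

For donors *i* = 1..n observed in two within-subject conditions
(fear/neutral), the predictor vector
**x** = (SCL, SCR, HR, RR, sweat mass, HA−, HA+, LA−, LA+) collects five
physiological endpoints and four circumplex cluster scores (high/low
arousal × positive/negative affect, each the mean of its member items,
derived by metric MDS of the item correlation structure). After 2.5-MAD
Winsorization per variable and condition, PLS-DA regresses the dummy-coded
condition (fear = 1, neutral = 0) on autoscaled predictors by NIPALS with
*A* latent components (chosen by maximizing leave-one-out Q²):

    y ≈ b₀ + Σⱼ bⱼ xⱼ ,   classify fear ⇔ ŷ ≥ 0.5

The unstandardized coefficients *bⱼ* define the composite fear score
`CFS(x) = b₀ + Σ bⱼ xⱼ` evaluated on raw fear-condition scores. CFS ranks
split donors into low/medium/high intensity tertiles, validated by
leave-one-out cross-validation and exact binomial tests against chance
(1/3). Diagnostics follow chemometrics practice: R², PRESS-based Q²,
classification accuracy, and VIP scores (Σ VIP² = p) with bootstrap CIs.

PID traces are reduced to per-trial baseline-corrected responses (mV);
their dependence on pad weight, emotion and freshness is estimated by
multiple regression, and their decay over a session by multi-start
nonlinear least squares for mono- and bi-exponential laws
`A₁e^(−k₁t) + A₂e^(−k₂t)`.

## Worked example

```r
library(fearscore)
cfg    <- generator_config(n_donors = 36, seed = 1)
donors <- simulate_donors(cfg)
fm     <- build_feature_matrix(donors)          # cluster, score, Winsorize
fit    <- plsda(fm[, attr(fm, "predictors")], fm$condition)
summary(fit)
#> PLS-DA summary: 4 component(s), R2 = 0.880, accuracy = 100.00%
q2_r2(fm[, attr(fm, "predictors")], fm$condition, fit$ncomp)$q2
#> [1] 0.839

cfs  <- compute_cfs(cfs_weights_from_plsda(fit), fm[fm$condition == "fear", ])
tert <- assign_tertiles(cfs, donor_id = fm$donor_id[fm$condition == "fear"])
round(tapply(tert$cfs, tert$category, mean), 2)
#>    low medium   high
#>   0.71   0.92   1.18

loocv_intensity(donors, ncomp = fit$ncomp)
#> LOO-CV fear-intensity categorization (midpoint rule, 4 component(s))
#> overall accuracy: 88.89% (0/36 folds failed)
#>   category  k  n accuracy        p
#> 1      low 12 12   100.00 1.88e-06
#> 2   medium  8 12    66.67 1.88e-02
#> 3     high 12 12   100.00 1.88e-06

fit_decay(extract_trials(simulate_pid_trace(cfg)), model = "bi")
#> bi-exponential decay fit (23 restarts, converged: TRUE)
#>       A1       k1       A2       k2
#> 24.99054  0.34614  7.82388  0.01892
#> R2 = 0.9997 on 35 trials
```

The model separates the 36 donors' fear from neutral records with 100%
training accuracy (R² = 0.88, Q² = 0.84); the fear-condition CFS tertiles
land near 0.7 / 0.9 / 1.2 and the held-out categorization recovers 32 of
36 donors. The simulated sweat pad's volatile output decays
bi-exponentially (fast component ~0.35/min, slow ~0.02/min) with R² > 0.99,
far above the best mono-exponential fit. `run_pipeline()` executes the
same chain end to end and writes all artifacts plus a run manifest.

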