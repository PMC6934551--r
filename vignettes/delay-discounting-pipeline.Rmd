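---
title: "Modelling delay-discounting choices: from task simulation to group statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling delay-discounting choices: from task simulation to group statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discountr)
library(dplyr)
```

## The problem

In an intertemporal-choice experiment a participant repeatedly chooses
between a smaller monetary reward available sooner (SS) and a larger reward
available later (LL). How steeply a person devalues delayed money — their
discount rate — is a stable individual difference that imaging studies
relate to neural measurements: the trial-by-trial *subjective value* of the
chosen option serves as a parametric regressor for fMRI, and per-subject
parameters enter group-level regressions against, for example, PET-derived
dopamine D2-receptor availability (BP~ND~) in regions of interest.

`discountr` implements this analysis chain end to end, with a synthetic-task
generator in place of scanner data so every stage can be exercised and
tested offline.

## The task and its simulator

Each trial offers an early amount \(A_{SS}\) at delay \(D_{SS}\) days versus
a late amount \(A_{LL}\) at \(D_{LL} > D_{SS}\). `generate_trials()`
reproduces the design's stated distributions:

* late amount: Gaussian, mean \$15, SD \$10, truncated to \[\$5, \$30\] by
  rejection sampling;
* early amount: the late amount reduced by a Uniform\[1%, 50%\] fraction,
  rounded to cents (when cent rounding would push the reduction a hair
  outside the 1–50% band, the early amount is pulled back by one cent so the
  band holds exactly);
* early delay drawn uniformly from {0, 14, 30} days ("today, 2 weeks,
  1 month", with a month taken as 30 days) and the late delay adding a
  uniform offset from {14, 30, 42} days;
* 84 trials split sequentially into two 42-trial runs, with onsets 12 s
  apart (the fixed choice-plus-ITI trial duration).

Several aspects of the real design are not specified by its description and
were fixed here once: the reduction fraction is sampled uniformly rather
than from the amount Gaussian; delay and amount menus are drawn
independently per trial; trials are not counterbalanced across runs; and the
\[\$5, \$30\] bounds govern the late amount only (the early amount may fall
below \$5). Simulated reaction times are truncated-lognormal (median 1.5 s,
support (0.3, 7.95\] s — the response window); they exist only to give
regressors realistic timing and never enter the likelihood.

`simulate_choices()` inverts the fitted likelihood: an agent with known
parameters chooses SS with the softmax probability of its subjective-value
difference, plus an independent miss (no-response) process. Fixed seeds make
designs and choice sequences bit-reproducible.

## The candidate value models

Six models compete to explain a participant's choices. Writing \(A\) for
amount, \(D\) for delay in days:

| model | subjective value | free parameters |
|---|---|---|
| hyperbolic | \(A/(1+kD)\) | \(k\), \(\beta\) |
| exponential | \(A e^{-kD}\) | \(k\), \(\beta\) |
| beta-delta (double exponential) | \(A\,(e^{-\beta_{dd} D}+e^{-\delta D})\) | \(\beta_{dd}\), \(\delta\), \(\beta\) |
| discounted utility | \(e^{-rA}/(r(1+kD))\) | \(r\), \(k\), \(\beta\) |
| quasi-hyperbolic (exponentiated delay) | \(A/(1+kD^{s})\) | \(k\), \(s\), \(\beta\) |
| random baseline | — (each option at probability 0.5) | none |

with the softmax choice rule
\(p(a) = e^{\beta\,SV_a} / (e^{\beta\,SV_a} + e^{\beta\,SV_b})\), where the
inverse temperature \(\beta\) captures choice stochasticity (0 = coin flip,
large = deterministic value maximisation). Because the beta-delta family
also uses the symbol \(\beta\), the package names the softmax parameter
`beta_temp` and the beta-delta rate `beta_dd` throughout.

Two of the printed forms differ from their textbook counterparts, and both
are implemented **exactly as written** rather than silently "repaired":

* the beta-delta sum has no \(\tfrac12\) factor, so \(SV(D{=}0) = 2A\);
* the discounted-utility numerator is \(e^{-rA}\), which makes subjective
  value *decrease* with amount (a \(1-e^{-rA}\) numerator would be the usual
  concave utility).

Fidelity to the comparison actually run matters more than plausibility here:
these families enter only as competitors in model selection, and altering
them would change the BIC ordering being replicated. Both quirks are
documented at the function level.

Discount rates are reported on the natural-log scale, `ln_k()`, because raw
\(k\) is strongly right-skewed across individuals.

## Fitting, model comparison, and predictive accuracy

`fit_model()` maximises the softmax likelihood over non-miss trials.
Numerical choices:

* **Parameterisation.** All parameters are positive, so optimisation runs in
  log space; positivity holds by construction and the inverse temperature is
  effectively bounded below only by floating-point underflow. A fitted
  temperature above 100 raises an `unbounded_beta` flag, signalling the
  near-deterministic plateau of the likelihood.
* **Multi-start Nelder-Mead.** A deterministic start grid —
  \(k \in \{10^{-4},10^{-3},10^{-2},0.1,1\}\),
  \(\beta \in \{0.1,1,10\}\), \(r \in \{0.01,0.1,1\}\),
  \(s \in \{0.5,1,2\}\), \(\beta_{dd},\delta \in \{10^{-3},10^{-2},0.1\}\) —
  crossed per family, each start run to relative objective tolerance
  \(10^{-6}\) (at most 2000 iterations); the best converged start wins, ties
  broken by lower negative log-likelihood then lexicographic parameter
  order. Tests verify the optimum beats a dense 100×100 log-spaced grid
  search within \(10^{-4}\) nats.
* **Probability floor.** Choice probabilities are floored at \(10^{-12}\)
  before logs, so extreme temperatures cannot produce infinite negative
  log-likelihoods.
* **Trial floor.** Fitting requires at least 10 valid (non-miss) trials
  (configurable in `fit_config()`).

Model fit is scored by \(BIC = p\,\ln(n_{valid}) - 2\,\ell_{max}\) (natural
log; hyperbolic and exponential pay \(p = 2\), the three-parameter families
\(p = 3\), the random baseline \(p = 0\) with the closed-form likelihood
\(\ell = -n\ln 2\)). `compare_models()` runs paired two-sided t-tests of the
reference model's BIC against each competitor across subjects (df = N − 1,
differences reference-minus-other so negative t favours the reference); a
zero-variance difference vector is flagged rather than returning NaN.

Predictive adequacy is scored by **balanced accuracy**: predictions are
deterministic (SS iff \(SV_{SS} > SV_{LL}\); exact ties go to LL, whose face
amount is strictly larger), tallied into per-class recalls and averaged,
\(\tfrac12\!\left(\frac{tSS}{tSS+fSS} + \frac{tLL}{tLL+fLL}\right)\). The
false counts are defined per *actual* class (fSS = actual-SS trials
mispredicted), the standard mean-recall reading; if a participant never
chose one option the present class's recall is returned with a `degenerate`
attribute. The random baseline's predictions are seeded coin flips, which
calibrate to 0.5.

## Subjective-value regressors

`build_regressors()` turns a fitted subject into the two first-level GLM
event regressors:

* **un-modulated**: one event per trial spanning the choice period — onset
  at stimulus onset, duration equal to the reaction time (7.95 s, the full
  window, for misses), weight 1;
* **sv-modulated**: one zero-duration event per non-miss trial at the moment
  of response (onset + RT), weighted by the chosen option's subjective value
  under the subject's fitted parameters, mean-centred within each run.

"At the choice reaction time" is read as response-locked onset; the
alternative reading (stimulus-locked, RT-long duration) is available via
`modulated_onset = "stimulus"`. Demeaning is per run — the convention FSL
FEAT applies to parametric EVs — rather than per session; weights before
centring equal the value-model outputs exactly, with no rescaling. Empty
regressors are an export error, since FEAT rejects empty EV files.
`group_average_sv_series()` implements the supplementary variant that swaps
each subject's discount rate for the cohort geometric mean
\(k = \exp(\overline{\ln k})\); `sv_rank_agreement()` measures (rather than
assumes) the Spearman rank agreement between the subject-specific and
group-average weight series.

## Group-level association stage

`run_association_grid()` crosses PET BP~ND~ ROIs (ventral striatum,
midbrain, vmPFC) with fMRI subjective-value ROIs (those three plus posterior
cingulate) — 12 standardized regressions, Bonferroni-corrected as one family
(threshold 0.05/12 ≈ 0.004). For a simple regression on z-scored variables
the standardized coefficient *is* Pearson r, its p-value comes from
\(t = r\sqrt{(n-2)/(1-r^2)}\) with n − 2 df, and its 95% interval from the
Fisher z-transform \(\tanh(\operatorname{atanh} r \pm 1.96/\sqrt{n-3})\) —
which reproduces the asymmetric intervals such regressions report.
Behavioural correlations (Ln(k), proportion sooner) form separate,
uncorrected families whose sizes are still recorded in the output.

Outlier triage follows the combined rule: a point is influential only when
its Cook's distance exceeds 4× the mean *and* its externally studentized
residual (t with n − 3 df, two-sided) is significant at 0.05; the
model-level heteroskedasticity check is Breusch-Pagan (the most common
choice where the test is otherwise unspecified). Single-criterion flags are
reported but never auto-excluded — dropping a subject is an explicit user
action. Diagnostics are computed on the unadjusted bivariate model;
covariate-adjusted follow-ups (`adjusted_regression()`, age z-scored, sex as
a 0/1 indicator) report the standardized partial coefficient with a t-based
Wald interval, since Fisher-z intervals are defined for simple correlations
only.

`simulate_subject_table()` provides a synthetic stand-in for the per-subject
scalar table, matching the study sample's marginal means and SDs (BP~ND~: VS
17.3 ± 2.90, midbrain 1.50 ± 0.236, vmPFC 0.762 ± 0.139; Ln(k)
−4.68 ± 1.27; age 20.9 ± 1.95; 12F/10M in 22) with an optional planted
association for power and ranking checks. All cross-variable correlations
are zero by construction except Ln(k) with proportion-sooner (planted at the
strong level such cohorts show, r ≈ 0.91).

## What the simulations do and do not establish

The generator matches the task's marginal distributions and the cohort's
parameter distribution (Ln(k) ~ N(−4.68, 1.27²), inverse temperature 3.74,
84 trials), so passing tests establish that the estimator recovers the
parameters that generated the data and that model selection identifies the
generating family. They do **not** establish behavioural realism beyond the
softmax-hyperbolic process: real participants show RT-value coupling,
attention lapses beyond an independent miss process, session effects, and
model misspecification, none of which are simulated. Two visible
consequences: simulated cohorts choose the sooner option ~43% of the time
(the real cohort's 55% depends on design-by-preference interactions the
independent menus do not reproduce), and simulated balanced accuracies run
high (~90% versus the upper-70s typical of real data), because the fitted
family is exactly the generating one. BIC values, by contrast, land close
to their empirical analogues (hyperbolic mean ≈ 31 on 84 trials), since the
likelihood scale is set by the temperature. The random baseline's BIC is
\(2 \cdot 84 \cdot \ln 2 \approx 116.4\) for a full-length session; a
reported random-model BIC near 62 is consistent only with roughly half that
trial count, a convention difference this package does not attempt to force
agreement with.

Test and reproduction problem sizes — 50-subject recovery cohorts, 20
subjects for the dense-grid oracle, \(10^4\)-trial marginal checks,
2000-replicate null calibrations — were chosen as the smallest sizes at
which the Monte-Carlo error is comfortably below each assertion's margin.

## Known limitations

* Fitting is per-subject maximum likelihood; no hierarchical shrinkage,
  AIC/cross-validation selection, or RT modelling.
* The regressor stage stops at event files: HRF convolution, GLM estimation,
  and voxelwise inference belong to the imaging toolchain.
* The beta-delta and discounted-utility forms are intentionally the printed
  ones (see above); users wanting literature-standard variants should treat
  those families' absolute SV scales with care — model *selection* is
  unaffected by the monotone-in-parameters quirks only within each family.
* Sex enters adjusted models as a single binary indicator; richer encodings
  are the user's responsibility.
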