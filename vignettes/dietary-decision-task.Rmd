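---
title: "Scoring and inference for the dietary decision-making task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and inference for the dietary decision-making task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietchoice)
```

## The measurement problem

Dietary cognitive restraint (the intent to restrict energy intake to control
weight) and disinhibited eating (eating in response to emotional or social
cues, or to palatable food being available) are usually measured by
questionnaire. The TFEQ-R18 provides three subscales — cognitive restraint
(CR, 6 items), uncontrolled eating (UE, 9 items) and emotional eating (EE, 3
items) — each rescaled to 0–100 by

$$\text{score} = \frac{\text{raw} - \text{raw}_{\min}}
  {\text{raw}_{\max} - \text{raw}_{\min}} \times 100 .$$

Because UE and EE are strongly correlated (around 0.70 in samples like this
one) and both index disinhibition, the package also forms a *disinhibited
eating* composite as their plain mean.

The dietary decision-making task measures the same constructs behaviourally.
Participants first rate 50 foods for taste and for health on 1–5 Likert
scales. The rated item closest to the participant's *median* taste and
health ratings becomes the **referent**; on each of 49 trials the
participant states a preference for a target food over that referent on a
−2 ("strong no") to +2 ("strong yes") scale while reaction time (RT) is
recorded to the millisecond, up to a 4 s stimulus window.

From the ratings and preferences the package derives, per participant:

* **health sensitivity** and **taste sensitivity** — the two slopes of the
  per-participant ordinary least squares model
  $\text{preference} \sim 1 + \Delta\text{health} + \Delta\text{taste}$,
  where $\Delta$ is the target-minus-referent rating difference;
* **proportion of healthy (tasty) options preferred** — preferred trials on
  which the preferred food was rated strictly healthier (tastier), divided
  by all completed trials;
* trial-level **difference scores**: preferred-minus-non-preferred health
  and taste differences (each forced into −4..4 by the 1–5 scales) and
  their composite, health-minus-taste, spanning −8..8 with the sparse
  extremes collapsed into ±5 (−8, −7, −6 → −5; 6, 7, 8 → 5).

The inference layer then mirrors the study design: implausible participants
are excluded, demographics that correlate with any outcome at *p* < 0.10
become covariates, task outcomes are regressed on the standardized
eating-behaviour scores, and single-trial RTs are regressed on the
difference scores, with moderation by restraint or disinhibition tested via
median splits (ties to the low stratum) and continuous interactions flagged
at *p* < 0.10 by a Wald *t* test.

## Decisions taken where the design was open

* **Neutral trials.** Difference scores are defined only on trials where a
  preference was indicated, but the per-participant sensitivity regressions
  keep neutral trials: 0 is a valid point on the −2..2 preference scale,
  and dropping it would both discard information and bias slopes upward.
* **Referent ties.** "Closest to the median on both taste and health" is
  implemented as the Euclidean distance to the median pair (a Chebyshev
  option exists); exact ties go to the lowest item id so scoring is
  deterministic.
* **RT trimming unit.** The ±2.2 SD trim is applied within participant by
  default — the conventional choice for RT data, since individuals differ
  strongly in baseline speed — in a single pass, with a pooled option.
* **Missing questionnaire items** are an error by default; an optional
  prorating mode imputes a participant's mean keyed response within the
  subscale. No missing-data rule is assumed silently.
* **Single-attribute difference range.** With 1–5 ratings a single
  attribute difference cannot leave −4..4; only the health-minus-taste
  composite spans −8..8. The code validates the former and collapses the
  latter.
* **Pooled OLS for trial-level RT models.** Trial-level models are plain
  pooled OLS. When slopes or intercepts genuinely vary across participants,
  pooled OLS understates the uncertainty of participant-level contrasts
  (the errors are clustered); `cluster_robust = TRUE` switches every
  trial-level model to participant-clustered sandwich standard errors. It
  is off by default so the default output matches the study-style analysis.

## What the synthetic cohort emulates

`sim_config()` + `generate_cohort()` produce a complete study-shaped data
set with known ground truth, so every scoring and inference step can be
verified without any external data. The generative model, participant $i$,
trial $t$:

1. **Traits.** $(CR, UE, EE)$ are trivariate normal on the 0–100 scale with
   means (42, 36, 36) and SDs (22, 19, 28) taken from the weight-status
   descriptives of samples of this kind; EE shifts +4 for women. The
   *latent* UE–EE correlation is pre-compensated upward so that the
   *scored* subscales — after item discretization, item noise and
   floor/ceiling censoring — land at the configured `rho_ue_ee` (default
   0.70). The compensation combines an analytic attenuation factor (item
   noise + rounding variance, averaged over the subscale) with a fixed
   0.975 censoring allowance calibrated once by simulation at the default
   trait distributions.
2. **Questionnaire items.** Each item discretizes its trait onto the 1–4
   response scale with Gaussian item noise (SD 0.3), rounding and clipping.
3. **Foods and ratings.** Fifty foods carry latent health and taste values
   (bivariate normal, correlation −0.3: tasty foods tend to be seen as less
   healthy); participant ratings add noise (SD 0.5), round and clip to 1–5.
4. **Preferences.** The referent is chosen by the *scoring module's own
   rule*. Trial utility is
   $u = w_{\text{health}}\,\Delta h + w_{\text{taste}}\,\Delta t +
   \varepsilon$, mapped to −2..2 by fixed symmetric thresholds at ±0.5 and
   ±1.5. The weights are trait-linked —
   $w_{\text{health}} = 0.35 + 0.15\,z_{CR} - 0.10\,z_{DIS} + \eta$ and
   conversely for taste — plus an idiosyncratic component
   $\eta \sim N(0, 0.4)$. The idiosyncratic part matters twice over: real
   sensitivity variance is mostly *not* trait-explained (published
   standardized trait slopes sit near 0.15, not 0.8), and it is what makes
   the weights identifiable from 49 trials.
5. **Reaction times.**
   $rt = \big(1300 + 6\,(\text{age}-34) - b_{\text{health}} hd -
   b_{\text{taste}} td\big)\, e^{\sigma Z}$, clipped to [200, 4000] ms and
   rounded to the millisecond, where $hd, td$ are the
   preferred-minus-non-preferred differences (0 on neutral trials).
   Population slopes default to 13 and 12 ms per unit — the magnitudes
   reported for tasks of this kind — modulated by ±6 ms per trait SD
   ($b_{\text{health}}$ rises with restraint and falls with disinhibition,
   $b_{\text{taste}}$ the reverse; the implied spread between median-split
   strata, 9–10 ms, sits inside the published 6–9 ms range), plus a 2 ms
   idiosyncratic SD. Multiplicative lognormal noise ($\sigma = 0.12$) keeps
   RTs positive and right-skewed with a mean near 1.3 s; 2% of trials get a
   1.8–3× inflation to exercise the outlier trim.

Noise scales are stated assumptions — no distributional RT parameters
beyond the ~1.3 s mean and 4 s cap are published for this task. $\sigma$
was fixed at 0.12 so that the linear difference-score structure, including
its trait moderation, is resolvable at the study's size (500 participants
× 49 trials); larger values mainly lower every test's power without
changing any estimand.

**The null generator.** For type-I-error checks of the interaction flag,
"moderation off" means `rt_trait_modulation = 0`, `rt_slope_resid_sd = 0`
*and* `rt_age_slope_ms = 0`. With any participant-level slope or intercept
heterogeneity left in, pooled OLS understates the interaction SE and the
flag fires above its nominal 10% rate (we measured ≈0.17–0.21 in
simulation) — which is exactly the clustering caveat above, not a defect of
the test statistic. Under the fully iid null the flag rate is consistent
with 0.10.

## What passing tests do and do not show

The generator reproduces the *structure* the analysis assumes: Likert
discreteness, referent anchoring, trait-linked weights, linear RT slopes
with lognormal noise, censored scales. It does not emulate real data's item
content (subscale items are parallel measurements of one trait, which makes
Cronbach's alpha run high, ~0.93–0.95, against ~0.84–0.90 in real samples),
sequential effects across trials, non-linear utility, or speed–accuracy
style strategies. Recovery of generator truth therefore validates the
pipeline's arithmetic and statistical logic, not the psychological model of
any particular sample.

## Numerical choices

* OLS fits go through R's QR decomposition (`lm` / `qr`); the test suite
  checks every fitted coefficient against a naive normal-equations solver
  at 1e-8.
* Rank-deficient per-participant designs (a participant whose target
  differences are collinear) are flagged, returned as `NA`, counted, and
  excluded from participant-level models.
* Zero-variance cases return defined answers: a constant RT vector trims
  nothing; a zero-variance score matrix makes Cronbach's alpha `NA` with a
  warning; constant variables are refused by the standardizer.
* Confidence intervals are exact *t* intervals, `estimate ± t_crit · SE`.
* Standardization uses the n−1 sample SD, so a standardized simple slope
  equals the Pearson correlation identically.

## Problem sizes used by the checks

The packaged checks run one default cohort (n = 500, 49 trials each, fixed
seed), a 10^6-draw normal sample for the trimming-fraction check, 100
random small instances for the OLS oracle comparison, and 200 null
replicates at n = 60 for the interaction flag-rate check — sizes chosen to
give each check resolving power while keeping a full run in minutes.

## Known limitations

* The deposited study data are not bundled; analyses of them require
  downloading the public repository and running `run_pipeline("analyze")`
  on the four tables. All printed numbers in this package come from the
  synthetic cohort.
* Trial-level inference is pooled OLS by design fidelity; for
  publication-grade uncertainty on trait-moderated RT effects use
  `cluster_robust = TRUE` or a mixed model outside this package.
* The generator's demographics are simple parametric sketches (enough for
  covariate screening to have true signal), not a demographic model of any
  population.
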