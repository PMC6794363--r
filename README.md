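# dietchoice

Scoring and inference for a dietary decision-making task, plus the
questionnaire that anchors it.

Researchers studying eating behaviour often want to know how much a
person's food choices are driven by *taste* versus *health* perceptions,
and how that relates to their dietary **cognitive restraint** (the intent
to restrict intake to control weight) and **disinhibited eating** (eating
in response to emotions or palatable-food availability). This package
implements the full analysis chain for a two-phase task that measures this:
participants rate 50 foods for taste and health (1–5), then state a −2..+2
preference for each remaining food against a **referent** (the item closest
to their median taste and health ratings) while reaction time is recorded.

What the package computes:

* **TFEQ-R18 scoring** — cognitive restraint (6 items), uncontrolled eating
  (9) and emotional eating (3), each rescaled by
  `(raw − min) / (max − min) × 100`; a disinhibited-eating composite
  `(UE + EE) / 2`; Cronbach's alpha.
* **Task scoring** — referent selection; per-trial preferred-minus-non-preferred
  health and taste difference scores and their health-minus-taste composite
  (extremes collapsed into ±5); per-participant **health sensitivity** and
  **taste sensitivity** as the slopes of
  `preference ~ Δhealth + Δtaste` (OLS, per participant); proportions of
  healthy/tasty options preferred; ±2.2 SD reaction-time trimming.
* **Inference** — plausibility-based participant exclusions, covariate
  screening at *p* < 0.10, standardized regressions of task outcomes on
  eating-behaviour scores, pooled trial-level RT regressions (ms per
  difference-score unit), and moderation of the RT slopes by restraint or
  disinhibition (median-split and continuous, interactions flagged at
  *p* < 0.10; participant-clustered SEs available behind a flag).
* **A synthetic cohort generator** with known ground truth (traits,
  preference weights, RT slopes), so the whole chain is testable offline.

## Worked example

The `analysis/` scripts run the whole study-shaped workflow on a simulated
cohort of 500 participants:

```sh
Rscript analysis/01_simulate.R    # writes results/cohort/
Rscript analysis/02_score.R       # writes results/scores/
Rscript analysis/03_inference.R   # writes results/analysis/
```

Step 2 prints, for the default seed:

```
Retained 500 of 500 participants; 0 excluded
Cronbach's alpha: CR 0.95, UE 0.94, EE 0.93
Scored UE-EE correlation: 0.641 -> disinhibition composite used
RT trimming removed 700 of 24500 trials (2.86%)
Mean retained RT: 1296 ms
```

— the two disinhibition subscales correlate strongly (target 0.70), the
trim removes about the 2.78% a ±2.2 SD rule should under normality, and
mean RT sits near the 1.3 s typical of this task. Step 3 then prints:

```
Standardized unadjusted slopes:
  restraint    -> health sensitivity +0.29, taste sensitivity -0.23
  disinhibition-> health sensitivity -0.21, taste sensitivity +0.28
Adjusted RT slopes: health -10.19 ms/unit, taste -7.07 ms/unit
Full-span (8-unit) speed differences: health 82 ms, taste 57 ms
Median-split restraint x health difference: low stratum -5.22, high stratum
-11.25 ms/unit (interaction p = 0.00819, flagged)
```

Read: restrained participants weight health more and taste less (and
vice versa for disinhibited participants); people answer faster the more
the preferred food dominates on either attribute (~10 ms per rating unit,
~82 ms across the full −4..4 span); and the health-difference speed-up is
roughly twice as steep in the high-restraint half of the sample — the
moderation the task is designed to expose.

The same chain is available as one call:

```r
library(dietchoice)
m <- run_pipeline("full", sim = sim_config(seed = 1), out_dir = "results/run")
m$results$moderation_table
```

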