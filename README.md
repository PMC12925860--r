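# faceddm

Behavioral modelling of binary happy–angry face-emotion labeling on a
15-step morph continuum, for computational-psychiatry studies of perceptual
bias in youth. The package decomposes choices and response times with a
drift-diffusion model (DDM) whose drift rate varies linearly with the morph
index, applies the standard trial- and participant-level quality control for
this task, and reproduces the two group-level analyses built on top of the
fits: a four-parameter logistic (4PL) comparison of psychometric inflection
points between diagnostic groups, and correlation/ANOVA summaries of the
fitted metrics against clinical questionnaire scores. A synthetic-data
generator emulates the full study — task schedule, diffusion observers by
diagnostic group, questionnaire cohorts with a target correlation structure,
and ROI beta profiles — so every stage runs and is tested offline.

## The model

On each trial an observer views morph `s` (1 = prototypically happy,
15 = prototypically angry, 8 = most ambiguous) and accumulates noisy
evidence between a lower ("happy") and upper ("angry") boundary separated by
`a`, starting at relative position `z_r`, with non-decision time `t0` and
diffusion constant fixed at 1. The drift rate is linear in the morph index:

    v(s) = v_int + s * v_slope

Two behavioral metrics follow:

- **sensitivity** `v_slope` — how steeply drift (and hence choice and
  speed) changes along the continuum;
- **perceptual bias** `s_indiff = -v_int / v_slope` — the morph index at
  which drift vanishes, i.e. the observer's point of indifference. Values
  below 8 mean ambiguous faces are tipped toward "angry".

Trials are scored with the Wiener first-passage-time likelihood (dual
small-time/large-time series, truncation error ≤ 1e-7 per evaluation) and
each participant is fitted by bounded maximum likelihood from multiple
starts. Group psychometric curves are summarised with a 4PL fit
`p(s) = gamma + (lam - gamma) / (1 + exp(-beta (s - x0)))` whose free
asymptotes adjust the inflection `x0` for the maximum probability of either
judgment; inflections are compared with a Wald t statistic.

## Worked example

```r
library(faceddm)

# a synthetic observer biased slightly toward angry (s_indiff ~ 7.86)
p <- ddm_params(v_int = -2.2, v_slope = 0.28, a = 1.2, z_r = 0.5, t0 = 0.25)

sched  <- generate_task_schedule(seed = 1)   # 540 events, 4 runs, ITIs >= 500 ms
trials <- simulate_trials(p, sched, seed = 2)

qc <- apply_qc(trials)                        # fast-RT filter + 80% inclusion rule
qc$report
#> QC: 450 trials in, 0 fast-RT removed; extreme-morph accuracy 93.3%; INCLUDED

fit <- fit_participant(qc$trials, seed = 3)
fit
#> Diffusion-model fit: 450 trials, converged (5 starts)
#> Diffusion-model parameters (drift linear in morph index)
#>   v_int = -2.4639, v_slope = 0.3029, a = 1.2089, z_r = 0.5153, t0 = 0.2484 s (sigma = 1)
#>   indifference point s_indiff = 8.134
#>   sensitivity (v_slope) = 0.3029; perceptual bias (s_indiff) = 8.134; nll = 74.64
```

The fitted sensitivity (0.30 vs true 0.28) and perceptual bias (8.13 vs
true 7.86) recover the simulated observer to within the sampling noise of a
450-trial session. Group-level inflection points from two 4PL fits are
compared with a Wald statistic; wrapping published group estimates
(7.65 [SE 0.06] vs 8.33 [SE 0.08]) reproduces the familiar group difference:

```r
cmp <- compare_inflections(fourpl_fit(0.02, 0.98, 1.5, 7.65, 0.06),
                           fourpl_fit(0.02, 0.98, 1.5, 8.33, 0.08))
cmp$t
#> [1] -6.8
```

`run_pipeline(pipeline_config(out_dir, seed))` wires the whole chain —
simulate → QC → fit → analyze → replicate → report — and writes six
artifacts (parameter table, correlation table, ANOVA/post hoc report, 4PL
replication, age–sensitivity replication, ROI contrast association) plus a
seed-stamped `metadata.json`.

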