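---
title: "Modelling face-emotion labeling with a stimulus-dependent-drift diffusion model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling face-emotion labeling with a stimulus-dependent-drift diffusion model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faceddm)
```

## The task and the model

The package targets a two-alternative face-emotion labeling task: faces
morphed linearly from prototypically happy (`s = 1`) to prototypically
angry (`s = 15`), with the middle morph (`s = 8`) the most ambiguous, shown
briefly and judged "happy" or "angry" under time pressure. Choices and
response times (RTs) are modelled jointly with a drift-diffusion model
(DDM): evidence accumulates as a Wiener process with drift `v` between an
absorbing lower boundary (a "happy" response) and upper boundary (an
"angry" response) separated by `a`, starting at relative position `z_r`,
and the observed RT adds a non-decision time `t0` for encoding and motor
execution.

The variant implemented here makes the drift a linear function of the morph
index,

$$v(s) = v_{\mathrm{int}} + s\, v_{\mathrm{slope}},$$

which yields the two metrics of interest per participant:

* **sensitivity** $v_{\mathrm{slope}}$, the rate at which the evidence
  stream changes along the morph continuum, and
* **perceptual bias** $s_{\mathrm{indiff}} = -v_{\mathrm{int}} /
  v_{\mathrm{slope}}$, the (real-valued) morph index at which the drift is
  zero — the observer's point of indifference. Values below the physical
  midpoint 8 indicate a tilt toward "angry" interpretations of ambiguous
  faces.

Assumptions worth keeping in view: drift is exactly linear in `s`
(curvature in the true psychometric mapping is absorbed into fit error);
there are no across-trial variability parameters (`sv`, `st0`, `sz` of the
full Ratcliff model are out of scope); no lapse process; and a single
stationary parameter set per participant across the session.

### Conventions

Five parameters are estimated per participant: `v_int`, `v_slope`, `a`
(> 0, evidence units), `z_r` (in (0, 1); 0.5 is unbiased), `t0` (seconds,
bounded above by the minimum observed RT). The diffusion constant is fixed
at `sigma = 1`; it is not jointly identifiable with `v` and `a`, and some
traditions fix 0.1 instead. All derived quantities reported by the package
(`s_indiff`, orderings and signs of `v_slope`) are invariant to that
convention, which the scale-invariance tests assert. The upper boundary
codes "angry" and positive drift favours it, so `v_slope` is positive for
typical observers; morphs are indexed 1-based so the printed group biases
(7.52, 8.48) straddle the midpoint 8. `z_r` is estimated freely per
participant rather than pinned at 0.5; it absorbs pre-stimulus response
bias, which is conceptually distinct from the perceptual bias carried by
$s_{\mathrm{indiff}}$.

## Numerics

**Likelihood.** The trial likelihood is the defective Wiener
first-passage-time density at the observed boundary and RT. It is computed
in C++ with the standard dual-series approach: for each evaluation the
small-time and large-time series term counts needed for a truncation error
below 1e-7 are computed, and the cheaper representation is used. Density
values are floored at 1e-100 inside the negative log-likelihood so a single
outlying trial cannot produce infinities during optimisation; any trial
with `rt <= t0` contributes a large fixed penalty (1e10) instead, which
also enforces the `t0` bound smoothly from inside the optimiser.

**Simulation.** `simulate_trials()` integrates the diffusion by
Euler–Maruyama with `dt = 1e-4` s. Discretisation leaves a small bias: a
path can cross a boundary inside a step and return, so absorption is
slightly delayed and choice fractions are marginally more extreme
(effectively the boundary sits ~0.58·√dt ≈ 0.006 evidence units too far
out). At the default parameters this shifts choice probabilities by ~1e-3
and mean RTs by ~5 ms — an order of magnitude below the sampling noise of a
450-trial session. The acceptance tests compare simulated choice fractions
with the exact absorption probability within 3 binomial SDs plus this
documented allowance.

**Fitting.** `fit_participant()` minimises the negative log-likelihood by
L-BFGS-B within bounds (`a` in [0.2, 5], `z_r` in [0.02, 0.98], `t0` in
[0, 0.999·min RT], drift parameters in wide boxes). Starts combine a
moment heuristic — a linear regression of signed choice on morph for the
drift line, 85% of the minimum RT for `t0` — with multiplicative jitter,
five starts by default, plus one polishing run from the incumbent. A fit is
flagged `converged` when a run with a clean optimiser status reaches the
best value within 1e-3; line-search failures of finite-difference L-BFGS-B
at an already-located optimum are thereby not misreported as failures.
Degenerate data (a single response type throughout) are flagged and never
silently fitted.

**4PL psychometric fits.** `fit_4pl()` performs (by default unweighted)
least squares of $p(s) = \gamma + (\lambda - \gamma)/(1 + e^{-\beta(s -
x_0)})$ via Levenberg–Marquardt, multi-started over a grid of inflection
values crossed with three slope starts. LM with box constraints can stall
with an asymptote pinned at 0 or 1; the fitter restarts once from the best
point nudged into the interior and keeps the better optimum. Standard
errors come from the Jacobian at the optimum (checked against a parametric
bootstrap in the tests). The free lower *and* upper asymptotes implement
the "adjusted for the maximum probability of either judgment" reading of
the group-curve analysis. Binomial weighting by trials-per-point is
available by configuration. The Wald comparison of two inflections uses a
configurable degrees-of-freedom value defaulting to 50; the published df
for this comparison is not derivable from the group sizes (27 + 24 − 2 =
49), so the package reports whatever df it is configured with rather than
guessing a provenance.

## Quality control

Two rules, applied in this order:

1. trials with RT **strictly below 150 ms** are removed (a value of exactly
   150 ms is kept, following the strict inequality in the rule);
2. a participant is included when accuracy on the two most extreme morphs —
   "happy" at `s = 1`, "angry" at `s = 15` — is **at least 80%**, pooled
   over the two extremes. Pooling is the weaker, more inclusive reading of
   the rule; a per-morph mode (each extreme separately ≥ 80%) is available
   via `mode = "per_morph"`. With no extreme-morph trials the status is
   returned as indeterminate, never silently passed.

Whether the original order of the two rules was filter-then-check is not
documented; filtering first is the conservative choice (anticipations
should not count against accuracy).

## Group statistics

Correlations between fitted metrics and clinical scores are Pearson,
pairwise-complete, Bonferroni-corrected over **all cells of the emitted
table** (2 metrics × 4 measures = 8 by default); since published family
sizes for such tables are rarely stated, the family size used is always
reported alongside the adjusted p. The one-way ANOVA is the classical
between/within decomposition; post hoc pairwise t tests use the pooled
within-group SD over all groups with `df = N − k` (classical post hoc
convention; Welch per-pair tests available), Bonferroni-corrected over the
number of pairs. The age–sensitivity replication correlates age with
sensitivity after excluding healthy participants, mirroring the replication
design in which healthy volunteers had contributed to the original finding.

## ROI contrasts

Valence and ambiguity are encoded as linear and quadratic contrasts over
the 15 morph regressors, centred on the middle morph. The quadratic is
additionally centred to zero sum, making it orthogonal to the linear set so
the two coefficients are separately interpretable; both are normalised to
unit sum of squares so coefficients are comparable across ROIs.
Per-participant coefficients are the orthogonal projections of the
15-value beta profile (plus intercept), and their association with a
symptom score is a Pearson correlation, with median-split mean profiles
emitted for plotting. Voxelwise mixed-effects modelling, covariates and
cluster correction are deliberately out of scope — the module operates on
desk-scale ROI summaries.

## The synthetic-data generator

The generator is first-class, tested code; it defines the conditions under
which the pipeline is exercised.

**Task schedule.** 15 morphs × 30 presentations plus 90 fixation-only
events (540 events) over 4 runs, stimulus events split 113/113/112/112 and
fixation 23/23/22/22 (per-run splits are not documented; the near-even
split is ours). Each run opens and closes with 10 s of fixation. ITIs are
drawn from a shifted exponential with a 500 ms floor; only the floor and
the ~421 s expected run length constrain the decay rate, so the mean excess
is solved per run from the run's event count and the 400 ms of stimulus +
mask time per presentation.

**Observers.** True bias is drawn per diagnostic group:
Normal(7.52, 0.95) for the DMDD-like group (n = 27) and Normal(8.48, 1.40)
for controls (n = 24), the published group moments; ADHD (n = 23), anxiety
(n = 19) and ODD (n = 2) groups, whose bias moments are not published, sit
between the two at mean 8.2, SD 1.2. The drift intercept is then set as
`v_int = −s_indiff · v_slope`, so each observer's true bias is exact by
construction. The remaining defaults are the package's own: `a` ~
N(1.2, 0.2) truncated at 0.4, `z_r` ~ N(0.5, 0.05) clamped to (0.05,
0.95), `t0` ~ N(0.25, 0.05) s truncated at 0.1, and sensitivity
`v_slope` ~ lognormal(log 0.3, 0.2). The sensitivity scale deserves a
note: it was chosen so that a typical observer's accuracy at the extreme
morphs is ~90%. Much shallower observers (e.g. `v_slope` ≈ 0.12 at
`a` = 1.2) would have ~71% extreme-morph accuracy — they would fail the
task's own 80% inclusion rule and produce group choice curves far from the
near-0/1 asymptotes that group psychometric fits in this literature show —
so such a default would simulate a population the analyzed sample could not
contain.

**Clinical cohort.** Child and parent forms of a 41-item anxiety scale
(items 0–2, total 0–82) and a 6-item irritability scale (items 0–2, total
0–12) are generated through a Gaussian copula: four latent instrument
factors, item latents loading λ = 0.5 on their factor, discretised at
equal-mass cutpoints and summed. Discretisation and item aggregation
attenuate correlations, so the factor correlations are **calibrated by
construction**: the total-score correlation implied by a factor correlation
is computed analytically (numerically integrated bivariate-normal item-pair
covariances) and inverted by root finding, separately for each target cell.
Targets default to the published cross-informant (anxiety 0.58,
irritability 0.56) and cross-measure (child 0.46, parent 0.50) values; the
two cells with no published value (child anxiety × parent irritability and
vice versa) default to 0.40, between the published same-informant values
and zero. The calibrated matrix is checked for positive semi-definiteness
before sampling. Ages are uniform on 8–22 years; diagnoses follow the
published sample composition (27/23/19/2/24 per 95).

**ROI betas.** Each participant's 15-value profile is intercept +
(base slope + coupling · standardised symptom) · linear weights +
quadratic term + iid Gaussian noise — exactly the forward model the
contrast module inverts, which is what makes the null and recovery
simulations in the tests meaningful.

What the generator does **not** emulate: across-trial parameter
variability, lapses and attention drops, RT contamination, item-level
questionnaire structure beyond a single factor per instrument, missing
data, and any spatial or temporal fMRI noise structure. Passing tests on
synthetic data therefore demonstrate the estimators' correctness and
calibration under the model's own assumptions, not robustness to the many
ways real data deviate from them.

## Problem sizes

The test suite and the acceptance script run at the study's own scale
where the quantity being checked depends on it: cohorts of 27 and 24
observers × 450 trials for the group-bias recoveries, 27 × 30 and 24 × 30
responses per morph for the 4PL recoveries, n = 10,000 for generator
calibration checks. Property suites (density normalisation,
simulator-vs-analytic agreement, statistic-vs-oracle identities) use
compact grids and toy tables, and the end-to-end pipeline smoke test uses a
reduced configuration (11 observers × 150 trials), chosen as the smallest
sizes at which the respective properties are informative.

## Known limitations

* Maximum likelihood on (choice, RT) pairs is the package's estimation
  choice; the original estimation objective for this task family is not
  documented, so parameter equality with any particular legacy codebase is
  not guaranteed — recovery of the generating parameters is the criterion
  used instead.
* With `z_r` free, the starting point and the drift intercept trade off;
  at shallow sensitivities the bias estimate inherits noticeable variance
  (the single-observer recovery tests quantify this).
* The Euler simulator's discretisation bias, though small, is visible in
  very large simulations; a bridge-corrected or exact sampler would remove
  it at some implementation cost.
* 4PL inflection SEs come from the local Jacobian and are mildly
  optimistic for small numbers of morph levels (the bootstrap check bounds
  the discrepancy at 20%).
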