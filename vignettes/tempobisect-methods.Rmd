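---
title: "Models and methods behind tempobisect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tempobisect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempobisect)
```

# The scientific problem

In an auditory temporal bisection task, listeners first learn a short (2 s)
and a long (5 s) reference interval and then classify sounds of intermediate
duration as closer to one reference or the other. Two parameters of the
resulting psychometric function summarize subjective time: the **bisection
point** (BP), the duration at which "long" responses reach 50% — a lower BP
means the listener overestimates duration — and **Weber's ratio** (WR), the
interquartile spread of the curve divided by the BP, an inverse index of
discrimination sensitivity. `tempobisect` implements the full analysis chain
for a clinical variant of this paradigm in which the sounds cross a 2×2
design of semantic category (environmental vs human) and emotional valence
(pleasant vs unpleasant), and participants belong to six diagnostic groups
(healthy controls, typical Alzheimer's disease, and the logopenic,
nonfluent and semantic variants of primary progressive aphasia, plus
behavioural-variant frontotemporal dementia). Because no participant-level
data are deposited for this paradigm, the package ships a first-class
synthetic-cohort generator so that every downstream stage can be exercised
and validated end to end.

# Trial scheduling

The experimental phase presents each of the 28 duration×condition
combinations (7 durations from 2 to 5 s in 0.5 s steps × 4 conditions) once
per block, for 8 blocks (224 trials). Within a block the order is
pseudo-randomized under the constraint that no two consecutive trials share
a condition; inter-trial intervals are uniform on [1, 3] s. The training
phase presents each of the 8 sound exemplars once at each reference (16
trials) and entry to the experiment requires a strictly-greater-than-80%
score (13/16).

Two scheduling choices were genuinely open:

* **Constraint scope.** Because participants may pause between blocks, the
  adjacency constraint is enforced within blocks by default; an
  `across_blocks` flag extends it over block boundaries for back-to-back
  presentation.
* **Algorithm.** Repeated shuffle-and-check (bounded at 10,000 retries per
  block) with a constructive most-constrained-first fallback. With 7 items
  in each of 4 conditions the fallback is always feasible (max condition
  count ≤ ⌈n/2⌉), so the generator cannot dead-end; both paths are
  deterministic given the seed.
* **Exemplar balancing** is unspecified in the design, so the two exemplars
  of each condition alternate round-robin across that condition's duration
  cells, with a seeded starting offset; block order is re-randomized per
  participant from a participant-derived substream.

# The synthetic responder: a scalar-timing clock

The generator follows the pacemaker–accumulator account of interval timing:
arousal and attention gate a pulse generator, so subjective duration is
`gain × t`, and timing noise is *scalar* — its standard deviation grows
proportionally with duration. A trial's decision compares noisy subjective
duration against a fixed memory-derived criterion `c`:

$$\tau \sim \mathcal N\!\left(g\,t,\ (w\,g\,t)^2\right), \qquad
\text{respond "long"} \iff \tau > c,$$

with a lapse probability splitting evenly between the two responses. The
analytic response curve is `P(long|t) = λ/2 + (1−λ)Φ((gt−c)/(wgt))`, which
crosses 0.5 exactly at `c/g` regardless of `w` and λ — so target bisection
points are hit by setting `g = c/BP*`, and the analytic Weber's ratio
`2wz/(1−(wz)²)` (with `z = Φ⁻¹(0.75)`) inverts in closed form to
`w = (√(1+WR*²) − 1)/(WR*·z)`. `params_from_targets()` performs this
inversion; tests verify it against a numerical root-find on the analytic
curve.

Choices worth noting:

* Noise is Normal on the linear timescale (classic scalar expectancy).
* Condition effects enter through the gain, keeping BP modulation
  orthogonal to sensitivity. The Weber coefficient accepts an optional
  per-condition mapping — a deliberate generalization, because the reported
  group profiles show WR varying across conditions while the analytic WR is
  gain-independent, so a single scalar coefficient could not reproduce that
  pattern.
* The criterion is fixed within a participant; trial-to-trial criterion
  drift is a documented extension point, not implemented.
* Default group targets (BP and WR per condition, with between-participant
  SDs), group sizes (24/11/8/8/11/8), valence-rating means (26/74/25/68 on
  the 0–100 scale), and covariate distributions (age, telephone-MMSE on the
  0–27 scale, digit spans, matrix reasoning; TIV ~ Normal(1400, 120)) follow
  the published group profiles of the cohort the simulator emulates. They
  are conveniences for producing realistic structure, not estimates of any
  individual. The default lapse rate is 0.02, a typical value for
  well-trained listeners.
* All randomness derives from one root seed through named substreams
  (`substream_seed`), so any stage reruns in isolation.

What the generator does *not* emulate: acoustics of the stimuli, training
failure and exclusion dynamics, session effects (remote vs in-person),
response times, or non-stationarity across blocks. Passing tests therefore
demonstrate that the analysis chain is correct and well calibrated under
scalar-timing assumptions — not that real cohort data would satisfy those
assumptions.

# Psychometric estimation

Responses are tabulated per condition×duration (proportion long = count of
"long" divided by the number of blocks) and fitted with

$$P(\text{long}\mid t) = \gamma + (1 - \gamma - \lambda)\,
F\!\left(\frac{t - \alpha}{\beta}\right),$$

where `F` is logistic by default (closed-form quantiles for testing;
cumulative normal selectable) and γ, λ are the guess and lapse asymptotes.
With only 7 design points unconstrained asymptotes are unidentifiable, so
they carry a Beta(1, 20)-shaped log-penalty and a hard bound at 0.25.
Estimation maximizes the penalized binomial log-likelihood with a two-phase
deterministic search: a vectorized coarse grid over data-scaled parameter
values screens ~540 start points, and the best four are polished with
box-constrained quasi-Newton (L-BFGS-B). Because the grid, bounds and starts
all scale with the duration range, the fit is exactly equivariant under
rescaling of the time axis (BP and quantiles scale, WR is invariant) — a
property the tests exercise at k = 2.

BP and the 0.25/0.75 quantiles are read off the *full* curve (asymptotes
included), matching how the 50% line crosses a plotted curve with a lowered
upper asymptote; inversion is numeric bisection to 1e-8 s, and an
`on_core` option inverts the core sigmoid instead for sensitivity analysis.
WR = (q75 − q25)/BP, log-transformed with the natural log for modelling.
Degenerate data (all-short or all-long everywhere) and non-crossing curves
(asymptote ≥ 0.25) yield `fit_ok = FALSE` with a diagnostic rather than an
exception; participants with any failed condition are excluded listwise
from group models, with counts logged.

At the design's 8 trials per cell, simulation shows median absolute BP
recovery error of roughly 0.06–0.15 s and median relative WR error of
roughly 19–28% depending on where the true BP sits in the 2–5 s range —
close to the binomial information floor for 56 trials, as recovery barely
improves even with the asymptotes clamped to zero. Recovery degrades
gracefully (monotonically) as noise grows. Recovery studies in the test
suite fit the cumulative-normal family — matched to the generator's normal
subjective-time noise — so that they measure estimator performance rather
than curve-shape mismatch; fitting the logistic default to clock-model data
adds a systematic WR attenuation of roughly 4–10%, worth remembering when
the analysis family and the true response process differ.

# Group-level inference

Candidate confounders are screened by one-way ANOVA when Levene's test
(median-centred) and a Shapiro screen of residuals both pass, else
Kruskal–Wallis; the normality rule is a fixed numeric threshold (p > 0.05)
so runs are reproducible. The main models are linear mixed models (REML,
`lme4`) with the full factorial of diagnostic group × semantic category ×
valence as fixed effects and a participant random intercept — the full
factorial because main effects and two- and three-way interaction tests are
all of interest. Fixed effects are reported with Wald z statistics; for the
study's group sizes (≈70 participants × 4 conditions) simulation shows the
z approximation holds its nominal 5% type-I rate within Monte-Carlo error.
WR is modelled on the natural-log scale, which reduces residual skewness.
Post hoc contrasts are pairwise z contrasts of estimated marginal means
(`emmeans`, asymptotic df), averaging over out-of-contrast factors with
equal weights; raw p values by default (a Holm option exists but is off, to
match the apparent reporting practice being emulated). Deviation scores are
the exact affine map `bp − 3.5` (positive = underestimation). Exploratory
correlations default to Spearman, switching to Pearson only when both
marginals pass the normality screen.

# Regional grey-matter association

The regressor of interest for each condition is the signed difference
Δ = (control-group mean BP) − (patient BP). Given the group profiles, Δ is
overall positive for environmental and negative for human conditions; a
*negative* volume–Δ slope indicates atrophy where the overall sign is
positive, and a *positive* slope where it is negative. Analysis is at
region (or synthetic voxel-within-ROI) scale — image processing is out of
scope — preserving the statistical skeleton: per region, `volume ~ Δ +
diagnosis + age + TIV + MMSE` over the combined patient cohort, one model
per condition (the per-condition description of the original assessment).
Family-wise error over the pre-specified right-hemisphere ROI family
(dorsolateral prefrontal, insula/operculum, inferior parietal, SMA,
precuneus) is controlled by max-|t| permutation: nuisance covariates are
partialled out once, Δ is permuted within diagnosis strata (diagnosis is in
the model), and each region's p is referred to the permutation null of the
family maximum, with Bonferroni as the cheap alternative. Adjusted p values
are forced to respect the `p_fwe ≥ p_raw` ordering. A
threshold-then-max helper reproduces cluster-forming logic (screen at raw
p < 0.001, declare at FWE p < 0.05) for synthetic-voxel families.

The default planted effects in the volume generator — slope −0.8 volume
units per second of Δ in the precuneus for pleasant environmental sounds,
+0.8 in the insula for unpleasant human sounds and +0.8 in the inferior
parietal region for pleasant human sounds, residual SD 0.5 — were
calibrated analytically before the association tests were written: with Δ
SD ≈ 0.5 s and n = 46 patients the delta t-test has a noncentrality near 5,
comfortably above the 80%-recovery requirement after 5-region max-T
correction. Null regions carry no slope.

# Numerical conventions and problem sizes

* Quantile inversion tolerance 1e-8 s; optimizer likelihood clamp 1e-12.
* Permutation p values use the add-one estimator `(1 + #{maxT ≥ |t|})/(B+1)`.
* CSV output: UTF-8, "." decimal, NA as empty field, ≥ 6 significant digits;
  every pipeline output is checksummed into a run manifest, and reruns with
  the same config are byte-identical.
* The test suite exercises: a 100-seed schedule sweep; 20-dataset
  equivalence of the MLE with a dense 4-D grid search (tolerance 1e-3 in
  penalized log-likelihood); 200 simulated participants per recovery
  setting; 500-replicate null calibrations of the mixed model and regional
  GLM; 200-replicate family-wise error control over 20 null regions
  (300 permutations each); and 100-replicate recovery of the planted
  regional effect. These sizes keep a full run in a few minutes on one CPU
  while leaving Monte-Carlo error well below the tolerances tested.

# Known limitations

* The estimator is not the Bayesian toolbox used in the original analyses;
  with its unreported configuration, parameter-level equivalence cannot be
  claimed, only definitional equivalence of BP/WR.
* Wald z inference on REML fits is asymptotic; with far smaller cohorts the
  convergence flag and the OLS cross-check matter more.
* WR recovery at 8 trials/cell is information-limited (~20–28% median
  relative error); studies needing tighter WR estimates need more blocks.
* The permutation test assumes exchangeability of Δ within diagnosis strata
  after covariate partialling (a Kennedy-style approximation, standard but
  approximate in small samples).
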