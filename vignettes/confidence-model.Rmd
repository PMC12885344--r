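---
title: "A dynamic drift-diffusion model of confidence and its distortions"
author: "confdrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dynamic drift-diffusion model of confidence and its distortions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confdrift)
```

## The model

`confdrift` simulates and fits a generative account of how people form
confidence in two-alternative forced-choice (2-AFC) decisions, and of how
that confidence is distorted by stable individual differences such as
trait anxiety or gender.

**Pre-decisional stage.** Evidence $e$ accumulates from a starting point
$z$ between absorbing bounds at $0$ and $a$:

$$e_{t+\mathrm{d}t} = e_t + s\,v\,\mathrm{d}t + \sigma\sqrt{\mathrm{d}t}\,\varepsilon,
\qquad \varepsilon \sim \mathcal N(0,1),$$

where $s = \pm 1$ is the stimulus direction and $v$ the drift-rate
magnitude. The first bound hit determines the choice $d = \pm 1$ and the
decision time; observed response time adds a nondecision component
$\tau$. The noise $\sigma$ is fixed at 1 because it trades off perfectly
with $v$ and $a$.

**Post-decisional stage.** Evidence continues to accumulate during the
interval $t_c$ between the choice and the confidence report (the
confidence response time), at the drift

$$v_{\text{post}} = v_r \, (s\,v) + d\,b .$$

$v_r$ is the *v-ratio*, a dynamic measure of metacognitive efficiency
(how faithfully post-decisional processing tracks the true evidence
stream; typically $0 < v_r < 1$), and $b$ is the *v-bias*, a
decision-contingent drift bias that accumulates evidence for ($b>0$) or
against ($b<0$) the choice just made. Because the post-decisional
increment over a known interval is just a Wiener displacement, it is
sampled in closed form,
$e_{\text{final}} \sim \mathcal N(e_{\text{dec}} + v_{\text{post}}\,t_c,\ \sigma^2 t_c)$,
with $t_c$ resampled with replacement from the subject's own empirical
confidence-RT distribution.

**Report stage.** Final evidence is made choice-relative by centring at
the bound midpoint, $x = d\,(e_{\text{final}} - a/2)$, and mapped to a
bounded report through a logistic transform with two criterion
parameters,

$$\text{conf} = \frac{1}{1 + \exp\{-(m\,x - c)\}},$$

an additive shift $c$ (*a-bias*; positive values produce underconfidence
at every evidence level) and a multiplicative slope $m$ (*m-bias*; how
steeply evidence converts into extreme confidence). The model has eight
free parameters: $v, a, z, \tau, v_r, b, c, m$.

Midpoint centring is a package convention: the reference point of the
logistic is not dictated by the model structure, and $a/2$ makes the two
choices exactly symmetric, with $x = a/2$ at the moment of decision for
either response.

## Three mechanisms of confidence distortion

An individual-difference score can distort confidence through three
distinct routes, each implemented by [`mechanism()`]:

* **D1 (accumulative)** — the score shifts `v_bias`. The distortion is
  *dynamic*: its effect on $x$ grows linearly with post-decision time, so
  underconfidence deepens the longer the report is delayed (a negative
  slope difference between high- and low-score groups).
* **D2 (additive)** — the score shifts `a_bias`. The criterion shift is
  constant while $|x|$ keeps growing, so its relative impact *fades* with
  post-decision time (a positive slope difference).
* **D3 (multiplicative)** — the score scales `m_bias`. The sign of its
  effect on mean confidence depends on where the evidence distribution
  sits relative to the criterion: compressing the sigmoid pulls reports
  toward the middle, which lowers mean confidence when baseline reports
  are high but raises it under a liberal (negative) criterion where
  error-trial evidence dominates the responsive range. Accordingly its
  time-course signature is inconsistent.

`phase_diagram()` maps these regimes. The default D1/D2 grid varies
`v_ratio` in {0.3, 0.55, 0.8}, `bound` in {1.5, 2, 2.5} and `drift` in
{0.8, 1.2}; the v-ratio range deliberately sits inside (0, 1), the range
typical of fitted metacognitive efficiency. Once the post-decisional
drift `v_ratio * drift` approaches 1.2,
baseline confidence saturates within the usual report interval and the
slope-difference signature of D1 degenerates (the saturated low-score
group has slope near zero while the biased group does not), which is a
regime the distortion analysis is not meant to describe. The D3 grid adds
`a_bias` in {-2.5, 0, 1.5} so both the under- and overconfidence regimes
of the multiplicative mechanism are represented.

## Fitting

The fitting target (`summarize_observed()`) follows quantile-probability
practice: response times are summarised by quantile-bin counts at
probabilities (.1, .3, .5, .7, .9), separately for correct and error
trials; confidence is summarised the same way in four classes crossing
accuracy with report speed (faster versus slower than the subject's
median confidence RT). On discrete (Likert) scales, per-level counts
replace quantile bins.

The accuracy split of the confidence classes matters for identifiability:
on correct trials the choice-relative post-decisional drift is the sum
$v_r v + b$, so if correct and error trials are pooled, `v_ratio` and
`v_bias` trade off along a nearly flat ridge and are jointly
under-determined. On error trials the two terms oppose
($-v_r v + b$ relative to the choice), which breaks the degeneracy;
profiling the objective along the ridge shows a sharp minimum at the
generating values only when the confidence classes are accuracy-split.

The objective (`chi_squared_objective()`) bins `n_sim` simulated trials
by the *observed* quantile edges. Within each modality (RT, confidence)
the classes form one multinomial: expected counts are the simulated
proportions over all cells of the modality, scaled to the total observed
count. This matters — renormalising within each class instead would
cancel the simulated proportion correct out of the objective entirely,
leaving the drift rate identified only by RT shape and re-opening a
drift-by-v_ratio compensation ridge. The objective sums
$(O-E)^2/(E+\varepsilon)$ over all cells with $\varepsilon = 1$ guarding
sparse bins; a simulated class with no trials contributes its maximal
penalty rather than `NaN`. All components are summed unweighted. The
default simulation count per evaluation is 4,000.

Minimisation uses a compact differential-evolution optimizer
(`de_optim()`, best/1/bin with reflection at the box) written for this
package. Because the objective is stochastic, all candidates within a
generation are evaluated under one simulation seed (common random
numbers) so comparisons between candidates are meaningful; parents are
re-scored whenever the seed changes, and the seed rotates every
`reseed_every` generations (default every generation) so the search
cannot overfit a single noise draw. Rotating less often (the fitting
runs here use every 5 generations) lets the population converge more
tightly between rotations at a small robustness cost; parent scores are
cached while the seed is unchanged, which saves half the evaluations. The default search box is
`drift` [0, 5], `bound` [0.5, 4], `start/bound` [0.2, 0.8], `ndt`
[0.05, 1.5] s, `v_ratio` [0, 2], `v_bias` [-2, 2], `a_bias` [-5, 5],
`m_bias` [0.1, 5]; the starting point is searched as a fraction of the
bound so the box is always feasible.

When a subject performed several tasks, `fit_multitask()` fits each task
separately, z-scores each parameter across subjects within task, and
averages the z-scores per subject.

## Numerical choices

* **Discretisation.** The walk uses Euler-Maruyama steps of `dt = 0.001`
  s by default (0.002 s inside fitting loops, where the objective
  compares simulation to simulation). Decision times are capped at
  `max_t = 10` s; capped trials are flagged, reported, and excluded from
  summaries, never silently dropped.
* **Boundary correction.** A discretely-observed walk overshoots the
  bounds by about $0.5826\,\sigma\sqrt{\mathrm{d}t}$ on average, which
  biases first-passage probabilities at $O(\sqrt{\mathrm{d}t})$.
  Absorption is therefore tested against bounds pulled inward by that
  amount (Siegmund's continuity correction), making choice probabilities
  converge at $O(\mathrm{d}t)$; at `dt = 0.001` the residual bias in
  choice probability is below 0.001 and the mean decision time sits
  within half a percent of the closed form. Oracle tests compare the
  simulator against the analytic absorbing-boundary formulas at
  `dt = 2.5e-4` with three-Monte-Carlo-SE bands at 50,000 trials (2%
  relative for the mean decision time, whose residual discretisation
  bias decays more slowly than the probability bias).
* **Random numbers.** The compiled simulator draws from a ziggurat
  standard-normal sampler over a 32-bit Mersenne Twister seeded per call,
  so every simulation is bitwise reproducible from its integer seed and
  an R-level `set.seed()` governs everything else.
* **Degenerate inputs.** Confidence reports are clamped to
  (1e-12, 1-1e-12) so the logistic inverse exists; a Likert rater with
  constant ratings yields a single occupied level; an accuracy class
  with fewer trials than bins is dropped from the objective with a
  logged warning; a zero-MAD response-time group skips the
  deviation-based exclusion rule rather than excluding everything.

## The synthetic cohort generator

`generate_cohort()` is the package's test bed: a population of subjects
with an anxiety score (standard normal), gender (Bernoulli(0.5) over
man/woman), and age (uniform 18-65), whose model parameters are the base
set plus linear couplings from the scores. The canonical design
(`default_study_design()`) encodes the qualitative pattern the model is
meant to disentangle: anxiety loads on `v_bias` (gain -0.5), `a_bias`
(+0.2) and `v_ratio` (-0.15); being a woman loads on `a_bias` only
(+0.6). With these gains the accumulative component dominates the
anxiety time course — anxiety-related underconfidence deepens with
post-decision time while the gender-related effect, being purely
additive, fades. The magnitudes are package constants calibrated once by
decomposing each coupling's contribution to the factor-by-time
interaction at the fixture scale (100 subjects by 400 trials): with equal
anxiety gains on `v_bias` and `a_bias` the two contributions cancel
almost exactly, and no time-course asymmetry would be detectable.

Confidence response times are log-normal (median about 1.5 s, log-SD
0.5) with a subject-specific location (SD 0.4 in log units), so subjects
differ in their typical report speed and between-subject time
regressions have support. Difficulty is emitted as a near-constant
staircase column (it is a regression covariate, not a drift modulator,
because staircased tasks hold difficulty near threshold within a fit).

What the generator does *not* emulate: staircase dynamics and
difficulty-dependent drift, trial-to-trial parameter variability,
sequential effects, lapses, or response-scale anchoring. Passing tests
on these cohorts therefore demonstrate that the pipeline recovers what
it plants under its own generative assumptions — parameter recovery,
sign patterns, exclusion-rule exactness — not that the model is correct
for any particular empirical data set.

## Preprocessing and analysis conventions

Trial exclusions: choice RTs under 100 ms; choice or confidence RTs more
than 3 MADs (normal-consistency factor 1.4826) from the median within
each dataset-task group, computed on the trials surviving the 100 ms
rule; groups with fewer than 5 trials or zero MAD skip the rule with a
log entry. Subject exclusions: on discrete scales, confidence-rating SD
below the scale resolution ($1/k$ for a $k$-point scale, on the unit
interval the ratings are mapped to); nonbinary participants are excluded
only from gender analyses. Standardisation is always to sample SD
($n-1$), within dataset-task groups.

Analyses are ordinary least squares at the subject level with
dataset-task fixed-effect indicators and per-coefficient Wald
chi-squared statistics — a deliberately lighter design than mixed-effects
estimation, adequate for sign- and recovery-based synthetic analyses.
Gender is coded woman = 1 so positive coefficients read "higher in
women". Fitted-parameter regressions first drop values more than 5 SDs
from their dataset-task mean (applied to `v_ratio`, `v_bias`, `a_bias`).
Time-course marginals tile subjects into six equal-count bins of median
confidence RT with percentile-bootstrap 95% intervals (2,000 resamples,
seeded).

## Problem sizes and budgets

The test suite and the acceptance script run everything at reduced but
honest scales chosen to keep a full run on a single core comfortable:
oracle checks at 50,000-100,000 draws; population simulations at 60
subjects by 200-400 trials per grid cell; parameter recovery at 20
subjects by 800 trials with a differential-evolution budget of
population 24 for 45 generations and 2,000 simulated trials per
evaluation, with the common-random-number seed rotated every 5
generations; the end-to-end pipeline at 40 subjects with a smaller
per-subject budget. Recovery correlations for the four confidence
parameters reach 0.75-0.98 at that budget; the full 4,000-simulation
default with a larger population budget tightens them further.

## Known limitations

* The quantile objective is not a likelihood; objective values are
  comparable across candidate parameters for one subject, not across
  subjects or data sizes.
* `v_ratio` is the least identified of the confidence parameters (its
  information comes mostly from error-trial confidence, a small fraction
  of trials); at a few hundred trials per subject its recovery is
  noticeably noisier than `a_bias` or `m_bias`.
* The fixed-effects OLS analyses understate uncertainty relative to the
  mixed-effects designs used for real multi-dataset cohorts; they are
  intended for synthetic sign-level inference.
* Euler discretisation, even corrected, is a simulation of the
  continuous model: quantities sensitive to fine-grained first-passage
  behaviour (extreme RT quantiles) inherit an $O(\mathrm{d}t)$ error.
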