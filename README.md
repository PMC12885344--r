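# confdrift

Dynamic post-decisional drift-diffusion modelling of confidence in
two-alternative forced-choice (2-AFC) tasks.

People's confidence in their decisions is systematically distorted by
stable individual differences — trait anxiety and gender are two
well-documented sources of underconfidence. `confdrift` implements a
generative model that localises such distortions in the *post-decisional*
period, between the choice and the confidence report, and so can ask not
just whether a group is underconfident but *when* that underconfidence
arises and whether extra deliberation deepens or remediates it. It is
aimed at computational-psychiatry and metacognition researchers working
with trial-level 2-AFC data (choice, response time, confidence rating,
confidence response time).

## The model

Evidence accumulates as a Wiener process `de = s·v·dt + σ·dW` from start
`z` between absorbing bounds 0 and `a`; the bound hit gives the choice
`d = ±1` and decision time (plus nondecision time `τ`). Accumulation
continues during the confidence response time `t_c` at the post-decisional
drift

    v_post = v_ratio · (s·v) + d · v_bias

where `v_ratio` is a dynamic measure of metacognitive efficiency and
`v_bias` a decision-contingent accumulation bias. Final evidence is mapped
to a report through a logistic with additive (`a_bias`) and multiplicative
(`m_bias`) criterion parameters:

    conf = 1 / (1 + exp(−(m_bias · d·(e − a/2) − a_bias)))

Eight free parameters: `v, a, z, τ, v_ratio, v_bias, a_bias, m_bias`
(`σ = 1` by convention). Three distortion mechanisms couple an
individual-difference score to confidence: accumulative (D1, via
`v_bias`), additive (D2, via `a_bias`), multiplicative (D3, via
`m_bias`) — distinguishable by how the distortion evolves with
post-decision time.

Fitting is simulation-based: quantile-bin chi-squared over RT
distributions (by accuracy) and confidence distributions (by accuracy ×
fast/slow confidence RT), minimised by differential evolution with common
random numbers. See the methods vignette
(`vignettes/confidence-model.Rmd`) for assumptions, numerical choices and
limitations.

## Worked example

```r
library(confdrift)

# simulate one subject and fit the model back
set.seed(1)
truth <- model_params(drift = 1.2, bound = 1.8, ndt = 0.35,
                      v_ratio = 0.7, v_bias = -0.5, a_bias = 0.8, m_bias = 1.5)
trials <- simulate_trials(truth, 800,
                          conf_rt_pool = rlnorm(800, log(1.5), 0.5),
                          dt = 0.002, seed = 11)
fit <- fit_subject(trials, n_sim = 2000, dt = 0.002,
                   de = de_control(np = 24, max_gen = 40, reseed_every = 5),
                   seed = 42)
print(fit)
#> Model fit (chi-squared = 36.76, converged, 1152 evals, seed 42)
#> Dynamic confidence DDM parameters
#>   pre-decision : drift=1.278 bound=1.877 start=1.15 ndt=0.3612 s
#>   post-decision: v_ratio=0.7559 v_bias=-0.5734
#>   confidence   : a_bias=0.8353 m_bias=1.566  (sigma=1)
```

The fitted chi-squared is the quantile-bin misfit at the optimum; every
recovered parameter sits near its generating value (compare `v_ratio`
0.76 vs 0.7, `v_bias` -0.57 vs -0.5, `a_bias` 0.84 vs 0.8, `m_bias` 1.57
vs 1.5). Across a population of subjects, truth-estimate correlations
for the four confidence parameters exceed 0.9 at this budget (see
`recovery_study()`).

A full synthetic study — scores, couplings, trials, preprocessing and the
model-free time-course analysis:

```r
design <- default_study_design(n_subjects = 100, n_trials = 400, seed = 33)
cohort <- generate_cohort(design)
subjects <- summarize_subjects(exclude_trials(cohort[!cohort$capped, ])$trials)
regress_time_interactions(subjects)
#> Regression (n = 100, 0 excluded)
#>  term                      estimate      se    chisq        p
#>  anxiety_z                 -0.5327  0.01613  1091.0  3.1e-239
#>  gender_num                -0.2524  0.03185    62.8   2.3e-15
#>  ...
#>  anxiety_z:med_conf_rt_z   -0.0743  0.01679    19.6   9.7e-06
#>  gender_num:med_conf_rt_z  +0.0639  0.03281     3.8    0.051
```

Both planted effects appear with their defining time courses: anxious
subjects are underconfident and *more so* the longer they take to report
confidence (negative interaction), women are underconfident immediately
after the decision but the effect *fades* with report time (positive
interaction).

Command-line interface (thin wrapper over the same functions):

```sh
Rscript inst/cli/confdrift.R simulate-cohort --subjects 60 --trials 400 --seed 1 --out cohort.csv
Rscript inst/cli/confdrift.R analyze --trials-file cohort.csv --out terms.csv
Rscript inst/cli/confdrift.R phase-diagram --mechanism D1 --out d1.csv
```

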