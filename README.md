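# slcurves

Statistical-learning curves from alternating serial reaction time (ASRT)
data: simulation, triplet scoring, learning-curve model selection, and
individual-differences analysis.

## What this is for

Implicit statistical learning (SL) — picking up probabilistic regularities in
a sequence without noticing them — is classically measured with the ASRT
task, in which fixed-pattern trials alternate with random trials and hide a
deterministic sequence inside apparent noise. People respond progressively
faster to probable than to improbable three-trial contexts (*triplets*), and
the per-block RT difference between improbable (Random-Low) and probable
(Random-High) random trials — the **SL score** — traces a learning curve.

`slcurves` is for researchers who want to go beyond "is there learning?" and
characterize *how* learning unfolds. It fits exponential, power and linear
learning curves to SL-score series by bounded maximum likelihood and selects
among them with AICc, BIC and BIC-approximated Bayes factors. The exponential
form

    y = A · (1 − e^−(x − x0)/τ)

decomposes each participant's learning into a **potential** (the saturation
level `A`, in ms — the ultimately attainable SL effect), an **efficiency**
(the time constant `τ`, in blocks — the curve reaches 63.2% of `A` at
`x0 + τ`; smaller is faster) and a starting point (`x0`). The package then
correlates `A` and `τ` with executive-function test scores via Kendall's
tau-b. Because trial-level ASRT data are rarely shared, a seeded synthetic
cohort generator with known ground truth is a first-class module: every stage
is testable end to end, and parameter-recovery claims are checked by
simulation rather than asserted.

## Worked example

```r
library(slcurves)

cohort    <- simulate_cohort(n_participants = 40, seed = 2026)
summaries <- summarize_blocks(cohort$trials)
sl        <- compute_sl_scores(summaries, mode = "raw")

fits <- fit_group_curve(sl, seed = 2026)
print(fits$exponential)
#> Learning-curve fit (exponential), n = 36, k = 4
#>   w1 = 13.41, w2 = -0.2028, w3 = 10.83, sigma = 0.3112
#>   logL = -9.0572, AICc = 27.4046, BIC = 32.4484, converged = TRUE

compare_models(fits)[5, ]
#>   m1          m0     delta_aicc bayes_factor interpretation
#>   exponential linear      102.2     1.53e+22 Very strongly supports the M1
```

The cohort was generated with group-level ground truth `A = 13.25`,
`x0 = −0.39`, `τ = 10.28`; the pooled fit recovers `A = 13.41`, `x0 = −0.20`,
`τ = 10.83` from the noisy simulated sessions, and the exponential form beats
the power and linear alternatives on both AICc and BIC. Individual
differences:

```r
curves <- fit_participants(sl, seed = 2026)
res    <- correlate_profiles(curves, cohort$neuropsych)
res[res$test %in% c("CBT_F", "ANT", "WCST"), ]
#>   parameter  test       r      p  n
#>           A CBT_F  0.2949 0.0071 40
#>           A   ANT  0.2692 0.0142 40
#>         tau  WCST  0.2538 0.0210 40   (independent tests stay near 0)
```

The generator planted Kendall correlations of 0.268 (Corsi block-tapping
forwards with `A`), 0.259 (attention network test with `A`) and 0.244
(Wisconsin card sorting with `τ`); the recovered `r` values above show the
full pipeline — trial simulation, triplet labeling, per-participant curve
fits, rank correlation — preserving them.

A complete run (simulate → score → regress → fit → correlate → report, with
per-stage manifests and a Markdown report with the fitted-curve figure):

```r
run_pipeline(default_config(), seed = 7, out_dir = "runs/r1")
```

or from a shell via the thin wrapper `inst/scripts/slcurves.R`
(`Rscript slcurves.R all --seed 7 --out runs/r1`).

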