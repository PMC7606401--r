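---
title: "Modeling statistical-learning curves from ASRT data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling statistical-learning curves from ASRT data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slcurves)
```

## The task and its hidden structure

In the alternating serial reaction time (ASRT) task a visual target appears in
one of four positions and the participant presses the matching button. Unknown
to the participant, *pattern* trials — whose positions follow a fixed cyclic
permutation of the four positions, e.g. 3–2–4–1 — strictly alternate with
*random* trials whose positions are drawn uniformly. A session consists of 36
blocks of 85 trials: 5 warm-up trials (random positions) followed by 10
repetitions of the 8-trial alternating unit. With a 500 ms stimulus, a 120 ms
inter-trial interval and a 200 ms lead-in, a block lasts 52.9 s.

Learning is measured on *triplets*, i.e. three consecutive trials. A triplet
terminated by a pattern trial (P–R–P) is **Pattern-High**: its third position
is always the pattern successor of its first. A triplet terminated by a random
trial (R–P–R) is **Random-High** when its third position happens to equal the
pattern successor of the first (probability 1/4) and **Random-Low** otherwise.
Of the 64 position identities (a, x, b), 16 are high-probability and 48
low-probability under any of the 24 pattern permutations, so each high
identity occurs about five times as often as each low identity. Among
classifiable trials the three conditions occur at 50%, 12.5% and 37.5%.
Triplets never span block boundaries, and the first 7 trials of each block are
excluded (warm-up members or insufficient history). No trill/repetition
exclusions are applied: `1-2-1` and `1-1-1` style triplets are retained, which
differs from parts of the ASRT literature but matches the analysis this
package implements.

## The SL score and its units

Comparing Random-High with Random-Low isolates pure probability learning (the
two conditions share the random trial type). The per-block **SL score** is
the absolute difference of their mean RTs, computed over correct responses
only; accuracy denominators use all non-excluded trials. Three unit
conventions are supported through `compute_sl_scores(mode = ...)`:

* `raw` — ms difference, directly interpretable;
* `normalized` — divided by the block's overall (count-weighted, correct-only)
  mean RT, removing global speed differences between participants and blocks;
* `rescaled` (default) — the normalized score multiplied by the participant's
  grand-mean RT, which restores ms-comparable units while keeping the
  per-block speed correction.

The default is `rescaled` because downstream saturation parameters are
conventionally reported in milliseconds while the normalization step is still
wanted; `raw` reproduces the plain RT-difference analysis. Raw scores are
invariant to an additive RT shift, normalized scores also to a multiplicative
rescaling — both properties are enforced by the test suite.

## Effects regressions

Group-level evidence of learning is assessed by OLS on the 2 × 36
block-by-condition cell means: `outcome ~ block_c + condition + block_c:condition`,
with the block order centered at its mean (18.5) and the condition dummy coded
0/1 with Random-High as reference for the probability contrast (Pattern-High
for the type contrast). In this balanced, centered design the intercept equals
the reference condition's grand mean and the interaction term measures the
growth of the condition difference per block — the regression signature of
statistical learning. AICc and BIC for these fits use the Gaussian
log-likelihood with k = 5 (four coefficients plus the error variance).

## Learning-curve models and model selection

Three families are fitted to an SL-score series by maximum likelihood under an
independent Gaussian observation model with constant residual SD:

* exponential: $y = w_1\,(1 - e^{-(x - w_2)/w_3})$
* power: $y = w_1\,(x - w_2)^{w_3}$
* linear: $y = w_1\,(x - w_2) + w_3$

For the exponential form the parameters have first-order step-response
semantics: $A = w_1$ is the saturation level — the *potential* of statistical
learning; $x_0 = w_2$ is the x-intercept — where learning starts; and
$\tau = w_3$ is the time constant — the *efficiency*: the curve reaches
$1 - 1/e \approx 63.2\%$ of $A$ at $x = x_0 + \tau$, so smaller $\tau$ means
faster approach to the attainable ceiling.

Fitting minimizes the negative log-likelihood with L-BFGS-B from the initial
values (1, 1, 1, 1). Individual fits use the empirical boundaries
$A \in [-500, 500]$, $x_0 \in [0, 50]$, $\tau \in [1, 50]$ and residual SD in
$(0, 30]$; the group fit widens the $x_0$ bound to $[-50, 50]$ because a group
curve may legitimately intercept slightly before block 1 (the published group
estimate is negative). If the first run fails or stops on a curve-parameter
bound, up to 10 seeded restarts are drawn inside the bounds (log-uniformly for
strictly positive parameters) and the best converged run wins; disabling
restarts reproduces the pure single-start behaviour. Domain violations inside
the optimizer (e.g. a power-model base crossing zero) return a large finite
penalty rather than NaN, which keeps the bounded quasi-Newton iterations
stable; the power-model bound on $w_2$ is additionally capped just below the
smallest block order. The power form is implemented as $(x - w_2)^{w_3}$; the
sign convention for $w_2$ varies in the literature, and with the domain guard
and symmetric bounds the two conventions are interchangeable up to the sign of
the fitted $w_2$.

Model comparison uses small-sample corrected criteria with natural logarithms,

$$\mathrm{AICc} = \frac{2kn}{n - k - 1} - 2\log L, \qquad
  \mathrm{BIC} = k \log n - 2\log L,$$

with k = 4 (three curve parameters plus the residual SD — the parameter count
is a modeling choice this package makes explicit), and the BIC-approximated
Bayes factor $\mathrm{BF}(M_1, M_0) = e^{-0.5(\mathrm{BIC}_{M_1} -
\mathrm{BIC}_{M_0})}$. Evidence bands follow the conventional scale: BF up to
1 supports $M_0$; 1–3 is not worth more than a bare mention; 3–20 positive;
20–150 strong; above 150 very strong ($\Delta$AICc bands at 2/4/7/10). The
best model must minimize both AICc and BIC; a disagreement is flagged rather
than silently resolved. By default the group curve is fitted to the per-block
mean series over participants (n = 36); `pooling = "stacked"` instead enters
every participant × block point into the likelihood — published group
analyses are ambiguous between the two, and the choice is therefore exposed.

```{r example-fit}
g <- tibble::tibble(
  block = 1:36,
  score = 13.25 * (1 - exp(-((1:36) + 0.39) / 10.28))
)
fit <- fit_mle(g$block, g$score, "exponential", scope = "group")
c(A = fit$w1, x0 = fit$w2, tau = fit$w3)
```

## Individual differences

Each participant's series is fitted with the exponential model under the
individual bounds; non-converged fits are flagged and excluded from
correlations. Fitted $A$ and $\tau$ are then correlated with ten
executive-function test scores (category/letter fluency, counting span and
Corsi block-tapping forwards/backwards, Wisconsin card sorting, Stroop,
attention network, Go/No-go) and with each other, using Kendall's tau-b.
Tau-b is chosen because neuropsych scores are discrete and tie-heavy; the
two-sided p-value uses the exact small-sample null when there are no ties and
the normal approximation with tie-adjusted variance otherwise. All variables
are z-scored (sample SD) first — this does not change any rank correlation
but makes the emitted standardized tables comparable. No multiple-comparison
adjustment is applied, matching the analysis convention this package
reproduces; `p.adjust` can of course be applied to the output columns.

## The synthetic-data generator

No public trial-level ASRT data accompany the analysis this package
implements, so the generator is a first-class, tested module rather than a
fixture. It emulates:

* the session structure above, with pattern permutations counterbalanced over
  every 24 consecutive participants (seeded cycle order);
* reaction times `base_rt - practice_slope*(block-1) + gap(block)*[Random-Low]
  + N(0, noise_sd)` truncated at a 100 ms floor, with
  `gap(b) = A(1 - exp(-(b - x0)/tau))` — so the noiseless per-block SL score
  equals `gap(b)` exactly;
* Bernoulli accuracy (default 0.92, matching the high accuracy typical of this
  task; error responses land uniformly on a non-target position and error RTs
  are never used downstream);
* neuropsych scores with a requested Kendall correlation to one learning
  parameter via a Gaussian copula, using $\rho = \sin(\pi\tau_K/2)$ so the
  expected Kendall correlation equals the request; each test is tied to a
  single parameter because prescribing exact rank correlations with both $A$
  and $\tau$ simultaneously is overdetermined.

Defaults are the study-scale conditions: 40 participants, A = 13.25 ms,
x0 = −0.39, τ = 10.28 blocks at group level, trial noise SD 5 ms, practice
slope 1 ms/block, base RT 280.5 ms. Cohort heterogeneity (A ~ N(13.25, 4),
τ ~ N(10.28, 3) clipped to [1.5, 45], x0 ≥ 0, base RT ~ N(280.5, 20)) is this
package's own choice, as individual-level distributions are not published.
What the generator does **not** emulate: right-skewed RT distributions
(Gaussian noise only), sequential RT dependencies (post-error slowing,
fatigue within blocks), rest-period effects, explicit-awareness strategies,
and response-time/accuracy trade-offs. Passing recovery tests therefore
demonstrates correctness of the estimation machinery under the stated
generative model, not robustness to every property of real RT data.

All randomness flows from one master seed split into named sub-streams
(`substream_seeds()`), so identical (config, seed) pairs reproduce every
table byte-identically while individual stages remain independently
re-runnable.

## Numerical choices and degenerate inputs

* The residual-SD lower bound is 1e-4 (not 0): a zero SD has no likelihood.
  On noiseless data the fit pins sigma at this bound and recovers the curve
  parameters to ~1e-4.
* A zero-variance regression outcome yields slopes 0 and a defined adjusted
  R² of 0 instead of NaN; rank-deficient designs raise an explicit error.
* A block with no correct trials in a condition yields a missing condition
  mean; missing Random-High/Low means propagate to a missing SL score (with a
  message) and are skipped by the likelihood with n reduced.
* The linear family is over-parameterized (only `w1` and the composite
  `w3 - w1 w2` are identified); its criteria still use k = 4 so the three
  families are compared under one parameter-counting rule.
* τ is weakly identified when A is near zero (no learning signal means no
  time constant) or when τ approaches the series length; such fits tend to
  pin at a bound and are flagged via `bounds_hit`. This bounds cohort-level
  rank-recovery of τ at realistic noise — the test suite asserts the
  oracle-measured recovery (Kendall ≳ 0.6 at trial noise 5 ms), not a
  hypothetical noiseless ideal.

## Problem sizes used by the checks

The packaged checks run at deliberately modest scale, chosen to exercise the
asymptotics that matter: 40–100 simulated sessions for the condition
proportions, 50 replicate group-series fits for parameter recovery (median
recovered A and τ within 10–15% of the generating values at noise SD 2 ms),
100 replicates for model-form recovery (exponential selected by AICc in ≥ 80%
of exponential-generated series at n = 36), and cohorts of 6–24 participants
for end-to-end pipeline tests.
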