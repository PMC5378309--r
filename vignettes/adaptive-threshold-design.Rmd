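---
title: "Adaptive biomarker-threshold trial designs: models, rules and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive biomarker-threshold trial designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbatt)
```

## The problem

Early-phase single-arm trials of targeted treatments often have a candidate
predictive biomarker measured on a continuous scale, with no established
cut-point separating "biomarker positive" from "negative" patients. Two
questions then have to be answered together: *is there a subpopulation in
which the response rate is clinically interesting*, and *where is its
boundary on the biomarker scale*? cbatt implements a two-stage enrichment
design that answers both: recruitment is restricted to subjects above a
biomarker threshold, the threshold is re-chosen at an interim analysis to
target a desired power, the final analysis is a binomial exact test on all
recruited subjects, and the threshold defining the responsive subpopulation
is estimated at the end.

## The model

All modelling is done on the biomarker *quantile* scale: raw measurements
are transformed through the empirical CDF of a reference sample, so the
transformed value $B$ is approximately Unif$[0,1]$ in the unscreened
population. The point response rate is logistic,

$$\pi(B) = \frac{e^{\delta_0 + \delta_1 B}}{1 + e^{\delta_0 + \delta_1 B}},$$

with $\delta_1$ the log odds ratio of response per unit quantile (assumed
non-negative: a monotone increasing biomarker–response association; a
negative association is handled by flipping the biomarker's sign before
entry). What matters for enrichment, however, is the *subset* response
rate — the mean of $\pi$ among subjects above a threshold:

$$\Pi(B) = \frac{1}{1-B}\int_B^1 \pi(u)\,du
         = \frac{\ln\!\left(\dfrac{1 + e^{\delta_0+\delta_1}}{1 + e^{\delta_0+\delta_1 B}}\right)}{\delta_1 (1-B)}.$$

The trial tests $H_0\!: \Pi(T^*) \le \rho$ for every threshold $T^*$
against the alternative that some subpopulation exceeds the reference rate
$\rho$. The *true threshold* $T$ is the smallest quantile with
$\Pi(T) = \rho$; the positive subset is deliberately defined to be as
large as possible.

```{r curve-plot, fig.width = 6, fig.height = 3.5}
curve <- calibrate_intercept(6, 0.5, 0.4) # Pi(0.5) = 0.4
autoplot(curve, rho = 0.4)
```

## The design

The total sample size $S = S_1 + S_2$, stage sizes, significance level
$\alpha$, target power $1-\beta$ and reference rate $\rho$ are fixed
before the study. Because all of these are pre-specified, the minimum
number of responses for a significant binomial exact test,

$$X_H = \min\{x : P(X \ge x \mid X \sim \mathrm{Bin}(S, \rho)) \le \alpha\},$$

is known before the trial starts (`required_responses()`). Stage 1
recruits $S_1$ subjects with $B \ge t_1$.

### The interim analysis

After stage 1, the remaining requirement is $X_{H,2} = X_H - X_{obs,1}$.
For each candidate stage-2 threshold $t^*_{2,k}$ in a pre-specified grid:

1. the stage-1 data are fitted by logistic regression
   (`fit_stage_model()`);
2. 1000 coefficient pairs are drawn from the bivariate normal sampling
   distribution implied by the inverse observed Fisher information
   (`sample_coefficients()`);
3. each draw gives a subset-rate estimate
   $\tilde\Pi(t^*_{2,k})$, and a beta distribution is fitted to the 1000
   draws;
4. the predicted stage-2 response count is beta-binomial,
   $X \sim \mathrm{BBi}(S_2, a, b)$, and the *predicted power* is
   $1-\beta' = P(X \ge X_{H,2})$ (`predicted_power()`).

The stage-2 threshold is the smallest grid value whose predicted power
reaches the target (`decide_adaptive()`). Three adaptive variants differ
in what happens when no grid value qualifies: AD1 stops for futility; AD2
continues at the largest grid threshold provided its predicted power
exceeds a floor $\gamma$; AD3 ($\gamma = 0$) always continues. Two fixed
comparators keep $t_2 = t_1$: FD1 applies a beta-binomial futility rule
directly to the observed stage-1 count — stop when
$P(X_{obs} \ge X_H \mid X_2 \sim \mathrm{BBi}(S_2, X_{obs,1}, S_1 - X_{obs,1}))$
falls strictly below $1-\beta_{FD}$ — and FD2 never stops.

### The final analysis

A completed trial pools all $S$ subjects and performs the binomial exact
test $P(X \ge X_{obs} \mid X \sim \mathrm{Bin}(S, \rho))$; significance is
declared at $p \le \alpha$. The threshold estimate $\hat T$ is the grid
value minimising $|\hat\Pi(B) - \rho|$ under the pooled fit; resampling
the pooled coefficients and recomputing the argmin per draw gives an
empirical-quantile interval (`estimate_threshold()`). Trials stopped at
the interim estimate the threshold from the stage-1 fit instead.

## Tunable parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `s1`, `s2` | stage sample sizes | — | equal stages are a good general choice; power is fairly flat in the split |
| `t1` | stage-1 recruitment threshold (quantile) | — | best prior guess of the hypothesis threshold |
| `rho` | reference response rate | — | clinical relevance (e.g. historical control rate) |
| `alpha` | exact-test level | 0.05 | conventional; the design is conservative, so larger values are defensible |
| `target_power` | interim target $1-\beta$ | 0.8 | conventional |
| `gamma` | AD2 continuation floor | — | trade-off between futility protection and completion rate |
| `fd_futility` | FD1 bound $1-\beta_{FD}$ | 0.2 | the standard comparator setting |
| `t2_grid` | candidate stage-2 thresholds | $0, 0.05, \dots, 0.95$ | 20 evenly spaced quantiles; values above ~0.95 make recruitment impractical (only 5% of screens eligible) |
| `n_draw` | coefficient resamples | 1000 | interim power estimates stabilise well below this; cheap |

## What the simulator emulates — and what it does not

The trial generator (`generate_stage()`, `run_trial()`, `simulate_oc()`)
draws quantiles uniformly on $[t, 1]$ — i.e. biomarker screening from a
perfectly characterised population distribution — and Bernoulli responses
from the true logistic curve. Scenario curves are calibrated by
root-finding so that the subset rate passes through a prescribed anchor
(`calibrate_intercept()`: e.g. $\Pi(0.5) = 0.4$ gives a true threshold of
exactly 0.5 at $\rho = 0.4$). This reproduces the idealised conditions of
the design's operating-characteristics study: immediate binary outcomes,
no dropout, no measurement error in the biomarker, a reference sample
large enough that the quantile transform is exact, and a response curve
that genuinely is logistic. Passing tests therefore demonstrate the
design's properties under its own assumptions; they say nothing about
model misspecification (e.g. a heavier-tailed link), assay drift between
screening and analysis, or outcome latency, all of which a real
deployment must consider.

Expected screening burden is accounted analytically: recruiting $n$
subjects above quantile $t$ costs $n/(1-t)$ screens in expectation. This
matches the arithmetic used in the reference study (100 screens for a
stopped trial, 200 for a completed one at $t = 0.5$) and avoids adding
Monte-Carlo noise to a deterministic quantity.

## Numerical choices

* **Subset-rate evaluation.** The closed form for $\Pi(B)$ divides by
  $\delta_1(1-B)$; when that width is below $10^{-4}$ the two
  $\ln(1+e^z)$ terms cancel catastrophically, so the implementation
  switches to the midpoint approximation
  $\Pi(B) \approx \operatorname{expit}(\delta_0 + \delta_1(1+B)/2)$,
  whose error is $O((\delta_1(1-B))^2/24) < 10^{-9}$ at the switch and
  which contains both analytic limits ($\delta_1 \to 0$ gives
  $\operatorname{expit}(\delta_0)$; $B \to 1$ gives $\pi(1)$) exactly.
  $\ln(1+e^z)$ itself is evaluated as
  $\max(z,0) + \mathrm{log1p}(e^{-|z|})$, safe for $|z| > 700$ as occurs
  in extreme coefficient draws.
* **Beta fitting.** The beta distribution is fitted to the
  $\tilde\Pi$ draws by the method of moments
  ($a = m(m(1-m)/v - 1)$, $b = a(1-m)/m$): fast, deterministic, and
  adequate given that the beta family tracks the draw distribution
  closely in this setting. Draws are clamped to
  $[10^{-9}, 1-10^{-9}]$ first (extreme negative-slope draws can pin the
  subset rate at the boundary), the sample variance is capped just below
  the $m(1-m)$ bound so the moment equations stay valid, and a
  numerically zero-variance draw set bypasses the beta fit in favour of
  the exact binomial tail at the mean.
* **Calibration.** $\Pi$ is strictly increasing in $\delta_0$, so the
  intercept solving $\Pi(b) = r$ is found by `uniroot` on $[-50, 50]$ to
  $10^{-12}$; two-anchor (near-null) curves nest a second root search
  over $\delta_1$.
* **Degenerate stage-1 fits.** All-zero responses stop an adaptive trial
  (the limiting predicted power is 0 everywhere); all-one responses, or a
  separated fit, continue at the smallest grid threshold (limiting
  predicted power 1). These events are logged via `message()`. In the
  simulated operating-characteristics scenarios they are vanishingly
  rare ($\pi$ stays well inside $(0.1, 0.9)$ at $S_1 = 50$), but the
  limits keep batch simulation robust.
* **Covariance repair.** The resampling covariance is
  eigendecomposed and negative eigenvalues are clipped at zero — relevant
  only for numerically near-singular interim fits.
* **ECDF convention.** The quantile transform uses
  rank$/n$ with maximal tie rank: the reference maximum maps to 1, values
  below the reference minimum to 0. Any monotone convention would do;
  this one round-trips exactly through the raw-scale back-transform
  (smallest reference order statistic whose quantile reaches the
  estimate).
* **Threshold search grid and ties.** $\hat T$ is searched on
  $0, 0.001, \dots, 0.999$; argmin ties break toward the smaller
  quantile, consistent with defining the positive subset as large as
  possible.
* **Interval construction.** The resampling interval takes per-draw
  argmin thresholds and reports their empirical quantiles (type-1, so the
  interval endpoints are attained grid values). An alternative reading —
  inverting the distribution of $|\tilde\Pi(B)-\rho|$ at fixed $B$ —
  would give a different (generally wider) construction; the per-draw
  argmin is used because it directly propagates coefficient uncertainty
  into threshold uncertainty. The default 75% coverage mirrors common
  reporting for this design; it is a free parameter.
* **Seeding.** Every stochastic entry point takes a seed; `run_trial()`
  derives independent substreams for stage-1 data, interim draws,
  stage-2 data and final-resampling, so changing `n_draw` does not
  perturb recruitment, and batch runs derive per-trial seeds from one
  master seed. All derived seeds stay below $2^{31}$.

## Problem sizes used in the shipped checks

The package's own test suite exercises the operating characteristics at
1000 simulated trials per scenario (spot values and bias recovery), 400
trials per design–scenario pair for the null-conservatism sweep, and
exact enumeration wherever the design permits it (constant-rate fixed
designs). The acceptance script (`scripts/acceptance.R`) reruns the three
headline adaptive-design quantities at 5000 trials each, the replication
at which the reference values are tabulated. A single 5000-trial adaptive
batch takes well under a minute on one core.

## Known limitations

* Binary outcomes only; a single interim; fixed $S_2$. Extensions
  (continuous or time-to-event outcomes, multiple interims, adaptive
  stage-2 size, fully Bayesian modelling) are out of scope here.
* The design is *conservative*: the overall type-I error is bounded by
  $\alpha$ but is typically far below it, because most null trials stop
  at the interim. Completed-study error rates are conditional quantities
  and should be read with the stopping rate alongside.
* Observed power in completed trials can fall below the predicted-power
  target: the continuation rule selects thresholds whose predicted power
  was, if anything, over-estimated (a selection asymmetry that grows
  when the true threshold is far above the stage-1 threshold).
* Threshold estimates extrapolate the logistic fit below the recruitment
  threshold; with $t_1$ near 1 and little low-quantile data, fixed
  designs in particular can estimate very poorly. The adaptive variants
  mitigate this by often recruiting stage 2 at lower thresholds.
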