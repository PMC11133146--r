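---
title: "Simulating and analysing real-world free-operant habit induction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing real-world free-operant habit induction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(freeoperant)
```

## The paradigm

`freeoperant` implements a desk-scale version of a smartphone-based
free-operant habit-induction paradigm. Participants (here, synthetic
agents) are free to "enter" a gamified app whenever they like. Each entry
costs one gold unit and pays 15 units with probability 1/3 (a VR-3
variable-ratio schedule); after six consecutive failures the seventh entry
is guaranteed to pay, and each day's first two entries are fixed to a rock
and then a gold find. Earnings accumulate in a warehouse that is emptied
every morning at the 05:00 day boundary.

Habitual control is probed by outcome devaluation: on the devaluation day
(day 3 of a 4-day short-training schedule, day 10 of an 11-day extensive
schedule), the fifth daily entry announces that the warehouse is full, so
further gold is worthless for the rest of the day. Control manipulations
(warehouse half full, value retained) flank the devaluation day; one
extensive group receives additional week-1 controls on days 2–4. From the
third daily entry of any manipulation day the outcome is masked. Entries
committed after the message is confirmed are the dependent variable:
a goal-directed agent stops entering once gold is worthless, a habitual
agent keeps going. A cave mini-task (15 gold piles and 15 rocks; each
press costs 10 units, each pile pays 15 while the warehouse is not full)
serves as the manipulation check.

Sensitivity to devaluation is summarised per participant by the
behavioral adaptation index

$$\mathrm{AI} \;=\; \frac{\sqrt{\mu_{\text{valued}}}-\sqrt{\text{devalued}}}
{\sqrt{\mu_{\text{valued}}}+\sqrt{\text{devalued}}},$$

where $\mu_{\text{valued}}$ averages the post-manipulation entry counts of
the two control days. The index lies in $[-1, 1]$; 1 means no devalued
entries at all, values near 0 mean responding insensitive to value.

## The synthetic-agent generator

Real participants emit entries in self-initiated micro-sessions. The
generator reproduces that structure with the simplest process that works:

* daily session count $\sim$ Poisson (default mean 7), session starts
  uniform in a waking window (08:00–23:00);
* entries per session $\sim 1 + \mathrm{NB}(\mu = 6.64, k = 2)$
  (default mean 7.64);
* within-session gaps $= 10 + \Gamma(2, 25)$ seconds, capped at 295 s, so
  they stay strictly below the 300-s sessionization threshold by
  construction;
* a per-participant engagement multiplier drawn from a lognormal with
  `sdlog = 1.4`, capped at 15. This triple was calibrated once against the
  published engagement descriptives (daily entries: median 53.5, mean
  122.2, SD 180.7) and then frozen; at these defaults the simulated
  cohort reproduces median ≈ 53.5, mean ≈ 122, SD ≈ 174.

Devaluation sensitivity is a thinning parameter $s \in [0, 1]$: on the
devaluation day each planned post-manipulation entry is retained with
probability $1-s$, so the expected post-manipulation count is $(1-s)$
times the matched valued-day expectation, and fractional habit strengths
are expressible ($s=1$ is full goal-directed adaptation, $s=0$ pure
habit). Control days use a separate (default 0) sensitivity.

Cohort-level defaults mirror the study's qualitative structure: the short
training group draws $s \sim \mathrm{Beta}(14, 3.5)$, chosen once so the
simulated short-group adaptation index averages about 0.47, the value the
study reports; the extensive groups draw from a 50/50 mixture of that
goal-directed population and a habitual population
$s \sim \mathrm{Beta}(1.5, 12)$, which yields the two-cluster index
structure under extensive training.

Two features of real data the generator deliberately does not model:
entry timing is not a cognitive process model (no circadian structure
beyond the waking window, no reactivity to reminders), and engagement and
sensitivity are drawn independently, whereas the study found more engaged
participants to be more goal-directed. Passing tests therefore speak to
the correctness of the pipeline, not to any behavioural theory of timing.

One structural consequence worth knowing: the index is quantized near its
upper bound. With $\mu_{\text{valued}} < 150$ there is no achievable value
between roughly 0.75 (one devalued entry) and exactly 1 (zero devalued
entries), so low-engagement goal-directed agents form an atom at 1. Under
a variance-floor EM this atom can surface as its own cluster in small
samples.

```{r example}
log <- simulate_participant(agent_params(devaluation_sensitivity = 0.9),
                            schedule_for_group("short"), seed = 1)
log
entries_under_manipulation(log)
```

## The confirmatory count models

The main analysis regresses post-manipulation entry counts on
`manipulation * group` with a participant random intercept. Counts this
overdispersed (the study's Poisson fit had dispersion ratio 11.683) need
heavier-tailed conditional families, so four are available: Poisson; an
observation-level random-effect model (OLRE: Poisson with an extra
per-observation normal intercept); NB1 (variance $\mu(1+\alpha)$, the
"quasi-Poisson" shape); and NB2 (variance $\mu + \mu^2/\theta$).

`fit_mixed_count()` maximizes the exact marginal likelihood, integrating
the participant intercept by adaptive Gauss–Hermite quadrature (15 nodes
by default; conditional modes found by a damped Newton search with a
monotone line search, tolerances scaled to the count magnitude). For OLRE
the observation-level effect is integrated by an inner adaptive
quadrature nested inside the participant-level one. Standard errors come
from the observed information (numerical Hessian at the optimum). In
cross-checks the Poisson fit matches `lme4::glmer` with `nAGQ = 15` to
four decimals, and the NB1/NB2/OLRE fits match (and slightly exceed, as
quadrature should) `glmmTMB`'s Laplace log-likelihoods.

The overdispersion diagnostic is the Pearson dispersion ratio
$\sum r_i^2 / \mathrm{df}$ computed from conditional residuals, as the
standard GLMM tools do. With few observations per participant and a
strong random effect this statistic is biased downward (the conditional
modes absorb participant degrees of freedom) — identically so in
`glmer` — so its equidispersion calibration holds in low-shrinkage
regimes, while the overdispersion signal it exists to detect (ratios far
above 1, as in the study) is unaffected.

Model selection follows the study: leave-one-out cross-validation with
mean squared prediction error, refitting without each held-out
observation and predicting it from the participant's re-estimated
conditional mode (leave-one-participant-out, predicting from the
population intercept distribution, is available as an option). Warm
starts from the full fit keep the refits cheap; fold refits use a looser
optimizer tolerance (`1e-6` relative) that does not move predictions at
the scale MSE can resolve. In simulations at 20 participants per dataset,
NB1 wins on NB1-generated data in about 85% of replicates.

Inference on the factorial structure uses Wald chi-square tests: the
4-df interaction block, simple interaction contrasts (devaluation versus
pre-devaluation control, across group pairs) and the simple group effects
on the reference day, mirroring the published coefficient layout.

## Latent subgroups and rank-based regression

`fit_mixture()` is a univariate Gaussian EM with 20 random restarts, a
variance floor of $10^{-4}$ and a $10^{-8}$ log-likelihood tolerance;
`select_k()` compares $k = 1$ versus $k = 2$ by BIC
($-2\ell + p\log n$, $p = 3k-1$), the study's criterion for deciding
whether a training group's index distribution hides a habitual subgroup.

The engagement analyses use rank-based regression: slopes minimize
Jaeckel's dispersion with Wilcoxon scores, the intercept is the median
residual, and per-term tests are drop-in-dispersion F statistics
$(RD/q)/(\hat\tau/2)$. The scale parameter
$\tau = (\sqrt{12}\int f^2)^{-1}$ is estimated by a Gaussian-kernel
density functional with Silverman bandwidth. Continuous predictors are
standardized before fitting and the training-duration factor is effect
coded ($-1$ short, $+1$ extensive), matching the published analysis
conventions. Under the null the term tests are approximately uniform
(checked by simulation); the estimator resists gross outliers that pull
least squares.

## The two-step task and the hybrid model

The post-experimental two-step task is simulated with the standard
structure: each stage-1 action commonly (0.7) leads to its associated
second-stage state and rarely (0.3) to the other; stage-2 reward
probabilities follow a reflecting Gaussian random walk (step SD 0.025,
bounds [0.25, 0.75] — the conventional drift, since only "gradually
changed" is specified).

The hybrid model has the five parameters the study estimates: learning
rate $\alpha$, stage-1 model-based and model-free weights, a stage-2
model-free weight, and perseverance (stage-1 choice stickiness). Stage-2
values update by $\delta = r - Q_2$; stage-1 model-free values back up
the obtained stage-2 value with eligibility $\lambda$ fixed at 1 (exposed
but not estimated), so the single learning rate carries the reward signal
to stage 1; model-based values combine the known transition
probabilities with the best stage-2 action. Estimation is MAP with
weakly-informative priors (Beta(2, 2) on $\alpha$, half-normal SD 5 on
the weights, normal SD 2 on perseverance) and multi-start L-BFGS-B —
a deliberate substitution for the study's hierarchical NUTS sampler,
trading shrinkage for speed while keeping the same likelihood, which an
MCMC backend could reuse. MAP estimates converge to maximum likelihood as
the priors flatten (tested), and simulate-and-refit recovery at 1000
trials per agent gives rank correlations above 0.9 for the model-based
and model-free weights.

Engagement exclusions follow the study: more than 10% missed trials,
mean response time beyond ±2 SD of the cohort mean, or more than 90%
same-key stage-1 presses.

## Numerical choices and problem sizes

* Quadrature: 15 adaptive Gauss–Hermite nodes by default (9 inner nodes
  for the OLRE observation integral); tests use 9 where many refits are
  needed. The mode searches use monotone damped Newton steps with
  count-scaled tolerances.
* Optimizer boundaries: random-effect SDs live on the log scale in
  $[e^{-6}, e^{3}]$; a boundary solution is reported, not hidden.
* Mixture EM: restarts guard against label-degenerate starts; an empty
  component aborts a start rather than being patched.
* An undefined adaptation index (no valued and no devalued entries) is an
  explicit error; cohort tables record it as `NA` rather than silently 0.
* Quartile membership uses linear-interpolation sample quantiles with
  membership at `<= Q1` / `>= Q3`, computed within training groups by
  default; an all-equal stratum is flagged as degenerate.
* Desk-scale problem sizes used by the test-suite oracles: cohorts of
  20–50 agents, 200 participants for coefficient recovery, 20 replicate
  datasets of 20 participants for model selection, 30 agents × 1000
  trials for RL recovery. These were chosen as the smallest sizes at
  which the corresponding properties are stable, and the methods hold
  unchanged at study scale.

## Known limitations

The day boundary is a clock offset on timezone-naive timestamps; the
three-press entry sequence is modelled as always completed (partial
sequences are logged but not analysed); the random-interval schedule
delivers the first reward after an exponential availability interval
without the full superstition dynamics of real RI schedules; and the
manipulation-day fifth entry itself (message plus cave) is excluded from
the dependent variable, with "entries under manipulation" counted from
message confirmation to the next day boundary.
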