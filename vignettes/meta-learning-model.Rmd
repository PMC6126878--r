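---
title: "A discrete cortical-brainstem reinforcement meta-learner: model, calibration, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A discrete cortical-brainstem reinforcement meta-learner}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmlsim)
```

## The model

`rmlsim` simulates trial-level behaviour of a four-module actor-critic
agent in which a cortical decision system recurrently controls its own
neuromodulation. Two cortical modules make decisions: an *action* system
that selects motor actions directed at the environment, and a *boost*
system that selects a discrete internal action `b` (integers 1–10), the
amount of catecholamine release. Two brainstem modules close the loop: a
dopaminergic module computes the teaching signals that train both cortical
systems, and a noradrenergic module sets the effort discount and both
learning rates. One fixed parameter set is used for every protocol in the
package:

| symbol | value | role |
|---|---|---|
| `rho` | 0.2 | TD discount on the successor value |
| `mu` | 0.1 | split of the boost between primary and non-primary reward |
| `tau` | 0.6 | softmax temperature (both decision systems) |
| `alpha` | 0.3 | low-pass constant of the learning-rate filter |
| `beta` | 0.2 | learning-rate floor |
| `omega` | 0.15 | cost per unit of boosting (value units / boost level) |

Per trial, the boost system draws `b` from a softmax over its boost values
`v_B(s, ·)`; norepinephrine is identified with the boost level (`NE = b`).
The action system then draws each action from

```
p(a | s) = softmax( v(s, a) - C(s, a) / NE, tau )
```

so high NE discounts action costs and energizes effortful behaviour. The
dopaminergic teaching signal for the action system is

```
DA = r (R + mu * b) + (1 - mu) * b * rho * max_a v(s', a)
```

where `r` is reward presence and `R` its magnitude. The boost level
amplifies both the primary reward term and the non-primary (TD) term; the
TD term is what carries conditioned reinforcement along cue chains. With
`mu = 0` and `b = 1` the expression is the ordinary Q-learning target. The
boost system is trained only by primary reward, discounted by the cost of
boosting:

```
DA_B = r (R - omega * b)
```

Both value stores follow the delta rule `v <- v + lambda * (DA - v)`, with
module-specific learning rates `lambda`, `lambda_B` set by the
noradrenergic filter, an approximate Kalman gain: the ratio of estimated
process variance (squared deviation of the tracked value from its
low-passed estimate) to estimated total variance (squared low-passed
unsigned prediction error), clamped to `[beta, 1]`. The single meta
parameter `alpha` encodes the assumption that outcome noise fluctuates
faster than genuine environmental change, which is what lets the filter
raise plasticity under volatility while protecting knowledge from noise.

## Numerical and structural choices

Several recurrences are printed in simultaneous subscript form and have to
be sequenced to be computed at all. The choices below are fixed in the
implementation and exercised by the oracle tests.

**Filter sequencing.** The value update for trial *t* uses the learning
rate currently held by the filter; the filter then ingests the post-update
value and the trial's prediction error, producing the rate for the next
trial. Ingesting the *post*-update value keeps the process-variance
estimator sensitive to the update steps themselves: during a genuine
contingency change the updates trend, the tracked value runs ahead of its
low-passed estimate, and the rate escalates — this positive feedback is
roughly twice as strong as under the pre-update alternative in the bandit
session, and is what speeds reversal learning.

**Per-entry value tracking.** The filter's learning rate and its
prediction-error low-pass are module-level, but the low-passed value
estimate is kept per value-table entry. A single module-level estimate
conflates policy switching with environmental change: alternating between
two actions of unequal value generates large spurious "process variance",
and in the three-environment bandit session this *inverts* the volatility
ordering of the learning rate (the stable 70/30 regime, which has the most
dispersed action values, shows the highest rate). Comparing each value
with its own running estimate removes the artifact while keeping one rate
per module.

**Division-by-zero clamp.** When the low-passed prediction error is
exactly zero the rate clamps to 1 if the process variance is positive and
to `beta` otherwise; values, estimates and rates start at zero, zero, and
`beta`.

**Lesions.** A dopaminergic lesion multiplies the reward components of
both teaching signals and the TD term by `da_gain`; the boosting cost
`omega * b` is *not* attenuated, so the lesioned cost-benefit curve
declines monotonically in `b` — the reward side shrinks while the cost
side does not. A cortical lesion multiplies the value readouts entering
both softmaxes, the successor value relayed to the dopaminergic module,
and the copies sent to the noradrenergic filter by `dacc_gain`, while the
delta rule keeps using the stored value as its own prediction. If the
update error were also computed against the attenuated readout, the store
would converge to `DA / dacc_gain` and the readout would exactly
compensate the lesion at steady state, abolishing its behavioural effect.
The learning rate is invariant to a common gain on the filter inputs (the
gain cancels in the variance ratio), so lesioning the filter's afferents
is cosmetic, but they are attenuated for consistency.

**Stay.** Every choice task carries a zero-cost, zero-reward "stay"
action; a stay trial terminates with `DA = 0` and updates the stay value
toward zero. Its frequency is the package's operationalization of apathy.

## Tasks and what the generator emulates

**Three-regime bandit session** (432 trials, three 144-trial blocks in
randomized order; values carry across block boundaries as in a continuous
session). `Stat`: arm probabilities 0.7/0.3; `Stat2`: 0.6/0.6 (maximal
outcome noise, no optimal arm); `Vol`: the probability-to-arm mapping
permutes every 30 trials, first switch uniform in the period. The
lower-probability arm always carries the larger magnitude while expected
value still favours the higher-probability arm (magnitudes 1.0 / 1.5; in
`Stat2` both arms use 1.25, the mean of the other regimes' magnitudes, so
the session's reward scale is constant). Accuracy is scored per trial
against the currently higher-expected-value arm, among engaged (non-stay)
trials: on a stay trial no option was sampled.

**Effort battery.** Two rewarded options plus stay. The variant fixes the
cost structure: `Effort` (costly high-reward vs cheap low-reward),
`NoEffort` (both cheap), `DoubleEffort` (both costly). The reward/cost
table is a package calibration, not a literature value: HR magnitude 1.3,
LR magnitude 0.4, high cost 2.5, low cost 0.2, 150 trials per phase. The
structure (which option is costly in which variant) is fixed by the
protocols; the four numbers were chosen once, by a grid scan scored only
on the qualitative phenomena the battery exists to show — intact
preference for the high-effort/high-reward option, lesion-induced shifts
toward the cheap option and disengagement, boost recruitment under effort,
boost devaluation under dopaminergic lesion with compensation in the easy
task, and the cost-benefit sweep geometry — and verified to hold across
independent seeds. With a weaker trade-off (e.g. HR 1.0 / high cost 2.0)
several of these directions sit on a knife edge and flip sign between
seeds at `tau = 0.6`.

**Conditioning chains.** Stage-wise training over three orders; each stage
starts one cue further from reward and uses the previously conditioned cue
as non-primary reward, with primary reward still delivered at the end of a
completed chain. Classical chains are passively observed (one action
channel); instrumental chains are binary choices with deterministic
transitions and 100%/0% reward for correct/wrong paths. Cue duration has
no discrete-time counterpart: each cue is one state-step. The cue-locked
dopaminergic response of order *k* is reported as the non-primary term of
the teaching signal evaluated at that cue — a stated proxy for a phasic
response the trial-level model does not otherwise define. Reported
summaries use the last 25% of trials of the final stage.

**Cost-benefit sweep.** The boost level is clamped at each value 1–10
(controller offline), the effort protocol is re-run 40 times per level,
and performance (mean reward signal reaching the boost controller), cost
(`omega * b` on rewarded trials) and net value are reported per level.

## What passing tests do and do not show

The generator produces Bernoulli or deterministic rewards with exactly the
scheduled contingencies; it has no reaction times, no intra-trial
dynamics, no drift in magnitudes, and no forgetting. Passing the package's
tests shows that the *mechanisms* behave as described under these idealized
conditions — it does not certify behaviour on empirical data, and three
study-scale quantities fall short of their published counterparts for
structural reasons worth knowing:

* **Volatile-block accuracy** (~57% vs 63.6%). The filter can only raise
  the learning rate once value drift is comparable to the outcome noise;
  with 70/30 Bernoulli outcomes the trial-level filter needs ~8–12 trials
  per reversal, while the published figure implies recovery within a few
  trials. Stationary-block accuracy, the learning-rate ordering
  (volatile > both stationary regimes) and the activity-proxy dissociation
  (mean unsigned PE maximal under 60/60 noise) are all reproduced.
* **Final-choice maze accuracy** (~93% vs 98 ± 0.4). With terminal reward
  magnitude 1 the final-choice value saturates at `1 + mu * b`, so the
  softmax at `tau = 0.6` caps two-option accuracy near 93–95%. The
  accuracy *gradient* across levels and its direction are reproduced, and
  the first-choice accuracy matches the published value within its
  interval.
* **Classical third-order blunting** (ratio ~0.4–0.5 vs "< 20%"). In the
  trial-level model the cue response decays geometrically at
  `(1 - mu) * rho * b` per order; driving it below 20% by order 3 would
  require a mean classical boost below ~2.5, whereas the softmax
  equilibrium over `v_B = 1 - omega * b` yields ~3.6. The dissociation
  itself — classical collapse steeper than instrumental, higher boosting
  in the instrumental paradigm — is reproduced.

One further reporting convention: the consistency between the free-running
boost controller and the clamped sweep is checked on the *mode* of the
free-running boost distribution. The mean is upward-biased because `b` is
drawn by a softmax over a range bounded below at 1; when the optimum sits
at the boundary the distribution is strongly asymmetric and its mean sits
2–3 levels above the optimum even for a well-behaved controller.

## Problem sizes

All shipped protocols run at study scale: 12 simulated subjects per
cohort, 432-trial bandit sessions, 150-trial effort phases, 100 trials per
conditioning stage, and 40 repetitions per clamped boost level. A full
cohort of any protocol takes seconds on a single core.

## Worked example

```{r}
sim1 <- run_simulation1(n_subjects = 12, seed = 1)
aggregate(cbind(mean_lam, mean_abs_pe, accuracy) ~ regime, sim1$summary,
          mean, na.action = na.pass, na.rm = TRUE)
```

## Known limitations

* Trial-level only: no intra-trial neural dynamics, no reaction times, and
  no coupling of the exported NE channel to an external consumer (the
  channel is logged per trial).
* No parameter fitting: the package simulates the fixed parameter set; it
  does not estimate parameters from behaviour.
* Contrast statistics produced by `summarize_cohort()` are descriptive
  outputs for cohort tables, not calibrated inference.
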