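---
title: "Modelling adaptive penalty-kick redirection training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling adaptive penalty-kick redirection training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redirkick)
```

## The problem

A penalty taker using the goalkeeper-dependent strategy watches the keeper
during the run-up and, if the keeper dives toward the intended side, must
redirect the kick to the open side. Whether redirection succeeds depends on
the *dive lead time* $\tau$: the interval between dive onset and foot–ball
contact. The quantity of scientific interest is the **50% redirection
threshold** $\theta$ — the smallest $\tau$ at which the player redirects
successfully half the time — and how much adaptive training lowers it.

`redirkick` simulates the whole measurement and training loop: a synthetic
player with latent psychometric parameters, noisy run-up kinematics with an
online time/radius dive trigger, a grid-Bayesian engine that estimates the
player's parameters after every kick and chooses the next dive lead time,
and analytics for the derived quantities (threshold change, probability of
improvement, success-rate curves, exact binomial test).

## Observer model

A (player, redirection-side) pair is described by four parameters:

* $\theta$ (`threshold_ms`) — 50% redirection threshold, ms;
* $s$ (`slope`) — steepness of the psychometric function, 1/ms;
* $\lambda$ (`lapse_rate`) — probability of failing for reasons unrelated to
  redirection timing (e.g. missing the target);
* $\alpha$ (`anticipation_rate`) — probability of committing to a side
  before the dive; an anticipated kick never counts as a success.

The redirection-specific component is logistic,
$F(\tau) = 1/(1+e^{-s(\tau-\theta)})$, and the probability of a successful
redirection kick is $(1-\alpha)(1-\lambda)F(\tau)$. On a no-redirection
trial success occurs with probability $(1-\alpha)(1-\lambda)$; an
anticipated no-redirection kick is ruled a failure (the player pre-committed),
which is what makes $\alpha$ and $\lambda$ identifiable from the eight
no-redirection kicks of each session. Defining $\theta$ on $F$ (where
$F(\theta)=\tfrac12$ exactly) rather than on the raw success rate is what
keeps the threshold estimate free of lapse- and anticipation-related bias.

The logistic form is a design choice — it is the standard two-parameter
psychometric core in adaptive psychophysics and has a closed form. The
likelihood case table used by the engine mirrors the generative simulator
exactly (a shared-oracle test checks every cell against Monte-Carlo
frequencies).

## Learning model

Training moves each side's threshold along an exponential curve in units of
training kicks, $\theta(k) = \theta_\infty + (\theta_0-\theta_\infty)
e^{-k/\rho}$. `calibrate_learning()` inverts the curve in closed form so the
expected group mean falls from 429.02 ms to 309.08 ms over the 200 training
kicks of a campaign (10 sessions of 20 kicks); with the default asymptote
129 ms below baseline this gives $\rho \approx 75$ kicks. Baseline kicks do
not drive learning. Only the threshold learns; slope, lapse and
anticipation are assumed stable over the twelve sessions.

Cohort defaults mirror the study population: baseline thresholds are drawn
from $N(429.02, 53.46^2)$ truncated to $[319, 536]$ ms; the two sides of a
player scatter around the player mean with SD 20 ms (no systematic side
difference); lapse and anticipation rates are Beta(2, 18) (mean 0.1 — small
but non-negligible rates, no printed values exist); slopes are log-normal
around 0.02 /ms. The slope centre is derived from the study's printed
success rates: deconvolving the group success curves (50% at the 429 ms
baseline threshold before training, ~85–90% there after training, with the
printed between-player threshold SDs) gives individual slopes of about
0.018–0.022 /ms.

## Run-up kinematics and the time/radius trigger

The dive must be launched *during the run-up* so that it lands $\tau$ ms
before foot–ball contact. The simulator generates run-up traces — radial
distance to the ball sampled at 60 Hz, trapezoidal speed profile
(acceleration 4 m/s², cruise 4 m/s), start radius uniform in 2.2–2.8 m
(the protocol requires at least 2 m), multiplicative trial-to-trial speed
variability (CV 5%) and additive per-sample position noise (SD 2 cm).

The **time/radius map** predicts remaining time-to-contact from current
radius. It is fit from the most recent 10 run-ups: all (radius, remaining
time) sample pairs are pooled, binned by radius (0.05 m bins), each bin
summarised by its median (robust to noise), monotonicity enforced by
isotonic pool-adjacent-violators regression, and empty interior bins filled
by linear interpolation. Each bin also stores its median radius as the
representative abscissa, which makes the map exact for noiseless uniform
motion. The first trial of a campaign uses an analytic cold-start map from
the nominal speed; the map is refit after every trial.

Triggering inverts the monotone map at the commanded $\tau$ and launches
the dive at the first sample whose radius falls at or below the trigger
radius (strictly causal; a prefix-equivalence test verifies no lookahead).
With noiseless uniform motion the realized lead time is within one sampling
period (16.7 ms) of the commanded one; under the default noise the median
absolute triggering error after a 10-trace warm-up is well under 40 ms.
The engine consumes the *realized* lead time as evidence, not the commanded
one, so triggering error does not bias the threshold estimate.

## The grid-Bayesian engine

The posterior over $(\theta, s, \lambda, \alpha)$ lives on a fixed grid:
$\theta$ 150–700 ms in 5 ms steps, 15 log-spaced slopes in 0.005–0.1 /ms,
and 7 equispaced values in 0–0.3 for each of $\lambda$ and $\alpha$
(81,585 nodes). Updates multiply the mass node-wise by the trial likelihood
and renormalize. Renormalizing after every trial keeps the mass on the unit
scale, so no log-domain accumulation is needed even over 240 trials; tail
mass below $10^{-280}$ is flushed to exact zero (it can never recover, and
subnormal arithmetic is extremely slow). The hot kernels (update and
expected-entropy scoring) are small C++ routines.

**Priors.** `init_posterior()` defaults to a flat prior, but the campaign
engine uses an empirical-Bayes prior: threshold $\sim N(429.02, 53.46^2)$ —
the published distribution of elite baseline thresholds — log-normal slope
centred at 0.02 /ms (log-SD 0.5, wider than the generative spread), and
Beta(2, 18) priors on lapse and anticipation. This is deliberate: with only
24 redirect kicks at slope 0.02 the Fisher information bounds any
flat-prior estimator's SD at roughly 24 ms, while the population prior
brings the posterior SD to ~17 ms at 40 kicks. The prior's centre is the
*population* mean, not any individual's value, so per-player estimates are
shrunk toward 429 ms; the shrinkage bias is below ~15 ms for thresholds
within one population SD of the centre and cancels at group level.

**Point estimate and interval.** The threshold estimate is the mean of the
$\theta$ marginal; the 95% credible interval inverts the marginal's
cumulative mass. Grid nodes are atoms, so the inverse CDF is a step
function — a point-mass posterior yields a zero-width interval — with
midpoint interpolation only when the target probability lands exactly on a
node boundary.

**Stimulus placement.** During baseline (pure estimation) the engine picks,
from a 150–650 ms candidate grid in 10 ms steps, the lead time minimizing
the expected post-update Shannon entropy of the $\theta$ marginal, the
expectation running over the posterior-predictive probabilities of the
three outcomes (anticipated / success / failure) of a redirection trial.
During training it targets the *optimal challenge zone*: the candidate
closest to the current $\theta$-marginal median (≈50% conditional success),
with a ±1-step uniform jitter against lock-in. Ties break toward the
smaller, harder lead time.

**Tracking a learning player.** A statically accumulated posterior over all
120 trials of a side estimates an information-weighted average of the
drifting threshold — roughly 360 ms for a player learning from 429 to
309 ms — not the end-state ability. The campaign therefore applies
exponential forgetting at the start of each training session: the session
side's posterior mass is tempered, $m \mapsto m^{\gamma}$ (renormalized),
with $\gamma = 0.36 \approx 0.95^{20}$ — per-kick forgetting of 0.95
compounded over a 20-kick session, chosen from the learning time constant
($\rho \approx 75$ kicks, so the threshold moves only a few ms within the
effective two-session memory). Baseline sessions are static, matching their
pure-estimation role. Tempering pulls the posterior toward uniform, which
slightly widens post-training intervals; that is the price of tracking.

## Campaign design

A campaign is 2 baseline + 10 training sessions per player, 20 kicks per
session, 12 of them (a uniformly random subset) requiring redirection. The
target side is fixed within a session and alternates across sessions from a
random start, so each redirection side receives one baseline and five
training sessions and both baseline thresholds are estimable. All kicks of
a session update the posterior of the session's redirection side; learning
advances on every training kick, including no-redirection kicks (every kick
practises the run-up and execution). Footedness is right by default;
redirecting left is then "crossed", right "reverse-crossed". Everything is
reproducible from the campaign seed, which drives the single global random
stream.

## Analytics

* `improvement_distribution()` forms the distribution of
  $\Delta = \theta_{\text{baseline}} - \theta_{\text{post}}$ by discrete
  cross-correlation of the two marginals, assuming independence (they come
  from disjoint trial sets). `prob_improvement` is the mass strictly above
  zero; "improvement larger than one standard deviation" uses the SD of the
  $\Delta$ distribution itself (an option switches to the baseline
  marginal's SD — the convention is genuinely ambiguous).
* `success_curve()` averages the success probability over the posterior,
  either "raw" ($(1-\alpha)(1-\lambda)F$, an observable rate) or as the
  redirection component $F$ alone. The component convention reproduces the
  defining property that success at a player's own threshold is 50%, which
  is how the study's reference success rates read; both modes are exported.
* `binomial_two_tailed()` is the exact test by tail summation, doubling the
  smaller tail and capping at 1 (a min-likelihood variant is available);
  24 successes in 26 trials at chance gives $1.05\times10^{-5}$.

## Problem sizes and numerical choices

The test-suite simulations use the study's own dimensions: 13 players × 12
sessions × 20 kicks per campaign; 50 seeded campaign replicates for the
end-to-end recovery check; 200 replicates of 40 engine-driven kicks for
parameter recovery; 1000 noisy trials (after a 10-trace warm-up) for
triggering accuracy. Oracle tests compare the sequential grid update with
brute-force joint enumeration on a 3×2×2×2 grid at $10^{-12}$, the entropy
policy with exhaustive expected-entropy computation, and the improvement
distribution with exhaustive pair enumeration. Degenerate inputs are
handled explicitly: evidence that annihilates the posterior raises a
degenerate-evidence error rather than returning NaNs; lead times outside a
map's predicted range raise a range error and campaign code clamps first.

## What the generator does and does not emulate

The synthetic cohort reproduces the published group-level statistics
(baseline threshold distribution, post-training mean, session structure)
and plausible but unverifiable micro-structure (logistic core, exponential
per-kick learning, Beta-distributed small lapse/anticipation rates, noisy
trapezoidal run-ups). It does not emulate: detection error in flagging
anticipation (flags are observed perfectly), slope/lapse/anticipation
changes with training, between-session forgetting or warm-up effects,
fatigue within a session, gaze behaviour, or 3-D ball and body kinematics.
Passing tests therefore certify the estimation and adaptation machinery
under the stated generative assumptions — not the biomechanical fidelity of
the simulation to real penalty kicks.

## Known limitations

* Estimates are shrunk toward the population prior; single-player use with
  an atypical threshold (far outside 319–536 ms) should widen `theta_sd` or
  use the flat prior.
* The independence assumption in the improvement distribution ignores the
  small correlation induced by carrying the tempered baseline posterior
  into training.
* Lapse and anticipation are estimated independently per side; partial
  pooling across sides would be more efficient but is deliberately out of
  scope.
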