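---
title: "Modelling transition-probability learning in the probabilistic SRT task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling transition-probability learning in the probabilistic SRT task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgfsrt)
```

## The task and what the model learns

In the four-choice probabilistic serial reaction time (SRT) task a stimulus
appears in one of four locations and the participant presses the matching
key.  Unbeknownst to the participant, the location on trial $t$ is decided
by the locations on trials $t-1$ and $t-2$: two second-order conditional
(SOC) sequences over the categories 1–4 each map every ordered pair of
distinct categories to a successor, and on each trial the continuation of
the currently *high-probability* sequence is used with probability 0.85,
the other sequence's continuation with probability 0.15.  After one
960-trial session the roles of the two sequences reverse, and a second
960-trial session follows.  Faster responses on high-probability
continuations are the behavioural signature of implicit learning; the
interesting computational question is how a learner tracks the 16
transition probabilities, and how its internal uncertainty shows up in
reaction times.

`hgfsrt` implements this workflow end to end: a generative simulator of the
task and of response behaviour, a categorical state-transition hierarchical
Gaussian filter (HGF) that estimates the transition probabilities trial by
trial, a linear Gaussian response model from belief regressors to log
reaction times, and per-participant Bayesian inference over the joint
model's 8 free parameters.

## The categorical state-transition HGF

The filter maintains one continuous node per ordered transition $i \to j$
between the four categories — a $4 \times 4$ array of 16 nodes.  Node
$(i,j)$ holds a Gaussian belief $\mathcal{N}(\mu_{ij}, 1/\pi_{ij})$ over
the log-odds of that transition.  Each trial has two phases.

**Prediction.**  Time passes for every node: the mean is carried forward
and the variance inflates by the predicted environmental volatility
$\Omega = e^{\omega}$,

$$\hat\mu_{ij} = \mu_{ij}, \qquad
  \hat\pi_{ij} = \frac{1}{1/\pi_{ij} + e^{\omega}}.$$

A single log-volatility $\omega$, shared by all 16 nodes, is the only free
perceptual parameter: more negative values mean a more stable world,
slower forgetting, and smaller updates.  The predicted transition matrix is
obtained by passing the $\hat\mu_{ij}$ through the logistic function
$S(\cdot)$ and renormalising each row, so row $i$ is a proper distribution
over the four continuations of category $i$.

**Update.**  When stimulus $j$ follows stimulus $i$, the four nodes of row
$i$ receive binary observations through their child nodes — 1 for the
transition that occurred, 0 for its three siblings — and take the standard
binary-child update with $\hat{b} = S(\hat\mu)$:

$$\delta = o - \hat b, \qquad
  \pi = \hat\pi + \hat b (1 - \hat b), \qquad
  \mu = \hat\mu + \delta / \pi.$$

Updates are precision-weighted: they are large when the prediction error
$\delta$ is large and when the belief is imprecise.  Nodes in the 12
inactive rows adopt their prediction as the new posterior, so $\omega$'s
forgetting acts globally — transitions that are never observed drift back
toward maximal uncertainty rather than freezing.

Two boundary conventions are worth stating because the data do not force
them.  First, the prediction step runs on *every* trial, including the
first of each session; since $\hat\mu = \mu$ this leaves the first
predicted matrix uniform under the default initial beliefs
($\mu_0 = 0, \pi_0 = 1$, fixed rather than estimated) and only starts the
volatility clock one step earlier.  Second, the first trial of each session
has no incoming transition (sessions are separated by a break), so it
triggers no update; its surprise regressor is set to $\ln 4$, the value
under a uniform prediction, and its uncertainty regressors to 0 because no
transition node is defined there.

## Belief regressors and the response model

Three quantities summarise the state of the filter on each trial, evaluated
*before* the outcome is seen:

* **Surprise** $\Im_t = -\ln p(u_t)$, the negative log of the normalised
  predicted probability of the observed category (nats);
* **Expected uncertainty**
  $U_{\mathrm{exp}} = S(\hat\mu)(1-S(\hat\mu)) / \hat\pi$ at the node of
  the observed transition — outcome variance scaled by belief imprecision;
* **Unexpected uncertainty**
  $U_{\mathrm{unexp}} = U_{\mathrm{exp}} \cdot e^{\omega}$ — the same
  quantity amplified by the anticipated volatility of the world.

The precision entering $U_{\mathrm{exp}}$ is the *predicted* precision
$\hat\pi$ of the current trial: the notation leaves posterior-vs-predicted
open, and we use the predicted state because the regressor must be
available before the outcome arrives.  Log reaction times are then modelled
linearly,

$$\mu_{RT} = \beta_0 + \beta_1 \Im + \beta_2 U_{\mathrm{exp}}
           + \beta_3 U_{\mathrm{unexp}} + \beta_4\,\text{PostError}
           + \beta_5\,\text{PostReversal}, \qquad
  \log RT \sim \mathcal{N}(\mu_{RT}, \sigma),$$

with post-error marking trials whose within-session predecessor was wrong
or missed, and post-reversal marking the second session.  All coefficients
are in natural-log-millisecond units; an intercept of 5.83 corresponds to a
baseline around 340 ms.  Together with $\omega$ this gives 8 free
parameters.

A structural point that shapes everything downstream: **within one
participant the two uncertainty regressors are exactly proportional**,
$U_{\mathrm{unexp}} = e^{\omega} U_{\mathrm{exp}}$ with $e^{\omega}$
constant over trials.  Only the combination
$\beta_2 + \beta_3 e^{\omega}$ is identified by the likelihood at a given
$\omega$; the individual $\beta_2$ and $\beta_3$ are separated only by
their priors.  This is a property of the model as specified, not of the
implementation — it is why recovery of $\beta_2$ and $\beta_3$ individually
is poor while their posteriors remain well calibrated, and the package's
tests check the identifiable combination against an ordinary-least-squares
oracle rather than pretending the ridge away.

The participant-level summary of belief updating averages $|\delta|$ per
node over that node's update trials and then over the 16 nodes.  The
absolute value is a deliberate choice: signed prediction errors average
toward zero by construction, which cannot express "magnitude of belief
updating".

## RT preprocessing

Reaction-time cleaning follows the standard lapse-exclusion rules: missing
responses are dropped, anticipations faster than 200 ms are dropped, and
among the surviving trials those slower than the participant's mean plus
two standard deviations are dropped.  The slow rule is one-sided because
the fast tail is already handled by the 200 ms floor.  The rules depend
only on the raw RT values, so re-filtering a filtered table is a no-op.

## Inference

`fit_hgf()` samples the joint posterior per participant by MCMC with 4
chains of 2,000 samples each, read as 1,000 adaptation samples plus 1,000
retained draws per chain (the warmup split is a convention choice).  The
sampler is a collapsed Metropolis-within-Gibbs scheme built around the
model's structure: because the coefficient priors and the likelihood are
both Gaussian, $\beta_0\ldots\beta_5$ can be integrated out analytically,
so $\omega$ and $\log\sigma$ take random-walk Metropolis steps on the
*marginal* posterior — each proposed $\omega$ re-runs the filter over the
full stimulus stream to rebuild the regressors — and the coefficient vector
is then drawn exactly from its conjugate multivariate normal conditional.
Collapsing matters here: with $\beta$ held fixed, a volatility move must
walk along the $\beta_3$–$\omega$ ridge created by the proportionality
above, and mixing on $\omega$ degrades badly.  Step sizes adapt toward a
0.44 acceptance rate during warmup only (Robbins–Monro, frozen afterwards,
so the retained chains are valid MCMC).

Priors default to weakly informative choices, all overridable through
`hgf_priors()`: $\omega \sim \mathcal{N}(-3, 2)$ covering the slow-learning
regimes relevant to implicit sequence learning,
$\beta_0 \sim \mathcal{N}(6, 2)$ centred on plausible baseline RTs,
$\beta_{1..5} \sim \mathcal{N}(0, 1)$, and
$\sigma \sim \text{Half-Normal}(0.5)$.  Credible intervals are reported at
94% equal-tailed.  Convergence is summarised by a split Gelman–Rubin
statistic computed as $\sqrt{1 + B/W}$ from the half-chain means' variance
$B$ and the mean within-half-chain variance $W$; this form is exactly 1
for identical chains, never below 1, and conservative (slightly larger)
relative to the small-sample-corrected variant.  Fits warn, rather than
fail, when any $\hat r$ exceeds 1.01.  Effective sample sizes use pooled
autocorrelations with Geyer's initial monotone truncation.

## The synthetic-data generator

Simulated agents are the package's test bed, and their defaults *are* the
study conditions: two 960-trial sessions, 85/15 continuation probabilities
with the reversal between sessions, response coefficients defaulting to the
group-level estimates typical of this task (baseline $\beta_0 = 5.83$,
post-error slowing $\beta_4 = 0.10$, $\sigma = 0.2$), and an exogenous
error rate of 0.08 reproducing accuracy near 0.92.  Each session starts
from an ordered pair drawn uniformly from the high-probability sequence's
12 pairs — the originating experiment does not state how its first two
trials were chosen, and a uniform draw guarantees a valid context with no
category bias — and the context resets across the between-session break.

What the generator deliberately does not emulate: response errors are
independent coin flips rather than consequences of the agent's beliefs (the
model does not explain accuracy, so errors are exogenous); there are no
attentional lapses, posture breaks, or fatigue drifts, so the RT
distribution is exactly the model's log-normal; and no responses are
missing.  Passing tests therefore demonstrate self-consistency of the
simulate–filter–fit loop, not robustness to the contaminants of real data.
One concrete consequence is documented in `recovery_study()`: applying the
lapse-exclusion rules to simulated data one-sidedly truncates the
generative log-normal tail and visibly biases the recovered $\sigma$
(downward) and $\beta_4$ (toward zero, because post-error trials are slower
and preferentially cut).  Recovery studies therefore fit all simulated
trials by default, while empirical fits keep the exclusions.

Parameter-recovery defaults simulate 20 agents at full task size
(2 × 960 trials, 4 chains × 2,000 samples; roughly two minutes in total on
one CPU).  For the volatility-recovery check the true $\omega$ values are
taken as an even grid over $[-6, -2]$ — the usual design when one parameter
is the target, because uniform draws add clustering noise to a 20-point
correlation — while the remaining parameters vary uniformly over ranges
spanning the between-participant spread typical of this task
($\beta_0 \in [5.4, 6.2]$, $\beta_4 \in [0.03, 0.17]$,
$\sigma \in [0.15, 0.3]$, and so on).

## Numerical choices

The logistic is evaluated in a branch-free stable form; $e^{\omega}$ is
clamped at $10^{12}$ and precisions floored at $10^{-12}$, so extreme
volatility proposals during sampling degrade gracefully instead of
overflowing.  The filter is implemented in C++ (with an exactly equivalent
regressor-only fast path for the sampler's inner loop) and is checked
against a straight-line R re-implementation to $10^{-10}$ at every trial.
Category codes are 1-based throughout, matching the task's printed
sequences.  All public operations take one integer seed from which every
downstream draw derives; two runs with the same seed are identical.

## Known limitations

* The hierarchy stops at the 16 transition nodes: no volatility parents,
  drift, or value coupling between nodes, so $\omega$ is a constant
  expectation of volatility rather than a tracked state.
* $\beta_2$ and $\beta_3$ are not separately identifiable within a
  participant (see above); interpret their individual posteriors as
  prior-shaped.
* With response weights near zero the likelihood carries little information
  about $\omega$ and its posterior stays close to the prior; volatility
  recovery is only as good as the belief regressors' leverage on RT.
* Accuracy is exogenous in simulation; the model neither predicts nor
  explains choice errors.
* The sampler's efficiency relies on the Gaussianity of the response
  model; a heavy-tailed RT likelihood would break the analytic collapse of
  the coefficients and need a different sampling scheme.
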