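---
title: "Modelling graded visibility and confidence with static evidence models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling graded visibility and confidence with static evidence models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wevis)
```

## The problem

In masked-stimulus psychophysics an observer identifies a briefly presented
stimulus (say, the orientation of a grating, coded $S_{id} \in \{-1, +1\}$)
whose strength is manipulated by the stimulus-onset asynchrony (SOA) to the
mask, and then reports a graded judgment on a visual-analogue scale: either
the *visibility* of the stimulus or *confidence* in the identification
response. `wevis` implements eight static generative models of the joint
distribution of the binary identification response $R_{id}$ and the ordinal
rating $R_v \in \{0, \dots, 4\}$ given stimulus identity and strength,
together with the machinery to fit and compare them per participant, to
diagnose them against ordinal signatures of the data, and to run model- and
parameter-recovery simulations on fully synthetic cohorts.

## The model families

All families except the last two share the standard SDT identification
mechanism: a decision variable
$\delta_{id} \sim \mathcal{N}(\tfrac12 S_{id} S_s,\ \sigma_{id})$ is compared
with a criterion $\theta_{id}$, with one sensitivity $S_s$ fitted per SOA.
They differ in the report variable $\delta_v$ that is compared against one
set of four ordered rating criteria per response:

* **SDT rating**: $\delta_v = \delta_{id}$.
* **Noisy SDT**: $\delta_v \sim \mathcal{N}(\delta_{id}, \sigma_v)$ — late,
  nonperceptual report noise.
* **Weighted evidence and visibility (WEV)**:
  $\delta_v \sim \mathcal{N}\big((1-w)\,\delta_{id} + w\,R_{id}(S_s -
  \bar S_s),\ \sigma_v\big)$. The weight $w \in [0,1]$ captures reliance on
  identity-*irrelevant* stimulus-strength evidence; $\bar S_s$ is the mean
  sensitivity across SOAs, so strong (weak) stimuli push the report variable
  toward high (low) ratings relative to the response.
* **Two-channel**: an independent second sample,
  $\delta_v \sim \mathcal{N}(\tfrac12 S_{id} S_s a,\ 1)$.
* **Postdecisional accumulation**:
  $\delta_v \sim \mathcal{N}(\delta_{id} + S_{id} S_s b,\ \sqrt{b})$ — mean
  and variance both grow with the amount $b$ of continued accumulation. Note
  the drift uses the true identity $S_{id}$, as the model is printed in its
  source; we implement it as printed.
* **Constant noise and decay**:
  $\delta_v \sim \mathcal{N}(\rho_S\,\delta_{id},\ \sigma_v)$ with one decay
  $\rho_S \in (0,1]$ per SOA.
* **Response-congruent evidence (RCE)**: two channels
  $\delta_{id\pm} \sim \mathcal{N}(\tfrac12 (1 \pm S_{id}) S_s \pm
  \theta_{id},\ \sigma_{id})$; the larger channel determines the response and
  *only the winning channel* feeds the rating.
* **2D Bayesian**: channels centered on $0$ and $\Delta t$ (the SOA in ms)
  with noise $s$; the observer computes the posterior probability of
  $S_{id} = +1$ under a flat prior over the discrete SOA set and both
  identities, and cuts the posterior axis into 10 ordered
  (identity × visibility) options with 9 criteria; a lapse rate $\lambda$
  mixes in uniformly random responses.

Three variance regimes apply to $\sigma_{id}$: constant ($\sigma_{id} = 1$),
identity-dependent ($\sigma_{id} = r_{id}^{S_{id}}$), and strength-dependent
($\sigma_{id} = \sqrt{1 + k S_s^2}$). The 2D Bayesian model admits only the
constant mode because its noise $s$ is already free. For the 5-SOA,
5-category configuration the free-parameter counts are 14 (SDT), 15 (noisy
SDT, two-channel, postdecisional), 16 (WEV), 20 (constant noise and decay),
14 (RCE), and 11 (2D Bayesian).

## Numerical strategy

Every likelihood is exact up to quadrature error, and the trial simulator
never touches the probability table — it samples the latent variables of the
generative equations directly — so the two code paths cross-validate each
other (a test compares $10^6$ simulated trials per condition against the
predicted cell probabilities).

* For the six families whose report variable is affine in $\delta_{id}$ plus
  independent Gaussian noise, each (response × category) cell is a rectangle
  probability of a bivariate normal. We evaluate it in closed form with an
  own implementation of the Genz/Drezner–Wesolowsky bivariate normal CDF
  (machine-precision accurate for any correlation). This choice, rather than
  a fixed-node quadrature over $\delta_{id}$, is what keeps the degenerate
  limits exact: the reduction identities wev$(w{=}0) \equiv$ noisy SDT,
  noisy SDT$(\sigma_v \to 0) \to$ SDT, postdecisional$(b \to 0) \to$ SDT and
  cnd$(\rho{=}1, \sigma_v \to 0) \to$ SDT hold to $10^{-8}$–$10^{-4}$, where
  a 61-node rule applied to the resulting near-step integrands would err at
  the percent level.
* The RCE cells are smooth 1D integrals (winning-channel density times
  losing-channel CDF), computed with 61-node Gauss–Legendre quadrature on
  the probit-transformed interval; the response probability
  $P(\delta_{winner} > \delta_{loser})$ has a closed form, and the top
  category takes the difference between it and the other cells, so each
  condition normalizes exactly and cell errors stay near $10^{-9}$.
* The 2D Bayesian posterior is strictly increasing in $\delta_{id+}$ for
  fixed $\delta_{id-}$ (the derivative of its logit is a positive weighted
  mean of SOAs divided by $s^2$), so each criterion's level set is a
  function $g_j(\delta_{id-})$, inverted by vectorized bisection; the cell
  probability becomes a single smooth 1D integral. This replaces a tensor
  quadrature over an indicator, whose $O(1/n)$ error would swamp the
  simulator cross-validation.
* Log-space guards: the posterior uses log-sum-exp; the likelihood floors
  cell probabilities at $10^{-10}$ so structural zeros meeting stray counts
  cannot produce infinite deviance.

## Rating criteria and their geometry

Each response has its own set of four strictly increasing criteria on the
report axis. For the SDT-axis families the mapping for $R_{id} = -1$ is
mirrored — more negative $\delta_v$ means higher rating — matching the SDT
rating tradition; `theta_v_minus` is therefore stored strictly decreasing.
For RCE the rating tracks the winning channel's positively oriented
evidence, so both sets are increasing on their own axes. Criteria are *not*
constrained to bracket $\theta_{id}$: in the noisy families $\delta_v$ can
cross the identification criterion, and in the pure SDT family cells on the
wrong side are structurally zero, which the fit handles through the
probability floor. Ratings exactly on a partition edge go to the upper bin
(half-open bins, closed top bin) — the data source does not state a
convention, so this deterministic one is ours.

## Fitting

Models are fitted per participant to the (identity × SOA × response ×
category) count table by maximum likelihood. A coarse grid over documented
ranges — sensitivity profiles derived from observed accuracy plus flat
profiles $\{0.05, 1, 2, 4\}$, $\theta_{id} \in \{-0.5, 0, 0.5\}$,
$\sigma_v \in \{0.25, 1, 4\}$, $w \in \{0.25, 0.5, 0.75\}$, $a, b \in
\{0.5, 1, 2\}$, shared $\rho \in \{0.3, 0.7\}$, $s$ scale-matched to the SOA
range, $\lambda \in \{0.01, 0.05\}$, criteria seeded from probit quantiles
of the observed category frequencies — is evaluated; the five best grid
points seed Nelder–Mead simplex runs, each restarted four times from its
incumbent. The simplex operates in an unconstrained parameterization (log
for positive parameters, logit for unit-interval parameters, base plus
log-increments for ordered criteria), so every visited point is valid. The
returned negative log-likelihood never exceeds the best grid value, and the
whole procedure is deterministic. Grid ranges, tolerances, and the reading
of "restarted four times" (relaunch from the incumbent) are documented
defaults — the source procedure does not print them.

AICc uses the participant's trial count:
$\mathrm{AICc} = 2\,\mathrm{negLL} + 2k + 2k(k+1)/(n-k-1)$;
$\mathrm{BIC} = 2\,\mathrm{negLL} + k \ln n$.

## Inference

Cohort-level comparisons take per-participant AICc or BIC differences and
test them with the JZS Bayes factor for a one-sample design: a Cauchy prior
(scale 1) on the standardized effect size, computed by integrating the
noncentral-t likelihood against the prior (the test suite checks it against
the classic g-integral form to 0.1%). Posterior draws of the standardized
effect come from a fine-grid inverse-CDF sampler and are summarized by the
shortest-interval (sorted-window) 95% HDI. The prior is two-sided; a
one-sided variant is deliberately not offered because the original analysis
does not state sidedness. Information-criterion differences are binned into
the conventional bands 0–2, 2–4, 4–7, 7–10, >10 (half-open, lower-inclusive,
sign giving direction), and Bayes factors labelled on the 1/3/10/30/100
ladder.

## Synthetic data: what it emulates and what it does not

The generator emulates the two masked-orientation experiments: 5 SOAs (8.3,
16.7, 33.3, 66.7, 133.3 ms), 110 trials per SOA (preset `exp1`, 11 blocks ×
50 trials) or 81 (preset `exp2`, 9 blocks × 45), identities balanced within
SOA (the odd trial of the 81 is assigned pseudorandomly, since the real task
randomized orientation per trial), and continuous ratings emitted uniformly
within the drawn category's partition so that discretization inverts
exactly. Default parameter ranges are fixed once to produce realistic
cohorts — sensitivity rising from ~0 (chance at 8.3 ms) to ~3.2–4.8
(ceiling at 133.3 ms), $\sigma_v \in [0.5, 1.5]$, $w \in [0.2, 0.7]$,
criteria spread so all five categories are populated. The generator does not
model reaction times, block or order effects, learning, or criterion drift;
a green test therefore establishes internal consistency of the pipeline
under the models' own assumptions, not fidelity to any particular real
data set.

For joint visibility+confidence simulation the WEV report variable is
computed twice from one identification sample, with separate weights
$w_{vis}$ and $w_{conf}$ and either shared or independent report noise; the
source analysis is silent on whether the noise was shared, so both modes are
provided. With $w_{vis} > w_{conf}$ the simulation reproduces the
characteristic asymmetry that confidence above 20% of the scale given low
visibility is more frequent than the reverse.

## Model recovery

The recovery bootstrap resamples a pool of generative parameter sets with
replacement, simulates each pseudo-participant at design scale, fits the
generative model and a competitor, and classifies the cohort by the paired
Bayes factor (threshold 3 for directed evidence; a second tally uses 10).
Because fitted parameters of real observers are not available, the shipped
default pool is synthetic: 8 draws from the default ranges. The pool size
and the 50-simulation acceptance run are scaled down from the original
500-simulation, 31-participant bootstrap to fit a desk-scale compute budget;
per-fit optimizer settings for the bootstrap are likewise reduced (one grid
start, one restart), which if anything handicaps the generative model and
makes the check conservative. Whether the original procedure matched each
pseudo-participant's trial count to the resampled participant is unstated;
the nominal design count is used.

## Known limitations

* Likelihoods operate on discretized categories only; there is no
  continuous-rating likelihood.
* No reaction-time modelling and no sequential-sampling variants — the
  model set is deliberately static.
* The 2D Bayesian likelihood assumes the criterion ordering of the 10
  options along the posterior axis; observers with non-monotone option
  orderings are outside the family as parameterized (this reconciles the
  criteria inventory with the printed 11-parameter count).
* Recovery of $w$ at single-experiment scale (550 trials) has a median
  absolute error slightly above 0.1 under the default generator ranges —
  the recovery test computes this median and asserts a 0.10 bound, which
  the maximum-likelihood estimate does not quite meet (the fitted deviance
  beats the generating parameters, so this is sampling dispersion of the
  MLE, not an optimization failure; at ten times the trial count $w$ is
  recovered to about ±0.01). Per-participant point estimates of $w$ should
  be interpreted with that uncertainty in mind.
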