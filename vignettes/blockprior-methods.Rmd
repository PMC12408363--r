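---
title: "Models and methods in blockprior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in blockprior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blockprior)
```

blockprior studies how a subject can estimate a block-structured stimulus
prior from trial history, and how such a subjective prior can be read out
from trial-wise neural activity with honest significance guarantees. This
vignette lays out the generative models, the estimation machinery, the
numerical choices, and what the synthetic-data experiments can and cannot
establish.

## The task generative model

Each session opens with `n_unbiased = 90` trials in which the stimulus side
is equiprobable. Thereafter the probability that the stimulus appears on the
right alternates between 0.2 and 0.8 in *blocks*. Block lengths are drawn
from an exponential distribution with scale `tau_block = 60` trials,
truncated to \[20, 100\]; the expected completed block length is therefore
51.15 trials (direct summation over the support). Within a block the
stimulus falls on the favoured side with probability `gamma = 0.8`, and the
signed contrast is the drawn side times a magnitude from
\{0, 0.0625, 0.125, 0.25, 1\}: zero contrast with probability 1/9, the rest
uniform. A zero-contrast trial still has a drawn (invisible) side and is
rewarded accordingly, which makes those trials the purest probe of prior
use. The default session length is 555 trials, the cohort-average length of
the sessions these analyses are designed for; reaction times in synthetic
sessions are log-normal (median 0.35 s) so the \[0.08, 2\] s inclusion
filters have realistic work to do.

Pseudosessions are fresh draws from this generative law matched to a
session's length. They are the null instrument used throughout: a target
rebuilt on a pseudosession has the same temporal statistics as the real
target but is independent of the recorded activity.

## Behavioural agents

All agents share a two-stage trial model. Across trials they maintain a
prior probability `p` that the stimulus will appear on the right:

* the **Bayes-optimal** (ideal observer) prior is exact forward filtering
  over the hidden block state (side, age). The hazard of a block ending at
  age `a` is `pmf(a) / P(L >= a)` with a forced switch at age 100; the prior
  for trial `t` conditions on sides `1..t-1` only, and the lead-in returns
  exactly 0.5. The filter is validated against brute-force enumeration of
  all block segmentations on small configurations (agreement to 1e-10).
* the **action kernel** and **stimulus kernel** maintain
  `pi_t = (1 - alpha) pi_{t-1} + alpha [event_{t-1} = right]` over the
  subject's own past choices or the past stimulus sides; missed trials skip
  the update. The weight of the event `k` trials back is
  `alpha (1 - alpha)^(k-1)`.
* the **true-block** agent reads the experimenter's block probability
  directly; with a greedy policy it is the omniscient upper bound.

Within a trial the agent perceives the contrast corrupted by Gaussian noise
(`sigma_c`), forms a posterior over sides by Bayes' rule with the percept
attributed to the trial's contrast magnitude on either side, and maps the
posterior to a choice by probability matching (sampling) or greedily, with
additive left/right lapses. Attributing the percept to the trial's own
magnitude makes the zero-contrast likelihood exactly flat, so at zero
contrast the choice probability equals the prior — the property the
zero-contrast analyses assume. The within-trial rule is an intentional,
compact approximation: one scalar `sigma_c`, two lapses, probability
matching by default. Sensory noise is marginalised by 61-point
Gauss-Hermite quadrature (cross-checked against Monte-Carlo to ~1e-3 with
2e5 draws).

## Fitting and comparing agents

Agent parameters are sampled by adaptive Metropolis-Hastings: four
Gaussian random-walk chains in a box (uniform priors: `alpha` in (0, 1\],
`sigma_c` in (0.01, 2\], lapses in \[0, 0.45\]), proposal covariance adapted
from the chain history during the first half of the run and frozen
afterwards so detailed balance holds for the kept samples, early stopping
(from step 1000) once every Gelman-Rubin statistic drops below 1.1 (the
diagnostic's conventional cut-off; burn-in is the first half). Held-out
evidence is the log of the *mean* held-out likelihood across posterior
samples — a log-sum-exp, never a mean of logs. Cohort-level comparison uses
the random-effects Dirichlet scheme with unit prior concentration; expected
model frequencies come from the variational posterior and exceedance
probabilities from 1e5 Dirichlet draws. Subjects need at least two sessions
for the leave-one-session-out evidence; singletons are excluded.

For leave-one-session-out cohorts the package runs the chains for 1000
steps (the point at which early stopping is first permitted) and thins the
kept samples to at most 500 for the held-out marginal; with four chains
this leaves 2000 kept draws per fit, and the recovery experiments below
show it resolves the model identities and learning rates at the stated
tolerances.

## Behavioural statistics

Reversal curves align zero-contrast performance on lags -5..+20 around
block switches (lag 0 is the first trial under the new block) and are
fitted with `p(t) = (B + (A - B) exp(-t / tau)) [t >= 0] + B [t < 0]`. The
asymptote `B` is estimated from the pre-reversal window, where the model
states the curve equals `B` exactly; `A` and `tau` then come from
count-weighted least squares on the post-reversal lags with a deterministic
multi-start grid. Anchoring `B` pre-reversal is a deliberate numerical
choice: a jointly fitted asymptote is dragged upward by late lags, which
are contaminated by the next reversal (blocks can be as short as 20
trials), and by the hazard-induced dip just before a switch, and the decay
constant then absorbs the mismatch. Cohort-level decay constants are
jackknifed by leaving out one mouse at a time; the replicate median is the
headline number and the usual jackknife variance formula gives its error.

The post-outcome asymmetry contrasts zero-contrast accuracy after a correct
versus an incorrect previous trial, under filters that isolate the last
outcome: block-conformant stimuli at `t`, `t-1`, `t-2`, a correct choice at
`t-2`, and at least ten trials since the block started. Agents integrating
stimulus sides are insensitive to their own errors and show no asymmetry;
agents integrating their own actions are self-confirmatory and are worse
after an error — the behavioural fingerprint that separates the model
classes.

## Decoding and the pseudosession null

The decoders are linear with L1 or L2 penalties (glmnet), wrapped in nested
cross-validation: interleaved random outer folds (5 for spike counts, 50
for widefield), an inner grid search for the penalty weight (5-fold, or
leave-one-out for widefield), held-out predictions assembled over the outer
folds, ten repetitions under different fold randomisations, and the median
pooled-prediction R-squared as the score. Pooled (rather than
per-fold-averaged) R-squared is used because small outer folds make
per-fold variance explode; the ten-run median then absorbs fold-assignment
luck. The per-modality penalty grids are fixed (spike counts 1e-5..1e-1,
widefield 1e-5..1e-2, behavioural covariates 1e-4..1e2, eye position
1e-4..1e4, contrast decoders 1e-5..1 and 1e-5..1e-2); a warning is raised
when the selected weight sits at a grid edge.

Significance never comes from the decoding score alone. Slow drift —
modelled in the synthetic generators as a per-unit random walk — correlates
with the block structure often enough to produce spuriously high
cross-validated scores. The pseudosession null decodes `M` targets rebuilt
on resampled sessions with the identical pipeline; the p-value is the
add-one-smoothed rank of the actual score, and the effect size is the
corrected R-squared (actual minus median null). Note the corrected score
can exceed the raw score when the median null is negative; that is a
property of the definition, not an error. Region-level evidence combines
session p-values by Fisher's method, and maps are thresholded by
Benjamini-Hochberg at a 1% false-discovery rate. Decoding weights are
declared significant outside the 2.5-97.5 percentile band of their
pseudo-weights, and the sessions-needed analysis subsamples session
p-values (1000 draws per subset size) to ask how many recordings a region
needs before its combined p drops below 0.05.

Action-kernel targets can be decoded, but the package follows the
principled refusal to attach pseudosession significance to them: an exact
null would require generating action sequences with the subject's true
statistics, and no perfect behavioural model is available. Where a
behavioural null is unavoidable (choice-coupling slopes,
orthogonalization), the fitted action-kernel model simulated on
pseudosessions is used and labelled as the approximation it is.

## Post-stimulus prior: neurometric curves

To separate prior from stimulus after stimulus onset, a linear decoder is
trained on the signed contrast and its held-out output is summarised as the
proportion of trials decoded rightward per contrast, split by whether the
prior is below or above 0.5. Both proportions are fitted jointly with erf
psychometric functions, `f(c) = gamma + (1 - gamma - lambda)
(erf((c - mu)/sigma) + 1)/2`, sharing the lapses and slope with only the
bias `mu` free per condition (binomial maximum likelihood; bounds: lapses
in \[0, 0.3\], `sigma` in (0.01, 2\], `mu` in \[-0.5, 0.5\]; ten random
restarts). The shift `f_high(0) - f_low(0)` measures prior encoding beyond
the stimulus; its null distribution again comes from pseudosessions. The
shared-parameter assumption is itself testable: `bic_shared_vs_independent`
returns the BIC margin. Zero-contrast trials contribute at `c = 0` in both
conditions.

## Information flow

Bin-resolved activity (ten 50-ms bins for spike counts, nine frames for
widefield) is decoded bin-by-bin, giving a region x trial x bin tensor of
decoded priors. For a directed pair the two series are concatenated
trial-major and a bivariate vector autoregression is fitted by least
squares (order by AIC, at most 5; unit-root series are differenced first
with a flag), and the Geweke spectral decomposition assigns a causality
amplitude to each frequency; the score is the mean over the positive
frequency grid. The parametric VAR route is a deliberate substitution for
nonparametric spectral factorization: it is deterministic, fast at desk
scale, and exact for the linear-Gaussian series produced here. Ignoring
trial boundaries in the VAR is a recorded convention; the series are
stationary across boundaries under the generative model. Significance uses
the same pseudosession logic — pseudo-priors decoded from the real
activity, the full Granger pipeline per pseudo — which is what keeps the
test calibrated when two regions share a latent prior drive: the shared
drive inflates the raw score and the null equally. Loop statistics report
the fraction of significant edges participating in directed cycles of
length 3 (the length is a parameter), and Fisher's method aggregates
session graphs to region level and region pairs to coarse groups.

## History dependence and timescales

Stepwise orthogonalization regresses the decoded prior on the last action,
the residual on the second-to-last action, and so on to lag `K = 10`,
absorbing action autocorrelation; on a noiseless kernel target with
independent +/-1 events the weights follow `alpha (1 - alpha)^(k-1) / 2`
(the 1/2 from the +/-1 coding). The per-lag null simulates the fitted
action-kernel agent on pseudosessions and decodes pseudo-priors from the
real activity; the stimulus variant uses the pseudosessions' own stimuli
and needs no behavioural model.

The neural decay model assumes each unit integrates past actions:
`Q_t = (1 - alpha_n) Q_{t-1} + alpha_n zeta_n^(a)` with Poisson emission
for spike counts (separate scaling factors after right and left choices,
since rates must stay positive) or `alpha_n zeta_n a` with Gaussian
emission for widefield. `Q` starts at its stationary mean under the
empirical action frequencies — removing the transient without an extra
parameter — and missed trials skip the update. Spike-count units enter only
if their median summed count is non-zero, they average at least 0.2 spikes
per trial (the "one spike every five trials" reading), and a two-sample
Kolmogorov-Smirnov test separates their counts by prior side at p < 0.05.
Per-unit likelihoods are maximised by bounded quasi-Newton with ten
restarts (`alpha` in \[1e-3, 1\]); the session's neural learning rate is
the mean over included units, and the timescale comparison is a Pearson
correlation across sessions against the behavioural learning rate.
The closed-loop consistency of the three routes — behavioural `alpha` by
MH, neural `alpha` by decay fitting, and the orthogonalization decay — is
the package's central integration test.

## What the synthetic data do and do not show

The generators expose their ground truth, so every analysis is exercised
closed-loop: couplings, learning rates and directed interactions are
recovered at known truth, and null configurations (zero gain, zero
coupling, drift only) calibrate every significance procedure at its nominal
level. The generators are deliberately minimal: Poisson or Gaussian
emissions with log-linear or low-rank structure, random-walk drift, AR(1)
bin dynamics. They do not emulate spike-sorting artefacts, burst
statistics, haemodynamic blur, inter-area conduction delays beyond one bin,
or non-stationary behaviour within a session. Passing the suite therefore
certifies the statistical machinery — not that real recordings satisfy the
generators' assumptions.

## Problem sizes and determinism

The simulation experiments use a 139-mouse cohort with three 555-trial
sessions per mouse for the behavioural summaries; 200 sessions for the
prior-contrast correlation; 500 exchangeable pseudo-targets for decoder
calibration; 30 subjects with two 300-trial sessions for the
model-recovery cohort; and pseudo counts of 15-60 in the significance unit
tests against 200-1000 in production settings (`M` is always an explicit
argument). These sizes were chosen so each estimate's Monte-Carlo error is
comfortably inside the tolerance being asserted. Every generator and
sampler takes an explicit seed and the whole pipeline is reproducible
bit-for-bit given one.
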