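---
title: "Models and methods: confidence in detection versus discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: confidence in detection versus discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(metadetect)
```

## The problem

Judging whether a grating is present in noise (detection, yes/no) is
computationally different from judging its tilt (discrimination,
clockwise/anticlockwise): perceptual evidence can support the presence of a
target but never directly its absence. Confidence in "no" responses must
therefore rest on something other than the strength of the percept -
plausibly on higher-order quantities such as beliefs about one's own
attentional state or about the current stimulus statistics. This package
implements three generative observer models that formalise competing
accounts of how confidence is computed in the two tasks, a simulator of the
behavioural experiment that would be used to compare them, the standard
metacognition metrics, and the two-step polynomial profile analysis used to
characterise how a signal (behavioural or regional) varies across the
six-point confidence scale. Everything runs on synthetic data from the
included generators.

## The signal detection kernel

Evidence is a scalar sample $x$. Discrimination is equal-variance SDT: the
two classes are $N(\mp\mu, \sigma)$ and the log likelihood ratio
$\mathrm{LLR}(x) = \log p(x\,|\,\mathrm{cw}) / p(x\,|\,\mathrm{acw})$ is
affine in $x$. Detection is unequal-variance SDT: noise is $N(0, 1)$ and
signal $N(\mu_s, \sigma_s)$ with $\sigma_s \ge 1$, making the LLR quadratic
in $x$ with positive curvature. Defaults are $\mu_s = 1.5$,
$\sigma_s = 1.5$ for detection and half-separation $0.75$ for
discrimination, giving matched accuracy in the low 70% range at the default
balanced criterion (the criterion solving $P(\text{upper response}) = 0.5$
under equal base rates, reflecting the near-unbiased responding the task
design targets). The $\sigma_s/\sigma_n$ ratio of 1.5 is a conventional
unequal-variance value; it is exposed everywhere and the tests probe a grid
around it.

Confidence for the static observer is the binned distance $|x - c|$ from
the criterion: five thresholds equally spaced between 0 and the 99th
percentile of that distance under the generative mixture (computed
analytically by root-finding on the mixture CDF), so a simulated observer
uses the whole scale. Binning is deterministic, exhaustive and exclusive.

A discretisation caveat that matters for interpreting polynomial fits:
even when the underlying quantity is exactly affine in $|x - c|$ (the
discrimination |LLR|), cell means over equally spaced distance bins are not
exactly affine in the bin index, because within-bin distributions are
skewed and the top bin is open. The residual quadratic this induces is a
few percent of the linear term; "essentially linear" claims in the tests
are therefore phrased relative to the linear term and to the
unequal-variance quadratic, not as exact zeros.

## The three observer models

All three models are summarised the same way: simulate many trials, assign
each trial a response and a confidence level, and average a model-specific
latent quantity per (task, response, confidence) cell - the object a
regional signal tracking that quantity would show. `curve_poly_fit()`
summarises each response's curve with an intercept + linear + quadratic
polynomial on centred confidence codes, with coefficient standard errors
propagated from the per-cell Monte-Carlo standard errors.

For the dynamic and attention models confidence is proportional to the
LLR of the chosen response, binned response-conditionally: thresholds run
from 0 to the response-specific 99th percentile of $|\mathrm{LLR}|$.
A global rule would leave no-responses stuck in the lower half of the
scale (their $|\mathrm{LLR}|$ is bounded by the depth of the LLR trough,
while yes-responses are unbounded), contradicting the empirical fact that
participants use the full scale after both responses; the
response-conditional rule is the discrete analogue of that behaviour.

### Static unequal-variance SDT

The latent quantity is $|\mathrm{LLR}(x)|$ itself. Because the
unequal-variance LLR is quadratic in $x$, detection yes-responses show a
pronounced positive quadratic confidence profile, while equal-variance
discrimination gives (essentially) linear profiles. Setting
$\sigma_s = \sigma_n$ removes the detection quadratic, and it grows
monotonically with the $\sigma_s/\sigma_n$ ratio - both are pinned by
tests.

### Dynamic criterion

The observer does not know the stimulus statistics; it maintains
normal-gamma beliefs and re-places its criterion where the
posterior-predictive LLR crosses zero, with no feedback. For detection the
beliefs cover the signal mean $m$ (pseudo-count $\kappa$) and the shared
sensory precision $\tau$ (Gamma$(\alpha, \beta)$), with the noise mean and
the sd ratio known. Each sample updates the beliefs with
responsibility weighting - the posterior probability $r$ that the sample
came from the signal class weights its contribution to the signal-mean and
to the two residual terms of the precision update (see
`dynamic_belief_update()` for the closed form). Pseudo-counts are
exponentially discounted (forgetting $\lambda$) before every update, so
learning never freezes in a stationary environment.

Defaults are $m = 1.5$, $\kappa = 1.5$, $\alpha = \beta = 1.2$,
$\lambda = 0.8$: a fast learner whose effective memory is roughly five
trials. The learning rate is not innocent. A slow learner still shows the
quadratic confidence effect, but it does *not* shift its criterion more on
switch than on stay trials: when the criterion barely moves, response
flips between consecutive same-stimulus trials are caused by
evidence-sampling noise, which selects ambiguous, small-update trials into
the switch set. Only when criterion motion is itself a substantial cause
of switching - a fast learner - do switch trials carry larger shifts, as
the model is meant to predict. The switch/stay contrast
(`dynamic_switch_stay_contrast()`) attributes to each trial the shift
produced by its own update: a switched response to an unchanged stimulus
category means consecutive samples disagreed, which is surprising under
the current beliefs and drives a larger update.

Discrimination is parameterised symmetrically: beliefs cover the
half-separation and the shared precision, and the zero-LLR criterion is
the class midpoint *whatever the beliefs are*, so the criterion never
moves and the $|\Delta c|$ profile is exactly flat. This implements the
computational argument that a symmetric discrimination problem requires no
criterion adaptation - only detection couples decision policy to beliefs
about both expected signal strength and precision. The model's signature
is therefore a positive quadratic $|\Delta c|$ confidence profile in
detection and an identically zero profile in discrimination.

### Attention monitoring

A binary latent state (on task with prior $p_{on} = 0.75$) is resampled
every trial and scales the precision of both class distributions:
$\tau_{on} = 1$, $\tau_{off} = 0.4$. Detection additionally keeps the
unequal-variance ratio (1.25) in both states. The observer computes the
joint posterior over (class, attention state), responds with the
maximum-posterior class, rates confidence on the attention-marginal LLR
(a switch to attention-conditional confidence is provided), and the latent
quantity plotted is the posterior probability of having been on task.

At these defaults all four responses show a strongly resolved quadratic
confidence profile plus a linear yes/no interaction within detection, and
task accuracy lands near the 70% staircase target (the attention mixture
itself produces the lapses). The quadratic is an inverted U: the
attention belief peaks at moderate confidence and falls toward both
extremes, because extreme samples - very signal-like or very noise-like
beyond what the sharp on-task distributions produce - are best explained
by the wide off-task distributions. The model's distinguishing
predictions, as implemented, are the *presence* of curvature for every
response including discrimination (where the static and dynamic models
predict none) and the yes/no asymmetry; the sign of the latent-variable
curvature is a parameterisation-dependent property and is not asserted.
The parameters were fixed once, from a scan documented in the development
notes, as the illustrative regime in which all of the model's qualitative
predictions are simultaneously resolvable; they are all exposed as
arguments.

## The behavioural task simulator

One subject's session is 5 runs x (one detection + one discrimination
block, random order) x 40 trials, balanced stimulus categories within
block, response mapping counterbalanced across each task's blocks, SNR
fixed within block. Difficulty control follows three rules:

* calibration staircase: every 10 trials, window accuracy < 60% divides
  SNR by 0.9 (easier), > 80% multiplies by 0.9 (harder); boundary
  accuracies leave it unchanged. With $d' = k \cdot \mathrm{SNR}$ this
  targets ~70% accuracy.
* block rule: accuracy <= 52.5% / >= 85% in the previous block of the same
  task divides/multiplies that task's SNR by 0.9 (inclusive boundaries).
* run rule: a between-task accuracy difference strictly greater than
  16.25 percentage points moves both SNRs by $\sqrt{0.9}$ toward balance
  (a small numerical guard keeps the exact boundary inert in floating
  point). When both the block and run rules could fire, the block rule is
  applied first by default; the order is a design option.

The observer's sensitivity follows $d' = k\,\mathrm{SNR}$ with $k = 3$ and
starting SNR 0.5 - the simplest monotone psychometric link, since no
specific form is prescribed; the detection variance ratio is 1.5 as in the
static model. Lapses are i.i.d. misses (response, confidence, correctness
all missing), default rate 0 (the analysis scripts use 2% for realism).
The session bonus is
$\pounds\,(\vec{a} \cdot \vec{c})/200$ with $\vec{a} \in \{\pm 1\}$ for
correct/incorrect and $\vec{c}$ the 1-6 confidence vector; missed trials
contribute nothing and no rounding is applied internally.

`generate_roi_profiles()` is the group-level synthetic stand-in for
regional activation estimates per confidence level: each subject x
response profile is $b_0 + b_1\,\mathrm{code} + b_2\,\mathrm{code}^2$ plus
i.i.d. Gaussian noise on centred codes. The default generative pattern is
the one the analysis is designed to detect - $b_2 = 0.5$ for both
detection responses and 0 for discrimination, with the linear term more
negative for no (-0.4) than yes (-0.2) responses - with noise sd 0.2 and
35 subjects, a moderate effect size regime in which recovery is reliable
but not trivial.

## Metacognition metrics

Response-conditional type-2 ROC curves plot the cumulative confidence
distribution of correct against incorrect trials, sweeping the threshold
from the highest level down (the area is direction-invariant; the point
ordering follows the high-to-low convention). AUROC2 is the trapezoidal
area over the 7 points: exactly 0.5 for identical distributions, exactly
1 for perfect separation. Degenerate sides (no correct or no incorrect
trials) raise errors naming the side. Missed trials are removed before any
metric is computed.

`meta_dprime()` implements the standard maximum-likelihood meta-d' model:
an equal-variance SDT observer with sensitivity meta-d', the type-1
criterion pinned at its empirical *relative* position $c' = c/d'$, and
response-specific type-2 criteria (parameterised as ordered offsets via
log transforms), fitted by BFGS on the response-conditional multinomial
likelihood. Zero cells are handled by the conventional $1/(2K)$ padding
(toggleable). Metacognitive efficiency is meta-d'/d'. The tests check the
fit against a brute-force grid search on a reduced-scale fixture, recovery
of the generative d' for an ideal observer, and collapse of the m-ratio
to zero when ratings are shuffled.

The exclusion rules mirror the pre-specified data-quality criteria at
subject level (missing > 20%, task accuracy < 60%, same response > 75% in
a task, same confidence level > 80% globally or per response, motion flags
in more than 2 runs) and run level (missing > 20%, accuracy < 60%,
response bias > 80%, same confidence level > 95%, motion). All
inequalities are strict except the accuracy rule, which excludes only
accuracy strictly below 60%; boundary behaviour is pinned by unit tests.
Motion is not computable from behaviour and enters as per-run flags.

## Two-step profile analysis

Step one fits each (subject, response) six-level profile by OLS on
$[1, \mathrm{code}, \mathrm{code}^2]$ with centred codes
($\mathrm{conf} - 3.5$), which decorrelates the linear and quadratic terms
on the full scale; a raw-code option exists, as does optional weighting by
per-level trial counts (default unweighted - the two-step approach is
chosen precisely for its indifference to the confidence distributions).
Masked levels are dropped; fewer than three available levels skips the
profile with a warning rather than silently shrinking group counts. Step
two turns a weight vector over (task, response) cells into one value per
subject and tests it against zero with a one-sample t-test
($d = t/\sqrt{n}$), two-sided and uncorrected across the contrast family
(a Bonferroni adjustment can be applied downstream if wanted). The
standard battery covers the overall quadratic effect, quadratic and linear
task differences, the within-detection linear yes-vs-no difference, and
per-task simple effects; missing cells yield named skipped rows.

The JZS Bayes factor for a one-sample t-test uses the
Cauchy(scale 1) effect-size prior, computed by adaptive quadrature of the
inverse-gamma mixture representation. The implementation is validated two
ways: against an independent fixed-grid quadrature at two resolutions
(1e-4 relative agreement), and against five published (t, BF01) pairs at
n = 35 under the same prior, which it reproduces to the printed precision.

```{r}
jzs_bayes_factor(0.30, n = 35)   # published as 7.29
jzs_bayes_factor(0.90, n = 35)   # published as 5.15
```

## Numerical choices and degenerate inputs

* Criterion placement and confidence thresholds come from `uniroot` on
  analytic CDFs (tolerances 1e-10 to 1e-12); no simulation is involved in
  rule construction.
* The dynamic observer aborts with a diagnostic if its precision belief
  collapses or no criterion solves the posterior-predictive LLR = 0.
* Equal on/off-task precisions make the attention state unidentifiable: a
  warning, not an error, and curves are still produced. A prior
  $p_{on} = 1$ degenerates to constant posterior 1.
* Rates of exactly 0 or 1 are rejected by `sensitivity_from_rates()`;
  count-level inputs take the +0.5 log-linear correction.
* All simulators take explicit seeds; the pipeline derives per-stage and
  per-subject seeds from one global seed via `substream_seed()`, so one
  subject's data do not depend on how many other subjects are simulated.

## Problem sizes

The analysis scripts simulate 35 subjects x 400 trials, summarise the
three models at 5x10^4 trials per task, and run the group battery at 35
subjects. The test suite uses 10^5-trial model runs for the qualitative
curve signatures, 50 x 2000 trials for staircase targeting, 20 recovery
fits at 4000 trials for meta-d', and 1000 null simulations for the type-I
error of the quadratic task contrast. These sizes resolve every asserted
effect at three Monte-Carlo standard errors or better.

## What the synthetic data do and do not show

The generators reproduce the experiment's design arithmetic, difficulty
control, response statistics, confidence usage and the group-level
coefficient patterns. They do not emulate serial dependencies in real
behaviour (beyond the dynamic observer's own), response times,
hemodynamics, spatial structure, or between-subject heterogeneity in
generative parameters (profile noise is i.i.d. within subject). Passing
tests therefore establish that the estimators and inference machinery
recover what the models put in at realistic sizes - not that the models
fit any particular dataset. Model comparison here is qualitative, as in
the source analyses: formal model fitting to empirical data is out of
scope.
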