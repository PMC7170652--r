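# metadetect

Generative models and analysis machinery for studying **metacognition in
visual detection versus discrimination**. Deciding *whether* a faint grating
is present (detection, yes/no) is computationally unlike deciding *which way*
it tilts (discrimination, clockwise/anticlockwise): evidence can support the
presence of a target but never directly its absence, so confidence in "no"
responses must draw on something beyond the strength of the percept. This
package is for computational cognitive scientists and psychophysicists who
want to simulate, compare and power-check the competing accounts of that
asymmetry without collecting data: every analysis runs on synthetic data from
the included generators.

## What's inside

**Three observer models**, each summarised as a response-by-confidence
prediction curve of its latent quantity:

- **Static unequal-variance SDT** — noise `N(0, 1)`, signal `N(μs, σs)` with
  `σs ≥ 1`; the evidence-to-LLR map `LLR(x) = log p(x|S2)/p(x|S1)` is affine
  for equal variances (discrimination) and quadratic for unequal variances
  (detection), so mean `|LLR|` per confidence level shows a pronounced
  positive quadratic effect for detection-yes responses only.
- **Dynamic criterion** — normal–gamma beliefs about the signal mean and the
  sensory precision, responsibility-weighted conjugate updates with
  exponential forgetting, criterion re-placed each trial where the
  posterior-predictive LLR crosses zero. Predicts a quadratic confidence
  profile of `|Δc|` in detection and an exactly flat one in discrimination
  (the symmetric problem needs no criterion adaptation), plus larger shifts
  on response-switch than response-repeat trials.
- **Attention monitoring** — a per-trial binary attention state scales
  sensory precision (`τ_on > τ_off`); the observer infers (class, attention)
  jointly and the plotted quantity is the posterior `P(onTask)`. Predicts
  curvature of the confidence profile for *all four* responses — including
  discrimination, where the other models predict none — and a yes/no
  interaction within detection.

**A behavioural task simulator**: 5 runs × two 40-trial blocks per subject,
balanced stimuli, counterbalanced response mappings, the three SNR control
rules (10-trial 60%/80% calibration staircase with factor 0.9; between-block
52.5%/85% rule; between-run 16.25% balancing rule with factor √0.9), an
i.i.d. lapse process, the confidence-weighted accuracy bonus
`£(a⃗·c⃗)/200`, and the study-style subject- and run-level exclusion rules.

**Metacognition metrics**: response-conditional type-2 ROC curves and their
area (AUROC2), and maximum-likelihood **meta-d′** with metacognitive
efficiency meta-d′/d′.

**Two-step confidence-profile analysis**: per-subject OLS of six-level
profiles on centred linear + quadratic confidence codes, group-level
one-sample t-tests on coefficient contrasts (Cohen's `d = t/√n`), the
standard contrast battery, and **JZS Bayes factors** (Cauchy scale-1 prior)
by numerical integration.

## Worked example

The repository is organised as an analysis workflow; the numbered scripts
under `analysis/` drive the package end to end and write tables under
`results/analysis/`:

```sh
Rscript analysis/01_simulate_behaviour.R
Rscript analysis/02_metacognition.R
Rscript analysis/03_model_predictions.R
Rscript analysis/04_group_inference.R
```

Stage 1 simulates 35 subjects (static SDT observer, d′ linear in SNR) and
applies the exclusion rules:

```
subjects simulated        : 35 (35 included)
accuracy detection        : 0.724
accuracy discrimination   : 0.774
P(yes) in detection       : 0.496
mean session bonus        : £2.99
```

Accuracy sits in the staircase's 60–80% band near the 70% target, detection
responding is unbiased, and the bonus is what the schedule pays a ~75%-correct
observer. Stage 2 computes metacognition metrics per subject:

```
mean AUROC2 yes / no      : 0.774 / 0.542
yes - no t(34) = 19.20, p = 8e-20, BF01 = 0.00
mean m-ratio detection    : 0.832
mean m-ratio discrimination: 0.955
```

Under the unequal-variance generative model, confidence after "yes" is far
more diagnostic of accuracy than after "no" — the characteristic
metacognitive asymmetry for judgments of absence — and meta-d′/d′ is
correspondingly lower for detection. Stage 3 prints each model's fitted
quadratic confidence coefficient per response (positive for detection under
the static and dynamic models, zero for their discrimination curves,
nonzero everywhere for attention monitoring) and the dynamic model's
switch/stay contrast (`0.0880 vs 0.0822`). Stage 4 runs the group battery on
synthetic regional profiles; with the default generative pattern the
quadratic task difference is detected (`t(34) = +108.85`) while the
discrimination quadratic stays null (`t(34) = +0.79, BF01 = 5.63`).

## Layout

- `R/` — the package: SDT kernel, observer models, task simulator,
  metacognition metrics, profile analysis, IO/pipeline.
- `analysis/` — numbered narrative drivers (the workflow above).
- `scripts/acceptance.R` — headline-quantity reproduction.
- `tests/testthat/` — unit, property and acceptance tests (oracle-based:
  quadrature, grid search, closed forms).
- `vignettes/detection-metacognition.Rmd` — the models, their assumptions,
  parameter defaults and numerical choices, in detail.
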