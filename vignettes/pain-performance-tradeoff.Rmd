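---
title: "Models and methods: the pain-performance trade-off pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: the pain-performance trade-off pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painbalance)
```

painbalance studies a simple but consequential idea: when a person performs a
demanding working-memory task while receiving thermal stimulation, attention
is a limited resource shared between the task and the pain. On trials where
more resources go to the task, performance is higher and reported sensation
lower; on trials where pain captures attention, sensation rises and
performance drops. The package provides every computational stage needed to
study that trade-off end to end on simulated data: individualized
psychophysical calibration, task difficulty calibration, trial scoring, two
multilevel mediation models with bootstrap inference, and trait moderation.

This vignette documents the models, the assumptions behind them, the default
parameter values and why they were chosen, and the limits of what the
simulation-based tests can show.

## The combined sensation scale

Warmth (0-100) and pain intensity (0-100) are reported on separate scales
but analysed on a single 0-200 continuum: warmth maps to 0-100 and pain
intensity to 100-200, so the warmth/pain boundary — pain intensity zero —
sits exactly at 100. Merging the scales avoids flooring effects in warm
trials and makes "crossing the pain threshold" a point on one axis.
`combine_scale()` implements the mapping and is strictly order-preserving
across the boundary.

## Thermal psychophysics

### Latent stimulus-response curve

Each subject's temperature-to-sensation mapping is a monotone power law,

$$ S(T) = g \, \max(0,\; T - T_0)^{\gamma}, $$

with offset $T_0$ (the temperature at which sensation leaves zero), gain $g$
and exponent $\gamma > 0$. This form matches the accelerating,
exponential-family curves typical of thermal psychophysics while keeping the
inverse closed-form, which matters because the individualized stimulation
temperatures are defined by inversion: the Warm temperature at combined
sensation 80, the pain threshold at 100, and the Pain temperature at 140
(pain intensity 40/100). A predicted Pain temperature above 49 °C is capped
at 49.0 — the maximal safe stimulation temperature — and flagged.

### Adaptation correction

Repeated stimulation changes ratings independently of temperature: a
site-nonspecific sensitization that grows with the overall presentation
index, and a site-specific habituation that decays with the per-site repeat
count. `correct_ratings()` fits, jointly with the curve, the additive model

$$ r_i = S(T_i) + s\left(e^{-1/\tau} - e^{-o_i/\tau}\right)
       + h\left(e^{-\delta (k_i - 1)} - 1\right) + \varepsilon_i, $$

where $o_i$ is presentation order (1-28) and $k_i$ the site repeat (1-7).
Both terms are parameterized *relative to the reference state* (first
presentation, first site visit), so the fitted curve keeps its scale and the
correction is exactly zero at the reference; corrected ratings are raw
ratings minus the fitted relative adaptation. Two numerical choices matter:

* The fit is bounded Levenberg-Marquardt (`minpack.lm`) with multiple
  starts; the curve parameters are seeded from a curve-only prefit on
  per-temperature means, which removes most local-optimum failures in the
  seven-parameter joint fit. Ties are broken by lowest residual.
* Corrected ratings are deliberately **not** clipped to [0, 200]: clipping
  would bias the subsequent curve fit at the extremes.

The split between the two adaptation components is only weakly identified
from a single 28-trial session (both are smooth in time); the correction
only ever uses their *sum*, which is well identified. The fit is estimated
per subject; whether a pooled estimate would be preferable is left open and
documented rather than guessed.

## The 2-back task engine

A 20-s trial holds `floor(20000 / (750 + interval))` items (250 ms fixation
+ 500 ms letter + blank interval), i.e. 6 letters at the slowest interval
(2583 ms) and 26 at the fastest (19 ms). Sequences use eight consonants; on
average 25% of letters after the two burn-in positions are targets (equal to
the letter two back) and 12.5% of letters are lures (equal to the one- or
three-back letter but not the two-back), which defeat familiarity-based
responding. Expected counts are fractional at most lengths; they are
resolved by stochastic rounding (floor plus a Bernoulli draw of the
fraction), which is deterministic whenever the expected count is integral
and makes the average fractions exact — deterministic rounding would bias
the target rate by up to 3 percentage points at some lengths.

### The A statistic

Performance is scored with the non-parametric signal-detection statistic
$A$: an estimate of the area under the proper ROC curve from a single (hit
rate, false-alarm rate) point, defined as the average of the areas under the
minimum-area and maximum-area proper ROC curves through that point. It is
0.5 at chance, 1.0 at perfect discrimination, finite at edge rates (unlike
$d'$, no continuity correction is needed), and distribution-free. The
implementation is the piecewise closed form; the test suite checks it to
1e-9 against an independent geometric construction (minimum area: the chord
polyline through the point; maximum area: the best clipped supporting line,
optimized over slope, with exact handling of the vertical-segment
degeneracies at $F = 0$ and $H = 1$). Below-chance points are mapped by
symmetry, $A(H,F) = 1 - A(F,H)$, and flagged. Missing responses are treated
as not-"same" (a miss on targets, no false alarm elsewhere).

### Staircase difficulty calibration

Task speed is individualized over 18 trials: starting at a 2583 ms blank
interval, the interval is decreased after two consecutive trials with
$A > 0.85$ and increased after two consecutive trials with $A < 0.75$,
clamped to [19, 2583] ms. The streak counter resets after each adjustment so
one fast pair is not counted twice. The adjustment size is not dictated by
the protocol; the default is multiplicative (×0.75 down, ×4/3 up,
configurable), chosen because the achievable range spans two orders of
magnitude and geometric steps give uniform relative resolution across it.

One property of this protocol is worth stating plainly. At typical
calibrated speeds (~580 ms) a trial holds ~15 letters, hence only 3-4
targets, so a single trial's $A$ is heavily quantized (SD ≈ 0.17) and the
mean over a run's final four trials has SD ≈ 0.09 — nearly twice the
half-width of the 0.75-0.85 band. Simulations in the test suite show that
even observers *pinned at their ideal interval* land their final-four mean
inside the band only about half the time; the staircase necessarily does a
little worse. The staircase therefore centers performance on the band (the
cross-run mean of final-trial $A$ is ≈ 0.77-0.78, and that is what the
acceptance script reports) but cannot guarantee band membership run by run;
the corresponding strict per-run check in the test suite documents this
honestly rather than passing by construction.

Simulated observers are logistic: per-letter accuracy rises from chance to
near ceiling with the blank interval, $p = 0.5 + (0.5 -
\text{lapse})\,\text{logit}^{-1}((I - m)/s)$, with midpoint $m$ drawn
log-normally around 579 ms (the typical calibrated interval), scale 150 ms
and lapse 0.02.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the statistical
conditions under which every downstream stage is validated.

* **Traits.** PCS (pain catastrophizing), STAI-T (trait anxiety) and 4-FFMQ
  (mindfulness, observing facet excluded) are drawn from a multivariate
  normal with the reference-cohort means and SDs (14.02/10.69, 39.34/10.13,
  103.22/17.20) and intercorrelations (0.43, −0.59, −0.66), then rounded and
  clipped to the printed scale ranges (0-52, 20-80, 32-160). Clipping
  attenuates the realized SDs slightly (up to ~7% for PCS, which has mass at
  0) and shifts the PCS mean up by ~3%; means remain within the tested 5%
  band.
* **Psychophysics.** Curve offsets are drawn around 41 °C, exponents
  log-normally around 1.3, and the gain is derived so the implied pain
  threshold matches a sampled threshold temperature (mean 46.2 °C, SD 1.24),
  coupling curve and covariate realistically. Calibration sessions place
  each of the 7 temperatures {40, 44, ..., 49} once on each of 4 forearm
  sites in a pseudorandom Latin-square order, add the two adaptation terms
  plus Gaussian rating noise (SD 8), and clip to [0, 200].
* **Behavioral sessions.** 36 trials (2 tasks × 2 heat levels × 9), in one
  fixed pseudorandom order shared by all subjects, as in a fixed-sequence
  session design. Per trial, a latent standard-normal attention variable $u$
  is shared between sensation and performance:
  $$ \text{sensation} = \mu_{s}(\text{cell}) + b_i
     + \sigma_s\,(w u + \sqrt{1-w^2}\,e_1), \qquad
     A = \mu_{A}(\text{cell}) + a_i
     + \sigma_A\,(\beta_i u + \sqrt{1-\beta_i^2}\,e_2), $$
  with subject random effects $b_i, a_i$, attention share $w = 0.6$ and the
  subject's coupling slope $\beta_i \le 0$. Cell means default to the
  reference four-condition means (sensation 129.85 / 116.17 / 49.09 / 37.74;
  A 0.99 / 0.84 / 0.99 / 0.86), so pain trials sit above the combined-scale
  threshold and warm trials below, the left-right control task sits at
  ceiling, and the mean task-analgesia and pain-interference measures come
  out at their implied values (13.68 rating units and 0.02 A units).
* **Coupling defaults.** The baseline coupling is $\beta = -0.11$ with
  $w = 0.6$; through the trial model above this implies a standardized
  trial-level $b$ path of about $-0.18$ in the pain-interference model
  (the magnitude reported for the real cohort). The generative magnitude of
  the coupling is not otherwise constrained, so defaults are calibrated to
  reproduce signs and orderings, not specific coefficient values.
  Moderation: each trait's latent z-score shifts the coupling by ±0.05
  (steeper with catastrophizing and anxiety, shallower with mindfulness),
  truncated at zero so the trade-off never becomes positive by default.
  Between-subject coupling noise defaults to zero so that switching
  moderation off makes every subject's slope identical — a useful exact
  null.
* **Discrete realization.** Each trial also carries integer hit /
  false-alarm counts consistent with its latent $A$ (inverted along the
  symmetric ROC diagonal and rounded against the trial's actual target and
  nontarget counts), so the scoring stage can recompute performance from
  counts; the mediation models use the latent continuous $A$ by default,
  since the count-based score adds pure quantization noise.

One cohort seed fans out deterministically into per-subject child seeds, so
any single subject is reproducible in isolation.

What the generator does *not* emulate: reaction times, response omission as
a cognitive process, pain unpleasantness as distinct from intensity, serial
dependence between trials beyond the adaptation terms, and any systematic
drift across the session. Tests passing under this generator show the
pipeline recovers the structure it assumes; they cannot certify behavior on
real data with features outside that structure.

## Multilevel mediation

A mediation model asks whether the covariance between a predictor $X$ and an
outcome $Y$ runs through a mediator $M$: $a$ is the $X \to M$ effect, $b$
the $M \to Y$ effect controlling $X$, $c$ the total effect, $c'$ the direct
effect controlling $M$, and $ab$ the indirect effect, with $c = c' + ab$ in
linear models. Two complementary models probe the trade-off from both
directions:

* **Pain interference** (2-back trials only): heat level → sensation →
  performance.
* **Task analgesia** (painful trials only): task difficulty → performance →
  sensation. Here the expected signature is *suppression*: the indirect
  effect through performance opposes the total analgesic effect, because
  the harder task lowers performance while higher performance lowers pain.

The estimator is a two-stage summary-statistics approach, fully specified:

1. Within each subject, the trial subset is filtered, the binary predictor
   is effect-coded (−0.5/+0.5, pain and 2-back positive) and standardized,
   and $M$ and $Y$ are z-scored within subject (so results are invariant to
   affine rescaling of individual rating or performance scales and to
   subject ordering). Per-subject OLS gives $a_i, b_i, c_i, c'_i$ and
   $ab_i = a_i b_i$; the decomposition $c_i = c'_i + a_i b_i$ holds to
   machine precision because all three regressions share one trial set.
   Subjects with fewer than 4 usable trials, constant variables, or an
   $X$-collinear mediator are excluded with classed errors and logged.
2. Population estimates are unweighted means of the per-subject
   coefficients (precision weighting at the second level is deliberately
   not applied, and documented). Inference resamples *subjects* with
   replacement — 10,000 times by default — jointly across paths, and forms
   bias-corrected (BC, not BCa: no acceleration term is described for this
   design) percentile intervals. Two-sided p-values come from the
   BC-adjusted bootstrap CDF evaluated at zero, with a degenerate branch
   (p = 1 for a zero estimate) when the bootstrap distribution has no
   variance. No multiple-testing correction is applied.

Monte-Carlo checks in the suite: type-I error for the $ab$ path within
5% ± 2% under a null generator (1000 cohorts of 41 subjects, 2000
resamples), interval coverage for the mean $a$ path within 95% ± 3%
(400 replications — a size chosen for runtime; the band is unchanged), and
recovery of $a$ and $b$ within ±0.05 of their generator-implied values at
200 subjects.

### Trait moderation

Each trait is tested one at a time as a second-level moderator. The
moderator is first residualized against three session covariates
(inter-session interval, pain threshold, calibrated task interval) so
moderation cannot be explained by them, then standardized; each per-subject
path coefficient is standardized and regressed on it. The coefficient
convention is explicit because printed tables can be ambiguous about coding:
**positive $b_2$ means the $b$ path becomes more positive per SD of the
moderator**. Under this convention, catastrophizing or anxiety steepening a
negative coupling yields negative $b_2$ (and mindfulness positive $b_2$).
The $ab$ moderation regresses the per-subject product $a_i b_i$ on the
moderator — the product of separately moderated paths is not testable per
subject. Bootstrap inference reuses the subject-resampling BC scheme, with
residualization and standardization redone inside every resample.

## Descriptives and exclusions

`score_questionnaire()` scores the three instruments from item responses
with reverse-keying; reverse-keyed indices are instrument metadata shipped
as editable defaults in `inst/extdata/questionnaire_keys.csv`, not study
data. `compute_mta_mpi()` derives mean task-induced analgesia and mean
pain-induced interference per subject; `group_stats()` runs the paired
contrasts (Cohen's d as mean difference over SD of differences, matching
paired-t reporting, with an exact null branch for zero-variance
differences), the signed-rank contrast of the two tasks, and the Pearson
correlation table. `quartile_slopes()` averages the per-subject $b$ path and
regression intercept over the highest- and lowest-scoring quartile
(`round(n/4)` subjects, 10 of 41) for plotting; since variables are z-scored
within subject the mean intercept is near zero by construction, and ties at
a quartile boundary are broken deterministically by subject id and flagged.

Participant-level exclusions mirror the emulated protocol: more than 50% of
trials missing, more than 50% of painful trials not tolerated, or
session-mean 2-back performance at or below chance ($A \le 0.5$). The
default pipeline simulates 45 subjects with four planted violators and
retains 41. Planted violations use fixed 60% counts so they always clear the
thresholds.

## Reproducibility

`run_pipeline()` chains every stage from one master seed (simulation,
bootstrap streams, and per-subject randomness all derive from it), writes
each stage's table as CSV plus a JSON manifest with a configuration hash,
per-stage row counts and the exclusion log, and is byte-identical across
reruns with the same seed. `scripts/acceptance.R` recomputes the package's
self-contained headline quantities — the A statistic's anchor values, the
combined-scale threshold mapping, and the staircase calibration band
attained by 200 simulated observers — from a fresh seed. Simulation sizes
throughout the tests (cohorts of 41, 200-1000 Monte-Carlo replications,
1000-2000 bootstrap resamples in simulation loops) are the package's chosen
balance between statistical resolution and a test suite that runs in
minutes.

## Known limitations

* The adaptation model is a documented stand-in with the right qualitative
  structure (site-specific + site-nonspecific components); the original
  dynamic model's exact parameterization is not public in the source
  protocol.
* Real-cohort coefficient values are not reproducible — the underlying
  dataset is not deposited — so mediation and moderation checks target
  signs, orderings and calibration of inference, not numeric agreement.
* The two-stage estimator treats per-subject coefficients as exchangeable
  draws; with very few trials per subject the first-stage noise inflates
  second-stage variance (it is absorbed, not modeled).
* Per-trial A quantization bounds how tightly any 18-trial staircase can
  pin individual runs to the 0.75-0.85 band (see the staircase section).
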