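---
title: "From paw tracking to a locomotor decision: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From paw tracking to a locomotor decision: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(obstride)
```

# The behaviour and the analysis problem

A head-fixed mouse trots on a wheel while a thin cylindrical obstacle
approaches at wheel speed, so that in "un-head-fixed" (world) coordinates the
mouse runs toward a stationary bar it must step over. The animal detects the
obstacle with its whiskers roughly 15 mm in front of the nose and, within a
few tens of milliseconds, either *shortens* the step of the forepaw currently
in swing (placing it in front of the obstacle) or *lengthens* it (clearing
the obstacle in one large step). The choice depends on where that paw would
have landed had nothing changed — its *predicted landing distance* — together
with the state of the body.

`obstride` implements the analysis chain needed to quantify this behaviour
from markerless two-view tracking at 250 Hz, plus a synthetic session
generator with planted ground truth so that every stage can be validated
end-to-end without raw video:

1. tracking quality control and un-head-fixing (`apply_qc()`, `unheadfix()`);
2. stance detection, step segmentation, control steps, Hildebrand gait
   diagrams, trial success (`detect_stance()`, `segment_steps()`,
   `hildebrand()`, `trial_success()`);
3. per-session landing models and predicted landing distances
   (`fit_landing_model()`, `predict_landing_distance()`);
4. the logistic shorten/lengthen decision model with 15-fold
   cross-validation, class weights, forward feature selection and shuffled
   baselines (`fit_decision_glm()`, `forward_select()`,
   `shuffled_baseline()`);
5. matched-control reaction-time estimation (`reaction_latencies()`);
6. sliding-window consensus detection of the first whisker-contact frame
   (`consensus_first_contact()`).

# The synthetic session model

`generate_session()` simulates the full measurement process. Its defaults
define the study conditions used throughout the test-suite and the
acceptance analyses.

## Gait

Wheel speed follows a stride-level AR(1) process with mean 0.55 m/s. The
configuration parameter `speed_sd` (default 0.10 m/s) is defined as the SD
of *per-step* wheel speeds — the regressor of the step-length law — and the
underlying stride process is run 4.5% wider to compensate for two small
shrinkage effects: limbs whose cycles span stride boundaries average two
stride speeds, and a finite autocorrelated session under-disperses relative
to the stationary law.

Limbs follow a trot: LF+RH share touchdown phase, RF+LH are half a stride
away. Step length obeys

\[ L = a + b\,v + \varepsilon, \qquad a = -3.7\ \text{mm},\ b = 107\ \text{mm/(m/s)}, \]

with `landing_noise_sd` = 6.9 mm. Internally each touchdown receives
independent placement noise of $6.9/\sqrt 2$ mm about a body-referenced home
position, which yields the requested marginal step-length residual without
letting paw positions drift away from the body. Two consequences follow *by
construction* rather than by tuning: the in-sample mean absolute error of a
linear landing model tends to $\sigma\sqrt{2/\pi} = 5.50$ mm
(the $E|N(0,\sigma)|$ identity), and the per-step speed/step-length Pearson
correlation tends to $b\,\sigma_v / \sqrt{b^2\sigma_v^2 + \sigma^2} \approx 0.84$.

Swing trajectories use a cosine horizontal profile and a half-sine height
profile. The swing apex scales with step length times swing duration
(about 10 mm at the mean speed; faster, longer steps are lifted higher).
This choice makes the swing phase linearly decodable from the vertical paw
velocity, so that a *linear* model of the eight contact features can
reconstruct the predicted landing distance — the property that lets the
logistic decision model approach the planted rule's ceiling, as the
published models evidently did on real data.

Frame indices are 1-based throughout (the `frame` column of the tracking
table indexes rows of the per-frame arrays directly).

## Trials and the planted decision

Obstacles engage at wheel distances 0.9/2.7/4.5 m per 5.4 m lap (jittered
±100 mm), start 0.31 m (±15 mm) from the nose, and have heights drawn
uniformly on 4–10 mm; the light is on in a random half of trials. Whisker
contact occurs when the obstacle reaches `whisker_reach` = 15 mm anterior of
the nose, plus speed-dependent jitter (`contact_speed_slope` 7.4 mm/(m/s),
noise SD 1.75 mm) calibrated to a contact-position/speed correlation of
about 0.27 — the relation later exploited to impute contact times in
whisker-trimmed sessions.

On every trial with exactly one forepaw in swing at contact (with a 0.6 duty
factor the forepaws are never both in swing; both-stance trials, about 20%,
are excluded downstream), a label is drawn from the planted rule

\[ P(\text{lengthen}) = \mathrm{logit}^{-1}\!\big( (\Delta_{\text{pred}} - \theta - c\,h)/\tau \big), \]

with threshold $\theta = -10$ mm, height coefficient $c = 1$ mm/mm (higher
obstacles make lengthening less likely), and temperature $\tau$. The default
$\tau$ = 6.15 mm is produced by `calibrate_decision_temperature()`, which
bisects $\tau$ until the rule's Bayes accuracy $E[\max(p, 1-p)]$ over the
generator's own trial-context distribution equals 0.73. The paw-home and
nose geometry (forepaw touchdowns 1.5 mm behind the nose reference) centres
$\Delta_{\text{pred}}$ near the effective threshold, giving roughly balanced
classes.

## Modification kinematics and the reaction latency

The planted modification begins exactly `planted_latency` (24 ms = 6 frames)
after contact. With the default gait law swings last only ~40 ms, so on many
trials the paw touches down at its unmodified landing before the onset. The
generator models this the way a rapid correction looks in practice: if the
paw is still airborne at onset the remainder of the swing is re-planned
(with an immediate velocity change and a smooth, zero-velocity landing at
the modified position); if it has already landed, a rapid corrective
re-step lifts it from the unmodified landing to the modified one. The first
frame at which the trajectory departs from its unmodified continuation is
the onset frame exactly, which is what makes the ±4 ms latency-recovery
checks meaningful. Downstream, `decision_dataset()` merges a post-contact
stance shorter than 24 ms into a single compound decision step, so labels
remain recoverable from kinematics alone.

Shortened steps land `U[5,15]` mm short of the prediction (and at least
3–8 mm in front of the obstacle); lengthened steps land `U[5,15]` mm beyond
the obstacle. Any swing crossing the engaged obstacle receives a smooth
clearance bump reaching the obstacle height plus a 4 mm (±0.8 mm) margin;
for the decision paw the bump is clipped to start no earlier than the
reaction onset, so no obstacle-driven change precedes the planted latency.

## What the generator does and does not emulate

It reproduces the statistical structure the pipeline depends on: the
speed/step-length law and its residuals, trot phase relations, jittered
obstacle geometry, contact-position/speed correlation, a body-state-dependent
planted decision, reaction latencies, height tracking of obstacle clearance,
and the four tracking-artifact classes (low confidence, single-frame jumps,
cross-view x disagreement, short gaps, via `inject_tracking_artifacts()`).
It does not emulate per-frame tracking jitter on clean sessions, grasping or
slipping, whisker kinematics, or video; passing tests therefore validate the
*pipeline logic and calibration*, not pose-estimation accuracy on real
video. The mean time from contact to paw-obstacle interception implied by
the default geometry is ~40–50 ms — the same order as, but shorter than, the
~63 ms seen in real mice, a consequence of choosing balanced decision
classes over a longer approach gap; `time_to_contact()` itself is exact on
constructed trajectories.

# Numerical and design choices

* **QC order and the median filter.** The five post-processing steps run in
  the documented order (confidence, jump, median, cross-view,
  interpolation). The 3-frame temporal median is applied as a *de-spiking*
  median by default (`median_spike_tol` = 10 mm): a sample is replaced only
  when it deviates from the window median by more than the tolerance, which
  is above genuine single-frame kinematic excursions at 250 Hz but below
  jump artifacts. `median_mode = "full"` restores the classic filter, which
  shaves every swing apex by ~0.5 mm.
* **Jump masking** marks samples that jump more than 15 mm/frame relative to
  *both* neighbours (an isolated spike), leaving genuine fast swings intact.
* **Stance rule.** `|v_world| <= 0.2` m/s *and* height within 5 mm, then a
  20 ms median debounce (5 frames at 250 Hz; nearest odd window at other
  rates). The camera-frame accessor `detect_stance_camera()` adds the wheel
  velocity back. Step speed is measured over the full cycle (previous
  touchdown to touchdown), the window over which the length/speed law holds
  identically.
* **Noiseless frame-exactness.** With noise off and the speed chosen so a
  stride is an integer number of frames, segmentation inverts the generator
  schedule frame-for-frame; at default noise, rare single-frame boundary
  ambiguities (<0.1% of frames) remain at slow strides.
* **Decision model.** Features are z-scored before fitting; folds are
  stratified and seeded; weights are inverse class frequencies; accuracy is
  the unweighted mean over 15 folds. Ties in greedy forward selection break
  by the canonical feature order. The cross-validated accuracy of the full
  model sits a few points below the calibrated 0.73 Bayes ceiling — the
  irreducible cost of estimating nine coefficients from ~150 trials per
  mouse — and that is the behaviour the acceptance band checks.
* **Reaction analysis.** Steps are aligned at swing onset and matched by
  Euclidean distance over (x, z) of the pre-contact window; the deviation is
  the RMS of per-coordinate z-scores against the family envelope (SD floored
  at 0.1 mm), and an onset requires 2 consecutive supra-threshold frames.
  "Mid-swing" means contact within the central 60% of the typical swing.
* **Consensus votes** are hard argmax votes (a soft-vote variant is a flag);
  ties resolve to the earliest frame so the detector does not bias late.
* **Trial matching** is greedy nearest-pair on z-scored features; with
  continuous features the result is invariant to trial ordering.
* **Trial success** sums contact durations across paws (<= 20 ms passes,
  inclusively); per-paw success means zero contact, and both readings are
  reported.

# Problem sizes used by the checks

The calibration analyses use 53 sessions of 65 trials (~260 control steps
each) for the correlation and landing-model statistics, and 20 mice x 3
sessions (~150 labelled decision trials per mouse) for the decision model
and its shuffled baseline. Property checks use 500-stream consensus
batches, 500-step kNN pools, 2,500 planted-rule draws for threshold
recovery, and four sessions per planted latency in {12, 24, 40} ms.

```{r example}
## a complete miniature analysis
gs <- generate_session(gait_config(n_trials = 10), seed = 1)
pl <- session_pipeline(gs)
ctrl <- session_control_steps(pl$steps, gs$truth$trials$contact_frame)
fit_landing_model(ctrl, paws = c("LF", "RF"))
dd <- simulate_decision_dataset(gait_config(), seed = 1, mouse = "m1")
fit_decision_glm(dd, folds = 10)
```

# Known limitations

* Clean sessions carry no per-frame tracking noise; QC recovery statistics
  are therefore exact-recovery statistics, optimistic relative to real
  tracking error (~0.3–0.6 mm on real video).
* The whiskerless degradation (temperature x3, landing noise x1.5) is a
  qualitative emulation of diffuse no-whisker behaviour; the true
  degradation is not quantified.
* Optimal bipartite trial matching is not implemented; the greedy
  nearest-pair selection is the only matcher.
* The generator's corrective re-step is a modelling device for late-contact
  trials; its kinematic shape (velocity-step onset, quadratic approach) is
  chosen for detectability and smooth landings, not fit to data.
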