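---
title: "Models and methods: pursuit and interception under varied gravities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: pursuit and interception under varied gravities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gravipursuit)
```

## The problem

Humans appear to carry an internalized assumption that objects accelerate
downward at earth gravity (9.81 m/s²), and to use it when predicting the
motion of things they watch and intercept. This package implements the full
analysis chain of an occlusion-paradigm experiment probing that prior in two
effector systems at once: smooth-pursuit eye movements while a ball flies on
a parabola, and a button press timed to the moment the ball returns to its
launch height after disappearing mid-flight. Gravity is manipulated as a
signed multiple of earth gravity (0.7, 0.85, 1, 1.15, 1.3, and an inverted
−1 condition in which the parabola hangs from the ceiling), crossed with two
launch speeds in each axis and two occlusion depths.

Because the package must be fully testable without any recorded data, it
contains a first-class generative model of the whole experiment — target
kinematics, eye traces in the tracker's surface coordinates, and button
presses — with known ground truth, so that every downstream stage can be
validated closed-loop.

## Target kinematics

The target experiences gravity and a drag force proportional to velocity:
$\ddot x = -(c/m)\,\dot x$, $\ddot y = -g - (c/m)\,\dot y$, with mass
$m = 0.057$ kg (a tennis ball) and drag coefficient $c = 0.005$ kg/s.
Writing $k = c/m$, the closed-form solution is

$$x(t) = x_0 + v_{xi}\,t\,\phi_1(kt), \qquad
  y(t) = y_0 + v_{yi}\,t\,\phi_1(kt) - g\,t^2\,\phi_2(kt),$$

with $\phi_1(u) = (1-e^{-u})/u$ and $\phi_2(u) = (e^{-u}-1+u)/u^2$. This
form is algebraically identical to the usual exponential expressions but
numerically stable: both $\phi$ functions are evaluated by series below
$|u| < 10^{-3}$, so the ballistic limit $c \to 0$ is exact to machine
precision rather than a catastrophic cancellation. The test suite confirms
agreement with an independent Runge–Kutta integration (`deSolve`) to well
under $10^{-6}$ m in every design condition.

The inverted condition is the mirror image about the launch height: the
target starts at 3.5 m (instead of 0.5 m), is launched downward, and
"gravity" pulls it back up. Flight time back to the launch height is found
by bracketed root search (`uniroot`, tolerance $10^{-12}$ s) on the vertical
displacement; the occlusion onset is a fraction of that *with-drag* flight
time (the stimulus is simulated with drag, so its fractions are defined on
the drag clock). Drag breaks the parabola's symmetry slightly: the vertical
extremum sits not at $x = 0$ but up to ~2.5% of the horizontal half-extent
downrange (8 cm for the longest 0.7 g flight) — the tests assert this
computed bound rather than the idealized equality.

## The 1g extrapolation model

When the target disappears with upward velocity $v_{up}$ and a remaining
vertical distance $d_y$ toward the coincidence height, an observer assuming
drag-free earth gravity predicts a remaining time

$$\hat t = \frac{v_{up} + \sqrt{v_{up}^2 + 2\,g_{earth}\,d_y}}{g_{earth}},$$

the positive root of the displacement equation (negative roots are behind
the observer in time). The drag-free assumption is part of the model: the
observer's predicted error on a 1 g *drag* stimulus is a few milliseconds,
not zero. For inverted trials the formula is applied in the mirrored frame —
a prior of earth *magnitude* along the stimulus's own vertical direction —
because a literal downward extrapolation of a ceiling-hung parabola never
reaches the coincidence height. Predicted errors are negative (early) below
1 g and positive (late) above it, by 30–270 ms depending on cell.

The competing account is a central tendency: responses timed from the mean
of all experienced occluded durations, predicting error = block-mean
occluded duration − trial occluded duration. `compare_models()` correlates
observed errors with both predictors, overall and per occlusion band, and
reports per-cell medians.

## The synthetic cohort

The generator's defaults are the study's conditions, fixed once:

* **Design**: 48 training trials, three 320-trial graded-gravity blocks
  (8 repetitions per factor combination) and one 384-trial inversion block
  (24 repetitions), 1344 experimental trials per subject; 10 subjects, half
  receiving the inversion block first. Occlusion fractions are drawn
  uniformly per trial within 20–25% (short) or 45–50% (long).
* **Pursuit gains**: 0.80 at 1 g, offset by the graded differences the
  paradigm is designed to detect (+0.053 at 0.7 g, +0.029 at 0.85 g,
  −0.043 at 1.15 g, −0.065 at 1.3 g, −0.13 at −1 g).
* **Variability**: trial-to-trial gain SD 0.222 and between-subject
  intercept SD 0.037. The 6:1 ratio is the design's stated assumption; the
  absolute scale is what a contrast standard error of 0.005 over ~1900
  trials per gravity level implies ($0.005 \times \sqrt{1920} \approx 0.22$).
* **Oculomotor structure**: fixation until a 150 ms pursuit latency, then a
  minimum-jerk catch-up saccade onto the target and pursuit whose
  displacement is `gain` × target displacement; further catch-ups whenever
  the position error exceeds 0.3 m (which reproduces the ~2 saccades per
  visible period that threshold classification should find); position noise
  5 mm at the stimulus plane; 6.4% confidence dropouts; after occlusion the
  gain decays (time constant 0.3 s) and one predictive saccade goes to the
  1g-extrapolated coincidence point, which is what makes the
  landing-error metric undershoot for sub-earth gravities.
* **Timing**: response = occlusion onset + a $(1-\lambda)/\lambda$ mixture
  of the 1g extrapolation and the block-mean occluded duration + Gaussian
  motor noise (SD 80 ms, roughly the spread of human interception timing)
  + the measured 49.259 ms projection delay.

What the generator deliberately does *not* emulate: pursuit latency
distributions, saccade main-sequence kinematics beyond a plausible
minimum-jerk shape, anticipatory pursuit, blinks (beyond confidence
dropouts), or any dependence of gain on time within a trial before
occlusion. Passing closed-loop tests therefore demonstrate that the
pipeline measures what it defines on data with the assumed structure — not
that real eyes behave this way.

## The gaze pipeline and its numerical choices

Stages, in order, with every constant exposed in `run_config()`:

1. **Filtering** — drop frames with confidence < 0.9, then frames outside
   the display (surface x outside [0, 1], y outside [−0.3, 1]), then frames
   with missing fields. Each stage's count is reported against the frames
   remaining after the previous stage, so stage percentages reproduce
   exactly on constructed fixtures.
2. **Scene mapping** — surface coordinates to screen metres (1.84 × 2.44 m
   screen), then ray-scaling about the viewpoint by the depth ratio
   6.15/2 = 3.075, so positions and velocities live at the stimulus plane.
   The printed stimulus plane is $z = -6.15$ m; the mapping uses the
   magnitude. The viewpoint height defaults to the screen centre (1.22 m),
   making the mapping exactly invertible by `scene_to_surface()`.
3. **Smoothing** — Gaussian kernel, SD 3 samples (15 ms; the width is a
   package choice, exposed as `smooth_sigma`), truncated at 4 SD, mirrored
   boundaries.
4. **Kinematics** — tangential speed over a 9-sample lag and its derivative
   over a 5-sample lag, both from actual timestamps (robust to dropped
   frames; windows stretched beyond 3× their nominal span are left
   undefined). Estimates are assigned to the window centre; for odd lags
   the centre falls between samples and the tie goes to the earlier
   sample. That half-sample convention is what lets injected saccade
   onsets be recovered within ±2 samples.
5. **Saccades** — a sample is saccadic when |tangential acceleration|
   exceeds 300 m/s² or eye speed exceeds 1.5× the instantaneous target
   speed. The magnitude reading of the acceleration criterion is
   deliberate: the deceleration edge of a saccade is as diagnostic as its
   onset. Segments closer than 2 samples merge; segments shorter than
   2 samples are dropped. A 2° saccade of physiological (~30 ms) duration
   is resolvable by these thresholds when directed along the motion path,
   as catch-up saccades are; the same saccade injected orthogonally late in
   the trajectory is near the velocity criterion's floor — a genuine
   resolution limit of lag-9 differencing at 200 Hz.
6. **Gain** — mean of eye speed / target speed over samples after the first
   catch-up saccade's *offset* (pursuit is measured after the saccade, and
   only saccades launched before occlusion qualify), before occlusion, and
   outside saccade segments *padded by 12 samples*. The padding matters:
   an unpadded lag-9 estimate within half a window plus the smoothing
   support of a saccade absorbs saccadic displacement and biases the gain
   upward by ~0.03; with padding the closed-loop bias is below 0.005. When
   no catch-up is on record — the widest 0.7 g trajectory starts beyond
   the display edge, so its catch-up happens off-surface — the window
   falls back to a configurable 0.2 s (latency plus saccade duration).

## Inference

Both confirmatory analyses are random-intercept linear mixed models fit by
**maximum likelihood** (not REML): likelihood-ratio tests between nested
fixed-effect structures are only defined for ML, and every reported
comparison is such a test against a chi-square reference. Gravity enters as
an unordered factor with 1 g as the reference level, so coefficients are
per-level contrasts against earth gravity. The timing analysis fits the
gravity × occlusion interaction model and keeps it only if dropping the
interaction significantly loses fit. Optimizer settings are lme4 defaults
with derivative checks disabled; fits are deterministic given the data.

`power_simulation()` reproduces the design's power logic by brute force:
simulate two-condition cohorts with intercept SD 0.037 and trial SD six
times that, fit the LMM pair, count rejections. At the design scale
(10 subjects × 60 trials per condition) the simulated type-I rate over 500
null cohorts sits inside [0.03, 0.07], and an effect of 0.1 gain units is
detected essentially always — the tests and the acceptance script compute
both from scratch.

## Problem sizes used in the checks

The shipped checks run the trajectory oracle over all 24 kinematic
conditions, closed-loop gain recovery over all 24 cells × 3 trials,
effect-size recovery on a 10-subject cohort (3840 inversion-block trials),
type-I calibration over 500 simulated cohorts, timing-model discrimination
over 100 two-subject cohorts, and power estimates over 100 cohorts per
design point. These sizes give Monte-Carlo error comfortably inside the
asserted tolerances while keeping a full run to a few minutes.

## Known limitations

* The generator's saccade program realigns the eye exactly onto the target;
  real catch-ups under- or over-shoot and their landing errors carry
  structure this package treats as free parameters, not predictions.
* The drag model is linear in velocity. A real tennis ball at these speeds
  is closer to quadratic drag; the linear coefficient here is a stimulus
  definition, not aerodynamics.
* With the printed screen geometry the widest 0.7 g trajectories exceed the
  display's horizontal extent at the stimulus depth, so their earliest and
  latest frames are unrecordable by construction; the pipeline handles
  this through the fallback gain window rather than pretending the frames
  exist.
* Mixed models use random intercepts only, matching the design; random
  slopes are out of scope.
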