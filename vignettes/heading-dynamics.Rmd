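---
title: "Modeling the temporal stability of heading perception"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the temporal stability of heading perception}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

An observer translating through a rigid world experiences a radial pattern
of image motion — optic flow — whose singularity, the focus of expansion
(FoE), marks the direction of self-motion (heading). When the simulated
heading changes abruptly mid-trial, judgments of the final heading are
attracted toward the initial one, and the attraction grows with the size of
the change and shrinks with postswitch viewing time. `headingCD` implements
a process model of that behavior: a recurrent competitive network of
heading-tuned units that accumulates evidence from optic flow over time, so
that a new heading takes time to overcome the signal built up by the old
one.

## The stimulus generator

Trials simulate translation at 1.5 m/s through a cloud of 10,000 dots
occupying depths 1.5–9 m. The flow field is computed analytically: a dot at
$(X, Y, Z)$ has azimuth $\alpha = \operatorname{atan2}(X, Z)$ and elevation
$\varepsilon = \operatorname{atan2}(Y, Z)$, and pure translation along
heading $h$ gives angular velocities

$$\dot\alpha = \frac{-T_x Z + X T_z}{X^2 + Z^2}, \qquad
  \dot\varepsilon = \frac{Y T_z}{Y^2 + Z^2},$$

with $(T_x, 0, T_z) = v(\sin h, 0, \cos h)$. Each visible dot deposits its
instantaneous angular velocity (degrees per frame) at its nearest pixel of
a 128 × 128 grid covering 90° × 90°; dots sharing a pixel are averaged and
empty pixels are zero (the model's MT stage densifies the field). A single
linear angle–pixel mapping of 90°/128 ≈ 0.703°/px is used for
rasterization, template placement and decoding, which keeps the three
mutually consistent across the wide field.

A trial is 34 frames (32 in the blackout protocol) with the heading switch
at frame 30. Repetitions of a condition differ only in the random placement
of dots — this is the only stochasticity in the system, and it is what the
precision statistics measure.

Choices the underlying reports leave open, fixed here once:

* **Observer speed, depth range** — taken from the human display
  (1.5 m/s, 1.5–9 m).
* **Frame-rate equivalent** — 30 fps, so one frame corresponds to 33 ms of
  motion; only the overall flow-speed scale depends on this, and the drive
  normalization (below) absorbs it.
* **Lateral extent** — the volume half-width defaults to
  $\text{far} \cdot \tan(\text{fov}/2) = 9$ m so that every depth plane
  fills the field of view; a narrower volume would leave the image
  periphery nearly empty at most depths.
* **Recycling** — dots leaving the volume respawn uniformly in its far
  half with fresh lateral positions, keeping density stationary across a
  trial. Dots inside the volume but outside the view simply persist.
* **Blackouts** — a blacked-out frame carries zero flow and an explicit
  invalid flag; the scene keeps moving underneath, so flow resumes in the
  advanced state.

What the generator does *not* emulate: luminance, dot visibility and size
cues, eye movements or rotational flow, the anisotropic 65° × 40° extent of
the human display, and the ±1° preswitch jitter used to keep human subjects
from anchoring. Passing tests therefore speak to the model's treatment of
ideal velocity fields, not to every property of the physical display.

## The model

The pipeline per frame is: **MT pooling** — each flow component is
convolved with a unit-sum Gaussian (SD 9.51 px) truncated at radius 6 px,
a coarse model of MT motion pooling without suppressive surrounds.
**Template match** — the pooled field is dotted against 128
radial-expansion templates whose FoEs sit at every pixel column of the
horizontal midline; template vectors are inverse-distance weighted
(capped at 1 near the FoE), which sharpens FoE selectivity. Activations are
half-wave rectified and multiplied by a normalization constant (below).
**Across-heading smoothing** — a 1-D Gaussian (SD 10.08 templates, radius
19) with renormalized edge kernels. **Recurrent competition** — the
smoothed drive updates an exponential trace,
$\mathrm{trace} \leftarrow c\,\mathrm{trace} + (1 - c)\,\mathrm{drive}$
with $c = 0.7$, which then feeds a shunting on-center/off-surround field

$$\dot x_i = -A x_i + (B - x_i)\,(I_i + f(x_i)) - x_i \sum_{j \neq i} f(x_j),$$

with decay $A = 0.81$ and upper bound $B = 146$. **Decoding** — the
population vector $i^* = \sum_i x_i h_i / \sum_i x_i$ over the units'
preferred headings $h_i$.

Because MT pooling is linear with a symmetric kernel, matching a pooled
frame against raw templates equals matching the raw frame against pooled
templates; `CDModel()` precomputes the pooled bank once and runs each frame
as a single matrix product (`runTrial()` therefore costs ~0.2 s per
34-frame trial).

### The recurrent signal function

The equation family above leaves the recurrent signal $f$ open, and the
choice matters more than any other in the package. A bare quadratic
$f(x) = x^2$ with $B = 146$ is untenable: the recurrent terms reach
$10^4$–$10^5$, explicit integration at any practical step explodes, and —
more fundamentally — every unit above the tiny threshold $A/B$ becomes
self-sustaining, so the first winner is permanent and the estimate never
moves toward a new heading, contradicting the very behavior the model
exists to produce. We therefore use the classic saturating (Naka–Rushton)
form

$$f(x) = g\,\frac{x^2}{K^2 + x^2},$$

which is faster than linear at low activity (contrast enhancement and
noise quenching) and bounded at high activity, so winners remain
displaceable by sustained contrary evidence. The constants $g = 8$,
$K = 16$ were fixed once by the package's calibration procedure (the same
random/grid search exposed as `parameterSearch()`), scored purely on the
qualitative target pattern: signed bias positive for every switch angle,
increasing with the absolute switch angle, decreasing from the frame-32 to
the frame-34 readout, with bounded, non-collapsing total activation. With
them, the model produces mean signed biases of roughly 1.4°, 2.9° and 5.8°
for 3°, 6° and 12° switches at the frame-32 readout, decreasing by frame
34 — the attraction-plus-accumulation signature — and repetition-to-
repetition precision of 0.4–0.6°.

### Drive normalization

Shunting dynamics care about the drive scale relative to $A$ and $B$, and
the raw dot products depend on arbitrary stimulus units. The raw rectified
activations are therefore multiplied by a constant fixed so that a
canonical noise-free full-field expansion frame — FoE at the image center,
radial direction, magnitude $(v/\text{fps})/\bar Z \cdot \sin(\text{ecc})$
with $\bar Z$ the geometric mean depth — yields a peak activation of 1.
The constant is computed deterministically at `CDModel()` construction, so
it adapts automatically if the scene configuration changes.

### Numerical integration

The field is integrated by explicit Euler with $dt = 0.05$ and 20 substeps
per frame (one time unit per video frame), with activations clipped to
$[0, B]$ after each substep. A coarser $dt = 0.1$ visibly changes
trial-level results (the dynamics ride on integration error), while
halving again to $dt = 0.02$ changes decoded headings by $\sim 10^{-2}$
degrees; $dt = 0.05$ is the accuracy/cost knee. Degenerate inputs are
handled by erroring rather than guessing: non-finite drives, all-zero
activation at a readout (possible only if decoding before any input), and
readouts outside the trial raise conditions the experiment runner never
triggers.

## Protocols and statistics

`makeConditionGrid(1, ...)` crosses preswitch headings 0°/±6° with switch
angles ±3°/±6°/±12° (18 conditions), 34 frames, switch at frame 30, and
decodes at frames 32 and 34 — the shorter/longer postswitch-duration
analogues. `makeConditionGrid(2, ...)` crosses the same 18 conditions with
four one-frame blackout schedules on the 32-frame protocol: none;
preblackout (frame 28 blank — one frame of preswitch flow separates
blackout and switch); midblackout (a blank inserted between preswitch and
postswitch flow, extending the trial to 33 frames so postswitch viewing is
not reduced); postblackout (frames 31–32 blank — one postswitch flow frame,
blackout to trial end). The published frame accounting for the blackout
protocol is internally inconsistent (a single one-step blackout cannot give
both stated postswitch durations within 32 frames); the schedules above
resolve it in favor of the stated postswitch viewing durations (three
steps, except one step in postblackout), and all of them are plain
`TrialSpec` fields, so other readings are one constructor call away.

Every (postswitch heading, repetition) also yields a matched no-switch
trial — 11 unique postswitch headings, as in the human design — sharing
the switch trials' dot-placement seed, which cancels dot-sampling noise
from the bias estimate.

Heading error is $E = H_\text{judged} - H_\text{true}$; per-trial heading
bias is the error minus the mean matched no-switch error, with biases of
positive switch angles negated so that positive always means attraction
toward the preswitch heading. Precision is the SD of decoded headings
across the repetitions of a condition. Confidence intervals in the
summaries are normal-approximation 95% intervals across trials,
descriptive only. Why subtract no-switch errors at the same postswitch
heading? The decoder, like human observers, has a center bias — broad
tuning plus a symmetric population vector shrinks eccentric estimates
toward straight ahead — and the subtraction removes exactly that
heading-dependent offset from the bias statistic.

## What the model does and does not reproduce

On the switch-duration grid the model reproduces attraction toward the
preswitch heading for all switch angles, growth of the bias with the
absolute switch angle, and its decline with postswitch viewing time. On
the blackout grid it reproduces elevated bias when the blackout follows
the switch and the equivalence of the no-blackout and early-blackout
conditions — and, like the published simulations, it does **not**
reproduce the elevated bias humans show in the midblackout condition: with
postswitch viewing time preserved, the evolving estimate recovers through
the blackout, which is precisely the published model shortfall (a
mechanism beyond recurrent evidence accumulation appears to be involved in
the human data).

Model precision across repetitions lands at 0.4–0.6° per condition group —
of the order of, but below, the ~1° the published simulations report and
well below the 2–3° of human judgments; tuning-bank heterogeneity (e.g. a
peripheral bias in preferred headings) is the known lever that would raise
it and is deliberately out of scope.

## Problem sizes

The packaged experiments use the full published grids: 180 switch + 110
no-switch trials for the switch-duration protocol and 720 + 110 for the
blackout protocol, 10 repetitions each, at 128 × 128 resolution with
10,000 dots — a few minutes per protocol on one core. The unit tests
exercise the same code paths at 32 × 32 resolution with proportionally
scaled filters, where each trial takes milliseconds.

## Limitations

* The recurrent equations are this package's concrete instantiation of an
  on-center/off-surround shunting field; $f$, $g$, $K$, the trace
  placement and the integrator are declared choices, exposed in
  `ModelParams`, not uniquely dictated by the behavioral data.
* Templates cover only midline (horizontal) headings and radial expansion;
  rotation, spiral flow and vertical heading components are out of scope.
* The generator's ideal velocity fields contain no measurement noise;
  conclusions about robustness to image noise would need an image-based
  front end.
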