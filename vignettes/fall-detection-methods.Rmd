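---
title: "Silhouette fall detection: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Silhouette fall detection: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fallwatch)
```

fallwatch detects falls and faints of a person moving indoors, from video
alone. The processing model is deliberately simple: adaptive background
subtraction isolates the moving silhouette, morphology and a size filter
remove artifacts, a Haar cascade and a HOG template decide whether the
region is a person, Mean-Shift follows the person between detections, and a
small set of spatiotemporal rules on the bounding box raises the alarm.
This vignette explains each stage, the parameters that matter, and the
design decisions taken where the method leaves room.

## The background model

Every pixel is modeled as a mixture of up to `G` Gaussians over a single
channel. A new pixel value `x` is compared with the components in order of
`w/sigma` (weight over spread — high-weight, low-variance components explain
the stable scene); the first component with `|x - mu| < c * sigma` is the
match. The *background* is the smallest prefix of components whose
cumulative weight exceeds `T`: a pixel whose match falls outside that prefix
— or that matches nothing — is foreground. A matched component's mean and
variance relax toward the sample at rate `rho = alpha * eta(x | mu, sigma)`
(`eta` the Gaussian density, clamped to `[alpha * 1e-4, 1]` for numerical
stability), the matched weight follows `w <- (1 - alpha) w + alpha` while
the others decay, and an unmatched pixel replaces the least probable
component with one centred at `x`. Weights are renormalized to sum one after
every update — the raw recursion alone lets mass drift — and components are
re-sorted by `w/sigma`.

Two channels are modeled in parallel on color input: **luminance**
(Rec. 601 luma) and **hue** (HSV hexcone, rescaled to the circular range
`[0, 256)` so intensity-scale defaults apply; distances and mean updates
follow the shortest arc). A cast shadow darkens a region without changing
its hue, so it appears in the luminance foreground but not in the hue
foreground; the entrywise product (logical AND) of the two masks removes
shadow-only pixels while keeping the true silhouette, which differs from
the background in both channels. The same mechanism absorbs pure-gain
illumination steps almost entirely: a lamp switching on changes luminance
everywhere but hue nowhere, so the dual mask stays quiet while the
luminance model re-learns. The hue model's blind spot is an achromatic
(grey) actor on a grey background; the generator therefore uses saturated
colors, and real deployments should expect degraded shadow discrimination
for low-saturation clothing.

**Calibration.** The model consumes `learn_frames = 40` movement-free
frames (2–3 s of video) before emitting any foreground. The
`rho = alpha * eta` recursion adapts variances at roughly `1e-4` per frame —
far too slowly for a 40-frame calibration to tighten the initial spread —
so during the learning phase the matched component instead follows
running-average sufficient statistics (`rho = 1/n`). After calibration the
update switches to the density-weighted recursion above, which is the form
the equivalence tests pin down against a literal per-pixel transcription.

**Defaults and why.** `G = 3` components, `alpha = 0.01`, `T = 0.7`,
`c = 2.5` are conventional for indoor scenes at 15 fps. The
initial/replacement spread `sigma0 = 15` deserves a note: with `c = 2.5`, a
replacement component matches anything within `±2.5 * sigma0`. At
`sigma0 = 30` that band is ±75 intensity levels — and because `rho` is tiny,
it never tightens — so after any global illumination change the re-learned
background swallows moderate-contrast objects entirely. `sigma0 = 15`
(±37.5) keeps a person distinguishable from a re-learned wall while still
tolerating sensor noise. A floor `sigma_min = 1` prevents degenerate
zero-variance components on noise-free input.

**Known limitation.** An adaptive background absorbs anything that stops
moving, on a timescale of roughly `log(T / w_bg) / log(1 - alpha)` ≈ 30
frames at defaults. A person walking slower than about one pixel per frame
is partially absorbed *while moving* and fragments the foreground. The
tracking layer (below) is what carries the system through absorption of a
fallen, motionless person; it cannot rescue arbitrarily slow walkers.

## Artifact removal and candidates

The raw mask is median-filtered (3×3 majority vote — for a binary mask the
median *is* the majority) and then eroded twice with a 3×3 box, with
out-of-frame pixels treated as background. Dilation is available but off by
default. 8-connected components are labeled (two-pass union–find), and
components smaller than `min_area = 60` pixels are discarded as artifacts:
below that size there is too little information to classify. Candidates are
returned largest-first with exact bounding boxes `(x, y, w, h)` — 0-based,
half-open — the single box convention used everywhere downstream.

## Classification

Candidates are routed by size. Below 24×12 pixels (h×w) a region is too
small to judge and stays *indeterminate*; between 24×12 and 96×48 the Haar
cascade alone decides; at or above 96×48 the HOG template match must also
agree. In every regime an upright-human proportion prior applies: the box's
height:width must lie in a multiplicative band around 2:1
(`2 / 1.4` to `2 × 1.4`), the geometric parameterisation of "roughly twice
as tall as wide". Classification crops take a 15% context margin around the
(erosion-tightened) box, and the crop is variance-normalized before Haar
evaluation so stump thresholds are contrast-invariant.

The **Haar cascade** is a small AdaBoost of decision stumps over randomly
placed two-, three- and four-rectangle features evaluated on an integral
image, with early rejection per stage. Stage thresholds sit a slack
fraction (0.35 of the stage's total vote) below the weakest training
positive, buying detection-rate headroom on patches unlike the training
set. No pretrained cascade ships with the package: `patch_bank()` renders
labeled silhouette/clutter patches and `train_haar_cascade()` fits the
cascade deterministically at run start, so the pipeline is self-contained.
This is a toy detector by design — it separates rendered silhouettes from
rendered clutter; it is not a pedestrian detector.

The **HOG descriptor** uses 8×8-pixel cells, 9 unsigned orientation bins
over `[0, π)` with linear interpolation between bin centres, 2×2-cell
blocks at 1-cell stride, per-block L2 normalization (`eps = 1e-5`).
Gradients come from the `[-1, 0, 1]` filter and its transpose with
edge-replicated borders; orientation is `atan(Iy/Ix)` with `Ix = 0` mapped
to π/2, folded to the unsigned range. Template distance is the per-block
RMS of the descriptor difference, which makes the scale independent of the
window size; the default threshold 0.95 was calibrated once on the
synthetic bank (clean silhouettes score ≈ 0.7–0.9 against the default
template, clutter and noise windows above 1.0). The default template is a
noise-free 2:1 ellipse rendered at 96×48, scaled down by `1/(1 + 2·margin)`
so that template and margin-padded candidate crops are registered.

## Tracking

Tracking is appearance-based Mean-Shift: each track stores a 16-bin hue
histogram from its acquisition box (pixels below saturation 0.1 or value 20
are excluded — their hue is unreliable), the histogram is back-projected
onto each frame, and the window moves to the kernel-weighted mean

m(x) = Σ K(x_i − x) w_i x_i / Σ K(x_i − x) w_i,  K(u) = exp(−‖u‖²/h²),

iterated until the shift falls below `eps = 0.1` px (at most 25
iterations), inside a search area of half the minimum object size around
the last box. Zero back-projected mass or non-convergence marks the track
unseen for the frame.

Fresh detections are matched to tracks greedily by nearest centroid within
12 px — adequate for scenes with one or two actors; a global assignment
would be the upgrade path for crowded scenes. Two gates make the greedy
matcher robust: a pair is matchable only if the candidate's hue histogram
overlaps the track's (Bhattacharyya ≥ 0.4), which stops background-colored
"ghost" regions (left where a person used to stand) from capturing the
person's track; and a matched detection smaller than half the track's box
area counts as partial — typical of a motionless person half-absorbed into
the background — so it refreshes the track's position but not its geometry.
Unmatched tracks fall back to Mean-Shift, which is what keeps the box, the
posture and the near-zero speed of a lying person alive long after the
background model has absorbed them. Tracks unseen for 15 frames (1 s), or
whose center leaves the frame, are retired. There is no velocity model:
the predicted position is the last position, which is exactly why the
tracker survives sudden stops and direction reversals.

## Fall rules

Two spatiotemporal parameters drive event detection. **P** is the bounding
box aspect ratio, width/height: a standing person measures about 0.5;
`p_fall = 0.7` is the ratio above which the posture is no longer upright,
and `p_lying = 1.2` the ratio of a person on the floor, giving the
three-state posture machine upright → falling → lying on the smoothed
ratio (mean over `ratio_window = 15` frames, 1 s). **K** (`k_frames`) is
the persistence requirement: the alarm fires only when, for more than K
consecutive frames, the posture is non-upright, the centroid speed (mean
displacement over the ratio window) stays below `speed_still = 1.5`
px/frame at the 320-px processing width, and the smoothed ratio is stable
(per-frame drift below 0.05; the jump *into* the fall band is itself the
onset, so stability binds only continuation frames). K is validated to its
legal band of 50–150 frames — 2 to 10 s at the 15 fps reference rate — and
defaults to 50, the most sensitive legal setting. With this construction
the trigger lands exactly `k_frames` after the onset, which is the latency
law the end-to-end tests assert for K ∈ {50, 100, 150}. The bounding-box
area and its relative change (logged with every event, default reference
0.2) corroborate the posture change but do not gate the alarm. While the
condition persists the alarm is not re-emitted; when the person resumes
upright movement the latch releases, so a later second fall alarms again.

Fall rules arm only for tracks classified human (configurable); tracking
itself always runs, so a person whose classification is delayed — entering
half-visible, for instance — is still followed and classified as soon as a
full detection arrives.

Responses are structured records only (`log`, `write-snapshot`, and the
action types a deployed system would wire to a phone call, siren, email,
text, loudspeaker or control signal); the package performs no real side
effects.

## The synthetic scene generator

`scene_spec()`/`render_sequence()` produce the sequences every test runs
on: a flat saturated background, one upright 2:1 ellipse silhouette
(brighter than the background — light clothing on a darker wall — and of
distinct hue) following linear waypoints, an optional cast shadow
(luminance × 0.6, hue untouched), an optional step illumination gain,
i.i.d. Gaussian pixel noise, and exact per-frame ground truth (box,
centroid, posture, event times). A fall pivots the ellipse about its base
over a 10-frame transition, producing the smooth ratio change a real fall
shows. The default frame is 320×180 at 15 fps, the pipeline's processing
size; the test suite renders at 160×90 to keep its runtime modest (the
regression battery of 40 sequences completes in under two minutes on one
CPU), with actor heights of 36–46 px and walking speeds of 1–2 px/frame —
typical of a person crossing a room at this resolution.

What passing on these scenes does *not* show: robustness to compression
artifacts, textured or multi-modal backgrounds (curtains, pets),
low-saturation clothing, occlusion by furniture, multiple interacting
people, or camera motion. The generator models the failure modes the
method is designed around — shadows, illumination steps, noise, entry and
exit — not photorealism.

## Numerical choices and degenerate inputs

Weights are renormalized every update; `rho` is clamped; spreads are
floored at `sigma_min`. Hue arithmetic is circular everywhere (distance,
mean update, wraparound). Degenerate boxes (zero width or height) map to
an `NA` ratio and the `unknown` posture, which never arms the alarm. A
single trajectory point yields speed 0 flagged "cold". Ties in the
`w/sigma` ordering keep their previous rank (stable sort), so the
component order — and therefore the mask — is deterministic. All
randomness (model initialization, cascade training, scene noise) flows
from explicit seeds; the same input, configuration and seed reproduce a
run bit-for-bit.

## Worked example

```{r example, eval = FALSE}
spec <- scene_spec(width = 160, height = 90, n_frames = 160,
                   actor_height = 40,
                   waypoints = data.frame(frame = c(40, 70), x = c(40, 70),
                                          y = 72),
                   fall_frame = 75, shadow = TRUE, noise_sigma = 2, seed = 7)
scene <- render_sequence(spec)
run <- run_pipeline(scene$frames, pipeline_config(scale = 1))
run
eval_run(run, scene$truth)
```

The run reports one track, classified human while upright, and one fall
event whose trigger sits `k_frames` after the detector's stillness onset;
`eval_run()` scores it against the rendered ground truth. The same
pipeline is available from the shell via the `fallwatch` script in
`inst/cli/` (`run`, `simulate`, `train-cascade`, `eval`).
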