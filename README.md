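# fallwatch

Rule-based fall and faint detection for indoor video monitoring of ill or
elderly persons, implemented as an R package with a synthetic-scene
generator so the whole pipeline is testable without any video data.

The problem: a camera watches a room; when the person in it falls and stays
down, the system must raise an alarm within seconds — with no wearable, no
floor sensors, and no human watching the feed. fallwatch implements the
classic lightweight video-processing chain for this task:

1. **Adaptive background subtraction.** Each pixel is a mixture of up to
   *G* Gaussians; a value within *c·σ* of a high-weight, low-variance
   component is background, everything else is foreground. Two models run
   in parallel — luminance and hue — and the foreground is their entrywise
   product: a cast shadow darkens a region but keeps its hue, so it drops
   out of the product mask.
2. **Artifact removal.** Median filter, double erosion, 8-connected
   labeling, and a 60-pixel minimum area for candidate objects.
3. **Classification.** A boosted Haar-feature cascade (minimum object size
   24×12) and a HOG template match (minimum 96×48), under an upright-human
   prior of 2:1 height:width on the bounding box.
4. **Mean-Shift tracking.** Hue-histogram back-projection with
   `K(u) = exp(−‖u‖²/h²)`, searched over half the minimum object size
   around the last position; tracks survive sudden stops and direction
   reversals because no linear-motion model is assumed.
5. **Fall rules.** Parameter **P** — the bounding-box aspect ratio
   (width/height): ≈0.5 standing, ≥0.7 falling, ≥1.2 lying. Parameter
   **K** — the persistence requirement: the alarm fires when a non-upright,
   motionless, stable posture lasts more than K frames (50–150 frames =
   2–10 s at 15 fps). Responses are structured log records.

## Worked example

```r
library(fallwatch)

spec <- scene_spec(width = 160, height = 90, n_frames = 160,
                   actor_height = 40,
                   waypoints = data.frame(frame = c(40, 70),
                                          x = c(40, 70), y = 72),
                   fall_frame = 75, shadow = TRUE, noise_sigma = 2, seed = 7)
scene <- render_sequence(spec)                 # frames + ground truth
run <- run_pipeline(scene$frames, pipeline_config(scale = 1))
run
#> <fall_run> 160 frames, 1 track(s), 1 fall event(s)
#>   fall: track 1, trigger frame 147 (onset 97), ratio 2.33, speed 0.00 px/frame
eval_run(run, scene$truth)
#>   n_events detected latency_frames false_alarms
#> 1        1     TRUE             62            0
```

The actor enters at frame 40, walks, falls at frame 75 and lies still from
frame 85. The pipeline calibrates its background models on the first 40
frames, acquires the person as track 1 (classified human by the Haar
cascade under the 2:1 prior), follows the fall through the posture machine
(ratio 0.43 upright → 2.33 lying), and — once the lying, motionless,
stable condition has persisted for K = 50 frames past its onset at frame
97 — raises exactly one alarm at frame 147, 62 frames (≈4 s) after the
true stillness onset. The walk-only variant of the same scene produces
zero events.

The same pipeline is scriptable from the shell:

```sh
inst/cli/fallwatch simulate --out /tmp/scene --frames 160 --fall-frame 75 --shadow TRUE
inst/cli/fallwatch run --input /tmp/scene --scale 1 --log-jsonl /tmp/events.jsonl
inst/cli/fallwatch eval --events /tmp/events.jsonl --truth /tmp/scene/ground_truth.csv
```

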