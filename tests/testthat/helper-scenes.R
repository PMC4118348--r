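# Shared synthetic-scene builders for the tests. Scenes are rendered at
# 160x90 to keep the suite fast; detector thresholds always stay at package
# defaults.

# A fall scene: entry at frame 40, walk, fall with a 10-frame transition,
# then lying still to the end.
fall_scene <- function(n_frames = 160L, fall_frame = 75L, seed = 7L,
                       shadow = TRUE, noise_sigma = 2,
                       illumination_step = NULL, actor_height = 40L) {
  scene_spec(width = 160L, height = 90L, n_frames = n_frames,
             actor_height = actor_height,
             waypoints = data.frame(frame = c(40L, fall_frame - 5L),
                                    x = c(40, 70), y = 72),
             fall_frame = fall_frame, fall_transition = 10L,
             shadow = shadow, noise_sigma = noise_sigma,
             illumination_step = illumination_step, seed = seed)
}

# A walk-only scene with a direction reversal and a stop at the end.
walk_scene <- function(n_frames = 170L, seed = 11L, shadow = TRUE,
                       noise_sigma = 2, illumination_step = NULL) {
  scene_spec(width = 160L, height = 90L, n_frames = n_frames,
             actor_height = 40L,
             waypoints = data.frame(frame = c(40L, 100L, 160L),
                                    x = c(30, 95, 35), y = 72),
             fall_frame = NA_integer_, shadow = shadow,
             noise_sigma = noise_sigma,
             illumination_step = illumination_step, seed = seed)
}

# The seeded 40-sequence battery: 20 falls, 20 walk-only, alternating cast
# shadow, every 5th sequence with a step illumination change. Walking
# speeds are 1-2 px/frame, typical at this processing width.
battery_spec <- function(i) {
  fall <- i <= 20L
  set.seed(1000L + i)
  ah <- sample(36:46, 1)
  x0 <- runif(1, 25, 40)
  if (fall) {
    fall_frame <- sample(70:90, 1)
    walk_frames <- fall_frame - 3L - 40L
    speed <- runif(1, 1, min(2, (115 - x0) / walk_frames))
    nf <- fall_frame + 100L
    wp <- data.frame(frame = c(40L, fall_frame - 3L),
                     x = c(x0, x0 + speed * walk_frames),
                     y = runif(1, 68, 76))
  } else {
    fall_frame <- NA_integer_
    nf <- 170L
    x1 <- x0 + runif(1, 55, 75)
    wp <- data.frame(frame = c(40L, 100L, 160L), x = c(x0, x1, x0),
                     y = runif(1, 68, 76))
  }
  scene_spec(width = 160L, height = 90L, n_frames = nf, actor_height = ah,
             waypoints = wp, fall_frame = fall_frame, fall_transition = 10L,
             shadow = (i %% 2L == 0L), noise_sigma = 2,
             illumination_step = if (i %% 5L == 0L) c(55, 1.25) else NULL,
             seed = 2000L + i)
}

# Memoized render of the standard fall scene used by several test files.
.scene_cache <- new.env(parent = emptyenv())
cached_fall_sequence <- function() {
  if (is.null(.scene_cache$fall))
    .scene_cache$fall <- render_sequence(fall_scene())
  .scene_cache$fall
}
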