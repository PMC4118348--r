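# Deterministic synthetic-scene renderer: a quasi-static indoor background,
# one moving upright silhouette (height:width 2:1) that may fall and lie
# still, optional cast shadow (same hue, lower luminance), step illumination
# changes and pixel noise -- the standard difficulty list for indoor
# fall-detection footage -- plus exact ground truth.

#' Declarative synthetic-scene specification
#'
#' @param width,height frame size in pixels (default 320x180, the processed
#'   frame size).
#' @param fps nominal frame rate (default 15).
#' @param n_frames total frames rendered.
#' @param bg_color background RGB in `[0, 255]`; the default is a muted,
#'   saturated blue-grey so the hue channel is well defined under noise.
#' @param actor_color silhouette RGB; hue distinct from the background and
#'   brighter in luminance (light clothing against a darker wall).
#' @param actor_height silhouette height in pixels when upright; the width
#'   is half the height (2:1 proportions).
#' @param waypoints matrix/data.frame with columns `frame`, `x`, `y`: the
#'   actor's base point (feet) path, linearly interpolated between rows.
#'   The actor is absent before the first waypoint frame.
#' @param fall_frame frame at which the fall starts, or `NA` for walk-only.
#' @param fall_transition frames over which the silhouette pivots about its
#'   base from upright to lying (default 10; the ratio change is smooth).
#' @param fall_direction +1 to fall toward +x, -1 toward -x.
#' @param shadow render a cast shadow (luminance scaled by `shadow_gain`,
#'   hue preserved).
#' @param shadow_gain luminance multiplier of the shadow region.
#' @param illumination_step `c(frame, gain)`: from `frame` on, all pixel
#'   values are multiplied by `gain` (step illumination change); `NULL` for
#'   none.
#' @param noise_sigma standard deviation of i.i.d. Gaussian pixel noise.
#' @param seed RNG seed; the same spec and seed give bit-identical frames.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(width = 320L, height = 180L, fps = 15,
                       n_frames = 150L,
                       bg_color = c(60, 75, 105),
                       actor_color = c(200, 80, 60),
                       actor_height = NULL,
                       waypoints = NULL,
                       fall_frame = NA_integer_, fall_transition = 10L,
                       fall_direction = 1,
                       shadow = FALSE, shadow_gain = 0.6,
                       illumination_step = NULL,
                       noise_sigma = 0, seed = 1L) {
  if (is.null(actor_height)) actor_height <- round(height * 0.45)
  if (is.null(waypoints)) {
    f0 <- min(40L, n_frames - 1L)
    waypoints <- if (n_frames - 1L > f0)
      data.frame(frame = c(f0, n_frames - 1L),
                 x = c(width * 0.3, width * 0.55), y = height * 0.8)
    else data.frame(frame = f0, x = width * 0.3, y = height * 0.8)
  }
  waypoints <- as.data.frame(waypoints)
  if (!all(c("frame", "x", "y") %in% names(waypoints)))
    stop_config("waypoints need columns frame, x, y")
  if (is.unsorted(waypoints$frame)) stop_config("waypoint frames must increase")
  structure(list(width = as.integer(width), height = as.integer(height),
                 fps = fps, n_frames = as.integer(n_frames),
                 bg_color = bg_color, actor_color = actor_color,
                 actor_height = actor_height, waypoints = waypoints,
                 fall_frame = fall_frame, fall_transition = as.integer(fall_transition),
                 fall_direction = fall_direction,
                 shadow = isTRUE(shadow), shadow_gain = shadow_gain,
                 illumination_step = illumination_step,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "scene_spec")
}

# Actor pose at frame t: base point from waypoints (frozen at the fall
# position once the fall starts) and pivot angle (0 upright, pi/2 lying).
actor_pose <- function(spec, t) {
  wp <- spec$waypoints
  if (t < wp$frame[1]) return(NULL)
  tq <- t
  if (!is.na(spec$fall_frame) && t >= spec$fall_frame) tq <- spec$fall_frame
  tq <- min(tq, wp$frame[nrow(wp)])
  if (nrow(wp) == 1L) {
    bx <- wp$x[1]; by <- wp$y[1]
  } else {
    bx <- stats::approx(wp$frame, wp$x, xout = tq, rule = 2)$y
    by <- stats::approx(wp$frame, wp$y, xout = tq, rule = 2)$y
  }
  angle <- 0
  if (!is.na(spec$fall_frame) && t >= spec$fall_frame)
    angle <- (pi / 2) * min(1, (t - spec$fall_frame + 1) / spec$fall_transition)
  list(base = c(bx, by), angle = angle * spec$fall_direction)
}

# Binary silhouette mask of an ellipse with semi-axes (h/4, h/2) pivoted by
# `angle` about its base point (0 = upright, pi/2 = lying toward +x).
actor_mask <- function(spec, pose) {
  M <- spec$height; N <- spec$width
  ry <- spec$actor_height / 2
  rx <- spec$actor_height / 4
  a <- pose$angle
  cx <- pose$base[1] + ry * sin(a)
  cy <- pose$base[2] - ry * cos(a)
  xs <- matrix(rep(0:(N - 1), each = M), M, N)
  ys <- matrix(rep(0:(M - 1), N), M, N)
  dx <- xs - cx; dy <- ys - cy
  # rotate into the ellipse frame: long axis at angle `a` from vertical
  u <- dx * sin(a) + dy * cos(a)          # along the long axis
  v <- dx * cos(a) - dy * sin(a)          # across
  (u / ry)^2 + (v / rx)^2 <= 1
}

# Squashed dark patch on the floor beside the actor's feet.
shadow_mask <- function(spec, pose) {
  M <- spec$height; N <- spec$width
  ry <- spec$actor_height / 2
  rx <- spec$actor_height / 4
  cx <- pose$base[1] + 0.8 * ry          # cast to +x of the feet
  cy <- pose$base[2]
  xs <- matrix(rep(0:(N - 1), each = M), M, N)
  ys <- matrix(rep(0:(M - 1), N), M, N)
  ((xs - cx) / (1.05 * ry))^2 + ((ys - cy) / (0.55 * rx))^2 <= 1
}

#' Render a synthetic sequence with ground truth
#'
#' Frames are composed back-to-front: background, cast shadow (luminance
#' scaled, hue preserved), actor silhouette, global illumination gain, then
#' seeded Gaussian pixel noise, clipped to `[0, 255]`. The ground truth
#' carries the exact noise-free bounding box, centroid and posture label per
#' frame, plus the event times.
#'
#' @param spec a [scene_spec()].
#' @return list with `frames` (list of MxNx3 arrays) and `truth` (list with
#'   per-frame data.frame `table` and `events`: `actor_enter`, `fall_onset`,
#'   `stillness_onset`).
#' @export
render_sequence <- function(spec) {
  if (!inherits(spec, "scene_spec")) stop_config("spec must be a scene_spec")
  M <- spec$height; N <- spec$width
  bg <- array(rep(spec$bg_color, each = M * N), c(M, N, 3))
  frames <- vector("list", spec$n_frames)
  tab <- data.frame(frame = 0:(spec$n_frames - 1L), present = FALSE,
                    x = NA_real_, y = NA_real_, w = NA_real_, h = NA_real_,
                    cx = NA_real_, cy = NA_real_, ratio = NA_real_,
                    posture = NA_character_)
  with_seed(spec$seed, {
    for (t in 0:(spec$n_frames - 1L)) {
      fr <- bg
      pose <- actor_pose(spec, t)
      if (!is.null(pose)) {
        am <- actor_mask(spec, pose)
        if (!any(am))
          stop_config("actor left the canvas entirely at frame ", t)
        if (spec$shadow) {
          sm <- shadow_mask(spec, pose) & !am
          for (ch in 1:3) {
            pl <- fr[, , ch]
            pl[sm] <- pl[sm] * spec$shadow_gain
            fr[, , ch] <- pl
          }
        }
        for (ch in 1:3) {
          pl <- fr[, , ch]
          pl[am] <- spec$actor_color[ch]
          fr[, , ch] <- pl
        }
        idx <- which(am, arr.ind = TRUE)
        x0 <- min(idx[, 2]) - 1L; x1 <- max(idx[, 2]) - 1L
        y0 <- min(idx[, 1]) - 1L; y1 <- max(idx[, 1]) - 1L
        w <- x1 - x0 + 1L; h <- y1 - y0 + 1L
        i <- t + 1L
        tab$present[i] <- TRUE
        tab$x[i] <- x0; tab$y[i] <- y0; tab$w[i] <- w; tab$h[i] <- h
        tab$cx[i] <- mean(idx[, 2] - 1L); tab$cy[i] <- mean(idx[, 1] - 1L)
        tab$ratio[i] <- w / h
        tab$posture[i] <- if (w / h < 0.7) "upright"
                          else if (w / h < 1.2) "falling" else "lying"
      }
      if (!is.null(spec$illumination_step) &&
          t >= spec$illumination_step[1])
        fr <- fr * spec$illumination_step[2]
      if (spec$noise_sigma > 0)
        fr <- fr + array(stats::rnorm(length(fr), 0, spec$noise_sigma), dim(fr))
      frames[[t + 1L]] <- pmin(pmax(fr, 0), 255)
    }
  })
  events <- list(actor_enter = spec$waypoints$frame[1],
                 fall_onset = spec$fall_frame,
                 stillness_onset = if (is.na(spec$fall_frame)) NA_integer_
                 else spec$fall_frame + spec$fall_transition)
  list(frames = frames, truth = list(table = tab, events = events))
}

#' Positive/negative patch bank for classifier training
#'
#' Renders `n` upright silhouette crops (positives) and `n` background or
#' clutter crops (negatives) at a given patch size, as grayscale matrices.
#' Positives jitter the silhouette's size and position; negatives mix flat
#' background, intensity gradients and non-human rectangular blobs.
#'
#' @param n patches per class; must be positive.
#' @param size patch size `c(h, w)` (default 24x12, the Haar minimum).
#' @param seed RNG seed; the bank is reproducible.
#' @return list with `pos` and `neg`, each a list of `n` matrices in
#'   `[0, 255]`.
#' @export
patch_bank <- function(n, size = c(24L, 12L), seed = 1L) {
  if (!is.numeric(n) || n < 1L) stop_config("n must be positive")
  h <- size[1]; w <- size[2]
  with_seed(seed, {
    pos <- lapply(seq_len(n), function(i) {
      # emulate pipeline candidate crops: tight-to-loose margins, bright
      # silhouette on darker background, sometimes a dark shadow corner
      bgv <- runif(1, 50, 120)
      fgv <- bgv + runif(1, 30, 110)
      m <- matrix(bgv, h, w)
      ry <- h / 2 * runif(1, 0.82, 1.0)
      rx <- w / 2 * runif(1, 0.75, 1.0)
      cy <- h / 2 + runif(1, -1, 1); cx <- w / 2 + runif(1, -1, 1)
      xs <- matrix(rep(seq_len(w), each = h), h, w)
      ys <- matrix(rep(seq_len(h), w), h, w)
      m[((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1] <- fgv
      if (runif(1) < 0.5) {
        # cast-shadow corner at the feet
        side <- sample(c(1L, 2L), 1)
        rows <- max(1L, h - sample(2:4, 1)):h
        cols <- if (side == 1L) 1:max(1L, w %/% 3L)
                else (w - w %/% 3L + 1L):w
        m[rows, cols] <- pmin(m[rows, cols], bgv * 0.5)
      }
      m + matrix(rnorm(h * w, 0, 3), h, w)
    })
    neg <- lapply(seq_len(n), function(i) {
      kind <- i %% 3L
      m <- if (kind == 0L) matrix(runif(1, 60, 200), h, w)
      else if (kind == 1L) matrix(rep(seq(runif(1, 40, 90),
                                          runif(1, 150, 220),
                                          length.out = w), each = h), h, w)
      else {
        m <- matrix(runif(1, 60, 120), h, w)
        bw <- sample(3:w, 1); bh <- sample(2:max(3L, h %/% 3L), 1)
        x0 <- sample(seq_len(w - bw + 1L), 1); y0 <- sample(seq_len(h - bh + 1L), 1)
        m[y0:(y0 + bh - 1L), x0:(x0 + bw - 1L)] <- runif(1, 150, 220)
        m
      }
      m + matrix(rnorm(h * w, 0, 3), h, w)
    })
    list(pos = lapply(pos, function(p) pmin(pmax(p, 0), 255)),
         neg = lapply(neg, function(p) pmin(pmax(p, 0), 255)))
  })
}
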