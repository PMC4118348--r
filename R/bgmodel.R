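# Adaptive per-pixel Gaussian-mixture background subtraction.
#
# Every pixel is modeled as a mixture of up to G Gaussians over a single
# channel (luminance, or hue treated circularly). Components are kept sorted
# by w/sigma so that high-weight, low-variance components -- the ones that
# explain the stable scene -- sit at the top of the list; the smallest prefix
# whose cumulative weight exceeds T is taken as the background.

#' Default background-model hyper-parameters
#'
#' @param G number of Gaussian components per pixel.
#' @param alpha learning constant in `(0, 1)`; weights and (through
#'   `rho = alpha * eta`) means/variances adapt at this rate.
#' @param c_match match constant: a pixel matches a component when its
#'   distance to the mean is below `c_match * sigma`.
#' @param T_bg proportion of probability mass accounted to the background.
#' @param sigma0 initial/replacement standard deviation (intensity units);
#'   with `c_match = 2.5` it sets the +/- 2.5 * sigma0 match band of freshly
#'   recruited components, e.g. after a step illumination change.
#' @param w0 weight assigned to a replacement component.
#' @param sigma_min floor on component standard deviations.
#' @param learn_frames number of movement-free frames consumed before the
#'   model is considered calibrated (default 40, about 2-3 s of video).
#' @return named list of hyper-parameters.
#' @export
bg_params <- function(G = 3L, alpha = 0.01, c_match = 2.5, T_bg = 0.7,
                      sigma0 = 15, w0 = 0.05, sigma_min = 1,
                      learn_frames = 40L) {
  if (G < 1L) stop_config("G must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop_config("alpha must be in (0, 1)")
  if (c_match <= 0) stop_config("c_match must be positive")
  if (T_bg <= 0 || T_bg >= 1) stop_config("T_bg must be in (0, 1)")
  if (sigma0 <= 0 || sigma_min <= 0) stop_config("sigma values must be positive")
  if (learn_frames < 1L) stop_config("learn_frames must be >= 1")
  list(G = as.integer(G), alpha = alpha, c_match = c_match, T_bg = T_bg,
       sigma0 = sigma0, w0 = w0, sigma_min = sigma_min,
       learn_frames = as.integer(learn_frames))
}

new_pixel_mixture <- function(channel, params, circular) {
  d <- dim(channel)
  P <- prod(d)
  G <- params$G
  mu <- matrix(runif(G * P, 0, if (circular) HUE_RANGE else 255), G, P)
  mu[1, ] <- as.vector(channel)
  sigma <- matrix(params$sigma0, G, P)
  w <- matrix(0, G, P)
  w[1, ] <- 1
  structure(list(mu = mu, sigma = sigma, w = w, dims = d, params = params,
                 circular = circular,
                 range = if (circular) HUE_RANGE else 256,
                 frames_seen = 1L),
            class = "pixel_mixture")
}

#' Initialize a background model from calibration frames
#'
#' The first frame seeds the top component of every pixel's mixture; the
#' remaining components start at seeded random means with zero weight and are
#' recruited as the scene is learned. All supplied frames are consumed with
#' the normal update; the model reports `calibrated = TRUE` once
#' `learn_frames` frames have been seen. Calibration frames are assumed free
#' of movement, and no foreground is emitted during calibration.
#'
#' @param frames list of single-channel frames (matrices), identical shape.
#' @param params hyper-parameters from [bg_params()].
#' @param circular treat the channel as circular (hue) rather than linear
#'   (intensity).
#' @param seed seed for the random initial component means.
#' @return an object of class `pixel_mixture`.
#' @export
bg_init <- function(frames, params = bg_params(), circular = FALSE,
                    seed = 1L) {
  if (!is.list(frames) || length(frames) == 0L)
    stop_config("at least one calibration frame is required")
  d <- dim(frames[[1]])
  for (f in frames) {
    if (!is.matrix(f)) stop_input("calibration frames must be single-channel matrices")
    if (!identical(dim(f), d)) stop_input("calibration frames differ in shape")
  }
  model <- with_seed(seed, new_pixel_mixture(frames[[1]], params, circular))
  for (f in frames[-1]) model <- bg_update(model, f)$model
  model
}

#' @export
print.pixel_mixture <- function(x, ...) {
  cat(sprintf(
    "<pixel_mixture> %dx%d px, G=%d, alpha=%g, T=%g, %s channel, %d frames (%s)\n",
    x$dims[1], x$dims[2], x$params$G, x$params$alpha, x$params$T_bg,
    if (x$circular) "circular" else "linear", x$frames_seen,
    if (bg_calibrated(x)) "calibrated" else "learning"))
  invisible(x)
}

#' Is the model past its learning phase?
#' @param model a `pixel_mixture`.
#' @return logical.
#' @export
bg_calibrated <- function(model) model$frames_seen >= model$params$learn_frames

#' Update the mixture with a new frame and classify its pixels
#'
#' For each pixel the distance `d = |x - mu|` to each component is checked in
#' rank order; the first component with `d < c_match * sigma` is the match.
#' A matched background component gives mask 0 and the component's mean and
#' variance move toward the pixel value at rate `rho = alpha * eta(x | mu,
#' sigma)`; the matched weight follows `w <- (1 - alpha) w + alpha`, all
#' others decay by `(1 - alpha)`. An unmatched pixel gives mask 1 and the
#' least probable component is replaced by one centred at the pixel value.
#' Weights are renormalized and components re-sorted by `w/sigma` after every
#' update.
#'
#' @param model a `pixel_mixture`.
#' @param channel single-channel frame matrix matching the model geometry.
#' @return list with elements `model` (updated) and `mask` (binary matrix;
#'   1 = foreground). During the learning phase the mask is all zero.
#' @export
bg_update <- function(model, channel) {
  if (!inherits(model, "pixel_mixture")) stop_input("model must be a pixel_mixture")
  if (!is.matrix(channel) || !identical(dim(channel), model$dims))
    stop_input("frame shape does not match model geometry")
  if (any(!is.finite(channel))) stop_input("frame contains non-finite pixel values")
  p <- model$params
  # During calibration, matched means/variances follow running-average
  # sufficient statistics (rho = 1/n) so that 40 movement-free frames
  # suffice to tighten the initial sigma to the scene's noise level; once
  # calibrated the update switches to the rho = alpha * eta recursion.
  rho_override <- if (bg_calibrated(model)) -1 else 1 / (model$frames_seen + 1)
  # state matrices are modified in place by the kernel; copy so that the
  # caller's object keeps value semantics
  mu <- model$mu + 0; sigma <- model$sigma + 0; w <- model$w + 0
  mask <- gmm_update_cpp(mu, sigma, w, as.vector(channel),
                         p$alpha, p$c_match, p$T_bg, p$sigma0, p$w0,
                         p$sigma_min, model$circular, model$range,
                         rho_override)
  model$mu <- mu; model$sigma <- sigma; model$w <- w
  learning <- !bg_calibrated(model)
  model$frames_seen <- model$frames_seen + 1L
  m <- matrix(mask, model$dims[1], model$dims[2])
  if (learning) m[] <- 0L
  list(model = model, mask = m)
}

#' Current background estimate
#'
#' Per pixel, the smallest prefix of components (in `w/sigma` order) whose
#' cumulative weight exceeds `T_bg` forms the background; the estimate is
#' their weight-averaged mean.
#'
#' @param model a `pixel_mixture`.
#' @return single-channel frame matrix.
#' @export
bg_background <- function(model) {
  B <- bg_prefix(model)
  G <- model$params$G
  sel <- outer(seq_len(G), B, "<=")          # G x P: component within prefix
  wsel <- model$w * sel
  est <- colSums(model$mu * wsel) / colSums(wsel)
  matrix(est, model$dims[1], model$dims[2])
}

# Number of background components per pixel: B = argmin_b (sum_k w_k > T).
bg_prefix <- function(model) {
  cw <- apply(model$w, 2, cumsum)
  if (is.null(dim(cw))) cw <- matrix(cw, nrow = 1)
  B <- apply(cw > model$params$T_bg, 2, function(z) {
    i <- which(z)
    if (length(i)) i[1] else nrow(cw)
  })
  as.integer(B)
}

#' Shadow-free foreground mask from dual background models
#'
#' A cast shadow darkens the scene but leaves the chrominance of the shaded
#' area unchanged, so it appears in a luminance-based foreground mask but not
#' in a hue-based one. The entrywise product (logical AND) of the two masks
#' therefore removes shadow-only pixels while keeping the true silhouette,
#' which differs from the background in both channels.
#'
#' @param model_lum luminance `pixel_mixture`.
#' @param model_hue hue (circular) `pixel_mixture` on the same geometry.
#' @param frame RGB frame.
#' @return list with `mask` (shadow-free binary matrix), `mask_lum`,
#'   `mask_hue`, and the two updated models (`model_lum`, `model_hue`).
#' @export
bg_shadow_free <- function(model_lum, model_hue, frame) {
  check_frame(frame)
  if (!frame_is_color(frame))
    stop_config("shadow elimination requires a color frame")
  if (!identical(model_lum$dims, model_hue$dims))
    stop_input("luminance and hue models have different geometry")
  up_l <- bg_update(model_lum, frame_luminance(frame))
  up_h <- bg_update(model_hue, frame_hue(frame))
  list(mask = up_l$mask * up_h$mask, mask_lum = up_l$mask,
       mask_hue = up_h$mask, model_lum = up_l$model, model_hue = up_h$model)
}

#' Save / load background-model state
#'
#' Serializes the flat state (component matrices plus hyper-parameters) so a
#' pipeline can be restarted without re-calibration.
#'
#' @param model a `pixel_mixture`.
#' @param path file path.
#' @return `read_bg_model` returns the restored `pixel_mixture`.
#' @export
write_bg_model <- function(model, path) {
  if (!inherits(model, "pixel_mixture")) stop_input("model must be a pixel_mixture")
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname write_bg_model
#' @export
read_bg_model <- function(path) {
  if (!file.exists(path)) stop_io("no such model file: ", path)
  structure(readRDS(path), class = "pixel_mixture")
}
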