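# End-to-end orchestration: configuration, the per-frame processing loop
# (background subtraction -> artifact removal -> classification -> tracking
# -> fall rules -> response), logging and evaluation against ground truth.

#' Full pipeline configuration
#'
#' Bundles every stage's parameters with their defaults: 640x360 capture
#' frames scaled by 0.5 to the 320x180 processing size, 40 movement-free
#' learning frames, a 60-pixel minimum candidate area, 2:1 human
#' proportions, 24x12 / 96x48 Haar and HOG size minima, and a Mean-Shift
#' search area of half the minimum object size.
#'
#' @param scale downscaling factor applied to input frames before
#'   processing.
#' @param min_area minimum candidate area in pixels.
#' @param shadow_elimination use the dual luminance/hue model on color
#'   input (falls back to luminance-only on grayscale).
#' @param bg background-model parameters, [bg_params()].
#' @param classify classification parameters, [classify_params()].
#' @param kernel Mean-Shift kernel, [kernel_params()].
#' @param fall fall rules, [fall_rule_config()].
#' @param response validated [response_rules()].
#' @param search_margin Mean-Shift search half-area `c(mx, my)` in pixels.
#' @param assoc_radius association radius in pixels.
#' @param assoc_appearance minimum Bhattacharyya coefficient between a
#'   track's hue histogram and a candidate's for the pair to be matchable
#'   (0 disables the appearance gate).
#' @param patience frames a track may stay unseen before retirement.
#' @param shrink_guard fraction of the current track-box area below which a
#'   matched detection counts as partial and does not overwrite geometry.
#' @param hue_bins appearance-histogram bins.
#' @param require_human arm fall rules only for tracks classified human
#'   (set `FALSE` to arm all tracks).
#' @param auto_classifiers when the classify config carries no cascade or
#'   template, build the defaults (trained/derived from the synthetic patch
#'   bank) at run start.
#' @param seed seed for model initialization and classifier training.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(scale = 0.5, min_area = 60L,
                            shadow_elimination = TRUE,
                            bg = bg_params(), classify = classify_params(),
                            kernel = kernel_params(),
                            fall = fall_rule_config(),
                            response = response_rules(),
                            search_margin = c(6, 12), assoc_radius = 12,
                            assoc_appearance = 0.4,
                            patience = 15L, shrink_guard = 0.5,
                            hue_bins = 16L,
                            require_human = TRUE, auto_classifiers = TRUE,
                            seed = 1L) {
  if (scale <= 0 || scale > 1) stop_config("scale: must be in (0, 1]")
  if (min_area < 1L) stop_config("min_area: must be >= 1")
  if (patience < 0L) stop_config("patience: must be >= 0")
  if (!inherits(fall, "fall_rule_config")) stop_config("fall: not a fall_rule_config")
  response <- response_rules(response)
  structure(list(scale = scale, min_area = as.integer(min_area),
                 shadow_elimination = isTRUE(shadow_elimination),
                 bg = bg, classify = classify, kernel = kernel, fall = fall,
                 response = response, search_margin = search_margin,
                 assoc_radius = assoc_radius,
                 assoc_appearance = assoc_appearance,
                 patience = as.integer(patience),
                 shrink_guard = shrink_guard, hue_bins = as.integer(hue_bins),
                 require_human = isTRUE(require_human),
                 auto_classifiers = isTRUE(auto_classifiers),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a flat YAML file
#'
#' Keys mirror the [pipeline_config()] arguments, with stage parameters
#' flattened as `bg.alpha`, `fall.k_frames`, `classify.hog_threshold`, etc.
#' Unknown keys raise a configuration error naming the key.
#'
#' @param path YAML file.
#' @param base configuration the file overrides.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, base = pipeline_config()) {
  if (!file.exists(path)) stop_io("no such config file: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) return(base)
  cfg <- unclass(base)
  groups <- c("bg", "classify", "kernel", "fall")
  for (key in names(vals)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) == 2L && parts[1] %in% groups) {
      if (!parts[2] %in% names(cfg[[parts[1]]]))
        stop_config("unknown config key: ", key)
      cfg[[parts[1]]][[parts[2]]] <- vals[[key]]
    } else if (length(parts) == 1L && key %in% names(cfg)) {
      cfg[[key]] <- vals[[key]]
    } else stop_config("unknown config key: ", key)
  }
  # re-validate through the constructors
  pipeline_config(scale = cfg$scale, min_area = cfg$min_area,
                  shadow_elimination = cfg$shadow_elimination,
                  bg = do.call(bg_params, cfg$bg),
                  classify = do.call(classify_params, cfg$classify),
                  kernel = do.call(kernel_params, cfg$kernel),
                  fall = do.call(fall_rule_config, unclass(cfg$fall)),
                  response = cfg$response,
                  search_margin = cfg$search_margin,
                  assoc_radius = cfg$assoc_radius,
                  assoc_appearance = cfg$assoc_appearance,
                  patience = cfg$patience,
                  shrink_guard = cfg$shrink_guard,
                  hue_bins = cfg$hue_bins, require_human = cfg$require_human,
                  auto_classifiers = cfg$auto_classifiers, seed = cfg$seed)
}

.fw_cache <- new.env(parent = emptyenv())

#' Default HOG silhouette template
#'
#' A noise-free upright 2:1 ellipse silhouette rendered at the 96x48 HOG
#' minimum size, with its descriptor precomputed. The silhouette fills the
#' window at the same relative scale a classification crop has after its
#' 15% context margin, so template and candidate are registered.
#' Deterministic and cached.
#'
#' @param margin fractional context margin the classifier adds around
#'   candidate boxes; the silhouette is scaled by `1 / (1 + 2 * margin)`.
#' @return a `hog_descriptor`.
#' @export
default_hog_template <- function(margin = 0.15) {
  key <- paste0("template_", margin)
  if (is.null(.fw_cache[[key]])) {
    h <- 96L; w <- 48L
    fill <- 1 / (1 + 2 * margin)
    m <- matrix(90, h, w)
    xs <- matrix(rep(seq_len(w), each = h), h, w)
    ys <- matrix(rep(seq_len(h), w), h, w)
    m[((xs - w / 2) / (w / 2 * fill))^2 +
        ((ys - h / 2) / (h / 2 * fill))^2 <= 1] <- 180
    .fw_cache[[key]] <- hog_descriptor(m)
  }
  .fw_cache[[key]]
}

#' Default Haar cascade
#'
#' A small boosted cascade trained on the synthetic patch bank (silhouette
#' positives vs background/clutter negatives) at the 24x12 base window, so
#' the pipeline is self-contained. Deterministic for a given seed; cached.
#'
#' @param seed training seed.
#' @return a `haar_cascade`.
#' @export
default_haar_cascade <- function(seed = 1L) {
  key <- paste0("cascade_", seed)
  if (is.null(.fw_cache[[key]])) {
    bank <- patch_bank(60, size = c(24L, 12L), seed = seed)
    .fw_cache[[key]] <- train_haar_cascade(bank$pos, bank$neg,
                                           window = c(24L, 12L), seed = seed)
  }
  .fw_cache[[key]]
}

#' Run the fall-detection pipeline on a frame sequence
#'
#' Executes the full processing loop: set parameters, open the input, build
#' the background model(s) on the leading movement-free frames, then per
#' frame localize foreground areas, classify detected objects with Haar and
#' HOG, track them (Mean-Shift when no fresh detection matches), check the
#' fall thresholds and raise the alarm. Frames are consumed strictly
#' sequentially -- no stage looks ahead.
#'
#' @param input directory of numbered PNG/JPEG frames, or a list of frames.
#' @param config a [pipeline_config()].
#' @param log_jsonl,log_csv optional event-log output paths.
#' @return object of class `fall_run`: list with `events`, `responses`,
#'   `track_table` (per-frame per-track measurements), `frames_processed`,
#'   `tracks_created`, `timing` (seconds per stage) and the resolved
#'   `config`.
#' @export
run_pipeline <- function(input, config = pipeline_config(),
                         log_jsonl = NULL, log_csv = NULL) {
  if (!inherits(config, "pipeline_config"))
    stop_config("config must be a pipeline_config")
  frames <- if (is.character(input)) read_frame_dir(input) else input
  if (!is.list(frames) || length(frames) == 0L)
    stop_io("input is empty: no frames to process")
  classify <- config$classify
  if (config$auto_classifiers) {
    if (is.null(classify$cascade))
      classify$cascade <- default_haar_cascade(config$seed)
    if (is.null(classify$template)) classify$template <- default_hog_template()
  }
  color <- frame_is_color(frames[[1]])
  dual <- config$shadow_elimination && color

  model_lum <- NULL; model_hue <- NULL
  tracks <- list(); next_id <- 1L
  tracks_created <- 0L
  events <- list(); responses <- list()
  tt <- vector("list", length(frames))
  timing <- c(background = 0, postproc = 0, classify_track = 0, events = 0)

  for (t0 in seq_along(frames)) {
    t <- t0 - 1L
    fr <- downscale(frames[[t0]], config$scale)
    p0 <- proc.time()[["elapsed"]]
    lum <- frame_luminance(fr)
    hsv <- if (color) frame_hsv(fr) else NULL
    if (is.null(model_lum)) {
      model_lum <- bg_init(list(lum), config$bg, seed = config$seed)
      if (dual) model_hue <- bg_init(list(hsv$h), config$bg, circular = TRUE,
                                     seed = config$seed + 1L)
      next
    }
    up <- bg_update(model_lum, lum); model_lum <- up$model
    mask <- up$mask
    if (dual) {
      uph <- bg_update(model_hue, hsv$h); model_hue <- uph$model
      mask <- mask * uph$mask
    }
    p1 <- proc.time()[["elapsed"]]; timing["background"] <- timing["background"] + p1 - p0
    cands <- list()
    if (any(mask > 0)) {
      cleaned <- clean_mask(mask)
      cands <- extract_candidates(cleaned, config$min_area)
    }
    p2 <- proc.time()[["elapsed"]]; timing["postproc"] <- timing["postproc"] + p2 - p1

    compat <- NULL
    if (color && config$assoc_appearance > 0 && length(tracks) &&
        length(cands)) {
      chists <- lapply(cands, function(cnd)
        hue_histogram(hsv, cnd$bbox, config$hue_bins))
      compat <- matrix(TRUE, length(tracks), length(cands))
      for (i in seq_along(tracks)) for (j in seq_along(cands))
        compat[i, j] <- sum(sqrt(tracks[[i]]$hist * chists[[j]])) >=
          config$assoc_appearance
    }
    assoc <- associate(tracks, cands, radius = config$assoc_radius,
                       patience = config$patience, frame_size = dim(lum),
                       next_id = next_id, min_area = config$min_area,
                       compat = compat)
    if (nrow(assoc$matches))
      for (k in seq_len(nrow(assoc$matches))) {
        i <- assoc$matches$track[k]; j <- assoc$matches$candidate[k]
        tracks[[i]]$frames_since_seen <- 0L
        bb <- tracks[[i]]$bbox
        # a detection much smaller than the track is a partial one (e.g. a
        # static person half-absorbed into the background): hold the last
        # geometry, but still log the position so speed reflects stillness
        if (cands[[j]]$area >= config$shrink_guard * bb[["w"]] * bb[["h"]])
          tracks[[i]] <- append_track_point(tracks[[i]], t,
                                            cands[[j]]$centroid,
                                            cands[[j]]$bbox)
        else
          tracks[[i]] <- append_track_point(tracks[[i]], t,
                                            tracks[[i]]$centroid, bb)
        if (identical(tracks[[i]]$label, "indeterminate"))
          tracks[[i]]$label <- as.character(
            classify_candidate(cands[[j]], fr, classify))
      }
    for (i in assoc$unmatched_tracks) {
      if (assoc$retired[i]) next
      if (color)
        tracks[[i]] <- track_object(tracks[[i]], fr, t, config$kernel,
                                    config$search_margin, hsv = hsv)
      else tracks[[i]]$frames_since_seen <- tracks[[i]]$frames_since_seen + 1L
    }
    keep <- !assoc$retired
    tracks <- tracks[keep]
    for (j in assoc$new_candidates) {
      tr <- new_track(next_id, cands[[j]], hsv, t, config$hue_bins)
      tr$label <- as.character(classify_candidate(cands[[j]], fr, classify))
      tr$detector <- new_fall_detector(config$fall)
      tracks[[length(tracks) + 1L]] <- tr
      next_id <- next_id + 1L
      tracks_created <- tracks_created + 1L
    }
    p3 <- proc.time()[["elapsed"]]
    timing["classify_track"] <- timing["classify_track"] + p3 - p2

    rows <- list()
    for (i in seq_along(tracks)) {
      tr <- tracks[[i]]
      spd <- speed(tr$trajectory, config$fall$ratio_window)
      armed <- !config$require_human || identical(tr$label, "human")
      if (armed) {
        if (is.null(tr$detector)) tr$detector <- new_fall_detector(config$fall)
        res <- fall_detector_step(tr$detector, t, tr$bbox, spd, tr$id)
        tr$detector <- res$detector
        if (!is.null(res$event)) {
          events[[length(events) + 1L]] <- res$event
          responses <- c(responses,
                         dispatch_response(res$event, config$response))
        }
      }
      tracks[[i]] <- tr
      rows[[i]] <- data.frame(
        frame = t, id = tr$id, x = tr$bbox[["x"]], y = tr$bbox[["y"]],
        w = tr$bbox[["w"]], h = tr$bbox[["h"]],
        ratio = aspect_ratio(tr$bbox),
        smoothed_ratio = if (is.null(tr$detector)) NA_real_
                         else tr$detector$smoothed,
        posture = if (is.null(tr$detector) || is.null(tr$detector$state))
          NA_character_ else tr$detector$state$posture,
        speed = as.numeric(spd), label = tr$label,
        seen = tr$frames_since_seen == 0L)
    }
    tt[[t0]] <- if (length(rows)) do.call(rbind, rows) else NULL
    p4 <- proc.time()[["elapsed"]]; timing["events"] <- timing["events"] + p4 - p3
  }
  track_table <- do.call(rbind, tt[!vapply(tt, is.null, logical(1))])
  if (is.null(track_table))
    track_table <- data.frame(frame = integer(0), id = integer(0))
  out <- structure(list(events = events, responses = responses,
                        track_table = track_table,
                        frames_processed = length(frames),
                        tracks_created = tracks_created,
                        timing = timing, config = config),
                   class = "fall_run")
  if (!is.null(log_jsonl) || !is.null(log_csv))
    write_event_log(events, log_jsonl, log_csv)
  out
}

#' @export
print.fall_run <- function(x, ...) {
  cat(sprintf("<fall_run> %d frames, %d track(s), %d fall event(s)\n",
              x$frames_processed, x$tracks_created, length(x$events)))
  for (e in x$events)
    cat(sprintf("  fall: track %d, trigger frame %d (onset %d), ratio %.2f, speed %.2f px/frame\n",
                e$track_id, e$trigger_frame, e$onset_frame, e$aspect_ratio,
                e$speed_px_per_frame))
  invisible(x)
}

#' Compare a run's event log against scene ground truth
#'
#' Computes detection (was a fall alarmed after the true stillness onset),
#' alarm latency in frames relative to the stillness onset, and the number
#' of false alarms (events in a walk-only scene, or before the fall).
#'
#' @param run a `fall_run`.
#' @param truth ground truth from [render_sequence()].
#' @return one-row data.frame with `n_events`, `detected`, `latency_frames`,
#'   `false_alarms`.
#' @export
eval_run <- function(run, truth) {
  ev <- run$events
  onset <- truth$events$stillness_onset
  trig <- vapply(ev, function(e) e$trigger_frame, numeric(1))
  if (is.na(onset)) {
    data.frame(n_events = length(ev), detected = NA,
               latency_frames = NA_real_, false_alarms = length(ev))
  } else {
    good <- trig >= onset
    data.frame(n_events = length(ev), detected = any(good),
               latency_frames = if (any(good)) min(trig[good]) - onset
                                else NA_real_,
               false_alarms = sum(!good))
  }
}
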