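# Fall/faint detection from track geometry: aspect-ratio parameter P,
# persistence parameter K, centroid speed and bounding-box area, plus the
# rule-based response dispatch.

#' Fall-rule configuration
#'
#' Parameter `P` is the bounding-box aspect ratio (width/height): a standing
#' person measures about 0.5, values above `p_fall` signal a fall in
#' progress and values above `p_lying` a person lying on the floor.
#' Parameter `K` (`k_frames`) is the number of consecutive frames the
#' changed, motionless posture must persist before the alarm fires; its
#' legal band is 50-150 frames, i.e. 2-10 s at the 15 fps reference rate.
#'
#' @param p_fall aspect-ratio threshold leaving the upright posture.
#' @param p_lying aspect-ratio threshold for the lying posture.
#' @param k_frames persistence in frames before the alarm; must lie in
#'   `[50, 150]`.
#' @param fps frame rate the defaults are calibrated for.
#' @param speed_still centroid speed (px/frame at the 320-px processing
#'   width) below which the person counts as motionless.
#' @param area_change_frac relative bounding-box area change treated as a
#'   posture change cue (logged with events).
#' @param ratio_window frames over which the aspect ratio is smoothed
#'   (1-2 s of video).
#' @param ratio_stable_tol maximum per-frame drift of the smoothed ratio for
#'   the proportions to count as unchanged.
#' @return named list of class `fall_rule_config`.
#' @export
fall_rule_config <- function(p_fall = 0.7, p_lying = 1.2, k_frames = 50L,
                             fps = 15, speed_still = 1.5,
                             area_change_frac = 0.2, ratio_window = 15L,
                             ratio_stable_tol = 0.05) {
  if (!(p_fall > 0 && p_fall < p_lying))
    stop_config("need 0 < p_fall < p_lying")
  if (k_frames < 50L || k_frames > 150L)
    stop_config("k_frames must be between 50 and 150 frames")
  if (ratio_window < 1L) stop_config("ratio_window must be >= 1")
  if (speed_still <= 0) stop_config("speed_still must be positive")
  structure(list(p_fall = p_fall, p_lying = p_lying,
                 k_frames = as.integer(k_frames), fps = fps,
                 speed_still = speed_still,
                 area_change_frac = area_change_frac,
                 ratio_window = as.integer(ratio_window),
                 ratio_stable_tol = ratio_stable_tol),
            class = "fall_rule_config")
}

#' Bounding-box aspect ratio (parameter P)
#'
#' Width divided by height: close to 0.5 for a standing person, above 1 for
#' a person lying on the floor.
#'
#' @param bbox `c(x, y, w, h)`.
#' @return numeric ratio, or `NA` for a degenerate box.
#' @export
aspect_ratio <- function(bbox) {
  w <- bbox[["w"]]; h <- bbox[["h"]]
  if (!is.finite(w) || !is.finite(h) || w <= 0 || h <= 0) return(NA_real_)
  w / h
}

#' Centroid speed over a trailing window
#'
#' Mean Euclidean displacement of the bounding-box center between successive
#' frames, in px/frame.
#'
#' @param trajectory matrix with columns `cx`, `cy` (one row per frame).
#' @param window number of trailing displacement steps to average.
#' @return speed in px/frame; 0 with attribute `cold = TRUE` when fewer than
#'   two points are available.
#' @export
speed <- function(trajectory, window = 5L) {
  n <- nrow(trajectory)
  if (is.null(n) || n < 2L) return(structure(0, cold = TRUE))
  i0 <- max(2L, n - window + 1L)
  dx <- diff(trajectory[(i0 - 1L):n, "cx"])
  dy <- diff(trajectory[(i0 - 1L):n, "cy"])
  mean(sqrt(dx^2 + dy^2))
}

#' Posture from the smoothed aspect ratio
#'
#' upright when `ratio < p_fall`; falling when `p_fall <= ratio < p_lying`;
#' lying when `ratio >= p_lying`; unknown for a degenerate ratio.
#'
#' @param state current posture state (list with `posture`, `entered_at`),
#'   or `NULL` to start one.
#' @param ratio smoothed aspect ratio.
#' @param config a `fall_rule_config`.
#' @param frame_idx current frame index.
#' @return posture state list with `posture` and `entered_at`.
#' @export
update_posture <- function(state, ratio, config = fall_rule_config(),
                           frame_idx = 0L) {
  posture <- if (!is.finite(ratio)) "unknown"
  else if (ratio < config$p_fall) "upright"
  else if (ratio < config$p_lying) "falling"
  else "lying"
  if (is.null(state) || !identical(state$posture, posture))
    list(posture = posture, entered_at = frame_idx)
  else state
}

# Per-track fall detector state machine. Step it once per frame; it keeps
# the smoothed ratio, posture, persistence counter and alarm latch.
new_fall_detector <- function(config = fall_rule_config()) {
  list(config = config, ratios = numeric(0), smoothed = NA_real_,
       state = NULL, counter = 0L, fired = FALSE, area_ref = NA_real_)
}

# Advance the detector. Returns list(detector, event): `event` is NULL or a
# fall_event list. All three conditions -- non-upright posture, speed below
# speed_still, stable smoothed ratio -- must hold for k_frames + 1
# consecutive frames, so the trigger lands exactly k_frames after the onset.
fall_detector_step <- function(det, frame_idx, bbox, spd, track_id = NA_integer_) {
  cfg <- det$config
  r <- aspect_ratio(bbox)
  det$ratios <- c(det$ratios, r)
  n <- length(det$ratios)
  win <- det$ratios[max(1L, n - cfg$ratio_window + 1L):n]
  prev_smoothed <- det$smoothed
  det$smoothed <- if (all(is.finite(win))) mean(win) else NA_real_
  det$state <- update_posture(det$state, det$smoothed, cfg, frame_idx)
  area <- bbox[["w"]] * bbox[["h"]]
  if (is.na(det$area_ref)) det$area_ref <- area
  # the jump into the fall band is itself the onset, so the stability
  # requirement applies to continuation frames only
  stable <- is.finite(det$smoothed) &&
    (det$counter == 0L || !is.finite(prev_smoothed) ||
       abs(det$smoothed - prev_smoothed) < cfg$ratio_stable_tol)
  cond <- det$state$posture %in% c("falling", "lying") &&
    spd < cfg$speed_still && stable
  event <- NULL
  if (cond) {
    det$counter <- det$counter + 1L
    if (det$counter == cfg$k_frames + 1L && !det$fired) {
      det$fired <- TRUE
      rule <- paste0("P>", cfg$p_fall, "&speed<", cfg$speed_still,
                     "&K=", cfg$k_frames)
      event <- list(track_id = track_id, trigger_frame = frame_idx,
                    onset_frame = frame_idx - cfg$k_frames,
                    rule = rule, event_type = "fall",
                    aspect_ratio = det$smoothed, area_px = area,
                    area_change = (area - det$area_ref) / det$area_ref,
                    speed_px_per_frame = as.numeric(spd),
                    posture = det$state$posture,
                    bbox = bbox)
    }
  } else {
    det$counter <- 0L
    # the person got up and moves normally: release the alarm latch
    if (det$fired && identical(det$state$posture, "upright"))
      det$fired <- FALSE
  }
  list(detector = det, event = event)
}

#' Detect falls on a per-frame geometry timeline
#'
#' Convenience wrapper running the per-track fall state machine over a table
#' of bounding boxes: posture must leave upright (smoothed width/height
#' ratio at or above `p_fall`), the centroid must be still, and the smoothed
#' ratio stable, for `k_frames` consecutive frames past the onset before an
#' alarm is emitted. The alarm is not re-emitted while the condition
#' persists and is released when the person resumes upright movement.
#'
#' @param timeline data.frame with columns `frame`, `x`, `y`, `w`, `h` (one
#'   row per frame, 0-based bbox).
#' @param config a `fall_rule_config`.
#' @param track_id id recorded in emitted events.
#' @return list of fall events (possibly empty).
#' @export
detect_falls <- function(timeline, config = fall_rule_config(),
                         track_id = 1L) {
  need <- c("frame", "x", "y", "w", "h")
  if (!all(need %in% names(timeline)))
    stop_input("timeline needs columns ", paste(need, collapse = ", "))
  det <- new_fall_detector(config)
  traj <- NULL
  events <- list()
  for (i in seq_len(nrow(timeline))) {
    bb <- c(x = timeline$x[i], y = timeline$y[i], w = timeline$w[i],
            h = timeline$h[i])
    ctr <- c(cx = bb[["x"]] + bb[["w"]] / 2, cy = bb[["y"]] + bb[["h"]] / 2)
    traj <- rbind(traj, c(cx = ctr[[1]], cy = ctr[[2]]))
    res <- fall_detector_step(det, timeline$frame[i], bb,
                              speed(traj, config$ratio_window), track_id)
    det <- res$detector
    if (!is.null(res$event)) events[[length(events) + 1L]] <- res$event
  }
  events
}

#' Validate response rules
#'
#' Responses are configurable logged actions only; the recognised types
#' mirror the actions a deployed system would take (phone call, siren,
#' email, text, loudspeaker message, control signal) plus `log` and
#' `write-snapshot`.
#'
#' @param rules character vector of action types.
#' @return the validated rules (invisibly classed).
#' @export
response_rules <- function(rules = c("log")) {
  allowed <- c("log", "write-snapshot", "phone-call", "siren", "email",
               "text-message", "loudspeaker", "control-signal")
  bad <- setdiff(rules, allowed)
  if (length(bad))
    stop_config("unknown response action type(s): ", paste(bad, collapse = ", "))
  structure(as.character(rules), class = "response_rules")
}

#' Dispatch configured responses for a fall event
#'
#' Renders each configured action as a structured record; no real side
#' effects are performed.
#'
#' @param event a fall event (from [detect_falls()] or the pipeline).
#' @param rules validated [response_rules()].
#' @return list of action records (`type`, `timestamp`, `event`).
#' @export
dispatch_response <- function(event, rules = response_rules()) {
  if (is.null(event)) stop_input("event must be present")
  if (!inherits(rules, "response_rules")) rules <- response_rules(rules)
  lapply(as.character(rules), function(r)
    list(type = r, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
         event = event))
}

# Event-log export ------------------------------------------------------------

events_to_df <- function(events) {
  if (length(events) == 0L)
    return(data.frame(frame_index = integer(0), track_id = integer(0),
                      event_type = character(0), x = integer(0),
                      y = integer(0), w = integer(0), h = integer(0),
                      aspect_ratio = numeric(0), area_px = numeric(0),
                      speed_px_per_frame = numeric(0), posture = character(0),
                      rule_fired = character(0)))
  do.call(rbind, lapply(events, function(e)
    data.frame(frame_index = e$trigger_frame, track_id = e$track_id,
               event_type = e$event_type, x = e$bbox[["x"]], y = e$bbox[["y"]],
               w = e$bbox[["w"]], h = e$bbox[["h"]],
               aspect_ratio = e$aspect_ratio, area_px = e$area_px,
               speed_px_per_frame = e$speed_px_per_frame,
               posture = e$posture, rule_fired = e$rule)))
}

#' Write an event log as JSON-lines and CSV
#'
#' @param events list of fall events.
#' @param jsonl_path,csv_path output paths (`NULL` to skip either).
#' @return invisibly, the event data.frame.
#' @export
write_event_log <- function(events, jsonl_path = NULL, csv_path = NULL) {
  df <- events_to_df(events)
  if (!is.null(jsonl_path)) {
    con <- file(jsonl_path, "w")
    on.exit(close(con), add = TRUE)
    for (i in seq_len(nrow(df)))
      writeLines(jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE,
                                  digits = NA), con)
  }
  if (!is.null(csv_path)) write.csv(df, csv_path, row.names = FALSE)
  invisible(df)
}
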