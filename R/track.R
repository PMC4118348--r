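# Mean-Shift tracking with hue-histogram back-projection, plus track-list
# management (greedy association, labeling, retirement).

#' Mean-Shift kernel parameters
#'
#' @param bandwidth Gaussian kernel bandwidth `h` in pixels;
#'   `K(u) = exp(-||u||^2 / h^2)`.
#' @param max_iter maximum Mean-Shift iterations per frame.
#' @param eps convergence tolerance in pixels.
#' @return named list.
#' @export
kernel_params <- function(bandwidth = 8, max_iter = 25L, eps = 0.1) {
  if (bandwidth <= 0 || eps <= 0) stop_config("bandwidth and eps must be positive")
  list(bandwidth = bandwidth, max_iter = as.integer(max_iter), eps = eps)
}

#' One Mean-Shift iteration
#'
#' Moves the center to the kernel- and weight-weighted mean of pixel
#' coordinates inside the window:
#' `m(x) = sum K(x_i - x) w_i x_i / sum K(x_i - x) w_i`.
#'
#' @param weights non-negative matrix (e.g., a histogram back-projection).
#' @param center current center `c(cx, cy)` in 0-based pixel coordinates.
#' @param window bbox `c(x, y, w, h)` (0-based, half-open) restricting the
#'   neighborhood; clipped to the frame.
#' @param kernel from [kernel_params()].
#' @return new center `c(cx, cy)`, or `NULL` when the weighted mass in the
#'   window is zero (lost-track signal).
#' @export
meanshift_step <- function(weights, center, window, kernel = kernel_params()) {
  M <- nrow(weights); N <- ncol(weights)
  x0 <- max(0L, floor(window[["x"]])); y0 <- max(0L, floor(window[["y"]]))
  x1 <- min(N - 1L, ceiling(window[["x"]] + window[["w"]] - 1))
  y1 <- min(M - 1L, ceiling(window[["y"]] + window[["h"]] - 1))
  if (x1 < x0 || y1 < y0) return(NULL)
  sub <- weights[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), drop = FALSE]
  ys <- y0:y1; xs <- x0:x1
  dy2 <- (ys - center[2])^2
  dx2 <- (xs - center[1])^2
  K <- exp(-(outer(dy2, dx2, "+")) / kernel$bandwidth^2)
  kw <- K * sub
  tot <- sum(kw)
  if (tot <= 0) return(NULL)
  c(cx = sum(t(kw) * xs) / tot, cy = sum(kw * ys) / tot)
}

#' Iterate Mean-Shift to convergence
#'
#' @inheritParams meanshift_step
#' @return list with `center`, `iterations`, `converged`, `mass` (total
#'   kernel-weighted mass at the final position), or `NULL` on zero mass.
#' @export
meanshift_converge <- function(weights, center, window, kernel = kernel_params()) {
  for (it in seq_len(kernel$max_iter)) {
    nc <- meanshift_step(weights, center, window, kernel)
    if (is.null(nc)) return(NULL)
    shift <- sqrt(sum((nc - center)^2))
    center <- nc
    # keep the window centred on the estimate as it moves
    window[["x"]] <- center[1] - window[["w"]] / 2
    window[["y"]] <- center[2] - window[["h"]] / 2
    if (shift < kernel$eps)
      return(list(center = center, iterations = it, converged = TRUE))
  }
  list(center = center, iterations = kernel$max_iter, converged = FALSE)
}

#' Hue histogram appearance model
#'
#' Histogram over `bins` equal hue intervals of the pixels inside a bounding
#' box; low-saturation and dark pixels, whose hue is unreliable, are
#' excluded. Normalized to sum 1 (uniform if nothing qualifies).
#'
#' @param hsv HSV decomposition of the frame (list `h`, `s`, `v` as produced
#'   internally; `h` in `[0, 256)`).
#' @param bbox `c(x, y, w, h)` 0-based half-open.
#' @param bins number of hue bins.
#' @param s_floor,v_floor saturation (0-1) and value (0-255) floors.
#' @return numeric vector of length `bins`.
#' @export
hue_histogram <- function(hsv, bbox, bins = 16L, s_floor = 0.1, v_floor = 20) {
  x0 <- bbox[["x"]] + 1L; y0 <- bbox[["y"]] + 1L
  x1 <- min(ncol(hsv$h), x0 + bbox[["w"]] - 1L)
  y1 <- min(nrow(hsv$h), y0 + bbox[["h"]] - 1L)
  h <- hsv$h[y0:y1, x0:x1]; s <- hsv$s[y0:y1, x0:x1]; v <- hsv$v[y0:y1, x0:x1]
  ok <- s >= s_floor & v >= v_floor
  if (!any(ok)) return(rep(1 / bins, bins))
  b <- pmin(floor(h[ok] / (HUE_RANGE / bins)), bins - 1L) + 1L
  out <- tabulate(b, nbins = bins)
  out / sum(out)
}

# Per-pixel likelihood of belonging to the appearance model.
back_project <- function(hsv, hist, s_floor = 0.1, v_floor = 20) {
  bins <- length(hist)
  b <- pmin(floor(hsv$h / (HUE_RANGE / bins)), bins - 1L) + 1L
  w <- matrix(hist[b], nrow(hsv$h), ncol(hsv$h))
  w[hsv$s < s_floor | hsv$v < v_floor] <- 0
  w
}

#' Create a tracked object
#'
#' @param id unique positive integer label.
#' @param cand candidate region the track is acquired from.
#' @param hsv HSV decomposition of the acquisition frame.
#' @param frame_idx acquisition frame index.
#' @param bins hue histogram bins.
#' @return object of class `tracked_object`.
#' @export
new_track <- function(id, cand, hsv = NULL, frame_idx = 0L, bins = 16L) {
  hist <- if (is.null(hsv)) rep(1 / bins, bins)
          else hue_histogram(hsv, cand$bbox, bins)
  structure(list(id = as.integer(id), bbox = cand$bbox,
                 centroid = cand$centroid, hist = hist,
                 trajectory = matrix(c(frame_idx, cand$centroid, cand$bbox),
                                     nrow = 1,
                                     dimnames = list(NULL, c("frame", "cx",
                                                             "cy", "x", "y",
                                                             "w", "h"))),
                 frames_since_seen = 0L, label = "indeterminate",
                 detector = NULL),
            class = "tracked_object")
}

append_track_point <- function(obj, frame_idx, centroid, bbox) {
  obj$centroid <- centroid
  obj$bbox <- bbox
  obj$trajectory <- rbind(obj$trajectory,
                          c(frame_idx, centroid, bbox))
  obj
}

#' Track an object by Mean-Shift on its appearance model
#'
#' The hue histogram recorded at acquisition is back-projected onto the
#' frame; Mean-Shift runs from the last known position, restricted to the
#' configured search margin around it, and the bounding box is recentred on
#' the converged mode. On zero back-projected mass or non-convergence the
#' object is marked unseen this frame.
#'
#' @param obj a `tracked_object`.
#' @param frame color frame.
#' @param frame_idx current frame index.
#' @param kernel from [kernel_params()].
#' @param search_margin `c(mx, my)`: half-size of the extra search area
#'   around the last box, in x and y. The default is half the minimum
#'   object size (12 wide x 24 tall halves to 6 x 12).
#' @param hsv optional precomputed HSV decomposition of `frame`.
#' @return updated `tracked_object`; `frames_since_seen` is reset on success
#'   and incremented on a lost frame.
#' @export
track_object <- function(obj, frame, frame_idx, kernel = kernel_params(),
                         search_margin = c(6, 12), hsv = NULL) {
  if (!inherits(obj, "tracked_object")) stop_input("obj must be a tracked_object")
  if (is.null(hsv)) hsv <- frame_hsv(frame)
  w <- back_project(hsv, obj$hist)
  bb <- obj$bbox
  window <- c(x = bb[["x"]] - search_margin[1], y = bb[["y"]] - search_margin[2],
              w = bb[["w"]] + 2 * search_margin[1],
              h = bb[["h"]] + 2 * search_margin[2])
  res <- meanshift_converge(w, obj$centroid, window, kernel)
  if (is.null(res) || !res$converged) {
    obj$frames_since_seen <- obj$frames_since_seen + 1L
    return(obj)
  }
  nb <- c(x = res$center[[1]] - bb[["w"]] / 2,
          y = res$center[[2]] - bb[["h"]] / 2, w = bb[["w"]], h = bb[["h"]])
  obj$frames_since_seen <- 0L
  append_track_point(obj, frame_idx, c(cx = res$center[[1]],
                                       cy = res$center[[2]]), nb)
}

#' Associate candidate regions with existing tracks
#'
#' Greedy nearest-centroid matching: the globally closest track/candidate
#' pair within `radius` is matched first, and so on. Unmatched candidates at
#' least `min_area` pixels spawn new tracks with fresh ids; tracks unseen
#' longer than `patience` frames, or whose center has left the frame, are
#' retired.
#'
#' @param tracks list of `tracked_object`s.
#' @param candidates list of candidate regions.
#' @param radius maximum centroid distance in pixels for a match.
#' @param patience frames a track may remain unseen before retirement.
#' @param frame_size `c(M, N)` of the frame, for the leaving-the-frame test
#'   (`NULL` disables it).
#' @param next_id first id for newly spawned tracks.
#' @param min_area minimum candidate area to spawn a track.
#' @param compat optional logical matrix (tracks x candidates): pairs marked
#'   `FALSE` are never matched. Used to gate matching on appearance so that
#'   a background-colored ghost region cannot capture a tracked person.
#' @return list with `matches` (data.frame track index / candidate index),
#'   `unmatched_tracks`, `new_candidates` (indices spawning tracks) and
#'   `retired` (logical per track, after accounting for this frame's misses).
#' @export
associate <- function(tracks, candidates, radius = 12, patience = 15L,
                      frame_size = NULL, next_id = 1L, min_area = 60L,
                      compat = NULL) {
  nt <- length(tracks); nc <- length(candidates)
  matches <- data.frame(track = integer(0), candidate = integer(0))
  if (nt > 0L && nc > 0L) {
    D <- matrix(Inf, nt, nc)
    for (i in seq_len(nt)) for (j in seq_len(nc))
      D[i, j] <- sqrt(sum((tracks[[i]]$centroid - candidates[[j]]$centroid)^2))
    if (!is.null(compat)) D[!compat] <- Inf
    while (TRUE) {
      m <- which(D == min(D), arr.ind = TRUE)[1, , drop = TRUE]
      if (!is.finite(D[m[1], m[2]]) || D[m[1], m[2]] > radius) break
      matches <- rbind(matches,
                       data.frame(track = m[[1]], candidate = m[[2]]))
      D[m[1], ] <- Inf; D[, m[2]] <- Inf
      if (all(!is.finite(D))) break
    }
  }
  unmatched_tracks <- setdiff(seq_len(nt), matches$track)
  new_candidates <- setdiff(seq_len(nc), matches$candidate)
  new_candidates <- new_candidates[vapply(candidates[new_candidates],
                                          function(cnd) cnd$area >= min_area,
                                          logical(1))]
  retired <- rep(FALSE, nt)
  for (i in unmatched_tracks) {
    miss <- tracks[[i]]$frames_since_seen + 1L
    out_of_frame <- FALSE
    if (!is.null(frame_size)) {
      ctr <- tracks[[i]]$centroid
      out_of_frame <- ctr[1] < 0 || ctr[2] < 0 ||
        ctr[1] >= frame_size[2] || ctr[2] >= frame_size[1]
    }
    retired[i] <- miss > patience || out_of_frame
  }
  list(matches = matches, unmatched_tracks = unmatched_tracks,
       new_candidates = new_candidates, retired = retired,
       next_id = next_id + length(new_candidates))
}
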