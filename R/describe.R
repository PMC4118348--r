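# HOG descriptor, Haar-like features, and the human/non-human routing of
# candidate regions.

#' Image gradients for HOG
#'
#' Vertical edges from the `[-1, 0, 1]` horizontal filter, horizontal edges
#' from its transpose; borders are edge-replicated. The magnitude is
#' `sqrt(Ix^2 + Iy^2)` and the orientation `atan(Iy / Ix)` in
#' `(-pi/2, pi/2]`, with `Ix = 0` mapped to `pi/2`.
#'
#' @param image single-channel matrix, at least 3x3.
#' @return list with matrices `ix`, `iy`, `magnitude`, `theta` (signed) and
#'   `theta_u` (folded to `[0, pi)` for unsigned orientation bins).
#' @export
gradients <- function(image) {
  if (!is.matrix(image)) stop_input("gradients require a single-channel image")
  if (any(dim(image) < 3L)) stop_input("image must be at least 3x3")
  M <- nrow(image); N <- ncol(image)
  right <- image[, c(2:N, N)]
  left  <- image[, c(1, 1:(N - 1))]
  down  <- image[c(2:M, M), ]
  up    <- image[c(1, 1:(M - 1)), ]
  ix <- right - left
  iy <- down - up
  mag <- sqrt(ix^2 + iy^2)
  theta <- atan(iy / ix)
  theta[ix == 0] <- pi / 2
  theta_u <- theta + pi * (theta < 0)
  theta_u[theta_u >= pi] <- 0
  list(ix = ix, iy = iy, magnitude = mag, theta = theta, theta_u = theta_u)
}

#' HOG parameters
#'
#' @param cell cell side in pixels.
#' @param block block side in cells.
#' @param bins number of unsigned orientation bins over `[0, pi)`.
#' @param stride block stride in cells.
#' @param eps normalization constant for the per-block L2 norm.
#' @return named list.
#' @export
hog_params <- function(cell = 8L, block = 2L, bins = 9L, stride = 1L,
                       eps = 1e-5) {
  if (cell < 1L || block < 1L || bins < 1L || stride < 1L)
    stop_config("HOG parameters must be positive integers")
  list(cell = as.integer(cell), block = as.integer(block),
       bins = as.integer(bins), stride = as.integer(stride), eps = eps)
}

# Magnitude-weighted orientation histograms on the non-overlapping cell grid.
# Returns an array bins x ncell_y x ncell_x. Incomplete trailing cells are
# dropped. Votes are interpolated linearly between the two nearest
# orientation-bin centres (circular over [0, pi)) to avoid quantization
# cliffs.
cell_histograms <- function(grad, params) {
  cs <- params$cell
  bins <- params$bins
  ny <- nrow(grad$magnitude) %/% cs
  nx <- ncol(grad$magnitude) %/% cs
  if (ny < 1L || nx < 1L) stop_input("patch smaller than one cell")
  rows <- seq_len(ny * cs); cols <- seq_len(nx * cs)
  mag <- as.vector(grad$magnitude[rows, cols])
  pos <- as.vector(grad$theta_u[rows, cols]) / (pi / bins) - 0.5
  b0 <- floor(pos)
  frac <- pos - b0
  lo <- ((b0 %% bins) + bins) %% bins
  hi <- (lo + 1L) %% bins
  cy <- (rows - 1L) %/% cs
  cx <- (cols - 1L) %/% cs
  cellid <- as.vector(outer(cy, cx * ny, "+"))      # 0-based cell index
  acc <- rep(0, ny * nx * bins)
  k_lo <- cellid * bins + lo + 1L
  k_hi <- cellid * bins + hi + 1L
  s1 <- tapply(mag * (1 - frac), k_lo, sum)
  s2 <- tapply(mag * frac, k_hi, sum)
  acc[as.integer(names(s1))] <- acc[as.integer(names(s1))] + s1
  acc[as.integer(names(s2))] <- acc[as.integer(names(s2))] + s2
  array(acc, c(bins, ny, nx))
}

#' HOG descriptor of an image patch
#'
#' The patch is divided into cells; each cell's magnitude-weighted unsigned
#' orientation histogram is computed with linear interpolation between the
#' two nearest bin centres, cells are grouped into overlapping blocks which
#' are L2-normalized independently, and the block vectors are concatenated.
#'
#' @param patch single-channel matrix, at least one block
#'   (`block * cell` pixels) in each dimension.
#' @param params from [hog_params()].
#' @return object of class `hog_descriptor`: list with `vector`, `params`,
#'   and the patch size `window = c(h, w)`.
#' @export
hog_descriptor <- function(patch, params = hog_params()) {
  if (!is.matrix(patch)) stop_input("HOG patch must be single-channel")
  if (any(dim(patch) < params$block * params$cell))
    stop_input("patch smaller than one HOG block")
  ch <- cell_histograms(gradients(patch), params)
  ny <- dim(ch)[2]; nx <- dim(ch)[3]
  b <- params$block; s <- params$stride
  by <- seq(1L, ny - b + 1L, by = s)
  bx <- seq(1L, nx - b + 1L, by = s)
  out <- vector("list", length(by) * length(bx))
  k <- 0L
  for (x0 in bx) for (y0 in by) {
    v <- as.vector(ch[, y0:(y0 + b - 1L), x0:(x0 + b - 1L)])
    k <- k + 1L
    out[[k]] <- v / sqrt(sum(v^2) + params$eps^2)
  }
  structure(list(vector = unlist(out), params = params, window = dim(patch)),
            class = "hog_descriptor")
}

#' Slide a HOG template over a frame
#'
#' Computes the per-block root-mean-square distance between the template
#' descriptor and the descriptor of every window position (the Euclidean
#' distance divided by the square root of the number of blocks, so the
#' scale is independent of the window size): the lower the value, the
#' greater the similarity (the map is "darkest" at the best match).
#'
#' @param frame single-channel matrix, at least as large as the template
#'   window.
#' @param template a `hog_descriptor`.
#' @param stride window stride in pixels (default: one cell).
#' @return matrix of distances, one row/column per window position; attribute
#'   `stride` records the pixel stride.
#' @export
match_template <- function(frame, template, stride = NULL) {
  if (!inherits(template, "hog_descriptor"))
    stop_input("template must be a hog_descriptor")
  if (is.null(stride)) stride <- template$params$cell
  win <- template$window
  if (any(dim(frame) < win)) stop_input("frame smaller than template window")
  ys <- seq(1L, nrow(frame) - win[1] + 1L, by = stride)
  xs <- seq(1L, ncol(frame) - win[2] + 1L, by = stride)
  out <- matrix(NA_real_, length(ys), length(xs))
  for (i in seq_along(ys)) for (j in seq_along(xs)) {
    d <- hog_descriptor(frame[ys[i]:(ys[i] + win[1] - 1L),
                               xs[j]:(xs[j] + win[2] - 1L)],
                        template$params)
    out[i, j] <- hog_distance(d, template)
  }
  structure(out, stride = stride, window = win,
            origins_y = ys - 1L, origins_x = xs - 1L)
}

# Per-block RMS distance between two descriptors of the same geometry.
hog_distance <- function(a, b) {
  nb <- length(b$vector) / (b$params$block^2 * b$params$bins)
  sqrt(sum((a$vector - b$vector)^2) / nb)
}

# Haar-like features --------------------------------------------------------

# A feature is a rectangle (x, y, w, h), 0-based half-open within the base
# window, split into positive and negative halves/thirds; its value is the
# raw intensity sum over positive parts minus the sum over negative parts.
# Types: "h2" (left/right), "v2" (top/bottom), "h3" (outer minus 2x middle,
# horizontal), "v3" (vertical thirds), "quad" (checkerboard).

integral_image <- function(patch) {
  s <- apply(apply(patch, 2, cumsum), 1, cumsum)  # transposed after second pass
  rbind(0, cbind(0, t(s)))
}

rect_sum <- function(ii, x, y, w, h) {
  # 0-based half-open rectangle; ii has a leading zero row/column
  ii[y + h + 1L, x + w + 1L] - ii[y + 1L, x + w + 1L] -
    ii[y + h + 1L, x + 1L] + ii[y + 1L, x + 1L]
}

haar_feature_value <- function(ii, feat) {
  x <- feat$rect[1]; y <- feat$rect[2]; w <- feat$rect[3]; h <- feat$rect[4]
  switch(feat$type,
    h2 = rect_sum(ii, x, y, w %/% 2, h) -
         rect_sum(ii, x + w %/% 2, y, w - w %/% 2, h),
    v2 = rect_sum(ii, x, y, w, h %/% 2) -
         rect_sum(ii, x, y + h %/% 2, w, h - h %/% 2),
    h3 = rect_sum(ii, x, y, w, h) - 2 * rect_sum(ii, x + w %/% 3, y, w %/% 3, h),
    v3 = rect_sum(ii, x, y, w, h) - 2 * rect_sum(ii, x, y + h %/% 3, w, h %/% 3),
    quad = rect_sum(ii, x, y, w %/% 2, h %/% 2) +
           rect_sum(ii, x + w %/% 2, y + h %/% 2, w - w %/% 2, h - h %/% 2) -
           rect_sum(ii, x + w %/% 2, y, w - w %/% 2, h %/% 2) -
           rect_sum(ii, x, y + h %/% 2, w %/% 2, h - h %/% 2),
    stop_config("unknown Haar feature type: ", feat$type))
}

#' Evaluate a Haar cascade on a patch
#'
#' The patch is resized to the cascade's base window and variance-normalized
#' (zero mean, unit standard deviation) so that stump thresholds are
#' contrast-invariant; an integral image is built and the boosted stages are
#' evaluated in order. The patch is rejected as soon as one stage's weighted
#' vote falls below its threshold, so negatives exit early. An empty cascade
#' accepts everything.
#'
#' @param patch single-channel matrix.
#' @param cascade a `haar_cascade` (see [train_haar_cascade()] /
#'   [read_haar_cascade()]).
#' @return logical: accepted by every stage.
#' @export
haar_evaluate <- function(patch, cascade) {
  if (!inherits(cascade, "haar_cascade"))
    stop_config("cascade must be a haar_cascade object")
  if (!is.matrix(patch)) stop_input("patch must be single-channel")
  win <- cascade$window
  if (!identical(dim(patch), as.integer(win)))
    patch <- resize_gray(patch, win[1], win[2])
  ii <- integral_image(haar_normalize(patch))
  for (stage in cascade$stages) {
    score <- 0
    for (st in stage$stumps) {
      v <- haar_feature_value(ii, st$feature)
      vote <- if (st$polarity * v < st$polarity * st$threshold) 1 else 0
      score <- score + st$weight * vote
    }
    if (score < stage$threshold) return(FALSE)
  }
  TRUE
}

# Variance normalization: stump thresholds become contrast-invariant.
haar_normalize <- function(patch) {
  s <- stats::sd(patch)
  (patch - mean(patch)) / max(s, 1e-6)
}

resize_gray <- function(m, h, w) {
  t(EBImage::imageData(EBImage::resize(EBImage::Image(t(m) / 255),
                                       w = w, h = h))) * 255
}

random_haar_features <- function(n, window) {
  types <- c("h2", "v2", "h3", "v3", "quad")
  lapply(seq_len(n), function(i) {
    type <- sample(types, 1)
    w <- sample(2:window[2], 1)
    h <- sample(2:window[1], 1)
    x <- sample(0:(window[2] - w), 1)
    y <- sample(0:(window[1] - h), 1)
    list(type = type, rect = c(x, y, w, h))
  })
}

#' Train a small boosted Haar cascade
#'
#' AdaBoost over decision stumps on randomly placed Haar-like features, the
#' feature-selection scheme behind attentional cascades. Each stage is
#' trained to pass (nearly) all positives while rejecting part of the
#' negatives; stage thresholds are set to the smallest positive stage score.
#' The trainer targets the self-contained synthetic patch bank; it is not a
#' production pedestrian detector.
#'
#' @param pos,neg lists of single-channel patches (positives/negatives), all
#'   at the base window size.
#' @param window base window `c(h, w)` (default 24x12, the minimum object
#'   size routed to the Haar classifier).
#' @param n_features number of candidate features sampled per stage.
#' @param n_stumps boosting rounds (stumps) per stage.
#' @param n_stages number of cascade stages.
#' @param stage_slack fraction of the stage's total vote weight subtracted
#'   from the lowest positive training score when setting the stage
#'   threshold; buys detection-rate headroom on patches unlike the training
#'   set.
#' @param seed RNG seed for feature sampling.
#' @return object of class `haar_cascade`.
#' @export
train_haar_cascade <- function(pos, neg, window = c(24L, 12L),
                               n_features = 150L, n_stumps = 10L,
                               n_stages = 2L, stage_slack = 0.35,
                               seed = 1L) {
  if (length(pos) == 0L || length(neg) == 0L)
    stop_config("need positive and negative training patches")
  window <- as.integer(window)
  pos <- lapply(pos, function(p) if (identical(dim(p), window)) p
                else resize_gray(p, window[1], window[2]))
  neg <- lapply(neg, function(p) if (identical(dim(p), window)) p
                else resize_gray(p, window[1], window[2]))
  ii_pos <- lapply(pos, function(p) integral_image(haar_normalize(p)))
  ii_neg <- lapply(neg, function(p) integral_image(haar_normalize(p)))
  stages <- with_seed(seed, {
    out <- list()
    neg_active <- ii_neg
    for (s in seq_len(n_stages)) {
      if (length(neg_active) == 0L) break
      feats <- random_haar_features(n_features, window)
      stage <- adaboost_stage(ii_pos, neg_active, feats, n_stumps, stage_slack)
      out[[s]] <- stage
      keep <- vapply(neg_active, function(ii)
        stage_score(ii, stage) >= stage$threshold, logical(1))
      neg_active <- neg_active[keep]   # later stages see surviving negatives
    }
    out
  })
  structure(list(window = window, stages = stages), class = "haar_cascade")
}

stage_score <- function(ii, stage) {
  score <- 0
  for (st in stage$stumps) {
    v <- haar_feature_value(ii, st$feature)
    if (st$polarity * v < st$polarity * st$threshold)
      score <- score + st$weight
  }
  score
}

adaboost_stage <- function(ii_pos, ii_neg, feats, n_stumps, stage_slack = 0.35) {
  np <- length(ii_pos); nn <- length(ii_neg)
  vals <- vapply(feats, function(f)
    c(vapply(ii_pos, haar_feature_value, numeric(1), feat = f),
      vapply(ii_neg, haar_feature_value, numeric(1), feat = f)),
    numeric(np + nn))                       # (np+nn) x nfeat
  y <- c(rep(1L, np), rep(0L, nn))
  wts <- c(rep(1 / (2 * np), np), rep(1 / (2 * nn), nn))
  stumps <- list()
  for (r in seq_len(n_stumps)) {
    wts <- wts / sum(wts)
    best <- NULL
    for (f in seq_along(feats)) {
      st <- best_stump(vals[, f], y, wts)
      if (is.null(best) || st$err < best$err) { best <- st; best$fi <- f }
    }
    eps <- max(best$err, 1e-10)
    beta <- eps / (1 - eps)
    alpha <- log(1 / beta)
    pred <- as.integer(best$polarity * vals[, best$fi] <
                         best$polarity * best$threshold)
    wts <- wts * beta^(as.numeric(pred == y))
    stumps[[r]] <- list(feature = feats[[best$fi]], polarity = best$polarity,
                        threshold = best$threshold, weight = alpha)
  }
  # stage threshold: lowest boosted score among training positives, minus a
  # slack fraction of the total vote so near-miss positives still pass
  pos_scores <- vapply(ii_pos, function(ii)
    stage_score(ii, list(stumps = stumps)), numeric(1))
  total <- sum(vapply(stumps, function(st) st$weight, numeric(1)))
  list(stumps = stumps,
       threshold = min(pos_scores) - stage_slack * total - 1e-9)
}

# Optimal threshold/polarity for one feature under current weights.
best_stump <- function(v, y, wts) {
  o <- order(v)
  vs <- v[o]; ys <- y[o]; ws <- wts[o]
  wp <- cumsum(ws * ys)          # weighted positives at/below cut
  wn <- cumsum(ws * (1 - ys))
  tp <- sum(ws * ys); tn <- sum(ws * (1 - ys))
  # stump predicts positive when polarity*v < polarity*thr
  err_lt <- wn + (tp - wp)       # positives below cut
  err_gt <- wp + (tn - wn)       # positives above cut
  i1 <- which.min(err_lt); i2 <- which.min(err_gt)
  if (err_lt[i1] <= err_gt[i2])
    list(err = err_lt[i1], polarity = 1,
         threshold = vs[i1] + 1e-9)
  else
    list(err = err_gt[i2], polarity = -1,
         threshold = vs[i2] + 1e-9)
}

#' Read / write a Haar cascade as JSON
#'
#' The schema is flat: `window`, then `stages`, each with a `threshold` and
#' `stumps` carrying `type`, `rect` (x, y, w, h), `polarity`, `feature
#' threshold` and `weight`.
#'
#' @param cascade a `haar_cascade`.
#' @param path file path.
#' @return `read_haar_cascade` returns a `haar_cascade`.
#' @export
write_haar_cascade <- function(cascade, path) {
  if (!inherits(cascade, "haar_cascade"))
    stop_config("cascade must be a haar_cascade object")
  jsonlite::write_json(unclass(cascade), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_haar_cascade
#' @export
read_haar_cascade <- function(path) {
  if (!file.exists(path)) stop_io("no such cascade file: ", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop_config("malformed cascade file: ",
                                                  conditionMessage(e)))
  if (is.null(obj$window) || is.null(obj$stages))
    stop_config("malformed cascade file: missing window/stages")
  stages <- lapply(obj$stages, function(s) {
    if (is.null(s$threshold) || is.null(s$stumps))
      stop_config("malformed cascade file: bad stage")
    list(threshold = s$threshold, stumps = lapply(s$stumps, function(st) {
      if (is.null(st$feature) || is.null(st$polarity) ||
          is.null(st$threshold) || is.null(st$weight))
        stop_config("malformed cascade file: bad stump")
      list(feature = list(type = st$feature$type,
                          rect = as.numeric(unlist(st$feature$rect))),
           polarity = st$polarity, threshold = st$threshold,
           weight = st$weight)
    }))
  })
  structure(list(window = as.integer(unlist(obj$window)), stages = stages),
            class = "haar_cascade")
}

#' Classification-stage parameters
#'
#' @param haar_min minimum object size `c(h, w)` for the Haar classifier
#'   (default 24x12); smaller candidates are left indeterminate.
#' @param hog_min minimum object size `c(h, w)` for the HOG classifier
#'   (default 96x48); candidates at or above it must also pass the HOG
#'   template match.
#' @param prop_target bounding-box height:width proportion of a human
#'   (default 2, i.e. 2:1).
#' @param prop_tol multiplicative tolerance of the proportion prior: a
#'   candidate is inside the band when `h/w` lies in
#'   `[prop_target / prop_tol, prop_target * prop_tol]`.
#' @param hog_threshold maximum per-block RMS descriptor distance to the
#'   template for the HOG match to count as human. Calibrated on the
#'   synthetic bank: clean silhouettes score about 0.7-0.9 against the
#'   default template, clutter and noise windows above 1.0.
#' @param crop_margin fractional context margin added around the candidate
#'   box before cropping the classification patch; compensates for the
#'   tightening caused by mask erosion.
#' @param cascade a `haar_cascade`, or `NULL` to skip the Haar gate.
#' @param template a `hog_descriptor`, or `NULL` to skip the HOG gate.
#' @return named list.
#' @export
classify_params <- function(haar_min = c(24L, 12L), hog_min = c(96L, 48L),
                            prop_target = 2, prop_tol = 1.4,
                            hog_threshold = 0.95, crop_margin = 0.15,
                            cascade = NULL, template = NULL) {
  if (prop_tol <= 1) stop_config("prop_tol must exceed 1")
  if (any(haar_min < 1L) || any(hog_min < 1L))
    stop_config("size minima must be positive")
  list(haar_min = as.integer(haar_min), hog_min = as.integer(hog_min),
       prop_target = prop_target, prop_tol = prop_tol,
       hog_threshold = hog_threshold, crop_margin = crop_margin,
       cascade = cascade, template = template)
}

#' Classify a candidate region as human / non-human / indeterminate
#'
#' Routing by candidate size: below the Haar minimum the candidate is too
#' small to judge (indeterminate); between the Haar and HOG minima only the
#' Haar cascade is consulted; at or above the HOG minimum both the cascade
#' and the HOG template match must agree. An upright-human proportion prior
#' (height:width near 2:1) must hold in every size regime.
#'
#' @param cand candidate region from [extract_candidates()].
#' @param frame frame the candidate was extracted from (color or grayscale).
#' @param params from [classify_params()].
#' @return character label, with attribute `paths`: named logical vector
#'   recording which classifiers were invoked (`haar`, `hog`) and the gate
#'   results (`haar_ok`, `hog_ok`, `prop_ok`).
#' @export
classify_candidate <- function(cand, frame, params = classify_params()) {
  bb <- cand$bbox
  h <- bb[["h"]]; w <- bb[["w"]]
  paths <- c(haar = FALSE, hog = FALSE, haar_ok = NA, hog_ok = NA,
             prop_ok = NA)
  if (h < params$haar_min[1] || w < params$haar_min[2])
    return(structure("indeterminate", paths = paths))
  prop <- h / w
  prop_ok <- prop >= params$prop_target / params$prop_tol &&
    prop <= params$prop_target * params$prop_tol
  paths["prop_ok"] <- prop_ok
  lum <- frame_luminance(frame)
  mx <- round(params$crop_margin * w); my <- round(params$crop_margin * h)
  y0 <- max(1L, bb[["y"]] + 1L - my); y1 <- min(nrow(lum), bb[["y"]] + h + my)
  x0 <- max(1L, bb[["x"]] + 1L - mx); x1 <- min(ncol(lum), bb[["x"]] + w + mx)
  patch <- lum[y0:y1, x0:x1]
  haar_ok <- TRUE
  if (!is.null(params$cascade)) {
    paths["haar"] <- TRUE
    haar_ok <- haar_evaluate(patch, params$cascade)
    paths["haar_ok"] <- haar_ok
  }
  hog_ok <- TRUE
  if (h >= params$hog_min[1] && w >= params$hog_min[2]) {
    paths["hog"] <- TRUE            # size routes the candidate to the HOG path
  }
  if (isTRUE(paths[["hog"]]) && !is.null(params$template)) {
    win <- params$template$window
    d <- hog_descriptor(resize_gray(patch, win[1], win[2]),
                        params$template$params)
    hog_ok <- hog_distance(d, params$template) < params$hog_threshold
    paths["hog_ok"] <- hog_ok
  }
  label <- if (haar_ok && hog_ok && prop_ok) "human" else "non-human"
  structure(label, paths = paths)
}
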