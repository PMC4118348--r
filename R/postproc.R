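# Artifact removal on the foreground mask and candidate-object extraction.

#' Clean a foreground mask
#'
#' Applies a median filter followed by a configurable number of erosions
#' (default two), the artifact-removal recipe for isolated false-positive
#' pixels and ragged region borders. Pixels outside the frame count as
#' background, so regions touching the frame edge erode there too. An
#' optional final dilation is available but off by default.
#'
#' @param mask binary matrix (values 0/1).
#' @param median_radius radius of the median window (1 = 3x3).
#' @param erosions number of erosion passes with `brush`.
#' @param dilations number of dilation passes after erosion (default 0).
#' @param brush odd side length of the square structuring element.
#' @return cleaned binary matrix.
#' @export
clean_mask <- function(mask, median_radius = 1L, erosions = 2L,
                       dilations = 0L, brush = 3L) {
  check_mask(mask)
  if (brush %% 2L != 1L || brush < 1L) stop_config("brush size must be odd")
  if (median_radius > 0L) mask <- binary_median(mask, median_radius)
  img <- EBImage::Image(t(mask))
  if (erosions > 0L || dilations > 0L) {
    kern <- EBImage::makeBrush(brush, shape = "box")
    pad <- erosions * (brush %/% 2L) + 1L
    img <- pad_image(img, pad)        # zero border: out-of-frame = background
    for (i in seq_len(erosions))  img <- EBImage::erode(img, kern)
    for (i in seq_len(dilations)) img <- EBImage::dilate(img, kern)
    img <- unpad_image(img, pad)
  }
  out <- t(EBImage::imageData(img))
  storage.mode(out) <- "integer"
  out
}

# Median filter specialized to binary masks: the median over a (2r+1)^2
# window of 0/1 values is a majority vote over the window's box sum.
# Out-of-frame pixels count as background.
binary_median <- function(mask, radius = 1L) {
  M <- nrow(mask); N <- ncol(mask)
  side <- 2L * radius + 1L
  pad <- matrix(0, M + 2L * radius, N + 2L * radius)
  pad[radius + seq_len(M), radius + seq_len(N)] <- mask
  acc <- matrix(0, M, N)
  for (dy in 0:(side - 1L)) for (dx in 0:(side - 1L))
    acc <- acc + pad[dy + seq_len(M), dx + seq_len(N)]
  out <- (acc >= (side * side + 1L) %/% 2L) * 1L
  storage.mode(out) <- "integer"
  out
}

check_mask <- function(mask) {
  if (!is.matrix(mask) || !is.numeric(mask))
    stop_input("mask must be a numeric matrix")
  if (!all(mask %in% c(0, 1)))
    stop_input("mask must be binary (0/1)")
  invisible(mask)
}

pad_image <- function(img, pad) {
  d <- dim(img)
  out <- matrix(0, d[1] + 2 * pad, d[2] + 2 * pad)
  out[pad + seq_len(d[1]), pad + seq_len(d[2])] <- EBImage::imageData(img)
  EBImage::Image(out)
}

unpad_image <- function(img, pad) {
  d <- dim(img)
  EBImage::Image(EBImage::imageData(img)[(pad + 1):(d[1] - pad),
                                         (pad + 1):(d[2] - pad)])
}

#' Label connected foreground components
#'
#' 8-connected labeling; labels are positive integers in order of first
#' appearance, background stays 0.
#'
#' @param mask binary matrix.
#' @return integer matrix of labels.
#' @export
label_components <- function(mask) {
  check_mask(mask)
  m <- mask
  storage.mode(m) <- "integer"
  label8_cpp(m)
}

#' Extract candidate objects of interest from a cleaned mask
#'
#' Components smaller than `min_area` pixels are ignored as artifacts; the
#' survivors are returned largest first with exact bounding boxes (0-based,
#' half-open `(x, y, w, h)`) and centroids.
#'
#' @param mask cleaned binary matrix.
#' @param min_area minimum component area in pixels (default 60).
#' @return list of candidate regions, each a list with `label`, `area`,
#'   `bbox = c(x, y, w, h)` and `centroid = c(cx, cy)`.
#' @export
extract_candidates <- function(mask, min_area = 60L) {
  lab <- label_components(mask)
  n <- max(lab)
  if (n == 0L) return(list())
  idx <- which(lab > 0L)
  labs <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab)          # 0-based y
  cols <- (idx - 1L) %/% nrow(lab)         # 0-based x
  out <- list()
  for (l in seq_len(n)) {
    sel <- labs == l
    area <- sum(sel)
    if (area < min_area) next
    y <- rows[sel]; x <- cols[sel]
    out[[length(out) + 1L]] <- list(
      label = l, area = area,
      bbox = c(x = min(x), y = min(y),
               w = max(x) - min(x) + 1L, h = max(y) - min(y) + 1L),
      centroid = c(cx = mean(x), cy = mean(y)))
  }
  out[order(vapply(out, function(r) r$area, numeric(1)), decreasing = TRUE)]
}
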