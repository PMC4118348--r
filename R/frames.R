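# Frame I/O and color conversions.
#
# Frames are plain numeric arrays in [0, 255]: an M x N matrix for grayscale
# (rows = image rows, i.e. y; columns = x) or an M x N x 3 array for RGB.
# Pixel coordinates exposed through the API are 0-based, row-major, with
# bounding boxes (x, y, w, h) half-open.

HUE_RANGE <- 256  # hue is rescaled from [0,1) to [0,256) so intensity-scale
                  # defaults (initial sigma etc.) apply to both channels

is_frame <- function(x) {
  is.numeric(x) && (is.matrix(x) || (is.array(x) && length(dim(x)) == 3L &&
                                       dim(x)[3] == 3L))
}

check_frame <- function(x, what = "frame") {
  if (!is_frame(x)) stop_input(what, " must be an MxN matrix or MxNx3 array")
  if (any(!is.finite(x))) stop_input(what, " contains non-finite pixel values")
  invisible(x)
}

frame_is_color <- function(x) length(dim(x)) == 3L

#' Luminance channel of a frame
#'
#' Grayscale frames are returned unchanged; RGB frames are converted with the
#' Rec. 601 luma weights (0.299, 0.587, 0.114).
#'
#' @param frame numeric matrix (grayscale) or MxNx3 array (RGB), values in
#'   `[0, 255]`.
#' @return numeric matrix of luminance values in `[0, 255]`.
#' @export
frame_luminance <- function(frame) {
  check_frame(frame)
  if (!frame_is_color(frame)) return(frame)
  0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
}

#' Hue channel of a frame
#'
#' Converts RGB to HSV with the standard hexcone formulation and rescales the
#' hue to the circular range `[0, 256)` so that it is commensurate with 8-bit
#' intensity values. Achromatic pixels (zero saturation) get hue 0.
#'
#' @inheritParams frame_luminance
#' @return numeric matrix of hue values in `[0, 256)`.
#' @export
frame_hue <- function(frame) {
  check_frame(frame)
  if (!frame_is_color(frame))
    stop_config("hue requires a color frame; got grayscale")
  d <- dim(frame)
  hsv <- rgb2hsv(rbind(as.vector(frame[, , 1]),
                       as.vector(frame[, , 2]),
                       as.vector(frame[, , 3])), maxColorValue = 255)
  matrix(hsv["h", ] * HUE_RANGE, d[1], d[2])
}

# Full HSV decomposition: h in [0,256), s in [0,1], v in [0,255].
frame_hsv <- function(frame) {
  check_frame(frame)
  if (!frame_is_color(frame))
    stop_config("HSV requires a color frame; got grayscale")
  d <- dim(frame)
  hsv <- rgb2hsv(rbind(as.vector(frame[, , 1]),
                       as.vector(frame[, , 2]),
                       as.vector(frame[, , 3])), maxColorValue = 255)
  list(h = matrix(hsv["h", ] * HUE_RANGE, d[1], d[2]),
       s = matrix(hsv["s", ], d[1], d[2]),
       v = matrix(hsv["v", ] * 255, d[1], d[2]))
}

#' Area-averaged downscaling
#'
#' Reduces a frame by `factor` in each spatial dimension. When `1/factor` is
#' an integer that divides both dimensions the result is an exact block mean;
#' otherwise bilinear resampling (EBImage) is used. `factor = 1` returns the
#' frame unchanged.
#'
#' @inheritParams frame_luminance
#' @param factor scaling factor in `(0, 1]`; the default 0.5 maps 640x360
#'   capture frames to the 320x180 processing size.
#' @return a frame of size `round(M * factor) x round(N * factor)`.
#' @export
downscale <- function(frame, factor = 0.5) {
  check_frame(frame)
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0 || factor > 1)
    stop_config("scaling factor must be in (0, 1]")
  if (factor == 1) return(frame)
  d <- dim(frame)
  k <- 1 / factor
  block <- abs(k - round(k)) < 1e-9 && d[1] %% round(k) == 0 &&
    d[2] %% round(k) == 0
  down1 <- function(m) {
    if (block) {
      k <- round(k)
      mm <- matrix(colMeans(matrix(m, nrow = k)), nrow = d[1] / k)
      # mm has averaged rows; average columns the same way
      t(matrix(colMeans(matrix(t(mm), nrow = k)), nrow = d[2] / k))
    } else {
      img <- EBImage::resize(EBImage::Image(t(m) / 255),
                             w = round(d[2] * factor),
                             h = round(d[1] * factor))
      t(EBImage::imageData(img)) * 255
    }
  }
  if (!frame_is_color(frame)) return(down1(frame))
  out <- array(0, c(round(d[1] * factor), round(d[2] * factor), 3L))
  for (ch in 1:3) out[, , ch] <- down1(frame[, , ch])
  out
}

#' Read a directory of numbered frames
#'
#' Frames are read in lexicographic filename order, the convention for frame
#' dumps. PNG/JPEG/TIFF are supported through EBImage.
#'
#' @param path directory containing image files.
#' @param pattern filename regex, default PNG/JPEG.
#' @return list of frames (matrices or MxNx3 arrays, values in `[0, 255]`).
#' @export
read_frame_dir <- function(path, pattern = "\\.(png|jpe?g|tiff?)$") {
  if (!dir.exists(path)) stop_io("input directory does not exist: ", path)
  files <- sort(list.files(path, pattern = pattern, full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) == 0L) stop_io("no image frames found in ", path)
  lapply(files, read_frame)
}

read_frame <- function(file) {
  img <- EBImage::imageData(EBImage::readImage(file))
  if (length(dim(img)) == 2L) return(t(img) * 255)
  img <- img[, , 1:3, drop = FALSE]  # drop alpha if present
  d <- dim(img)
  out <- array(0, c(d[2], d[1], 3L))
  for (ch in 1:3) out[, , ch] <- t(img[, , ch]) * 255
  out
}

#' Write frames as numbered PNG files
#'
#' @param frames list of frames.
#' @param path output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
write_frame_dir <- function(frames, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  paths <- character(length(frames))
  for (i in seq_along(frames)) {
    f <- frames[[i]] / 255
    img <- if (frame_is_color(frames[[i]])) {
      d <- dim(f)
      a <- array(0, c(d[2], d[1], 3L))
      for (ch in 1:3) a[, , ch] <- t(f[, , ch])
      EBImage::Image(a, colormode = "Color")
    } else EBImage::Image(t(f))
    paths[i] <- file.path(path, sprintf("frame_%05d.png", i - 1L))
    EBImage::writeImage(img, paths[i])
  }
  invisible(paths)
}
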