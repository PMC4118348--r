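test_that("calibration: static input yields the input as top component", {
  frames <- replicate(40, matrix(128, 4, 4), simplify = FALSE)
  m <- bg_init(frames, bg_params())
  expect_true(bg_calibrated(m))
  expect_equal(unname(m$mu[1, ]), rep(128, 16))
  expect_equal(unname(m$w[1, ]), rep(1, 16), tolerance = 1e-12)
  # a static scene after calibration produces an empty mask
  expect_equal(sum(bg_update(m, matrix(128, 4, 4))$mask), 0)
})

test_that("model stays uncalibrated until the configured learning count", {
  m <- bg_init(list(matrix(10, 2, 2)), bg_params())
  expect_false(bg_calibrated(m))
  for (i in 2:39) m <- bg_update(m, matrix(10, 2, 2))$model
  expect_false(bg_calibrated(m))                       # 39 frames seen
  up <- bg_update(m, matrix(200, 2, 2))
  expect_equal(sum(up$mask), 0)                        # still learning: no output
  expect_true(bg_calibrated(up$model))                 # 40th frame consumed
})

test_that("input validation raises typed errors", {
  expect_error(bg_init(list(), bg_params()), class = "fallwatch_config_error")
  expect_error(bg_init(list(matrix(0, 2, 2), matrix(0, 3, 3))),
               class = "fallwatch_input_error")
  m <- bg_init(list(matrix(0, 2, 2)))
  expect_error(bg_update(m, matrix(NA_real_, 2, 2)),
               class = "fallwatch_input_error")
  expect_error(bg_update(m, matrix(0, 3, 3)), class = "fallwatch_input_error")
})

test_that("unmatched pixel replaces the least probable component", {
  p <- bg_params(G = 1, learn_frames = 1)
  m <- bg_init(list(matrix(100, 1, 1)), p)
  m$sigma[1, 1] <- 10
  r <- bg_update(m, matrix(200, 1, 1))   # d = 100 > 2.5 * 10
  expect_equal(r$mask[1, 1], 1L)
  expect_equal(r$model$mu[1, 1], 200)
  expect_equal(r$model$sigma[1, 1], p$sigma0)
})

test_that("matched pixel contracts the mean toward the sample", {
  p <- bg_params(G = 1, alpha = 0.05, learn_frames = 1)
  m <- bg_init(list(matrix(100, 1, 1)), p)
  m$sigma[1, 1] <- 10
  r <- bg_update(m, matrix(105, 1, 1))   # d = 5 < 25
  expect_equal(r$mask[1, 1], 0L)
  expect_gt(r$model$mu[1, 1], 100)
  expect_lt(r$model$mu[1, 1], 105)
  # closed form: rho = alpha * dnorm(105, 100, 10)
  rho <- 0.05 * dnorm(105, 100, 10)
  expect_equal(r$model$mu[1, 1], (1 - rho) * 100 + rho * 105, tolerance = 1e-12)
})

test_that("background selection uses the smallest prefix above T", {
  mk <- function(ws, T_bg) {
    p <- bg_params(G = length(ws), T_bg = T_bg, learn_frames = 1)
    m <- bg_init(list(matrix(50, 1, 1)), p)
    m$w[, 1] <- ws
    m$mu[, 1] <- seq(10, by = 100, length.out = length(ws))
    m$sigma[, 1] <- 5
    m
  }
  expect_equal(fallwatch:::bg_prefix(mk(c(0.8, 0.2), 0.7)), 1L)
  expect_equal(fallwatch:::bg_prefix(mk(c(0.4, 0.35, 0.25), 0.7)), 2L)
  expect_equal(fallwatch:::bg_prefix(mk(c(0.5, 0.3, 0.2), 1e-9)), 1L)
  # the background estimate is the weighted mean of the prefix components
  expect_equal(bg_background(mk(c(0.8, 0.2), 0.7))[1, 1], 10)
  m <- mk(c(0.4, 0.35, 0.25), 0.7)
  expect_equal(bg_background(m)[1, 1], (0.4 * 10 + 0.35 * 110) / 0.75)
})

test_that("calibrated update matches the literal per-pixel transcription", {
  p <- bg_params(G = 3, alpha = 0.05, learn_frames = 1)
  for (circular in c(FALSE, TRUE)) {
    set.seed(42)
    m <- bg_init(list(matrix(runif(64, 0, 250), 8, 8)), p,
                 circular = circular, seed = 9)
    o <- list(mu = m$mu, sigma = m$sigma, w = m$w)
    for (rep in 1:100) {
      x <- runif(64, 0, if (circular) 255.9 else 255)
      up <- bg_update(m, matrix(x, 8, 8))
      m <- up$model
      o <- oracle_gmm_update(o$mu, o$sigma, o$w, x, p,
                             circular = circular,
                             range = if (circular) 256 else 256)
      expect_identical(as.integer(up$mask), o$mask)
      expect_equal(m$mu, o$mu, tolerance = 1e-12)
      expect_equal(m$sigma, o$sigma, tolerance = 1e-12)
      expect_equal(m$w, o$w, tolerance = 1e-12)
    }
  }
})

test_that("weights stay normalized and means adapt monotonically", {
  p <- bg_params(G = 3, alpha = 0.03, learn_frames = 1)
  set.seed(1)
  m <- bg_init(list(matrix(runif(16, 0, 255), 4, 4)), p)
  for (i in 1:50) {
    m <- bg_update(m, matrix(runif(16, 0, 255), 4, 4))$model
    expect_equal(unname(colSums(m$w)), rep(1, 16), tolerance = 1e-9)
  }
  # constant input: |mu - v| of the top component is non-increasing
  v <- 77
  m2 <- bg_init(list(matrix(200, 3, 3)), p)
  err <- Inf
  for (i in 1:200) {
    m2 <- bg_update(m2, matrix(v, 3, 3))$model
    e <- max(abs(m2$mu[1, ] - v))
    expect_lte(e, err + 1e-12)
    err <- e
  }
  expect_lt(err, 30)   # contraction made visible progress
})

test_that("foreground fraction recovers after a step illumination change", {
  p <- bg_params(learn_frames = 20)
  base <- matrix(100, 12, 12)
  m <- bg_init(replicate(20, base, simplify = FALSE), p)
  gain <- 1.3
  fracs <- numeric(80)
  for (i in 1:80) {
    up <- bg_update(m, base * gain)
    m <- up$model
    fracs[i] <- mean(up$mask)
  }
  expect_equal(fracs[1], 1)                # the step floods the mask
  # the replacement component's weight needs ~ log(T/w_bg)/log(1-alpha)
  # frames to enter the background prefix; bound with 2x margin
  bound <- ceiling(2 * log(p$T_bg / 0.95) / log(1 - p$alpha))
  expect_lt(mean(fracs[bound:80]), 0.01)
})

test_that("dual-model foreground removes hue-stable shadows", {
  bg <- array(rep(c(60, 75, 105), each = 100), c(10, 10, 3))
  calib <- replicate(40, bg, simplify = FALSE)
  ml <- bg_init(lapply(calib, frame_luminance), bg_params())
  mh <- bg_init(lapply(calib, frame_hue), bg_params(), circular = TRUE)
  fr <- bg
  fr[1:5, 1:5, ] <- fr[1:5, 1:5, ] * 0.6         # shadow: darker, same hue
  fr[8:10, 8:10, 1] <- 200; fr[8:10, 8:10, 2] <- 80; fr[8:10, 8:10, 3] <- 60
  r <- bg_shadow_free(ml, mh, fr)
  expect_equal(sum(r$mask[1:5, 1:5]), 0)         # shadow suppressed
  expect_equal(sum(r$mask[8:10, 8:10]), 9)       # object kept
  expect_equal(sum(r$mask_lum[1:5, 1:5]), 25)    # but luminance saw it
  # an unchanged scene yields an empty mask
  r2 <- bg_shadow_free(r$model_lum, r$model_hue, bg)
  expect_equal(sum(r2$mask), 0)
  expect_error(bg_shadow_free(ml, mh, matrix(0, 10, 10)),
               class = "fallwatch_config_error")
})

test_that("model state round-trips through serialization", {
  m <- bg_init(list(matrix(5, 2, 2)), bg_params())
  f <- withr::local_tempfile(fileext = ".rds")
  write_bg_model(m, f)
  m2 <- read_bg_model(f)
  expect_equal(m, m2)
  expect_error(read_bg_model(file.path(tempdir(), "nope.rds")),
               class = "fallwatch_io_error")
})
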