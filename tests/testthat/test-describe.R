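test_that("gradients follow the [-1,0,1] filter and arctan orientation", {
  # plane f = 1.5x + 2y: Ix = 3, Iy = 4, |G| = 5 in the interior
  xs <- matrix(rep(0:9, each = 10), 10, 10)
  ys <- matrix(rep(0:9, 10), 10, 10)
  g <- gradients(1.5 * xs + 2 * ys)
  expect_equal(g$ix[5, 5], 3)
  expect_equal(g$iy[5, 5], 4)
  expect_equal(g$magnitude[5, 5], 5)
  expect_equal(g$theta[5, 5], atan(4 / 3))

  expect_true(all(gradients(matrix(7, 6, 6))$magnitude == 0))
  g2 <- gradients(0.5 * xs + 0.5 * ys)     # Ix = Iy -> theta = pi/4
  expect_equal(g2$theta[4, 4], pi / 4)
  g3 <- gradients(2 * ys)                  # Ix = 0 -> theta = pi/2
  expect_equal(g3$theta[4, 4], pi / 2)
  # magnitude identity holds everywhere on random input
  set.seed(2); r <- matrix(runif(100, 0, 255), 10, 10)
  gr <- gradients(r)
  expect_equal(gr$magnitude, sqrt(gr$ix^2 + gr$iy^2))
  expect_true(all(gr$theta_u >= 0 & gr$theta_u < pi))
  expect_error(gradients(array(0, c(4, 4, 3))), class = "fallwatch_input_error")
  expect_error(gradients(matrix(0, 2, 2)), class = "fallwatch_input_error")
})

test_that("HOG descriptor equals the naive double-loop recomputation", {
  expect_true(all(hog_descriptor(matrix(50, 32, 32))$vector == 0))
  set.seed(8)
  for (i in 1:8) {
    h <- sample(c(16, 24, 48, 96), 1); w <- sample(c(16, 32, 48), 1)
    patch <- matrix(runif(h * w, 0, 255), h, w)
    expect_equal(hog_descriptor(patch)$vector, oracle_hog(patch),
                 tolerance = 1e-12)
  }
  expect_error(hog_descriptor(matrix(0, 8, 8)),   # smaller than one block
               class = "fallwatch_input_error")
})

test_that("cell histograms are invariant to translation by whole cells", {
  set.seed(13)
  patch <- matrix(runif(48 * 48, 0, 255), 48, 48)
  shifted <- patch[, c(9:48, 1:8)]                 # cyclic shift by one cell
  ch <- fallwatch:::cell_histograms(gradients(patch), hog_params())
  cs <- fallwatch:::cell_histograms(gradients(shifted), hog_params())
  # away from the image border and the cyclic seam, shifted cell cx holds
  # exactly the histogram of original cell cx + 1
  expect_equal(cs[, , 2:4], ch[, , 3:5], tolerance = 1e-12)
})

test_that("template matching finds itself and separates structure from noise", {
  set.seed(21)
  fr <- matrix(runif(120 * 160, 0, 255), 120, 160)
  tpl <- hog_descriptor(fr[25:72, 49:80])          # 48x32 cut
  mt <- match_template(fr, tpl, stride = 8)
  hit <- which(mt == min(mt), arr.ind = TRUE)
  expect_equal(min(mt), 0)
  expect_equal(attr(mt, "origins_y")[hit[1]], 24)
  expect_equal(attr(mt, "origins_x")[hit[2]], 48)

  # two identical silhouettes -> two zero-distance hits
  fr2 <- matrix(90, 120, 160)
  sil <- fallwatch:::resize_gray(patch_bank(1, c(48, 24), seed = 2)$pos[[1]], 48, 24)
  fr2[17:64, 17:40] <- sil
  fr2[57:104, 121:144] <- sil
  tpl2 <- hog_descriptor(sil)
  mt2 <- match_template(fr2, tpl2, stride = 8)
  expect_equal(sum(mt2 < 1e-9), 2)

  # structured template against pure noise: no sub-threshold minimum at the
  # default match threshold
  noise <- matrix(runif(160 * 200, 0, 255), 160, 200)
  mt3 <- match_template(noise, default_hog_template(), stride = 8)
  expect_gt(min(mt3), classify_params()$hog_threshold)
})

test_that("Haar feature values equal direct rectangle summation", {
  # two-rectangle vertical split on a half-black/half-white patch
  patch <- cbind(matrix(0, 20, 10), matrix(255, 20, 10))
  ii <- fallwatch:::integral_image(patch)
  f <- list(type = "h2", rect = c(0, 0, 20, 20))
  expect_equal(fallwatch:::haar_feature_value(ii, f), 0 - 255 * 200)
  expect_equal(fallwatch:::haar_feature_value(ii, f),
               oracle_haar_value(patch, f))
  set.seed(31)
  for (i in 1:1000) {
    p <- matrix(runif(24 * 12, 0, 255), 24, 12)
    ii <- fallwatch:::integral_image(p)
    ft <- fallwatch:::random_haar_features(1, c(24L, 12L))[[1]]
    expect_equal(fallwatch:::haar_feature_value(ii, ft),
                 oracle_haar_value(p, ft), tolerance = 1e-8)
  }
})

test_that("cascade evaluation accepts vacuously and rejects impossible stages", {
  empty <- structure(list(window = c(24L, 12L), stages = list()),
                     class = "haar_cascade")
  expect_true(haar_evaluate(matrix(runif(288), 24, 12), empty))
  impossible <- structure(list(window = c(24L, 12L), stages = list(
    list(threshold = 1, stumps = list()))), class = "haar_cascade")
  expect_false(haar_evaluate(matrix(runif(288), 24, 12), impossible))
})

test_that("trained cascade separates silhouettes from clutter and round-trips", {
  bank <- patch_bank(40, seed = 3)
  casc <- train_haar_cascade(bank$pos, bank$neg, seed = 3)
  held <- patch_bank(30, seed = 99)
  expect_gte(mean(vapply(held$pos, haar_evaluate, logical(1), cascade = casc)), 0.9)
  expect_lte(mean(vapply(held$neg, haar_evaluate, logical(1), cascade = casc)), 0.1)

  f <- withr::local_tempfile(fileext = ".json")
  write_haar_cascade(casc, f)
  casc2 <- read_haar_cascade(f)
  expect_equal(casc2$window, casc$window)
  set.seed(4); p <- matrix(runif(288, 0, 255), 24, 12)
  expect_equal(haar_evaluate(p, casc2), haar_evaluate(p, casc))

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"not": "a cascade"}', bad)
  expect_error(read_haar_cascade(bad), class = "fallwatch_config_error")
  expect_error(read_haar_cascade(file.path(tempdir(), "missing.json")),
               class = "fallwatch_io_error")
})

test_that("classification routes candidates by size and proportion", {
  params <- classify_params(cascade = default_haar_cascade(1),
                            template = default_hog_template())
  fr <- matrix(80, 180, 320)
  mk <- function(x, y, w, h) list(bbox = c(x = x, y = y, w = w, h = h),
                                  area = w * h,
                                  centroid = c(cx = x + w / 2, cy = y + h / 2))
  # below the Haar minimum: too small to judge
  lab <- classify_candidate(mk(10, 10, 10, 20), fr, params)
  expect_equal(as.character(lab), "indeterminate")
  # a square blob violates the 2:1 proportion prior
  fr2 <- fr; fr2[41:140, 41:140] <- 200
  lab2 <- classify_candidate(mk(40, 40, 100, 100), fr2, params)
  expect_equal(as.character(lab2), "non-human")
  expect_false(attr(lab2, "paths")[["prop_ok"]])
  # an upright synthetic silhouette with matching appearance is human
  xs <- matrix(rep(1:50, each = 100), 100, 50)
  ys <- matrix(rep(1:100, 50), 100, 50)
  sil <- matrix(80, 100, 50)
  sil[((xs - 25) / 24)^2 + ((ys - 50) / 49)^2 <= 1] <- 170
  set.seed(12)
  sil <- sil + matrix(rnorm(5000, 0, 2), 100, 50)
  fr3 <- fr; fr3[31:130, 101:150] <- sil
  lab3 <- classify_candidate(mk(100, 30, 50, 100), fr3, params)
  expect_equal(as.character(lab3), "human")
  expect_true(all(attr(lab3, "paths")[c("haar", "hog")]))
  # determinism
  lab4 <- classify_candidate(mk(100, 30, 50, 100), fr3, params)
  expect_identical(lab3, lab4)
})

test_that("the HOG path is invoked exactly at its size minimum", {
  params <- classify_params(cascade = NULL, template = NULL)
  fr <- matrix(80, 300, 320)
  probe <- function(h) {
    w <- h / 2
    cand <- list(bbox = c(x = 10, y = 10, w = w, h = h), area = w * h,
                 centroid = c(cx = 10 + w / 2, cy = 10 + h / 2))
    attr(classify_candidate(cand, fr, params), "paths")[["hog"]]
  }
  heights <- seq(24, 120, by = 2)
  routed <- vapply(heights, probe, logical(1))
  expect_equal(min(heights[routed]), 96)
  expect_false(any(routed[heights < 96]))
})
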