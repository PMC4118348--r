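sym_blob <- function(size = 50, center = 25, radius = 8) {
  xs <- matrix(rep(0:(size - 1), each = size), size, size)
  ys <- matrix(rep(0:(size - 1), size), size, size)
  ((xs - center)^2 + (ys - center)^2 <= radius^2) * 1
}

test_that("Mean-Shift fixes symmetric mass and attracts offset starts", {
  w <- sym_blob()
  win <- c(x = 10, y = 10, w = 30, h = 30)
  st <- meanshift_step(w, c(25, 25), win, kernel_params())
  expect_equal(unname(st), c(25, 25), tolerance = 1e-6)
  cv <- meanshift_converge(w, c(27, 23), c(x = 12, y = 8, w = 30, h = 30),
                           kernel_params(eps = 1e-4))
  expect_true(cv$converged)
  expect_equal(unname(cv$center), c(25, 25), tolerance = 0.05)
})

test_that("a flat kernel over uniform weights gives the window centroid", {
  w <- matrix(1, 40, 40)
  win <- c(x = 10, y = 4, w = 11, h = 21)
  st <- meanshift_step(w, c(15, 14), win, kernel_params(bandwidth = 1e6))
  expect_equal(unname(st), c(15, 14), tolerance = 1e-9)  # centroid of window
  win2 <- c(x = 8, y = 2, w = 15, h = 25)
  st2 <- meanshift_step(w, c(12, 10), win2, kernel_params(bandwidth = 1e6))
  expect_equal(unname(st2), c(mean(8:22), mean(2:26)), tolerance = 1e-9)
})

test_that("each iteration does not decrease kernel-weighted mass", {
  set.seed(17)
  w <- sym_blob() + matrix(runif(2500, 0, 0.05), 50, 50)
  kern <- kernel_params()
  center <- c(30, 20)
  win <- c(x = center[1] - 12, y = center[2] - 12, w = 24, h = 24)
  mass_at <- function(ctr) {
    ctr <- unname(ctr)
    xs <- 0:49; ys <- 0:49
    K <- exp(-outer((ys - ctr[2])^2, (xs - ctr[1])^2, "+") / kern$bandwidth^2)
    inside <- outer(ys >= ctr[2] - 12 & ys <= ctr[2] + 11,
                    xs >= ctr[1] - 12 & xs <= ctr[1] + 11, "&")
    sum(K * w * inside)
  }
  prev <- mass_at(center)
  for (i in 1:10) {
    nc <- unname(meanshift_step(w, center,
                                c(x = center[1] - 12, y = center[2] - 12,
                                  w = 24, h = 24), kern))
    cur <- mass_at(nc)
    expect_gte(cur, prev - 1e-9)
    prev <- cur
    center <- nc
  }
})

test_that("zero weighted mass signals a lost track", {
  w <- matrix(0, 20, 20)
  expect_null(meanshift_step(w, c(10, 10), c(x = 5, y = 5, w = 10, h = 10)))
})

test_that("a static colored object is held to sub-pixel drift", {
  spec <- scene_spec(width = 120, height = 80, n_frames = 95,
                     actor_height = 36,
                     waypoints = data.frame(frame = c(40, 41), x = 60, y = 64),
                     fall_frame = NA, noise_sigma = 2, seed = 3)
  seqs <- render_sequence(spec)
  hsv0 <- fallwatch:::frame_hsv(seqs$frames[[45]])
  gt0 <- seqs$truth$table[45, ]
  cand <- list(bbox = c(x = gt0$x, y = gt0$y, w = gt0$w, h = gt0$h),
               centroid = c(cx = gt0$cx, cy = gt0$cy), area = 500)
  obj <- new_track(1, cand, hsv0, 44)
  start <- obj$centroid
  for (t in 45:94)
    obj <- track_object(obj, seqs$frames[[t + 1]], t)
  expect_lt(sqrt(sum((obj$centroid - start)^2)), 0.5)
})

test_that("a 3 px/frame mover is tracked within 2 px per frame", {
  spec <- scene_spec(width = 160, height = 90, n_frames = 80,
                     actor_height = 36,
                     waypoints = data.frame(frame = c(40, 79), x = c(30, 147),
                                            y = 70),
                     fall_frame = NA, noise_sigma = 2, seed = 5)
  seqs <- render_sequence(spec)
  gt <- seqs$truth$table
  hsv0 <- fallwatch:::frame_hsv(seqs$frames[[41]])
  g <- gt[41, ]
  cand <- list(bbox = c(x = g$x, y = g$y, w = g$w, h = g$h),
               centroid = c(cx = g$cx, cy = g$cy), area = 500)
  obj <- new_track(1, cand, hsv0, 40)
  errs <- c()
  for (t in 41:79) {
    obj <- track_object(obj, seqs$frames[[t + 1]], t,
                        search_margin = c(8, 12))
    errs <- c(errs, sqrt((obj$centroid[1] - gt$cx[t + 1])^2 +
                           (obj$centroid[2] - gt$cy[t + 1])^2))
  }
  expect_lt(max(errs), 2)
})

test_that("greedy association matches, spawns and retires correctly", {
  mk_cand <- function(cx, cy, area = 100)
    list(bbox = c(x = cx - 5, y = cy - 5, w = 10, h = 10),
         centroid = c(cx = cx, cy = cy), area = area)
  tr <- new_track(1, mk_cand(50, 50), NULL, 0)
  # one candidate 3 px away within radius 12: matched
  a <- associate(list(tr), list(mk_cand(53, 50)), radius = 12)
  expect_equal(nrow(a$matches), 1)
  # no tracks, two candidates: two new ids
  a2 <- associate(list(), list(mk_cand(10, 10), mk_cand(40, 40)), next_id = 5)
  expect_equal(a2$new_candidates, c(1, 2))
  expect_equal(a2$next_id, 7)
  # candidates below the minimum area do not spawn
  a3 <- associate(list(), list(mk_cand(10, 10, area = 30)), min_area = 60)
  expect_length(a3$new_candidates, 0)
  # a track unseen beyond patience is retired
  tr$frames_since_seen <- 15L
  a4 <- associate(list(tr), list(), patience = 15)
  expect_true(a4$retired[1])
  # a track whose center left the frame is retired immediately
  tr2 <- new_track(2, mk_cand(200, 50), NULL, 0)
  a5 <- associate(list(tr2), list(), frame_size = c(90, 160))
  expect_true(a5$retired[1])
  # incompatible pairs are never matched even when nearest
  a6 <- associate(list(tr), list(mk_cand(53, 50)), radius = 12,
                  compat = matrix(FALSE, 1, 1))
  expect_equal(nrow(a6$matches), 0)
})

test_that("the id survives a stop and a direction reversal", {
  spec <- walk_scene(seed = 23, shadow = FALSE)
  seqs <- render_sequence(spec)
  run <- run_pipeline(seqs$frames, pipeline_config(scale = 1))
  tt <- run$track_table
  ids <- unique(tt$id)
  # the actor's own track covers the whole active span under one label
  main <- as.integer(names(which.max(table(tt$id))))
  span <- range(tt$frame[tt$id == main])
  expect_equal(main, 1L)
  expect_lte(span[1], 42)
  expect_gte(span[2], 165)
})
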