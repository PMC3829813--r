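make_gray_frame <- function(geo, value = 255) {
  matrix(value, geo$height_px, geo$width_px)
}

disc_idx <- function(geo, center, radius) {
  H <- geo$height_px; W <- geo$width_px
  col <- matrix(rep(seq_len(W), each = H), H, W)
  row <- matrix(rep(seq_len(H), W), H, W)
  (col - center[1])^2 + (row - center[2])^2 <= radius^2
}

test_that("threshold calibration averages the sub-cutoff platform pixels", {
  geo <- tiny_geometry()
  f <- make_gray_frame(geo)
  plat <- disc_idx(geo, geo$platform_center, geo$platform_radius_px)
  f[plat] <- 80
  thr <- calibrate_threshold(list(f), geo)
  expect_equal(thr$value, 80)

  # half at 60, half at 100: the 100s fail the strict cutoff
  f2 <- make_gray_frame(geo)
  ids <- which(plat)
  f2[ids[seq(1, length(ids), 2)]] <- 60
  f2[ids[seq(2, length(ids), 2)]] <- 100
  thr2 <- calibrate_threshold(list(f2), geo, cutoff = 100)
  expect_equal(thr2$value, 60)

  # per-channel averaging on RGB input
  f3 <- array(255, dim = c(geo$height_px, geo$width_px, 3))
  for (k in 1:3) { ch <- f3[, , k]; ch[plat] <- 50 + 10 * k; f3[, , k] <- ch }
  thr3 <- calibrate_threshold(list(f3), geo)
  expect_equal(thr3$value, c(60, 70, 80))
})

test_that("calibration over repeated frames equals a single frame", {
  geo <- tiny_geometry()
  f <- make_gray_frame(geo)
  f[disc_idx(geo, geo$platform_center, geo$platform_radius_px)] <- 42
  one <- calibrate_threshold(list(f), geo)
  ten <- calibrate_threshold(rep(list(f), 10), geo)
  expect_equal(one$value, ten$value)
})

test_that("calibration falls back to the cutoff when nothing qualifies", {
  geo <- tiny_geometry()
  f <- make_gray_frame(geo, 255)
  f[disc_idx(geo, geo$platform_center, geo$platform_radius_px)] <- 200
  expect_warning(thr <- calibrate_threshold(list(f), geo), "cutoff")
  expect_equal(thr$value, 100)
})

test_that("segmentation keeps only the largest component inside reach", {
  geo <- tiny_geometry()
  f <- make_gray_frame(geo)
  f[20:29, 20:24] <- 10                      # 50-px blob
  f[33:36, 30:32] <- 10                      # 12-px blob (droppings)
  thr <- color_threshold(100)
  mask <- segment_body(f, thr, geo)
  expect_true(mask$valid)
  expect_equal(nrow(mask$coords), 50)
  # oracle: brute-force flood fill finds the same component sizes
  lab <- brute_label8(f < 100 & disc_idx(geo, geo$platform_center,
                                         geo$reach_radius_px))
  expect_equal(sort(tabulate(lab[lab > 0]), decreasing = TRUE), c(50, 12))
  expect_true(all(f[as.matrix(mask$coords[, c(2, 1)])] == 10))

  # blob fully outside the reach radius is masked away
  f2 <- make_gray_frame(geo)
  f2[2:5, 2:5] <- 10
  mask2 <- segment_body(f2, thr, geo)
  expect_false(mask2$valid)
  expect_equal(nrow(mask2$coords), 0)
})

test_that("segmentation labels agree with the flood-fill oracle on noise images", {
  geo <- tiny_geometry()
  set.seed(99)
  for (rep in 1:3) {
    f <- make_gray_frame(geo)
    spots <- sample(which(disc_idx(geo, geo$platform_center,
                                   geo$reach_radius_px - 2)), 120)
    f[spots] <- 10
    mask <- segment_body(f, color_threshold(100), geo)
    lab <- brute_label8(f < 100 & disc_idx(geo, geo$platform_center,
                                           geo$reach_radius_px))
    expect_equal(nrow(mask$coords), max(tabulate(lab[lab > 0])))
  }
})

test_that("radial weights ramp linearly from platform center to reach border", {
  geo <- test_geometry()
  cx <- geo$platform_center[1]; cy <- geo$platform_center[2]
  coords <- rbind(c(cx, cy),
                  c(cx + geo$reach_radius_px, cy),
                  c(cx, cy + geo$reach_radius_px / 2))
  mask <- structure(list(coords = coords, dim = c(400, 400), valid = TRUE),
                    class = "body_mask")
  w <- weight_coordinates(mask, geo)$w
  expect_equal(w, c(1, 0, 0.5))
})

test_that("weighted center of gravity behaves like a physical centroid", {
  wset <- list(coords = rbind(c(0, 0), c(10, 4)), w = c(1, 1))
  expect_equal(body_cog(wset), c(5, 2))
  geo <- test_geometry()
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  ring <- cbind(geo$platform_center[1] + 30 * cos(th),
                geo$platform_center[2] + 30 * sin(th))
  mask <- structure(list(coords = ring, dim = c(400, 400), valid = TRUE),
                    class = "body_mask")
  wts <- weight_coordinates(mask, geo)
  expect_equal(body_cog(wts), geo$platform_center, tolerance = 1e-8)
})

test_that("weighting pulls the cog behind the unweighted centroid", {
  geo <- test_geometry()
  f <- render_mouse_frame(mouse_pose(0, 0, 30), geo)
  thr <- calibrate_threshold(list(f), geo)
  mask <- segment_body(f, thr, geo)
  wts <- weight_coordinates(mask, geo)
  cog <- body_cog(wts)
  centroid <- colMeans(mask$coords)
  nose <- pose_landmarks(mouse_pose(0, 0, 30), geo)$nose_px
  d <- function(p) sqrt(sum((p - nose)^2))
  expect_gte(d(cog), d(centroid) - 1e-9)
})

test_that("nose search equals exhaustive brute-force score maximization", {
  # straight-line blob with equal weights: far end wins
  coords <- cbind(10:60, rep(5, 51))
  wset <- list(coords = coords, w = rep(1, 51))
  expect_equal(locate_nose(wset, c(10, 5)), c(60, 5))

  set.seed(17)
  for (rep in 1:5) {
    n <- 50
    coords <- cbind(sample.int(80, n, TRUE), sample.int(80, n, TRUE))
    w <- round(runif(n), 2)
    cog <- c(40, 40)
    wset <- list(coords = coords, w = w)
    expect_equal(locate_nose(wset, cog), brute_nose(coords, w, cog))
  }
})

test_that("nose lands on the rendered snout tip", {
  geo <- test_geometry()
  for (h in c(0, 77, 190, 301)) {
    pose <- mouse_pose(5, -8, h)
    f <- render_mouse_frame(pose, geo)
    thr <- calibrate_threshold(list(f), geo)
    mask <- segment_body(f, thr, geo)
    wts <- weight_coordinates(mask, geo)
    nose <- locate_nose(wts, body_cog(wts))
    truth <- pose_landmarks(pose, geo)$nose_px
    expect_lt(sqrt(sum((nose - truth)^2)), 3)
  }
})

test_that("head center is the masked centroid near the nose", {
  # full disc around the nose: centroid is the nose itself
  th <- seq(0, 2 * pi, length.out = 200)
  rr <- rep(seq(0.5, 9.5, 1), each = 200)
  disc <- unique(round(cbind(50 + rr * cos(th), 50 + rr * sin(th))))
  mask <- structure(list(coords = disc, dim = c(100, 100), valid = TRUE),
                    class = "body_mask")
  hc <- locate_head_center(mask, c(50, 50), 10)
  expect_equal(hc, c(50, 50), tolerance = 0.05)

  # half-disc: direct averaging oracle
  half <- disc[disc[, 1] <= 50, ]
  maskh <- structure(list(coords = half, dim = c(100, 100), valid = TRUE),
                     class = "body_mask")
  hch <- locate_head_center(maskh, c(50, 50), 10)
  keep <- (half[, 1] - 50)^2 + (half[, 2] - 50)^2 <= 100
  expect_equal(hch, c(mean(half[keep, 1]), mean(half[keep, 2])))
})

test_that("head center matches the rendered head-ellipse center", {
  geo <- test_geometry()
  for (h in c(10, 135, 260)) {
    pose <- mouse_pose(-6, 4, h)
    f <- render_mouse_frame(pose, geo)
    thr <- calibrate_threshold(list(f), geo)
    mask <- segment_body(f, thr, geo)
    wts <- weight_coordinates(mask, geo)
    nose <- locate_nose(wts, body_cog(wts))
    hc <- locate_head_center(mask, nose, 10 / geo$mm_per_px)
    truth <- pose_landmarks(pose, geo)$head_center_px
    expect_lt(sqrt(sum((hc - truth)^2)), 3)
  }
})

test_that("gaze angle follows the head-to-nose vector convention", {
  expect_equal(compute_gaze(c(0, 0), c(1, 0)), 0)
  expect_equal(compute_gaze(c(0, 0), c(0, -1)), 90)   # -y is up on screen
  expect_equal(compute_gaze(c(0, 0), c(-1, 1)), 225)
  expect_error(compute_gaze(c(2, 2), c(2, 2)), "coincide")
})

test_that("gaze recovery is rotation-equivariant and translation-invariant", {
  geo <- test_geometry()
  headings <- seq(0, 350, by = 40)
  frames <- lapply(headings, function(h)
    render_mouse_frame(mouse_pose(0, 0, h), geo))
  thr <- calibrate_threshold(frames[1], geo)
  tr <- track_sequence(frames, geo, threshold = thr)
  expect_true(all(tr$valid))
  errs <- ang_err(tr$gaze_deg, headings)
  expect_lte(median(errs), 5)
  expect_lte(max(errs), 15)

  # same heading at different platform positions
  gz <- sapply(list(c(0, 0), c(15, 0), c(-10, 12), c(0, -18)), function(p) {
    f <- render_mouse_frame(mouse_pose(p[1], p[2], 120), geo)
    t1 <- track_sequence(list(f), geo, threshold = thr)
    t1$gaze_deg[1]
  })
  expect_true(all(ang_err(gz, 120) <= 5))
})

test_that("inverted polarity yields the identical gaze", {
  geo <- test_geometry()
  pose <- mouse_pose(4, 9, 222)
  f <- render_mouse_frame(pose, geo, dark_on_light = TRUE)
  fi <- render_mouse_frame(pose, geo, dark_on_light = FALSE)
  t1 <- track_sequence(list(f), geo,
                       threshold = calibrate_threshold(list(f), geo))
  thr_i <- calibrate_threshold(list(fi), geo, polarity = "light_on_dark")
  t2 <- track_sequence(list(fi), geo, polarity = "light_on_dark",
                       threshold = thr_i)
  expect_equal(t1$gaze_deg, t2$gaze_deg, tolerance = 1e-9)
})

test_that("track_sequence flags failures and is deterministic", {
  geo <- test_geometry()
  blank <- matrix(255, geo$height_px, geo$width_px)
  tr <- track_sequence(rep(list(blank), 3), geo,
                       threshold = color_threshold(100))
  expect_false(any(tr$valid))
  expect_true(all(is.na(tr$gaze_deg)))

  frames <- c(rep(list(render_mouse_frame(mouse_pose(0, 0, 45), geo)), 11),
              list(blank))
  tr1 <- track_sequence(frames, geo)
  tr2 <- track_sequence(frames, geo)
  expect_identical(tr1, tr2)
  expect_equal(sum(tr1$valid), 11)
  expect_false(tr1$valid[12])  # bad frame flagged, not dropped
  expect_error(track_sequence(frames[1:5], geo), "11 frames")
})
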