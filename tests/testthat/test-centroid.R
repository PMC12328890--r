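blank_frame <- function(n = 84) matrix(0, n, n)

test_that("component segmentation counts objects and respects 8-connectivity", {
  vtr <- vtr_spec("custom", 10, 10, 30, 30)
  f <- blank_frame()
  f[15:18, 15:18] <- 0.8
  expect_length(segment_components(f, vtr), 1)
  f[25:28, 25:28] <- 0.7   # separated by background
  expect_length(segment_components(f, vtr), 2)
  expect_length(segment_components(blank_frame(), vtr), 0)
  # diagonal touch merges under 8-connectivity
  g <- blank_frame()
  g[20, 20] <- 0.9; g[21, 21] <- 0.9
  expect_length(segment_components(g, vtr), 1)
  # but a knight's-move gap does not
  h <- blank_frame()
  h[20, 20] <- 0.9; h[22, 21] <- 0.9
  expect_length(segment_components(h, vtr), 2)
})

test_that("intensity-weighted centroid matches hand-computed oracles", {
  expect_equal(intensity_weighted_centroid(10, 20, 0.7), c(row = 10, col = 20))
  # pixels at x = 0 and x = 4 with intensities 1 and 3: centroid at x = 3
  expect_equal(intensity_weighted_centroid(c(5, 5), c(0, 4), c(1, 3))[["col"]],
               (0 * 1 + 4 * 3) / 4)
  # symmetric intensities give the geometric centre
  rows <- c(4, 5, 6); ints <- c(1, 2, 1)
  expect_equal(intensity_weighted_centroid(rows, c(7, 7, 7), ints)[["row"]], 5)
  expect_error(intensity_weighted_centroid(numeric(0), numeric(0), numeric(0)),
               "empty")
  expect_error(intensity_weighted_centroid(1, 1, 0), "zero total")
})

test_that("seed initialisation picks the nearest component with deterministic ties", {
  vtr <- vtr_spec("custom", 1, 1, 40, 40)
  f <- blank_frame()
  f[10:12, 10:12] <- 0.9
  init <- initialize_track(f, vtr, 11, 11)
  expect_equal(unname(init$centroid), c(11, 11))
  # two equidistant components: lower (row-major) index wins
  f2 <- blank_frame()
  f2[10, 10] <- 0.9; f2[30, 30] <- 0.9
  init2 <- initialize_track(f2, vtr, 20, 20)
  expect_equal(init2$component, 1)
  expect_equal(unname(init2$centroid), c(10, 10))
  expect_error(initialize_track(blank_frame(), vtr, 20, 20),
               "initialization failed")
  expect_error(initialize_track(f, vtr, 50, 50), "inside the VTR")
})

test_that("a three-component frame initialises on the seeded object", {
  vtr <- vtr_spec("custom", 1, 1, 60, 60)
  f <- blank_frame()
  f[10:14, 10:14] <- 0.6    # distractor A
  f[30:34, 30:34] <- 0.9    # the object of interest
  f[50:54, 50:54] <- 0.7    # distractor B
  init <- initialize_track(f, vtr, 32, 33)
  expect_equal(unname(init$centroid), c(32, 32))
})

test_that("tracked centroids equal the brute-force whole-VTR oracle on noiseless phantoms", {
  g <- gesture_spec(150, 300, 100, 250, 5)
  ph <- render_phantom_video(test_lx_scene(gesture = g), duration_ms = 900)
  vtr <- test_vtr()
  tr <- track_centroids(ph$video, vtr, 50, 38)
  expect_true(all(tr$valid))
  rows <- vtr$top:(vtr$top + vtr$height - 1)
  cols <- vtr$left:(vtr$left + vtr$width - 1)
  for (i in seq_len(nrow(tr))) {
    bf <- brute_force_centroid(ph$video$frames[, , i], rows, cols)
    expect_lt(abs(tr$y_px[i] - bf[["row"]]), 0.1)
    expect_lt(abs(tr$x_px[i] - bf[["col"]]), 0.1)
  }
  # and both stay within 0.1 px of the exact trajectory
  expect_lt(max(abs(tr$y_px - ph$ground_truth$y_px)), 0.1)
})

test_that("a stationary blob yields a constant track at the ground-truth centre", {
  ph <- render_phantom_video(test_lx_scene(), duration_ms = 300)
  tr <- track_centroids(ph$video, test_vtr(), 50, 38)
  expect_lt(diff(range(tr$y_px)), 1e-9)
  expect_lt(abs(tr$y_px[1] - 50), 0.1)
  expect_lt(abs(tr$x_px[1] - 38), 0.1)
})

test_that("the tracked vertical displacement recovers the gesture amplitude", {
  g <- gesture_spec(150, 300, 150, 250, 5)
  ph <- render_phantom_video(test_lx_scene(gesture = g), duration_ms = 1000)
  tr <- track_centroids(ph$video, test_vtr(), 50, 38)
  disp <- max(tr$vertical_mm) - tr$vertical_mm[1]
  expect_lt(abs(disp - 5), 0.5 * acquisition_spec()$px_size_mm)
})

test_that("continuity rejects a distractor entering the VTR", {
  acq <- acquisition_spec()
  vtr <- vtr_spec("custom", 30, 25, 25, 25, acq)
  g <- gesture_spec(150, 300, 150, 250, 5)
  distractor <- phantom_blob(45, 36, rx_px = 2.5, ry_px = 3, peak = 0.8)
  attr(distractor, "appear_ms") <- 350
  scene <- phantom_scene(phantom_blob(34, 44), larynx_gesture = g,
                         distractors = list(distractor))
  ph <- render_phantom_video(scene, acq, duration_ms = 1000)
  tr <- track_centroids(ph$video, vtr, 44, 34)
  expect_lt(max(abs(tr$y_px - ph$ground_truth$y_px)), 1)
  expect_lt(max(abs(tr$x_px - 34)), 1)
})

test_that("dropout frames are flagged invalid and the track resumes", {
  ph <- render_phantom_video(test_lx_scene(), duration_ms = 300)
  fr <- ph$video$frames
  fr[, , 10:12] <- 0   # blank out three frames
  vid <- video_sequence(fr, ph$video$acq)
  tr <- track_centroids(vid, test_vtr(), 50, 38)
  expect_equal(which(!tr$valid), 10:12)
  expect_true(all(is.na(tr$y_px[10:12])))
  expect_lt(abs(tr$y_px[13] - 50), 0.1)
})

test_that("tracks are invariant to uniform intensity rescaling", {
  g <- gesture_spec(100, 250, 80, 200, 4)
  ph <- render_phantom_video(test_lx_scene(gesture = g), duration_ms = 750)
  tr1 <- track_centroids(ph$video, test_vtr(), 50, 38)
  vid2 <- video_sequence(ph$video$frames * 0.55, ph$video$acq)
  tr2 <- track_centroids(vid2, test_vtr(), 50, 38)
  expect_equal(tr1$y_px, tr2$y_px, tolerance = 1e-12)
  expect_equal(tr1$x_px, tr2$x_px, tolerance = 1e-12)
})

test_that("local quadratic smoothing reproduces polynomials and denoises tracks", {
  t <- (0:99) * 12.008
  base <- data.frame(time_ms = t, valid = TRUE)
  cst <- cbind(base, vertical_mm = 7)
  expect_equal(smooth_local_quadratic(cst, 30)$vertical_mm, rep(7, 100))
  quad <- cbind(base, vertical_mm = 1 + 0.01 * t - 1e-5 * t^2)
  sm <- smooth_local_quadratic(quad, 30)
  expect_equal(sm$vertical_mm[10:90], quad$vertical_mm[10:90], tolerance = 1e-6)
  # monotone cosine ramp stays monotone after smoothing (no overshoot > 2 %)
  g <- gesture_spec(200, 400, 0.1, 400, 5)
  y <- gesture_trajectory(g, t)
  ramp <- cbind(base, vertical_mm = y)
  smr <- smooth_local_quadratic(ramp, 30)$vertical_mm
  rise <- smr[t <= 600]
  expect_true(all(diff(rise) > -0.02 * 5))
  expect_lt(max(smr), 5 + 0.02 * 5)
  expect_error(smooth_local_quadratic(quad[1:20, ], 30), "span_points")
})

test_that("noisy cosine tracks smooth to within half a pixel RMS of truth", {
  set.seed(42)
  t <- (0:119) * 12.008
  g <- gesture_spec(300, 350, 150, 300, 5)
  truth <- gesture_trajectory(g, t) / acquisition_spec()$px_size_mm
  rms <- replicate(10, {
    tr <- data.frame(time_ms = t, valid = TRUE,
                     y_px = 50 - truth + rnorm(120, 0, 0.5))
    sm <- smooth_local_quadratic(tr, 30, columns = "y_px")
    sqrt(mean((sm$y_px - (50 - truth))^2))
  })
  expect_lt(mean(rms), 0.5)
})

test_that("VTR validation enforces frame bounds and larynx geometry", {
  expect_error(vtr_spec("LX", 80, 35, 17, 6), "outside")
  expect_warning(vtr_spec("LX", 10, 10, 40, 20), "larynx regions")
  expect_silent(vtr_spec("custom", 10, 10, 40, 20))
})
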