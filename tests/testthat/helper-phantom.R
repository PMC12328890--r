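# Shared phantom builders and independent oracles for the test suite.

# Standard test geometry: blob resting at row 50, col 38, inside an
# LX-style VTR of 17 x 6 px (40.5 x 14.3 mm); oral ROI at (31, 62) with the
# tissue edge transiting the central band of the region.
test_acq <- function() acquisition_spec()

test_vtr <- function(acq = test_acq()) {
  vtr_spec("LX", top = 41, left = 35, height = 17, width = 6, acq)
}

test_lx_scene <- function(gesture = NULL, oral_tissue = NULL,
                          distractors = list(), noise_sd = 0,
                          blob = phantom_blob(38, 50)) {
  phantom_scene(blob, larynx_gesture = gesture, oral_tissue = oral_tissue,
                distractors = distractors, noise_sd = noise_sd)
}

test_oral_roi <- function() roi_spec("LAB", center_row = 31, center_col = 62,
                                     radius_px = 3)

test_oral_tissue <- function(gesture) {
  phantom_tissue(col_min = 55, col_max = 70, base_row_px = 31 + 1.26,
                 gesture = gesture, depth_px = 14)
}

# Brute-force intensity-weighted average over a whole region - the oracle
# the component-based tracker is checked against.
brute_force_centroid <- function(frame, rows, cols) {
  crop <- frame[rows, cols, drop = FALSE]
  w <- sum(crop)
  r <- matrix(rows, length(rows), length(cols))
  c <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  c(row = sum(crop * r) / w, col = sum(crop * c) / w)
}

# Independent dense oracle for the oral gesture's landmark times: the exact
# mean-coverage signal of the circular ROI under the tissue-edge trajectory,
# evaluated on a 0.25 ms grid, with the velocity-threshold definitions
# applied directly. Shares only scene parameters with the pipeline.
oracle_oral_landmarks <- function(gesture, base_row_px, roi_row = 31,
                                  radius = 3, depth_px = 14, dt = 0.25,
                                  px_size_mm = test_acq()$px_size_mm) {
  drs <- -radius:radius
  counts <- vapply(drs, function(dr) sum(dr^2 + (-radius:radius)^2 <= radius^2),
                   numeric(1))
  rows <- roi_row + drs
  tend <- gesture$onset_ms + gesture$transition_ms + gesture$hold_ms +
    gesture$release_ms
  t <- seq(0, tend + 100, by = dt)
  edge <- base_row_px - gesture_trajectory(gesture, t) / px_size_mm
  bottom <- base_row_px + depth_px
  sig <- vapply(seq_along(t), function(i) {
    cov <- pmin(rows + 0.5, bottom) - pmax(rows - 0.5, edge[i])
    sum(counts * pmin(pmax(cov, 0), 1))
  }, numeric(1))
  v <- c(diff(sig), 0) / dt
  ip <- which.max(v)
  lev <- 0.2 * v[ip]
  ons <- t[max(which(v[1:ip] < lev))]
  iext <- which.max(sig)
  aft <- (ip + 1):iext
  tons <- t[aft[which(v[aft] < lev)[1]]]
  c(ons = ons, tons = tons)
}

# One end-to-end recovery case: render a two-gesture phantom, run the full
# tracking + ROI + smoothing + landmark pipeline, and return the errors of
# the recovered displacement and lags against ground truth.
recovery_case <- function(lx_on, lx_T, lx_A, or_on, or_T, seed,
                          noise_sd = 0.01) {
  acq <- test_acq()
  glx <- gesture_spec(lx_on, lx_T, 140, 340, lx_A)
  gor <- gesture_spec(or_on, or_T, 180, 320, 6)
  scene <- test_lx_scene(gesture = glx, oral_tissue = test_oral_tissue(gor),
                         noise_sd = noise_sd)
  dur <- max(lx_on + lx_T + 140 + 340, or_on + or_T + 180 + 320) + 150
  ph <- render_phantom_video(scene, acq, dur, seed = seed)
  tr <- smooth_local_quadratic(track_centroids(ph$video, test_vtr(acq), 50, 38))
  lx <- find_gesture_landmarks(tr$vertical_mm, tr$time_ms,
                               direction = if (lx_A >= 0) "raising" else "lowering")
  ser <- smooth_local_quadratic(smooth_weighted_linear(
    roi_intensity_series(ph$video, test_oral_roi())), 30)
  oral <- find_gesture_landmarks(ser$value, ser$time_ms, direction = "raising")
  tlx <- gesture_landmark_times(glx)
  tor <- oracle_oral_landmarks(gor, base_row_px = 31 + 1.26)
  m <- derive_measures(lx, oral)
  c(onset_err = m$onset_lag_ms - (tlx[["ons"]] - tor[["ons"]]),
    target_err = m$target_lag_ms - (tlx[["ons"]] - tor[["tons"]]),
    disp_err = m$lx_displacement_mm - lx_A)
}
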