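sampled_gesture <- function(g, dur, per = 2 * 6.004) {
  t <- seq(0, dur, by = per)
  list(t = t, y = gesture_trajectory(g, t))
}

test_that("velocity estimation matches constants, lines, and the cosine peak", {
  t <- (0:49) * 12
  expect_equal(estimate_velocity(rep(2, 50), t), rep(0, 50))
  expect_equal(estimate_velocity(3 + 0.25 * t, t), rep(0.25, 50))
  g <- gesture_spec(100, 240, 100, 240, 6)
  s <- sampled_gesture(g, 800)
  v <- estimate_velocity(s$y, s$t)
  expect_equal(max(v), 6 * pi / (2 * 240), tolerance = 0.02)
  expect_error(estimate_velocity(1:10, rev(seq_len(10))), "increasing")
  expect_error(estimate_velocity(1:2, 1:2), "3 points")
})

test_that("landmarks on a clean cosine ramp match the analytic crossings", {
  g <- gesture_spec(300, 350, 150, 300, 5)
  s <- sampled_gesture(g, 1250)
  lm <- find_gesture_landmarks(s$y, s$t, direction = "raising")
  tl <- gesture_landmark_times(g)
  per <- 2 * 6.004
  expect_true(all(lm$found))
  expect_lt(abs(lm["ons", "time_ms"] - tl[["ons"]]), 1.5 * per)
  expect_lt(abs(lm["ons", "time_ms"] - (300 + 0.0641 * 350)), 1.5 * per)
  expect_lt(abs(lm["pvel", "time_ms"] - tl[["pvel"]]), 1.5 * per)
  expect_lt(abs(lm["tons", "time_ms"] - (300 + 0.9359 * 350)), 1.5 * per)
  expect_lt(abs(lm["toff", "time_ms"] - tl[["toff"]]), 1.5 * per)
  # MAX lies inside the hold and near its centre
  expect_gt(lm["max", "time_ms"], 300 + 350 - per)
  expect_lt(lm["max", "time_ms"], 300 + 350 + 150 + per)
})

test_that("lowering gestures mirror raising ones", {
  g <- gesture_spec(300, 350, 150, 300, -5)
  s <- sampled_gesture(g, 1250)
  lm <- find_gesture_landmarks(s$y, s$t, direction = "lowering")
  tl <- gesture_landmark_times(g)
  expect_true(all(lm$found))
  expect_lt(abs(lm["ons", "time_ms"] - tl[["ons"]]), 18)
  expect_lt(abs(lm["tons", "time_ms"] - tl[["tons"]]), 18)
  expect_equal(lm["max", "value"], -5, tolerance = 0.05)
})

test_that("landmark ordering ONS <= PVEL <= TONS <= MAX <= TOFF holds when found", {
  set.seed(9)
  for (i in 1:12) {
    g <- gesture_spec(200 + 40 * i %% 3, 250 + 50 * (i %% 4), 60 + 30 * (i %% 2),
                      250, sample(c(-6, -4, 4, 6), 1))
    s <- sampled_gesture(g, 1400)
    y <- s$y + rnorm(length(s$y), 0, 0.02)
    df <- data.frame(time_ms = s$t, value = y)
    ys <- smooth_local_quadratic(df, 30, columns = "value")$value
    lm <- find_gesture_landmarks(ys, s$t,
                                 direction = if (g$amplitude_mm > 0) "raising"
                                             else "lowering")
    tms <- lm$time_ms[lm$found]
    expect_true(all(diff(tms) >= 0))
  }
})

test_that("monotone drift without velocity peak structure yields found = FALSE", {
  t <- (0:99) * 12
  lm <- find_gesture_landmarks(0.01 * t, t, direction = "raising")
  expect_false(lm["tons", "found"])
  expect_false(lm["max", "found"])
  # constant signal: nothing found
  lm0 <- find_gesture_landmarks(rep(1, 100), t, direction = "raising")
  expect_false(any(lm0$found))
})

test_that("raising the threshold never moves ONS earlier nor TONS later", {
  g <- gesture_spec(300, 400, 150, 300, 5)
  s <- sampled_gesture(g, 1300)
  prev_ons <- -Inf; prev_tons <- Inf
  for (thr in c(0.1, 0.2, 0.3, 0.4)) {
    lm <- find_gesture_landmarks(s$y, s$t, threshold = thr,
                                 direction = "raising")
    expect_gte(lm["ons", "time_ms"], prev_ons)
    expect_lte(lm["tons", "time_ms"], prev_tons)
    prev_ons <- lm["ons", "time_ms"]; prev_tons <- lm["tons", "time_ms"]
  }
})

test_that("derived measures combine landmarks with the documented signs", {
  mk <- function(times, found = TRUE) {
    df <- data.frame(time_ms = times, value = c(10, 11, 14, 15, 14.5),
                     found = found,
                     row.names = c("ons", "pvel", "tons", "max", "toff"))
    class(df) <- c("gesture_landmarks", "data.frame")
    df
  }
  lx <- mk(c(150, 200, 240, 260, 300))
  oral <- mk(c(100, 130, 160, 200, 250))
  m <- derive_measures(lx, oral)
  expect_equal(m$onset_lag_ms, 50)          # LX_ONS - Oral_ONS
  expect_equal(m$target_lag_ms, -10)        # LX_ONS - Oral_TONS
  expect_equal(m$lx_duration_ms, 150)
  expect_equal(m$lx_displacement_mm, 5)     # value at MAX minus value at ONS
  expect_equal(m$lx_extremum_mm, 15)
  # a missing oral TONS leaves only the target lag undefined
  oral2 <- oral; oral2["tons", "found"] <- FALSE
  m2 <- derive_measures(lx, oral2)
  expect_true(is.na(m2$target_lag_ms))
  expect_equal(m2$onset_lag_ms, 50)
  expect_true(is.na(derive_measures(lx)$onset_lag_ms))
})

test_that("the omission rule drops flagged tokens and logs counts exactly", {
  tab <- generate_study_tokens(seed = 71)
  res <- apply_omission_rule(tab)
  expect_equal(nrow(res$retained) + sum(tab$omitted), nrow(tab))
  oc <- default_class_params()$omission_counts
  for (j in seq_len(nrow(oc))) {
    got <- res$omission_log$n_omitted[
      res$omission_log$speaker == oc$speaker[j] &
      res$omission_log$consonant == oc$consonant[j]]
    expect_equal(got, oc$n_omit[j])
  }
  # measure-level missingness also triggers omission
  tab$onset_lag_ms[1] <- NA
  tab$omitted <- FALSE
  res2 <- apply_omission_rule(tab, measures = "onset_lag_ms")
  kept_nonlag <- sum(is.na(tab$onset_lag_ms))
  expect_equal(nrow(res2$retained), nrow(tab) - kept_nonlag)
})

test_that("the recovered displacement of a lowering phantom matches its amplitude", {
  g <- gesture_spec(300, 400, 150, 320, -4)
  ph <- render_phantom_video(test_lx_scene(gesture = g), duration_ms = 1350,
                             seed = 3)
  tr <- smooth_local_quadratic(track_centroids(ph$video, test_vtr(), 50, 38))
  lm <- find_gesture_landmarks(tr$vertical_mm, tr$time_ms,
                               direction = "lowering")
  m <- derive_measures(lm)
  expect_lt(abs(m$lx_displacement_mm - (-4)), 0.2)
})
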