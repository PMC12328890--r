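# Velocity-threshold gesture landmarks and derived timing measures.
#
# A gesture signal (ROI mean intensity for oral gestures, vertical centroid
# position for laryngeal gestures) is annotated with five landmarks:
#   ONS  - movement onset: velocity reaches 20 % of the first velocity peak
#   PVEL - peak velocity of the movement toward the target
#   TONS - target attainment: velocity falls back below the 20 % threshold
#   MAX  - maximum displacement: the velocity minimum nearest the signal's
#          extremum
#   TOFF - target offset: velocity of the release movement rises above 20 %
#          of the release peak
# All landmark times are sub-frame, by linear interpolation of the velocity
# between samples.

#' Estimate signal velocity by finite differences
#'
#' Central differences in the interior, one-sided at the ends. Units are
#' signal units per ms. Intended to run on smoothed signals.
#'
#' @param signal numeric vector (>= 3 points).
#' @param times_ms strictly increasing timestamps, ms.
#' @return numeric vector of velocities, same length.
#' @export
estimate_velocity <- function(signal, times_ms) {
  n <- length(signal)
  if (n < 3) stopf("need at least 3 points")
  if (length(times_ms) != n) stopf("signal and times differ in length")
  if (any(diff(times_ms) <= 0)) stopf("times must be strictly increasing")
  v <- numeric(n)
  v[1] <- (signal[2] - signal[1]) / (times_ms[2] - times_ms[1])
  v[n] <- (signal[n] - signal[n - 1]) / (times_ms[n] - times_ms[n - 1])
  i <- 2:(n - 1)
  v[i] <- (signal[i + 1] - signal[i - 1]) / (times_ms[i + 1] - times_ms[i - 1])
  v
}

# Indices of local maxima of v (plateau-tolerant: first point of each
# plateau), restricted to values above `floor`.
local_maxima <- function(v, floor = -Inf) {
  n <- length(v)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  cand <- i[v[i] > v[i - 1] & v[i] >= v[i + 1] & v[i] > floor]
  cand
}

#' Detect velocity-threshold landmarks of one gesture
#'
#' The toward-target velocity is the signed velocity for a raising gesture
#' (target = signal maximum) and its negation for a lowering gesture. PVEL
#' is the first local velocity maximum above a noise floor (a fraction of
#' the global absolute velocity maximum); ONS is the last crossing of
#' `threshold * v(PVEL)` before PVEL; TONS the first fall below that level
#' after PVEL and not after the positional extremum; MAX the velocity
#' minimum (in absolute value) nearest the extremum; TOFF the first rise of
#' the away-from-target velocity above `threshold` times the release peak
#' velocity, after MAX. A landmark that cannot be located has its `found`
#' flag set to `FALSE` rather than raising an error; downstream token
#' omission feeds on those flags.
#'
#' @param signal numeric vector, already smoothed.
#' @param times_ms timestamps, ms.
#' @param threshold velocity threshold fraction (default 0.2).
#' @param direction `"raising"` (target is the signal maximum) or
#'   `"lowering"` (target is the minimum).
#' @param noise_floor fraction of the global absolute velocity maximum
#'   below which local velocity peaks are disregarded. The default of 0.1
#'   rejects the small spurious velocity ripples that centroid pixel
#'   quantisation leaves even after smoothing.
#' @return a `gesture_landmarks` object: data frame with rows `ons`,
#'   `pvel`, `tons`, `max`, `toff` and columns `time_ms`, `value`, `found`.
#' @export
find_gesture_landmarks <- function(signal, times_ms, threshold = 0.2,
                                   direction = c("raising", "lowering"),
                                   noise_floor = 0.1) {
  direction <- match.arg(direction)
  if (threshold <= 0 || threshold >= 1) stopf("threshold must be in (0, 1)")
  v <- estimate_velocity(signal, times_ms)
  vt <- if (direction == "raising") v else -v
  n <- length(signal)
  res <- data.frame(time_ms = rep(NA_real_, 5), value = NA_real_,
                    found = FALSE,
                    row.names = c("ons", "pvel", "tons", "max", "toff"))
  finish <- function(res) {
    ok <- res$found
    res$value[ok] <- stats::approx(times_ms, signal, xout = res$time_ms[ok])$y
    class(res) <- c("gesture_landmarks", "data.frame")
    res
  }
  vmax <- max(abs(vt))
  if (vmax == 0) return(finish(res))
  peaks <- local_maxima(vt, floor = noise_floor * vmax)
  if (!length(peaks)) return(finish(res))
  ip <- peaks[1]
  vp <- vt[ip]
  lev <- threshold * vp
  res["pvel", "time_ms"] <- times_ms[ip]
  res["pvel", "found"] <- TRUE

  # ONS: last upward crossing of `lev` before PVEL
  below <- which(vt[seq_len(ip)] < lev)
  if (length(below) && max(below) < ip) {
    i <- max(below)
    res["ons", "time_ms"] <- interp_crossing(times_ms, vt, i, lev)
    res["ons", "found"] <- TRUE
  }

  # positional extremum toward the target, at or after PVEL
  seg <- ip:n
  iext <- seg[which.max(if (direction == "raising") signal[seg] else -signal[seg])]

  # TONS: first fall below `lev` after PVEL, not after the extremum
  if (iext > ip) {
    after <- (ip + 1):iext
    bel <- after[vt[after] < lev]
    if (length(bel)) {
      i <- bel[1] - 1L
      res["tons", "time_ms"] <- interp_crossing(times_ms, vt, i, lev)
      res["tons", "found"] <- TRUE
    }
  }

  # MAX: |velocity| minimum nearest the extremum (plateaus allowed); the
  # minimum must lie below the threshold level, otherwise the movement
  # never pauses and no displacement maximum is attained
  av <- abs(vt)
  cand <- (ip:n)[-c(1)]
  cand <- cand[cand > 1 & cand < n]
  mins <- cand[av[cand] <= av[cand - 1] & av[cand] <= av[cand + 1] &
               av[cand] < lev]
  if (length(mins)) {
    k <- mins[order(abs(mins - iext), mins)[1]]
    res["max", "time_ms"] <- times_ms[k]
    res["max", "found"] <- TRUE
    imax_lm <- k
  } else imax_lm <- NA_integer_

  # TOFF: release movement away from the target after MAX
  if (!is.na(imax_lm) && imax_lm < n - 1) {
    va <- -vt
    rel <- imax_lm:n
    vrel <- max(va[rel])
    if (vrel > noise_floor * vmax) {
      lev2 <- threshold * vrel
      above <- rel[va[rel] >= lev2]
      if (length(above) && above[1] > imax_lm) {
        i <- above[1] - 1L
        res["toff", "time_ms"] <- interp_crossing(times_ms, va, i, lev2)
        res["toff", "found"] <- TRUE
      }
    }
  }
  finish(res)
}

#' Derive kinematic measures from larynx and oral landmarks
#'
#' * `lx_displacement_mm`: signed change in vertical position between the
#'   larynx MAX and ONS landmarks.
#' * `lx_extremum_mm`: absolute vertical position at the larynx MAX.
#' * `onset_lag_ms`: larynx ONS time minus oral ONS time.
#' * `target_lag_ms`: larynx ONS time minus oral TONS time.
#' * `lx_duration_ms`: larynx TOFF minus larynx ONS.
#'
#' Positive lags mean the larynx movement onset follows the oral landmark.
#' A measure whose landmarks are not all found is `NA`.
#'
#' @param lx_landmarks `gesture_landmarks` of the vertical larynx signal
#'   (values in mm above the VTR bottom).
#' @param oral_landmarks `gesture_landmarks` of the oral constriction
#'   signal, or `NULL` if no oral gesture is analysed (lags become `NA`).
#' @return one-row data frame of the five measures.
#' @export
derive_measures <- function(lx_landmarks, oral_landmarks = NULL) {
  stopifnot(inherits(lx_landmarks, "gesture_landmarks"))
  lk <- function(lm, w, col = "time_ms")
    if (!is.null(lm) && lm[w, "found"]) lm[w, col] else NA_real_
  data.frame(
    lx_displacement_mm = lk(lx_landmarks, "max", "value") -
                         lk(lx_landmarks, "ons", "value"),
    lx_extremum_mm = lk(lx_landmarks, "max", "value"),
    onset_lag_ms = lk(lx_landmarks, "ons") - lk(oral_landmarks, "ons"),
    target_lag_ms = lk(lx_landmarks, "ons") - lk(oral_landmarks, "tons"),
    lx_duration_ms = lk(lx_landmarks, "toff") - lk(lx_landmarks, "ons")
  )
}

#' Apply the token-omission rule to a measure table
#'
#' Tokens whose gestures could not be captured (simulator `omitted` flag,
#' or any `NA` among the requested measures) are excluded, and the
#' per-speaker, per-consonant omission counts are reported alongside the
#' retained table.
#'
#' @param table a measure table (one row per token) with columns `speaker`,
#'   `consonant`, and measure columns.
#' @param measures measure columns whose missingness triggers omission;
#'   defaults to the simulator's `omitted` flag only.
#' @return list with `retained` (filtered table) and `omission_log`
#'   (data frame `speaker`, `consonant`, `n_omitted`).
#' @export
apply_omission_rule <- function(table, measures = character(0)) {
  drop <- rep(FALSE, nrow(table))
  if ("omitted" %in% names(table)) drop <- drop | table$omitted
  for (m in measures) drop <- drop | is.na(table[[m]])
  log <- stats::aggregate(list(n_omitted = drop),
                          by = list(speaker = table$speaker,
                                    consonant = table$consonant), FUN = sum)
  log <- log[log$n_omitted > 0, ]
  log <- log[order(log$speaker, log$consonant), ]
  rownames(log) <- NULL
  list(retained = table[!drop, , drop = FALSE], omission_log = log)
}
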