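#' Specification of a single articulatory gesture
#'
#' A gesture is modelled as a smooth excursion from rest to a target and
#' back: a cosine-ramp transition of duration `transition_ms`, an optional
#' hold at the target, and a mirrored cosine release. The cosine ramp has a
#' single velocity peak at the transition midpoint with closed-form value
#' `A * pi / (2 * transition_ms)`, and its 20 % velocity crossings are
#' analytically invertible, which makes landmark detection checkable against
#' ground truth.
#'
#' @param onset_ms time at which movement toward the target begins, ms.
#' @param transition_ms movement-to-target duration, ms (> 0).
#' @param hold_ms duration of the hold at the target, ms (>= 0).
#' @param release_ms duration of the return movement, ms (> 0).
#' @param amplitude_mm signed target amplitude; positive = raising.
#' @return an object of class `gesture_spec`.
#' @seealso [gesture_trajectory()], [gesture_landmark_times()]
#' @export
gesture_spec <- function(onset_ms, transition_ms, hold_ms = 0, release_ms,
                         amplitude_mm) {
  if (!is.numeric(transition_ms) || transition_ms <= 0)
    stopf("transition_ms must be positive")
  if (!is.numeric(release_ms) || release_ms <= 0)
    stopf("release_ms must be positive")
  if (hold_ms < 0) stopf("hold_ms must be non-negative")
  if (onset_ms < 0) stopf("onset_ms must be non-negative")
  structure(list(onset_ms = onset_ms, transition_ms = transition_ms,
                 hold_ms = hold_ms, release_ms = release_ms,
                 amplitude_mm = amplitude_mm,
                 trajectory_shape = "cosine_ramp"),
            class = "gesture_spec")
}

#' Evaluate a cosine-ramp gesture trajectory
#'
#' Position of the gesture at times `t`: 0 before onset,
#' `A * (1 - cos(pi * (t - onset) / transition)) / 2` during the transition,
#' `A` during the hold, the mirrored cosine during the release, and 0 after.
#' Continuous everywhere.
#'
#' @param spec a [gesture_spec()].
#' @param t times in ms (vectorised), must be >= 0.
#' @return positions in mm, same length as `t`.
#' @export
gesture_trajectory <- function(spec, t) {
  stopifnot(inherits(spec, "gesture_spec"))
  if (any(t < 0)) stopf("t must be non-negative")
  A <- spec$amplitude_mm
  s <- t - spec$onset_ms
  Tt <- spec$transition_ms; H <- spec$hold_ms; Tr <- spec$release_ms
  out <- numeric(length(t))
  up <- s >= 0 & s < Tt
  out[up] <- A * (1 - cos(pi * s[up] / Tt)) / 2
  out[s >= Tt & s < Tt + H] <- A
  dn <- s >= Tt + H & s < Tt + H + Tr
  out[dn] <- A * (1 + cos(pi * (s[dn] - Tt - H) / Tr)) / 2
  out
}

#' Closed-form velocity of a cosine-ramp gesture
#'
#' @inheritParams gesture_trajectory
#' @return velocity in mm/ms, same length as `t`.
#' @export
gesture_velocity <- function(spec, t) {
  stopifnot(inherits(spec, "gesture_spec"))
  A <- spec$amplitude_mm
  s <- t - spec$onset_ms
  Tt <- spec$transition_ms; H <- spec$hold_ms; Tr <- spec$release_ms
  out <- numeric(length(t))
  up <- s >= 0 & s < Tt
  out[up] <- A * pi / (2 * Tt) * sin(pi * s[up] / Tt)
  dn <- s >= Tt + H & s < Tt + H + Tr
  out[dn] <- -A * pi / (2 * Tr) * sin(pi * (s[dn] - Tt - H) / Tr)
  out
}

#' Analytic velocity-threshold landmark times of a cosine-ramp gesture
#'
#' For a cosine transition the toward-target velocity is
#' `v(s) = A*pi/(2*T) * sin(pi*s/T)`, so the fractional-threshold crossings
#' solve `sin(pi*s/T) = q`: movement onset at `s = (T/pi) * asin(q)`
#' (about `0.0641 * T` at the conventional 20 % threshold), peak velocity at
#' `s = T/2`, and target attainment at `s = T - (T/pi) * asin(q)`. The
#' maximum lies at the centre of the hold, and the target offset mirrors the
#' onset within the release. These are the ground-truth values that a
#' velocity-threshold landmark detector should recover.
#'
#' @param spec a [gesture_spec()].
#' @param threshold velocity threshold as a fraction of peak velocity.
#' @return named numeric vector of times in ms:
#'   `ons`, `pvel`, `tons`, `max`, `toff`.
#' @export
gesture_landmark_times <- function(spec, threshold = 0.2) {
  stopifnot(inherits(spec, "gesture_spec"))
  if (threshold <= 0 || threshold >= 1)
    stopf("threshold must be in (0, 1)")
  t0 <- spec$onset_ms; Tt <- spec$transition_ms
  H <- spec$hold_ms; Tr <- spec$release_ms
  d <- asin(threshold) / pi
  c(ons  = t0 + d * Tt,
    pvel = t0 + Tt / 2,
    tons = t0 + (1 - d) * Tt,
    max  = t0 + Tt + H / 2,
    toff = t0 + Tt + H + d * Tr)
}
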