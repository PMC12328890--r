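# Phantom scene construction and rendering.
#
# Phantoms emulate the geometry of a mid-sagittal rtMRI recording: a bright
# compact larynx-like object moving vertically inside the frame, optional
# oral "tissue" sliding into a fixed region (mimicking constriction
# formation), and optional distractor objects. Every moving element follows
# a closed-form cosine-ramp gesture, so the exact object centre and the
# analytic landmark times are known per frame and can serve as ground truth
# for the tracking and landmark-detection stages.

#' Describe the bright larynx-like object of a phantom scene
#'
#' The object is an elliptical raised-cosine intensity bump:
#' `I = peak * cos(pi * rho / 2)` for elliptical radius `rho <= 1`. The
#' profile is smooth and compactly supported, so its sampled
#' intensity-weighted centroid matches the analytic centre to well under
#' 0.1 px.
#'
#' @param x_px,y_px centre in pixel coordinates (x = column, y = row,
#'   row 1 at the image top).
#' @param rx_px,ry_px semi-axes in px (>= 1).
#' @param peak peak intensity in (0, 1].
#' @return a `phantom_blob` object.
#' @export
phantom_blob <- function(x_px, y_px, rx_px = 2.5, ry_px = 5.5, peak = 0.9) {
  if (rx_px < 1 || ry_px < 1) stopf("blob radii must be >= 1 px")
  if (peak <= 0 || peak > 1) stopf("peak intensity must be in (0, 1]")
  structure(list(x_px = x_px, y_px = y_px, rx_px = rx_px, ry_px = ry_px,
                 peak = peak), class = "phantom_blob")
}

#' Describe an oral-tissue element filling a region of a phantom scene
#'
#' A block of tissue whose top edge rises from `base_row_px` by the gesture
#' trajectory (converted mm -> px at render time), emulating an articulator
#' forming a constriction inside a fixed region of interest. The edge is
#' anti-aliased by per-pixel row coverage, so the mean region intensity
#' varies smoothly with edge position.
#'
#' @param col_min,col_max column range occupied by the tissue.
#' @param base_row_px row of the tissue top edge at rest (continuous
#'   coordinates; larger = lower in the image).
#' @param gesture a [gesture_spec()] with positive amplitude = tissue rising.
#' @param depth_px tissue thickness below the resting edge, px.
#' @param peak tissue intensity in (0, 1].
#' @return a `phantom_tissue` object.
#' @export
phantom_tissue <- function(col_min, col_max, base_row_px, gesture,
                           depth_px = 12, peak = 0.9) {
  stopifnot(inherits(gesture, "gesture_spec"))
  if (peak <= 0 || peak > 1) stopf("peak intensity must be in (0, 1]")
  if (col_min > col_max) stopf("col_min must be <= col_max")
  structure(list(col_min = col_min, col_max = col_max,
                 base_row_px = base_row_px, gesture = gesture,
                 depth_px = depth_px, peak = peak),
            class = "phantom_tissue")
}

#' Assemble a phantom scene
#'
#' @param larynx_blob a [phantom_blob()]; its centre follows
#'   `larynx_gesture` vertically (positive amplitude = raising = smaller
#'   row index).
#' @param larynx_gesture a [gesture_spec()] or `NULL` for a stationary blob.
#' @param oral_tissue a [phantom_tissue()] or `NULL`.
#' @param distractors list of additional [phantom_blob()]s, each optionally
#'   carrying attributes `gesture` (a [gesture_spec()] moving it
#'   vertically), `appear_ms` and `disappear_ms` (visibility window).
#' @param noise_sd standard deviation of the added intensity noise.
#' @param noise_model `"gaussian"` (additive) or `"rician"` (magnitude of a
#'   complex Gaussian perturbation, as in magnitude MR images).
#' @return a `phantom_scene` object.
#' @export
phantom_scene <- function(larynx_blob, larynx_gesture = NULL,
                          oral_tissue = NULL, distractors = list(),
                          noise_sd = 0,
                          noise_model = c("gaussian", "rician")) {
  stopifnot(inherits(larynx_blob, "phantom_blob"))
  if (!is.null(larynx_gesture)) stopifnot(inherits(larynx_gesture, "gesture_spec"))
  if (!is.null(oral_tissue)) stopifnot(inherits(oral_tissue, "phantom_tissue"))
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  structure(list(larynx_blob = larynx_blob, larynx_gesture = larynx_gesture,
                 oral_tissue = oral_tissue, distractors = distractors,
                 noise_sd = noise_sd,
                 noise_model = match.arg(noise_model)),
            class = "phantom_scene")
}

blob_intensity <- function(n, cx, cy, rx, ry, peak) {
  x <- matrix(rep(seq_len(n), each = n), n, n)   # column index
  y <- matrix(rep(seq_len(n), times = n), n, n)  # row index
  rho <- sqrt(((x - cx) / rx)^2 + ((y - cy) / ry)^2)
  I <- matrix(0, n, n)
  inside <- rho <= 1
  I[inside] <- peak * cos(pi * rho[inside] / 2)
  I
}

tissue_intensity <- function(n, tis, traj_px) {
  edge <- tis$base_row_px - traj_px
  bottom <- tis$base_row_px + tis$depth_px
  rows <- seq_len(n)
  # per-row coverage of [edge, bottom] over pixel [r - 0.5, r + 0.5]
  cov <- pmin(rows + 0.5, bottom) - pmax(rows - 0.5, edge)
  cov <- pmin(pmax(cov, 0), 1)
  I <- matrix(0, n, n)
  cols <- max(1L, tis$col_min):min(n, tis$col_max)
  I[, cols] <- cov * tis$peak
  I
}

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env)
  on.exit(if (had) assign(".Random.seed", old, envir = env)
          else rm(".Random.seed", envir = env), add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Render a phantom video with per-frame ground truth
#'
#' Draws the scene at each frame time (`(i - 1) * frame_period_ms`), with
#' the larynx blob centre displaced vertically by its gesture trajectory
#' converted from mm to px through the acquisition pixel size. The frame
#' count is `floor(duration_ms * frame_rate_fps / 1000)`. Rendering under
#' the same seed is bit-identical.
#'
#' @param scene a [phantom_scene()].
#' @param acq an [acquisition_spec()].
#' @param duration_ms video duration in ms; must cover every gesture in the
#'   scene.
#' @param seed integer seed for the noise generator, or `NULL` to use the
#'   current RNG stream.
#' @return a list with elements `video` (a [video_sequence()]) and
#'   `ground_truth`, a data frame with one row per frame: `frame`,
#'   `time_ms`, exact larynx centre `x_px`, `y_px`, and its vertical
#'   trajectory value `position_mm`.
#' @export
render_phantom_video <- function(scene, acq = acquisition_spec(),
                                 duration_ms, seed = NULL) {
  stopifnot(inherits(scene, "phantom_scene"), inherits(acq, "acquisition_spec"))
  gend <- function(g) if (is.null(g)) 0 else
    g$onset_ms + g$transition_ms + g$hold_ms + g$release_ms
  ends <- c(gend(scene$larynx_gesture),
            if (!is.null(scene$oral_tissue)) gend(scene$oral_tissue$gesture),
            vapply(scene$distractors,
                   function(d) gend(attr(d, "gesture")), numeric(1)))
  if (duration_ms < max(ends))
    stopf("duration_ms (%g) does not cover all gestures (last ends at %g ms)",
          duration_ms, max(ends))
  n <- acq$grid_px
  nf <- floor(duration_ms * acq$frame_rate_fps / 1000)
  if (nf < 1) stopf("duration too short for a single frame")
  times <- (seq_len(nf) - 1) * acq$frame_period_ms
  lb <- scene$larynx_blob
  traj <- if (is.null(scene$larynx_gesture)) rep(0, nf) else
    gesture_trajectory(scene$larynx_gesture, times)
  cy <- lb$y_px - traj / acq$px_size_mm  # raising (positive mm) = up = smaller row
  if (any(cy - lb$ry_px < 0.5) || any(cy + lb$ry_px > n + 0.5) ||
      lb$x_px - lb$rx_px < 0.5 || lb$x_px + lb$rx_px > n + 0.5)
    stopf("larynx blob leaves the frame")
  frames <- array(0, c(n, n, nf))
  for (i in seq_len(nf)) {
    I <- blob_intensity(n, lb$x_px, cy[i], lb$rx_px, lb$ry_px, lb$peak)
    if (!is.null(scene$oral_tissue)) {
      tp <- gesture_trajectory(scene$oral_tissue$gesture, times[i]) / acq$px_size_mm
      I <- I + tissue_intensity(n, scene$oral_tissue, tp)
    }
    for (d in scene$distractors) {
      ap <- attr(d, "appear_ms") %||% 0
      dis <- attr(d, "disappear_ms") %||% Inf
      if (times[i] < ap || times[i] > dis) next
      dg <- attr(d, "gesture")
      dy <- if (is.null(dg)) 0 else
        gesture_trajectory(dg, times[i]) / acq$px_size_mm
      I <- I + blob_intensity(n, d$x_px, d$y_px - dy, d$rx_px, d$ry_px, d$peak)
    }
    frames[, , i] <- pmin(I, 1)
  }
  if (scene$noise_sd > 0) {
    frames <- with_seed(seed, {
      if (scene$noise_model == "gaussian") {
        frames + array(stats::rnorm(length(frames), 0, scene$noise_sd),
                       dim(frames))
      } else {
        sqrt((frames + array(stats::rnorm(length(frames), 0, scene$noise_sd),
                             dim(frames)))^2 +
             array(stats::rnorm(length(frames), 0, scene$noise_sd),
                   dim(frames))^2)
      }
    })
    frames[frames < 0] <- 0
    frames[frames > 1] <- 1
  }
  list(video = video_sequence(frames, acq),
       ground_truth = data.frame(frame = seq_len(nf), time_ms = times,
                                 x_px = lb$x_px, y_px = cy,
                                 position_mm = traj))
}
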