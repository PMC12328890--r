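# Intensity-weighted centroid tracking inside a fixed vocal-tract region.
#
# Non-constriction gestures (vertical larynx motion, velum action) do not
# form a constriction at a fixed place, so ROI intensity is not a usable
# proxy. Instead, the bright tissue body is segmented inside a fixed
# rectangular vocal-tract region (VTR) every frame, each 8-connected
# component gets an intensity-weighted centroid, and the track follows the
# component whose centroid is closest to the previous frame's centroid
# (seed-initialised in frame 1). Continuity keeps distractor objects that
# enter the VTR from capturing the track.

#' Define a rectangular vocal-tract region
#'
#' For a larynx region the conventional dimensions are 10-20 mm wide and
#' about 40 mm tall - tall enough to contain the full vertical excursion of
#' the larynx; a warning is issued when an `"LX"`-labelled region departs
#' from that geometry.
#'
#' @param label region label, e.g. `"LX"`.
#' @param top,left top-left pixel of the rectangle (row, col).
#' @param height,width rectangle size in px.
#' @param acq an [acquisition_spec()] used to validate the frame bounds and
#'   derive mm dimensions.
#' @return a `vtr_spec` object with derived `height_mm`, `width_mm`.
#' @export
vtr_spec <- function(label, top, left, height, width,
                     acq = acquisition_spec()) {
  if (!all(vapply(list(top, left, height, width), is_count, TRUE)))
    stopf("top, left, height, width must be positive integers")
  if (top + height - 1 > acq$grid_px || left + width - 1 > acq$grid_px)
    stopf("VTR extends outside the %d px frame", acq$grid_px)
  height_mm <- height * acq$px_size_mm
  width_mm <- width * acq$px_size_mm
  if (identical(label, "LX") &&
      (width_mm < 10 || width_mm > 20 || abs(height_mm - 40) > 5))
    warning(sprintf(
      "LX region is %.1f x %.1f mm; conventional larynx regions are 10-20 mm wide and ~40 mm tall",
      width_mm, height_mm), call. = FALSE)
  structure(list(label = label, top = as.integer(top), left = as.integer(left),
                 height = as.integer(height), width = as.integer(width),
                 height_mm = height_mm, width_mm = width_mm,
                 px_size_mm = acq$px_size_mm),
            class = "vtr_spec")
}

#' Resolve a segmentation threshold for a frame crop
#'
#' Policies: `fraction` (default) thresholds at `value` times the robust
#' maximum (99th percentile) of the crop; `otsu` minimises intra-class
#' intensity variance over a 256-bin histogram; `absolute` uses `value`
#' directly. The default fraction of 0.1 keeps the cut well above the
#' background noise at typical magnitude-image SNR while capturing most of
#' the object's intensity skirt, so the component centroid stays close to
#' the ideal whole-region intensity-weighted position and the pixel
#' quantisation ripple of the track is minimised.
#'
#' @param crop numeric matrix of VTR intensities.
#' @param policy list with `method` and (for fraction/absolute) `value`.
#' @return threshold intensity.
#' @export
segmentation_threshold <- function(crop,
                                   policy = list(method = "fraction",
                                                 value = 0.1)) {
  method <- policy$method %||% "fraction"
  switch(method,
    fraction = {
      v <- policy$value %||% 0.1
      v * stats::quantile(crop, 0.99, names = FALSE)
    },
    absolute = policy$value,
    otsu = {
      h <- graphics::hist(crop, breaks = seq(min(crop), max(crop),
                                             length.out = 257), plot = FALSE)
      p <- h$counts / sum(h$counts)
      mids <- h$mids
      w1 <- cumsum(p); mu <- cumsum(p * mids); muT <- mu[length(mu)]
      sb <- (muT * w1 - mu)^2 / (w1 * (1 - w1))
      sb[!is.finite(sb)] <- 0
      mids[which.max(sb)]
    },
    stopf("unknown threshold policy '%s'", method))
}

# 8-connected component labelling of a logical matrix by flood fill.
# Returns an integer matrix; components are numbered in row-major order of
# their first pixel, which gives deterministic component indices.
label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nextlab <- 0L
  # row-major scan: rows outer
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c] || lab[r, c] != 0L) next
    nextlab <- nextlab + 1L
    stack <- (c - 1L) * nr + r
    lab[r, c] <- nextlab
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      pr <- (p - 1L) %% nr + 1L; pc <- (p - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        qr <- pr + dr; qc <- pc + dc
        if (qr < 1L || qr > nr || qc < 1L || qc > nc) next
        if (mask[qr, qc] && lab[qr, qc] == 0L) {
          lab[qr, qc] <- nextlab
          stack <- c(stack, (qc - 1L) * nr + qr)
        }
      }
    }
  }
  lab
}

#' Intensity-weighted centroid of a pixel set
#'
#' `sum(intensity * coordinate) / sum(intensity)` per axis.
#'
#' @param rows,cols pixel coordinates.
#' @param intensities pixel intensities (non-negative, positive total).
#' @return named vector `c(row, col)` in continuous pixel coordinates.
#' @export
intensity_weighted_centroid <- function(rows, cols, intensities) {
  if (!length(rows)) stopf("empty component")
  w <- sum(intensities)
  if (w <= 0) stopf("component has zero total intensity")
  c(row = sum(intensities * rows) / w, col = sum(intensities * cols) / w)
}

#' Segment connected components inside a VTR
#'
#' Thresholds the VTR crop of one frame and labels the 8-connected
#' supra-threshold components. An empty result (no pixel above threshold)
#' is a valid signal value, not an error.
#'
#' @param frame numeric matrix (a full video frame).
#' @param vtr a [vtr_spec()].
#' @param threshold_policy see [segmentation_threshold()].
#' @return a list of components ordered by the row-major position of their
#'   first pixel; each has `rows`, `cols` (full-frame coordinates),
#'   `intensities`, and `centroid` (`c(row, col)`).
#' @export
segment_components <- function(frame, vtr,
                               threshold_policy = list(method = "fraction",
                                                       value = 0.1)) {
  stopifnot(is.matrix(frame), inherits(vtr, "vtr_spec"))
  rows <- vtr$top:(vtr$top + vtr$height - 1L)
  cols <- vtr$left:(vtr$left + vtr$width - 1L)
  crop <- frame[rows, cols, drop = FALSE]
  thr <- segmentation_threshold(crop, threshold_policy)
  mask <- crop >= thr & crop > 0
  if (!any(mask)) return(list())
  lab <- label_components8(mask)
  lapply(seq_len(max(lab)), function(k) {
    sel <- which(lab == k)
    r <- (sel - 1L) %% nrow(crop) + 1L
    c <- (sel - 1L) %/% nrow(crop) + 1L
    comp <- list(rows = rows[r], cols = cols[c], intensities = crop[sel])
    comp$centroid <- intensity_weighted_centroid(comp$rows, comp$cols,
                                                 comp$intensities)
    comp
  })
}

#' Select the seeded component centroid in the first frame
#'
#' Of all component centroids in the frame, returns the one closest
#' (Euclidean) to the seed point; ties go to the lower component index
#' (row-major order of first pixels).
#'
#' @param frame numeric matrix.
#' @param vtr a [vtr_spec()].
#' @param seed_row,seed_col seed point, must lie inside the VTR.
#' @param threshold_policy see [segmentation_threshold()].
#' @return list with `centroid` and `component`.
#' @export
initialize_track <- function(frame, vtr, seed_row, seed_col,
                             threshold_policy = list(method = "fraction",
                                                     value = 0.1)) {
  if (seed_row < vtr$top || seed_row > vtr$top + vtr$height - 1 ||
      seed_col < vtr$left || seed_col > vtr$left + vtr$width - 1)
    stopf("seed point must lie inside the VTR")
  comps <- segment_components(frame, vtr, threshold_policy)
  if (!length(comps))
    stopf("initialization failed: no component in the first frame")
  d <- vapply(comps, function(cp)
    sqrt((cp$centroid["row"] - seed_row)^2 + (cp$centroid["col"] - seed_col)^2),
    numeric(1))
  k <- which.min(d)  # which.min returns the first (lowest-index) minimum
  list(centroid = comps[[k]]$centroid, component = k)
}

#' Track the seeded object's centroid through a video
#'
#' Frame 1 selects the component nearest the seed; every later frame
#' selects the component whose centroid is nearest the previous centroid.
#' Frames with no supra-threshold component are flagged invalid, and the
#' last valid centroid is carried as the continuity reference so the track
#' can resume after dropouts. The vertical coordinate is also reported in
#' mm above the bottom edge of the VTR, so that raising is positive.
#'
#' @param video a [video_sequence()].
#' @param vtr a [vtr_spec()].
#' @param seed_row,seed_col seed point inside the VTR.
#' @param threshold_policy see [segmentation_threshold()].
#' @return a `centroid_track` data frame: `frame`, `time_ms`, `x_px`
#'   (column), `y_px` (row), `x_mm`, `y_mm`, `vertical_mm`, `valid`.
#' @export
track_centroids <- function(video, vtr, seed_row, seed_col,
                            threshold_policy = list(method = "fraction",
                                                    value = 0.1)) {
  stopifnot(inherits(video, "video_sequence"), inherits(vtr, "vtr_spec"))
  nf <- n_frames(video)
  y <- x <- rep(NA_real_, nf)
  valid <- logical(nf)
  init <- initialize_track(video$frames[, , 1], vtr, seed_row, seed_col,
                           threshold_policy)
  prev <- init$centroid
  y[1] <- prev["row"]; x[1] <- prev["col"]; valid[1] <- TRUE
  for (i in 2:nf) {
    comps <- segment_components(video$frames[, , i], vtr, threshold_policy)
    if (!length(comps)) next  # dropout: invalid, keep prev as reference
    d <- vapply(comps, function(cp)
      sqrt((cp$centroid["row"] - prev["row"])^2 +
           (cp$centroid["col"] - prev["col"])^2), numeric(1))
    k <- which.min(d)
    prev <- comps[[k]]$centroid
    y[i] <- prev["row"]; x[i] <- prev["col"]; valid[i] <- TRUE
  }
  px <- vtr$px_size_mm
  bottom_edge <- vtr$top + vtr$height - 1 + 0.5  # outer boundary of last row
  out <- data.frame(frame = seq_len(nf), time_ms = frame_times(video),
                    x_px = x, y_px = y, x_mm = x * px, y_mm = y * px,
                    vertical_mm = (bottom_edge - y) * px, valid = valid)
  attr(out, "vtr") <- vtr
  class(out) <- c("centroid_track", "data.frame")
  out
}

#' Local quadratic (loess) smoothing of a centroid track
#'
#' Locally weighted second-degree polynomial regression with a window of
#' `span_points` data points, applied per axis against time. Invalid frames
#' are interpolated by the fit and then re-flagged invalid. The same
#' smoothing applies to any gesture signal ahead of landmark detection
#' (an `intensity_series` is accepted via its `value` column).
#'
#' @param track a `centroid_track` from [track_centroids()], or any data
#'   frame with `time_ms` and the columns in `columns` (a missing `valid`
#'   column means all frames are valid).
#' @param span_points local span, in data points (default 30).
#' @param columns columns to smooth.
#' @return the track with smoothed columns.
#' @export
smooth_local_quadratic <- function(track, span_points = 30,
                                   columns = c("x_px", "y_px", "x_mm",
                                               "y_mm", "vertical_mm",
                                               "value")) {
  if (!is_count(span_points)) stopf("span_points must be a positive integer")
  ok <- if ("valid" %in% names(track)) track$valid else rep(TRUE, nrow(track))
  if (sum(ok) < span_points)
    stopf("track has %d valid frames; need at least span_points = %d",
          sum(ok), span_points)
  t <- track$time_ms
  for (cl in intersect(columns, names(track))) {
    df <- data.frame(tt = t[ok], yy = track[[cl]][ok])
    fit <- stats::loess(yy ~ tt, data = df, span = span_points / sum(ok),
                        degree = 2, family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    track[[cl]] <- stats::predict(fit, newdata = data.frame(tt = t))
  }
  track
}
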