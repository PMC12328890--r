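# Region-of-interest analysis for oral constriction gestures.
#
# Constriction formation by the lips, tongue tip, or tongue body shows up
# as tissue moving into a fixed, small region along the vocal-tract
# midline: the mean pixel intensity of the region rises as the constriction
# forms and falls as it releases. The midline itself is found from the
# per-pixel temporal standard deviation of the video, which is highest
# where tissue moves in and out.

#' Per-pixel temporal standard deviation map
#'
#' Sample SD of each pixel's intensity across frames. High-SD pixels trace
#' the moving air-tissue boundaries of the vocal tract.
#'
#' @param video a [video_sequence()] with at least 2 frames.
#' @return an `sd_map` object: a matrix the size of a frame.
#' @export
compute_sd_map <- function(video) {
  stopifnot(inherits(video, "video_sequence"))
  nf <- n_frames(video)
  if (nf < 2) stopf("need at least 2 frames to compute a temporal SD")
  d <- dim(video$frames)
  m <- matrix(video$frames, d[1] * d[2], nf)
  mu <- rowMeans(m)
  sdv <- sqrt(rowSums((m - mu)^2) / (nf - 1))
  structure(matrix(sdv, d[1], d[2]), class = "sd_map")
}

#' Derive a vocal-tract midline from an SD map
#'
#' Selects the `n_select` pixels with the highest temporal SD and orders
#' them into a path by nearest-neighbour chaining, starting from the most
#' anterior (smallest column, then smallest row) selected pixel. Ties in SD
#' rank and in chaining distance are broken by row-major pixel order, so the
#' result is deterministic for a given map.
#'
#' @param sd_map an `sd_map` from [compute_sd_map()].
#' @param n_select number of pixels to select.
#' @return data frame with columns `row`, `col`, `sd`, in path order.
#' @export
derive_midline <- function(sd_map, n_select = 100) {
  stopifnot(inherits(sd_map, "sd_map"))
  if (all(sd_map == 0)) stopf("SD map is all zero (static video)")
  if (!is_count(n_select)) stopf("n_select must be a positive integer")
  n_select <- min(n_select, sum(sd_map > 0))
  m <- unclass(sd_map)
  # ties resolve in row-major order: top-to-bottom, then left-to-right
  idx <- order(-as.vector(m), row(m), col(m))[seq_len(n_select)]
  pts <- data.frame(row = row(m)[idx], col = col(m)[idx],
                    sd = as.vector(m)[idx])
  start <- order(pts$col, pts$row)[1]
  path <- integer(n_select)
  path[1] <- start
  left <- setdiff(seq_len(n_select), start)
  for (i in seq_len(n_select - 1)) {
    cur <- path[i]
    d2 <- (pts$row[left] - pts$row[cur])^2 + (pts$col[left] - pts$col[cur])^2
    best <- left[order(d2, pts$row[left], pts$col[left])[1]]
    path[i + 1] <- best
    left <- setdiff(left, best)
  }
  out <- pts[path, ]
  rownames(out) <- NULL
  out
}

#' Define a pseudo-circular region of interest
#'
#' A region of radius `radius_px` (default 3, the conventional choice at
#' 2.4 mm pixels) centred on a pixel. Membership uses a centre-in-circle
#' test: pixel (r, c) belongs if its centre lies within `radius_px` of the
#' region centre.
#'
#' @param label region label, typically one of `"LAB"`, `"COR"`, `"DOR"`;
#'   free-form labels are allowed.
#' @param center_row,center_col region centre, px.
#' @param radius_px radius in px (>= 1).
#' @param frame_px frame size used to validate that the region lies fully
#'   inside the image, or `NULL` to skip validation here.
#' @return an `roi_spec` object.
#' @export
roi_spec <- function(label, center_row, center_col, radius_px = 3,
                     frame_px = NULL) {
  if (radius_px < 1) stopf("radius_px must be >= 1")
  if (!is.null(frame_px)) {
    if (center_row - radius_px < 1 || center_row + radius_px > frame_px ||
        center_col - radius_px < 1 || center_col + radius_px > frame_px)
      stopf("ROI '%s' is not fully inside the %d px frame", label, frame_px)
  }
  structure(list(label = label, center_row = center_row,
                 center_col = center_col, radius_px = radius_px),
            class = "roi_spec")
}

roi_pixel_mask <- function(roi, nrow_px, ncol_px) {
  r <- matrix(seq_len(nrow_px), nrow_px, ncol_px)
  c <- matrix(seq_len(ncol_px), nrow_px, ncol_px, byrow = TRUE)
  (r - roi$center_row)^2 + (c - roi$center_col)^2 <= roi$radius_px^2
}

#' Mean-intensity time series of a region of interest
#'
#' Frame-by-frame mean intensity over the region's pixels. Higher values
#' indicate more tissue inside the region, i.e. a more fully formed
#' constriction.
#'
#' @param video a [video_sequence()].
#' @param roi an [roi_spec()].
#' @return an `intensity_series` object: a data frame with columns `frame`,
#'   `time_ms`, `value`, and attributes `label`.
#' @export
roi_intensity_series <- function(video, roi) {
  stopifnot(inherits(video, "video_sequence"), inherits(roi, "roi_spec"))
  d <- dim(video$frames)
  if (roi$center_row - roi$radius_px < 1 || roi$center_row + roi$radius_px > d[1] ||
      roi$center_col - roi$radius_px < 1 || roi$center_col + roi$radius_px > d[2])
    stopf("ROI '%s' is not fully inside the frame", roi$label)
  mask <- roi_pixel_mask(roi, d[1], d[2])
  npx <- d[1] * d[2]
  m <- matrix(video$frames, npx, d[3])
  vals <- colMeans(m[as.vector(mask), , drop = FALSE])
  out <- data.frame(frame = seq_len(d[3]), time_ms = frame_times(video),
                    value = vals)
  attr(out, "label") <- roi$label
  class(out) <- c("intensity_series", "data.frame")
  out
}

#' Locally weighted linear smoothing of an intensity series
#'
#' Fits a weighted straight line around every sample and evaluates it at
#' that sample. With `h_units = "frames"` (default) the weights are
#' Gaussian with standard deviation `h` frame periods, a light smoothing
#' that suppresses frame-to-frame noise while leaving the velocity
#' structure of gestures (and hence threshold landmarks) essentially
#' unbiased. With `h_units = "fraction"` the classical tricube
#' nearest-neighbour weighting is used with span `h` (a fraction of the
#' series); spans that are large relative to a gesture flatten its velocity
#' profile and are not suitable ahead of landmark detection.
#'
#' @param series an `intensity_series` (or any data frame with `time_ms`
#'   and `value`), at least 5 points.
#' @param h kernel width: SD in frame periods, or span fraction.
#' @param h_units `"frames"` or `"fraction"`.
#' @return the series with `value` replaced by its smoothed version.
#' @export
smooth_weighted_linear <- function(series, h = 0.9,
                                   h_units = c("frames", "fraction")) {
  h_units <- match.arg(h_units)
  t <- series$time_ms; y <- series$value
  n <- length(y)
  if (n < 5) stopf("need at least 5 points to smooth")
  if (diff(range(t)) == 0) stopf("degenerate series: all timestamps equal")
  if (h <= 0) stopf("h must be positive")
  if (h_units == "fraction") {
    if (h > 1) stopf("span fraction must be <= 1")
    fit <- stats::loess(y ~ t, span = h, degree = 1, family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    series$value <- stats::predict(fit, newdata = data.frame(t = t))
    return(series)
  }
  dt <- stats::median(diff(t))
  out <- numeric(n)
  halfw <- max(2L, ceiling(4 * h))  # beyond 4 SD the weights are negligible
  for (i in seq_len(n)) {
    j <- max(1L, i - halfw):min(n, i + halfw)
    w <- exp(-0.5 * ((t[j] - t[i]) / (h * dt))^2)
    X <- cbind(1, t[j] - t[i])
    out[i] <- stats::lm.wfit(X, y[j], w)$coefficients[1]
  }
  series$value <- out
  series
}
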