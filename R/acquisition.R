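#' Acquisition geometry of a real-time MRI protocol
#'
#' Describes the spatial and temporal calibration of a dynamic mid-sagittal
#' MRI sequence: field of view, reconstruction grid, spiral repetition time,
#' number of interleaves, and the sliding-window width used for view-sharing
#' reconstruction. The effective frame rate and pixel size are derived, not
#' set: `frame_rate_fps = 1000 / (sliding_window_tr * tr_ms)` and
#' `px_size_mm = fov_mm / grid_px`.
#'
#' The defaults reproduce a 1.5 T speech-production protocol: 200 mm field of
#' view on an 84 x 84 grid (2.38 mm pixels), TR 6.004 ms with 13 spiral
#' interleaves (so each fully sampled image spans 78.052 ms), and a 2-TR
#' sliding window giving an effective rate of 83.3 frames/s.
#'
#' @param fov_mm field of view in mm (square).
#' @param grid_px reconstruction grid size in pixels (square).
#' @param tr_ms repetition time of one spiral interleaf, ms.
#' @param interleaves number of spiral interleaves per fully sampled image.
#' @param sliding_window_tr width of the view-sharing window, in TRs.
#' @return an object of class `acquisition_spec` with derived fields
#'   `frame_rate_fps`, `frame_period_ms`, `px_size_mm` and
#'   `image_span_ms` (`interleaves * tr_ms`).
#' @examples
#' acq <- acquisition_spec()
#' acq$frame_rate_fps  # ~83.3
#' acq$px_size_mm      # ~2.38
#' @export
acquisition_spec <- function(fov_mm = 200, grid_px = 84, tr_ms = 6.004,
                             interleaves = 13, sliding_window_tr = 2) {
  vals <- c(fov_mm = fov_mm, grid_px = grid_px, tr_ms = tr_ms,
            interleaves = interleaves, sliding_window_tr = sliding_window_tr)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stopf("all acquisition parameters must be positive and finite")
  if (!is_count(grid_px)) stopf("grid_px must be a positive integer")
  spec <- list(
    fov_mm = fov_mm, grid_px = as.integer(grid_px), tr_ms = tr_ms,
    interleaves = as.integer(interleaves),
    sliding_window_tr = as.integer(sliding_window_tr),
    frame_rate_fps = 1000 / (sliding_window_tr * tr_ms),
    frame_period_ms = sliding_window_tr * tr_ms,
    px_size_mm = fov_mm / grid_px,
    image_span_ms = interleaves * tr_ms
  )
  class(spec) <- "acquisition_spec"
  spec
}

#' @export
print.acquisition_spec <- function(x, ...) {
  cat(sprintf(
    "rtMRI acquisition: %g x %g mm FOV on %d x %d px (%.3f mm/px)\n",
    x$fov_mm, x$fov_mm, x$grid_px, x$grid_px, x$px_size_mm))
  cat(sprintf(
    "  TR %.3f ms, %d interleaves (image span %.3f ms), %d-TR window -> %.1f frames/s\n",
    x$tr_ms, x$interleaves, x$image_span_ms, x$sliding_window_tr,
    x$frame_rate_fps))
  invisible(x)
}
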