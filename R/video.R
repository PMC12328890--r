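#' Construct a dynamic image sequence
#'
#' An ordered stack of grayscale frames with spatial (mm/px) and temporal
#' (ms/frame) calibration taken from an [acquisition_spec()]. Frames are
#' stored as a 3-D array `[row, col, frame]` with row 1 at the top of the
#' image and intensities on a floating-point `[0, 1]` scale.
#'
#' @param frames numeric 3-D array `[row, col, frame]`, or a matrix for a
#'   single frame.
#' @param acq an [acquisition_spec()] providing calibration.
#' @return an object of class `video_sequence`.
#' @export
video_sequence <- function(frames, acq = acquisition_spec()) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3)
    stopf("frames must be a [row, col, frame] array")
  stopifnot(inherits(acq, "acquisition_spec"))
  structure(list(frames = frames, acq = acq), class = "video_sequence")
}

#' Number of frames in a video sequence
#' @param video a [video_sequence()].
#' @return integer frame count.
#' @export
n_frames <- function(video) {
  stopifnot(inherits(video, "video_sequence"))
  dim(video$frames)[3]
}

#' Frame timestamps of a video sequence
#'
#' Frame `i` is stamped `(i - 1) * frame_period_ms`, i.e. the first frame is
#' at 0 ms.
#'
#' @param video a [video_sequence()].
#' @return numeric vector of times in ms.
#' @export
frame_times <- function(video) {
  stopifnot(inherits(video, "video_sequence"))
  (seq_len(n_frames(video)) - 1) * video$acq$frame_period_ms
}

#' @export
print.video_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("video_sequence: %d frames of %d x %d px, %.1f frames/s (%.1f ms)\n",
              d[3], d[1], d[2], x$acq$frame_rate_fps,
              d[3] * x$acq$frame_period_ms))
  invisible(x)
}

#' Write a video sequence as a multi-page TIFF
#'
#' One grayscale page per frame, 16-bit, intensities clipped to `[0, 1]`.
#'
#' @param video a [video_sequence()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_video_tiff <- function(video, path) {
  stopifnot(inherits(video, "video_sequence"))
  n <- n_frames(video)
  pages <- lapply(seq_len(n), function(i) {
    fr <- video$frames[, , i]
    fr[fr < 0] <- 0; fr[fr > 1] <- 1
    fr
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF as a video sequence
#'
#' @param path TIFF file path.
#' @param acq an [acquisition_spec()] giving the calibration of the
#'   recording (TIFF carries no temporal metadata).
#' @return a [video_sequence()].
#' @export
read_video_tiff <- function(path, acq = acquisition_spec()) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- vapply(pages, identity,
                   matrix(0, nrow(pages[[1]]), ncol(pages[[1]])))
  video_sequence(frames, acq)
}
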