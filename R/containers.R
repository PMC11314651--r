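#' Luminance frame stack
#'
#' A `frame_stack` holds a non-contact AVF recording as a 3-D luminance array
#' indexed `(frame, row, col)`, together with its sampling metadata. Each
#' pixel's time series is one AVF waveform; the whole stack is what the camera
#' writes to a multi-page TIFF.
#'
#' @param data Numeric 3-D array, dimensions `(frames, rows, cols)`.
#' @param fps Frame rate in Hz (default 40, the acquisition rate of the
#'   imaging system).
#' @param pixel_pitch_mm Spatial sampling in mm per pixel (default 0.08).
#' @param meta Named list of free-form provenance (seed, cohort label, ...).
#'
#' @return An object of class `frame_stack` with elements `data`, `fps`,
#'   `pixel_pitch_mm`, `meta`.
#' @examples
#' st <- frame_stack(array(rnorm(4 * 3 * 3), c(4, 3, 3)), fps = 40)
#' dim(st$data)
#' @export
frame_stack <- function(data, fps = 40, pixel_pitch_mm = 0.08, meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-D array (frame, row, col)")
  }
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    stop("`fps` must be a positive scalar")
  }
  if (dim(data)[1] < 1L) stop("stack must contain at least one frame")
  structure(
    list(data = data, fps = fps, pixel_pitch_mm = pixel_pitch_mm, meta = meta),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<frame_stack> %d frames of %d x %d px @ %g fps (%.2f s, pitch %g mm)\n",
    d[1], d[2], d[3], x$fps, d[1] / x$fps, x$pixel_pitch_mm
  ))
  if (!is.null(x$meta$cohort_label)) {
    cat("  cohort:", x$meta$cohort_label, "\n")
  }
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$data)

n_frames <- function(stack) dim(stack$data)[1]
n_rows <- function(stack) dim(stack$data)[2]
n_cols <- function(stack) dim(stack$data)[3]

#' Luminance waveform
#'
#' A single AVF luminance time series at a fixed sampling rate — the object
#' whose spectrum carries the pulse harmonics and the 5-10 Hz Thrill
#' component.
#'
#' @param samples Numeric vector of luminance values.
#' @param fs Sampling rate in Hz.
#' @return An object of class `waveform` with elements `samples` and `fs`.
#' @examples
#' w <- waveform(sin(2 * pi * 1.2 * (0:399) / 40), fs = 40)
#' @export
waveform <- function(samples, fs) {
  if (!is.numeric(samples) || length(samples) < 1L) {
    stop("`samples` must be a non-empty numeric vector")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a positive scalar")
  }
  structure(list(samples = as.numeric(samples), fs = fs), class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf(
    "<waveform> %d samples @ %g Hz (%.2f s)\n",
    length(x$samples), x$fs, length(x$samples) / x$fs
  ))
  invisible(x)
}

#' @export
length.waveform <- function(x) length(x$samples)

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# drop S3 classes recursively so nested result objects serialize as plain JSON
strip_s3 <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_s3) else x
}

stopifnot_odd <- function(n, what = "kernel size") {
  if (!is.numeric(n) || length(n) != 1L || n != round(n) || n < 1 || n %% 2 == 0) {
    stop(sprintf("%s must be a positive odd integer, got %s", what, format(n)))
  }
}
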