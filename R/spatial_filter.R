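#' Moving-average (box) kernel
#'
#' The N x N uniform smoothing kernel applied frame-by-frame to suppress
#' diffuse-reflection noise: every weight equals `1/N^2`, so the filtered
#' value g(i, j) is the plain mean of the centered N x N window around
#' f(i, j). N must be odd so the window has a center pixel.
#'
#' @param size_n Odd positive integer N.
#' @return A list of class `kernel` with `size_n` and the `weights` matrix.
#' @export
box_kernel <- function(size_n) {
  stopifnot_odd(size_n)
  structure(
    list(size_n = as.integer(size_n),
         weights = matrix(1 / size_n^2, size_n, size_n)),
    class = "kernel"
  )
}

# indices of a replicate-padded axis of length n with half-width h
clamp_index <- function(n, h) pmin(pmax(seq(1 - h, n + h), 1L), n)

# box mean of one frame (matrix) with replicate padding, via integral image
box_mean_frame <- function(frame, size_n) {
  if (size_n == 1L) return(frame)
  rng <- range(frame)
  if (rng[1] == rng[2]) return(frame) # constant frames are fixed points, exactly
  h <- (size_n - 1L) %/% 2L
  nr <- nrow(frame)
  nc <- ncol(frame)
  p <- frame[clamp_index(nr, h), clamp_index(nc, h), drop = FALSE]
  # summed-area table with a zero border
  s <- matrix(0, nrow(p) + 1L, ncol(p) + 1L)
  s[-1L, -1L] <- apply(apply(p, 2L, cumsum), 1L, cumsum) |> t()
  i1 <- seq_len(nr)
  i2 <- i1 + size_n
  j1 <- seq_len(nc)
  j2 <- j1 + size_n
  (s[i2, j2] - s[i1, j2] - s[i2, j1] + s[i1, j1]) / size_n^2
}

#' Spatial moving-average filter over an image stack
#'
#' Smooths every frame with the centered N x N uniform kernel, sliding one
#' pixel at a time in a raster scan. Borders are handled by edge replication,
#' so the output has the same shape as the input and constant images are
#' preserved exactly. This is the denoising stage applied before any spectral
#' analysis; increasing N suppresses spatially incoherent noise while the
#' spatially smooth vessel signal survives.
#'
#' @param stack A [frame_stack()].
#' @param size_n Odd kernel size N with `1 <= N <= min(rows, cols)`.
#' @return A [frame_stack()] of identical shape holding g(i, j) per frame.
#' @examples
#' st <- frame_stack(array(rnorm(2 * 8 * 8), c(2, 8, 8)))
#' sm <- moving_average(st, 3)
#' @export
moving_average <- function(stack, size_n) {
  stopifnot(inherits(stack, "frame_stack"))
  stopifnot_odd(size_n)
  if (size_n > min(n_rows(stack), n_cols(stack))) {
    stop(sprintf("kernel size %d exceeds image extent %d x %d",
                 size_n, n_rows(stack), n_cols(stack)))
  }
  if (size_n == 1L) return(stack)
  out <- stack$data
  for (t in seq_len(n_frames(stack))) {
    out[t, , ] <- box_mean_frame(stack$data[t, , ], size_n)
  }
  frame_stack(out, fps = stack$fps, pixel_pitch_mm = stack$pixel_pitch_mm,
              meta = c(stack$meta, list(kernel_n = as.integer(size_n))))
}

#' Default kernel-size sweep grid
#'
#' Odd kernel sizes 1, 3, ..., 201 — the 101-point sweep used to trace
#' SNR_thr as a function of N. For images smaller than 201 px pass
#' `max_n = ` the largest odd size that fits.
#'
#' @param max_n Largest kernel size (default 201).
#' @return Integer vector of odd sizes.
#' @examples
#' length(default_kernel_grid()) # 101
#' @export
default_kernel_grid <- function(max_n = 201) {
  if (max_n < 1) stop("`max_n` must be >= 1")
  seq(1L, as.integer(max_n), by = 2L)
}

#' Apply the moving average over a sweep of kernel sizes
#'
#' One smoothed stack per kernel size; the default grid yields 101 smoothed
#' versions of the recording. Note this materializes every smoothed stack —
#' for SNR curves use [snr_curve()], which smooths only the analysis pixel.
#'
#' @param stack A [frame_stack()].
#' @param n_values Odd kernel sizes (default [default_kernel_grid()]).
#' @return Named list mapping kernel size to the smoothed [frame_stack()].
#' @export
sweep_kernels <- function(stack, n_values = default_kernel_grid()) {
  res <- lapply(n_values, function(n) moving_average(stack, n))
  names(res) <- as.character(n_values)
  res
}

# Time series of pixel (r, c) after an N x N moving average, computed without
# smoothing the full stack: with replicate padding the smoothed value is a
# fixed weighted mean of whole-pixel time series, weights = outer product of
# clamped-index multiplicities. Exactly equals
# extract_waveform(moving_average(stack, n), c(r, c)).
smoothed_pixel_waveform <- function(stack, roi, size_n) {
  stopifnot_odd(size_n)
  nr <- n_rows(stack)
  nc <- n_cols(stack)
  r <- as.integer(roi[1])
  c <- as.integer(roi[2])
  if (r < 1 || r > nr || c < 1 || c > nc) stop("roi outside image")
  if (size_n > min(nr, nc)) stop("kernel size exceeds image extent")
  h <- (size_n - 1L) %/% 2L
  wr <- tabulate(pmin(pmax((r - h):(r + h), 1L), nr), nbins = nr)
  wc <- tabulate(pmin(pmax((c - h):(c + h), 1L), nc), nbins = nc)
  w <- as.vector(wr %o% wc) / size_n^2
  idx <- which(w > 0) # only the window's pixels contribute
  m <- matrix(stack$data, n_frames(stack), nr * nc)[, idx, drop = FALSE]
  # center each pixel series before the weighted sum: identical in exact
  # arithmetic, but keeps the large luminance baseline out of the accumulation
  mu <- colMeans(m)
  y <- as.numeric(sweep(m, 2, mu) %*% w[idx]) + sum(mu * w[idx])
  waveform(y, fs = stack$fps)
}
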