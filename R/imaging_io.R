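#' Write a frame stack to a multi-page grayscale TIFF
#'
#' Stores the stack as 16-bit (or 8-bit) grayscale pages, one frame per page,
#' with no compression — the lossless on-disk format of the acquisition
#' system. Luminance values must already be integers on the digital-number
#' grid (`0 .. 2^bits - 1`), as produced by [generate_stack()] with
#' `quantize = TRUE`; non-integer stacks are rejected so a round trip is
#' always exact. Sampling metadata goes to a YAML sidecar `<path>.yaml`.
#'
#' @param stack A [frame_stack()] with integer-valued data in range.
#' @param path Output TIFF path.
#' @param bits Bits per sample, 8 or 16 (default 16).
#' @param sidecar Write the YAML sidecar with `fps`, `pixel_pitch_mm` and
#'   `meta` (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16, sidecar = TRUE) {
  stopifnot(inherits(stack, "frame_stack"))
  if (!bits %in% c(8, 16)) stop("`bits` must be 8 or 16")
  maxdn <- 2^bits - 1
  d <- stack$data
  if (any(d != round(d)) || min(d) < 0 || max(d) > maxdn) {
    stop(sprintf(
      "stack data must be integers in [0, %d] for lossless %d-bit TIFF storage; quantize first",
      maxdn, bits
    ))
  }
  frames <- lapply(seq_len(dim(d)[1]), function(t) d[t, , ] / maxdn)
  tiff::writeTIFF(frames, path, bits.per.sample = bits, compression = "none")
  if (sidecar) {
    yaml::write_yaml(
      c(list(fps = stack$fps, pixel_pitch_mm = stack$pixel_pitch_mm, bits = bits),
        stack$meta),
      paste0(path, ".yaml")
    )
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF into a frame stack
#'
#' Inverse of [write_stack()]: pages become frames, pixel values are returned
#' on the original integer digital-number grid, and `fps` / `pixel_pitch_mm`
#' are taken from the YAML sidecar when present (defaults 40 fps, 0.08 mm
#' otherwise).
#'
#' @param path Path to a multi-page grayscale TIFF.
#' @param fps,pixel_pitch_mm Fallbacks when no sidecar exists.
#' @return A [frame_stack()].
#' @export
read_stack <- function(path, fps = 40, pixel_pitch_mm = 0.08) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1)))) {
    stop("TIFF contains non-grayscale (multi-channel) pages")
  }
  shapes <- vapply(pages, dim, integer(2))
  if (ncol(shapes) > 1 && any(shapes != shapes[, 1])) {
    stop("TIFF pages have unequal shapes")
  }
  meta <- list()
  side <- paste0(path, ".yaml")
  if (file.exists(side)) {
    y <- yaml::read_yaml(side)
    if (!is.null(y$fps)) fps <- y$fps
    if (!is.null(y$pixel_pitch_mm)) pixel_pitch_mm <- y$pixel_pitch_mm
    meta <- y[setdiff(names(y), c("fps", "pixel_pitch_mm"))]
  }
  data <- array(0, c(length(pages), shapes[1, 1], shapes[2, 1]))
  for (t in seq_along(pages)) data[t, , ] <- pages[[t]]
  frame_stack(data, fps = fps, pixel_pitch_mm = pixel_pitch_mm, meta = meta)
}

#' Extract the waveform of a single pixel
#'
#' Returns the luminance time series at one pixel. Spatial context enters the
#' analysis only through the moving-average filter ([moving_average()]); this
#' accessor is a pure projection, independent of all other pixels.
#'
#' @param stack A [frame_stack()].
#' @param roi_center Integer `(row, col)`, 1-based.
#' @return A [waveform()] with `fs = stack$fps`.
#' @export
extract_waveform <- function(stack, roi_center) {
  stopifnot(inherits(stack, "frame_stack"), length(roi_center) == 2L)
  r <- as.integer(roi_center[1])
  c <- as.integer(roi_center[2])
  if (r < 1 || r > n_rows(stack) || c < 1 || c > n_cols(stack)) {
    stop(sprintf("roi_center (%d, %d) outside %d x %d image", r, c,
                 n_rows(stack), n_cols(stack)))
  }
  waveform(stack$data[, r, c], fs = stack$fps)
}

#' Automatically select the analysis pixel
#'
#' Picks the pixel with the largest Thrill-band (5-10 Hz) power after a
#' default 21 x 21 moving average — i.e. the point on the smoothed image where
#' the vessel's vibration is strongest. Saturated or otherwise constant raw
#' pixels (e.g. specular halation patches) carry no luminance signal and are
#' excluded from candidacy, unless the whole stack is constant. Deterministic;
#' exact ties are broken in row-major order (first by row, then by column).
#' The smoothing kernel is shrunk to the largest odd size that fits if the
#' image is smaller than `kernel_n`.
#'
#' @param stack A [frame_stack()] with at least 256 frames.
#' @param kernel_n Moving-average kernel size used before the band-power map
#'   (odd, default 21).
#' @param band Frequency band in Hz (default `c(5, 10)`).
#' @return Integer vector `(row, col)`, 1-based.
#' @export
auto_select_roi <- function(stack, kernel_n = 21, band = c(5, 10)) {
  stopifnot(inherits(stack, "frame_stack"))
  nt <- n_frames(stack)
  if (nt < 256) stop("stack too short for one FFT segment (need >= 256 frames)")
  k <- min(kernel_n, n_rows(stack), n_cols(stack))
  if (k %% 2 == 0) k <- k - 1
  nr <- n_rows(stack)
  nc <- n_cols(stack)
  # spatial smoothing is linear, so it commutes with the temporal FFT:
  # smooth only the in-band FFT coefficient planes instead of every frame
  m <- matrix(stack$data, nt, nr * nc) # columns = pixels, column-major
  X <- stats::mvfft(m)
  f <- (seq_len(nt) - 1) * stack$fps / nt
  sel <- which(f >= band[1] & f <= band[2]) # excludes DC, no mean removal needed
  pmat <- matrix(0, nr, nc)
  for (b in sel) {
    re <- box_mean_frame(matrix(Re(X[b, ]), nr, nc), k)
    im <- box_mean_frame(matrix(Im(X[b, ]), nr, nc), k)
    pmat <- pmat + re^2 + im^2
  }
  # constant raw pixels (saturated halation) hold no signal at kernel 1
  live <- matrix(col_vars(m) > 0, nr, nc)
  if (any(live)) pmat[!live] <- -Inf
  # row-major tie-break: scan rows first
  idx <- which.max(as.vector(t(pmat)))
  c(row = (idx - 1) %/% nc + 1L, col = (idx - 1) %% nc + 1L)
}

# per-column (pixel) variance of the frames x pixels matrix
col_vars <- function(m) {
  mu <- colMeans(m)
  colMeans(m^2) - mu^2
}

#' Export a waveform as CSV
#'
#' Two columns: `time_s`, `luminance`.
#'
#' @param w A [waveform()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  utils::write.csv(
    data.frame(time_s = (seq_along(w$samples) - 1) / w$fs, luminance = w$samples),
    path,
    row.names = FALSE
  )
  invisible(path)
}

#' Read a waveform from CSV
#'
#' @param path CSV with columns `time_s`, `luminance` (as written by
#'   [write_waveform_csv()]); `fs` is inferred from the time column.
#' @return A [waveform()].
#' @export
read_waveform_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "luminance") %in% names(d))) {
    stop("CSV must have columns time_s, luminance")
  }
  dt <- diff(d$time_s)
  if (length(dt) < 1 || any(dt <= 0)) stop("time_s must be strictly increasing")
  waveform(d$luminance, fs = 1 / stats::median(dt))
}
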