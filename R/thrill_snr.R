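#' Band peaks for one kernel size
#'
#' Runs the per-kernel quantification pipeline at one analysis pixel:
#' smooth with the N x N moving average, take the pixel waveform, then for
#' each of the two bands — Thrill 5-10 Hz, reference noise 15-20 Hz —
#' band-pass filter, compute segmented Hanning-windowed power spectra, take
#' each segment's in-band peak, and report the median across segments.
#' The waveform mean is removed before filtering (DC carries no Thrill
#' information and would otherwise dominate edge transients).
#'
#' @param stack A [frame_stack()] with >= 256 frames.
#' @param roi `(row, col)` analysis pixel, 1-based.
#' @param kernel_n Odd moving-average kernel size N.
#' @param thrill_band,noise_band Band edges in Hz.
#' @param nfft,overlap Spectral segmentation settings (see
#'   [segment_spectra()]).
#' @return List of class `band_peaks`: `kernel_n`, `peak_thrill`,
#'   `peak_noise`.
#' @export
band_peaks_for_kernel <- function(stack, roi, kernel_n,
                                  thrill_band = c(5, 10), noise_band = c(15, 20),
                                  nfft = 256, overlap = 0.75) {
  stopifnot(inherits(stack, "frame_stack"))
  if (n_frames(stack) < nfft) {
    stop(sprintf("stack has %d frames; need >= %d for one FFT segment",
                 n_frames(stack), nfft))
  }
  w <- smoothed_pixel_waveform(stack, roi, kernel_n)
  w$samples <- w$samples - mean(w$samples)
  structure(
    list(
      kernel_n = as.integer(kernel_n),
      peak_thrill = median_band_peak(w, thrill_band, nfft, overlap),
      peak_noise = median_band_peak(w, noise_band, nfft, overlap)
    ),
    class = "band_peaks"
  )
}

median_band_peak <- function(w, band, nfft, overlap) {
  filtered <- bandpass(w, band[1], band[2])
  spectra <- segment_spectra(filtered, nfft = nfft, overlap = overlap)
  stats::median(vapply(spectra, band_peak, numeric(1), f_lo = band[1], f_hi = band[2]))
}

#' Thrill signal-to-noise ratio
#'
#' `SNR_thr(N) = Peak_thrill(N) / Peak_noise(N)`: the median Thrill-band
#' (5-10 Hz) spectral peak over the median noise-band (15-20 Hz) spectral
#' peak. Dimensionless and invariant to global luminance rescaling.
#'
#' @param bp A `band_peaks` object from [band_peaks_for_kernel()].
#' @return Scalar SNR.
#' @export
snr_thr <- function(bp) {
  stopifnot(inherits(bp, "band_peaks"))
  if (bp$peak_noise <= 0) {
    stop("peak_noise is zero (noiseless input): SNR_thr is degenerate")
  }
  bp$peak_thrill / bp$peak_noise
}

#' SNR_thr across the kernel-size sweep
#'
#' Computes `SNR_thr(N)` for every kernel size in `n_values` at a fixed
#' analysis pixel — the same pixel for all N. The default 1..201 odd grid
#' traces 101 values; images smaller than the largest requested kernel must
#' be swept with a capped grid (see [default_kernel_grid()]).
#'
#' @inheritParams band_peaks_for_kernel
#' @param roi `(row, col)` analysis pixel; `NULL` selects it with
#'   [auto_select_roi()].
#' @param n_values Odd kernel sizes (default [default_kernel_grid()]).
#' @param recording_id,cohort_label Optional labels carried into the result
#'   (default: taken from `stack$meta` when present).
#' @return An object of class `snr_curve_result`: data frame `entries` with
#'   columns `kernel_n`, `peak_thrill`, `peak_noise`, `snr`, plus
#'   `recording_id`, `cohort_label`, `roi`.
#' @export
snr_curve <- function(stack, roi = NULL, n_values = default_kernel_grid(),
                      thrill_band = c(5, 10), noise_band = c(15, 20),
                      nfft = 256, overlap = 0.75,
                      recording_id = NULL, cohort_label = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  n_values <- as.integer(n_values)
  if (any(n_values %% 2L == 0L) || any(n_values < 1L)) {
    stop("all kernel sizes must be positive odd integers")
  }
  if (is.unsorted(n_values, strictly = TRUE)) stop("n_values must be strictly increasing")
  if (is.null(roi)) roi <- auto_select_roi(stack)
  if (is.null(recording_id)) recording_id <- stack$meta$recording_id %||% "rec"
  if (is.null(cohort_label)) cohort_label <- stack$meta$cohort_label %||% NA_character_
  rows <- lapply(n_values, function(n) {
    bp <- band_peaks_for_kernel(stack, roi, n, thrill_band, noise_band, nfft, overlap)
    data.frame(kernel_n = bp$kernel_n, peak_thrill = bp$peak_thrill,
               peak_noise = bp$peak_noise, snr = snr_thr(bp))
  })
  structure(
    list(entries = do.call(rbind, rows), recording_id = recording_id,
         cohort_label = cohort_label, roi = as.integer(roi)),
    class = "snr_curve_result"
  )
}

#' @export
print.snr_curve_result <- function(x, ...) {
  cat(sprintf("<snr_curve> %s [%s], %d kernel sizes, roi (%d, %d)\n",
              x$recording_id, x$cohort_label, nrow(x$entries), x$roi[1], x$roi[2]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flatten SNR curves into the interchange table
#'
#' Long-format table, one row per (recording, kernel size): the CSV format
#' consumed by the kernel-optimization and group-comparison stages.
#'
#' @param curves A list of `snr_curve_result` objects (or a single one).
#' @return Data frame with columns `recording_id`, `cohort_label`,
#'   `kernel_n`, `peak_thrill`, `peak_noise`, `snr`.
#' @export
snr_curves_table <- function(curves) {
  if (inherits(curves, "snr_curve_result")) curves <- list(curves)
  do.call(rbind, lapply(curves, function(cv) {
    cbind(
      data.frame(recording_id = cv$recording_id, cohort_label = cv$cohort_label,
                 stringsAsFactors = FALSE),
      cv$entries
    )
  }))
}

#' Write / read the SNR-curve interchange CSV
#'
#' @param tab Data frame as produced by [snr_curves_table()].
#' @param path CSV path.
#' @return `path` (writer, invisibly) or the data frame (reader).
#' @export
write_snr_csv <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_snr_csv
#' @export
read_snr_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
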