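#' Power spectrum of one windowed segment
#'
#' One-sided power spectrum container. `power` is scaled so that
#' `sum(power)` equals the energy (mean square x length) of the tapered,
#' mean-removed segment — Parseval's identity holds exactly.
#'
#' @param freqs Frequency bins in Hz, nondecreasing, max <= fs/2.
#' @param power Nonnegative power values (luminance^2).
#' @param window Taper label (e.g. `"hanning"`).
#' @param nfft Segment length in samples.
#' @return An object of class `power_spectrum`.
#' @export
power_spectrum <- function(freqs, power, window = "hanning", nfft = length(power)) {
  if (length(freqs) != length(power)) stop("freqs and power lengths differ")
  if (is.unsorted(freqs)) stop("freqs must be nondecreasing")
  if (any(power < -1e-12)) stop("power must be nonnegative")
  structure(list(freqs = freqs, power = pmax(power, 0), window = window,
                 nfft = as.integer(nfft)),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins, 0-%.3g Hz, %s window, nfft=%d\n",
              length(x$freqs), max(x$freqs), x$window, x$nfft))
  invisible(x)
}

butter_sos <- function(order, w, type) signal::butter(order, w, type = type)

# One IIR pass started from its steady state for a level x0: as if the input
# had been x0 forever, so a constant input produces no startup transient.
iir_steady <- function(b, a, x, x0) {
  g0 <- sum(b) / sum(a) # DC gain
  as.numeric(signal::filter(b, a, x,
                            init.x = rep(x0, length(b) - 1),
                            init.y = rep(x0 * g0, length(a) - 1)))
}

# Zero-phase filtering: forward-backward application with odd-reflection
# padding at both ends (3 x filter length) and steady-state initial
# conditions, which together suppress the edge transients of a bare
# forward-backward pass.
zero_phase <- function(b, a, x) {
  nf <- max(length(b), length(a))
  pad <- 3L * (nf - 1L)
  n <- length(x)
  if (n <= pad) {
    stop(sprintf("waveform too short for zero-phase filtering (need > %d samples)", pad))
  }
  head_pad <- 2 * x[1] - x[(pad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - pad)]
  xp <- c(head_pad, x, tail_pad)
  y <- iir_steady(b, a, xp, xp[1])
  y <- rev(iir_steady(b, a, rev(y), y[length(y)]))
  y[(pad + 1):(pad + n)]
}

#' Band-pass filter a waveform
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass. The Thrill
#' component is extracted with `bandpass(w, 5, 10)`; the reference noise band
#' with `bandpass(w, 15, 20)`. When `f_hi` reaches Nyquist (as the 15-20 Hz
#' band does at 40 fps) the band-pass degenerates to a high-pass at `f_lo`:
#' a digital corner at Nyquist is ill-posed (and one squeezed just below it
#' puts poles nearly on the unit circle), while sampling itself already
#' bounds the band at fs/2.
#'
#' @param w A [waveform()].
#' @param f_lo,f_hi Band edges in Hz, `0 < f_lo < f_hi <= fs/2`.
#' @return The filtered [waveform()], same length.
#' @export
bandpass <- function(w, f_lo, f_hi) {
  stopifnot(inherits(w, "waveform"))
  nyq <- w$fs / 2
  if (!(f_lo > 0 && f_lo < f_hi && f_hi <= nyq + 1e-9)) {
    stop(sprintf("invalid band [%g, %g] Hz for fs = %g Hz", f_lo, f_hi, w$fs))
  }
  bt <- if (f_hi >= 0.995 * nyq) {
    butter_sos(4, f_lo / nyq, "high")
  } else {
    butter_sos(4, c(f_lo / nyq, f_hi / nyq), "pass")
  }
  waveform(zero_phase(bt$b, bt$a, w$samples), fs = w$fs)
}

#' Low-pass filter a waveform
#'
#' Zero-phase 4th-order Butterworth low-pass; used to probe how many pulse
#' harmonics contribute to the waveform shape (see
#' [lpf_correlation_curve()]).
#'
#' @param w A [waveform()].
#' @param f_cut Cut-off frequency in Hz, `0 < f_cut < fs/2`.
#' @return The filtered [waveform()], same length.
#' @export
lowpass <- function(w, f_cut) {
  stopifnot(inherits(w, "waveform"))
  nyq <- w$fs / 2
  if (!(f_cut > 0 && f_cut < nyq)) {
    stop(sprintf("invalid cutoff %g Hz for fs = %g Hz", f_cut, w$fs))
  }
  bt <- butter_sos(4, f_cut / nyq, "low")
  waveform(zero_phase(bt$b, bt$a, w$samples), fs = w$fs)
}

hanning_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

#' Segmented Hanning-windowed power spectra
#'
#' Splits the waveform into 256-sample segments with 75% overlap (step =
#' nfft/4), removes each segment's mean, applies a Hanning taper, and returns
#' one one-sided power spectrum per segment. A 400-sample recording (10 s at
#' 40 fps) yields 3 segments, so downstream medians are over at least three
#' values.
#'
#' @param w A [waveform()] with `length >= nfft`.
#' @param nfft Segment length in samples (default 256).
#' @param overlap Fractional overlap between consecutive segments
#'   (default 0.75).
#' @return List of [power_spectrum()] objects, one per segment.
#' @export
segment_spectra <- function(w, nfft = 256, overlap = 0.75) {
  stopifnot(inherits(w, "waveform"))
  x <- w$samples
  n <- length(x)
  if (n < nfft) stop(sprintf("waveform has %d samples; need >= nfft = %d", n, nfft))
  step <- max(1L, as.integer(round(nfft * (1 - overlap))))
  n_seg <- (n - nfft) %/% step + 1L
  taper <- hanning_window(nfft)
  half <- nfft %/% 2L
  freqs <- (0:half) * w$fs / nfft
  lapply(seq_len(n_seg), function(s) {
    seg <- x[((s - 1L) * step + 1L):((s - 1L) * step + nfft)]
    seg <- (seg - mean(seg)) * taper
    X <- stats::fft(seg)
    p2 <- Mod(X[1:(half + 1L)])^2 / nfft
    # fold negative frequencies onto positive bins (one-sided scaling)
    if (nfft %% 2L == 0L) {
      p2[2:half] <- 2 * p2[2:half]
    } else {
      p2[2:(half + 1L)] <- 2 * p2[2:(half + 1L)]
    }
    power_spectrum(freqs, p2, window = "hanning", nfft = nfft)
  })
}

#' Peak power inside a frequency band
#'
#' Maximum of the power spectrum over bins with `f_lo <= freq <= f_hi`. This
#' is the per-segment "peak" whose median across segments defines
#' Peak_thrill(N) and Peak_noise(N).
#'
#' @param s A [power_spectrum()].
#' @param f_lo,f_hi Band edges in Hz; the band must contain at least one bin.
#' @return Scalar peak power.
#' @export
band_peak <- function(s, f_lo, f_hi) {
  stopifnot(inherits(s, "power_spectrum"))
  sel <- s$freqs >= f_lo & s$freqs <= f_hi
  if (!any(sel)) stop(sprintf("band [%g, %g] Hz contains no spectral bin", f_lo, f_hi))
  max(s$power[sel])
}

#' Harmonic structure of a pulse spectrum
#'
#' Finds the pulse fundamental as the power argmax inside the physiologic
#' heart-rate search range, then reads power at the nearest bins to the
#' integer multiples `n * fundamental` up to `max_order`. Pulse spectra show
#' peaks at integer multiples of the fundamental (n <= 6) that shrink with
#' order; this report is how that structure is measured.
#'
#' @param s A [power_spectrum()] from a segment of >= 256 samples.
#' @param max_order Highest harmonic order reported (default 6).
#' @param search_range Fundamental search range in Hz (default
#'   `c(0.5, 3.0)`).
#' @return List of class `harmonic_report`: `fundamental_hz`,
#'   `harmonic_freqs`, `harmonic_powers`, `max_order`.
#' @export
harmonic_analysis <- function(s, max_order = 6, search_range = c(0.5, 3.0)) {
  stopifnot(inherits(s, "power_spectrum"))
  sel <- s$freqs > search_range[1] & s$freqs < search_range[2]
  if (!any(sel) || all(s$power[sel] <= 0)) {
    stop("no spectral power in the fundamental search range")
  }
  idx <- which(sel)[which.max(s$power[sel])]
  f0 <- s$freqs[idx]
  orders <- seq_len(max_order)
  hfreq <- hpow <- numeric(max_order)
  for (k in orders) {
    target <- k * f0
    j <- which.min(abs(s$freqs - target))
    hfreq[k] <- s$freqs[j]
    hpow[k] <- s$power[j]
  }
  structure(
    list(fundamental_hz = f0, harmonic_freqs = hfreq, harmonic_powers = hpow,
         max_order = as.integer(max_order)),
    class = "harmonic_report"
  )
}

#' @export
print.harmonic_report <- function(x, ...) {
  cat(sprintf("<harmonic_report> fundamental %.3g Hz, %d harmonics\n",
              x$fundamental_hz, x$max_order))
  invisible(x)
}

#' Cross-correlation between a waveform and its low-pass filtered versions
#'
#' For each cutoff, computes the zero-lag Pearson correlation (mean removed)
#' between the original waveform and `lowpass(w, cutoff)`. Sweeping the
#' cutoff between successive harmonics shows how many harmonics carry the
#' waveform's shape: the curve rises with cutoff and saturates once the
#' contributing harmonics are all inside the passband.
#'
#' @param w A [waveform()]; must not be constant.
#' @param cutoffs Cutoff frequencies in Hz, each in `(0, fs/2)`.
#' @return Data frame with columns `cutoff_hz`, `correlation`.
#' @export
lpf_correlation_curve <- function(w, cutoffs) {
  stopifnot(inherits(w, "waveform"))
  if (stats::sd(w$samples) == 0) {
    stop("waveform is constant: correlation with its filtered version is undefined")
  }
  data.frame(
    cutoff_hz = cutoffs,
    correlation = vapply(cutoffs, function(fc) {
      y <- lowpass(w, fc)$samples
      if (stats::sd(y) == 0) return(0)
      stats::cor(w$samples, y)
    }, numeric(1))
  )
}

#' Export a power spectrum as CSV
#'
#' @param s A [power_spectrum()].
#' @param path Output path; columns `freq_hz`, `power`.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(inherits(s, "power_spectrum"))
  utils::write.csv(data.frame(freq_hz = s$freqs, power = s$power), path,
                   row.names = FALSE)
  invisible(path)
}
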