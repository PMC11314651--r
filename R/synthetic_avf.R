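#' Parameters of the synthetic AVF signal generator
#'
#' Bundles everything needed to simulate one non-contact AVF recording. The
#' simulated luminance waveform is the composite the imaging system observes:
#' a pulse wave (fundamental plus integer harmonics of decaying amplitude), an
#' additive Thrill component confined to the 5-10 Hz band, and wide-band
#' noise. Defaults describe a resting adult at approximately 72 bpm with a
#' Thrill amplitude comparable to the third pulse harmonic.
#'
#' @param fundamental_hz Pulse fundamental frequency in Hz; must lie in
#'   (0.5, 3.0), the physiologic heart-rate range.
#' @param harmonic_amps Relative amplitudes of harmonics n = 1..length;
#'   must be strictly decreasing (harmonic peaks shrink with order). The
#'   default models the non-contact modality: harmonics 1-3 at `1/n`, and
#'   harmonics 4-6 near the diffuse-reflection floor — in non-contact
#'   recordings the reduced photosensitivity leaves only the first three
#'   harmonics resolvable, which is also why the 5-10 Hz band can be
#'   attributed to Thrill rather than pulse.
#' @param thrill_amp Relative amplitude of the Thrill component (same units
#'   as `harmonic_amps`).
#' @param thrill_center_hz Center frequency of the Thrill oscillation, inside
#'   \[5, 10\] Hz.
#' @param noise_sd Standard deviation of additive white Gaussian noise, in
#'   the same relative luminance units.
#' @param halation_count Number of static saturated specular patches added to
#'   image stacks (residual glare the polarizing filter did not remove).
#' @param stenosis_factor Multiplier in (0, 1\] applied to `thrill_amp`;
#'   1 for the normal cohort, < 1 for stenosis (reduced Thrill).
#' @param fps Sampling/frame rate in Hz.
#' @param duration_s Recording length in seconds.
#' @param rows,cols Image size in pixels.
#' @param seed Integer RNG seed; every random draw the generator makes is a
#'   deterministic function of it.
#'
#' @return A list of class `synth_params`.
#' @seealso [generate_waveform()], [generate_stack()], [generate_cohort()]
#' @export
synth_params <- function(fundamental_hz = 1.2,
                         harmonic_amps = c(1, 1/2, 1/3, 0.05, 0.04, 0.03),
                         thrill_amp = 0.35,
                         thrill_center_hz = 7.5,
                         noise_sd = 0.15,
                         halation_count = 3,
                         stenosis_factor = 1,
                         fps = 40,
                         duration_s = 10,
                         rows = 64,
                         cols = 64,
                         seed = 1L) {
  p <- structure(
    list(
      fundamental_hz = fundamental_hz, harmonic_amps = as.numeric(harmonic_amps),
      thrill_amp = thrill_amp, thrill_center_hz = thrill_center_hz,
      noise_sd = noise_sd, halation_count = as.integer(halation_count),
      stenosis_factor = stenosis_factor, fps = fps, duration_s = duration_s,
      rows = as.integer(rows), cols = as.integer(cols), seed = as.integer(seed)
    ),
    class = "synth_params"
  )
  validate_synth_params(p)
  p
}

validate_synth_params <- function(p) {
  if (p$fundamental_hz <= 0.5 || p$fundamental_hz >= 3.0) {
    stop("`fundamental_hz` must lie in (0.5, 3.0) Hz")
  }
  k <- length(p$harmonic_amps)
  if (k < 1L) stop("`harmonic_amps` must have at least one entry")
  if (k > 1L && any(diff(p$harmonic_amps) >= 0)) {
    stop("`harmonic_amps` must be strictly decreasing with harmonic order")
  }
  if (p$stenosis_factor <= 0 || p$stenosis_factor > 1) {
    stop("`stenosis_factor` must lie in (0, 1]")
  }
  if (p$thrill_center_hz < 5 || p$thrill_center_hz > 10) {
    stop("`thrill_center_hz` must lie in [5, 10] Hz")
  }
  if (p$noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (p$fps <= 0 || p$duration_s <= 0) stop("`fps` and `duration_s` must be positive")
  nyq <- p$fps / 2
  if (k * p$fundamental_hz >= nyq) {
    stop(sprintf(
      "highest harmonic (%g Hz) is at or above Nyquist (%g Hz): aliasing",
      k * p$fundamental_hz, nyq
    ))
  }
  if (p$thrill_amp > 0 && 10 >= nyq + 1e-12) {
    # Thrill band extends to 10 Hz by definition; band edge must stay below Nyquist
    if (10 > nyq) stop("Thrill band (5-10 Hz) exceeds Nyquist: increase fps")
  }
  if (p$rows < 1L || p$cols < 1L) stop("`rows` and `cols` must be >= 1")
  invisible(p)
}

# Band-limited quasi-periodic Thrill oscillation of unit peak amplitude
# scaling: an amplitude-modulated tone at thrill_center_hz with slow random
# phase drift, then resynthesized through a full-record DFT projection so its
# spectral support lies exactly inside [5, 10] Hz. Consumes RNG draws.
thrill_component <- function(n, fps, center_hz, fundamental_hz) {
  t <- (seq_len(n) - 1) / fps
  # narrowband phase drift: integrated smoothed Gaussian, sd ~0.25 Hz
  drift <- stats::filter(stats::rnorm(n, sd = 0.25), rep(1 / fps, fps), sides = 1)
  drift[is.na(drift)] <- 0
  inst_f <- pmin(pmax(center_hz + as.numeric(drift), 5.3), 9.7)
  phase <- 2 * pi * cumsum(inst_f) / fps + stats::runif(1, 0, 2 * pi)
  # amplitude modulation locked to the heartbeat (Thrill pulses with each beat)
  env <- 1 + 0.35 * sin(2 * pi * fundamental_hz * t + stats::runif(1, 0, 2 * pi))
  x <- env * sin(phase)
  # project onto the 5-10 Hz DFT subspace: exact band confinement
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fps / n
  f_alias <- pmin(f, fps - f) # two-sided bin frequencies
  X[f_alias < 5 | f_alias > 10] <- 0 + 0i
  x_band <- Re(stats::fft(X, inverse = TRUE)) / n
  x_band / max(abs(x_band))
}

#' Generate a synthetic AVF luminance waveform
#'
#' Simulates the 1-D luminance time series observed at one pixel: the sum of
#' (a) the pulse wave, \eqn{\sum_n a_n \sin(2\pi n f_0 t + \phi_n)} with
#' harmonic phases drawn uniformly per seed, (b) a band-limited quasi-periodic
#' Thrill oscillation whose spectral support lies inside 5-10 Hz, scaled by
#' `thrill_amp * stenosis_factor`, and (c) white Gaussian noise of standard
#' deviation `noise_sd`. Output is bit-identical for a fixed seed.
#'
#' @param params A [synth_params()] object.
#' @return A [waveform()] of length `fps * duration_s`.
#' @examples
#' w <- generate_waveform(synth_params(seed = 7))
#' length(w$samples) # 400 samples = 10 s at 40 fps
#' @export
generate_waveform <- function(params) {
  validate_synth_params(params)
  n <- round(params$fps * params$duration_s)
  if (n < 256) stop("duration_s * fps must be >= 256 samples (one FFT segment)")
  with_seed(params$seed, {
    w <- clean_waveform_samples(params, n)
    if (params$noise_sd > 0) w <- w + stats::rnorm(n, sd = params$noise_sd)
    waveform(w, fs = params$fps)
  })
}

# Pulse + Thrill (no additive white noise); assumes RNG already seeded.
# Draw order is fixed so generate_waveform and generate_stack agree on the
# deterministic part for the same seed.
clean_waveform_samples <- function(params, n) {
  t <- (seq_len(n) - 1) / params$fps
  k <- length(params$harmonic_amps)
  phases <- stats::runif(k, 0, 2 * pi)
  pulse <- rep(0, n)
  for (h in seq_len(k)) {
    pulse <- pulse +
      params$harmonic_amps[h] * sin(2 * pi * h * params$fundamental_hz * t + phases[h])
  }
  amp <- params$thrill_amp * params$stenosis_factor
  if (amp > 0) {
    pulse <- pulse + amp * thrill_component(n, params$fps, params$thrill_center_hz,
                                            params$fundamental_hz)
  }
  pulse
}

#' Generate a synthetic AVF image stack
#'
#' Spatializes [generate_waveform()] into a full recording: every pixel's time
#' series is `baseline + gain * (profile(i, j) * s(t) + noise)`, where `s(t)`
#' is the noiseless pulse + Thrill waveform, `profile` is a Gaussian vessel
#' ridge running along the row axis (the vessel appears as a bright column
#' band), and the noise is independent per pixel with standard deviation
#' `noise_sd` (diffuse skin reflection). `halation_count` static saturated
#' patches emulate residual specular glare.
#'
#' @param params A [synth_params()] object.
#' @param spatial `"ridge"` (default) for the Gaussian vessel profile or
#'   `"flat"` for a uniform profile of 1 (every pixel carries the full
#'   signal — useful for controlled tests).
#' @param ridge_width_px Gaussian sigma of the vessel ridge, in pixels.
#' @param baseline Luminance offset in digital numbers (DN).
#' @param gain DN per unit of relative waveform amplitude.
#' @param quantize If `TRUE` (default), round to the integer DN grid and clip
#'   to \[0, 65535\], emulating the camera's 16-bit digitizer (stacks written
#'   to TIFF round-trip exactly). Set `FALSE` for exact-arithmetic tests.
#' @return A [frame_stack()] with `meta` recording the generator settings.
#' @export
generate_stack <- function(params, spatial = c("ridge", "flat"),
                           ridge_width_px = 5, baseline = 20000, gain = 4000,
                           quantize = TRUE) {
  validate_synth_params(params)
  spatial <- match.arg(spatial)
  n <- round(params$fps * params$duration_s)
  rows <- params$rows
  cols <- params$cols
  with_seed(params$seed, {
    s <- clean_waveform_samples(params, n)
    if (spatial == "flat") {
      profile <- matrix(1, rows, cols)
    } else {
      ridge_col <- (cols + 1) / 2
      d2 <- (seq_len(cols) - ridge_col)^2
      profile <- matrix(rep(0.02 + 0.98 * exp(-d2 / (2 * ridge_width_px^2)),
                            each = rows), rows, cols)
    }
    # (pixels x frames): signal then independent per-pixel noise
    m <- as.vector(profile) %o% s
    if (params$noise_sd > 0) {
      m <- m + matrix(stats::rnorm(length(m), sd = params$noise_sd), nrow(m), ncol(m))
    }
    m <- baseline + gain * m
    data <- aperm(array(m, c(rows, cols, n)), c(3, 1, 2))
    if (params$halation_count > 0) {
      hr <- sample.int(rows, params$halation_count, replace = TRUE)
      hc <- sample.int(cols, params$halation_count, replace = TRUE)
      for (k in seq_len(params$halation_count)) {
        ri <- pmax(1, hr[k] - 1):pmin(rows, hr[k] + 1)
        ci <- pmax(1, hc[k] - 1):pmin(cols, hc[k] + 1)
        data[, ri, ci] <- 65535
      }
    }
    if (quantize) {
      data <- round(data)
      data[data < 0] <- 0
      data[data > 65535] <- 65535
    }
    frame_stack(
      data, fps = params$fps,
      meta = list(
        seed = params$seed, spatial = spatial,
        stenosis_factor = params$stenosis_factor,
        baseline = baseline, gain = gain, quantized = quantize
      )
    )
  })
}

#' Draw per-recording parameters for a simulated cohort
#'
#' Produces the per-recording jittered parameter sets a cohort simulation
#' uses, without realizing the (large) image stacks. Jitter emulates
#' between-session physiological and optical variation: heart rate varies
#' around the base value, Thrill amplitude and noise level are log-normal,
#' and the Thrill center frequency moves within the band. Stenosis recordings
#' additionally have their Thrill amplitude multiplied by `stenosis_factor`.
#'
#' @param n_normal,n_stenosis Number of recordings per cohort (each >= 1).
#' @param base A [synth_params()] object giving the cohort-level means.
#' @param seed Master seed; per-recording seeds are derived from it, so the
#'   whole cohort is reproducible.
#' @param stenosis_factor Thrill multiplier for the stenosis cohort
#'   (default 0.5).
#' @return A data frame with one row per recording: `recording_id`,
#'   `cohort_label`, `seed`, and the jittered generator parameters.
#' @export
cohort_params <- function(n_normal, n_stenosis, base = synth_params(),
                          seed = 1L, stenosis_factor = 0.5) {
  if (n_normal < 1 || n_stenosis < 1) stop("need at least one recording per cohort")
  n_tot <- n_normal + n_stenosis
  with_seed(seed, {
    f0 <- pmin(pmax(stats::rnorm(n_tot, base$fundamental_hz, 0.12), 0.8), 2.0)
    ta <- base$thrill_amp * exp(stats::rnorm(n_tot, 0, 0.3))
    ns <- base$noise_sd * exp(stats::rnorm(n_tot, 0, 0.2))
    tc <- stats::runif(n_tot, 6.5, 8.5)
    seeds <- sample.int(.Machine$integer.max - 1L, n_tot)
    data.frame(
      recording_id = sprintf("rec%03d", seq_len(n_tot)),
      cohort_label = rep(c("normal", "stenosis"), c(n_normal, n_stenosis)),
      seed = seeds,
      fundamental_hz = f0,
      thrill_amp = ta,
      thrill_center_hz = tc,
      noise_sd = ns,
      stenosis_factor = rep(c(1, stenosis_factor), c(n_normal, n_stenosis)),
      stringsAsFactors = FALSE
    )
  })
}

params_for_recording <- function(base, row) {
  synth_params(
    fundamental_hz = row$fundamental_hz,
    harmonic_amps = base$harmonic_amps,
    thrill_amp = row$thrill_amp,
    thrill_center_hz = row$thrill_center_hz,
    noise_sd = row$noise_sd,
    halation_count = base$halation_count,
    stenosis_factor = row$stenosis_factor,
    fps = base$fps, duration_s = base$duration_s,
    rows = base$rows, cols = base$cols,
    seed = row$seed
  )
}

#' Generate a labeled synthetic cohort of AVF recordings
#'
#' Realizes the recordings described by [cohort_params()] as image stacks.
#' For large cohorts prefer iterating over `cohort_params()` yourself (or use
#' [analyze_cohort()]) so only one stack is in memory at a time.
#'
#' @inheritParams cohort_params
#' @param ... Passed to [generate_stack()] (e.g. `spatial`, `quantize`).
#' @return A list with one element per recording, each a list with `stack`
#'   (a [frame_stack()]), `label` (`"normal"` or `"stenosis"`) and
#'   `recording_id`.
#' @export
generate_cohort <- function(n_normal, n_stenosis, base = synth_params(),
                            seed = 1L, stenosis_factor = 0.5, ...) {
  tab <- cohort_params(n_normal, n_stenosis, base, seed, stenosis_factor)
  lapply(seq_len(nrow(tab)), function(i) {
    p <- params_for_recording(base, tab[i, ])
    st <- generate_stack(p, ...)
    st$meta$cohort_label <- tab$cohort_label[i]
    st$meta$recording_id <- tab$recording_id[i]
    list(stack = st, label = tab$cohort_label[i], recording_id = tab$recording_id[i])
  })
}
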