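fs <- 40
t400 <- (0:399) / fs

test_that("bandpass preserves in-band tones and attenuates out-of-band ones", {
  w7 <- waveform(sin(2 * pi * 7 * t400), fs)
  out7 <- bandpass(w7, 5, 10)
  expect_equal(length(out7$samples), 400)
  expect_equal(rms(out7$samples) / rms(w7$samples), 1, tolerance = 0.01)

  w12 <- waveform(sin(2 * pi * 1.2 * t400), fs)
  out12 <- bandpass(w12, 5, 10)
  expect_lt(rms(out12$samples) / rms(w12$samples), 0.1) # >= 20 dB down

  z <- bandpass(waveform(rep(0, 400), fs), 5, 10)
  expect_equal(z$samples, rep(0, 400))
})

test_that("the noise band reaching Nyquist passes 17 Hz near unity", {
  w17 <- waveform(sin(2 * pi * 17 * t400), fs)
  out <- bandpass(w17, 15, 20)
  expect_equal(rms(out$samples) / rms(w17$samples), 1, tolerance = 0.02)
  expect_error(bandpass(w17, 10, 5), "invalid band")
  expect_error(bandpass(w17, 0, 10), "invalid band")
})

test_that("lowpass separates pulse fundamentals from Thrill-range tones", {
  cst <- waveform(rep(3.2, 400), fs)
  expect_equal(lowpass(cst, 4.6)$samples, rep(3.2, 400), tolerance = 1e-9)

  mix <- waveform(sin(2 * pi * 1.2 * t400) + sin(2 * pi * 7 * t400), fs)
  out <- lowpass(mix, 4.6)
  # both tones sit on exact DFT bins of a 400-sample record
  amp_at <- function(x, f) 2 * Mod(stats::fft(x)[f * 400 / fs + 1]) / 400
  expect_equal(amp_at(out$samples, 1.2), 1, tolerance = 0.01)
  expect_lt(amp_at(out$samples, 7), 0.1)

  hi <- lowpass(mix, 15)
  expect_gt(stats::cor(hi$samples, mix$samples), 0.999)
  expect_error(lowpass(mix, 25), "invalid cutoff")
  expect_error(lowpass(waveform(rnorm(10), fs), 5), "too short")
  expect_error(bandpass(waveform(rnorm(20), fs), 5, 10), "too short")
})

test_that("zero-phase filtering preserves pulse timing within one sample", {
  x <- exp(-((t400 - 5)^2) / (2 * 0.15^2))
  peak0 <- which.max(x)
  expect_lte(abs(which.max(lowpass(waveform(x, fs), 5)$samples) - peak0), 1)
})

test_that("segmentation yields floor((len - nfft)/step) + 1 Hanning segments", {
  w <- waveform(rnorm(400), fs)
  specs <- segment_spectra(w)
  expect_length(specs, 3) # (400 - 256) %/% 64 + 1
  expect_equal(specs[[1]]$window, "hanning")
  expect_length(segment_spectra(waveform(rnorm(256), fs)), 1)
  expect_error(segment_spectra(waveform(rnorm(255), fs)), "need >=")
  z <- segment_spectra(waveform(rep(0, 400), fs))
  expect_true(all(vapply(z, function(s) all(s$power == 0), logical(1))))
})

test_that("Parseval holds per segment and bin-centered tones land on their bin", {
  set.seed(9)
  x <- rnorm(256)
  s <- segment_spectra(waveform(x, fs), nfft = 256)[[1]]
  taper <- 0.5 - 0.5 * cos(2 * pi * (0:255) / 255)
  energy <- sum(((x - mean(x)) * taper)^2)
  expect_equal(sum(s$power), energy, tolerance = 1e-8)

  for (k in c(16, 32, 45, 64, 96)) { # bin centers k * fs/256
    f <- k * fs / 256
    tone <- sin(2 * pi * f * (0:255) / fs)
    sp <- segment_spectra(waveform(tone, fs), nfft = 256)[[1]]
    expect_equal(which.max(sp$power), k + 1)
  }
})

test_that("a pure 5 Hz tone peaks within one bin of 5 Hz in every segment", {
  w <- waveform(sin(2 * pi * 5 * t400), fs)
  for (s in segment_spectra(w)) {
    expect_lte(abs(s$freqs[which.max(s$power)] - 5), fs / 256)
  }
})

test_that("band_peak equals a linear scan over in-band bins", {
  freqs <- seq(0, 20, by = 0.15625)
  set.seed(2)
  pw <- runif(length(freqs))
  s <- power_spectrum(freqs, pw, nfft = 256)
  sel <- freqs >= 5 & freqs <= 10
  expect_equal(band_peak(s, 5, 10), max(pw[sel]))
  single <- power_spectrum(freqs, replace(numeric(length(freqs)), 46, 3.3))
  expect_equal(band_peak(single, 5, 10), 3.3) # bin 46 is 7.03 Hz
  expect_equal(band_peak(single, 15, 20), 0)
  expect_error(band_peak(s, 20.5, 21), "no spectral bin")
})

test_that("harmonic analysis recovers the fundamental and decaying peaks", {
  p <- synth_params(seed = 6, fundamental_hz = 1.2, harmonic_amps = 1 / (1:6),
                    thrill_amp = 0, noise_sd = 0)
  w <- generate_waveform(p)
  s <- segment_spectra(w)[[1]]
  rep6 <- harmonic_analysis(s)
  expect_lte(abs(rep6$fundamental_hz - 1.2), fs / 256)
  expect_length(rep6$harmonic_powers, 6)
  expect_true(all(diff(rep6$harmonic_powers) < 0))

  tone <- segment_spectra(waveform(sin(2 * pi * 1 * t400), fs))[[1]]
  rep1 <- harmonic_analysis(tone)
  expect_lte(abs(rep1$fundamental_hz - 1), fs / 256)
  expect_true(all(rep1$harmonic_powers[2:6] < 1e-4 * rep1$harmonic_powers[1]))
  expect_error(harmonic_analysis(segment_spectra(waveform(rep(0, 256), fs))[[1]]),
               "no spectral power")
})

test_that("LPF correlation rises with cutoff and saturates above the content", {
  p <- synth_params(seed = 8, fundamental_hz = 1.2, thrill_amp = 0, noise_sd = 0)
  w <- generate_waveform(p)
  curve <- lpf_correlation_curve(w, c(1.8, 3.0, 4.2, 5.4, 6.6, 7.8, 9.0))
  expect_true(all(diff(curve$correlation) > -1e-6))
  expect_gt(curve$correlation[nrow(curve)], 0.999)
  expect_true(all(curve$correlation >= -1 & curve$correlation <= 1))
  expect_error(lpf_correlation_curve(waveform(rep(1, 400), fs), 5), "constant")
})

test_that("stop-band content is strongly attenuated by the LPF", {
  w1 <- waveform(sin(2 * pi * 1 * t400), fs)
  out <- lowpass(w1, 0.5)
  expect_lt(rms(out$samples) / rms(w1$samples), 0.1)
})
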