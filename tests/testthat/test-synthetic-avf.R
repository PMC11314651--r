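test_that("generator is bit-deterministic for a fixed seed", {
  p <- synth_params(seed = 17)
  expect_identical(generate_waveform(p)$samples, generate_waveform(p)$samples)
  s1 <- generate_stack(p)
  s2 <- generate_stack(p)
  expect_identical(s1$data, s2$data)
  p2 <- synth_params(seed = 18)
  expect_false(identical(generate_waveform(p)$samples, generate_waveform(p2)$samples))
})

test_that("single-component limit is a pure sinusoid at the fundamental", {
  p <- synth_params(seed = 4, harmonic_amps = 1, thrill_amp = 0, noise_sd = 0,
                    fundamental_hz = 1.25)
  w <- generate_waveform(p)
  t <- (seq_along(w$samples) - 1) / w$fs
  fit <- lm(w$samples ~ sin(2 * pi * 1.25 * t) + cos(2 * pi * 1.25 * t) - 1)
  expect_lt(sum(residuals(fit)^2) / sum(w$samples^2), 1e-20)
  expect_equal(sqrt(sum(coef(fit)^2)), 1, tolerance = 1e-12)
})

test_that("parameter validation rejects unphysical settings", {
  expect_error(synth_params(fundamental_hz = 4), "fundamental_hz")
  expect_error(synth_params(harmonic_amps = c(1, 1)), "decreasing")
  expect_error(synth_params(stenosis_factor = 0), "stenosis_factor")
  expect_error(synth_params(thrill_center_hz = 12), "thrill_center_hz")
  # 6 harmonics of a 2.9 Hz fundamental reach 17.4 Hz < 20, but 7 would alias
  expect_error(
    synth_params(fundamental_hz = 2.9, harmonic_amps = 1 / (1:7)),
    "Nyquist"
  )
  expect_error(generate_waveform(synth_params(duration_s = 5)), "256")
})

test_that("stenosis factor scales Thrill band power quadratically", {
  # harmonics truncated below 5 Hz so the band holds only the Thrill component
  mk <- function(sf) {
    synth_params(seed = 9, noise_sd = 0, thrill_amp = 1, stenosis_factor = sf,
                 harmonic_amps = c(1, 0.5, 0.33))
  }
  pw <- function(sf) {
    w <- generate_waveform(mk(sf))
    band_power_dft(w$samples, w$fs, 5, 10)
  }
  expect_equal(pw(0.5) / pw(1), 0.25, tolerance = 1e-3)
})

test_that("Thrill component power is confined to 5-10 Hz", {
  for (seed in c(2, 23)) {
    p <- synth_params(seed = seed, noise_sd = 0, thrill_amp = 1,
                      harmonic_amps = c(1e-9, 5e-10))
    w <- generate_waveform(p)
    total <- band_power_dft(w$samples, w$fs, 0, w$fs / 2)
    inband <- band_power_dft(w$samples, w$fs, 5, 10)
    expect_gt(inband / total, 0.99)
  }
})

test_that("expected Thrill band power is nondecreasing in thrill_amp", {
  for (seed in 1:10) {
    pw <- vapply(c(0.1, 0.4, 1), function(a) {
      w <- generate_waveform(synth_params(seed = seed, thrill_amp = a,
                                          noise_sd = 0,
                                          harmonic_amps = c(1, 0.5, 0.33)))
      band_power_dft(w$samples, w$fs, 5, 10)
    }, numeric(1))
    expect_true(all(diff(pw) > 0))
  }
})

test_that("flat noiseless stack reproduces the waveform at every pixel", {
  p <- synth_params(seed = 11, noise_sd = 0, halation_count = 0,
                    rows = 8, cols = 8)
  st <- generate_stack(p, spatial = "flat", baseline = 0, gain = 1,
                       quantize = FALSE)
  w <- generate_waveform(p)
  expect_equal(st$data[, 3, 5], w$samples, tolerance = 1e-12)
  expect_equal(st$data[, 1, 1], st$data[, 8, 8], tolerance = 0)
})

test_that("vessel ridge concentrates Thrill band power", {
  p <- synth_params(seed = 13, noise_sd = 0, halation_count = 0,
                    rows = 48, cols = 48)
  st <- generate_stack(p, ridge_width_px = 5, quantize = FALSE)
  ridge_col <- (48 + 1) / 2
  on <- st$data[, 24, round(ridge_col)]
  off <- st$data[, 24, round(ridge_col) - 20]
  expect_gt(band_power_dft(on, st$fps, 5, 10),
            band_power_dft(off, st$fps, 5, 10))
})

test_that("cohort generation yields the requested labels, deterministically", {
  base <- synth_params(rows = 8, cols = 8)
  coh <- generate_cohort(2, 2, base, seed = 5)
  expect_length(coh, 4)
  expect_equal(sum(vapply(coh, `[[`, "", "label") == "normal"), 2)
  expect_equal(sum(vapply(coh, `[[`, "", "label") == "stenosis"), 2)
  coh2 <- generate_cohort(2, 2, base, seed = 5)
  expect_identical(coh[[3]]$stack$data, coh2[[3]]$stack$data)
  tab <- cohort_params(10, 10, base, seed = 5, stenosis_factor = 0.5)
  expect_true(all(tab$stenosis_factor[tab$cohort_label == "stenosis"] == 0.5))
  expect_true(all(tab$stenosis_factor[tab$cohort_label == "normal"] == 1))
  expect_true(all(tab$fundamental_hz > 0.5 & tab$fundamental_hz < 3))
  expect_true(all(tab$thrill_center_hz >= 5 & tab$thrill_center_hz <= 10))
})
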