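make_tab <- function(curves, labels, grid = seq(1, 41, 2)) {
  do.call(rbind, lapply(seq_along(curves), function(i) {
    data.frame(recording_id = sprintf("r%02d", i), cohort_label = labels[i],
               kernel_n = grid, peak_thrill = NA, peak_noise = NA,
               snr = curves[[i]])
  }))
}

test_that("cohort curve is the element-wise mean across recordings", {
  grid <- seq(1, 41, 2)
  set.seed(4)
  cs <- replicate(3, runif(length(grid)), simplify = FALSE)
  tab <- make_tab(cs, rep("normal", 3), grid)
  got <- cohort_curve(tab, "normal")
  oracle <- numeric(length(grid))
  for (j in seq_along(grid)) {
    oracle[j] <- (cs[[1]][j] + cs[[2]][j] + cs[[3]][j]) / 3
  }
  expect_equal(got$snr, oracle, tolerance = 1e-12)
  expect_equal(got$kernel_n, grid)

  single <- cohort_curve(make_tab(cs[1], "normal", grid), "normal")
  expect_equal(single$snr, cs[[1]])
  twin <- cohort_curve(make_tab(cs[c(1, 1)], rep("normal", 2), grid), "normal")
  expect_equal(twin$snr, cs[[1]])
  expect_error(cohort_curve(tab, "stenosis"), "no recordings")

  med <- cohort_curve(tab, "normal", agg = "median")
  expect_equal(med$snr, apply(do.call(rbind, cs), 2, median))
})

test_that("cohort curve rejects mismatched kernel grids", {
  tab <- rbind(
    data.frame(recording_id = "a", cohort_label = "normal",
               kernel_n = c(1, 3), peak_thrill = NA, peak_noise = NA, snr = 1:2),
    data.frame(recording_id = "b", cohort_label = "normal",
               kernel_n = c(1, 5), peak_thrill = NA, peak_noise = NA, snr = 1:2)
  )
  expect_error(cohort_curve(tab, "normal"), "mismatched")
})

test_that("min-max normalization maps to [0,1] and ignores affine rescaling", {
  expect_equal(normalize_curve(c(1, 2, 3)), c(0, 0.5, 1))
  ramp <- seq(0, 1, length.out = 11)
  expect_equal(normalize_curve(ramp), ramp)
  set.seed(6)
  v <- rnorm(20)
  expect_equal(normalize_curve(3.7 * v + 11), normalize_curve(v), tolerance = 1e-12)
  expect_error(normalize_curve(rep(2, 5)), "constant")
})

test_that("polynomial smoothing reproduces exact polynomials and OLS solutions", {
  n <- seq(1, 41, 2)
  x <- (n - 21) / 20
  exact <- 0.3 - 0.2 * x + 0.5 * x^2 - x^3 + 0.1 * x^4 + 0.2 * x^5 - 0.4 * x^6
  fit <- fit_residual_poly(n, exact)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$fitted, exact, tolerance = 1e-9)

  # noisy data: coefficients must match the explicit normal-equations solve
  set.seed(12)
  y <- exact + rnorm(length(n), sd = 0.05)
  fit2 <- fit_residual_poly(n, y)
  V <- outer(x, 0:6, `^`)
  beta <- solve(t(V) %*% V, t(V) %*% y)
  expect_equal(fit2$coeffs, as.numeric(beta), tolerance = 1e-6)

  const <- fit_residual_poly(n, rep(0.4, length(n)))
  expect_true(is.na(const$r_squared))
  expect_equal(const$fitted, rep(0.4, length(n)), tolerance = 1e-9)

  # interpolation limit: order = points - 1 reproduces the data
  n8 <- seq(1, 15, 2)
  set.seed(13)
  y8 <- rnorm(8)
  fit3 <- fit_residual_poly(n8, y8, order = 7)
  expect_equal(fit3$fitted, y8, tolerance = 1e-8)

  expect_error(fit_residual_poly(seq(1, 11, 2), rnorm(6)), "order-6")
})

test_that("N_opt is the grid argmax of the smoothed residual", {
  n <- seq(1, 41, 2)
  x <- (n - 21) / 20
  bump <- exp(-x^2 / 0.08) # peak at N = 21
  fit <- fit_residual_poly(n, bump)
  expect_equal(select_n_opt(n, fit), 21)

  rising <- fit_residual_poly(n, (n / 41)^1.5)
  expect_equal(select_n_opt(n, rising), 41)

  flatfit <- list(coeffs = c(0.5, rep(0, 6)), rescale = c(21, 20))
  expect_equal(select_n_opt(n, flatfit), 1) # all tied -> smallest N
})

test_that("optimize_kernel recovers a planted separation peak within +/- 6", {
  grid <- seq(1, 61, 2)
  base <- log1p(grid) / log1p(61)
  for (seed in 1:10) {
    set.seed(seed)
    n_star <- sample(seq(15, 27, 2), 1)
    bump <- 0.35 * exp(-((grid - n_star)^2) / (2 * 4^2))
    curves <- c(
      lapply(1:6, function(i) base + bump + rnorm(length(grid), sd = 0.02)),
      lapply(1:6, function(i) base + rnorm(length(grid), sd = 0.02))
    )
    tab <- make_tab(curves, rep(c("normal", "stenosis"), each = 6), grid)
    opt <- optimize_kernel(tab)
    expect_lte(abs(opt$n_opt - n_star), 6)
    expect_true(opt$n_opt %in% grid)
    expect_lte(opt$r_squared, 1)
    expect_equal(opt$residual, opt$curve_normal - opt$curve_stenosis)
  }
})

test_that("optimization results serialize to JSON", {
  grid <- seq(1, 21, 2)
  set.seed(3)
  curves <- lapply(1:4, function(i) sort(runif(length(grid))))
  tab <- make_tab(curves, c("normal", "normal", "stenosis", "stenosis"), grid)
  opt <- optimize_kernel(tab)
  path <- withr::local_tempfile(fileext = ".json")
  write_opt_json(opt, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$n_opt, opt$n_opt)
  expect_equal(back$r_squared, opt$r_squared, tolerance = 1e-12)
})
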