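#' Cohort-level SNR curve
#'
#' Aggregates per-recording SNR curves of one cohort into a single curve per
#' kernel size. The group curve is the arithmetic mean across recordings by
#' default; the median is available for robustness to outlying recordings.
#'
#' @param tab Long-format SNR table ([snr_curves_table()] /
#'   [read_snr_csv()]).
#' @param label Cohort label to aggregate (`"normal"` or `"stenosis"`).
#' @param agg `"mean"` (default) or `"median"`.
#' @return Data frame with columns `kernel_n`, `snr`, sorted by `kernel_n`.
#' @export
cohort_curve <- function(tab, label, agg = c("mean", "median")) {
  agg <- match.arg(agg)
  sub <- tab[tab$cohort_label == label, , drop = FALSE]
  if (nrow(sub) == 0) stop("no recordings with cohort_label = ", label)
  grids <- split(sub$kernel_n, sub$recording_id)
  g0 <- sort(unique(sub$kernel_n))
  same <- vapply(grids, function(g) identical(sort(g), g0), logical(1))
  if (!all(same)) stop("recordings have mismatched kernel-size grids")
  f <- if (agg == "mean") mean else stats::median
  out <- stats::aggregate(snr ~ kernel_n, data = sub, FUN = f)
  out[order(out$kernel_n), , drop = FALSE]
}

#' Min-max normalize a curve to \[0, 1\]
#'
#' `(v - min(v)) / (max(v) - min(v))`. Normalization makes the shapes of the
#' normal and stenosis SNR curves comparable before their residual is taken;
#' it is invariant to any positive affine rescaling of the input. Constant
#' curves are rejected (no shape to normalize).
#'
#' @param values Numeric vector (SNR per kernel size).
#' @return Numeric vector in \[0, 1\].
#' @examples
#' normalize_curve(c(1, 2, 3)) # 0.0 0.5 1.0
#' @export
normalize_curve <- function(values) {
  if (!is.numeric(values) || length(values) < 2) {
    stop("`values` must be a numeric vector of length >= 2")
  }
  rng <- range(values)
  if (rng[1] == rng[2]) stop("curve is constant: min-max normalization undefined")
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Least-squares polynomial smoothing of the residual curve
#'
#' Fits an order-6 (by default) polynomial in kernel size N to the residual
#' between normalized cohort curves. For conditioning, N is internally
#' rescaled to \[-1, 1\]; the returned coefficients are in that rescaled
#' basis (ascending powers), together with the rescaling used and the
#' coefficient of determination.
#'
#' @param n_values Kernel sizes (abscissa).
#' @param residual Residual values, same length.
#' @param order Polynomial order (default 6); needs
#'   `length(n_values) >= order + 1` (equality is the interpolation limit,
#'   where the fit reproduces the data exactly).
#' @return List with `coeffs` (length `order + 1`, ascending powers of the
#'   rescaled abscissa), `r_squared`, `fitted`, and `rescale` (`c(center,
#'   halfwidth)` mapping `x = (N - center) / halfwidth`).
#' @export
fit_residual_poly <- function(n_values, residual, order = 6) {
  if (length(n_values) != length(residual)) stop("n_values and residual lengths differ")
  if (length(n_values) < order + 1) {
    stop(sprintf("need >= %d points to fit an order-%d polynomial",
                 order + 1, order))
  }
  ctr <- (max(n_values) + min(n_values)) / 2
  hw <- (max(n_values) - min(n_values)) / 2
  if (hw == 0) stop("n_values are all identical")
  x <- (n_values - ctr) / hw
  V <- stats::poly(x, degree = order, raw = TRUE, simple = TRUE)
  fit <- stats::lm.fit(cbind(1, V), residual)
  coeffs <- unname(fit$coefficients)
  if (anyNA(coeffs)) stop("rank-deficient polynomial design")
  fitted <- as.numeric(cbind(1, V) %*% coeffs)
  ss_tot <- sum((residual - mean(residual))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - sum((residual - fitted)^2) / ss_tot
  list(coeffs = coeffs, r_squared = r2, fitted = fitted, rescale = c(ctr, hw))
}

eval_poly <- function(coeffs, n, rescale) {
  x <- (n - rescale[1]) / rescale[2]
  as.numeric(outer(x, 0:(length(coeffs) - 1), `^`) %*% coeffs)
}

#' Select the optimal kernel size
#'
#' `N_opt` is the kernel size at which the *smoothed* residual between the
#' normalized cohort curves is largest — the N that best separates the
#' normal and stenosis groups. Evaluated on the sweep grid itself, so the
#' result is always a member of the grid; exact ties go to the smaller N.
#'
#' @param n_values Sweep grid of odd kernel sizes.
#' @param poly_fit Result of [fit_residual_poly()].
#' @return The selected odd kernel size.
#' @export
select_n_opt <- function(n_values, poly_fit) {
  vals <- eval_poly(poly_fit$coeffs, n_values, poly_fit$rescale)
  n_values[which.max(vals)] # which.max returns the first (smallest N) on ties
}

#' Kernel-size optimization between cohorts
#'
#' The full optimization stage: average SNR curves within each cohort,
#' min-max normalize each group curve, take the residual (normal minus
#' stenosis), smooth it with a 6th-order least-squares polynomial, and return
#' the kernel size maximizing the smoothed residual.
#'
#' @param tab Long-format SNR table covering both cohorts
#'   ([snr_curves_table()]).
#' @param order Polynomial order for residual smoothing (default 6).
#' @param agg Group-curve aggregator, `"mean"` (default) or `"median"`.
#' @param normalize `"per_curve"` (default) min-max scales each group curve
#'   on its own range; `"joint"` scales both by the pooled range.
#' @return An object of class `opt_result`: `n_values`, `curve_normal`,
#'   `curve_stenosis` (normalized), `residual`, `poly_coeffs`, `poly_rescale`,
#'   `r_squared`, `smoothed`, `n_opt`.
#' @export
optimize_kernel <- function(tab, order = 6, agg = c("mean", "median"),
                            normalize = c("per_curve", "joint")) {
  agg <- match.arg(agg)
  normalize <- match.arg(normalize)
  cn <- cohort_curve(tab, "normal", agg)
  cs <- cohort_curve(tab, "stenosis", agg)
  if (!identical(cn$kernel_n, cs$kernel_n)) {
    stop("normal and stenosis cohorts were swept on different kernel grids")
  }
  if (normalize == "per_curve") {
    vn <- normalize_curve(cn$snr)
    vs <- normalize_curve(cs$snr)
  } else {
    rng <- range(c(cn$snr, cs$snr))
    if (rng[1] == rng[2]) stop("curves are constant: normalization undefined")
    vn <- (cn$snr - rng[1]) / (rng[2] - rng[1])
    vs <- (cs$snr - rng[1]) / (rng[2] - rng[1])
  }
  residual <- vn - vs
  pf <- fit_residual_poly(cn$kernel_n, residual, order = order)
  structure(
    list(
      n_values = cn$kernel_n, curve_normal = vn, curve_stenosis = vs,
      residual = residual, poly_coeffs = pf$coeffs, poly_rescale = pf$rescale,
      r_squared = pf$r_squared, smoothed = pf$fitted,
      n_opt = select_n_opt(cn$kernel_n, pf)
    ),
    class = "opt_result"
  )
}

#' @export
print.opt_result <- function(x, ...) {
  cat(sprintf("<opt_result> N_opt = %d over %d kernel sizes (R^2 of residual fit: %.3f)\n",
              x$n_opt, length(x$n_values), x$r_squared))
  invisible(x)
}

#' Plot the kernel-optimization curves
#'
#' Normalized cohort SNR curves, their residual, and the smoothed residual
#' with the selected N_opt marked.
#'
#' @param x An `opt_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.opt_result <- function(x, ...) {
  graphics::plot(x$n_values, x$curve_normal, type = "l", col = "blue",
                 xlab = "kernel size N", ylab = "normalized SNR / residual",
                 ylim = range(c(x$curve_normal, x$curve_stenosis, x$residual,
                                x$smoothed)), ...)
  graphics::lines(x$n_values, x$curve_stenosis, col = "red")
  graphics::lines(x$n_values, x$residual, lty = 2, col = "grey40")
  graphics::lines(x$n_values, x$smoothed, lwd = 2)
  graphics::abline(v = x$n_opt, lty = 3)
  graphics::legend("topleft", bty = "n",
                   legend = c("normal", "stenosis", "residual", "smoothed", "N_opt"),
                   col = c("blue", "red", "grey40", "black", "black"),
                   lty = c(1, 1, 2, 1, 3), lwd = c(1, 1, 1, 2, 1))
  invisible(x)
}

#' Write an optimization result as JSON
#'
#' @param opt An `opt_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_opt_json <- function(opt, path) {
  stopifnot(inherits(opt, "opt_result"))
  jsonlite::write_json(unclass(opt), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
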