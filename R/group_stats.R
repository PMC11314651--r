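#' Descriptive summary of one cohort's SNR values
#'
#' Quartiles by linear interpolation (the type-7 convention), with
#' `iqr = q75 - q25` computed from the same quantiles.
#'
#' @param values Numeric SNR values, `length >= 1`.
#' @param label Cohort label carried into the summary.
#' @return List of class `group_summary`: `label`, `n`, `q25`, `median`,
#'   `q75`, `iqr`.
#' @export
summarize_snr <- function(values, label = NA_character_) {
  if (length(values) < 1) stop("empty input")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  structure(
    list(label = label, n = length(values),
         q25 = q[1], median = q[2], q75 = q[3], iqr = q[3] - q[1]),
    class = "group_summary"
  )
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> %s: n=%d, q25=%.3g, median=%.3g, q75=%.3g, IQR=%.3g\n",
              x$label, x$n, x$q25, x$median, x$q75, x$iqr))
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' W statistic and p-value (Royston's AS R94 algorithm, via
#' [stats::shapiro.test()]). Used to decide whether the cohort SNR values can
#' be treated as normal; in practice they are right-skewed and the
#' nonparametric route is taken.
#'
#' @param values Numeric sample, `3 <= n <= 5000`, nonzero variance.
#' @return List with `w` and `p`.
#' @export
shapiro_wilk <- function(values) {
  n <- length(values)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(values) == 0) stop("zero variance: normality test undefined")
  ht <- stats::shapiro.test(values)
  list(w = unname(ht$statistic), p = unname(ht$p.value))
}

#' Mann-Whitney U test
#'
#' Two-sample rank test of the null that the two cohorts' SNR distributions
#' are identical. U is computed from rank sums with midranks for ties. The
#' p-value is exact (full null distribution of U) when `n1 * n2 <= 64` and
#' there are no ties, otherwise the normal approximation with tie and
#' continuity corrections is used. Computation is delegated to
#' [stats::wilcox.test()], whose W statistic for `x` vs `y` is exactly U.
#'
#' @param a,b Numeric samples (nonempty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return List of class `mw_report`: `u` (statistic for `a` vs `b`), `p`,
#'   `method` (`"exact"` or `"normal-approximation"`), `n1`, `n2`.
#' @export
mann_whitney_u <- function(a, b, alternative = "two.sided") {
  if (length(a) < 1 || length(b) < 1) stop("both groups must be nonempty")
  ties <- any(duplicated(c(a, b)))
  exact <- !ties && length(a) * length(b) <= 64
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative, exact = exact,
                       correct = TRUE)
  )
  structure(
    list(u = unname(ht$statistic), p = unname(ht$p.value),
         method = if (exact) "exact" else "normal-approximation",
         n1 = length(a), n2 = length(b)),
    class = "mw_report"
  )
}

#' @export
print.mw_report <- function(x, ...) {
  cat(sprintf("<mann-whitney> U = %g (n1=%d, n2=%d), p = %.4g [%s]\n",
              x$u, x$n1, x$n2, x$p, x$method))
  invisible(x)
}

#' Compare cohorts on SNR_thr(N_opt)
#'
#' The statistical endpoint of the pipeline: per-group Shapiro-Wilk normality
#' checks, a Mann-Whitney U test between the groups (reported regardless of
#' the normality outcome — cohort SNR values are typically non-normal, which
#' is why the nonparametric test is the endpoint), and quartile summaries.
#'
#' @param values Numeric SNR_thr(N_opt) values, one per recording.
#' @param labels Cohort label per value (`"normal"` / `"stenosis"`).
#' @param alternative Passed to [mann_whitney_u()] (default two-sided).
#' @param shapiro `"per_group"` (default) runs the normality check within
#'   each cohort; `"pooled"` runs it once on all values.
#' @return List of class `cohort_comparison`: `summary_normal`,
#'   `summary_stenosis`, `shapiro_normal`, `shapiro_stenosis` (or
#'   `shapiro_pooled`), `test` (an `mw_report`).
#' @export
compare_cohorts <- function(values, labels, alternative = "two.sided",
                            shapiro = c("per_group", "pooled")) {
  shapiro <- match.arg(shapiro)
  if (length(values) != length(labels)) stop("values and labels lengths differ")
  a <- values[labels == "normal"]
  b <- values[labels == "stenosis"]
  if (length(a) == 0 || length(b) == 0) stop("both cohorts must be nonempty")
  sw <- function(v) {
    tryCatch(shapiro_wilk(v), error = function(e) list(w = NA_real_, p = NA_real_))
  }
  res <- list(
    summary_normal = summarize_snr(a, "normal"),
    summary_stenosis = summarize_snr(b, "stenosis"),
    test = mann_whitney_u(a, b, alternative = alternative)
  )
  if (shapiro == "per_group") {
    res$shapiro_normal <- sw(a)
    res$shapiro_stenosis <- sw(b)
  } else {
    res$shapiro_pooled <- sw(values)
  }
  structure(res, class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat("Cohort comparison of SNR_thr(N_opt)\n")
  print(x$summary_normal)
  print(x$summary_stenosis)
  if (!is.null(x$shapiro_normal)) {
    cat(sprintf("  Shapiro-Wilk: normal p=%.3g, stenosis p=%.3g\n",
                x$shapiro_normal$p, x$shapiro_stenosis$p))
  }
  print(x$test)
  invisible(x)
}

#' Write the comparison report
#'
#' JSON (machine-readable) and an optional plain-text rendering.
#'
#' @param cmp A `cohort_comparison`.
#' @param json_path Output JSON path.
#' @param txt_path Optional plain-text path.
#' @return `json_path`, invisibly.
#' @export
write_stats_report <- function(cmp, json_path, txt_path = NULL) {
  stopifnot(inherits(cmp, "cohort_comparison"))
  jsonlite::write_json(strip_s3(cmp), json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w")
    sink(con)
    print(cmp)
    sink()
    close(con)
  }
  invisible(json_path)
}
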