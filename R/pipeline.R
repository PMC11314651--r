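#' Pipeline configuration
#'
#' All tunable settings of the simulate-sweep-optimize-compare pipeline in
#' one validated object. Defaults follow the acquisition protocol (40 fps,
#' 10 s exposures) and the analysis constants (5-10 Hz Thrill band, 15-20 Hz
#' noise band, 256-point Hanning segments, odd kernel grid 1..201).
#'
#' @param fps Frame rate in Hz.
#' @param duration_s Recording length in seconds.
#' @param thrill_band,noise_band Band edges in Hz; must be disjoint.
#' @param nfft FFT segment length; must not exceed `fps * duration_s`.
#' @param overlap Fractional segment overlap.
#' @param kernel_max Largest kernel size of the odd sweep grid; capped at the
#'   image extent when stacks are analyzed.
#' @param rows,cols Simulated image size in pixels.
#' @param stenosis_factor Thrill multiplier for simulated stenosis cohorts.
#' @param seed Master seed for all randomness.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(fps = 40, duration_s = 10,
                            thrill_band = c(5, 10), noise_band = c(15, 20),
                            nfft = 256, overlap = 0.75, kernel_max = 201,
                            rows = 64, cols = 64, stenosis_factor = 0.5,
                            seed = 1L) {
  if (max(thrill_band) > min(noise_band)) stop("thrill and noise bands must be disjoint")
  if (nfft > fps * duration_s) stop("nfft exceeds the number of frames per recording")
  if (kernel_max %% 2 == 0) stop("kernel_max must be odd")
  structure(
    list(fps = fps, duration_s = duration_s, thrill_band = thrill_band,
         noise_band = noise_band, nfft = nfft, overlap = overlap,
         kernel_max = as.integer(kernel_max), rows = as.integer(rows),
         cols = as.integer(cols), stenosis_factor = stenosis_factor,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

config_hash <- function(config) {
  substr(tools::md5sum(
    {
      f <- tempfile()
      yaml::write_yaml(unclass(config), f)
      f
    }
  ), 1, 12)[[1]]
}

base_params_from_config <- function(config) {
  synth_params(fps = config$fps, duration_s = config$duration_s,
               rows = config$rows, cols = config$cols, seed = config$seed)
}

kernel_grid_for <- function(config) {
  cap <- min(config$kernel_max, config$rows, config$cols)
  if (cap %% 2 == 0) cap <- cap - 1
  default_kernel_grid(cap)
}

#' Simulate a cohort to disk
#'
#' Writes one multi-page TIFF (plus YAML sidecar) per simulated recording and
#' a YAML manifest listing every file with its cohort label, seed and the
#' configuration hash. Deterministic for a fixed config seed.
#'
#' @param config A [pipeline_config()].
#' @param n_normal,n_stenosis Cohort sizes.
#' @param out_dir Output directory (created if needed).
#' @return Path to the manifest YAML, invisibly.
#' @export
run_simulate <- function(config, n_normal, n_stenosis, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  base <- base_params_from_config(config)
  tab <- cohort_params(n_normal, n_stenosis, base, seed = config$seed,
                       stenosis_factor = config$stenosis_factor)
  entries <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    p <- params_for_recording(base, tab[i, ])
    st <- generate_stack(p)
    st$meta$cohort_label <- tab$cohort_label[i]
    st$meta$recording_id <- tab$recording_id[i]
    fn <- file.path(out_dir, paste0(tab$recording_id[i], ".tiff"))
    write_stack(st, fn)
    entries[[i]] <- list(recording_id = tab$recording_id[i],
                         path = basename(fn),
                         cohort_label = tab$cohort_label[i],
                         seed = tab$seed[i])
  }
  manifest <- list(config = unclass(config), config_hash = config_hash(config),
                   recordings = entries)
  mpath <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, mpath)
  invisible(mpath)
}

#' SNR curve of one recording under a pipeline configuration
#'
#' Selects the analysis pixel with [auto_select_roi()] and sweeps the kernel
#' grid (capped at the image extent).
#'
#' @param stack A [frame_stack()].
#' @param config A [pipeline_config()].
#' @return An `snr_curve_result` (see [snr_curve()]).
#' @export
analyze_recording <- function(stack, config = pipeline_config()) {
  grid <- kernel_grid_for(config)
  grid <- grid[grid <= min(n_rows(stack), n_cols(stack))]
  roi <- auto_select_roi(stack, band = config$thrill_band)
  snr_curve(stack, roi = roi, n_values = grid,
            thrill_band = config$thrill_band, noise_band = config$noise_band,
            nfft = config$nfft, overlap = config$overlap)
}

#' Run the full analysis on a simulated cohort, in memory
#'
#' Streams the cohort (one recording generated, analyzed and discarded at a
#' time), then optimizes the kernel size between cohorts and compares the
#' groups at `SNR_thr(N_opt)`.
#'
#' @param config A [pipeline_config()].
#' @param n_normal,n_stenosis Cohort sizes.
#' @return List of class `pipeline_result`: `curves` (long-format SNR table),
#'   `opt` (an `opt_result`), `stats` (a `cohort_comparison`), `snr_at_nopt`
#'   (data frame `recording_id`, `cohort_label`, `snr`).
#' @export
analyze_cohort <- function(config, n_normal, n_stenosis) {
  stopifnot(inherits(config, "pipeline_config"))
  base <- base_params_from_config(config)
  tab <- cohort_params(n_normal, n_stenosis, base, seed = config$seed,
                       stenosis_factor = config$stenosis_factor)
  curves <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    p <- params_for_recording(base, tab[i, ])
    st <- generate_stack(p)
    st$meta$cohort_label <- tab$cohort_label[i]
    st$meta$recording_id <- tab$recording_id[i]
    curves[[i]] <- analyze_recording(st, config)
  }
  finish_pipeline(snr_curves_table(curves), config)
}

finish_pipeline <- function(curve_tab, config) {
  opt <- optimize_kernel(curve_tab)
  at_opt <- curve_tab[curve_tab$kernel_n == opt$n_opt, , drop = FALSE]
  cmp <- compare_cohorts(at_opt$snr, at_opt$cohort_label)
  structure(
    list(curves = curve_tab, opt = opt, stats = cmp,
         snr_at_nopt = at_opt[, c("recording_id", "cohort_label", "snr")],
         config_hash = config_hash(config)),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("AVF Thrill quantification pipeline\n")
  print(x$opt)
  print(x$stats)
  invisible(x)
}

#' Run the full analysis from a simulation manifest on disk
#'
#' Reads every TIFF listed in the manifest, computes its SNR curve, then the
#' kernel optimization and cohort comparison. Writes the SNR-curve CSV, the
#' optimization JSON, the statistics JSON and a plain-text summary into
#' `out_dir`; each output records the configuration hash.
#'
#' @param config A [pipeline_config()].
#' @param manifest_path Manifest YAML written by [run_simulate()].
#' @param out_dir Output directory (default: the manifest's directory).
#' @param verbose Log each stage to the console.
#' @return A `pipeline_result`, invisibly.
#' @export
run_full <- function(config, manifest_path, out_dir = dirname(manifest_path),
                     verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  man <- yaml::read_yaml(manifest_path)
  if (is.null(man$recordings) || length(man$recordings) == 0) {
    stop("manifest lists no recordings")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  curves <- vector("list", length(man$recordings))
  for (i in seq_along(man$recordings)) {
    rec <- man$recordings[[i]]
    path <- file.path(dirname(manifest_path), rec$path)
    say("[sweep] %s (%s)", rec$recording_id, rec$cohort_label)
    st <- read_stack(path)
    st$meta$recording_id <- rec$recording_id
    st$meta$cohort_label <- rec$cohort_label
    curves[[i]] <- analyze_recording(st, config)
  }
  res <- finish_pipeline(snr_curves_table(curves), config)
  say("[optimize] N_opt = %d (R^2 = %.3f)", res$opt$n_opt, res$opt$r_squared)
  say("[compare] Mann-Whitney p = %.4g", res$stats$test$p)
  tab <- res$curves
  tab$config_hash <- res$config_hash
  write_snr_csv(tab, file.path(out_dir, "snr_curves.csv"))
  opt_out <- c(unclass(res$opt), list(config_hash = res$config_hash))
  jsonlite::write_json(opt_out, file.path(out_dir, "opt_result.json"),
                       auto_unbox = TRUE, digits = NA)
  stats_payload <- c(strip_s3(res$stats),
                     list(n_opt = res$opt$n_opt, config_hash = res$config_hash))
  jsonlite::write_json(stats_payload, file.path(out_dir, "stats_report.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(out_dir, "summary.txt"), "w")
  sink(con)
  print(res)
  cat("config:", res$config_hash, "\n")
  sink()
  close(con)
  invisible(res)
}
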