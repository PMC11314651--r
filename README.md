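# avfthrill

Quantifies the **Thrill** — the fine vibration of a hemodialysis
arteriovenous fistula (AVF) — from non-contact luminance video, and detects
stenosis as a group-level reduction of that vibration. It is aimed at
researchers in biomedical optics and dialysis-access monitoring who want a
reproducible, testable implementation of the full analysis chain, including a
synthetic recording generator that stands in for clinical footage.

## Method

Every pixel of a 40 fps luminance stack is a plethysmographic waveform: a
pulse wave with decaying harmonics plus, over a healthy fistula, a
quasi-periodic Thrill component confined to the 5–10 Hz band. The pipeline:

1. smooth each frame with an N×N moving-average kernel (odd N, swept
   1..201 — 101 kernel sizes),
2. at a fixed analysis pixel, band-pass the smoothed waveform and compute
   Hanning-windowed 256-point FFT power spectra on 75 %-overlapping
   segments,
3. form the Thrill signal-to-noise ratio per kernel size

   `SNR_thr(N) = Peak_thrill(N) / Peak_noise(N)`

   where each peak is the median across segments of the in-band spectral
   maximum (Thrill band 5–10 Hz, reference noise band 15–20 Hz),
4. choose the optimal kernel `N_opt` as the size maximizing the smoothed
   (6th-order polynomial) residual between the min–max-normalized cohort SNR
   curves of the normal and stenosis groups,
5. compare the groups at `SNR_thr(N_opt)` with Shapiro–Wilk normality checks
   and a two-sided Mann–Whitney U test plus quartile summaries.

A stenotic fistula has a weaker Thrill: its 5–10 Hz power drops while the
noise band is unchanged, so `SNR_thr(N_opt)` separates the cohorts.

See `vignettes/thrill-quantification.Rmd` for the signal model, the
synthetic-data generator's assumptions and every numerical choice.

## Worked example

Simulate a small cohort (six recordings per group, 32×32 px so the kernel
sweep caps at 31) and run the whole chain in memory:

```r
library(avfthrill)
cfg <- pipeline_config(rows = 32, cols = 32, kernel_max = 31, seed = 42)
res <- analyze_cohort(cfg, n_normal = 6, n_stenosis = 6)
print(res)
#> AVF Thrill quantification pipeline
#> <opt_result> N_opt = 3 over 16 kernel sizes (R^2 of residual fit: 0.401)
#> Cohort comparison of SNR_thr(N_opt)
#> <group_summary> normal: n=6, q25=75.4, median=131, q75=260, IQR=184
#> <group_summary> stenosis: n=6, q25=14.1, median=27.3, q75=81.8, IQR=67.6
#>   Shapiro-Wilk: normal p=0.0211, stenosis p=0.00343
#> <mann-whitney> U = 29 (n1=6, n2=6), p = 0.09307 [exact]
```

Reading the output: the stenosis cohort's median `SNR_thr(N_opt)` is about a
fifth of the normal cohort's — the simulated stenosis halves the Thrill
amplitude, i.e. quarters its band power, and sampling jitter does the rest.
With only six recordings per group the exact Mann–Whitney test cannot reach
significance (p = 0.093); at the study scale of 50 recordings per group the
difference is detected at p < 0.01 in every simulated replicate
(`scripts/acceptance.R` below measures exactly that). `plot(res$opt)` draws
the two normalized SNR curves, their residual and the smoothed residual whose
peak defines `N_opt`.

The same pipeline runs file-based: `run_simulate()` writes 16-bit multi-page
TIFF recordings with a YAML manifest, `run_full()` consumes the manifest and
writes the SNR-curve CSV, the optimization JSON and the statistics report. A
thin command-line wrapper lives at `inst/cli/avfthrill.R`
(`Rscript avfthrill.R simulate|full ...`).

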