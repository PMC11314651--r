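# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: direct DFT sums, nested loops, full enumeration.

# total spectral power of x in [lo, hi] Hz by direct DFT (two-sided bins)
band_power_dft <- function(x, fs, lo, hi) {
  x <- x - mean(x)
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  fa <- pmin(f, fs - f)
  sum(Mod(X[fa >= lo & fa <= hi])^2) / n
}

# windowed mean with replicate padding, nested loops
brute_box_mean <- function(frame, n) {
  h <- (n - 1) / 2
  nr <- nrow(frame)
  nc <- ncol(frame)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      s <- 0
      for (m in -h:h) {
        for (k in -h:h) {
          s <- s + frame[min(max(i + m, 1), nr), min(max(j + k, 1), nc)]
        }
      }
      out[i, j] <- s / n^2
    }
  }
  out
}

# Mann-Whitney U (a vs b) from rank sums, no ties assumed
u_stat <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

# exact two-sided p by full enumeration of all C(n1+n2, n1) labelings,
# doubling the smaller tail (the convention of exact rank tests)
enum_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  n <- length(pooled)
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  u <- u_stat(a, b)
  m <- n1 * (n - n1) / 2
  p <- if (u > m) mean(us >= u) else mean(us <= u)
  min(1, 2 * p)
}

# flat-profile stack whose every pixel carries the same sum of tones
tone_stack <- function(freqs, amps, fs = 40, n = 400, rows = 4, cols = 4) {
  t <- (seq_len(n) - 1) / fs
  x <- rep(0, n)
  for (i in seq_along(freqs)) x <- x + amps[i] * sin(2 * pi * freqs[i] * t)
  frame_stack(array(rep(x, rows * cols), c(n, rows, cols)), fps = fs)
}

rms <- function(x) sqrt(mean(x^2))
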