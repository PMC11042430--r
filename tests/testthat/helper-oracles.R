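# Independent signal-processing oracles used to check the implementation.

# Analytic-signal amplitude envelope via the frequency-domain construction.
analytic_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# Ideal (brick-wall) FFT band-pass.
fft_bandpass <- function(x, fs, lo, hi) {
  n <- length(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  X <- stats::fft(x)
  X[f < lo | f > hi] <- 0
  Re(stats::fft(X, inverse = TRUE) / n)
}

# Log-log spectral slope fitted to a smoothed periodogram (independent of
# the package's spectrogram code).
loglog_slope <- function(x, fs, f_lo = 1, f_hi = 100) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), spans = c(11, 11),
                          plot = FALSE, taper = 0.1, detrend = TRUE)
  keep <- sp$freq >= f_lo & sp$freq <= f_hi
  unname(stats::coef(stats::lm(log10(sp$spec[keep]) ~
                                 log10(sp$freq[keep])))[2])
}

# Small, fast generator configuration shared across tests.
tiny_cfg <- function(...) {
  args <- utils::modifyList(list(n_channels = 4, duration_s = 12), list(...))
  do.call(synth_config, args)
}

# Brute-force re-statement of the two component-rejection rules, evaluated
# literally per row.
brute_force_keep <- function(row, combine = "or", nonartifact = "max") {
  art <- c(row[["muscle"]], row[["eye"]], row[["heart"]],
           row[["line_noise"]], row[["channel_noise"]])
  ref <- if (nonartifact == "max") max(row[["brain"]], row[["other"]])
         else min(row[["brain"]], row[["other"]])
  crit1 <- FALSE
  for (a in art) if (a > ref) crit1 <- TRUE
  crit2 <- sum(art) > 50
  removed <- if (combine == "or") crit1 || crit2 else crit1 && crit2
  !removed
}

# Random class-probability rows that sum to 100.
random_prob_rows <- function(n, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rexp(n * 7), n, 7)
  m <- 100 * m / rowSums(m)
  colnames(m) <- c("brain", "muscle", "eye", "heart", "line_noise",
                   "channel_noise", "other")
  as.data.frame(m)
}
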