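#' Configuration of the synthetic spike-wave EEG generator
#'
#' The generator emulates the two EEG regimes the detector must separate:
#' interictal background (1/f "pink" activity with an alpha rhythm) and
#' absence-seizure activity, i.e. a generalized ~3/s spike-and-wave discharge.
#' The spike-wave train is synthesized as a sum of phase-locked harmonic
#' partials of the fundamental rate, all multiplied by one shared slow random
#' amplitude envelope. Non-sinusoidality (the harmonic stack) reproduces the
#' spectral content reaching into the beta-gamma range, and the shared
#' envelope is what induces power-to-power coupling between the harmonics --
#' the signature the comodulogram stage detects.
#'
#' @param fs sampling frequency, samples/second.
#' @param n_channels number of scalp channels.
#' @param duration_s segment duration in seconds (> 0).
#' @param swd_rate_hz fundamental spike-wave repetition rate in Hz.
#' @param n_harmonics number of harmonic partials; partials at or above the
#'   Nyquist frequency are truncated (with a message).
#' @param harmonic_decay per-partial amplitude decay: partial k has relative
#'   amplitude `harmonic_decay^(k-1)`.
#' @param envelope_bw_hz bandwidth (Hz) of the shared slow amplitude envelope;
#'   the envelope is low-pass filtered positive noise.
#' @param background_slope exponent alpha of the 1/f^alpha background power
#'   spectrum (0 gives white noise).
#' @param alpha_peak_hz centre frequency of the background alpha rhythm;
#'   `NA` disables the peak.
#' @param snr seizure-to-background RMS amplitude ratio; 0 yields pure
#'   background.
#' @param seed default seed used by [generate_dataset()] to derive
#'   per-segment seeds.
#' @return A `synth_config` list, validated.
#' @export
synth_config <- function(fs = 256, n_channels = 19, duration_s = 10,
                         swd_rate_hz = 3, n_harmonics = 20,
                         harmonic_decay = 0.85, envelope_bw_hz = 0.5,
                         background_slope = 1.5, alpha_peak_hz = 10,
                         snr = 3, seed = 1) {
  cfg <- list(fs = fs, n_channels = n_channels, duration_s = duration_s,
              swd_rate_hz = swd_rate_hz, n_harmonics = n_harmonics,
              harmonic_decay = harmonic_decay,
              envelope_bw_hz = envelope_bw_hz,
              background_slope = background_slope,
              alpha_peak_hz = alpha_peak_hz, snr = snr, seed = seed)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L
  if (!num1(cfg$fs) || cfg$fs <= 0) {
    stop_with("cfcdetect_config", "fs must be a positive number")
  }
  if (!num1(cfg$duration_s) || !is.finite(cfg$duration_s) ||
      cfg$duration_s <= 0) {
    stop_with("cfcdetect_config", "duration_s must be > 0")
  }
  if (!num1(cfg$n_channels) || cfg$n_channels < 1) {
    stop_with("cfcdetect_config", "n_channels must be >= 1")
  }
  if (!num1(cfg$swd_rate_hz) || cfg$swd_rate_hz <= 0 ||
      cfg$swd_rate_hz >= cfg$fs / 2) {
    stop_with("cfcdetect_config", "swd_rate_hz must lie in (0, fs/2)")
  }
  if (!num1(cfg$n_harmonics) || cfg$n_harmonics < 1) {
    stop_with("cfcdetect_config", "n_harmonics must be >= 1")
  }
  if (!num1(cfg$snr) || cfg$snr < 0) {
    stop_with("cfcdetect_config", "snr must be >= 0")
  }
  invisible(cfg)
}

# --- frequency-domain noise shaping helpers ---------------------------------

# Gaussian noise with power spectrum proportional to gain(f)^2: shape the
# FFT of white noise by gain() over the folded (two-sided) frequency axis.
shaped_noise <- function(n, fs, gain) {
  w <- stats::rnorm(n)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                     # folded frequencies, 0..fs/2
  g <- gain(f)
  g[1] <- 0                                # remove DC
  x <- Re(stats::fft(stats::fft(w) * g, inverse = TRUE)) / n
  x / stats::sd(x)
}

one_over_f_noise <- function(n, fs, alpha) {
  if (alpha == 0) {
    x <- stats::rnorm(n)
    return((x - mean(x)) / stats::sd(x))
  }
  shaped_noise(n, fs, function(f) ifelse(f > 0, f^(-alpha / 2), 0))
}

narrowband_noise <- function(n, fs, f0, bw) {
  shaped_noise(n, fs, function(f) exp(-0.5 * ((f - f0) / bw)^2))
}

# Slow positive envelope: low-pass Gaussian noise, offset and rectified,
# normalized to unit mean.
slow_envelope <- function(n, fs, bw_hz) {
  e <- shaped_noise(n, fs, function(f) exp(-0.5 * (f / bw_hz)^2))
  e <- pmax(1 + 0.5 * e, 0.05)
  e / mean(e)
}

# --- generators --------------------------------------------------------------

# Background data drawn from the *current* RNG stream (channels x samples).
synth_background_data <- function(cfg) {
  n <- round(cfg$duration_s * cfg$fs)
  if (n < 2) stop_with("cfcdetect_config", "duration_s too short at this fs")
  common <- one_over_f_noise(n, cfg$fs, cfg$background_slope)
  data <- matrix(0, cfg$n_channels, n)
  for (ch in seq_len(cfg$n_channels)) {
    x <- one_over_f_noise(n, cfg$fs, cfg$background_slope)
    if (is.finite(cfg$alpha_peak_hz %||% NA_real_)) {
      x <- x + 0.4 * narrowband_noise(n, cfg$fs, cfg$alpha_peak_hz, 1)
    }
    data[ch, ] <- x + 0.2 * common
  }
  10 * data   # microvolt-scale background
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Spike-and-wave source with shared slow envelope, drawn from the current
# RNG stream; unit RMS before the envelope is applied.
synth_swd_source <- function(cfg) {
  n <- round(cfg$duration_s * cfg$fs)
  nyq <- cfg$fs / 2
  k_max <- floor((nyq - 1e-9) / cfg$swd_rate_hz)
  k_use <- min(cfg$n_harmonics, k_max)
  if (k_use < cfg$n_harmonics) {
    message(sprintf(
      "synthetic: truncated %d harmonic partial(s) at or above Nyquist (%g Hz)",
      cfg$n_harmonics - k_use, nyq))
  }
  # slowly varying instantaneous rate -> cycle-to-cycle jitter broadens the
  # fundamental peak into the 3-12 Hz band
  jitter <- shaped_noise(n, cfg$fs, function(f) exp(-0.5 * (f / 1)^2))
  f_inst <- cfg$swd_rate_hz * (1 + 0.06 * jitter)
  theta <- 2 * pi * cumsum(f_inst) / cfg$fs
  phases <- stats::runif(cfg$n_harmonics, 0, 2 * pi)  # fixed spike shape
  s <- numeric(n)
  for (k in seq_len(k_use)) {
    s <- s + cfg$harmonic_decay^(k - 1) * cos(k * theta + phases[k])
  }
  env <- slow_envelope(n, cfg$fs, cfg$envelope_bw_hz)
  s <- s / sqrt(mean(s^2))
  s * env
}

#' Generate a synthetic background (interictal) EEG segment
#'
#' Channels are independent 1/f^alpha noise draws with a narrowband alpha
#' rhythm, plus a small component common to all channels; amplitudes are on
#' a microvolt scale. The same `(config, seed)` pair always yields a
#' bit-identical segment.
#'
#' @param config a [synth_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @param segment_id identifier for the returned segment.
#' @return An [eeg_segment()] labelled `"background"`.
#' @export
generate_background <- function(config, seed = config$seed,
                                segment_id = "bg") {
  validate_synth_config(config)
  data <- with_seed(seed, synth_background_data(config))
  eeg_segment(data, fs = config$fs, label = "background",
              segment_id = segment_id)
}

#' Generate a synthetic absence-seizure EEG segment
#'
#' Background activity (identical to [generate_background()] under the same
#' seed) plus a generalized spike-and-wave train: a non-sinusoidal waveform
#' at `swd_rate_hz` built from `n_harmonics` phase-locked partials whose
#' amplitudes decay geometrically, all multiplied by one shared slow random
#' envelope. The common source is mixed into every channel with random gains
#' and scaled so its RMS is `snr` times the background RMS. With `snr = 0`
#' the output equals the background segment bit for bit.
#'
#' @inheritParams generate_background
#' @return An [eeg_segment()] labelled `"seizure"`.
#' @export
generate_seizure <- function(config, seed = config$seed,
                             segment_id = "sz") {
  validate_synth_config(config)
  data <- with_seed(seed, {
    bg <- synth_background_data(config)
    src <- synth_swd_source(config)
    gains <- stats::runif(config$n_channels, 0.5, 1.5)
    bg_rms <- sqrt(mean(bg^2))
    src_rms <- sqrt(mean(src^2))
    bg + config$snr * bg_rms * (gains %o% (src / src_rms))
  })
  label <- if (config$snr == 0) "background" else "seizure"
  eeg_segment(data, fs = config$fs, label = label, segment_id = segment_id)
}

#' Generate a labelled synthetic dataset of seizure and background segments
#'
#' Per-segment durations are drawn independently and identically for both
#' classes from `duration_range` (uniform), mirroring a corpus in which
#' background segments were selected to approximately match seizure segments
#' in duration. Each segment gets its own derived seed, recorded in the
#' manifest, so any single segment can be regenerated in isolation.
#'
#' @param n_seizure,n_background counts per class (each >= 1).
#' @param config a [synth_config()]; its `duration_s` is overridden per
#'   segment.
#' @param seed integer seed governing durations and per-segment seeds.
#' @param duration_range two-element numeric range of segment durations in
#'   seconds.
#' @return A list with `segments` (list of [eeg_segment()]) and `manifest`
#'   (data.frame with columns `segment_id`, `label`, `duration_s`, `seed`).
#' @export
generate_dataset <- function(n_seizure, n_background,
                             config = synth_config(), seed = config$seed,
                             duration_range = c(5, 20)) {
  if (n_seizure < 1 || n_background < 1) {
    stop_with("cfcdetect_config", "need at least one segment per class")
  }
  validate_synth_config(config)
  n_total <- n_seizure + n_background
  plan <- with_seed(seed, {
    data.frame(
      segment_id = sprintf("seg%04d", seq_len(n_total)),
      label = rep(c("seizure", "background"), c(n_seizure, n_background)),
      duration_s = stats::runif(n_total, duration_range[1], duration_range[2]),
      seed = sample.int(.Machine$integer.max, n_total),
      stringsAsFactors = FALSE
    )
  })
  segments <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    cfg_i <- config
    cfg_i$duration_s <- plan$duration_s[i]
    segments[[i]] <- if (plan$label[i] == "seizure") {
      generate_seizure(cfg_i, seed = plan$seed[i],
                       segment_id = plan$segment_id[i])
    } else {
      generate_background(cfg_i, seed = plan$seed[i],
                          segment_id = plan$segment_id[i])
    }
  }
  list(segments = segments, manifest = plan)
}

#' Write a synthetic dataset to disk
#'
#' One CSV per segment (see [write_segment_csv()]) plus `manifest.csv` with
#' columns `segment_id,label,duration_s,seed`.
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (seg in dataset$segments) {
    write_segment_csv(seg, file.path(dir, paste0(seg$segment_id, ".csv")))
  }
  utils::write.csv(dataset$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @param fs sampling rate the segments were generated at.
#' @export
read_dataset <- function(dir, fs = 256) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  segments <- lapply(seq_len(nrow(manifest)), function(i) {
    read_segment_csv(file.path(dir, paste0(manifest$segment_id[i], ".csv")),
                     fs = fs, label = manifest$label[i],
                     segment_id = manifest$segment_id[i])
  })
  list(segments = segments, manifest = manifest)
}
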