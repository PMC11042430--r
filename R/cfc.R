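#' Logarithmically spaced frequency grid
#'
#' Geometric spacing from `f_min` to `f_max` (endpoints exact), the axis on
#' which comodulograms are computed. The default 2-120 Hz range spans delta
#' through high gamma.
#'
#' @param f_min,f_max grid endpoints in Hz, `0 < f_min < f_max`.
#' @param n_freqs number of grid points (>= 2).
#' @return Numeric vector of class `freq_grid`.
#' @export
make_grid <- function(f_min = 2, f_max = 120, n_freqs = 100) {
  if (!(f_min > 0 && f_max > f_min)) {
    stop_with("cfcdetect_grid", "need 0 < f_min < f_max")
  }
  if (n_freqs < 2) stop_with("cfcdetect_grid", "n_freqs must be >= 2")
  g <- exp(seq(log(f_min), log(f_max), length.out = n_freqs))
  g[1] <- f_min
  g[n_freqs] <- f_max
  structure(g, class = "freq_grid")
}

#' Short-time log-power spectrogram on a log-frequency grid
#'
#' Slides a Hann-tapered window along the signal, takes the FFT power in
#' each window, interpolates it onto the grid and converts to dB
#' (10 log10, floored at the smallest positive double so silence never
#' produces -Inf). The window must be long enough to resolve the lowest
#' grid frequency (`window_s >= 2 / f_min`).
#'
#' @param x single-component numeric time-series.
#' @param fs sampling frequency in Hz.
#' @param grid a [make_grid()] with `f_max < fs / 2`.
#' @param window_s window length in seconds.
#' @param overlap fractional window overlap in `[0, 1)`.
#' @return A `spectrogram` object: `power` (windows x frequencies, dB),
#'   `grid`, `window_s`, `overlap`, `fs`.
#' @export
compute_spectrogram <- function(x, fs, grid = make_grid(), window_s = 2,
                                overlap = 0.5) {
  f_min <- grid[1]
  f_max <- grid[length(grid)]
  if (f_max >= fs / 2) {
    stop_with("cfcdetect_grid", "grid maximum %g Hz at/above Nyquist", f_max)
  }
  if (window_s < 2 / f_min) {
    stop_with("cfcdetect_grid",
              "window_s = %g too short to resolve f_min = %g Hz",
              window_s, f_min)
  }
  win <- round(window_s * fs)
  if (length(x) < win) {
    stop_with("cfcdetect_too_short",
              "signal (%d samples) shorter than one window (%d samples)",
              length(x), win)
  }
  hop <- max(1L, round(win * (1 - overlap)))
  starts <- seq(1L, length(x) - win + 1L, by = hop)
  taper <- 0.5 - 0.5 * cos(2 * pi * (0:(win - 1)) / (win - 1))
  nf <- floor(win / 2) + 1L
  fft_freqs <- (seq_len(nf) - 1) * fs / win
  power <- matrix(0, length(starts), length(grid))
  for (w in seq_along(starts)) {
    seg <- x[starts[w]:(starts[w] + win - 1L)] * taper
    p <- Mod(stats::fft(seg))[seq_len(nf)]^2
    power[w, ] <- stats::approx(fft_freqs, p, xout = as.numeric(grid))$y
  }
  power <- 10 * log10(pmax(power, .Machine$double.xmin))
  structure(
    list(power = power, grid = grid, window_s = window_s, overlap = overlap,
         fs = fs),
    class = "spectrogram"
  )
}

#' Power-to-power comodulogram of one spectrogram
#'
#' Entry (i, j) is the correlation, across time windows, between the
#' log-power time course at grid frequency i and at grid frequency j —
#' amplitude-to-amplitude cross-frequency coupling. Frequencies with zero
#' power variance get 0 off the diagonal (with a message) and 1 on it.
#' At least `min_windows` windows are required for the correlations to be
#' meaningful.
#'
#' @param spec a [compute_spectrogram()] result.
#' @param method correlation flavour, `"pearson"` (default) or `"spearman"`.
#' @param min_windows minimum number of time windows.
#' @return A `cfc_matrix`: symmetric unit-diagonal matrix of correlations
#'   in `[-1, 1]` with attributes `grid` and `n_windows`.
#' @export
compute_comodulogram <- function(spec, method = c("pearson", "spearman"),
                                 min_windows = 8) {
  method <- match.arg(method)
  nw <- nrow(spec$power)
  if (nw < min_windows) {
    stop_with("cfcdetect_insufficient_data",
              "only %d windows; need >= %d", nw, min_windows)
  }
  suppressWarnings(C <- stats::cor(spec$power, method = method))
  if (anyNA(C)) {
    message("comodulogram: zero-variance frequency bin(s); coupling set to 0")
    C[is.na(C)] <- 0
  }
  C <- (C + t(C)) / 2
  diag(C) <- 1
  cfc_matrix(C, spec$grid, nw)
}

cfc_matrix <- function(C, grid, n_windows) {
  structure(C, grid = grid, n_windows = n_windows,
            class = c("cfc_matrix", "matrix", "array"))
}

#' @export
print.cfc_matrix <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("<cfc_matrix> %d x %d, %g-%g Hz, %d windows\n",
              nrow(x), ncol(x), g[1], g[length(g)], attr(x, "n_windows")))
  invisible(x)
}

#' Per-segment comodulogram, averaged over good components
#'
#' Computes one comodulogram per component activation and returns their
#' element-wise arithmetic mean — the per-segment feature matrix fed to the
#' classifier. The mean of symmetric unit-diagonal matrices keeps those
#' invariants.
#'
#' @param acts an `ic_activations` object with at least one component.
#' @inheritParams compute_spectrogram
#' @inheritParams compute_comodulogram
#' @return A `cfc_matrix`.
#' @export
segment_cfc <- function(acts, grid = make_grid(), window_s = 2,
                        overlap = 0.5, method = "pearson", min_windows = 8) {
  n_ic <- nrow(acts$acts)
  if (n_ic < 1) stop_with("cfcdetect_empty_selection", "no components")
  acc <- NULL
  nw <- NULL
  for (i in seq_len(n_ic)) {
    spec <- compute_spectrogram(acts$acts[i, ], acts$fs, grid, window_s,
                                overlap)
    C <- compute_comodulogram(spec, method = method,
                              min_windows = min_windows)
    acc <- if (is.null(acc)) unclass(C) else acc + unclass(C)
    nw <- attr(C, "n_windows")
  }
  cfc_matrix(acc / n_ic, grid, nw)
}

#' Flatten a comodulogram into a feature vector
#'
#' By default keeps the upper triangle including the diagonal (the matrix is
#' symmetric, so the rest is redundant), giving
#' `n_freqs * (n_freqs + 1) / 2` correlations.
#'
#' @param mat a `cfc_matrix`.
#' @param full keep the full flattened matrix instead of the upper triangle.
#' @return Numeric feature vector.
#' @export
flatten_cfc <- function(mat, full = FALSE) {
  m <- unclass(mat)
  if (full) as.numeric(m) else m[upper.tri(m, diag = TRUE)]
}

#' Write a comodulogram as CSV, grid in the header
#'
#' @param mat a `cfc_matrix`.
#' @param path output file.
#' @export
write_cfc_csv <- function(mat, path) {
  g <- attr(mat, "grid")
  df <- as.data.frame(unclass(mat))
  names(df) <- sprintf("f%.4g", g)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
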