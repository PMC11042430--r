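#' Re-reference a segment to the common average
#'
#' Subtracts, at every sample, the instantaneous mean over channels, so the
#' channel mean of the output is zero at each time point. Idempotent:
#' applying it twice equals applying it once.
#'
#' @param segment an [eeg_segment()] with at least two channels.
#' @return The re-referenced [eeg_segment()].
#' @export
common_average_reference <- function(segment) {
  if (n_channels(segment) < 2) {
    stop_with("cfcdetect_reference",
              "common average reference needs >= 2 channels")
  }
  out <- segment
  out$data <- sweep(segment$data, 2, colMeans(segment$data))
  out
}

#' Zero-phase notch filter at the line frequency and its harmonics
#'
#' A cascade of second-order Butterworth band-stop filters, one per harmonic
#' `k * line_hz` below the Nyquist frequency, each applied forward-backward
#' (`signal::filtfilt`) for zero phase distortion. Harmonics whose stop band
#' would reach the Nyquist frequency are skipped with a warning.
#'
#' @param segment an [eeg_segment()].
#' @param line_hz mains frequency (60 in North America, 50 elsewhere).
#' @param n_harmonics how many multiples of `line_hz` to notch (1 = the line
#'   frequency only).
#' @param bandwidth_hz full width of each stop band in Hz.
#' @return The filtered [eeg_segment()].
#' @export
notch_filter <- function(segment, line_hz = 60, n_harmonics = 3,
                         bandwidth_hz = 2) {
  fs <- segment$fs
  nyq <- fs / 2
  if (line_hz + bandwidth_hz / 2 >= nyq) {
    stop_with("cfcdetect_config", "line frequency at or above Nyquist")
  }
  out <- segment
  for (k in seq_len(n_harmonics)) {
    f0 <- k * line_hz
    if (f0 + bandwidth_hz / 2 >= nyq) {
      warning(sprintf("notch_filter: harmonic %g Hz at/above Nyquist, skipped",
                      f0), call. = FALSE)
      next
    }
    band <- c(f0 - bandwidth_hz / 2, f0 + bandwidth_hz / 2) / nyq
    bf <- signal::butter(2, band, type = "stop")
    for (ch in seq_len(n_channels(out))) {
      out$data[ch, ] <- signal::filtfilt(bf, out$data[ch, ])
    }
  }
  assert_finite(out$data, "notch-filtered data")
  out
}

#' Annotation table constructor
#'
#' Validated table of labelled time intervals within segments, as produced by
#' clinical annotators: one row per event with onset/offset in seconds
#' relative to the start of the parent segment.
#'
#' @param segment_id character vector of parent segment ids.
#' @param onset_s,offset_s interval bounds in seconds, `0 <= onset < offset`.
#' @param label per-row labels among `background`, `seizure`, `other`.
#' @return A `data.frame` with class `annotation_table`.
#' @export
annotation_table <- function(segment_id, onset_s, offset_s, label) {
  df <- data.frame(segment_id = as.character(segment_id),
                   onset_s = as.numeric(onset_s),
                   offset_s = as.numeric(offset_s),
                   label = as.character(label), stringsAsFactors = FALSE)
  bad <- which(!(df$onset_s >= 0 & df$onset_s < df$offset_s))
  if (length(bad)) {
    stop_with("cfcdetect_annotation",
              "annotation row %d: need 0 <= onset < offset", bad[1])
  }
  if (!all(df$label %in% c("background", "seizure", "other"))) {
    stop_with("cfcdetect_annotation", "labels must be background/seizure/other")
  }
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' @rdname annotation_table
#' @param path CSV file with columns `segment_id,onset_s,offset_s,label`.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  annotation_table(df$segment_id, df$onset_s, df$offset_s, df$label)
}

#' Extract annotated sub-segments
#'
#' Cuts one labelled sub-segment per annotation row referring to this
#' segment. Sample indices are zero-based and half-open: samples
#' `floor(onset_s * fs)` up to (excluding) `floor(offset_s * fs)`.
#' Overlapping annotation rows yield independent sub-segments.
#'
#' @param segment an [eeg_segment()].
#' @param annotations an [annotation_table()].
#' @return A list of [eeg_segment()], one per matching annotation row.
#' @export
extract_intervals <- function(segment, annotations) {
  rows <- which(annotations$segment_id == segment$segment_id)
  if (!length(rows)) {
    stop_with("cfcdetect_annotation", "no annotations for segment '%s'",
              segment$segment_id)
  }
  n <- n_samples(segment)
  lapply(rows, function(r) {
    i0 <- floor(annotations$onset_s[r] * segment$fs)
    i1 <- floor(annotations$offset_s[r] * segment$fs)
    if (i0 < 0 || i1 > n || i0 >= i1) {
      stop_with("cfcdetect_annotation",
                "annotation row %d lies outside segment '%s'",
                r, segment$segment_id)
    }
    lbl <- annotations$label[r]
    if (!lbl %in% c("background", "seizure")) lbl <- "background"
    eeg_segment(segment$data[, (i0 + 1):i1, drop = FALSE], fs = segment$fs,
                label = lbl,
                segment_id = sprintf("%s#%d", segment$segment_id, r))
  })
}

#' Unmixing matrix (independent-component projection)
#'
#' Carries the result of an external ICA decomposition: a components x
#' channels matrix `W` such that component activations are `W %*% data`.
#' When no decomposition is available, [identity_unmixing()] treats each
#' channel as its own component.
#'
#' @param W numeric matrix, components in rows, channels in columns; must
#'   have full row rank and no more components than channels.
#' @param source `"precomputed"` or `"identity"`.
#' @return An `unmixing_matrix` object.
#' @export
unmixing_matrix <- function(W, source = c("precomputed", "identity")) {
  source <- match.arg(source)
  W <- as.matrix(W)
  if (nrow(W) > ncol(W)) {
    stop_with("cfcdetect_dimension", "more components than channels")
  }
  if (qr(W)$rank < nrow(W)) {
    stop_with("cfcdetect_dimension", "unmixing matrix is row-rank deficient")
  }
  structure(list(W = W, source = source), class = "unmixing_matrix")
}

#' @rdname unmixing_matrix
#' @param n_channels channel count for the identity fallback.
#' @export
identity_unmixing <- function(n_channels) {
  unmixing_matrix(diag(n_channels), source = "identity")
}

#' @rdname unmixing_matrix
#' @param path delimited text file holding `W`, components in rows.
#' @export
read_unmixing <- function(path) {
  unmixing_matrix(as.matrix(utils::read.table(path)), source = "precomputed")
}

#' Project a segment onto independent components
#'
#' Applies the unmixing matrix to the channel data; with the identity matrix
#' the activations are the channel time-series themselves.
#'
#' @param segment an [eeg_segment()].
#' @param unmixing an [unmixing_matrix()] whose column count equals the
#'   segment's channel count.
#' @return An `ic_activations` object: components x samples matrix plus
#'   sampling rate, parent segment id and label.
#' @export
apply_unmixing <- function(segment, unmixing) {
  W <- unmixing$W
  if (ncol(W) != n_channels(segment)) {
    stop_with("cfcdetect_dimension",
              "unmixing has %d columns but segment has %d channels",
              ncol(W), n_channels(segment))
  }
  structure(
    list(acts = W %*% segment$data, fs = segment$fs,
         segment_id = segment$segment_id, label = segment$label),
    class = "ic_activations"
  )
}

#' @export
print.ic_activations <- function(x, ...) {
  cat(sprintf("<ic_activations '%s'> %d components x %d samples @ %g Hz\n",
              x$segment_id, nrow(x$acts), ncol(x$acts), x$fs))
  invisible(x)
}
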