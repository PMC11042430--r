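#' EEG segment container
#'
#' A labelled multichannel EEG window: a channels x samples numeric matrix in
#' microvolts with its sampling rate, class label and an identifier.
#'
#' @param data numeric matrix, channels in rows, samples in columns.
#' @param fs sampling frequency in Hz (> 0).
#' @param label either `"background"` or `"seizure"`.
#' @param segment_id opaque identifier string.
#' @return An object of class `eeg_segment`.
#' @examples
#' seg <- eeg_segment(matrix(rnorm(2 * 256), 2), fs = 256,
#'                    label = "background", segment_id = "s1")
#' n_samples(seg)
#' @export
eeg_segment <- function(data, fs, label = c("background", "seizure"),
                        segment_id = "segment") {
  label <- match.arg(label)
  if (!is.matrix(data) || !is.numeric(data)) {
    stop_with("cfcdetect_config", "segment data must be a numeric matrix")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop_with("cfcdetect_config", "fs must be a single positive number")
  }
  assert_finite(data, "segment data")
  structure(
    list(data = data, fs = fs, label = label,
         segment_id = as.character(segment_id)),
    class = "eeg_segment"
  )
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment '%s'> %d channels x %d samples @ %g Hz, label: %s\n",
              x$segment_id, nrow(x$data), ncol(x$data), x$fs, x$label))
  invisible(x)
}

#' @rdname eeg_segment
#' @param x an `eeg_segment`.
#' @export
n_channels <- function(x) nrow(x$data)

#' @rdname eeg_segment
#' @export
n_samples <- function(x) ncol(x$data)

#' @rdname eeg_segment
#' @export
duration_s <- function(x) ncol(x$data) / x$fs

#' Write / read EEG segments as portable CSV containers
#'
#' Each segment is stored as one CSV file (samples in rows, channels in
#' columns) whose header row names the channels; sampling rate, label and id
#' travel in the companion manifest (see [generate_dataset()]) or are passed
#' back explicitly when reading.
#'
#' @param segment an `eeg_segment`.
#' @param path file path to write to.
#' @export
write_segment_csv <- function(segment, path) {
  df <- as.data.frame(t(segment$data))
  names(df) <- sprintf("ch%02d", seq_len(n_channels(segment)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_segment_csv
#' @param path file path to read from.
#' @param fs,label,segment_id metadata for the restored segment (typically
#'   taken from the dataset manifest).
#' @export
read_segment_csv <- function(path, fs, label, segment_id) {
  df <- utils::read.csv(path)
  m <- t(as.matrix(df))
  dimnames(m) <- NULL
  eeg_segment(m, fs = fs, label = label, segment_id = segment_id)
}
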