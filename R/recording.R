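#' Construct an EEG recording
#'
#' A recording is a single-channel EEG time series in microvolts with its
#' sampling frequency and optional subject metadata. It is the unit of input
#' for epoch segmentation and, after feature extraction, one row of the
#' feature table.
#'
#' @param samples Numeric vector of amplitudes in microvolts. Must be
#'   non-empty and free of `NA`.
#' @param fs Sampling frequency in Hz (> 0).
#' @param subject_id Subject identifier carried through to the feature table.
#' @param channel Montage label, e.g. `"C3-A2"`.
#' @param label Optional class label, one of `"apnea"` or `"normal"`, or `NA`.
#'
#' @return An object of class `eeg_recording`: a list with elements
#'   `subject_id`, `channel`, `fs`, `samples`, `label`.
#' @examples
#' rec <- recording(sin(2 * pi * 10 * seq(0, 2, by = 1 / 200)), fs = 200)
#' duration_seconds(rec)
#' @export
recording <- function(samples, fs, subject_id = "subject", channel = "",
                      label = NA_character_) {
  samples <- as.numeric(samples)
  stopifnot(length(samples) > 0, !anyNA(samples), is.numeric(fs), fs > 0)
  if (!is.na(label)) {
    label <- match.arg(label, c("apnea", "normal"))
  }
  structure(
    list(
      subject_id = as.character(subject_id),
      channel = as.character(channel),
      fs = as.numeric(fs),
      samples = samples,
      label = label
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  lab <- if (is.na(x$label)) "unlabelled" else x$label
  cat(sprintf(
    "<eeg_recording> %s [%s] %.6g Hz, %d samples (%.1f s), %s\n",
    x$subject_id, x$channel, x$fs, length(x$samples),
    duration_seconds(x), lab
  ))
  invisible(x)
}

#' Duration of a recording in seconds
#'
#' @param rec An `eeg_recording`.
#' @return `length(samples) / fs`.
#' @export
duration_seconds <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  length(rec$samples) / rec$fs
}

new_epoch <- function(samples, fs, subject_id, index) {
  structure(
    list(subject_id = subject_id, index = as.integer(index),
         fs = fs, samples = samples),
    class = "eeg_epoch"
  )
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch> %s #%d, %.6g Hz, %d samples\n",
              x$subject_id, x$index, x$fs, length(x$samples)))
  invisible(x)
}

#' Segment a recording into fixed-length epochs
#'
#' Splits the recording into contiguous, non-overlapping windows of
#' `epoch_seconds` (30 s by sleep-scoring convention). A trailing partial
#' window is discarded, so every epoch from one recording has identical
#' length and the concatenation of all epochs is a prefix of the source
#' signal. A recording shorter than one epoch yields an empty list.
#'
#' @param rec An `eeg_recording`.
#' @param epoch_seconds Epoch length in seconds (> 0); default 30.
#' @return List of `eeg_epoch` objects in temporal order, `index` starting
#'   at 0.
#' @examples
#' rec <- recording(rnorm(200 * 95), fs = 200)
#' length(segment_epochs(rec))  # 3 full 30-s epochs; last 5 s dropped
#' @export
segment_epochs <- function(rec, epoch_seconds = 30) {
  stopifnot(inherits(rec, "eeg_recording"), epoch_seconds > 0)
  epoch_len <- round(rec$fs * epoch_seconds)
  stopifnot(epoch_len >= 1)
  n_epochs <- length(rec$samples) %/% epoch_len
  if (n_epochs == 0) return(list())
  lapply(seq_len(n_epochs) - 1L, function(i) {
    idx <- (i * epoch_len + 1L):((i + 1L) * epoch_len)
    new_epoch(rec$samples[idx], rec$fs, rec$subject_id, i)
  })
}

# Accept a bare numeric vector, an epoch, or a recording wherever a signal
# is needed; returns list(samples, fs).
as_signal <- function(x, fs = NULL) {
  if (inherits(x, "eeg_epoch") || inherits(x, "eeg_recording")) {
    list(samples = x$samples, fs = x$fs)
  } else {
    stopifnot(is.numeric(x), !is.null(fs))
    list(samples = as.numeric(x), fs = fs)
  }
}
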