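#' @title EDF (European Data Format) input and output
#' @description
#' Minimal EDF support: enough of the standard to round-trip polysomnography
#' EEG channels. EDF stores an ASCII header (256 bytes plus 256 per signal)
#' followed by data records of 16-bit little-endian integers; physical values
#' are recovered by the per-signal linear calibration
#' `phys = (dig - dig_min) * (phys_max - phys_min) / (dig_max - dig_min) + phys_min`.
#' Only continuous EDF (not EDF+D) is handled, which covers the sleep
#' databases this pipeline targets.
#' @name edf
NULL

edf_field <- function(con, n) {
  raw <- readChar(con, n, useBytes = TRUE)
  if (nchar(raw, type = "bytes") < n) stop("corrupt EDF header: truncated", call. = FALSE)
  trimws(raw)
}

edf_num <- function(x, what) {
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v))) stop(sprintf("corrupt EDF header: bad %s field", what), call. = FALSE)
  v
}

# Channel labels are matched case-insensitively with internal whitespace
# collapsed: the public sleep databases label montages inconsistently
# ("C3-A2", "C3 A2", "EEG C3-A2" would still differ, but spacing and case
# never decide a match).
normalize_channel <- function(x) tolower(gsub("\\s+", "", x))

read_edf_header <- function(con) {
  seek(con, 0)
  version <- edf_field(con, 8)
  patient <- edf_field(con, 80)
  rec_id <- edf_field(con, 80)
  startdate <- edf_field(con, 8)
  starttime <- edf_field(con, 8)
  header_bytes <- edf_num(edf_field(con, 8), "header size")
  reserved <- edf_field(con, 44)
  n_records <- edf_num(edf_field(con, 8), "record count")
  record_duration <- edf_num(edf_field(con, 8), "record duration")
  ns <- edf_num(edf_field(con, 4), "signal count")
  if (ns < 1 || ns != round(ns)) stop("corrupt EDF header: signal count", call. = FALSE)
  field <- function(n) vapply(seq_len(ns), function(i) edf_field(con, n), character(1))
  sig <- list(
    label = field(16), transducer = field(80), phys_dim = field(8),
    phys_min = edf_num(field(8), "physical minimum"),
    phys_max = edf_num(field(8), "physical maximum"),
    dig_min = edf_num(field(8), "digital minimum"),
    dig_max = edf_num(field(8), "digital maximum"),
    prefilter = field(80),
    samples_per_record = edf_num(field(8), "samples per record"),
    reserved = field(32)
  )
  list(
    version = version, patient = patient, recording_id = rec_id,
    startdate = startdate, starttime = starttime,
    header_bytes = header_bytes, reserved = reserved,
    n_records = n_records, record_duration = record_duration,
    ns = ns, signals = sig
  )
}

#' Read one EEG channel from an EDF file
#'
#' Opens an EDF file, locates the signal whose label matches `channel`
#' (case-insensitive, whitespace ignored), applies the header's
#' digital-to-physical calibration, and returns the channel as an
#' [recording()]. The sampling frequency is taken from the header
#' (`samples_per_record / record_duration`).
#'
#' @param path Path to an EDF file.
#' @param channel Channel label to extract, e.g. `"C3-A2"`.
#' @param subject_id Subject identifier for the returned recording; defaults
#'   to the file name without extension.
#' @param label Optional class label (`"apnea"`/`"normal"`) to attach.
#' @return An `eeg_recording`.
#' @seealso [write_edf()], [read_labels()]
#' @export
read_recording <- function(path, channel, subject_id = NULL,
                           label = NA_character_) {
  if (!file.exists(path)) stop(sprintf("EDF file not found: %s", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- read_edf_header(con)
  idx <- which(normalize_channel(hdr$signals$label) == normalize_channel(channel))
  if (length(idx) == 0) {
    stop(sprintf(
      "channel '%s' not present in %s; available channels: %s",
      channel, path, paste(hdr$signals$label, collapse = ", ")
    ), call. = FALSE)
  }
  idx <- idx[1]
  spr <- hdr$signals$samples_per_record
  if (hdr$record_duration <= 0) stop("corrupt EDF header: record duration", call. = FALSE)
  fs <- spr[idx] / hdr$record_duration

  seek(con, hdr$header_bytes)
  record_words <- sum(spr)
  offset_words <- if (idx > 1) sum(spr[seq_len(idx - 1)]) else 0
  out <- numeric(hdr$n_records * spr[idx])
  for (r in seq_len(hdr$n_records)) {
    rec <- readBin(con, "integer", n = record_words, size = 2,
                   signed = TRUE, endian = "little")
    if (length(rec) < record_words) stop("corrupt EDF file: truncated data", call. = FALSE)
    out[((r - 1) * spr[idx] + 1):(r * spr[idx])] <-
      rec[(offset_words + 1):(offset_words + spr[idx])]
  }
  gain <- (hdr$signals$phys_max[idx] - hdr$signals$phys_min[idx]) /
    (hdr$signals$dig_max[idx] - hdr$signals$dig_min[idx])
  phys <- (out - hdr$signals$dig_min[idx]) * gain + hdr$signals$phys_min[idx]
  if (is.null(subject_id)) subject_id <- sub("\\.[^.]*$", "", basename(path))
  recording(phys, fs = fs, subject_id = subject_id,
            channel = hdr$signals$label[idx], label = label)
}

edf_pad <- function(x, n) {
  x <- as.character(x)
  if (nchar(x, type = "bytes") > n) x <- substr(x, 1, n)
  formatC(x, width = -n)
}

edf_numfield <- function(x, n) {
  s <- formatC(x, format = "fg", width = 1, digits = 8)
  if (nchar(s) > n) s <- substr(s, 1, n)
  edf_pad(s, n)
}

#' Write recordings to an EDF file
#'
#' Writes one or more single-channel recordings (which must share an
#' integer sampling frequency and a common length) as an EDF file with
#' 1-second data records. Amplitudes are quantized to the 16-bit digital
#' range using a symmetric physical range covering the data, so the
#' round-trip error is bounded by half a quantization step. Mainly used to
#' export synthetic cohorts and build test fixtures.
#'
#' @param recordings A single `eeg_recording` or a list of them (one EDF
#'   signal each; channel labels become EDF signal labels).
#' @param path Output path.
#' @param phys_range Optional symmetric physical range in microvolts; by
#'   default the smallest range covering all samples (at least ±1).
#' @return `path`, invisibly.
#' @export
write_edf <- function(recordings, path, phys_range = NULL) {
  if (inherits(recordings, "eeg_recording")) recordings <- list(recordings)
  stopifnot(length(recordings) > 0,
            all(vapply(recordings, inherits, logical(1), "eeg_recording")))
  fs <- unique(vapply(recordings, function(r) r$fs, numeric(1)))
  stopifnot(length(fs) == 1, fs == round(fs))
  lens <- unique(vapply(recordings, function(r) length(r$samples), integer(1)))
  stopifnot(length(lens) == 1)
  n_records <- lens %/% fs
  stopifnot(n_records >= 1)
  ns <- length(recordings)

  if (is.null(phys_range)) {
    phys_range <- max(1, vapply(recordings, function(r) max(abs(r$samples)), numeric(1)))
  }
  # symmetric digital range so that 0 uV maps exactly onto digital 0
  dig_min <- -32767; dig_max <- 32767
  phys_min <- -phys_range; phys_max <- phys_range
  gain <- (phys_max - phys_min) / (dig_max - dig_min)

  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s) writeChar(s, con, eos = NULL)
  put(edf_pad("0", 8))
  put(edf_pad(recordings[[1]]$subject_id, 80))
  put(edf_pad("apneawave synthetic export", 80))
  put(edf_pad("01.01.00", 8))
  put(edf_pad("00.00.00", 8))
  put(edf_numfield(256 * (ns + 1), 8))
  put(edf_pad("", 44))
  put(edf_numfield(n_records, 8))
  put(edf_numfield(1, 8))
  put(edf_numfield(ns, 4))
  labels <- vapply(recordings, function(r) {
    if (nzchar(r$channel)) r$channel else "EEG"
  }, character(1))
  for (lab in labels) put(edf_pad(lab, 16))
  for (i in seq_len(ns)) put(edf_pad("", 80))
  for (i in seq_len(ns)) put(edf_pad("uV", 8))
  for (i in seq_len(ns)) put(edf_numfield(phys_min, 8))
  for (i in seq_len(ns)) put(edf_numfield(phys_max, 8))
  for (i in seq_len(ns)) put(edf_numfield(dig_min, 8))
  for (i in seq_len(ns)) put(edf_numfield(dig_max, 8))
  for (i in seq_len(ns)) put(edf_pad("", 80))
  for (i in seq_len(ns)) put(edf_numfield(fs, 8))
  for (i in seq_len(ns)) put(edf_pad("", 32))

  digital <- lapply(recordings, function(r) {
    d <- round((r$samples - phys_min) / gain) + dig_min
    as.integer(pmin(pmax(d, dig_min), dig_max))
  })
  for (r in seq_len(n_records)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (s in seq_len(ns)) {
      writeBin(digital[[s]][idx], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read a sidecar label table
#'
#' Class labels are supplied separately from the EDF files as a two-column
#' CSV with header `subject_id,label`, where `label` is `"apnea"` or
#' `"normal"`. Database-specific annotation formats are out of scope: labels
#' are taken as given.
#'
#' @param path Path to the CSV.
#' @return A tibble with character columns `subject_id` and `label`.
#' @export
read_labels <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    label = readr::col_character()
  ))
  if (!all(c("subject_id", "label") %in% names(tab))) {
    stop("label file must have columns 'subject_id' and 'label'", call. = FALSE)
  }
  bad <- setdiff(unique(tab$label), c("apnea", "normal"))
  if (length(bad)) {
    stop(sprintf("unknown labels in %s: %s", path, paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  tibble::as_tibble(tab[c("subject_id", "label")])
}
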