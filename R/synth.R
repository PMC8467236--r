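#' @title Synthetic EEG cohorts with controlled band power
#' @description
#' Band-limited Gaussian noise with a prescribed power budget per EEG band
#' stands in for clinical recordings, so every pipeline stage — EDF
#' round-trip, notch, decomposition, features, classifiers — is testable
#' without downloading polysomnography databases. The class contrast is an
#' explicit synthetic convention (apnea-like recordings lean on slow delta
#' and theta activity, normal ones on alpha and beta); no physiological
#' claim is attached to it.
#' @name synth
NULL

#' Specification of one synthetic recording
#'
#' @param fs Sampling frequency in Hz; default 200 (the rate of the
#'   C3-A2 recordings the pipeline targets).
#' @param duration_s Duration in seconds; default 60 (two 30-s epochs).
#' @param band_power Named nonnegative relative powers per band; need not
#'   sum to 1. At least one must be positive unless both `noise_sd` and
#'   `mains_amplitude` are positive or everything is intentionally zero.
#' @param mains_amplitude Amplitude (microvolts) of an injected 50 Hz
#'   powerline sinusoid; default 0.
#' @param mains_hz Powerline frequency; default 50.
#' @param noise_sd Standard deviation of added broadband white noise;
#'   default 0.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(fs = 200, duration_s = 60,
                       band_power = c(delta = 1, theta = 1, alpha = 1,
                                      beta = 1, gamma = 0.5),
                       mains_amplitude = 0, mains_hz = 50, noise_sd = 0,
                       seed = 1L) {
  stopifnot(fs > 0, duration_s > 0, all(band_power >= 0),
            mains_amplitude >= 0, noise_sd >= 0)
  structure(
    list(fs = fs, duration_s = duration_s, band_power = band_power,
         mains_amplitude = mains_amplitude, mains_hz = mains_hz,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "synth_spec"
  )
}

# White Gaussian noise filtered to [lo, hi) with a zero-phase order-4
# Butterworth; degenerate edges fall back to low-/high-pass.
band_limited_noise <- function(n, fs, lo, hi) {
  x <- stats::rnorm(n)
  nyq <- fs / 2
  hi <- min(hi, nyq * 0.999)
  if (hi <= lo) return(numeric(n))
  filt <- if (lo <= 0) {
    signal::butter(4, hi / nyq, type = "low")
  } else if (hi >= nyq * 0.999) {
    signal::butter(4, lo / nyq, type = "high")
  } else {
    signal::butter(2, c(lo, hi) / nyq, type = "pass")
  }
  signal::filtfilt(filt, x)
}

#' Generate one synthetic EEG recording
#'
#' Sums band-limited Gaussian noise over the EEG bands — each component
#' rescaled so its RMS is proportional to the square root of the requested
#' band power — plus an optional mains sinusoid and broadband white noise.
#' Bands lying above Nyquist are skipped with a warning.
#'
#' @param spec A [synth_spec()].
#' @param subject_id,label Metadata for the returned recording.
#' @param bands Band definition table; default [eeg_bands()].
#' @return An `eeg_recording` of `round(fs * duration_s)` samples.
#' @examples
#' rec <- generate_recording(synth_spec(band_power = c(alpha = 1), seed = 7))
#' @export
generate_recording <- function(spec, subject_id = "synthetic", label = NA_character_,
                               bands = eeg_bands()) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- round(spec$fs * spec$duration_s)
  nyq <- spec$fs / 2
  with_local_seed(spec$seed, {
    x <- numeric(n)
    for (b in names(spec$band_power)) {
      p <- spec$band_power[[b]]
      if (p <= 0) next
      row <- bands[bands$band == b, ]
      if (nrow(row) == 0) stop(sprintf("unknown band '%s'", b), call. = FALSE)
      if (row$lo >= nyq) {
        warning(sprintf("band %s lies above Nyquist (%g Hz); skipped", b, nyq),
                call. = FALSE)
        next
      }
      comp <- band_limited_noise(n, spec$fs, row$lo, min(row$hi, nyq))
      rms <- sqrt(mean(comp^2))
      if (rms > 0) x <- x + comp * sqrt(p) / rms
    }
    if (spec$mains_amplitude > 0) {
      t <- (seq_len(n) - 1) / spec$fs
      x <- x + spec$mains_amplitude * sin(2 * pi * spec$mains_hz * t)
    }
    if (spec$noise_sd > 0) x <- x + stats::rnorm(n, sd = spec$noise_sd)
    recording(x, fs = spec$fs, subject_id = subject_id, channel = "C3-A2",
              label = label)
  })
}

#' Default class-conditional band-power profiles
#'
#' The synthetic convention separating the two classes: apnea-like
#' recordings carry elevated slow-wave (delta, theta) power, normal
#' recordings elevated alpha and beta power. `separation = 1` is the
#' default contrast; 0 collapses both classes onto the mid-point profile
#' (the null), and values in between interpolate, which is useful for
#' monotonicity checks.
#'
#' @param separation Contrast strength in `[0, 1]`; default 1.
#' @return Named list `apnea` / `normal` of band-power vectors.
#' @export
cohort_profiles <- function(separation = 1) {
  stopifnot(separation >= 0, separation <= 1)
  apnea <- c(delta = 4.0, theta = 2.0, alpha = 0.5, beta = 0.3, gamma = 0.1)
  normal <- c(delta = 1.0, theta = 0.8, alpha = 2.5, beta = 1.5, gamma = 0.3)
  mid <- (apnea + normal) / 2
  list(
    apnea = mid + (apnea - mid) * separation,
    normal = mid + (normal - mid) * separation
  )
}

#' Generate a labeled synthetic cohort
#'
#' Draws `n_per_class` recordings per class from class-specific band-power
#' profiles with per-recording lognormal jitter on the powers (so features
#' vary within class), fully reproducible from `seed`. Subject ids are
#' `apnea_01 ... normal_01 ...`.
#'
#' @param n_per_class Recordings per class (>= 1).
#' @param profiles Named list `apnea`/`normal` of band-power vectors;
#'   default [cohort_profiles()].
#' @param fs,duration_s,mains_amplitude,noise_sd Passed to each
#'   recording's [synth_spec()]; defaults 200 Hz, 60 s, no mains, white
#'   noise sd 0.2.
#' @param jitter_sdlog Standard deviation (log scale) of the lognormal
#'   per-recording power jitter; default 0.25.
#' @param seed Integer cohort seed.
#' @return List of `eeg_recording` objects, apnea first.
#' @examples
#' cohort <- generate_cohort(n_per_class = 2, duration_s = 30, seed = 42)
#' vapply(cohort, function(r) r$label, character(1))
#' @export
generate_cohort <- function(n_per_class, profiles = cohort_profiles(),
                            fs = 200, duration_s = 60, mains_amplitude = 0,
                            noise_sd = 0.2, jitter_sdlog = 0.25, seed = 1L) {
  stopifnot(n_per_class >= 1,
            all(c("apnea", "normal") %in% names(profiles)))
  recs <- list()
  i <- 0L
  for (cl in c("apnea", "normal")) {
    base <- profiles[[cl]]
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      # per-recording derived seed keeps every draw independent and the
      # whole cohort reproducible from the single cohort seed
      rec_seed <- (as.integer(seed) * 1009L + i * 7919L) %% .Machine$integer.max
      jitter <- with_local_seed(rec_seed, {
        if (jitter_sdlog > 0) stats::rlnorm(length(base), 0, jitter_sdlog) else rep(1, length(base))
      })
      powers <- stats::setNames(base * jitter, names(base))
      spec <- synth_spec(fs = fs, duration_s = duration_s,
                         band_power = powers,
                         mains_amplitude = mains_amplitude,
                         noise_sd = noise_sd, seed = rec_seed + 1L)
      recs[[i]] <- generate_recording(
        spec, subject_id = sprintf("%s_%02d", cl, j), label = cl
      )
    }
  }
  recs
}

#' Export a synthetic cohort as EDF files plus a label CSV
#'
#' Writes one EDF per recording (named `<subject_id>.edf`) and a sidecar
#' `labels.csv` with columns `subject_id,label`, matching the input layout
#' the pipeline expects for real data.
#'
#' @param cohort List of labeled `eeg_recording` objects.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_edf <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in cohort) {
    write_edf(rec, file.path(dir, paste0(rec$subject_id, ".edf")))
  }
  labels <- tibble::tibble(
    subject_id = vapply(cohort, function(r) r$subject_id, character(1)),
    label = vapply(cohort, function(r) r$label, character(1))
  )
  readr::write_csv(labels, file.path(dir, "labels.csv"))
  invisible(dir)
}
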