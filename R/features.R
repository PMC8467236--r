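#' @title Entropy, energy and band-ratio features
#' @description
#' Fourteen features summarize each recording: the Shannon wavelet entropy
#' and the energy of the five band coefficient vectors (10 features), plus
#' four band-power ratio indices named after the physiological quantities
#' they track in the EEG literature: "heart rate" (theta/alpha), "brain
#' perfusion" (alpha/delta), "neural activity" (beta/theta) and
#' "synchronization" (delta/theta).
#' @name features
NULL

RATIO_EPS <- 1e-12

#' Shannon wavelet entropy of a coefficient vector
#'
#' The coefficients are normalized to unit L2 norm so that
#' `q_i = c_i^2 / sum(c^2)` is a probability distribution, and
#' `H = -sum(q_i * log(q_i))` with the `0 * log 0 = 0` convention. Under
#' this normalized convention H is scale-invariant and bounded in
#' `[0, log(N)]`; an all-zero vector returns 0.
#'
#' @param coeffs Non-empty numeric vector of wavelet coefficients.
#' @param base Logarithm base; natural log by default.
#' @return Scalar entropy (dimensionless).
#' @examples
#' wavelet_entropy(rep(1, 8))  # uniform: log(8)
#' wavelet_entropy(c(5, 0, 0, 0))  # single spike: 0
#' @export
wavelet_entropy <- function(coeffs, base = exp(1)) {
  stopifnot(length(coeffs) > 0)
  total <- sum(coeffs^2)
  if (total == 0) return(0)
  q <- coeffs^2 / total
  q <- q[q > 0]
  -sum(q * log(q)) / log(base)
}

#' Energy of a coefficient vector
#'
#' Sum of squared coefficients. An empty vector (a band entirely above
#' Nyquist) has energy 0 by convention.
#'
#' @param coeffs Numeric vector.
#' @return Nonnegative scalar.
#' @export
band_energy <- function(coeffs) {
  if (length(coeffs) == 0) return(0)
  sum(coeffs^2)
}

#' Band-power ratio indices
#'
#' Four named ratios of band energies: heart rate = theta/alpha, brain
#' perfusion = alpha/delta, neural activity = beta/theta, synchronization =
#' delta/theta. Denominators are guarded with an additive epsilon (1e-12)
#' so degenerate inputs (empty or silent bands) yield finite values instead
#' of errors.
#'
#' @param band_energies Named numeric vector or list with entries `delta`,
#'   `theta`, `alpha`, `beta`, `gamma`.
#' @return A named list with `heart_rate_ratio`, `brain_perfusion_ratio`,
#'   `neural_activity_ratio`, `synchronization_ratio`.
#' @examples
#' band_ratios(c(delta = 4, theta = 2, alpha = 1, beta = 8, gamma = 1))
#' @export
band_ratios <- function(band_energies) {
  e <- band_energies
  missing <- setdiff(band_names(), names(e))
  if (length(missing)) {
    stop(sprintf("missing band energies: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  rat <- function(num, den) e[[num]] / (e[[den]] + RATIO_EPS)
  list(
    heart_rate_ratio = rat("theta", "alpha"),
    brain_perfusion_ratio = rat("alpha", "delta"),
    neural_activity_ratio = rat("beta", "theta"),
    synchronization_ratio = rat("delta", "theta")
  )
}

#' Names of the 14 features, in table order
#'
#' @return Character vector: five entropies, five energies, four ratios.
#' @export
feature_names <- function() {
  c(paste0("entropy_", band_names()),
    paste0("energy_", band_names()),
    "heart_rate_ratio", "brain_perfusion_ratio",
    "neural_activity_ratio", "synchronization_ratio")
}

#' Assemble the 14-feature vector for one epoch
#'
#' Computes entropy and energy for each of the five band coefficient
#' vectors and the four ratio indices, returned as a single tibble row in
#' the fixed column order of [feature_names()]. Deterministic for fixed
#' input.
#'
#' @param bc A `band_coefficients` object from
#'   [extract_band_coefficients()].
#' @param subject_id,label Metadata carried into the row.
#' @return A one-row tibble: `subject_id`, `label`, then the 14 features.
#' @export
feature_vector <- function(bc, subject_id = "subject", label = NA_character_) {
  stopifnot(inherits(bc, "band_coefficients"),
            all(band_names() %in% names(bc)))
  ent <- vapply(band_names(), function(b) {
    if (length(bc[[b]]) == 0) 0 else wavelet_entropy(bc[[b]])
  }, numeric(1))
  en <- vapply(band_names(), function(b) band_energy(bc[[b]]), numeric(1))
  ratios <- band_ratios(en)
  row <- c(as.list(stats::setNames(ent, paste0("entropy_", band_names()))),
           as.list(stats::setNames(en, paste0("energy_", band_names()))),
           ratios)
  tibble::as_tibble(c(list(subject_id = as.character(subject_id),
                           label = as.character(label)), row))
}

#' Average per-epoch feature vectors into one recording-level row
#'
#' Features are computed per 30-s epoch and summarized per recording by
#' the per-feature arithmetic mean, so the classifier sees one row per
#' subject. All rows must come from the same subject.
#'
#' @param per_epoch Tibble of per-epoch feature rows (as from
#'   [feature_vector()]).
#' @return A one-row tibble with the same columns.
#' @export
aggregate_recording <- function(per_epoch) {
  stopifnot(nrow(per_epoch) >= 1)
  ids <- unique(per_epoch$subject_id)
  if (length(ids) != 1) {
    stop(sprintf("cannot aggregate across subjects: %s",
                 paste(ids, collapse = ", ")), call. = FALSE)
  }
  dplyr::summarise(
    per_epoch,
    subject_id = ids,
    label = unique(.data$label)[1],
    dplyr::across(dplyr::all_of(feature_names()), mean)
  )
}

#' Extract the feature table from a set of recordings
#'
#' End-to-end feature stage: each recording is segmented into epochs,
#' notch-filtered, decomposed into bands, and summarized as 14 features;
#' epochs are averaged per recording unless `per_epoch = TRUE`, in which
#' case one row per epoch is returned with an extra `epoch` column.
#'
#' @param recordings A list of `eeg_recording` objects (or a single one).
#' @param epoch_seconds Epoch length in seconds; default 30.
#' @param notch `NULL` to disable, or a list with `f0` and `q` (defaults
#'   50 Hz / 30) for the powerline notch.
#' @param wavelet,level,bands Passed to [extract_band_coefficients()].
#' @param per_epoch Return per-epoch rows instead of per-recording means.
#' @return A tibble with columns `subject_id`, `label`,
#'   (`epoch`,) and the 14 features of [feature_names()].
#' @export
extract_features <- function(recordings, epoch_seconds = 30,
                             notch = list(f0 = 50, q = 30),
                             wavelet = "db8", level = "auto",
                             bands = eeg_bands(), per_epoch = FALSE) {
  if (inherits(recordings, "eeg_recording")) recordings <- list(recordings)
  rows <- purrr::map(recordings, function(rec) {
    epochs <- segment_epochs(rec, epoch_seconds)
    if (length(epochs) == 0) {
      stop(sprintf("recording %s is shorter than one epoch", rec$subject_id),
           call. = FALSE)
    }
    per <- purrr::map(epochs, function(ep) {
      if (!is.null(notch)) {
        ep <- apply_notch(ep, f0 = notch$f0 %||% 50, q = notch$q %||% 30)
      }
      bc <- extract_band_coefficients(ep, wavelet = wavelet, level = level,
                                      bands = bands)
      fv <- feature_vector(bc, rec$subject_id, rec$label)
      fv$epoch <- ep$index
      fv
    })
    per <- dplyr::bind_rows(per)
    if (per_epoch) {
      dplyr::relocate(per, "epoch", .after = "label")
    } else {
      aggregate_recording(dplyr::select(per, -"epoch"))
    }
  })
  dplyr::bind_rows(rows)
}
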