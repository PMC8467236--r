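# Shared fixture builders: everything is generated in code, no stored data.

# Pure sinusoid sampled at fs for `seconds`, first sample at t = 1/fs.
tone <- function(freq, fs, seconds = 30, amplitude = 1) {
  t <- seq(1 / fs, seconds, by = 1 / fs)
  amplitude * sin(2 * pi * freq * t)
}

rand_signal <- function(n, seed) {
  set.seed(seed)
  stats::rnorm(n)
}

# Small well-separated labeled feature table built from two Gaussian blobs;
# cheap stand-in where full synthetic recordings are not needed.
blob_features <- function(n_per_class = 20, shift = 4, sd = 0.5, seed = 1) {
  set.seed(seed)
  make_rows <- function(label, mu) {
    m <- matrix(stats::rnorm(n_per_class * 14, mean = mu, sd = sd),
                nrow = n_per_class)
    colnames(m) <- feature_names()
    dplyr::bind_cols(
      tibble::tibble(
        subject_id = sprintf("%s_%02d", label, seq_len(n_per_class)),
        label = label
      ),
      tibble::as_tibble(m)
    )
  }
  dplyr::bind_rows(make_rows("apnea", 0), make_rows("normal", shift))
}

band_energy_shares <- function(bc) {
  en <- vapply(bc, band_energy, numeric(1))
  en / sum(en)
}
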