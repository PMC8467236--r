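# Direct-summation entropy oracle, independent of the implementation.
entropy_oracle <- function(coeffs) {
  q <- coeffs^2 / sum(coeffs^2)
  s <- 0
  for (qi in q) if (qi > 0) s <- s - qi * log(qi)
  s
}

test_that("wavelet entropy matches the normalized Shannon form", {
  expect_identical(wavelet_entropy(c(3.7, 0, 0, 0)), 0)
  expect_equal(wavelet_entropy(rep(2, 8)), log(8))
  expect_equal(wavelet_entropy(rep(-0.1, 8)), log(8))

  set.seed(21)
  for (i in 1:20) {
    v <- rnorm(16)
    expect_equal(wavelet_entropy(v), entropy_oracle(v), tolerance = 1e-12)
  }
  expect_identical(wavelet_entropy(rep(0, 5)), 0)
  expect_error(wavelet_entropy(numeric(0)))
})

test_that("entropy is scale-invariant and bounded by log N", {
  set.seed(22)
  for (i in 1:10) {
    v <- rnorm(sample(4:64, 1))
    h <- wavelet_entropy(v)
    expect_gte(h, 0)
    expect_lte(h, log(length(v)) + 1e-12)
    expect_equal(wavelet_entropy(137.5 * v), h, tolerance = 1e-10)
    expect_equal(wavelet_entropy(-v), h, tolerance = 1e-12)
  }
})

test_that("band energy is the sum of squares and quadratically homogeneous", {
  expect_identical(band_energy(c(3, 4)), 25)
  expect_identical(band_energy(rep(0, 10)), 0)
  expect_identical(band_energy(numeric(0)), 0)

  set.seed(23)
  v <- rnorm(1000)
  expect_equal(band_energy(v), sum(vapply(v, function(x) x * x, numeric(1))),
               tolerance = 1e-12)
  expect_equal(band_energy(3 * v), 9 * band_energy(v), tolerance = 1e-12)
})

test_that("band ratios implement the four named indices", {
  eq <- band_ratios(c(delta = 2, theta = 2, alpha = 2, beta = 2, gamma = 2))
  expect_equal(unlist(eq), c(heart_rate_ratio = 1, brain_perfusion_ratio = 1,
                             neural_activity_ratio = 1,
                             synchronization_ratio = 1),
               tolerance = 1e-9)

  r <- band_ratios(c(delta = 1, theta = 2, alpha = 1, beta = 1, gamma = 1))
  expect_equal(r$heart_rate_ratio, 2, tolerance = 1e-9)

  # hand evaluation for energies (delta, theta, alpha, beta, gamma)
  h <- band_ratios(c(delta = 4, theta = 2, alpha = 1, beta = 8, gamma = 1))
  expect_equal(unlist(h), c(heart_rate_ratio = 2, brain_perfusion_ratio = 0.25,
                            neural_activity_ratio = 4,
                            synchronization_ratio = 2),
               tolerance = 1e-9)

  expect_error(band_ratios(c(delta = 1, theta = 1)), "missing band")
})

test_that("the cyclic ratio identity holds for random energies", {
  set.seed(24)
  for (i in 1:10) {
    e <- stats::setNames(runif(5, 0.1, 10), c("delta", "theta", "alpha",
                                              "beta", "gamma"))
    r <- band_ratios(e)
    # delta/theta * theta/alpha * alpha/delta == 1
    expect_equal(r$synchronization_ratio * r$heart_rate_ratio *
                   r$brain_perfusion_ratio, 1, tolerance = 1e-6)
  }
})

test_that("feature vectors carry exactly 14 named features", {
  bc <- extract_band_coefficients(rand_signal(6000, 25), fs = 200)
  fv <- feature_vector(bc, "s1", "apnea")
  expect_identical(setdiff(names(fv), c("subject_id", "label")),
                   feature_names())
  expect_length(feature_names(), 14)
  expect_length(grep("^(entropy|energy)_", feature_names()), 10)
  expect_length(grep("_ratio$", feature_names()), 4)
  expect_true(all(vapply(fv[feature_names()], is.numeric, logical(1))))

  # degenerate all-zero input flows through with zeros everywhere
  z <- feature_vector(extract_band_coefficients(rep(0, 6000), fs = 200))
  expect_true(all(unlist(z[feature_names()]) == 0))

  # alpha-dominant input makes energy_alpha the largest energy feature
  a <- feature_vector(extract_band_coefficients(tone(10, 200, 30), fs = 200))
  energies <- unlist(a[paste0("energy_", c("delta", "theta", "alpha",
                                           "beta", "gamma"))])
  expect_identical(names(which.max(energies)), "energy_alpha")
})

test_that("recording aggregation is the per-feature mean over epochs", {
  bc <- extract_band_coefficients(rand_signal(6000, 26), fs = 200)
  one <- feature_vector(bc, "s1", "apnea")
  expect_equal(aggregate_recording(one), one)

  two <- dplyr::bind_rows(one, one)
  two$energy_alpha <- c(2, 4)
  agg <- aggregate_recording(two)
  expect_identical(agg$energy_alpha, 3)

  set.seed(27)
  many <- dplyr::bind_rows(lapply(1:10, function(i) {
    fv <- one
    fv[feature_names()] <- as.list(rnorm(14))
    fv
  }))
  agg <- aggregate_recording(many)
  expect_equal(unlist(agg[feature_names()]),
               colMeans(as.matrix(many[feature_names()])), tolerance = 1e-12)

  mixed <- dplyr::bind_rows(one, dplyr::mutate(one, subject_id = "s2"))
  expect_error(aggregate_recording(mixed), "across subjects")
})

test_that("extract_features returns one row per recording or per epoch", {
  recs <- list(
    recording(rand_signal(200 * 65, 28), fs = 200, subject_id = "a",
              label = "apnea"),
    recording(rand_signal(200 * 65, 29), fs = 200, subject_id = "b",
              label = "normal")
  )
  per_rec <- extract_features(recs)
  expect_identical(nrow(per_rec), 2L)
  expect_identical(per_rec$subject_id, c("a", "b"))

  per_ep <- extract_features(recs, per_epoch = TRUE)
  expect_identical(nrow(per_ep), 4L)  # two full 30-s epochs each
  expect_identical(per_ep$epoch, c(0L, 1L, 0L, 1L))

  short <- recording(rnorm(100), fs = 200, subject_id = "tiny")
  expect_error(extract_features(short), "shorter than one epoch")
})
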