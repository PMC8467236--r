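# Independent oracle: brute-force maximal-overlap band assignment.
brute_force_assignment <- function(fs, level, bands = eeg_bands()) {
  nyq <- fs / 2
  bin <- fs / 2^(level + 1)
  out <- stats::setNames(rep(list(integer(0)), nrow(bands)), bands$band)
  for (k in 0:(2^level - 1)) {
    best <- NA_integer_; best_ov <- -1
    for (i in seq_len(nrow(bands))) {
      ov <- max(0, min((k + 1) * bin, min(bands$hi[i], nyq)) -
                   max(k * bin, bands$lo[i]))
      if (ov > best_ov) { best_ov <- ov; best <- i }
    }
    if (best_ov <= 0) best <- nrow(bands)
    out[[best]] <- c(out[[best]], k)
  }
  out
}

test_that("a three-level tree yields eight terminal nodes and zero maps to zero", {
  nodes <- wpd_decompose(rand_signal(6000, 1), fs = 200, level = 3)
  expect_length(nodes, 8)
  expect_identical(sort(vapply(nodes, function(n) n$freq_index, integer(1))), 0:7)

  z <- wpd_decompose(rep(0, 4096), fs = 200, level = 5)
  expect_true(all(vapply(z, function(n) all(n$coefficients == 0), logical(1))))

  expect_error(wpd_decompose(rnorm(4), fs = 200, level = 6), "too short")
  expect_error(wpd_decompose(rnorm(512), fs = 200, wavelet = "db99", level = 2),
               "unknown wavelet")
})

test_that("node energies satisfy Parseval for periodized orthogonal wavelets", {
  x <- rand_signal(4096, seed = 2)
  nodes <- wpd_decompose(x, fs = 200, wavelet = "db8", level = 6)
  e_nodes <- sum(vapply(nodes, function(n) sum(n$coefficients^2), numeric(1)))
  expect_equal(e_nodes, sum(x^2), tolerance = 1e-8)

  # and per-band grouping neither loses nor duplicates energy
  bc <- extract_band_coefficients(x, fs = 200, level = 6)
  expect_equal(sum(vapply(bc, band_energy, numeric(1))), sum(x^2),
               tolerance = 1e-8)
})

test_that("frequency ordering is the Gray-code permutation of the packet paths", {
  # level 1: identity
  n1 <- frequency_order(wpd_decompose(rand_signal(256, 3), fs = 64, level = 1))
  expect_identical(vapply(n1, function(n) n$natural_index, integer(1)), 0:1)

  # level 2: natural paths (AA, AD, DA, DD) sit at frequency positions (0,1,3,2)
  n2 <- wpd_decompose(rand_signal(256, 3), fs = 64, level = 2)
  expect_identical(vapply(n2, function(n) n$freq_index, integer(1)),
                   c(0L, 1L, 3L, 2L))

  # tone-probe oracle at level 3: a tone at the center of interval k
  # concentrates its energy in frequency-ordered node k
  for (k in 0:7) {
    probe <- tone((k + 0.5) * 4, fs = 64, seconds = 16)
    fo <- frequency_order(wpd_decompose(probe, fs = 64, level = 3))
    en <- vapply(fo, function(n) sum(n$coefficients^2), numeric(1))
    expect_identical(which.max(en) - 1L, k)
    expect_gte(max(en) / sum(en), 0.6)
  }

  # frequency intervals tile [0, Nyquist) in order
  fo <- frequency_order(wpd_decompose(rand_signal(512, 8), fs = 128, level = 4))
  lo <- vapply(fo, function(n) n$freq_interval[1], numeric(1))
  hi <- vapply(fo, function(n) n$freq_interval[2], numeric(1))
  expect_equal(lo, seq(0, 64 - 4, by = 4))
  expect_equal(hi, lo + 4)

  expect_error(frequency_order(structure(fo[1:3], class = "wpd_nodes")),
               "incomplete")
})

test_that("band assignment follows the maximal-overlap rule", {
  # forced example: 4 Hz bins at fs 64; node 3 = [12,16) overlaps alpha by
  # 1 Hz and beta by 2 Hz, so beta wins; gamma is empty below Nyquist 32
  got <- assign_bands(fs = 64, level = 3)
  expect_identical(got, list(delta = 0L, theta = 1L, alpha = 2L,
                             beta = 3:7, gamma = integer(0)))

  # brute-force oracle across the three database sampling rates
  for (fs in c(100, 200, 512)) {
    level <- auto_wpd_level(fs)
    expect_identical(assign_bands(fs, level), brute_force_assignment(fs, level),
                     info = sprintf("fs = %g", fs))
  }

  # a single all-covering band absorbs every node
  all_band <- tibble::tibble(band = "wide", lo = 0, hi = Inf)
  got <- assign_bands(fs = 200, level = 4, bands = all_band)
  expect_identical(got$wide, 0:15)

  expect_error(assign_bands(fs = 200, level = 3,
                            bands = eeg_bands()[integer(0), ]))
})

test_that("auto level keeps node bandwidth at or below 2 Hz", {
  expect_identical(auto_wpd_level(100), 5L)
  expect_identical(auto_wpd_level(200), 6L)
  expect_identical(auto_wpd_level(512), 7L)
  for (fs in c(100, 200, 512)) {
    L <- auto_wpd_level(fs)
    expect_lte(fs / 2^(L + 1), 2)
    expect_gt(fs / 2^L, 2)  # smallest such level
  }
})

test_that("band extraction concentrates pure tones in their nominal band", {
  t30 <- function(f, fs) tone(f, fs, 30)
  bc_alpha <- extract_band_coefficients(t30(10, 200), fs = 200)
  expect_gte(band_energy_shares(bc_alpha)[["alpha"]], 0.6)

  bc_delta <- extract_band_coefficients(t30(2, 200), fs = 200)
  expect_gte(band_energy_shares(bc_delta)[["delta"]], 0.6)

  z <- extract_band_coefficients(rep(0, 6000), fs = 200)
  expect_named(z, c("delta", "theta", "alpha", "beta", "gamma"))
  expect_true(all(vapply(z, function(v) all(v == 0), logical(1))))
})

test_that("a literal three-level tree stays available but warns about resolution", {
  expect_warning(
    bc <- extract_band_coefficients(rand_signal(6000, 6), fs = 200, level = 3),
    "bins"
  )
  expect_length(unlist(attr(bc, "assignment")), 8)
})
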