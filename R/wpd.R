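#' @title Wavelet packet decomposition into EEG frequency bands
#' @description
#' A wavelet packet decomposition (WPD) recursively splits both the low-pass
#' and high-pass branches of the discrete wavelet transform, so depth `L`
#' yields a full binary tree with `2^L` terminal nodes of equal nominal
#' bandwidth `fs / 2^(L+1)`. Terminal nodes come out of the recursion in
#' filter-path (natural/Paley) order, which interleaves frequencies because
#' decimating a high-pass branch mirrors its spectrum; [frequency_order()]
#' applies the Gray-code (sequency) permutation so node `k` covers
#' `[k, k+1) * fs / 2^(L+1)` Hz, after which [assign_bands()] maps nodes to
#' the five clinical EEG bands and [extract_band_coefficients()] composes
#' the whole stage.
#' @name wpd
NULL

# One periodized analysis step. Circular convolution against the analysis
# filters followed by dyadic downsampling; orthonormal for even input
# length. Odd intermediate lengths are extended by repeating the last
# sample before splitting (the usual periodization convention), which is
# why exact Parseval equality is only guaranteed when the input length is
# divisible by 2^level.
dwt_step <- function(x, filt) {
  n <- length(x)
  if (n %% 2L == 1L) {
    x <- c(x, x[n])
    n <- n + 1L
  }
  L <- filt$length
  # wrap the signal so that index arithmetic is plain (periodic extension)
  ext <- c(x, x[seq_len(min(L - 1, n))])
  while (length(ext) < n + L - 1) ext <- c(ext, ext[seq_len(n)])
  starts <- seq(1L, n, by = 2L)
  a <- numeric(n %/% 2L)
  d <- numeric(n %/% 2L)
  for (m in seq_len(L)) {
    a <- a + filt$lo[m] * ext[starts + m - 1L]
    d <- d + filt$hi[m] * ext[starts + m - 1L]
  }
  list(a = a, d = d)
}

#' Decompose a signal into wavelet packet terminal nodes
#'
#' Runs a full `level`-deep wavelet packet tree with periodized boundary
#' handling and returns the `2^level` terminal coefficient vectors in
#' natural (filter-path) order. With an orthogonal wavelet and an input
#' length divisible by `2^level`, total coefficient energy equals signal
#' energy (Parseval).
#'
#' @param x An `eeg_epoch`, `eeg_recording`, or numeric vector.
#' @param fs Sampling frequency in Hz (required for a bare numeric `x`).
#' @param wavelet Daubechies wavelet name; default `"db8"`.
#' @param level Decomposition depth (>= 1).
#' @return A list of class `wpd_nodes`: elements of class `wpd_node`, each
#'   with `level`, `natural_index` (0-based filter path), `freq_index`
#'   (0-based position after frequency ordering), `freq_interval` (Hz), and
#'   `coefficients`. Natural order; pass to [frequency_order()] before any
#'   frequency-based interpretation.
#' @examples
#' nodes <- wpd_decompose(rnorm(4096), fs = 200, level = 3)
#' length(nodes)  # 8 terminal nodes from a 3-level tree
#' @export
wpd_decompose <- function(x, fs = NULL, wavelet = "db8", level) {
  sig <- as_signal(x, fs)
  stopifnot(level >= 1, level == round(level))
  level <- as.integer(level)
  filt <- wavelet_filter_pair(wavelet)
  min_len <- 2^level
  if (length(sig$samples) < min_len) {
    stop(sprintf("signal of length %d is too short for a %d-level decomposition",
                 length(sig$samples), level), call. = FALSE)
  }
  tree <- list(sig$samples)
  for (j in seq_len(level)) {
    tree <- unlist(lapply(tree, function(node) {
      s <- dwt_step(node, filt)
      list(s$a, s$d)
    }), recursive = FALSE)
  }
  n_nodes <- 2^level
  bin_width <- sig$fs / 2^(level + 1)
  freq_idx <- gray_decode(seq_len(n_nodes) - 1L)
  nodes <- lapply(seq_len(n_nodes), function(i) {
    fi <- freq_idx[i]
    structure(
      list(
        level = level,
        natural_index = i - 1L,
        freq_index = fi,
        freq_interval = c(fi * bin_width, (fi + 1) * bin_width),
        coefficients = tree[[i]]
      ),
      class = "wpd_node"
    )
  })
  structure(nodes, class = "wpd_nodes", fs = sig$fs, wavelet = wavelet)
}

# Gray-code permutation: natural (Paley) index -> frequency position.
# Every high-pass decimation mirrors the sub-spectrum, so a node's children
# swap whenever the node itself sits at an odd frequency position; unrolling
# the recursion, the natural index is the binary-reflected Gray code of the
# frequency position, and the forward map is therefore the Gray decode
# (cumulative-XOR of the bits from the top down).
gray_decode <- function(n) {
  x <- as.integer(n)
  s <- 1L
  while (s < 32L) {
    x <- bitwXor(x, bitwShiftR(x, s))
    s <- s * 2L
  }
  x
}

#' Reorder wavelet packet nodes by ascending frequency
#'
#' Permutes a complete set of terminal nodes from natural (filter-path)
#' order into sequency order, so that node `k` of the result covers the
#' frequency interval `[k, k+1) * fs / 2^(level+1)`. This step is mandatory
#' before mapping nodes to physical frequency bands: in natural order the
#' high-pass decimations leave sub-bands interleaved.
#'
#' @param nodes A `wpd_nodes` list from [wpd_decompose()].
#' @return The same nodes sorted by `freq_index`.
#' @export
frequency_order <- function(nodes) {
  stopifnot(inherits(nodes, "wpd_nodes"))
  idx <- vapply(nodes, function(n) n$freq_index, integer(1))
  level <- nodes[[1]]$level
  if (length(nodes) != 2^level || !setequal(idx, seq_along(nodes) - 1L)) {
    stop("incomplete terminal node set: frequency indices must cover 0..2^level-1",
         call. = FALSE)
  }
  out <- nodes[order(idx)]
  attributes(out) <- attributes(nodes)
  out
}

#' @export
print.wpd_node <- function(x, ...) {
  cat(sprintf("<wpd_node> level %d, freq bin %d [%.4g, %.4g) Hz, %d coefficients\n",
              x$level, x$freq_index, x$freq_interval[1], x$freq_interval[2],
              length(x$coefficients)))
  invisible(x)
}

#' Clinical EEG frequency band definitions
#'
#' The conventional five-band partition of the EEG spectrum: delta below
#' 4 Hz, theta 4-8 Hz, alpha 8-13 Hz, beta 14-32 Hz, gamma above 32 Hz
#' (capped at Nyquist when used). The 13-14 Hz gap between alpha and beta
#' is inherited from the clinical convention and is resolved per node by
#' the maximal-overlap rule in [assign_bands()].
#'
#' @param gamma_hi Upper edge for gamma in Hz; defaults to `Inf` and is
#'   capped at Nyquist during band assignment.
#' @return A tibble with columns `band` (character, ascending frequency),
#'   `lo`, `hi` in Hz.
#' @export
eeg_bands <- function(gamma_hi = Inf) {
  tibble::tibble(
    band = band_names(),
    lo = c(0, 4, 8, 14, 32),
    hi = c(4, 8, 13, 32, gamma_hi)
  )
}

band_names <- function() c("delta", "theta", "alpha", "beta", "gamma")

#' Assign frequency-ordered node indices to EEG bands
#'
#' Each terminal node spans `fs / 2^(level+1)` Hz; it is assigned to the
#' band with which its interval overlaps most (after capping band edges at
#' Nyquist), ties broken toward the lower-frequency band. Nodes above every
#' band's range fall to gamma. A band entirely above Nyquist receives no
#' nodes.
#'
#' @param fs Sampling frequency in Hz.
#' @param level Decomposition depth.
#' @param bands Band definition table as from [eeg_bands()].
#' @return Named list `band -> integer vector of freq_index` (0-based),
#'   in band order.
#' @examples
#' assign_bands(fs = 64, level = 3)
#' @export
assign_bands <- function(fs, level, bands = eeg_bands()) {
  stopifnot(nrow(bands) > 0, all(bands$lo < bands$hi))
  nyquist <- fs / 2
  bin <- fs / 2^(level + 1)
  n_nodes <- 2^level
  lo <- bands$lo
  hi <- pmin(bands$hi, nyquist)
  assignment <- stats::setNames(vector("list", nrow(bands)), bands$band)
  for (k in seq_len(n_nodes) - 1) {
    node_lo <- k * bin
    node_hi <- (k + 1) * bin
    overlap <- pmax(0, pmin(node_hi, hi) - pmax(node_lo, lo))
    if (all(overlap <= 0)) {
      # node sits above every band's range: cap into the highest band
      target <- nrow(bands)
    } else {
      target <- which.max(overlap) # which.max takes the first (lower) band on ties
    }
    assignment[[target]] <- c(assignment[[target]], as.integer(k))
  }
  lapply(assignment, function(v) if (is.null(v)) integer(0) else v)
}

#' Automatic decomposition depth for band resolution
#'
#' The smallest level whose bin width `fs / 2^(level+1)` is at most
#' `max_bin_hz` (2 Hz by default), so that delta and theta occupy distinct
#' nodes: level 5 at 100 Hz, 6 at 200 Hz, 7 at 512 Hz.
#'
#' @param fs Sampling frequency in Hz.
#' @param max_bin_hz Maximum admissible node bandwidth in Hz.
#' @return Integer level >= 1.
#' @export
auto_wpd_level <- function(fs, max_bin_hz = 2) {
  stopifnot(fs > 0, max_bin_hz > 0)
  max(1L, as.integer(ceiling(log2(fs / max_bin_hz) - 1)))
}

#' Decompose an epoch into per-band wavelet coefficients
#'
#' Full sub-band stage: wavelet packet decomposition, frequency ordering,
#' node-to-band assignment, and concatenation of each band's node
#' coefficients in ascending frequency. With `level = "auto"` the depth is
#' chosen by [auto_wpd_level()] so the bin width is at most 2 Hz and
#' delta/theta are resolvable. A literal `level = 3` reproduces the
#' three-level binary tree (8 nodes) but cannot separate the low bands at
#' typical sampling rates, so it triggers a warning when the bin width
#' exceeds the narrowest band.
#'
#' @param x An `eeg_epoch`, `eeg_recording`, or numeric vector.
#' @param fs Sampling frequency (for numeric `x`).
#' @param wavelet Daubechies wavelet name; default `"db8"`.
#' @param level Integer depth or `"auto"` (default).
#' @param bands Band definition table as from [eeg_bands()].
#' @return Object of class `band_coefficients`: named list `band -> numeric
#'   coefficient vector` with attributes `assignment` (band -> freq_index
#'   map), `fs`, `level`, `wavelet`. A band lying entirely above Nyquist
#'   has a zero-length vector.
#' @examples
#' t <- seq(0, 30, by = 1 / 200)[-1]
#' bc <- extract_band_coefficients(sin(2 * pi * 10 * t), fs = 200)
#' names(which.max(vapply(bc, function(z) sum(z^2), numeric(1))))  # "alpha"
#' @export
extract_band_coefficients <- function(x, fs = NULL, wavelet = "db8",
                                      level = "auto", bands = eeg_bands()) {
  sig <- as_signal(x, fs)
  if (identical(level, "auto")) {
    level <- auto_wpd_level(sig$fs)
  } else {
    level <- as.integer(level)
    bin <- sig$fs / 2^(level + 1)
    narrowest <- min(bands$hi - bands$lo)
    if (bin > narrowest) {
      warning(sprintf(
        paste0("level %d gives %.3g Hz bins at fs = %g Hz, wider than the ",
               "narrowest band (%g Hz); adjacent bands will share nodes"),
        level, bin, sig$fs, narrowest), call. = FALSE)
    }
  }
  nodes <- frequency_order(wpd_decompose(sig$samples, sig$fs, wavelet, level))
  assignment <- assign_bands(sig$fs, level, bands)
  coef_by_band <- lapply(assignment, function(idx) {
    if (length(idx) == 0) return(numeric(0))
    # nodes are frequency-ordered, so freq_index k is element k + 1
    unlist(lapply(nodes[idx + 1L], function(n) n$coefficients), use.names = FALSE)
  })
  structure(coef_by_band, class = "band_coefficients",
            assignment = assignment, fs = sig$fs, level = level,
            wavelet = wavelet)
}

#' @export
print.band_coefficients <- function(x, ...) {
  cat(sprintf("<band_coefficients> %s, level %d, fs %g Hz\n",
              attr(x, "wavelet"), attr(x, "level"), attr(x, "fs")))
  for (b in names(x)) {
    cat(sprintf("  %-6s %5d coefficients (nodes %s)\n", b, length(x[[b]]),
                paste(attr(x, "assignment")[[b]], collapse = ",")))
  }
  invisible(x)
}
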