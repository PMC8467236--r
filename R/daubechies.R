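# Orthonormal Daubechies scaling (low-pass) filters, dbN = N vanishing
# moments, 2N taps. Values are the published extremal-phase coefficients
# normalized so that sum(h) = sqrt(2) and sum(h^2) = 1.
daubechies_filters <- list(
  db1 = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(0.48296291314453416, 0.8365163037378079, 0.2241438680420134,
          -0.12940952255126037),
  db4 = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
          -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
          0.0328830116668852, -0.010597401785069032),
  db6 = c(0.11154074335010947, 0.49462389039845306, 0.7511339080210954,
          0.31525035170919763, -0.22626469396543983, -0.12976686756726194,
          0.09750160558732304, 0.027522865530305727, -0.03158203931748603,
          0.0005538422011614961, 0.004777257510945511, -0.0010773010853084796),
  db8 = c(0.05441584224310401, 0.31287159091429995, 0.6756307362972898,
          0.5853546836542067, -0.015829105256349306, -0.2840155429615469,
          0.0004724845739132828, 0.12874742662047847, -0.017369301001807547,
          -0.044088253930794755, 0.013981027917398282, 0.008746094047405777,
          -0.004870352993451574, -0.00039174037337694705,
          0.0006754494064505693, -0.00011747678412476953),
  db10 = c(0.026670057900555554, 0.1881768000776915, 0.5272011889317256,
           0.6884590394536035, 0.2811723436605775, -0.24984642432731538,
           -0.19594627437737705, 0.12736934033579325, 0.09305736460357235,
           -0.07139414716639708, -0.029457536821875813, 0.033212674059341,
           0.0036065535669561697, -0.010733175483330575, 0.001395351747052901,
           0.001992405295185056, -0.0006858566949597116,
           -0.00011646685512928545, 9.358867032006959e-05,
           -1.3264202894521244e-05)
)

#' Quadrature filter pair for a Daubechies wavelet
#'
#' Returns the analysis low-pass (scaling) and high-pass (wavelet) filters
#' for `dbN`. The high-pass filter is the quadrature mirror
#' `g[n] = (-1)^n h[L - 1 - n]`.
#'
#' @param wavelet Wavelet name; one of `"db1"`, `"db2"`, `"db4"`, `"db6"`,
#'   `"db8"` (default), `"db10"`.
#' @return List with elements `lo`, `hi`, and `length`.
#' @keywords internal
wavelet_filter_pair <- function(wavelet = "db8") {
  h <- daubechies_filters[[wavelet]]
  if (is.null(h)) {
    stop(sprintf("unknown wavelet '%s'; available: %s", wavelet,
                 paste(names(daubechies_filters), collapse = ", ")),
         call. = FALSE)
  }
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)
  list(lo = h, hi = g, length = L)
}
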