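#' Measure the tallest peak of a spectrum
#'
#' Direct, model-free measurement of the tallest spectral line: peak position
#' (grid argmax), height, full width at half maximum (linear interpolation of
#' the two half-height crossings, reported in Hz), and numerically integrated
#' area on the ppm axis. Used to close the loop between simulated component
#' parameters and what the rendered spectrum actually shows.
#'
#' @param spec An `nmr_spectrum`.
#' @return A one-row tibble with columns `ppm`, `height`, `fwhm_hz`, `area`.
#' @export
measure_peak <- function(spec) {
  stopifnot(inherits(spec, "nmr_spectrum"))
  y <- spec$intensity
  x <- spec$ppm
  ih <- which.max(y)
  h <- y[ih]
  half <- h / 2
  sf <- spectrum_meta(spec)$spectrometer_freq
  cross <- function(i1, i2) {
    x[i1] + (half - y[i1]) * (x[i2] - x[i1]) / (y[i2] - y[i1])
  }
  below_l <- which(y[seq_len(ih - 1)] < half)
  below_r <- which(y[(ih + 1):length(y)] < half) + ih
  if (length(below_l) == 0 || length(below_r) == 0) {
    fwhm_hz <- NA_real_
  } else {
    il <- max(below_l)
    ir <- min(below_r)
    fwhm_hz <- abs(cross(il, il + 1) - cross(ir - 1, ir)) * sf
  }
  dppm <- abs(x[2] - x[1])
  tibble::tibble(ppm = x[ih], height = h, fwhm_hz = fwhm_hz,
                 area = sum(y) * dppm)
}
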