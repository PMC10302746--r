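#' Uniform prior box over Lorentzian component parameters
#'
#' Each component is parameterized by its area `M` (arbitrary units), its
#' chemical shift `omega` (ppm), and `beta`, the common logarithm of its full
#' width at half maximum in Hz. The prior is uniform over the box and zero
#' outside. The defaults are the ranges used for in-cell 19F spectra of
#' fluorinated H-Ras: M in \[0, 700\] a.u., omega in \[-62, -55\] ppm, beta in
#' \[1, 4\] (i.e. FWHM from 10 Hz to 10,000 Hz).
#'
#' @param M_range,omega_range,beta_range Length-2 numeric ranges.
#' @return A `prior_box` object (named list of ranges).
#' @export
prior_box <- function(M_range = c(0, 700), omega_range = c(-62, -55),
                      beta_range = c(1, 4)) {
  for (r in list(M_range, omega_range, beta_range)) {
    if (length(r) != 2 || !(r[1] < r[2])) {
      stop("Each prior range must be a length-2 increasing numeric vector.",
           call. = FALSE)
    }
  }
  structure(
    list(M_range = M_range, omega_range = omega_range, beta_range = beta_range),
    class = "prior_box"
  )
}

box_widths <- function(box) {
  c(M = diff(box$M_range), omega = diff(box$omega_range),
    beta = diff(box$beta_range))
}

box_lower <- function(box) {
  c(M = box$M_range[1], omega = box$omega_range[1], beta = box$beta_range[1])
}

#' Construct a component parameter set
#'
#' A parameter set is a tibble with one row per Lorentzian component and
#' columns `M` (area, a.u.), `omega` (shift, ppm) and `beta` (log10 FWHM in
#' Hz). Zero rows encode the pure-noise model (K = 0).
#'
#' @param M,omega,beta Equal-length numeric vectors.
#' @return A tibble of class `param_set`.
#' @export
param_set <- function(M = numeric(), omega = numeric(), beta = numeric()) {
  out <- tibble::tibble(M = as.numeric(M), omega = as.numeric(omega),
                        beta = as.numeric(beta))
  class(out) <- c("param_set", class(out))
  out
}

#' Evaluate one absorptive Lorentzian component
#'
#' The line is area-normalized: with FWHM `gamma = 10^beta / spectrometer_freq`
#' in ppm,
#' `f(x) = (M / pi) * (gamma / 2) / ((x - omega)^2 + (gamma / 2)^2)`,
#' so its integral over the ppm axis is `M` and its peak height is
#' `2 M / (pi * gamma)`.
#'
#' @param x ppm grid.
#' @param M Peak area (a.u.).
#' @param omega Chemical shift (ppm).
#' @param beta log10 of the FWHM in Hz.
#' @param spectrometer_freq Spectrometer frequency in MHz (> 0), used to
#'   convert the FWHM from Hz to ppm.
#' @return Intensities on `x`.
#' @export
lorentzian_component <- function(x, M, omega, beta, spectrometer_freq = 565.0) {
  if (spectrometer_freq <= 0) {
    stop("`spectrometer_freq` must be positive.", call. = FALSE)
  }
  half_gamma <- (10^beta / spectrometer_freq) / 2
  (M / pi) * half_gamma / ((x - omega)^2 + half_gamma^2)
}

#' Evaluate a Lorentzian mixture on a ppm grid
#'
#' The model spectrum is the elementwise sum of the component Lorentzians; an
#' empty parameter set (K = 0) gives the zero spectrum. The mixture is
#' invariant under permutation of the component rows.
#'
#' @param x ppm grid.
#' @param params A `param_set` (tibble with columns `M`, `omega`, `beta`).
#' @param spectrometer_freq Spectrometer frequency in MHz.
#' @return Intensities on `x`.
#' @export
mixture_spectrum <- function(x, params, spectrometer_freq = 565.0) {
  if (nrow(params) == 0) return(numeric(length(x)))
  as.numeric(cpp_mixture(x, params$M, params$omega, params$beta,
                         spectrometer_freq))
}

#' Gaussian log likelihood of a spectrum under a Lorentzian mixture
#'
#' The spectral noise is modelled as white Gaussian with known standard
#' deviation `sigma` (the plug-in estimate from the FID tail), so
#' `log L = sum_n \[-1/2 log(2 pi sigma^2) - (y_n - F(x_n))^2 / (2 sigma^2)\]`.
#'
#' @param spec An `nmr_spectrum` with a positive `noise_sigma`.
#' @param params A `param_set`.
#' @return Scalar log likelihood.
#' @export
log_likelihood <- function(spec, params) {
  sigma <- noise_sigma(spec)
  if (is.na(sigma) || sigma <= 0) {
    stop("`spec` must carry a positive `noise_sigma`.", call. = FALSE)
  }
  sf <- spectrum_meta(spec)$spectrometer_freq
  cpp_loglik(spec$ppm, spec$intensity, params$M, params$omega, params$beta,
             sf, sigma)
}

#' Log prior density of a parameter set under a uniform box
#'
#' Inside the box the density of each component is `1 / volume`, so the log
#' prior is `-K * log(volume)`; any parameter outside gives `-Inf`. K = 0
#' returns 0 (the empty product).
#'
#' @param params A `param_set`.
#' @param box A [prior_box()].
#' @return Scalar log prior (possibly `-Inf`).
#' @export
log_prior <- function(params, box = prior_box()) {
  if (nrow(params) == 0) return(0)
  inside <-
    params$M >= box$M_range[1] & params$M <= box$M_range[2] &
    params$omega >= box$omega_range[1] & params$omega <= box$omega_range[2] &
    params$beta >= box$beta_range[1] & params$beta <= box$beta_range[2]
  if (!all(inside)) return(-Inf)
  -nrow(params) * log(prod(box_widths(box)))
}
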