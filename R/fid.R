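#' Construct a raw FID object
#'
#' An `nmr_fid` holds a one-dimensional complex free induction decay together
#' with the acquisition metadata needed to place its Fourier transform on a
#' referenced ppm axis. The dwell time is `1 / (sweep_width * spectrometer_freq)`
#' seconds, so the full sweep in Hz is `sweep_width * spectrometer_freq`.
#'
#' @param points Complex vector of time-domain samples (arbitrary units).
#' @param spectrometer_freq Spectrometer (Larmor) frequency in MHz. The 19F
#'   preset used throughout is 565.0 MHz.
#' @param sweep_width Spectral width in ppm (preset 237).
#' @param group_delay Digital-filter group delay in samples; fractional values
#'   are allowed, must be >= 0.
#' @param reference_shift Chemical shift in ppm assigned to the carrier
#'   (centre of the spectrum). The trifluoroacetic-acid reference at
#'   -76.55 ppm is the documented 19F preset.
#' @param scans Number of summed transients (metadata only).
#'
#' @return An object of class `nmr_fid`.
#' @export
new_fid <- function(points, spectrometer_freq = 565.0, sweep_width = 237,
                    group_delay = 0, reference_shift = -76.55, scans = 1L) {
  if (!is.complex(points)) points <- as.complex(points)
  if (!is.numeric(spectrometer_freq) || spectrometer_freq <= 0) {
    stop("`spectrometer_freq` must be a positive number of MHz.", call. = FALSE)
  }
  if (!is.numeric(sweep_width) || sweep_width <= 0) {
    stop("`sweep_width` must be a positive number of ppm.", call. = FALSE)
  }
  if (!is.numeric(group_delay) || group_delay < 0) {
    stop("`group_delay` must be >= 0 samples.", call. = FALSE)
  }
  structure(
    list(
      points = points,
      n_points = length(points),
      spectrometer_freq = spectrometer_freq,
      sweep_width = sweep_width,
      group_delay = group_delay,
      reference_shift = reference_shift,
      scans = as.integer(scans)
    ),
    class = "nmr_fid"
  )
}

#' @export
print.nmr_fid <- function(x, ...) {
  cat(sprintf(
    "<nmr_fid> %d complex points | %.1f MHz | %.0f ppm sweep | dwell %.3f us\n",
    x$n_points, x$spectrometer_freq, x$sweep_width, dwell_time(x) * 1e6
  ))
  cat(sprintf(
    "  group delay %g, reference %.2f ppm, %d scan(s)\n",
    x$group_delay, x$reference_shift, x$scans
  ))
  invisible(x)
}

#' Dwell time of an FID in seconds
#'
#' @param fid An `nmr_fid`.
#' @return Sampling interval in seconds.
#' @export
dwell_time <- function(fid) {
  # sweep in Hz = sweep_width (ppm) * spectrometer_freq (MHz)
  1 / (fid$sweep_width * fid$spectrometer_freq)
}

# internal: time axis in seconds for each complex sample
fid_times <- function(fid) {
  (seq_len(fid$n_points) - 1) * dwell_time(fid)
}

# internal: frequency-domain linear phase ramp for a delay of `delay` samples.
# Positive `delay` shifts the signal later in time.
apply_fractional_delay <- function(points, delay) {
  n <- length(points)
  k <- seq_len(n) - 1
  kk <- ifelse(k < n / 2, k, k - n)
  spec <- stats::fft(points)
  spec <- spec * exp(-2i * pi * delay * kk / n)
  stats::fft(spec, inverse = TRUE) / n
}

#' Remove the digital-filter group delay from an FID
#'
#' Digitally filtered FIDs carry a leading artifact that displaces the
#' effective time origin by the group delay. This restores the time origin:
#' the integer part of the delay is undone by a circular sample shift and the
#' fractional part by a frequency-domain linear phase ramp. The length of the
#' FID is preserved (the displaced leading samples wrap to the noise tail).
#'
#' @param fid An `nmr_fid` with `group_delay >= 0`.
#' @return An `nmr_fid` of the same length with `group_delay = 0`.
#' @export
remove_digital_filter <- function(fid) {
  stopifnot(inherits(fid, "nmr_fid"))
  g <- fid$group_delay
  if (is.na(g) || g < 0) {
    stop("Invalid metadata: group delay must be >= 0 samples.", call. = FALSE)
  }
  if (g == 0) return(fid)
  pts <- fid$points
  g_int <- floor(g)
  g_frac <- g - g_int
  if (g_int > 0) {
    n <- length(pts)
    idx <- ((seq_len(n) - 1 + g_int) %% n) + 1
    pts <- pts[idx]
  }
  if (g_frac > 0) {
    pts <- apply_fractional_delay(pts, -g_frac)
  }
  out <- fid
  out$points <- pts
  out$group_delay <- 0
  out
}

# internal: inject a group delay (used by the simulator); exact inverse of
# remove_digital_filter for the same delay.
inject_group_delay <- function(fid, delay) {
  if (delay == 0) return(fid)
  pts <- fid$points
  g_int <- floor(delay)
  g_frac <- delay - g_int
  if (g_frac > 0) pts <- apply_fractional_delay(pts, g_frac)
  if (g_int > 0) {
    n <- length(pts)
    idx <- ((seq_len(n) - 1 - g_int) %% n) + 1
    pts <- pts[idx]
  }
  out <- fid
  out$points <- pts
  out$group_delay <- delay
  out
}

#' Truncate an FID and zero-fill it
#'
#' Retains the first `n_keep` complex points and pads with zeros to `n_total`
#' points. The defaults reproduce the preprocessing used for in-cell 19F
#' spectra: keep 4096 points (30.6 ms at the 565 MHz / 237 ppm preset) and
#' zero-fill to 8192.
#'
#' @param fid An `nmr_fid`.
#' @param n_keep Number of leading complex points to retain.
#' @param n_total Output length after zero-filling; must be >= `n_keep`.
#' @return An `nmr_fid` of `n_total` points.
#' @export
truncate_zero_fill <- function(fid, n_keep = 4096, n_total = 8192) {
  stopifnot(inherits(fid, "nmr_fid"))
  if (n_keep <= 0 || n_keep > fid$n_points) {
    stop(sprintf(
      "`n_keep` (%d) must be between 1 and the available %d points.",
      n_keep, fid$n_points
    ), call. = FALSE)
  }
  if (n_total < n_keep) {
    stop("`n_total` must be >= `n_keep`.", call. = FALSE)
  }
  pts <- c(fid$points[seq_len(n_keep)], complex(real = rep(0, n_total - n_keep)))
  out <- fid
  out$points <- pts
  out$n_points <- as.integer(n_total)
  out
}

#' Fourier-transform an FID into a referenced spectrum
#'
#' Applies an unnormalized discrete Fourier transform (no apodization), places
#' the result on a descending ppm axis centred at the reference shift, and
#' keeps the real (absorptive) part as the intensity. The axis spacing is
#' `sweep_width / n_points` ppm.
#'
#' @param fid A preprocessed `nmr_fid` (filter removed, truncated/zero-filled).
#' @param noise_sigma Optional spectral noise standard deviation to attach
#'   (see [estimate_noise_sigma()]).
#' @return An `nmr_spectrum`: a tibble with columns `ppm` (descending) and
#'   `intensity`, carrying `noise_sigma` and acquisition metadata as
#'   attributes.
#' @export
fid_to_spectrum <- function(fid, noise_sigma = NA_real_) {
  stopifnot(inherits(fid, "nmr_fid"))
  n <- fid$n_points
  raw <- stats::fft(fid$points)
  # reorder to frequencies (-n/2 .. n/2 - 1) * df
  half <- n %/% 2
  shifted <- c(raw[(half + 1):n], raw[1:half])
  freq_hz <- (seq_len(n) - 1 - half) / (n * dwell_time(fid))
  ppm <- fid$reference_shift + freq_hz / fid$spectrometer_freq
  ord <- rev(seq_len(n)) # descending ppm, NMR convention
  new_spectrum(
    ppm = ppm[ord],
    intensity = Re(shifted)[ord],
    noise_sigma = noise_sigma,
    meta = fid_meta(fid)
  )
}

fid_meta <- function(fid) {
  list(
    spectrometer_freq = fid$spectrometer_freq,
    sweep_width = fid$sweep_width,
    reference_shift = fid$reference_shift,
    scans = fid$scans
  )
}

#' Construct an `nmr_spectrum`
#'
#' A spectrum is a tibble of `ppm` and `intensity` with the spectral noise
#' standard deviation and the acquisition metadata attached as attributes.
#'
#' @param ppm Strictly monotonic ppm axis.
#' @param intensity Real intensities, same length as `ppm`.
#' @param noise_sigma Spectral noise standard deviation (a.u.).
#' @param meta List of acquisition metadata (at least `spectrometer_freq`).
#' @return A tibble of class `nmr_spectrum`.
#' @export
new_spectrum <- function(ppm, intensity, noise_sigma = NA_real_, meta = list()) {
  stopifnot(length(ppm) == length(intensity))
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0))) {
    stop("`ppm` must be strictly monotonic.", call. = FALSE)
  }
  out <- tibble::tibble(ppm = ppm, intensity = intensity)
  attr(out, "noise_sigma") <- noise_sigma
  attr(out, "meta") <- meta
  class(out) <- c("nmr_spectrum", class(out))
  out
}

#' Spectral noise standard deviation attached to a spectrum
#' @param spec An `nmr_spectrum`.
#' @return Numeric scalar (may be `NA` if never estimated).
#' @export
noise_sigma <- function(spec) attr(spec, "noise_sigma")

#' Acquisition metadata attached to a spectrum
#' @param spec An `nmr_spectrum`.
#' @return Named list.
#' @export
spectrum_meta <- function(spec) attr(spec, "meta")

#' Robust polynomial baseline correction
#'
#' Fits a polynomial of the given order to the baseline and subtracts it.
#' The fit is iteratively reweighted: points lying more than three running
#' standard deviations above the current fit are excluded (at most ten
#' refits), so that positive signal peaks do not drag the baseline up.
#'
#' @param spec An `nmr_spectrum`.
#' @param order Polynomial order (default 4).
#' @return A baseline-corrected `nmr_spectrum`.
#' @export
baseline_correct <- function(spec, order = 4) {
  stopifnot(inherits(spec, "nmr_spectrum"))
  n <- nrow(spec)
  if (order < 0) stop("`order` must be >= 0.", call. = FALSE)
  if (order >= n) {
    stop(sprintf("`order` (%d) must be smaller than the number of points (%d).",
                 order, n), call. = FALSE)
  }
  x <- scale_unit(spec$ppm)
  y <- spec$intensity
  X <- stats::poly(x, degree = max(order, 1), raw = TRUE)
  if (order == 0) X <- X[, 0, drop = FALSE]
  keep <- rep(TRUE, n)
  fit <- rep(mean(y), n)
  for (iter in seq_len(10)) {
    co <- stats::lm.fit(cbind(1, X[keep, , drop = FALSE]), y[keep])$coefficients
    co[is.na(co)] <- 0
    fit <- drop(cbind(1, X) %*% co)
    res <- y - fit
    s <- stats::sd(res[keep])
    if (!is.finite(s) || s == 0) break
    keep_new <- res <= 3 * s
    if (identical(keep_new, keep)) break
    keep <- keep_new
  }
  out <- spec
  out$intensity <- y - fit
  out
}

scale_unit <- function(x) {
  r <- range(x)
  if (diff(r) == 0) return(x * 0)
  (x - mean(r)) / (diff(r) / 2)
}

#' Estimate the spectral noise standard deviation from the FID tail
#'
#' The thermal-noise level is estimated from the part of the FID after
#' `tail_start` seconds (default 30.6 ms, where all signals of interest have
#' decayed). If the per-quadrature time-domain standard deviation of the tail
#' is `sigma_t` and the first `n_keep` points are retained before the
#' unnormalized transform, each spectral bin's real part has variance
#' `n_keep * sigma_t^2`; the returned value is `sqrt(n_keep) * sigma_t`.
#'
#' @param fid An `nmr_fid` longer than `tail_start` seconds.
#' @param tail_start Start of the noise tail in seconds.
#' @param n_keep Number of points retained for the transform (default 4096).
#' @return Spectral-domain noise standard deviation (a.u.).
#' @export
estimate_noise_sigma <- function(fid, tail_start = 0.0306, n_keep = 4096) {
  stopifnot(inherits(fid, "nmr_fid"))
  dt <- dwell_time(fid)
  first <- floor(tail_start / dt) + 1
  n_tail <- fid$n_points - first + 1
  if (n_tail < 64) {
    stop(sprintf(
      "FID tail after %.4f s has %d points; at least 64 are needed. Acquire at least %.4f s.",
      tail_start, max(n_tail, 0), tail_start + 64 * dt
    ), call. = FALSE)
  }
  tail_pts <- fid$points[first:fid$n_points]
  # pooled per-quadrature SD about the mean of each quadrature
  v <- (stats::var(Re(tail_pts)) + stats::var(Im(tail_pts))) / 2
  sqrt(n_keep * v)
}

#' Exponential apodization for display
#'
#' Multiplies the FID by `exp(-pi * lb * t)`, broadening every Lorentzian line
#' by `lb` Hz. Used only for visual overlays of model and observed spectra;
#' the fitted data are never apodized.
#'
#' @param fid An `nmr_fid`.
#' @param lb Line-broadening factor in Hz (default 200).
#' @return The apodized `nmr_fid`.
#' @export
apodize <- function(fid, lb = 200) {
  stopifnot(inherits(fid, "nmr_fid"))
  if (lb < 0) stop("`lb` must be >= 0 Hz.", call. = FALSE)
  if (lb == 0) return(fid)
  out <- fid
  out$points <- fid$points * exp(-pi * lb * fid_times(fid))
  out
}

#' Preprocess an FID into the spectrum used for fitting
#'
#' Chains the standard preprocessing: digital-filter removal, truncation to
#' `n_keep` points and zero-filling to `n_total`, Fourier transform (no
#' apodization), polynomial baseline correction, and tail-based noise
#' estimation. The result carries the estimated `noise_sigma`.
#'
#' @param fid A raw `nmr_fid`.
#' @param n_keep,n_total Truncation/zero-fill lengths (defaults 4096/8192).
#' @param baseline_order Polynomial order for baseline correction (default 4);
#'   use `NA` to skip.
#' @param tail_start Start of the noise tail in seconds (default 30.6 ms).
#' @return An `nmr_spectrum` ready for deconvolution.
#' @export
preprocess_fid <- function(fid, n_keep = 4096, n_total = 8192,
                           baseline_order = 4, tail_start = 0.0306) {
  fid <- remove_digital_filter(fid)
  sigma <- estimate_noise_sigma(fid, tail_start = tail_start, n_keep = n_keep)
  fid_cut <- truncate_zero_fill(fid, n_keep = n_keep, n_total = n_total)
  spec <- fid_to_spectrum(fid_cut, noise_sigma = sigma)
  if (!is.na(baseline_order)) spec <- baseline_correct(spec, order = baseline_order)
  spec
}
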