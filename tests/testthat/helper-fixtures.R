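# Shared fixtures: all synthetic, generated at test time.

# default 19F acquisition at simulator scale
test_acq <- function(...) acquisition_params(...)

# a reduced deconvolution problem: N = 2048 spectrum (keep 1024 of 4096
# simulated points), broad lines only, so tempered runs stay fast
selection_spec <- function(components, snr, seed) {
  sigma_t <- if (nrow(components) > 0) {
    selection_sigma_t(components, snr)
  } else {
    1
  }
  acq <- acquisition_params(n_points = 4096, noise_sigma_t = sigma_t)
  fid <- simulate_fid(components, acq, seed = seed)
  preprocess_fid(fid, n_keep = 1024, n_total = 2048,
                 tail_start = 1024 / (237 * 565))
}

# per-quadrature time-domain noise SD giving the requested spectral SNR for
# the reduced problem (tallest rendered peak height over spectral noise SD)
selection_sigma_t <- function(components, snr, n_keep = 1024) {
  acq <- acquisition_params(n_points = 4 * n_keep, noise_sigma_t = 0)
  fid <- simulate_fid(components, acq)
  spec <- fid_to_spectrum(truncate_zero_fill(fid, n_keep, 2 * n_keep))
  max(spec$intensity) / (snr * sqrt(n_keep))
}

selection_ladder <- function() build_ladder(8, 0.01)

selection_cfg <- function() {
  chain_config(6000, 3000, 3, n_chains = 5, max_outliers = 2)
}

# the reduced evidence-oracle problem: N = 256 spectrum, one wide line,
# low SNR, prior box restricted to wide lines so the geometric ladder
# resolves the thermodynamic integrand
oracle_problem <- function(seed = 11) {
  acq <- acquisition_params(n_points = 1024, noise_sigma_t = 15 / sqrt(128))
  comp <- data.frame(area = 150, shift = -58.5, fwhm = 3000)
  fid <- simulate_fid(comp, acq, seed = seed)
  spec <- preprocess_fid(fid, n_keep = 128, n_total = 256, tail_start = 0.002)
  list(spec = spec, box = prior_box(beta_range = c(3, 3.7)))
}

# independent oracle: -log evidence by midpoint-rule quadrature over the
# prior box, written against the Lorentzian formula directly (no reuse of
# the package's mixture code)
grid_neg_log_evidence <- function(spec, box, n_grid = 120) {
  y <- spec$intensity
  x <- spec$ppm
  sf <- spectrum_meta(spec)$spectrometer_freq
  sig <- noise_sigma(spec)
  mid <- function(r, n) r[1] + (seq_len(n) - 0.5) * diff(r) / n
  Ms <- mid(box$M_range, n_grid)
  Ws <- mid(box$omega_range, n_grid)
  Bs <- mid(box$beta_range, n_grid)
  lconst <- -length(y) / 2 * log(2 * pi * sig^2)
  yy <- sum(y * y)
  ll <- array(NA_real_, c(n_grid, n_grid, n_grid))
  for (iw in seq_len(n_grid)) {
    for (ib in seq_len(n_grid)) {
      hg <- 10^Bs[ib] / sf / 2
      L <- (1 / pi) * hg / ((x - Ws[iw])^2 + hg^2)
      a <- sum(y * L)
      b <- sum(L * L)
      ll[, iw, ib] <- lconst - (yy - 2 * Ms * a + Ms^2 * b) / (2 * sig^2)
    }
  }
  m <- max(ll)
  -(m + log(mean(exp(ll - m)))) # mean over cells = (1/V) * integral
}

# multiset fingerprint of each draw's component parameter triples
draw_multisets <- function(draw_matrix, K) {
  apply(draw_matrix, 1, function(r) {
    trip <- matrix(r, ncol = 3) # rows = components (M, omega, beta)
    paste(sort(apply(round(trip, 12), 1, paste, collapse = ",")),
          collapse = "|")
  })
}

# small synthetic posterior objects built directly, no MCMC needed
fake_posterior <- function(draws, log_posterior = NULL, K = ncol(draws) / 3,
                           box = prior_box()) {
  colnames(draws) <- nmrdecon:::theta_names(K)
  if (is.null(log_posterior)) log_posterior <- rep(0, nrow(draws))
  structure(
    list(draws = draws, log_posterior = log_posterior,
         log_lik = log_posterior, K = K, box = box,
         meta = list(spectrometer_freq = 565), seed = 1L),
    class = "posterior_draws"
  )
}

# two clean well-separated components with per-draw label scrambling
scrambled_two_component <- function(n = 500, seed = 10) {
  set.seed(seed)
  clean <- cbind(rnorm(n, 100, 3), rnorm(n, 400, 3),   # M
                 rnorm(n, -60, 0.05), rnorm(n, -56, 0.05), # omega
                 rnorm(n, 1.5, 0.02), rnorm(n, 3.0, 0.02)) # beta
  swap <- sample(c(TRUE, FALSE), n, replace = TRUE)
  scram <- clean
  scram[swap, ] <- clean[swap, c(2, 1, 4, 3, 6, 5)]
  list(clean = clean, scrambled = scram, swap = swap)
}

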