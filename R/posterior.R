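#' Resolve label switching by anchor-based relabeling
#'
#' The mixture posterior is K!-fold symmetric under permutation of component
#' labels, so marginal summaries of "component k" are meaningless until draws
#' are reordered consistently. This implements an anchored scheme: an initial
#' anchor parameter set is picked at random from the draws; then, repeatedly,
#' (a) each draw's components are permuted to minimize the standardized
#' Euclidean distance to the anchor (coordinates M, omega, beta each scaled
#' by their standard deviation over all draws and components, computed once
#' from the unrelabeled draws), and (b) the anchor is replaced by the
#' component-wise mean of the relabeled draws. Iteration stops when no draw
#' changes permutation, or after `max_iter` rounds. Each draw is only ever
#' permuted, so per-draw parameter multisets are preserved exactly.
#'
#' @param samples A `posterior_draws` object.
#' @param seed Seed for the random anchor choice.
#' @param max_iter Maximum relabeling iterations (default 20).
#' @return The relabeled `posterior_draws`.
#' @export
relabel_draws <- function(samples, seed = 1L, max_iter = 20) {
  stopifnot(inherits(samples, "posterior_draws"))
  K <- samples$K
  if (K == 1) return(samples)
  draws <- samples$draws
  T_n <- nrow(draws)
  # per-dimension scales pooled over draws and components, held fixed
  scales <- vapply(c("M", "omega", "beta"), function(p) {
    s <- stats::sd(as.vector(draws[, paste0(p, "_", seq_len(K))]))
    if (!is.finite(s) || s == 0) {
      warning(sprintf("Zero variance in dimension `%s`; scaling by 1.", p))
      s <- 1
    }
    s
  }, numeric(1))

  perms <- perm_matrix(K)
  n_perm <- nrow(perms)

  arr <- array(draws, dim = c(T_n, K, 3)) # [draw, component, (M, omega, beta)]
  set.seed(seed)
  anchor <- arr[sample.int(T_n, 1), , , drop = FALSE]
  anchor <- matrix(anchor, nrow = K, ncol = 3)

  assignment <- rep(1L, T_n)
  for (iter in seq_len(max_iter)) {
    # cost[t, p] = squared standardized distance of draw t under permutation p
    cost <- matrix(0, T_n, n_perm)
    for (p in seq_len(n_perm)) {
      for (k in seq_len(K)) {
        src <- perms[p, k] # draw component placed at anchor slot k
        for (dname in 1:3) {
          cost[, p] <- cost[, p] +
            ((arr[, src, dname] - anchor[k, dname]) / scales[dname])^2
        }
      }
    }
    new_assignment <- max.col(-cost, ties.method = "first")
    changed <- !identical(new_assignment, assignment)
    assignment <- new_assignment
    relabeled <- arr
    for (p in seq_len(n_perm)) {
      sel <- assignment == p
      if (!any(sel)) next
      relabeled[sel, , ] <- arr[sel, perms[p, ], , drop = FALSE]
    }
    anchor <- matrix(apply(relabeled, c(2, 3), mean), nrow = K)
    if (!changed && iter > 1) break
  }

  out <- samples
  new_draws <- matrix(relabeled, nrow = T_n)
  colnames(new_draws) <- theta_names(K)
  # array layout is [draw, component, dim]; theta_names layout matches
  out$draws <- new_draws
  out$relabel_iterations <- iter
  out
}

# all permutations of 1..K as rows
perm_matrix <- function(K) {
  if (K == 1) return(matrix(1L, 1, 1))
  sub <- perm_matrix(K - 1)
  out <- matrix(0L, 0, K)
  for (pos in seq_len(K)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], K,
                   sub[, seq(pos, K - 1)[seq_len(K - pos)], drop = FALSE])
    out <- rbind(out, block)
  }
  colnames(out) <- NULL
  out
}

#' Maximum a posteriori estimate from retained draws
#'
#' Returns the retained draw with the largest unnormalized posterior density.
#' Ties are broken by the earliest draw index.
#'
#' @param samples A `posterior_draws` object (ideally relabeled).
#' @return A `param_set` tibble with `K` rows plus columns `fwhm_hz`
#'   (`10^beta`) and `component`.
#' @export
map_estimate <- function(samples) {
  stopifnot(inherits(samples, "posterior_draws"), nrow(samples$draws) >= 1)
  i <- which.max(samples$log_posterior)
  row <- samples$draws[i, ]
  K <- samples$K
  out <- param_set(M = row[seq_len(K)], omega = row[K + seq_len(K)],
                   beta = row[2 * K + seq_len(K)])
  out$fwhm_hz <- 10^out$beta
  out$component <- seq_len(K)
  attr(out, "map_index") <- i
  attr(out, "log_posterior") <- samples$log_posterior[i]
  out
}

#' Percentile credible intervals and MAP summary per component
#'
#' For each component and parameter, reports the MAP value together with the
#' equal-tailed percentile credible interval of the relabeled draws. The
#' linewidth is additionally reported in Hz: since `x -> 10^x` is monotone,
#' percentile endpoints of FWHM are the transformed endpoints of `beta`.
#'
#' @param samples A relabeled `posterior_draws` object with at least 40 draws.
#' @param level Credible level in percent (default 95).
#' @return A `signal_summary` tibble with columns `component`, `parameter`
#'   (`M`, `omega`, `beta`, `fwhm_hz`), `map`, `lower`, `upper`, `level`.
#' @export
credible_intervals <- function(samples, level = 95) {
  stopifnot(inherits(samples, "posterior_draws"))
  if (nrow(samples$draws) < 40) {
    stop("At least 40 retained draws are required for percentile intervals.",
         call. = FALSE)
  }
  K <- samples$K
  probs <- c((100 - level) / 200, 1 - (100 - level) / 200)
  map <- map_estimate(samples)
  rows <- purrr::map_dfr(seq_len(K), function(k) {
    cols <- c(M = paste0("M_", k), omega = paste0("omega_", k),
              beta = paste0("beta_", k))
    qs <- lapply(cols, function(cn) {
      stats::quantile(samples$draws[, cn], probs = probs, names = FALSE,
                      type = 7)
    })
    tibble::tibble(
      component = k,
      parameter = c("M", "omega", "beta", "fwhm_hz"),
      map = c(map$M[k], map$omega[k], map$beta[k], map$fwhm_hz[k]),
      lower = c(qs$M[1], qs$omega[1], qs$beta[1], 10^qs$beta[1]),
      upper = c(qs$M[2], qs$omega[2], qs$beta[2], 10^qs$beta[2]),
      level = level
    )
  })
  class(rows) <- c("signal_summary", class(rows))
  rows
}

#' Render the MAP model spectrum over the observed spectrum
#'
#' Reconstructs a noise-free model FID from the MAP parameter set, applies the
#' display apodization (default 200 Hz exponential broadening) to both the
#' model FID and the observed FID, transforms both with the same
#' truncation/zero-fill settings, and returns aligned curves for plotting.
#' The apodization is display-only: it broadens every Lorentzian by `lb` Hz
#' but is never used in fitting.
#'
#' @param map_params A `param_set` (e.g. from [map_estimate()]).
#' @param fid_observed The observed `nmr_fid` (after digital-filter removal).
#' @param lb Display line broadening in Hz (default 200).
#' @param n_keep,n_total Truncation/zero-fill settings (defaults 4096/8192).
#' @param baseline_order Baseline order applied to the observed spectrum.
#' @return A tibble with columns `ppm`, `observed`, `model`.
#' @export
render_map_overlay <- function(map_params, fid_observed, lb = 200,
                               n_keep = 4096, n_total = 8192,
                               baseline_order = 4) {
  stopifnot(inherits(fid_observed, "nmr_fid"))
  acq <- acquisition_params(
    spectrometer_freq = fid_observed$spectrometer_freq,
    sweep_width = fid_observed$sweep_width,
    n_points = fid_observed$n_points,
    reference_shift = fid_observed$reference_shift,
    noise_sigma_t = 0
  )
  comp <- tibble::tibble(area = map_params$M, shift = map_params$omega,
                         fwhm = 10^map_params$beta)
  model_fid <- simulate_fid(comp, acq)
  prep <- function(f) {
    f <- apodize(f, lb = lb)
    f <- truncate_zero_fill(f, n_keep = n_keep, n_total = n_total)
    fid_to_spectrum(f)
  }
  model_spec <- prep(model_fid)
  obs_spec <- prep(fid_observed)
  if (!is.na(baseline_order)) {
    obs_spec <- baseline_correct(obs_spec, order = baseline_order)
  }
  tibble::tibble(ppm = obs_spec$ppm, observed = obs_spec$intensity,
                 model = model_spec$intensity)
}
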