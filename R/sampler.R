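#' Geometric inverse-temperature ladder
#'
#' Builds the ladder `0 = beta_0 < beta_1 < ... < beta_J = 1` used for
#' thermodynamic integration. For `j >= 1` the values are geometric,
#' `beta_j = beta1^((J - j) / (J - 1))`, so the consecutive ratio
#' `beta_{j-1} / beta_j` is constant (0.9006 for the defaults `J = 45`,
#' `beta1 = 0.01`, giving 46 ladder values in total) and `beta_J` is exactly 1.
#'
#' @param J Index of the top temperature (number of positive rungs).
#' @param beta1 First positive inverse temperature, in (0, 1].
#' @return Numeric vector of `J + 1` inverse temperatures starting at 0.
#' @export
build_ladder <- function(J = 45, beta1 = 0.01) {
  if (J < 1) stop("`J` must be >= 1.", call. = FALSE)
  if (!is.numeric(beta1) || beta1 <= 0 || beta1 > 1) {
    stop("`beta1` must be in (0, 1].", call. = FALSE)
  }
  if (J == 1) return(c(0, 1))
  betas <- beta1^((J - seq_len(J)) / (J - 1))
  ladder <- c(0, betas)
  stopifnot(all(diff(ladder) > 0), ladder[1] == 0,
            abs(ladder[length(ladder)] - 1) < 1e-9)
  ladder
}

#' Number of retained MCMC samples for a chain configuration
#'
#' @param total_steps,burn_in,thinning Chain settings; `burn_in < total_steps`
#'   and `thinning >= 1`.
#' @return `floor((total_steps - burn_in) / thinning)`.
#' @export
retained_samples <- function(total_steps, burn_in, thinning) {
  stopifnot(burn_in < total_steps, thinning >= 1)
  floor((total_steps - burn_in) / thinning)
}

#' Chain configuration
#'
#' Bundles the MCMC settings used by the tempered and posterior runs.
#'
#' @param total_steps,burn_in,thinning Per-chain step counts.
#' @param n_chains Number of independent chains per (K, beta).
#' @param max_outliers Upper bound on chains removable by the generalized ESD
#'   screen; must be `< n_chains`.
#' @return A `chain_config` list.
#' @export
chain_config <- function(total_steps = 20000, burn_in = 10000, thinning = 10,
                         n_chains = 5, max_outliers = 2) {
  stopifnot(burn_in < total_steps, thinning >= 1, max_outliers < n_chains)
  structure(
    list(total_steps = total_steps, burn_in = burn_in, thinning = thinning,
         n_chains = n_chains, max_outliers = max_outliers),
    class = "chain_config"
  )
}

#' Named run profiles
#'
#' `"paper"` is the full-scale protocol for production spectra: 46-rung ladder
#' (`J = 45`, `beta1 = 0.01`), 19 chains with at most 9 excludable as
#' outliers, 400,000 tempered steps (burn-in 200,000, thinning 100, so 2000
#' retained per chain) and a 100,050,000-step posterior run (burn-in 50,000,
#' thinning 200, so 500,000 retained). `"desk"` is a scaled-down profile for
#' interactive work and testing: `J = 12`, 5 chains (at most 2 excluded),
#' 20,000 tempered steps (burn-in 10,000, thinning 10) and a 60,000-step
#' posterior run (burn-in 10,000, thinning 25, 2000 retained).
#'
#' @param name `"desk"` or `"paper"`.
#' @return A list with elements `ladder`, `tempered` and `posterior`.
#' @export
run_profile <- function(name = c("desk", "paper")) {
  name <- match.arg(name)
  if (name == "paper") {
    list(
      name = "paper",
      ladder = build_ladder(J = 45, beta1 = 0.01),
      tempered = chain_config(400000, 200000, 100, n_chains = 19,
                              max_outliers = 9),
      posterior = chain_config(100050000, 50000, 200, n_chains = 1,
                               max_outliers = 0)
    )
  } else {
    list(
      name = "desk",
      ladder = build_ladder(J = 12, beta1 = 0.01),
      tempered = chain_config(20000, 10000, 10, n_chains = 5, max_outliers = 2),
      posterior = chain_config(60000, 10000, 25, n_chains = 1, max_outliers = 0)
    )
  }
}

# internal: deterministic sub-seed derivation so any (K, beta, chain) sub-run
# is reproducible in isolation. Kept below 2^31.
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master)
  for (i in idx) s <- (s * 69069 + i * 1234567 + 97) %% 2147483629
  as.integer(s)
}

# internal: draw n i.i.d. parameter sets uniformly from the prior box,
# returned as an n x 3K matrix (M_1..M_K, omega_1..omega_K, beta_1..beta_K)
draw_prior_matrix <- function(n, K, box) {
  lo <- box_lower(box)
  w <- box_widths(box)
  m <- matrix(stats::runif(n * 3 * K), nrow = n)
  for (k in seq_len(K)) {
    m[, k] <- lo["M"] + w["M"] * m[, k]
    m[, K + k] <- lo["omega"] + w["omega"] * m[, K + k]
    m[, 2 * K + k] <- lo["beta"] + w["beta"] * m[, 2 * K + k]
  }
  colnames(m) <- theta_names(K)
  m
}

theta_names <- function(K) {
  c(paste0("M_", seq_len(K)), paste0("omega_", seq_len(K)),
    paste0("beta_", seq_len(K)))
}

# internal: log likelihood for rows of a theta matrix
loglik_matrix <- function(spec, theta, K) {
  sf <- spectrum_meta(spec)$spectrometer_freq
  sigma <- noise_sigma(spec)
  apply(theta, 1, function(row) {
    cpp_loglik(spec$ppm, spec$intensity, row[seq_len(K)],
               row[K + seq_len(K)], row[2 * K + seq_len(K)], sf, sigma)
  })
}

# internal: random chain initialization — the best of `init_pool` i.i.d. prior
# draws under the tempered target beta * log L (the prior term is constant in
# the box). A pool of 1 is a plain uniform start.
draw_chain_init <- function(spec, K, box, beta, init_pool) {
  pool <- draw_prior_matrix(max(init_pool, 1), K, box)
  if (init_pool <= 1 || beta == 0) return(drop(pool[1, ]))
  ll <- loglik_matrix(spec, pool, K)
  pool[which.max(beta * ll), ]
}

#' Tempered MCMC over an inverse-temperature ladder
#'
#' For each positive rung of the ladder, runs `n_chains` independent adaptive
#' random-walk Metropolis chains targeting `prior(theta) * likelihood^beta`,
#' each started from its own uniform draw inside the prior box. At `beta = 0`
#' the target is the prior itself, so retained samples are drawn i.i.d. from
#' the box instead of by MCMC. Per-chain means of the log likelihood over the
#' retained samples are recorded for thermodynamic integration.
#'
#' @param spec An `nmr_spectrum` with a positive `noise_sigma`.
#' @param K Number of Lorentzian components (>= 1; K = 0 needs no sampling).
#' @param ladder Inverse-temperature ladder from [build_ladder()].
#' @param cfg A [chain_config()].
#' @param box A [prior_box()].
#' @param seed Master seed; sub-seeds per (beta, chain) are derived
#'   deterministically.
#' @param keep_draws Ladder values (numeric) whose retained draws should be
#'   kept in the result (default: only `beta = 1`).
#' @param init_pool Size of the pool of i.i.d. prior draws from which each
#'   chain's start is picked (the best under the tempered target); 1 gives a
#'   plain uniform start.
#' @return A `tempered_run` list with elements `mean_loglik` (tibble with
#'   columns `beta_index`, `beta`, `chain`, `mean_loglik`, `accept_rate`),
#'   `draws` (named list of retained-draw matrices for kept rungs, rows pooled
#'   over chains), `K`, `ladder`, and `cfg`.
#' @export
sample_tempered <- function(spec, K, ladder, cfg, box = prior_box(),
                            seed = 1L, keep_draws = 1, init_pool = 100) {
  stopifnot(inherits(spec, "nmr_spectrum"), K >= 1)
  sigma <- noise_sigma(spec)
  if (is.na(sigma) || sigma <= 0) {
    stop("`spec` must carry a positive `noise_sigma`.", call. = FALSE)
  }
  sf <- spectrum_meta(spec)$spectrometer_freq
  lo <- rep(box_lower(box), each = K)
  up <- lo + rep(box_widths(box), each = K)
  n_keep <- retained_samples(cfg$total_steps, cfg$burn_in, cfg$thinning)

  rows <- list()
  draws_kept <- list()
  for (j in seq_along(ladder)) {
    beta_j <- ladder[j]
    if (beta_j == 0) {
      # exact i.i.d. prior draws: one pooled set, no chain structure needed
      set.seed(derive_seed(seed, K, j, 0L))
      theta0 <- draw_prior_matrix(n_keep, K, box)
      ll0 <- loglik_matrix(spec, theta0, K)
      rows[[length(rows) + 1]] <- tibble::tibble(
        beta_index = j - 1L, beta = 0, chain = seq_len(cfg$n_chains),
        mean_loglik = mean(ll0), accept_rate = 1
      )
      if (any(abs(keep_draws - 0) < 1e-12)) {
        draws_kept[[format_beta(0)]] <- theta0
      }
      next
    }
    chain_draws <- vector("list", cfg$n_chains)
    for (ch in seq_len(cfg$n_chains)) {
      set.seed(derive_seed(seed, K, j, ch))
      init <- draw_chain_init(spec, K, box, beta_j, init_pool)
      res <- cpp_am_chain(spec$ppm, spec$intensity, K, sf, sigma, beta_j,
                          lo, up, init, cfg$total_steps, cfg$burn_in,
                          cfg$thinning)
      rows[[length(rows) + 1]] <- tibble::tibble(
        beta_index = j - 1L, beta = beta_j, chain = ch,
        mean_loglik = mean(res$loglik), accept_rate = res$accept_rate
      )
      chain_draws[[ch]] <- res$draws
    }
    if (any(abs(keep_draws - beta_j) < 1e-12)) {
      pooled <- do.call(rbind, chain_draws)
      colnames(pooled) <- theta_names(K)
      draws_kept[[format_beta(beta_j)]] <- pooled
    }
  }

  structure(
    list(
      mean_loglik = dplyr::bind_rows(rows),
      draws = draws_kept,
      K = K, ladder = ladder, cfg = cfg, seed = seed
    ),
    class = "tempered_run"
  )
}

format_beta <- function(beta) as.character(signif(beta, 10))

#' Generalized extreme Studentized deviate (gESD) screen
#'
#' Two-sided gESD test for up to `max_outliers` outliers among per-chain
#' statistics (here, retained-sample means of the log likelihood). At each of
#' `max_outliers` rounds the most extreme remaining value is removed if its
#' Studentized deviate exceeds the round's critical value; the surviving
#' indices are returned. Never removes more than `max_outliers` values.
#'
#' @param x Numeric vector of per-chain statistics (length >= 3).
#' @param max_outliers Maximum number of removable values (default 9, the
#'   production setting for 19 chains).
#' @param alpha Significance level of the test (default 0.05).
#' @return Integer vector of indices into `x` that survive the screen.
#' @export
exclude_outlier_chains <- function(x, max_outliers = 9, alpha = 0.05) {
  n <- length(x)
  if (n < 3) stop("At least 3 values are needed for the gESD test.",
                  call. = FALSE)
  stopifnot(max_outliers < n)
  if (max_outliers == 0) return(seq_len(n))
  keep <- seq_len(n)
  candidates <- integer()
  removed_at <- integer()
  work <- x
  idx <- seq_len(n)
  n_signif <- 0L
  for (i in seq_len(max_outliers)) {
    m <- mean(work)
    s <- stats::sd(work)
    if (!is.finite(s) || s == 0) break
    dev <- abs(work - m)
    worst <- which.max(dev)
    R_i <- dev[worst] / s
    ni <- length(work)
    p <- 1 - alpha / (2 * ni)
    t_crit <- stats::qt(p, df = ni - 2)
    lambda_i <- (ni - 1) * t_crit / sqrt((ni - 2 + t_crit^2) * ni)
    candidates <- c(candidates, idx[worst])
    if (R_i > lambda_i) n_signif <- i
    work <- work[-worst]
    idx <- idx[-worst]
    if (length(work) < 3) break
  }
  if (n_signif > 0) keep <- setdiff(keep, candidates[seq_len(n_signif)])
  keep
}

#' Thermodynamic-integration Bayes free energy
#'
#' The Bayes free energy is minus the log model evidence,
#' `F(K) = -integral_0^1 E_beta[log L] d beta`, approximated by the
#' trapezoidal rule over the ladder. The per-rung expectations are the
#' equal-weight means over chains that survive the gESD screen; the
#' `beta = 0` endpoint uses exact i.i.d. prior draws. For K = 0 the model has
#' no parameters, so `F(0) = -log L(D | zero model)` in closed form (use
#' [free_energy_k0()]).
#'
#' @param run A `tempered_run` from [sample_tempered()].
#' @param alpha Significance level for the gESD chain screen.
#' @return A list with `free_energy`, `by_rung` (tibble with pooled
#'   expectations), and `excluded` (list of excluded chain indices per rung).
#' @export
ti_free_energy <- function(run, alpha = 0.05) {
  stopifnot(inherits(run, "tempered_run"))
  ml <- run$mean_loglik
  betas <- run$ladder
  max_out <- run$cfg$max_outliers
  expectations <- numeric(length(betas))
  excluded <- vector("list", length(betas))
  for (j in seq_along(betas)) {
    sub <- ml[ml$beta_index == j - 1L, ]
    vals <- sub$mean_loglik
    if (betas[j] == 0 || max_out == 0 || length(vals) < 3) {
      kept <- seq_along(vals)
    } else {
      kept <- exclude_outlier_chains(vals, max_outliers = max_out,
                                     alpha = alpha)
    }
    expectations[j] <- mean(vals[kept])
    excluded[[j]] <- setdiff(seq_along(vals), kept)
  }
  if (any(!is.finite(expectations))) {
    stop("Non-finite per-temperature expectations at rung(s): ",
         paste(which(!is.finite(expectations)) - 1, collapse = ", "),
         call. = FALSE)
  }
  f <- -sum(diff(betas) * (utils::head(expectations, -1) +
                             utils::tail(expectations, -1)) / 2)
  list(
    free_energy = f,
    by_rung = tibble::tibble(beta = betas, mean_loglik = expectations,
                             n_excluded = lengths(excluded)),
    excluded = excluded
  )
}

#' Free energy of the pure-noise model (K = 0)
#'
#' The zero-component model has no parameters, so its evidence is the
#' likelihood itself and
#' `F(0) = -sum_n [ -1/2 log(2 pi sigma^2) - y_n^2 / (2 sigma^2) ]`.
#'
#' @param spec An `nmr_spectrum` with positive `noise_sigma`.
#' @return Scalar free energy.
#' @export
free_energy_k0 <- function(spec) {
  -log_likelihood(spec, param_set())
}

#' Posterior over the number of components
#'
#' `P(K | D)` is proportional to `exp(-F(K)) * phi(K)` with a uniform prior
#' `phi` over the candidate set; the normalization is overflow-safe
#' (log-sum-exp).
#'
#' @param free_energy Named or unnamed numeric vector of free energies for
#'   `K = 0, 1, ..., K_max` (in that order if unnamed).
#' @return A tibble with columns `K`, `free_energy`, `posterior`, summing to 1.
#' @export
model_order_posterior <- function(free_energy) {
  if (all(!is.finite(free_energy))) {
    stop("All free energies are non-finite.", call. = FALSE)
  }
  ks <- if (!is.null(names(free_energy))) {
    as.integer(names(free_energy))
  } else {
    seq_along(free_energy) - 1L
  }
  lw <- -free_energy
  lw_max <- max(lw[is.finite(lw)])
  w <- exp(lw - lw_max)
  w[!is.finite(lw)] <- 0
  tibble::tibble(K = ks, free_energy = as.numeric(free_energy),
                 posterior = w / sum(w))
}

#' Model evidence across candidate component counts
#'
#' Runs the full model-order selection: for each `K` in `0..K_max`, computes
#' the Bayes free energy (closed form for K = 0, tempered MCMC plus
#' thermodynamic integration otherwise) and converts the free energies into
#' the posterior `P(K | D)` under a uniform prior over K.
#'
#' @param spec An `nmr_spectrum` with positive `noise_sigma`.
#' @param k_max Largest candidate component count (default 3).
#' @param ladder,cfg,box,seed As in [sample_tempered()].
#' @param alpha gESD significance level.
#' @return An `nmr_evidence` object: list with `table` (tibble `K`,
#'   `free_energy`, `posterior`), `k_map` (most probable K), `runs`
#'   (per-K tempered runs), `by_rung`, and `excluded`.
#' @export
estimate_evidence <- function(spec, k_max = 3, ladder = build_ladder(12, 0.01),
                              cfg = chain_config(), box = prior_box(),
                              seed = 1L, alpha = 0.05) {
  stopifnot(k_max >= 0)
  fe <- numeric(k_max + 1)
  runs <- vector("list", k_max + 1)
  rungs <- vector("list", k_max + 1)
  excl <- vector("list", k_max + 1)
  fe[1] <- free_energy_k0(spec)
  for (K in seq_len(k_max)) {
    run <- sample_tempered(spec, K, ladder, cfg, box, seed = seed)
    ti <- ti_free_energy(run, alpha = alpha)
    fe[K + 1] <- ti$free_energy
    runs[[K + 1]] <- run
    rungs[[K + 1]] <- ti$by_rung
    excl[[K + 1]] <- ti$excluded
  }
  tab <- model_order_posterior(fe)
  structure(
    list(table = tab, k_map = tab$K[which.max(tab$posterior)], runs = runs,
         by_rung = rungs, excluded = excl, seed = seed),
    class = "nmr_evidence"
  )
}

#' @export
print.nmr_evidence <- function(x, ...) {
  cat("<nmr_evidence> posterior over the number of components\n")
  print(as.data.frame(x$table), row.names = FALSE)
  cat(sprintf("most probable K: %d\n", x$k_map))
  invisible(x)
}

#' Full posterior sampling at beta = 1 for a fixed K
#'
#' Runs the long posterior chain(s) at unit inverse temperature and returns
#' the retained draws together with their unnormalized log posterior
#' densities, ready for relabeling and summarizing. With the production
#' profile the retained count is 500,000 (100,050,000 steps, burn-in 50,000,
#' thinning 200).
#'
#' @param spec An `nmr_spectrum` with positive `noise_sigma`.
#' @param K Number of components (>= 1).
#' @param cfg A [chain_config()] (its `max_outliers` is ignored here).
#' @param box A [prior_box()].
#' @param seed Master seed.
#' @param init_pool Size of the prior-draw pool for each chain's start (see
#'   [sample_tempered()]).
#' @return A `posterior_draws` object: list with `draws` (T x 3K matrix with
#'   columns `M_k`, `omega_k`, `beta_k`), `log_posterior`, `log_lik`, `K`,
#'   `box`, and `meta`.
#' @export
sample_posterior <- function(spec, K, cfg = run_profile("desk")$posterior,
                             box = prior_box(), seed = 1L, init_pool = 100) {
  stopifnot(K >= 1)
  sigma <- noise_sigma(spec)
  sf <- spectrum_meta(spec)$spectrometer_freq
  lo <- rep(box_lower(box), each = K)
  up <- lo + rep(box_widths(box), each = K)
  all_draws <- list()
  all_ll <- list()
  for (ch in seq_len(cfg$n_chains)) {
    set.seed(derive_seed(seed, K, 1000L, ch))
    init <- draw_chain_init(spec, K, box, 1.0, init_pool)
    res <- cpp_am_chain(spec$ppm, spec$intensity, K, sf, sigma, 1.0,
                        lo, up, init, cfg$total_steps, cfg$burn_in,
                        cfg$thinning)
    all_draws[[ch]] <- res$draws
    all_ll[[ch]] <- res$loglik
  }
  draws <- do.call(rbind, all_draws)
  colnames(draws) <- theta_names(K)
  ll <- unlist(all_ll)
  lp_const <- -K * log(prod(box_widths(box)))
  structure(
    list(draws = draws, log_posterior = ll + lp_const, log_lik = ll, K = K,
         box = box, meta = spectrum_meta(spec), seed = seed),
    class = "posterior_draws"
  )
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("<posterior_draws> %d retained draws, K = %d components\n",
              nrow(x$draws), x$K))
  invisible(x)
}
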