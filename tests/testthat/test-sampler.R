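test_that("the geometric ladder has the documented shape", {
  lad <- build_ladder(45, 0.01)
  expect_length(lad, 46)
  expect_identical(lad[1], 0)
  expect_equal(lad[46], 1)
  ratios <- lad[2:45] / lad[3:46]
  expect_equal(round(ratios, 4), rep(0.9006, 44))
  expect_lt(max(ratios) - min(ratios), 1e-12)
  expect_true(all(diff(lad) > 0))

  expect_identical(build_ladder(1), c(0, 1))
  expect_error(build_ladder(45, 0), "beta1")
})

test_that("retained sample counts follow floor((total - burn) / thin)", {
  expect_equal(retained_samples(400000, 200000, 100), 2000)
  expect_equal(retained_samples(100050000, 50000, 200), 500000)
  expect_equal(retained_samples(10, 0, 1), 10)
})

test_that("beta = 0 retained draws are uniform over the prior box", {
  spec <- selection_spec(data.frame(area = 300, shift = -58.2, fwhm = 300),
                         snr = 10, seed = 1)
  run <- sample_tempered(spec, 1, ladder = c(0, 1),
                         cfg = chain_config(4010, 10, 2, n_chains = 3,
                                            max_outliers = 1),
                         seed = 1, keep_draws = 0)
  draws <- run$draws[["0"]]
  expect_equal(nrow(draws), 2000)
  expect_gt(ks.test(draws[, "M_1"], "punif", 0, 700)$p.value, 0.01)
  expect_gt(ks.test(draws[, "omega_1"], "punif", -62, -55)$p.value, 0.01)
  expect_gt(ks.test(draws[, "beta_1"], "punif", 1, 4)$p.value, 0.01)
})

test_that("a flat likelihood leaves the beta = 1 posterior at the prior", {
  # y identically zero with an enormous sigma: likelihood ratios ~ 1
  x <- seq(-62, -55, length.out = 128)
  spec <- new_spectrum(x, rep(0, 128), noise_sigma = 1e9,
                       meta = list(spectrometer_freq = 565))
  run <- sample_tempered(spec, 1, ladder = c(0, 1),
                         cfg = chain_config(124000, 4000, 60, n_chains = 1,
                                            max_outliers = 0),
                         seed = 2, keep_draws = 1, init_pool = 1)
  draws <- run$draws[["1"]]
  expect_gt(ks.test(draws[, "M_1"], "punif", 0, 700)$p.value, 0.01)
  expect_gt(ks.test(draws[, "omega_1"], "punif", -62, -55)$p.value, 0.01)
  expect_gt(ks.test(draws[, "beta_1"], "punif", 1, 4)$p.value, 0.01)
})

test_that("beta = 1 sampling recovers a high-SNR single component", {
  comp <- data.frame(area = 300, shift = -58.2, fwhm = 300)
  spec <- selection_spec(comp, snr = 30, seed = 3)
  run <- sample_tempered(spec, 1, ladder = c(0, 1),
                         cfg = chain_config(12000, 6000, 3, n_chains = 3,
                                            max_outliers = 1),
                         seed = 3)
  draws <- run$draws[["1"]]
  for (col_truth in list(c("M_1", 300), c("omega_1", -58.2),
                         c("beta_1", log10(300)))) {
    m <- mean(draws[, col_truth[1]])
    s <- sd(draws[, col_truth[1]])
    expect_lt(abs(m - as.numeric(col_truth[2])), 3 * s + 1e-12)
  }
})

test_that("the gESD screen removes extremes and respects its cap", {
  expect_identical(exclude_outlier_chains(rep(1.5, 19)), 1:19)

  # 18 tightly clustered values plus one extreme: only the extreme goes
  x <- c(seq(-0.1, 0.1, length.out = 18), 1e6)
  expect_identical(exclude_outlier_chains(x, max_outliers = 9), 1:18)

  # never removes more than the cap, for any of several contaminated inputs
  for (s in 1:20) {
    set.seed(s)
    x <- c(rnorm(10, 0, 0.5), runif(9, -50, 50))
    kept <- exclude_outlier_chains(x, max_outliers = 9)
    expect_gte(length(kept), 10)
    expect_lte(length(kept), 19)
  }
})

test_that("free energy identities hold exactly", {
  # K = 0: closed form, no sampling
  x <- seq(-60, -56, length.out = 64)
  set.seed(4)
  y <- rnorm(64, sd = 2)
  spec <- new_spectrum(x, y, noise_sigma = 2,
                       meta = list(spectrometer_freq = 565))
  expect_equal(free_energy_k0(spec),
               -sum(-0.5 * log(2 * pi * 4) - y^2 / 8))

  # constant log L = c at every rung integrates to -c
  lad <- build_ladder(6, 0.01)
  fake <- structure(
    list(mean_loglik = tibble::tibble(
      beta_index = rep(seq_along(lad) - 1L, each = 3),
      beta = rep(lad, each = 3),
      chain = rep(1:3, length(lad)),
      mean_loglik = -123.45, accept_rate = 0.3),
      ladder = lad, cfg = chain_config(100, 50, 1, 3, 1)),
    class = "tempered_run")
  expect_equal(ti_free_energy(fake)$free_energy, 123.45)
})

test_that("the model-order posterior is a softmax of minus free energy", {
  tab <- model_order_posterior(c(5, 5, 5, 5))
  expect_equal(tab$posterior, rep(0.25, 4))
  expect_identical(tab$K, 0:3)

  tab2 <- model_order_posterior(c(0, 10, 20, 30))
  direct <- exp(-c(0, 10, 20, 30)) / sum(exp(-c(0, 10, 20, 30)))
  expect_equal(tab2$posterior, direct)
  expect_lt(abs(sum(tab2$posterior) - 1), 1e-12)

  # overflow-safe for huge free energies
  tab3 <- model_order_posterior(c(1e6, 1e6 + 3, 1e6 + 50))
  expect_equal(tab3$posterior[1], 1 / (1 + exp(-3) + exp(-50)))
  expect_error(model_order_posterior(c(Inf, Inf)), "non-finite")
})

test_that("posterior runs are deterministic under a fixed seed", {
  spec <- selection_spec(data.frame(area = 300, shift = -58.2, fwhm = 300),
                         snr = 10, seed = 5)
  cfg <- chain_config(4000, 1000, 10, n_chains = 1, max_outliers = 0)
  p1 <- sample_posterior(spec, 1, cfg = cfg, seed = 7)
  p2 <- sample_posterior(spec, 1, cfg = cfg, seed = 7)
  expect_identical(p1$draws, p2$draws)
  expect_identical(p1$log_posterior, p2$log_posterior)
  expect_equal(nrow(p1$draws), retained_samples(4000, 1000, 10))
})

test_that("expected log likelihood rises along the ladder", {
  spec <- selection_spec(data.frame(area = 300, shift = -58.2, fwhm = 300),
                         snr = 10, seed = 6)
  run <- sample_tempered(spec, 1, ladder = selection_ladder(),
                         cfg = selection_cfg(), seed = 6)
  ti <- ti_free_energy(run)
  e <- ti$by_rung$mean_loglik
  # monotone trend with stochastic tolerance: no decrease larger than 2% of
  # the total rise
  rise <- e[length(e)] - e[1]
  expect_gt(rise, 0)
  expect_true(all(diff(e) > -0.02 * rise))
})
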