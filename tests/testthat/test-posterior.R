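test_that("relabeling is the identity for K = 1", {
  set.seed(2)
  p <- fake_posterior(cbind(runif(50, 0, 700), runif(50, -62, -55),
                            runif(50, 1, 4)))
  expect_identical(relabel_draws(p, seed = 1), p)
})

test_that("relabeling unmixes scrambled well-separated components", {
  sc <- scrambled_two_component()
  p <- fake_posterior(sc$scrambled)
  rl <- relabel_draws(p, seed = 3)

  # labels resolved: each slot stays on one side of the shift midpoint
  o1 <- rl$draws[, "omega_1"]
  o2 <- rl$draws[, "omega_2"]
  expect_true(all(o1 < -58) || all(o1 > -58))
  expect_true(all(o2 < -58) || all(o2 > -58))
  expect_true(xor(all(o1 < -58), all(o2 < -58)))

  # pure permutation per draw: parameter multisets preserved exactly
  expect_identical(draw_multisets(rl$draws, 2),
                   draw_multisets(sc$scrambled, 2))
})

test_that("relabeling is equivariant under a global input permutation", {
  sc <- scrambled_two_component(seed = 11)
  p <- fake_posterior(sc$scrambled)
  g <- fake_posterior(sc$scrambled[, c(2, 1, 4, 3, 6, 5)])
  r1 <- relabel_draws(p, seed = 5)$draws
  r2 <- relabel_draws(g, seed = 5)$draws
  same <- isTRUE(all.equal(r1, r2, check.attributes = FALSE))
  swapped <- isTRUE(all.equal(r1, r2[, c(2, 1, 4, 3, 6, 5)],
                              check.attributes = FALSE))
  expect_true(same || swapped)
})

test_that("the MAP estimate is the highest-density retained draw", {
  set.seed(6)
  d <- cbind(runif(200, 0, 700), runif(200, -62, -55), runif(200, 1, 4))
  lp <- rnorm(200)
  p <- fake_posterior(d, lp)
  m <- map_estimate(p)
  i <- which.max(lp) # independent full scan
  expect_equal(m$M, d[i, 1])
  expect_equal(m$omega, d[i, 2])
  expect_equal(m$fwhm_hz, 10^d[i, 3])

  # ties broken by earliest index
  lp2 <- rep(0, 200)
  expect_identical(attr(map_estimate(fake_posterior(d, lp2)), "map_index"), 1L)

  # all draws identical -> that draw
  dd <- d[rep(1, 50), ]
  expect_equal(map_estimate(fake_posterior(dd, rep(1, 50)))$M, d[1, 1])
})

test_that("credible intervals are percentile-based and transform-consistent", {
  # constant samples give a zero-width interval
  d <- cbind(rep(300, 50), rep(-58, 50), rep(2, 50))
  ci <- credible_intervals(fake_posterior(d))
  expect_equal(ci$lower, ci$upper)
  expect_equal(ci$map[ci$parameter == "M"], 300)

  # large normal sample reproduces +/- 1.96 quantiles
  set.seed(9)
  z <- rnorm(1e5)
  dz <- cbind(350 + z, -58 + 0 * z, 2 + 0 * z)
  ci2 <- credible_intervals(fake_posterior(dz))
  r <- ci2[ci2$parameter == "M", ]
  expect_lt(abs((r$lower - 350) - (-1.96)), 0.05)
  expect_lt(abs((r$upper - 350) - 1.96), 0.05)

  # FWHM interval is 10^(beta interval), endpoint by endpoint
  set.seed(12)
  db <- cbind(runif(500, 0, 700), runif(500, -62, -55), runif(500, 1, 4))
  ci3 <- credible_intervals(fake_posterior(db))
  expect_equal(ci3$lower[ci3$parameter == "fwhm_hz"],
               10^ci3$lower[ci3$parameter == "beta"])
  expect_equal(ci3$upper[ci3$parameter == "fwhm_hz"],
               10^ci3$upper[ci3$parameter == "beta"])

  # MAP lies inside its own interval; intervals contain the stated fraction
  set.seed(13)
  dmix <- cbind(rnorm(2000, 300, 10), rnorm(2000, -58, 0.1),
                rnorm(2000, 2, 0.05))
  lp <- -((dmix[, 1] - 300) / 10)^2
  ci4 <- credible_intervals(fake_posterior(dmix, lp))
  expect_true(all(ci4$lower <= ci4$map & ci4$map <= ci4$upper))
  covered <- mean(dmix[, 1] >= ci4$lower[ci4$parameter == "M"] &
                    dmix[, 1] <= ci4$upper[ci4$parameter == "M"])
  expect_equal(covered, 0.95, tolerance = 0.002)

  expect_error(credible_intervals(fake_posterior(d[1:10, ])), "40")
})

test_that("the MAP overlay reproduces self-generated data and adds lb", {
  comp <- data.frame(area = 300, shift = -58.2, fwhm = 300)
  acq <- test_acq(n_points = 4096)
  fid <- simulate_fid(comp, acq)
  map <- param_set(M = 300, omega = -58.2, beta = log10(300))

  # lb = 0, noise-free data generated from the MAP itself -> identical curves
  ov0 <- render_map_overlay(map, fid, lb = 0, n_keep = 1024, n_total = 2048,
                            baseline_order = NA)
  expect_equal(ov0$model, ov0$observed, tolerance = 1e-8)

  # apodized overlay width = MAP FWHM + lb within the axis resolution
  ov <- render_map_overlay(map, fid, lb = 200, n_keep = 1024, n_total = 2048,
                           baseline_order = NA)
  spec <- new_spectrum(ov$ppm, ov$model,
                       meta = list(spectrometer_freq = 565))
  expect_lt(abs(measure_peak(spec)$fwhm_hz - 500), (237 / 2048) * 565)

  # component order never matters
  map2 <- param_set(M = c(100, 300), omega = c(-60, -58.2),
                    beta = c(2, log10(300)))
  ovA <- render_map_overlay(map2, fid, lb = 200, n_keep = 1024,
                            n_total = 2048, baseline_order = NA)
  ovB <- render_map_overlay(map2[2:1, ], fid, lb = 200, n_keep = 1024,
                            n_total = 2048, baseline_order = NA)
  expect_equal(ovA$model, ovB$model)
})
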