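test_that("acquisition metadata gives the documented dwell and 30.6 ms window", {
  fid <- new_fid(complex(real = rep(0, 64)))
  expect_equal(dwell_time(fid), 1 / (237 * 565))
  expect_equal(round(4096 * dwell_time(fid) * 1000, 1), 30.6)
})

test_that("group-delay removal restores the time origin", {
  acq <- test_acq(n_points = 2048)
  fid <- simulate_fid(data.frame(area = 1, shift = -58, fwhm = 300), acq)

  # identity at zero delay
  expect_identical(remove_digital_filter(fid), fid)

  # integer delay: exact inverse of the circular shift the simulator applies
  fid_g <- nmrdecon:::inject_group_delay(fid, 37)
  rec <- remove_digital_filter(fid_g)
  expect_equal(rec$points, fid$points, tolerance = 1e-12)
  expect_identical(rec$group_delay, 0)
  expect_identical(rec$n_points, fid$n_points)

  # fractional delay: corrected spectrum peaks within one point of delay-free
  fid_f <- nmrdecon:::inject_group_delay(fid, 21.6)
  rec_f <- remove_digital_filter(fid_f)
  sp0 <- fid_to_spectrum(truncate_zero_fill(fid, 1024, 2048))
  sp1 <- fid_to_spectrum(truncate_zero_fill(rec_f, 1024, 2048))
  expect_lte(abs(which.max(sp0$intensity) - which.max(sp1$intensity)), 1)

  # invalid metadata
  bad <- fid
  bad$group_delay <- -1
  expect_error(remove_digital_filter(bad), "group delay")
})

test_that("truncation and zero-filling keep the right points and energy", {
  set.seed(1)
  pts <- complex(real = rnorm(512), imaginary = rnorm(512))
  fid <- new_fid(pts)

  out <- truncate_zero_fill(fid, n_keep = 128, n_total = 256)
  expect_identical(out$n_points, 256L)
  expect_identical(out$points[1:128], pts[1:128])
  expect_true(all(out$points[129:256] == 0))
  expect_equal(sum(Mod(out$points)^2), sum(Mod(pts[1:128])^2))
  expect_lte(sum(Mod(out$points)^2), sum(Mod(pts)^2))

  # identity case
  expect_equal(truncate_zero_fill(fid, 512, 512)$points, pts)

  expect_error(truncate_zero_fill(fid, 1024, 2048), "512")
})

test_that("the transform is linear, zero-preserving, and axis-correct", {
  acq <- test_acq(n_points = 2048)
  f1 <- simulate_fid(data.frame(area = 1, shift = -57, fwhm = 200), acq)
  f2 <- simulate_fid(data.frame(area = 2, shift = -60, fwhm = 500), acq)
  fsum <- f1
  fsum$points <- f1$points + f2$points

  s1 <- fid_to_spectrum(f1)
  s2 <- fid_to_spectrum(f2)
  ssum <- fid_to_spectrum(fsum)
  expect_equal(ssum$intensity, s1$intensity + s2$intensity, tolerance = 1e-10)

  zero <- new_fid(complex(real = rep(0, 256)))
  expect_true(all(fid_to_spectrum(zero)$intensity == 0))

  # descending ppm axis spanning the sweep with spacing sweep/N
  expect_true(all(diff(s1$ppm) < 0))
  expect_equal(abs(diff(s1$ppm)[1]), 237 / 2048)
  expect_equal(length(s1$ppm) * abs(diff(s1$ppm)[1]), 237)

  # noise-free exponential decay exp(-pi*Gamma*t) shows FWHM = Gamma
  fidw <- simulate_fid(data.frame(area = 1, shift = -58, fwhm = 400), acq)
  spw <- fid_to_spectrum(truncate_zero_fill(fidw, 1024, 2048))
  expect_lt(abs(measure_peak(spw)$fwhm_hz - 400),
            (237 / 2048) * 565) # one axis point
})

test_that("baseline correction removes polynomials but preserves peaks", {
  x <- seq(-70, -50, length.out = 1024)
  quartic <- 5 + 0.2 * x + 0.01 * x^2 + 1e-3 * x^3 + 2e-5 * x^4
  spec <- new_spectrum(x, quartic, meta = list(spectrometer_freq = 565))
  out <- baseline_correct(spec, order = 4)
  expect_lt(max(abs(out$intensity)), 1e-6 * diff(range(quartic)))

  # quartic + one narrow Lorentzian: recovered area within 2%
  lor <- lorentzian_component(x, M = 50, omega = -58, beta = 1.5, 565)
  spec2 <- new_spectrum(x, quartic + lor, meta = list(spectrometer_freq = 565))
  out2 <- baseline_correct(spec2, order = 4)
  dppm <- abs(diff(x)[1])
  area_in <- sum(lor) * dppm
  expect_lt(abs(sum(out2$intensity) * dppm - area_in) / area_in, 0.02)

  # near-idempotence
  out3 <- baseline_correct(out2, order = 4)
  expect_equal(out3$intensity, out2$intensity,
               tolerance = 0.01 * diff(range(out2$intensity)))

  expect_error(baseline_correct(spec, order = 2000), "smaller")
})

test_that("tail noise estimation bridges time and spectral domains", {
  # zero tail -> zero sigma; amplitude linearity
  acq <- test_acq(n_points = 8192)
  fid0 <- simulate_fid(data.frame(area = 1, shift = -58, fwhm = 2000), acq)
  expect_equal(estimate_noise_sigma(fid0, tail_start = 0.02, n_keep = 1024), 0,
               tolerance = 1e-8)

  set.seed(7)
  fidn <- simulate_noise_fid(test_acq(n_points = 8192, noise_sigma_t = 0.5))
  s1 <- estimate_noise_sigma(fidn, n_keep = 1024)
  fid2 <- fidn
  fid2$points <- 2 * fidn$points
  expect_equal(estimate_noise_sigma(fid2, n_keep = 1024), 2 * s1)

  # Monte-Carlo: estimator matches the empirical spectral real-part SD
  set.seed(42)
  ratio <- replicate(50, {
    f <- simulate_noise_fid(test_acq(noise_sigma_t = 1))
    sp <- fid_to_spectrum(truncate_zero_fill(f, 4096, 8192))
    estimate_noise_sigma(f) / sd(sp$intensity)
  })
  expect_lt(abs(mean(ratio) - 1), 0.05)

  short <- new_fid(complex(real = rep(0, 128)))
  expect_error(estimate_noise_sigma(short), "at least 64")
})

test_that("display apodization broadens a Lorentzian by lb", {
  acq <- test_acq(n_points = 16384)
  fid <- simulate_fid(data.frame(area = 1, shift = -58, fwhm = 164.8), acq)

  expect_identical(apodize(fid, 0), fid)
  ap <- apodize(fid, 200)
  expect_identical(ap$points[1], fid$points[1]) # t = 0 weight is 1

  w <- measure_peak(fid_to_spectrum(truncate_zero_fill(ap, 4096, 8192)))$fwhm_hz
  expect_lt(abs(w - (164.8 + 200)), (237 / 8192) * 565)
})
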