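test_that("error metrics match hand computation", {
  x <- array(c(1, 2, 3, 4, 5, 6, 7, 8), c(2, 2, 2))
  y <- array(c(1, 2, 2, 6, 5, 5, 7, 9), c(2, 2, 2))
  expect_equal(mse(x, x), 0)
  expect_equal(mse(x, y), (0 + 0 + 1 + 4 + 0 + 1 + 0 + 1) / 8)
  expect_equal(mae(x, y), (0 + 0 + 1 + 2 + 0 + 1 + 0 + 1) / 8)
  expect_equal(mse(x, x + 3), 9)
  expect_error(mse(x, array(0, c(2, 2, 1))), "differ")
})

test_that("3D SSIM is 1 on identical inputs, symmetric and bounded", {
  set.seed(40)
  x <- array(runif(15^3, 0, 40), c(15, 15, 15))
  y <- array(runif(15^3, 0, 40), c(15, 15, 15))
  expect_equal(ssim3d(x, x), 1, tolerance = 1e-12)
  expect_equal(ssim3d(x, y), ssim3d(y, x), tolerance = 1e-12)
  expect_lte(ssim3d(x, y), 1)
  expect_lt(ssim3d(x, y), ssim3d(x, x))
})

test_that("SSIM of constant volumes matches the analytic value", {
  # zero variances collapse the structure term; the index reduces to the
  # luminance term
  p <- ssim_params()
  for (ab in list(c(3, 3), c(2, 5), c(10, 0.5))) {
    a <- ab[1]; b <- ab[2]
    x <- array(a, c(5, 5, 5)); y <- array(b, c(5, 5, 5))
    expect_equal(ssim3d(x, y), (2 * a * b + p$C1) / (a^2 + b^2 + p$C1),
                 tolerance = 1e-9)
  }
})

test_that("PSNR follows its closed form and its MSE duality", {
  x <- array(0, c(6, 6, 6))
  expect_equal(psnr(x + 40, x), 0)
  expect_equal(psnr(x + 4, x), 20)
  set.seed(41)
  a <- array(runif(10^3, 0, 40), c(10, 10, 10))
  b <- array(runif(10^3, 0, 40), c(10, 10, 10))
  expect_equal(psnr(a, b), 20 * log10(40) - 10 * log10(mse(a, b)),
               tolerance = 1e-9)
  expect_warning(p <- psnr(a, a), "infinite")
  expect_equal(p, Inf)
})

test_that("SNR maps use the population deviation and mask zero spread", {
  v1 <- array(9, c(3, 3, 3)); v2 <- array(11, c(3, 3, 3))
  sm <- snr_map(list(v1, v2))
  expect_equal(sm$n_reps, 2)
  expect_equal(unique(as.numeric(sm$mean)), 10)
  expect_equal(unique(as.numeric(sm$sd)), 1) # population sigma, not n-1
  expect_equal(unique(as.numeric(sm$values)), 20) # 20 log10(10/1)
  expect_true(all(sm$mask))

  same <- snr_map(list(v1, v1, v1))
  expect_false(any(same$mask))
  expect_true(all(is.na(same$values)))
  expect_error(snr_map(list(v1)), "2 repetitions")
})

test_that("Poisson repetition stacks reproduce the shot-noise SNR", {
  # oracle: counts ~ Poisson(lambda) give SNR = 20 log10(sqrt(lambda))
  set.seed(42)
  lambda <- 400
  stack <- lapply(1:80, function(i) array(rpois(8^3, lambda), c(8, 8, 8)))
  sm <- snr_map(stack)
  expect_lt(abs(mean(sm$values[sm$mask]) - 10 * log10(lambda)), 0.5)
})

test_that("SNR improvements aggregate as piecewise means", {
  set.seed(43)
  base <- lapply(1:10, function(i) array(rnorm(6^3, 100, 10), c(6, 6, 6)))
  sm_before <- snr_map(base)
  expect_equal(delta_snr(sm_before, sm_before)$delta_snr_all, 0)
  expect_true(is.na(delta_snr(sm_before, sm_before)$delta_snr_eff))

  # shrink deviations about the mean by 2 everywhere: exactly +20 log10(2)
  mu <- Reduce(`+`, base) / 10
  half <- lapply(base, function(v) mu + (v - mu) / 2)
  ds <- delta_snr(sm_before, snr_map(half))
  gain <- 20 * log10(2)
  expect_equal(ds$delta_snr_all, gain, tolerance = 1e-9)
  expect_equal(ds$delta_snr_eff, gain, tolerance = 1e-9)

  # improve only half of the voxels: all = gain/2, eff = gain
  sel <- array(FALSE, c(6, 6, 6)); sel[1:3, , ] <- TRUE
  mixed <- lapply(base, function(v) { v[sel] <- mu[sel] + (v[sel] - mu[sel]) / 2; v })
  ds <- delta_snr(sm_before, snr_map(mixed))
  expect_equal(ds$delta_snr_all, gain / 2, tolerance = 1e-9)
  expect_equal(ds$delta_snr_eff, gain, tolerance = 1e-9)
})

test_that("the photon multiplier matches the published worked examples", {
  expect_equal(photon_multiplier(0), 1)
  expect_equal(photon_multiplier(20), 100)
  expect_equal(photon_multiplier(10), 10)
  expect_true(all(diff(photon_multiplier(seq(0, 30, 0.5))) > 0))
  expect_equal(photon_multiplier(3 + 4),
               photon_multiplier(3) * photon_multiplier(4))
  # printed cascade-column pairs (dSNR_all in dB -> MF) reproduce to 1e-2
  # relative, absorbing the 4-decimal rounding of the inputs
  dsnr <- c(18.9565, 16.1272, 14.2469, 14.4447, 15.6349, 14.5437,
            14.0396, 14.5478, 11.9179)
  mf <- c(78.6412, 40.9940, 26.5883, 27.8272, 36.6008, 28.4689,
          25.3490, 28.4957, 15.5521)
  expect_true(all(abs(photon_multiplier(dsnr) - mf) / mf < 0.01))
})

test_that("metric reports keep MF consistent with the SNR improvement", {
  set.seed(44)
  base <- lapply(1:8, function(i) array(rnorm(6^3, 50, 5), c(6, 6, 6)))
  mu <- Reduce(`+`, base) / 8
  better <- lapply(base, function(v) mu + (v - mu) / 3)
  clean <- array(runif(6^3, 0, 40), c(6, 6, 6))
  noisy <- clean + array(rnorm(6^3, 0, 1), c(6, 6, 6))
  rep <- metrics_report(clean, noisy, before = snr_map(base),
                        after = snr_map(better),
                        metadata = list(benchmark = "b1"))
  expect_s3_class(rep, "metrics_report")
  expect_equal(rep$mf, 10^(rep$delta_snr_all / 10), tolerance = 1e-9)
  expect_equal(rep$mse, mse(clean, noisy))
})

test_that("cross-section profiles track the free axis", {
  const <- lapply(1:5, function(i) array(7 + i * 1e-3, c(8, 10, 12)))
  pr <- cross_section_profile(const, axis = 3, fixed = c(4, 5))
  expect_equal(nrow(pr), 12)
  expect_equal(pr$position, 1:12)
  expect_equal(diff(range(pr$mean)), 0) # constant volume -> flat profile
  pr2 <- cross_section_profile(const, axis = 1, fixed = c(5, 6))
  expect_equal(nrow(pr2), 8)
  expect_error(cross_section_profile(const, axis = 3, fixed = c(40, 5)),
               "outside")
  # identity "denoiser": before/after profiles identical
  expect_identical(cross_section_profile(const, 3, c(4, 5)),
                   cross_section_profile(lapply(const, identity), 3, c(4, 5)))
})
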