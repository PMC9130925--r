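test_that("Henyey-Greenstein sampling matches its density", {
  # isotropic limit: exact closed form
  u <- c(0, 0.25, 0.5, 0.75, 0.999)
  expect_equal(hg_sample(0, u), 2 * u - 1, tolerance = 1e-12)
  # extreme deviates stay in range at high anisotropy
  expect_true(all(abs(hg_sample(0.99, c(0, 1 - 1e-12))) <= 1))
  expect_error(hg_sample(1, 0.5), "anisotropy")

  # oracle: E[cos theta] by numerical quadrature of the HG density
  g <- 0.9
  dens <- function(ct) 0.5 * (1 - g^2) / (1 + g^2 - 2 * g * ct)^1.5
  expected <- integrate(function(ct) ct * dens(ct), -1, 1,
                        rel.tol = 1e-10)$value
  expect_equal(expected, g, tolerance = 1e-8) # sanity on the oracle itself
  set.seed(11)
  draws <- hg_sample(g, runif(1e6))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - expected), 3 * se)
})

test_that("energy is conserved to 1e-6 with roulette disabled", {
  set.seed(12)
  # heterogeneous phantom incl. refractive mismatch
  m <- array(0L, c(14, 14, 14)); m[4:9, 4:9, 4:9] <- 1L
  ph <- compose_phantom(list(m))
  src <- source_spec("isotropic", c(7, 7, 7))
  for (boundary in c("fresnel", "absorbing")) {
    sp <- simulation_spec(photon_count = 1500, seed = 5, time_gate_ns = 0.5,
                          boundary = boundary, roulette = FALSE)
    st <- simulate_fluence(ph, src, sp)$stats
    bal <- st$total_launched_weight -
      (st$total_absorbed_weight + st$total_escaped_weight +
         st$total_time_gated_out_weight + st$live_residual_weight)
    expect_lt(abs(bal) / st$total_launched_weight, 1e-6)
  }
})

test_that("fluence is non-negative, finite and seed-deterministic", {
  ph <- homogeneous_phantom(12)
  src <- source_spec("isotropic", c(6, 6, 6))
  sp <- simulation_spec(photon_count = 500, seed = 21, time_gate_ns = 1)
  a <- simulate_fluence(ph, src, sp)$fluence
  b <- simulate_fluence(ph, src, sp)$fluence
  expect_identical(a$values, b$values)
  expect_true(all(is.finite(a$values)))
  expect_true(all(a$values >= 0))
  sp$seed <- 22L
  d <- simulate_fluence(ph, src, sp)$fluence
  expect_false(identical(a$values, d$values))
})

test_that("a pencil beam in a non-scattering medium deposits along its ray", {
  ph <- homogeneous_phantom(10, mua = 0.1, musp = 1, g = 0.9)
  ph$properties$mus <- 0 # no scattering at all
  ph$properties$musp <- 0
  src <- source_spec("pencil", c(5.5, 5.5, 0.5), direction = c(0, 0, 1))
  sp <- simulation_spec(photon_count = 10, seed = 2, time_gate_ns = 5,
                        boundary = "absorbing", roulette = FALSE)
  v <- simulate_fluence(ph, src, sp)$fluence$values
  on_ray <- v[6, 6, ]
  expect_true(all(on_ray > 0))
  off <- v; off[6, 6, ] <- 0
  expect_equal(sum(off), 0)
  # continuous absorption: deposition decays monotonically along the ray
  # (the first voxel only sees a half-length entry segment, so start at 2)
  expect_true(all(diff(on_ray[-1]) < 0))
})

test_that("per-photon normalization is independent of photon count", {
  ph <- homogeneous_phantom(12)
  src <- source_spec("isotropic", c(6, 6, 6))
  reps_lo <- run_repetitions(ph, src, simulation_spec(500, time_gate_ns = 1),
                             n_reps = 12, base_seed = 100)
  reps_hi <- run_repetitions(ph, src, simulation_spec(5000, time_gate_ns = 1),
                             n_reps = 12, base_seed = 300)
  tot_lo <- vapply(reps_lo, function(v) mean(v$values), numeric(1))
  tot_hi <- vapply(reps_hi, function(v) mean(v$values), numeric(1))
  # two-sample comparison: difference within combined sampling error
  se <- sqrt(var(tot_lo) / 12 + var(tot_hi) / 12)
  expect_lt(abs(mean(tot_lo) - mean(tot_hi)), 4 * se)
})

test_that("repetition stacks are order-stable and independently seeded", {
  ph <- homogeneous_phantom(10)
  src <- source_spec("isotropic", c(5, 5, 5))
  sp <- simulation_spec(photon_count = 200, seed = 1, time_gate_ns = 0.5)
  st <- run_repetitions(ph, src, sp, n_reps = 3, base_seed = 40)
  expect_length(st, 3)
  expect_equal(vapply(st, `[[`, 0, "seed"), c(40, 41, 42))
  expect_false(identical(st[[1]]$values, st[[2]]$values))
  expect_error(run_repetitions(ph, src, sp, n_reps = 1), "n_reps")
})

test_that("cube benchmarks scale linearly and share geometry", {
  b1 <- benchmark_domain("b1", 1)
  expect_equal(dim(b1$phantom$label_grid), c(100L, 100L, 100L))
  expect_equal(unique(as.integer(b1$phantom$label_grid)), 0L)
  expect_equal(b1$phantom$voxel_size, 1)

  b2 <- benchmark_domain("b2", 0.32)
  expect_equal(dim(b2$phantom$label_grid), c(32L, 32L, 32L))
  side <- sum(b2$phantom$label_grid[, 16, 16] == 1L)
  expect_equal(side, 13) # round(40 * 0.32)
  b1s <- benchmark_domain("b1", 0.32)
  outside <- b2$phantom$label_grid == 0L
  expect_true(all(b1s$phantom$label_grid[outside] == 0L))

  b3 <- benchmark_domain("b3", 0.32)
  expect_equal(b3$phantom$label_grid, b2$phantom$label_grid)
  expect_false(isTRUE(all.equal(b3$phantom$properties,
                                b2$phantom$properties)))
  expect_error(benchmark_domain("b9"), "valid names")
})

test_that("zero-absorption voxels use the path-length estimator", {
  ph <- homogeneous_phantom(10, mua = 0, musp = 1, g = 0.5)
  ph$properties$mus <- 2
  src <- source_spec("isotropic", c(5, 5, 5))
  sp <- simulation_spec(photon_count = 300, seed = 9, time_gate_ns = 0.5,
                        roulette = FALSE)
  out <- simulate_fluence(ph, src, sp)
  expect_true(all(is.finite(out$fluence$values)))
  expect_gt(max(out$fluence$values), 0)
  expect_equal(out$stats$total_absorbed_weight, 0)
})
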