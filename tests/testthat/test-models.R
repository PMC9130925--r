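test_that("zeroed residual heads give an exact pass-through", {
  set.seed(20)
  y <- array(runif(24^3, 0, 12), c(24, 24, 24))
  for (arch in c("dncnn", "unet", "cascade")) {
    m <- mc_denoiser(arch, tiny_global(), tiny_local(), seed = 3)
    mcdenoise:::zero_residual_heads(m)
    expect_identical(denoise_volume(m, y), y)
  }
})

test_that("spatial shape is preserved, including non-stride sizes", {
  set.seed(21)
  m <- mc_denoiser("cascade", tiny_global(), tiny_local(), seed = 3)
  for (n in c(17, 24, 33)) {
    y <- array(runif(n^3), c(n, n, n))
    out <- denoise_volume(m, y)
    expect_equal(dim(out), c(n, n, n))
    expect_true(all(is.finite(out)))
  }
  # anisotropic shape
  y <- array(runif(16 * 24 * 18), c(16, 24, 18))
  expect_equal(dim(denoise_volume(m, y)), c(16, 24, 18))
})

test_that("inference is deterministic for fixed weights", {
  set.seed(22)
  m <- mc_denoiser("cascade", tiny_global(), tiny_local(), seed = 5)
  y <- array(runif(24^3), c(24, 24, 24))
  expect_identical(denoise_volume(m, y), denoise_volume(m, y))
})

test_that("patch tiling approximates whole-volume inference", {
  set.seed(23)
  m <- mc_denoiser("cascade", tiny_global(), tiny_local(), seed = 7)
  y <- array(runif(48^3, 0, 10), c(48, 48, 48))
  whole <- denoise_volume(m, y)
  tiled <- denoise_volume(m, y, tiling = "patches", patch_size = 32,
                          overlap = 16)
  expect_lt(sqrt(mean((whole - tiled)^2)), 1e-3)
  # identity model: tiling is exact regardless of geometry
  mid <- mcdenoise:::zero_residual_heads(
    mc_denoiser("cascade", tiny_global(), tiny_local(), seed = 1))
  y2 <- array(runif(24^3), c(24, 24, 24))
  expect_equal(denoise_volume(mid, y2, tiling = "patches",
                              patch_size = 16, overlap = 8), y2)
  expect_error(denoise_volume(m, y, tiling = "patches", patch_size = 15),
               "stride")
})

test_that("non-finite inputs are rejected with a located error", {
  m <- mc_denoiser("dncnn", tiny_global(), seed = 1)
  y <- array(1, c(8, 8, 8)); y[13] <- NaN
  expect_error(denoise_volume(m, y), "voxel index 13")
})

test_that("dual-gain inference with a pass-through model returns the input", {
  set.seed(24)
  m <- mc_denoiser("cascade", tiny_global(), tiny_local(), seed = 2)
  mcdenoise:::zero_residual_heads(m)
  x <- fluence_volume(array(10^runif(16^3, -8, 0), c(16, 16, 16)), 1)
  out <- predict(m, x)
  rel <- abs(out$values - x$values) / pmax(x$values, 1e-300)
  expect_lt(max(rel), 1e-9)
})

test_that("checkpoints round-trip through JSON", {
  set.seed(25)
  m <- mc_denoiser("cascade", tiny_global(), tiny_local(), seed = 9)
  m$trained <- TRUE
  m$meta <- list(epochs = 3L, best_epoch = 2L)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  save_checkpoint(m, tf)
  m2 <- load_checkpoint(tf)
  y <- array(runif(16^3), c(16, 16, 16))
  expect_equal(denoise_volume(m2, y), denoise_volume(m, y),
               tolerance = 1e-12)
  expect_true(m2$trained)
})

test_that("stage specs validate their invariants", {
  expect_error(global_stage_spec(depth = 2))
  expect_error(global_stage_spec(kernel = 4))
  expect_error(local_stage_spec(n_scales = 1))
  m <- mc_denoiser("unet", local_spec = local_stage_spec(n_scales = 3,
                                                         base_width = 4),
                   seed = 1)
  expect_equal(m$stride_multiple, 4L)
  # 24 is already divisible by 4: no padding artifacts expected
  y <- array(runif(24^3), c(24, 24, 24))
  expect_equal(dim(denoise_volume(m, y)), c(24, 24, 24))
})
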