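test_that("the Ln loss matches its closed forms", {
  a <- array(1, c(4, 4, 4, 1, 2))
  expect_equal(ln_loss(a, a, 2), 0)
  expect_equal(ln_loss(a + 2, a, 2), 4)
  expect_equal(ln_loss(a + 2, a, 1), 2)
  set.seed(30)
  p <- array(runif(128), c(4, 4, 4, 1, 2))
  q <- array(runif(128), c(4, 4, 4, 1, 2))
  expect_gte(ln_loss(p, q, 1), ln_loss(p, q, 2)) # |e| >= e^2 for |e| <= 1
  expect_error(ln_loss(a, a[, , , , 1, drop = FALSE], 2), "shapes")
  expect_error(ln_loss(a, a, 3), "exponent")
})

test_that("augmentation applies identical transforms to input and label", {
  set.seed(31)
  pair <- training_pair(array(runif(8^3), c(8, 8, 8)),
                        array(runif(8^3), c(8, 8, 8)), 1e2, 1e4)
  expect_identical(augment_pair(pair, p = 0), pair)
  for (i in 1:25) {
    aug <- augment_pair(pair, p = 1)
    # rotations/flips permute voxels: multisets preserved
    expect_equal(sort(as.numeric(aug$noisy)), sort(as.numeric(pair$noisy)))
    # label consistency: any error metric is invariant under the joint
    # transform
    expect_equal(mse(aug$noisy, aug$clean), mse(pair$noisy, pair$clean))
  }
  bad <- training_pair(array(runif(8 * 8 * 4), c(8, 8, 4)),
                       array(runif(8 * 8 * 4), c(8, 8, 4)), 1e2, 1e4)
  set.seed(99)
  expect_error(replicate(50, augment_pair(bad, p = 1)), "non-cubic")
})

test_that("transform application rate matches the configured probability", {
  # volume symmetric under every axis flip but not under 90-degree
  # rotations: a change in the volume pinpoints a rotation draw
  w1 <- c(1, 2, 2, 1); w2 <- c(10, 20, 20, 10); w3 <- c(100, 200, 200, 100)
  base <- outer(outer(w1, w2, `+`), w3, `+`)
  pair <- training_pair(base, base, 1e2, 1e4)
  set.seed(32)
  hits <- replicate(1e4, {
    aug <- augment_pair(pair, p = 0.7)
    !identical(aug$noisy, pair$noisy)
  })
  expect_gt(mean(hits), 0.68)
  expect_lt(mean(hits), 0.72)
})

test_that("dataset assembly pairs every noisy level with the clean level", {
  fx <- fixture_catalog()
  set.seed(33)
  pairs <- assemble_dataset(fx$fluence_dir, fx$manifest_path,
                            photon_levels = c(1e2, 1e3), clean_level = 1e4)
  expect_length(pairs, 3 * 2)
  for (p in pairs) {
    expect_s3_class(p, "training_pair")
    expect_false(identical(p$noisy, p$clean)) # stochastic sims differ
    expect_gt(p$clean_photons, p$noisy_photons)
    expect_true(p$gain %in% c(1, 1e7))
  }
  expect_error(assemble_dataset(fx$fluence_dir, fx$manifest_path,
                                c(1e2, 5e3), 1e4), "level")
  fixed <- assemble_dataset(fx$fluence_dir, fx$manifest_path, 1e2, 1e4,
                            gain_policy = "fixed", fixed_gain = 1e7)
  expect_true(all(vapply(fixed, `[[`, 0, "gain") == 1e7))
})

test_that("learning-rate schedule ramps linearly then anneals to zero", {
  cfg <- train_config(base_lr = 1e-4, warmup_iters = 1000)
  expect_equal(mcdenoise:::lr_at(500, 10000, cfg), 0.5e-4)
  expect_equal(mcdenoise:::lr_at(1000, 10000, cfg), 1e-4)
  expect_lt(mcdenoise:::lr_at(10000, 10000, cfg), 1e-6)
  mid <- mcdenoise:::lr_at(5500, 10000, cfg)
  expect_equal(mid, 0.5e-4, tolerance = 1e-8) # halfway through the cosine
})

test_that("weight decay exempts biases and batch-norm parameters", {
  m <- mc_denoiser("cascade", tiny_global(), tiny_local(), seed = 1)
  refs <- mcdenoise:::param_refs(m)
  for (r in refs) {
    if (r$slot %in% c("b", "gamma", "beta")) expect_false(r$decay)
    if (r$slot == "w") expect_true(r$decay)
    if (r$bn) expect_true(r$slot %in% c("gamma", "beta"))
  }
  expect_gt(sum(vapply(refs, function(r) r$decay, logical(1))), 0)
})

test_that("a short seeded run reduces the loss and reproduces exactly", {
  fx <- fixture_catalog()
  set.seed(34)
  pairs <- assemble_dataset(fx$fluence_dir, fx$manifest_path, 1e3, 1e4,
                            gain_policy = "fixed", fixed_gain = 1e7)
  cfg <- train_config(epochs = 3, batch_size = 2, base_lr = 1e-3,
                      warmup_iters = 2, seed = 55)
  m1 <- mc_denoiser("dncnn", tiny_global(), seed = 8)
  fit1 <- train_denoiser(m1, pairs, pairs[1], cfg)
  expect_lt(tail(fit1$history$train_loss, 1), fit1$history$train_loss[1])
  expect_length(fit1$history$epoch, 3)
  expect_true(fit1$model$trained)
  m2 <- mc_denoiser("dncnn", tiny_global(), seed = 8)
  fit2 <- train_denoiser(m2, pairs, pairs[1], cfg)
  expect_identical(fit1$history$train_loss, fit2$history$train_loss)
  expect_identical(fit1$history$val_mse, fit2$history$val_mse)
})

test_that("checkpoint selection follows the configured rule", {
  h <- structure(list(epoch = 1:3,
                      val_mse = c(0.5, 0.2, 0.3),
                      val_ssim = c(0.90, 0.92, 0.95),
                      val_psnr = c(30, 33, 31)), class = "mc_history")
  expect_equal(select_best(h, "mse"), 2)
  expect_equal(select_best(h, "ssim"), 3)
  expect_equal(select_best(h, "psnr"), 2)
  # rank sums: epoch1 = 3+3+3 = 9, epoch2 = 1+2+1 = 4, epoch3 = 2+1+2 = 5
  expect_equal(select_best(h, "composite"), 2)
  one <- structure(list(epoch = 1L, val_mse = 1, val_ssim = 0.5,
                        val_psnr = 10), class = "mc_history")
  expect_equal(select_best(one, "composite"), 1)
  inc <- structure(list(epoch = 1:4, val_mse = rep(NA_real_, 4),
                        val_ssim = rep(NA_real_, 4),
                        val_psnr = c(10, 20, 30, 40)), class = "mc_history")
  expect_equal(select_best(inc, "psnr"), 4)
  expect_error(select_best(inc, "mse"), "absent|requires")
})
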