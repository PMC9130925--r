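test_that("sampled shapes are fully parameterized and reproducible", {
  set.seed(10)
  expect_error(sample_shape(c(4, 64, 64)), "all >= 8")
  for (i in 1:50) {
    sp <- sample_shape(c(32, 32, 32), kind = "polyhedron")
    expect_true(sp$n_points >= 4 && sp$n_points <= 10)
    expect_equal(nrow(sp$points), sp$n_points)
  }
  set.seed(123)
  a <- sample_shape(c(32, 32, 32))
  set.seed(123)
  b <- sample_shape(c(32, 32, 32))
  expect_identical(a, b)
})

test_that("shape kind is drawn with an even split", {
  set.seed(4)
  kinds <- replicate(1e4, sample_shape(c(8, 8, 8), kind = NULL)$kind)
  p_poly <- mean(kinds == "polyhedron")
  expect_gt(p_poly, 0.47)
  expect_lt(p_poly, 0.53)
})

test_that("polyhedron rasterization matches a brute-force point-in-hull test", {
  # tetrahedron with vertices at voxel centers: those voxels are inside
  verts <- rbind(c(2.5, 2.5, 2.5), c(8.5, 2.5, 2.5),
                 c(2.5, 8.5, 2.5), c(2.5, 2.5, 8.5))
  m <- rasterize_polyhedron(manual_polyhedron(verts), c(12, 12, 12))
  expect_equal(m[3, 3, 3], 1L)
  expect_equal(m[9, 3, 3], 1L)
  expect_equal(m[3, 9, 3], 1L)
  expect_equal(m[3, 3, 9], 1L)
  expect_equal(m[12, 12, 12], 0L)

  # axis-aligned cube spanning [2,5]^3 mm: independent oracle counts the
  # voxel centers inside the box
  corners <- as.matrix(expand.grid(c(2, 5), c(2, 5), c(2, 5)))
  m <- rasterize_polyhedron(manual_polyhedron(corners), c(10, 10, 10))
  centers <- as.matrix(expand.grid(1:10 - 0.5, 1:10 - 0.5, 1:10 - 0.5))
  inside <- rowSums(centers >= 2 & centers <= 5) == 3
  expect_equal(sum(m), sum(inside))

  # hull translated fully outside the grid rasterizes to nothing
  far <- manual_polyhedron(verts)
  far$translation <- c(100, 100, 100)
  expect_equal(sum(rasterize_polyhedron(far, c(12, 12, 12))), 0)

  # coplanar point set is degenerate
  flat <- rbind(c(2, 2, 2), c(8, 2, 2), c(2, 8, 2), c(8, 8, 2))
  expect_error(rasterize_polyhedron(manual_polyhedron(flat), c(12, 12, 12)),
               "degenerate")
})

test_that("letter rasterization extrudes a 2D glyph", {
  sp <- manual_letter("I", c(24, 24, 24), font_size = 14, thickness = 5)
  m <- rasterize_letter(sp, c(24, 24, 24))
  expect_gt(sum(m), 0)
  # with identity pose, all extruded slices are identical copies
  zs <- which(apply(m, 3, sum) > 0)
  expect_equal(length(zs), 5)
  for (z in zs[-1]) expect_identical(m[, , z], m[, , zs[1]])
  # an unrotated "I" is one solid connected slab: flood fill from one voxel
  # reaches every voxel of the mask
  occ <- which(m == 1L, arr.ind = TRUE)
  visited <- array(FALSE, dim(m))
  queue <- list(occ[1, ])
  visited[occ[1, 1], occ[1, 2], occ[1, 3]] <- TRUE
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    for (d in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                   c(0,0,1), c(0,0,-1))) {
      w <- v + d
      if (all(w >= 1) && all(w <= 24) && m[w[1], w[2], w[3]] == 1L &&
          !visited[w[1], w[2], w[3]]) {
        visited[w[1], w[2], w[3]] <- TRUE
        queue[[length(queue) + 1]] <- w
      }
    }
  }
  expect_equal(sum(visited), sum(m))
})

test_that("phantom composition assigns unique labels to every overlap", {
  # empty mask list: homogeneous background only
  set.seed(2)
  ph <- compose_phantom(list(), grid_shape = c(10, 10, 10))
  expect_s3_class(ph, "mc_phantom")
  expect_equal(unique(as.integer(ph$label_grid)), 0L)
  expect_equal(nrow(ph$properties), 1)

  # two overlapping boxes: intersection gets label 1 + 2 = 3
  m1 <- array(0L, c(10, 10, 10)); m1[1:6, , ] <- 1L
  m2 <- array(0L, c(10, 10, 10)); m2[4:10, , ] <- 1L
  ph <- compose_phantom(list(m1, m2))
  expect_setequal(unique(as.integer(ph$label_grid)), c(1L, 3L, 2L))
  expect_equal(unique(as.integer(ph$label_grid[4:6, , ])), 3L)

  # three mutually overlapping boxes: labels are the subset sums
  m3 <- array(0L, c(10, 10, 10)); m3[5, 5, ] <- 1L
  m1[, , ] <- 0L; m1[3:7, 3:7, ] <- 1L
  m2[, , ] <- 0L; m2[5:9, 5:9, ] <- 1L
  ph <- compose_phantom(list(m1, m2, m3))
  labs <- sort(unique(as.integer(ph$label_grid)))
  expect_true(all(labs %in% 0:7))
  expect_true(7L %in% labs)   # triple overlap at (5, 5, z)
  expect_true(all(labs %in% ph$properties$label))

  expect_error(compose_phantom(list(m1, array(0L, c(5, 5, 5)))),
               "mismatched")
  expect_error(compose_phantom(rep(list(m1), 5)), "at most 4")
})

test_that("optical property draws respect the tissue distributions", {
  set.seed(5)
  p <- sample_optical_properties(1e4)
  expect_true(all(p$g >= 0.9 & p$g < 1))
  expect_true(all(p$n >= 1 & p$n <= 10))
  expect_true(all(p$mua >= 0))
  expect_true(all(p$mus >= 0))
  expect_true(all(p$mus >= p$musp)) # mus = musp / (1 - g), g >= 0.9

  # folded-normal oracle: E|N(1,1)| = sqrt(2/pi) e^{-1/2} + 1 - 2 pnorm(-1)
  set.seed(6)
  musp <- sample_optical_properties(1e5)$musp
  expected <- sqrt(2 / pi) * exp(-0.5) + (1 - 2 * pnorm(-1))
  se <- sd(musp) / sqrt(length(musp))
  expect_lt(abs(mean(musp) - expected), 3 * se)

  # narrowed refractive-index override
  set.seed(7)
  p <- sample_optical_properties(100, n_range = c(1.33, 1.5))
  expect_true(all(p$n >= 1.33 & p$n <= 1.5))
})

test_that("simulation configs place sources inside and gate in [0.1, 1] ns", {
  ph <- homogeneous_phantom(12)
  set.seed(8)
  for (i in 1:200) {
    cfg <- sample_simulation_config(ph)
    expect_true(all(cfg$source$position > 0 & cfg$source$position < 12))
    expect_true(cfg$time_gate_ns >= 0.1 && cfg$time_gate_ns <= 1)
  }
  set.seed(9); a <- sample_simulation_config(ph)
  set.seed(9); b <- sample_simulation_config(ph)
  expect_identical(a, b)
})

test_that("generated datasets are deterministic and label-closed", {
  d1 <- file.path(tempdir(), "gen1"); d2 <- file.path(tempdir(), "gen2")
  on.exit(unlink(c(d1, d2), recursive = TRUE), add = TRUE)
  generate_dataset(3, grid_shape = c(12, 12, 12), seed = 42, out_dir = d1)
  generate_dataset(3, grid_shape = c(12, 12, 12), seed = 42, out_dir = d2)
  expect_identical(readLines(file.path(d1, "manifest.json")),
                   readLines(file.path(d2, "manifest.json")))
  # phantom round trip + label closure over a batch of seeded phantoms
  for (f in list.files(d1, pattern = "\\.nii$", full.names = TRUE)) {
    ph <- read_phantom(f)
    expect_true(all(unique(as.integer(ph$label_grid)) %in%
                      ph$properties$label))
  }
  set.seed(31)
  for (i in 1:40) {
    n_shapes <- sample(0:4, 1)
    masks <- list()
    if (n_shapes > 0)
      for (j in seq_len(n_shapes)) {
        sp <- sample_shape(c(16, 16, 16))
        masks[[j]] <- if (sp$kind == "polyhedron")
          rasterize_polyhedron(sp, c(16, 16, 16))
        else rasterize_letter(sp, c(16, 16, 16))
      }
    ph <- compose_phantom(masks, grid_shape = c(16, 16, 16))
    expect_true(all(unique(as.integer(ph$label_grid)) %in%
                      ph$properties$label))
  }
})

test_that("single-domain dataset with no shapes is homogeneous", {
  d <- file.path(tempdir(), "gen0")
  on.exit(unlink(d, recursive = TRUE), add = TRUE)
  generate_dataset(1, grid_shape = c(12, 12, 12), seed = 3, out_dir = d,
                   n_shapes = 0)
  ph <- read_phantom(file.path(d, "phantom_001.nii"))
  expect_equal(unique(as.integer(ph$label_grid)), 0L)
})
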