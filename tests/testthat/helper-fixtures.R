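# Shared fixtures built in code at test time.

# homogeneous phantom with fixed tissue-like optics
homogeneous_phantom <- function(n = 20, mua = 0.01, musp = 1, g = 0.9,
                                n_idx = 1.37) {
  ph <- compose_phantom(list(), grid_shape = c(n, n, n))
  ph$properties$mua <- mua
  ph$properties$musp <- musp
  ph$properties$g <- g
  ph$properties$mus <- musp / (1 - g)
  ph$properties$n <- n_idx
  ph
}

# a shape_spec built by hand (identity pose) around a given point set
manual_polyhedron <- function(points) {
  structure(list(kind = "polyhedron", rotation = diag(3),
                 translation = c(0, 0, 0), n_points = nrow(points),
                 sphere_center = colMeans(points), sphere_radius = NA_real_,
                 points = points),
            class = "shape_spec")
}

manual_letter <- function(ch, grid_shape, font_size, thickness,
                          angle2d = 0, rotation = diag(3),
                          translation = c(0, 0, 0)) {
  structure(list(kind = "ascii-letter", rotation = rotation,
                 translation = translation, character = ch,
                 font_size = font_size, angle2d = angle2d,
                 thickness = thickness),
            class = "shape_spec")
}

# small denoiser specs used throughout the model/training tests
tiny_global <- function() global_stage_spec(depth = 4, width = 8)
tiny_local <- function() local_stage_spec(n_scales = 2, base_width = 4)

# miniature simulated-fluence catalog, built once per test session
fixture_catalog <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_fixtures(seed = 77, n_domains = 3,
                              grid_shape = c(16, 16, 16),
                              photon_levels = c(1e2, 1e3, 1e4))
    cache
  }
})
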