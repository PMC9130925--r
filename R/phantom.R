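#' Sample random optical properties for one tissue label
#'
#' Draws absorption, scattering anisotropy, reduced scattering and refractive
#' index from distributions spanning the range of biological tissues:
#' \eqn{\mu_a = |N(0.01, 0.05)|} per mm, \eqn{g \sim U[0.9, 1)},
#' \eqn{\mu_s' = |N(1, 1)|} per mm with \eqn{\mu_s = \mu_s'/(1-g)}, and
#' \eqn{n \sim U[1, 10]} by default.  The refractive-index range is far wider
#' than real tissue (n of 1.33 to 1.5); it is kept as the generator's default
#' to exercise strong internal refraction, and can be narrowed via
#' \code{n_range}.
#'
#' @param n_draws number of property sets to draw
#' @param n_range length-2 numeric range for the refractive index
#' @return data.frame with columns \code{mua}, \code{mus}, \code{musp},
#'   \code{g}, \code{n}
#' @export
sample_optical_properties <- function(n_draws = 1, n_range = c(1, 10)) {
  stopifnot(n_draws >= 1, length(n_range) == 2, n_range[1] >= 1)
  mua <- abs(rnorm(n_draws, 0.01, 0.05))
  g <- runif(n_draws, 0.9, 1)
  musp <- abs(rnorm(n_draws, 1, 1))
  data.frame(mua = mua, mus = musp / (1 - g), musp = musp, g = g,
             n = runif(n_draws, n_range[1], n_range[2]))
}

# uniform random rotation matrix (uniform over SO(3) via random unit quaternion)
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  quat_to_mat(q)
}

quat_to_mat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# uniform-area random points on the unit sphere (random equidistribution:
# cos(theta) uniform on [-1,1], azimuth uniform)
sphere_points <- function(n) {
  cz <- runif(n, -1, 1)
  ph <- runif(n, 0, 2 * pi)
  sz <- sqrt(pmax(0, 1 - cz^2))
  cbind(sz * cos(ph), sz * sin(ph), cz)
}

#' Sample a random inclusion shape
#'
#' Draws either a random convex polyhedron (4 to 10 points on a random
#' sphere) or a random extruded ASCII letter, with equal probability, fully
#' parameterized: random 3D rotation (uniform over rotations), translation,
#' and for letters a random glyph, font size, in-plane angle and extrusion
#' thickness.
#'
#' @param grid_shape integer length-3 grid dimensions (all >= 8)
#' @param voxel_size isotropic voxel edge length in mm
#' @param kind optional; force \code{"polyhedron"} or \code{"ascii-letter"}
#' @return an object of class \code{shape_spec}
#' @export
sample_shape <- function(grid_shape, voxel_size = 1, kind = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 8))
    stop("grid_shape must have three dimensions, all >= 8")
  if (is.null(kind))
    kind <- if (runif(1) < 0.5) "polyhedron" else "ascii-letter"
  kind <- match.arg(kind, c("polyhedron", "ascii-letter"))
  extent <- grid_shape * voxel_size
  spec <- list(kind = kind,
               rotation = random_rotation(),
               translation = runif(3, -0.1, 0.1) * extent)
  if (kind == "polyhedron") {
    n_pts <- sample(4:10, 1)
    center <- runif(3, 0.25, 0.75) * extent
    radius <- runif(1, 0.10, 0.30) * min(extent)
    # resample until the point set spans 3 dimensions (bounded retries)
    for (try in 1:10) {
      pts <- sphere_points(n_pts)
      if (point_rank(pts) == 3) break
    }
    spec$n_points <- n_pts
    spec$sphere_center <- center
    spec$sphere_radius <- radius
    spec$points <- sweep(pts * radius, 2, center, `+`)
  } else {
    spec$character <- sample(c(LETTERS, letters), 1)
    spec$font_size <- runif(1, 0.30, 0.70) * min(grid_shape[1:2]) # voxels
    spec$angle2d <- runif(1, 0, 360)
    max_t <- max(1L, as.integer(round(0.4 * grid_shape[3])))
    spec$thickness <- sample(seq_len(max_t), 1)
  }
  structure(spec, class = "shape_spec")
}

point_rank <- function(pts) {
  ctr <- sweep(pts, 2, colMeans(pts))
  sv <- svd(ctr)$d
  sum(sv > max(sv) * 1e-8)
}

# voxel-center coordinates (mm) for a grid; centers at (i - 0.5) * h
voxel_centers_1d <- function(n, h) (seq_len(n) - 0.5) * h

# supporting half-spaces of the convex hull of a small 3D point set, found by
# brute force over point triples; rows are (nx, ny, nz, d) with inside
# meaning n.p <= d
hull_planes <- function(pts) {
  n <- nrow(pts)
  if (n < 4 || point_rank(pts) < 3)
    stop("polyhedron points are degenerate (fewer than 4 non-coplanar points)")
  ctr <- colMeans(pts)
  planes <- list()
  scale <- max(dist(pts))
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    nrm <- crossprod3(pts[j, ] - pts[i, ], pts[k, ] - pts[i, ])
    len <- sqrt(sum(nrm^2))
    if (len < 1e-10 * scale^2) next
    nrm <- nrm / len
    d <- sum(nrm * pts[i, ])
    if (sum(nrm * ctr) > d) { nrm <- -nrm; d <- -d }
    offs <- pts %*% nrm - d
    if (all(offs <= 1e-9 * scale)) planes[[length(planes) + 1]] <- c(nrm, d)
  }
  do.call(rbind, planes)
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rasterize a convex polyhedron shape into a binary voxel mask
#'
#' The point set is rotated about its sphere center, translated, and its
#' convex hull is voxelized: a voxel belongs to the shape iff its center lies
#' inside (or on) the hull.
#'
#' @param spec a \code{shape_spec} with \code{kind == "polyhedron"}
#' @param grid_shape integer length-3 grid dimensions
#' @param voxel_size voxel edge length in mm
#' @return 3D integer array of 0/1
#' @export
rasterize_polyhedron <- function(spec, grid_shape, voxel_size = 1) {
  stopifnot(inherits(spec, "shape_spec"), spec$kind == "polyhedron")
  grid_shape <- as.integer(grid_shape)
  pts <- spec$points
  ctr <- spec$sphere_center
  pts <- sweep(sweep(pts, 2, ctr) %*% t(spec$rotation), 2,
               ctr + spec$translation, `+`)
  planes <- hull_planes(pts)
  mask <- array(0L, grid_shape)
  lo <- pmax(1L, as.integer(floor(apply(pts, 2, min) / voxel_size)) + 1L)
  hi <- pmin(grid_shape, as.integer(ceiling(apply(pts, 2, max) / voxel_size)))
  if (any(lo > hi)) return(mask)
  xs <- voxel_centers_1d(grid_shape[1], voxel_size)[lo[1]:hi[1]]
  ys <- voxel_centers_1d(grid_shape[2], voxel_size)[lo[2]:hi[2]]
  zs <- voxel_centers_1d(grid_shape[3], voxel_size)[lo[3]:hi[3]]
  ctrs <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  inside <- rep(TRUE, nrow(ctrs))
  eps <- 1e-9 * max(1, max(abs(pts)))
  for (r in seq_len(nrow(planes))) {
    inside <- inside & (ctrs %*% planes[r, 1:3] <= planes[r, 4] + eps)
    if (!any(inside)) break
  }
  sub <- array(as.integer(inside), dim = c(length(xs), length(ys), length(zs)))
  mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub
  mask
}

# Render one character as a binary 2D matrix on an nx-by-ny canvas using the
# R graphics engine (cairo PNG device, monospace family), thresholded at 50%
# coverage.  Glyph height is calibrated to font_size pixels; srt applies the
# in-plane rotation.
render_glyph <- function(ch, nx, ny, font_size, angle = 0) {
  tf <- tempfile(fileext = ".png")
  on.exit(unlink(tf), add = TRUE)
  ok <- tryCatch({
    grDevices::png(tf, width = nx, height = ny, type = "cairo")
    TRUE
  }, error = function(e) FALSE)
  if (!ok)
    stop("glyph rendering requires a functional cairo PNG device")
  par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  plot.new()
  plot.window(c(0, nx), c(0, ny))
  h1 <- strheight(ch, cex = 1, family = "mono", font = 2)
  cex <- if (h1 > 0) 0.72 * font_size / h1 else 1
  text(nx / 2, ny / 2, ch, cex = cex, family = "mono", font = 2, srt = angle)
  dev.off()
  img <- png::readPNG(tf)
  gr <- if (length(dim(img)) == 3) apply(img[, , 1:3, drop = FALSE], c(1, 2), mean) else img
  # PNG rows run top-to-bottom; flip to y-up and transpose to (x, y)
  m <- t(gr[rev(seq_len(nrow(gr))), , drop = FALSE])
  (m < 0.5) * 1L
}

#' Rasterize an extruded ASCII letter into a binary voxel mask
#'
#' The glyph is rendered in 2D at the requested font size and in-plane
#' rotation, thresholded, replicated along the z axis for \code{thickness}
#' slices, then rotated/translated in 3D and resampled onto the grid with
#' nearest-neighbor interpolation.
#'
#' @inheritParams rasterize_polyhedron
#' @export
rasterize_letter <- function(spec, grid_shape, voxel_size = 1) {
  stopifnot(inherits(spec, "shape_spec"), spec$kind == "ascii-letter")
  grid_shape <- as.integer(grid_shape)
  g2d <- render_glyph(spec$character, grid_shape[1], grid_shape[2],
                      spec$font_size, spec$angle2d)
  thick <- max(1L, as.integer(spec$thickness))
  vol <- array(0L, grid_shape)
  z0 <- max(1L, as.integer(round((grid_shape[3] - thick) / 2)) + 1L)
  z1 <- min(grid_shape[3], z0 + thick - 1L)
  for (z in z0:z1) vol[, , z] <- g2d
  resample_mask(vol, spec$rotation, spec$translation, voxel_size)
}

# nearest-neighbor resample of a binary volume under rotation about the grid
# center followed by translation (both in mm)
resample_mask <- function(vol, rotation, translation, voxel_size) {
  dm <- dim(vol)
  if (identical(rotation, diag(3)) && all(translation == 0)) return(vol)
  ctr <- dm * voxel_size / 2
  xs <- voxel_centers_1d(dm[1], voxel_size)
  ys <- voxel_centers_1d(dm[2], voxel_size)
  zs <- voxel_centers_1d(dm[3], voxel_size)
  grid <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  # inverse map: undo translation, rotate back about the center
  src <- sweep(sweep(grid, 2, ctr + translation) %*% rotation, 2, ctr, `+`)
  idx <- sweep(src, 2, rep(voxel_size, 3), `/`) + 0.5
  ii <- round(idx)
  ok <- ii[, 1] >= 1 & ii[, 1] <= dm[1] & ii[, 2] >= 1 & ii[, 2] <= dm[2] &
    ii[, 3] >= 1 & ii[, 3] <= dm[3]
  out <- integer(nrow(grid))
  lin <- (ii[ok, 3] - 1) * dm[1] * dm[2] + (ii[ok, 2] - 1) * dm[1] + ii[ok, 1]
  out[ok] <- vol[lin]
  array(out, dm)
}

#' Compose binary shape masks into a labeled phantom
#'
#' Each mask is multiplied by a distinct power-of-two coefficient and the
#' results are accumulated, so every overlap pattern of shapes receives its
#' own unique label (new inclusions are created wherever shapes intersect).
#' Every resulting label, including the background (0), gets independently
#' sampled optical properties.
#'
#' @param masks list of 0 to 4 binary 3D arrays of identical shape
#' @param grid_shape grid dimensions (used when \code{masks} is empty)
#' @param voxel_size voxel edge length in mm
#' @param n_range refractive-index sampling range passed to
#'   \code{\link{sample_optical_properties}}
#' @return an object of class \code{mc_phantom}
#' @export
compose_phantom <- function(masks, grid_shape = NULL, voxel_size = 1,
                            n_range = c(1, 10)) {
  if (length(masks) > 4) stop("at most 4 shape masks are supported")
  if (length(masks) == 0) {
    if (is.null(grid_shape)) stop("grid_shape required when masks is empty")
    acc <- array(0L, as.integer(grid_shape))
  } else {
    dm <- dim(masks[[1]])
    for (m in masks)
      if (!identical(dim(m), dm)) stop("shape masks have mismatched dimensions")
    acc <- array(0L, dm)
    for (i in seq_along(masks))
      acc <- acc + as.integer(2^(i - 1)) * (masks[[i]] != 0L)
  }
  labels <- sort(unique(as.integer(acc)))
  if (!0L %in% labels) labels <- c(0L, labels)
  props <- sample_optical_properties(length(labels), n_range = n_range)
  props <- cbind(label = labels, props)
  structure(list(label_grid = acc, properties = props,
                 voxel_size = voxel_size),
            class = "mc_phantom")
}

#' @export
print.mc_phantom <- function(x, ...) {
  dm <- dim(x$label_grid)
  cat(sprintf("Voxel phantom: %d x %d x %d grid, %.3g mm voxels, %d label(s)\n",
              dm[1], dm[2], dm[3], x$voxel_size, nrow(x$properties)))
  print(x$properties, row.names = FALSE)
  invisible(x)
}

#' Sample a source and time gate for a phantom
#'
#' Places an isotropic point source uniformly at random strictly inside the
#' domain and draws a continuous-wave time-gate length uniformly between 0.1
#' and 1 ns.
#'
#' @param phantom an \code{mc_phantom}
#' @return list with \code{source} (a \code{source_spec}) and
#'   \code{time_gate_ns}
#' @export
sample_simulation_config <- function(phantom) {
  stopifnot(inherits(phantom, "mc_phantom"))
  extent <- dim(phantom$label_grid) * phantom$voxel_size
  pos <- runif(3, 0.01, 0.99) * extent
  list(source = source_spec("isotropic", pos),
       time_gate_ns = runif(1, 0.1, 1))
}

#' Construct a light-source specification
#'
#' @param kind \code{"isotropic"} or \code{"pencil"}
#' @param position length-3 position in mm
#' @param direction unit direction (pencil sources only)
#' @export
source_spec <- function(kind = c("isotropic", "pencil"), position,
                        direction = c(0, 0, 1)) {
  kind <- match.arg(kind)
  stopifnot(length(position) == 3)
  if (kind == "pencil") {
    nrm <- sqrt(sum(direction^2))
    if (abs(nrm - 1) > 1e-6) direction <- direction / nrm
  }
  structure(list(kind = kind, position = as.numeric(position),
                 direction = as.numeric(direction)), class = "source_spec")
}

# one fully random phantom + simulation configuration
random_domain <- function(grid_shape, voxel_size = 1, n_shapes = NULL,
                          n_range = c(1, 10)) {
  if (is.null(n_shapes)) n_shapes <- sample(0:4, 1)
  masks <- list()
  if (n_shapes > 0) {
    for (i in seq_len(n_shapes)) {
      sp <- sample_shape(grid_shape, voxel_size)
      masks[[i]] <- if (sp$kind == "polyhedron")
        rasterize_polyhedron(sp, grid_shape, voxel_size)
      else rasterize_letter(sp, grid_shape, voxel_size)
    }
  }
  ph <- compose_phantom(masks, grid_shape, voxel_size, n_range = n_range)
  cfg <- sample_simulation_config(ph)
  list(phantom = ph, source = cfg$source, time_gate_ns = cfg$time_gate_ns)
}

#' Generate a catalog of random simulation domains
#'
#' Produces \code{n_domains} random phantoms with per-domain source
#' placements, time gates and seeds, saves each phantom (NIfTI label grid +
#' JSON property sidecar) under \code{out_dir}, and writes a JSON manifest.
#' Fully deterministic under \code{seed}.
#'
#' @param n_domains number of domains (>= 1)
#' @param grid_shape grid dimensions (training default 64^3; validation data
#'   in the reference protocol uses 128^3)
#' @param voxel_size voxel edge length in mm
#' @param seed integer seed
#' @param out_dir output directory (created if needed)
#' @param n_shapes optional fixed number of shapes per domain (otherwise
#'   uniform on 0..4)
#' @param n_range refractive-index sampling range
#' @return the manifest, invisibly (list; also written to
#'   \code{out_dir/manifest.json})
#' @export
generate_dataset <- function(n_domains, grid_shape = c(64, 64, 64),
                             voxel_size = 1, seed = 1, out_dir,
                             n_shapes = NULL, n_range = c(1, 10)) {
  stopifnot(n_domains >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  domains <- vector("list", n_domains)
  for (i in seq_len(n_domains)) {
    dom <- random_domain(grid_shape, voxel_size, n_shapes, n_range)
    dom_seed <- sample.int(2L^30L, 1) # headroom for derived per-level seeds
    base <- sprintf("phantom_%03d", i)
    ph_path <- file.path(out_dir, paste0(base, ".nii"))
    write_phantom(dom$phantom, ph_path)
    domains[[i]] <- list(id = i, phantom_path = basename(ph_path),
                         properties_path = paste0(base, ".json"),
                         source = list(kind = dom$source$kind,
                                       position = dom$source$position),
                         time_gate_ns = dom$time_gate_ns, seed = dom_seed)
  }
  manifest <- list(seed = seed, grid_shape = as.integer(grid_shape),
                   voxel_size_mm = voxel_size, n_domains = n_domains,
                   domains = domains)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
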