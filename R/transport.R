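#' Sample the Henyey-Greenstein deflection cosine
#'
#' Inverse-CDF sampling of the Henyey-Greenstein phase function with
#' anisotropy \code{g}; for \code{g = 0} this reduces to the isotropic
#' \code{2u - 1}.
#'
#' @param g scattering anisotropy, in (-1, 1)
#' @param u uniform deviates in [0, 1)
#' @return deflection cosines in [-1, 1]
#' @export
hg_sample <- function(g, u) .hg_sample_cpp(g, as.numeric(u))

#' Construct a simulation specification
#'
#' @param photon_count number of photon packets (>= 1)
#' @param seed integer run seed; fully determines the output
#' @param time_gate_ns continuous-wave time gate in ns; photons are scored
#'   only up to this time-of-flight
#' @param boundary \code{"fresnel"} (reflection/refraction against external
#'   n = 1 at the domain faces) or \code{"absorbing"}
#' @param roulette enable Russian roulette termination of low-weight packets
#' @param roulette_threshold packet weight below which roulette is played
#' @param roulette_survival survival probability (survivors' weight is
#'   boosted by its inverse)
#' @return an object of class \code{simulation_spec}
#' @export
simulation_spec <- function(photon_count = 1e4, seed = 1, time_gate_ns = 1,
                            boundary = c("fresnel", "absorbing"),
                            roulette = TRUE, roulette_threshold = 1e-4,
                            roulette_survival = 0.1) {
  boundary <- match.arg(boundary)
  stopifnot(photon_count >= 1, time_gate_ns > 0,
            roulette_survival > 0, roulette_survival <= 1)
  structure(list(photon_count = photon_count, seed = as.integer(seed),
                 time_gate_ns = time_gate_ns, boundary = boundary,
                 roulette = roulette,
                 roulette_threshold = roulette_threshold,
                 roulette_survival = roulette_survival),
            class = "simulation_spec")
}

fluence_volume <- function(values, voxel_size, photon_count = NA_real_,
                           seed = NA_integer_, time_gate_ns = NA_real_) {
  structure(list(values = values, voxel_size = voxel_size,
                 photon_count = photon_count, seed = seed,
                 time_gate_ns = time_gate_ns),
            class = "fluence_volume")
}

#' @export
print.fluence_volume <- function(x, ...) {
  dm <- dim(x$values)
  cat(sprintf(paste0("Fluence volume: %d x %d x %d, %.3g mm voxels, ",
                     "%g photons (seed %s)\n  range [%.4g, %.4g] /mm^2 ",
                     "per photon\n"),
              dm[1], dm[2], dm[3], x$voxel_size, x$photon_count,
              as.character(x$seed), min(x$values), max(x$values)))
  invisible(x)
}

#' Run one Monte Carlo fluence simulation
#'
#' Propagates photon packets through the voxelized phantom with exponential
#' step sampling against the local scattering coefficient,
#' Henyey-Greenstein scattering, continuous absorption weighting, Fresnel
#' reflection/refraction at refractive-index mismatches across axis-aligned
#' voxel faces, and a continuous-wave time gate.  Fluence is scored as
#' deposited energy per voxel divided by (mua * voxel volume * photon
#' count); zero-absorption voxels fall back to the equivalent path-length
#' estimator.  Deterministic under the run seed.
#'
#' @param phantom an \code{mc_phantom}
#' @param source a \code{source_spec} positioned inside the grid
#' @param spec a \code{simulation_spec}
#' @return list with \code{fluence} (a \code{fluence_volume}) and
#'   \code{stats} (launched/absorbed/escaped/gated/residual weights)
#' @export
simulate_fluence <- function(phantom, source, spec) {
  stopifnot(inherits(phantom, "mc_phantom"), inherits(source, "source_spec"),
            inherits(spec, "simulation_spec"))
  dm <- dim(phantom$label_grid)
  h <- phantom$voxel_size
  extent <- dm * h
  if (any(source$position <= 0) || any(source$position >= extent))
    stop("source position must lie strictly inside the domain")
  props <- phantom$properties
  labs <- sort(unique(as.integer(phantom$label_grid)))
  if (!all(labs %in% props$label))
    stop("phantom labels without optical properties: ",
         paste(setdiff(labs, props$label), collapse = ", "))
  # map grid labels onto 0-based rows of the property table
  lut <- match(as.integer(phantom$label_grid), props$label) - 1L
  res <- .mc_simulate_cpp(lut, as.integer(dm), h,
                          as.numeric(props$mua), as.numeric(props$mus),
                          as.numeric(props$g), as.numeric(props$n),
                          as.numeric(source$position),
                          as.integer(source$kind == "isotropic"),
                          as.numeric(source$direction),
                          as.numeric(spec$photon_count),
                          spec$time_gate_ns,
                          as.integer(spec$boundary == "fresnel"),
                          as.integer(spec$roulette),
                          spec$roulette_threshold, spec$roulette_survival,
                          as.numeric(spec$seed))
  vals <- array(res$fluence_raw / (h^3 * spec$photon_count), dim = dm)
  stats <- list(total_launched_weight = res$launched,
                total_absorbed_weight = res$absorbed,
                total_escaped_weight = res$escaped,
                total_time_gated_out_weight = res$gated,
                live_residual_weight = res$residual)
  list(fluence = fluence_volume(vals, h, spec$photon_count, spec$seed,
                                spec$time_gate_ns),
       stats = stats)
}

#' Run independently seeded repetitions of a simulation
#'
#' Seeds run from \code{base_seed} upward in steps of one; the returned list
#' is ordered by repetition index.
#'
#' @inheritParams simulate_fluence
#' @param n_reps number of repetitions (>= 2; the reference protocol uses
#'   100)
#' @param base_seed seed of the first repetition
#' @return list of \code{fluence_volume} objects
#' @export
run_repetitions <- function(phantom, source, spec, n_reps = 100,
                            base_seed = spec$seed) {
  stopifnot(n_reps >= 2)
  out <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    sp <- spec
    sp$seed <- as.integer(base_seed + i - 1L)
    r <- tryCatch(simulate_fluence(phantom, source, sp),
                  error = function(e)
                    stop("repetition ", i, ": ", conditionMessage(e)))
    out[[i]] <- r$fluence
  }
  out
}

# default benchmark optical properties (the cube benchmarks reference
# externally published coefficients; these defaults are configurable and no
# quantitative check depends on their exact values)
benchmark_defaults <- function() {
  list(background = list(mua = 0.005, musp = 1, g = 0.9, n = 1.37),
       absorber = list(mua = 0.05, musp = 1, g = 0.9, n = 1.37),
       refractive = list(mua = 0.005, musp = 1, g = 0.9, n = 1.0))
}

#' Construct a scaled standard cube benchmark
#'
#' Three standard benchmark domains: \code{b1} a homogeneous
#' 100x100x100 mm cube (1-mm voxels), \code{b2} the same cube with a
#' centered 40x40x40 mm cubic absorber, and \code{b3} the same cube with a
#' centered refractive inclusion.  \code{scale_factor} shrinks every linear
#' dimension for desk-scale runs.
#'
#' @param name one of \code{"b1"}, \code{"b2"}, \code{"b3"}
#' @param scale_factor linear scaling in (0, 1]
#' @param properties optional override of \code{benchmark_defaults()}
#' @param photon_count,seed,time_gate_ns passed into the returned
#'   \code{simulation_spec}
#' @return list with \code{phantom}, \code{source} (isotropic, at the domain
#'   center) and \code{spec}
#' @export
benchmark_domain <- function(name, scale_factor = 1,
                             properties = benchmark_defaults(),
                             photon_count = 1e4, seed = 1,
                             time_gate_ns = 1) {
  if (!name %in% c("b1", "b2", "b3"))
    stop("unknown benchmark '", name, "'; valid names: b1, b2, b3")
  stopifnot(scale_factor > 0, scale_factor <= 1)
  n <- max(8L, as.integer(round(100 * scale_factor)))
  grid <- array(0L, c(n, n, n))
  bg <- properties$background
  prop_rows <- data.frame(label = 0L, mua = bg$mua,
                          mus = bg$musp / (1 - bg$g), musp = bg$musp,
                          g = bg$g, n = bg$n)
  if (name != "b1") {
    side <- max(2L, as.integer(round(40 * scale_factor)))
    lo <- as.integer(floor((n - side) / 2)) + 1L
    hi <- lo + side - 1L
    grid[lo:hi, lo:hi, lo:hi] <- 1L
    inc <- if (name == "b2") properties$absorber else properties$refractive
    prop_rows <- rbind(prop_rows,
                       data.frame(label = 1L, mua = inc$mua,
                                  mus = inc$musp / (1 - inc$g),
                                  musp = inc$musp, g = inc$g, n = inc$n))
  }
  phantom <- structure(list(label_grid = grid, properties = prop_rows,
                            voxel_size = 1), class = "mc_phantom")
  list(phantom = phantom,
       source = source_spec("isotropic", rep(n / 2, 3)),
       spec = simulation_spec(photon_count = photon_count, seed = seed,
                              time_gate_ns = time_gate_ns))
}
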