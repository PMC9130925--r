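# End-to-end orchestration: generate -> simulate -> train -> denoise ->
# evaluate, with per-stage seeds derived deterministically from the global
# seed and provenance sidecars (config hash + stage seed) next to every
# stage's outputs.

fluence_filename <- function(domain_id, photons)
  sprintf("fluence_dom%03d_n%g.nii", domain_id, photons)

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tf))
}

write_provenance <- function(dir, stage, config, seed) {
  jsonlite::write_json(
    list(stage = stage, config_hash = config_hash(config),
         stage_seed = seed,
         package_version = as.character(utils::packageVersion("mcdenoise"))),
    file.path(dir, paste0(stage, "_provenance.json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Default pipeline configuration
#'
#' @param seed global seed; every stage seed is derived from it
#' @param out_dir run directory
#' @param n_domains,grid_shape,voxel_size,n_shapes generator settings
#' @param photon_levels ascending photon counts simulated per domain (the
#'   highest level is the clean/ground-truth level)
#' @param time_gate_override optional fixed time gate (ns) replacing the
#'   per-domain sampled gates
#' @param stages character subset of
#'   \code{c("generate", "simulate", "train", "evaluate")}
#' @param architecture,global_spec,local_spec denoiser settings
#' @param train train-stage settings (a \code{\link{train_config}})
#' @export
pipeline_config <- function(seed = 1, out_dir = tempfile("mcdn_run_"),
                            n_domains = 6, grid_shape = c(24, 24, 24),
                            voxel_size = 1, n_shapes = NULL,
                            photon_levels = c(1e2, 1e3, 1e4),
                            time_gate_override = NULL,
                            stages = c("generate", "simulate", "train",
                                       "evaluate"),
                            architecture = "cascade",
                            global_spec = global_stage_spec(depth = 5,
                                                            width = 8),
                            local_spec = local_stage_spec(n_scales = 2,
                                                          base_width = 8),
                            train = train_config()) {
  stopifnot(length(photon_levels) >= 2, !is.unsorted(photon_levels))
  list(seed = seed, out_dir = out_dir, n_domains = n_domains,
       grid_shape = grid_shape, voxel_size = voxel_size,
       n_shapes = n_shapes, photon_levels = photon_levels,
       time_gate_override = time_gate_override, stages = stages,
       architecture = architecture, global_spec = global_spec,
       local_spec = local_spec, train = train)
}

#' Run the simulation/training/evaluation pipeline
#'
#' Executes the requested stages in order inside the configured run
#' directory.  Every stage writes a provenance sidecar naming the config
#' hash and its seed; a rerun with the same configuration reproduces the
#' same artifacts.
#'
#' @param config a \code{\link{pipeline_config}} (or path to a JSON file
#'   with the same fields)
#' @return the run directory, invisibly; stage outputs live beneath it
#'   (\code{phantoms/}, \code{fluence/}, \code{model/}, \code{reports/})
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) {
    raw <- jsonlite::read_json(config, simplifyVector = TRUE)
    config <- do.call(pipeline_config, raw[setdiff(names(raw), "stages")])
    config$stages <- raw$stages %||% config$stages
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_fail <- function(stage, e)
    stop("pipeline stage '", stage, "' failed in ", config$out_dir, ": ",
         conditionMessage(e), call. = FALSE)

  ph_dir <- file.path(config$out_dir, "phantoms")
  fl_dir <- file.path(config$out_dir, "fluence")
  manifest_path <- file.path(ph_dir, "manifest.json")

  if ("generate" %in% config$stages) {
    tryCatch({
      generate_dataset(config$n_domains, config$grid_shape,
                       config$voxel_size, seed = config$seed,
                       out_dir = ph_dir, n_shapes = config$n_shapes)
      write_provenance(ph_dir, "generate", config, config$seed)
    }, error = function(e) stage_fail("generate", e))
  }

  if ("simulate" %in% config$stages) {
    tryCatch({
      dir.create(fl_dir, showWarnings = FALSE)
      manifest <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
      for (dom in manifest$domains) {
        ph <- read_phantom(file.path(ph_dir, dom$phantom_path))
        src <- source_spec(dom$source$kind, unlist(dom$source$position))
        gate <- config$time_gate_override %||% dom$time_gate_ns
        for (li in seq_along(config$photon_levels)) {
          lev <- config$photon_levels[li]
          spec <- simulation_spec(photon_count = lev,
                                  seed = dom$seed + li,
                                  time_gate_ns = gate)
          res <- simulate_fluence(ph, src, spec)
          write_fluence(res$fluence,
                        file.path(fl_dir, fluence_filename(dom$id, lev)))
        }
      }
      write_provenance(fl_dir, "simulate", config, config$seed)
    }, error = function(e) stage_fail("simulate", e))
  }

  if ("train" %in% config$stages) {
    tryCatch({
      md_dir <- file.path(config$out_dir, "model")
      dir.create(md_dir, showWarnings = FALSE)
      levels <- config$photon_levels
      clean <- levels[length(levels)]
      noisy <- levels[-length(levels)]
      set.seed(config$seed + 1L)
      pairs <- assemble_dataset(fl_dir, manifest_path, noisy, clean)
      n_val <- max(1, round(0.25 * length(pairs)))
      val_idx <- seq_len(n_val)
      model <- mc_denoiser(config$architecture, config$global_spec,
                           config$local_spec, seed = config$seed + 2L)
      fit <- train_denoiser(model, pairs[-val_idx], pairs[val_idx],
                            config$train)
      save_checkpoint(fit$model, file.path(md_dir, "checkpoint.json"))
      utils::write.csv(data.frame(epoch = fit$history$epoch,
                                  train_loss = fit$history$train_loss,
                                  val_mse = fit$history$val_mse,
                                  val_ssim = fit$history$val_ssim,
                                  val_psnr = fit$history$val_psnr),
                       file.path(md_dir, "history.csv"), row.names = FALSE)
      write_provenance(md_dir, "train", config, config$seed + 1L)
    }, error = function(e) stage_fail("train", e))
  }

  if ("evaluate" %in% config$stages) {
    tryCatch({
      rp_dir <- file.path(config$out_dir, "reports")
      dir.create(rp_dir, showWarnings = FALSE)
      model <- load_checkpoint(file.path(config$out_dir, "model",
                                         "checkpoint.json"))
      manifest <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
      levels <- config$photon_levels
      clean_lev <- levels[length(levels)]
      gain <- merge_policy()$high_gain
      reports <- list()
      for (dom in manifest$domains) {
        clean <- read_fluence(file.path(fl_dir,
                                        fluence_filename(dom$id, clean_lev)))
        for (lev in levels[-length(levels)]) {
          noisy <- read_fluence(file.path(fl_dir,
                                          fluence_filename(dom$id, lev)))
          den <- predict(model, noisy)
          rep <- metrics_report(forward_log(clean, gain),
                                forward_log(den, gain),
                                metadata = list(domain = dom$id,
                                                photons = lev))
          reports[[length(reports) + 1]] <-
            c(domain = dom$id, photons = lev, mse = rep$mse,
              ssim = rep$ssim, psnr = rep$psnr)
        }
      }
      utils::write.csv(do.call(rbind, reports),
                       file.path(rp_dir, "global_metrics.csv"),
                       row.names = FALSE)
      write_provenance(rp_dir, "evaluate", config, config$seed)
    }, error = function(e) stage_fail("evaluate", e))
  }
  invisible(config$out_dir)
}

#' Build the miniature fixture catalog used by the test-suite
#'
#' Six random 24-voxel cubic domains simulated at photon levels ascending
#' tenfold (100, 1000, 10000), regenerable bit-identically from the seed.
#' This is the desk-scale stand-in for a production corpus of hundreds of
#' 64-voxel training domains.
#'
#' @param seed integer seed
#' @param out output directory
#' @param n_domains,grid_shape,photon_levels overrides of the defaults
#' @return list with \code{dir}, \code{manifest_path},
#'   \code{photon_levels}
#' @export
make_fixtures <- function(seed = 1, out = tempfile("mcdn_fixtures_"),
                          n_domains = 6, grid_shape = c(24, 24, 24),
                          photon_levels = c(1e2, 1e3, 1e4)) {
  cfg <- pipeline_config(seed = seed, out_dir = out, n_domains = n_domains,
                         grid_shape = grid_shape,
                         photon_levels = photon_levels,
                         stages = c("generate", "simulate"))
  run_pipeline(cfg)
  list(dir = out, manifest_path = file.path(out, "phantoms", "manifest.json"),
       fluence_dir = file.path(out, "fluence"),
       photon_levels = photon_levels)
}
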