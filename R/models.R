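#' Specification of the global (DnCNN-style) denoising stage
#'
#' A plain stack of 3D convolutions with batch normalization and rectifier
#' nonlinearities in the interior blocks, predicting a noise map that is
#' subtracted from the input (residual learning).  Effective at removing
#' spatially invariant noise.
#'
#' @param depth number of convolution blocks (>= 3)
#' @param width channels per interior block (>= 8)
#' @param kernel odd convolution kernel size in voxels
#' @export
global_stage_spec <- function(depth = 8, width = 32, kernel = 3) {
  stopifnot(depth >= 3, width >= 8, kernel %% 2 == 1)
  structure(list(depth = depth, width = width, kernel = kernel),
            class = "global_stage_spec")
}

#' Specification of the local (UNet-style) denoising stage
#'
#' An encoder/decoder with average pooling, transposed convolutions and
#' skip connections; batch normalization sits between the convolution,
#' transposed-convolution and pooling layers.  Captures spatially varying
#' noise left behind by the global stage.
#'
#' @param n_scales encoder/decoder levels (>= 2); spatial dims are padded
#'   internally to a multiple of \code{2^(n_scales - 1)}
#' @param base_width channels at the top level
#' @export
local_stage_spec <- function(n_scales = 3, base_width = 16) {
  stopifnot(n_scales >= 2, base_width >= 4)
  structure(list(n_scales = n_scales, base_width = base_width),
            class = "local_stage_spec")
}

add_dncnn_layers <- function(layers, spec, prefix) {
  d <- spec$depth; w <- spec$width; k <- spec$kernel
  layers[[paste0(prefix, "conv1")]] <- layer_conv(1, w, k)
  for (i in seq(2, d - 1)) {
    layers[[paste0(prefix, "conv", i)]] <- layer_conv(w, w, k)
    layers[[paste0(prefix, "bn", i)]] <- layer_bn(w)
  }
  layers[[paste0(prefix, "conv", d)]] <- layer_conv(w, 1, k, head = TRUE)
  layers
}

add_unet_layers <- function(layers, spec, prefix) {
  s <- spec$n_scales; b <- spec$base_width
  ch <- b * 2^(seq_len(s) - 1)
  for (l in seq_len(s)) {
    cin <- if (l == 1) 1 else ch[l - 1]
    layers[[paste0(prefix, "enc", l, "_convA")]] <- layer_conv(cin, ch[l], 3)
    layers[[paste0(prefix, "enc", l, "_bnA")]] <- layer_bn(ch[l])
    layers[[paste0(prefix, "enc", l, "_convB")]] <- layer_conv(ch[l], ch[l], 3)
    layers[[paste0(prefix, "enc", l, "_bnB")]] <- layer_bn(ch[l])
  }
  for (l in seq(s - 1, 1)) {
    layers[[paste0(prefix, "dec", l, "_tconv")]] <- layer_tconv(ch[l + 1], ch[l])
    layers[[paste0(prefix, "dec", l, "_bnT")]] <- layer_bn(ch[l])
    layers[[paste0(prefix, "dec", l, "_convA")]] <- layer_conv(2 * ch[l], ch[l], 3)
    layers[[paste0(prefix, "dec", l, "_bnA")]] <- layer_bn(ch[l])
    layers[[paste0(prefix, "dec", l, "_convB")]] <- layer_conv(ch[l], ch[l], 3)
    layers[[paste0(prefix, "dec", l, "_bnB")]] <- layer_bn(ch[l])
  }
  layers[[paste0(prefix, "head")]] <- layer_conv(ch[1], 1, 3, head = TRUE)
  layers
}

#' Construct a residual 3D denoiser model
#'
#' Three architectures share the same contract (log-space volume in,
#' same-shape log-space volume out):
#' \itemize{
#'   \item \code{"dncnn"}: the global stage alone, \code{m(y) = y - r(y)}
#'   \item \code{"unet"}: the local stage alone, likewise residual
#'   \item \code{"cascade"}: global stage then local stage,
#'     \code{m(y) = (y - r1(y)) - r2(y - r1(y))}; both stages learn in the
#'     residual space and are trained jointly end-to-end
#' }
#'
#' @param architecture one of \code{"cascade"}, \code{"dncnn"},
#'   \code{"unet"}
#' @param global_spec a \code{\link{global_stage_spec}}
#' @param local_spec a \code{\link{local_stage_spec}}
#' @param seed seed for parameter initialization
#' @return an object of class \code{mc_denoiser}
#' @export
mc_denoiser <- function(architecture = c("cascade", "dncnn", "unet"),
                        global_spec = global_stage_spec(),
                        local_spec = local_stage_spec(), seed = NULL) {
  architecture <- match.arg(architecture)
  if (!is.null(seed)) set.seed(seed)
  layers <- list()
  if (architecture %in% c("cascade", "dncnn"))
    layers <- add_dncnn_layers(layers, global_spec, "g_")
  if (architecture %in% c("cascade", "unet"))
    layers <- add_unet_layers(layers, local_spec, "u_")
  stride <- if (architecture == "dncnn") 1L else 2L^(local_spec$n_scales - 1L)
  structure(list(architecture = architecture,
                 global_spec = global_spec, local_spec = local_spec,
                 layers = layers, stride_multiple = stride,
                 trained = FALSE, meta = list()),
            class = "mc_denoiser")
}

#' @rdname mc_denoiser
#' @export
build_cascade <- function(global_spec = global_stage_spec(),
                          local_spec = local_stage_spec(), seed = NULL)
  mc_denoiser("cascade", global_spec, local_spec, seed = seed)

#' @rdname mc_denoiser
#' @export
build_dncnn3d <- function(global_spec = global_stage_spec(), seed = NULL)
  mc_denoiser("dncnn", global_spec = global_spec, seed = seed)

#' @rdname mc_denoiser
#' @export
build_unet3d <- function(local_spec = local_stage_spec(), seed = NULL)
  mc_denoiser("unet", local_spec = local_spec, seed = seed)

dncnn_forward <- function(model, tape, in_id, training) {
  d <- model$global_spec$depth
  id <- tp_relu(tape, tp_conv(tape, in_id, model$layers[["g_conv1"]]))
  for (i in seq(2, d - 1)) {
    id <- tp_conv(tape, id, model$layers[[paste0("g_conv", i)]])
    id <- tp_bn(tape, id, model$layers[[paste0("g_bn", i)]], training)
    id <- tp_relu(tape, id)
  }
  resid <- tp_conv(tape, id, model$layers[[paste0("g_conv", d)]])
  tp_sub(tape, in_id, resid)
}

unet_forward <- function(model, tape, in_id, training) {
  s <- model$local_spec$n_scales
  skips <- integer(s - 1)
  id <- in_id
  for (l in seq_len(s)) {
    for (half in c("A", "B")) {
      id <- tp_conv(tape, id, model$layers[[paste0("u_enc", l, "_conv", half)]])
      id <- tp_bn(tape, id, model$layers[[paste0("u_enc", l, "_bn", half)]],
                  training)
      id <- tp_relu(tape, id)
    }
    if (l < s) { skips[l] <- id; id <- tp_pool(tape, id) }
  }
  for (l in seq(s - 1, 1)) {
    id <- tp_tconv(tape, id, model$layers[[paste0("u_dec", l, "_tconv")]])
    id <- tp_bn(tape, id, model$layers[[paste0("u_dec", l, "_bnT")]], training)
    id <- tp_relu(tape, id)
    id <- tp_concat(tape, id, skips[l])
    for (half in c("A", "B")) {
      id <- tp_conv(tape, id, model$layers[[paste0("u_dec", l, "_conv", half)]])
      id <- tp_bn(tape, id, model$layers[[paste0("u_dec", l, "_bn", half)]],
                  training)
      id <- tp_relu(tape, id)
    }
  }
  resid <- tp_conv(tape, id, model$layers[["u_head"]])
  tp_sub(tape, in_id, resid)
}

# forward pass on a 5-D batch tensor; returns list(tape, out_id)
model_forward <- function(model, xb, training = FALSE) {
  tape <- tape_new()
  in_id <- tp_input(tape, xb)
  out_id <- switch(model$architecture,
    dncnn = dncnn_forward(model, tape, in_id, training),
    unet = unet_forward(model, tape, in_id, training),
    cascade = {
      mid <- dncnn_forward(model, tape, in_id, training)
      unet_forward(model, tape, mid, training)
    })
  list(tape = tape, out_id = out_id)
}

pad_to_multiple <- function(x, m) {
  d <- dim(x)
  target <- as.integer(ceiling(d[1:3] / m) * m)
  if (all(target == d[1:3])) return(list(x = x, orig = d[1:3]))
  idx <- lapply(1:3, function(a) pmin(seq_len(target[a]), d[a]))
  list(x = x[idx[[1]], idx[[2]], idx[[3]], , , drop = FALSE], orig = d[1:3])
}

#' Apply a denoiser to a log-space volume
#'
#' Whole-volume inference is the reference path; \code{tiling = "patches"}
#' trades memory for locality by processing overlapping cubic patches and
#' keeping only each patch's interior (halo cropping): every output voxel
#' is computed with at least \code{overlap/2} voxels of true context on
#' each side, so the tiled result converges to the whole-volume output as
#' the overlap approaches the network's receptive field.  Inputs whose
#' spatial dimensions are not a multiple of the model's stride are
#' replicate-padded internally and the output cropped back.
#'
#' @param model an \code{mc_denoiser}
#' @param y 3D numeric array in log space (finite everywhere)
#' @param tiling \code{"whole"} or \code{"patches"}
#' @param patch_size cubic patch edge (multiple of the model stride)
#' @param overlap patch overlap in voxels (even; the cropped halo is half
#'   of it on each side)
#' @return denoised 3D array, same shape as \code{y}
#' @export
denoise_volume <- function(model, y, tiling = c("whole", "patches"),
                           patch_size = 48, overlap = 16) {
  tiling <- match.arg(tiling)
  bad <- which(!is.finite(y))
  if (length(bad))
    stop("non-finite input at voxel index ", bad[1])
  d3 <- dim(y)
  if (tiling == "whole") {
    xb <- array(y, c(d3, 1L, 1L))
    pd <- pad_to_multiple(xb, model$stride_multiple)
    fw <- model_forward(model, pd$x, training = FALSE)
    out <- tp_value(fw$tape, fw$out_id)
    return(array(out[seq_len(d3[1]), seq_len(d3[2]), seq_len(d3[3]), 1, 1],
                 d3))
  }
  if (patch_size %% model$stride_multiple != 0)
    stop("patch_size must be a multiple of the model stride (",
         model$stride_multiple, ")")
  if (overlap %% 2 != 0) stop("overlap must be even")
  step <- patch_size - overlap
  if (step <= 0) stop("overlap must be smaller than patch_size")
  margin <- overlap %/% 2L
  starts <- function(n) {
    if (n <= patch_size) return(1L)
    s <- seq(1L, n - patch_size + 1L, by = step)
    if (tail(s, 1) != n - patch_size + 1L) s <- c(s, n - patch_size + 1L)
    s
  }
  out <- array(NA_real_, d3)
  for (sx in starts(d3[1])) for (sy in starts(d3[2])) for (sz in starts(d3[3])) {
    ex <- min(sx + patch_size - 1L, d3[1])
    ey <- min(sy + patch_size - 1L, d3[2])
    ez <- min(sz + patch_size - 1L, d3[3])
    den <- denoise_volume(model, y[sx:ex, sy:ey, sz:ez, drop = FALSE],
                          tiling = "whole")
    # keep the interior; retain the border only where the patch touches
    # the volume boundary
    kx <- (if (sx == 1) sx else sx + margin):(if (ex == d3[1]) ex else ex - margin)
    ky <- (if (sy == 1) sy else sy + margin):(if (ey == d3[2]) ey else ey - margin)
    kz <- (if (sz == 1) sz else sz + margin):(if (ez == d3[3]) ez else ez - margin)
    out[kx, ky, kz] <- den[kx - sx + 1L, ky - sy + 1L, kz - sz + 1L]
  }
  stopifnot(!anyNA(out))
  out
}

#' Denoise a fluence volume with the dual-gain procedure
#'
#' @param object a trained \code{mc_denoiser}
#' @param x a \code{fluence_volume} or non-negative 3D array
#' @param policy a \code{\link{merge_policy}}
#' @param ... unused
#' @return object of the same kind as \code{x} with denoised values
#' @export
predict.mc_denoiser <- function(object, x, policy = merge_policy(), ...) {
  out <- dual_gain_denoise(x, object, policy)
  if (inherits(x, "fluence_volume")) {
    x$values <- out
    x
  } else out
}

#' @export
print.mc_denoiser <- function(x, ...) {
  np <- sum(vapply(coef(x), length, integer(1)))
  cat(sprintf("Residual 3D denoiser (%s), %s parameters, %s\n",
              x$architecture, format(np, big.mark = ","),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' @export
summary.mc_denoiser <- function(object, ...) {
  cat(sprintf("Architecture: %s\n", object$architecture))
  if (object$architecture %in% c("cascade", "dncnn"))
    cat(sprintf("  global stage: depth %d, width %d, kernel %d\n",
                object$global_spec$depth, object$global_spec$width,
                object$global_spec$kernel))
  if (object$architecture %in% c("cascade", "unet"))
    cat(sprintf("  local stage: %d scales, base width %d\n",
                object$local_spec$n_scales, object$local_spec$base_width))
  cat(sprintf("  stride multiple: %d\n", object$stride_multiple))
  np <- sum(vapply(coef(object), length, integer(1)))
  cat(sprintf("  parameters: %s\n", format(np, big.mark = ",")))
  if (object$trained && length(object$meta)) {
    cat(sprintf("  trained: %d epochs, best epoch %d\n",
                object$meta$epochs %||% NA_integer_,
                object$meta$best_epoch %||% NA_integer_))
  }
  invisible(object)
}

#' @export
coef.mc_denoiser <- function(object, ...) {
  out <- list()
  for (nm in names(object$layers)) {
    ly <- object$layers[[nm]]
    if (ly$type %in% c("conv", "tconv")) {
      out[[paste0(nm, ".w")]] <- ly$w
      out[[paste0(nm, ".b")]] <- ly$b
    } else if (ly$type == "bn") {
      out[[paste0(nm, ".gamma")]] <- ly$gamma
      out[[paste0(nm, ".beta")]] <- ly$beta
    }
  }
  out
}

# zero all residual heads: the model becomes an exact pass-through
zero_residual_heads <- function(model) {
  for (nm in names(model$layers)) {
    ly <- model$layers[[nm]]
    if (ly$type == "conv" && isTRUE(ly$head)) {
      ly$w[] <- 0
      ly$b[] <- 0
    }
  }
  invisible(model)
}

#' Save / load a denoiser checkpoint
#'
#' Checkpoints are plain JSON: architecture + stage specs + flattened
#' parameter tensors, loadable with no external state.
#'
#' @param model an \code{mc_denoiser}
#' @param path output path (\code{.json})
#' @export
save_checkpoint <- function(model, path) {
  params <- snapshot_params(model)
  flat <- lapply(params, function(p) lapply(p, function(v)
    list(dim = if (is.null(dim(v))) length(v) else dim(v),
         data = as.numeric(v))))
  jsonlite::write_json(
    list(architecture = model$architecture,
         global_spec = unclass(model$global_spec),
         local_spec = unclass(model$local_spec),
         trained = model$trained, meta = model$meta, params = flat),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param path path to a checkpoint written by \code{save_checkpoint}
#' @export
load_checkpoint <- function(path) {
  ck <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- mc_denoiser(ck$architecture,
                       do.call(global_stage_spec, as.list(ck$global_spec)),
                       do.call(local_stage_spec, as.list(ck$local_spec)))
  for (nm in names(ck$params)) {
    ly <- model$layers[[nm]]
    for (fld in names(ck$params[[nm]])) {
      v <- ck$params[[nm]][[fld]]
      val <- array(as.numeric(v$data), dim = as.integer(v$dim))
      if (length(v$dim) == 1) val <- as.numeric(val)
      assign(fld, val, envir = ly)
    }
  }
  model$trained <- isTRUE(ck$trained)
  model$meta <- as.list(ck$meta)
  model
}
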