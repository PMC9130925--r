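#' Mini-batch Ln loss in log space
#'
#' Mean element-wise \code{|pred - target|^n} over the mini-batch; \code{n
#' = 2} (the default used for training) penalizes large errors more than
#' \code{n = 1}.
#'
#' @param pred,target numeric arrays of identical shape
#' @param n loss exponent, 1 or 2
#' @export
ln_loss <- function(pred, target, n = 2) {
  if (!identical(dim(pred), dim(target)))
    stop("prediction and target shapes differ")
  if (!n %in% c(1, 2)) stop("loss exponent n must be 1 or 2")
  mean(abs(pred - target)^n)
}

# one 90-degree rotation of a 3D array about a coordinate axis
rot90_3d <- function(a, axis) {
  switch(axis,
         # about x: (y, z) -> (z, -y)
         `1` = aperm(a[, , dim(a)[3]:1, drop = FALSE], c(1, 3, 2)),
         # about y: (z, x) -> (x, -z)
         `2` = aperm(a[dim(a)[1]:1, , , drop = FALSE], c(3, 2, 1)),
         # about z: (x, y) -> (y, -x)
         `3` = aperm(a[, dim(a)[2]:1, , drop = FALSE], c(2, 1, 3)),
         stop("axis must be 1, 2 or 3"))
}

flip_3d <- function(a, axis) {
  switch(axis,
         `1` = a[dim(a)[1]:1, , , drop = FALSE],
         `2` = a[, dim(a)[2]:1, , drop = FALSE],
         `3` = a[, , dim(a)[3]:1, drop = FALSE],
         stop("axis must be 1, 2 or 3"))
}

#' Construct a noisy/clean training pair
#'
#' @param noisy,clean 3D fluence arrays of identical shape from the same
#'   phantom/source/gate; \code{clean} must come from a strictly higher
#'   photon count
#' @param noisy_photons,clean_photons the two photon counts
#' @param domain_id identifier of the originating phantom
#' @param gain log-transform gain assigned to the pair
#' @export
training_pair <- function(noisy, clean, noisy_photons, clean_photons,
                          domain_id = NA_integer_, gain = 1) {
  if (!identical(dim(noisy), dim(clean)))
    stop("noisy and clean volumes have different shapes")
  if (!(clean_photons > noisy_photons))
    stop("clean photon count must exceed the noisy photon count")
  structure(list(noisy = noisy, clean = clean,
                 noisy_photons = noisy_photons,
                 clean_photons = clean_photons,
                 domain_id = domain_id, gain = gain),
            class = "training_pair")
}

#' Randomly rotate/flip a training pair
#'
#' With probability \code{p} applies one 90-degree rotation about a
#' uniformly chosen axis, and independently with probability \code{p} one
#' flip along a uniformly chosen axis.  The identical transform is applied
#' to the noisy input and the clean label.
#'
#' @param pair a \code{\link{training_pair}}
#' @param p application probability of each transform (default 0.7)
#' @export
augment_pair <- function(pair, p = 0.7) {
  dm <- dim(pair$noisy)
  do_rot <- runif(1) < p
  do_flip <- runif(1) < p
  if (do_rot) {
    ax <- sample(1:3, 1)
    other <- setdiff(1:3, ax)
    if (dm[other[1]] != dm[other[2]])
      stop("90-degree rotation requires equal dimensions in the rotation ",
           "plane (volume is non-cubic)")
    pair$noisy <- rot90_3d(pair$noisy, ax)
    pair$clean <- rot90_3d(pair$clean, ax)
  }
  if (do_flip) {
    ax <- sample(1:3, 1)
    pair$noisy <- flip_3d(pair$noisy, ax)
    pair$clean <- flip_3d(pair$clean, ax)
  }
  pair
}

#' Assemble noisy/clean pairs from a simulated-fluence manifest
#'
#' Expects the directory layout written by \code{\link{run_pipeline}} /
#' \code{\link{make_fixtures}}: one fluence volume per (domain, photon
#' level).  One pair is created per domain and noisy level against the
#' common clean level.  Volumes stay in fluence space; the assigned gain is
#' applied on the fly during training.
#'
#' @param fluence_dir directory holding \code{fluence_dom<ID>_n<COUNT>.nii}
#' @param manifest dataset manifest (list, or path to manifest.json)
#' @param photon_levels numeric vector of noisy photon counts
#' @param clean_level photon count treated as ground truth (must exceed all
#'   noisy levels)
#' @param gain_policy \code{"dual-random"} draws each pair's gain uniformly
#'   from \code{c(low, high)} of the inference merge policy;
#'   \code{"fixed"} uses \code{fixed_gain} for every pair
#' @param fixed_gain gain used when \code{gain_policy = "fixed"}
#' @return list of \code{\link{training_pair}} objects
#' @export
assemble_dataset <- function(fluence_dir, manifest, photon_levels,
                             clean_level,
                             gain_policy = c("dual-random", "fixed"),
                             fixed_gain = 1e7) {
  gain_policy <- match.arg(gain_policy)
  if (is.character(manifest))
    manifest <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  stopifnot(all(photon_levels < clean_level))
  pairs <- list()
  for (dom in manifest$domains) {
    id <- dom$id
    clean_path <- file.path(fluence_dir,
                            sprintf("fluence_dom%03d_n%g.nii", id, clean_level))
    if (!file.exists(clean_path))
      stop("missing fluence volume for domain ", id, " at clean level ",
           clean_level)
    clean <- read_fluence(clean_path)
    for (lev in photon_levels) {
      noisy_path <- file.path(fluence_dir,
                              sprintf("fluence_dom%03d_n%g.nii", id, lev))
      if (!file.exists(noisy_path))
        stop("missing fluence volume for domain ", id, " at level ", lev)
      noisy <- read_fluence(noisy_path)
      gain <- if (gain_policy == "fixed") fixed_gain
              else sample(c(1, 1e7), 1)
      pairs[[length(pairs) + 1]] <-
        training_pair(noisy$values, clean$values, lev, clean_level,
                      domain_id = id, gain = gain)
    }
  }
  pairs
}

#' Training configuration
#'
#' Defaults are desk-scale: the reference large-scale recipe (base learning
#' rate 1e-4, 1000 warm-up iterations, 1500 epochs, batch 4 per device)
#' is reproduced by passing those values explicitly.  Weight decay is
#' decoupled (AdamW) and exempts all bias and batch-norm parameters;
#' gradients are norm-clipped per group (2 for batch-norm parameters, 1 for
#' all others).
#'
#' @param epochs training epochs
#' @param batch_size pairs per mini-batch
#' @param base_lr base learning rate
#' @param weight_decay decoupled weight decay for non-exempt parameters
#' @param warmup_iters linear warm-up mini-batch iterations
#' @param clip_bn,clip_other gradient-norm clip values per parameter group
#' @param p_augment rotation/flip application probability
#' @param loss_n loss exponent (1 or 2)
#' @param patch_size optional cubic crop edge (voxels): each mini-batch
#'   sample is a random same-location crop of a pair's noisy and clean
#'   volumes, the standard way to multiply effective training samples for
#'   convolutional denoisers; \code{NULL} trains on whole volumes
#' @param iters_per_epoch mini-batch iterations per epoch; defaults to one
#'   pass over the pairs
#' @param selection validation metric used to pick the best checkpoint:
#'   \code{"composite"} (rank-sum of MSE down, SSIM up, PSNR up),
#'   \code{"mse"}, \code{"ssim"} or \code{"psnr"}
#' @param seed RNG seed for shuffling/augmentation
#' @export
train_config <- function(epochs = 40, batch_size = 4, base_lr = 1e-3,
                         weight_decay = 1e-4, warmup_iters = 20,
                         clip_bn = 2, clip_other = 1, p_augment = 0.7,
                         loss_n = 2, patch_size = NULL,
                         iters_per_epoch = NULL,
                         selection = c("composite", "mse", "ssim", "psnr"),
                         seed = 1) {
  selection <- match.arg(selection)
  stopifnot(epochs >= 1, batch_size >= 1, base_lr > 0, weight_decay >= 0,
            warmup_iters >= 0, clip_bn > 0, clip_other > 0,
            p_augment >= 0, p_augment <= 1, loss_n %in% c(1, 2),
            is.null(patch_size) || patch_size >= 8,
            is.null(iters_per_epoch) || iters_per_epoch >= 1)
  structure(list(epochs = epochs, batch_size = batch_size,
                 base_lr = base_lr, weight_decay = weight_decay,
                 warmup_iters = warmup_iters, clip_bn = clip_bn,
                 clip_other = clip_other, p_augment = p_augment,
                 loss_n = loss_n, patch_size = patch_size,
                 iters_per_epoch = iters_per_epoch,
                 selection = selection, seed = seed),
            class = "train_config")
}

# random same-location cubic crop of both members of a pair
crop_pair <- function(pair, size) {
  dm <- dim(pair$noisy)
  if (any(dm < size)) return(pair)
  o <- vapply(dm, function(n) sample.int(n - size + 1L, 1), integer(1))
  ix <- lapply(1:3, function(a) o[a]:(o[a] + size - 1L))
  pair$noisy <- pair$noisy[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  pair$clean <- pair$clean[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  pair
}

# linear warmup followed by cosine annealing to ~0
lr_at <- function(iter, total_iters, cfg) {
  if (cfg$warmup_iters > 0 && iter <= cfg$warmup_iters)
    return(cfg$base_lr * iter / cfg$warmup_iters)
  denom <- max(1, total_iters - cfg$warmup_iters)
  frac <- min(1, (iter - cfg$warmup_iters) / denom)
  cfg$base_lr * 0.5 * (1 + cos(pi * frac))
}

# group gradients by clipping class and rescale so each group's global norm
# stays below its clip value
clip_gradients <- function(model, refs, clip_bn, clip_other) {
  for (is_bn in c(TRUE, FALSE)) {
    sel <- Filter(function(r) r$bn == is_bn, refs)
    ss <- 0
    for (r in sel) {
      g <- get(r$grad, envir = model$layers[[r$layer]])
      if (!is.null(g)) ss <- ss + sum(g^2)
    }
    nrm <- sqrt(ss)
    clip <- if (is_bn) clip_bn else clip_other
    if (nrm > clip) {
      sc <- clip / nrm
      for (r in sel) {
        ly <- model$layers[[r$layer]]
        g <- get(r$grad, envir = ly)
        if (!is.null(g)) assign(r$grad, g * sc, envir = ly)
      }
    }
  }
}

#' Train a residual denoiser on noisy/clean fluence pairs
#'
#' Optimizes the log-space Ln loss with Adam and decoupled weight decay
#' (exempting batch-norm and bias parameters), a linear-warmup +
#' cosine-annealing learning-rate schedule, per-group gradient-norm
#' clipping, and on-the-fly rotation/flip augmentation applied identically
#' to input and label.  Validation global metrics (MSE, SSIM, PSNR in log
#' space) are computed each epoch and the best checkpoint under the
#' configured selection rule is restored into the returned model.
#'
#' @param model an \code{mc_denoiser}
#' @param pairs list of \code{\link{training_pair}}s
#' @param val_pairs held-out pairs for checkpoint selection (may be a
#'   subset of size >= 1); if \code{NULL}, the training pairs are reused
#' @param config a \code{\link{train_config}}
#' @return list with \code{model} (best checkpoint restored, marked
#'   trained) and \code{history} (class \code{mc_history})
#' @export
train_denoiser <- function(model, pairs, val_pairs = NULL,
                           config = train_config()) {
  stopifnot(inherits(model, "mc_denoiser"), length(pairs) >= 1)
  if (is.null(val_pairs)) val_pairs <- pairs
  set.seed(config$seed)
  refs <- param_refs(model)
  # Adam state per parameter ref
  state <- lapply(refs, function(r) {
    v <- get(r$slot, envir = model$layers[[r$layer]])
    list(m = array(0, dim = dim(v) %||% length(v)),
         v = array(0, dim = dim(v) %||% length(v)))
  })
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  pair_gains <- vapply(pairs, `[[`, 0, "gain")
  iters_per_epoch <- config$iters_per_epoch %||%
    sum(vapply(split(seq_along(pairs), pair_gains),
               function(x) ceiling(length(x) / config$batch_size),
               numeric(1)))
  total_iters <- config$epochs * iters_per_epoch
  iter <- 0L
  hist <- list(epoch = integer(0), train_loss = numeric(0),
               val_mse = numeric(0), val_ssim = numeric(0),
               val_psnr = numeric(0), lr = numeric(0))
  best_snap <- NULL

  gains <- pair_gains
  for (ep in seq_len(config$epochs)) {
    # mini-batches are gain-homogeneous: pairs in a batch share the
    # transform gain, which keeps the batch-norm statistics on one scale
    batches <- list()
    if (is.null(config$iters_per_epoch)) {
      # one shuffled pass over the pairs, grouped by gain
      for (g in unique(gains)) {
        gi <- sample(which(gains == g))
        for (bs in seq(1, length(gi), by = config$batch_size))
          batches[[length(batches) + 1]] <-
            gi[bs:min(bs + config$batch_size - 1, length(gi))]
      }
      batches <- batches[sample(length(batches))]
    } else {
      # fixed number of randomly drawn batches (used with patch sampling)
      for (i in seq_len(iters_per_epoch)) {
        g <- gains[sample(length(gains), 1)]
        gi <- which(gains == g)
        batches[[i]] <- gi[sample.int(length(gi),
                                      min(config$batch_size, length(gi)))]
      }
    }
    ep_loss <- 0; ep_n <- 0
    for (idx in batches) {
      batch <- lapply(pairs[idx], augment_pair, p = config$p_augment)
      if (!is.null(config$patch_size))
        batch <- lapply(batch, crop_pair, size = config$patch_size)
      dm <- dim(batch[[1]]$noisy)
      B <- length(batch)
      xb <- array(0, c(dm, 1L, B))
      yb <- array(0, c(dm, 1L, B))
      for (i in seq_len(B)) {
        g <- batch[[i]]$gain
        xb[, , , 1, i] <- forward_log(batch[[i]]$noisy, g)
        yb[, , , 1, i] <- forward_log(batch[[i]]$clean, g)
      }
      iter <- iter + 1L
      lr <- lr_at(iter, total_iters, config)
      zero_grads(model)
      fw <- model_forward(model, xb, training = TRUE)
      pred <- tp_value(fw$tape, fw$out_id)
      loss <- ln_loss(pred, yb, config$loss_n)
      if (!is.finite(loss))
        stop("training diverged (non-finite loss) at epoch ", ep,
             ", iteration ", iter)
      ep_loss <- ep_loss + loss * B; ep_n <- ep_n + B
      diff <- pred - yb
      gout <- if (config$loss_n == 2) 2 * diff / length(diff)
              else sign(diff) / length(diff)
      tp_backward(fw$tape, fw$out_id, gout)
      clip_gradients(model, refs, config$clip_bn, config$clip_other)
      for (j in seq_along(refs)) {
        r <- refs[[j]]
        ly <- model$layers[[r$layer]]
        g <- get(r$grad, envir = ly)
        if (is.null(g)) next
        p <- get(r$slot, envir = ly)
        st <- state[[j]]
        st$m <- beta1 * st$m + (1 - beta1) * g
        st$v <- beta2 * st$v + (1 - beta2) * g^2
        state[[j]] <- st
        mhat <- st$m / (1 - beta1^iter)
        vhat <- st$v / (1 - beta2^iter)
        p <- p - lr * mhat / (sqrt(vhat) + eps)
        if (r$decay && config$weight_decay > 0)
          p <- p - lr * config$weight_decay * p
        assign(r$slot, p, envir = ly)
      }
    }
    vm <- validate_denoiser(model, val_pairs)
    hist$epoch <- c(hist$epoch, ep)
    hist$train_loss <- c(hist$train_loss, ep_loss / ep_n)
    hist$val_mse <- c(hist$val_mse, vm["mse"])
    hist$val_ssim <- c(hist$val_ssim, vm["ssim"])
    hist$val_psnr <- c(hist$val_psnr, vm["psnr"])
    hist$lr <- c(hist$lr, lr)
    best <- select_best(structure(hist, class = "mc_history"),
                        config$selection)
    if (best == ep) best_snap <- snapshot_params(model)
  }
  history <- structure(hist, class = "mc_history")
  best_epoch <- select_best(history, config$selection)
  if (!is.null(best_snap)) restore_params(model, best_snap)
  model$trained <- TRUE
  model$meta <- list(epochs = config$epochs, best_epoch = best_epoch,
                     selection = config$selection,
                     gains = sort(unique(vapply(pairs, `[[`, 0, "gain"))),
                     val_mse = unname(hist$val_mse[best_epoch]))
  history$best_epoch <- best_epoch
  list(model = model, history = history)
}

# per-epoch validation global metrics, computed in each pair's gain space
validate_denoiser <- function(model, val_pairs) {
  ms <- ss <- ps <- numeric(length(val_pairs))
  for (i in seq_along(val_pairs)) {
    p <- val_pairs[[i]]
    yn <- forward_log(p$noisy, p$gain)
    yc <- forward_log(p$clean, p$gain)
    den <- denoise_volume(model, yn)
    ms[i] <- mse(den, yc)
    ss[i] <- ssim3d(den, yc)
    ps[i] <- psnr(den, yc)
  }
  c(mse = mean(ms), ssim = mean(ss), psnr = mean(ps[is.finite(ps)]))
}

#' Select the best epoch from a training history
#'
#' \code{"mse"} minimizes, \code{"ssim"}/\code{"psnr"} maximize, and
#' \code{"composite"} minimizes the rank-sum of (MSE rank ascending, SSIM
#' rank descending, PSNR rank descending).  Ties resolve to the earliest
#' epoch.
#'
#' @param history an \code{mc_history}
#' @param metric selection rule
#' @return the selected epoch number
#' @export
select_best <- function(history,
                        metric = c("composite", "mse", "ssim", "psnr")) {
  metric <- match.arg(metric)
  n <- length(history$epoch)
  if (n == 0) stop("history is empty")
  key <- switch(metric,
    mse = history$val_mse,
    ssim = -history$val_ssim,
    psnr = -history$val_psnr,
    composite = {
      if (anyNA(history$val_mse) || anyNA(history$val_ssim) ||
          anyNA(history$val_psnr))
        stop("composite selection requires mse, ssim and psnr in history")
      rank(history$val_mse, ties.method = "min") +
        rank(-history$val_ssim, ties.method = "min") +
        rank(-history$val_psnr, ties.method = "min")
    })
  if (anyNA(key)) stop("selection metric '", metric, "' absent from history")
  which.min(key)
}

#' @export
print.mc_history <- function(x, ...) {
  df <- data.frame(epoch = x$epoch, train_loss = x$train_loss,
                   val_mse = x$val_mse, val_ssim = x$val_ssim,
                   val_psnr = x$val_psnr)
  cat(sprintf("Training history (%d epochs%s)\n", length(x$epoch),
              if (!is.null(x$best_epoch))
                paste0(", best epoch ", x$best_epoch) else ""))
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.mc_history <- function(x, ...) {
  par(mfrow = c(1, 2))
  plot(x$epoch, x$train_loss, type = "b", xlab = "epoch",
       ylab = "training loss", log = "y", main = "loss")
  plot(x$epoch, x$val_mse, type = "b", xlab = "epoch",
       ylab = "validation MSE (log space)", log = "y", main = "validation")
  invisible(x)
}
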