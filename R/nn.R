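# Minimal reverse-mode machinery for the 3D residual denoisers.
# Tensors are 5-D double arrays with dim = (X, Y, Z, C, B).  Layers are
# environments (mutable parameter + gradient slots); the tape is an
# environment holding the forward graph so one backward pass can accumulate
# parameter gradients.

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  e
}

layer_conv <- function(ci, co, k = 3, head = FALSE) {
  sd <- if (head) 1e-3 else sqrt(2 / (k^3 * ci))
  new_layer("conv",
            w = array(rnorm(k^3 * ci * co, 0, sd), c(k, k, k, ci, co)),
            b = numeric(co), k = k, ci = ci, co = co, head = head,
            gw = NULL, gb = NULL)
}

layer_tconv <- function(ci, co) {
  sd <- sqrt(2 / (8 * ci))
  new_layer("tconv",
            w = array(rnorm(8 * ci * co, 0, sd), c(2, 2, 2, ci, co)),
            b = numeric(co), ci = ci, co = co, gw = NULL, gb = NULL)
}

layer_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  new_layer("bn", gamma = rep(1, c), beta = numeric(c),
            running_mean = numeric(c), running_var = rep(1, c),
            momentum = momentum, eps = eps, nchan = c,
            ggamma = NULL, gbeta = NULL)
}

# ---- tape ----

tape_new <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- list()
  e
}

tp_push <- function(tape, op, inputs, value, layer = NULL, saved = NULL) {
  id <- length(tape$nodes) + 1L
  tape$nodes[[id]] <- list(op = op, inputs = inputs, value = value,
                           layer = layer, saved = saved)
  id
}

# force id before touching tape$nodes: the id argument may be a lazily
# evaluated call that itself appends nodes to the tape
tp_value <- function(tape, id) {
  force(id)
  tape$nodes[[id]]$value
}

tp_input <- function(tape, x) tp_push(tape, "input", integer(0), x)

tp_conv <- function(tape, id, layer) {
  x <- tp_value(tape, id)
  out <- .conv3d_fwd_cpp(x, dim(x), layer$w, layer$k, layer$ci, layer$co,
                         layer$b)
  dim(out) <- c(dim(x)[1:3], layer$co, dim(x)[5])
  tp_push(tape, "conv", id, out, layer)
}

tp_tconv <- function(tape, id, layer) {
  x <- tp_value(tape, id)
  out <- .tconv2_fwd_cpp(x, dim(x), layer$w, layer$ci, layer$co, layer$b)
  dim(out) <- c(2 * dim(x)[1:3], layer$co, dim(x)[5])
  tp_push(tape, "tconv", id, out, layer)
}

tp_relu <- function(tape, id) {
  x <- tp_value(tape, id)
  tp_push(tape, "relu", id, pmax(x, 0))
}

tp_pool <- function(tape, id) {
  x <- tp_value(tape, id)
  out <- .avgpool2_fwd_cpp(x, dim(x))
  dim(out) <- c(dim(x)[1:3] %/% 2L, dim(x)[4:5])
  tp_push(tape, "pool", id, out)
}

tp_bn <- function(tape, id, layer, training) {
  x <- tp_value(tape, id)
  d <- dim(x)
  C <- d[4]
  out <- x
  mu <- numeric(C); invstd <- numeric(C)
  xhat <- if (training) x else NULL
  for (cc in seq_len(C)) {
    xs <- x[, , , cc, , drop = FALSE]
    if (training) {
      m <- mean(xs)
      v <- mean((xs - m)^2)
      layer$running_mean[cc] <- (1 - layer$momentum) * layer$running_mean[cc] +
        layer$momentum * m
      layer$running_var[cc] <- (1 - layer$momentum) * layer$running_var[cc] +
        layer$momentum * v
    } else {
      m <- layer$running_mean[cc]
      v <- layer$running_var[cc]
    }
    iv <- 1 / sqrt(v + layer$eps)
    xh <- (xs - m) * iv
    if (training) xhat[, , , cc, ] <- xh
    out[, , , cc, ] <- xh * layer$gamma[cc] + layer$beta[cc]
    mu[cc] <- m; invstd[cc] <- iv
  }
  tp_push(tape, "bn", id, out, layer,
          saved = list(mean = mu, invstd = invstd, xhat = xhat,
                       training = training))
}

tp_sub <- function(tape, ida, idb) {
  force(ida); force(idb)
  tp_push(tape, "sub", c(ida, idb),
          tp_value(tape, ida) - tp_value(tape, idb))
}

tp_concat <- function(tape, ida, idb) {
  force(ida); force(idb)
  a <- tp_value(tape, ida); b <- tp_value(tape, idb)
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4], da[5]))
  out[, , , seq_len(da[4]), ] <- a
  out[, , , da[4] + seq_len(db[4]), ] <- b
  tp_push(tape, "concat", c(ida, idb), out, saved = list(ca = da[4]))
}

# backward pass from node out_id with upstream gradient gout; accumulates
# parameter gradients into each layer's gw/gb (ggamma/gbeta) slots
tp_backward <- function(tape, out_id, gout) {
  n <- length(tape$nodes)
  grads <- vector("list", n)
  grads[[out_id]] <- gout
  acc <- function(id, g) {
    if (is.null(grads[[id]])) grads[[id]] <<- g
    else grads[[id]] <<- grads[[id]] + g
  }
  for (id in rev(seq_len(n))) {
    g <- grads[[id]]
    if (is.null(g)) next
    nd <- tape$nodes[[id]]
    switch(nd$op,
      input = NULL,
      conv = {
        ly <- nd$layer
        x <- tp_value(tape, nd$inputs)
        bw <- .conv3d_bwd_cpp(x, dim(x), ly$w, ly$k, ly$ci, ly$co, g)
        ly$gw <- if (is.null(ly$gw)) array(bw$gw, dim(ly$w)) else
          ly$gw + array(bw$gw, dim(ly$w))
        ly$gb <- if (is.null(ly$gb)) bw$gb else ly$gb + bw$gb
        gi <- bw$gin; dim(gi) <- dim(x)
        acc(nd$inputs, gi)
      },
      tconv = {
        ly <- nd$layer
        x <- tp_value(tape, nd$inputs)
        bw <- .tconv2_bwd_cpp(x, dim(x), ly$w, ly$ci, ly$co, g)
        ly$gw <- if (is.null(ly$gw)) array(bw$gw, dim(ly$w)) else
          ly$gw + array(bw$gw, dim(ly$w))
        ly$gb <- if (is.null(ly$gb)) bw$gb else ly$gb + bw$gb
        gi <- bw$gin; dim(gi) <- dim(x)
        acc(nd$inputs, gi)
      },
      relu = {
        x <- tp_value(tape, nd$inputs)
        acc(nd$inputs, g * (x > 0))
      },
      pool = {
        x <- tp_value(tape, nd$inputs)
        gi <- .avgpool2_bwd_cpp(g, dim(x))
        dim(gi) <- dim(x)
        acc(nd$inputs, gi)
      },
      bn = {
        ly <- nd$layer
        sv <- nd$saved
        if (!isTRUE(sv$training))
          stop("backward through a batch-norm layer run in eval mode")
        x <- tp_value(tape, nd$inputs)
        gi <- g
        C <- dim(x)[4]
        gg <- numeric(C); gb <- numeric(C)
        for (cc in seq_len(C)) {
          go <- g[, , , cc, , drop = FALSE]
          xh <- sv$xhat[, , , cc, , drop = FALSE]
          m <- length(go)
          gg[cc] <- sum(go * xh)
          gb[cc] <- sum(go)
          dxh <- go * ly$gamma[cc]
          gi[, , , cc, ] <- (sv$invstd[cc] / m) *
            (m * dxh - sum(dxh) - xh * sum(dxh * xh))
        }
        ly$ggamma <- if (is.null(ly$ggamma)) gg else ly$ggamma + gg
        ly$gbeta <- if (is.null(ly$gbeta)) gb else ly$gbeta + gb
        acc(nd$inputs, gi)
      },
      sub = {
        acc(nd$inputs[1], g)
        acc(nd$inputs[2], -g)
      },
      concat = {
        ca <- nd$saved$ca
        acc(nd$inputs[1], g[, , , seq_len(ca), , drop = FALSE])
        acc(nd$inputs[2], g[, , , -seq_len(ca), , drop = FALSE])
      },
      stop("unknown op in backward: ", nd$op))
  }
  invisible(grads)
}

# ---- parameter bookkeeping ----

# enumerate (layer, slot) parameter references for an mc_denoiser;
# slot "w" on conv/tconv is a decayed weight, "b"/"gamma"/"beta" are not
param_refs <- function(model) {
  refs <- list()
  for (nm in names(model$layers)) {
    ly <- model$layers[[nm]]
    if (ly$type %in% c("conv", "tconv")) {
      refs[[length(refs) + 1]] <- list(layer = nm, slot = "w", grad = "gw",
                                       decay = TRUE, bn = FALSE)
      refs[[length(refs) + 1]] <- list(layer = nm, slot = "b", grad = "gb",
                                       decay = FALSE, bn = FALSE)
    } else if (ly$type == "bn") {
      refs[[length(refs) + 1]] <- list(layer = nm, slot = "gamma",
                                       grad = "ggamma", decay = FALSE,
                                       bn = TRUE)
      refs[[length(refs) + 1]] <- list(layer = nm, slot = "beta",
                                       grad = "gbeta", decay = FALSE,
                                       bn = TRUE)
    }
  }
  refs
}

zero_grads <- function(model) {
  for (ly in model$layers) {
    if (ly$type %in% c("conv", "tconv")) { ly$gw <- NULL; ly$gb <- NULL }
    if (ly$type == "bn") { ly$ggamma <- NULL; ly$gbeta <- NULL }
  }
  invisible(model)
}

# deep copy of all parameter values (layers are environments, so plain
# list-copy would alias them)
snapshot_params <- function(model) {
  lapply(model$layers, function(ly) {
    if (ly$type %in% c("conv", "tconv")) list(w = ly$w, b = ly$b)
    else if (ly$type == "bn") list(gamma = ly$gamma, beta = ly$beta,
                                   running_mean = ly$running_mean,
                                   running_var = ly$running_var)
    else list()
  })
}

restore_params <- function(model, snap) {
  for (nm in names(snap)) {
    ly <- model$layers[[nm]]
    for (fld in names(snap[[nm]])) assign(fld, snap[[nm]][[fld]], envir = ly)
  }
  invisible(model)
}
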