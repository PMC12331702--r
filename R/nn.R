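## Minimal reverse-mode training engine for the spectral encoder.
##
## Layers are closures over an environment carrying `params` and
## `grads`; `fwd(x, training)` caches whatever `bwd(dy)` needs. Image
## batches are channel-first C x H x W x B arrays (so convolution
## outputs need no permutation); feature batches are D x B matrices.
## Convolution im2col/col2im and max-pooling run in C++
## (src/conv_ops.cpp); everything else is BLAS-backed matrix algebra.

newLayer <- function(type) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- list()
  e$grads <- list()
  e
}

heInit <- function(nout, nin, fan_in) {
  matrix(stats::rnorm(nout * nin, 0, sqrt(2 / fan_in)), nout, nin)
}

nnConv <- function(cin, cout, k, stride = 1L, pad = 0L) {
  l <- newLayer("conv")
  l$k <- as.integer(k); l$stride <- as.integer(stride); l$pad <- as.integer(pad)
  l$cin <- cin; l$cout <- cout
  l$params$W <- heInit(cout, k * k * cin, k * k * cin)
  l$params$b <- numeric(cout)
  l$fwd <- function(x, training = FALSE) {
    d <- dim(x) # (C, H, W, B)
    l$dims <- d
    cols <- cpp_im2col(x, d[1], d[2], d[3], d[4], l$k, l$stride, l$pad)
    if (training) l$cols <- cols
    oh <- (d[2] + 2 * l$pad - l$k) %/% l$stride + 1L
    ow <- (d[3] + 2 * l$pad - l$k) %/% l$stride + 1L
    y <- l$params$W %*% cols + l$params$b
    array(y, c(l$cout, oh, ow, d[4]))
  }
  l$bwd <- function(dy) {
    dymat <- matrix(dy, nrow = l$cout)
    l$grads$W <- tcrossprod(dymat, l$cols)
    l$grads$b <- rowSums(dymat)
    dcols <- crossprod(l$params$W, dymat)
    dm <- l$dims
    array(
      cpp_col2im(dcols, dm[1], dm[2], dm[3], dm[4], l$k, l$stride, l$pad),
      dm
    )
  }
  l
}

nnBatchNorm <- function(C, momentum = 0.1, eps = 1e-5) {
  l <- newLayer("bn")
  l$C <- C; l$eps <- eps; l$momentum <- momentum
  l$params$gamma <- rep(1, C)
  l$params$beta <- numeric(C)
  l$run_mean <- numeric(C)
  l$run_var <- rep(1, C)
  l$fwd <- function(x, training = FALSE) {
    d <- dim(x) # (C, H, W, B): channel is the fastest-varying index,
    l$dims <- d # so length-C vectors recycle correctly over the rows
    m <- matrix(x, nrow = l$C)
    if (training) {
      mu <- rowMeans(m)
      v <- rowMeans(m^2) - mu^2
      l$run_mean <- (1 - l$momentum) * l$run_mean + l$momentum * mu
      l$run_var <- (1 - l$momentum) * l$run_var + l$momentum * v
    } else {
      mu <- l$run_mean
      v <- l$run_var
    }
    invstd <- 1 / sqrt(v + l$eps)
    xhat <- (m - mu) * invstd
    if (training) {
      l$xhat <- xhat
      l$invstd <- invstd
    }
    array(xhat * l$params$gamma + l$params$beta, d)
  }
  l$bwd <- function(dy) {
    dm <- matrix(dy, nrow = l$C)
    l$grads$gamma <- rowSums(dm * l$xhat)
    l$grads$beta <- rowSums(dm)
    dxhat <- dm * l$params$gamma
    dx <- (dxhat - rowMeans(dxhat) - l$xhat * rowMeans(dxhat * l$xhat)) * l$invstd
    array(dx, l$dims)
  }
  l
}

nnReLU <- function() {
  l <- newLayer("relu")
  l$fwd <- function(x, training = FALSE) {
    if (training) l$mask <- x > 0
    x * (x > 0)
  }
  l$bwd <- function(dy) dy * l$mask
  l
}

nnMaxPool <- function(k, stride, pad = 0L) {
  l <- newLayer("maxpool")
  l$k <- as.integer(k); l$stride <- as.integer(stride); l$pad <- as.integer(pad)
  l$fwd <- function(x, training = FALSE) {
    d <- dim(x) # (C, H, W, B)
    l$dims <- d
    r <- cpp_maxpool(x, d[1], d[2], d[3], d[4], l$k, l$stride, l$pad)
    if (training) l$argmax <- r$argmax
    oh <- (d[2] + 2 * l$pad - l$k) %/% l$stride + 1L
    ow <- (d[3] + 2 * l$pad - l$k) %/% l$stride + 1L
    array(r$out, c(d[1], oh, ow, d[4]))
  }
  l$bwd <- function(dy) {
    dx <- numeric(prod(l$dims))
    agg <- rowsum(as.numeric(dy), l$argmax)
    dx[as.integer(rownames(agg))] <- agg
    array(dx, l$dims)
  }
  l
}

nnGlobalAvgPool <- function() {
  l <- newLayer("gap")
  l$fwd <- function(x, training = FALSE) {
    d <- dim(x) # (C, H, W, B)
    l$dims <- d
    hw <- d[2] * d[3]
    dim(x) <- c(d[1], hw, d[4])
    out <- matrix(0, d[1], d[4]) # C x B features
    for (b in seq_len(d[4])) out[, b] <- rowMeans(x[, , b, drop = FALSE])
    out
  }
  l$bwd <- function(dy) {
    d <- l$dims
    hw <- d[2] * d[3]
    # column (hw, b) blocks each receive dy[, b] / hw
    array(dy[, rep(seq_len(d[4]), each = hw), drop = FALSE] / hw, d)
  }
  l
}

nnLinear <- function(nin, nout) {
  l <- newLayer("linear")
  l$params$W <- heInit(nout, nin, nin)
  l$params$b <- numeric(nout)
  l$fwd <- function(x, training = FALSE) {
    if (training) l$x <- x
    l$params$W %*% x + l$params$b
  }
  l$bwd <- function(dy) {
    l$grads$W <- tcrossprod(dy, l$x)
    l$grads$b <- rowSums(dy)
    crossprod(l$params$W, dy)
  }
  l
}

## Gradient reversal: identity forward, -lambda-scaled backward.
nnGRL <- function(lambda = 0.3) {
  l <- newLayer("grl")
  l$lambda <- lambda
  l$fwd <- function(x, training = FALSE) x
  l$bwd <- function(dy) -l$lambda * dy
  l
}

## Pre-activation-free bottleneck residual block (1x1 -> 3x3 -> 1x1,
## each followed by batch norm; ReLU after the residual sum).
nnBottleneck <- function(cin, cmid, cout, stride = 1L) {
  l <- newLayer("bottleneck")
  l$main <- list(
    nnConv(cin, cmid, 1L), nnBatchNorm(cmid), nnReLU(),
    nnConv(cmid, cmid, 3L, stride = stride, pad = 1L), nnBatchNorm(cmid), nnReLU(),
    nnConv(cmid, cout, 1L), nnBatchNorm(cout)
  )
  l$proj <- if (cin != cout || stride != 1L) {
    list(nnConv(cin, cout, 1L, stride = stride), nnBatchNorm(cout))
  } else {
    list()
  }
  l$relu <- nnReLU()
  l$fwd <- function(x, training = FALSE) {
    h <- x
    for (sub in l$main) h <- sub$fwd(h, training)
    s <- x
    for (sub in l$proj) s <- sub$fwd(s, training)
    l$relu$fwd(h + s, training)
  }
  l$bwd <- function(dy) {
    dsum <- l$relu$bwd(dy)
    dh <- dsum
    for (sub in rev(l$main)) dh <- sub$bwd(dh)
    ds <- dsum
    for (sub in rev(l$proj)) ds <- sub$bwd(ds)
    dh + ds
  }
  l
}

nnSequential <- function(layers) {
  l <- newLayer("sequential")
  l$layers <- layers
  l$fwd <- function(x, training = FALSE) {
    for (sub in l$layers) x <- sub$fwd(x, training)
    x
  }
  l$bwd <- function(dy) {
    for (sub in rev(l$layers)) dy <- sub$bwd(dy)
    dy
  }
  l
}

## Flatten composite layers into the list of primitive parameterized
## layers (for the optimizer and for parameter snapshots).
collectLayers <- function(l) {
  if (l$type == "sequential") {
    unlist(lapply(l$layers, collectLayers), recursive = FALSE)
  } else if (l$type == "bottleneck") {
    c(
      unlist(lapply(l$main, collectLayers), recursive = FALSE),
      unlist(lapply(l$proj, collectLayers), recursive = FALSE)
    )
  } else if (length(l$params)) {
    list(l)
  } else {
    list()
  }
}

snapshotParams <- function(net) {
  lapply(collectLayers(net), function(l) {
    list(params = l$params, run_mean = l$run_mean, run_var = l$run_var)
  })
}

restoreParams <- function(net, snap) {
  ls <- collectLayers(net)
  stopifnot(length(ls) == length(snap))
  for (i in seq_along(ls)) {
    ls[[i]]$params <- snap[[i]]$params
    if (!is.null(snap[[i]]$run_mean)) {
      ls[[i]]$run_mean <- snap[[i]]$run_mean
      ls[[i]]$run_var <- snap[[i]]$run_var
    }
  }
  invisible(net)
}

## Adam over one or more networks' parameterized layers.
nnAdam <- function(nets, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (!is.list(nets)) nets <- list(nets)
  layers <- unlist(lapply(nets, collectLayers), recursive = FALSE)
  state <- lapply(layers, function(l) {
    list(
      m = lapply(l$params, function(p) p * 0),
      v = lapply(l$params, function(p) p * 0)
    )
  })
  t <- 0L
  step <- function(lr) {
    t <<- t + 1L
    for (i in seq_along(layers)) {
      l <- layers[[i]]
      for (nm in names(l$params)) {
        g <- l$grads[[nm]]
        if (is.null(g)) next
        state[[i]]$m[[nm]] <<- beta1 * state[[i]]$m[[nm]] + (1 - beta1) * g
        state[[i]]$v[[nm]] <<- beta2 * state[[i]]$v[[nm]] + (1 - beta2) * g^2
        mhat <- state[[i]]$m[[nm]] / (1 - beta1^t)
        vhat <- state[[i]]$v[[nm]] / (1 - beta2^t)
        l$params[[nm]] <- l$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    invisible(NULL)
  }
  list(step = step, layers = layers)
}
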