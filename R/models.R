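#' Encoder architecture configuration
#'
#' Two presets of the residual spectral encoder. `"full"` is the
#' full-scale architecture: 224 x 224 x 3 input, a 7x7/stride-2 stem
#' with 64 filters and 3x3 max-pooling, then bottleneck residual
#' stages expanding channels 64 -> 256 -> 512 -> 1024 (x4 bottleneck
#' expansion, about 21 convolutional layers). `"small"` is the
#' desk-scale default used throughout the tests: 32 x 32 x 3 input
#' with channels 16 -> 32 -> 64 -> 128 and one bottleneck block per
#' stage.
#'
#' @param preset `"small"` or `"full"`.
#' @param side input image side length (overrides the preset).
#' @param channels channel schedule: stem filters followed by the
#'   three stage output widths, strictly increasing.
#' @param blocks_per_stage residual blocks per stage.
#' @param seed integer seed for weight initialization.
#' @return list of class `EncoderConfig`.
#' @export
encoderConfig <- function(preset = c("small", "full"), side = NULL,
                          channels = NULL, blocks_per_stage = NULL,
                          seed = 1L) {
  preset <- match.arg(preset)
  def <- switch(preset,
    small = list(side = 32L, channels = c(16L, 32L, 64L, 128L), blocks = 1L),
    full = list(side = 224L, channels = c(64L, 256L, 512L, 1024L), blocks = 2L)
  )
  side <- as.integer(side %||% def$side)
  channels <- as.integer(channels %||% def$channels)
  blocks <- as.integer(blocks_per_stage %||% def$blocks)
  if (side < 8L) stop("input side must be >= 8")
  if (any(diff(channels) <= 0)) stop("channel schedule must be increasing")
  structure(
    list(
      preset = preset, side = side, channels = channels,
      blocks_per_stage = blocks, feature_dim = channels[length(channels)],
      seed = as.integer(seed)
    ),
    class = "EncoderConfig"
  )
}

#' Reshape a 1-D spectrum into a square 3-channel image
#'
#' The spectrum is linearly interpolated to `side^2` samples (sampled
#' at `side^2` equally spaced positions along the band axis), written
#' into the image row-major, and replicated into three identical
#' channels — the structural transform that lets 2-D residual
#' encoders consume 1-D reflectance. [imageToSpectrum()] inverts it
#' up to interpolation error.
#'
#' @param spectrum numeric vector of b >= 2 reflectance values.
#' @param side image side length (>= 2).
#' @return array of dim `c(side, side, 3)`.
#' @export
spectrumToImage <- function(spectrum, side) {
  if (side < 2) stop("side must be >= 2")
  b <- length(spectrum)
  if (b < 2) stop("spectrum must have at least 2 bands")
  v <- stats::approx(seq_len(b), spectrum, n = side * side)$y
  m <- matrix(v, side, side, byrow = TRUE)
  array(c(m, m, m), c(side, side, 3L))
}

#' Recover a spectrum from its image encoding
#'
#' @param image array from [spectrumToImage()] (or its first channel).
#' @param b number of bands to reconstruct.
#' @return numeric vector of length `b`.
#' @export
imageToSpectrum <- function(image, b) {
  m <- if (length(dim(image)) == 3L) image[, , 1L] else image
  v <- as.numeric(t(m)) # row-major unravel
  pos <- seq(1, b, length.out = length(v))
  stats::approx(pos, v, xout = seq_len(b))$y
}

## n x b spectra matrix -> channel-first (3, side, side, n) image batch
## (the layout the network consumes internally)
spectraToImages <- function(X, side) {
  n <- nrow(X)
  b <- ncol(X)
  out <- array(0, c(3L, side, side, n))
  xs <- seq_len(b)
  for (i in seq_len(n)) {
    v <- stats::approx(xs, X[i, ], n = side * side)$y
    m <- matrix(v, side, side, byrow = TRUE)
    # replicate into 3 leading channels: channel index varies fastest
    out[, , , i] <- rep(as.numeric(m), each = 3L)
  }
  out
}

#' Build the residual spectral encoder
#'
#' Deterministically initialized (He scheme under the config seed).
#' Forward maps an image batch `(side, side, 3, B)` to a
#' `feature_dim x B` feature matrix via global average pooling of the
#' last stage.
#'
#' @param cfg an [encoderConfig()].
#' @return object of class `SpectralEncoder`.
#' @export
buildEncoder <- function(cfg = encoderConfig()) {
  stopifnot(inherits(cfg, "EncoderConfig"))
  ch <- cfg$channels
  localSeed(cfg$seed, {
    layers <- list(
      nnConv(3L, ch[1], 7L, stride = 2L, pad = 3L),
      nnBatchNorm(ch[1]), nnReLU(),
      nnMaxPool(3L, 2L, pad = 1L)
    )
    cin <- ch[1]
    for (s in seq_along(ch[-1])) {
      cout <- ch[s + 1]
      for (bl in seq_len(cfg$blocks_per_stage)) {
        stride <- if (bl == 1L && s > 1L) 2L else 1L
        layers <- c(layers, list(nnBottleneck(cin, max(cout %/% 4L, 4L), cout, stride)))
        cin <- cout
      }
    }
    layers <- c(layers, list(nnGlobalAvgPool()))
    structure(
      list(net = nnSequential(layers), cfg = cfg, feature_dim = cfg$feature_dim),
      class = "SpectralEncoder"
    )
  })
}

#' Forward pass of the encoder
#'
#' @param encoder a [buildEncoder()] object.
#' @param images array `(side, side, 3, B)` (channel-last, as produced
#'   by [spectrumToImage()]); channel-first `(3, side, side, B)`
#'   batches are also accepted and used as-is.
#' @param training `TRUE` inside the training loop (batch statistics,
#'   caches for backprop); `FALSE` for pure inference.
#' @return `B x feature_dim` feature matrix (samples in rows).
#' @export
encodeFeatures <- function(encoder, images, training = FALSE) {
  d <- dim(images)
  if (length(d) == 3L) {
    dim(images) <- c(d, 1L)
    d <- dim(images)
  }
  if (d[1] != 3L && d[3] == 3L) images <- aperm(images, c(3, 1, 2, 4))
  t(encoder$net$fwd(images, training))
}

#' Build the trait regression head
#'
#' A two-layer perceptron `feature_dim -> hidden -> 3` predicting the
#' (internally min-max scaled) CHL, EWT, LMA targets.
#'
#' @param feature_dim encoder feature dimension.
#' @param hidden hidden width (default 64).
#' @param seed integer seed.
#' @return object of class `TraitHead`.
#' @export
buildTraitHead <- function(feature_dim, hidden = 64L, seed = 1L) {
  localSeed(seed, {
    structure(
      list(net = nnSequential(list(
        nnLinear(feature_dim, hidden), nnReLU(), nnLinear(hidden, 3L)
      ))),
      class = "TraitHead"
    )
  })
}

## Min-max target scaler (fit on training rows only).
fitTraitScaler <- function(Y) {
  lo <- apply(Y, 2, min)
  hi <- apply(Y, 2, max)
  rng <- ifelse(hi > lo, hi - lo, 1)
  list(lo = lo, rng = rng)
}
scaleTraits <- function(Y, sc) sweep(sweep(Y, 2, sc$lo, "-"), 2, sc$rng, "/")
unscaleTraits <- function(Y, sc) sweep(sweep(Y, 2, sc$rng, "*"), 2, sc$lo, "+")

#' Assemble an untrained trait model
#'
#' Bundles a freshly initialized encoder and regression head with the
#' wavelength-grid/side bookkeeping needed for prediction. The target
#' scaler is fit during training. The object has reference semantics
#' (like the layers it contains): [pretrain()] and [adapt()] update it
#' in place and also return it.
#'
#' @param cfg an [encoderConfig()].
#' @param hidden regression-head hidden width.
#' @return object of class `TraitModel`.
#' @export
buildTraitModel <- function(cfg = encoderConfig(), hidden = 64L) {
  m <- new.env(parent = emptyenv())
  m$encoder <- buildEncoder(cfg)
  m$head <- buildTraitHead(cfg$feature_dim, hidden, seed = deriveSeed(cfg$seed, 11L))
  m$cfg <- cfg
  m$hidden <- as.integer(hidden)
  m$scaler <- NULL
  class(m) <- "TraitModel"
  m
}

#' Predict traits from spectra
#'
#' @param model a trained `TraitModel` (from [pretrain()] / [adapt()]).
#' @param x a [SpectraSet-class] or an n x b reflectance matrix.
#' @param batch inference batch size.
#' @return n x 3 matrix of CHL, EWT, LMA predictions in trait units.
#' @export
predictTraits <- function(model, x, batch = 256L) {
  X <- if (is(x, "SpectraSet")) reflectance(x) else as.matrix(x)
  if (is.null(model$scaler)) stop("model has not been trained")
  n <- nrow(X)
  out <- matrix(0, n, 3, dimnames = list(NULL, TRAIT_NAMES))
  side <- model$cfg$side
  for (start in seq(1, n, by = batch)) {
    idx <- start:min(start + batch - 1, n)
    imgs <- spectraToImages(X[idx, , drop = FALSE], side)
    f <- model$encoder$net$fwd(imgs, training = FALSE)
    ys <- model$head$net$fwd(f, training = FALSE)
    out[idx, ] <- unscaleTraits(t(ys), model$scaler)
  }
  out
}

#' Fit a PLS2 regression (NIPALS)
#'
#' Partial least squares with centered predictors and responses, the
#' standard chemometrics baseline mapping reflectance to traits
#' through a low-dimensional latent space. When `ncomp` is `NULL` it
#' is chosen by internal 5-fold cross-validation over 1..`max_comp`.
#'
#' @param X n x b predictor matrix.
#' @param Y n x T response matrix (or vector).
#' @param ncomp number of latent components, or `NULL` for CV choice.
#' @param max_comp largest component count tried by CV (default 20).
#' @param seed seed for the CV fold assignment.
#' @return object of class `PLSRModel`.
#' @export
plsrFit <- function(X, Y, ncomp = NULL, max_comp = 20L, seed = 1L) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (any(!is.finite(X)) || any(!is.finite(Y))) stop("X and Y must be finite")
  n <- nrow(X)
  b <- ncol(X)
  limit <- min(n - 1L, b)
  if (is.null(ncomp)) {
    cand <- seq_len(min(max_comp, limit))
    if (length(cand) > 1L) {
      folds <- localSeed(seed, sample(rep_len(seq_len(5L), n)))
      press <- matrix(0, 5L, length(cand))
      for (f in 1:5) {
        tr <- folds != f
        if (sum(tr) < 2 || sum(!tr) < 1) next
        fit <- plsrCore(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
          min(max(cand), sum(tr) - 1L, b))
        for (ci in seq_along(cand)) {
          a <- min(cand[ci], fit$ncomp)
          pred <- plsrPredictCore(fit, X[!tr, , drop = FALSE], a)
          err <- (pred - Y[!tr, , drop = FALSE])^2
          vy <- apply(Y, 2, stats::var)
          press[f, ci] <- mean(sweep(err, 2, ifelse(vy > 0, vy, 1), "/"))
        }
      }
      ncomp <- cand[which.min(colMeans(press))]
    } else {
      ncomp <- 1L
    }
  }
  if (ncomp < 1L || ncomp > limit) {
    stop("ncomp must be between 1 and min(n - 1, b) = ", limit)
  }
  fit <- plsrCore(X, Y, ncomp)
  structure(fit, class = "PLSRModel")
}

plsrCore <- function(X, Y, ncomp) {
  mx <- colMeans(X)
  my <- colMeans(Y)
  E <- sweep(X, 2, mx)
  Fr <- sweep(Y, 2, my)
  vy <- apply(Fr, 2, function(z) sum(z^2))
  const_y <- vy <= .Machine$double.eps * nrow(Y)
  if (any(const_y)) {
    warning("zero-variance response column(s) fit as constants: ",
      paste(colnames(Y)[const_y] %||% which(const_y), collapse = ", "))
  }
  Fw <- Fr[, !const_y, drop = FALSE]
  p_x <- ncol(E)
  q_y <- ncol(Fw)
  W <- matrix(0, p_x, ncomp)
  P <- matrix(0, p_x, ncomp)
  Q <- matrix(0, q_y, ncomp)
  Tm <- matrix(0, nrow(E), ncomp)
  a <- 0L
  while (a < ncomp) {
    if (q_y == 0L || sum(Fw^2) < 1e-300 || sum(E^2) < 1e-300) break
    u <- Fw[, which.max(colSums(Fw^2))]
    t_old <- rep(Inf, nrow(E))
    for (it in 1:500) {
      w <- crossprod(E, u)
      w <- w / sqrt(sum(w^2))
      tt <- E %*% w
      q <- crossprod(Fw, tt) / sum(tt^2)
      u <- Fw %*% q / sum(q^2)
      if (sum((tt - t_old)^2) < 1e-24 * sum(tt^2)) break
      t_old <- tt
    }
    p <- crossprod(E, tt) / sum(tt^2)
    a <- a + 1L
    W[, a] <- w
    P[, a] <- p
    Q[, a] <- q
    Tm[, a] <- tt
    E <- E - tt %*% t(p)
    Fw <- Fw - tt %*% t(q)
  }
  ncomp <- a
  list(
    W = W[, seq_len(max(a, 1L)), drop = FALSE],
    P = P[, seq_len(max(a, 1L)), drop = FALSE],
    Q = Q[, seq_len(max(a, 1L)), drop = FALSE],
    scores = Tm[, seq_len(max(a, 1L)), drop = FALSE],
    x_mean = mx, y_mean = my, const_y = const_y, ncomp = ncomp,
    y_names = colnames(Y)
  )
}

plsrPredictCore <- function(fit, Xnew, ncomp = fit$ncomp) {
  Xc <- sweep(as.matrix(Xnew), 2, fit$x_mean)
  q_total <- length(fit$y_mean)
  pred <- matrix(rep(fit$y_mean, each = nrow(Xc)), nrow(Xc), q_total)
  colnames(pred) <- fit$y_names
  if (fit$ncomp >= 1L && ncomp >= 1L && any(!fit$const_y)) {
    a <- seq_len(min(ncomp, fit$ncomp))
    W <- fit$W[, a, drop = FALSE]
    P <- fit$P[, a, drop = FALSE]
    Q <- fit$Q[, a, drop = FALSE]
    B <- W %*% solve(crossprod(P, W), t(Q))
    pred[, !fit$const_y] <- pred[, !fit$const_y, drop = FALSE] + Xc %*% B
  }
  pred
}

#' Predict from a PLSR model
#'
#' @param model a [plsrFit()] object.
#' @param X new n x b predictor matrix.
#' @param ncomp optionally predict with fewer components.
#' @return n x T prediction matrix.
#' @export
plsrPredict <- function(model, X, ncomp = model$ncomp) {
  stopifnot(inherits(model, "PLSRModel"))
  plsrPredictCore(model, X, ncomp)
}
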