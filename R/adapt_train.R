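#' Two-stage training configuration
#'
#' Stage 1 is physics-informed pretraining on a simulated corpus;
#' stage 2 is joint fine-tuning and adversarial domain alignment on a
#' source/target pair. Full-scale defaults: stage 1 runs 200 epochs at
#' batch 64 with Adam, learning rate decaying linearly from 1e-3 to
#' 1e-5; stage 2 runs 100 epochs at batch 32 with learning rate 1e-4.
#' The composite stage-2 objective is `lambda1 * L_MSE + lambda2 *
#' L_DA` with defaults 1.0 and 0.3, and the gradient-reversal strength
#' is 0.3.
#'
#' @param stage1_epochs,stage1_batch,stage1_lr,stage1_lr_end stage-1
#'   optimization settings.
#' @param stage2_epochs,stage2_batch,stage2_lr stage-2 settings.
#' @param lambda1,lambda2 composite-loss weights (>= 0).
#' @param lambda_grl gradient-reversal strength (>= 0).
#' @param da_mode `"discriminator"` (adversarial domain classifier
#'   behind a gradient-reversal layer) or `"cosine"` (direct prototype
#'   alignment).
#' @param grl_ramp logical; ramp the reversal strength from 0 to its
#'   full value over stage 2 with the standard warm-up schedule
#'   `2 / (1 + exp(-10 p)) - 1` (p = training progress), shielding the
#'   encoder from the noisy gradients of a still-untrained domain
#'   classifier. Default `TRUE`.
#' @param fewshot_frac labeled target fraction assumed by generators.
#' @param val_frac fraction of training rows held out for the
#'   per-epoch validation loss (and early stopping where enabled).
#' @param patience early-stopping patience in epochs.
#' @param seed integer seed governing batching and initialization.
#' @return list of class `TrainConfig`.
#' @export
trainConfig <- function(stage1_epochs = 200L, stage1_batch = 64L,
                        stage1_lr = 1e-3, stage1_lr_end = 1e-5,
                        stage2_epochs = 100L, stage2_batch = 32L,
                        stage2_lr = 1e-4, lambda1 = 1.0, lambda2 = 0.3,
                        lambda_grl = 0.3,
                        da_mode = c("discriminator", "cosine"),
                        grl_ramp = TRUE,
                        fewshot_frac = 0.1, val_frac = 0.15,
                        patience = 10L, seed = 1L) {
  da_mode <- match.arg(da_mode)
  if (lambda1 < 0 || lambda2 < 0 || lambda_grl < 0) {
    stop("loss weights must be >= 0")
  }
  if (stage1_epochs < 0 || stage2_epochs < 0) stop("epochs must be >= 0")
  if (stage1_batch < 1 || stage2_batch < 1) stop("batch size must be >= 1")
  structure(
    list(
      stage1_epochs = as.integer(stage1_epochs),
      stage1_batch = as.integer(stage1_batch),
      stage1_lr = stage1_lr, stage1_lr_end = stage1_lr_end,
      stage2_epochs = as.integer(stage2_epochs),
      stage2_batch = as.integer(stage2_batch),
      stage2_lr = stage2_lr,
      lambda1 = lambda1, lambda2 = lambda2, lambda_grl = lambda_grl,
      da_mode = da_mode, grl_ramp = isTRUE(grl_ramp),
      fewshot_frac = fewshot_frac,
      val_frac = val_frac, patience = as.integer(patience),
      seed = as.integer(seed)
    ),
    class = "TrainConfig"
  )
}

#' Multi-trait mean squared error
#'
#' Per-trait mean of squared errors over the M samples; the combined
#' loss is the sum over the T traits.
#'
#' @param y M x T observed matrix.
#' @param yhat M x T predicted matrix.
#' @return list with `total` (scalar) and `per_trait` (length-T).
#' @export
mseLoss <- function(y, yhat) {
  y <- as.matrix(y)
  yhat <- as.matrix(yhat)
  if (!all(dim(y) == dim(yhat))) stop("shape mismatch between y and yhat")
  if (nrow(y) < 1) stop("need at least one sample")
  per <- colMeans((y - yhat)^2)
  list(total = sum(per), per_trait = per)
}

#' Contrastive attention between domain feature batches
#'
#' For each source row the weight is the largest cosine similarity to
#' any target row, clamped at zero (and symmetrically for target
#' rows); each row is rescaled by its weight. Shared cross-domain
#' patterns are emphasized, domain-specific rows are suppressed.
#' Zero-norm rows get weight 0.
#'
#' @param Fs source feature batch (n_s x D, rows = samples).
#' @param Ft target feature batch (n_t x D).
#' @return list with `Fs_weighted`, `Ft_weighted`, `w_source`,
#'   `w_target`.
#' @export
contrastiveAttention <- function(Fs, Ft) {
  Fs <- as.matrix(Fs)
  Ft <- as.matrix(Ft)
  if (ncol(Fs) != ncol(Ft)) stop("feature dimensions differ")
  norm_s <- sqrt(rowSums(Fs^2))
  norm_t <- sqrt(rowSums(Ft^2))
  Ns <- Fs / ifelse(norm_s > 0, norm_s, 1)
  Nt <- Ft / ifelse(norm_t > 0, norm_t, 1)
  S <- Ns %*% t(Nt)
  w_s <- pmax(apply(S, 1, max), 0) * (norm_s > 0)
  w_t <- pmax(apply(S, 2, max), 0) * (norm_t > 0)
  list(
    Fs_weighted = Fs * w_s, Ft_weighted = Ft * w_t,
    w_source = w_s, w_target = w_t
  )
}

#' Gradient reversal (forward pass)
#'
#' Identity in the forward direction; during backpropagation the
#' gradient flowing to the input is the downstream gradient scaled by
#' `-lambda_grl` (see [gradReversalBackward()]). Placing this between
#' the encoder and the domain classifier makes minimizing the domain
#' loss adversarial for the encoder.
#'
#' @param x any numeric array.
#' @param lambda_grl reversal strength (>= 0); kept for symmetry with
#'   the backward pass, unused in the forward identity.
#' @return `x`, unchanged.
#' @export
gradReversal <- function(x, lambda_grl = 0.3) {
  if (lambda_grl < 0) stop("lambda_grl must be >= 0")
  x
}

#' Gradient reversal (backward pass)
#'
#' @param grad gradient with respect to the output of [gradReversal()].
#' @param lambda_grl reversal strength.
#' @return `-lambda_grl * grad`, the gradient w.r.t. the input.
#' @export
gradReversalBackward <- function(grad, lambda_grl = 0.3) {
  if (lambda_grl < 0) stop("lambda_grl must be >= 0")
  -lambda_grl * grad
}

#' Build the domain discriminator
#'
#' Two-layer classifier `feature_dim -> hidden -> 1` emitting the
#' source-vs-target logit used by the adversarial domain-adaptation
#' loss.
#'
#' @param feature_dim feature dimension.
#' @param hidden hidden width.
#' @param seed integer seed.
#' @return object of class `DomainDiscriminator`.
#' @export
buildDiscriminator <- function(feature_dim, hidden = 32L, seed = 1L) {
  localSeed(seed, {
    structure(
      list(net = nnSequential(list(
        nnLinear(feature_dim, hidden), nnReLU(), nnLinear(hidden, 1L)
      ))),
      class = "DomainDiscriminator"
    )
  })
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Domain-adaptation loss on weighted feature batches
#'
#' `"discriminator"` mode (the default, canonical adversarial recipe):
#' binary cross-entropy of a domain classifier applied to the
#' attention-weighted features, with gradient reversal inserted
#' between encoder and classifier during training. `"cosine"` mode:
#' `1 - cos(mean source prototype, mean target prototype)`, minimized
#' directly with no reversal.
#'
#' @param Fs_w weighted source features (n_s x D).
#' @param Ft_w weighted target features (n_t x D).
#' @param mode `"discriminator"` or `"cosine"`.
#' @param discriminator a [buildDiscriminator()] object (required in
#'   discriminator mode).
#' @return scalar loss.
#' @export
domainAdaptationLoss <- function(Fs_w, Ft_w,
                                 mode = c("discriminator", "cosine"),
                                 discriminator = NULL) {
  mode <- match.arg(mode)
  Fs_w <- as.matrix(Fs_w)
  Ft_w <- as.matrix(Ft_w)
  if (mode == "discriminator") {
    if (is.null(discriminator)) stop("discriminator mode needs a discriminator")
    X <- t(rbind(Fs_w, Ft_w))
    ylab <- c(rep(1, nrow(Fs_w)), rep(0, nrow(Ft_w)))
    p <- sigmoid(as.numeric(discriminator$net$fwd(X, training = FALSE)))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -mean(ylab * log(p) + (1 - ylab) * log(1 - p))
  } else {
    ps <- colMeans(Fs_w)
    pt <- colMeans(Ft_w)
    ns <- sqrt(sum(ps^2))
    nt <- sqrt(sum(pt^2))
    if (ns == 0 || nt == 0) return(1)
    1 - sum(ps * pt) / (ns * nt)
  }
}

#' Composite stage-2 objective
#'
#' @param l_mse regression loss.
#' @param l_da domain-adaptation loss.
#' @param lambda1,lambda2 non-negative weights (defaults 1.0 and 0.3).
#' @return `lambda1 * l_mse + lambda2 * l_da`.
#' @export
compositeLoss <- function(l_mse, l_da, lambda1 = 1.0, lambda2 = 0.3) {
  if (lambda1 < 0 || lambda2 < 0) stop("weights must be >= 0")
  lambda1 * l_mse + lambda2 * l_da
}

## One supervised forward/backward on a labeled image batch; returns
## loss and leaves gradients in the layers. dfeat is returned so the
## caller can merge additional feature gradients before the encoder
## backward pass.
supervisedStep <- function(model, imgs, y_scaled) {
  f <- model$encoder$net$fwd(imgs, training = TRUE)
  yhat <- model$head$net$fwd(f, training = TRUE)
  B <- ncol(yhat)
  err <- yhat - y_scaled # 3 x B
  loss <- sum(rowMeans(err^2))
  dy <- 2 * err / B
  dfeat <- model$head$net$bwd(dy)
  list(loss = loss, dfeat = dfeat, features = f)
}

#' Stage 1: physics-informed pretraining
#'
#' Trains encoder and regression head on a fully labeled simulated
#' corpus by minimizing the summed per-trait MSE, with targets min-max
#' scaled to \[0, 1\] on the training split. The learning rate decays
#' linearly from `stage1_lr` to `stage1_lr_end`. A `val_frac` fraction
#' of the corpus is held out and its loss recorded per epoch.
#' Deterministic for a fixed `cfg$seed`. The model is updated in
#' place and returned.
#'
#' @param model a [buildTraitModel()] object.
#' @param corpus fully labeled [SpectraSet-class].
#' @param cfg a [trainConfig()].
#' @param epochs override for `cfg$stage1_epochs`.
#' @return list with `model` and `history` (per-epoch data.frame with
#'   `epoch`, `train_loss`, `val_loss`).
#' @export
pretrain <- function(model, corpus, cfg = trainConfig(), epochs = NULL) {
  if (!is(corpus, "SpectraSet") || ncol(corpus) < 1) stop("empty corpus")
  if (!all(isLabeled(corpus))) stop("pretraining corpus must be fully labeled")
  epochs <- as.integer(epochs %||% cfg$stage1_epochs)
  X <- reflectance(corpus)
  Y <- traits(corpus)
  n <- nrow(X)
  localSeed(deriveSeed(cfg$seed, 21L), {
    nval <- max(0L, round(cfg$val_frac * n))
    if (n - nval < 1) nval <- 0L
    val_idx <- if (nval > 0) sample.int(n, nval) else integer(0)
    tr_idx <- setdiff(seq_len(n), val_idx)
    model$scaler <- fitTraitScaler(Y[tr_idx, , drop = FALSE])
    Ys <- scaleTraits(Y, model$scaler)
    imgs <- spectraToImages(X, model$cfg$side)
    val_imgs <- if (nval > 0) imgs[, , , val_idx, drop = FALSE] else NULL
    opt <- nnAdam(list(model$encoder$net, model$head$net))
    hist <- data.frame(
      epoch = integer(0), train_loss = numeric(0), val_loss = numeric(0)
    )
    if (epochs > 0) {
      lrs <- if (epochs == 1) {
        cfg$stage1_lr
      } else {
        seq(cfg$stage1_lr, cfg$stage1_lr_end, length.out = epochs)
      }
      for (ep in seq_len(epochs)) {
        ord <- sample(tr_idx)
        losses <- c()
        for (start in seq(1, length(ord), by = cfg$stage1_batch)) {
          idx <- ord[start:min(start + cfg$stage1_batch - 1L, length(ord))]
          if (length(idx) < 2) next # batch norm needs >= 2 rows
          st <- supervisedStep(
            model, imgs[, , , idx, drop = FALSE],
            t(Ys[idx, , drop = FALSE])
          )
          model$encoder$net$bwd(st$dfeat)
          opt$step(lrs[ep])
          losses <- c(losses, st$loss)
        }
        vloss <- NA_real_
        if (nval > 0) {
          fv <- model$encoder$net$fwd(val_imgs, training = FALSE)
          yv <- model$head$net$fwd(fv, training = FALSE)
          vloss <- sum(rowMeans((yv - t(Ys[val_idx, , drop = FALSE]))^2))
        }
        hist <- rbind(hist, data.frame(
          epoch = ep, train_loss = mean(losses), val_loss = vloss
        ))
      }
    }
    list(model = model, history = hist)
  })
}

#' Stage 2: fine-tuning with adversarial domain alignment
#'
#' Jointly feeds source and target batches through the encoder. The
#' regression head sees the labeled rows (all source rows plus the
#' few-shot labeled target subset); the domain-adaptation loss sees
#' every row of both domains through contrastive attention weighting
#' and, in discriminator mode, a gradient-reversal layer feeding the
#' domain classifier. Optimizes `lambda1 * L_MSE + lambda2 * L_DA`
#' with the stage-2 settings. With `lambda2 = 0` this reduces to
#' supervised fine-tuning and the domain loss is never evaluated.
#'
#' @param model a (typically pretrained) `TraitModel`.
#' @param source labeled source-domain [SpectraSet-class].
#' @param target target-domain [SpectraSet-class]; rows flagged
#'   `fewshot` contribute their labels.
#' @param cfg a [trainConfig()].
#' @param epochs override for `cfg$stage2_epochs`.
#' @return list with `model`, `discriminator` (or `NULL`) and
#'   `history` (per-epoch `epoch`, `mse_loss`, `da_loss`).
#' @export
adapt <- function(model, source, target, cfg = trainConfig(), epochs = NULL) {
  if (!is(target, "SpectraSet") || ncol(target) < 1) stop("no target rows")
  if (!is(source, "SpectraSet") || ncol(source) < 1) stop("no source rows")
  if (!any(isLabeled(source))) stop("source must be labeled")
  epochs <- as.integer(epochs %||% cfg$stage2_epochs)
  side <- model$cfg$side

  Xs <- reflectance(source)
  Xt <- reflectance(target)
  Ys <- traits(source)
  Yt <- traits(target)
  ns <- nrow(Xs)
  nt <- nrow(Xt)
  few <- which(fewShot(target) & isLabeled(target))

  if (is.null(model$scaler)) {
    lab <- rbind(Ys[isLabeled(source), , drop = FALSE], Yt[few, , drop = FALSE])
    model$scaler <- fitTraitScaler(lab)
  }
  Ys_s <- scaleTraits(Ys, model$scaler)
  Yt_s <- scaleTraits(Yt, model$scaler)

  disc <- NULL
  if (cfg$lambda2 > 0 && cfg$da_mode == "discriminator") {
    disc <- buildDiscriminator(model$cfg$feature_dim,
      seed = deriveSeed(cfg$seed, 31L)
    )
  }
  nets <- list(model$encoder$net, model$head$net)
  if (!is.null(disc)) nets <- c(nets, list(disc$net))
  opt <- nnAdam(nets)

  imgs_s <- spectraToImages(Xs, side)
  imgs_t <- spectraToImages(Xt, side)
  half <- max(1L, cfg$stage2_batch %/% 2L)
  steps <- max(1L, ceiling(ns / half))
  hist <- data.frame(epoch = integer(0), mse_loss = numeric(0), da_loss = numeric(0))

  total_steps <- max(1L, epochs * steps)
  gstep <- 0L
  localSeed(deriveSeed(cfg$seed, 22L), {
    for (ep in seq_len(epochs)) {
      ord_s <- sample.int(ns)
      mse_ep <- c()
      da_ep <- c()
      for (stp in seq_len(steps)) {
        gstep <- gstep + 1L
        ramp <- if (isTRUE(cfg$grl_ramp)) {
          2 / (1 + exp(-10 * gstep / total_steps)) - 1
        } else {
          1
        }
        is_ <- ord_s[(((stp - 1L) * half) %% ns) + seq_len(half)]
        is_ <- is_[!is.na(is_)]
        it_ <- sample.int(nt, min(half, nt))
        if (length(is_) + length(it_) < 2) next
        imgs <- array(0, c(3L, side, side, length(is_) + length(it_)))
        imgs[, , , seq_along(is_)] <- imgs_s[, , , is_, drop = FALSE]
        imgs[, , , length(is_) + seq_along(it_)] <- imgs_t[, , , it_, drop = FALSE]
        f <- model$encoder$net$fwd(imgs, training = TRUE)
        src_cols <- seq_along(is_)
        tgt_cols <- length(is_) + seq_along(it_)
        lab_cols <- c(src_cols, tgt_cols[it_ %in% few])
        y_lab <- rbind(
          Ys_s[is_, , drop = FALSE],
          Yt_s[it_[it_ %in% few], , drop = FALSE]
        )
        dfeat <- matrix(0, nrow(f), ncol(f))

        yhat <- model$head$net$fwd(f[, lab_cols, drop = FALSE], training = TRUE)
        err <- yhat - t(y_lab)
        l_mse <- sum(rowMeans(err^2))
        dhead <- model$head$net$bwd(2 * err / ncol(yhat))
        dfeat[, lab_cols] <- dfeat[, lab_cols] + cfg$lambda1 * dhead

        l_da <- 0
        if (cfg$lambda2 > 0) {
          att <- contrastiveAttention(t(f[, src_cols, drop = FALSE]), t(f[, tgt_cols, drop = FALSE]))
          w <- c(att$w_source, att$w_target)
          Xw <- rbind(att$Fs_weighted, att$Ft_weighted) # B x D
          if (cfg$da_mode == "discriminator") {
            logits <- disc$net$fwd(t(Xw), training = TRUE)
            ylab <- c(rep(1, length(src_cols)), rep(0, length(tgt_cols)))
            p <- pmin(pmax(sigmoid(as.numeric(logits)), 1e-12), 1 - 1e-12)
            l_da <- -mean(ylab * log(p) + (1 - ylab) * log(1 - p))
            # the discriminator trains on the full BCE gradient; only
            # the reversed gradient reaching the encoder is attenuated
            # (lambda2 * lambda_grl), the canonical DANN weighting
            dlogit <- matrix((p - ylab) / length(p), 1)
            dXw <- disc$net$bwd(dlogit)
            dXw_enc <- cfg$lambda2 * ramp *
              gradReversalBackward(dXw, cfg$lambda_grl)
          } else {
            ps <- colMeans(att$Fs_weighted)
            pt <- colMeans(att$Ft_weighted)
            nps <- sqrt(sum(ps^2))
            npt <- sqrt(sum(pt^2))
            if (nps > 0 && npt > 0) {
              cs <- sum(ps * pt) / (nps * npt)
              l_da <- 1 - cs
              dps <- -(pt / (nps * npt) - cs * ps / nps^2)
              dpt <- -(ps / (nps * npt) - cs * pt / npt^2)
              dXw_enc <- cfg$lambda2 * cbind(
                matrix(dps / length(src_cols), nrow(f), length(src_cols)),
                matrix(dpt / length(tgt_cols), nrow(f), length(tgt_cols))
              )
            } else {
              dXw_enc <- matrix(0, nrow(f), ncol(f))
            }
          }
          # attention weights treated as constants: d(w_i f_i)/d f_i = w_i
          dfeat <- dfeat + sweep(dXw_enc, 2, w, "*")
        }
        model$encoder$net$bwd(dfeat)
        opt$step(cfg$stage2_lr)
        mse_ep <- c(mse_ep, l_mse)
        da_ep <- c(da_ep, l_da)
      }
      hist <- rbind(hist, data.frame(
        epoch = ep, mse_loss = mean(mse_ep), da_loss = mean(da_ep)
      ))
    }
    list(model = model, discriminator = disc, history = hist)
  })
}

#' Deep-copy a trait model
#'
#' `TraitModel` objects have reference semantics, so training one
#' handle trains them all; cloning snapshots the weights (and batch
#' statistics) into an independent copy. Used to branch a pretrained
#' model into several fine-tuning arms.
#'
#' @param model a `TraitModel`.
#' @return an independent `TraitModel` with identical parameters.
#' @export
cloneTraitModel <- function(model) {
  m2 <- buildTraitModel(model$cfg, hidden = model$hidden)
  restoreParams(m2$encoder$net, snapshotParams(model$encoder$net))
  restoreParams(m2$head$net, snapshotParams(model$head$net))
  m2$scaler <- model$scaler
  m2
}
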