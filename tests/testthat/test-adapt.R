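# Losses, gradient reversal, attention, and the two training stages.

test_that("multi-trait MSE follows the per-trait-sum definition", {
  y <- matrix(1:6, 2, 3)
  expect_equal(mseLoss(y, y)$total, 0)
  expect_equal(mseLoss(matrix(2), matrix(5))$total, 9)
  # per-trait losses (1, 2, 3) combine to 6
  yhat <- y + rep(c(1, sqrt(2), sqrt(3)), each = 2)
  out <- mseLoss(y, yhat)
  expect_equal(unname(out$per_trait), c(1, 2, 3), tolerance = 1e-12)
  expect_equal(out$total, 6, tolerance = 1e-12)
  expect_error(mseLoss(y, matrix(1:4, 2, 2)), "shape")
})

test_that("contrastive attention weights obey the cosine contract", {
  set.seed(5)
  Fs <- matrix(rnorm(12), 3, 4)
  # identical batches: all weights 1, outputs equal inputs
  att <- contrastiveAttention(Fs, Fs)
  expect_equal(att$w_source, rep(1, 3), tolerance = 1e-12)
  expect_equal(att$Fs_weighted, Fs, tolerance = 1e-12)

  # orthogonal rows: all weights 0, weighted maps zero
  A <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  B <- rbind(c(0, 0, 1, 0), c(0, 0, 0, 1))
  att2 <- contrastiveAttention(A, B)
  expect_equal(att2$w_source, c(0, 0))
  expect_true(all(att2$Fs_weighted == 0))
  expect_true(all(att2$Ft_weighted == 0))

  # positive rescaling of a row leaves its weight unchanged
  Fs2 <- Fs
  Fs2[2, ] <- 7.3 * Fs2[2, ]
  Ft <- matrix(rnorm(8), 2, 4)
  expect_equal(contrastiveAttention(Fs2, Ft)$w_source[2],
    contrastiveAttention(Fs, Ft)$w_source[2],
    tolerance = 1e-12)

  # zero-norm row gets weight zero
  Fs3 <- Fs
  Fs3[1, ] <- 0
  expect_equal(contrastiveAttention(Fs3, Ft)$w_source[1], 0)

  # weights always within [0, 1]
  for (i in 1:5) {
    w <- contrastiveAttention(matrix(rnorm(20), 5), matrix(rnorm(12), 3))
    expect_true(all(w$w_source >= 0 & w$w_source <= 1))
    expect_true(all(w$w_target >= 0 & w$w_target <= 1))
  }
})

test_that("gradient reversal is a forward identity with scaled negation back", {
  x <- array(rnorm(24), c(2, 3, 4))
  expect_identical(gradReversal(x, 0.3), x)
  g <- rnorm(10)
  expect_equal(gradReversalBackward(g, 0.3), -0.3 * g)
  expect_equal(gradReversalBackward(g, 0), rep(0, 10))

  # finite differences through a small composed function
  set.seed(3)
  lin <- ppada:::nnLinear(4L, 2L)
  grl <- ppada:::nnGRL(0.3)
  xin <- matrix(rnorm(4), 4, 1)
  # downstream scalar: sum of the linear output
  fwd <- function(v) sum(lin$fwd(grl$fwd(matrix(v, 4, 1), TRUE), TRUE))
  y <- lin$fwd(grl$fwd(xin, TRUE), TRUE)
  up <- grl$bwd(lin$bwd(matrix(1, 2, 1)))
  for (i in 1:4) {
    eps <- 1e-6
    v1 <- xin[, 1]
    v1[i] <- v1[i] + eps
    v2 <- xin[, 1]
    v2[i] <- v2[i] - eps
    fd <- (fwd(v1) - fwd(v2)) / (2 * eps) # gradient w.r.t. the output side
    expect_equal(up[i, 1], -0.3 * fd, tolerance = 1e-5)
  }
})

test_that("domain-adaptation loss hits its analytic anchor points", {
  set.seed(11)
  Fs <- matrix(rnorm(8), 2, 4)
  Ft <- matrix(rnorm(8), 2, 4)
  # zeroed discriminator emits probability 0.5 everywhere: loss = ln 2
  disc <- buildDiscriminator(4L, hidden = 4L, seed = 1)
  for (l in ppada:::collectLayers(disc$net)) {
    for (nm in names(l$params)) l$params[[nm]] <- l$params[[nm]] * 0
  }
  expect_equal(domainAdaptationLoss(Fs, Ft, "discriminator", disc), log(2),
    tolerance = 1e-12)

  # cosine mode: identical prototypes give 0, opposite give 2
  expect_equal(domainAdaptationLoss(Fs, Fs, "cosine"), 0, tolerance = 1e-12)
  expect_equal(domainAdaptationLoss(Fs, -Fs, "cosine"), 2, tolerance = 1e-12)
  expect_error(domainAdaptationLoss(Fs, Ft, "banana"))
})

test_that("composite loss is the weighted sum of its terms", {
  expect_equal(compositeLoss(2, 4, 0.5, 0.5), 3)
  expect_equal(compositeLoss(2, 100, 1.5, 0), 3)
  expect_equal(compositeLoss(1, 1), 1.3) # default (1, 0.3) weighting
  # linear in each term
  expect_equal(
    compositeLoss(2, 3, 1, 0.3) + compositeLoss(5, 7, 1, 0.3),
    compositeLoss(7, 10, 1, 0.3)
  )
  expect_error(compositeLoss(1, 1, -1, 0.3), "weights")
})

test_that("pretraining honors its epoch, determinism and progress contracts", {
  oc <- coarseConstants()
  corpus <- generateCorpus(n = 120, constants = oc, seed = 3)
  cfg0 <- trainConfig(stage1_epochs = 0, seed = 5)
  ecfg <- encoderConfig("small", side = 16L, seed = 5)

  # epochs = 0 leaves the initialization untouched
  m0 <- buildTraitModel(ecfg)
  snap <- ppada:::snapshotParams(m0$encoder$net)
  fit0 <- pretrain(m0, corpus, cfg0)
  expect_identical(ppada:::snapshotParams(fit0$model$encoder$net), snap)
  expect_equal(nrow(fit0$history), 0L)

  # loss decreases over a short run; identical seeds reproduce exactly
  cfg <- trainConfig(stage1_epochs = 4, stage1_lr = 1e-3, stage1_lr_end = 5e-4, seed = 5)
  f1 <- pretrain(buildTraitModel(ecfg), corpus, cfg)
  f2 <- pretrain(buildTraitModel(ecfg), corpus, cfg)
  expect_lt(tail(f1$history$train_loss, 1), f1$history$train_loss[1])
  expect_identical(f1$history, f2$history)
  expect_identical(
    ppada:::snapshotParams(f1$model$encoder$net),
    ppada:::snapshotParams(f2$model$encoder$net)
  )

  expect_error(pretrain(m0, corpus[, integer(0)], cfg), "empty")
})

test_that("adaptation trains both objectives and honors its error contract", {
  oc <- coarseConstants()
  cfgp <- domainShiftConfig(
    target_ranges = prospectRanges(Cab = c(30.1, 110)),
    gain = 0.95, noise_sd = 0.01,
    n_source = 60, n_target = 60, fewshot_frac = 0.2, seed = 17
  )
  pair <- makeDomainPair(cfgp, oc)
  ecfg <- encoderConfig("small", side = 16L, seed = 6)

  # lambda2 = 0: pure supervised fine-tuning, domain loss never evaluated
  cfg_sup <- trainConfig(stage2_epochs = 2, lambda2 = 0, seed = 6)
  fit_sup <- adapt(buildTraitModel(ecfg), pair$source, pair$target, cfg_sup)
  expect_null(fit_sup$discriminator)
  expect_true(all(fit_sup$history$da_loss == 0))
  expect_equal(nrow(fit_sup$history), 2L)

  # adversarial mode records both losses and returns a discriminator
  cfg_da <- trainConfig(stage2_epochs = 2, lambda2 = 0.3, seed = 6)
  fit_da <- adapt(buildTraitModel(ecfg), pair$source, pair$target, cfg_da)
  expect_s3_class(fit_da$discriminator, "DomainDiscriminator")
  expect_true(all(is.finite(fit_da$history$da_loss)))
  expect_true(all(fit_da$history$da_loss > 0))

  # cosine mode runs too
  cfg_cos <- trainConfig(stage2_epochs = 1, lambda2 = 0.3, da_mode = "cosine", seed = 6)
  fit_cos <- adapt(buildTraitModel(ecfg), pair$source, pair$target, cfg_cos)
  expect_true(all(fit_cos$history$da_loss >= 0))

  # predictions come back in trait units
  pred <- predictTraits(fit_da$model, pair$target)
  expect_equal(dim(pred), c(60L, 3L))

  expect_error(
    adapt(buildTraitModel(ecfg), pair$source, pair$target[, integer(0)], cfg_da),
    "target"
  )
  unlabeled <- SpectraSet(reflectance(pair$source), wavelengths(pair$source))
  expect_error(adapt(buildTraitModel(ecfg), unlabeled, pair$target, cfg_da), "labeled")
})

test_that("a full two-stage run is reproducible under fixed seeds", {
  oc <- coarseConstants()
  corpus <- generateCorpus(n = 60, constants = oc, seed = 23)
  pair <- makeDomainPair(
    domainShiftConfig(n_source = 40, n_target = 40, fewshot_frac = 0.2, seed = 24),
    oc
  )
  run_both <- function() {
    ecfg <- encoderConfig("small", side = 16L, seed = 9)
    cfg <- trainConfig(stage1_epochs = 2, stage2_epochs = 2, seed = 9)
    m <- buildTraitModel(ecfg)
    pretrain(m, corpus, cfg)
    adapt(m, pair$source, pair$target, cfg)
    predictTraits(m, pair$target)
  }
  expect_identical(run_both(), run_both())
})
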