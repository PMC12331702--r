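#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - \sum_i (\hat y_i - y_i)^2 / \sum_i (y_i - \bar y)^2}.
#' May be negative for predictions worse than the mean.
#'
#' @param y observed values (n >= 2, not constant).
#' @param yhat predicted values.
#' @return scalar R-squared.
#' @export
rSquared <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  if (length(y) < 2) stop("need at least 2 samples")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("undefined denominator: y is constant")
  1 - sum((yhat - y)^2) / ss_tot
}

#' Normalized root mean square error
#'
#' RMSE divided by the mean of the observed values:
#' \eqn{nRMSE = \sqrt{\frac{1}{n}\sum_i (\hat y_i - y_i)^2} / \bar y}.
#' Invariant under common positive rescaling of `y` and `yhat`.
#'
#' @param y observed values with non-zero mean.
#' @param yhat predicted values.
#' @return scalar nRMSE (>= 0).
#' @export
nrmse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  ybar <- mean(y)
  if (ybar == 0) stop("division error: mean(y) is zero")
  sqrt(mean((yhat - y)^2)) / ybar
}

#' Pool several SpectraSet tables
#'
#' Column-binds tables sharing one wavelength grid; sample ids are
#' made unique.
#'
#' @param tables list of [SpectraSet-class] objects.
#' @return one pooled [SpectraSet-class].
#' @export
combineSpectraSets <- function(tables) {
  stopifnot(length(tables) >= 1)
  wl <- wavelengths(tables[[1]])
  for (tb in tables) {
    if (!isTRUE(all.equal(wavelengths(tb), wl))) {
      stop("tables must share one wavelength grid (use resampleToGrid)")
    }
  }
  refl <- do.call(rbind, lapply(tables, reflectance))
  tr <- do.call(rbind, lapply(tables, traits))
  SpectraSet(
    reflectance = refl,
    wavelength_nm = wl,
    traits = tr,
    domain = unlist(lapply(tables, domainLabels)),
    sample_id = make.unique(unlist(lapply(tables, function(tb) colData(tb)$sample_id))),
    fewshot = unlist(lapply(tables, fewShot))
  )
}

#' Stratified k-fold split plan
#'
#' Pools the tables and partitions rows into `k` test folds such that
#' within every fold the per-dataset counts are proportional to the
#' pool composition within one sample. From each training split a
#' `val_frac` fraction is set aside for internal validation (early
#' stopping); the test rows never influence training.
#'
#' @param tables list of [SpectraSet-class] objects (each dataset must
#'   have at least `k` rows), or one pooled set.
#' @param k number of folds (default 5).
#' @param seed integer seed; assignments are deterministic.
#' @param val_frac internal-validation fraction of each training
#'   split (default 0.15).
#' @return list of class `KFoldPlan`: `pooled` (SpectraSet), `fold`
#'   (integer per pooled row) and `splits` (per fold: `train`, `val`,
#'   `test` row indices).
#' @export
stratifiedKfold <- function(tables, k = 5L, seed = 1L, val_frac = 0.15) {
  if (k < 2) stop("k must be >= 2")
  pooled <- if (is(tables, "SpectraSet")) tables else combineSpectraSets(tables)
  dom <- domainLabels(pooled)
  n <- ncol(pooled)
  cnt <- table(dom)
  if (any(cnt < k)) {
    stop(
      "dataset(s) smaller than k: ",
      paste(names(cnt)[cnt < k], collapse = ", ")
    )
  }
  fold <- integer(n)
  localSeed(deriveSeed(seed, 51L), {
    for (d in names(cnt)) {
      idx <- sample(which(dom == d))
      fold[idx] <- rep_len(sample.int(k), length(idx))
    }
    splits <- lapply(seq_len(k), function(f) {
      test <- which(fold == f)
      rest <- which(fold != f)
      nval <- round(val_frac * length(rest))
      val <- if (nval > 0) sample(rest, nval) else integer(0)
      list(train = setdiff(rest, val), val = val, test = test)
    })
    structure(
      list(pooled = pooled, fold = fold, splits = splits, k = k, seed = seed),
      class = "KFoldPlan"
    )
  })
}

subsetSpectra <- function(x, idx) {
  SpectraSet(
    reflectance = reflectance(x)[idx, , drop = FALSE],
    wavelength_nm = wavelengths(x),
    traits = traits(x)[idx, , drop = FALSE],
    domain = domainLabels(x)[idx],
    sample_id = colData(x)$sample_id[idx],
    fewshot = fewShot(x)[idx],
    params = metadata(x)$params[idx, , drop = FALSE]
  )
}

reportRow <- function(protocol, model, train, test, seed, y, yhat) {
  do.call(rbind, lapply(TRAIT_NAMES, function(tn) {
    data.frame(
      protocol = protocol, model = model, train = train, test = test,
      seed = seed, trait = tn,
      r2 = rSquared(y[, tn], yhat[, tn]),
      nrmse = nrmse(y[, tn], yhat[, tn])
    )
  }))
}

#' Model runners for the benchmark zoo
#'
#' Builds a closure `function(train, test, seed)` returning trait
#' predictions for the test rows, training only on `train` (plus, for
#' the domain-adaptive models, the unlabeled/few-shot rows of `test`
#' as the target domain). The five runners mirror the benchmark:
#' \itemize{
#'   \item `PLSR` — standardized bands, NIPALS PLS2.
#'   \item `ResNet` — encoder + head supervised on `train` only.
#'   \item `ResNet-PROSPECT` — physics-pretrained, then fine-tuned on
#'     `train` (equivalent to the full model with `lambda2 = 0`).
#'   \item `ResNet-GRL` — adversarial alignment without pretraining
#'     (the full model with pretraining disabled).
#'   \item `PPADA-Net` — pretraining plus adversarial adaptation.
#' }
#'
#' @param name one of the five model names above.
#' @param constants an [OpticalConstants-class] (needed by the
#'   pretrained runners).
#' @param cfg a [trainConfig()].
#' @param pretrain_n synthetic pretraining-corpus size.
#' @param encoder_cfg an [encoderConfig()]; default small preset.
#' @param ncomp fixed PLSR component count (`NULL` = internal CV).
#' @return closure `function(train, test, seed) -> n x 3 matrix`.
#' @export
modelRunner <- function(name = c("PLSR", "ResNet", "ResNet-PROSPECT", "ResNet-GRL", "PPADA-Net"),
                        constants = NULL, cfg = trainConfig(),
                        pretrain_n = 2000L, encoder_cfg = NULL, ncomp = NULL) {
  name <- match.arg(name)
  needs_physics <- name %in% c("ResNet-PROSPECT", "PPADA-Net")
  if (needs_physics && is.null(constants)) {
    stop(name, " needs optical constants for pretraining")
  }
  force(cfg)
  function(train, test, seed) {
    if (name == "PLSR") {
      bs <- fitBandStats(train)
      Xtr <- reflectance(standardize(train, bs))
      Xte <- reflectance(standardize(test, bs))
      fit <- plsrFit(Xtr, traits(train), ncomp = ncomp, seed = deriveSeed(seed, 61L))
      return(plsrPredict(fit, Xte))
    }
    cfg2 <- cfg
    cfg2$seed <- deriveSeed(seed, 62L)
    ecfg <- encoder_cfg %||% encoderConfig("small", seed = cfg2$seed)
    ecfg$seed <- cfg2$seed
    model <- buildTraitModel(ecfg)
    if (needs_physics) {
      corpus <- generateCorpus(
        n = pretrain_n, constants = constants,
        seed = deriveSeed(seed, 63L)
      )
      pretrain(model, corpus, cfg2)
    }
    if (name %in% c("ResNet-GRL", "PPADA-Net")) {
      adapt(model, train, test, cfg2)
    } else {
      # supervised (fine-)tuning on the training datasets only
      ft_cfg <- cfg2
      ft_cfg$stage1_epochs <- cfg2$stage2_epochs
      ft_cfg$stage1_batch <- cfg2$stage2_batch
      ft_cfg$stage1_lr <- if (needs_physics) cfg2$stage2_lr else cfg2$stage1_lr
      ft_cfg$stage1_lr_end <- cfg2$stage2_lr
      if (!needs_physics) model$scaler <- NULL
      pretrain(model, train, ft_cfg)
    }
    predictTraits(model, test)
  }
}

#' Leave-one-dataset-out (and pairwise) validation
#'
#' One trial per held-out table: the remaining tables train the model
#' and the held-out table is predicted. In `pairwise` mode every
#' ordered pair (train dataset, test dataset) is one trial. All
#' statistics a runner fits (band standardization, target scalers,
#' PLSR components) come from its training rows only.
#'
#' @param tables named list of >= 2 [SpectraSet-class] objects.
#' @param runner a [modelRunner()]-style closure (or oracle).
#' @param pairwise `FALSE` for leave-one-out trials, `TRUE` for all
#'   ordered pairs.
#' @param seed integer seed passed to the runner.
#' @param model_name label recorded in the report.
#' @return `EvalReport` data.frame: one row per trial x trait with
#'   columns protocol, model, train, test, seed, trait, r2, nrmse.
#' @export
leaveOneDatasetOut <- function(tables, runner, pairwise = FALSE,
                               seed = 1L, model_name = "model") {
  if (length(tables) < 2) stop("need at least 2 tables")
  nm <- names(tables) %||% sprintf("D%d", seq_along(tables))
  if (is.null(names(tables))) names(tables) <- nm
  rows <- list()
  if (pairwise) {
    for (i in seq_along(tables)) {
      for (j in seq_along(tables)) {
        if (i == j) next
        pred <- runner(tables[[i]], tables[[j]], seed)
        rows[[length(rows) + 1]] <- reportRow(
          "pairwise", model_name, nm[i], nm[j], seed,
          traits(tables[[j]]), pred
        )
      }
    }
  } else {
    for (j in seq_along(tables)) {
      train <- combineSpectraSets(tables[-j])
      pred <- runner(train, tables[[j]], seed)
      rows[[length(rows) + 1]] <- reportRow(
        "lodo", model_name, paste(nm[-j], collapse = "+"), nm[j], seed,
        traits(tables[[j]]), pred
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("EvalReport", class(out))
  out
}

#' Stratified k-fold evaluation
#'
#' Runs a model runner over every fold of a [stratifiedKfold()] plan.
#'
#' @param plan a `KFoldPlan`.
#' @param runner a [modelRunner()]-style closure.
#' @param seed integer seed passed to the runner.
#' @param model_name label recorded in the report.
#' @return `EvalReport` data.frame (one row per fold x trait).
#' @export
evaluateKfold <- function(plan, runner, seed = 1L, model_name = "model") {
  stopifnot(inherits(plan, "KFoldPlan"))
  rows <- lapply(seq_len(plan$k), function(f) {
    sp <- plan$splits[[f]]
    train <- subsetSpectra(plan$pooled, sp$train)
    test <- subsetSpectra(plan$pooled, sp$test)
    pred <- runner(train, test, deriveSeed(seed, f))
    reportRow(
      "kfold", model_name, sprintf("fold%d-train", f),
      sprintf("fold%d-test", f), seed, traits(test), pred
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("EvalReport", class(out))
  out
}

#' Benchmark the model zoo on one scenario
#'
#' Runs the requested models on a shared source/target scenario with
#' identical splits and seeds, reporting target-domain metrics per
#' model x trait (mean and sd over the seeds).
#'
#' @param scenario a [domainShiftConfig()] (realized via
#'   [makeDomainPair()]) or a list `list(source =, target =)` of
#'   [SpectraSet-class] objects.
#' @param models character vector of [modelRunner()] names.
#' @param constants an [OpticalConstants-class] for the physics-based
#'   models (and for scenario realization).
#' @param cfg a [trainConfig()].
#' @param seeds integer vector of replicate seeds.
#' @param pretrain_n synthetic pretraining-corpus size.
#' @param encoder_cfg an [encoderConfig()].
#' @return `EvalReport` data.frame over model x trait x seed; the
#'   evaluation rows are the target rows not flagged few-shot.
#' @export
benchmark <- function(scenario,
                      models = c("PLSR", "ResNet", "ResNet-PROSPECT", "ResNet-GRL", "PPADA-Net"),
                      constants = NULL, cfg = trainConfig(), seeds = 1L,
                      pretrain_n = 2000L, encoder_cfg = NULL) {
  known <- c("PLSR", "ResNet", "ResNet-PROSPECT", "ResNet-GRL", "PPADA-Net")
  bad <- setdiff(models, known)
  if (length(bad)) stop("unknown model name(s): ", paste(bad, collapse = ", "))
  if (inherits(scenario, "DomainShiftConfig")) {
    if (is.null(constants)) stop("scenario realization needs optical constants")
    pair <- makeDomainPair(scenario, constants)
  } else {
    pair <- scenario
  }
  eval_idx <- which(!fewShot(pair$target))
  test <- subsetSpectra(pair$target, eval_idx)
  rows <- list()
  for (m in models) {
    run <- modelRunner(m,
      constants = constants, cfg = cfg,
      pretrain_n = pretrain_n, encoder_cfg = encoder_cfg
    )
    for (s in seeds) {
      pred <- run(pair$source, pair$target, s)[eval_idx, , drop = FALSE]
      rows[[length(rows) + 1]] <- reportRow(
        "benchmark", m, "source", "target", s, traits(test), pred
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("EvalReport", class(out))
  out
}

#' Aggregate an EvalReport
#'
#' @param report an `EvalReport` data.frame.
#' @return data.frame of mean and sd of R-squared and nRMSE per
#'   model x trait.
#' @export
summarizeReport <- function(report) {
  agg <- stats::aggregate(
    cbind(r2, nrmse) ~ model + trait, report,
    function(v) c(mean = mean(v), sd = stats::sd(v))
  )
  data.frame(
    model = agg$model, trait = agg$trait,
    r2_mean = agg$r2[, "mean"], r2_sd = agg$r2[, "sd"],
    nrmse_mean = agg$nrmse[, "mean"], nrmse_sd = agg$nrmse[, "sd"]
  )
}

#' Pretraining-corpus size sweep
#'
#' Pretrains the encoder on corpora of increasing size and evaluates
#' trait recovery on an independent simulated test set, tracing how
#' physics-informed accuracy grows with synthetic data volume.
#'
#' @param sizes corpus sizes, e.g. `seq(2000, 20000, by = 2000)`.
#' @param constants an [OpticalConstants-class].
#' @param cfg a [trainConfig()].
#' @param n_test held-out simulated test leaves (default 500).
#' @param seed integer seed.
#' @param encoder_cfg an [encoderConfig()].
#' @return data.frame with one row per size x trait (`r2`, `nrmse`).
#' @export
sweepPretrainSize <- function(sizes, constants, cfg = trainConfig(),
                              n_test = 500L, seed = 1L, encoder_cfg = NULL) {
  test <- generateCorpus(
    n = n_test, constants = constants,
    seed = deriveSeed(seed, 71L)
  )
  rows <- list()
  for (nz in sizes) {
    ecfg <- encoder_cfg %||% encoderConfig("small")
    ecfg$seed <- deriveSeed(seed, 72L)
    model <- buildTraitModel(ecfg)
    corpus <- generateCorpus(
      n = nz, constants = constants,
      seed = deriveSeed(seed, 73L)
    )
    cfg2 <- cfg
    cfg2$seed <- deriveSeed(seed, 74L)
    pretrain(model, corpus, cfg2)
    pred <- predictTraits(model, test)
    rows[[length(rows) + 1]] <- cbind(
      size = nz,
      reportRow("pretrain-sweep", "PPADA-pretrain", "synthetic", "synthetic", seed, traits(test), pred)
    )
  }
  do.call(rbind, rows)
}
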