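# Metrics, validation protocols, and the benchmark harness.

bruteR2 <- function(y, yhat) {
  num <- 0
  den <- 0
  yb <- sum(y) / length(y)
  for (i in seq_along(y)) {
    num <- num + (yhat[i] - y[i])^2
    den <- den + (y[i] - yb)^2
  }
  1 - num / den
}

bruteNrmse <- function(y, yhat) {
  s <- 0
  for (i in seq_along(y)) s <- s + (yhat[i] - y[i])^2
  sqrt(s / length(y)) / (sum(y) / length(y))
}

test_that("metrics match brute-force arithmetic and hand-checked cases", {
  # hand cases
  y <- c(1, 2, 3)
  yhat <- c(2, 3, 4)
  expect_equal(rSquared(y, yhat), -0.5, tolerance = 1e-15)
  expect_equal(nrmse(y, yhat), 0.5, tolerance = 1e-15)
  expect_equal(rSquared(y, y), 1)
  expect_equal(rSquared(y, rep(mean(y), 3)), 0)
  expect_equal(nrmse(y, y), 0)

  # scale invariance of nRMSE
  expect_equal(nrmse(10 * y, 10 * yhat), nrmse(y, yhat), tolerance = 1e-12)

  # brute-force comparison over many random vectors
  set.seed(77)
  for (i in 1:200) {
    n <- sample(2:50, 1)
    a <- rnorm(n)
    b <- rnorm(n)
    a <- a + seq_len(n) * 0.01 # avoid constant y
    expect_equal(rSquared(a, b), bruteR2(a, b), tolerance = 1e-12)
    if (abs(mean(a)) > 1e-6) {
      expect_equal(nrmse(a, b), bruteNrmse(a, b), tolerance = 1e-12)
    }
  }

  expect_error(rSquared(rep(1, 5), rnorm(5)), "constant")
  expect_error(nrmse(c(-1, 1), c(0, 0)), "division")
  expect_error(rSquared(1, 1), "at least 2")
})

test_that("stratified k-fold keeps per-dataset proportions within one", {
  tb <- twoDomainTable(n_per = 50)
  plan <- stratifiedKfold(list(tb$a, tb$b), k = 5, seed = 3)
  expect_equal(sort(unlist(lapply(plan$splits, `[[`, "test"))), 1:100)

  dom <- domainLabels(plan$pooled)
  for (f in 1:5) {
    test <- plan$splits[[f]]$test
    expect_true(abs(sum(dom[test] == "D1") - 10) <= 1)
    expect_true(abs(sum(dom[test] == "D2") - 10) <= 1)
    # train/val/test partition each fold's complement
    sp <- plan$splits[[f]]
    expect_length(intersect(sp$train, sp$test), 0)
    expect_length(intersect(sp$val, sp$test), 0)
    expect_length(intersect(sp$train, sp$val), 0)
    expect_equal(length(sp$val), round(0.15 * 80))
  }

  # deterministic given the seed
  plan2 <- stratifiedKfold(list(tb$a, tb$b), k = 5, seed = 3)
  expect_identical(plan$fold, plan2$fold)

  small <- subsetSpectra <- plan$pooled[, 1:3]
  expect_error(stratifiedKfold(list(tb$a[, 1:3]), k = 5), "smaller than k")
})

test_that("LODO and pairwise protocols produce the right trial structure", {
  oc <- coarseConstants()
  tabs <- lapply(1:5, function(i) {
    generateCorpus(n = 12, constants = oc, seed = 100 + i, domain = paste0("D", i))
  })
  names(tabs) <- paste0("D", 1:5)

  seen <- new.env()
  seen$pairs <- list()
  spyOracle <- function(train, test, seed) {
    # leakage check: held-out ids never intersect training ids
    expect_length(
      intersect(colData(train)$sample_id, colData(test)$sample_id), 0
    )
    seen$pairs <- c(seen$pairs, list(c(ncol(train), ncol(test))))
    traits(test)
  }

  lodo <- leaveOneDatasetOut(tabs, spyOracle, model_name = "oracle")
  expect_equal(nrow(lodo), 5 * 3) # 5 trials x 3 traits
  expect_true(all(lodo$r2 == 1))
  expect_true(all(lodo$nrmse == 0))

  pw <- leaveOneDatasetOut(tabs, spyOracle, pairwise = TRUE, model_name = "oracle")
  expect_equal(nrow(pw), 20 * 3) # 20 ordered train-test groups
  expect_setequal(unique(paste(pw$train, pw$test)),
    apply(expand.grid(paste0("D", 1:5), paste0("D", 1:5)), 1, function(r) {
      if (r[1] == r[2]) NA else paste(r[1], r[2])
    })[!is.na(apply(expand.grid(1:5, 1:5), 1, function(r) if (r[1] == r[2]) NA else 1))])

  # two identical tables: symmetric trials give identical metrics
  twin <- list(A = tabs[[1]], B = tabs[[1]])
  pred_plsr <- modelRunner("PLSR", ncomp = 3)
  rep2 <- leaveOneDatasetOut(twin, pred_plsr, pairwise = TRUE, model_name = "PLSR")
  ab <- rep2[rep2$train == "A", c("trait", "r2", "nrmse")]
  ba <- rep2[rep2$train == "B", c("trait", "r2", "nrmse")]
  expect_equal(ab$r2, ba$r2, tolerance = 1e-10)

  expect_error(leaveOneDatasetOut(tabs[1], spyOracle), "at least 2")
})

test_that("the oracle model is perfect under every protocol", {
  tb <- twoDomainTable(n_per = 25)
  plan <- stratifiedKfold(list(tb$a, tb$b), k = 5, seed = 2)
  rep_k <- evaluateKfold(plan, oracleRunner, model_name = "oracle")
  expect_true(all(rep_k$r2 == 1))
  expect_true(all(rep_k$nrmse == 0))

  rep_l <- leaveOneDatasetOut(list(D1 = tb$a, D2 = tb$b), oracleRunner)
  expect_true(all(rep_l$r2 == 1 & rep_l$nrmse == 0))
})

test_that("PLSR transfers well on a mild synthetic domain shift", {
  oc <- coarseConstants()
  pair <- makeDomainPair(
    domainShiftConfig(
      gain = 1.02, noise_sd = 0.002,
      n_source = 120, n_target = 60, seed = 5
    ),
    oc
  )
  run <- modelRunner("PLSR", ncomp = 12)
  pred <- run(pair$source, pair$target, 1)
  y <- traits(pair$target)
  expect_gt(rSquared(y[, "CHL"], pred[, "CHL"]), 0.8)
  expect_gt(rSquared(y[, "EWT"], pred[, "EWT"]), 0.8)
})

test_that("benchmark produces the model x trait x metric grid", {
  oc <- coarseConstants()
  scen <- domainShiftConfig(
    target_ranges = prospectRanges(Cab = c(20.1, 110)),
    gain = 0.97, noise_sd = 0.005,
    n_source = 40, n_target = 40, fewshot_frac = 0.2, seed = 12
  )
  cfg <- trainConfig(
    stage1_epochs = 1, stage2_epochs = 1,
    stage1_batch = 16, stage2_batch = 16, seed = 12
  )
  ecfg <- encoderConfig("small", side = 16L)
  rep5 <- benchmark(scen,
    models = c("PLSR", "ResNet", "ResNet-PROSPECT", "ResNet-GRL", "PPADA-Net"),
    constants = oc, cfg = cfg, seeds = 1L,
    pretrain_n = 40L, encoder_cfg = ecfg
  )
  # 5 models x 3 traits, two metrics per row
  expect_equal(nrow(rep5), 15L)
  expect_setequal(unique(rep5$model),
    c("PLSR", "ResNet", "ResNet-PROSPECT", "ResNet-GRL", "PPADA-Net"))
  expect_true(all(c("r2", "nrmse") %in% colnames(rep5)))
  expect_true(all(is.finite(rep5$r2)))

  summ <- summarizeReport(rep5)
  expect_equal(nrow(summ), 15L)

  expect_error(benchmark(scen, models = "GPT", constants = oc), "unknown model")
})

test_that("the pretraining-size sweep emits one row per size and trait", {
  oc <- coarseConstants()
  cfg <- trainConfig(stage1_epochs = 1, stage1_batch = 16, seed = 3)
  sw <- sweepPretrainSize(c(30, 60), oc,
    cfg = cfg, n_test = 20,
    encoder_cfg = encoderConfig("small", side = 16L)
  )
  expect_equal(nrow(sw), 2 * 3)
  expect_setequal(unique(sw$size), c(30, 60))
})
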