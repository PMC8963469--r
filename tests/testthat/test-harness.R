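test_that("metric formulas match hand computations and inequalities", {
  y <- c(1, 2, 3, 4); yhat <- c(1, 2, 3, 5)
  expect_equal(r2Score(y, yhat), 0.8, tolerance = 1e-12)
  expect_equal(maeScore(y, yhat), 0.25, tolerance = 1e-12)
  expect_equal(rmseScore(y, yhat), 0.5, tolerance = 1e-12)
  expect_equal(r2Score(y, y), 1)
  expect_equal(rmseScore(y, y), 0)
  expect_error(r2Score(rep(2, 5), 1:5), "constant")
  # RMSE >= MAE (power-mean inequality) on random prediction pairs
  set.seed(4)
  for (i in 1:20) {
    a <- rnorm(50); b <- rnorm(50)
    expect_gte(rmseScore(a, b), maeScore(a, b))
  }
})

test_that("stratified splitting matches the documented counts and distributions", {
  ds <- sharedDataset("vis")
  sp <- splitDataset(ds, seed = 3)
  nTr <- table(sp$train@campaign)[sp$train@campaignLevels]
  nVa <- table(sp$validation@campaign)[sp$validation@campaignLevels]
  expect_identical(unname(as.integer(nTr)), c(86L, 86L, 86L, 86L, 60L))
  expect_identical(unname(as.integer(nVa)), c(22L, 22L, 22L, 22L, 15L))
  # per-campaign medians agree closely between the subsets
  for (cp in ds@campaignLevels) {
    mTr <- median(sp$train@y[sp$train@campaign == cp])
    mVa <- median(sp$validation@y[sp$validation@campaign == cp])
    expect_lt(abs(mTr - mVa), 2.5)
  }
  # deterministic under the seed
  sp2 <- splitDataset(ds, seed = 3)
  expect_identical(sp$train@y, sp2$train@y)
})

test_that("small campaigns split 4/1 and tiny ones error", {
  x <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("a", "b")))
  ds <- new("SpadDataset", x = x, y = 1:5 + 0.0, campaign = rep("t1", 5),
            campaignLevels = "t1", predictorSet = "vis")
  sp <- splitDataset(ds, seed = 1)
  expect_length(sp$train@y, 4L)
  expect_length(sp$validation@y, 1L)
  tiny <- new("SpadDataset", x = x[1:4, ], y = 1:4 + 0.0,
              campaign = rep("t1", 4), campaignLevels = "t1",
              predictorSet = "vis")
  expect_error(splitDataset(tiny), "too small")
})

test_that("large-sample stratified medians match an exhaustive sort-and-deal oracle", {
  spec <- campaignSpec("t", c(21, 29, 33, 38, 45), 10000L)
  y <- simulateSpad(spec, seed = 21)
  x <- matrix(y + rnorm(10000), ncol = 1, dimnames = list(NULL, "v"))
  ds <- new("SpadDataset", x = x, y = y, campaign = rep("t", 10000L),
            campaignLevels = "t", predictorSet = "vis")
  sp <- splitDataset(ds, seed = 5)
  expect_lt(abs(median(sp$train@y) - median(sp$validation@y)), 0.5)
  # oracle: dealing one of each consecutive 5 sorted values into validation
  # bounds the achievable median gap; the implementation must do as well
  ys <- sort(y)
  oracleVal <- ys[seq(3, 10000, by = 5)]   # middle of each rank group
  expect_lt(abs(median(sp$validation@y) - median(oracleVal)), 0.5)
})

test_that("the roster contains the 17 configurations with the named variants", {
  cfgs <- rosterConfigs()
  expect_length(cfgs, 17L)
  fam <- vapply(cfgs, `[[`, character(1), "family")
  expect_identical(as.integer(table(fam)[c("linear", "plsr", "tree",
                                           "ensemble", "svr", "gpr")]),
                   c(1L, 1L, 3L, 2L, 6L, 4L))
  expect_true(all(c("gpr_exponential", "gpr_squared_exponential",
                    "gpr_matern52", "gpr_rational_quadratic",
                    "svr_linear", "svr_quadratic", "svr_cubic",
                    "ensemble_boosted", "ensemble_bagged_rf") %in%
                    names(cfgs)))
  expect_identical(cfgs$ensemble_bagged_rf$hyperparams$ntrees, 60L)
  expect_identical(cfgs$ensemble_boosted$hyperparams$ntrees, 60L)
})

test_that("linear data is recovered to numerical precision by the linear family", {
  set.seed(7)
  x <- matrix(rnorm(400), 100, 4, dimnames = list(NULL, paste0("x", 1:4)))
  beta <- c(2, -1, 0.5, 3)
  y <- drop(x %*% beta) + 7
  ds <- new("SpadDataset", x = x, y = y, campaign = rep("t1", 100),
            campaignLevels = "t1", predictorSet = "vis")
  m <- fitSequential(rosterConfigs()$linear_ols, ds, seed = 1)
  # closed-form least-squares oracle via the normal equations
  A <- cbind(1, x)
  betaHat <- solve(t(A) %*% A, t(A) %*% y)
  expect_lt(max(abs(coef(m@fit) - betaHat)), 1e-8)
  expect_lt(max(abs(predictSpad(m, x) - y)), 1e-8)
})

test_that("cross-validated R2 scores sensible models and rejects constant y", {
  ds <- sharedDataset("vis")
  sp <- splitDataset(ds, seed = 3)
  r2 <- crossValidateR2(rosterConfigs()$plsr_plsr, sp$train, seed = 1)
  expect_gt(r2, 0.7)
  expect_lte(r2, 1)
  const <- new("SpadDataset", x = sp$train@x, y = rep(5, length(sp$train@y)),
               campaign = sp$train@campaign,
               campaignLevels = sp$train@campaignLevels, predictorSet = "vis")
  expect_error(crossValidateR2(rosterConfigs()$plsr_plsr, const), "constant")
})

test_that("with a single campaign, sequential and retraining coincide", {
  tab <- sharedTable()
  one <- tab[tab$campaign == tab$campaign[1L], ]
  ds <- suppressWarnings(makeDataset(one, "vis"))
  for (nm in c("plsr_plsr", "ensemble_bagged_rf")) {
    cfg <- rosterConfigs()[[nm]]
    mS <- fitSequential(cfg, ds, seed = 11)
    mR <- fitRetraining(cfg, ds, seed = 11)
    expect_length(mR, 1L)
    expect_identical(predictSpad(mS, ds@x), predictSpad(mR[[1L]], ds@x))
  }
})

test_that("retraining uses moving two-campaign windows with frozen tuning", {
  ds <- sharedDataset("vis")
  sp <- splitDataset(ds, seed = 3)
  cfg <- rosterConfigs()$plsr_plsr
  models <- fitRetraining(cfg, sp$train, seed = 2)
  expect_length(models, 5L)
  expect_named(models, sp$train@campaignLevels)
  # component count tuned on the first campaign and frozen afterwards
  ncomps <- vapply(models, function(m) m@config$hyperparams$ncomp,
                   integer(1))
  expect_true(all(ncomps == ncomps[1L]))
  # a missing campaign is rejected
  part <- chlorospec:::datasetSlice(sp$train, sp$train@campaign != "20171218")
  expect_error(fitRetraining(cfg, part, seed = 2), "missing campaign")
})

test_that("evaluation produces per-campaign records with valid predictions", {
  ds <- sharedDataset("vis")
  sp <- splitDataset(ds, seed = 3)
  m <- fitSequential(rosterConfigs()$plsr_plsr, sp$train, seed = 1)
  rec <- evaluateModel(m, sp$validation)
  expect_identical(rec$scope,
                   c("overall", sp$validation@campaignLevels))
  expect_true(all(rec$rmse >= rec$mae))
  expect_true(all(rec$rmse >= 0))
  expect_identical(rec$strategy[1L], "sequential")
})

test_that("the 5-unit threshold keeps and excludes the documented records", {
  rec <- data.frame(model = c("plsr_all", "plsr_selected", "x"),
                    rmse = c(4.40, 5.45, 5.0),
                    mae = c(3.50, 4.27, 5.0))
  out <- selectModels(rec, threshold = 5)
  expect_identical(out$selected$model, c("plsr_all", "x"))
  expect_identical(out$excluded$model, "plsr_selected")
  empty <- rec[0, ]
  outE <- selectModels(empty)
  expect_identical(nrow(outE$selected), 0L)
})

test_that("correlation diagnostics are exact and flag degenerate columns", {
  x <- c(1, 3, 4, 6, 8, 9)
  m <- cbind(a = x, b = -x, c = c(2, 1, 4, 3, 6, 5))
  ds <- new("SpadDataset", x = m, y = x, campaign = rep("t", 6),
            campaignLevels = "t", predictorSet = "vis")
  r <- correlationMatrix(ds)
  expect_equal(unname(r["spad", "a"]), 1, tolerance = 1e-12)
  expect_equal(unname(r["spad", "b"]), -1, tolerance = 1e-12)
  # hand computation of Pearson r for the third column
  hand <- sum((x - mean(x)) * (m[, 3] - mean(m[, 3]))) /
    sqrt(sum((x - mean(x))^2) * sum((m[, 3] - mean(m[, 3]))^2))
  expect_equal(unname(r["spad", "c"]), hand, tolerance = 1e-12)
  expect_true(isSymmetric(r))
  expect_true(all(abs(r) <= 1 + 1e-12))
  mc <- cbind(m, d = rep(1, 6))
  dsc <- new("SpadDataset", x = mc, y = x, campaign = rep("t", 6),
             campaignLevels = "t", predictorSet = "vis")
  expect_warning(rc <- correlationMatrix(dsc), "constant")
  expect_true(is.na(rc["d", "a"]) && is.na(rc["spad", "d"]))
})

test_that("distribution comparison reports exact gaps and flags", {
  obs <- c(30, 32, 34, 50, 52, 54)
  cps <- rep(c("t1", "t2"), each = 3)
  same <- compareDistributions(obs, cps, obs, cps)
  expect_equal(same$medianGap, c(0, 0), tolerance = 1e-12)
  expect_false(any(same$flagged))
  shifted <- compareDistributions(obs + 3, cps, obs, cps)
  expect_equal(shifted$medianGap, c(3, 3), tolerance = 1e-12)
  # independent quantile check of the summary columns
  expect_equal(shifted$predMedian[1L],
               unname(quantile(obs[1:3] + 3, 0.5)), tolerance = 1e-12)
  missing <- compareDistributions(obs[1:3], cps[1:3], obs, cps)
  expect_true(missing$flagged[missing$campaign == "t2"])
})

test_that("the 145-band predictor matrix is the column subset of the all-bands matrix", {
  dsAll <- sharedDataset("all_bands")
  dsSel <- sharedDataset("selected_bands")
  sel <- registryWavelengths(viRegistry())
  expect_identical(ncol(dsSel@x), 145L)
  expect_identical(colnames(dsSel@x), sprintf("b%.3f", sel))
  expect_identical(dsSel@x, dsAll@x[, colnames(dsSel@x)])
})

test_that("metrics records reproduce exactly under identical seeds", {
  ds <- sharedDataset("vis")
  sp <- splitDataset(ds, seed = 3)
  for (nm in c("plsr_plsr", "ensemble_bagged_rf", "svr_medium_gaussian")) {
    cfg <- rosterConfigs()[[nm]]
    m1 <- fitSequential(cfg, sp$train, seed = 17)
    m2 <- fitSequential(cfg, sp$train, seed = 17)
    e1 <- evaluateModel(m1, sp$validation)
    e2 <- evaluateModel(m2, sp$validation)
    expect_identical(e1$rmse, e2$rmse)
    expect_identical(e1$mae, e2$mae)
  }
})

test_that("NIPALS PLSR agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(3)
  x <- matrix(rnorm(300), 60, 5, dimnames = list(NULL, paste0("v", 1:5)))
  y <- 2 * x[, 1] - x[, 3] + rnorm(60, 0, 0.3)
  fit <- chlorospec:::plsrCore(x, y, 3L)
  ours <- chlorospec:::plsrPredict(fit, x)
  mo <- mixOmics::pls(x, matrix(y, ncol = 1), ncomp = 3,
                      mode = "regression", scale = TRUE)
  theirs <- predict(mo, x)$predict[, 1, 3]
  expect_lt(max(abs(ours - theirs)), 1e-10)
  expect_equal(abs(cor(fit$weights[, 1], mo$loadings$X[, 1])), 1,
               tolerance = 1e-9)
})
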