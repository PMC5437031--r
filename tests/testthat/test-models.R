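# Base classifiers, fusion, fingerprint ranking, serialization.

test_that("a flexible learner separates linearly separable toy data", {
  X <- withr::with_seed(1, {
    cbind(f1 = c(rnorm(10, -2), rnorm(10, 2)),
          f2 = c(rnorm(10, -2), rnorm(10, 2)))
  })
  y <- rep(c(0, 1), each = 10)
  mdl <- trainBase(X, y, baseConfig("random_forest", seed = 1))
  p <- predictBase(mdl, X)
  expect_equal(as.integer(p >= 0.5), y)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("degenerate inputs are refused", {
  X <- matrix(rnorm(20), 10)
  colnames(X) <- c("a", "b")
  expect_error(trainBase(X, rep(1, 10), baseConfig("random_forest")),
               "single class")
  expect_error(trainBase(X[, 0], rep(c(0, 1), 5),
                         baseConfig("random_forest")), "feature")
})

test_that("all three algorithms beat the majority baseline on planted signal", {
  fx <- smallFixture(200, seed = 1)
  cs <- fx$compounds
  y <- compoundLabels(cs)
  fm <- featureSelect(computeMatrix(cs, "MACCS"))$matrix
  X <- fpValues(fm)
  folds <- withr::with_seed(1, sample(rep_len(1:5, length(y))))
  for (alg in c("svm_rbf", "random_forest", "xgboost")) {
    correct <- 0
    for (f in 1:5) {
      mdl <- trainBase(X[folds != f, , drop = FALSE], y[folds != f],
                       baseConfig(alg, seed = 1))
      p <- predictBase(mdl, X[folds == f, , drop = FALSE])
      correct <- correct + sum((p >= 0.5) == (y[folds == f] == 1))
    }
    acc <- 100 * correct / length(y)
    majority <- 100 * max(table(y)) / length(y)
    expect_gte(acc, majority + 10)
  }
})

test_that("hyperparameter search runs on training rows and is reproducible", {
  fx <- smallFixture(60, seed = 2)
  X <- fpValues(featureSelect(computeMatrix(fx$compounds, "MACCS"))$matrix)
  y <- compoundLabels(fx$compounds)
  cfg <- baseConfig("svm_rbf", seed = 5, tune = TRUE, n_draws = 4L,
                    inner_k = 3L)
  m1 <- trainBase(X, y, cfg)
  m2 <- trainBase(X, y, cfg)
  expect_equal(predictBase(m1, X), predictBase(m2, X))
  xcfg <- baseConfig("xgboost", seed = 5, tune = TRUE, inner_k = 3L,
                     grid = expand.grid(eta = c(0.1, 0.3), max_depth = 3L,
                                        min_child_weight = 1,
                                        nrounds = 20L))
  m3 <- trainBase(X, y, xcfg)
  expect_true(all(predictBase(m3, X) >= 0 & predictBase(m3, X) <= 1))
})

test_that("ensemble probability is the arithmetic mean of member probabilities", {
  fx <- smallFixture(40, seed = 3)
  cs <- fx$compounds
  fams <- c("MACCS", "Estate", "FP4")
  mats <- computeMatrices(cs, fams)
  mdl <- trainEnsemble(cs, fams, "random_forest", matrices = mats,
                       base = baseConfig("random_forest", seed = 1))
  pred <- ensemblePredict(mdl, mats)
  # recompute the mean outside the model path
  manual <- rowMeans(vapply(fams, function(f)
    predictBase(mdl@members[[f]], mats[[f]]), numeric(length(cs))))
  expect_equal(pred$probability, unname(manual), tolerance = 1e-12)
  # bounded by member min/max and permutation-invariant
  pm <- as.matrix(pred[, paste0("prob_", fams)])
  expect_true(all(pred$probability >= apply(pm, 1, min) - 1e-12))
  expect_true(all(pred$probability <= apply(pm, 1, max) + 1e-12))
  mdl_perm <- mdl
  mdl_perm@members <- rev(mdl@members)
  expect_equal(ensemblePredict(mdl_perm, mats)$probability,
               pred$probability)
  # single member: ensemble equals that base classifier
  mdl1 <- mdl
  mdl1@members <- mdl@members["MACCS"]
  expect_equal(ensemblePredict(mdl1, mats)$probability,
               predictBase(mdl@members$MACCS, mats$MACCS))
})

test_that("fusion of fixed member probabilities respects the 0.5 rule", {
  # 7 members at 0,0,0,0,1,1,1 -> mean 3/7, class non-carcinogen
  p <- c(0, 0, 0, 0, 1, 1, 1)
  expect_equal(mean(p), 3 / 7, tolerance = 1e-12)
  expect_lt(mean(p), 0.5)
  m <- suppressWarnings(computeMetrics(1, mean(p)))   # one-class AUC NA
  expect_equal(m$FN, 1)   # called negative
  # threshold is inclusive at exactly 0.5
  expect_equal(suppressWarnings(computeMetrics(1, 0.5))$TP, 1)
})

test_that("fingerprint ranking: published per-family accuracies pick the top seven", {
  q <- data.frame(
    algorithm = rep(c("svm", "rf", "xgb"), each = 12),
    fingerprint = rep(c("CDK", "CDKExt", "CDKGraph", "Estate", "MACCS",
                        "Pubchem", "FP4", "FP4C", "KR", "KRC", "AP2D",
                        "AP2DC"), 3),
    Q = c(67.5, 67.9, 65.0, 63.0, 67.1, 68.1, 64.6, 62.2, 66.5, 66.7,
          63.5, 63.4,
          68.3, 68.4, 66.6, 64.2, 67.4, 68.0, 62.1, 63.6, 67.0, 66.5,
          64.1, 64.7,
          67.0, 68.3, 65.1, 63.0, 67.2, 67.8, 62.5, 61.1, 66.0, 66.5,
          64.4, 64.4))
  top7 <- rankFingerprints(q, k = 7)
  expect_setequal(top7, c("CDK", "CDKExt", "CDKGraph", "MACCS", "Pubchem",
                          "KR", "KRC"))
  expect_setequal(setdiff(unique(q$fingerprint), top7),
                  c("Estate", "FP4", "FP4C", "AP2D", "AP2DC"))
})

test_that("fingerprint ranking is a stable sort, agreeing with brute force", {
  tab <- withr::with_seed(11, data.frame(
    algorithm = rep(c("a", "b"), each = 6),
    fingerprint = rep(paste0("f", 1:6), 2),
    Q = round(runif(12, 60, 70), 1)))
  ranked <- rankFingerprints(tab)
  means <- tapply(tab$Q, tab$fingerprint, mean)[unique(tab$fingerprint)]
  brute <- names(means)[order(-means)]
  expect_equal(ranked, brute)
  # all-equal accuracies preserve input order
  tab$Q <- 65
  expect_equal(rankFingerprints(tab), paste0("f", 1:6))
})

test_that("model bundles round-trip and refuse incompatible versions", {
  fx <- smallFixture(40, seed = 3)
  mats <- computeMatrices(fx$compounds, c("MACCS", "Estate"))
  for (alg in c("random_forest", "xgboost", "svm_rbf")) {
    mdl <- trainEnsemble(fx$compounds, c("MACCS", "Estate"), alg,
                         matrices = mats,
                         base = baseConfig(alg, seed = 4))
    path <- withr::local_tempfile(fileext = ".rds")
    saveEnsemble(mdl, path)
    back <- loadEnsemble(path)
    expect_equal(ensemblePredict(back, mats)$probability,
                 ensemblePredict(mdl, mats)$probability,
                 tolerance = 1e-10)
  }
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(format_version = "0"), bad)
  expect_error(loadEnsemble(bad), "incompatible")
})

test_that("missing member fingerprints raise a contract error naming the member", {
  fx <- smallFixture(40, seed = 3)
  mats <- computeMatrices(fx$compounds, c("MACCS", "Estate"))
  mdl <- trainEnsemble(fx$compounds, c("MACCS", "Estate"), "random_forest",
                       matrices = mats)
  expect_error(ensemblePredict(mdl, mats["MACCS"]), "Estate")
})

test_that("seeded training is reproducible end to end", {
  fx <- smallFixture(50, seed = 4)
  mats <- computeMatrices(fx$compounds, "MACCS")
  for (alg in c("random_forest", "xgboost", "svm_rbf")) {
    m1 <- trainEnsemble(fx$compounds, "MACCS", alg, matrices = mats,
                        base = baseConfig(alg, seed = 9))
    m2 <- trainEnsemble(fx$compounds, "MACCS", alg, matrices = mats,
                        base = baseConfig(alg, seed = 9))
    expect_equal(ensemblePredict(m1, mats)$probability,
                 ensemblePredict(m2, mats)$probability, info = alg)
  }
})
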