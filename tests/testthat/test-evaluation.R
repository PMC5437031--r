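# Repeated cross-validation, external validation, learning curves.

test_that("every compound is tested exactly once per repeat", {
  y <- rep(c(0L, 1L), each = 20)
  for (strat in c(TRUE, FALSE)) {
    folds <- CarcinoEnsemble:::.makeFolds(y, 5L, strat, seed = 123L)
    expect_equal(sort(unique(folds)), 1:5)
    expect_true(all(abs(table(folds) - 8) <= 1))
    # union of test folds = dataset; each index in exactly one fold
    expect_length(folds, 40L)
  }
  # stratified folds keep class balance within one compound
  folds <- CarcinoEnsemble:::.makeFolds(y, 5L, TRUE, seed = 5L)
  for (f in 1:5)
    expect_lte(abs(sum(y[folds == f]) - 4), 1)
})

test_that("repeated CV produces k x repeats records in order, deterministically", {
  fx <- smallFixture(50, seed = 4)
  mats <- computeMatrices(fx$compounds, "MACCS")
  cv <- cvConfig(k = 5, repeats = 3, seed = 42)
  res <- repeatedCV(fx$compounds, "MACCS", "random_forest", cv = cv,
                    matrices = mats)
  rec <- cvRecords(res)
  expect_equal(nrow(rec), 15L)
  expect_equal(rec$`repeat`, rep(1:3, each = 5))
  expect_equal(rec$fold, rep(1:5, 3))
  # per-fold confusion counts cover the fold sizes
  expect_equal(sum(rec$TP + rec$TN + rec$FP + rec$FN), 3 * 50)
  res2 <- repeatedCV(fx$compounds, "MACCS", "random_forest", cv = cv,
                     matrices = mats)
  expect_identical(cvRecords(res2), rec)
  expect_identical(cvSummary(res2), cvSummary(res))
})

test_that("stored summaries match recomputation from the raw records", {
  fx <- smallFixture(50, seed = 4)
  mats <- computeMatrices(fx$compounds, "MACCS")
  res <- repeatedCV(fx$compounds, "MACCS", "random_forest",
                    cv = cvConfig(repeats = 2, seed = 1), matrices = mats)
  rec <- cvRecords(res)
  s <- cvSummary(res)
  expect_equal(s$mean[s$metric == "Q"], mean(rec$Q), tolerance = 1e-10)
  expect_equal(s$sd[s$metric == "SE"], sd(rec$SE), tolerance = 1e-10)
  expect_equal(s$mean[s$metric == "AUC"], mean(100 * rec$AUC),
               tolerance = 1e-10)
})

test_that("label-shuffled data scores at chance", {
  fx <- smallFixture(80, seed = 6)
  y <- compoundLabels(fx$compounds)
  null_cs <- withLabels(fx$compounds,
                        withr::with_seed(1, sample(unname(y))))
  mats <- computeMatrices(null_cs, "MACCS")
  res <- repeatedCV(null_cs, "MACCS", "random_forest",
                    cv = cvConfig(repeats = 5, seed = 2), matrices = mats)
  q <- cvSummary(res)$mean[cvSummary(res)$metric == "Q"]
  expect_gt(q, 35)
  expect_lt(q, 65)
})

test_that("leakage-safe and global selection scopes both run", {
  fx <- smallFixture(50, seed = 4)
  mats <- computeMatrices(fx$compounds, "Estate")
  for (scope in c("fold", "global")) {
    res <- repeatedCV(fx$compounds, "Estate", "random_forest",
                      cv = cvConfig(repeats = 1, seed = 3),
                      fs = featSelConfig(scope = scope), matrices = mats)
    expect_equal(nrow(cvRecords(res)), 5L)
    expect_equal(res@config$scope, scope)
  }
})

test_that("external validation reports resubstitution optimism and flags overlap", {
  fx <- smallFixture(60, seed = 5)
  cs <- fx$compounds
  mats <- computeMatrices(cs, "MACCS")
  mdl <- trainEnsemble(cs, "MACCS", "random_forest", matrices = mats,
                       base = baseConfig("random_forest", seed = 1))
  cvres <- repeatedCV(cs, "MACCS", "random_forest",
                      cv = cvConfig(repeats = 2, seed = 1),
                      matrices = mats)
  # model applied to its own training data: optimistic, and every
  # compound is a duplicate
  expect_warning(ev <- externalValidate(mdl, cs), "duplicated")
  expect_gte(ev$metrics$Q,
             cvSummary(cvres)$mean[cvSummary(cvres)$metric == "Q"])
  expect_equal(nrow(ev$predictions), 60L)

  expect_error(externalValidate(mdl, cs[integer(0)]), "empty")

  # disjoint external set: no warning, one row per compound
  ext <- smallFixture(20, seed = 99)$compounds
  ext <- deduplicate(ext, cs)
  expect_silent(ev2 <- externalValidate(mdl, ext))
  expect_equal(nrow(ev2$predictions), length(ext))
})

test_that("learning-curve bookkeeping: draws, records and disjoint subsamples", {
  fx <- smallFixture(120, seed = 8)
  lc <- learningCurve(fx$compounds, sizes = 100L, repeats = 2L,
                      fingerprints = "MACCS", seed = 3)
  cvrec <- lc$records[lc$records$phase == "cv", ]
  expect_equal(nrow(cvrec), 2L)          # one row per subsample draw
  expect_equal(unique(cvrec$size), 100L)
  expect_true(all(c("mean", "se") %in% names(lc$summary)))
  expect_error(learningCurve(fx$compounds, sizes = 500L, repeats = 1L,
                             fingerprints = "MACCS"), "exceeds")
  # subsamples are drawn without replacement
  sub <- withr::with_seed(deriveSeed(3, "lc-100-1-1"),
                          sample(120, 100))
  expect_equal(anyDuplicated(sub), 0L)
})

test_that("learning curves rise with sample size under planted signal", {
  # weaker enrichment than the default fixture, so performance is still
  # data-limited (a near-perfect single bit saturates at tiny n)
  fx <- generateFixture(fixtureConfig(n_total = 300, seed = 2,
                                      motifs = defaultMotifs(enrich = 0.65,
                                                             leak = 0.35)))
  lc <- learningCurve(fx$compounds, sizes = c(50L, 250L), repeats = 10L,
                      fingerprints = "MACCS", seed = 2)
  s <- lc$summary
  q_small <- s$mean[s$size == 50 & s$metric == "Q" & s$phase == "cv"]
  q_large <- s$mean[s$size == 250 & s$metric == "Q" & s$phase == "cv"]
  expect_gte(q_large, q_small)
})

test_that("CV results serialize to tidy CSV and JSON", {
  fx <- smallFixture(50, seed = 4)
  mats <- computeMatrices(fx$compounds, "Estate")
  res <- repeatedCV(fx$compounds, "Estate", "random_forest",
                    cv = cvConfig(repeats = 1, seed = 1), matrices = mats)
  csv <- withr::local_tempfile(fileext = ".csv")
  json <- withr::local_tempfile(fileext = ".json")
  writeCVResult(res, csv = csv, json = json)
  back <- read.csv(csv)
  expect_equal(nrow(back), 5L)
  expect_true(all(c("repeat.", "fold", "TP", "TN", "FP", "FN", "Q", "SE",
                    "SP", "AUC") %in% names(back)))
  js <- jsonlite::read_json(json)
  expect_equal(js$config$k, 5L)
})
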