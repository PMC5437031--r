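# Gini-importance substructure mining and occurrence counts.

test_that("a perfectly discriminative planted key ranks first", {
  # single motif, full enrichment, no leak: the nitrosamine keys separate
  # the classes perfectly and must dominate the importance ranking
  cfg <- fixtureConfig(n_total = 80, seed = 1,
                       motifs = defaultMotifs(enrich = 1, leak = 0)[1])
  fx <- generateFixture(cfg)
  tab <- giniImportance(fx$compounds, "MACCS", repeats = 5, seed = 1)
  motif_keys <- fixtureMotifKeys(cfg, "MACCS")$nitrosamine
  reps <- selectionRepresentatives(attr(tab, "selection"), motif_keys)
  expect_gt(length(reps), 0)
  expect_true(tab$key[1] %in% reps)
  expect_true(all(tab$mean_decrease_gini >= 0))
  # the table is a permutation of the kept bits, sorted descending
  expect_setequal(tab$key, attr(tab, "selection")@kept)
  expect_true(!is.unsorted(rev(tab$mean_decrease_gini)))
})

test_that("importance of duplicated informative bits splits between the copies", {
  cfg <- fixtureConfig(n_total = 100, seed = 2,
                       motifs = defaultMotifs(enrich = 1, leak = 0)[1])
  fx <- generateFixture(cfg)
  y <- compoundLabels(fx$compounds)
  sel <- featureSelect(computeMatrix(fx$compounds, "MACCS"))
  base <- fpValues(sel$matrix)
  sig <- matchKeys("MACCS", "[#7]~[#7]")
  rep_key <- unname(selectionRepresentatives(sel$report, sig))
  expect_length(rep_key, 1L)
  imp_single <- withr::with_seed(1, {
    fit <- ranger::ranger(x = base, y = factor(y), num.trees = 500,
                          importance = "impurity", seed = 1,
                          num.threads = 1)
    ranger::importance(fit)[rep_key]
  })
  dup <- cbind(base, copy = base[, rep_key])
  imp_dup <- withr::with_seed(1, {
    fit <- ranger::ranger(x = dup, y = factor(y), num.trees = 500,
                          importance = "impurity", seed = 1,
                          num.threads = 1)
    ranger::importance(fit)
  })
  pair_sum <- imp_dup[rep_key] + imp_dup["copy"]
  expect_lt(imp_dup[rep_key], imp_single)      # importance is shared
  expect_lt(abs(pair_sum - imp_single) / imp_single, 0.2)
})

test_that("hashed families are refused for importance analysis", {
  fx <- smallFixture(30)
  expect_error(giniImportance(fx$compounds, "CDK"), "hashed-path")
})

test_that("topFeatures truncates stably and warns past the table size", {
  tab <- data.frame(key = paste0("k", 1:4),
                    mean_decrease_gini = c(4, 3, 2, 1))
  expect_equal(nrow(topFeatures(tab, 0)), 0L)
  expect_identical(topFeatures(tab, 4), tab)
  expect_equal(topFeatures(tab, 2)$key, c("k1", "k2"))
  expect_warning(all_rows <- topFeatures(tab, 9), "exceeds")
  expect_equal(nrow(all_rows), 4L)
})

test_that("occurrence counts count molecules per class, not matches", {
  cs <- tinySet(c("CCCN(C)N=O", "CCCCN(C)N=O", "CCCC", "CCCO"),
                labels = c(1, 1, 0, 0))
  oc <- occurrenceCounts(cs, "[#7]~[#7]")
  expect_equal(unname(oc), c(2L, 0L))
  # a molecule with two matches still counts once
  cs2 <- tinySet(c("O=NN(C)CCN(C)N=O", "CCCC"), labels = c(1, 0))
  expect_equal(unname(occurrenceCounts(cs2, "[#7]=[#8]")), c(1L, 0L))
  # pattern absent everywhere
  expect_equal(unname(occurrenceCounts(cs, "[#16]")), c(0L, 0L))
  expect_error(occurrenceCounts(cs, "[[["), "SMARTS")
})

test_that("occurrence counts agree with the generator's planted memberships", {
  cfg <- fixtureConfig(n_total = 60, seed = 3,
                       motifs = defaultMotifs(enrich = 1, leak = 0))
  fx <- generateFixture(cfg)
  manifest <- fx$manifest
  oc <- occurrenceCounts(fx$compounds, "[#7]~[#7]")
  planted <- grepl("nitrosamine", manifest$motifs)
  expect_equal(unname(oc["n_positives_with_match"]),
               sum(planted & manifest$label == 1))
  expect_equal(unname(oc["n_negatives_with_match"]),
               sum(planted & manifest$label == 0))
  # full enrichment / zero leak: counts equal the class sizes exactly
  expect_equal(unname(oc["n_positives_with_match"]),
               sum(manifest$label == 1))
  expect_equal(unname(oc["n_negatives_with_match"]), 0L)
})

test_that("removing the planted signal strictly lowers CV accuracy", {
  cfg <- fixtureConfig(n_total = 100, seed = 5,
                       motifs = defaultMotifs(enrich = 0.85, leak = 0.15)[1])
  fx <- generateFixture(cfg)
  cs <- fx$compounds
  fm <- computeMatrix(cs, "MACCS")
  tab <- giniImportance(cs, "MACCS", repeats = 3, seed = 1, matrix = fm)
  top_key <- tab$key[1]
  v <- fpValues(fm)
  # drop the top bit together with its exact duplicates (the correlation
  # filter would otherwise resurrect the same signal under another name)
  dup <- vapply(colnames(v), function(cn)
    all(v[, cn] == v[, top_key]), logical(1))
  v_red <- v[, !dup, drop = FALSE]
  cv <- cvConfig(repeats = 5, seed = 7)
  q_full <- cvSummary(repeatedCV(cs, "MACCS", "random_forest", cv = cv,
                                 matrices = list(MACCS = fm)))
  q_red <- cvSummary(repeatedCV(cs, "MACCS", "random_forest", cv = cv,
                                matrices = list(
                                  MACCS = new("FingerprintMatrix",
                                              values = v_red,
                                              spec = fpSpec(fm)))))
  expect_lt(q_red$mean[q_red$metric == "Q"],
            q_full$mean[q_full$metric == "Q"])
})
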