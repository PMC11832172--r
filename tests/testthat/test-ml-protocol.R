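# Feature binning, subset enumeration, block splits, folds, and the
# tune/CV/rank pipeline.

test_that("feature-set enumeration is the power set around the fixed
          feature", {
  expect_length(enumerateFeatureSets(mlOptionalFeatures()), 8192L)
  expect_length(enumerateFeatureSets("one"), 2L)
  sets <- enumerateFeatureSets(c("a", "b", "c"), alwaysInclude = "esm")
  expect_length(sets, 8L)
  # explicit power-set oracle
  oracle <- list(character(0), "a", "b", c("a", "b"), "c", c("a", "c"),
                 c("b", "c"), c("a", "b", "c"))
  got <- lapply(sets, setdiff, y = "esm")
  for (sub in oracle)
    expect_true(any(vapply(got, function(g) setequal(g, sub), logical(1))))
  expect_true(all(vapply(sets, function(s) "esm" %in% s, logical(1))))
  expect_error(enumerateFeatureSets(c("a", "b"), alwaysInclude = "a"),
               "optional")
})

test_that("binning replaces values by bin medians with at most 5 levels", {
  tab <- data.frame(x = c(1, 2, 3, 10, 11, 12, 100, 101))
  spec <- list(x = list(edges = c(0, 5, 50, 200)))
  out <- binFeatures(tab, spec)
  expect_identical(sort(unique(out$x)), c(2, 11, 100.5))
  # constant feature collapses to itself
  ctab <- data.frame(x = rep(7, 10))
  expect_identical(unique(binFeatures(ctab,
                                      list(x = list(edges = c(0, 10))))$x),
                   7)
  # auto spec never exceeds 5 distinct values and is idempotent
  set.seed(2)
  big <- data.frame(pocket_volume = rnorm(500), flexibility = rexp(500))
  spec5 <- makeBinSpec(big, c("pocket_volume", "flexibility"), nBins = 5)
  b1 <- binFeatures(big, spec5)
  expect_lte(length(unique(b1$pocket_volume)), 5L)
  b2 <- binFeatures(b1, spec5)
  expect_equal(b2$pocket_volume, b1$pocket_volume)
  expect_equal(b2$flexibility, b1$flexibility)
})

test_that("out-of-range values are clamped to the nearest bin and
          flagged", {
  tab <- data.frame(x = c(-5, 1, 300))
  out <- binFeatures(tab, list(x = list(edges = c(0, 5, 50, 200))))
  clamped <- attr(out, "clamped")
  expect_identical(sort(clamped$row), c(1L, 3L))
  expect_false(any(is.na(out$x)))
})

test_that("the default monotone map constrains the two continuous
          features", {
  m <- defaultMonotoneConstraints()
  expect_identical(unname(m["esm_llr"]), 1L)
  expect_identical(unname(m["stability_diff"]), -1L)
  expect_true(all(m[setdiff(names(m), c("esm_llr", "stability_diff"))]
                  == 0L))
})

test_that("block split reproduces the 230-position, 18-amino-acid training
          set", {
  sp <- makeSplit(1059:1345, aminoAcids(), metInhibitors(), seed = 3)
  expect_length(sp$train$positions, 230L)
  expect_length(sp$test$positions, 57L)    # floor(0.2 * 287)
  expect_length(sp$train$aminoAcids, 18L)
  expect_length(sp$test$aminoAcids, 2L)
  expect_length(intersect(sp$train$positions, sp$test$positions), 0L)
  expect_identical(makeSplit(1059:1345, aminoAcids(), metInhibitors(),
                             seed = 3), sp)
  # trivial split: nothing held out
  none <- makeSplit(1:10, aminoAcids(), "crizotinib",
                    heldOutInhibitors = character(),
                    positionFraction = 0, nHeldOutAminoAcids = 0)
  expect_length(none$test$positions, 0L)
  # floor arithmetic at small n
  small <- makeSplit(1:10, aminoAcids(), "crizotinib",
                     heldOutInhibitors = character(),
                     positionFraction = 0.2, seed = 1)
  expect_length(small$test$positions, 2L)
  expect_length(small$train$positions, 8L)
  expect_error(makeSplit(1:10, aminoAcids(), "x", heldOutInhibitors = "y"),
               "inhibitor")
  expect_error(makeSplit(1:10, c("A", "C"), "x",
                         heldOutInhibitors = character(),
                         nHeldOutAminoAcids = 2), "amino acid")
  expect_error(makeSplit(1:10, aminoAcids(), "x",
                         heldOutInhibitors = character(),
                         positionFraction = 1), "positionFraction")
})

test_that("no test row shares every block with training", {
  tab <- simulateFeatureTable(buildLibrary(1059, 1090),
                              inhibitors = c("crizotinib", "savolitinib",
                                             "cabozantinib"),
                              seed = 2)
  sp <- makeSplit(unique(tab$position), unique(tab$mutAa),
                  unique(tab$inhibitor),
                  heldOutInhibitors = "crizotinib", seed = 4)
  idx <- splitFeatureTable(tab, sp)
  expect_length(intersect(idx$train, idx$test), 0L)
  expect_equal(length(idx$train) + length(idx$test), nrow(tab))
  test <- tab[idx$test, ]
  held <- test$inhibitor %in% sp$test$inhibitors |
    test$position %in% sp$test$positions |
    test$mutAa %in% sp$test$aminoAcids
  expect_true(all(held))
  train <- tab[idx$train, ]
  expect_false(any(train$inhibitor %in% sp$test$inhibitors))
  expect_false(any(train$position %in% sp$test$positions))
  expect_false(any(train$mutAa %in% sp$test$aminoAcids))
})

test_that("CV folds partition positions into near-equal disjoint parts", {
  folds <- makeCvFolds(1:230, LETTERS[1:18], k = 10, seed = 1)
  sizes <- lengths(lapply(folds, `[[`, "positions"))
  expect_true(all(sizes == 23L))
  allPos <- unlist(lapply(folds, `[[`, "positions"))
  expect_length(allPos, 230L)
  expect_length(unique(allPos), 230L)     # disjoint and exhaustive
  expect_true(all(lengths(lapply(folds, `[[`, "aminoAcids")) == 2L))
  # k = 1: the whole training set in one fold
  one <- makeCvFolds(1:20, LETTERS[1:4], k = 1, seed = 1)
  expect_length(one, 1L)
  expect_setequal(one[[1]]$positions, 1:20)
  # 20 positions over 10 folds -> 2 per part
  tiny <- makeCvFolds(1:20, LETTERS[1:18], k = 10, seed = 2)
  expect_true(all(lengths(lapply(tiny, `[[`, "positions")) == 2L))
  expect_setequal(unlist(lapply(tiny, `[[`, "positions")), 1:20)
})

test_that("the tuning pipeline recovers a planted monotone signal and
          ranks the informative feature set first", {
  tab <- simulateFeatureTable(buildLibrary(1059, 1082),
                              inhibitors = c("savolitinib",
                                             "cabozantinib",
                                             "merestinib"),
                              seed = 6, noiseSd = 0.3)
  sp <- makeSplit(unique(tab$position), unique(tab$mutAa),
                  unique(tab$inhibitor),
                  heldOutInhibitors = "merestinib",
                  seed = 6)
  folds <- makeCvFolds(sp$train$positions, sp$train$aminoAcids, k = 3,
                       seed = 6)
  sets <- list(c("esm_llr", "stability_diff"),
               c("esm_llr", "pocket_volume"))
  fit <- tuneTrainSelect(tab, sets, sp, folds, budget = 2, seed = 6)
  # planted signal: far better than an uninformative intercept baseline
  expect_gt(fit$leaderboard$cvR[1], 0.3)
  # the set containing the second informative feature wins the ranking
  expect_match(fit$leaderboard$set[1], "stability_diff")
  expect_true(all(c("r", "mse", "n") %in% colnames(fit$test)))
  expect_identical(sort(as.character(fit$test$inhibitor)),
                   sort(unique(tab$inhibitor[splitFeatureTable(tab,
                                                               sp)$test])))
  expect_false(is.na(fit$testOverall["r"]))
})

test_that("a budget of one trial runs with default hyperparameters", {
  tab <- simulateFeatureTable(buildLibrary(1059, 1070),
                              inhibitors = c("savolitinib",
                                             "cabozantinib"),
                              seed = 1)
  sp <- makeSplit(unique(tab$position), unique(tab$mutAa),
                  unique(tab$inhibitor),
                  heldOutInhibitors = character(), seed = 1)
  folds <- makeCvFolds(sp$train$positions, sp$train$aminoAcids, k = 2,
                       seed = 1)
  fit <- tuneTrainSelect(tab, list("esm_llr"), sp, folds, budget = 1,
                         seed = 1)
  expect_identical(fit$best$params, xgboostRegressor()$defaultParams())
})

test_that("monotone constraints are honored by the fitted model", {
  set.seed(9)
  n <- 400
  tab <- data.frame(position = rep(1:40, 10), mutAa = "V",
                    inhibitor = "savolitinib",
                    esm_llr = rnorm(n), pocket_volume = rnorm(n))
  tab$fitness <- tab$esm_llr + rnorm(n, 0, 0.2)
  sp <- makeSplit(1:40, "V", "savolitinib",
                  heldOutInhibitors = character(),
                  positionFraction = 0.2, nHeldOutAminoAcids = 0,
                  seed = 9)
  folds <- makeCvFolds(sp$train$positions, "V", k = 2,
                       nAminoAcidsPerFold = 1, seed = 9)
  fit <- tuneTrainSelect(tab, list(c("esm_llr", "pocket_volume")), sp,
                         folds, budget = 1, seed = 9)
  reg <- xgboostRegressor()
  grid <- cbind(esm_llr = seq(-2, 2, length.out = 50), pocket_volume = 0)
  pred <- reg$predict(fit$best$model, grid)
  expect_true(all(diff(pred) >= -1e-9))   # non-decreasing in esm_llr
})

test_that("a regressor without monotone support violates the contract", {
  dummy <- list(name = "plain-lm", supportsMonotone = FALSE,
                defaultParams = function() list(),
                sampleParams = function() list(),
                fit = function(x, y, monotone, params) lm.fit(cbind(1, x), y),
                predict = function(model, x)
                  drop(cbind(1, x) %*% model$coefficients))
  tab <- data.frame(position = 1:20, mutAa = "V",
                    inhibitor = "savolitinib",
                    esm_llr = rnorm(20), fitness = rnorm(20))
  sp <- makeSplit(1:20, "V", "savolitinib",
                  heldOutInhibitors = character(),
                  positionFraction = 0, nHeldOutAminoAcids = 0)
  folds <- makeCvFolds(1:20, "V", k = 2, nAminoAcidsPerFold = 1)
  expect_error(tuneTrainSelect(tab, list("esm_llr"), sp, folds,
                               regressor = dummy, budget = 1),
               "monotone")
  # DMSO rows are excluded from ML data by construction
  tabD <- tab; tabD$inhibitor <- "DMSO"
  expect_error(tuneTrainSelect(tabD, list("esm_llr"), sp, folds,
                               budget = 1),
               "DMSO")
})
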