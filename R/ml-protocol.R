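# Block-holdout machine-learning protocol for inhibitor fitness prediction.
#
# The protocol — not any particular fitted model — is the deliverable here:
# interpretable features are coarsened into 4-5 bins represented by the bin
# median, two features carry monotone constraints (the evolutionary
# log-likelihood feature positive, the stability-difference feature
# negative), train/test separation is by whole blocks (inhibitors, residue
# positions, amino-acid identities) so no test row shares any block with
# training, feature subsets are enumerated exhaustively around the
# always-present evolutionary feature, and a pluggable boosted-tree
# regressor is tuned, cross-validated blockwise and ranked by CV
# correlation.

#' Names of the interpretable feature columns
#'
#' The always-present evolutionary-likelihood feature (protein
#' language-model log-likelihood-ratio role) plus the 13 optional
#' structure- and chemistry-derived features the protocol enumerates over.
#'
#' @return \code{mlFeatureNames()}: character vector of all 14;
#'   \code{mlOptionalFeatures()}: the 13 optional ones.
#' @export
#' @examples
#' mlFeatureNames()
mlFeatureNames <- function() c("esm_llr", mlOptionalFeatures())

#' @rdname mlFeatureNames
#' @export
mlOptionalFeatures <- function() {
  c("stability_diff", "inhibitor_bound_stability", "atp_distance",
    "inhibitor_distance", "flexibility", "residue_displacement",
    "ligand_displacement", "inhibitor_mw", "binding_score",
    "pocket_volume", "pocket_hydrophobicity", "pocket_polarity",
    "residue_volume_change")
}

#' Default monotone-constraint map
#'
#' The evolutionary-likelihood feature is constrained positively (+1), the
#' stability-difference feature negatively (-1), all other features are
#' unconstrained (0). Reassign by passing a modified map to
#' [tuneTrainSelect()].
#'
#' @return Named integer vector over [mlFeatureNames()].
#' @export
#' @examples
#' defaultMonotoneConstraints()[c("esm_llr", "stability_diff")]
defaultMonotoneConstraints <- function() {
  m <- stats::setNames(rep(0L, length(mlFeatureNames())), mlFeatureNames())
  m["esm_llr"] <- 1L
  m["stability_diff"] <- -1L
  m
}

#' Enumerate feature subsets around a fixed feature
#'
#' One feature set per subset of the optional features (including the
#' empty subset), each augmented with the always-included feature:
#' \eqn{2^{|optional|}} sets in total (8192 for the full 13).
#'
#' @param optionalFeatures Character vector of optional feature names.
#' @param alwaysInclude The fixed feature (must not be optional).
#' @return List of character vectors (the fixed feature first).
#' @export
#' @examples
#' length(enumerateFeatureSets(mlOptionalFeatures()))   # 8192
enumerateFeatureSets <- function(optionalFeatures,
                                 alwaysInclude = "esm_llr") {
  if (alwaysInclude %in% optionalFeatures)
    stop("the always-included feature cannot also be optional")
  n <- length(optionalFeatures)
  lapply(seq_len(2^n) - 1L, function(code) {
    pick <- bitwAnd(code, 2^(seq_len(n) - 1L)) > 0
    c(alwaysInclude, optionalFeatures[pick])
  })
}

#' Build a binning specification from observed feature values
#'
#' Chooses bin edges per feature from the observed distribution
#' (quantile-based, so that heavily populated ranges get their own bins)
#' for coarsening into \code{nBins} (4 or 5) bins.
#'
#' @param table Feature table (\code{data.frame}).
#' @param features Features to bin (default: all optional features present
#'   except the monotone-constrained ones, which stay continuous).
#' @param nBins Number of bins, 4 or 5.
#' @return Named list of \code{list(edges = ...)} per feature.
#' @export
#' @examples
#' tab <- data.frame(pocket_volume = rnorm(100))
#' makeBinSpec(tab, "pocket_volume", nBins = 4)
makeBinSpec <- function(table, features = NULL, nBins = 5L) {
  if (!nBins %in% 4:5) stop("nBins must be 4 or 5")
  if (is.null(features)) {
    cons <- defaultMonotoneConstraints()
    features <- intersect(setdiff(mlFeatureNames(),
                                  names(cons)[cons != 0L]),
                          colnames(table))
  }
  spec <- lapply(features, function(f) {
    v <- table[[f]]
    edges <- unique(stats::quantile(v, probs = seq(0, 1, length.out =
                                                     nBins + 1),
                                    names = FALSE, type = 7))
    list(edges = edges)
  })
  stats::setNames(spec, features)
}

#' Coarsen features into binned median representatives
#'
#' Replaces each binned feature value by the median of the raw values
#' falling into its bin, so each binned feature takes at most 5 distinct
#' values. Values outside all bins are clamped to the nearest bin and
#' flagged in the \code{"clamped"} attribute. Unbinned features (by
#' default the two monotone-constrained ones) pass through unchanged.
#' Binning is idempotent.
#'
#' @param table Feature table.
#' @param spec Bin specification from [makeBinSpec()] (or hand-built:
#'   named list of \code{list(edges)}).
#' @return The table with binned columns replaced; attribute
#'   \code{"clamped"} names (feature, row) pairs that were clamped.
#' @export
#' @examples
#' tab <- data.frame(x = c(1, 2, 3, 10, 11, 12, 100, 101))
#' spec <- list(x = list(edges = c(0, 5, 50, 200)))
#' unique(binFeatures(tab, spec)$x)   # 2, 11, 100.5
binFeatures <- function(table, spec) {
  clamped <- data.frame(feature = character(), row = integer())
  for (f in names(spec)) {
    if (!f %in% colnames(table)) stop("spec names absent feature: ", f)
    edges <- spec[[f]]$edges
    if (length(edges) < 2L) stop("feature ", f, " needs >= 2 bin edges")
    v <- table[[f]]
    idx <- findInterval(v, edges, rightmost.closed = TRUE)
    out <- which(idx == 0L | idx > length(edges) - 1L)
    if (length(out)) {
      idx[idx == 0L] <- 1L
      idx[idx > length(edges) - 1L] <- length(edges) - 1L
      clamped <- rbind(clamped, data.frame(feature = f, row = out))
    }
    reps <- vapply(seq_len(length(edges) - 1L), function(b) {
      members <- v[idx == b]
      if (length(members)) stats::median(members) else NA_real_
    }, numeric(1))
    table[[f]] <- reps[idx]
  }
  attr(table, "clamped") <- clamped
  table
}

#' Block train/test split by inhibitor, position and amino acid
#'
#' Holds out (a) whole inhibitors, (b) a fraction of randomly chosen
#' residue positions (floor rounding), and (c) randomly chosen amino-acid
#' identities. A data row is a test row iff its inhibitor, position or
#' amino acid is held out, so every test row differs from all training
#' rows in at least one whole block. With the default design (287
#' positions, 20 amino acids, fraction 0.2, 2 amino acids) training covers
#' 230 positions and 18 amino acids.
#'
#' @param positions All residue positions in the data.
#' @param aminoAcids All amino-acid identities in the data.
#' @param inhibitors All inhibitors in the data.
#' @param heldOutInhibitors Inhibitors held out entirely (default one
#'   type I and one type II).
#' @param positionFraction Fraction of positions held out (must be < 1).
#' @param nHeldOutAminoAcids Number of amino acids held out (must be
#'   < \code{length(aminoAcids)}).
#' @param seed Seed making the draw reproducible.
#'
#' @return A list with \code{train} and \code{test}, each naming
#'   \code{positions}, \code{aminoAcids} and \code{inhibitors}, plus the
#'   \code{seed}.
#' @seealso [splitFeatureTable()], [makeCvFolds()]
#' @export
#' @examples
#' sp <- makeSplit(1059:1345, aminoAcids(), "crizotinib",
#'                 heldOutInhibitors = character(), seed = 1)
#' length(sp$train$positions)   # 230
makeSplit <- function(positions, aminoAcids, inhibitors,
                      heldOutInhibitors = c("crizotinib", "glesatinib"),
                      positionFraction = 0.2, nHeldOutAminoAcids = 2L,
                      seed = 1L) {
  if (positionFraction < 0 || positionFraction >= 1)
    stop("positionFraction must lie in [0, 1)")
  if (nHeldOutAminoAcids >= length(aminoAcids))
    stop("cannot hold out every amino acid")
  if (!all(heldOutInhibitors %in% inhibitors))
    stop("held-out inhibitor(s) not in the inhibitor list")
  set.seed(as.integer(seed))
  nPos <- floor(positionFraction * length(positions))
  heldPos <- sort(sample(positions, nPos))
  heldAa <- sort(sample(aminoAcids, nHeldOutAminoAcids))
  list(train = list(positions = setdiff(positions, heldPos),
                    aminoAcids = setdiff(aminoAcids, heldAa),
                    inhibitors = setdiff(inhibitors, heldOutInhibitors)),
       test = list(positions = heldPos, aminoAcids = heldAa,
                   inhibitors = heldOutInhibitors),
       seed = as.integer(seed))
}

#' Assign feature-table rows to the train/test blocks
#'
#' @param table Feature table with columns \code{position}, \code{mutAa}
#'   and \code{inhibitor}.
#' @param split Output of [makeSplit()].
#' @return List of integer row indices \code{train} and \code{test}
#'   (disjoint, exhaustive).
#' @export
splitFeatureTable <- function(table, split) {
  isTest <- table$inhibitor %in% split$test$inhibitors |
    table$position %in% split$test$positions |
    table$mutAa %in% split$test$aminoAcids
  list(train = which(!isTest), test = which(isTest))
}

#' Blocked cross-validation folds over positions and amino acids
#'
#' Partitions the training positions into \code{k} near-equal disjoint
#' parts (230 positions at k = 10 gives 23 per part) and draws a block of
#' \code{nAminoAcidsPerFold} amino acids per fold — uniformly without
#' replacement within a fold, independently across folds, so amino acids
#' re-appear across folds when \code{k} blocks exceed the pool (18
#' training amino acids cannot fill 10 disjoint pairs). The validation
#' rows of fold i are those whose position falls in part i \emph{or} whose
#' amino acid falls in block i.
#'
#' @param trainPositions Training positions from [makeSplit()].
#' @param trainAminoAcids Training amino acids from [makeSplit()].
#' @param k Number of folds.
#' @param nAminoAcidsPerFold Amino acids per fold block.
#' @param seed Seed.
#' @return List of \code{k} folds, each \code{list(positions, aminoAcids)};
#'   the position parts are pairwise disjoint and cover
#'   \code{trainPositions}.
#' @export
#' @examples
#' folds <- makeCvFolds(1:230, LETTERS[1:18], k = 10, seed = 1)
#' lengths(lapply(folds, `[[`, "positions"))   # 23 each
makeCvFolds <- function(trainPositions, trainAminoAcids, k = 10L,
                        nAminoAcidsPerFold = 2L, seed = 1L) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (nAminoAcidsPerFold > length(trainAminoAcids))
    stop("amino-acid block larger than the training pool")
  set.seed(as.integer(seed))
  shuffled <- sample(trainPositions)
  sizes <- diff(floor(seq(0, length(shuffled), length.out = k + 1)))
  part <- rep(seq_len(k), times = sizes)
  lapply(seq_len(k), function(i) {
    list(positions = sort(shuffled[part == i]),
         aminoAcids = sort(sample(trainAminoAcids, nAminoAcidsPerFold)))
  })
}

#' Boosted-tree regressor backend (XGBoost)
#'
#' The shipped implementation of the pluggable regressor contract used by
#' [tuneTrainSelect()]. A contract is a list with \code{name},
#' \code{supportsMonotone}, \code{fit(x, y, monotone, params)},
#' \code{predict(model, x)}, \code{defaultParams()} and
#' \code{sampleParams()} drawing one random configuration of the tunable
#' knobs: booster type, maximum tree depth, number of trees, learning
#' rate, minimum split loss, column subsample ratio, L1/L2 regularization
#' strengths and the tree growth policy.
#'
#' @param nthread Threads for fitting (default 1).
#' @return A regressor contract list.
#' @export
#' @examples
#' reg <- xgboostRegressor()
#' reg$supportsMonotone
xgboostRegressor <- function(nthread = 1L) {
  asParams <- function(params, monotone) {
    nr <- params$n_estimators
    params$n_estimators <- NULL
    list(params = c(list(objective = "reg:squarederror",
                         tree_method = "hist", nthread = nthread,
                         monotone_constraints = paste0(
                           "(", paste(monotone, collapse = ","), ")")),
                    params),
         nrounds = nr)
  }
  list(
    name = "xgboost",
    supportsMonotone = TRUE,
    defaultParams = function() {
      list(booster = "gbtree", max_depth = 4L, n_estimators = 100L,
           eta = 0.1, gamma = 0, colsample_bytree = 1, alpha = 0,
           lambda = 1, grow_policy = "depthwise")
    },
    sampleParams = function() {
      list(booster = sample(c("gbtree", "dart"), 1),
           max_depth = sample(2:8, 1),
           n_estimators = sample(c(50L, 100L, 200L), 1),
           eta = exp(stats::runif(1, log(0.01), log(0.3))),
           gamma = stats::runif(1, 0, 5),
           colsample_bytree = stats::runif(1, 0.5, 1),
           alpha = exp(stats::runif(1, log(1e-3), log(10))),
           lambda = exp(stats::runif(1, log(1e-3), log(10))),
           grow_policy = sample(c("depthwise", "lossguide"), 1))
    },
    fit = function(x, y, monotone, params) {
      a <- asParams(params, monotone)
      xgboost::xgb.train(params = a$params,
                         data = xgboost::xgb.DMatrix(x, label = y),
                         nrounds = a$nrounds, verbose = 0)
    },
    predict = function(model, x) {
      stats::predict(model, xgboost::xgb.DMatrix(x))
    }
  )
}

featureMatrix <- function(table, features) {
  as.matrix(table[, features, drop = FALSE])
}

evalMetrics <- function(pred, obs) {
  r <- if (length(obs) >= 3 && stats::sd(obs) > 0 && stats::sd(pred) > 0)
    stats::cor(pred, obs) else NA_real_
  c(r = r, mse = mean((pred - obs)^2))
}

#' Tune, cross-validate, rank and evaluate feature-set models
#'
#' For each candidate feature set: tunes hyperparameters on an internal
#' 80/20 split of the training rows (random search within the trial
#' budget, minimizing mean squared error; a budget of 1 uses the
#' backend's defaults), runs blocked k-fold cross-validation recording
#' mean Pearson r and MSE, then ranks sets by CV correlation. The winning
#' set is refit on the full training rows and evaluated per inhibitor on
#' the held-out test rows.
#'
#' @param table Feature table with columns \code{position}, \code{mutAa},
#'   \code{inhibitor}, the feature columns, and the target.
#' @param featureSets List of character vectors (from
#'   [enumerateFeatureSets()] or a sampled subset).
#' @param split Output of [makeSplit()].
#' @param folds Output of [makeCvFolds()].
#' @param constraints Named monotone-constraint map (default
#'   [defaultMonotoneConstraints()]).
#' @param regressor Regressor contract (default [xgboostRegressor()]);
#'   must support monotone constraints if any are non-zero.
#' @param budget Hyperparameter-search trials per feature set.
#' @param target Target column name.
#' @param seed Seed for the tuning subsample and search.
#'
#' @return A list: \code{leaderboard} (one row per feature set, ranked by
#'   CV correlation: features, cvR, cvMSE), \code{best} (features, tuned
#'   params, fitted model), \code{test} (per-inhibitor r, mse, n on the
#'   held-out rows) and \code{testOverall}.
#' @export
#' @examples
#' # see the package vignette for an end-to-end protocol run
tuneTrainSelect <- function(table, featureSets, split, folds,
                            constraints = defaultMonotoneConstraints(),
                            regressor = xgboostRegressor(), budget = 5L,
                            target = "fitness", seed = 1L) {
  if (any(table$inhibitor %in% c("DMSO")))
    stop("feature tables must not contain DMSO rows")
  idx <- splitFeatureTable(table, split)
  if (!length(idx$train)) stop("empty training set")
  train <- table[idx$train, , drop = FALSE]
  test <- table[idx$test, , drop = FALSE]
  y <- train[[target]]

  consFor <- function(features) {
    v <- integer(length(features))
    known <- intersect(features, names(constraints))
    v[match(known, features)] <- constraints[known]
    if (any(v != 0L) && !isTRUE(regressor$supportsMonotone))
      stop("regressor '", regressor$name,
           "' does not support monotone constraints")
    v
  }

  set.seed(as.integer(seed))
  nTr <- nrow(train)
  tuneHold <- sample(nTr, max(1L, floor(0.2 * nTr)))
  tuneFit <- setdiff(seq_len(nTr), tuneHold)

  foldVal <- lapply(folds, function(f)
    which(train$position %in% f$positions |
            train$mutAa %in% f$aminoAcids))

  results <- vector("list", length(featureSets))
  for (s in seq_along(featureSets)) {
    feats <- featureSets[[s]]
    mono <- consFor(feats)
    X <- featureMatrix(train, feats)

    best <- list(mse = Inf, params = regressor$defaultParams())
    trials <- if (budget <= 1L) list(regressor$defaultParams()) else
      c(list(regressor$defaultParams()),
        replicate(budget - 1L, regressor$sampleParams(),
                  simplify = FALSE))
    for (params in trials) {
      fit <- regressor$fit(X[tuneFit, , drop = FALSE], y[tuneFit],
                           mono, params)
      mse <- mean((regressor$predict(fit, X[tuneHold, , drop = FALSE]) -
                     y[tuneHold])^2)
      if (mse < best$mse) best <- list(mse = mse, params = params)
    }

    cv <- vapply(foldVal, function(val) {
      if (length(val) < 3L || length(val) >= nTr)
        return(c(r = NA_real_, mse = NA_real_))
      fit <- regressor$fit(X[-val, , drop = FALSE], y[-val], mono,
                           best$params)
      evalMetrics(regressor$predict(fit, X[val, , drop = FALSE]), y[val])
    }, c(r = 0, mse = 0))
    results[[s]] <- list(features = feats, params = best$params,
                         cvR = mean(cv["r", ], na.rm = TRUE),
                         cvMSE = mean(cv["mse", ], na.rm = TRUE))
  }

  board <- data.frame(
    set = vapply(results, function(x) paste(x$features, collapse = "+"),
                 character(1)),
    nFeatures = vapply(results, function(x) length(x$features), integer(1)),
    cvR = vapply(results, function(x) x$cvR, numeric(1)),
    cvMSE = vapply(results, function(x) x$cvMSE, numeric(1)))
  ord <- order(-board$cvR)
  board <- board[ord, ]
  rownames(board) <- NULL
  winner <- results[[ord[1]]]

  finalFit <- regressor$fit(featureMatrix(train, winner$features), y,
                            consFor(winner$features), winner$params)
  testPerInh <- NULL
  testOverall <- c(r = NA_real_, mse = NA_real_)
  if (nrow(test)) {
    pred <- regressor$predict(finalFit,
                              featureMatrix(test, winner$features))
    obs <- test[[target]]
    testOverall <- evalMetrics(pred, obs)
    testPerInh <- do.call(rbind, lapply(split(seq_len(nrow(test)),
                                              test$inhibitor),
      function(i) {
        m <- evalMetrics(pred[i], obs[i])
        data.frame(inhibitor = test$inhibitor[i[1]], r = m["r"],
                   mse = m["mse"], n = length(i))
      }))
    rownames(testPerInh) <- NULL
  }
  list(leaderboard = board,
       best = list(features = winner$features, params = winner$params,
                   model = finalFit),
       test = testPerInh, testOverall = testOverall)
}

#' Synthetic feature table for exercising the ML protocol
#'
#' Generates a feature table over (missense variant, inhibitor) rows with
#' the full 14-feature layout: a per-variant evolutionary-likelihood
#' feature, per-variant structural stand-ins, and per-inhibitor chemical
#' stand-ins. The target fitness is built to increase with the
#' evolutionary feature and decrease with the stability-difference
#' feature (matching the monotone-constraint assumptions) plus noise; the
#' remaining features are uninformative. All features are synthetic
#' stand-ins — no structures, docking or language models are involved —
#' so the table exercises the protocol, not real predictive performance.
#'
#' @param library Variant table from [buildLibrary()] (missense rows are
#'   used).
#' @param inhibitors Inhibitor panel (default: the shipped panel minus
#'   the type I 1/2 inhibitor, which the protocol excludes along with
#'   DMSO).
#' @param seed Seed.
#' @param noiseSd Residual noise on the target.
#' @return \code{data.frame} with variant, position, mutAa, inhibitor,
#'   the 14 feature columns and \code{fitness}.
#' @export
#' @examples
#' tab <- simulateFeatureTable(buildLibrary(1059, 1070), seed = 1)
#' nrow(tab)   # missense variants x 10 inhibitors
simulateFeatureTable <- function(library,
                                 inhibitors = setdiff(metInhibitors(),
                                                      "AMG-458"),
                                 seed = 1L, noiseSd = 0.4) {
  set.seed(as.integer(seed))
  mis <- library[library$vclass == "missense", ]
  nv <- nrow(mis)
  perVariant <- data.frame(
    variant = mis$name, position = mis$position, mutAa = mis$mutAa,
    esm_llr = stats::rnorm(nv),
    stability_diff = stats::rnorm(nv),
    atp_distance = stats::runif(nv, 3, 30),
    flexibility = stats::rgamma(nv, 2, 2),
    residue_displacement = stats::rnorm(nv, 1, 0.3),
    residue_volume_change = stats::rnorm(nv, 0, 40))
  perInh <- data.frame(
    inhibitor = inhibitors,
    inhibitor_mw = stats::runif(length(inhibitors), 300, 650),
    pocket_volume = stats::runif(length(inhibitors), 200, 900),
    pocket_hydrophobicity = stats::runif(length(inhibitors), 0, 1),
    pocket_polarity = stats::runif(length(inhibitors), 0, 1))
  tab <- merge(perVariant, perInh, by = NULL)
  n <- nrow(tab)
  tab$inhibitor_bound_stability <- stats::rnorm(n)
  tab$inhibitor_distance <- stats::runif(n, 2, 25)
  tab$ligand_displacement <- stats::rnorm(n, 0.5, 0.2)
  tab$binding_score <- stats::rnorm(n, -7, 1.5)
  inhEffect <- stats::setNames(stats::rnorm(length(inhibitors), 0, 0.3),
                               inhibitors)
  tab$fitness <- 0.9 * tab$esm_llr - 0.5 * tab$stability_diff +
    inhEffect[tab$inhibitor] + stats::rnorm(n, 0, noiseSd)
  tab[order(tab$inhibitor, tab$position, tab$mutAa),
      c("variant", "position", "mutAa", "inhibitor", mlFeatureNames(),
        "fitness")]
}
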