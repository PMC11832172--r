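# Synthetic pooled-selection experiments with known ground-truth fitness.
#
# Latent dynamics: a variant with fitness beta (doublings/interval relative
# to wild type) grows by a factor 2^(d + beta) per harvest interval, where d
# is the wild-type cadence. Sequencing then samples each (condition,
# replicate, timepoint) cell multinomially at the configured depth.

#' Number of sequencing samples implied by a design
#'
#' Counts the physical sequencing samples of a pooled-selection design:
#' one T0 per (library, replicate) when T0 is shared across conditions
#' (otherwise one per condition), plus one sample per (library, replicate,
#' condition, post-T0 time point). The default design yields 222.
#'
#' @param design An [ExperimentDesign()].
#' @return Integer sample count.
#' @export
#' @examples
#' countSamples(ExperimentDesign())   # 222
countSamples <- function(design) {
  stopifnot(is(design, "ExperimentDesign"))
  nc <- length(design@conditions)
  t0 <- design@nLibraries * design@nReplicates *
    (if (design@sharedT0) 1L else nc)
  post <- design@nLibraries * design@nReplicates * nc *
    design@nPostTimepoints
  as.integer(t0 + post)
}

# Stable per-(replicate, condition) seed streams derived from the master
# seed; kept below 2^31 - 1 so set.seed() accepts them on any platform.
deriveSeed <- function(master, replicate, condIndex = 0L) {
  ((as.numeric(master) * 7919 + replicate * 104729 + condIndex * 1299709)
    %% 2147483629) + 1
}

#' Draw ground-truth fitness for a variant library
#'
#' Assigns every (variant, condition) pair a true fitness on the
#' doublings-per-interval scale. Synonymous variants are 0 in every
#' condition (the wild-type normalization convention); nonsense variants
#' are at the dead level \eqn{-d}; missense DMSO fitness is drawn from the
#' configured two-component mixture (wild-type-like around 0,
#' loss-of-function around \eqn{-d}); inhibitor fitness is
#' \code{min(beta_DMSO, sensitiveLevel)} — every variant is drug-sensitive
#' unless a \code{resistanceSpec} row in the config plants an effect, which
#' overrides the default for its (variant, condition).
#'
#' @param library Variant table from [buildLibrary()].
#' @param design An [ExperimentDesign()].
#' @param cfg A [SimConfig()]; \code{cfg@seed} makes the draw reproducible.
#'
#' @return A \code{GroundTruth} object; access the variants-by-conditions
#'   fitness matrix with [trueBeta()].
#' @export
#' @examples
#' lib <- buildLibrary(1100, 1102)
#' truth <- drawGroundTruth(lib, ExperimentDesign(), SimConfig(seed = 3))
#' trueBeta(truth)[lib$vclass == "synonymous", ]   # all zero
drawGroundTruth <- function(library, design, cfg) {
  stopifnot(is(design, "ExperimentDesign"), is(cfg, "SimConfig"))
  d <- design@wtDoublingsPerInterval
  mx <- cfg@dmsoMixture
  meanLof <- if (is.na(mx$meanLof)) -d else mx$meanLof
  sens <- if (is.na(cfg@sensitiveLevel)) -d else cfg@sensitiveLevel
  conds <- design@conditions
  nv <- nrow(library)

  beta <- matrix(0, nv, length(conds),
                 dimnames = list(library$name, conds))
  set.seed(deriveSeed(cfg@seed, 0L, 0L))
  mis <- which(library$vclass == "missense")
  isLof <- stats::runif(length(mis)) >= mx$weightWt
  bDmso <- ifelse(isLof,
                  stats::rnorm(length(mis), meanLof, mx$sdLof),
                  stats::rnorm(length(mis), mx$meanWt, mx$sdWt))
  non <- which(library$vclass == "nonsense")

  for (j in seq_along(conds)) {
    col <- numeric(nv)
    if (conds[j] == "DMSO") {
      col[mis] <- bDmso
      col[non] <- -d
    } else {
      col[mis] <- pmin(bDmso, sens)
      col[non] <- pmin(-d, sens)
    }
    beta[, j] <- col
  }

  rs <- cfg@resistanceSpec
  if (nrow(rs)) {
    key <- paste(library$position, library$mutAa)
    for (i in seq_len(nrow(rs))) {
      v <- match(paste(rs$position[i], rs$mutAa[i]), key)
      if (is.na(v))
        stop("resistanceSpec names a variant absent from the library: ",
             rs$position[i], rs$mutAa[i])
      if (!rs$condition[i] %in% conds)
        stop("resistanceSpec names an unknown condition: ", rs$condition[i])
      beta[v, rs$condition[i]] <- rs$beta[i]
    }
  }
  # planting never overrides the wild-type convention for synonymous rows
  beta[library$vclass == "synonymous", ] <- 0

  new("GroundTruth", beta = beta, variants = library,
      seed = cfg@seed)
}

sampleCounts <- function(expected, depth, model) {
  if (model == "multinomial") {
    as.numeric(stats::rmultinom(1, size = round(depth),
                                prob = expected / sum(expected)))
  } else {
    stats::rpois(length(expected), depth * expected / sum(expected))
  }
}

#' Simulate a pooled inhibitor-selection sequencing experiment
#'
#' Propagates latent variant abundances through the selection —
#' \eqn{N_v(t+1) = N_v(t) \, 2^{d + \beta_{v,c}}} per interval — and draws
#' sequencing counts for every (condition, replicate, time point) cell.
#' With a shared T0, one pre-selection sample is drawn per replicate and
#' copied into every condition's grid. In noiseless mode counts are the
#' exact expected read shares at the configured depth (real-valued);
#' otherwise each sample is drawn multinomially (or Poisson) at that depth
#' from a seed stream derived per (replicate, condition), so runs are
#' reproducible and replicates independent.
#'
#' @param truth A \code{GroundTruth} from [drawGroundTruth()].
#' @param design An [ExperimentDesign()].
#' @param cfg A [SimConfig()].
#'
#' @return A \linkS4class{DmsExperiment} with the complete
#'   condition-by-replicate-by-timepoint count grid.
#' @export
#' @examples
#' lib <- buildLibrary(1100, 1104)
#' des <- ExperimentDesign(conditions = c("crizotinib", "DMSO"))
#' cfg <- SimConfig(depthPerSample = 1e4, seed = 11)
#' sim <- simulateExperiment(drawGroundTruth(lib, des, cfg), des, cfg)
#' sim
simulateExperiment <- function(truth, design, cfg) {
  stopifnot(is(truth, "GroundTruth"), is(design, "ExperimentDesign"),
            is(cfg, "SimConfig"))
  if (cfg@depthPerSample < 0) stop("negative sequencing depth")
  conds <- design@conditions
  if (!all(conds %in% colnames(truth@beta)))
    stop("ground truth does not cover every design condition")
  lib <- truth@variants
  nv <- nrow(lib)
  R <- design@nReplicates
  Tn <- design@nPostTimepoints + 1L
  d <- design@wtDoublingsPerInterval
  depth <- cfg@depthPerSample

  nCells <- length(conds) * R * Tn
  countsMat <- matrix(0, nv, nCells)
  condCol <- character(nCells); repCol <- integer(nCells)
  tpCol <- integer(nCells)

  n0 <- rep(cfg@pseudoInitialCount, nv)

  # T0: one draw per replicate when shared, reused across conditions
  t0counts <- vector("list", R)
  for (r in seq_len(R)) {
    if (cfg@noiseless) {
      t0counts[[r]] <- depth * n0 / sum(n0)
    } else {
      set.seed(deriveSeed(cfg@seed, r, 0L))
      t0counts[[r]] <- sampleCounts(n0, depth, cfg@noiseModel)
    }
  }

  cell <- 0L
  for (j in seq_along(conds)) {
    growth <- 2^(d + truth@beta[, conds[j]])
    for (r in seq_len(R)) {
      if (!cfg@noiseless) set.seed(deriveSeed(cfg@seed, r, j))
      abun <- n0
      for (tp in seq_len(Tn) - 1L) {
        if (tp > 0L) abun <- abun * growth
        cell <- cell + 1L
        condCol[cell] <- conds[j]; repCol[cell] <- r; tpCol[cell] <- tp
        if (tp == 0L && design@sharedT0) {
          countsMat[, cell] <- t0counts[[r]]
        } else if (cfg@noiseless) {
          countsMat[, cell] <- depth * abun / sum(abun)
        } else {
          countsMat[, cell] <- sampleCounts(abun, depth, cfg@noiseModel)
        }
      }
    }
  }

  cd <- DataFrame(condition = condCol, replicate = repCol,
                  timepoint = tpCol)
  rownames(countsMat) <- lib$name
  colnames(countsMat) <- paste(condCol, repCol, paste0("T", tpCol),
                               sep = "_")
  se <- SummarizedExperiment(assays = list(counts = countsMat),
                             rowData = lib, colData = cd)
  out <- new("DmsExperiment", se)
  metadata(out)$design <- design
  metadata(out)$wtDoublingsPerInterval <- d
  out
}
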