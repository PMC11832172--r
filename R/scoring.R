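# Fitness scoring on the cell-doubling-rate scale.
#
# Counts are log2-transformed and centered per sample on the synonymous
# (wild-type-encoding) pool, so a variant tracking wild type is flat at 0.
# Each trajectory is anchored at its first time point and regressed on
# t = 1..T; the per-replicate OLS slope is the variant's growth-rate
# advantage in doublings per interval, averaged over replicates with a
# replicate-derived standard error. Under the wild-type cadence of d
# doublings/interval, beta = -d means no growth and beta = +1 means one
# extra doubling per interval.

#' Wild-type-normalized log2 count trajectories
#'
#' Converts one condition's filtered counts to normalized trajectories:
#' \eqn{m_{v,r,t} = \log_2(c_{v,r,t} + pc) - center_{r,t}}, where the
#' per-sample center is the median (or mean) over the synonymous pool of
#' \eqn{\log_2(c + pc)}; each trajectory is then anchored at its own first
#' time point so only slopes carry information. Time points are indexed
#' t = 1..T (T0 mapped to t = 1), so slopes are per harvest interval.
#'
#' @param x A \linkS4class{DmsExperiment} restricted to one condition
#'   (e.g. the \code{counts} element of [filterVariants()] output).
#' @param pseudocount Continuity correction added inside the log2
#'   (default 0.5; use 0 for strictly positive, e.g. noiseless, counts).
#' @param center \code{"median"} (default) or \code{"mean"} over the
#'   synonymous pool.
#'
#' @return A list: \code{m} (variants x cells matrix of normalized values),
#'   \code{replicate} and \code{t} (per-column indices, t starting at 1).
#' @export
#' @examples
#' lib <- buildLibrary(1100, 1102)
#' des <- ExperimentDesign(conditions = "DMSO")
#' cfg <- SimConfig(noiseless = TRUE, seed = 1)
#' sim <- simulateExperiment(drawGroundTruth(lib, des, cfg), des, cfg)
#' nt <- normalizeCounts(filterVariants(sim, FilterThresholds(), "DMSO")$counts,
#'                       pseudocount = 0)
#' max(abs(nt$m[rowData(sim)$vclass == "synonymous", ]))   # ~0
normalizeCounts <- function(x, pseudocount = 0.5,
                            center = c("median", "mean")) {
  stopifnot(is(x, "DmsExperiment"))
  center <- match.arg(center)
  cd <- colData(x)
  if (length(unique(cd$condition)) != 1L)
    stop("normalizeCounts expects a single-condition table; ",
         "use scoreAll() for multi-condition scoring")
  syn <- which(rowData(x)$vclass == "synonymous")
  if (!length(syn))
    stop("no synonymous variants available for wild-type normalization")
  L <- log2(counts(x) + pseudocount)
  centerFun <- if (center == "median") stats::median else mean
  ctr <- apply(L[syn, , drop = FALSE], 2, centerFun)
  m <- sweep(L, 2, ctr)

  tIdx <- cd$timepoint - min(cd$timepoint) + 1L
  # anchor each (variant, replicate) trajectory at t = 1
  for (r in unique(cd$replicate)) {
    colsR <- which(cd$replicate == r)
    anchor <- m[, colsR[which.min(tIdx[colsR])]]
    m[, colsR] <- m[, colsR] - anchor
  }
  list(m = m, replicate = cd$replicate, t = tIdx)
}

# OLS slope of each row of m on t (shared design across rows).
slopeFit <- function(m, t) {
  tc <- t - mean(t)
  drop(m %*% tc) / sum(tc^2)
}

#' Score one condition's normalized trajectories
#'
#' Fits an ordinary-least-squares slope of the normalized log2 trajectory
#' on the time index t = 1..T independently per replicate; the fitness
#' score beta is the mean of replicate slopes and its standard error the
#' replicate standard deviation over \eqn{\sqrt{R}} (infinite when R = 1,
#' where no replicate spread exists). Units: doublings per interval
#' relative to wild type.
#'
#' @param trajectories Output of [normalizeCounts()].
#' @return A \code{DataFrame}: variant, beta, se, nReps.
#' @export
#' @examples
#' m <- rbind(v1 = c(0, 0.5, 1.0, 1.5))   # one replicate, beta = 0.5
#' scoreTrajectories(list(m = m, replicate = rep(1, 4), t = 1:4))$beta
scoreTrajectories <- function(trajectories) {
  m <- trajectories$m
  reps <- unique(trajectories$replicate)
  if (length(unique(trajectories$t)) < 2L)
    stop("scoring needs at least two time points")
  slopes <- matrix(NA_real_, nrow(m), length(reps))
  for (k in seq_along(reps)) {
    cols <- which(trajectories$replicate == reps[k])
    ord <- cols[order(trajectories$t[cols])]
    slopes[, k] <- slopeFit(m[, ord, drop = FALSE],
                            trajectories$t[ord])
  }
  beta <- rowMeans(slopes)
  R <- length(reps)
  se <- if (R > 1L) apply(slopes, 1, stats::sd) / sqrt(R) else
    rep(Inf, nrow(m))
  DataFrame(variant = rownames(m), beta = beta, se = se, nReps = R)
}

#' Score every condition of a count table
#'
#' Runs the full per-condition pipeline — count filtering, wild-type
#' normalization, per-replicate slope regression — independently for each
#' condition, exactly as conditions were selected independently in the
#' screen, and assembles the results into a \linkS4class{ScoreMatrix}.
#' Cells are \code{NA} where a variant failed that condition's filter.
#'
#' @param x A \linkS4class{DmsExperiment}.
#' @param thresholds A [FilterThresholds()].
#' @param pseudocount Passed to [normalizeCounts()].
#' @param center Passed to [normalizeCounts()].
#' @param conditions Conditions to score (default: all in the table;
#'   requesting an absent condition drops it with a warning).
#'
#' @return A \linkS4class{ScoreMatrix} with assays \code{beta}, \code{se},
#'   \code{nReps}.
#' @export
#' @examples
#' lib <- buildLibrary(1100, 1103)
#' des <- ExperimentDesign(conditions = c("crizotinib", "DMSO"))
#' cfg <- SimConfig(noiseless = TRUE, seed = 1)
#' sim <- simulateExperiment(drawGroundTruth(lib, des, cfg), des, cfg)
#' sm <- scoreAll(sim, pseudocount = 0)
#' scores(sm)[1:4, ]
scoreAll <- function(x, thresholds = FilterThresholds(),
                     pseudocount = 0.5, center = c("median", "mean"),
                     conditions = NULL) {
  stopifnot(is(x, "DmsExperiment"))
  center <- match.arg(center)
  have <- unique(colData(x)$condition)
  if (is.null(conditions)) conditions <- have
  absent <- setdiff(conditions, have)
  if (length(absent)) {
    warning("condition(s) absent from the table: ",
            paste(absent, collapse = ", "))
    conditions <- intersect(conditions, have)
  }
  lib <- rowData(x)
  nv <- nrow(x)
  beta <- se <- matrix(NA_real_, nv, length(conditions),
                       dimnames = list(lib$name, conditions))
  nReps <- matrix(NA_integer_, nv, length(conditions),
                  dimnames = list(lib$name, conditions))
  for (cond in conditions) {
    flt <- filterVariants(x, thresholds, cond)
    if (!nrow(flt$counts)) next
    traj <- normalizeCounts(flt$counts, pseudocount, center)
    sc <- scoreTrajectories(traj)
    i <- match(sc$variant, lib$name)
    beta[i, cond] <- sc$beta
    se[i, cond] <- sc$se
    nReps[i, cond] <- sc$nReps
  }
  seOut <- SummarizedExperiment(
    assays = list(beta = beta, se = se, nReps = nReps),
    rowData = lib)
  out <- new("ScoreMatrix", seOut)
  metadata(out)$scoreType <- "beta"
  metadata(out)$pseudocount <- pseudocount
  out
}

#' Recenter inhibitor scores on the DMSO control
#'
#' Computes the drug-specific score
#' \eqn{\gamma_{v,inh} = \beta_{v,inh} - \beta_{v,DMSO}} for every
#' inhibitor column, isolating inhibitor response from folding or
#' expression effects shared with the control. Standard errors combine in
#' quadrature; the DMSO column of the result is identically 0 (a condition
#' against itself). Cells missing in either operand stay missing.
#'
#' @param sm A \linkS4class{ScoreMatrix} of raw beta scores containing a
#'   \code{"DMSO"} column.
#' @param dmso Name of the control column.
#' @return A \code{ScoreMatrix} with \code{metadata()$scoreType = "gamma"}.
#' @export
#' @examples
#' # see scoreAll(); gamma = beta with the DMSO column subtracted
dmsoRecenter <- function(sm, dmso = "DMSO") {
  stopifnot(is(sm, "ScoreMatrix"))
  if (!dmso %in% colnames(sm))
    stop("score matrix has no '", dmso, "' column to recenter on")
  b <- scores(sm); s <- scoreErrors(sm)
  gamma <- b - b[, dmso]
  gse <- sqrt(s^2 + s[, dmso]^2)
  gamma[, dmso] <- ifelse(is.na(b[, dmso]), NA_real_, 0)
  gse[, dmso] <- ifelse(is.na(b[, dmso]), NA_real_, 0)
  out <- new("ScoreMatrix", SummarizedExperiment(
    assays = list(beta = gamma, se = gse, nReps = scoreReplicates(sm)),
    rowData = rowData(sm)))
  metadata(out)$scoreType <- "gamma"
  metadata(out)$dmso <- dmso
  out
}
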