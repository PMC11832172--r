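#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   rowData colData assayNames
NULL

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' The twenty proteinogenic amino acids
#'
#' One-letter codes, alphabetical. The stop symbol used throughout the
#' package is \code{"*"}.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aminoAcids()
aminoAcids <- function() AA20

# ---------------------------------------------------------------------------
# ExperimentDesign

#' @rdname ExperimentDesign
#' @export
setClass("ExperimentDesign",
  representation(
    nLibraries = "integer",
    nReplicates = "integer",
    conditions = "character",
    nPostTimepoints = "integer",
    sharedT0 = "logical",
    wtDoublingsPerInterval = "numeric"
  )
)

setValidity("ExperimentDesign", function(object) {
  msg <- character()
  if (object@nLibraries < 1L) msg <- c(msg, "nLibraries must be >= 1")
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
  if (length(object@conditions) < 1L) msg <- c(msg, "need >= 1 condition")
  if (anyDuplicated(object@conditions))
    msg <- c(msg, "conditions must be unique")
  if (object@nPostTimepoints < 1L)
    msg <- c(msg, "nPostTimepoints must be >= 1")
  if (!(object@wtDoublingsPerInterval > 0))
    msg <- c(msg, "wtDoublingsPerInterval must be > 0")
  if (length(msg)) msg else TRUE
})

#' Pooled-selection experimental design
#'
#' Describes the layout of a pooled Ba/F3 inhibitor selection: libraries,
#' replicates per library, selection conditions (inhibitors plus the DMSO
#' control), number of post-T0 harvests, whether the pre-selection T0 sample
#' is shared across conditions within a replicate, and the wild-type growth
#' cadence in cell doublings per harvest interval.
#'
#' The defaults reproduce the study design this package models: 2 libraries,
#' 3 replicates each, 11 inhibitors plus DMSO, harvests T0..T3 taken every
#' two wild-type doublings (~72 h), with T0 sequenced once per replicate.
#'
#' @param nLibraries Number of independently screened libraries.
#' @param nReplicates Replicates per library.
#' @param conditions Character vector of condition names; must include
#'   \code{"DMSO"} for downstream recentering.
#' @param nPostTimepoints Number of post-selection harvests after T0.
#' @param sharedT0 Is the T0 sample shared across conditions in a replicate?
#' @param wtDoublingsPerInterval Wild-type doublings per harvest interval
#'   (the quantity \eqn{d}; scores are reported relative to it).
#'
#' @return An \code{ExperimentDesign} object.
#' @seealso [countSamples()], [simulateExperiment()]
#' @export
#' @examples
#' design <- ExperimentDesign()
#' countSamples(design)   # 222 sequencing samples in the default design
ExperimentDesign <- function(nLibraries = 2L,
                             nReplicates = 3L,
                             conditions = c(metInhibitors(), "DMSO"),
                             nPostTimepoints = 3L,
                             sharedT0 = TRUE,
                             wtDoublingsPerInterval = 2) {
  new("ExperimentDesign",
      nLibraries = as.integer(nLibraries),
      nReplicates = as.integer(nReplicates),
      conditions = as.character(conditions),
      nPostTimepoints = as.integer(nPostTimepoints),
      sharedT0 = isTRUE(sharedT0),
      wtDoublingsPerInterval = as.numeric(wtDoublingsPerInterval))
}

setMethod("show", "ExperimentDesign", function(object) {
  cat("ExperimentDesign:", object@nLibraries, "libraries x",
      object@nReplicates, "replicates,", length(object@conditions),
      "conditions,", object@nPostTimepoints + 1L, "time points",
      if (object@sharedT0) "(shared T0)" else "(per-condition T0)", "\n")
  cat("  wild-type growth:", object@wtDoublingsPerInterval,
      "doublings/interval\n")
  cat("  sequencing samples:", countSamples(object), "\n")
})

#' @rdname ExperimentDesign
#' @param object,x An \code{ExperimentDesign}.
#' @export
conditions <- function(x) x@conditions

#' @rdname ExperimentDesign
#' @export
nReplicates <- function(x) x@nReplicates

#' @rdname ExperimentDesign
#' @export
nTimepoints <- function(x) x@nPostTimepoints + 1L

# ---------------------------------------------------------------------------
# SimConfig

#' @rdname SimConfig
#' @export
setClass("SimConfig",
  representation(
    depthPerSample = "numeric",
    pseudoInitialCount = "numeric",
    dmsoMixture = "list",
    sensitiveLevel = "numeric",
    resistanceSpec = "data.frame",
    noiseless = "logical",
    noiseModel = "character",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@depthPerSample < 0) msg <- c(msg, "depthPerSample must be >= 0")
  if (object@pseudoInitialCount <= 0)
    msg <- c(msg, "pseudoInitialCount must be > 0")
  mx <- object@dmsoMixture
  need <- c("weightWt", "meanWt", "sdWt", "meanLof", "sdLof")
  if (!all(need %in% names(mx))) {
    msg <- c(msg, paste("dmsoMixture must name", paste(need, collapse = ", ")))
  } else if (mx$weightWt < 0 || mx$weightWt > 1) {
    msg <- c(msg, "dmsoMixture weights must lie in [0, 1] and sum to 1")
  }
  if (nrow(object@resistanceSpec) &&
      !all(c("position", "mutAa", "condition", "beta") %in%
           colnames(object@resistanceSpec)))
    msg <- c(msg, "resistanceSpec needs columns position, mutAa, condition, beta")
  if (!object@noiseModel %in% c("multinomial", "poisson"))
    msg <- c(msg, "noiseModel must be 'multinomial' or 'poisson'")
  if (length(msg)) msg else TRUE
})

#' Simulation configuration for synthetic selection counts
#'
#' Parameters of the synthetic-data generator: sequencing depth, starting
#' cell-equivalents per variant, the two-component mixture generating the
#' DMSO fitness distribution (a wild-type-like component centered at 0 and a
#' loss-of-function component centered at the "dead" score \eqn{-d}),
#' planted inhibitor-specific resistance effects, and the sampling model.
#'
#' The mixture emulates the bimodal DMSO fitness distribution seen in
#' kinase-domain scans: a narrow wild-type-like peak and a broad
#' loss-of-function peak at the non-growing score. Under an inhibitor every
#' variant is sensitive (fitness pulled down to \code{sensitiveLevel})
#' unless a \code{resistanceSpec} row plants a resistance effect for it.
#'
#' @param depthPerSample Expected total reads per (replicate, time point)
#'   sample.
#' @param pseudoInitialCount Starting cell-equivalents per variant at T0.
#' @param dmsoMixture Named list with \code{weightWt}, \code{meanWt},
#'   \code{sdWt}, \code{meanLof}, \code{sdLof}; the loss-of-function weight
#'   is \code{1 - weightWt}. \code{meanLof = NA} resolves to \eqn{-d} at
#'   draw time.
#' @param sensitiveLevel Fitness of non-resistant variants under inhibitor;
#'   \code{NA} resolves to the dead score \eqn{-d}.
#' @param resistanceSpec \code{data.frame} with columns \code{position},
#'   \code{mutAa}, \code{condition}, \code{beta}: planted fitness effects
#'   that override the defaults (rows with condition \code{"DMSO"} are
#'   allowed, e.g. to make a planted resistance mutation inhibitor-specific).
#' @param noiseless If \code{TRUE}, emit exact expected counts (real-valued,
#'   no sampling).
#' @param noiseModel \code{"multinomial"} (total depth fixed per sample) or
#'   \code{"poisson"} (independent per-variant counts at the same mean).
#' @param seed Master seed; per-(replicate, condition) streams are derived
#'   from it deterministically.
#'
#' @return A \code{SimConfig} object.
#' @export
#' @examples
#' cfg <- SimConfig(depthPerSample = 1e5, seed = 7)
SimConfig <- function(depthPerSample = 1e6,
                      pseudoInitialCount = 100,
                      dmsoMixture = list(weightWt = 0.55, meanWt = 0,
                                         sdWt = 0.15, meanLof = NA_real_,
                                         sdLof = 0.4),
                      sensitiveLevel = NA_real_,
                      resistanceSpec = data.frame(position = integer(),
                                                  mutAa = character(),
                                                  condition = character(),
                                                  beta = numeric()),
                      noiseless = FALSE,
                      noiseModel = c("multinomial", "poisson"),
                      seed = 1L) {
  new("SimConfig",
      depthPerSample = as.numeric(depthPerSample),
      pseudoInitialCount = as.numeric(pseudoInitialCount),
      dmsoMixture = dmsoMixture,
      sensitiveLevel = as.numeric(sensitiveLevel),
      resistanceSpec = resistanceSpec,
      noiseless = isTRUE(noiseless),
      noiseModel = match.arg(noiseModel),
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: depth", format(object@depthPerSample, big.mark = ","),
      "| model", if (object@noiseless) "noiseless" else object@noiseModel,
      "| seed", object@seed, "\n")
  cat("  planted effects:", nrow(object@resistanceSpec), "\n")
})

# ---------------------------------------------------------------------------
# GroundTruth

#' @rdname drawGroundTruth
#' @export
setClass("GroundTruth",
  representation(
    beta = "matrix",          # variants x conditions, true fitness
    variants = "DataFrame",
    seed = "integer"
  )
)

setValidity("GroundTruth", function(object) {
  if (nrow(object@beta) != nrow(object@variants))
    return("beta rows must match the variant table")
  TRUE
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@beta), "variants x",
      ncol(object@beta), "conditions (seed", paste0(object@seed, ")"), "\n")
})

#' @rdname drawGroundTruth
#' @param truth A \code{GroundTruth} object.
#' @export
trueBeta <- function(truth) truth@beta

# ---------------------------------------------------------------------------
# FilterThresholds

#' @rdname FilterThresholds
#' @export
setClass("FilterThresholds",
  representation(
    minMeanCount = "numeric",
    maxZeroFractionAll = "numeric",
    maxZeroFractionT0 = "numeric"
  )
)

setValidity("FilterThresholds", function(object) {
  msg <- character()
  if (object@minMeanCount < 0) msg <- c(msg, "minMeanCount must be >= 0")
  for (s in c("maxZeroFractionAll", "maxZeroFractionT0")) {
    v <- slot(object, s)
    if (v < 0 || v > 1) msg <- c(msg, paste(s, "must lie in [0, 1]"))
  }
  if (length(msg)) msg else TRUE
})

#' Pre-scoring variant count filters
#'
#' Thresholds for retaining a variant in one condition before scoring:
#' mean count over the replicate-by-timepoint grid at least
#' \code{minMeanCount}, fraction of zero cells over the grid at most
#' \code{maxZeroFractionAll}, and fraction of zero T0 cells over the
#' replicates at most \code{maxZeroFractionT0}. All three thresholds are
#' inclusive. The defaults (4, 10/12, 2/3) are the rules applied to the
#' 3-replicate, 4-timepoint inhibitor screen this package models.
#'
#' @param minMeanCount Minimum mean count over the full grid (inclusive).
#' @param maxZeroFractionAll Maximum fraction of zero cells (inclusive).
#' @param maxZeroFractionT0 Maximum fraction of zero T0 cells (inclusive).
#'
#' @return A \code{FilterThresholds} object.
#' @seealso [filterVariants()]
#' @export
#' @examples
#' FilterThresholds()                     # the shipped defaults
#' FilterThresholds(minMeanCount = 10)    # stricter mean-count rule
FilterThresholds <- function(minMeanCount = 4,
                             maxZeroFractionAll = 10 / 12,
                             maxZeroFractionT0 = 2 / 3) {
  new("FilterThresholds",
      minMeanCount = as.numeric(minMeanCount),
      maxZeroFractionAll = as.numeric(maxZeroFractionAll),
      maxZeroFractionT0 = as.numeric(maxZeroFractionT0))
}

setMethod("show", "FilterThresholds", function(object) {
  cat("FilterThresholds: mean >=", object@minMeanCount,
      "| zero fraction <=", round(object@maxZeroFractionAll, 4),
      "| T0 zero fraction <=", round(object@maxZeroFractionT0, 4), "\n")
})

# ---------------------------------------------------------------------------
# ClassCutoffs

#' @rdname ClassCutoffs
#' @export
setClass("ClassCutoffs",
  representation(
    resistanceBetaThreshold = "numeric",
    resistanceTestAlpha = "numeric",
    dmsoBetaMax = "numeric",
    gofGammaMin = "numeric",
    lofGammaMax = "numeric"
  )
)

setValidity("ClassCutoffs", function(object) {
  if (object@resistanceTestAlpha <= 0 || object@resistanceTestAlpha >= 1)
    return("resistanceTestAlpha must lie in (0, 1)")
  TRUE
})

#' Resistance and gain/loss-of-function classification cutoffs
#'
#' A resistance mutation for an inhibitor must (i) grow significantly faster
#' than wild type under that inhibitor — one-sided test of
#' \eqn{\beta_{inh} > 0.5} at level \code{resistanceTestAlpha} — and (ii)
#' not exceed wild-type growth in DMSO (\eqn{\beta_{DMSO} \le 0}, effect
#' size only, no test). On the recentered score
#' \eqn{\gamma = \beta_{inh} - \beta_{DMSO}}, gain-of-function is
#' \eqn{\gamma > 0.75} and loss-of-function \eqn{\gamma < 0}, both strict.
#'
#' @param resistanceBetaThreshold Null value for the one-sided inhibitor
#'   test (doublings per interval above wild type).
#' @param resistanceTestAlpha One-sided p-value cutoff.
#' @param dmsoBetaMax Maximum DMSO score (inclusive).
#' @param gofGammaMin Gain-of-function threshold on gamma (strict).
#' @param lofGammaMax Loss-of-function threshold on gamma (strict).
#'
#' @return A \code{ClassCutoffs} object.
#' @seealso [classifyResistance()], [classifyGofLof()]
#' @export
#' @examples
#' ClassCutoffs()
ClassCutoffs <- function(resistanceBetaThreshold = 0.5,
                         resistanceTestAlpha = 0.1,
                         dmsoBetaMax = 0,
                         gofGammaMin = 0.75,
                         lofGammaMax = 0) {
  new("ClassCutoffs",
      resistanceBetaThreshold = as.numeric(resistanceBetaThreshold),
      resistanceTestAlpha = as.numeric(resistanceTestAlpha),
      dmsoBetaMax = as.numeric(dmsoBetaMax),
      gofGammaMin = as.numeric(gofGammaMin),
      lofGammaMax = as.numeric(lofGammaMax))
}

setMethod("show", "ClassCutoffs", function(object) {
  cat("ClassCutoffs: beta_inh >", object@resistanceBetaThreshold,
      "at alpha", object@resistanceTestAlpha,
      "& beta_DMSO <=", object@dmsoBetaMax, "\n")
  cat("  GOF: gamma >", object@gofGammaMin,
      " LOF: gamma <", object@lofGammaMax, "\n")
})

# ---------------------------------------------------------------------------
# DmsExperiment and ScoreMatrix (SummarizedExperiment subclasses)

#' Container for pooled-selection variant counts
#'
#' A \code{DmsExperiment} extends
#' \linkS4class{SummarizedExperiment}: rows are library variants (with
#' \code{position}, \code{wtAa}, \code{mutAa}, \code{vclass} in the row
#' data), columns are sequencing samples (with \code{condition},
#' \code{replicate}, \code{timepoint} in the column data), and the single
#' assay \code{"counts"} holds read counts. The column grid is complete:
#' every (condition, replicate, timepoint) cell is present, with a shared
#' T0 materialized once per condition. Counts are integer after sampling
#' and real-valued in noiseless simulations.
#'
#' @seealso [simulateExperiment()], [readCounts()], [filterVariants()]
#' @export
setClass("DmsExperiment", contains = "SummarizedExperiment")

setValidity("DmsExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  rd <- rowData(object)
  if (!all(c("position", "wtAa", "mutAa", "vclass") %in% colnames(rd)))
    msg <- c(msg, "rowData needs position, wtAa, mutAa, vclass")
  cd <- colData(object)
  if (!all(c("condition", "replicate", "timepoint") %in% colnames(cd)))
    msg <- c(msg, "colData needs condition, replicate, timepoint")
  if ("counts" %in% assayNames(object) &&
      any(assay(object, "counts") < 0, na.rm = TRUE))
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DmsExperiment", function(object) {
  cd <- colData(object)
  cat("DmsExperiment:", nrow(object), "variants x", ncol(object),
      "sample cells\n")
  cat("  conditions:", paste(unique(cd$condition), collapse = ", "), "\n")
  cat("  replicates:", length(unique(cd$replicate)),
      "| time points:", length(unique(cd$timepoint)), "\n")
})

#' Matrix of per-variant fitness scores across conditions
#'
#' A \code{ScoreMatrix} extends \linkS4class{SummarizedExperiment}:
#' rows are variants, columns are conditions, and the assays \code{"beta"}
#' (doublings per interval relative to wild type), \code{"se"} (replicate
#' standard error) and \code{"nReps"} hold the scoring results; cells are
#' \code{NA} where a variant failed that condition's count filter.
#' \code{metadata()$scoreType} is \code{"beta"} for raw scores or
#' \code{"gamma"} after DMSO recentering.
#'
#' @seealso [scoreAll()], [dmsoRecenter()], [pearsonMatrix()]
#' @export
setClass("ScoreMatrix", contains = "SummarizedExperiment")

setValidity("ScoreMatrix", function(object) {
  msg <- character()
  if (!all(c("beta", "se", "nReps") %in% assayNames(object)))
    msg <- c(msg, "assays beta, se, nReps are required")
  if (is.null(colnames(object)))
    msg <- c(msg, "conditions must be column names")
  if ("se" %in% assayNames(object) &&
      any(assay(object, "se") < 0, na.rm = TRUE))
    msg <- c(msg, "standard errors must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ScoreMatrix", function(object) {
  st <- metadata(object)$scoreType
  cat("ScoreMatrix (", if (is.null(st)) "beta" else st, "): ",
      nrow(object), " variants x ", ncol(object), " conditions\n", sep = "")
  cat("  conditions:", paste(colnames(object), collapse = ", "), "\n")
  b <- assay(object, "beta")
  cat("  scored cells:", sum(!is.na(b)), "of", length(b), "\n")
})

#' @rdname ScoreMatrix-accessors
#' @title Score matrix accessors
#' @description Extract the score, standard-error or replicate-count matrix
#'   from a \linkS4class{ScoreMatrix} (variants in rows, conditions in
#'   columns).
#' @param x A \code{ScoreMatrix}.
#' @return A numeric matrix.
#' @export
scores <- function(x) assay(x, "beta")

#' @rdname ScoreMatrix-accessors
#' @export
scoreErrors <- function(x) assay(x, "se")

#' @rdname ScoreMatrix-accessors
#' @export
scoreReplicates <- function(x) assay(x, "nReps")

#' @rdname DmsExperiment-accessors
#' @title Count container accessors
#' @description Extract the count matrix or the variant table from a
#'   \linkS4class{DmsExperiment}.
#' @param x A \code{DmsExperiment}.
#' @return \code{counts()} returns the variants-by-samples matrix;
#'   \code{variantInfo()} the per-variant \code{DataFrame}.
#' @export
counts <- function(x) assay(x, "counts")

#' @rdname DmsExperiment-accessors
#' @export
variantInfo <- function(x) rowData(x)
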