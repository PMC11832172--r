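suppressPackageStartupMessages({
  library(SummarizedExperiment)
  library(S4Vectors)
})

# Small two-condition noiseless simulation used across tests.
# plant: data.frame(position, mutAa, condition, beta) or NULL.
noiselessSim <- function(startPos = 1100, endPos = 1104,
                         conditions = c("crizotinib", "DMSO"),
                         plant = NULL, d = 2, seed = 1) {
  lib <- buildLibrary(startPos, endPos)
  des <- ExperimentDesign(conditions = conditions,
                          wtDoublingsPerInterval = d)
  cfg <- SimConfig(noiseless = TRUE, seed = seed,
                   resistanceSpec = if (is.null(plant))
                     data.frame(position = integer(), mutAa = character(),
                                condition = character(), beta = numeric())
                   else plant)
  truth <- drawGroundTruth(lib, des, cfg)
  sim <- simulateExperiment(truth, des, cfg)
  list(lib = lib, des = des, cfg = cfg, truth = truth, sim = sim)
}

# Build a ScoreMatrix directly from beta/se matrices (for toy inputs).
toyScoreMatrix <- function(beta, se = NULL, type = "beta",
                           nReps = 3L) {
  if (is.null(rownames(beta)))
    rownames(beta) <- paste0("v", seq_len(nrow(beta)))
  if (is.null(se)) se <- matrix(0.1, nrow(beta), ncol(beta),
                                dimnames = dimnames(beta))
  rd <- DataFrame(name = rownames(beta),
                  position = seq_len(nrow(beta)) + 1099L,
                  wtAa = "A", mutAa = "V",
                  vclass = "missense")
  reps <- matrix(nReps, nrow(beta), ncol(beta), dimnames = dimnames(beta))
  sm <- new("ScoreMatrix", SummarizedExperiment(
    assays = list(beta = beta, se = se, nReps = reps), rowData = rd))
  metadata(sm)$scoreType <- type
  sm
}

# Minimal label table for the aggregation operations.
toyLabels <- function(variant, position, mutAa, condition,
                      isResistance = TRUE) {
  DataFrame(variant = variant, position = as.integer(position),
            wtAa = "A", mutAa = mutAa, condition = condition,
            beta = 1, se = 0.1, gamma = 1.2, pvalue = 0.01,
            isResistance = isResistance, gofClass = "GOF")
}

# A tiny in-memory DmsExperiment from an explicit count matrix.
# mat: variants x (replicate, timepoint) cells for a single condition.
toyCountTable <- function(mat, vclass = NULL, condition = "DMSO",
                          replicates = 3L, timepoints = 4L) {
  stopifnot(ncol(mat) == replicates * timepoints)
  nv <- nrow(mat)
  if (is.null(vclass)) vclass <- rep("missense", nv)
  rd <- DataFrame(name = rownames(mat),
                  position = seq_len(nv) + 1099L,
                  wtAa = "A",
                  mutAa = ifelse(vclass == "synonymous", "A", "V"),
                  vclass = vclass)
  cd <- DataFrame(condition = condition,
                  replicate = rep(seq_len(replicates), each = timepoints),
                  timepoint = rep(seq_len(timepoints) - 1L, replicates))
  colnames(mat) <- paste(cd$condition, cd$replicate,
                         paste0("T", cd$timepoint), sep = "_")
  new("DmsExperiment", SummarizedExperiment(
    assays = list(counts = mat), rowData = rd, colData = cd))
}
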