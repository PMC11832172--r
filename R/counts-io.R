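# Long-format count table I/O and the pre-scoring variant filters.
#
# On-disk format: tab-separated with header
#   variant position wt_aa mut_aa condition replicate timepoint count
# one row per (variant, condition, replicate, timepoint) cell.

countsColumns <- c("variant", "position", "wt_aa", "mut_aa",
                   "condition", "replicate", "timepoint", "count")

#' Read and write long-format variant count tables
#'
#' \code{readCounts()} parses a tab-separated count table (one row per
#' variant, condition, replicate and time point) into a
#' \linkS4class{DmsExperiment}; \code{writeCounts()} is its inverse, and
#' the round trip is lossless. Malformed rows — negative counts, duplicate
#' (variant, condition, replicate, timepoint) keys, non-numeric counts —
#' are reported with their line numbers. Grid cells absent from the file
#' are filled with zero counts and recorded in
#' \code{metadata()$missingCells}.
#'
#' @param path File path.
#' @return \code{readCounts()}: a \code{DmsExperiment}.
#' @export
#' @examples
#' lib <- buildLibrary(1100, 1101)
#' des <- ExperimentDesign(conditions = c("crizotinib", "DMSO"),
#'                         nReplicates = 2)
#' cfg <- SimConfig(depthPerSample = 1000, seed = 5)
#' sim <- simulateExperiment(drawGroundTruth(lib, des, cfg), des, cfg)
#' tf <- tempfile(fileext = ".tsv")
#' writeCounts(sim, tf)
#' identical(dim(readCounts(tf)), dim(sim))
readCounts <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           check.names = FALSE)
  if (!all(countsColumns %in% colnames(raw)))
    stop("count table must have columns: ",
         paste(countsColumns, collapse = ", "))
  line <- seq_len(nrow(raw)) + 1L   # header is line 1

  cnt <- suppressWarnings(as.numeric(raw$count))
  bad <- which(is.na(cnt))
  if (length(bad))
    stop("non-numeric count at line(s): ", paste(head(line[bad], 5),
                                                 collapse = ", "))
  neg <- which(cnt < 0)
  if (length(neg))
    stop("negative count at line(s): ", paste(head(line[neg], 5),
                                              collapse = ", "))
  key <- paste(raw$variant, raw$condition, raw$replicate, raw$timepoint)
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (variant, condition, replicate, timepoint) key at ",
         "line(s): ", paste(head(line[dup], 5), collapse = ", "))

  vtab <- unique(raw[, c("variant", "position", "wt_aa", "mut_aa")])
  if (anyDuplicated(vtab$variant))
    stop("variant names map to inconsistent position/wt_aa/mut_aa rows")
  vtab <- vtab[order(as.integer(vtab$position),
                     ifelse(vtab$mut_aa == "*", "zz", vtab$mut_aa)), ]
  lib <- DataFrame(
    name = vtab$variant,
    position = as.integer(vtab$position),
    wtAa = vtab$wt_aa,
    mutAa = vtab$mut_aa,
    vclass = ifelse(vtab$mut_aa == "*", "nonsense",
                    ifelse(vtab$mut_aa == vtab$wt_aa, "synonymous",
                           "missense")))

  conds <- unique(raw$condition)
  reps <- sort(unique(as.integer(raw$replicate)))
  tps <- sort(unique(as.integer(raw$timepoint)))
  grid <- expand.grid(timepoint = tps, replicate = reps,
                      condition = conds, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("condition", "replicate", "timepoint")]
  cellKey <- paste(grid$condition, grid$replicate, grid$timepoint)

  mat <- matrix(0, nrow(lib), nrow(grid),
                dimnames = list(lib$name,
                                paste(grid$condition, grid$replicate,
                                      paste0("T", grid$timepoint),
                                      sep = "_")))
  ri <- match(raw$variant, lib$name)
  ci <- match(paste(raw$condition, raw$replicate, raw$timepoint), cellKey)
  mat[cbind(ri, ci)] <- cnt

  filled <- unique(ci)
  missing <- setdiff(seq_len(nrow(grid)), filled)

  se <- SummarizedExperiment(assays = list(counts = mat), rowData = lib,
                             colData = DataFrame(grid))
  out <- new("DmsExperiment", se)
  if (length(missing))
    metadata(out)$missingCells <- colnames(mat)[missing]
  out
}

#' @rdname readCounts
#' @param x A \linkS4class{DmsExperiment}.
#' @return \code{writeCounts()}: the path, invisibly.
#' @export
writeCounts <- function(x, path) {
  stopifnot(is(x, "DmsExperiment"))
  rd <- rowData(x); cd <- colData(x)
  mat <- counts(x)
  long <- data.frame(
    variant = rep(rd$name, times = ncol(mat)),
    position = rep(rd$position, times = ncol(mat)),
    wt_aa = rep(rd$wtAa, times = ncol(mat)),
    mut_aa = rep(rd$mutAa, times = ncol(mat)),
    condition = rep(cd$condition, each = nrow(mat)),
    replicate = rep(cd$replicate, each = nrow(mat)),
    timepoint = rep(cd$timepoint, each = nrow(mat)),
    count = as.vector(mat),
    stringsAsFactors = FALSE)
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Per-variant filter evaluation over one condition's R x T grid.
# Returns pass flags and the failing rule names.
evaluateFilters <- function(mat, t0cols, th) {
  nCells <- ncol(mat)
  meanCount <- rowMeans(mat)
  zeroFrac <- rowMeans(mat == 0)
  t0ZeroFrac <- rowMeans(mat[, t0cols, drop = FALSE] == 0)
  passMean <- meanCount >= th@minMeanCount
  passZero <- zeroFrac <= th@maxZeroFractionAll
  passT0 <- t0ZeroFrac <= th@maxZeroFractionT0
  failed <- character(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    f <- c(if (!passMean[i]) "mean_count",
           if (!passZero[i]) "zero_fraction",
           if (!passT0[i]) "t0_zero_fraction")
    failed[i] <- paste(f, collapse = ";")
  }
  list(pass = unname(passMean & passZero & passT0), failed = failed,
       meanCount = unname(meanCount), zeroFrac = unname(zeroFrac),
       t0ZeroFrac = unname(t0ZeroFrac))
}

#' Filter variants in one condition before scoring
#'
#' Applies the three pre-scoring count rules to one condition's
#' replicate-by-timepoint grid: a variant is retained iff (i) its mean
#' count over all cells is at least the minimum, (ii) its fraction of zero
#' cells is at most the cap, and (iii) its fraction of zero T0 cells
#' across replicates is at most the T0 cap. All thresholds are inclusive.
#' Grid cells missing from the table count as zeros (flagged in the report
#' via \code{metadata()$missingCells} on read).
#'
#' @param x A \linkS4class{DmsExperiment}.
#' @param thresholds A [FilterThresholds()].
#' @param condition Condition name to filter.
#'
#' @return A list with \code{counts} (the \code{DmsExperiment} restricted
#'   to the condition's columns and the retained variants) and
#'   \code{report} (a \code{DataFrame}: variant, pass, failedRules,
#'   meanCount, zeroFraction, t0ZeroFraction).
#' @export
#' @examples
#' lib <- buildLibrary(1100, 1101)
#' des <- ExperimentDesign(conditions = "DMSO")
#' cfg <- SimConfig(depthPerSample = 500, seed = 2)
#' sim <- simulateExperiment(drawGroundTruth(lib, des, cfg), des, cfg)
#' res <- filterVariants(sim, FilterThresholds(), "DMSO")
#' table(res$report$pass)
filterVariants <- function(x, thresholds = FilterThresholds(),
                           condition) {
  stopifnot(is(x, "DmsExperiment"), is(thresholds, "FilterThresholds"))
  cd <- colData(x)
  sel <- which(cd$condition == condition)
  if (!length(sel)) {
    warning("condition '", condition, "' not present; empty result")
    rep0 <- DataFrame(variant = character(), pass = logical(),
                      failedRules = character(), meanCount = numeric(),
                      zeroFraction = numeric(), t0ZeroFraction = numeric())
    return(list(counts = x[integer(0), integer(0)], report = rep0))
  }
  sub <- x[, sel]
  mat <- counts(sub)
  t0cols <- which(colData(sub)$timepoint == min(colData(sub)$timepoint))
  ev <- evaluateFilters(mat, t0cols, thresholds)
  report <- DataFrame(variant = rowData(sub)$name, pass = ev$pass,
                      failedRules = ev$failed, meanCount = ev$meanCount,
                      zeroFraction = ev$zeroFrac,
                      t0ZeroFraction = ev$t0ZeroFrac)
  list(counts = sub[ev$pass, ], report = report)
}
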