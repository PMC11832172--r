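# Resistance, GOF/LOF, hotspot and differential-sensitivity calls.
#
# A resistance mutation for an inhibitor grows significantly faster than
# wild type under that inhibitor (one-sided test of beta_inh > 0.5 at the
# 0.1 cutoff) while not exceeding wild-type growth in DMSO
# (beta_DMSO <= 0, effect size only). GOF/LOF labels use the recentered
# score gamma = beta_inh - beta_DMSO with strict thresholds (> 0.75, < 0).

resistancePvalue <- function(beta, se, threshold) {
  z <- (beta - threshold) / se
  p <- stats::pnorm(z, lower.tail = FALSE)
  # se = 0: decided by effect size alone; boundary value sits at p = 0.5
  exact <- which(se == 0)
  p[exact] <- ifelse(beta[exact] > threshold, 0,
                     ifelse(beta[exact] < threshold, 1, 0.5))
  p
}

#' Classify inhibitor-specific resistance mutations
#'
#' Vectorized resistance call for one inhibitor condition: a variant is
#' resistant iff the one-sided p-value for \eqn{H_0: \beta_{inh} \le 0.5}
#' (upper-tail normal on \eqn{(\beta - 0.5)/se}) is at most the test
#' cutoff, and its DMSO score does not exceed wild type
#' (\eqn{\beta_{DMSO} \le 0}). With \code{seFree = TRUE} (for designs
#' without replicate spread) the test is replaced by the plain effect-size
#' rule \eqn{\beta_{inh} > 0.5}. Variants missing either score are
#' unclassified (\code{NA}).
#'
#' @param betaInh,seInh Inhibitor-condition score and standard error.
#' @param betaDmso DMSO-condition score.
#' @param cutoffs A [ClassCutoffs()].
#' @param seFree Use the effect-size-only rule instead of the test.
#'
#' @return A \code{DataFrame}: isResistance (logical, \code{NA} when
#'   unclassified), pvalue, gamma.
#' @export
#' @examples
#' classifyResistance(betaInh = 1.0, seInh = 0.2, betaDmso = -0.1,
#'                    cutoffs = ClassCutoffs())   # z = 2.5 -> resistant
classifyResistance <- function(betaInh, seInh, betaDmso,
                               cutoffs = ClassCutoffs(), seFree = FALSE) {
  stopifnot(is(cutoffs, "ClassCutoffs"))
  thr <- cutoffs@resistanceBetaThreshold
  if (seFree) {
    p <- rep(NA_real_, length(betaInh))
    sig <- betaInh > thr
  } else {
    p <- resistancePvalue(betaInh, seInh, thr)
    sig <- p <= cutoffs@resistanceTestAlpha
  }
  res <- sig & (betaDmso <= cutoffs@dmsoBetaMax)
  res[is.na(betaInh) | is.na(betaDmso)] <- NA
  DataFrame(isResistance = res, pvalue = p, gamma = betaInh - betaDmso)
}

#' Gain/loss-of-function label from a recentered score
#'
#' Strict thresholds on \eqn{\gamma = \beta_{inh} - \beta_{DMSO}}:
#' \code{"GOF"} iff \eqn{\gamma > 0.75}, \code{"LOF"} iff \eqn{\gamma < 0},
#' else \code{"neutral"}.
#'
#' @param gamma Numeric vector of recentered scores.
#' @param cutoffs A [ClassCutoffs()].
#' @return Character vector in \code{c("GOF", "LOF", "neutral")} with
#'   \code{NA} for missing input.
#' @export
#' @examples
#' classifyGofLof(c(0, 0.76, -0.01))   # neutral, GOF, LOF
classifyGofLof <- function(gamma, cutoffs = ClassCutoffs()) {
  stopifnot(is(cutoffs, "ClassCutoffs"))
  out <- ifelse(gamma > cutoffs@gofGammaMin, "GOF",
                ifelse(gamma < cutoffs@lofGammaMax, "LOF", "neutral"))
  out[is.na(gamma)] <- NA_character_
  out
}

#' Label every variant in every inhibitor condition
#'
#' Applies [classifyResistance()] and [classifyGofLof()] to each
#' non-control column of a raw (beta) \linkS4class{ScoreMatrix}, producing
#' the long label table used by the hotspot, shared-set and
#' differential-sensitivity analyses.
#'
#' @param sm A beta-scale \code{ScoreMatrix} with a DMSO column.
#' @param cutoffs A [ClassCutoffs()].
#' @param dmso Control column name.
#' @param seFree Passed to [classifyResistance()].
#'
#' @return A \code{DataFrame}: variant, position, wtAa, mutAa, condition,
#'   beta, se, gamma, pvalue, isResistance, gofClass.
#' @export
#' @examples
#' # labels <- classifyAll(scoreAll(sim))
classifyAll <- function(sm, cutoffs = ClassCutoffs(), dmso = "DMSO",
                        seFree = FALSE) {
  stopifnot(is(sm, "ScoreMatrix"))
  if (!identical(metadata(sm)$scoreType, "beta"))
    stop("classifyAll needs raw beta scores (gamma is derived internally)")
  if (!dmso %in% colnames(sm))
    stop("score matrix has no '", dmso, "' column")
  inhs <- setdiff(colnames(sm), dmso)
  b <- scores(sm); s <- scoreErrors(sm)
  rd <- rowData(sm)
  out <- lapply(inhs, function(cond) {
    cls <- classifyResistance(unname(b[, cond]), unname(s[, cond]),
                              unname(b[, dmso]), cutoffs, seFree)
    DataFrame(variant = rd$name, position = rd$position,
              wtAa = rd$wtAa, mutAa = rd$mutAa, condition = cond,
              beta = unname(b[, cond]), se = unname(s[, cond]),
              gamma = cls$gamma, pvalue = cls$pvalue,
              isResistance = cls$isResistance,
              gofClass = classifyGofLof(cls$gamma, cutoffs))
  })
  do.call(rbind, out)
}

resistantRows <- function(labels, condition = NULL) {
  keep <- !is.na(labels$isResistance) & labels$isResistance
  if (!is.null(condition)) keep <- keep & labels$condition %in% condition
  labels[keep, , drop = FALSE]
}

#' Positions harboring at least one resistance mutation
#'
#' @param labels Label table from [classifyAll()].
#' @param condition Optional condition (or set of conditions) to restrict
#'   to; default uses all.
#' @return Sorted integer vector of positions.
#' @export
#' @examples
#' # resistancePositions(labels, "crizotinib")
resistancePositions <- function(labels, condition = NULL) {
  sort(unique(resistantRows(labels, condition)$position))
}

#' Resistance hotspot counts by inhibitor type
#'
#' Aggregates statistically filtered resistance events
#' (mutation, inhibitor) by residue position and inhibitor type — the
#' collapsed hotspot view — together with the per-mutation expansion whose
#' row sums reproduce the position-level tiles.
#'
#' @param labels Label table from [classifyAll()].
#' @param typemap Named vector mapping condition to inhibitor type
#'   (default [inhibitorTypeMap()]).
#'
#' @return A list of two \code{data.frame}s: \code{byPosition}
#'   (position x type counts) and \code{byMutation}
#'   (position, mutAa, type counts).
#' @export
#' @examples
#' # hs <- hotspotCounts(labels); head(hs$byPosition)
hotspotCounts <- function(labels, typemap = inhibitorTypeMap()) {
  res <- resistantRows(labels)
  miss <- setdiff(unique(res$condition), names(typemap))
  if (length(miss))
    stop("typemap does not cover condition(s): ",
         paste(miss, collapse = ", "))
  types <- sort(unique(unname(typemap)))
  emptyCounts <- function(keys) {
    out <- data.frame(keys, stringsAsFactors = FALSE)
    for (ty in types) out[[ty]] <- integer(nrow(out))
    out
  }
  if (!nrow(res)) {
    return(list(byPosition = emptyCounts(data.frame(position = integer())),
                byMutation = emptyCounts(data.frame(position = integer(),
                                                    mutAa = character()))))
  }
  res$type <- unname(typemap[res$condition])
  byMut <- as.data.frame(table(position = res$position, mutAa = res$mutAa,
                               type = res$type),
                         stringsAsFactors = FALSE)
  wideM <- stats::reshape(byMut, idvar = c("position", "mutAa"),
                          timevar = "type", direction = "wide")
  names(wideM) <- sub("^Freq\\.", "", names(wideM))
  for (ty in setdiff(types, names(wideM))) wideM[[ty]] <- 0L
  wideM <- wideM[rowSums(wideM[, types, drop = FALSE]) > 0, ]
  wideM$position <- as.integer(wideM$position)
  wideM <- wideM[order(wideM$position, wideM$mutAa),
                 c("position", "mutAa", types)]
  rownames(wideM) <- NULL

  byPos <- stats::aggregate(wideM[, types, drop = FALSE],
                            by = list(position = wideM$position), FUN = sum)
  byPos <- byPos[order(byPos$position), ]
  rownames(byPos) <- NULL
  list(byPosition = byPos, byMutation = wideM)
}

#' Resistance mutations shared across inhibitor types
#'
#' Venn partition of distinct resistance mutations over the three
#' ATP-competitive inhibitor classes. A mutation belongs to a class if it
#' is resistant to at least one inhibitor of that class; the seven region
#' counts sum to the number of distinct resistance mutations across the
#' three classes.
#'
#' @param labels Label table from [classifyAll()].
#' @param typemap Named condition-to-type vector.
#' @param types The three classes to partition over.
#'
#' @return Named integer vector over the regions \code{typeI},
#'   \code{typeII}, \code{typeI_half}, \code{typeI.typeII},
#'   \code{typeI.typeI_half}, \code{typeII.typeI_half},
#'   \code{typeI.typeII.typeI_half} (exclusive regions), plus attribute
#'   \code{"members"}: the per-region variant names.
#' @export
#' @examples
#' # sharedResistanceSets(labels)
sharedResistanceSets <- function(labels, typemap = inhibitorTypeMap(),
                                 types = c("typeI", "typeII",
                                           "typeI_half")) {
  stopifnot(length(types) == 3L)
  res <- resistantRows(labels)
  res <- res[res$condition %in% names(typemap), , drop = FALSE]
  res$type <- unname(typemap[res$condition])
  sets <- lapply(types, function(ty)
    unique(res$variant[res$type == ty]))
  names(sets) <- types
  all <- unique(unlist(sets))
  inA <- all %in% sets[[1]]; inB <- all %in% sets[[2]]
  inC <- all %in% sets[[3]]
  region <- paste0(ifelse(inA, "A", ""), ifelse(inB, "B", ""),
                   ifelse(inC, "C", ""))
  regionNames <- c(A = types[1], B = types[2], C = types[3],
                   AB = paste(types[1], types[2], sep = "."),
                   AC = paste(types[1], types[3], sep = "."),
                   BC = paste(types[2], types[3], sep = "."),
                   ABC = paste(types[1], types[2], types[3], sep = "."))
  counts <- stats::setNames(integer(7), unname(regionNames))
  members <- stats::setNames(vector("list", 7), unname(regionNames))
  for (code in names(regionNames)) {
    hit <- all[region == code]
    counts[regionNames[[code]]] <- length(hit)
    members[[regionNames[[code]]]] <- hit
  }
  attr(counts, "members") <- members
  counts
}

#' Differential sensitivity between two inhibitors
#'
#' Variants that are gain-of-function under one inhibitor but
#' loss-of-function under another — candidate non-cross-resistant pairs
#' for sequential dosing. The two returned sets are disjoint by
#' construction (no variant can have \eqn{\gamma > 0.75} and
#' \eqn{\gamma < 0} in the same condition). Optionally, membership can be
#' restricted to variants that also pass the resistance test in the
#' gain-of-function condition.
#'
#' @param sm A gamma-scale \linkS4class{ScoreMatrix} from
#'   [dmsoRecenter()].
#' @param condA,condB The two inhibitor columns to contrast.
#' @param cutoffs A [ClassCutoffs()].
#' @param requireTest If \code{TRUE}, additionally require the variant to
#'   be a statistically filtered resistance mutation in its
#'   gain-of-function condition (needs \code{labels}).
#' @param labels Label table from [classifyAll()] (only with
#'   \code{requireTest}).
#'
#' @return A list: \code{gofA_lofB} and \code{gofB_lofA}, character
#'   vectors of variant names.
#' @export
#' @examples
#' # differentialSensitivity(gammaSm, "crizotinib", "cabozantinib")
differentialSensitivity <- function(sm, condA, condB,
                                    cutoffs = ClassCutoffs(),
                                    requireTest = FALSE, labels = NULL) {
  stopifnot(is(sm, "ScoreMatrix"))
  if (!identical(metadata(sm)$scoreType, "gamma"))
    stop("differentialSensitivity expects DMSO-recentered (gamma) scores")
  for (cond in c(condA, condB))
    if (!cond %in% colnames(sm)) stop("no column '", cond, "'")
  g <- scores(sm)
  gA <- g[, condA]; gB <- g[, condB]
  ok <- !is.na(gA) & !is.na(gB)
  gofAlofB <- ok & gA > cutoffs@gofGammaMin & gB < cutoffs@lofGammaMax
  gofBlofA <- ok & gB > cutoffs@gofGammaMin & gA < cutoffs@lofGammaMax
  vn <- rownames(g)
  if (requireTest) {
    if (is.null(labels))
      stop("requireTest = TRUE needs the label table from classifyAll()")
    resA <- resistantRows(labels, condA)$variant
    resB <- resistantRows(labels, condB)$variant
    gofAlofB <- gofAlofB & vn %in% resA
    gofBlofA <- gofBlofA & vn %in% resB
  }
  list(gofA_lofB = vn[gofAlofB], gofB_lofA = vn[gofBlofA])
}
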