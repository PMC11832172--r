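# Pairwise condition-similarity analysis on fitness score matrices.

#' Pairwise Pearson correlation between conditions
#'
#' Correlates every pair of condition columns of a score matrix over the
#' variants scored in both (pairwise-complete deletion, so per-condition
#' filter differences do not null out the matrix). With
#' \code{useGamma = TRUE} the matrix is DMSO-recentered first and the
#' control column dropped, giving the drug-specific comparison. Pairs
#' sharing fewer than \code{minShared} variants are left \code{NA} with a
#' warning.
#'
#' @param sm A \linkS4class{ScoreMatrix}.
#' @param useGamma Correlate DMSO-subtracted scores instead of raw beta.
#' @param minShared Minimum pairwise-complete variants (default 3).
#' @param dmso Control column name (for recentering).
#'
#' @return A list: \code{r} (symmetric correlation matrix, unit diagonal)
#'   and \code{nPairs} (pairwise-complete observation counts).
#' @export
#' @examples
#' # cm <- pearsonMatrix(scoreAll(sim)); round(cm$r, 2)
pearsonMatrix <- function(sm, useGamma = FALSE, minShared = 3L,
                          dmso = "DMSO") {
  stopifnot(is(sm, "ScoreMatrix"))
  if (useGamma) {
    if (!identical(metadata(sm)$scoreType, "gamma"))
      sm <- dmsoRecenter(sm, dmso)
    sm <- sm[, setdiff(colnames(sm), dmso)]
  }
  b <- scores(sm)
  nc <- ncol(b)
  r <- matrix(NA_real_, nc, nc, dimnames = list(colnames(b), colnames(b)))
  nPairs <- matrix(0L, nc, nc, dimnames = dimnames(r))
  for (i in seq_len(nc)) {
    for (j in i:nc) {
      ok <- !is.na(b[, i]) & !is.na(b[, j])
      nPairs[i, j] <- nPairs[j, i] <- sum(ok)
      if (i == j) {
        r[i, j] <- 1
      } else if (sum(ok) >= minShared) {
        r[i, j] <- r[j, i] <- stats::cor(b[ok, i], b[ok, j])
      }
    }
  }
  low <- which(nPairs < minShared & upper.tri(nPairs), arr.ind = TRUE)
  if (nrow(low))
    warning("pair(s) with fewer than ", minShared,
            " shared variants left NA: ",
            paste(colnames(b)[low[, 1]], colnames(b)[low[, 2]],
                  sep = "~", collapse = ", "))
  list(r = r, nPairs = nPairs)
}
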