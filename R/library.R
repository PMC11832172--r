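# Saturation-mutagenesis library enumeration over the MET kinase domain
# (juxtamembrane tail + kinase domain, residues 1059-1345 in MET numbering).

MET_KD_START <- 1059L
MET_KD_END <- 1345L

#' Default inhibitor panel and type map
#'
#' The eleven ATP-competitive MET inhibitors the package's default design
#' screens, and their binding-mode classes: type I bind the active
#' conformation, type II extend into the back pocket of an inactive
#' conformation, type I 1/2 engage both, and tivantinib (a proposed
#' non-ATP-competitive compound) is typed "other".
#'
#' @return \code{metInhibitors()}: character vector of the 11 inhibitor
#'   names. \code{inhibitorTypeMap()}: named character vector mapping each
#'   inhibitor to \code{"typeI"}, \code{"typeII"}, \code{"typeI_half"} or
#'   \code{"other"}.
#' @export
#' @examples
#' inhibitorTypeMap()
metInhibitors <- function() {
  c("crizotinib", "capmatinib", "tepotinib", "glumetinib", "savolitinib",
    "NVP-BVU972", "cabozantinib", "glesatinib", "merestinib",
    "AMG-458", "tivantinib")
}

#' @rdname metInhibitors
#' @export
inhibitorTypeMap <- function() {
  c(crizotinib = "typeI", capmatinib = "typeI", tepotinib = "typeI",
    glumetinib = "typeI", savolitinib = "typeI", `NVP-BVU972` = "typeI",
    cabozantinib = "typeII", glesatinib = "typeII", merestinib = "typeII",
    `AMG-458` = "typeI_half", tivantinib = "other")
}

#' Synthetic wild-type sequence for the 1059-1345 region
#'
#' A deterministic synthetic 287-residue amino-acid sequence used as the
#' default wild-type reference when enumerating the variant library. It is
#' a stand-in generated in code — not the MET protein sequence — and serves
#' only to give every position a defined wild-type identity so that
#' synonymous variants and variant names are well formed. Supply the real
#' sequence to [buildLibrary()] for position-faithful wild-type residues.
#'
#' @param startPos,endPos Residue range (defaults: the modeled region).
#' @return Character vector of one-letter residues named by position.
#' @export
#' @examples
#' wt <- syntheticWtSequence()
#' length(wt)   # 287
syntheticWtSequence <- function(startPos = MET_KD_START,
                                endPos = MET_KD_END) {
  stopifnot(startPos <= endPos)
  pos <- seq.int(startPos, endPos)
  # fixed linear-congruential walk: stable across platforms and R versions
  state <- 20260101
  idx <- integer(length(pos))
  for (i in seq_along(pos)) {
    state <- (state * 1103515245 + 12345) %% 2147483648
    idx[i] <- (state %% 20L) + 1L
  }
  stats::setNames(AA20[idx], pos)
}

variantName <- function(wtAa, position, mutAa) {
  paste0(wtAa, position, mutAa)
}

#' Enumerate a site-saturation variant library
#'
#' Builds the variant table for a saturation-mutagenesis library over a
#' residue range: at every position all 20 amino acids (19 missense plus
#' the synonymous wild-type codon), plus an early-stop control variant at
#' every \code{stopSpacing}-th position starting from \code{startPos}
#' (inclusive stepping). Ordering is deterministic: position-major,
#' alphabetical mutant amino acid, with the stop variant last within its
#' position.
#'
#' @param startPos,endPos First and last residue (1-based, inclusive).
#' @param stopSpacing Spacing of stop-control positions (default 11).
#' @param wtSequence Optional named character vector of wild-type residues
#'   covering \code{startPos:endPos} (names = positions); defaults to the
#'   synthetic stand-in from [syntheticWtSequence()].
#'
#' @return A \link[S4Vectors]{DataFrame} with one row per variant and
#'   columns \code{name}, \code{position}, \code{wtAa}, \code{mutAa},
#'   \code{vclass} (\code{missense}/\code{synonymous}/\code{nonsense}).
#' @export
#' @examples
#' lib <- buildLibrary(1059, 1345)
#' table(lib$vclass)          # 5453 missense, 287 synonymous, 27 nonsense
buildLibrary <- function(startPos = MET_KD_START, endPos = MET_KD_END,
                         stopSpacing = 11L, wtSequence = NULL) {
  startPos <- as.integer(startPos); endPos <- as.integer(endPos)
  if (is.na(startPos) || is.na(endPos) || startPos > endPos)
    stop("invalid residue range: startPos must be <= endPos")
  stopSpacing <- as.integer(stopSpacing)
  if (is.na(stopSpacing) || stopSpacing < 1L)
    stop("stopSpacing must be >= 1")
  pos <- seq.int(startPos, endPos)
  if (is.null(wtSequence)) {
    wtSequence <- syntheticWtSequence(startPos, endPos)
  } else {
    if (is.null(names(wtSequence)) && length(wtSequence) == length(pos))
      names(wtSequence) <- pos
    if (!all(as.character(pos) %in% names(wtSequence)))
      stop("wtSequence must cover every position in the range")
    wtSequence <- wtSequence[as.character(pos)]
  }

  stopPos <- seq.int(startPos, endPos, by = stopSpacing)
  rows <- lapply(seq_along(pos), function(i) {
    p <- pos[i]
    wt <- unname(wtSequence[i])
    mut <- AA20
    if (p %in% stopPos) mut <- c(mut, "*")
    data.frame(position = p, wtAa = wt, mutAa = mut,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  vclass <- ifelse(tab$mutAa == "*", "nonsense",
                   ifelse(tab$mutAa == tab$wtAa, "synonymous", "missense"))
  DataFrame(name = variantName(tab$wtAa, tab$position, tab$mutAa),
            position = tab$position, wtAa = tab$wtAa, mutAa = tab$mutAa,
            vclass = vclass)
}
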