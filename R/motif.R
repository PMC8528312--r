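# Translation-initiation motif definition and matching.

#' Describe the translation-initiation motif searched by the designer
#'
#' A motif is a Shine-Dalgarno hexamer within \code{maxSDMismatches} of the
#' consensus, followed by a 3-7 nt spacer, followed by a start codon. The
#' default window (18 nt) is the maximal motif span 6+7+3 rounded up to a
#' codon multiple.
#'
#' @param sdConsensus consensus ribosome-binding hexamer.
#' @param maxSDMismatches allowed Hamming distance to the consensus.
#' @param spacerMin,spacerMax spacer length bounds (nt).
#' @param startCodons accepted start codons (ATG by default).
#' @param windowNt search-window size; defaults to the maximal motif span
#'   rounded up to a codon multiple.
#' @return a \linkS4class{MotifSpec}.
#' @export
motifSpec <- function(sdConsensus = "AGGAGG", maxSDMismatches = 1L,
                      spacerMin = 3L, spacerMax = 7L,
                      startCodons = "ATG", windowNt = NULL) {
  sdConsensus <- toupper(sdConsensus)
  if (is.null(windowNt)) {
    windowNt <- nchar(sdConsensus) + spacerMax + 3L
    windowNt <- as.integer(ceiling(windowNt / 3) * 3)
  }
  new("MotifSpec", sdConsensus = sdConsensus,
      maxSDMismatches = as.integer(maxSDMismatches),
      spacerMin = as.integer(spacerMin), spacerMax = as.integer(spacerMax),
      startCodons = toupper(startCodons), windowNt = as.integer(windowNt))
}

#' Designer configuration constructor
#'
#' @param stringency "S0" (synonymous changes only), "S1" (one amino-acid
#'   change allowed in total) or "S2plus" (one change for the motif plus
#'   suggested manual substitutions for irremovable new-frame stops).
#' @param motif a \linkS4class{MotifSpec}.
#' @param maxRepeatLen mononucleotide runs longer than this are cleared
#'   best-effort (they are frameshift hotspots).
#' @param clearRareCodons,clearSecondaryStarts enable the optional passes.
#' @return a \linkS4class{DesignConfig}.
#' @export
designConfig <- function(stringency = c("S1", "S0", "S2plus"),
                         motif = motifSpec(), maxRepeatLen = 3L,
                         clearRareCodons = TRUE, clearSecondaryStarts = TRUE) {
  stringency <- match.arg(stringency)
  new("DesignConfig", motif = motif, stringency = stringency,
      maxRepeatLen = as.integer(maxRepeatLen),
      clearRareCodons = clearRareCodons,
      clearSecondaryStarts = clearSecondaryStarts)
}

.hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Find translation-initiation motif placements in a window
#'
#' Reports every placement where a substring within
#' \code{maxSDMismatches} of the Shine-Dalgarno consensus is followed by an
#' in-range spacer and then a start codon. Coordinates are 0-based.
#'
#' @param window DNA string.
#' @param spec a \linkS4class{MotifSpec}.
#' @return data.frame with columns \code{sd_start}, \code{spacer_len},
#'   \code{start_pos}, ordered by ascending \code{sd_start} then spacer.
#' @examples
#' matchMotif("AGGAGGCCCCCATG", motifSpec())
#' @export
matchMotif <- function(window, spec = motifSpec()) {
  window <- toupper(window)
  n <- nchar(window)
  sdLen <- nchar(spec@sdConsensus)
  out <- list()
  maxSd <- n - sdLen - spec@spacerMin - 3L
  if (maxSd >= 0L) {
    consChars <- strsplit(spec@sdConsensus, "")[[1]]
    chars <- strsplit(window, "")[[1]]
    for (sdStart in 0:maxSd) {
      mm <- sum(chars[(sdStart + 1L):(sdStart + sdLen)] != consChars)
      if (mm > spec@maxSDMismatches) next
      for (spacer in spec@spacerMin:spec@spacerMax) {
        sp <- sdStart + sdLen + spacer
        if (sp + 3L > n) break
        cod <- substr(window, sp + 1L, sp + 3L)
        if (cod %in% spec@startCodons)
          out[[length(out) + 1L]] <- c(sdStart, spacer, sp, mm)
      }
    }
  }
  if (!length(out))
    return(data.frame(sd_start = integer(), spacer_len = integer(),
                      start_pos = integer(), sd_mismatches = integer()))
  m <- do.call(rbind, out)
  data.frame(sd_start = as.integer(m[, 1]), spacer_len = as.integer(m[, 2]),
             start_pos = as.integer(m[, 3]), sd_mismatches = as.integer(m[, 4]))
}
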