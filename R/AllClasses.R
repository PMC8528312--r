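#' @import methods
#' @importFrom stats dpois median pnorm qnorm qt quantile rbinom rexp runif sd
#'   setNames wilcox.test var
#' @importFrom utils head read.delim write.table
NULL

#' Codon table for a genetic code
#'
#' Holds the codon to amino-acid map, the synonym sets derived from it, the
#' configurable set of rare codons and the allowed start codons. The default
#' is the standard (bacterial, translation table 11) genetic code as shipped
#' with Biostrings.
#'
#' @slot code named character vector mapping all 64 codons to one-letter
#'   amino acids, stop codons mapped to \code{"*"}.
#' @slot synonymSets named list: amino acid -> sorted character vector of its
#'   sense codons. The sets partition the 61 sense codons.
#' @slot rareCodons character vector of codons treated as rare.
#' @slot startCodons character vector of codons accepted as created starts.
#' @export
setClass("CodonTable", representation(
  code = "character",
  synonymSets = "list",
  rareCodons = "character",
  startCodons = "character"
))

setValidity("CodonTable", function(object) {
  msg <- character()
  if (length(object@code) != 64L) msg <- c(msg, "code must map all 64 codons")
  sense <- sort(unlist(object@synonymSets, use.names = FALSE))
  if (length(sense) != 61L || anyDuplicated(sense))
    msg <- c(msg, "synonymSets must partition the 61 sense codons")
  if (any(object@code[sense] == "*"))
    msg <- c(msg, "synonymSets must not contain stop codons")
  if (length(msg)) msg else TRUE
})

#' A validated protein-coding sequence
#'
#' One CDS on its coding strand. Validity requires a positive length that is
#' a multiple of 3 and a frame-0 translation free of internal stop codons;
#' a missing start codon or terminal stop codon only triggers a warning at
#' construction time (some inputs are CDS fragments).
#'
#' @slot id record identifier (first whitespace-delimited FASTA token).
#' @slot sequence upper-case DNA string over A/C/G/T.
#' @slot description free-text description.
#' @slot source provenance (file and record locator).
#' @export
setClass("CDSRecord", representation(
  id = "character",
  sequence = "character",
  description = "character",
  source = "character"
))

setValidity("CDSRecord", function(object) {
  msg <- character()
  s <- object@sequence
  if (length(s) != 1L || nchar(s) == 0L) return("sequence must be a single non-empty string")
  bad <- .firstNonACGT(s)
  if (!is.na(bad)) return(sprintf("non-ACGT character '%s' at position %d (0-based)",
                                  substr(s, bad + 1L, bad + 1L), bad))
  if (nchar(s) %% 3L != 0L) msg <- c(msg, "length must be a positive multiple of 3")
  else {
    aa <- .translateChars(s, 0L)
    body <- substr(aa, 1L, nchar(aa) - 1L)
    if (grepl("*", body, fixed = TRUE))
      msg <- c(msg, "frame-0 translation contains an internal stop codon")
  }
  if (length(msg)) msg else TRUE
})

#' Specification of a translation-initiation motif
#'
#' A motif is a Shine-Dalgarno hexamer (within a Hamming-distance tolerance
#' of the consensus) followed by a short spacer followed by a start codon.
#'
#' @slot sdConsensus consensus Shine-Dalgarno sequence (default "AGGAGG").
#' @slot maxSDMismatches maximum Hamming distance to the consensus.
#' @slot spacerMin,spacerMax allowed spacer length range in nucleotides.
#' @slot startCodons accepted start codons.
#' @slot windowNt search-window size in nucleotides (codon multiple).
#' @export
setClass("MotifSpec", representation(
  sdConsensus = "character",
  maxSDMismatches = "integer",
  spacerMin = "integer",
  spacerMax = "integer",
  startCodons = "character",
  windowNt = "integer"
))

setValidity("MotifSpec", function(object) {
  msg <- character()
  if (object@spacerMin > object@spacerMax) msg <- c(msg, "spacerMin must be <= spacerMax")
  need <- nchar(object@sdConsensus) + object@spacerMax + 3L
  need <- as.integer(ceiling(need / 3) * 3)
  if (object@windowNt < need)
    msg <- c(msg, sprintf("windowNt must be >= %d (motif span rounded up to a codon)", need))
  if (length(msg)) msg else TRUE
})

#' Designer configuration
#'
#' @slot motif a \linkS4class{MotifSpec}.
#' @slot stringency "S0" (no amino-acid change), "S1" (one change allowed in
#'   total) or "S2plus" (one change for the motif; irremovable new-frame stop
#'   codons are reported as remaining manual substitutions).
#' @slot maxRepeatLen mononucleotide runs longer than this are cleared.
#' @slot clearRareCodons,clearSecondaryStarts enable the best-effort passes.
#' @export
setClass("DesignConfig", representation(
  motif = "MotifSpec",
  stringency = "character",
  maxRepeatLen = "integer",
  clearRareCodons = "logical",
  clearSecondaryStarts = "logical"
))

setValidity("DesignConfig", function(object) {
  if (!object@stringency %in% c("S0", "S1", "S2plus"))
    return("stringency must be one of S0, S1, S2plus")
  TRUE
})

#' A designed overlapping-reading-frame candidate
#'
#' @slot cdsId identifier of the host CDS.
#' @slot startNt 0-based position of the created start codon.
#' @slot frame frame offset of the new reading frame (1 or 2).
#' @slot edits data.frame of nucleotide edits (position, ref, alt,
#'   synonymous, purpose).
#' @slot overlapFraction (L - startNt) / L.
#' @slot aaChangesMade amino-acid changes applied to the host protein.
#' @slot aaChangesRemaining manual substitutions still required (S2plus).
#' @slot sdMismatches Hamming distance of the created SD to the consensus.
#' @slot spacerLen spacer length of the created motif.
#' @slot editedSequence full edited host CDS.
#' @slot flags named logicals: frame_stop_free, secondary_starts_cleared,
#'   repeats_cleared, rare_codons_cleared.
#' @slot suggestions list of suggested manual substitutions per irremovable
#'   stop (S2plus only).
#' @export
setClass("OverlapCandidate", representation(
  cdsId = "character",
  startNt = "integer",
  frame = "integer",
  edits = "data.frame",
  overlapFraction = "numeric",
  aaChangesMade = "integer",
  aaChangesRemaining = "integer",
  sdMismatches = "integer",
  spacerLen = "integer",
  editedSequence = "character",
  flags = "logical",
  suggestions = "list"
))

setValidity("OverlapCandidate", function(object) {
  msg <- character()
  if (!object@frame %in% c(1L, 2L)) msg <- c(msg, "frame must be 1 or 2")
  if (object@startNt %% 3L != object@frame)
    msg <- c(msg, "startNt mod 3 must equal the frame offset")
  if (object@overlapFraction <= 0 || object@overlapFraction > 1)
    msg <- c(msg, "overlapFraction must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' A rejected design site
#'
#' Returned (as a value, not an error) by \code{\link{clearFrame}} when a
#' raw motif site cannot be turned into an acceptable candidate under the
#' configured stringency.
#'
#' @slot cdsId,startNt,frame site identity.
#' @slot reason one of "irremovable_stop", "budget_exceeded".
#' @export
setClass("OverlapRejection", representation(
  cdsId = "character",
  startNt = "integer",
  frame = "integer",
  reason = "character"
))

#' Monte-Carlo protection simulation parameters
#'
#' @slot Pe average deleteriousness of a single amino-acid substitution.
#' @slot fs fraction of mutations that are frameshifts.
#' @slot overlapFraction fraction of the upstream gene inside the overlap.
#' @slot upstreamLenNt,downstreamLenNt coding-sequence lengths.
#' @slot lofModel "discrete_stochastic" or "continuous_deterministic".
#' @slot overlapMode "riboverlap" (only the reading frames overlap) or
#'   "protein_overlap" (the proteins themselves overlap, so substitutions in
#'   the overlap also hit the downstream protein).
#' @slot nReps number of Monte-Carlo replicates.
#' @slot seed RNG seed.
#' @slot lofThreshold activity threshold for the continuous model.
#' @export
setClass("ProtectionParams", representation(
  Pe = "numeric",
  fs = "numeric",
  overlapFraction = "numeric",
  upstreamLenNt = "integer",
  downstreamLenNt = "integer",
  lofModel = "character",
  overlapMode = "character",
  nReps = "integer",
  seed = "integer",
  lofThreshold = "numeric"
))

setValidity("ProtectionParams", function(object) {
  msg <- character()
  for (nm in c("Pe", "fs", "overlapFraction")) {
    v <- slot(object, nm)
    if (v < 0 || v > 1) msg <- c(msg, sprintf("%s must be in [0, 1]", nm))
  }
  if (object@upstreamLenNt <= 0L || object@downstreamLenNt <= 0L)
    msg <- c(msg, "gene lengths must be positive")
  if (object@nReps <= 0L) msg <- c(msg, "nReps must be positive")
  if (!object@lofModel %in% c("discrete_stochastic", "continuous_deterministic"))
    msg <- c(msg, "unknown lofModel")
  if (!object@overlapMode %in% c("riboverlap", "protein_overlap"))
    msg <- c(msg, "unknown overlapMode")
  if (length(msg)) msg else TRUE
})

#' Result of a protection simulation
#'
#' @slot protection fraction of upstream loss-of-function mutations that also
#'   inactivate the downstream gene (NA when undefined).
#' @slot ci95 normal-approximation 95\% confidence interval.
#' @slot nUpstreamLof number of replicates with upstream loss of function.
#' @slot nPurged number of those that also lost the downstream gene.
#' @slot params the \linkS4class{ProtectionParams} used.
#' @export
setClass("ProtectionResult", representation(
  protection = "numeric",
  ci95 = "numeric",
  nUpstreamLof = "integer",
  nPurged = "integer",
  params = "ProtectionParams"
))
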