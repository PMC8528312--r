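# Genetic-code primitives: translation that reads through stop codons,
# exhaustive synonymous-variant enumeration, amino-acid edit distance.

# 0-based index of the first non-ACGT character, NA if clean.
.firstNonACGT <- function(s) {
  m <- regexpr("[^ACGT]", s)
  if (m[1] == -1L) NA_integer_ else as.integer(m[1]) - 1L
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")

# Codons of a string starting at a 0-based offset; trailing partial codon
# discarded.
.codonsOf <- function(s, offset = 0L) {
  n <- nchar(s) - offset
  k <- n %/% 3L
  if (k <= 0L) return(character())
  starts <- offset + 3L * (seq_len(k) - 1L) + 1L
  substring(s, starts, starts + 2L)
}

# Internal translation on a pre-validated string (no ACGT check).
.translateChars <- function(s, offset = 0L, code = NULL) {
  if (is.null(code)) code <- .standardCode()
  paste(code[.codonsOf(s, offset)], collapse = "")
}

.standardCodeCache <- new.env(parent = emptyenv())
.standardCode <- function() {
  if (is.null(.standardCodeCache$code)) {
    gc0 <- Biostrings::GENETIC_CODE
    .standardCodeCache$code <- setNames(as.character(gc0), names(gc0))
  }
  .standardCodeCache$code
}

# The 8 least-used E. coli codons (overridable); rare codons impede
# expression of the new frame and are cleared best-effort.
.DEFAULT_RARE <- c("AGG", "AGA", "CGA", "CGG", "CTA", "ATA", "CCC", "TCG")

#' Build a codon table
#'
#' Constructs a \linkS4class{CodonTable} from the standard genetic code
#' (bacterial translation table 11 equals the standard code for these
#' purposes). Synonym sets are sorted lexicographically so that variant
#' enumeration is deterministic.
#'
#' @param rareCodons codons treated as rare (default: the 8 least-used
#'   \emph{E. coli} codons).
#' @param startCodons codons accepted as created start codons (default ATG
#'   only; GTG/TTG can be added for organisms that tolerate them).
#' @return a \linkS4class{CodonTable}.
#' @examples
#' tab <- codonTable()
#' tab@synonymSets[["L"]]
#' @export
codonTable <- function(rareCodons = .DEFAULT_RARE, startCodons = "ATG") {
  code <- .standardCode()
  sense <- names(code)[code != "*"]
  sets <- split(sense, code[sense])
  sets <- lapply(sets, sort)
  new("CodonTable", code = code, synonymSets = sets,
      rareCodons = toupper(rareCodons), startCodons = toupper(startCodons))
}

.codonTableCache <- new.env(parent = emptyenv())
.defaultTable <- function() {
  if (is.null(.codonTableCache$tab)) .codonTableCache$tab <- codonTable()
  .codonTableCache$tab
}

#' Translate a DNA string in a given frame, reading through stop codons
#'
#' Reads complete codons from a 0-based offset, discarding any trailing
#' partial codon. Stop codons are rendered as \code{"*"} and translation does
#' not halt at them: the design operations need to see every stop in a frame.
#'
#' @param sequence DNA string over A/C/G/T.
#' @param offset 0-based nucleotide offset at which to start reading.
#' @param table a \linkS4class{CodonTable}.
#' @return amino-acid string, one symbol per complete codon.
#' @examples
#' translateFrame("ATGTAA", 0)  # "M*"
#' translateFrame("ATGTAA", 1)  # "C"
#' @export
translateFrame <- function(sequence, offset = 0L, table = .defaultTable()) {
  sequence <- toupper(sequence)
  bad <- .firstNonACGT(sequence)
  if (!is.na(bad))
    stop(sprintf("non-ACGT character '%s' at position %d (0-based)",
                 substr(sequence, bad + 1L, bad + 1L), bad))
  offset <- as.integer(offset)
  if (offset < 0L || offset >= nchar(sequence))
    stop("offset must be in [0, length)")
  .translateChars(sequence, offset, table@code)
}

#' Enumerate all synonymous variants of a codon-aligned window
#'
#' Yields every string obtained by independently replacing each codon with a
#' codon from its synonym set (the original window is among them). Order is
#' deterministic: the first codon position varies slowest, and within each
#' position codons are taken in lexicographic order. The number of variants
#' is the product of the synonym-set sizes.
#'
#' @param window DNA string, length a multiple of 3, sense codons only.
#' @param table a \linkS4class{CodonTable}.
#' @return character vector of variant windows.
#' @examples
#' synonymousVariants("TTA")       # the six leucine codons
#' length(synonymousVariants("ATGTGGTTA"))  # 1 * 1 * 6
#' @export
synonymousVariants <- function(window, table = .defaultTable()) {
  window <- toupper(window)
  if (nchar(window) %% 3L != 0L || nchar(window) == 0L)
    stop("window length must be a positive multiple of 3")
  bad <- .firstNonACGT(window)
  if (!is.na(bad)) stop(sprintf("non-ACGT character at position %d", bad))
  cods <- .codonsOf(window)
  aas <- table@code[cods]
  if (any(aas == "*")) stop("window contains a stop codon")
  sets <- table@synonymSets[aas]
  # first position most significant: expand with later positions cycling fastest
  grid <- expand.grid(rev(sets), KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(sets)), drop = FALSE]
  do.call(paste0, grid)
}

#' Amino-acid edit distance between two equal-length, frame-aligned windows
#'
#' Counts the codon positions whose translations differ: the "stringency
#' cost" of a recoded variant.
#'
#' @param original,variant DNA strings of equal length, multiple of 3.
#' @param table a \linkS4class{CodonTable}.
#' @return integer count of amino-acid differences.
#' @examples
#' aaEditDistance("TTA", "CTG")  # 0, both leucine
#' aaEditDistance("TTA", "TTT")  # 1
#' @export
aaEditDistance <- function(original, variant, table = .defaultTable()) {
  original <- toupper(original); variant <- toupper(variant)
  if (nchar(original) != nchar(variant)) stop("length mismatch")
  if (nchar(original) %% 3L != 0L) stop("length must be a multiple of 3")
  sum(table@code[.codonsOf(original)] != table@code[.codonsOf(variant)])
}

#' Construct a validated CDS record
#'
#' @param id record identifier.
#' @param sequence DNA string; must be a positive multiple of 3 with no
#'   internal frame-0 stop codon. A missing leading start codon or trailing
#'   stop codon triggers a warning only.
#' @param description optional description.
#' @param source optional provenance string (file and record locator).
#' @param table a \linkS4class{CodonTable} (for the start-codon warning).
#' @return a \linkS4class{CDSRecord}.
#' @export
CDSRecord <- function(id, sequence, description = "", source = "",
                      table = .defaultTable()) {
  sequence <- toupper(sequence)
  obj <- new("CDSRecord", id = as.character(id), sequence = sequence,
             description = description, source = source)
  n <- nchar(sequence)
  if (!substr(sequence, 1L, 3L) %in% table@startCodons)
    warning(sprintf("CDS '%s' does not begin with a start codon", id))
  if (!substr(sequence, n - 2L, n) %in% .STOP_CODONS)
    warning(sprintf("CDS '%s' does not end with a stop codon", id))
  obj
}

#' @describeIn CDSRecord sequence accessor
#' @param x a \linkS4class{CDSRecord}.
#' @export
cdsSequence <- function(x) x@sequence

#' @describeIn CDSRecord id accessor
#' @export
cdsId <- function(x) x@id

#' @describeIn CDSRecord CDS length in nucleotides
#' @export
cdsLength <- function(x) nchar(x@sequence)

setMethod("show", "CDSRecord", function(object) {
  n <- nchar(object@sequence)
  cat(sprintf("CDSRecord '%s': %d nt (%d codons)\n", object@id, n, n %/% 3L))
  if (nzchar(object@source)) cat("  source:", object@source, "\n")
})

setMethod("show", "CodonTable", function(object) {
  cat(sprintf("CodonTable: %d sense codons, %d amino acids, %d rare codons, starts: %s\n",
              sum(object@code != "*"), length(object@synonymSets),
              length(object@rareCodons), paste(object@startCodons, collapse = ",")))
})
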