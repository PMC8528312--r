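# File input/output: FASTA and GenBank CDS readers, provenance-stamped TSV
# report writers. Coordinates in all written reports are 0-based half-open
# (stated in the report headers).

#' Read CDS records from a (multi-)FASTA file
#'
#' Record id is the first whitespace-delimited token of the header; the
#' rest becomes the description. Records failing CDS validation are dropped
#' with a warning unless \code{strict}.
#'
#' @param path FASTA file.
#' @param strict error (rather than warn and skip) on invalid CDSs.
#' @return list of \linkS4class{CDSRecord}.
#' @export
readCDSFasta <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  set <- Biostrings::readDNAStringSet(path)
  out <- list()
  for (i in seq_along(set)) {
    header <- names(set)[i]
    id <- sub("\\s.*$", "", header)
    desc <- sub("^\\S+\\s*", "", header)
    rec <- tryCatch(
      suppressWarnings(CDSRecord(id, as.character(set[[i]]), description = desc,
                                 source = sprintf("%s:record %d", path, i))),
      error = function(e) e)
    if (inherits(rec, "error")) {
      if (strict) stop(sprintf("record '%s': %s", id, conditionMessage(rec)))
      warning(sprintf("skipping record '%s': %s", id, conditionMessage(rec)))
    } else out[[length(out) + 1L]] <- rec
  }
  out
}

#' Write CDS records to FASTA
#'
#' @param records list of \linkS4class{CDSRecord}.
#' @param path output file.
#' @export
writeCDSFasta <- function(records, path) {
  seqs <- Biostrings::DNAStringSet(vapply(records, cdsSequence, ""))
  names(seqs) <- vapply(records, function(r)
    trimws(paste(r@id, r@description)), "")
  Biostrings::writeXStringSet(seqs, path)
}

.revComp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Parse "join(12..78,134..202)", "complement(...)", "12..78" into a
# data.frame of 1-based inclusive intervals plus a strand flag.
.parseLocation <- function(loc) {
  strand <- "+"
  loc <- gsub("[<>]", "", loc)
  while (grepl("^(complement|join|order)\\(", loc)) {
    if (grepl("^complement\\(", loc)) strand <- if (strand == "+") "-" else "+"
    loc <- sub("^[a-z]+\\((.*)\\)$", "\\1", loc)
  }
  parts <- strsplit(loc, ",")[[1]]
  iv <- do.call(rbind, lapply(parts, function(p) {
    p <- trimws(p)
    if (grepl("\\.\\.", p)) {
      se <- as.integer(strsplit(p, "\\.\\.")[[1]])
    } else se <- rep(as.integer(p), 2L)
    data.frame(start = se[1], end = se[2])
  }))
  list(intervals = iv, strand = strand)
}

#' Extract CDS features from a GenBank flat file
#'
#' Minimal offline parser for the GenBank flat-file format: reads the ORIGIN
#' sequence of each LOCUS and every CDS feature, joins compound locations
#' and reverse-complements minus-strand features so that each record's
#' sequence is the coding strand. Feature id preference:
#' /locus_tag, then /gene, then a positional name.
#'
#' @param path GenBank file.
#' @param strict error (rather than warn and skip) on invalid CDSs.
#' @return list of \linkS4class{CDSRecord}.
#' @export
readCDSGenBank <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  out <- list()
  locusStarts <- grep("^LOCUS", lines)
  locusEnds <- c(locusStarts[-1] - 1L, length(lines))
  for (li in seq_along(locusStarts)) {
    block <- lines[locusStarts[li]:locusEnds[li]]
    # sequence
    oi <- grep("^ORIGIN", block)
    if (!length(oi)) next
    seqLines <- block[(oi[1] + 1L):length(block)]
    seqLines <- seqLines[!grepl("^//", seqLines)]
    genome <- toupper(gsub("[^A-Za-z]", "", paste(seqLines, collapse = "")))
    # CDS features with their location strings (locations may wrap lines)
    fi <- grep("^     CDS\\s", block)
    for (k in seq_along(fi)) {
      j <- fi[k]
      loc <- trimws(sub("^     CDS\\s+", "", block[j]))
      # continuation lines: keep appending while parentheses are unbalanced
      while (sum(strsplit(loc, "")[[1]] == "(") >
             sum(strsplit(loc, "")[[1]] == ")") && j + 1L <= length(block)) {
        j <- j + 1L
        loc <- paste0(loc, trimws(block[j]))
      }
      # qualifiers up to the next feature
      qEnd <- if (k < length(fi)) fi[k + 1L] - 1L else {
        nxt <- grep("^     \\S", block)
        nxt <- nxt[nxt > fi[k]]
        if (length(nxt)) nxt[1] - 1L else length(block)
      }
      quals <- block[(fi[k] + 1L):min(qEnd, length(block))]
      getQual <- function(name) {
        m <- grep(sprintf('^\\s+/%s="?', name), quals, value = TRUE)
        if (!length(m)) return(NA_character_)
        gsub('"', "", sub(sprintf('^\\s+/%s="?', name), "", m[1]))
      }
      id <- getQual("locus_tag")
      if (is.na(id)) id <- getQual("gene")
      if (is.na(id)) id <- sprintf("CDS_%d_%d", li, k)
      pl <- tryCatch(.parseLocation(loc), error = function(e) NULL)
      if (is.null(pl)) next
      seqStr <- paste(vapply(seq_len(nrow(pl$intervals)), function(r)
        substr(genome, pl$intervals$start[r], pl$intervals$end[r]), ""),
        collapse = "")
      if (pl$strand == "-") seqStr <- .revComp(seqStr)
      rec <- tryCatch(
        suppressWarnings(CDSRecord(id, seqStr,
                                   description = getQual("product"),
                                   source = sprintf("%s:CDS %s", path, loc))),
        error = function(e) e)
      if (inherits(rec, "error")) {
        if (strict) stop(sprintf("CDS '%s': %s", id, conditionMessage(rec)))
        warning(sprintf("skipping CDS '%s': %s", id, conditionMessage(rec)))
      } else out[[length(out) + 1L]] <- rec
    }
  }
  out
}

#' Write a report table as provenance-stamped TSV
#'
#' Tab-separated, '#'-prefixed header lines carrying tool version and
#' provenance, '.' for missing values, UTF-8, LF line endings. All
#' coordinates are 0-based (stated in the header).
#'
#' @param df data.frame.
#' @param path output file.
#' @param provenance named character vector added to the header.
#' @export
writeTableTsv <- function(df, path, provenance = character()) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- c(sprintf("# orfoverlap %s",
                   as.character(utils::packageVersion("orfoverlap"))),
           "# coordinates: 0-based, half-open",
           if (length(provenance))
             sprintf("# %s: %s", names(provenance), provenance))
  writeLines(hdr, con, sep = "\n")
  df2 <- df
  for (j in seq_along(df2)) {
    v <- as.character(df2[[j]])
    v[is.na(v)] <- "."
    df2[[j]] <- v
  }
  writeLines(paste(names(df2), collapse = "\t"), con, sep = "\n")
  if (nrow(df2))
    writeLines(do.call(paste, c(unname(df2), sep = "\t")), con, sep = "\n")
}

#' Read back a TSV report written by \code{\link{writeTableTsv}}
#'
#' @param path file path.
#' @return data.frame with '.' restored to NA and column types re-inferred.
#' @export
readTableTsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  df <- read.delim(path, comment.char = "#", sep = "\t",
                   na.strings = ".", stringsAsFactors = FALSE)
  df
}
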