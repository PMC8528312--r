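# The core design algorithm: create a translation-initiation motif in an
# alternate frame inside an existing CDS via (near-)synonymous recoding,
# then clear the new frame (stop codons, secondary starts, repeats, rare
# codons) for downstream expression.
#
# Implementation note: the search is organised per candidate start position
# rather than per 18-nt window. Because the motif constrains only the
# nucleotides under the SD hexamer and the start codon, enumerating the
# synonym sets of the existing-frame codons that overlap those positions is
# exactly equivalent to brute-forcing all synonymous variants of a window
# covering the motif, and prunes the search space considerably. Spacer
# nucleotides are unconstrained and left untouched.

.charsOf <- function(s) strsplit(s, "")[[1]]

.replaceCodons <- function(chars, codonIdxs, codons) {
  for (i in seq_along(codonIdxs)) {
    p <- 3L * codonIdxs[i]
    chars[(p + 1L):(p + 3L)] <- .charsOf(codons[i])
  }
  chars
}

.codonAt <- function(chars, idx) paste(chars[(3L * idx + 1L):(3L * idx + 3L)], collapse = "")

# new-frame stop positions (0-based nt) scanning from s to the end;
# integer codon encoding (A=0,C=1,G=2,T=3): TAA=48, TAG=50, TGA=56
.newFrameStops <- function(chars, s, L) {
  v <- match(chars, c("A", "C", "G", "T")) - 1L
  starts <- seq.int(s, L - 3L, by = 3L)
  cod <- v[starts + 1L] * 16L + v[starts + 2L] * 4L + v[starts + 3L]
  starts[cod == 48L | cod == 50L | cod == 56L]
}

# Sense-codon bookkeeping shared by the enumeration routines: the 61 sense
# codons in lexicographic order, their letter matrix, and per-amino-acid
# synonym sets as indices into that order.
.senseInfoCache <- new.env(parent = emptyenv())
.senseInfo <- function(table) {
  key <- paste(table@startCodons, collapse = ",")
  info <- .senseInfoCache[[key]]
  if (!is.null(info)) return(info)
  sense <- sort(unlist(table@synonymSets, use.names = FALSE))
  info <- list(
    sense = sense,
    letters = do.call(rbind, strsplit(sense, "")),
    synIdx = lapply(table@synonymSets, function(s) match(sort(s), sense)))
  .senseInfoCache[[key]] <- info
  info
}

# Enumerate assignments of codons (rows of an integer matrix indexing the
# sense-codon list) for the given codon indices. budget 0: synonym sets
# only. budget 1: additionally, assignments where exactly one codon is
# replaced non-synonymously (cost 1). Grids are pairwise disjoint, so the
# amino-acid cost is known by construction.
.enumAssignments <- function(idxs, origCodons, table, budget) {
  info <- .senseInfo(table)
  aas <- table@code[origCodons]
  synOpts <- lapply(aas, function(a) info$synIdx[[a]])
  grids <- list(expand.grid(rev(synOpts), KEEP.OUT.ATTRS = FALSE)[,
                  rev(seq_along(synOpts)), drop = FALSE])
  if (budget >= 1L) {
    for (w in seq_along(idxs)) {
      opts <- synOpts
      opts[[w]] <- setdiff(seq_along(info$sense), synOpts[[w]])
      grids[[length(grids) + 1L]] <-
        expand.grid(rev(opts), KEEP.OUT.ATTRS = FALSE)[,
          rev(seq_along(opts)), drop = FALSE]
    }
  }
  mats <- lapply(grids, function(g) {
    m <- as.matrix(g); dimnames(m) <- NULL; m
  })
  m <- do.call(rbind, mats)
  aaCost <- rep.int(c(0L, rep.int(1L, length(mats) - 1L)),
                    vapply(mats, nrow, integer(1)))
  list(idx = m, aaCost = aaCost, sense = info$sense, letters = info$letters)
}

# codon strings of one assignment row
.assignmentCodons <- function(en, r) en$sense[en$idx[r, ]]

# Letters attainable at each nucleotide position of the CDS body by
# synonymous recoding alone; used as a cheap feasibility prefilter.
.achievableLetters <- function(chars, nBody, table) {
  ach <- vector("list", 3L * nBody)
  for (i in 0:(nBody - 1L)) {
    syns <- table@synonymSets[[table@code[.codonAt(chars, i)]]]
    for (k in 1:3)
      ach[[3L * i + k]] <- unique(substr(syns, k, k))
  }
  ach
}

#' Enumerate raw motif-creation sites in a CDS
#'
#' For every alternate-frame position at which the motif can fit inside the
#' CDS body, searches all synonymous recodings (plus, at stringency S1 and
#' above, recodings with a single amino-acid change) of the existing-frame
#' codons under the SD hexamer and the start codon. Per (start position,
#' frame) only the minimum-cost variant is kept: fewest amino-acid changes,
#' then fewest nucleotide edits, then lexicographically smallest edited
#' sequence. A start codon that already exists with a satisfying upstream
#' motif yields a zero-edit site.
#'
#' @param cds a \linkS4class{CDSRecord}.
#' @param config a \linkS4class{DesignConfig}.
#' @param table a \linkS4class{CodonTable}.
#' @return list of raw sites (internal structure) ordered by start position;
#'   feed to \code{\link{clearFrame}} or use \code{\link{designOverlaps}}.
#' @export
findMotifSites <- function(cds, config = designConfig(), table = .defaultTable()) {
  spec <- config@motif
  budget <- if (config@stringency == "S0") 0L else 1L
  s0 <- cds@sequence
  L <- nchar(s0)
  nCod <- L %/% 3L
  nBody <- nCod - 1L          # terminal stop codon is immutable
  chars <- .charsOf(s0)
  sdLen <- nchar(spec@sdConsensus)
  consChars <- .charsOf(spec@sdConsensus)
  ach <- .achievableLetters(chars, nBody, table)

  sites <- list()
  sMin <- sdLen + spec@spacerMin
  sMax <- L - 6L              # start codon fully within the body
  if (sMax < sMin) return(sites)
  # per-codon-index lookup: nucleotide edit distance from the original codon
  # to each sense codon (vectorized scoring of assignment rows)
  info <- .senseInfo(table)
  distLookup <- lapply(0:(nBody - 1L), function(i) {
    oc <- .charsOf(.codonAt(chars, i))
    rowSums(info$letters != matrix(oc, nrow(info$letters), 3, byrow = TRUE))
  })
  enumCache <- new.env(parent = emptyenv())
  for (s in sMin:sMax) {
    f <- s %% 3L
    if (f == 0L) next
    startPos <- s:(s + 2L)
    startIdx <- unique(startPos %/% 3L)
    best <- NULL
    for (pass in 0:budget) {       # pass 0: synonymous only; pass 1: one AA
      if (pass == 1L && !is.null(best)) break
      for (spacer in spec@spacerMin:spec@spacerMax) {
        sdStart <- s - spacer - sdLen
        if (sdStart < 0L) next
        sdPos <- sdStart:(sdStart + sdLen - 1L)
        sdIdx <- unique(sdPos %/% 3L)
        idxs <- sort(unique(c(sdIdx, startIdx)))
        if (any(idxs >= nBody)) next
        # prefilter: count constrained positions whose target letter is not
        # synonymously achievable, grouped by codon (one wildcard codon can
        # rescue its own positions at pass 1)
        sdBadCodon <- integer()
        for (k in seq_len(sdLen)) {
          p <- sdPos[k]
          if (!(consChars[k] %in% ach[[p + 1L]])) sdBadCodon <- c(sdBadCodon, p %/% 3L)
        }
        startCod <- .charsOf(spec@startCodons[1])  # used only for quick check below
        startBadCodon <- integer()
        startFeasible <- FALSE
        for (sc in spec@startCodons) {
          scChars <- .charsOf(sc)
          bad <- integer()
          for (k in 1:3)
            if (!(scChars[k] %in% ach[[startPos[k] + 1L]])) bad <- c(bad, startPos[k] %/% 3L)
          if (length(bad) == 0L) startFeasible <- TRUE
          startBadCodon <- bad   # per last start codon; refined check below
        }
        if (pass == 0L) {
          if (!startFeasible && length(spec@startCodons) == 1L) next
          if (length(sdBadCodon) > spec@maxSDMismatches) next
        } else {
          # one wildcard codon can fix all its own bad positions
          allBad <- c(sdBadCodon, if (!startFeasible) startBadCodon)
          if (length(allBad)) {
            tabBad <- table(allBad)
            if (length(allBad) - max(tabBad) > spec@maxSDMismatches &&
                length(unique(allBad)) > 1L) next
          }
        }
        cacheKey <- paste(c(idxs, pass), collapse = ",")
        en <- enumCache[[cacheKey]]
        if (is.null(en)) {
          origCodons <- vapply(idxs, function(i) .codonAt(chars, i), "")
          en <- .enumAssignments(idxs, origCodons, table, pass)
          enumCache[[cacheKey]] <- en
        }
        m <- en$idx
        nr <- nrow(m)
        if (!nr) next
        # vectorized motif check over assignment rows
        letterAt <- function(p) {
          ci <- match(p %/% 3L, idxs)
          en$letters[m[, ci], p %% 3L + 1L]
        }
        mmv <- integer(nr)
        for (k in seq_len(sdLen))
          mmv <- mmv + (letterAt(sdPos[k]) != consChars[k])
        startStr <- paste0(letterAt(startPos[1]), letterAt(startPos[2]),
                           letterAt(startPos[3]))
        ok <- which(mmv <= spec@maxSDMismatches & startStr %in% spec@startCodons)
        if (!length(ok)) next
        ntEdits <- numeric(nr)
        for (j in seq_along(idxs))
          ntEdits <- ntEdits + distLookup[[idxs[j] + 1L]][m[, j]]
        assignStr <- do.call(paste0, lapply(seq_along(idxs),
                                            function(j) en$sense[m[ok, j]]))
        o <- ok[order(en$aaCost[ok], ntEdits[ok], assignStr, mmv[ok])[1]]
        newChars <- .replaceCodons(chars, idxs, en$sense[m[o, ]])
        key <- list(aa = en$aaCost[o], edits = unname(ntEdits[o]),
                    seq = paste(newChars, collapse = ""),
                    mm = unname(mmv[o]), spacer = spacer, sdStart = sdStart)
        if (is.null(best) ||
            key$aa < best$aa ||
            (key$aa == best$aa && (key$edits < best$edits ||
             (key$edits == best$edits && (key$seq < best$seq ||
              (key$seq == best$seq && (key$mm < best$mm ||
               (key$mm == best$mm && key$spacer < best$spacer))))))))
          best <- key
      }
    }
    if (!is.null(best)) {
      sites[[length(sites) + 1L]] <- list(
        cdsId = cds@id, startNt = as.integer(s), frame = as.integer(f),
        sdStart = as.integer(best$sdStart), spacer = as.integer(best$spacer),
        sdMismatches = as.integer(best$mm), aaCost = as.integer(best$aa),
        editedSeq = best$seq)
    }
  }
  sites
}

# motif placements over a whole sequence (used for secondary-start clearing)
.allPlacements <- function(seqStr, spec) {
  matchMotif(seqStr, spec)
}

#' Clear the new reading frame of a raw motif site
#'
#' Scans the new frame from the created start codon to the end of the CDS.
#' Stop codons are removed by synonymous recoding of the (at most two)
#' overlapping existing-frame codons; a recoding must not touch the created
#' motif, and must not create a new stop in the new frame. Under stringency
#' S0 an irremovable stop rejects the site; under S1 a single amino-acid
#' change (if not already spent on the motif) may be used; under S2plus
#' irremovable stops are reported as remaining manual substitutions together
#' with suggested replacements. Afterwards, best-effort synonymous passes
#' remove secondary translation-initiation motifs downstream of the created
#' one, mononucleotide runs longer than \code{maxRepeatLen}, and rare codons
#' in the new frame.
#'
#' @param cds the host \linkS4class{CDSRecord}.
#' @param raw a raw site from \code{\link{findMotifSites}}.
#' @param config a \linkS4class{DesignConfig}.
#' @param table a \linkS4class{CodonTable}.
#' @return an \linkS4class{OverlapCandidate}, or an
#'   \linkS4class{OverlapRejection} when the site cannot be cleared.
#' @export
clearFrame <- function(cds, raw, config = designConfig(), table = .defaultTable()) {
  orig <- cds@sequence
  L <- nchar(orig)
  nCod <- L %/% 3L
  termIdx <- nCod - 1L
  s <- raw$startNt
  chars <- .charsOf(raw$editedSeq)
  origChars <- .charsOf(orig)
  locked <- c(raw$sdStart:(raw$sdStart + nchar(config@motif@sdConsensus) - 1L),
              s:(s + 2L)) + 1L      # 1-based indices into chars
  aaUsed <- raw$aaCost
  aaBudgetTotal <- switch(config@stringency, S0 = 0L, S1 = 1L, S2plus = 1L)
  purpose <- rep(NA_character_, L)
  purpose[which(chars != origChars)] <- "motif_creation"

  stopSafe <- function(newChars, removedQ, tolerated) {
    # no stop may appear in the new frame that was not already there
    after <- .newFrameStops(newChars, s, L)
    before <- .newFrameStops(chars, s, L)
    allowed <- setdiff(before, removedQ)
    all(after %in% c(allowed, tolerated)) &&
      (length(removedQ) == 0L || !any(removedQ %in% after))
  }

  trySynFix <- function(q, tolerated, wildcard = FALSE) {
    idxs <- unique(c(q, q + 2L) %/% 3L)
    idxs <- idxs[idxs >= 0L & idxs < termIdx]
    if (!length(idxs)) return(NULL)
    origCodons <- vapply(idxs, function(i) .codonAt(chars, i), "")
    en <- .enumAssignments(idxs, origCodons, table, if (wildcard) 1L else 0L)
    best <- NULL
    for (r in seq_len(nrow(en$idx))) {
      if (wildcard && en$aaCost[r] == 0L) next   # pure-synonymous handled earlier
      cand <- .replaceCodons(chars, idxs, .assignmentCodons(en, r))
      if (any(cand[locked] != chars[locked])) next
      if (paste(cand[(q + 1L):(q + 3L)], collapse = "") %in% .STOP_CODONS) next
      if (!stopSafe(cand, q, tolerated)) next
      edits <- sum(cand != chars)
      if (edits == 0L) next
      repl <- paste(.assignmentCodons(en, r), collapse = "")
      if (is.null(best) || edits < best$edits ||
          (edits == best$edits && repl < best$repl))
        best <- list(chars = cand, edits = edits, repl = repl,
                     aaCost = en$aaCost[r], idxs = idxs)
    }
    best
  }

  # ---- stop-codon removal ----
  remaining <- 0L
  suggestions <- list()
  tolerated <- integer()   # S2plus stops left for manual substitution
  repeat {
    stops <- setdiff(.newFrameStops(chars, s, L), tolerated)
    if (!length(stops)) break
    q <- stops[1]
    fix <- trySynFix(q, tolerated)
    if (!is.null(fix)) {
      purpose[which(fix$chars != chars)] <- "stop_removal"
      chars <- fix$chars
      next
    }
    if (config@stringency == "S1" && aaUsed < aaBudgetTotal) {
      fix <- trySynFix(q, tolerated, wildcard = TRUE)
      if (!is.null(fix)) {
        purpose[which(fix$chars != chars)] <- "stop_removal"
        chars <- fix$chars
        aaUsed <- aaUsed + fix$aaCost
        next
      }
    }
    if (config@stringency == "S2plus") {
      # collect suggested non-synonymous single-codon replacements
      sug <- list()
      idxs <- unique(c(q, q + 2L) %/% 3L)
      idxs <- idxs[idxs >= 0L & idxs < termIdx]
      if (length(idxs)) {
        origCodons <- vapply(idxs, function(i) .codonAt(chars, i), "")
        en <- .enumAssignments(idxs, origCodons, table, 1L)
        for (r in seq_len(nrow(en$idx))) {
          if (en$aaCost[r] == 0L) next
          cand <- .replaceCodons(chars, idxs, .assignmentCodons(en, r))
          if (any(cand[locked] != chars[locked])) next
          if (paste(cand[(q + 1L):(q + 3L)], collapse = "") %in% .STOP_CODONS) next
          if (!stopSafe(cand, q, tolerated)) next
          sug[[length(sug) + 1L]] <- data.frame(
            codon_idx = idxs, from = origCodons, to = .assignmentCodons(en, r),
            stringsAsFactors = FALSE)
        }
      }
      suggestions[[as.character(q)]] <- sug
      remaining <- remaining + 1L
      tolerated <- c(tolerated, q)
      next
    }
    return(new("OverlapRejection", cdsId = cds@id, startNt = s,
               frame = raw$frame, reason = "irremovable_stop"))
  }

  bestEffort <- function(idxs, accept, purposeTag) {
    # try synonymous recodings of the given codons; accept(newChars) must
    # approve; returns TRUE if an edit was applied
    idxs <- idxs[idxs >= 0L & idxs < termIdx]
    if (!length(idxs)) return(FALSE)
    origCodons <- vapply(idxs, function(i) .codonAt(chars, i), "")
    en <- .enumAssignments(idxs, origCodons, table, 0L)
    best <- NULL
    for (r in seq_len(nrow(en$idx))) {
      cand <- .replaceCodons(chars, idxs, .assignmentCodons(en, r))
      if (any(cand[locked] != chars[locked])) next
      if (!stopSafe(cand, integer(), tolerated)) next
      if (!accept(cand)) next
      edits <- sum(cand != chars)
      if (edits == 0L) next
      repl <- paste(.assignmentCodons(en, r), collapse = "")
      if (is.null(best) || edits < best$edits ||
          (edits == best$edits && repl < best$repl))
        best <- list(chars = cand, edits = edits, repl = repl)
    }
    if (is.null(best)) return(FALSE)
    purpose[which(best$chars != chars)] <<- purposeTag
    chars <<- best$chars
    TRUE
  }

  # ---- secondary translation-initiation motifs downstream of ours ----
  if (config@clearSecondaryStarts) {
    guard2 <- 0L
    repeat {
      pl <- .allPlacements(paste(chars, collapse = ""), config@motif)
      pl <- pl[pl$start_pos > s, , drop = FALSE]
      if (!nrow(pl) || guard2 > 50L) break
      guard2 <- guard2 + 1L
      p <- pl$start_pos[1]
      ok <- bestEffort(unique(c(p, p + 2L) %/% 3L), function(cand) {
        !(paste(cand[(p + 1L):(p + 3L)], collapse = "") %in% config@motif@startCodons)
      }, "secondary_start_removal")
      if (!ok) break
    }
    pl <- .allPlacements(paste(chars, collapse = ""), config@motif)
    secondaryCleared <- !any(pl$start_pos > s)
  } else secondaryCleared <- NA
  # ---- mononucleotide runs in the new frame region ----
  runsOver <- function(cc) {
    r <- rle(cc[(s + 1L):L])
    w <- which(r$lengths > config@maxRepeatLen)
    if (!length(w)) return(integer())
    ends <- cumsum(r$lengths)
    s + (ends[w] - r$lengths[w])    # 0-based run starts within full seq
  }
  guard <- 0L
  repeat {
    rs <- runsOver(chars)
    if (!length(rs) || guard > 50L) break
    guard <- guard + 1L
    r0 <- rs[1]
    runLen <- rle(chars[(r0 + 1L):L])$lengths[1]
    idxs <- unique(seq.int(r0, r0 + runLen - 1L) %/% 3L)
    ok <- bestEffort(idxs, function(cand) {
      rr <- runsOver(cand)
      !length(rr) || all(rr > r0) || length(rr) < length(rs)
    }, "repeat_removal")
    if (!ok) break
  }
  repeatsCleared <- length(runsOver(chars)) == 0L
  # ---- rare codons in the new frame ----
  if (config@clearRareCodons && length(table@rareCodons)) {
    nfStartsAll <- seq.int(s, L - 3L, by = 3L)
    for (q in nfStartsAll) {
      cod <- paste(chars[(q + 1L):(q + 3L)], collapse = "")
      if (!(cod %in% table@rareCodons)) next
      bestEffort(unique(c(q, q + 2L) %/% 3L), function(cand) {
        nc <- paste(cand[(q + 1L):(q + 3L)], collapse = "")
        !(nc %in% table@rareCodons) && !(nc %in% .STOP_CODONS)
      }, "rare_codon_removal")
    }
    nfCods <- vapply(seq.int(s, L - 3L, by = 3L),
                     function(q) paste(chars[(q + 1L):(q + 3L)], collapse = ""), "")
    rareCleared <- !any(nfCods %in% table@rareCodons)
  } else rareCleared <- NA

  finalSeq <- paste(chars, collapse = "")
  diffPos <- which(chars != origChars) - 1L     # 0-based
  synFlag <- vapply(diffPos, function(p) {
    i <- p %/% 3L
    table@code[.codonAt(origChars, i)] == table@code[.codonAt(chars, i)]
  }, logical(1))
  edits <- data.frame(
    position = diffPos,
    ref = origChars[diffPos + 1L],
    alt = chars[diffPos + 1L],
    synonymous = synFlag,
    purpose = purpose[diffPos + 1L],
    stringsAsFactors = FALSE)
  flags <- c(frame_stop_free = remaining == 0L &&
               length(.newFrameStops(chars, s, L)) == 0L,
             secondary_starts_cleared = isTRUE(secondaryCleared),
             repeats_cleared = repeatsCleared,
             rare_codons_cleared = isTRUE(rareCleared))
  new("OverlapCandidate",
      cdsId = cds@id, startNt = s, frame = raw$frame, edits = edits,
      overlapFraction = (L - s) / L,
      aaChangesMade = as.integer(aaEditDistance(orig, finalSeq, table)),
      aaChangesRemaining = remaining,
      sdMismatches = raw$sdMismatches, spacerLen = raw$spacer,
      editedSequence = finalSeq, flags = flags, suggestions = suggestions)
}

#' Design overlapping-reading-frame candidates for a CDS
#'
#' Full pipeline: \code{\link{findMotifSites}} then \code{\link{clearFrame}}
#' on each site. Candidates are sorted by ascending start position (that is,
#' descending overlap fraction), then by ascending amino-acid cost. The
#' result is deterministic for a fixed input and configuration.
#'
#' @param cds a \linkS4class{CDSRecord}.
#' @param config a \linkS4class{DesignConfig}.
#' @param table a \linkS4class{CodonTable}.
#' @return list of \linkS4class{OverlapCandidate}; rejected sites are
#'   attached as attribute \code{"rejections"}.
#' @examples
#' cds <- CDSRecord("toy", "ATGAGGAGGCATCATCATGCATAA")
#' cand <- designOverlaps(cds, designConfig("S0"))
#' cand[[1]]@startNt          # 16
#' cand[[1]]@overlapFraction  # 1/3
#' @export
designOverlaps <- function(cds, config = designConfig(), table = .defaultTable()) {
  sites <- findMotifSites(cds, config, table)
  res <- lapply(sites, function(raw) clearFrame(cds, raw, config, table))
  keep <- vapply(res, function(x) is(x, "OverlapCandidate"), logical(1))
  cands <- res[keep]
  rej <- res[!keep]
  if (length(cands)) {
    o <- order(vapply(cands, function(x) x@startNt, integer(1)),
               vapply(cands, function(x) x@aaChangesMade +
                        x@aaChangesRemaining, integer(1)))
    cands <- cands[o]
  }
  attr(cands, "rejections") <- rej
  cands
}

#' Tabulate design candidates
#'
#' @param candidates list of \linkS4class{OverlapCandidate} as returned by
#'   \code{\link{designOverlaps}}.
#' @return data.frame, one row per candidate (0-based coordinates).
#' @export
candidateTable <- function(candidates) {
  if (!length(candidates))
    return(data.frame(cds_id = character(), start_nt = integer(),
                      frame = integer(), overlap_fraction = numeric(),
                      n_syn_edits = integer(), aa_changes_made = integer(),
                      aa_changes_remaining = integer(),
                      sd_mismatches = integer(), spacer_len = integer(),
                      flags = character(), edit_list = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(candidates, function(x) {
    data.frame(
      cds_id = x@cdsId, start_nt = x@startNt, frame = x@frame,
      overlap_fraction = x@overlapFraction,
      n_syn_edits = sum(x@edits$synonymous),
      aa_changes_made = x@aaChangesMade,
      aa_changes_remaining = x@aaChangesRemaining,
      sd_mismatches = x@sdMismatches, spacer_len = x@spacerLen,
      flags = paste(names(x@flags)[x@flags %in% TRUE], collapse = ";"),
      edit_list = if (nrow(x@edits))
        paste(sprintf("%d:%s>%s", x@edits$position, x@edits$ref, x@edits$alt),
              collapse = ";") else ".",
      stringsAsFactors = FALSE)
  }))
}

setMethod("show", "OverlapCandidate", function(object) {
  cat(sprintf(
    "OverlapCandidate in '%s': start %d (frame +%d), overlap %.1f%%, SD mm %d, spacer %d\n",
    object@cdsId, object@startNt, object@frame, 100 * object@overlapFraction,
    object@sdMismatches, object@spacerLen))
  cat(sprintf("  edits: %d (%d AA made, %d AA remaining); flags: %s\n",
              nrow(object@edits), object@aaChangesMade, object@aaChangesRemaining,
              paste(names(object@flags)[object@flags %in% TRUE], collapse = ",")))
})

setMethod("show", "OverlapRejection", function(object) {
  cat(sprintf("OverlapRejection in '%s' at %d (frame +%d): %s\n",
              object@cdsId, object@startNt, object@frame, object@reason))
})

#' Fuse a downstream CDS into a designed overlap
#'
#' Builds the final construct: the edited host sequence, a 0-2 nt phasing
#' pad so that the downstream CDS lies in the candidate's frame, then the
#' downstream CDS body (its own start codon dropped by default, since
#' initiation uses the created motif) and its stop codon. The junction pad
#' is chosen so that no stop codon and no new initiation motif is created at
#' the junction.
#'
#' @param cds the host \linkS4class{CDSRecord}.
#' @param candidate an accepted \linkS4class{OverlapCandidate} for that CDS.
#' @param downstream the essential gene, a \linkS4class{CDSRecord}.
#' @param dropStartCodon drop the downstream gene's own start codon.
#' @param padAlphabet preferred pad nucleotides, tried first (default "GC").
#' @param table a \linkS4class{CodonTable}.
#' @return list with \code{sequence}, \code{features} (data.frame of
#'   0-based half-open CDS features), \code{extensionProtein} (the
#'   N-terminal extension fused to the downstream protein) and \code{padLen}.
#' @export
applyOverlap <- function(cds, candidate, downstream, dropStartCodon = TRUE,
                         padAlphabet = "GC", table = .defaultTable()) {
  if (!is(candidate, "OverlapCandidate")) stop("candidate must be an OverlapCandidate")
  if (candidate@aaChangesRemaining > 0L)
    stop("candidate has remaining manual substitutions; resolve them first")
  down <- downstream@sequence
  if (nchar(down) == 0L) stop("downstream CDS is empty")
  body <- down
  if (dropStartCodon) body <- substr(body, 4L, nchar(body))
  if (nchar(body) < 3L) stop("downstream CDS too short after dropping its start codon")
  up <- candidate@editedSequence
  L <- nchar(up)
  s <- candidate@startNt
  padLen <- (3L - ((L - s) %% 3L)) %% 3L

  tryPads <- if (padLen == 0L) "" else {
    base <- substr(paste(rep(padAlphabet, 3), collapse = ""), 1L, padLen)
    alts <- apply(expand.grid(rep(list(c("G", "C", "A", "T")), padLen)), 1L,
                  paste, collapse = "")
    unique(c(base, alts))
  }
  spec <- motifSpec()
  chosen <- NULL
  for (pad in tryPads) {
    constructSeq <- paste0(up, pad, body)
    # junction region: last upstream codon of the new frame through the
    # first downstream codons
    jStart <- max(s, L - 6L)
    jEnd <- min(nchar(constructSeq), L + padLen + 6L)
    junction <- substr(constructSeq, jStart + 1L, jEnd)
    off <- (s - jStart) %% 3L
    aaJ <- .translateChars(junction, off, table@code)
    if (grepl("*", aaJ, fixed = TRUE)) next
    # the pad must not create a new initiation motif: reject pads for which
    # a motif placement in the junction window touches a pad nucleotide
    jWin0 <- max(0L, L - 14L)
    jWin <- substr(constructSeq, jWin0 + 1L, min(nchar(constructSeq), L + padLen + 15L))
    pl <- matchMotif(jWin, spec)
    if (nrow(pl) && padLen > 0L) {
      padRange <- L:(L + padLen - 1L)
      touches <- vapply(seq_len(nrow(pl)), function(i) {
        sdAbs <- jWin0 + pl$sd_start[i] + 0:5
        stAbs <- jWin0 + pl$start_pos[i] + 0:2
        any(c(sdAbs, stAbs) %in% padRange)
      }, logical(1))
      if (any(touches)) next
    }
    chosen <- pad
    break
  }
  if (is.null(chosen)) {
    constructSeq <- paste0(up, tryPads[1], body)
    bad <- .codonsOf(substr(constructSeq, s + 1L, nchar(constructSeq)))
    bad <- bad[bad %in% .STOP_CODONS]
    stop(sprintf("junction stop codon(s) cannot be padded away: %s",
                 paste(unique(bad), collapse = ",")))
  }
  constructSeq <- paste0(up, chosen, body)

  # verification (i): host protein unchanged except declared AA changes
  aaDiff <- aaEditDistance(cds@sequence, up, table)
  if (aaDiff != candidate@aaChangesMade)
    stop("host protein changed beyond the declared amino-acid edits")
  # verification (ii): new-frame translation = extension + downstream protein
  full <- .translateChars(constructSeq, s, table@code)
  downProt <- .translateChars(body, 0L, table@code)
  nExt <- nchar(full) - nchar(downProt)
  extension <- substr(full, 1L, nExt)
  if (substr(full, nExt + 1L, nchar(full)) != downProt)
    stop("new-frame translation does not end with the downstream protein")
  bodyAA <- substr(full, 1L, nchar(full) - 1L)
  if (grepl("*", bodyAA, fixed = TRUE))
    stop("new-frame translation contains an internal stop codon")

  features <- data.frame(
    feature = c("host_CDS", "overlap_CDS"),
    start = c(0L, s),
    end = c(L, nchar(constructSeq)),
    frame = c(0L, candidate@frame),
    note = c("existing gene (frame 0)",
             "created reading frame: N-terminal extension + downstream gene"),
    stringsAsFactors = FALSE)
  list(sequence = constructSeq, features = features,
       extensionProtein = extension, padLen = padLen)
}
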