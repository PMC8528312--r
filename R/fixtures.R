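# Synthetic-data generators: random valid CDSs with controllable codon
# usage, CDSs with planted translation-initiation motifs in an alternate
# frame (with the expected design answer), and Luria-Delbrueck fluctuation
# counts. These make every module testable without any downloaded data.

#' Random valid CDS
#'
#' Samples a coding sequence of the requested length: a start codon, a
#' stop-free body drawn from the sense codons according to the usage
#' weights, and a terminal stop codon.
#'
#' @param lengthCodons total length in codons (>= 3) including start and
#'   stop.
#' @param usageBias optional named numeric vector of codon weights (sense
#'   codons; missing codons get weight 0). Default: uniform over sense
#'   codons.
#' @param seed RNG seed (NULL: use the current RNG state).
#' @param id record id.
#' @param table a \linkS4class{CodonTable}.
#' @return a \linkS4class{CDSRecord}.
#' @export
randomCDS <- function(lengthCodons, usageBias = NULL, seed = NULL,
                      id = "synthetic_cds", table = .defaultTable()) {
  stopifnot(lengthCodons >= 3)
  if (!is.null(seed)) set.seed(seed)
  sense <- sort(unlist(table@synonymSets, use.names = FALSE))
  w <- rep(1, length(sense))
  if (!is.null(usageBias)) {
    w <- usageBias[sense]
    w[is.na(w)] <- 0
  }
  nBody <- lengthCodons - 2L
  body <- if (nBody > 0L) sample(sense, nBody, replace = TRUE, prob = w) else character()
  seq <- paste0("ATG", paste(body, collapse = ""), "TAA")
  CDSRecord(id, seq, description = "synthetic random CDS", source = "synthetic")
}

#' Plant a zero-edit initiation motif into a CDS
#'
#' Rewrites a CDS so that it contains, by construction, a zero-edit design
#' candidate at the stated start position and frame: the SD consensus, a
#' spacer and a start codon are written in, frame-0 stop codons accidentally
#' created are repaired using free (non-motif) nucleotides, and the new
#' frame downstream of the planted start is made stop-free. The result is
#' verified with \code{\link{designOverlaps}}.
#'
#' @param cds a \linkS4class{CDSRecord} to edit.
#' @param startNt 0-based position for the planted start codon; must be in
#'   an alternate frame and leave room for the motif and the terminal stop.
#' @param spec a \linkS4class{MotifSpec}; the consensus SD and a mid-range
#'   spacer are planted.
#' @param spacer spacer length to plant.
#' @param seed RNG seed for the repair sampling.
#' @param table a \linkS4class{CodonTable}.
#' @return list with \code{cds} (the edited record) and \code{expected}
#'   (list with startNt, frame, sdStart, spacer).
#' @export
plantMotif <- function(cds, startNt, spec = motifSpec(), spacer = 5L,
                       seed = NULL, table = .defaultTable()) {
  if (!is.null(seed)) set.seed(seed)
  s <- as.integer(startNt)
  L <- nchar(cds@sequence)
  sdLen <- nchar(spec@sdConsensus)
  if (s %% 3L == 0L) stop("planted start must be in an alternate frame")
  sdStart <- s - spacer - sdLen
  if (sdStart < 3L) stop("no room upstream for the motif")
  if (s + 3L > L - 3L) stop("no room downstream of the planted start")
  chars <- .charsOf(cds@sequence)
  motifPos <- c(sdStart:(sdStart + sdLen - 1L), s:(s + 2L)) + 1L
  chars[(sdStart + 1L):(sdStart + sdLen)] <- .charsOf(spec@sdConsensus)
  chars[(s + 1L):(s + 3L)] <- .charsOf(spec@startCodons[1])

  repair <- function(chars) {
    # frame-0 body must be stop-free; resample free nts of offending codons
    for (i in 1:(L %/% 3L - 2L)) {
      tries <- 0L
      while (.codonAt(chars, i) %in% .STOP_CODONS) {
        free <- setdiff((3L * i + 1L):(3L * i + 3L), motifPos)
        if (!length(free)) stop("infeasible plant: locked frame-0 stop codon")
        chars[free[sample.int(length(free), 1L)]] <- sample(c("A", "C", "G", "T"), 1L)
        tries <- tries + 1L
        if (tries > 100L) stop("infeasible plant: cannot repair frame-0 stop")
      }
    }
    chars
  }
  chars <- repair(chars)
  # make the planted new frame stop-free using free nucleotides
  guard <- 0L
  repeat {
    stops <- .newFrameStops(chars, s, L)
    if (!length(stops)) break
    guard <- guard + 1L
    if (guard > 500L) stop("infeasible plant: cannot clear the new frame")
    q <- stops[1]
    free <- setdiff((q + 1L):(q + 3L), motifPos)
    free <- free[free <= L - 3L]          # keep the terminal stop intact
    if (!length(free)) stop("infeasible plant: locked new-frame stop")
    chars[free[sample.int(length(free), 1L)]] <- sample(c("A", "C", "G", "T"), 1L)
    chars <- repair(chars)
  }
  out <- CDSRecord(cds@id, paste(chars, collapse = ""),
                   description = "synthetic CDS with planted motif",
                   source = "synthetic")
  cand <- designOverlaps(out, designConfig("S0", motif = spec), table)
  hit <- Filter(function(x) x@startNt == s, cand)
  if (!length(hit)) stop("verification failed: planted motif not recovered")
  list(cds = out,
       expected = list(startNt = s, frame = s %% 3L, sdStart = sdStart,
                       spacer = as.integer(spacer)))
}

#' Synthetic Luria-Delbrueck fluctuation counts
#'
#' Simulates parallel cultures by discrete doubling generations with
#' mutation at division; mutant clones founded at generation g grow to
#' 2^(G-g) cells, yielding the characteristic heavy-tailed mutant-count
#' distribution with expected mutation number \code{mTrue} per culture.
#'
#' @param mTrue expected number of mutational events per culture.
#' @param nPops number of parallel cultures.
#' @param generations number of doubling generations.
#' @param platingEfficiency probability that a mutant cell is plated and
#'   counted.
#' @param seed RNG seed.
#' @return data.frame with columns \code{population_id} and
#'   \code{mutant_count}.
#' @export
synthFluctuationCounts <- function(mTrue, nPops, generations = 20L,
                                   platingEfficiency = 1, seed = NULL) {
  stopifnot(mTrue >= 0)
  if (!is.null(seed)) set.seed(seed)
  G <- as.integer(generations)
  # divisions at generation g: 2^(g-1); mu chosen so the expected number of
  # mutations per culture over all divisions is mTrue
  divisions <- 2^(0:(G - 1L))
  mu <- mTrue / sum(divisions)
  counts <- vapply(seq_len(nPops), function(i) {
    nMut <- rbinom(G, size = divisions, prob = min(1, mu))
    cells <- sum(nMut * 2^((G - 1L):0))
    if (platingEfficiency < 1 && cells > 0)
      cells <- rbinom(1L, size = cells, prob = platingEfficiency)
    cells
  }, numeric(1))
  data.frame(population_id = seq_len(nPops), mutant_count = counts)
}
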