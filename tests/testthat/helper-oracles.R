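# Independent oracles used by the tests. These are deliberately naive
# re-derivations (loops, enumeration, root-finding) kept separate from the
# package implementations they check.

# position-by-position motif checker (naive loops, no vectorization)
oracleMotifPlacements <- function(seq, sd = "AGGAGG", maxMM = 1,
                                  spacerMin = 3, spacerMax = 7,
                                  starts = "ATG") {
  n <- nchar(seq)
  hits <- list()
  for (sdStart in 0:(n - 1)) {
    if (sdStart + nchar(sd) > n) next
    mm <- 0
    for (k in seq_len(nchar(sd)))
      if (substr(seq, sdStart + k, sdStart + k) != substr(sd, k, k))
        mm <- mm + 1
    if (mm > maxMM) next
    for (spacer in spacerMin:spacerMax) {
      sp <- sdStart + nchar(sd) + spacer
      if (sp + 3 > n) next
      if (substr(seq, sp + 1, sp + 3) %in% starts)
        hits[[length(hits) + 1]] <- c(sd_start = sdStart, spacer_len = spacer,
                                      start_pos = sp)
    }
  }
  if (!length(hits)) return(data.frame(sd_start = integer(),
                                       spacer_len = integer(),
                                       start_pos = integer()))
  as.data.frame(do.call(rbind, hits))
}

# exhaustive full-sequence synonymous design oracle for tiny CDSs: the set
# of (start_pos, frame) reachable by ANY combination of synonymous changes
# across the whole body (terminal stop kept intact), with the motif fully
# inside the CDS and the start codon fully within the body.
oracleExhaustiveDesign <- function(cds, maxVariants = 60000) {
  seqStr <- cdsSequence(cds)
  L <- nchar(seqStr)
  body <- substr(seqStr, 1, L - 3)
  nVar <- prod(vapply(orfoverlap:::.codonsOf(body),
                      function(c) {
                        tab <- orfoverlap:::.defaultTable()
                        length(tab@synonymSets[[tab@code[c]]])
                      }, numeric(1)))
  if (nVar > maxVariants) stop("fixture too degenerate for exhaustive oracle")
  variants <- synonymousVariants(body)
  found <- character()
  for (v in variants) {
    full <- paste0(v, substr(seqStr, L - 2, L))
    pl <- oracleMotifPlacements(full)
    if (!nrow(pl)) next
    keep <- pl$start_pos %% 3 != 0 & pl$start_pos + 3 <= L - 3
    for (p in pl$start_pos[keep])
      found <- union(found, paste(p, p %% 3))
  }
  found
}

# exact Mann-Whitney one-sided p by enumeration of all group assignments
oracleMWUExact <- function(x, y, alternative = "greater") {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  uOf <- function(ix) {
    xs <- pooled[ix]; ys <- pooled[-ix]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  uObs <- uOf(seq_len(n1))
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, uOf)
  if (alternative == "greater") mean(us >= uObs) else mean(us <= uObs)
}

# Lea-Coulson median equation root: r/m - ln(m) = 1.24
oracleLeaCoulson <- function(medianCount) {
  uniroot(function(m) medianCount / m - log(m) - 1.24,
          interval = c(1e-8, 1e8), tol = 1e-10)$root
}

# naive exact protection for the discrete model: explicit loop over every
# mutation position and type, probabilities written out longhand
oracleProtectionDiscrete <- function(Pe, fs, overlap, Lu, Ld) {
  num <- 0; den <- 0
  nDownAll <- Ld %/% 3
  for (x in 0:(Lu - 1)) {
    inOv <- x >= (1 - overlap) * Lu
    # frameshift
    nUp <- ceiling((Lu - x) / 3)
    pU <- 1 - (1 - Pe)^nUp
    pD <- if (inOv) 1 - (1 - Pe)^nDownAll else 0
    num <- num + fs * pU * pD / Lu
    den <- den + fs * pU / Lu
    # substitution
    pU <- Pe
    num <- num + (1 - fs) * pU * 0 / Lu
    den <- den + (1 - fs) * pU / Lu
  }
  num / den
}

# low-degeneracy random CDS (synonym-set sizes <= 3) for exhaustive oracles
lowDegeneracyCDS <- function(nBodyCodons, seed, planted = FALSE) {
  set.seed(seed)
  pool <- c("TGG", "GAT", "GAC", "TTT", "TTC", "CAT", "CAC", "AAA", "AAG",
            "GAA", "GAG", "TAT", "TAC", "TGT", "TGC", "AAT", "AAC",
            "CAA", "CAG", "ATT", "ATC", "ATA")
  body <- sample(pool, nBodyCodons, replace = TRUE)
  if (planted) {
    # AGG AGG as lysine/glutamate-compatible context is impossible; plant
    # an A/G-rich stretch instead: K E E gives AAr GAr GAr
    i <- max(2, nBodyCodons %/% 3)
    body[i:(i + 2)] <- c("AAG", "GAG", "GAG")
    if (i + 5 <= nBodyCodons) body[i + 4] <- "ATG"
  }
  seqStr <- paste0("ATG", paste(body, collapse = ""), "TAA")
  suppressWarnings(CDSRecord(sprintf("lowdeg_%d", seed), seqStr,
                             source = "synthetic"))
}
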