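# Monte-Carlo estimation of the protection conferred by an overlap: the
# fraction of loss-of-function (LOF) mutations in the costly upstream gene
# that also inactivate the overlapped downstream essential gene and are
# therefore purged by selection. A matching exact-expectation calculation
# (sum over mutation positions and types) serves as the deterministic
# counterpart of the sampler.

#' Construct protection-simulation parameters
#'
#' @param Pe average deleteriousness of one amino-acid substitution.
#' @param fs fraction of mutations that are frameshift-causing indels.
#' @param overlapFraction fraction of the upstream gene included in the
#'   overlap (its 3'-terminal part).
#' @param upstreamLenNt,downstreamLenNt coding-sequence lengths (default
#'   1 kb each).
#' @param lofModel "discrete_stochastic" (Bernoulli loss of function per
#'   amino-acid change) or "continuous_deterministic" (multiplicative
#'   activity loss, LOF below \code{lofThreshold}).
#' @param overlapMode "riboverlap": only the reading frames overlap, so a
#'   substitution never harms the downstream protein; "protein_overlap": the
#'   proteins themselves overlap and substitutions in the overlap also count
#'   against the downstream gene.
#' @param nReps Monte-Carlo replicates.
#' @param seed RNG seed.
#' @param lofThreshold activity threshold for the continuous model.
#' @return a \linkS4class{ProtectionParams}.
#' @export
protectionParams <- function(Pe, fs, overlapFraction,
                             upstreamLenNt = 1000L, downstreamLenNt = 1000L,
                             lofModel = c("discrete_stochastic",
                                          "continuous_deterministic"),
                             overlapMode = c("riboverlap", "protein_overlap"),
                             nReps = 100000L, seed = 1L, lofThreshold = 0.5) {
  new("ProtectionParams", Pe = Pe, fs = fs, overlapFraction = overlapFraction,
      upstreamLenNt = as.integer(upstreamLenNt),
      downstreamLenNt = as.integer(downstreamLenNt),
      lofModel = match.arg(lofModel), overlapMode = match.arg(overlapMode),
      nReps = as.integer(nReps), seed = as.integer(seed),
      lofThreshold = lofThreshold)
}

#' Draw random mutations in the upstream gene
#'
#' Each mutation is a frameshift with probability \code{fs}, otherwise a
#' base-pair substitution; its position is uniform over the upstream gene.
#'
#' @param params a \linkS4class{ProtectionParams}.
#' @param n number of mutations to draw.
#' @return data.frame with columns \code{type} and \code{position} (0-based).
#' @export
drawMutation <- function(params, n = 1L) {
  data.frame(
    type = ifelse(runif(n) < params@fs, "frameshift", "substitution"),
    position = sample.int(params@upstreamLenNt, n, replace = TRUE) - 1L,
    stringsAsFactors = FALSE)
}

#' Bernoulli loss-of-function draw under the discrete model
#'
#' A protein carrying \code{n} amino-acid changes is non-functional with
#' probability \eqn{1 - (1 - Pe)^n}.
#'
#' @param nChanges integer vector of amino-acid change counts.
#' @param Pe per-change deleteriousness.
#' @return logical vector of LOF outcomes.
#' @export
lofDiscrete <- function(nChanges, Pe) {
  runif(length(nChanges)) < 1 - (1 - Pe)^nChanges
}

#' Activity impact under the continuous model
#'
#' \eqn{I(n) = 1 - (1 - Pe)^n}: each amino-acid change degrades activity by
#' a multiplicative factor (1 - Pe).
#'
#' @param nChanges integer vector of amino-acid change counts.
#' @param Pe per-change deleteriousness.
#' @return numeric impact in [0, 1].
#' @export
impactContinuous <- function(nChanges, Pe) {
  1 - (1 - Pe)^nChanges
}

# amino-acid change counts implied by one mutation for both genes
.mutationEffects <- function(params, type, x) {
  Lu <- params@upstreamLenNt
  Ld <- params@downstreamLenNt
  fsMask <- type == "frameshift"
  nUp <- ifelse(fsMask, ceiling((Lu - x) / 3), 1L)
  inOverlap <- x >= (1 - params@overlapFraction) * Lu
  nDown <- integer(length(x))
  nDown[fsMask & inOverlap] <- Ld %/% 3L
  if (params@overlapMode == "protein_overlap")
    nDown[!fsMask & inOverlap] <- 1L
  list(nUp = as.integer(nUp), nDown = nDown)
}

#' Monte-Carlo protection of an overlap
#'
#' For each replicate one mutation is drawn in the upstream gene. A
#' frameshift at position x scrambles all upstream codons downstream of x
#' and, if x lies in the overlap region, shifts the downstream gene's whole
#' frame (all its codons change). A substitution changes one upstream amino
#' acid; in protein-overlap mode a substitution inside the overlap also
#' changes one downstream amino acid, in riboverlap mode it never touches
#' the downstream protein. Loss of function of each gene follows the
#' configured model; the protection is the fraction of upstream-LOF
#' replicates in which the downstream gene is also lost.
#'
#' @param params a \linkS4class{ProtectionParams}.
#' @return a \linkS4class{ProtectionResult}; \code{protection} is \code{NA}
#'   when no replicate lost the upstream gene.
#' @examples
#' p <- protectionParams(Pe = 0.1, fs = 0.7, overlapFraction = 1,
#'                       nReps = 10000, seed = 7)
#' simulateProtection(p)
#' @export
simulateProtection <- function(params) {
  set.seed(params@seed)
  n <- params@nReps
  mut <- drawMutation(params, n)
  eff <- .mutationEffects(params, mut$type, mut$position)
  if (params@lofModel == "discrete_stochastic") {
    lofUp <- lofDiscrete(eff$nUp, params@Pe)
    lofDown <- lofDiscrete(eff$nDown, params@Pe)
  } else {
    lofUp <- (1 - impactContinuous(eff$nUp, params@Pe)) < params@lofThreshold
    lofDown <- (1 - impactContinuous(eff$nDown, params@Pe)) < params@lofThreshold
  }
  nLof <- sum(lofUp)
  nPurged <- sum(lofUp & lofDown)
  if (nLof == 0L) {
    prot <- NA_real_
    ci <- c(NA_real_, NA_real_)
  } else {
    prot <- nPurged / nLof
    se <- sqrt(prot * (1 - prot) / nLof)
    ci <- c(max(0, prot - 1.96 * se), min(1, prot + 1.96 * se))
  }
  new("ProtectionResult", protection = prot, ci95 = ci,
      nUpstreamLof = as.integer(nLof), nPurged = as.integer(nPurged),
      params = params)
}

#' Exact-expectation protection
#'
#' Closed-form counterpart of \code{\link{simulateProtection}}: the
#' protection is the ratio of sums over mutation positions and types of the
#' per-replicate LOF probabilities under the same effect rules. For the
#' continuous model either the LOF-threshold ratio or the normalized
#' dot-product of the impacts on the two genes can be requested.
#'
#' @param params a \linkS4class{ProtectionParams} (\code{nReps}/\code{seed}
#'   ignored).
#' @param continuousMetric for the continuous model: "threshold" (ratio of
#'   LOF indicator expectations) or "dot" (mean of the product of impacts,
#'   normalized by the mean upstream impact).
#' @return protection as a single number.
#' @export
protectionExact <- function(params, continuousMetric = c("threshold", "dot")) {
  continuousMetric <- match.arg(continuousMetric)
  Lu <- params@upstreamLenNt
  x <- 0:(Lu - 1L)
  effFs <- .mutationEffects(params, rep("frameshift", Lu), x)
  effSub <- .mutationEffects(params, rep("substitution", Lu), x)
  if (params@lofModel == "discrete_stochastic") {
    pU_fs <- 1 - (1 - params@Pe)^effFs$nUp
    pD_fs <- 1 - (1 - params@Pe)^effFs$nDown
    pU_sub <- 1 - (1 - params@Pe)^effSub$nUp
    pD_sub <- 1 - (1 - params@Pe)^effSub$nDown
    num <- mean(params@fs * pU_fs * pD_fs + (1 - params@fs) * pU_sub * pD_sub)
    den <- mean(params@fs * pU_fs + (1 - params@fs) * pU_sub)
    return(num / den)
  }
  iU_fs <- impactContinuous(effFs$nUp, params@Pe)
  iD_fs <- impactContinuous(effFs$nDown, params@Pe)
  iU_sub <- impactContinuous(effSub$nUp, params@Pe)
  iD_sub <- impactContinuous(effSub$nDown, params@Pe)
  if (continuousMetric == "threshold") {
    thr <- params@lofThreshold
    lU_fs <- (1 - iU_fs) < thr; lD_fs <- (1 - iD_fs) < thr
    lU_sub <- (1 - iU_sub) < thr; lD_sub <- (1 - iD_sub) < thr
    num <- mean(params@fs * lU_fs * lD_fs + (1 - params@fs) * lU_sub * lD_sub)
    den <- mean(params@fs * lU_fs + (1 - params@fs) * lU_sub)
    return(num / den)
  }
  num <- mean(params@fs * iU_fs * iD_fs + (1 - params@fs) * iU_sub * iD_sub)
  den <- mean(params@fs * iU_fs + (1 - params@fs) * iU_sub)
  num / den
}

#' Protection over a parameter grid
#'
#' One \code{\link{simulateProtection}} run per combination of the supplied
#' parameter values; deterministic given the seed (each combination uses a
#' distinct seed derived from \code{seed}).
#'
#' @param PeValues,fsValues,overlapValues numeric vectors.
#' @param modes,models character vectors of overlap modes / LOF models.
#' @param nReps replicates per combination.
#' @param seed base seed.
#' @param upstreamLenNt,downstreamLenNt gene lengths.
#' @return data.frame, one row per combination, with the protection, its
#'   95\% CI and the exact-expectation value.
#' @export
protectionGrid <- function(PeValues = c(0.1, 0.3, 0.5),
                           fsValues = c(0.1, 0.3, 0.7),
                           overlapValues = seq(0, 1, by = 0.1),
                           modes = "riboverlap",
                           models = "discrete_stochastic",
                           nReps = 10000L, seed = 1L,
                           upstreamLenNt = 1000L, downstreamLenNt = 1000L) {
  grid <- expand.grid(pe = PeValues, fs = fsValues, overlap_fraction = overlapValues,
                      mode = modes, model = models,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    p <- protectionParams(g$pe, g$fs, g$overlap_fraction,
                          upstreamLenNt, downstreamLenNt,
                          lofModel = g$model, overlapMode = g$mode,
                          nReps = nReps, seed = (seed + i) %% .Machine$integer.max)
    r <- simulateProtection(p)
    data.frame(g, protection = r@protection,
               ci_lo = r@ci95[1], ci_hi = r@ci95[2],
               exact = protectionExact(p),
               n_lof = r@nUpstreamLof, n_reps = nReps,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

setMethod("show", "ProtectionResult", function(object) {
  p <- object@params
  cat(sprintf(
    "ProtectionResult: %.4f [%.4f, %.4f] (Pe=%.2g, fs=%.2g, overlap=%.2g, %s, %s)\n",
    object@protection, object@ci95[1], object@ci95[2], p@Pe, p@fs,
    p@overlapFraction, p@lofModel, p@overlapMode))
  cat(sprintf("  %d / %d upstream-LOF replicates purged (of %d reps)\n",
              object@nPurged, object@nUpstreamLof, p@nReps))
})
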