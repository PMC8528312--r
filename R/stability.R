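# Analytic circuit-lifetime model: mutation supply is Poisson with rate
# mu * N per generation, so the waiting time to the first selectable
# loss-of-function mutation is exponential and the median lifetime is
# ln(2) / (mu * N). An overlap scales mu by (1 - protection).

#' Poisson probability of m mutational events in dt generations
#'
#' @param m number of events.
#' @param muEff per-genome-per-generation rate of selectable
#'   loss-of-function mutations.
#' @param N constant population size.
#' @param dt number of (synchronous-equivalent) generations.
#' @return \eqn{e^{-\mu N \Delta t} (\mu N \Delta t)^m / m!}.
#' @export
poissonPmf <- function(m, muEff, N, dt) {
  dpois(m, lambda = muEff * N * dt)
}

#' Median circuit lifetime in generations
#'
#' The first selectable mutation arrives after an exponential waiting time
#' with rate mu*N; its median is ln(2)/(mu*N).
#'
#' @param muEff effective mutation rate (already scaled by any protection).
#' @param N population size.
#' @return median lifetime in generations (Inf when muEff is 0).
#' @export
medianLifetime <- function(muEff, N) {
  ifelse(muEff * N == 0, Inf, log(2) / (muEff * N))
}

#' Multiplicative lifetime gain from a protection fraction
#'
#' A protection p scales the selectable mutation rate by (1 - p) and hence
#' multiplies the median lifetime by 1 / (1 - p).
#'
#' @param protection fraction of loss-of-function mutations purged.
#' @return fold change of the median lifetime (Inf at protection 1).
#' @export
lifetimeFoldChange <- function(protection) {
  ifelse(protection >= 1, Inf, 1 / (1 - protection))
}

#' Survival probability of a multi-gene circuit
#'
#' The circuit is functional while none of its n genes has acquired a
#' selectable loss-of-function mutation:
#' \eqn{p(t) = e^{-N t \sum_i \mu_i (1 - p_i)}}.
#'
#' @param t generations (vectorized).
#' @param N population size.
#' @param mus per-gene loss-of-function mutation rates.
#' @param protections optional per-gene protection fractions (default 0).
#' @return survival probability.
#' @export
circuitSurvival <- function(t, N, mus, protections = NULL) {
  if (is.null(protections)) protections <- rep(0, length(mus))
  stopifnot(length(protections) == length(mus))
  exp(-N * t * sum(mus * (1 - protections)))
}

#' Empirical multi-gene lifetime simulation
#'
#' Samples circuits of n genes from a pool of (gene length, best achievable
#' overlap fraction) pairs and compares the median circuit lifetime with and
#' without per-gene overlaps. Per-gene protections come from the
#' exact-expectation protection model at each gene's best overlap fraction.
#'
#' @param pool data.frame with columns \code{length_nt} and
#'   \code{overlap_fraction}.
#' @param nGenes genes per circuit.
#' @param reps number of sampled circuits.
#' @param Pe,fs protection-model parameters for the per-gene protections.
#' @param muPerBp loss-of-function mutation rate per base pair per
#'   generation.
#' @param N population size.
#' @param seed RNG seed.
#' @return list with \code{medianWith}, \code{medianWithout} (generations)
#'   and \code{relativeIncrease} (medianWith / medianWithout - 1).
#' @export
multiGeneLifetimeSim <- function(pool, nGenes, reps = 1000L, Pe = 0.1,
                                 fs = 0.3, muPerBp = 1e-10, N = 1e6,
                                 seed = 1L) {
  stopifnot(nrow(pool) >= 1L, nGenes >= 1L)
  set.seed(seed)
  fracs <- sort(unique(pool$overlap_fraction))
  protAt <- vapply(fracs, function(f) {
    if (f <= 0) return(0)
    protectionExact(protectionParams(Pe, fs, f, nReps = 1L))
  }, numeric(1))
  names(protAt) <- as.character(fracs)
  lifeWith <- numeric(reps)
  lifeWithout <- numeric(reps)
  for (r in seq_len(reps)) {
    idx <- sample.int(nrow(pool), nGenes, replace = TRUE)
    mus <- muPerBp * pool$length_nt[idx]
    prot <- protAt[as.character(pool$overlap_fraction[idx])]
    lifeWithout[r] <- medianLifetime(sum(mus), N)
    lifeWith[r] <- medianLifetime(sum(mus * (1 - prot)), N)
  }
  mw <- median(lifeWith); mwo <- median(lifeWithout)
  list(medianWith = mw, medianWithout = mwo,
       relativeIncrease = mw / mwo - 1)
}

#' Median-lifetime table over a (mu, N) grid
#'
#' Tidy table of the analytic median lifetime for each rate/population-size
#' combination, with and without a protection applied.
#'
#' @param muValues,NValues numeric grids.
#' @param protection protection fraction applied in the protected column.
#' @return data.frame with columns mu, N, lifetime, lifetime_protected.
#' @export
lifetimeGrid <- function(muValues, NValues, protection = 0) {
  grid <- expand.grid(mu = muValues, N = NValues, KEEP.OUT.ATTRS = FALSE)
  grid$lifetime <- medianLifetime(grid$mu, grid$N)
  grid$lifetime_protected <- medianLifetime(grid$mu * (1 - protection), grid$N)
  grid
}
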