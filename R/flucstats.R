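# Fluctuation-assay statistics: per-population escape fractions, one-sided
# Mann-Whitney U with rank-biserial effect size, and the Jones median
# estimator of the expected number of mutational events per culture.

#' Per-population escape fractions from colony counts
#'
#' For each population, the fraction of costly-gene loss-of-function mutants
#' (colonies on the counter-selective plate) that retained the essential
#' gene (colonies on the doubly selective plate), after dilution correction.
#' Populations with zero colonies on the counter-selective plate are
#' excluded with a warning; fractions above 1 are kept but flagged.
#'
#' @param counts data.frame with columns \code{population_id}, \code{group},
#'   \code{dog_count}, \code{dog_dilution}, \code{dogkan_count},
#'   \code{dogkan_dilution} (dilution = multiplicative plating factor; equal
#'   factors cancel). Extra columns (e.g. \code{strain}) are carried along.
#' @return the input with added columns \code{escape_fraction} and
#'   \code{flagged_gt1}, excluded rows dropped.
#' @examples
#' d <- data.frame(population_id = 1:2, group = "overlap",
#'                 dog_count = c(100, 80), dog_dilution = 1,
#'                 dogkan_count = c(25, 0), dogkan_dilution = 1)
#' escapeFraction(d)$escape_fraction  # 0.25, 0
#' @export
escapeFraction <- function(counts) {
  stopifnot(all(c("dog_count", "dogkan_count") %in% names(counts)))
  if (is.null(counts$dog_dilution)) counts$dog_dilution <- 1
  if (is.null(counts$dogkan_dilution)) counts$dogkan_dilution <- 1
  if (any(counts$dog_count < 0 | counts$dogkan_count < 0))
    stop("colony counts must be non-negative")
  zero <- counts$dog_count == 0
  if (any(zero)) {
    warning(sprintf("%d population(s) with zero counter-selective colonies excluded",
                    sum(zero)))
    counts <- counts[!zero, , drop = FALSE]
  }
  fr <- (counts$dogkan_count * counts$dogkan_dilution) /
    (counts$dog_count * counts$dog_dilution)
  counts$escape_fraction <- pmax(fr, 0)
  counts$flagged_gt1 <- fr > 1
  counts
}

#' Rank-biserial correlation from a Mann-Whitney U statistic
#'
#' \eqn{r = 1 - 2U/(n_1 n_2)}.
#'
#' @param U the Mann-Whitney U statistic (number of (x, y) pairs with
#'   x > y, ties counted 1/2).
#' @param n1,n2 group sizes.
#' @return r in [-1, 1].
#' @examples
#' rankBiserial(95, 11, 12)
#' @export
rankBiserial <- function(U, n1, n2) {
  if (n1 * n2 == 0) stop("both groups must be non-empty")
  1 - 2 * U / (n1 * n2)
}

#' One-sided Mann-Whitney U test with rank-biserial effect size
#'
#' U is the number of (x, y) pairs with x > y (ties 1/2), i.e. the statistic
#' of \code{stats::wilcox.test(x, y)}. The p-value is exact (by enumeration)
#' when both samples are small and tie-free, with the normal approximation
#' and tie correction otherwise — the behaviour of
#' \code{stats::wilcox.test}, which backs this function.
#'
#' @param x,y numeric samples (x = reference group, y = comparison group).
#' @param alternative direction passed to \code{wilcox.test}; the default
#'   "greater" tests whether x tends to exceed y.
#' @return list with \code{U}, \code{pOneSided}, \code{n1}, \code{n2},
#'   \code{rRankBiserial}.
#' @export
mannWhitneyOneSided <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) > 0, length(y) > 0)
  if (length(unique(c(x, y))) == 1L) {
    warning("all observations tied; test uninformative")
    U <- length(x) * length(y) / 2
    return(list(U = U, pOneSided = 0.5, n1 = length(x), n2 = length(y),
                rRankBiserial = 0))
  }
  wt <- suppressWarnings(wilcox.test(x, y, alternative = alternative,
                                     exact = NULL, correct = TRUE))
  U <- unname(wt$statistic)
  list(U = U, pOneSided = unname(wt$p.value),
       n1 = length(x), n2 = length(y),
       rRankBiserial = rankBiserial(U, length(x), length(y)))
}

#' Jones median estimator of the expected mutation number
#'
#' Median-based Luria-Delbrueck estimator of the expected number m of
#' mutational events per culture from per-population mutant counts:
#' \eqn{m = (\tilde r - 0.693) / (\ln \tilde r + 0.3665)} where
#' \eqn{\tilde r} is the sample median. When the median is 0 the P0 method
#' \eqn{m = -\ln(\mathrm{fraction\ of\ zero\ cultures})} is used, so m = 0
#' when every count is 0.
#'
#' @param mutantCounts integer vector of per-culture mutant counts.
#' @return estimated expected number of mutations per culture.
#' @export
jonesEstimator <- function(mutantCounts) {
  if (any(mutantCounts < 0)) stop("mutant counts must be non-negative")
  if (!length(mutantCounts)) stop("empty counts")
  med <- median(mutantCounts)
  if (med <= 0) return(-log(mean(mutantCounts == 0)))
  (med - 0.693) / (log(med) + 0.3665)
}

#' Summary of avoided mutations between two groups
#'
#' Reports 1 - summary(escape fractions of the overlap group) /
#' summary(escape fractions of the control group) for both the median and
#' the mean.
#'
#' @param overlapFractions,controlFractions per-population escape fractions.
#' @return list with \code{avoidedMedian} and \code{avoidedMean}.
#' @export
avoidedMutations <- function(overlapFractions, controlFractions) {
  list(avoidedMedian = 1 - median(overlapFractions) / median(controlFractions),
       avoidedMean = 1 - mean(overlapFractions) / mean(controlFractions))
}
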