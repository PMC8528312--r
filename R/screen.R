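# Batch application of the designer with the summary statistics used for
# genome-scale screens: earliest creatable overlap per gene per stringency,
# cumulative distributions of the earliest position, and per-group means
# with 95% confidence intervals.

#' Screen a set of CDSs for creatable overlapping reading frames
#'
#' Runs the designer on every valid record at each requested stringency and
#' reports, per gene and stringency, the earliest candidate start and the
#' best (largest) achievable overlap fraction. Invalid CDSs are skipped and
#' counted.
#'
#' @param records list of \linkS4class{CDSRecord}.
#' @param stringencies character vector among "S0", "S1", "S2plus".
#' @param config base \linkS4class{DesignConfig}; its stringency slot is
#'   replaced per level.
#' @param mapping optional data.frame (id, label) attaching a group label
#'   (e.g. species or functional category) to each gene.
#' @param table a \linkS4class{CodonTable}.
#' @return data.frame with one row per valid CDS: \code{cds_id},
#'   \code{length_nt}, then per stringency \code{earliest_start_<S>} (NA if
#'   no candidate) and \code{best_overlap_<S>} (0 if none), plus
#'   \code{label} when a mapping is given. The number of skipped records is
#'   attached as attribute \code{"skipped"}.
#' @export
screenGenes <- function(records, stringencies = c("S0", "S1", "S2plus"),
                        config = designConfig(), mapping = NULL,
                        table = .defaultTable()) {
  skipped <- 0L
  rows <- list()
  for (rec in records) {
    ok <- tryCatch({ validObject(rec); TRUE },
                   error = function(e) FALSE)
    if (!ok) { skipped <- skipped + 1L; next }
    row <- list(cds_id = rec@id, length_nt = nchar(rec@sequence))
    for (st in stringencies) {
      cfg <- config; cfg@stringency <- st
      cands <- designOverlaps(rec, cfg, table)
      if (length(cands)) {
        starts <- vapply(cands, function(x) x@startNt, integer(1))
        row[[paste0("earliest_start_", st)]] <- min(starts)
        row[[paste0("best_overlap_", st)]] <-
          max(vapply(cands, function(x) x@overlapFraction, numeric(1)))
      } else {
        row[[paste0("earliest_start_", st)]] <- NA_integer_
        row[[paste0("best_overlap_", st)]] <- 0
      }
    }
    rows[[length(rows) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    cols <- c("cds_id", "length_nt",
              paste0("earliest_start_", rep(stringencies, each = 0L)))
    df <- data.frame(cds_id = character(), length_nt = integer(),
                     stringsAsFactors = FALSE)
    for (st in stringencies) {
      df[[paste0("earliest_start_", st)]] <- integer()
      df[[paste0("best_overlap_", st)]] <- numeric()
    }
    df
  }
  if (!is.null(mapping) && nrow(out))
    out$label <- mapping$label[match(out$cds_id, mapping$id)]
  attr(out, "skipped") <- skipped
  out
}

#' Cumulative distribution of the earliest candidate position
#'
#' Step function over relative position in [0, 1]: the fraction of genes
#' whose earliest candidate lies at or before that relative position. Genes
#' without a candidate contribute to no step and are reported separately.
#'
#' @param rows output of \code{\link{screenGenes}}.
#' @param stringency which stringency column to use.
#' @return data.frame (relative_position, cumulative_fraction), with the
#'   no-candidate fraction attached as attribute \code{"no_candidate"}.
#' @export
cumulativePositionDistribution <- function(rows, stringency = "S1") {
  col <- paste0("earliest_start_", stringency)
  stopifnot(col %in% names(rows), nrow(rows) > 0)
  rel <- rows[[col]] / rows$length_nt
  n <- nrow(rows)
  noCand <- mean(is.na(rel))
  rel <- sort(rel[!is.na(rel)])
  out <- if (length(rel))
    data.frame(relative_position = unique(rel),
               cumulative_fraction = vapply(unique(rel),
                                            function(p) sum(rel <= p) / n,
                                            numeric(1)))
  else data.frame(relative_position = numeric(), cumulative_fraction = numeric())
  attr(out, "no_candidate") <- noCand
  out
}

#' Per-group mean best overlap fraction with 95% confidence interval
#'
#' t-interval for groups smaller than 30, normal approximation otherwise;
#' single-member groups get a degenerate, flagged interval.
#'
#' @param rows output of \code{\link{screenGenes}} with a \code{label}
#'   column (or the column named by \code{groupKey}).
#' @param stringency which best-overlap column to summarize.
#' @param groupKey grouping column name.
#' @return data.frame (label, n, mean, ci_lo, ci_hi, degenerate).
#' @export
groupSummary <- function(rows, stringency = "S1", groupKey = "label") {
  col <- paste0("best_overlap_", stringency)
  stopifnot(col %in% names(rows), groupKey %in% names(rows))
  groups <- split(rows[[col]], rows[[groupKey]])
  out <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]
    n <- length(v); m <- mean(v)
    if (n == 1L)
      return(data.frame(label = g, n = n, mean = m, ci_lo = m, ci_hi = m,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    se <- sd(v) / sqrt(n)
    q <- if (n < 30) qt(0.975, n - 1) else qnorm(0.975)
    data.frame(label = g, n = n, mean = m, ci_lo = m - q * se,
               ci_hi = m + q * se, degenerate = FALSE,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
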