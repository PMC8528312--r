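screenFixture <- function() {
  recs <- list()
  planted <- list()
  for (i in 1:6) {
    base <- randomCDS(30, seed = 40 + i, id = sprintf("gene%02d", i))
    if (i <= 3) {
      s <- c(31L, 43L, 61L)[i]
      pl <- plantMotif(base, s, seed = 40 + i)
      pl$cds@id <- base@id
      recs[[i]] <- pl$cds
      planted[[base@id]] <- s
    } else recs[[i]] <- base
  }
  list(records = recs, planted = planted)
}

test_that("empty input yields an empty, well-formed report", {
  out <- screenGenes(list())
  expect_identical(nrow(out), 0L)
  expect_true(all(c("cds_id", "length_nt") %in% names(out)))
  expect_identical(attr(out, "skipped"), 0L)
})

test_that("planted fixture genes report their earliest candidate positions", {
  fx <- screenFixture()
  out <- screenGenes(fx$records, stringencies = c("S0", "S1"))
  expect_identical(nrow(out), 6L)
  for (id in names(fx$planted)) {
    row <- out[out$cds_id == id, ]
    expect_lte(row$earliest_start_S0, fx$planted[[id]])
  }
  # stringency monotonicity per gene, and for detection fractions
  expect_true(all(out$best_overlap_S0 <= out$best_overlap_S1))
  expect_gte(mean(!is.na(out$earliest_start_S1)),
             mean(!is.na(out$earliest_start_S0)))
})

test_that("invalid records are skipped and counted", {
  bad <- new("CDSRecord", id = "ok", sequence = "ATGAAATAA",
             description = "", source = "")
  bad@sequence <- "ATGTAATAA"   # internal stop smuggled past the constructor
  recs <- list(randomCDS(20, seed = 1, id = "good"), bad)
  out <- screenGenes(recs, stringencies = "S0")
  expect_identical(nrow(out), 1L)
  expect_identical(attr(out, "skipped"), 1L)
})

test_that("cumulative position distribution matches hand enumeration", {
  rows <- data.frame(
    cds_id = sprintf("g%d", 1:10),
    length_nt = rep(100L, 10),
    earliest_start_S1 = c(0L, 10L, 10L, 25L, 50L, 75L, NA, NA, 90L, 5L),
    best_overlap_S1 = runif(10))
  cd <- cumulativePositionDistribution(rows, "S1")
  expect_equal(attr(cd, "no_candidate"), 0.2)
  expect_true(all(diff(cd$cumulative_fraction) > 0))
  expect_equal(max(cd$cumulative_fraction), 0.8)
  expect_equal(cd$cumulative_fraction[cd$relative_position == 0.10], 0.4)
  # all candidates at position 0 step immediately to the candidate fraction
  rows2 <- data.frame(cds_id = c("a", "b"), length_nt = c(30L, 30L),
                      earliest_start_S1 = c(0L, 0L),
                      best_overlap_S1 = c(1, 1))
  cd2 <- cumulativePositionDistribution(rows2, "S1")
  expect_identical(cd2$relative_position, 0)
  expect_identical(cd2$cumulative_fraction, 1)
  # no candidates at all
  rows3 <- data.frame(cds_id = "a", length_nt = 30L,
                      earliest_start_S1 = NA_integer_, best_overlap_S1 = 0)
  cd3 <- cumulativePositionDistribution(rows3, "S1")
  expect_identical(nrow(cd3), 0L)
  expect_equal(attr(cd3, "no_candidate"), 1)
})

test_that("group summaries reproduce the closed-form t-interval", {
  rows <- data.frame(
    cds_id = sprintf("g%d", 1:7),
    length_nt = 300L,
    best_overlap_S1 = c(0.2, 0.4, 0.6, 0.5, 0.5, 0.5, 0.9),
    label = c("A", "A", "A", "B", "B", "B", "C"))
  gs <- groupSummary(rows, "S1")
  a <- c(0.2, 0.4, 0.6)
  expect_equal(gs$mean[gs$label == "A"], mean(a))
  expect_equal(gs$ci_hi[gs$label == "A"],
               mean(a) + qt(0.975, 2) * sd(a) / sqrt(3))
  # all-equal group: zero-width interval
  expect_equal(gs$ci_lo[gs$label == "B"], 0.5)
  expect_equal(gs$ci_hi[gs$label == "B"], 0.5)
  # singleton: degenerate and flagged
  expect_true(gs$degenerate[gs$label == "C"])
})

test_that("screening output is stable across repeated runs", {
  fx <- screenFixture()
  a <- screenGenes(fx$records, stringencies = "S1")
  b <- screenGenes(fx$records, stringencies = "S1")
  expect_identical(a, b)
})
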