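test_that("random CDSs are valid, seeded and reproducible", {
  expect_identical(cdsSequence(randomCDS(3, seed = 1)),
                   cdsSequence(randomCDS(3, seed = 1)))
  expect_identical(substr(cdsSequence(randomCDS(3, seed = 2)), 1, 3), "ATG")
  expect_identical(nchar(cdsSequence(randomCDS(3, seed = 2))), 9L)
  for (seed in 1:200) {
    cds <- randomCDS(sample(3:60, 1), seed = seed)
    expect_true(validObject(cds))
  }
})

test_that("codon-usage bias shapes the sampled body", {
  bias <- c(AAA = 1)   # lysine AAA only
  cds <- randomCDS(30, usageBias = bias, seed = 5)
  body <- substr(cdsSequence(cds), 4, 30 * 3 - 3)
  expect_true(all(orfoverlap:::.codonsOf(body) == "AAA"))
})

test_that("planted motifs are recovered by the designer at the planted site", {
  for (seed in c(1, 7, 19)) {
    base <- randomCDS(40, seed = seed)
    s <- 3L * 20L + 1L   # relative position ~0.5, frame +1
    pl <- plantMotif(base, s, seed = seed)
    expect_identical(pl$expected$startNt, s)
    cand <- designOverlaps(pl$cds, designConfig("S0"))
    starts <- vapply(cand, function(x) x@startNt, integer(1))
    expect_true(s %in% starts)
    x <- cand[[which(starts == s)[1]]]
    expect_equal(x@overlapFraction, (cdsLength(pl$cds) - s) / cdsLength(pl$cds))
  }
})

test_that("corrupting the planted SD below tolerance hides the site", {
  base <- randomCDS(40, seed = 3)
  s <- 61
  pl <- plantMotif(base, s, seed = 3)
  seqStr <- cdsSequence(pl$cds)
  sd0 <- pl$expected$sdStart
  # introduce 2 mismatches into the SD hexamer without creating stops
  chars <- strsplit(seqStr, "")[[1]]
  chars[sd0 + 1] <- "T"; chars[sd0 + 4] <- "C"
  corrupted <- try(suppressWarnings(
    CDSRecord("corrupted", paste(chars, collapse = ""))), silent = TRUE)
  if (!inherits(corrupted, "try-error")) {
    # the zero-edit placement is gone; the site may only return via recoding
    pl2 <- matchMotif(substr(cdsSequence(corrupted), sd0 + 1, s + 3),
                      motifSpec())
    expect_false(any(pl2$start_pos + sd0 == s))
  }
})

test_that("planting at the last codon is impossible", {
  base <- randomCDS(40, seed = 9)
  expect_error(plantMotif(base, cdsLength(base) - 2), "frame|room")
})

test_that("fluctuation counts are heavy-tailed with the expected mutation load", {
  d0 <- synthFluctuationCounts(0, 30, seed = 1)
  expect_true(all(d0$mutant_count == 0))
  d <- synthFluctuationCounts(5, 400, seed = 2)
  expect_identical(nrow(d), 400L)
  # heavy tail: max/median far above a Poisson with the same mean
  set.seed(3)
  pois <- rpois(400, mean(d$mutant_count))
  expect_gt(max(d$mutant_count) / max(1, median(d$mutant_count)),
            max(pois) / max(1, median(pois)))
  expect_identical(synthFluctuationCounts(5, 20, seed = 4)$mutant_count,
                   synthFluctuationCounts(5, 20, seed = 4)$mutant_count)
})

test_that("the Jones estimator recovers the planted mutation number", {
  ests <- vapply(1:30, function(i) {
    d <- synthFluctuationCounts(5, 100, seed = 1000 + i)
    jonesEstimator(d$mutant_count)
  }, numeric(1))
  expect_lt(abs(median(ests) - 5) / 5, 0.30)
})
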