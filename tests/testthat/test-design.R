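toyCds <- function() CDSRecord("toy", "ATGAGGAGGCATCATCATGCATAA")

test_that("a pre-planted motif yields a zero-edit candidate with the right geometry", {
  cand <- designOverlaps(toyCds(), designConfig("S0"))
  starts <- vapply(cand, function(x) x@startNt, integer(1))
  expect_true(16L %in% starts)
  c16 <- cand[[which(starts == 16L)[1]]]
  expect_identical(c16@frame, 1L)
  expect_identical(nrow(c16@edits), 0L)
  expect_equal(c16@overlapFraction, (24 - 16) / 24)
  expect_identical(c16@sdMismatches, 0L)
  expect_identical(c16@spacerLen, 7L)
  expect_true(c16@flags[["frame_stop_free"]])
})

test_that("stringency-0 candidates never change the encoded protein", {
  for (seed in 1:40) {
    cds <- randomCDS(sample(15:45, 1), seed = seed)
    for (x in designOverlaps(cds, designConfig("S0"))) {
      expect_identical(translateFrame(x@editedSequence, 0),
                       translateFrame(cdsSequence(cds), 0))
      expect_identical(x@aaChangesMade, 0L)
      expect_identical(x@aaChangesRemaining, 0L)
      expect_true(all(x@edits$synonymous))
    }
  }
})

test_that("edited sequences differ from the original exactly at the listed edits", {
  for (seed in c(3, 9, 21)) {
    cds <- randomCDS(40, seed = seed)
    for (cfg in list(designConfig("S0"), designConfig("S1"))) {
      for (x in designOverlaps(cds, cfg)) {
        a <- strsplit(cdsSequence(cds), "")[[1]]
        b <- strsplit(x@editedSequence, "")[[1]]
        expect_identical(which(a != b) - 1L, x@edits$position)
        expect_identical(a[x@edits$position + 1L], x@edits$ref)
        expect_identical(b[x@edits$position + 1L], x@edits$alt)
      }
    }
  }
})

test_that("candidate start codons are out of frame and frames are stop-free", {
  for (seed in 11:25) {
    cds <- randomCDS(30, seed = seed)
    for (x in designOverlaps(cds, designConfig("S1"))) {
      expect_true(x@startNt %% 3L == x@frame && x@frame %in% c(1L, 2L))
      if (x@flags[["frame_stop_free"]]) {
        aa <- translateFrame(x@editedSequence, x@startNt)
        expect_false(grepl("*", aa, fixed = TRUE))
        expect_identical(substr(aa, 1, 1), "M")
      }
    }
  }
})

test_that("windowed search agrees with the exhaustive full-sequence oracle", {
  # CDSs of <= 12 codons built from low-degeneracy codons so that ALL
  # full-sequence synonymous variants can be enumerated
  nChecked <- 0
  for (seed in 1:30) {
    cds <- lowDegeneracyCDS(sample(6:10, 1), seed = seed,
                            planted = seed %% 3 == 0)
    want <- tryCatch(oracleExhaustiveDesign(cds), error = function(e) NULL)
    if (is.null(want)) next
    nChecked <- nChecked + 1
    got <- findMotifSites(cds, designConfig("S0"))
    gotKeys <- vapply(got, function(x) paste(x$startNt, x$frame), "")
    expect_setequal(gotKeys, want)
  }
  expect_gte(nChecked, 20)
})

test_that("stop codons in the new frame are removed with minimal synonymous edits", {
  # SD from AAG GAG G at nt 4-9, spacer 3, ATG at nt 13 (frame +1); the new
  # frame reads TAA at nt 19 over host codons TTA (Leu) + AAA (Lys). The
  # exhaustive fix set for the Leu codon is {CTT, CTC} (TTG/CTA/CTG
  # re-create a stop); both cost 2 nucleotide edits and the lexicographic
  # tie-break selects CTC
  seqStr <- paste0("ATG", "AAG", "GAG", "GAT", "TAT", "GTT",
                   "TTA", "AAA", "CAT", "TAA")
  cds <- suppressWarnings(CDSRecord("stopcase", seqStr))
  cand <- designOverlaps(cds, designConfig("S0"))
  starts <- vapply(cand, function(x) x@startNt, integer(1))
  expect_true(13L %in% starts)
  x <- cand[[which(starts == 13L)[1]]]
  expect_true(x@flags[["frame_stop_free"]])
  aa <- translateFrame(x@editedSequence, 13)
  expect_false(grepl("*", aa, fixed = TRUE))
  # the Leu codon (nt 18..20, 0-based) must have become CTT or CTC, and the
  # minimal-edit + lexicographic tie-break picks CTC
  fixed <- substr(x@editedSequence, 19, 21)
  expect_true(fixed %in% c("CTT", "CTC"))
  expect_identical(fixed, "CTC")
  expect_identical(translateFrame(x@editedSequence, 0),
                   translateFrame(seqStr, 0))
})

test_that("irremovable stops reject at S0 but become remaining changes at S2plus", {
  # new-frame stop TGA at nt 19 whose overlapping host codons are ATG + ATG
  # (methionine has no synonyms), after a motif at nt 13
  seqStr <- paste0("ATG", "AAG", "GAG", "GAT", "TAT", "GTT",
                   "ATG", "ATG", "CAT", "TAA")
  cds <- suppressWarnings(CDSRecord("hardstop", seqStr))
  s0 <- designOverlaps(cds, designConfig("S0"))
  s2 <- designOverlaps(cds, designConfig("S2plus"))
  k0 <- vapply(s0, function(x) x@startNt, integer(1))
  k2 <- vapply(s2, function(x) x@startNt, integer(1))
  expect_false(13L %in% k0)
  rej <- attr(s0, "rejections")
  expect_true(length(rej) >= 1)
  rejAt13 <- Filter(function(r) r@startNt == 13L, rej)
  expect_length(rejAt13, 1)
  expect_identical(rejAt13[[1]]@reason, "irremovable_stop")
  expect_true(13L %in% k2)
  x <- s2[[which(k2 == 13L)[1]]]
  expect_gte(x@aaChangesRemaining, 1L)
  expect_false(x@flags[["frame_stop_free"]])
  expect_gte(length(x@suggestions), 1L)
})

test_that("stringency relaxations only add candidate sites", {
  for (seed in c(2, 5, 8, 13)) {
    cds <- randomCDS(35, seed = seed)
    key <- function(cands) vapply(cands, function(x)
      paste(x@startNt, x@frame), "")
    k0 <- key(designOverlaps(cds, designConfig("S0")))
    k1 <- key(designOverlaps(cds, designConfig("S1")))
    k2 <- key(designOverlaps(cds, designConfig("S2plus")))
    expect_true(all(k0 %in% k1))
    expect_true(all(k1 %in% k2))
  }
})

test_that("candidate reports are byte-identical across runs", {
  cds <- randomCDS(40, seed = 99)
  t1 <- candidateTable(designOverlaps(cds, designConfig("S1")))
  t2 <- candidateTable(designOverlaps(cds, designConfig("S1")))
  expect_identical(t1, t2)
})

test_that("candidates are sorted by start position then amino-acid cost", {
  cds <- randomCDS(60, seed = 4)
  cand <- designOverlaps(cds, designConfig("S1"))
  if (length(cand) > 1) {
    starts <- vapply(cand, function(x) x@startNt, integer(1))
    expect_true(all(diff(starts) >= 0))
    fracs <- vapply(cand, function(x) x@overlapFraction, numeric(1))
    expect_true(all(diff(fracs) <= 0))
  }
})
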