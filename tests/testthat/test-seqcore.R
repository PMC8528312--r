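test_that("translation reads through stops, honours frames, drops partial codons", {
  expect_identical(translateFrame("ATGTAA", 0), "M*")
  expect_identical(translateFrame("ATGTAA", 1), "C")
  expect_identical(translateFrame("TTATTGCTTCTCCTACTG", 0), "LLLLLL")
  expect_identical(translateFrame("ATGAAATGA", 0), "MK*")
  expect_error(translateFrame("ATGNAA", 0), "position 3")
  expect_error(translateFrame("ATG", 5))
})

test_that("synonymous variant enumeration is exhaustive, ordered and validated", {
  expect_identical(synonymousVariants("ATG"), "ATG")
  expect_setequal(synonymousVariants("TTA"),
                  c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"))
  expect_length(synonymousVariants("ATGTGGTTA"), 6)
  expect_error(synonymousVariants("ATGTAA"), "stop codon")
  expect_error(synonymousVariants("ATGA"), "multiple of 3")
  # deterministic order: repeated calls identical, first codon varies slowest
  v <- synonymousVariants("TTATGG")
  expect_identical(v, synonymousVariants("TTATGG"))
  expect_identical(substr(v, 4, 6), rep("TGG", 6))
  # count = product of synonym-set sizes, checked by exhaustive enumeration
  tab <- codonTable()
  for (w in c("ATGTTA", "GGGCGA", "TCATCG", "AAATGGATTTAT")) {
    sizes <- vapply(orfoverlap:::.codonsOf(w),
                    function(c) length(tab@synonymSets[[tab@code[c]]]),
                    numeric(1))
    vv <- synonymousVariants(w)
    expect_length(vv, prod(sizes))
    expect_false(anyDuplicated(vv) > 0)
    # every variant translates identically
    expect_true(all(vapply(vv, function(x) aaEditDistance(w, x) == 0, logical(1))))
  }
})

test_that("amino-acid edit distance counts differing codon translations", {
  expect_identical(aaEditDistance("TTA", "CTG"), 0L)
  expect_identical(aaEditDistance("TTA", "TTT"), 1L)
  expect_identical(aaEditDistance("ATGAAA", "ATGAAA"), 0L)
  expect_identical(aaEditDistance("ATGAAATTT", "ATGGAATTC"), 1L)
  expect_error(aaEditDistance("ATG", "ATGAAA"), "mismatch")
})

test_that("codon table partitions the sense codons", {
  tab <- codonTable()
  sense <- sort(unlist(tab@synonymSets, use.names = FALSE))
  expect_length(sense, 61)
  expect_false(anyDuplicated(sense) > 0)
  expect_false(any(c("TAA", "TAG", "TGA") %in% sense))
  expect_true(all(vapply(names(tab@synonymSets), function(a)
    all(tab@code[tab@synonymSets[[a]]] == a), logical(1))))
})

test_that("CDS validation enforces frame and rejects ambiguity codes", {
  expect_s4_class(CDSRecord("ok", "ATGAAATAA"), "CDSRecord")
  expect_error(CDSRecord("bad", "ATGAATAA"), "multiple of 3")
  expect_error(CDSRecord("bad", "ATGTAATAA"), "internal stop")
  expect_error(CDSRecord("bad", "ATGNNNTAA"), "non-ACGT")
  expect_warning(CDSRecord("frag", "AAAGGGTAA"), "start codon")
  expect_warning(CDSRecord("frag", "ATGAAAGGG"), "stop codon")
})

test_that("frame-0 translation of valid CDSs never stops early", {
  for (seed in 1:25) {
    cds <- randomCDS(sample(5:40, 1), seed = seed)
    aa <- translateFrame(cdsSequence(cds), 0)
    expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE))
    expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
  }
})
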