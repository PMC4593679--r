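test_that("nucMask and iupacUnion follow the IUPAC code", {
  expect_identical(cladophylo:::nucMask(c("A", "C", "G", "T")),
                   c(1L, 2L, 4L, 8L))
  expect_identical(iupacUnion(c("A", "G")), "R")
  expect_identical(iupacUnion(c("C", "T")), "Y")
  expect_identical(iupacUnion(c("A", "C", "G", "T")), "N")
  expect_identical(iupacUnion("A"), "A")
  expect_identical(iupacUnion(c("A", "R")), "R")  # union through ambiguity
  # unknown characters behave as fully ambiguous
  expect_identical(cladophylo:::nucMask("Z"), 15L)
})

test_that("childSeed is the documented LCG step", {
  expect_identical(childSeed(1L, 1L),
                   as.integer((1 * 48271 + 1) %% (2^31 - 1)))
  expect_identical(childSeed(123L, 45L),
                   as.integer((123 * 48271 + 45) %% (2^31 - 1)))
  # distinct stages give distinct seeds
  s <- vapply(1:50, function(k) childSeed(7L, k), numeric(1))
  expect_identical(anyDuplicated(s), 0L)
})

test_that("FASTA writer/reader round-trips", {
  seqs <- c(one = "MKV-LL", two = "MKVQLL")
  path <- withr::local_tempfile(fileext = ".fa")
  writeFasta(seqs, path, type = "AA")
  back <- readFastaChar(path, type = "AA")
  expect_identical(back, seqs)
})

test_that("sequence/matrix conversions invert each other", {
  seqs <- c(a = "ACGT", b = "A-GT")
  m <- cladophylo:::.seqsToMatrix(seqs)
  expect_identical(dim(m), c(2L, 4L))
  expect_identical(cladophylo:::.matrixToSeqs(m), seqs)
})
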