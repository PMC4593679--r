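test_that("degeneracy table collapses synonymous families", {
  degen <- buildDegenTable()
  gc <- Biostrings::GENETIC_CODE
  sense <- gc[gc != "*"]
  expect_length(degen$table, 61L)
  # same family <-> same pattern, for every sense codon pair
  for (c1 in names(sense)) for (c2 in names(sense)) {
    same <- sense[[c1]] == sense[[c2]]
    expect_identical(degen$table[[c1]] == degen$table[[c2]], same)
  }
  # single-codon families stay literal; Leu family unions six codons
  expect_identical(degen$table[["ATG"]], "ATG")
  expect_identical(degen$table[["TGG"]], "TGG")
  expect_identical(degen$patterns[["L"]], "YTN")
  expect_identical(degen$patterns[["R"]], "MGN")
  expect_identical(degen$patterns[["S"]], "WSN")
})

test_that("synonymous-only sequence pairs become identical after coding", {
  # two rows differing only synonymously: Leu TTA/CTG, Arg CGT/AGA, Ser TCT/AGC
  m <- rbind(a = strsplit("TTACGTTCT", "")[[1]],
             b = strsplit("CTGAGAAGC", "")[[1]])
  enc <- degenEncode(m)
  expect_identical(enc[1, ], enc[2, ])
  expect_identical(paste(enc[1, ], collapse = ""), "YTNMGNWSN")
  # a non-synonymous difference is preserved as a difference
  m2 <- rbind(a = strsplit("AAAGGG", "")[[1]],   # K G
              b = strsplit("AAGGAT", "")[[1]])   # K D
  enc2 <- degenEncode(m2)
  expect_identical(enc2[1, 1:3], enc2[2, 1:3])
  expect_false(all(enc2[1, 4:6] == enc2[2, 4:6]))
})

test_that("gaps, partial gaps, stops and ambiguity are handled", {
  m <- rbind(a = strsplit("---A--TAARTT", "")[[1]])
  expect_warning(enc <- degenEncode(m), "stop")
  # all-gap codon stays; partial-gap codon -> NNN; stop -> NNN
  expect_identical(paste(enc[1, 1:3], collapse = ""), "---")
  expect_identical(paste(enc[1, 4:6], collapse = ""), "NNN")
  expect_identical(paste(enc[1, 7:9], collapse = ""), "NNN")
  # RTT = {ATT, GTT} spans Ile and Val: unresolved -> NNN
  expect_identical(paste(enc[1, 10:12], collapse = ""), "NNN")
  lg <- attr(enc, "log")
  expect_identical(unname(lg["stops"]), 1L)
  expect_gte(unname(lg["unresolved"]), 2L)
  # ambiguity resolvable within one family is coded: YTA is Leu-only
  encY <- degenEncode(rbind(a = strsplit("YTA", "")[[1]]))
  expect_identical(paste(encY[1, ], collapse = ""), "YTN")
})

test_that("SuperMatrix input requires all codon positions and keeps labels", {
  seqs <- rbind(tA = strsplit("TTACGT", "")[[1]],
                tB = strsplit("CTGAGA", "")[[1]])
  sm <- SuperMatrix(seqs, data.frame(orthogroup = "og1",
                                     codon_pos = rep_len(1:3, 6L)))
  enc <- degenEncode(sm)
  expect_s4_class(enc, "SuperMatrix")
  expect_identical(enc@labels, sm@labels)
  sm12 <- selectCodonPositions(sm, c(1, 2))
  expect_error(degenEncode(sm12), "three codon positions")
})

test_that("degeneracy table writer emits one row per sense codon", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeDegenTable(path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  expect_identical(nrow(df), 61L)
  expect_setequal(names(df), c("codon", "residue", "pattern"))
  expect_false(any(df$residue == "*"))
})
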