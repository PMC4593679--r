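.identityMatrix <- function() {
  aa <- cladophylo:::AMINO_ACIDS
  s <- matrix(-4L, 20, 20, dimnames = list(aa, aa))
  diag(s) <- 6L
  q <- matrix(1 / 400, 20, 20)
  new("SubstitutionMatrix", name = "ID", scores = s, pairFreqs = q,
      margFreqs = rowSums(q), scale = 0.5, nBlocks = 1L, nPositions = 1L)
}

.smallSm <- function(seqs, ogs = "og1") {
  nc <- ncol(seqs)
  SuperMatrix(seqs, data.frame(orthogroup = rep_len(ogs, nc),
                               codon_pos = rep_len(1:3, nc)))
}

test_that("threading places an exact substring at its reference columns", {
  mat <- .identityMatrix()
  ref <- "MKVLHAGHIWRTYDEK"
  th <- threadFragment("HAGHIWRT", ref, mat)
  expect_identical(th$row, c(rep("-", 4), strsplit("HAGHIWRT", "")[[1]],
                             rep("-", 4)))
  expect_identical(th$map[5:12], 1:8)
  expect_identical(th$dropped, 0L)
  expect_identical(th$tstart, 5L)
  expect_identical(th$tend, 12L)
})

test_that("threading drops peptide residues inserted relative to the reference", {
  mat <- .identityMatrix()
  ref <- "MKVLHAGHIWRTYDEK"
  # peptide = ref[1:10] with two extra residues inserted in the middle
  pep <- "MKVLHCCAGHIW"
  th <- threadFragment(pep, ref, mat)
  expect_identical(th$dropped, 2L)
  expect_identical(th$row[1:10], strsplit("MKVLHAGHIW", "")[[1]])
})

test_that("backtranslation restores source codons per threaded residue", {
  rows <- list(tA = c("M", "K", "-"), tB = c("-", "K", "V"))
  maps <- list(tA = c(1L, 2L, NA), tB = c(NA, 1L, 2L))
  codons <- list(tA = c("ATG", "AAA"), tB = c("AAG", "GTT"))
  bt <- backtranslate(rows, maps, codons)
  expect_identical(paste(bt["tA", ], collapse = ""), "ATGAAA---")
  expect_identical(paste(bt["tB", ], collapse = ""), "---AAGGTT")
})

test_that("concatenation unions taxa and labels columns", {
  a1 <- rbind(tA = strsplit("ATGAAA", "")[[1]], tB = strsplit("ATGAAG", "")[[1]])
  a2 <- rbind(tB = strsplit("CCC", "")[[1]], tC = strsplit("CCG", "")[[1]])
  sm <- concatenateAlignments(list(og1 = a1, og2 = a2))
  expect_identical(rownames(sm@seqs), c("tA", "tB", "tC"))
  expect_identical(ncol(sm@seqs), 9L)
  expect_identical(sm@labels$orthogroup, rep(c("og1", "og2"), c(6, 3)))
  expect_identical(sm@labels$codon_pos, c(1:3, 1:3, 1:3))
  # absent taxa are all-gap in the other orthogroup
  expect_identical(unname(sm@seqs["tA", 7:9]), rep("-", 3))
  expect_identical(unname(sm@seqs["tC", 1:6]), rep("-", 6))
})

test_that("occupancy filter equals brute force on random matrices", {
  for (seed in 1:30) {
    nT <- sample(3:8, 1); nCod <- sample(2:6, 1)
    m <- randomAln(nT, 3L * nCod, seed + 3000, gapProb = 0.4,
                   names = paste0("t", seq_len(nT)))
    sm <- .smallSm(m)
    for (minTaxa in 0:nT) {
      got <- filterByOccupancy(sm, minTaxa)
      keep <- vapply(seq_len(ncol(m)), function(j)
        sum(!(m[, j] %in% c("-", ".", "?"))) >= minTaxa, logical(1))
      expect_identical(got@seqs, m[, keep, drop = FALSE])
      expect_identical(got@labels$codon_pos, sm@labels$codon_pos[keep])
    }
    # monotonicity: stricter thresholds keep fewer columns
    ncols <- vapply(0:nT, function(k) ncol(filterByOccupancy(sm, k)@seqs), 0L)
    expect_true(all(diff(ncols) <= 0))
    # full occupancy implies 100% completeness
    full <- filterByOccupancy(sm, nT)
    if (ncol(full@seqs) > 0) expect_equal(completeness(full), 100)
  }
})

test_that("codon-position selection equals brute force", {
  for (seed in 1:10) {
    m <- randomAln(4, 12L, seed + 4000, names = paste0("t", 1:4))
    sm <- .smallSm(m)
    for (pos in list(1, 2, 3, c(1, 2), 1:3)) {
      got <- selectCodonPositions(sm, pos)
      keep <- sm@labels$codon_pos %in% pos
      expect_identical(got@seqs, m[, keep, drop = FALSE])
    }
  }
})

test_that("completeness counts ambiguity as data and handles empties", {
  m <- rbind(tA = c("A", "N", "-"), tB = c("-", "?", "G"))
  expect_equal(completeness(.smallSm(m)), 100 * 3 / 6)
  empty <- filterByOccupancy(.smallSm(m), 5L)
  expect_message(val <- completeness(empty), "empty")
  expect_equal(val, 100)
})

test_that("PHYLIP round-trip preserves the matrix", {
  m <- randomAln(5, 9L, 77, names = c("t1", "longer_name", "t3", "t4", "t5"))
  sm <- .smallSm(m)
  path <- withr::local_tempfile(fileext = ".phy")
  writePhylip(sm, path)
  back <- readPhylip(path)
  expect_identical(back, m)
})

test_that("partition writer emits codon-position blocks", {
  m <- randomAln(3, 12L, 5, names = paste0("t", 1:3))
  sm <- .smallSm(m)
  path <- withr::local_tempfile(fileext = ".txt")
  writePartitions(sm, path)
  lines <- readLines(path)
  expect_length(lines, 3L)
  expect_true(all(grepl("^DNA, pos[123] =", lines)))
})

test_that("variant ladder builds the documented set with nested occupancy", {
  withr::with_seed(9, {
    nT <- 20L; nCod <- 10L
    # gaps fall codon-wise (as produced by backtranslation), stops excluded
    sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
    m <- matrix("-", nT, 3L * nCod, dimnames = list(sprintf("t%02d", 1:nT)))
    for (i in seq_len(nT)) for (j in seq_len(nCod)) {
      if (runif(1) >= 0.35)
        m[i, (3L * j - 2L):(3L * j)] <- strsplit(sample(sense, 1), "")[[1]]
    }
    sm <- .smallSm(m)
    v <- supermatrixVariants(sm)
    expect_setequal(names(v), c("unfiltered", "nt123", "min16", "min18",
                                "complete", "nt12", "degen1"))
    expect_identical(ncol(v$unfiltered@seqs), 30L)
    # occupancy nesting
    expect_lte(ncol(v$min16@seqs), ncol(v$nt123@seqs))
    expect_lte(ncol(v$min18@seqs), ncol(v$min16@seqs))
    expect_lte(ncol(v$complete@seqs), ncol(v$min18@seqs))
    # nt12 strips third positions of nt123
    expect_identical(ncol(v$nt12@seqs), 2L * ncol(v$nt123@seqs) %/% 3L)
    expect_true(all(v$nt12@labels$codon_pos %in% c(1L, 2L)))
    # degen1 has the same shape as nt123
    expect_identical(dim(v$degen1@seqs), dim(v$nt123@seqs))
    expect_equal(completeness(v$complete), 100)
    smry <- attr(v, "summary")
    expect_true(all(c("variant", "columns", "completeness") %in% names(smry)))
  })
})
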