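# random toy block set: nBlocks blocks of <= 5 sequences x <= 20 columns
.randomBlocks <- function(seed, nBlocks = 3L) {
  aa <- cladophylo:::AMINO_ACIDS
  withr::with_seed(seed, {
    lapply(seq_len(nBlocks), function(b) {
      n <- sample(2:5, 1); w <- sample(10:20, 1)
      # correlated rows so identities span the 0.5 weighting threshold
      base <- sample(aa, w, TRUE)
      m <- do.call(rbind, lapply(seq_len(n), function(i) {
        mut <- runif(w) < runif(1, 0.05, 0.9)
        out <- base
        out[mut] <- sample(aa, sum(mut), TRUE)
        out
      }))
      list(cluster = paste0("c", b), start = 0L, end = w, width = w,
           seqs = m, taxa = paste0("t", seq_len(n)))
    })
  })
}

test_that("cluster percent identity matches a hand-computed case", {
  cl <- sequenceCluster("c1", c("t1", "t2", "t3"), c("s1", "s2", "s3"),
                        c("MKVL", "MKI-", "M-VL"))
  # pairs: s1/s2 over 3 comparable cols (MKV vs MKI) = 2/3;
  # s1/s3 over 3 cols (MVL vs MVL) = 1; s2/s3 over 2 cols (MI vs MV) = 1/2
  expect_equal(clusterPercentIdentity(cl), mean(c(2/3, 1, 1/2)))
  expect_true(is.na(clusterPercentIdentity(
    sequenceCluster("c2", "t1", "s1", "MKVL"))))
})

test_that("cluster filter enforces membership and inclusive identity", {
  mk <- function(id, seqs) sequenceCluster(id, paste0("t", seq_along(seqs)),
                                           paste0(id, "_", seq_along(seqs)), seqs)
  exact70 <- mk("b", c("AAAAAAAAAA", "AAAAAAACCC"))  # identity exactly 0.70
  clusters <- list(mk("a", "MKVL"),                    # singleton: dropped
                   exact70,                            # boundary: kept
                   mk("c", c("AAAAAAAAAA", "CCCCCCCCCC")))  # 0 identity: dropped
  kept <- filterClusters(clusters)
  expect_identical(vapply(kept, `[[`, "", "id"), "b")
  rep <- attr(kept, "report")
  expect_identical(rep$kept, c(FALSE, TRUE, FALSE))
  expect_equal(rep$identity[2], 0.70)
})

test_that("reference taxon is the most frequent, ties broken and flagged", {
  mk <- function(id, taxa) sequenceCluster(id, taxa, paste0(id, seq_along(taxa)),
                                           rep("MKVL", length(taxa)))
  sel <- selectReferenceTaxon(list(mk("a", c("tB", "tC")),
                                   mk("b", c("tB", "tA")),
                                   mk("c", c("tA", "tC"))))
  expect_identical(sel$taxon, "tA")  # three-way tie -> lexicographic
  expect_true(sel$tie)
  sel2 <- selectReferenceTaxon(list(mk("a", c("tB", "tC")),
                                    mk("b", c("tB", "tA"))))
  expect_identical(sel2$taxon, "tB")
  expect_false(sel2$tie)
})

test_that("block extraction finds gap-free conserved runs", {
  # 14 columns: col 5 has a gap, col 10 is below 50% conservation
  seqs <- c("MKVLAAGHIWRTYD",
            "MKVLA-GHICRTYD",
            "MKVLAAGHIERTYD",
            "MKVLAAGHIARTYD")
  cl <- sequenceCluster("c1", paste0("t", 1:4), paste0("s", 1:4), seqs)
  b <- extractBlocks(cl, minBlockWidth = 3L, minColumnConservation = 0.5)
  # gap column 6 splits runs; col 10 (W/C/E/A: max 1/4 < 0.5) splits again;
  # the middle run spans 3 columns, the width floor of 3 keeps it
  expect_identical(vapply(b, `[[`, 0L, "start"), c(0L, 6L, 10L))
  expect_identical(vapply(b, `[[`, 0L, "end"), c(5L, 9L, 14L))
  expect_identical(b[[1]]$seqs[2, ], c("M", "K", "V", "L", "A"))
  # width floor removes short runs
  expect_length(extractBlocks(cl, minBlockWidth = 5L), 1L)
})

test_that("log-odds matrix matches the brute-force oracle", {
  for (seed in 1:8) {
    blocks <- .randomBlocks(seed, nBlocks = sample(1:4, 1))
    got <- computeLogOddsMatrix(blocks)
    want <- oracleLogOdds(blocks)
    expect_equal(got@pairFreqs, want$q, tolerance = 1e-12)
    expect_identical(scoreMatrix(got), want$s)
    expect_equal(sum(got@pairFreqs), 1, tolerance = 1e-12)
    expect_identical(scoreMatrix(got), t(scoreMatrix(got)))
  }
})

test_that("scoring matrix text round-trips", {
  m <- computeLogOddsMatrix(.randomBlocks(99), name = "TOY")
  path <- withr::local_tempfile(fileext = ".txt")
  writeScoringMatrix(m, path)
  back <- readScoringMatrix(path)
  expect_identical(back, scoreMatrix(m))
})

test_that("core orthologue database reconciles reference protein ids", {
  cl1 <- sequenceCluster("og1", c("ref", "tB"), c("og1_m1", "og1_m2"),
                         c("MKVLAAGHIWRT", "MKVLAVGHIWRT"))
  cl2 <- sequenceCluster("og2", c("tB", "tC"), c("og2_m1", "og2_m2"),
                         c("MNPQRSTVWYAC", "MNPQRSTVWYAC"))
  proteome <- c(og1_ref = "MKVLAAGHIWRT", other = "MMMM")
  db <- buildCoreOrthologueDb(list(cl1, cl2), "ref", proteome = proteome)
  # only the cluster containing the reference taxon enters the database
  expect_identical(names(db@orthogroups), "og1")
  og <- db@orthogroups[["og1"]]
  # refProteinId re-pointed at the proteome entry with the same sequence
  expect_identical(og$refProteinId, "og1_ref")
  expect_identical(unname(db@proteome[og$refProteinId]), "MKVLAAGHIWRT")
  expect_s3_class(og$profile, "ProfileModel")
})
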