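.toyMatrix <- function() {
  # small deterministic substitution matrix: +5 match, -2 mismatch
  aa <- cladophylo:::AMINO_ACIDS
  s <- matrix(-2L, 20, 20, dimnames = list(aa, aa))
  diag(s) <- 5L
  q <- matrix(1, 20, 20); q <- q / sum(q)
  new("SubstitutionMatrix", name = "TOY", scores = s, pairFreqs = q,
      margFreqs = rowSums(q), scale = 0.5, nBlocks = 1L, nPositions = 1L)
}

test_that("six-frame translation produces correct peptides and coordinates", {
  # forward frame +1: ATG AAA TGT TAA CCC -> MKC | P (stop splits)
  tx <- "ATGAAATGTTAACCC"
  pep <- sixFrameTranslate(tx, id = "t1")
  f1 <- pep[pep$frame == 1L, ]
  expect_identical(f1$peptide, c("MKC", "P"))
  expect_identical(f1$ntStart, c(0L, 12L))
  # reverse frames read the reverse complement with its own coordinates
  rc <- cladophylo:::.revcomp(tx)
  m1 <- pep[pep$frame == -1L, ]
  expect_identical(m1$peptide[1],
                   paste(Biostrings::GENETIC_CODE[substring(
                     rc, c(1, 4, 7, 10, 13), c(3, 6, 9, 12, 15))],
                     collapse = ""))
  expect_identical(attr(pep, "strandSeqs")[["-"]], rc)
  # ambiguity codons become X; length filter applies per peptide
  pep2 <- sixFrameTranslate("ATGNNNAAA", id = "t2")
  expect_identical(pep2$peptide[pep2$frame == 1L], "MXK")
  pep3 <- sixFrameTranslate(tx, minPeptideLength = 2L)
  expect_false("P" %in% pep3$peptide[pep3$frame == 1L])
})

test_that("batch Smith-Waterman equals the brute-force oracle", {
  mat <- .toyMatrix()
  aa <- cladophylo:::AMINO_ACIDS
  M <- rbind(cbind(scoreMatrix(mat), X = 0L), X = 0L)
  withr::with_seed(404, {
    for (rep in 1:25) {
      q <- sample(aa, sample(3:7, 1), TRUE)
      t <- sample(aa, sample(3:7, 1), TRUE)
      got <- cladophylo:::.sw_score_batch(
        list(match(q, c(aa, "X")) - 1L), list(match(t, c(aa, "X")) - 1L),
        M, 4, 1, TRUE)
      want <- oracleSwScore(q, t, scoreMatrix(mat), 4, 1)
      expect_equal(got, want)
    }
  })
})

test_that("traceback alignment reproduces the batch score", {
  mat <- .toyMatrix()
  withr::with_seed(77, {
    aa <- cladophylo:::AMINO_ACIDS
    for (rep in 1:10) {
      q <- paste(sample(aa, 25, TRUE), collapse = "")
      t <- paste(sample(aa, 30, TRUE), collapse = "")
      M <- rbind(cbind(scoreMatrix(mat), X = 0L), X = 0L)
      S <- M[cladophylo:::.pepIdx(q), cladophylo:::.pepIdx(t), drop = FALSE]
      al <- cladophylo:::.sw_align_scores(S, 11, 1)
      sc <- cladophylo:::.sw_score_batch(
        list(cladophylo:::.pepIdx0(q)), list(cladophylo:::.pepIdx0(t)),
        M, 11, 1, TRUE)
      expect_equal(al$score, sc)
      # matched pairs are strictly increasing in both sequences
      if (nrow(al$pairs) > 1) {
        expect_true(all(diff(al$pairs[, 1]) >= 1))
        expect_true(all(diff(al$pairs[, 2]) >= 1))
      }
    }
  })
})

test_that("profile scores follow the log-odds definition", {
  aln <- c(a = "MK-L", b = "MKVL", c = "MRVL")
  prof <- buildProfile(aln, pseudocount = 1)
  expect_s3_class(prof, "ProfileModel")
  expect_identical(prof$width, 4L)
  # column 2: K twice, R once among 3 non-gap residues, bg = 1/20
  bg <- 1 / 20
  expect_equal(unname(prof$scores["K", 2]),
               log2(((2 + 1 * bg) / (3 + 1)) / bg))
  expect_equal(unname(prof$scores["R", 2]),
               log2(((1 + 1 * bg) / (3 + 1)) / bg))
  # X row scores zero everywhere
  expect_equal(unname(prof$scores["X", ]), rep(0, 4))
  # majority-gap columns are dropped
  aln2 <- c(a = "M--L", b = "MK-L", c = "M--L")
  prof2 <- buildProfile(aln2)
  expect_identical(prof2$width, 2L)
})

test_that("Gumbel fit recovers known location and scale", {
  withr::with_seed(2024, {
    mu <- 35; beta <- 4
    x <- mu - beta * log(-log(runif(5000)))
    fit <- cladophylo:::.fitGumbel(x)
    expect_equal(fit$mu, mu, tolerance = 0.05)
    expect_equal(fit$beta, beta, tolerance = 0.05)
  })
})

test_that("E-values scale with search space and decrease in score", {
  prof <- buildProfile(c(a = "MKVLMKVL", b = "MKVLMKVL"))
  prof$calibration <- list(mu = 20, beta = 3)
  e1 <- profileEvalue(30, prof, searchSpace = 1)
  expect_equal(e1, exp(-(30 - 20) / 3))
  expect_equal(profileEvalue(30, prof, searchSpace = 100), 100 * e1)
  expect_lt(profileEvalue(40, prof, 1), e1)
})

test_that("provisional assignment applies E-filter, quartile and ties", {
  # one orthogroup whose profile is sharply peaked on a known sequence
  target <- "MKVLHAGHIWRTYDEKNPQS"
  prof <- buildProfile(setNames(rep(target, 3), c("a", "b", "c")))
  prof$calibration <- list(mu = 5, beta = 1)
  db <- new("CoreOrthologueSet", referenceTaxon = "ref",
            orthogroups = list(og1 = list(id = "og1", profile = prof,
                                          refProtein = target,
                                          refProteinId = "r1")),
            proteome = c(r1 = target))
  mkPep <- function(seqs) data.frame(
    transcript = paste0("tx", seq_along(seqs)), frame = 1L, peptide = seqs,
    ntStart = 0L, peptide_id = paste0("p", seq_along(seqs)),
    stringsAsFactors = FALSE)
  # eight peptides with decreasing similarity to the target
  aa <- cladophylo:::AMINO_ACIDS
  seqs <- vapply(0:7, function(k) {
    s <- strsplit(target, "")[[1]]
    if (k > 0) s[seq_len(k) * 2] <- "A"
    paste(s, collapse = "")
  }, character(1))
  peps <- mkPep(seqs)
  hits <- assignProvisional(peps, db, evalueCutoff = 1e-3, quartile = 0.25,
                            searchSpace = 1, seedFilter = FALSE)
  # replicate the documented rule independently
  sc <- cladophylo:::.profile_score_batch(
    lapply(peps$peptide, cladophylo:::.pepIdx0), prof$scores, 11, 1)
  ev <- exp(-(sc - 5) / 1)
  pass <- which(ev <= 1e-3)
  kTop <- ceiling(length(pass) * 0.25)
  boundary <- sort(sc[pass], decreasing = TRUE)[kTop]
  wantIds <- peps$peptide_id[pass][sc[pass] >= boundary]
  expect_setequal(hits$peptide_id, wantIds)
  # boundary ties: duplicate the boundary sequence, both must survive
  boundSeq <- peps$peptide[match(sort(wantIds)[length(wantIds)], peps$peptide_id)]
  peps2 <- mkPep(c(seqs, boundSeq))
  hits2 <- assignProvisional(peps2, db, evalueCutoff = 1e-3, quartile = 0.25,
                             searchSpace = 1, seedFilter = FALSE)
  expect_gte(nrow(hits2), length(wantIds) + 1L)
  # only the best frame of a transcript is kept
  peps3 <- mkPep(c(target, target))
  peps3$transcript <- "tx1"; peps3$frame <- c(1L, 2L)
  hits3 <- assignProvisional(peps3, db, evalueCutoff = 1e-3, quartile = 1,
                             searchSpace = 1, seedFilter = FALSE)
  expect_identical(nrow(hits3), 1L)
})

test_that("seed prefilter never changes reported scores of true hits", {
  target <- "MKVLHAGHIWRTYDEKNPQS"
  prof <- buildProfile(setNames(rep(target, 2), c("a", "b")))
  prof$calibration <- list(mu = 5, beta = 1)
  db <- new("CoreOrthologueSet", referenceTaxon = "ref",
            orthogroups = list(og1 = list(id = "og1", profile = prof,
                                          refProtein = target,
                                          refProteinId = "r1")),
            proteome = c(r1 = target))
  peps <- data.frame(transcript = "tx1", frame = 1L, peptide = target,
                     ntStart = 0L, peptide_id = "p1", stringsAsFactors = FALSE)
  h1 <- assignProvisional(peps, db, evalueCutoff = 1, quartile = 1,
                          searchSpace = 1, seedFilter = TRUE)
  h2 <- assignProvisional(peps, db, evalueCutoff = 1, quartile = 1,
                          searchSpace = 1, seedFilter = FALSE)
  expect_equal(h1$score, h2$score)
})

test_that("reciprocal best hit confirms only matches to the assigned reference", {
  mat <- .toyMatrix()
  refA <- "MKVLHAGHIWRTYDEKNPQS"
  refB <- "CCWWHHEEDDNNQQKKRRSS"
  profA <- buildProfile(setNames(rep(refA, 2), c("a", "b")))
  profA$calibration <- list(mu = 5, beta = 1)
  db <- new("CoreOrthologueSet", referenceTaxon = "ref",
            orthogroups = list(ogA = list(id = "ogA", profile = profA,
                                          refProtein = refA,
                                          refProteinId = "rA")),
            proteome = c(rA = refA, rB = refB))
  peps <- data.frame(transcript = c("t1", "t2"), frame = 1L,
                     peptide = c(refA, refB), ntStart = 0L,
                     peptide_id = c("p1", "p2"), stringsAsFactors = FALSE)
  hits <- data.frame(peptide_id = c("p1", "p2"), transcript = c("t1", "t2"),
                     frame = 1L, orthogroup = "ogA", score = 50,
                     evalue = 1e-10, stringsAsFactors = FALSE)
  out <- reciprocalBestHit(hits, peps, db, mat, evalueCutoff = 1e-3,
                           calibration = list(mu = 20, beta = 3))
  # p1's proteome best is rA (its own reference): confirmed
  expect_true(out$confirmed[out$peptide_id == "p1"])
  expect_identical(out$best_protein[out$peptide_id == "p1"], "rA")
  # p2's best hit is rB, not ogA's reference: rejected
  expect_false(out$confirmed[out$peptide_id == "p2"])
})
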