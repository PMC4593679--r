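test_that("clan classification matches the exhaustive oracle", {
  withr::with_seed(500, {
    for (rep in 1:60) {
      nTip <- sample(4:12, 1)
      nTaxa <- sample(2:4, 1)
      labels <- paste0("t", sample(seq_len(nTaxa), nTip, TRUE), "__c",
                       seq_len(nTip))
      tr <- ape::rtree(nTip, rooted = FALSE)
      tr$tip.label <- labels
      for (tx in paste0("t", seq_len(nTaxa))) {
        got <- detectClans(tr, tx)
        leaves <- labels[cladophylo:::.leafTaxon(labels) == tx]
        if (length(leaves) == 0L) {
          expect_identical(got$class, "absent")
        } else if (length(leaves) == 1L) {
          expect_identical(got$class, "single")
        } else {
          want <- if (oracleIsClan(tr, leaves)) "in_paralogue" else
            "out_paralogue"
          expect_identical(got$class, want)
          expect_setequal(got$leaves, leaves)
        }
      }
    }
  })
})

test_that("planted in- and out-paralogues are classified correctly", {
  # tA's two copies sister to each other: in-paralogues
  tin <- ape::read.tree(text = "((tA__1:1,tA__2:1):1,(tB__1:1,tC__1:1):1);")
  expect_identical(detectClans(tin, "tA")$class, "in_paralogue")
  # tA's copies split across the deepest edge: out-paralogues
  tout <- ape::read.tree(text = "((tA__1:1,tB__1:1):1,(tA__2:1,tC__1:1):1);")
  expect_identical(detectClans(tout, "tA")$class, "out_paralogue")
  # works regardless of rooting
  expect_identical(detectClans(ape::unroot(tout), "tA")$class, "out_paralogue")
})

test_that("consensus sequence ignores gaps and encodes ties", {
  # col1 unanimous; col2 majority over a gap; col3 tie A/G -> R (DNA)
  seqs <- c("AAA", "A-G", "ACA", "-CG")
  expect_identical(consensusSequence(seqs, "DNA"), "ACR")
  expect_identical(consensusSequence(c("AA", "--"), "DNA"), "AA")
  expect_identical(consensusSequence(c("--", "--"), "DNA"), "--")
  # amino-acid ties become X
  expect_identical(consensusSequence(c("MK", "ML"), "AA"), "MX")
})

test_that("orthogroup filtering discards out-paralogues, merges in-paralogues", {
  aln <- rbind(tA__1 = c("A", "A", "A"), tA__2 = c("A", "A", "G"),
               tB__1 = c("C", "C", "C"), tC__1 = c("T", "T", "T"))
  tin <- ape::read.tree(text = "((tA__1:1,tA__2:1):1,(tB__1:1,tC__1:1):1);")
  res <- filterOrthogroup(tin, aln, "DNA")
  expect_true(res$keep)
  expect_setequal(rownames(res$alignment), c("tA", "tB", "tC"))
  # merged tA row is the consensus (tie at col 3 -> R)
  expect_identical(unname(res$alignment["tA", ]), c("A", "A", "R"))
  expect_identical(unname(res$alignment["tB", ]), c("C", "C", "C"))
  tout <- ape::read.tree(text = "((tA__1:1,tB__1:1):1,(tA__2:1,tC__1:1):1);")
  res2 <- filterOrthogroup(tout, aln, "DNA")
  expect_false(res2$keep)
  expect_null(res2$alignment)
  expect_identical(res2$report$class[res2$report$taxon == "tA"],
                   "out_paralogue")
})
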