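# helper: small random GTR+I+G parameter set
.randParams <- function(seed, pinv = 0.2, k = 4L) {
  withr::with_seed(seed, {
    fr <- runif(4, 0.5, 2); fr <- fr / sum(fr)
    gtrParams(rates = runif(6, 0.5, 3), freqs = fr, pinv = pinv,
              alpha = runif(1, 0.4, 2), k = k)
  })
}

test_that("two-sequence Jukes-Cantor matches the closed form", {
  # JC = GTR with equal rates and frequencies, no invariant sites, one
  # gamma category; two tips at distance t
  withr::with_seed(11, {
    n <- 200L
    s1 <- paste(sample(c("A","C","G","T"), n, TRUE), collapse = "")
    s2 <- paste(sample(c("A","C","G","T"), n, TRUE), collapse = "")
  })
  for (t in c(0.05, 0.3, 1.2)) {
    tr <- ape::read.tree(text = sprintf("(a:%f,b:%f);", t / 2, t / 2))
    p <- gtrParams(k = 1L)
    ll <- treeLogLikelihood(tr, c(a = s1, b = s2), p)
    expect_equal(ll, oracleJc2(s1, s2, t), tolerance = 1e-6)
  }
})

test_that("likelihood equals exhaustive state summation (<= 5 taxa)", {
  skip_if_not_installed("Matrix")
  for (seed in 1:3) {
    nTip <- c(4L, 5L, 5L)[seed]
    tr <- randomTree(nTip, seed)
    tr$edge.length <- tr$edge.length / 2 + 0.05
    aln <- randomAln(nTip, 4L, seed + 100, gapProb = 0.15,
                     names = tr$tip.label)
    # include an ambiguity code to exercise partial masks
    aln[1, 1] <- "R"
    p <- .randParams(seed)
    ll <- treeLogLikelihood(tr, aln, p)
    llo <- oracleLoglik(tr, aln, p)
    expect_equal(ll, llo, tolerance = 1e-10)
  }
})

test_that("likelihood is invariant to re-rooting", {
  tr <- randomTree(6L, 42)
  tr$edge.length <- tr$edge.length + 0.05
  aln <- randomAln(6L, 60L, 7, names = tr$tip.label)
  p <- .randParams(3)
  ref <- treeLogLikelihood(tr, aln, p)
  for (tip in tr$tip.label[1:4]) {
    rr <- ape::root(tr, outgroup = tip, resolve.root = TRUE)
    expect_equal(treeLogLikelihood(rr, aln, p), ref, tolerance = 1e-8)
  }
})

test_that("invariant-site and gamma mixture behave as defined", {
  skip_if_not_installed("Matrix")
  tr <- randomTree(4L, 5)
  tr$edge.length <- tr$edge.length + 0.1
  aln <- randomAln(4L, 3L, 9, gapProb = 0, names = tr$tip.label)
  # force one constant column: invariant term must be active there
  aln[, 2] <- "C"
  p <- .randParams(8, pinv = 0.35)
  expect_equal(treeLogLikelihood(tr, aln, p), oracleLoglik(tr, aln, p),
               tolerance = 1e-10)
  # pinv = 0 equals the pure gamma mixture
  p0 <- gtrParams(rates = p@rates, freqs = p@freqs, pinv = 0,
                  alpha = p@alpha, k = p@k)
  expect_equal(treeLogLikelihood(tr, aln, p0), oracleLoglik(tr, aln, p0),
               tolerance = 1e-10)
})

test_that("partitioned likelihood is the sum of per-subset likelihoods", {
  tr <- randomTree(5L, 21)
  tr$edge.length <- tr$edge.length + 0.05
  aln <- randomAln(5L, 30L, 31, names = tr$tip.label)
  p1 <- .randParams(1); p2 <- .randParams(2)
  subsetOf <- rep(1:2, each = 15L)
  ps <- partitionScheme(subsetOf, list(p1, p2), multipliers = c(1.4, 0.6))
  ll <- treeLogLikelihood(tr, aln, ps)
  # per-subset reference: scale branch lengths by the multiplier
  scale <- function(t, m) { t$edge.length <- t$edge.length * m; t }
  ll1 <- treeLogLikelihood(scale(tr, 1.4), aln[, 1:15], p1)
  ll2 <- treeLogLikelihood(scale(tr, 0.6), aln[, 16:30], p2)
  expect_equal(ll, ll1 + ll2, tolerance = 1e-8)
})

test_that("all-gap columns contribute zero log-likelihood", {
  tr <- randomTree(4L, 2)
  tr$edge.length <- tr$edge.length + 0.1
  aln <- randomAln(4L, 10L, 13, names = tr$tip.label)
  p <- .randParams(4)
  ref <- treeLogLikelihood(tr, aln, p)
  aln2 <- cbind(aln, matrix("-", 4, 3))
  expect_equal(treeLogLikelihood(tr, aln2, p), ref, tolerance = 1e-10)
})

test_that("SuperMatrix input matches plain matrix input", {
  tr <- randomTree(4L, 6)
  tr$edge.length <- tr$edge.length + 0.1
  aln <- randomAln(4L, 12L, 17, names = tr$tip.label)
  sm <- SuperMatrix(aln, data.frame(orthogroup = "og1",
                                    codon_pos = rep_len(1:3, 12L)))
  p <- .randParams(5)
  expect_equal(treeLogLikelihood(tr, sm, p),
               treeLogLikelihood(tr, aln, p), tolerance = 1e-12)
})
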