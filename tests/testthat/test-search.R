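# simulate a small alignment on a known tree so searches have signal
.simAln <- function(tree, nSites, seed, rate = 1) {
  bases <- c("A", "C", "G", "T")
  P <- function(t) 0.25 + (diag(4) - 0.25) * exp(-4 * rate * t / 3)  # JC
  withr::with_seed(seed, {
    tr <- reorder(tree, "cladewise")
    nTip <- length(tr$tip.label)
    root <- nTip + 1L
    st <- matrix(0L, max(tr$edge), nSites)
    st[root, ] <- sample(1:4, nSites, TRUE)
    for (e in seq_len(nrow(tr$edge))) {
      a <- tr$edge[e, 1]; b <- tr$edge[e, 2]
      Pe <- P(tr$edge.length[e])
      st[b, ] <- vapply(st[a, ], function(x) sample(1:4, 1, prob = Pe[x, ]),
                        0L)
    }
    m <- matrix(bases[st[seq_len(nTip), ]], nrow = nTip)
    rownames(m) <- tr$tip.label
    m
  })
}

test_that("RF distance agrees with phangorn on random tree pairs", {
  skip_if_not_installed("phangorn")
  withr::with_seed(88, {
    for (rep in 1:20) {
      n <- sample(4:12, 1)
      t1 <- ape::rtree(n, rooted = FALSE)
      t2 <- ape::rtree(n, rooted = FALSE)
      t2$tip.label <- sample(t1$tip.label)
      expect_identical(rfDistance(t1, t2),
                       as.integer(phangorn::RF.dist(t1, t2)))
      expect_identical(rfDistance(t1, t1), 0L)
    }
  })
})

test_that("stepwise addition and NNI recover a clear 6-taxon topology", {
  true <- ape::read.tree(
    text = "((a:0.1,b:0.1):0.15,(c:0.1,d:0.1):0.15,(e:0.1,f:0.1):0.15);")
  aln <- .simAln(true, 800L, 303)
  model <- gtrParams(k = 4L, alpha = 1)
  t0 <- stepwiseAdditionTree(aln, model, seed = 5L)
  expect_setequal(t0$tip.label, true$tip.label)
  res <- nniSearch(t0, aln, model)
  expect_identical(rfDistance(res$tree, true), 0L)
  # NNI never decreases the likelihood relative to its start
  ll0 <- treeLogLikelihood(t0, aln, model)
  expect_gte(res$logLik, ll0 - 1e-8)
  expect_equal(res$logLik, treeLogLikelihood(res$tree, aln, model),
               tolerance = 1e-6)
})

test_that("model optimisation improves the likelihood and keeps validity", {
  true <- ape::read.tree(
    text = "((a:0.15,b:0.15):0.1,(c:0.15,d:0.15):0.1,e:0.2);")
  aln <- .simAln(true, 400L, 7)
  start <- gtrParams(alpha = 2, pinv = 0.05)
  ll0 <- treeLogLikelihood(true, aln, start)
  fit <- mlOptimize(true, aln, start, maxRounds = 2L)
  expect_gte(fit$logLik, ll0)
  expect_s4_class(fit$model, "GTRParams")
  expect_true(abs(sum(fit$model@freqs) - 1) < 1e-8)
  expect_true(all(fit$model@rates > 0))
  expect_equal(fit$logLik, treeLogLikelihood(fit$tree, aln, fit$model),
               tolerance = 1e-6)
})

test_that("bootstrap replicates are deterministic in the seed", {
  true <- ape::read.tree(
    text = "((a:0.1,b:0.1):0.2,(c:0.1,d:0.1):0.2,e:0.2);")
  aln <- .simAln(true, 300L, 19)
  model <- gtrParams()
  b1 <- bootstrapReplicates(aln, model, true, nReps = 5L, seed = 4L)
  b2 <- bootstrapReplicates(aln, model, true, nReps = 5L, seed = 4L)
  splitsOf <- function(t) sort(cladophylo:::.splits(t))
  expect_equal(lapply(b1, splitsOf), lapply(b2, splitsOf))
  expect_length(b1, 5L)
})

test_that("majority-rule consensus and support mapping count splits correctly", {
  tAB <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1,e:1);")
  tAC <- ape::read.tree(text = "((a:1,c:1):1,(b:1,d:1):1,e:1);")
  trees <- c(rep(list(tAB), 3), list(tAC))
  cons <- majorityRuleConsensus(trees)
  # ab|cde and cd|abe occur in 3/4 = 75% of trees
  labs <- cons$node.label[nzchar(cons$node.label)]
  expect_setequal(labs, c("75.0", "75.0"))
  supp <- mapSupport(tAB, trees)
  expect_setequal(supp$node.label[nzchar(supp$node.label)],
                  c("75.0", "75.0"))
  supp2 <- mapSupport(tAC, trees)
  expect_setequal(supp2$node.label[nzchar(supp2$node.label)],
                  c("25.0", "25.0"))
})

test_that("full ML search returns a coherent TreeSearchResult", {
  true <- ape::read.tree(
    text = "((a:0.1,b:0.1):0.2,(c:0.1,d:0.1):0.2,(e:0.1,f:0.1):0.2);")
  aln <- .simAln(true, 600L, 11)
  res <- mlTreeSearch(aln, nReplicates = 3L, nBootstrap = 10L, seed = 2L)
  expect_s4_class(res, "TreeSearchResult")
  expect_identical(nrow(res@replicates), 3L)
  expect_length(res@bootstrapTrees, 10L)
  expect_identical(rfDistance(res@bestTree, true), 0L)
  expect_equal(res@logLik,
               treeLogLikelihood(res@bestTree, aln, res@model),
               tolerance = 1e-6)
  # support labels are percentages
  supp <- res@supportTree$node.label
  supp <- supp[nzchar(supp)]
  expect_true(all(as.numeric(supp) >= 0 & as.numeric(supp) <= 100))
  # strong signal: true clades should be well supported here
  expect_gte(median(as.numeric(supp)), 80)
})
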