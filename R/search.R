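# Maximum-likelihood tree search: branch-length and model optimisation,
# stepwise-addition starting trees, NNI hill climbing, nonparametric
# bootstrap and consensus/support summaries.

# --- internal search context: pattern-compressed data reused across trees ---
.mkContext <- function(alignment, model) {
  if (is(alignment, "SuperMatrix")) alignment <- alignment@seqs
  if (!is.matrix(alignment)) alignment <- .seqsToMatrix(alignment)
  em <- .engineModels(model, nCols = ncol(alignment))
  pat <- .compressPatterns(.maskMatrix(alignment), em$subsetOfCol)
  list(aln = alignment, taxa = rownames(alignment), models = em$models,
       subsetOfCol = em$subsetOfCol, tip = pat$tip, w = pat$w,
       subset = pat$subset, model = model)
}

# thinned view of a context for heuristic stages: resample pattern weights
# by a single multinomial draw of maxSites sites (probability proportional
# to weight) and drop patterns that received no draws.  Pattern order is
# preserved, so the subset sorting the engine relies on is kept.  Exact
# stages (final optimisation, reported likelihoods) always use the full
# context.
.ctxThin <- function(ctx, maxSites = Inf, seed = 1L) {
  if (!is.finite(maxSites) || sum(ctx$w) <= maxSites) return(ctx)
  wNew <- withr::with_seed(seed,
    as.numeric(rmultinom(1, maxSites, ctx$w / sum(ctx$w))))
  keep <- which(wNew > 0)
  ctx$tip <- ctx$tip[, keep, drop = FALSE]
  ctx$w <- wNew[keep]
  ctx$subset <- ctx$subset[keep]
  ctx
}

# swap in new model parameters without recompressing site patterns (the
# pattern/subset structure depends only on the alignment)
.ctxRemodel <- function(ctx, model) {
  ctx$models <- .engineModels(model, nCols = length(ctx$subsetOfCol))$models
  ctx$model <- model
  ctx
}

.ctxLoglik <- function(ctx, tree, w = NULL) {
  tree <- .normalizeTree(tree)
  tipm <- ctx$tip[tree$tip.label, , drop = FALSE]
  .phylo_loglik(tree$edge, length(tree$tip.label), tree$edge.length, tipm,
                w %||% ctx$w, ctx$subset, ctx$models)$loglik
}

.ctxOptimBlens <- function(ctx, tree, nsweeps = 3L, tol = 1e-4, w = NULL) {
  tree <- .normalizeTree(tree)
  tipm <- ctx$tip[tree$tip.label, , drop = FALSE]
  r <- .phylo_optimize_blens(tree$edge, length(tree$tip.label),
                             tree$edge.length, tipm, w %||% ctx$w, ctx$subset,
                             ctx$models, nsweeps = nsweeps, tol = tol)
  tree$edge.length <- r$blen
  list(tree = tree, logLik = r$loglik)
}

# --- tree surgery ------------------------------------------------------------

.addTip <- function(tree, label, edgeIdx, tNew, splitAt = 0.5) {
  nT <- length(tree$tip.label)
  edge <- tree$edge; blen <- tree$edge.length
  edge[edge > nT] <- edge[edge > nT] + 1L
  newTip <- nT + 1L
  newNode <- max(edge) + 1L
  b <- edge[edgeIdx, 2]; t0 <- blen[edgeIdx]
  edge[edgeIdx, 2] <- newNode; blen[edgeIdx] <- t0 * splitAt
  edge <- rbind(edge, c(newNode, b), c(newNode, newTip))
  blen <- c(blen, t0 * (1 - splitAt), tNew)
  .rebuildPhylo(edge, blen, c(tree$tip.label, label))
}

# apply one NNI swap described by a row of .phylo_nni_eval output:
# edge u--S becomes v--S, edge v--C becomes u--C (lengths follow subtrees)
.applyNni <- function(tree, u, v, S, C) {
  edge <- tree$edge
  rS <- which((edge[, 1] == u & edge[, 2] == S) | (edge[, 1] == S & edge[, 2] == u))
  rC <- which((edge[, 1] == v & edge[, 2] == C) | (edge[, 1] == C & edge[, 2] == v))
  stopifnot(length(rS) == 1L, length(rC) == 1L)
  edge[rS, ][edge[rS, ] == u] <- v
  edge[rC, ][edge[rC, ] == v] <- u
  .rebuildPhylo(edge, tree$edge.length, tree$tip.label)
}

# --- starting trees ----------------------------------------------------------

#' Stepwise-addition starting tree
#'
#' Taxa are added in a seeded random order; each new taxon is placed on the
#' edge maximising the likelihood (pendant length \code{tNew}, insertion at
#' the edge midpoint), followed every few insertions by a quick
#' branch-length pass.
#'
#' @param alignment character matrix / named vector / SuperMatrix
#' @param model GTRParams or PartitionScheme
#' @param seed integer seed controlling the addition order
#' @param tNew pendant branch length for fresh placements
#' @param ctx optional precomputed search context (internal reuse)
#' @param maxSites cap on the effective number of sites used while scoring
#'   placements (the alignment is subsampled proportionally to pattern
#'   weight); the default uses every site
#' @return an unrooted phylo tree
#' @export
stepwiseAdditionTree <- function(alignment, model, seed = 1L, tNew = 0.1,
                                 ctx = NULL, maxSites = Inf) {
  if (is.null(ctx)) ctx <- .mkContext(alignment, model)
  ctx <- .ctxThin(ctx, maxSites, seed = seed)
  taxa <- ctx$taxa
  if (length(taxa) < 4L) {
    tr <- ape::stree(length(taxa), tip.label = taxa)
    tr$edge.length <- rep(tNew, nrow(tr$edge))
    return(tr)
  }
  ord <- withr::with_seed(seed, sample(taxa))
  tree <- ape::stree(3, tip.label = ord[1:3])
  tree$edge.length <- rep(tNew, 3L)
  for (i in 4:length(ord)) {
    tree <- .normalizeTree(tree)
    tipm <- ctx$tip[tree$tip.label, , drop = FALSE]
    scores <- .phylo_placement(tree$edge, length(tree$tip.label),
                               tree$edge.length, tipm, ctx$w, ctx$subset,
                               ctx$models, ctx$tip[ord[i], ], tNew)
    tree <- .addTip(tree, ord[i], which.max(scores), tNew)
    if (i %% 6L == 0L || i == length(ord))
      tree <- .ctxOptimBlens(ctx, tree, nsweeps = 1L)$tree
  }
  tree
}

# --- NNI hill climbing -------------------------------------------------------

.nniOnce <- function(ctx, tree, tol = 1e-4, w = NULL) {
  tree <- .normalizeTree(tree)
  tipm <- ctx$tip[tree$tip.label, , drop = FALSE]
  ev <- .phylo_nni_eval(tree$edge, length(tree$tip.label), tree$edge.length,
                        tipm, w %||% ctx$w, ctx$subset, ctx$models)
  if (nrow(ev) == 0L)
    return(list(tree = tree, logLik = .ctxLoglik(ctx, tree, w), improved = FALSE))
  cur <- max(ev$lnl_cur)
  cand <- pmax(ev$lnl_swapSC, ev$lnl_swapSD)
  bi <- which.max(cand)
  if (cand[bi] - cur <= tol)
    return(list(tree = tree, logLik = cur, improved = FALSE))
  useSC <- ev$lnl_swapSC[bi] >= ev$lnl_swapSD[bi]
  tree2 <- .applyNni(tree, ev$u[bi], ev$v[bi], ev$S[bi],
                     if (useSC) ev$C[bi] else ev$D[bi])
  list(tree = tree2, logLik = cand[bi], improved = TRUE)
}

#' NNI hill-climbing search (single replicate)
#'
#' Repeated nearest-neighbour-interchange sweeps from a starting tree,
#' accepting the best improving rearrangement per sweep and re-optimising
#' branch lengths after accepted swaps, until no neighbour improves the
#' log-likelihood by more than \code{tol}.
#'
#' @param startTree phylo starting tree with branch lengths
#' @param alignment character matrix / named vector / SuperMatrix
#' @param model GTRParams or PartitionScheme
#' @param tol minimum log-likelihood improvement to accept a move
#' @param optimizeBlens re-optimise branch lengths during the climb
#' @return list(tree, logLik)
#' @export
nniSearch <- function(startTree, alignment, model, tol = 1e-4,
                      optimizeBlens = TRUE) {
  ctx <- .mkContext(alignment, model)
  .ctxNniSearch(ctx, startTree, tol = tol, optimizeBlens = optimizeBlens)
}

# one tip-reinsertion (single-taxon SPR) pass: every tip is pruned and
# re-placed on its likelihood-optimal edge (same placement kernel as
# stepwise addition).  The pass is accepted only if the branch-length
# optimised log-likelihood improves on the starting tree.
.ctxSprPass <- function(ctx, tree, ll0, w = NULL, tNew = 0.1) {
  cand <- tree
  for (tip in cand$tip.label) {
    t2 <- .normalizeTree(ape::drop.tip(cand, tip))
    tipm <- ctx$tip[t2$tip.label, , drop = FALSE]
    scores <- .phylo_placement(t2$edge, length(t2$tip.label), t2$edge.length,
                               tipm, w %||% ctx$w, ctx$subset, ctx$models,
                               ctx$tip[tip, ], tNew)
    cand <- .addTip(t2, tip, which.max(scores), tNew)
  }
  res <- .ctxOptimBlens(ctx, cand, nsweeps = 2L, w = w)
  if (res$logLik > ll0) list(tree = res$tree, logLik = res$logLik,
                             improved = TRUE)
  else list(tree = tree, logLik = ll0, improved = FALSE)
}

# full hill climb: alternate NNI convergence with tip-reinsertion passes
# until neither improves
.ctxTreeSearch <- function(ctx, tree, tol = 1e-4, w = NULL, maxCycles = 5L) {
  res <- .ctxNniSearch(ctx, tree, tol = tol, w = w)
  for (cyc in seq_len(maxCycles)) {
    spr <- .ctxSprPass(ctx, res$tree, res$logLik, w = w)
    if (!spr$improved) break
    res <- .ctxNniSearch(ctx, spr$tree, tol = tol, w = w)
    if (res$logLik < spr$logLik) res <- spr
  }
  res
}

.ctxNniSearch <- function(ctx, tree, tol = 1e-4, optimizeBlens = TRUE,
                          w = NULL, maxMoves = 200L) {
  if (optimizeBlens) tree <- .ctxOptimBlens(ctx, tree, nsweeps = 2L, w = w)$tree
  moves <- 0L
  sinceOpt <- 0L
  res <- list(tree = tree, logLik = NA_real_)
  repeat {
    step <- .nniOnce(ctx, res$tree, tol = tol, w = w)
    if (!step$improved) { res$logLik <- step$logLik; break }
    res$tree <- step$tree; res$logLik <- step$logLik
    moves <- moves + 1L; sinceOpt <- sinceOpt + 1L
    if (optimizeBlens && sinceOpt >= 3L) {
      res <- .ctxOptimBlens(ctx, res$tree, nsweeps = 1L, w = w)
      sinceOpt <- 0L
    }
    if (moves >= maxMoves) break
  }
  if (optimizeBlens) res <- .ctxOptimBlens(ctx, res$tree, nsweeps = 2L, w = w)
  res
}

# --- model parameter optimisation -------------------------------------------

# pack/unpack GTRParams to an unconstrained vector (GT exchangeability = 1)
.packGtr <- function(p, fitPinv = TRUE) {
  c(log(p@rates[1:5] / p@rates[6]), log(p@freqs[1:3] / p@freqs[4]),
    log(p@alpha), if (fitPinv) qlogis(min(max(p@pinv, 1e-4), 0.98)))
}
.unpackGtr <- function(th, k, fitPinv = TRUE, pinv0 = 0) {
  r <- c(exp(th[1:5]), 1)
  f <- exp(c(th[6:8], 0)); f <- f / sum(f)
  gtrParams(rates = r, freqs = f,
            pinv = if (fitPinv) plogis(th[10]) else pinv0,
            alpha = min(exp(th[9]), 1e3), k = k)
}

# optimise model parameters for one subset on fixed tree/branch lengths;
# site patterns are compressed once (via ctx) and only the 4x4 model
# rebuild happens per objective evaluation
.optimizeGtrParams <- function(tree, alignment, start, maxit = 120,
                               fitPinv = TRUE, ctx = NULL) {
  if (is.null(ctx)) ctx <- .mkContext(alignment, start)
  tree <- .normalizeTree(tree)
  tipm <- ctx$tip[tree$tip.label, , drop = FALSE]
  nTip <- length(tree$tip.label)
  nc <- length(ctx$subsetOfCol)
  fn <- function(th) {
    p <- try(.unpackGtr(th, start@k, fitPinv, start@pinv), silent = TRUE)
    if (inherits(p, "try-error")) return(1e10)
    m <- try(.engineModels(p, nCols = nc)$models, silent = TRUE)
    if (inherits(m, "try-error")) return(1e10)
    ll <- try(.phylo_loglik(tree$edge, nTip, tree$edge.length, tipm, ctx$w,
                            ctx$subset, m)$loglik, silent = TRUE)
    if (inherits(ll, "try-error") || !is.finite(ll)) return(1e10)
    -ll
  }
  th0 <- .packGtr(start, fitPinv)
  opt <- optim(th0, fn, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-7))
  list(params = .unpackGtr(opt$par, start@k, fitPinv, start@pinv),
       logLik = -opt$value)
}

# empirical starting model from the data
.empiricalStart <- function(alignment, k = 4L, pinv = 0.1, alpha = 1) {
  if (is(alignment, "SuperMatrix")) alignment <- alignment@seqs
  if (!is.matrix(alignment)) alignment <- .seqsToMatrix(alignment)
  tab <- table(factor(alignment, levels = c("A", "C", "G", "T")))
  f <- (as.numeric(tab) + 1) / (sum(tab) + 4)
  gtrParams(rates = rep(1, 6), freqs = f, pinv = pinv, alpha = alpha, k = k)
}

#' Joint optimisation of branch lengths and model parameters
#'
#' Coordinate ascent alternating per-edge bracketed branch-length
#' optimisation with Nelder-Mead optimisation of the substitution-model
#' parameters, until the log-likelihood improves by less than \code{tol}.
#' For a partitioned model each subset's parameters (and its rate
#' multiplier) are optimised on its own columns; multipliers are then
#' renormalised to a data-weighted mean of 1 with branch lengths rescaled
#' to compensate, leaving the likelihood unchanged.
#'
#' @param tree phylo tree with branch lengths
#' @param alignment character matrix / named vector / SuperMatrix
#' @param model GTRParams or PartitionScheme (starting values)
#' @param maxRounds maximum alternation rounds
#' @param tol convergence tolerance on the log-likelihood
#' @param fitModel also optimise model parameters (otherwise branch lengths only)
#' @param fitSites cap on the effective number of sites used inside the
#'   Nelder-Mead model-parameter objective (weight-proportional pattern
#'   subsample); branch lengths and all reported likelihoods always use the
#'   full data
#' @return list(tree, model, logLik)
#' @export
mlOptimize <- function(tree, alignment, model, maxRounds = 3L, tol = 1e-2,
                       fitModel = TRUE, fitSites = Inf) {
  if (is(alignment, "SuperMatrix")) alignment <- alignment@seqs
  if (!is.matrix(alignment)) alignment <- .seqsToMatrix(alignment)
  ctx <- .mkContext(alignment, model)
  fitCtx <- .ctxThin(ctx, fitSites, seed = 1L)
  thinned <- length(fitCtx$w) < length(ctx$w)
  partitioned <- !is(model, "GTRParams")
  if (partitioned && fitModel) {
    subCtx <- lapply(seq_along(model@models), function(s)
      .mkContext(alignment[, model@subsetOf == s, drop = FALSE],
                 model@models[[s]]))
  }
  prev <- -Inf
  for (round in seq_len(maxRounds)) {
    ctx <- .ctxRemodel(ctx, model)
    ob <- .ctxOptimBlens(ctx, tree, nsweeps = 3L)
    tree <- ob$tree; ll <- ob$logLik
    if (fitModel) {
      if (!partitioned) {
        fit <- .optimizeGtrParams(tree, NULL, model,
                                  ctx = if (thinned) fitCtx else ctx)
        model <- fit$params
        ll <- if (thinned) .ctxLoglik(.ctxRemodel(ctx, model), tree)
              else fit$logLik
      } else {
        nSub <- length(model@models)
        mults <- model@multipliers
        nCols <- tabulate(model@subsetOf, nSub)
        for (s in seq_len(nSub)) {
          trS <- tree; trS$edge.length <- tree$edge.length * mults[s]
          fit <- .optimizeGtrParams(trS, NULL, model@models[[s]],
                                    ctx = subCtx[[s]])
          model@models[[s]] <- fit$params
          sctx <- .ctxRemodel(subCtx[[s]], model@models[[s]])
          # refit multiplier by 1-D search on this subset
          om <- optimize(function(lm) {
            trS2 <- tree; trS2$edge.length <- tree$edge.length * exp(lm)
            .ctxLoglik(sctx, trS2)
          }, interval = log(c(0.05, 20)), maximum = TRUE, tol = 1e-3)
          mults[s] <- exp(om$maximum)
        }
        wm <- sum(mults * nCols) / sum(nCols)
        model@multipliers <- mults / wm
        tree$edge.length <- tree$edge.length * wm
        ctx <- .ctxRemodel(ctx, model)
        ll <- .ctxLoglik(ctx, tree)
      }
    }
    if (ll - prev < tol) break
    prev <- ll
  }
  list(tree = tree, model = model, logLik = ll)
}

# --- bootstrap, consensus, support, RF --------------------------------------

# resample pattern weights: column bootstrap within partition subsets
.bootstrapWeights <- function(ctx, seed) {
  withr::with_seed(seed, {
    w <- numeric(length(ctx$w))
    for (s in unique(ctx$subset)) {
      i <- which(ctx$subset == s)
      n <- round(sum(ctx$w[i]))
      w[i] <- as.numeric(rmultinom(1, n, ctx$w[i] / sum(ctx$w[i])))
    }
    w
  })
}

#' Nonparametric bootstrap replicate trees
#'
#' Each replicate resamples alignment columns with replacement (within
#' partition subsets for partitioned models, preserving each subset's column
#' count), then runs an NNI search started from \code{startTree} with
#' branch lengths and model held at their ML estimates.
#'
#' @param alignment character matrix / named vector / SuperMatrix
#' @param model GTRParams or PartitionScheme (ML estimates)
#' @param startTree tree to start each replicate search from
#' @param nReps number of replicates
#' @param seed integer seed
#' @param optimizeBlens re-optimise branch lengths within each replicate
#' @return list of phylo trees (class multiPhylo)
#' @export
bootstrapReplicates <- function(alignment, model, startTree, nReps = 100L,
                                seed = 1L, optimizeBlens = FALSE) {
  ctx <- .mkContext(alignment, model)
  trees <- vector("list", nReps)
  for (r in seq_len(nReps)) {
    w <- .bootstrapWeights(ctx, childSeed(seed, r))
    # patterns drawn zero times contribute nothing: search a reduced view
    keep <- which(w > 0)
    cv <- ctx
    cv$tip <- ctx$tip[, keep, drop = FALSE]
    cv$subset <- ctx$subset[keep]
    res <- .ctxNniSearch(cv, startTree, optimizeBlens = optimizeBlens,
                         w = w[keep])
    trees[[r]] <- res$tree
  }
  class(trees) <- "multiPhylo"
  trees
}

# bipartitions of an unrooted tree as canonical tip-name strings; each split
# is represented by the side NOT containing the alphabetically first label,
# so the encoding is identical across trees whatever their tip ordering
.splits <- function(tree) {
  tree <- ape::unroot(tree)
  nT <- length(tree$tip.label)
  anchor <- which(tree$tip.label == min(tree$tip.label))[1]
  desc <- .tipDescendants(tree)
  out <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    if (ch <= nT) next
    side <- desc[[ch]]
    if (length(side) <= 1L || length(side) >= nT - 1L) next
    if (anchor %in% side) side <- setdiff(seq_len(nT), side)
    out <- c(out, paste(sort(tree$tip.label[side]), collapse = "|"))
  }
  unique(out)
}

.tipDescendants <- function(tree) {
  nT <- length(tree$tip.label)
  nN <- max(tree$edge)
  desc <- vector("list", nN)
  for (i in seq_len(nT)) desc[[i]] <- i
  edges <- reorder(tree, "postorder")$edge
  for (e in seq_len(nrow(edges)))
    desc[[edges[e, 1]]] <- c(desc[[edges[e, 1]]], desc[[edges[e, 2]]])
  desc
}

#' Robinson-Foulds distance
#'
#' Symmetric-difference count of the non-trivial bipartitions of two
#' unrooted trees on the same leaf set.
#'
#' @param a,b phylo trees with identical tip labels
#' @return non-negative integer
#' @export
rfDistance <- function(a, b) {
  if (!setequal(a$tip.label, b$tip.label)) stop("trees must share one leaf set")
  sa <- .splits(a); sb <- .splits(b)
  length(setdiff(sa, sb)) + length(setdiff(sb, sa))
}

#' Majority-rule consensus tree
#'
#' Contains exactly the bipartitions present in more than half of the input
#' trees; internal nodes are labelled with their percentage occurrence.
#'
#' @param trees list / multiPhylo of trees on one leaf set
#' @return phylo consensus tree with node labels giving support percentages
#' @export
majorityRuleConsensus <- function(trees) {
  class(trees) <- "multiPhylo"
  labs <- lapply(trees, function(t) sort(t$tip.label))
  if (length(unique(vapply(labs, paste, character(1), collapse = "|"))) != 1L)
    stop("all trees must share one leaf set")
  cons <- ape::consensus(trees, p = 0.5)
  counts <- .splitSupport(cons, trees)
  cons$node.label <- counts
  cons
}

# per-internal-node support (% of trees containing that node's bipartition);
# root of an unrooted consensus gets an empty label
.splitSupport <- function(target, trees) {
  tab <- table(unlist(lapply(trees, .splits)))
  nT <- length(target$tip.label)
  anchor <- which(target$tip.label == min(target$tip.label))[1]
  # descendant sets on the target exactly as labelled: node numbering must
  # match the tree whose node.label slot receives these values
  desc <- .tipDescendants(target)
  nodes <- (nT + 1L):max(target$edge)
  vapply(nodes, function(nd) {
    side <- desc[[nd]]
    if (length(side) %in% c(0L, nT)) return("")
    if (anchor %in% side) side <- setdiff(seq_len(nT), side)
    if (length(side) <= 1L || length(side) >= nT - 1L) return("")
    key <- paste(sort(target$tip.label[side]), collapse = "|")
    n <- if (key %in% names(tab)) tab[[key]] else 0L
    sprintf("%.1f", 100 * n / length(trees))
  }, character(1))
}

#' Map bootstrap support onto a best tree
#'
#' Annotates each internal edge of \code{bestTree} with the percentage of
#' \code{trees} containing the same bipartition.
#'
#' @param bestTree phylo tree to annotate
#' @param trees bootstrap trees on the same leaf set
#' @return \code{bestTree} with node labels giving support percentages
#' @export
mapSupport <- function(bestTree, trees) {
  bestTree$node.label <- .splitSupport(bestTree, trees)
  bestTree
}

# --- top-level search --------------------------------------------------------

#' Maximum-likelihood tree inference with bootstrap
#'
#' Runs \code{nReplicates} seeded search replicates (stepwise-addition
#' starting tree followed by NNI hill climbing), keeps the best tree,
#' re-optimises it jointly with the model, then runs the nonparametric
#' bootstrap and builds the majority-rule consensus and the support-mapped
#' best tree.
#'
#' @param alignment character matrix / named vector / SuperMatrix
#' @param model starting GTRParams or PartitionScheme (NULL = empirical start)
#' @param nReplicates number of independent search replicates
#' @param nBootstrap number of bootstrap replicates (0 = none)
#' @param seed master integer seed
#' @param fitModel optimise model parameters (once, on an initial tree)
#' @param heuristicSites cap on the effective number of sites used by the
#'   heuristic stages (starting trees, replicate NNI climbs and the model-fit
#'   objective) via weight-proportional pattern subsampling.  Replicates are
#'   ranked, the best tree refined, and all reported likelihoods computed on
#'   the full data.  Use \code{Inf} to disable thinning everywhere.
#' @param verbose print progress
#' @return a \linkS4class{TreeSearchResult}
#' @export
mlTreeSearch <- function(alignment, model = NULL, nReplicates = 10L,
                         nBootstrap = 0L, seed = 1L, fitModel = TRUE,
                         heuristicSites = 5000L, verbose = FALSE) {
  if (is(alignment, "SuperMatrix")) alignment <- alignment@seqs
  if (!is.matrix(alignment)) alignment <- .seqsToMatrix(alignment)
  if (is.null(model)) model <- .empiricalStart(alignment)
  # model fit on a quick initial tree, then held fixed across replicates
  if (fitModel) {
    t0 <- stepwiseAdditionTree(alignment, model, seed = childSeed(seed, 1000L),
                               maxSites = heuristicSites)
    fit <- mlOptimize(t0, alignment, model, maxRounds = 2L,
                      fitSites = heuristicSites)
    model <- fit$model
    .msg(sprintf("model fit: lnL %.3f", fit$logLik), verbose = verbose)
  }
  ctx <- .mkContext(alignment, model)
  hctx <- .ctxThin(ctx, heuristicSites, seed = childSeed(seed, 2000L))
  thinned <- length(hctx$w) < length(ctx$w)
  reps <- data.frame(replicate = integer(), logLik = numeric(), seed = integer())
  best <- NULL; bestLl <- -Inf
  for (r in seq_len(nReplicates)) {
    sr <- childSeed(seed, r)
    start <- stepwiseAdditionTree(alignment, model, seed = sr, ctx = hctx)
    res <- .ctxTreeSearch(hctx, start)
    # rank replicates on the full data so thinning never picks the best tree
    ll <- if (thinned) .ctxLoglik(ctx, res$tree) else res$logLik
    reps <- rbind(reps, data.frame(replicate = r, logLik = ll, seed = sr))
    if (ll > bestLl) { bestLl <- ll; best <- res$tree }
    .msg(sprintf("replicate %d: lnL %.3f", r, ll), verbose = verbose)
  }
  # refine the winner on the full data (a no-op sweep when nothing changes);
  # NNI suffices here because the tip-reinsertion escapes already ran per
  # replicate; the winning replicate keeps its refined log-likelihood
  if (thinned) {
    full <- .ctxNniSearch(ctx, best)
    best <- full$tree; bestLl <- full$logLik
    reps$logLik[which.max(reps$logLik)] <- bestLl
  }
  final <- mlOptimize(best, alignment, model, maxRounds = 2L,
                      fitModel = fitModel, fitSites = heuristicSites)
  if (final$logLik > bestLl) {
    bestLl <- final$logLik; best <- final$tree; model <- final$model
    reps$logLik[which.max(reps$logLik)] <- bestLl
  }
  bs <- list(); consTree <- NULL; supTree <- NULL
  if (nBootstrap > 0L) {
    bs <- bootstrapReplicates(alignment, model, best, nReps = nBootstrap,
                              seed = childSeed(seed, 5000L))
    consTree <- majorityRuleConsensus(bs)
    supTree <- mapSupport(best, bs)
  }
  new("TreeSearchResult", bestTree = best, logLik = bestLl, replicates = reps,
      model = model, bootstrapTrees = unclass(bs), consensus = consTree,
      supportTree = supTree)
}
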