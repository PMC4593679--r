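# Felsenstein pruning likelihood under GTR+I+G, with pattern compression.
# The numerical core lives in src/phylo.cpp; this file prepares the data
# (IUPAC masks, site-pattern compression, tree normalisation) and exposes
# the user-facing likelihood function.

# Normalise a phylo tree for the engine: node nTip+1 is the traversal root,
# edge rows parent -> child. Accepts rooted or unrooted binary trees.
.normalizeTree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape phylo object")
  reorder(tree, "cladewise")
}

# Re-derive a valid phylo object from an arbitrary (possibly reoriented)
# edge matrix after tree surgery: DFS from root relabels internal nodes.
.rebuildPhylo <- function(edge, blen, tipLabels) {
  nTip <- length(tipLabels)
  root <- nTip + 1L
  nNode <- max(edge)
  adj <- vector("list", nNode)
  eid <- vector("list", nNode)
  for (r in seq_len(nrow(edge))) {
    a <- edge[r, 1]; b <- edge[r, 2]
    adj[[a]] <- c(adj[[a]], b); eid[[a]] <- c(eid[[a]], r)
    adj[[b]] <- c(adj[[b]], a); eid[[b]] <- c(eid[[b]], r)
  }
  # DFS assigning new internal ids in pre-order
  newId <- integer(nNode)
  newId[seq_len(nTip)] <- seq_len(nTip)
  nextInternal <- root
  stack <- root; parent <- integer(nNode)
  outE <- matrix(0L, nrow(edge), 2); outL <- numeric(nrow(edge)); k <- 0L
  while (length(stack)) {
    x <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (x > nTip) { newId[x] <- nextInternal; nextInternal <- nextInternal + 1L }
    for (i in seq_along(adj[[x]])) {
      y <- adj[[x]][i]
      if (parent[x] == y) next
      parent[y] <- x
      k <- k + 1L
      outE[k, ] <- c(x, y)   # old ids; remap below
      outL[k] <- blen[eid[[x]][i]]
      stack <- c(stack, y)
    }
  }
  # remap requires children visited after parents: outE rows follow DFS order
  outE[] <- newId[outE]
  tr <- list(edge = outE, edge.length = outL, tip.label = tipLabels,
             Nnode = nNode - nTip)
  class(tr) <- "phylo"
  attr(tr, "order") <- NULL
  reorder(tr, "cladewise")
}

# character alignment matrix -> integer mask matrix (taxa x columns)
.maskMatrix <- function(seqMat) {
  m <- matrix(nucMask(seqMat), nrow = nrow(seqMat))
  rownames(m) <- rownames(seqMat)
  m
}

# compress columns to unique (pattern, subset) pairs; returns tip matrix,
# weights, 0-based subset ids sorted by subset
.compressPatterns <- function(maskMat, subsetOf) {
  key <- paste(subsetOf, apply(maskMat, 2L, paste, collapse = ","), sep = "|")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  w <- tabulate(idx, nbins = sum(first))
  tip <- maskMat[, first, drop = FALSE]
  sub <- subsetOf[first]
  ord <- order(sub)
  list(tip = tip[, ord, drop = FALSE], w = as.numeric(w[ord]),
       subset = as.integer(sub[ord] - 1L))
}

# Assemble engine inputs for one (tree, alignment, model) triple.
.engineInputs <- function(tree, alignment, model) {
  tree <- .normalizeTree(tree)
  if (is(alignment, "SuperMatrix")) alignment <- alignment@seqs
  if (!is.matrix(alignment)) alignment <- .seqsToMatrix(alignment)
  if (ncol(alignment) == 0L) stop("zero-length alignment")
  if (!all(tree$tip.label %in% rownames(alignment)))
    stop("alignment must contain a row for every tree tip")
  alignment <- alignment[tree$tip.label, , drop = FALSE]
  em <- .engineModels(model, nCols = ncol(alignment))
  if (length(em$subsetOfCol) != ncol(alignment))
    stop("partition subsetOf length must equal alignment columns")
  pat <- .compressPatterns(.maskMatrix(alignment), em$subsetOfCol)
  list(tree = tree, edge = tree$edge, nTip = length(tree$tip.label),
       blen = tree$edge.length, tip = pat$tip, w = pat$w,
       subset = pat$subset, models = em$models)
}

#' Log-likelihood of a tree under GTR+I+G
#'
#' Felsenstein pruning over site patterns with per-node rescaling. IUPAC
#' ambiguity codes (including those produced by degeneracy coding and
#' in-paralogue consensus) are treated as partial information: a tip with
#' code R contributes likelihood 1 for states A and G. The per-site
#' likelihood is \code{pinv * L_inv + (1 - pinv) * mean_c L_c} where the
#' invariant term is non-zero only for columns compatible with a constant
#' site and \code{L_c} are the discrete-gamma category likelihoods, with
#' category rates scaled by \code{1 / (1 - pinv)} (the standard I+G
#' convention keeping the mixture's mean rate at 1, so branch lengths stay
#' in expected substitutions per site).
#'
#' @param tree ape phylo tree (branch lengths required)
#' @param alignment character matrix (rows = taxa), named character vector of
#'   equal-length sequences, or a \linkS4class{SuperMatrix}
#' @param model \linkS4class{GTRParams} or \linkS4class{PartitionScheme}
#' @return log-likelihood (numeric scalar)
#' @export
treeLogLikelihood <- function(tree, alignment, model) {
  inp <- .engineInputs(tree, alignment, model)
  .phylo_loglik(inp$edge, inp$nTip, inp$blen, inp$tip, inp$w, inp$subset,
                inp$models)$loglik
}
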