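# Independent reference implementations ("oracles") used by the tests.
# Each is written as naively as possible -- direct transcription of the
# defining formulas, with no shared code paths with the package internals.

# --- alignment oracles -------------------------------------------------------

# brute-force Smith-Waterman by enumerating all local alignments of short
# sequences (gap of length k costs open + k * ext). Recursive expansion over
# all (start, path) combinations; exponential, only for <= ~8 residues.
oracleSwScore <- function(q, t, score, gapOpen, gapExt) {
  qn <- length(q); tn <- length(t)
  best <- 0
  # H[i][j]: best alignment ending exactly at (i, j); recompute by recursion
  memo <- new.env()
  rec <- function(i, j, state) {
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <-
      if (state == "M") {
        s <- score[q[i], t[j]]
        cand <- 0
        if (i > 1 && j > 1)
          cand <- max(rec(i - 1, j - 1, "M"), rec(i - 1, j - 1, "E"),
                      rec(i - 1, j - 1, "F"), 0)
        s + max(cand, 0)
      } else if (state == "E") { # gap in query (consumes target)
        if (j <= 1) -Inf else
          max(rec(i, j - 1, "M") - gapOpen - gapExt,
              rec(i, j - 1, "E") - gapExt)
      } else {                   # gap in target (consumes query)
        if (i <= 1) -Inf else
          max(rec(i - 1, j, "M") - gapOpen - gapExt,
              rec(i - 1, j, "F") - gapExt)
      }
    memo[[key]] <- out
    out
  }
  for (i in seq_len(qn)) for (j in seq_len(tn))
    best <- max(best, rec(i, j, "M"))
  best
}

# --- substitution-matrix oracle ----------------------------------------------

# direct transcription: single-linkage weights, per-column weighted pair
# counts, half-count fold, pseudocount, log-odds. Independent of the package
# implementation (no rle tricks, no index arithmetic shared).
oracleLogOdds <- function(blocks, threshold = 0.50, scale = 0.5) {
  aa <- cladophylo:::AMINO_ACIDS
  f <- matrix(0, 20, 20, dimnames = list(aa, aa))
  for (b in blocks) {
    m <- b$seqs
    n <- nrow(m)
    if (n < 2) next
    # single linkage: repeatedly merge any two components containing a pair
    # with identity >= threshold
    comp <- as.list(seq_len(n))
    repeat {
      merged <- FALSE
      for (x in seq_along(comp)) {
        for (y in seq_along(comp)) {
          if (x >= y) next
          hit <- FALSE
          for (i in comp[[x]]) for (j in comp[[y]]) {
            if (mean(m[i, ] == m[j, ]) >= threshold) hit <- TRUE
          }
          if (hit) {
            comp[[x]] <- c(comp[[x]], comp[[y]])
            comp <- comp[-y]
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (!merged) break
    }
    w <- numeric(n)
    for (cmp in comp) for (i in cmp) w[i] <- 1 / length(cmp)
    for (col in seq_len(ncol(m))) {
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        a1 <- m[i, col]; a2 <- m[j, col]
        f[a1, a2] <- f[a1, a2] + w[i] * w[j]
        if (a1 != a2) f[a2, a1] <- f[a2, a1] + w[i] * w[j]
      }
    }
  }
  q <- f
  for (i in 1:20) for (j in 1:20) if (i != j) q[i, j] <- q[i, j] / 2
  if (any(q == 0)) q <- q + 1
  q <- q / sum(q)
  p <- rowSums(q)
  s <- matrix(0L, 20, 20, dimnames = dimnames(q))
  for (i in 1:20) for (j in 1:20)
    s[i, j] <- as.integer(round(log2(q[i, j] / (p[i] * p[j])) / scale))
  list(q = q, p = p, s = s)
}

# --- likelihood oracles ------------------------------------------------------

# GTR rate matrix, directly from the definition
oracleQ <- function(rates, freqs) {
  Q <- matrix(0, 4, 4, dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
  pairs <- rbind(c(1,2), c(1,3), c(1,4), c(2,3), c(2,4), c(3,4))
  for (k in 1:6) {
    i <- pairs[k,1]; j <- pairs[k,2]
    Q[i, j] <- rates[k] * freqs[j]
    Q[j, i] <- rates[k] * freqs[i]
  }
  diag(Q) <- -rowSums(Q)
  Q / sum(-diag(Q) * freqs)
}

# exhaustive likelihood: sum over all internal-node state assignments
oracleLoglik <- function(tree, alignment, params) {
  freqs <- params@freqs
  Q <- oracleQ(params@rates, freqs)
  k <- params@k
  # standard I+G convention: variable-site category rates are scaled by
  # 1/(1-pinv) so the mixture's mean rate stays 1
  rates <- cladophylo::discreteGammaRates(params@alpha, k) / (1 - params@pinv)
  bases <- c("A", "C", "G", "T")
  tree <- reorder(tree, "cladewise")
  nTip <- length(tree$tip.label)
  nNode <- max(tree$edge)
  root <- nTip + 1L
  aln <- alignment[tree$tip.label, , drop = FALSE]
  masks <- matrix(cladophylo:::nucMask(aln), nrow = nrow(aln))
  total <- 0
  for (col in seq_len(ncol(aln))) {
    # invariant-site term: compatible constant states
    linv <- 0
    for (x in 1:4) {
      ok <- all(bitwAnd(masks[, col], bitwShiftL(1L, x - 1L)) > 0L)
      if (ok) linv <- linv + freqs[x]
    }
    lvar <- 0
    for (r in rates) {
      P <- lapply(tree$edge.length, function(t) Matrix::expm(Q * t * r))
      # enumerate all internal states
      nInt <- nNode - nTip
      lsum <- 0
      grid <- do.call(expand.grid, rep(list(1:4), nInt))
      for (g in seq_len(nrow(grid))) {
        state <- integer(nNode)
        state[(nTip + 1L):nNode] <- as.integer(grid[g, ])
        # tips: sum over compatible states
        term <- freqs[state[root]]
        for (e in seq_len(nrow(tree$edge))) {
          a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
          Pe <- as.matrix(P[[e]])
          if (b <= nTip) {
            s <- 0
            for (x in 1:4)
              if (bitwAnd(masks[b, col], bitwShiftL(1L, x - 1L)) > 0L)
                s <- s + Pe[state[a], x]
            term <- term * s
          } else {
            term <- term * Pe[state[a], state[b]]
          }
        }
        lsum <- lsum + term
      }
      lvar <- lvar + lsum / k
    }
    lik <- params@pinv * linv + (1 - params@pinv) * lvar
    total <- total + log(lik)
  }
  total
}

# closed-form Jukes-Cantor likelihood for two sequences separated by t
oracleJc2 <- function(seq1, seq2, t) {
  pSame <- 1/4 + 3/4 * exp(-4 * t / 3)
  pDiff <- 1/4 - 1/4 * exp(-4 * t / 3)
  s1 <- strsplit(seq1, "")[[1]]; s2 <- strsplit(seq2, "")[[1]]
  sum(ifelse(s1 == s2, log(pSame / 4), log(pDiff / 4)) + log(4) + log(1/4))
}

# --- paralogy oracle ---------------------------------------------------------

# clan test by exhaustive bipartition enumeration with ape::prop.part on the
# tree rooted at each possible edge -- independent mechanism: collect every
# edge-induced tip-label split of the unrooted tree via ape's bipartition
# machinery and check both sides.
oracleIsClan <- function(tree, leaves) {
  nTip <- length(tree$tip.label)
  if (length(leaves) <= 1L) return(TRUE)
  if (length(leaves) == nTip) return(TRUE)
  ut <- ape::unroot(tree)
  pp <- ape::prop.part(ut)
  all <- ut$tip.label
  sides <- list()
  for (p in pp) sides[[length(sides) + 1L]] <- ut$tip.label[p]
  # pendant edges give singleton sides too
  for (tp in all) sides[[length(sides) + 1L]] <- tp
  for (s in sides) {
    if (setequal(s, leaves) || setequal(setdiff(all, s), leaves)) return(TRUE)
  }
  FALSE
}

# --- misc --------------------------------------------------------------------

# random unrooted binary tree with labelled tips
randomTree <- function(n, seed, labels = NULL) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n, rooted = FALSE)
    if (!is.null(labels)) tr$tip.label <- labels
    tr
  })
}

# random gapped alignment matrix
randomAln <- function(nSeq, nCol, seed, alphabet = c("A","C","G","T"),
                      gapProb = 0.1, names = paste0("s", seq_len(nSeq))) {
  withr::with_seed(seed, {
    m <- matrix(sample(alphabet, nSeq * nCol, replace = TRUE), nrow = nSeq)
    m[matrix(runif(nSeq * nCol) < gapProb, nrow = nSeq)] <- "-"
    rownames(m) <- names
    m
  })
}
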