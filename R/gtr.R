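# GTR+I+G model machinery: rate matrix, discrete gamma, eigensystem prep.

#' Build the GTR generator matrix Q
#'
#' Off-diagonal entries are \code{Q[i, j] = r_ij * pi_j} with symmetric
#' exchangeabilities r (order AC, AG, AT, CG, CT, GT); diagonals make rows
#' sum to zero and the matrix is normalised so the mean substitution rate
#' \code{-sum(pi_i Q_ii)} equals 1. Detailed balance
#' \code{pi_i Q_ij = pi_j Q_ji} holds by construction.
#'
#' @param params a \linkS4class{GTRParams} object, or a numeric vector of six
#'   exchangeabilities (then \code{freqs} must be given)
#' @param freqs base frequencies when \code{params} is a plain vector
#' @return 4 x 4 numeric generator matrix with dimnames ACGT
#' @export
gtrRateMatrix <- function(params, freqs = NULL) {
  if (is(params, "GTRParams")) {
    r <- params@rates; pi <- params@freqs
  } else {
    r <- as.numeric(params); pi <- as.numeric(freqs)
  }
  if (length(r) != 6L || any(r <= 0)) stop("need 6 positive exchangeabilities")
  if (any(pi <= 0)) stop("zero or negative base frequency")
  Q <- matrix(0, 4, 4, dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
  idx <- rbind(c(1,2), c(1,3), c(1,4), c(2,3), c(2,4), c(3,4))
  for (e in seq_len(6)) {
    i <- idx[e, 1]; j <- idx[e, 2]
    Q[i, j] <- r[e] * pi[j]
    Q[j, i] <- r[e] * pi[i]
  }
  diag(Q) <- -rowSums(Q)
  Q / sum(-pi * diag(Q))
}

#' Discrete gamma rate categories
#'
#' Category rates are the means of the k equal-probability slices of a
#' Gamma(alpha, rate = alpha) distribution (mean 1), the classic
#' equal-weight discretisation.
#'
#' @param alpha gamma shape (> 0)
#' @param k number of categories (>= 1)
#' @return numeric vector of k rates with mean 1
#' @export
discreteGammaRates <- function(alpha, k) {
  stopifnot(alpha > 0, k >= 1)
  if (k == 1L) return(1.0)
  q <- qgamma(seq_len(k - 1) / k, shape = alpha, rate = alpha)
  # mean of a gamma slice via the incomplete-gamma identity
  cum <- pgamma(c(0, q, Inf), shape = alpha + 1, rate = alpha)
  rates <- k * diff(cum)
  rates / mean(rates) * 1  # guard tiny numerical drift; mean is 1 analytically
}

# eigendecomposition of Q via symmetrisation (pi^1/2 Q pi^-1/2 symmetric)
.gtrEigen <- function(Q, pi) {
  s <- sqrt(pi)
  S <- diag(s) %*% Q %*% diag(1 / s)
  eig <- eigen((S + t(S)) / 2, symmetric = TRUE)
  U <- diag(1 / s) %*% eig$vectors
  Uinv <- t(eig$vectors) %*% diag(s)
  list(U = U, Uinv = Uinv, lambda = eig$values)
}

# Build the per-subset model list consumed by the C++ engine.
# model: GTRParams or PartitionScheme; returns list(models=list, subsetOfCol=int)
.engineModels <- function(model, nCols = NULL) {
  asSub <- function(p, mult) {
    Q <- gtrRateMatrix(p)
    ei <- .gtrEigen(Q, p@freqs)
    # standard I+G convention: variable-site rates are scaled by 1/(1-pinv)
    # so the mixture keeps mean rate 1 and pinv decouples from the global
    # branch-length scale
    list(U = ei$U, Uinv = ei$Uinv, lambda = ei$lambda, pi = p@freqs,
         rates = discreteGammaRates(p@alpha, p@k) / (1 - p@pinv),
         pinv = p@pinv, mult = mult)
  }
  if (is(model, "GTRParams")) {
    list(models = list(asSub(model, 1)), subsetOfCol = rep(1L, nCols %||% 1L))
  } else if (is(model, "PartitionScheme")) {
    ks <- vapply(model@models, function(m) m@k, integer(1))
    if (length(unique(ks)) != 1L)
      stop("all subsets must use the same number of gamma categories")
    list(models = mapply(asSub, model@models, model@multipliers,
                         SIMPLIFY = FALSE),
         subsetOfCol = model@subsetOf)
  } else stop("model must be GTRParams or PartitionScheme")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
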