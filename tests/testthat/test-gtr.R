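test_that("GTR rate matrix matches the definition and is normalised", {
  p <- gtrParams(rates = c(1.2, 3.1, 0.8, 0.9, 4.0, 1.0),
                 freqs = c(0.3, 0.2, 0.25, 0.25))
  Q <- gtrRateMatrix(p)
  Qo <- oracleQ(p@rates, p@freqs)
  expect_equal(unname(Q), unname(Qo), tolerance = 1e-12)
  # rows sum to zero, expected rate is 1
  expect_equal(unname(rowSums(Q)), rep(0, 4), tolerance = 1e-12)
  expect_equal(sum(-diag(Q) * p@freqs), 1, tolerance = 1e-12)
  # detailed balance: pi_i q_ij = pi_j q_ji
  expect_equal(p@freqs * Q, t(p@freqs * Q), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("discrete gamma categories match numerical quadrature", {
  for (alpha in c(0.3, 0.8, 2.5)) {
    k <- 4L
    r <- discreteGammaRates(alpha, k)
    expect_equal(mean(r), 1, tolerance = 1e-12)
    expect_true(all(diff(r) > 0))
    # oracle: mean of each equal-probability slice by numeric integration
    qs <- c(0, qgamma(seq_len(k - 1) / k, alpha, rate = alpha), Inf)
    ro <- vapply(seq_len(k), function(i) {
      k * integrate(function(x) x * dgamma(x, alpha, rate = alpha),
                    qs[i], qs[i + 1], rel.tol = 1e-12)$value
    }, numeric(1))
    expect_equal(r, ro, tolerance = 1e-8)
  }
  expect_identical(discreteGammaRates(1.0, 1L), 1.0)
})

test_that("eigendecomposition reproduces the matrix exponential", {
  skip_if_not_installed("Matrix")
  p <- gtrParams(rates = c(2, 5, 1, 1.3, 6, 1), freqs = c(0.35, 0.15, 0.2, 0.3))
  Q <- gtrRateMatrix(p)
  ei <- cladophylo:::.gtrEigen(Q, p@freqs)
  for (t in c(0.01, 0.2, 1.5)) {
    P <- ei$U %*% diag(exp(ei$lambda * t)) %*% ei$Uinv
    Pref <- as.matrix(Matrix::expm(Q * t))
    expect_equal(P, Pref, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-10)
    expect_true(all(P > 0))
  }
})

test_that("GTRParams validity rejects bad inputs", {
  expect_error(gtrParams(rates = rep(1, 5)), "exchangeabilities")
  expect_error(gtrParams(freqs = c(0.5, 0.5, 0.5, 0.5)), "summing to 1")
  expect_error(gtrParams(pinv = 1), "pinv")
  expect_error(gtrParams(alpha = 0), "alpha")
})
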