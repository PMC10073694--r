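test_that("Fisher-z intervals behave and shrink with n", {
  ci1 <- fisherZCi(0.8, 20)
  ci2 <- fisherZCi(0.8, 50)
  ci3 <- fisherZCi(0.8, 200)
  expect_lt(ci2[2] - ci2[1], ci1[2] - ci1[1])
  expect_lt(ci3[2] - ci3[1], ci2[2] - ci2[1])
  expect_true(all(diff(c(ci1[1], 0.8, ci1[2])) > 0))
  expect_error(fisherZCi(0.5, 3), "n >= 4")
})

test_that("pearsonWithCi uses pairwise deletion and flags degeneracy", {
  x <- c(1, 2, 3, 4, 5, NA, 7)
  y <- c(2.1, 3.9, 6.2, 8.1, 9.8, 12, NA)
  pc <- pearsonWithCi(x, y)
  expect_identical(pc$n, 5L)
  expect_gt(pc$r, 0.99)
  expect_true(pc$ciLow <= pc$r && pc$r <= pc$ciHigh)

  exact <- pearsonWithCi(1:10, 2 * (1:10) + 3)
  expect_equal(exact$r, 1.0)

  expect_error(pearsonWithCi(rep(1, 6), 1:6), "zero variance")
  expect_error(pearsonWithCi(1:3, 1:3), ">= 4 complete pairs")
})

test_that("OLS fit recovers exact lines and matches r squared", {
  f <- linearFitR2(1:20, 2 * (1:20) + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r2, 1.0)

  withr::with_seed(14, {
    x <- rnorm(500)
    y <- rnorm(500)
  })
  expect_lt(linearFitR2(x, y)$r2, 0.02)   # independent variables

  xy <- withr::with_seed(15, list(x = rnorm(40), e = rnorm(40, 0, 0.5)))
  yy <- 3 * xy$x + xy$e
  expect_equal(linearFitR2(xy$x, yy)$r2, pearsonWithCi(xy$x, yy)$r^2,
               tolerance = 1e-9)

  expect_error(linearFitR2(rep(2, 10), 1:10), "degenerate")
})

test_that("Bland-Altman bias, limits, and CI follow their definitions", {
  a <- c(0.2, 0.5, 0.9, 0.4)
  ident <- blandAltman(a, a)
  expect_equal(ident$bias, 0)
  expect_equal(ident$sdDiff, 0)
  expect_equal(c(ident$loaLow, ident$loaHigh), c(0, 0))

  off <- blandAltman(a, a + 0.1)    # d = a - b convention
  expect_equal(off$bias, -0.1)
  expect_equal(off$sdDiff, 0)

  withr::with_seed(16, {
    b <- rnorm(100, 0.5, 0.2)
    d <- rnorm(100, 0.01, 0.05)
  })
  ba <- blandAltman(b + d, b)
  expect_equal(ba$loaHigh - ba$loaLow, 2 * 1.96 * ba$sdDiff)
  expect_true(ba$biasCiLow < ba$bias && ba$bias < ba$biasCiHigh)
  expect_gt(ba$loaHigh - ba$loaLow, ba$biasCiHigh - ba$biasCiLow)
  expect_equal(ba$means, (2 * b + d) / 2)
  expect_error(blandAltman(1:3, 1:4), "length mismatch")
})

test_that("factor analysis retains, rotates, and normalizes as documented", {
  ## one latent factor: exactly one eigenvalue > 1, >= 95% variance
  withr::with_seed(17, {
    g <- rnorm(200)
    X1 <- sapply(1:6, function(i) g + rnorm(200, 0, 0.15))
  })
  fa1 <- factorAnalysis(X1)
  expect_identical(fa1$nFactors, 1L)
  expect_identical(sum(fa1$eigenvalues > 1), 1L)
  expect_gte(fa1$totalVariance, 0.95)
  expect_true(all(fa1$loadings > 0))   # sign normalization

  ## eigenvalues of a correlation decomposition sum to the variable count
  expect_equal(sum(fa1$eigenvalues), 6, tolerance = 1e-9)

  ## two orthogonal latent blocks: clean varimax separation
  withr::with_seed(18, {
    g1 <- rnorm(200); g2 <- rnorm(200)
    X2 <- cbind(sapply(1:3, function(i) g1 + rnorm(200, 0, 0.1)),
                sapply(1:3, function(i) g2 + rnorm(200, 0, 0.1)))
  })
  fa2 <- factorAnalysis(X2)
  expect_identical(fa2$nFactors, 2L)
  own <- apply(abs(fa2$loadings), 1, max)
  cross <- apply(abs(fa2$loadings), 1, min)
  expect_true(all(own > 0.9))
  expect_true(all(cross < 0.2))

  ## varimax preserves communalities: compare to the unrotated PCA loadings
  R <- cor(X2)
  ee <- eigen(R, symmetric = TRUE)
  L <- ee$vectors[, 1:2] %*% diag(sqrt(ee$values[1:2]))
  expect_equal(unname(fa2$communalities), rowSums(L^2), tolerance = 1e-9)

  ## independent variables: no eigenvalue materially above 1
  withr::with_seed(19, X3 <- matrix(rnorm(200 * 6), ncol = 6))
  fa3 <- factorAnalysis(X3)
  expect_lt(max(fa3$eigenvalues), 1.5)

  ## forced extraction beyond the variable count is refused
  expect_error(factorAnalysis(X1, 9), "cannot extract")
  expect_error(factorAnalysis(X1[1:4, ]), "complete rows")
})
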