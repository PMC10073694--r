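## Cohort-level concurrent-validity statistics: Pearson correlations with
## Fisher-z intervals, OLS fits, Bland-Altman agreement, and varimax-rotated
## principal-component factor analysis.

#' Fisher-z confidence interval for a Pearson correlation
#'
#' `tanh(atanh(r) +/- z_{1-alpha/2} / sqrt(n - 3))`.
#'
#' @param r sample correlation.
#' @param n number of pairs (must be >= 4).
#' @param alpha two-sided significance level (default 0.05).
#' @return numeric `c(low, high)`.
#' @export
fisherZCi <- function(r, n, alpha = 0.05) {
  if (n < 4) stopf("Fisher-z interval needs n >= 4")
  z <- atanh(r)
  half <- stats::qnorm(1 - alpha / 2) / sqrt(n - 3)
  tanh(c(z - half, z + half))
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Pairwise deletion of incomplete pairs; errors on zero variance.
#'
#' @param x,y numeric vectors (may contain `NA`).
#' @param alpha two-sided significance level.
#' @return list with `n`, `r`, `ciLow`, `ciHigh`.
#' @export
pearsonWithCi <- function(x, y, alpha = 0.05) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stopf("need >= 4 complete pairs (have %d)", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stopf("zero variance")
  r <- stats::cor(x, y)
  ci <- fisherZCi(r, n, alpha)
  list(n = n, r = r, ciLow = ci[1], ciHigh = ci[2])
}

#' Simple linear fit with R-squared
#'
#' Ordinary least squares of `y` on `x` (pairwise-complete); `R^2` equals
#' the squared Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @return list with `slope`, `intercept`, `r2`, `n`.
#' @export
linearFitR2 <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stopf("need >= 3 complete pairs")
  if (stats::sd(x) == 0) stopf("degenerate x")
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = stats::cor(x, y)^2, n = length(x))
}

#' Bland-Altman agreement summary
#'
#' Differences are `d = a - b` (convention fixed and documented). Reports
#' the bias (mean difference), the sample SD of the differences, the
#' conventional limits of agreement `bias +/- 1.96 * SD`, and — separately
#' labeled — the t-based confidence interval for the bias itself,
#' `bias +/- t_{n-1, 1-alpha/2} * SD / sqrt(n)`. Per-pair means `(a + b)/2`
#' are returned for plotting.
#'
#' @param a,b equal-length paired measurements.
#' @param alpha significance level for the bias CI (default 0.05).
#' @return list with `bias`, `sdDiff`, `loaLow`, `loaHigh`, `biasCiLow`,
#'   `biasCiHigh`, `means`, `diffs`, `n`.
#' @export
blandAltman <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b)) stopf("length mismatch")
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 2) stopf("need >= 2 pairs")
  d <- a - b
  bias <- mean(d)
  sdd <- stats::sd(d)
  halfCi <- stats::qt(1 - alpha / 2, n - 1) * sdd / sqrt(n)
  list(bias = bias, sdDiff = sdd,
       loaLow = bias - 1.96 * sdd, loaHigh = bias + 1.96 * sdd,
       biasCiLow = bias - halfCi, biasCiHigh = bias + halfCi,
       means = (a + b) / 2, diffs = d, n = n)
}

## Varimax rotation with multiple deterministic starts. The pairwise
## rotation algorithm can stall in a local optimum of the varimax criterion
## when started from the identity, so several fixed orthonormal starting
## rotations are tried and the solution with the highest criterion value
## (column variance of squared loadings) is kept.
rotateVarimax <- function(L) {
  k <- ncol(L)
  crit <- function(M) sum(apply(M^2, 2, stats::var))
  starts <- list(diag(k))
  qmats <- withSeed(20240101, lapply(1:8, function(i)
    qr.Q(qr(matrix(stats::rnorm(k * k), k)))))
  starts <- c(starts, qmats)
  best <- L
  bc <- -Inf
  for (S in starts) {
    r <- stats::varimax(L %*% S, normalize = TRUE, eps = 1e-8)
    Lr <- unclass(r$loadings)
    if (crit(Lr) > bc) { bc <- crit(Lr); best <- Lr }
  }
  best
}

#' Principal-component factor analysis with varimax rotation
#'
#' Variables are standardized and the correlation matrix (listwise-complete
#' rows) eigendecomposed. In `"auto"` mode components with eigenvalue > 1
#' are retained; a fixed count can be forced. Retained loadings
#' (`eigenvector * sqrt(eigenvalue)`) are varimax-rotated with Kaiser
#' normalization (a single retained component is left unrotated), and each
#' factor's sign is normalized so its largest-magnitude loading is positive.
#'
#' @param scoreMatrix numeric matrix or data.frame, subjects x variables.
#' @param nFactors `"auto"` (eigenvalue > 1) or a fixed positive count.
#' @return list with `eigenvalues`, `nFactors`, `loadings` (variables x
#'   factors), `varianceExplained` (per factor, fractions of total
#'   variance), `totalVariance`, `communalities`, `n`.
#' @export
factorAnalysis <- function(scoreMatrix, nFactors = "auto") {
  X <- as.matrix(scoreMatrix)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  p <- ncol(X)
  if (p < 3) stopf("need >= 3 variables")
  if (nrow(X) < 5) stopf("need >= 5 complete rows after listwise deletion")
  R <- stats::cor(X)
  if (anyNA(R)) stopf("singular correlation matrix (constant variable)")
  ee <- eigen(R, symmetric = TRUE)
  ee$values <- pmax(ee$values, 0)
  k <- if (identical(nFactors, "auto")) max(1L, sum(ee$values > 1))
       else as.integer(nFactors)
  if (k > p) stopf("cannot extract %d factors from %d variables", k, p)
  if (ee$values[k] < 1e-10)
    stopf("singular correlation matrix: only %d non-null components",
          sum(ee$values > 1e-10))
  L <- ee$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ee$values[seq_len(k)]), k)
  if (k > 1) L <- rotateVarimax(L)
  for (j in seq_len(k)) {
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  }
  dimnames(L) <- list(colnames(X), paste0("F", seq_len(k)))
  ve <- colSums(L^2) / p
  list(eigenvalues = ee$values, nFactors = k, loadings = L,
       varianceExplained = ve, totalVariance = sum(ve),
       communalities = rowSums(L^2), n = nrow(X))
}
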