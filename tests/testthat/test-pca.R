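test_that("decompose satisfies its eigen invariants on a degenerate case", {
  x <- diag(2)
  dimnames(x) <- list(c("g1", "g2"), c("s1", "s2"))
  em <- ExpressionMatrix(x, c("case", "control"))
  d <- suppressWarnings(pcaDecompose(em))
  expect_equal(eigenValues(d), c(1, 1))
  u <- pcScores(d)
  expect_equal(colSums(u^2), c(PC1 = 1, PC2 = 1))
  # X (X^T u_k) = lambda_k u_k and v_k = X^T u_k
  expect_equal(x %*% (t(x) %*% u), u %*% diag(eigenValues(d)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(pcLoadings(d), t(x) %*% u, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("decompose agrees with a dense gram-matrix eigendecomposition", {
  for (seed in 1:3) {
    em <- normalizeSamples(rand_em(8, 3, 2, seed = seed))
    x <- exprsValues(em)
    d <- pcaDecompose(em)
    oracle <- dense_gram_oracle(x)
    expect_equal(eigenValues(d), oracle$values, tolerance = 1e-8)
    # score subspace agreement up to sign, component by component
    agree <- abs(colSums(pcScores(d) * oracle$vectors))
    expect_equal(unname(agree), rep(1, length(agree)), tolerance = 1e-8)
    # sigma_k recomputed directly from returned scores
    expect_equal(scoreSd(d), apply(pcScores(d), 2, sd), tolerance = 1e-12)
    # loadings identity and eigen equation on the full decomposition
    expect_lt(max(abs(pcLoadings(d) - t(x) %*% pcScores(d))), 1e-10)
  }
})

test_that("components with distinctly class-separated loadings enter Omega", {
  set.seed(21)
  n <- 20
  loadings <- cbind(c(rep(1, 10), rep(-1, 10)) + rnorm(n, sd = 1e-3),
                    rnorm(n))
  d <- fake_decomp(matrix(rnorm(50 * 2), 50), loadings)
  s <- selectPCs(d, rep(c("case", "control"), each = 10))
  expect_true(1L %in% omega(s))
  expect_error(selectPCs(d, rep("case", n)), "both classes")
})

test_that("per-component p-values are exact Welch t-tests", {
  a <- c(1.1, 2.3, 0.7); b <- c(3.0, 4.2, 3.9)
  d <- fake_decomp(matrix(rnorm(20), 20, 1), cbind(c(a, b)))
  s <- selectPCs(d, rep(c("case", "control"), each = 3))
  # textbook Welch formula
  se <- sqrt(var(a) / 3 + var(b) / 3)
  tstat <- (mean(a) - mean(b)) / se
  df <- se^4 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(unname(s@pvalues), 2 * pt(-abs(tstat), df), tolerance = 1e-12)
})

test_that("null components enter Omega at about the nominal rate", {
  set.seed(31)
  k <- 200
  d <- fake_decomp(matrix(rnorm(300 * k), 300), matrix(rnorm(220 * k), 220))
  s <- selectPCs(d, sample(rep(c("case", "control"), each = 110)))
  frac <- length(omega(s)) / k
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / k))
})

test_that("chi-squared outlier probabilities follow the standardized scores", {
  # all-zero scores on Omega give P = 1
  sc <- cbind(c(rep(0, 9), 1), rnorm(10))
  d <- fake_decomp(sc, cbind(c(rep(2, 5), rep(-2, 5)) + rnorm(10, sd = .01),
                             rnorm(10)))
  s <- selectPCs(d, rep(c("case", "control"), each = 5))
  expect_identical(unname(omega(s)), 1L)
  p <- chi2OutlierPvalues(d, s)
  expect_equal(unname(p[1:9]), rep(1, 9))
  # a standardized score of 1.96 with |Omega| = 1 gives P ~ 0.050
  set.seed(5)
  z <- rnorm(200)
  f <- function(a) a - 1.96 * sd(c(z, a))
  a <- uniroot(f, c(0, 10), tol = 1e-12)$root
  sc2 <- cbind(c(z, a))
  d2 <- fake_decomp(sc2, cbind(c(rep(2, 5), rep(-2, 5)) + rnorm(10, sd = .01)))
  s2 <- selectPCs(d2, rep(c("case", "control"), each = 5))
  p2 <- chi2OutlierPvalues(d2, s2)
  expect_equal(unname(p2[201]), 0.050, tolerance = 5e-4)
  # empty Omega is an error
  s_empty <- new("PCSelection", omega = integer(), pvalues = c(0.5, 0.9),
                 alpha = 0.05)
  expect_error(chi2OutlierPvalues(d, s_empty), "no discriminative components")
})

test_that("under iid Gaussian scores the outlier probabilities are uniform", {
  set.seed(41)
  n <- 10000
  sc <- matrix(rnorm(n * 3), n)
  ld <- cbind(c(rep(1, 8), rep(-1, 8)) + rnorm(16, sd = .01),
              c(rep(1, 8), rep(-1, 8)) + rnorm(16, sd = .01),
              c(rep(1, 8), rep(-1, 8)) + rnorm(16, sd = .01))
  d <- fake_decomp(sc, ld)
  s <- selectPCs(d, rep(c("case", "control"), each = 8))
  expect_identical(unname(omega(s)), 1:3)
  p <- chi2OutlierPvalues(d, s)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
  # P_i monotone non-increasing in the statistic
  stat <- rowSums(sweep(pcScores(d), 2, scoreSd(d), "/")^2)
  expect_true(all(diff(p[order(stat)]) <= 1e-15))
})

test_that("BH adjustment matches the step-up definition and p.adjust", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  set.seed(13)
  p <- runif(200)^1.7
  expect_equal(bhAdjust(p), bh_oracle(p), tolerance = 1e-14)
  expect_equal(bhAdjust(p), p.adjust(p, method = "BH"), tolerance = 1e-14)
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("feature selection is invariant to score sign flips and rescaling", {
  em <- normalizeSamples(rand_em(300, 10, 10, seed = 17))
  res <- selectFeatures(em)
  d <- pcaDecompose(em)
  s <- selectPCs(d, classLabels(em))
  p <- chi2OutlierPvalues(d, s)
  # flip every score vector; rescale one by c > 0 with its sigma
  flipped <- new("PCADecomposition", scores = -pcScores(d),
                 loadings = -pcLoadings(d), eigenvalues = eigenValues(d),
                 scoreSd = scoreSd(d))
  expect_equal(chi2OutlierPvalues(flipped, s), p, tolerance = 1e-12)
  sc <- pcScores(d); sc[, 1] <- 3 * sc[, 1]
  sig <- scoreSd(d); sig[1] <- 3 * sig[1]
  rescaled <- new("PCADecomposition",
                  scores = sweep(sc, 2, sqrt(colSums(sc^2)), "/"),
                  loadings = pcLoadings(d), eigenvalues = eigenValues(d),
                  scoreSd = sig / sqrt(colSums(sc^2)))
  expect_equal(chi2OutlierPvalues(rescaled, s), p, tolerance = 1e-12)
  expect_identical(res@selected, adjustedP(res) < res@threshold)
})

test_that("planted class-shifted features are recovered at small scale", {
  set.seed(23)
  n <- 500; planted <- 1:20
  x <- matrix(rnorm(n * 30), n,
              dimnames = list(sprintf("f%03d", 1:n), sprintf("s%02d", 1:30)))
  x[planted, 1:15] <- x[planted, 1:15] + 2.5
  em <- normalizeSamples(
    ExpressionMatrix(x, rep(c("case", "control"), each = 15)))
  res <- selectFeatures(em)
  hits <- selectedFeatures(res)
  expect_gte(mean(sprintf("f%03d", planted) %in% hits), 0.9)
  expect_gte(mean(hits %in% sprintf("f%03d", planted)), 0.8)
})
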