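test_that("GRM matches hand-computed and brute-force oracles", {
  # identical genotypes: centering removes everything
  expect_equal(compute_grm(matrix(1, 5, 4)), matrix(0, 5, 5))
  # monomorphic homozygotes fail the MAF filter entirely
  expect_error(compute_grm(matrix(0, 5, 4)), "MAF")
  # one marker, genotypes (0, 2): center to (-1, +1), outer product
  K <- compute_grm(matrix(c(0, 2), 2, 1), maf = 0)
  expect_equal(K, matrix(c(1, -1, -1, 1), 2, 2))
  # brute-force recomputation on random genotypes
  set.seed(62)
  X <- matrix(rbinom(50 * 200, 2, 0.3), 50, 200)
  K <- compute_grm(X, maf = 0.001)
  p <- colMeans(X) / 2
  keep <- pmin(p, 1 - p) >= 0.001
  Xk <- X[, keep]
  Ko <- matrix(0, 50, 50)
  for (m in seq_len(ncol(Xk))) {
    g <- Xk[, m] - mean(Xk[, m])
    Ko <- Ko + outer(g, g)
  }
  Ko <- Ko / ncol(Xk)
  expect_equal(K, Ko, tolerance = 1e-12)
  expect_equal(K, t(K))
  expect_equal(mean(diag(K)), mean(apply(Xk, 2, function(g)
    mean((g - mean(g))^2))), tolerance = 1e-12)
})

test_that("univariate scan p-values match the regression t-test oracle", {
  set.seed(63)
  n <- 80
  hap <- random_hap(n, 30)
  phen <- cbind(rnorm(n), rnorm(n))
  phen[, 1] <- phen[, 1] + 0.8 * (hap[seq(1, 2 * n, 2), 3] +
                                    hap[seq(2, 2 * n, 2), 3])
  s <- make_sample(hap, chr = rep(1, 30), cM = seq(0, 0.29, 0.01),
                   role = rep("neutral", 30), phen = phen)
  scan <- univariate_scan(s, 1, fdr = 0.1)
  for (j in c(1, 3, 10, 30)) {
    fit <- summary(lm(phen[, 1] ~ s$X[, j]))
    expect_equal(scan$p[j], fit$coefficients[2, 4], tolerance = 1e-10)
    expect_equal(scan$beta[j], fit$coefficients[2, 1], tolerance = 1e-10)
  }
  expect_true(scan$significant[3])
})

test_that("perfect signal is significant, monomorphic markers are skipped", {
  set.seed(64)
  n <- 60
  hap <- random_hap(n, 5)
  hap[, 5] <- 0                          # monomorphic
  g <- hap[seq(1, 2 * n, 2), 1] + hap[seq(2, 2 * n, 2), 1]
  phen <- cbind(as.numeric(g), rnorm(n))
  s <- make_sample(hap, rep(1, 5), seq(0, 0.04, 0.01),
                   rep("neutral", 5), phen)
  scan <- univariate_scan(s, 1)
  expect_lt(scan$p[1], 1e-30)
  expect_true(scan$significant[1])
  expect_true(is.na(scan$p[5]))
  expect_equal(scan$skipped[5], "monomorphic")
})

test_that("Benjamini-Hochberg under the complete null yields no discoveries", {
  set.seed(65)
  n <- 100
  hap <- random_hap(n, 400)
  phen <- cbind(rnorm(n), rnorm(n))   # independent of every marker
  s <- make_sample(hap, rep(1, 400), seq_len(400) * 1e-4,
                   rep("neutral", 400), phen)
  scan <- univariate_scan(s, 1, fdr = 0.1)
  expect_equal(sum(scan$significant), 0)
})

test_that("BH adjustment reproduces the hand-computed example", {
  p <- c(0.001, 0.02, 0.04, 0.05)
  adj <- p.adjust(p, "BH")
  expect_equal(adj, c(0.004, 0.04, 0.05, 0.05))
  expect_true(all(adj <= 0.1))  # all four significant at FDR 0.1
})

test_that("Storey q-values: anchors, BH equivalence at pi0 = 1, monotonicity", {
  expect_true(all(storey_qvalues(rep(1, 20)) == 1))
  set.seed(66)
  p <- c(runif(400), runif(40, 0, 1e-3))
  q1 <- storey_qvalues(p, pi0 = 1)
  expect_equal(as.numeric(q1), p.adjust(p, "BH"), tolerance = 1e-12)
  q <- storey_qvalues(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))        # monotone in p
  expect_lte(attr(q, "pi0"), 1)
  # null p-values: pi0 estimated near 1
  pu <- runif(1e4)
  expect_gte(attr(storey_qvalues(pu), "pi0"), 0.9)
})

test_that("multivariate scan with K = 0 matches the fixed-effects GLS oracle", {
  set.seed(67)
  n <- 60
  hap <- random_hap(n, 25)
  phen <- cbind(rnorm(n), rnorm(n))
  phen[, 1] <- phen[, 1] + 1.5 * (hap[seq(1, 2 * n, 2), 2] +
                                    hap[seq(2, 2 * n, 2), 2])
  s <- make_sample(hap, rep(1, 25), seq(0, 0.24, 0.01),
                   rep("neutral", 25), phen)
  K <- matrix(0, n, n)
  scan <- multivariate_scan(s, K, fdr = 0.1)
  # with K = 0 the covariance is Sigma = Ve for every observation; the
  # GLS fit then coincides with per-trait OLS and the LRT statistic is
  # tr(Sigma^-1 (R0'R0 - R1'R1)) over null/full OLS residuals
  Ve <- attr(scan, "Ve")
  Si <- solve(Ve)
  R0 <- residuals(lm(phen ~ 1))
  for (j in c(1, 2, 17)) {
    R1 <- residuals(lm(phen ~ s$X[, j]))
    lrt <- sum(diag(Si %*% (crossprod(R0) - crossprod(R1))))
    expect_equal(scan$stat[j], lrt, tolerance = 1e-6)
    expect_equal(scan$p[j], pchisq(lrt, 2, lower.tail = FALSE),
                 tolerance = 1e-6)
  }
  expect_lt(scan$p[2], 0.01)   # the causal marker carries clear signal
})

test_that("multivariate scan p-values are uniform under the null", {
  set.seed(68)
  n <- 150
  M <- 1200
  hap <- random_hap(n, M)
  phen <- cbind(rnorm(n), rnorm(n))
  s <- make_sample(hap, rep(1, M), seq_len(M) * 1e-4,
                   rep("neutral", M), phen)
  scan <- multivariate_scan(s, compute_grm(s), fdr = 0.1)
  ks <- suppressWarnings(ks.test(scan$p[!is.na(scan$p)], "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("joint test has a power advantage for shared-effect markers", {
  set.seed(69)
  n <- 120
  M <- 60
  hap <- random_hap(n, M, p = rep(0.5, M))
  odd <- seq(1, 2 * n, 2)
  g <- hap[odd, ] + hap[odd + 1, ]
  # markers 1-3 carry equal true effects on both traits
  b <- 0.25
  e1 <- rnorm(n); e2 <- rnorm(n)
  phen <- cbind(e1 + b * rowSums(g[, 1:3]), e2 + b * rowSums(g[, 1:3]))
  s <- make_sample(hap, rep(1, M), seq_len(M) * 1e-4,
                   rep("neutral", M), phen)
  mv <- multivariate_scan(s, matrix(0, n, n))
  u1 <- univariate_scan(s, 1)
  idx <- 1:3
  expect_gte(mean(-log10(mv$p[idx])), mean(-log10(u1$p[idx])))
})
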