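test_that("g_matrix estimates (co)variances and flags degenerate input", {
  m <- g_matrix(cbind(c(0, 1), c(0, 1)))
  expect_equal(m$gcor, 1)
  mono <- g_matrix(matrix(5, 10, 2))
  expect_equal(c(mono$var1, mono$var2, mono$cov, mono$gcor), rep(0, 4))
  expect_false(mono$gcor_defined)
  expect_error(g_matrix(matrix(0, 1, 2)), "2 individuals")
  set.seed(31)
  r <- 0.627
  z <- matrix(rnorm(2e4), ncol = 2) %*% chol(matrix(c(1, r, r, 1), 2, 2))
  expect_equal(g_matrix(z)$gcor, r, tolerance = 0.02)
  # invariance to adding a constant
  expect_equal(g_matrix(z + 100)$gcor, g_matrix(z)$gcor)
})

test_that("genic + LD covariance decomposition is exact", {
  sel <- build_selection(100, 0.9, c(10, 10))
  cfg <- sim_config(build_architecture("linkage", 20, 0),
                    mutation_params(1e-3, 0.1), sel,
                    N = 150, generations = 300, sample_size = 50, seed = 32)
  sim <- run_simulation(cfg)
  d <- genic_gametic_covariance(sim$population)
  expect_equal(d$gametic_cov, d$genic_cov + d$ld_cov)
  # nonpleiotropic architecture: all covariance is LD covariance
  expect_identical(d$genic_cov, 0)
  # phenotypic covariance = 2 x gametic covariance at random union of
  # gametes; the realized difference is the cross-haplotype covariance
  # within individuals, a mean-zero term of order sd1*sd2/sqrt(N)
  g <- g_matrix(sim$population)
  expect_lt(abs(g$cov - 2 * d$gametic_cov),
            4 * sqrt(g$var1 * g$var2 / g$n_individuals))
  # pleiotropic architecture accumulates genic covariance
  cfgp <- sim_config(build_architecture("pleiotropy", 20),
                     mutation_params(1e-3, 0.1), sel,
                     N = 150, generations = 300, sample_size = 50, seed = 33)
  dp <- genic_gametic_covariance(run_simulation(cfgp)$population)
  expect_gt(abs(dp$genic_cov), 0)
})

test_that("shuffling one locus across haplotypes destroys LD covariance", {
  sel <- build_selection(100, 0.9, c(10, 10))
  cfg <- sim_config(build_architecture("linkage", 30, 0),
                    mutation_params(1e-3, 0.1), sel,
                    N = 200, generations = 400, sample_size = 50, seed = 34)
  pop <- run_simulation(cfg)$population
  set.seed(35)
  t2 <- which(pop$arch$loci$trait2)
  for (l in t2) pop$v2[l, ] <- pop$v2[l, sample(ncol(pop$v2))]
  d <- genic_gametic_covariance(pop)
  # permutation leaves only sampling noise in the LD component
  h1 <- colSums(pop$v1[pop$arch$loci$trait1, ])
  h2 <- colSums(pop$v2[t2, ])
  noise <- 3 * sd(h1) * sd(h2) / sqrt(ncol(pop$v1))
  expect_lt(abs(d$ld_cov), noise)
})

test_that("multiallelic r2 matches haplotype-table anchors", {
  # complete coupling LD
  expect_equal(as.numeric(
    multiallelic_r2(rep(c("A", "a"), each = 50),
                    rep(c("B", "b"), each = 50))), 1)
  # worked example: (AB, Ab, aB, ab) = (35, 15, 15, 35)/100 -> D = 0.1
  a <- rep(c("A", "A", "a", "a"), c(35, 15, 15, 35))
  b <- rep(c("B", "b", "B", "b"), c(35, 15, 15, 35))
  expect_equal(as.numeric(multiallelic_r2(a, b)), 0.16)
  # monomorphic flagged as undefined 0
  r <- multiallelic_r2(rep("A", 10), rep(c("B", "b"), 5))
  expect_identical(as.numeric(r), 0)
  expect_false(attr(r, "defined"))
  expect_error(multiallelic_r2(1:4, 1:6), "same haplotypes")
})

test_that("biallelic multiallelic r2 equals squared Pearson correlation", {
  set.seed(36)
  for (i in 1:20) {
    x <- rbinom(200, 1, runif(1, 0.1, 0.9))
    y <- ifelse(runif(200) < 0.7, x, rbinom(200, 1, 0.5))
    if (var(x) == 0 || var(y) == 0) next
    expect_equal(as.numeric(multiallelic_r2(x, y)), cor(x, y)^2,
                 tolerance = 1e-12)
  }
  # independent loci are near linkage equilibrium
  x <- rbinom(5000, 1, 0.5); y <- rbinom(5000, 1, 0.5)
  expect_lt(as.numeric(multiallelic_r2(x, y)), 0.005)
})

test_that("allelic kurtosis matches closed forms", {
  set.seed(37)
  expect_lt(abs(allelic_kurtosis(rnorm(1e5))), 0.1)
  expect_equal(as.numeric(
    allelic_kurtosis(c(-2, 2), freq = c(0.5, 0.5))), -2)
  # rare-allele two-point distribution: excess kurtosis (1 - 6pq) / pq
  p <- 0.01
  k <- allelic_kurtosis(c(0, 1), freq = c(1 - p, p))
  expect_equal(as.numeric(k), (1 - 6 * p * (1 - p)) / (p * (1 - p)),
               tolerance = 1e-10)
  expect_gt(as.numeric(k), 90)
  deg <- allelic_kurtosis(rep(1, 10))
  expect_true(is.na(deg))
  expect_false(attr(deg, "defined"))
})

test_that("segregating counts respect locus roles", {
  sel <- build_selection(100, 0, c(0, 0))
  cfg <- sim_config(build_architecture("linkage", 6, 0),
                    mutation_params(0, 0.1), sel,
                    N = 20, generations = 0, sample_size = 10, seed = 38)
  pop <- initialize_population(cfg)
  s0 <- segregating_counts(pop)
  expect_equal(s0$n_qtl_segregating, 0)
  # make 3 QTL polymorphic by hand
  pop$v1[c(1, 3), 1] <- 99
  pop$v2[6, 2] <- -99
  s1 <- segregating_counts(pop)
  expect_equal(s1$n_qtl_segregating, 3)
})
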