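sel_std <- build_selection(100, 0.9, c(10, 10))

test_that("populations initialize monomorphic at the optimum", {
  cfg <- sim_config(build_architecture("pleiotropy", 120),
                    mutation_params(1e-5, 0.1), sel_std,
                    N = 50, generations = 0, sample_size = 10, seed = 41)
  pop <- initialize_population(cfg)
  expect_true(all(pop$v1 == 10 / 240))   # theta_k / (2 n_k)
  expect_true(all(pop$v2 == 10 / 240))
  expect_true(all(pop$phen == 10))
  expect_equal(g_matrix(pop)$var1, 0)
  sel0 <- build_selection(100, 0.9, c(0, 0))
  cfg0 <- sim_config(build_architecture("linkage", 10, 0),
                     mutation_params(1e-5, 0.1), sel0,
                     N = 20, generations = 0, sample_size = 5, seed = 42)
  expect_true(all(initialize_population(cfg0)$v1 == 0))
})

test_that("QTN initialization recenters phenotypes exactly at the optimum", {
  set.seed(43)
  cfg <- sim_config(build_architecture("linkage", 15, 0, qtn = TRUE),
                    mutation_params(1e-5, 0.1, mode = "qtn_biallelic"),
                    sel_std, N = 30, generations = 0, sample_size = 10)
  pop <- initialize_population(cfg)
  expect_equal(unname(pop$phen), matrix(10, 30, 2))
  expect_equal(phenotypes_from_genotypes(pop), unname(pop$phen))
  # monomorphic: all copies share the locus sign
  expect_true(all(apply(pop$v1, 1, function(x) length(unique(x))) == 1))
})

test_that("without variation the next generation is unchanged and fit", {
  cfg <- sim_config(build_architecture("pleiotropy", 10),
                    mutation_params(0, 0.1, neutral_mu = 0), sel_std,
                    N = 40, generations = 5, sample_size = 10, seed = 44)
  sim <- run_simulation(cfg)
  expect_true(all(sim$population$phen == 10))
  expect_true(all(sim$trajectory$var1 == 0))
  expect_equal(ncol(sim$population$v1), 2 * 40)   # N constant
})

test_that("phenotypes stay consistent with haplotypes after evolution", {
  cfg <- sim_config(build_architecture("linkage", 12, 0.5),
                    mutation_params(1e-2, 0.1), sel_std,
                    N = 80, generations = 150, sample_size = 20, seed = 45)
  sim <- run_simulation(cfg)
  expect_equal(phenotypes_from_genotypes(sim$population),
               unname(sim$population$phen), tolerance = 1e-12)
  expect_equal(ncol(sim$population$v1), 160)
})

test_that("identical seeds give bit-reproducible runs", {
  mk <- function() {
    cfg <- sim_config(build_architecture("pleiotropy", 10),
                      mutation_params(1e-3, 0.1), sel_std,
                      N = 60, generations = 100, sample_size = 20,
                      seed = 46)
    run_simulation(cfg)
  }
  a <- mk(); b <- mk()
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$population$v1, b$population$v1)
  expect_identical(a$sample_idx, b$sample_idx)
})

test_that("migrant offspring fraction matches the backward rate", {
  sel0 <- build_selection(Inf, 0, c(10, 10))
  cfg <- sim_config(build_architecture("pleiotropy", 5),
                    mutation_params(1e-5, 0.1), sel0,
                    N = 200, generations = 200, migration_rate = 0.1,
                    source_selection = build_selection(Inf, 0, c(10, 10)),
                    burnin_generations = 0, sample_size = 20,
                    record_every = 1, seed = 47)
  sim <- run_simulation(cfg)
  mf <- sim$trajectory$migrant_fraction[sim$trajectory$phase == "migration"]
  expect_lt(abs(mean(mf) - 0.1), 0.01)
})

test_that("neutral allele-frequency drift matches Wright-Fisher sampling", {
  # one diallelic neutral locus started at p = 0.5, selection off:
  # E[dp] = 0 and Var[dp] = p(1-p)/(2N) per generation
  off <- build_selection(Inf, 0, c(0, 0))
  arch <- build_architecture("pleiotropy", 1,
                             neutral_panel = neutral_panel_spec(1, 0.1, 0))
  cfg <- sim_config(arch, mutation_params(0, 0.1, neutral_mu = 0), off,
                    N = 100, generations = 0, sample_size = 10)
  nl <- which(arch$loci$role == "neutral")
  set.seed(48)
  dp <- replicate(400, {
    pop <- initialize_population(cfg)
    pop$v1[nl, ] <- rep(c(0, 1), 100)  # exact p = 0.5
    nxt <- advance_generation(pop, cfg)
    mean(nxt$v1[nl, ]) - 0.5
  })
  expect_lt(abs(mean(dp)), 3 * sd(dp) / sqrt(400))
  v_exp <- 0.25 / (2 * 100)
  expect_lt(abs(var(dp) - v_exp), 3 * v_exp * sqrt(2 / 399))
})

test_that("heterozygosity decays at rate 1/(2N) without selection", {
  off <- build_selection(Inf, 0, c(0, 0))
  arch <- build_architecture("pleiotropy", 1,
                             neutral_panel = neutral_panel_spec(8, 0.1, 0))
  N <- 50
  cfg <- sim_config(arch, mutation_params(0, 0.1, neutral_mu = 0), off,
                    N = N, generations = 0, sample_size = 10)
  nl <- which(arch$loci$role == "neutral")
  gens <- 60
  set.seed(49)
  hets <- replicate(25, {
    pop <- initialize_population(cfg)
    pop$v1[nl, ] <- matrix(rep(rep(c(0, 1), N), length(nl)),
                           nrow = length(nl), byrow = TRUE)
    pop <- advance_generation(pop, cfg, generations = gens)
    p <- rowMeans(pop$v1[nl, , drop = FALSE])
    mean(2 * p * (1 - p))
  })
  H0 <- 0.5
  expected <- H0 * (1 - 1 / (2 * N))^gens
  # Monte-Carlo band over 25 replicates (the 8 loci within a replicate
  # are tightly linked and share a pedigree, so they are correlated)
  expect_lt(abs(mean(hets) - expected), 3 * sd(hets) / sqrt(25) + 0.02)
})

test_that("no correlational selection leaves no systematic genetic correlation", {
  sel0 <- build_selection(100, 0, c(10, 10))
  g <- vapply(1:6, function(s) {
    cfg <- sim_config(build_architecture("pleiotropy", 20),
                      mutation_params(1e-3, 0.1), sel0,
                      N = 200, generations = 800, sample_size = 50,
                      seed = 50 + s)
    equilibrium_gcor(run_simulation(cfg), window = 10)
  }, numeric(1))
  expect_lt(abs(mean(g)), 3 * sd(g) / sqrt(length(g)) + 0.05)
})

test_that("fitness collapse raises an informative error", {
  # optimum far away and monomorphic: every offspring has fitness ~ 0
  selbad <- build_selection(0.0001, 0, c(1e6, 1e6))
  cfg <- sim_config(build_architecture("pleiotropy", 2),
                    mutation_params(0, 0.1), selbad,
                    N = 10, generations = 1, sample_size = 5, seed = 51)
  pop <- initialize_population(cfg)
  pop$phen[] <- 0           # everyone far from the optimum
  pop$v1[] <- 0; pop$v2[] <- 0; pop$basal <- c(0, 0)
  expect_error(advance_generation(pop, cfg), "fitness collapsed")
})
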