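#' Simulation configuration
#'
#' Bundles everything one forward-in-time run needs: the genetic
#' architecture, the mutation model, the selection regime(s), demography
#' and bookkeeping. The defaults correspond to the reference study
#' conditions: 5000 diploid hermaphrodites evolving for 50,000 generations
#' from a monomorphic start.
#'
#' @param architecture A [build_architecture()] spec.
#' @param mutation A [mutation_params()] object; its mode must match the
#'   architecture (`qtn = TRUE` requires `"qtn_biallelic"`).
#' @param selection A [build_selection()] regime for the focal deme.
#' @param N Individuals per deme (constant across generations).
#' @param generations Number of generations to simulate (for migration
#'   runs: generations *with* migration, after the burn-in).
#' @param migration_rate Backward migration rate `m` into the focal deme:
#'   the expected fraction of offspring whose parents both come from the
#'   source deme. `0` disables the second deme.
#' @param source_selection Selection regime of the source deme; required
#'   when `migration_rate > 0`. The source deme evolves concurrently under
#'   its own regime and is unaffected by the focal deme (unidirectional
#'   island-mainland migration). Use [source_selection_default()] for the
#'   standard source regime.
#' @param burnin_generations Generations both demes evolve independently
#'   (m = 0) before migration starts (only used when `migration_rate > 0`).
#' @param sample_size Individuals sampled (without replacement) at the
#'   final generation for downstream association mapping.
#' @param record_every Recording cadence for the trajectory of summary
#'   statistics; default `max(1, generations %/% 50)`.
#' @param seed Optional integer seed; when set, runs are bit-reproducible.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(architecture, mutation, selection,
                       N = 5000, generations = 50000,
                       migration_rate = 0, source_selection = NULL,
                       burnin_generations = 40000,
                       sample_size = 1000, record_every = NULL,
                       seed = NULL) {
  stopifnot(inherits(architecture, "architecture_spec"),
            inherits(mutation, "mutation_params"),
            inherits(selection, "selection_regime"))
  if (architecture$qtn && mutation$mode != "qtn_biallelic")
    stop("a QTN architecture requires mutation mode 'qtn_biallelic'")
  if (!architecture$qtn && mutation$mode == "qtn_biallelic")
    stop("mutation mode 'qtn_biallelic' requires an architecture built with qtn = TRUE")
  if (migration_rate < 0 || migration_rate >= 1)
    stop("migration_rate must be in [0, 1)")
  if (migration_rate > 0 && is.null(source_selection))
    stop("migration requires a source_selection regime")
  if (!is.null(source_selection))
    stopifnot(inherits(source_selection, "selection_regime"))
  if (sample_size > N) stop("sample_size must not exceed N")
  if (is.null(record_every)) record_every <- max(1L, generations %/% 50L)
  structure(list(architecture = architecture, mutation = mutation,
                 selection = selection, N = as.integer(N),
                 generations = as.integer(generations),
                 migration_rate = migration_rate,
                 source_selection = source_selection,
                 burnin_generations = as.integer(burnin_generations),
                 sample_size = as.integer(sample_size),
                 record_every = as.integer(record_every),
                 seed = seed),
            class = "sim_config")
}

#' Default source-deme selection regime for migration runs
#'
#' The source deme is under the same stabilizing-selection strength as the
#' focal deme with its own correlational selection, and its optimum is
#' displaced 10 phenotypic units from the focal optimum along the diagonal
#' (`theta_src = theta_focal + (10 / sqrt(2)) * (1, 1)`). Pass explicit
#' `optima` to override (e.g. `c(50, 50)`).
#'
#' @param focal The focal deme's [build_selection()] regime.
#' @param rho_omega Correlational selection in the source deme.
#' @param distance Displacement of the source optimum along the diagonal.
#' @param optima Optional explicit source optima (overrides `distance`).
#' @return A `selection_regime`.
#' @export
source_selection_default <- function(focal, rho_omega = 0.9, distance = 10,
                                     optima = NULL) {
  stopifnot(inherits(focal, "selection_regime"))
  if (is.null(optima))
    optima <- focal$optima + (distance / sqrt(2)) * c(1, 1)
  build_selection(focal$omega2, rho_omega, optima)
}

#' Initialize a monomorphic population at the optimum
#'
#' Every individual starts with phenotype exactly at the local optimum and
#' zero genetic variance. In continuum mode every allele copy at a trait-k
#' locus holds `theta_k / (2 * n_k)` (`n_k` loci affecting trait k). In
#' biallelic QTN mode each locus is assigned a fixed effect magnitude
#' (`|N(0, alpha2)|` per affected trait, or `sqrt(alpha2)` when
#' `qtn_equal_magnitudes`) and a random initial sign, identical across all
#' copies (monomorphic); the residual `theta_k - sum(effects)` is carried
#' by a non-evolving basal value so selection pressure at generation 0 is
#' zero, exactly as in continuum mode.
#'
#' @param config A [sim_config()].
#' @param deme `"focal"` or `"source"` (selects the optimum used).
#' @return Object of class `wf_population`: haplotype arrays `v1`, `v2`
#'   (`L x 2N`, effect on trait 1 / trait 2; neutral markers keep their
#'   0/1 state in `v1`), phenotype matrix `phen` (`N x 2`), basal values,
#'   generation counter and deme id.
#' @export
initialize_population <- function(config, deme = c("focal", "source")) {
  stopifnot(inherits(config, "sim_config"))
  deme <- match.arg(deme)
  regime <- if (deme == "focal") config$selection else config$source_selection
  if (is.null(regime)) stop("no selection regime for the source deme")
  arch <- config$architecture
  loci <- arch$loci
  L <- nrow(loci)
  N <- config$N
  theta <- regime$optima
  n1 <- sum(loci$trait1)
  n2 <- sum(loci$trait2)
  v1 <- matrix(0, L, 2 * N)
  v2 <- matrix(0, L, 2 * N)
  basal <- c(0, 0)
  if (!arch$qtn) {
    if (n1 > 0) v1[loci$trait1, ] <- theta[1] / (2 * n1)
    if (n2 > 0) v2[loci$trait2, ] <- theta[2] / (2 * n2)
  } else {
    s <- sqrt(config$mutation$alpha2)
    sign0 <- sample(c(-1, 1), L, replace = TRUE)
    mag1 <- if (config$mutation$qtn_equal_magnitudes) rep(s, L)
            else abs(rnorm(L, 0, s))
    mag2 <- if (config$mutation$qtn_equal_magnitudes) rep(s, L)
            else abs(rnorm(L, 0, s))
    a1 <- ifelse(loci$trait1, sign0 * mag1, 0)
    a2 <- ifelse(loci$trait2, sign0 * mag2, 0)
    v1[] <- a1
    v2[] <- a2
    v1[loci$role == "neutral", ] <- 0
    basal <- c(theta[1] - 2 * sum(a1), theta[2] - 2 * sum(a2))
  }
  phen <- matrix(rep(theta, each = N), N, 2)
  structure(list(v1 = v1, v2 = v2, phen = phen, basal = basal,
                 generation = 0L, deme_id = deme, arch = arch),
            class = "wf_population")
}

#' @export
print.wf_population <- function(x, ...) {
  cat(sprintf("<wf_population> deme=%s, N=%d, L=%d, generation=%d\n",
              x$deme_id, ncol(x$v1) / 2, nrow(x$v1), x$generation))
  invisible(x)
}

#' Recompute phenotypes from haplotypes
#'
#' The phenotype of an individual is the sum of the allelic values of all
#' loci affecting each trait over its two haplotypes (plus the deme's basal
#' value in QTN mode). Used to assert phenotype/haplotype consistency.
#'
#' @param pop A `wf_population`.
#' @return `N x 2` phenotype matrix.
#' @export
phenotypes_from_genotypes <- function(pop) {
  stopifnot(inherits(pop, "wf_population"))
  loci <- pop$arch$loci
  N <- ncol(pop$v1) / 2
  t1 <- loci$trait1
  t2 <- loci$trait2
  h1 <- colSums(pop$v1[t1, , drop = FALSE])
  h2 <- colSums(pop$v2[t2, , drop = FALSE])
  odd <- seq(1, 2 * N, by = 2)
  cbind(h1[odd] + h1[odd + 1] + pop$basal[1],
        h2[odd] + h2[odd + 1] + pop$basal[2])
}

.engine_call <- function(pop, config, generations, record_every,
                         m = 0, source = NULL) {
  lay <- .arch_engine_layout(config$architecture)
  regime <- if (pop$deme_id == "focal") config$selection
            else config$source_selection
  src <- NULL
  if (!is.null(source)) {
    src <- list(v1 = source$v1, v2 = source$v2,
                phen1 = source$phen[, 1], phen2 = source$phen[, 2],
                basal = source$basal,
                oinv = config$source_selection$Omega_inv,
                theta = config$source_selection$optima)
  }
  .wf_engine(pop$v1, pop$v2, pop$phen[, 1], pop$phen[, 2], pop$basal,
             regime$Omega_inv, regime$optima,
             lay$role, lay$pos, lay$chr_start, lay$chr_end, lay$chr_len,
             config$mutation$mu, sqrt(config$mutation$alpha2),
             config$mutation$neutral_mu,
             as.integer(generations), as.integer(record_every),
             m, src)
}

.update_pop <- function(pop, v1, v2, phen, generations) {
  pop$v1 <- v1; pop$v2 <- v2; pop$phen <- phen
  pop$generation <- pop$generation + generations
  pop
}

#' Advance a population by one generation
#'
#' Produces the next generation of exactly `N` adults: parents are drawn
#' uniformly with replacement (selfing permitted) from the local deme, or
#' both from the source deme with probability `migration_rate`; each parent
#' contributes one recombined, mutated gamete; the offspring survives
#' viability selection with probability `w(z)`; rejection sampling repeats
#' until `N` survivors are collected. When a source population is given it
#' is advanced concurrently under its own regime.
#'
#' @param pop Focal `wf_population`.
#' @param config A [sim_config()].
#' @param source Optional source `wf_population` (required when
#'   `config$migration_rate > 0`).
#' @param generations Number of generations to advance (default 1).
#' @return The next-generation focal population with the trajectory of
#'   recorded statistics attached as attribute `"trajectory"`, or (with a
#'   source) a list `list(population, source)`.
#' @export
advance_generation <- function(pop, config, source = NULL,
                               generations = 1L) {
  stopifnot(inherits(pop, "wf_population"))
  m <- config$migration_rate
  if (m > 0 && is.null(source))
    stop("migration_rate > 0 requires a source population")
  res <- .engine_call(pop, config, as.integer(generations), 1L,
                      m = if (is.null(source)) 0 else m, source = source)
  newpop <- .update_pop(pop, res$v1, res$v2, res$phen,
                        as.integer(generations))
  attr(newpop, "trajectory") <- as.data.frame(res$trajectory)
  if (is.null(source)) return(newpop)
  newsrc <- .update_pop(source, res$source_v1, res$source_v2,
                        res$source_phen, as.integer(generations))
  list(population = newpop, source = newsrc)
}

#' Run a forward simulation to mutation-selection(-migration) balance
#'
#' Initializes monomorphic population(s) at their optima and evolves them
#' for the configured number of generations, recording the G-matrix,
#' genetic correlation, mean phenotypes and segregating-locus count at the
#' configured cadence. For migration runs the two demes are first burnt in
#' independently for `burnin_generations`, then migration operates for
#' `generations`. At the end a sample of `sample_size` individuals is
#' drawn without replacement for association mapping.
#'
#' @param config A [sim_config()].
#' @return Object of class `wf_simulation`: `trajectory` (data frame with
#'   one row per record: generation, mean phenotypes, genetic variances,
#'   covariance, correlation, segregating QTL count, migrant fraction,
#'   phase), final `population` (and `source_population` for migration
#'   runs), `sample_idx`, and the `config`.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  pop <- initialize_population(config, "focal")
  m <- config$migration_rate

  traj0 <- data.frame(generation = 0,
                      mean_z1 = mean(pop$phen[, 1]),
                      mean_z2 = mean(pop$phen[, 2]),
                      var1 = 0, var2 = 0, cov = 0, gcor = 0,
                      n_qtl_segregating = 0, migrant_fraction = 0,
                      phase = "burnin")

  if (m > 0) {
    src <- initialize_population(config, "source")
    gb <- config$burnin_generations
    if (gb > 0) {
      rb_f <- .engine_call(pop, config, gb, config$record_every)
      pop <- .update_pop(pop, rb_f$v1, rb_f$v2, rb_f$phen, gb)
      rb_s <- .engine_call(src, config, gb, config$record_every)
      src <- .update_pop(src, rb_s$v1, rb_s$v2, rb_s$phen, gb)
      burn_traj <- cbind(as.data.frame(rb_f$trajectory), phase = "burnin")
    } else burn_traj <- NULL
    rm <- .engine_call(pop, config, config$generations, config$record_every,
                       m = m, source = src)
    pop <- .update_pop(pop, rm$v1, rm$v2, rm$phen, config$generations)
    src <- .update_pop(src, rm$source_v1, rm$source_v2, rm$source_phen,
                       config$generations)
    mig_traj <- as.data.frame(rm$trajectory)
    mig_traj$generation <- mig_traj$generation + gb
    mig_traj <- cbind(mig_traj, phase = "migration")
    traj <- rbind(traj0, burn_traj, mig_traj)
    source_population <- src
  } else {
    if (config$generations > 0) {
      res <- .engine_call(pop, config, config$generations,
                          config$record_every)
      pop <- .update_pop(pop, res$v1, res$v2, res$phen, config$generations)
      traj <- rbind(traj0,
                    cbind(as.data.frame(res$trajectory), phase = "burnin"))
    } else traj <- traj0
    source_population <- NULL
  }

  sample_idx <- sample(config$N, config$sample_size)
  structure(list(trajectory = traj, population = pop,
                 source_population = source_population,
                 sample_idx = sample_idx, config = config),
            class = "wf_simulation")
}

#' @export
print.wf_simulation <- function(x, ...) {
  n <- nrow(x$trajectory)
  cat(sprintf("<wf_simulation> %s architecture, N=%d, %d generations; final Gcor=%.4f\n",
              x$config$architecture$architecture_kind, x$config$N,
              x$population$generation, x$trajectory$gcor[n]))
  invisible(x)
}

#' Equilibrium genetic correlation of a run
#'
#' Mean of the recorded genetic correlation over the last `window` records
#' (default: the final record only).
#'
#' @param sim A `wf_simulation`.
#' @param window Number of trailing records to average.
#' @return Scalar genetic correlation.
#' @export
equilibrium_gcor <- function(sim, window = 1) {
  stopifnot(inherits(sim, "wf_simulation"))
  g <- sim$trajectory$gcor
  mean(tail(g, window))
}
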