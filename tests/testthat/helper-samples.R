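# Build a synthetic genotype_sample directly from haplotype matrices,
# bypassing the simulator, for controlled association-mapping tests.
make_sample <- function(hap, chr, cM, role, phen, truth = NULL,
                        causal_alleles = NULL) {
  n <- nrow(hap) / 2
  p1 <- colMeans(hap)
  minor <- ifelse(p1 <= 0.5, 1L, 0L)
  maf <- pmin(p1, 1 - p1)
  odd <- seq(1, 2 * n, by = 2)
  cnt1 <- hap[odd, , drop = FALSE] + hap[odd + 1, , drop = FALSE]
  X <- sweep(cnt1, 2, minor == 0L, function(a, flip) ifelse(flip, 2 - a, a))
  colnames(X) <- sprintf("M%d", seq_len(ncol(X)))
  map <- data.frame(marker = colnames(X), locus_id = seq_len(ncol(X)),
                    chr = chr, cM = cM, role = role, maf = maf,
                    minor_allele = minor, stringsAsFactors = FALSE)
  if (is.null(truth))
    truth <- data.frame(locus_id = integer(), chr = integer(),
                        cM = numeric(), role = character(),
                        pair = integer(), segregating = logical())
  structure(list(X = X, hap = hap, map = map, phen = phen, truth = truth,
                 causal_alleles = causal_alleles, arch = NULL, n = n),
            class = "genotype_sample")
}

# Random biallelic haplotypes: 2n x M with per-marker allele frequencies p
random_hap <- function(n, M, p = NULL) {
  if (is.null(p)) p <- runif(M, 0.1, 0.9)
  matrix(rbinom(2 * n * M, 1, rep(p, each = 2 * n)), 2 * n, M)
}

# One small simulated sample shared by several gwaa tests
small_sim_sample <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sel <- build_selection(100, 0.9, c(10, 10))
      np <- neutral_panel_spec(40, 0.1, 1e-4)
      cfg <- sim_config(build_architecture("pleiotropy", 6,
                                           neutral_panel = np),
                        mutation_params(1e-4, 0.1, neutral_mu = 1e-4),
                        sel, N = 120, generations = 600,
                        sample_size = 100, seed = 61)
      cache <<- as_genotype_sample(run_simulation(cfg))
    }
    cache
  }
})
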