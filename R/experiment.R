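#' Parameter grid of a named experiment preset
#'
#' Returns the simulation conditions of the package's standard
#' experiments as a data frame (one row per condition), at full scale
#' (reference study conditions: N = 5000, 50,000 generations, 120 loci
#' per trait, 30-50 replicates per cell; the association-mapping tables
#' use 10 replicates with 1000 neutral markers per chromosome and samples
#' of 1000) or at a reduced desk scale (N = 500, 60 loci per trait,
#' 5000 generations, 10 replicates, 100 neutral markers per chromosome,
#' samples of 400; neutral-marker mutation rescaled to keep 4*N*mu fixed).
#'
#' Presets: `"fig3"` mutation-rate grid for pleiotropy vs. fully linked
#' pairs; `"fig4"` within-pair map-distance grid under three selection
#' settings; `"fig5"` between-pair spacing on a single chromosome;
#' `"fig6"` migration-rate grid with source correlational selection 0.9
#' or 0; `"table1"` multivariate GWA conditions; `"table2"` univariate
#' GWA conditions; `"table3"` biallelic-QTN scan conditions.
#'
#' @param preset One of `"fig3"`, `"fig4"`, `"fig5"`, `"fig6"`,
#'   `"table1"`, `"table2"`, `"table3"`.
#' @param scale `"full"` or `"reduced"`.
#' @return Data frame of conditions with a `label` column and all
#'   [sim_config()]-relevant parameters, plus attributes `replicates` and
#'   `scale`.
#' @export
experiment_preset <- function(preset = c("fig3", "fig4", "fig5", "fig6",
                                         "table1", "table2", "table3"),
                              scale = c("full", "reduced")) {
  preset <- match.arg(preset)
  scale <- match.arg(scale)
  full <- scale == "full"
  N <- if (full) 5000 else 500
  nl <- if (full) 120 else 60
  gens <- if (full) 50000 else 5000
  reps <- if (full) switch(preset, fig3 = 30, fig4 = 30, fig5 = 30,
                           fig6 = 50, 10) else 10
  nn <- if (full) 1000 else 100
  neutral_mu <- if (full) 1e-6 else 1e-5
  samp <- if (full) 1000 else 400

  base <- data.frame(N = N, n_loci = nl, generations = gens,
                     omega2 = 100, rho_omega = 0.9,
                     within_pair_cM = 0, between_pair_cM = NA,
                     m = 0, source_rho = NA, burnin = NA,
                     neutral_n = NA, neutral_mu = NA, qtn = FALSE,
                     sample_size = NA)

  grid <- switch(preset,
    fig3 = {
      g <- expand.grid(kind = c("pleiotropy", "linkage"),
                       mu = c(1e-3, 1e-4, 1e-5),
                       alpha2 = c(0.001, 0.1),
                       stringsAsFactors = FALSE)
      cbind(g, base)
    },
    fig4 = {
      g <- expand.grid(kind = c("pleiotropy", "linkage"),
                       mu = c(1e-3, 1e-5),
                       alpha2 = c(0.001, 0.1),
                       panel = c("A", "B", "C"),
                       d = c(0, 0.1, 1),
                       stringsAsFactors = FALSE)
      g <- g[!(g$kind == "pleiotropy" & g$d > 0), ]
      b <- base
      g2 <- cbind(g[, c("kind", "mu", "alpha2")], b[rep(1, nrow(g)), ])
      g2$within_pair_cM <- g$d
      g2$omega2 <- ifelse(g$panel == "A", 50, 100)
      g2$rho_omega <- ifelse(g$panel == "C", 0.5, 0.9)
      g2$panel <- g$panel
      g2
    },
    fig5 = {
      g <- expand.grid(kind = "linkage", mu = c(1e-5, 1e-3), alpha2 = 0.1,
                       d_between = c(0.001, 0.1, 1),
                       stringsAsFactors = FALSE)
      g <- rbind(cbind(g[, c("kind", "mu", "alpha2")],
                       base[rep(1, nrow(g)), ],
                       set_between = g$d_between),
                 cbind(data.frame(kind = "pleiotropy", mu = 1e-5,
                                  alpha2 = 0.1),
                       base, set_between = NA))
      g$between_pair_cM <- g$set_between
      g$set_between <- NULL
      g
    },
    fig6 = {
      g <- expand.grid(kind = c("pleiotropy", "linkage"),
                       within = c(0, 0.1, 1),
                       m = c(0.001, 0.01, 0.1),
                       source_rho = c(0, 0.9),
                       stringsAsFactors = FALSE)
      g <- g[!(g$kind == "pleiotropy" & g$within > 0), ]
      b <- base[rep(1, nrow(g)), ]
      b$rho_omega <- 0            # no correlational selection in the focal deme
      b$m <- g$m
      b$source_rho <- g$source_rho
      b$within_pair_cM <- g$within
      b$burnin <- if (full) 40000 else 2000
      b$generations <- if (full) 10000 else 3000
      cbind(g[, "kind", drop = FALSE], mu = 1e-5, alpha2 = 0.1, b)
    },
    table1 = ,
    table2 = {
      g <- expand.grid(kind = c("linkage", "pleiotropy"),
                       mut = c("gauss_small", "gauss_large",
                               "low_small", "hoc"),
                       stringsAsFactors = FALSE)
      g$alpha2 <- ifelse(g$mut %in% c("gauss_small", "low_small"),
                         0.001, 0.1)
      g$mu <- ifelse(g$mut %in% c("gauss_small", "gauss_large"),
                     1e-3, 1e-5)
      g$rho_omega2 <- ifelse(g$kind == "pleiotropy" & g$mut == "hoc",
                             0.06, 0.9)
      extra <- data.frame(kind = "pleiotropy", mut = "hoc_rho09",
                          alpha2 = 0.1, mu = 1e-5, rho_omega2 = 0.9)
      g <- rbind(g, extra)
      b <- base[rep(1, nrow(g)), ]
      b$rho_omega <- g$rho_omega2
      b$neutral_n <- nn
      b$neutral_mu <- neutral_mu
      b$sample_size <- samp
      cbind(g[, c("kind", "mu", "alpha2")], b)
    },
    table3 = {
      g <- data.frame(
        kind = c(rep("linkage", 4), rep("pleiotropy", 4)),
        alpha2 = rep(c(0.001, 0.1, 0.001, 0.1), 2),
        mu = rep(c(1e-3, 1e-3, 1e-5, 1e-5), 2),
        rho = c(0.9, 0.9, 0.9, 0.9, 0.9, 0.85, 0.01, 0.01))
      b <- base[rep(1, nrow(g)), ]
      b$rho_omega <- g$rho
      b$qtn <- TRUE
      b$sample_size <- samp
      cbind(g[, c("kind", "mu", "alpha2")], b)
    })

  grid$label <- sprintf("%s_mu%g_a%g_row%d", grid$kind, grid$mu,
                        grid$alpha2, seq_len(nrow(grid)))
  rownames(grid) <- NULL
  structure(grid, replicates = reps, scale = scale, preset = preset)
}

.condition_config <- function(row, seed = NULL) {
  np <- if (!is.na(row$neutral_n))
    neutral_panel_spec(row$neutral_n, 0.1, row$neutral_mu) else NULL
  arch <- build_architecture(
    kind = row$kind, n_loci_per_trait = row$n_loci,
    within_pair_cM = row$within_pair_cM,
    between_pair_cM = if (is.na(row$between_pair_cM)) NULL
                      else row$between_pair_cM,
    neutral_panel = np, qtn = isTRUE(row$qtn))
  mut <- mutation_params(
    row$mu, row$alpha2,
    mode = if (isTRUE(row$qtn)) "qtn_biallelic" else "continuum",
    neutral_mu = if (is.na(row$neutral_mu)) 1e-6 else row$neutral_mu)
  sel <- build_selection(row$omega2, row$rho_omega, c(10, 10))
  src <- if (row$m > 0)
    source_selection_default(sel, rho_omega = row$source_rho) else NULL
  sim_config(arch, mut, sel, N = row$N, generations = row$generations,
             migration_rate = row$m, source_selection = src,
             burnin_generations = if (is.na(row$burnin)) 0 else row$burnin,
             sample_size = if (is.na(row$sample_size))
               min(1000, row$N) else row$sample_size,
             seed = seed)
}

#' Run an experiment preset over a replicate grid
#'
#' Runs every condition of a preset for each seed, collects the
#' equilibrium genetic correlation (and, for the association-mapping
#' presets, the scan-based discovery metrics), and aggregates means and
#' standard deviations/errors per condition. Identical seeds give
#' byte-identical summaries. Failing replicates are reported and skipped.
#'
#' @param preset Preset name (see [experiment_preset()]) or a conditions
#'   data frame from it.
#' @param scale `"reduced"` (default) or `"full"`.
#' @param seeds Integer vector of replicate seeds; defaults to
#'   `seq_len(replicates)` of the preset.
#' @param fdr FDR level for the scan-based presets.
#' @param out Optional directory to write `replicates.tsv` and
#'   `summary.tsv` into.
#' @return List with `replicates` (per-run rows) and `summary`
#'   (per-condition aggregates).
#' @export
run_experiment <- function(preset, scale = "reduced", seeds = NULL,
                           fdr = 0.1, out = NULL) {
  grid <- if (is.data.frame(preset)) preset
          else experiment_preset(preset, scale)
  name <- attr(grid, "preset")
  if (is.null(seeds)) seeds <- seq_len(attr(grid, "replicates"))
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    row <- grid[i, ]
    for (s in seeds) {
      rec <- tryCatch({
        cfg <- .condition_config(row, seed = s)
        sim <- run_simulation(cfg)
        r <- data.frame(label = row$label, seed = s,
                        gcor = equilibrium_gcor(sim),
                        n_qtl_segregating =
                          tail(sim$trajectory$n_qtl_segregating, 1))
        if (!is.na(row$neutral_n) || isTRUE(row$qtn)) {
          smp <- as_genotype_sample(sim)
          if (isTRUE(row$qtn)) {
            rep_q <- discovery_metrics(qtn_scan(smp, fdr = fdr), smp)
            r$FPR <- rep_q$FPR; r$FNR <- rep_q$FNR
            r$N_sign <- rep_q$N_sign; r$N_pleio <- rep_q$N_pleio
            r$N_segr <- rep_q$N_segr
          } else if (identical(name, "table2")) {
            scans <- list(univariate_scan(smp, 1, fdr = fdr),
                          univariate_scan(smp, 2, fdr = fdr))
            rp <- discovery_metrics(scans, smp)
            r$DRpleio <- rp$DRpleio; r$DR_single <- rp$DR_single
            r$SNPsig <- rp$SNPsig; r$SNPpleio <- rp$SNPpleio
            r$r2_mean <- rp$r2_mean
          } else {
            K <- compute_grm(smp)
            sc <- multivariate_scan(smp, K, fdr = fdr)
            rp <- discovery_metrics(sc, smp)
            r$DR <- rp$DR; r$SNPpleio <- rp$SNPpleio
            r$r2_mean <- rp$r2_mean
          }
        }
        r
      }, error = function(e) {
        warning(sprintf("replicate failed (%s, seed %d): %s",
                        row$label, s, conditionMessage(e)), call. = FALSE)
        NULL
      })
      if (!is.null(rec)) rows[[length(rows) + 1]] <- rec
    }
  }
  if (length(rows) == 0) stop("all replicates failed")
  reps <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(unique(unlist(lapply(rows, names))), names(r))
    for (m in miss) r[[m]] <- NA
    r
  }))
  num <- setdiff(names(reps)[vapply(reps, is.numeric, logical(1))], "seed")
  agg <- do.call(rbind, lapply(split(reps, reps$label), function(df) {
    out <- data.frame(label = df$label[1], n_replicates = nrow(df))
    for (v in num) {
      out[[paste0(v, "_mean")]] <- mean(df[[v]], na.rm = TRUE)
      out[[paste0(v, "_sd")]] <- if (nrow(df) > 1) sd(df[[v]], na.rm = TRUE)
                                 else NA_real_
      out[[paste0(v, "_se")]] <- out[[paste0(v, "_sd")]] / sqrt(nrow(df))
    }
    out
  }))
  rownames(agg) <- NULL
  res <- list(replicates = reps, summary = agg, conditions = grid)
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write.table(reps, file.path(out, "replicates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(agg, file.path(out, "summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  res
}
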