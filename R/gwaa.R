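#' Centered genetic relatedness matrix
#'
#' `K = (1/M) * sum_m (g_m - mean(g_m)) (g_m - mean(g_m))'` over the
#' markers passing the minor-allele-frequency filter: centered but not
#' variance-standardized.
#'
#' @param x A `genotype_sample` or an `n x M` dosage matrix.
#' @param maf Minor-allele-frequency threshold (markers below are
#'   excluded; default 0.001).
#' @return Symmetric `n x n` kinship matrix.
#' @export
compute_grm <- function(x, maf = 0.001) {
  G <- if (inherits(x, "genotype_sample")) x$X else as.matrix(x)
  p <- colMeans(G) / 2
  keep <- pmin(p, 1 - p) >= maf
  if (!any(keep)) stop("no markers pass the MAF filter")
  G <- G[, keep, drop = FALSE]
  Gc <- sweep(G, 2, colMeans(G))
  tcrossprod(Gc) / ncol(G)
}

.scan_loci <- function(sample, loci = c("neutral", "qtn", "all")) {
  loci <- match.arg(loci)
  role <- sample$map$role
  switch(loci,
         neutral = which(role == "neutral"),
         qtn = which(role != "neutral"),
         all = seq_along(role))
}

#' Univariate association scan (simple linear regression)
#'
#' Regresses one trait on each marker's dosage (`y = b0 + b1 g`), takes
#' the two-sided t-test p-value on the slope, and adjusts for multiple
#' comparisons with Benjamini-Hochberg at the given FDR level. Markers
#' failing the MAF filter are skipped with a recorded reason.
#'
#' @param sample A `genotype_sample`.
#' @param trait 1 or 2.
#' @param fdr False-discovery-rate level (default 0.1).
#' @param maf MAF threshold (default 0.001; use 0 to keep every
#'   segregating marker, as in the QTN scans).
#' @param loci Which markers to scan: `"neutral"` markers (default),
#'   `"qtn"` causal QTN only, or `"all"`.
#' @return A `scan_result` data frame (marker, chr, cM, maf, beta, stat,
#'   p, p_adj, significant, skipped) with scan metadata in attributes.
#' @export
univariate_scan <- function(sample, trait, fdr = 0.1, maf = 0.001,
                            loci = "neutral") {
  stopifnot(inherits(sample, "genotype_sample"), trait %in% 1:2)
  sel <- .scan_loci(sample, loci)
  map <- sample$map[sel, , drop = FALSE]
  X <- sample$X[, sel, drop = FALSE]
  y <- sample$phen[, trait]
  n <- length(y)
  usable <- map$maf > 0 & map$maf >= maf
  yc <- y - mean(y)
  Xc <- sweep(X, 2, colMeans(X))
  Sxx <- colSums(Xc^2)
  Sxy <- as.vector(crossprod(Xc, yc))
  beta <- ifelse(Sxx > 0, Sxy / Sxx, NA_real_)
  Syy <- sum(yc^2)
  rss <- Syy - ifelse(Sxx > 0, Sxy^2 / Sxx, 0)
  se <- sqrt(pmax(rss, 0) / ((n - 2) * Sxx))
  tstat <- beta / se
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[!usable] <- NA_real_
  p_adj <- rep(NA_real_, length(p))
  p_adj[usable] <- p.adjust(p[usable], method = "BH")
  res <- data.frame(map[, c("marker", "locus_id", "chr", "cM", "role",
                            "maf")],
                    beta = beta, stat = tstat, p = p, p_adj = p_adj,
                    significant = !is.na(p_adj) & p_adj <= fdr,
                    skipped = ifelse(usable, "",
                                     ifelse(map$maf == 0, "monomorphic",
                                            "below MAF threshold")),
                    stringsAsFactors = FALSE)
  structure(res, class = c("scan_result", "data.frame"),
            scan_type = paste0("univariate-", trait), fdr = fdr,
            trait = trait, loci = loci, n = n)
}

#' Storey q-values
#'
#' Estimates the null proportion `pi0` on the lambda grid
#' `0.05, 0.10, ..., 0.95` via `mean(p > lambda) / (1 - lambda)`, smoothed
#' with a cubic spline (df = 3) evaluated at the largest lambda and
#' clamped to `(0, 1]`; then `q_i = min_{p_j >= p_i} pi0 * m * p_j /
#' rank(p_j)`. With `pi0 = 1` this reproduces Benjamini-Hochberg adjusted
#' p-values exactly.
#'
#' @param p Vector of p-values in `[0, 1]` (NAs preserved).
#' @param pi0 Optional fixed null proportion overriding the estimate.
#' @return q-values, monotone nondecreasing in p, with the `pi0` used as
#'   an attribute.
#' @export
storey_qvalues <- function(p, pi0 = NULL) {
  ok <- !is.na(p)
  pv <- p[ok]
  if (length(pv) == 0) stop("no p-values")
  if (any(pv < 0 | pv > 1)) stop("p-values must be in [0, 1]")
  m <- length(pv)
  if (is.null(pi0)) {
    lambda <- seq(0.05, 0.95, by = 0.05)
    pi0_l <- vapply(lambda, function(l) mean(pv > l) / (1 - l), numeric(1))
    pi0 <- tryCatch({
      fit <- smooth.spline(lambda, pi0_l, df = 3)
      predict(fit, x = max(lambda))$y
    }, error = function(e) min(pi0_l[length(pi0_l)], 1))
    pi0 <- min(max(pi0, .Machine$double.eps), 1)
  } else {
    stopifnot(pi0 > 0, pi0 <= 1)
  }
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(pi0 * m * pv[o] / rank(pv, ties.method = "max")[o]))[ro]
  out <- rep(NA_real_, length(p))
  out[ok] <- q
  structure(out, pi0 = pi0)
}

# Negative restricted log-likelihood (x2) of the bivariate no-marker null
# model on the eigenbasis of K; par = log-Cholesky of (Vg, Ve).
.mvlmm_nll <- function(par, d, ystar, xstar) {
  if (any(!is.finite(par)) || any(abs(par) > 50)) return(1e12)
  Lg <- matrix(c(exp(par[1]), par[2], 0, exp(par[3])), 2, 2)
  Le <- matrix(c(exp(par[4]), par[5], 0, exp(par[6])), 2, 2)
  Vg <- Lg %*% t(Lg); Ve <- Le %*% t(Le)
  n <- length(d)
  A <- matrix(0, 2, 2); bv <- c(0, 0)
  Sinv <- .sigma_inverses(d, Vg, Ve)
  ll <- -sum(log(Sinv$det))  # sum of log|Sigma_i|; det holds the inverses
  w11 <- Sinv$i11; w12 <- Sinv$i12; w22 <- Sinv$i22
  x2 <- xstar^2
  A[1, 1] <- sum(x2 * w11); A[2, 2] <- sum(x2 * w22)
  A[1, 2] <- A[2, 1] <- sum(x2 * w12)
  y1 <- ystar[, 1]; y2 <- ystar[, 2]
  bv[1] <- sum(xstar * (w11 * y1 + w12 * y2))
  bv[2] <- sum(xstar * (w12 * y1 + w22 * y2))
  beta <- tryCatch(solve(A, bv), error = function(e) c(0, 0))
  r1 <- y1 - xstar * beta[1]; r2 <- y2 - xstar * beta[2]
  quad <- sum(w11 * r1^2 + 2 * w12 * r1 * r2 + w22 * r2^2)
  detA <- A[1, 1] * A[2, 2] - A[1, 2]^2
  out <- ll + quad + log(max(detA, .Machine$double.xmin))
  if (!is.finite(out)) 1e12 else out
}

# Per-observation inverses of Sigma_i = d_i Vg + Ve; det holds
# 1/|Sigma_i| for the log-likelihood.
.sigma_inverses <- function(d, Vg, Ve) {
  s11 <- d * Vg[1, 1] + Ve[1, 1]
  s12 <- d * Vg[1, 2] + Ve[1, 2]
  s22 <- d * Vg[2, 2] + Ve[2, 2]
  det <- s11 * s22 - s12^2
  if (any(det <= 0)) det <- pmax(det, .Machine$double.xmin)
  list(i11 = s22 / det, i12 = -s12 / det, i22 = s11 / det, det = 1 / det)
}

#' Multivariate linear mixed-model association scan
#'
#' Two-trait mixed model with marker fixed effects on both traits and a
#' random polygenic effect with covariance `K (x) Vg` plus residual
#' `I (x) Ve`. The 2x2 variance components `Vg`, `Ve` are estimated once
#' under the no-marker null by restricted maximum likelihood on the
#' eigenbasis of `K`, then held fixed across markers; each marker is
#' tested by a likelihood-ratio test (2 degrees of freedom: one
#' coefficient per trait) against the null with the same plugged-in
#' covariances. P-values are transformed to Storey q-values over the
#' scan; a marker is significant iff `q <= fdr`.
#'
#' @param sample A `genotype_sample`.
#' @param K Kinship matrix from [compute_grm()] (must be positive
#'   semidefinite).
#' @param fdr FDR level for q-value significance (default 0.1).
#' @param maf MAF threshold (default 0.001).
#' @param loci Markers to scan (as in [univariate_scan()]).
#' @return A `scan_result` data frame with per-marker effect estimates on
#'   both traits, the LRT statistic, p, q and significance; `Vg`, `Ve`,
#'   and the REML convergence code are attached as attributes.
#' @export
multivariate_scan <- function(sample, K, fdr = 0.1, maf = 0.001,
                              loci = "neutral") {
  stopifnot(inherits(sample, "genotype_sample"))
  n <- sample$n
  stopifnot(nrow(K) == n, ncol(K) == n)
  eig <- eigen(K, symmetric = TRUE)
  if (min(eig$values) < -1e-8 * max(abs(eig$values), 1))
    stop("kinship matrix is not positive semidefinite")
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  Y <- sample$phen
  ystar <- crossprod(U, Y)
  ones <- crossprod(U, rep(1, n))[, 1]

  # starting values: split the phenotypic covariance evenly
  P <- cov(Y)
  P <- P + diag(2) * max(diag(P)) * 1e-3
  L0 <- t(chol(P / 2))
  par0 <- c(log(L0[1, 1]), L0[2, 1], log(L0[2, 2]),
            log(L0[1, 1]), L0[2, 1], log(L0[2, 2]))
  opt <- optim(par0, .mvlmm_nll, d = d, ystar = ystar, xstar = ones,
               method = "BFGS", control = list(maxit = 500))
  Lg <- matrix(c(exp(opt$par[1]), opt$par[2], 0, exp(opt$par[3])), 2, 2)
  Le <- matrix(c(exp(opt$par[4]), opt$par[5], 0, exp(opt$par[6])), 2, 2)
  Vg <- Lg %*% t(Lg); Ve <- Le %*% t(Le)

  Sinv <- .sigma_inverses(d, Vg, Ve)
  w11 <- Sinv$i11; w12 <- Sinv$i12; w22 <- Sinv$i22
  y1 <- ystar[, 1]; y2 <- ystar[, 2]

  # null (intercept-only) profile quadratic form with fixed Vg, Ve
  null_fit <- .gls_quad(cbind(ones), w11, w12, w22, y1, y2)

  sel <- .scan_loci(sample, loci)
  map <- sample$map[sel, , drop = FALSE]
  usable <- map$maf > 0 & map$maf >= maf
  M <- nrow(map)
  beta1 <- beta2 <- stat <- p <- rep(NA_real_, M)
  singular <- rep(FALSE, M)
  Gs <- crossprod(U, sample$X[, sel, drop = FALSE])
  for (j in which(usable)) {
    fit <- tryCatch(
      .gls_quad(cbind(ones, Gs[, j]), w11, w12, w22, y1, y2),
      error = function(e) NULL)
    if (is.null(fit)) { singular[j] <- TRUE; next }
    lrt <- null_fit$quad - fit$quad
    stat[j] <- max(lrt, 0)
    p[j] <- pchisq(stat[j], df = 2, lower.tail = FALSE)
    beta1[j] <- fit$beta[3]; beta2[j] <- fit$beta[4]
  }
  usable <- usable & !singular
  q <- rep(NA_real_, M)
  if (any(usable)) q[usable] <- storey_qvalues(p[usable])
  res <- data.frame(map[, c("marker", "locus_id", "chr", "cM", "role",
                            "maf")],
                    beta1 = beta1, beta2 = beta2, stat = stat, p = p,
                    q = q, significant = !is.na(q) & q <= fdr,
                    skipped = ifelse(usable, "",
                                     ifelse(singular, "singular fit",
                                            ifelse(map$maf == 0,
                                                   "monomorphic",
                                                   "below MAF threshold"))),
                    stringsAsFactors = FALSE)
  structure(res, class = c("scan_result", "data.frame"),
            scan_type = "multivariate", fdr = fdr, loci = loci, n = n,
            Vg = Vg, Ve = Ve, reml_convergence = opt$convergence)
}

# Bivariate GLS with per-observation 2x2 weights; X has k columns, the
# coefficient vector interleaves (beta_trait1, beta_trait2) per column.
# Returns the residual quadratic form (the -2 log-likelihood kernel).
.gls_quad <- function(X, w11, w12, w22, y1, y2) {
  k <- ncol(X)
  A <- matrix(0, 2 * k, 2 * k)
  bv <- numeric(2 * k)
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      xx <- X[, a] * X[, b]
      A[2 * a - 1, 2 * b - 1] <- sum(xx * w11)
      A[2 * a - 1, 2 * b] <- A[2 * a, 2 * b - 1] <- sum(xx * w12)
      A[2 * a, 2 * b] <- sum(xx * w22)
    }
    bv[2 * a - 1] <- sum(X[, a] * (w11 * y1 + w12 * y2))
    bv[2 * a] <- sum(X[, a] * (w12 * y1 + w22 * y2))
  }
  beta <- solve(A, bv)
  fit1 <- X %*% beta[seq(1, 2 * k, 2)]
  fit2 <- X %*% beta[seq(2, 2 * k, 2)]
  r1 <- y1 - fit1; r2 <- y2 - fit2
  quad <- sum(w11 * r1^2 + 2 * w12 * r1 * r2 + w22 * r2^2)
  list(beta = beta, quad = quad)
}

#' Univariate scans of causative QTNs
#'
#' Regresses each segregating QTN's own genotype on each trait separately
#' (simple linear regression) with Benjamini-Hochberg correction over the
#' segregating QTNs only, as used for the spurious-pleiotropy
#' (FPR) and missed-pleiotropy (FNR) rates.
#'
#' @param sample A `genotype_sample` from a QTN-mode simulation.
#' @param fdr FDR level (default 0.1).
#' @return List of two `scan_result`s (trait 1 and trait 2).
#' @export
qtn_scan <- function(sample, fdr = 0.1) {
  if (!any(sample$map$role != "neutral"))
    stop("sample contains no QTN markers; run the simulation in QTN mode")
  list(univariate_scan(sample, 1, fdr = fdr, maf = 0, loci = "qtn"),
       univariate_scan(sample, 2, fdr = fdr, maf = 0, loci = "qtn"))
}
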