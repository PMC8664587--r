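#' Estimate the G-matrix from phenotypes
#'
#' With no environmental effects on the traits, the phenotypic
#' (co)variances of a population equal its genetic (co)variances, so the
#' G-matrix is estimated directly from the two phenotype columns
#' (denominator `n - 1`). The genetic correlation is defined as 0 (and
#' flagged) when either variance is 0.
#'
#' @param x An `n x 2` phenotype matrix, a `wf_population`, or a
#'   `wf_simulation` (final population).
#' @return Object of class `gmatrix_estimate`: `var1`, `var2`, `cov`,
#'   `gcor`, `n_individuals`, `gcor_defined`.
#' @export
g_matrix <- function(x) {
  if (inherits(x, "wf_simulation")) x <- x$population
  if (inherits(x, "wf_population")) x <- x$phen
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 individuals")
  v1 <- var(x[, 1]); v2 <- var(x[, 2]); cv <- cov(x[, 1], x[, 2])
  defined <- v1 > 0 && v2 > 0
  structure(list(var1 = v1, var2 = v2, cov = cv,
                 gcor = if (defined) cv / sqrt(v1 * v2) else 0,
                 n_individuals = nrow(x), gcor_defined = defined),
            class = "gmatrix_estimate")
}

#' @export
print.gmatrix_estimate <- function(x, ...) {
  cat(sprintf("<gmatrix_estimate> n=%d  var1=%.4g var2=%.4g cov=%.4g gcor=%.4f%s\n",
              x$n_individuals, x$var1, x$var2, x$cov, x$gcor,
              if (x$gcor_defined) "" else " (undefined; zero variance)"))
  invisible(x)
}

#' Decompose the gametic covariance into genic and LD components
#'
#' The gametic covariance is the covariance, across the `2N` haplotypes in
#' the population, of a haplotype's summed allelic effect on trait 1 with
#' its summed effect on trait 2. The genic covariance is the sum over loci
#' of each locus's own cross-trait allelic covariance (nonzero only at
#' pleiotropic loci, the "within gamete allele effect covariance"); the
#' remainder is the between-locus linkage-disequilibrium contribution.
#' The decomposition `gametic = genic + ld` is exact, and under random
#' union of gametes the total genetic covariance of phenotypes is twice
#' the gametic covariance.
#'
#' @param pop A `wf_population`.
#' @return List `gametic_cov`, `genic_cov`, `ld_cov`.
#' @export
genic_gametic_covariance <- function(pop) {
  stopifnot(inherits(pop, "wf_population"))
  loci <- pop$arch$loci
  t1 <- loci$trait1; t2 <- loci$trait2
  h1 <- colSums(pop$v1[t1, , drop = FALSE])
  h2 <- colSums(pop$v2[t2, , drop = FALSE])
  gametic <- cov(h1, h2)
  causal <- which(t1 | t2)
  genic <- sum(vapply(causal, function(l)
    cov(pop$v1[l, ], pop$v2[l, ]), numeric(1)))
  list(gametic_cov = gametic, genic_cov = genic,
       ld_cov = gametic - genic)
}

#' Multiallelic linkage-disequilibrium r-squared
#'
#' `r^2 = sum_ij D_ij^2 / ((1 - sum_i p_i^2) (1 - sum_j q_j^2))` with
#' `D_ij = f_ij - p_i q_j`, where `f_ij` are haplotype frequencies and
#' `p`, `q` the allele frequencies at the two loci. Reduces to the squared
#' Pearson correlation of 0/1 allele indicators when both loci are
#' diallelic. Returns 0 (flagged via the `"defined"` attribute) when
#' either locus is monomorphic.
#'
#' @param locusA,locusB Allele states of the two loci across the same
#'   haplotypes (any atomic type; continuum-of-alleles values count as the
#'   same allele iff identical).
#' @return r-squared in `[0, 1]`.
#' @export
multiallelic_r2 <- function(locusA, locusB) {
  if (length(locusA) != length(locusB))
    stop("loci must be observed on the same haplotypes")
  a <- as.character(locusA); b <- as.character(locusB)
  if (length(unique(a)) < 2 || length(unique(b)) < 2)
    return(structure(0, defined = FALSE))
  tab <- table(a, b) / length(a)
  p <- rowSums(tab); q <- colSums(tab)
  D <- tab - p %o% q
  r2 <- sum(D^2) / ((1 - sum(p^2)) * (1 - sum(q^2)))
  structure(as.numeric(r2), defined = TRUE)
}

#' Frequency-weighted excess kurtosis of allelic values at a locus
#'
#' Population-moment formula (no small-sample correction):
#' `m4 / m2^2 - 3` with moments about the (weighted) mean. Under the
#' house-of-cards regime this is strongly positive (rare alleles of large
#' effect); a symmetric two-point distribution gives the minimum, -2.
#'
#' @param values Allelic values at the locus.
#' @param freq Optional weights (allele-copy frequencies); equal weights
#'   by default.
#' @return Excess kurtosis; `NA` (flagged) for a degenerate (zero
#'   variance) distribution.
#' @export
allelic_kurtosis <- function(values, freq = NULL) {
  if (is.null(freq)) freq <- rep(1, length(values))
  if (length(freq) != length(values)) stop("freq length mismatch")
  w <- freq / sum(freq)
  m <- sum(w * values)
  m2 <- sum(w * (values - m)^2)
  if (m2 == 0) return(structure(NA_real_, defined = FALSE))
  m4 <- sum(w * (values - m)^4)
  structure(m4 / m2^2 - 3, defined = TRUE)
}

#' Count segregating loci per role class
#'
#' A locus is segregating iff at least two distinct alleles are present
#' (continuum-of-alleles loci: distinct allelic-value pairs; QTN and
#' neutral markers: distinct states).
#'
#' @param pop A `wf_population` or `genotype_sample`.
#' @return Named list: `per_role` (counts by locus role),
#'   `n_qtl_segregating` (continuum QTL), `n_qtn_segregating`,
#'   `n_snp_polymorphic` (neutral markers).
#' @export
segregating_counts <- function(pop) {
  if (inherits(pop, "genotype_sample")) {
    roles <- pop$truth$role
    seg <- pop$truth$segregating
    snp_poly <- sum(pop$map$maf > 0 & pop$map$role == "neutral")
    per_role <- tapply(seg, roles, sum)
  } else {
    stopifnot(inherits(pop, "wf_population"))
    loci <- pop$arch$loci
    seg_l <- vapply(seq_len(nrow(loci)), function(l) {
      any(pop$v1[l, ] != pop$v1[l, 1]) || any(pop$v2[l, ] != pop$v2[l, 1])
    }, logical(1))
    per_role <- tapply(seg_l, loci$role, sum)
    roles <- loci$role
    seg <- seg_l
    snp_poly <- sum(seg_l[roles == "neutral"])
  }
  qtl <- roles %in% c("qtl_trait1", "qtl_trait2", "qtl_pleio")
  qtn <- roles %in% c("qtn_trait1", "qtn_trait2", "qtn_pleio")
  list(per_role = per_role,
       n_qtl_segregating = sum(seg[qtl]),
       n_qtn_segregating = sum(seg[qtn]),
       n_snp_polymorphic = snp_poly)
}
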