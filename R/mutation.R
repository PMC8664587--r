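#' Mutation model parameters
#'
#' Parameters of the mutation process at causal loci and neutral markers.
#' Causal loci mutate at rate `mu` per haploid locus per transmitted gamete
#' per generation. In `"continuum"` mode a Gaussian effect `N(0, alpha2)`
#' is added to the existing allelic value (continuum-of-alleles); at
#' pleiotropic loci the effect on each trait is an independent draw, so the
#' mutational covariance matrix is `M = alpha2 * I` with no mutational
#' correlation. In `"qtn_biallelic"` mode each causal locus carries a fixed
#' effect magnitude and mutation only flips the sign of the allelic effect.
#' Neutral markers are reversible diallelic loci flipping 0/1 at rate
#' `neutral_mu`.
#'
#' @param mu Per-haploid-locus per-generation mutation rate in `[0, 1]`.
#' @param alpha2 Per-locus mutational variance (> 0).
#' @param mode `"continuum"` or `"qtn_biallelic"`.
#' @param neutral_mu Neutral-marker mutation rate.
#' @param qtn_equal_magnitudes If `TRUE`, every QTN locus gets the same
#'   effect magnitude `sqrt(alpha2)`; otherwise (default) each locus's
#'   magnitude is `|N(0, alpha2)|`, drawn once at initialization.
#' @return Object of class `mutation_params`.
#' @export
mutation_params <- function(mu, alpha2,
                            mode = c("continuum", "qtn_biallelic"),
                            neutral_mu = 1e-6,
                            qtn_equal_magnitudes = FALSE) {
  mode <- match.arg(mode)
  if (mu < 0 || mu > 1) stop("mu must be in [0, 1]")
  if (alpha2 <= 0) stop("alpha2 must be positive")
  if (neutral_mu < 0 || neutral_mu > 1) stop("neutral_mu must be in [0, 1]")
  structure(list(mu = mu, alpha2 = alpha2, mode = mode,
                 neutral_mu = neutral_mu,
                 qtn_equal_magnitudes = qtn_equal_magnitudes),
            class = "mutation_params")
}

#' Sample pleiotropic mutation effects
#'
#' Draws mutation-effect vectors at a pleiotropic locus: bivariate Gaussian
#' with mean zero and covariance `alpha2 * I` (independent effects on the
#' two traits, no mutational correlation).
#'
#' @param params A [mutation_params()] object with `mode = "continuum"`.
#' @param n Number of draws.
#' @return Data frame with columns `effect1`, `effect2` and the direction
#'   angle `theta = atan2(effect2, effect1)` (in `[0, 2*pi)`).
#' @export
sample_pleiotropic_effect <- function(params, n = 1) {
  stopifnot(inherits(params, "mutation_params"))
  if (params$mode != "continuum")
    stop("pleiotropic continuum effects require mode = 'continuum'")
  s <- sqrt(params$alpha2)
  e1 <- rnorm(n, 0, s)
  e2 <- rnorm(n, 0, s)
  data.frame(effect1 = e1, effect2 = e2,
             theta = atan2(e2, e1) %% (2 * pi))
}

#' Sample nonpleiotropic mutation effects
#'
#' Draws mutation effects at a locus affecting a single trait: magnitude
#' `a ~ N(0, alpha2)` on the target trait's axis, exactly zero on the other
#' axis. The direction angle is restricted to `{0, pi}` (trait 1) or
#' `{pi/2, 3*pi/2}` (trait 2). Over many mutation events at a linked pair
#' the realized joint distribution is the cross-shaped mixture in which
#' both components are jointly nonzero only for double mutations
#' (probability `mu^2` per haplotype pair per generation).
#'
#' @inheritParams sample_pleiotropic_effect
#' @param target_trait 1 or 2.
#' @return Data frame with columns `effect1`, `effect2`, `theta`.
#' @export
sample_nonpleiotropic_effect <- function(params, target_trait, n = 1) {
  stopifnot(inherits(params, "mutation_params"))
  if (params$mode != "continuum")
    stop("continuum effects require mode = 'continuum'")
  if (!target_trait %in% c(1, 2)) stop("target_trait must be 1 or 2")
  a <- rnorm(n, 0, sqrt(params$alpha2))
  if (target_trait == 1)
    data.frame(effect1 = a, effect2 = 0, theta = ifelse(a >= 0, 0, pi))
  else
    data.frame(effect1 = 0, effect2 = a,
               theta = ifelse(a >= 0, pi / 2, 3 * pi / 2))
}

#' Apply one generation of mutation to a gamete
#'
#' Reference (R-level) implementation of the per-gamete mutation process
#' used by the forward simulator: each causal locus mutates independently
#' with probability `mu` (continuum: add a Gaussian effect to the current
#' allelic value; QTN: flip the sign of the allelic effect), and each
#' neutral marker flips its 0/1 state with probability `neutral_mu`.
#' Non-mutated loci are returned bit-exactly unchanged.
#'
#' @param gamete Numeric matrix `L x 2`: column 1 is the allelic effect on
#'   trait 1 (or neutral-marker state), column 2 the effect on trait 2.
#' @param arch The [build_architecture()] spec the gamete belongs to.
#' @param params A [mutation_params()] object.
#' @return The mutated gamete (same shape).
#' @export
apply_mutations <- function(gamete, arch, params) {
  stopifnot(inherits(arch, "architecture_spec"),
            inherits(params, "mutation_params"))
  if (nrow(gamete) != nrow(arch$loci) || ncol(gamete) != 2)
    stop("gamete dimensions do not match the architecture")
  loci <- arch$loci
  causal <- which(loci$role != "neutral")
  hit <- causal[runif(length(causal)) < params$mu]
  s <- sqrt(params$alpha2)
  for (l in hit) {
    if (params$mode == "continuum") {
      if (loci$trait1[l]) gamete[l, 1] <- gamete[l, 1] + rnorm(1, 0, s)
      if (loci$trait2[l]) gamete[l, 2] <- gamete[l, 2] + rnorm(1, 0, s)
    } else {
      if (loci$trait1[l]) gamete[l, 1] <- -gamete[l, 1]
      if (loci$trait2[l]) gamete[l, 2] <- -gamete[l, 2]
    }
  }
  neut <- which(loci$role == "neutral")
  flip <- neut[runif(length(neut)) < params$neutral_mu]
  if (length(flip)) gamete[flip, 1] <- 1 - gamete[flip, 1]
  gamete
}
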