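#' Equilibrium genetic (co)variance and correlation under the Gaussian
#' regime (Lande)
#'
#' Closed-form per-locus equilibrium of the genetic variance `c`, genetic
#' covariance `b`, and genetic correlation `r = b/c` for two traits with
#' equal mutational variances and selection strengths at
#' mutation-selection balance in an infinite population (Gaussian allelic
#' approximation). The equilibrium per-locus covariance matrix solves
#' `C Omega^-1 C = M` with `M = mu * alpha2 * I`, i.e.
#' `C = sqrt(mu * alpha2) * Omega^(1/2)`, giving
#' \deqn{c = \sqrt{(1 + \sqrt{1-\rho_\omega^2})\,\omega^2 \mu \alpha^2 / 2},
#'       \quad b = \rho_\omega \omega^2 \mu \alpha^2 / (2c).}
#' The ratio is independent of `mu`, `alpha2` and `omega2`:
#' `r = rho_omega / (1 + sqrt(1 - rho_omega^2))`.
#'
#' @param rho_omega Correlational selection in `(-1, 1)`.
#' @param omega2 Stabilizing-selection variance (> 0).
#' @param mu Per-haploid-locus mutation rate (> 0).
#' @param alpha2 Per-locus mutational variance (> 0).
#' @param n_loci Number of loci per trait; `b` and `c` scale linearly with
#'   `n_loci` (linkage equilibrium between loci), the correlation does not.
#' @return List with `covariance` (b), `variance` (c), `correlation` (r).
#' @examples
#' lande_equilibrium(0.9, 100, 1e-5, 0.1)$correlation  # 0.62679...
#' @export
lande_equilibrium <- function(rho_omega, omega2, mu, alpha2, n_loci = 1) {
  if (abs(rho_omega) >= 1) stop("|rho_omega| must be < 1")
  if (omega2 <= 0 || mu <= 0 || alpha2 <= 0)
    stop("omega2, mu and alpha2 must be positive")
  s <- sqrt(1 - rho_omega^2)
  c_loc <- sqrt((1 + s) * omega2 * mu * alpha2 / 2)
  b_loc <- rho_omega * omega2 * mu * alpha2 / (2 * c_loc)
  list(covariance = n_loci * b_loc,
       variance = n_loci * c_loc,
       correlation = b_loc / c_loc)
}

#' House-of-cards equilibrium G-matrix for one locus (or fully linked pair)
#'
#' Equilibrium genetic variance-covariance matrix contributed by a single
#' haploid pleiotropic locus (or a fully linked haploid pair of
#' nonpleiotropic loci) under the house-of-cards approximation for an
#' infinite population at the optimum:
#' `G = 2 mu a a' / (a' Omega^-1 a)` with mutation vector
#' `a = a (cos(theta), sin(theta))'`. The equivalent trigonometric closed
#' form is
#' `G = 2 mu omega2 (1 - rho^2) / (1 - rho * 2 cos(theta) sin(theta)) *
#'  [[cos^2, cos*sin], [cos*sin, sin^2]]`.
#' The magnitude `a` cancels; for `theta` on the trait axes
#' (`0, pi/2, pi, 3pi/2`) the off-diagonal vanishes: nonpleiotropic
#' mutations generate no genetic covariance.
#'
#' @param theta_angle Direction of the mutational vector in the two-trait
#'   plane (radians).
#' @param mu Per-haploid-locus mutation rate.
#' @param omega2 Stabilizing-selection variance.
#' @param rho_omega Correlational selection in `(-1, 1)`.
#' @param form `"outer"` evaluates the matrix-algebra form,
#'   `"closed"` the trigonometric closed form; the two agree to machine
#'   precision.
#' @param n_loci Number of such loci; `G` scales linearly (linkage
#'   equilibrium between loci).
#' @return A 2x2 positive semidefinite rank-1 matrix.
#' @examples
#' hoc_gmatrix(pi / 4, 1e-5, 100, 0.9)  # all entries 1.9e-3
#' @export
hoc_gmatrix <- function(theta_angle, mu, omega2, rho_omega,
                        form = c("outer", "closed"), n_loci = 1) {
  form <- match.arg(form)
  if (abs(rho_omega) >= 1) stop("|rho_omega| must be < 1 (singular Omega)")
  ct <- cos(theta_angle); st <- sin(theta_angle)
  if (form == "outer") {
    a <- c(ct, st)
    Oinv <- matrix(c(1, -rho_omega, -rho_omega, 1), 2, 2) /
      (omega2 * (1 - rho_omega^2))
    G <- 2 * mu * (a %o% a) / drop(a %*% Oinv %*% a)
  } else {
    scl <- 2 * mu * omega2 * (1 - rho_omega^2) /
      (1 - rho_omega * 2 * ct * st)
    G <- scl * matrix(c(ct^2, ct * st, ct * st, st^2), 2, 2)
  }
  n_loci * G
}

#' Classify the mutation regime
#'
#' The Gaussian regime holds for frequent mutations of small effect
#' (`mu >> alpha2 / omega2`), the house-of-cards regime for rare mutations
#' of large effect (`mu << alpha2 / omega2`). A factor-of-10 margin around
#' `mu = alpha2 / omega2` separates the two; parameter sets inside the
#' margin are `"intermediate"`.
#'
#' @inheritParams lande_equilibrium
#' @return `"gaussian"`, `"house_of_cards"`, or `"intermediate"`.
#' @examples
#' classify_regime(1e-3, 0.001, 100)  # "gaussian"
#' classify_regime(1e-5, 0.1, 100)    # "house_of_cards"
#' @export
classify_regime <- function(mu, alpha2, omega2) {
  if (mu <= 0 || alpha2 <= 0 || omega2 <= 0)
    stop("parameters must be positive")
  ratio <- alpha2 / omega2
  if (mu >= 10 * ratio) "gaussian"
  else if (mu <= 0.1 * ratio) "house_of_cards"
  else "intermediate"
}
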