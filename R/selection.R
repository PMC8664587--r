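#' Build a Gaussian stabilizing + correlational selection regime
#'
#' Constructs the bivariate Gaussian selection surface
#' `Omega = omega2 * [[1, rho], [rho, 1]]` with stabilizing-selection
#' variance `omega2` shared by both traits (smaller `omega2` = stronger
#' selection) and correlational-selection coefficient `rho_omega`, together
#' with the local trait optima.
#'
#' @param omega2 Positive stabilizing-selection variance. `Inf` disables
#'   selection entirely (`Omega_inv = 0`, every fitness is 1), which gives
#'   pure Wright-Fisher drift.
#' @param rho_omega Correlational selection in `(-1, 1)`; `|rho| >= 1`
#'   would make the surface singular and is rejected.
#' @param optima Length-2 vector of local trait optima.
#' @return Object of class `selection_regime` with elements `omega2`,
#'   `rho_omega`, `optima`, `Omega` and the cached inverse `Omega_inv`.
#' @examples
#' reg <- build_selection(100, 0.9, c(10, 10))
#' reg$Omega_inv  # [[1, -0.9], [-0.9, 1]] / 19
#' @export
build_selection <- function(omega2, rho_omega = 0, optima = c(10, 10)) {
  if (omega2 <= 0) stop("omega2 must be positive")
  if (abs(rho_omega) >= 1)
    stop("|rho_omega| must be < 1 (singular selection surface)")
  stopifnot(length(optima) == 2)
  Omega <- omega2 * matrix(c(1, rho_omega, rho_omega, 1), 2, 2)
  Omega_inv <- matrix(c(1, -rho_omega, -rho_omega, 1), 2, 2) /
    (omega2 * (1 - rho_omega^2))
  structure(list(omega2 = omega2, rho_omega = rho_omega,
                 optima = as.numeric(optima),
                 Omega = Omega, Omega_inv = Omega_inv),
            class = "selection_regime")
}

#' @export
print.selection_regime <- function(x, ...) {
  cat(sprintf("<selection_regime> omega2=%g, rho_omega=%g, optima=(%g, %g)\n",
              x$omega2, x$rho_omega, x$optima[1], x$optima[2]))
  invisible(x)
}

#' Gaussian viability fitness of two-trait phenotypes
#'
#' Survival probability `w = exp(-(z - theta)' Omega^-1 (z - theta) / 2)`.
#' `w = 1` exactly at the optimum. With `rho_omega > 0`, deviations along
#' the diagonal `(c, c)` are penalized less than anti-diagonal deviations
#' `(c, -c)` of equal norm.
#'
#' @param z Length-2 phenotype vector or an `n x 2` matrix of phenotypes.
#' @param regime A [build_selection()] regime.
#' @return Survival probabilities in `(0, 1]`.
#' @export
fitness <- function(z, regime) {
  stopifnot(inherits(regime, "selection_regime"))
  if (is.null(dim(z))) z <- matrix(z, ncol = 2)
  d <- sweep(z, 2, regime$optima)
  Oi <- regime$Omega_inv
  q <- Oi[1, 1] * d[, 1]^2 + 2 * Oi[1, 2] * d[, 1] * d[, 2] +
    Oi[2, 2] * d[, 2]^2
  exp(-0.5 * q)
}
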