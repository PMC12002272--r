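#' Total farmer growth rate
#'
#' The farming population grows both endogenously (rate `gamma_f`) and by
#' external migration into the study area (rate `mu`).  The two act as
#' hyperparameters of a single total growth rate used by the dynamical
#' system.
#'
#' @param gamma_f Endogenous farmer net growth rate, per year. Must be >= 0.
#' @param mu Farmer migration rate, per year. Must be >= 0.
#' @return `gamma_f + mu`, the total farmer growth rate per year.
#' @examples
#' totalFarmerGrowth(0.015, 0.035)
#' @export
totalFarmerGrowth <- function(gamma_f, mu) {
  if (any(!is.finite(gamma_f)) || any(!is.finite(mu)))
    stop("growth and migration rates must be finite")
  if (any(gamma_f < 0) || any(mu < 0))
    stop("growth and migration rates must be non-negative")
  gamma_f + mu
}

#' Model parameter set
#'
#' Bundles the six rates of the competition model: intrinsic growth of
#' hunter-gatherers (`gamma_hg`) and farmers (`gamma_f`), farmer migration
#' (`mu`), interspecific mortality of each group (`delta_hg`, `delta_f` --
#' excess per-capita disappearance proportional to the other group's
#' density) and the assimilation proportion `eta` (fraction of the
#' hunter-gatherer interaction-loss flux converted into farmers).  The
#' derived total farmer growth `gamma_f_total = gamma_f + mu` is computed
#' once and stored.
#'
#' @param gamma_hg Hunter-gatherer net growth rate, per year.
#' @param gamma_f Farmer endogenous net growth rate, per year.
#' @param delta_hg Hunter-gatherer interspecific mortality, per year per
#'   unit farmer density.
#' @param delta_f Farmer interspecific mortality, per year per unit
#'   hunter-gatherer density.
#' @param eta Assimilation proportion in `[0, 1]`.
#' @param mu Farmer migration rate, per year (default 0).
#' @return An object of class `lvParams`: a named list with the six rates
#'   plus `gamma_f_total`.
#' @examples
#' p <- lvParams(gamma_hg = 0.015, gamma_f = 0.02, delta_hg = 0.01,
#'               delta_f = 0.01, eta = 0.1)
#' p$gamma_f_total
#' @export
lvParams <- function(gamma_hg, gamma_f, delta_hg, delta_f, eta = 0, mu = 0) {
  vals <- c(gamma_hg = gamma_hg, gamma_f = gamma_f, mu = mu,
            delta_hg = delta_hg, delta_f = delta_f, eta = eta)
  if (any(!is.finite(vals))) stop("all parameters must be finite")
  if (any(vals < 0)) stop("all parameters must be non-negative")
  if (eta > 1) stop("eta must lie in [0, 1]")
  structure(list(gamma_hg = gamma_hg, gamma_f = gamma_f, mu = mu,
                 delta_hg = delta_hg, delta_f = delta_f, eta = eta,
                 gamma_f_total = totalFarmerGrowth(gamma_f, mu)),
            class = "lvParams")
}

#' @export
print.lvParams <- function(x, ...) {
  cat("Lotka-Volterra competition parameters (per year):\n")
  cat(sprintf("  gamma_hg = %g   gamma_f = %g   mu = %g  (gamma_f_total = %g)\n",
              x$gamma_hg, x$gamma_f, x$mu, x$gamma_f_total))
  cat(sprintf("  delta_hg = %g   delta_f = %g   eta = %g\n",
              x$delta_hg, x$delta_f, x$eta))
  invisible(x)
}

#' Initial conditions and carrying capacities
#'
#' By default the incumbent hunter-gatherers start at their carrying
#' capacity (`HG0 = K_hg`), and the initial farming population is given
#' through the ratio `rho = F0 / HG0`.  Either `rho` or `F0` may be
#' supplied (exactly one).
#'
#' @param K_hg Hunter-gatherer carrying capacity (> 0), arbitrary density
#'   units; the default unit is `K_hg = 1`.
#' @param K_f Farmer carrying capacity (> 0), same units.
#' @param HG0 Initial hunter-gatherer density; defaults to `K_hg`.
#' @param rho Initial farmer-to-hunter-gatherer ratio `F0 / HG0`.
#' @param F0 Initial farmer density (alternative to `rho`).
#' @return An object of class `lvInit` with fields `HG0`, `F0`, `rho`,
#'   `K_hg`, `K_f`.
#' @examples
#' lvInit(K_hg = 1, K_f = 1.5, rho = 0.1)
#' @export
lvInit <- function(K_hg = 1, K_f = 1.5, HG0 = K_hg, rho = NULL, F0 = NULL) {
  if (!is.null(rho) && !is.null(F0))
    stop("supply exactly one of 'rho' or 'F0'")
  if (is.null(rho) && is.null(F0)) rho <- 0
  if (K_hg <= 0 || K_f <= 0) stop("carrying capacities must be positive")
  if (HG0 <= 0) stop("HG0 must be positive")
  if (is.null(F0)) F0 <- rho * HG0 else rho <- F0 / HG0
  if (F0 < 0) stop("F0 must be non-negative")
  structure(list(HG0 = HG0, F0 = F0, rho = rho, K_hg = K_hg, K_f = K_f),
            class = "lvInit")
}

#' @export
print.lvInit <- function(x, ...) {
  cat(sprintf("Initial conditions: HG0 = %g, F0 = %g (rho = %g); K_hg = %g, K_f = %g\n",
              x$HG0, x$F0, x$rho, x$K_hg, x$K_f))
  invisible(x)
}
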