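# Analytic fixed points, linear stability, and the four competition regimes.
#
# The system always has the trivial equilibrium (0, 0) and the two
# single-population logistic equilibria (K_hg, 0) and (0, K_f).  An interior
# coexistence point, when it exists with positive components, solves the two
# nullclines, which are linear in (HG, F) even with assimilation folded in:
#   gamma_hg (1 - HG/K_hg) - delta_hg F = 0
#   gamma_f_total (1 - F/K_f) + (eta delta_hg - delta_f) HG = 0

lvJacobian <- function(HG, F, params, K_hg, K_f) {
  a <- params$eta * params$delta_hg - params$delta_f
  matrix(c(params$gamma_hg * (1 - 2 * HG / K_hg) - params$delta_hg * F,
           a * F,
           -params$delta_hg * HG,
           params$gamma_f_total * (1 - 2 * F / K_f) + a * HG),
         nrow = 2)
}

stabilityLabel <- function(J, tol = 1e-10) {
  ev <- Re(eigen(J, only.values = TRUE)$values)
  if (all(ev < -tol)) "stable"
  else if (all(ev > tol)) "unstable"
  else if (any(ev > tol) && any(ev < -tol)) "saddle"
  else "degenerate"
}

#' Fixed points of the competition system
#'
#' Returns every non-negative equilibrium -- the origin, the two boundary
#' (single-population) equilibria, and the interior coexistence point when
#' it has positive components -- together with its linear stability from the
#' eigenvalues of the 2x2 Jacobian.
#'
#' @param params An [lvParams] object.
#' @param K_hg,K_f Carrying capacities (> 0).
#' @param tol Tolerance on eigenvalue real parts for the stability call.
#' @return A `data.frame` with columns `HG`, `F`, `type`
#'   (`origin`, `hg_only`, `f_only`, `coexistence`) and `stability`
#'   (`stable`, `unstable`, `saddle`, `degenerate`).
#' @examples
#' p <- lvParams(0.02, 0.02, 0.01, 0.01)
#' fixedPoints(p, K_hg = 1, K_f = 1.5)
#' @export
fixedPoints <- function(params, K_hg = 1, K_f = 1.5, tol = 1e-10) {
  stopifnot(inherits(params, "lvParams"))
  if (K_hg <= 0 || K_f <= 0) stop("carrying capacities must be positive")
  pts <- data.frame(HG = c(0, K_hg, 0), F = c(0, 0, K_f),
                    type = c("origin", "hg_only", "f_only"),
                    stringsAsFactors = FALSE)
  # interior root of the (linear) nullcline system A x = b
  A <- rbind(c(params$gamma_hg / K_hg, params$delta_hg),
             c(params$delta_f - params$eta * params$delta_hg,
               params$gamma_f_total / K_f))
  b <- c(params$gamma_hg, params$gamma_f_total)
  if (abs(det(A)) > tol) {
    x <- solve(A, b)
    if (all(x > tol)) {
      pts <- rbind(pts, data.frame(HG = x[1], F = x[2],
                                   type = "coexistence",
                                   stringsAsFactors = FALSE))
    }
  }
  pts$stability <- vapply(seq_len(nrow(pts)), function(i) {
    stabilityLabel(lvJacobian(pts$HG[i], pts$F[i], params, K_hg, K_f), tol)
  }, character(1))
  pts
}

#' Invasion thresholds of the two boundary equilibria
#'
#' The hunter-gatherers can invade the farmer-only state `(0, K_f)` iff
#' `gamma_hg > delta_hg * K_f`; the farmers can invade the
#' hunter-gatherer-only state `(K_hg, 0)` iff
#' `gamma_f_total > delta_f * K_hg - eta * delta_hg * K_hg`.  Because the
#' invasion eigenvalues are linear in the parameters these thresholds are
#' exact for any `eta`.
#'
#' @inheritParams fixedPoints
#' @return A named numeric vector with `gamma_hg_crit` (critical
#'   hunter-gatherer growth rate for invading the farmer-only state) and
#'   `delta_f_crit` (critical farmer interspecific mortality above which
#'   farmers cannot invade the hunter-gatherer-only state).
#' @examples
#' p <- lvParams(0.015, 0.02, 0.01, 0.01)
#' invasionThresholds(p, K_hg = 1, K_f = 1.5)
#' @export
invasionThresholds <- function(params, K_hg = 1, K_f = 1.5) {
  stopifnot(inherits(params, "lvParams"))
  c(gamma_hg_crit = params$delta_hg * K_f,
    delta_f_crit = params$gamma_f_total / K_hg +
      params$eta * params$delta_hg)
}

#' Classify the long-run competition regime
#'
#' Mutual-invasibility classification from the Jacobian eigenvalues at the
#' two boundary equilibria: if each population can invade the other's
#' single-population state the outcome is stable coexistence; if neither
#' can, the surviving population depends on the initial conditions
#' (bistability); if exactly one can, only that population survives.
#'
#' Parameters lying exactly on a threshold (within `tol`) are degenerate:
#' the less restrictive regime is returned with a warning and the
#' `degenerate` flag set.
#'
#' @inheritParams fixedPoints
#' @return An object of class `lvRegime`: list with `label` (one of
#'   `"HG_only"`, `"F_only"`, `"coexistence"`,
#'   `"initial_condition_dependent"`), the two invasion eigenvalues
#'   `lambda_hg`, `lambda_f`, and `degenerate`.
#' @examples
#' p <- lvParams(0.015, 0.02, 0.005, 0.01)
#' classifyRegime(p, K_hg = 1, K_f = 1.5)$label
#' @export
classifyRegime <- function(params, K_hg = 1, K_f = 1.5, tol = 1e-10) {
  stopifnot(inherits(params, "lvParams"))
  if (K_hg <= 0 || K_f <= 0) stop("carrying capacities must be positive")
  lambda_hg <- params$gamma_hg - params$delta_hg * K_f
  lambda_f <- params$gamma_f_total +
    (params$eta * params$delta_hg - params$delta_f) * K_hg
  degenerate <- abs(lambda_hg) <= tol || abs(lambda_f) <= tol
  if (degenerate)
    warning("parameters lie on a regime boundary; returning the less restrictive regime")
  # on-threshold invaders count as successful (less restrictive outcome)
  hg_inv <- lambda_hg >= -tol
  f_inv <- lambda_f >= -tol
  label <- if (hg_inv && f_inv) "coexistence"
  else if (!hg_inv && !f_inv) "initial_condition_dependent"
  else if (hg_inv) "HG_only"
  else "F_only"
  structure(list(label = label, lambda_hg = lambda_hg, lambda_f = lambda_f,
                 degenerate = degenerate),
            class = "lvRegime")
}

#' @export
print.lvRegime <- function(x, ...) {
  cat(sprintf("Regime: %s  (invasion eigenvalues: HG %.4g, F %.4g%s)\n",
              x$label, x$lambda_hg, x$lambda_f,
              if (x$degenerate) "; degenerate" else ""))
  invisible(x)
}

#' Export a two-parameter regime phase diagram
#'
#' Evaluates [classifyRegime] over a rectangular grid of two parameters and
#' returns (optionally writes) a long-format table suitable for plotting.
#'
#' @param params Baseline [lvParams]; the two swept parameters are
#'   overridden cell by cell.
#' @param sweep Named list of two numeric ranges, e.g.
#'   `list(delta_hg = c(0, 0.04), delta_f = c(0, 0.04))`.  Names must be
#'   `lvParams` fields.
#' @param K_hg,K_f Carrying capacities.
#' @param resolution Grid points per axis.
#' @param path Optional CSV output path.
#' @return A `data.frame` with the two parameter columns and `regime`.
#' @export
regimeGrid <- function(params, sweep, K_hg = 1, K_f = 1.5, resolution = 50,
                       path = NULL) {
  stopifnot(length(sweep) == 2, !is.null(names(sweep)))
  ax <- lapply(sweep, function(r) seq(r[1], r[2], length.out = resolution))
  grid <- expand.grid(ax, KEEP.OUT.ATTRS = FALSE)
  grid$regime <- vapply(seq_len(nrow(grid)), function(i) {
    p <- params
    p[[names(sweep)[1]]] <- grid[i, 1]
    p[[names(sweep)[2]]] <- grid[i, 2]
    p <- lvParams(p$gamma_hg, p$gamma_f, p$delta_hg, p$delta_f,
                  eta = p$eta, mu = p$mu)
    suppressWarnings(classifyRegime(p, K_hg, K_f)$label)
  }, character(1))
  if (!is.null(path)) utils::write.csv(grid, path, row.names = FALSE)
  grid
}
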