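# Event detection on trajectories and the two theoretical scenario-grid
# experiments (growth-rate sweep and interspecific-mortality sweep).

#' Detect the three key demographic events on a trajectory
#'
#' Event 1: the first year in which farmers exceed the hunter-gatherers
#' (the population ratio passes 1).  Event 2: the first year in which the
#' farmers reach their carrying capacity, operationalized as
#' `F >= (1 - tol_K) * K_f`.  Event 3: the first year in which the
#' hunter-gatherers disappear, operationalized as
#' `HG < tol_extinct * K_hg`.  Events are evaluated from year 1 onward;
#' events that do not occur within the trajectory horizon are `NA`
#' (censored), never clamped to the horizon.
#'
#' @param traj An `lvTrajectory` from [lvSimulate].
#' @param K_hg,K_f Carrying capacities; default to the trajectory's own
#'   initial-condition attributes.
#' @param tol_K Relative tolerance for "carrying capacity reached"
#'   (default 1\%).
#' @param tol_extinct Extinction threshold as a fraction of `K_hg`
#'   (default 1\%).
#' @return A list of class `lvEvents` with `t_overtake`, `t_farmer_K`,
#'   `t_hg_extinct` (years, or `NA` when censored).
#' @examples
#' p <- lvParams(0.015, 0.05, 0.01, 0.01, eta = 0.2, mu = 0)
#' traj <- lvSimulate(p, lvInit(K_hg = 1, K_f = 1.5, rho = 0.4), 1500)
#' detectEvents(traj)
#' @export
detectEvents <- function(traj, K_hg = NULL, K_f = NULL,
                         tol_K = 0.01, tol_extinct = 0.01) {
  init <- attr(traj, "init")
  if (is.null(K_hg)) K_hg <- init$K_hg
  if (is.null(K_f)) K_f <- init$K_f
  if (is.null(K_hg) || is.null(K_f))
    stop("carrying capacities unavailable; pass K_hg and K_f explicitly")
  idx <- traj$t >= 1
  t1 <- traj$t[idx][which(traj$F[idx] > traj$HG[idx])[1]]
  t2 <- traj$t[idx][which(traj$F[idx] >= (1 - tol_K) * K_f)[1]]
  t3 <- traj$t[idx][which(traj$HG[idx] < tol_extinct * K_hg)[1]]
  structure(list(t_overtake = t1, t_farmer_K = t2, t_hg_extinct = t3),
            class = "lvEvents")
}

#' @export
print.lvEvents <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "not within horizon" else sprintf("%d y", v)
  cat("Demographic events (years since interaction start):\n")
  cat("  farmers overtake hunter-gatherers:", fmt(x$t_overtake), "\n")
  cat("  farmers reach carrying capacity:  ", fmt(x$t_farmer_K), "\n")
  cat("  hunter-gatherers disappear:       ", fmt(x$t_hg_extinct), "\n")
  invisible(x)
}

#' The nine (eta, rho) exploration scenarios
#'
#' Fixed values of the assimilation proportion and the initial
#' farmer-to-forager ratio under which the two grid experiments are run.
#'
#' @return A `data.frame` with columns `eta` (0, 0.1, 0.2) and `rho`
#'   (0.1, 0.2, 0.4), nine rows.
#' @export
scenarioTable <- function() {
  expand.grid(rho = c(0.1, 0.2, 0.4), eta = c(0, 0.1, 0.2),
              KEEP.OUT.ATTRS = FALSE)[, c("eta", "rho")]
}

#' Run a theoretical scenario-grid experiment
#'
#' Experiment 1 sweeps the two interspecific mortality parameters
#' (`delta_hg`, `delta_f`) over `[0, 0.04]^2` with the growth rates held at
#' `gamma_hg = 0.015` and `gamma_f_total = 0.02`.  Experiment 2 sweeps the
#' growth rates over `gamma_hg in [0.001, 0.022]` and
#' `gamma_f_total in [0.015, 0.07]` with both mortalities held at 0.01.
#' Each grid is run under one or more of the nine (eta, rho) scenarios
#' (see [scenarioTable]); hunter-gatherers start at carrying capacity.
#'
#' @param experiment 1 or 2.
#' @param eta,rho Scenario values; `NULL` runs all nine scenarios.
#' @param resolution Grid points per axis (default 50).
#' @param horizon Maximum timespan in years (default 1500).
#' @param K_hg,K_f Carrying capacities (defaults 1 and 1.5).
#' @param step Solver step in years.
#' @param range1,range2 Optional overrides of the two swept-parameter
#'   ranges.
#' @param tol_K,tol_extinct Event thresholds, see [detectEvents].
#' @return A `data.frame` with one row per grid cell and scenario:
#'   `eta`, `rho`, the two swept parameters, the three event times
#'   (`NA` = censored at the horizon) and the analytic `regime` label.
#' @examples
#' ex2 <- runExperiment(2, eta = 0, rho = 0.1, resolution = 5, horizon = 800)
#' max(ex2$t_overtake, na.rm = TRUE)
#' @export
runExperiment <- function(experiment, eta = NULL, rho = NULL, resolution = 50,
                          horizon = 1500, K_hg = 1, K_f = 1.5, step = 0.1,
                          range1 = NULL, range2 = NULL,
                          tol_K = 0.01, tol_extinct = 0.01) {
  stopifnot(experiment %in% c(1, 2), resolution >= 2)
  scen <- scenarioTable()
  if (!is.null(eta)) scen <- scen[scen$eta %in% eta, , drop = FALSE]
  if (!is.null(rho)) scen <- scen[scen$rho %in% rho, , drop = FALSE]
  if (nrow(scen) == 0) stop("no scenario matches the requested eta/rho")
  if (experiment == 1) {
    nm <- c("delta_hg", "delta_f")
    r1 <- if (is.null(range1)) c(0, 0.04) else range1
    r2 <- if (is.null(range2)) c(0, 0.04) else range2
    fixed <- c(gamma_hg = 0.015, gamma_f_total = 0.02)
  } else {
    nm <- c("gamma_hg", "gamma_f_total")
    r1 <- if (is.null(range1)) c(0.001, 0.022) else range1
    r2 <- if (is.null(range2)) c(0.015, 0.07) else range2
    fixed <- c(delta_hg = 0.01, delta_f = 0.01)
  }
  ax1 <- seq(r1[1], r1[2], length.out = resolution)
  ax2 <- seq(r2[1], r2[2], length.out = resolution)
  cells <- expand.grid(v1 = ax1, v2 = ax2, KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(scen))
  for (s in seq_len(nrow(scen))) {
    e <- scen$eta[s]; r <- scen$rho[s]
    init <- lvInit(K_hg = K_hg, K_f = K_f, rho = r)
    res <- matrix(NA_real_, nrow(cells), 3)
    regime <- character(nrow(cells))
    for (i in seq_len(nrow(cells))) {
      pv <- c(stats::setNames(as.numeric(cells[i, ]), nm), fixed)
      p <- lvParams(gamma_hg = pv[["gamma_hg"]],
                    gamma_f = pv[["gamma_f_total"]],
                    delta_hg = pv[["delta_hg"]], delta_f = pv[["delta_f"]],
                    eta = e, mu = 0)
      traj <- lvSimulate(p, init, horizon, step = step)
      ev <- detectEvents(traj, K_hg, K_f, tol_K, tol_extinct)
      res[i, ] <- c(ev$t_overtake, ev$t_farmer_K, ev$t_hg_extinct)
      regime[i] <- suppressWarnings(classifyRegime(p, K_hg, K_f)$label)
    }
    df <- data.frame(eta = e, rho = r, cells$v1, cells$v2,
                     t_overtake = res[, 1], t_farmer_K = res[, 2],
                     t_hg_extinct = res[, 3], regime = regime,
                     stringsAsFactors = FALSE)
    names(df)[3:4] <- nm
    out[[s]] <- df
  }
  do.call(rbind, out)
}
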