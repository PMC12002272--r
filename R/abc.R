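# Likelihood-free fitting of the competition model to paired observed SPDs:
# rejection sampling on the priors followed by a sequential Monte Carlo
# refinement with a shrinking tolerance (first quartile of the candidate
# distances) and a uniform +/-20% perturbation kernel.

#' Uniform prior ranges for the model parameters
#'
#' Defaults follow ranges suggested for late hunter-gatherers and early
#' farmers in the archaeological demography literature: growth rates
#' `gamma_hg ~ U(0.001, 0.022)` and `gamma_f ~ U(0.015, 0.035)`,
#' interspecific mortalities `delta_hg, delta_f ~ U(0, 0.04)`,
#' assimilation `eta ~ U(0, 0.3)` and migration `mu ~ U(0, 0.035)`.  The
#' initial-ratio prior `rho ~ U(0.1, 0.4)` and the initial forager density
#' `HG0 ~ U(0.8, 1.2)` (in carrying-capacity units) are package defaults,
#' exposed here for overriding.
#'
#' @param ... Named length-2 numeric vectors overriding individual ranges,
#'   e.g. `eta = c(0, 0.5)`.
#' @return Named list of `c(min, max)` ranges of class `abcPriors`.
#' @examples
#' abcPriors(rho = c(0.05, 0.5))
#' @export
abcPriors <- function(...) {
  pr <- list(gamma_hg = c(0.001, 0.022), gamma_f = c(0.015, 0.035),
             delta_hg = c(0, 0.04), delta_f = c(0, 0.04),
             eta = c(0, 0.3), mu = c(0, 0.035),
             rho = c(0.1, 0.4), HG0 = c(0.8, 1.2))
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(pr)) stop("unknown prior name: ", nm)
    stopifnot(length(over[[nm]]) == 2, over[[nm]][1] <= over[[nm]][2])
    pr[[nm]] <- as.numeric(over[[nm]])
  }
  structure(pr, class = "abcPriors")
}

samplePriors <- function(n, priors) {
  as.data.frame(lapply(priors, function(r) stats::runif(n, r[1], r[2])))
}

#' Assemble an observed case for inference
#'
#' Applies the full data-preparation pipeline to a labelled radiocarbon
#' date table: drop dates with measurement error above `sd_max`; calibrate
#' on `curve`; fix the chronological window (by default from 100 years
#' before the earliest -- i.e. oldest median -- farming date down to the
#' year where the farmer SPD peaks); keep dates with more than half their
#' calibrated mass inside the window; thin to one date per `bin_width`-year
#' bin within each population; and build the paired hunter-gatherer and
#' farmer SPDs, jointly normalized so the two densities together sum to 1
#' (preserving their relative sizes).  The farmer carrying capacity is set
#' from the SPD peak ratio: `K_f = K_hg * max(SPD_f) / max(SPD_hg)`.
#'
#' @param dates `data.frame` with columns `lab_id`, `cra`, `sd`, `label`
#'   (labels `"hg"` / `"farmer"`).
#' @param curve A `calCurve`.
#' @param window Optional length-2 numeric (calBP) fixing the analysis
#'   window; when `NULL` it is derived from the data as above.
#' @param lead Years added before the earliest farming date (default 100).
#' @param sd_max Maximum retained measurement error (default 120).
#' @param bin_width Thinning bin width in years (default 20).
#' @return An `abcCase`: list with the window, grid (descending calBP),
#'   observed SPD pair, retained counts, peak-ratio `kf_ratio`, the
#'   measurement-error pool and the curve.
#' @export
buildCase <- function(dates, curve, window = NULL, lead = 100,
                      sd_max = 120, bin_width = 20) {
  req <- c("lab_id", "cra", "sd", "label")
  if (!all(req %in% names(dates)))
    stop("dates must have columns ", paste(req, collapse = ", "))
  if (!all(dates$label %in% c("hg", "farmer")))
    stop("labels must be 'hg' or 'farmer'")
  dates <- dates[dates$sd <= sd_max, , drop = FALSE]
  if (!any(dates$label == "farmer"))
    stop("no farming dates remain after the measurement-error filter")
  if (!any(dates$label == "hg"))
    stop("no hunter-gatherer dates remain after the measurement-error filter")
  dens <- calibrateDates(dates$cra, dates$sd, curve)
  med <- calMedian(dens)
  if (is.null(window)) {
    start <- max(med[dates$label == "farmer"]) + lead
    prov <- windowIndices(curve$calbp, c(start, min(curve$calbp)))
    fsum <- rowSums(dens[prov, dates$label == "farmer", drop = FALSE])
    end <- curve$calbp[prov][which.max(fsum)]
    window <- c(start, end)
  }
  start <- max(window); end <- min(window)
  if (start <= end + 1) stop("degenerate analysis window")
  keep <- windowFilter(dens, window)
  if (!any(keep & dates$label == "farmer") || !any(keep & dates$label == "hg"))
    stop("a population has no dates left inside the analysis window")
  spds <- list(); n_lab <- c(hg = 0L, farmer = 0L)
  for (lab in c("hg", "farmer")) {
    sel <- which(keep & dates$label == lab)
    sel <- sel[binThin(med[sel], bin_width)]
    n_lab[lab] <- length(sel)
    spds[[lab]] <- buildSPD(dens[, sel, drop = FALSE], window, "none",
                            calbp = curve$calbp)
  }
  tot <- sum(spds$hg$density) + sum(spds$farmer$density)
  spd_hg <- spds$hg$density / tot
  spd_f <- spds$farmer$density / tot
  if (start > max(curve$calbp) || end < min(curve$calbp))
    stop("analysis window extends beyond the calibration curve span")
  widx <- windowIndices(curve$calbp, c(start, end))
  structure(list(window = c(start = start, end = end),
                 grid = spds$hg$calbp,
                 spd = list(hg = spd_hg, f = spd_f),
                 n_hg = unname(n_lab["hg"]), n_f = unname(n_lab["farmer"]),
                 n_dates = sum(n_lab),
                 kf_ratio = max(spd_f) / max(spd_hg),
                 sd_pool = dates$sd[keep],
                 curve = curve,
                 curve_sig2 = curve$sigma^2,
                 i0 = min(widx), i1 = max(widx)),
            class = "abcCase")
}

#' @export
print.abcCase <- function(x, ...) {
  cat(sprintf("Observed case: window %d-%d calBP (%d y), %d dates (hg %d / farmer %d), K_f/K_hg = %.3g\n",
              x$window["start"], x$window["end"],
              x$window["start"] - x$window["end"], x$n_dates,
              x$n_hg, x$n_f, x$kf_ratio))
  invisible(x)
}

#' Distance between simulated and observed SPD pairs
#'
#' The tolerance measure of the inference: the sum of the Euclidean
#' distances between the simulated and observed SPDs of the
#' hunter-gatherers and of the farmers, on a shared annual grid.
#'
#' @param sim,obs Lists with numeric components `hg` and `f` on identical
#'   grids.
#' @return A single non-negative distance.
#' @export
spdDistance <- function(sim, obs) {
  if (length(sim$hg) != length(obs$hg) || length(sim$f) != length(obs$f))
    stop("simulated and observed SPDs are on different grids")
  sqrt(sum((sim$hg - obs$hg)^2)) + sqrt(sum((sim$f - obs$f)^2))
}

#' Simulate a candidate SPD pair for one parameter draw
#'
#' Integrates the competition model over the case window (with
#' `K_hg = HG0` and `K_f` from the case peak ratio), draws the same number
#' of labelled dates as the observed case via [sampleDatesFromModel] (with
#' measurement errors resampled from the observed pool), recalibrates
#' them, and rebuilds the SPD pair on the case grid with the same joint
#' normalization as the observed pair.
#'
#' @param theta Named list/one-row data.frame with `gamma_hg`, `gamma_f`,
#'   `mu`, `delta_hg`, `delta_f`, `eta`, `rho`, `HG0`.
#' @param case An `abcCase`.
#' @param step Solver step, years.
#' @param tail_sd Calibrated densities are evaluated within `tail_sd`
#'   composed standard deviations of the measured age.
#' @return List with `hg` and `f` SPD vectors on the case grid.
#' @export
simulateCandidate <- function(theta, case, step = 1, tail_sd = 5) {
  horizon <- as.integer(case$window[["start"]] - case$window[["end"]])
  m <- .lv_integrate_cpp(theta$gamma_hg, theta$gamma_f + theta$mu,
                         theta$delta_hg, theta$delta_f, theta$eta,
                         theta$HG0, case$kf_ratio * theta$HG0,
                         theta$HG0, theta$rho * theta$HG0,
                         horizon, step, 1e-12)
  w <- m[, 1] + m[, 2]
  if (sum(w) <= 0) stop("trajectory has zero total density; cannot sample dates")
  n <- case$n_dates
  # identical draw sequence to sampleDatesFromModel (years, labels,
  # measurement errors, uncalibrated ages)
  ti <- sample.int(length(w), n, replace = TRUE, prob = w)
  farmer <- stats::runif(n) < m[ti, 2] / w[ti]
  sd <- if (length(case$sd_pool) > 1)
    sample(case$sd_pool, n, replace = TRUE)
  else rep(case$sd_pool, n)
  gi <- (case$window[["start"]] - (ti - 1L)) - case$curve$calbp[1] + 1L
  cra <- stats::rnorm(n, case$curve$c14[gi],
                      sqrt(sd^2 + case$curve$sigma[gi]^2))
  s <- .spd_sample_cpp(cra, sd, farmer, case$curve$c14, case$curve_sig2,
                       case$i0 - 1L, case$i1 - 1L, tail_sd)
  hg <- rev(s$hg)  # ascending calBP -> the case grid (descending calBP)
  f <- rev(s$f)
  tot <- sum(hg) + sum(f)
  if (tot == 0) stop("candidate SPDs have zero mass inside the window")
  list(hg = hg / tot, f = f / tot)
}

# fixed parameter-column order shared with the compiled engine
abcParNames <- c("gamma_hg", "gamma_f", "mu", "delta_hg", "delta_f",
                 "eta", "rho", "HG0")

# case payload consumed by the compiled batch simulator; SPDs are passed in
# ascending calBP order (the internal accumulation order)
caseForEngine <- function(case, step, tail_sd = 5) {
  list(obs_hg = rev(case$spd$hg), obs_f = rev(case$spd$f),
       mu = case$curve$c14, sig2 = case$curve_sig2,
       calbp = as.numeric(case$curve$calbp),
       sd_pool = as.numeric(case$sd_pool),
       n_dates = as.integer(case$n_dates),
       horizon = as.integer(case$window[["start"]] - case$window[["end"]]),
       gi0 = as.integer(case$window[["start"]] - case$curve$calbp[1]),
       kf_ratio = case$kf_ratio, step = step, clip_tol = 1e-12,
       tail_sd = tail_sd)
}

#' Rejection-sampling stage
#'
#' Draws `n_sims` parameter sets from the priors, simulates each
#' (compiled pipeline equivalent to [simulateCandidate]), and keeps the
#' `keep` particles with the smallest distance to the observed SPD pair
#' (ties broken by draw order).
#'
#' @param case An `abcCase`.
#' @param priors An [abcPriors] list.
#' @param n_sims Number of prior draws (default 15000).
#' @param keep Number of particles retained (default 500).
#' @param step Solver step, years.
#' @return `data.frame` of particles: parameter columns plus `epsilon`
#'   and `stage = 0`.
#' @export
rejectionABC <- function(case, priors = abcPriors(), n_sims = 15000,
                         keep = 500, step = 1) {
  stopifnot(n_sims >= keep)
  draws <- samplePriors(n_sims, priors)
  eps <- .abc_batch_cpp(as.matrix(draws[, abcParNames]),
                        caseForEngine(case, step))
  sel <- order(eps)[seq_len(keep)]
  out <- draws[sel, abcParNames, drop = FALSE]
  out$epsilon <- eps[sel]
  out$stage <- 0L
  rownames(out) <- NULL
  out
}

# Uniform +/-20% perturbation of one particle, redrawn until inside the
# prior support.  A small absolute floor (1e-4 of the prior width) keeps
# particles at a zero lower bound from freezing under the multiplicative
# kernel.
perturbParticle <- function(x, priors) {
  out <- x
  for (nm in names(priors)) {
    r <- priors[[nm]]
    w <- max(0.2 * abs(x[[nm]]), 1e-4 * (r[2] - r[1]))
    repeat {
      v <- stats::runif(1, x[[nm]] - w, x[[nm]] + w)
      if (v >= r[1] && v <= r[2]) break
    }
    out[[nm]] <- v
  }
  out
}

#' Sequential Monte Carlo refinement
#'
#' Runs `stages` SMC stages.  Each stage receives the previous particles
#' as candidates, sets its tolerance to the first quartile of their
#' distances, and then repeatedly picks a candidate uniformly at random,
#' perturbs every parameter with the uniform `U(x - 20\%, x + 20\%)`
#' kernel (redrawn until inside the prior support), simulates, and accepts
#' the proposal if its distance falls below the stage tolerance, until
#' `nrow(particles)` proposals have been accepted.
#'
#' @param case An `abcCase`.
#' @param particles Candidate particles (from [rejectionABC] or a previous
#'   SMC run).
#' @param priors An [abcPriors] list.
#' @param stages Number of SMC stages (default 6).
#' @param step Solver step, years.
#' @param max_attempts_factor A stage errors out ("stall") after
#'   `max_attempts_factor * keep` attempted proposals.
#' @return List of class `abcSMC` with the final `particles`, the
#'   per-stage tolerance `schedule` and per-stage `acceptance` rates.
#' @export
smcABC <- function(case, particles, priors = abcPriors(), stages = 6,
                   step = 1, max_attempts_factor = 2000) {
  keep <- nrow(particles)
  cs <- caseForEngine(case, step)
  lo <- vapply(priors[abcParNames], `[`, numeric(1), 1)
  hi <- vapply(priors[abcParNames], `[`, numeric(1), 2)
  schedule <- numeric(stages)
  acceptance <- numeric(stages)
  mat <- as.matrix(particles[, abcParNames])
  eps <- particles$epsilon
  for (s in seq_len(stages)) {
    eps_thr <- stats::quantile(eps, 0.25, names = FALSE)
    schedule[s] <- eps_thr
    st <- .abc_smc_stage_cpp(mat, eps_thr, lo, hi,
                             as.integer(max_attempts_factor * keep), cs)
    mat <- st$particles
    eps <- st$epsilon
    acceptance[s] <- keep / st$attempts
  }
  out <- as.data.frame(mat)
  names(out) <- abcParNames
  out$epsilon <- eps
  out$stage <- stages
  structure(list(particles = out, schedule = schedule,
                 acceptance = acceptance),
            class = "abcSMC")
}

#' Full inference with randomized restarts
#'
#' Runs the complete rejection + SMC pipeline `starts` times from
#' independent random seeds, pools the final-stage particles of all runs,
#' and keeps the `keep` pooled particles with the smallest distance --
#' guarding against individual runs settling in local optima.
#'
#' @param case An `abcCase`.
#' @param priors An [abcPriors] list.
#' @param n_sims,keep,stages,starts Inference budget: prior draws per
#'   rejection stage, particles kept, SMC stages, randomized starts.
#'   Defaults are the full budget (15000 / 500 / 6 / 100); reduce for
#'   desk-scale runs.
#' @param seed Optional master seed; per-start substream seeds are drawn
#'   from it and recorded on the result.
#' @param step Solver step, years.
#' @return List of class `abcFit`: pooled `particles` (with a `start`
#'   column), per-start tolerance `schedules`, acceptance rates, substream
#'   `seeds` and the `case`.
#' @export
fitABC <- function(case, priors = abcPriors(), n_sims = 15000, keep = 500,
                   stages = 6, starts = 100, seed = NULL, step = 1) {
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, starts)
  runs <- vector("list", starts)
  schedules <- matrix(NA_real_, starts, stages)
  acceptance <- matrix(NA_real_, starts, stages)
  for (k in seq_len(starts)) {
    set.seed(seeds[k])
    cand <- rejectionABC(case, priors, n_sims, keep, step)
    smc <- smcABC(case, cand, priors, stages, step)
    smc$particles$start <- k
    runs[[k]] <- smc$particles
    schedules[k, ] <- smc$schedule
    acceptance[k, ] <- smc$acceptance
  }
  pooled <- do.call(rbind, runs)
  pooled <- pooled[order(pooled$epsilon)[seq_len(min(keep, nrow(pooled)))], ]
  rownames(pooled) <- NULL
  structure(list(particles = pooled, schedules = schedules,
                 acceptance = acceptance, seeds = seeds, priors = priors,
                 budget = c(n_sims = n_sims, keep = keep, stages = stages,
                            starts = starts),
                 case = case),
            class = "abcFit")
}

#' @export
print.abcFit <- function(x, ...) {
  b <- x$budget
  cat(sprintf("ABC-SMC fit: %d particles pooled from %d start(s) (budget %d sims / %d kept / %d stages)\n",
              nrow(x$particles), b["starts"], b["n_sims"], b["keep"],
              b["stages"]))
  cat(sprintf("  distance range: %.4g - %.4g\n",
              min(x$particles$epsilon), max(x$particles$epsilon)))
  invisible(x)
}

#' Highest posterior density interval from samples
#'
#' Shortest interval containing a fraction `prob` of the sample: the
#' minimum-width window over the sorted values.
#'
#' @param x Numeric sample.
#' @param prob Probability mass (default 0.95).
#' @return Named numeric `c(lower, upper)`.
#' @examples
#' hpdi(rnorm(10000))
#' @export
hpdi <- function(x, prob = 0.95) {
  xs <- sort(x)
  n <- length(xs)
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(lower = xs[1], upper = xs[n]))
  starts <- seq_len(n - m)
  w <- xs[starts + m] - xs[starts]
  i <- which.min(w)
  c(lower = xs[i], upper = xs[i + m])
}

#' Posterior summaries, event-time posteriors, and predictive bands
#'
#' Per-parameter median, mean and 95\% HPDI (including the derived total
#' farmer growth); event-time posteriors from the deterministic trajectory
#' of each particle (farmer overtake, farmer carrying capacity,
#' hunter-gatherer disappearance); the fraction of particles in which the
#' hunter-gatherers disappear inside the window; and pointwise 95\%
#' posterior predictive SPD bands from resimulated particles.
#'
#' @param fit An `abcFit` (or a bare particle `data.frame` plus `case`).
#' @param case The `abcCase`; defaults to `fit$case`.
#' @param prob Credible mass for the HPDIs (default 0.95).
#' @param n_pred Number of particles resimulated for the predictive bands
#'   (0 disables banding).
#' @param step Solver step, years.
#' @return List of class `abcSummary` with elements `params` (summary
#'   table), `events` (per-particle event times), `event_summary`,
#'   `extinction_fraction`, and `bands`.
#' @export
summarizePosterior <- function(fit, case = NULL, prob = 0.95, n_pred = 100,
                               step = 1) {
  particles <- if (is.data.frame(fit)) fit else fit$particles
  if (is.null(case)) case <- fit$case
  stopifnot(nrow(particles) > 0)
  particles$gamma_f_total <- particles$gamma_f + particles$mu
  par_names <- c("gamma_hg", "gamma_f", "mu", "gamma_f_total", "delta_hg",
                 "delta_f", "eta", "rho", "HG0")
  par_names <- intersect(par_names, names(particles))
  tab <- do.call(rbind, lapply(par_names, function(nm) {
    x <- particles[[nm]]
    h <- hpdi(x, prob)
    data.frame(parameter = nm, median = stats::median(x), mean = mean(x),
               hpdi_lower = h[["lower"]], hpdi_upper = h[["upper"]])
  }))
  horizon <- as.integer(case$window["start"] - case$window["end"])
  ev <- do.call(rbind, lapply(seq_len(nrow(particles)), function(i) {
    th <- particles[i, ]
    p <- lvParams(th$gamma_hg, th$gamma_f, th$delta_hg, th$delta_f,
                  eta = th$eta, mu = th$mu)
    init <- lvInit(K_hg = th$HG0, K_f = case$kf_ratio * th$HG0,
                   rho = th$rho)
    e <- detectEvents(lvSimulate(p, init, horizon, step = step))
    data.frame(t_overtake = e$t_overtake, t_farmer_K = e$t_farmer_K,
               t_hg_extinct = e$t_hg_extinct)
  }))
  ev_summary <- do.call(rbind, lapply(names(ev), function(nm) {
    x <- ev[[nm]][!is.na(ev[[nm]])]
    if (length(x) == 0)
      return(data.frame(event = nm, n = 0L, median = NA_real_,
                        mean = NA_real_, hpdi_lower = NA_real_,
                        hpdi_upper = NA_real_))
    h <- hpdi(x, prob)
    data.frame(event = nm, n = length(x), median = stats::median(x),
               mean = mean(x), hpdi_lower = h[["lower"]],
               hpdi_upper = h[["upper"]])
  }))
  bands <- NULL
  if (n_pred > 0) {
    idx <- if (nrow(particles) <= n_pred) seq_len(nrow(particles))
    else sample.int(nrow(particles), n_pred)
    sims_hg <- sims_f <- matrix(NA_real_, length(case$grid), length(idx))
    for (j in seq_along(idx)) {
      s <- simulateCandidate(particles[idx[j], ], case, step)
      sims_hg[, j] <- s$hg
      sims_f[, j] <- s$f
    }
    qs <- c((1 - prob) / 2, 1 - (1 - prob) / 2)
    bands <- data.frame(calbp = case$grid,
                        hg_lower = apply(sims_hg, 1, quantile, qs[1]),
                        hg_upper = apply(sims_hg, 1, quantile, qs[2]),
                        f_lower = apply(sims_f, 1, quantile, qs[1]),
                        f_upper = apply(sims_f, 1, quantile, qs[2]),
                        hg_obs = case$spd$hg, f_obs = case$spd$f)
  }
  structure(list(params = tab, events = ev, event_summary = ev_summary,
                 extinction_fraction = mean(!is.na(ev$t_hg_extinct)),
                 bands = bands, prob = prob),
            class = "abcSummary")
}

#' @export
print.abcSummary <- function(x, ...) {
  cat(sprintf("Posterior summary (%d%% HPDI):\n", round(100 * x$prob)))
  print(x$params, row.names = FALSE, digits = 3)
  cat("\nEvent-time posteriors (years since interaction start):\n")
  print(x$event_summary, row.names = FALSE, digits = 4)
  cat(sprintf("\nHunter-gatherer disappearance within the window: %.1f%% of particles\n",
              100 * x$extinction_fraction))
  invisible(x)
}
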