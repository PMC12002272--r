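# Fully synthetic, ground-truth-labelled radiocarbon datasets generated from
# known parameters, and the tactical parameter-recovery experiments run on
# them.

#' Tactical-simulation design
#'
#' The factorial design of the parameter-recovery experiments: sample
#' sizes 10/25/50/100/200/400 dates, total interaction periods of
#' 600/800/1000 years, and interaction starting points 100/200/300/400
#' years before the earliest farming date.  The default true parameter
#' values sit at the midpoints of the priors.
#'
#' @param n_dates Sample sizes to test.
#' @param interaction_length Interaction periods, years.
#' @param offsets Pre-farming starting offsets, years.
#' @param replicates Replicates per design cell.
#' @param truth Named list: true `params` ([lvParams]) and `rho`.
#' @param budget Named numeric: `n_sims`, `keep`, `stages`, `starts` for
#'   each fit (default is a reduced desk-scale budget; the full budget is
#'   15000/500/6/100).
#' @return A list of class `tacticalDesign`.
#' @export
tacticalDesign <- function(n_dates = c(10, 25, 50, 100, 200, 400),
                           interaction_length = c(600, 800, 1000),
                           offsets = c(100, 200, 300, 400),
                           replicates = 1,
                           truth = NULL,
                           budget = c(n_sims = 1500, keep = 100,
                                      stages = 3, starts = 5)) {
  if (is.null(truth)) {
    pr <- abcPriors()
    mid <- function(nm) mean(pr[[nm]])
    truth <- list(params = lvParams(mid("gamma_hg"), mid("gamma_f"),
                                    mid("delta_hg"), mid("delta_f"),
                                    eta = mid("eta"), mu = mid("mu")),
                  rho = mid("rho"))
  }
  stopifnot(replicates >= 1,
            all(c("n_sims", "keep", "stages", "starts") %in% names(budget)))
  structure(list(n_dates = n_dates,
                 interaction_length = interaction_length,
                 offsets = offsets, replicates = replicates,
                 truth = truth, budget = budget),
            class = "tacticalDesign")
}

#' Generate a synthetic labelled radiocarbon dataset
#'
#' Integrates the model from known parameters, samples `n` labelled dates
#' from the trajectory (multinomial in time, binomial in population label,
#' with uncalibrate noise; see [sampleDatesFromModel]), and returns a date
#' table schema-identical to an observed case together with a ground-truth
#' sidecar.  The truth record is carried separately so it can never leak
#' into the fitting path.
#'
#' @param params True [lvParams].
#' @param rho True initial farmer-to-forager ratio.
#' @param n Number of dates.
#' @param curve A `calCurve`.
#' @param interaction_length Window length, years.
#' @param start_calbp Calendar year (calBP) at which the interaction
#'   starts.
#' @param HG0 Initial forager density (`K_hg = HG0`).
#' @param K_f True farmer carrying capacity.
#' @param sd_model Measurement-error model (default constant 40 y); see
#'   [sampleDatesFromModel].
#' @param step Solver step, years.
#' @return List with `dates` (the date table) and `truth` (parameters,
#'   rho, capacities, window).
#' @export
generateDataset <- function(params, rho, n, curve,
                            interaction_length = 800, start_calbp = 7000,
                            HG0 = 1, K_f = 1.5, sd_model = 40, step = 0.1) {
  stopifnot(inherits(params, "lvParams"), n >= 1)
  init <- lvInit(K_hg = HG0, K_f = K_f, rho = rho)
  traj <- lvSimulate(params, init, interaction_length, step = step)
  if (sum(traj$HG + traj$F) <= 0)
    stop("degenerate trajectory: zero total density")
  dates <- sampleDatesFromModel(traj, n, curve, start_calbp, sd_model)
  truth <- list(params = params, rho = rho, HG0 = HG0, K_hg = HG0,
                K_f = K_f,
                window = c(start = start_calbp,
                           end = start_calbp - interaction_length))
  list(dates = dates, truth = truth)
}

#' Write a generated date table as CSV
#'
#' @param dates Date table from [generateDataset].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeDates <- function(dates, path) {
  utils::write.csv(dates, path, row.names = FALSE)
  invisible(path)
}

#' Read a labelled radiocarbon date table
#'
#' @param path CSV with columns `lab_id`, `cra`, `sd`, `label`.
#' @return A `data.frame`.
#' @export
readDates <- function(path) {
  d <- utils::read.table(path, sep = ",", header = TRUE,
                         stringsAsFactors = FALSE)
  req <- c("lab_id", "cra", "sd", "label")
  if (!all(req %in% names(d)))
    stop("date table must have columns ", paste(req, collapse = ", "))
  d
}

#' Parameter-recovery suite
#'
#' For each design cell (sample size x interaction length x offset) and
#' replicate: generate a synthetic dataset from the true parameters,
#' assemble the case with the standard pipeline (window fixed from the
#' design), fit by ABC-SMC at the design budget, and record per-parameter
#' posterior bias (median minus truth), RMSE contribution, and whether the
#' 95\% HPDI covers the truth.
#'
#' @param design A [tacticalDesign].
#' @param curve A `calCurve`.
#' @param priors An [abcPriors] list.
#' @param start_calbp Calendar anchor of the interaction start, calBP.
#' @param verbose Print one line per fitted cell.
#' @return A `data.frame`, one row per cell x replicate x parameter, with
#'   columns `n`, `length`, `offset`, `replicate`, `parameter`, `truth`,
#'   `estimate` (posterior median), `bias`, `covered`.  Cells whose fit
#'   fails are reported with `NA` estimates, never silently dropped.
#' @export
recoverySuite <- function(design, curve, priors = abcPriors(),
                          start_calbp = 7000, verbose = FALSE) {
  stopifnot(inherits(design, "tacticalDesign"))
  b <- design$budget
  cells <- expand.grid(n = design$n_dates,
                       length = design$interaction_length,
                       offset = design$offsets,
                       replicate = seq_len(design$replicates),
                       KEEP.OUT.ATTRS = FALSE)
  truth_vec <- c(gamma_hg = design$truth$params$gamma_hg,
                 gamma_f_total = design$truth$params$gamma_f_total,
                 delta_hg = design$truth$params$delta_hg,
                 delta_f = design$truth$params$delta_f,
                 eta = design$truth$params$eta,
                 rho = design$truth$rho)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    res <- tryCatch({
      gen <- generateDataset(design$truth$params, design$truth$rho,
                             n = cl$n, curve = curve,
                             interaction_length = cl$length,
                             start_calbp = start_calbp)
      # the fitted window starts `offset` years before the earliest
      # (oldest-median) farming date, mirroring the observed-case rule
      dens <- calibrateDates(gen$dates$cra, gen$dates$sd, curve)
      med <- calMedian(dens)
      start <- max(med[gen$dates$label == "farmer"]) + cl$offset
      case <- buildCase(gen$dates, curve,
                        window = c(start, start - cl$length))
      fit <- fitABC(case, priors, n_sims = b["n_sims"], keep = b["keep"],
                    stages = b["stages"], starts = b["starts"])
      sm <- summarizePosterior(fit, n_pred = 0)
      tab <- sm$params
      data.frame(parameter = names(truth_vec),
                 truth = unname(truth_vec),
                 estimate = tab$median[match(names(truth_vec),
                                             tab$parameter)],
                 covered = truth_vec >=
                   tab$hpdi_lower[match(names(truth_vec), tab$parameter)] &
                   truth_vec <=
                   tab$hpdi_upper[match(names(truth_vec), tab$parameter)])
    }, error = function(e) {
      data.frame(parameter = names(truth_vec), truth = unname(truth_vec),
                 estimate = NA_real_, covered = NA)
    })
    res$bias <- res$estimate - res$truth
    rows[[i]] <- cbind(cl, res, row.names = NULL)
    if (verbose)
      cat(sprintf("cell %d/%d: n=%d length=%d offset=%d rep=%d done\n",
                  i, nrow(cells), cl$n, cl$length, cl$offset, cl$replicate))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
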