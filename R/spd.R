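# Calibration of individual dates, window filtering, binning/thinning, and
# summed probability distributions (SPDs) on an annual calBP grid.

#' Calibrate radiocarbon dates
#'
#' For each date the calibrated density at calendar year `t` is
#' proportional to `Normal(cra; c14(t), sqrt(sd^2 + sigma(t)^2))`,
#' normalized to sum to 1 over the full curve support (before any
#' windowing).
#'
#' @param cra Conventional radiocarbon ages, years BP.
#' @param sd 1-sigma measurement errors, years (> 0); recycled.
#' @param curve A `calCurve`.
#' @param tail_sd Densities are evaluated only within `tail_sd` composed
#'   standard deviations of the measured age (the remainder is numerically
#'   zero).
#' @return A matrix with one column per date and one row per curve grid
#'   year; attribute `calbp` carries the grid (ascending calBP).  Column
#'   sums are 1.
#' @examples
#' crv <- syntheticCalCurve(4000, 7000)
#' d <- calibrateDates(5000, 40, crv)
#' sum(d)
#' @export
calibrateDates <- function(cra, sd, curve, tail_sd = 10) {
  stopifnot(inherits(curve, "calCurve"))
  n <- length(cra)
  sd <- rep_len(sd, n)
  if (any(sd <= 0)) stop("measurement errors must be positive")
  mu <- curve$c14
  sig <- curve$sigma
  out <- matrix(0, nrow = nrow(curve), ncol = n)
  for (j in seq_len(n)) {
    s <- sqrt(sd[j]^2 + sig^2)
    band <- which(abs(mu - cra[j]) <= tail_sd * s)
    if (length(band) == 0)
      stop(sprintf("date %g +/- %g BP lies outside the calibration curve span",
                   cra[j], sd[j]))
    dens <- stats::dnorm(cra[j], mu[band], s[band])
    out[band, j] <- dens / sum(dens)
  }
  attr(out, "calbp") <- curve$calbp
  out
}

# Weighted median calendar year (calBP) of each calibrated density.
#' Median calibrated date
#'
#' @param dens Density matrix from [calibrateDates].
#' @return Numeric vector of median calibrated years (calBP), one per date.
#' @export
calMedian <- function(dens) {
  calbp <- attr(dens, "calbp")
  apply(dens, 2, function(d) {
    cs <- cumsum(d) / sum(d)
    calbp[which(cs >= 0.5)[1]]
  })
}

# Indices of the window [start, end] calBP (inclusive) on a curve grid.
windowIndices <- function(calbp, window) {
  lo <- min(window); hi <- max(window)
  which(calbp >= lo & calbp <= hi)
}

#' Window mass filter
#'
#' Retains a date if and only if strictly more than half of its calibrated
#' probability mass falls inside the chronological window (boundary rule:
#' exactly 50\% is dropped).
#'
#' @param dens Density matrix from [calibrateDates] (columns sum to 1).
#' @param window Length-2 numeric, window limits in calBP (any order).
#' @return Logical vector: `TRUE` for retained dates.
#' @export
windowFilter <- function(dens, window) {
  idx <- windowIndices(attr(dens, "calbp"), window)
  mass <- colSums(dens[idx, , drop = FALSE])
  mass > 0.5
}

#' Random thinning in calendar bins
#'
#' Partitions dates into consecutive calendar bins by their median
#' calibrated year and keeps exactly one date, chosen uniformly at random,
#' per occupied bin.  Deterministic for a fixed RNG state.
#'
#' @param med_calbp Median calibrated years (calBP), e.g. from
#'   [calMedian].
#' @param bin_width Bin width in years (default 20).
#' @return Integer indices of the retained dates, in ascending index
#'   order.
#' @export
binThin <- function(med_calbp, bin_width = 20) {
  bins <- floor(med_calbp / bin_width)
  keep <- vapply(split(seq_along(med_calbp), bins), function(idx) {
    idx[sample.int(length(idx), 1L)]
  }, integer(1))
  sort(unname(keep))
}

#' Summed probability distribution
#'
#' Sums windowed calibrated densities on the annual grid.  With
#' `normalize = "none"` the SPD retains the per-date masses (a date fully
#' inside the window contributes total mass 1); `"sum1"` rescales the SPD
#' to unit mass over the window.
#'
#' @param dens Density matrix from [calibrateDates].
#' @param window Length-2 numeric, calBP.
#' @param normalize `"none"` or `"sum1"`.
#' @param calbp Grid of the density rows; defaults to the matrix's
#'   `calbp` attribute (supply explicitly after subsetting columns).
#' @return An `spd`: data.frame with `calbp` (descending: old to young)
#'   and `density`; attributes `n_dates` and `normalize`.
#' @export
buildSPD <- function(dens, window, normalize = c("none", "sum1"),
                     calbp = attr(dens, "calbp")) {
  normalize <- match.arg(normalize)
  if (ncol(dens) == 0) stop("cannot build an SPD from an empty date list")
  if (is.null(calbp)) stop("density matrix carries no calbp grid")
  idx <- windowIndices(calbp, window)
  d <- rowSums(dens[idx, , drop = FALSE])
  grid <- calbp[idx]
  o <- order(grid, decreasing = TRUE)
  d <- d[o]; grid <- grid[o]
  if (normalize == "sum1") {
    if (sum(d) == 0) stop("SPD has zero mass inside the window")
    d <- d / sum(d)
  }
  out <- data.frame(calbp = grid, density = d)
  attr(out, "n_dates") <- ncol(dens)
  attr(out, "normalize") <- normalize
  class(out) <- c("spd", "data.frame")
  out
}

#' @export
print.spd <- function(x, ...) {
  cat(sprintf("SPD over %d-%d calBP from %d dates (normalize = %s)\n",
              max(x$calbp), min(x$calbp), attr(x, "n_dates"),
              attr(x, "normalize")))
  invisible(x)
}

#' @export
plot.spd <- function(x, ...) {
  graphics::plot(x$calbp, x$density, type = "l", xlim = rev(range(x$calbp)),
                 xlab = "cal BP", ylab = "summed probability", ...)
  invisible(x)
}

#' Export a pair of population SPDs as CSV
#'
#' @param spd_hg,spd_f `spd` objects on the same grid.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeSPDPair <- function(spd_hg, spd_f, path) {
  if (!identical(spd_hg$calbp, spd_f$calbp))
    stop("the two SPDs are on different grids")
  utils::write.csv(data.frame(calbp = spd_hg$calbp,
                              density_hg = spd_hg$density,
                              density_farmer = spd_f$density),
                   path, row.names = FALSE)
  invisible(path)
}

#' Draw radiocarbon dates from a model trajectory
#'
#' Emulates the generation of an archaeological radiocarbon sample from a
#' simulated demographic history: (i) `n` calendar years are drawn from
#' the discretized total density `HG(t) + F(t)`; (ii) each date is
#' labelled `"farmer"` with probability `F(t) / (HG(t) + F(t))` at its
#' year, otherwise `"hg"`; (iii) each calendar year is "uncalibrated" --
#' the conventional age is drawn from
#' `Normal(c14(t), sqrt(sd^2 + sigma(t)^2))` with a measurement error from
#' `sd_model` -- so that recalibrating the sample reproduces the
#' information loss of the calibration process.
#'
#' @param traj An `lvTrajectory` covering the window.
#' @param n Number of dates to draw.
#' @param curve A `calCurve`.
#' @param start_calbp Calendar year (calBP) of trajectory time `t = 0`;
#'   model year `t` maps to `start_calbp - t`.
#' @param sd_model Measurement-error model: a single value, a numeric pool
#'   resampled with replacement, or a `function(n)` returning `n` errors.
#' @param lab_prefix Prefix for generated lab identifiers.
#' @return A `data.frame` with columns `lab_id`, `cra`, `sd`, `label`.
#' @export
sampleDatesFromModel <- function(traj, n, curve, start_calbp, sd_model = 40,
                                 lab_prefix = "SIM") {
  stopifnot(n >= 1)
  w <- traj$HG + traj$F
  if (sum(w) <= 0) stop("trajectory has zero total density; cannot sample dates")
  ti <- sample.int(length(w), n, replace = TRUE, prob = w)
  p_f <- traj$F[ti] / w[ti]
  label <- ifelse(stats::runif(n) < p_f, "farmer", "hg")
  sd <- if (is.function(sd_model)) sd_model(n)
  else if (length(sd_model) > 1) sample(sd_model, n, replace = TRUE)
  else rep(sd_model, n)
  calbp <- start_calbp - traj$t[ti]
  cv <- curveAt(curve, calbp)
  cra <- stats::rnorm(n, cv$c14, sqrt(sd^2 + cv$sigma^2))
  data.frame(lab_id = sprintf("%s-%05d", lab_prefix, seq_len(n)),
             cra = cra, sd = sd, label = label, stringsAsFactors = FALSE)
}
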