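# Calibration-curve handling.  A curve maps calendar years BP to expected
# conventional radiocarbon ages (CRA) with a 1-sigma curve error; internally
# curves are stored interpolated to an annual calBP grid.

#' Construct a calibration curve from anchor points
#'
#' Linearly interpolates the supplied anchors to an annual calBP grid.
#' Mostly useful for building small synthetic curves in examples and
#' tests; files are read with [readCalCurve].
#'
#' @param calbp Calendar years BP (strictly monotone).
#' @param c14 Conventional radiocarbon ages at the anchors.
#' @param sigma 1-sigma curve errors at the anchors (> 0).
#' @param name Curve label.
#' @return A `calCurve`.
#' @export
newCalCurve <- function(calbp, c14, sigma, name = "curve") {
  grid <- seq(min(calbp), max(calbp))
  out <- data.frame(calbp = grid,
                    c14 = stats::approx(calbp, c14, xout = grid)$y,
                    sigma = stats::approx(calbp, sigma, xout = grid)$y)
  attr(out, "name") <- name
  class(out) <- c("calCurve", "data.frame")
  out
}

#' Read a radiocarbon calibration curve
#'
#' Parses the standard `.14c` format: comment lines starting with `#`,
#' then comma- or whitespace-separated columns whose first three are
#' calendar age BP, conventional radiocarbon age BP, and the 1-sigma curve
#' error (IntCal-style files carry two further columns, which are
#' ignored).  The curve is linearly interpolated to an annual calBP grid.
#'
#' @param path Path to the `.14c` file.
#' @param name Curve label stored on the object.
#' @return A `calCurve`: data.frame with columns `calbp`, `c14`, `sigma`
#'   on a 1-year calBP grid.
#' @export
readCalCurve <- function(path, name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2) stop("calibration curve file is empty or too short")
  sep <- if (grepl(",", lines[1])) "," else ""
  tab <- utils::read.table(text = lines, sep = sep, header = FALSE,
                           strip.white = TRUE)
  if (ncol(tab) < 3)
    stop("calibration curve must have at least 3 columns (calBP, 14C age, error)")
  calbp <- as.numeric(tab[[1]])
  if (any(is.na(calbp)) || any(duplicated(calbp)) ||
      !(all(diff(calbp) > 0) || all(diff(calbp) < 0)))
    stop("calBP column must be strictly monotone")
  sigma <- as.numeric(tab[[3]])
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("curve errors must be positive")
  newCalCurve(calbp, as.numeric(tab[[2]]), sigma, name)
}

#' @export
print.calCurve <- function(x, ...) {
  cat(sprintf("Calibration curve '%s': %d-%d calBP (annual grid, %d points)\n",
              attr(x, "name"), max(x$calbp), min(x$calbp), nrow(x)))
  invisible(x)
}

#' Synthetic calibration curve
#'
#' Builds a smooth synthetic curve for simulation and testing:
#' `c14(calbp) = calbp + wiggle_amp * sin(2 pi calbp / wiggle_period)` with
#' constant curve error.  With the default amplitude/period the curve is
#' strictly monotone, so calibrated densities remain unimodal.  It is a
#' stand-in with the same format and units as a real atmospheric curve,
#' not a measured record.
#'
#' @param calbp_min,calbp_max Calendar span in years BP.
#' @param wiggle_amp Amplitude of the sinusoidal wiggle, 14C years.
#' @param wiggle_period Period of the wiggle, calendar years.
#' @param sigma Constant 1-sigma curve error, years.
#' @return A `calCurve`.
#' @examples
#' crv <- syntheticCalCurve(3000, 9000)
#' @export
syntheticCalCurve <- function(calbp_min = 1000, calbp_max = 10000,
                              wiggle_amp = 20, wiggle_period = 500,
                              sigma = 15) {
  calbp <- seq(calbp_min, calbp_max)
  c14 <- calbp + wiggle_amp * sin(2 * pi * calbp / wiggle_period)
  newCalCurve(calbp, c14, rep(sigma, length(calbp)),
              name = "synthetic")
}

# Curve lookup at (integer) calendar years BP.
curveAt <- function(curve, calbp) {
  idx <- calbp - curve$calbp[1] + 1L
  if (any(idx < 1L | idx > nrow(curve)))
    stop("calendar year outside the calibration curve span")
  list(c14 = curve$c14[idx], sigma = curve$sigma[idx])
}
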