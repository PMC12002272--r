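test_that("curve files parse, interpolate linearly, and reject bad input", {
  path <- tempfile(fileext = ".14c")
  writeLines(c("# synthetic toy curve",
               "# calBP, 14C age, error",
               "5000,4950,20", "5010,4970,24", "5020,4980,20"), path)
  crv <- readCalCurve(path)
  expect_s3_class(crv, "calCurve")
  expect_equal(nrow(crv), 21)           # annual grid between anchors
  expect_equal(crv$c14[crv$calbp == 5000], 4950)
  # midpoint of a 10-year segment is the mean of the flanking anchors
  expect_equal(crv$c14[crv$calbp == 5005], (4950 + 4970) / 2)
  expect_equal(crv$sigma[crv$calbp == 5005], 22)
  # whitespace-separated variant parses identically
  path2 <- tempfile(fileext = ".14c")
  writeLines(c("# comment", "5000 4950 20", "5010 4970 24", "5020 4980 20"),
             path2)
  expect_equal(readCalCurve(path2)$c14, crv$c14)
  # malformed files
  bad <- tempfile()
  writeLines(c("5000,4950", "5010,4970"), bad)
  expect_error(readCalCurve(bad), "3 columns")
  writeLines(c("5000,4950,20", "5000,4970,24"), bad)
  expect_error(readCalCurve(bad), "monotone")
  writeLines("# only comments", bad)
  expect_error(readCalCurve(bad), "empty|short")
})

test_that("the shipped synthetic example curve loads", {
  path <- system.file("extdata", "synthetic_curve.14c", package = "lvcarbon")
  expect_true(nzchar(path))
  crv <- readCalCurve(path)
  expect_true(all(diff(crv$calbp) == 1))
  expect_true(all(crv$sigma > 0))
})

test_that("calibrated densities are normal on an identity curve and sum to 1", {
  # identity curve with negligible curve error
  crv <- newCalCurve(4000:6000, 4000:6000, rep(1e-3, 2001))
  d <- calibrateDates(5000, 50, crv)
  expect_equal(sum(d), 1, tolerance = 1e-9)
  grid <- attr(d, "calbp")
  expect_equal(grid[which.max(d)], 5000)
  ref <- dnorm(grid, 5000, 50)
  expect_equal(as.numeric(d), ref / sum(ref), tolerance = 1e-6)
})

test_that("calibration matches a brute-force evaluation on a wiggly curve", {
  crv <- testCurve()
  d <- calibrateDates(c(5000, 7400), c(40, 90), crv)
  expect_equal(colSums(d), c(1, 1), tolerance = 1e-9)
  # independent direct formula: per-year normal density, then normalize
  for (j in 1:2) {
    cra <- c(5000, 7400)[j]; sd <- c(40, 90)[j]
    ref <- dnorm(cra, crv$c14, sqrt(sd^2 + crv$sigma^2))
    ref <- ref / sum(ref)
    expect_equal(as.numeric(d[, j]), ref, tolerance = 1e-6)
  }
  expect_error(calibrateDates(99999, 30, crv), "outside")
  expect_error(calibrateDates(5000, -1, crv), "positive")
})

test_that("window filtering keeps dates with strictly more than half their mass", {
  # densities with exactly known masses inside the window [4500, 5000]:
  # each column splits its unit mass between one in-window year (4800)
  # and one outside year (5200)
  grid <- 4000:6000
  inside <- c(0.9, 0.6, 0.5, 0.4, 0.1)
  dens <- vapply(inside, function(m) {
    d <- numeric(length(grid))
    d[grid == 4800] <- m
    d[grid == 5200] <- 1 - m
    d
  }, numeric(length(grid)))
  attr(dens, "calbp") <- grid
  keep <- windowFilter(dens, c(5000, 4500))
  # strict '>' boundary rule: the exactly-half date is dropped
  expect_identical(keep, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(sum(keep), 2L)
})

test_that("bin thinning keeps one date per occupied bin, reproducibly", {
  med <- c(5001, 5005, 5012, 5039, 5041, 5080)
  set.seed(1); k1 <- binThin(med, 20)
  set.seed(1); k2 <- binThin(med, 20)
  expect_identical(k1, k2)
  bins <- floor(med[k1] / 20)
  expect_false(any(duplicated(bins)))
  expect_equal(length(k1), 4L)  # occupied bins: 250 (x3), 251, 252, 254
  # all dates in distinct bins: output equals input
  med2 <- c(5001, 5025, 5049, 5061)
  expect_identical(binThin(med2, 20), seq_along(med2))
  # many dates collapsing into one bin: exactly one survives
  expect_length(binThin(rep(5003, 7), 20), 1L)
})

test_that("SPDs add single-date densities and honour normalization modes", {
  crv <- testCurve()
  window <- c(6000, 5000)
  d1 <- calibrateDates(5500, 40, crv)
  spd1 <- buildSPD(d1, window)
  idx <- which(crv$calbp >= 5000 & crv$calbp <= 6000)
  expect_equal(sum(spd1$density), sum(d1[idx, 1]))
  expect_true(all(diff(spd1$calbp) == -1))  # old-to-young grid
  # two identical dates: SPD is exactly twice the single-date density
  d2 <- calibrateDates(c(5500, 5500), c(40, 40), crv)
  spd2 <- buildSPD(d2, window)
  expect_equal(spd2$density, 2 * spd1$density)
  # additivity for heterogeneous dates
  d3 <- calibrateDates(c(5200, 5500, 5800), c(30, 40, 50), crv)
  spd3 <- buildSPD(d3, window)
  expect_equal(sum(spd3$density), sum(colSums(d3[idx, ])))
  norm <- buildSPD(d3, window, normalize = "sum1")
  expect_equal(sum(norm$density), 1)
  expect_error(buildSPD(d3[, 0, drop = FALSE], window), "empty")
})

test_that("dates sampled from a trajectory follow its density and labels", {
  crv <- testCurve()
  p <- lvParams(0.015, 0.03, 0.01, 0.01, eta = 0.1)
  traj <- lvSimulate(p, lvInit(K_hg = 1, K_f = 1.5, rho = 0.2), 500)
  # farmers absent: all labels hg
  traj0 <- lvSimulate(lvParams(0.015, 0.03, 0, 0), lvInit(K_hg = 1, K_f = 1.5),
                      300)
  set.seed(1)
  d0 <- sampleDatesFromModel(traj0, 50, crv, 8000)
  expect_true(all(d0$label == "hg"))
  # equal densities: farmer fraction near one half
  trajE <- traj0
  trajE$F <- trajE$HG
  set.seed(2)
  dE <- sampleDatesFromModel(trajE, 10000, crv, 8000)
  phat <- mean(dE$label == "farmer")
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / 10000))
  # point-mass trajectory on an identity curve: cra ~ Normal(c14(t), composed sd)
  idcrv <- newCalCurve(4000:6000, 4000:6000, rep(10, 2001))
  trajP <- traj0[1:2, ]
  trajP$HG <- c(1, 0); trajP$F <- c(0, 0)
  attr(trajP, "init") <- attr(traj0, "init")
  set.seed(3)
  dP <- sampleDatesFromModel(trajP, 10000, idcrv, 5500, sd_model = 30)
  ks <- ks.test(dP$cra, "pnorm", 5500, sqrt(30^2 + 10^2))
  expect_gt(ks$p.value, 0.01)
  expect_error(sampleDatesFromModel(trajP[2, ], 10, idcrv, 5500), "zero total")
})

test_that("uncalibrating then recalibrating recovers the calendar year", {
  crv <- testCurve()
  set.seed(42)
  years <- sample(5000:8000, 1000, replace = TRUE)
  sd <- 40
  cv <- lvcarbon:::curveAt(crv, years)
  cra <- rnorm(1000, cv$c14, sqrt(sd^2 + cv$sigma^2))
  dens <- calibrateDates(cra, sd, crv)
  post_mean <- colSums(dens * crv$calbp)
  # posterior-mean calendar year within 2 sd of the true year, on average
  expect_lt(mean(abs(post_mean - years)), 2 * sd)
})

test_that("sd filtering and window filtering commute", {
  crv <- testCurve()
  set.seed(9)
  n <- 40
  dates <- data.frame(lab_id = sprintf("D%02d", 1:n),
                      cra = runif(n, 4800, 8200),
                      sd = sample(c(30, 60, 150), n, replace = TRUE),
                      label = "hg", stringsAsFactors = FALSE)
  window <- c(7500, 5500)
  dens <- calibrateDates(dates$cra, dates$sd, crv)
  keepA <- dates$sd <= 120 & windowFilter(dens, window)
  keepB <- windowFilter(dens, window) & dates$sd <= 120
  expect_identical(keepA, keepB)
})

test_that("SPDs of large samples converge to the generating density", {
  # round trip: trajectory -> dates (small errors) -> SPD ~ trajectory shape
  crv <- newCalCurve(4000:9000, 4000:9000, rep(1, 5001))
  p <- lvParams(0.015, 0.03, 0.01, 0.01, eta = 0.1)
  traj <- lvSimulate(p, lvInit(K_hg = 1, K_f = 1.5, rho = 0.2), 600)
  set.seed(11)
  d <- sampleDatesFromModel(traj, 20000, crv, 8000, sd_model = 2)
  dens <- calibrateDates(d$cra, d$sd, crv)
  spd <- buildSPD(dens, c(8000, 7400), normalize = "sum1")
  target <- (traj$HG + traj$F) / sum(traj$HG + traj$F)
  expect_lt(sum(abs(spd$density - target)), 0.1)  # L1 on the annual grid
})

test_that("SPD pairs export to CSV", {
  crv <- testCurve()
  d <- calibrateDates(c(5500, 5600), c(40, 40), crv)
  s1 <- buildSPD(d[, 1, drop = FALSE], c(6000, 5000), calbp = crv$calbp)
  s2 <- buildSPD(d[, 2, drop = FALSE], c(6000, 5000), calbp = crv$calbp)
  path <- tempfile(fileext = ".csv")
  writeSPDPair(s1, s2, path)
  back <- read.csv(path)
  expect_equal(names(back), c("calbp", "density_hg", "density_farmer"))
  expect_equal(back$density_hg, s1$density)
})
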