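test_that("prior ranges default to the documented supports and validate overrides", {
  pr <- abcPriors()
  expect_equal(pr$gamma_hg, c(0.001, 0.022))
  expect_equal(pr$gamma_f, c(0.015, 0.035))
  expect_equal(pr$delta_hg, c(0, 0.04))
  expect_equal(pr$delta_f, c(0, 0.04))
  expect_equal(pr$eta, c(0, 0.3))
  expect_equal(pr$mu, c(0, 0.035))
  over <- abcPriors(rho = c(0.05, 0.5))
  expect_equal(over$rho, c(0.05, 0.5))
  expect_error(abcPriors(nonsense = c(0, 1)), "unknown prior")
})

test_that("case assembly applies the window, capacity and filter rules", {
  crv <- testCurve()
  set.seed(21)
  truth <- lvParams(0.012, 0.03, 0.012, 0.01, eta = 0.1, mu = 0.005)
  gen <- generateDataset(truth, 0.25, n = 150, curve = crv,
                         interaction_length = 700, start_calbp = 7600)
  case <- buildCase(gen$dates, crv, window = c(7600, 6900))
  expect_s3_class(case, "abcCase")
  expect_equal(unname(case$window["start"] - case$window["end"]), 700)
  expect_equal(length(case$grid), 701)
  expect_equal(case$n_dates, case$n_hg + case$n_f)
  # joint normalization: the two SPDs together carry unit mass
  expect_equal(sum(case$spd$hg) + sum(case$spd$f), 1, tolerance = 1e-12)
  # capacity ratio from the SPD peak heights
  expect_equal(case$kf_ratio, max(case$spd$f) / max(case$spd$hg))
  # the window start precedes the earliest farming date by >= the lead
  dens <- calibrateDates(gen$dates$cra, gen$dates$sd, crv)
  med <- calMedian(dens)
  auto <- buildCase(gen$dates, crv)
  expect_gte(unname(auto$window["start"]),
             max(med[gen$dates$label == "farmer"]) + 100)
  # all-farmer errors too large: filtered out -> case error
  bad <- gen$dates
  bad$sd[bad$label == "farmer"] <- 150
  expect_error(buildCase(bad, crv), "farming dates")
  expect_error(buildCase(gen$dates[0, ], crv), "farming dates")
})

test_that("the SPD distance is the summed per-population Euclidean norm", {
  obs <- list(hg = c(0.1, 0.2, 0.3), f = c(0.05, 0.1, 0.25))
  expect_equal(spdDistance(obs, obs), 0)
  # single-coordinate difference in the farmer SPD
  sim <- obs
  sim$f[2] <- sim$f[2] + 0.07
  expect_equal(spdDistance(sim, obs), 0.07)
  # random vectors against the direct formula
  set.seed(1)
  a <- list(hg = runif(50), f = runif(50))
  b <- list(hg = runif(50), f = runif(50))
  expect_equal(spdDistance(a, b),
               sqrt(sum((a$hg - b$hg)^2)) + sqrt(sum((a$f - b$f)^2)))
  expect_error(spdDistance(list(hg = 1:3, f = 1:3), list(hg = 1:2, f = 1:3)),
               "different grids")
})

test_that("candidate simulation matches the composed reference pipeline", {
  sc <- makeSyntheticCase(31, n = 120)
  case <- sc$case
  th <- data.frame(gamma_hg = 0.01, gamma_f = 0.02, mu = 0.01,
                   delta_hg = 0.01, delta_f = 0.01, eta = 0.1,
                   rho = 0.2, HG0 = 1)
  set.seed(7)
  fast <- simulateCandidate(th, case, step = 0.5, tail_sd = 5)
  # reference route: public dynamics + date-sampling + calibration steps
  set.seed(7)
  p <- lvParams(th$gamma_hg, th$gamma_f, th$delta_hg, th$delta_f,
                eta = th$eta, mu = th$mu)
  init <- lvInit(K_hg = th$HG0, K_f = case$kf_ratio * th$HG0, rho = th$rho)
  horizon <- unname(case$window["start"] - case$window["end"])
  traj <- lvSimulate(p, init, horizon, step = 0.5)
  d <- sampleDatesFromModel(traj, case$n_dates, sc$curve,
                            case$window[["start"]], sd_model = case$sd_pool)
  dens <- calibrateDates(d$cra, d$sd, sc$curve, tail_sd = 5)
  idx <- which(sc$curve$calbp >= case$window["end"] &
                 sc$curve$calbp <= case$window["start"])
  hg <- rev(rowSums(dens[idx, d$label == "hg", drop = FALSE]))
  f <- rev(rowSums(dens[idx, d$label == "farmer", drop = FALSE]))
  tot <- sum(hg) + sum(f)
  expect_equal(fast$hg, hg / tot, tolerance = 1e-12)
  expect_equal(fast$f, f / tot, tolerance = 1e-12)
  # determinism under a fixed seed
  set.seed(99); s1 <- simulateCandidate(th, case)
  set.seed(99); s2 <- simulateCandidate(th, case)
  expect_identical(s1, s2)
  # farmers never present: farmer SPD identically zero
  th0 <- th; th0$rho <- 0; th0$eta <- 0
  set.seed(1)
  s0 <- simulateCandidate(th0, case)
  expect_true(all(s0$f == 0))
  expect_gt(sum(s0$hg), 0)
})

test_that("the compiled batch engine agrees with the reference simulator", {
  sc <- makeSyntheticCase(32, n = 100)
  case <- sc$case
  th <- data.frame(gamma_hg = 0.01, gamma_f = 0.02, mu = 0.01,
                   delta_hg = 0.01, delta_f = 0.01, eta = 0.1,
                   rho = 0.2, HG0 = 1)
  cs <- caseForEngine(case, step = 1)
  m <- as.matrix(th[rep(1, 300), abcParNames])
  set.seed(5)
  e_engine <- .abc_batch_cpp(m, cs)
  set.seed(6)
  e_ref <- replicate(300, spdDistance(simulateCandidate(th, case), case$spd))
  # same distance distribution from the two routes (fixed seeds)
  expect_lt(abs(mean(e_engine) - mean(e_ref)) / mean(e_ref), 0.05)
  expect_gt(ks.test(e_engine, e_ref)$p.value, 0.01)
})

test_that("rejection keeps the lowest-distance particles inside the priors", {
  sc <- makeSyntheticCase(33, n = 100)
  pr <- abcPriors()
  set.seed(1)
  part <- rejectionABC(sc$case, pr, n_sims = 400, keep = 50)
  expect_equal(nrow(part), 50)
  expect_true(all(part$stage == 0))
  expect_true(all(diff(order(part$epsilon)) == 1))  # sorted ascending
  for (nm in names(pr))
    expect_true(all(part[[nm]] >= pr[[nm]][1] & part[[nm]] <= pr[[nm]][2]))
  # n_sims = keep retains everything; keep = 1 retains the global minimum
  set.seed(2)
  all_kept <- rejectionABC(sc$case, pr, n_sims = 30, keep = 30)
  expect_equal(nrow(all_kept), 30)
  set.seed(3)
  best <- rejectionABC(sc$case, pr, n_sims = 200, keep = 1)
  expect_equal(nrow(best), 1)
  # retained distances beat the typical prior draw (known-theta case)
  set.seed(4)
  prior_eps <- rejectionABC(sc$case, pr, n_sims = 200, keep = 200)$epsilon
  expect_lt(stats::wilcox.test(part$epsilon, prior_eps,
                               alternative = "less")$p.value, 0.01)
})

test_that("the perturbation kernel respects the prior support", {
  pr <- abcPriors()
  x <- list(gamma_hg = 0.001, gamma_f = 0.035, mu = 0, delta_hg = 0,
            delta_f = 0.04, eta = 0, rho = 0.4, HG0 = 0.8)
  set.seed(8)
  for (i in 1:200) {
    y <- perturbParticle(x, pr)
    for (nm in names(pr))
      expect_true(y[[nm]] >= pr[[nm]][1] && y[[nm]] <= pr[[nm]][2])
  }
  # zero-valued parameters do not freeze: the jitter floor moves them
  set.seed(9)
  moved <- replicate(50, perturbParticle(x, pr)$eta)
  expect_gt(max(moved), 0)
})

test_that("SMC tolerances shrink monotonically and particles stay in support", {
  sc <- makeSyntheticCase(34, n = 100)
  pr <- abcPriors()
  set.seed(10)
  cand <- rejectionABC(sc$case, pr, n_sims = 500, keep = 60)
  smc <- smcABC(sc$case, cand, pr, stages = 2)
  expect_length(smc$schedule, 2)
  expect_true(all(diff(smc$schedule) <= 0))
  expect_equal(smc$schedule[1],
               unname(quantile(cand$epsilon, 0.25, names = FALSE)))
  expect_true(all(smc$particles$epsilon < smc$schedule[2]))
  for (nm in names(pr))
    expect_true(all(smc$particles[[nm]] >= pr[[nm]][1] &
                      smc$particles[[nm]] <= pr[[nm]][2]))
  expect_equal(nrow(smc$particles), 60)
})

test_that("multi-start pooling keeps the overall best particles", {
  sc <- makeSyntheticCase(35, n = 80)
  pr <- abcPriors()
  fit1 <- fitABC(sc$case, pr, n_sims = 300, keep = 40, stages = 1,
                 starts = 1, seed = 5)
  expect_equal(nrow(fit1$particles), 40)
  fit2 <- fitABC(sc$case, pr, n_sims = 300, keep = 40, stages = 1,
                 starts = 2, seed = 5)
  # pooled best-40 cannot be worse than either single run's worst particle
  expect_lte(max(fit2$particles$epsilon), max(fit1$particles$epsilon))
  # reproducibility under the master seed
  fit1b <- fitABC(sc$case, pr, n_sims = 300, keep = 40, stages = 1,
                  starts = 1, seed = 5)
  expect_identical(fit1$particles, fit1b$particles)
})

test_that("the shortest-interval HPDI matches the normal closed form", {
  set.seed(123)
  x <- rnorm(1e5)
  h <- hpdi(x, 0.95)
  expect_equal(unname(h["lower"]), -1.96, tolerance = 0.02)
  expect_equal(unname(h["upper"]), 1.96, tolerance = 0.02)
  # a skewed sample: HPDI is shorter than the central interval
  y <- rexp(1e5)
  hy <- hpdi(y, 0.9)
  ci <- quantile(y, c(0.05, 0.95))
  expect_lt(hy["upper"] - hy["lower"], ci[2] - ci[1])
  expect_equal(unname(hy["lower"]), 0, tolerance = 0.01)
})

test_that("posterior summaries cover parameters, events and extinction", {
  sc <- makeSyntheticCase(36, n = 100)
  pr <- abcPriors()
  fit <- fitABC(sc$case, pr, n_sims = 300, keep = 50, stages = 1,
                starts = 1, seed = 77)
  sm <- summarizePosterior(fit, n_pred = 25)
  expect_s3_class(sm, "abcSummary")
  expect_true(all(c("gamma_hg", "gamma_f_total", "eta", "rho") %in%
                    sm$params$parameter))
  expect_true(all(sm$params$hpdi_lower <= sm$params$median &
                    sm$params$median <= sm$params$hpdi_upper))
  expect_gte(sm$extinction_fraction, 0)
  expect_lte(sm$extinction_fraction, 1)
  expect_equal(nrow(sm$bands), length(sc$case$grid))
  expect_true(all(sm$bands$hg_lower <= sm$bands$hg_upper))
  # identical particles: zero-width intervals at the common value
  one <- fit$particles[rep(1, 10), ]
  sm1 <- summarizePosterior(one, sc$case, n_pred = 0)
  g <- sm1$params[sm1$params$parameter == "gamma_hg", ]
  expect_equal(g$hpdi_lower, g$hpdi_upper)
  expect_equal(g$median, fit$particles$gamma_hg[1])
})
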