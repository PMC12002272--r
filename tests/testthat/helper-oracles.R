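# Independent oracles and shared fixtures for the test suite.

# Plain-R classical RK4 integrator for the competition system, written
# independently of the compiled solver (same clipping rule so that
# extinction is a shared absorbing state).
rk4Oracle <- function(params, init, horizon, step, clip_tol = 1e-12) {
  f <- function(HG, F) {
    I <- params$delta_hg * HG * F
    c(params$gamma_hg * HG * (1 - HG / init$K_hg) - I,
      params$gamma_f_total * F * (1 - F / init$K_f) + params$eta * I -
        params$delta_f * HG * F)
  }
  nsub <- round(1 / step)
  h <- 1 / nsub
  out <- matrix(NA_real_, horizon + 1, 2)
  y <- c(init$HG0, init$F0)
  y[y < clip_tol] <- 0
  out[1, ] <- y
  for (yr in seq_len(horizon)) {
    for (s in seq_len(nsub)) {
      k1 <- f(y[1], y[2])
      k2 <- f(y[1] + h / 2 * k1[1], y[2] + h / 2 * k1[2])
      k3 <- f(y[1] + h / 2 * k2[1], y[2] + h / 2 * k2[2])
      k4 <- f(y[1] + h * k3[1], y[2] + h * k3[2])
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      y[y < clip_tol] <- 0
    }
    out[yr + 1, ] <- y
  }
  out
}

# Closed-form logistic growth from x0 toward K at rate r.
logisticClosedForm <- function(t, x0, K, r) {
  K / (1 + (K / x0 - 1) * exp(-r * t))
}

# Relative error with a floor on the denominator: populations below the
# floor are compared absolutely at the floor scale.
relErr <- function(a, b, floor = 1e-6) {
  max(abs(a - b) / pmax(abs(b), floor))
}

# Ten parameter sets spanning the prior ranges (fixed, not random).
priorSpanningParams <- function() {
  list(
    lvParams(0.001, 0.015, 0.000, 0.000, eta = 0.0, mu = 0.000),
    lvParams(0.022, 0.035, 0.040, 0.040, eta = 0.3, mu = 0.035),
    lvParams(0.0115, 0.025, 0.020, 0.020, eta = 0.15, mu = 0.0175),
    lvParams(0.015, 0.020, 0.010, 0.010, eta = 0.0, mu = 0.000),
    lvParams(0.002, 0.035, 0.005, 0.035, eta = 0.25, mu = 0.030),
    lvParams(0.020, 0.016, 0.035, 0.005, eta = 0.05, mu = 0.002),
    lvParams(0.010, 0.030, 0.000, 0.025, eta = 0.30, mu = 0.010),
    lvParams(0.018, 0.022, 0.025, 0.000, eta = 0.10, mu = 0.020),
    lvParams(0.005, 0.018, 0.012, 0.030, eta = 0.20, mu = 0.005),
    lvParams(0.021, 0.033, 0.008, 0.015, eta = 0.02, mu = 0.033))
}

# Small synthetic curve shared across radiocarbon tests.
testCurve <- function() syntheticCalCurve(4000, 9000)

# A synthetic observed case from known parameters (the recovery setup).
makeSyntheticCase <- function(seed, n = 100, truth = NULL, rho = 0.25,
                              length = 800, start = 7800) {
  if (is.null(truth)) {
    pr <- abcPriors()
    mid <- function(nm) mean(pr[[nm]])
    truth <- lvParams(mid("gamma_hg"), mid("gamma_f"), mid("delta_hg"),
                      mid("delta_f"), eta = mid("eta"), mu = mid("mu"))
  }
  set.seed(seed)
  crv <- testCurve()
  gen <- generateDataset(truth, rho, n = n, curve = crv,
                         interaction_length = length, start_calbp = start)
  case <- buildCase(gen$dates, crv, window = c(start, start - length))
  list(case = case, truth = truth, rho = rho, curve = crv, gen = gen)
}
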