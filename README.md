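# lvcarbon

Demographic competition between the last hunter-gatherers and the first
farmers, as a generalized Lotka-Volterra system fitted to radiocarbon
summed probability distributions (SPDs).

When farming spreads into a region by migration, the incumbent foragers
and the incoming farmers compete for the same space and resources.
`lvcarbon` is for archaeologists and quantitative demographers who want
to move from narrating that process to estimating its rates: how fast
each population grew, how strongly each suppressed the other, what share
of foragers was absorbed into farming communities, and how long the
replacement took — using nothing but labelled radiocarbon dates as data.

## The model

Two coupled ODEs describe forager density $HG(t)$ and farmer density
$F(t)$:

$$\frac{dHG}{dt} = \gamma_{hg}\,HG\Big(1-\frac{HG}{K_{hg}}\Big) - \delta_{hg}\,HG\,F$$

$$\frac{dF}{dt} = \gamma'_f\,F\Big(1-\frac{F}{K_f}\Big) + \eta\,\delta_{hg}\,HG\,F - \delta_f\,HG\,F$$

with intrinsic growth rates $\gamma_{hg}$ and $\gamma'_f = \gamma_f + \mu$
(farmer growth folds in a migration stream $\mu$), interspecific
mortalities $\delta_{hg}, \delta_f$ (excess disappearance proportional to
the other group's density), and an assimilation proportion $\eta$
converting the forager interaction loss $I_{hg} = \delta_{hg} HG\, F$
into farmers.  The model has the four classical competition outcomes
(forager-only, farmer-only, stable coexistence, initial-condition
dependent), classified analytically from the invasion eigenvalues at the
boundary equilibria.

Fitting is likelihood-free (ABC-SMC): candidate parameter draws are
turned into synthetic radiocarbon datasets (sample calendar years from
the simulated demography, label each date binomially by the local
population mix, uncalibrate and recalibrate to emulate the information
loss), compared with the observed per-population SPDs by summed
Euclidean distance, and refined through rejection sampling plus a
six-stage sequential Monte Carlo scheme with a shrinking first-quartile
tolerance, a uniform ±20% perturbation kernel and 100 randomized
restarts.

## Worked example

Simulate one interaction scenario, classify its long-run outcome, then
recover known parameters from a fully synthetic 100-date radiocarbon
dataset at a reduced desk-scale budget:

```r
library(lvcarbon)

p <- lvParams(gamma_hg = 0.015, gamma_f = 0.02, mu = 0.005,
              delta_hg = 0.015, delta_f = 0.01, eta = 0.1)
traj <- lvSimulate(p, lvInit(K_hg = 1, K_f = 1.5, rho = 0.1), horizon = 1000)
detectEvents(traj)
#> Demographic events (years since interaction start):
#>   farmers overtake hunter-gatherers: 154 y
#>   farmers reach carrying capacity:   624 y
#>   hunter-gatherers disappear:        718 y
classifyRegime(p, K_hg = 1, K_f = 1.5)
#> Regime: F_only  (invasion eigenvalues: HG -0.0075, F 0.0165)

crv <- syntheticCalCurve(4000, 9000)
set.seed(1)
truth <- lvParams(0.0115, 0.025, 0.02, 0.02, eta = 0.15, mu = 0.0175)
gen <- generateDataset(truth, rho = 0.25, n = 100, curve = crv,
                       interaction_length = 800, start_calbp = 7800)
case <- buildCase(gen$dates, crv, window = c(7800, 7000))
fit <- fitABC(case, n_sims = 1500, keep = 100, stages = 3, starts = 5,
              seed = 42)
summarizePosterior(fit, n_pred = 0)
#> Posterior summary (95% HPDI):
#>      parameter  median   mean hpdi_lower hpdi_upper
#>       gamma_hg 0.00936 0.0104   0.002633     0.0217
#>  gamma_f_total 0.04268 0.0425   0.023014     0.0604
#>       delta_hg 0.01388 0.0149   0.005807     0.0295
#>            eta 0.15263 0.1500   0.002692     0.2662
#>            rho 0.20250 0.2196   0.100781     0.3537
#>            ...
#> Event-time posteriors (years since interaction start):
#>         event   n median   mean hpdi_lower hpdi_upper
#>    t_overtake 100   53.5  56.53         31         89
#>    t_farmer_K 100  255.0 278.97        141        432
#>  t_hg_extinct  96  272.0 302.11        129        567
#>
#> Hunter-gatherer disappearance within the window: 96.0% of particles
```

The generating values ($\gamma_{hg} = 0.0115$, $\gamma'_f = 0.0425$,
$\eta = 0.15$, $\rho = 0.25$) all fall inside their 95% HPDIs — the
posterior medians land close to them — and the event-time posteriors
translate the fitted parameters back into years-to-replacement.

A command-line wrapper is installed as `exec/lvcarbon` with subcommands
`simulate`, `explore`, `fit`, `tactical` and `summarize`; each run
writes a JSON manifest with the seed, configuration echo and input
checksums.

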