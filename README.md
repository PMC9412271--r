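# scrim — integrated spatial capture–recapture models

`scrim` estimates animal population **density** for species that are hard to
identify individually (no usable natural marks), by integrating three data
sources that share one latent spatial process:

1. **Spatial capture–recapture (SCR)** histories — individually identified
   encounters (e.g. live traps + transponder tags) at known locations;
2. **Occupancy (detection/nondetection)** records — per-camera counts of
   occasions with at least one detection of the species, identity unknown,
   usually over a larger area;
3. **Telemetry** — thinned fixes (one per survey day) of a few tagged
   individuals.

It is aimed at quantitative ecologists who want SCR-quality density
estimates from a small, cheap marking effort plus camera traps.

## Model

Activity centers are uniform on a planar state space `S`
(`s_i ~ Uniform(S)`, density `D = N/|S|`); detection decays with distance
through a half-normal rate and the cloglog link:

    lambda_ij = lambda_0 * exp(-d_ij^2 / (2 sigma^2)),    p = 1 - exp(-lambda)

    y_scr[i,j] ~ Binomial(K_j, p_scr_ij)                      (live traps)
    y_occ[j]   ~ Binomial(K_j, 1 - prod_i (1 - p_occ_ij)^z_i) (cameras)
    fix_ir     ~ BVN(s_i, sigma^2 I)                          (telemetry)

with data augmentation (`z_i ~ Bern(psi)`, `N = sum z_i`) for unknown `N`,
a shared `sigma`, detector-class-specific baselines `lambda_0`, and an
optional reversible-jump bait covariate on the live-trap baseline.
Inference is a compiled Metropolis-within-Gibbs sampler; summaries report
posterior mean, half-sample mode, SD, 95% CRI, CV = SD/mean, split-chain
Rhat and ESS. Model variants: `scr`, `scr_tel`, `scr_occ`, `scr_occ_tel`.

## Worked example

```r
library(scrim)

# a full synthetic survey: 60 clustered live traps, 40 cameras, 4 collars,
# calibrated to ~21 captures and ~97 camera detections at D = 0.35 /km^2
bundle <- simulate_scenario(scenario_config(seed = 11))
bundle
#> integrated SCR bundle: 20 individuals, 27 captures, 60 live traps
#>   occupancy: 40 cameras, 110 detections
#>   telemetry: 4 tagged, 20/20/20/20 fixes
#> state space: x [-2.19, 16.73] km, y [-2.29, 10.36] km, area 239.5 km^2

fit <- run_fit(bundle, fit_config(variant = "scr_occ_tel",
                                  n_iter = 2500, n_burn = 500, seed = 2))
posterior_summary(fit)
#>               param     mean     mode       sd    q2.5    q97.5    cv rhat
#> D                 D   0.4651   0.4217  0.10779  0.2839   0.7056 0.232 1.05
#> N                 N 111.3965 101.0000 25.81695 68.0000 169.0000 0.232 1.05
#> sigma         sigma   0.5949   0.5865  0.03036  0.5384   0.6583 0.051 1.03
#> lam0_trap lam0_trap   0.0234   0.0193  0.00685  0.0128   0.0387 0.293 1.02
#> lam0_cam   lam0_cam   0.0416   0.0380  0.01122  0.0244   0.0696 0.270 1.06
#> psi             psi   0.3722   0.3534  0.08973  0.2145   0.5675 0.241 1.05
```

The generative truth here was a realized `D = 0.38` (`N = 91` on
239.5 km²) and `sigma = 0.6` km: the posterior of `sigma` (0.59 ± 0.03)
and the credible interval for `D` recover it, and the CV of `D` (0.23) is
what the occupancy and telemetry blocks buy — the SCR-only fit on the same
data and seed has CV ≈ 0.31.

Goodness of fit and the experiment harnesses:

```r
posterior_predictive_check(fit, bundle, n_draws = 400)   # 3 Bayesian p-values
run_sim_study(scenario_config(), n_datasets = 100)        # bias/RMSE table
run_dilution_study(bundle, levels = c(19, 38, 58, 77))    # CV vs sample size
compare_variants(bundle)                                  # 4-variant report
```

A command-line interface wraps the same pipeline
(`system.file("cli", "scrim.R", package = "scrim")`):

```sh
Rscript scrim.R simulate --config scenario.json --out data/
Rscript scrim.R fit --variant scr-occ-tel --data data/ --out draws.csv
Rscript scrim.R gof --data data/ --draws draws.csv --out gof.csv
Rscript scrim.R experiment sim-study --out results/
```

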