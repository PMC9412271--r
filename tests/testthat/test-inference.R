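# a minimal observed bundle on the toy world: one individual caught once
toy_bundle <- function(K_live = c(1L, 1L), K_cam = c(1L, 1L),
                       y_occ = c(1L, 0L), with_occ = TRUE) {
  w <- toy_world(K_live, K_cam)
  scr <- scr_data(matrix(c(1L, 0L), 1), w$live)
  scrim_data(traps = w$live, scr = scr,
             cameras = if (with_occ) w$cams,
             occ = if (with_occ) occ_data(y_occ, w$cams),
             space = w$space)
}

test_that("run_fit is deterministic under seed and honours n_iter = 0", {
  b <- toy_bundle()
  cfg <- fit_config(variant = "scr_occ", M = 20, n_chains = 2,
                    n_iter = 300, n_burn = 100, seed = 4)
  f1 <- suppressWarnings(run_fit(b, cfg))
  f2 <- suppressWarnings(run_fit(b, cfg))
  expect_identical(f1$chains, f2$chains)
  expect_equal(nrow(f1$chains[[1]]), 200L)
  f0 <- run_fit(b, fit_config(variant = "scr_occ", M = 20, n_iter = 0,
                              n_burn = 0))
  expect_length(f0$chains, 0L)
  expect_error(posterior_summary(f0), "no stored draws")
  # missing blocks are refused
  b_noocc <- toy_bundle(with_occ = FALSE)
  expect_error(run_fit(b_noocc, fit_config(variant = "scr_occ", M = 20)),
               "occupancy")
  expect_error(run_fit(b, fit_config(variant = "scr_tel", M = 20)),
               "telemetry")
})

test_that("psi full conditional is its conjugate Beta", {
  # freeze everything but psi with sum(z) = 56 of M = 200: draws are iid
  # Beta(1 + 56, 1 + 144)
  b <- toy_bundle()
  M <- 200
  zfix <- c(1L, rep(1L, 55), rep(0L, M - 56))
  cfg <- fit_config(variant = "scr", M = M, n_chains = 2, n_iter = 3000,
                    n_burn = 0, update = "psi", init = list(z = zfix),
                    adapt = FALSE, seed = 11)
  fit <- run_fit(b, cfg)
  expect_true(all(pooled_draws(fit, "N") == 56))
  psi <- pooled_draws(fit, "psi")
  a <- 57; bb <- 145
  expect_equal(mean(psi), a / (a + bb), tolerance = 0.01)
  expect_equal(stats::sd(psi), sqrt(a * bb / ((a + bb)^2 * (a + bb + 1))),
               tolerance = 0.05)
  ks <- suppressWarnings(stats::ks.test(psi, stats::pbeta, a, bb))
  expect_gt(ks$p.value, 1e-4)
})

test_that("with vanishing likelihood the sampler returns the prior", {
  # no observed individuals and a frozen, essentially-zero baseline rate:
  # the target collapses to the prior, so sigma ~ U(0, 5) and psi ~ Beta(1,1)
  w <- toy_world()
  scr0 <- scr_data(matrix(integer(), 0, 2), w$live)
  b <- scrim_data(traps = w$live, scr = scr0, space = w$space)
  cfg <- fit_config(variant = "scr", M = 40, n_chains = 3, n_iter = 8000,
                    n_burn = 1000, update = c("z", "s", "sigma", "psi"),
                    init = list(beta0 = log(1e-9)), seed = 21)
  fit <- suppressWarnings(run_fit(b, cfg))
  sig <- pooled_draws(fit, "sigma")[seq(1, 21000, by = 7)]
  expect_equal(mean(sig), 2.5, tolerance = 0.1)
  ec <- stats::ecdf(sig)
  grid <- seq(0.1, 4.9, by = 0.1)
  expect_lt(max(abs(ec(grid) - grid / 5)), 0.05)
  expect_equal(mean(pooled_draws(fit, "psi")), 0.5, tolerance = 0.1)
})

test_that("telemetry-only posterior concentrates at the profile value", {
  set.seed(31)
  sig_true <- 0.6
  fixes <- list(cbind(rnorm(100, 5, sig_true), rnorm(100, 4, sig_true)))
  tel <- telemetry_data(fixes, link = 1L)
  w <- toy_world()
  b <- scrim_data(traps = w$live, scr = scr_data(matrix(c(1L, 0L), 1)),
                  telemetry = tel, space = state_space(c(0, 10), c(0, 10)))
  fit <- run_fit(b, fit_config(variant = "tel", M = 5, n_chains = 2,
                               n_iter = 3000, n_burn = 500, seed = 5))
  prof <- telemetry_sigma_profile(tel)
  sig <- pooled_draws(fit, "sigma")
  expect_equal(mean(sig), prof, tolerance = 0.05)
  # activity center posterior: mean at the centroid, SD ~ sigma/sqrt(R)
  sx <- pooled_draws(fit, "sx1")
  expect_equal(mean(sx), mean(fixes[[1]][, 1]), tolerance = 0.05)
  expect_equal(stats::sd(sx), prof / sqrt(100), tolerance = 0.25)
})

test_that("acceptance rates are tuned into a healthy band", {
  b <- small_bundle(seed = 77)
  fit <- run_fit(b, fit_config(variant = "scr_occ_tel", M = 250,
                               n_chains = 1, n_iter = 1500, n_burn = 500,
                               seed = 3))
  rates <- fit$acceptance[c("s", "sigma", "lam0_trap", "lam0_cam")]
  expect_true(all(rates > 0.1 & rates < 0.6))
})

test_that("reversible jump detects a strong bait effect and rejects a null", {
  cfg_s <- scenario_config(lam0_trap = 0.01, lam0_cam = 0.04,
                           bait_effect = 2, target_captures = NULL,
                           target_occ_detections = NULL, seed = 13)
  b_eff <- simulate_scenario(cfg_s)
  fitc <- fit_config(variant = "scr", M = 300, n_chains = 2, n_iter = 2500,
                     n_burn = 500, covariate_select = TRUE, seed = 7)
  f_eff <- suppressWarnings(run_fit(b_eff, fitc))
  expect_gt(mean(pooled_draws(f_eff, "w")), 0.9)
  expect_gt(mean(pooled_draws(f_eff, "beta1")[pooled_draws(f_eff, "w") == 1]),
            0.5)

  cfg_n <- scenario_config(lam0_trap = 0.025, lam0_cam = 0.04,
                           bait_effect = 0, target_captures = NULL,
                           target_occ_detections = NULL, seed = 13)
  b_null <- simulate_scenario(cfg_n)
  f_null <- suppressWarnings(run_fit(b_null, fitc))
  expect_lt(mean(pooled_draws(f_null, "w")), 0.3)

  # with the indicator frozen at zero the covariate model matches the plain
  # model's posterior within Monte-Carlo error
  fit_plain <- suppressWarnings(
    run_fit(b_null, fit_config(variant = "scr", M = 300, n_chains = 2,
                               n_iter = 2000, n_burn = 500, seed = 9)))
  fit_cov0 <- suppressWarnings(
    run_fit(b_null, fit_config(variant = "scr", M = 300, n_chains = 2,
                               n_iter = 2000, n_burn = 500, covariate = TRUE,
                               init = list(w = 0L),
                               update = c("z", "s", "sigma", "lam0_trap",
                                          "psi"),
                               seed = 9)))
  s1 <- posterior_summary(fit_plain, c("sigma", "D"))
  s2 <- posterior_summary(fit_cov0, c("sigma", "D"))
  expect_equal(s1["sigma", "mean"], s2["sigma", "mean"], tolerance = 0.1)
  expect_equal(s1["D", "mean"], s2["D", "mean"], tolerance = 0.15)
})

test_that("posterior_summary computes the stated statistics", {
  set.seed(2)
  x <- lapply(1:3, function(i) cbind(D = rnorm(4000, 10, 2)))
  su <- posterior_summary(fake_fit(x), params = "D")
  pooled <- unlist(lapply(x, function(m) m[, 1]))
  expect_equal(su$mean, mean(pooled))
  expect_equal(su$sd, stats::sd(pooled))
  expect_equal(su$cv, stats::sd(pooled) / mean(pooled))
  expect_equal(su$q2.5, unname(stats::quantile(pooled, 0.025)))
  expect_equal(su$mode, 10, tolerance = 0.05)     # symmetric: mode ~ mean
  expect_lt(su$rhat, 1.01)
  expect_gt(su$ess, 2000)
  # constant chains: zero spread, flagged diagnostics
  xc <- lapply(1:3, function(i) cbind(D = rep(2, 100)))
  sc <- posterior_summary(fake_fit(xc), params = "D")
  expect_equal(sc$sd, 0)
  expect_equal(sc$cv, 0)
  expect_true(is.na(sc$rhat))
  # diverging chains are detected
  xd <- list(cbind(D = rnorm(500, 0)), cbind(D = rnorm(500, 5)))
  expect_gt(posterior_summary(fake_fit(xd), params = "D")$rhat, 1.5)
})

test_that("half_sample_mode finds the bulk of a skewed sample", {
  set.seed(5)
  x <- c(rnorm(2000, 1, 0.2), rexp(500) + 2)
  expect_equal(half_sample_mode(x), 1, tolerance = 0.1)
  expect_equal(half_sample_mode(c(3, 3, 3)), 3)
  expect_equal(half_sample_mode(2), 2)
})

test_that("cv_reduction reproduces the headline precision gain", {
  ref <- data.frame(param = "D", cv = 0.349, row.names = "D")
  cand <- data.frame(param = "D", cv = 0.219, row.names = "D")
  red <- cv_reduction(ref, cand, "D")
  expect_gt(red, 37.2); expect_lt(red, 37.3)
  expect_equal(cv_reduction(ref, ref, "D"), 0)
  worse <- data.frame(param = "D", cv = 0.5, row.names = "D")
  expect_lt(cv_reduction(ref, worse, "D"), 0)
  expect_error(cv_reduction(ref, cand, "sigma"), "not present")
  zero <- data.frame(param = "D", cv = 0, row.names = "D")
  expect_error(cv_reduction(zero, cand, "D"), "zero")
})

test_that("joint_log_posterior is additive in the submodels and finite", {
  b <- small_bundle(seed = 15)
  M <- 60
  n <- nrow(b$scr$y)
  set.seed(6)
  st <- augmented_state(z = c(rep(1L, n), rbinom(M - n, 1, 0.4)),
                        s = cbind(runif(M, b$space$xlim[1], b$space$xlim[2]),
                                  runif(M, b$space$ylim[1], b$space$ylim[2])),
                        psi = 0.4, lam0_trap = 0.03, lam0_cam = 0.05,
                        sigma = 0.6, n_obs = n)
  st$s[seq_len(n), ] <- attr(b, "truth")$s[attr(b, "truth")$captured, ]
  lp_scr <- joint_log_posterior(st, b, "scr")
  lp_all <- joint_log_posterior(st, b, "scr_occ_tel")
  expect_equal(lp_all - lp_scr,
               occ_loglik(st, b$cameras, b$occ) +
                 telemetry_loglik(st, b$telemetry) +
                 stats::dunif(st$lam0_cam, 0, 1, log = TRUE))
  # fuzz: finite for admissible random states
  for (k in 1:20) {
    st$sigma <- runif(1, 0.1, 4.9)
    st$lam0_trap <- runif(1, 0.001, 0.9)
    st$lam0_cam <- runif(1, 0.001, 0.9)
    expect_true(is.finite(joint_log_posterior(st, b, "scr_occ_tel")))
  }
})
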