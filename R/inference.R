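#' MCMC fit configuration
#'
#' Settings for the Metropolis-within-Gibbs sampler.  Priors default to the
#' vague choices standard in BUGS-style SCR practice: `psi ~ Beta(1, 1)`,
#' `sigma ~ Uniform(0, 5 km)`, baseline rates `~ Uniform(0, 1)` per detector
#' class, covariate coefficients `~ Normal(0, sd 10)`, and prior inclusion
#' probability 0.5 for the reversible-jump covariate indicator.  Proposal
#' scales are adapted toward 0.35 acceptance during burn-in only, so the
#' post-burn-in kernel is a fixed, valid MCMC kernel.
#'
#' @param variant Submodel combination: `"scr"`, `"scr_occ"`, `"scr_tel"`,
#'   `"scr_occ_tel"`, or `"tel"` (telemetry alone; mainly for validation).
#' @param M Augmentation size (must exceed the observed count comfortably).
#' @param n_chains,n_iter,n_burn Chains, total iterations per chain, and
#'   burn-in iterations discarded from the front.
#' @param priors Named list overriding `psi` (Beta shape pair), `sigma_max`,
#'   `lam0_trap_max`, `lam0_cam_max`, `beta_sd`, `rj_sd`, `rj_prior`.
#' @param proposal Named list of initial random-walk SDs: `s` (km), and
#'   log-scale SDs `sigma`, `lam0_trap`, `lam0_cam`, plus `beta1`.
#' @param covariate Include the bait covariate on the live-trap baseline.
#' @param covariate_select Additionally sample its inclusion indicator by
#'   reversible jump.
#' @param cov_link Link for the covariate model: `"log"` (on the rate;
#'   default) or `"logit"` (on the scale of a probability-like baseline).
#' @param update Parameter blocks to update; removing blocks freezes them at
#'   their initial values (used for oracle tests and prior-sampling checks).
#' @param init Named list of initial-value overrides
#'   (`psi, sigma, lam0_trap, lam0_cam, beta1, w, z, s`).
#' @param adapt Adapt proposal scales during burn-in.
#' @param seed Master seed; per-chain streams are derived from it.
#' @return A `fit_config` list.
#' @export
fit_config <- function(variant = c("scr_occ_tel", "scr_occ", "scr_tel",
                                   "scr", "tel"),
                       M = 300, n_chains = 3, n_iter = 6000, n_burn = 1000,
                       priors = list(), proposal = list(),
                       covariate = FALSE, covariate_select = FALSE,
                       cov_link = c("log", "logit"),
                       update = c("z", "s", "sigma", "lam0_trap",
                                  "lam0_cam", "psi"),
                       init = list(), adapt = TRUE, seed = 1) {
  variant <- match.arg(variant)
  cov_link <- match.arg(cov_link)
  if (n_iter > 0 && n_iter <= n_burn) stop("need n_iter > n_burn >= 0")
  pr <- utils::modifyList(list(psi = c(1, 1), sigma_max = 5,
                               lam0_trap_max = 1, lam0_cam_max = 1,
                               beta_sd = 10, rj_sd = 1, rj_prior = 0.5),
                          priors)
  pp <- utils::modifyList(list(s = 0.6, sigma = 0.12, lam0_trap = 0.3,
                               lam0_cam = 0.25, beta1 = 0.3),
                          proposal)
  structure(list(variant = variant, M = as.integer(M),
                 n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burn = as.integer(n_burn), priors = pr, proposal = pp,
                 covariate = covariate || covariate_select,
                 covariate_select = covariate_select, cov_link = cov_link,
                 update = update, init = init, adapt = adapt,
                 seed = as.integer(seed)),
            class = "fit_config")
}

variant_uses <- function(variant) {
  list(scr = variant != "tel",
       occ = variant %in% c("scr_occ", "scr_occ_tel"),
       tel = variant %in% c("scr_tel", "scr_occ_tel", "tel"))
}

## drop zero-effort detectors (with their data columns), warning once
drop_dead_traps <- function(traps, y = NULL) {
  dead <- which(traps$effort == 0)
  if (!length(dead)) return(list(traps = traps, y = y))
  warning(sprintf("dropping %d detector(s) with zero effort", length(dead)))
  keep <- setdiff(seq_len(n_traps(traps)), dead)
  tr <- trap_array(traps$coords[keep, , drop = FALSE], traps$kind,
                   traps$effort[keep],
                   if (is.null(traps$bait)) NULL else traps$bait[keep])
  if (!is.null(y)) y <- y[, keep, drop = FALSE]
  list(traps = tr, y = y)
}

#' Fit an integrated SCR model by MCMC
#'
#' Runs seeded, independent Metropolis-within-Gibbs chains over the
#' data-augmented state with a systematic scan (inclusion indicators, then
#' activity centers, then detection/scale parameters, then the optional
#' reversible-jump covariate move, then the conjugate draw of `psi`).
#' Non-convergence is reported by the diagnostics in [posterior_summary()],
#' never raised as an error.
#'
#' @param data A [scrim_data()] bundle holding the blocks the variant needs.
#' @param config A [fit_config()].
#' @return A `scrim_fit`: retained draws per chain (parameters, realized `N`
#'   and `D = N/area`, and the pinned activity centers), acceptance rates,
#'   and the configuration used.
#' @export
run_fit <- function(data, config = fit_config()) {
  stopifnot(inherits(data, "scrim_data"), inherits(config, "fit_config"))
  use <- variant_uses(config$variant)
  if (use$occ && is.null(data$occ))
    stop("variant ", config$variant, " needs occupancy data")
  if (use$tel && is.null(data$telemetry))
    stop("variant ", config$variant, " needs telemetry data")

  dt <- drop_dead_traps(data$traps, data$scr$y)
  traps <- dt$traps
  y <- dt$y
  if (config$variant == "tel") y <- y[0, , drop = FALSE]
  n <- nrow(y)
  if (use$scr && config$M <= n) stop("augmentation size M must exceed n")

  if (use$occ) {
    dc <- drop_dead_traps(data$cameras)
    cameras <- dc$traps
    yocc <- data$occ$counts[data$cameras$effort > 0]
  } else {
    cameras <- trap_array(matrix(0, 1, 2), "camera", 0L)
    cameras$coords <- cameras$coords[0, , drop = FALSE]
    cameras$effort <- integer()
    yocc <- integer()
  }

  tel <- data$telemetry
  if (config$variant == "tel") {
    m <- length(tel$fixes)
    tel_slot <- seq_len(m) - 1L
    n_pin <- m
  } else if (use$tel) {
    tel_slot <- tel$link - 1L
    n_pin <- n
  } else {
    tel <- NULL
    tel_slot <- integer()
    n_pin <- n
  }
  tel_mx <- tel_my <- tel_ss <- numeric()
  tel_R <- integer()
  if (!is.null(tel) && length(tel_slot)) {
    tel_mx <- vapply(tel$fixes, function(f) mean(f[, 1]), 0)
    tel_my <- vapply(tel$fixes, function(f) mean(f[, 2]), 0)
    tel_ss <- vapply(tel$fixes, function(f)
      sum((f[, 1] - mean(f[, 1]))^2 + (f[, 2] - mean(f[, 2]))^2), 0)
    tel_R <- vapply(tel$fixes, nrow, 1L)
  }

  space <- data$space
  M <- config$M
  bait <- if (config$covariate && !is.null(traps$bait)) traps$bait
          else rep(0L, n_traps(traps))
  if (config$covariate && is.null(traps$bait))
    stop("covariate model requested but no bait covariate on the live traps")

  pr <- config$priors
  priors_cpp <- list(sigma_max = pr$sigma_max, lam0_trap_max = pr$lam0_trap_max,
                     lam0_cam_max = pr$lam0_cam_max, beta_sd = pr$beta_sd,
                     rj_sd = pr$rj_sd, rj_prior = pr$rj_prior,
                     psi_a = pr$psi[1], psi_b = pr$psi[2])
  flags <- list(use_scr = use$scr, use_occ = use$occ, use_tel = use$tel,
                use_cov = config$covariate, use_rj = config$covariate_select,
                cov_link = if (config$cov_link == "log") 0L else 1L,
                upd_z = "z" %in% config$update,
                upd_s = "s" %in% config$update,
                upd_sigma = "sigma" %in% config$update,
                upd_lam0t = "lam0_trap" %in% config$update,
                upd_lam0c = "lam0_cam" %in% config$update,
                upd_psi = "psi" %in% config$update,
                adapt = config$adapt)

  if (config$n_iter == 0) {
    return(structure(list(chains = list(), acceptance = NULL, config = config,
                          area = space$area, n_obs = n, n_pin = n_pin),
                     class = "scrim_fit"))
  }

  chain_seeds <- with_seed(config$seed,
                           sample.int(.Machine$integer.max - 1L,
                                      config$n_chains))
  chains <- vector("list", config$n_chains)
  accs <- NULL
  for (ch in seq_len(config$n_chains)) {
    res <- with_seed(chain_seeds[ch], {
      init <- default_inits(config, n, n_pin, M, y, traps, tel, tel_slot, space)
      init <- utils::modifyList(init, config$init)
      init$z <- as.integer(init$z)
      run_chain_cpp(y, traps$effort, bait, traps$coords,
                    as.integer(yocc), cameras$effort, cameras$coords,
                    as.integer(tel_slot), tel_mx, tel_my, tel_ss, tel_R,
                    M, n_pin,
                    c(space$xlim, space$ylim), priors_cpp, init,
                    config$proposal, flags, config$n_iter, config$n_burn)
    })
    dr <- res$draws
    colnames(dr) <- c("psi", "sigma", "lam0_trap", "lam0_cam", "beta1", "w",
                      "N", "lam0_trap_bait",
                      if (n_pin > 0) c(paste0("sx", seq_len(n_pin)),
                                       paste0("sy", seq_len(n_pin))))
    dr <- cbind(dr, D = dr[, "N"] / space$area)
    chains[[ch]] <- dr
    accs <- rbind(accs, res$acceptance)
  }
  acceptance <- colMeans(accs)
  names(acceptance) <- colnames(accs)
  fit <- structure(list(chains = chains, acceptance = acceptance,
                        config = config, area = space$area, n_obs = n,
                        n_pin = n_pin, variant = config$variant),
                   class = "scrim_fit")
  Nmax <- max(vapply(chains, function(d) max(d[, "N"]), 0))
  if (config$variant != "tel" && Nmax >= M)
    warning("posterior mass of N touches the augmentation bound M; increase M")
  fit
}

default_inits <- function(config, n, n_pin, M, y, traps, tel, tel_slot, space) {
  s <- cbind(stats::runif(M, space$xlim[1], space$xlim[2]),
             stats::runif(M, space$ylim[1], space$ylim[2]))
  if (n > 0) {
    for (i in seq_len(n)) {
      wgt <- y[i, ]
      if (sum(wgt) > 0)
        s[i, ] <- c(sum(traps$coords[, 1] * wgt), sum(traps$coords[, 2] * wgt)) / sum(wgt)
    }
  }
  if (!is.null(tel) && length(tel_slot))
    for (k in seq_along(tel_slot))
      s[tel_slot[k] + 1L, ] <- colMeans(tel$fixes[[k]])
  ## clamp starts inside the state space
  s[, 1] <- pmin(pmax(s[, 1], space$xlim[1]), space$xlim[2])
  s[, 2] <- pmin(pmax(s[, 2], space$ylim[1]), space$ylim[2])
  z <- c(rep(1L, n_pin), stats::rbinom(M - n_pin, 1, 0.5))
  lam0t <- stats::runif(1, 0.005, 0.1)
  list(psi = stats::runif(1, 0.2, 0.8),
       sigma = stats::runif(1, 0.25, min(1.5, 0.9 * config$priors$sigma_max)),
       beta0 = log(lam0t), beta1 = 0,
       lam0_cam = stats::runif(1, 0.005, 0.1),
       w = if (config$covariate && !config$covariate_select) 1L else 0L,
       z = z, s = s)
}

#' @export
print.scrim_fit <- function(x, ...) {
  cat(sprintf("scrim fit (%s): %d chains x %d retained iterations\n",
              x$config$variant, length(x$chains),
              if (length(x$chains)) nrow(x$chains[[1]]) else 0L))
  if (!is.null(x$acceptance)) {
    cat("acceptance rates:\n")
    print(round(x$acceptance, 3))
  }
  invisible(x)
}

#' Pooled draws of one parameter
#'
#' @param fit A `scrim_fit`.
#' @param param Column name, e.g. `"D"`, `"sigma"`.
#' @return Numeric vector of pooled post-burn-in draws.
#' @export
pooled_draws <- function(fit, param) {
  unlist(lapply(fit$chains, function(d) d[, param]), use.names = FALSE)
}

#' Half-sample mode
#'
#' Robust mode estimate of a sample by recursive halving: repeatedly keep
#' the shortest half-interval until at most three points remain.
#'
#' @param x Numeric vector.
#' @return Scalar mode estimate.
#' @export
half_sample_mode <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0) return(NA_real_)
  while (n > 3) {
    h <- ceiling(n / 2)
    widths <- x[h:n] - x[seq_len(n - h + 1)]
    i <- which.min(widths)
    x <- x[i:(i + h - 1)]
    n <- h
  }
  if (n == 3) {
    if (x[3] - x[2] < x[2] - x[1]) x <- x[2:3]
    else if (x[2] - x[1] < x[3] - x[2]) x <- x[1:2]
  }
  mean(x)
}

## kernel-density mode (optional alternative estimator)
kde_mode <- function(x) {
  d <- stats::density(x)
  d$x[which.max(d$y)]
}

## split-chain potential scale reduction factor
split_rhat <- function(chain_list) {
  halves <- unlist(lapply(chain_list, function(x) {
    t2 <- length(x) %/% 2
    list(x[seq_len(t2)], x[seq(t2 + 1, 2 * t2)])
  }), recursive = FALSE)
  Tn <- length(halves[[1]])
  if (Tn < 2) return(NA_real_)
  mns <- vapply(halves, mean, 0)
  vrs <- vapply(halves, stats::var, 0)
  W <- mean(vrs)
  if (!is.finite(W) || W == 0) return(NA_real_)
  B <- Tn * stats::var(mns)
  sqrt(((Tn - 1) / Tn * W + B / Tn) / W)
}

## effective sample size from chain-averaged autocorrelations (Geyer-style
## truncation at the first negative paired sum)
ess_basic <- function(chain_list) {
  Tn <- length(chain_list[[1]])
  if (Tn < 4) return(NA_real_)
  if (all(vapply(chain_list, function(x) stats::var(x) == 0, TRUE)))
    return(NA_real_)
  lag_max <- min(Tn - 2L, 500L)
  rho <- rowMeans(vapply(chain_list, function(x) {
    if (stats::var(x) == 0) rep(0, lag_max + 1)
    else as.numeric(stats::acf(x, lag.max = lag_max, plot = FALSE,
                               demean = TRUE)$acf)
  }, numeric(lag_max + 1)))
  tau <- 1
  k <- 1
  while (k + 1 <= lag_max) {
    pair <- rho[k + 1] + rho[k + 2]
    if (!is.finite(pair) || pair < 0) break
    tau <- tau + 2 * pair
    k <- k + 2
  }
  length(chain_list) * Tn / tau
}

#' Posterior summary table
#'
#' Mean, half-sample mode, SD, central 95% credible interval, coefficient of
#' variation (`CV = SD/mean`), split-chain Rhat and effective sample size,
#' for each requested parameter (including derived realized `N` and
#' `D = N/area`).
#'
#' @param fit A `scrim_fit`.
#' @param params Parameters to summarize; defaults to all estimated ones.
#' @param mode Mode estimator, `"hsm"` (half-sample, default) or `"kde"`.
#' @return A data frame with one row per parameter, class
#'   `posterior_summary`.
#' @export
posterior_summary <- function(fit, params = NULL, mode = c("hsm", "kde")) {
  mode <- match.arg(mode)
  if (!length(fit$chains)) stop("fit has no stored draws")
  avail <- colnames(fit$chains[[1]])
  if (is.null(params)) {
    params <- intersect(c("D", "N", "sigma", "lam0_trap", "lam0_cam",
                          "beta1", "w", "psi"), avail)
    params <- params[vapply(params, function(p)
      !anyNA(fit$chains[[1]][, p]), TRUE)]
  }
  mfun <- if (mode == "hsm") half_sample_mode else kde_mode
  rows <- lapply(params, function(p) {
    per_chain <- lapply(fit$chains, function(d) d[, p])
    x <- unlist(per_chain, use.names = FALSE)
    q <- stats::quantile(x, c(0.025, 0.975), names = FALSE)
    m <- mean(x)
    data.frame(param = p, mean = m, mode = mfun(x), sd = stats::sd(x),
               q2.5 = q[1], q97.5 = q[2],
               cv = if (m == 0) NA_real_ else stats::sd(x) / m,
               rhat = split_rhat(per_chain), ess = ess_basic(per_chain))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$param
  class(out) <- c("posterior_summary", class(out))
  out
}

#' Percent reduction in coefficient of variation
#'
#' `100 * (CV_ref - CV_cand) / CV_ref` for one parameter; positive values
#' mean the candidate model is more precise than the reference.
#'
#' @param reference,candidate [posterior_summary()] tables.
#' @param param Parameter name present in both.
#' @return Percent CV reduction (scalar).
#' @export
cv_reduction <- function(reference, candidate, param) {
  if (!param %in% rownames(reference) || !param %in% rownames(candidate))
    stop("parameter ", param, " not present in both summaries")
  cvr <- reference[param, "cv"]
  cvc <- candidate[param, "cv"]
  if (!is.finite(cvr) || cvr == 0) stop("reference CV is zero or undefined")
  100 * (cvr - cvc) / cvr
}

#' Joint log-posterior of an augmented state
#'
#' Reference (pure R) evaluation of the unnormalised log-posterior: the
#' submodel log-likelihoods required by the variant plus the log-priors and
#' the augmentation terms (`z ~ Bern(psi)`, `s` uniform on the state space).
#' Used as the slow oracle against which the compiled sampler is validated.
#'
#' @param state An [augmented_state()].
#' @param data A [scrim_data()].
#' @param variant Model variant (see [fit_config()]).
#' @param priors Prior list as in [fit_config()].
#' @return Scalar log-density (`-Inf` allowed, never `NaN` for admissible
#'   states).
#' @export
joint_log_posterior <- function(state, data, variant = "scr_occ_tel",
                                priors = fit_config()$priors) {
  use <- variant_uses(variant)
  ll <- 0
  if (use$scr) ll <- ll + scr_loglik(state, data$traps, data$scr)
  if (use$occ) ll <- ll + occ_loglik(state, data$cameras, data$occ)
  if (use$tel) ll <- ll + telemetry_loglik(state, data$telemetry)
  M <- length(state$z)
  ll <- ll + sum(stats::dbinom(state$z, 1, state$psi, log = TRUE))
  ll <- ll - M * log(data$space$area)
  ll <- ll + stats::dbeta(state$psi, priors$psi[1], priors$psi[2], log = TRUE)
  ll <- ll + stats::dunif(state$sigma, 0, priors$sigma_max, log = TRUE)
  if (use$scr) {
    if (is.na(state$beta0))
      ll <- ll + stats::dunif(state$lam0_trap, 0, priors$lam0_trap_max,
                              log = TRUE)
    else
      ll <- ll + stats::dnorm(state$beta0, 0, priors$beta_sd, log = TRUE) +
        state$w * stats::dnorm(state$beta1, 0, priors$beta_sd, log = TRUE)
  }
  if (use$occ)
    ll <- ll + stats::dunif(state$lam0_cam, 0, priors$lam0_cam_max, log = TRUE)
  ll
}
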