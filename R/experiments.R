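#' Relative bias of a set of estimates
#'
#' `(mean(estimates) - truth) / truth`.
#'
#' @param estimates Numeric vector of point estimates.
#' @param truth Nonzero true value.
#' @return Scalar relative bias.
#' @export
relative_bias <- function(estimates, truth) {
  if (truth == 0) stop("relative bias is undefined for zero truth")
  (mean(estimates) - truth) / truth
}

#' Root-mean-square error of a set of estimates
#'
#' @inheritParams relative_bias
#' @return Scalar RMSE.
#' @export
rmse <- function(estimates, truth) {
  if (!length(estimates)) stop("no estimates supplied")
  sqrt(mean((estimates - truth)^2))
}

#' Simulation study: bias and RMSE across model variants
#'
#' Simulates `n_datasets` datasets from one generative scenario (detector
#' geometry fixed across datasets, as in a real deployment), fits every
#' requested variant to the same data — dropping the occupancy/telemetry
#' blocks a variant does not use — summarizes each fit by the posterior
#' mode, and aggregates relative bias and RMSE for density, sigma, and the
#' live-trap baseline rate.  Single-fit failures are logged and excluded,
#' with the count reported.
#'
#' @param config A [scenario_config()]; calibrated once up front.
#' @param n_datasets Number of simulated datasets.
#' @param variants Model variants to fit.
#' @param fit_cfg Template [fit_config()] (variant and seed overridden per
#'   fit).
#' @param seed Master seed; per-dataset seeds are derived from it.
#' @return A `sim_study_result`: `summary` data frame (variant x parameter
#'   relative bias and RMSE), `estimates` (per-dataset modes), `truth`, and
#'   `n_failed`.
#' @export
run_sim_study <- function(config = scenario_config(), n_datasets = 100,
                          variants = c("scr_occ_tel", "scr_occ", "scr_tel",
                                       "scr"),
                          fit_cfg = fit_config(n_iter = 7000, n_burn = 1000),
                          seed = 1) {
  stopifnot(all(variants %in% c("scr_occ_tel", "scr_occ", "scr_tel", "scr")))
  arrays <- make_trap_arrays(config)
  config <- calibrate_scenario(config, arrays)
  dataset_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                              n_datasets))
  params <- c("D", "sigma", "lam0_trap")
  est <- list()
  realized <- list()
  n_failed <- 0L
  for (dset in seq_len(n_datasets)) {
    bundle <- simulate_scenario(config, seed = dataset_seeds[dset],
                                arrays = arrays)
    tru <- attr(bundle, "truth")
    realized[[dset]] <- data.frame(dataset = dset, N = tru$N, D = tru$D)
    for (v in variants) {
      fit <- tryCatch({
        cfg <- fit_cfg
        cfg$variant <- v
        cfg$seed <- dataset_seeds[dset] %% 100000L + match(v, variants)
        run_fit(bundle, cfg)
      }, error = function(e) {
        message(sprintf("fit failed (dataset %d, %s): %s", dset, v,
                        conditionMessage(e)))
        NULL
      })
      if (is.null(fit)) { n_failed <- n_failed + 1L; next }
      su <- posterior_summary(fit, params = params)
      est[[length(est) + 1L]] <- data.frame(
        dataset = dset, variant = v, param = params,
        mode = su[params, "mode"], mean = su[params, "mean"],
        q2.5 = su[params, "q2.5"], q97.5 = su[params, "q97.5"],
        rhat_D = su["D", "rhat"])
    }
  }
  est <- do.call(rbind, est)
  truth <- c(D = config$density, sigma = config$sigma,
             lam0_trap = config$lam0_trap)
  agg <- do.call(rbind, lapply(split(est, est[c("variant", "param")]),
    function(g) {
      if (!nrow(g)) return(NULL)
      data.frame(variant = g$variant[1], param = g$param[1],
                 relative_bias = relative_bias(g$mode, truth[[g$param[1]]]),
                 rmse = rmse(g$mode, truth[[g$param[1]]]),
                 n = nrow(g))
    }))
  rownames(agg) <- NULL
  structure(list(summary = agg, estimates = est, truth = truth,
                 realized = do.call(rbind, realized), n_failed = n_failed),
            class = "sim_study_result")
}

#' @export
print.sim_study_result <- function(x, ...) {
  cat(sprintf("simulation study (%d failed fits excluded)\n", x$n_failed))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Occupancy-dilution study
#'
#' Repeatedly thins the occupancy detections of one bundle down to fixed
#' totals (hypergeometric removal of events), refits the full integrated
#' model on each diluted dataset, and records the posterior coefficient of
#' variation of density.  Quantifies how occupancy sample size buys
#' precision.
#'
#' @param bundle A [scrim_data()] with occupancy data.
#' @param levels Retained-detection counts (e.g. `c(19, 38, 58, 77)`).
#' @param n_reps Diluted replicates per level.
#' @param fit_cfg [fit_config()] used for the refits (variant forced to
#'   `"scr_occ_tel"` unless the bundle lacks telemetry).
#' @param seed Master seed.
#' @param paired Nest the removals within a replicate (one random event
#'   permutation per replicate; level `L` keeps its first `L` events).
#'   Marginally each level is still a uniform subsample of the detections,
#'   but levels become positively correlated within a replicate, which
#'   sharpens between-level comparisons at a given replicate budget.
#'   `FALSE` draws every level independently via [dilute_occ()].
#' @return A `dilution_result` with per-replicate CVs and per-level mean/SD.
#' @export
run_dilution_study <- function(bundle, levels = c(19, 38, 58, 77),
                               n_reps = 100,
                               fit_cfg = fit_config(n_iter = 7000,
                                                    n_burn = 1000),
                               seed = 1, paired = TRUE) {
  if (is.null(bundle$occ)) stop("bundle has no occupancy data")
  total <- sum(bundle$occ$counts)
  if (any(levels > total))
    stop("dilution level exceeds the available detections")
  fit_cfg$variant <- if (is.null(bundle$telemetry)) "scr_occ" else "scr_occ_tel"
  rep_seeds <- with_seed(seed, matrix(sample.int(.Machine$integer.max - 1L,
                                                 length(levels) * n_reps),
                                      length(levels)))
  events <- rep(seq_along(bundle$occ$counts), bundle$occ$counts)
  rows <- list()
  for (r in seq_len(n_reps)) {
    perm <- if (paired) with_seed(rep_seeds[1, r], sample(events)) else NULL
    for (li in seq_along(levels)) {
      s <- rep_seeds[li, r]
      b <- bundle
      b$occ <- if (paired)
        occ_data(tabulate(perm[seq_len(levels[li])],
                          nbins = length(bundle$occ$counts)))
      else dilute_occ(bundle$occ, levels[li], seed = s)
      cfg <- fit_cfg
      cfg$seed <- rep_seeds[1, r] %% 100000L
      fit <- run_fit(b, cfg)
      su <- posterior_summary(fit, params = c("D", "N"))
      rows[[length(rows) + 1L]] <- data.frame(
        retained = levels[li], rep = r, cv_D = su["D", "cv"],
        mode_D = su["D", "mode"])
    }
  }
  per_rep <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per_rep, per_rep$retained), function(g)
    data.frame(retained = g$retained[1], cv_mean = mean(g$cv_D),
               cv_sd = stats::sd(g$cv_D), n = nrow(g))))
  agg <- agg[order(agg$retained), ]
  rownames(agg) <- NULL
  structure(list(summary = agg, per_rep = per_rep, total = total),
            class = "dilution_result")
}

#' @export
print.dilution_result <- function(x, ...) {
  cat(sprintf("occupancy dilution study (full data: %d detections)\n",
              x$total))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Fit and compare all four model variants on one dataset
#'
#' Produces the case-study-style report: posterior mean, mode, SD, 95%
#' credible interval and CV for density, sigma and the baseline rates under
#' SCR, SCR-Tel, SCR-Occ and SCR-Occ-Tel, plus the percent CV reduction of
#' each integrated variant relative to plain SCR (and of `lam0_cam`
#' relative to SCR-Occ).  Variants whose data blocks are absent from the
#' bundle are skipped with a message.
#'
#' @param bundle A [scrim_data()].
#' @param fit_cfg Template [fit_config()].
#' @param seed Master seed (per-variant seeds derived).
#' @return A `variant_comparison`: `table` (tidy per variant x parameter)
#'   and the list of fitted `scrim_fit` objects.
#' @export
compare_variants <- function(bundle,
                             fit_cfg = fit_config(n_iter = 60000,
                                                  n_burn = 10000),
                             seed = 1) {
  variants <- c("scr", "scr_tel", "scr_occ", "scr_occ_tel")
  keep <- vapply(variants, function(v) {
    u <- variant_uses(v)
    (!u$occ || !is.null(bundle$occ)) && (!u$tel || !is.null(bundle$telemetry))
  }, TRUE)
  skipped <- variants[!keep]
  if (length(skipped))
    message("skipping variants lacking data: ", paste(skipped, collapse = ", "))
  variants <- variants[keep]
  fits <- list()
  sums <- list()
  for (v in variants) {
    cfg <- fit_cfg
    cfg$variant <- v
    cfg$seed <- seed + match(v, variants)
    fits[[v]] <- run_fit(bundle, cfg)
    sums[[v]] <- posterior_summary(fits[[v]])
  }
  ref <- sums[["scr"]]
  rows <- list()
  for (v in variants) {
    su <- sums[[v]]
    pars <- intersect(c("D", "sigma", "lam0_trap", "lam0_cam"),
                      rownames(su))
    for (p in pars) {
      red <- NA_real_
      if (p %in% rownames(ref) && v != "scr")
        red <- cv_reduction(ref, su, p)
      if (p == "lam0_cam" && v == "scr_occ_tel" && "scr_occ" %in% names(sums))
        red <- cv_reduction(sums[["scr_occ"]], su, p)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(variant = v),
        su[p, c("param", "mean", "mode", "sd", "q2.5", "q97.5", "cv",
                "rhat", "ess")],
        data.frame(cv_reduction_pct = red))
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits), class = "variant_comparison")
}

#' @export
print.variant_comparison <- function(x, ...) {
  print(x$table, digits = 3)
  invisible(x)
}
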