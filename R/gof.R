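#' Freeman-Tukey discrepancy at a chosen aggregation level
#'
#' The discrepancy functional is Freeman-Tukey,
#' \eqn{\sum (\sqrt{obs} - \sqrt{exp})^2}, applied at one of three
#' aggregation levels of the individual-by-trap encounter counts:
#' `"ind_trap"` (per cell), `"ind_freq"` (per-individual row totals),
#' `"trap_freq"` (per-trap column totals, aggregated over individuals).
#' A chi-square style alternative `(obs - exp)^2 / (exp + 1e-10)` is
#' available through `fun`.
#'
#' @param obs,expected Nonnegative matrices of identical shape (observed
#'   counts and their posterior-draw expectations).
#' @param flavor Aggregation level.
#' @param fun `"freeman_tukey"` (default) or `"chisq"`.
#' @return Scalar discrepancy.
#' @export
discrepancy <- function(obs, expected,
                        flavor = c("ind_trap", "ind_freq", "trap_freq"),
                        fun = c("freeman_tukey", "chisq")) {
  flavor <- match.arg(flavor)
  fun <- match.arg(fun)
  obs <- as.matrix(obs); expected <- as.matrix(expected)
  if (any(obs < 0) || any(expected < 0)) stop("negative counts")
  if (!all(dim(obs) == dim(expected))) stop("dimension mismatch")
  o <- switch(flavor, ind_trap = obs, ind_freq = rowSums(obs),
              trap_freq = colSums(obs))
  e <- switch(flavor, ind_trap = expected, ind_freq = rowSums(expected),
              trap_freq = colSums(expected))
  if (fun == "freeman_tukey") sum((sqrt(o) - sqrt(e))^2)
  else sum((o - e)^2 / (e + 1e-10))
}

#' Posterior-predictive goodness-of-fit check
#'
#' For a subsample of posterior draws, simulates replicate SCR encounter
#' data from that draw's parameters and pinned activity centers (the
#' posterior predictive of the observation process, conditioned on the
#' drawn latent state), computes the discrepancy of the observed and the
#' replicated data against the draw's expected counts at the three
#' aggregation levels, and reports the Bayesian p-value per statistic:
#' the proportion of draws with replicate discrepancy above the observed
#' one, ties counted one half.
#'
#' @param fit A `scrim_fit` from [run_fit()] (SCR-containing variant).
#' @param data The [scrim_data()] that was fitted.
#' @param n_draws Number of posterior draws to use.
#' @param seed Seed for draw subsampling and replicate simulation.
#' @param fun Discrepancy functional passed to [discrepancy()].
#' @return A `gof_result`: per statistic a data frame of paired
#'   (observed, replicated) discrepancies and the Bayesian p-value `bpv`.
#' @export
posterior_predictive_check <- function(fit, data, n_draws = 500, seed = 1,
                                       fun = "freeman_tukey") {
  if (!length(fit$chains)) stop("fit has no stored draws")
  y <- data$scr$y
  n <- nrow(y)
  if (n == 0 || fit$n_obs != n)
    stop("goodness-of-fit needs the SCR block the model was fitted to")
  traps <- drop_dead_traps(data$traps, y)
  y <- traps$y; traps <- traps$traps
  K <- traps$effort
  all_draws <- do.call(rbind, fit$chains)
  if (n_draws > nrow(all_draws))
    stop("n_draws exceeds the number of stored draws")
  su <- posterior_summary(fit, params = "sigma")
  if (is.finite(su$rhat) && su$rhat > 1.1)
    warning("chains may not have converged (sigma Rhat > 1.1)")
  flavors <- c("ind_trap", "ind_freq", "trap_freq")
  with_seed(seed, {
    pick <- sample.int(nrow(all_draws), n_draws)
    res <- matrix(NA_real_, n_draws, 2 * length(flavors))
    for (r in seq_len(n_draws)) {
      d <- all_draws[pick[r], ]
      s <- cbind(d[paste0("sx", seq_len(n))], d[paste0("sy", seq_len(n))])
      lam0 <- rep(d[["lam0_trap"]], n_traps(traps))
      if (!is.null(traps$bait) && !is.na(d[["w"]]) && d[["w"]] > 0)
        lam0 <- ifelse(traps$bait == 1, d[["lam0_trap_bait"]], lam0)
      dist <- dist_to_traps(s, traps$coords)
      p <- rate_to_prob(sweep(exp(-dist^2 / (2 * d[["sigma"]]^2)), 2L,
                              lam0, "*"))
      expected <- sweep(p, 2L, K, "*")
      yrep <- matrix(stats::rbinom(length(p), rep(K, each = n), p), n)
      ## observed individuals are in the data *because* they were captured;
      ## condition each replicate history on >= 1 encounter so observed and
      ## replicated data are exchangeable under the model
      for (tries in 1:100) {
        zero <- which(rowSums(yrep) == 0)
        if (!length(zero)) break
        yrep[zero, ] <- matrix(
          stats::rbinom(length(zero) * ncol(p), rep(K, each = length(zero)),
                        p[zero, , drop = FALSE]), length(zero))
      }
      for (f in seq_along(flavors)) {
        res[r, 2 * f - 1] <- discrepancy(y, expected, flavors[f], fun)
        res[r, 2 * f] <- discrepancy(yrep, expected, flavors[f], fun)
      }
    }
    out <- lapply(seq_along(flavors), function(f) {
      obs <- res[, 2 * f - 1]; rep_ <- res[, 2 * f]
      list(pairs = data.frame(observed = obs, replicated = rep_),
           bpv = mean(rep_ > obs) + 0.5 * mean(rep_ == obs))
    })
    names(out) <- flavors
    structure(out, class = "gof_result", n_draws = n_draws)
  })
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("posterior-predictive check (%d draws)\n", attr(x, "n_draws")))
  for (nm in names(x))
    cat(sprintf("  %-9s Bayesian p-value = %.3f\n", nm, x[[nm]]$bpv))
  invisible(x)
}

#' Bayesian p-values of a goodness-of-fit result
#'
#' @param x A `gof_result`.
#' @return Named numeric vector of the three Bayesian p-values.
#' @export
bpv <- function(x) {
  stopifnot(inherits(x, "gof_result"))
  vapply(x, function(e) e$bpv, 0)
}
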