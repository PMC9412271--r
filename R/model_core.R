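#' Rectangular state space for activity centers
#'
#' The state space \eqn{S} is the planar region over which latent activity
#' centers are assumed uniformly distributed.  Density is defined as
#' \eqn{D = N/|S|}, so the extent of \eqn{S} is part of the model, not a
#' plotting convenience.  All coordinates in the package are kilometres in a
#' local planar frame.
#'
#' @param xlim,ylim Numeric length-2 vectors, the rectangle bounds (km).
#' @return An object of class `state_space` with elements `xlim`, `ylim`
#'   and `area` (km^2).
#' @examples
#' s <- state_space(c(0, 10), c(0, 8))
#' s$area
#' @export
state_space <- function(xlim, ylim) {
  stopifnot(length(xlim) == 2L, length(ylim) == 2L,
            is.finite(xlim), is.finite(ylim))
  if (diff(xlim) <= 0 || diff(ylim) <= 0)
    stop("state space must have positive extent on both axes")
  structure(list(xlim = as.numeric(xlim), ylim = as.numeric(ylim),
                 area = diff(xlim) * diff(ylim)),
            class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("state space: x [%.2f, %.2f] km, y [%.2f, %.2f] km, area %.1f km^2\n",
              x$xlim[1], x$xlim[2], x$ylim[1], x$ylim[2], x$area))
  invisible(x)
}

#' Detector array
#'
#' A set of detectors of one class: `"live"` box traps yielding individually
#' identified captures, or `"camera"` stations yielding detection/nondetection
#' records without identity.  Effort is a per-detector number of (collapsed)
#' sampling occasions; an optional binary bait covariate is allowed for live
#' traps only.
#'
#' @param coords J x 2 numeric matrix of detector positions (km).
#' @param kind `"live"` or `"camera"`, one class per array.
#' @param effort Integer vector of occasions per detector (`K_j >= 0`);
#'   recycled if scalar.
#' @param bait Optional 0/1 vector, live traps only.
#' @return A `trap_array` object.
#' @export
trap_array <- function(coords, kind = c("live", "camera"), effort, bait = NULL) {
  kind <- match.arg(kind)
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L || nrow(coords) < 1L)
    stop("coords must be a J x 2 matrix with J >= 1")
  storage.mode(coords) <- "double"
  J <- nrow(coords)
  effort <- rep_len(as.integer(effort), J)
  if (any(is.na(effort)) || any(effort < 0)) stop("effort K_j must be >= 0")
  if (!is.null(bait)) {
    if (kind != "live") stop("bait covariate is defined for live traps only")
    bait <- rep_len(as.integer(bait), J)
    if (!all(bait %in% c(0L, 1L))) stop("bait must be binary 0/1")
  }
  structure(list(coords = coords, kind = kind, effort = effort, bait = bait),
            class = "trap_array")
}

#' @export
print.trap_array <- function(x, ...) {
  cat(sprintf("%s-trap array: J = %d, effort %d-%d occasions%s\n",
              x$kind, nrow(x$coords), min(x$effort), max(x$effort),
              if (is.null(x$bait)) "" else ", bait covariate present"))
  invisible(x)
}

n_traps <- function(traps) nrow(traps$coords)

#' Spatial capture-recapture data
#'
#' Occasion-aggregated encounter counts: `y[i, j]` is the number of occasions
#' (out of `K_j`) on which identified individual `i` was caught in live trap
#' `j`.  Every retained individual must have been detected at least once.
#'
#' @param y n x J nonnegative integer matrix.
#' @param traps The matching live [trap_array()] (used to validate `y <= K_j`).
#' @param individuals Optional character ids, one per row.
#' @return An `scr_data` object.
#' @export
scr_data <- function(y, traps = NULL, individuals = NULL) {
  y <- as.matrix(y)
  storage.mode(y) <- "integer"
  if (any(is.na(y)) || any(y < 0)) stop("encounter counts must be nonnegative")
  if (nrow(y) > 0 && any(rowSums(y) == 0))
    stop("every observed individual must have at least one encounter")
  if (!is.null(traps)) {
    if (ncol(y) != n_traps(traps)) stop("y has wrong number of trap columns")
    if (any(sweep(y, 2L, traps$effort) > 0))
      stop("encounter count exceeds trap effort K_j: corrupted data")
  }
  if (is.null(individuals)) individuals <- as.character(seq_len(nrow(y)))
  structure(list(y = y, individuals = as.character(individuals)),
            class = "scr_data")
}

#' Occupancy (detection/nondetection) data
#'
#' Per-camera counts of occasions with at least one detection of the target
#' species, individual identity unknown.
#'
#' @param counts Length-Jcam nonnegative integer vector.
#' @param cameras The matching camera [trap_array()].
#' @return An `occ_data` object.
#' @export
occ_data <- function(counts, cameras = NULL) {
  counts <- as.integer(counts)
  if (any(is.na(counts)) || any(counts < 0)) stop("detection counts must be >= 0")
  if (!is.null(cameras)) {
    if (length(counts) != n_traps(cameras)) stop("counts length != number of cameras")
    if (any(counts > cameras$effort))
      stop("detections exceed camera effort K_j")
  }
  structure(list(counts = counts), class = "occ_data")
}

#' Telemetry data
#'
#' Thinned telemetry fixes (one per survey day) for a subset of the captured
#' individuals.  `link` maps each tagged individual to its row in the SCR
#' capture matrix, because tagged animals come from the live-capture cohort
#' and therefore share an activity-center slot with their capture history.
#'
#' @param fixes List of R_i x 2 coordinate matrices (km), one per tagged
#'   individual.
#' @param link Integer vector, the SCR row index of each tagged individual.
#' @return A `telemetry_data` object.
#' @export
telemetry_data <- function(fixes, link) {
  stopifnot(is.list(fixes), length(fixes) == length(link))
  fixes <- lapply(fixes, function(f) {
    f <- as.matrix(f); storage.mode(f) <- "double"
    if (ncol(f) != 2L || nrow(f) < 1L) stop("each tagged individual needs >= 1 fix")
    f
  })
  link <- as.integer(link)
  if (any(link < 1L) || anyDuplicated(link)) stop("invalid telemetry link indices")
  structure(list(fixes = fixes, link = link), class = "telemetry_data")
}

#' Augmented model state
#'
#' One complete parameter + latent-variable configuration of the
#' data-augmented model: a super-population of `M` slots with inclusion
#' indicators `z` (the first `n` pinned to 1 for observed individuals),
#' activity centers `s`, inclusion probability `psi`, detector-class baseline
#' rates, the shared half-normal scale `sigma`, and the optional bait-effect
#' coefficients used by the covariate model.
#'
#' @param z Binary inclusion vector, length M.
#' @param s M x 2 activity-center matrix (km).
#' @param psi Inclusion probability in (0, 1).
#' @param lam0_trap,lam0_cam Baseline encounter rates per occasion (>= 0).
#' @param sigma Half-normal scale (km), > 0.
#' @param beta0,beta1 Bait-covariate intercept/effect on the link scale.
#' @param w Binary covariate-inclusion indicator.
#' @param n_obs Number of observed individuals pinned to z = 1.
#' @return An `augmented_state` object.
#' @export
augmented_state <- function(z, s, psi, lam0_trap, lam0_cam = NA_real_,
                            sigma, beta0 = NA_real_, beta1 = 0, w = 0L,
                            n_obs = 0L) {
  z <- as.integer(z)
  s <- as.matrix(s)
  if (nrow(s) != length(z) || ncol(s) != 2L) stop("s must be M x 2")
  if (sigma <= 0) stop("sigma must be positive")
  if (any(!z %in% c(0L, 1L))) stop("z must be binary")
  if (n_obs > 0 && any(z[seq_len(n_obs)] != 1L))
    stop("observed individuals must have z = 1")
  if (!is.na(lam0_trap) && lam0_trap < 0) stop("lam0_trap must be >= 0")
  if (!is.na(lam0_cam) && lam0_cam < 0) stop("lam0_cam must be >= 0")
  if (psi < 0 || psi > 1) stop("psi must lie in [0, 1]")
  structure(list(z = z, s = s, psi = psi, lam0_trap = lam0_trap,
                 lam0_cam = lam0_cam, sigma = sigma, beta0 = beta0,
                 beta1 = beta1, w = as.integer(w), n_obs = as.integer(n_obs)),
            class = "augmented_state")
}

#' Half-normal encounter rate
#'
#' Expected encounters per occasion for an individual whose activity center
#' lies at distance `d` from the detector:
#' \deqn{\lambda(d) = \lambda_0 \exp(-d^2 / (2\sigma^2)).}
#'
#' @param d Distance(s) in km, >= 0.
#' @param lam0 Baseline rate at distance zero, >= 0.
#' @param sigma Half-normal scale (km), > 0.
#' @return Encounter rate(s), same length as `d`.
#' @examples
#' encounter_rate(0.652, lam0 = 0.014, sigma = 0.652) # = 0.014 * exp(-1/2)
#' @export
encounter_rate <- function(d, lam0, sigma) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (any(lam0 < 0)) stop("lam0 must be nonnegative")
  if (any(d < 0)) stop("distances must be nonnegative")
  lam0 * exp(-d^2 / (2 * sigma^2))
}

#' Complementary log-log link from rate to probability
#'
#' Converts an encounter rate per occasion into a detection probability,
#' \eqn{p = 1 - \exp(-\lambda)}.  This is the exact per-occasion detection
#' probability when within-occasion encounters are Poisson with mean
#' \eqn{\lambda}.
#'
#' @param lam Nonnegative rate(s).
#' @return Probability in [0, 1].
#' @export
rate_to_prob <- function(lam) {
  if (any(lam < 0)) stop("rate must be nonnegative")
  -expm1(-lam)
}

## distance matrix between M activity centers and J detectors
dist_to_traps <- function(s, coords) {
  s <- matrix(as.numeric(s), ncol = 2L)
  dx <- outer(s[, 1], coords[, 1], "-")
  dy <- outer(s[, 2], coords[, 2], "-")
  sqrt(dx * dx + dy * dy)
}

## per-trap baseline rate vector under the optional bait covariate.
## link = "log" (default) or "logit"; with w = 0 both reduce to a scalar
## baseline exp(beta0) resp. plogis(beta0) applied to the rate.
lam0_trap_vector <- function(state, traps, link = c("log", "logit")) {
  link <- match.arg(link)
  J <- n_traps(traps)
  if (is.na(state$beta0)) return(rep(state$lam0_trap, J))
  eta <- state$beta0 + state$w * state$beta1 * (if (is.null(traps$bait)) 0 else traps$bait)
  if (link == "log") exp(eta) else stats::plogis(eta)
}

#' Log-likelihood of the SCR capture histories
#'
#' Occasion-aggregated binomial likelihood of the observed individual-by-trap
#' encounter counts, plus the all-zero binomial mass of the augmented latent
#' individuals with `z = 1`.  Detection probability comes from the shared
#' half-normal rate through the cloglog link.
#'
#' @param state An [augmented_state()].
#' @param traps Live [trap_array()].
#' @param data [scr_data()] whose rows occupy the first `n_obs` slots.
#' @param link Link for the bait-covariate model, `"log"` or `"logit"`.
#' @return Scalar log-likelihood.
#' @export
scr_loglik <- function(state, traps, data, link = "log") {
  y <- data$y
  n <- nrow(y)
  if (state$n_obs != n) stop("state$n_obs must equal nrow(data$y)")
  K <- traps$effort
  if (any(sweep(y, 2L, K) > 0)) stop("y > K_j: corrupted data")
  lam0 <- lam0_trap_vector(state, traps, link)
  d <- dist_to_traps(state$s, traps$coords)
  lam <- sweep(exp(-d^2 / (2 * state$sigma^2)), 2L, lam0, "*")
  p <- rate_to_prob(lam)
  ll <- 0
  if (n > 0) {
    pobs <- p[seq_len(n), , drop = FALSE]
    ll <- ll + sum(stats::dbinom(y, rep(K, each = n), pobs, log = TRUE))
  }
  latent <- which(state$z == 1L)
  latent <- latent[latent > n]
  if (length(latent) > 0) {
    ## all-zero binomial mass: K_j * log(1 - p) = -K_j * lambda
    ll <- ll - sum(sweep(lam[latent, , drop = FALSE], 2L, K, "*"))
  }
  ll
}

#' Per-camera occupancy detection probability
#'
#' Probability that camera `j` records at least one detection on an occasion:
#' \eqn{1 - \prod_i (1 - p_{ij})^{z_i}}, the union over included individuals
#' of per-individual half-normal detection.  With the cloglog link this is
#' \eqn{1 - \exp(-\sum_i z_i \lambda_{ij})}.
#'
#' @param state An [augmented_state()].
#' @param cameras Camera [trap_array()].
#' @param j Camera index (vectorised; default all cameras).
#' @return Detection probability per requested camera.
#' @export
occ_det_prob <- function(state, cameras, j = seq_len(n_traps(cameras))) {
  d <- dist_to_traps(state$s, cameras$coords[j, , drop = FALSE])
  lam <- encounter_rate(d, state$lam0_cam, state$sigma)
  -expm1(-colSums(lam * state$z))
}

#' Log-likelihood of the occupancy data
#'
#' Per-camera binomial likelihood of the number of occasions with at least
#' one detection, out of `K_j`, with success probability [occ_det_prob()].
#'
#' @inheritParams occ_det_prob
#' @param data [occ_data()].
#' @return Scalar log-likelihood.
#' @export
occ_loglik <- function(state, cameras, data) {
  y <- data$counts
  K <- cameras$effort
  if (any(y > K)) stop("y_occ > K_j: corrupted data")
  if (any(y > 0 & K == 0)) stop("detections at a camera with zero effort")
  P <- occ_det_prob(state, cameras)
  sum(stats::dbinom(y, K, P, log = TRUE))
}

#' Log-likelihood of the telemetry fixes
#'
#' Independent bivariate-normal fixes centered on each tagged individual's
#' activity center with isotropic variance `sigma^2` (zero covariance), the
#' movement-model reading of the half-normal detection scale.
#'
#' @param state An [augmented_state()].
#' @param tel [telemetry_data()]; `link` indices address rows of `state$s`.
#' @return Scalar log-likelihood.
#' @export
telemetry_loglik <- function(state, tel) {
  if (state$sigma <= 0) stop("sigma must be positive")
  ll <- 0
  for (i in seq_along(tel$fixes)) {
    f <- tel$fixes[[i]]
    si <- state$s[tel$link[i], ]
    ll <- ll + sum(stats::dnorm(f[, 1], si[1], state$sigma, log = TRUE)) +
               sum(stats::dnorm(f[, 2], si[2], state$sigma, log = TRUE))
  }
  ll
}

#' Closed-form profile estimate of sigma from telemetry alone
#'
#' With each activity center profiled at its fix centroid, the maximum of the
#' telemetry likelihood in `sigma^2` is the mean squared deviation pooled
#' over both axes: \eqn{\hat\sigma^2 = \sum_i \sum_r \|l_{ir} - \bar l_i\|^2
#' / (2 \sum_i R_i)}.
#'
#' @param tel [telemetry_data()].
#' @return The profile MLE of sigma (km).
#' @export
telemetry_sigma_profile <- function(tel) {
  ss <- 0; ntot <- 0L
  for (f in tel$fixes) {
    ctr <- colMeans(f)
    ss <- ss + sum((f[, 1] - ctr[1])^2 + (f[, 2] - ctr[2])^2)
    ntot <- ntot + nrow(f)
  }
  sqrt(ss / (2 * ntot))
}
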