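#' Generative scenario configuration
#'
#' Describes the "true world" used by the simulator: density and movement
#' scale of the target population, detector geometry and effort, telemetry
#' effort, and either explicit baseline rates or calibration targets from
#' which the rates are solved.  Defaults emulate a mesocarnivore survey with
#' 60 clustered live traps (17 occasions each), 40 camera stations active
#' 52-98 days on a coarse jittered grid (mean nearest-neighbour spacing about
#' 1.27 km), true density 0.35 individuals/km^2, sigma 0.6 km, around 21
#' total live captures, about 97 camera detections, and 4 collared
#' individuals with 20 thinned fixes each.
#'
#' @param density True density, individuals/km^2.
#' @param sigma Half-normal scale / movement SD, km.
#' @param lam0_trap,lam0_cam Baseline rates per occasion; `NULL` means solve
#'   them from `target_captures` / `target_occ_detections` for the generated
#'   geometry (see [calibrate_scenario()]).
#' @param target_captures Expected total number of live-trap captures used to
#'   calibrate `lam0_trap` when it is `NULL`.
#' @param target_occ_detections Expected total camera detections used to
#'   calibrate `lam0_cam` when it is `NULL`.
#' @param n_live,n_cam Number of live traps / camera stations.
#' @param K_trap Occasions per live trap.
#' @param K_cam_range Min/max camera-days; per-camera effort is drawn
#'   uniformly in this range.
#' @param n_collared Number of telemetry-tagged individuals (must end up
#'   captured).
#' @param fixes_per_collar Thinned fixes per collared individual.
#' @param M Augmentation size used when simulating the population.
#' @param buffer State-space buffer (km) beyond the detector bounding box.
#' @param bait_effect True bait effect on log(lam0_trap) for baited traps
#'   (0 = no effect; used by covariate-selection experiments).
#' @param seed Integer seed controlling all generator randomness.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(density = 0.35, sigma = 0.6,
                            lam0_trap = NULL, lam0_cam = NULL,
                            target_captures = 21, target_occ_detections = 97,
                            n_live = 60, n_cam = 40, K_trap = 17,
                            K_cam_range = c(52L, 98L),
                            n_collared = 4, fixes_per_collar = 20,
                            M = 200, buffer = 2, bait_effect = 0, seed = 1) {
  stopifnot(density >= 0, sigma > 0, n_live > 0, n_cam > 0, K_trap >= 0,
            n_collared >= 0, fixes_per_collar >= 1, M > 0, buffer >= 0)
  structure(list(density = density, sigma = sigma, lam0_trap = lam0_trap,
                 lam0_cam = lam0_cam, target_captures = target_captures,
                 target_occ_detections = target_occ_detections,
                 n_live = as.integer(n_live), n_cam = as.integer(n_cam),
                 K_trap = as.integer(K_trap),
                 K_cam_range = as.integer(K_cam_range),
                 n_collared = as.integer(n_collared),
                 fixes_per_collar = as.integer(fixes_per_collar),
                 M = as.integer(M), buffer = buffer,
                 bait_effect = bait_effect, seed = as.integer(seed)),
            class = "scenario_config")
}

## run expr with a private RNG stream, restoring the caller's stream after
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate the live-trap and camera arrays
#'
#' Live traps: clusters of five traps (spread about 177 m, the mean
#' intertrap distance of the emulated design) around jittered cluster
#' centers, 12 clusters in a roughly 9 x 6 km envelope.  Cameras: a jittered
#' 10 x 4 grid with 1.35 km column spacing, giving a mean nearest-neighbour
#' distance of about 1.27 km over an envelope of roughly 100 km^2 that
#' partially overlaps the live-trap envelope.  Per-camera effort is drawn
#' uniformly within `K_cam_range`.
#'
#' @param config A [scenario_config()].
#' @param seed Seed; defaults to `config$seed`.
#' @return List with elements `live` and `cameras`, both [trap_array()]s.
#' @export
make_trap_arrays <- function(config, seed = config$seed) {
  with_seed(seed, {
    ## cameras: 10 x 4 jittered grid
    nc <- config$n_cam
    ncol_g <- 10L; nrow_g <- ceiling(nc / ncol_g)
    gx <- rep(seq(0, by = 1.35, length.out = ncol_g), nrow_g)[seq_len(nc)]
    gy <- rep(seq(0, by = 2.7, length.out = nrow_g), each = ncol_g)[seq_len(nc)]
    cam_xy <- cbind(gx + stats::runif(nc, -0.3, 0.3),
                    gy + stats::runif(nc, -0.3, 0.3))
    K_cam <- sample(seq(config$K_cam_range[1], config$K_cam_range[2]),
                    nc, replace = TRUE)
    cameras <- trap_array(cam_xy, "camera", K_cam)

    ## live traps: clusters of 5 around jittered centers, offset to the east
    ## so the two envelopes overlap only partially
    n_live <- config$n_live
    n_clust <- ceiling(n_live / 5L)
    cxg <- ceiling(sqrt(n_clust)); cyg <- ceiling(n_clust / cxg)
    cx <- rep(6.0 + seq(0, by = 2.8, length.out = cxg), cyg)[seq_len(n_clust)]
    cy <- rep(1.0 + seq(0, by = 2.5, length.out = cyg), each = cxg)[seq_len(n_clust)]
    cx <- cx + stats::runif(n_clust, -0.4, 0.4)
    cy <- cy + stats::runif(n_clust, -0.4, 0.4)
    off <- rbind(c(0, 0), c(0.177, 0), c(-0.177, 0), c(0, 0.177), c(0, -0.177))
    live_xy <- matrix(NA_real_, n_live, 2)
    for (k in seq_len(n_live)) {
      cl <- ((k - 1L) %/% 5L) + 1L
      o <- off[((k - 1L) %% 5L) + 1L, ]
      live_xy[k, ] <- c(cx[cl], cy[cl]) + o + stats::runif(2, -0.05, 0.05)
    }
    live <- trap_array(live_xy, "live", config$K_trap,
                       bait = rep_len(c(0L, 1L), n_live))
    list(live = live, cameras = cameras)
  })
}

#' State space enclosing a set of detector arrays
#'
#' Bounding rectangle of all detector coordinates buffered by `buffer` km on
#' every side.  The buffer should be large relative to `sigma` (the default
#' scenario uses about 3 sigma) so that individuals with non-negligible
#' detection probability are inside the state space.
#'
#' @param arrays List of [trap_array()]s.
#' @param buffer Buffer width in km.
#' @return A [state_space()].
#' @export
state_space_from_arrays <- function(arrays, buffer = 2) {
  xy <- do.call(rbind, lapply(arrays, function(a) a$coords))
  state_space(range(xy[, 1]) + c(-buffer, buffer),
              range(xy[, 2]) + c(-buffer, buffer))
}

## expected total captures as a function of lam0, by uniform-s quadrature
expected_captures <- function(lam0, sgrid, traps, sigma, EN) {
  d <- dist_to_traps(sgrid, traps$coords)
  p <- rate_to_prob(encounter_rate(d, lam0, sigma))
  EN * mean(p %*% traps$effort)
}

## expected total camera detections under the union-over-individuals model
expected_occ <- function(lam0c, pops, cameras, sigma) {
  tot <- vapply(pops, function(s) {
    d <- dist_to_traps(s, cameras$coords)
    lam <- encounter_rate(d, lam0c, sigma)
    sum(cameras$effort * rate_to_prob(colSums(lam)))
  }, numeric(1))
  mean(tot)
}

#' Solve baseline rates from capture/detection targets
#'
#' The emulated study chose baseline detection rate and effort jointly to
#' yield about 21 live captures and about 97 camera detections.  Given the
#' geometry, effort, density, and sigma, this helper solves `lam0_trap` so
#' the expected total capture count matches `target_captures`, and
#' `lam0_cam` so the expected total camera detections match
#' `target_occ_detections`.  Expectations are computed by fixed-seed Monte
#' Carlo integration over the uniform activity-center distribution.
#'
#' @param config A [scenario_config()].
#' @param arrays Optional detector arrays (regenerated from `config` if
#'   missing).
#' @return The config with `lam0_trap` / `lam0_cam` filled in.
#' @export
calibrate_scenario <- function(config, arrays = NULL) {
  if (is.null(arrays)) arrays <- make_trap_arrays(config)
  space <- state_space_from_arrays(arrays, config$buffer)
  EN <- config$density * space$area
  with_seed(777L, {
    sgrid <- cbind(stats::runif(4000, space$xlim[1], space$xlim[2]),
                   stats::runif(4000, space$ylim[1], space$ylim[2]))
    if (is.null(config$lam0_trap)) {
      f <- function(l0) expected_captures(l0, sgrid, arrays$live,
                                          config$sigma, EN) -
        config$target_captures
      config$lam0_trap <- stats::uniroot(f, c(1e-6, 5), tol = 1e-8)$root
    }
    if (is.null(config$lam0_cam)) {
      pops <- replicate(300, {
        N <- stats::rbinom(1, config$M, min(1, EN / config$M))
        cbind(stats::runif(N, space$xlim[1], space$xlim[2]),
              stats::runif(N, space$ylim[1], space$ylim[2]))
      }, simplify = FALSE)
      g <- function(l0) expected_occ(l0, pops, arrays$cameras, config$sigma) -
        config$target_occ_detections
      config$lam0_cam <- stats::uniroot(g, c(1e-6, 5), tol = 1e-8)$root
    }
  })
  config
}

#' Simulate the latent population
#'
#' Realized population size is `N ~ Binomial(M, psi)` with
#' `psi = density * area / M`, and activity centers are uniform on the state
#' space (homogeneous point process).
#'
#' @param config A [scenario_config()].
#' @param space A [state_space()].
#' @return List with `s` (N x 2 centers), `N`, `M`, `psi`.
#' @export
simulate_population <- function(config, space) {
  psi <- config$density * space$area / config$M
  if (psi > 1) stop("density * area exceeds augmentation size M")
  N <- stats::rbinom(1, config$M, psi)
  s <- cbind(stats::runif(N, space$xlim[1], space$xlim[2]),
             stats::runif(N, space$ylim[1], space$ylim[2]))
  list(s = s, N = N, M = config$M, psi = psi)
}

## per-trap baseline rates including any true bait effect
true_lam0_by_trap <- function(config, traps) {
  b <- if (is.null(traps$bait)) rep(0L, n_traps(traps)) else traps$bait
  config$lam0_trap * exp(config$bait_effect * b)
}

#' Simulate SCR capture histories
#'
#' Per-occasion Bernoulli encounters (equivalently a binomial count out of
#' `K_j`) with half-normal detection; individuals never captured are dropped
#' from the data but reported through the `captured` attribute so truth
#' bookkeeping stays possible.
#'
#' @param pop Output of [simulate_population()].
#' @param traps Live [trap_array()].
#' @param config A calibrated [scenario_config()].
#' @return An [scr_data()]; attribute `captured` gives the population row of
#'   each retained individual.
#' @export
simulate_scr <- function(pop, traps, config) {
  J <- n_traps(traps)
  if (pop$N == 0) {
    out <- scr_data(matrix(integer(), 0, J))
    attr(out, "captured") <- integer()
    return(out)
  }
  lam0 <- true_lam0_by_trap(config, traps)
  d <- dist_to_traps(pop$s, traps$coords)
  p <- rate_to_prob(sweep(exp(-d^2 / (2 * config$sigma^2)), 2L, lam0, "*"))
  y <- matrix(stats::rbinom(length(p), rep(traps$effort, each = pop$N), p),
              pop$N, J)
  captured <- which(rowSums(y) > 0)
  out <- scr_data(y[captured, , drop = FALSE], traps)
  attr(out, "captured") <- captured
  out
}

#' Simulate occupancy (detection/nondetection) data
#'
#' A camera detects on an occasion when at least one member of the
#' population is detected there; under the cloglog link the union
#' probability is `1 - exp(-sum_i lambda_ij)` and the per-camera count is
#' binomial over `K_j` occasions.  `method = "daily"` instead simulates
#' latent per-individual daily Poisson counts and reduces them with
#' [quantize()]; it returns the same distribution and is kept as a slower,
#' structurally explicit cross-check.
#'
#' @inheritParams simulate_scr
#' @param cameras Camera [trap_array()].
#' @param method `"binomial"` (aggregate) or `"daily"` (per-occasion counts).
#' @return An [occ_data()].  For `method = "daily"` the attribute `counts`
#'   holds the latent individual x camera x occasion count array.
#' @export
simulate_occ <- function(pop, cameras, config, method = c("binomial", "daily")) {
  method <- match.arg(method)
  J <- n_traps(cameras)
  if (pop$N == 0) return(occ_data(rep(0L, J), cameras))
  d <- dist_to_traps(pop$s, cameras$coords)
  lam <- encounter_rate(d, config$lam0_cam, config$sigma)
  if (method == "binomial") {
    P <- rate_to_prob(colSums(lam))
    return(occ_data(stats::rbinom(J, cameras$effort, P), cameras))
  }
  Kmax <- max(cameras$effort)
  counts <- array(stats::rpois(pop$N * J * Kmax, rep(lam, Kmax)),
                  dim = c(pop$N, J, Kmax))
  ## mask occasions beyond each camera's effort
  for (j in seq_len(J)) if (cameras$effort[j] < Kmax)
    counts[, j, seq(cameras$effort[j] + 1L, Kmax)] <- 0L
  binary <- quantize(counts)
  det_jk <- apply(binary, c(2, 3), max)
  out <- occ_data(as.integer(rowSums(det_jk)), cameras)
  attr(out, "counts") <- counts
  out
}

#' Simulate telemetry fixes
#'
#' Collars a subset of the captured individuals and draws independent
#' bivariate-normal fixes (`sigma^2 I` covariance) around each one's
#' activity center — the generative counterpart of one thinned fix per
#' survey day.
#'
#' @inheritParams simulate_scr
#' @param scr The [simulate_scr()] output (collared animals must come from
#'   the captured cohort).
#' @return A [telemetry_data()] whose `link` indexes rows of `scr$y`, or
#'   `NULL` when `n_collared` is 0.
#' @export
simulate_telemetry <- function(pop, scr, config) {
  if (config$n_collared == 0) return(NULL)
  captured <- attr(scr, "captured")
  if (config$n_collared > length(captured))
    stop("cannot collar more individuals than were captured")
  tagged_rows <- sort(sample(seq_along(captured), config$n_collared))
  fixes <- lapply(tagged_rows, function(r) {
    s <- pop$s[captured[r], ]
    cbind(stats::rnorm(config$fixes_per_collar, s[1], config$sigma),
          stats::rnorm(config$fixes_per_collar, s[2], config$sigma))
  })
  telemetry_data(fixes, tagged_rows)
}

#' Quantize counts to binary detections
#'
#' Elementwise indicator `count > 0`; used to reduce daily counts to the
#' Bernoulli scale the model assumes.  Idempotent.
#'
#' @param x Nonnegative numeric vector/matrix/array.
#' @return Integer 0/1 object with the same shape.
#' @export
quantize <- function(x) {
  if (any(x < 0)) stop("counts must be nonnegative")
  out <- (x > 0) + 0L
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

#' Thin telemetry records to one fix per survey day
#'
#' Keeps exactly one uniformly chosen fix per individual-day, the standard
#' mitigation for temporal autocorrelation in telemetry.
#'
#' @param df Data frame with columns `individual`, `day`, `x`, `y`.
#' @param seed Optional seed for reproducible selection.
#' @return Data frame with one row per individual-day, original column set.
#' @export
thin_telemetry <- function(df, seed = NULL) {
  stopifnot(all(c("individual", "day", "x", "y") %in% names(df)))
  pick <- function(idx) if (length(idx) == 1L) idx else sample(idx, 1L)
  run <- function() {
    keys <- interaction(df$individual, df$day, drop = TRUE)
    keep <- unlist(lapply(split(seq_len(nrow(df)), keys), pick),
                   use.names = FALSE)
    df[sort(keep), , drop = FALSE]
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Dilute occupancy data to a fixed number of detections
#'
#' Removes detection events uniformly at random without replacement until
#' exactly `retain` remain — multivariate-hypergeometric allocation of the
#' retained events over cameras, used to study how occupancy sample size
#' drives precision.
#'
#' @param occ An [occ_data()].
#' @param retain Number of detections to keep (0..total).
#' @param seed Optional seed.
#' @return An [occ_data()] with total count exactly `retain`.
#' @export
dilute_occ <- function(occ, retain, seed = NULL) {
  total <- sum(occ$counts)
  if (retain > total) stop("retain exceeds the available detections")
  if (retain == total) return(occ)
  run <- function() {
    events <- rep(seq_along(occ$counts), occ$counts)
    kept <- if (retain == 0) integer() else
      events[sample.int(length(events), retain)]
    occ_data(tabulate(kept, nbins = length(occ$counts)))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate a complete integrated dataset
#'
#' Generates geometry, state space, population, SCR, occupancy, and
#' telemetry blocks under one seed; calibrates baseline rates from the
#' scenario targets when they are not given.  This is the package's
#' self-contained stand-in for a field campaign.
#'
#' @param config A [scenario_config()].
#' @param seed Seed; defaults to `config$seed`.
#' @param arrays Optional pre-built detector arrays (kept fixed across
#'   replicate datasets in the simulation experiments).
#' @return A [scrim_data()] bundle; attribute `truth` records the generative
#'   values (N, D, sigma, rates, centers, captured indices).
#' @export
simulate_scenario <- function(config, seed = config$seed, arrays = NULL) {
  if (is.null(arrays)) arrays <- make_trap_arrays(config)
  if (is.null(config$lam0_trap) || is.null(config$lam0_cam))
    config <- calibrate_scenario(config, arrays)
  space <- state_space_from_arrays(arrays, config$buffer)
  with_seed(seed, {
    pop <- simulate_population(config, space)
    scr <- simulate_scr(pop, arrays$live, config)
    occ <- simulate_occ(pop, arrays$cameras, config)
    tel <- tryCatch(simulate_telemetry(pop, scr, config),
                    error = function(e) {
                      warning("telemetry skipped: ", conditionMessage(e))
                      NULL
                    })
    bundle <- scrim_data(traps = arrays$live, cameras = arrays$cameras,
                         scr = scr, occ = occ, telemetry = tel, space = space)
    attr(bundle, "truth") <- list(
      N = pop$N, D = pop$N / space$area, density = config$density,
      sigma = config$sigma, lam0_trap = config$lam0_trap,
      lam0_cam = config$lam0_cam, s = pop$s,
      captured = attr(scr, "captured"), config = config)
    bundle
  })
}
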