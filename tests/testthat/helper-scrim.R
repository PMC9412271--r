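# shared fixtures and independent oracles, built in code

# small deterministic world: 2 live traps, 2 cameras, tight state space
toy_world <- function(K_live = c(1L, 1L), K_cam = c(1L, 1L)) {
  live <- trap_array(rbind(c(1, 1), c(2, 1)), "live", K_live)
  cams <- trap_array(rbind(c(1, 2), c(2, 2)), "camera", K_cam)
  space <- state_space(c(0, 3), c(0, 3))
  list(live = live, cams = cams, space = space)
}

# exhaustive oracle for the occupancy likelihood: enumerate every
# per-individual, per-occasion detection outcome and accumulate the
# probability of each per-camera count of occupied occasions
occ_loglik_enum <- function(state, cameras, data) {
  inc <- which(state$z == 1L)
  ll <- 0
  for (j in seq_len(nrow(cameras$coords))) {
    K <- cameras$effort[j]
    y <- data$counts[j]
    if (K == 0) { if (y > 0) return(-Inf) else next }
    d <- sqrt(colSums((t(state$s[inc, , drop = FALSE]) -
                         cameras$coords[j, ])^2))
    p <- rate_to_prob(encounter_rate(d, state$lam0_cam, state$sigma))
    m <- length(inc)
    if (m == 0) { ll <- ll + if (y == 0) 0 else -Inf; next }
    # outcomes: m individuals x K occasions binary detections
    grid <- as.matrix(expand.grid(rep(list(0:1), m * K)))
    prob_j <- 0
    for (r in seq_len(nrow(grid))) {
      o <- matrix(grid[r, ], m, K)
      pr <- prod(ifelse(o == 1, p, 1 - p))
      occupied <- sum(colSums(o) > 0)
      if (occupied == y) prob_j <- prob_j + pr
    }
    ll <- ll + log(prob_j)
  }
  ll
}

# enumerated posterior over latent inclusion vectors given everything else
# fixed; returns the marginal pmf of realized N = sum(z)
enum_N_posterior <- function(bundle, state, variant, n_obs,
                             priors = fit_config()$priors) {
  M <- length(state$z)
  latent <- setdiff(seq_len(M), seq_len(n_obs))
  combos <- as.matrix(expand.grid(rep(list(0:1), length(latent))))
  logw <- apply(combos, 1, function(zl) {
    st <- state
    st$z[latent] <- as.integer(zl)
    joint_log_posterior(st, bundle, variant, priors)
  })
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  N <- n_obs + rowSums(combos)
  tapply(w, factor(N, levels = 0:M), sum, default = 0)
}

# deterministic small integrated bundle for io / structural tests
small_bundle <- function(seed = 42) {
  cfg <- scenario_config(seed = seed)
  simulate_scenario(cfg)
}

# fabricate a scrim_fit from a draws matrix (for summary/gof plumbing tests)
fake_fit <- function(chains, area = 100, n_obs = 0) {
  structure(list(chains = chains, acceptance = NULL, config = NULL,
                 area = area, n_obs = n_obs, n_pin = n_obs),
            class = "scrim_fit")
}
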