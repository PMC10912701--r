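# Shared fixtures: small grids and configs keep unit tests fast; the
# default-sized objects are exercised in the acceptance suite.

tiny_grid <- function() {
  param_grid(theta_ms = seq(250, 600, by = 25),
             slope = c(0.01, 0.02, 0.04),
             lapse = c(0, 0.1, 0.2),
             anticipation = c(0, 0.1, 0.2))
}

# coarse grid for brute-force oracle comparisons
coarse_grid <- function() {
  param_grid(theta_ms = c(350, 430, 510), slope = c(0.01, 0.03),
             lapse = c(0.05, 0.15), anticipation = c(0.05, 0.15))
}

small_campaign_config <- function(seed = 1, ...) {
  campaign_config(n_players = 2, n_baseline_sessions = 2,
                  n_training_sessions = 2, kicks_per_session = 10,
                  n_redirect_per_session = 6, seed = seed,
                  engine = list(grid = tiny_grid(),
                                candidate_tau_ms = seq(260, 590, by = 15)),
                  ...)
}

# the engine prior used by recovery simulations: population threshold prior
# plus weakly informative nuisance priors (the campaign default)
study_prior <- function(grid = param_grid()) {
  init_posterior(grid, prior = "normal", slope_meanlog = log(0.02),
                 lapse_shape = c(2, 18), anticipation_shape = c(2, 18))
}

# run one engine-driven estimation block against a simulated static player
recover_threshold <- function(seed, truth, n_kicks = 40, grid = param_grid(),
                              policy = "entropy") {
  set.seed(seed)
  post <- study_prior(grid)
  n_red <- round(0.6 * n_kicks)
  types <- sample(c(rep("redirect", n_red),
                    rep("no_redirect", n_kicks - n_red)))
  for (type in types) {
    tau <- select_next_tau(post, policy = policy)
    out <- simulate_kick(truth, trial_type = type, tau_ms = tau)
    post <- update_posterior(post, trial_evidence(type, tau,
                                                  out$anticipated,
                                                  out$success))
  }
  threshold_estimate(post)$estimate_ms
}
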