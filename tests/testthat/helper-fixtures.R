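# Shared fixtures, all generated in code.

# A degenerate or custom pmf on an arbitrary support (for oracle tests).
make_pmf <- function(support, mass, condition = "custom") {
  structure(list(condition = condition, support = support, mass = mass),
            class = "condition_pmf")
}

# Small deterministic trial table with hand-set stimuli and responses.
make_trials <- function(p, response, participant_id = "P01",
                        condition = "U") {
  data.frame(participant_id = participant_id, condition = condition,
             block = as.integer((seq_along(p) - 1) %/% 99 + 1),
             trial_index = seq_along(p),
             n_dots = 400L, p = p, response = response,
             stringsAsFactors = FALSE)
}

# One simulated participant under a named family with shared default
# generating values (used across the model tests).
sim_participant <- function(model, seed, n_trials = 693, condition = "U",
                            beta0 = 0.8, beta_lags = 0.05, betaC = 0,
                            kappa = 0.05, omega = 2, sigma_noise = 0.3) {
  prm <- observer_params(model, beta0 = beta0, beta_lags = beta_lags,
                         betaC = betaC, kappa = kappa, omega = omega,
                         sigma_noise = sigma_noise)
  design <- experiment_design(n_trials = n_trials,
                              n_blocks = n_trials %/% 99,
                              block_size = 99)
  stim <- generate_stimulus_sequence(condition_pmf(condition), design,
                                     seed = seed)
  simulate_observer(prm, stim, seed = seed + 1, condition = condition)
}
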