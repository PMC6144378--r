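test_that("stimulus sequences are reproducible and respect the design", {
  pmf <- condition_pmf("U")
  des <- experiment_design()
  s1 <- generate_stimulus_sequence(pmf, des, seed = 7)
  s2 <- generate_stimulus_sequence(pmf, des, seed = 7)
  expect_identical(s1, s2)
  expect_length(s1, 693)
  expect_true(all(s1 %in% pmf$support))
  expect_false(identical(s1, generate_stimulus_sequence(pmf, des, seed = 8)))
  # point-mass pmf gives a constant sequence in both modes
  pt <- make_pmf(0.42, 1)
  expect_equal(generate_stimulus_sequence(pt, des, 1, "iid"), rep(0.42, 693))
  expect_equal(generate_stimulus_sequence(pt, des, 1, "block-balanced"),
               rep(0.42, 693))
  # block-balanced blocks track theta to within multinomial sampling error
  sb <- generate_stimulus_sequence(condition_pmf("S"), des, seed = 3,
                                   mode = "block-balanced")
  blocks <- split(sb, rep(1:7, each = 99))
  frac_small <- vapply(blocks, function(b) mean(b <= 0.10), numeric(1))
  # Binomial(99, 50/99) fraction: sd ~ 0.05; all blocks within 4 sd
  expect_true(all(abs(frac_small - 50 / 99) < 0.2))
})

test_that("iid sequences reproduce the enumerated adjacent-trial distance", {
  pmf <- condition_pmf("U")
  des <- experiment_design()
  d_obs <- mean(vapply(1:16, function(i) {
    S <- log_odds(generate_stimulus_sequence(pmf, des, seed = 100 + i,
                                             mode = "iid"))
    mean(abs(diff(S)))
  }, numeric(1)))
  expect_equal(d_obs, expected_adjacent_distance(pmf), tolerance = 0.05 / 1.9)
})

test_that("noiseless observers reduce to their defining maps", {
  stim <- c(0.2, 0.5, 0.8, 0.05, 0.95)
  # identity observer
  id <- observer_params("LLO", beta0 = 1, betaC = 0, sigma_noise = 0)
  expect_equal(simulate_observer(id, stim, seed = 1)$response, stim)
  # LLO with sigma = 0 is exactly affine in log-odds
  prm <- observer_params("LLO", beta0 = 0.7, betaC = 0.3, sigma_noise = 0)
  tab <- simulate_observer(prm, stim, seed = 1)
  expect_equal(log_odds(tab$response), 0.7 * log_odds(stim) + 0.3,
               tolerance = 1e-12)
  # AL with kappa = 0 collapses onto LLO with the same coefficients
  al0 <- observer_params("AL", beta0 = 0.7, betaC = 0.3, kappa = 0,
                         sigma_noise = 0)
  expect_equal(simulate_observer(al0, stim, seed = 1)$response, tab$response)
  # AL-NL sequential term vanishes when the previous response equals the
  # current stimulus: constant stimuli + identity backbone stay identity
  nl <- observer_params("AL-NL", beta0 = 1, beta_lags = 0.3, betaC = 0,
                        kappa = 0, omega = 1, sigma_noise = 0)
  expect_equal(simulate_observer(nl, rep(0.3, 20), seed = 1)$response,
               rep(0.3, 20))
})

test_that("simulation is deterministic and mirror-symmetric", {
  prm <- observer_params("AL-NL", beta0 = 0.8, beta_lags = 0.05, betaC = 0.1,
                         kappa = 0.1, omega = 2, sigma_noise = 0.3)
  stim <- generate_stimulus_sequence(condition_pmf("S"),
                                     experiment_design(), seed = 5)
  t1 <- simulate_observer(prm, stim, seed = 6)
  t2 <- simulate_observer(prm, stim, seed = 6)
  expect_identical(t1, t2)
  # mirroring stimuli and negating the intercept mirrors the responses
  prm0 <- observer_params("AL-NL", beta0 = 0.8, beta_lags = 0.05,
                          betaC = 0.1, kappa = 0.1, omega = 2,
                          sigma_noise = 0)
  prm_m <- observer_params("AL-NL", beta0 = 0.8, beta_lags = 0.05,
                           betaC = -0.1, kappa = 0.1, omega = 2,
                           sigma_noise = 0)
  r <- simulate_observer(prm0, stim, seed = 1)$response
  r_m <- simulate_observer(prm_m, 1 - stim, seed = 1)$response
  expect_equal(r_m, 1 - r, tolerance = 1e-10)
})

test_that("the adaptation level tracks the stimulus mean", {
  pmf <- condition_pmf("S")
  target <- sum(pmf$mass * log_odds(pmf$support))
  des <- experiment_design(n_trials = 4950, n_blocks = 50, block_size = 99)
  S <- log_odds(generate_stimulus_sequence(pmf, des, seed = 11, mode = "iid"))
  L <- adaptation_levels(S, kappa = 0.05)
  late <- L[2000:4950]
  expect_lt(abs(mean(late) - target), 0.15)
  # kappa = 0 keeps the initial level
  expect_equal(adaptation_levels(S, 0, L_init = 0.3), rep(0.3, length(S)))
})

test_that("cohort simulation produces the full bookkeeping", {
  prm <- observer_params("LLO", beta0 = 0.8, betaC = 0, sigma_noise = 0.3)
  des <- experiment_design(n_participants = 3)
  tab <- simulate_cohort("U", prm, des, seed = 21)
  expect_equal(nrow(tab), 3 * 693)
  expect_equal(length(unique(tab$participant_id)), 3)
  expect_equal(unique(tab$condition), "U")
  expect_identical(tab, simulate_cohort("U", prm, des, seed = 21))
  expect_silent(validate_trials(tab))
  # identical parameters but sigma 0: all participants differ only via stimuli
  prm0 <- observer_params("LLO", beta0 = 0.8, betaC = 0, sigma_noise = 0)
  t0 <- simulate_cohort("U", prm0, experiment_design(n_participants = 2),
                        seed = 4)
  parts <- split(t0, t0$participant_id)
  same_stim <- parts[[1]]$p == parts[[2]]$p
  expect_equal(parts[[1]]$response[same_stim], parts[[2]]$response[same_stim])
})

test_that("pooled LLO fit recovers the generating slope from a cohort", {
  prm <- observer_params("LLO", beta0 = 0.8, betaC = 0, sigma_noise = 0.3)
  tab <- simulate_cohort("U", prm, experiment_design(n_participants = 16),
                         seed = 31)
  fit <- fit_llo(tab)
  expect_equal(fit$gamma, 0.8, tolerance = 0.05 / 0.8)
})

test_that("trial tables round-trip through CSV", {
  prm <- observer_params("AL", beta0 = 0.9, betaC = 0.05, kappa = 0.2,
                         sigma_noise = 0.2)
  tab <- simulate_cohort("E", prm, experiment_design(n_participants = 2),
                         seed = 41)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(tab, path)
  back <- read_trial_csv(path)
  expect_equal(back$p, tab$p, tolerance = 1e-6)
  expect_equal(back$response, tab$response, tolerance = 1e-6)
  expect_identical(back$participant_id, tab$participant_id)
  expect_identical(back$trial_index, tab$trial_index)
  # reader rejects malformed tables
  bad <- tab
  bad$trial_index[2] <- 99L
  expect_error(validate_trials(bad), "dense")
})
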