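test_that("sequential OLS agrees with the normal-equations oracle", {
  withr::with_seed(23, {
    p <- sample(p_support(), 50, replace = TRUE)
    r <- clamp_response(logistic(0.8 * log_odds(p) + rnorm(50, 0, 0.3)))
  })
  tab <- make_trials(p, r)
  fit <- fit_sequential_ols(tab, m = 1)
  S <- log_odds(p); R <- log_odds(r)
  X <- cbind(S[2:50], R[1:49], 1)
  Y <- R[2:50]
  beta <- solve(t(X) %*% X, t(X) %*% Y)
  expect_lt(abs(fit$beta0 - beta[1]), 1e-10)
  expect_lt(abs(fit$beta_lags[1] - beta[2]), 1e-10)
  expect_lt(abs(fit$betaC - beta[3]), 1e-10)
})

test_that("identity responses with shuffled stimuli yield beta0 = 1, no lag", {
  withr::with_seed(31, p <- sample(p_support(), 200, replace = TRUE))
  tab <- make_trials(p, p)
  fit <- fit_sequential_ols(tab, m = 1)
  expect_equal(fit$beta0, 1, tolerance = 1e-10)
  expect_lt(abs(fit$beta_lags[1]), 1e-10)
  expect_lt(abs(fit$betaC), 1e-10)
  # collinear design rejected with a diagnostic
  expect_error(fit_sequential_ols(make_trials(rep(0.5, 40), rep(0.5, 40))),
               "collinear")
})

test_that("white-noise responses show no spurious sequential effect", {
  withr::with_seed(37, {
    p <- sample(p_support(), 600, replace = TRUE)
    r <- clamp_response(logistic(rnorm(600, 0, 1)))
  })
  fit <- fit_sequential_ols(make_trials(p, r), m = 1)
  expect_lt(abs(fit$beta_lags[1]), 3 * fit$se[["Rlag1"]])
})

test_that("a known linear sequential effect is recovered", {
  prm <- observer_params("LLO-L", beta0 = 0.8, beta_lags = 0.05, betaC = 0,
                         sigma_noise = 0.3)
  for (seed in 1:4) {
    stim <- generate_stimulus_sequence(condition_pmf("U"),
                                       experiment_design(), seed = seed)
    tab <- simulate_observer(prm, stim, seed = seed + 10)
    fit <- fit_sequential_ols(tab, m = 1)
    expect_equal(fit$beta_lags[1], 0.05, tolerance = 0.02 / 0.05)
  }
})

test_that("the WLS map cell agrees with the explicit weighted oracle", {
  withr::with_seed(41, {
    p <- sample(p_support(), 60, replace = TRUE)
    r <- clamp_response(logistic(0.8 * log_odds(p) + rnorm(60, 0, 0.3)))
  })
  tab <- make_trials(p, r)
  map <- wls_beta_map(tab, sigma_k = 0.1, grid_n = 3, min_ess = 0)
  # oracle at the centre cell (p_n = p_{n-1} = 0.5): kernel weights squared
  # on the diagonal of W, coefficients (X'WX)^{-1} X'WY
  S <- log_odds(p); R <- log_odds(r)
  X <- cbind(S[2:60], R[1:59], 1)
  Y <- R[2:60]
  w <- exp(-((p[2:60] - 0.5)^2 + (p[1:59] - 0.5)^2) / (2 * 0.1^2))
  W <- diag(w^2)
  beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% Y)
  expect_lt(abs(map$beta_map[2, 2] - beta[2]), 1e-10)
})

test_that("an enormous kernel span recovers the global OLS coefficient", {
  withr::with_seed(43, {
    p <- sample(p_support(), 300, replace = TRUE)
    r <- clamp_response(logistic(0.8 * log_odds(p) + rnorm(300, 0, 0.3)))
  })
  tab <- make_trials(p, r)
  global <- fit_sequential_ols(tab, m = 1)$beta_lags[1]
  map <- wls_beta_map(tab, sigma_k = 1e3, grid_n = 5)
  expect_lt(max(abs(map$beta_map - global)), 1e-6)
})

test_that("DoG-generated cohorts produce a diagonal ridge", {
  prm <- observer_params("AL-NL", beta0 = 0.8, beta_lags = 0.05, betaC = 0,
                         kappa = 0.05, omega = 2, sigma_noise = 0.3)
  tab <- simulate_cohort("U", prm, experiment_design(n_participants = 8),
                         seed = 53)
  map <- wls_beta_map(tab)
  d <- abs(outer(map$grid_pn, map$grid_pprev, "-"))
  ok <- is.finite(map$beta_map)
  near <- mean(map$beta_map[d <= 0.05 & ok])
  far <- mean(map$beta_map[d > 0.4 & ok])
  expect_gt(near, far)
  # attraction decays with inter-trial distance across the whole map
  expect_lt(cor(d[ok], map$beta_map[ok]), -0.3)
  # mirror symmetry of the estimator for mirror-symmetric generators:
  # mirroring the data mirrors the map
  mir <- tab
  mir$p <- 1 - tab$p
  mir$response <- 1 - tab$response
  map_m <- wls_beta_map(mir)
  expect_equal(map_m$beta_map[25:1, 25:1], map$beta_map, tolerance = 1e-8)
})

test_that("model-predicted maps separate linear from non-linear generators", {
  stim <- lapply(1:4, function(i) {
    generate_stimulus_sequence(condition_pmf("U"), experiment_design(),
                               seed = 60 + i)
  })
  # no sequential effect: map flat at zero up to Monte-Carlo error
  none <- observer_params("LLO", beta0 = 0.8, betaC = 0, sigma_noise = 0.3)
  map0 <- predicted_beta_map(none, stim, n_sim = 10, seed = 1)
  expect_lt(mean(abs(map0$beta_map), na.rm = TRUE), 0.03)
  expect_lt(max(abs(map0$beta_map), na.rm = TRUE), 0.12)
  # linear generator: flat map at the generating coefficient
  lin <- observer_params("LLO-L", beta0 = 0.8, beta_lags = 0.05, betaC = 0,
                         sigma_noise = 0.3)
  mapL <- predicted_beta_map(lin, stim, n_sim = 5, seed = 2)
  expect_lt(sd(mapL$beta_map, na.rm = TRUE), 0.03)
  # DoG generator: ridge whose reach grows with omega
  mk <- function(omega, seed) {
    prm <- observer_params("AL-NL", beta0 = 0.8, beta_lags = 0.05,
                           betaC = 0, kappa = 0, omega = omega,
                           sigma_noise = 0.3)
    predicted_beta_map(prm, stim, n_sim = 5, seed = seed)
  }
  ridge_reach <- function(map) {
    d <- abs(outer(map$grid_pn, map$grid_pprev, "-"))
    ok <- is.finite(map$beta_map)
    mid <- mean(map$beta_map[d > 0.2 & d <= 0.4 & ok])
    near <- mean(map$beta_map[d <= 0.05 & ok])
    mid / near
  }
  expect_gt(ridge_reach(mk(4, 3)), ridge_reach(mk(1, 4)))
})

test_that("map correlation behaves as Pearson r with pairwise deletion", {
  withr::with_seed(71, vals <- matrix(rnorm(25), 5, 5))
  mk_map <- function(m) {
    structure(list(grid_pn = seq(0.01, 0.99, length.out = 5),
                   grid_pprev = seq(0.01, 0.99, length.out = 5),
                   beta_map = m, sigma_k = 0.1, n_maps = 1),
              class = "seq_effect_map")
  }
  a <- mk_map(vals)
  expect_equal(map_correlation(a, a), 1)
  expect_equal(map_correlation(a, mk_map(-vals)), -1)
  holey <- vals
  holey[1:3, 1] <- NA
  expect_equal(map_correlation(a, mk_map(holey)), 1)
  few <- matrix(NA_real_, 5, 5)
  few[1, 1:2] <- 1
  expect_error(map_correlation(a, mk_map(few)), "fewer than 3")
  b <- mk_map(vals)
  b$grid_pn <- b$grid_pn + 0.1
  expect_error(map_correlation(a, b), "different grids")
})
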