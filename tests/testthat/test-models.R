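test_that("family definitions carry the right parameter counts", {
  k <- vapply(model_family_names(), function(f) model_family(f)$k, integer(1))
  expect_equal(unname(k), c(3L, 4L, 4L, 5L, 5L, 6L))
  expect_equal(model_family("AL-NL")$param_names,
               c("beta0", "beta_m1", "betaC", "kappa", "omega", "sigma"))
})

test_that("the likelihood matches a per-trial hand-rolled oracle", {
  tab <- sim_participant("AL-NL", seed = 3, n_trials = 99)[1:20, ]
  theta <- c(beta0 = 0.75, beta_m1 = 0.04, betaC = 0.1, kappa = 0.1,
             omega = 1.5, sigma = 0.35)
  nll <- negloglik("AL-NL", theta, tab)
  # oracle: explicit loop over trials
  S <- log_odds(tab$p)
  R <- log_odds(clamp_response(tab$response))
  L <- numeric(20); L[1] <- 0
  for (n in 2:20) L[n] <- L[n - 1] + 0.1 * (S[n - 1] - L[n - 1])
  oracle <- 0
  for (n in 6:20) {
    d <- R[n - 1] - S[n]
    mu <- 0.75 * (S[n] - L[n]) + 0.04 * d * exp(-d^2 / (2 * 1.5^2)) + 0.1
    oracle <- oracle - dnorm(R[n], mu, 0.35, log = TRUE)
  }
  expect_lt(abs(nll - oracle), 1e-10)
  expect_error(negloglik("AL-NL", replace(theta, 6, -1), tab), "sigma")
})

test_that("likelihood self-consistency on noiseless data", {
  prm <- observer_params("AL", beta0 = 0.8, betaC = 0.1, kappa = 0.2,
                         sigma_noise = 0)
  stim <- generate_stimulus_sequence(condition_pmf("U"),
                                     experiment_design(99, 1, 99), seed = 5)
  tab <- simulate_observer(prm, stim, seed = 6)
  nll <- negloglik("AL", c(beta0 = 0.8, betaC = 0.1, kappa = 0.2,
                           sigma = 0.1), tab)
  # residuals are exactly zero: nll equals the sum of log-density maxima
  expect_equal(nll, -94 * dnorm(0, 0, 0.1, log = TRUE), tolerance = 1e-8)
  # shifting all R and betaC by the same constant leaves residuals unchanged
  tab2 <- tab
  tab2$response <- logistic(log_odds(tab$response) + 0.3)
  nll2 <- negloglik("AL", c(beta0 = 0.8, betaC = 0.4, kappa = 0.2,
                            sigma = 0.1), tab2)
  expect_equal(nll2, nll, tolerance = 1e-8)
})

test_that("AICc follows the printed small-sample formula", {
  expect_equal(aicc(-50, 2, 100), 104 + 4 / 97, tolerance = 1e-12)
  # monotone in the likelihood
  expect_lt(aicc(-49, 2, 100), aicc(-50, 2, 100))
  # k = 1 has no correction: reduces to AIC
  expect_equal(aicc(-10, 1, 30), 22)
  # conventional correction available behind the switch
  expect_equal(aicc(-50, 2, 100, correction = "2k(k+1)"), 104 + 12 / 97,
               tolerance = 1e-12)
  expect_error(aicc(-10, 5, 6), "exceed")
})

test_that("fitting recovers generating parameters and nests properly", {
  tab <- sim_participant("AL-NL", seed = 11)
  fit <- fit_model("AL-NL", tab, seed = 2)
  expect_true(fit$converged)
  est <- fit$estimates
  expect_equal(unname(est["beta0"]), 0.8, tolerance = 0.1)
  expect_equal(unname(est["sigma"]), 0.3, tolerance = 0.1)
  expect_equal(unname(est["beta_m1"]), 0.05, tolerance = 0.6)
  # nesting: the superset family never fits worse
  ll <- vapply(model_family_names(), function(f) {
    fit_model(f, tab, seed = 2)$loglik
  }, numeric(1))
  expect_gte(ll[["AL"]] + 1e-6, ll[["LLO"]])
  expect_gte(ll[["LLO-L"]] + 1e-6, ll[["LLO"]])
  expect_gte(ll[["AL-L"]] + 1e-6, ll[["LLO-L"]])
  expect_gte(ll[["AL-NL"]] + 1e-6, ll[["LLO-NL"]])
  # kappa recovered near zero when the generator has a constant level
  tab0 <- sim_participant("AL-NL", seed = 12, kappa = 0)
  fit0 <- fit_model("AL-NL", tab0, seed = 2)
  expect_lt(unname(fit0$estimates["kappa"]), 0.05)
})

test_that("the DoG family approaches the linear family as omega grows", {
  tab <- sim_participant("LLO-L", seed = 21)
  ll_L <- fit_model("LLO-L", tab, seed = 3)$loglik
  ll_NL <- fit_model("LLO-NL", tab, seed = 3)$loglik
  expect_gte(ll_NL, ll_L - 2)
})

test_that("profile and full optimization routes agree", {
  tab <- sim_participant("AL-NL", seed = 31)
  prof <- fit_model("AL-NL", tab, seed = 4, method = "profile")
  full <- fit_model("AL-NL", tab, n_restarts = 40, seed = 4, method = "full")
  # profiling solves the linear block exactly, so it can only do better
  expect_gte(prof$loglik, full$loglik - 0.1)
  expect_equal(unname(prof$estimates["beta0"]),
               unname(full$estimates["beta0"]), tolerance = 0.05)
  expect_equal(unname(prof$estimates["sigma"]),
               unname(full$estimates["sigma"]), tolerance = 0.02)
})

test_that("model comparison aggregates AICc across participants", {
  tabs <- lapply(1:3, function(i) sim_participant("AL-NL", seed = 40 + i))
  fits <- lapply(tabs, function(tt) {
    lapply(c("LLO", "AL-NL"), function(f) fit_model(f, tt, seed = 5))
  })
  cmp <- compare_models(fits)
  expect_equal(cmp$family[1], "AL-NL")
  mat <- attr(cmp, "per_participant")
  expect_lt(max(abs(colSums(mat)[cmp$family] - cmp$sum_aicc)), 1e-9)
  expect_equal(sum(cmp$n_best), 3)
  # a single family is trivially best
  cmp1 <- compare_models(lapply(fits, function(f) f[2]))
  expect_equal(cmp1$family, "AL-NL")
  expect_equal(cmp1$delta_aicc, 0)
})

test_that("protected exceedance probabilities behave at the limits", {
  # identical evidence: symmetric 1/K
  le <- matrix(0, 6, 3)
  r <- protected_exceedance_probability(le)
  expect_equal(unname(r$pxp), rep(1 / 3, 3), tolerance = 1e-9)
  expect_equal(sum(r$pxp), 1, tolerance = 1e-9)
  # overwhelming dominance: probability concentrates on the winner
  le2 <- cbind(0, -50, -50)[rep(1, 8), ]
  r2 <- protected_exceedance_probability(le2)
  expect_gt(r2$pxp[1], 0.95)
  expect_equal(sum(r2$pxp), 1, tolerance = 1e-9)
  expect_lt(r2$bor, 0.05)
  expect_true(all(r$pxp >= 0 & r$pxp <= 1))
  expect_error(protected_exceedance_probability(matrix(0, 1, 3)), ">= 2")
  expect_error(protected_exceedance_probability(matrix(c(0, NA, 0, 0), 2, 2)),
               "finite")
})

test_that("exceedance probabilities match a Dirichlet sampling oracle", {
  withr::with_seed(91, le <- matrix(rnorm(12, sd = 2), 4, 3))
  r <- protected_exceedance_probability(le)
  # oracle: draw from Dirichlet(alpha) via independent gammas and count the
  # argmax frequencies
  withr::with_seed(92, {
    g <- sapply(r$alpha, function(a) stats::rgamma(2e5, a, 1))
    ep_mc <- tabulate(apply(g, 1, which.max), 3) / 2e5
  })
  expect_lt(max(abs(r$ep - ep_mc)), 0.02)
})
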