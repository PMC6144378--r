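#' Adaptation-level theory prediction
#'
#' Predicted subjective relative-frequency under adaptation-level theory: the
#' LLO transform applied to the stimulus *relative to an adaptation level L*,
#' \deqn{\lambda[\pi(p)] = \gamma(\lambda[p] - \lambda[L]) + (1-\gamma)\lambda[p_0],}
#' where the adaptation level follows the central tendency of the stimulus
#' distribution, \eqn{\lambda[L] = \eta \sum_p \theta(p) \lambda[p]} (exact
#' enumeration over the 99-value support). Because L depends only on the
#' distribution's central tendency, the theory predicts a contrast effect:
#' overall overestimation when small p dominate (Small condition), overall
#' underestimation when large p dominate (Large), and no difference between
#' the Uniform and Extreme conditions.
#'
#' @param pmf a `condition_pmf` (the stimulus distribution).
#' @param gamma LLO slope (> 0).
#' @param p0 crossover point in (0, 1).
#' @param eta adaptation-level gain.
#' @param p_grid probabilities at which to evaluate the curve (default the
#'   99-value support).
#' @return `data.frame` with columns `p` and `pi_p`.
#' @examples
#' crv <- al_theory_curve(condition_pmf("S"))
#' head(crv)
#' @export
al_theory_curve <- function(pmf, gamma = 0.8, p0 = 0.5, eta = 0.2,
                            p_grid = p_support()) {
  stopifnot(inherits(pmf, "condition_pmf"), gamma > 0, p0 > 0, p0 < 1)
  lam_L <- eta * sum(pmf$mass * log_odds(pmf$support))
  pi_p <- logistic(gamma * (log_odds(p_grid) - lam_L) +
                     (1 - gamma) * log_odds(p0))
  data.frame(p = p_grid, pi_p = pi_p)
}

#' Bayesian (posterior-mean) observer prediction
#'
#' Predicted subjective relative-frequency for an observer who perceives the
#' stimulus through Gaussian noise on the log-odds scale,
#' \eqn{\Pr(\lambda[y] \mid p) \propto \exp(-(\lambda[y]-\lambda[p])^2 / 2\sigma^2)},
#' holds the condition's true stimulus distribution \eqn{\theta} as prior, and
#' reports the posterior mean (Bayes least squares) estimate
#' \eqn{\pi_y = \sum_q q \Pr(q \mid y)}. The percept is marginalized out by
#' quadrature on the log-odds scale:
#' \eqn{\pi(p) = \int \pi_y \Pr(y \mid p)\, dy}. This observer is attracted
#' toward the concentrated regions of \eqn{\theta}, the opposite context
#' effect to adaptation-level theory.
#'
#' @param pmf a `condition_pmf` (prior over the 99-value support).
#' @param sigma_noise percept noise SD in log-odds (> 0).
#' @param p_grid probabilities at which to evaluate the curve.
#' @param y_bounds bounds of the percept grid on the log-odds scale; must
#'   retain at least 1 - 1e-6 of percept mass for every `p_grid` value.
#' @param n_y number of (trapezoidal) quadrature points.
#' @return `data.frame` with columns `p` and `pi_p`.
#' @export
bayes_bls_curve <- function(pmf, sigma_noise = 1, p_grid = p_support(),
                            y_bounds = c(-10, 10), n_y = 1401) {
  stopifnot(inherits(pmf, "condition_pmf"), sigma_noise > 0, n_y >= 50,
            length(y_bounds) == 2, y_bounds[1] < y_bounds[2])
  lam_p <- log_odds(p_grid)
  miss <- stats::pnorm(y_bounds[1], lam_p, sigma_noise) +
    stats::pnorm(y_bounds[2], lam_p, sigma_noise, lower.tail = FALSE)
  if (any(miss > 1e-6)) {
    stop("percept grid too narrow: it must hold >= 1 - 1e-6 of the percept ",
         "mass for every p; widen `y_bounds`.", call. = FALSE)
  }
  lam_y <- seq(y_bounds[1], y_bounds[2], length.out = n_y)
  lam_q <- log_odds(pmf$support)
  # posterior over the support for each percept value, normalized per column
  # in log space (robust to underflow at small sigma)
  loglik_qy <- -outer(lam_q, lam_y, "-")^2 / (2 * sigma_noise^2) +
    log(pmf$mass)
  lik_qy <- exp(sweep(loglik_qy, 2, apply(loglik_qy, 2, max)))
  post <- sweep(lik_qy, 2, colSums(lik_qy), "/")
  pi_y <- colSums(post * pmf$support)        # BLS estimate per percept
  # trapezoidal weights on the percept grid
  dy <- diff(lam_y)
  w <- c(dy[1] / 2, (dy[-1] + dy[-length(dy)]) / 2, dy[length(dy)] / 2)
  logdens <- -outer(lam_y, lam_p, "-")^2 / (2 * sigma_noise^2)
  dens <- exp(sweep(logdens, 2, apply(logdens, 2, max)))
  wdens <- dens * w
  pi_p <- colSums(wdens * pi_y) / colSums(wdens)
  data.frame(p = p_grid, pi_p = pi_p)
}
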