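#' Fit the linear-in-log-odds (LLO) distortion model
#'
#' Least-squares fit of `R = log_odds(response)` on `S = log_odds(p)` for one
#' participant (equivalent to the Gaussian MLE, since the models' noise is
#' Gaussian in log-odds). The slope is the distortion parameter `gamma`
#' (gamma < 1: inverted-S distortion) and the intercept `c` maps to the
#' crossover point `p0 = logistic(c / (1 - gamma))` — the probability at
#' which subjective equals objective relative-frequency. `p0` is reported as
#' `NA` when `|1 - gamma| < 1e-6` (no crossover for an identity slope).
#'
#' @param trials a trial table for a single participant (or any data.frame
#'   with `p` and `response` columns); at least 10 trials spanning at least 3
#'   distinct p values.
#' @return an object of class `llo_fit` with elements `gamma`, `p0`,
#'   `intercept`, `residual_sd`, `n_trials`.
#' @examples
#' prm <- observer_params("LLO", beta0 = 0.8,
#'                        betaC = (1 - 0.8) * log_odds(0.5), sigma_noise = 0)
#' tab <- simulate_observer(prm, p_support(), seed = 1)
#' fit_llo(tab)  # recovers gamma = 0.8, p0 = 0.5 exactly
#' @export
fit_llo <- function(trials) {
  S <- log_odds(trials$p)
  R <- log_odds(clamp_response(trials$response))
  if (length(S) < 10 || length(unique(trials$p)) < 3) {
    stop("fit_llo needs >= 10 trials spanning >= 3 distinct p values.",
         call. = FALSE)
  }
  if (stats::var(S) == 0) stop("degenerate design: all stimuli equal.",
                               call. = FALSE)
  fit <- stats::lm.fit(cbind(S = S, intercept = 1), R)
  gamma <- unname(fit$coefficients["S"])
  intercept <- unname(fit$coefficients["intercept"])
  p0 <- if (abs(1 - gamma) < 1e-6) NA_real_ else
    logistic(intercept / (1 - gamma))
  structure(list(gamma = gamma, p0 = p0, intercept = intercept,
                 residual_sd = sqrt(mean(fit$residuals^2)),
                 n_trials = length(S)),
            class = "llo_fit")
}

#' @export
print.llo_fit <- function(x, ...) {
  cat(sprintf("<llo_fit> gamma = %.4f, p0 = %s (n = %d, residual SD %.3f)\n",
              x$gamma, ifelse(is.na(x$p0), "NA", sprintf("%.4f", x$p0)),
              x$n_trials, x$residual_sd))
  invisible(x)
}

#' Kernel-smoothed distortion curve
#'
#' Nadaraya-Watson kernel estimate of the deviation `response - p` as a
#' function of p, with a Gaussian kernel of bandwidth `h` on the probability
#' scale:
#' \deqn{\hat M_h(x) = \frac{\sum_i K((x - p_i)/h)\,(r_i - p_i)}
#'                         {\sum_i K((x - p_i)/h)}.}
#' Evaluated at every grid value (default 0.01, ..., 0.99) over all trials of
#' one participant.
#'
#' @param trials a trial table (one participant).
#' @param h kernel bandwidth in probability units (default 0.03).
#' @param p_grid evaluation grid.
#' @return an object of class `smoothed_curve`: list with `p_grid`, `values`
#'   (smoothed `response - p`), `h`, `n_trials`.
#' @export
smooth_curve <- function(trials, h = 0.03, p_grid = p_support()) {
  stopifnot(h > 0, nrow(trials) >= 1)
  x <- trials$p
  y <- clamp_response(trials$response) - trials$p
  K <- exp(-outer(p_grid, x, "-")^2 / (2 * h^2))  # Gaussian kernel, constant
  values <- as.numeric(K %*% y) / rowSums(K)      # factors cancel in the ratio
  structure(list(p_grid = p_grid, values = values, h = h,
                 n_trials = length(x)),
            class = "smoothed_curve")
}

#' @export
print.smoothed_curve <- function(x, ...) {
  cat(sprintf(
    "<smoothed_curve> %d grid points, h = %g, n = %d, range [%.3f, %.3f]\n",
    length(x$p_grid), x$h, x$n_trials, min(x$values), max(x$values)))
  invisible(x)
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Curvature and elevation of a distortion curve
#'
#' Non-parametric analogues of `gamma` and `p0`: the curvature is the total
#' area between the smoothed `response - p` curve and the zero line
#' (\eqn{\int |f|\,dp}), the elevation the signed area
#' (\eqn{\int f\,dp} — area above zero minus area below). Both use the
#' trapezoidal rule over the grid; units are (probability)^2.
#'
#' @param curve a `smoothed_curve`.
#' @return list with `curvature` (>= 0) and `elevation`
#'   (`|elevation| <= curvature`).
#' @export
curvature_elevation <- function(curve) {
  stopifnot(inherits(curve, "smoothed_curve"))
  list(curvature = trapz(curve$p_grid, abs(curve$values)),
       elevation = trapz(curve$p_grid, curve$values))
}

#' Bootstrap clouds of group-mean distortion measures
#'
#' Resamples participants with replacement and returns the group means of
#' each measure for every resample — the "cloud" visualization of the
#' variability of group means (default 500 resamples of 16 participants).
#'
#' @param metrics a data.frame with one row per participant and numeric
#'   measure columns (e.g. `gamma` and `p0`, or `curvature` and `elevation`).
#' @param n_boot number of resamples.
#' @param seed integer seed.
#' @return a data.frame with `n_boot` rows of resampled group means.
#' @export
bootstrap_cloud <- function(metrics, n_boot = 500, seed = 1) {
  num <- vapply(metrics, is.numeric, logical(1))
  stopifnot(nrow(metrics) >= 2, any(num))
  m <- as.matrix(metrics[, num, drop = FALSE])
  withr::with_seed(seed, {
    out <- t(vapply(seq_len(n_boot), function(b) {
      colMeans(m[sample.int(nrow(m), replace = TRUE), , drop = FALSE])
    }, numeric(ncol(m))))
  })
  as.data.frame(out)
}
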