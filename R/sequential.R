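#' Lagged regression frame
#'
#' Builds, within each participant, the rows usable for an m-lag sequential
#' regression: for trials n > m, the current response and stimulus in
#' log-odds, the m previous responses, and the current and previous stimulus
#' probabilities.
#'
#' @param trials a trial table.
#' @param m number of lags.
#' @return data.frame with columns `participant_id`, `R`, `S`,
#'   `Rlag1..Rlagm`, `p`, `p_lag1`.
#' @keywords internal
lagged_frame <- function(trials, m = 1) {
  trials <- validate_trials(trials)
  parts <- split(trials, trials$participant_id)
  out <- lapply(parts, function(tt) {
    tt <- tt[order(tt$trial_index), ]
    n <- nrow(tt)
    if (n <= m) return(NULL)
    S <- log_odds(tt$p)
    R <- log_odds(clamp_response(tt$response))
    idx <- (m + 1):n
    lags <- vapply(seq_len(m), function(i) R[idx - i], numeric(length(idx)))
    colnames(lags) <- paste0("Rlag", seq_len(m))
    cbind(data.frame(participant_id = tt$participant_id[idx],
                     R = R[idx], S = S[idx],
                     p = tt$p[idx], p_lag1 = tt$p[idx - 1],
                     stringsAsFactors = FALSE),
          as.data.frame(lags))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Linear sequential-effect regression
#'
#' Ordinary least squares of the current response on the current stimulus and
#' the previous m responses (all in log-odds):
#' `R_n = beta0 S_n + sum_i beta_{-i} R_{n-i} + betaC + noise`. A positive
#' lag-1 coefficient indicates attraction toward the previous response.
#' Lags are formed within participants; trials with index <= m are excluded.
#'
#' @param trials a trial table.
#' @param m number of lags (default 1).
#' @return an object of class `seq_fit`: `beta0`, `beta_lags`, `betaC`, `m`,
#'   `n`, plus coefficient standard errors.
#' @export
fit_sequential_ols <- function(trials, m = 1) {
  fr <- lagged_frame(trials, m)
  if (is.null(fr) || nrow(fr) < m + 10) {
    stop("need at least m + 10 usable trials.", call. = FALSE)
  }
  X <- as.matrix(cbind(S = fr$S, fr[paste0("Rlag", seq_len(m))],
                       intercept = 1))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stop("collinear design: rank ", qx$rank, " < ", ncol(X),
         " columns (constant stimuli or responses?).", call. = FALSE)
  }
  fit <- stats::lm.fit(X, fr$R)
  co <- fit$coefficients
  sigma2 <- sum(fit$residuals^2) / (nrow(X) - ncol(X))
  se <- sqrt(diag(chol2inv(qr.R(qx))) * sigma2)
  names(se) <- colnames(X)
  structure(list(beta0 = unname(co["S"]),
                 beta_lags = unname(co[paste0("Rlag", seq_len(m))]),
                 betaC = unname(co["intercept"]),
                 se = se, m = m, n = nrow(X)),
            class = "seq_fit")
}

#' @export
print.seq_fit <- function(x, ...) {
  cat(sprintf("<seq_fit> m = %d, n = %d\n", x$m, x$n))
  cat(sprintf("  beta0 = %.4f, beta_lags = [%s], betaC = %.4f\n",
              x$beta0, paste(sprintf("%.4f", x$beta_lags), collapse = ", "),
              x$betaC))
  invisible(x)
}

# Grid moment matrices for the kernel-weighted local regressions: for every
# z, M_z[i, j] = sum_r A[r, i] * z_r * B[r, j]; with A, B the squared
# per-dimension kernels this gives all entries of X'WX and X'WY for every
# grid cell in a handful of matrix products.
wls_map_single <- function(p, p_lag, S, Rlag, Y, grid_pn, grid_pprev,
                           sigma_k, min_ess) {
  A <- exp(-outer(p, grid_pn, "-")^2 / (sigma_k^2))       # squared kernel
  B <- exp(-outer(p_lag, grid_pprev, "-")^2 / (sigma_k^2))
  Mz <- function(z) crossprod(A, z * B)
  m_ss <- Mz(S * S); m_sr <- Mz(S * Rlag); m_s <- Mz(S)
  m_rr <- Mz(Rlag * Rlag); m_r <- Mz(Rlag); m_1 <- Mz(rep(1, length(S)))
  m_sy <- Mz(S * Y); m_ry <- Mz(Rlag * Y); m_y <- Mz(Y)
  m_1sq <- crossprod(A^2, B^2)                            # sum of v^2
  ess <- m_1^2 / m_1sq
  g1 <- length(grid_pn); g2 <- length(grid_pprev)
  beta <- matrix(NA_real_, g1, g2)
  for (i in seq_len(g1)) {
    for (j in seq_len(g2)) {
      if (!is.finite(ess[i, j]) || ess[i, j] < min_ess) next
      XtWX <- matrix(c(m_ss[i, j], m_sr[i, j], m_s[i, j],
                       m_sr[i, j], m_rr[i, j], m_r[i, j],
                       m_s[i, j],  m_r[i, j],  m_1[i, j]), 3, 3)
      XtWY <- c(m_sy[i, j], m_ry[i, j], m_y[i, j])
      co <- tryCatch(solve(XtWX, XtWY), error = function(e) NULL)
      if (!is.null(co)) beta[i, j] <- co[2]
    }
  }
  beta
}

#' Local (stimulus-dependent) sequential-effect map
#'
#' Estimates the lag-1 coefficient beta_{-1} as a function of the current and
#' previous stimulus, via weighted least squares of `R_j` on
#' `(S_j, R_{j-1}, 1)` centred at each grid cell `(p_n, p_{n-1})`. The weight
#' of trial j is a two-dimensional Gaussian kernel
#' `w_j = exp(-((p_j - p_n)^2 + (p_{j-1} - p_{n-1})^2) / (2 sigma_k^2))`
#' (up to a constant), and the WLS weight matrix carries the *squared*
#' kernel weights `w_j^2` on its diagonal. Cells whose effective sample size
#' (Kish formula on the squared weights) falls below `min_ess` are flagged
#' `NA` rather than extrapolated. With multiple participants the map is
#' estimated per participant and averaged cell-wise.
#'
#' A stimulus-independent (linear) sequential effect implies a flat map; a
#' derivative-of-Gaussian attraction implies a ridge along the diagonal
#' `p_{n-1} = p_n`.
#'
#' @param trials a trial table (>= 30 rows).
#' @param sigma_k kernel span in probability units (default 0.1).
#' @param grid_n number of evenly spaced grid values per axis over
#'   \[0.01, 0.99\] (default 25; 99 reproduces the full support grid).
#' @param min_ess minimum effective sample size per cell.
#' @param by_participant estimate per participant and average (default) or
#'   pool all trials into one regression.
#' @return an object of class `seq_effect_map`: `grid_pn`, `grid_pprev`,
#'   `beta_map` (matrix, rows indexed by `p_n`), `sigma_k`.
#' @export
wls_beta_map <- function(trials, sigma_k = 0.1, grid_n = 25, min_ess = 5,
                         by_participant = TRUE) {
  stopifnot(nrow(trials) >= 30, sigma_k > 0)
  grid_pn <- seq(0.01, 0.99, length.out = grid_n)
  grid_pprev <- grid_pn
  fr <- lagged_frame(trials, m = 1)
  groups <- if (by_participant) split(fr, fr$participant_id) else list(fr)
  maps <- lapply(groups, function(g) {
    wls_map_single(g$p, g$p_lag1, g$S, g$Rlag1, g$R,
                   grid_pn, grid_pprev, sigma_k, min_ess)
  })
  beta_map <- average_maps(maps)
  structure(list(grid_pn = grid_pn, grid_pprev = grid_pprev,
                 beta_map = beta_map, sigma_k = sigma_k,
                 n_maps = length(maps)),
            class = "seq_effect_map")
}

average_maps <- function(maps) {
  arr <- simplify2array(maps)
  if (length(dim(arr)) == 2) return(arr)
  out <- apply(arr, c(1, 2), function(v) {
    v <- v[is.finite(v)]
    if (length(v)) mean(v) else NA_real_
  })
  out
}

#' @export
print.seq_effect_map <- function(x, ...) {
  ok <- is.finite(x$beta_map)
  cat(sprintf(
    "<seq_effect_map> %d x %d grid, sigma_k = %g, %d/%d cells estimable\n",
    length(x$grid_pn), length(x$grid_pprev), x$sigma_k, sum(ok),
    length(ok)))
  if (any(ok)) {
    cat(sprintf("  beta_-1 range [%.4f, %.4f]\n",
                min(x$beta_map[ok]), max(x$beta_map[ok])))
  }
  invisible(x)
}

#' Model-predicted sequential-effect map
#'
#' Simulates responses from a (fitted) generative model on given stimulus
#' sequences `n_sim` times, computes the WLS beta map of each simulation, and
#' averages the maps cell-wise — the model's prediction for the pattern of
#' stimulus-dependent sequential effects.
#'
#' @param params an `observer_params` (typically fitted values).
#' @param stimuli a numeric vector (one sequence) or a list of per-participant
#'   stimulus sequences.
#' @param n_sim number of simulated replicates (default 20).
#' @param seed integer seed.
#' @inheritParams wls_beta_map
#' @return a `seq_effect_map`.
#' @export
predicted_beta_map <- function(params, stimuli, n_sim = 20, seed = 1,
                               sigma_k = 0.1, grid_n = 25, min_ess = 5) {
  if (!is.list(stimuli)) stimuli <- list(stimuli)
  seeds <- withr::with_seed(seed, matrix(
    sample.int(.Machine$integer.max - 1L, n_sim * length(stimuli)),
    nrow = n_sim))
  grid_pn <- seq(0.01, 0.99, length.out = grid_n)
  maps <- vector("list", n_sim * length(stimuli))
  k <- 0
  for (s in seq_len(n_sim)) {
    for (pp in seq_along(stimuli)) {
      tab <- simulate_observer(params, stimuli[[pp]], seed = seeds[s, pp],
                               participant_id = sprintf("sim%02d_%02d", s, pp))
      fr <- lagged_frame(tab, m = 1)
      k <- k + 1
      maps[[k]] <- wls_map_single(fr$p, fr$p_lag1, fr$S, fr$Rlag1, fr$R,
                                  grid_pn, grid_pn, sigma_k, min_ess)
    }
  }
  structure(list(grid_pn = grid_pn, grid_pprev = grid_pn,
                 beta_map = average_maps(maps), sigma_k = sigma_k,
                 n_maps = length(maps)),
            class = "seq_effect_map")
}

#' Correlation between two sequential-effect maps
#'
#' Pearson correlation between two beta maps over their flattened grid cells,
#' with pairwise deletion of cells missing in either map. Used to score how
#' well a model's predicted pattern of sequential effects matches the
#' observed one.
#'
#' @param observed,predicted `seq_effect_map` objects on identical grids.
#' @return Pearson's r (scalar).
#' @export
map_correlation <- function(observed, predicted) {
  stopifnot(inherits(observed, "seq_effect_map"),
            inherits(predicted, "seq_effect_map"))
  if (!isTRUE(all.equal(observed$grid_pn, predicted$grid_pn)) ||
      !isTRUE(all.equal(observed$grid_pprev, predicted$grid_pprev))) {
    stop("maps are on different grids.", call. = FALSE)
  }
  a <- as.vector(observed$beta_map)
  b <- as.vector(predicted$beta_map)
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3) stop("fewer than 3 jointly estimable cells.", call. = FALSE)
  stats::cor(a[ok], b[ok])
}
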