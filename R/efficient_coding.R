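#' KL divergence of responses from the uniform distribution
#'
#' Bins responses into `n_bins` equal-width bins over \[0, 1\] (right-closed
#' last bin) and computes the Kullback-Leibler divergence of the empirical
#' bin frequencies from the uniform distribution,
#' \eqn{\sum_i f_r(i) \log(f_r(i) / f_u(i))} with \eqn{f_u(i) = 1/n_{bins}},
#' natural log (nats); empty bins contribute 0. Under efficient coding the
#' information-maximizing response distribution on a bounded scale is
#' uniform, so smaller values indicate a more efficient response mapping.
#'
#' @param responses numeric vector in \[0, 1\].
#' @param n_bins number of bins (default 10).
#' @return scalar KL divergence in nats (>= 0).
#' @examples
#' kl_to_uniform(rep(0.05, 100))       # everything in one bin: log(10)
#' kl_to_uniform((1:100 - 0.5) / 100)  # exactly uniform: 0
#' @export
kl_to_uniform <- function(responses, n_bins = 10) {
  stopifnot(length(responses) >= 1, all(responses >= 0 & responses <= 1))
  counts <- bin_counts(responses, n_bins)
  kl_counts(counts, n_bins)
}

bin_counts <- function(responses, n_bins) {
  idx <- pmin(floor(responses * n_bins) + 1L, n_bins)  # last bin right-closed
  tabulate(idx, nbins = n_bins)
}

kl_counts <- function(counts, n_bins) {
  f <- counts / sum(counts)
  nz <- f > 0
  sum(f[nz] * log(f[nz] * n_bins))
}

#' U-mapping resampled KL divergences
#'
#' Simulates what the response distribution of a target condition would look
#' like if its stimuli were answered through the Uniform condition's
#' stimulus-to-response mapping: for every target stimulus, a virtual
#' response is drawn uniformly (with replacement) from the observed
#' Uniform-condition responses to the identical stimulus value. The function
#' returns the KL divergence from uniform of each of `n_sim` virtual response
#' sets.
#'
#' Target stimuli without an exact match in the Uniform-condition data fall
#' back to the nearest available stimulus value (distance on the p scale,
#' ties resolved toward 0.5) when `fallback = TRUE`; otherwise they raise an
#' error.
#'
#' Internally the virtual responses are not materialized one by one: since
#' binning is deterministic per response, the bin counts contributed by each
#' stimulus value are drawn as a multinomial over that value's pool bin
#' proportions, which is distributionally identical and feasible at
#' `n_sim = 1e6`.
#'
#' @param target_stimuli numeric vector of stimulus probabilities of the
#'   target condition (one entry per trial).
#' @param uniform_trials trial table of the Uniform condition (reference
#'   mapping).
#' @param n_sim number of simulated response sets (default 10000).
#' @param seed integer seed.
#' @param n_bins number of bins.
#' @param fallback use nearest-stimulus fallback for unmatched stimuli.
#' @return numeric vector of `n_sim` KL divergences (nats).
#' @export
u_mapping_resample <- function(target_stimuli, uniform_trials, n_sim = 10000,
                               seed = 1, n_bins = 10, fallback = TRUE) {
  stopifnot(length(target_stimuli) >= 1, nrow(uniform_trials) >= 1)
  uniform_trials <- validate_trials(uniform_trials)
  pools <- split(uniform_trials$response, uniform_trials$p)
  pool_p <- as.numeric(names(pools))
  tab <- table(target_stimuli)
  targ_p <- as.numeric(names(tab))
  targ_n <- as.integer(tab)
  match_idx <- vapply(targ_p, function(p) {
    d <- abs(pool_p - p)
    hit <- which(d < 1e-9)
    if (length(hit)) return(hit[1])
    if (!fallback) {
      stop("no Uniform-condition responses for stimulus p = ", p,
           " and fallback is disabled.", call. = FALSE)
    }
    cand <- which(d == min(d))
    cand[which.min(abs(pool_p[cand] - 0.5))]  # ties toward 0.5
  }, integer(1))
  # bin proportions of each matched pool
  props <- lapply(match_idx, function(i) {
    ct <- bin_counts(clamp_response(pools[[i]]), n_bins)
    ct / sum(ct)
  })
  withr::with_seed(seed, {
    counts <- matrix(0L, n_bins, n_sim)
    for (u in seq_along(targ_p)) {
      counts <- counts + rmultinom(n_sim, targ_n[u], props[[u]])
    }
  })
  apply(counts, 2, kl_counts, n_bins = n_bins)
}

#' Efficient-coding divergence test
#'
#' Tests whether a condition's stimulus-to-response mapping moves its
#' response distribution toward the information-maximizing uniform
#' distribution, relative to the Uniform condition's mapping. Responses of
#' the target condition are pooled across its participants; the statistic is
#' \deqn{D_{KL}(observed \| uniform) - D_{KL}(U\!-\!mapping \| uniform),}
#' one difference per U-mapping simulation. A negative difference means the
#' condition's own mapping is closer to efficient coding than borrowing the
#' Uniform condition's mapping would be; the Uniform condition itself serves
#' as a sanity check (difference distribution centred near 0).
#'
#' @param observed_trials trial table of the target condition.
#' @param uniform_trials trial table of the Uniform condition.
#' @inheritParams u_mapping_resample
#' @return an object of class `ec_result`: `dkl_observed`, `dkl_umapping`
#'   (vector of simulated KLs), `difference_quantiles` (0.5%, 25%, 50%, 75%,
#'   99.5% of observed minus simulated), `n_sim`, `n_bins`.
#' @export
ec_difference <- function(observed_trials, uniform_trials, n_sim = 10000,
                          seed = 1, n_bins = 10, fallback = TRUE) {
  observed_trials <- validate_trials(observed_trials)
  dkl_obs <- kl_to_uniform(observed_trials$response, n_bins)
  sims <- u_mapping_resample(observed_trials$p, uniform_trials,
                             n_sim = n_sim, seed = seed, n_bins = n_bins,
                             fallback = fallback)
  diffs <- dkl_obs - sims
  q <- quantile(diffs, c(0.005, 0.25, 0.5, 0.75, 0.995), names = FALSE)
  structure(list(dkl_observed = dkl_obs, dkl_umapping = sims,
                 difference_quantiles = setNames(
                   q, c("q0.5%", "q25%", "median", "q75%", "q99.5%")),
                 n_sim = n_sim, n_bins = n_bins),
            class = "ec_result")
}

#' @export
print.ec_result <- function(x, ...) {
  cat(sprintf(
    "<ec_result> D_KL(observed||uniform) = %.4f nats (%d bins, %d sims)\n",
    x$dkl_observed, x$n_bins, x$n_sim))
  cat("  observed - U-mapping difference quantiles:\n")
  print(round(x$difference_quantiles, 4))
  invisible(x)
}
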