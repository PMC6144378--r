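#' Log-odds transform
#'
#' `log_odds()` maps a probability to natural-log odds,
#' \eqn{\lambda(p) = \log(p / (1 - p))}; `logistic()` is its inverse.
#' The log-odds scale is the scale on which linear-in-log-odds (LLO)
#' probability distortion and all six observer models are linear.
#'
#' @param p numeric vector of probabilities, strictly inside (0, 1).
#' @return `log_odds()`: numeric vector of natural-log odds.
#' @seealso [clamp_response()] for mapping boundary responses into (0, 1)
#'   before transforming.
#' @examples
#' log_odds(0.5)            # 0
#' logistic(log_odds(0.07)) # 0.07
#' @export
log_odds <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p <= 0) || any(p >= 1)) {
    stop("`p` must lie strictly inside (0, 1); clamp boundary values first ",
         "(see `clamp_response()`).", call. = FALSE)
  }
  log(p / (1 - p))
}

#' @rdname log_odds
#' @param x numeric vector of finite log-odds values.
#' @return `logistic()`: numeric vector of probabilities in (0, 1).
#' @export
logistic <- function(x) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop("`x` must be finite.", call. = FALSE)
  }
  1 / (1 + exp(-x))
}

#' Clamp responses into the open unit interval
#'
#' The response bar allows reports of exactly 0 and 100%, where log-odds is
#' undefined. Reports below `lower` are set to `lower` and above `upper` to
#' `upper`; the defaults are half of the 0.01 stimulus step inside each
#' boundary.
#'
#' @param p numeric vector of reported probabilities (may touch 0 or 1).
#' @param lower,upper clamping bounds, defaults 0.005 and 0.995.
#' @return numeric vector in `[lower, upper]`.
#' @export
clamp_response <- function(p, lower = 0.005, upper = 0.995) {
  pmin(pmax(p, lower), upper)
}

#' Support grid of the stimulus distributions
#'
#' The 99 admissible relative-frequencies 0.01, 0.02, ..., 0.99, generated as
#' i/100 to avoid accumulation error.
#'
#' @return numeric vector of length 99.
#' @export
p_support <- function() (1:99) / 100

#' Stimulus-distribution conditions
#'
#' Returns the discrete probability mass function \eqn{\theta(p)} over the
#' 99-value support for one of the four distribution conditions:
#' * `"U"` (Uniform): mass 1/99 everywhere;
#' * `"E"` (Extreme): mass 3/99 on each value in \[0.01, 0.10\] and
#'   \[0.90, 0.99\], (39/79)/99 on each middle value;
#' * `"S"` (Small): mass 5/99 on each value in \[0.01, 0.10\] (so 50/99 of
#'   trials show a small p), (49/89)/99 elsewhere;
#' * `"L"` (Large): the mirror image of `"S"`.
#'
#' @param condition one of `"U"`, `"E"`, `"S"`, `"L"`.
#' @return an object of class `condition_pmf`: a list with elements
#'   `condition`, `support` (length 99) and `mass` (sums to 1).
#' @examples
#' pmf <- condition_pmf("S")
#' sum(pmf$mass[pmf$support <= 0.10])  # 50/99
#' @export
condition_pmf <- function(condition = c("U", "E", "S", "L")) {
  condition <- match.arg(condition)
  support <- p_support()
  small <- support <= 0.10 + 1e-12
  large <- support >= 0.90 - 1e-12
  mid_E <- !small & !large
  mass <- switch(condition,
    U = rep(1 / 99, 99),
    E = ifelse(small | large, 3 / 99, (39 / 79) / 99),
    S = ifelse(small, 5 / 99, (49 / 89) / 99),
    L = ifelse(large, 5 / 99, (49 / 89) / 99)
  )
  new_condition_pmf(condition, support, mass)
}

new_condition_pmf <- function(condition, support, mass) {
  stopifnot(length(support) == length(mass))
  if (any(mass < 0)) stop("pmf masses must be non-negative.", call. = FALSE)
  if (abs(sum(mass) - 1) > 1e-12) {
    stop("pmf masses must sum to 1 within 1e-12.", call. = FALSE)
  }
  structure(list(condition = condition, support = support, mass = mass),
            class = "condition_pmf")
}

#' @export
print.condition_pmf <- function(x, ...) {
  cat(sprintf("<condition_pmf> condition %s, %d support values in [%g, %g]\n",
              x$condition, length(x$support), min(x$support), max(x$support)))
  cat(sprintf("  mean p = %.4f, mass on [0.01,0.10] = %.4f, on [0.90,0.99] = %.4f\n",
              sum(x$support * x$mass),
              sum(x$mass[x$support <= 0.10 + 1e-12]),
              sum(x$mass[x$support >= 0.90 - 1e-12])))
  invisible(x)
}

#' Mirror a stimulus distribution
#'
#' Reflects the pmf through p = 0.5 (mass at p moves to 1 - p). The Small and
#' Large conditions are mirrors of each other.
#'
#' @param pmf a `condition_pmf`.
#' @return a `condition_pmf` on the same support.
#' @export
mirror_pmf <- function(pmf) {
  stopifnot(inherits(pmf, "condition_pmf"))
  new_condition_pmf(paste0("mirror(", pmf$condition, ")"),
                    pmf$support, rev(pmf$mass))
}

#' Expected log-odds distance between adjacent trials
#'
#' The expected absolute log-odds difference between two independent draws
#' from a stimulus distribution,
#' \eqn{\sum_i \sum_j \theta(p_i)\,\theta(p_j)\,|\lambda(p_i)-\lambda(p_j)|},
#' computed by exact double enumeration over the support grid. This is the
#' population value of the mean adjacent-trial distance |S_n - S_{n-1}| in an
#' i.i.d. stimulus sequence; it quantifies how dispersed consecutive stimuli
#' are in each condition (largest for Extreme, smallest for Uniform).
#'
#' @param pmf a `condition_pmf`.
#' @return scalar, in log-odds units.
#' @examples
#' expected_adjacent_distance(condition_pmf("U"))  # about 1.91
#' @export
expected_adjacent_distance <- function(pmf) {
  stopifnot(inherits(pmf, "condition_pmf"))
  lo <- log_odds(pmf$support)
  sum(outer(pmf$mass, pmf$mass) * abs(outer(lo, lo, "-")))
}
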