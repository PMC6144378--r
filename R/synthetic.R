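#' Experiment design constants
#'
#' Bundles the design of the relative-frequency judgment experiment: 693
#' trials per participant in 7 blocks of 99, 16 participants per condition,
#' and displays of 200, 300, ..., 800 dots.
#'
#' @param n_trials total trials per participant.
#' @param n_blocks number of blocks.
#' @param block_size trials per block; must satisfy
#'   `n_trials == n_blocks * block_size`.
#' @param n_participants participants per condition.
#' @param dot_totals admissible total dot counts per display.
#' @return an object of class `experiment_design` (a validated list).
#' @export
experiment_design <- function(n_trials = 693, n_blocks = 7, block_size = 99,
                              n_participants = 16,
                              dot_totals = seq(200, 800, by = 100)) {
  if (n_trials != n_blocks * block_size) {
    stop("`n_trials` must equal `n_blocks * block_size`.", call. = FALSE)
  }
  stopifnot(n_trials >= 1, n_participants >= 1, all(dot_totals > 0))
  structure(list(n_trials = as.integer(n_trials),
                 n_blocks = as.integer(n_blocks),
                 block_size = as.integer(block_size),
                 n_participants = as.integer(n_participants),
                 dot_totals = as.integer(dot_totals)),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf(
    "<experiment_design> %d trials (%d blocks x %d), %d participants/condition\n",
    x$n_trials, x$n_blocks, x$block_size, x$n_participants))
  invisible(x)
}

#' Generative observer parameters
#'
#' Parameters of the six response models. All models share the LLO backbone
#' `R_n = beta0 * S_n + betaC + noise` on the log-odds scale; `AL*` variants
#' replace `S_n` by `S_n - L_n` with the adaptation level `L_n` updated by the
#' delta rule `L_n = L_{n-1} + kappa * (S_{n-1} - L_{n-1})`; `*-L` variants add
#' linear previous-response terms `beta_lags[i] * R_{n-i}`; `*-NL` variants
#' add derivative-of-Gaussian terms
#' `beta_lags[i] * (R_{n-i} - S_n) * exp(-(R_{n-i} - S_n)^2 / (2 omega^2))`,
#' an attraction toward the previous response that peaks at inter-trial
#' distance `omega` and vanishes at 0 and at large distances.
#'
#' Parameters irrelevant to the chosen model are carried but ignored.
#'
#' @param model one of `"LLO"`, `"AL"`, `"LLO-L"`, `"LLO-NL"`, `"AL-L"`,
#'   `"AL-NL"`.
#' @param beta0 slope on the (possibly adaptation-referenced) stimulus.
#' @param beta_lags numeric vector of lag coefficients, one per lag
#'   (length `m`).
#' @param betaC intercept, log-odds units.
#' @param kappa delta-rule learning rate in \[0, 1\].
#' @param omega scope-of-influence of the DoG sequential effect (> 0),
#'   log-odds units.
#' @param sigma_noise response noise SD (>= 0; 0 gives a deterministic
#'   observer), log-odds units.
#' @param L_init initial adaptation level, log-odds (0 is a neutral start at
#'   p = 0.5).
#' @return an object of class `observer_params`.
#' @export
observer_params <- function(model = c("LLO", "AL", "LLO-L", "LLO-NL",
                                      "AL-L", "AL-NL"),
                            beta0 = 1, beta_lags = 0.05, betaC = 0,
                            kappa = 0.05, omega = 2, sigma_noise = 0.3,
                            L_init = 0) {
  model <- match.arg(model)
  stopifnot(is.numeric(beta_lags), length(beta_lags) >= 1)
  if (kappa < 0 || kappa > 1) stop("`kappa` must be in [0, 1].", call. = FALSE)
  if (omega <= 0) stop("`omega` must be > 0.", call. = FALSE)
  if (sigma_noise < 0) stop("`sigma_noise` must be >= 0.", call. = FALSE)
  structure(list(model = model, beta0 = beta0, beta_lags = beta_lags,
                 betaC = betaC, kappa = kappa, omega = omega,
                 sigma_noise = sigma_noise, L_init = L_init,
                 m = length(beta_lags)),
            class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf("<observer_params> model %s\n", x$model))
  cat(sprintf("  beta0 = %g, beta_lags = [%s], betaC = %g\n",
              x$beta0, paste(signif(x$beta_lags, 4), collapse = ", "), x$betaC))
  cat(sprintf("  kappa = %g, omega = %g, sigma_noise = %g, L_init = %g\n",
              x$kappa, x$omega, x$sigma_noise, x$L_init))
  invisible(x)
}

model_has_adaptation <- function(model) model %in% c("AL", "AL-L", "AL-NL")
model_seq_kind <- function(model) {
  switch(model,
         "LLO" = "none", "AL" = "none",
         "LLO-L" = "linear", "AL-L" = "linear",
         "LLO-NL" = "nonlinear", "AL-NL" = "nonlinear")
}

# DoG attraction kernel: d * exp(-d^2 / (2 omega^2)), maximal at |d| = omega
dog <- function(d, omega) d * exp(-d^2 / (2 * omega^2))

#' Delta-rule adaptation levels
#'
#' Computes the adaptation-level trajectory `L_n` implied by a stimulus
#' sequence in log-odds: `L_1 = L_init`,
#' `L_n = L_{n-1} + kappa * (S_{n-1} - L_{n-1})`.
#'
#' @param S numeric vector of stimuli in log-odds.
#' @param kappa learning rate in \[0, 1\].
#' @param L_init initial level (log-odds).
#' @return numeric vector the same length as `S`.
#' @export
adaptation_levels <- function(S, kappa, L_init = 0) {
  n <- length(S)
  if (n == 0) return(numeric(0))
  if (kappa == 0) return(rep(L_init, n))
  out <- stats::filter(kappa * S[-n], 1 - kappa, method = "recursive",
                       init = L_init)
  c(L_init, as.numeric(out))
}

#' Generate a stimulus sequence for one participant
#'
#' Draws `design$n_trials` stimuli from a condition's distribution. In
#' `"iid"` mode every trial is an independent draw from \eqn{\theta}; in
#' `"block-balanced"` mode each 99-trial block is a multinomial draw of
#' block-size counts from \eqn{\theta}, shuffled within the block (so block
#' compositions track the design distribution more tightly).
#'
#' @param pmf a `condition_pmf`.
#' @param design an `experiment_design`.
#' @param seed integer seed; the sequence is deterministic given the seed.
#' @param mode `"block-balanced"` (default) or `"iid"`.
#' @return numeric vector of length `design$n_trials` on the support grid.
#' @export
generate_stimulus_sequence <- function(pmf, design = experiment_design(),
                                       seed = 1,
                                       mode = c("block-balanced", "iid")) {
  stopifnot(inherits(pmf, "condition_pmf"), inherits(design, "experiment_design"))
  mode <- match.arg(mode)
  withr::with_seed(seed, {
    if (mode == "iid") {
      pmf$support[sample.int(length(pmf$support), design$n_trials,
                             replace = TRUE, prob = pmf$mass)]
    } else {
      unlist(lapply(seq_len(design$n_blocks), function(b) {
        counts <- as.vector(rmultinom(1, design$block_size, pmf$mass))
        block <- rep(pmf$support, counts)
        block[sample.int(length(block))]
      }), use.names = FALSE)
    }
  })
}

#' Simulate one observer
#'
#' Generates trial-by-trial responses from one of the six generative models.
#' The lag terms feed on the *realized* (noisy, clamped) previous responses,
#' and the adaptation level is updated from the presented stimuli by the
#' delta rule. Trials with fewer available lags than `m` use only the
#' available ones. Responses are returned on the probability scale via the
#' logistic transform and clamped into \[0.005, 0.995\].
#'
#' @param params an `observer_params`.
#' @param stimuli numeric vector of stimulus probabilities on (0, 1).
#' @param seed integer seed (response noise and dot counts).
#' @param participant_id identifier written into the table.
#' @param condition condition label written into the table.
#' @param block_size trials per block (for the block column).
#' @param dot_totals admissible dot counts (display covariate; carried but
#'   never used in analysis).
#' @return a trial table `data.frame` with columns `participant_id`,
#'   `condition`, `block`, `trial_index`, `n_dots`, `p`, `response`.
#' @examples
#' prm <- observer_params("LLO", beta0 = 1, betaC = 0, sigma_noise = 0)
#' tab <- simulate_observer(prm, c(0.2, 0.5, 0.8), seed = 1)
#' tab$response  # identical to the stimuli: the identity observer
#' @export
simulate_observer <- function(params, stimuli, seed = 1,
                              participant_id = "P01",
                              condition = NA_character_,
                              block_size = 99L,
                              dot_totals = seq(200L, 800L, by = 100L)) {
  stopifnot(inherits(params, "observer_params"), length(stimuli) >= 1)
  if (any(stimuli <= 0 | stimuli >= 1)) {
    stop("stimuli must lie strictly inside (0, 1).", call. = FALSE)
  }
  n <- length(stimuli)
  if (params$m >= n) stop("number of lags `m` must be < number of trials.",
                          call. = FALSE)
  S <- log_odds(stimuli)
  has_ad <- model_has_adaptation(params$model)
  seq_kind <- model_seq_kind(params$model)
  L <- if (has_ad) adaptation_levels(S, params$kappa, params$L_init) else
    rep(0, n)
  withr::with_seed(seed, {
    eps <- if (params$sigma_noise > 0) rnorm(n, 0, params$sigma_noise) else
      rep(0, n)
    n_dots <- sample(dot_totals, n, replace = TRUE)
    R <- numeric(n)
    for (i in seq_len(n)) {
      mu <- params$beta0 * (S[i] - L[i]) + params$betaC
      if (seq_kind != "none") {
        lags <- seq_len(min(params$m, i - 1L))
        if (length(lags)) {
          prev <- R[i - lags]
          term <- if (seq_kind == "linear") prev else
            dog(prev - S[i], params$omega)
          mu <- mu + sum(params$beta_lags[lags] * term)
        }
      }
      # store the realized response in log-odds after clamping, so that lag
      # terms see exactly what an analyst would recover from the data file
      R[i] <- log_odds(clamp_response(logistic(mu + eps[i])))
    }
  })
  data.frame(participant_id = participant_id,
             condition = condition,
             block = as.integer((seq_len(n) - 1L) %/% block_size + 1L),
             trial_index = seq_len(n),
             n_dots = as.integer(n_dots),
             p = stimuli,
             response = logistic(R),
             stringsAsFactors = FALSE)
}

#' Simulate a cohort of observers
#'
#' Runs `design$n_participants` independent observers for one condition, each
#' with its own stimulus sequence and noise stream; all per-participant seeds
#' are derived reproducibly from the master seed. Optionally jitters
#' parameters across participants.
#'
#' @param condition condition label (`"U"`, `"E"`, `"S"`, `"L"`) or a
#'   `condition_pmf`.
#' @param params an `observer_params` (group-level values).
#' @param design an `experiment_design`.
#' @param seed master integer seed.
#' @param mode stimulus sequencing mode, see [generate_stimulus_sequence()].
#' @param jitter optional named numeric vector of between-participant
#'   parameter spreads: log-normal SD (on the log scale) for `beta0`, `omega`
#'   and `sigma_noise`; normal SD for `betaC`, `beta_lags` and `kappa`
#'   (`kappa` is clamped back into \[0, 1\]). Default: no spread.
#' @return a trial table `data.frame` with
#'   `design$n_participants * design$n_trials` rows.
#' @export
simulate_cohort <- function(condition, params, design = experiment_design(),
                            seed = 1, mode = c("block-balanced", "iid"),
                            jitter = NULL) {
  mode <- match.arg(mode)
  pmf <- if (inherits(condition, "condition_pmf")) condition else
    condition_pmf(condition)
  label <- pmf$condition
  n_pp <- design$n_participants
  seeds <- withr::with_seed(seed, matrix(
    sample.int(.Machine$integer.max - 1L, 3L * n_pp), nrow = n_pp))
  tabs <- lapply(seq_len(n_pp), function(i) {
    prm <- if (is.null(jitter)) params else
      jitter_params(params, jitter, seeds[i, 3])
    stim <- generate_stimulus_sequence(pmf, design, seed = seeds[i, 1],
                                       mode = mode)
    simulate_observer(prm, stim, seed = seeds[i, 2],
                      participant_id = sprintf("%s%02d", label, i),
                      condition = label,
                      block_size = design$block_size,
                      dot_totals = design$dot_totals)
  })
  do.call(rbind, tabs)
}

jitter_params <- function(params, jitter, seed) {
  withr::with_seed(seed, {
    p <- params
    for (nm in names(jitter)) {
      sd <- jitter[[nm]]
      if (sd <= 0) next
      if (nm %in% c("beta0", "omega", "sigma_noise")) {
        p[[nm]] <- p[[nm]] * exp(rnorm(1, 0, sd))
      } else if (nm == "kappa") {
        p[[nm]] <- min(1, max(0, p[[nm]] + rnorm(1, 0, sd)))
      } else if (nm %in% c("betaC", "beta_lags")) {
        p[[nm]] <- p[[nm]] + rnorm(length(p[[nm]]), 0, sd)
      }
    }
    do.call(observer_params,
            p[c("model", "beta0", "beta_lags", "betaC", "kappa", "omega",
                "sigma_noise", "L_init")])
  })
}

#' Validate a trial table
#'
#' Checks the trial-table contract: required columns present, `p` strictly
#' inside (0, 1), responses in (0, 1) (clamped if `clamp = TRUE`), and
#' `trial_index` dense (1, 2, ...) and ordered within each participant.
#'
#' @param trials a trial table `data.frame`.
#' @param clamp if `TRUE` (default), boundary responses are clamped into
#'   \[0.005, 0.995\] rather than rejected.
#' @return the validated (possibly clamped) trial table, invisibly usable.
#' @export
validate_trials <- function(trials, clamp = TRUE) {
  needed <- c("participant_id", "condition", "block", "trial_index",
              "n_dots", "p", "response")
  missing <- setdiff(needed, names(trials))
  if (length(missing)) {
    stop("trial table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(trials$p <= 0 | trials$p >= 1)) {
    bad <- which(trials$p <= 0 | trials$p >= 1)[1]
    stop("invalid stimulus p at row ", bad, call. = FALSE)
  }
  if (clamp) {
    trials$response <- clamp_response(trials$response)
  } else if (any(trials$response <= 0 | trials$response >= 1)) {
    bad <- which(trials$response <= 0 | trials$response >= 1)[1]
    stop("invalid response at row ", bad, call. = FALSE)
  }
  for (id in unique(trials$participant_id)) {
    ti <- trials$trial_index[trials$participant_id == id]
    if (!identical(as.integer(ti), seq_along(ti))) {
      stop("trial_index not dense/ordered for participant ", id, call. = FALSE)
    }
  }
  trials
}

#' Log-odds view of a trial table
#'
#' Adds the derived columns `S = log_odds(p)` and `R = log_odds(response)`.
#'
#' @param trials a trial table.
#' @return the trial table with columns `S` and `R` appended.
#' @export
add_logodds <- function(trials) {
  trials$S <- log_odds(trials$p)
  trials$R <- log_odds(clamp_response(trials$response))
  trials
}

#' Read and write trial tables as CSV
#'
#' Trial tables are serialized as UTF-8 CSV with the canonical header
#' `participant_id,condition,block,trial_index,n_dots,p,response`; `p` and
#' `response` are written with 6 decimal places. The reader validates the
#' trial-table invariants and clamps boundary responses.
#'
#' @param trials a trial table.
#' @param path file path.
#' @return `read_trial_csv()` returns a validated trial table;
#'   `write_trial_csv()` returns `path` invisibly.
#' @export
write_trial_csv <- function(trials, path) {
  trials <- validate_trials(trials)
  out <- trials[, c("participant_id", "condition", "block", "trial_index",
                    "n_dots", "p", "response")]
  out$p <- sprintf("%.6f", out$p)
  out$response <- sprintf("%.6f", out$response)
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  tab$p <- as.numeric(tab$p)
  tab$response <- as.numeric(tab$response)
  validate_trials(tab)
}
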