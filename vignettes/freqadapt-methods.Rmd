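---
title: "Models and methods behind freqadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind freqadapt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(freqadapt)
```

## The scientific problem

When people judge the relative-frequency of a target among distractors — for
instance the proportion of black dots in a mixed black-and-white array —
their reports are systematically distorted: small proportions are
overestimated and large ones underestimated, an "inverted-S" curve. The
question this package addresses computationally is whether and how that
distortion *adapts to the statistics of the environment*: if most stimuli
are small proportions, or most are extreme, does the whole
stimulus-to-report mapping shift, and through what trial-by-trial
mechanisms?

The experimental design the package emulates has four between-subject
conditions that differ only in the distribution of the objective
relative-frequency $p \in \{0.01, 0.02, \ldots, 0.99\}$:

* **U** (Uniform): each value with probability $1/99$;
* **E** (Extreme): probability $3/99$ for each value in $[0.01, 0.10]$ and
  $[0.90, 0.99]$, $\frac{39}{79}\cdot\frac{1}{99}$ for each middle value;
* **S** (Small): $5/99$ for each value in $[0.01, 0.10]$ (half of all trials
  show a small proportion), $\frac{49}{89}\cdot\frac{1}{99}$ elsewhere;
* **L** (Large): the mirror image of S.

Each simulated participant completes 693 trials in 7 blocks of 99, with 16
participants per condition — the design constants in `experiment_design()`.

All modelling is done on the log-odds scale $\lambda(p) = \log\frac{p}{1-p}$
(natural logarithm throughout), writing $S_n = \lambda(p_n)$ for the
stimulus and $R_n = \lambda(\pi(p_n))$ for the report of trial $n$.

## The six response models

All six generative models in `simulate_observer()` / `fit_model()` share the
linear-in-log-odds (LLO) backbone and add at most two mechanisms:

| family | mean of $R_n$ |
|---|---|
| LLO | $\beta_0 S_n + \beta_C$ |
| AL | $\beta_0 (S_n - L_n) + \beta_C$ |
| LLO-L | $\beta_0 S_n + \sum_i \beta_{-i} R_{n-i} + \beta_C$ |
| AL-L | $\beta_0 (S_n - L_n) + \sum_i \beta_{-i} R_{n-i} + \beta_C$ |
| LLO-NL | $\beta_0 S_n + \sum_i \beta_{-i} g_\omega(R_{n-i} - S_n) + \beta_C$ |
| AL-NL | $\beta_0 (S_n - L_n) + \sum_i \beta_{-i} g_\omega(R_{n-i} - S_n) + \beta_C$ |

with Gaussian response noise of SD $\sigma$ added to the mean, the
delta-rule **adaptation level** $L_n = L_{n-1} + \kappa (S_{n-1} - L_{n-1})$
(learning rate $\kappa \in [0,1]$, neutral start $L_1 = 0$, i.e. $p = 0.5$),
and the **derivative-of-Gaussian (DoG)** attraction kernel
$g_\omega(d) = d\, e^{-d^2 / 2\omega^2}$, which peaks at inter-trial
distance $|d| = \omega$ (the "scope of influence") and vanishes both at
$d = 0$ and at large distances. With one lag ($m = 1$, the default; lags are
configurable) the free-parameter counts including $\sigma$ are 3, 4, 4, 5,
5, 6.

Generation uses the *realized* (noisy, clamped) previous responses in the
lag terms, because that is what the analysis-side regressions condition on.
Trials with fewer available lags than $m$ simply drop the unavailable
terms; on the fitting side those early trials are excluded altogether
(trials $n \ge 6$ are fitted), which keeps the likelihoods of models with
different $m \le 5$ comparable.

Reports of exactly 0 or 100% are legal on the response bar but undefined in
log-odds; they are clamped to 0.005 / 0.995 — half of the 0.01 stimulus
step — before transforming (`clamp_response()`).

## Theory-level predictors

Two closed-form predictors (`al_theory_curve()`, `bayes_bls_curve()`)
formalize the opposing context-effect predictions:

* **Adaptation-level theory**: $\lambda[\pi(p)] = \gamma(\lambda[p] -
  \lambda[L]) + (1-\gamma)\lambda[p_0]$ with $\lambda[L] = \eta \sum_p
  \theta(p) \lambda[p]$ computed by exact enumeration. Defaults $\gamma =
  0.8$, $p_0 = 0.5$, $\eta = 0.2$. Prediction: *repulsion* from the
  concentrated region — overestimation in S, underestimation in L, no
  U-vs-E difference (both symmetric).
* **Bayesian posterior-mean (BLS) observer**: the percept $y$ is Gaussian
  around $\lambda[p]$ (SD $\sigma_{noise}$, default 1), the prior is the
  condition's true distribution $\theta$, the report is the posterior mean
  over the 99-value support, and the percept is marginalized out by
  trapezoidal quadrature *on the log-odds scale* (the change-of-variables
  factor of the probability-scale density cancels in the normalized
  quadrature ratio). Prediction: *attraction* toward the concentrated
  region — the opposite elevation ordering, and a steeper curve in E.

The percept grid defaults to $\lambda[y] \in [-10, 10]$ with 1401 points,
which holds at least $1 - 10^{-6}$ of the percept mass for every support
value at $\sigma_{noise} = 1$ (missing mass $\approx 3\times10^{-8}$); the
function refuses narrower grids rather than silently truncating. Doubling
the grid density moves no curve value by more than $10^{-4}$. Posterior and
marginalization weights are normalized per grid column after a log-space
maximum shift, so the vanishing-noise limit ($\sigma_{noise} \to 0$,
$\pi(p) \to p$) is numerically exact.

## Measuring distortion

`fit_llo()` estimates the distortion parametrically by ordinary least
squares of $R$ on $S$: the LLO model is *linear* in log-odds and all six
models carry Gaussian noise in log-odds, so least squares in that space is
the maximum-likelihood estimator; nonlinear fitting on the probability
scale would presume a different noise model. The slope is $\gamma$
(curvature of the distortion) and the intercept $c$ maps to the crossover
point $p_0 = \text{logistic}(c/(1-\gamma))$, reported as `NA` when
$|1 - \gamma| < 10^{-6}$ (an identity-slope curve has no crossover).

`smooth_curve()` estimates the same curve non-parametrically: a
Nadaraya–Watson kernel mean of $\pi(p) - p$ with a Gaussian kernel on the
probability scale, fixed bandwidth $h = 0.03$, evaluated on the 99-value
grid. The fixed bandwidth (rather than per-participant optimal selection,
which for this design lands between 0.02 and 0.07) avoids comparing curves
smoothed by different amounts. From the smoothed curve,
`curvature_elevation()` computes the **curvature** $\int |f|\,dp$ and
**elevation** $\int f\,dp$ by the trapezoidal rule — at a grid step of 0.01
the choice of quadrature rule is immaterial at the reported precision.
Group variability is visualized by `bootstrap_cloud()`: 500 resamples of
the 16 participants with replacement, each contributing a group mean.

## Sequential effects

`fit_sequential_ols()` is the standard linear probe: OLS of $R_n$ on
$(S_n, R_{n-1}, \ldots, R_{n-m}, 1)$, lags formed within participant.
Previous stimuli are not entered alongside previous responses — the two are
strongly collinear in this design and the package follows the convention of
regressing on responses.

`wls_beta_map()` relaxes linearity: at every grid cell $(p_n, p_{n-1})$ it
reruns the lag-1 regression as weighted least squares, the weight of trial
$j$ being a two-dimensional Gaussian kernel in
$(p_j - p_n, p_{j-1} - p_{n-1})$ with span $\sigma_k = 0.1$, and the WLS
weight matrix carrying the *squared* kernel weights on its diagonal —
implemented exactly in that form. The cell stores the local coefficient on
$R_{j-1}$. Because Gaussian weights never vanish, every trial contributes
to every cell; near-empty corners are protected by a Kish effective-sample-
size guard (cells with ESS below 5 are reported `NA`, never extrapolated).
The default grid is $25 \times 25$ over $[0.01, 0.99]$: the full
$99 \times 99$ grid (available via `grid_n = 99`) costs ~16x more and adds
no structure at the kernel span used. Internally all cells are computed at
once from a handful of kernel-moment matrix products, so maps are cheap.

A flat map indicates a linear effect; a ridge along $p_{n-1} = p_n$ is the
signature of DoG attraction. `predicted_beta_map()` pushes fitted model
parameters back through the generator ($n_{sim} = 20$ simulated replicates
by default — one simulation would be noticeably noisier, and the average
stabilizes the predicted map) and `map_correlation()` scores observed
against predicted maps by Pearson's r over jointly estimable cells
(pairwise deletion).

## Model fitting and comparison

`negloglik()` evaluates the Gaussian likelihood with lag terms fed by
observed responses and $L_n$ recursed from observed stimuli. `fit_model()`
maximizes it under box bounds ($\beta_0 \in (0, 2]$,
$\beta_{-i} \in [-0.5, 0.5]$, $\beta_C \in [-2, 2]$, $\kappa \in [0, 1]$,
$\omega \in (0.1, 10]$, $\sigma \in (0.01, 3]$) with multi-start bounded
quasi-Newton search (L-BFGS-B), 20 random restarts by default (configurable
up to the 300 a cautious user might want).

Two implementation choices matter here:

* **Profiling.** Given the nonlinear parameters ($\kappa$, $\omega$), the
  linear coefficients and $\sigma$ have closed-form conditional MLEs, so
  the default route (`method = "profile"`) searches only the 0-, 1- or
  2-dimensional nonlinear space and solves the rest exactly — LLO and
  LLO-L are closed form outright. This reaches the identical maximum as the
  joint search (`method = "full"`, kept and cross-checked in the tests),
  deterministically and orders of magnitude faster. In the profile route
  the linear coefficients are not box-constrained; on data remotely
  resembling this design their MLEs sit far inside the bounds, which exist
  mainly to contain the random restarts of the joint search.
* **Grid-seeded restarts.** The likelihood valley in $\kappa$ is narrow
  near small learning rates, and a quasi-Newton line search started at a
  large $\kappa$ can overshoot the valley and stall on the $\kappa = 0$
  boundary. The profile route therefore augments the uniform random
  restarts with the three best points of a deterministic coarse
  $(\kappa, \omega)$ grid scan (the profile likelihood makes this scan
  essentially free). This removed every such stall in the package's
  recovery studies.

Models are compared by the small-sample-corrected Akaike criterion as the
pipeline defines it, $\mathrm{AICc} = -2\ln\hat L + 2k +
\frac{2k(k-1)}{N-k-1}$. Note the correction term: the textbook AICc uses
$2k(k+1)$ in the numerator. The package implements the $2k(k-1)$ form as
its comparison metric and exposes the textbook form behind
`aicc(..., correction = "2k(k+1)")`; the two differ by $4k/(N-k-1)$ per
model, negligible at $N = 688$ but surfaced rather than silently "fixed".
$\sigma$ is counted in $k$, and $k$ is reported alongside every AICc.

Group-level selection uses `protected_exceedance_probability()`: a
random-effects scheme in which each participant's generating model is drawn
from a Dirichlet-distributed population frequency vector, fitted by
variational Bayes on the per-participant log evidences (approximated by
$-\mathrm{AICc}/2$). Exceedance probabilities are computed *exactly* by 1-D
quadrature on the independent-gamma representation of the Dirichlet (no
Monte Carlo in the estimator itself; a sampling oracle verifies it in the
tests), and are protected by the Bayesian omnibus risk — the posterior
probability, from the variational free energies of the random-effects model
and the equal-frequency null, that observed differences are chance — via
$\mathrm{PXP}_k = (1-\mathrm{BOR})\,\mathrm{EP}_k + \mathrm{BOR}/K$.

## Efficient coding

On a response scale bounded by 0 and 1, the information-maximizing response
distribution is uniform. `kl_to_uniform()` measures the distance from that
optimum: responses pooled across a condition's participants, 10 equal bins
(right-closed last bin), KL divergence in nats with empty bins contributing
zero. `u_mapping_resample()` builds the counterfactual: the condition's own
stimuli answered through the *Uniform condition's* empirical
stimulus-to-response mapping, each virtual response drawn uniformly with
replacement from the Uniform-condition responses to the identical stimulus
value (nearest-value fallback, ties toward 0.5, for stimuli the Uniform
cohort happened never to see). Since binning is deterministic per response,
the per-stimulus draws are realized as multinomial bin counts over the
matched pool's bin proportions — distributionally identical to drawing
responses one at a time and feasible at the configurable maximum of
$10^6$ simulations; the default of $10^4$ already pins the reported
quantiles. `ec_difference()` reports
$D_{KL}(\text{observed}\,\|\,\text{uniform}) -
D_{KL}(\text{U-mapping}\,\|\,\text{uniform})$ per simulation with median,
quartiles and 99% interval; negative values mean the condition's own
mapping is the more efficient code, and the Uniform condition against
itself provides the straddling-zero sanity check.

## The synthetic generator: what it does and does not emulate

The pipeline ships its own data generator because the paradigm's raw data
are not redistributable. `simulate_cohort()` reproduces the *design*: the
four stimulus distributions on the 99-value support, 693 trials in 7
blocks, 16 participants per condition, dot totals carried as a display
covariate (never analysed). Stimulus order is either i.i.d. or
block-balanced (per-block multinomial counts, shuffled within block); the
original sequencing scheme is not documented, so both are provided and
block-balanced is the default. Exact per-block balancing is impossible for
the skewed conditions (their per-block expected counts are non-integer),
which is why the balanced mode draws multinomial counts rather than fixed
ones.

Per-condition generator defaults (used by `reproduce_study()` and
`default_config()`) are calibrated once to the cohort medians reported for
this paradigm: $\beta_0 = 0.82, 0.76, 0.80, 0.80$ (U, E, S, L; the S and L
slopes are not reported and are set to the round intermediate value),
$p_0 = 0.5, 0.5, 0.59, 0.39$ mapped to intercepts via
$\beta_C = (1-\beta_0)\lambda(p_0)$, $\omega = 1.296, 2.209, 1.989, 1.890$,
$\beta_{-1} = 0.05$, $\sigma = 0.3$, and $\kappa = 0.05$ for U, S, L but 0
for E — mirroring the finding that adaptation confers no advantage in the
Extreme condition. Within a cohort, parameters are fixed across
participants by default (optional log-normal jitter is available), so
between-participant variance in the synthetic cohorts reflects stimulus
and noise realizations only.

What the generator deliberately does *not* emulate: perceptual numerosity
noise driven by the dot counts (the display covariate is inert), lapses and
motor error on the response bar beyond Gaussian log-odds noise,
practice/fatigue nonstationarity, and individual differences in the
generating mechanism. Consequently, passing pipeline tests demonstrate
that the estimators recover what the models generate at this design's
scale — not that human data satisfy those models. One visible artifact of
full delta-rule adaptation with these parameters is that synthetic S/L
elevations are larger than the modest medians real cohorts show; the
qualitative orderings, which are what the pipeline asserts, are unaffected.

## Problem sizes and reproducibility

Every stochastic function takes an integer seed and derives any internal
seeds reproducibly from it; same seed, bit-identical output. The package's
own validation runs at these sizes, chosen to give each check clear
resolution: parameter recovery over 24 seeds of one 693-trial AL-NL
participant; model recovery over 10 master seeds, each fitting all six
families to eight 693-trial participants per generating family (20
restarts); sequential-map model separation on an 8-participant cohort with
10-replicate predicted maps; efficient-coding direction on full 16
participant cohorts with $10^4$ U-mapping simulations.

## Known limitations

* The DoG sequential kernel is the only non-linear form considered; the
  model comparison can say it beats linear and absent sequential effects,
  not that it is the true form.
* The adaptation-level recursion assumes a single reference point; bimodal
  environments (condition E) are represented, but a mixture-reference
  observer is not in the model space.
* `-AICc/2` is a proxy for log model evidence in the group-level
  selection; with strongly informative priors over parameters the ranking
  could differ.
* The WLS beta map inherits the usual local-regression caveats: the kernel
  span trades variance for resolution, and cells far from the data (the
  skewed conditions' sparse corners) are suppressed by the ESS guard
  rather than estimated.
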