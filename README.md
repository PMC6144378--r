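# freqadapt

Simulation and analysis pipeline for the psychophysics of **visual
relative-frequency judgment under manipulated stimulus statistics** — for
researchers studying probability distortion, trial-by-trial adaptation and
serial dependence in magnitude-like judgments.

People judging the proportion of, say, black dots in a mixed dot array show
an inverted-S distortion: small proportions overestimated, large ones
underestimated. On the log-odds scale $\lambda(p) = \log\frac{p}{1-p}$ this
distortion is linear (the LLO model),

$$\lambda[\pi(p)] = \gamma\,\lambda[p] + (1-\gamma)\,\lambda[p_0],$$

with slope $\gamma$ (curvature) and crossover $p_0$ (elevation). `freqadapt`
implements, end to end and on synthetic data:

* the four stimulus-distribution conditions (Uniform / Extreme / Small /
  Large over $p \in \{0.01, \ldots, 0.99\}$) and their statistics;
* six generative observer models combining LLO with delta-rule
  **adaptation-level** learning
  ($L_n = L_{n-1} + \kappa(S_{n-1} - L_{n-1})$) and **linear** or
  **derivative-of-Gaussian** sequential effects
  ($\beta_{-1}\,(R_{n-1}-S_n)\,e^{-(R_{n-1}-S_n)^2/2\omega^2}$);
* theory-level predictors of context effects (adaptation-level repulsion
  vs. Bayesian posterior-mean attraction);
* parametric (LLO) and non-parametric (Nadaraya–Watson smoothing +
  curvature/elevation areas) distortion measures with bootstrap clouds;
* linear sequential regressions and the kernel-weighted WLS map of the
  local lag-1 coefficient over $(p_n, p_{n-1})$, plus model-predicted maps
  and their correlations;
* maximum-likelihood fitting of all six models, small-sample-corrected AIC
  comparison, and random-effects group selection (protected exceedance
  probabilities);
* an efficient-coding test: KL divergence of pooled responses from the
  uniform distribution, against U-mapping resampled counterfactuals.

See `vignettes/freqadapt-methods.Rmd` for the models, assumptions and
numerical choices.

## Worked example

Simulate one participant from the adapting, non-linearly sequential
observer (AL-NL) under the Uniform condition, then ask the pipeline what it
sees:

```r
library(freqadapt)

prm  <- observer_params("AL-NL", beta0 = 0.8, beta_lags = 0.05, betaC = 0,
                        kappa = 0.05, omega = 2, sigma_noise = 0.3)
stim <- generate_stimulus_sequence(condition_pmf("U"), seed = 1)
tab  <- simulate_observer(prm, stim, seed = 2, condition = "U")

fit_llo(tab)
#> <llo_fit> gamma = 0.7825, p0 = 0.5412 (n = 693, residual SD 0.363)
```

The recovered slope $\gamma \approx 0.78$ is the generating $\beta_0 = 0.8$
(inverted-S distortion), and the crossover sits near the neutral 0.5.
Fitting all six model families and comparing by AICc identifies the
generating mechanism:

```r
fits <- lapply(model_family_names(), function(f) fit_model(f, tab, seed = 3))
compare_models(list(fits))
#>   family k sum_aicc delta_aicc n_best
#> 6  AL-NL 6 337.2056    0.00000      1
#> 2     AL 4 347.8499   10.64427      0
#> 5   AL-L 5 348.6925   11.48686      0
#> 4 LLO-NL 5 561.7797  224.57410      0
#> 1    LLO 3 565.6081  228.40253      0
#> 3  LLO-L 4 565.6769  228.47131      0
```

AL-NL wins (lowest AICc); the ~224-point gap to the non-adapting families
is the footprint of the delta-rule adaptation level, and the ~10-point gap
to AL/AL-L is the derivative-of-Gaussian sequential effect. The full
study-scale pipeline — four conditions, 16 participants each, distortion
measures, beta maps, model selection and the efficient-coding test, with
pass/fail checks of the qualitative findings — is one call:

```r
report <- reproduce_study(seed = 1)
```

A thin command-line wrapper with `simulate` / `analyze` / `reproduce` /
`theory` subcommands is installed at `inst/cli/freqadapt`.

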