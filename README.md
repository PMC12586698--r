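# hgfsrt

Transition-probability learning in the four-choice probabilistic serial
reaction time (SRT) task, modelled with a categorical state-transition
hierarchical Gaussian filter (HGF).

The package is for computational cognitive modellers who want the full
workflow for this task — **simulate → filter → fit → recover** — with no
external data: a generative simulator of the task (two second-order
conditional sequences with 85/15 continuation probabilities, reversed
between two 960-trial sessions) and of response behaviour, the belief
filter, a reaction-time response model, and per-participant Bayesian
inference with convergence diagnostics and parameter-recovery studies.

## The model

The filter tracks a Gaussian belief over the log-odds of each of the 16
transitions between the four stimulus categories.  Each trial, every node
first takes a prediction step in which the belief variance inflates by the
anticipated volatility e<sup>ω</sup>:

    mu_hat = mu
    pi_hat = 1 / (1/pi + exp(omega))

The predicted log-odds are pushed through the logistic function and
row-normalised into a 4×4 transition-probability matrix.  The row of the
previous stimulus then receives binary observations (1 for the transition
that occurred, 0 for its siblings) and takes the precision-weighted update

    delta = o - logistic(mu_hat)
    pi    = pi_hat + b_hat (1 - b_hat)
    mu    = mu_hat + delta / pi

Three belief regressors — Shannon surprise −ln p(observed), expected
uncertainty S(μ̂)(1−S(μ̂))/π̂, and unexpected uncertainty (the same times
e<sup>ω</sup>) — enter a linear model for log reaction times together with
post-error and post-reversal indicators:

    mu_RT  = b0 + b1·surprise + b2·U_expected + b3·U_unexpected
             + b4·post_error + b5·post_reversal
    log RT ~ Normal(mu_RT, sigma)

The 8 free parameters (ω, β0–β5, σ) are fitted per participant by MCMC
(4 chains × 2,000 samples; a collapsed Metropolis-within-Gibbs sampler that
re-runs the filter for every proposed ω), with split Gelman–Rubin r̂ and
effective-sample-size diagnostics.

## Worked example

Simulate one participant at the study conditions, filter the stimulus
stream, and fit the joint model:

```r
library(hgfsrt)

trials <- generate_task(sequence_spec(), seed = 1)          # 2 x 960 trials
trials <- simulate_agent(trials, hgf_params(omega = -4),
                         response_params(5.83, 0.05, -0.02, -0.15, 0.10, -0.01,
                                         sigma = 0.2),
                         seed = 2)
mean(trials$correct)
#> [1] 0.9161458

traj <- hgf_filter(trials$stimulus, hgf_params(-4), session = trials$session)
traj
#> Categorical state-transition HGF trajectory: 1920 trials, omega = -4
#>   mean surprise: 1.200 nats (ln 4 = 1.386 at chance)
#>   final predicted transition matrix:
#>       1     2     3     4
#> 1 0.000 0.313 0.376 0.311
#> 2 0.349 0.000 0.396 0.254
#> 3 0.273 0.363 0.000 0.364
#> 4 0.295 0.451 0.253 0.000

fit <- fit_hgf(filter_rt(trials), chains = 4, samples = 2000, seed = 3)
summary(fit)
#>   parameter     mean      sd   ci_low ci_high rhat  ess
#> 1     omega -5.18727 0.99863 -6.98800 -3.2177 1.01  828
#> 2     beta0  5.84241 0.04375  5.76407  5.9316 1.00 3175
#> 3     beta1  0.04678 0.02436  0.00395  0.0964 1.00 2182
#> 4     beta2 -0.27914 0.30152 -0.82407  0.2996 1.00 2958
#> 5     beta3 -0.00985 1.00202 -1.93028  1.8992 1.00 4000
#> 6     beta4  0.08076 0.01522  0.05159  0.1097 1.00 4000
#> 7     beta5 -0.00177 0.00869 -0.01803  0.0150 1.00 3945
#> 8     sigma  0.18049 0.00289  0.17518  0.1859 1.00  964
```

Reading the output: mean surprise is well below the ln 4 ≈ 1.386 chance
level, so the filter has learned the sequence structure, and the diagonal
of the final transition matrix is near zero — the SOC sequences never
repeat a category, and the model discovers this.  In the fit, the true
simulating values sit inside the 94% credible intervals (ω = −4,
β1 = 0.05, β4 = 0.10), all r̂ ≤ 1.01, and σ is slightly below its true 0.2
because the slow-RT exclusion rule trims the upper tail of the generative
log-normal — see the vignette for why recovery studies skip that rule.
β3's posterior simply returns its prior: within a participant the two
uncertainty regressors are exactly proportional, so only their combination
is identified.

Parameter recovery over a simulated cohort:

```r
rec <- recovery_study(n_agents = 20, seed = 42)
rec$summary   # per-parameter correlation, bias, RMSE, 94% CI coverage
```

A thin command-line front end with `simulate`, `filter`, `fit`, `recover`
and `run` subcommands lives in `inst/cli/hgfsrt.R`.

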