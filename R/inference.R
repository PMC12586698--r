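#' Prior specification for the joint perceptual + response model
#'
#' Weakly informative defaults: the log-volatility prior covers the slow
#' regimes typical of implicit sequence learning, the intercept prior is
#' centred on log-RTs around 400 ms, the slope priors are centred on zero,
#' and the residual-SD prior is half-normal.  All are overridable.
#'
#' @param omega Length-2 numeric `c(location, scale)` of the normal prior
#'   on the log-volatility.
#' @param beta0 Normal prior `c(location, scale)` on the intercept.
#' @param beta1,beta2,beta3,beta4,beta5 Normal priors `c(location, scale)`
#'   on the slope coefficients.
#' @param sigma Scale of the half-normal prior on the residual SD.
#' @return An object of class `"hgf_priors"`.
#' @examples
#' hgf_priors(omega = c(-4, 1))
#' @export
hgf_priors <- function(omega = c(-3, 2), beta0 = c(6, 2),
                       beta1 = c(0, 1), beta2 = c(0, 1), beta3 = c(0, 1),
                       beta4 = c(0, 1), beta5 = c(0, 1), sigma = 0.5) {
  pr <- list(omega = omega, beta0 = beta0, beta1 = beta1, beta2 = beta2,
             beta3 = beta3, beta4 = beta4, beta5 = beta5)
  for (nm in names(pr)) {
    p <- pr[[nm]]
    if (length(p) != 2L || !all(is.finite(p)) || p[2] <= 0)
      stop(sprintf("prior on `%s` must be c(location, scale) with scale > 0", nm))
  }
  if (!(is.finite(sigma) && sigma > 0))
    stop("half-normal scale for `sigma` must be strictly positive")
  structure(c(pr, list(sigma = sigma)), class = "hgf_priors")
}

#' @export
print.hgf_priors <- function(x, ...) {
  cat("Priors (normal location/scale; sigma half-normal):\n")
  for (nm in setdiff(names(x), "sigma"))
    cat(sprintf("  %-6s ~ Normal(%g, %g)\n", nm, x[[nm]][1], x[[nm]][2]))
  cat(sprintf("  sigma  ~ Half-Normal(%g)\n", x$sigma))
  invisible(x)
}

.hgf_par_names <- c("omega", "beta0", "beta1", "beta2", "beta3", "beta4",
                    "beta5", "sigma")

# design matrix of the response model at a given omega
.hgf_design <- function(stimuli, new_session, omega, mu0, pi0,
                        post_error, post_reversal, keep) {
  reg <- hgf_regressors_cpp(stimuli, new_session, omega, mu0, pi0)
  cbind(1, reg[keep, 1L], reg[keep, 2L], reg[keep, 3L],
        post_error[keep], post_reversal[keep])
}

#' Fit the categorical state-transition HGF to one participant
#'
#' Samples the joint posterior of the 8 free parameters (log-volatility
#' `omega`, the six response-model coefficients `beta0`--`beta5`, and the
#' residual SD `sigma`) by Markov chain Monte Carlo.  For every proposed
#' `omega` the HGF filter is re-run on the stimulus stream to rebuild the
#' belief regressors, so the perceptual and response models are fitted
#' jointly.  The sampler is a collapsed Metropolis-within-Gibbs scheme:
#' because the coefficient priors are Gaussian and the likelihood is
#' Gaussian, the coefficients can be integrated out analytically, so
#' `omega` and `log(sigma)` take random-walk Metropolis steps on the
#' marginal posterior (step sizes adapted during warmup) and the
#' coefficient vector is then drawn exactly from its conjugate multivariate
#' normal conditional.  Collapsing removes the random-walk coupling between
#' the volatility and the coefficients along the ridge created by the
#' proportionality of the two uncertainty regressors.
#' Reaction times are cleaned with [filter_rt()] before fitting unless the
#' table already carries exclusion flags.
#'
#' @param trials Trial data frame (columns `session`, `stimulus`,
#'   `correct`, `rt_ms`) from [simulate_agent()] or [read_trials()].
#' @param priors An [hgf_priors()] object.
#' @param chains Number of chains (default 4).
#' @param samples Total MCMC samples per chain (default 2000), interpreted
#'   as `warmup` adaptation samples followed by `samples - warmup` retained
#'   draws.
#' @param warmup Warmup samples per chain (default `samples / 2`).
#' @param seed Integer seed; chain c uses `seed + c - 1`.
#' @param mu0,pi0 Fixed initial beliefs of the filter.
#' @param fix_omega Optional fixed value for `omega`; when supplied the
#'   log-volatility is held constant and only the 7 response parameters are
#'   sampled (used for oracle checks).
#' @return An object of class `"hgf_fit"` with the draws (array
#'   iterations x chains x parameters), posterior summaries, and
#'   convergence diagnostics.  See [summary.hgf_fit()].
#' @examples
#' \donttest{
#' trials <- simulate_agent(generate_task(sequence_spec(trials_per_session = 240)),
#'                          hgf_params(omega = -4), response_params(), seed = 1)
#' fit <- fit_hgf(trials, chains = 2, samples = 400, seed = 1)
#' summary(fit)
#' }
#' @export
fit_hgf <- function(trials, priors = hgf_priors(), chains = 4L,
                    samples = 2000L, warmup = samples %/% 2L, seed = 1L,
                    mu0 = 0, pi0 = 1, fix_omega = NULL) {
  stopifnot(inherits(priors, "hgf_priors"))
  chains <- as.integer(chains)
  samples <- as.integer(samples)
  warmup <- as.integer(warmup)
  if (warmup < 50L || warmup >= samples)
    stop("`warmup` must be at least 50 and smaller than `samples`")
  if (chains < 1L) stop("at least one chain is required")
  if (chains < 2L)
    warning("with a single chain the Gelman-Rubin diagnostic relies on ",
            "split halves only; diagnostics are degraded")
  if (is.null(trials$excluded)) trials <- filter_rt(trials)
  keep <- !trials$excluded
  if (sum(keep) < 100L)
    stop("fewer than 100 included trials; refusing to fit")

  stimuli <- as.integer(trials$stimulus)
  n_all <- length(stimuli)
  new_session <- c(TRUE, trials$session[-1L] != trials$session[-n_all])
  err <- is.na(trials$correct) | !trials$correct
  post_error <- c(FALSE, err[-n_all])
  post_error[new_session] <- FALSE
  post_error <- as.numeric(post_error)
  post_reversal <- as.numeric(trials$session == "post")
  y <- log(trials$rt_ms[keep])
  n <- length(y)

  prior_mean <- vapply(priors[c("beta0", "beta1", "beta2", "beta3", "beta4",
                                "beta5")], `[`, numeric(1), 1L)
  prior_sd <- vapply(priors[c("beta0", "beta1", "beta2", "beta3", "beta4",
                              "beta5")], `[`, numeric(1), 2L)
  S0inv <- diag(1 / prior_sd^2)
  S0inv_m0 <- prior_mean / prior_sd^2
  om_prior <- priors$omega
  sig_scale <- priors$sigma
  sample_omega <- is.null(fix_omega)

  n_keep <- samples - warmup
  draws <- array(NA_real_, dim = c(n_keep, chains, 8L),
                 dimnames = list(NULL, paste0("chain", seq_len(chains)),
                                 .hgf_par_names))
  accept <- matrix(0, chains, 2L, dimnames = list(NULL, c("omega", "sigma")))

  # sufficient statistics of the design at a given omega
  suff <- function(omega) {
    X <- .hgf_design(stimuli, new_session, omega, mu0, pi0,
                     post_error, post_reversal, keep)
    r0 <- y - drop(X %*% prior_mean)
    list(XtX = crossprod(X), Xty = drop(crossprod(X, y)),
         Xtr0 = drop(crossprod(X, r0)), r0s = sum(r0^2))
  }
  # log p(y | omega, sigma) with the coefficients integrated out
  # (additive constants, including the prior determinant, dropped)
  marg_ll <- function(st, sigma) {
    A <- st$XtX / sigma^2 + S0inv
    chA <- chol(A)
    v <- st$Xtr0 / sigma^2
    z <- forwardsolve(t(chA), v)
    -n * log(sigma) - sum(log(diag(chA))) -
      0.5 * (st$r0s / sigma^2 - sum(z^2))
  }

  for (ch in seq_len(chains)) {
    set.seed(as.integer(seed) + ch - 1L)
    # initial values: prior draws with reduced spread, away from boundaries
    omega <- if (sample_omega)
      stats::rnorm(1, om_prior[1], om_prior[2] / 4) else fix_omega
    sigma <- abs(stats::rnorm(1, 0, sig_scale / 2)) + 0.05
    st <- suff(omega)
    ll <- marg_ll(st, sigma)
    if (!is.finite(ll)) stop("non-finite likelihood at initial values")

    ls_om <- log(0.2)   # RW step sizes, adapted during warmup
    ls_sig <- log(0.1)
    acc_om <- 0; acc_sig <- 0

    for (it in seq_len(samples)) {
      ## omega: random-walk Metropolis on the collapsed posterior
      ## (filter re-run per proposal)
      if (sample_omega) {
        om_new <- omega + stats::rnorm(1, 0, exp(ls_om))
        st_new <- suff(om_new)
        ll_new <- marg_ll(st_new, sigma)
        lr <- (ll_new + stats::dnorm(om_new, om_prior[1], om_prior[2], log = TRUE)) -
              (ll + stats::dnorm(omega, om_prior[1], om_prior[2], log = TRUE))
        a <- is.finite(lr) && log(stats::runif(1)) < lr
        if (a) { omega <- om_new; st <- st_new; ll <- ll_new }
        if (it <= warmup) {
          alpha <- if (is.finite(lr)) min(1, exp(lr)) else 0
          ls_om <- ls_om + (alpha - 0.44) / sqrt(it)
        } else acc_om <- acc_om + a
      }

      ## sigma: random-walk Metropolis on the log scale, also collapsed
      lsig_new <- log(sigma) + stats::rnorm(1, 0, exp(ls_sig))
      sig_new <- exp(lsig_new)
      ll_new <- marg_ll(st, sig_new)
      # half-normal prior + log-scale Jacobian
      lr <- (ll_new - sig_new^2 / (2 * sig_scale^2) + lsig_new) -
            (ll - sigma^2 / (2 * sig_scale^2) + log(sigma))
      a <- is.finite(lr) && log(stats::runif(1)) < lr
      if (a) { sigma <- sig_new; ll <- ll_new }
      if (it <= warmup) {
        alpha <- if (is.finite(lr)) min(1, exp(lr)) else 0
        ls_sig <- ls_sig + (alpha - 0.44) / sqrt(it)
      } else acc_sig <- acc_sig + a

      if (it > warmup) {
        ## beta: exact draw from its conjugate conditional
        prec <- st$XtX / sigma^2 + S0inv
        ch_prec <- chol(prec)
        mn <- backsolve(ch_prec, forwardsolve(t(ch_prec),
                        st$Xty / sigma^2 + S0inv_m0))
        beta <- mn + backsolve(ch_prec, stats::rnorm(6))
        draws[it - warmup, ch, ] <- c(omega, beta, sigma)
      }
    }
    accept[ch, ] <- c(acc_om, acc_sig) / n_keep
  }

  par_idx <- if (sample_omega) seq_len(8L) else 2:8
  rh <- apply(draws[, , par_idx, drop = FALSE], 3, function(m) rhat(m))
  es <- apply(draws[, , par_idx, drop = FALSE], 3, function(m) ess(m))
  if (any(rh > 1.01))
    warning(sprintf("Gelman-Rubin diagnostic above 1.01 for: %s",
                    paste(names(rh)[rh > 1.01], collapse = ", ")))

  smry <- data.frame(
    parameter = .hgf_par_names[par_idx],
    mean = apply(draws[, , par_idx, drop = FALSE], 3, mean),
    sd = apply(draws[, , par_idx, drop = FALSE], 3, stats::sd),
    ci_low = apply(draws[, , par_idx, drop = FALSE], 3, stats::quantile,
                   probs = 0.03),
    ci_high = apply(draws[, , par_idx, drop = FALSE], 3, stats::quantile,
                    probs = 0.97),
    rhat = rh, ess = es, row.names = NULL
  )

  structure(list(draws = draws, summary = smry, accept = accept,
                 chains = chains, samples = samples, warmup = warmup,
                 seed = as.integer(seed), priors = priors,
                 fix_omega = fix_omega, n_included = n,
                 trials = trials, mu0 = mu0, pi0 = pi0,
                 ci_level = 0.94, call = match.call()),
            class = "hgf_fit")
}

#' @export
print.hgf_fit <- function(x, ...) {
  cat(sprintf(
    "Categorical state-transition HGF fit: %d chains x %d samples (%d warmup), %d trials\n",
    x$chains, x$samples, x$warmup, x$n_included))
  print(summary(x), digits = 3)
  invisible(x)
}

#' Posterior summary of an HGF fit
#'
#' @param object An `"hgf_fit"`.
#' @param ... Unused.
#' @return A data frame with one row per sampled parameter: posterior
#'   `mean`, `sd`, equal-tailed 94% credible interval (`ci_low`,
#'   `ci_high`), split Gelman-Rubin `rhat`, and effective sample size
#'   `ess`.
#' @export
summary.hgf_fit <- function(object, ...) object$summary

#' @export
coef.hgf_fit <- function(object, ...) {
  stats::setNames(object$summary$mean, object$summary$parameter)
}

#' Trace plots of the MCMC chains
#'
#' @param x An `"hgf_fit"`.
#' @param pars Parameter names to plot (default: all sampled).
#' @param ... Unused.
#' @export
plot.hgf_fit <- function(x, pars = x$summary$parameter, ...) {
  old <- graphics::par(mfrow = c(ceiling(length(pars) / 2), 2),
                       mar = c(3, 4, 1.5, 0.5))
  on.exit(graphics::par(old))
  for (p in pars) {
    graphics::matplot(x$draws[, , p], type = "l", lty = 1, ylab = p,
                      xlab = "", main = p, cex.main = 0.9)
  }
  invisible(x)
}

# regressors at the posterior-mean omega (or the fixed value)
.hgf_fit_regressors <- function(object) {
  om <- if (is.null(object$fix_omega))
    object$summary$mean[object$summary$parameter == "omega"]
  else object$fix_omega
  traj <- hgf_filter(object$trials$stimulus,
                     hgf_params(omega = om, mu0 = object$mu0, pi0 = object$pi0),
                     session = object$trials$session)
  regressor_table(traj, object$trials)
}

#' Fitted mean log reaction times
#'
#' Evaluates the linear predictor at the posterior means (with the filter
#' re-run at the posterior-mean log-volatility).
#'
#' @param object An `"hgf_fit"`.
#' @param ... Unused.
#' @return Numeric vector of predicted mean log-RTs, one per trial
#'   (including excluded trials).
#' @export
predict.hgf_fit <- function(object, ...) {
  cf <- coef(object)
  rp <- response_params(cf[["beta0"]], cf[["beta1"]], cf[["beta2"]],
                        cf[["beta3"]], cf[["beta4"]], cf[["beta5"]],
                        cf[["sigma"]])
  mu_rt(.hgf_fit_regressors(object), rp)
}

#' @export
residuals.hgf_fit <- function(object, ...) {
  log(object$trials$rt_ms) - predict(object)
}

#' Posterior-predictive reaction times
#'
#' Draws parameter vectors from the retained posterior samples and
#' simulates log-RTs from the response model for each trial.
#'
#' @param object An `"hgf_fit"`.
#' @param nsim Number of replicated datasets (default 1).
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A matrix of simulated `rt_ms`, trials x `nsim`.
#' @export
simulate.hgf_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$draws
  flat <- matrix(d, prod(dim(d)[1:2]), dim(d)[3],
                 dimnames = list(NULL, dimnames(d)[[3]]))
  reg <- .hgf_fit_regressors(object)
  n <- nrow(reg)
  out <- matrix(NA_real_, n, nsim)
  pick <- sample.int(nrow(flat), nsim, replace = TRUE)
  for (s in seq_len(nsim)) {
    p <- flat[pick[s], ]
    om <- if (is.null(object$fix_omega)) p[["omega"]] else object$fix_omega
    traj <- hgf_filter(object$trials$stimulus,
                       hgf_params(om, object$mu0, object$pi0),
                       session = object$trials$session)
    rg <- regressor_table(traj, object$trials)
    rp <- response_params(p[["beta0"]], p[["beta1"]], p[["beta2"]],
                          p[["beta3"]], p[["beta4"]], p[["beta5"]],
                          p[["sigma"]])
    out[, s] <- exp(stats::rnorm(n, mu_rt(rg, rp), p[["sigma"]]))
  }
  out
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Compares between-chain and within-chain variance.  With `split = TRUE`
#' (the default) each chain is first split in half, which also detects
#' within-chain drift.  The statistic is
#' `sqrt(1 + var(chain means) / W)` where `W` is the mean within-chain
#' variance, so it is exactly 1 when all chains are identical copies and
#' always at least 1.
#'
#' @param x A matrix of draws, iterations x chains.
#' @param split Split each chain in half before computing (default TRUE).
#' @return A single number `>= 1`.
#' @examples
#' set.seed(1)
#' good <- matrix(rnorm(4000), 1000, 4)
#' rhat(good)           # close to 1
#' bad <- cbind(rnorm(1000), rnorm(1000, 5))
#' rhat(bad)            # far above 1.01
#' @export
rhat <- function(x, split = TRUE) {
  x <- as.matrix(x)
  if (ncol(x) < 2L && !split) stop("at least 2 chains are required")
  if (split) {
    n2 <- nrow(x) %/% 2L
    x <- cbind(x[seq_len(n2), , drop = FALSE],
               x[n2 + seq_len(n2), , drop = FALSE])
  }
  if (nrow(x) < 2L) stop("chains too short")
  w <- mean(apply(x, 2, stats::var))
  if (w == 0) stop("degenerate (zero-variance) chains")
  b <- stats::var(colMeans(x))
  sqrt(1 + b / w)
}

#' Multi-chain effective sample size
#'
#' Combines within-chain autocorrelations across chains (using the pooled
#' variance that also drives [rhat()]) and truncates the autocorrelation
#' sum with Geyer's initial monotone positive-pair rule.
#'
#' @param x A matrix of draws, iterations x chains.
#' @return Estimated effective number of independent draws.
#' @export
ess <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (n < 4L) stop("chains too short for an ESS estimate")
  w <- mean(apply(x, 2, stats::var))
  if (w == 0) stop("degenerate (zero-variance) chains")
  b <- if (m > 1L) stats::var(colMeans(x)) else 0
  var_plus <- (n - 1) / n * w + b
  lag_max <- min(n - 1L, 500L)
  acov <- sapply(seq_len(m), function(c) {
    stats::acf(x[, c], lag.max = lag_max, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1]
  })
  rho <- 1 - (w - rowMeans(acov)[-1L]) / var_plus
  # Geyer: sum consecutive pairs while positive and non-increasing
  tau <- 0; prev <- Inf
  for (k in seq(1L, length(rho) - 1L, by = 2L)) {
    pair <- rho[k] + rho[k + 1L]
    if (pair < 0) break
    pair <- min(pair, prev)
    tau <- tau + pair
    prev <- pair
  }
  n * m / (1 + 2 * tau)
}

#' Parameter-recovery study on a simulated cohort
#'
#' Simulates `n_agents` synthetic participants with true parameters drawn
#' uniformly from the supplied ranges, fits each with [fit_hgf()], and
#' summarises how well the posterior recovers the truth: per-parameter
#' correlation between true values and posterior means, bias, RMSE, and
#' coverage of the 94% credible intervals.
#'
#' @param n_agents Number of simulated participants (default 20).
#' @param ranges Named list of length-2 ranges for the 8 parameters;
#'   defaults span the spread typical of SRT participants (log-volatility
#'   in \[-6, -2\], post-error slowing around 0.1).
#' @param trials_per_session Trials per session of the simulated task
#'   (default 960, two sessions).
#' @param chains,samples Passed to [fit_hgf()].
#' @param error_rate Simulated error rate (default 0.08).
#' @param seed Master seed; agent k derives its own streams from it.
#' @param priors Passed to [fit_hgf()].
#' @param omega_values Optional vector of `n_agents` true log-volatility
#'   values, e.g. an even grid over the range of interest; the usual design
#'   for single-parameter recovery because it removes the clustering noise
#'   of uniform draws from the recovery correlation.  Default `NULL`: draw
#'   uniformly from `ranges$omega` like every other parameter.
#' @param filter_rts Apply the [filter_rt()] exclusion rules before fitting
#'   (default `FALSE`).  Simulated agents produce no attentional lapses, so
#'   the lapse-exclusion rules would one-sidedly truncate the generative
#'   log-normal RT distribution and bias the recovered residual SD and
#'   post-error weight; recovery therefore fits all simulated trials unless
#'   truncation effects are the object of study.
#' @return An object of class `"hgf_recovery"`: `agents` (per agent x
#'   parameter: truth, posterior mean/SD/CI, coverage flag, max rhat) and
#'   `summary` (per parameter: correlation, bias, RMSE, coverage).
#' @export
recovery_study <- function(n_agents = 20L,
                           ranges = list(omega = c(-6, -2),
                                         beta0 = c(5.4, 6.2),
                                         beta1 = c(-0.2, 0.3),
                                         beta2 = c(-0.5, 0.5),
                                         beta3 = c(-0.5, 0.5),
                                         beta4 = c(0.03, 0.17),
                                         beta5 = c(-0.06, 0.04),
                                         sigma = c(0.15, 0.3)),
                           trials_per_session = 960L, chains = 4L,
                           samples = 2000L, error_rate = 0.08, seed = 1L,
                           priors = hgf_priors(), omega_values = NULL,
                           filter_rts = FALSE) {
  stopifnot(all(.hgf_par_names %in% names(ranges)))
  if (any(!vapply(ranges, function(r) all(is.finite(r)), logical(1))))
    stop("all parameter ranges must be finite")
  set.seed(as.integer(seed))
  truth <- sapply(.hgf_par_names, function(p)
    stats::runif(n_agents, ranges[[p]][1], ranges[[p]][2]))
  if (!is.null(omega_values)) {
    if (length(omega_values) != n_agents || any(!is.finite(omega_values)))
      stop("`omega_values` must supply one finite value per agent")
    truth[, "omega"] <- omega_values
  }
  spec <- sequence_spec(trials_per_session = trials_per_session)

  rows <- vector("list", n_agents)
  for (k in seq_len(n_agents)) {
    tp <- truth[k, ]
    agent_seed <- as.integer(seed) + k * 101L
    trials <- tryCatch({
      trials <- generate_task(spec, seed = agent_seed)
      simulate_agent(trials, hgf_params(omega = tp[["omega"]]),
                     response_params(tp[["beta0"]], tp[["beta1"]],
                                     tp[["beta2"]], tp[["beta3"]],
                                     tp[["beta4"]], tp[["beta5"]],
                                     tp[["sigma"]]),
                     error_rate = error_rate, seed = agent_seed + 1L)
    }, error = function(e) stop(sprintf("agent %d simulation failed: %s",
                                        k, conditionMessage(e))))
    if (filter_rts) {
      trials <- filter_rt(trials)
    } else {
      trials$excluded <- FALSE
      trials$exclude_reason <- NA_character_
    }
    fit <- tryCatch(
      fit_hgf(trials, priors = priors, chains = chains, samples = samples,
              seed = agent_seed + 2L),
      error = function(e) stop(sprintf("agent %d fit failed: %s",
                                       k, conditionMessage(e))))
    s <- summary(fit)
    rows[[k]] <- data.frame(
      agent = k, parameter = s$parameter,
      true = as.numeric(tp[s$parameter]),
      mean = s$mean, sd = s$sd, ci_low = s$ci_low, ci_high = s$ci_high,
      covered = as.numeric(tp[s$parameter]) >= s$ci_low &
                as.numeric(tp[s$parameter]) <= s$ci_high,
      rhat_max = max(s$rhat)
    )
  }
  agents <- do.call(rbind, rows)
  smry <- do.call(rbind, lapply(split(agents, agents$parameter), function(d) {
    data.frame(parameter = d$parameter[1],
               correlation = if (stats::sd(d$true) > 0)
                 stats::cor(d$true, d$mean) else NA_real_,
               bias = mean(d$mean - d$true),
               rmse = sqrt(mean((d$mean - d$true)^2)),
               coverage = mean(d$covered))
  }))
  smry <- smry[match(.hgf_par_names, smry$parameter), ]
  rownames(smry) <- NULL
  structure(list(agents = agents, summary = smry, n_agents = n_agents,
                 seed = as.integer(seed)),
            class = "hgf_recovery")
}

#' @export
print.hgf_recovery <- function(x, ...) {
  cat(sprintf("Parameter recovery on %d simulated agents\n", x$n_agents))
  print(x$summary, digits = 3)
  cat(sprintf("overall 94%% CI coverage: %.3f\n", mean(x$agents$covered)))
  invisible(x)
}
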