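#' Response-model parameters
#'
#' The response model maps belief and task regressors onto log reaction
#' times through a linear predictor
#' `mu_rt = beta0 + beta1 * surprise + beta2 * u_expected +
#' beta3 * u_unexpected + beta4 * post_error + beta5 * post_reversal`,
#' and observed log-RTs are Gaussian around it with standard deviation
#' `sigma`.  All coefficients are in natural-log-millisecond units, so an
#' intercept near 5.8 corresponds to a baseline RT around 340 ms.
#'
#' @param beta0 Intercept (log-ms).
#' @param beta1 Weight of Shannon surprise.
#' @param beta2 Weight of expected uncertainty.
#' @param beta3 Weight of unexpected uncertainty.
#' @param beta4 Post-error slowing weight.
#' @param beta5 Post-reversal weight.
#' @param sigma Residual SD of log-RT; strictly positive.
#' @return An object of class `"response_params"`.
#' @examples
#' response_params(beta0 = 5.83, beta4 = 0.10, sigma = 0.2)
#' @export
response_params <- function(beta0 = 5.83, beta1 = 0, beta2 = 0, beta3 = 0,
                            beta4 = 0.10, beta5 = 0, sigma = 0.2) {
  if (!(is.finite(sigma) && sigma > 0)) stop("`sigma` must be strictly positive")
  betas <- c(beta0, beta1, beta2, beta3, beta4, beta5)
  if (any(!is.finite(betas))) stop("all beta coefficients must be finite")
  structure(list(beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
                 beta4 = beta4, beta5 = beta5, sigma = sigma),
            class = "response_params")
}

#' @export
print.response_params <- function(x, ...) {
  cat("Linear log-RT response model parameters:\n")
  print(unlist(x))
  invisible(x)
}

#' Flag reaction-time outliers for exclusion
#'
#' Applies the standard RT cleaning rules: missing responses are excluded;
#' anticipations faster than 200 ms are excluded; and, among the trials
#' that survive those rules, trials slower than the participant's mean plus
#' two standard deviations are excluded.  The slow rule is one-sided
#' because the fast tail is already handled by the 200 ms floor.  The rules
#' depend only on the raw `rt_ms` values, so re-filtering a filtered table
#' reproduces the same flags.
#'
#' @param trials Trial data frame with an `rt_ms` column.
#' @param fast_ms Fast cutoff in milliseconds (default 200).
#' @param sd_mult Multiplier of the SD for the slow cutoff (default 2).
#' @return `trials` with logical column `excluded` and character column
#'   `exclude_reason` (`"missing"`, `"fast"`, `"slow"`, or `NA`).
#' @examples
#' tab <- data.frame(rt_ms = c(150, rep(300, 50), 900))
#' subset(filter_rt(tab), excluded)$exclude_reason
#' @export
filter_rt <- function(trials, fast_ms = 200, sd_mult = 2) {
  rt <- trials$rt_ms
  reason <- rep(NA_character_, length(rt))
  reason[is.na(rt)] <- "missing"
  reason[!is.na(rt) & rt < fast_ms] <- "fast"
  keep <- is.na(reason)
  if (sum(keep) < 2L)
    stop("fewer than 2 valid trials remain; slow-outlier SD is undefined")
  m <- mean(rt[keep])
  s <- stats::sd(rt[keep])
  reason[keep & rt > m + sd_mult * s] <- "slow"
  trials$excluded <- !is.na(reason)
  trials$exclude_reason <- reason
  trials
}

#' Linear predictor of log reaction time
#'
#' @param regressors Regressor table from [regressor_table()] (or any data
#'   frame with columns `surprise`, `u_expected`, `u_unexpected`,
#'   `post_error`, `post_reversal`).
#' @param params A [response_params()] object.
#' @return Numeric vector of predicted mean log-RTs (log-ms).
#' @examples
#' reg <- data.frame(surprise = 1, u_expected = 0.1, u_unexpected = 0.05,
#'                   post_error = 1, post_reversal = 0)
#' mu_rt(reg, response_params(5.8, 0.05, -0.02, -0.15, 0.10, -0.01))
#' @export
mu_rt <- function(regressors, params) {
  stopifnot(inherits(params, "response_params"))
  params$beta0 +
    params$beta1 * regressors$surprise +
    params$beta2 * regressors$u_expected +
    params$beta3 * regressors$u_unexpected +
    params$beta4 * regressors$post_error +
    params$beta5 * regressors$post_reversal
}

#' Gaussian log-likelihood of observed log reaction times
#'
#' Sums the normal log-density of `log(rt_ms)` around the linear predictor
#' over the non-excluded trials.  Trials flagged by [filter_rt()] (or with
#' missing RT) do not contribute.
#'
#' @param trials Trial data frame with `rt_ms` and, optionally, the
#'   `excluded` flag from [filter_rt()].
#' @param regressors Aligned regressor table (see [mu_rt()]).
#' @param params A [response_params()] object.
#' @return The summed log-likelihood (a single number).
#' @export
rt_loglik <- function(trials, regressors, params) {
  stopifnot(inherits(params, "response_params"))
  if (params$sigma <= 0) stop("`sigma` must be strictly positive")
  if (nrow(trials) != nrow(regressors))
    stop("`trials` and `regressors` have different lengths")
  keep <- !is.na(trials$rt_ms)
  if (!is.null(trials$excluded)) keep <- keep & !trials$excluded
  mu <- mu_rt(regressors[keep, , drop = FALSE], params)
  sum(stats::dnorm(log(trials$rt_ms[keep]), mean = mu, sd = params$sigma,
                   log = TRUE))
}
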