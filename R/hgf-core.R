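#' Perceptual parameters of the categorical state-transition HGF
#'
#' The filter maintains one continuous node per ordered transition between
#' the four stimulus categories (a 4x4 array of 16 nodes), each holding a
#' Gaussian belief over the log-odds of that transition.  A single
#' log-volatility parameter `omega`, shared by all 16 nodes, controls how
#' fast those beliefs are expected to drift between trials: the predicted
#' volatility is `exp(omega)`, which is added to the belief variance in
#' every prediction step.  Initial beliefs are fixed, not estimated;
#' `omega` is the only free perceptual parameter.
#'
#' @param omega Log-volatility (unitless, log scale). More negative values
#'   mean a more stable world: less forgetting and smaller updates.
#' @param mu0 Initial belief mean for every node (default 0, i.e. log-odds
#'   of 0.5 before normalization).
#' @param pi0 Initial belief precision for every node (default 1); must be
#'   strictly positive.
#' @return An object of class `"hgf_params"`.
#' @examples
#' hgf_params(omega = -4)
#' @export
hgf_params <- function(omega = -4, mu0 = 0, pi0 = 1) {
  if (!is.finite(omega)) stop("`omega` must be finite")
  if (!(is.finite(pi0) && pi0 > 0)) stop("`pi0` must be strictly positive")
  if (!is.finite(mu0)) stop("`mu0` must be finite")
  structure(list(omega = omega, mu0 = mu0, pi0 = pi0), class = "hgf_params")
}

#' @export
print.hgf_params <- function(x, ...) {
  cat(sprintf(
    "Categorical state-transition HGF parameters: omega = %g, mu0 = %g, pi0 = %g\n",
    x$omega, x$mu0, x$pi0))
  invisible(x)
}

# Numerical guards shared by the R reference path and documentation;
# the C++ filter applies the same constants.
.hgf_exp_cap <- 1e12
.hgf_pi_floor <- 1e-12

logistic <- function(x) {
  # branch-free stable logistic
  ifelse(x >= 0, 1 / (1 + exp(-x)), exp(x) / (1 + exp(x)))
}

#' Initialise the 4x4 transition-node network
#'
#' @param params An [hgf_params()] object.
#' @return A list with 4x4 matrices `mu` and `pi` (rows: from-category,
#'   columns: to-category).
#' @examples
#' net <- hgf_init(hgf_params())
#' normalized_prediction(net$mu)  # uniform 0.25 everywhere
#' @export
hgf_init <- function(params) {
  stopifnot(inherits(params, "hgf_params"))
  dn <- list(from = as.character(1:4), to = as.character(1:4))
  list(mu = matrix(params$mu0, 4, 4, dimnames = dn),
       pi = matrix(params$pi0, 4, 4, dimnames = dn))
}

#' Prediction step for a transition node
#'
#' Time passes: the mean prediction carries the posterior mean forward
#' (no drift), while the predicted precision shrinks because the predicted
#' volatility `exp(omega)` is added to the belief variance:
#' `pi_hat = 1 / (1/pi + exp(omega))`.
#'
#' @param mu,pi Posterior mean and precision of the node.
#' @param params An [hgf_params()] object supplying `omega`.
#' @return A list with `mu_hat` and `pi_hat`.
#' @examples
#' hgf_predict(mu = 0.3, pi = 2, hgf_params(omega = -2))$pi_hat  # ~1.5740
#' @export
hgf_predict <- function(mu, pi, params) {
  stopifnot(inherits(params, "hgf_params"))
  if (any(pi <= 0)) stop("precision must be strictly positive")
  vol <- min(exp(params$omega), .hgf_exp_cap)
  pi_hat <- pmax(1 / (1 / pi + vol), .hgf_pi_floor)
  list(mu_hat = mu, pi_hat = pi_hat)
}

#' Observation update for a transition node with a binary child
#'
#' The binary child of node (i, j) is 1 when transition i -> j occurred and
#' 0 when it did not.  The predicted outcome probability is
#' `b_hat = logistic(mu_hat)`; the prediction error `delta = observed -
#' b_hat` is precision-weighted into the mean, and the outcome variance
#' `b_hat (1 - b_hat)` sharpens the precision:
#' `pi = pi_hat + b_hat (1 - b_hat)`, `mu = mu_hat + delta / pi`.
#'
#' @param mu_hat,pi_hat Predicted mean and precision from [hgf_predict()].
#' @param observed 0 or 1.
#' @return A list with `mu`, `pi`, `delta`, `b_hat`.
#' @examples
#' hgf_update(mu_hat = 0, pi_hat = 1, observed = 1)  # delta 0.5, mu 0.4
#' @export
hgf_update <- function(mu_hat, pi_hat, observed) {
  if (!all(observed %in% c(0, 1))) stop("`observed` must be 0 or 1")
  if (any(pi_hat <= 0)) stop("predicted precision must be strictly positive")
  b_hat <- logistic(mu_hat)
  delta <- observed - b_hat
  pi <- pi_hat + b_hat * (1 - b_hat)
  list(mu = mu_hat + delta / pi, pi = pi, delta = delta, b_hat = b_hat)
}

#' Normalise predicted log-odds into transition probabilities
#'
#' Each belief mean is passed through the logistic function and the rows
#' (from-categories) are renormalised so that the four continuations of
#' each category form a probability distribution.
#'
#' @param mu_hat 4x4 matrix of predicted belief means.
#' @return 4x4 matrix of transition probabilities; rows sum to 1.
#' @examples
#' normalized_prediction(matrix(0, 4, 4))  # all 0.25
#' @export
normalized_prediction <- function(mu_hat) {
  s <- logistic(mu_hat)
  sweep(s, 1, rowSums(s), "/")
}

#' Run the categorical state-transition HGF over a stimulus stream
#'
#' For every trial after the first of a session, all 16 nodes take a
#' prediction step (time passes for unobserved transitions too), the
#' predicted transition matrix is normalised, and the four nodes of the row
#' belonging to the previous stimulus are updated with a binary observation
#' (1 for the transition that occurred, 0 for its three siblings).  Nodes in
#' inactive rows adopt their prediction as the new posterior.  The first
#' trial of each session has no incoming transition: it records the current
#' normalised prediction and performs no update.
#'
#' @param stimuli Integer vector of stimulus categories in 1--4.
#' @param params An [hgf_params()] object.
#' @param session Optional vector of session labels aligned with `stimuli`;
#'   a change of label marks a session boundary (context reset, no update
#'   on the boundary trial).  Default: one single session.
#' @return An object of class `"hgf_trajectory"`: a list with `n_trials`,
#'   per-trial 4x4 slices `mu`, `pi`, `mu_hat`, `pi_hat`, `delta` (arrays
#'   `[trial, from, to]`; `delta` is `NA` on nodes not updated that trial),
#'   `prediction` (normalised predicted transition matrices), `from`/`to`
#'   (the observed transition, `NA` on session-initial trials), and the
#'   regressors `surprise`, `u_expected`, `u_unexpected`.
#' @examples
#' traj <- hgf_filter(c(1, 4, 3, 2, 4), hgf_params(omega = -4))
#' traj$prediction[3, , ]  # predicted transition matrix before trial 3
#' @export
hgf_filter <- function(stimuli, params, session = NULL) {
  stopifnot(inherits(params, "hgf_params"))
  stimuli <- as.integer(stimuli)
  if (any(is.na(stimuli)) || any(!(stimuli %in% 1:4)))
    stop("stimuli must be category codes in 1..4")
  n <- length(stimuli)
  if (n < 1L) stop("empty stimulus stream")
  new_session <- if (is.null(session)) {
    c(TRUE, rep(FALSE, n - 1L))
  } else {
    if (length(session) != n) stop("`session` must align with `stimuli`")
    c(TRUE, session[-1L] != session[-n])
  }
  res <- hgf_filter_cpp(stimuli, as.logical(new_session),
                        params$omega, params$mu0, params$pi0)
  dn <- list(NULL, as.character(1:4), as.character(1:4))
  for (nm in c("mu", "pi", "mu_hat", "pi_hat", "delta", "prediction")) {
    dim(res[[nm]]) <- c(n, 4L, 4L)
    dimnames(res[[nm]]) <- dn
  }
  res$n_trials <- n
  res$stimuli <- stimuli
  res$new_session <- as.logical(new_session)
  res$params <- params
  class(res) <- "hgf_trajectory"
  res
}

#' @export
print.hgf_trajectory <- function(x, ...) {
  cat(sprintf(
    "Categorical state-transition HGF trajectory: %d trials, omega = %g\n",
    x$n_trials, x$params$omega))
  cat(sprintf("  mean surprise: %.3f nats (ln 4 = %.3f at chance)\n",
              mean(x$surprise), log(4)))
  cat("  final predicted transition matrix:\n")
  print(round(x$prediction[x$n_trials, , ], 3))
  invisible(x)
}

#' Plot the inferred transition probabilities over trials
#'
#' One line per transition (16 in total), showing how the normalised
#' predicted probability of each category-to-category transition evolves.
#'
#' @param x An `"hgf_trajectory"`.
#' @param from Optional from-category (1--4) to restrict the panel to one
#'   row of the transition matrix.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the matrix of plotted probabilities.
#' @export
plot.hgf_trajectory <- function(x, from = NULL, ...) {
  p <- matrix(x$prediction, x$n_trials, 16L)
  labs <- as.vector(outer(1:4, 1:4, function(i, j) sprintf("%d>%d", i, j)))
  if (!is.null(from)) {
    keep <- as.vector(outer(1:4, 1:4, function(i, j) i == from))
    p <- p[, keep, drop = FALSE]
    labs <- labs[keep]
  }
  graphics::matplot(p, type = "l", lty = 1, xlab = "trial",
                    ylab = "predicted transition probability", ...)
  graphics::legend("topright", legend = labs, col = seq_len(ncol(p)),
                   lty = 1, cex = 0.6, ncol = 4, bty = "n")
  invisible(p)
}

#' Export a belief trajectory as a long table
#'
#' @param traj An `"hgf_trajectory"`.
#' @return A data frame with one row per trial x node: `trial`, `from`,
#'   `to`, `mu`, `pi`, `mu_hat`, `pi_hat`, `delta`.
#' @export
trajectory_table <- function(traj) {
  stopifnot(inherits(traj, "hgf_trajectory"))
  n <- traj$n_trials
  grid <- expand.grid(trial = seq_len(n), from = 1:4, to = 1:4)
  grid <- grid[order(grid$trial, grid$from, grid$to), ]
  idx <- cbind(grid$trial, grid$from, grid$to)
  data.frame(grid,
             mu = traj$mu[idx], pi = traj$pi[idx],
             mu_hat = traj$mu_hat[idx], pi_hat = traj$pi_hat[idx],
             delta = traj$delta[idx], row.names = NULL)
}
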