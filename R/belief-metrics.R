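#' Shannon surprise of an observed category
#'
#' The unexpectedness of the observation under the model's one-step-ahead
#' prediction: the negative natural log of the predicted probability of the
#' category that occurred (in nats).
#'
#' @param predicted_row Probability vector over the four categories (a row
#'   of the normalised predicted transition matrix); must sum to 1.
#' @param observed Observed category in 1--4.
#' @return Nonnegative surprise in nats.
#' @examples
#' surprise(rep(0.25, 4), 3)              # ln 4
#' surprise(c(0.1, 0.2, 0.3, 0.4), 4)     # -ln 0.4
#' @export
surprise <- function(predicted_row, observed) {
  if (length(predicted_row) != 4L || abs(sum(predicted_row) - 1) > 1e-6)
    stop("`predicted_row` must be four probabilities summing to 1")
  if (!(observed %in% 1:4)) stop("`observed` must be a category in 1..4")
  p <- predicted_row[observed]
  if (p <= 0) stop("predicted probability of the observed category is 0")
  -log(p)
}

#' Expected uncertainty of a transition belief
#'
#' The outcome variance of the predicted binary transition,
#' `S(mu_hat) (1 - S(mu_hat))`, scaled by the imprecision `1/pi` of the
#' belief about that transition's log-odds.  It is largest when the belief
#' mean sits at 0 (transition probability 0.5) and shrinks as the belief
#' sharpens.
#'
#' @param mu_hat Predicted belief mean (log-odds).
#' @param pi Belief precision (strictly positive); the filter evaluates it
#'   at the predicted precision of the current trial, so the quantity is
#'   available before the outcome.
#' @return Nonnegative expected uncertainty.
#' @examples
#' expected_uncertainty(0, 4)  # 0.0625
#' @export
expected_uncertainty <- function(mu_hat, pi) {
  if (any(pi <= 0)) stop("`pi` must be strictly positive")
  s <- logistic(mu_hat)
  s * (1 - s) / pi
}

#' Unexpected uncertainty of a transition belief
#'
#' Expected uncertainty amplified by the predicted environmental volatility
#' `exp(omega)`: uncertainty the agent attributes to the world changing
#' rather than to noisy outcomes.
#'
#' @inheritParams expected_uncertainty
#' @param omega Log-volatility.
#' @return Nonnegative unexpected uncertainty, equal to
#'   `expected_uncertainty(mu_hat, pi) * exp(omega)`.
#' @examples
#' unexpected_uncertainty(0, 4, omega = log(2))  # 0.125
#' @export
unexpected_uncertainty <- function(mu_hat, pi, omega) {
  expected_uncertainty(mu_hat, pi) * exp(omega)
}

#' Assemble the trial-wise regressor table for the response model
#'
#' Combines the belief regressors recorded by [hgf_filter()] (surprise,
#' expected and unexpected uncertainty) with the task regressors: post-error
#' (the previous trial of the same session was incorrect or missed) and
#' post-reversal (the trial belongs to the post-reversal session).  The
#' first trial of each session has `post_error = 0` and surprise `ln 4`
#' (the uniform fallback prediction; no transition is defined there, so
#' both uncertainty regressors are 0).
#'
#' @param trajectory An `"hgf_trajectory"` from [hgf_filter()].
#' @param trials Trial data frame aligned with the trajectory (columns
#'   `session` and `correct`; `rt_ms` optional).
#' @return A data frame with columns `trial`, `surprise`, `u_expected`,
#'   `u_unexpected`, `post_error`, `post_reversal`.
#' @export
regressor_table <- function(trajectory, trials) {
  stopifnot(inherits(trajectory, "hgf_trajectory"))
  n <- trajectory$n_trials
  if (nrow(trials) != n)
    stop("`trials` and `trajectory` have different lengths")
  correct <- trials$correct
  # a missed response (NA) counts as an error for the post-error regressor
  err <- is.na(correct) | !correct
  post_error <- c(FALSE, err[-n])
  post_error[trajectory$new_session] <- FALSE
  post_reversal <- as.integer(trials$session == "post")
  data.frame(
    trial = seq_len(n),
    surprise = trajectory$surprise,
    u_expected = trajectory$u_expected,
    u_unexpected = trajectory$u_unexpected,
    post_error = as.integer(post_error),
    post_reversal = post_reversal
  )
}

#' Participant-level mean high-level prediction error
#'
#' For each of the 16 transition nodes, the absolute prediction errors
#' `|delta|` over the trials on which that node was updated are averaged;
#' the node means are then averaged into a single participant-level summary
#' of the magnitude of belief updating.
#'
#' @param trajectory An `"hgf_trajectory"`.
#' @return A single nonnegative number.
#' @export
participant_mean_pe <- function(trajectory) {
  stopifnot(inherits(trajectory, "hgf_trajectory"))
  node_means <- apply(abs(trajectory$delta), c(2, 3), mean, na.rm = TRUE)
  if (any(!is.finite(node_means)))
    stop("at least one transition node was never updated")
  mean(node_means)
}
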