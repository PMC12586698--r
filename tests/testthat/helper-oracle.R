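# Independent straight-line re-implementation of the transition filter,
# written with explicit loops and no shared code with the package internals.
# Used as the oracle for equivalence tests.
oracle_filter <- function(stimuli, omega, mu0 = 0, pi0 = 1,
                          new_session = NULL) {
  n <- length(stimuli)
  if (is.null(new_session)) new_session <- c(TRUE, rep(FALSE, n - 1))
  mu <- matrix(mu0, 4, 4)
  pi <- matrix(pi0, 4, 4)
  out <- list(mu = array(NA_real_, c(n, 4, 4)), pi = array(NA_real_, c(n, 4, 4)),
              mu_hat = array(NA_real_, c(n, 4, 4)),
              pi_hat = array(NA_real_, c(n, 4, 4)),
              delta = array(NA_real_, c(n, 4, 4)),
              prediction = array(NA_real_, c(n, 4, 4)),
              surprise = numeric(n), u_expected = numeric(n),
              u_unexpected = numeric(n))
  for (t in seq_len(n)) {
    mu_hat <- matrix(NA_real_, 4, 4)
    pi_hat <- matrix(NA_real_, 4, 4)
    for (i in 1:4) for (j in 1:4) {
      mu_hat[i, j] <- mu[i, j]
      pi_hat[i, j] <- 1 / (1 / pi[i, j] + exp(omega))
    }
    pred <- matrix(NA_real_, 4, 4)
    for (i in 1:4) {
      rs <- 0
      for (j in 1:4) rs <- rs + plogis(mu_hat[i, j])
      for (j in 1:4) pred[i, j] <- plogis(mu_hat[i, j]) / rs
    }
    if (new_session[t]) {
      out$surprise[t] <- log(4)
      out$u_expected[t] <- 0
      out$u_unexpected[t] <- 0
      mu <- mu_hat
      pi <- pi_hat
    } else {
      i <- stimuli[t - 1]
      j <- stimuli[t]
      out$surprise[t] <- -log(pred[i, j])
      s_ij <- plogis(mu_hat[i, j])
      out$u_expected[t] <- s_ij * (1 - s_ij) / pi_hat[i, j]
      out$u_unexpected[t] <- out$u_expected[t] * exp(omega)
      mu_new <- mu_hat
      pi_new <- pi_hat
      for (jj in 1:4) {
        b <- plogis(mu_hat[i, jj])
        d <- as.numeric(jj == j) - b
        pi_new[i, jj] <- pi_hat[i, jj] + b * (1 - b)
        mu_new[i, jj] <- mu_hat[i, jj] + d / pi_new[i, jj]
        out$delta[t, i, jj] <- d
      }
      mu <- mu_new
      pi <- pi_new
    }
    out$mu[t, , ] <- mu
    out$pi[t, , ] <- pi
    out$mu_hat[t, , ] <- mu_hat
    out$pi_hat[t, , ] <- pi_hat
    out$prediction[t, , ] <- pred
  }
  out
}

# small simulated participant shared by inference tests
make_small_agent <- function(trials_per_session = 240, omega = -4,
                             resp = response_params(5.83, 0.05, -0.02, -0.15,
                                                    0.10, -0.01, sigma = 0.2),
                             seed = 1) {
  spec <- sequence_spec(trials_per_session = trials_per_session)
  simulate_agent(generate_task(spec, seed = seed), hgf_params(omega = omega),
                 resp, seed = seed + 1)
}
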