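test_that("network initialisation has 16 nodes and a uniform prediction", {
  net <- hgf_init(hgf_params(omega = -4))
  expect_equal(dim(net$mu), c(4L, 4L))
  expect_equal(length(net$mu), 16L)
  expect_true(all(net$mu == 0) && all(net$pi == 1))
  expect_equal(unname(normalized_prediction(net$mu)),
               matrix(0.25, 4, 4))
  expect_error(hgf_params(pi0 = 0), "pi0")
  expect_error(hgf_params(omega = Inf), "omega")
})

test_that("prediction step matches its closed form", {
  # omega = 0: predicted volatility exp(0) = 1
  p <- hgf_predict(mu = 0.5, pi = 2, hgf_params(omega = 0))
  expect_equal(p$pi_hat, 1 / (1 / 2 + 1))
  expect_equal(p$mu_hat, 0.5)
  # derived closed-form value
  p <- hgf_predict(mu = 0.3, pi = 2, hgf_params(omega = -2))
  expect_equal(p$pi_hat, 1 / (0.5 + exp(-2)), tolerance = 1e-12)
  expect_equal(round(p$pi_hat, 4), 1.5740)
  # omega -> -Inf limit: no forgetting (pi_hat -> pi)
  p <- hgf_predict(mu = 0.3, pi = 2, hgf_params(omega = -700))
  expect_equal(p$pi_hat, 2, tolerance = 1e-9)
  # pi_hat always strictly below the prior precision for finite volatility
  p <- hgf_predict(mu = 0, pi = 5, hgf_params(omega = -4))
  expect_lt(p$pi_hat, 5)
  expect_error(hgf_predict(mu = 0, pi = -1, hgf_params(-4)), "positive")
})

test_that("binary observation update matches its closed form", {
  u <- hgf_update(mu_hat = 0, pi_hat = 1, observed = 1)
  expect_equal(u$b_hat, 0.5)
  expect_equal(u$delta, 0.5)
  expect_equal(u$pi, 1.25)
  expect_equal(u$mu, 0.4)
  # mirror symmetry of the logistic about 0
  u0 <- hgf_update(mu_hat = 0, pi_hat = 1, observed = 0)
  expect_equal(u0$mu, -0.4)
  # posterior precision always exceeds predicted precision
  for (mh in c(-2, 0, 3)) {
    u <- hgf_update(mh, pi_hat = 0.7, observed = 1)
    expect_gt(u$pi, 0.7)
    expect_equal(sign(u$mu - mh), sign(u$delta))
    expect_lte(abs(u$delta), 1)
  }
  # update magnitude decreases with predicted precision at fixed delta
  lo <- hgf_update(0, pi_hat = 0.5, observed = 1)
  hi <- hgf_update(0, pi_hat = 5, observed = 1)
  expect_gt(abs(lo$mu - 0), abs(hi$mu - 0))
  expect_error(hgf_update(0, 1, observed = 0.5), "0 or 1")
})

test_that("normalised prediction is a proper, monotone probability map", {
  m <- matrix(rnorm(16), 4, 4)
  p <- normalized_prediction(m)
  expect_equal(unname(rowSums(p)), rep(1, 4), tolerance = 1e-12)
  expect_true(all(p > 0 & p < 1))
  # direct evaluation against logistic + normalize
  expect_equal(p[2, 3], plogis(m[2, 3]) / sum(plogis(m[2, ])),
               tolerance = 1e-12)
  # increasing one belief raises its probability, lowers its row siblings
  m2 <- m
  m2[1, 2] <- m[1, 2] + 1
  p2 <- normalized_prediction(m2)
  expect_gt(p2[1, 2], p[1, 2])
  expect_true(all(p2[1, -2] < p[1, -2]))
  expect_equal(p2[3, ], p[3, ])
})

test_that("a single observed transition updates only the active row", {
  omega <- -4
  traj <- hgf_filter(c(1L, 4L), hgf_params(omega))
  # two prediction steps from pi0 = 1 before the trial-2 update
  pi_hat <- 1 / (1 + 2 * exp(omega))
  # node (1,4) saw outcome 1; its siblings in row 1 saw 0
  expect_equal(traj$delta[2, 1, 4], 0.5)
  expect_equal(traj$delta[2, 1, 1], -0.5)
  expect_equal(traj$pi[2, 1, 4], pi_hat + 0.25, tolerance = 1e-12)
  expect_equal(traj$mu[2, 1, 4], 0.5 / (pi_hat + 0.25), tolerance = 1e-12)
  expect_equal(traj$mu[2, 1, 2], -0.5 / (pi_hat + 0.25), tolerance = 1e-12)
  # rows 2-4 keep their prediction as posterior
  expect_true(all(traj$mu[2, 2:4, ] == 0))
  expect_true(all(is.na(traj$delta[2, 2:4, ])))
  expect_error(hgf_filter(c(1L, 5L), hgf_params(omega)), "1..4")
})

test_that("filter matches the straight-line oracle on a printed-sequence prefix", {
  stimuli <- srt_sequences()$a[1:20]
  for (omega in c(-6, -4, -2)) {
    traj <- hgf_filter(stimuli, hgf_params(omega))
    orc <- oracle_filter(stimuli, omega)
    for (f in c("mu", "pi", "mu_hat", "pi_hat", "prediction",
                "surprise", "u_expected", "u_unexpected")) {
      expect_equal(unname(as.array(traj[[f]])), unname(orc[[f]]),
                   tolerance = 1e-10, ignore_attr = TRUE)
    }
    expect_equal(unname(as.array(traj$delta)), orc$delta,
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("filter matches the oracle on random multi-session streams", {
  set.seed(31)
  for (rep in 1:3) {
    stimuli <- sample(1:4, 40, replace = TRUE)
    session <- rep(c("pre", "post"), each = 20)
    traj <- hgf_filter(stimuli, hgf_params(-3), session = session)
    orc <- oracle_filter(stimuli, -3,
                         new_session = seq_along(stimuli) %in% c(1, 21))
    expect_equal(unname(as.array(traj$prediction)), orc$prediction,
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(traj$surprise, orc$surprise, tolerance = 1e-10)
    expect_equal(unname(as.array(traj$mu)), orc$mu, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("a transition that never occurs is learned away", {
  # repeated cycling through sequence A never produces 1 -> 1
  stimuli <- rep(srt_sequences()$a, 10)
  traj <- hgf_filter(stimuli, hgf_params(-4))
  p11 <- traj$prediction[, 1, 1]
  expect_lt(p11[length(p11)], 0.05)
  expect_lt(p11[length(p11)], p11[3])
})

test_that("strict alternation drives its transition probabilities toward 1", {
  stimuli <- rep(c(1L, 2L), 150)
  traj <- hgf_filter(stimuli, hgf_params(-4))
  p21 <- traj$prediction[, 1, 2]  # p(2 | 1)
  p12 <- traj$prediction[, 2, 1]  # p(1 | 2)
  expect_gt(p21[300], 0.95)
  expect_gt(p12[300], 0.95)
  # monotone growth of the predicted probability across trials
  expect_true(all(diff(p21[3:300]) > -1e-12))
})

test_that("predictions stay normalised and precisions ordered on task streams", {
  trials <- generate_task(sequence_spec(trials_per_session = 240L), seed = 13)
  traj <- hgf_filter(trials$stimulus, hgf_params(-4),
                     session = trials$session)
  n <- traj$n_trials
  row_sums <- apply(traj$prediction, c(1, 2), sum)
  expect_lt(max(abs(row_sums - 1)), 1e-9)
  expect_true(all(traj$prediction > 0 & traj$prediction < 1))
  expect_true(all(traj$pi > 0) && all(traj$pi_hat > 0))
  # prediction loses precision relative to the previous posterior
  expect_true(all(traj$pi_hat[2:n, , ] < traj$pi[1:(n - 1), , ]))
  # observation updates gain precision over the prediction
  expect_true(all(traj$pi >= traj$pi_hat))
  expect_true(all(abs(traj$delta) <= 1, na.rm = TRUE))
})

test_that("larger volatility means less precision and larger updates", {
  stimuli <- rep(srt_sequences()$a, 3)
  lo <- hgf_filter(stimuli, hgf_params(-5))
  hi <- hgf_filter(stimuli, hgf_params(-2))
  expect_true(all(hi$pi_hat < lo$pi_hat))
  step_lo <- abs(lo$mu - lo$mu_hat)[!is.na(lo$delta)]
  step_hi <- abs(hi$mu - hi$mu_hat)[!is.na(hi$delta)]
  expect_true(all(step_hi > step_lo))
})

test_that("without observations precision decays along its closed form", {
  # k prediction steps take pi0 to 1/(1/pi0 + k exp(omega)), approaching
  # the map's fixed point at 0
  omega <- -2
  stimuli <- rep(c(2L, 3L, 4L), 40)  # row 1 never active as from-category
  traj <- hgf_filter(stimuli, hgf_params(omega, pi0 = 1))
  k <- 60
  expect_equal(traj$pi[k, 1, 1], 1 / (1 + k * exp(omega)), tolerance = 1e-10)
  expect_true(all(diff(traj$pi[, 1, 1]) < 0))
})

test_that("trajectory export is aligned with the filter state", {
  traj <- hgf_filter(c(1L, 4L, 2L), hgf_params(-3))
  tab <- trajectory_table(traj)
  expect_equal(nrow(tab), 3L * 16L)
  expect_equal(names(tab),
               c("trial", "from", "to", "mu", "pi", "mu_hat", "pi_hat", "delta"))
  r <- tab[tab$trial == 2 & tab$from == 1 & tab$to == 4, ]
  expect_equal(r$mu, traj$mu[2, 1, 4])
  expect_equal(r$delta, traj$delta[2, 1, 4])
})
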