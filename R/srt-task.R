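#' Default second-order conditional sequences of the four-choice SRT task
#'
#' The probabilistic serial reaction time (SRT) task draws its stimuli from
#' two second-order conditional (SOC) sequences over the categories 1--4.
#' In a SOC sequence the ordered pair of the two preceding stimuli uniquely
#' determines the next stimulus, so learning requires tracking transitions,
#' not single-item frequencies.  The two sequences share the same 12 ordered
#' pairs of distinct categories but continue each pair differently, and
#' neither contains an immediate repetition of a category.
#'
#' @return A list with integer vectors `a` and `b`, each of length 24.
#' @examples
#' srt_sequences()$a
#' @export
srt_sequences <- function() {
  list(
    a = c(1L, 2L, 1L, 4L, 3L, 2L, 4L, 1L, 3L, 4L, 2L, 3L,
          1L, 2L, 1L, 4L, 3L, 2L, 4L, 1L, 3L, 4L, 2L, 3L),
    b = c(1L, 3L, 2L, 3L, 4L, 1L, 2L, 4L, 3L, 1L, 4L, 2L,
          1L, 3L, 2L, 3L, 4L, 1L, 2L, 4L, 3L, 1L, 4L, 2L)
  )
}

#' Specify the probabilistic SRT task
#'
#' Bundles the two deciding SOC sequences with the probability of following
#' the high-probability sequence and the session layout.  In session `"pre"`
#' sequence A is the high-probability generator; after the reversal
#' (session `"post"`) the roles of the two sequences are swapped.
#'
#' @param sequence_a,sequence_b Integer vectors of category labels in 1--4;
#'   each must be a valid SOC sequence (see [srt_sequences()]) and both must
#'   cover the same set of ordered pairs.
#' @param p_high Probability that a trial continues the currently
#'   high-probability sequence (default 0.85).
#' @param trials_per_session Number of trials in each session (default 960).
#' @param n_sessions Number of sessions (default 2; session 2 has the
#'   sequence roles reversed).
#' @return An object of class `"sequence_spec"`.
#' @examples
#' spec <- sequence_spec()
#' spec$p_high
#' @export
sequence_spec <- function(sequence_a = srt_sequences()$a,
                          sequence_b = srt_sequences()$b,
                          p_high = 0.85,
                          trials_per_session = 960L,
                          n_sessions = 2L) {
  sequence_a <- as.integer(sequence_a)
  sequence_b <- as.integer(sequence_b)
  # p_high = 1 is allowed as the degenerate deterministic case
  if (!(is.numeric(p_high) && length(p_high) == 1L && p_high > 0 && p_high <= 1))
    stop("`p_high` must be a single probability in (0, 1]")
  if (trials_per_session < 3L)
    stop("`trials_per_session` must be at least 3")
  map_a <- build_pair_map(sequence_a)
  map_b <- build_pair_map(sequence_b)
  if (!setequal(names(map_a), names(map_b)))
    stop("the two sequences must cover the same set of ordered category pairs")
  structure(
    list(sequence_a = sequence_a, sequence_b = sequence_b,
         p_high = p_high,
         trials_per_session = as.integer(trials_per_session),
         n_sessions = as.integer(n_sessions),
         pair_map_a = map_a, pair_map_b = map_b),
    class = "sequence_spec"
  )
}

#' @export
print.sequence_spec <- function(x, ...) {
  cat("Probabilistic SRT task specification\n")
  cat("  sequence A:", paste(x$sequence_a[1:12], collapse = "-"), "...\n")
  cat("  sequence B:", paste(x$sequence_b[1:12], collapse = "-"), "...\n")
  cat(sprintf("  p(high-probability continuation): %.2f\n", x$p_high))
  cat(sprintf("  sessions: %d x %d trials (roles swapped after session 1)\n",
              x$n_sessions, x$trials_per_session))
  invisible(x)
}

pair_key <- function(i, j) paste(i, j, sep = ",")

#' Build the pair-to-successor map of a SOC sequence
#'
#' Treats the sequence as cyclic and records, for every ordered pair of
#' consecutive categories, the category that follows it.  For a valid SOC
#' sequence this mapping is a function: a pair never has two different
#' successors.
#'
#' @param sequence Integer vector of category labels in 1--4.
#' @return A named integer vector; names are `"i,j"` pair keys, values the
#'   successor category.
#' @examples
#' build_pair_map(srt_sequences()$a)[["1,2"]]  # 1
#' build_pair_map(srt_sequences()$b)[["1,2"]]  # 4
#' @export
build_pair_map <- function(sequence) {
  sequence <- as.integer(sequence)
  n <- length(sequence)
  if (n < 3L) stop("sequence must have at least 3 elements")
  if (!all(sequence %in% 1:4))
    stop("sequence categories must be in 1..4")
  if (any(sequence == c(sequence[-1L], sequence[1L])))
    stop("sequence contains an immediate repetition of a category")
  map <- integer(0)
  for (t in seq_len(n)) {
    i <- sequence[if (t == 1L) n - 1L else if (t == 2L) n else t - 2L]
    j <- sequence[if (t == 1L) n else t - 1L]
    key <- pair_key(i, j)
    nxt <- sequence[t]
    if (!is.na(map[key]) && map[key] != nxt)
      stop(sprintf("pair (%d,%d) maps to both %d and %d: not a valid SOC sequence",
                   i, j, map[key], nxt))
    map[key] <- nxt
  }
  map
}

#' Generate the stimulus stream of one SRT session
#'
#' The first two stimuli seed the context with an ordered pair drawn
#' uniformly from the high-probability sequence's pairs.  Every subsequent
#' stimulus continues the current pair according to the high-probability
#' sequence with probability `p_high`, and according to the low-probability
#' sequence otherwise.  In session `"post"` the roles of sequences A and B
#' are swapped.
#'
#' @param spec A [sequence_spec()].
#' @param session `"pre"` or `"post"`.
#' @param seed Integer seed fixing the random stream.
#' @return A data frame of trial records with columns `trial`, `session`,
#'   `stimulus`, `source` (`"high"`, `"low"`, or `NA` for the two context
#'   trials), `correct`, `rt_ms` (the last two `NA` until an agent is
#'   simulated).
#' @examples
#' s <- generate_session(sequence_spec(), "pre", seed = 1)
#' mean(s$source == "high", na.rm = TRUE)
#' @export
generate_session <- function(spec, session = c("pre", "post"), seed = 1L) {
  stopifnot(inherits(spec, "sequence_spec"))
  session <- match.arg(session)
  high_map <- if (session == "pre") spec$pair_map_a else spec$pair_map_b
  low_map  <- if (session == "pre") spec$pair_map_b else spec$pair_map_a
  n <- spec$trials_per_session

  set.seed(as.integer(seed))
  stim <- integer(n)
  src <- rep(NA_character_, n)
  pairs <- names(high_map)
  start <- strsplit(sample(pairs, 1L), ",", fixed = TRUE)[[1L]]
  stim[1:2] <- as.integer(start)
  use_high <- stats::runif(n) < spec$p_high
  for (t in 3:n) {
    key <- pair_key(stim[t - 2L], stim[t - 1L])
    if (is.na(high_map[key]) || is.na(low_map[key]))
      stop(sprintf("pair (%s) has no continuation in one of the sequences", key))
    if (use_high[t]) {
      stim[t] <- high_map[[key]]
      src[t] <- "high"
    } else {
      stim[t] <- low_map[[key]]
      src[t] <- "low"
    }
  }
  data.frame(trial = seq_len(n), session = session, stimulus = stim,
             source = src, correct = NA, rt_ms = NA_real_,
             stringsAsFactors = FALSE)
}

#' Generate the full two-session SRT task
#'
#' Sessions are generated independently (the context resets across the
#' between-session break) with the sequence roles reversed in session 2.
#' Trial indices run continuously across sessions.
#'
#' @inheritParams generate_session
#' @return A trial data frame covering all sessions (see
#'   [generate_session()]).
#' @export
generate_task <- function(spec = sequence_spec(), seed = 1L) {
  labels <- c("pre", "post")[seq_len(spec$n_sessions)]
  out <- do.call(rbind, lapply(seq_along(labels), function(k) {
    generate_session(spec, labels[k], seed = as.integer(seed) + (k - 1L) * 1009L)
  }))
  out$trial <- seq_len(nrow(out))
  out
}

#' Simulate an agent's responses on a stimulus stream
#'
#' Runs the categorical state-transition HGF on the stimuli, derives the
#' trial-wise belief regressors, and generates behaviour from the response
#' model: correctness is an exogenous Bernoulli process (the model does not
#' explain accuracy), and log reaction times are Gaussian around the linear
#' predictor, so `rt_ms = exp(N(mu_rt, sigma))`.
#'
#' @param trials Trial data frame from [generate_task()] (columns `trial`,
#'   `session`, `stimulus`).
#' @param hgf An [hgf_params()] object (perceptual parameters).
#' @param resp A [response_params()] object (response-model parameters).
#' @param error_rate Probability of an incorrect response on any trial
#'   (default 0.08, i.e. accuracy around 0.92).
#' @param seed Integer seed fixing the random stream.
#' @return `trials` with `correct` and `rt_ms` filled in.
#' @examples
#' trials <- generate_task(sequence_spec(trials_per_session = 120), seed = 1)
#' sim <- simulate_agent(trials, hgf_params(omega = -4),
#'                       response_params(), seed = 1)
#' head(sim$rt_ms)
#' @export
simulate_agent <- function(trials, hgf, resp, error_rate = 0.08, seed = 1L) {
  stopifnot(inherits(hgf, "hgf_params"), inherits(resp, "response_params"))
  if (!(error_rate >= 0 && error_rate < 1))
    stop("`error_rate` must be in [0, 1)")
  set.seed(as.integer(seed))
  n <- nrow(trials)
  trials$correct <- stats::runif(n) >= error_rate
  traj <- hgf_filter(trials$stimulus, hgf, session = trials$session)
  reg <- regressor_table(traj, trials)
  mu <- mu_rt(reg, resp)
  if (any(!is.finite(mu))) stop("non-finite response-model regressors")
  trials$rt_ms <- exp(stats::rnorm(n, mean = mu, sd = resp$sigma))
  trials
}
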