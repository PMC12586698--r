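#' Read a trial table from delimited text
#'
#' Expects a comma-separated file with a header row containing at least
#' `trial`, `session`, `stimulus`; `source`, `correct` and `rt_ms` are
#' optional and filled with `NA` when absent.  Unknown columns are
#' preserved.  Missing reaction times are parsed as missing, never as zero.
#'
#' @param path Path to the CSV file.
#' @return A trial data frame (see [generate_session()]).
#' @export
read_trials <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial", "session", "stimulus")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("trial table %s lacks required column(s): %s",
                 path, paste(miss, collapse = ", ")))
  for (opt in c("source", "correct", "rt_ms"))
    if (is.null(tab[[opt]])) tab[[opt]] <- NA
  bad <- which(!(tab$stimulus %in% 1:4))
  if (length(bad))
    stop(sprintf("invalid stimulus value %s in row %d (column `stimulus`)",
                 tab$stimulus[bad[1]], bad[1]))
  bad <- which(!(tab$session %in% c("pre", "post")))
  if (length(bad))
    stop(sprintf("invalid session label '%s' in row %d (column `session`)",
                 tab$session[bad[1]], bad[1]))
  if (any(!is.na(tab$rt_ms) & tab$rt_ms <= 0))
    stop("`rt_ms` must be positive when present")
  tab$stimulus <- as.integer(tab$stimulus)
  tab$correct <- as.logical(tab$correct)
  tab$rt_ms <- as.numeric(tab$rt_ms)
  tab
}

#' Write a trial table as delimited text
#'
#' @param trials Trial data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read or write model parameters as JSON
#'
#' The parameter file carries the log-volatility `omega` together with the
#' seven response-model fields (`beta0`--`beta5`, `sigma`).
#'
#' @param path JSON file path.
#' @return `read_params()`: a list with elements `hgf` ([hgf_params()]) and
#'   `response` ([response_params()]).
#' @export
read_params <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("omega", "beta0", "beta1", "beta2", "beta3", "beta4", "beta5",
            "sigma")
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop(sprintf("parameter file lacks field(s): %s",
                 paste(miss, collapse = ", ")))
  list(hgf = hgf_params(omega = p$omega,
                        mu0 = if (is.null(p$mu0)) 0 else p$mu0,
                        pi0 = if (is.null(p$pi0)) 1 else p$pi0),
       response = response_params(p$beta0, p$beta1, p$beta2, p$beta3,
                                  p$beta4, p$beta5, p$sigma))
}

#' @rdname read_params
#' @param hgf An [hgf_params()] object.
#' @param response A [response_params()] object.
#' @export
write_params <- function(hgf, response, path) {
  jsonlite::write_json(c(unclass(hgf), unclass(response)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# stable fingerprint of a configuration list, for output provenance
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Default pipeline configuration
#'
#' @param seed Master seed for all stages.
#' @param trials_per_session,p_high Task settings (see [sequence_spec()]).
#' @param omega,mu0,pi0 Perceptual parameters of the simulated agent.
#' @param response Named list of the seven response-model fields used for
#'   simulation.
#' @param error_rate Simulated error rate.
#' @param chains,samples MCMC settings for the fitting stage.
#' @param recover_agents Number of agents in the recovery stage (0 skips
#'   it).
#' @param out_dir Output directory.
#' @return A named list understood by [run_pipeline()].
#' @export
pipeline_config <- function(seed = 1L, trials_per_session = 960L,
                            p_high = 0.85, omega = -4, mu0 = 0, pi0 = 1,
                            response = list(beta0 = 5.83, beta1 = 0.05,
                                            beta2 = -0.02, beta3 = -0.15,
                                            beta4 = 0.10, beta5 = -0.01,
                                            sigma = 0.2),
                            error_rate = 0.08, chains = 4L, samples = 2000L,
                            recover_agents = 0L, out_dir = "hgfsrt-run") {
  list(seed = as.integer(seed), trials_per_session = as.integer(trials_per_session),
       p_high = p_high, omega = omega, mu0 = mu0, pi0 = pi0,
       response = response, error_rate = error_rate,
       chains = as.integer(chains), samples = as.integer(samples),
       recover_agents = as.integer(recover_agents), out_dir = out_dir)
}

.stage_log <- function(con, stage, t0, ...) {
  kv <- c(...)
  line <- sprintf("stage=%s elapsed_s=%.2f %s", stage,
                  as.numeric(Sys.time()) - t0,
                  paste(names(kv), kv, sep = "=", collapse = " "))
  writeLines(line, con)
  message(line)
}

#' Run the full simulate -> filter -> fit (-> recover) pipeline
#'
#' Executes the stages in order and writes every artifact to the output
#' directory: the simulated trial table, the belief trajectory, the
#' regressor table, the posterior summary, the recovery report (when
#' requested), and a log.  Each output is stamped with the configuration
#' hash, seed, and package version.  Stages fail fast with the stage name;
#' outputs written before a failure are kept.
#'
#' @param config A [pipeline_config()] list.
#' @return Invisibly, a list with the output paths and the in-memory stage
#'   results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  stamp <- c(config_hash = hash, seed = config$seed,
             package_version = as.character(utils::packageVersion("hgfsrt")))
  log_path <- file.path(config$out_dir, "pipeline.log")
  con <- file(log_path, "w")
  on.exit(close(con))
  writeLines(sprintf("# hgfsrt pipeline %s", paste(names(stamp), stamp,
                                                   sep = "=", collapse = " ")),
             con)
  stamp_file <- function(path) {
    # provenance header as a comment line understood by read.csv(comment.char)
    lines <- readLines(path)
    writeLines(c(sprintf("# %s", paste(names(stamp), stamp, sep = "=",
                                       collapse = " ")), lines), path)
  }
  run_stage <- function(stage, expr) {
    t0 <- as.numeric(Sys.time())
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
    .stage_log(con, stage, t0)
    out
  }

  rp <- do.call(response_params, config$response)
  hp <- hgf_params(config$omega, config$mu0, config$pi0)
  spec <- sequence_spec(p_high = config$p_high,
                        trials_per_session = config$trials_per_session)

  trials <- run_stage("simulate", {
    trials <- generate_task(spec, seed = config$seed)
    simulate_agent(trials, hp, rp, error_rate = config$error_rate,
                   seed = config$seed + 1L)
  })
  trials_path <- file.path(config$out_dir, "trials.csv")
  write_trials(trials, trials_path); stamp_file(trials_path)

  filt <- run_stage("filter", {
    traj <- hgf_filter(trials$stimulus, hp, session = trials$session)
    list(traj = traj, reg = regressor_table(traj, trials))
  })
  traj_path <- file.path(config$out_dir, "trajectory.csv")
  utils::write.csv(trajectory_table(filt$traj), traj_path, row.names = FALSE)
  stamp_file(traj_path)
  reg_path <- file.path(config$out_dir, "regressors.csv")
  utils::write.csv(filt$reg, reg_path, row.names = FALSE); stamp_file(reg_path)

  if (config$chains < 2L)
    warning("chains < 2: the Gelman-Rubin diagnostic is undefined across ",
            "chains and convergence assessment is degraded")
  fit <- run_stage("fit", fit_hgf(filter_rt(trials), chains = config$chains,
                                  samples = config$samples,
                                  seed = config$seed + 2L))
  post_path <- file.path(config$out_dir, "posterior.json")
  jsonlite::write_json(list(provenance = as.list(stamp),
                            summary = summary(fit),
                            accept = as.data.frame(fit$accept)),
                       post_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  .stage_log(con, "fit-diagnostics", as.numeric(Sys.time()),
             max_rhat = sprintf("%.4f", max(summary(fit)$rhat)),
             min_ess = sprintf("%.0f", min(summary(fit)$ess)))

  rec <- NULL
  if (config$recover_agents > 0L) {
    rec <- run_stage("recover",
                     recovery_study(config$recover_agents,
                                    trials_per_session = config$trials_per_session,
                                    chains = config$chains,
                                    samples = config$samples,
                                    seed = config$seed + 3L))
    rec_path <- file.path(config$out_dir, "recovery.csv")
    utils::write.csv(rec$agents, rec_path, row.names = FALSE)
    stamp_file(rec_path)
  }

  invisible(list(paths = list(trials = trials_path, trajectory = traj_path,
                              regressors = reg_path, posterior = post_path,
                              log = log_path),
                 trials = trials, trajectory = filt$traj,
                 regressors = filt$reg, fit = fit, recovery = rec))
}
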