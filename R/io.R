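#' Load and validate a simulation configuration
#'
#' Reads a YAML configuration describing one simulation: which task, the
#' learner parameters, the trial/replicate counts, and the per-task block.
#' Missing fields are filled with the reference defaults
#' `(alpha, epsilon, gamma, k_plus, k_minus) = (0.5, 0.3, 0, 0.9, 0.9)`,
#' `trials = 100`, `replicates = 30000`. Unknown keys are rejected (typo
#' safety), and every bound violation names the offending field.
#'
#' @param path Path to a YAML file.
#' @return A validated `cc_config` object.
#' @seealso [as_sim_config()] for programmatic construction,
#'   [dump_config()] for the inverse, [run_from_config()] to execute.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  as_sim_config(yaml::read_yaml(path))
}

#' @rdname load_config
#' @param x A named list with the same structure as the YAML file.
#' @export
as_sim_config <- function(x) {
  stopifnot(is.list(x))
  known <- c("task", "params", "trials", "replicates", "seed",
             "moments", "igt", "two_stage", "market", "outputs")
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         "; known keys are ", paste(known, collapse = ", "), call. = FALSE)
  task <- x$task %||% "stationary"
  if (!task %in% c("stationary", "igt", "two_stage", "market"))
    stop("`task` must be one of stationary, igt, two_stage, market; got ",
         task, call. = FALSE)
  pk <- c("alpha", "epsilon", "gamma", "k_plus", "k_minus")
  badp <- setdiff(names(x$params), pk)
  if (length(badp))
    stop("unknown params key(s): ", paste(badp, collapse = ", "), call. = FALSE)
  params <- do.call(critic_params, x$params %||% list())
  ok <- c("log_q", "log_u", "trials_csv")
  bado <- setdiff(names(x$outputs), ok)
  if (length(bado))
    stop("unknown outputs key(s): ", paste(bado, collapse = ", "), call. = FALSE)
  cfg <- list(
    task = task, params = params,
    trials = as.integer(x$trials %||% 100L),
    replicates = as.integer(x$replicates %||% 30000L),
    seed = as.integer(x$seed %||% 1L),
    moments = do.call(moment_spec, x$moments %||% list()),
    igt = if (is.null(x$igt)) deck_scheme() else do.call(deck_scheme, x$igt),
    two_stage = do.call(two_stage_layout, x$two_stage %||% list()),
    market = do.call(market_config, x$market %||% list()),
    outputs = list(log_q = isTRUE(x$outputs$log_q %||% TRUE),
                   log_u = isTRUE(x$outputs$log_u %||% TRUE),
                   trials_csv = isTRUE(x$outputs$trials_csv %||% FALSE))
  )
  if (cfg$trials < 1) stop("`trials` must be >= 1", call. = FALSE)
  if (cfg$replicates < 1) stop("`replicates` must be >= 1", call. = FALSE)
  structure(cfg, class = "cc_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a configuration back to YAML
#'
#' `load_config(dump_config(cfg, path))` is the identity.
#'
#' @param cfg A `cc_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "cc_config"))
  out <- list(
    task = cfg$task,
    params = unclass(cfg$params),
    trials = cfg$trials, replicates = cfg$replicates, seed = cfg$seed,
    moments = unclass(cfg$moments),
    igt = list(decks = cfg$igt$decks),
    two_stage = unclass(cfg$two_stage),
    market = unclass(cfg$market),
    outputs = cfg$outputs
  )
  out$two_stage$init_probs <- cfg$two_stage$init_probs
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Build the task environment described by a configuration
#'
#' @param cfg A `cc_config`.
#' @return A `cc_env`.
#' @export
build_env <- function(cfg) {
  stopifnot(inherits(cfg, "cc_config"))
  switch(cfg$task,
         stationary = stationary_env(cfg$moments),
         igt = igt_env(cfg$igt),
         two_stage = two_stage_env(cfg$two_stage),
         market = market_env(cfg$market))
}

#' Run the simulation described by a configuration
#'
#' @param cfg A `cc_config` (see [load_config()]).
#' @param seed Optional override of the configured seed.
#' @return A `cc_sim`.
#' @export
run_from_config <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "cc_config"))
  run_replicates(build_env(cfg), cfg$params,
                 n_trials = cfg$trials, n_reps = cfg$replicates,
                 seed = seed %||% cfg$seed,
                 log_q = cfg$outputs$log_q, log_u = cfg$outputs$log_u)
}

generic_summary <- function(sim) {
  df <- data.frame(
    trial = seq_len(sim$n_trials),
    mean_reward = colMeans(sim$reward),
    mean_d_q_plus = colMeans(sim$d_q_plus),
    mean_d_q_minus = colMeans(sim$d_q_minus),
    p_explore = colMeans(sim$explored)
  )
  if (!is.null(sim$q_plus) && sim$n_states == 1L && sim$n_actions == 1L) {
    df$mean_q_plus <- colMeans(sim$q_plus[, , 1, 1])
    df$mean_q_minus <- colMeans(sim$q_minus[, , 1, 1])
    if (!is.null(sim$q_neutral))
      df$mean_q_neutral <- colMeans(sim$q_neutral[, , 1, 1])
  }
  df
}

trials_long <- function(sim) {
  R <- sim$n_reps; T <- sim$n_trials
  df <- data.frame(
    replicate = rep(seq_len(R), T),
    trial = rep(seq_len(T), each = R),
    state = as.vector(sim$state),
    action = as.vector(sim$action),
    reward = as.vector(sim$reward),
    explored = as.vector(sim$explored),
    delta_plus = as.vector(sim$delta_plus),
    delta_minus = as.vector(sim$delta_minus),
    d_q_plus = as.vector(sim$d_q_plus),
    d_q_minus = as.vector(sim$d_q_minus)
  )
  for (f in names(sim$metadata)) df[[f]] <- as.vector(sim$metadata[[f]])
  df
}

#' Write simulation outputs to a directory
#'
#' Emits `summary.csv` (tidy per-trial replicate aggregates), optionally
#' `trials.csv` (the full long-format trial log), `config.json` (the
#' resolved run description and seed), a `manifest.json` inventory with an
#' MD5 hash per emitted file, and a plain-text `run.log`. Re-running the
#' same simulation into a fresh directory reproduces byte-identical CSVs.
#' Files are staged under temporary names and renamed at the end, so a
#' failure leaves no partial outputs.
#'
#' @param sim A `cc_sim`.
#' @param dir Output directory (created if needed).
#' @param trials_csv Also write the full trial log?
#' @return Named character vector of written paths (the inventory),
#'   invisibly.
#' @export
write_outputs <- function(sim, dir, trials_csv = FALSE) {
  stopifnot(inherits(sim, "cc_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir,
                             call. = FALSE)
  t0 <- Sys.time()
  staged <- character()
  stage <- function(name, writer) {
    tmp <- file.path(dir, paste0(".", name, ".tmp"))
    writer(tmp)
    staged[[name]] <<- tmp
  }
  ok <- FALSE
  on.exit(if (!ok) unlink(unlist(staged)))
  stage("summary.csv", function(p)
    utils::write.csv(generic_summary(sim), p, row.names = FALSE))
  if (trials_csv)
    stage("trials.csv", function(p)
      utils::write.csv(trials_long(sim), p, row.names = FALSE))
  stage("config.json", function(p)
    jsonlite::write_json(list(
      task = sim$env_name, params = unclass(sim$params),
      trials = sim$n_trials, replicates = sim$n_reps, seed = sim$seed,
      package_version = as.character(utils::packageVersion("competingcritics"))
    ), p, auto_unbox = TRUE, digits = NA, pretty = TRUE))
  final <- file.path(dir, names(staged))
  names(final) <- names(staged)
  for (nm in names(staged)) file.rename(staged[[nm]], final[[nm]])
  hashes <- tools::md5sum(final)
  names(hashes) <- names(staged)
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(
    created = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    seed = sim$seed, task = sim$env_name,
    files = as.list(hashes)
  ), manifest_path, auto_unbox = TRUE, pretty = TRUE)
  log_path <- file.path(dir, "run.log")
  writeLines(c(
    sprintf("task=%s replicates=%d trials=%d seed=%d", sim$env_name,
            sim$n_reps, sim$n_trials, sim$seed),
    sprintf("written=%s", paste(names(staged), collapse = ",")),
    sprintf("elapsed_s=%.3f", as.numeric(Sys.time() - t0, units = "secs"))
  ), log_path)
  ok <- TRUE
  invisible(c(final, manifest = manifest_path, log = log_path))
}
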