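#' Run seeded replicates of the competing-critics learner on a task
#'
#' Advances `n_reps` independent simulations in lock-step through `n_trials`
#' decisions. Each trial follows the model's decision loop: draw a uniform
#' utility `U(a) ~ Unif[Q-(S,a), Q+(S,a)]` for every available action, select
#' an action by epsilon-greedy over the draws, step the environment, compute
#' both prediction errors from the pre-update tables, then apply the
#' asymmetric updates (and the risk-neutral reference update) simultaneously.
#' The utility draw happens on every trial -- exploration only changes which
#' action is returned -- so latency readouts exist for all trials.
#'
#' All randomness flows from `seed` through R's Mersenne-Twister stream; the
#' caller's RNG state is restored on exit. Identical `(config, seed)` give
#' identical results.
#'
#' @param env A task environment ([stationary_env()], [igt_env()],
#'   [two_stage_env()], [market_env()]).
#' @param params A [critic_params()].
#' @param n_trials Decisions per replicate (default 100).
#' @param n_reps Number of replicates (default 30000, the reference
#'   simulation scale; desk-scale analyses typically use 2000).
#' @param seed Integer base seed.
#' @param neutral Track the risk-neutral reference table too?
#' @param log_q Keep full per-trial snapshots of all value tables? (Memory
#'   grows as `n_reps * n_trials * n_states * n_actions`; switch off for
#'   large grid sweeps.)
#' @param log_u Keep the per-trial utility draws?
#' @return An object of class `cc_sim`: matrices `action`, `state`, `reward`,
#'   `greedy_action`, `explored`, `delta_plus`, `delta_minus`, `d_q_plus`,
#'   `d_q_minus` (and neutral counterparts) of shape `n_reps x n_trials`;
#'   optional arrays `u` (`n_reps x n_trials x n_actions`) and `q_plus`,
#'   `q_minus`, `q_neutral` (`n_reps x n_trials x n_states x n_actions`,
#'   post-update snapshots); final tables `q_plus_final` etc.; environment
#'   `metadata` matrices; and the resolved configuration with its seed.
#' @examples
#' sim <- run_replicates(stationary_env(moment_spec(0.5, 0.2, 0, 2.5)),
#'                       n_trials = 20, n_reps = 50, seed = 1)
#' dim(sim$reward)
#' @export
run_replicates <- function(env, params = critic_params(),
                           n_trials = 100, n_reps = 30000, seed = 1L,
                           neutral = TRUE, log_q = TRUE, log_u = TRUE) {
  stopifnot(inherits(env, "cc_env"), inherits(params, "critic_params"),
            n_trials >= 1, n_reps >= 1)
  if (!is.null(.GlobalEnv$.Random.seed)) {
    old_seed <- .GlobalEnv$.Random.seed
    on.exit(assign(".Random.seed", old_seed, envir = .GlobalEnv))
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  R <- as.integer(n_reps); T <- as.integer(n_trials)
  S <- env$n_states; A <- env$n_actions
  avail <- env$available
  n_avail_by_state <- rowSums(avail)

  qp <- array(0, c(R, S, A)); qm <- qp
  qn <- if (neutral) qp else NULL
  rs <- env$reset(R)
  state <- rs$state; internal <- rs$internal
  rep_idx <- seq_len(R)

  m_int <- function() matrix(NA_integer_, R, T)
  m_num <- function() matrix(NA_real_, R, T)
  logs <- list(action = m_int(), state = m_int(), next_state = m_int(),
               terminal = matrix(NA, R, T),
               reward = m_num(), greedy_action = m_int(),
               explored = matrix(NA, R, T),
               delta_plus = m_num(), delta_minus = m_num(),
               d_q_plus = m_num(), d_q_minus = m_num())
  if (neutral) { logs$delta_neutral <- m_num(); logs$d_q_neutral <- m_num() }
  u_log <- if (log_u) array(NA_real_, c(R, T, A)) else NULL
  if (log_q) {
    qp_log <- array(NA_real_, c(R, T, S, A)); qm_log <- qp_log
    qn_log <- if (neutral) qp_log else NULL
  }
  metadata <- if (length(env$metadata_fields))
    stats::setNames(vector("list", length(env$metadata_fields)),
                    env$metadata_fields) else NULL

  lin <- function(s, a) rep_idx + R * (s - 1L) + R * S * (a - 1L)

  for (t in seq_len(T)) {
    # utility draws on the (ordered) interval between the two critic values
    u <- matrix(-Inf, R, A)
    avail_now <- matrix(avail[state, , drop = FALSE], R, A)
    for (a in seq_len(A)) {
      ii <- lin(state, a)
      qpa <- qp[ii]; qma <- qm[ii]
      lo <- pmin(qpa, qma); hi <- pmax(qpa, qma)
      ua <- lo + stats::runif(R) * (hi - lo)
      u[, a] <- ifelse(avail_now[, a], ua, -Inf)
    }
    greedy <- max.col(u, ties.method = "random")

    # epsilon-greedy: explore picks uniformly among available non-greedy actions
    n_av <- n_avail_by_state[state]
    explore <- stats::runif(R) < params$epsilon & n_av > 1L
    chosen <- greedy
    if (any(explore)) {
      j <- 1L + as.integer(floor(stats::runif(R) * (n_av - 1L)))
      cnt <- integer(R); pick <- integer(R)
      for (a in seq_len(A)) {
        ok <- explore & avail_now[, a] & a != greedy
        cnt <- cnt + ok
        hit <- ok & cnt == j & pick == 0L
        pick[hit] <- a
      }
      chosen[explore] <- pick[explore]
    }

    res <- env$step(internal, state, chosen)
    internal <- res$internal

    # prediction errors from pre-update tables; terminal => no continuation
    nmax <- function(q) {
      m <- matrix(-Inf, R, A)
      for (a in seq_len(A)) {
        ok <- avail[cbind(res$next_state, a)]
        qa <- q[lin(res$next_state, a)]
        m[, a] <- ifelse(ok, qa, -Inf)
      }
      out <- do.call(pmax, lapply(seq_len(A), function(a) m[, a]))
      ifelse(res$terminal, 0, out)
    }
    ii <- lin(state, chosen)
    dp <- res$reward + params$gamma * nmax(qp) - qp[ii]
    dm <- res$reward + params$gamma * nmax(qm) - qm[ii]
    if (any(!is.finite(dp)) || any(!is.finite(dm)))
      stop(sprintf(
        "non-finite prediction error at trial %d (first bad replicate %d); check gamma/reward configuration",
        t, which(!is.finite(dp) | !is.finite(dm))[1]), call. = FALSE)
    wp <- (1 + params$k_plus) * (dp > 0) + (1 - params$k_plus) * (dp < 0)
    wm <- (1 - params$k_minus) * (dm > 0) + (1 + params$k_minus) * (dm < 0)
    dqp <- params$alpha * wp * dp
    dqm <- params$alpha * wm * dm
    qp[ii] <- qp[ii] + dqp
    qm[ii] <- qm[ii] + dqm
    if (neutral) {
      dn <- res$reward + params$gamma * nmax(qn) - qn[ii]
      dqn <- params$alpha * dn
      qn[ii] <- qn[ii] + dqn
      logs$delta_neutral[, t] <- dn
      logs$d_q_neutral[, t] <- dqn
    }

    logs$action[, t] <- chosen
    logs$state[, t] <- state
    logs$next_state[, t] <- res$next_state
    logs$terminal[, t] <- res$terminal
    logs$reward[, t] <- res$reward
    logs$greedy_action[, t] <- greedy
    logs$explored[, t] <- explore
    logs$delta_plus[, t] <- dp
    logs$delta_minus[, t] <- dm
    logs$d_q_plus[, t] <- dqp
    logs$d_q_minus[, t] <- dqm
    if (log_u) {
      ut <- u; ut[!avail_now] <- NA_real_
      u_log[, t, ] <- ut
    }
    if (log_q) {
      qp_log[, t, , ] <- qp; qm_log[, t, , ] <- qm
      if (neutral) qn_log[, t, , ] <- qn
    }
    if (!is.null(metadata))
      for (f in env$metadata_fields) {
        v <- res$metadata[[f]]
        if (is.null(metadata[[f]]))
          metadata[[f]] <- matrix(v[NA_integer_][1], R, T)
        metadata[[f]][, t] <- v
      }

    state <- res$next_state
  }

  out <- c(logs, list(
    u = u_log,
    q_plus = if (log_q) qp_log else NULL,
    q_minus = if (log_q) qm_log else NULL,
    q_neutral = if (log_q && neutral) qn_log else NULL,
    q_plus_final = qp, q_minus_final = qm,
    q_neutral_final = if (neutral) qn else NULL,
    metadata = metadata,
    env_name = env$name, params = params,
    n_reps = R, n_trials = T, seed = seed,
    n_states = S, n_actions = A, available = avail))
  class(out) <- "cc_sim"
  out
}

#' @export
print.cc_sim <- function(x, ...) {
  cat(sprintf("<cc_sim: %s> %d replicates x %d trials, seed %d\n",
              x$env_name, x$n_reps, x$n_trials, x$seed))
  print(x$params)
  invisible(x)
}

#' Per-trial summary and asymptotes of the value functions
#'
#' For the single-state, single-action task: the replicate mean and
#' interquartile range of each value function at every trial, plus asymptote
#' estimates taken as the replicate-and-trial mean over the final
#' `tail_window` trials (the curves are visibly flat well before trial 80 at
#' the default learning rate).
#'
#' @param sim A `cc_sim` from the stationary task, run with `log_q = TRUE`.
#' @param tail_window Number of final trials in the asymptote average.
#' @return A list: `by_trial`, a long data frame `(trial, critic, mean, q25,
#'   q75)`; `asymptote`, named means for `q_plus`, `q_minus` (and
#'   `q_neutral`); `gap` (`q_plus - q_minus`), `midpoint`, and the asymptotic
#'   `iqr` of each critic (IQR of the replicate tail-means).
#' @export
summarize_q <- function(sim, tail_window = 20) {
  stopifnot(inherits(sim, "cc_sim"))
  if (is.null(sim$q_plus))
    stop("run_replicates() must be called with log_q = TRUE", call. = FALSE)
  if (sim$n_states != 1L || sim$n_actions != 1L)
    stop("asymptote summaries are defined for the single-state task only",
         call. = FALSE)
  if (sim$n_trials < tail_window)
    stop(sprintf("need at least tail_window = %d trials, have %d",
                 tail_window, sim$n_trials), call. = FALSE)
  tabs <- list(q_plus = sim$q_plus[, , 1, 1],
               q_minus = sim$q_minus[, , 1, 1])
  if (!is.null(sim$q_neutral)) tabs$q_neutral <- sim$q_neutral[, , 1, 1]
  by_trial <- do.call(rbind, lapply(names(tabs), function(nm) {
    m <- tabs[[nm]]
    qs <- apply(m, 2, stats::quantile, probs = c(0.25, 0.75), names = FALSE)
    data.frame(trial = seq_len(ncol(m)), critic = nm,
               mean = colMeans(m), q25 = qs[1, ], q75 = qs[2, ])
  }))
  tail_idx <- (sim$n_trials - tail_window + 1L):sim$n_trials
  tail_means <- lapply(tabs, function(m) rowMeans(m[, tail_idx, drop = FALSE]))
  asym <- vapply(tail_means, mean, numeric(1))
  iqr <- vapply(tail_means, function(v) diff(stats::quantile(v, c(0.25, 0.75))),
                numeric(1))
  list(by_trial = by_trial, asymptote = asym,
       gap = unname(asym["q_plus"] - asym["q_minus"]),
       midpoint = unname((asym["q_plus"] + asym["q_minus"]) / 2),
       iqr = iqr, tail_window = tail_window)
}

#' Grids of (k+, k-) points for parameter sweeps
#'
#' @param resolution Lattice resolution per axis on `[0, 1]^2` (default 11).
#' @param points Optional data frame with columns `k_plus`, `k_minus` to use
#'   instead of the lattice (e.g. the anti-diagonal `k_plus = 1 - k_minus`).
#' @return Data frame of grid points with their sensitivity coordinates.
#' @export
sweep_grid <- function(resolution = 11, points = NULL) {
  g <- if (is.null(points)) {
    ks <- seq(0, 1, length.out = resolution)
    expand.grid(k_plus = ks, k_minus = ks)
  } else {
    stopifnot(all(c("k_plus", "k_minus") %in% names(points)))
    as.data.frame(points)[c("k_plus", "k_minus")]
  }
  if (any(g$k_plus < 0 | g$k_plus > 1 | g$k_minus < 0 | g$k_minus > 1))
    stop("grid points must lie in [0, 1]^2", call. = FALSE)
  g$s_r <- g$k_plus - g$k_minus
  g$s_u <- g$k_plus + g$k_minus
  g
}

#' Sweep the learner over a (k+, k-) grid
#'
#' Runs [run_replicates()] at every grid point (each with its own seed
#' derived from `seed` by offsetting with the point index) and attaches a
#' per-point summary.
#'
#' @param env Task environment.
#' @param grid A [sweep_grid()] data frame.
#' @param params Baseline [critic_params()]; `k_plus`/`k_minus` are replaced
#'   per point.
#' @param n_trials,n_reps,seed Passed to [run_replicates()].
#' @param summarise Function `cc_sim -> ` named numeric vector (or coercible
#'   one-row list); its names become summary columns. The default reports the
#'   asymptotic `midpoint` and `gap` of the two critics and needs the
#'   stationary task.
#' @param ... Further arguments to [run_replicates()] (e.g. `log_q = FALSE`
#'   with a summariser that does not need trajectories).
#' @return `grid` with the summary columns appended (tidy, one row per
#'   point).
#' @export
run_sweep <- function(env, grid = sweep_grid(), params = critic_params(),
                      n_trials = 100, n_reps = 2000, seed = 1L,
                      summarise = summarise_midpoint_gap, ...) {
  stopifnot(nrow(grid) >= 1)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- critic_params(alpha = params$alpha, epsilon = params$epsilon,
                       gamma = params$gamma,
                       k_plus = grid$k_plus[i], k_minus = grid$k_minus[i])
    sim <- run_replicates(env, p, n_trials = n_trials, n_reps = n_reps,
                          seed = seed + i, ...)
    unlist(summarise(sim))
  })
  cbind(grid, do.call(rbind, rows), row.names = NULL)
}

#' @rdname run_sweep
#' @param sim A `cc_sim`.
#' @export
summarise_midpoint_gap <- function(sim) {
  s <- summarize_q(sim)
  c(midpoint = s$midpoint, gap = s$gap)
}

#' Deck selection proportions in the Iowa Gambling Task
#'
#' @param sim A `cc_sim` from [igt_env()].
#' @return Named numeric vector of selection proportions for decks A-D,
#'   aggregated over all trials and replicates (sums to 1).
#' @export
deck_frequencies <- function(sim) {
  stopifnot(inherits(sim, "cc_sim"))
  if (sim$env_name != "igt")
    stop("deck_frequencies() needs a simulation of the IGT", call. = FALSE)
  tab <- table(factor(sim$metadata$deck, levels = c("A", "B", "C", "D")))
  prop <- as.numeric(tab) / sum(tab)
  names(prop) <- names(tab)
  prop
}

#' Stay probabilities in the two-stage task
#'
#' The probability of repeating the previous first-stage action, conditioned
#' on whether the previous trial's stage-1 transition was common or rare and
#' whether its stage-2 choice was rewarded. Computed over consecutive
#' first-stage trial pairs pooled across replicates.
#'
#' @param sim A `cc_sim` from [two_stage_env()].
#' @return A data frame with one row per (rewarded, transition) cell:
#'   `p_stay`, pair count `n`, plus an attribute `"common_minus_rare"` giving
#'   the common - rare stay difference per reward condition. Cells with no
#'   qualifying pairs have `p_stay = NA`.
#' @export
stay_probabilities <- function(sim) {
  stopifnot(inherits(sim, "cc_sim"))
  if (sim$env_name != "two_stage")
    stop("stay_probabilities() needs a simulation of the two-stage task",
         call. = FALSE)
  stage1 <- which(sim$metadata$stage[1, ] == 1L)
  stage1 <- stage1[stage1 + 2L <= sim$n_trials]
  if (!length(stage1))
    stop("no consecutive first-stage trial pairs available", call. = FALSE)
  stay <- sim$action[, stage1 + 2L, drop = FALSE] ==
    sim$action[, stage1, drop = FALSE]
  transition <- sim$metadata$transition[, stage1, drop = FALSE]
  rewarded <- sim$metadata$rewarded[, stage1 + 1L, drop = FALSE]
  cells <- expand.grid(rewarded = c(TRUE, FALSE),
                       transition = c("common", "rare"),
                       stringsAsFactors = FALSE)
  cells$p_stay <- NA_real_
  cells$n <- 0L
  for (i in seq_len(nrow(cells))) {
    sel <- rewarded == cells$rewarded[i] & transition == cells$transition[i]
    cells$n[i] <- sum(sel)
    if (cells$n[i] > 0) cells$p_stay[i] <- mean(stay[sel])
  }
  diffs <- vapply(c(TRUE, FALSE), function(rw) {
    cells$p_stay[cells$rewarded == rw & cells$transition == "common"] -
      cells$p_stay[cells$rewarded == rw & cells$transition == "rare"]
  }, numeric(1))
  names(diffs) <- c("rewarded", "unrewarded")
  attr(cells, "common_minus_rare") <- diffs
  cells
}
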