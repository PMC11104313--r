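#' Latency transform from utility to time units
#'
#' A strictly decreasing map `F(x) = exp(-b x)` turning a utility draw (on
#' the reward scale) into a reaction-time proxy. Because `F` is strictly
#' decreasing, `min_a F(U(a)) = F(max_a U(a))` and the action chosen via the
#' shortest latency is exactly the greedy action; only the time scale, not
#' the choice probabilities, is affected by `b`.
#'
#' @param b Latency-scale parameter, > 0, in 1/reward units. Only orderings
#'   and variability of latencies are interpretable, so the default `b = 1`
#'   is a pure choice of units.
#' @return Object of class `latency_map` with fields `b` and the transform
#'   `f`.
#' @export
latency_map <- function(b = 1) {
  stopifnot(is.numeric(b), length(b) == 1, b > 0)
  structure(list(b = b, f = function(x) exp(-b * x)), class = "latency_map")
}

#' Reaction-time proxy for one utility draw
#'
#' @param draw Output of [draw_utilities()] (a greedy, non-exploration
#'   trial is the intended case).
#' @param map A [latency_map()].
#' @return List with `latency = min_a F(U(a))` and `action`, the arg-min of
#'   the transformed utilities -- provably the arg-max of the raw utilities.
#' @export
reaction_time <- function(draw, map = latency_map()) {
  lat <- map$f(draw$u)
  list(latency = min(lat), action = draw$greedy_action)
}

#' Reaction-time proxies for a whole simulation
#'
#' @param sim A `cc_sim` run with `log_u = TRUE`.
#' @param map A [latency_map()].
#' @param greedy_only Restrict to trials on which the learner behaved
#'   greedily (default), the regime in which the latency reading applies.
#' @return Data frame `(replicate, trial, latency, action)` with one row per
#'   qualifying trial.
#' @export
reaction_times <- function(sim, map = latency_map(), greedy_only = TRUE) {
  stopifnot(inherits(sim, "cc_sim"))
  if (is.null(sim$u))
    stop("run_replicates() must be called with log_u = TRUE", call. = FALSE)
  max_u <- apply(sim$u, c(1, 2), max, na.rm = TRUE)
  keep <- if (greedy_only) !sim$explored else matrix(TRUE, sim$n_reps, sim$n_trials)
  idx <- which(keep, arr.ind = TRUE)
  data.frame(replicate = idx[, 1], trial = idx[, 2],
             latency = map$f(max_u[keep]),
             action = sim$greedy_action[keep])
}

#' Mean and SD of the per-trial maximum utility draw
#'
#' Larger mean `max_a U(a)` is hypothesized to correspond to faster
#' reactions; its variability maps to reaction-time variability. Pooled over
#' all replicates and trials.
#'
#' @param sim A `cc_sim` run with `log_u = TRUE`.
#' @param greedy_only Restrict to greedy trials? Default `FALSE`: the
#'   summary maps pool every trial's draw, and exploration only affects which
#'   action was then taken.
#' @return Named numeric vector `(mean, sd)`.
#' @export
max_utility_stats <- function(sim, greedy_only = FALSE) {
  stopifnot(inherits(sim, "cc_sim"))
  if (is.null(sim$u))
    stop("run_replicates() must be called with log_u = TRUE", call. = FALSE)
  max_u <- apply(sim$u, c(1, 2), max, na.rm = TRUE)
  if (greedy_only) max_u <- max_u[!sim$explored]
  c(mean = mean(max_u), sd = stats::sd(as.numeric(max_u)))
}

# Task-level RPE per (replicate, trial) for a market simulation: the
# fractional price gain z-scored against its strict predecessors within the
# same market (n - 1 denominator; warm-up and zero-SD cases give 0).
market_rpe <- function(sim) {
  gains <- sim$metadata$frac_gain
  market <- sim$metadata$market[1, ]  # market schedule is common to replicates
  rpe <- matrix(0, nrow(gains), ncol(gains))
  for (m in unique(market)) {
    cols <- which(market == m)
    s1 <- 0; s2 <- 0
    for (j in seq_along(cols)) {
      npast <- j - 1L
      if (npast >= 2L) {
        mu <- s1 / npast
        v <- (s2 - npast * mu^2) / (npast - 1L)
        g <- gains[, cols[j]]
        rpe[, cols[j]] <- ifelse(v > 0, (g - mu) / sqrt(v), 0)
      }
      s1 <- s1 + gains[, cols[j]]
      s2 <- s2 + gains[, cols[j]]^2
    }
  }
  rpe
}

#' Conditional means of the critic updates in the market task
#'
#' Groups trials of a market simulation by the sign of the task-level reward
#' prediction error and the bet level (optionally also the next trial's bet)
#' and reports the mean optimistic update `dQ+` (the dopamine-like transient)
#' and the mean negated pessimistic update `-dQ-` (the serotonin-like
#' transient) per cell, with cell counts. Trials with RPE exactly 0 --
#' including the two warm-up trials of each market -- are excluded; when
#' conditioning on the next bet, the final trial of the run is also dropped.
#' Empty cells are kept with `n = 0` and `NA` means rather than fabricated.
#'
#' @param sim A `cc_sim` from [market_env()].
#' @param by_next_bet Split cells further by the subsequent trial's bet?
#' @return Data frame with columns `rpe_sign`, `bet`, (optionally
#'   `next_bet`,) `mean_d_q_plus`, `mean_neg_d_q_minus`, `n`.
#' @export
transient_table <- function(sim, by_next_bet = FALSE) {
  stopifnot(inherits(sim, "cc_sim"))
  if (sim$env_name != "market")
    stop("transient_table() needs a simulation of the market task",
         call. = FALSE)
  rpe <- market_rpe(sim)
  bet <- sim$metadata$bet
  keep <- rpe != 0
  grp <- list(
    rpe_sign = ifelse(rpe > 0, "positive", "negative"),
    bet = bet
  )
  if (by_next_bet) {
    nb <- cbind(bet[, -1, drop = FALSE], NA_real_)
    grp$next_bet <- nb
    keep <- keep & !is.na(nb)
  }
  levs <- list(rpe_sign = c("negative", "positive"),
               bet = sort(unique(as.numeric(bet))))
  if (by_next_bet) levs$next_bet <- levs$bet
  cells <- expand.grid(levs, stringsAsFactors = FALSE)
  cells$mean_d_q_plus <- NA_real_
  cells$mean_neg_d_q_minus <- NA_real_
  cells$n <- 0L
  for (i in seq_len(nrow(cells))) {
    sel <- keep & grp$rpe_sign == cells$rpe_sign[i] & grp$bet == cells$bet[i]
    if (by_next_bet) sel <- sel & grp$next_bet == cells$next_bet[i]
    cells$n[i] <- sum(sel)
    if (cells$n[i] > 0) {
      cells$mean_d_q_plus[i] <- mean(sim$d_q_plus[sel])
      cells$mean_neg_d_q_minus[i] <- mean(-sim$d_q_minus[sel])
    }
  }
  cells
}
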