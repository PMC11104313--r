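#' Paired optimistic/pessimistic value tables
#'
#' Holds the tabular state-action value functions of the two critics: the
#' optimistic `q_plus`, the pessimistic `q_minus`, and (optionally) a
#' risk-neutral reference `q_neutral` updated by classic Q-learning with the
#' same learning rate and discount. All tables start at zero.
#'
#' @param n_states Number of discrete states.
#' @param n_actions Number of discrete actions (tables are rectangular; use
#'   the `available` mask to restrict actions per state).
#' @param neutral Keep a risk-neutral reference table too?
#' @param available Logical `n_states x n_actions` matrix marking which
#'   actions exist in which state. Defaults to all available.
#' @return An object of class `critic_pair` with matrices `q_plus`,
#'   `q_minus`, optionally `q_neutral`, and the `available` mask.
#' @examples
#' cp <- critic_pair(1, 4)
#' cp$q_plus
#' @export
critic_pair <- function(n_states, n_actions, neutral = TRUE,
                        available = NULL) {
  stopifnot(n_states >= 1, n_actions >= 1)
  z <- matrix(0, n_states, n_actions)
  if (is.null(available)) available <- matrix(TRUE, n_states, n_actions)
  stopifnot(identical(dim(available), dim(z)))
  if (any(rowSums(available) == 0))
    stop("every state needs at least one available action", call. = FALSE)
  structure(
    list(q_plus = z, q_minus = z,
         q_neutral = if (neutral) z else NULL,
         available = available),
    class = "critic_pair"
  )
}

max_next <- function(q, next_state, next_actions) {
  if (length(next_actions) == 0L) return(0)  # terminal convention
  max(q[next_state, next_actions])
}

#' Prediction errors of the two critics
#'
#' For a transition `(S, A, R, S')`, each critic's temporal-difference error
#' is `delta = R + gamma * max_a Q(S', a) - Q(S, A)`, computed against its own
#' table. When the episode terminates at `S'` (no next actions), the
#' max-over-actions term is 0.
#'
#' @param critics A [critic_pair()].
#' @param state,action Indices of the visited state-action pair.
#' @param reward Observed reward.
#' @param next_state Index of the successor state.
#' @param next_actions Integer vector of actions available in `next_state`;
#'   `integer(0)` marks a terminal transition.
#' @param gamma Discount factor.
#' @return Named list with `delta_plus`, `delta_minus`, and (when the neutral
#'   table is kept) `delta_neutral`.
#' @export
prediction_errors <- function(critics, state, action, reward,
                              next_state, next_actions, gamma) {
  if (state < 1 || state > nrow(critics$q_plus) ||
      action < 1 || action > ncol(critics$q_plus) ||
      !critics$available[state, action])
    stop(sprintf("state-action pair (%d, %d) is not indexed in the critic tables",
                 state, action), call. = FALSE)
  out <- list(
    delta_plus = reward + gamma * max_next(critics$q_plus, next_state, next_actions) -
      critics$q_plus[state, action],
    delta_minus = reward + gamma * max_next(critics$q_minus, next_state, next_actions) -
      critics$q_minus[state, action]
  )
  if (!is.null(critics$q_neutral))
    out$delta_neutral <- reward +
      gamma * max_next(critics$q_neutral, next_state, next_actions) -
      critics$q_neutral[state, action]
  out
}

# Asymmetric update weight: (1 + k) on one error sign, (1 - k) on the other,
# and 0 at delta == 0 (both sign indicators false, so the update vanishes
# either way; the explicit 0 only matters for logging).
update_weight <- function(delta, k, optimistic) {
  if (optimistic) {
    (1 + k) * (delta > 0) + (1 - k) * (delta < 0)
  } else {
    (1 - k) * (delta > 0) + (1 + k) * (delta < 0)
  }
}

#' Apply the paired asymmetric temporal-difference update
#'
#' Both prediction errors are computed from the pre-update tables, then both
#' tables are written (simultaneous update). The optimistic critic moves by
#' `alpha * [(1 + k_plus) 1{d > 0} + (1 - k_plus) 1{d < 0}] * d` so gains are
#' amplified; the pessimistic critic uses `(1 - k_minus)` on gains and
#' `(1 + k_minus)` on losses so losses are amplified. The risk-neutral table,
#' when present, gets the classic update `alpha * delta`.
#'
#' @inheritParams prediction_errors
#' @param params A [critic_params()].
#' @return List with the updated `critics` and an update record holding
#'   `delta_plus`, `delta_minus`, `d_q_plus`, `d_q_minus` (and the neutral
#'   pair when tracked). A non-finite error aborts with a diagnostic, since
#'   runaway values indicate a gamma/reward misconfiguration.
#' @export
apply_update <- function(critics, state, action, reward,
                         next_state, next_actions, params) {
  d <- prediction_errors(critics, state, action, reward,
                         next_state, next_actions, params$gamma)
  if (!all(vapply(d, is.finite, logical(1))))
    stop(sprintf(
      "non-finite prediction error at (state %d, action %d): delta+ = %g, delta- = %g",
      state, action, d$delta_plus, d$delta_minus), call. = FALSE)
  dqp <- params$alpha * update_weight(d$delta_plus, params$k_plus, TRUE) * d$delta_plus
  dqm <- params$alpha * update_weight(d$delta_minus, params$k_minus, FALSE) * d$delta_minus
  critics$q_plus[state, action] <- critics$q_plus[state, action] + dqp
  critics$q_minus[state, action] <- critics$q_minus[state, action] + dqm
  rec <- list(delta_plus = d$delta_plus, delta_minus = d$delta_minus,
              d_q_plus = dqp, d_q_minus = dqm)
  if (!is.null(critics$q_neutral)) {
    dqn <- params$alpha * d$delta_neutral
    critics$q_neutral[state, action] <- critics$q_neutral[state, action] + dqn
    rec$delta_neutral <- d$delta_neutral
    rec$d_q_neutral <- dqn
  }
  list(critics = critics, record = rec)
}

#' Uniform utility draws over the critic interval
#'
#' For each available action, a utility `U(a)` is drawn uniformly from the
#' closed interval spanned by the two critic values for that state-action
#' pair. Endpoints are ordered before sampling so the rule is total even if a
#' parameter regime lets the pessimistic value exceed the optimistic one; a
#' degenerate interval returns the common value exactly.
#'
#' @param critics A [critic_pair()].
#' @param state State index.
#' @param actions Integer vector of available actions (non-empty).
#' @return Named list with the utility vector `u` (named by action index) and
#'   `greedy_action`, the arg-max of `u` with uniform random tie-breaking.
#' @export
draw_utilities <- function(critics, state, actions) {
  stopifnot(length(actions) >= 1L)
  qp <- critics$q_plus[state, actions]
  qm <- critics$q_minus[state, actions]
  lo <- pmin(qp, qm)
  hi <- pmax(qp, qm)
  u <- lo + stats::runif(length(actions)) * (hi - lo)
  names(u) <- as.character(actions)
  top <- which(u == max(u))
  greedy <- if (length(top) == 1L) top else top[sample.int(length(top), 1L)]
  list(u = u, greedy_action = actions[greedy])
}

#' Epsilon-greedy selection over drawn utilities
#'
#' With probability `1 - epsilon` the greedy action (largest utility) is
#' returned; with probability `epsilon` one of the non-greedy actions is
#' returned uniformly at random. Single-action states always return the sole
#' action.
#'
#' @param draw Output of [draw_utilities()].
#' @param epsilon Exploration probability.
#' @return The chosen action index.
#' @export
select_action <- function(draw, epsilon) {
  actions <- as.integer(names(draw$u))
  if (length(actions) == 1L) return(actions)
  if (stats::runif(1) < epsilon) {
    others <- actions[actions != draw$greedy_action]
    if (length(others) == 1L) others else others[sample.int(length(others), 1L)]
  } else {
    draw$greedy_action
  }
}

#' One classic Q-learning step on the risk-neutral reference table
#'
#' Convenience wrapper used when only the reference learner is of interest;
#' [apply_update()] already advances the neutral table alongside the critics.
#'
#' @inheritParams apply_update
#' @return List with updated `critics` and the applied `d_q`.
#' @export
update_neutral <- function(critics, state, action, reward,
                           next_state, next_actions, params) {
  if (is.null(critics$q_neutral))
    stop("critic_pair was built without a neutral table", call. = FALSE)
  delta <- reward +
    params$gamma * max_next(critics$q_neutral, next_state, next_actions) -
    critics$q_neutral[state, action]
  dq <- params$alpha * delta
  critics$q_neutral[state, action] <- critics$q_neutral[state, action] + dq
  list(critics = critics, d_q = dq, delta = delta)
}
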