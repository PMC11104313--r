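#' Task environment contract
#'
#' All four tasks implement one vectorized contract so the replicate engine
#' can advance many independent simulations in lock-step. An environment is a
#' list of class `cc_env` with:
#' \describe{
#'   \item{`name`}{task identifier.}
#'   \item{`n_states`, `n_actions`}{table dimensions (`n_actions` is the
#'     rectangular maximum; `available` masks per-state action sets).}
#'   \item{`available`}{logical `n_states x n_actions` matrix.}
#'   \item{`reset(n)`}{returns `list(state, internal)`: initial state vector
#'     for `n` replicates plus any per-replicate internal state.}
#'   \item{`step(internal, state, action)`}{vectorized transition: returns
#'     `list(reward, next_state, terminal, metadata, internal)`, where
#'     `metadata` is a named list of per-replicate annotation vectors and
#'     `terminal` marks transitions after which the discounted continuation
#'     term is zero and the state is re-initialized.}
#' }
#' Transitions respect a fixed Markov kernel `p(s', r | s, a)`; scalar use is
#' the `n = 1` case.
#'
#' @name cc_env
#' @keywords internal
NULL

new_cc_env <- function(name, n_states, n_actions, available,
                       reset, step, metadata_fields = character()) {
  structure(list(name = name, n_states = n_states, n_actions = n_actions,
                 available = available, reset = reset, step = step,
                 metadata_fields = metadata_fields),
            class = "cc_env")
}

#' @export
print.cc_env <- function(x, ...) {
  cat(sprintf("<cc_env: %s> %d state(s), up to %d action(s)\n",
              x$name, x$n_states, x$n_actions))
  invisible(x)
}

#' Single-state, single-action reward-learning environment
#'
#' The degenerate task in which learning is driven purely by the shape of the
#' reward distribution: one state, one action, rewards drawn i.i.d. from a
#' four-moment specification, never terminal.
#'
#' @param spec A [moment_spec()].
#' @return A `cc_env`.
#' @export
stationary_env <- function(spec = moment_spec()) {
  stopifnot(inherits(spec, "moment_spec"))
  new_cc_env(
    name = "stationary", n_states = 1L, n_actions = 1L,
    available = matrix(TRUE, 1, 1),
    reset = function(n) list(state = rep(1L, n), internal = NULL),
    step = function(internal, state, action) {
      n <- length(state)
      list(reward = sample_rewards(spec, n),
           next_state = rep(1L, n),
           terminal = rep(FALSE, n),
           metadata = NULL, internal = internal)
    }
  )
}

#' Deck payoff scheme for the Iowa Gambling Task
#'
#' Each deck is a finite net-payoff distribution (support plus
#' probabilities). The default follows the classic task structure, scaled so
#' that Deck C pays uniformly from \{+50, 0\}: the "bad" decks A and B have
#' expected net value -25 per draw (A through frequent moderate losses, B
#' through a rare but very large one) and the "good" decks C and D have +25.
#'
#' @param decks Named list `A`..`D`, each `list(support, prob)`.
#' @return Object of class `deck_scheme`; expected values are attached.
#' @examples
#' sapply(deck_scheme()$decks, function(d) sum(d$support * d$prob))
#' @export
deck_scheme <- function(decks = list(
  A = list(support = c(100, -150), prob = c(0.5, 0.5)),
  B = list(support = c(100, -1150), prob = c(0.9, 0.1)),
  C = list(support = c(50, 0), prob = c(0.5, 0.5)),
  D = list(support = c(50, -200), prob = c(0.9, 0.1))
)) {
  stopifnot(identical(sort(names(decks)), c("A", "B", "C", "D")))
  ev <- vapply(decks, function(d) {
    stopifnot(length(d$support) == length(d$prob),
              abs(sum(d$prob) - 1) < 1e-12, all(d$prob >= 0))
    sum(d$support * d$prob)
  }, numeric(1))
  if (!(ev[["A"]] < 0 && ev[["B"]] < 0))
    stop("decks A and B must have negative expected net value", call. = FALSE)
  if (!(ev[["C"]] > 0 && ev[["D"]] > 0))
    stop("decks C and D must have positive expected net value", call. = FALSE)
  structure(list(decks = decks, expected_value = ev), class = "deck_scheme")
}

#' Iowa Gambling Task environment
#'
#' One state, four actions (decks A-D); each step draws a net payoff from the
#' chosen deck's distribution. Metadata records the deck label.
#'
#' @param scheme A [deck_scheme()].
#' @return A `cc_env`.
#' @export
igt_env <- function(scheme = deck_scheme()) {
  stopifnot(inherits(scheme, "deck_scheme"))
  labels <- c("A", "B", "C", "D")
  new_cc_env(
    name = "igt", n_states = 1L, n_actions = 4L,
    available = matrix(TRUE, 1, 4),
    metadata_fields = "deck",
    reset = function(n) list(state = rep(1L, n), internal = NULL),
    step = function(internal, state, action) {
      if (any(action < 1L | action > 4L))
        stop("unknown deck id: ", paste(unique(action[action < 1 | action > 4]),
                                        collapse = ", "), call. = FALSE)
      n <- length(state)
      reward <- numeric(n)
      for (a in unique(action)) {
        idx <- which(action == a)
        d <- scheme$decks[[a]]
        reward[idx] <- d$support[
          sample.int(length(d$support), length(idx), replace = TRUE, prob = d$prob)]
      }
      list(reward = reward, next_state = rep(1L, n),
           terminal = rep(FALSE, n),
           metadata = list(deck = labels[action]), internal = internal)
    }
  )
}

#' Layout of the two-stage Markov task
#'
#' First-stage state 1 (two actions) leads to second-stage state 2 or 3: the
#' "common" destination of each first-stage action is reached with
#' probability `p_common`, the other ("rare") with its complement.
#' Second-stage choices pay a Bernoulli reward of `reward_value`; the four
#' second-stage reward probabilities follow independent reflecting Gaussian
#' random walks on `p_bounds`, redrawn each completed trial with step SD
#' `walk_sd`. First-stage rewards are identically zero, and the return from
#' stage two to stage one is treated as an ordinary state transition.
#'
#' @param p_common Probability of the common transition (default 0.7).
#' @param reward_value Second-stage reward magnitude.
#' @param p_bounds Reflecting bounds for the reward-probability walks.
#' @param walk_sd Step SD of the walks; 0 freezes the probabilities.
#' @param init_probs Optional length-4 vector of initial reward
#'   probabilities, ordered (state 2 action 1, state 2 action 2, state 3
#'   action 1, state 3 action 2); default draws them uniformly in `p_bounds`
#'   per replicate.
#' @return Object of class `two_stage_layout`.
#' @export
two_stage_layout <- function(p_common = 0.7, reward_value = 1,
                             p_bounds = c(0.25, 0.75), walk_sd = 0.025,
                             init_probs = NULL) {
  stopifnot(p_common > 0, p_common < 1,
            length(p_bounds) == 2, p_bounds[1] < p_bounds[2],
            p_bounds[1] >= 0, p_bounds[2] <= 1, walk_sd >= 0)
  if (!is.null(init_probs))
    stopifnot(length(init_probs) == 4,
              all(init_probs >= 0), all(init_probs <= 1))
  structure(list(p_common = p_common, reward_value = reward_value,
                 p_bounds = p_bounds, walk_sd = walk_sd,
                 init_probs = init_probs),
            class = "two_stage_layout")
}

reflect_into <- function(x, lo, hi) {
  # reflecting boundaries for the reward-probability random walks
  width <- hi - lo
  y <- (x - lo) %% (2 * width)
  lo + ifelse(y > width, 2 * width - y, y)
}

#' Two-stage Markov task environment
#'
#' @param layout A [two_stage_layout()].
#' @return A `cc_env`. Metadata per step: `stage` (1 or 2), `transition`
#'   (`"common"`/`"rare"`, stage-1 steps only), `rewarded` (stage-2 steps
#'   only).
#' @export
two_stage_env <- function(layout = two_stage_layout()) {
  stopifnot(inherits(layout, "two_stage_layout"))
  new_cc_env(
    name = "two_stage", n_states = 3L, n_actions = 2L,
    available = matrix(TRUE, 3, 2),
    metadata_fields = c("stage", "transition", "rewarded"),
    reset = function(n) {
      probs <- if (is.null(layout$init_probs)) {
        matrix(stats::runif(4 * n, layout$p_bounds[1], layout$p_bounds[2]), n, 4)
      } else {
        matrix(rep(layout$init_probs, each = n), n, 4)
      }
      list(state = rep(1L, n), internal = list(probs = probs))
    },
    step = function(internal, state, action) {
      n <- length(state)
      reward <- numeric(n)
      next_state <- integer(n)
      stage <- ifelse(state == 1L, 1L, 2L)
      transition <- rep(NA_character_, n)
      rewarded <- rep(NA, n)
      s1 <- state == 1L
      if (any(s1)) {
        common <- stats::runif(sum(s1)) < layout$p_common
        # common destination of action 1 is state 2, of action 2 is state 3
        dest_common <- ifelse(action[s1] == 1L, 2L, 3L)
        dest_rare <- ifelse(action[s1] == 1L, 3L, 2L)
        next_state[s1] <- ifelse(common, dest_common, dest_rare)
        transition[s1] <- ifelse(common, "common", "rare")
      }
      s2 <- !s1
      if (any(s2)) {
        col <- (state[s2] - 2L) * 2L + action[s2]  # columns: s2a1 s2a2 s3a1 s3a2
        p <- internal$probs[cbind(which(s2), col)]
        hit <- stats::runif(sum(s2)) < p
        reward[s2] <- ifelse(hit, layout$reward_value, 0)
        rewarded[s2] <- hit
        next_state[s2] <- 1L
        # a completed trial advances the reward-probability walks
        if (layout$walk_sd > 0) {
          idx <- which(s2)
          shift <- matrix(stats::rnorm(length(idx) * 4, 0, layout$walk_sd),
                          length(idx), 4)
          internal$probs[idx, ] <- reflect_into(
            internal$probs[idx, , drop = FALSE] + shift,
            layout$p_bounds[1], layout$p_bounds[2])
        }
      }
      list(reward = reward, next_state = next_state,
           terminal = rep(FALSE, n),
           metadata = list(stage = stage, transition = transition,
                           rewarded = rewarded),
           internal = internal)
    }
  )
}

#' Market betting task configuration
#'
#' @param n_markets Number of markets (default 6).
#' @param trials_per_market Decisions per market (default 20).
#' @param volatility SD of the per-trial fractional price move.
#' @param p0 Starting price of each market (currency units, > 0).
#' @param bets Two bet levels in percent (default `c(25, 75)`).
#' @return Object of class `market_config`.
#' @export
market_config <- function(n_markets = 6, trials_per_market = 20,
                          volatility = 0.05, p0 = 100, bets = c(25, 75)) {
  stopifnot(n_markets >= 1, trials_per_market >= 1, volatility > 0, p0 > 0,
            length(bets) == 2, bets[1] < bets[2])
  structure(list(n_markets = n_markets, trials_per_market = trials_per_market,
                 volatility = volatility, p0 = p0, bets = bets),
            class = "market_config")
}

#' Stock-market betting environment
#'
#' One state, two actions (low/high bet). Prices follow an independent
#' multiplicative Gaussian walk per replicate, `p' = p (1 + eta)` with
#' `eta ~ N(0, volatility^2)` truncated above -0.9 so prices stay positive;
#' each market restarts at `p0`. The reward is the percent gain relative to
#' the counterfactual neutral 50\% bet:
#' `R = ((p' - p) / p) * (bet - 50)`, so a +10\% move with the 75\% bet pays
#' +2.5 and with the 25\% bet pays -2.5. Every decision is episodic for
#' learning (terminal), while the price path persists across decisions within
#' a market. Metadata records the market index, trial within market, bet
#' level, and the fractional price gain used by the task-level reward
#' prediction error.
#'
#' @param config A [market_config()].
#' @return A `cc_env`.
#' @export
market_env <- function(config = market_config()) {
  stopifnot(inherits(config, "market_config"))
  total <- config$n_markets * config$trials_per_market
  new_cc_env(
    name = "market", n_states = 1L, n_actions = 2L,
    available = matrix(TRUE, 1, 2),
    metadata_fields = c("market", "trial_in_market", "bet", "frac_gain"),
    reset = function(n) {
      list(state = rep(1L, n),
           internal = list(price = rep(config$p0, n), t = 0L))
    },
    step = function(internal, state, action) {
      n <- length(state)
      t <- internal$t + 1L
      if (t > total)
        stop(sprintf("market task is over after %d decisions", total),
             call. = FALSE)
      market <- (t - 1L) %/% config$trials_per_market + 1L
      tim <- (t - 1L) %% config$trials_per_market + 1L
      if (tim == 1L) internal$price <- rep(config$p0, n)  # new market
      if (any(internal$price <= 0))
        stop("non-positive market price encountered", call. = FALSE)
      eta <- stats::rnorm(n, 0, config$volatility)
      while (any(bad <- eta <= -0.9))
        eta[bad] <- stats::rnorm(sum(bad), 0, config$volatility)
      bet <- config$bets[action]
      reward <- eta * (bet - 50)
      internal$price <- internal$price * (1 + eta)
      internal$t <- t
      list(reward = reward, next_state = rep(1L, n),
           terminal = rep(TRUE, n),
           metadata = list(market = rep(market, n),
                           trial_in_market = rep(tim, n),
                           bet = bet, frac_gain = eta),
           internal = internal)
    }
  )
}

#' Task-level reward prediction error
#'
#' The percent gain of the current trial centered to the mean of its past
#' values within the same market and scaled by their standard deviation
#' (`n - 1` denominator). With fewer than two past values, or when the past
#' values are all equal (zero SD), the RPE is defined as 0.
#'
#' @param past Numeric vector of past percent gains (possibly empty).
#' @param current Current trial's percent gain.
#' @return The z-scored RPE, a single number.
#' @seealso [rpe_series()] to transform a whole within-market sequence.
#' @export
compute_rpe <- function(past, current) {
  if (length(past) < 2L) return(0)
  s <- stats::sd(past)
  if (s == 0) return(0)
  (current - mean(past)) / s
}

#' RPE sequence for one within-market gain history
#'
#' @param gains Numeric vector of percent gains in trial order.
#' @return Numeric vector of the same length: `compute_rpe` of each trial
#'   against its strict predecessors.
#' @export
rpe_series <- function(gains) {
  vapply(seq_along(gains),
         function(i) compute_rpe(gains[seq_len(i - 1L)], gains[i]),
         numeric(1))
}
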