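test_that("identical configuration and seed reproduce the simulation exactly", {
  a <- run_stationary(n_reps = 50, n_trials = 30, seed = 99)
  b <- run_stationary(n_reps = 50, n_trials = 30, seed = 99)
  expect_identical(a, b)
  c <- run_stationary(n_reps = 50, n_trials = 30, seed = 100)
  expect_false(identical(a$reward, c$reward))
  # the engine restores the caller's RNG state
  set.seed(1); before <- .Random.seed
  invisible(run_stationary(n_reps = 5, n_trials = 5, seed = 3))
  expect_identical(before, .Random.seed)
})

test_that("risk-neutral weights collapse both critics onto classic Q-learning", {
  p0 <- critic_params(k_plus = 0, k_minus = 0)
  sim <- run_stationary(p0, n_reps = 100, n_trials = 50, seed = 12)
  expect_identical(sim$q_plus, sim$q_neutral)
  expect_identical(sim$q_minus, sim$q_neutral)
  expect_identical(sim$d_q_plus, sim$d_q_neutral)
})

test_that("critic ordering Q- <= Q <= Q+ holds through entire runs at k = 0.9", {
  sim <- run_stationary(n_reps = 300, n_trials = 100, seed = 13)
  qp <- sim$q_plus[, , 1, 1]; qm <- sim$q_minus[, , 1, 1]
  qn <- sim$q_neutral[, , 1, 1]
  expect_true(all(qm <= qn + 1e-12))
  expect_true(all(qn <= qp + 1e-12))
})

test_that("extreme asymmetry makes the critics one-sided monotone", {
  # k+ = 1: negative optimistic errors carry weight (1 - k+) = 0
  sim <- run_stationary(critic_params(k_plus = 1, k_minus = 1),
                        n_reps = 100, n_trials = 60, seed = 14)
  dqp <- sim$d_q_plus; dqm <- sim$d_q_minus
  expect_true(all(dqp >= 0))
  expect_true(all(dqm <= 0))
  qp <- sim$q_plus[, , 1, 1]
  expect_true(all(qp[, -1] - qp[, -ncol(qp)] >= 0))
})

test_that("near-constant rewards drive every table to the reward value", {
  spec <- moment_spec(0.7, 1e-9, 0, 2.5)
  # slowest mode is the pessimist's gain side: factor (1 - 0.05) per trial
  sim <- run_stationary(spec = spec, n_reps = 50, n_trials = 200, seed = 15)
  expect_lt(max(abs(sim$q_plus_final - 0.7)), 1e-3)
  expect_lt(max(abs(sim$q_minus_final - 0.7)), 0.7 * 0.95^200 + 1e-6)
  expect_lt(max(abs(sim$q_neutral_final - 0.7)), 1e-3)
})

test_that("value summaries report asymptotes, gap, and IQR per critic", {
  sim <- run_stationary(n_reps = 400, n_trials = 100, seed = 16)
  s <- summarize_q(sim)
  expect_setequal(unique(s$by_trial$critic), c("q_plus", "q_minus", "q_neutral"))
  expect_identical(nrow(s$by_trial), 300L)
  # optimist above neutral above pessimist on average
  expect_gt(s$asymptote["q_plus"], s$asymptote["q_neutral"])
  expect_gt(s$asymptote["q_neutral"], s$asymptote["q_minus"])
  expect_equal(s$midpoint, unname(mean(s$asymptote[c("q_plus", "q_minus")])))
  expect_error(summarize_q(run_stationary(n_reps = 10, n_trials = 10, seed = 1)),
               "tail_window")
  igt <- run_replicates(igt_env(), n_trials = 10, n_reps = 10, seed = 1)
  expect_error(summarize_q(igt), "single-state")
})

test_that("replicate summaries tighten as 1/sqrt(R)", {
  tail_mean <- function(sim) {
    qm <- sim$q_minus[, , 1, 1]
    rowMeans(qm[, 81:100])
  }
  small <- tail_mean(run_stationary(n_reps = 400, n_trials = 100, seed = 17))
  big <- tail_mean(run_stationary(n_reps = 1600, n_trials = 100, seed = 18))
  se_small <- sd(small) / sqrt(400)
  se_big <- sd(big) / sqrt(1600)
  expect_gt(se_small / se_big, 1.5)
  expect_lt(se_small / se_big, 2.7)
})

test_that("sweeps tile the unit square and collapse at the origin", {
  g <- sweep_grid(3)
  expect_identical(nrow(g), 9L)
  expect_true(all(g$s_r == g$k_plus - g$k_minus))
  expect_error(sweep_grid(points = data.frame(k_plus = 1.2, k_minus = 0)),
               "\\[0, 1\\]")
  env <- stationary_env(spec_ref())
  sw <- run_sweep(env, sweep_grid(points = data.frame(k_plus = c(0, 0.9),
                                                      k_minus = c(0, 0.9))),
                  n_trials = 100, n_reps = 300, seed = 30)
  # risk-neutral point: gap ~ 0 and midpoint at the asymptotic Q
  expect_lt(abs(sw$gap[1]), 1e-12)
  expect_lt(abs(sw$midpoint[1] - 0.5), 0.02)
  expect_gt(sw$gap[2], 0.3)
})

test_that("deck frequencies are proportions over replicates and trials", {
  sim <- run_replicates(igt_env(), n_trials = 40, n_reps = 200, seed = 31,
                        log_q = FALSE)
  f <- deck_frequencies(sim)
  expect_named(f, c("A", "B", "C", "D"))
  expect_equal(sum(f), 1)
  expect_error(deck_frequencies(run_stationary(n_reps = 5, n_trials = 5)),
               "IGT")
})

test_that("stay probabilities match a hand-counted record list", {
  # three first-stage trials with actions L, L, R; first pair after a
  # rewarded common transition (stay), second after an unrewarded rare
  # transition (switch)
  fake <- structure(list(
    env_name = "two_stage", n_reps = 1L, n_trials = 6L,
    action = matrix(c(1L, 1L, 1L, 2L, 2L, 1L), 1),
    metadata = list(
      stage = matrix(c(1L, 2L, 1L, 2L, 1L, 2L), 1),
      transition = matrix(c("common", NA, "rare", NA, "common", NA), 1),
      rewarded = matrix(c(NA, TRUE, NA, FALSE, NA, TRUE), 1)
    )), class = "cc_sim")
  st <- stay_probabilities(fake)
  get <- function(rw, tr) st$p_stay[st$rewarded == rw & st$transition == tr]
  expect_identical(get(TRUE, "common"), 1)   # L -> L after rewarded common
  expect_identical(get(FALSE, "rare"), 0)    # L -> R after unrewarded rare
  expect_identical(st$n[st$rewarded & st$transition == "common"], 1L)
  expect_true(all(is.na(c(get(FALSE, "common"), get(TRUE, "rare")))))
})

test_that("symmetric two-stage rewards equalize all four stay cells", {
  # pinned 0.5 reward probabilities and balanced critics: no cell should
  # differ beyond Monte-Carlo error
  env <- two_stage_env(two_stage_layout(init_probs = rep(0.5, 4), walk_sd = 0))
  sim <- run_replicates(env, critic_params(gamma = 0.9), n_trials = 80,
                        n_reps = 3000, seed = 32, log_q = FALSE, log_u = FALSE)
  st <- stay_probabilities(sim)
  se <- sqrt(0.25 / min(st$n))
  expect_lt(max(st$p_stay) - min(st$p_stay), 4 * se)
})
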