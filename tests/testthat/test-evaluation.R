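test_that("exact evaluation of canonical policies matches closed forms", {
  env <- reference_env()

  # immediate guess: 250 points, no sampling, no time
  g <- evaluate_exact(static_policy(0.5), env)
  expect_equal(g$expected_reward, 250)
  expect_equal(g$expected_cost, 0)
  expect_equal(g$expected_decision_time, 0)
  expect_equal(g$accuracy, 0.5)

  # noiseless stimulus: one observation decides perfectly
  env1 <- tiny_env(1, 0, horizon = 5)
  r1 <- evaluate_exact(static_policy(0.9), env1)
  expect_equal(r1$accuracy, 1)
  expect_equal(r1$expected_decision_time, 1)
  expect_equal(r1$expected_cost, env1$costs$values[1])
  expect_equal(r1$expected_reward, 1000)

  # unreachable bound: every trial times out at the all-in -1000
  tmo <- evaluate_exact(static_policy(1), env)
  expect_equal(tmo$timeout_probability, 1)
  expect_equal(tmo$net_reward, -1000)
  expect_equal(tmo$expected_decision_time, 30)
})

test_that("stopping mass is conserved across policies and belief models", {
  for (dir in c("increasing", "decreasing")) {
    env <- reference_env(dir)
    for (K in c(Inf, 100)) {
      m <- belief_model(env, K)
      for (pol in list(backward_induction(env, m), static_policy(0.75))) {
        r <- evaluate_exact(pol, env, m)
        expect_equal(r$accuracy + r$error_probability + r$timeout_probability,
                     1, tolerance = 1e-10)
        expect_gte(r$expected_cost, 0)
        expect_lte(r$expected_cost, env$costs$cumulative[30] + 1e-9)
      }
    }
  }
})

test_that("Monte Carlo simulation agrees with exact propagation within 3 SE", {
  combos <- list(
    list(env = reference_env("increasing"), K = Inf, thr = NA),
    list(env = reference_env("increasing"), K = 100, thr = NA),
    list(env = reference_env("decreasing"), K = Inf, thr = 0.8),
    list(env = tiny_env(0.5, 0.1, 30), K = Inf, thr = NA),
    list(env = tiny_env(0.2, 0.12, 30, "decreasing"), K = 1000, thr = 0.7))
  ok <- 0L
  for (i in seq_along(combos)) {
    cb <- combos[[i]]
    m <- belief_model(cb$env, cb$K)
    pol <- if (is.na(cb$thr)) backward_induction(cb$env, m)
           else static_policy(cb$thr)
    ex <- evaluate_exact(pol, cb$env, m)
    mc <- simulate_trials(pol, cb$env, m, seed = 100 + i,
                          min_error_trials = 400,
                          batch_size = 1000, keep_trials = FALSE)$result
    if (abs(mc$net_reward - ex$net_reward) <= 3 * mc$standard_error)
      ok <- ok + 1L
    expect_equal(mc$accuracy, ex$accuracy, tolerance = 0.05)
  }
  expect_gte(ok, length(combos) - 1L)  # binomial tolerance on 3-SE misses
})

test_that("simulation is reproducible and respects the error-trial quota", {
  env <- reference_env()
  pol <- static_policy(0.66)
  a <- simulate_trials(pol, env, seed = 42, min_error_trials = 150,
                       batch_size = 500)
  b <- simulate_trials(pol, env, seed = 42, min_error_trials = 150,
                       batch_size = 500)
  expect_identical(a$trials, b$trials)
  expect_gte(a$result$n_error_trials, 150)
  expect_equal(a$result$n_trials, nrow(a$trials))

  # immediate-guess policy: accuracy ~ 0.5, net ~ 250
  g <- simulate_trials(static_policy(0.5), env, seed = 1,
                       min_error_trials = 200, batch_size = 500)$result
  expect_equal(g$net_reward, 250, tolerance = 3 * g$standard_error / 250)
  expect_equal(g$expected_decision_time, 0)

  # a policy that never errs trips the trial cap with a clear message
  env1 <- tiny_env(1, 0, horizon = 5)
  expect_error(
    simulate_trials(static_policy(0.9), env1, seed = 1,
                    min_error_trials = 10, batch_size = 100,
                    max_trials = 500),
    "trial cap")
})

test_that("reward rate reporting modes rescale without reordering", {
  env <- reference_env()
  g <- evaluate_exact(static_policy(0.5), env)
  expect_equal(reward_rate(g), 250)
  expect_equal(reward_rate(g, rr_spec(T_t = 1, t_i = 1,
                                      report_mode = "rate")), 125)

  pol <- backward_induction(env)
  dyn <- evaluate_exact(pol, env)
  bs <- best_static(env)
  sp <- rr_spec(T_t = 30, t_i = 5, report_mode = "rate")
  expect_equal(reward_rate(bs$result, sp) / reward_rate(dyn, sp),
               reward_rate(bs$result) / reward_rate(dyn))
  expect_error(rr_spec(T_t = 0, report_mode = "rate"), "denominator")
})

test_that("best static search is exhaustive, dominated, and method-consistent", {
  # pure noise: guessing immediately is the best static policy
  envn <- tiny_env(0.3, 0.3, 30)
  bsn <- best_static(envn)
  expect_equal(bsn$policy$threshold, 0.5)
  expect_equal(bsn$result$net_reward, 250)

  env <- reference_env()
  pol <- backward_induction(env)
  dyn <- evaluate_exact(pol, env)
  bs <- best_static(env)
  expect_lte(bs$result$net_reward, dyn$net_reward + 1e-9)
  # the known-rate candidate set is exhaustive over distinct policies:
  # a much finer grid cannot find anything better
  fine <- best_static(env, thresholds = seq(0.5, 1, by = 0.0005))
  expect_lte(fine$result$net_reward, bs$result$net_reward + 1e-9)

  # Monte Carlo search lands within 2 SE of the exact optimum's value
  # (candidates capped below the near-unreachable bounds whose error-trial
  # quota would require enormous simulations)
  cand <- static_candidates(env)
  cand <- cand[cand <= 0.92]
  mcbs <- best_static(env, method = "monte_carlo", thresholds = cand,
                      min_error_trials = 300, seed = 5, batch_size = 1000)
  exact_at_mc <- evaluate_exact(mcbs$policy, env)
  expect_lte(abs(exact_at_mc$net_reward - bs$result$net_reward),
             2 * mcbs$result$standard_error)
  expect_error(best_static(env, thresholds = numeric(0)), "empty")
})

test_that("softening the error penalty never hurts any policy", {
  soft <- reward_scheme(penalty_incorrect = 0, timeout_total = -1000)
  for (dir in c("increasing", "decreasing")) {
    hard_env <- reference_env(dir)
    soft_env <- environment_spec(rate_pair(0.38, 0.24), soft,
                                 logistic_cost_schedule(dir))
    for (thr in c(0.5, 0.66, 0.88)) {
      expect_gte(evaluate_exact(static_policy(thr), soft_env)$net_reward,
                 evaluate_exact(static_policy(thr), hard_env)$net_reward)
    }
    pol <- backward_induction(hard_env)  # same fixed policy in both worlds
    expect_gte(evaluate_exact(pol, soft_env)$net_reward,
               evaluate_exact(pol, hard_env)$net_reward)
  }
})
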