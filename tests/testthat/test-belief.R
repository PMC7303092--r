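test_that("known-rate likelihoods and Bayes updates match direct arithmetic", {
  rates <- rate_pair(0.38, 0.24)
  pr <- event_probabilities(rates)

  expect_equal(likelihood_known(observation(TRUE, FALSE), rates, "l"), 0.2888)
  expect_equal(likelihood_known(observation(TRUE, TRUE), rates, "l"),
               likelihood_known(observation(TRUE, TRUE), rates, "r"))
  lik_sum <- sum(vapply(list(c(1, 0), c(0, 1), c(1, 1), c(0, 0)),
                        likelihood_known, numeric(1), rates = rates,
                        hypothesis = "l"))
  expect_equal(lik_sum, 1)
  # the opposite hypothesis swaps the rate roles
  expect_equal(likelihood_known(observation(TRUE, FALSE), rates, "r"), 0.1488)

  expect_equal(update_known(0.5, observation(TRUE, FALSE), pr),
               0.2888 / 0.4376)
  expect_equal(update_known(0.5, observation(FALSE, FALSE), pr), 0.5)
  expect_equal(update_known(0.7, observation(TRUE, TRUE), pr), 0.7)
  # a lone right flash undoes a lone left flash from any start
  for (pi0 in c(0.2, 0.5, 0.9)) {
    pi1 <- update_known(pi0, observation(TRUE, FALSE), pr)
    expect_equal(update_known(pi1, observation(FALSE, TRUE), pr), pi0)
  }
})

test_that("net-evidence sufficient statistic equals the step-by-step recursion", {
  pr <- event_probabilities(rate_pair(0.38, 0.24))
  set.seed(11)
  for (rep in 1:5) {
    n <- 20
    obs <- matrix(stats::runif(2 * n) < 0.4, n, 2)
    pi <- 0.5
    d <- 0L
    for (i in seq_len(n)) {
      pi <- update_known(pi, observation(obs[i, 1], obs[i, 2]), pr)
      d <- d + (obs[i, 1] & !obs[i, 2]) - (obs[i, 2] & !obs[i, 1])
      expect_equal(optbound:::posterior_known_d(d, pr), pi, tolerance = 1e-12)
    }
  }
})

test_that("beta-marginal likelihoods have the stated closed-form anchors", {
  env <- environment_spec(rate_pair(0.38, 0.24))
  m <- belief_model(env, K = 100)

  expect_equal(log_marginal_likelihood(0, 0, 0, m, "l"), 0)
  expect_equal(log_marginal_likelihood(0, 0, 0, m, "r"), 0)
  # first-draw predictive equals the prior mean
  expect_equal(log_marginal_likelihood(1, 1, 0, m, "l"), log(0.38 * 0.76))
  # hypothesis exchange symmetry at symmetric counts
  for (t in c(2, 6, 10)) {
    k <- t / 2
    expect_equal(log_marginal_likelihood(t, k, k, m, "l"),
                 log_marginal_likelihood(t, k, k, m, "r"))
  }
  expect_error(log_marginal_likelihood(1, 1, 0, belief_model(env), "l"),
               "finite-K")
  # degenerate rates cannot carry a finite-precision beta prior
  expect_error(belief_model(environment_spec(rate_pair(1, 0)), K = 100),
               "positive")
})

test_that("uncertain posterior is symmetric, sufficient, and oracle-exact", {
  env <- tiny_env(0.38, 0.24, horizon = 4)
  m <- belief_model(env, K = 100)

  expect_equal(posterior_uncertain(2, 1, 1, m), 0.5)
  expect_equal(posterior_uncertain(6, 3, 3, m), 0.5)

  # permutation sufficiency + agreement with the sequence-product oracle,
  # enumerated over every history of length <= 4
  for (t in 1:4) {
    for (h in all_histories(t)) {
      k_l <- sum(vapply(h, `[`, integer(1), 1))
      k_r <- sum(vapply(h, `[`, integer(1), 2))
      expect_equal(posterior_uncertain(t, k_l, k_r, m),
                   hist_posterior(h, env, m), tolerance = 1e-10)
    }
  }
})

test_that("uncertain posterior converges monotonically to the known-rate one", {
  env <- reference_env()
  pr <- env$probs
  max_err <- vapply(c(1e2, 1e3, 1e4, 1e8), function(K) {
    m <- belief_model(env, K)
    worst <- 0
    for (t in 0:30) {
      k_l <- matrix(0:t, t + 1, t + 1)
      k_r <- t(k_l)
      pu <- posterior_uncertain(t, k_l, k_r, m)
      pk <- optbound:::posterior_known_d(as.vector(k_l - k_r), pr)
      worst <- max(worst, max(abs(as.vector(pu) - pk)))
    }
    worst
  }, numeric(1))
  expect_true(all(diff(max_err) < 0))
  expect_lt(max_err[4], 1e-4)  # K = 1e8 is numerically the known-rate model
})

test_that("predictive distributions normalise and make the posterior a martingale", {
  env <- reference_env()
  known <- belief_model(env)
  unc <- belief_model(env, K = 100)
  pr <- env$probs

  px <- predictive_distribution(list(d = 0), known)
  expect_equal(unname(px["p10"]), (pr$p + pr$q) / 2)
  expect_equal(unname(px["p01"]), (pr$p + pr$q) / 2)
  expect_equal(sum(px), 1, tolerance = 1e-12)

  px0 <- predictive_distribution(list(t = 0, k_l = 0, k_r = 0), unc)
  expect_equal(unname(px0["p10"]), 0.5 * (0.2888 + 0.1488))
  expect_equal(sum(px0), 1, tolerance = 1e-12)

  # martingale: predictive-weighted next posteriors equal the current one
  for (t in c(0, 3, 7)) {
    for (d in seq(-t, t)) {
      px <- predictive_distribution(list(d = d), known)
      nxt <- optbound:::posterior_known_d(c(d + 1, d - 1, d, d), pr)
      expect_equal(sum(px * nxt), optbound:::posterior_known_d(d, pr),
                   tolerance = 1e-10)
    }
    for (k_l in 0:t) for (k_r in 0:t) {
      px <- predictive_distribution(list(t = t, k_l = k_l, k_r = k_r), unc)
      nxt <- posterior_uncertain(t + 1, c(k_l + 1, k_l, k_l + 1, k_l),
                                 c(k_r, k_r + 1, k_r + 1, k_r), unc)
      expect_equal(sum(px * nxt),
                   posterior_uncertain(t, k_l, k_r, unc), tolerance = 1e-10)
    }
  }
})

test_that("belief trajectories expose the sufficient statistics", {
  env <- reference_env()
  m <- belief_model(env, K = 1000)
  obs <- rbind(c(1, 0), c(1, 1), c(0, 1), c(0, 0), c(1, 0))
  tr <- belief_trajectory(obs, m)
  expect_equal(tr$t, 0:5)
  expect_equal(tr$pi[1], 0.5)
  expect_equal(tr$k_l, c(0, 1, 2, 2, 2, 3))
  expect_equal(tr$k_r, c(0, 0, 1, 2, 2, 2))
  expect_equal(tr$d, c(0, 1, 1, 0, 0, 1))
  expect_equal(tr$pi[6], posterior_uncertain(5, 3, 2, m))
  # known-rate trajectory reduces to the d statistic
  trk <- belief_trajectory(obs, belief_model(env))
  expect_equal(trk$pi, optbound:::posterior_known_d(trk$d, env$probs))
})
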