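# Independent oracles used by the tests.  Everything here recomputes
# quantities from first principles over explicit observation histories
# (4^t nodes), deliberately avoiding the package's sufficient-statistic
# lattices and closed-form beta-function marginals.

# The four observation types as (left, right) flash indicators.
OBS <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(0L, 0L))

# Likelihood of one observation given both rates and a target side.
obs_lik <- function(x, rate_left, rate_right) {
  (if (x[1] == 1L) rate_left else 1 - rate_left) *
    (if (x[2] == 1L) rate_right else 1 - rate_right)
}

# P(history | hypothesis) for the known-rate model: a plain product of
# per-step likelihoods.
hist_lik_known <- function(history, rates, hypothesis) {
  rl <- if (hypothesis == "l") rates$theta_T else rates$theta_D
  rr <- if (hypothesis == "l") rates$theta_D else rates$theta_T
  prod(vapply(history, obs_lik, numeric(1), rate_left = rl, rate_right = rr))
}

# P(history | hypothesis) for the beta-uncertain model, built as the chain
# product of one-step beta-posterior predictive probabilities (an
# independent route to the closed-form beta-binomial marginal).
hist_lik_uncertain <- function(history, model, hypothesis) {
  aL <- if (hypothesis == "l") model$alpha_T else model$alpha_D
  bL <- if (hypothesis == "l") model$beta_T else model$beta_D
  aR <- if (hypothesis == "l") model$alpha_D else model$alpha_T
  bR <- if (hypothesis == "l") model$beta_D else model$beta_T
  lik <- 1
  for (x in history) {
    pl <- aL / (aL + bL)
    pr <- aR / (aR + bR)
    lik <- lik * (if (x[1] == 1L) pl else 1 - pl) *
      (if (x[2] == 1L) pr else 1 - pr)
    aL <- aL + x[1]; bL <- bL + 1 - x[1]
    aR <- aR + x[2]; bR <- bR + 1 - x[2]
  }
  lik
}

hist_lik <- function(history, env, model, hypothesis) {
  if (model$type == "known") hist_lik_known(history, env$rates, hypothesis)
  else hist_lik_uncertain(history, model, hypothesis)
}

# Posterior P(left is target | history) from the unbiased 0.5 prior.
hist_posterior <- function(history, env, model) {
  ml <- hist_lik(history, env, model, "l")
  mr <- hist_lik(history, env, model, "r")
  if (ml + mr == 0) return(0.5)
  ml / (ml + mr)
}

# The decision-maker's one-step predictive over the four observations.
hist_predictive <- function(history, env, model) {
  pi <- hist_posterior(history, env, model)
  vapply(OBS, function(x) {
    pl <- hist_lik(c(history, list(x)), env, model, "l") /
      max(hist_lik(history, env, model, "l"), .Machine$double.xmin)
    pr <- hist_lik(c(history, list(x)), env, model, "r") /
      max(hist_lik(history, env, model, "r"), .Machine$double.xmin)
    pi * pl + (1 - pi) * pr
  }, numeric(1))
}

# Brute-force backward induction over the un-aggregated history tree.
# Returns the optimal go-forward value at the given history node.
oracle_value <- function(env, model, history = list()) {
  t <- length(history)
  pi <- hist_posterior(history, env, model)
  rew <- env$rewards
  vdec <- max(decide_value(pi, "l", rew), decide_value(pi, "r", rew))
  if (t == env$horizon) return(vdec)
  px <- hist_predictive(history, env, model)
  cont <- -env$costs$values[t + 1] +
    sum(px * vapply(seq_along(OBS), function(i) {
      oracle_value(env, model, c(history, list(OBS[[i]])))
    }, numeric(1)))
  max(vdec, cont)
}

# All observation histories of length t (list of lists).
all_histories <- function(t) {
  if (t == 0) return(list(list()))
  shorter <- all_histories(t - 1)
  out <- list()
  for (h in shorter) for (x in OBS) out[[length(out) + 1L]] <- c(h, list(x))
  out
}

# Reference environment of the worked examples: theta = (0.38, 0.24).
reference_env <- function(direction = "increasing", horizon = 30L) {
  environment_spec(rate_pair(0.38, 0.24),
                   reward_scheme(horizon = horizon),
                   logistic_cost_schedule(direction, horizon = horizon))
}

# Small environment helper for oracle-sized tests.
tiny_env <- function(theta_T, theta_D, horizon, direction = "increasing") {
  environment_spec(rate_pair(theta_T, theta_D),
                   reward_scheme(horizon = horizon),
                   logistic_cost_schedule(direction, horizon = horizon))
}
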