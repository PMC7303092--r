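#' Observation
#'
#' One time step's sensory event: whether the left and the right stimulus
#' flashed.  The four possible values are (1,0), (0,1), (1,1), (0,0).
#'
#' @param left_flash,right_flash Logical scalars.
#' @return An object of class `"observation"`.
#' @export
observation <- function(left_flash, right_flash) {
  stopifnot(is.logical(left_flash) || left_flash %in% c(0, 1),
            is.logical(right_flash) || right_flash %in% c(0, 1))
  structure(list(left_flash = as.logical(left_flash),
                 right_flash = as.logical(right_flash)),
            class = "observation")
}

#' Belief model: known rates or beta-uncertain rates
#'
#' Describes how the decision-maker updates beliefs.  With `K = Inf` the
#' rates are known exactly and the posterior depends on the data only
#' through the net evidence count `d` (veridical minus misleading
#' discriminating observations).  With finite prior precision `K` the rates
#' are uncertain: each rate carries a beta prior with `alpha = theta * K`,
#' `beta = (1 - theta) * K` (mode at the true rate for large `K`), the
#' likelihood is marginalised over the rates, and the sufficient statistic
#' grows to the per-side flash counts `(k_l, k_r)`.
#'
#' @param env An [environment_spec()].
#' @param K Prior precision: positive finite number, or `Inf` for exactly
#'   known rates.
#' @return An object of class `"belief_model"`, with `type` `"known"` or
#'   `"uncertain"`; the uncertain variant carries the beta parameters
#'   `alpha_T`, `beta_T`, `alpha_D`, `beta_D`.
#' @examples
#' env <- environment_spec(rate_pair(0.38, 0.24))
#' belief_model(env, K = 100)
#' @export
belief_model <- function(env, K = Inf) {
  stopifnot(inherits(env, "env_spec"), is.numeric(K), length(K) == 1L, K > 0)
  if (is.infinite(K)) {
    return(structure(list(type = "known", env = env, K = Inf),
                     class = "belief_model"))
  }
  tT <- env$rates$theta_T
  tD <- env$rates$theta_D
  par <- c(alpha_T = tT * K, beta_T = (1 - tT) * K,
           alpha_D = tD * K, beta_D = (1 - tD) * K)
  if (any(par <= 0))
    stop("beta prior parameters must be positive: finite K requires rates strictly inside (0, 1)")
  structure(c(list(type = "uncertain", env = env, K = K), as.list(par)),
            class = "belief_model")
}

#' Observation likelihood under known rates
#'
#' Likelihood of a single observation under one of the two hypotheses.
#' Under "left is target" the left stimulus flashes with rate `theta_T` and
#' the right with `theta_D`; the opposite hypothesis swaps the roles.
#'
#' @param x An [observation()] (or length-2 0/1 vector `(left, right)`).
#' @param rates A [rate_pair()].
#' @param hypothesis `"l"` or `"r"`.
#' @return The likelihood, a probability.
#' @examples
#' likelihood_known(observation(TRUE, FALSE), rate_pair(0.38, 0.24), "l")
#' @export
likelihood_known <- function(x, rates, hypothesis = c("l", "r")) {
  hypothesis <- match.arg(hypothesis)
  if (!inherits(x, "observation")) x <- observation(x[[1]], x[[2]])
  stopifnot(inherits(rates, "rate_pair"))
  left_rate <- if (hypothesis == "l") rates$theta_T else rates$theta_D
  right_rate <- if (hypothesis == "l") rates$theta_D else rates$theta_T
  (if (x$left_flash) left_rate else 1 - left_rate) *
    (if (x$right_flash) right_rate else 1 - right_rate)
}

#' Bayes update of the posterior belief under known rates
#'
#' One-step Bayesian update of the belief `pi` that the left stimulus is the
#' target.  Observations in which both or neither stimulus flashes have
#' equal likelihood under either hypothesis and leave the belief unchanged;
#' a lone left flash multiplies the odds by `p/q`, a lone right flash by
#' `q/p`.
#'
#' @param pi Current belief in \[0, 1\] that the left stimulus is the target.
#' @param x An [observation()].
#' @param probs An [event_probabilities()].
#' @return The updated belief.
#' @examples
#' pr <- event_probabilities(rate_pair(0.38, 0.24))
#' update_known(0.5, observation(TRUE, FALSE), pr)  # 0.2888 / 0.4376
#' @export
update_known <- function(pi, x, probs) {
  stopifnot(is.numeric(pi), pi >= 0, pi <= 1, inherits(probs, "event_probs"))
  if (!inherits(x, "observation")) x <- observation(x[[1]], x[[2]])
  if (x$left_flash == x$right_flash) return(pi)
  lam_l <- if (x$left_flash) probs$p else probs$q
  lam_r <- if (x$left_flash) probs$q else probs$p
  num <- pi * lam_l
  den <- num + (1 - pi) * lam_r
  if (den == 0) return(0.5)
  num / den
}

# Posterior that the left stimulus is the target, from the signed net
# evidence count d, under known rates.  pi(d) = (p/q)^d / (1 + (p/q)^d),
# computed as plogis(d * log(p/q)); vectorised over d.
posterior_known_d <- function(d, probs) {
  stopifnot(inherits(probs, "event_probs"))
  p <- probs$p
  q <- probs$q
  out <- rep(0.5, length(d))
  if (p == q) return(out)
  llr <- log(p) - log(q)  # may be +Inf when q = 0
  nz <- d != 0
  if (is.finite(llr)) {
    out[nz] <- stats::plogis(d[nz] * llr)
  } else {
    out[nz] <- ifelse(d[nz] > 0, 1, 0)
  }
  out
}

#' Log marginal likelihood of the observation counts under rate uncertainty
#'
#' Full-history marginal likelihood of a sequence with `k_l` left flashes and
#' `k_r` right flashes in `t` steps, with the rates integrated out against
#' their beta priors.  Each side contributes a beta-binomial sequence
#' marginal `B(alpha + k, beta + t - k) / B(alpha, beta)` (no binomial
#' coefficient: the order of a specific sequence is fixed); under "left is
#' target" the target prior applies to the left counts, under the opposite
#' hypothesis to the right counts.  Computed in log space via `lbeta`.
#'
#' @param t Integer number of observations (vectorised with `k_l`, `k_r`).
#' @param k_l,k_r Flash counts for the left and right stimulus, in
#'   \[0, `t`\].
#' @param model A finite-`K` [belief_model()].
#' @param hypothesis `"l"` or `"r"`.
#' @return Log marginal likelihood(s).
#' @export
log_marginal_likelihood <- function(t, k_l, k_r, model,
                                    hypothesis = c("l", "r")) {
  hypothesis <- match.arg(hypothesis)
  stopifnot(inherits(model, "belief_model"))
  if (model$type != "uncertain")
    stop("log_marginal_likelihood requires a finite-K (uncertain) belief model")
  stopifnot(all(k_l >= 0), all(k_r >= 0), all(k_l <= t), all(k_r <= t))
  if (hypothesis == "l") {
    aL <- model$alpha_T; bL <- model$beta_T
    aR <- model$alpha_D; bR <- model$beta_D
  } else {
    aL <- model$alpha_D; bL <- model$beta_D
    aR <- model$alpha_T; bR <- model$beta_T
  }
  lbeta(aL + k_l, bL + t - k_l) - lbeta(aL, bL) +
    lbeta(aR + k_r, bR + t - k_r) - lbeta(aR, bR)
}

#' Posterior belief under rate uncertainty
#'
#' Posterior probability that the left stimulus is the target given the
#' flash counts, from an unbiased prior of 0.5:
#' `pi = m_l / (m_l + m_r)` with the two marginal likelihoods computed in
#' log space for stability.  As `K` grows this converges to the known-rate
#' posterior for the same net evidence.
#'
#' @inheritParams log_marginal_likelihood
#' @return Posterior probability (vectorised like the count arguments).
#' @examples
#' env <- environment_spec(rate_pair(0.38, 0.24))
#' m <- belief_model(env, K = 100)
#' posterior_uncertain(2, 1, 1, m)  # balanced evidence: 0.5
#' @export
posterior_uncertain <- function(t, k_l, k_r, model) {
  ll <- log_marginal_likelihood(t, k_l, k_r, model, "l")
  lr <- log_marginal_likelihood(t, k_l, k_r, model, "r")
  stats::plogis(ll - lr)
}

# Posterior tables for the uncertain model: element [[t + 1]] is the
# (t+1) x (t+1) matrix of pi over k_l (rows) and k_r (cols), t = 0..horizon.
posterior_table_uncertain <- function(model, horizon = model$env$horizon) {
  lapply(0:horizon, function(t) {
    k_l <- matrix(0:t, t + 1L, t + 1L)
    k_r <- matrix(0:t, t + 1L, t + 1L, byrow = TRUE)
    matrix(posterior_uncertain(t, k_l, k_r, model), t + 1L, t + 1L)
  })
}

#' One-step predictive distribution over the four observations
#'
#' The decision-maker's own predictive distribution for the next
#' observation, mixing the two hypothesis-conditional predictives with the
#' current posterior.  Under known rates the conditional event probabilities
#' are fixed at `(p, q, p_both, p_neither)`; under rate uncertainty each
#' side's flash probability is the beta-posterior mean
#' `(alpha + k) / (K + t)`.  This is the transition law of the belief-state
#' dynamic program and makes the posterior a martingale.
#'
#' @param state For a known-rate model, a list with field `d` (signed net
#'   evidence); for an uncertain model, a list with fields `t`, `k_l`,
#'   `k_r`.
#' @param model A [belief_model()].
#' @return Named probability vector `c(p10, p01, p11, p00)` over the events
#'   "left only", "right only", "both", "neither"; sums to 1.
#' @examples
#' env <- environment_spec(rate_pair(0.38, 0.24))
#' predictive_distribution(list(d = 0), belief_model(env))
#' @export
predictive_distribution <- function(state, model) {
  stopifnot(inherits(model, "belief_model"))
  if (model$type == "known") {
    probs <- model$env$probs
    pi <- posterior_known_d(state$d, probs)
    c(p10 = pi * probs$p + (1 - pi) * probs$q,
      p01 = pi * probs$q + (1 - pi) * probs$p,
      p11 = probs$p_both,
      p00 = probs$p_neither)
  } else {
    t <- state$t
    k_l <- state$k_l
    k_r <- state$k_r
    pi <- posterior_uncertain(t, k_l, k_r, model)
    den <- model$K + t
    # hypothesis-conditional beta-posterior-mean flash probabilities
    fl_l <- (model$alpha_T + k_l) / den  # left flash | left is target
    fr_l <- (model$alpha_D + k_r) / den
    fl_r <- (model$alpha_D + k_l) / den  # left flash | right is target
    fr_r <- (model$alpha_T + k_r) / den
    c(p10 = pi * fl_l * (1 - fr_l) + (1 - pi) * fl_r * (1 - fr_r),
      p01 = pi * (1 - fl_l) * fr_l + (1 - pi) * (1 - fl_r) * fr_r,
      p11 = pi * fl_l * fr_l + (1 - pi) * fl_r * fr_r,
      p00 = pi * (1 - fl_l) * (1 - fr_l) + (1 - pi) * (1 - fl_r) * (1 - fr_r))
  }
}

#' Belief trajectory for a sequence of observations
#'
#' Runs the belief model over an observation sequence and returns the
#' posterior after every step, together with the sufficient statistics.
#'
#' @param observations A list of [observation()]s (or a 2-column 0/1
#'   matrix with columns left, right).
#' @param model A [belief_model()].
#' @return A `data.frame` with columns `t`, `k_l`, `k_r`, `d`, `pi`
#'   (row `t = 0` is the unbiased prior 0.5).
#' @export
belief_trajectory <- function(observations, model) {
  stopifnot(inherits(model, "belief_model"))
  if (is.matrix(observations)) {
    obs <- lapply(seq_len(nrow(observations)),
                  function(i) observation(observations[i, 1], observations[i, 2]))
  } else obs <- observations
  n <- length(obs)
  k_l <- k_r <- d <- integer(n + 1L)
  pi <- numeric(n + 1L)
  pi[1L] <- 0.5
  for (i in seq_len(n)) {
    x <- obs[[i]]
    k_l[i + 1L] <- k_l[i] + as.integer(x$left_flash)
    k_r[i + 1L] <- k_r[i] + as.integer(x$right_flash)
    d[i + 1L] <- d[i] + as.integer(x$left_flash & !x$right_flash) -
      as.integer(x$right_flash & !x$left_flash)
    pi[i + 1L] <- if (model$type == "known") {
      posterior_known_d(d[i + 1L], model$env$probs)
    } else {
      posterior_uncertain(i, k_l[i + 1L], k_r[i + 1L], model)
    }
  }
  data.frame(t = 0:n, k_l = k_l, k_r = k_r, d = d, pi = pi)
}
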