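# ---- result container -----------------------------------------------------

evaluation_result <- function(R, C, Td, accuracy, error, timeout,
                              standard_error = NA_real_,
                              n_trials = NA_integer_,
                              n_error_trials = NA_integer_) {
  structure(list(expected_reward = R,
                 expected_cost = C,
                 net_reward = R - C,
                 expected_decision_time = Td,
                 accuracy = accuracy,
                 error_probability = error,
                 timeout_probability = timeout,
                 standard_error = standard_error,
                 n_trials = n_trials,
                 n_error_trials = n_error_trials),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf(paste0("<evaluation_result> net %.4f (reward %.4f - cost %.4f)\n",
                     "  accuracy %.4f, errors %.4f, timeouts %.4f, mean ",
                     "decision time %.3f\n"),
              x$net_reward, x$expected_reward, x$expected_cost, x$accuracy,
              x$error_probability, x$timeout_probability,
              x$expected_decision_time))
  if (!is.na(x$n_trials))
    cat(sprintf("  Monte Carlo: %d trials (%d errors), SE(net) %.4f\n",
                x$n_trials, x$n_error_trials, x$standard_error))
  invisible(x)
}

# ---- exact forward propagation --------------------------------------------

# Forward-propagates state occupancancy under the TRUE generative process for
# one target side over the (t, d) lattice.  `stop_fun(t, pi)` returns
# logical stop masks (n_states x ncol) for decide-left / decide-right;
# `ncol` parallel policies (columns) are propagated at once.
propagate_known <- function(env, side, ncol, stop_fun) {
  T <- env$horizon
  probs <- env$probs
  rew <- env$rewards
  ccum0 <- c(0, env$costs$cumulative)
  p_up <- if (side == "l") probs$p else probs$q  # lone target-side flash
  p_dn <- if (side == "l") probs$q else probs$p
  p_st <- probs$p_both + probs$p_neither
  occ <- matrix(1, 1L, ncol)
  R <- C <- Td <- corr <- err <- tmo <- numeric(ncol)
  for (t in 0:T) {
    pi <- posterior_known_d(seq.int(-t, t), probs)
    s <- stop_fun(t, pi)
    Pl <- colSums(occ * s$l)
    Pr <- colSums(occ * s$r)
    stopped <- Pl + Pr
    if (side == "l") {
      corr <- corr + Pl; err <- err + Pr
      R <- R + Pl * rew$reward_correct + Pr * rew$penalty_incorrect
    } else {
      corr <- corr + Pr; err <- err + Pl
      R <- R + Pr * rew$reward_correct + Pl * rew$penalty_incorrect
    }
    C <- C + stopped * ccum0[t + 1L]
    Td <- Td + stopped * t
    occ <- occ * !(s$l | s$r)
    if (t < T) {
      nw <- matrix(0, 2L * t + 3L, ncol)
      i <- seq_len(2L * t + 1L)
      nw[i, ] <- p_dn * occ
      nw[i + 1L, ] <- nw[i + 1L, , drop = FALSE] + p_st * occ
      nw[i + 2L, ] <- nw[i + 2L, , drop = FALSE] + p_up * occ
      occ <- nw
    } else {
      tmo <- colSums(occ)
      R <- R + tmo * (rew$timeout_total + ccum0[T + 1L])
      C <- C + tmo * ccum0[T + 1L]
      Td <- Td + tmo * T
    }
  }
  list(R = R, C = C, Td = Td, correct = corr, error = err, timeout = tmo)
}

# Same engine over the (t, k_l, k_r) count lattice (uncertain belief model).
# States at time t are flattened column-major: index kl + 1 + (t+1)*kr.
propagate_uncertain <- function(env, side, ncol, stop_fun, pt) {
  T <- env$horizon
  probs <- env$probs
  rew <- env$rewards
  ccum0 <- c(0, env$costs$cumulative)
  # true event probabilities by outcome, oriented to the true target side
  p10 <- if (side == "l") probs$p else probs$q  # left-only flash
  p01 <- if (side == "l") probs$q else probs$p
  p11 <- probs$p_both
  p00 <- probs$p_neither
  occ <- matrix(1, 1L, ncol)
  R <- C <- Td <- corr <- err <- tmo <- numeric(ncol)
  for (t in 0:T) {
    pi <- as.vector(pt[[t + 1L]])
    s <- stop_fun(t, pi)
    Pl <- colSums(occ * s$l)
    Pr <- colSums(occ * s$r)
    stopped <- Pl + Pr
    if (side == "l") {
      corr <- corr + Pl; err <- err + Pr
      R <- R + Pl * rew$reward_correct + Pr * rew$penalty_incorrect
    } else {
      corr <- corr + Pr; err <- err + Pl
      R <- R + Pr * rew$reward_correct + Pl * rew$penalty_incorrect
    }
    C <- C + stopped * ccum0[t + 1L]
    Td <- Td + stopped * t
    occ <- occ * !(s$l | s$r)
    if (t < T) {
      kl <- rep.int(0:t, t + 1L)
      kr <- rep(0:t, each = t + 1L)
      i00 <- kl + 1L + (t + 2L) * kr
      nw <- matrix(0, (t + 2L)^2, ncol)
      nw[i00, ] <- p00 * occ
      nw[i00 + 1L, ] <- nw[i00 + 1L, , drop = FALSE] + p10 * occ
      j01 <- i00 + t + 2L
      nw[j01, ] <- nw[j01, , drop = FALSE] + p01 * occ
      nw[j01 + 1L, ] <- nw[j01 + 1L, , drop = FALSE] + p11 * occ
      occ <- nw
    } else {
      tmo <- colSums(occ)
      R <- R + tmo * (rew$timeout_total + ccum0[T + 1L])
      C <- C + tmo * ccum0[T + 1L]
      Td <- Td + tmo * T
    }
  }
  list(R = R, C = C, Td = Td, correct = corr, error = err, timeout = tmo)
}

# Averages the two equiprobable target sides and checks mass conservation.
propagate_both_sides <- function(env, model, ncol, stop_fun) {
  if (model$type == "known") {
    a <- propagate_known(env, "l", ncol, stop_fun)
    b <- propagate_known(env, "r", ncol, stop_fun)
  } else {
    pt <- posterior_table_uncertain(model, env$horizon)
    a <- propagate_uncertain(env, "l", ncol, stop_fun, pt)
    b <- propagate_uncertain(env, "r", ncol, stop_fun, pt)
  }
  out <- Map(function(u, v) (u + v) / 2, a, b)
  mass <- out$correct + out$error + out$timeout
  if (any(abs(mass - 1) > 1e-9))
    stop("internal error: stopping probabilities do not conserve mass")
  out
}

stop_fun_from_policy <- function(policy) {
  function(t, pi) {
    lay <- policy$layers[[t + 1L]]
    act <- as.vector(lay$action)
    list(l = matrix(act == "decide_l", ncol = 1L),
         r = matrix(act == "decide_r", ncol = 1L))
  }
}

stop_fun_from_thresholds <- function(thresholds, horizon) {
  function(t, pi) {
    l <- outer(pi, thresholds, `>=`)
    r <- outer(pi, 1 - thresholds, `<=`) & !l  # exact 0.5 tie goes left
    list(l = l, r = r)
  }
}

#' Exact policy evaluation by forward propagation
#'
#' Deterministically computes a policy's expected reward, sampling cost,
#' decision time, accuracy, error, and timeout probabilities by propagating
#' state occupancy probabilities under the true generative process,
#' conditioning on each target side with probability 1/2.  Under a
#' finite-`K` belief model the observations are still generated from the
#' true rates; only the decision-maker's updating marginalises over them.
#'
#' @param policy A [backward_induction()] policy table or a
#'   [static_policy()].
#' @param env An [environment_spec()].
#' @param model A [belief_model()] describing the decision-maker's updating.
#' @return An object of class `"evaluation_result"`.
#' @examples
#' env <- environment_spec(rate_pair(0.38, 0.24))
#' evaluate_exact(backward_induction(env), env)
#' @export
evaluate_exact <- function(policy, env, model = belief_model(env)) {
  UseMethod("evaluate_exact")
}

#' @export
evaluate_exact.policy_table <- function(policy, env, model = policy$model) {
  stopifnot(inherits(env, "env_spec"), inherits(model, "belief_model"))
  if (policy$env$horizon != env$horizon)
    stop("policy and environment horizons differ")
  if (policy$model_type != model$type)
    stop("policy was computed under a different belief model type")
  r <- propagate_both_sides(env, model, 1L, stop_fun_from_policy(policy))
  evaluation_result(r$R, r$C, r$Td, r$correct, r$error, r$timeout)
}

#' @export
evaluate_exact.static_policy <- function(policy, env, model = belief_model(env)) {
  stopifnot(inherits(env, "env_spec"), inherits(model, "belief_model"))
  r <- propagate_both_sides(env, model, 1L,
                            stop_fun_from_thresholds(policy$threshold,
                                                     env$horizon))
  evaluation_result(r$R, r$C, r$Td, r$correct, r$error, r$timeout)
}

# Exact evaluation of many static thresholds at once (vectorised columns).
eval_static_exact <- function(thresholds, env, model) {
  r <- propagate_both_sides(env, model, length(thresholds),
                            stop_fun_from_thresholds(thresholds, env$horizon))
  data.frame(threshold = thresholds,
             net_reward = r$R - r$C,
             expected_reward = r$R,
             expected_cost = r$C,
             expected_decision_time = r$Td,
             accuracy = r$correct,
             error_probability = r$error,
             timeout_probability = r$timeout)
}

# ---- reward rate ----------------------------------------------------------

#' Reward-rate reporting specification
#'
#' Trial-timing constants of the reward-rate definition.  With fixed trial
#' length, fixed inter-trial interval, and no punishment delay the
#' denominator is constant, so maximising reward rate is the same as
#' maximising expected net reward; `report_mode = "net_reward"` (the
#' default) reports the numerator, `"rate"` divides by the constant
#' denominator.
#'
#' @param T_t Total trial duration in steps (default 30: trials run to the
#'   deadline regardless of the decision time).
#' @param t_i Inter-trial interval (default 0).
#' @param t_p Punishment delay for errors (default 0).
#' @param report_mode `"net_reward"` or `"rate"`.
#' @return An object of class `"rr_spec"`.
#' @export
rr_spec <- function(T_t = 30, t_i = 0, t_p = 0,
                    report_mode = c("net_reward", "rate")) {
  report_mode <- match.arg(report_mode)
  stopifnot(is.numeric(T_t), is.numeric(t_i), is.numeric(t_p))
  if (report_mode == "rate" && T_t + t_i + t_p <= 0)
    stop("rate mode requires a positive denominator T_t + t_i + t_p")
  structure(list(T_t = T_t, t_i = t_i, t_p = t_p, report_mode = report_mode),
            class = "rr_spec")
}

#' Reward rate of an evaluated policy
#'
#' `net_reward` mode returns the expected reward minus expected sampling
#' costs; `rate` mode divides by the constant trial-timing denominator.
#' Policy orderings (and static/dynamic ratios) are identical in both modes.
#'
#' @param result An `"evaluation_result"`.
#' @param spec An [rr_spec()].
#' @return A number: points, or points per time step.
#' @export
reward_rate <- function(result, spec = rr_spec()) {
  stopifnot(inherits(result, "evaluation_result"), inherits(spec, "rr_spec"))
  net <- result$expected_reward - result$expected_cost
  if (spec$report_mode == "net_reward") net
  else net / (spec$T_t + spec$t_i + spec$t_p)
}

# ---- Monte Carlo simulation -----------------------------------------------

#' Monte Carlo policy evaluation by trial simulation
#'
#' Samples complete trials from the true generative process (target side
#' equiprobable, observations Bernoulli at the true rates), applies the
#' policy's stopping rule to the decision-maker's belief trajectory, and
#' keeps simulating fixed-size batches until a minimum number of
#' error trials has accumulated, so the decision-time distribution is well
#' resolved even for accurate policies.  Batches are seeded from a counter
#' so the same `seed` reproduces the identical trial stream.
#'
#' @param policy A [backward_induction()] policy table or a
#'   [static_policy()].
#' @param env An [environment_spec()].
#' @param model A [belief_model()].
#' @param seed Integer seed.
#' @param min_error_trials Error-trial quota before stopping (default
#'   20000).
#' @param batch_size Trials per batch (default 2000).
#' @param max_trials Trial cap; exceeding it before meeting the quota is an
#'   error (default 2e6), which catches policies that never err.
#' @param keep_trials Return the per-trial records (default `TRUE`).
#' @return A list with `result` (an `"evaluation_result"` including the
#'   standard error of the net reward) and, if requested, `trials` (a
#'   `data.frame` with one row per trial: `true_target_side`, `decision`,
#'   `decision_time`, `reward`, `cost`).
#' @examples
#' env <- environment_spec(rate_pair(0.38, 0.24))
#' sim <- simulate_trials(static_policy(0.5), env, seed = 1,
#'                        min_error_trials = 50, batch_size = 200)
#' sim$result$accuracy  # ~0.5 for the immediate-guess policy
#' @export
simulate_trials <- function(policy, env, model = belief_model(env), seed = 1L,
                            min_error_trials = 20000L, batch_size = 2000L,
                            max_trials = 2e6, keep_trials = TRUE) {
  stopifnot(inherits(env, "env_spec"), inherits(model, "belief_model"),
            min_error_trials >= 1, batch_size >= 1)
  is_static <- inherits(policy, "static_policy")
  if (!is_static && !inherits(policy, "policy_table"))
    stop("policy must be a policy_table or static_policy")
  T <- env$horizon
  tT <- env$rates$theta_T
  tD <- env$rates$theta_D
  rew <- env$rewards
  ccum0 <- c(0, env$costs$cumulative)
  pt <- if (is_static && model$type == "uncertain")
    posterior_table_uncertain(model, T) else NULL

  actions_at <- function(t, d, kl, kr) {
    if (!is_static) {
      lay <- policy$layers[[t + 1L]]
      if (policy$model_type == "known") lay$action[d + t + 1L]
      else lay$action[cbind(kl + 1L, kr + 1L)]
    } else {
      pi <- if (model$type == "known") posterior_known_d(d, env$probs)
      else pt[[t + 1L]][cbind(kl + 1L, kr + 1L)]
      static_policy_actions(policy$threshold, pi)
    }
  }

  sim_batch <- function(n) {
    side <- sample(1:2, n, replace = TRUE)   # 1 = left target
    pl <- ifelse(side == 1L, tT, tD)
    pr <- ifelse(side == 1L, tD, tT)
    d <- kl <- kr <- integer(n)
    dec <- integer(n)                         # 0 none, 1 left, 2 right
    Td <- rep.int(T, n)
    active <- rep(TRUE, n)
    for (t in 0:T) {
      idx <- which(active)
      if (length(idx) == 0L) break
      a <- actions_at(t, d[idx], kl[idx], kr[idx])
      sl <- a == "decide_l"
      sr <- a == "decide_r"
      dec[idx[sl]] <- 1L
      dec[idx[sr]] <- 2L
      Td[idx[sl | sr]] <- t
      active[idx] <- !(sl | sr)
      if (t < T) {
        idx <- which(active)
        if (length(idx) == 0L) break
        lf <- stats::runif(length(idx)) < pl[idx]
        rf <- stats::runif(length(idx)) < pr[idx]
        kl[idx] <- kl[idx] + lf
        kr[idx] <- kr[idx] + rf
        d[idx] <- d[idx] + (lf & !rf) - (rf & !lf)
      }
    }
    correct <- dec == side
    reward <- ifelse(dec == 0L, rew$timeout_total + ccum0[T + 1L],
                     ifelse(correct, rew$reward_correct,
                            rew$penalty_incorrect))
    cost <- ccum0[Td + 1L]
    data.frame(true_target_side = c("l", "r")[side],
               decision = c("timeout", "l", "r")[dec + 1L],
               decision_time = Td, reward = reward, cost = cost,
               correct = correct, error = dec != 0L & !correct)
  }

  batches <- list()
  n_err <- 0L
  n_tot <- 0L
  b <- 0L
  while (n_err < min_error_trials) {
    if (n_tot >= max_trials)
      stop(sprintf(paste0("trial cap of %g reached with only %d error ",
                          "trials (quota %d); the policy may never err in ",
                          "this environment - raise max_trials or lower ",
                          "min_error_trials"),
                   max_trials, n_err, min_error_trials))
    b <- b + 1L
    set.seed(((as.integer(seed) + b - 1L) %% 2147483646L) + 1L)
    df <- sim_batch(batch_size)
    batches[[b]] <- df
    n_err <- n_err + sum(df$error)
    n_tot <- n_tot + nrow(df)
  }
  trials <- do.call(rbind, batches)
  net <- trials$reward - trials$cost
  res <- evaluation_result(
    R = mean(trials$reward), C = mean(trials$cost),
    Td = mean(trials$decision_time),
    accuracy = mean(trials$correct),
    error = mean(trials$error),
    timeout = mean(trials$decision == "timeout"),
    standard_error = stats::sd(net) / sqrt(n_tot),
    n_trials = n_tot, n_error_trials = n_err)
  out <- list(result = res)
  if (keep_trials)
    out$trials <- trials[, c("true_target_side", "decision", "decision_time",
                             "reward", "cost")]
  out
}

# ---- best static threshold ------------------------------------------------

#' Candidate static thresholds
#'
#' For a known-rate model the reachable posteriors form a finite set, so the
#' candidates (0.5 plus the midpoints between consecutive reachable
#' posterior values above 0.5) enumerate every distinct static policy and
#' make the search exact.  For an uncertain model a 0.005-step grid over
#' \[0.5, 1\] is used.
#'
#' @param env An [environment_spec()].
#' @param model A [belief_model()].
#' @return Increasing numeric vector of thresholds starting at 0.5.
#' @export
static_candidates <- function(env, model = belief_model(env)) {
  stopifnot(inherits(env, "env_spec"), inherits(model, "belief_model"))
  if (model$type == "known") {
    pis <- posterior_known_d(0:env$horizon, env$probs)
    u <- sort(unique(pis[pis > 0.5]))
    if (length(u) == 0L) return(0.5)
    prev <- c(0.5, u[-length(u)])
    c(0.5, (prev + u) / 2)
  } else {
    seq(0.5, 1, by = 0.005)
  }
}

#' Best static decision criterion
#'
#' Evaluates every candidate static threshold and returns the one with the
#' highest expected net reward (ties broken toward the lower threshold).
#' The exact method uses deterministic forward propagation; the Monte Carlo
#' method evaluates each candidate by trial simulation with an error-trial
#' quota, mirroring the simulation-based search of the original analysis.
#'
#' @param env An [environment_spec()].
#' @param model A [belief_model()].
#' @param method `"exact"` (default) or `"monte_carlo"`.
#' @param thresholds Candidate thresholds; defaults to
#'   [static_candidates()].
#' @param min_error_trials,seed,batch_size Monte Carlo controls.
#' @return A list of class `"best_static"` with `policy` (the maximising
#'   [static_policy()]), `result` (its `"evaluation_result"`), and `table`
#'   (per-candidate evaluations).
#' @examples
#' env <- environment_spec(rate_pair(0.38, 0.24))
#' bs <- best_static(env)
#' bs$policy$threshold
#' @export
best_static <- function(env, model = belief_model(env),
                        method = c("exact", "monte_carlo"),
                        thresholds = static_candidates(env, model),
                        min_error_trials = 20000L, seed = 1L,
                        batch_size = 2000L) {
  method <- match.arg(method)
  if (length(thresholds) == 0L) stop("empty static-threshold candidate set")
  thresholds <- sort(thresholds)
  if (method == "exact") {
    tab <- eval_static_exact(thresholds, env, model)
    k <- which.max(tab$net_reward)
    res <- evaluation_result(tab$expected_reward[k], tab$expected_cost[k],
                             tab$expected_decision_time[k], tab$accuracy[k],
                             tab$error_probability[k],
                             tab$timeout_probability[k])
  } else {
    evals <- lapply(seq_along(thresholds), function(i) {
      simulate_trials(static_policy(thresholds[i]), env, model,
                      seed = seed + i - 1L,
                      min_error_trials = min_error_trials,
                      batch_size = batch_size, keep_trials = FALSE)$result
    })
    net <- vapply(evals, function(r) r$net_reward, numeric(1))
    tab <- data.frame(threshold = thresholds, net_reward = net)
    k <- which.max(net)
    res <- evals[[k]]
  }
  structure(list(policy = static_policy(thresholds[k]), result = res,
                 table = tab),
            class = "best_static")
}
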