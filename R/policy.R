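#' Expected immediate reward of committing to a decision
#'
#' Expected points from deciding now at posterior belief `pi`, excluding
#' sampling costs already sunk: `reward_correct * pi +
#' penalty_incorrect * (1 - pi)` for the left side, with `pi` mirrored for
#' the right side.  At `pi = 0.5` either side is worth 250 points under the
#' default scheme.
#'
#' @param pi Posterior belief(s) that the left stimulus is the target.
#' @param side `"l"` or `"r"`.
#' @param rewards A [reward_scheme()].
#' @return Expected points (vectorised over `pi`).
#' @export
decide_value <- function(pi, side = c("l", "r"), rewards = reward_scheme()) {
  side <- match.arg(side)
  stopifnot(all(pi >= 0), all(pi <= 1), inherits(rewards, "reward_scheme"))
  pc <- if (side == "l") pi else 1 - pi
  rewards$reward_correct * pc + rewards$penalty_incorrect * (1 - pc)
}

# Shared layer finisher: given decide values and (optionally) a
# continuation value, apply the tie-breaking rules (decide beats wait on
# exact ties; the left side is reported at exact decide ties, flagged).
resolve_actions <- function(vl, vr, cont = NULL) {
  vdec <- pmax(vl, vr)
  side <- ifelse(vl >= vr, "decide_l", "decide_r")
  tie <- vl == vr
  if (is.null(cont)) {
    list(value = vdec, action = side, decide_tie = tie)
  } else {
    wait <- cont > vdec
    list(value = ifelse(wait, cont, vdec),
         action = ifelse(wait, "wait", side),
         decide_tie = tie & !wait)
  }
}

#' Reward-rate optimal policy by backward induction
#'
#' Computes the optimal decide-left / decide-right / wait policy for every
#' reachable belief state and time step by finite-horizon dynamic
#' programming.  At the deadline the two decide actions are compared
#' (guessing dominates the timeout outcome); before the deadline the
#' continuation value charges the next step's sampling cost and takes the
#' expectation of the successor values under the decision-maker's own
#' predictive distribution.  Known-rate models use the `(t, d)` net-evidence
#' lattice; uncertain-rate models the `(t, k_l, k_r)` count lattice.
#' Values are "go-forward": sunk sampling costs are excluded, so the root
#' value is the policy's expected net reward.
#'
#' @param env An [environment_spec()].
#' @param model A [belief_model()] (defaults to known rates).
#' @return An object of class `"policy_table"`: a list with `model_type`,
#'   `env`, `model`, and `layers`, where `layers[[t + 1]]` holds the states,
#'   posteriors `pi`, `action`, `value`, and exact-tie flags for time `t`.
#' @examples
#' env <- environment_spec(rate_pair(0.38, 0.24))
#' pol <- backward_induction(env)
#' pol$layers[[1]]$value  # expected net reward of the optimal policy
#' @export
backward_induction <- function(env, model = belief_model(env)) {
  stopifnot(inherits(env, "env_spec"), inherits(model, "belief_model"))
  if (model$type == "known") {
    backward_induction_known(env, model)
  } else {
    backward_induction_uncertain(env, model)
  }
}

backward_induction_known <- function(env, model) {
  T <- env$horizon
  probs <- env$probs
  rew <- env$rewards
  cost <- env$costs$values
  stay <- probs$p_both + probs$p_neither
  layers <- vector("list", T + 1L)
  for (t in T:0) {
    d <- seq.int(-t, t)
    pi <- posterior_known_d(d, probs)
    vl <- decide_value(pi, "l", rew)
    # the right-decision value is the exact mirror of the left one; taking
    # it by reflection (and symmetrising the continuation below) makes the
    # policy's left-right symmetry exact in floating point
    vr <- rev(vl)
    if (t == T) {
      res <- resolve_actions(vl, vr)
    } else {
      vnext <- layers[[t + 2L]]$value
      idx <- d + t + 2L  # position of d in the (t+1) layer's -(t+1)..(t+1)
      p_up <- pi * probs$p + (1 - pi) * probs$q
      p_dn <- pi * probs$q + (1 - pi) * probs$p
      cont <- -cost[t + 1L] +
        p_up * vnext[idx + 1L] + p_dn * vnext[idx - 1L] + stay * vnext[idx]
      cont <- (cont + rev(cont)) / 2
      res <- resolve_actions(vl, vr, cont)
    }
    layers[[t + 1L]] <- list(t = t, d = d, pi = pi, action = res$action,
                             value = res$value, decide_tie = res$decide_tie)
  }
  structure(list(model_type = "known", env = env, model = model,
                 layers = layers),
            class = "policy_table")
}

backward_induction_uncertain <- function(env, model) {
  T <- env$horizon
  rew <- env$rewards
  cost <- env$costs$values
  K <- model$K
  pt <- posterior_table_uncertain(model, T)
  layers <- vector("list", T + 1L)
  for (t in T:0) {
    n <- t + 1L
    pi <- pt[[t + 1L]]
    vl <- decide_value(pi, "l", rew)
    dim(vl) <- c(n, n)
    vr <- t(vl)  # exact mirror: state (k_l, k_r) reflects to (k_r, k_l)
    if (t == T) {
      res <- resolve_actions(vl, vr)
    } else {
      v1 <- layers[[t + 2L]]$value  # (t+2) x (t+2)
      den <- K + t
      fl_l <- (model$alpha_T + 0:t) / den  # left flash | H_l, by k_l
      fr_l <- (model$alpha_D + 0:t) / den  # right flash | H_l, by k_r
      fl_r <- (model$alpha_D + 0:t) / den  # left flash | H_r, by k_l
      fr_r <- (model$alpha_T + 0:t) / den  # right flash | H_r, by k_r
      p10 <- pi * outer(fl_l, 1 - fr_l) + (1 - pi) * outer(fl_r, 1 - fr_r)
      p01 <- pi * outer(1 - fl_l, fr_l) + (1 - pi) * outer(1 - fl_r, fr_r)
      p11 <- pi * outer(fl_l, fr_l) + (1 - pi) * outer(fl_r, fr_r)
      p00 <- pi * outer(1 - fl_l, 1 - fr_l) +
        (1 - pi) * outer(1 - fl_r, 1 - fr_r)
      lo <- seq_len(n)
      hi <- lo + 1L
      cont <- -cost[t + 1L] +
        p00 * v1[lo, lo, drop = FALSE] + p10 * v1[hi, lo, drop = FALSE] +
        p01 * v1[lo, hi, drop = FALSE] + p11 * v1[hi, hi, drop = FALSE]
      cont <- (cont + t(cont)) / 2
      res <- resolve_actions(vl, vr, cont)
    }
    action <- matrix(res$action, n, n)
    value <- matrix(res$value, n, n)
    tie <- matrix(res$decide_tie, n, n)
    layers[[t + 1L]] <- list(t = t, k = 0:t, pi = pi, action = action,
                             value = value, decide_tie = tie)
  }
  structure(list(model_type = "uncertain", env = env, model = model,
                 layers = layers),
            class = "policy_table")
}

#' @export
print.policy_table <- function(x, ...) {
  cat(sprintf("<policy_table> %s-rate model, horizon %d, root value %.4f\n",
              x$model_type, x$env$horizon, x$layers[[1L]]$value[1L]))
  invisible(x)
}

#' Extract the upper criterion curve from a policy
#'
#' Projects a policy onto the posterior-probability scale: for each time
#' step, the upper criterion `delta_l(t)` is the smallest posterior among
#' states whose action is decide-left (`defined = FALSE` where no such state
#' exists), and the lower criterion is its mirror `1 - delta_l(t)`.  A
#' per-step `threshold_consistent` flag records whether the decide-left
#' region is exactly the upper set `{pi >= delta_l(t)}` of lattice states —
#' always true for known-rate models, and a diagnostic for uncertain-rate
#' models where the posterior need not be a sufficient statistic for the
#' optimal action.
#'
#' @param policy A [backward_induction()] result.
#' @return A `data.frame` of class `"criterion_curve"` with columns `t`,
#'   `delta_l`, `delta_r`, `defined`, `threshold_consistent`.
#' @examples
#' env <- environment_spec(rate_pair(0.38, 0.24))
#' cc <- extract_criterion(backward_induction(env))
#' cc$delta_l[31]  # collapses to 0.5 at the deadline
#' @export
extract_criterion <- function(policy) {
  stopifnot(inherits(policy, "policy_table"))
  T <- policy$env$horizon
  delta_l <- rep(NA_real_, T + 1L)
  defined <- logical(T + 1L)
  consistent <- rep(NA, T + 1L)
  for (t in 0:T) {
    lay <- policy$layers[[t + 1L]]
    pi <- as.vector(lay$pi)
    act <- as.vector(lay$action)
    dec_l <- act == "decide_l" | (lay$decide_tie & act != "wait")
    if (any(dec_l)) {
      delta_l[t + 1L] <- min(pi[dec_l])
      defined[t + 1L] <- TRUE
      consistent[t + 1L] <- all(dec_l[pi >= delta_l[t + 1L]])
    }
  }
  out <- data.frame(t = 0:T, delta_l = delta_l, delta_r = 1 - delta_l,
                    defined = defined, threshold_consistent = consistent)
  class(out) <- c("criterion_curve", "data.frame")
  out
}

#' Write a criterion curve to CSV
#'
#' @param curve An [extract_criterion()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_criterion_csv <- function(curve, path) {
  stopifnot(inherits(curve, "criterion_curve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Static (time-invariant) decision policy
#'
#' A static criterion decides left as soon as the posterior reaches
#' `threshold`, decides right as soon as it reaches `1 - threshold`, and
#' otherwise waits; a trial that never crosses resolves as a timeout with
#' the all-in timeout outcome.  `threshold = 0.5` is the immediate-guess
#' policy (the belief starts exactly at the criterion).
#'
#' @param threshold Criterion on the posterior scale, in \[0.5, 1\].
#' @return An object of class `"static_policy"`.
#' @export
static_policy <- function(threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0.5, threshold <= 1)
  structure(list(threshold = threshold), class = "static_policy")
}

#' Action of a static policy at a belief state
#'
#' @param threshold Static criterion in \[0.5, 1\].
#' @param pi Posterior belief(s).
#' @return Character vector: `"decide_l"`, `"decide_r"`, or `"wait"`.  The
#'   exact tie at `pi = 0.5` with `threshold = 0.5` reports the
#'   value-equivalent left side.
#' @export
static_policy_actions <- function(threshold, pi) {
  stopifnot(threshold >= 0.5, threshold <= 1, all(pi >= 0), all(pi <= 1))
  ifelse(pi >= threshold, "decide_l",
         ifelse(pi <= 1 - threshold, "decide_r", "wait"))
}
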