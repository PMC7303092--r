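#' Stimulus rate pair
#'
#' Constructs the pair of Bernoulli flash rates defining a two-alternative
#' expanded judgment environment: the target stimulus flashes with rate
#' `theta_T`, the distractor with rate `theta_D`, independently at every
#' discrete time step.  The target rate must be at least the distractor rate;
#' equality is allowed only to express the degenerate maximum-difficulty
#' limit in which the two stimuli are indistinguishable.
#'
#' @param theta_T Flash probability of the target stimulus, in \[0, 1\].
#' @param theta_D Flash probability of the distractor stimulus, in
#'   \[0, `theta_T`\].
#' @return An object of class `"rate_pair"` with fields `theta_T`, `theta_D`.
#' @examples
#' rate_pair(0.38, 0.24)
#' @export
rate_pair <- function(theta_T, theta_D) {
  stopifnot(is.numeric(theta_T), length(theta_T) == 1L, is.finite(theta_T),
            is.numeric(theta_D), length(theta_D) == 1L, is.finite(theta_D))
  if (theta_T < 0 || theta_T > 1 || theta_D < 0 || theta_D > 1)
    stop("rates must lie in [0, 1]")
  if (theta_D > theta_T)
    stop("theta_D must not exceed theta_T (the target flashes at the higher rate)")
  structure(list(theta_T = theta_T, theta_D = theta_D), class = "rate_pair")
}

#' Four-outcome observation distribution
#'
#' Each time step the observer sees one of four events: only the target
#' flashes (probability `p = theta_T (1 - theta_D)`), only the distractor
#' flashes (`q = theta_D (1 - theta_T)`), both flash (`theta_T theta_D`), or
#' neither flashes (`(1 - theta_T)(1 - theta_D)`).  Only the first two carry
#' discriminating information when the rates are known; task difficulty is
#' governed by the gap `p - q`.
#'
#' @param rates A [rate_pair()].
#' @return An object of class `"event_probs"` with fields `p`, `q`,
#'   `p_both`, `p_neither`, summing to 1.
#' @examples
#' event_probabilities(rate_pair(0.38, 0.24))
#' @export
event_probabilities <- function(rates) {
  stopifnot(inherits(rates, "rate_pair"))
  tT <- rates$theta_T
  tD <- rates$theta_D
  structure(list(p         = tT * (1 - tD),
                 q         = tD * (1 - tT),
                 p_both    = tT * tD,
                 p_neither = (1 - tT) * (1 - tD)),
            class = "event_probs")
}

#' Feasibility of a (p, q) pair
#'
#' Tests whether a pair of discriminating-event probabilities `(p, q)` can
#' arise from some rate pair with `theta_T >= theta_D`.  Inverting
#' `p = theta_T (1 - theta_D)`, `q = theta_D (1 - theta_T)` leads to the
#' quadratic `theta_D^2 + theta_D (p - q - 1) + q = 0`, which has a real root
#' iff `(1 - p + q)^2 >= 4 q`; together with `q <= p` this characterises the
#' feasible region (equivalently `q <= p <= (1 - sqrt(q))^2`).
#'
#' @param p,q Numeric vectors of probabilities in \[0, 1\] (recycled).
#' @return Logical vector.
#' @examples
#' is_feasible_pq(0.2888, 0.1488)  # TRUE: the (0.38, 0.24) environment
#' is_feasible_pq(0.5, 0.45)       # FALSE
#' @export
is_feasible_pq <- function(p, q) {
  stopifnot(is.numeric(p), is.numeric(q),
            all(p >= 0 & p <= 1), all(q >= 0 & q <= 1))
  q <= p & (1 - p + q)^2 >= 4 * q
}

#' Recover stimulus rates from (p, q)
#'
#' Inverts the map from rates to discriminating-event probabilities.  Both
#' roots of the inversion quadratic give valid rate pairs reproducing
#' `(p, q)`; the smaller `theta_D` root is returned so the inverse is
#' deterministic (only analyses with rate uncertainty depend on the choice).
#'
#' @param p,q Scalar probabilities with `is_feasible_pq(p, q)` true.
#' @return A [rate_pair()]; round-trips through [event_probabilities()]
#'   to `(p, q)` within 1e-10.
#' @examples
#' rates_from_pq(0.2888, 0.1488)  # theta_T = 0.38, theta_D = 0.24
#' @export
rates_from_pq <- function(p, q) {
  stopifnot(length(p) == 1L, length(q) == 1L)
  if (!is_feasible_pq(p, q)) {
    stop(sprintf(paste0("infeasible (p, q) = (%g, %g): requires q <= p and ",
                        "discriminant (1 - p + q)^2 - 4q >= 0 (here %g)"),
                 p, q, (1 - p + q)^2 - 4 * q))
  }
  s <- sqrt(max((1 - p + q)^2 - 4 * q, 0))
  theta_D <- ((1 - p + q) - s) / 2
  rate_pair(theta_D + (p - q), theta_D)
}

#' Reward scheme
#'
#' Point rewards of the task: a constant reward for correct decisions, a
#' constant penalty for incorrect decisions, and an all-in timeout outcome
#' for failing to commit before the decision deadline at `horizon` steps.
#' With the defaults the timeout of -1000 points decomposes into the 500
#' points of fully accrued sampling costs plus the 500-point incorrect
#' penalty.
#'
#' @param reward_correct Points for a correct decision (default +1000).
#' @param penalty_incorrect Points for an incorrect decision (default -500).
#' @param timeout_total All-in points for never deciding, inclusive of all
#'   sampling costs paid along the way (default -1000).
#' @param horizon Number of observation steps before the deadline
#'   (default 30).
#' @return An object of class `"reward_scheme"`.
#' @export
reward_scheme <- function(reward_correct = 1000, penalty_incorrect = -500,
                          timeout_total = -1000, horizon = 30L) {
  stopifnot(is.numeric(reward_correct), is.numeric(penalty_incorrect),
            is.numeric(timeout_total), horizon >= 1)
  if (timeout_total > penalty_incorrect)
    stop("timeout_total must not exceed penalty_incorrect")
  structure(list(reward_correct    = reward_correct,
                 penalty_incorrect = penalty_incorrect,
                 timeout_total     = timeout_total,
                 horizon           = as.integer(horizon)),
            class = "reward_scheme")
}

#' Logistic sampling-cost schedule
#'
#' Per-step sampling costs `c(t) = scale / (1 + exp(3 - t/10))` for the
#' increasing direction; the decreasing direction traverses the same curve
#' backwards, `c_dec(t) = c_inc(horizon + 1 - t)`.  With the default scale
#' 74.92217 and horizon 30 the cumulative cost over a full trial is 500
#' points, so that together with the default rewards, guessing at the
#' deadline nets 250 - 500 points and a timeout nets -1000.
#'
#' @param direction `"increasing"` or `"decreasing"`.
#' @param horizon Number of observation steps (default 30).
#' @param scale Logistic amplitude in points (default 74.92217).
#' @return An object of class `"cost_schedule"` with per-step `values`
#'   (length `horizon`) and their running sum `cumulative`.
#' @examples
#' cs <- logistic_cost_schedule("increasing")
#' cs$cumulative[30]  # ~500 points
#' @export
logistic_cost_schedule <- function(direction = c("increasing", "decreasing"),
                                   horizon = 30L, scale = 74.92217) {
  direction <- match.arg(direction)
  stopifnot(horizon >= 1, scale > 0)
  horizon <- as.integer(horizon)
  t <- seq_len(horizon)
  tt <- if (direction == "increasing") t else horizon + 1L - t
  values <- scale / (1 + exp(3 - tt / 10))
  structure(list(direction = direction, horizon = horizon, scale = scale,
                 values = values, cumulative = cumsum(values)),
            class = "cost_schedule")
}

#' Decision environment specification
#'
#' Bundles stimulus rates, derived event probabilities, the reward scheme,
#' and the sampling-cost schedule into one environment object consumed by
#' the belief, policy, and evaluation functions.
#'
#' @param rates A [rate_pair()].
#' @param rewards A [reward_scheme()].
#' @param costs A [logistic_cost_schedule()]; its horizon must match the
#'   reward scheme's.
#' @return An object of class `"env_spec"` with fields `rates`, `probs`,
#'   `rewards`, `costs`, `horizon`.
#' @examples
#' env <- environment_spec(rate_pair(0.38, 0.24))
#' @export
environment_spec <- function(rates,
                             rewards = reward_scheme(),
                             costs = logistic_cost_schedule("increasing",
                                                            horizon = rewards$horizon)) {
  stopifnot(inherits(rates, "rate_pair"), inherits(rewards, "reward_scheme"),
            inherits(costs, "cost_schedule"))
  if (costs$horizon != rewards$horizon)
    stop("cost schedule horizon must equal reward scheme horizon")
  structure(list(rates = rates,
                 probs = event_probabilities(rates),
                 rewards = rewards,
                 costs = costs,
                 horizon = rewards$horizon),
            class = "env_spec")
}

# Radical-inverse (van der Corput) digits of i in the given base; the
# low-discrepancy backbone of the deterministic grid.
radical_inverse <- function(i, base) {
  r <- numeric(length(i))
  f <- 1 / base
  i <- as.integer(i)
  while (any(i > 0L)) {
    r <- r + f * (i %% base)
    i <- i %/% base
    f <- f / base
  }
  r
}

#' Deterministic quasi-uniform (p, q) grid over the feasible region
#'
#' Generates `n_points` distinct feasible pairs `(p, q)` covering the
#' difficulty space of the decision environment.  A Halton low-discrepancy
#' sequence (bases 2 and 3) is mapped onto the bounding box
#' `q` in (0, 1/4), `p` in (0, 1) and filtered to the strict interior of the
#' feasible region `q < p < (1 - sqrt(q))^2`; the same arguments always give
#' the identical grid.  `layout_seed > 0` applies a deterministic toroidal
#' shift to the sequence, giving alternative layouts of the same character.
#'
#' @param n_points Number of grid points (default 201).
#' @param layout_seed Non-negative integer selecting the layout (default 0,
#'   the unshifted Halton sequence).
#' @return A `data.frame` of class `"parameter_grid"` with columns `p`, `q`,
#'   `theta_T`, `theta_D`, one row per point, all feasible with `p > q`.
#' @examples
#' g <- make_grid(51)
#' all(is_feasible_pq(g$p, g$q))
#' @export
make_grid <- function(n_points = 201L, layout_seed = 0L) {
  stopifnot(n_points >= 1, layout_seed >= 0)
  n_points <- as.integer(n_points)
  shift_u <- if (layout_seed > 0) radical_inverse(layout_seed, 5) else 0
  shift_v <- if (layout_seed > 0) radical_inverse(layout_seed, 7) else 0
  p <- numeric(0)
  q <- numeric(0)
  i0 <- 1L
  block <- max(64L, 8L * n_points)
  while (length(p) < n_points) {
    i <- seq.int(i0, i0 + block - 1L)
    u <- (radical_inverse(i, 2) + shift_u) %% 1
    v <- (radical_inverse(i, 3) + shift_v) %% 1
    pp <- u
    qq <- v / 4
    keep <- qq > 0 & pp < 1 & qq < pp & (1 - pp + qq)^2 > 4 * qq
    p <- c(p, pp[keep])
    q <- c(q, qq[keep])
    i0 <- i0 + block
  }
  p <- p[seq_len(n_points)]
  q <- q[seq_len(n_points)]
  th <- vapply(seq_len(n_points),
               function(j) unlist(rates_from_pq(p[j], q[j])), numeric(2))
  out <- data.frame(p = p, q = q, theta_T = th[1L, ], theta_D = th[2L, ])
  class(out) <- c("parameter_grid", "data.frame")
  out
}

#' Read an environment specification from a config file
#'
#' Reads a YAML (or JSON) key-value file describing an environment.
#' Recognised keys: `theta_T`/`theta_D` or `p`/`q` (exactly one
#' parameterisation), `direction`, `horizon`, `K`, and an optional `rewards`
#' block with `correct`, `incorrect`, `timeout`.
#'
#' @param path Path to the config file.
#' @return A list with elements `env` (an [environment_spec()]) and `K`
#'   (prior precision; `Inf` if absent).
#' @export
read_environment_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  has_theta <- !is.null(cfg$theta_T) || !is.null(cfg$theta_D)
  has_pq <- !is.null(cfg$p) || !is.null(cfg$q)
  if (has_theta && has_pq)
    stop("config error: give either theta_T/theta_D or p/q, not both")
  if (has_theta) {
    if (is.null(cfg$theta_T) || is.null(cfg$theta_D))
      stop("config error: both keys theta_T and theta_D are required")
    rates <- rate_pair(cfg$theta_T, cfg$theta_D)
  } else if (has_pq) {
    if (is.null(cfg$p) || is.null(cfg$q))
      stop("config error: both keys p and q are required")
    rates <- rates_from_pq(cfg$p, cfg$q)
  } else {
    stop("config error: missing keys theta_T/theta_D (or p/q)")
  }
  horizon <- if (is.null(cfg$horizon)) 30L else as.integer(cfg$horizon)
  rew <- cfg$rewards
  rewards <- reward_scheme(
    reward_correct    = if (is.null(rew$correct)) 1000 else rew$correct,
    penalty_incorrect = if (is.null(rew$incorrect)) -500 else rew$incorrect,
    timeout_total     = if (is.null(rew$timeout)) -1000 else rew$timeout,
    horizon           = horizon)
  direction <- if (is.null(cfg$direction)) "increasing" else cfg$direction
  if (!direction %in% c("increasing", "decreasing"))
    stop("config error: key direction must be 'increasing' or 'decreasing'")
  costs <- logistic_cost_schedule(direction, horizon = horizon)
  K <- if (is.null(cfg$K)) Inf else if (identical(cfg$K, "Inf")) Inf else as.numeric(cfg$K)
  list(env = environment_spec(rates, rewards, costs), K = K)
}

#' @export
print.env_spec <- function(x, ...) {
  cat(sprintf("<env_spec> theta_T = %g, theta_D = %g (p = %g, q = %g)\n",
              x$rates$theta_T, x$rates$theta_D, x$probs$p, x$probs$q))
  cat(sprintf("  horizon %d, %s costs (total %.2f), rewards +%g/%g, timeout %g\n",
              x$horizon, x$costs$direction, x$costs$cumulative[x$horizon],
              x$rewards$reward_correct, x$rewards$penalty_incorrect,
              x$rewards$timeout_total))
  invisible(x)
}
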