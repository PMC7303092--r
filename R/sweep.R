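#' Parameter-space sweep comparing dynamic and static criteria
#'
#' For every combination of grid point, cost direction, and prior precision,
#' builds the environment, derives the optimal dynamic policy by backward
#' induction, searches the best static threshold, evaluates both, and
#' records their expected reward rates and the static/dynamic ratio.
#' Exact-mode sweeps are fully deterministic.  Per-point failures are caught
#' and recorded as `NA` rows; the `failures` attribute lists them.
#'
#' @param grid A [make_grid()] result, or any data frame with columns `p`,
#'   `q` (feasible pairs; `theta_T`, `theta_D` are derived if absent).
#' @param directions Cost-schedule directions to sweep (default both).
#' @param K_levels Prior precisions to sweep (default `Inf`, exactly known
#'   rates).
#' @param rewards A [reward_scheme()] shared by all points.
#' @param method `"exact"` or `"monte_carlo"` evaluation.
#' @param min_error_trials,seed Monte Carlo controls (ignored for exact).
#' @param verbose Emit per-point progress messages.
#' @return A `data.frame` of class `"sweep_result"` with columns `p`, `q`,
#'   `theta_T`, `theta_D`, `direction`, `K`, `rr_dynamic`, `rr_static`,
#'   `best_static_threshold`, `ratio`.  The ratio is `rr_static /
#'   rr_dynamic` (net-reward scale) and is `NA` if `rr_dynamic <= 0`.
#' @examples
#' run_sweep(make_grid(3), directions = "increasing")
#' @export
run_sweep <- function(grid,
                      directions = c("increasing", "decreasing"),
                      K_levels = Inf,
                      rewards = reward_scheme(),
                      method = c("exact", "monte_carlo"),
                      min_error_trials = 20000L, seed = 1L,
                      verbose = FALSE) {
  method <- match.arg(method)
  stopifnot(is.data.frame(grid), all(c("p", "q") %in% names(grid)),
            all(directions %in% c("increasing", "decreasing")))
  if (!all(is_feasible_pq(grid$p, grid$q)))
    stop("grid contains infeasible (p, q) points")
  if (!all(c("theta_T", "theta_D") %in% names(grid))) {
    th <- vapply(seq_len(nrow(grid)),
                 function(i) unlist(rates_from_pq(grid$p[i], grid$q[i])),
                 numeric(2))
    grid$theta_T <- th[1L, ]
    grid$theta_D <- th[2L, ]
  }
  combos <- expand.grid(point = seq_len(nrow(grid)), direction = directions,
                        K = K_levels, stringsAsFactors = FALSE)
  failures <- list()
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    j <- combos$point[i]
    dir <- combos$direction[i]
    K <- combos$K[i]
    rec <- data.frame(p = grid$p[j], q = grid$q[j],
                      theta_T = grid$theta_T[j], theta_D = grid$theta_D[j],
                      direction = dir, K = K,
                      rr_dynamic = NA_real_, rr_static = NA_real_,
                      best_static_threshold = NA_real_, ratio = NA_real_)
    res <- tryCatch({
      env <- environment_spec(rate_pair(grid$theta_T[j], grid$theta_D[j]),
                              rewards,
                              logistic_cost_schedule(dir,
                                                     horizon = rewards$horizon))
      model <- belief_model(env, K)
      pol <- backward_induction(env, model)
      if (method == "exact") {
        dyn <- evaluate_exact(pol, env, model)
        bs <- best_static(env, model, method = "exact")
      } else {
        dyn <- simulate_trials(pol, env, model, seed = seed,
                               min_error_trials = min_error_trials,
                               keep_trials = FALSE)$result
        bs <- best_static(env, model, method = "monte_carlo",
                          min_error_trials = min_error_trials, seed = seed)
      }
      rec$rr_dynamic <- dyn$net_reward
      rec$rr_static <- bs$result$net_reward
      rec$best_static_threshold <- bs$policy$threshold
      rec$ratio <- if (rec$rr_dynamic > 0) rec$rr_static / rec$rr_dynamic
                   else NA_real_
      rec
    }, error = function(e) {
      failures[[length(failures) + 1L]] <<-
        list(point = j, direction = dir, K = K,
             message = conditionMessage(e))
      rec
    })
    rows[[i]] <- res
    if (verbose)
      message(sprintf("sweep %d/%d: p=%.4f q=%.4f %s K=%s ratio=%.4f",
                      i, nrow(combos), rec$p, rec$q, dir, format(K),
                      res$ratio))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sweep_result", "data.frame")
  attr(out, "failures") <- failures
  out
}

#' Coverage of the parameter space by a near-optimal static criterion
#'
#' Fraction of sweep records in a single (direction, prior-precision)
#' stratum whose static/dynamic reward-rate ratio reaches the given
#' threshold.
#'
#' @param records A [run_sweep()] result (or compatible data frame)
#'   restricted to one direction and one `K`.
#' @param ratio_threshold Ratio cut-off (default 0.95).
#' @return An object of class `"coverage_summary"` with fields `direction`,
#'   `K`, `ratio_threshold`, `fraction_covered`, `n_points`.
#' @examples
#' sw <- run_sweep(make_grid(5), directions = "increasing")
#' coverage(sw)
#' @export
coverage <- function(records, ratio_threshold = 0.95) {
  stopifnot(is.data.frame(records), nrow(records) > 0,
            all(c("ratio", "direction", "K") %in% names(records)))
  if (length(unique(records$direction)) != 1L ||
      length(unique(records$K)) != 1L)
    stop("coverage requires a single (direction, K) stratum; split the records first")
  if (anyNA(records$ratio))
    stop("coverage undefined: records contain missing ratios (failed points or non-positive dynamic values)")
  structure(list(direction = records$direction[1L],
                 K = records$K[1L],
                 ratio_threshold = ratio_threshold,
                 fraction_covered = mean(records$ratio >= ratio_threshold),
                 n_points = nrow(records)),
            class = "coverage_summary")
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf(paste0("<coverage_summary> %s costs, K = %s: %.1f%% of %d ",
                     "points have static/dynamic ratio >= %.2f\n"),
              x$direction, format(x$K), 100 * x$fraction_covered,
              x$n_points, x$ratio_threshold))
  invisible(x)
}
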