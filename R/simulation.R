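#' Simulate event histories from a constant-hazard tree
#'
#' Subjects start in the root state and move along the tree by competing
#' exponential clocks: at each state one exponential time is drawn per
#' outgoing edge and the minimum wins (exact for constant hazards by
#' memorylessness). Follow-up ends at the administrative horizon `tau` or
#' at an independent exponential censoring time, whichever comes first;
#' subjects reaching an absorbing (leaf) state before that keep no censor
#' row.
#'
#' @param tree A [multistate_tree()] with hazards on all edges.
#' @param n Number of subjects.
#' @param tau Administrative censoring time.
#' @param censor_rate Exponential censoring rate (0 = administrative only).
#' @param arm Arm label written into the records.
#' @param seed Optional seed.
#' @return Event-history tibble (`id`, `arm`, `time`, `event`).
#' @export
simulate_arm <- function(tree, n, tau, censor_rate = 0, arm = "A",
                         seed = NULL) {
  if (anyNA(tree$edges$hazard)) stop_wcomp("tree has edges without hazards")
  if (!is.null(seed)) set.seed(seed)
  e <- tree$edges
  cens <- if (censor_rate > 0) pmin(rexp(n, censor_rate), tau) else rep(tau, n)

  id <- paste0(arm, seq_len(n))
  cur_state <- rep(tree$root, n)
  cur_time <- numeric(n)
  alive <- seq_len(n)      # indices still in a transient state, uncensored
  rows <- list()
  while (length(alive)) {
    nxt_alive <- integer(0)
    for (g in unique(cur_state[alive])) {
      sub <- alive[cur_state[alive] == g]
      out <- which(e$from == g)
      if (!length(out)) next                     # absorbing state
      rates <- e$hazard[out]
      R <- sum(rates)
      if (R == 0) next
      t_new <- cur_time[sub] + rexp(length(sub), R)
      dest <- out[sample.int(length(out), length(sub), replace = TRUE,
                             prob = rates)]
      keep <- t_new <= cens[sub]                  # event at the boundary counts
      if (any(keep)) {
        ks <- sub[keep]
        rows[[length(rows) + 1]] <- tibble(
          id = id[ks], arm = arm, time = t_new[keep],
          event = e$component[dest[keep]])
        cur_state[ks] <- e$to[dest[keep]]
        cur_time[ks] <- t_new[keep]
        nxt_alive <- c(nxt_alive, ks)
      }
    }
    alive <- nxt_alive
  }
  # censor rows for subjects not absorbed in a leaf state
  leaves <- setdiff(tree$states, tree$edges$from)
  open <- which(!(cur_state %in% leaves))
  out <- bind_rows(rows)
  if (length(open)) {
    out <- bind_rows(out, tibble(id = id[open], arm = arm,
                                 time = cens[open], event = "censor"))
  }
  arrange(out, .data$id, .data$time)
}

#' Two-arm simulation scenario
#'
#' Bundles the control and intervention multistate models with the trial
#' dimensions used by [coverage_study()] and [power_samplesize()].
#'
#' @param treeA,treeB Control / intervention [multistate_tree()]s.
#' @param n_per_arm Subjects per arm (>= 2).
#' @param tau Follow-up horizon (> 0).
#' @param censor_rate Exponential censoring rate before `tau` (0 =
#'   administrative censoring only).
#' @export
scenario_spec <- function(treeA, treeB, n_per_arm, tau, censor_rate = 0) {
  if (n_per_arm < 2) stop_wcomp("n_per_arm must be at least 2")
  if (tau <= 0) stop_wcomp("tau must be positive")
  structure(list(treeA = treeA, treeB = treeB, n_per_arm = n_per_arm,
                 tau = tau, censor_rate = censor_rate),
            class = "wc_scenario")
}

#' Uniform weight grid on the cone-simplex intersection
#'
#' Builds a regular lattice on the simplex `{w >= 0, sum(w) = 1}`, keeps
#' the points inside the cone, and chooses the lattice resolution so that
#' the kept count is closest to `target_points`. Used to approximate
#' simultaneous coverage over the infinitely many weight vectors in the
#' cone.
#'
#' @param cone A [cone()].
#' @param target_points Desired number of grid points.
#' @return Matrix with one weight vector per row.
#' @export
simplex_cone_grid <- function(cone, target_points) {
  K <- cone$K
  grid_for <- function(m) {
    pts <- compositions(m, K) / m
    keep <- apply(pts, 1, function(w) cone_contains(cone, w, tol = 1e-9))
    pts[keep, , drop = FALSE]
  }
  count_for <- function(m) nrow(grid_for(m))
  if (count_for(max(4 * K, 8)) == 0) stop_wcomp("cone does not intersect the simplex")
  # kept counts grow with the lattice resolution m: bracket the target, then
  # binary-search the smallest m reaching it and keep the closer neighbour
  hi <- 1
  while (count_for(hi) < target_points && hi < 5000) hi <- hi * 2
  lo <- max(1, hi %/% 2)
  while (lo < hi - 1) {
    mid <- (lo + hi) %/% 2
    if (count_for(mid) >= target_points) hi <- mid else lo <- mid
  }
  best <- if (count_for(lo) > 0 &&
              abs(count_for(lo) - target_points) < abs(count_for(hi) - target_points)) {
    lo
  } else hi
  grid_for(best)
}

# all length-K non-negative integer vectors summing to m
compositions <- function(m, K) {
  if (K == 1) return(matrix(m, 1, 1))
  do.call(rbind, lapply(0:m, function(i) {
    cbind(i, compositions(m - i, K - 1))
  }))
}

#' Monte Carlo simultaneous coverage study
#'
#' Replicates a two-arm trial, estimates the event-type probability
#' difference and covariance per replication (Aalen-Johansen when there is
#' censoring before `tau`, multinomial otherwise), and records for each
#' method whether the two-sided intervals cover the true weighted
#' differences for *every* weight vector on a cone-simplex grid
#' simultaneously. True values come from the analytic constant-hazard
#' probabilities. Replications with a degenerate estimated covariance are
#' dropped and counted.
#'
#' @param scenario A [scenario_spec()].
#' @param scheme A [build_scheme()] scheme.
#' @param cone A [cone()] for the chi-bar method.
#' @param methods Subset of `c("chibar", "scheffe", "unadjusted")`.
#' @param reps Number of replications.
#' @param grid_points Target size of the weight grid.
#' @param seed Master seed.
#' @param alpha Two-sided level.
#' @param abseps Orthant-probability tolerance for the per-replication
#'   chi-bar weights.
#' @return A `wc_coverage` object; `tidy()` gives one row per method with
#'   simultaneous coverage, its Monte Carlo standard error and mean
#'   relative efficiency.
#' @export
coverage_study <- function(scenario, scheme, cone,
                           methods = c("chibar", "scheffe", "unadjusted"),
                           reps = 1000, grid_points = 1000, seed = 1,
                           alpha = 0.05, abseps = 2.5e-4) {
  methods <- match.arg(methods, c("chibar", "scheffe", "unadjusted"),
                       several.ok = TRUE)
  W <- simplex_cone_grid(cone, grid_points)
  pA <- analytic_event_probs(scenario$treeA, scenario$tau, scheme)$prob
  pB <- analytic_event_probs(scenario$treeB, scenario$tau, scheme)$prob
  truth <- drop(W %*% (pA - pB))
  K <- scheme$K

  set.seed(seed)
  cover <- matrix(NA, reps, length(methods), dimnames = list(NULL, methods))
  re <- matrix(NA_real_, reps, length(methods), dimnames = list(NULL, methods))
  dropped <- 0L
  for (r in seq_len(reps)) {
    d <- tryCatch(
      simulate_and_estimate(scenario, scheme),
      wcomp_error = function(e) NULL)
    if (is.null(d)) { dropped <- dropped + 1L; next }
    ok <- tryCatch({ solve_pd(d$V); TRUE }, wcomp_error = function(e) FALSE)
    if (!ok) { dropped <- dropped + 1L; next }
    est <- drop(W %*% d$D)
    se <- sqrt(rowSums((W %*% d$V) * W))
    for (meth in methods) {
      eta <- switch(meth,
        chibar = chibar_quantile(1 - alpha / 2,
                                 chibar_weights(cone, d$V, abseps = abseps)),
        scheffe = qchisq(1 - alpha, df = K),
        unadjusted = qchisq(1 - alpha, df = 1))
      cover[r, meth] <- all(abs(est - truth) <= sqrt(eta) * se)
      re[r, meth] <- sqrt(eta) / qnorm(0.975)
    }
  }
  structure(list(cover = cover, re = re, reps = reps, dropped = dropped,
                 grid_size = nrow(W), methods = methods, alpha = alpha,
                 scenario = scenario),
            class = "wc_coverage")
}

simulate_and_estimate <- function(scenario, scheme) {
  dA <- simulate_arm(scenario$treeA, scenario$n_per_arm, scenario$tau,
                     scenario$censor_rate, arm = "A")
  dB <- simulate_arm(scenario$treeB, scenario$n_per_arm, scenario$tau,
                     scenario$censor_rate, arm = "B")
  if (scenario$censor_rate > 0) {
    arm_difference(
      aalen_johansen_arm(dA, scenario$treeA, scenario$tau, scheme),
      aalen_johansen_arm(dB, scenario$treeB, scenario$tau, scheme))
  } else {
    arm_difference(
      estimate_binary_arm(dA, scheme, scenario$tau),
      estimate_binary_arm(dB, scheme, scenario$tau))
  }
}

#' @method tidy wc_coverage
#' @export
tidy.wc_coverage <- function(x, ...) {
  n_used <- colSums(!is.na(x$cover))
  cov <- colMeans(x$cover, na.rm = TRUE)
  tibble(method = x$methods,
         simultaneous_coverage = cov,
         mc_se = sqrt(cov * (1 - cov) / n_used),
         mean_relative_efficiency = colMeans(x$re, na.rm = TRUE),
         reps_used = n_used, grid_size = x$grid_size)
}

#' @export
print.wc_coverage <- function(x, ...) {
  cat(sprintf("<wc_coverage: %d reps (%d dropped), %d grid weights>\n",
              x$reps, x$dropped, x$grid_size))
  print(tidy(x))
  invisible(x)
}

#' @method autoplot wc_coverage
#' @export
autoplot.wc_coverage <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$method,
                                   y = .data$simultaneous_coverage)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1 - object$alpha, linetype = 2) +
    ggplot2::labs(y = "simultaneous coverage")
}

#' Simulation-based power and sample size
#'
#' Estimates the rejection probability of a weighted composite-endpoint
#' test across candidate per-arm sample sizes and reports the smallest
#' candidate reaching the target power, with a linearly interpolated
#' crossing. The test statistic uses the designated weight vector; the
#' critical value is either unadjusted, Scheffe, or the chi-bar quantile
#' for a cone recomputed from each replication's estimated covariance. With
#' `simultaneous = TRUE` and several weight rows, "detection" means
#' rejection for every supplied weight vector (sufficient for all conic
#' combinations of them).
#'
#' @param scenario A [scenario_spec()]; its `n_per_arm` is ignored in
#'   favour of `n_candidates`.
#' @param scheme A [build_scheme()] scheme.
#' @param weights Weight vector (or matrix of rows, with
#'   `simultaneous = TRUE`).
#' @param method `"unadjusted"`, `"scheffe"` or `"chibar"`.
#' @param cone A [cone()] (chibar only).
#' @param n_candidates Increasing vector of per-arm sample sizes.
#' @param reps Replications per candidate.
#' @param alpha Two-sided level.
#' @param target_power Target power in (0, 1).
#' @param seed Master seed.
#' @param simultaneous Require rejection at every weight row.
#' @param abseps Orthant-probability tolerance (chibar).
#' @return A `wc_power`: `curve` (tibble n / power / mc_se), `n_star`
#'   (smallest candidate with power >= target), `n_interp` (linear
#'   interpolation of the crossing), `reached` flag.
#' @export
power_samplesize <- function(scenario, scheme, weights, method = "unadjusted",
                             cone = NULL, n_candidates, reps = 1000,
                             alpha = 0.05, target_power = 0.9, seed = 1,
                             simultaneous = FALSE, abseps = 2.5e-4) {
  method <- match.arg(method, c("unadjusted", "scheffe", "chibar"))
  if (is.unsorted(n_candidates, strictly = TRUE)) {
    stop_wcomp("n_candidates must be strictly increasing")
  }
  if (target_power <= 0 || target_power >= 1) stop_wcomp("target_power must be in (0,1)")
  W <- as_weight_matrix(weights, scheme$K)
  set.seed(seed)
  curve <- purrr::map_dfr(n_candidates, function(n) {
    sc <- scenario
    sc$n_per_arm <- n
    rej <- logical(reps)
    for (r in seq_len(reps)) {
      d <- simulate_and_estimate(sc, scheme)
      eta <- switch(method,
        chibar = chibar_quantile(1 - alpha / 2,
                                 chibar_weights(cone, d$V, abseps = abseps)),
        scheffe = qchisq(1 - alpha, df = scheme$K),
        unadjusted = qchisq(1 - alpha, df = 1))
      est <- drop(W %*% d$D)
      se <- sqrt(rowSums((W %*% d$V) * W))
      rj <- abs(est) > sqrt(eta) * se
      rej[r] <- if (simultaneous) all(rj) else rj[1]
    }
    p <- mean(rej)
    tibble(n = n, power = p, mc_se = sqrt(p * (1 - p) / reps))
  })
  reached <- any(curve$power >= target_power)
  n_star <- if (reached) min(curve$n[curve$power >= target_power]) else NA_real_
  n_interp <- interp_crossing(curve$n, curve$power, target_power)
  structure(list(curve = curve, n_star = n_star, n_interp = n_interp,
                 reached = reached, target_power = target_power,
                 method = method, alpha = alpha, reps = reps),
            class = "wc_power")
}

# first upward crossing of the target by linear interpolation
interp_crossing <- function(n, p, target) {
  for (i in seq_along(n)[-1]) {
    if (p[i - 1] < target && p[i] >= target) {
      return(n[i - 1] + (target - p[i - 1]) / (p[i] - p[i - 1]) * (n[i] - n[i - 1]))
    }
  }
  if (p[1] >= target) return(n[1])
  NA_real_
}

#' @method tidy wc_power
#' @export
tidy.wc_power <- function(x, ...) x$curve

#' @method glance wc_power
#' @export
glance.wc_power <- function(x, ...) {
  tibble(n_star = x$n_star, n_interp = x$n_interp, reached = x$reached,
         target_power = x$target_power, method = x$method, reps = x$reps)
}

#' @export
print.wc_power <- function(x, ...) {
  cat(sprintf("<wc_power: %s test, target %.0f%%>\n",
              x$method, 100 * x$target_power))
  print(x$curve)
  if (x$reached) cat(sprintf("n_star = %g (interpolated %.0f)\n", x$n_star, x$n_interp))
  else cat("target power not reached in candidate range\n")
  invisible(x)
}

#' @method autoplot wc_power
#' @export
autoplot.wc_power <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$n, y = .data$power)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$target_power, linetype = 2) +
    ggplot2::labs(x = "subjects per arm", y = "simulated power")
}
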