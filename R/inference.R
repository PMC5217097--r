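#' Weighted risk-difference statistic
#'
#' For a weight vector `w`, the statistic is `w' D` with standard error
#' `sqrt(w' V w)`; with weights standardized to sum to one it is the
#' weighted average of the absolute risk differences across event types.
#'
#' @param diff A `wc_difference` (from [wce_estimate()], [arm_difference()]
#'   or [integrated_difference()]).
#' @param w Numeric weight vector of length K.
#' @return One-row tibble with `estimate` and `std.error`.
#' @export
weighted_stat <- function(diff, w) {
  w <- as.numeric(w)
  if (length(w) != length(diff$D)) stop_wcomp("weight vector has wrong length")
  v <- drop(t(w) %*% diff$V %*% w)
  if (v <= 0) stop_wcomp("weight vector has zero variance direction")
  tibble(estimate = sum(w * diff$D), std.error = sqrt(v))
}

#' Critical values for simultaneous inference
#'
#' The squared critical value `eta` entering the interval
#' `w'D -/+ sqrt(eta) * se(w)`:
#' * `"chibar"`: the `1 - alpha/2` quantile of the chi-bar-squared
#'   distribution determined by the cone and the (estimated) covariance --
#'   simultaneous two-sided `1 - alpha` coverage over every weight vector
#'   in the cone;
#' * `"scheffe"`: the `1 - alpha` quantile of the chi-squared distribution
#'   with K degrees of freedom -- simultaneous over all contrasts;
#' * `"unadjusted"`: the `1 - alpha` quantile of the chi-squared
#'   distribution with 1 degree of freedom (`1.96^2` at `alpha = 0.05`) --
#'   pointwise coverage only.
#'
#' @param method `"chibar"`, `"scheffe"` or `"unadjusted"`.
#' @param alpha Two-sided level (default 0.05).
#' @param cone A [cone()] (chibar only).
#' @param V Covariance of the difference estimate (chibar only).
#' @param K Number of event types (scheffe only).
#' @param weights Optional precomputed [chibar_weights()]; otherwise they
#'   are computed exactly from `cone` and `V`.
#' @param abseps Orthant-probability tolerance for the exact weights.
#' @return A `wc_critical_value` with `eta`, `level`, `method`, and for the
#'   chi-bar method the mixing `weights`.
#' @export
critical_value <- function(method = c("chibar", "scheffe", "unadjusted"),
                           alpha = 0.05, cone = NULL, V = NULL, K = NULL,
                           weights = NULL, abseps = 1e-6) {
  method <- arg_match(method)
  if (alpha <= 0 || alpha >= 1) stop_wcomp("alpha must be in (0, 1)")
  if (method == "chibar") {
    if (is.null(weights)) {
      if (is.null(cone) || is.null(V)) stop_wcomp("chibar needs `cone` and `V` (or `weights`)")
      weights <- chibar_weights(cone, V, abseps = abseps)
    }
    eta <- chibar_quantile(1 - alpha / 2, weights)
    level <- 1 - alpha / 2
  } else if (method == "scheffe") {
    if (is.null(K)) K <- if (!is.null(V)) nrow(V) else stop_wcomp("scheffe needs `K` or `V`")
    eta <- qchisq(1 - alpha, df = K)
    level <- 1 - alpha
  } else {
    eta <- qchisq(1 - alpha, df = 1)
    level <- 1 - alpha
  }
  structure(list(eta = as.numeric(eta), level = level, method = method,
                 alpha = alpha, weights = if (method == "chibar") weights),
            class = "wc_critical_value")
}

#' @export
print.wc_critical_value <- function(x, ...) {
  cat(sprintf("<wc_critical_value: %s, eta = %.4f (sqrt = %.4f), alpha = %g>\n",
              x$method, x$eta, sqrt(x$eta), x$alpha))
  invisible(x)
}

#' Width of a method's intervals relative to unadjusted Wald intervals
#'
#' `sqrt(eta) / z_{0.975}`: the factor by which a method's confidence
#' intervals are wider than unadjusted 95 percent Wald intervals.
#'
#' @param eta Squared critical value, or a `wc_critical_value`.
#' @export
relative_efficiency <- function(eta) {
  if (inherits(eta, "wc_critical_value")) eta <- eta$eta
  if (any(eta <= 0)) stop_wcomp("eta must be positive")
  sqrt(eta) / qnorm(0.975)
}

eta_of <- function(eta) {
  if (inherits(eta, "wc_critical_value")) eta$eta else as.numeric(eta)
}

#' Simultaneous confidence intervals for weighted risk differences
#'
#' For each supplied weight vector, builds the interval
#' `w'D -/+ sqrt(eta) (w'Vw)^{1/2}` (two-sided) or the one-sided lower
#' interval `[w'D - sqrt(eta) (w'Vw)^{1/2}, Inf)`. With the chi-bar
#' critical value the intervals hold simultaneously over every `w` in the
#' cone, so the caller should only evaluate weight vectors inside it
#' ([cone_contains()] checks membership).
#'
#' @param diff A `wc_difference`.
#' @param weights Weight vector, matrix (one row per weight vector), or
#'   data frame of weight rows.
#' @param eta A `wc_critical_value` or bare squared critical value.
#' @param sided `"two"` or `"one"`.
#' @return Tibble with one row per weight vector: `estimate`, `std.error`,
#'   `lower`, `upper`, `eta`, `method`.
#' @export
simultaneous_ci <- function(diff, weights, eta, sided = c("two", "one")) {
  sided <- arg_match(sided)
  W <- as_weight_matrix(weights, length(diff$D))
  e <- eta_of(eta)
  method <- if (inherits(eta, "wc_critical_value")) eta$method else "custom"
  est <- drop(W %*% diff$D)
  se <- sqrt(rowSums((W %*% diff$V) * W))
  if (any(se <= 0)) stop_wcomp("a weight vector has zero standard error")
  half <- sqrt(e) * se
  tibble(weight = lapply(seq_len(nrow(W)), function(i) unname(W[i, ])),
         estimate = est, std.error = se,
         lower = est - half,
         upper = if (sided == "two") est + half else Inf,
         eta = e, method = method, sided = sided)
}

#' Simultaneous tests for weighted risk differences
#'
#' A weight vector's null hypothesis (`w'D = 0` two-sided, `w'D <= 0`
#' one-sided) is rejected when zero lies outside its simultaneous
#' confidence interval. The adjusted p-value is the smallest `alpha` at
#' which rejection occurs, obtained by exact inversion of the monotone
#' critical-value function (the chi-bar mixture CDF of the squared
#' standardized statistic, or the corresponding chi-squared CDF).
#'
#' @inheritParams simultaneous_ci
#' @return The [simultaneous_ci()] tibble plus `statistic` (standardized),
#'   `reject` and `adjusted_p`.
#' @export
simultaneous_test <- function(diff, weights, eta, sided = c("two", "one")) {
  sided <- arg_match(sided)
  out <- simultaneous_ci(diff, weights, eta, sided)
  z <- out$estimate / out$std.error
  out$statistic <- z
  out$reject <- if (sided == "two") out$lower > 0 | out$upper < 0 else out$lower > 0
  method <- if (inherits(eta, "wc_critical_value")) eta$method else "custom"
  z2 <- if (sided == "two") z^2 else pmax(z, 0)^2
  out$adjusted_p <- switch(
    method,
    chibar = {
      w <- eta$weights
      p1 <- chibar_tail(z2, w)  # P(Z^2 >= z2), one-sided family
      if (sided == "two") pmin(1, 2 * p1) else pmin(1, 2 * p1)
    },
    scheffe = pchisq(z2, df = length(diff$D), lower.tail = FALSE),
    unadjusted = pchisq(z2, df = 1, lower.tail = FALSE),
    rep(NA_real_, length(z)))
  if (method %in% c("scheffe", "unadjusted") && sided == "one") {
    out$adjusted_p <- ifelse(z <= 0, 1, out$adjusted_p / 2)
  }
  out
}

as_weight_matrix <- function(weights, K) {
  if (is.data.frame(weights)) weights <- as.matrix(weights)
  if (is.null(dim(weights))) weights <- matrix(as.numeric(weights), nrow = 1)
  if (ncol(weights) != K) stop_wcomp("weight rows must have %d columns", K)
  if (any(rowSums(abs(weights)) == 0)) stop_wcomp("the zero weight vector is not allowed")
  weights
}

#' Power-optimal weight direction
#'
#' The direction `w` proportional to `V^{-1} D` maximizes the standardized
#' statistic `w'D / sqrt(w'Vw)`; returned normalized to sum to one.
#' Advisory only: confirmatory weights should be chosen on clinical
#' grounds, not for power.
#'
#' @param diff A `wc_difference`.
#' @export
power_optimal_direction <- function(diff) {
  w <- drop(solve_pd(diff$V) %*% diff$D)
  w / sum(w)
}

#' Smallest rejecting relative weight for a two-type endpoint
#'
#' For K = 2 event types with weights standardized to sum to one, finds the
#' smallest weight `a` on the selected event type at which the simultaneous
#' two-sided interval for the weighted difference excludes zero (lower
#' bound crosses zero). Root-finding on the interval lower bound.
#'
#' @param diff A `wc_difference` with exactly two event types.
#' @param eta A `wc_critical_value` or squared critical value.
#' @param component Index (or name) of the event type whose relative weight
#'   is varied; the other type gets weight `1 - a`.
#' @export
weight_threshold <- function(diff, eta, component = 1) {
  if (length(diff$D) != 2) stop_wcomp("weight_threshold() needs exactly 2 event types")
  if (is.character(component)) component <- match(component, names(diff$D))
  e <- eta_of(eta)
  lower <- function(a) {
    w <- if (component == 1) c(a, 1 - a) else c(1 - a, a)
    sum(w * diff$D) - sqrt(e) * sqrt(drop(t(w) %*% diff$V %*% w))
  }
  lo <- lower(1e-9); hi <- lower(1 - 1e-9)
  if (lo > 0) return(0)
  if (hi < 0) return(NA_real_)
  uniroot(lower, c(1e-9, 1 - 1e-9), tol = 1e-10)$root
}

#' Confidence-interval curve over relative weights (two event types)
#'
#' Sweeps the relative weight of the first event type across (0, 1) and
#' returns estimate and simultaneous/unadjusted interval bounds at each
#' grid point; `autoplot()` displays the familiar weighted risk-difference
#' band plot.
#'
#' @param diff A `wc_difference` with two event types.
#' @param etas Named list of critical values (e.g.
#'   `list(chibar = cv1, unadjusted = cv2)`).
#' @param n_grid Number of grid points.
#' @export
ci_weight_curve <- function(diff, etas, n_grid = 199) {
  if (length(diff$D) != 2) stop_wcomp("ci_weight_curve() needs exactly 2 event types")
  a <- seq(0.005, 0.995, length.out = n_grid)
  W <- cbind(a, 1 - a)
  rows <- purrr::map(names(etas), function(nm) {
    ci <- simultaneous_ci(diff, W, etas[[nm]])
    tibble(rel_weight = a, estimate = ci$estimate,
           lower = ci$lower, upper = ci$upper, method = nm)
  })
  out <- bind_rows(rows)
  class(out) <- c("wc_ci_curve", class(out))
  out
}

#' @method autoplot wc_ci_curve
#' @export
autoplot.wc_ci_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rel_weight)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper,
                                      fill = .data$method), alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "relative weight of first event type",
                  y = "weighted risk difference")
}
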