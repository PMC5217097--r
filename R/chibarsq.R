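#' Convex cones of weight vectors
#'
#' A weight cone is specified by `s` equality rows `A_eq` and `K - s`
#' inequality rows `A_ineq`: the cone is
#' `{w : A_eq w = 0, A_ineq w >= 0}`. The stacked K x K matrix must be of
#' full rank and at least one row must be an inequality.
#'
#' `cone_nonneg(K)` is the non-negative orthant. `cone_ordered(K)` is the
#' severity chain `w_K >= ... >= w_1 >= 0` (event types are ordered from
#' least to most severe, so the most severe type gets the largest weight);
#' `decreasing = TRUE` reverses the chain. `cone_spanned(G)` is the cone
#' generated by the columns of an invertible matrix `G` (each column a
#' generator weight vector), i.e. all non-negative combinations of the
#' generators.
#'
#' @param A_eq Numeric matrix of equality rows (may be `NULL` or 0-row).
#' @param A_ineq Numeric matrix of inequality rows.
#' @return A `wc_cone` with fields `A_eq`, `A_ineq`, `K`, `s`.
#' @examples
#' cone_ordered(3)
#' @export
cone <- function(A_ineq, A_eq = NULL) {
  A_ineq <- matrix(as.numeric(A_ineq), nrow = NROW(A_ineq))
  K <- ncol(A_ineq)
  if (is.null(A_eq)) A_eq <- matrix(numeric(0), 0, K)
  A_eq <- matrix(as.numeric(A_eq), ncol = K)
  if (nrow(A_ineq) == 0) stop_wcomp("at least one inequality row is required")
  A <- rbind(A_eq, A_ineq)
  if (nrow(A) != K) stop_wcomp("need K = %d stacked constraint rows, got %d", K, nrow(A))
  if (qr(A)$rank < K) stop_wcomp("stacked constraint matrix is rank deficient")
  structure(list(A_eq = A_eq, A_ineq = A_ineq, K = K, s = nrow(A_eq)),
            class = "wc_cone")
}

#' @rdname cone
#' @param K Dimension (number of event types).
#' @export
cone_nonneg <- function(K) cone(diag(1, K))

#' @rdname cone
#' @param decreasing If `TRUE` the chain is `w_1 >= ... >= w_K >= 0`.
#' @export
cone_ordered <- function(K, decreasing = FALSE) {
  if (K < 2) return(cone_nonneg(K))
  A <- matrix(0, K, K)
  A[1, 1] <- 1
  for (i in 2:K) { A[i, i - 1] <- -1; A[i, i] <- 1 }
  if (decreasing) A <- A[, K:1]
  cone(A)
}

#' @rdname cone
#' @param G Invertible K x K matrix whose columns generate the cone.
#' @export
cone_spanned <- function(G) {
  G <- as.matrix(G)
  if (nrow(G) != ncol(G)) stop_wcomp("generator matrix must be square")
  cone(solve(G))  # w = G lambda, lambda >= 0  <=>  G^{-1} w >= 0
}

#' @export
print.wc_cone <- function(x, ...) {
  cat(sprintf("<wc_cone: K = %d, %d equality / %d inequality rows>\n",
              x$K, x$s, nrow(x$A_ineq)))
  invisible(x)
}

#' Is a weight vector inside the cone?
#'
#' @param cone A [cone()].
#' @param w Numeric weight vector.
#' @param tol Constraint tolerance.
#' @export
cone_contains <- function(cone, w, tol = 1e-10) {
  okeq <- if (cone$s) all(abs(cone$A_eq %*% w) <= tol) else TRUE
  okeq && all(cone$A_ineq %*% w >= -tol)
}

# change of basis: the cone becomes the orthant in y = A w coordinates,
# with only the inequality block free. Returns the inequality columns of
# A^{-1} (so w = B_in y_in) and the covariance of the reduced problem.
reduce_cone <- function(cone, V) {
  B <- solve(rbind(cone$A_eq, cone$A_ineq))
  B_in <- B[, (cone$s + 1):cone$K, drop = FALSE]
  list(B_in = B_in, Vt = t(B_in) %*% V %*% B_in)
}

#' Metric projection onto a cone
#'
#' Computes `argmin_{w in C} (z - w)' V^{-1} (z - w)` by exact quadratic
#' programming, together with the dimension of the smallest face of the
#' cone containing the projection. The Moreau decomposition gives the
#' Pythagoras identity `|z|^2 = |w*|^2 + |z - w*|^2` in the `V^{-1}`
#' metric.
#'
#' @param z Numeric vector of length K.
#' @param V Positive-definite covariance matrix defining the metric.
#' @param cone A [cone()].
#' @param tol Support threshold for deciding active constraints.
#' @return List with `w` (the projection) and `face_dim`.
#' @export
project <- function(z, V, cone, tol = 1e-9) {
  Vi <- solve_pd(V)
  red <- reduce_cone(cone, V)
  B <- red$B_in
  # min_y>=0 (z - B y)' Vi (z - B y): QP in y
  Dmat <- t(B) %*% Vi %*% B
  dvec <- drop(t(B) %*% Vi %*% z)
  m <- ncol(B)
  sol <- quadprog::solve.QP(Dmat, dvec, diag(1, m), rep(0, m))
  y <- pmax(sol$solution, 0)
  scale <- sqrt(diag(Dmat))
  supp <- y * scale > tol * max(1, max(abs(dvec / scale)))
  list(w = drop(B %*% y), face_dim = sum(supp))
}

solve_pd <- function(V) {
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10 * max(ev)) {
    stop_wcomp(paste0("covariance matrix is (nearly) singular; ",
                      "remove redundant event types, e.g. the no-event category"))
  }
  solve((V + t(V)) / 2)
}

# ---- orthant probabilities -------------------------------------------------

# P(N(0, S) >= 0): closed forms up to dimension 3, quasi-Monte Carlo
# integration (mvtnorm) above
orthant_prob <- function(S, abseps = 1e-6) {
  d <- NROW(S)
  if (d == 0) return(1)
  if (d == 1) return(0.5)
  R <- cov2cor(S)
  if (d == 2) return(0.25 + asin(R[1, 2]) / (2 * pi))
  if (d == 3) {
    return(0.125 + (asin(R[1, 2]) + asin(R[1, 3]) + asin(R[2, 3])) / (4 * pi))
  }
  as.numeric(mvtnorm::pmvnorm(
    lower = rep(0, d), upper = rep(Inf, d), sigma = R,
    algorithm = mvtnorm::GenzBretz(abseps = abseps, maxpts = 50000)))
}

# ---- chi-bar-squared weights ----------------------------------------------

#' Mixing weights of the chi-bar-squared distribution
#'
#' The squared cone-restricted maximal standardized contrast
#' `Z(C, V)^2 = max_{w in C} (w'z)^2 / (w'Vw)` (positive part, `z ~ N(0, V)`)
#' follows a chi-bar-squared distribution: a mixture of chi-squared
#' distributions with 0 to K degrees of freedom. The mixing weight of
#' component `i` is the probability that the projection of a standard
#' normal vector onto the transformed cone `V^{1/2} C` lands on a face of
#' dimension `i`.
#'
#' `chibar_weights()` computes them exactly by subset enumeration over the
#' inequality constraints (each term a product of two multivariate-normal
#' orthant probabilities), or by Monte Carlo face counting of simulated
#' projections. For equality-constrained cones the weights are supported on
#' dimensions `0 .. K - s`.
#'
#' @param cone A [cone()].
#' @param V Positive-definite covariance matrix of the contrast estimate.
#' @param method `"exact"` (subset enumeration, requires `K - s <= 8`) or
#'   `"mc"`.
#' @param reps Monte Carlo replications (method `"mc"`), at least 1000.
#' @param seed Seed for the Monte Carlo draw; required for `"mc"`.
#' @param abseps Absolute tolerance passed to the orthant-probability
#'   integration.
#' @return A `wc_chibar_weights`: numeric vector `w_tilde` of length K + 1
#'   (dimensions 0..K), with `method` and, for Monte Carlo, `mc_se`.
#' @examples
#' chibar_weights(cone_nonneg(3), diag(3))$w_tilde  # binomial(3, 1/2) / 8
#' @export
chibar_weights <- function(cone, V, method = c("exact", "mc"),
                           reps = 10000, seed = NULL, abseps = 1e-6) {
  method <- arg_match(method)
  if (!is.matrix(V) || nrow(V) != cone$K) stop_wcomp("V must be %d x %d", cone$K, cone$K)
  solve_pd(V)  # singularity guard
  red <- reduce_cone(cone, V)
  m <- ncol(red$B_in)
  if (method == "exact") {
    if (m > 8) stop_wcomp("exact weights limited to K - s <= 8; use method = 'mc'")
    w_red <- orthant_face_weights(red$Vt, abseps = abseps)
    mc_se <- NULL
  } else {
    if (reps < 1000) stop_wcomp("use at least 1000 Monte Carlo replications")
    if (is.null(seed)) stop_wcomp("Monte Carlo weights require a seed")
    w_red <- orthant_face_weights_mc(red$Vt, reps = reps, seed = seed)
    mc_se <- sqrt(w_red * (1 - w_red) / reps)
  }
  w <- numeric(cone$K + 1)
  w[seq_along(w_red)] <- w_red
  se <- if (is.null(mc_se)) NULL else { s <- numeric(cone$K + 1); s[seq_along(mc_se)] <- mc_se; s }
  structure(list(w_tilde = w, method = if (method == "exact") "exact" else "monte_carlo",
                 mc_se = se, K = cone$K),
            class = "wc_chibar_weights")
}

# exact face-dimension probabilities for the orthant problem with reduced
# covariance Vt: P(face dim = |J|) summed over subsets J, each term
# OP((Vt_JJ)^{-1}) * OP(Schur complement Vt_JcJc.J)
orthant_face_weights <- function(Vt, abseps = 1e-6) {
  m <- nrow(Vt)
  w <- numeric(m + 1)
  for (b in 0:(2^m - 1)) {
    J <- which(bitwAnd(b, 2^(seq_len(m) - 1)) > 0)
    Jc <- setdiff(seq_len(m), J)
    p1 <- if (length(J)) {
      orthant_prob(solve(Vt[J, J, drop = FALSE]), abseps)
    } else 1
    p2 <- if (length(Jc)) {
      Sc <- Vt[Jc, Jc, drop = FALSE]
      if (length(J)) {
        Sc <- Sc - Vt[Jc, J, drop = FALSE] %*%
          solve(Vt[J, J, drop = FALSE], Vt[J, Jc, drop = FALSE])
      }
      orthant_prob(Sc, abseps)
    } else 1
    w[length(J) + 1] <- w[length(J) + 1] + p1 * p2
  }
  w / sum(w)
}

# Monte Carlo face counting: the face dimension of the projection of
# eps ~ N(0, I) onto the cone {G y, y >= 0} with G'G = Vt equals the
# support size of the non-negative least-squares solution
orthant_face_weights_mc <- function(Vt, reps, seed) {
  m <- nrow(Vt)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  Y <- mvtnorm::rmvnorm(reps, sigma = Vt)     # y = G' eps
  dvec_all <- Y
  counts <- integer(m + 1)
  Amat <- diag(1, m)
  b0 <- rep(0, m)
  scale <- sqrt(diag(Vt))
  for (r in seq_len(reps)) {
    sol <- quadprog::solve.QP(Vt, dvec_all[r, ], Amat, b0)
    y <- sol$solution
    supp <- sum(y * scale > 1e-8 * max(1, max(abs(dvec_all[r, ] / scale))))
    counts[supp + 1] <- counts[supp + 1] + 1L
  }
  counts / reps
}

#' @export
print.wc_chibar_weights <- function(x, ...) {
  cat(sprintf("<wc_chibar_weights (%s)>\n", x$method))
  print(setNames(round(x$w_tilde, 6), paste0("df", 0:(length(x$w_tilde) - 1))))
  invisible(x)
}

#' @method tidy wc_chibar_weights
#' @export
tidy.wc_chibar_weights <- function(x, ...) {
  out <- tibble(df = 0:(length(x$w_tilde) - 1), weight = x$w_tilde)
  if (!is.null(x$mc_se)) out$mc_se <- x$mc_se
  out
}

#' Tail probability and quantile of a chi-bar-squared mixture
#'
#' `chibar_tail(c, weights)` evaluates `P(Z^2 >= c)` for the squared
#' statistic: the weighted sum of chi-squared survival functions at the
#' squared-scale argument `c` (the zero-degree component is a point mass at
#' zero, so it contributes only at `c = 0`). `chibar_quantile(p, weights)`
#' inverts the mixture CDF by bracketed root finding; when `p` does not
#' exceed the zero-component mass the quantile is 0 (flagged via the
#' `"at_mass"` attribute).
#'
#' @param c Non-negative squared-scale argument.
#' @param weights A `wc_chibar_weights` (or bare numeric vector of mixing
#'   weights for dimensions 0..K).
#' @param p Probability in (0, 1).
#' @export
chibar_tail <- function(c, weights) {
  w <- chibar_w(weights)
  if (any(c < 0)) stop_wcomp("c must be non-negative")
  vapply(c, function(ci) {
    if (ci == 0) return(1)
    sum(w[-1] * pchisq(ci, df = seq_along(w[-1]), lower.tail = FALSE))
  }, numeric(1))
}

#' @rdname chibar_tail
#' @export
chibar_quantile <- function(p, weights) {
  w <- chibar_w(weights)
  if (p <= 0 || p >= 1) stop_wcomp("p must be in (0, 1)")
  if (p <= w[1]) return(structure(0, at_mass = TRUE))
  K <- length(w) - 1
  upper <- qchisq(p, df = K) + 1
  while (1 - chibar_tail(upper, w) < p) upper <- upper * 2
  uniroot(function(c0) (1 - chibar_tail(c0, w)) - p,
          interval = c(0, upper), tol = 1e-10)$root
}

chibar_w <- function(weights) {
  w <- if (inherits(weights, "wc_chibar_weights")) weights$w_tilde else as.numeric(weights)
  if (any(w < -1e-12)) stop_wcomp("invalid mixing weights")
  tot <- sum(w)
  if (abs(tot - 1) > 1e-6) stop_wcomp("mixing weights must sum to one (got %.6f)", tot)
  w / tot
}
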