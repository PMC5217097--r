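# shared fixtures and independent oracles

nf_components <- function() component_set(c("N", "F"), fatal = c(FALSE, TRUE))

nmf_components <- function() {
  component_set(c("N", "M", "F"), fatal = c(FALSE, FALSE, TRUE))
}

cardio_components <- function() {
  component_set(c("MI", "ST", "DE"), fatal = c(FALSE, FALSE, TRUE))
}

# closed-form state probabilities of the illness-death model with constant
# hazards (nested exponential integrals; independent of the package's
# matrix-exponential route)
ill_death_probs <- function(l01, l02, l12, t) {
  l0 <- l01 + l02
  pN <- if (abs(l12 - l0) < 1e-12) l01 * t * exp(-l0 * t) else
    l01 / (l12 - l0) * (exp(-l0 * t) - exp(-l12 * t))
  pNplus <- l01 / l0 * (1 - exp(-l0 * t))   # ever entered N
  pF <- l02 / l0 * (1 - exp(-l0 * t))
  c(N = pN, F = pF, N.F = pNplus - pN)
}

# brute-force projection onto the non-negative orthant in the V^{-1} metric:
# enumerate all support sets, solve each restricted problem, keep the
# feasible candidate with the smallest distance
project_orthant_bruteforce <- function(z, V) {
  K <- length(z)
  Vi <- solve(V)
  best <- NULL
  for (b in 0:(2^K - 1)) {
    J <- which(bitwAnd(b, 2^(seq_len(K) - 1)) > 0)
    w <- numeric(K)
    if (length(J)) {
      w[J] <- solve(Vi[J, J, drop = FALSE], drop(Vi[J, , drop = FALSE] %*% z))
    }
    if (any(w < -1e-10)) next
    d <- drop(t(z - w) %*% Vi %*% (z - w))
    if (is.null(best) || d < best$d - 1e-12) best <- list(w = w, d = d, dim = sum(w > 1e-9))
  }
  best
}

# quick two-arm event-history dataset from the illness-death model
sim_two_arm <- function(n = 200, tau = 5, censor_rate = 0, seed = 1,
                        treeB = tree_illness_death()) {
  set.seed(seed)
  dplyr::bind_rows(
    simulate_arm(tree_illness_death(), n, tau, censor_rate, arm = "A"),
    simulate_arm(treeB, n, tau, censor_rate, arm = "B"))
}

exhaustive_scheme_id <- function() {
  build_scheme(nf_components(), "exhaustive", tree = tree_illness_death())
}

random_pd <- function(K, scale = 1) {
  A <- matrix(rnorm(K * K), K)
  crossprod(A) / K + diag(K) * 0.1 * scale
}
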