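#' Multinomial estimation of event-type probabilities for one arm
#'
#' For complete follow-up through `tau` the event-type probabilities are the
#' observed proportions and the covariance follows from the underlying
#' multinomial distribution over exhaustive event types (including the
#' excluded no-event category); overlapping schemes inherit their covariance
#' through the scheme's linear map `L`.
#'
#' @param data Event-history records for a single arm.
#' @param scheme A [build_scheme()] scheme.
#' @param tau Follow-up horizon.
#' @return A `wc_arm_estimate`: fields `probs`, `cov`, `n`, `tau`, `scheme`,
#'   `estimator`.
#' @seealso [aalen_johansen_arm()] for right-censored data.
#' @export
estimate_binary_arm <- function(data, scheme, tau) {
  if (length(unique(data$arm)) != 1) {
    stop_wcomp("estimate_binary_arm() expects records for exactly one arm")
  }
  core <- classify_core(data, scheme, tau)
  n <- core$n
  p_ex <- colSums(core$ex_ind) / n
  V_ex <- (diag(p_ex, length(p_ex)) - tcrossprod(p_ex)) / n
  new_arm_estimate(
    probs = drop(scheme$L %*% p_ex),
    cov = scheme$L %*% V_ex %*% t(scheme$L),
    n = n, tau = tau, scheme = scheme, estimator = "multinomial")
}

new_arm_estimate <- function(probs, cov, n, tau, scheme, estimator,
                             truncated_at = NULL) {
  names(probs) <- scheme$event_types
  cov <- check_psd(cov)
  dimnames(cov) <- list(scheme$event_types, scheme$event_types)
  structure(list(probs = probs, cov = cov, n = n, tau = tau,
                 scheme = scheme, estimator = estimator,
                 truncated_at = truncated_at),
            class = "wc_arm_estimate")
}

#' @export
print.wc_arm_estimate <- function(x, ...) {
  cat(sprintf("<wc_arm_estimate: %s, n = %d, tau = %g>\n",
              x$estimator, x$n, x$tau))
  print(tidy(x))
  invisible(x)
}

#' @method tidy wc_arm_estimate
#' @export
tidy.wc_arm_estimate <- function(x, ...) {
  tibble(event_type = names(x$probs), estimate = unname(x$probs),
         std.error = sqrt(diag(x$cov)))
}

#' Aalen-Johansen estimation of event-type probabilities for one arm
#'
#' Estimates state-occupation probabilities of the directed-tree multistate
#' model at `tau` by the Aalen-Johansen product-limit estimator, which
#' handles right-censoring and reduces to the observed proportions when no
#' subject is censored before `tau`. The covariance is a Greenwood-type
#' estimator obtained by propagating the multinomial covariance of each
#' transition-hazard increment through the product-integral.
#'
#' If every subject leaves observation before `tau`, the estimate is carried
#' forward from the last estimable time, recorded in `truncated_at`.
#'
#' @inheritParams estimate_binary_arm
#' @param tree A [multistate_tree()] consistent with the records.
#' @export
aalen_johansen_arm <- function(data, tree, tau, scheme) {
  if (length(unique(data$arm)) != 1) {
    stop_wcomp("aalen_johansen_arm() expects records for exactly one arm")
  }
  validate_history(data)
  fit <- aj_fit(data, tree, tau, covariance = TRUE)
  M <- state_aggregation(tree, scheme)[, names(fit$probs), drop = FALSE]
  p_ex <- drop(M %*% fit$probs)
  V_ex <- M %*% fit$cov %*% t(M)
  new_arm_estimate(
    probs = drop(scheme$L %*% p_ex),
    cov = scheme$L %*% V_ex %*% t(scheme$L),
    n = fit$n, tau = tau, scheme = scheme, estimator = "aalen-johansen",
    truncated_at = fit$truncated_at)
}

# ---- Aalen-Johansen engine -------------------------------------------------

# Reconstructs subject paths through the tree (integer state indices) and
# precomputes what the product-limit passes need: transitions, per-event-time
# groups, and risk sets per transient state at every event time.
aj_prepare <- function(data, tree, tau) {
  data <- data[order(data$id, data$time), , drop = FALSE]
  ids <- unique(data$id)
  n <- length(ids)
  si <- match(data$id, ids)
  states <- tree$states
  S <- length(states)
  comps <- unique(tree$edges$component)
  # edge lookup: emap[state, component] = destination state
  emap <- matrix(NA_integer_, S, length(comps))
  ef <- match(tree$edges$from, states)
  et <- match(tree$edges$to, states)
  ec <- match(tree$edges$component, comps)
  emap[cbind(ef, ec)] <- et

  is_ev <- data$event != "censor"
  ev_si <- si[is_ev]
  ev_ci <- match(data$event[is_ev], comps)
  if (anyNA(ev_ci)) {
    stop_wcomp("event label(s) not a component of the tree: %s",
               paste(unique(data$event[is_ev][is.na(ev_ci)]), collapse = ", "))
  }
  ev_t <- data$time[is_ev]
  k <- sequence(rle(ev_si)$lengths)
  cur <- rep(1L, n)                          # states[1] is the root
  t_sub <- integer(0); t_time <- numeric(0)
  t_from <- integer(0); t_to <- integer(0)
  if (length(k)) {
    parts <- vector("list", max(k))
    for (kk in seq_len(max(k))) {
      sel <- which(k == kk)
      sj <- ev_si[sel]
      nxt <- emap[cbind(cur[sj], ev_ci[sel])]
      if (anyNA(nxt)) {
        bad <- sel[is.na(nxt)][1]
        stop_wcomp("transition '%s' from state '%s' is not an edge of the tree",
                   data$event[is_ev][bad], states[cur[ev_si[bad]]])
      }
      parts[[kk]] <- list(sub = sj, time = ev_t[sel], from = cur[sj], to = nxt)
      cur[sj] <- nxt
    }
    t_sub <- unlist(lapply(parts, `[[`, "sub"))
    t_time <- unlist(lapply(parts, `[[`, "time"))
    t_from <- unlist(lapply(parts, `[[`, "from"))
    t_to <- unlist(lapply(parts, `[[`, "to"))
  }
  end <- rep(Inf, n)                         # absorbed subjects stay observed
  end[si[!is_ev]] <- data$time[!is_ev]
  leaf <- !(seq_len(S) %in% ef)
  not_absorbed <- !leaf[cur] & is.infinite(end)
  if (any(not_absorbed)) {
    stop_wcomp("subject(s) without censor row nor absorbing event: %s",
               paste(head(ids[not_absorbed], 5), collapse = ", "))
  }

  sel_tau <- t_time <= tau
  utimes <- sort(unique(t_time[sel_tau]))
  Tn <- length(utimes)
  grp <- split(which(sel_tau), match(t_time[sel_tau], utimes))

  # risk set Y[t, g]: in state g just before utimes[t] and still observed;
  # entries/exits use all transitions, also those beyond tau
  Y <- matrix(0L, Tn, S)
  for (g in unique(t_from[sel_tau])) {
    if (g == 1L) {
      subj <- seq_len(n); ent <- rep(0, n)
    } else {
      selto <- t_to == g
      subj <- t_sub[selto]; ent <- t_time[selto]
    }
    nxt <- rep(Inf, length(subj))
    selg <- t_from == g
    if (any(selg)) nxt[match(t_sub[selg], subj)] <- t_time[selg]
    ex <- pmin(nxt, end[subj])
    es <- sort(ent)
    xs <- sort(ex[is.finite(ex)])
    Y[, g] <- findInterval(utimes - 1e-12, es) - findInterval(utimes - 1e-12, xs)
  }

  max_obs <- max(c(end[is.finite(end)], t_time, 0))
  truncated_at <- if (max_obs < tau && all(is.finite(end))) max_obs else NULL

  list(n = n, S = S, states = states, utimes = utimes, Tn = Tn, grp = grp,
       t_from = t_from, t_to = t_to, Y = Y, truncated_at = truncated_at)
}

# Aalen-Johansen product-limit estimator; optionally the Greenwood-type
# covariance (multinomial increment covariances propagated through P(0,u-)
# and P(u,tau)) and/or the whole occupation trajectory
aj_engine <- function(data, tree, tau, covariance = FALSE, path = FALSE) {
  pp <- aj_prepare(data, tree, tau)
  S <- pp$S; Tn <- pp$Tn
  if (!is.null(pp$truncated_at)) {
    warn(sprintf("risk set exhausted at %g before tau = %g; carrying last value forward",
                 pp$truncated_at, tau))
  }
  p <- c(1, numeric(S - 1))
  path_m <- NULL
  if (path) {
    path_m <- matrix(0, Tn + 1, S, dimnames = list(NULL, pp$states))
    path_m[1, 1] <- 1
  }
  Ms <- if (covariance) vector("list", Tn)
  prev <- if (covariance) matrix(0, Tn, S)
  for (m in seq_len(Tn)) {
    idx <- pp$grp[[m]]
    if (covariance) {
      prev[m, ] <- p
      Mu <- diag(1, S)
    }
    for (g in unique(pp$t_from[idx])) {
      sel <- idx[pp$t_from[idx] == g]
      Yg <- pp$Y[m, g]
      cnt <- tabulate(pp$t_to[sel], S)
      if (Yg < sum(cnt)) stop_wcomp("risk set smaller than transition count")
      move <- p[g] * cnt / Yg
      p <- p + move
      p[g] <- p[g] - sum(move)
      if (covariance) {
        Mu[g, ] <- cnt / Yg
        Mu[g, g] <- 1 - sum(cnt) / Yg
      }
    }
    if (covariance) Ms[[m]] <- Mu
    if (path) path_m[m + 1, ] <- p
  }
  out <- list(probs = setNames(p[-1], pp$states[-1]), n = pp$n,
              truncated_at = pp$truncated_at)
  if (path) { out$times <- pp$utimes; out$path <- path_m }
  if (covariance) {
    # suffix products P(u_m, tau), then per-time per-state contributions
    suffix <- vector("list", Tn)
    acc <- diag(1, S)
    for (m in rev(seq_len(Tn))) { suffix[[m]] <- acc; acc <- Ms[[m]] %*% acc }
    Vfull <- matrix(0, S, S)
    for (m in seq_len(Tn)) {
      idx <- pp$grp[[m]]
      B <- suffix[[m]]
      for (g in unique(pp$t_from[idx])) {
        sel <- idx[pp$t_from[idx] == g]
        Yg <- pp$Y[m, g]
        cntS <- tabulate(pp$t_to[sel], S)
        dest <- which(cntS > 0)
        nn <- cntS[dest]
        # multinomial covariance of the hazard increments to each child,
        # extended with the diagonal 'stay' entry via negative row sums
        Cj <- (diag(nn, length(nn)) - tcrossprod(nn) / Yg) / Yg^2
        supp <- c(g, dest)
        Cg <- matrix(0, length(supp), length(supp))
        Cg[-1, -1] <- Cj
        Cg[1, -1] <- -colSums(Cj)
        Cg[-1, 1] <- -rowSums(Cj)
        Cg[1, 1] <- sum(Cj)
        Bs <- B[supp, , drop = FALSE]
        Vfull <- Vfull + prev[m, g]^2 * crossprod(Bs, Cg %*% Bs)
      }
    }
    out$cov <- Vfull[-1, -1, drop = FALSE]
    dimnames(out$cov) <- list(pp$states[-1], pp$states[-1])
  }
  out
}

aj_fit <- function(data, tree, tau, covariance = FALSE) {
  aj_engine(data, tree, tau, covariance = covariance)
}

# AJ occupation probabilities evaluated on a time grid (step function,
# right-continuous); rows = grid points, cols = non-root states
aj_on_grid <- function(data, tree, grid, subset = NULL) {
  if (!is.null(subset)) data <- data[data$id %in% subset, , drop = FALSE]
  fit <- aj_engine(data, tree, max(grid), path = TRUE)
  tt <- c(0, fit$times)
  idx <- findInterval(grid, tt)
  fit$path[idx, -1, drop = FALSE]
}

#' Transform an arm estimate linearly
#'
#' Applies a linear map `L` to the probabilities and covariance of an
#' estimate (`probs <- L probs`, `cov <- L cov L'`), e.g. to move from the
#' exhaustive to the marginal scheme or to collapse event types.
#'
#' @param est A `wc_arm_estimate`.
#' @param L Numeric matrix with `length(est$probs)` columns.
#' @param event_types Optional labels for the transformed types.
#' @export
transform_estimate <- function(est, L, event_types = NULL) {
  L <- as.matrix(L)
  if (ncol(L) != length(est$probs)) stop_wcomp("L has %d columns, estimate has %d types",
                                               ncol(L), length(est$probs))
  out <- est
  out$probs <- drop(L %*% est$probs)
  out$cov <- check_psd(L %*% est$cov %*% t(L))
  if (is.null(event_types)) event_types <- paste0("T", seq_len(nrow(L)))
  names(out$probs) <- event_types
  dimnames(out$cov) <- list(event_types, event_types)
  out$scheme$event_types <- event_types
  out$scheme$L <- L %*% est$scheme$L
  out$scheme$K <- nrow(L)
  out
}

#' Between-arm difference of event-type probabilities
#'
#' Computes `D = probs_A - probs_B` with plug-in covariance
#' `V = cov_A + cov_B` (independent arms). Arm A is the reference arm, so a
#' positive difference means the event type is more frequent under A.
#'
#' @param estA,estB `wc_arm_estimate`s for the two arms, with identical
#'   scheme and horizon.
#' @return A `wc_difference`: fields `D`, `V`, `n_A`, `n_B`, `tau`, `scheme`.
#' @export
arm_difference <- function(estA, estB) {
  if (!identical(estA$scheme$event_types, estB$scheme$event_types) ||
      !identical(estA$scheme$setting, estB$scheme$setting)) {
    stop_wcomp("arm estimates use different schemes")
  }
  if (!isTRUE(all.equal(estA$tau, estB$tau))) stop_wcomp("arm estimates use different tau")
  structure(list(D = estA$probs - estB$probs,
                 V = check_psd(estA$cov + estB$cov),
                 n_A = estA$n, n_B = estB$n, tau = estA$tau,
                 scheme = estA$scheme),
            class = "wc_difference")
}

#' @export
print.wc_difference <- function(x, ...) {
  cat(sprintf("<wc_difference: %d event type(s), n = %d + %d, tau = %g>\n",
              length(x$D), x$n_A, x$n_B, x$tau))
  print(tidy(x))
  invisible(x)
}

#' @method tidy wc_difference
#' @export
tidy.wc_difference <- function(x, ...) {
  tibble(event_type = names(x$D), estimate = unname(x$D),
         std.error = sqrt(diag(x$V)))
}

#' @method glance wc_difference
#' @export
glance.wc_difference <- function(x, ...) {
  tibble(n_A = x$n_A, n_B = x$n_B, tau = x$tau, K = length(x$D),
         setting = x$scheme$setting)
}

#' Estimate the event-type probability difference between two arms
#'
#' Convenience wrapper: splits the records by arm, estimates each arm
#' (multinomially, or by Aalen-Johansen when `tree` is given and censoring
#' before `tau` is present) and returns their difference, arm A minus arm B.
#'
#' @param data Event-history records for both arms.
#' @param scheme A [build_scheme()] scheme.
#' @param tau Follow-up horizon.
#' @param tree Optional [multistate_tree()]; required for right-censored data.
#' @param arms Optional length-2 character vector fixing which arm is A
#'   (first) and B; defaults to the sorted unique arm labels.
#' @param estimator `"auto"` (default), `"multinomial"` or `"aalen-johansen"`.
#' @export
wce_estimate <- function(data, scheme, tau, tree = NULL, arms = NULL,
                         estimator = c("auto", "multinomial", "aalen-johansen")) {
  estimator <- arg_match(estimator)
  validate_history(data)
  if (is.null(arms)) arms <- sort(unique(as.character(data$arm)))
  if (length(arms) != 2) stop_wcomp("need exactly two arms, got: %s",
                                    paste(arms, collapse = ", "))
  one <- function(a) {
    d <- data[data$arm == a, , drop = FALSE]
    if (estimator == "multinomial") return(estimate_binary_arm(d, scheme, tau))
    if (estimator == "aalen-johansen") return(aalen_johansen_arm(d, tree, tau, scheme))
    # auto: multinomial when follow-up is complete, AJ otherwise
    complete <- tryCatch({classify_events(d, scheme, tau); TRUE},
                         error = function(e) FALSE)
    if (complete) estimate_binary_arm(d, scheme, tau)
    else {
      if (is.null(tree)) stop_wcomp("right-censored records need a multistate tree")
      aalen_johansen_arm(d, tree, tau, scheme)
    }
  }
  arm_difference(one(arms[1]), one(arms[2]))
}

#' Integrated probability difference with jackknife covariance
#'
#' The integrated statistic accumulates the weighted-in-time difference of
#' event-type probability curves, `sum_j h(t_j) (pA(t_j) - pB(t_j)) dt`,
#' over a regular left-endpoint Riemann grid from 0 to `tau`. With
#' `h == 1` and a single absorbing event this is the difference in
#' restricted means of the time to the event. The covariance is the sum of
#' per-arm leave-one-subject-out jackknife estimates.
#'
#' @inheritParams wce_estimate
#' @param h Non-negative weight function of time; default constant 1.
#' @param grid_step Riemann grid spacing; default `tau / 200`.
#' @return A `wc_integrated` (also a `wc_difference`): `D`, `V`, plus
#'   `h_spec` and `grid_step`.
#' @export
integrated_difference <- function(data, tree, tau, scheme, h = NULL,
                                  grid_step = tau / 200, arms = NULL) {
  validate_history(data)
  if (grid_step <= 0 || grid_step >= tau) stop_wcomp("grid_step must be in (0, tau)")
  if (is.null(h)) h <- function(t) rep(1, length(t))
  grid <- seq(0, tau - grid_step, by = grid_step)
  hv <- h(grid)
  if (any(hv < 0)) stop_wcomp("h must be non-negative on the grid")
  if (is.null(arms)) arms <- sort(unique(as.character(data$arm)))
  M <- state_aggregation(tree, scheme)

  integrate_arm <- function(d, subset = NULL) {
    P <- aj_on_grid(d, tree, c(grid, tau), subset)  # include tau for findInterval
    P <- P[seq_along(grid), , drop = FALSE]
    p_ex <- t(M[, colnames(P), drop = FALSE] %*% t(P))  # grid x K_ex
    p_s <- p_ex %*% t(scheme$L)               # grid x K
    drop(crossprod(p_s, hv)) * grid_step
  }
  jack <- function(d) {
    ids <- unique(d$id)
    n <- length(ids)
    th <- vapply(ids, function(i) integrate_arm(d, subset = setdiff(ids, i)),
                 numeric(scheme$K))
    th <- if (scheme$K == 1) matrix(th, ncol = 1) else t(th)
    thbar <- colMeans(th)
    cent <- sweep(th, 2, thbar)
    ((n - 1) / n) * crossprod(cent)
  }
  dA <- data[data$arm == arms[1], , drop = FALSE]
  dB <- data[data$arm == arms[2], , drop = FALSE]
  D <- integrate_arm(dA) - integrate_arm(dB)
  V <- check_psd(jack(dA) + jack(dB))
  names(D) <- scheme$event_types
  dimnames(V) <- list(scheme$event_types, scheme$event_types)
  structure(list(D = D, V = V, n_A = length(unique(dA$id)),
                 n_B = length(unique(dB$id)), tau = tau, scheme = scheme,
                 h_spec = deparse(body(h)), grid_step = grid_step),
            class = c("wc_integrated", "wc_difference"))
}

# jackknife covariance of the (non-integrated) AJ probabilities at tau;
# used to validate the Greenwood-type estimator
jackknife_arm_cov <- function(data, tree, tau, scheme) {
  ids <- unique(data$id)
  n <- length(ids)
  M <- state_aggregation(tree, scheme)
  one <- function(drop_id) {
    f <- aj_fit(data[data$id != drop_id, , drop = FALSE], tree, tau)
    drop(scheme$L %*% (M[, names(f$probs), drop = FALSE] %*% f$probs))
  }
  th <- t(vapply(ids, one, numeric(scheme$K)))
  cent <- sweep(th, 2, colMeans(th))
  ((n - 1) / n) * crossprod(cent)
}
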