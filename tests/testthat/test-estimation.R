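test_that("multinomial estimates reproduce the enteric-fever fractions", {
  d <- enteric_fever_data()
  sch <- build_scheme(enteric_fever_components(), "competing_risks")
  cef <- estimate_binary_arm(d[d$arm == "Cefixime", ], sch, tau = 1)
  expect_equal(unname(cef$probs["failure"]), 20 / 77, tolerance = 1e-12)
  expect_equal(unname(cef$probs["relapse"]), 6 / 77, tolerance = 1e-12)
  expect_equal(cef$n, 77)

  diff <- wce_estimate(d, sch, tau = 1, arms = c("Cefixime", "Gatifloxacin"))
  expect_equal(unname(diff$D["failure"]), 20 / 77 - 1 / 92, tolerance = 1e-12)
  expect_equal(unname(diff$D["relapse"]), 6 / 77 - 2 / 92, tolerance = 1e-12)

  # plug-in covariance is the sum of the two per-arm multinomial covariances
  mcov <- function(p, n) (diag(p) - tcrossprod(p)) / n
  expected_V <- mcov(c(6, 20) / 77, 77) + mcov(c(2, 1) / 92, 92)
  expect_equal(unname(diff$V), unname(expected_V), tolerance = 1e-12)
})

test_that("a single subject gives a unit probability vector with zero covariance", {
  hist <- tibble::tibble(id = "x", arm = "A", time = 1, event = "F")
  est <- estimate_binary_arm(hist, build_scheme(nf_components(), "exhaustive"), 5)
  expect_equal(unname(est$probs), c(0, 1, 0))
  expect_equal(unname(est$cov), matrix(0, 3, 3))
})

test_that("the hand-worked 4-subject Aalen-Johansen estimate is reproduced", {
  dat <- tibble::tribble(
    ~id, ~arm, ~time, ~event,
    "1", "A", 1.0, "N",
    "1", "A", 2.0, "F",
    "2", "A", 1.5, "censor",
    "3", "A", 3.0, "F",
    "4", "A", 5.0, "censor")
  sch <- exhaustive_scheme_id()
  aj <- aalen_johansen_arm(dat, tree_illness_death(), 5, sch)
  # product-limit by hand over the three event times 1, 2, 3
  expect_equal(unname(aj$probs), c(0, 3 / 8, 1 / 4), tolerance = 1e-12)
})

test_that("without censoring before tau the AJ estimate equals the proportions", {
  for (seed in c(2, 3)) {
    dat <- sim_two_arm(n = 120, seed = seed)
    a <- dat[dat$arm == "A", ]
    sch <- exhaustive_scheme_id()
    e_mult <- estimate_binary_arm(a, sch, 5)
    e_aj <- aalen_johansen_arm(a, tree_illness_death(), 5, sch)
    expect_equal(e_aj$probs, e_mult$probs, tolerance = 1e-12)
  }
})

test_that("AJ probabilities and standard errors match mstate on censored data", {
  skip_if_not_installed("mstate")
  tree <- tree_illness_death()
  sch <- exhaustive_scheme_id()
  set.seed(11)
  dat <- simulate_arm(tree, 400, tau = 5, censor_rate = 0.1, arm = "A")
  aj <- aalen_johansen_arm(dat, tree, 5, sch)

  tmat <- mstate::transMat(x = list(c(2, 3), c(4), c(), c()),
                           names = c("init", "N", "F", "NF"))
  ids <- unique(dat$id)
  rows <- lapply(ids, function(i) {
    d <- dat[dat$id == i, ]
    ev <- d[d$event != "censor", ]
    cens_t <- if (any(d$event == "censor")) max(d$time[d$event == "censor"]) else Inf
    t_N <- if (nrow(ev) && ev$event[1] == "N") ev$time[1] else NA
    t_F1 <- if (nrow(ev) && ev$event[1] == "F") ev$time[1] else NA
    t_F2 <- if (nrow(ev) > 1) ev$time[2] else NA
    end1 <- min(cens_t, t_N, t_F1, na.rm = TRUE)
    data.frame(
      id = i,
      from = c(1, 1, if (!is.na(t_N)) 2),
      to = c(2, 3, if (!is.na(t_N)) 4),
      trans = c(1, 2, if (!is.na(t_N)) 3),
      Tstart = c(0, 0, if (!is.na(t_N)) t_N),
      Tstop = c(end1, end1, if (!is.na(t_N)) min(cens_t, t_F2, na.rm = TRUE)),
      status = c(!is.na(t_N) && end1 == t_N, !is.na(t_F1) && end1 == t_F1,
                 if (!is.na(t_N)) !is.na(t_F2)) * 1)
  })
  ms <- do.call(rbind, rows)
  class(ms) <- c("msdata", "data.frame")
  attr(ms, "trans") <- tmat
  cx <- survival::coxph(survival::Surv(Tstart, Tstop, status) ~
                          survival::strata(trans), data = ms)
  pt <- mstate::probtrans(mstate::msfit(cx, trans = tmat), predt = 0)[[1]]
  last <- pt[max(which(pt$time <= 5)), ]
  expect_equal(unname(aj$probs), unname(unlist(last[paste0("pstate", 2:4)])),
               tolerance = 1e-8)
  expect_equal(unname(sqrt(diag(aj$cov))), unname(unlist(last[paste0("se", 2:4)])),
               tolerance = 0.02)
})

test_that("AJ converges to the analytic constant-hazard probabilities", {
  tree <- tree_illness_death()
  sch <- exhaustive_scheme_id()
  set.seed(21)
  n <- 20000
  dat <- simulate_arm(tree, n, tau = 5, censor_rate = 0.05, arm = "A")
  aj <- aalen_johansen_arm(dat, tree, 5, sch)
  truth <- ill_death_probs(0.05, 0.02, 0.2, 5)
  # 3 standard errors using the estimator's own Greenwood standard errors
  expect_true(all(abs(aj$probs - truth) <= 3 * sqrt(diag(aj$cov)) + 1e-12))
})

test_that("linear transforms move estimate and covariance together", {
  dat <- sim_two_arm(n = 100, seed = 31)
  a <- dat[dat$arm == "A", ]
  exh <- estimate_binary_arm(a, build_scheme(nf_components(), "exhaustive"), 5)

  same <- transform_estimate(exh, diag(1, 3), names(exh$probs))
  expect_equal(same$probs, exh$probs)
  expect_equal(same$cov, exh$cov)

  # published marginal transformation == estimating marginally directly
  L <- rbind(c(1, 0, 1), c(0, 1, 1))
  marg1 <- transform_estimate(exh, L, c("N", "F"))
  marg2 <- estimate_binary_arm(a, build_scheme(nf_components(), "marginal"), 5)
  expect_equal(marg1$probs, marg2$probs, tolerance = 1e-12)
  expect_equal(unname(marg1$cov), unname(marg2$cov), tolerance = 1e-12)

  # collapsing a non-overlapping scheme to any-event gives binomial variance
  any_ev <- transform_estimate(exh, matrix(1, 1, 3), "any")
  p <- sum(exh$probs)
  expect_equal(unname(any_ev$cov[1, 1]), p * (1 - p) / exh$n, tolerance = 1e-12)
})

test_that("jackknife and Greenwood covariances agree at moderate sample size", {
  tree <- tree_illness_death()
  sch <- exhaustive_scheme_id()
  set.seed(41)
  dat <- simulate_arm(tree, 500, tau = 5, censor_rate = 0.05, arm = "A")
  aj <- aalen_johansen_arm(dat, tree, 5, sch)
  jk <- wcomp:::jackknife_arm_cov(dat, tree, 5, sch)
  rel <- norm(jk - aj$cov, "F") / norm(aj$cov, "F")
  expect_lt(rel, 0.15)
})

test_that("covariance estimates are symmetric and PSD", {
  dat <- sim_two_arm(n = 150, censor_rate = 0.05, seed = 51)
  sch <- exhaustive_scheme_id()
  d <- wce_estimate(dat, sch, 5, tree = tree_illness_death())
  expect_equal(d$V, t(d$V))
  expect_gte(min(eigen(d$V, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
})

test_that("identical arms give a zero integrated difference", {
  set.seed(61)
  one <- simulate_arm(tree_illness_death(), 60, 5, 0.05, arm = "A")
  two <- one
  two$arm <- "B"
  two$id <- paste0("B", two$id)
  dat <- dplyr::bind_rows(one, two)
  sch <- exhaustive_scheme_id()
  int <- integrated_difference(dat, tree_illness_death(), 5, sch, grid_step = 0.1)
  expect_equal(unname(int$D), c(0, 0, 0), tolerance = 1e-12)
})

test_that("integrated difference with h = 1 recovers restricted-mean differences", {
  # single absorbing event: integral of (1 - S) up to tau, i.e. tau minus the
  # restricted mean survival time from the Kaplan-Meier curve
  tree1 <- multistate_tree(tibble::tibble(from = "initial", to = "F",
                                          component = "F", hazard = 0.3))
  sch1 <- build_scheme(component_set("F", fatal = TRUE), "exhaustive", tree1)
  set.seed(71)
  datA <- simulate_arm(tree1, 150, tau = 4, censor_rate = 0.1, arm = "A")
  datB <- simulate_arm(scale_hazards(tree1, 0.6), 150, tau = 4,
                       censor_rate = 0.1, arm = "B")
  dat <- dplyr::bind_rows(datA, datB)
  gs <- 4 / 400
  int <- integrated_difference(dat, tree1, 4, sch1, grid_step = gs)

  rmst_deficit <- function(d) {
    stat <- as.integer(d$event == "F")
    fit <- survival::survfit(survival::Surv(d$time, stat) ~ 1)
    Sfun <- stats::stepfun(fit$time, c(1, fit$surv))
    grid <- seq(0, 4 - gs, by = gs)
    sum(1 - Sfun(grid)) * gs
  }
  expected <- rmst_deficit(datA) - rmst_deficit(datB)
  expect_equal(unname(int$D), expected, tolerance = 1e-10)
})

test_that("the Riemann sum converges under grid refinement", {
  dat <- sim_two_arm(n = 150, censor_rate = 0.05, seed = 81,
                     treeB = scale_hazards(tree_illness_death(), 0.75))
  sch <- exhaustive_scheme_id()
  g <- function(gs) integrated_difference(dat, tree_illness_death(), 5, sch,
                                          grid_step = gs)$D
  ref <- g(5 / 400)
  err_coarse <- sqrt(sum((g(5 / 50) - ref)^2))
  err_fine <- sqrt(sum((g(5 / 200) - ref)^2))
  expect_lt(err_fine, err_coarse / 2)
  expect_lt(err_fine, 0.01 * max(abs(ref), 0.05))
})

test_that("an exhausted risk set before tau carries forward with a flag", {
  dat <- tibble::tibble(id = c("1", "2"), arm = "A",
                        time = c(1, 2), event = c("censor", "censor"))
  sch <- exhaustive_scheme_id()
  expect_warning(
    aj <- aalen_johansen_arm(dat, tree_illness_death(), 5, sch),
    "carrying")
  expect_equal(aj$truncated_at, 2)
})
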