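test_that("zero hazards produce only administrative censoring rows", {
  tree0 <- tree_illness_death(rates = c(0, 0, 0))
  set.seed(301)
  dat <- simulate_arm(tree0, 50, tau = 5, censor_rate = 0, arm = "A")
  expect_equal(nrow(dat), 50)
  expect_true(all(dat$event == "censor"))
  expect_true(all(dat$time == 5))
})

test_that("simulated event-type proportions converge to the analytic oracle", {
  tree <- tree_illness_death()
  sch <- exhaustive_scheme_id()
  set.seed(307)
  n <- 20000
  dat <- simulate_arm(tree, n, tau = 5, censor_rate = 0, arm = "A")
  est <- estimate_binary_arm(dat, sch, 5)
  truth <- ill_death_probs(0.05, 0.02, 0.2, 5)
  se <- sqrt(truth * (1 - truth) / n)
  expect_true(all(abs(est$probs - truth) <= 3 * se))

  # second-series and cardiovascular models against the matrix exponential
  for (tr in list(tree_two_transient(), tree_cardiovascular("intervention"))) {
    comps <- wcomp:::tree_components(tr)
    sch_t <- build_scheme(comps, "exhaustive", tr)
    truth_t <- analytic_event_probs(tr, 3, sch_t)$prob
    dat_t <- simulate_arm(tr, n, tau = 3, censor_rate = 0, arm = "A")
    est_t <- estimate_binary_arm(dat_t, sch_t, 3)
    se_t <- sqrt(truth_t * (1 - truth_t) / n)
    expect_true(all(abs(est_t$probs - truth_t) <= 3 * se_t))
  }
})

test_that("the censoring fraction matches its analytic value", {
  # P(censored before tau) = int_0^tau r e^{-rc} P(not absorbed by c) dc
  tree <- tree_illness_death()
  r <- 0.05
  surv_not_dead <- function(c) {
    p <- vapply(c, function(ci) sum(ill_death_probs(0.05, 0.02, 0.2, ci)[c("N")]) , numeric(1))
    p0 <- exp(-0.07 * c)
    p0 + p
  }
  truth <- stats::integrate(function(c) r * exp(-r * c) * surv_not_dead(c),
                            0, 5)$value
  set.seed(311)
  n <- 20000
  dat <- simulate_arm(tree, n, tau = 5, censor_rate = r, arm = "A")
  cens_early <- tapply(dat$time, dat$id, max) < 5 - 1e-9 &
    !tapply(dat$event, dat$id, function(e) !"censor" %in% e)
  frac <- mean(cens_early)
  expect_equal(frac, truth, tolerance = 3 * sqrt(truth * (1 - truth) / n) / truth)
})

test_that("simplex grids land near the target size and inside the cone", {
  g2 <- simplex_cone_grid(cone_nonneg(2), 1000)
  expect_equal(ncol(g2), 2)
  expect_true(abs(nrow(g2) - 1000) <= 10)
  expect_true(all(abs(rowSums(g2) - 1) < 1e-9))
  expect_true(all(g2 >= 0))
  expect_true(all(rowSums(abs(g2)) > 0))

  # decreasing order cone in two dimensions keeps the first weight dominant
  g_ord <- simplex_cone_grid(cone_ordered(2, decreasing = TRUE), 300)
  expect_true(all(g_ord[, 1] >= 0.5 - 1e-9))

  g5 <- simplex_cone_grid(cone_nonneg(5), 1e4)
  expect_lt(abs(nrow(g5) - 1e4) / 1e4, 0.2)

  expect_error(simplex_cone_grid(cone(matrix(-1, 1, 1)), 100), "intersect")
})

test_that("coverage ordering and efficiency ordering hold replication-wise", {
  tree <- tree_illness_death()
  sch <- exhaustive_scheme_id()
  scn <- scenario_spec(tree, tree, n_per_arm = 200, tau = 5, censor_rate = 0)
  res <- coverage_study(scn, sch, cone_nonneg(3), reps = 60,
                        grid_points = 200, seed = 5)
  td <- tidy(res)
  cov <- setNames(td$simultaneous_coverage, td$method)
  expect_lte(cov["unadjusted"], cov["chibar"])
  expect_lte(cov["chibar"], cov["scheffe"])
  # per replication: Scheffe covers whenever chi-bar covers
  both <- stats::complete.cases(res$cover)
  expect_true(all(res$cover[both, "scheffe"] >= res$cover[both, "chibar"]))
  # relative efficiencies: unadjusted <= chi-bar <= Scheffe in every rep
  expect_true(all(res$re[both, "unadjusted"] <= res$re[both, "chibar"] + 1e-12))
  expect_true(all(res$re[both, "chibar"] <= res$re[both, "scheffe"] + 1e-12))

  # order-cone chi-bar never beats the orthant in width
  res_ord <- coverage_study(scn, sch, cone_ordered(3), methods = "chibar",
                            reps = 20, grid_points = 200, seed = 5)
  expect_lte(mean(res_ord$re[, "chibar"], na.rm = TRUE),
             mean(res$re[, "chibar"], na.rm = TRUE))
})

test_that("coverage studies are reproducible under a fixed seed", {
  tree <- tree_illness_death()
  sch <- exhaustive_scheme_id()
  scn <- scenario_spec(tree, tree, n_per_arm = 100, tau = 5, censor_rate = 0.05)
  r1 <- coverage_study(scn, sch, cone_nonneg(3), reps = 15, grid_points = 100, seed = 77)
  r2 <- coverage_study(scn, sch, cone_nonneg(3), reps = 15, grid_points = 100, seed = 77)
  expect_identical(tidy(r1), tidy(r2))
})

test_that("power under the null is the nominal level", {
  tree <- tree_illness_death()
  sch <- exhaustive_scheme_id()
  scn <- scenario_spec(tree, tree, n_per_arm = 150, tau = 5, censor_rate = 0)
  pw <- power_samplesize(scn, sch, weights = c(1, 1, 1), method = "unadjusted",
                         n_candidates = 150, reps = 400, seed = 17,
                         target_power = 0.9)
  expect_lt(abs(pw$curve$power - 0.05), 3 * sqrt(0.05 * 0.95 / 400) + 0.01)
  expect_false(pw$reached)
})

test_that("power rises with sample size and the crossing is interpolated", {
  tree <- tree_illness_death()
  treeB <- scale_hazards(tree_illness_death(), 0.5)
  sch <- exhaustive_scheme_id()
  scn <- scenario_spec(tree, treeB, n_per_arm = 100, tau = 5, censor_rate = 0)
  pw <- power_samplesize(scn, sch, weights = c(1, 1, 1), method = "unadjusted",
                         n_candidates = c(60, 240), reps = 250, seed = 19,
                         target_power = 0.7)
  expect_lte(pw$curve$power[1], pw$curve$power[2] + 0.05)
  if (pw$reached) {
    expect_equal(pw$n_star, min(pw$curve$n[pw$curve$power >= 0.7]))
    expect_true(pw$n_interp <= pw$n_star)
  }
})

test_that("scenario configs round-trip through YAML", {
  scn <- read_scenario("cardiovascular")
  expect_s3_class(scn, "wc_scenario")
  expect_equal(scn$tau, 3)
  expect_equal(scn$censor_rate, 0.05)
  expect_equal(sort(scn$treeA$states),
               sort(tree_cardiovascular("control")$states))
  p <- analytic_event_probs(scn$treeA, 3)
  expect_equal(1 - p$prob[p$state == "initial"],
               1 - analytic_event_probs(tree_cardiovascular("control"), 3)$prob[1],
               tolerance = 1e-12)
})
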