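# Weighted least-squares objective and particle swarm fitting.

test_that("the objective is a sigma-weighted sum of squares", {
  tc <- make_toy_chain(2, feed = 1, k = 2)
  m <- tc$model
  ds <- make_calibration_data(m, c("conc:M1", "flux:STEP1"), noise_sigma = 0)
  # perfect fit
  expect_equal(calibration_objective(m$params, m, ds), 0, tolerance = 1e-6)
  # one point off by 2 sigma contributes 4
  ds2 <- ds[1, , drop = FALSE]
  attr(ds2, "conditions") <- attr(ds, "conditions")
  ds2$value <- ds2$value + 2 * ds2$sigma
  expect_equal(calibration_objective(m$params, m, ds2), 4, tolerance = 1e-6)
  expect_error({
    ds3 <- ds
    ds3$sigma <- 0
    calibration_objective(m$params, m, ds3)
  }, "sigma")
})

test_that("chi-square expectation holds for noisy synthetic data", {
  tc <- make_toy_chain(4, forms = "mm", feed = 1, vmax = 3, km = 0.8)
  m <- tc$model
  conds <- list(a = list(), b = list(scale = c(FEED = 0.6)),
                c = list(scale = c(FEED = 1.5)))
  obs <- c("conc:M1", "conc:M2", "conc:M3", "flux:STEP1", "flux:STEP3")
  # sigma = 5%, ~45 points over three seeds: f(true)/n concentrates near 1
  ratios <- vapply(1:3, function(sd) {
    ds <- make_calibration_data(m, obs, conds, noise_sigma = 0.05, seed = sd)
    calibration_objective(m$params, m, ds) / nrow(ds)
  }, 0)
  expect_equal(mean(ratios), 1, tolerance = 0.4)
})

test_that("simulation failure returns a finite penalty, not an exception", {
  tc <- make_toy_chain(2, forms = "mm", feed = 1, vmax = 3, km = 1)
  m <- tc$model
  ds <- make_calibration_data(m, "conc:M1", noise_sigma = 0)
  # Vmax below the feed: no steady state with positive throughput
  p_bad <- c(STEP1.Vmax = 0.5)
  val <- calibration_objective(p_bad, m, ds)
  expect_true(is.finite(val))
  expect_gte(val, 1e10)
})

test_that("PSO respects bounds, is seeded, and descends on convex objectives", {
  sphere <- function(x) sum((x - 0.3)^2)
  f1 <- fit_pso(sphere, rep(-1, 3), rep(1, 3), n_particles = 15, iters = 40,
                seed = 8)
  f2 <- fit_pso(sphere, rep(-1, 3), rep(1, 3), n_particles = 15, iters = 40,
                seed = 8)
  expect_identical(f1, f2)
  expect_equal(f1$par, rep(0.3, 3), tolerance = 0.01)
  expect_true(all(diff(f1$trace) <= 0))
  # pinned coordinates: lower == upper
  f3 <- fit_pso(sphere, c(0.5, -1, -1), c(0.5, 1, 1), n_particles = 10,
                iters = 10, seed = 1)
  expect_equal(f3$par[1], 0.5)
})

test_that("zero-noise parameters are recovered within 5% on a toy model", {
  toy <- make_toy_chain(3, forms = c("mm", "ma"), feed = 1, vmax = 3,
                        km = 0.8, k = 2)
  m <- toy$model
  conds <- list(low = list(scale = c(FEED = 0.5)), ref = list(),
                high = list(scale = c(FEED = 1.8)))
  ds <- make_calibration_data(m, c("conc:M1", "conc:M2", "flux:STEP2"),
                              conds, noise_sigma = 0, seed = 3)
  truth <- m$params[c("STEP1.Vmax", "STEP1.Km_M1", "STEP2.kf")]
  fit <- fit_model(m, ds, free = names(truth), n_particles = 30, iters = 80,
                   seed = 7)
  rep <- recovery_report(truth, fit$par)
  expect_lt(max(rep$rel_error), 0.05)
  expect_false(any(rep$at_bound))
})

test_that("a parameter the data cannot see is flagged at its bound", {
  toy <- make_toy_chain(3, forms = c("ma", "ma"), feed = 1, k = c(2, 3))
  m <- toy$model
  # only observe M2: STEP1.kf does not influence it (M2 = feed / k2)
  ds <- make_calibration_data(m, "conc:M2", noise_sigma = 0)
  truth <- m$params[c("STEP1.kf", "STEP2.kf")]
  fit <- fit_model(m, ds, free = names(truth), n_particles = 20, iters = 40,
                   seed = 12)
  rep <- recovery_report(truth, fit$par)
  expect_lt(rep$rel_error[rep$parameter == "STEP2.kf"], 0.05)
  # the dead parameter wanders: typically pinned at a bound or far off
  dead <- rep[rep$parameter == "STEP1.kf", ]
  expect_true(dead$at_bound || dead$rel_error > 0.2)
})

test_that("noisy recovery keeps the median relative error moderate", {
  toy <- make_toy_chain(3, forms = c("mm", "ma"), feed = 1, vmax = 3,
                        km = 0.8, k = 2)
  m <- toy$model
  conds <- list(low = list(scale = c(FEED = 0.5)), ref = list(),
                high = list(scale = c(FEED = 1.8)))
  ds <- make_calibration_data(m, c("conc:M1", "conc:M2", "flux:STEP2"),
                              conds, noise_sigma = 0.05, seed = 21)
  truth <- m$params[c("STEP1.Vmax", "STEP1.Km_M1", "STEP2.kf")]
  fit <- fit_model(m, ds, free = names(truth), n_particles = 30, iters = 60,
                   seed = 4)
  rep <- recovery_report(truth, fit$par)
  expect_lt(stats::median(rep$rel_error), 0.15)
})
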