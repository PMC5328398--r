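# Time-course integration and steady-state solving.

test_that("zero-capacity model yields a constant trajectory", {
  tc <- make_toy_chain(3, feed = 1, k = 2)
  tr <- simulate_model(tc$model, c(1, 10, 100), scale = 0)
  for (sp in c("M1", "M2")) {
    expect_equal(tr[[sp]], rep(tc$model$species$conc[tc$model$species$id == sp], 3))
  }
})

test_that("reversible isomerization relaxes along the analytic exponential", {
  iso <- make_reversible_pair(kf = 1, kr = 0.5, a0 = 1, b0 = 0)
  tg <- c(0.2, 0.5, 1, 2, 5)
  tr <- simulate_model(iso$model, tg)
  expect_equal(tr$A, iso$analytic(tr$time), tolerance = 1e-5)
  # closed system: total mass conserved along the trajectory
  expect_equal(tr$A + tr$B, rep(1, length(tg)), tolerance = 1e-8)
})

test_that("boundary species stay fixed during simulation", {
  m <- with_excess_glucose(ref_model())
  tr <- simulate_model(m, c(10, 100))
  expect_equal(tr$GLC_e, rep(10, 2))
  expect_equal(tr$H_c, rep(0.1, 2))
})

test_that("conserved pools stay constant along reference-model trajectories", {
  m <- ref_model()
  x0 <- setNames(m$species$conc, m$species$id)
  x0["PYR"] <- x0["PYR"] * 2   # kick the state off the steady state
  tr <- simulate_model(m, c(10, 1000), initial_state = x0)
  aden <- unname(rowSums(tr[, c("ATP", "ADP", "AMP", "CAMP")]))
  expect_equal(aden, rep(aden[1], nrow(tr)), tolerance = 1e-6)
  nad <- unname(rowSums(tr[, c("NAD", "NADH")]))
  expect_equal(nad, rep(nad[1], nrow(tr)), tolerance = 1e-6)
})

test_that("toy steady states match the closed forms to 1e-8", {
  tc <- make_toy_chain(4, forms = c("ma", "mm", "ma"), feed = 1.3,
                       k = c(2, 1, 0.7), vmax = 4, km = 0.6)
  st <- steady_state(tc$model, initial_guess = tc$steady_state$concentrations * 1.7,
                     atol = 1e-12, rtol = 1e-10)
  expect_true(st$converged)
  expect_equal(st$concentrations, tc$steady_state$concentrations,
               tolerance = 1e-8)
  expect_lt(st$residual_norm, 1e-8)
  # the cofactor cycle conserves C + D: perturb within the moiety class,
  # otherwise the solver correctly finds the steady state of another class
  ty <- make_toy_cycle()
  g <- ty$steady_state$concentrations
  g["M"] <- g["M"] * 3
  g["C"] <- g["C"] - 0.2
  g["D"] <- g["D"] + 0.2
  st2 <- steady_state(ty$model, initial_guess = g, atol = 1e-12, rtol = 1e-10)
  expect_true(st2$converged)
  expect_equal(st2$concentrations, ty$steady_state$concentrations,
               tolerance = 1e-8)
})

test_that("reference chemostat steady state has growth 0.1 1/h and tiny residuals", {
  st <- ref_steady()
  expect_true(st$converged)
  expect_equal(unname(st$fluxes["GROWTH"] * 3600), 0.1, tolerance = 1e-6)
  m <- ref_model()
  dyn <- !m$species$boundary
  r <- colikin:::steady_residual(m, st$concentrations, rep(1, 68))
  expect_true(all(abs(r$dx) <= 1e-8 + 1e-6 * st$concentrations[dyn]))
  # fluxes reported by the solver equal evaluate_rates at the solution
  expect_equal(st$fluxes, evaluate_rates(m, st$concentrations))
})

test_that("a perturbed reference state returns to the reference steady state", {
  m <- ref_model()
  st <- ref_steady()
  x0 <- st$concentrations
  dyn <- !m$species$boundary
  set.seed(9)
  x0[dyn] <- x0[dyn] * exp(rnorm(sum(dyn), 0, 0.1))
  # moiety totals must match the reference for the comparison to make sense
  C <- moiety_matrix(m)
  x0[dyn] <- x0[dyn] + as.numeric(C %*% crossprod(C, st$concentrations[dyn] - x0[dyn]))
  tr <- simulate_model(m, c(1e4, 9e4), initial_state = pmax(x0, 1e-12))
  xe <- unlist(tr[nrow(tr), -1])
  expect_equal(unname(xe[dyn]), unname(st$concentrations[dyn]), tolerance = 1e-2)
  # and simulating onward from the steady state itself stays put
  tr2 <- simulate_model(m, c(1e4, 9e4), initial_state = st$concentrations)
  expect_equal(unname(unlist(tr2[2, -1])), unname(st$concentrations),
               tolerance = 1e-5)
})

test_that("a blocked network reports non-convergence or a zero-growth state", {
  m <- ref_model()
  sc <- setNames(rep(1, 68), names(m$reactions))
  sc["GLT"] <- 0   # no citrate synthase: TCA cut
  st <- steady_state(with_excess_glucose(m), scale = sc)
  expect_true(!st$converged || st$fluxes["GROWTH"] * 3600 < 0.05)
  expect_s3_class(st, "steady_state")   # failure is a flag, not an exception
})

test_that("strictly positive initial guesses are required", {
  m <- ref_model()
  x0 <- setNames(m$species$conc, m$species$id)
  x0["PYR"] <- 0
  expect_error(steady_state(m, initial_guess = x0), "strictly positive")
})
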