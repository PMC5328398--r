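# Stoichiometric model, uniform flux-space sampling, envelopes.

test_that("the stoichiometric model keeps every kinetic reaction", {
  m <- ref_model()
  sm <- to_stoichiometric(m)
  expect_equal(ncol(sm$S), 68L)
  # the kinetic reference flux vector satisfies the stoichiometric constraints
  v_ref <- attr(m, "reference_fluxes")
  expect_lt(max(abs(sm$S %*% v_ref)), 1e-10)
  # reversibility follows the rate-law family
  expect_true(sm$reversible[["PGI"]])
  expect_true(sm$reversible[["ATP_SYN"]])
  expect_false(sm$reversible[["PFK"]])
  expect_false(sm$reversible[["GROWTH"]])
  expect_true(all(sm$lb[!sm$reversible] == 0))
  m_empty <- m
  m_empty$reactions <- list()
  expect_error(to_stoichiometric(m_empty), "empty")
})

test_that("hit-and-run sampling is uniform on the probability simplex", {
  pt <- flux_polytope(matrix(1, 1, 3), 1, rep(0, 3), rep(1, 3))
  sm <- sample_flux_space(pt, 10000, seed = 5)
  # analytic moments of the uniform 2-simplex: mean 1/3 per coordinate
  expect_equal(unname(colMeans(sm)), rep(1 / 3, 3), tolerance = 0.02)
  # every sample satisfies the constraints
  expect_lt(max(abs(rowSums(sm) - 1)), 1e-9)
  expect_true(all(sm >= -1e-9 & sm <= 1 + 1e-9))
})

test_that("chain restarts with different seeds agree within Monte-Carlo error", {
  m <- ref_model()
  sm <- to_stoichiometric(m)
  s1 <- sample_flux_space(sm, 300, seed = 1)
  s2 <- sample_flux_space(sm, 300, seed = 99)
  # summary statistics are exchangeable across restarts
  r1 <- colMeans(s1) / (sm$ub - sm$lb)
  r2 <- colMeans(s2) / (sm$ub - sm$lb)
  expect_lt(stats::median(abs(r1 - r2)), 0.1)
  # constraint membership
  expect_lt(max(abs(sm$S %*% t(s1))), 1e-9)
})

test_that("kinetic steady states lie inside the stoichiometric polytope", {
  ens <- small_ensemble()
  m <- ref_model()
  sm <- to_stoichiometric(m, cap_factor = 1e3)
  ok <- which(ens$converged)[1:10]
  for (i in ok) {
    v <- ens$fluxes[i, ]
    # residual bound follows from the ensemble solver tolerance
    # (atol 1e-8 + rtol 1e-6 per species, volume-scaled)
    tol <- 1e-7 + 1e-6 * max(ens$concentrations[i, ])
    expect_lt(max(abs(sm$S %*% v)), tol)
  }
})

test_that("LP envelopes recover the vertices of a toy triangle", {
  pt <- flux_polytope(matrix(1, 1, 3), 1, rep(0, 3), rep(1, 3))
  env <- stoichiometric_boundaries(pt, list(c(1, 0, 0), c(0, 1, 0)),
                                   grid = c(0, 0.25, 1, 1.4))
  expect_equal(env$y_min[env$feasible], c(0, 0, 0))
  expect_equal(env$y_max[1:3], c(1, 0.75, 0), tolerance = 1e-9)
  expect_false(env$feasible[4])   # outside the simplex: flagged, no error
})

test_that("maximal growth is non-decreasing in glucose uptake near zero uptake", {
  m <- ref_model()
  sm <- to_stoichiometric(m)
  env <- stoichiometric_boundaries(sm, list("PTS4", "GROWTH"),
                                   grid = c(0.05, 0.2, 0.5) * max(sm$ub["PTS4"]))
  expect_true(all(env$feasible))
  expect_true(all(diff(env$y_max) >= -1e-9))
})

test_that("the kinetic envelope of a controllable toy matches an exhaustive scan", {
  # two-step mass-action chain: with factors (f_feed, f1) in [0.1, 10]^2,
  # pinning M1 = flux/(k f1) at its reference value leaves the chain flux
  # free over f1 in [0.1, 10]; an exhaustive factor scan is the oracle
  tc <- make_toy_chain(2, feed = 1, k = 2)
  m <- tc$model
  conc_m1 <- function(st) unname(st$concentrations["M1"])
  flux_out <- function(st) unname(st$fluxes["STEP1"])
  grid_f <- 10^seq(-1, 1, length.out = 15)
  pts <- expand.grid(ff = grid_f, f1 = grid_f)
  vals <- t(apply(pts, 1, function(p) {
    st <- steady_state(m, scale = c(FEED = p[1], STEP1 = p[2]))
    c(conc_m1(st), flux_out(st))
  }))
  target <- 0.5   # the reference M1
  near <- abs(vals[, 1] - target) / target <= 0.05
  env <- kinetic_boundaries(m, list(conc_m1, flux_out), grid = target,
                            pin_tol = 0.05, n_particles = 15, iters = 25,
                            seed = 2, glucose_mM = NULL)
  expect_true(env$pinned[1])
  expect_gte(env$y_max[1], max(vals[near, 2]) * 0.8)
  expect_lte(env$y_min[1], min(vals[near, 2]) * 1.2)
})
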