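# Synthetic-data generators: toys, calibration datasets, validation tables.

test_that("toy chain closed forms satisfy the model's own residual check", {
  tc <- make_toy_chain(2, feed = 1, k = c(2))
  expect_equal(unname(tc$steady_state$concentrations["M1"]), 0.5)
  for (spec in list(make_toy_chain(5, forms = "mm", feed = 0.7, vmax = 2, km = 0.3),
                    make_toy_branch(feed = 2, k_a = 1, k_b = 4),
                    make_toy_cycle(feed = 0.5, k2 = 3, k3 = 1, c_total = 1.5))) {
    r <- colikin:::steady_residual(spec$model,
                                   spec$steady_state$concentrations[
                                     spec$model$species$id],
                                   rep(1, length(spec$model$reactions)))
    expect_lt(max(abs(r$dx)), 1e-10)
    # numerical solver agrees with the closed form to 1e-8; the start point
    # is perturbed within the analytic state's conserved-moiety class
    g <- moiety_preserving_perturbation(spec)
    st <- steady_state(spec$model, initial_guess = g,
                       atol = 1e-12, rtol = 1e-10)
    expect_equal(st$concentrations,
                 spec$steady_state$concentrations[spec$model$species$id],
                 tolerance = 1e-8)
  }
  expect_error(make_toy_chain(1), "n_steps")
  expect_error(make_toy_chain(3, forms = "hill"), "unsupported")
  expect_error(make_toy_chain(2, forms = "mm", feed = 2, vmax = 1), "Vmax")
})

test_that("the summation theorem holds on a saturable toy chain", {
  cm <- control_coefficients(toy_chain5()$model)
  expect_equal(unname(rowSums(cm$C_J)), rep(1, 5), tolerance = 0.01)
})

test_that("calibration datasets are seeded and honest about their noise", {
  tc <- make_toy_chain(3, forms = "mm", feed = 1, vmax = 3, km = 0.8)
  m <- tc$model
  d1 <- make_calibration_data(m, c("conc:M1", "conc:M2"), noise_sigma = 0.05,
                              seed = 17)
  d2 <- make_calibration_data(m, c("conc:M1", "conc:M2"), noise_sigma = 0.05,
                              seed = 17)
  expect_identical(d1, d2)
  d0 <- make_calibration_data(m, c("conc:M1", "conc:M2"), noise_sigma = 0)
  expect_equal(calibration_objective(m$params, m, d0), 0, tolerance = 1e-6)
  expect_true(all(d1$sigma > 0))
})

test_that("time-course calibration data follow the simulated trajectories", {
  iso <- make_reversible_pair(kf = 1, kr = 0.5)
  ds <- make_calibration_data(iso$model, "conc:A", times = c(0.5, 1, 2),
                              noise_sigma = 0)
  expect_equal(ds$value, iso$analytic(ds$time), tolerance = 1e-5)
})

test_that("validation tables subsample the ensemble with lognormal noise", {
  ens <- small_ensemble()
  n_ok <- sum(ens$converged)
  vt0 <- make_validation_table(ens, n_rows = 20, noise_sigma = 0, seed = 9)
  # zero noise: rows are exact ensemble states, inside the observed ranges
  rng <- range(ens$fluxes[ens$converged, "GROWTH"] * 3600)
  expect_true(all(vt0$growth_rate >= rng[1] & vt0$growth_rate <= rng[2]))
  # 10% noise preserves the growth ranking (same seed: same subsample)
  vt1 <- make_validation_table(ens, n_rows = 20, noise_sigma = 0.1, seed = 9)
  expect_gt(cor(vt0$growth_rate, vt1$growth_rate, method = "spearman"), 0.9)
  expect_error(make_validation_table(ens, n_rows = n_ok + 1), "converged")
})

test_that("dataset TSV files round-trip including their conditions", {
  tc <- make_toy_chain(3, forms = "mm", feed = 1, vmax = 3, km = 0.8)
  conds <- list(ref = list(), up = list(scale = c(FEED = 1.5)))
  ds <- make_calibration_data(tc$model, c("conc:M1", "flux:STEP2"), conds,
                              noise_sigma = 0.05, seed = 2)
  path <- tempfile(fileext = ".tsv")
  write_dataset_tsv(ds, path)
  back <- read_dataset_tsv(path)
  expect_equal(back$value, ds$value, tolerance = 1e-12)
  expect_equal(back$sigma, ds$sigma, tolerance = 1e-12)
  expect_equal(back$observable, ds$observable)
  cb <- attr(back, "conditions")
  expect_equal(cb$up$scale[["FEED"]], 1.5)
})
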