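# Metabolic control analysis: finite differences, summation theorems,
# overall controls, robustness sampling.

test_that("control coefficients match a brute-force secant oracle on a toy chain", {
  t5 <- toy_chain5()
  cm <- control_coefficients(t5$model)
  # independent oracle: two-sided secant at +-1% capacity, solved separately
  h_big <- log(1.01)
  m <- t5$model
  ref <- steady_state(m, atol = 1e-12, rtol = 1e-10)
  rn <- names(m$reactions)
  for (j in seq_along(rn)) {
    sc_p <- rep(1, length(rn)); sc_p[j] <- 1.01
    sc_m <- rep(1, length(rn)); sc_m[j] <- 1 / 1.01
    st_p <- steady_state(m, ref$concentrations, scale = sc_p,
                         atol = 1e-12, rtol = 1e-10)
    st_m <- steady_state(m, ref$concentrations, scale = sc_m,
                         atol = 1e-12, rtol = 1e-10)
    oracle <- (st_p$fluxes - st_m$fluxes) / (2 * h_big * ref$fluxes)
    big <- abs(oracle) > 0.05
    if (any(big)) {
      expect_equal(unname(cm$C_J[big, j]), unname(oracle[big]),
                   tolerance = 0.02)
    }
  }
})

test_that("summation theorems hold on the toy chain", {
  cm <- control_coefficients(toy_chain5()$model)
  expect_equal(unname(rowSums(cm$C_J)), rep(1, nrow(cm$C_J)), tolerance = 0.01)
  expect_equal(unname(rowSums(cm$C_M)), rep(0, nrow(cm$C_M)), tolerance = 0.01)
})

test_that("control coefficients are invariant under a common capacity rescaling", {
  # scaling every rate by a common factor rescales time only: same scaled
  # control coefficients
  t5 <- toy_chain5()
  m2 <- t5$model
  m2$params <- m2$params * ifelse(grepl("Vmax$|kf$", names(m2$params)), 2.7, 1)
  cm1 <- control_coefficients(t5$model)
  cm2 <- control_coefficients(m2)
  expect_equal(cm1$C_J, cm2$C_J, tolerance = 1e-6)
  expect_equal(cm1$C_M, cm2$C_M, tolerance = 1e-5)
})

test_that("overall control is the L2 norm of the coefficient columns", {
  cm <- ref_mca()
  oc <- overall_control(cm)
  j <- match("ZWF", oc$step)
  expect_equal(oc$CJ[j], sqrt(sum(cm$C_J[, "ZWF"]^2, na.rm = TRUE)))
  # trivial columns
  fake <- cm
  fake$C_J[, "ZWF"] <- 0
  fake$C_M[, "ZWF"] <- 0
  oc0 <- overall_control(fake)
  expect_equal(oc0$CJ[j], 0)
  fake$C_J[, "ZWF"] <- c(-0.4, rep(0, nrow(fake$C_J) - 1))
  expect_equal(overall_control(fake)$CJ[j], 0.4)
})

test_that("control summary computes the headline fractions and correlation", {
  cm <- ref_mca()
  oc <- overall_control(cm)
  sm <- control_summary(oc, cm)
  expect_true(sm$frac_enzyme_flux_cc_small > 0.5 &&
                sm$frac_enzyme_flux_cc_small <= 1)
  expect_true(sm$frac_env_flux_cc_large >= 0 && sm$frac_env_flux_cc_large <= 1)
  expect_true(abs(sm$pearson_overall) <= 1)
  # identical CJ and CC give Pearson exactly 1
  oc_id <- data.frame(step = oc$step, CJ = oc$CJ, CC = oc$CJ)
  expect_equal(control_summary(oc_id, cm)$pearson_overall, 1)
  expect_error(control_summary(oc[1:2, ], cm), "3 steps")
})

test_that("zero-spread robustness reproduces the reference overall control", {
  t5 <- toy_chain5()
  rb <- control_robustness(t5$model, n_samples = 3, spread = 0, seed = 5)
  oc <- overall_control(control_coefficients(t5$model))
  for (i in 1:3) {
    expect_equal(unname(rb$CJ[i, ]), oc$CJ, tolerance = 1e-8)
  }
  expect_equal(rb$n_failed, 0L)
})

test_that("robustness sampling reports finite per-step quantiles and is seeded", {
  t5 <- toy_chain5()
  rb1 <- control_robustness(t5$model, n_samples = 8, spread = 0.2, seed = 42)
  rb2 <- control_robustness(t5$model, n_samples = 8, spread = 0.2, seed = 42)
  expect_equal(rb1$CJ, rb2$CJ)
  expect_true(all(is.finite(rb1$quantiles)))
  # the feed retains the largest median overall flux control on the chain
  med <- rb1$quantiles["50%", ]
  expect_equal(names(which.max(med)), "FEED")
})
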