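# Model container, reference-instance census, structural checks, compiled
# evaluators.

test_that("reference instance matches the documented census", {
  m <- ref_model()
  expect_equal(nrow(m$compartments), 3L)
  expect_equal(nrow(m$species), 62L)
  expect_equal(length(m$reactions), 68L)
  cen <- interaction_census(m)
  expect_equal(cen$total, 255L)
  expect_equal(cen$modifier_only, 34L)
  # periplasm at 20% of total cell volume: V_peri / (V_peri + V_cyto) = 0.2
  vols <- setNames(m$compartments$volume, m$compartments$id)
  expect_equal(unname(vols["periplasm"] / (vols["periplasm"] + vols["cytoplasm"])),
               0.2)
})

test_that("stoichiometric matrix columns match reaction stoichiometries", {
  m <- ref_model()
  for (rid in sample(names(m$reactions), 10)) {
    r <- m$reactions[[rid]]
    col <- m$S[, rid]
    expect_equal(col[names(r$stoich)], r$stoich)
    expect_true(all(col[setdiff(rownames(m$S), names(r$stoich))] == 0))
  }
})

test_that("every declared parameter appears in its rate law and vice versa", {
  m <- ref_model()
  sp <- m$species$id
  for (r in m$reactions) {
    used <- all.vars(r$expr)
    declared <- paste0(r$id, ".", r$params)
    expect_setequal(setdiff(used, sp), declared)
    # modifiers are exactly the law's species that are not in the stoichiometry
    expect_setequal(r$modifiers, setdiff(intersect(used, sp), names(r$stoich)))
  }
})

test_that("structural linter rejects inconsistent models", {
  comp <- data.frame(id = "cytoplasm", volume = 1, kind = "cytoplasm")
  sp <- data.frame(id = "A", compartment = "cytoplasm", conc = 1, boundary = FALSE)
  law <- list(form = "constant", params = "Vmax", expr = quote(`R1.Vmax`))
  expect_error(new_reaction("R1", c(A = 0), law), "nonzero")
  expect_error(
    kinetic_model("bad", comp, sp,
                  list(new_reaction("R1", c(B = 1), law)),
                  c(R1.Vmax = 1)),
    "unknown species")
  law_bad <- list(form = "constant", params = c("Vmax", "Km_A"),
                  expr = quote(`R1.Vmax`))
  expect_error(
    kinetic_model("bad", comp, sp,
                  list(new_reaction("R1", c(A = 1), law_bad)),
                  c(R1.Vmax = 1, R1.Km_A = 1)),
    "absent from its rate law")
  expect_error(
    kinetic_model("bad", comp, sp,
                  list(new_reaction("R1", c(A = 1), law)),
                  c(R1.Vmax = -2)),
    "Vmax")
})

test_that("compiled C evaluator agrees with the generated R evaluator", {
  m <- ref_model()
  f_c <- colikin:::model_rate_fn(m)
  f_r <- colikin:::compile_rates_r(m)
  set.seed(4)
  for (k in 1:5) {
    x <- setNames(m$species$conc * 10^runif(62, -1, 1), m$species$id)
    vc <- f_c(x, m$params, 1)
    vr <- f_r(x, m$params, 1)
    expect_equal(as.numeric(vc), as.numeric(vr), tolerance = 1e-12)
  }
})

test_that("analytic rate Jacobian matches finite differences", {
  m <- ref_model()
  x <- setNames(m$species$conc, m$species$id)
  Ja <- colikin:::rate_jacobian(m, x, 1)
  m2 <- m
  attr(m2, ".jac_sym") <- NULL
  Jf <- colikin:::rate_jacobian(m2, x, 1)
  expect_lt(max(abs(Ja - Jf)) / max(abs(Ja)), 1e-4)
})

test_that("evaluate_rates is deterministic and validates its input", {
  m <- ref_model()
  x <- setNames(m$species$conc, m$species$id)
  v1 <- evaluate_rates(m, x)
  expect_identical(v1, evaluate_rates(m, x))
  expect_equal(unname(evaluate_rates(m, x, scale = 0)), rep(0, 68))
  x_bad <- x; x_bad["ATP"] <- -1
  expect_error(evaluate_rates(m, x_bad), "non-negative")
  expect_error(evaluate_rates(m, x[-1]), "missing")
})

test_that("reference rates reproduce the designed steady-state fluxes", {
  m <- ref_model()
  v <- evaluate_rates(m, setNames(m$species$conc, m$species$id))
  v_ref <- attr(m, "reference_fluxes")
  expect_equal(unname(v), unname(v_ref[names(v)]), tolerance = 1e-10)
  # toy two-step chain: both rates equal at the analytic steady state
  tc <- make_toy_chain(2, feed = 1, k = 2)
  vt <- evaluate_rates(tc$model, tc$steady_state$concentrations)
  expect_equal(unname(vt[1]), unname(vt[2]), tolerance = 1e-12)
})

test_that("conserved moieties are found from the null space, not assumed", {
  m <- ref_model()
  C <- moiety_matrix(m)
  expect_equal(ncol(C), 10L)   # adenylate, NAD, NADP, FAD, Q, CoA, 4 PTS pairs
  # the adenylate indicator is a conservation relation: c' (S/V)_dyn = 0
  dyn <- !m$species$boundary
  M <- (m$S / colikin:::species_volumes(m))[dyn, ]
  aden <- as.numeric(m$species$id[dyn] %in% c("ATP", "ADP", "AMP", "CAMP"))
  expect_lt(max(abs(aden %*% M)), 1e-10)
  # and it lies in the span of the computed moiety basis
  resid <- aden - C %*% crossprod(C, aden)
  expect_lt(max(abs(resid)), 1e-8)
})
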