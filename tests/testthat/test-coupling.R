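# Systemic variables, Spearman / mutual-information couplings, homeostasis.

test_that("systemic variables are complete and internally consistent", {
  ens <- small_ensemble()
  sv <- systemic_variables(ens)
  expect_equal(nrow(sv), sum(ens$converged))
  expect_true(all(c("growth_rate", "glc_uptake", "o2_uptake", "atp_production",
                    "nadh_production", "nadph_production", "biomass_yield",
                    "atp_yield", "sum_flux", "enzyme_cost", "total_pool",
                    "tca_rel") %in% names(sv)))
  # yields are rate / glucose uptake
  expect_equal(sv$atp_yield, sv$atp_production / sv$glc_uptake)
  # the sum of |fluxes| dominates any single intracellular flux
  expect_true(all(sv$sum_flux >= abs(sv$tca_flux)))
})

test_that("a degenerate all-ones ensemble gives identical variable rows", {
  m <- ref_model()
  ens <- ensemble_steady_states(m, sample_enzyme_levels(m, 3, lo = 1, hi = 1))
  sv <- systemic_variables(ens)
  for (cl in names(sv)) {
    expect_equal(diff(range(sv[[cl]])), 0, tolerance = 1e-6)
  }
})

test_that("gross cofactor production equals the hand-computed producing sum", {
  ty <- make_toy_cycle(feed = 1, k2 = 5, k3 = 2, c_total = 2)
  st <- steady_state(ty$model)
  # 'D' is produced only by USE, at the feed flux
  S <- ty$model$S
  prod_d <- sum(pmax(S["D", ] * st$fluxes, 0))
  expect_equal(prod_d, 1, tolerance = 1e-8)
})

test_that("enzyme cost sums factor * concentration * length with 18 uM default", {
  conc <- c(R1 = 10, R2 = NA)
  aa <- c(R1 = 400, R2 = 250)
  expect_equal(enzyme_cost(c(R1 = 1, R2 = 1), conc, aa), 10 * 400 + 18 * 250)
  expect_equal(enzyme_cost(c(R1 = 2, R2 = 0.5), conc, aa),
               2 * 10 * 400 + 0.5 * 18 * 250)
  expect_equal(enzyme_cost(c(R1 = 0, R2 = 0), conc, aa), 0)
  expect_error(enzyme_cost(c(R1 = -1, R2 = 1), conc, aa), ">= 0")
})

test_that("Spearman correlation is invariant under monotone transforms", {
  set.seed(31)
  df <- data.frame(a = rexp(200))
  df$b <- log(df$a)          # strictly monotone transform
  df$c <- rnorm(200)
  rho <- spearman_matrix(df)
  expect_equal(rho["a", "b"], 1)
  expect_lt(abs(rho["a", "c"]), 0.2)
  expect_equal(rho, t(rho))
  expect_error(spearman_matrix(df[1:5, ]), "10 rows")
})

test_that("independent columns have near-zero rank correlation at n = 10000", {
  set.seed(32)
  df <- data.frame(x = rnorm(10000), y = runif(10000))
  rho <- spearman_matrix(df)
  expect_lt(abs(rho["x", "y"]), 0.05)
})

test_that("mutual information hits its identity and independence limits", {
  set.seed(33)
  n <- 3000
  x <- rnorm(n)
  df <- data.frame(x = x, same = 2 * x + 5, indep = runif(n))
  res <- mutual_information_matrix(df, n_bins = 8)
  # identical columns with equal-frequency bins: MI = marginal entropy = log(bins)
  expect_equal(res$mi["x", "same"], log(8), tolerance = 0.01)
  expect_equal(res$mi["x", "x"], log(8), tolerance = 0.01)
  # independent columns: MI below the plug-in bias bound ~ (bins-1)^2 / (2n)
  expect_lt(res$mi["x", "indep"], (8 - 1)^2 / (2 * n) * 3)
  expect_equal(res$mi, t(res$mi))
  expect_true(all(res$mi >= 0))
})

test_that("mutual information is invariant under joint row relabeling", {
  set.seed(34)
  df <- data.frame(a = rnorm(500), b = rnorm(500))
  df$b <- df$a + 0.5 * df$b
  perm <- sample(500)
  m1 <- mutual_information_matrix(df, n_bins = 5)$mi
  m2 <- mutual_information_matrix(df[perm, ], n_bins = 5)$mi
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("strong Spearman couplings sit high in the mutual-information ranking", {
  ens <- small_ensemble()
  sv <- systemic_variables(ens)
  keep <- vapply(sv, function(col) all(is.finite(col)), TRUE)
  sv <- sv[, keep]
  rho <- spearman_matrix(sv)
  mi <- mutual_information_matrix(sv)$mi
  ut <- upper.tri(rho)
  strong <- which(abs(rho[ut]) > 0.85)
  if (length(strong)) {
    mi_vals <- mi[ut]
    thresh <- stats::quantile(mi_vals, 0.75)
    expect_gt(mean(mi_vals[strong] >= thresh), 0.6)
  }
})

test_that("homeostasis summary reports the k-fold fraction and is monotone in k", {
  # single state at the reference: fraction is 1
  hs1 <- homeostasis_summary(47, reference_total_mM = 47, k = 3)
  expect_equal(hs1$fraction_within, 1)
  totals <- c(10, 20, 47, 90, 200, 500)
  f3 <- homeostasis_summary(totals, 47, k = 3)$fraction_within
  f5 <- homeostasis_summary(totals, 47, k = 5)$fraction_within
  f10 <- homeostasis_summary(totals, 47, k = 10)$fraction_within
  expect_true(f3 <= f5 && f5 <= f10)
  # ensemble path: totals match the concentration sums
  ens <- small_ensemble()
  hs <- homeostasis_summary(ens)
  expect_equal(length(hs$totals), sum(ens$converged))
  expect_equal(hs$reference_total,
               sum(ref_model()$species$conc[
                 ref_model()$species$compartment == "cytoplasm" &
                   !ref_model()$species$id %in% attr(ref_model(), "enzyme_species")]))
  expect_equal(max(hs$cumulative$freq), 1)
})
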