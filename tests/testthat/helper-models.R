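# Shared fixtures, built once per run and memoized.  Everything is generated
# in code; there are no stored binary fixtures.

# several acceptance checks compare against published-instance values and can
# fail together on the synthetic instance; always run the whole suite
options(testthat.progress.max_fails = Inf)

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

ref_model <- function() memo("model", function() ecoli_reference_model())

ref_steady <- function() memo("steady", function()
  steady_state(ref_model(), atol = 1e-12, rtol = 1e-10))

ref_mca <- function() memo("mca", function()
  control_coefficients(ref_model(), reference = ref_steady()))

small_ensemble <- function() memo("ensemble", function() {
  m <- ref_model()
  ensemble_steady_states(m, sample_enzyme_levels(m, 60, seed = 11))
})

# five-step saturable toy chain used by several MCA tests
toy_chain5 <- function() memo("chain5", function()
  make_toy_chain(5, forms = "mm", feed = 1, vmax = 3, km = 0.8))

# perturb a toy's analytic steady state without leaving its conserved-moiety
# class (project the perturbation onto the reachable subspace)
moiety_preserving_perturbation <- function(spec, factor = 1.8) {
  m <- spec$model
  x <- spec$steady_state$concentrations[m$species$id]
  g <- x * factor
  C <- moiety_matrix(m)
  dyn <- !m$species$boundary
  if (ncol(C)) {
    g[dyn] <- g[dyn] + as.numeric(C %*% crossprod(C, x[dyn] - g[dyn]))
  }
  pmax(g, 1e-6)
}
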