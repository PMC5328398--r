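# Exploration of the kinetic solution space with random enzyme levels.
#
# Enzyme levels (Vmax of every enzymatic step) are scaled by independent
# log-uniform factors in [0.1, 10] -- each order of magnitude sampled in
# equal proportion -- and the corresponding steady states are solved under
# excess glucose.  Non-converged samples are flagged and counted, never
# silently dropped; downstream statistics use the converged subset.

#' Sample random enzyme-level scale factors
#'
#' Draws independent per-reaction factors from a log-uniform distribution on
#' `[lo, hi]` (base-10 uniform in the exponent).  Steps listed in
#' `fixed_steps` (by default the model's non-enzymatic steps: nutrient feed,
#' washout, gas transfer, spontaneous hydrolysis, membrane leak) keep factor
#' 1.  The whole factor matrix is drawn up front from the seed, so results
#' do not depend on how the subsequent solves are scheduled.
#'
#' @param model a `kinetic_model` (or an integer number of reactions)
#' @param n number of samples
#' @param lo,hi factor bounds, `0 < lo < hi`
#' @param seed integer seed
#' @param fixed_steps reaction ids kept at factor 1
#' @return matrix `n x n_reactions` of scale factors, with reaction-id
#'   column names and attributes `seed`, `lo`, `hi`
#' @export
sample_enzyme_levels <- function(model, n, lo = 0.1, hi = 10, seed = 1,
                                 fixed_steps = non_enzymatic_steps(model)) {
  if (!(lo > 0 && lo <= hi)) stop("need 0 < lo <= hi", call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  rn <- if (is.numeric(model)) paste0("R", seq_len(model)) else names(model$reactions)
  set.seed(seed)
  f <- matrix(10^stats::runif(n * length(rn), log10(lo), log10(hi)),
              nrow = n, dimnames = list(NULL, rn))
  f[, colnames(f) %in% fixed_steps] <- 1
  structure(f, seed = seed, lo = lo, hi = hi)
}

# non-enzymatic steps of a model (attribute set by the reference builder)
non_enzymatic_steps <- function(model) {
  if (is.numeric(model)) return(character(0))
  ns <- attr(model, "non_enzymatic_steps")
  if (is.null(ns)) character(0) else ns
}

#' Solve the steady-state ensemble for sampled enzyme levels
#'
#' For each row of `samples`, the model with scaled enzyme capacities is
#' solved to steady state under excess glucose (extracellular glucose fixed
#' at `glucose_mM`).  Every sample is recorded with its convergence flag.
#'
#' @param model a `kinetic_model` (the reference condition; the excess
#'   glucose boundary is applied internally)
#' @param samples factor matrix from [sample_enzyme_levels()]
#' @param glucose_mM fixed extracellular glucose (mM)
#' @param atol,rtol steady-state tolerances
#' @param progress print a dot every 50 samples
#' @return object of class `ensemble_result`: list with `factors`,
#'   `concentrations` (n x species), `fluxes` (n x reactions), `converged`
#'   (logical), `condition`, `model`
#' @export
ensemble_steady_states <- function(model, samples, glucose_mM = 10,
                                   atol = 1e-8, rtol = 1e-6, progress = FALSE) {
  mg <- with_excess_glucose(model, glucose_mM)
  base <- steady_state(mg, atol = atol, rtol = rtol)
  if (!base$converged) stop("base excess-glucose steady state did not converge",
                            call. = FALSE)
  n <- nrow(samples)
  sp <- mg$species$id
  rn <- names(mg$reactions)
  conc <- matrix(NA_real_, n, length(sp), dimnames = list(NULL, sp))
  flux <- matrix(NA_real_, n, length(rn), dimnames = list(NULL, rn))
  conv <- logical(n)
  for (i in seq_len(n)) {
    st <- steady_state(mg, initial_guess = base$concentrations,
                       scale = samples[i, ], atol = atol, rtol = rtol,
                       max_iter = 30L)
    conv[i] <- st$converged
    conc[i, ] <- st$concentrations
    flux[i, ] <- st$fluxes
    if (progress && i %% 50 == 0) cat(".")
  }
  if (progress) cat("\n")
  if (mean(conv) < 0.1) {
    stop("ensemble failed: only ", sum(conv), "/", n, " samples converged",
         call. = FALSE)
  }
  structure(list(factors = samples, concentrations = conc, fluxes = flux,
                 converged = conv, condition = list(glucose_mM = glucose_mM),
                 model = mg),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat("<ensemble_result> ", nrow(x$factors), " samples, ",
      sum(x$converged), " converged (",
      round(100 * mean(x$converged), 1), "%), glucose ",
      x$condition$glucose_mM, " mM\n", sep = "")
  invisible(x)
}

#' Write an ensemble to a TSV file
#'
#' One row per sample: scale factors, convergence flag, all fluxes and all
#' concentrations.  Units: mM and mM/s (cytoplasm basis).
#'
#' @param ensemble an `ensemble_result`
#' @param path output file
#' @return invisibly, the path
#' @export
write_ensemble_tsv <- function(ensemble, path) {
  df <- data.frame(
    sample = seq_len(nrow(ensemble$factors)),
    converged = ensemble$converged,
    setNames(as.data.frame(ensemble$factors),
             paste0("factor.", colnames(ensemble$factors))),
    setNames(as.data.frame(ensemble$fluxes),
             paste0("flux.", colnames(ensemble$fluxes))),
    setNames(as.data.frame(ensemble$concentrations),
             paste0("conc.", colnames(ensemble$concentrations))),
    check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# colikin ensemble: factors dimensionless, fluxes mM/s (cytoplasm basis), concentrations mM", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
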