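# Metabolic control analysis by finite differences.
#
# Scaled flux control coefficients C^J_E = d ln J / d ln E and concentration
# control coefficients C^M_E = d ln M / d ln E quantify the fractional
# response of every steady-state flux and metabolite pool to a fractional
# change in the capacity of one step.  They are computed by central
# differences on ln E: the steady state is re-solved with step E scaled by
# exp(+-h) and the scaled difference (J(+h) - J(-h)) / (2 h J_ref) is taken
# (identical to the log-derivative to first order, but well defined when a
# small net flux changes sign inside the bracket).  The summation theorems
# (flux rows sum to 1, concentration rows to 0) double as a validation of
# the differencing step and solver precision.

#' Flux and concentration control coefficients
#'
#' @param model a `kinetic_model`
#' @param reference optional converged `steady_state` to linearize around
#'   (computed at tight tolerance if missing)
#' @param perturbation relative step h on ln E (default 1e-3)
#' @param flux_tol fluxes with `|J_ref|` below this (mM/s) are excluded from
#'   `C_J` (scaled control of a zero flux is undefined); exclusions are
#'   reported in the result
#' @param atol,rtol solver tolerances for the perturbed steady states;
#'   defaults much tighter than for plain simulation because the differences
#'   divide by `2 h`
#' @return object of class `control_matrices`: list with `C_J` (flux x
#'   step), `C_M` (metabolite x step; dynamic species), `reference`,
#'   `excluded_fluxes`, `failed_steps`, `perturbation`
#' @export
control_coefficients <- function(model, reference = NULL, perturbation = 1e-3,
                                 flux_tol = 1e-12, atol = 1e-12, rtol = 1e-10) {
  if (is.null(reference)) {
    reference <- steady_state(model, atol = atol, rtol = rtol)
  }
  if (!reference$converged) stop("reference steady state not converged", call. = FALSE)
  h <- perturbation
  rn <- names(model$reactions)
  n_rxn <- length(rn)
  dyn <- !model$species$boundary
  mets <- model$species$id[dyn]
  x_ref <- reference$concentrations[dyn]
  J_ref <- reference$fluxes

  keep_flux <- abs(J_ref) > flux_tol
  C_J <- matrix(NA_real_, n_rxn, n_rxn, dimnames = list(rn, rn))
  C_M <- matrix(NA_real_, length(mets), n_rxn, dimnames = list(mets, rn))
  failed <- character(0)

  solve_pert <- function(scale_vec, hh) {
    st <- steady_state(model, initial_guess = reference$concentrations,
                       scale = scale_vec, fallback = FALSE,
                       atol = atol, rtol = rtol)
    if (!st$converged) {
      st <- steady_state(model, initial_guess = reference$concentrations,
                         scale = scale_vec, fallback = TRUE,
                         atol = atol, rtol = rtol)
    }
    st
  }

  for (j in seq_len(n_rxn)) {
    hh <- h
    done <- FALSE
    for (attempt in 1:2) {
      sc_p <- rep(1, n_rxn); sc_p[j] <- exp(hh)
      sc_m <- rep(1, n_rxn); sc_m[j] <- exp(-hh)
      st_p <- solve_pert(sc_p, hh)
      st_m <- solve_pert(sc_m, hh)
      if (st_p$converged && st_m$converged) {
        C_J[, j] <- (st_p$fluxes - st_m$fluxes) / (2 * hh * J_ref)
        C_M[, j] <- (st_p$concentrations[dyn] - st_m$concentrations[dyn]) /
          (2 * hh * x_ref)
        done <- TRUE
        break
      }
      hh <- hh / 2   # retry with halved step
    }
    if (!done) failed <- c(failed, rn[j])
  }
  C_J[!keep_flux, ] <- NA_real_

  structure(list(C_J = C_J, C_M = C_M, reference = reference,
                 excluded_fluxes = rn[!keep_flux], failed_steps = failed,
                 perturbation = h),
            class = "control_matrices")
}

#' @export
print.control_matrices <- function(x, ...) {
  cat("<control_matrices> ", nrow(x$C_J), " fluxes x ", ncol(x$C_J),
      " steps; ", nrow(x$C_M), " metabolites\n", sep = "")
  rs <- rowSums(x$C_J, na.rm = FALSE)
  cat("  flux summation residual (max |sum - 1|): ",
      format(max(abs(rs - 1), na.rm = TRUE), digits = 3), "\n", sep = "")
  invisible(x)
}

#' Overall control exerted by each step
#'
#' The overall flux control of step E is the L2 norm of all its flux control
#' coefficients (column E of `C_J`), and likewise for concentrations: a
#' one-number summary of the system-wide influence of each step.
#'
#' @param matrices a `control_matrices` object
#' @return data.frame with columns `step`, `CJ` (overall flux control), `CC`
#'   (overall concentration control)
#' @export
overall_control <- function(matrices) {
  cj <- apply(matrices$C_J, 2, function(col) sqrt(sum(col^2, na.rm = TRUE)))
  cc <- apply(matrices$C_M, 2, function(col) sqrt(sum(col^2, na.rm = TRUE)))
  data.frame(step = colnames(matrices$C_J), CJ = unname(cj), CC = unname(cc))
}

#' Summary statistics of the control structure
#'
#' Computes the distributional summaries used to describe how control is
#' shared between the enzymes and the environment: the fraction of enzyme
#' flux (and concentration) control coefficients within `[-band, band]`, the
#' fraction of the environment step's coefficients above `band`, and the
#' Pearson correlation between the overall flux and concentration controls
#' across steps.
#'
#' @param overall output of [overall_control()]
#' @param matrices the `control_matrices` the summary refers to
#' @param environment_step id of the environment (nutrient supply) step;
#'   all other steps count as enzymes
#' @param band coefficient magnitude defining "low control" (default 0.3)
#' @return list with `frac_enzyme_flux_cc_small`, `frac_env_flux_cc_large`,
#'   `frac_enzyme_conc_cc_small`, `frac_env_conc_cc_large`,
#'   `pearson_overall` and `pearson_p`
#' @export
control_summary <- function(overall, matrices, environment_step = "GLC_FEED",
                            band = 0.3) {
  if (nrow(overall) < 3) stop("need at least 3 steps for the correlation", call. = FALSE)
  steps <- colnames(matrices$C_J)
  enz <- setdiff(steps, environment_step)
  cj_enz <- matrices$C_J[, enz, drop = FALSE]
  cm_enz <- matrices$C_M[, enz, drop = FALSE]
  env_in <- environment_step %in% steps
  ct <- stats::cor.test(overall$CJ, overall$CC, method = "pearson")
  list(
    frac_enzyme_flux_cc_small = mean(abs(cj_enz) <= band, na.rm = TRUE),
    frac_env_flux_cc_large = if (env_in)
      mean(matrices$C_J[, environment_step] > band, na.rm = TRUE) else NA_real_,
    frac_enzyme_conc_cc_small = mean(abs(cm_enz) <= band, na.rm = TRUE),
    frac_env_conc_cc_large = if (env_in)
      mean(matrices$C_M[, environment_step] > band, na.rm = TRUE) else NA_real_,
    pearson_overall = unname(ct$estimate),
    pearson_p = ct$p.value
  )
}

#' Robustness of the overall controls to parameter uncertainty
#'
#' Re-runs the full control analysis for `n_samples` random parameter
#' vectors, each drawn uniformly and independently within `+-spread` around
#' the reference values, and summarizes the distribution of each step's
#' overall controls.  Non-converged samples are dropped and counted; more
#' than 50\% failures aborts with diagnostics.
#'
#' @param model a `kinetic_model`
#' @param n_samples number of random parameter sets
#' @param spread relative half-width of the uniform perturbation (0.2 =
#'   +-20\%)
#' @param seed integer seed (results are reproducible for a fixed seed)
#' @param perturbation finite-difference step passed on to
#'   [control_coefficients()]
#' @return list with `CJ` and `CC` (matrices n_samples x steps, NA rows for
#'   failed samples), `quantiles` (per-step 25/50/75\% of CJ), `n_failed`
#' @export
control_robustness <- function(model, n_samples, spread = 0.2, seed = 1,
                               perturbation = 1e-3) {
  stopifnot(n_samples >= 1)
  set.seed(seed)
  rn <- names(model$reactions)
  p0 <- model$params
  draws <- matrix(stats::runif(n_samples * length(p0), 1 - spread, 1 + spread),
                  n_samples, length(p0))
  CJ <- CC <- matrix(NA_real_, n_samples, length(rn), dimnames = list(NULL, rn))
  n_failed <- 0L
  for (i in seq_len(n_samples)) {
    mi <- model
    mi$params <- p0 * draws[i, ]
    res <- tryCatch({
      cm <- control_coefficients(mi, perturbation = perturbation)
      overall_control(cm)
    }, error = function(e) NULL)
    if (is.null(res)) {
      n_failed <- n_failed + 1L
    } else {
      CJ[i, ] <- res$CJ
      CC[i, ] <- res$CC
    }
    if (n_failed > n_samples / 2) {
      stop("more than half of the parameter samples failed (",
           n_failed, "/", i, ")", call. = FALSE)
    }
  }
  qs <- apply(CJ, 2, stats::quantile, probs = c(0.25, 0.5, 0.75), na.rm = TRUE)
  list(CJ = CJ, CC = CC, quantiles = qs, n_failed = n_failed,
       spread = spread, seed = seed)
}
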