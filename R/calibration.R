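# Constrained weighted least-squares calibration with particle swarm
# optimization, exercised by parameter recovery on synthetic data.

#' Box constraints for calibrated parameter classes
#'
#' The biologically reasonable ranges used as box constraints during
#' fitting: Km in [1e-4, 1e3] mM, Vmax in [1e-2, 1e3] mM/s, Keq in
#' [1e-4, 1e6].  Parameters whose (unprefixed) name does not start with
#' Km/Vmax/Keq get the widest class.
#'
#' @param par_names character vector of (prefixed) parameter names
#' @return list with `lower` and `upper` named vectors
#' @export
parameter_bounds <- function(par_names) {
  base <- sub("^[^.]+\\.", "", par_names)
  lower <- ifelse(startsWith(base, "Km") | startsWith(base, "Ki") |
                    startsWith(base, "Ka") | startsWith(base, "Kp"), 1e-4,
                  ifelse(startsWith(base, "Vmax"), 1e-2,
                         ifelse(startsWith(base, "Keq"), 1e-4, 1e-4)))
  upper <- ifelse(startsWith(base, "Km") | startsWith(base, "Ki") |
                    startsWith(base, "Ka") | startsWith(base, "Kp"), 1e3,
                  ifelse(startsWith(base, "Vmax"), 1e3,
                         ifelse(startsWith(base, "Keq"), 1e6, 1e6)))
  list(lower = setNames(lower, par_names), upper = setNames(upper, par_names))
}

#' Weighted least-squares calibration objective
#'
#' `f(p) = sum_i ((x_i - y_i(p)) / sigma_i)^2` where `y_i(p)` is the
#' simulated observable for data point i: a steady-state flux or
#' concentration (`time = NA`) or a time-course concentration, under the
#' point's condition.  A simulation failure at `p` returns a large finite
#' penalty (1e12 plus a distance-to-bounds term), never an exception, so
#' the swarm keeps moving.
#'
#' @param p named parameter vector (subset of the model's parameters)
#' @param model a `kinetic_model`
#' @param dataset a calibration dataset as produced by
#'   [make_calibration_data()]: data.frame with columns `observable`
#'   (`"flux:ID"` or `"conc:ID"`), `condition`, `time` (s, `NA` for steady
#'   state), `value`, `sigma` (> 0), plus a `conditions` attribute (named
#'   list of per-condition settings: `boundary` named concentrations,
#'   `scale` factors)
#' @param bounds optional bounds list (for the failure penalty term)
#' @return scalar objective value
#' @export
calibration_objective <- function(p, model, dataset, bounds = NULL) {
  if (any(dataset$sigma <= 0)) stop("sigma must be > 0", call. = FALSE)
  m <- tryCatch(set_params(model, p), error = function(e) NULL)
  if (is.null(m)) return(failure_penalty(p, bounds))
  conds <- attr(dataset, "conditions")
  if (is.null(conds)) conds <- list(default = list())
  total <- 0
  for (cid in unique(dataset$condition)) {
    rows <- dataset[dataset$condition == cid, , drop = FALSE]
    cond <- conds[[cid]]
    mc <- m
    if (!is.null(cond$boundary)) {
      mc <- set_boundary(mc, names(cond$boundary), unname(cond$boundary))
    }
    scale <- if (is.null(cond$scale)) 1 else cond$scale
    ss_rows <- rows[is.na(rows$time), , drop = FALSE]
    tc_rows <- rows[!is.na(rows$time), , drop = FALSE]
    if (nrow(ss_rows)) {
      st <- tryCatch(steady_state(mc, scale = scale), error = function(e) NULL)
      if (is.null(st) || !st$converged) return(failure_penalty(p, bounds))
      y <- vapply(ss_rows$observable, observe, 0, st = st)
      total <- total + sum(((ss_rows$value - y) / ss_rows$sigma)^2)
    }
    if (nrow(tc_rows)) {
      tg <- sort(unique(tc_rows$time))
      tr <- tryCatch(simulate_model(mc, tg, scale = scale),
                     error = function(e) NULL)
      if (is.null(tr)) return(failure_penalty(p, bounds))
      for (k in seq_len(nrow(tc_rows))) {
        sp_id <- sub("^conc:", "", tc_rows$observable[k])
        y <- tr[match(tc_rows$time[k], tr$time), sp_id]
        total <- total + ((tc_rows$value[k] - y) / tc_rows$sigma[k])^2
      }
    }
  }
  total
}

observe <- function(obs, st) {
  if (startsWith(obs, "flux:")) return(unname(st$fluxes[sub("^flux:", "", obs)]))
  if (startsWith(obs, "conc:")) return(unname(st$concentrations[sub("^conc:", "", obs)]))
  stop("observable must be 'flux:ID' or 'conc:ID': ", obs, call. = FALSE)
}

failure_penalty <- function(p, bounds) {
  pen <- 1e12
  if (!is.null(bounds)) {
    mid <- sqrt(bounds$lower * bounds$upper)
    pen <- pen + sum(abs(log(pmax(p, 1e-300) / mid)))
  }
  pen
}

#' Particle swarm optimization (gbest, reflective bounds)
#'
#' Standard global-best PSO: swarm of `n_particles`, inertia `w`, cognitive
#' and social accelerations `c1`, `c2`; positions that cross a bound are
#' reflected and the velocity component inverted.  Deterministic for a
#' fixed seed.
#'
#' @param objective function of a numeric vector returning a scalar
#' @param lower,upper numeric bound vectors (equal-length); equal bounds pin
#'   a coordinate
#' @param n_particles swarm size
#' @param iters number of iterations
#' @param w,c1,c2 PSO hyperparameters
#' @param seed integer seed
#' @return list with `par`, `value`, `trace` (best value per iteration,
#'   non-increasing), `seed`
#' @export
fit_pso <- function(objective, lower, upper, n_particles = 50, iters = 100,
                    w = 0.7, c1 = 1.5, c2 = 1.5, seed = 1) {
  stopifnot(length(lower) == length(upper), all(upper >= lower))
  d <- length(lower)
  set.seed(seed)
  span <- upper - lower
  X <- matrix(stats::runif(n_particles * d), n_particles, d)
  X <- sweep(sweep(X, 2, span, `*`), 2, lower, `+`)
  X[1, ] <- (lower + upper) / 2
  V <- matrix(stats::runif(n_particles * d, -1, 1), n_particles, d) *
    matrix(span / 10, n_particles, d, byrow = TRUE)
  fx <- apply(X, 1, objective)
  if (!any(is.finite(fx))) stop("no feasible evaluation in the initial swarm",
                                call. = FALSE)
  Pb <- X
  fpb <- fx
  g <- which.min(fpb)
  gbest <- Pb[g, ]
  fgbest <- fpb[g]
  trace <- numeric(iters)
  for (it in seq_len(iters)) {
    r1 <- matrix(stats::runif(n_particles * d), n_particles, d)
    r2 <- matrix(stats::runif(n_particles * d), n_particles, d)
    V <- w * V + c1 * r1 * (Pb - X) +
      c2 * r2 * (matrix(gbest, n_particles, d, byrow = TRUE) - X)
    X <- X + V
    # reflective bound handling
    for (j in seq_len(d)) {
      lo <- lower[j]; hi <- upper[j]
      if (hi == lo) { X[, j] <- lo; V[, j] <- 0; next }
      below <- X[, j] < lo
      above <- X[, j] > hi
      X[below, j] <- pmin(2 * lo - X[below, j], hi)
      X[above, j] <- pmax(2 * hi - X[above, j], lo)
      V[below | above, j] <- -V[below | above, j]
    }
    fx <- apply(X, 1, objective)
    better <- fx < fpb
    Pb[better, ] <- X[better, , drop = FALSE]
    fpb[better] <- fx[better]
    g <- which.min(fpb)
    if (fpb[g] < fgbest) {
      gbest <- Pb[g, ]
      fgbest <- fpb[g]
    }
    trace[it] <- fgbest
  }
  list(par = gbest, value = fgbest, trace = trace, seed = seed)
}

#' Fit model parameters to a calibration dataset
#'
#' Box-constrained global minimization of [calibration_objective()] by
#' particle swarm over log10-transformed parameters (the natural scale for
#' rate constants and binding constants), with independent swarm restarts
#' and a Nelder-Mead refinement of the best swarm optimum.
#'
#' @param model a `kinetic_model`
#' @param dataset calibration dataset (see [calibration_objective()])
#' @param free named vector of starting values for the free parameters, or a
#'   character vector of parameter names (starting from current values)
#' @param lower,upper optional named bound overrides; defaults from
#'   [parameter_bounds()]
#' @param n_particles,iters,seed swarm settings
#' @param n_starts independent swarm restarts (seeds derived from `seed`);
#'   the best final objective wins.  Restarts are the standard guard
#'   against a swarm stalling on a correlated parameter ridge.
#' @return list with `par` (fitted named vector), `value`, `trace` (of the
#'   winning start), `seed`
#' @export
fit_model <- function(model, dataset, free, lower = NULL, upper = NULL,
                      n_particles = 50, iters = 100, seed = 1, n_starts = 2) {
  if (is.character(free)) free <- model$params[free]
  pb <- parameter_bounds(names(free))
  lo <- pb$lower
  hi <- pb$upper
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  obj <- function(logp) {
    p <- setNames(10^logp, names(free))
    calibration_objective(p, model, dataset, bounds = list(lower = lo, upper = hi))
  }
  best <- NULL
  for (k in seq_len(max(n_starts, 1))) {
    fit <- fit_pso(obj, log10(lo), log10(hi), n_particles = n_particles,
                   iters = iters, seed = seed + (k - 1L) * 1000000L)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # local refinement from the swarm optimum (Nelder-Mead follows the
  # correlated parameter ridges a finite swarm can stall on), clamped to
  # the box constraints
  pol <- tryCatch(stats::optim(best$par, obj, method = "Nelder-Mead",
                               control = list(maxit = 500, reltol = 1e-12)),
                  error = function(e) NULL)
  if (!is.null(pol) && is.finite(pol$value) && pol$value < best$value) {
    par_log <- pmin(pmax(pol$par, log10(lo)), log10(hi))
    val <- obj(par_log)
    if (val <= best$value) {
      best$par <- par_log
      best$value <- val
    }
  }
  list(par = setNames(10^best$par, names(free)), value = best$value,
       trace = best$trace, seed = seed)
}

#' Parameter-recovery report
#'
#' Compares fitted against true parameters: relative errors and flags for
#' parameters sitting at (or within 1\% of) their bounds -- the usual
#' signature of non-identifiability under the given dataset.
#'
#' @param true_p,fitted_p named parameter vectors (same names)
#' @param lower,upper bounds used in the fit (defaults from
#'   [parameter_bounds()])
#' @return data.frame with `parameter`, `true`, `fitted`, `rel_error`,
#'   `at_bound`
#' @export
recovery_report <- function(true_p, fitted_p, lower = NULL, upper = NULL) {
  stopifnot(setequal(names(true_p), names(fitted_p)))
  fitted_p <- fitted_p[names(true_p)]
  pb <- parameter_bounds(names(true_p))
  lo <- if (is.null(lower)) pb$lower else lower
  hi <- if (is.null(upper)) pb$upper else upper
  span <- log10(hi) - log10(lo)
  at_bound <- (log10(fitted_p) - log10(lo)) < 0.01 * span |
    (log10(hi) - log10(fitted_p)) < 0.01 * span
  data.frame(parameter = names(true_p),
             true = unname(true_p),
             fitted = unname(fitted_p),
             rel_error = unname(abs(fitted_p - true_p) / abs(true_p)),
             at_bound = unname(at_bound))
}
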