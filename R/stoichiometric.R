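# Stoichiometric (constraint-based) counterpart of the kinetic model:
# uniform sampling of the flux polytope {v : S v = b, lb <= v <= ub} and
# boundary (envelope) estimation with and without metabolic regulation.

#' Derive the stoichiometric model from a kinetic model
#'
#' Strips the kinetics: keeps the stoichiometric matrix restricted to
#' internal species (cellular, non-boundary), infers reversibility from the
#' rate-law family (mass action and reversible Michaelis-Menten forms,
#' including the respiratory laws with their thermodynamic back term, are
#' reversible; irreversible Michaelis-Menten, irreversible mass action,
#' constant-rate and growth laws are not) and caps all bounds at
#' `cap_factor` times the reference flux magnitude (floored at `cap_min`),
#' so the polytope is bounded.
#'
#' @param model a `kinetic_model`
#' @param cap_factor bound cap as a multiple of each reference flux
#' @param cap_min minimal cap (mM/s), applied where the reference flux is
#'   tiny
#' @param reference_fluxes optional named flux vector used for the caps
#'   (defaults to the model's designed reference fluxes, else all-`cap_min`)
#' @return object of class `stoich_model`: list with `S` (internal species x
#'   reactions), `lb`, `ub`, `b` (zeros), `reversible`, `v0` (a strictly
#'   interior feasible point, when available), `caps` metadata
#' @export
to_stoichiometric <- function(model, cap_factor = 10, cap_min = 0.1,
                              reference_fluxes = attr(model, "reference_fluxes")) {
  if (!length(model$reactions)) stop("empty model", call. = FALSE)
  internal <- model$species$compartment != "environment" & !model$species$boundary
  S <- model$S[internal, , drop = FALSE]
  rev_forms <- c("mass_action_reversible", "reversible_michaelis_menten",
                 "ndhi", "ndh2", "sqr", "cytbo", "atp_syn")
  reversible <- vapply(model$reactions, function(r) r$form %in% rev_forms, TRUE)
  rn <- names(model$reactions)
  if (is.null(reference_fluxes)) {
    cap <- rep(cap_min, length(rn))
  } else {
    cap <- pmax(cap_factor * abs(reference_fluxes[rn]), cap_min)
  }
  ub <- cap
  lb <- ifelse(reversible, -cap, 0)
  names(ub) <- names(lb) <- rn
  v0 <- if (!is.null(reference_fluxes)) reference_fluxes[rn] else NULL
  if (!is.null(v0) && (any(v0 <= lb) || any(v0 >= ub))) v0 <- NULL
  structure(list(S = S, lb = lb, ub = ub, b = rep(0, nrow(S)),
                 reversible = reversible, v0 = v0,
                 caps = list(cap_factor = cap_factor, cap_min = cap_min)),
            class = "stoich_model")
}

#' @export
print.stoich_model <- function(x, ...) {
  cat("<stoich_model> ", nrow(x$S), " internal species x ", ncol(x$S),
      " reactions (", sum(x$reversible), " reversible)\n", sep = "")
  invisible(x)
}

#' Build a flux polytope from explicit constraints
#'
#' General constructor for `{v : A v = b, lb <= v <= ub}` polytopes (used by
#' the sampler tests on analytic polytopes such as the probability simplex).
#'
#' @param A equality constraint matrix
#' @param b right-hand side
#' @param lb,ub variable bounds
#' @param v0 optional strictly interior point
#' @return a `stoich_model`
#' @export
flux_polytope <- function(A, b, lb, ub, v0 = NULL) {
  structure(list(S = A, lb = lb, ub = ub, b = b,
                 reversible = lb < 0, v0 = v0, caps = NULL),
            class = "stoich_model")
}

# strictly interior feasible point by a Chebyshev-like LP in null-space
# coordinates: max s  s.t.  lb + s <= v_p + N t <= ub - s
find_interior <- function(smodel) {
  S <- smodel$S
  N <- null_right(S)
  d <- ncol(N)
  if (d == 0) stop("flux polytope has no degrees of freedom", call. = FALSE)
  v_p <- if (max(abs(smodel$b)) == 0) numeric(ncol(S))
         else as.numeric(MASS_ginv(S) %*% smodel$b)
  A_box <- rbind(N, -N)
  b_box <- c(smodel$ub - v_p, v_p - smodel$lb)
  # variables: (tp, tm, s) all >= 0
  A1 <- cbind(A_box, -A_box, 1)
  obj <- c(rep(0, 2 * d), 1)
  sol <- tryCatch(boot::simplex(a = obj, A1 = A1, b1 = b_box, maxi = TRUE),
                  error = function(e) list(solved = -1))
  if (sol$solved != 1 || sol$value <= 0) {
    stop("could not find a strictly interior point of the flux polytope",
         call. = FALSE)
  }
  t_opt <- sol$soln[seq_len(d)] - sol$soln[d + seq_len(d)]
  as.numeric(v_p + N %*% t_opt)
}

#' Uniformly sample the flux polytope (hit-and-run)
#'
#' Approximately uniform samples from `{v : S v = b, lb <= v <= ub}` by
#' hit-and-run over the null-space parameterization: directions are drawn
#' isotropically in the null space of `S`, the feasible chord is computed
#' from the box bounds, and a point is drawn uniformly on it.  Warm-up
#' (`10 * dim` steps) and thinning (`dim` steps) follow standard practice;
#' uniformity is validated on analytic polytopes in the test suite.
#'
#' @param smodel a `stoich_model`
#' @param n number of samples
#' @param seed integer seed
#' @param warmup,thin override the warm-up and thinning step counts
#' @param start optional feasible starting point (defaults to the model's
#'   `v0`, else an interior point found by linear programming)
#' @return matrix `n x n_reactions`; every row satisfies the constraints to
#'   1e-9
#' @export
sample_flux_space <- function(smodel, n, seed = 1, warmup = NULL, thin = NULL,
                              start = NULL) {
  S <- smodel$S
  N <- null_right(S)
  d <- ncol(N)
  if (d == 0) stop("flux polytope has no degrees of freedom", call. = FALSE)
  v <- start
  if (is.null(v)) v <- smodel$v0
  if (is.null(v)) v <- find_interior(smodel)
  v <- as.numeric(v)
  if (any(v < smodel$lb - 1e-9) || any(v > smodel$ub + 1e-9) ||
      max(abs(S %*% v - smodel$b)) > 1e-6) {
    stop("starting point is not feasible", call. = FALSE)
  }
  if (is.null(warmup)) warmup <- 10L * d
  if (is.null(thin)) thin <- d
  set.seed(seed)
  out <- matrix(NA_real_, n, ncol(S), dimnames = list(NULL, colnames(S)))
  lb <- smodel$lb
  ub <- smodel$ub
  step <- function(v) {
    dir <- as.numeric(N %*% stats::rnorm(d))
    nrm <- sqrt(sum(dir^2))
    if (nrm < 1e-12) return(v)
    dir <- dir / nrm
    # chord [a_lo, a_hi] from lb <= v + a dir <= ub
    with_dir <- abs(dir) > 1e-12
    a_up <- (ub[with_dir] - v[with_dir]) / dir[with_dir]
    a_dn <- (lb[with_dir] - v[with_dir]) / dir[with_dir]
    a_lo <- max(pmin(a_up, a_dn))
    a_hi <- min(pmax(a_up, a_dn))
    if (!is.finite(a_lo) || !is.finite(a_hi) || a_hi <= a_lo) {
      stop("unbounded or empty chord: cap the flux bounds", call. = FALSE)
    }
    v + stats::runif(1, a_lo, a_hi) * dir
  }
  for (k in seq_len(warmup)) v <- step(v)
  for (i in seq_len(n)) {
    for (k in seq_len(thin)) v <- step(v)
    out[i, ] <- v
  }
  out
}

# LP helper: minimize / maximize  obj' v  over the polytope.  The equality
# system S v = b is eliminated first (v = v_p + N t over the null space of
# S), so the solver only sees the box constraints and any extra equality
# rows -- a far smaller and better-conditioned problem for boot::simplex.
polytope_lp <- function(smodel, obj, extra_A = NULL, extra_b = NULL,
                        maximize = TRUE, origin = NULL) {
  Aeq <- smodel$S
  beq <- smodel$b
  if (!is.null(extra_A)) {
    Aeq <- rbind(Aeq, extra_A)
    beq <- c(beq, extra_b)
  }
  # LP origin: a feasible point of the (pinned) polytope; boot::simplex
  # needs the box slack at the origin to be non-negative
  v_p <- origin
  if (is.null(v_p)) {
    v0 <- smodel$v0
    if (is.null(v0)) v0 <- tryCatch(find_interior(smodel), error = function(e) NULL)
    if (is.null(v0)) return(NULL)
    v_p <- as.numeric(v0)
    if (!is.null(extra_A)) {
      Ns <- null_right(smodel$S)
      Tm <- extra_A %*% Ns
      t0 <- as.numeric(MASS_ginv(Tm) %*% (extra_b - extra_A %*% v_p))
      v_p <- v_p + as.numeric(Ns %*% t0)
    }
  }
  if (max(abs(Aeq %*% v_p - beq)) > 1e-7 * (1 + max(abs(beq)))) return(NULL)
  if (any(v_p < smodel$lb - 1e-7) || any(v_p > smodel$ub + 1e-7)) return(NULL)
  N <- null_right(Aeq)
  d <- ncol(N)
  tol_box <- 1e-9
  if (d == 0) {
    if (all(v_p >= smodel$lb - tol_box) && all(v_p <= smodel$ub + tol_box)) {
      return(list(value = as.numeric(obj %*% v_p), v = v_p))
    }
    return(NULL)
  }
  # variables: t = tp - tm, both >= 0; box constraints as inequalities
  # (boot::simplex needs a non-negative right-hand side: tiny violations of
  # the box at the origin are clipped; the solution is re-checked below)
  A_box <- rbind(N, -N)
  b_box <- pmax(c(smodel$ub - v_p, v_p - smodel$lb), 0)
  A1 <- cbind(A_box, -A_box)
  obj_t <- as.numeric(obj %*% N)
  a <- c(obj_t, -obj_t)
  sol <- tryCatch(boot::simplex(a = a, A1 = A1, b1 = b_box, maxi = maximize),
                  error = function(e) list(solved = -1))
  if (sol$solved != 1) return(NULL)
  t_opt <- sol$soln[seq_len(d)] - sol$soln[d + seq_len(d)]
  v <- v_p + as.numeric(N %*% t_opt)
  if (any(v < smodel$lb - 1e-6) || any(v > smodel$ub + 1e-6)) return(NULL)
  list(value = as.numeric(obj %*% v), v = v)
}

#' Boundaries of the stoichiometric solution space
#'
#' For each grid value of the first variable, minimizes and maximizes the
#' second variable by linear programming subject to the polytope constraints
#' and the first variable pinned at the grid value; the envelope is exact up
#' to LP tolerance.  Variables are linear functionals of the flux vector,
#' given as coefficient vectors or single reaction ids.
#'
#' @param smodel a `stoich_model`
#' @param variable_pair list of two variables, each either a reaction id or
#'   a named/full-length coefficient vector
#' @param grid grid values for variable 1 (or an integer count; the grid then
#'   spans the LP-feasible range of variable 1)
#' @return data.frame with `x`, `y_min`, `y_max`, `feasible`
#' @export
stoichiometric_boundaries <- function(smodel, variable_pair, grid = 15) {
  c1 <- variable_coef(smodel, variable_pair[[1]])
  c2 <- variable_coef(smodel, variable_pair[[2]])
  lo1 <- polytope_lp(smodel, c1, maximize = FALSE)
  hi1 <- polytope_lp(smodel, c1, maximize = TRUE)
  if (is.null(lo1) || is.null(hi1)) stop("variable-1 range LP failed", call. = FALSE)
  if (length(grid) == 1L) {
    grid <- seq(lo1$value, hi1$value, length.out = as.integer(grid))
  }
  # feasible origins for the pinned LPs: interpolate between polytope points
  # whose pin values bracket the grid value (the polytope is convex)
  pts <- rbind(lo1$v, hi1$v)
  if (!is.null(smodel$v0)) pts <- rbind(pts, as.numeric(smodel$v0))
  pin_vals <- as.numeric(pts %*% c1)
  origin_for <- function(g) {
    below <- which(pin_vals <= g + 1e-12)
    above <- which(pin_vals >= g - 1e-12)
    if (!length(below) || !length(above)) return(NULL)
    i <- below[which.max(pin_vals[below])]
    j <- above[which.min(pin_vals[above])]
    if (abs(pin_vals[j] - pin_vals[i]) < 1e-300) return(pts[i, ])
    a <- (g - pin_vals[i]) / (pin_vals[j] - pin_vals[i])
    (1 - a) * pts[i, ] + a * pts[j, ]
  }
  res <- data.frame(x = grid, y_min = NA_real_, y_max = NA_real_,
                    feasible = FALSE)
  for (k in seq_along(grid)) {
    org <- origin_for(grid[k])
    if (is.null(org)) next
    lo <- polytope_lp(smodel, c2, extra_A = matrix(c1, 1), extra_b = grid[k],
                      maximize = FALSE, origin = org)
    hi <- polytope_lp(smodel, c2, extra_A = matrix(c1, 1), extra_b = grid[k],
                      maximize = TRUE, origin = org)
    if (!is.null(lo) && !is.null(hi)) {
      res$y_min[k] <- lo$value
      res$y_max[k] <- hi$value
      res$feasible[k] <- TRUE
    }
  }
  res
}

# resolve a variable definition (reaction id or coefficient vector) into a
# full-length coefficient vector over reactions
variable_coef <- function(smodel, var) {
  rn <- colnames(smodel$S)
  n <- ncol(smodel$S)
  if (is.character(var) && length(var) == 1L) {
    i <- match(var, rn)
    if (is.na(i)) stop("unknown reaction: ", var, call. = FALSE)
    coef <- numeric(n)
    coef[i] <- 1
    return(coef)
  }
  if (!is.null(names(var))) {
    coef <- numeric(n)
    coef[match(names(var), rn)] <- var
    return(coef)
  }
  if (length(var) != n) stop("coefficient vector has wrong length", call. = FALSE)
  as.numeric(var)
}

#' Boundaries of the kinetic solution space
#'
#' Estimates the envelope of a pair of steady-state variables reachable by
#' varying enzyme levels within `[lo, hi]`: for each grid value of variable
#' 1, a particle-swarm search over log enzyme factors maximizes (and
#' minimizes) variable 2 subject to variable 1 pinned within `pin_tol`
#' relative tolerance (penalty formulation).  Returns the achieved envelope
#' points; entries where the optimizer exhausted its budget without a
#' feasible pin are flagged approximate.
#'
#' @param model a `kinetic_model` (excess-glucose condition applied
#'   internally, matching the ensemble runs)
#' @param variable_pair list of two functions `f(steady_state) -> scalar`,
#'   or reaction ids (then the steady-state flux of that reaction is used)
#' @param grid grid of variable-1 target values
#' @param lo,hi enzyme factor bounds
#' @param pin_tol relative pinning tolerance on variable 1
#' @param n_particles,iters swarm settings per envelope point
#' @param seed integer seed
#' @param glucose_mM excess-glucose condition (`NULL`: leave the
#'   model's condition unchanged, e.g. for toy models without glucose)
#' @return data.frame with `x` (targeted value), `x_achieved`, `y_min`,
#'   `y_max`, `pinned`
#' @export
kinetic_boundaries <- function(model, variable_pair, grid, lo = 0.1, hi = 10,
                               pin_tol = 0.02, n_particles = 20, iters = 25,
                               seed = 1, glucose_mM = 10) {
  mg <- if (is.null(glucose_mM)) model else with_excess_glucose(model, glucose_mM)
  base <- steady_state(mg)
  v1 <- variable_fun(variable_pair[[1]])
  v2 <- variable_fun(variable_pair[[2]])
  fixed <- names(mg$reactions) %in% non_enzymatic_steps(mg)
  n_free <- sum(!fixed)
  eval_point <- function(logf) {
    sc <- rep(1, length(fixed))
    sc[!fixed] <- 10^logf
    st <- steady_state(mg, initial_guess = base$concentrations, scale = sc,
                       fallback = FALSE, max_iter = 30L)
    if (!st$converged) return(NULL)
    c(v1(st), v2(st))
  }
  res <- data.frame(x = grid, x_achieved = NA_real_, y_min = NA_real_,
                    y_max = NA_real_, pinned = FALSE)
  for (k in seq_along(grid)) {
    target <- grid[k]
    ys <- c(NA_real_, NA_real_)
    xs <- c(NA_real_, NA_real_)
    pin_ok <- c(FALSE, FALSE)
    for (side in 1:2) {
      sgn <- if (side == 1) 1 else -1
      obj <- function(logf) {
        pt <- eval_point(logf)
        if (is.null(pt)) return(1e8)
        pen <- max(0, abs(pt[1] - target) / max(abs(target), 1e-9) - pin_tol)
        -sgn * pt[2] + 1e4 * pen
      }
      fit <- fit_pso(obj, lower = rep(log10(lo), n_free),
                     upper = rep(log10(hi), n_free),
                     n_particles = n_particles, iters = iters,
                     seed = seed + 1000 * k + side)
      pt <- eval_point(fit$par)
      if (!is.null(pt)) {
        xs[side] <- pt[1]
        ys[side] <- pt[2]
        pin_ok[side] <- abs(pt[1] - target) / max(abs(target), 1e-9) <= pin_tol
      }
    }
    res$x_achieved[k] <- mean(xs, na.rm = TRUE)
    res$y_max[k] <- ys[1]
    res$y_min[k] <- ys[2]
    res$pinned[k] <- all(pin_ok)
  }
  res
}

# turn a variable spec (function or reaction id) into f(steady_state)
variable_fun <- function(var) {
  if (is.function(var)) return(var)
  if (is.character(var) && length(var) == 1L) {
    force(var)
    return(function(st) unname(st$fluxes[var]))
  }
  stop("variable must be a function or a reaction id", call. = FALSE)
}
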