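# Time-course simulation and steady-state solving.
#
# The ODE system is dx_i/dt = (1/V_i) * sum_j S_ij v_j(x), with rates v in
# mM/s on the cytoplasmic volume basis and V_i the relative volume of the
# species' compartment (cytoplasm = 1).  Boundary species are held fixed.

# right-hand side closure shared by simulate() and the integration fallback
make_rhs <- function(model, scale) {
  f <- model_rate_fn(model)
  dyn <- !model$species$boundary
  inv_vol <- 1 / species_volumes(model)
  S <- model$S
  p <- model$params
  function(t, x, parms) {
    v <- f(x, p, scale)
    dx <- inv_vol * as.numeric(S %*% v)
    dx[!dyn] <- 0
    list(dx)
  }
}

#' Simulate a kinetic model
#'
#' Integrates the ODE system over a time grid with `deSolve::lsoda`
#' (automatic stiff/non-stiff switching).  Boundary species stay constant;
#' conserved moieties implied by the stoichiometry are preserved by
#' construction of the right-hand side.
#'
#' @param model a `kinetic_model`
#' @param t_grid increasing vector of output times (s)
#' @param initial_state optional named concentration vector (defaults to the
#'   model's reference concentrations)
#' @param scale optional per-reaction enzyme-level scale factors
#' @param atol,rtol absolute (mM) and relative integration tolerances
#' @return data.frame: `time` plus one column per species (mM)
#' @export
simulate_model <- function(model, t_grid, initial_state = NULL, scale = 1,
                           atol = 1e-8, rtol = 1e-6) {
  if (is.unsorted(t_grid, strictly = TRUE)) {
    stop("t_grid must be strictly increasing", call. = FALSE)
  }
  x0 <- if (is.null(initial_state)) setNames(model$species$conc, model$species$id)
        else setNames(order_concs(model, initial_state), model$species$id)
  scale <- order_factors(model, scale)
  rhs <- make_rhs(model, scale)
  times <- if (t_grid[1] > 0) c(0, t_grid) else t_grid
  out <- deSolve::lsoda(y = x0, times = times, func = rhs, parms = NULL,
                        atol = atol, rtol = rtol, maxsteps = 20000)
  if (attr(out, "istate")[1] < 0) {
    stop("integration failed at t = ", max(out[, "time"]),
         "; last state: ", paste(signif(out[nrow(out), -1], 3), collapse = ", "),
         call. = FALSE)
  }
  out <- as.data.frame(out)
  out[out$time %in% t_grid, , drop = FALSE]
}

# ---- sparse rate Jacobian via column grouping -------------------------------

# species -> reactions incidence and a greedy coloring of species such that
# no reaction depends on two species of the same color; the rate Jacobian
# then needs one perturbed evaluation per color instead of per species
jac_structure <- function(model) {
  sp <- model$species$id
  dep <- lapply(model$reactions, function(r) intersect(all.vars(r$expr), sp))
  n <- length(sp)
  conflict <- vector("list", n)
  names(conflict) <- sp
  for (d in dep) {
    for (s in d) conflict[[s]] <- union(conflict[[s]], setdiff(d, s))
  }
  color <- setNames(integer(n), sp)
  for (s in sp[order(-vapply(conflict, length, 0L))]) {
    used <- color[conflict[[s]]]
    color[s] <- min(setdiff(seq_len(n), used[used > 0]))
  }
  # reaction -> species columns it depends on (indices), and the transpose
  dep_idx <- lapply(dep, function(d) match(d, sp))
  rows_by_species <- lapply(seq_len(n), function(i)
    which(vapply(dep_idx, function(d) i %in% d, TRUE)))
  list(color = color, dep = dep_idx, rows = rows_by_species)
}

model_jac_info <- function(model) {
  info <- attr(model, ".jac_info")
  if (is.null(info)) info <- jac_structure(model)
  info
}

# symbolic sparse Jacobian dv/dx: differentiate every rate law with respect
# to each species it depends on, and compile the derivative expressions for
# the C evaluator; returns NULL when differentiation or compilation is not
# possible (the colored-FD path is used instead)
jac_symbolic <- function(model) {
  sp <- model$species$id
  sp_index <- setNames(seq_along(sp), sp)
  par_index <- setNames(seq_along(model$params), names(model$params))
  rows <- cols <- integer(0)
  progs <- list()
  for (k in seq_along(model$reactions)) {
    r <- model$reactions[[k]]
    for (s in intersect(all.vars(r$expr), sp)) {
      d <- tryCatch(stats::D(r$expr, s), error = function(e) NULL)
      if (is.null(d)) return(NULL)
      bc <- expr_to_code(d, sp_index, par_index)
      if (is.null(bc)) return(NULL)
      rows <- c(rows, k)
      cols <- c(cols, sp_index[[s]])
      progs[[length(progs) + 1L]] <- bc
    }
  }
  code <- integer(0)
  consts <- numeric(0)
  starts <- lens <- integer(length(progs))
  for (k in seq_along(progs)) {
    bc <- progs[[k]]
    if (length(bc$code)) {
      is_const <- bc$code[seq(1, length(bc$code), 2)] == RL_OPS[["CONST"]]
      argpos <- seq(2, length(bc$code), 2)[is_const]
      bc$code[argpos] <- bc$code[argpos] + length(consts)
    }
    starts[k] <- length(code)
    lens[k] <- length(bc$code)
    code <- c(code, bc$code)
    consts <- c(consts, bc$consts)
  }
  list(rows = rows, cols = cols, code = as.integer(code),
       starts = as.integer(starts), lens = as.integer(lens),
       consts = if (length(consts)) as.numeric(consts) else 0)
}

# Jacobian dv/dx (n_reactions x n_species, dense storage): analytic when the
# model carries compiled derivative programs, colored FD otherwise
rate_jacobian <- function(model, x, scale, v0 = NULL) {
  ja <- attr(model, ".jac_sym")
  if (!is.null(ja)) {
    sym <- tryCatch(getNativeSymbolInfo("C_eval_rates"), error = function(e) NULL)
    if (!is.null(sym)) {
      sc <- if (length(scale) == 1L) rep(as.numeric(scale), length(ja$rows))
            else as.numeric(scale)[ja$rows]
      vals <- .Call(sym, ja$code, ja$starts, ja$lens, ja$consts,
                    as.numeric(x), as.numeric(model$params), sc)
      J <- matrix(0, length(model$reactions), length(x))
      J[cbind(ja$rows, ja$cols)] <- vals
      return(J)
    }
  }
  f <- model_rate_fn(model)
  p <- model$params
  info <- model_jac_info(model)
  if (is.null(v0)) v0 <- f(x, p, scale)
  n_sp <- length(x)
  J <- matrix(0, length(v0), n_sp)
  for (cl in unique(info$color)) {
    idx <- which(info$color == cl)
    h <- 1e-5 * pmax(abs(x[idx]), 1e-9)
    xp <- x
    xp[idx] <- xp[idx] + h
    dv <- (f(xp, p, scale) - v0)
    for (k in seq_along(idx)) {
      i <- idx[k]
      rows <- info$rows[[i]]
      J[rows, i] <- dv[rows] / h[k]
    }
  }
  J
}

# residual dx/dt (dynamic species only)
steady_residual <- function(model, x, scale) {
  f <- model_rate_fn(model)
  v <- f(x, model$params, scale)
  dyn <- !model$species$boundary
  dx <- as.numeric(model$S %*% v) / species_volumes(model)
  list(dx = dx[dyn], v = v)
}

#' Solve for a steady state
#'
#' Finds roots of the steady-state system with a damped Newton-type
#' iteration formulated for stiff kinetic models: variables are
#' log-concentrations of the dynamic species (positivity by construction,
#' relative steps across decades of concentration), residuals are scaled by
#' the per-species tolerance, the step is restricted to directions that
#' leave the conserved-moiety totals unchanged (the moiety basis is the
#' left null space of the volume-scaled stoichiometric matrix, computed,
#' never assumed), every iterate is projected exactly back onto the linear
#' moiety manifold, and the step is regularized adaptively
#' (Levenberg-Marquardt damping with a QR solve), which interpolates
#' between full Newton steps near the solution and conservative descent far
#' from it.  The rate Jacobian is analytic (symbolically differentiated
#' rate laws compiled for the C evaluator), with a colored
#' finite-difference fallback.  If the iteration stalls, the solver
#' integrates the ODE system toward the attractor ("integrate to steady
#' state") and retries.  Convergence requires
#' `|dx_i/dt| <= atol + rtol * x_i` for every dynamic species.
#'
#' Non-convergence is reported through the `converged` flag (not an error),
#' so ensemble runs can account for failed samples.
#'
#' @param model a `kinetic_model`
#' @param initial_guess optional named concentration vector; defaults to the
#'   model's reference concentrations.  Must be strictly positive for
#'   dynamic species.
#' @param scale optional per-reaction enzyme-level scale factors
#' @param atol absolute tolerance on residuals (mM/s), default 1e-8
#' @param rtol relative tolerance, default 1e-6
#' @param max_iter iteration budget per attempt
#' @param fallback logical: allow the integrate-and-retry fallback
#' @return object of class `steady_state`: list with `concentrations`,
#'   `fluxes`, `residual_norm` (max |dx/dt|), `converged`, `iterations`,
#'   `method`
#' @export
steady_state <- function(model, initial_guess = NULL, scale = 1,
                         atol = 1e-8, rtol = 1e-6, max_iter = 80L,
                         fallback = TRUE) {
  sp <- model$species$id
  x0 <- if (is.null(initial_guess)) setNames(model$species$conc, sp)
        else setNames(order_concs(model, initial_guess), sp)
  dyn <- !model$species$boundary
  if (any(x0[dyn] <= 0)) {
    stop("initial guess must be strictly positive for non-boundary species",
         call. = FALSE)
  }
  scale <- order_factors(model, scale)
  f <- model_rate_fn(model)
  p <- model$params
  inv_vol <- 1 / species_volumes(model)
  M <- (model$S * inv_vol)[dyn, , drop = FALSE]   # dx_dyn/dt = M v
  # conserved moieties: orthonormal left null basis of M; totals are fixed
  # by the start point and enforced exactly by projecting every iterate
  # back onto the (linear) moiety manifold
  Cm <- null_left(M)
  c0 <- if (ncol(Cm)) as.numeric(crossprod(Cm, x0[dyn])) else numeric(0)
  project_moiety <- function(x) {
    if (ncol(Cm)) {
      x[dyn] <- x[dyn] + as.numeric(Cm %*% (c0 - crossprod(Cm, x[dyn])))
      x[dyn] <- pmax(x[dyn], 1e-15)
    }
    x
  }

  tol_ok <- function(x, r) all(abs(r) <= atol + rtol * x[dyn])

  # scaled log-space residual vector
  R_of <- function(x) {
    r <- as.numeric(M %*% f(x, p, scale))
    dr <- 1 / (atol + rtol * x[dyn])
    list(R = dr * r, r = r, dr = dr)
  }

  lm_solve <- function(x, iter_budget) {
    x <- project_moiety(x)
    cur <- R_of(x)
    lambda <- 1e-4
    it <- 0L
    while (it < iter_budget) {
      if (tol_ok(x, cur$r)) return(list(x = x, r = cur$r, it = it, ok = TRUE))
      Jv <- rate_jacobian(model, x, scale)
      X <- x[dyn]
      Jw <- (cur$dr * (M %*% Jv[, dyn, drop = FALSE])) %*% diag(X, length(X))
      # restrict the log-space step to directions that keep the conserved
      # moiety totals fixed to first order: dw = Z y with Cm' X Z = 0
      Z <- if (ncol(Cm)) null_right(crossprod(Cm, diag(X, length(X)))) else diag(length(X))
      Jz <- Jw %*% Z
      cn <- sqrt(colSums(Jz^2))
      cn[cn < 1e-300] <- 1e-300
      Js <- Jz %*% diag(1 / cn, length(cn))                  # unit column norms
      n_w <- ncol(Js)
      accepted <- FALSE
      for (try in 1:12) {
        # regularized least-squares step via QR on the stacked system
        # (avoids the condition-squaring of the normal equations)
        Astack <- rbind(Js, diag(sqrt(lambda), n_w))
        bstack <- c(-cur$R, numeric(n_w))
        dw <- tryCatch(as.numeric(Z %*% ((1 / cn) * qr.solve(Astack, bstack))),
                       error = function(e) NULL)
        if (!is.null(dw)) {
          mx <- max(abs(dw))
          if (mx > 3) dw <- dw * (3 / mx)   # cap at e^3 fold change per step
          x_new <- x
          x_new[dyn] <- X * exp(dw)
          x_new <- project_moiety(x_new)
          new <- R_of(x_new)
          if (all(is.finite(new$R)) &&
              (sum(new$R^2) < sum(cur$R^2) || tol_ok(x_new, new$r))) {
            x <- x_new
            cur <- new
            lambda <- max(lambda / 3, 1e-12)
            accepted <- TRUE
            break
          }
        }
        lambda <- lambda * 8
      }
      it <- it + 1L
      if (!accepted) return(list(x = x, r = cur$r, it = it, ok = FALSE))
    }
    list(x = x, r = cur$r, it = it, ok = tol_ok(x, cur$r))
  }

  res <- lm_solve(x0, max_iter)
  total_it <- res$it
  method <- "newton"
  if (!res$ok && fallback) {
    # follow the true dynamics toward the attractor, polishing with the
    # Newton iteration at geometrically increasing horizons
    rhs <- make_rhs(model, scale)
    jac <- function(t, y, parms) {
      Jv <- rate_jacobian(model, y, scale)
      J <- (model$S %*% Jv) * inv_vol
      J[!dyn, ] <- 0
      J
    }
    x <- x0
    t_done <- 0
    for (horizon in c(1e3, 3e4, 1e6)) {
      sim <- tryCatch(suppressWarnings(
        deSolve::lsoda(y = x, times = c(0, horizon - t_done), func = rhs,
                       parms = NULL, atol = 1e-9, rtol = 1e-7,
                       jacfunc = jac, jactype = "fullusr", maxsteps = 25000)),
        error = function(e) NULL)
      if (is.null(sim) || nrow(sim) < 2 || attr(sim, "istate")[1] < 0) break
      t_done <- horizon
      x <- setNames(pmax(as.numeric(sim[nrow(sim), -1]), 1e-15), sp)
      x[!dyn] <- x0[!dyn]
      res2 <- lm_solve(x, max_iter)
      total_it <- total_it + res2$it
      if (res2$ok) {
        res <- res2
        method <- "newton+integrate"
        break
      }
      if (max(abs(res2$r)) < max(abs(res$r))) {
        res <- res2
        method <- "integrate"
      }
    }
  }

  x <- setNames(as.numeric(res$x), sp)
  v <- f(x, p, scale)
  names(v) <- names(model$reactions)
  dx_full <- abs(as.numeric(M %*% v))
  structure(list(concentrations = x, fluxes = v,
                 residual_norm = if (length(dx_full)) max(dx_full) else 0,
                 converged = res$ok, iterations = total_it,
                 method = method),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat("<steady_state> converged: ", x$converged,
      " | max |dx/dt| = ", format(x$residual_norm, digits = 3),
      " mM/s | method: ", x$method, "\n", sep = "")
  invisible(x)
}

# orthonormal basis of the (right) null space of M
null_right <- function(M, tol = 1e-9) {
  sv <- svd(M, nu = 0, nv = ncol(M))
  r <- sum(sv$d > tol * max(sv$d, 1e-300))
  if (r == ncol(M)) return(matrix(0, ncol(M), 0))
  sv$v[, (r + 1):ncol(M), drop = FALSE]
}

# orthonormal basis of the left null space of M (conservation relations)
null_left <- function(M, tol = 1e-9) {
  sv <- svd(M)
  r <- sum(sv$d > tol * max(sv$d, 1e-300))
  if (r == nrow(M)) return(matrix(0, nrow(M), 0))
  sv$u[, (r + 1):nrow(M), drop = FALSE]
}

# orthonormal basis of the column space of M (directions the state can move)
range_basis <- function(M, tol = 1e-9) {
  sv <- svd(M)
  r <- sum(sv$d > tol * max(sv$d, 1e-300))
  sv$u[, seq_len(r), drop = FALSE]
}

# dense forward-difference Jacobian of g at u (g(u) pre-evaluated as g0);
# used by the toy-model oracles where sparsity is not worth exploiting
fd_jacobian <- function(g, u, g0) {
  n <- length(u)
  J <- matrix(0, length(g0), n)
  for (k in seq_len(n)) {
    h <- 1e-5 * max(abs(u[k]), 1e-9)
    up <- u
    up[k] <- u[k] + h
    J[, k] <- (g(up) - g0) / h
  }
  J
}

# tiny pseudo-inverse (avoids importing MASS for one call)
MASS_ginv <- function(A, tol = 1e-12) {
  sv <- svd(A)
  keep <- sv$d > tol * max(sv$d, 1e-300)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  sv$v[, keep, drop = FALSE] %*% (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}
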