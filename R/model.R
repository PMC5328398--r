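# Kinetic model container: compartments, species, reactions with symbolic
# rate laws, global parameter vector, stoichiometric matrix.

#' Create a reaction
#'
#' @param id reaction identifier
#' @param stoich named numeric vector, species -> signed stoichiometric
#'   coefficient (negative = consumed)
#' @param law a rate law as built by the internal constructors (list with
#'   `form`, `params`, `expr`)
#' @param modifiers ids of species entering the rate law without being
#'   consumed or produced
#' @return a `reaction` object
#' @keywords internal
new_reaction <- function(id, stoich, law, modifiers = character()) {
  if (!length(stoich) || all(stoich == 0)) {
    stop("reaction ", id, " must have at least one nonzero stoichiometric coefficient",
         call. = FALSE)
  }
  structure(list(id = id, stoich = stoich[stoich != 0], modifiers = modifiers,
                 form = law$form, params = law$params, expr = law$expr),
            class = "reaction")
}

#' Assemble a kinetic model
#'
#' Builds the model container used by the simulator and all downstream
#' analyses, checks structural consistency (referenced species exist,
#' rate-law expressions only use declared species and parameters, every
#' declared parameter appears in its expression) and assembles the
#' stoichiometric matrix.
#'
#' @param id model name
#' @param compartments data.frame with columns `id`, `volume` (relative
#'   volume, > 0), `kind` (one of environment/periplasm/cytoplasm)
#' @param species data.frame with columns `id`, `compartment`, `conc`
#'   (initial/reference concentration, mM), `boundary` (logical; boundary
#'   species are held fixed during simulation)
#' @param reactions list of `reaction` objects
#' @param params named numeric vector of all kinetic parameters, names
#'   prefixed with the reaction id (`"PGI.Vmax"`)
#' @return object of class `kinetic_model`
#' @export
kinetic_model <- function(id, compartments, species, reactions, params) {
  stopifnot(is.data.frame(compartments), is.data.frame(species), is.list(reactions))
  if (any(compartments$volume <= 0)) stop("compartment volumes must be > 0", call. = FALSE)
  if (!all(species$compartment %in% compartments$id)) {
    stop("species reference unknown compartments", call. = FALSE)
  }
  if (any(species$conc < 0)) stop("species concentrations must be >= 0", call. = FALSE)
  if (anyDuplicated(species$id)) stop("duplicated species ids", call. = FALSE)
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(names(reactions))) stop("duplicated reaction ids", call. = FALSE)

  # structural linter
  for (r in reactions) {
    bad <- setdiff(c(names(r$stoich), r$modifiers), species$id)
    if (length(bad)) {
      stop("reaction ", r$id, " references unknown species: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    declared <- pref(r$id, r$params)
    used <- all.vars(r$expr)
    bad_sym <- setdiff(used, c(species$id, declared))
    if (length(bad_sym)) {
      stop("reaction ", r$id, " rate law uses undeclared symbols: ",
           paste(bad_sym, collapse = ", "), call. = FALSE)
    }
    unused <- setdiff(declared, used)
    if (length(unused)) {
      stop("reaction ", r$id, " declares parameters absent from its rate law: ",
           paste(unused, collapse = ", "), call. = FALSE)
    }
    missing_p <- setdiff(declared, names(params))
    if (length(missing_p)) {
      stop("missing parameter values: ", paste(missing_p, collapse = ", "),
           call. = FALSE)
    }
  }
  check_parameter_signs(params)

  S <- matrix(0, nrow(species), length(reactions),
              dimnames = list(species$id, names(reactions)))
  for (r in reactions) S[names(r$stoich), r$id] <- r$stoich

  structure(list(id = id, compartments = compartments, species = species,
                 reactions = reactions, params = params, S = S),
            class = "kinetic_model")
}

check_parameter_signs <- function(params) {
  nm <- sub("^[^.]+\\.", "", names(params))
  if (any(params[startsWith(nm, "Vmax")] < 0)) stop("Vmax must be >= 0", call. = FALSE)
  if (any(params[startsWith(nm, "Km")] <= 0)) stop("Km must be > 0", call. = FALSE)
  if (any(params[startsWith(nm, "Keq")] <= 0)) stop("Keq must be > 0", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat("<kinetic_model> ", x$id, "\n", sep = "")
  cat("  compartments: ", nrow(x$compartments),
      " | species: ", nrow(x$species),
      " (", sum(x$species$boundary), " boundary)",
      " | reactions: ", length(x$reactions),
      " | parameters: ", length(x$params), "\n", sep = "")
  cen <- interaction_census(x)
  cat("  metabolite-enzyme interactions: ", cen$total,
      " (", cen$modifier_only, " modifier-only)\n", sep = "")
  invisible(x)
}

# per-species compartment volume vector
species_volumes <- function(model) {
  vol <- setNames(model$compartments$volume, model$compartments$id)
  unname(vol[model$species$compartment])
}

#' Count metabolite-enzyme interactions
#'
#' Counts, over all reactions, the distinct metabolite species appearing in
#' each rate law as reactant, product or modifier.  Species flagged as
#' enzymes (`enzyme_species`, e.g. the PTS phospho-carrier proteins) are not
#' metabolites and are excluded.  Interactions where the metabolite is
#' neither consumed nor produced (modifier-only) are the long-range
#' regulatory interactions.
#'
#' @param model a `kinetic_model`
#' @param enzyme_species species ids to exclude from the census (defaults to
#'   the model's `enzyme_species` attribute, if set)
#' @return list with `total`, `modifier_only`, `reactant_product` counts and
#'   a data.frame `edges` (reaction, species, role)
#' @export
interaction_census <- function(model, enzyme_species = attr(model, "enzyme_species")) {
  if (is.null(enzyme_species)) enzyme_species <- character()
  edges <- do.call(rbind, lapply(model$reactions, function(r) {
    rp <- setdiff(names(r$stoich), enzyme_species)
    mod <- setdiff(setdiff(r$modifiers, names(r$stoich)), enzyme_species)
    rbind(
      if (length(rp)) data.frame(reaction = r$id, species = rp, role = "reactant_product"),
      if (length(mod)) data.frame(reaction = r$id, species = mod, role = "modifier")
    )
  }))
  rownames(edges) <- NULL
  list(total = nrow(edges),
       modifier_only = sum(edges$role == "modifier"),
       reactant_product = sum(edges$role == "reactant_product"),
       edges = edges)
}

# ---- compiled evaluators ----------------------------------------------------

# opcodes of the C stack-machine evaluator (keep in sync with rate_eval.c)
RL_OPS <- c(CONST = 0L, X = 1L, P = 2L, ADD = 3L, SUB = 4L, MUL = 5L,
            DIV = 6L, POW = 7L, NEG = 8L, LOG = 9L)

# translate one rate-law expression into postfix (op, arg) pairs; returns
# NULL if the expression uses a construct outside the supported subset
expr_to_code <- function(e, sp_index, par_index) {
  code <- integer(0)
  consts <- numeric(0)
  emit <- function(op, arg = 0L) code <<- c(code, op, as.integer(arg))
  ok <- TRUE
  rec <- function(e) {
    if (!ok) return()
    if (is.numeric(e)) {
      consts <<- c(consts, as.numeric(e))
      emit(RL_OPS[["CONST"]], length(consts) - 1L)
    } else if (is.symbol(e)) {
      nm <- as.character(e)
      i <- sp_index[nm]
      j <- par_index[nm]
      if (!is.na(i)) emit(RL_OPS[["X"]], i - 1L)
      else if (!is.na(j)) emit(RL_OPS[["P"]], j - 1L)
      else ok <<- FALSE
    } else if (is.call(e)) {
      fn <- as.character(e[[1]])
      if (fn == "(") {
        rec(e[[2]])
      } else if (fn == "-" && length(e) == 2L) {
        rec(e[[2]]); emit(RL_OPS[["NEG"]])
      } else if (fn == "+" && length(e) == 2L) {
        rec(e[[2]])
      } else if (fn == "log" && length(e) == 2L) {
        rec(e[[2]]); emit(RL_OPS[["LOG"]])
      } else if (fn %in% c("+", "-", "*", "/", "^") && length(e) == 3L) {
        rec(e[[2]]); rec(e[[3]])
        emit(RL_OPS[[c("+" = "ADD", "-" = "SUB", "*" = "MUL",
                       "/" = "DIV", "^" = "POW")[fn]]])
      } else {
        ok <<- FALSE
      }
    } else {
      ok <<- FALSE
    }
  }
  rec(e)
  if (!ok) return(NULL)
  list(code = code, consts = consts)
}

# translate all rate laws; NULL if any expression is unsupported
model_bytecode <- function(model) {
  sp_index <- setNames(seq_along(model$species$id), model$species$id)
  par_index <- setNames(seq_along(model$params), names(model$params))
  code <- integer(0)
  consts <- numeric(0)
  starts <- lens <- integer(length(model$reactions))
  for (k in seq_along(model$reactions)) {
    bc <- expr_to_code(model$reactions[[k]]$expr, sp_index, par_index)
    if (is.null(bc)) return(NULL)
    # rebase constant indices into the shared constant table
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
  list(code = code, starts = starts, lens = lens,
       consts = if (length(consts)) consts else 0)
}

# Build a fast function (x, p, scale) -> flux vector.  Uses the C
# stack-machine evaluator when every rate law falls in its expression
# subset (always true for the models built by this package), otherwise a
# generated byte-compiled R function.
compile_rates <- function(model) {
  bc <- model_bytecode(model)
  sym <- tryCatch(getNativeSymbolInfo("C_eval_rates"), error = function(e) NULL)
  if (!is.null(bc) && !is.null(sym)) {
    code <- as.integer(bc$code)
    starts <- as.integer(bc$starts)
    lens <- as.integer(bc$lens)
    consts <- as.numeric(bc$consts)
    n_rxn <- length(model$reactions)
    f <- function(x, p, scale) {
      if (length(scale) == 1L) scale <- rep(as.numeric(scale), n_rxn)
      .Call(sym, code, starts, lens, consts,
            as.numeric(x), as.numeric(p), as.numeric(scale))
    }
    return(f)
  }
  compile_rates_r(model)
}

# pure-R evaluator (fallback and independent cross-check of the C path)
compile_rates_r <- function(model) {
  sp <- model$species$id
  pn <- names(model$params)
  exprs <- vapply(model$reactions, function(r) deparse1(r$expr), "")
  txt <- paste0(
    "function(x, p, scale) {\n",
    paste(sprintf("`%s` <- x[[%d]]", sp, seq_along(sp)), collapse = "\n"), "\n",
    paste(sprintf("`%s` <- p[[%d]]", pn, seq_along(pn)), collapse = "\n"), "\n",
    "scale * c(", paste(exprs, collapse = ",\n"), ")\n}"
  )
  f <- eval(parse(text = txt), envir = baseenv())
  compiler::cmpfun(f)
}

# retrieve (and cache on the model, by attribute) the compiled rate function
model_rate_fn <- function(model) {
  f <- attr(model, ".rate_fn")
  if (is.null(f)) f <- compile_rates(model)
  f
}

#' Attach the compiled rate evaluator to a model
#'
#' Compiling the 68 rate-law expressions into one function is cheap but not
#' free; ensemble workflows call [steady_state()] thousands of times, so the
#' compiled evaluator is cached on the model object.  Any function returning
#' a modified model drops the cache automatically (attributes are rebuilt).
#'
#' @param model a `kinetic_model`
#' @return the model with a cached evaluator attribute
#' @export
compile_model <- function(model) {
  attr(model, ".rate_fn") <- compile_rates(model)
  attr(model, ".jac_info") <- jac_structure(model)
  attr(model, ".jac_sym") <- jac_symbolic(model)
  model
}

#' Evaluate all reaction rates at a given state
#'
#' @param model a `kinetic_model`
#' @param concentrations named (or model-ordered) vector of concentrations
#'   (mM); must be complete, finite and non-negative
#' @param scale optional per-reaction rate multipliers (enzyme-level scale
#'   factors), default 1
#' @return named vector of reaction rates (mM/s, cytoplasm basis)
#' @export
evaluate_rates <- function(model, concentrations, scale = 1) {
  x <- order_concs(model, concentrations)
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("concentrations must be finite and non-negative", call. = FALSE)
  }
  f <- model_rate_fn(model)
  v <- f(x, model$params, scale)
  names(v) <- names(model$reactions)
  v
}

order_concs <- function(model, concentrations) {
  sp <- model$species$id
  if (is.null(names(concentrations))) {
    if (length(concentrations) != length(sp)) {
      stop("concentration vector has wrong length", call. = FALSE)
    }
    return(as.numeric(concentrations))
  }
  missing_sp <- setdiff(sp, names(concentrations))
  if (length(missing_sp)) {
    stop("missing concentrations for: ", paste(missing_sp, collapse = ", "),
         call. = FALSE)
  }
  as.numeric(concentrations[sp])
}

#' Scale enzyme levels (Vmax) of a model
#'
#' Multiplies each reaction's rate by a factor, equivalent to scaling its
#' Vmax / rate constant: all rate laws in the package are linear in their
#' capacity parameter.
#'
#' @param model a `kinetic_model`
#' @param factors named or reaction-ordered vector of scale factors
#' @return the factors, ordered like `model$reactions` (helper used by the
#'   ensemble and control-analysis code)
#' @keywords internal
order_factors <- function(model, factors) {
  rn <- names(model$reactions)
  if (length(factors) == 1L && is.null(names(factors))) {
    return(rep(as.numeric(factors), length(rn)))
  }
  if (!is.null(names(factors))) {
    out <- rep(1, length(rn))
    names(out) <- rn
    out[names(factors)] <- factors
    return(unname(out))
  }
  if (length(factors) != length(rn)) stop("wrong number of scale factors", call. = FALSE)
  as.numeric(factors)
}

#' Set a species as boundary (fixed concentration)
#'
#' @param model a `kinetic_model`
#' @param species species id
#' @param conc optional fixed concentration (mM)
#' @param boundary logical flag
#' @return modified model
#' @export
set_boundary <- function(model, species, conc = NULL, boundary = TRUE) {
  i <- match(species, model$species$id)
  if (any(is.na(i))) stop("unknown species: ",
                          paste(species[is.na(i)], collapse = ", "), call. = FALSE)
  model$species$boundary[i] <- boundary
  if (!is.null(conc)) model$species$conc[i] <- conc
  model
}

#' Update kinetic parameter values
#'
#' @param model a `kinetic_model`
#' @param values named numeric vector of (prefixed) parameter values
#' @return modified model
#' @export
set_params <- function(model, values) {
  bad <- setdiff(names(values), names(model$params))
  if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "), call. = FALSE)
  model$params[names(values)] <- values
  check_parameter_signs(model$params)
  model
}

#' Conserved-moiety matrix
#'
#' Left null space of the volume-scaled stoichiometric matrix restricted to
#' dynamic (non-boundary) species: each column is a conservation relation
#' `sum_i c_i x_i = const` along any trajectory.  Computed, not assumed.
#'
#' @param model a `kinetic_model`
#' @param tol singular-value tolerance
#' @return matrix (dynamic species x n_moieties), possibly with 0 columns
#' @export
moiety_matrix <- function(model, tol = 1e-9) {
  dyn <- !model$species$boundary
  M <- model$S[dyn, , drop = FALSE] / species_volumes(model)[dyn]
  sv <- svd(M)
  r <- sum(sv$d > tol * max(sv$d))
  if (r == nrow(M)) {
    return(matrix(0, nrow(M), 0, dimnames = list(model$species$id[dyn], NULL)))
  }
  C <- sv$u[, (r + 1):nrow(M), drop = FALSE]
  rownames(C) <- model$species$id[dyn]
  C
}
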