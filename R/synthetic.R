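# Synthetic data: analytic toy kinetic networks, noisy pseudo-experimental
# calibration datasets, and synthetic validation flux tables.  Everything a
# test needs is generated here in code -- no external files.

toy_compartment <- function() {
  data.frame(id = "cytoplasm", volume = 1, kind = "cytoplasm")
}

#' Boundary-fed linear toy pathway with a closed-form steady state
#'
#' Builds a chain: a constant feed (rate `feed` mM/s) into M1, then
#' `n_steps - 1` consuming steps M1 -> M2 -> ... -> (sink).  Steps are
#' irreversible mass action (`"ma"`, rate `k * M`) or irreversible
#' Michaelis-Menten (`"mm"`, rate `Vmax * M / (Km + M)`, requires
#' `Vmax > feed`).  At steady state every step carries the feed flux, so
#' each intermediate solves its own step's rate law in closed form.
#'
#' @param n_steps total number of reactions (>= 2, including the feed)
#' @param forms form of each consuming step: `"ma"` or `"mm"`, recycled
#' @param feed feed rate (mM/s)
#' @param k rate constants of the `"ma"` steps (recycled)
#' @param vmax,km parameters of the `"mm"` steps (recycled)
#' @return list with `model` (a `kinetic_model`) and `steady_state`
#'   (analytic concentrations and fluxes)
#' @export
make_toy_chain <- function(n_steps, forms = "ma", feed = 1, k = 2,
                           vmax = 4, km = 1) {
  if (n_steps < 2) stop("n_steps must be >= 2", call. = FALSE)
  n_met <- n_steps - 1L
  forms <- rep_len(forms, n_met)
  bad <- setdiff(forms, c("ma", "mm"))
  if (length(bad)) stop("unsupported form(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  k <- rep_len(k, n_met)
  vmax <- rep_len(vmax, n_met)
  km <- rep_len(km, n_met)
  mets <- paste0("M", seq_len(n_met))

  # analytic steady state: every step carries `feed`
  conc <- numeric(n_met)
  for (i in seq_len(n_met)) {
    conc[i] <- if (forms[i] == "ma") feed / k[i]
    else {
      if (vmax[i] <= feed) stop("mm step ", i, " needs Vmax > feed", call. = FALSE)
      km[i] * feed / (vmax[i] - feed)
    }
  }

  reactions <- list(new_reaction("FEED", c(M1 = 1), rl_const("FEED")))
  params <- c(FEED.Vmax = feed)
  for (i in seq_len(n_met)) {
    rid <- paste0("STEP", i)
    stoich <- setNames(-1, mets[i])
    if (i < n_met) stoich <- c(stoich, setNames(1, mets[i + 1L]))
    if (forms[i] == "ma") {
      law <- rl_mass_action(rid, mets[i], 1, reversible = FALSE)
      params <- c(params, setNames(k[i], pref(rid, "kf")))
    } else {
      law <- rl_irr_mm(rid, mets[i], 1)
      params <- c(params, setNames(c(vmax[i], km[i]),
                                   pref(rid, c("Vmax", paste0("Km_", mets[i])))))
    }
    reactions <- c(reactions, list(new_reaction(rid, stoich, law)))
  }
  species <- data.frame(id = mets, compartment = "cytoplasm", conc = conc,
                        boundary = FALSE)
  model <- compile_model(kinetic_model("toy_chain", toy_compartment(), species,
                                       reactions, params))
  fluxes <- setNames(rep(feed, n_steps), names(model$reactions))
  list(model = model,
       steady_state = list(concentrations = setNames(conc, mets),
                           fluxes = fluxes))
}

#' Branched toy network with a closed-form steady state
#'
#' A feed into M1 that drains through two competing mass-action branches
#' (rates `k_a * M1`, `k_b * M1`); the branch point is the minimal test case
#' for flux-partition control.
#'
#' @param feed feed rate (mM/s)
#' @param k_a,k_b branch rate constants
#' @return list with `model` and analytic `steady_state`
#' @export
make_toy_branch <- function(feed = 1, k_a = 2, k_b = 3) {
  m1 <- feed / (k_a + k_b)
  reactions <- list(
    new_reaction("FEED", c(M1 = 1), rl_const("FEED")),
    new_reaction("BR_A", c(M1 = -1), rl_mass_action("BR_A", "M1", 1, reversible = FALSE)),
    new_reaction("BR_B", c(M1 = -1), rl_mass_action("BR_B", "M1", 1, reversible = FALSE)))
  params <- c(FEED.Vmax = feed, BR_A.kf = k_a, BR_B.kf = k_b)
  species <- data.frame(id = "M1", compartment = "cytoplasm", conc = m1,
                        boundary = FALSE)
  model <- compile_model(kinetic_model("toy_branch", toy_compartment(), species,
                                       reactions, params))
  list(model = model,
       steady_state = list(concentrations = c(M1 = m1),
                           fluxes = c(FEED = feed, BR_A = k_a * m1,
                                      BR_B = k_b * m1)))
}

#' Cofactor-cycle toy network with a conserved moiety
#'
#' A feed into M, which is consumed by a cofactor-coupled step
#' (`M + C -> D`, mass action `k2 * M * C`) with cofactor regeneration
#' (`D -> C`, `k3 * D`).  The total `C + D` is conserved, so this is the
#' minimal test case for the conserved-moiety machinery.
#'
#' @param feed feed rate (mM/s)
#' @param k2,k3 rate constants
#' @param c_total conserved cofactor total (mM); requires
#'   `c_total > feed / k3`
#' @return list with `model` and analytic `steady_state`
#' @export
make_toy_cycle <- function(feed = 1, k2 = 5, k3 = 2, c_total = 2) {
  d <- feed / k3
  if (d >= c_total) stop("need c_total > feed / k3", call. = FALSE)
  cc <- c_total - d
  m <- feed / (k2 * cc)
  reactions <- list(
    new_reaction("FEED", c(M = 1), rl_const("FEED")),
    new_reaction("USE", c(M = -1, C = -1, D = 1),
                 rl_mass_action("USE", c("M", "C"), c(1, 1), reversible = FALSE)),
    new_reaction("REGEN", c(D = -1, C = 1),
                 rl_mass_action("REGEN", "D", 1, reversible = FALSE)))
  params <- c(FEED.Vmax = feed, USE.kf = k2, REGEN.kf = k3)
  species <- data.frame(id = c("M", "C", "D"), compartment = "cytoplasm",
                        conc = c(m, cc, d), boundary = FALSE)
  model <- compile_model(kinetic_model("toy_cycle", toy_compartment(), species,
                                       reactions, params))
  list(model = model,
       steady_state = list(concentrations = c(M = m, C = cc, D = d),
                           fluxes = c(FEED = feed, USE = feed, REGEN = feed)))
}

#' Closed reversible isomerization with an analytic trajectory
#'
#' `A <-> B` by reversible mass action (`kf`, `kr`): the relaxation to
#' equilibrium is a single exponential,
#' `A(t) = A_eq + (A_0 - A_eq) exp(-(kf + kr) t)` with
#' `A_eq = kr (A_0 + B_0) / (kf + kr)` -- the closed-form oracle for the
#' time-course integrator.
#'
#' @param kf,kr forward and backward rate constants (1/s)
#' @param a0,b0 initial concentrations (mM)
#' @return list with `model`, `analytic` (function of t returning A), and
#'   `rate` (`kf + kr`)
#' @export
make_reversible_pair <- function(kf = 1, kr = 0.5, a0 = 1, b0 = 0) {
  reactions <- list(
    new_reaction("ISO", c(A = -1, B = 1),
                 rl_mass_action("ISO", "A", 1, "B", 1, reversible = TRUE)))
  params <- c(ISO.kf = kf, ISO.Keq = kf / kr)
  species <- data.frame(id = c("A", "B"), compartment = "cytoplasm",
                        conc = c(a0, b0), boundary = FALSE)
  model <- compile_model(kinetic_model("toy_iso", toy_compartment(), species,
                                       reactions, params))
  a_eq <- kr * (a0 + b0) / (kf + kr)
  list(model = model,
       analytic = function(t) a_eq + (a0 - a_eq) * exp(-(kf + kr) * t),
       rate = kf + kr)
}

#' Generate a noisy pseudo-experimental calibration dataset
#'
#' Simulates the requested observables under each condition and perturbs
#' them with Gaussian noise of relative standard deviation `noise_sigma`
#' (per-point sigma recorded, as weighted least squares requires).
#'
#' @param model a `kinetic_model`
#' @param observables character vector, entries `"flux:ID"` or `"conc:ID"`
#' @param conditions named list of conditions (each a list with optional
#'   `boundary` named concentrations and `scale` factors); default one
#'   unmodified condition
#' @param times numeric vector of time points (s) for time-course
#'   observables, or `NULL` for steady-state points
#' @param noise_sigma relative noise level (0 = exact)
#' @param seed integer seed
#' @return data.frame (`observable`, `condition`, `time`, `value`, `sigma`)
#'   with the `conditions` list attached as an attribute
#' @export
make_calibration_data <- function(model, observables,
                                  conditions = list(default = list()),
                                  times = NULL, noise_sigma = 0.05, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (cid in names(conditions)) {
    cond <- conditions[[cid]]
    mc <- model
    if (!is.null(cond$boundary)) {
      mc <- set_boundary(mc, names(cond$boundary), unname(cond$boundary))
    }
    scale <- if (is.null(cond$scale)) 1 else cond$scale
    if (is.null(times)) {
      st <- steady_state(mc, scale = scale)
      if (!st$converged) stop("condition ", cid, ": steady state failed",
                              call. = FALSE)
      y <- vapply(observables, observe, 0, st = st)
      rows[[length(rows) + 1L]] <- data.frame(
        observable = observables, condition = cid, time = NA_real_, truth = y)
    } else {
      tr <- tryCatch(simulate_model(mc, times, scale = scale),
                     error = function(e) stop("condition ", cid,
                                              ": simulation failed", call. = FALSE))
      for (obs in observables) {
        sp_id <- sub("^conc:", "", obs)
        rows[[length(rows) + 1L]] <- data.frame(
          observable = obs, condition = cid, time = times,
          truth = tr[match(times, tr$time), sp_id])
      }
    }
  }
  df <- do.call(rbind, rows)
  df$sigma <- pmax(noise_sigma * abs(df$truth), 1e-12)
  if (noise_sigma == 0) df$sigma <- pmax(1e-6 * abs(df$truth), 1e-12)
  df$value <- df$truth + if (noise_sigma > 0)
    stats::rnorm(nrow(df), 0, df$sigma) else 0
  df$truth <- NULL
  rownames(df) <- NULL
  attr(df, "conditions") <- conditions
  df
}

#' Synthetic validation flux table
#'
#' Emulates a literature compilation of growth experiments: subsamples
#' converged ensemble states and perturbs the four headline fluxes (growth
#' rate, glucose uptake, oxygen uptake, citrate-synthase flux) with
#' multiplicative lognormal noise, the natural noise family for flux
#' measurements.
#'
#' @param ensemble an `ensemble_result`
#' @param n_rows number of synthetic experiments (default 254)
#' @param noise_sigma lognormal sigma (0 = exact states)
#' @param seed integer seed
#' @return data.frame (`experiment`, `growth_rate` 1/h, `glc_uptake`,
#'   `o2_uptake`, `citrate_synthase_flux` mM/s)
#' @export
make_validation_table <- function(ensemble, n_rows = 254, noise_sigma = 0.1,
                                  seed = 1) {
  ok <- which(ensemble$converged)
  if (length(ok) < n_rows) {
    stop("ensemble has only ", length(ok), " converged states, need ", n_rows,
         call. = FALSE)
  }
  set.seed(seed)
  pick <- sample(ok, n_rows)
  noise <- function(x) x * exp(stats::rnorm(length(x), 0, noise_sigma))
  data.frame(
    experiment = seq_len(n_rows),
    growth_rate = noise(ensemble$fluxes[pick, "GROWTH"] * 3600),
    glc_uptake = noise(ensemble$fluxes[pick, "PTS4"]),
    o2_uptake = noise(ensemble$fluxes[pick, "O2_TR"]),
    citrate_synthase_flux = noise(ensemble$fluxes[pick, "GLT"]))
}

#' Write / read a calibration dataset as TSV
#'
#' The conditions list is serialized as JSON in a header comment, so the
#' file round-trips completely.
#'
#' @param dataset a calibration dataset
#' @param path file path
#' @return the path (writer, invisibly) / the dataset (reader)
#' @export
write_dataset_tsv <- function(dataset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  conds <- attr(dataset, "conditions")
  # named vectors become JSON objects (names survive the round trip)
  conds_j <- lapply(conds, function(cd) lapply(cd, as.list))
  writeLines(paste0("#conditions ", jsonlite::toJSON(conds_j, digits = NA,
                                                     auto_unbox = TRUE)), con)
  utils::write.table(format(dataset, digits = 17, trim = TRUE), con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_tsv
#' @export
read_dataset_tsv <- function(path) {
  first <- readLines(path, n = 1)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  df$time <- as.numeric(df$time)
  df$value <- as.numeric(df$value)
  df$sigma <- as.numeric(df$sigma)
  if (startsWith(first, "#conditions ")) {
    conds <- jsonlite::fromJSON(sub("^#conditions ", "", first),
                                simplifyVector = FALSE)
    attr(df, "conditions") <- lapply(conds, function(cd) lapply(cd, unlist))
  }
  df
}
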