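# Rate laws of the central carbon / energy network.
#
# All concentrations are mM, all rates mM/s referenced to cytoplasmic volume,
# time is s.  Rate laws are stored as symbolic R expressions in species ids
# and reaction-prefixed parameter names ("PGI.Vmax"), so they can be
# evaluated, linted and exported to SBML/MathML.

#' Trans-membrane pH difference
#'
#' Computes the pH difference across the inner membrane from the proton
#' concentrations on each side, `log10(h_cytoplasm / h_periplasm)`.  pH is a
#' base-10 quantity, so the base-10 logarithm is used.  With a periplasm more
#' acidic than the cytoplasm the value is negative; the respiratory rate laws
#' depend only on even powers of it.
#'
#' @param h_cytoplasm cytoplasmic proton concentration (mM), > 0
#' @param h_periplasm periplasmic proton concentration (mM), > 0
#' @return dimensionless pH difference (cytoplasm minus periplasm)
#' @examples
#' delta_ph(1e-4, 1e-4)      # 0
#' delta_ph(1e-3, 1e-4)      # 1: one pH unit
#' @export
delta_ph <- function(h_cytoplasm, h_periplasm) {
  if (any(!is.finite(h_cytoplasm)) || any(!is.finite(h_periplasm)) ||
      any(h_cytoplasm <= 0) || any(h_periplasm <= 0)) {
    stop("proton concentrations must be positive and finite", call. = FALSE)
  }
  log10(h_cytoplasm / h_periplasm)
}

#' Oxidative-phosphorylation rate laws
#'
#' Literal mass-action rate laws of the respiratory chain and ATP synthase,
#' with the sigmoidal proton-motive gating of the proton pumps (NDH-I,
#' cytochrome bo oxidase) and of the ATP synthase:
#' \itemize{
#'  \item `ndhi`:    `Vmax * 1/(1+dpH^2) * (NADH*Q - NAD*QH2/Keq)`
#'  \item `ndh2`:    `Vmax * (NADH*Q - NAD*QH2/Keq)`
#'  \item `sqr`:     `Vmax * (FADH2*Q - FAD*QH2/Keq)`
#'  \item `cytbo`:   `Vmax * 1/(1+dpH^2) * (QH2^2*O2 - Q^2/Keq)`
#'  \item `atp_syn`: `Vmax * dpH^4/(1+dpH^4) * (ADP*P - ATP/Keq)`
#' }
#' `dpH` is taken from `concentrations["dpH"]` if present, otherwise computed
#' with [delta_ph()] from `concentrations["H_c"]` and `concentrations["H_p"]`.
#'
#' @param form one of `"ndhi"`, `"ndh2"`, `"sqr"`, `"cytbo"`, `"atp_syn"`
#' @param concentrations named vector of the involved concentrations (mM)
#' @param params named list/vector with `Vmax` (mM/s) and `Keq` (> 0)
#' @return rate in mM/s
#' @export
rate_oxphos <- function(form, concentrations, params) {
  forms <- c("ndhi", "ndh2", "sqr", "cytbo", "atp_syn")
  if (!is.character(form) || length(form) != 1L || !form %in% forms) {
    stop("unknown oxidative-phosphorylation rate-law form: ",
         paste(form, collapse = ", "), call. = FALSE)
  }
  conc <- as.list(concentrations)
  need_par <- c("Vmax", "Keq")
  missing_par <- setdiff(need_par, names(params))
  if (length(missing_par)) {
    stop("missing parameter(s): ", paste(missing_par, collapse = ", "),
         call. = FALSE)
  }
  vmax <- as.numeric(params[["Vmax"]])
  keq <- as.numeric(params[["Keq"]])
  if (vmax < 0) stop("Vmax must be >= 0", call. = FALSE)
  if (keq <= 0) stop("Keq must be > 0", call. = FALSE)

  need_conc <- switch(form,
    ndhi = , ndh2 = c("NADH", "Q", "NAD", "QH2"),
    sqr = c("FADH2", "Q", "FAD", "QH2"),
    cytbo = c("QH2", "O2", "Q"),
    atp_syn = c("ADP", "P", "ATP"))
  missing_conc <- setdiff(need_conc, names(conc))
  if (length(missing_conc)) {
    stop("missing concentration(s): ", paste(missing_conc, collapse = ", "),
         call. = FALSE)
  }
  if (any(unlist(conc[need_conc]) < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  dph <- if ("dpH" %in% names(conc)) as.numeric(conc[["dpH"]])
         else delta_ph(conc[["H_c"]], conc[["H_p"]])

  with(conc, switch(form,
    ndhi    = vmax * (1 / (1 + dph^2)) * (NADH * Q - NAD * QH2 / keq),
    ndh2    = vmax * (NADH * Q - NAD * QH2 / keq),
    sqr     = vmax * (FADH2 * Q - FAD * QH2 / keq),
    cytbo   = vmax * (1 / (1 + dph^2)) * (QH2^2 * O2 - Q^2 / keq),
    atp_syn = vmax * (dph^4 / (1 + dph^4)) * (ADP * P - ATP / keq)))
}

#' Multiplicative growth rate law
#'
#' Growth rate as a saturable function of every biomass building block:
#' `mu = Vmax * prod_i S_i / (S_i + Km_i)`.  The rate increases monotonically
#' with each pool, saturates at `Vmax`, and vanishes when any pool vanishes,
#' so building blocks are consumed in fixed stoichiometric proportions.
#'
#' @param s building-block concentrations (mM), named or not
#' @param km half-saturation constants (mM), recycled against `s`
#' @param vmax maximal specific growth rate (1/s)
#' @return specific growth rate mu (1/s)
#' @export
rate_growth <- function(s, km, vmax) {
  if (length(s) == 0L) stop("empty building-block list", call. = FALSE)
  if (length(km) != length(s)) km <- rep_len(km, length(s))
  if (any(km <= 0)) stop("Km values must be > 0", call. = FALSE)
  if (any(s < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (vmax < 0) stop("Vmax must be >= 0", call. = FALSE)
  vmax * prod(s / (s + km))
}

#' Porin-facilitated exchange rate (reversible Michaelis-Menten)
#'
#' Saturable diffusion through an outer-membrane porin:
#' `v = Vmax * (s_out - s_in/Keq) / (Km + s_out + s_in * Km / Km_in)`.
#' The sign follows the concentration gradient, the rate is zero at the
#' `Keq`-defined equilibrium and saturates at `Vmax` for `s_out >> Km`,
#' `s_in = 0`.
#'
#' @param s_out concentration on the outer side (mM)
#' @param s_in concentration on the inner side (mM)
#' @param params named list/vector with `Vmax`, `Km` (> 0), `Keq` (> 0) and
#'   optionally `Km_in` (defaults to `Km`)
#' @return rate in mM/s (positive = inward)
#' @export
rate_exchange_porin <- function(s_out, s_in, params) {
  p <- as.list(params)
  for (nm in c("Vmax", "Km", "Keq")) {
    if (is.null(p[[nm]])) stop("missing parameter: ", nm, call. = FALSE)
  }
  if (p$Km <= 0) stop("Km must be > 0", call. = FALSE)
  if (p$Keq <= 0) stop("Keq must be > 0", call. = FALSE)
  if (any(c(s_out, s_in) < 0)) stop("concentrations must be >= 0", call. = FALSE)
  km_in <- if (is.null(p$Km_in)) p$Km else p$Km_in
  p$Vmax * (s_out - s_in / p$Keq) / (p$Km + s_out + s_in * p$Km / km_in)
}

# ---- symbolic rate-law constructors (internal) -------------------------------

# A rate_law is list(form, params = character vector of *unprefixed* names,
# expr = R expression using species ids and prefixed parameter symbols).

pref <- function(rid, nm) paste0(rid, ".", nm)
bq <- function(nm) paste0("`", nm, "`")

rl_parse <- function(form, rid, pars, text) {
  list(form = form,
       params = pars,
       expr = str2lang(text))
}

# power helper: "X" or "X^2"
pw <- function(sp, n) if (n == 1) sp else paste0(sp, "^", n)

# constant-rate law (e.g. chemostat feed): v = Vmax
rl_const <- function(rid) {
  rl_parse("constant", rid, "Vmax", bq(pref(rid, "Vmax")))
}

# (ir)reversible mass action on the reaction's stoichiometry
rl_mass_action <- function(rid, sub, sub_n, prod = character(), prod_n = numeric(),
                           reversible = TRUE) {
  fwd <- paste(mapply(pw, sub, sub_n), collapse = "*")
  if (!reversible || !length(prod)) {
    return(rl_parse("mass_action_irreversible", rid, "kf",
                    paste0(bq(pref(rid, "kf")), "*", fwd)))
  }
  back <- paste(mapply(pw, prod, prod_n), collapse = "*")
  rl_parse("mass_action_reversible", rid, c("kf", "Keq"),
           sprintf("%s*(%s - %s/%s)", bq(pref(rid, "kf")), fwd, back,
                   bq(pref(rid, "Keq"))))
}

# generalized reversible Michaelis-Menten (convenience-kinetics denominator)
rl_rev_mm <- function(rid, sub, sub_n, prod, prod_n) {
  kms <- paste0("Km_", c(sub, prod))
  s_sc <- mapply(function(s, n) pw(sprintf("(%s/%s)", s, bq(pref(rid, paste0("Km_", s)))), n),
                 sub, sub_n)
  p_sc <- mapply(function(s, n) pw(sprintf("(%s/%s)", s, bq(pref(rid, paste0("Km_", s)))), n),
                 prod, prod_n)
  s_den <- mapply(function(s, n) pw(sprintf("(1 + %s/%s)", s, bq(pref(rid, paste0("Km_", s)))), n),
                  sub, sub_n)
  p_den <- mapply(function(s, n) pw(sprintf("(1 + %s/%s)", s, bq(pref(rid, paste0("Km_", s)))), n),
                  prod, prod_n)
  txt <- sprintf("%s*(%s - (%s)/%s)/(%s + %s - 1)",
                 bq(pref(rid, "Vmax")),
                 paste(s_sc, collapse = "*"),
                 paste(p_sc, collapse = "*"),
                 bq(pref(rid, "Keq")),
                 paste(s_den, collapse = "*"),
                 paste(p_den, collapse = "*"))
  rl_parse("reversible_michaelis_menten", rid, c("Vmax", "Keq", kms), txt)
}

# irreversible Michaelis-Menten with competitive product binding:
# v = Vmax * prod (S/(S+Km))^n * prod 1/(1+P/Kp).  The product terms give
# every irreversible step the saturable product feedback real enzymes have.
rl_irr_mm <- function(rid, sub, sub_n, prod = character()) {
  kms <- paste0("Km_", sub)
  terms <- mapply(function(s, n) pw(sprintf("(%s/(%s + %s))", s, s, bq(pref(rid, paste0("Km_", s)))), n),
                  sub, sub_n)
  pars <- c("Vmax", kms)
  txt <- paste0(bq(pref(rid, "Vmax")), "*", paste(terms, collapse = "*"))
  if (length(prod)) {
    pterms <- vapply(prod, function(s)
      sprintf("(1/(1 + %s/%s))", s, bq(pref(rid, paste0("Kp_", s)))), "")
    txt <- paste0(txt, "*", paste(pterms, collapse = "*"))
    pars <- c(pars, paste0("Kp_", prod))
  }
  rl_parse("irreversible_michaelis_menten", rid, pars, txt)
}

# multiply a law by a hyperbolic/Hill inhibition term 1/(1+(I/Ki)^n)
rl_inhibit <- function(law, rid, sp, hill = FALSE) {
  ki <- paste0("Ki_", sp)
  if (hill) {
    nn <- paste0("n_", sp)
    term <- sprintf("(1/(1 + (%s/%s)^%s))", sp, bq(pref(rid, ki)), bq(pref(rid, nn)))
    law$params <- c(law$params, ki, nn)
  } else {
    term <- sprintf("(1/(1 + %s/%s))", sp, bq(pref(rid, ki)))
    law$params <- c(law$params, ki)
  }
  law$expr <- str2lang(paste0(deparse1(law$expr), " * ", term))
  law
}

# multiply a law by an activation term (A/Ka)^n / (1+(A/Ka)^n)
rl_activate <- function(law, rid, sp, hill = FALSE) {
  ka <- paste0("Ka_", sp)
  if (hill) {
    nn <- paste0("n_", sp)
    term <- sprintf("((%s/%s)^%s/(1 + (%s/%s)^%s))", sp, bq(pref(rid, ka)),
                    bq(pref(rid, nn)), sp, bq(pref(rid, ka)), bq(pref(rid, nn)))
    law$params <- c(law$params, ka, nn)
  } else {
    term <- sprintf("((%s/%s)/(1 + %s/%s))", sp, bq(pref(rid, ka)), sp, bq(pref(rid, ka)))
    law$params <- c(law$params, ka)
  }
  law$expr <- str2lang(paste0(deparse1(law$expr), " * ", term))
  law
}

# proton-motive gating helper used by the oxidative-phosphorylation laws;
# written with log() so the expression stays differentiable by stats::D
dph_txt <- "((log(H_c/H_p))/2.302585092994046)"

rl_oxphos <- function(rid, form) {
  body <- switch(form,
    ndhi    = sprintf("%%s * (1/(1 + %s^2)) * (NADH*Q - NAD*QH2/%%s)", dph_txt),
    ndh2    = "%s * (NADH*Q - NAD*QH2/%s)",
    sqr     = "%s * (FADH2*Q - FAD*QH2/%s)",
    cytbo   = sprintf("%%s * (1/(1 + %s^2)) * (QH2^2*O2 - Q^2/%%s)", dph_txt),
    atp_syn = sprintf("%%s * (%s^4/(1 + %s^4)) * (ADP*P - ATP/%%s)", dph_txt, dph_txt),
    stop("unknown oxphos form: ", form))
  rl_parse(form, rid, c("Vmax", "Keq"),
           sprintf(body, bq(pref(rid, "Vmax")), bq(pref(rid, "Keq"))))
}

rl_growth <- function(rid, precursors) {
  kms <- paste0("Km_", precursors)
  terms <- vapply(precursors, function(s)
    sprintf("(%s/(%s + %s))", s, s, bq(pref(rid, paste0("Km_", s)))), "")
  rl_parse("growth_multiplicative", rid, c("Vmax", kms),
           paste0(bq(pref(rid, "Vmax")), "*", paste(terms, collapse = "*")))
}
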