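# Functional-coupling analysis: systemic physiological variables per steady
# state, pairwise Spearman rank correlation and mutual information, and
# metabolite homeostasis summaries.

#' Systemic physiological variables of an ensemble
#'
#' For every converged steady state, computes the variables that summarize
#' the physiological state of the cell: growth rate (1/h), glucose and
#' oxygen uptake rates (mM/s, cytoplasm basis), gross ATP / NADH / NADPH
#' production rates (stoichiometry-weighted sums over producing reactions),
#' biomass and cofactor yields (per glucose uptake), sum of absolute
#' intracellular fluxes (exchange and feed steps excluded), enzyme cost
#' (amino acids x concentration, scaled by the sampled enzyme factors),
#' total intracellular metabolite pool (mM, cytoplasmic metabolites), the
#' derived ratios ATP production / sum of fluxes, enzyme cost / sum of
#' fluxes and sum of fluxes / glucose uptake, and absolute plus relative
#' (per glucose uptake) fluxes of pathway-representative steps (citrate
#' synthase for the TCA cycle, G6P dehydrogenase for the PPP, phosphogluconate
#' dehydratase for the ED pathway, isocitrate lyase for the glyoxylate
#' shunt, acetate kinase for overflow metabolism).
#'
#' Rows with zero glucose uptake get `NA` yields (excluded from rank
#' statistics by the correlation functions).
#'
#' @param ensemble an `ensemble_result`
#' @param model the `kinetic_model` the ensemble was run on (defaults to the
#'   one stored in the ensemble)
#' @param enzyme_table optional data.frame (reaction, conc_uM, aa_count) for
#'   the enzyme cost; defaults to the packaged synthetic abundance table
#' @return data.frame, one row per converged steady state
#' @export
systemic_variables <- function(ensemble, model = ensemble$model,
                               enzyme_table = NULL) {
  ok <- ensemble$converged
  if (!any(ok)) stop("ensemble has no converged states", call. = FALSE)
  flux <- ensemble$fluxes[ok, , drop = FALSE]
  conc <- ensemble$concentrations[ok, , drop = FALSE]
  fact <- ensemble$factors[ok, , drop = FALSE]
  rn <- colnames(flux)
  S <- model$S

  gross_production <- function(sp) {
    coef <- S[sp, ]
    prod_mat <- sweep(flux, 2, coef, `*`)
    prod_mat[prod_mat < 0] <- 0
    rowSums(prod_mat)
  }

  exchange <- c("GLC_FEED", "ACE_OUT", "XCH_GLC", "XCH_ACE", "XCH_P", "O2_TR")
  intra <- setdiff(rn, exchange)
  cyto_mets <- model$species$id[model$species$compartment == "cytoplasm" &
                                  !model$species$id %in% attr(model, "enzyme_species")]

  if (is.null(enzyme_table)) enzyme_table <- enzyme_abundance_table()
  cost <- apply(fact, 1, function(f)
    enzyme_cost(f, setNames(enzyme_table$conc_uM, enzyme_table$reaction),
                setNames(enzyme_table$aa_count, enzyme_table$reaction)))

  glc <- flux[, "PTS4"]
  growth <- flux[, "GROWTH"] * 3600
  sum_flux <- rowSums(abs(flux[, intra, drop = FALSE]))
  atp <- gross_production("ATP")
  nadh <- gross_production("NADH")
  nadph <- gross_production("NADPH")
  yield_of <- function(x) ifelse(glc > 0, x / glc, NA_real_)

  out <- data.frame(
    growth_rate = growth,
    glc_uptake = glc,
    o2_uptake = flux[, "O2_TR"],
    atp_production = atp,
    nadh_production = nadh,
    nadph_production = nadph,
    biomass_yield = yield_of(growth),
    atp_yield = yield_of(atp),
    nadh_yield = yield_of(nadh),
    nadph_yield = yield_of(nadph),
    sum_flux = sum_flux,
    enzyme_cost = cost,
    total_pool = rowSums(conc[, cyto_mets, drop = FALSE]),
    atp_per_sumflux = atp / sum_flux,
    cost_per_sumflux = cost / sum_flux,
    sumflux_per_glc = yield_of(sum_flux),
    tca_flux = flux[, "GLT"],
    ppp_flux = flux[, "ZWF"],
    ed_flux = flux[, "EDD"],
    glyoxylate_flux = flux[, "ICL"],
    acetate_flux = flux[, "ACK"],
    tca_rel = yield_of(flux[, "GLT"]),
    ppp_rel = yield_of(flux[, "ZWF"]),
    ed_rel = yield_of(flux[, "EDD"]),
    glyoxylate_rel = yield_of(flux[, "ICL"]),
    acetate_rel = yield_of(flux[, "ACK"]))
  attr(out, "units") <- c(growth_rate = "1/h", fluxes = "mM/s (cytoplasm basis)",
                          total_pool = "mM", enzyme_cost = "residue.uM")
  out
}

# packaged synthetic enzyme abundance table (reaction, conc_uM, aa_count)
enzyme_abundance_table <- function() {
  path <- system.file("extdata", "enzyme_abundance_synthetic.tsv",
                      package = "colikin")
  if (!nzchar(path)) {
    path <- file.path("inst", "extdata", "enzyme_abundance_synthetic.tsv")
  }
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Proteome cost of the expressed enzyme levels
#'
#' `sum_r factor_r * concentration_r * aa_r`: the total amino-acid
#' investment in the pathway enzymes, a proxy for proteome allocation.
#' Reactions without a measured concentration contribute at the default
#' concentration (the average over other enzymes, 18 uM).
#'
#' @param enzyme_scale_factors named (or table-ordered) vector of enzyme
#'   scale factors, >= 0
#' @param enzyme_concentrations named vector of enzyme concentrations (uM)
#' @param aa_counts named vector of protein lengths (amino acids)
#' @param default_conc_uM concentration used where unknown (uM)
#' @return total cost (residue.uM)
#' @export
enzyme_cost <- function(enzyme_scale_factors, enzyme_concentrations, aa_counts,
                        default_conc_uM = 18) {
  if (any(enzyme_scale_factors < 0)) stop("factors must be >= 0", call. = FALSE)
  ids <- names(aa_counts)
  f <- if (!is.null(names(enzyme_scale_factors)))
    enzyme_scale_factors[ids] else rep_len(enzyme_scale_factors, length(ids))
  f[is.na(f)] <- 1
  conc <- enzyme_concentrations[ids]
  conc[is.na(conc)] <- default_conc_uM
  sum(f * conc * aa_counts)
}

#' Pairwise Spearman rank correlation matrix
#'
#' @param table data.frame of systemic variables (numeric columns)
#' @return symmetric correlation matrix; constant columns give `NA` entries
#' @export
spearman_matrix <- function(table) {
  x <- as.matrix(table)
  if (nrow(x) < 10) stop("need at least 10 rows", call. = FALSE)
  suppressWarnings(stats::cor(x, method = "spearman",
                              use = "pairwise.complete.obs"))
}

# equal-frequency discretization into nb bins (average ranks for ties)
equal_freq_bins <- function(x, nb) {
  r <- rank(x, ties.method = "average", na.last = "keep")
  b <- ceiling(r / (sum(!is.na(x)) / nb))
  pmin(pmax(b, 1L), nb)
}

#' Pairwise mutual information matrix (plug-in, equal-frequency bins)
#'
#' Discretizes each column into equal-frequency bins (default
#' `floor(n^(1/3))`, capped at 30) and computes the plug-in discrete mutual
#' information in nats for every pair.  The diagonal holds the empirical
#' marginal entropy.  Constant columns yield zero rows, with a warning.
#'
#' @param table data.frame of systemic variables
#' @param n_bins number of bins (`>= 2`); default `floor(n^(1/3))` capped at 30
#' @return list with `mi` (symmetric matrix, nats), `n_bins`, `binning`
#' @export
mutual_information_matrix <- function(table, n_bins = NULL) {
  x <- as.matrix(table)
  n <- nrow(x)
  if (n < 10) stop("need at least 10 rows", call. = FALSE)
  if (is.null(n_bins)) n_bins <- min(max(floor(n^(1 / 3)), 2L), 30L)
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  const <- apply(x, 2, function(col) length(unique(col[!is.na(col)])) <= 1)
  if (any(const)) {
    warning("constant column(s): ", paste(colnames(x)[const], collapse = ", "),
            "; their MI is reported as 0")
  }
  disc <- apply(x, 2, equal_freq_bins, nb = n_bins)
  p <- ncol(x)
  mi <- matrix(0, p, p, dimnames = list(colnames(x), colnames(x)))
  ent <- function(counts) {
    pr <- counts[counts > 0] / sum(counts)
    -sum(pr * log(pr))
  }
  H <- apply(disc, 2, function(col) ent(table(col)))
  for (i in seq_len(p)) {
    mi[i, i] <- H[i]
    for (j in seq_len(p)) {
      if (j <= i) next
      ok <- !is.na(disc[, i]) & !is.na(disc[, j])
      if (!any(ok) || const[i] || const[j]) next
      Hij <- ent(table(disc[ok, i], disc[ok, j]))
      val <- max(H[i] + H[j] - Hij, 0)
      mi[i, j] <- mi[j, i] <- val
    }
  }
  list(mi = mi, n_bins = n_bins, binning = "equal_frequency", units = "nats")
}

#' Homeostasis of the total metabolite pool
#'
#' Distribution of the total intracellular metabolite concentration across
#' the ensemble, its cumulative curve, and the fraction of steady states
#' whose total pool stays within `k`-fold of the reference total.
#'
#' @param ensemble an `ensemble_result` (or a numeric vector of total pools)
#' @param reference_total_mM reference total pool (mM); defaults to the
#'   model's reference concentrations when an ensemble is given
#' @param k fold-change defining the homeostatic band (default 3)
#' @param breaks histogram breaks passed to [graphics::hist] semantics
#'   (computed, not plotted)
#' @return list with `totals`, `reference_total`, `fraction_within`,
#'   `histogram` (data.frame mid/count), `cumulative` (data.frame value/freq)
#' @export
homeostasis_summary <- function(ensemble, reference_total_mM = NULL, k = 3,
                                breaks = 30) {
  if (inherits(ensemble, "ensemble_result")) {
    model <- ensemble$model
    cyto_mets <- model$species$id[model$species$compartment == "cytoplasm" &
                                    !model$species$id %in% attr(model, "enzyme_species")]
    totals <- rowSums(ensemble$concentrations[ensemble$converged, cyto_mets,
                                              drop = FALSE])
    if (is.null(reference_total_mM)) {
      reference_total_mM <- sum(setNames(model$species$conc, model$species$id)[cyto_mets])
    }
  } else {
    totals <- as.numeric(ensemble)
    if (is.null(reference_total_mM)) stop("reference_total_mM required", call. = FALSE)
  }
  frac <- mean(totals > reference_total_mM / k & totals < reference_total_mM * k)
  h <- graphics::hist(log10(totals), breaks = breaks, plot = FALSE)
  srt <- sort(totals)
  list(totals = totals,
       reference_total = reference_total_mM,
       k = k,
       fraction_within = frac,
       histogram = data.frame(log10_mid = h$mids, count = h$counts),
       cumulative = data.frame(value = srt,
                               freq = seq_along(srt) / length(srt)))
}
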