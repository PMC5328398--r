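# Synthetic reference instance of E. coli central carbon and energy
# metabolism.
#
# The published, literature-calibrated kinetic models of this network are
# distributed as supplementary SBML files; this package instead *constructs*
# a synthetic reference instance with the same structural census (3
# compartments, 62 species, 68 reactions, 255 metabolite-enzyme interactions
# of which 34 are long-range/modifier-only) and the same rate-law families,
# calibrated by design to the canonical reference condition: glucose-limited
# chemostat, dilution rate 0.1 1/h, realistic metabolite concentrations with
# a total intracellular pool of ~47 mM.  The construction fixes a target
# steady state (concentrations x*, fluxes v* with S v* = 0) and solves each
# rate law's capacity parameter so that v(x*) = v* exactly, which makes the
# reference steady state known in closed form.  See the methods vignette for
# the full design rationale.

MU_REF <- 0.1 / 3600   # reference growth rate, 1/s (0.1 1/h)

# biomass demand per unit growth rate (mM per [mu]=1/s unit flux); ATP/ADP,
# NADPH/NADP and ACCOA/COA appear pairwise so the cofactor moieties are
# conserved; 4000 of the 17000 phosphate groups stay in biomass.
GROWTH_COEF <- c(G6P = -660, R5P = -280, E4P = -115, PEP = -470, PYR = -880,
                 ACCOA = -1200, OAA = -570, AKG = -345, NADPH = -5400,
                 ATP = -17000,
                 NADP = 5400, ADP = 17000, P = 13000, COA = 1200)

PTS_PROTEINS <- c("EI", "EIP", "HPR", "HPRP", "EIIA", "EIIAP", "EIICB", "EIICBP")

# steps with no enzyme behind them: chemostat feed and washout, passive gas
# transfer, spontaneous acetyl-phosphate hydrolysis, membrane proton leak.
# Random enzyme-level ensembles leave these at their reference capacity.
NON_ENZYMATIC_STEPS <- c("GLC_FEED", "ACE_OUT", "O2_TR", "ACP_SPON", "HLEAK")

# ---- species table ----------------------------------------------------------

ecoli_species <- function() {
  df <- rbind(
    # environment
    data.frame(id = c("GLC_e", "ACE_e", "P_e", "O2_e"),
               compartment = "environment",
               conc = c(0.02, 0.42, 10, 0.21),
               boundary = c(FALSE, FALSE, TRUE, TRUE)),
    # periplasm
    data.frame(id = c("GLC_p", "ACE_p", "P_p", "H_p"),
               compartment = "periplasm",
               conc = c(0.005, 0.5, 9, 0.2),
               boundary = FALSE),
    # cytoplasm: glycolysis
    data.frame(id = c("G6P", "F6P", "FDP", "DAP", "GAP", "BPG", "PG3", "PG2",
                      "PEP", "PYR"),
               compartment = "cytoplasm",
               conc = c(0.8, 0.25, 9.0, 0.5, 0.08, 0.07, 2.2, 0.4, 0.9, 0.8),
               boundary = FALSE),
    # pentose phosphate / Entner-Doudoroff
    data.frame(id = c("GL6P", "PGN", "RU5P", "R5P", "X5P", "S7P", "E4P", "KDPG"),
               compartment = "cytoplasm",
               conc = c(0.02, 0.12, 0.12, 0.4, 0.2, 0.3, 0.06, 0.06),
               boundary = FALSE),
    # TCA cycle / glyoxylate shunt
    data.frame(id = c("ACCOA", "COA", "CIT", "ICIT", "AKG", "SUCCOA", "SUC",
                      "FUM", "MAL", "OAA", "GLX"),
               compartment = "cytoplasm",
               conc = c(0.6, 0.3, 1.1, 0.11, 0.7, 0.15, 1.0, 0.3, 2.2, 0.05, 0.02),
               boundary = FALSE),
    # acetate metabolism
    data.frame(id = c("ACP", "ACE"),
               compartment = "cytoplasm",
               conc = c(0.08, 0.6),
               boundary = FALSE),
    # nucleotides, redox carriers, phosphate, protons (buffer-equivalent
    # pools: only the ratio H_c/H_p, i.e. the pH difference, enters the
    # rate laws), oxygen
    data.frame(id = c("ATP", "ADP", "AMP", "CAMP", "NAD", "NADH", "NADP",
                      "NADPH", "FAD", "FADH2", "Q", "QH2", "P", "H_c", "O2"),
               compartment = "cytoplasm",
               conc = c(4.0, 0.6, 0.28, 0.08, 2.0, 0.12, 0.08, 0.17, 0.12,
                        0.06, 0.6, 0.4, 15.0, 0.1, 0.12),
               boundary = c(rep(FALSE, 13), TRUE, FALSE)),
    # PTS phospho-carrier proteins (enzymes, not metabolites)
    data.frame(id = PTS_PROTEINS,
               compartment = "cytoplasm",
               conc = c(0.005, 0.005, 0.01, 0.01, 0.02, 0.02, 0.01, 0.01),
               boundary = FALSE)
  )
  rownames(df) <- NULL
  df
}

ecoli_compartments <- function() {
  # periplasm = 20% of total cell volume => periplasm/cytoplasm = 0.25
  data.frame(id = c("environment", "periplasm", "cytoplasm"),
             volume = c(100, 0.25, 1),
             kind = c("environment", "periplasm", "cytoplasm"))
}

# ---- reaction table ---------------------------------------------------------

# each entry: stoich, form, optional regulation (inh / act, with hill flag),
# optional overrides (Keq value, Km values), optional guess flux
ecoli_reactions <- function() {
  rx <- function(stoich, form, inh = NULL, act = NULL, keq = NULL,
                 km = NULL, hill = character(), ki_mult = NULL, ka_mult = NULL,
                 keq_mult = NULL, kp = NULL) {
    list(stoich = stoich, form = form, inh = inh, act = act, keq = keq,
         km = km, hill = hill, ki_mult = ki_mult, ka_mult = ka_mult,
         keq_mult = keq_mult, kp = kp)
  }
  list(
    # environment / exchange
    GLC_FEED = rx(c(GLC_e = 1), "const"),
    ACE_OUT  = rx(c(ACE_e = -1), "ma_irr"),
    XCH_GLC  = rx(c(GLC_e = -1, GLC_p = 1), "porin", keq = 1,
                  km = c(GLC_e = 0.05, GLC_p = 0.05)),
    XCH_ACE  = rx(c(ACE_p = -1, ACE_e = 1), "porin", keq = 1,
                  km = c(ACE_p = 5, ACE_e = 5)),
    XCH_P    = rx(c(P_e = -1, P_p = 1), "porin", keq = 1,
                  km = c(P_e = 12, P_p = 12)),
    O2_TR    = rx(c(O2_e = -1, O2 = 1), "ma", keq = 1),
    ACE_TR   = rx(c(ACE = -1, ACE_p = 1), "ma", keq = 1),
    PIT      = rx(c(P_p = -1, P = 1), "rmm", keq = 2),
    # glucose phosphotransferase system
    PTS0 = rx(c(EI = -1, PEP = -1, EIP = 1, PYR = 1), "ma", inh = "AKG",
              keq_mult = 1.25),
    PTS1 = rx(c(EIP = -1, HPR = -1, EI = 1, HPRP = 1), "ma", keq_mult = 1.25),
    PTS2 = rx(c(HPRP = -1, EIIA = -1, HPR = 1, EIIAP = 1), "ma", keq_mult = 1.25),
    PTS3 = rx(c(EIIAP = -1, EIICB = -1, EIIA = 1, EIICBP = 1), "ma",
              keq_mult = 1.25),
    PTS4 = rx(c(EIICBP = -1, GLC_p = -1, EIICB = 1, G6P = 1), "mm",
              km = c(GLC_p = 0.01), kp = c(G6P = 0.8)),
    # glycolysis / gluconeogenesis
    PGI  = rx(c(G6P = -1, F6P = 1), "rmm", keq = 1.2, inh = "PGN"),
    PFK  = rx(c(F6P = -1, ATP = -1, FDP = 1, ADP = 1), "mm",
              inh = c("PEP", "CIT"), act = "AMP",
              km = c(F6P = 1.0), ki_mult = c(PEP = 10, CIT = 8)),
    PFKB = rx(c(F6P = -1, ATP = -1, FDP = 1, ADP = 1), "mm"),
    FBP  = rx(c(FDP = -1, F6P = 1), "mm", inh = "AMP", act = c("PEP", "CIT")),
    FBA  = rx(c(FDP = -1, DAP = 1, GAP = 1), "rmm", keq = 1.5),
    TPI  = rx(c(DAP = -1, GAP = 1), "rmm", keq = 1.2),
    GDH  = rx(c(GAP = -1, NAD = -1, P = -1, BPG = 1, NADH = 1), "rmm", keq = 1.2),
    PGK  = rx(c(BPG = -1, ADP = -1, PG3 = 1, ATP = 1), "rmm", keq = 1.2),
    GPM  = rx(c(PG3 = -1, PG2 = 1), "rmm", keq = 1.2),
    ENO  = rx(c(PG2 = -1, PEP = 1), "rmm", keq = 1.2),
    PYK  = rx(c(PEP = -1, ADP = -1, PYR = 1, ATP = 1), "mm",
              act = c("FDP", "AMP")),
    PPS  = rx(c(PYR = -1, ATP = -1, PEP = 1, AMP = 1, P = 1), "mm", inh = "ADP"),
    PDH  = rx(c(PYR = -1, NAD = -1, COA = -1, ACCOA = 1, NADH = 1), "mm",
              km = c(PYR = 3)),
    # pentose phosphate pathway
    ZWF  = rx(c(G6P = -1, NADP = -1, GL6P = 1, NADPH = 1), "rmm", inh = "ATP"),
    PGL  = rx(c(GL6P = -1, PGN = 1), "rmm", keq = 2),
    GND  = rx(c(PGN = -1, NADP = -1, RU5P = 1, NADPH = 1), "mm", inh = "ATP"),
    RPE  = rx(c(RU5P = -1, X5P = 1), "rmm", keq = 1.2),
    RPI  = rx(c(RU5P = -1, R5P = 1), "rmm", keq = 1.2),
    TKT1 = rx(c(R5P = -1, X5P = -1, S7P = 1, GAP = 1), "rmm", keq = 1.2),
    TAL  = rx(c(S7P = -1, GAP = -1, F6P = 1, E4P = 1), "rmm", keq = 1.2),
    TKT2 = rx(c(X5P = -1, E4P = -1, F6P = 1, GAP = 1), "rmm", keq = 1.2),
    # Entner-Doudoroff
    EDD  = rx(c(PGN = -1, KDPG = 1), "mm"),
    EDA  = rx(c(KDPG = -1, PYR = 1, GAP = 1), "rmm", keq = 50),
    # anaplerosis
    PPC  = rx(c(PEP = -1, OAA = 1, P = 1), "mm",
              act = c("FDP", "ACCOA"), inh = "MAL"),
    PCK  = rx(c(OAA = -1, ATP = -1, PEP = 1, ADP = 1), "mm", inh = "NADH"),
    MAE  = rx(c(MAL = -1, NADP = -1, PYR = 1, NADPH = 1), "mm", inh = "ACCOA"),
    # TCA cycle
    GLT    = rx(c(ACCOA = -1, OAA = -1, CIT = 1, COA = 1), "mm",
                inh = c("NADH", "AKG", "ATP"), hill = "NADH",
                ki_mult = c(NADH = 2, AKG = 8, ATP = 8)),
    ACN    = rx(c(CIT = -1, ICIT = 1), "rmm", keq = 1.2),
    ICD    = rx(c(ICIT = -1, NADP = -1, AKG = 1, NADPH = 1), "rmm",
                inh = "GLX", act = "ADP"),
    AKGDH  = rx(c(AKG = -1, NAD = -1, COA = -1, SUCCOA = 1, NADH = 1), "mm"),
    SUCOAS = rx(c(SUCCOA = -1, ADP = -1, P = -1, SUC = 1, ATP = 1, COA = 1), "rmm", keq = 1.5),
    SDH    = rx(c(SUC = -1, FAD = -1, FUM = 1, FADH2 = 1), "rmm", keq = 1.5, inh = "OAA"),
    FUMA   = rx(c(FUM = -1, MAL = 1), "rmm", keq = 1.2, inh = "OAA"),
    MDH    = rx(c(MAL = -1, NAD = -1, OAA = 1, NADH = 1), "rmm", keq = 1.2),
    MQO    = rx(c(MAL = -1, Q = -1, OAA = 1, QH2 = 1), "ma_irr"),
    FRD    = rx(c(FUM = -1, QH2 = -1, SUC = 1, Q = 1), "ma"),
    # glyoxylate shunt
    ICL  = rx(c(ICIT = -1, SUC = 1, GLX = 1), "mm", inh = c("PG3", "PEP")),
    MALS = rx(c(GLX = -1, ACCOA = -1, MAL = 1, COA = 1), "mm"),
    # acetate metabolism
    PTA      = rx(c(ACCOA = -1, P = -1, ACP = 1, COA = 1), "rmm", keq = 1.5,
                  inh = "NADH", km = c(ACCOA = 4)),
    ACK      = rx(c(ACP = -1, ADP = -1, ACE = 1, ATP = 1), "rmm", keq = 1.2),
    ACS      = rx(c(ACE = -1, ATP = -1, COA = -1, ACCOA = 1, AMP = 1, P = 2), "mm"),
    ACP_SPON = rx(c(ACP = -1, ACE = 1, P = 1), "ma_irr"),
    POXB     = rx(c(PYR = -1, Q = -1, ACE = 1, QH2 = 1), "mm", km = c(PYR = 10)),
    # oxidative phosphorylation
    NDHI    = rx(c(NADH = -1, Q = -1, NAD = 1, QH2 = 1, H_p = 4), "ndhi"),
    NDHII   = rx(c(NADH = -1, Q = -1, NAD = 1, QH2 = 1), "ndh2"),
    SQR     = rx(c(FADH2 = -1, Q = -1, FAD = 1, QH2 = 1), "sqr"),
    CYTBO   = rx(c(QH2 = -2, O2 = -1, Q = 2, H_p = 8), "cytbo"),
    ATP_SYN = rx(c(ADP = -1, P = -1, H_p = -4, ATP = 1), "atp_syn"),
    HLEAK   = rx(c(H_p = -1), "hleak", keq = 1),
    # nucleotide interconversion and maintenance
    ATP_NGAM = rx(c(ATP = -1, ADP = 1, P = 1), "mm"),
    ADK      = rx(c(ATP = -1, AMP = -1, ADP = 2), "ma"),
    CYA      = rx(c(ATP = -1, CAMP = 1), "mm", act = "PEP", inh = "PYR"),
    DOS      = rx(c(CAMP = -1, AMP = 1), "mm"),
    PNT      = rx(c(NADPH = -1, NAD = -1, NADP = 1, NADH = 1), "ma"),
    # growth (biomass synthesis)
    GROWTH   = rx(GROWTH_COEF, "growth")
  )
}

# hand-specified reference flux pattern (mM/s, cytoplasm basis).  Values are
# mutually consistent up to rounding; an exact weighted projection onto
# {v : S v = 0} is applied afterwards.
ecoli_flux_guess <- function() {
  c(GLC_FEED = 0.15, ACE_OUT = 0.004, XCH_GLC = 0.15, XCH_ACE = 0.004,
    XCH_P = 0.15573, O2_TR = 0.417035, ACE_TR = 0.004, PIT = 0.15573,
    PTS0 = 0.15, PTS1 = 0.15, PTS2 = 0.15, PTS3 = 0.15, PTS4 = 0.15,
    PGI = 0.0787, PFK = 0.103446, PFKB = 0.004, FBP = 0.003, FBA = 0.104446,
    TPI = 0.104446, GDH = 0.225165, PGK = 0.225165, GPM = 0.225165,
    ENO = 0.225165, PYK = 0.038675, PPS = 0.002, PDH = 0.169215,
    ZWF = 0.053, PGL = 0.053, GND = 0.048, RPE = 0.025747, RPI = 0.022253,
    TKT1 = 0.014473, TAL = 0.014473, TKT2 = 0.011273,
    EDD = 0.005, EDA = 0.005,
    PPC = 0.02843, PCK = 0.003, MAE = 0.004,
    GLT = 0.129865, ACN = 0.129865, ICD = 0.125865, AKGDH = 0.116275,
    SUCOAS = 0.116275, SDH = 0.121275, FUMA = 0.120275, MDH = 0.115275,
    MQO = 0.005, FRD = 0.001,
    ICL = 0.004, MALS = 0.004,
    PTA = 0.006, ACK = 0.005, ACS = 0.004, ACP_SPON = 0.001, POXB = 0.002,
    NDHI = 0.47, NDHII = 0.236795, SQR = 0.121275, CYTBO = 0.417035,
    ATP_SYN = 0.561831, HLEAK = 2.968956,
    ATP_NGAM = 0.35, ADK = 0.007, CYA = 0.001, DOS = 0.001, PNT = 0.080865,
    GROWTH = MU_REF)
}

# weighted projection of the flux guess onto {v : S_dyn v = 0}; weights are
# the squared guesses, so corrections are balanced in relative terms.  The
# growth flux is the design target (dilution rate 0.1 1/h) and is given a
# near-zero weight so the correction lands on the other fluxes.
project_reference_fluxes <- function(S_dyn, guess) {
  w <- guess^2
  w["GROWTH"] <- w["GROWTH"] * 1e-8
  SW <- S_dyn * rep(w, each = nrow(S_dyn))
  A <- SW %*% t(S_dyn)
  corr <- as.numeric(t(SW) %*% MASS_ginv(A) %*% (S_dyn %*% guess))
  v <- guess - corr
  names(v) <- names(guess)
  v
}

# ---- rate-law assembly and capacity solving ---------------------------------

# porin-type reversible Michaelis-Menten used by the outer-membrane exchanges
rl_porin <- function(rid, s_out, s_in) {
  km_o <- bq(pref(rid, paste0("Km_", s_out)))
  km_i <- bq(pref(rid, paste0("Km_", s_in)))
  txt <- sprintf("%s*(%s - %s/%s)/(%s + %s + %s*%s/%s)",
                 bq(pref(rid, "Vmax")), s_out, s_in, bq(pref(rid, "Keq")),
                 km_o, s_out, s_in, km_o, km_i)
  rl_parse("reversible_michaelis_menten", rid,
           c("Vmax", "Keq", paste0("Km_", c(s_out, s_in))), txt)
}

# proton leak across the inner membrane: k * (H_p - H_c / Keq)
rl_hleak <- function(rid) {
  rl_parse("mass_action_reversible", rid, c("kf", "Keq"),
           sprintf("%s*(H_p - H_c/%s)", bq(pref(rid, "kf")),
                   bq(pref(rid, "Keq"))))
}

GROWTH_PRECURSORS <- c("G6P", "R5P", "E4P", "PEP", "PYR", "ACCOA", "OAA",
                       "AKG", "NADPH", "ATP")

# cofactor species: enzymes bind these tightly (half-saturation well below
# the pool size), so default Km = 0.25 x* instead of 2 x*
COFACTOR_SPECIES <- c("ATP", "ADP", "AMP", "NAD", "NADH", "NADP", "NADPH",
                      "COA", "FAD", "FADH2", "Q", "QH2", "P")

default_km <- function(sp_ids, x) {
  mult <- ifelse(sp_ids %in% COFACTOR_SPECIES, 0.25, 2)
  setNames(unname(mult * x[sp_ids]), sp_ids)
}

# build the rate law of one reaction spec (capacity parameter set to 1;
# returns law plus the named non-capacity parameter values)
build_law <- function(rid, spec, x) {
  st <- spec$stoich
  sub <- names(st)[st < 0]
  sub_n <- abs(st[st < 0])
  prod <- names(st)[st > 0]
  prod_n <- st[st > 0]
  vals <- numeric(0)
  law <- switch(spec$form,
    const = rl_const(rid),
    ma_irr = rl_mass_action(rid, sub, sub_n, reversible = FALSE),
    ma = {
      gamma <- prod(x[prod]^prod_n) / prod(x[sub]^sub_n)
      keq <- if (!is.null(spec$keq)) spec$keq
             else if (!is.null(spec$keq_mult)) spec$keq_mult * gamma
             else 2 * gamma
      vals <- c(vals, Keq = unname(keq))
      rl_mass_action(rid, sub, sub_n, prod, prod_n, reversible = TRUE)
    },
    rmm = {
      kms <- default_km(c(sub, prod), x)
      if (!is.null(spec$km)) kms[names(spec$km)] <- spec$km
      # Keq expressed as a displacement multiple of the scaled mass-action
      # ratio at the reference state, so flux direction is Km-independent
      disp <- if (!is.null(spec$keq)) spec$keq else 4
      gs <- prod((x[prod] / kms[prod])^prod_n) /
            prod((x[sub] / kms[sub])^sub_n)
      vals <- c(vals, Keq = unname(disp * gs),
                setNames(kms, paste0("Km_", names(kms))))
      rl_rev_mm(rid, sub, sub_n, prod, prod_n)
    },
    mm = {
      kms <- default_km(sub, x)
      if (!is.null(spec$km)) kms[names(spec$km)] <- spec$km
      kps <- setNames(unname(3 * x[prod]), prod)
      if (!is.null(spec$kp)) kps[names(spec$kp)] <- spec$kp
      vals <- c(vals, setNames(kms, paste0("Km_", names(kms))),
                setNames(unname(kps), paste0("Kp_", names(kps))))
      rl_irr_mm(rid, sub, sub_n, prod)
    },
    porin = {
      s_out <- sub
      s_in <- prod
      kms <- setNames(unname(x[c(s_out, s_in)]), c(s_out, s_in))
      if (!is.null(spec$km)) kms[names(spec$km)] <- spec$km
      vals <- c(vals, Keq = unname(spec$keq),
                setNames(kms, paste0("Km_", names(kms))))
      rl_porin(rid, s_out, s_in)
    },
    hleak = {
      vals <- c(vals, Keq = unname(spec$keq))
      rl_hleak(rid)
    },
    ndhi = , ndh2 = , sqr = , cytbo = , atp_syn = {
      gamma <- switch(spec$form,
        ndhi = , ndh2 = (x["NAD"] * x["QH2"]) / (x["NADH"] * x["Q"]),
        sqr = (x["FAD"] * x["QH2"]) / (x["FADH2"] * x["Q"]),
        cytbo = x["Q"]^2 / (x["QH2"]^2 * x["O2"]),
        atp_syn = x["ATP"] / (x["ADP"] * x["P"]))
      vals <- c(vals, Keq = unname(5 * gamma))
      rl_oxphos(rid, spec$form)
    },
    growth = {
      kms <- x[GROWTH_PRECURSORS] / 4
      vals <- c(vals, setNames(unname(kms), paste0("Km_", GROWTH_PRECURSORS)))
      rl_growth(rid, GROWTH_PRECURSORS)
    },
    stop("unknown rate-law form: ", spec$form))

  for (sp in spec$inh) {
    h <- sp %in% spec$hill
    law <- rl_inhibit(law, rid, sp, hill = h)
    mult <- if (!is.null(spec$ki_mult) && sp %in% names(spec$ki_mult))
      spec$ki_mult[[sp]] else 4
    vals <- c(vals, setNames(unname(mult * x[sp]), paste0("Ki_", sp)))
    if (h) vals <- c(vals, setNames(2, paste0("n_", sp)))
  }
  for (sp in spec$act) {
    h <- sp %in% spec$hill
    law <- rl_activate(law, rid, sp, hill = h)
    mult <- if (!is.null(spec$ka_mult) && sp %in% names(spec$ka_mult))
      spec$ka_mult[[sp]] else 1
    vals <- c(vals, setNames(unname(mult * x[sp]), paste0("Ka_", sp)))
    if (h) vals <- c(vals, setNames(2, paste0("n_", sp)))
  }
  list(law = law, values = vals)
}

#' The synthetic E. coli reference model
#'
#' Builds the packaged synthetic reference instance of the central carbon and
#' energy network of \emph{Escherichia coli}: 3 compartments (environment,
#' periplasm at 20\% of cell volume, cytoplasm), 62 species, 68 reactions
#' (PTS, glycolysis/gluconeogenesis, pentose phosphate, Entner-Doudoroff,
#' anaplerosis, TCA cycle, glyoxylate shunt, acetate metabolism, oxidative
#' phosphorylation with proton-motive gating, nucleotide interconversion,
#' growth), 255 metabolite-enzyme interactions of which 34 are long-range
#' (modifier-only).  The model is calibrated by construction to a
#' glucose-limited chemostat at growth rate 0.1 1/h: its reference
#' concentrations are an exact steady state.
#'
#' @param compile attach the compiled rate evaluator (recommended)
#' @return a `kinetic_model` with attributes `reference_fluxes` (designed
#'   steady-state fluxes) and `enzyme_species` (the PTS phospho-carrier
#'   proteins, excluded from the metabolite census)
#' @export
ecoli_reference_model <- function(compile = TRUE) {
  sp_df <- ecoli_species()
  comp <- ecoli_compartments()
  specs <- ecoli_reactions()
  x <- setNames(sp_df$conc, sp_df$id)

  # exact reference fluxes
  S <- matrix(0, nrow(sp_df), length(specs),
              dimnames = list(sp_df$id, names(specs)))
  for (id in names(specs)) S[names(specs[[id]]$stoich), id] <- specs[[id]]$stoich
  dyn <- !sp_df$boundary
  v_ref <- project_reference_fluxes(S[dyn, , drop = FALSE], ecoli_flux_guess())

  # build laws; solve each capacity parameter so that v(x*) = v*
  reactions <- vector("list", length(specs))
  params <- numeric(0)
  for (k in seq_along(specs)) {
    rid <- names(specs)[k]
    bl <- build_law(rid, specs[[k]], x)
    cap_name <- intersect(c("Vmax", "kf"), bl$law$params)
    pv <- setNames(numeric(length(bl$law$params)), pref(rid, bl$law$params))
    if (length(bl$values)) pv[pref(rid, names(bl$values))] <- bl$values
    pv[pref(rid, cap_name)] <- 1
    val <- eval(bl$law$expr, envir = as.list(c(x, pv)))
    if (!is.finite(val) || val == 0) {
      stop("degenerate rate law at reference state: ", rid, call. = FALSE)
    }
    cap <- v_ref[rid] / val
    if (cap < 0) {
      stop("reference flux direction inconsistent with rate law: ", rid,
           call. = FALSE)
    }
    pv[pref(rid, cap_name)] <- cap
    mods <- setdiff(intersect(all.vars(bl$law$expr), sp_df$id),
                    names(specs[[k]]$stoich))
    reactions[[k]] <- new_reaction(rid, specs[[k]]$stoich, bl$law, mods)
    params <- c(params, pv)
  }

  model <- kinetic_model("ecoli_central_metabolism_synthetic", comp, sp_df,
                         reactions, params)
  attr(model, "enzyme_species") <- PTS_PROTEINS
  attr(model, "non_enzymatic_steps") <- NON_ENZYMATIC_STEPS
  attr(model, "reference_fluxes") <- v_ref
  if (compile) model <- compile_model(model)
  model
}

#' Switch the model to the excess-glucose condition
#'
#' Fixes extracellular glucose as a boundary species (default 10 mM), the
#' condition under which the kinetic solution space is explored with random
#' enzyme levels.
#'
#' @param model a `kinetic_model` (typically [ecoli_reference_model()])
#' @param glucose_mM fixed extracellular glucose concentration
#' @return modified model
#' @export
with_excess_glucose <- function(model, glucose_mM = 10) {
  set_boundary(model, "GLC_e", conc = glucose_mM, boundary = TRUE)
}

#' Build the reference model from a parameter source
#'
#' Reads a model either from an SBML file (`.xml`) or from the plain-text
#' parameter-table dialect (`.tsv`; columns `scope`, `id`, `parameter`,
#' `value`, `unit`): the packaged table reproduces [ecoli_reference_model()]
#' without any download.  A TSV source supplies parameter values and
#' reference concentrations for the fixed network structure; every parameter
#' and species of the structure must be covered.
#'
#' @param source path to an `.xml` (SBML) or `.tsv` (parameter table) file
#' @return a `kinetic_model`
#' @export
build_reference_model <- function(source) {
  if (!is.character(source) || length(source) != 1L || !nzchar(source) ||
      !file.exists(source)) {
    stop("parameter source not found: ", if (length(source)) source else "<empty>",
         call. = FALSE)
  }
  if (grepl("\\.xml$", source, ignore.case = TRUE)) {
    return(read_sbml_model(source))
  }
  tab <- utils::read.delim(source, comment.char = "#", stringsAsFactors = FALSE)
  if (!nrow(tab)) stop("empty parameter source: ", source, call. = FALSE)
  model <- ecoli_reference_model(compile = FALSE)
  par_rows <- tab[tab$scope == "reaction", , drop = FALSE]
  have <- paste0(par_rows$id, ".", par_rows$parameter)
  missing_p <- setdiff(names(model$params), have)
  if (length(missing_p)) {
    stop("parameter source is missing: ", paste(missing_p, collapse = ", "),
         call. = FALSE)
  }
  model$params[have] <- par_rows$value
  conc_rows <- tab[tab$scope == "species", , drop = FALSE]
  missing_s <- setdiff(model$species$id, conc_rows$id)
  if (length(missing_s)) {
    stop("parameter source is missing concentrations for: ",
         paste(missing_s, collapse = ", "), call. = FALSE)
  }
  model$species$conc <- conc_rows$value[match(model$species$id, conc_rows$id)]
  check_parameter_signs(model$params)
  compile_model(model)
}

#' Write a model's parameters as a plain-text table
#'
#' @param model a `kinetic_model`
#' @param path output TSV path
#' @return invisibly, the path
#' @export
write_parameter_table <- function(model, path) {
  pr <- data.frame(scope = "reaction",
                   id = sub("\\..*$", "", names(model$params)),
                   parameter = sub("^[^.]+\\.", "", names(model$params)),
                   value = unname(model$params),
                   unit = "mixed(mM,mM/s,1/s,dimensionless)")
  sp <- data.frame(scope = "species", id = model$species$id,
                   parameter = "conc", value = model$species$conc, unit = "mM")
  cm <- data.frame(scope = "compartment", id = model$compartments$id,
                   parameter = "volume", value = model$compartments$volume,
                   unit = "relative")
  out <- rbind(pr, sp, cm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# colikin parameter table: concentrations mM, time s, rates mM/s (cytoplasm basis)",
               "# synthetic reference instance (see package documentation)"), con)
  utils::write.table(format(out, digits = 17, scientific = TRUE, trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
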