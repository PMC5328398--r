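---
title: "Kinetic modelling and control analysis of E. coli central metabolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modelling and control analysis of E. coli central metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Metabolic fluxes in a bacterium are shaped by two regulatory layers:
*hierarchical* regulation (changes in enzyme amounts through gene
expression) and *metabolic* regulation (changes in enzyme activities
through metabolite-enzyme interactions: substrates, products, and
allosteric effectors).  A way to isolate the contribution of the metabolic
layer is to build a kinetic (ODE) model of central metabolism in which
enzyme amounts are explicit parameters, and then ask what the network does
when those amounts are varied at random - any structure that survives
random enzyme levels must come from metabolite-enzyme interactions, not
from coordinated gene expression.

`colikin` implements this whole programme for the central carbon and
energy metabolism of *Escherichia coli*:

* a kinetic model container with symbolic rate laws, compiled to a small
  C evaluator, plus time-course simulation and steady-state solving;
* metabolic control analysis (MCA) by finite differences, with the
  summation theorems as a built-in validation;
* ensemble exploration of the *kinetic* solution space under random
  enzyme levels, and uniform (hit-and-run) sampling of the
  *stoichiometric* solution space of the same network;
* functional-coupling statistics between systemic physiological variables
  (Spearman rank correlation and mutual information on equal-frequency
  bins) and metabolite-homeostasis summaries;
* solution-space boundary estimation on both model types;
* constrained weighted least-squares calibration by particle swarm
  optimization, exercised through parameter recovery on synthetic data.

## The model

The network covers glucose transport through the outer membrane and the
phosphotransferase system (PTS), glycolysis/gluconeogenesis, the pentose
phosphate and Entner-Doudoroff pathways, anaplerosis, the TCA cycle and
glyoxylate shunt, acetate metabolism, oxidative phosphorylation,
nucleotide interconversion, and a single growth reaction that consumes all
biomass precursors in fixed stoichiometric proportions.  It has 3
compartments (environment, periplasm at 20% of the cell volume,
cytoplasm), 62 species and 68 reactions, with 255 metabolite-enzyme
interactions of which 34 are long-range (the metabolite is neither
substrate nor product of the reaction it modulates).

Units are mM for concentrations and s for time; all rates are mM/s on the
cytoplasmic-volume basis, and the ODE right-hand side rescales
cross-compartment transport by the volume ratios.

### Rate laws

The oxidative-phosphorylation steps use literal mass-action laws with a
sigmoidal gating by the trans-membrane pH difference
$\Delta\mathrm{pH} = \log_{10}(H_c/H_p)$ (base 10, because pH is a base-10
quantity):

$$v_\mathrm{NDH1} = V\frac{1}{1+\Delta\mathrm{pH}^2}\Big(\mathrm{NADH}\cdot Q - \frac{\mathrm{NAD}\cdot QH_2}{K_{eq}}\Big),
\qquad
v_\mathrm{ATPsyn} = V\frac{\Delta\mathrm{pH}^4}{1+\Delta\mathrm{pH}^4}\Big(\mathrm{ADP}\cdot P - \frac{\mathrm{ATP}}{K_{eq}}\Big)$$

and analogous forms for NDH-2, succinate:quinone oxidoreductase and the
cytochrome *bo* oxidase (quadratic in quinol).  The attenuation terms are
even powers of $\Delta\mathrm{pH}$, so they are insensitive to its sign;
the only sign-sensitive behaviour enters through the mass-action back
terms.  Growth is multiplicative in all precursor pools,

$$\mu = V \prod_i \frac{S_i}{S_i + K_{m,i}},$$

which makes the growth rate monotone in every pool, saturating at $V$,
and zero whenever any pool empties.  Everything else uses reversible
Michaelis-Menten kinetics (convenience-kinetics denominators), irreversible
Michaelis-Menten with competitive product binding, mass action, or
saturable porin diffusion for the outer-membrane exchanges.  Allosteric
interactions multiply the laws with hyperbolic (or Hill) inhibition and
activation terms.

### The synthetic reference instance

Literature-calibrated kinetic models of this network exist, but their
parameter sets are distributed as supplementary material and are
transcriptions of hundreds of literature values.  `colikin` instead
*constructs* its reference instance (`ecoli_reference_model()`), and the
construction is part of the package:

1. **Target state.** Reference concentrations are fixed at realistic
   values for glucose-limited growth (FBP and inorganic phosphate the
   largest pools; total cytoplasmic metabolite pool about 47 mM), and a
   reference flux pattern is specified by hand (glucose uptake 0.15 mM/s,
   about 30% of G6P routed into the pentose phosphate pathway, small
   Entner-Doudoroff/glyoxylate/overflow fluxes, respiration balancing the
   redox ledger) and projected exactly onto $\{v : S v = 0\}$ by a
   relative-weighted least-squares correction, with the growth flux pinned
   at the design target, a dilution rate of 0.1 1/h.
2. **Parameter solving.** With the state fixed, every rate law's
   saturation, inhibition and equilibrium parameters are set by simple
   rules, and its capacity parameter ($V_{max}$ or $k$) is solved so that
   the law reproduces the target flux exactly.  The designed state is then
   an *exact* steady state of the ODE system, known in closed form - this
   is what makes desk-scale verification possible.

The parameter rules are the scientific content of the calibration:

* carbon substrate/product sites bind at $K_m = 2x^*$ (occupancy 1/3;
  capacity headroom for the excess-glucose condition), cofactor sites at
  $K_m = 0.25x^*$ (enzymes are saturated in ATP, NAD(P)H, CoA and
  phosphate at physiological pools);
* near-equilibrium steps (the PPP rearrangements, lower glycolysis,
  aconitase, fumarase, malate dehydrogenase, PTA/ACK, succinyl-CoA
  synthetase and the PTS phospho-relay) run at a thermodynamic
  displacement of 1.2-1.5, which anchors their substrate/product pools to
  each other and gives them the large capacity-to-flux ratio (and hence
  negligible flux control) real near-equilibrium enzymes have;
* irreversible committed steps carry competitive product inhibition with
  $K_p = 3x^*$, the saturable product feedback real enzymes have, which
  bounds intermediate pools when downstream capacity is scaled down;
* allosteric effectors bind at $K_i = 4x^*$ ($K_a = x^*$ for activators),
  i.e. regulation is mild at the reference state and engages when the
  state moves; the only cooperative interaction is NADH inhibition of
  citrate synthase (Hill 2, $K_i = 2x^*$), plus a deliberately weak PEP
  inhibition of PFK ($K_i = 10x^*$) - stronger settings created a
  bistable glycolytic trap under excess glucose;
* proton pools are *buffer-equivalent* (0.1 / 0.2 mM): only the pH
  difference enters the rate laws, and this scaling removes a six-orders
  stiffness without changing any $\Delta$pH-dependent behaviour.

What the instance deliberately does **not** reproduce: the published
literature parameterization itself.  Headline numbers that depend on the
exact literature elasticities (individual control-coefficient values, the
86%-within-3-fold homeostasis fraction) will differ; structural and
qualitative results (census, summation theorems, growth-uptake coupling,
energy-redox coupling, bounded pools) are reproduced.  The test suite
makes this split explicit.

### Numerical methods

Steady states are found by a damped Newton-type iteration designed for
stiff kinetic systems: variables are log-concentrations of the dynamic
species (positivity for free, relative steps across decades), residuals
are scaled by the per-species tolerance `atol + rtol*x`, the step is
restricted to directions that keep the conserved-moiety totals fixed
(the left null space of the volume-scaled stoichiometric matrix is
computed, never assumed), every iterate is projected exactly back onto
the moiety manifold, and the step is regularized adaptively
(Levenberg-Marquardt) with a QR solve of the stacked system.  When the
iteration stalls, the solver integrates the ODE system toward the
attractor (`deSolve::lsoda` with the model's analytic Jacobian) and
re-polishes.  Convergence requires `|dx_i/dt| <= atol + rtol*x_i` for
every dynamic species (defaults 1e-8 and 1e-6); non-convergence is a
reported flag, so ensembles can do honest accounting.  Rate laws and
their symbolic derivatives are compiled to a small C stack machine, which
makes ensemble workloads tractable (about 0.2 s per random steady state).

MCA uses central differences on $\ln E$ with relative step $10^{-3}$ and
tight solver tolerances (1e-12/1e-10), with the sign-robust form
$(J(+h)-J(-h))/(2hJ^{ref})$: small net fluxes (the acetate loop) can
change sign inside the bracket, where a log-difference is undefined.  The
summation theorems (flux rows sum to 1, concentration rows to 0, both
within 0.01) double as an end-to-end validation of step size and solver
precision.  Steps whose reference flux is below 1e-12 mM/s are excluded
from the scaled flux matrix and reported.

The flux polytope $\{v: Sv=0,\ lb\le v\le ub\}$ of the stoichiometric
model is sampled by hit-and-run over the null-space parameterization
(warm-up `10*dim`, thinning `dim`); bounds are capped at 10x the
reference flux per reaction (the polytope must be bounded; the caps are
recorded).  Envelopes are exact LPs (`boot::simplex`) on the
stoichiometric side and penalty-constrained particle-swarm searches over
log enzyme factors on the kinetic side (targets pinned within 2%).

The calibration objective is the standard weighted sum of squares
$f(p)=\sum_i ((x_i-y_i(p))/\sigma_i)^2$; failed simulations contribute a
large finite penalty so the swarm keeps moving.  The swarm itself is
plain global-best PSO (50 particles, inertia 0.7, accelerations 1.5/1.5,
reflective bounds) over log10 parameters within the box constraints
$K_m \in [10^{-4},10^3]$ mM, $V_{max} \in [10^{-2},10^3]$ mM/s,
$K_{eq} \in [10^{-4},10^6]$; `fit_model()` runs two independent swarms and
refines the better optimum with a Nelder-Mead polish, the standard guard
against a finite swarm stalling on correlated parameter ridges.

### Ensembles and what they do (not) show

`sample_enzyme_levels()` draws per-reaction factors log-uniformly in
[0.1, 10] - each order of magnitude sampled in equal proportion - and
`ensemble_steady_states()` solves the corresponding steady states under
excess glucose (extracellular glucose fixed at 10 mM).  The five
non-enzymatic steps (nutrient feed, acetate washout, oxygen transfer,
spontaneous acetyl-phosphate hydrolysis, the membrane proton leak) keep
their reference capacity: they have no enzyme to vary.  The sampled
distribution is a probe of the reachable solution space, not a model of
expression noise; distributional statements (correlations, homeostasis
fractions) describe the network's regulatory structure, not the
probability of a cell visiting a state.

Problem sizes used by the shipped analyses: ensembles of 2000 random
enzyme vectors (the published analyses use 600 000; the rank-correlation
statistics stabilize well below 2000), 3000-10000 flux-space samples,
and toy models with 2-5 reactions for every oracle-checked property.

### Known limitations

* The bundled instance is a synthetic surrogate: equal structure and
  rate-law families, its own calibration.  Quantities tied to the
  literature parameter values are approximated qualitatively at best.
* Under excess glucose the instance up-shifts growth only mildly
  (0.103 vs 0.1 1/h); the PTS phospho-relay throttles uptake through the
  PEP/PYR ratio more strongly than in a literature-calibrated model.
* Homeostasis: pools remain bounded under order-of-magnitude enzyme
  changes, but the fraction of ensemble states within 3-fold of the
  reference total pool is ~0.4 rather than ~0.86 - the synthetic
  elasticity spectrum is looser than the literature one.
* The hierarchical (gene-expression) layer is absent by design; the SBML
  reader covers the subset of constructs this package writes.

## A short tour

```{r tour}
library(colikin)

model <- ecoli_reference_model()
model                       # census: 62 species, 68 reactions, 255 (34) edges

ref <- steady_state(model)
ref$fluxes["GROWTH"] * 3600 # 0.1 (1/h): the chemostat dilution rate

cm <- control_coefficients(model)
oc <- overall_control(cm)
head(oc[order(-oc$CJ), ])   # glucose supply dominates the overall control

ens <- ensemble_steady_states(model, sample_enzyme_levels(model, 500, seed = 1))
sv <- systemic_variables(ens)
cor(sv$growth_rate, sv$glc_uptake, method = "spearman")
homeostasis_summary(ens)$fraction_within
```
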