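---
title: "Thermodynamics-based flux analysis of a syntrophic methanogenic coculture: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{syntmfa methods}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Syntrophic propionate oxidation is thermodynamically marginal: under
standard conditions the conversion

    propionate + 2 H2O -> acetate + CO2 + 3 H2

is strongly endergonic, and *Syntrophobacter fumaroxidans* can only grow on
propionate when a hydrogenotrophic partner such as *Methanospirillum
hungatei* keeps the H2 (or formate) concentration low by converting it to
methane. `syntmfa` implements the computational machinery needed to study
this coupling quantitatively: thermodynamics-based metabolic flux analysis
(TMFA) as a mixed-integer linear program, its parsimonious (minimum total
flux) variant, thermodynamic variability analysis, and a fixed-biomass
chemostat formulation in which two species share one medium — including its
metabolite activities, which is precisely what couples their
thermodynamics.

# The TMFA formulation

Flux balance analysis finds a flux vector $v$ maximizing an objective
subject to steady state ($S v = 0$) and capacity bounds. TMFA adds, for
every reaction with a Gibbs energy estimate, the requirement that flux and
transformed reaction energy have opposite signs. The package encodes this
in the standard way:

* every reaction is split into two non-negative directed halves, each with
  a binary use indicator $z$; $z_{fwd} + z_{rev} \le 1$;
* the transformed energy is
  $\Delta_r G' = \Delta_r G'^0 + \delta + RT \sum_j s_{ij} \ln c_j
  + n_{ion} \cdot c_{ion}$,
  with $\ln c_j$ decision variables bounded by the metabolite concentration
  bounds and $\delta$ a slack bounded by the confidence interval of the
  $\Delta_r G'^0$ estimate ($|\delta| \le z \cdot SE$, $z = 1.96$ at the
  95% level, $2.576$ at 99%);
* using a direction activates
  $\pm\Delta_r G' \le -\varepsilon + K(1 - z)$, i.e. the energy must
  strictly oppose the flux (an MILP cannot express strict inequality, so
  the configurable margin $\varepsilon = 0.5$ kJ/mol stands in for it);
* $K$ is computed per model as an upper bound on any attainable
  $|\Delta_r G'|$ given the concentration bounds, CI widths and ion costs,
  plus a safety margin — never a magic constant.

Reactions without an estimate — all ferredoxin-containing reactions, since
group-contribution methods cannot assign a formation energy to ferredoxin —
keep their direction binaries but carry no energy constraint. Their
direction is controlled only by bounds and condition profiles, and the RNF
complex is fixed in its ferredoxin-reducing, proton-consuming direction in
the curated bacterial core: with three exempt electron carriers an
unconstrained RNF would close a cycle able to pump protons from nothing.

## Uncertainty on the reaction basis

The per-reaction slack $\delta_i$ is deliberately independent between
reactions. This is tractable (each slack is one bounded variable) but loose:
around a stoichiometric cycle the true energies must sum to zero, while
independent slacks allow the sum to move by the sum of the half-widths.
The package documents this as a property rather than hiding it: the
three-reaction `loop_fixture()` carries no flux when SEs are zero (the loop
law), and the same cycle can run once each reaction is granted an SE of
3 kJ/mol. Test fixtures are generated from explicit formation-energy
assignments so that this distinction is exact, not approximate.

## Fixed-activity conventions

Water and protons appear in stoichiometry (the elemental balance checker
uses them) but are excluded from both concentration variables and mass
balance: the medium is treated as buffered and aqueous. Cofactor pairs
(NAD(H), F420, menaquinone, CoA thioesters, adenylates) and carrier-bound
one-carbon intermediates have fixed activities; their physiological ratios
are folded into the curated $\Delta_r G'^0$ values — for example the
adenylate system is assigned the physiological phosphorylation potential of
$-55$ kJ/mol rather than the standard $-32$. Dissolved H2 and formate have
no concentration lower bound (they fall well below 0.01 mM in syntrophic
media); the solver substitutes a numerical floor of $10^{-10}$ M. All other
species use the global bounds of 0.01 mM and 20 mM.

## Membrane energetics

Ion translocation is stoichiometric: periplasmic protons and sodium ions
are explicit, mass-balanced species, so proton-motive-force generation by
fumarate reductase and consumption by ATP synthase close exactly over any
steady state. Their energetic contribution is a single configurable
parameter, `ion_cost` (default 17.4 kJ/mol $= F \times 180$ mV), added per
ion moved. This is a declared surrogate for a full membrane-potential/pH
treatment: the published membrane potentials for these organisms are not
available, and a per-ion cost keeps the accounting transparent.

# The curated cores

The two core models transcribe the experimentally characterised carbon and
electron pathways. Their calibration dials are exactly two integers:
fumarate reductase translocates 2 H+ per turnover and ATP synthase consumes
4 ions per ATP. With those values:

* the methanogen gains 0.5 ATP per CH4 (2 Na+ exported by the
  methyltransferase, converted 1:1 to protons by the antiporter, 4 protons
  per ATP), consuming 4 H2 per CH4;
* the bacterium nets $+0.5$ ATP per propionate in coculture: $+1$ at
  succinyl-CoA synthetase minus $0.5$ invested to drive succinate oxidation
  backwards through the fumarate-reductase/menaquinone step;
* fumarate respiration yields 3 ATP per 7 fumarate (12 protons from six
  menaquinol oxidations), reproducing the 7 fumarate $\to$ 6 succinate +
  4 CO2 overall stoichiometry at the ATP optimum.

Two structural choices deserve justification. First, the full oxidation of
fumarate to 4 CO2 releases 12 electrons — six carrier pairs, not five — so
the lumped acetyl-CoA oxidation step yields 2 NADH + 2 reduced ferredoxin
on top of the malate dehydrogenase NADH and the PFOR ferredoxin. Second,
the lumped oxidation branch carries no substrate-level ATP: at the maximal-H2
solution on fumarate (1 fumarate $\to$ 4 CO2 + 6 H2) no proton-motive force
is generated and the net ATP yield must be exactly zero, which an oxidative
SLP site would violate. Propionate activation uses the
acetyl-CoA:propionate CoA-transferase, so acetate release carries no kinase
ATP; the single SLP site in the propionate pathway is succinyl-CoA
synthetase.

The sodium-coupled ATP-synthase variant (`core_variant(atpase_coupling =
"sodium")`) lets methyltransferase-exported Na+ drive ATP synthesis
directly; the antiporter then has no proton consumer and its flux is forced
to zero by ion closure — the same behaviour the uncertainty analysis of the
ion stoichiometries predicts.

The formyltransferase (FMFTSPFT) is the one reaction whose slack is bounded
by a 99% rather than 95% confidence interval. Because its participants are
carrier-bound (fixed activity), its energy is $\Delta_r G'^0 + \delta$
exactly; with the curated estimate of $+10$ kJ/mol and SE 5, the 95% slack
($\pm 9.8$) cannot reach $-\varepsilon$, while the 99% slack ($\pm 12.88$)
can. The core therefore shuts down at the 95% level — the package's test
suite asserts this.

The curated thermodynamic table is data, not code: it is derived at build
time from one internal, self-consistent formation-energy assignment (on a
pH-7 transformed convention), so cycles of non-exempt reactions sum to
exactly zero, and it can be swapped for external estimates via the tabular
dialect. Standard errors are curated per reaction class; the membrane
steps that must run against the redox ladder at very low product
concentrations (the cytosolic hydrogenase and formate dehydrogenase, the
F420-reducing hydrogenase) carry SE 10 kJ/mol, the magnitude typical of
group-contribution estimates. A pleasant side effect of these numbers is
that menaquinol-driven H2 production becomes infeasible above roughly
$10^{-8}$ M dissolved H2 (about 2 Pa), the right order of magnitude for the
observed cessation of monoculture H2 production near 10 Pa.

# Parsimonious TMFA and the enzyme-cost weights

`solve_ptmfa()` fixes the stage-1 optimum (relative tolerance $10^{-6}$)
and minimizes $\sum_i w_i |v_i|$ over the directed halves. The weights are
an enzyme-cost proxy: enzymatic reactions weigh 1, while exchanges and
passive, diffusion-like membrane crossings (H2, CO2, formate, methane,
carboxylic acids crossing the membrane; the extracellular formate
$\leftrightarrow$ CO2 + H2 interconversion) weigh 0, since they are not
enzyme-limited in the same sense. With the electron-transfer reactions
expressed per pair (the confurcating enzymes transfer two pairs per
turnover), the H2-transfer and formate-transfer routings of the coculture
have identical weighted flux — they are exact alternate optima, which is
how the package reproduces the observed equivalence of the two
interspecies electron carriers.

# The chemostat coculture

`build_reactor()` merges the two cores over their shared extracellular
metabolites. Three formulation choices matter:

* **Shared medium activities.** The extracellular ln-concentration
  variables are common to both species' thermodynamic constraints: one
  reactor, one medium. This is the mechanism of syntrophy in the model.
* **Inequality reactor balances.** Extracellular species carry
  biomass-weighted community rows $\sum_k X_k q_{jk} \ge 0$ (flux steady
  state; accumulation is washed out by dilution) instead of unit mass
  balances; feed substrates are free in sign. Species rates $q_{jk}$ are
  membrane-crossing fluxes, not per-species drains, because drains on a
  shared pool would make the species attribution arbitrary under biomass
  weighting.
* **Fixed biomasses.** Both species' growth fluxes are pinned to the
  dilution rate and the biomass concentrations are parameters, keeping the
  problem a MILP. Only the biomass ratio matters when the feed is
  unlimited — scaling both concentrations leaves all yields unchanged, a
  property the tests assert.

Infeasibility at a grid point is a first-class result: it is exactly how
the model expresses "the consumer cannot pay its maintenance at this
biomass ratio", and sweeps flag it per point rather than failing.
`critical_ratio()` bisects the consumer-to-producer ratio down to the point
where the community H2 yield reaches zero; at higher ratios the reactor is
infeasible. For the curated pair at $D = 0.05$/day the critical
*M. hungatei* : *S. fumaroxidans* ratio is finite and somewhat above 1;
its exact value at genome scale depends on the full reconstructions and
their free-energy estimates, which is why the package asserts finiteness
and monotone bracketing rather than a number.

Biomass in the cores is an energy-plus-small-carbon drain (GAM ATP plus one
acetate + one CO2 carbon equivalent per unit growth for the bacterium, CO2
plus two F420H2 for the archaeon); full biomass composition is out of
scope, and the genome-scale growth predictions are not reproduced by these
cores by design.

# Calibration

`fit_maintenance()` is ordinary least squares on the chemostat energy
balance $q_{ATP} = GAM\,\mu + NGAM$ (unweighted; a negative intercept is
clipped to zero with a warning). `fit_sur()` inverts the monotone
growth-versus-uptake-cap curve by bisection, returning the smallest cap at
which TMFA maximal growth matches the observation within $10^{-3}$/day.
The shipped defaults (GAM 22.8 mmol ATP/gDW, NGAM 3.36 mmol ATP/gDW/day and
uptake caps 37.7/27.6 mmol/gDW/day for the bacterium; 47, 0.6, 75.7 and 955
for the archaeon) are stored as verified constants of the builders, since
the underlying chemostat measurements are not redistributed with the
package; `core_parameters()` lists them with units.

# Synthetic data

`generate_network()` draws a linear uptake-to-secretion chain with
formation energies decreasing in steps of 5–25 kJ/mol (so a feasible
downhill path always exists), plus random shortcut reactions and optional
deliberate 3-cycles, all $\Delta_r G'^0$ values computed from the same
formation assignment. Everything is deterministic given the seed, and the
generator restores the caller's RNG state. `chemostat_dataset()` produces
seeded Gaussian-noise maintenance data. What these fixtures emulate is the
*structure* of the inference problem — consistent energies, cycles, noisy
linear calibration data; what they do not emulate is genome-scale topology,
correlated group-contribution errors, or real measurement error models, so
green property tests certify the machinery, not field performance on a
particular organism.

# Numerical choices

* Strictness margin $\varepsilon = 0.5$ kJ/mol; optimality and
  stage-coupling tolerances $10^{-6}$ (relative); steady-state and
  sign-coupling assertions at $10^{-6}$ in flux units.
* Concentration floor $10^{-10}$ M for species without a lower bound.
* Directed halves of unbounded reactions are capped at 1000 mmol/gDW/day
  inside the MILP (binaries need finite big-M); plain FBA keeps infinite
  bounds and reports unboundedness.
* The MILP backend is scipy's HiGHS-based `milp` (single-threaded,
  deterministic; relative MIP gap 0), called through a bundled script; any
  backend honouring the same contract can be plugged in via
  `options(syntmfa.milp_backend = ...)`.
* Alternate optima are real (the carrier-equivalence is one); reported
  fluxes are whichever vertex the solver returns, deterministically for a
  fixed model and backend.

Problem sizes throughout the package's tests and scripts are the curated
cores (27–36 reactions per species, 48 in the combined reactor) and
synthetic networks of 5–8 metabolites; these sizes exercise every code
path while keeping a full run of the suite in minutes on one CPU.

# Known limitations

* Reaction-basis uncertainty ignores thermodynamic interconnectivity
  between reactions sharing metabolites; formation/group-basis constraints
  are future work, and the fixture suite already probes the difference.
* Thermo-exempt reactions (all ferredoxin chemistry) are direction-
  controlled only by curation; like the underlying method, the package
  cannot rule out H2 production in monoculture on thermodynamic grounds
  alone, and the monoculture profiles therefore block it qualitatively.
* Membrane transport is thermodynamically exempt; predicted extracellular
  concentration bounds are correspondingly loose compared to a model with
  explicit transport energetics.
* The cores reproduce overall catabolic stoichiometries and ATP yields,
  not growth rates or genome-scale secretion patterns; those require the
  full reconstructions, which the SBML reader can load but whose numeric
  reproduction is explicitly out of scope.
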