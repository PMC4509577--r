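# syntmfa

Thermodynamics-based metabolic flux analysis (TMFA) for syntrophic
microbial communities, with curated core models of the propionate-oxidizing
bacterium *Syntrophobacter fumaroxidans* and the hydrogenotrophic
methanogen *Methanospirillum hungatei*.

## What it does, and for whom

Syntrophic propionate oxidation

    propionate + 2 H2O -> acetate + CO2 + 3 H2

is endergonic under standard conditions; it proceeds only because a partner
methanogen consumes the H2 (or formate) and keeps its concentration low.
`syntmfa` is for microbial physiologists and systems biologists who want to
interrogate such thermodynamically marginal metabolism quantitatively: it
couples reaction directionality to transformed Gibbs energies inside a
mixed-integer program, propagates confidence-interval uncertainty on the
energy estimates, and extends the formulation to a two-species chemostat in
which both organisms share one medium — including the medium's metabolite
activities, which is what couples their thermodynamics.

At its core is the TMFA constraint set: for each reaction *i* with an
energy estimate, direction binaries `z` enforce

    v_i,d <= ub * z_i,d
    ±Δ_r G'_i <= -ε + K (1 - z_i,d)
    Δ_r G'_i = Δ_r G'⁰_i + δ_i + RT Σ_j s_ij ln c_j (+ ion terms),
    |δ_i| <= z(CI) * SE_i

with metabolite log-concentrations `ln c_j` bounded (0.01 mM–20 mM by
default; no lower bound for dissolved H2 and formate) and the slack `δ_i`
bounded by the 95% (or, where curated, 99%) confidence interval of the
estimate. Ferredoxin reactions, which have no estimates, keep binaries but
no energy constraint. On top of this sit:

* `solve_tmfa()` / `solve_fba()` — MILP optimum / LP relaxation;
* `solve_ptmfa()` — two-stage parsimonious variant (fix the optimum,
  minimize weighted total flux as an enzyme-cost proxy);
* `solve_variability()` — min/max of concentrations, fluxes or reaction
  energies over the (near-)optimal feasible region;
* `build_reactor()` / `solve_reactor()` / `sweep_reactor()` /
  `critical_ratio()` — fixed-biomass chemostat coculture with
  biomass-weighted reactor balances and a species-weighted parsimonious
  objective;
* `build_sfu_core()` / `build_mhu_core()` / `condition_profiles()` —
  curated cores and the named growth-condition overlays;
* `fit_maintenance()` / `fit_sur()` — GAM/NGAM and uptake-cap calibration;
* `generate_network()` / `loop_fixture()` / `chemostat_dataset()` —
  seed-reproducible synthetic test surfaces;
* tabular (TSV) and SBML readers/writers, `tidy()`/`glance()` methods and
  `autoplot()` figures throughout, plus a thin command-line wrapper in
  `exec/syntmfa`.

The MILP backend is scipy's HiGHS-based `milp`, driven through a small
bundled Python script (Python ≥ 3.9 with numpy and scipy on `PATH`); any
solver honouring the same contract can be plugged in via
`options(syntmfa.milp_backend = ...)`.

## Worked example

Maximal ATP production by the *S. fumaroxidans* core growing syntrophically
on one propionate, with CO2 (not formate) as the carbon by-product:

```r
library(syntmfa)
library(dplyr)

sfu <- build_sfu_core()
sfu
#> <metabolic_model> sfu_core
#>   metabolites: 36 (3 boundary)
#>   reactions:   36 (7 exchanges, 22 thermo-exempt)
#>   objective:   ATPSINK  GAM = 22.8  NGAM = 3.36

sol <- sfu |>
  apply_condition(condition_profiles()$coculture) |>
  relax_maintenance() |>                 # no-growth overall stoichiometry
  fix_uptake("EX_prop", 1) |>
  block_reaction("EX_for") |>
  solve_tmfa(objective = "ATPSINK")

glance(sol)
#> # A tibble: 1 × 5
#>   status  objective objective_value n_active total_flux
#>   <chr>   <chr>               <dbl>    <int>      <dbl>
#> 1 optimal ATPSINK               0.5       20         NA

tidy(sol) |> filter(abs(flux) > 1e-6) |> arrange(desc(abs(flux)))
#> # A tibble: 20 × 5
#>   reaction  flux drg_prime drg0_adjust exempt
#>   <chr>    <dbl>     <dbl>       <dbl> <lgl>
#> 1 Th2      -3.00    NA           NA    TRUE
#> 2 EX_h2     3.00    NA           NA    TRUE
#> 3 PCT       1      -35.4         -7.84 FALSE
#> 4 TC        1      -11.8         -7.84 FALSE
#> 5 MUT       1      -12.9         -5.88 FALSE
#> 6 SCS       1      -15.9         -7.84 FALSE
#> 7 FRD      -1       13.3        -11.8  FALSE
#> 8 FUM       1       -0.500       -5.88 FALSE
#> # ...
```

Read: the optimum nets **0.5 mol ATP per mol propionate** and exports
**3 H2** (the `Th2`/`EX_h2` rows) alongside one acetate and one CO2 — the
syntrophic overall stoichiometry. Every used reaction with an energy
estimate has `drg_prime` opposing its flux (`FRD` runs in reverse, as
succinate dehydrogenase, at +13.3 kJ/mol); `drg0_adjust` is the
confidence-interval slack each reaction used. The net ATP gain is the
succinyl-CoA synthetase ATP minus the proton-motive-force investment that
drives succinate oxidation backwards through the menaquinone pool — the
energetic signature of syntrophic propionate oxidation.

The two-species chemostat at a 3:4 *M. hungatei* : *S. fumaroxidans*
biomass ratio and D = 0.05/day:

```r
cp <- build_reactor(apply_condition(build_sfu_core(),
                                    condition_profiles()$coculture),
                    build_mhu_core(), X_A = 4, X_B = 3, D = 0.05)
rs <- solve_reactor(cp, force_zero = "for_e")   # H2-only transfer
tidy(rs)   # community rates (mmol/L/day) and yields per propionate
```

At this ratio the community exports H2 (yield ≈ 1 mol/mol propionate): the
bacterium produces more H2 than the methanogen's energy demand consumes.
`critical_ratio()` bisects to the biomass ratio where the net H2 yield
first reaches zero; beyond it the methanogen can no longer pay its
maintenance and the reactor is infeasible.

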