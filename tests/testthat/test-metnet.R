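# Network data model, readers/writers, and constraint overlays.

test_that("tabular round trip preserves ids, stoichiometry, bounds and thermodynamics", {
  for (mdl in list(build_sfu_core(), build_mhu_core(),
                   generate_network(synthetic_spec(seed = 4,
                                                   se_mode = "uniform")))) {
    dir <- withr::local_tempdir()
    write_model_tsv(mdl, dir)
    back <- load_model(dir, "tabular")
    expect_identical(back$metabolites$id, mdl$metabolites$id)
    expect_identical(back$reactions$id, mdl$reactions$id)
    expect_identical(back$reactions$stoich, mdl$reactions$stoich)
    expect_identical(back$reactions$lb, mdl$reactions$lb)
    expect_identical(back$reactions$ub, mdl$reactions$ub)
    expect_identical(back$reactions$drg0_est, mdl$reactions$drg0_est)
    expect_identical(back$reactions$drg0_se, mdl$reactions$drg0_se)
    expect_identical(back$reactions$ci_level, mdl$reactions$ci_level)
    expect_identical(back$reactions$thermo_exempt,
                     mdl$reactions$thermo_exempt)
    expect_identical(back$gam, mdl$gam)
    expect_identical(unlist(back$sur_caps), unlist(mdl$sur_caps))
  }
})

test_that("minimal tabular model loads with absent thermodynamics as exempt", {
  mets <- dplyr::bind_rows(metabolite("m1"), metabolite("m2"),
                           metabolite("m3"))
  rxns <- dplyr::bind_rows(reaction("r1", c(m1 = -1, m2 = 1)),
                           reaction("r2", c(m2 = -1, m3 = 1)))
  mdl <- metabolic_model(mets, rxns, objective_id = "r2", id = "mini")
  dir <- withr::local_tempdir()
  write_model_tsv(mdl, dir)
  back <- load_model(dir)
  expect_equal(nrow(back$metabolites), 3)
  expect_equal(nrow(back$reactions), 2)
  expect_true(all(back$reactions$thermo_exempt))
})

test_that("SBML serialization of the Mhu core round-trips ids, stoich and bounds", {
  mdl <- build_mhu_core()
  file <- withr::local_tempfile(fileext = ".xml")
  write_model_sbml(mdl, file)
  back <- read_model_sbml(file)
  expect_identical(back$metabolites$id, mdl$metabolites$id)
  expect_identical(back$reactions$id, mdl$reactions$id)
  reorder_stoich <- function(l) purrr::map(l, function(s) s[order(names(s))])
  expect_equal(reorder_stoich(back$reactions$stoich),
               reorder_stoich(mdl$reactions$stoich))
  expect_equal(back$reactions$lb, mdl$reactions$lb)
  expect_equal(back$reactions$ub, mdl$reactions$ub)
})

test_that("undeclared metabolites and duplicate ids are validation errors naming ids", {
  mets <- dplyr::bind_rows(metabolite("m1"), metabolite("m2"))
  expect_error(
    metabolic_model(mets, reaction("r1", c(m1 = -1, ghost = 1)),
                    objective_id = "r1"),
    "ghost")
  expect_error(
    metabolic_model(dplyr::bind_rows(mets, metabolite("m1")),
                    reaction("r1", c(m1 = -1, m2 = 1)),
                    objective_id = "r1"),
    "duplicate")
})

test_that("elemental balance checker counts atoms and skips exchanges", {
  # lumped fumarate oxidation: fumarate + 4 H2O -> 4 CO2 + 6 H2
  mets <- dplyr::bind_rows(
    metabolite("fum", formula = "C4H4O4"),
    metabolite("h2o", formula = "H2O", boundary = TRUE, fixed_conc = TRUE),
    metabolite("co2", formula = "CO2"),
    metabolite("h2", formula = "H2"),
    metabolite("x_e", compartment = "extracellular", formula = "CO2")
  )
  rxns <- dplyr::bind_rows(
    reaction("LUMP", c(fum = -1, h2o = -4, co2 = 4, h2 = 6)),
    reaction("BAD", c(co2 = -1, h2 = 1)),
    reaction("EX_x", c(x_e = -1), is_exchange = TRUE)
  )
  mdl <- metabolic_model(mets, rxns, objective_id = "LUMP")
  rep <- check_elemental_balance(mdl)
  expect_false("LUMP" %in% rep$deltas$reaction)
  expect_true("BAD" %in% rep$deltas$reaction)
  expect_false("EX_x" %in% c(rep$checked, rep$unchecked))
  # CH4 -> CH3 is one hydrogen short
  bad <- metabolic_model(
    dplyr::bind_rows(metabolite("a", formula = "CH4"),
                     metabolite("b", formula = "CH3")),
    reaction("r", c(a = -1, b = 1)), objective_id = "r")
  d <- check_elemental_balance(bad)$deltas
  expect_equal(d$delta[d$element == "H"], -1)
})

test_that("apply_condition tightens bounds, registers ratios, and is idempotent", {
  mdl <- build_sfu_core()
  prof <- condition_profiles()$fumprop_mono
  once <- apply_condition(mdl, prof)
  twice <- apply_condition(once, prof)
  i <- match("EX_h2", once$reactions$id)
  expect_equal(unname(unlist(once$reactions[i, c("lb", "ub")])), c(0, 0))
  expect_identical(once$reactions, twice$reactions)
  expect_identical(once$uptake_ratios, twice$uptake_ratios)
  # never widens: every bound is within the original interval
  expect_true(all(once$reactions$lb >= mdl$reactions$lb))
  expect_true(all(once$reactions$ub <= mdl$reactions$ub))
})

test_that("uptake-ratio and coupling constraints hold at solver solutions", {
  mdl <- relax_maintenance(
    apply_condition(build_sfu_core(), condition_profiles()$fumprop_mono))
  mdl <- fix_uptake(mdl, "EX_prop", 1)
  sol <- solve_tmfa(mdl, objective = "ATPSINK")
  expect_equal(flux_of(sol, "EX_fum"), 3 * flux_of(sol, "EX_prop"),
               tolerance = 1e-6)

  # explicit flux coupling between fumarate reductase and the cytosolic
  # hydrogenase (membrane co-localization)
  cpl <- condition_profile(
    "frd_cyth2ase",
    couplings = tibble::tibble(rxn_a = "FRD", rxn_b = "cytH2ase",
                               ratio = 1))
  mdl2 <- apply_condition(
    relax_maintenance(
      apply_condition(build_sfu_core(), condition_profiles()$fumarate_mono)),
    cpl)
  mdl2 <- fix_uptake(mdl2, "EX_fum", 7)
  sol2 <- solve_tmfa(mdl2, objective = "ATPSINK")
  expect_equal(flux_of(sol2, "FRD"), flux_of(sol2, "cytH2ase"),
               tolerance = 1e-6)
})

test_that("conflicting direction fixes raise an error", {
  expect_error(
    apply_condition(build_sfu_core(), condition_profile(
      "bad", direction_fixes = c(FRD = "forward", FRD = "reverse"))),
    "conflicting")
})
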