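# Curated core models: elemental closure, growth-mode stoichiometries, and
# bioenergetic calibration.

sfu_yield_run <- function(profile, uptake_ex, uptake, objective = "ATPSINK") {
  mdl <- relax_maintenance(
    apply_condition(build_sfu_core(), condition_profiles()[[profile]]))
  mdl <- fix_uptake(mdl, uptake_ex, uptake)
  solve_tmfa(mdl, objective = objective)
}

test_that("every formulated internal reaction of both cores is balanced", {
  for (mdl in list(build_sfu_core(), build_mhu_core(),
                   build_mhu_core(core_variant(atpase_coupling = "sodium")))) {
    rep <- check_elemental_balance(mdl)
    expect_equal(nrow(rep$deltas), 0)
    # only the biomass drains lack formulas
    expect_true(all(grepl("^BIOMASS", rep$unchecked)))
  }
})

test_that("the Mhu core yields 0.5 ATP per CH4 from 4 H2 per CH4", {
  mhu <- relax_maintenance(
    apply_condition(build_mhu_core(),
                    condition_profiles()$mhu_hydrogenotrophic))
  mhu <- fix_uptake(mhu, "EX_co2", 10)
  sol <- solve_tmfa(mhu, objective = "ATPSINK_MHU")
  expect_equal(sol$status, "optimal")
  ch4 <- flux_of(sol, "EX_ch4")
  expect_equal(sol$objective_value / ch4, 0.5, tolerance = 1e-6)
  expect_equal(-flux_of(sol, "EX_h2") / ch4, 4, tolerance = 1e-6)
  expect_sign_coupling(sol)
  expect_lt(max_balance_residual(mhu, sol), 1e-5)
})

test_that("sodium-coupled ATP synthase silences the antiporter at the same yield", {
  mhu <- relax_maintenance(
    apply_condition(build_mhu_core(core_variant(atpase_coupling = "sodium")),
                    condition_profiles()$mhu_hydrogenotrophic))
  mhu <- fix_uptake(mhu, "EX_co2", 10)
  sol <- solve_tmfa(mhu, objective = "ATPSINK_MHU")
  expect_equal(sol$objective_value / flux_of(sol, "EX_ch4"), 0.5,
               tolerance = 1e-6)
  expect_equal(flux_of(sol, "NAT3_1"), 0, tolerance = 1e-6)
})

test_that("the formyltransferase needs its 99% confidence interval", {
  # at the 95% level the carrier-bound formyl transfer (+10 kJ/mol, SE 5)
  # cannot reach DrG' <= -eps and methanogenesis shuts down
  mhu <- build_mhu_core()
  i <- match("FMFTSPFT", mhu$reactions$id)
  expect_equal(mhu$reactions$ci_level[i], 0.99)
  m95 <- mhu
  m95$reactions$ci_level[i] <- 0.95
  m95 <- fix_uptake(relax_maintenance(
    apply_condition(m95, condition_profiles()$mhu_hydrogenotrophic)),
    "EX_co2", 10)
  sol95 <- solve_tmfa(m95, objective = "ATPSINK_MHU")
  v95 <- if (sol95$status == "optimal") sol95$objective_value else 0
  expect_equal(v95, 0, tolerance = 1e-6)
})

test_that("fumarate monoculture reproduces 7 fumarate -> 6 succinate + 4 CO2", {
  sol <- sfu_yield_run("fumarate_mono", "EX_fum", 7)
  expect_equal(sol$status, "optimal")
  expect_equal(flux_of(sol, "EX_succ"), 6, tolerance = 1e-6)
  expect_equal(flux_of(sol, "EX_co2"), 4, tolerance = 1e-6)
  expect_equal(flux_of(sol, "EX_ac"), 0, tolerance = 1e-6)
  # redox bookkeeping: six menaquinol per six fumarate reduced
  expect_equal(flux_of(sol, "FRD"), 6, tolerance = 1e-6)
  expect_sign_coupling(sol)
  # periplasmic ion closure is part of steady state
  expect_lt(max_balance_residual(sol_model <- relax_maintenance(
    apply_condition(build_sfu_core(), condition_profiles()$fumarate_mono)),
    sol), 1e-5)
})

test_that("fumarate+propionate monoculture yields 3 succinate per propionate", {
  sol <- sfu_yield_run("fumprop_mono", "EX_prop", 1)
  expect_equal(flux_of(sol, "EX_succ"), 3, tolerance = 1e-6)
  expect_equal(flux_of(sol, "EX_ac"), 1, tolerance = 1e-6)
  expect_equal(flux_of(sol, "EX_co2"), 1, tolerance = 1e-6)
  expect_equal(-flux_of(sol, "EX_fum"), 3, tolerance = 1e-6)
})

test_that("coculture profile yields 3 H2 (CO2 mode) or 2 H2 + formate (formate mode)", {
  mdl <- relax_maintenance(
    apply_condition(build_sfu_core(), condition_profiles()$coculture))
  m3 <- block_reaction(fix_uptake(mdl, "EX_prop", 1), "EX_for")
  s3 <- solve_tmfa(m3, objective = "ATPSINK")
  expect_equal(flux_of(s3, "EX_h2"), 3, tolerance = 1e-6)
  expect_equal(flux_of(s3, "EX_ac"), 1, tolerance = 1e-6)
  expect_gt(s3$objective_value, 0) # net ATP positive despite the SDH cost

  m4 <- block_reaction(fix_uptake(mdl, "EX_prop", 1), "EX_co2")
  s4 <- solve_tmfa(m4, objective = "ATPSINK")
  expect_equal(flux_of(s4, "EX_h2"), 2, tolerance = 1e-6)
  expect_equal(flux_of(s4, "EX_for"), 1, tolerance = 1e-6)
})

test_that("maximal H2 on fumarate gives 6 H2 + 4 CO2 with zero net ATP", {
  mdl <- relax_maintenance(
    apply_condition(build_sfu_core(), condition_profiles()$fumarate_h2))
  mdl <- fix_uptake(mdl, "EX_fum", 1)
  sol <- solve_tmfa(mdl, objective = "EX_h2")
  expect_equal(sol$objective_value, 6, tolerance = 1e-6)
  expect_equal(flux_of(sol, "EX_co2"), 4, tolerance = 1e-6)
  # no PMF is generated: ATP drain and synthase are both silent
  expect_equal(flux_of(sol, "ATPSINK"), 0, tolerance = 1e-6)
  expect_equal(flux_of(sol, "ATPS"), 0, tolerance = 1e-6)
})

test_that("builders expose the documented maintenance and uptake defaults", {
  sfu <- build_sfu_core()
  mhu <- build_mhu_core()
  expect_equal(c(sfu$gam, sfu$ngam), c(22.8, 3.36))
  expect_equal(c(mhu$gam, mhu$ngam), c(47, 0.6))
  expect_equal(unname(sfu$sur_caps[c("EX_prop", "EX_fum")]), c(37.7, 27.6))
  expect_equal(unname(mhu$sur_caps[c("EX_co2", "EX_for")]), c(75.7, 955))
})
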