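# MILP engine: TMFA, parsimonious TMFA, and variability analysis.

test_that("a feasible downhill chain carries flux at the uptake cap", {
  sol <- solve_tmfa(chain_model())
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 5, tolerance = 1e-6)
  expect_lt(max_balance_residual(chain_model(), sol), 1e-6)
  expect_sign_coupling(sol)
})

test_that("an uphill middle reaction beyond the concentration span blocks the chain", {
  # RT ln over the global bounds spans at most ~19.6 kJ/mol per unit
  # stoichiometry at 310 K; +50 kJ/mol cannot be rescued
  sol <- solve_tmfa(chain_model(mid_drg0 = 50))
  expect_equal(sol$objective_value, 0, tolerance = 1e-9)
})

test_that("widening the confidence level never decreases the optimum", {
  # +25 kJ/mol with SE 10 between fixed-activity metabolites: infeasible at
  # the 95% level (25 - 19.6 > -eps), feasible at 99% (25 - 25.76 < -eps)
  m95 <- chain_model(mid_drg0 = 25, mid_se = 10, mid_ci = 0.95,
                     fixed_conc_mid = TRUE)
  m99 <- chain_model(mid_drg0 = 25, mid_se = 10, mid_ci = 0.99,
                     fixed_conc_mid = TRUE)
  v95 <- solve_tmfa(m95)$objective_value
  v99 <- solve_tmfa(m99)$objective_value
  expect_equal(v95, 0, tolerance = 1e-9)
  expect_equal(v99, 5, tolerance = 1e-6)
  expect_gte(v99, v95)
})

test_that("the loop law forbids net cycle flux and CI slack can restore it", {
  sol <- solve_tmfa(loop_fixture(), objective = "RAB")
  expect_equal(sol$objective_value, 0, tolerance = 1e-9)
  # with SE = 3 at 95%, each energy can move by 5.88: enough to make all
  # three negative (+10 needs 10.5 of the 17.64 total slack)
  sol3 <- solve_tmfa(loop_fixture(se = 3), objective = "RAB")
  expect_gt(sol3$objective_value, 0)
  expect_sign_coupling(sol3)
  # without thermodynamic constraints the unbounded loop is exposed
  fba <- solve_fba(loop_fixture(bounded = FALSE), objective = "RAB")
  expect_equal(fba$status, "unbounded")
})

test_that("TMFA is bounded by FBA on seeded synthetic networks", {
  for (seed in 1:8) {
    net <- generate_network(synthetic_spec(
      n_metabolites = 6, n_reactions = 8, cycle_injections = 1,
      se_mode = if (seed %% 2) "zero" else "uniform", seed = seed))
    fba <- solve_fba(net)
    tmfa <- solve_tmfa(net)
    expect_equal(tmfa$status, "optimal")
    expect_lte(tmfa$objective_value, fba$objective_value + 1e-6)
    expect_sign_coupling(tmfa)
    expect_lt(max_balance_residual(net, tmfa), 1e-6)
  }
})

test_that("deterministic replay returns identical objectives", {
  net <- generate_network(synthetic_spec(seed = 5, cycle_injections = 1))
  v1 <- solve_tmfa(net)$objective_value
  v2 <- solve_tmfa(net)$objective_value
  expect_equal(v1, v2, tolerance = 1e-6)
})

test_that("pTMFA prefers the direct route and preserves the stage-1 optimum", {
  mdl <- chain_model()
  extra <- dplyr::bind_rows(
    reaction("Rd1", c(A = -1, B = 1), lb = 0, drg0_est = -5),
    reaction("Rd2", c(A = -1, B = 1), lb = 0, drg0_est = -5)
  )
  mdl$reactions <- dplyr::bind_rows(mdl$reactions, extra)
  p <- solve_ptmfa(mdl)
  expect_equal(p$objective_value, p$stage1_objective, tolerance = 1e-5)
  # direct route: three internal reactions at flux 5 -> total flux 15
  expect_equal(p$total_flux, 15, tolerance = 1e-3)
  expect_equal(flux_of(p, "Rd1"), 0, tolerance = 1e-6)
  # the stage-1 incumbent is feasible for stage 2, so the minimized total
  # flux can never exceed the incumbent's
  s1 <- solve_tmfa(mdl)
  w <- mdl$reactions$parsimony_weight
  incumbent <- sum(abs(s1$fluxes$flux) * w[match(s1$fluxes$reaction,
                                                 mdl$reactions$id)])
  expect_lte(p$total_flux, incumbent + 1e-6)
})

test_that("variability ranges behave and nest under bound tightening", {
  mdl <- chain_model()
  tg <- tibble::tibble(type = c("conc", "flux", "energy"),
                       id = c("A", "R1", "R1"))
  v <- solve_variability(mdl, targets = tg, objective_floor = 1)
  expect_equal(v$lo[v$type == "flux"], 5, tolerance = 1e-6)
  expect_equal(v$hi[v$type == "flux"], 5, tolerance = 1e-6)
  expect_lte(v$hi[v$type == "energy"], -0.5 + 1e-6)

  # an unconstrained metabolite in a thermo-exempt network spans the global
  # concentration bounds
  mets <- dplyr::bind_rows(metabolite("X_e", compartment = "extracellular"),
                           metabolite("Y"))
  rxns <- dplyr::bind_rows(
    reaction("T1", c(X_e = -1, Y = 1)),
    reaction("EX_X", c(X_e = -1), lb = -10, is_exchange = TRUE),
    reaction("SINK", c(Y = -1), lb = 0))
  free <- metabolic_model(mets, rxns, objective_id = "SINK")
  vf <- solve_variability(free, targets = "Y", objective_floor = NULL)
  expect_equal(vf$lo, 1e-5, tolerance = 1e-6)
  expect_equal(vf$hi, 0.02, tolerance = 1e-6)

  # forced flux through A -> B with DrG'0 = 0 forbids c_B >= c_A
  mets2 <- dplyr::bind_rows(
    metabolite("A", compartment = "extracellular"),
    metabolite("B", compartment = "extracellular"))
  rx2 <- dplyr::bind_rows(
    reaction("RAB", c(A = -1, B = 1), lb = 1, ub = 1, drg0_est = 0),
    reaction("EX_A", c(A = -1), lb = -10, ub = 0, is_exchange = TRUE),
    reaction("EX_B", c(B = -1), lb = 0, ub = 10, is_exchange = TRUE))
  forced <- metabolic_model(mets2, rx2, objective_id = "EX_B")
  vr <- solve_variability(forced, targets = c("A", "B"),
                          objective_floor = NULL)
  expect_lt(vr$lo[vr$id == "B"], vr$hi[vr$id == "A"])
  ve <- solve_variability(forced,
                          targets = tibble::tibble(type = "energy",
                                                   id = "RAB"),
                          objective_floor = NULL)
  expect_lte(ve$hi, -0.5 + 1e-6) # max ln c_B - ln c_A stays negative

  # tightening a concentration bound never widens any returned range
  tight <- mdl
  i <- match("A", tight$metabolites$id)
  tight$metabolites$conc_lb[i] <- 1e-4
  tight$metabolites$conc_ub[i] <- 0.01
  vt <- solve_variability(tight, targets = tg, objective_floor = 1)
  expect_gte(vt$lo[1], v$lo[1] - 1e-9)
  expect_lte(vt$hi[1], v$hi[1] + 1e-9)
})

test_that("max_yield fixes uptake and reports the mol/mol ratio", {
  mdl <- chain_model(cap = 1000)
  y <- max_yield(mdl, product_exchange = "EX_P",
                 substrate_exchange = "EX_S", fixed_uptake = 3)
  expect_equal(y$yield, 1, tolerance = 1e-6)
  blocked <- mdl
  i <- match("EX_P", blocked$reactions$id)
  blocked$reactions$ub[i] <- 0
  # with the product path closed the substrate cannot be consumed either:
  # a fixed uptake is then infeasible, so use a sink-free yield of zero
  y0 <- max_yield(block_reaction(mdl, "T_out"),
                  product_exchange = "EX_P", substrate_exchange = "EX_S",
                  fixed_uptake = 3)
  expect_true(is.na(y0$yield) || y0$yield == 0)
})

test_that("infeasible problems report status with a conflict hint", {
  mdl <- chain_model()
  i <- match("EX_P", mdl$reactions$id)
  mdl$reactions$lb[i] <- 8 # demand above the uptake cap
  sol <- solve_tmfa(mdl)
  expect_equal(sol$status, "infeasible")
  expect_match(sol$conflict_hint, "constraint groups")
})
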