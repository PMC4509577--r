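# Chemostat coculture: reactor balances, species-weighted parsimony,
# sweeps and the critical biomass ratio.

coculture_pair <- function(gam_sfu = 22.8, ngam_sfu = 3.36,
                           gam_mhu = 47, ngam_mhu = 0.6) {
  list(
    sfu = apply_condition(build_sfu_core(gam = gam_sfu, ngam = ngam_sfu),
                          condition_profiles()$coculture),
    mhu = build_mhu_core(gam = gam_mhu, ngam = ngam_mhu)
  )
}

test_that("zero growth and maintenance admit the all-zero solution", {
  pair <- coculture_pair(0, 0, 0, 0)
  cp <- build_reactor(pair$sfu, pair$mhu, X_A = 4, X_B = 3, D = 0)
  rs <- solve_reactor(cp)
  expect_equal(rs$status, "optimal")
  expect_equal(rs$objective_value, 0, tolerance = 1e-6)
})

test_that("mismatched shared media are rejected with the symmetric difference", {
  pair <- coculture_pair()
  odd <- pair$mhu
  odd$metabolites <- dplyr::bind_rows(
    odd$metabolites,
    metabolite("mystery_e", compartment = "extracellular"))
  expect_error(build_reactor(pair$sfu, odd, 4, 3, 0.05), "mystery_e")
})

test_that("a consumed-but-never-produced metabolite is an infeasible balance", {
  cp <- build_reactor(toy_producer(), toy_consumer(demand = 1),
                      X_A = 1, X_B = 3, D = 0, feed = "s_e")
  # consumer needs 3 H2/L/day, producer supplies 2: community H2 < 0
  rs <- solve_reactor(cp)
  expect_equal(rs$status, "infeasible")
  expect_match(rs$conflict_hint, "community balances")
})

test_that("zero-maintenance coculture converts propionate to acetate + 0.25 CO2 + 0.75 CH4", {
  pair <- coculture_pair(0, 0, 0, 0)
  cp <- build_reactor(pair$sfu, pair$mhu, X_A = 4, X_B = 3, D = 0)
  rs <- solve_reactor(cp, objective = "max_rate", rate_met = "ch4_e",
                      force_zero = c("h2_e", "for_e"))
  y <- stats::setNames(rs$community_yields$yield,
                       rs$community_yields$metabolite)
  expect_equal(unname(y["ch4_e"]), 0.75, tolerance = 1e-6)
  expect_equal(unname(y["co2_e"]), 0.25, tolerance = 1e-6)
  expect_equal(unname(y["ac_e"]), 1, tolerance = 1e-6)
  expect_equal(unname(y["prop_e"]), -1, tolerance = 1e-6)
  # community carbon conservation: C(propionate) = C(products)
  carbon <- c(prop_e = 3, ac_e = 2, co2_e = 1, ch4_e = 1, for_e = 1,
              succ_e = 4, fum_e = 4, h2_e = 0)
  r <- stats::setNames(rs$community_rates$rate, rs$community_rates$metabolite)
  expect_equal(sum(r * carbon[names(r)]), 0, tolerance = 1e-6)
})

test_that("H2 and formate transfer are objective-equivalent alternate optima", {
  pair <- coculture_pair()
  cp_h2 <- build_reactor(block_reaction(pair$sfu, "Tfor"),
                         block_reaction(pair$mhu, "EFDH"),
                         X_A = 4, X_B = 3, D = 0.05)
  cp_for <- build_reactor(block_reaction(pair$sfu, "Th2"), pair$mhu,
                          X_A = 4, X_B = 3, D = 0.05)
  a <- solve_reactor(cp_h2)
  b <- solve_reactor(cp_for)
  expect_equal(a$status, "optimal")
  expect_equal(b$status, "optimal")
  expect_equal(a$objective_value, b$objective_value,
               tolerance = 1e-6 * max(1, abs(a$objective_value)))
  ya <- stats::setNames(a$community_yields$yield,
                        a$community_yields$metabolite)
  yb <- stats::setNames(b$community_yields$yield,
                        b$community_yields$metabolite)
  expect_equal(unname(ya["ch4_e"]), unname(yb["ch4_e"]), tolerance = 1e-6)
  expect_equal(unname(ya["ac_e"]), unname(yb["ac_e"]), tolerance = 1e-6)
  # one electron pair per carrier molecule: total carrier export matches
  expect_equal(unname(ya["h2_e"] + ya["for_e"]),
               unname(yb["h2_e"] + yb["for_e"]), tolerance = 1e-6)
})

test_that("at a 3:4 Mhu:Sfu ratio the community exports H2", {
  pair <- coculture_pair()
  cp <- build_reactor(pair$sfu, pair$mhu, X_A = 4, X_B = 3, D = 0.05)
  rs <- solve_reactor(cp, force_zero = "for_e")
  y <- rs$community_yields
  expect_gt(y$yield[y$metabolite == "h2_e"], 0)
})

test_that("scaling both biomasses leaves yields unchanged", {
  pair <- coculture_pair()
  y_at <- function(scale) {
    cp <- build_reactor(pair$sfu, pair$mhu, X_A = 4 * scale, X_B = 3 * scale,
                        D = 0.05)
    rs <- solve_reactor(cp, force_zero = "for_e")
    rs$community_yields$yield
  }
  expect_equal(y_at(1), y_at(2.5), tolerance = 1e-6)
})

test_that("community H2 yield is non-increasing in the Mhu:Sfu biomass ratio", {
  pair <- coculture_pair()
  sw <- sweep_reactor(pair$sfu, pair$mhu, variable = "biomass_ratio",
                      grid = c(0.25, 0.6, 0.95), X_A = 4, D = 0.05,
                      force_zero = "for_e")
  h2 <- dplyr::filter(sw, metabolite == "h2_e")
  expect_true(all(diff(h2$yield) <= 1e-6))
})

test_that("propionate uptake per gDW increases with dilution rate", {
  pair <- coculture_pair()
  sw <- sweep_reactor(pair$sfu, pair$mhu, variable = "dilution",
                      grid = c(0.02, 0.1, 0.2), X_A = 4, X_B = 3,
                      force_zero = "for_e")
  prop <- dplyr::filter(sw, metabolite == "prop_e")
  expect_true(all(prop$status == "optimal"))
  expect_true(all(diff(-prop$rate) > 0))
  # embedded species solutions still satisfy single-species invariants
  cp <- build_reactor(pair$sfu, pair$mhu, X_A = 4, X_B = 3, D = 0.1)
  rs <- solve_reactor(cp, force_zero = "for_e")
  expect_sign_coupling(rs$solution)
  grow <- rs$solution$fluxes
  expect_equal(grow$flux[grow$reaction == "BIOMASS_SFU"], 0.1,
               tolerance = 1e-6)
  expect_equal(grow$flux[grow$reaction == "BIOMASS_MHU"], 0.1,
               tolerance = 1e-6)
})

test_that("the critical ratio of the toy pair is 2.0 and zero demand censors", {
  crit <- critical_ratio(toy_producer(), toy_consumer(demand = 1), D = 0,
                         tol = 0.01, max_ratio = 4, carrier = "h2_e",
                         feed = "s_e", force_zero = character())
  expect_false(crit$censored)
  expect_equal(crit$ratio, 2, tolerance = 0.02)
  lazy <- critical_ratio(toy_producer(), toy_consumer(demand = 0), D = 0,
                         tol = 0.05, max_ratio = 4, carrier = "h2_e",
                         feed = "s_e", force_zero = character())
  expect_true(lazy$censored)
})

test_that("the curated pair has a finite positive critical ratio at D = 0.05", {
  pair <- coculture_pair()
  crit <- critical_ratio(pair$sfu, pair$mhu, D = 0.05, tol = 0.05,
                         max_ratio = 4)
  expect_false(crit$censored)
  expect_gt(crit$ratio, 0)
  # bracketing is monotone: yield positive below, zero/infeasible above
  expect_gt(crit$yield_lo, 0)
  tr <- crit$trace[order(crit$trace$ratio), ]
  ok <- tr[tr$status == "optimal", ]
  expect_true(all(diff(ok$yield) <= 1e-6))
})
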