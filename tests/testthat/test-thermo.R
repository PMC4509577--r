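# Transformed Gibbs energy evaluation and confidence-interval machinery.

test_that("ci_halfwidth applies the normal quantiles", {
  expect_equal(ci_halfwidth(0, 0.95), 0)
  expect_equal(ci_halfwidth(10, 0.95), 19.6)
  expect_equal(ci_halfwidth(10, 0.99), 25.76)
  expect_error(ci_halfwidth(10, 0.90), "confidence level")
})

test_that("reaction_energy reproduces hand-computed values", {
  mets <- dplyr::bind_rows(metabolite("A"), metabolite("B"),
                           metabolite("w", boundary = TRUE,
                                      fixed_conc = TRUE))
  rxns <- dplyr::bind_rows(
    reaction("fwd", c(A = -1, B = 1, w = 1), drg0_est = 0, drg0_se = 2),
    reaction("rev", c(B = -1, A = 1, w = 1), drg0_est = 0, drg0_se = 2),
    reaction("ref", c(A = -1, B = 1), drg0_est = -12.5, drg0_se = 0),
    reaction("exempt_r", c(A = -1, B = 1))
  )
  mdl <- metabolic_model(mets, rxns, objective_id = "fwd")
  p298 <- thermo_params(T = 298.15)

  # reference state: all concentrations 1 M, no slack -> DrG'0 exactly
  expect_equal(reaction_energy(mdl, "ref", c(A = 0, B = 0), 0, p298), -12.5)

  # A -> B with c_A = 0.02 M, c_B = 1e-5 M at 298.15 K:
  # RT ln(5e-4) = 2.4788 * (-7.6009) = -18.84 kJ/mol
  lnc <- c(A = log(0.02), B = log(1e-5))
  expect_equal(reaction_energy(mdl, "fwd", lnc, 0, p298), -18.84,
               tolerance = 1e-3)

  # antisymmetry under reversal at equal concentrations (water excluded)
  expect_equal(reaction_energy(mdl, "fwd", lnc, 0, p298),
               -reaction_energy(mdl, "rev", lnc, 0, p298))

  # slack must stay within the CI half-width; exempt reactions refuse
  expect_error(reaction_energy(mdl, "fwd", lnc, adjust = 5), "half-width")
  expect_error(reaction_energy(mdl, "exempt_r", lnc), "exempt")
  expect_error(reaction_energy(mdl, "fwd", c(A = 0)), "B")
})

test_that("spectator coefficients and fixed-activity species change nothing", {
  mets <- dplyr::bind_rows(metabolite("A"), metabolite("B"),
                           metabolite("cof", fixed_conc = TRUE))
  r1 <- reaction("r1", c(A = -1, B = 1), drg0_est = 3)
  r2 <- reaction("r2", c(A = -1, B = 1, cof = 2), drg0_est = 3)
  mdl <- metabolic_model(mets, dplyr::bind_rows(r1, r2),
                         objective_id = "r1")
  lnc <- c(A = -4, B = -9)
  expect_equal(reaction_energy(mdl, "r1", lnc),
               reaction_energy(mdl, "r2", lnc))
})

test_that("formation-consistent cycles have energies summing to zero", {
  net <- generate_network(synthetic_spec(n_metabolites = 6, n_reactions = 7,
                                         cycle_injections = 2, seed = 11))
  rx <- net$reactions
  cyc <- rx[grepl("^RC01_", rx$id), ]
  expect_equal(sum(cyc$drg0_est), 0, tolerance = 1e-9)
  # and realized energies cancel too (concentration terms telescope)
  lnc <- stats::setNames(stats::runif(nrow(net$metabolites), -10, -4),
                         net$metabolites$id)
  g <- purrr::map_dbl(cyc$id, function(r)
    reaction_energy(net, r, lnc, 0, thermo_params()))
  expect_equal(sum(g), 0, tolerance = 1e-9)
})

test_that("with SE > 0 the CI-adjusted cycle range exceeds the consistent range", {
  # around a closed cycle the formation-consistent energies sum to exactly
  # zero; with independent per-reaction slacks the attainable sum widens to
  # +/- sum of half-widths — the documented looseness of a reaction-basis
  # uncertainty treatment
  lf <- loop_fixture(se = 3)
  hw <- ci_halfwidth(lf$reactions$drg0_se, 0.95)
  expect_equal(sum(hw), 3 * 1.96 * 3)
  expect_gt(sum(hw), 0)
})

test_that("the computed big-M dominates every attainable |DrG'|", {
  mdl <- build_sfu_core()
  p <- thermo_params()
  K <- compute_big_m(mdl, p)
  cv <- mdl$metabolites[!mdl$metabolites$fixed_conc &
                          !mdl$metabolites$boundary & !mdl$metabolites$ion, ]
  worst_ln <- stats::setNames(
    pmax(abs(log(ifelse(is.na(cv$conc_lb), p$conc_floor, cv$conc_lb))),
         abs(log(cv$conc_ub))), cv$id)
  for (k in which(!mdl$reactions$thermo_exempt)) {
    r <- mdl$reactions[k, ]
    s <- r$stoich[[1]]
    in_cv <- intersect(names(s), cv$id)
    g_max <- abs(r$drg0_est) + ci_halfwidth(r$drg0_se, r$ci_level) +
      p$R * p$T * sum(abs(s[in_cv]) * worst_ln[in_cv]) +
      abs(sum(s[startsWith(names(s), "hp_")])) * p$ion_cost
    expect_lt(g_max, K)
  }
})
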