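# Small models and assertions shared across the suite. Everything is built
# in code; nothing is read from disk.

flux_of <- function(sol, id) sol$fluxes$flux[match(id, sol$fluxes$reaction)]

# linear uptake -> A -> B -> secretion chain with configurable middle energy
chain_model <- function(mid_drg0 = -10, mid_se = 0, mid_ci = 0.95,
                        cap = 5, fixed_conc_mid = FALSE) {
  mets <- dplyr::bind_rows(
    metabolite("S_e", compartment = "extracellular"),
    metabolite("A", fixed_conc = fixed_conc_mid),
    metabolite("B", fixed_conc = fixed_conc_mid),
    metabolite("P_e", compartment = "extracellular")
  )
  rxns <- dplyr::bind_rows(
    reaction("T_up", c(S_e = -1, A = 1), lb = 0),
    reaction("R1", c(A = -1, B = 1), lb = 0, drg0_est = mid_drg0,
             drg0_se = mid_se, ci_level = mid_ci),
    reaction("T_out", c(B = -1, P_e = 1), lb = 0),
    reaction("EX_S", c(S_e = -1), lb = -cap, ub = 0, is_exchange = TRUE),
    reaction("EX_P", c(P_e = -1), lb = 0, ub = 1000, is_exchange = TRUE)
  )
  metabolic_model(mets, rxns, objective_id = "EX_P", id = "chain")
}

# steady-state residual over balanced metabolites
max_balance_residual <- function(model, sol) {
  S <- stoich_matrix(model)
  keep <- !model$metabolites$boundary
  v <- sol$fluxes$flux[match(colnames(S), sol$fluxes$reaction)]
  max(abs(as.numeric(S[keep, , drop = FALSE] %*% v)))
}

# the sign rule: every non-exempt reaction carrying flux has an energy
# opposing it
expect_sign_coupling <- function(sol, tol = 1e-6) {
  d <- dplyr::left_join(sol$fluxes, sol$energies, by = "reaction")
  d <- dplyr::filter(d, !exempt, abs(flux) > tol)
  if (nrow(d)) {
    expect_true(all(sign(d$drg_prime) == -sign(d$flux)),
                label = paste("sign coupling violated for:",
                              paste(d$reaction[sign(d$drg_prime) !=
                                                 -sign(d$flux)],
                                    collapse = ", ")))
  }
  invisible(d)
}

# toy producer/consumer pair for the chemostat: the producer emits 2 H2 per
# gDW/day, the consumer requires `demand` H2 per gDW/day
toy_producer <- function() {
  mets <- dplyr::bind_rows(
    metabolite("s_e", compartment = "extracellular"),
    metabolite("h2_e", compartment = "extracellular", conc_lb = NA),
    metabolite("atp_P", fixed_conc = TRUE),
    metabolite("bio_P", boundary = TRUE, fixed_conc = TRUE)
  )
  rxns <- dplyr::bind_rows(
    reaction("PMK", c(s_e = -1, h2_e = 2, atp_P = 1), lb = 0),
    reaction("ATPM_P", c(atp_P = -1), lb = 1, ub = 1),
    reaction("GROW_P", c(s_e = -0.1, bio_P = 1), lb = 0)
  )
  m <- metabolic_model(mets, rxns, objective_id = "ATPM_P",
                       atpm_id = "ATPM_P", id = "toy_producer")
  m$growth_id <- "GROW_P"
  m
}

toy_consumer <- function(demand = 1) {
  mets <- dplyr::bind_rows(
    metabolite("s_e", compartment = "extracellular"),
    metabolite("h2_e", compartment = "extracellular", conc_lb = NA),
    metabolite("atp_C", compartment = "cytosol_B", fixed_conc = TRUE),
    metabolite("bio_C", compartment = "cytosol_B", boundary = TRUE,
               fixed_conc = TRUE)
  )
  rxns <- dplyr::bind_rows(
    reaction("CMK", c(h2_e = -1, atp_C = 1), lb = 0),
    reaction("ATPM_C", c(atp_C = -1), lb = demand, ub = max(demand, 1)),
    reaction("GROW_C", c(atp_C = -0.01, bio_C = 1), lb = 0)
  )
  m <- metabolic_model(mets, rxns, objective_id = "ATPM_C",
                       atpm_id = "ATPM_C", id = "toy_consumer")
  m$growth_id <- "GROW_C"
  m
}
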