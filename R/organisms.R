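# Curated core models of the syntrophic pair:
#   species A = Syntrophobacter fumaroxidans (propionate/fumarate metabolism,
#               methylmalonyl-CoA pathway, menaquinone-coupled fumarate
#               reductase, confurcating hydrogenase/formate dehydrogenase)
#   species B = Methanospirillum hungatei (hydrogenotrophic methanogenesis,
#               CO2 -> CH4 via the methanofuran/H4MPT/coenzyme-M pathway)
#
# Reaction DrG'0 values are derived from a single internal formation-energy
# assignment (a synthetic, self-consistent table on a pH-7 transformed
# convention with physiological cofactor ratios folded in), so that any
# stoichiometric cycle of non-exempt reactions has energies summing to
# exactly zero. Ferredoxin-containing reactions carry no estimate and are
# thermodynamically exempt. Standard errors are curated per reaction class;
# membrane steps that must run against the ambient redox ladder at low
# product concentrations (cytosolic hydrogenase / formate dehydrogenase,
# F420-reducing hydrogenase) carry the largest uncertainties, consistent
# with group-contribution error magnitudes.

core_formation <- function() {
  c(
    h2o = -157.6, h = 0, na = 0, hp = 0, nap = 0, nac = 0,
    co2 = -386.0, h2 = 79.9, "for" = -307.4, ch4 = 117.8,
    prop = -356.2, ac = -449.1, fum = -521.9, succ = -528.0,
    mal = -682.9, oaa = -715.7, pyr = -350.0,
    nad = 0, nadh = 61.8, f420 = 0, f420h2 = 69.5, mq = 0, mqh2 = 14.3,
    coa = 0, atp = 212.6, adp = 0, pi = 0,
    succoa = -317.4, mmcoa = -310.4, propcoa = 59.3, accoa = -25.6,
    mfr = 0, fmfr = -170, h4mpt = 0, fh4mpt = -160, menyl = -7.4,
    mlen = 67.1, mh4mpt = 131.6, com = 0, mcom = 101.6, cob = 0,
    hsfd = -61.2, fd = 0, fdh2 = 79.9
  )
}

# species-agnostic base id of a compartmentalised metabolite id
base_id <- function(id) sub("_(cA|cB|e|A|B)$", "", id)

drg0_of <- function(stoich) {
  fe <- core_formation()
  b <- base_id(names(stoich))
  miss <- setdiff(b, names(fe))
  if (length(miss)) {
    stop("no formation energy for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sum(stoich * fe[b])
}

core_formulas <- function() {
  c(
    h2o = "H2O", h = "H", na = "Na",
    co2 = "CO2", h2 = "H2", "for" = "CH2O2", ch4 = "CH4",
    prop = "C3H6O2", ac = "C2H4O2", fum = "C4H4O4", succ = "C4H6O4",
    mal = "C4H6O5", oaa = "C4H4O5", pyr = "C3H4O3",
    nad = "Nad", nadh = "NadH", f420 = "Fo", f420h2 = "FoH2",
    mq = "Mq", mqh2 = "MqH2",
    coa = "CoaH", atp = "AdnH3P3O10", adp = "AdnH2P2O7", pi = "H3PO4",
    succoa = "CoaC4H5O3", mmcoa = "CoaC4H5O3", propcoa = "CoaC3H5O",
    accoa = "CoaC2H3O",
    mfr = "MfrH", fmfr = "MfrCHO", h4mpt = "HmpH2", fh4mpt = "HmpHCHO",
    menyl = "HmpCH", mlen = "HmpCH2", mh4mpt = "HmpHCH3",
    com = "ComH", mcom = "ComCH3", cob = "CobH", hsfd = "ComCob",
    fd = "Fd", fdh2 = "FdH2"
  )
}

# shared extracellular medium: identical in both cores so the reactor can
# merge them
extracellular_mets <- function() {
  f <- core_formulas()
  dplyr::bind_rows(
    metabolite("h2o", "water", "extracellular", f[["h2o"]],
               fixed_conc = TRUE, boundary = TRUE),
    metabolite("h", "proton", "extracellular", f[["h"]],
               fixed_conc = TRUE, boundary = TRUE),
    metabolite("prop_e", "propionate", "extracellular", f[["prop"]]),
    metabolite("fum_e", "fumarate", "extracellular", f[["fum"]]),
    metabolite("succ_e", "succinate", "extracellular", f[["succ"]]),
    metabolite("ac_e", "acetate", "extracellular", f[["ac"]]),
    metabolite("co2_e", "carbon dioxide", "extracellular", f[["co2"]]),
    metabolite("h2_e", "dihydrogen", "extracellular", f[["h2"]],
               conc_lb = NA),
    metabolite("for_e", "formate", "extracellular", f[["for"]],
               conc_lb = NA),
    metabolite("ch4_e", "methane", "extracellular", f[["ch4"]])
  )
}

carrier <- function(id, name, compartment, formula) {
  metabolite(id, name, compartment, formula, fixed_conc = TRUE)
}

# reaction with curated thermodynamics (DrG'0 from the formation table)
crxn <- function(id, stoich, se, lb = -1000, ub = 1000, ci = 0.95,
                 name = id, weight = 1) {
  reaction(id, stoich, lb = lb, ub = ub, name = name,
           drg0_est = drg0_of(stoich), drg0_se = se, ci_level = ci,
           parsimony_weight = weight)
}

# ferredoxin (or otherwise estimate-free) reaction: thermo exempt
xrxn <- function(id, stoich, lb = -1000, ub = 1000, name = id, weight = 1) {
  reaction(id, stoich, lb = lb, ub = ub, name = name,
           parsimony_weight = weight)
}

transport <- function(id, met_base, cyt_suffix, name = id) {
  # written extracellular -> cytosol: positive flux is uptake
  s <- stats::setNames(c(-1, 1), c(paste0(met_base, "_e"),
                                   paste0(met_base, cyt_suffix)))
  reaction(id, s, lb = -1000, ub = 1000, name = name, parsimony_weight = 0)
}

exchange <- function(id, met_e, lb = -1000, ub = 1000) {
  reaction(id, stats::setNames(-1, met_e), lb = lb, ub = ub,
           is_exchange = TRUE, parsimony_weight = 0)
}

#' Curated core model of Syntrophobacter fumaroxidans
#'
#' Transcribes the experimentally characterised carbon and electron
#' transport pathways: propionate activation by acetyl-CoA:propionate
#' CoA-transferase, the methylmalonyl-CoA pathway to succinate (one
#' substrate-level ATP at succinyl-CoA synthetase), the menaquinone-coupled,
#' proton-translocating fumarate reductase / succinate dehydrogenase, the
#' fumarate oxidation branch to acetyl-CoA (malate dehydrogenase NADH,
#' pyruvate:ferredoxin oxidoreductase), a lumped full oxidation of
#' acetyl-CoA to CO2 (releasing 2 NADH and 2 reduced-ferredoxin pairs; with
#' malate dehydrogenase and PFOR the complete oxidation of fumarate yields
#' the six reducing-equivalent pairs elemental balance demands), the
#' confurcating hydrogenase and formate dehydrogenase, the cytosolic
#' (menaquinol-coupled) hydrogenase and formate dehydrogenase, the
#' ferredoxin-oxidizing hydrogenase and formate dehydrogenase, formate
#' hydrogen lyase, RNF (fixed in its ferredoxin-reducing,
#' proton-motive-force-consuming direction), and the proton-coupled ATP
#' synthase. Ferredoxin reactions are thermodynamically exempt.
#'
#' @param gam Growth-associated maintenance, mmol ATP/gDW (default 22.8).
#' @param ngam Non-growth maintenance, mmol ATP/gDW/day (default 3.36).
#' @param sur_propionate,sur_fumarate Substrate uptake caps, mmol/gDW/day
#'   (defaults 37.7 and 27.6).
#' @param frd_h_per_turnover Protons translocated by fumarate reductase per
#'   turnover (default 2).
#' @param atpase_ions_per_atp Protons consumed by ATP synthase per ATP
#'   (default 4). Together with `frd_h_per_turnover` this calibrates the
#'   ATP yield of each growth mode.
#' @return A `metabolic_model` with objective `ATPSINK` (ATP drain),
#'   maintenance reaction `ATPM`, and growth reaction `BIOMASS_SFU`
#'   (recorded in `$growth_id`).
#' @export
build_sfu_core <- function(gam = 22.8, ngam = 3.36,
                           sur_propionate = 37.7, sur_fumarate = 27.6,
                           frd_h_per_turnover = 2, atpase_ions_per_atp = 4) {
  f <- core_formulas()
  mets <- dplyr::bind_rows(
    extracellular_mets(),
    metabolite("prop_cA", "propionate", "cytosol_A", f[["prop"]]),
    metabolite("fum_cA", "fumarate", "cytosol_A", f[["fum"]]),
    metabolite("succ_cA", "succinate", "cytosol_A", f[["succ"]]),
    metabolite("mal_cA", "malate", "cytosol_A", f[["mal"]]),
    metabolite("oaa_cA", "oxaloacetate", "cytosol_A", f[["oaa"]]),
    metabolite("pyr_cA", "pyruvate", "cytosol_A", f[["pyr"]]),
    metabolite("ac_cA", "acetate", "cytosol_A", f[["ac"]]),
    metabolite("co2_cA", "carbon dioxide", "cytosol_A", f[["co2"]]),
    metabolite("for_cA", "formate", "cytosol_A", f[["for"]],
               conc_lb = NA),
    metabolite("h2_cA", "dihydrogen", "cytosol_A", f[["h2"]],
               conc_lb = NA),
    carrier("nad_A", "NAD+", "cytosol_A", f[["nad"]]),
    carrier("nadh_A", "NADH", "cytosol_A", f[["nadh"]]),
    carrier("fdox_A", "oxidized ferredoxin", "cytosol_A", f[["fd"]]),
    carrier("fdred_A", "reduced ferredoxin", "cytosol_A", f[["fdh2"]]),
    carrier("mq_A", "menaquinone", "cytosol_A", f[["mq"]]),
    carrier("mqh2_A", "menaquinol", "cytosol_A", f[["mqh2"]]),
    carrier("coa_A", "coenzyme A", "cytosol_A", f[["coa"]]),
    carrier("accoa_A", "acetyl-CoA", "cytosol_A", f[["accoa"]]),
    carrier("propcoa_A", "propionyl-CoA", "cytosol_A", f[["propcoa"]]),
    carrier("mmcoa_A", "methylmalonyl-CoA", "cytosol_A", f[["mmcoa"]]),
    carrier("succoa_A", "succinyl-CoA", "cytosol_A", f[["succoa"]]),
    carrier("atp_A", "ATP", "cytosol_A", f[["atp"]]),
    carrier("adp_A", "ADP", "cytosol_A", f[["adp"]]),
    carrier("pi_A", "phosphate", "cytosol_A", f[["pi"]]),
    metabolite("hp_A", "periplasmic proton", "cytosol_A", "H",
               fixed_conc = TRUE, ion = TRUE),
    metabolite("biomass_A", "biomass", "cytosol_A", boundary = TRUE,
               fixed_conc = TRUE)
  )

  nh <- frd_h_per_turnover
  na_ <- atpase_ions_per_atp
  rxns <- dplyr::bind_rows(
    # propionate oxidation (methylmalonyl-CoA pathway)
    crxn("PCT", c(accoa_A = -1, prop_cA = -1, ac_cA = 1, propcoa_A = 1),
         se = 4, lb = 0, name = "acetyl-CoA:propionate CoA-transferase"),
    crxn("TC", c(propcoa_A = -1, oaa_cA = -1, mmcoa_A = 1, pyr_cA = 1),
         se = 4, name = "methylmalonyl-CoA:pyruvate transcarboxylase"),
    crxn("MUT", c(mmcoa_A = -1, succoa_A = 1), se = 3,
         name = "methylmalonyl-CoA mutase/epimerase"),
    crxn("SCS", c(succoa_A = -1, adp_A = -1, pi_A = -1,
                  succ_cA = 1, coa_A = 1, atp_A = 1), se = 4,
         name = "succinyl-CoA synthetase"),
    # fumarate reduction / succinate oxidation (menaquinone pool, PMF)
    crxn("FRD", stats::setNames(
           c(-1, -1, -nh, 1, 1, nh),
           c("fum_cA", "mqh2_A", "h", "succ_cA", "mq_A", "hp_A")),
         se = 6, name = "fumarate reductase / succinate dehydrogenase"),
    # fumarate oxidation branch
    crxn("FUM", c(fum_cA = -1, h2o = -1, mal_cA = 1), se = 3,
         name = "fumarase"),
    crxn("MDH", c(mal_cA = -1, nad_A = -1, oaa_cA = 1, nadh_A = 1, h = 1),
         se = 6, name = "malate dehydrogenase"),
    crxn("OAD", c(oaa_cA = -1, pyr_cA = 1, co2_cA = 1), se = 4, lb = 0,
         name = "oxaloacetate decarboxylase (irreversible)"),
    xrxn("PFOR", c(pyr_cA = -1, coa_A = -1, fdox_A = -1,
                   accoa_A = 1, co2_cA = 1, fdred_A = 1),
         name = "pyruvate:ferredoxin oxidoreductase"),
    xrxn("ACOAOX", c(accoa_A = -1, h2o = -3, nad_A = -2, fdox_A = -2,
                     co2_cA = 2, nadh_A = 2, fdred_A = 2, coa_A = 1, h = 2),
         lb = 0, name = "acetyl-CoA full oxidation (lumped)"),
    # electron transfer to H2 / formate
    xrxn("cH2ase", c(nadh_A = -1, h = -1, fdred_A = -1,
                     nad_A = 1, fdox_A = 1, h2_cA = 2),
         name = "confurcating hydrogenase"),
    crxn("cytH2ase", c(h2_cA = -1, mq_A = -1, mqh2_A = 1), se = 10,
         name = "cytosolic (menaquinone-coupled) hydrogenase"),
    xrxn("frH2ase", c(fdred_A = -1, fdox_A = 1, h2_cA = 1),
         name = "ferredoxin-oxidizing hydrogenase"),
    crxn("FHL", c(for_cA = -1, co2_cA = 1, h2_cA = 1), se = 3,
         name = "formate hydrogen lyase"),
    xrxn("cFDH", c(nadh_A = -1, fdred_A = -1, co2_cA = -2, h = -1,
                   nad_A = 1, fdox_A = 1, for_cA = 2),
         name = "confurcating formate dehydrogenase"),
    crxn("cytFDH", c(co2_cA = -1, mqh2_A = -1, for_cA = 1, mq_A = 1),
         se = 10, name = "cytosolic (menaquinone-coupled) formate dehydrogenase"),
    xrxn("frFDH", c(fdred_A = -1, co2_cA = -1, fdox_A = 1, for_cA = 1),
         name = "ferredoxin-oxidizing formate dehydrogenase"),
    xrxn("RNF", c(nadh_A = -1, fdox_A = -1, hp_A = -1,
                  nad_A = 1, fdred_A = 1),
         lb = 0, name = "RNF complex (ferredoxin-reducing direction)"),
    # energy conservation and maintenance
    crxn("ATPS", stats::setNames(
           c(-1, -1, -na_, 1, 1, na_),
           c("adp_A", "pi_A", "hp_A", "atp_A", "h2o", "h")),
         se = 9, name = "F1F0 ATP synthase"),
    crxn("ATPM", c(atp_A = -1, h2o = -1, adp_A = 1, pi_A = 1),
         se = 9, lb = ngam, ub = max(ngam, 1000), weight = 0,
         name = "non-growth maintenance"),
    crxn("ATPSINK", c(atp_A = -1, h2o = -1, adp_A = 1, pi_A = 1),
         se = 9, lb = 0, ub = 1000, weight = 0, name = "ATP drain"),
    reaction("BIOMASS_SFU", stats::setNames(
               c(-gam, -gam, -1, -1, gam, gam, 1),
               c("atp_A", "h2o", "ac_cA", "co2_cA", "adp_A", "pi_A",
                 "biomass_A")),
             lb = 0, ub = 1000, parsimony_weight = 0,
             name = "biomass (ATP + acetate/CO2 carbon drain)"),
    # membrane crossings (passive, thermodynamically exempt) and exchanges
    transport("Tprop", "prop", "_cA"), transport("Tfum", "fum", "_cA"),
    transport("Tsucc", "succ", "_cA"), transport("Tac", "ac", "_cA"),
    transport("Tco2", "co2", "_cA"), transport("Th2", "h2", "_cA"),
    transport("Tfor", "for", "_cA"),
    exchange("EX_prop", "prop_e", lb = -sur_propionate),
    exchange("EX_fum", "fum_e", lb = -sur_fumarate),
    exchange("EX_succ", "succ_e", lb = 0),
    exchange("EX_ac", "ac_e", lb = 0),
    exchange("EX_co2", "co2_e"),
    exchange("EX_h2", "h2_e"),
    exchange("EX_for", "for_e")
  )
  mdl <- metabolic_model(
    mets, rxns, objective_id = "ATPSINK", atpm_id = "ATPM",
    gam = gam, ngam = ngam,
    sur_caps = c(EX_prop = sur_propionate, EX_fum = sur_fumarate),
    id = "sfu_core"
  )
  mdl$growth_id <- "BIOMASS_SFU"
  mdl
}

#' Ion-stoichiometry variant of the M. hungatei core
#'
#' @param mtr_na_stoich Na+ ions exported per methyl-H4MPT:coenzyme-M
#'   methyltransferase turnover (default 2; the group-contribution upper
#'   limit is 4).
#' @param antiporter_ratio Na+ translocated per H+ by the Na+/H+ antiporter
#'   (default 1).
#' @param atpase_ions_per_atp Ions translocated per ATP by the A1A0 ATP
#'   synthase (default 4).
#' @param atpase_coupling `"proton"` (default) or `"sodium"`; sodium
#'   coupling lets methyltransferase-exported Na+ drive ATP synthesis
#'   directly, silencing the antiporter.
#' @return An object of class `core_variant`.
#' @export
core_variant <- function(mtr_na_stoich = 2, antiporter_ratio = 1,
                         atpase_ions_per_atp = 4,
                         atpase_coupling = c("proton", "sodium")) {
  atpase_coupling <- match.arg(atpase_coupling)
  stopifnot(mtr_na_stoich > 0, antiporter_ratio > 0,
            atpase_ions_per_atp > 0)
  structure(list(mtr_na_stoich = mtr_na_stoich,
                 antiporter_ratio = antiporter_ratio,
                 atpase_ions_per_atp = atpase_ions_per_atp,
                 atpase_coupling = atpase_coupling),
            class = "core_variant")
}

#' Curated core model of Methanospirillum hungatei
#'
#' Transcribes the hydrogenotrophic methanogenesis pathway (overall
#' CO2 + 4 H2 -> CH4 + 2 H2O): formylmethanofuran dehydrogenase
#' (ferredoxin-dependent, exempt), formyltransferase FMFTSPFT (the one
#' reaction whose energy slack is bounded by a 99% rather than 95%
#' confidence interval), cyclohydrolase, F420-dependent dehydrogenase and
#' reductase, the sodium-pumping methyltransferase MTSPCMMT_CM5HBCMT,
#' methyl-coenzyme-M reductase, the electron-bifurcating heterodisulfide
#' reductase (the sole ferredoxin-reducing step), the F420-reducing
#' hydrogenase, the Na+/H+ antiporter NAT3_1, the A1A0 ATP synthase, and an
#' extracellular-facing formate dehydrogenase interconverting formate with
#' CO2 + H2.
#'
#' @param variant A [core_variant()].
#' @param gam Growth-associated maintenance, mmol ATP/gDW (default 47).
#' @param ngam Non-growth maintenance, mmol ATP/gDW/day (default 0.6).
#' @param sur_co2,sur_formate Substrate uptake caps, mmol/gDW/day
#'   (defaults 75.7 and 955).
#' @return A `metabolic_model` with objective `ATPSINK_MHU`, maintenance
#'   `ATPM_MHU`, growth `BIOMASS_MHU`.
#' @export
build_mhu_core <- function(variant = core_variant(), gam = 47, ngam = 0.6,
                           sur_co2 = 75.7, sur_formate = 955) {
  stopifnot(inherits(variant, "core_variant"))
  f <- core_formulas()
  mets <- dplyr::bind_rows(
    extracellular_mets(),
    metabolite("co2_cB", "carbon dioxide", "cytosol_B", f[["co2"]]),
    metabolite("h2_cB", "dihydrogen", "cytosol_B", f[["h2"]],
               conc_lb = NA),
    metabolite("ch4_cB", "methane", "cytosol_B", f[["ch4"]]),
    metabolite("ac_cB", "acetate", "cytosol_B", f[["ac"]]),
    carrier("mfr_B", "methanofuran", "cytosol_B", f[["mfr"]]),
    carrier("fmfr_B", "formyl-methanofuran", "cytosol_B", f[["fmfr"]]),
    carrier("h4mpt_B", "tetrahydromethanopterin", "cytosol_B", f[["h4mpt"]]),
    carrier("fh4mpt_B", "formyl-H4MPT", "cytosol_B", f[["fh4mpt"]]),
    carrier("menyl_B", "methenyl-H4MPT", "cytosol_B", f[["menyl"]]),
    carrier("mlen_B", "methylene-H4MPT", "cytosol_B", f[["mlen"]]),
    carrier("mh4mpt_B", "methyl-H4MPT", "cytosol_B", f[["mh4mpt"]]),
    carrier("com_B", "coenzyme M", "cytosol_B", f[["com"]]),
    carrier("mcom_B", "methyl-coenzyme M", "cytosol_B", f[["mcom"]]),
    carrier("cob_B", "coenzyme B", "cytosol_B", f[["cob"]]),
    carrier("hsfd_B", "CoM-S-S-CoB heterodisulfide", "cytosol_B",
            f[["hsfd"]]),
    carrier("fdox_B", "oxidized ferredoxin", "cytosol_B", f[["fd"]]),
    carrier("fdred_B", "reduced ferredoxin", "cytosol_B", f[["fdh2"]]),
    carrier("f420_B", "coenzyme F420", "cytosol_B", f[["f420"]]),
    carrier("f420h2_B", "reduced F420", "cytosol_B", f[["f420h2"]]),
    carrier("atp_B", "ATP", "cytosol_B", f[["atp"]]),
    carrier("adp_B", "ADP", "cytosol_B", f[["adp"]]),
    carrier("pi_B", "phosphate", "cytosol_B", f[["pi"]]),
    carrier("nac_B", "cytosolic Na+", "cytosol_B", f[["na"]]),
    metabolite("hp_B", "periplasmic proton", "cytosol_B", "H",
               fixed_conc = TRUE, ion = TRUE),
    metabolite("nap_B", "periplasmic Na+", "cytosol_B", "Na",
               fixed_conc = TRUE, ion = TRUE),
    metabolite("biomass_B", "biomass", "cytosol_B", boundary = TRUE,
               fixed_conc = TRUE)
  )

  n_na <- variant$mtr_na_stoich
  r_ant <- variant$antiporter_ratio
  n_atp <- variant$atpase_ions_per_atp
  atps <- if (variant$atpase_coupling == "proton") {
    crxn("ATPS_MHU", stats::setNames(
           c(-1, -1, -n_atp, 1, 1, n_atp),
           c("adp_B", "pi_B", "hp_B", "atp_B", "h2o", "h")),
         se = 9, name = "A1A0 ATP synthase (H+-coupled)")
  } else {
    crxn("ATPS_MHU", stats::setNames(
           c(-1, -1, -n_atp, 1, 1, n_atp),
           c("adp_B", "pi_B", "nap_B", "atp_B", "h2o", "nac_B")),
         se = 9, name = "A1A0 ATP synthase (Na+-coupled)")
  }

  rxns <- dplyr::bind_rows(
    xrxn("FMD", c(co2_cB = -1, mfr_B = -1, fdred_B = -1,
                  fmfr_B = 1, h2o = 1, fdox_B = 1),
         name = "formylmethanofuran dehydrogenase"),
    crxn("FMFTSPFT", c(fmfr_B = -1, h4mpt_B = -1, fh4mpt_B = 1, mfr_B = 1),
         se = 5, ci = 0.99,
         name = "formylmethanofuran:H4MPT formyltransferase"),
    crxn("MCH", c(fh4mpt_B = -1, h = -1, menyl_B = 1, h2o = 1), se = 3,
         name = "methenyl-H4MPT cyclohydrolase"),
    crxn("MTD", c(menyl_B = -1, f420h2_B = -1, mlen_B = 1, f420_B = 1,
                  h = 1), se = 4,
         name = "F420-dependent methylene-H4MPT dehydrogenase"),
    crxn("MER", c(mlen_B = -1, f420h2_B = -1, mh4mpt_B = 1, f420_B = 1),
         se = 3, name = "F420-dependent methylene-H4MPT reductase"),
    crxn("MTSPCMMT_CM5HBCMT", stats::setNames(
           c(-1, -1, -n_na, 1, 1, n_na),
           c("mh4mpt_B", "com_B", "nac_B", "h4mpt_B", "mcom_B", "nap_B")),
         se = 4, name = "methyl-H4MPT:coenzyme-M methyltransferase (Na+ pump)"),
    crxn("MCR", c(mcom_B = -1, cob_B = -1, ch4_cB = 1, hsfd_B = 1), se = 5,
         name = "methyl-coenzyme M reductase"),
    xrxn("HDR", c(h2_cB = -2, hsfd_B = -1, fdox_B = -1,
                  com_B = 1, cob_B = 1, fdred_B = 1),
         name = "electron-bifurcating heterodisulfide reductase"),
    crxn("FRH", c(h2_cB = -1, f420_B = -1, f420h2_B = 1), se = 10,
         name = "F420-reducing hydrogenase"),
    crxn("NAT3_1", stats::setNames(
           c(-r_ant, -1, r_ant, 1),
           c("nap_B", "h", "nac_B", "hp_B")),
         se = 2, name = "Na+/H+ antiporter"),
    atps,
    crxn("EFDH", c(for_e = -1, co2_e = 1, h2_e = 1), se = 3,
         lb = -sur_formate, ub = sur_formate, weight = 0,
         name = "formate dehydrogenase (extracellular-facing)"),
    crxn("ATPM_MHU", c(atp_B = -1, h2o = -1, adp_B = 1, pi_B = 1),
         se = 9, lb = ngam, ub = max(ngam, 1000), weight = 0,
         name = "non-growth maintenance"),
    crxn("ATPSINK_MHU", c(atp_B = -1, h2o = -1, adp_B = 1, pi_B = 1),
         se = 9, lb = 0, ub = 1000, weight = 0, name = "ATP drain"),
    reaction("BIOMASS_MHU", stats::setNames(
               c(-gam, -gam, -1, -2, gam, gam, 2, 1),
               c("atp_B", "h2o", "co2_cB", "f420h2_B", "adp_B", "pi_B",
                 "f420_B", "biomass_B")),
             lb = 0, ub = 1000, parsimony_weight = 0,
             name = "biomass (ATP + CO2 carbon drain)"),
    transport("Tco2_M", "co2", "_cB"), transport("Th2_M", "h2", "_cB"),
    transport("Tch4_M", "ch4", "_cB"), transport("Tac_M", "ac", "_cB"),
    exchange("EX_co2", "co2_e", lb = -sur_co2),
    exchange("EX_h2", "h2_e"),
    exchange("EX_for", "for_e", lb = -sur_formate),
    exchange("EX_ch4", "ch4_e", lb = 0),
    exchange("EX_ac", "ac_e", lb = 0),
    # medium species untouched by the Mhu core still need drains so the
    # monoculture model is solvable with the full shared medium declared
    exchange("EX_prop", "prop_e"), exchange("EX_fum", "fum_e"),
    exchange("EX_succ", "succ_e", lb = 0)
  )
  mdl <- metabolic_model(
    mets, rxns, objective_id = "ATPSINK_MHU", atpm_id = "ATPM_MHU",
    gam = gam, ngam = ngam,
    sur_caps = c(EX_co2 = sur_co2, EX_for = sur_formate),
    id = "mhu_core"
  )
  mdl$growth_id <- "BIOMASS_MHU"
  mdl$variant <- variant
  mdl
}

#' Named condition profiles for the curated cores
#'
#' * `fumarate_mono`: monoculture growth on fumarate alone — propionate,
#'   H2 and formate exchange blocked (monoculture simulations prevent H2
#'   production), CO2/succinate/acetate secretion-only.
#' * `fumarate_h2`: the H2-production scenario on fumarate — as
#'   `fumarate_mono` but with the H2 exchange open.
#' * `fumprop_mono`: monoculture on fumarate plus propionate — H2/formate
#'   blocked, fumarate:propionate uptake ratio fixed at 3, fumarate
#'   reductase and the cytosolic hydrogenase fixed in their
#'   fumarate-reducing / menaquinone-reducing directions.
#' * `coculture`: syntrophic growth on propionate — fumarate exchange
#'   blocked, H2/formate/CO2 exchange open.
#' * `mhu_hydrogenotrophic`: M. hungatei growing on CO2 + H2 only —
#'   formate exchange blocked, methane secretion-only.
#' * `reduced_network`: the curated core *is* the reduced reaction set, so
#'   this profile adds no constraints (provided for interface parity).
#'
#' @return A named list of [condition_profile()] objects.
#' @export
condition_profiles <- function() {
  list(
    fumarate_mono = condition_profile(
      "fumarate_mono",
      direction_fixes = c(EX_co2 = "forward", EX_succ = "forward",
                          EX_ac = "forward"),
      blocked_exchanges = c("EX_prop", "EX_h2", "EX_for")
    ),
    fumarate_h2 = condition_profile(
      "fumarate_h2",
      direction_fixes = c(EX_co2 = "forward", EX_succ = "forward",
                          EX_ac = "forward"),
      blocked_exchanges = c("EX_prop", "EX_for")
    ),
    fumprop_mono = condition_profile(
      "fumprop_mono",
      direction_fixes = c(EX_co2 = "forward", EX_succ = "forward",
                          EX_ac = "forward", FRD = "forward",
                          cytH2ase = "forward"),
      uptake_ratios = tibble::tibble(ex_a = "EX_fum", ex_b = "EX_prop",
                                     ratio = 3),
      blocked_exchanges = c("EX_h2", "EX_for")
    ),
    coculture = condition_profile(
      "coculture",
      direction_fixes = c(EX_succ = "forward", EX_ac = "forward"),
      blocked_exchanges = "EX_fum"
    ),
    mhu_hydrogenotrophic = condition_profile(
      "mhu_hydrogenotrophic",
      direction_fixes = c(EX_ch4 = "forward"),
      blocked_exchanges = "EX_for"
    ),
    reduced_network = condition_profile("reduced_network")
  )
}
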