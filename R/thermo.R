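#' Thermodynamic parameters
#'
#' Bundles the constants entering the transformed-Gibbs-energy constraints.
#'
#' @param T Temperature, K. Default 310.15 K.
#' @param R Gas constant, kJ/mol/K.
#' @param eps Strict-inequality margin, kJ/mol: the MILP realizes
#'   "DrG' < 0 for a used direction" as DrG' <= -eps.
#' @param K_bigM Big-M constant, kJ/mol, deactivating the energy constraint
#'   of unused directions. `NULL` (default) computes it per model from
#'   concentration bounds and confidence-interval widths via
#'   [compute_big_m()]; a fixed value can be supplied.
#' @param z95,z99 Normal quantiles bounding the energy slack at the 95% and
#'   99% confidence levels (1.96, 2.576).
#' @param default_conc_lb,default_conc_ub Global concentration bounds, molar
#'   (0.01 mM and 20 mM).
#' @param conc_floor Numerical concentration floor, molar, substituted for
#'   metabolites declared without a lower bound (dissolved H2, formate).
#' @param ion_cost Electrochemical cost of moving one ion across the
#'   cytoplasmic membrane against the proton/sodium motive force, kJ/mol.
#'   Default 17.4 kJ/mol (= F x 180 mV). This is a declared surrogate for a
#'   full delta-psi/delta-pH treatment: reactions exporting n ions have
#'   `n * ion_cost` added to their transformed energy, importing reactions
#'   the negative.
#' @param flux_cap Default magnitude used to cap unbounded directed flux
#'   halves in the MILP, mmol/gDW/day.
#' @return An object of class `thermo_params`.
#' @export
thermo_params <- function(T = 310.15, R = 8.314e-3, eps = 0.5, K_bigM = NULL,
                          z95 = 1.96, z99 = 2.576,
                          default_conc_lb = 1e-5, default_conc_ub = 0.02,
                          conc_floor = 1e-10, ion_cost = 17.4,
                          flux_cap = 1000) {
  stopifnot(T > 0, R > 0, eps > 0, conc_floor > 0,
            default_conc_lb > 0, default_conc_lb <= default_conc_ub)
  structure(
    list(T = T, R = R, eps = eps, K_bigM = K_bigM, z95 = z95, z99 = z99,
         default_conc_lb = default_conc_lb, default_conc_ub = default_conc_ub,
         conc_floor = conc_floor, ion_cost = ion_cost, flux_cap = flux_cap),
    class = "thermo_params"
  )
}

#' Confidence-interval half-width of a Gibbs energy estimate
#'
#' @param se Standard error of the reaction energy estimate, kJ/mol.
#' @param level Confidence level, 0.95 or 0.99.
#' @param params A [thermo_params()] supplying the quantiles.
#' @return `z(level) * se`, kJ/mol.
#' @export
ci_halfwidth <- function(se, level = 0.95, params = thermo_params()) {
  stopifnot(all(se >= 0, na.rm = TRUE))
  z <- ifelse(level == 0.95, params$z95,
              ifelse(level == 0.99, params$z99, NA_real_))
  if (anyNA(z)) stop("unsupported confidence level; use 0.95 or 0.99",
                     call. = FALSE)
  z * se
}

# ln-concentration bounds for every concentration-variable metabolite;
# fixed-activity species (water, protons, cofactor pairs, carrier-bound
# intermediates, translocated ions) get no variable.
conc_var_table <- function(model, params) {
  mets <- model$metabolites
  keep <- !mets$fixed_conc & !mets$boundary & !mets$ion
  m <- mets[keep, ]
  lb <- ifelse(is.na(m$conc_lb), params$conc_floor, m$conc_lb)
  tibble::tibble(id = m$id, ln_lb = log(lb), ln_ub = log(m$conc_ub))
}

# per-reaction ion translocation count (sum of coefficients of ion species)
ion_translocation <- function(model) {
  ion_ids <- model$metabolites$id[model$metabolites$ion]
  purrr::map_dbl(model$reactions$stoich, function(s) {
    sum(s[names(s) %in% ion_ids])
  })
}

#' Transformed Gibbs energy of a reaction
#'
#' Evaluates DrG' = DrG'0 + adjust + RT * sum_j s_ij ln c_j (+ ion terms),
#' where the sum runs over concentration-variable metabolites only
#' (water, protons and fixed-activity species are excluded) and `adjust` is
#' the confidence-interval slack on the estimate.
#'
#' @param model A `metabolic_model`.
#' @param rxn_id Reaction id.
#' @param ln_conc Named numeric vector of ln(molar) concentrations covering
#'   the reaction's concentration-variable participants.
#' @param adjust CI slack delta, kJ/mol; must satisfy
#'   |adjust| <= [ci_halfwidth()] of the reaction's estimate.
#' @param params A [thermo_params()].
#' @return DrG', kJ/mol.
#' @export
reaction_energy <- function(model, rxn_id, ln_conc = numeric(),
                            adjust = 0, params = thermo_params()) {
  i <- match(rxn_id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction '", rxn_id, "'", call. = FALSE)
  r <- model$reactions[i, ]
  if (r$thermo_exempt) {
    stop("reaction '", rxn_id, "' is thermo-exempt (no DrG'0 estimate)",
         call. = FALSE)
  }
  hw <- ci_halfwidth(r$drg0_se, r$ci_level, params)
  if (abs(adjust) > hw + 1e-9) {
    stop("adjust exceeds the ", r$ci_level * 100,
         "% confidence half-width (", signif(hw, 6), " kJ/mol)", call. = FALSE)
  }
  s <- r$stoich[[1]]
  mets <- model$metabolites
  idx <- match(names(s), mets$id)
  conc_var <- !mets$fixed_conc[idx] & !mets$boundary[idx] & !mets$ion[idx]
  need <- names(s)[conc_var]
  miss <- setdiff(need, names(ln_conc))
  if (length(miss)) {
    stop("missing ln-concentration for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  rt_term <- sum(s[need] * ln_conc[need])
  ion_term <- sum(s[names(s) %in% mets$id[mets$ion]]) * params$ion_cost
  r$drg0_est + adjust + params$R * params$T * rt_term + ion_term
}

#' Compute a model-specific big-M energy constant
#'
#' The constant must dominate the largest attainable |DrG'| given the
#' concentration bounds, CI slacks and ion costs, so that the energy
#' constraint of an unused direction can never bind.
#'
#' @param model A `metabolic_model`.
#' @param params A [thermo_params()].
#' @return kJ/mol.
#' @export
compute_big_m <- function(model, params = thermo_params()) {
  cv <- conc_var_table(model, params)
  ln_abs_max <- stats::setNames(pmax(abs(cv$ln_lb), abs(cv$ln_ub)), cv$id)
  ion_ids <- model$metabolites$id[model$metabolites$ion]
  worst <- purrr::map_dbl(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    if (r$thermo_exempt) return(0)
    s <- r$stoich[[1]]
    in_cv <- names(s)[names(s) %in% cv$id]
    conc_part <- sum(abs(s[in_cv]) * ln_abs_max[in_cv])
    ion_part <- abs(sum(s[names(s) %in% ion_ids])) * params$ion_cost
    abs(r$drg0_est) + ci_halfwidth(r$drg0_se, r$ci_level, params) +
      params$R * params$T * conc_part + ion_part
  })
  max(worst, 1) + params$eps + 10
}
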