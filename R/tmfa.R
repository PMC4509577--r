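#' Thermodynamics-based metabolic flux analysis
#'
#' Solves the TMFA mixed-integer program: optimize a reaction flux subject
#' to steady-state mass balance, flux bounds, direction binaries, and the
#' constraint that every used, non-exempt reaction direction has a strictly
#' negative transformed Gibbs energy (realized as DrG' <= -eps), with DrG'
#' built from ln-concentration variables and a confidence-interval slack on
#' the DrG'0 estimate.
#'
#' @param model A `metabolic_model`.
#' @param params A [thermo_params()].
#' @param objective Reaction id to optimize (default: the model objective).
#' @param sense `"max"` or `"min"`.
#' @param options Solver options passed to the backend.
#' @return A `tmfa_solution` with fields `status`, `objective_value`,
#'   `fluxes`, `directions`, `ln_conc`, `energies`.
#' @seealso [solve_ptmfa()], [solve_variability()], [solve_fba()]
#' @export
solve_tmfa <- function(model, params = thermo_params(),
                       objective = model$objective_id, sense = "max",
                       options = list()) {
  prob <- build_tmfa_problem(model, params, thermo = TRUE, binaries = TRUE)
  res <- milp_solve(problem_payload(prob),
                    list(obj_net_flux(prob, objective, sense)), options)[[1]]
  sol <- extract_solution(prob, res, objective, sense)
  if (sol$status == "infeasible") {
    sol$conflict_hint <- infeasibility_hint(prob)
  }
  sol
}

#' Flux balance analysis (no thermodynamic constraints)
#'
#' Plain LP reference: steady state, bounds and couplings only. Used as the
#' relaxation bound for TMFA (the TMFA optimum can never exceed it).
#'
#' @inheritParams solve_tmfa
#' @return A `tmfa_solution` (with `ln_conc`/`energies` absent).
#' @export
solve_fba <- function(model, params = thermo_params(),
                      objective = model$objective_id, sense = "max",
                      options = list()) {
  prob <- build_tmfa_problem(model, params, thermo = FALSE, binaries = FALSE)
  res <- milp_solve(problem_payload(prob),
                    list(obj_net_flux(prob, objective, sense)), options)[[1]]
  extract_solution(prob, res, objective, sense)
}

#' Parsimonious TMFA
#'
#' Two-stage optimization: stage 1 finds the TMFA optimum of the objective;
#' stage 2 fixes the objective at that optimum (within a relative tolerance)
#' and minimizes the weighted total absolute flux through the network,
#' linearized over the directed halves. Reaction `parsimony_weight`s default
#' to 1 for enzymatic reactions and 0 for exchanges and passive diffusion
#' steps, so the stage-2 objective is an enzyme-cost proxy.
#'
#' @inheritParams solve_tmfa
#' @param stage_tol Relative tolerance coupling stage 2 to the stage-1
#'   optimum.
#' @return A `tmfa_solution`; `objective_value` is the (stage-1) objective
#'   achieved by the returned fluxes and `total_flux` the weighted total
#'   flux minimized in stage 2.
#' @export
solve_ptmfa <- function(model, params = thermo_params(),
                        objective = model$objective_id, sense = "max",
                        stage_tol = 1e-6, options = list()) {
  stage1 <- solve_tmfa(model, params, objective, sense, options)
  if (stage1$status != "optimal") return(stage1)
  vstar <- stage1$objective_value

  prob <- build_tmfa_problem(model, params, thermo = TRUE, binaries = TRUE)
  floor_val <- vstar - abs(vstar) * stage_tol
  ceil_val <- vstar + abs(vstar) * stage_tol
  ob <- obj_net_flux(prob, objective)
  if (sense == "max") {
    problem_add_row(prob, j = ob$idx, x = ob$val, cl = floor_val, cu = Inf,
                    label = "stage1_floor")
  } else {
    problem_add_row(prob, j = ob$idx, x = ob$val, cl = -Inf, cu = ceil_val,
                    label = "stage1_ceiling")
  }
  res <- milp_solve(problem_payload(prob), list(obj_total_flux(prob)),
                    options)[[1]]
  sol <- extract_solution(prob, res, objective, sense)
  if (sol$status == "optimal") {
    sol$total_flux <- res$objective
    sol$stage1_objective <- vstar
    net <- sol$fluxes$flux[match(objective, sol$fluxes$reaction)]
    sol$objective_value <- net
  }
  sol
}

#' Thermodynamic variability analysis
#'
#' Minimum and maximum of selected quantities (metabolite concentrations,
#' reaction fluxes, or reaction transformed Gibbs energies) over the
#' TMFA-feasible region, optionally restricted to solutions achieving at
#' least `objective_floor` times the optimum objective.
#'
#' @inheritParams solve_tmfa
#' @param targets A data frame (or tibble) with columns `type`
#'   (`"conc"`, `"flux"`, or `"energy"`) and `id` (metabolite or reaction
#'   id), or a character vector of metabolite ids (treated as `"conc"`).
#' @param objective_floor Fraction of the optimum the objective must retain
#'   (use `NULL` to skip the objective constraint entirely).
#' @return A tibble with columns `type`, `id`, `lo`, `hi`. Concentration
#'   ranges are reported in molar.
#' @export
solve_variability <- function(model, params = thermo_params(),
                              targets, objective_floor = 1.0,
                              objective = model$objective_id, sense = "max",
                              options = list()) {
  if (is.character(targets)) {
    targets <- tibble::tibble(type = "conc", id = targets)
  }
  targets <- tibble::as_tibble(targets)
  stopifnot(all(targets$type %in% c("conc", "flux", "energy")))

  prob <- build_tmfa_problem(model, params, thermo = TRUE, binaries = TRUE)
  if (!is.null(objective_floor) && !is.null(objective)) {
    base <- solve_tmfa(model, params, objective, sense, options)
    if (base$status != "optimal") {
      stop("base TMFA problem is ", base$status, call. = FALSE)
    }
    ob <- obj_net_flux(prob, objective)
    vstar <- base$objective_value
    if (sense == "max") {
      problem_add_row(prob, ob$idx, ob$val,
                      cl = vstar * objective_floor - 1e-9, cu = Inf,
                      label = "objective_floor")
    } else {
      problem_add_row(prob, ob$idx, ob$val,
                      cl = -Inf, cu = vstar * objective_floor + 1e-9,
                      label = "objective_ceiling")
    }
  }

  target_obj <- function(type, id, sns) {
    if (type == "conc") {
      if (!id %in% names(prob$i_conc)) {
        stop("'", id, "' has no concentration variable", call. = FALSE)
      }
      list(idx = prob$i_conc[[id]], val = 1, sense = sns)
    } else if (type == "flux") {
      obj_net_flux(prob, id, sns)
    } else {
      k <- match(id, model$reactions$id)
      if (model$reactions$thermo_exempt[k]) {
        stop("'", id, "' is thermo-exempt; its energy has no range",
             call. = FALSE)
      }
      s <- model$reactions$stoich[[k]]
      s_cv <- s[names(s) %in% names(prob$i_conc)]
      idx <- unname(prob$i_conc[names(s_cv)])
      val <- prob$RT * unname(s_cv)
      di <- prob$i_delta[[id]]
      if (!is.na(di)) { idx <- c(idx, di); val <- c(val, 1) }
      list(idx = idx, val = val, sense = sns)
    }
  }
  objectives <- purrr::flatten(purrr::map2(targets$type, targets$id,
    function(ty, id) list(target_obj(ty, id, "min"), target_obj(ty, id, "max"))))
  res <- milp_solve(problem_payload(prob), objectives, options)

  purrr::map_dfr(seq_len(nrow(targets)), function(k) {
    lo <- res[[2 * k - 1]]; hi <- res[[2 * k]]
    ty <- targets$type[k]; id <- targets$id[k]
    shift <- if (ty == "energy") {
      prob$const_energy[match(id, model$reactions$id)]
    } else 0
    to_units <- function(v) {
      if (ty == "conc") exp(v) else v + shift
    }
    lo_val <- if (lo$status == "optimal") to_units(lo$objective) else NA_real_
    hi_val <- if (hi$status == "optimal") to_units(hi$objective) else NA_real_
    stat <- paste(lo$status, hi$status, sep = "/")
    tibble::tibble(type = ty, id = id, lo = lo_val, hi = hi_val,
                   status = stat)
  })
}

#' Maximum product yield at fixed substrate uptake
#'
#' Fixes the substrate exchange at a given uptake rate, maximizes the
#' product exchange via TMFA, and returns the mol/mol yield. By default the
#' maintenance demands are relaxed (the experimental overall stoichiometries
#' this reproduces were derived assuming no growth), so the yield reflects
#' pure pathway stoichiometry.
#'
#' @inheritParams solve_tmfa
#' @param product_exchange,substrate_exchange Exchange reaction ids.
#' @param fixed_uptake Substrate uptake, mmol/gDW/day (> 0).
#' @param maintenance Keep the NGAM constraint active? Default `FALSE`.
#' @return A list: `yield` (mol product per mol substrate), `solution`.
#' @export
max_yield <- function(model, params = thermo_params(),
                      product_exchange, substrate_exchange, fixed_uptake,
                      maintenance = FALSE, options = list()) {
  stopifnot(fixed_uptake > 0)
  i <- match(substrate_exchange, model$reactions$id)
  if (is.na(i)) stop("unknown exchange '", substrate_exchange, "'",
                     call. = FALSE)
  model$reactions$lb[i] <- -fixed_uptake
  model$reactions$ub[i] <- -fixed_uptake
  if (!maintenance && !is.na(model$atpm_id)) {
    k <- match(model$atpm_id, model$reactions$id)
    model$reactions$lb[k] <- 0
  }
  sol <- solve_tmfa(model, params, objective = product_exchange,
                    sense = "max", options = options)
  yield <- if (sol$status == "optimal") sol$objective_value / fixed_uptake
           else NA_real_
  list(yield = yield, solution = sol)
}

# Cheap infeasibility diagnosis: relax each labeled constraint group with
# elastic slacks in the LP relaxation and report groups needing slack.
infeasibility_hint <- function(prob) {
  groups <- unique(sub(":.*$", "", prob$acc$label))
  paste0("binding constraint groups: ", paste(groups, collapse = ", "),
         "; check bounds fixed to nonzero values and community balances")
}
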