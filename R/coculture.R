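# Two-species chemostat (continuous coculture) formulation.
#
# Each species keeps its full TMFA constraint set; the shared extracellular
# metabolites are merged between the two models (one reactor, one medium:
# the species are thermodynamically coupled through the shared
# ln-concentration variables). Unit mass-balance rows on extracellular
# species are replaced by biomass-weighted community rows
#     sum_k X_k * (net secretion of species k)  >= 0
# for every non-feed metabolite (flux steady state: net accumulation is
# washed out by dilution), with feed substrates free in sign. Both species'
# growth fluxes are fixed at the dilution rate, turning the problem into a
# MIP with fixed biomass concentrations.

#' Build a two-species chemostat problem
#'
#' @param species_a,species_b `metabolic_model`s with distinct cytosols and
#'   identical declared extracellular metabolites (the curated cores from
#'   [build_sfu_core()] / [build_mhu_core()] satisfy this). Exchange
#'   reactions are dropped: a species' interaction with the medium is its
#'   membrane-crossing (transport) flux.
#' @param X_A,X_B Biomass concentrations, gDW/L.
#' @param D Dilution rate, 1/day; both species grow at exactly this rate.
#' @param feed Extracellular metabolite ids present in the feed (may have
#'   net flux into the reactor). Default propionate only.
#' @return An object of class `coculture_problem`.
#' @export
build_reactor <- function(species_a, species_b, X_A, X_B, D,
                          feed = "prop_e") {
  stopifnot(X_A >= 0, X_B >= 0, D >= 0)
  ext <- function(m) {
    m$metabolites$id[m$metabolites$compartment == "extracellular" &
                       !m$metabolites$boundary]
  }
  ea <- ext(species_a); eb <- ext(species_b)
  sym <- c(setdiff(ea, eb), setdiff(eb, ea))
  if (length(sym)) {
    stop("shared extracellular metabolites do not match; symmetric ",
         "difference: ", paste(sym, collapse = ", "), call. = FALSE)
  }
  bad_feed <- setdiff(feed, ea)
  if (length(bad_feed)) {
    stop("feed metabolites not in the shared medium: ",
         paste(bad_feed, collapse = ", "), call. = FALSE)
  }

  keep_a <- !species_a$reactions$is_exchange
  keep_b <- !species_b$reactions$is_exchange
  rxns_a <- species_a$reactions[keep_a, ]
  rxns_b <- species_b$reactions[keep_b, ]
  clash <- intersect(rxns_a$id, rxns_b$id)
  if (length(clash)) {
    stop("reaction id collision between species: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  mets <- dplyr::bind_rows(species_a$metabolites, species_b$metabolites)
  mets <- mets[!duplicated(mets$id), ]

  combined <- metabolic_model(
    mets, dplyr::bind_rows(rxns_a, rxns_b),
    objective_id = species_a$objective_id,
    id = paste0(species_a$id, "+", species_b$id),
    couplings = dplyr::bind_rows(species_a$couplings, species_b$couplings),
    uptake_ratios = dplyr::bind_rows(species_a$uptake_ratios,
                                     species_b$uptake_ratios)
  )
  # fix growth at the dilution rate
  for (g in c(species_a$growth_id, species_b$growth_id)) {
    if (is.null(g) || is.na(g)) {
      stop("species models must declare a growth reaction ($growth_id)",
           call. = FALSE)
    }
    i <- match(g, combined$reactions$id)
    combined$reactions$lb[i] <- D
    combined$reactions$ub[i] <- D
  }
  structure(
    list(model = combined, X_A = X_A, X_B = X_B, D = D, feed = feed,
         shared = ea,
         species_of = c(stats::setNames(rep("A", nrow(rxns_a)), rxns_a$id),
                        stats::setNames(rep("B", nrow(rxns_b)), rxns_b$id)),
         growth_a = species_a$growth_id, growth_b = species_b$growth_id,
         species_ids = c(A = species_a$id, B = species_b$id)),
    class = "coculture_problem"
  )
}

#' @export
print.coculture_problem <- function(x, ...) {
  cat("<coculture_problem> ", x$species_ids[["A"]], " (X_A = ", x$X_A,
      " gDW/L) + ", x$species_ids[["B"]], " (X_B = ", x$X_B,
      " gDW/L), D = ", x$D, "/day\n", sep = "")
  cat("  feed: ", paste(x$feed, collapse = ", "),
      "; shared medium: ", length(x$shared), " metabolites\n", sep = "")
  invisible(x)
}

# community net-production row of one shared metabolite:
# sum_k X_k * sum_i s_ij v_i over the species' reactions
community_terms <- function(cp, prob, met) {
  rxns <- cp$model$reactions
  idx <- val <- numeric(0)
  for (k in seq_len(nrow(rxns))) {
    s <- rxns$stoich[[k]]
    if (!met %in% names(s)) next
    X <- if (cp$species_of[[rxns$id[k]]] == "A") cp$X_A else cp$X_B
    coef <- X * s[[met]]
    if (coef == 0) next
    idx <- c(idx, prob$i_vf[[rxns$id[k]]], prob$i_vr[[rxns$id[k]]])
    val <- c(val, coef, -coef)
  }
  list(idx = idx, val = val)
}

#' Solve a chemostat coculture problem
#'
#' The default objective minimizes the species-weighted total flux through
#' the two networks (parsimonious criterion, the species' growth being fixed
#' at the dilution rate). `objective = "max_rate"` instead maximizes the
#' community net production rate of `rate_met` (used e.g. for the maximal
#' methane yield of the zero-maintenance community).
#'
#' @param cp A [build_reactor()] problem.
#' @param params A [thermo_params()].
#' @param objective `"parsimony"` or `"max_rate"`.
#' @param rate_met Extracellular metabolite whose community rate is
#'   maximized when `objective = "max_rate"`.
#' @param force_zero Extracellular metabolites whose community net rate is
#'   pinned to exactly zero (e.g. `c("h2_e", "for_e")` to forbid net
#'   hydrogen/formate export).
#' @param options Backend options.
#' @return An object of class `reactor_solution`: `status`,
#'   `objective_value`, `community_rates` (mmol/L/day, positive = net
#'   production), `community_yields` (mol per mol feed consumed),
#'   `species_rates` (per-gDW specific exchange rates), and the underlying
#'   `tmfa_solution` in `$solution`.
#' @export
solve_reactor <- function(cp, params = thermo_params(),
                          objective = c("parsimony", "max_rate"),
                          rate_met = "ch4_e", force_zero = character(),
                          options = list()) {
  stopifnot(inherits(cp, "coculture_problem"))
  objective <- match.arg(objective)
  prob <- build_tmfa_problem(cp$model, params, balance_skip = cp$shared)
  for (met in cp$shared) {
    tm <- community_terms(cp, prob, met)
    if (!length(tm$idx)) next
    if (met %in% force_zero) {
      problem_add_row(prob, tm$idx, tm$val, cl = 0, cu = 0,
                      label = paste0("community:", met))
    } else if (met %in% cp$feed) {
      next # free in sign
    } else {
      problem_add_row(prob, tm$idx, tm$val, cl = 0, cu = Inf,
                      label = paste0("community:", met))
    }
  }
  ob <- if (objective == "parsimony") {
    X <- ifelse(cp$species_of[cp$model$reactions$id] == "A", cp$X_A, cp$X_B)
    obj_total_flux(prob, sense = "min",
                   weights = cp$model$reactions$parsimony_weight * X)
  } else {
    tm <- community_terms(cp, prob, rate_met)
    list(idx = tm$idx, val = tm$val, sense = "max")
  }
  res <- milp_solve(problem_payload(prob), list(ob), options)[[1]]
  sol <- extract_solution(prob, res,
                          paste0("reactor_", objective), ob$sense)
  if (sol$status != "optimal") {
    out <- structure(
      list(status = sol$status, solution = sol,
           conflict_hint = reactor_conflict_hint(cp),
           X_A = cp$X_A, X_B = cp$X_B, D = cp$D),
      class = "reactor_solution")
    return(out)
  }
  flux <- stats::setNames(sol$fluxes$flux, sol$fluxes$reaction)
  spec_rate <- function(species, met) {
    rxns <- cp$model$reactions
    tot <- 0
    for (k in seq_len(nrow(rxns))) {
      if (cp$species_of[[rxns$id[k]]] != species) next
      s <- rxns$stoich[[k]]
      if (met %in% names(s)) tot <- tot + s[[met]] * flux[[rxns$id[k]]]
    }
    tot
  }
  species_rates <- tidyr::expand_grid(species = c("A", "B"),
                                      metabolite = cp$shared) |>
    dplyr::mutate(rate = purrr::map2_dbl(.data$species, .data$metabolite,
                                         spec_rate))
  community_rates <- species_rates |>
    dplyr::mutate(X = ifelse(.data$species == "A", cp$X_A, cp$X_B)) |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::summarise(rate = sum(.data$rate * .data$X), .groups = "drop")
  feed_cons <- -sum(community_rates$rate[community_rates$metabolite %in%
                                           cp$feed])
  yields <- community_rates |>
    dplyr::mutate(yield = if (feed_cons > 1e-9) .data$rate / feed_cons
                  else NA_real_)
  structure(
    list(status = "optimal", objective_value = sol$objective_value,
         community_rates = community_rates, community_yields = yields,
         species_rates = species_rates, solution = sol,
         X_A = cp$X_A, X_B = cp$X_B, D = cp$D, feed = cp$feed),
    class = "reactor_solution"
  )
}

reactor_conflict_hint <- function(cp) {
  paste0("infeasible at (X_A = ", cp$X_A, ", X_B = ", cp$X_B, ", D = ",
         cp$D, "); binding groups include the fixed growth rates (",
         cp$growth_a, ", ", cp$growth_b,
         "), maintenance demands, and the community balances of: ",
         paste(setdiff(cp$shared, cp$feed), collapse = ", "))
}

#' @export
print.reactor_solution <- function(x, ...) {
  cat("<reactor_solution> status: ", x$status, "\n", sep = "")
  if (x$status == "optimal") {
    cat("  objective: ", format(x$objective_value, digits = 6), "\n", sep = "")
    nz <- dplyr::filter(x$community_yields, abs(.data$rate) > 1e-6)
    print(nz)
  } else if (!is.null(x$conflict_hint)) {
    cat("  ", x$conflict_hint, "\n", sep = "")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.reactor_solution <- function(x, ...) {
  if (x$status != "optimal") {
    return(tibble::tibble(metabolite = character(), rate = numeric(),
                          yield = numeric()))
  }
  x$community_yields
}

#' @exportS3Method generics::glance
glance.reactor_solution <- function(x, ...) {
  tibble::tibble(status = x$status,
                 objective_value = x$objective_value %||% NA_real_,
                 X_A = x$X_A, X_B = x$X_B, D = x$D)
}

#' Sweep a coculture over dilution rates or biomass ratios
#'
#' Re-solves the reactor over a grid, one [solve_reactor()] call per grid
#' point; infeasible points are flagged, not fatal.
#'
#' @param species_a,species_b Species models (see [build_reactor()]).
#' @param variable `"dilution"` (grid of D values at fixed `X_A`, `X_B`) or
#'   `"biomass_ratio"` (grid of X_B/X_A ratios at fixed `X_A` and `D`).
#' @param grid Numeric grid (non-negative).
#' @param X_A,X_B,D Fixed values for the non-swept parameters.
#' @param feed,force_zero,objective,rate_met,params,options Passed to
#'   [build_reactor()] / [solve_reactor()].
#' @return A tibble of class `reactor_sweep`: one row per grid point and
#'   shared metabolite, with community `rate`, `yield` and solve `status`.
#' @export
sweep_reactor <- function(species_a, species_b,
                          variable = c("dilution", "biomass_ratio"),
                          grid, X_A = 4, X_B = 3, D = 0.05,
                          feed = "prop_e", force_zero = character(),
                          objective = "parsimony", rate_met = "ch4_e",
                          params = thermo_params(), options = list()) {
  variable <- match.arg(variable)
  stopifnot(length(grid) >= 1, all(grid >= 0))
  rows <- purrr::map_dfr(grid, function(g) {
    cp <- if (variable == "dilution") {
      build_reactor(species_a, species_b, X_A, X_B, D = g, feed = feed)
    } else {
      build_reactor(species_a, species_b, X_A, X_B = g * X_A, D = D,
                    feed = feed)
    }
    rs <- solve_reactor(cp, params, objective = objective,
                        rate_met = rate_met, force_zero = force_zero,
                        options = options)
    if (rs$status != "optimal") {
      return(tibble::tibble(variable = variable, value = g,
                            metabolite = NA_character_, rate = NA_real_,
                            yield = NA_real_, status = rs$status,
                            objective_value = NA_real_))
    }
    dplyr::mutate(rs$community_yields, variable = variable, value = g,
                  status = "optimal",
                  objective_value = rs$objective_value) |>
      dplyr::select("variable", "value", "metabolite", "rate", "yield",
                    "status", "objective_value")
  })
  class(rows) <- c("reactor_sweep", class(rows))
  rows
}

#' Plot a coculture sweep
#'
#' Community yields of the non-trivial shared metabolites against the swept
#' variable; infeasible grid points appear as gaps.
#'
#' @param object A [sweep_reactor()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reactor_sweep <- function(object, ...) {
  dat <- dplyr::filter(object, !is.na(.data$metabolite),
                       abs(.data$rate) > 1e-9)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$value, y = .data$yield,
                                    colour = .data$metabolite)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = unique(object$variable),
      y = "community yield (mol per mol feed)",
      colour = "metabolite"
    ) +
    ggplot2::theme_minimal()
}

#' Critical biomass ratio for complete hydrogen consumption
#'
#' Finds, by bisection, the consumer:producer biomass ratio at which the
#' community net yield of an electron carrier (H2 by default) first reaches
#' zero at fixed dilution rate. Beyond that ratio the consumer's energy
#' demand exceeds what the producer supplies and the reactor is infeasible.
#'
#' @param species_a Producer model (its biomass is the ratio denominator).
#' @param species_b Consumer model.
#' @param D Dilution rate, 1/day.
#' @param params A [thermo_params()].
#' @param X_A Producer biomass, gDW/L (only the ratio matters when the feed
#'   is unlimited).
#' @param tol Absolute tolerance on the ratio.
#' @param max_ratio Upper end of the search interval.
#' @param carrier Shared metabolite whose yield is tracked (`"h2_e"`).
#' @param feed,force_zero Passed to the reactor builder/solver; by default
#'   formate exchange is pinned to zero so all electron transfer is carried
#'   by H2.
#' @param options Backend options.
#' @return A list: `ratio` (NA if censored), `censored`, `bracket` (lo/hi
#'   ratios), `yield_lo`/`yield_hi` (bracketing carrier yields), `trace`
#'   (tibble of all evaluations).
#' @export
critical_ratio <- function(species_a, species_b, D = 0.05,
                           params = thermo_params(), X_A = 1, tol = 0.01,
                           max_ratio = 8, carrier = "h2_e",
                           feed = "prop_e", force_zero = "for_e",
                           options = list()) {
  evals <- list()
  yield_at <- function(ratio) {
    cp <- build_reactor(species_a, species_b, X_A = X_A, X_B = ratio * X_A,
                        D = D, feed = feed)
    rs <- solve_reactor(cp, params, force_zero = force_zero,
                        options = options)
    y <- if (rs$status == "optimal") {
      rs$community_yields$yield[rs$community_yields$metabolite == carrier]
    } else NA_real_
    evals[[length(evals) + 1]] <<- tibble::tibble(
      ratio = ratio, yield = y, status = rs$status)
    y
  }
  y0 <- yield_at(0)
  if (is.na(y0) || y0 <= 1e-9) {
    stop("carrier yield at ratio 0 is not positive (", y0,
         "); nothing to bisect", call. = FALSE)
  }
  y_hi <- yield_at(max_ratio)
  if (!is.na(y_hi) && y_hi > 1e-9) {
    return(list(ratio = NA_real_, censored = TRUE,
                bracket = c(0, max_ratio), yield_lo = y0, yield_hi = y_hi,
                trace = dplyr::bind_rows(evals)))
  }
  lo <- 0; hi <- max_ratio; y_lo <- y0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    y_mid <- yield_at(mid)
    if (!is.na(y_mid) && y_mid > 1e-9) {
      lo <- mid; y_lo <- y_mid
    } else {
      hi <- mid; y_hi <- y_mid
    }
  }
  list(ratio = (lo + hi) / 2, censored = FALSE, bracket = c(lo, hi),
       yield_lo = y_lo, yield_hi = y_hi, trace = dplyr::bind_rows(evals))
}
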