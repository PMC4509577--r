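# Seed-reproducible synthetic networks and datasets.
#
# Networks are generated from an explicit per-metabolite formation-energy
# assignment, so reaction DrG'0 values are thermodynamically consistent by
# construction (cycle sums are exactly zero when the standard-error mode is
# "zero"), which is what the loop-law tests rely on.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Specification for a synthetic test network
#'
#' @param n_metabolites Number of metabolites (>= 2).
#' @param n_reactions Number of internal reactions (>= `n_metabolites - 1`;
#'   the generator first builds a feasible uptake-to-secretion chain, then
#'   adds random shortcut reactions).
#' @param n_exchanges Number of exchange reactions (>= 2: one uptake, the
#'   rest secretion drains).
#' @param cycle_injections Number of deliberate 3-cycles added (each adds 3
#'   reactions over existing metabolites).
#' @param se_mode `"zero"` (DrG'0 exact, SE = 0) or `"uniform"` (SE drawn
#'   uniformly from `se_range`).
#' @param se_range Length-2 numeric, kJ/mol.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_metabolites = 8, n_reactions = 10,
                           n_exchanges = 2, cycle_injections = 0,
                           se_mode = c("zero", "uniform"),
                           se_range = c(5, 15), seed = 1) {
  se_mode <- match.arg(se_mode)
  if (n_metabolites < 2) stop("need at least 2 metabolites", call. = FALSE)
  if (n_reactions < n_metabolites - 1) {
    stop("n_reactions must be >= n_metabolites - 1 (no path possible)",
         call. = FALSE)
  }
  if (n_exchanges < 2) stop("need at least 2 exchanges", call. = FALSE)
  structure(list(n_metabolites = n_metabolites, n_reactions = n_reactions,
                 n_exchanges = n_exchanges,
                 cycle_injections = cycle_injections,
                 se_mode = se_mode, se_range = se_range, seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic metabolic network
#'
#' Builds a connected network with a thermodynamically feasible
#' uptake-to-secretion chain. Every metabolite receives a formation energy;
#' each reaction's DrG'0 is the stoichiometric sum of formation energies,
#' so any cycle's DrG'0 values sum to exactly zero in `se_mode = "zero"`.
#'
#' @param spec A [synthetic_spec()].
#' @return A validated `metabolic_model` with attribute
#'   `formation_energies`.
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_metabolites
    ids <- sprintf("M%02d", seq_len(n))
    # formation energies decrease along the chain -> feasible downhill path
    steps <- stats::runif(n - 1, 5, 25)
    fe <- stats::setNames(-100 - c(0, cumsum(steps)), ids)

    mets <- dplyr::bind_rows(purrr::map(ids, function(m) {
      metabolite(m, compartment = if (m %in% c(ids[1], ids[n]))
        "extracellular" else "cytosol_A")
    }))

    drg0 <- function(s) sum(s * fe[names(s)])
    mk_se <- function() {
      if (spec$se_mode == "zero") 0 else
        stats::runif(1, spec$se_range[1], spec$se_range[2])
    }
    rxn_list <- list()
    for (k in seq_len(n - 1)) {
      s <- stats::setNames(c(-1, 1), ids[c(k, k + 1)])
      rxn_list[[length(rxn_list) + 1]] <-
        reaction(sprintf("R%02d", k), s, lb = 0, ub = 1000,
                 drg0_est = drg0(s), drg0_se = mk_se())
    }
    extra <- spec$n_reactions - (n - 1)
    k_extra <- 0
    while (k_extra < extra) {
      pair <- sort(sample.int(n, 2))
      s <- stats::setNames(c(-1, 1), ids[pair])
      k_extra <- k_extra + 1
      rxn_list[[length(rxn_list) + 1]] <-
        reaction(sprintf("RX%02d", k_extra), s, lb = -1000, ub = 1000,
                 drg0_est = drg0(s), drg0_se = mk_se())
    }
    for (cyc in seq_len(spec$cycle_injections)) {
      tri <- sample.int(n, 3)
      for (e in 1:3) {
        a <- tri[e]; b <- tri[e %% 3 + 1]
        s <- stats::setNames(c(-1, 1), ids[c(a, b)])
        rxn_list[[length(rxn_list) + 1]] <-
          reaction(sprintf("RC%02d_%d", cyc, e), s, lb = -1000, ub = 1000,
                   drg0_est = drg0(s), drg0_se = mk_se())
      }
    }
    ex_ids <- character(spec$n_exchanges)
    ex_mets <- c(ids[1], ids[n],
                 if (spec$n_exchanges > 2)
                   sample(ids[-c(1, n)], spec$n_exchanges - 2))
    for (e in seq_len(spec$n_exchanges)) {
      m <- ex_mets[e]
      ex_ids[e] <- paste0("EX_", m)
      bounds <- if (e == 1) c(-10, 0) else c(0, 1000)
      rxn_list[[length(rxn_list) + 1]] <-
        reaction(ex_ids[e], stats::setNames(-1, m),
                 lb = bounds[1], ub = bounds[2], is_exchange = TRUE)
    }
    mdl <- metabolic_model(
      mets, dplyr::bind_rows(rxn_list),
      objective_id = paste0("EX_", ids[n]),
      id = sprintf("synthetic_seed%d", spec$seed)
    )
    attr(mdl, "formation_energies") <- fe
    mdl
  })
}

#' Three-reaction thermodynamic loop fixture
#'
#' Three metabolites in a closed cycle A -> B -> C -> A with DrG'0 of
#' (-5, -5, +10) kJ/mol (summing to zero, as any formation-consistent cycle
#' must) and no exchanges. With SE = 0 the only feasible flux distribution
#' is all-zero: no sign assignment makes all three energies negative. With
#' SE large enough the CI slacks can push all three energies negative and
#' the cycle may carry flux — the documented flexibility of the
#' reaction-basis uncertainty treatment.
#'
#' @param se Standard error applied to all three reactions, kJ/mol.
#' @param bounded Use finite (+/-1000) flux bounds (default). `FALSE` gives
#'   infinite bounds so that plain FBA exhibits the unbounded loop.
#' @return A `metabolic_model`.
#' @export
loop_fixture <- function(se = 0, bounded = TRUE) {
  b <- if (bounded) 1000 else Inf
  mets <- dplyr::bind_rows(
    metabolite("A", formula = "C2H4O2"),
    metabolite("B", formula = "C2H4O2"),
    metabolite("C", formula = "C2H4O2")
  )
  rxns <- dplyr::bind_rows(
    reaction("RAB", c(A = -1, B = 1), lb = -b, ub = b,
             drg0_est = -5, drg0_se = se),
    reaction("RBC", c(B = -1, C = 1), lb = -b, ub = b,
             drg0_est = -5, drg0_se = se),
    reaction("RCA", c(C = -1, A = 1), lb = -b, ub = b,
             drg0_est = 10, drg0_se = se)
  )
  metabolic_model(mets, rxns, objective_id = "RAB", id = "loop_fixture")
}

#' Synthetic chemostat maintenance dataset
#'
#' Generates (growth rate, ATP demand) observations from the linear energy
#' balance q_ATP = GAM * mu + NGAM plus Gaussian noise, for exercising
#' [fit_maintenance()].
#'
#' @param gam Growth-associated maintenance, mmol ATP/gDW.
#' @param ngam Non-growth maintenance, mmol ATP/gDW/day.
#' @param mu_grid Growth rates, 1/day.
#' @param noise_sd Gaussian noise SD on q_ATP.
#' @param seed Integer seed.
#' @return Tibble with columns `mu`, `q_atp`.
#' @export
chemostat_dataset <- function(gam, ngam, mu_grid, noise_sd = 0, seed = 1) {
  stopifnot(length(mu_grid) >= 1)
  with_seed(seed, {
    tibble::tibble(
      mu = mu_grid,
      q_atp = gam * mu_grid + ngam +
        stats::rnorm(length(mu_grid), 0, noise_sd)
    )
  })
}
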