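#' Construct a condition profile
#'
#' A condition profile is a named overlay of qualitative constraints applied
#' to a model before solving: reaction direction fixes, flux-equality
#' couplings (e.g. between fumarate reductase and the cytosolic hydrogenase,
#' which share the membrane), uptake-ratio constraints between two exchanges
#' (e.g. three fumarate taken up per propionate), and blocked exchanges
#' (e.g. no H2 production in monoculture).
#'
#' @param name Token naming the profile.
#' @param direction_fixes Named character vector reaction id -> one of
#'   `"forward"`, `"reverse"`, `"off"`.
#' @param couplings Tibble/data frame with columns `rxn_a`, `rxn_b`, `ratio`:
#'   constraints v_a = ratio * v_b.
#' @param uptake_ratios Tibble with columns `ex_a`, `ex_b`, `ratio`:
#'   uptake through `ex_a` equals `ratio` times uptake through `ex_b`.
#' @param blocked_exchanges Character vector of exchange ids forced to zero.
#' @return An object of class `condition_profile`.
#' @export
condition_profile <- function(name,
                              direction_fixes = character(),
                              couplings = NULL,
                              uptake_ratios = NULL,
                              blocked_exchanges = character()) {
  if (length(direction_fixes)) {
    bad <- setdiff(unique(direction_fixes), c("forward", "reverse", "off"))
    if (length(bad)) {
      stop("unknown direction fix value(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  couplings <- tibble::as_tibble(couplings %||%
    tibble::tibble(rxn_a = character(), rxn_b = character(), ratio = numeric()))
  uptake_ratios <- tibble::as_tibble(uptake_ratios %||%
    tibble::tibble(ex_a = character(), ex_b = character(), ratio = numeric()))
  if (nrow(couplings) && any(couplings$ratio <= 0)) {
    stop("coupling ratios must be > 0", call. = FALSE)
  }
  if (nrow(uptake_ratios) && any(uptake_ratios$ratio <= 0)) {
    stop("uptake ratios must be > 0", call. = FALSE)
  }
  structure(
    list(name = name, direction_fixes = direction_fixes,
         couplings = couplings, uptake_ratios = uptake_ratios,
         blocked_exchanges = blocked_exchanges),
    class = "condition_profile"
  )
}

#' Apply a condition profile to a model
#'
#' Returns a copy of the model with bounds tightened according to the
#' profile's direction fixes, blocked exchanges set to zero flux, and
#' coupling / uptake-ratio constraints registered for the solver. Bounds are
#' only ever tightened, never widened, so the feasible flux set of the
#' result is a subset of the input's and the operation is idempotent.
#'
#' @param model A `metabolic_model`.
#' @param profile A [condition_profile()].
#' @return The constrained `metabolic_model`.
#' @export
apply_condition <- function(model, profile) {
  stopifnot(inherits(profile, "condition_profile"))
  rxns <- model$reactions
  ids <- rxns$id
  refs <- c(names(profile$direction_fixes), profile$blocked_exchanges,
            profile$couplings$rxn_a, profile$couplings$rxn_b,
            profile$uptake_ratios$ex_a, profile$uptake_ratios$ex_b)
  unknown <- setdiff(refs, ids)
  if (length(unknown)) {
    stop("profile '", profile$name, "' references unknown reactions: ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(names(profile$direction_fixes))) {
    dup <- unique(names(profile$direction_fixes)[
      duplicated(names(profile$direction_fixes))])
    stop("conflicting direction fixes for: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  for (r in names(profile$direction_fixes)) {
    i <- match(r, ids)
    fix <- profile$direction_fixes[[r]]
    if (fix == "forward") {
      rxns$lb[i] <- max(rxns$lb[i], 0)
    } else if (fix == "reverse") {
      rxns$ub[i] <- min(rxns$ub[i], 0)
    } else { # off
      rxns$lb[i] <- max(rxns$lb[i], 0)
      rxns$ub[i] <- min(rxns$ub[i], 0)
    }
  }
  for (r in profile$blocked_exchanges) {
    i <- match(r, ids)
    rxns$lb[i] <- max(rxns$lb[i], 0)
    rxns$ub[i] <- min(rxns$ub[i], 0)
  }
  model$reactions <- rxns
  model$couplings <- dplyr::distinct(
    dplyr::bind_rows(model$couplings, profile$couplings))
  model$uptake_ratios <- dplyr::distinct(
    dplyr::bind_rows(model$uptake_ratios, profile$uptake_ratios))
  model$condition <- profile$name
  model
}

#' Fix an exchange at a given uptake rate
#'
#' Convenience for yield analyses: sets both bounds of `exchange` to
#' `-uptake` (exchanges are drains, so negative flux is uptake).
#'
#' @param model A `metabolic_model`.
#' @param exchange Exchange reaction id.
#' @param uptake Uptake rate, mmol/gDW/day (> 0 consumes the substrate).
#' @return The modified model.
#' @export
fix_uptake <- function(model, exchange, uptake) {
  i <- match(exchange, model$reactions$id)
  if (is.na(i)) stop("unknown exchange '", exchange, "'", call. = FALSE)
  model$reactions$lb[i] <- -uptake
  model$reactions$ub[i] <- -uptake
  model
}

#' Block a reaction (zero flux in both directions)
#'
#' @param model A `metabolic_model`.
#' @param rxn Reaction id(s).
#' @return The modified model.
#' @export
block_reaction <- function(model, rxn) {
  i <- match(rxn, model$reactions$id)
  if (anyNA(i)) stop("unknown reaction(s): ",
                     paste(rxn[is.na(i)], collapse = ", "), call. = FALSE)
  model$reactions$lb[i] <- 0
  model$reactions$ub[i] <- 0
  model
}

#' Relax the non-growth maintenance demand
#'
#' Sets the ATPM lower bound to zero, the convention used when reproducing
#' experimental overall stoichiometries derived assuming no growth.
#'
#' @param model A `metabolic_model`.
#' @return The modified model.
#' @export
relax_maintenance <- function(model) {
  if (is.na(model$atpm_id)) return(model)
  i <- match(model$atpm_id, model$reactions$id)
  model$reactions$lb[i] <- 0
  model
}
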