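#' Construct a metabolite record
#'
#' Metabolites are rows of the `metabolites` table of a [metabolic_model()].
#' Concentration bounds are molar; the defaults (1e-5 M to 0.02 M) are the
#' global bounds used for all thermodynamically active species. A metabolite
#' with `conc_lb = NA` has no concentration lower bound (used for dissolved
#' H2 and formate, which can fall well below 0.01 mM); the solver substitutes
#' a numerical floor (`conc_floor` in [thermo_params()]).
#'
#' @param id Short unique token.
#' @param name Free-text name; defaults to `id`.
#' @param compartment One of `"cytosol_A"`, `"cytosol_B"`, `"extracellular"`.
#' @param formula Elemental composition, e.g. `"C4H4O4"`. Moiety tokens
#'   (capitalised multi-letter symbols such as `"Coa"`, `"Mfr"`) are allowed
#'   and treated as indivisible pseudo-elements by the balance checker.
#' @param charge Integer formal charge (optional).
#' @param conc_lb,conc_ub Concentration bounds, molar. `conc_lb = NA` means
#'   no lower bound.
#' @param fixed_conc Logical; `TRUE` for species whose activity is held fixed
#'   (cofactor pairs, carrier-bound intermediates): they appear in
#'   stoichiometry and mass balance but contribute no RT*ln(c) term.
#' @param boundary Logical; `TRUE` for species exempt from mass balance
#'   (water and protons in a buffered aqueous medium).
#' @param ion Logical; `TRUE` for translocated-ion species (periplasmic H+ or
#'   Na+). They are mass balanced, carry no concentration variable, and add a
#'   fixed electrochemical cost per ion to reaction energies (see
#'   [thermo_params()] `ion_cost`).
#' @return A one-row tibble.
#' @export
metabolite <- function(id, name = id, compartment = "cytosol_A",
                       formula = NA_character_, charge = NA_integer_,
                       conc_lb = 1e-5, conc_ub = 0.02,
                       fixed_conc = FALSE, boundary = FALSE, ion = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!compartment %in% c("cytosol_A", "cytosol_B", "extracellular")) {
    stop("unknown compartment: ", compartment, call. = FALSE)
  }
  if (!is.na(conc_lb)) {
    if (conc_lb <= 0) stop("conc_lb must be > 0 for '", id, "'", call. = FALSE)
    if (conc_lb > conc_ub) stop("conc_lb > conc_ub for '", id, "'", call. = FALSE)
  }
  tibble::tibble(
    id = id, name = name, compartment = compartment,
    formula = formula, charge = as.integer(charge),
    conc_lb = as.numeric(conc_lb), conc_ub = as.numeric(conc_ub),
    fixed_conc = isTRUE(fixed_conc), boundary = isTRUE(boundary),
    ion = isTRUE(ion)
  )
}

#' Construct a reaction record
#'
#' Fluxes are in mmol/gDW/day throughout. `stoich` maps metabolite ids to
#' signed coefficients (negative = consumed). Exchange reactions are
#' single-metabolite drains on extracellular species with coefficient -1,
#' so negative flux is uptake and positive flux is secretion.
#'
#' A reaction without a standard transformed Gibbs energy estimate
#' (`drg0_est = NA`) is `thermo_exempt`: it receives direction binaries but
#' no energy constraint (the treatment applied to ferredoxin-containing
#' reactions, for which group-contribution estimates do not exist).
#'
#' @param id Short unique token.
#' @param stoich Named numeric vector of coefficients.
#' @param lb,ub Flux bounds, mmol/gDW/day.
#' @param name Free text.
#' @param drg0_est Standard transformed Gibbs energy of reaction, kJ/mol
#'   (`NA` = no estimate, reaction is thermodynamically exempt).
#' @param drg0_se Standard error of `drg0_est`, kJ/mol.
#' @param ci_level Confidence level bounding the energy slack: 0.95 or 0.99.
#' @param is_exchange Logical.
#' @param parsimony_weight Weight of |flux| in the parsimonious (stage-2)
#'   objective. Enzymatic reactions weigh 1; exchanges and passive
#'   diffusion-like membrane crossings weigh 0 (enzyme-cost proxy).
#' @return A one-row tibble with a list-column `stoich`.
#' @export
reaction <- function(id, stoich, lb = -1000, ub = 1000, name = id,
                     drg0_est = NA_real_, drg0_se = NA_real_,
                     ci_level = 0.95, is_exchange = FALSE,
                     parsimony_weight = if (is_exchange) 0 else 1) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (is.null(names(stoich)) || any(!nzchar(names(stoich)))) {
    stop("stoich must be a fully named numeric vector (reaction '", id, "')",
         call. = FALSE)
  }
  if (anyDuplicated(names(stoich))) {
    stop("duplicate metabolite in stoich of '", id, "'", call. = FALSE)
  }
  if (lb > ub) stop("lb > ub for reaction '", id, "'", call. = FALSE)
  if (!is.na(drg0_se) && drg0_se < 0) {
    stop("drg0_se must be >= 0 for '", id, "'", call. = FALSE)
  }
  if (!ci_level %in% c(0.95, 0.99)) {
    stop("ci_level must be 0.95 or 0.99 for '", id, "'", call. = FALSE)
  }
  exempt <- is.na(drg0_est)
  tibble::tibble(
    id = id, name = name,
    stoich = list(stoich[stoich != 0]),
    lb = as.numeric(lb), ub = as.numeric(ub),
    drg0_est = as.numeric(drg0_est),
    drg0_se = as.numeric(if (exempt) NA_real_ else
      ifelse(is.na(drg0_se), 0, drg0_se)),
    ci_level = as.numeric(ci_level),
    thermo_exempt = exempt,
    is_exchange = isTRUE(is_exchange),
    parsimony_weight = as.numeric(parsimony_weight)
  )
}

#' Assemble and validate a metabolic model
#'
#' @param metabolites Tibble of [metabolite()] rows (rows are rbind-able).
#' @param reactions Tibble of [reaction()] rows.
#' @param objective_id Reaction id of the default objective (biomass, ATP
#'   sink, or a product exchange).
#' @param atpm_id Reaction id of the non-growth maintenance (ATPM) drain,
#'   or `NA`.
#' @param gam Growth-associated maintenance, mmol ATP/gDW.
#' @param ngam Non-growth-associated maintenance, mmol ATP/gDW/day.
#' @param sur_caps Named numeric vector: exchange id -> maximum uptake
#'   (mmol/gDW/day). Applied as a lower flux bound of -cap on the exchange.
#' @param couplings Tibble with columns `rxn_a`, `rxn_b`, `ratio`
#'   (constraints v_a = ratio * v_b), or `NULL`.
#' @param uptake_ratios Tibble with columns `ex_a`, `ex_b`, `ratio`
#'   (uptake_a = ratio * uptake_b on exchange fluxes), or `NULL`.
#' @param id Model identifier.
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, objective_id,
                            atpm_id = NA_character_, gam = 0, ngam = 0,
                            sur_caps = NULL, couplings = NULL,
                            uptake_ratios = NULL, id = "model") {
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  mdl <- structure(
    list(
      id = id,
      metabolites = metabolites,
      reactions = reactions,
      objective_id = objective_id,
      atpm_id = atpm_id,
      gam = gam, ngam = ngam,
      sur_caps = sur_caps %||% stats::setNames(numeric(0), character(0)),
      couplings = couplings %||%
        tibble::tibble(rxn_a = character(), rxn_b = character(), ratio = numeric()),
      uptake_ratios = uptake_ratios %||%
        tibble::tibble(ex_a = character(), ex_b = character(), ratio = numeric())
    ),
    class = "metabolic_model"
  )
  validate_model(mdl)
  # apply uptake caps as exchange lower bounds
  if (length(mdl$sur_caps)) {
    for (ex in names(mdl$sur_caps)) {
      i <- match(ex, mdl$reactions$id)
      mdl$reactions$lb[i] <- max(mdl$reactions$lb[i], -abs(mdl$sur_caps[[ex]]))
    }
  }
  mdl
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Validate a metabolic model
#'
#' Checks id uniqueness, stoichiometry references, objective/maintenance
#' resolution, bound sanity, and the exchange-reaction contract (exchanges
#' touch exactly one non-boundary metabolite).
#'
#' @param model A `metabolic_model`.
#' @return The model, invisibly. Errors describe every offending id.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites
  rxns <- model$reactions
  if (anyDuplicated(mets$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(rxns$id)) {
    stop("duplicate reaction ids: ",
         paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- purrr::imap(rxns$stoich, function(s, i) {
    setdiff(names(s), mets$id)
  })
  missing <- unique(unlist(bad))
  if (length(missing)) {
    offenders <- rxns$id[lengths(bad) > 0]
    stop("stoichiometry references undeclared metabolites: ",
         paste(missing, collapse = ", "),
         " (in reactions ", paste(offenders, collapse = ", "), ")",
         call. = FALSE)
  }
  if (!is.na(model$objective_id) && !model$objective_id %in% rxns$id) {
    stop("objective_id '", model$objective_id, "' is not a reaction",
         call. = FALSE)
  }
  if (!is.na(model$atpm_id) && !model$atpm_id %in% rxns$id) {
    stop("atpm_id '", model$atpm_id, "' is not a reaction", call. = FALSE)
  }
  if (any(rxns$lb > rxns$ub)) {
    stop("lb > ub for: ", paste(rxns$id[rxns$lb > rxns$ub], collapse = ", "),
         call. = FALSE)
  }
  ex <- rxns[rxns$is_exchange, ]
  if (nrow(ex)) {
    nb <- purrr::map_int(ex$stoich, function(s) {
      sum(!mets$boundary[match(names(s), mets$id)])
    })
    if (any(nb != 1L)) {
      stop("exchange reactions must touch exactly one non-boundary metabolite: ",
           paste(ex$id[nb != 1L], collapse = ", "), call. = FALSE)
    }
  }
  bad_cap <- setdiff(names(model$sur_caps), rxns$id)
  if (length(bad_cap)) {
    stop("sur_caps name unknown exchanges: ", paste(bad_cap, collapse = ", "),
         call. = FALSE)
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites),
      " (", sum(x$metabolites$boundary), " boundary)\n", sep = "")
  cat("  reactions:   ", nrow(x$reactions),
      " (", sum(x$reactions$is_exchange), " exchanges, ",
      sum(x$reactions$thermo_exempt), " thermo-exempt)\n", sep = "")
  cat("  objective:   ", x$objective_id,
      "  GAM = ", x$gam, "  NGAM = ", x$ngam, "\n", sep = "")
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' @param model A `metabolic_model`.
#' @return A sparse `dgCMatrix` (metabolites x reactions), including boundary
#'   species (callers drop the rows they do not balance).
#' @export
stoich_matrix <- function(model) {
  mets <- model$metabolites$id
  rxns <- model$reactions$id
  trip <- purrr::imap_dfr(model$reactions$stoich, function(s, j) {
    tibble::tibble(i = match(names(s), mets), j = j, x = unname(s))
  })
  Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                       dims = c(length(mets), length(rxns)),
                       dimnames = list(mets, rxns))
}

# parse "C4H4O4" / "CoaC21..." style formulas into a named count vector;
# element tokens are an uppercase letter plus lowercase tail.
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(NULL)
  m <- gregexpr("([A-Z][a-z]*)([0-9]*\\.?[0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]*)([0-9]*\\.?[0-9]*)", formula))[[1]]
  if (!length(parts) || sum(nchar(parts)) != nchar(formula)) {
    stop("cannot parse formula '", formula, "'", call. = FALSE)
  }
  el <- sub("^([A-Z][a-z]*).*$", "\\1", parts)
  ct <- sub("^[A-Z][a-z]*", "", parts)
  ct <- ifelse(ct == "", 1, as.numeric(ct))
  tapply(ct, el, sum)
}

#' Check elemental balance of internal reactions
#'
#' For every non-exchange reaction whose participants all carry formulas,
#' reports the net atom count per element. An empty report (no rows with
#' nonzero delta) means the checked reactions are balanced. Reactions with
#' any missing formula are listed as unchecked.
#'
#' @param model A `metabolic_model`.
#' @return A list of class `balance_report`: `$deltas` (tibble
#'   reaction/element/delta for imbalanced reactions), `$unchecked`
#'   (character vector of reaction ids), `$checked` (ids checked).
#' @export
check_elemental_balance <- function(model) {
  mets <- model$metabolites
  has_formula <- !is.na(mets$formula) & nzchar(mets$formula)
  if (!any(has_formula)) {
    stop("no metabolite carries a formula; nothing to check", call. = FALSE)
  }
  atoms <- stats::setNames(purrr::map(mets$formula, function(f) {
    if (is.na(f) || !nzchar(f)) NULL else parse_formula(f)
  }), mets$id)

  internal <- model$reactions[!model$reactions$is_exchange, ]
  # biomass/maintenance-style drains on pseudo-species are skipped like
  # exchanges: they are definitionally unbalanced
  res <- purrr::map(seq_len(nrow(internal)), function(k) {
    s <- internal$stoich[[k]]
    a <- atoms[names(s)]
    if (any(purrr::map_lgl(a, is.null))) return("unchecked")
    tot <- list()
    for (j in seq_along(s)) {
      for (el in names(a[[j]])) {
        tot[[el]] <- (tot[[el]] %||% 0) + s[[j]] * a[[j]][[el]]
      }
    }
    tot <- unlist(tot)
    tot <- tot[abs(tot) > 1e-9]
    if (!length(tot)) return("balanced")
    tibble::tibble(reaction = internal$id[k], element = names(tot),
                   delta = unname(tot))
  })
  unchecked <- internal$id[purrr::map_lgl(res, identical, "unchecked")]
  checked <- setdiff(internal$id, unchecked)
  deltas <- dplyr::bind_rows(purrr::keep(res, is.data.frame))
  structure(list(deltas = deltas, unchecked = unchecked, checked = checked),
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat("<balance_report> ", length(x$checked), " reactions checked, ",
      length(x$unchecked), " unchecked\n", sep = "")
  if (nrow(x$deltas) == 0) {
    cat("  all checked reactions balanced\n")
  } else {
    print(x$deltas)
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.balance_report <- function(x, ...) x$deltas
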