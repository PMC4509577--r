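# Tabular model dialect: four TSV tables under one directory.
#
#   metabolites.tsv  id name compartment formula charge conc_lb conc_ub
#                    fixed_conc boundary ion
#   reactions.tsv    id name stoich lb ub is_exchange parsimony_weight
#                    (stoich is a compact JSON map metabolite -> coefficient,
#                     serialized at full precision for bit-exact round trips)
#   thermo.tsv       reaction_id drg0_est drg0_se ci_level exempt
#   model.tsv        key value   (scalars and JSON-encoded tables:
#                    sur_caps, couplings, uptake_ratios)

# JSON cells must survive verbatim: write without quoting and read with
# quoting disabled (the dialect guarantees no embedded tabs or newlines)
write_tsv_plain <- function(x, file) {
  # doubles at 17 significant digits round-trip bit-exactly
  x <- dplyr::mutate(x, dplyr::across(
    dplyr::where(is.double),
    function(v) ifelse(is.na(v), NA_character_, sprintf("%.17g", v))))
  readr::write_delim(x, file, delim = "\t", quote = "none", escape = "none")
}

#' Write a model in the tabular dialect
#'
#' @param model A `metabolic_model`.
#' @param path Directory to create/overwrite the four TSV files in.
#' @return `path`, invisibly.
#' @export
write_model_tsv <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_tsv_plain(model$metabolites, file.path(path, "metabolites.tsv"))
  rx <- model$reactions
  rx_out <- tibble::tibble(
    id = rx$id, name = rx$name,
    stoich = purrr::map_chr(rx$stoich, function(s) {
      as.character(jsonlite::toJSON(as.list(s), auto_unbox = TRUE,
                                    digits = NA))
    }),
    lb = rx$lb, ub = rx$ub, is_exchange = rx$is_exchange,
    parsimony_weight = rx$parsimony_weight
  )
  write_tsv_plain(rx_out, file.path(path, "reactions.tsv"))
  write_tsv_plain(
    tibble::tibble(reaction_id = rx$id, drg0_est = rx$drg0_est,
                   drg0_se = rx$drg0_se, ci_level = rx$ci_level,
                   exempt = rx$thermo_exempt),
    file.path(path, "thermo.tsv"))
  kv <- tibble::tibble(
    key = c("id", "objective_id", "atpm_id", "gam", "ngam", "growth_id",
            "sur_caps", "couplings", "uptake_ratios"),
    value = c(model$id, model$objective_id, model$atpm_id,
              as.character(jsonlite::toJSON(model$gam, digits = NA)),
              as.character(jsonlite::toJSON(model$ngam, digits = NA)),
              model$growth_id %||% NA_character_,
              as.character(jsonlite::toJSON(as.list(model$sur_caps),
                                            auto_unbox = TRUE, digits = NA)),
              as.character(jsonlite::toJSON(model$couplings, digits = NA)),
              as.character(jsonlite::toJSON(model$uptake_ratios,
                                            digits = NA)))
  )
  write_tsv_plain(kv, file.path(path, "model.tsv"))
  invisible(path)
}

#' Read a model from the tabular dialect or SBML
#'
#' @param path For `format = "tabular"`, the directory written by
#'   [write_model_tsv()]; for `format = "sbml"`, an SBML Level 3 file.
#' @param format `"tabular"` or `"sbml"`.
#' @return A validated `metabolic_model`. Reactions without thermodynamic
#'   entries are thermo-exempt, not errors.
#' @export
load_model <- function(path, format = c("tabular", "sbml")) {
  format <- match.arg(format)
  if (format == "sbml") return(read_model_sbml(path))
  read_model_tsv(path)
}

#' @rdname load_model
#' @export
read_model_tsv <- function(path) {
  need <- file.path(path, c("metabolites.tsv", "reactions.tsv",
                            "thermo.tsv", "model.tsv"))
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    stop("not a tabular model directory; missing: ",
         paste(basename(missing), collapse = ", "), call. = FALSE)
  }
  # columns are read as text and converted with base R parsers, which are
  # correctly rounded (bit-exact round trip of %.17g output)
  read_plain <- function(file) {
    readr::read_tsv(file, show_col_types = FALSE, quote = "",
                    col_types = readr::cols(.default = "c"))
  }
  num <- function(x) as.numeric(x)
  lgl <- function(x) as.logical(x)
  mets <- read_plain(need[1]) |>
    dplyr::mutate(charge = as.integer(.data$charge),
                  conc_lb = num(.data$conc_lb), conc_ub = num(.data$conc_ub),
                  fixed_conc = lgl(.data$fixed_conc),
                  boundary = lgl(.data$boundary), ion = lgl(.data$ion))
  rx_in <- read_plain(need[2]) |>
    dplyr::mutate(lb = num(.data$lb), ub = num(.data$ub),
                  is_exchange = lgl(.data$is_exchange),
                  parsimony_weight = num(.data$parsimony_weight))
  th <- read_plain(need[3]) |>
    dplyr::mutate(drg0_est = num(.data$drg0_est),
                  drg0_se = num(.data$drg0_se),
                  ci_level = num(.data$ci_level),
                  exempt = lgl(.data$exempt))
  kv <- read_plain(need[4])
  get_kv <- function(k) kv$value[match(k, kv$key)]

  stoich <- purrr::map(seq_len(nrow(rx_in)), function(k) {
    s <- tryCatch(
      jsonlite::fromJSON(rx_in$stoich[k]),
      error = function(e) stop("reactions.tsv: cannot parse stoich of '",
                               rx_in$id[k], "': ", conditionMessage(e),
                               call. = FALSE))
    v <- unlist(s)
    stats::setNames(as.numeric(v), names(v))
  })
  th_idx <- match(rx_in$id, th$reaction_id)
  rxns <- dplyr::bind_rows(purrr::map(seq_len(nrow(rx_in)), function(k) {
    ti <- th_idx[k]
    exempt <- is.na(ti) || isTRUE(th$exempt[ti]) || is.na(th$drg0_est[ti])
    reaction(rx_in$id[k], stoich[[k]], lb = rx_in$lb[k], ub = rx_in$ub[k],
             name = rx_in$name[k],
             drg0_est = if (exempt) NA_real_ else th$drg0_est[ti],
             drg0_se = if (exempt) NA_real_ else th$drg0_se[ti],
             ci_level = if (exempt || is.na(th$ci_level[ti])) 0.95
                        else th$ci_level[ti],
             is_exchange = rx_in$is_exchange[k],
             parsimony_weight = rx_in$parsimony_weight[k])
  }))
  from_json_tbl <- function(txt, cols) {
    x <- jsonlite::fromJSON(txt)
    if (length(x) == 0 || (is.data.frame(x) && nrow(x) == 0)) return(NULL)
    tibble::as_tibble(x)
  }
  sur <- jsonlite::fromJSON(get_kv("sur_caps"))
  mdl <- metabolic_model(
    mets, rxns,
    objective_id = get_kv("objective_id"),
    atpm_id = get_kv("atpm_id"),
    gam = as.numeric(jsonlite::fromJSON(get_kv("gam"))),
    ngam = as.numeric(jsonlite::fromJSON(get_kv("ngam"))),
    sur_caps = if (length(sur)) unlist(sur) else NULL,
    couplings = from_json_tbl(get_kv("couplings")),
    uptake_ratios = from_json_tbl(get_kv("uptake_ratios")),
    id = get_kv("id")
  )
  g <- get_kv("growth_id")
  if (!is.na(g)) mdl$growth_id <- g
  mdl
}

#' Write a balance report as TSV
#'
#' @param report A [check_elemental_balance()] result.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_balance_tsv <- function(report, file) {
  stopifnot(inherits(report, "balance_report"))
  readr::write_tsv(report$deltas, file)
  invisible(file)
}
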