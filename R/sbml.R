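# Minimal SBML Level 3 (with the fbc flux-bounds convention) writer and
# reader built on xml2. The writer serializes ids, names, compartments,
# formulas, boundary flags, stoichiometry and flux bounds — the fields the
# exchange format is contractually required to preserve. Thermodynamic
# fields and concentration bounds travel in the tabular dialect
# (write_model_tsv); SBML read of external genome-scale models yields
# thermo-exempt reactions unless a thermo table is merged afterwards.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Write a model as SBML Level 3
#'
#' @param model A `metabolic_model`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_model_sbml <- function(model, file) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) format(x, digits = 17, scientific = TRUE)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" ',
                   'fbc:required="false">'), SBML_NS, FBC_NS),
    sprintf('  <model id="%s" fbc:strict="false">', esc(model$id))
  )
  comps <- unique(model$metabolites$compartment)
  lines <- c(lines, "    <listOfCompartments>",
             sprintf('      <compartment id="%s" constant="true"/>', comps),
             "    </listOfCompartments>", "    <listOfSpecies>")
  m <- model$metabolites
  for (k in seq_len(nrow(m))) {
    attrs <- sprintf(
      paste0('id="%s" name="%s" compartment="%s" boundaryCondition="%s" ',
             'hasOnlySubstanceUnits="false" constant="false"'),
      esc(m$id[k]), esc(m$name[k]), m$compartment[k],
      if (m$boundary[k]) "true" else "false")
    if (!is.na(m$formula[k])) {
      attrs <- paste0(attrs, sprintf(' fbc:chemicalFormula="%s"',
                                     esc(m$formula[k])))
    }
    if (!is.na(m$charge[k])) {
      attrs <- paste0(attrs, sprintf(' fbc:charge="%d"', m$charge[k]))
    }
    lines <- c(lines, paste0("      <species ", attrs, "/>"))
  }
  lines <- c(lines, "    </listOfSpecies>", "    <listOfParameters>")
  r <- model$reactions
  for (k in seq_len(nrow(r))) {
    lines <- c(lines,
      sprintf('      <parameter id="lb_%s" value="%s" constant="true"/>',
              esc(r$id[k]), num(r$lb[k])),
      sprintf('      <parameter id="ub_%s" value="%s" constant="true"/>',
              esc(r$id[k]), num(r$ub[k])))
  }
  lines <- c(lines, "    </listOfParameters>", "    <listOfReactions>")
  for (k in seq_len(nrow(r))) {
    s <- r$stoich[[k]]
    reac <- s[s < 0]; prod <- s[s > 0]
    lines <- c(lines, sprintf(
      paste0('      <reaction id="%s" name="%s" reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="lb_%s" fbc:upperFluxBound="ub_%s">'),
      esc(r$id[k]), esc(r$name[k]), if (r$lb[k] < 0) "true" else "false",
      esc(r$id[k]), esc(r$id[k])))
    if (length(reac)) {
      lines <- c(lines, "        <listOfReactants>",
        sprintf(paste0('          <speciesReference species="%s" ',
                       'stoichiometry="%s" constant="true"/>'),
                esc(names(reac)), num(-unname(reac))),
        "        </listOfReactants>")
    }
    if (length(prod)) {
      lines <- c(lines, "        <listOfProducts>",
        sprintf(paste0('          <speciesReference species="%s" ',
                       'stoichiometry="%s" constant="true"/>'),
                esc(names(prod)), num(unname(prod))),
        "        </listOfProducts>")
    }
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>", "  </model>", "</sbml>")
  writeLines(lines, file)
  invisible(file)
}

#' Read an SBML Level 3 model
#'
#' Understands the fbc flux-bound convention (parameter references) with a
#' fallback to `reversible` flags and default bounds. All reactions are
#' thermo-exempt on read; merge a thermo table afterwards if available.
#' Exchange reactions are recognised as single-species boundary drains or
#' ids starting with `EX_`/`R_EX_`.
#'
#' @param file SBML path.
#' @param default_bound Magnitude used when no explicit bound is present.
#' @return A validated `metabolic_model`.
#' @export
read_model_sbml <- function(file, default_bound = 1000) {
  if (!file.exists(file)) stop("no such file: ", file, call. = FALSE)
  doc <- tryCatch(xml2::read_xml(file), error = function(e) {
    stop("cannot parse SBML '", file, "': ", conditionMessage(e),
         call. = FALSE)
  })
  xml2::xml_ns_strip(doc)
  mdl_node <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mdl_node, "xml_missing")) {
    stop("no <model> element in '", file, "'", call. = FALSE)
  }
  attr_or <- function(node, attr, default = NA_character_) {
    v <- xml2::xml_attr(node, attr)
    ifelse(is.na(v), default, v)
  }
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  mets <- dplyr::bind_rows(purrr::map(sp, function(n) {
    comp <- attr_or(n, "compartment", "extracellular")
    if (!comp %in% c("cytosol_A", "cytosol_B", "extracellular")) {
      comp <- "cytosol_A" # external GEM compartments mapped to one cytosol
    }
    metabolite(
      xml2::xml_attr(n, "id"),
      name = attr_or(n, "name", xml2::xml_attr(n, "id")),
      compartment = comp,
      formula = attr_or(n, "chemicalFormula"),
      charge = suppressWarnings(as.integer(attr_or(n, "charge"))),
      boundary = identical(attr_or(n, "boundaryCondition", "false"), "true")
    )
  }))
  pars <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                          xml2::xml_attr(pars, "id"))
  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rxns <- dplyr::bind_rows(purrr::map(rx, function(n) {
    id <- xml2::xml_attr(n, "id")
    get_side <- function(xpath, sign) {
      refs <- xml2::xml_find_all(n, xpath)
      if (!length(refs)) return(numeric(0))
      stats::setNames(
        sign * as.numeric(xml2::xml_attr(refs, "stoichiometry")),
        xml2::xml_attr(refs, "species"))
    }
    s <- c(get_side("./listOfReactants/speciesReference", -1),
           get_side("./listOfProducts/speciesReference", 1))
    if (anyNA(s)) {
      stop("reaction '", id, "': missing stoichiometry attribute",
           call. = FALSE)
    }
    if (anyDuplicated(names(s))) { # species on both sides: net coefficient
      s <- tapply(s, names(s), sum)
      s <- stats::setNames(as.numeric(s), names(s))
    }
    lb_ref <- attr_or(n, "lowerFluxBound")
    ub_ref <- attr_or(n, "upperFluxBound")
    rev <- identical(attr_or(n, "reversible", "true"), "true")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(pval)) pval[[lb_ref]]
          else if (rev) -default_bound else 0
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(pval)) pval[[ub_ref]]
          else default_bound
    non_bound <- names(s)[!mets$boundary[match(names(s), mets$id)]]
    is_ex <- grepl("^(R_)?EX_", id) ||
      (length(s) >= 1 && length(non_bound) == 1 && length(s) == 1)
    reaction(id, s, lb = lb, ub = ub,
             name = attr_or(n, "name", id), is_exchange = is_ex,
             parsimony_weight = if (is_ex) 0 else 1)
  }))
  obj <- if (nrow(rxns)) rxns$id[1] else NA_character_
  metabolic_model(mets, rxns, objective_id = obj,
                  id = attr_or(mdl_node, "id", "sbml_model"))
}
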