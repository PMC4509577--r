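#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.tmfa_solution <- function(x, ...) {
  cat("<tmfa_solution> ", x$model_id, "\n", sep = "")
  cat("  status:    ", x$status, "\n", sep = "")
  cat("  objective: ", x$objective, " (", x$sense %||% "max", ") = ",
      format(x$objective_value, digits = 6), "\n", sep = "")
  if (!is.null(x$total_flux)) {
    cat("  total weighted flux: ", format(x$total_flux, digits = 6), "\n",
        sep = "")
  }
  if (!is.null(x$fluxes)) {
    active <- sum(abs(x$fluxes$flux) > 1e-6)
    cat("  active reactions: ", active, "/", nrow(x$fluxes), "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a TMFA solution into a long tibble
#'
#' One row per reaction: flux, transformed Gibbs energy (NA for exempt
#' reactions), and CI slack used.
#'
#' @param x A `tmfa_solution`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.tmfa_solution <- function(x, ...) {
  if (is.null(x$fluxes)) {
    return(tibble::tibble(reaction = character(), flux = numeric()))
  }
  out <- x$fluxes
  if (!is.null(x$energies)) {
    out <- dplyr::left_join(out, x$energies, by = "reaction")
  }
  out
}

#' One-row summary of a TMFA solution
#'
#' @param x A `tmfa_solution`.
#' @param ... Unused.
#' @return A one-row tibble: status, objective, value, active reaction
#'   count, weighted total flux (if parsimonious).
#' @exportS3Method generics::glance
glance.tmfa_solution <- function(x, ...) {
  tibble::tibble(
    status = x$status,
    objective = x$objective,
    objective_value = x$objective_value,
    n_active = if (is.null(x$fluxes)) NA_integer_ else
      sum(abs(x$fluxes$flux) > 1e-6),
    total_flux = x$total_flux %||% NA_real_
  )
}

#' Concentration table of a TMFA solution
#'
#' @param x A `tmfa_solution`.
#' @return Tibble of metabolite, ln-concentration and molar concentration.
#' @export
concentrations <- function(x) {
  stopifnot(inherits(x, "tmfa_solution"))
  x$ln_conc %||% tibble::tibble(metabolite = character(),
                                ln_conc = numeric(), conc = numeric())
}

#' Plot the active fluxes of a TMFA solution
#'
#' Horizontal bar chart of reactions carrying flux above a threshold,
#' coloured by the sign of their transformed Gibbs energy (grey for
#' thermodynamically exempt reactions).
#'
#' @param object A `tmfa_solution`.
#' @param threshold Minimum |flux| shown.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tmfa_solution <- function(object, threshold = 1e-6, ...) {
  stopifnot(object$status == "optimal")
  dat <- tidy(object)
  dat <- dplyr::filter(dat, abs(.data$flux) > threshold)
  if ("exempt" %in% names(dat)) {
    dat$thermo <- dplyr::case_when(
      dat$exempt ~ "exempt",
      dat$drg_prime < 0 ~ "DrG' < 0",
      TRUE ~ "DrG' > 0")
  } else {
    dat$thermo <- "n/a"
  }
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$flux, y = stats::reorder(.data$reaction, abs(.data$flux)),
    fill = .data$thermo)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "flux (mmol/gDW/day)", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
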