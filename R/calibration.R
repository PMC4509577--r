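#' Fit maintenance parameters from chemostat energy-balance data
#'
#' Ordinary least squares on the linear chemostat energy balance
#' q_ATP = GAM * mu + NGAM: the slope is the growth-associated maintenance
#' (mmol ATP per gDW of biomass formed) and the intercept the non-growth
#' maintenance (mmol ATP/gDW/day spent keeping cells alive).
#'
#' @param points Data frame with columns `mu` (growth rate, 1/day) and
#'   `q_atp` (specific ATP demand, mmol/gDW/day); at least two distinct
#'   `mu` values.
#' @return An object of class `maintenance_fit`: `gam`, `ngam`,
#'   `clipped` (TRUE if a negative intercept was clipped to zero), and the
#'   underlying `lm` fit in `$fit`.
#' @export
fit_maintenance <- function(points) {
  points <- tibble::as_tibble(points)
  stopifnot(all(c("mu", "q_atp") %in% names(points)))
  if (length(unique(points$mu)) < 2) {
    stop("maintenance parameters are unidentifiable from a single growth ",
         "rate; provide at least two distinct mu values", call. = FALSE)
  }
  fit <- stats::lm(q_atp ~ mu, data = points)
  gam <- unname(stats::coef(fit)[["mu"]])
  ngam <- unname(stats::coef(fit)[["(Intercept)"]])
  clipped <- FALSE
  if (ngam < 0) {
    warning("fitted NGAM was negative (", signif(ngam, 4),
            "); clipping to 0", call. = FALSE)
    ngam <- 0
    clipped <- TRUE
  }
  structure(list(gam = gam, ngam = ngam, clipped = clipped, fit = fit,
                 n = nrow(points)),
            class = "maintenance_fit")
}

#' @export
print.maintenance_fit <- function(x, ...) {
  cat("<maintenance_fit>  GAM = ", signif(x$gam, 6),
      " mmol ATP/gDW,  NGAM = ", signif(x$ngam, 6),
      " mmol ATP/gDW/day  (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.maintenance_fit <- function(x, ...) {
  tibble::tibble(term = c("gam", "ngam"),
                 estimate = c(x$gam, x$ngam),
                 std.error = tryCatch(
                   unname(sqrt(diag(stats::vcov(x$fit))))[c(2, 1)],
                   error = function(e) c(NA_real_, NA_real_)))
}

#' @exportS3Method generics::glance
glance.maintenance_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(gam = x$gam, ngam = x$ngam, clipped = x$clipped,
                 r.squared = s$r.squared, sigma = s$sigma, n = x$n)
}

#' Fit a substrate uptake cap to an observed growth rate
#'
#' Finds, by bisection, the smallest uptake cap on one exchange at which
#' the TMFA-maximal growth rate matches an observed growth rate. Growth is
#' monotone non-decreasing in the cap (asserted during the search).
#'
#' @param model A `metabolic_model` with maintenance parameters set and a
#'   growth reaction recorded in `$growth_id`.
#' @param exchange Substrate exchange id whose cap is fitted.
#' @param mu Observed growth rate, 1/day.
#' @param params A [thermo_params()].
#' @param tol Tolerance on the achieved growth rate, 1/day.
#' @param cap_hi Upper end of the cap search interval, mmol/gDW/day.
#' @param options Backend options.
#' @return A list: `sur` (fitted cap), `mu_achieved`, `iterations`.
#' @export
fit_sur <- function(model, exchange, mu, params = thermo_params(),
                    tol = 1e-3, cap_hi = 1000, options = list()) {
  if (is.null(model$growth_id) || is.na(model$growth_id)) {
    stop("model must declare a growth reaction ($growth_id)", call. = FALSE)
  }
  i <- match(exchange, model$reactions$id)
  if (is.na(i)) stop("unknown exchange '", exchange, "'", call. = FALSE)
  mu_at <- function(cap) {
    m <- model
    m$reactions$lb[i] <- -cap
    s <- solve_tmfa(m, params, objective = model$growth_id, sense = "max",
                    options = options)
    if (s$status != "optimal") return(NA_real_)
    s$objective_value
  }
  mu_max <- mu_at(cap_hi)
  if (is.na(mu_max) || mu_max < mu - tol) {
    stop("observed growth rate ", mu, " is unreachable at any cap; ",
         "asymptotic maximum is ", signif(mu_max, 6), call. = FALSE)
  }
  lo <- 0; hi <- cap_hi; it <- 0; mu_lo <- mu_at(0)
  if (!is.na(mu_lo) && mu_lo >= mu - tol) {
    return(list(sur = 0, mu_achieved = mu_lo, iterations = 1L))
  }
  mu_mid <- NA_real_
  cap_tol <- max(cap_hi * 1e-4, 1e-6)
  while (hi - lo > cap_tol) {
    mid <- (lo + hi) / 2
    mu_mid <- mu_at(mid)
    it <- it + 1
    if (!is.na(mu_mid) && mu_mid >= mu - tol) hi <- mid else lo <- mid
    if (it > 40) break
  }
  list(sur = hi, mu_achieved = mu_at(hi), iterations = it)
}

#' Shipped uptake and maintenance parameters of the curated cores
#'
#' The calibration data behind these constants are chemostat growth
#' measurements; the values are stored as verified defaults of the core
#' builders and returned here for reference.
#'
#' @return A tibble with columns `species`, `parameter`, `value`, `units`.
#' @export
core_parameters <- function() {
  tibble::tribble(
    ~species, ~parameter, ~value, ~units,
    "sfu", "gam", 22.8, "mmol ATP/gDW",
    "sfu", "ngam", 3.36, "mmol ATP/gDW/day",
    "sfu", "sur_propionate", 37.7, "mmol/gDW/day",
    "sfu", "sur_fumarate", 27.6, "mmol/gDW/day",
    "mhu", "gam", 47, "mmol ATP/gDW",
    "mhu", "ngam", 0.6, "mmol ATP/gDW/day",
    "mhu", "sur_co2", 75.7, "mmol/gDW/day",
    "mhu", "sur_formate", 955, "mmol/gDW/day"
  )
}
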