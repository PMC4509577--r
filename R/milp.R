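# TMFA mixed-integer formulation.
#
# Every reaction is split into two non-negative directed halves, each with
# its own binary use indicator z. Using a direction (z = 1) activates the
# constraint that the reaction's transformed Gibbs energy opposes it:
#   forward:  DrG' <= -eps + K (1 - z_fwd)
#   reverse: -DrG' <= -eps + K (1 - z_rev)
# with DrG' = DrG'0 + delta + RT * sum_j s_ij ln(c_j) + ion terms, the slack
# delta bounded by the confidence half-width of the DrG'0 estimate, and
# ln-concentration variables bounded by the metabolite concentration bounds.
# Thermo-exempt reactions keep their binaries (z_fwd + z_rev <= 1) but carry
# no energy constraint.

new_row_acc <- function() {
  env <- new.env(parent = emptyenv())
  env$i <- list(); env$j <- list(); env$x <- list()
  env$cl <- numeric(); env$cu <- numeric(); env$label <- character()
  env$n <- 0L
  env
}

add_row <- function(acc, j, x, cl, cu, label) {
  acc$n <- acc$n + 1L
  acc$i[[acc$n]] <- rep.int(acc$n, length(j))
  acc$j[[acc$n]] <- j
  acc$x[[acc$n]] <- x
  acc$cl[acc$n] <- cl
  acc$cu[acc$n] <- cu
  acc$label[acc$n] <- label
  invisible(acc)
}

# Build the MILP skeleton for one model. `balance_skip` lists metabolite ids
# excluded from unit mass balance (used by the coculture reactor, which
# replaces extracellular unit balances with biomass-weighted community rows).
build_tmfa_problem <- function(model, params = thermo_params(),
                               thermo = TRUE, binaries = TRUE,
                               balance_skip = character()) {
  rxns <- model$reactions
  mets <- model$metabolites
  n_r <- nrow(rxns)

  lbf <- pmax(rxns$lb, 0); ubf <- pmax(rxns$ub, 0)
  lbr <- pmax(-rxns$ub, 0); ubr <- pmax(-rxns$lb, 0)
  if (binaries) { # binary big-M rows need finite caps
    ubf <- pmin(ubf, params$flux_cap)
    ubr <- pmin(ubr, params$flux_cap)
  }

  vars <- tibble::tibble(kind = character(), id = character(),
                         lb = numeric(), ub = numeric(), int = integer())
  push_vars <- function(kind, id, lb, ub, int = 0L) {
    tibble::tibble(kind = kind, id = id, lb = lb, ub = ub, int = int)
  }
  vars <- dplyr::bind_rows(
    push_vars("vf", rxns$id, lbf, ubf),
    push_vars("vr", rxns$id, lbr, ubr)
  )

  use_zf <- use_zr <- rep(FALSE, n_r)
  if (binaries) {
    use_zf <- ubf > 0
    use_zr <- ubr > 0
    vars <- dplyr::bind_rows(
      vars,
      push_vars("zf", rxns$id[use_zf], 0, 1, 1L),
      push_vars("zr", rxns$id[use_zr], 0, 1, 1L)
    )
  }

  cv <- conc_var_table(model, params)
  nonexempt <- !rxns$thermo_exempt
  hw <- rep(0, n_r)
  hw[nonexempt] <- ci_halfwidth(rxns$drg0_se[nonexempt],
                                rxns$ci_level[nonexempt], params)
  use_delta <- rep(FALSE, n_r)
  if (thermo) {
    vars <- dplyr::bind_rows(vars, push_vars("conc", cv$id, cv$ln_lb, cv$ln_ub))
    use_delta <- nonexempt & hw > 0
    vars <- dplyr::bind_rows(
      vars, push_vars("delta", rxns$id[use_delta], -hw[use_delta],
                      hw[use_delta]))
  }
  vars$index <- seq_len(nrow(vars))

  vidx <- function(kind, id) {
    m <- vars$index[vars$kind == kind][match(id, vars$id[vars$kind == kind])]
    m
  }
  i_vf <- stats::setNames(vidx("vf", rxns$id), rxns$id)
  i_vr <- stats::setNames(vidx("vr", rxns$id), rxns$id)
  i_zf <- stats::setNames(rep(NA_integer_, n_r), rxns$id)
  i_zr <- stats::setNames(rep(NA_integer_, n_r), rxns$id)
  if (binaries) {
    i_zf[rxns$id[use_zf]] <- vidx("zf", rxns$id[use_zf])
    i_zr[rxns$id[use_zr]] <- vidx("zr", rxns$id[use_zr])
  }
  i_conc <- stats::setNames(integer(0), character(0))
  i_delta <- stats::setNames(rep(NA_integer_, n_r), rxns$id)
  if (thermo) {
    i_conc <- stats::setNames(vidx("conc", cv$id), cv$id)
    i_delta[rxns$id[use_delta]] <- vidx("delta", rxns$id[use_delta])
  }

  ion_n <- ion_translocation(model)
  const_energy <- ifelse(nonexempt,
                         rxns$drg0_est + ion_n * params$ion_cost, NA_real_)
  K <- params$K_bigM %||% if (thermo) compute_big_m(model, params) else 0
  RT <- params$R * params$T

  acc <- new_row_acc()

  # mass balance
  balance_ids <- mets$id[!mets$boundary & !(mets$id %in% balance_skip)]
  S <- stoich_matrix(model)
  for (met in balance_ids) {
    row <- S[met, ]
    nz <- which(row != 0)
    if (!length(nz)) next
    rids <- colnames(S)[nz]
    add_row(acc,
            j = c(i_vf[rids], i_vr[rids]),
            x = c(row[nz], -row[nz]),
            cl = 0, cu = 0, label = paste0("balance:", met))
  }

  if (binaries) {
    for (k in seq_len(n_r)) {
      r <- rxns$id[k]
      if (use_zf[k]) {
        add_row(acc, j = c(i_vf[r], i_zf[r]), x = c(1, -ubf[k]),
                cl = -Inf, cu = 0, label = paste0("cap_fwd:", r))
      }
      if (use_zr[k]) {
        add_row(acc, j = c(i_vr[r], i_zr[r]), x = c(1, -ubr[k]),
                cl = -Inf, cu = 0, label = paste0("cap_rev:", r))
      }
      if (use_zf[k] && use_zr[k]) {
        add_row(acc, j = c(i_zf[r], i_zr[r]), x = c(1, 1),
                cl = -Inf, cu = 1, label = paste0("one_dir:", r))
      }
    }
  }

  if (thermo && binaries) {
    for (k in which(nonexempt)) {
      r <- rxns$id[k]
      s <- rxns$stoich[[k]]
      s_cv <- s[names(s) %in% names(i_conc)]
      jj <- unname(i_conc[names(s_cv)])
      for (dir in c("fwd", "rev")) {
        zi <- if (dir == "fwd") i_zf[r] else i_zr[r]
        if (is.na(zi)) next
        sgn <- if (dir == "fwd") 1 else -1
        j <- c(jj, if (use_delta[k]) i_delta[r], zi)
        x <- c(sgn * RT * unname(s_cv), if (use_delta[k]) sgn, K)
        add_row(acc, j = j, x = x, cl = -Inf,
                cu = K - params$eps - sgn * const_energy[k],
                label = paste0("thermo_", dir, ":", r))
      }
    }
  }

  # flux couplings v_a = ratio * v_b (also used for uptake ratios, which
  # reduce to the same net-flux identity)
  pairs <- dplyr::bind_rows(
    model$couplings,
    if (nrow(model$uptake_ratios)) {
      tibble::tibble(rxn_a = model$uptake_ratios$ex_a,
                     rxn_b = model$uptake_ratios$ex_b,
                     ratio = model$uptake_ratios$ratio)
    }
  )
  if (!is.null(pairs) && nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- pairs$rxn_a[k]; b <- pairs$rxn_b[k]; rho <- pairs$ratio[k]
      add_row(acc,
              j = c(i_vf[a], i_vr[a], i_vf[b], i_vr[b]),
              x = c(1, -1, -rho, rho),
              cl = 0, cu = 0, label = paste0("coupling:", a, "=", rho, "*", b))
    }
  }

  structure(
    list(model = model, params = params, thermo = thermo, binaries = binaries,
         vars = vars, acc = acc,
         i_vf = i_vf, i_vr = i_vr, i_zf = i_zf, i_zr = i_zr,
         i_conc = i_conc, i_delta = i_delta,
         const_energy = const_energy, K = K, RT = RT,
         balance_skip = balance_skip),
    class = "tmfa_problem"
  )
}

# extra row added post-hoc (objective floors, community balances, ...)
problem_add_row <- function(prob, j, x, cl, cu, label) {
  add_row(prob$acc, j = j, x = x, cl = cl, cu = cu, label = label)
  prob
}

problem_payload <- function(prob) {
  acc <- prob$acc
  list(
    n_var = nrow(prob$vars),
    lb = prob$vars$lb, ub = prob$vars$ub,
    integrality = prob$vars$int,
    constraints = list(
      nrow = acc$n,
      i = unlist(acc$i, use.names = FALSE) %||% integer(0),
      j = unlist(acc$j, use.names = FALSE) %||% integer(0),
      x = unlist(acc$x, use.names = FALSE) %||% numeric(0),
      cl = acc$cl, cu = acc$cu
    )
  )
}

# sparse objective over the net flux of one reaction
obj_net_flux <- function(prob, rxn_id, sense = "max") {
  list(idx = c(prob$i_vf[[rxn_id]], prob$i_vr[[rxn_id]]),
       val = c(1, -1), sense = sense)
}

# weighted total-flux (parsimony) objective over all directed halves
obj_total_flux <- function(prob, sense = "min", weights = NULL) {
  w <- weights %||% prob$model$reactions$parsimony_weight
  keep <- w != 0
  ids <- prob$model$reactions$id[keep]
  list(idx = c(prob$i_vf[ids], prob$i_vr[ids]),
       val = rep(w[keep], 2), sense = sense)
}

extract_solution <- function(prob, res, objective_label, sense) {
  if (res$status != "optimal") {
    return(structure(
      list(status = res$status, objective = objective_label,
           objective_value = NA_real_, fluxes = NULL, directions = NULL,
           ln_conc = NULL, energies = NULL, message = res$message %||% NULL,
           model_id = prob$model$id),
      class = "tmfa_solution"))
  }
  x <- res$x
  rxns <- prob$model$reactions
  flux <- x[prob$i_vf[rxns$id]] - x[prob$i_vr[rxns$id]]
  fluxes <- tibble::tibble(reaction = rxns$id, flux = flux)
  directions <- tibble::tibble(
    reaction = rxns$id,
    z_fwd = ifelse(is.na(prob$i_zf[rxns$id]), NA_real_,
                   x[prob$i_zf[rxns$id]]),
    z_rev = ifelse(is.na(prob$i_zr[rxns$id]), NA_real_,
                   x[prob$i_zr[rxns$id]])
  )
  ln_conc <- NULL
  energies <- NULL
  if (prob$thermo) {
    ln_conc <- tibble::tibble(
      metabolite = names(prob$i_conc),
      ln_conc = unname(x[prob$i_conc]),
      conc = exp(unname(x[prob$i_conc]))
    )
    lnc <- stats::setNames(ln_conc$ln_conc, ln_conc$metabolite)
    energies <- purrr::map_dfr(seq_len(nrow(rxns)), function(k) {
      if (rxns$thermo_exempt[k]) {
        return(tibble::tibble(reaction = rxns$id[k], drg_prime = NA_real_,
                              drg0_adjust = NA_real_, exempt = TRUE))
      }
      s <- rxns$stoich[[k]]
      s_cv <- s[names(s) %in% names(lnc)]
      delta <- if (!is.na(prob$i_delta[rxns$id[k]])) {
        x[prob$i_delta[rxns$id[k]]]
      } else 0
      g <- prob$const_energy[k] + delta +
        prob$RT * sum(s_cv * lnc[names(s_cv)])
      tibble::tibble(reaction = rxns$id[k], drg_prime = g,
                     drg0_adjust = delta, exempt = FALSE)
    })
  }
  structure(
    list(status = "optimal", objective = objective_label,
         objective_value = res$objective, sense = sense,
         fluxes = fluxes, directions = directions,
         ln_conc = ln_conc, energies = energies,
         model_id = prob$model$id, x = x),
    class = "tmfa_solution"
  )
}
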