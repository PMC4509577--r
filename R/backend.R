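# MILP solver backend.
#
# The package builds all matrices in R and delegates the mixed-integer solve
# to scipy.optimize.milp (HiGHS) through a small bundled Python script; any
# backend satisfying the same contract can be substituted via
# options(syntmfa.milp_backend = <function>).

the_inf <- 1e30  # sentinel for +/- infinity across the JSON boundary

find_python <- function() {
  opt <- getOption("syntmfa.python", NULL)
  if (!is.null(opt) && nzchar(opt)) return(opt)
  p <- Sys.which("python3")
  if (!nzchar(p)) p <- Sys.which("python")
  if (!nzchar(p)) {
    stop("no python interpreter found on PATH; the MILP backend requires ",
         "Python with numpy and scipy (>= 1.9)", call. = FALSE)
  }
  unname(p)
}

backend_script <- function() {
  s <- system.file("python", "milp_solve.py", package = "syntmfa")
  if (!nzchar(s)) {
    # during development (pkgload) inst/ is on the source path
    s <- system.file("inst", "python", "milp_solve.py", package = "syntmfa")
  }
  if (!nzchar(s)) stop("bundled solver script not found", call. = FALSE)
  s
}

#' Solve a mixed-integer linear program
#'
#' Low-level entry to the MILP backend. One call solves any number of
#' objectives over a shared constraint set (used to batch variability
#' analyses). Most users call [solve_tmfa()] and friends instead.
#'
#' @param prob List with elements `n_var`, `lb`, `ub` (numeric, `Inf`
#'   allowed), `integrality` (0/1), and `constraints`: a list with `nrow`
#'   and triplet vectors `i`, `j`, `x` plus row bounds `cl`, `cu`.
#' @param objectives List of objectives; each a list with 1-based sparse
#'   `idx`, `val`, and `sense` (`"max"` or `"min"`).
#' @param options List: `mip_rel_gap`, `time_limit` (seconds).
#' @return List of results, each with `status` and, when optimal,
#'   `objective` and the variable vector `x`.
#' @export
milp_solve <- function(prob, objectives, options = list()) {
  backend <- getOption("syntmfa.milp_backend", NULL)
  if (!is.null(backend)) return(backend(prob, objectives, options))

  cap <- function(v) pmax(pmin(v, the_inf), -the_inf)
  payload <- list(
    n_var = prob$n_var,
    lb = cap(prob$lb), ub = cap(prob$ub),
    integrality = as.integer(prob$integrality),
    constraints = list(
      nrow = prob$constraints$nrow,
      i = as.integer(prob$constraints$i),
      j = as.integer(prob$constraints$j),
      x = prob$constraints$x,
      cl = cap(prob$constraints$cl), cu = cap(prob$constraints$cu)
    ),
    objectives = purrr::map(objectives, function(ob) {
      list(idx = as.integer(ob$idx), val = ob$val,
           sense = ob$sense %||% "max")
    }),
    options = options
  )
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA)
  status <- suppressWarnings(
    system2(find_python(), c(shQuote(backend_script()), shQuote(fin),
                             shQuote(fout)),
            stdout = TRUE, stderr = TRUE)
  )
  if (!file.exists(fout)) {
    stop("MILP backend failed:\n", paste(status, collapse = "\n"),
         call. = FALSE)
  }
  res <- jsonlite::read_json(fout, simplifyVector = FALSE)
  purrr::map(res, function(r) {
    r <- as.list(r)
    if (!is.null(r$x)) r$x <- as.numeric(unlist(r$x))
    if (!is.null(r$objective)) r$objective <- as.numeric(r$objective)
    r$status <- as.character(r$status)
    r
  })
}
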