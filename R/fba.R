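#' Flux balance analysis
#'
#' Maximizes biomass flux subject to steady-state mass balance (`S v = 0`)
#' and flux bounds. The medium, if given, is applied first via
#' [apply_medium()]. The optimum is unique; the reported flux vector is one
#' optimal vertex and may be degenerate — use [fva()] wherever a unique
#' per-reaction answer is required.
#'
#' @param model A `pan_reactome` or `strain_model`.
#' @param med Optional [medium()]; if `NULL` the model's current bounds are
#'   used as-is.
#' @param ngam NGAM floor passed to [apply_medium()].
#' @return A list of class `fba_solution`: `objective_value` (1/h),
#'   `fluxes` (named numeric), `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`).
#' @export
fba <- function(model, med = NULL, ngam = 1) {
  if (!is.null(med)) model <- apply_medium(model, med, ngam = ngam, strict = FALSE)
  S <- stoich_matrix(model)
  r <- model$reactions
  obj <- as.numeric(r$id == model$biomass_id)
  sol <- lp_solve_fba(obj, S, r$lower_bound, r$upper_bound, maximize = TRUE)
  structure(list(objective_value = sol$objective,
                 fluxes = stats::setNames(sol$fluxes, r$id),
                 status = sol$status),
            class = "fba_solution")
}

#' @export
print.fba_solution <- function(x, ...) {
  cat("<fba_solution> status:", x$status, " objective:",
      format(x$objective_value, digits = 6), "\n")
  invisible(x)
}

#' Flux variability analysis
#'
#' For each requested reaction, minimizes and maximizes its flux subject to
#' mass balance, bounds, and biomass flux held at or above
#' `fraction_of_optimum` times the FBA optimum.
#'
#' @inheritParams fba
#' @param fraction_of_optimum Fraction of the biomass optimum to enforce, in
#'   `[0, 1]`; default 1 (ranges at the optimum).
#' @param reactions Optional character vector restricting the analysis to a
#'   subset of reaction ids.
#' @return Tibble of class `fva_result` with columns `reaction_id`, `min`,
#'   `max`; attribute `fraction_of_optimum`.
#' @export
fva <- function(model, med = NULL, fraction_of_optimum = 1, reactions = NULL,
                ngam = 1) {
  stopifnot(fraction_of_optimum >= 0, fraction_of_optimum <= 1)
  if (!is.null(med)) model <- apply_medium(model, med, ngam = ngam, strict = FALSE)
  base <- fba(model)
  if (base$status != "optimal") stop("FVA base problem is ", base$status)
  r <- model$reactions
  S <- stoich_matrix(model)
  lb <- r$lower_bound; ub <- r$upper_bound
  bio <- which(r$id == model$biomass_id)
  # small absolute slack below the target keeps the near-optimal face from
  # degenerating into a numerically empty sliver
  target <- fraction_of_optimum * base$objective_value
  lb[bio] <- max(lb[bio], target - pmax(1e-6, 1e-6 * abs(target)))
  ids <- if (is.null(reactions)) r$id else {
    stopifnot(all(reactions %in% r$id))
    reactions
  }
  res <- purrr::map_dfr(ids, function(rid) {
    j <- which(r$id == rid)
    obj <- numeric(ncol(S)); obj[j] <- 1
    lo <- lp_solve_fba(obj, S, lb, ub, maximize = FALSE)
    hi <- lp_solve_fba(obj, S, lb, ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("FVA subproblem for '", rid, "' terminated ", lo$status, "/", hi$status)
    }
    tibble::tibble(reaction_id = rid,
                   min = min(lo$objective, hi$objective),
                   max = max(lo$objective, hi$objective))
  })
  structure(res, fraction_of_optimum = fraction_of_optimum,
            class = c("fva_result", class(res)))
}
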