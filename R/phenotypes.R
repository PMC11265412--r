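#' Carbon-source growth call
#'
#' Closes glucose uptake, opens the target carbon source's exchange to the
#' stated uptake magnitude (default 1000 mmol/gDCW/h), and runs FBA. Growth
#' is reported iff the predicted growth rate is strictly above
#' `growth_threshold`; a model that lacks the carbon source's exchange
#' reaction entirely is an immediate no-growth call.
#'
#' @param model A `strain_model`.
#' @param med The base [medium()].
#' @param csource_exchange Exchange reaction id of the target carbon source.
#' @param glucose_exchange Exchange reaction id of the default carbon
#'   source that gets closed.
#' @param uptake Uptake magnitude opened for the target source.
#' @param growth_threshold Growth call threshold (1/h), strict.
#' @param ngam NGAM floor.
#' @return Logical growth call.
#' @export
carbon_source_growth <- function(model, med, csource_exchange,
                                 glucose_exchange = "EX_glc_e",
                                 uptake = 1000, growth_threshold = 0.01,
                                 ngam = 1) {
  if (!csource_exchange %in% model$reactions$id) return(FALSE)
  tab <- tibble::as_tibble(med)
  tab <- tab[tab$exchange_id != glucose_exchange, ]
  tab <- tab[tab$exchange_id != csource_exchange, ]
  tab <- dplyr::bind_rows(tab, tibble::tibble(exchange_id = csource_exchange,
                                              uptake = uptake))
  med2 <- medium(tab, name = paste0(attr(med, "name"), "+", csource_exchange))
  sol <- fba(model, med2, ngam = ngam)
  if (sol$status != "optimal") return(FALSE)
  sol$objective_value > growth_threshold
}

#' Single-omission essentiality of medium components
#'
#' For each listed medium component independently, sets its uptake to zero,
#' reruns FBA, and reports the component as essential (an auxotrophy) iff
#' the predicted growth rate falls strictly below `growth_threshold`. The
#' medium is restored between tests; each omission runs on a fresh copy of
#' the constrained model.
#'
#' @param model A `strain_model`.
#' @param med The full [medium()]; the model must grow on it (error
#'   otherwise — omission results would be undefined).
#' @param components Exchange ids to test; default all medium components.
#' @param growth_threshold Auxotrophy threshold (1/h), strict below.
#' @param ngam NGAM floor.
#' @return Tibble of class `essentiality_profile`: `component`, `growth`
#'   (1/h under omission), `verdict` (`"essential"`/`"non_essential"`);
#'   attributes `strain_id`, `growth_threshold`.
#' @export
single_omission_essentiality <- function(model, med, components = NULL,
                                         growth_threshold = 0.01, ngam = 1) {
  if (is.null(components)) components <- med$exchange_id
  stopifnot(all(components %in% med$exchange_id))
  if (!verify_functionality(model, med, growth_threshold, ngam = ngam)) {
    stop("model ", model$strain_id %||% "<template>",
         " does not grow on the full medium; omission results undefined")
  }
  res <- purrr::map_dfr(components, function(comp) {
    tab <- tibble::as_tibble(med)
    tab$uptake[tab$exchange_id == comp] <- 0
    sol <- fba(model, medium(tab), ngam = ngam)
    g <- if (sol$status == "optimal") sol$objective_value else 0
    tibble::tibble(component = comp, growth = g,
                   verdict = if (g < growth_threshold) "essential" else "non_essential")
  })
  structure(res, strain_id = model$strain_id %||% NA_character_,
            growth_threshold = growth_threshold,
            class = c("essentiality_profile", class(res)))
}

#' Fermentation (by-product secretion) profile
#'
#' Runs FBA on the medium and reports every exchange with secretion flux
#' above the tolerance as part of the fermentation profile, together with
#' FVA secretion ranges for all exchange reactions at the stated fraction of
#' the growth optimum. The FBA-based secreted set can be degenerate between
#' alternate optima; the FVA ranges are the unique answer.
#'
#' @param model A growing `strain_model` (error otherwise).
#' @param med A [medium()].
#' @param fva_fraction Fraction of optimum for the FVA ranges; default 1.
#' @param secretion_tol Positive-secretion floor (mmol/gDCW/h).
#' @param growth_threshold Growth requirement on the medium.
#' @param ngam NGAM floor.
#' @return Tibble of class `fermentation_profile`: `exchange_id`, `fba_flux`,
#'   `min`, `max`, `secreted` (FBA call), `producible` (FVA max above
#'   tolerance).
#' @export
fermentation_profile <- function(model, med, fva_fraction = 1,
                                 secretion_tol = 1e-6,
                                 growth_threshold = 0.01, ngam = 1) {
  if (!verify_functionality(model, med, growth_threshold, ngam = ngam)) {
    stop("model ", model$strain_id %||% "<template>", " does not grow on this medium")
  }
  constrained <- apply_medium(model, med, ngam = ngam, strict = FALSE)
  ex_ids <- sort(constrained$reactions$id[constrained$reactions$rtype == "exchange"])
  sol <- fba(constrained)
  ranges <- fva(constrained, fraction_of_optimum = fva_fraction, reactions = ex_ids)
  res <- tibble::tibble(
    exchange_id = ex_ids,
    fba_flux = unname(sol$fluxes[ex_ids]),
    min = ranges$min[match(ex_ids, ranges$reaction_id)],
    max = ranges$max[match(ex_ids, ranges$reaction_id)])
  res$secreted <- res$fba_flux > secretion_tol
  res$producible <- res$max > secretion_tol
  structure(res, strain_id = model$strain_id %||% NA_character_,
            fva_fraction = fva_fraction,
            class = c("fermentation_profile", class(res)))
}

#' Core-fluxome activity and growth correlation
#'
#' For a set of core reactions shared by all models, computes per-strain FVA
#' ranges at the stated fraction of each strain's optimum, flags reactions
#' active in every strain, and correlates each reaction's maximum flux with
#' the strains' growth rates (Pearson). Reactions whose maximum flux does
#' not vary across strains have an undefined correlation and are reported as
#' `NA`, not 1.
#'
#' @param models List of growing `strain_model`s (at least 3; error below —
#'   the correlation is unstable).
#' @param med A [medium()] applied to every model, or a named list of media
#'   keyed by strain id (e.g. strain-specific carbon-source uptakes, the
#'   natural way growth-rate diversity arises on a shared medium recipe).
#' @param core_reactions Reaction ids present in every model.
#' @param fva_fraction Fraction of optimum; default 1.
#' @param activity_tol Flux magnitude above which a reaction counts as
#'   active.
#' @param ngam NGAM floor.
#' @return Tibble: `reaction_id`, `active_in_all`, `r` (Pearson correlation
#'   of max flux vs growth rate, `NA` when degenerate).
#' @export
core_fluxome <- function(models, med, core_reactions, fva_fraction = 1,
                         activity_tol = 1e-6, ngam = 1) {
  if (length(models) < 3L) stop("core fluxome analysis needs at least 3 strains")
  med_for <- function(mod) {
    if (inherits(med, "panflux_medium")) med else med[[mod$strain_id]]
  }
  for (mod in models) {
    if (!all(core_reactions %in% mod$reactions$id)) {
      stop("core reaction(s) missing from model ", mod$strain_id %||% "<unnamed>")
    }
    if (is.null(med_for(mod))) stop("no medium supplied for model ",
                                    mod$strain_id %||% "<unnamed>")
  }
  growth <- vapply(models, function(mod) {
    sol <- fba(mod, med_for(mod), ngam = ngam)
    if (sol$status != "optimal" || sol$objective_value <= 0) {
      stop("non-growing model ", mod$strain_id %||% "<unnamed>", " in core fluxome analysis")
    }
    sol$objective_value
  }, numeric(1))
  per_strain <- lapply(models, function(mod) {
    fva(mod, med_for(mod), fraction_of_optimum = fva_fraction,
        reactions = core_reactions, ngam = ngam)
  })
  purrr::map_dfr(core_reactions, function(rid) {
    mins <- vapply(per_strain, function(fv) fv$min[fv$reaction_id == rid], numeric(1))
    maxs <- vapply(per_strain, function(fv) fv$max[fv$reaction_id == rid], numeric(1))
    active <- all(pmax(abs(mins), abs(maxs)) > activity_tol)
    # variance floor of 1e-4: below meaningful flux variation, above the
    # FVA slack artifacts that keep a truly constant flux from being exactly
    # constant numerically
    r <- if (stats::sd(maxs) < 1e-4 || stats::sd(growth) < 1e-12) NA_real_ else
      stats::cor(maxs, growth)
    tibble::tibble(reaction_id = rid, active_in_all = active, r = r)
  })
}
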