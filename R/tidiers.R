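#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PERMANOVA result
#'
#' @param x A `permanova_result`.
#' @param ... Unused.
#' @return Tibble with one row per term (between / within / total) holding
#'   degrees of freedom, sums of squares, pseudo-F, R2 and p-value,
#'   mirroring an ANOVA-style table.
#' @export
tidy.permanova_result <- function(x, ...) {
  tibble::tibble(
    term = c("between", "within", "total"),
    df = c(x$df_between, x$df_within, x$df_between + x$df_within),
    sum_of_squares = c(x$ss_between, x$ss_within, x$ss_total),
    pseudo_F = c(x$pseudo_F, NA_real_, NA_real_),
    R2 = c(x$R2, 1 - x$R2, 1),
    p_value = c(x$p_value, NA_real_, NA_real_))
}

#' @rdname tidy.permanova_result
#' @export
glance.permanova_result <- function(x, ...) {
  tibble::tibble(pseudo_F = x$pseudo_F, R2 = x$R2, p_value = x$p_value,
                 n_permutations = x$n_permutations, exact = x$exact,
                 seed = x$seed)
}

#' Tidy a gapfill result
#'
#' @param x A `gapfill_result`.
#' @param ... Unused.
#' @return Tibble with one row per added reaction (zero rows when nothing
#'   was added).
#' @export
tidy.gapfill_result <- function(x, ...) {
  tibble::tibble(reaction_id = x$added_reactions,
                 status = rep(x$status, length(x$added_reactions)))
}

#' @rdname tidy.gapfill_result
#' @export
glance.gapfill_result <- function(x, ...) {
  tibble::tibble(status = x$status, n_added = length(x$added_reactions),
                 growth_before = x$growth_before, growth_after = x$growth_after,
                 certified_minimal = x$certified_minimal)
}

#' Tidy an FBA solution into a flux table
#'
#' @param x An `fba_solution`.
#' @param ... Unused.
#' @return Tibble `reaction_id`, `flux`.
#' @export
tidy.fba_solution <- function(x, ...) {
  tibble::tibble(reaction_id = names(x$fluxes), flux = unname(x$fluxes))
}

#' @rdname tidy.fba_solution
#' @export
glance.fba_solution <- function(x, ...) {
  tibble::tibble(status = x$status, objective_value = x$objective_value)
}
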