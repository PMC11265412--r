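#' Define a chemically defined medium
#'
#' A medium is a table of maximum uptake rates for exchange reactions.
#' Magnitudes are non-negative (mmol/gDCW/h); the sign convention is
#' export-positive, so an uptake magnitude `u` becomes exchange lower bound
#' `-u` when the medium is applied.
#'
#' @param uptake_limits Named numeric vector (exchange id -> uptake
#'   magnitude) or a tibble with columns `exchange_id`, `uptake`.
#' @param name Medium label.
#' @return An object of class `panflux_medium`: tibble `exchange_id`,
#'   `uptake` with a `name` attribute.
#' @export
medium <- function(uptake_limits, name = "medium") {
  if (is.numeric(uptake_limits) && !is.null(names(uptake_limits))) {
    tab <- tibble::tibble(exchange_id = names(uptake_limits),
                          uptake = unname(uptake_limits))
  } else {
    tab <- tibble::as_tibble(uptake_limits)[, c("exchange_id", "uptake")]
  }
  if (any(tab$uptake < 0)) stop("uptake magnitudes must be >= 0")
  if (anyDuplicated(tab$exchange_id)) stop("duplicate exchange ids in medium")
  structure(tab, name = name, class = c("panflux_medium", class(tab)))
}

#' Read / write a medium TSV
#'
#' Columns `exchange_id`, `uptake_mmol_gDCW_h`; lines starting with `#` are
#' comments.
#'
#' @param path File path.
#' @param name Medium label (read) .
#' @return A `panflux_medium` (read); the path, invisibly (write).
#' @export
read_medium_tsv <- function(path, name = basename(path)) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  medium(tibble::tibble(exchange_id = tab$exchange_id,
                        uptake = tab$uptake_mmol_gDCW_h), name = name)
}

#' @rdname read_medium_tsv
#' @param x A `panflux_medium`.
#' @export
write_medium_tsv <- function(x, path) {
  lines <- c("# chemically defined medium: maximum uptake magnitudes (mmol/gDCW/h)",
             "exchange_id\tuptake_mmol_gDCW_h",
             paste(x$exchange_id, format(x$uptake, trim = TRUE, scientific = FALSE), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Apply a medium to a model
#'
#' Sets the lower bound of every exchange reaction listed in the medium to
#' minus its uptake magnitude and closes (lower bound 0) every exchange not
#' listed — minimal-medium semantics, required for meaningful auxotrophy
#' simulation. Secretion (upper) bounds are untouched. The NGAM lower bound
#' is enforced at `ngam`. Applying the same medium twice is idempotent, and
#' no bound is widened beyond the template's declared magnitude.
#'
#' @param model A `pan_reactome` or `strain_model`.
#' @param med A [medium()].
#' @param ngam Non-growth-associated maintenance flux floor (mmol/gDCW/h);
#'   default 1.
#' @param strict If `TRUE` (default), a medium entry naming an exchange that
#'   is absent from the model is an error; if `FALSE` it is ignored (a strain
#'   model need not carry every template exchange).
#' @return The model with constrained bounds.
#' @export
apply_medium <- function(model, med, ngam = 1, strict = TRUE) {
  r <- model$reactions
  ex <- r$rtype == "exchange"
  unknown <- setdiff(med$exchange_id, r$id[ex])
  if (length(unknown) > 0L) {
    if (strict) stop("medium names unknown exchange reaction(s): ",
                     paste(unknown, collapse = ", "))
    med <- med[!med$exchange_id %in% unknown, ]
  }
  # close all uptakes, then open the listed ones
  r$lower_bound[ex] <- 0
  idx <- match(med$exchange_id, r$id)
  keep <- !is.na(idx)
  r$lower_bound[idx[keep]] <- pmax(-med$uptake[keep], -.panflux_big_bound)
  ng <- r$id == model$ngam_id
  r$lower_bound[ng] <- ngam
  if (r$upper_bound[ng] < ngam) stop("NGAM floor exceeds the NGAM upper bound")
  model$reactions <- r
  model
}
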