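#' Parse an elemental formula in Hill notation
#'
#' Turns a formula string such as `"C6H12O6"` into a named integer vector of
#' element counts. Element symbols are an upper-case letter optionally
#' followed by lower-case letters (so artificial bookkeeping elements like
#' `"Ad"` or `"Nc"` parse like real ones). The symbols `R` and `X` denote
#' pseudo-elements (R-groups, unspecified moieties); formulas containing them
#' parse, but [check_mass_charge_balance()] exempts the reactions that touch
#' them, since such metabolites are never balanceable.
#'
#' @param formula A single formula string. An empty string yields an empty
#'   count vector.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C6H12O6")
#' parse_formula("C3H4O3")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  if (is.na(formula) || formula == "") return(stats::setNames(integer(0), character(0)))
  tokens <- gregexpr("[A-Z][a-z]*[0-9]*", formula)[[1]]
  matched <- regmatches(formula, gregexpr("[A-Z][a-z]*[0-9]*", formula))[[1]]
  if (sum(nchar(matched)) != nchar(formula)) {
    stop("unparseable formula: '", formula, "'")
  }
  syms <- sub("[0-9]+$", "", matched)
  counts <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", matched)))
  counts[is.na(counts)] <- 1L
  if (any(counts < 0)) stop("negative element count in formula: '", formula, "'")
  out <- tapply(counts, syms, sum)
  stats::setNames(as.integer(out), names(out))
}

#' @rdname parse_formula
#' @export
has_pseudo_elements <- function(formula) {
  counts <- parse_formula(formula)
  any(names(counts) %in% c("R", "X"))
}
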