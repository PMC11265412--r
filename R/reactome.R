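#' Reaction-type taxonomy
#'
#' Reactions in a pan-reactome carry one of seven type labels. Only
#' `gene_associated` reactions have a GPR rule; `exchange`, `orphan`,
#' `spontaneous`, `demand` and `sink` reactions are non-genetic network
#' plumbing that every strain model inherits from the template, and exactly
#' one `biomass` reaction acts as the growth objective.
#'
#' @format Character vector of valid type labels.
#' @export
reaction_types <- c("gene_associated", "exchange", "orphan", "spontaneous",
                    "demand", "sink", "biomass")

# rtypes that are carried into every strain model regardless of homology
universal_rtypes <- c("exchange", "orphan", "spontaneous", "demand", "sink", "biomass")

#' Construct a GPR rule in disjunctive normal form
#'
#' A gene-protein-reaction rule is stored as a list of allele sets
#' (character vectors); the reaction is available if all alleles of at least
#' one set are present. Multiple sets capture multi-allelic GPRs, where
#' distinct gene sets (alleles) can each supply the same reaction.
#'
#' @param ... Character vectors, one per alternative allele set.
#' @return A list of class `gpr_rule`.
#' @examples
#' gpr_rule(c("g1", "g2"), "g3")  # (g1 AND g2) OR g3
#' @export
gpr_rule <- function(...) {
  alts <- lapply(list(...), as.character)
  if (length(alts) == 0L) stop("a GPR rule needs at least one alternative allele set")
  if (any(vapply(alts, length, 1L) == 0L)) stop("empty allele set in GPR rule")
  alts <- lapply(alts, function(a) sort(unique(a)))
  structure(alts, class = "gpr_rule")
}

#' Evaluate a GPR rule against a set of present alleles
#'
#' @param rule A [gpr_rule()].
#' @param present Character vector of allele ids present in a strain.
#' @return `TRUE` if at least one alternative allele set is fully contained
#'   in `present`.
#' @export
eval_gpr <- function(rule, present) {
  any(vapply(rule, function(alt) all(alt %in% present), logical(1)))
}

#' Assemble a pan-reactome object
#'
#' The pan-reactome is the family-wide template network: metabolites,
#' reactions with bounds and type labels, stoichiometry in long format,
#' multi-allelic GPR rules, and the ids of the biomass and ATP-maintenance
#' (NGAM) reactions. All structural invariants are checked on construction.
#'
#' @param metabolites Tibble with columns `id`, `name`, `formula`, `charge`,
#'   `compartment`.
#' @param reactions Tibble with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `subsystem`, `rtype`.
#' @param stoichiometry Tibble with columns `reaction_id`, `metabolite_id`,
#'   `coefficient` (negative = consumed).
#' @param gprs Named list mapping reaction id to a [gpr_rule()]; exactly the
#'   `gene_associated` reactions must appear.
#' @param biomass_id,ngam_id Ids of the biomass and NGAM reactions.
#' @param allele_catalog Optional named character vector of reference protein
#'   sequences per allele.
#' @param compartments Declared compartment labels.
#' @return An object of class `pan_reactome`.
#' @export
pan_reactome <- function(metabolites, reactions, stoichiometry, gprs,
                         biomass_id, ngam_id, allele_catalog = NULL,
                         compartments = c("c", "e")) {
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  stoichiometry <- tibble::as_tibble(stoichiometry)
  obj <- structure(
    list(metabolites = metabolites, reactions = reactions,
         stoichiometry = stoichiometry, gprs = gprs,
         biomass_id = biomass_id, ngam_id = ngam_id,
         allele_catalog = allele_catalog, compartments = compartments),
    class = "pan_reactome")
  validate_pan_reactome(obj)
  obj
}

#' Validate the structural invariants of a pan-reactome or strain model
#'
#' @param x A `pan_reactome` or `strain_model`.
#' @return `x`, invisibly; errors describe the first violated invariant.
#' @export
validate_pan_reactome <- function(x) {
  m <- x$metabolites; r <- x$reactions; st <- x$stoichiometry
  if (anyDuplicated(m$id)) stop("duplicate metabolite ids")
  if (anyDuplicated(r$id)) stop("duplicate reaction ids")
  if (!all(m$compartment %in% x$compartments)) {
    stop("metabolite compartment outside the declared compartments")
  }
  if (any(r$lower_bound > r$upper_bound)) stop("reaction with lower_bound > upper_bound")
  if (!all(r$rtype %in% reaction_types)) stop("unknown reaction type label")
  if (!all(st$metabolite_id %in% m$id)) {
    missing <- setdiff(st$metabolite_id, m$id)
    stop("stoichiometry references unknown metabolite(s): ", paste(missing, collapse = ", "))
  }
  if (!all(st$reaction_id %in% r$id)) stop("stoichiometry references unknown reaction(s)")
  empty <- setdiff(r$id, unique(st$reaction_id))
  if (length(empty) > 0L) stop("reaction(s) with empty stoichiometry: ", paste(empty, collapse = ", "))
  if (sum(r$rtype == "biomass") != 1L) stop("exactly one biomass reaction is required")
  if (!x$biomass_id %in% r$id || r$rtype[r$id == x$biomass_id] != "biomass") {
    stop("biomass_id does not name the biomass reaction")
  }
  if (!x$ngam_id %in% r$id) stop("ngam_id not found among reactions")
  ga <- r$id[r$rtype == "gene_associated"]
  if (!setequal(ga, names(x$gprs))) {
    stop("gene_associated reactions and GPR rules must match one-to-one")
  }
  invisible(x)
}

#' @export
print.pan_reactome <- function(x, ...) {
  cat("<pan_reactome> ", nrow(x$reactions), " reactions, ",
      nrow(x$metabolites), " metabolites, ",
      length(x$gprs), " GPR rules\n", sep = "")
  tab <- classify_reaction_types(x)
  cat(paste0("  ", tab$rtype, ": ", tab$n, collapse = "\n"), "\n", sep = "")
  invisible(x)
}

#' Count reactions per type
#'
#' Returns the breakdown of a reactome into gene-associated, exchange,
#' orphan, spontaneous, demand, sink and biomass reactions. The counts
#' partition the reaction set.
#'
#' @param reactome A `pan_reactome` or `strain_model`.
#' @return Tibble with columns `rtype` and `n`, one row per type (zero rows
#'   included), summing to the total reaction count.
#' @export
classify_reaction_types <- function(reactome) {
  counts <- table(factor(reactome$reactions$rtype, levels = reaction_types))
  tibble::tibble(rtype = names(counts), n = as.integer(counts))
}

#' Check elemental mass and charge balance of a reactome
#'
#' For every `gene_associated` and `spontaneous` reaction, sums
#' coefficient-weighted element counts and charges over the participating
#' metabolites. Exchange, demand, sink and biomass reactions are exempt by
#' construction (they are net drains). Reactions touching a metabolite whose
#' formula contains a pseudo-element (`R`, `X`) are exempted with a warning.
#' Element and charge arithmetic is exact integer arithmetic.
#'
#' @param reactome A `pan_reactome` or `strain_model`.
#' @return Tibble with columns `reaction_id`, `quantity` (element symbol or
#'   `"charge"`), `imbalance` (signed net amount). Zero rows certify a
#'   balanced network.
#' @export
check_mass_charge_balance <- function(reactome) {
  m <- reactome$metabolites
  checked <- reactome$reactions$id[reactome$reactions$rtype %in% c("gene_associated", "spontaneous")]
  parsed <- lapply(stats::setNames(m$formula, m$id), parse_formula)
  pseudo <- vapply(parsed, function(p) any(names(p) %in% c("R", "X")), logical(1))
  charge <- stats::setNames(m$charge, m$id)
  st <- reactome$stoichiometry

  rows <- list()
  for (rid in checked) {
    part <- st[st$reaction_id == rid, ]
    if (any(pseudo[part$metabolite_id])) {
      warning("reaction '", rid, "' touches a pseudo-element metabolite; exempt from balance check")
      next
    }
    elems <- unique(unlist(lapply(parsed[part$metabolite_id], names)))
    for (el in elems) {
      cnt <- vapply(parsed[part$metabolite_id], function(p) {
        if (el %in% names(p)) p[[el]] else 0L
      }, integer(1))
      net <- sum(part$coefficient * cnt)
      if (net != 0) rows[[length(rows) + 1L]] <- tibble::tibble(
        reaction_id = rid, quantity = el, imbalance = net)
    }
    netq <- sum(part$coefficient * charge[part$metabolite_id])
    if (netq != 0) rows[[length(rows) + 1L]] <- tibble::tibble(
      reaction_id = rid, quantity = "charge", imbalance = netq)
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(reaction_id = character(), quantity = character(),
                          imbalance = numeric()))
  }
  dplyr::bind_rows(rows)
}

#' Detect thermodynamically infeasible cycles
#'
#' Closes every exchange reaction (both bounds zero) and runs flux
#' variability analysis with a zero objective. Any reaction whose flux range
#' exceeds the tolerance can carry flux with no net exchange with the
#' environment, i.e. participates in a thermodynamically infeasible cycle
#' (TIC). An empty result certifies the absence of TICs.
#'
#' @param reactome A `pan_reactome` or `strain_model`.
#' @param tol Flux tolerance in mmol/gDCW/h; default `1e-6` (above LP solver
#'   noise, below any meaningful flux).
#' @return Character vector of reaction ids able to carry cyclic flux.
#' @export
detect_infeasible_cycles <- function(reactome, tol = 1e-6) {
  r <- reactome$reactions
  closed <- r
  ex <- closed$rtype %in% c("exchange", "demand", "sink")
  closed$lower_bound[ex] <- 0
  closed$upper_bound[ex] <- 0
  # the NGAM floor would force flux; relax every lower bound floor above 0
  closed$lower_bound <- pmin(closed$lower_bound, 0)
  closed$upper_bound <- pmax(closed$upper_bound, 0)
  x <- reactome
  x$reactions <- closed

  S <- stoich_matrix(x)
  lb <- closed$lower_bound; ub <- closed$upper_bound
  hits <- character(0)
  for (j in seq_len(ncol(S))) {
    obj <- numeric(ncol(S)); obj[j] <- 1
    up <- lp_solve_fba(obj, S, lb, ub, maximize = TRUE)
    dn <- lp_solve_fba(obj, S, lb, ub, maximize = FALSE)
    if ((up$status == "optimal" && abs(up$objective) > tol) ||
        (dn$status == "optimal" && abs(dn$objective) > tol)) {
      hits <- c(hits, closed$id[j])
    }
  }
  hits
}
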