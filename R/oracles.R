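#' Brute-force FBA by vertex enumeration
#'
#' Reference implementation for verifying the LP-based [fba()] on tiny
#' networks: enumerates every basic feasible solution (vertex) of
#' `{S v = 0, lb <= v <= ub}` by fixing each choice of non-basic variables
#' at a bound and solving the remaining square system, then takes the best
#' objective over vertices. Exponential in the reaction count — intended for
#' networks of at most ~8 reactions.
#'
#' @param S Stoichiometric matrix (metabolites x reactions).
#' @param lb,ub Finite bound vectors.
#' @param obj Objective coefficient vector.
#' @param maximize Direction; default `TRUE`.
#' @param tol Feasibility tolerance.
#' @return List: `status` (`"optimal"` or `"infeasible"`), `objective`,
#'   `vertices` (matrix of all distinct feasible vertices, columns =
#'   reactions), `objectives` (per vertex).
#' @export
fba_brute_force <- function(S, lb, ub, obj, maximize = TRUE, tol = 1e-7) {
  n <- ncol(S)
  r <- qr(S)$rank
  verts <- list()
  free_sets <- if (r == 0) list(integer(0)) else
    utils::combn(n, min(r, n), simplify = FALSE)
  for (fs in free_sets) {
    bs <- setdiff(seq_len(n), fs)
    Sf <- S[, fs, drop = FALSE]
    if (length(fs) > 0 && qr(Sf)$rank < length(fs)) next
    k <- length(bs)
    for (mask in seq_len(2^k) - 1L) {
      at_ub <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1L)))
      v <- numeric(n)
      v[bs] <- ifelse(at_ub, ub[bs], lb[bs])
      rhs <- -as.vector(S[, bs, drop = FALSE] %*% v[bs])
      if (length(fs) > 0) {
        sol <- qr.solve(qr(Sf), rhs)
        v[fs] <- sol
      } else if (max(abs(rhs)) > tol) next
      if (max(abs(as.vector(S %*% v))) > tol) next
      if (any(v < lb - tol) || any(v > ub + tol)) next
      verts[[length(verts) + 1L]] <- pmin(pmax(v, lb), ub)
    }
  }
  if (length(verts) == 0L) {
    return(list(status = "infeasible", objective = NA_real_,
                vertices = matrix(numeric(0), 0, n), objectives = numeric(0)))
  }
  V <- unique(do.call(rbind, lapply(verts, round, digits = 9)))
  objs <- as.vector(V %*% obj)
  best <- if (maximize) max(objs) else min(objs)
  list(status = "optimal", objective = best, vertices = V, objectives = objs)
}

#' Brute-force minimal gapfill by subset enumeration
#'
#' Reference for [gapfill()]: tries candidate subsets in order of increasing
#' size (lexicographic within a size) and returns the first subset whose
#' addition lets the model exceed the growth threshold. Exponential —
#' intended for candidate sets of at most ~12 reactions.
#'
#' @inheritParams gapfill
#' @param candidates Candidate reaction ids (default: all template
#'   reactions absent from the model).
#' @return List: `added_reactions` (a certified minimum-cardinality subset,
#'   `NULL` when infeasible), `size`, `status`.
#' @export
gapfill_brute_force <- function(model, reactome, med, growth_threshold = 0.01,
                                candidates = NULL, ngam = 1) {
  if (verify_functionality(model, med, growth_threshold, ngam = ngam)) {
    return(list(added_reactions = character(0), size = 0L, status = "already_functional"))
  }
  if (is.null(candidates)) {
    candidates <- sort(setdiff(reactome$reactions$id, model$reactions$id))
  }
  for (k in seq_along(candidates)) {
    for (subset in utils::combn(candidates, k, simplify = FALSE)) {
      trial <- add_reactions(model, reactome, subset)
      if (verify_functionality(trial, med, growth_threshold, ngam = ngam)) {
        return(list(added_reactions = subset, size = k, status = "filled"))
      }
    }
  }
  list(added_reactions = NULL, size = NA_integer_, status = "infeasible")
}

#' Exhaustive two-sided Fisher p by hypergeometric enumeration
#'
#' Reference for [fisher_exact()]: enumerates every table with the observed
#' margins and sums the probabilities of those no more probable than the
#' observed table.
#'
#' @inheritParams fisher_exact
#' @return Two-sided p-value.
#' @export
fisher_enumerate <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  lo <- max(0, k - m2); hi <- min(k, m1)
  av <- lo:hi
  probs <- stats::dhyper(av, m1, m2, k)
  p_obs <- stats::dhyper(a, m1, m2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
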