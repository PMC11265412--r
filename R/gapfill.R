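# General LP: optimize obj'z  s.t.  Aeq z = beq, Aineq z <= bineq, lb <= z <= ub.
# Inequalities are converted to equalities with box-bounded slack variables:
# the underlying simplex is markedly more reliable on its pure-equality path
# than on mixed constraint systems.
lp_solve_gen <- function(obj, Aeq, beq, Aineq, bineq, lb, ub,
                         maximize = FALSE, maxiter = 20000L) {
  n <- length(obj)
  m <- nrow(Aineq)
  # slack upper bounds from interval arithmetic over the variable box
  row_min <- vapply(seq_len(m), function(i) {
    sum(pmin(Aineq[i, ] * lb, Aineq[i, ] * ub))
  }, numeric(1))
  smax <- pmax(bineq - row_min, 0)
  A2 <- rbind(cbind(Aeq, matrix(0, nrow(Aeq), m)),
              cbind(Aineq, diag(m)))
  b2 <- c(beq, bineq)
  lb2 <- c(lb, rep(0, m))
  ub2 <- c(ub, smax)
  obj2 <- c(obj, rep(0, m))
  res <- .lp_run(function(bigM, eps) {
    pracma::linprog(obj2 + eps * seq_along(obj2),
                    Aeq = A2, beq = b2 - as.vector(A2 %*% lb2),
                    ub = ub2 - lb2, maximize = maximize, maxiter = maxiter,
                    bigM = bigM)
  })
  if (is.null(res$errno) || res$errno < 0) {
    return(list(status = "infeasible", objective = NA_real_, z = rep(NA_real_, n)))
  }
  z <- res$x[seq_len(n)] + lb
  z <- pmin(pmax(z, lb), ub)
  list(status = "optimal", objective = sum(obj * z), z = z)
}

#' Check that a model can produce biomass on a medium
#'
#' @param model A `strain_model` (or `pan_reactome`).
#' @param med A [medium()].
#' @param growth_threshold Growth call threshold (1/h); growth means FBA
#'   optimum strictly above it. Default 0.01.
#' @param ngam NGAM floor.
#' @return `TRUE` iff the FBA biomass optimum exceeds `growth_threshold`.
#' @export
verify_functionality <- function(model, med, growth_threshold = 0.01, ngam = 1) {
  sol <- fba(model, med, ngam = ngam)
  if (sol$status == "infeasible") return(FALSE)
  if (sol$status != "optimal") stop("FBA terminated '", sol$status, "' for model ",
                                    model$strain_id %||% "<template>")
  sol$objective_value > growth_threshold
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Add template reactions (and their metabolites) to a strain model.
add_reactions <- function(model, reactome, ids, provenance = "gapfilled") {
  ids <- setdiff(ids, model$reactions$id)
  if (length(ids) == 0L) return(model)
  extra <- reactome$reactions[reactome$reactions$id %in% ids, ]
  st_extra <- reactome$stoichiometry[reactome$stoichiometry$reaction_id %in% ids, ]
  model$reactions <- dplyr::bind_rows(model$reactions, extra)
  model$stoichiometry <- dplyr::bind_rows(model$stoichiometry, st_extra)
  new_mets <- setdiff(st_extra$metabolite_id, model$metabolites$id)
  model$metabolites <- dplyr::bind_rows(
    model$metabolites, reactome$metabolites[reactome$metabolites$id %in% new_mets, ])
  model$gprs <- c(model$gprs, reactome$gprs[intersect(ids, names(reactome$gprs))])
  if (!is.null(model$provenance)) {
    model$provenance <- c(model$provenance, stats::setNames(rep(provenance, length(ids)), ids))
  }
  validate_pan_reactome(model)
  model
}

#' Minimal-addition gapfilling
#'
#' Restores biomass production to a draft strain model by adding a
#' minimum-weight set of template reactions. Formulated as a binary-indicator
#' MILP — minimize the summed weights of added reactions subject to
#' steady-state mass balance, candidate bounds gated by the indicators, and
#' biomass flux at least `growth_threshold` — and solved by a deterministic
#' best-bound branch-and-bound over LP relaxations, so the returned set is
#' certified minimal. If the time limit is hit, a deterministic greedy pass
#' (add all candidates, then attempt single-reaction removals in
#' lexicographic order) supplies a feasible but non-certified answer.
#'
#' @param model A `strain_model`.
#' @param reactome The template [pan_reactome()]; its reactions absent from
#'   the model form the candidate set.
#' @param med A [medium()].
#' @param growth_threshold Biomass flux (1/h) the repaired model must
#'   exceed; default 0.01, shared with all phenotype calls.
#' @param weights Optional named numeric of per-candidate costs (default
#'   uniform 1).
#' @param time_limit Seconds before falling back to the greedy pass;
#'   default 60.
#' @param ngam NGAM floor.
#' @return A list of class `gapfill_result`: `added_reactions`,
#'   `growth_before`, `growth_after`, `status` (`"already_functional"`,
#'   `"filled"` or `"infeasible"`), `certified_minimal`, and `model` (the
#'   repaired model; untouched input when not filled).
#' @export
gapfill <- function(model, reactome, med, growth_threshold = 0.01,
                    weights = NULL, time_limit = 60, ngam = 1) {
  sol0 <- fba(model, med, ngam = ngam)
  growth_before <- if (sol0$status == "optimal") sol0$objective_value else 0
  if (sol0$status == "optimal" && sol0$objective_value > growth_threshold) {
    return(structure(list(added_reactions = character(0),
                          growth_before = growth_before,
                          growth_after = growth_before,
                          status = "already_functional",
                          certified_minimal = TRUE, model = model),
                     class = "gapfill_result"))
  }
  candidates <- sort(setdiff(reactome$reactions$id, model$reactions$id))
  full <- add_reactions(model, reactome, candidates)
  if (!verify_functionality(full, med, growth_threshold, ngam = ngam)) {
    return(structure(list(added_reactions = character(0),
                          growth_before = growth_before,
                          growth_after = growth_before,
                          status = "infeasible",
                          certified_minimal = TRUE, model = model),
                     class = "gapfill_result"))
  }
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(candidates)), candidates)
  stopifnot(all(candidates %in% names(weights)), all(weights > 0))

  constrained <- apply_medium(full, med, ngam = ngam, strict = FALSE)
  r <- constrained$reactions
  S <- stoich_matrix(constrained)
  n <- nrow(r); k <- length(candidates)
  cand_idx <- match(candidates, r$id)
  bio_idx <- which(r$id == constrained$biomass_id)
  lb <- r$lower_bound; ub <- r$upper_bound
  lb[bio_idx] <- max(lb[bio_idx], growth_threshold * (1 + 1e-6))

  # variables: z = (v_1..v_n, y_1..y_k)
  Aeq <- cbind(S, matrix(0, nrow(S), k))
  beq <- rep(0, nrow(S))
  # v_i - ub_i y_i <= 0  and  -v_i + lb_i y_i <= 0  for candidates
  Aineq <- matrix(0, 2L * k, n + k)
  for (j in seq_len(k)) {
    i <- cand_idx[j]
    Aineq[2L * j - 1L, i] <- 1;  Aineq[2L * j - 1L, n + j] <- -ub[i]
    Aineq[2L * j, i] <- -1;      Aineq[2L * j, n + j] <- lb[i]
  }
  bineq <- rep(0, 2L * k)
  w <- unname(weights[candidates])
  obj <- c(rep(0, n), w)
  zlb <- c(lb, rep(0, k)); zub <- c(ub, rep(1, k))
  # candidate fluxes are gated by y, so their own bounds relax to the gate
  zlb[cand_idx] <- pmin(lb[cand_idx], 0)
  zub[cand_idx] <- pmax(ub[cand_idx], 0)

  deadline <- Sys.time() + time_limit

  # greedy incumbent first: add everything, then attempt single-reaction
  # removals in lexicographic order — cheap and usually already minimal,
  # which makes the branch-and-bound bound tight from the start
  greedy <- candidates
  for (rid in candidates) {
    trial <- setdiff(greedy, rid)
    mtry <- add_reactions(model, reactome, trial)
    if (verify_functionality(mtry, med, growth_threshold, ngam = ngam)) greedy <- trial
  }
  best <- list(obj = sum(w[candidates %in% greedy]),
               y = as.numeric(candidates %in% greedy))
  integral_w <- all(abs(w - round(w)) < 1e-9)
  timed_out <- FALSE
  ytol <- 1e-6

  # DFS branch-and-bound; branch to y=1 first to find incumbents early
  stack <- list(list(fix = rep(NA_real_, k)))
  while (length(stack) > 0L) {
    if (Sys.time() > deadline) { timed_out <- TRUE; break }
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nlb <- zlb; nub <- zub
    f0 <- !is.na(node$fix) & node$fix == 0
    f1 <- !is.na(node$fix) & node$fix == 1
    nub[n + which(f0)] <- 0
    nlb[n + which(f1)] <- 1
    rel <- lp_solve_gen(obj, Aeq, beq, Aineq, bineq, nlb, nub, maximize = FALSE)
    if (rel$status != "optimal") next
    # with integral weights the LP bound rounds up to the next integer
    bound <- if (integral_w) ceiling(rel$objective - 1e-6) else rel$objective
    if (bound >= best$obj - 1e-7) next
    y <- rel$z[n + seq_len(k)]
    frac <- which(y > ytol & y < 1 - ytol)
    if (length(frac) == 0L) {
      best <- list(obj = sum(w[y > 0.5]), y = as.numeric(y > 0.5))
      next
    }
    j <- frac[which.max(pmin(y[frac], 1 - y[frac]))]
    child0 <- node; child0$fix[j] <- 0
    child1 <- node; child1$fix[j] <- 1
    stack[[length(stack) + 1L]] <- child0
    stack[[length(stack) + 1L]] <- child1
  }

  added <- candidates[best$y > 0.5]
  certified <- !timed_out

  repaired <- add_reactions(model, reactome, added)
  sol1 <- fba(repaired, med, ngam = ngam)
  structure(list(added_reactions = added,
                 growth_before = growth_before,
                 growth_after = sol1$objective_value,
                 status = "filled",
                 certified_minimal = certified, model = repaired),
            class = "gapfill_result")
}

#' @export
print.gapfill_result <- function(x, ...) {
  cat("<gapfill_result> status:", x$status,
      " added:", length(x$added_reactions),
      " growth:", format(x$growth_before, digits = 4), "->",
      format(x$growth_after, digits = 4),
      if (!x$certified_minimal) " (not certified minimal)" else "", "\n")
  invisible(x)
}
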