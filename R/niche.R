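# run code with a temporary RNG state seeded from `seed`
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Jaccard distances between strain reactomes
#'
#' `d(s, t) = 1 - |R_s intersect R_t| / |R_s union R_t|` over the strains'
#' reaction sets.
#'
#' @param pam A `presence_absence` matrix.
#' @return Symmetric distance matrix (zero diagonal, values in `[0, 1]`)
#'   with strain labels.
#' @export
jaccard_distances <- function(pam) {
  mat <- unclass(pam)
  sizes <- rowSums(mat)
  if (any(sizes == 0)) {
    stop("strain(s) with empty reactome: ",
         paste(rownames(mat)[sizes == 0], collapse = ", "))
  }
  inter <- mat %*% t(mat)
  uni <- outer(sizes, sizes, `+`) - inter
  d <- 1 - inter / uni
  diag(d) <- 0
  dimnames(d) <- list(rownames(mat), rownames(mat))
  d
}

.permanova_ss <- function(A2, groups) {
  # A2 = squared distances; groups = integer codes
  N <- nrow(A2)
  ss_total <- sum(A2[upper.tri(A2)]) / N
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ss_within <- ss_within + sum(A2[idx, idx][upper.tri(A2[idx, idx])]) / length(idx)
  }
  c(total = ss_total, within = ss_within)
}

.permanova_F <- function(A2, groups) {
  ss <- .permanova_ss(A2, groups)
  a <- length(unique(groups)); N <- nrow(A2)
  ((ss["total"] - ss["within"]) / (a - 1)) / (ss["within"] / (N - a))
}

# enumerate all distinct assignments of group sizes to N positions
.enumerate_labelings <- function(sizes) {
  N <- sum(sizes)
  out <- list()
  recurse <- function(avail, remaining_sizes, assignment, gi) {
    if (length(remaining_sizes) == 1L) {
      assignment[avail] <- gi
      out[[length(out) + 1L]] <<- assignment
      return(invisible())
    }
    k <- remaining_sizes[1]
    # fix the first available position into the first group's choices only
    # when the group sizes are tied, to avoid double counting? groups are
    # labeled (distinct factors), so all combinations count.
    combs <- utils::combn(avail, k, simplify = FALSE)
    for (cb in combs) {
      assignment[cb] <- gi
      recurse(setdiff(avail, cb), remaining_sizes[-1], assignment, gi + 1L)
    }
  }
  recurse(seq_len(N), sizes, integer(N), 1L)
  out
}

#' PERMANOVA on a distance matrix
#'
#' One-factor permutational multivariate analysis of variance.
#' `SS_total = (1/N) * sum_{i<j} d_ij^2`, `SS_within = sum_g (1/n_g) *
#' sum_{i<j in g} d_ij^2`, `pseudo_F = (SS_between / (a-1)) / (SS_within /
#' (N-a))`, and the p-value is `(1 + #permuted F >= observed F) / (1 +
#' n_permutations)` with label permutations drawn under the stated seed.
#' When the number of distinct labelings is at most `max_exact`, the exact
#' permutation distribution is enumerated instead and the p-value is the
#' exact tail fraction.
#'
#' @param dist Symmetric distance matrix with row/column labels.
#' @param labels Grouping factor, one entry per row of `dist` (at least 2
#'   groups, each with at least 2 members).
#' @param n_permutations Number of random permutations; default 999.
#' @param seed Integer seed for the permutation draw (mandatory).
#' @param max_exact Enumerate exactly when the distinct labeling count is at
#'   most this; default 10000.
#' @return A list of class `permanova_result`: `pseudo_F`, `R2`, `p_value`,
#'   `n_permutations` (or the exact labeling count), `exact`, `seed`,
#'   `ss_between`, `ss_within`, `ss_total`, `df_between`, `df_within`.
#' @export
permanova <- function(dist, labels, n_permutations = 999, seed,
                      max_exact = 10000) {
  stopifnot(is.matrix(dist), nrow(dist) == ncol(dist))
  labels <- as.factor(labels)
  stopifnot(length(labels) == nrow(dist))
  sizes <- table(labels)
  if (length(sizes) < 2L) stop("PERMANOVA needs at least 2 groups")
  if (any(sizes < 2L)) stop("singleton group(s): ",
                            paste(names(sizes)[sizes < 2], collapse = ", "))
  groups <- as.integer(labels)
  A2 <- dist^2
  N <- nrow(A2); a <- length(sizes)
  ss <- .permanova_ss(A2, groups)
  ss_between <- ss[["total"]] - ss[["within"]]
  F_obs <- (ss_between / (a - 1)) / (ss[["within"]] / (N - a))

  n_distinct <- round(exp(lgamma(N + 1) - sum(lgamma(as.integer(sizes) + 1))))
  if (n_distinct <= max_exact) {
    labelings <- .enumerate_labelings(as.integer(table(groups)))
    Fs <- vapply(labelings, function(g) .permanova_F(A2, g), numeric(1))
    p <- mean(Fs >= F_obs - 1e-12)
    n_used <- length(labelings)
    exact <- TRUE
  } else {
    perm_F <- with_seed(seed, {
      vapply(seq_len(n_permutations), function(i) {
        .permanova_F(A2, sample(groups))
      }, numeric(1))
    })
    p <- (1 + sum(perm_F >= F_obs - 1e-12)) / (1 + n_permutations)
    n_used <- n_permutations
    exact <- FALSE
  }
  structure(list(pseudo_F = unname(F_obs), R2 = unname(ss_between / ss[["total"]]),
                 p_value = p, n_permutations = n_used, exact = exact,
                 seed = seed, ss_between = unname(ss_between),
                 ss_within = unname(ss[["within"]]), ss_total = unname(ss[["total"]]),
                 df_between = a - 1, df_within = N - a),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("<permanova> pseudo-F =", format(x$pseudo_F, digits = 5),
      " R2 =", format(x$R2, digits = 4),
      " p =", format(x$p_value, digits = 4),
      if (x$exact) " (exact enumeration)" else
        paste0(" (", x$n_permutations, " permutations)"), "\n")
  invisible(x)
}

#' Reaction-by-niche contingency tables
#'
#' One-vs-rest 2x2 tables over labeled strains: `a` strains in the niche
#' carrying the reaction, `b` in the niche without it, `c` outside with it,
#' `d` outside without it. Only niches with at least `min_niche_size`
#' strains are considered (the "more than 10 strains" rule read strictly).
#' Strains with a missing niche label are dropped from the analysis.
#'
#' @param pam A `presence_absence` matrix.
#' @param niche_labels Character vector of niche labels per strain (default:
#'   the metadata's `isolation_source` column).
#' @param min_niche_size Minimum strains per included niche; default 11.
#' @return Tibble: `reaction_id`, `niche`, `a`, `b`, `c`, `d`.
#' @export
build_contingency <- function(pam, niche_labels = NULL, min_niche_size = 11) {
  mat <- unclass(pam)
  if (is.null(niche_labels)) {
    meta <- attr(pam, "metadata")
    stopifnot(!is.null(meta), "isolation_source" %in% names(meta))
    niche_labels <- meta$isolation_source[match(rownames(mat), meta$strain_id)]
  }
  keep <- !is.na(niche_labels)
  mat <- mat[keep, , drop = FALSE]
  niche_labels <- niche_labels[keep]
  counts <- table(niche_labels)
  niches <- names(counts)[counts >= min_niche_size]
  purrr::map_dfr(sort(niches), function(nc) {
    inn <- niche_labels == nc
    a <- colSums(mat[inn, , drop = FALSE])
    c_ <- colSums(mat[!inn, , drop = FALSE])
    tibble::tibble(reaction_id = colnames(mat), niche = nc,
                   a = as.integer(a), b = as.integer(sum(inn) - a),
                   c = as.integer(c_), d = as.integer(sum(!inn) - c_))
  })
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact p: the sum of hypergeometric probabilities, over tables
#' with the observed margins, that do not exceed the observed table's
#' probability. Delegates to [stats::fisher.test()].
#'
#' @param a,b,c,d Cell counts (niche-with, niche-without, outside-with,
#'   outside-without).
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(a, b, c, d) {
  stats::fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE))$p.value
}

#' Log odds ratio with Haldane-Anscombe correction
#'
#' Natural-log odds ratio `ln((a d) / (b c))`. When any cell is zero, the
#' pseudocount is added to all four cells first (Haldane-Anscombe), keeping
#' the ratio finite for niche-exclusive reactions.
#'
#' @inheritParams fisher_exact
#' @param pseudocount Added to every cell when a zero is present; default
#'   0.5.
#' @return Natural-log odds ratio.
#' @export
log_odds_ratio <- function(a, b, c, d, pseudocount = 0.5) {
  if (any(c(a, b, c, d) == 0)) {
    a <- a + pseudocount; b <- b + pseudocount
    c <- c + pseudocount; d <- d + pseudocount
  }
  log((a * d) / (b * c))
}

#' Pearson chi-square test on a 2x2 table (no continuity correction)
#'
#' @inheritParams fisher_exact
#' @return List with `statistic` and `p_value` (upper tail of chi-square
#'   with 1 df). A zero margin is an error (expected counts must be
#'   positive).
#' @export
chi_square <- function(a, b, c, d) {
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin in contingency table; chi-square undefined")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Per-reaction niche enrichment statistics
#'
#' Builds one-vs-rest contingency tables ([build_contingency()]) and
#' computes the natural-log odds ratio, Fisher exact p and chi-square p for
#' every (reaction, niche) pair. Chi-square is `NA` where a margin is zero.
#'
#' @inheritParams build_contingency
#' @param pseudocount Haldane-Anscombe pseudocount for the odds ratio.
#' @return Tibble of class `enrichment_result`: contingency columns plus
#'   `log_or`, `fisher_p`, `chi2_p`.
#' @export
niche_enrichment <- function(pam, niche_labels = NULL, min_niche_size = 11,
                             pseudocount = 0.5) {
  tabs <- build_contingency(pam, niche_labels, min_niche_size)
  if (nrow(tabs) == 0L) {
    return(structure(tibble::tibble(reaction_id = character(), niche = character(),
                                    a = integer(), b = integer(), c = integer(),
                                    d = integer(), log_or = numeric(),
                                    fisher_p = numeric(), chi2_p = numeric()),
                     class = c("enrichment_result", class(tibble::tibble()))))
  }
  tabs$log_or <- purrr::pmap_dbl(tabs[c("a", "b", "c", "d")], log_odds_ratio,
                                 pseudocount = pseudocount)
  tabs$fisher_p <- purrr::pmap_dbl(tabs[c("a", "b", "c", "d")], fisher_exact)
  tabs$chi2_p <- purrr::pmap_dbl(tabs[c("a", "b", "c", "d")], function(a, b, c, d) {
    tryCatch(chi_square(a, b, c, d)$p_value, error = function(e) NA_real_)
  })
  structure(tabs, class = c("enrichment_result", class(tabs)))
}

#' Filter enrichment results to niche-enriched reactions
#'
#' Keeps (reaction, niche) pairs whose log odds ratio exceeds `lor_min`
#' (natural log; default 5). With `require_exclusive`, a reaction is kept
#' only if it passes the threshold in exactly one niche.
#'
#' @param results Tibble from [niche_enrichment()].
#' @param lor_min Log odds ratio threshold, strict.
#' @param require_exclusive Keep only reactions enriched in a single niche.
#' @return Filtered tibble with an added logical `exclusive` column.
#' @export
select_enriched <- function(results, lor_min = 5, require_exclusive = TRUE) {
  hits <- results[results$log_or > lor_min, , drop = FALSE]
  n_niches <- table(hits$reaction_id)
  hits$exclusive <- unname(n_niches[hits$reaction_id] == 1L)
  if (require_exclusive) hits <- hits[hits$exclusive, , drop = FALSE]
  hits
}

#' PCA embedding of the presence-absence matrix
#'
#' Principal components of the column-centered (not scaled) 0/1 matrix.
#' Each component's sign is fixed by making its largest-magnitude loading
#' positive, so embeddings are deterministic.
#'
#' @param pam A `presence_absence` matrix.
#' @param n_components Number of components requested; default 3. If the
#'   matrix rank is lower, fewer are returned with a warning.
#' @return List of class `pca_embedding`: `scores` (tibble `strain_id`,
#'   `PC1`, ...), `explained_variance` (fractions, non-increasing),
#'   `loadings` (matrix).
#' @export
pca_embed <- function(pam, n_components = 3) {
  mat <- unclass(pam)
  stopifnot(nrow(mat) >= n_components)
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  pos <- pc$sdev > 1e-10
  k <- min(n_components, sum(pos))
  if (k < n_components) warning("matrix rank ", sum(pos), " below requested ",
                                n_components, " components; returning ", k)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) { rot[, j] <- -rot[, j]; scores[, j] <- -scores[, j] }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    scores = tibble::as_tibble(scores, .name_repair = "minimal") |>
      stats::setNames(paste0("PC", seq_len(k))) |>
      tibble::add_column(strain_id = rownames(mat), .before = 1),
    explained_variance = ev[seq_len(k)], loadings = rot),
    class = "pca_embedding")
}

#' Seeded k-means clustering of embedded strains
#'
#' Deterministic wrapper around [stats::kmeans()]: identical seeds give
#' identical labels. The default `k = 9` mirrors clustering strains into
#' nine major niche groups.
#'
#' @param coordinates Numeric matrix or the `scores` tibble of
#'   [pca_embed()] (the `strain_id` column is dropped).
#' @param k Number of clusters (must not exceed the number of points).
#' @param seed Integer seed (mandatory).
#' @param nstart Random restarts; default 10.
#' @return Integer cluster labels (1..k), named by strain where available.
#' @export
kmeans_clusters <- function(coordinates, k = 9, seed, nstart = 10) {
  if (is.data.frame(coordinates)) {
    ids <- coordinates$strain_id
    coordinates <- as.matrix(coordinates[setdiff(names(coordinates), "strain_id")])
    rownames(coordinates) <- ids
  }
  if (k > nrow(coordinates)) stop("k exceeds the number of points")
  km <- with_seed(seed, stats::kmeans(coordinates, centers = k, nstart = nstart))
  stats::setNames(km$cluster, rownames(coordinates))
}
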