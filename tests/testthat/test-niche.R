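test_that("Jaccard distances match the set formula and metric axioms", {
  m <- matrix(c(1, 1, 1, 0,   # s1: r1 r2 r3
                0, 1, 1, 1,   # s2: r2 r3 r4
                1, 1, 1, 0),  # s3 = s1
              nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), paste0("r", 1:4)))
  d <- jaccard_distances(tiny_pam(m))
  expect_equal(d["s1", "s2"], 0.5)     # 1 - 2/4
  expect_equal(d["s1", "s3"], 0)
  expect_equal(diag(d), c(s1 = 0, s2 = 0, s3 = 0))
  expect_equal(d, t(d))

  disjoint <- matrix(c(1, 0, 0, 1), nrow = 2, byrow = TRUE,
                     dimnames = list(c("a", "b"), c("r1", "r2")))
  expect_equal(jaccard_distances(tiny_pam(disjoint))["a", "b"], 1)

  zero <- matrix(c(1, 0), nrow = 2,
                 dimnames = list(c("a", "b"), "r1"))
  expect_error(jaccard_distances(tiny_pam(zero)), "empty reactome.*b")

  # triangle inequality on random binary matrices
  set.seed(3)
  rm <- matrix(rbinom(10 * 12, 1, 0.5), nrow = 10,
               dimnames = list(paste0("s", 1:10), paste0("r", 1:12)))
  rm[, 1] <- 1
  dd <- jaccard_distances(tiny_pam(rm))
  for (i in 1:8) for (j in (i + 1):9) for (k in (j + 1):10) {
    expect_lte(dd[i, k], dd[i, j] + dd[j, k] + 1e-12)
  }
})

sep_pam <- function() {
  # two internally identical, mutually distant groups of 4
  m <- rbind(matrix(rep(c(1, 1, 1, 0, 0, 0), each = 4), nrow = 4),
             matrix(rep(c(0, 0, 0, 1, 1, 1), each = 4), nrow = 4))
  dimnames(m) <- list(paste0("s", 1:8), paste0("r", 1:6))
  tiny_pam(m)
}

test_that("PERMANOVA separates planted groups with the enumeration-minimum p", {
  d <- jaccard_distances(sep_pam())
  groups <- rep(c("g1", "g2"), each = 4)
  res <- permanova(d, groups, seed = 1)
  expect_true(res$exact)           # C(8,4) = 70 labelings, enumerated
  expect_equal(res$R2, 1, tolerance = 1e-9)
  expect_equal(res$p_value, 2 / 70) # observed labeling and its mirror
  expect_equal(res$n_permutations, 70)
})

test_that("pseudo-F is invariant to permuting labels within groups", {
  set.seed(5)
  m <- matrix(rbinom(12 * 20, 1, 0.4), nrow = 12,
              dimnames = list(paste0("s", 1:12), paste0("r", 1:20)))
  m[, 1] <- 1
  d <- jaccard_distances(tiny_pam(m))
  g <- rep(c("a", "b", "c"), each = 4)
  f1 <- panflux:::.permanova_F(d^2, as.integer(factor(g)))
  shuffled <- g
  shuffled[1:4] <- g[c(3, 1, 4, 2)]   # permute within group a
  f2 <- panflux:::.permanova_F(d^2, as.integer(factor(shuffled)))
  expect_equal(f1, f2)
})

test_that("PERMANOVA agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(8)
  m <- matrix(rbinom(14 * 30, 1, 0.35), nrow = 14,
              dimnames = list(paste0("s", 1:14), paste0("r", 1:30)))
  m[, 1] <- 1
  pam <- tiny_pam(m)
  d <- jaccard_distances(pam)
  g <- factor(rep(c("a", "b"), each = 7))
  res <- permanova(d, g, n_permutations = 499, seed = 4, max_exact = 10)
  ref <- vegan::adonis2(stats::as.dist(d) ~ g, permutations = 999)
  expect_equal(res$pseudo_F, ref$F[1], tolerance = 1e-8)
  expect_equal(res$R2, ref$R2[1], tolerance = 1e-8)
})

test_that("exact enumeration agrees with seeded permutation sampling", {
  d <- jaccard_distances(sep_pam())
  g <- rep(c("g1", "g2"), each = 4)
  exact <- permanova(d, g, seed = 2)
  sampled <- permanova(d, g, n_permutations = 999, seed = 2, max_exact = 10)
  expect_false(sampled$exact)
  expect_equal(exact$pseudo_F, sampled$pseudo_F)
  expect_equal(exact$R2, sampled$R2)
  # sampled p concentrates at the permutation floor for separated groups
  expect_lte(sampled$p_value, 0.05)
  expect_gte(sampled$p_value, 1 / 1000)
  # identical seeds reproduce identical p-values
  expect_equal(sampled$p_value,
               permanova(d, g, n_permutations = 999, seed = 2, max_exact = 10)$p_value)
})

test_that("PERMANOVA input validation rejects degenerate groupings", {
  d <- jaccard_distances(sep_pam())
  expect_error(permanova(d, rep("g1", 8), seed = 1), "at least 2 groups")
  expect_error(permanova(d, c("a", rep("b", 7)), seed = 1), "singleton")
})

test_that("contingency tables have consistent margins and niche-size gating", {
  # niche of 12 strains, 8 carry; 100 outside, 10 carry
  m <- matrix(0L, nrow = 112, ncol = 1,
              dimnames = list(paste0("s", 1:112), "rx"))
  m[1:8, 1] <- 1L       # carriers inside the niche
  m[13:22, 1] <- 1L     # carriers outside
  pam <- tiny_pam(cbind(m, anchor = 1L),
                  niche = c(rep("kefir", 12), rep("other", 100)))
  tabs <- build_contingency(pam)
  row <- tabs[tabs$reaction_id == "rx" & tabs$niche == "kefir", ]
  expect_equal(unlist(row[c("a", "b", "c", "d")], use.names = FALSE),
               c(8L, 4L, 10L, 90L))
  expect_true(all(tabs$a + tabs$b + tabs$c + tabs$d == 112L))

  # a niche of exactly 10 strains is excluded (strictly more than 10 required)
  pam10 <- tiny_pam(cbind(m, anchor = 1L),
                    niche = c(rep("tiny", 10), rep("other", 102)))
  expect_false("tiny" %in% build_contingency(pam10)$niche)
})

test_that("Fisher p-values match hypergeometric enumeration", {
  expect_equal(fisher_exact(2, 0, 0, 2), 1 / 3, tolerance = 1e-12)
  expect_equal(fisher_exact(5, 5, 5, 5), 1, tolerance = 1e-12)
  set.seed(12)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    cells <- as.vector(stats::rmultinom(1, n, prob = runif(4, 0.1, 1)))
    expect_equal(do.call(fisher_exact, as.list(cells)),
                 do.call(fisher_enumerate, as.list(cells)),
                 tolerance = 1e-9)
  }
})

test_that("log odds ratios use the Haldane-Anscombe correction only on zeros", {
  expect_equal(log_odds_ratio(8, 2, 10, 80), log(32), tolerance = 1e-12)
  expect_equal(log_odds_ratio(5, 0, 2, 10),
               log((5.5 * 10.5) / (0.5 * 2.5)), tolerance = 1e-12)
  expect_equal(log_odds_ratio(7, 7, 7, 7), 0)
  # direction agreement with enrichment on uncorrected cells
  expect_gt(log_odds_ratio(8, 2, 10, 80), 0)   # 8/2 > 10/80
  expect_lt(log_odds_ratio(2, 8, 80, 10), 0)
})

test_that("chi-square matches the closed form and symmetries", {
  res <- chi_square(10, 10, 10, 10)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  obs <- c(12, 4, 6, 14)
  res2 <- chi_square(obs[1], obs[2], obs[3], obs[4])
  tab <- matrix(obs, 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res2$statistic, sum((tab - expected)^2 / expected),
               tolerance = 1e-12)
  # transposing the table leaves the statistic unchanged
  res3 <- chi_square(obs[1], obs[3], obs[2], obs[4])
  expect_equal(res2$statistic, res3$statistic)
  expect_error(chi_square(0, 0, 5, 5), "zero margin")
})

test_that("enrichment selection keeps strong, exclusive hits", {
  results <- tibble::tibble(
    reaction_id = c("r1", "r2", "r2", "r3"),
    niche = c("kefir", "kefir", "wine", "kefir"),
    a = 1, b = 1, c = 1, d = 1,
    log_or = c(6, 6, 7, 4),
    fisher_p = 0.01, chi2_p = 0.01)
  kept <- select_enriched(results, lor_min = 5)
  expect_equal(kept$reaction_id, "r1")
  both <- select_enriched(results, lor_min = 5, require_exclusive = FALSE)
  expect_setequal(both$reaction_id, c("r1", "r2"))
  expect_true(all(both$reaction_id %in% results$reaction_id))
})

test_that("PCA embedding is deterministic and variance-faithful", {
  # variation along a single reaction: one component carries everything
  m <- matrix(0L, 6, 3, dimnames = list(paste0("s", 1:6), paste0("r", 1:3)))
  m[, 1] <- c(0L, 1L, 0L, 1L, 0L, 1L)
  m[, 3] <- 1L
  emb <- pca_embed(tiny_pam(m), n_components = 1)
  expect_equal(emb$explained_variance[1], 1, tolerance = 1e-12)

  # full-rank embedding reproduces pairwise Euclidean distances
  set.seed(21)
  mm <- matrix(rbinom(8 * 10, 1, 0.5), 8,
               dimnames = list(paste0("s", 1:8), paste0("r", 1:10)))
  mm[, 1] <- 1
  full <- pca_embed(tiny_pam(mm), n_components = 7)
  centered <- scale(mm, center = TRUE, scale = FALSE)
  sc <- as.matrix(full$scores[, -1])
  expect_equal(as.matrix(stats::dist(sc)), as.matrix(stats::dist(centered)),
               ignore_attr = TRUE, tolerance = 1e-8)

  # sign convention: each component's largest-magnitude loading is positive
  for (j in seq_len(ncol(full$loadings))) {
    expect_gte(full$loadings[which.max(abs(full$loadings[, j])), j], 0)
  }
  # rank deficiency returns fewer components with a warning
  expect_warning(pca_embed(tiny_pam(m), n_components = 3), "rank")
})

test_that("k-means clustering is seeded and recovers separated blobs", {
  set.seed(2)
  pts <- rbind(matrix(rnorm(20, 0), ncol = 2),
               matrix(rnorm(20, 10), ncol = 2))
  rownames(pts) <- paste0("s", 1:20)
  cl <- kmeans_clusters(pts, k = 2, seed = 7)
  expect_length(unique(cl[1:10]), 1L)
  expect_length(unique(cl[11:20]), 1L)
  expect_false(cl[[1]] == cl[[11]])
  expect_equal(kmeans_clusters(pts, k = 2, seed = 7), cl)
  expect_length(unique(kmeans_clusters(pts, k = 1, seed = 1)), 1L)
  expect_error(kmeans_clusters(pts, k = 21, seed = 1), "exceeds")
})

test_that("planted niche-enriched reactions dominate their niche's odds ratios", {
  cfg <- synthetic_config(seed = 17, strains_per_species = 10)
  rb <- generate_reactome(cfg)
  pop <- generate_strains(rb, cfg)
  enr <- niche_enrichment(pop$truth$pam)
  for (i in seq_len(nrow(pop$truth$enriched))) {
    niche <- pop$truth$enriched$niche[i]
    planted <- pop$truth$enriched$reaction_id[i]
    sub <- enr[enr$niche == niche, ]
    expect_equal(sub$reaction_id[which.max(sub$log_or)], planted)
  }
  kept <- select_enriched(enr, lor_min = 5)
  expect_setequal(kept$reaction_id, pop$truth$enriched$reaction_id)
})
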