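test_that("reaction frequencies are percent carriage", {
  m <- matrix(c(1, 1, 1, 0,
                1, 1, 1, 1), nrow = 4, ncol = 2,
              dimnames = list(paste0("s", 1:4), c("r1", "r2")))
  pam <- tiny_pam(m)
  fr <- reaction_frequency(pam)
  expect_equal(fr$frequency[fr$reaction_id == "r1"], 75)
  expect_equal(fr$frequency[fr$reaction_id == "r2"], 100)
  # column-sum oracle
  expect_equal(fr$frequency, unname(100 * colSums(m) / nrow(m)))
  # subset restriction
  fr2 <- reaction_frequency(pam, c("s1", "s2"))
  expect_equal(fr2$frequency, c(100, 100))
  expect_error(reaction_frequency(pam, character(0)), "empty strain subset")
})

test_that("partition boundaries follow the strict-core convention", {
  freq <- tibble::tibble(
    reaction_id = c("a", "b", "c", "d", "e", "f"),
    frequency = c(100, 99, 50, 15, 14.9, 0))
  part <- partition_reactome(freq)
  cls <- stats::setNames(as.character(part$class), part$reaction_id)
  expect_equal(cls[["a"]], "core")
  expect_equal(cls[["b"]], "accessory")   # F = 99 exactly is accessory
  expect_equal(cls[["c"]], "accessory")
  expect_equal(cls[["d"]], "accessory")   # F = 15 exactly is accessory
  expect_equal(cls[["e"]], "rare")
  expect_equal(cls[["f"]], "absent")
})

test_that("the partition is exhaustive and disjoint on random frequencies", {
  set.seed(9)
  freq <- tibble::tibble(reaction_id = paste0("r", 1:500),
                         frequency = round(runif(500, 0, 100), 2))
  part <- partition_reactome(freq)
  expect_equal(nrow(part), 500L)
  expect_false(anyNA(part$class))
  observed <- part[part$frequency > 0, ]
  expect_true(all(observed$class %in% c("core", "accessory", "rare")))
  expect_true(all(part$class[part$frequency == 0] == "absent"))
})

test_that("species-unique reactions require exclusive carriage", {
  m <- matrix(c(1, 1, 0, 0,   # rX: only species X strains
                1, 0, 1, 0,   # rXY: crosses species
                0, 0, 0, 0),  # rNone: nowhere
              nrow = 4, ncol = 3,
              dimnames = list(paste0("s", 1:4), c("rX", "rXY", "rNone")))
  pam <- tiny_pam(m, species = c("X", "X", "Y", "Y"))
  uq <- unique_reactions(pam)
  expect_equal(uq$reaction_id, "rX")
  expect_equal(uq$species, "X")
  expect_equal(uq$n_strains, 2)

  # exhaustive scan oracle over all (reaction, species) pairs
  meta_sp <- c(s1 = "X", s2 = "X", s3 = "Y", s4 = "Y")
  brute <- list()
  for (rid in colnames(m)) {
    for (sp in unique(meta_sp)) {
      inside <- sum(m[names(meta_sp)[meta_sp == sp], rid])
      outside <- sum(m[names(meta_sp)[meta_sp != sp], rid])
      if (inside > 0 && outside == 0) brute[[length(brute) + 1L]] <- c(rid, sp)
    }
  }
  expect_equal(nrow(uq), length(brute))

  # invariant to strain ordering
  perm <- tiny_pam(m[c(3, 1, 4, 2), ], species = c("Y", "X", "Y", "X"))
  expect_equal(unique_reactions(perm), uq)
})

test_that("unique reactions demand complete species labels", {
  m <- matrix(1, 2, 1, dimnames = list(c("s1", "s2"), "r1"))
  pam <- tiny_pam(m, species = c("X", NA))
  expect_error(unique_reactions(pam), "species metadata")
})

test_that("intra-species percentages partition the observed reactome", {
  m <- matrix(c(1, 1, 1,   # backbone, all three strains
                1, 0, 0,   # private to s1
                0, 1, 0,   # private to s2
                0, 0, 1),  # private to s3
              nrow = 3, ncol = 4, byrow = FALSE,
              dimnames = list(paste0("s", 1:3), c("bb", "p1", "p2", "p3")))
  pam <- tiny_pam(m)
  res <- intra_species_partition(pam)
  expect_equal(res$core_pct, 25)   # backbone of 4 observed reactions
  expect_equal(res$rare_pct, 0)    # privates are 33.3% of 3 strains: accessory
  expect_equal(res$core_pct + res$accessory_pct + res$rare_pct, 100,
               tolerance = 0.1)

  # identical strains: all core
  ident <- tiny_pam(matrix(1, 3, 4, dimnames = dimnames(m)))
  res2 <- intra_species_partition(ident)
  expect_equal(res2$core_pct, 100)
  expect_equal(res2$accessory_pct, 0)

  # species below the strain minimum are skipped with a warning
  solo <- tiny_pam(m, species = c("spA", "spA", "spB"))
  expect_warning(res3 <- intra_species_partition(solo), "skipped")
  expect_equal(res3$species, "spA")
})

test_that("duplicating a strain never demotes a core reaction", {
  cfg <- small_cfg(seed = 13)
  rb <- generate_reactome(cfg)
  pop <- generate_strains(rb, cfg)
  pam <- pop$truth$pam
  part0 <- partition_reactome(reaction_frequency(pam))
  core0 <- part0$reaction_id[part0$class == "core"]

  mat <- unclass(pam)
  dup <- rbind(mat, clone = mat[1, ])
  rownames(dup) <- c(rownames(mat), "clone")
  meta <- attr(pam, "metadata")
  meta2 <- dplyr::bind_rows(meta, dplyr::mutate(meta[1, ], strain_id = "clone"))
  profiles <- lapply(stats::setNames(nm = rownames(dup)), function(s)
    stats::setNames(dup[s, ] == 1, colnames(dup)))
  pam2 <- build_presence_matrix(profiles, meta2)
  part1 <- partition_reactome(reaction_frequency(pam2))
  core1 <- part1$reaction_id[part1$class == "core"]
  expect_true(all(core0 %in% core1))
})
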