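test_that("generated reactomes are balanced, cycle-free and deterministic", {
  cfg <- small_cfg(seed = 6)
  rb <- generate_reactome(cfg)
  expect_equal(nrow(check_mass_charge_balance(rb$reactome)), 0L)
  expect_length(detect_infeasible_cycles(rb$reactome), 0L)

  # identical configs give byte-identical SBML
  f1 <- withr::local_tempfile(fileext = ".xml")
  f2 <- withr::local_tempfile(fileext = ".xml")
  write_reactome_sbml(rb$reactome, f1)
  write_reactome_sbml(generate_reactome(small_cfg(seed = 6))$reactome, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("breaking the planted core pathway abolishes growth", {
  cfg <- small_cfg(seed = 6)
  rb <- generate_reactome(cfg)
  med <- generate_medium(cfg)
  expect_true(verify_functionality(rb$reactome, med))
  pres <- stats::setNames(rb$reactome$reactions$id != "GLY", rb$reactome$reactions$id)
  broken <- assemble_draft(rb$reactome, pres, "broken")
  expect_false(verify_functionality(broken, med))
})

test_that("every generated strain grows above threshold on the generated medium", {
  cfg <- small_cfg(seed = 11)
  rb <- generate_reactome(cfg)
  med <- generate_medium(cfg)
  pop <- generate_strains(rb, cfg)
  mods <- map_strains(pop$similarities, rb$reactome, pop$metadata)
  growth <- vapply(mods, function(m) fba(m, med)$objective_value, numeric(1))
  expect_true(all(growth > 0.01))
  # growth matches the planted closed-form rates under per-strain uptakes
  truth <- pop$truth$growth
  for (s in names(mods)[c(1, 6, 11)]) {
    tab <- tibble::as_tibble(med)
    tab$uptake[tab$exchange_id == "EX_glc_e"] <-
      truth$glc_uptake[truth$strain_id == s]
    expect_equal(fba(mods[[s]], medium(tab))$objective_value,
                 truth$growth_rate[truth$strain_id == s], tolerance = 1e-6)
  }
})

test_that("noiseless mapping recovers the planted presence-absence matrix", {
  cfg <- small_cfg(seed = 23)
  rb <- generate_reactome(cfg)
  pop <- generate_strains(rb, cfg)
  mods <- map_strains(pop$similarities, rb$reactome, pop$metadata)
  pam <- build_presence_matrix(mods, pop$metadata, reactome = rb$reactome)
  planted <- unclass(pop$truth$pam)
  expect_equal(unclass(pam)[rownames(planted), colnames(planted)], planted,
               ignore_attr = TRUE)
})

test_that("adversarial near-threshold identities still separate at the 70% rule", {
  cfg <- small_cfg(seed = 31, identity_mode = "adversarial")
  rb <- generate_reactome(cfg)
  pop <- generate_strains(rb, cfg)
  mods <- map_strains(pop$similarities, rb$reactome, pop$metadata)
  pam <- build_presence_matrix(mods, pop$metadata, reactome = rb$reactome)
  planted <- unclass(pop$truth$pam)
  expect_equal(unclass(pam)[rownames(planted), colnames(planted)], planted,
               ignore_attr = TRUE)
})

test_that("planted auxotrophies land in the configured species", {
  cfg <- small_cfg(seed = 11)
  pop <- generate_strains(generate_reactome(cfg), cfg)
  aux <- pop$truth$auxotrophies
  sp2 <- aux[grepl("^sp2_", aux$strain_id), ]
  expect_true(all(c("EX_glc_e", "EX_aa3_e") %in% sp2$component))
  sp1 <- aux[grepl("^sp1_", aux$strain_id), ]
  expect_equal(sort(unique(sp1$component)), "EX_glc_e")
})

test_that("dropout removes only accessory content and respects the seed", {
  cfg <- small_cfg(seed = 41, dropout_rate = 0.3, strains_per_species = 8)
  rb <- generate_reactome(cfg)
  pop1 <- generate_strains(rb, cfg)
  pop2 <- generate_strains(rb, cfg)
  expect_identical(pop1$profiles, pop2$profiles)   # same seed, same dropout
  # core reactions are never dropped
  core_ids <- rb$roles$id[rb$roles$role == "core"]
  for (p in pop1$profiles) expect_true(all(p[core_ids]))
  # some accessory content is actually lost at 30% dropout
  acc_ids <- rb$roles$id[rb$roles$role == "species_accessory"]
  lost <- vapply(names(pop1$profiles), function(s) {
    own <- acc_ids[rb$roles$species[match(acc_ids, rb$roles$id)] ==
                     pop1$metadata$species[pop1$metadata$strain_id == s]]
    sum(!pop1$profiles[[s]][own])
  }, numeric(1))
  expect_gt(sum(lost), 0)
})

test_that("the fixture bundle feeds every pipeline stage from disk", {
  dir <- withr::local_tempdir()
  cfg <- small_cfg(seed = 19)
  bundle <- emit_fixture_bundle(cfg, dir)
  reactome <- load_reactome(file.path(dir, "reactome.sbml.xml"),
                            file.path(dir, "gprs.tsv"))
  med <- read_medium_tsv(file.path(dir, "medium.tsv"))
  sims <- read_similarity_tsv(file.path(dir, "similarities.tsv"))
  meta <- readr::read_tsv(file.path(dir, "metadata.tsv"), show_col_types = FALSE)
  mods <- map_strains(sims, reactome, meta)
  pam <- build_presence_matrix(mods, meta, reactome = reactome)
  planted <- read_presence_matrix(file.path(dir, "planted_pam.csv"),
                                  file.path(dir, "planted_pam_metadata.tsv"))
  expect_equal(unclass(pam)[rownames(planted), colnames(planted)],
               unclass(planted), ignore_attr = TRUE)
  expect_true(verify_functionality(mods[[1]], med))

  # manifest hashes are stable for one seed
  dir2 <- withr::local_tempdir()
  bundle2 <- emit_fixture_bundle(cfg, dir2)
  expect_equal(bundle$manifest$md5, bundle2$manifest$md5)

  # a different seed changes strain files but not the reactome topology
  bundle3 <- emit_fixture_bundle(small_cfg(seed = 20), withr::local_tempdir())
  expect_equal(nrow(bundle3$reactome$reactions), nrow(bundle$reactome$reactions))
  expect_false(identical(bundle3$strains$similarities, bundle$strains$similarities))
})
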