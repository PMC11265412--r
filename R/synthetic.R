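#' Configuration for the synthetic pan-genome generator
#'
#' The generator emits a small, exactly mass- and charge-balanced mock
#' pan-reactome with the architecture of a family-wide template: a
#' glucose-to-biomass core pathway with ATP/redox currency and NGAM,
#' per-species accessory branches (an alternative carbon source and a
#' fermentation overflow branch each), species-unique and rare dead-end
#' reactions, amino-acid biosynthesis modules that can be knocked out to
#' plant auxotrophies, multi-allelic GPRs, and niche labels with planted
#' niche-enriched reactions. All randomness is governed by `seed`.
#'
#' @param n_species,strains_per_species Population structure; defaults 3 x 5.
#' @param n_amino_acids Mock amino acids (biosynthesis module + exchange
#'   each); default 6. The first two are the glutamate/aspartate analogues
#'   with doubled uptake in the generated medium.
#' @param n_unique_per_species Dead-end reactions exclusive to each species.
#' @param n_rare_reactions Family-wide rare-reaction pool, each carried by
#'   1-2 strains.
#' @param auxotrophy_plan Named list: species id -> amino-acid ids whose
#'   biosynthesis module that species lacks.
#' @param niche_plan Character vector of niche labels; each niche gets one
#'   planted enriched reaction carried by exactly its members. Strains are
#'   stratified round-robin across niches within every species.
#' @param allele_multiplicity GPR alternatives per gene-associated reaction.
#' @param dropout_rate Probability that a strain loses one of its species'
#'   accessory reactions; default 0 (noiseless).
#' @param glc_uptake,aa_uptake,rich_aa_uptake,am_uptake Medium uptake
#'   magnitudes (mmol/gDCW/h).
#' @param ngam Non-growth-associated maintenance flux.
#' @param uptake_range Per-strain glucose uptake scaling interval planting
#'   growth-rate diversity.
#' @param identity_mode `"separated"` (carried alleles 85-100%, absent
#'   30-60%) or `"adversarial"` (70-80% vs 60-69.9%, probing the BBH
#'   boundary).
#' @param seed Integer seed (mandatory).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_species = 3, strains_per_species = 5,
                             n_amino_acids = 6, n_unique_per_species = 2,
                             n_rare_reactions = 4,
                             auxotrophy_plan = list(sp2 = "aa3", sp3 = "aa5"),
                             niche_plan = c("kefir_like", "brine_like"),
                             allele_multiplicity = 2, dropout_rate = 0,
                             glc_uptake = 10, aa_uptake = 1, rich_aa_uptake = 2,
                             am_uptake = 10, ngam = 1, uptake_range = c(6, 14),
                             identity_mode = c("separated", "adversarial"),
                             seed) {
  stopifnot(n_species >= 1, strains_per_species >= 1, n_amino_acids >= 3,
            dropout_rate >= 0, dropout_rate <= 1, !missing(seed))
  aa_ids <- paste0("aa", seq_len(n_amino_acids))
  bad <- setdiff(unlist(auxotrophy_plan), aa_ids)
  if (length(bad)) stop("auxotrophy plan names unknown amino acid(s): ",
                        paste(bad, collapse = ", "))
  structure(list(
    n_species = n_species, strains_per_species = strains_per_species,
    n_amino_acids = n_amino_acids, n_unique_per_species = n_unique_per_species,
    n_rare_reactions = n_rare_reactions, auxotrophy_plan = auxotrophy_plan,
    niche_plan = niche_plan, allele_multiplicity = allele_multiplicity,
    dropout_rate = dropout_rate, glc_uptake = glc_uptake,
    aa_uptake = aa_uptake, rich_aa_uptake = rich_aa_uptake,
    am_uptake = am_uptake, ngam = ngam, uptake_range = uptake_range,
    identity_mode = match.arg(identity_mode), seed = as.integer(seed)),
    class = "synthetic_config")
}

# biomass coefficients of the mock core chemistry
.syn_biomass_lac <- 1
.syn_biomass_aa <- 0.25
.syn_biomass_atp <- 4

.syn_gpr <- function(rid, mult) {
  alts <- lapply(seq_len(mult), function(k) {
    if (k %% 2 == 0) paste0(rid, "_a", k, c("x", "y")) else paste0(rid, "_a", k)
  })
  do.call(gpr_rule, alts)
}

#' Generate the synthetic pan-reactome
#'
#' Builds the template network described in [synthetic_config()]. The
#' emitted reactome passes [check_mass_charge_balance()] with an empty
#' report and contains no thermodynamically infeasible cycles. The result is
#' deterministic for a given config (the reactome topology depends only on
#' the config's counts, not on the seed).
#'
#' @param config A [synthetic_config()].
#' @return List: `reactome` (a [pan_reactome()]) and `roles` (tibble
#'   `reaction_id`, `role`, `species` documenting the planted architecture:
#'   `universal`, `core`, `aa_module`, `species_accessory`, `unique`,
#'   `rare_pool`, `niche_enriched`).
#' @export
generate_reactome <- function(config) {
  sp_ids <- paste0("sp", seq_len(config$n_species))
  aa_ids <- paste0("aa", seq_len(config$n_amino_acids))

  mets <- list()
  met <- function(id, formula, compartment = "c", name = id, charge = 0L) {
    mets[[length(mets) + 1L]] <<- tibble::tibble(
      id = id, name = name, formula = formula, charge = charge,
      compartment = compartment)
  }
  met("glc_e", "C6H12O6", "e"); met("glc", "C6H12O6")
  met("pyr", "C3H4O3"); met("lac", "C3H6O3"); met("lac_e", "C3H6O3", "e")
  met("am_e", "H3N", "e"); met("am", "H3N")
  met("atp", "AdP3"); met("adp", "AdP2"); met("p", "P")
  met("nad", "Nc"); met("nadh", "H2Nc")
  for (aa in aa_ids) {
    met(paste0("pre_", aa), "C3H9NO3")
    met(aa, "C3H9NO3"); met(paste0(aa, "_e"), "C3H9NO3", "e")
  }
  for (sp in sp_ids) {
    met(paste0("ferm_", sp), "C3H6O3"); met(paste0("ferm_", sp, "_e"), "C3H6O3", "e")
    met(paste0("csrc_", sp), "C6H12O6"); met(paste0("csrc_", sp, "_e"), "C6H12O6", "e")
    for (j in seq_len(config$n_unique_per_species)) {
      met(paste0("umet_", sp, "_", j), "C3H4O3")
    }
  }
  for (j in seq_len(config$n_rare_reactions)) met(paste0("raremet_", j), "C3H4O3")
  for (nc in config$niche_plan) met(paste0("nichemet_", nc), "C3H4O3")

  rxns <- list(); st <- list(); roles <- list()
  rx <- function(id, stoich, rtype, role, species = NA_character_,
                 lb = 0, ub = .panflux_big_bound, subsystem = "core", name = id) {
    rxns[[length(rxns) + 1L]] <<- tibble::tibble(
      id = id, name = name, lower_bound = lb, upper_bound = ub,
      subsystem = subsystem, rtype = rtype)
    st[[length(st) + 1L]] <<- tibble::tibble(
      reaction_id = id, metabolite_id = names(stoich),
      coefficient = unname(stoich))
    roles[[length(roles) + 1L]] <<- tibble::tibble(
      id = id, role = role, species = species)
  }
  ex <- function(met_id, role = "universal") {
    rx(paste0("EX_", met_id), c(-1) |> stats::setNames(met_id), "exchange", role,
       subsystem = "exchange")
  }

  ex("glc_e")
  rx("T_glc", c(glc_e = -1, glc = 1), "gene_associated", "core", subsystem = "transport")
  rx("GLY", c(glc = -1, adp = -2, p = -2, nad = -2, pyr = 2, atp = 2, nadh = 2),
     "gene_associated", "core", subsystem = "glycolysis")
  rx("LDH", c(pyr = -1, nadh = -1, lac = 1, nad = 1), "gene_associated", "core",
     subsystem = "fermentation")
  rx("T_lac", c(lac = -1, lac_e = 1), "gene_associated", "core", subsystem = "transport")
  ex("lac_e")
  rx("T_am", c(am_e = -1, am = 1), "spontaneous", "universal", subsystem = "transport")
  ex("am_e")
  rx("NGAM", c(atp = -1, adp = 1, p = 1), "orphan", "universal", lb = config$ngam,
     subsystem = "maintenance")
  bio <- c(stats::setNames(rep(-.syn_biomass_aa, length(aa_ids)), aa_ids),
           lac = -.syn_biomass_lac, atp = -.syn_biomass_atp,
           adp = .syn_biomass_atp, p = .syn_biomass_atp)
  rx("BIOMASS", bio, "biomass", "universal", subsystem = "biomass")

  for (aa in aa_ids) {
    rx(paste0("AAS_", aa), c(lac = -1, am = -1) |>
         c(stats::setNames(1, paste0("pre_", aa))), "gene_associated",
       "aa_module", subsystem = "amino acid biosynthesis")
    rx(paste0("MAT_", aa),
       stats::setNames(c(-1, 1), c(paste0("pre_", aa), aa)),
       "gene_associated", "aa_module", subsystem = "amino acid biosynthesis")
    rx(paste0("T_", aa), stats::setNames(c(-1, 1), c(paste0(aa, "_e"), aa)),
       "gene_associated", "core", subsystem = "transport")
    ex(paste0(aa, "_e"))
  }
  for (sp in sp_ids) {
    rx(paste0("FER_", sp),
       stats::setNames(c(-1, -1, 1, 1), c("pyr", "nadh", paste0("ferm_", sp), "nad")),
       "gene_associated", "species_accessory", species = sp, subsystem = "fermentation")
    rx(paste0("T_ferm_", sp),
       stats::setNames(c(-1, 1), paste0("ferm_", sp, c("", "_e"))),
       "gene_associated", "species_accessory", species = sp, subsystem = "transport")
    ex(paste0("ferm_", sp, "_e"))
    rx(paste0("T_csrc_", sp),
       stats::setNames(c(-1, 1), paste0("csrc_", sp, c("_e", ""))),
       "gene_associated", "species_accessory", species = sp, subsystem = "transport")
    rx(paste0("ISO_csrc_", sp),
       stats::setNames(c(-1, 1), c(paste0("csrc_", sp), "glc")),
       "gene_associated", "species_accessory", species = sp, subsystem = "sugar catabolism")
    ex(paste0("csrc_", sp, "_e"))
    for (j in seq_len(config$n_unique_per_species)) {
      rx(paste0("U_", sp, "_", j),
         stats::setNames(c(-1, 1), c("pyr", paste0("umet_", sp, "_", j))),
         "gene_associated", "unique", species = sp, subsystem = "species-specific")
    }
  }
  for (j in seq_len(config$n_rare_reactions)) {
    rx(paste0("RARE_", j), stats::setNames(c(-1, 1), c("pyr", paste0("raremet_", j))),
       "gene_associated", "rare_pool", subsystem = "rare")
  }
  for (nc in config$niche_plan) {
    rx(paste0("NICHE_", nc), stats::setNames(c(-1, 1), c("pyr", paste0("nichemet_", nc))),
       "gene_associated", "niche_enriched", subsystem = "niche adaptation")
  }

  reactions <- dplyr::bind_rows(rxns)
  gprs <- lapply(stats::setNames(nm = reactions$id[reactions$rtype == "gene_associated"]),
                 .syn_gpr, mult = config$allele_multiplicity)
  reactome <- pan_reactome(dplyr::bind_rows(mets), reactions, dplyr::bind_rows(st),
                           gprs, biomass_id = "BIOMASS", ngam_id = "NGAM")
  list(reactome = reactome, roles = dplyr::bind_rows(roles))
}

#' Generate the chemically defined mock medium
#'
#' Glucose at the configured uptake, every amino acid at 1 mmol/gDCW/h
#' except the first two (the glutamate/aspartate analogues) at 2, and the
#' nitrogen source. Exchanges not listed (fermentation products, alternative
#' carbon sources) are closed to uptake when the medium is applied.
#'
#' @param config A [synthetic_config()].
#' @return A [medium()].
#' @export
generate_medium <- function(config) {
  aa_ids <- paste0("aa", seq_len(config$n_amino_acids))
  up <- c(stats::setNames(config$glc_uptake, "EX_glc_e"),
          stats::setNames(config$am_uptake, "EX_am_e"),
          stats::setNames(
            ifelse(aa_ids %in% c("aa1", "aa2"), config$rich_aa_uptake, config$aa_uptake),
            paste0("EX_", aa_ids, "_e")))
  medium(up, name = "synthetic CDM")
}

# analytic growth rate of the planted chemistry under the generated medium
.syn_growth <- function(config, glc_uptake, deleted_aas) {
  mu_atp <- (2 * glc_uptake - config$ngam) / .syn_biomass_atp
  caps <- vapply(deleted_aas, function(aa) {
    up <- if (aa %in% c("aa1", "aa2")) config$rich_aa_uptake else config$aa_uptake
    up / .syn_biomass_aa
  }, numeric(1))
  max(min(c(mu_atp, caps)), 0)
}

#' Generate the strain population with planted ground truth
#'
#' Draws the strain presence profiles (core + own-species accessory minus
#' dropout, minus the auxotrophy plan's biosynthesis modules, plus assigned
#' unique/rare/niche reactions), the bidirectional-best-hit similarity
#' table, the strain metadata, and a ground-truth record of everything
#' planted. Fully deterministic under the config's seed.
#'
#' @param reactome_bundle Output of [generate_reactome()].
#' @param config The same [synthetic_config()].
#' @return List: `profiles` (named list of presence vectors), `similarities`
#'   (tibble), `metadata` (tibble `strain_id`, `species`, `genus`,
#'   `isolation_source`), and `truth` — a list with `pam` (planted
#'   `presence_absence`), `partition` (planted family classes), `unique`
#'   (planted species-unique sets), `auxotrophies` (strain x essential
#'   exchange), `enriched` (niche -> planted reaction), `growth` (tibble
#'   `strain_id`, `glc_uptake`, `growth_rate` from the closed-form planted
#'   chemistry).
#' @export
generate_strains <- function(reactome_bundle, config) {
  reactome <- reactome_bundle$reactome
  roles <- reactome_bundle$roles
  sp_ids <- paste0("sp", seq_len(config$n_species))
  strains <- unlist(lapply(sp_ids, function(sp)
    paste0(sp, "_st", seq_len(config$strains_per_species))))
  species_of <- stats::setNames(rep(sp_ids, each = config$strains_per_species), strains)
  genus_of <- stats::setNames(paste0("g", ceiling(match(species_of, sp_ids) / 2)), strains)
  niche_of <- stats::setNames(unlist(lapply(sp_ids, function(sp)
    rep(config$niche_plan, length.out = config$strains_per_species))), strains)

  ga <- roles$id[roles$id %in% names(reactome$gprs)]
  role_of <- stats::setNames(roles$role, roles$id)
  role_sp <- stats::setNames(roles$species, roles$id)

  with_seed(config$seed, {
    # assignments for unique (subset of own species) and rare (1-2 strains)
    unique_carriers <- list()
    for (rid in roles$id[roles$role == "unique"]) {
      sp <- role_sp[[rid]]
      sp_strains <- strains[species_of == sp]
      n_carry <- sample(seq_len(min(3, length(sp_strains))), 1)
      unique_carriers[[rid]] <- sort(sample(sp_strains, n_carry))
    }
    rare_carriers <- list()
    for (rid in roles$id[roles$role == "rare_pool"]) {
      rare_carriers[[rid]] <- sort(sample(strains, sample(1:2, 1)))
    }

    deleted_of <- lapply(stats::setNames(nm = strains), function(s) {
      as.character(unlist(config$auxotrophy_plan[[species_of[[s]]]]))
    })

    profiles <- lapply(stats::setNames(nm = strains), function(s) {
      sp <- species_of[[s]]
      pres <- stats::setNames(rep(FALSE, length(ga)), ga)
      pres[ga[role_of[ga] == "core"]] <- TRUE
      module_aas <- setdiff(paste0("aa", seq_len(config$n_amino_acids)), deleted_of[[s]])
      pres[c(paste0("AAS_", module_aas), paste0("MAT_", module_aas))] <- TRUE
      acc <- ga[role_of[ga] == "species_accessory" & role_sp[ga] == sp]
      kept <- acc[stats::runif(length(acc)) >= config$dropout_rate]
      pres[kept] <- TRUE
      for (rid in names(unique_carriers)) if (s %in% unique_carriers[[rid]]) pres[rid] <- TRUE
      for (rid in names(rare_carriers)) if (s %in% rare_carriers[[rid]]) pres[rid] <- TRUE
      pres[paste0("NICHE_", niche_of[[s]])] <- TRUE
      pres
    })

    id_carried <- function(n) switch(config$identity_mode,
      separated = stats::runif(n, 85, 100), adversarial = stats::runif(n, 70, 80))
    id_absent <- function(n) switch(config$identity_mode,
      separated = stats::runif(n, 30, 60), adversarial = stats::runif(n, 60, 69.9))

    sims <- purrr::map_dfr(strains, function(s) {
      pres <- profiles[[s]]
      gene_i <- 0L
      purrr::map_dfr(ga, function(rid) {
        rule <- reactome$gprs[[rid]]
        if (pres[[rid]]) {
          alt <- rule[[sample.int(length(rule), 1)]]
          gene_i <<- gene_i + length(alt)
          tibble::tibble(strain_id = s,
                         strain_gene = paste0(s, "_g", gene_i - seq_along(alt) + 1L),
                         allele = alt,
                         pident_fwd = round(id_carried(length(alt)), 2),
                         pident_rev = round(id_carried(length(alt)), 2),
                         mutual_best = 1L)
        } else {
          # spurious sub-threshold or non-mutual signal against one allele
          allele <- rule[[1]][1]
          gene_i <<- gene_i + 1L
          nonmutual <- stats::runif(1) < 0.2
          tibble::tibble(strain_id = s,
                         strain_gene = paste0(s, "_g", gene_i),
                         allele = allele,
                         pident_fwd = round(if (nonmutual) stats::runif(1, 75, 95) else id_absent(1), 2),
                         pident_rev = round(if (nonmutual) stats::runif(1, 75, 95) else id_absent(1), 2),
                         mutual_best = if (nonmutual) 0L else 1L)
        }
      })
    })

    uptakes <- sample(seq(config$uptake_range[1], config$uptake_range[2],
                          length.out = length(strains)))
  })

  metadata <- tibble::tibble(strain_id = strains, species = unname(species_of),
                             genus = unname(genus_of),
                             isolation_source = unname(niche_of))

  universe <- reactome$reactions$id
  pam_rows <- lapply(profiles, function(pres) {
    full <- stats::setNames(rep(TRUE, length(universe)), universe)
    full[names(pres)] <- pres
    full
  })
  pam <- build_presence_matrix(pam_rows, metadata)

  freq <- 100 * colMeans(unclass(pam))
  planted_class <- ifelse(freq > 99, "core",
                   ifelse(freq >= 15, "accessory",
                   ifelse(freq > 0, "rare", "absent")))
  carriers <- apply(unclass(pam), 2, function(col) unique(species_of[rownames(pam)[col == 1]]),
                    simplify = FALSE)
  planted_unique <- purrr::map_dfr(universe, function(rid) {
    sps <- carriers[[rid]]
    if (length(sps) == 1L && sum(unclass(pam)[, rid]) > 0) {
      tibble::tibble(reaction_id = rid, species = sps)
    } else tibble::tibble()
  })

  aux <- purrr::map_dfr(strains, function(s) {
    del <- deleted_of[[s]]
    comps <- c("EX_glc_e", if (length(del)) paste0("EX_", del, "_e"))
    tibble::tibble(strain_id = s, component = comps)
  })

  growth <- tibble::tibble(
    strain_id = strains,
    glc_uptake = uptakes,
    growth_rate = vapply(strains, function(s)
      .syn_growth(config, uptakes[[match(s, strains)]], deleted_of[[s]]),
      numeric(1), USE.NAMES = FALSE))

  truth <- list(
    pam = pam,
    partition = tibble::tibble(reaction_id = universe, frequency = unname(freq),
                               class = unname(planted_class)),
    unique = planted_unique,
    auxotrophies = aux,
    enriched = tibble::tibble(niche = config$niche_plan,
                              reaction_id = paste0("NICHE_", config$niche_plan)),
    growth = growth)
  list(profiles = profiles, similarities = sims, metadata = metadata, truth = truth)
}

#' Write a complete synthetic fixture bundle to disk
#'
#' One call produces every input the pipeline stages read — the reactome
#' SBML, the GPR sidecar TSV, the medium TSV, the similarity table, the
#' strain metadata, the planted presence-absence matrix — plus a
#' ground-truth JSON and a manifest of file hashes. Byte-stable across runs
#' with one seed.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the generated objects (`reactome`,
#'   `roles`, `medium`, `strains`) and `manifest` (tibble `file`, `md5`).
#' @export
emit_fixture_bundle <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rb <- generate_reactome(config)
  med <- generate_medium(config)
  pop <- generate_strains(rb, config)
  paths <- c(
    reactome = file.path(dir, "reactome.sbml.xml"),
    gprs = file.path(dir, "gprs.tsv"),
    medium = file.path(dir, "medium.tsv"),
    similarities = file.path(dir, "similarities.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    pam = file.path(dir, "planted_pam.csv"),
    pam_meta = file.path(dir, "planted_pam_metadata.tsv"),
    truth = file.path(dir, "ground_truth.json"))
  write_reactome_sbml(rb$reactome, paths[["reactome"]])
  write_gpr_tsv(rb$reactome$gprs, paths[["gprs"]])
  write_medium_tsv(med, paths[["medium"]])
  readr::write_tsv(pop$similarities, paths[["similarities"]])
  readr::write_tsv(pop$metadata, paths[["metadata"]])
  write_presence_matrix(pop$truth$pam, paths[["pam"]], paths[["pam_meta"]])
  truth_json <- pop$truth
  truth_json$pam <- NULL
  jsonlite::write_json(truth_json, paths[["truth"]], digits = NA, pretty = TRUE)
  manifest <- tibble::tibble(file = basename(unname(paths)),
                             md5 = unname(tools::md5sum(unname(paths))))
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  invisible(list(reactome = rb$reactome, roles = rb$roles, medium = med,
                 strains = pop, manifest = manifest))
}

#' Generate a small gapfilling benchmark instance
#'
#' Builds a linear biosynthetic pathway whose segments each hold one or two
#' parallel isoenzyme reactions, deletes a random subset of the segment
#' reactions from the strain model, and offers the deleted reactions plus
#' dead-end decoys as gapfill candidates. The certified minimum addition is
#' one reaction per fully-deleted segment, which [gapfill_brute_force()] can
#' verify exhaustively.
#'
#' @param seed Integer seed.
#' @param n_segments Pathway length; default 6.
#' @param n_decoys Dead-end candidate reactions; default 4.
#' @param p_parallel Probability a segment has a redundant parallel
#'   reaction.
#' @param p_delete Per-reaction deletion probability.
#' @return List: `model` (broken draft), `reactome` (template), `medium`,
#'   `deleted` (removed reaction ids), `candidates`.
#' @export
generate_gapfill_instance <- function(seed, n_segments = 6, n_decoys = 4,
                                      p_parallel = 0.4, p_delete = 0.35) {
  with_seed(seed, {
    mets <- tibble::tibble(
      id = c("s_e", paste0("m", 0:n_segments), "fuel",
             paste0("dead", seq_len(n_decoys))),
      name = c("s_e", paste0("m", 0:n_segments), "fuel",
               paste0("dead", seq_len(n_decoys))),
      formula = "C1", charge = 0L,
      compartment = c("e", rep("c", n_segments + 1 + 1 + n_decoys)))
    rxns <- list(); st <- list()
    rx <- function(id, stoich, rtype, lb = 0, ub = 1000) {
      rxns[[length(rxns) + 1L]] <<- tibble::tibble(
        id = id, name = id, lower_bound = lb, upper_bound = ub,
        subsystem = "toy", rtype = rtype)
      st[[length(st) + 1L]] <<- tibble::tibble(
        reaction_id = id, metabolite_id = names(stoich), coefficient = unname(stoich))
    }
    rx("EX_s_e", c(s_e = -1), "exchange")
    rx("T_s", c(s_e = -1, m0 = 1), "gene_associated")
    seg_rxns <- character(0)
    seg_of <- character(0)
    for (i in seq_len(n_segments)) {
      n_par <- if (stats::runif(1) < p_parallel) 2L else 1L
      for (k in seq_len(n_par)) {
        rid <- paste0("SEG", i, letters[k])
        rx(rid, stats::setNames(c(-1, 1), paste0("m", c(i - 1, i))), "gene_associated")
        seg_rxns <- c(seg_rxns, rid)
        seg_of <- c(seg_of, as.character(i))
      }
    }
    for (j in seq_len(n_decoys)) {
      rx(paste0("DECOY", j), stats::setNames(c(-1, 1), c("m0", paste0("dead", j))),
         "gene_associated")
    }
    rx("SRC_fuel", c(fuel = 1), "orphan")
    rx("NGAM", c(fuel = -1), "orphan", lb = 0)
    rx("BIOMASS", stats::setNames(-1, paste0("m", n_segments)), "biomass")
    reactions <- dplyr::bind_rows(rxns)
    ga <- reactions$id[reactions$rtype == "gene_associated"]
    gprs <- lapply(stats::setNames(nm = ga), function(rid) gpr_rule(paste0(rid, "_a1")))
    reactome <- pan_reactome(mets, reactions, dplyr::bind_rows(st), gprs,
                             biomass_id = "BIOMASS", ngam_id = "NGAM")
    deleted <- seg_rxns[stats::runif(length(seg_rxns)) < p_delete]
    # always knock out one full segment so the pathway is genuinely broken
    knockout <- sample(seq_len(n_segments), 1)
    deleted <- sort(unique(c(deleted, seg_rxns[seg_of == as.character(knockout)])))
    decoys <- paste0("DECOY", seq_len(n_decoys))
    pres <- stats::setNames(!reactome$reactions$id %in% c(deleted, decoys),
                            reactome$reactions$id)
    model <- assemble_draft(reactome, pres, strain_id = paste0("toy", seed))
    med <- medium(c(EX_s_e = 10), name = "toy medium")
    list(model = model, reactome = reactome, medium = med, deleted = deleted,
         candidates = sort(c(deleted, decoys)))
  })
}
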