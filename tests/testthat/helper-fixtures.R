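# Hand-built toy networks used across the test files. All are constructed
# in code; nothing is read from disk except where file I/O itself is under
# test.

# Linear uptake -> conversion -> biomass chain:
#   EX_A (uptake <= uptake), T: A_e -> A, CONV: A -> B, BIOMASS: B ->
# plus an orphan fuel loop so the NGAM floor is always satisfiable.
toy_chain_reactome <- function(uptake = 10, yield = 1) {
  mets <- tibble::tibble(
    id = c("A_e", "A", "B", "fuel"),
    name = c("A_e", "A", "B", "fuel"),
    formula = c("C2H4", "C2H4", "C2H4", "R"),
    charge = 0L,
    compartment = c("e", "c", "c", "c"))
  rxns <- tibble::tibble(
    id = c("EX_A_e", "T_A", "CONV", "SRC_fuel", "NGAM", "BIOMASS"),
    name = id, lower_bound = c(-uptake, 0, 0, 0, 0, 0),
    upper_bound = 1000, subsystem = "toy",
    rtype = c("exchange", "gene_associated", "gene_associated",
              "orphan", "orphan", "biomass"))
  st <- tibble::tibble(
    reaction_id = c("EX_A_e", "T_A", "T_A", "CONV", "CONV", "SRC_fuel",
                    "NGAM", "BIOMASS"),
    metabolite_id = c("A_e", "A_e", "A", "A", "B", "fuel", "fuel", "B"),
    coefficient = c(-1, -1, 1, -1, yield, 1, -1, -1))
  gprs <- list(T_A = gpr_rule("tA_a1"), CONV = gpr_rule("conv_a1"))
  pan_reactome(mets, rxns, st, gprs, biomass_id = "BIOMASS", ngam_id = "NGAM")
}

toy_chain_medium <- function(uptake = 10) medium(c(EX_A_e = uptake), name = "toy")

# Homolactic toy: glucose -> 2 lactate, biomass drains lactate with yield 1,
# lactate can also be secreted. Uptake u gives optimum growth 2u - secretion.
homolactic_reactome <- function() {
  mets <- tibble::tibble(
    id = c("glc_e", "glc", "lacm", "lac_e", "fuel"),
    name = id,
    formula = c("C6H12O6", "C6H12O6", "C3H6O3", "C3H6O3", "R"),
    charge = 0L, compartment = c("e", "c", "c", "e", "c"))
  rxns <- tibble::tibble(
    id = c("EX_glc_e", "T_glc", "GLY2", "T_lac", "EX_lac_e", "SRC_fuel",
           "NGAM", "BIOMASS"),
    name = id, lower_bound = 0,
    upper_bound = c(1000, 1000, 1000, 1000, 1000, 1000, 1000, 5),
    subsystem = "toy",
    rtype = c("exchange", "gene_associated", "gene_associated",
              "gene_associated", "exchange", "orphan", "orphan", "biomass"))
  st <- tibble::tibble(
    reaction_id = c("EX_glc_e", "T_glc", "T_glc", "GLY2", "GLY2", "T_lac",
                    "T_lac", "EX_lac_e", "SRC_fuel", "NGAM", "BIOMASS"),
    metabolite_id = c("glc_e", "glc_e", "glc", "glc", "lacm", "lacm",
                      "lac_e", "lac_e", "fuel", "fuel", "lacm"),
    coefficient = c(-1, -1, 1, -1, 2, -1, 1, -1, 1, -1, -1))
  gprs <- list(T_glc = gpr_rule("tg_a1"), GLY2 = gpr_rule("gly_a1"),
               T_lac = gpr_rule("tl_a1"))
  pan_reactome(mets, rxns, st, gprs, biomass_id = "BIOMASS", ngam_id = "NGAM")
}

# Random tiny networks for solver-oracle comparisons. Bounds always allow
# zero flux, so every instance is feasible and (with finite bounds) bounded.
random_tiny_network <- function(n_rxn, n_met, density = 0.5) {
  repeat {
    S <- matrix(0, n_met, n_rxn)
    nz <- matrix(stats::runif(n_met * n_rxn) < density, n_met, n_rxn)
    S[nz] <- sample(c(-2, -1, 1, 2), sum(nz), replace = TRUE)
    if (all(colSums(S != 0) > 0)) break
  }
  lb <- ifelse(stats::runif(n_rxn) < 0.5, -stats::runif(n_rxn, 1, 10), 0)
  ub <- stats::runif(n_rxn, 1, 10)
  obj <- numeric(n_rxn)
  obj[sample.int(n_rxn, 1)] <- 1
  list(S = S, lb = lb, ub = ub, obj = obj)
}

# Convert an arbitrary boolean DNF rule to its truth-table evaluation: used
# as the exhaustive oracle for GPR evaluation.
dnf_truth_table <- function(rule, alleles) {
  n <- length(alleles)
  vapply(seq_len(2^n) - 1L, function(mask) {
    present <- alleles[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0]
    any(vapply(rule, function(alt) all(alt %in% present), logical(1)))
  }, logical(1))
}

small_cfg <- function(seed = 11, ...) synthetic_config(seed = seed, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Chain toy extended with a reaction whose GPR has two alternatives.
toy_gpr_reactome <- function() {
  r <- toy_chain_reactome()
  r$reactions <- dplyr::bind_rows(r$reactions, tibble::tibble(
    id = "RX", name = "RX", lower_bound = 0, upper_bound = 1000,
    subsystem = "toy", rtype = "gene_associated"))
  r$stoichiometry <- dplyr::bind_rows(r$stoichiometry, tibble::tibble(
    reaction_id = "RX", metabolite_id = c("A", "B"), coefficient = c(-1, 1)))
  r$gprs$RX <- gpr_rule(c("g1", "g2"), "g3")
  validate_pan_reactome(r)
  r
}

# Chain toy with a substrate-starved (disconnected) conversion.
toy_gpr_reactome_disconnected <- function() {
  r <- toy_chain_reactome()
  r$metabolites <- dplyr::bind_rows(r$metabolites, tibble::tibble(
    id = c("P", "Q"), name = c("P", "Q"), formula = "C1", charge = 0L,
    compartment = "c"))
  r$reactions <- dplyr::bind_rows(r$reactions, tibble::tibble(
    id = "ORPHX", name = "ORPHX", lower_bound = 0, upper_bound = 1000,
    subsystem = "toy", rtype = "gene_associated"))
  r$stoichiometry <- dplyr::bind_rows(r$stoichiometry, tibble::tibble(
    reaction_id = "ORPHX", metabolite_id = c("P", "Q"), coefficient = c(-1, 1)))
  r$gprs$ORPHX <- gpr_rule("ox_a1")
  validate_pan_reactome(r)
  r
}

# Build a presence_absence object straight from a binary matrix.
tiny_pam <- function(mat, species = NULL, niche = NULL) {
  strains <- rownames(mat)
  meta <- tibble::tibble(
    strain_id = strains,
    species = species %||% rep("spA", length(strains)),
    genus = "g1",
    isolation_source = niche %||% rep("src", length(strains)))
  profiles <- lapply(stats::setNames(nm = strains), function(s) {
    stats::setNames(mat[s, ] == 1, colnames(mat))
  })
  build_presence_matrix(profiles, meta)
}
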