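#' Call allele presence from bidirectional-best-hit evidence
#'
#' An allele is called present in a strain when some hit against it is a
#' mutual (bidirectional) best hit and the smaller of the two alignment
#' identities reaches the threshold. The 70% default follows the common BBH
#' convention with an inclusive boundary.
#'
#' @param hits Tibble of homology hits with columns `allele`,
#'   `pident_fwd`, `pident_rev`, `mutual_best` (logical or 0/1). Extra
#'   columns (e.g. `strain_gene`) are ignored.
#' @param threshold Percent identity threshold, inclusive; default 70.
#' @return Character vector of present allele ids (sorted, unique).
#' @export
call_allele_presence <- function(hits, threshold = 70) {
  hits <- tibble::as_tibble(hits)
  idn <- c(hits$pident_fwd, hits$pident_rev)
  if (any(idn < 0 | idn > 100)) stop("percent identity outside [0, 100]")
  keep <- as.logical(hits$mutual_best) &
    pmin(hits$pident_fwd, hits$pident_rev) >= threshold
  sort(unique(hits$allele[keep]))
}

#' Map present alleles to reaction presence
#'
#' A `gene_associated` reaction is present when at least one GPR alternative
#' allele set is fully contained in the present alleles; reactions of any
#' other type are present by definition (template plumbing carried by every
#' strain).
#'
#' @param present_alleles Character vector of allele ids.
#' @param reactome A [pan_reactome()].
#' @return Named logical vector over the reactome's reaction ids.
#' @export
reactions_from_alleles <- function(present_alleles, reactome) {
  r <- reactome$reactions
  out <- stats::setNames(rep(TRUE, nrow(r)), r$id)
  ga <- r$id[r$rtype == "gene_associated"]
  out[ga] <- vapply(reactome$gprs[ga], eval_gpr, logical(1),
                    present = present_alleles)
  out
}

#' Assemble a draft strain model from a reaction presence vector
#'
#' The draft contains exactly the present gene-associated reactions plus
#' every exchange, orphan, spontaneous, demand and sink reaction of the
#' template, the biomass reaction and the NGAM reaction. Metabolites are
#' restricted to those the retained reactions touch. Provenance records
#' whether each reaction was homology-mapped or universal.
#'
#' @param reactome A [pan_reactome()].
#' @param presence Named logical vector indexed by the reactome's reaction
#'   ids (as from [reactions_from_alleles()]).
#' @param strain_id Strain identifier.
#' @param species,genus,isolation_source Strain metadata labels.
#' @return A `strain_model` (inherits `pan_reactome`).
#' @export
assemble_draft <- function(reactome, presence, strain_id,
                           species = NA_character_, genus = NA_character_,
                           isolation_source = NA_character_) {
  r <- reactome$reactions
  stopifnot(all(r$id %in% names(presence)))
  universal <- r$rtype %in% universal_rtypes | r$id %in% c(reactome$biomass_id, reactome$ngam_id)
  keep <- universal | (r$rtype == "gene_associated" & unname(presence[r$id]))
  kept <- r[keep, ]
  st <- reactome$stoichiometry[reactome$stoichiometry$reaction_id %in% kept$id, ]
  mets <- reactome$metabolites[reactome$metabolites$id %in% unique(st$metabolite_id), ]
  provenance <- stats::setNames(ifelse(universal[keep], "universal", "mapped"), kept$id)
  obj <- structure(
    list(metabolites = mets, reactions = kept, stoichiometry = st,
         gprs = reactome$gprs[intersect(names(reactome$gprs), kept$id)],
         biomass_id = reactome$biomass_id, ngam_id = reactome$ngam_id,
         allele_catalog = NULL, compartments = reactome$compartments,
         strain_id = strain_id, species = species, genus = genus,
         isolation_source = isolation_source, provenance = provenance),
    class = c("strain_model", "pan_reactome"))
  validate_pan_reactome(obj)
  obj
}

#' @export
print.strain_model <- function(x, ...) {
  cat("<strain_model> ", x$strain_id, " (", x$species, "): ",
      nrow(x$reactions), " reactions, ", nrow(x$metabolites),
      " metabolites\n", sep = "")
  invisible(x)
}

#' Build a strain-by-reaction presence-absence matrix
#'
#' @param presence Either a named list of presence vectors (strain id ->
#'   named logical over a shared reaction universe) or a list of
#'   `strain_model` objects (presence inferred against `reactome`).
#' @param metadata Tibble with columns `strain_id`, `species`, and
#'   optionally `genus`, `isolation_source`.
#' @param reactome Required when `presence` is a list of models: the
#'   template defining the reaction universe (columns).
#' @return An object of class `presence_absence`: binary matrix
#'   (strains x reactions) with a `metadata` attribute.
#' @export
build_presence_matrix <- function(presence, metadata, reactome = NULL) {
  metadata <- tibble::as_tibble(metadata)
  if (anyDuplicated(metadata$strain_id)) stop("duplicate strain ids in metadata")
  if (length(presence) > 0 && inherits(presence[[1]], "strain_model")) {
    stopifnot(!is.null(reactome))
    universe <- reactome$reactions$id
    names(presence) <- vapply(presence, `[[`, "", "strain_id")
    presence <- lapply(presence, function(mod) {
      stats::setNames(universe %in% mod$reactions$id, universe)
    })
  }
  strains <- names(presence)
  if (is.null(strains) || anyDuplicated(strains)) stop("presence vectors must be uniquely named by strain")
  universe <- names(presence[[1]])
  mat <- do.call(rbind, lapply(presence, function(p) as.integer(unname(p[universe]))))
  dimnames(mat) <- list(strains, universe)
  missing_meta <- setdiff(strains, metadata$strain_id)
  if (length(missing_meta) > 0L) stop("metadata missing for strain(s): ",
                                      paste(missing_meta, collapse = ", "))
  metadata <- metadata[match(strains, metadata$strain_id), ]
  structure(mat, metadata = metadata, class = c("presence_absence", "matrix"))
}

#' Read / write a presence-absence matrix as CSV
#'
#' Strains are rows, reactions columns; the first column holds strain ids.
#' Metadata travels in its own TSV (`strain_id`, `species`, `genus`,
#' `isolation_source`).
#'
#' @param pam A `presence_absence` matrix.
#' @param path CSV path; `metadata_path` the TSV path.
#' @return Paths invisibly (write); a `presence_absence` (read).
#' @export
write_presence_matrix <- function(pam, path, metadata_path) {
  df <- data.frame(strain_id = rownames(pam), unclass(pam), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  readr::write_tsv(attr(pam, "metadata"), metadata_path)
  invisible(c(path, metadata_path))
}

#' @rdname write_presence_matrix
#' @export
read_presence_matrix <- function(path, metadata_path) {
  df <- utils::read.csv(path, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "integer"
  rownames(mat) <- df[[1]]
  metadata <- readr::read_tsv(metadata_path, show_col_types = FALSE)
  metadata <- metadata[match(rownames(mat), metadata$strain_id), ]
  structure(mat, metadata = metadata, class = c("presence_absence", "matrix"))
}

#' Read a strain-by-allele similarity table
#'
#' TSV with columns `strain_id`, `strain_gene`, `allele`, `pident_fwd`,
#' `pident_rev`, `mutual_best` — the tabular shape of a bidirectional
#' protein search. The pipeline's contract starts here; running the aligner
#' itself is out of scope.
#'
#' @param path TSV path.
#' @return Tibble of hits.
#' @export
read_similarity_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    strain_id = readr::col_character(),
                    strain_gene = readr::col_character(),
                    allele = readr::col_character(),
                    pident_fwd = readr::col_double(),
                    pident_rev = readr::col_double(),
                    mutual_best = readr::col_integer()))
}

#' Map a full similarity table to per-strain draft models
#'
#' Convenience pipeline: split the similarity table by strain, call allele
#' presence, evaluate GPRs and assemble drafts.
#'
#' @param similarities Tibble as from [read_similarity_tsv()].
#' @param reactome A [pan_reactome()].
#' @param metadata Strain metadata tibble (`strain_id`, `species`, ...).
#' @param threshold BBH identity threshold (percent), inclusive.
#' @return Named list of `strain_model` objects.
#' @export
map_strains <- function(similarities, reactome, metadata, threshold = 70) {
  metadata <- tibble::as_tibble(metadata)
  by_strain <- split(similarities, similarities$strain_id)
  models <- lapply(names(by_strain), function(sid) {
    alleles <- call_allele_presence(by_strain[[sid]], threshold = threshold)
    pres <- reactions_from_alleles(alleles, reactome)
    meta <- metadata[metadata$strain_id == sid, ]
    assemble_draft(reactome, pres, sid,
                   species = if (nrow(meta)) meta$species[[1]] else NA_character_,
                   genus = if (nrow(meta) && "genus" %in% names(meta)) meta$genus[[1]] else NA_character_,
                   isolation_source = if (nrow(meta) && "isolation_source" %in% names(meta)) meta$isolation_source[[1]] else NA_character_)
  })
  stats::setNames(models, names(by_strain))
}
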