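#' Reaction carriage frequency
#'
#' Percentage of strains carrying each reaction, optionally over a subset of
#' strains.
#'
#' @param pam A `presence_absence` matrix from [build_presence_matrix()].
#' @param strain_subset Optional character vector of strain ids.
#' @return Tibble `reaction_id`, `frequency` (percent, 0-100).
#' @export
reaction_frequency <- function(pam, strain_subset = NULL) {
  mat <- unclass(pam)
  if (!is.null(strain_subset)) {
    if (length(strain_subset) == 0L) stop("empty strain subset")
    stopifnot(all(strain_subset %in% rownames(mat)))
    mat <- mat[strain_subset, , drop = FALSE]
  }
  if (nrow(mat) == 0L) stop("empty presence-absence matrix")
  tibble::tibble(reaction_id = colnames(mat),
                 frequency = unname(100 * colMeans(mat)))
}

#' Partition a reactome into core / accessory / rare sets
#'
#' Frequency-based partition: core is strictly `F > core_min`, accessory is
#' `accessory_min <= F <= core_min`, rare is `0 < F < accessory_min`.
#' Reactions absent from every strain (`F = 0`) fall into a fourth,
#' reported-but-unclassified `absent` bin. Defaults follow the 99 / 15
#' percent convention for family-wide reactomes.
#'
#' @param freq Tibble from [reaction_frequency()] (columns `reaction_id`,
#'   `frequency`), or a `presence_absence` matrix (frequencies computed
#'   internally).
#' @param core_min,accessory_min Percent thresholds, `0 < accessory_min <
#'   core_min < 100`.
#' @return Tibble of class `reactome_partition`: `reaction_id`, `frequency`,
#'   `class` (factor `core`/`accessory`/`rare`/`absent`); thresholds kept as
#'   attributes.
#' @export
partition_reactome <- function(freq, core_min = 99, accessory_min = 15) {
  stopifnot(accessory_min > 0, accessory_min < core_min, core_min < 100)
  if (inherits(freq, "presence_absence")) freq <- reaction_frequency(freq)
  f <- freq$frequency
  cls <- dplyr::case_when(
    f > core_min ~ "core",
    f >= accessory_min ~ "accessory",
    f > 0 ~ "rare",
    TRUE ~ "absent")
  out <- tibble::tibble(reaction_id = freq$reaction_id, frequency = f,
                        class = factor(cls, levels = c("core", "accessory", "rare", "absent")))
  structure(out, core_min = core_min, accessory_min = accessory_min,
            class = c("reactome_partition", class(out)))
}

#' Species-unique reactions
#'
#' A reaction is unique to a species when at least one strain carries it and
#' every carrying strain belongs to that species — whether the reaction
#' occurs in one or several of the species' strains.
#'
#' @param pam A `presence_absence` matrix; its metadata must have a
#'   `species` column with no missing labels.
#' @return Tibble `reaction_id`, `species`, `n_strains` (carrying strains),
#'   one row per unique reaction.
#' @export
unique_reactions <- function(pam) {
  meta <- attr(pam, "metadata")
  if (is.null(meta) || !"species" %in% names(meta) || anyNA(meta$species)) {
    stop("species metadata missing for unique-reaction analysis")
  }
  mat <- unclass(pam)
  species <- meta$species[match(rownames(mat), meta$strain_id)]
  carried <- colSums(mat) > 0
  rows <- purrr::map_dfr(colnames(mat)[carried], function(rid) {
    sp <- unique(species[mat[, rid] == 1])
    if (length(sp) == 1L) {
      tibble::tibble(reaction_id = rid, species = sp,
                     n_strains = sum(mat[, rid]))
    } else tibble::tibble()
  })
  rows
}

#' Intra-species core / accessory / rare percentages
#'
#' For each species with at least `min_strains` strains, computes reaction
#' frequencies over that species' strains only, partitions them with the
#' same thresholds as the family-wide analysis, and reports the percentage
#' of the species' observed reactome (frequency > 0) in each class. The
#' three percentages sum to 100 up to rounding.
#'
#' @param pam A `presence_absence` matrix with species metadata.
#' @param core_min,accessory_min Partition thresholds (percent).
#' @param min_strains Minimum strains for a species to be included; smaller
#'   species are skipped with a warning. Default 2.
#' @return Tibble: `species`, `n_strains`, `core_pct`, `accessory_pct`,
#'   `rare_pct`, `n_reactions` (observed reactome size).
#' @export
intra_species_partition <- function(pam, core_min = 99, accessory_min = 15,
                                    min_strains = 2) {
  meta <- attr(pam, "metadata")
  stopifnot(!is.null(meta), "species" %in% names(meta))
  mat <- unclass(pam)
  species <- meta$species[match(rownames(mat), meta$strain_id)]
  purrr::map_dfr(sort(unique(species)), function(sp) {
    strains <- rownames(mat)[species == sp]
    if (length(strains) < min_strains) {
      warning("species '", sp, "' has fewer than ", min_strains,
              " strains; skipped")
      return(tibble::tibble())
    }
    part <- partition_reactome(reaction_frequency(pam, strains),
                               core_min = core_min, accessory_min = accessory_min)
    observed <- part[part$class != "absent", ]
    n <- nrow(observed)
    tibble::tibble(species = sp, n_strains = length(strains),
                   core_pct = 100 * sum(observed$class == "core") / n,
                   accessory_pct = 100 * sum(observed$class == "accessory") / n,
                   rare_pct = 100 * sum(observed$class == "rare") / n,
                   n_reactions = n)
  })
}
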