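SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Write a reactome (or strain model) to SBML
#'
#' Emits SBML Level 3 Version 1 with fbc-style parameterized flux bounds,
#' species charge/formula attributes and an active biomass objective. The
#' reaction type and subsystem labels travel in XHTML notes; the NGAM
#' reaction id in the model notes. GPR alternatives exceed what standard GPR
#' strings express and are stored in the sidecar TSV (see
#' [write_gpr_tsv()]), per the package's exchange format.
#'
#' @param x A `pan_reactome` or `strain_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reactome_sbml <- function(x, path) {
  num <- function(v) formatC(v, format = "g", digits = 17)
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
            SBML_CORE_NS, SBML_FBC_NS),
    sprintf('  <model id="reactome" fbc:strict="true">'),
    '    <notes><body xmlns="http://www.w3.org/1999/xhtml">',
    sprintf('      <p>ngam: %s</p>', esc(x$ngam_id)),
    '    </body></notes>',
    '    <listOfCompartments>',
    sprintf('      <compartment id="%s" constant="true"/>', x$compartments),
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  m <- x$metabolites
  lines <- c(lines, sprintf(
    paste0('      <species id="M_%s" name="%s" compartment="%s"',
           ' hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"',
           ' fbc:charge="%d" fbc:chemicalFormula="%s"/>'),
    m$id, esc(m$name), m$compartment, as.integer(m$charge), m$formula))
  lines <- c(lines, '    </listOfSpecies>', '    <listOfParameters>')
  r <- x$reactions
  lines <- c(lines,
             sprintf('      <parameter id="bnd_%s_lb" value="%s" constant="true"/>',
                     r$id, num(r$lower_bound)),
             sprintf('      <parameter id="bnd_%s_ub" value="%s" constant="true"/>',
                     r$id, num(r$upper_bound)))
  lines <- c(lines, '    </listOfParameters>', '    <listOfReactions>')
  st <- x$stoichiometry
  for (i in seq_len(nrow(r))) {
    rid <- r$id[i]
    part <- st[st$reaction_id == rid, ]
    lines <- c(lines, sprintf(
      paste0('      <reaction id="R_%s" name="%s" reversible="%s" fast="false"',
             ' fbc:lowerFluxBound="bnd_%s_lb" fbc:upperFluxBound="bnd_%s_ub">'),
      rid, esc(r$name[i]), if (r$lower_bound[i] < 0) "true" else "false", rid, rid))
    lines <- c(lines,
               '        <notes><body xmlns="http://www.w3.org/1999/xhtml">',
               sprintf('          <p>rtype: %s</p>', r$rtype[i]),
               sprintf('          <p>subsystem: %s</p>', esc(r$subsystem[i])),
               '        </body></notes>')
    reac <- part[part$coefficient < 0, ]
    prod <- part[part$coefficient > 0, ]
    if (nrow(reac) > 0) {
      lines <- c(lines, '        <listOfReactants>',
                 sprintf('          <speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
                         reac$metabolite_id, num(-reac$coefficient)),
                 '        </listOfReactants>')
    }
    if (nrow(prod) > 0) {
      lines <- c(lines, '        <listOfProducts>',
                 sprintf('          <speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
                         prod$metabolite_id, num(prod$coefficient)),
                 '        </listOfProducts>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>',
             '    <fbc:listOfObjectives fbc:activeObjective="obj">',
             '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
             '        <fbc:listOfFluxObjectives>',
             sprintf('          <fbc:fluxObjective fbc:reaction="R_%s" fbc:coefficient="1"/>',
                     x$biomass_id),
             '        </fbc:listOfFluxObjectives>',
             '      </fbc:objective>',
             '    </fbc:listOfObjectives>',
             '  </model>',
             '</sbml>')
  writeLines(lines, path)
  invisible(path)
}

#' Write / read the GPR sidecar TSV
#'
#' Columns `reaction_id`, `allele_set` (semicolon-joined allele ids), one row
#' per alternative allele set of the reaction's DNF rule.
#'
#' @param gprs Named list of [gpr_rule()] objects.
#' @param path File path.
#' @return `path` invisibly (write); a named list of `gpr_rule` (read).
#' @export
write_gpr_tsv <- function(gprs, path) {
  rows <- unlist(lapply(names(gprs), function(rid) {
    vapply(gprs[[rid]], function(alt) paste(rid, paste(alt, collapse = ";"), sep = "\t"), "")
  }))
  writeLines(c("reaction_id\tallele_set", rows), path)
  invisible(path)
}

#' @rdname write_gpr_tsv
#' @export
read_gpr_tsv <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  alts <- strsplit(tab$allele_set, ";", fixed = TRUE)
  split_alts <- split(alts, tab$reaction_id)
  lapply(split_alts, function(a) do.call(gpr_rule, a))
}

.sbml_notes_field <- function(node, key, ns) {
  ps <- xml2::xml_find_all(node, ".//d1:notes//*[local-name()='p']", ns)
  txt <- xml2::xml_text(ps)
  hit <- grep(paste0("^", key, ":"), txt, value = TRUE)
  if (length(hit) == 0L) return(NA_character_)
  trimws(sub(paste0("^", key, ":"), "", hit[[1]]))
}

#' Load a pan-reactome from SBML plus a GPR table
#'
#' Parses the SBML dialect written by [write_reactome_sbml()] and joins the
#' multi-allelic GPR rules from the sidecar TSV. Reaction and metabolite
#' counts are preserved from the document; a GPR row naming a reaction
#' absent from the SBML is a validation error. Malformed XML propagates the
#' parser's error, which names the offending line.
#'
#' @param sbml_source Path to the SBML file.
#' @param gpr_table Path to the GPR TSV ([read_gpr_tsv()] format), or a
#'   pre-built named list of [gpr_rule()]s.
#' @return A validated [pan_reactome()].
#' @export
load_reactome <- function(sbml_source, gpr_table) {
  doc <- xml2::read_xml(sbml_source)
  ns <- c(d1 = SBML_CORE_NS, fbc = SBML_FBC_NS)
  sp <- xml2::xml_find_all(doc, ".//d1:listOfSpecies/d1:species", ns)
  metabolites <- tibble::tibble(
    id = sub("^M_", "", xml2::xml_attr(sp, "id")),
    name = xml2::xml_attr(sp, "name"),
    formula = xml2::xml_attr(sp, "fbc:chemicalFormula", ns),
    charge = as.integer(xml2::xml_attr(sp, "fbc:charge", ns)),
    compartment = xml2::xml_attr(sp, "compartment"))

  pars <- xml2::xml_find_all(doc, ".//d1:listOfParameters/d1:parameter", ns)
  bounds <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))

  rx <- xml2::xml_find_all(doc, ".//d1:listOfReactions/d1:reaction", ns)
  rids <- sub("^R_", "", xml2::xml_attr(rx, "id"))
  reactions <- tibble::tibble(
    id = rids,
    name = xml2::xml_attr(rx, "name"),
    lower_bound = unname(bounds[xml2::xml_attr(rx, "fbc:lowerFluxBound", ns)]),
    upper_bound = unname(bounds[xml2::xml_attr(rx, "fbc:upperFluxBound", ns)]),
    subsystem = vapply(rx, .sbml_notes_field, "", key = "subsystem", ns = ns),
    rtype = vapply(rx, .sbml_notes_field, "", key = "rtype", ns = ns))

  st <- purrr::map2_dfr(rx, rids, function(node, rid) {
    reac <- xml2::xml_find_all(node, "./d1:listOfReactants/d1:speciesReference", ns)
    prod <- xml2::xml_find_all(node, "./d1:listOfProducts/d1:speciesReference", ns)
    tibble::tibble(
      reaction_id = rid,
      metabolite_id = sub("^M_", "", c(xml2::xml_attr(reac, "species"),
                                       xml2::xml_attr(prod, "species"))),
      coefficient = c(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
                      as.numeric(xml2::xml_attr(prod, "stoichiometry"))))
  })

  obj <- xml2::xml_find_first(doc, ".//fbc:listOfObjectives//fbc:fluxObjective", ns)
  biomass_id <- sub("^R_", "", xml2::xml_attr(obj, "fbc:reaction", ns))
  model_node <- xml2::xml_find_first(doc, ".//d1:model", ns)
  ngam_id <- .sbml_notes_field(model_node, "ngam", ns)
  comp <- xml2::xml_attr(xml2::xml_find_all(doc, ".//d1:listOfCompartments/d1:compartment", ns), "id")

  gprs <- if (is.list(gpr_table)) gpr_table else read_gpr_tsv(gpr_table)
  bad <- setdiff(names(gprs), reactions$id)
  if (length(bad) > 0L) {
    stop("GPR table references unknown reaction(s): ", paste(bad, collapse = ", "))
  }
  pan_reactome(metabolites, reactions, st, gprs,
               biomass_id = biomass_id, ngam_id = ngam_id, compartments = comp)
}
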