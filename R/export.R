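#' Export a reaction network
#'
#' Formats:
#' \describe{
#'   \item{sbml}{SBML Level 3 Version 2 core, one compartment, species
#'     with initial concentrations, mass-action kinetic laws in MathML.}
#'   \item{csv}{two files, \code{<path>_species.csv} and
#'     \code{<path>_reactions.csv}; round-trips through
#'     \code{\link{import_network_csv}}.}
#'   \item{bngl}{plain-text listing of the 12 rules in a BioNetGen-like
#'     site grammar, plus parameter block.}
#' }
#'
#' @param network a \code{plcg_network}.
#' @param path output file path (for csv, used as a stem).
#' @param format one of \code{"sbml"}, \code{"csv"}, \code{"bngl"}.
#' @param initial named initial concentrations (uM) by species label;
#'   defaults to the standard initial condition (all PLC autoinhibited in
#'   the cytosol, all receptor free).
#' @return invisible character vector of files written.
#' @export
export_network <- function(network, path,
                           format = c("sbml", "csv", "bngl"),
                           initial = NULL) {
  format <- match.arg(format)
  switch(format,
    sbml = export_sbml(network, path, initial),
    csv  = export_csv(network, path),
    bngl = export_bngl(network, path)
  )
}

sbml_id <- function(labels) {
  id <- gsub("[^A-Za-z0-9_]", "_", labels)
  gsub("_+", "_", id)
}

export_sbml <- function(network, path, initial = NULL) {
  y0 <- initial_state(network)
  if (!is.null(initial)) y0[names(initial)] <- unlist(initial)
  sp <- network$species
  sid <- sbml_id(sp$label)

  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2")
  model <- xml2::xml_add_child(doc, "model", id = "plcg1_activation",
                               substanceUnits = "substance",
                               timeUnits = "second")
  lc <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(lc, "compartment", id = "cell", spatialDimensions = "3",
                      size = "1", constant = "true")
  ls <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(nrow(sp)))
    xml2::xml_add_child(ls, "species", id = sid[i], name = sp$label[i],
                        compartment = "cell",
                        initialConcentration = format(y0[i], digits = 15),
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  lp <- xml2::xml_add_child(model, "listOfParameters")
  for (j in seq_len(nrow(network$reactions)))
    xml2::xml_add_child(lp, "parameter",
                        id = sprintf("k_r%d", j),
                        name = network$reactions$rate_name[j],
                        value = format(network$reactions$rate_value[j],
                                       digits = 15),
                        constant = "true")
  lr <- xml2::xml_add_child(model, "listOfReactions")
  for (j in seq_len(nrow(network$reactions))) {
    rxn <- xml2::xml_add_child(lr, "reaction",
                               id = sprintf("r%d", j),
                               name = network$reactions$rule[j],
                               reversible = "false")
    rl <- xml2::xml_add_child(rxn, "listOfReactants")
    rids <- reaction_side(network$reactions$reactants[j])
    for (i in rids)
      xml2::xml_add_child(rl, "speciesReference", species = sid[i],
                          stoichiometry = "1", constant = "true")
    pl <- xml2::xml_add_child(rxn, "listOfProducts")
    for (i in reaction_side(network$reactions$products[j]))
      xml2::xml_add_child(pl, "speciesReference", species = sid[i],
                          stoichiometry = "1", constant = "true")
    kl <- xml2::xml_add_child(rxn, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math",
                                xmlns = "http://www.w3.org/1998/Math/MathML")
    ap <- xml2::xml_add_child(math, "apply")
    xml2::xml_add_child(ap, "times")
    xml2::xml_add_child(ap, "ci", sprintf("k_r%d", j))
    for (i in rids) xml2::xml_add_child(ap, "ci", sid[i])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

export_csv <- function(network, path) {
  stem <- sub("\\.csv$", "", path)
  f_sp <- paste0(stem, "_species.csv")
  f_rx <- paste0(stem, "_reactions.csv")
  utils::write.csv(network$species, f_sp, row.names = FALSE)
  utils::write.csv(network$reactions, f_rx, row.names = FALSE)
  invisible(c(f_sp, f_rx))
}

#' Re-import a CSV network export
#'
#' @param path the stem (or either file) passed to the CSV export.
#' @return a \code{plcg_network} with species, reactions, and
#'   stoichiometry rebuilt (states/params not restored).
#' @export
import_network_csv <- function(path) {
  stem <- sub("(_species|_reactions)?\\.csv$", "", path)
  sp <- utils::read.csv(paste0(stem, "_species.csv"),
                        stringsAsFactors = FALSE)
  rx <- utils::read.csv(paste0(stem, "_reactions.csv"),
                        stringsAsFactors = FALSE)
  rx$reactants <- as.character(rx$reactants)
  rx$products <- as.character(rx$products)
  net <- structure(list(species = sp, reactions = rx), class = "plcg_network")
  net$stoich <- stoichiometry_matrix(net)
  net
}

export_bngl <- function(network, path) {
  rs <- plcg_ruleset()
  kv <- rate_values(network$params)
  lines <- c("begin parameters")
  p <- network$params
  for (nm in .param_names)
    lines <- c(lines, sprintf("  %s %g", nm, p[[nm]]))
  lines <- c(lines, "end parameters", "",
             "begin molecule types",
             "  PLC(nSH2,Y783~u~p,cSH2~free~core~pY,core~inact~act)",
             "  RTK(pY)",
             "end molecule types", "", "begin reaction rules")
  for (r in rs) {
    pat <- vapply(names(r$pattern), function(s)
      sprintf("%s~{%s}", s, paste(.abbrev[[s]][r$pattern[[s]]],
                                  collapse = ",")), character(1))
    arrow <- sprintf("%s: %s  ->  %s~%s  k=%s (%g)",
                     r$name, paste(pat, collapse = ","),
                     r$site, .abbrev[[r$site]][r$to], r$rate, kv[[r$rate]])
    if (r$molecularity == "bimolecular")
      arrow <- paste(arrow, "+ RTK(pY)")
    lines <- c(lines, paste0("  ", arrow))
  }
  lines <- c(lines, "end reaction rules")
  writeLines(lines, path)
  invisible(path)
}
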