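# SBML Level 3 (+ fbc) reader built on xml2. Reads species, reactions with
# stoichiometries, flux bounds via fbc bound parameters, and gene
# associations (fbc:geneProductAssociation), returning the association as
# rule text in the gpr column. Boundary-condition species are dropped from
# the stoichiometry (they are exchange sinks/sources).

read_sbml_model <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)  # work namespace-free; fbc attrs keep their prefix

  params <- xml2::xml_find_all(doc, ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  gps <- xml2::xml_find_all(doc, ".//*[local-name()='listOfGeneProducts']/*")
  glab <- stats::setNames(
    ifelse(is.na(xml2::xml_attr(gps, "label")), xml2::xml_attr(gps, "id"),
           xml2::xml_attr(gps, "label")),
    xml2::xml_attr(gps, "id"))

  species <- xml2::xml_find_all(doc, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  boundary <- xml2::xml_attr(species, "boundaryCondition") %in% c("true", "1")
  boundary_ids <- xml2::xml_attr(species, "id")[boundary]

  gpr_text <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      gid <- xml2::xml_attr(node, "geneProduct")
      return(glab[[gid]] %||% gid)
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, gpr_text, "")
    op <- if (nm == "and") " and " else " or "
    paste0("(", paste(parts, collapse = op), ")")
  }

  rxn_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (length(rxn_nodes) == 0L) stop("no reactions found in SBML file: ", path)
  rows <- lapply(rxn_nodes, function(rn) {
    rid <- xml2::xml_attr(rn, "id")
    if (is.na(rid)) stop("SBML reaction without an id in ", path)
    side <- function(xp, sgn) {
      refs <- xml2::xml_find_all(rn, xp)
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      stats::setNames(sgn * st, xml2::xml_attr(refs, "species"))
    }
    coef <- c(side("./*[local-name()='listOfReactants']/*", -1),
              side("./*[local-name()='listOfProducts']/*", +1))
    coef <- coef[!names(coef) %in% boundary_ids]
    rev <- xml2::xml_attr(rn, "reversible") %in% c("true", "1")
    lbref <- xml2::xml_attr(rn, "lowerFluxBound")
    ubref <- xml2::xml_attr(rn, "upperFluxBound")
    lb <- if (!is.na(lbref) && lbref %in% names(pval)) pval[[lbref]]
          else if (rev) -Inf else 0
    ub <- if (!is.na(ubref) && ubref %in% names(pval)) pval[[ubref]] else Inf
    gpa <- xml2::xml_find_first(rn, "./*[local-name()='geneProductAssociation']")
    gpr <- if (inherits(gpa, "xml_missing")) "" else {
      kids <- xml2::xml_children(gpa)
      if (length(kids) == 0L) "" else gpr_text(kids[[1]])
    }
    tibble::tibble(reaction_id = rid,
                   equation = format_equation(coef, reversible = lb < 0),
                   lb = lb, ub = ub, gpr = gpr, cost = 1,
                   status = "deletable")
  })
  metabolic_model(dplyr::bind_rows(rows))
}
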