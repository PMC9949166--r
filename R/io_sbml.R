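# SBML Level 3 + FBC (version 2) reader/writer.
#
# Covers the subset of SBML-FBC that constraint-based models use in
# practice: compartments, species, global flux-bound parameters referenced
# through fbc:lowerFluxBound / fbc:upperFluxBound, reactant/product
# stoichiometry, and one active fbc objective.  Written with xml2; no
# external SBML library is required.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse SBML file '", path,
                                           "': ", conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  mnode <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mnode, "xml_missing")) stop("SBML file '", path,
                                           "' has no <model> element")
  num_attr <- function(node, attr, default = NA_real_) {
    v <- xml2::xml_attr(node, attr)
    if (is.na(v)) default else as.numeric(v)
  }

  params <- new.env(parent = emptyenv())
  for (p in xml2::xml_find_all(mnode, "./listOfParameters/parameter"))
    assign(xml2::xml_attr(p, "id"), num_attr(p, "value"), envir = params)
  bound_of <- function(ref, default) {
    if (is.na(ref)) return(default)
    if (!exists(ref, envir = params))
      stop("flux bound parameter '", ref, "' is not defined in '", path, "'")
    get(ref, envir = params)
  }

  snodes <- xml2::xml_find_all(mnode, "./listOfSpecies/species")
  if (!length(snodes)) stop("SBML file '", path, "' lists no species")
  mets <- data.frame(
    id = xml2::xml_attr(snodes, "id"),
    name = xml2::xml_attr(snodes, "name"),
    compartment = xml2::xml_attr(snodes, "compartment"),
    formula = xml2::xml_attr(snodes, "chemicalFormula"),
    stringsAsFactors = FALSE)
  mets$name[is.na(mets$name)] <- mets$id[is.na(mets$name)]

  rnodes <- xml2::xml_find_all(mnode, "./listOfReactions/reaction")
  if (!length(rnodes)) stop("SBML file '", path, "' lists no reactions")
  stoich <- list()
  rows <- lapply(rnodes, function(r) {
    rid <- xml2::xml_attr(r, "id")
    s <- numeric()
    for (sp in xml2::xml_find_all(r, "./listOfReactants/speciesReference")) {
      met <- xml2::xml_attr(sp, "species")
      s[met] <- (if (is.null(s[met][[1]]) || is.na(s[met])) 0 else s[met]) -
        num_attr(sp, "stoichiometry", 1)
    }
    for (sp in xml2::xml_find_all(r, "./listOfProducts/speciesReference")) {
      met <- xml2::xml_attr(sp, "species")
      s[met] <- (if (is.na(s[met])) 0 else s[met]) +
        num_attr(sp, "stoichiometry", 1)
    }
    if (!length(s)) stop("reaction '", rid, "' in '", path,
                         "' has no reactants or products")
    stoich[[rid]] <<- s
    rev <- identical(xml2::xml_attr(r, "reversible"), "true")
    data.frame(
      id = rid,
      lower_bound = bound_of(xml2::xml_attr(r, "lowerFluxBound"),
                             if (rev) -1000 else 0),
      upper_bound = bound_of(xml2::xml_attr(r, "upperFluxBound"), 1000),
      objective_coefficient = 0,
      stringsAsFactors = FALSE)
  })
  rxns <- do.call(rbind, rows)

  # fbc-prefixed elements keep their namespace even after stripping the
  # default one, so match the flux objectives by local name
  onodes <- xml2::xml_find_all(mnode,
                               ".//*[local-name()='fluxObjective']")
  biomass_id <- NULL
  for (o in onodes) {
    rid <- xml2::xml_attr(o, "reaction")
    coef <- num_attr(o, "coefficient", 1)
    rxns$objective_coefficient[rxns$id == rid] <- coef
    if (coef > 0) biomass_id <- rid
  }
  if (is.null(biomass_id))
    stop("SBML file '", path, "' defines no positive flux objective ",
         "(biomass reaction)")

  metabolic_model(id = xml2::xml_attr(mnode, "id") %||% "model",
                  mets = mets, rxns = rxns, stoich = stoich,
                  biomass_reaction_id = biomass_id)
}

write_model_sbml <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = SBML_NS, "xmlns:fbc" = FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mnode <- xml2::xml_add_child(doc, "model", id = model$id,
                               "fbc:strict" = "true")

  comps <- xml2::xml_add_child(mnode, "listOfCompartments")
  for (cid in unique(model$mets$compartment))
    xml2::xml_add_child(comps, "compartment", id = cid, constant = "true")

  sl <- xml2::xml_add_child(mnode, "listOfSpecies")
  for (i in seq_len(nrow(model$mets))) {
    m <- model$mets[i, ]
    sp <- xml2::xml_add_child(
      sl, "species", id = m$id, name = m$name, compartment = m$compartment,
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
    if (!is.na(m$formula))
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", m$formula)
  }

  # one shared parameter per distinct bound value
  bounds <- sort(unique(c(model$rxns$lower_bound, model$rxns$upper_bound)))
  bkey <- function(x) sprintf("%.17g", x)
  pid <- stats::setNames(sprintf("fb_%d", seq_along(bounds)), bkey(bounds))
  pl <- xml2::xml_add_child(mnode, "listOfParameters")
  for (k in seq_along(bounds))
    xml2::xml_add_child(pl, "parameter", id = pid[[k]],
                        value = bkey(bounds[k]),
                        constant = "true", sboTerm = "SBO:0000626")

  rl <- xml2::xml_add_child(mnode, "listOfReactions")
  for (i in seq_len(nrow(model$rxns))) {
    r <- model$rxns[i, ]
    rn <- xml2::xml_add_child(
      rl, "reaction", id = r$id,
      reversible = if (r$lower_bound < 0) "true" else "false",
      fast = "false")
    xml2::xml_set_attr(rn, "fbc:lowerFluxBound",
                       pid[[bkey(r$lower_bound)]])
    xml2::xml_set_attr(rn, "fbc:upperFluxBound",
                       pid[[bkey(r$upper_bound)]])
    s <- model$stoich[[r$id]]
    reac <- s[s < 0]; prod <- s[s > 0]
    if (length(reac)) {
      lr <- xml2::xml_add_child(rn, "listOfReactants")
      for (met in names(reac))
        xml2::xml_add_child(lr, "speciesReference", species = met,
                            stoichiometry = sprintf("%.17g", -reac[[met]]),
                            constant = "true")
    }
    if (length(prod)) {
      lp <- xml2::xml_add_child(rn, "listOfProducts")
      for (met in names(prod))
        xml2::xml_add_child(lp, "speciesReference", species = met,
                            stoichiometry = sprintf("%.17g", prod[[met]]),
                            constant = "true")
    }
  }

  ol <- xml2::xml_add_child(mnode, "fbc:listOfObjectives",
                            "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(ol, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  fl <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  for (i in which(model$rxns$objective_coefficient != 0))
    xml2::xml_add_child(
      fl, "fbc:fluxObjective", "fbc:reaction" = model$rxns$id[i],
      "fbc:coefficient" = sprintf(
        "%.17g", model$rxns$objective_coefficient[i]))

  xml2::write_xml(doc, path)
  invisible(path)
}
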