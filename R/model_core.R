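#' Construct a constraint-based metabolic model
#'
#' A `metabolic_model` is the package's central container: a stoichiometric
#' network with bounded reactions, tagged exchange reactions and one biomass
#' (objective) reaction.  Flux units are mmol/gDW/hr throughout; the biomass
#' flux is read as the growth rate (1/hr).
#'
#' The exchange sign convention is the usual one in community metabolic
#' modelling: an exchange reaction consumes exactly one external metabolite
#' with coefficient -1, so negative exchange flux means uptake into the
#' organism and positive flux means secretion.
#'
#' @param id species/model identifier.
#' @param mets data.frame with columns `id`, `name`, `compartment` and
#'   optionally `formula`.  Compartment `"e"` marks the external space.
#' @param rxns data.frame with columns `id`, `lower_bound`, `upper_bound`,
#'   `objective_coefficient` and optionally `is_exchange` (auto-detected
#'   when absent).
#' @param stoich named list (one element per reaction id) of named numeric
#'   vectors mapping metabolite id to a signed coefficient (negative =
#'   consumed).
#' @param biomass_reaction_id id of the biomass reaction; defaults to the
#'   unique reaction with a positive objective coefficient.
#' @param external_compartment compartment id treated as extracellular.
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, mets, rxns, stoich, biomass_reaction_id = NULL,
                            external_compartment = "e") {
  mets <- as.data.frame(mets, stringsAsFactors = FALSE)
  rxns <- as.data.frame(rxns, stringsAsFactors = FALSE)
  if (is.null(mets$name)) mets$name <- mets$id
  if (is.null(mets$formula)) mets$formula <- NA_character_
  if (is.null(rxns$objective_coefficient)) rxns$objective_coefficient <- 0
  if (is.null(biomass_reaction_id)) {
    cand <- rxns$id[rxns$objective_coefficient > 0]
    if (length(cand) != 1L)
      stop("cannot infer biomass reaction: expected exactly one reaction ",
           "with objective_coefficient > 0, found ", length(cand))
    biomass_reaction_id <- cand
  }
  if (is.null(rxns$is_exchange))
    rxns$is_exchange <- detect_exchanges(mets, rxns$id, stoich,
                                         external_compartment)
  model <- structure(
    list(id = id, mets = mets, rxns = rxns, stoich = stoich,
         biomass_reaction_id = biomass_reaction_id,
         external_compartment = external_compartment),
    class = "metabolic_model")
  validate_model(model)
  model
}

detect_exchanges <- function(mets, rxn_ids, stoich, external_compartment) {
  ext <- mets$id[mets$compartment == external_compartment]
  vapply(rxn_ids, function(rid) {
    s <- stoich[[rid]]
    length(s) == 1L && names(s) %in% ext && s[[1L]] == -1
  }, logical(1L), USE.NAMES = FALSE)
}

#' Validate a metabolic model's structural invariants
#'
#' Checks id uniqueness, bound ordering, stoichiometry resolution, the
#' exchange-reaction convention (single external metabolite, coefficient -1)
#' and the presence of a biomass reaction with positive objective weight.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; errors describe the offending element.
#' @export
validate_model <- function(model) {
  mets <- model$mets; rxns <- model$rxns
  if (anyDuplicated(mets$id)) stop("duplicate metabolite ids: ",
    paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  if (anyDuplicated(rxns$id)) stop("duplicate reaction ids: ",
    paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", "))
  if (any(!nzchar(mets$id))) stop("empty metabolite id")
  if (any(!nzchar(mets$compartment))) stop("empty metabolite compartment")
  bad <- rxns$id[rxns$lower_bound > rxns$upper_bound]
  if (length(bad)) stop("lower_bound > upper_bound for reaction(s): ",
                        paste(bad, collapse = ", "))
  for (rid in rxns$id) {
    s <- model$stoich[[rid]]
    if (is.null(s) || !length(s))
      stop("reaction ", rid, " has empty stoichiometry")
    unknown <- setdiff(names(s), mets$id)
    if (length(unknown))
      stop("reaction ", rid, " references unknown metabolite(s): ",
           paste(unknown, collapse = ", "))
  }
  if (!model$biomass_reaction_id %in% rxns$id)
    stop("biomass reaction '", model$biomass_reaction_id,
         "' not found in the model")
  if (rxns$objective_coefficient[rxns$id == model$biomass_reaction_id] <= 0)
    stop("biomass reaction must have objective_coefficient > 0")
  if (!any(rxns$is_exchange))
    stop("model has no exchange reaction")
  ext <- mets$id[mets$compartment == model$external_compartment]
  for (rid in rxns$id[rxns$is_exchange]) {
    s <- model$stoich[[rid]]
    if (length(s) != 1L || !(names(s) %in% ext) || s[[1L]] != -1)
      stop("exchange reaction ", rid, " must consume exactly one external ",
           "metabolite with coefficient -1")
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n",
      "  metabolites: ", nrow(x$mets),
      "  reactions: ", nrow(x$rxns),
      "  exchanges: ", sum(x$rxns$is_exchange), "\n",
      "  biomass: ", x$biomass_reaction_id, "\n", sep = "")
  invisible(x)
}

#' Exchange reactions of a model
#'
#' @param model a `metabolic_model`.
#' @return data.frame with columns `reaction_id`, `metabolite_id` (the
#'   external metabolite each exchange moves) and `compound_id` (the
#'   environmental compound name: the metabolite id with its external
#'   compartment suffix stripped).  Media, Biolog tables and annotations
#'   are keyed by `compound_id`.
#' @export
exchanges <- function(model) {
  ex <- model$rxns$id[model$rxns$is_exchange]
  met <- vapply(ex, function(rid) names(model$stoich[[rid]])[1L],
                character(1L), USE.NAMES = FALSE)
  data.frame(
    reaction_id = ex,
    metabolite_id = met,
    compound_id = sub(paste0("_", model$external_compartment, "$"), "", met),
    stringsAsFactors = FALSE)
}

#' Construct a growth medium
#'
#' A medium maps external compound ids to their environmental availability:
#' maximum uptake flux (mmol/gDW/hr) in the batch modes, or a concentration
#' in mM for the spatial simulator.
#'
#' @param availabilities named non-negative numeric vector keyed by external
#'   metabolite id.
#' @param name medium label.
#' @return object of class `medium` (a named numeric vector).
#' @export
medium <- function(availabilities = numeric(), name = "medium") {
  availabilities <- unlist(availabilities)
  if (length(availabilities) && (is.null(names(availabilities)) ||
      any(!nzchar(names(availabilities)))))
    stop("medium availabilities must be named by compound id")
  if (any(availabilities < 0)) stop("medium availabilities must be >= 0")
  structure(as.numeric(availabilities), names = names(availabilities),
            medium_name = name, class = "medium")
}

#' @export
print.medium <- function(x, ...) {
  cat("<medium> ", attr(x, "medium_name"), ": ", length(x), " compounds\n",
      sep = "")
  invisible(x)
}

#' Constrain a model's exchange bounds by a growth medium
#'
#' Every exchange reaction whose compound appears in the medium gets its
#' lower bound set to minus the availability (uptake allowed up to the
#' available amount); exchanges for compounds absent from the medium are
#' closed to uptake (lower bound 0), so the medium fully defines the
#' environment.  Upper bounds (secretion) are never touched.  Compounds
#' named in `keep_defaults` keep the model's own lower bound, which is how
#' freely available species (water, protons, oxygen, trace metals) are
#' exempted from the medium budget.
#'
#' @param model a `metabolic_model`.
#' @param med a [medium()] in mmol/gDW/hr.
#' @param keep_defaults character vector of compound ids whose exchange
#'   bounds are left at the model defaults.
#' @param warn_unknown warn about medium compounds with no exchange
#'   reaction in this model; community-wide media routinely contain
#'   compounds individual members cannot use, so internal per-member calls
#'   disable the warning.
#' @return a new, constrained `metabolic_model`; the input is unmodified.
#' @export
apply_medium <- function(model, med, keep_defaults = character(),
                         warn_unknown = TRUE) {
  ex <- exchanges(model)
  unknown <- setdiff(names(med), ex$compound_id)
  if (length(unknown) && warn_unknown)
    warning("medium compound(s) with no exchange reaction in ", model$id,
            ": ", paste(unknown, collapse = ", "))
  for (k in seq_len(nrow(ex))) {
    cmp <- ex$compound_id[k]
    if (cmp %in% keep_defaults) next
    i <- match(ex$reaction_id[k], model$rxns$id)
    model$rxns$lower_bound[i] <-
      if (cmp %in% names(med)) -med[[cmp]] else 0
  }
  model
}

#' Add a supplement to a medium
#'
#' Increases the availability of one compound by a fixed dose, creating the
#' entry when absent.  This is the in-silico analogue of spiking a culture
#' medium with a single nutrient.
#'
#' @param med a [medium()].
#' @param compound compound id.
#' @param amount non-negative dose (same units as the medium).
#' @return the supplemented medium.
#' @export
supplement_medium <- function(med, compound, amount) {
  if (!is.numeric(amount) || length(amount) != 1L || is.na(amount) ||
      amount < 0)
    stop("supplement amount must be a single non-negative number")
  vals <- as.numeric(med); names(vals) <- names(med)
  if (compound %in% names(vals)) vals[[compound]] <- vals[[compound]] + amount
  else vals[[compound]] <- amount
  medium(vals, name = attr(med, "medium_name"))
}

#' Construct a Biolog phenotype table
#'
#' @param compound_id character vector of assayed compounds.
#' @param od590,od750 dye / turbidity optical densities (>= 0); may be
#'   omitted when `growth` is given directly.
#' @param growth optional logical vector of precomputed growth calls.
#' @return data.frame of class `biolog_table`.
#' @export
biolog_table <- function(compound_id, od590 = NULL, od750 = NULL,
                         growth = NULL) {
  if (anyDuplicated(compound_id)) stop("duplicate compound ids in Biolog table")
  if (is.null(growth)) {
    if (is.null(od590) || is.null(od750))
      stop("either OD values or a growth call must be provided")
    if (any(od590 < 0) || any(od750 < 0)) stop("OD values must be >= 0")
    tab <- data.frame(compound_id = compound_id, od590 = od590,
                      od750 = od750, stringsAsFactors = FALSE)
  } else {
    tab <- data.frame(compound_id = compound_id, growth = as.logical(growth),
                      stringsAsFactors = FALSE)
  }
  class(tab) <- c("biolog_table", "data.frame")
  tab
}

#' Biolog growth call for one compound
#'
#' Growth on a compound is called when OD590 - OD750 strictly exceeds 0.1
#' (boundary equality is non-growth), or from the stored boolean when the
#' table carries precomputed calls.  A compound that is not on the plate is
#' reported as `NA` ("not assayed"), which downstream steps keep distinct
#' from a negative call.
#'
#' @param table a [biolog_table()].
#' @param compound compound id.
#' @param threshold OD difference that must be exceeded (default 0.1).
#' @return `TRUE`, `FALSE`, or `NA` when the compound was not assayed.
#' @export
biolog_growth_call <- function(table, compound, threshold = 0.1) {
  i <- match(compound, table$compound_id)
  if (is.na(i)) return(NA)
  if (!is.null(table$growth)) return(table$growth[i])
  (table$od590[i] - table$od750[i]) > threshold
}

# ---- tabular interfaces ----------------------------------------------------

#' Read / write a medium as TSV (columns: compound_id, availability)
#' @param path file path.
#' @param name medium label used when reading.
#' @return a [medium()].
#' @export
read_medium_tsv <- function(path, name = basename(path)) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  req_cols(d, c("compound_id", "availability"), path)
  medium(stats::setNames(d$availability, d$compound_id), name = name)
}

#' @rdname read_medium_tsv
#' @param med a [medium()] to write.
#' @export
write_medium_tsv <- function(med, path) {
  utils::write.table(
    data.frame(compound_id = names(med), availability = as.numeric(med)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a Biolog table from TSV
#'
#' Expects columns `compound_id, od590, od750`, or `compound_id, growth`.
#' @param path file path.
#' @return a [biolog_table()].
#' @export
read_biolog_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (all(c("od590", "od750") %in% names(d)))
    biolog_table(d$compound_id, od590 = d$od590, od750 = d$od750)
  else {
    req_cols(d, c("compound_id", "growth"), path)
    biolog_table(d$compound_id, growth = d$growth)
  }
}

#' Read compound-class annotations from TSV (columns: compound_id, class)
#'
#' Multiple rows per compound accumulate into a set of class labels
#' (HMDB-style, e.g. "amino acid").
#' @param path file path.
#' @return named list mapping compound id to a character vector of classes.
#' @export
read_annotation_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  req_cols(d, c("compound_id", "class"), path)
  if (any(!nzchar(d$class))) stop("empty class label in ", path)
  split(d$class, d$compound_id)
}

#' Read host colonization proportions from TSV
#'
#' Expects columns `condition, compartment, species, proportion` with
#' compartment in {lawn, worm} and proportions in \[0, 1\].
#' @param path file path.
#' @return data.frame.
#' @export
read_colonization_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  req_cols(d, c("condition", "compartment", "species", "proportion"), path)
  if (any(d$proportion < 0 | d$proportion > 1))
    stop("proportions must lie in [0, 1]")
  if (!all(d$compartment %in% c("lawn", "worm")))
    stop("compartment must be 'lawn' or 'worm'")
  d
}

req_cols <- function(d, cols, path) {
  miss <- setdiff(cols, names(d))
  if (length(miss))
    stop("file ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  invisible(d)
}
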