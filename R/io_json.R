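#' Read a metabolic model from file
#'
#' Two dialects are supported: SBML Level 3 with the FBC extension (the
#' community interchange standard) and a lighter tabular JSON dialect used
#' for toy and synthetic models.  The JSON schema is:
#'
#' ```
#' {
#'   "id": "species",
#'   "biomass_reaction_id": "BIOMASS",
#'   "metabolites": [{"id", "name", "compartment", "formula"}, ...],
#'   "reactions":  [{"id", "stoichiometry": {"met": coef, ...},
#'                   "lower_bound", "upper_bound",
#'                   "objective_coefficient", "is_exchange"}, ...]
#' }
#' ```
#'
#' `is_exchange` may be omitted; single-metabolite reactions consuming one
#' external-compartment metabolite with coefficient -1 are then auto-tagged.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"json"` or `"sbml"`.
#' @return a [metabolic_model()].
#' @export
read_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  if (format == "sbml") read_model_sbml(path) else read_model_json(path)
}

#' Write a metabolic model to file
#'
#' @param model a [metabolic_model()].
#' @inheritParams read_model
#' @return the path, invisibly.
#' @export
write_model <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  if (format == "sbml") write_model_sbml(model, path)
  else write_model_json(model, path)
}

read_model_json <- function(path) {
  x <- tryCatch(jsonlite::read_json(path),
                error = function(e) stop("cannot parse JSON model '", path,
                                         "': ", conditionMessage(e)))
  for (field in c("id", "metabolites", "reactions"))
    if (is.null(x[[field]]))
      stop("JSON model '", path, "' lacks required field '", field, "'")
  mets <- do.call(rbind, lapply(x$metabolites, function(m) {
    if (is.null(m$id) || is.null(m$compartment))
      stop("metabolite entry without id/compartment in '", path, "'")
    data.frame(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment,
               formula = m$formula %||% NA_character_,
               stringsAsFactors = FALSE)
  }))
  stoich <- list()
  rxns <- do.call(rbind, lapply(x$reactions, function(r) {
    if (is.null(r$id) || is.null(r$stoichiometry))
      stop("reaction entry without id/stoichiometry in '", path, "'")
    stoich[[r$id]] <<- unlist(r$stoichiometry)
    data.frame(id = r$id,
               lower_bound = r$lower_bound %||% 0,
               upper_bound = r$upper_bound %||% 1000,
               objective_coefficient = r$objective_coefficient %||% 0,
               is_exchange = r$is_exchange %||% NA,
               stringsAsFactors = FALSE)
  }))
  if (all(is.na(rxns$is_exchange))) rxns$is_exchange <- NULL
  else rxns$is_exchange[is.na(rxns$is_exchange)] <- FALSE
  metabolic_model(id = x$id, mets = mets, rxns = rxns, stoich = stoich,
                  biomass_reaction_id = x$biomass_reaction_id,
                  external_compartment = x$external_compartment %||% "e")
}

write_model_json <- function(model, path) {
  out <- list(
    id = model$id,
    external_compartment = model$external_compartment,
    biomass_reaction_id = model$biomass_reaction_id,
    metabolites = lapply(seq_len(nrow(model$mets)), function(i) {
      m <- model$mets[i, ]
      x <- list(id = m$id, name = m$name, compartment = m$compartment)
      if (!is.na(m$formula)) x$formula <- m$formula
      x
    }),
    reactions = lapply(seq_len(nrow(model$rxns)), function(i) {
      r <- model$rxns[i, ]
      list(id = r$id,
           stoichiometry = as.list(model$stoich[[r$id]]),
           lower_bound = r$lower_bound, upper_bound = r$upper_bound,
           objective_coefficient = r$objective_coefficient,
           is_exchange = r$is_exchange)
    }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
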