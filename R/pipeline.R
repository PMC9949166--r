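# Run configuration and the end-to-end pipeline driver.

#' Build and validate a run configuration
#'
#' Defaults follow the screen's standard operating point: supplement dose
#' 10 mmol/gDW/hr (batch) and 0.01 mM (spatial), 30x30 grid, 20 individuals
#' per species, 12 iterations, 15 replicates, 1000-fold medium dilution,
#' sixth-digit rounding, selection cutoff 0.01, numerical tolerance 1e-6,
#' FDR alpha 0.05.  Values may be overridden from a YAML file or a named
#' list; unknown keys are rejected by name.
#'
#' @param config named list or path to a YAML file with overrides.
#' @return object of class `prebioscreen_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    seed = 42L,
    dose = 10, dose_mM = 0.01,
    cutoff = 0.01, digits = 6, tol = 1e-6, alpha = 0.05,
    grid = c(30L, 30L), n_per_species = 20L, n_steps = 12L,
    n_replicates = 15L, dilution = 1000,
    timestep_hours = 1, cell_volume_ul = 1,
    flux_penalty = 1e-6,
    methods = c("fba_single", "community_fba", "abm"),
    niche_sizes = NULL, niche_iterations = 50L,
    out_dir = "prebioscreen_results")
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  for (k in c("cutoff", "digits", "tol", "alpha", "dose", "dose_mM"))
    if (!is.numeric(cfg[[k]]) || any(cfg[[k]] < 0))
      stop("configuration key '", k, "' must be non-negative")
  structure(cfg, class = "prebioscreen_config")
}

#' Run the full analysis pipeline
#'
#' Stages, in order: uptake-niche analysis of the community; the requested
#' screen arms with intersection and Biolog confirmation; compound-class
#' enrichment of the confirmed set (when annotations are given).  All
#' outputs are written as TSV/JSON under `config$out_dir` together with a
#' `manifest.json` recording the configuration, seeds, package version and
#' per-file checksums; a rerun with the same configuration reproduces the
#' checksums.
#'
#' @param models list of member [metabolic_model()]s (target first by
#'   default).
#' @param med batch [medium()].
#' @param medium_mM spatial [medium()]; required when the `abm` arm is run.
#' @param biolog optional [biolog_table()].
#' @param annotation optional compound-class annotation (named list).
#' @param config a [run_config()].
#' @param target target species id.
#' @return the directory path, invisibly; the `screen_result` and
#'   `niche_report` are attached as attributes.
#' @export
run_pipeline <- function(models, med, medium_mM = NULL, biolog = NULL,
                         annotation = NULL, config = run_config(),
                         target = models[[1L]]$id) {
  stopifnot(inherits(config, "prebioscreen_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(...) file.path(config$out_dir, ...)
  written <- character()
  emit_tsv <- function(d, name) {
    utils::write.table(d, outfile(name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <<- c(written, name)
  }
  emit_json <- function(x, name) {
    jsonlite::write_json(x, outfile(name), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <<- c(written, name)
  }

  # stage 1: niche analysis
  profiles <- lapply(models, uptake_profile, med = med, tol = config$tol)
  niche <- unique_uptake_compounds(profiles)
  emit_json(list(community = niche$community,
                 unique_compounds = niche$unique_compounds,
                 fraction_with_unique = niche$fraction_with_unique),
            "niche_report.json")
  emit_tsv(do.call(rbind, lapply(profiles, function(p)
    if (length(p$uptake_compounds))
      data.frame(species_id = p$species_id,
                 compound_id = p$uptake_compounds) else NULL)),
    "uptake_profiles.tsv")

  # stage 2: the screen
  other <- setdiff(vapply(models, `[[`, character(1L), "id"), target)[1L]
  screen <- run_screen(
    models, med, medium_mM = medium_mM, target = target, other = other,
    methods = config$methods, biolog = biolog, dose = config$dose,
    cutoff = config$cutoff, digits = config$digits,
    dose_mM = config$dose_mM, n_steps = config$n_steps,
    n_replicates = config$n_replicates, grid = config$grid,
    n_per_species = config$n_per_species, alpha = config$alpha,
    seed = config$seed)
  for (m in names(attr(screen, "evidence")))
    emit_tsv(attr(screen, "evidence")[[m]], paste0("screen_", m, ".tsv"))
  emit_json(list(per_method = screen$per_method,
                 intersection = screen$intersection,
                 biolog_confirmed = screen$biolog_confirmed,
                 not_assayed = screen$not_assayed,
                 biolog_negative = screen$biolog_negative,
                 target = target), "screen_result.json")

  # stage 3: enrichment of the confirmed candidates
  if (!is.null(annotation) && length(screen$biolog_confirmed)) {
    tmodel <- models[[match(target,
                            vapply(models, `[[`, character(1L), "id"))]]
    background <- intersect(names(annotation),
                            exchanges(tmodel)$compound_id)
    enr <- class_enrichment(intersect(screen$biolog_confirmed, background),
                            annotation, background)
    emit_tsv(enr, "class_enrichment.tsv")
  }

  manifest <- list(
    package = "prebioscreen",
    version = as.character(utils::packageVersion("prebioscreen")),
    config = unclass(config),
    files = as.list(tools::md5sum(outfile(written))))
  names(manifest$files) <- written
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  out <- config$out_dir
  attr(out, "screen") <- screen
  attr(out, "niche") <- niche
  invisible(out)
}
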