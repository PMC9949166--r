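# Uptake-niche analysis: which compounds can each species take up, which of
# those are unique within a community, and how the chance of holding a
# unique compound falls as communities grow.

#' Uptake profile of a species under a medium
#'
#' Constrains the model with the medium, then tests every exchange reaction
#' with [can_take_up()]: a compound belongs to the profile when the minimal
#' feasible flux through its exchange is strictly negative, i.e. when the
#' network can actually absorb it.  Uptake capability is a species-by-medium
#' property, independent of the community the species is later placed in,
#' so profiles are computed once and reused across community subsets.
#'
#' @param model a [metabolic_model()].
#' @param med a [medium()].
#' @param probe `"off"` (default): compounds absent from the medium are
#'   closed and cannot appear in the profile; `"open"`: every exchange is
#'   opened at `probe_flux` instead, a sensitivity mode that explores the
#'   full structural uptake repertoire.
#' @param probe_flux availability used in probe mode (mmol/gDW/hr).
#' @param tol numerical zero threshold for the uptake test.
#' @return object of class `uptake_profile`: list with `species_id` and the
#'   character set `uptake_compounds`.
#' @export
uptake_profile <- function(model, med, probe = c("off", "open"),
                           probe_flux = 10, tol = 1e-6) {
  probe <- match.arg(probe)
  ex <- exchanges(model)
  m <- if (probe == "open")
    apply_medium(model, medium(stats::setNames(
      rep(probe_flux, nrow(ex)), ex$compound_id), name = "probe"))
  else apply_medium(model, med, warn_unknown = FALSE)
  ok <- vapply(ex$reaction_id, function(rid) can_take_up(m, rid, tol = tol),
               logical(1L), USE.NAMES = FALSE)
  structure(list(species_id = model$id,
                 uptake_compounds = sort(ex$compound_id[ok])),
            class = "uptake_profile")
}

#' @export
print.uptake_profile <- function(x, ...) {
  cat("<uptake_profile> ", x$species_id, ": ",
      length(x$uptake_compounds), " compounds\n", sep = "")
  invisible(x)
}

#' Read precomputed uptake profiles from TSV
#'
#' Accepts a table with columns `species_id, compound_id` (one row per
#' species-compound pair), as written by the pipeline, so the subsampling
#' analysis can run without re-solving any model.
#'
#' @param path file path.
#' @return list of [uptake_profile()]s.
#' @export
read_uptake_profiles_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  req_cols(d, c("species_id", "compound_id"), path)
  by_species <- split(d$compound_id, d$species_id)
  lapply(names(by_species), function(sid)
    structure(list(species_id = sid,
                   uptake_compounds = sort(unique(by_species[[sid]]))),
              class = "uptake_profile"))
}

#' Unique uptake compounds within a community
#'
#' For each species, the set difference of its uptake set against the union
#' of all other members' sets: compounds only that species can consume --
#' its private metabolic niche.  The report's `fraction_with_unique` is the
#' fraction of community members holding at least one such compound.
#'
#' @param profiles list of [uptake_profile()]s with distinct species ids
#'   (>= 2).
#' @return object of class `niche_report`: list with `community`,
#'   `unique_compounds` (per-species sets) and `fraction_with_unique`.
#' @export
unique_uptake_compounds <- function(profiles) {
  if (length(profiles) < 2L) stop("need at least two uptake profiles")
  ids <- vapply(profiles, `[[`, character(1L), "species_id")
  if (anyDuplicated(ids)) stop("duplicate species ids: ",
    paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sets <- lapply(profiles, `[[`, "uptake_compounds")
  names(sets) <- ids
  uniq <- lapply(seq_along(sets), function(i)
    setdiff(sets[[i]], unlist(sets[-i], use.names = FALSE)))
  names(uniq) <- ids
  structure(list(
    community = ids, unique_compounds = uniq,
    fraction_with_unique = mean(lengths(uniq) > 0)),
    class = "niche_report")
}

#' @export
print.niche_report <- function(x, ...) {
  cat("<niche_report> ", length(x$community), " species, fraction with a ",
      "unique compound: ", format(x$fraction_with_unique), "\n", sep = "")
  invisible(x)
}

#' Unique-compound fraction versus community size
#'
#' Draws random communities (uniform subsets without replacement) of
#' increasing size from a pool of uptake profiles and records, for each
#' draw, the fraction of members holding at least one unique uptake
#' compound.  With overlapping niches this fraction falls quickly with
#' community size, which is what rules out single-species niches as a
#' general supplementation strategy.
#'
#' @param profiles list of [uptake_profile()]s (the pool).
#' @param sizes integer community sizes, each within `[2, length(profiles)]`.
#' @param iterations random subsets per size.
#' @param seed RNG seed; the table is reproducible given the seed.
#' @return data.frame with columns `size`, `iteration`,
#'   `fraction_with_unique`.
#' @export
unique_fraction_curve <- function(profiles, sizes, iterations = 50,
                                  seed = 1) {
  if (any(sizes < 2) || any(sizes > length(profiles)))
    stop("sizes must lie in [2, number of profiles]")
  if (iterations < 1) stop("iterations must be >= 1")
  with_seed(seed, {
    rows <- lapply(sizes, function(sz) {
      fr <- vapply(seq_len(iterations), function(it) {
        unique_uptake_compounds(
          profiles[sample(length(profiles), sz)])$fraction_with_unique
      }, numeric(1L))
      data.frame(size = sz, iteration = seq_len(iterations),
                 fraction_with_unique = fr)
    })
    do.call(rbind, rows)
  })
}
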