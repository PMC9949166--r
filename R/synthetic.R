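# Synthetic metabolic models with planted ground truth.
#
# The generator builds the smallest networks whose FBA optima are analytic:
# per uptake compound c with biomass yield y, three reactions
#   EX_c:   c_e <->           (exchange; medium sets the uptake bound)
#   T_c:    c_e -> c_c        (transport)
#   CNV_c:  c_c -> y * X      (conversion into the biomass precursor X)
# plus one biomass reaction BIOMASS: X -> (objective).  Growth is then
# mu = sum_c y_c * u_c with u_c the realized uptake flux, which makes every
# planted effect checkable in closed form.

#' Specification of one synthetic species
#'
#' @param species_id species name.
#' @param uptake named numeric vector: compound id -> biomass yield
#'   (gDW produced per mmol of compound taken up, per unit flux).
#' @param unique_compounds subset of `names(uptake)` planted as compounds
#'   no other community member can take up.
#' @param secretion optional named list: compound id (consumed) -> named
#'   numeric of secreted compound id -> stoichiometric fraction.
#' @param dead_end_exchanges compounds given an exchange reaction but no
#'   consuming pathway; mass balance forces their uptake to zero, which
#'   makes them structurally inert supplements.
#' @return object of class `species_spec`.
#' @export
species_spec <- function(species_id, uptake, unique_compounds = character(),
                         secretion = NULL,
                         dead_end_exchanges = character()) {
  if (anyDuplicated(names(uptake))) stop("duplicate compound ids in uptake")
  if (any(uptake < 0)) stop("yields must be >= 0")
  if (!all(unique_compounds %in% names(uptake)))
    stop("unique_compounds must be a subset of the uptake compounds")
  structure(list(species_id = species_id, uptake = uptake,
                 unique_compounds = unique_compounds, secretion = secretion,
                 dead_end_exchanges = dead_end_exchanges),
            class = "species_spec")
}

#' Build a toy metabolic model from a species specification
#'
#' The resulting model satisfies all `metabolic_model` invariants, and its
#' uptake profile on a permissive medium equals exactly the spec's uptake
#' set (plus nothing): that equality is the generator's ground-truth
#' contract used throughout the test-suite.
#'
#' @param spec a [species_spec()].
#' @param default_bound magnitude used for unconstrained internal bounds.
#' @return a [metabolic_model()].
#' @export
generate_species_model <- function(spec, default_bound = 1000) {
  stopifnot(inherits(spec, "species_spec"))
  mets <- data.frame(id = "X", name = "biomass precursor",
                     compartment = "c", formula = NA_character_,
                     stringsAsFactors = FALSE)
  rxns <- list(); stoich <- list()
  add_met <- function(id, comp) {
    if (!id %in% mets$id)
      mets <<- rbind(mets, data.frame(id = id, name = id, compartment = comp,
                                      formula = NA_character_))
  }
  add_rxn <- function(id, s, lb, ub, obj = 0) {
    rxns[[id]] <<- data.frame(id = id, lower_bound = lb, upper_bound = ub,
                              objective_coefficient = obj)
    stoich[[id]] <<- s
  }
  secreted <- unique(unlist(lapply(spec$secretion, names)))
  for (cmp in names(spec$uptake)) {
    y <- spec$uptake[[cmp]]
    ce <- paste0(cmp, "_e"); cc <- paste0(cmp, "_c")
    add_met(ce, "e"); add_met(cc, "c")
    add_rxn(paste0("EX_", cmp), stats::setNames(-1, ce),
            -default_bound, default_bound)
    add_rxn(paste0("T_", cmp), stats::setNames(c(-1, 1), c(ce, cc)),
            0, default_bound)
    s <- stats::setNames(c(-1, y), c(cc, "X"))
    sec <- spec$secretion[[cmp]]
    if (!is.null(sec)) {
      se <- paste0(names(sec), "_e")
      for (m in se) add_met(m, "e")
      s <- c(s, stats::setNames(as.numeric(sec), se))
    }
    add_rxn(paste0("CNV_", cmp), s, 0, default_bound)
  }
  # secretion-only exchanges (no uptake) for secreted products
  for (cmp in setdiff(secreted, names(spec$uptake))) {
    ce <- paste0(cmp, "_e"); add_met(ce, "e")
    add_rxn(paste0("EX_", cmp), stats::setNames(-1, ce), 0, default_bound)
  }
  for (cmp in setdiff(spec$dead_end_exchanges, names(spec$uptake))) {
    ce <- paste0(cmp, "_e"); add_met(ce, "e")
    add_rxn(paste0("EX_", cmp), stats::setNames(-1, ce),
            -default_bound, default_bound)
  }
  add_rxn("BIOMASS", stats::setNames(-1, "X"), 0, default_bound, obj = 1)
  metabolic_model(id = spec$species_id, mets = mets,
                  rxns = do.call(rbind, rxns), stoich = stoich,
                  biomass_reaction_id = "BIOMASS")
}

#' Two-species benchmark with planted precision prebiotics
#'
#' Emulates a two-member community in which the species share most of their
#' uptake compounds while each also holds a small private niche; the default
#' 17/2/1 compound split reproduces an 85%/10%/5% shared/target-only/
#' competitor-only partition of the uptake-compound universe.  A planted
#' subset of the shared compounds gives the target species a biomass-yield
#' advantage (factor `advantage`); on all remaining shared compounds the
#' competitor holds a slight edge (`competitor_edge`), reflecting a
#' generally competitive second species.  Those planted compounds are the
#' precision prebiotics the screen must recover.
#'
#' @param n_shared,n_unique_target,n_unique_other compound counts per
#'   niche category.
#' @param n_prebiotics number of shared compounds planted with a target
#'   yield advantage.
#' @param advantage target/competitor yield ratio on planted compounds
#'   (> 1).
#' @param competitor_edge competitor/target yield ratio on non-planted
#'   shared compounds (>= 1).
#' @param base_yield central biomass yield (gDW per mmol).
#' @param availability batch-medium availability per compound
#'   (mmol/gDW/hr).
#' @param conc_mM spatial-medium concentration per compound (mM, before
#'   dilution).
#' @param n_not_on_plate number of shared non-planted compounds left off
#'   the Biolog plate ("not assayed").
#' @param target_id,other_id species names.
#' @param seed RNG seed; output is byte-identical for equal seeds.
#' @return list with `models` (target first), `medium` (batch),
#'   `medium_mM` (spatial), `biolog`, `annotation`, and `ground_truth`
#'   (planted prebiotics, niche categories, per-species yields).
#' @export
generate_two_species_benchmark <- function(
    n_shared = 17, n_unique_target = 2, n_unique_other = 1,
    n_prebiotics = 8, advantage = 1.5, competitor_edge = 1.1,
    base_yield = 0.05, availability = 10, conc_mM = 10,
    n_not_on_plate = 1, target_id = "target", other_id = "competitor",
    seed = 1) {
  if (advantage <= 1) stop("advantage factor must be > 1")
  if (competitor_edge < 1) stop("competitor_edge must be >= 1")
  if (n_prebiotics > n_shared) stop("more planted prebiotics than shared compounds")
  with_seed(seed, {

  shared <- sprintf("S%02d", seq_len(n_shared))
  ut <- sprintf("UT%d", seq_len(n_unique_target))
  uo <- sprintf("UO%d", seq_len(n_unique_other))
  planted <- sort(sample(shared, n_prebiotics))
  plain <- setdiff(shared, planted)

  jit <- function(n) base_yield * stats::runif(n, 0.8, 1.2)
  y_other_shared <- stats::setNames(jit(n_shared), shared)
  y_target_shared <- ifelse(shared %in% planted,
                            y_other_shared * advantage,
                            y_other_shared / competitor_edge)
  names(y_target_shared) <- shared
  y_target <- c(y_target_shared, stats::setNames(jit(n_unique_target), ut))
  y_other <- c(y_other_shared, stats::setNames(jit(n_unique_other), uo))

  models <- list(
    generate_species_model(species_spec(target_id, y_target,
                                        unique_compounds = ut)),
    generate_species_model(species_spec(other_id, y_other,
                                        unique_compounds = uo)))
  names(models) <- c(target_id, other_id)

  all_cmp <- c(shared, ut, uo)
  med <- medium(stats::setNames(rep(availability, length(all_cmp)), all_cmp),
                name = "synthetic NGM-like (batch)")
  med_mM <- medium(stats::setNames(rep(conc_mM, length(all_cmp)), all_cmp),
                   name = "synthetic NGM-like (mM)")

  # Biolog: positive for everything the target can take up, negative for
  # competitor-only compounds; a few shared compounds are left off the
  # plate to exercise the "not assayed" path.
  off_plate <- if (n_not_on_plate > 0)
    sort(sample(plain, min(n_not_on_plate, length(plain)))) else character()
  assayed <- setdiff(all_cmp, off_plate)
  biolog <- biolog_table(
    compound_id = assayed,
    od590 = ifelse(assayed %in% names(y_target), 0.45, 0.25),
    od750 = rep(0.2, length(assayed)))

  # class annotation with one class over-represented among the planted set
  classes <- stats::setNames(rep("carbohydrate", length(all_cmp)), all_cmp)
  classes[planted] <- "amino acid"
  extra_aa <- utils::head(plain, 2)
  classes[extra_aa] <- "amino acid"
  classes[uo] <- "organic acid"
  annotation <- lapply(classes, function(x) x)

  list(models = models, medium = med, medium_mM = med_mM, biolog = biolog,
       annotation = annotation,
       ground_truth = list(
         planted_prebiotics = planted, target = target_id,
         shared = shared, unique_target = ut, unique_other = uo,
         yields = list(target = y_target, competitor = y_other),
         not_on_plate = off_plate))
  })
}

#' Null benchmark: two identical species and inert supplements
#'
#' Builds two metabolically identical species that grow on a shared set of
#' usable compounds, plus a panel of inert compounds present in the
#' environment but connected to neither species' metabolism (dead-end
#' exchanges).  Because no asymmetry is planted, a calibrated screen should
#' select nothing.
#'
#' @param n_usable number of shared growth compounds.
#' @param n_inert number of inert (dead-end) supplement compounds.
#' @param base_yield,availability,conc_mM as in
#'   [generate_two_species_benchmark()].
#' @param seed RNG seed.
#' @return list with `models`, `medium`, `medium_mM`, and `inert_compounds`.
#' @export
generate_null_benchmark <- function(n_usable = 10, n_inert = 40,
                                    base_yield = 0.05, availability = 10,
                                    conc_mM = 10, seed = 1) {
  with_seed(seed, {
  usable <- sprintf("S%02d", seq_len(n_usable))
  inert <- sprintf("Z%02d", seq_len(n_inert))
  y <- stats::setNames(base_yield * stats::runif(n_usable, 0.8, 1.2), usable)
  mk <- function(id) generate_species_model(
    species_spec(id, y, dead_end_exchanges = inert))
  models <- list(N1 = mk("N1"), N2 = mk("N2"))
  all_cmp <- c(usable, inert)
  list(models = models,
       medium = medium(stats::setNames(rep(availability, length(all_cmp)),
                                       all_cmp), name = "null (batch)"),
       medium_mM = medium(stats::setNames(rep(conc_mM, length(all_cmp)),
                                          all_cmp), name = "null (mM)"),
       inert_compounds = inert)
  })
}

#' Pool of species with tunable uptake-niche overlap
#'
#' Each species draws `n_compounds` uptake compounds from a common pool
#' whose size is `n_compounds / overlap`, giving an expected pairwise
#' niche overlap equal to `overlap`.  `overlap = 1` yields identical
#' profiles; `overlap = 0` yields fully disjoint private niches.
#'
#' @param n_species number of species.
#' @param overlap expected pairwise uptake-set overlap in \[0, 1\].
#' @param n_compounds uptake compounds per species.
#' @param seed RNG seed.
#' @param base_yield central biomass yield.
#' @return list of [metabolic_model()]s; the companion permissive medium
#'   covering the whole pool is attached as attribute `medium`.
#' @export
generate_community_pool <- function(n_species, overlap, n_compounds = 10,
                                    seed = 1, base_yield = 0.05) {
  if (overlap < 0 || overlap > 1) stop("overlap must lie in [0, 1]")
  with_seed(seed, {
  if (overlap == 0) {
    pool_size <- n_compounds * n_species
  } else {
    pool_size <- max(n_compounds, ceiling(n_compounds / overlap))
  }
  pool <- sprintf("P%03d", seq_len(pool_size))
  models <- lapply(seq_len(n_species), function(i) {
    cmps <- if (overlap == 0)
      pool[(i - 1) * n_compounds + seq_len(n_compounds)]
    else if (overlap == 1) pool
    else sample(pool, n_compounds)
    y <- stats::setNames(base_yield * stats::runif(length(cmps), 0.8, 1.2),
                         cmps)
    generate_species_model(species_spec(sprintf("SP%03d", i), y))
  })
  names(models) <- sprintf("SP%03d", seq_len(n_species))
  attr(models, "medium") <- medium(
    stats::setNames(rep(10, pool_size), pool), name = "pool (permissive)")
  models
  })
}

# evaluate an expression under a fixed seed, restoring the caller's RNG
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
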