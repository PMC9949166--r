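# The decision layer: run the three screen arms (single-species FBA,
# community FBA, individual-based simulation), apply the rounding and
# cutoff rules, intersect the arms, cross-reference Biolog growth calls,
# test compound-class enrichment, and compare host colonization
# proportions against a diet-shift expectation.

#' Single-species FBA supplementation screen
#'
#' For each compound, the model is grown on the baseline medium and on the
#' medium with `dose` added, and the relative growth-rate increase
#' `(mu_suppl - mu_base) / mu_base` is recorded, with both growth rates
#' rounded to `digits` decimals first.  A compound is selected when the
#' relative change strictly exceeds `cutoff`.  A zero baseline growth rate
#' leaves the change undefined; such compounds are excluded and flagged.
#'
#' @param model target [metabolic_model()].
#' @param med baseline [medium()].
#' @param compounds compound ids to screen (default: all medium compounds).
#' @param dose supplement dose (default 10 mmol/gDW/hr).
#' @param cutoff selection threshold on the relative change (default 0.01).
#' @param digits rounding of raw growth rates (default 6).
#' @return data.frame (compound, mu_base, mu_suppl, rel_change, selected,
#'   note) with the selected compound ids in attribute `selected`.
#' @export
screen_single_fba <- function(model, med, compounds = names(med), dose = 10,
                              cutoff = 0.01, digits = 6) {
  base <- solve_fba(apply_medium(model, med, warn_unknown = FALSE))
  if (base$status != "optimal")
    stop("baseline FBA ended with status ", base$status)
  mu0 <- round(base$objective_value, digits)
  rows <- lapply(compounds, function(cmp) {
    s <- solve_fba(apply_medium(model, supplement_medium(med, cmp, dose),
                                warn_unknown = FALSE))
    mu1 <- round(s$objective_value, digits)
    if (mu0 <= 0)
      return(data.frame(compound = cmp, mu_base = mu0, mu_suppl = mu1,
                        rel_change = NA_real_, selected = FALSE,
                        note = "undefined-baseline"))
    data.frame(compound = cmp, mu_base = mu0, mu_suppl = mu1,
               rel_change = (mu1 - mu0) / mu0,
               selected = (mu1 - mu0) / mu0 > cutoff, note = "")
  })
  out <- do.call(rbind, rows)
  attr(out, "selected") <- out$compound[out$selected]
  out
}

#' Community-FBA supplementation screen for a target species
#'
#' Wraps [community_supplement_effect()] over a compound panel and selects
#' the compounds whose supplementation increases the target's normalized
#' abundance by more than `cutoff`.
#'
#' @inheritParams community_supplement_effect
#' @param target species id whose enrichment is screened for.
#' @param compounds compound ids to screen.
#' @return data.frame (compound, delta, growth_ratio, selected, screenable)
#'   for the target species, selected ids in attribute `selected`.
#' @export
screen_community_fba <- function(models, med, target,
                                 compounds = names(med), dose = 10,
                                 flux_penalty = 1e-6, cutoff = 0.01,
                                 digits = 6) {
  ids <- vapply(models, `[[`, character(1L), "id")
  if (!target %in% ids) stop("target '", target, "' is not among the models")
  rows <- lapply(compounds, function(cmp) {
    eff <- community_supplement_effect(models, med, cmp, dose = dose,
                                       flux_penalty = flux_penalty,
                                       digits = digits, cutoff = cutoff)
    tr <- eff[eff$species == target, ]
    data.frame(compound = cmp, delta = tr$delta,
               growth_ratio = tr$growth_ratio, selected = tr$selected,
               screenable = attr(eff, "screenable"))
  })
  out <- do.call(rbind, rows)
  attr(out, "selected") <- out$compound[out$selected]
  out
}

#' Two-sided Wilcoxon rank sum test
#'
#' Exact p-value for small tieless samples (total n <= 20), normal
#' approximation with tie correction otherwise; symmetric in its arguments.
#' All-tied inputs give p = 1.
#'
#' @param x,y numeric vectors (non-empty).
#' @return the two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("x and y must be non-empty")
  if (all(c(x, y) == c(x, y)[1L])) return(1)  # fully tied
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- !has_ties && (length(x) + length(y)) <= 20
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up adjustment (monotone in the sorted order, capped at 1).
#'
#' @param pvalues numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-compound selection statistics for the individual-based arm
#'
#' Compares the target's and the competitor's per-replicate relative
#' biomass changes with a two-sided Wilcoxon rank sum test.  The compound
#' is a candidate when the target's median change exceeds the competitor's;
#' significance is assessed on the (later FDR-adjusted) p-value.
#'
#' @param result an [run_supplement_replicates()] result with relative
#'   changes (i.e. from a supplemented run).
#' @param target,other species ids.
#' @return one-row data.frame: medians, their difference, raw p-value, and
#'   `median_favors_target`.
#' @export
screen_abm_stats <- function(result, target, other) {
  rel <- result$rel_change
  if (is.null(rel)) stop("result carries no relative changes ",
                         "(control-only run?)")
  xt <- rel$rel_change[rel$species == target]
  xo <- rel$rel_change[rel$species == other]
  if (length(xt) < 2 || length(xo) < 2)
    stop("need >= 2 replicates per species")
  data.frame(compound = result$compound,
             median_target = stats::median(xt),
             median_other = stats::median(xo),
             median_diff = stats::median(xt) - stats::median(xo),
             p_value = wilcoxon_rank_sum(xt, xo),
             median_favors_target = stats::median(xt) > stats::median(xo))
}

#' Individual-based simulation screen for a target species
#'
#' Runs matched supplementation replicates for every compound (one shared
#' control set), tests target-vs-competitor relative biomass changes per
#' compound, adjusts p-values across compounds with Benjamini-Hochberg, and
#' selects compounds whose effect on the target is larger by median and
#' significant at `alpha` after adjustment.
#'
#' @inheritParams run_supplement_replicates
#' @param target,other species ids (target is screened for).
#' @param compounds compound ids to screen.
#' @param alpha FDR-adjusted significance level (default 0.05).
#' @param ... passed to [run_supplement_replicates()] /(from there)
#'   [init_arena()], e.g. `grid`, `n_per_species`.
#' @return data.frame of per-compound statistics with adjusted p-values and
#'   selection flags; selected ids in attribute `selected`.
#' @export
screen_abm <- function(models, medium_mM, target, other,
                       compounds = names(medium_mM), dose_mM = 0.01,
                       n_steps = 12, n_replicates = 15, seed = 1,
                       alpha = 0.05, ...) {
  control <- run_supplement_replicates(models, medium_mM, compound = NULL,
                                       n_steps = n_steps,
                                       n_replicates = n_replicates,
                                       seed = seed, ...)
  rows <- lapply(compounds, function(cmp) {
    res <- run_supplement_replicates(models, medium_mM, compound = cmp,
                                     dose_mM = dose_mM, n_steps = n_steps,
                                     n_replicates = n_replicates,
                                     seed = seed, control = control, ...)
    screen_abm_stats(res, target, other)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_fdr(out$p_value)
  out$selected <- out$median_favors_target & out$p_adjusted < alpha
  attr(out, "selected") <- out$compound[out$selected]
  out
}

#' Intersect screen arms and confirm with Biolog data
#'
#' The candidate set is the intersection of the per-method selections; a
#' candidate is Biolog-confirmed when the plate supports growth of the
#' target on it.  Candidates without a plate entry are reported separately
#' as `not_assayed`, never silently dropped.
#'
#' @param per_method_sets named list of character vectors (selected
#'   compound ids per method).
#' @param biolog optional [biolog_table()].
#' @return object of class `screen_result` with `per_method`,
#'   `intersection`, `biolog_confirmed`, `not_assayed` and
#'   `biolog_negative`.
#' @export
intersect_and_confirm <- function(per_method_sets, biolog = NULL) {
  if (!length(per_method_sets)) stop("need at least one method set")
  inter <- sort(Reduce(intersect, per_method_sets))
  confirmed <- character(); not_assayed <- character(); neg <- character()
  if (!is.null(biolog)) {
    for (cmp in inter) {
      g <- biolog_growth_call(biolog, cmp)
      if (is.na(g)) not_assayed <- c(not_assayed, cmp)
      else if (g) confirmed <- c(confirmed, cmp)
      else neg <- c(neg, cmp)
    }
  }
  structure(list(per_method = per_method_sets, intersection = inter,
                 biolog_confirmed = confirmed, not_assayed = not_assayed,
                 biolog_negative = neg),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result>\n")
  for (m in names(x$per_method))
    cat("  ", m, ": ", length(x$per_method[[m]]), " selected\n", sep = "")
  cat("  shared across methods: ", length(x$intersection),
      "\n  Biolog-confirmed: ", length(x$biolog_confirmed),
      if (length(x$not_assayed))
        paste0("  (not assayed: ", length(x$not_assayed), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Compound-class enrichment of a candidate set
#'
#' One-sided Fisher's exact test (enrichment) per class on the 2x2 table of
#' candidate membership versus class membership over a background compound
#' universe (typically all metabolites of the target's model), with a
#' Benjamini-Hochberg adjusted column.
#'
#' @param candidates character vector, subset of `background`.
#' @param annotation named list: compound id -> character vector of class
#'   labels.
#' @param background character vector of background compound ids.
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`.
#' @return data.frame (class, in-candidates/in-class counts, odds ratio,
#'   p_value, p_adjusted), sorted by p-value.
#' @export
class_enrichment <- function(candidates, annotation, background,
                             alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (!all(candidates %in% background))
    stop("candidates must be a subset of the background")
  classes <- sort(unique(unlist(annotation[background])))
  rows <- lapply(classes, function(cl) {
    in_class <- background[vapply(background, function(cmp)
      cl %in% annotation[[cmp]], logical(1L))]
    a <- length(intersect(candidates, in_class))
    b <- length(setdiff(candidates, in_class))
    c_ <- length(setdiff(in_class, candidates))
    d <- length(background) - a - b - c_
    ft <- stats::fisher.test(matrix(c(a, c_, b, d), 2L),
                             alternative = alternative)
    data.frame(class = cl, n_candidates_in_class = a,
               n_candidates_not_in_class = b,
               n_background_in_class = length(in_class),
               odds_ratio = unname(ft$estimate), p_value = ft$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_fdr(out$p_value)
  out[order(out$p_value), ]
}

#' Expected target proportion in the host after supplementation
#'
#' Under the null hypothesis that supplementation changes host colonization
#' only through the diet available on the lawn, the expected proportion of
#' the target in supplemented hosts is the proportion on supplemented lawns
#' multiplied by the host-filtering shift observed without supplementation:
#'
#'   E = prop_lawn_suppl * (prop_worm_base / prop_lawn_base)
#'
#' Observed host proportions above this expectation indicate an enrichment
#' inside the host beyond the change in diet.
#'
#' @param prop_lawn_base,prop_lawn_suppl,prop_worm_base proportions in
#'   \[0, 1\]; `prop_lawn_base` must be positive.
#' @return the expected proportion, clipped to \[0, 1\] with a warning when
#'   the host-filtering ratio pushes it above 1.
#' @export
expected_worm_proportion <- function(prop_lawn_base, prop_lawn_suppl,
                                     prop_worm_base) {
  props <- c(prop_lawn_base, prop_lawn_suppl, prop_worm_base)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (prop_lawn_base <= 0)
    stop("expectation undefined: baseline lawn proportion is zero")
  e <- prop_lawn_suppl * prop_worm_base / prop_lawn_base
  if (e > 1) {
    warning("expected proportion exceeds 1; clipped")
    e <- 1
  }
  e
}

#' Chi-square test of observed counts against expected proportions
#'
#' Pearson goodness-of-fit of two observed category counts against expected
#' proportions (df = 1), without continuity correction.
#'
#' @param observed_counts positive counts of length 2.
#' @param expected_props expected proportions of length 2, summing to 1.
#' @return list with `chi2`, `df` and `p`.
#' @export
chisq_observed_vs_expected <- function(observed_counts, expected_props) {
  if (length(observed_counts) != 2L || length(expected_props) != 2L)
    stop("expected two categories")
  if (any(observed_counts <= 0)) stop("counts must be positive")
  if (abs(sum(expected_props) - 1) > 1e-9)
    stop("expected proportions must sum to 1")
  if (any(expected_props <= 0)) stop("zero expected count")
  expected <- sum(observed_counts) * expected_props
  chi2 <- sum((observed_counts - expected)^2 / expected)
  list(chi2 = chi2, df = 1L,
       p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' Run the full three-arm precision-prebiotic screen
#'
#' Executes the requested arms at their defaults (dose 10 mmol/gDW/hr for
#' the batch arms, 0.01 mM once at the start for the spatial arm; sixth-
#' digit rounding; selection cutoff 0.01; FDR alpha 0.05), intersects the
#' per-arm selections, and cross-references the result with Biolog growth
#' calls for the target.  Compounds only the target can take up are
#' excluded from the panel by default: such single-species niches are
#' screened out up front, mirroring the motivation for looking at shared
#' compounds in the first place.
#'
#' @param models list of member [metabolic_model()]s; the first two are the
#'   target and competitor unless `target`/`other` are given.
#' @param med batch [medium()] (mmol/gDW/hr).
#' @param medium_mM spatial [medium()] (mM) for the individual-based arm.
#' @param target,other species ids.
#' @param methods subset of `c("fba_single", "community_fba", "abm")`.
#' @param compounds panel to screen; default: all medium compounds except
#'   the target's unique uptake compounds.
#' @param biolog optional [biolog_table()].
#' @param dose,cutoff,digits batch-arm parameters.
#' @param dose_mM,n_steps,n_replicates,grid,n_per_species,alpha spatial-arm
#'   parameters.
#' @param seed master seed for the stochastic arm.
#' @return a `screen_result` with per-arm evidence tables in attribute
#'   `evidence`.
#' @export
run_screen <- function(models, med, medium_mM = NULL,
                       target = models[[1L]]$id, other = models[[2L]]$id,
                       methods = c("fba_single", "community_fba", "abm"),
                       compounds = NULL, biolog = NULL, dose = 10,
                       cutoff = 0.01, digits = 6, dose_mM = 0.01,
                       n_steps = 12, n_replicates = 15, grid = c(30, 30),
                       n_per_species = 20, alpha = 0.05, seed = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  ids <- vapply(models, `[[`, character(1L), "id")
  tmodel <- models[[match(target, ids)]]
  if (is.null(compounds)) {
    profiles <- lapply(models, uptake_profile, med = med)
    uniq <- unique_uptake_compounds(profiles)$unique_compounds[[target]]
    compounds <- setdiff(names(med), uniq)
  }
  sets <- list(); evidence <- list()
  if ("fba_single" %in% methods) {
    evidence$fba_single <- screen_single_fba(tmodel, med, compounds,
                                             dose = dose, cutoff = cutoff,
                                             digits = digits)
    sets$fba_single <- attr(evidence$fba_single, "selected")
  }
  if ("community_fba" %in% methods) {
    evidence$community_fba <- screen_community_fba(
      models, med, target, compounds, dose = dose, cutoff = cutoff,
      digits = digits)
    sets$community_fba <- attr(evidence$community_fba, "selected")
  }
  if ("abm" %in% methods) {
    if (is.null(medium_mM))
      stop("the individual-based arm needs a medium in mM")
    evidence$abm <- screen_abm(models, medium_mM, target, other, compounds,
                               dose_mM = dose_mM, n_steps = n_steps,
                               n_replicates = n_replicates, seed = seed,
                               alpha = alpha, grid = grid,
                               n_per_species = n_per_species)
    sets$abm <- attr(evidence$abm, "selected")
  }
  out <- intersect_and_confirm(sets, biolog)
  attr(out, "evidence") <- evidence
  out$target <- target
  out
}
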