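# Community FBA: merge species models into one LP over a shared nutrient
# pool, maximize the summed growth rate with a small total-flux penalty as
# tie-breaker, and report growth-rate-normalized species abundances.

#' Merge species models into a community model
#'
#' Internal metabolites and reactions of every member are prefixed with the
#' species id, so members interact only through a shared external
#' compartment: each member's former exchange reaction becomes a reversible
#' member-to-pool transport (uptake from the pool unbounded), and one
#' community-level exchange reaction per environmental compound carries the
#' medium bound.  Each member keeps its own biomass reaction; no fixed
#' community biomass composition is imposed, so the community optimum is
#' free to allocate growth across members.
#'
#' @param models list of >= 2 [metabolic_model()]s sharing an external
#'   compound namespace.
#' @param med a [medium()] bounding the community exchanges
#'   (mmol/gDW/hr).
#' @param transport_bound magnitude of the member-to-pool transport bounds.
#' @return a `community_model` (also a valid `metabolic_model`), with the
#'   member ids in attribute `members` and their biomass reaction ids in
#'   attribute `member_biomass_ids`.
#' @export
merge_models <- function(models, med, transport_bound = 1000) {
  if (length(models) < 2L) stop("need at least two models to merge")
  ids <- vapply(models, `[[`, character(1L), "id")
  if (anyDuplicated(ids)) stop("duplicate species ids: ",
    paste(ids[duplicated(ids)], collapse = ", "))

  mets <- list(); rxns <- list(); stoich <- list()
  pool <- character()  # environmental compounds seen so far
  biomass_ids <- stats::setNames(character(length(models)), ids)

  for (mdl in models) {
    sid <- mdl$id
    pre <- function(x) paste0(sid, "__", x)
    ex <- exchanges(mdl)
    ext_ids <- mdl$mets$id[mdl$mets$compartment == mdl$external_compartment]
    # member metabolites: all prefixed; former externals become a
    # member-boundary compartment so only the pool is shared
    for (i in seq_len(nrow(mdl$mets))) {
      m <- mdl$mets[i, ]
      mets[[pre(m$id)]] <- data.frame(
        id = pre(m$id), name = m$name,
        compartment = if (m$id %in% ext_ids) paste0(sid, "_b")
                      else paste0(sid, "_", m$compartment),
        formula = m$formula, stringsAsFactors = FALSE)
    }
    ex_map <- stats::setNames(ex$compound_id, ex$reaction_id)
    for (i in seq_len(nrow(mdl$rxns))) {
      r <- mdl$rxns[i, ]
      s <- mdl$stoich[[r$id]]
      if (r$is_exchange) {
        cmp <- ex_map[[r$id]]
        pool_met <- paste0("pool__", cmp)
        if (!cmp %in% pool) {
          pool <- c(pool, cmp)
          mets[[pool_met]] <- data.frame(
            id = pool_met, name = cmp, compartment = "e",
            formula = NA_character_, stringsAsFactors = FALSE)
        }
        # pool -> member boundary metabolite, reversible (secretion = reverse)
        rid <- paste0("TR_", sid, "__", cmp)
        rxns[[rid]] <- data.frame(
          id = rid, lower_bound = -transport_bound,
          upper_bound = transport_bound, objective_coefficient = 0,
          is_exchange = FALSE, stringsAsFactors = FALSE)
        stoich[[rid]] <- stats::setNames(c(-1, 1),
                                         c(pool_met, pre(names(s)[1L])))
      } else {
        rid <- pre(r$id)
        rxns[[rid]] <- data.frame(
          id = rid, lower_bound = r$lower_bound,
          upper_bound = r$upper_bound,
          objective_coefficient = r$objective_coefficient,
          is_exchange = FALSE, stringsAsFactors = FALSE)
        stoich[[rid]] <- stats::setNames(as.numeric(s), pre(names(s)))
        if (r$id == mdl$biomass_reaction_id) biomass_ids[[sid]] <- rid
      }
    }
  }
  # one community exchange per environmental compound, bounded by the medium
  for (cmp in pool) {
    rid <- paste0("EX_", cmp)
    avail <- if (cmp %in% names(med)) med[[cmp]] else 0
    rxns[[rid]] <- data.frame(
      id = rid, lower_bound = -avail, upper_bound = transport_bound,
      objective_coefficient = 0, is_exchange = TRUE,
      stringsAsFactors = FALSE)
    stoich[[rid]] <- stats::setNames(-1, paste0("pool__", cmp))
  }
  unknown <- setdiff(names(med), pool)
  if (length(unknown))
    warning("medium compound(s) with no exchange in any member: ",
            paste(unknown, collapse = ", "))

  cm <- metabolic_model(
    id = paste(ids, collapse = "+"),
    mets = do.call(rbind, mets), rxns = do.call(rbind, rxns),
    stoich = stoich, biomass_reaction_id = biomass_ids[[1L]])
  # community objective: sum of member growth rates
  cm$rxns$objective_coefficient <- as.numeric(cm$rxns$id %in% biomass_ids)
  attr(cm, "members") <- ids
  attr(cm, "member_biomass_ids") <- biomass_ids
  class(cm) <- c("community_model", class(cm))
  cm
}

#' Community growth by summed-growth maximization
#'
#' Maximizes the sum of the member growth rates with a concomitant
#' minimization of total flux (penalty coefficient `flux_penalty` on
#' `sum(|v|)`), then normalizes each member's growth rate by the community
#' growth rate.  Since total community growth is what the objective
#' maximizes, the optimum routes resources to whichever member converts the
#' medium into biomass most efficiently; the normalized abundances expose
#' exactly that allocation.
#'
#' @param cm a [merge_models()] community model.
#' @param flux_penalty weight of the total-flux minimization (default
#'   `1e-6`).
#' @return object of class `community_growth_result`: `community_growth`,
#'   `member_growth`, `normalized_abundance` (NA with `degenerate` flag
#'   when total growth is zero), and the full `flux_solution`.
#' @export
community_growth <- function(cm, flux_penalty = 1e-6) {
  if (!inherits(cm, "community_model")) stop("cm must be a community_model")
  sol <- solve_fba_pfba(cm, flux_penalty = flux_penalty)
  if (sol$status != "optimal")
    stop("community optimization ended with status ", sol$status)
  bids <- attr(cm, "member_biomass_ids")
  mu <- stats::setNames(as.numeric(sol$fluxes[bids]), names(bids))
  total <- sum(mu)
  undefined <- total <= 1e-9
  structure(list(
    community_growth = total,
    member_growth = mu,
    normalized_abundance = if (undefined)
      stats::setNames(rep(NA_real_, length(mu)), names(mu)) else mu / total,
    undefined_abundance = undefined,
    solution = sol), class = "community_growth_result")
}

#' @export
print.community_growth_result <- function(x, ...) {
  cat("<community_growth_result> total growth ", format(x$community_growth),
      "\n", sep = "")
  print(round(rbind(growth = x$member_growth,
                    abundance = x$normalized_abundance), 6))
  invisible(x)
}

#' Effect of one supplement on community composition
#'
#' Solves the community model on the baseline medium and on the medium
#' supplemented with `dose` of one compound, and reports the change in each
#' member's growth-rate-normalized abundance.  Raw values are rounded to
#' `digits` decimals before differencing to suppress numerical noise, and a
#' member is flagged `selected` when its abundance increase strictly
#' exceeds `cutoff`.  A raw growth-rate ratio is reported alongside as an
#' alternative change measure.
#'
#' @param models list of member [metabolic_model()]s.
#' @param med baseline [medium()].
#' @param compound supplemented compound id.
#' @param dose added availability (default 10 mmol/gDW/hr).
#' @param flux_penalty passed to [community_growth()].
#' @param digits rounding applied to raw values (default 6).
#' @param cutoff abundance-change selection threshold (default 0.01).
#' @return data.frame with one row per member: baseline/supplemented
#'   abundance and growth, `delta` (abundance change), `growth_ratio`, and
#'   `selected`; attribute `screenable` is FALSE when the compound has no
#'   exchange in any member (in which case deltas are NA).
#' @export
community_supplement_effect <- function(models, med, compound, dose = 10,
                                        flux_penalty = 1e-6, digits = 6,
                                        cutoff = 0.01) {
  if (dose < 0) stop("dose must be >= 0")
  cm0 <- merge_models(models, med)
  ids <- attr(cm0, "members")
  screenable <- paste0("EX_", compound) %in% cm0$rxns$id
  if (!screenable) {
    out <- data.frame(species = ids, baseline_abundance = NA_real_,
                      suppl_abundance = NA_real_, delta = NA_real_,
                      baseline_growth = NA_real_, suppl_growth = NA_real_,
                      growth_ratio = NA_real_, selected = FALSE)
    attr(out, "screenable") <- FALSE
    return(out)
  }
  base <- community_growth(cm0, flux_penalty)
  cm1 <- merge_models(models, supplement_medium(med, compound, dose))
  supp <- community_growth(cm1, flux_penalty)
  ab0 <- round(base$normalized_abundance, digits)
  ab1 <- round(supp$normalized_abundance, digits)
  g0 <- round(base$member_growth, digits)
  g1 <- round(supp$member_growth, digits)
  delta <- ab1 - ab0
  out <- data.frame(
    species = ids,
    baseline_abundance = as.numeric(ab0[ids]),
    suppl_abundance = as.numeric(ab1[ids]),
    delta = as.numeric(delta[ids]),
    baseline_growth = as.numeric(g0[ids]),
    suppl_growth = as.numeric(g1[ids]),
    growth_ratio = as.numeric(ifelse(g0[ids] > 0, g1[ids] / g0[ids],
                                     NA_real_)),
    selected = as.numeric(delta[ids]) > cutoff)
  out$selected[is.na(out$delta)] <- FALSE
  attr(out, "screenable") <- TRUE
  out
}
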