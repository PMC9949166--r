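# Flux balance analysis on top of the bundled dense simplex backend.

# Bounds of +/-Inf are clamped to this box before solving; genome-scale
# conventions use +/-1000, so the box is never active for sensible models.
LP_BIG <- 1e6

#' Low-level linear program solver
#'
#' Maximizes `obj %*% x` subject to `A x = b` and `lb <= x <= ub`, using the
#' package's dense bounded-variable two-phase simplex.  Infinite bounds are
#' clamped to a large finite box.
#'
#' @param A constraint matrix.
#' @param b right-hand side.
#' @param obj objective coefficients.
#' @param lb,ub variable bounds.
#' @param tol pivot tolerance.
#' @return list with `status` (one of `"optimal"`, `"infeasible"`,
#'   `"maxiter"`, `"unbounded"`), `objective` and solution vector `x`.
#' @export
solve_lp <- function(A, b, obj, lb, ub, tol = 1e-9) {
  lb <- pmax(lb, -LP_BIG); ub <- pmin(ub, LP_BIG)
  res <- simplex_solve(as.matrix(A), as.numeric(b), as.numeric(obj),
                       as.numeric(lb), as.numeric(ub), tol = tol)
  res$status <- c("optimal", "infeasible", "maxiter", "unbounded")[
    res$status + 1L]
  res
}

#' Stoichiometric matrix of a model
#'
#' @param model a [metabolic_model()].
#' @return dense numeric matrix (metabolites x reactions) with dimnames.
#' @export
stoichiometric_matrix <- function(model) {
  S <- matrix(0, nrow(model$mets), nrow(model$rxns),
              dimnames = list(model$mets$id, model$rxns$id))
  for (rid in model$rxns$id) {
    s <- model$stoich[[rid]]
    S[names(s), rid] <- s
  }
  S
}

# Prepared LP data reused across repeated solves of the same network
# (the agent-based simulator re-solves one species model with fresh
# exchange bounds at every individual step).
fba_problem <- function(model) {
  S <- stoichiometric_matrix(model)
  list(S = S,
       rxn_ids = model$rxns$id,
       lb = stats::setNames(model$rxns$lower_bound, model$rxns$id),
       ub = stats::setNames(model$rxns$upper_bound, model$rxns$id),
       obj = stats::setNames(model$rxns$objective_coefficient, model$rxns$id))
}

flux_solution <- function(status, objective, fluxes) {
  structure(list(status = status, objective_value = objective,
                 fluxes = fluxes), class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status: ", x$status,
      "  objective: ", format(x$objective_value), "\n", sep = "")
  invisible(x)
}

#' Write a flux solution to TSV or JSON
#'
#' TSV carries two columns (`reaction_id`, `flux`); JSON additionally
#' records the status and objective value.
#'
#' @param solution a `flux_solution`.
#' @param path output path; the extension picks the format (`.json` for
#'   JSON, anything else for TSV).
#' @return the path, invisibly.
#' @export
write_fluxes <- function(solution, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(status = solution$status,
                              objective_value = solution$objective_value,
                              fluxes = as.list(solution$fluxes)),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    utils::write.table(data.frame(reaction_id = names(solution$fluxes),
                                  flux = as.numeric(solution$fluxes)),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Flux balance analysis
#'
#' Maximizes the objective (biomass) flux subject to the steady-state
#' constraint `S v = 0` and the reaction bounds.  Solver failures are
#' reported through `status`, never as a silent zero.
#'
#' @param model a [metabolic_model()].
#' @return a `flux_solution` with `status`, `objective_value`, and the
#'   named flux vector `fluxes`.
#' @export
solve_fba <- function(model) {
  p <- fba_problem(model)
  res <- solve_lp(p$S, rep(0, nrow(p$S)), p$obj, p$lb, p$ub)
  flux_solution(res$status,
                if (res$status == "optimal") res$objective else NA_real_,
                stats::setNames(res$x, p$rxn_ids))
}

# pFBA solve on prepared problem data with replaceable bounds; used by
# solve_fba_pfba and, on the hot path, by the agent simulator.
solve_pfba_problem <- function(p, flux_penalty, lb = p$lb, ub = p$ub) {
  if (flux_penalty == 0) {
    res <- solve_lp(p$S, rep(0, nrow(p$S)), p$obj, lb, ub)
    return(flux_solution(res$status,
                         if (res$status == "optimal") res$objective else
                           NA_real_,
                         stats::setNames(res$x, p$rxn_ids)))
  }
  # split v = f - r with f, r >= 0 so that |v| = f + r at the optimum
  n <- length(p$rxn_ids)
  A2 <- cbind(p$S, -p$S)
  lbf <- pmax(lb, 0); ubf <- pmax(ub, 0)
  lbr <- pmax(-ub, 0); ubr <- pmax(-lb, 0)
  obj2 <- c(p$obj - flux_penalty, -p$obj - flux_penalty)
  res <- solve_lp(A2, rep(0, nrow(p$S)), obj2, c(lbf, lbr), c(ubf, ubr))
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  flux_solution(res$status,
                if (res$status == "optimal") sum(p$obj * v) else NA_real_,
                stats::setNames(v, p$rxn_ids))
}

#' Parsimonious flux balance analysis (penalized total flux)
#'
#' Maximizes `objective - flux_penalty * sum(|v|)` in a single linear
#' program, with absolute values linearized by splitting each flux into
#' non-negative forward and reverse components.  The reported
#' `objective_value` is the plain (unpenalized) objective evaluated at the
#' penalized optimum.  With `flux_penalty = 0` this is identical to
#' [solve_fba()].  The small default penalty acts as a secondary objective
#' that removes futile cycles and resolves degenerate optima.
#'
#' @param model a [metabolic_model()].
#' @param flux_penalty non-negative weight on the total absolute flux
#'   (default `1e-6`).
#' @return a `flux_solution`.
#' @export
solve_fba_pfba <- function(model, flux_penalty = 1e-6) {
  if (!is.numeric(flux_penalty) || flux_penalty < 0)
    stop("flux_penalty must be >= 0")
  solve_pfba_problem(fba_problem(model), flux_penalty)
}

#' Minimum feasible flux through an exchange reaction
#'
#' Minimizes the flux of one exchange reaction subject only to steady state
#' and the bounds (no growth requirement by default).  Because uptake is
#' negative flux, this corresponds to maximizing the uptake of that
#' compound; a structurally dead-end exchange is forced to zero by mass
#' balance.
#'
#' @param model a [metabolic_model()]; apply the medium first.
#' @param exchange_id id of an exchange reaction.
#' @param min_growth optional lower bound imposed on the biomass flux while
#'   minimizing (default 0 = no growth requirement), exposed for
#'   sensitivity analysis.
#' @return the minimal flux value (<= 0 whenever the lower bound is <= 0).
#' @export
min_exchange_flux <- function(model, exchange_id, min_growth = 0) {
  i <- match(exchange_id, model$rxns$id)
  if (is.na(i) || !model$rxns$is_exchange[i])
    stop("'", exchange_id, "' is not an exchange reaction of ", model$id)
  p <- fba_problem(model)
  lb <- p$lb
  if (min_growth > 0)
    lb[model$biomass_reaction_id] <- max(lb[model$biomass_reaction_id],
                                         min_growth)
  obj <- stats::setNames(numeric(length(p$rxn_ids)), p$rxn_ids)
  obj[exchange_id] <- -1  # maximize -v_ex = minimize v_ex
  res <- solve_lp(p$S, rep(0, nrow(p$S)), obj, lb, p$ub)
  if (res$status != "optimal")
    stop("exchange-flux minimization for ", exchange_id, " ended with ",
         "status ", res$status)
  -res$objective
}

#' Can a model take up a compound?
#'
#' A compound can be taken up when the minimal feasible flux through its
#' exchange reaction is strictly negative beyond the numerical tolerance.
#' The test is invariant to scaling of the biomass objective because no
#' growth constraint is imposed.
#'
#' @inheritParams min_exchange_flux
#' @param tol strictly positive numerical zero threshold (default `1e-6`,
#'   matching the sixth-digit rounding used throughout the screen).
#' @return `TRUE` iff the minimal exchange flux is `< -tol`.
#' @export
can_take_up <- function(model, exchange_id, tol = 1e-6, min_growth = 0) {
  if (!is.numeric(tol) || tol <= 0) stop("tol must be > 0")
  min_exchange_flux(model, exchange_id, min_growth = min_growth) < -tol
}
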