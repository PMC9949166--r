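# Minimal individual-based spatial simulator: individuals solve FBA against
# the nutrient pool of their grid cell, grow, divide into free neighboring
# cells, perform a random walk, and substrates diffuse by a conservative
# discrete-Laplacian pass.  This is an independent minimal arena; numeric
# agreement with any particular individual-based framework is not a goal.

#' Initialize a spatial arena
#'
#' Converts a medium given in mM into per-cell substrate amounts (mmol)
#' through the configured dilution factor and cell volume, and scatters
#' `n_per_species` individuals of each species over distinct cells
#' (at most one individual per cell).
#'
#' @param models list of [metabolic_model()]s (one per species).
#' @param medium_mM a [medium()] with concentrations in mM.
#' @param n_per_species individuals inoculated per species (default 20).
#' @param grid `(rows, cols)` of the arena (default `c(30, 30)`).
#' @param dilution factor applied to the medium concentrations
#'   (default 1000), which keeps nutrients from being exhausted only after
#'   the arena is overgrown.
#' @param cell_volume_ul volume represented by one grid cell (microliters);
#'   1 mM in 1 uL is 1e-6 mmol.
#' @param init_biomass starting biomass per individual (gDW).  The default
#'   1e-9 gDW represents a microcolony-scale individual.
#' @param timestep_hours length of one iteration (default 1 h).
#' @param max_uptake cap on any single uptake flux (mmol/gDW/hr).
#' @param seed RNG seed; identical seeds give identical arenas.
#' @return object of class `arena`.
#' @export
init_arena <- function(models, medium_mM, n_per_species = 20,
                       grid = c(30, 30), dilution = 1000,
                       cell_volume_ul = 1, init_biomass = 1e-9,
                       timestep_hours = 1, max_uptake = 1000, seed = 1) {
  ids <- vapply(models, `[[`, character(1L), "id")
  names(models) <- ids
  ncell <- prod(grid)
  ntot <- n_per_species * length(models)
  if (ntot > ncell)
    stop("cannot place ", ntot, " individuals on ", ncell,
         " cells with exclusive occupancy")
  cmp <- names(medium_mM)
  # mmol per cell: mM -> mmol/uL is 1e-6
  per_cell <- as.numeric(medium_mM) / dilution * cell_volume_ul * 1e-6
  substrate <- matrix(rep(per_cell, each = ncell), nrow = ncell,
                      dimnames = list(NULL, cmp))
  flux_penalty <- 1e-6
  problems <- lapply(models, arena_problem, flux_penalty = flux_penalty,
                     substrate_compounds = cmp)
  neighbors <- lapply(seq_len(ncell), cell_neighbors, nr = grid[1],
                      nc = grid[2])
  with_seed(seed, {
    cells <- sample.int(ncell, ntot)
    inds <- data.frame(
      species = rep(ids, each = n_per_species),
      biomass = rep(init_biomass, ntot),
      cell = cells)
    rng <- get(".Random.seed", globalenv())
    structure(list(
      grid = grid, substrate = substrate, individuals = inds,
      models = models, problems = problems, neighbors = neighbors,
      params = list(timestep_hours = timestep_hours,
                    cell_volume_ul = cell_volume_ul,
                    init_biomass = init_biomass, dilution = dilution,
                    max_uptake = max_uptake, divide_at = 2 * init_biomass,
                    diffusion_rate = 0.5, flux_penalty = flux_penalty),
      rng_state = rng, seed = seed, time = 0L),
      class = "arena")
  })
}

# Per-species prepared LP for the arena hot path: the parsimonious-FBA
# split formulation (v = f - r) is assembled once; per individual only the
# reverse-part upper bounds of the exchange reactions change (uptake cap
# from the local cell), so a step costs one bound update plus one simplex
# call.  Also precomputes the substrate-column mapping and a flag telling
# whether the species can grow with all uptake closed (if not, individuals
# on empty cells skip the LP entirely).
arena_problem <- function(model, flux_penalty, substrate_compounds) {
  p <- fba_problem(model)
  ex <- exchanges(model)
  p$ex_rxn <- ex$reaction_id
  p$ex_cmp <- ex$compound_id
  p$ex_idx <- match(p$ex_rxn, p$rxn_ids)
  p$ex_col <- match(p$ex_cmp, substrate_compounds)  # NA = not in arena
  closed <- p$lb
  closed[p$ex_idx] <- 0
  sol <- solve_pfba_problem(p, 0, lb = closed)
  p$grows_when_starved <- sol$status == "optimal" &&
    sol$objective_value > 1e-9
  p$biomass_idx <- match(model$biomass_reaction_id, p$rxn_ids)
  n <- length(p$rxn_ids)
  lb <- pmax(p$lb, -LP_BIG); ub <- pmin(p$ub, LP_BIG)
  p$split <- list(
    n = n,
    A = cbind(p$S, -p$S),
    b = rep(0, nrow(p$S)),
    obj = c(p$obj - flux_penalty, -p$obj - flux_penalty),
    lb = c(pmax(lb, 0), pmax(-ub, 0)),
    ub = c(pmax(ub, 0), pmax(-lb, 0)))
  p
}

#' @export
print.arena <- function(x, ...) {
  tot <- tapply(x$individuals$biomass, x$individuals$species, sum)
  cat("<arena> ", x$grid[1], "x", x$grid[2], " grid, t = ", x$time,
      ", ", nrow(x$individuals), " individuals\n", sep = "")
  print(tot)
  invisible(x)
}

#' Add a compound uniformly to every arena cell
#'
#' The spatial analogue of [supplement_medium()]: `conc_mM` of the compound
#' is added once, distributed homogeneously over the grid.
#'
#' @param arena an [init_arena()] arena.
#' @param compound compound id.
#' @param conc_mM added concentration (mM, post-dilution scale).
#' @return the supplemented arena.
#' @export
arena_add_compound <- function(arena, compound, conc_mM) {
  if (conc_mM < 0) stop("conc_mM must be >= 0")
  amt <- conc_mM * arena$params$cell_volume_ul * 1e-6
  if (!compound %in% colnames(arena$substrate)) {
    arena$substrate <- cbind(arena$substrate,
                             matrix(0, nrow(arena$substrate), 1,
                                    dimnames = list(NULL, compound)))
  }
  arena$substrate[, compound] <- arena$substrate[, compound] + amt
  arena
}

#' Advance the arena by one timestep
#'
#' In seeded-random order, every individual (1) gets its exchange lower
#' bounds set from its cell: uptake of compound c is capped at
#' `local_amount(c) / (biomass * dt)`, the local analogue of
#' "uptake limited by the available amount"; (2) runs parsimonious FBA;
#' (3) grows linearly within the step, `biomass * (1 + mu * dt)`;
#' (4) withdraws consumed and deposits secreted amounts in its cell;
#' (5) divides into a random free neighboring cell once its biomass reaches
#' twice the inoculation biomass; and (6) moves to one of its 8 neighbors
#' (or stays), with moves into occupied cells or over the reflecting
#' boundary cancelled.  Afterwards each substrate diffuses by one
#' conservative discrete-Laplacian averaging pass.  An individual whose FBA
#' is infeasible simply idles for the step.
#'
#' @param arena an [init_arena()] arena.
#' @return the advanced arena.
#' @export
arena_step <- function(arena) {
  caller_rng <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(caller_rng))
    assign(".Random.seed", caller_rng, envir = globalenv()))
  assign(".Random.seed", arena$rng_state, envir = globalenv())
  pr <- arena$params
  dt <- pr$timestep_hours
  nr <- arena$grid[1]; nc <- arena$grid[2]
  ncell <- nr * nc
  sub <- arena$substrate
  cmps <- colnames(sub)
  inds <- arena$individuals
  occupied <- logical(ncell)
  occupied[inds$cell] <- TRUE

  ord <- sample.int(nrow(inds))
  nb_species <- character(); nb_biomass <- numeric(); nb_cell <- integer()
  for (i in ord) {
    sp <- inds$species[i]
    p <- arena$problems[[sp]]
    cell <- inds$cell[i]
    bm <- inds$biomass[i]
    known <- !is.na(p$ex_col)
    loc_ex <- numeric(length(p$ex_cmp))
    loc_ex[known] <- sub[cell, p$ex_col[known]]
    if (!p$grows_when_starved && all(loc_ex <= 1e-15)) {
      mu <- 0
    } else {
      spl <- p$split
      ub2 <- spl$ub
      ub2[spl$n + p$ex_idx] <- pmin(pr$max_uptake, loc_ex / (bm * dt))
      res <- simplex_solve(spl$A, spl$b, spl$obj, spl$lb, ub2)
      if (res$status != 0L) {
        mu <- 0  # infeasible individual idles this step
      } else {
        v_bio <- res$x[p$biomass_idx] - res$x[spl$n + p$biomass_idx]
        mu <- max(0, v_bio)
        v_ex <- res$x[p$ex_idx] - res$x[spl$n + p$ex_idx]
        dmol <- v_ex * bm * dt          # <0 consumed, >0 secreted
        take <- pmax(-dmol, 0)[known]
        give <- pmax(dmol, 0)[known]
        kc <- p$ex_col[known]
        cur <- sub[cell, kc]
        sub[cell, kc] <- pmax(cur - pmin(take, cur), 0) + give
      }
    }
    bm_new <- bm * (1 + mu * dt)
    # division: split in half, daughter to a random free neighbor
    if (bm_new >= pr$divide_at) {
      nb <- arena$neighbors[[cell]]
      free <- nb[!occupied[nb]]
      if (length(free)) {
        dest <- free[sample.int(length(free), 1L)]
        bm_new <- bm_new / 2
        nb_species <- c(nb_species, sp)
        nb_biomass <- c(nb_biomass, bm_new)
        nb_cell <- c(nb_cell, dest)
        occupied[dest] <- TRUE
      }
    }
    inds$biomass[i] <- bm_new
    # random walk: one of the 8 neighbors or stay; occupied target = stay
    nb <- c(cell, arena$neighbors[[cell]])
    dest <- nb[sample.int(length(nb), 1L)]
    if (dest != cell && !occupied[dest]) {
      occupied[cell] <- FALSE
      occupied[dest] <- TRUE
      inds$cell[i] <- dest
    }
  }
  if (length(nb_cell))
    inds <- rbind(inds, data.frame(species = nb_species,
                                   biomass = nb_biomass, cell = nb_cell))
  sub <- diffuse(sub, nr, nc, pr$diffusion_rate)

  arena$substrate <- sub
  arena$individuals <- inds
  arena$rng_state <- get(".Random.seed", globalenv())
  arena$time <- arena$time + 1L
  arena
}

# 8-neighborhood of a cell (column-major index), reflecting boundary
cell_neighbors <- function(cell, nr, nc) {
  r <- (cell - 1L) %% nr + 1L
  cl <- (cell - 1L) %/% nr + 1L
  rr <- pmax(1L, pmin(nr, r + c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)))
  cc <- pmax(1L, pmin(nc, cl + c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)))
  nb <- unique((cc - 1L) * nr + rr)
  nb[nb != cell]
}

# conservative 4-neighbor diffusion: every open cell pair (i,j) exchanges
# rate/4 * (x_j - x_i); missing neighbors at the boundary exchange nothing,
# so each compound's grid total is preserved exactly
diffuse <- function(sub, nr, nc, rate) {
  if (rate <= 0) return(sub)
  for (k in seq_len(ncol(sub))) {
    x <- matrix(sub[, k], nr, nc)
    dx <- matrix(0, nr, nc)
    if (nr > 1) {
      d <- x[-1, , drop = FALSE] - x[-nr, , drop = FALSE]
      dx[-nr, ] <- dx[-nr, ] + d
      dx[-1, ] <- dx[-1, ] - d
    }
    if (nc > 1) {
      d <- x[, -1, drop = FALSE] - x[, -nc, drop = FALSE]
      dx[, -nc] <- dx[, -nc] + d
      dx[, -1] <- dx[, -1] - d
    }
    sub[, k] <- as.numeric(x + rate / 4 * dx)
  }
  sub
}

#' Run matched supplementation replicates in the arena
#'
#' Runs `n_replicates` simulations of `n_steps` iterations each.  When a
#' compound is supplemented, every replicate is paired with an
#' unsupplemented control started from the same derived seed (identical
#' initial arena and random stream), and the per-species relative change of
#' total biomass at the final timestep, rounded to `digits` decimals, is
#' recorded.  Matched pairing removes the between-replicate variance of the
#' spatial race from the supplement contrast.
#'
#' @inheritParams init_arena
#' @param compound supplemented compound id, or `NULL` for control-only
#'   runs.
#' @param dose_mM concentration added once at the start (default 0.01 mM).
#' @param n_steps iterations per replicate (default 12).
#' @param n_replicates replicates (default 15).
#' @param digits rounding of the relative changes (default 6).
#' @param control optional precomputed control result (from a previous call
#'   with `compound = NULL` and the same seed/layout), reused to avoid
#'   re-simulating the shared baselines.
#' @param ... further arguments passed to [init_arena()].
#' @return object of class `abm_run_result`: `trajectory` (replicate,
#'   timestep, species, total_biomass; timestep 1 is the initial state) and
#'   `rel_change` (replicate, species, rel_change; `NULL` for control-only
#'   runs).
#' @export
run_supplement_replicates <- function(models, medium_mM, compound = NULL,
                                      dose_mM = 0.01, n_steps = 12,
                                      n_replicates = 15, seed = 1,
                                      digits = 6, control = NULL, ...) {
  if (n_steps < 1 || n_replicates < 1)
    stop("n_steps and n_replicates must be >= 1")
  run_one <- function(rep_seed, cmp) {
    arena <- init_arena(models, medium_mM, seed = rep_seed, ...)
    if (!is.null(cmp)) arena <- arena_add_compound(arena, cmp, dose_mM)
    ids <- names(arena$models)
    traj <- matrix(0, n_steps + 1L, length(ids),
                   dimnames = list(NULL, ids))
    totals <- function(a) {
      s <- tapply(a$individuals$biomass, a$individuals$species, sum)
      out <- stats::setNames(rep(0, length(ids)), ids)
      out[names(s)] <- s
      out
    }
    traj[1L, ] <- totals(arena)
    for (t in seq_len(n_steps)) {
      arena <- arena_step(arena)
      traj[t + 1L, ] <- totals(arena)
    }
    traj
  }
  seeds <- seed + seq_len(n_replicates)
  runs <- lapply(seeds, run_one, cmp = compound)
  species <- colnames(runs[[1L]])
  traj <- do.call(rbind, lapply(seq_along(runs), function(r)
    data.frame(replicate = r,
               timestep = rep(seq_len(n_steps + 1L), length(species)),
               species = rep(species, each = n_steps + 1L),
               total_biomass = as.numeric(runs[[r]]))))
  rel <- NULL
  if (!is.null(compound)) {
    ctrl_runs <- if (!is.null(control)) {
      stopifnot(identical(control$seeds, seeds))
      control$runs
    } else lapply(seeds, run_one, cmp = NULL)
    rel <- do.call(rbind, lapply(seq_along(runs), function(r) {
      fin <- runs[[r]][n_steps + 1L, ]
      fin0 <- ctrl_runs[[r]][n_steps + 1L, ]
      data.frame(replicate = r, species = species,
                 rel_change = round((fin - fin0) / fin0, digits))
    }))
  }
  structure(list(trajectory = traj, rel_change = rel, compound = compound,
                 dose_mM = if (is.null(compound)) NA_real_ else dose_mM,
                 seeds = seeds, runs = runs),
            class = "abm_run_result")
}

#' @export
print.abm_run_result <- function(x, ...) {
  cat("<abm_run_result> ", length(x$seeds), " replicates",
      if (!is.null(x$compound))
        paste0(", supplement ", x$compound, " @ ", x$dose_mM, " mM"),
      "\n", sep = "")
  invisible(x)
}
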