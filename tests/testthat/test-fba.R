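# FBA engine: optima, parsimonious variant, uptake test.

simple_model <- function(lb_A = -10) {
  m <- generate_species_model(species_spec("s", c(A = 1)))
  apply_medium(m, medium(c(A = -lb_A)))
}

test_that("FBA finds the single-bottleneck optimum and reports starvation", {
  expect_equal(solve_fba(simple_model(-10))$objective_value, 10,
               tolerance = 1e-9)
  expect_equal(solve_fba(simple_model(0))$objective_value, 0,
               tolerance = 1e-9)
})

test_that("two-route model reaches the oracle optimum", {
  m <- generate_species_model(species_spec("two", c(A = 1, B = 2)))
  m <- apply_medium(m, medium(c(A = 10, B = 5)))
  sol <- solve_fba(m)
  expect_equal(sol$objective_value, 20, tolerance = 1e-9)  # 10*1 + 5*2
  expect_equal(sol$objective_value, oracle_fba(m)$objective,
               tolerance = 1e-6)
})

test_that("optimal solutions satisfy steady state, bounds, and the objective identity", {
  m <- apply_medium(
    generate_species_model(species_spec("inv", c(A = 1.3, B = 0.4),
                                        secretion = list(A = c(W = 0.5)))),
    medium(c(A = 6, B = 3)))
  sol <- solve_fba(m)
  expect_equal(sol$status, "optimal")
  S <- stoichiometric_matrix(m)
  expect_lt(max(abs(S %*% sol$fluxes[colnames(S)])), 1e-6)
  expect_true(all(sol$fluxes >= m$rxns$lower_bound[
    match(names(sol$fluxes), m$rxns$id)] - 1e-6))
  expect_true(all(sol$fluxes <= m$rxns$upper_bound[
    match(names(sol$fluxes), m$rxns$id)] + 1e-6))
  expect_equal(sol$objective_value,
               sum(m$rxns$objective_coefficient *
                     sol$fluxes[m$rxns$id]), tolerance = 1e-6)
})

test_that("objective matches the independent LP oracle on random toy models", {
  for (seed in 1:20) {
    m <- random_toy_model(seed)
    mine <- solve_fba(m)
    ref <- oracle_fba(m)
    expect_equal(mine$status, ref$status, info = paste("seed", seed))
    if (ref$status == "optimal")
      expect_equal(mine$objective_value, ref$objective, tolerance = 1e-6,
                   info = paste("seed", seed))
  }
})

test_that("flux solutions serialize to TSV and JSON", {
  m <- apply_medium(generate_species_model(species_spec("w", c(A = 1))),
                    medium(c(A = 4)))
  sol <- solve_fba(m)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  write_fluxes(sol, f1)
  d <- utils::read.delim(f1)
  expect_equal(d$flux[d$reaction_id == "BIOMASS"], 4)
  f2 <- withr::local_tempfile(fileext = ".json")
  write_fluxes(sol, f2)
  j <- jsonlite::read_json(f2)
  expect_equal(j$objective_value, 4)
  expect_equal(j$status, "optimal")
})

test_that("relaxing an exchange bound never decreases the optimum", {
  for (seed in 21:32) {
    m <- random_toy_model(seed)
    base <- solve_fba(m)$objective_value
    ex <- exchanges(m)$reaction_id
    for (rid in ex) {
      m2 <- m
      i <- match(rid, m2$rxns$id)
      m2$rxns$lower_bound[i] <- m2$rxns$lower_bound[i] - 5
      expect_gte(solve_fba(m2)$objective_value, base - 1e-9)
    }
  }
})

test_that("pFBA with zero penalty equals FBA and removes futile cycles", {
  m <- apply_medium(generate_species_model(species_spec("p", c(A = 1))),
                    medium(c(A = 10)))
  expect_equal(solve_fba_pfba(m, 0)$objective_value,
               solve_fba(m)$objective_value)
  # penalized optimum within flux_penalty * sum|v| of the plain optimum
  for (pen in c(1e-2, 1e-4, 1e-6)) {
    s <- solve_fba_pfba(m, pen)
    expect_lte(abs(s$objective_value - 10), pen * sum(abs(s$fluxes)) + 1e-9)
  }

  # futile cycle: reversible A_c <-> B_c pair that can loop without cost
  mets <- data.frame(id = c("A_e", "A_c", "B_c"),
                     compartment = c("e", "c", "c"))
  rxns <- data.frame(id = c("EX_A", "T_A", "C1", "C2", "GROW"),
                     lower_bound = c(-10, 0, -1000, -1000, 0),
                     upper_bound = c(1000, 1000, 1000, 1000, 1000),
                     objective_coefficient = c(0, 0, 0, 0, 1))
  stoich <- list(EX_A = c(A_e = -1), T_A = c(A_e = -1, A_c = 1),
                 C1 = c(A_c = -1, B_c = 1), C2 = c(B_c = -1, A_c = 1),
                 GROW = c(A_c = -1))
  mc <- metabolic_model("cycle", mets, rxns, stoich)
  s <- solve_fba_pfba(mc, 1e-6)
  expect_equal(s$objective_value, 10, tolerance = 1e-5)
  # the penalty drives the loop to its minimal coupled flux
  expect_lt(abs(s$fluxes[["C2"]]), 1e-6)
})

test_that("minimum exchange flux distinguishes usable, dead-end and coupled compounds", {
  m <- apply_medium(generate_species_model(
    species_spec("u", c(A = 1), dead_end_exchanges = "B")),
    medium(c(A = 10, B = 10)))
  expect_equal(min_exchange_flux(m, "EX_A"), -10, tolerance = 1e-9)
  expect_equal(min_exchange_flux(m, "EX_B"), 0, tolerance = 1e-9)
  expect_error(min_exchange_flux(m, "T_A"), "not an exchange")

  # consumption of C requires co-uptake of absent compound D
  mets <- data.frame(id = c("C_e", "D_e", "C_c", "D_c"),
                     compartment = c("e", "e", "c", "c"))
  rxns <- data.frame(id = c("EX_C", "EX_D", "T_C", "T_D", "CONV", "GROW"),
                     lower_bound = c(-10, 0, 0, 0, 0, 0),
                     upper_bound = rep(1000, 6),
                     objective_coefficient = c(0, 0, 0, 0, 0, 1))
  stoich <- list(EX_C = c(C_e = -1), EX_D = c(D_e = -1),
                 T_C = c(C_e = -1, C_c = 1), T_D = c(D_e = -1, D_c = 1),
                 CONV = c(C_c = -1, D_c = -1, X = 1),
                 GROW = c(X = -1))
  mets <- rbind(mets, data.frame(id = "X", compartment = "c"))
  mcpl <- metabolic_model("coupled", mets, rxns, stoich)
  expect_equal(min_exchange_flux(mcpl, "EX_C"), 0, tolerance = 1e-9)
  # oracle agreement for the coupled minimization
  p <- list(A = stoichiometric_matrix(mcpl), b = rep(0, nrow(mcpl$mets)),
            obj = -(mcpl$rxns$id == "EX_C"),
            lb = mcpl$rxns$lower_bound, ub = mcpl$rxns$upper_bound)
  expect_equal(-oracle_lp_batch(list(p))[[1]]$objective, 0, tolerance = 1e-6)
})

test_that("the uptake call applies its tolerance and ignores objective scaling", {
  m <- apply_medium(generate_species_model(species_spec("t", c(A = 1))),
                    medium(c(A = 10)))
  expect_true(can_take_up(m, "EX_A"))
  m0 <- apply_medium(m, medium(c(A = 1e-9)))
  expect_false(can_take_up(m0, "EX_A", tol = 1e-6))  # noise suppressed
  expect_error(can_take_up(m, "EX_A", tol = 0), "tol")
  m_scaled <- m
  m_scaled$rxns$objective_coefficient <-
    m_scaled$rxns$objective_coefficient * 1000
  expect_equal(can_take_up(m_scaled, "EX_A"), can_take_up(m, "EX_A"))
})
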