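# Community model construction and summed-growth optimization.

two_member_models <- function(yield_P = 2, yield_Q = 1) {
  list(generate_species_model(species_spec("P", c(A = yield_P))),
       generate_species_model(species_spec("Q", c(A = yield_Q))))
}

test_that("merging builds one pool exchange, member transports and member biomasses", {
  cm <- merge_models(two_member_models(), medium(c(A = 10)))
  expect_equal(sum(cm$rxns$is_exchange), 1L)
  expect_true("EX_A" %in% cm$rxns$id)
  expect_setequal(grep("^TR_", cm$rxns$id, value = TRUE),
                  c("TR_P__A", "TR_Q__A"))
  bids <- attr(cm, "member_biomass_ids")
  expect_setequal(names(bids), c("P", "Q"))
  expect_true(all(bids %in% cm$rxns$id))
  # members share no metabolites outside the pool compartment
  comp <- stats::setNames(cm$mets$compartment, cm$mets$id)
  for (rid in grep("^P__", cm$rxns$id, value = TRUE))
    expect_false(any(grepl("^Q__", names(cm$stoich[[rid]]))))
  expect_error(merge_models(two_member_models()[1], medium(c(A = 1))),
               "at least two")
})

test_that("merging a model with its renamed twin doubles structure minus shared exchanges", {
  m1 <- generate_species_model(species_spec("T1", c(A = 1, B = 1)))
  m2 <- generate_species_model(species_spec("T2", c(A = 1, B = 1)))
  cm <- merge_models(list(m1, m2), medium(c(A = 5, B = 5)))
  # per member: all non-exchange reactions + one transport per exchange
  n_member <- nrow(m1$rxns) - sum(m1$rxns$is_exchange) +
    sum(m1$rxns$is_exchange)
  expect_equal(nrow(cm$rxns), 2 * n_member + 2)  # + 2 pool exchanges
})

test_that("the most efficient member takes the shared pool", {
  models <- two_member_models(yield_P = 2, yield_Q = 1)
  cg <- community_growth(merge_models(models, medium(c(A = 10))))
  expect_equal(cg$member_growth[["P"]], 20, tolerance = 1e-5)
  expect_equal(cg$member_growth[["Q"]], 0, tolerance = 1e-5)
  expect_equal(cg$normalized_abundance[["P"]], 1, tolerance = 1e-5)
  # oracle check of the community optimum
  cm <- merge_models(models, medium(c(A = 10)))
  p <- list(A = stoichiometric_matrix(cm), b = rep(0, nrow(cm$mets)),
            obj = cm$rxns$objective_coefficient,
            lb = cm$rxns$lower_bound, ub = cm$rxns$upper_bound)
  expect_equal(cg$community_growth, oracle_lp_batch(list(p))[[1]]$objective,
               tolerance = 1e-4)
})

test_that("identical members split the pool total; zero-yield member grows zero", {
  models <- two_member_models(1, 1)
  cg <- community_growth(merge_models(models, medium(c(A = 10))))
  expect_equal(cg$community_growth, 10, tolerance = 1e-5)

  m_dead <- generate_species_model(species_spec("D", c(A = 0)))
  m_live <- generate_species_model(species_spec("L", c(A = 1)))
  cg2 <- community_growth(merge_models(list(m_dead, m_live),
                                       medium(c(A = 10))))
  expect_equal(cg2$member_growth[["D"]], 0, tolerance = 1e-6)
  expect_equal(cg2$member_growth[["L"]], 10, tolerance = 1e-5)
})

test_that("community solutions respect conservation and mono-culture ceilings", {
  b <- generate_two_species_benchmark(seed = 3)
  cm <- merge_models(b$models, b$medium)
  cg <- community_growth(cm)
  # normalized abundances sum to 1
  expect_equal(sum(cg$normalized_abundance), 1, tolerance = 1e-9)
  # community growth = sum of member growth
  expect_equal(cg$community_growth, sum(cg$member_growth),
               tolerance = 1e-6)
  # community uptake of each compound <= medium availability
  fl <- cg$solution$fluxes
  for (rid in cm$rxns$id[cm$rxns$is_exchange]) {
    avail <- -cm$rxns$lower_bound[match(rid, cm$rxns$id)]
    expect_lte(-fl[[rid]], avail + 1e-6)
  }
  # each member's growth never exceeds its mono-culture optimum
  for (mdl in b$models) {
    mono <- solve_fba(apply_medium(mdl, b$medium))$objective_value
    expect_lte(cg$member_growth[[mdl$id]], mono + 1e-6)
  }
})

test_that("supplementation effects honor dose 0, the cutoff, and screenability", {
  models <- two_member_models(2, 1)
  med <- medium(c(A = 10))
  eff0 <- community_supplement_effect(models, med, "A", dose = 0)
  expect_true(all(eff0$delta == 0))
  expect_false(any(eff0$selected))

  # change below the cutoff after rounding is never selected
  effs <- community_supplement_effect(models, med, "A", dose = 10)
  expect_true(all(effs$delta[effs$selected] > 0.01))

  effna <- community_supplement_effect(models, med, "nonexistent")
  expect_false(attr(effna, "screenable"))
  expect_true(all(is.na(effna$delta)))
  expect_false(any(effna$selected))
})

test_that("planted prebiotics shift normalized abundance toward the target only", {
  b <- generate_two_species_benchmark(seed = 2)
  gt <- b$ground_truth
  planted <- gt$planted_prebiotics[1]
  plain <- setdiff(gt$shared, gt$planted_prebiotics)[1]
  eff_p <- community_supplement_effect(b$models, b$medium, planted)
  expect_true(eff_p$selected[eff_p$species == gt$target])
  expect_false(eff_p$selected[eff_p$species != gt$target])
  eff_n <- community_supplement_effect(b$models, b$medium, plain)
  expect_false(eff_n$selected[eff_n$species == gt$target])
})
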