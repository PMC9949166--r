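# Individual-based spatial simulator: determinism, conservation, growth.

small_models <- function() {
  list(generate_species_model(species_spec("A", c(a = 0.5))),
       generate_species_model(species_spec("B", c(a = 0.4))))
}

test_that("arena initialization is seeded, exclusive and correctly diluted", {
  med <- medium(c(a = 10))
  a1 <- init_arena(small_models(), med, n_per_species = 5, grid = c(6, 6),
                   seed = 3)
  a2 <- init_arena(small_models(), med, n_per_species = 5, grid = c(6, 6),
                   seed = 3)
  expect_identical(a1$individuals, a2$individuals)
  expect_identical(a1$substrate, a2$substrate)
  expect_equal(nrow(a1$individuals), 10)
  expect_equal(as.numeric(table(a1$individuals$species)), c(5, 5))
  expect_false(anyDuplicated(a1$individuals$cell) > 0)
  # 10 mM / 1000 = 0.01 mM; x 1 uL = 1e-8 mmol per cell
  expect_equal(unique(as.numeric(a1$substrate)), 1e-8)
  expect_error(init_arena(small_models(), med, n_per_species = 20,
                          grid = c(3, 3)), "exclusive occupancy")
})

test_that("zero substrate means no growth, ever", {
  a <- init_arena(small_models(), medium(c(a = 0)), n_per_species = 4,
                  grid = c(5, 5), seed = 1)
  b0 <- sum(a$individuals$biomass)
  for (i in 1:4) a <- arena_step(a)
  expect_equal(sum(a$individuals$biomass), b0)
})

test_that("a lone individual follows the closed-form one-step update", {
  m <- generate_species_model(species_spec("solo", c(a = 0.5)))
  med <- medium(c(a = 10))  # 1e-8 mmol per cell after dilution
  a <- init_arena(list(m), med, n_per_species = 1, grid = c(1, 1),
                  seed = 2, max_uptake = 1000)
  bm0 <- a$individuals$biomass
  # uptake bound u = min(cap, local/(bm*dt)) = min(1000, 1e-8/1e-9) = 10
  a1 <- arena_step(a)
  expect_equal(a1$individuals$biomass[1], bm0 * (1 + 0.5 * 10),
               tolerance = 1e-9)
  # consumed = u * bm * dt
  expect_equal(sum(a$substrate) - sum(a1$substrate), 10 * bm0 * 1,
               tolerance = 1e-12)
})

test_that("substrate never goes negative and consumption is bounded by supply", {
  b <- generate_two_species_benchmark(seed = 5)
  a <- init_arena(b$models, b$medium_mM, n_per_species = 6, grid = c(6, 6),
                  seed = 9)
  supplied <- colSums(a$substrate)
  for (t in 1:6) {
    a <- arena_step(a)
    expect_true(all(a$substrate >= -1e-9))
  }
  consumed <- supplied - colSums(a$substrate)
  # no compound is consumed beyond what was supplied (none are secreted here)
  expect_true(all(consumed <= supplied + 1e-12))
})

test_that("diffusion conserves each compound's grid total", {
  set.seed(8)
  a <- init_arena(small_models(), medium(c(a = 10)), n_per_species = 2,
                  grid = c(7, 5), seed = 4)
  a$substrate[, 1] <- stats::runif(nrow(a$substrate))
  tot0 <- colSums(a$substrate)
  d <- prebioscreen:::diffuse(a$substrate, 7, 5, 0.5)
  expect_equal(colSums(d), tot0, tolerance = 1e-12)
  expect_false(identical(as.numeric(d[, 1]), as.numeric(a$substrate[, 1])))
})

test_that("with ample substrate total biomass grows monotonically", {
  m <- generate_species_model(species_spec("mono", c(a = 0.5)))
  a <- init_arena(list(m), medium(c(a = 1e5)), n_per_species = 3,
                  grid = c(6, 6), seed = 6)
  tot <- sum(a$individuals$biomass)
  for (t in 1:5) {
    a <- arena_step(a)
    tot_new <- sum(a$individuals$biomass)
    expect_gte(tot_new, tot)
    tot <- tot_new
  }
  # growth implies division happened; occupancy stays exclusive
  expect_gt(nrow(a$individuals), 3)
  expect_false(anyDuplicated(a$individuals$cell) > 0)
  expect_true(all(a$individuals$cell >= 1 & a$individuals$cell <= 36))
})

test_that("replicate runs are bit-reproducible and a null supplement changes nothing", {
  b <- generate_two_species_benchmark(seed = 7)
  args <- list(models = b$models, medium_mM = b$medium_mM,
               n_steps = 3, n_replicates = 2, seed = 11,
               grid = c(6, 6), n_per_species = 4)
  r1 <- do.call(run_supplement_replicates, args)
  r2 <- do.call(run_supplement_replicates, args)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_equal(sort(unique(r1$trajectory$timestep)), 1:4)

  r0 <- do.call(run_supplement_replicates,
                c(args, list(compound = b$ground_truth$shared[1],
                             dose_mM = 0)))
  expect_true(all(r0$rel_change$rel_change == 0))
})

test_that("a supplement favoring the target raises its biomass more than the competitor's", {
  b <- generate_two_species_benchmark(seed = 1)
  planted <- b$ground_truth$planted_prebiotics[1]
  r <- run_supplement_replicates(b$models, b$medium_mM, compound = planted,
                                 n_steps = 8, n_replicates = 4, seed = 21,
                                 grid = c(8, 8), n_per_species = 8)
  med_t <- stats::median(r$rel_change$rel_change[
    r$rel_change$species == b$ground_truth$target])
  med_o <- stats::median(r$rel_change$rel_change[
    r$rel_change$species != b$ground_truth$target])
  expect_gt(med_t, med_o)
  expect_gt(med_t, 0)
})
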