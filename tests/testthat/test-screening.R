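# Screening decision layer: per-arm selection rules, the statistics, the
# intersection/Biolog logic, enrichment, and the host-proportion analysis.

test_that("single-FBA screen applies the relative-change cutoff after rounding", {
  b <- generate_two_species_benchmark(seed = 4)
  gt <- b$ground_truth
  sc <- screen_single_fba(b$models[[1]], b$medium)
  # every planted compound boosts the target by more than 1%
  expect_true(all(gt$planted_prebiotics %in% attr(sc, "selected")))
  # the competitor-only compound cannot boost the target
  expect_false(any(gt$unique_other %in% attr(sc, "selected")))
  expect_true(all(sc$rel_change[sc$selected] > 0.01))

  # borderline changes are not selected (cutoff is strict)
  m <- generate_species_model(species_spec("tiny", c(a = 1, b = 0.0005)))
  med <- medium(c(a = 10, b = 10))
  sc2 <- screen_single_fba(m, med, compounds = "b")
  expect_equal(sc2$rel_change, 0.005 / 10.005, tolerance = 1e-6)
  expect_false(sc2$selected)

  # zero baseline growth is flagged, not propagated
  m0 <- generate_species_model(species_spec("starved", c(a = 1)))
  sc3 <- suppressWarnings(
    screen_single_fba(m0, medium(c(zz = 10)), compounds = "zz"))
  expect_equal(sc3$note, "undefined-baseline")
  expect_false(sc3$selected)
})

test_that("wilcoxon_rank_sum matches exhaustive enumeration and is symmetric", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4)), 1 / 3)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(wilcoxon_rank_sum(c(5, 1, 9), c(2, 7)),
               wilcoxon_rank_sum(c(2, 7), c(5, 1, 9)))
  expect_error(wilcoxon_rank_sum(numeric(), 1), "non-empty")

  set.seed(33)
  for (k in 1:25) {
    nx <- sample(1:5, 1); ny <- sample(1:5, 1)
    vals <- sample(100, nx + ny)  # tieless
    x <- vals[seq_len(nx)]; y <- vals[nx + seq_len(ny)]
    expect_equal(wilcoxon_rank_sum(x, y), enum_wilcox_p(x, y),
                 tolerance = 1e-12,
                 info = paste("case", k))
  }
})

test_that("BH adjustment reproduces the hand-computed step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.01, 7)), rep(0.01, 7))
  # hand-computed: sorted p * m / rank, cumulative minimum from the tail
  p <- c(0.005, 0.049, 0.05, 0.2)
  expect_equal(bh_fdr(p), c(0.02, 0.0666666666666667, 0.0666666666666667, 0.2),
               tolerance = 1e-12)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the ABM selection rule needs both median ordering and significance", {
  mk_result <- function(xt, xo) {
    structure(list(compound = "c1", rel_change = data.frame(
      replicate = rep(seq_along(xt), 2),
      species = rep(c("T", "O"), each = length(xt)),
      rel_change = c(xt, xo))), class = "abm_run_result")
  }
  s <- screen_abm_stats(mk_result(c(1, 2, 3), c(4, 5, 6)), "T", "O")
  expect_equal(s$p_value, 0.1)
  expect_false(s$median_favors_target)
  s2 <- screen_abm_stats(mk_result(c(4, 5, 6), c(1, 2, 3)), "T", "O")
  expect_true(s2$median_favors_target)
  s3 <- screen_abm_stats(mk_result(c(1, 2, 3), c(1, 2, 3)), "T", "O")
  expect_equal(s3$p_value, 1)
  expect_false(s3$median_favors_target)
})

test_that("intersection and Biolog confirmation follow set algebra", {
  sets <- list(fba = c("a", "b", "c"), community = c("b", "c"),
               abm = c("b", "c", "d"))
  biolog <- biolog_table(c("b", "x"), od590 = c(0.4, 0.4),
                         od750 = c(0.2, 0.35))
  res <- intersect_and_confirm(sets, biolog)
  expect_setequal(res$intersection, c("b", "c"))
  expect_equal(res$biolog_confirmed, "b")
  expect_equal(res$not_assayed, "c")  # kept visible, not dropped

  res2 <- intersect_and_confirm(list(a = character(), b = c("x")))
  expect_equal(res2$intersection, character())
})

test_that("class enrichment matches the hypergeometric oracle", {
  ann <- list(a = "aa", b = "aa", c = "sugar", d = "sugar")
  enr <- class_enrichment(c("a", "b"), ann, c("a", "b", "c", "d"))
  aa <- enr[enr$class == "aa", ]
  expect_equal(aa$p_value, 1 / 6)           # one-sided
  expect_equal(enum_fisher_greater(2, 0, 0, 2), 1 / 6)
  enr2 <- class_enrichment(c("a", "b"), ann, c("a", "b", "c", "d"),
                           alternative = "two.sided")
  expect_equal(enr2[enr2$class == "aa", ]$p_value, 1 / 3)

  # degenerate: candidates = background -> nothing enriched
  enr3 <- class_enrichment(c("a", "b", "c", "d"), ann, c("a", "b", "c", "d"))
  expect_true(all(enr3$p_value == 1))

  # planted class-biased candidates give that class the smallest p
  b <- generate_two_species_benchmark(seed = 6)
  gt <- b$ground_truth
  bg <- c(gt$shared, gt$unique_target, gt$unique_other)
  enr4 <- class_enrichment(gt$planted_prebiotics, b$annotation, bg)
  expect_equal(enr4$class[which.min(enr4$p_value)], "amino acid")

  expect_error(class_enrichment("zz", ann, c("a", "b")), "subset")

  # sweep of 2x2 tables against the enumeration oracle
  for (a_ in 0:3) for (b_ in 0:3) for (c_ in 0:3) for (d_ in 0:3) {
    if (a_ + b_ == 0 || a_ + c_ == 0) next
    cand <- c(sprintf("i%d", seq_len(a_ + b_)))
    bg <- c(cand, sprintf("o%d", seq_len(c_ + d_)))
    if (length(bg) < 2) next
    ann2 <- stats::setNames(as.list(c(rep("k", a_), rep("no", b_),
                                      rep("k", c_), rep("no", d_))), bg)
    pk <- class_enrichment(cand, ann2, bg)
    pk <- pk[pk$class == "k", ]
    if (!nrow(pk)) next
    expect_equal(pk$p_value, enum_fisher_greater(a_, b_, c_, d_),
                 tolerance = 1e-12,
                 info = sprintf("table %d %d %d %d", a_, b_, c_, d_))
  }
})

test_that("expected host proportion reproduces its identity limits", {
  expect_equal(expected_worm_proportion(0.6, 0.75, 0.5), 0.625)
  # no supplementation effect on the lawn: expectation = worm baseline
  expect_equal(expected_worm_proportion(0.6, 0.6, 0.5), 0.5)
  # no host filtering: expectation = supplemented lawn proportion
  expect_equal(expected_worm_proportion(0.6, 0.75, 0.6), 0.75)
  expect_error(expected_worm_proportion(0, 0.5, 0.5), "undefined")
  expect_warning(e <- expected_worm_proportion(0.1, 0.9, 0.9), "clipped")
  expect_equal(e, 1)
})

test_that("chi-square of observed versus expected proportions", {
  r0 <- chisq_observed_vs_expected(c(50, 50), c(0.5, 0.5))
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p, 1)
  r1 <- chisq_observed_vs_expected(c(30, 70), c(0.5, 0.5))
  expect_equal(r1$chi2, 16)  # (30-50)^2/50 + (70-50)^2/50
  expect_equal(r1$df, 1L)
  expect_error(chisq_observed_vs_expected(c(10, 10), c(1, 0)), "zero")
  # survival function at the reference statistic
  expect_equal(stats::pchisq(10.244, 1, lower.tail = FALSE), 0.0013,
               tolerance = 0.05)
})
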