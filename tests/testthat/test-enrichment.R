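test_that("category enrichment matches exact binomial intervals", {
  universe <- sprintf("p%03d", 1:500)
  categories <- tibble::tibble(
    probe_id = universe,
    category = rep(c("a", "b", "c", "d", "e"), each = 100))
  dmr <- c(universe[1:10], universe[101:130])  # a: 10/100, b: 30/100
  enr <- category_enrichment(dmr, categories, universe)
  a <- enr[enr$category == "a", ]
  expect_equal(a$fraction, 0.10)
  # Clopper-Pearson bounds cross-checked against stats::binom.test
  bt <- stats::binom.test(10, 100)$conf.int
  expect_equal(a$ci_low, bt[1], tolerance = 1e-9)
  expect_equal(a$ci_high, bt[2], tolerance = 1e-9)
  expect_equal(unique(enr$background_fraction), 40 / 500)
  # conservation over a disjoint exhaustive category map
  expect_equal(sum(enr$n_dmr_probes_in_category), length(dmr))
  # all probes DMR: fraction 1 with upper bound 1
  all_dmr <- category_enrichment(universe, categories, universe)
  expect_true(all(all_dmr$fraction == 1))
  expect_true(all(all_dmr$ci_high == 1))
  expect_error(category_enrichment("zzz", categories, universe), "subset")
  expect_error(category_enrichment(dmr, categories, character()), "empty")
})

test_that("Wilson intervals are available and near the exact ones", {
  universe <- sprintf("p%03d", 1:200)
  categories <- tibble::tibble(probe_id = universe, category = "a")
  enr_w <- category_enrichment(universe[1:20], categories, universe,
                               method = "wilson")
  enr_cp <- category_enrichment(universe[1:20], categories, universe)
  expect_lt(abs(enr_w$ci_low - enr_cp$ci_low), 0.02)
  expect_lt(abs(enr_w$ci_high - enr_cp$ci_high), 0.02)
})

test_that("chromatin-state classification recovers designed states", {
  k4 <- tibble::tibble(region_id = sprintf("T%02d", 1:20),
                       norm_score = c(rep(100, 5), rep(2, 15)))
  k27 <- tibble::tibble(region_id = sprintf("T%02d", 1:20),
                        norm_score = c(rep(0, 5), rep(80, 5), rep(1, 10)))
  st <- classify_chromatin_states(k4, k27)
  expect_equal(st$state[1], "K4hi/K27lo")
  expect_equal(st$state[6], "K4lo/K27hi")
  expect_equal(st$state[15], "K4lo/K27lo")
  zero <- tibble::tibble(region_id = k4$region_id, norm_score = 0)
  expect_error(classify_chromatin_states(zero, k27), "all-zero")
  # strong-separation recovery against the generator's truth
  co <- simulate_cohort(cohort_config(seed = 13, n_probes = 8000))
  st2 <- classify_chromatin_states(simulate_chip_counts(co, "H3K4me3"),
                                   simulate_chip_counts(co, "H3K27me3"))
  truth <- co$truth$promoters
  m <- merge(st2, truth[c("tss_id", "state")], by = "tss_id")
  expect_gte(mean(m$state.x == m$state.y), 0.90)
})

test_that("housekeeping depletion chi-square behaves at the extremes", {
  universe <- sprintf("T%03d", 1:400)
  hk <- universe[1:100]
  # DMR set drawn to exclude housekeeping genes entirely
  res <- housekeeping_depletion_test(universe[101:220], hk, universe)
  expect_lt(res$p_value, 1e-5)
  expect_true(res$estimate$depleted)
  # observed equals expected exactly: chi2 = 0, p = 1
  dmr_prop <- c(universe[1:25], universe[101:175])  # 25% of hk, 25% of rest
  res0 <- housekeeping_depletion_test(dmr_prop, hk, universe)
  expect_equal(res0$statistic, 0, tolerance = 1e-12)
  expect_equal(res0$p_value, 1)
  expect_error(housekeeping_depletion_test(universe, hk, universe),
               "degenerate")
})

test_that("aDMR-versus-control comparison validates inputs", {
  co <- simulate_cohort(cohort_config(seed = 17, n_probes = 3000,
                                      n_pairs = 2, epiallele_rate = 0.3))
  kept <- suppressMessages(filter_probes(co$manifest))
  age <- simulate_age_scores(co, n_designated = 100, overlap = 1)
  expect_error(admr_variability_comparison(age, co$beta$dense, co$sheet,
                                           kept, n_top = 0), "positive")
  expect_error(admr_variability_comparison(age, co$beta$dense, co$sheet,
                                           kept, n_top = 3000,
                                           n_control = 3000), "exceeds")
  res <- admr_variability_comparison(age, co$beta$dense, co$sheet, kept,
                                     n_top = 100, n_control = 100,
                                     n_boot = 200, seed = 8)
  expect_setequal(res$set, c("admr", "control"))
  expect_true(all(res$ci_low <= res$mean_abs_delta &
                    res$mean_abs_delta <= res$ci_high))
  # deterministic given the seed
  res2 <- admr_variability_comparison(age, co$beta$dense, co$sheet, kept,
                                      n_top = 100, n_control = 100,
                                      n_boot = 200, seed = 8)
  expect_identical(as.data.frame(res), as.data.frame(res2))
})
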