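small_cfg <- function(...) {
  cohort_config(seed = 42, n_probes = 2000, n_pairs = 3,
                n_tech_replicates = 2, tech_rep_pairs = 2, ...)
}

test_that("identical configuration gives bit-identical cohorts", {
  a <- simulate_cohort(small_cfg())
  b <- simulate_cohort(small_cfg())
  expect_identical(a$beta, b$beta)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$truth$epialleles, b$truth$epialleles)
  expect_identical(simulate_expression(a), simulate_expression(b))
  expect_identical(simulate_chip_counts(a, "H2A.Z"),
                   simulate_chip_counts(b, "H2A.Z"))
})

test_that("degenerate limit: no epialleles and vanishing noise makes
           co-twins identical", {
  co <- simulate_cohort(small_cfg(epiallele_rate = 0, tech_noise_sd = 1e-8,
                                  missing_rate = 0))
  s <- co$sheet
  twin1 <- s$sample_id[s$individual_id == "ind011" & s$platform == "dense" &
                         s$replicate_id == "r1"]
  twin2 <- s$sample_id[s$individual_id == "ind012" & s$platform == "dense" &
                         s$replicate_id == "r1"]
  expect_equal(co$beta$dense[[twin1]], co$beta$dense[[twin2]],
               tolerance = 1e-6)
  expect_equal(nrow(co$truth$epialleles), 0L)
})

test_that("planted epialleles are conserved, realized and persistence-tagged", {
  co <- simulate_cohort(small_cfg(epiallele_rate = 0.3,
                                  epiallele_delta = 0.15,
                                  missing_rate = 0))
  truth <- co$truth$epialleles
  # conservation: each planted probe appears exactly once; all in manifest
  expect_equal(anyDuplicated(truth$probe_id), 0L)
  expect_true(all(truth$probe_id %in% co$manifest$probe_id))
  # run lengths within the configured range
  runs <- table(truth$epiallele_id)
  expect_true(all(runs >= 2 & runs <= 5))
  # realized intra-pair deltas at planted, persisting probes reach at least
  # two-thirds of the planted shift (noise sd 0.015 against delta 0.15)
  s <- co$sheet
  ind <- co$individuals
  deltas <- vapply(seq_len(nrow(truth)), function(i) {
    owner <- truth$individual_id[i]
    pair <- ind$pair_id[ind$individual_id == owner]
    cotwin <- setdiff(ind$individual_id[ind$pair_id == pair], owner)
    so <- s$sample_id[s$individual_id == owner & s$platform == "dense" &
                        s$replicate_id == "r1"]
    sc <- s$sample_id[s$individual_id == cotwin & s$platform == "dense" &
                        s$replicate_id == "r1"]
    r <- match(truth$probe_id[i], co$beta$dense$probe_id)
    co$beta$dense[[so]][r] - co$beta$dense[[sc]][r]
  }, double(1))
  persisting <- truth$persists_t2
  expect_true(all(abs(deltas[persisting]) >= 0.10))
  expect_equal(sign(deltas[persisting]), truth$direction[persisting])
  # non-persisting epialleles are absent from the time-2 matrix
  if (any(!persisting))
    expect_true(all(abs(deltas[!persisting]) < 0.10))
})

test_that("sparse platform is a strict promoter-biased subset", {
  co <- simulate_cohort(small_cfg())
  expect_true(all(co$sparse_manifest$probe_id %in% co$manifest$probe_id))
  expect_lt(nrow(co$sparse_manifest), nrow(co$manifest))
  prom_frac_sparse <- mean(co$sparse_manifest$feature_class == "promoter")
  prom_frac_dense <- mean(co$manifest$feature_class == "promoter")
  expect_gt(prom_frac_sparse, prom_frac_dense)
  # co-twin beta correlation exceeds cross-pair correlation (pair effects)
  g <- simulate_cohort(small_cfg(genetic_rate = 0.2, genetic_delta = 0.1,
                                 missing_rate = 0))
  col_of <- function(i) {
    sid <- g$sheet$sample_id[g$sheet$individual_id == i &
                               g$sheet$platform == "dense" &
                               g$sheet$replicate_id == "r1"]
    g$beta$dense[[sid]]
  }
  intra <- cor(col_of("ind011"), col_of("ind012"))
  inter <- cor(col_of("ind011"), col_of("ind022"))
  expect_gt(intra, inter)
})

test_that("expression tiers respect the 1-FPKM boundary and lognormal means", {
  co <- simulate_cohort(small_cfg())
  expr <- simulate_expression(co)
  tier <- co$truth$promoters$tier
  ind <- co$individuals$individual_id[1]
  expect_true(all(expr[[ind]][tier == "low"] < 1))
  expect_true(all(expr[[ind]][tier == "high"] >= 1))
  # pooled across individuals, tier means recover the (truncation-corrected)
  # log-normal means within 10%
  vals_low <- unlist(expr[tier == "low", -1])
  m_low <- exp(co$config$expr_low_meanlog + co$config$expr_low_sdlog^2 / 2)
  expect_lt(abs(mean(vals_low) - m_low) / m_low, 0.10)
  vals_high <- unlist(expr[tier == "high", -1])
  m_high <- exp(co$config$expr_high_meanlog + co$config$expr_high_sdlog^2 / 2)
  expect_lt(abs(mean(vals_high) - m_high) / m_high, 0.10)
})

test_that("H2A.Z counts track the configured methylation coupling", {
  co <- simulate_cohort(cohort_config(seed = 5, n_probes = 8000))
  chip <- simulate_chip_counts(co, "H2A.Z")
  beta <- co$beta$dense[[co$sheet$sample_id[1]]]
  idx <- match(chip$region_id, co$beta$dense$probe_id)
  rho <- cor(beta[idx], chip$norm_score, method = "spearman",
             use = "complete.obs")
  expect_gt(rho, -0.7)
  expect_lt(rho, -0.5)
  # uncoupled generator: correlation near zero
  co0 <- simulate_cohort(cohort_config(seed = 5, n_probes = 8000,
                                       meth_chip_coupling = 0))
  chip0 <- simulate_chip_counts(co0, "H2A.Z")
  beta0 <- co0$beta$dense[[co0$sheet$sample_id[1]]]
  idx0 <- match(chip0$region_id, co0$beta$dense$probe_id)
  rho0 <- cor(beta0[idx0], chip0$norm_score, method = "spearman",
              use = "complete.obs")
  expect_lt(abs(rho0), 0.1)
})

test_that("K27 counts at K4lo/K27hi promoters clear the hi threshold", {
  co <- simulate_cohort(cohort_config(seed = 5, n_probes = 12000))
  k27 <- simulate_chip_counts(co, "H3K27me3")
  cut <- stats::quantile(k27$norm_score, 0.75)
  truth <- co$truth$promoters
  hi_scores <- k27$norm_score[match(
    truth$tss_id[truth$state == "K4lo/K27hi"], k27$region_id)]
  expect_gte(mean(hi_scores > cut), 0.90)
})

test_that("age scores separate the designated set as configured", {
  co <- simulate_cohort(small_cfg(epiallele_rate = 0.4))
  planted <- unique(
    co$truth$epialleles$probe_id[co$truth$epialleles$persists_t2])
  n_des <- min(50L, length(planted))
  age <- simulate_age_scores(co, n_designated = n_des, overlap = 1)
  expect_equal(sum(age$designated), n_des)
  expect_true(all(age$probe_id[age$designated] %in% planted))
  expect_gt(min(age$age_score[age$designated]),
            max(age$age_score[!age$designated]))
  # independent designation: overlap with planted probes matches prevalence
  age0 <- simulate_age_scores(co, n_designated = 200L, overlap = NULL)
  prevalence <- length(planted) / nrow(co$manifest)
  frac <- mean(age0$probe_id[age0$designated] %in% planted)
  expect_lt(abs(frac - prevalence), 0.08)
  expect_error(simulate_age_scores(co, n_designated = 1e6, overlap = 1),
               "designated")
})

test_that("cohort variability mode plants pair-difference deviations", {
  co <- simulate_cohort(small_cfg(variability_mode = "cohort",
                                  epiallele_rate = 0.3, missing_rate = 0))
  truth <- co$truth$epialleles
  expect_gt(nrow(truth), 0)
  s <- co$sheet
  d <- co$beta$dense
  idx <- match(truth$probe_id, d$probe_id)
  diffs <- unlist(lapply(unique(s$pair_id), function(p) {
    ii <- unique(s$individual_id[s$pair_id == p])
    s1 <- s$sample_id[s$individual_id == ii[1] & s$platform == "dense" &
                        s$replicate_id == "r1"]
    s2 <- s$sample_id[s$individual_id == ii[2] & s$platform == "dense" &
                        s$replicate_id == "r1"]
    d[[s1]][idx] - d[[s2]][idx]
  }))
  # pair-difference SD ~ sqrt(epiallele_delta^2 + 2 * noise^2)
  target <- sqrt(co$config$epiallele_delta^2 + 2 * co$config$tech_noise_sd^2)
  expect_lt(abs(sd(diffs) - target) / target, 0.10)
})
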