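test_that("promoter windows are anchor-symmetric and clipped", {
  tss <- tibble::tibble(chromosome = "chr1", start = c(5000L, 300L),
                        end = c(5001L, 301L), name = c("T1", "T2"),
                        strand = "+")
  w <- promoter_window(tss)
  expect_equal(w$start, c(4000L, 0L))
  expect_equal(w$end, c(6000L, 1300L))
  # minus-strand gene: anchor is end - 1
  minus <- tibble::tibble(chromosome = "chr1", start = 2000L, end = 9000L,
                          name = "T3", strand = "-")
  wm <- promoter_window(minus)
  expect_equal(wm$start, 7999L)
  expect_equal(wm$end, 9999L)
})

test_that("probe-TSS assignment uses nearest anchor with deterministic ties", {
  tss <- tibble::tibble(chromosome = "chr1",
                        start = c(1000L, 2000L), end = c(1001L, 2001L),
                        name = c("T1", "T2"), strand = "+")
  probes <- tibble::tibble(probe_id = c("p0", "p1", "p2", "p3"),
                           chromosome = "chr1",
                           position = c(1000L, 1500L, 1800L, 3500L))
  a <- assign_probes_to_tss(probes, tss)
  expect_equal(a$tss_id[a$probe_id == "p0"], "T1")
  expect_equal(a$tss_distance[a$probe_id == "p0"], 0L)
  # equidistant: smaller anchor coordinate wins
  expect_equal(a$tss_id[a$probe_id == "p1"], "T1")
  expect_equal(a$tss_id[a$probe_id == "p2"], "T2")
  # beyond 1 kb: unassigned
  expect_false("p3" %in% a$probe_id)
  # coincident anchors: lexicographically smaller id wins
  tss2 <- tibble::tibble(chromosome = "chr1", start = 1000L, end = 1001L,
                         name = c("TB", "TA"), strand = "+")
  a2 <- assign_probes_to_tss(probes[1, ], tss2)
  expect_equal(a2$tss_id, "TA")
})

test_that("fragment counting matches a quadratic all-pairs oracle", {
  # half-open semantics at the boundary
  frag <- tibble::tibble(chromosome = "chr1", start = c(90L, 150L),
                         end = c(190L, 200L))
  region <- tibble::tibble(chromosome = "chr1", start = 100L, end = 150L,
                           name = "r1")
  expect_equal(count_fragments(frag, region)$raw_count, 1L)
  for (s in 1:10) {
    withr::with_seed(900 + s, {
      frags <- tibble::tibble(
        chromosome = sample(c("chr1", "chr2"), 400, replace = TRUE),
        start = sample.int(10000L, 400, replace = TRUE))
      frags$end <- frags$start + sample.int(500L, 400, replace = TRUE)
      regions <- tibble::tibble(
        chromosome = sample(c("chr1", "chr2"), 40, replace = TRUE),
        start = sample.int(10000L, 40, replace = TRUE))
      regions$end <- regions$start + sample.int(300L, 40, replace = TRUE)
    })
    got <- count_fragments(frags, regions)$raw_count
    want <- vapply(seq_len(nrow(regions)), function(i) {
      sum(frags$chromosome == regions$chromosome[i] &
            frags$start < regions$end[i] & frags$end > regions$start[i])
    }, integer(1))
    expect_equal(got, want)
  }
})

test_that("count normalization is linear in the library total", {
  track <- tibble::tibble(region_id = c("a", "b"), raw_count = c(50L, 0L))
  n1 <- normalize_counts(track, library_total = 1e7)
  expect_equal(n1$norm_score, c(50, 0))
  n2 <- normalize_counts(track, library_total = 2e7)
  expect_equal(n2$norm_score, n1$norm_score / 2)
  expect_error(normalize_counts(track, library_total = 0), "positive")
})

test_that("Spearman test reproduces the rank formula and guards input", {
  expect_equal(tidy(spearman_test(1:10, (1:10)^2))$statistic, 1)
  expect_equal(tidy(spearman_test(1:10, -(1:10)))$statistic, -1)
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  # direct rank formula (no ties): 1 - 6*sum(d^2)/(n(n^2-1))
  rho_direct <- 1 - 6 * sum((rank(x) - rank(y))^2) / (5 * 24)
  expect_equal(tidy(spearman_test(x, y))$statistic, rho_direct)
  expect_error(spearman_test(c(1, 1, 1), 1:3), "constant")
  expect_error(spearman_test(1:2, 1:2), ">= 3")
})

test_that("binned bootstrap series is deterministic and flags small bins", {
  withr::with_seed(77, {
    df <- tibble::tibble(delta = runif(400, -0.2, 0.2),
                         y = rnorm(400))
  })
  b1 <- binned_mean_ci(df, response = "y", n_boot = 200, seed = 4)
  b2 <- binned_mean_ci(df, response = "y", n_boot = 200, seed = 4)
  expect_identical(as.data.frame(b1), as.data.frame(b2))
  expect_true(all(b1$ci_low <= b1$mean & b1$mean <= b1$ci_high,
                  na.rm = TRUE))
  # bins are contiguous on a bin_width lattice
  expect_equal(b1$bin_low, round(b1$bin_low / 0.05) * 0.05, tolerance = 1e-9)
  expect_equal(diff(b1$bin_low), rep(0.05, nrow(b1) - 1), tolerance = 1e-9)
  # constant response: degenerate intervals at the constant
  dfc <- tibble::tibble(delta = runif(50, -0.1, 0.1), y = 1.5)
  bc <- binned_mean_ci(dfc, response = "y", n_boot = 50)
  expect_true(all(bc$ci_low == 1.5 & bc$ci_high == 1.5, na.rm = TRUE))
  # small bins flagged without intervals
  dfs <- tibble::tibble(delta = c(-0.07, 0.01, 0.012, 0.013, 0.02),
                        y = rnorm(5))
  bs <- binned_mean_ci(dfs, response = "y", n_boot = 50)
  expect_true(bs$flagged[bs$n == 1])
  expect_true(is.na(bs$ci_low[bs$n == 1]))
})

test_that("bootstrap intervals agree with an independent implementation
           and cover the truth", {
  withr::with_seed(12, x <- rnorm(400))
  b <- binned_mean_ci(tibble::tibble(delta = 0, y = x), response = "y",
                      n_boot = 4000, seed = 9)
  ref <- withr::with_seed(101, {
    means <- replicate(4000, mean(sample(x, replace = TRUE)))
    quantile(means, c(0.025, 0.975))
  })
  expect_lt(abs(b$ci_low - ref[[1]]), 0.012)
  expect_lt(abs(b$ci_high - ref[[2]]), 0.012)
  # empirical coverage of the true mean across repeated small datasets
  hits <- vapply(1:200, function(s) {
    withr::with_seed(5000 + s, y <- rnorm(50, 2, 1))
    ci <- binned_mean_ci(tibble::tibble(delta = 0, y = y), response = "y",
                         n_boot = 400, seed = s)
    ci$ci_low[1] <= 2 && 2 <= ci$ci_high[1]
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("expression ratio series is zero-centred for equal expression", {
  co <- simulate_cohort(cohort_config(seed = 21, n_probes = 4000))
  kept <- suppressMessages(filter_probes(co$manifest))
  assignment <- assign_probes_to_tss(kept, co$tss)
  expr <- simulate_expression(co)
  e1 <- tibble::tibble(tss_id = expr$tss_id, fpkm = expr[[2]])
  s <- co$sheet$sample_id[co$sheet$platform == "dense"][1:2]
  d <- compute_deltas(co$beta$dense, s[1], s[2], kept)
  ser <- expression_ratio_series(d, assignment, e1, e1, n_boot = 100)
  expect_true(all(abs(ser$mean) < 1e-12))
  expect_error(expression_ratio_series(d, assignment[0, ], e1, e1),
               "empty")
})

test_that("expression shift test detects planted low-expression targeting", {
  expr <- tibble::tibble(tss_id = sprintf("T%03d", 1:200),
                         fpkm = c(runif(100, 0.01, 0.9),
                                  runif(100, 1.5, 30)))
  low_set <- expr$tss_id[1:60]
  res <- expression_shift_test(low_set, expr$tss_id, expr)
  expect_lt(res$p_value, 1e-6)
  expect_gt(res$estimate$frac_low_dmr, res$estimate$frac_low_non_dmr)
  # constant expression: no detectable shift
  const <- tibble::tibble(tss_id = expr$tss_id, fpkm = 2)
  expect_equal(expression_shift_test(low_set, expr$tss_id, const)$p_value, 1)
  expect_error(expression_shift_test(character(), expr$tss_id, expr),
               "non-empty")
  expect_error(expression_shift_test("zzz", expr$tss_id, expr), "subset")
})
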