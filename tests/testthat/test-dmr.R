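track <- function(pos, delta, chrom = "chr1") {
  tibble::tibble(probe_id = sprintf("p%03d", seq_along(pos)),
                 chromosome = chrom, position = as.integer(pos),
                 delta = delta)
}

test_that("compute_deltas subtracts B from A and propagates missingness", {
  manifest <- tibble::tibble(
    probe_id = c("p1", "p2", "p3"), chromosome = "chr1",
    position = c(300L, 100L, 200L), multi_mapped = FALSE,
    snp_overlap = FALSE, sex_chromosome = FALSE, feature_class = "other",
    cgi_relation = "open_sea")
  beta <- tibble::tibble(probe_id = c("p1", "p2", "p3"),
                         a = c(0.80, NA, 0.3), b = c(0.70, 0.5, 0.3))
  d <- compute_deltas(beta, "a", "b", manifest)
  expect_equal(d$probe_id, c("p2", "p3", "p1"))  # coordinate sorted
  expect_equal(d$delta, c(NA, 0, 0.10), tolerance = 1e-12)
  expect_equal(compute_deltas(beta, "a", "a", manifest)$delta,
               c(NA, 0, 0))
  expect_error(compute_deltas(beta, "a", "zz", manifest), "unknown sample")
})

test_that("the adjacency/threshold/direction rule is enforced", {
  # two close gains plus an isolated third probe -> one 2-probe call
  calls <- call_iidmrs(track(c(100, 400, 2000), c(0.08, 0.06, 0.20)))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start, 100L)
  expect_equal(calls$end, 402L)
  expect_equal(calls$n_probes, 2L)
  expect_equal(calls$direction, "gain")

  # sign change breaks directional consistency
  expect_equal(nrow(call_iidmrs(track(c(100, 300), c(0.08, -0.06)))), 0L)
  # sub-threshold and missing probes break runs
  expect_equal(nrow(call_iidmrs(track(c(100, 200, 300),
                                      c(0.08, 0.02, 0.06)))), 0L)
  expect_equal(nrow(call_iidmrs(track(c(100, 200, 300),
                                      c(0.08, NA, 0.06)))), 0L)
  # chromosome change breaks runs even at close coordinates
  t2 <- track(c(100, 150), c(0.1, 0.1), chrom = c("chr1", "chr2"))
  expect_equal(nrow(call_iidmrs(t2)), 0L)
  # zero track, no calls; unsorted input is an error
  expect_equal(nrow(call_iidmrs(track(c(100, 200), c(0, 0)))), 0L)
  expect_error(call_iidmrs(track(c(200, 100), c(0.1, 0.1))), "sorted")
})

test_that("caller matches the brute-force oracle on random instances", {
  for (s in 1:60) {
    d <- random_delta_track(n = sample(20:90, 1), seed = 4000 + s)
    got <- call_iidmrs(d)
    want <- oracle_iidmrs(d)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$direction, want$direction)
      expect_equal(got$probe_ids, want$probe_ids)
    }
  }
})

test_that("swapping samples flips direction and nothing else", {
  for (s in 1:20) {
    d <- random_delta_track(n = 60, seed = 7000 + s)
    flipped <- d
    flipped$delta <- -flipped$delta
    a <- call_iidmrs(d)
    b <- call_iidmrs(flipped)
    expect_equal(nrow(a), nrow(b))
    expect_equal(a$start, b$start)
    expect_equal(a$probe_ids, b$probe_ids)
    if (nrow(a))
      expect_equal(b$direction,
                   ifelse(a$direction == "gain", "loss", "gain"))
  }
})

test_that("tightening thresholds never creates or extends calls", {
  covered_by <- function(inner, outer) {
    # every member probe of `inner` calls appears in some `outer` call
    all(unlist(inner$probe_ids) %in% unlist(outer$probe_ids))
  }
  for (s in 1:20) {
    d <- random_delta_track(n = 80, seed = 8000 + s)
    loose <- call_iidmrs(d, min_delta = 0.04, max_gap = 600)
    tight_delta <- call_iidmrs(d, min_delta = 0.08, max_gap = 600)
    tight_gap <- call_iidmrs(d, min_delta = 0.04, max_gap = 200)
    expect_true(covered_by(tight_delta, loose))
    expect_true(covered_by(tight_gap, loose))
  }
})

test_that("call summaries count calls and member probes per feature", {
  manifest <- tibble::tibble(
    probe_id = sprintf("p%03d", 1:3), chromosome = "chr1",
    position = c(100L, 200L, 300L), multi_mapped = FALSE,
    snp_overlap = FALSE, sex_chromosome = FALSE,
    feature_class = "promoter", cgi_relation = "island")
  calls <- call_iidmrs(track(c(100, 200, 300), c(0.1, 0.1, 0.1)))
  cc <- count_dmr_probes(calls, manifest)
  expect_equal(cc$n_calls, 1L)
  expect_equal(cc$n_probes, 3L)
  expect_equal(
    cc$by_feature$n_probes[cc$by_feature$feature_class == "promoter"], 3L)
  empty <- count_dmr_probes(calls[0, ], manifest)
  expect_equal(empty$n_calls, 0L)
  expect_equal(sum(empty$by_feature$n_probes), 0L)
})
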