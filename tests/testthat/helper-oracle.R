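# Brute-force oracle for the iiDMR caller: enumerates candidate probe runs
# and tests the definition directly (every member qualifies, one sign,
# successive members on one chromosome and <= max_gap apart, >= min_probes,
# not extendable in either direction).

oracle_iidmrs <- function(deltas, min_delta = 0.05, min_probes = 2,
                          max_gap = 500) {
  n <- nrow(deltas)
  d <- deltas$delta
  ok_run <- function(i, j) {
    idx <- i:j
    dd <- d[idx]
    if (anyNA(dd)) return(FALSE)
    if (any(abs(dd) < min_delta)) return(FALSE)
    if (!(all(dd > 0) || all(dd < 0))) return(FALSE)
    if (length(unique(deltas$chromosome[idx])) != 1) return(FALSE)
    if (j > i && any(diff(deltas$position[idx]) > max_gap)) return(FALSE)
    TRUE
  }
  out <- list()
  for (i in seq_len(n)) {
    if (!ok_run(i, i)) next
    j <- i
    while (j + 1 <= n && ok_run(i, j + 1)) j <- j + 1
    if (j - i + 1 < min_probes) next
    if (i > 1 && ok_run(i - 1, j)) next  # extendable left: not maximal
    out[[length(out) + 1]] <- tibble::tibble(
      chromosome = deltas$chromosome[i],
      start = deltas$position[i],
      end = deltas$position[j] + 2L,
      n_probes = j - i + 1L,
      direction = if (d[i] > 0) "gain" else "loss",
      probe_ids = list(deltas$probe_id[i:j]))
  }
  if (!length(out)) {
    return(tibble::tibble(chromosome = character(), start = integer(),
                          end = integer(), n_probes = integer(),
                          direction = character(), probe_ids = list()))
  }
  dplyr::bind_rows(out)
}

# Random delta track on 1-2 chromosomes with irregular spacing, missing
# values and sign mixtures, for property tests.
random_delta_track <- function(n, seed) {
  withr::with_seed(seed, {
    n_chrom <- sample(1:2, 1)
    chrom <- sort(sample(paste0("chr", seq_len(n_chrom)), n, replace = TRUE))
    pos <- unlist(lapply(split(seq_len(n), chrom), function(idx)
      cumsum(sample(c(50L, 100L, 200L, 450L, 600L, 1500L),
                    length(idx), replace = TRUE))), use.names = FALSE)
    delta <- rnorm(n, 0, 0.06)
    delta[runif(n) < 0.05] <- NA_real_
    tibble::tibble(probe_id = sprintf("p%04d", seq_len(n)),
                   chromosome = chrom, position = pos, delta = delta)
  })
}

# Tiny fully-specified sample sheet used across tests.
toy_sheet <- function() {
  tibble::tibble(
    sample_id = c("a1_s", "a2_s", "b1_s", "b2_s"),
    individual_id = c("a1", "a2", "b1", "b2"),
    pair_id = c("A", "A", "B", "B"),
    replicate_id = "r1", time_point = 2L, platform = "dense")
}
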