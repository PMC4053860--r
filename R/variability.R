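# Cohort-scale variability: per-probe RMS intra-/inter-pair methylation
# differences, derangement-style pair permutation, and the permutation test
# comparing biological (co-twin) against technical (replicate) iiDMR calls.

# One representative sample per individual: first row in sheet order for
# the requested platform/time point.
representative_samples <- function(sheet, platform = "dense",
                                   time_point = NULL) {
  sub <- sheet[sheet$platform == platform, , drop = FALSE]
  if (!nrow(sub)) abort(sprintf("no samples on platform '%s'", platform))
  tp <- time_point %||% max(sub$time_point)
  sub <- sub[sub$time_point == tp, , drop = FALSE]
  sub[!duplicated(sub$individual_id), , drop = FALSE]
}

complete_pairs <- function(sheet) {
  ind <- unique(sheet[c("individual_id", "pair_id")])
  counts <- table(ind$pair_id)
  full <- names(counts)[counts == 2]
  lapply(setNames(full, full), function(p)
    sort(ind$individual_id[ind$pair_id == p]))
}

#' Per-probe RMS intra- and inter-pair methylation variability
#'
#' For each probe, `rms_intra` is the root-mean-square of the co-twin beta
#' differences across complete pairs (pairs with a missing beta at that
#' probe are dropped from that probe's mean). `rms_inter` is the same
#' measure computed on permuted pairings in which no individual is matched
#' to their true co-twin, pooled over `n_pair_perm` seeded permutations.
#' Probes measured in fewer than two pairs are omitted.
#'
#' @param beta Wide beta tibble.
#' @param sheet Sample sheet; one representative sample per individual is
#'   used (first replicate on the given platform/time point).
#' @param n_pair_perm Number of seeded pair permutations pooled into
#'   `rms_inter` (set to 1 for a single-permutation measure).
#' @param seed Integer seed for the permutations.
#' @param platform,time_point Sample selection (defaults: dense platform,
#'   latest time point).
#' @return A tibble: `probe_id`, `n_pairs`, `rms_intra`, `rms_inter`.
#' @export
rms_profile <- function(beta, sheet, n_pair_perm = 20L, seed = 1L,
                        platform = "dense", time_point = NULL) {
  reps <- representative_samples(sheet, platform, time_point)
  pairs <- complete_pairs(reps)
  if (length(pairs) < 2) abort("need >= 2 complete pairs")
  m <- beta_matrix(beta)
  col_of <- function(ind) m[, reps$sample_id[match(ind, reps$individual_id)]]
  sq_diffs <- function(pairing) {
    matrix(vapply(pairing, function(p) (col_of(p[1]) - col_of(p[2]))^2,
                  double(nrow(m))), nrow = nrow(m))
  }
  sq_intra <- sq_diffs(pairs)
  n_ok <- rowSums(!is.na(sq_intra))
  rms_intra <- sqrt(rowMeans(sq_intra, na.rm = TRUE))

  sq_inter <- matrix(NA_real_, nrow(m), 0)
  for (k in seq_len(n_pair_perm)) {
    perm <- permute_pairs(reps, seed = derive_seed(seed, paste0("perm", k)))
    pairing <- lapply(seq_len(nrow(perm)), function(i)
      c(perm$individual_1[i], perm$individual_2[i]))
    sq_inter <- cbind(sq_inter, sq_diffs(pairing))
  }
  rms_inter <- sqrt(rowMeans(sq_inter, na.rm = TRUE))

  keep <- n_ok >= 2
  tibble(probe_id = rownames(m), n_pairs = as.integer(n_ok),
         rms_intra = rms_intra, rms_inter = rms_inter)[keep, ]
}

#' Permute twin pairs into a non-co-twin pairing
#'
#' Produces a derangement-style re-pairing: the first twin of pair `i` is
#' matched with the second twin of pair `sigma(i)`, where `sigma` is a
#' random derangement of the pair indices, so no individual is ever matched
#' to their true co-twin. Deterministic given `seed`.
#'
#' @param sheet Sample sheet (or any tibble with `individual_id`,
#'   `pair_id`); needs at least two complete pairs.
#' @param seed Integer seed.
#' @return A tibble: `new_pair_id`, `individual_1`, `individual_2`,
#'   `pair_1`, `pair_2`.
#' @export
permute_pairs <- function(sheet, seed = 1L) {
  pairs <- complete_pairs(sheet)
  k <- length(pairs)
  if (k < 2) abort("need >= 2 complete pairs to permute")
  sigma <- withr::with_seed(seed, {
    repeat {
      s <- sample.int(k)
      if (!any(s == seq_len(k))) break
    }
    s
  })
  tibble(new_pair_id = sprintf("perm%02d", seq_len(k)),
         individual_1 = vapply(pairs, `[`, character(1), 1),
         individual_2 = vapply(pairs[sigma], `[`, character(1), 2),
         pair_1 = names(pairs),
         pair_2 = names(pairs)[sigma])
}

#' Permutation test of biological versus technical iiDMR variation
#'
#' Counts iiDMR calls in every co-twin comparison (replicate-matched twin
#' contrasts) and every technical-replicate comparison (within-individual
#' replicate contrasts), and tests whether biological variation exceeds
#' technical variation. The statistic is the ratio of the mean biological
#' call count to the mean technical call count; the null distribution is
#' built by permuting the biological/technical labels over the comparisons
#' and recomputing the ratio, with `p = (1 + #null >= observed) /
#' (n_perm + 1)`.
#'
#' @param beta Wide beta tibble (dense platform samples).
#' @param sheet Sample sheet containing technical replicates for at least
#'   two individuals from at least two pairs.
#' @param manifest Kept (QC-filtered) probe manifest.
#' @param min_delta,min_probes,max_gap Caller parameters ([call_iidmrs()]).
#' @param n_perm Number of label permutations (>= 1).
#' @param seed Integer seed.
#' @param platform,time_point Sample selection.
#' @return An `iidmr_test`; `details` holds the per-comparison call counts
#'   and labels.
#' @export
technical_vs_biological_test <- function(beta, sheet, manifest,
                                         min_delta = 0.05, min_probes = 2L,
                                         max_gap = 500L, n_perm = 1000L,
                                         seed = 1L, platform = "dense",
                                         time_point = NULL) {
  if (n_perm < 1) abort("n_perm must be >= 1")
  sub <- sheet[sheet$platform == platform, , drop = FALSE]
  tp <- time_point %||% max(sub$time_point)
  sub <- sub[sub$time_point == tp, , drop = FALSE]

  rep_counts <- table(sub$individual_id)
  rep_inds <- names(rep_counts)[rep_counts >= 2]
  rep_pairs <- unique(sub$pair_id[sub$individual_id %in% rep_inds])
  if (length(rep_inds) < 2 || length(rep_pairs) < 2)
    abort("need technical replicates for >= 2 individuals from >= 2 pairs")

  comparisons <- list()
  pairs <- complete_pairs(sub[sub$pair_id %in% rep_pairs, , drop = FALSE])
  for (p in names(pairs)) {
    a <- sub[sub$individual_id == pairs[[p]][1], , drop = FALSE]
    b <- sub[sub$individual_id == pairs[[p]][2], , drop = FALSE]
    shared <- intersect(a$replicate_id, b$replicate_id)
    for (r in shared)
      comparisons[[length(comparisons) + 1L]] <- tibble(
        sample_a = a$sample_id[a$replicate_id == r],
        sample_b = b$sample_id[b$replicate_id == r],
        label = "biological")
  }
  for (ind in rep_inds) {
    s <- sub$sample_id[sub$individual_id == ind]
    cmb <- utils::combn(s, 2)
    for (j in seq_len(ncol(cmb)))
      comparisons[[length(comparisons) + 1L]] <- tibble(
        sample_a = cmb[1, j], sample_b = cmb[2, j], label = "technical")
  }
  comparisons <- bind_rows(comparisons)

  comparisons$n_calls <- vapply(seq_len(nrow(comparisons)), function(i) {
    d <- compute_deltas(beta, comparisons$sample_a[i],
                        comparisons$sample_b[i], manifest)
    nrow(call_iidmrs(d, min_delta, min_probes, max_gap))
  }, integer(1))

  ratio <- function(counts, is_bio) {
    mb <- mean(counts[is_bio]); mt <- mean(counts[!is_bio])
    if (mt == 0 && mb == 0) return(NA_real_)
    if (mt == 0) return(Inf)
    mb / mt
  }
  is_bio <- comparisons$label == "biological"
  observed <- ratio(comparisons$n_calls, is_bio)
  if (is.na(observed))
    warn("no iiDMR calls in any comparison; statistic undefined")
  null <- withr::with_seed(derive_seed(seed, "tvb"), {
    vapply(seq_len(n_perm), function(i) {
      perm <- sample(is_bio)
      ratio(comparisons$n_calls, perm)
    }, double(1))
  })
  p <- if (is.na(observed)) NA_real_ else
    (1 + sum(!is.na(null) & null >= observed)) / (n_perm + 1)
  new_iidmr_test(
    statistic_name = "biological/technical iiDMR call ratio",
    statistic = observed, p_value = p,
    estimate = list(mean_biological = mean(comparisons$n_calls[is_bio]),
                    mean_technical = mean(comparisons$n_calls[!is_bio]),
                    p_resolution = 1 / (n_perm + 1)),
    n_resamples = as.integer(n_perm), seed = as.integer(seed),
    details = comparisons)
}
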