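# Temporal stability across platforms: matching the sparse (27K-like)
# probe set to the dense (450K-like) one, and the chi-square test asking
# whether methylation differences at the current time point recur with the
# same direction at the historic time point more often than chance.

#' Common probes between two platform manifests
#'
#' @param dense_manifest,sparse_manifest Validated probe manifests.
#' @return A character vector of shared probe ids, in dense-manifest order.
#'   The fraction of sparse probes matched is reported via a message.
#' @export
match_platforms <- function(dense_manifest, sparse_manifest) {
  common <- dense_manifest$probe_id[
    dense_manifest$probe_id %in% sparse_manifest$probe_id]
  if (!length(common)) abort("no probes shared between the two platforms")
  inform(sprintf("%.1f%% of sparse-platform probes matched (%d / %d)",
                 100 * length(common) / nrow(sparse_manifest),
                 length(common), nrow(sparse_manifest)))
  common
}

#' Direction-consistency test across time points
#'
#' Selects probes whose current (time point 2) inter-individual difference
#' strictly exceeds `threshold` in absolute value, and tallies how many
#' show a historic (time point 1) difference of the same sign. The
#' statistic is a 1-df goodness-of-fit chi-square against the null that
#' same and opposite directions are equiprobable (expected n/2 each).
#' Probes with a missing or exactly zero historic delta are excluded and
#' counted.
#'
#' @param delta_t2,delta_t1 Delta tracks (see [compute_deltas()]) for the
#'   current and historic time points, restricted to common probes (they
#'   are joined on `probe_id`).
#' @param threshold Selection threshold on `|delta_t2|` (strict, matching
#'   the ">5%" rule; default 0.05).
#' @param correct Apply the continuity correction (default `FALSE`).
#' @param null_prop Null same-direction proportion (default 0.5).
#' @return An `iidmr_test`; `details` holds the sign-by-sign 2x2 tally,
#'   `estimate` the same-direction proportion and exclusion count.
#' @export
direction_consistency_test <- function(delta_t2, delta_t1, threshold = 0.05,
                                       correct = FALSE, null_prop = 0.5) {
  joined <- inner_join(
    delta_t2[c("probe_id", "delta")] |> rename(delta_t2 = "delta"),
    delta_t1[c("probe_id", "delta")] |> rename(delta_t1 = "delta"),
    by = "probe_id")
  sel <- joined[!is.na(joined$delta_t2) &
                  abs(joined$delta_t2) > threshold, , drop = FALSE]
  excluded <- is.na(sel$delta_t1) | sel$delta_t1 == 0
  n_excluded <- sum(excluded)
  sel <- sel[!excluded, , drop = FALSE]
  n <- nrow(sel)
  if (!n) abort("no probes selected above the threshold")
  same <- sign(sel$delta_t1) == sign(sel$delta_t2)
  n_same <- sum(same)
  expected <- n * null_prop
  cc <- if (correct) 0.5 else 0
  stat <- (abs(n_same - expected) - cc)^2 / expected +
    (abs((n - n_same) - (n - expected)) - cc)^2 / (n - expected)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  tally <- sel |>
    mutate(dir_t2 = ifelse(.data$delta_t2 > 0, "gain", "loss"),
           dir_t1 = ifelse(.data$delta_t1 > 0, "gain", "loss")) |>
    dplyr::count(.data$dir_t2, .data$dir_t1, name = "n")
  new_iidmr_test(
    statistic_name = "direction-consistency chi-square (1 df)",
    statistic = stat, p_value = p,
    estimate = list(prop_same_direction = n_same / n, n_selected = n,
                    n_same = n_same, n_excluded = n_excluded),
    details = tally)
}
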