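# The core caller: inter-individual DMRs from per-probe beta differences.
#
# A probe "qualifies" for a comparison when its absolute beta difference
# meets the threshold; a call is a maximal run of >= min_probes consecutive
# qualifying probes (consecutive in the kept, coordinate-sorted probe list)
# of identical sign, with successive members <= max_gap bp apart on one
# chromosome. Missing values, sign changes, chromosome changes and large
# gaps all terminate a run.

#' Per-probe beta differences between two samples
#'
#' @param beta Wide beta tibble (`probe_id` + sample columns).
#' @param sample_a,sample_b Sample column names; the delta is
#'   `beta[sample_a] - beta[sample_b]` (A relative to B).
#' @param manifest Kept probe manifest; restricts and orders the track.
#' @return A delta track tibble: `probe_id`, `chromosome`, `position`,
#'   `delta`, sorted by `(chromosome, position)`. `delta` is missing where
#'   either beta is missing.
#' @export
compute_deltas <- function(beta, sample_a, sample_b, manifest) {
  for (s in c(sample_a, sample_b))
    if (!s %in% names(beta)) abort(sprintf("unknown sample id '%s'", s))
  track <- manifest[manifest$probe_id %in% beta$probe_id,
                    c("probe_id", "chromosome", "position")]
  idx <- match(track$probe_id, beta$probe_id)
  track$delta <- beta[[sample_a]][idx] - beta[[sample_b]][idx]
  as_tibble(sort_by_coord(track))
}

#' Call inter-individual DMRs from a delta track
#'
#' Implements the adjacency/threshold/direction rule: calls are the maximal
#' runs of at least `min_probes` consecutive probes whose absolute delta is
#' at least `min_delta` (comparisons on raw floating values, no rounding),
#' all of one sign, each successive pair of member probes at most `max_gap`
#' bp apart on the same chromosome. The reported interval runs from the
#' first member probe's position to the last member's position + 2, covering
#' the final CpG dinucleotide.
#'
#' @param deltas A delta track from [compute_deltas()], sorted by
#'   coordinate (unsorted input is an error).
#' @param min_delta Minimum absolute beta difference (inclusive); default
#'   0.05, i.e. the 5% rule.
#' @param min_probes Minimum member probes per call; default 2.
#' @param max_gap Maximum distance in bp between successive member probes;
#'   default 500.
#' @param comparison_id Optional label recorded on every call.
#' @return A tibble with one row per call: `chromosome`, `start`, `end`,
#'   `n_probes`, `direction` (`"gain"`/`"loss"`, sign of A minus B),
#'   `mean_delta`, `mean_abs_delta`, `comparison_id`, and list-columns
#'   `probe_ids`, `deltas`.
#' @export
call_iidmrs <- function(deltas, min_delta = 0.05, min_probes = 2L,
                        max_gap = 500L, comparison_id = NULL) {
  stopifnot(min_delta > 0, min_probes >= 1, max_gap >= 0)
  n <- nrow(deltas)
  empty <- tibble(chromosome = character(), start = integer(),
                  end = integer(), n_probes = integer(),
                  direction = character(), mean_delta = double(),
                  mean_abs_delta = double(),
                  comparison_id = character(),
                  probe_ids = list(), deltas = list())
  if (!n) return(empty)
  ord <- order(chrom_order(deltas$chromosome), deltas$position)
  if (!identical(ord, seq_len(n)))
    abort("delta track must be sorted by (chromosome, position)")
  d <- deltas$delta
  q <- !is.na(d) & abs(d) >= min_delta
  if (!any(q)) return(empty)
  same_chrom <- deltas$chromosome[-1] == deltas$chromosome[-n]
  gap_ok <- (deltas$position[-1] - deltas$position[-n]) <= max_gap
  sign_same <- sign(d[-1]) == sign(d[-n])
  joinable <- c(FALSE, q[-1] & q[-n] & same_chrom & gap_ok &
                  !is.na(sign_same) & sign_same)
  run <- cumsum(!joinable)
  member <- which(q)
  run_id <- run[member]
  sizes <- tabulate(match(run_id, unique(run_id)))
  keep_runs <- unique(run_id)[sizes >= min_probes]
  if (!length(keep_runs)) return(empty)
  member <- member[run_id %in% keep_runs]
  run_id <- run[member]
  firsts <- member[!duplicated(run_id)]
  lasts <- member[!duplicated(run_id, fromLast = TRUE)]
  dl <- split(d[member], run_id)
  pid <- split(deltas$probe_id[member], run_id)
  ord_runs <- order(firsts)
  calls <- tibble(
    chromosome = deltas$chromosome[firsts],
    start = deltas$position[firsts],
    end = deltas$position[lasts] + 2L,
    n_probes = lasts - firsts + 1L,
    direction = ifelse(d[firsts] > 0, "gain", "loss"),
    mean_delta = unname(vapply(dl, mean, double(1))),
    mean_abs_delta = unname(vapply(dl, function(x) mean(abs(x)), double(1))),
    comparison_id = comparison_id %||% NA_character_,
    probe_ids = unname(pid),
    deltas = unname(dl))
  calls[ord_runs, ]
}

#' Summarise a set of iiDMR calls
#'
#' @param calls Calls from [call_iidmrs()] for one comparison.
#' @param manifest Probe manifest providing `feature_class` per probe.
#' @return A list: `n_calls`, `n_probes` (member probes) and `by_feature`,
#'   a tibble of member-probe counts per `feature_class`.
#' @export
count_dmr_probes <- function(calls, manifest) {
  probes <- unlist(calls$probe_ids, use.names = FALSE)
  feat <- manifest$feature_class[match(probes, manifest$probe_id)]
  by_feature <- tibble(feature_class = .feature_levels,
                       n_probes = unname(vapply(
                         .feature_levels,
                         function(f) sum(feat == f, na.rm = TRUE),
                         integer(1))))
  list(n_calls = nrow(calls), n_probes = length(probes),
       by_feature = by_feature)
}
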