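# Probe-universe QC: drop multi-mapping probes, probes overlapping known
# SNPs, and probes on the sex chromosomes, mirroring the exclusions used to
# define an analysis set on Illumina-style arrays.

#' Filter the probe universe
#'
#' Keeps probes with `multi_mapped = FALSE`, `snp_overlap = FALSE` and
#' `sex_chromosome = FALSE`. A probe failing several criteria is reported
#' once, under the first reason in the fixed precedence
#' `multi_mapped > snp_overlap > sex_chromosome`; the kept set itself does
#' not depend on the precedence. Input order is preserved.
#'
#' @param manifest A validated probe manifest tibble.
#' @return The kept probes, with the per-reason exclusion report attached as
#'   attribute `"qc_report"` (see [qc_report()]).
#' @examples
#' m <- simulate_cohort(cohort_config(seed = 1, n_probes = 400))$manifest
#' kept <- filter_probes(m)
#' qc_report(kept)
#' @export
filter_probes <- function(manifest) {
  validate_manifest(manifest)
  why <- rep(NA_character_, nrow(manifest))
  why[manifest$sex_chromosome] <- "sex_chromosome"
  why[manifest$snp_overlap] <- "snp_overlap"
  why[manifest$multi_mapped] <- "multi_mapped"
  kept <- manifest[is.na(why), , drop = FALSE]
  if (!nrow(kept))
    abort("probe QC removed every probe; nothing left to analyze")
  report <- tibble(
    reason = c("multi_mapped", "snp_overlap", "sex_chromosome"),
    n_removed = c(sum(why == "multi_mapped", na.rm = TRUE),
                  sum(why == "snp_overlap", na.rm = TRUE),
                  sum(why == "sex_chromosome", na.rm = TRUE)))
  attr(kept, "qc_report") <- report
  kept
}

#' Exclusion report of a QC-filtered manifest
#'
#' @param kept The result of [filter_probes()].
#' @return A tibble with one row per exclusion reason and the count removed.
#' @export
qc_report <- function(kept) {
  rep <- attr(kept, "qc_report")
  if (is.null(rep)) abort("no qc_report attribute; was filter_probes() run?")
  rep
}
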