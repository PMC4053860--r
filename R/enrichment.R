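# Enrichment/depletion of iiDMR probes across genomic features, ES-cell
# chromatin-state quadrants, housekeeping genes, and ageing-associated
# probes.

clopper_pearson <- function(k, n, conf = 0.95) {
  alpha <- 1 - conf
  low <- ifelse(k == 0, 0, qbeta(alpha / 2, k, n - k + 1))
  high <- ifelse(k == n, 1, qbeta(1 - alpha / 2, k + 1, n - k))
  cbind(low = low, high = high)
}

wilson_interval <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  cbind(low = pmax(0, centre - half), high = pmin(1, centre + half))
}

#' iiDMR enrichment across probe categories
#'
#' For each category, reports the fraction of its probes called as iiDMR
#' members with a binomial confidence interval, against the background
#' fraction of iiDMR probes in the whole universe (the "dashed line").
#'
#' @param dmr_probe_ids Character vector of iiDMR member probe ids (must be
#'   a subset of the universe).
#' @param categories A tibble mapping `probe_id` to `category`.
#' @param universe The kept probe universe: a manifest tibble or a
#'   character vector of probe ids.
#' @param conf Interval coverage (default 0.95).
#' @param method `"clopper-pearson"` (exact, default) or `"wilson"`.
#' @return A tibble of class `iidmr_enrichment`: `category`,
#'   `n_category_probes`, `n_dmr_probes_in_category`, `fraction`, `ci_low`,
#'   `ci_high`, `background_fraction`; empty categories are flagged with
#'   `NA` fractions.
#' @export
category_enrichment <- function(dmr_probe_ids, categories, universe,
                                conf = 0.95,
                                method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  if (is.data.frame(universe)) universe <- universe$probe_id
  universe <- unique(universe)
  if (!length(universe)) abort("empty probe universe")
  dmr_probe_ids <- unique(dmr_probe_ids)
  if (!all(dmr_probe_ids %in% universe))
    abort("dmr_probe_ids must be a subset of the universe")
  categories <- categories[categories$probe_id %in% universe, , drop = FALSE]
  background <- length(dmr_probe_ids) / length(universe)
  is_dmr <- categories$probe_id %in% dmr_probe_ids
  out <- categories |>
    mutate(is_dmr = is_dmr) |>
    group_by(.data$category) |>
    summarise(n_category_probes = dplyr::n_distinct(.data$probe_id),
              n_dmr_probes_in_category =
                dplyr::n_distinct(.data$probe_id[.data$is_dmr]),
              .groups = "drop")
  ci_fun <- if (method == "clopper-pearson") clopper_pearson
            else wilson_interval
  ci <- ci_fun(out$n_dmr_probes_in_category, out$n_category_probes, conf)
  out <- out |>
    mutate(fraction = .data$n_dmr_probes_in_category /
             .data$n_category_probes,
           ci_low = ci[, "low"], ci_high = ci[, "high"],
           background_fraction = background)
  empty <- out$n_category_probes == 0
  out$fraction[empty] <- NA_real_
  out$ci_low[empty] <- NA_real_; out$ci_high[empty] <- NA_real_
  structure(out, class = c("iidmr_enrichment", class(out)),
            background_fraction = background, method = method)
}

#' Classify promoters into K4/K27 chromatin-state quadrants
#'
#' A mark is "hi" at a promoter iff its normalized score strictly exceeds
#' the `hi_quantile` quantile of that mark's promoter-wide scores; the
#' four-way state (`K4hi/K27hi`, `K4hi/K27lo`, `K4lo/K27hi`, `K4lo/K27lo`)
#' follows.
#'
#' @param k4,k27 Count tracks (`region_id`, `norm_score`) covering the same
#'   promoter set.
#' @param hi_quantile Quantile cut (default 0.75).
#' @return A tibble: `tss_id`, `k4_score`, `k27_score`, `state`.
#' @export
classify_chromatin_states <- function(k4, k27, hi_quantile = 0.75) {
  joined <- inner_join(
    rename(k4[c("region_id", "norm_score")], k4_score = "norm_score"),
    rename(k27[c("region_id", "norm_score")], k27_score = "norm_score"),
    by = "region_id")
  if (!nrow(joined)) abort("tracks cover disjoint promoter sets")
  if (all(joined$k4_score == 0) || all(joined$k27_score == 0))
    abort("all-zero count track: quantile threshold degenerate")
  cut4 <- quantile(joined$k4_score, hi_quantile, names = FALSE)
  cut27 <- quantile(joined$k27_score, hi_quantile, names = FALSE)
  joined |>
    mutate(state = paste0(ifelse(.data$k4_score > cut4, "K4hi", "K4lo"),
                          "/",
                          ifelse(.data$k27_score > cut27, "K27hi", "K27lo"))) |>
    rename(tss_id = "region_id")
}

#' Housekeeping-gene depletion of iiDMR promoters
#'
#' 2x2 contingency chi-square (no continuity correction by default) of DMR
#' membership against housekeeping membership over a TSS universe, with the
#' depletion direction reported (observed overlap below expectation).
#'
#' @param dmr_tss,housekeeping_tss Character vectors of TSS ids, both
#'   subsets of `universe_tss`.
#' @param universe_tss Character vector of all TSS ids considered.
#' @param correct Continuity correction (default `FALSE`).
#' @return An `iidmr_test`; `estimate` holds observed/expected overlap and
#'   a `depleted` flag.
#' @export
housekeeping_depletion_test <- function(dmr_tss, housekeeping_tss,
                                        universe_tss, correct = FALSE) {
  universe_tss <- unique(universe_tss)
  dmr_tss <- unique(dmr_tss); housekeeping_tss <- unique(housekeeping_tss)
  if (!all(dmr_tss %in% universe_tss) ||
      !all(housekeeping_tss %in% universe_tss))
    abort("both sets must be subsets of the universe")
  is_dmr <- universe_tss %in% dmr_tss
  is_hk <- universe_tss %in% housekeeping_tss
  tab <- table(factor(is_dmr, c(FALSE, TRUE)), factor(is_hk, c(FALSE, TRUE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    abort("degenerate margin in the 2x2 table")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  observed <- sum(is_dmr & is_hk)
  expected <- sum(is_dmr) * sum(is_hk) / length(universe_tss)
  new_iidmr_test(
    statistic_name = "housekeeping 2x2 chi-square (1 df)",
    statistic = unname(ct$statistic), p_value = ct$p.value,
    estimate = list(observed_overlap = observed,
                    expected_overlap = expected,
                    depleted = observed < expected),
    details = as_tibble(as.data.frame(tab)) |>
      setNames(c("is_dmr", "is_housekeeping", "n")))
}

#' Variability of ageing-associated probes versus random controls
#'
#' Takes the `n_top` probes with the highest methylation-ageing correlation
#' as aDMRs (ties at the rank boundary broken by probe id) and `n_control`
#' seeded-random probes from the remainder as controls; collects absolute
#' methylation differences across every pairwise comparison in the study
#' design, and reports the mean with a percentile-bootstrap interval per
#' set.
#'
#' @param age_scores A tibble: `probe_id`, `age_score`.
#' @param beta Wide beta tibble.
#' @param sheet Sample sheet ([comparison_plan()] supplies the pairings).
#' @param manifest Kept probe manifest.
#' @param n_top,n_control Set sizes (both > 0;
#'   `n_top + n_control <= universe`).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed (control sampling + bootstrap).
#' @return A tibble with one row per set (`admr`, `control`): `n_probes`,
#'   `n_values`, `mean_abs_delta`, `ci_low`, `ci_high`.
#' @export
admr_variability_comparison <- function(age_scores, beta, sheet, manifest,
                                        n_top = 500L, n_control = 500L,
                                        n_boot = 1000L, seed = 1L) {
  if (n_top < 1 || n_control < 1) abort("set sizes must be positive")
  scores <- age_scores[age_scores$probe_id %in% manifest$probe_id, ]
  if (n_top + n_control > nrow(scores))
    abort("n_top + n_control exceeds the probe universe")
  ord <- order(-scores$age_score, scores$probe_id)
  top <- scores$probe_id[ord[seq_len(n_top)]]
  rest <- scores$probe_id[ord[-seq_len(n_top)]]
  control <- withr::with_seed(derive_seed(seed, "admr_control"),
                              sample(rest, n_control))
  plan <- comparison_plan(sheet)
  plan <- plan[plan$type %in% c("intra_pair", "inter_pair"), , drop = FALSE]
  if (!nrow(plan)) abort("no pairwise comparisons available")
  abs_deltas <- function(ids) {
    unlist(lapply(seq_len(nrow(plan)), function(i) {
      d <- compute_deltas(beta, plan$sample_a[i], plan$sample_b[i], manifest)
      v <- abs(d$delta[match(ids, d$probe_id)])
      v[!is.na(v)]
    }), use.names = FALSE)
  }
  vals <- list(admr = abs_deltas(top), control = abs_deltas(control))
  withr::with_seed(derive_seed(seed, "admr_boot"), {
    purrr::map_dfr(names(vals), function(s) {
      v <- vals[[s]]
      ci <- boot_mean_ci(v, n_boot)
      tibble(set = s, n_probes = if (s == "admr") n_top else n_control,
             n_values = length(v), mean_abs_delta = mean(v),
             ci_low = ci[1], ci_high = ci[2])
    })
  })
}
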