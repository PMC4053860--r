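# Integration of methylation differences with chromatin and expression:
# promoter windows, nearest-TSS probe assignment, fragment counting over
# probe regions, library-size normalization, Spearman correlation, and the
# binned bootstrap analyses relating methylation differences to H2A.Z and
# expression ratios.

#' Promoter windows around TSS anchors
#'
#' A promoter is the window `[anchor - flank, anchor + flank)` around the
#' strand-aware TSS anchor (interval start for `+`/unknown strand, interval
#' end minus 1 for `-`), clipped at zero.
#'
#' @param tss A tibble of TSS intervals (`chromosome`, `start`, `end`,
#'   optionally `strand`, `name`).
#' @param flank Half-width in bp (default 1000: TSS +/- 1 kb).
#' @return A tibble of promoter intervals carrying the TSS `name`.
#' @export
promoter_window <- function(tss, flank = 1000L) {
  anchor <- tss_anchor(tss)
  tibble(chromosome = tss$chromosome,
         start = pmax(0L, as.integer(anchor - flank)),
         end = as.integer(anchor + flank),
         name = col_or(tss, "name",
                       sprintf("promoter%05d", seq_len(nrow(tss)))),
         strand = col_or(tss, "strand", "+"))
}

tss_anchor <- function(tss) {
  strand <- col_or(tss, "strand", rep("+", nrow(tss)))
  ifelse(strand == "-", tss$end - 1L, tss$start)
}

#' Assign probes to their nearest TSS
#'
#' Each probe maps to the TSS with the nearest strand-aware anchor if and
#' only if the distance is at most `max_distance` bp; ties are broken by
#' the smaller anchor coordinate, then lexicographic TSS id.
#'
#' @param probes A probe manifest (`probe_id`, `chromosome`, `position`).
#' @param tss TSS intervals with a `name` column.
#' @param max_distance Maximum assignment distance (default 1000 bp).
#' @return A tibble: `probe_id`, `tss_id`, `tss_distance` (signed,
#'   probe minus anchor) for assigned probes only.
#' @export
assign_probes_to_tss <- function(probes, tss, max_distance = 1000L) {
  tss <- mutate(tss, anchor = tss_anchor(tss),
                name = col_or(tss, "name",
                              sprintf("tss%05d", seq_len(nrow(tss)))))
  out <- lapply(split(seq_len(nrow(probes)), probes$chromosome),
                function(pi) {
    tc <- tss[tss$chromosome == probes$chromosome[pi[1]], , drop = FALSE]
    if (!nrow(tc)) return(NULL)
    tc <- tc[order(tc$anchor, tc$name), , drop = FALSE]
    tc <- tc[!duplicated(tc$anchor), , drop = FALSE]  # lex-first per anchor
    pos <- probes$position[pi]
    j <- findInterval(pos, tc$anchor)
    left <- pmax(j, 1L)
    right <- pmin(j + 1L, nrow(tc))
    d_left <- abs(pos - tc$anchor[left]); d_left[j < 1] <- Inf
    d_right <- abs(pos - tc$anchor[right]); d_right[j >= nrow(tc)] <- Inf
    pick <- ifelse(d_left <= d_right, left, right)  # tie -> smaller anchor
    dist <- pos - tc$anchor[pick]
    ok <- abs(dist) <= max_distance
    tibble(probe_id = probes$probe_id[pi][ok],
           tss_id = tc$name[pick][ok],
           tss_distance = as.integer(dist[ok]))
  })
  bind_rows(out[!vapply(out, is.null, logical(1))])
}

#' Count fragments overlapping regions
#'
#' Counts, for each region, the number of fragments with at least 1 bp of
#' half-open overlap; a fragment fully containing a region still counts
#' once.
#'
#' @param fragments,regions Interval tibbles (`chromosome`, `start`, `end`,
#'   half-open); `regions` may carry a `name` column used as `region_id`.
#' @return The regions with `region_id` and `raw_count` columns.
#' @export
count_fragments <- function(fragments, regions) {
  region_id <- col_or(regions, "name",
                      sprintf("region%06d", seq_len(nrow(regions))))
  counts <- integer(nrow(regions))
  for (chr in unique(regions$chromosome)) {
    ri <- which(regions$chromosome == chr)
    fi <- which(fragments$chromosome == chr)
    if (!length(fi)) next
    # half-open [start, end) -> 1-based closed [start + 1, end]
    r_ir <- IRanges::IRanges(regions$start[ri] + 1L, regions$end[ri])
    f_ir <- IRanges::IRanges(fragments$start[fi] + 1L, fragments$end[fi])
    counts[ri] <- IRanges::countOverlaps(r_ir, f_ir)
  }
  tibble(region_id = region_id, chromosome = regions$chromosome,
         start = regions$start, end = regions$end, raw_count = counts)
}

#' Library-size normalize a count track
#'
#' @param track A tibble with a `raw_count` column.
#' @param library_total Total fragments in the library (> 0).
#' @param scale Counts-per-`scale` normalization constant (default 1e7).
#' @return The track with a `norm_score` column
#'   (`raw_count * scale / library_total`).
#' @export
normalize_counts <- function(track, library_total, scale = 1e7) {
  if (length(library_total) != 1 || library_total <= 0)
    abort("library_total must be a single positive number")
  mutate(track, norm_score = .data$raw_count * scale / library_total)
}

#' Spearman rank correlation test
#'
#' Mid-rank ties, two-sided p-value from the large-sample approximation;
#' incomplete pairs are dropped.
#'
#' @param x,y Paired numeric vectors (>= 3 complete pairs; a constant
#'   vector is an error).
#' @return An `iidmr_test` with the correlation as `statistic`.
#' @export
spearman_test <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need >= 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    abort("Spearman correlation undefined for a constant vector")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  new_iidmr_test(statistic_name = "Spearman rho",
                 statistic = unname(ct$estimate), p_value = ct$p.value,
                 estimate = list(n = length(x)))
}

#' Binned means with percentile-bootstrap intervals
#'
#' Bins a per-probe response by the methylation difference (bin edges at
#' multiples of `bin_width` covering the observed range) and reports, per
#' bin, the mean response with a percentile bootstrap confidence interval.
#' Bins with fewer than `min_n` observations are flagged and get no
#' interval. Deterministic given `seed`.
#'
#' @param data A tibble holding the delta and response columns.
#' @param response,delta Column names (character) of the response and the
#'   methylation difference.
#' @param bin_width Bin width on the delta axis (default 0.05).
#' @param n_boot Bootstrap resamples per bin (default 1000).
#' @param seed Integer seed.
#' @param conf Interval coverage (default 0.95).
#' @param min_n Minimum bin occupancy for an interval (default 3).
#' @return A tibble of class `iidmr_binned`: `bin_low`, `bin_high`,
#'   `bin_mid`, `n`, `mean`, `ci_low`, `ci_high`, `flagged`.
#' @export
binned_mean_ci <- function(data, response, delta = "delta",
                           bin_width = 0.05, n_boot = 1000L, seed = 1L,
                           conf = 0.95, min_n = 3L) {
  d <- data[[delta]]; y <- data[[response]]
  ok <- complete.cases(d, y)
  d <- d[ok]; y <- y[ok]
  if (!length(d)) abort("no complete (delta, response) observations")
  lo <- floor(min(d) / bin_width) * bin_width
  hi <- ceiling(max(d) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  bin <- findInterval(d, breaks, rightmost.closed = TRUE)
  out <- withr::with_seed(derive_seed(seed, "binned_ci"), {
    purrr::map_dfr(seq_len(length(breaks) - 1), function(b) {
      yy <- y[bin == b]
      nb <- length(yy)
      if (!nb) return(NULL)
      if (nb >= min_n) {
        ci <- boot_mean_ci(yy, n_boot, conf)
      } else ci <- c(NA_real_, NA_real_)
      tibble(bin_low = breaks[b], bin_high = breaks[b + 1],
             bin_mid = (breaks[b] + breaks[b + 1]) / 2,
             n = nb, mean = mean(yy),
             ci_low = ci[1], ci_high = ci[2], flagged = nb < min_n)
    })
  })
  structure(out, class = c("iidmr_binned", class(out)),
            n_boot = as.integer(n_boot), seed = as.integer(seed))
}

#' Binned expression log-ratio series
#'
#' For every probe assigned to a TSS, the response is
#' `log(FPKM_A + eps) - log(FPKM_B + eps)` (individual A relative to B,
#' matching the orientation of the methylation delta); the series is then
#' binned as in [binned_mean_ci()].
#'
#' @param deltas Delta track for the comparison A vs B.
#' @param assignment Probe-to-TSS map from [assign_probes_to_tss()].
#' @param expr_a,expr_b Two-column expression tibbles (`tss_id`, `fpkm`).
#' @param pseudocount `eps` added inside the logs (default 1).
#' @inheritParams binned_mean_ci
#' @return An `iidmr_binned` tibble.
#' @export
expression_ratio_series <- function(deltas, assignment, expr_a, expr_b,
                                    bin_width = 0.05, n_boot = 1000L,
                                    seed = 1L, pseudocount = 1) {
  if (!nrow(assignment)) abort("empty probe-to-TSS assignment")
  df <- deltas |>
    inner_join(assignment, by = "probe_id") |>
    inner_join(rename(expr_a[c("tss_id", "fpkm")], fpkm_a = "fpkm"),
               by = "tss_id") |>
    inner_join(rename(expr_b[c("tss_id", "fpkm")], fpkm_b = "fpkm"),
               by = "tss_id") |>
    mutate(log_ratio = log(.data$fpkm_a + pseudocount) -
             log(.data$fpkm_b + pseudocount))
  binned_mean_ci(df, response = "log_ratio", delta = "delta",
                 bin_width = bin_width, n_boot = n_boot, seed = seed)
}

#' Expression shift of DMR-associated genes
#'
#' One-sided rank-sum (Wilcoxon) test of whether DMR-assigned genes are
#' expressed at lower levels than the remaining genes, plus the fraction of
#' each set below 1 FPKM (the low-expression boundary).
#'
#' @param dmr_tss Character vector of DMR-associated TSS ids (subset of
#'   `all_tss`).
#' @param all_tss Character vector of all assayed TSS ids.
#' @param expr Two-column expression tibble (`tss_id`, `fpkm`).
#' @param pseudocount Added inside the log transform (default 1).
#' @return An `iidmr_test`; `estimate` holds the per-set low-expression
#'   fractions and sizes.
#' @export
expression_shift_test <- function(dmr_tss, all_tss, expr, pseudocount = 1) {
  dmr_tss <- unique(dmr_tss); all_tss <- unique(all_tss)
  if (!length(dmr_tss) || !length(all_tss))
    abort("both TSS sets must be non-empty")
  if (!all(dmr_tss %in% all_tss)) abort("dmr_tss must be a subset of all_tss")
  non_dmr <- setdiff(all_tss, dmr_tss)
  if (!length(non_dmr)) abort("no non-DMR genes left to compare against")
  f <- setNames(expr$fpkm, expr$tss_id)
  x <- log(f[dmr_tss] + pseudocount)
  yv <- log(f[non_dmr] + pseudocount)
  x <- x[!is.na(x)]; yv <- yv[!is.na(yv)]
  if (!length(x) || !length(yv)) abort("no expression values for a set")
  if (sd(c(x, yv)) == 0) {
    p <- 1  # constant expression: no shift detectable
    stat <- NA_real_
  } else {
    wt <- suppressWarnings(wilcox.test(x, yv, alternative = "less",
                                       exact = FALSE))
    p <- wt$p.value; stat <- unname(wt$statistic)
  }
  new_iidmr_test(
    statistic_name = "rank-sum shift, DMR genes lower",
    statistic = stat, p_value = p,
    estimate = list(
      frac_low_dmr = mean(f[dmr_tss] < 1, na.rm = TRUE),
      frac_low_non_dmr = mean(f[non_dmr] < 1, na.rm = TRUE),
      n_dmr = length(x), n_non_dmr = length(yv)))
}
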