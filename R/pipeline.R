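# Orchestration: the pairwise comparison plan of a twin study design and
# the end-to-end pipeline over a (synthetic or supplied) cohort.

#' Pairwise comparison plan for a twin design
#'
#' Enumerates co-twin comparisons (`intra_pair`), cross-pair comparisons of
#' unrelated individuals (`inter_pair`) and within-individual replicate
#' comparisons (`technical`), with deterministic ordering. With
#' `inter_mode = "representative"` (default), one cross-pair comparison is
#' made per unordered pair of twin pairs, using the first individual (by
#' id) of each; the classic five-individual design (two full pairs plus an
#' unpaired co-twin) then yields exactly five pairwise comparisons.
#' `"exhaustive"` enumerates every cross-pair individual pairing.
#'
#' @param sheet Sample sheet.
#' @param inter_mode `"representative"` or `"exhaustive"`.
#' @param platform,time_point Sample selection for the individual-level
#'   comparisons (defaults: dense platform, latest time point).
#' @return A tibble: `comparison_id`, `type`, `individual_a`,
#'   `individual_b`, `sample_a`, `sample_b`.
#' @export
comparison_plan <- function(sheet,
                            inter_mode = c("representative", "exhaustive"),
                            platform = "dense", time_point = NULL) {
  inter_mode <- match.arg(inter_mode)
  validate_sample_sheet(sheet)
  reps <- representative_samples(sheet, platform, time_point)
  sample_of <- setNames(reps$sample_id, reps$individual_id)
  pair_ids <- unique(reps$pair_id)
  members <- lapply(setNames(pair_ids, pair_ids), function(p)
    sort(unique(reps$individual_id[reps$pair_id == p])))

  rows <- list()
  add <- function(type, a, b) {
    rows[[length(rows) + 1L]] <<- tibble(
      comparison_id = paste0(a, "_vs_", b), type = type,
      individual_a = a, individual_b = b,
      sample_a = unname(sample_of[a]), sample_b = unname(sample_of[b]))
  }
  for (p in pair_ids)
    if (length(members[[p]]) == 2)
      add("intra_pair", members[[p]][1], members[[p]][2])
  if (length(pair_ids) >= 2) {
    pp <- utils::combn(pair_ids, 2)
    for (j in seq_len(ncol(pp))) {
      m1 <- members[[pp[1, j]]]; m2 <- members[[pp[2, j]]]
      if (inter_mode == "representative") {
        add("inter_pair", m1[1], m2[1])
      } else {
        for (a in m1) for (b in m2) add("inter_pair", a, b)
      }
    }
  }
  sub <- sheet[sheet$platform == platform, , drop = FALSE]
  tp <- time_point %||% max(sub$time_point)
  sub <- sub[sub$time_point == tp, , drop = FALSE]
  for (ind in unique(sub$individual_id)) {
    s <- sort(sub$sample_id[sub$individual_id == ind])
    if (length(s) >= 2) {
      cmb <- utils::combn(s, 2)
      for (j in seq_len(ncol(cmb)))
        rows[[length(rows) + 1L]] <- tibble(
          comparison_id = paste0(cmb[1, j], "_vs_", cmb[2, j]),
          type = "technical", individual_a = ind, individual_b = ind,
          sample_a = cmb[1, j], sample_b = cmb[2, j])
    }
  }
  bind_rows(rows)
}

#' Pipeline configuration
#'
#' Bundles the cohort (or input paths), the caller and test parameters and
#' the stage toggles; one global seed from which every stage seed derives
#' deterministically.
#'
#' @param outdir Output directory for stage results.
#' @param seed Global seed.
#' @param cohort_cfg A [cohort_config()] for the simulated cohort.
#' @param min_delta,min_probes,max_gap iiDMR caller parameters.
#' @param temporal_threshold Strict selection threshold for the temporal
#'   direction test.
#' @param bin_width,n_boot,n_perm,hi_quantile,n_pair_perm Stage parameters.
#' @param stages Character vector of stages to run (subset of
#'   `c("qc", "dmr", "variability", "temporal", "integration",
#'   "enrichment")`).
#' @return A validated list of class `iidmr_pipeline_config`.
#' @export
pipeline_config <- function(outdir = tempfile("iidmr_run_"), seed = 1L,
                            cohort_cfg = NULL,
                            min_delta = 0.05, min_probes = 2L,
                            max_gap = 500L, temporal_threshold = 0.05,
                            bin_width = 0.05, n_boot = 1000L,
                            n_perm = 1000L, hi_quantile = 0.75,
                            n_pair_perm = 20L,
                            stages = c("qc", "dmr", "variability",
                                       "temporal", "integration",
                                       "enrichment")) {
  stopifnot(min_delta > 0, min_probes >= 1, max_gap >= 0, bin_width > 0,
            n_boot >= 1, n_perm >= 1, hi_quantile > 0, hi_quantile < 1)
  bad <- setdiff(stages, c("qc", "dmr", "variability", "temporal",
                           "integration", "enrichment"))
  if (length(bad)) abort(paste("unknown stage(s):", paste(bad, collapse = ", ")))
  structure(list(outdir = outdir, seed = as.integer(seed),
                 cohort_cfg = cohort_cfg %||% cohort_config(seed = seed),
                 min_delta = min_delta, min_probes = as.integer(min_probes),
                 max_gap = as.integer(max_gap),
                 temporal_threshold = temporal_threshold,
                 bin_width = bin_width, n_boot = as.integer(n_boot),
                 n_perm = as.integer(n_perm), hi_quantile = hi_quantile,
                 n_pair_perm = as.integer(n_pair_perm), stages = stages),
            class = "iidmr_pipeline_config")
}

#' Run the full iiDMR pipeline on a synthetic cohort
#'
#' Simulates (or accepts) a cohort, then runs probe QC, iiDMR calling over
#' the comparison plan, the biological-vs-technical permutation test, the
#' RMS variability profile, the cross-platform temporal direction test, the
#' methylation/H2A.Z/expression integration analyses, and the enrichment
#' analyses. Stage outputs are written as TSV/BED under `config$outdir`
#' with a machine-readable `summary.json`; any stage error aborts with the
#' stage name and leaves a `FAILED_<stage>` marker.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optionally a pre-built [simulate_cohort()] result;
#'   otherwise simulated from `config$cohort_cfg`.
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  stopifnot(inherits(config, "iidmr_pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(parameters = config[setdiff(names(config),
                                              c("cohort_cfg", "outdir"))])
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      file.create(file.path(config$outdir, paste0("FAILED_", name)))
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  cohort <- cohort %||% simulate_cohort(config$cohort_cfg)
  kept <- cohort$manifest

  if ("qc" %in% config$stages) run_stage("qc", function() {
    kept <<- filter_probes(cohort$manifest)
    readr::write_tsv(qc_report(kept), file.path(config$outdir, "qc_report.tsv"))
  })

  plan <- comparison_plan(cohort$sheet)
  calls_by_comparison <- list()
  if ("dmr" %in% config$stages) run_stage("dmr", function() {
    pairwise <- plan[plan$type != "technical", , drop = FALSE]
    for (i in seq_len(nrow(pairwise))) {
      d <- compute_deltas(cohort$beta$dense, pairwise$sample_a[i],
                          pairwise$sample_b[i], kept)
      calls <- call_iidmrs(d, config$min_delta, config$min_probes,
                           config$max_gap,
                           comparison_id = pairwise$comparison_id[i])
      calls_by_comparison[[pairwise$comparison_id[i]]] <<- calls
      write_dmr_bed(calls, file.path(
        config$outdir, paste0("dmrs_", pairwise$comparison_id[i], ".bed")))
    }
    tab <- purrr::map_dfr(names(calls_by_comparison), function(id) {
      cc <- count_dmr_probes(calls_by_comparison[[id]], kept)
      tibble(comparison_id = id,
             type = pairwise$type[pairwise$comparison_id == id],
             n_dmrs = cc$n_calls, n_probes = cc$n_probes)
    })
    readr::write_tsv(tab, file.path(config$outdir, "dmr_counts.tsv"))
    summary$dmr_counts <<- tab
  })

  if ("variability" %in% config$stages) run_stage("variability", function() {
    prof <- rms_profile(cohort$beta$dense, cohort$sheet,
                        n_pair_perm = config$n_pair_perm,
                        seed = derive_seed(config$seed, "rms"))
    readr::write_tsv(prof, file.path(config$outdir, "rms_profile.tsv"))
    summary$rms <<- list(mean_rms_intra = mean(prof$rms_intra),
                         mean_rms_inter = mean(prof$rms_inter))
    tvb <- technical_vs_biological_test(
      cohort$beta$dense, cohort$sheet, kept,
      min_delta = config$min_delta, min_probes = config$min_probes,
      max_gap = config$max_gap, n_perm = config$n_perm,
      seed = derive_seed(config$seed, "tvb"))
    summary$technical_vs_biological <<- as.list(tidy(tvb))
  })

  if ("temporal" %in% config$stages) run_stage("temporal", function() {
    common <- match_platforms(kept, cohort$sparse_manifest)
    common_manifest <- kept[kept$probe_id %in% common, , drop = FALSE]
    intra <- plan[plan$type == "intra_pair", , drop = FALSE]
    sparse_of <- function(ind) {
      s <- cohort$sheet
      s$sample_id[s$individual_id == ind & s$platform == "sparse"][1]
    }
    d2 <- list(); d1 <- list()
    for (i in seq_len(nrow(intra))) {
      d2[[i]] <- compute_deltas(cohort$beta$dense, intra$sample_a[i],
                                intra$sample_b[i], common_manifest)
      d1[[i]] <- compute_deltas(cohort$beta$sparse,
                                sparse_of(intra$individual_a[i]),
                                sparse_of(intra$individual_b[i]),
                                common_manifest)
      d2[[i]]$probe_id <- paste0(intra$comparison_id[i], ":", d2[[i]]$probe_id)
      d1[[i]]$probe_id <- paste0(intra$comparison_id[i], ":", d1[[i]]$probe_id)
    }
    res <- direction_consistency_test(bind_rows(d2), bind_rows(d1),
                                      threshold = config$temporal_threshold)
    readr::write_tsv(res$details, file.path(config$outdir,
                                            "temporal_tally.tsv"))
    summary$temporal <<- c(as.list(tidy(res)), res$estimate)
  })

  expr <- simulate_expression(cohort)
  if ("integration" %in% config$stages) run_stage("integration", function() {
    ind1 <- cohort$individuals$individual_id[1]
    h2az <- simulate_chip_counts(cohort, "H2A.Z", individual = ind1)
    assignment <- assign_probes_to_tss(kept, cohort$tss)
    prom_meth <- kept |>
      inner_join(assignment, by = "probe_id") |>
      inner_join(tibble(probe_id = cohort$beta$dense$probe_id,
                        beta = cohort$beta$dense[[
                          representative_samples(cohort$sheet)$sample_id[1]]]),
                 by = "probe_id") |>
      inner_join(rename(h2az[c("region_id", "norm_score")],
                        probe_id = "region_id"), by = "probe_id") |>
      group_by(.data$tss_id) |>
      summarise(meth = mean(.data$beta, na.rm = TRUE),
                h2az = mean(.data$norm_score), .groups = "drop") |>
      inner_join(tibble(tss_id = expr$tss_id, fpkm = expr[[ind1]]),
                 by = "tss_id")
    summary$correlations <<- list(
      meth_vs_h2az = tidy(spearman_test(prom_meth$meth, prom_meth$h2az)),
      h2az_vs_expression = tidy(spearman_test(prom_meth$h2az,
                                              log(prom_meth$fpkm + 1))),
      meth_vs_expression = tidy(spearman_test(prom_meth$meth,
                                              log(prom_meth$fpkm + 1))))
    readr::write_tsv(prom_meth, file.path(config$outdir,
                                          "promoter_integration.tsv"))
    dmr_tss <- unique(assignment$tss_id[
      assignment$probe_id %in%
        unlist(purrr::map(calls_by_comparison, "probe_ids"))])
    if (length(dmr_tss) && length(dmr_tss) < nrow(expr)) {
      shift <- expression_shift_test(
        dmr_tss, expr$tss_id,
        tibble(tss_id = expr$tss_id, fpkm = expr[[ind1]]))
      summary$expression_shift <<- c(as.list(tidy(shift)), shift$estimate)
    }
  })

  if ("enrichment" %in% config$stages) run_stage("enrichment", function() {
    dmr_probes <- unique(unlist(purrr::map(calls_by_comparison,
                                           "probe_ids")))
    if (!length(dmr_probes)) {
      summary$enrichment <<- list(note = "no iiDMR calls; enrichment skipped")
      return(invisible())
    }
    feat <- category_enrichment(
      dmr_probes, tibble(probe_id = kept$probe_id,
                         category = kept$feature_class), kept)
    readr::write_tsv(feat, file.path(config$outdir,
                                     "feature_enrichment.tsv"))
    k4 <- simulate_chip_counts(cohort, "H3K4me3")
    k27 <- simulate_chip_counts(cohort, "H3K27me3")
    states <- classify_chromatin_states(k4, k27, config$hi_quantile)
    prom_map <- kept |>
      filter(!is.na(.data$nearest_tss_id)) |>
      inner_join(rename(states[c("tss_id", "state")],
                        nearest_tss_id = "tss_id"), by = "nearest_tss_id")
    state_enr <- category_enrichment(
      intersect(dmr_probes, prom_map$probe_id),
      tibble(probe_id = prom_map$probe_id, category = prom_map$state),
      prom_map$probe_id)
    readr::write_tsv(state_enr, file.path(config$outdir,
                                          "state_enrichment.tsv"))
    summary$enrichment <<- list(feature = feat, chromatin_state = state_enr)
  })

  summary_path <- file.path(config$outdir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE, pretty = TRUE)
  invisible(summary)
}
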