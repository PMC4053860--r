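# Synthetic monozygotic-twin cohort generator.
#
# Emulates the statistical structure the downstream analyses assume: a
# 450K-like probe grid laid out in CpG-island-like clusters, bimodal
# baseline methylation, co-twin-shared pair effects, individual-specific
# planted epialleles (contiguous 2-5 probe runs at intermediate-methylation
# promoters, preferentially at lowly expressed / K4lo promoters), temporal
# persistence to a second time point, a promoter-biased sparse (27K-like)
# platform subset, technical replicates, H2A.Z counts anti-correlated with
# promoter methylation, tiered FPKM expression and ES-cell-like K4/K27
# chromatin states. Identical configuration (including seed) gives
# bit-identical output; each component draws from its own derived seed.

#' Configuration for the synthetic twin cohort
#'
#' Defaults encode the stated simulation world: 20,000 probes in clusters of
#' 8 spaced 100 bp (inter-cluster gap 2 kb), 5 twin pairs with triplicate
#' technical replicates for the first two pairs, bimodal baseline beta at
#' 0.15/0.85, per-measurement technical noise sd 0.015 on the beta scale,
#' epialleles planted at 5% of promoters with beta shift 0.15 over 2-5
#' consecutive probes (90% at low-expression promoters), 80% persisting to
#' the second time point, pair-shared genetic shifts of sd 0.05 at 5% of
#' loci, and a target methylation-H2A.Z rank correlation of -0.6.
#'
#' @param seed Integer seed; every component derives its own sub-seed.
#' @param n_probes,n_pairs Cohort size.
#' @param n_tech_replicates Technical replicates per individual of the first
#'   `tech_rep_pairs` pairs (dense platform, time point 2).
#' @param tech_rep_pairs Number of pairs profiled in replicate.
#' @param cgi_cluster_size,probe_spacing_bp,cgi_spacing_bp Probe layout:
#'   probes per cluster, spacing within a cluster (<= 200 bp), gap between
#'   clusters.
#' @param baseline_beta_modes Unmethylated/methylated baseline modes.
#' @param cluster_baseline_sd Per-cluster (promoter-level) baseline spread
#'   around the mode.
#' @param baseline_jitter_sd Per-probe jitter around the cluster baseline.
#' @param tech_noise_sd Per-measurement beta-scale noise sd (> 0); applied
#'   on the logit scale with a slope correction so the realized beta-scale
#'   sd approximates this value at any methylation level.
#' @param missing_rate Per-cell missingness rate.
#' @param multi_mapped_rate,snp_overlap_rate,sex_chromosome_rate Mask-flag
#'   rates (the last is the fraction of clusters placed on chrX).
#' @param promoter_fraction Fraction of clusters annotated as promoters.
#' @param epiallele_rate Fraction of eligible (autosomal promoter) clusters
#'   carrying a planted epiallele.
#' @param epiallele_delta Planted beta shift (> 0).
#' @param epiallele_run_range Run length range (consecutive probes).
#' @param temporal_stability Probability a planted epiallele persists to
#'   time point 2.
#' @param genetic_rate,genetic_delta Fraction of clusters with pair-shared
#'   shifts, and the sd of those shifts.
#' @param meth_chip_coupling Target Spearman correlation between promoter
#'   methylation and H2A.Z counts (<= 0).
#' @param lowexpr_targeting Probability a planted epiallele lands at a
#'   low-expression (K4lo) promoter.
#' @param variability_mode `"owner"` (default): each epiallele is owned by
#'   one individual with a fixed shift of `epiallele_delta`. `"cohort"`:
#'   every individual draws an independent deviation with sd
#'   `epiallele_delta / sqrt(2)` at planted loci, so the intra-pair
#'   difference SD equals `epiallele_delta` cohort-wide.
#' @param chip_mean,chip_dispersion,chip_probe_corr H2A.Z count model:
#'   negative-binomial mean and dispersion, and the latent probe-to-promoter
#'   correlation.
#' @param mark_mean_hi,mark_mean_lo K4/K27 count means for hi/lo promoters.
#' @param expr_low_meanlog,expr_low_sdlog,expr_high_meanlog,expr_high_sdlog
#'   Log-normal FPKM parameters per expression tier (low tier truncated to
#'   (0, 1), high tier to [1, Inf); the 1-FPKM boundary is the low/high
#'   expression cutoff).
#' @param expr_coupling Slope of log-FPKM on an individual's methylation
#'   deviation at the promoter (default 0: no methylation-expression
#'   coupling, matching the negligible correlation observed in CD14+ data).
#' @param p_low_given_meth,p_low_given_unmeth Probability a promoter is
#'   low-expression given its baseline methylation mode.
#' @param p_bivalent_given_high Probability a high-expression (K4hi)
#'   promoter is bivalent (K4hi/K27hi).
#' @param p_k27_given_low Probability a low-expression (K4lo) promoter is
#'   K27hi; the default makes 25% of promoters hi for each mark, matching
#'   the 0.75 hi-quantile classification rule.
#' @return A validated list of class `iidmr_config`.
#' @export
cohort_config <- function(seed = 1L,
                          n_probes = 20000L,
                          n_pairs = 5L,
                          n_tech_replicates = 3L,
                          tech_rep_pairs = 2L,
                          cgi_cluster_size = 8L,
                          probe_spacing_bp = 100L,
                          cgi_spacing_bp = 2000L,
                          baseline_beta_modes = c(0.15, 0.85),
                          cluster_baseline_sd = 0.05,
                          baseline_jitter_sd = 0.02,
                          tech_noise_sd = 0.015,
                          missing_rate = 0.002,
                          multi_mapped_rate = 0.01,
                          snp_overlap_rate = 0.02,
                          sex_chromosome_rate = 0.02,
                          promoter_fraction = 0.5,
                          epiallele_rate = 0.05,
                          epiallele_delta = 0.15,
                          epiallele_run_range = c(2L, 5L),
                          temporal_stability = 0.8,
                          genetic_rate = 0.05,
                          genetic_delta = 0.05,
                          meth_chip_coupling = -0.6,
                          lowexpr_targeting = 0.9,
                          variability_mode = c("owner", "cohort"),
                          chip_mean = 50,
                          chip_dispersion = 0.2,
                          chip_probe_corr = 0.9,
                          mark_mean_hi = 100,
                          mark_mean_lo = 5,
                          expr_low_meanlog = log(0.25),
                          expr_low_sdlog = 0.5,
                          expr_high_meanlog = log(8),
                          expr_high_sdlog = 0.6,
                          expr_coupling = 0,
                          p_low_given_meth = 0.95,
                          p_low_given_unmeth = 0.55,
                          p_bivalent_given_high = 0.15,
                          p_k27_given_low = 0.2833) {
  cfg <- list(seed = as.integer(seed), n_probes = as.integer(n_probes),
              n_pairs = as.integer(n_pairs),
              n_tech_replicates = as.integer(n_tech_replicates),
              tech_rep_pairs = as.integer(tech_rep_pairs),
              cgi_cluster_size = as.integer(cgi_cluster_size),
              probe_spacing_bp = as.integer(probe_spacing_bp),
              cgi_spacing_bp = as.integer(cgi_spacing_bp),
              baseline_beta_modes = baseline_beta_modes,
              cluster_baseline_sd = cluster_baseline_sd,
              baseline_jitter_sd = baseline_jitter_sd,
              tech_noise_sd = tech_noise_sd,
              missing_rate = missing_rate,
              multi_mapped_rate = multi_mapped_rate,
              snp_overlap_rate = snp_overlap_rate,
              sex_chromosome_rate = sex_chromosome_rate,
              promoter_fraction = promoter_fraction,
              epiallele_rate = epiallele_rate,
              epiallele_delta = epiallele_delta,
              epiallele_run_range = as.integer(epiallele_run_range),
              temporal_stability = temporal_stability,
              genetic_rate = genetic_rate,
              genetic_delta = genetic_delta,
              meth_chip_coupling = meth_chip_coupling,
              lowexpr_targeting = lowexpr_targeting,
              variability_mode = match.arg(variability_mode),
              chip_mean = chip_mean,
              chip_dispersion = chip_dispersion,
              chip_probe_corr = chip_probe_corr,
              mark_mean_hi = mark_mean_hi,
              mark_mean_lo = mark_mean_lo,
              expr_low_meanlog = expr_low_meanlog,
              expr_low_sdlog = expr_low_sdlog,
              expr_high_meanlog = expr_high_meanlog,
              expr_high_sdlog = expr_high_sdlog,
              expr_coupling = expr_coupling,
              p_low_given_meth = p_low_given_meth,
              p_low_given_unmeth = p_low_given_unmeth,
              p_bivalent_given_high = p_bivalent_given_high,
              p_k27_given_low = p_k27_given_low)
  rates <- c(cfg$missing_rate, cfg$multi_mapped_rate, cfg$snp_overlap_rate,
             cfg$sex_chromosome_rate, cfg$promoter_fraction,
             cfg$epiallele_rate, cfg$temporal_stability, cfg$genetic_rate,
             cfg$lowexpr_targeting, cfg$p_low_given_meth,
             cfg$p_low_given_unmeth, cfg$p_bivalent_given_high,
             cfg$p_k27_given_low)
  if (any(rates < 0 | rates > 1)) abort("all rates must lie in [0, 1]")
  if (cfg$tech_noise_sd <= 0) abort("tech_noise_sd must be > 0")
  if (cfg$epiallele_delta <= 0) abort("epiallele_delta must be > 0")
  if (cfg$meth_chip_coupling > 0)
    abort("meth_chip_coupling must be <= 0 (anti-correlation)")
  if (cfg$n_pairs < 1 || cfg$n_probes < cfg$cgi_cluster_size)
    abort("cohort too small")
  if (cfg$probe_spacing_bp > 200)
    abort("probe_spacing_bp must be <= 200 (CGI-like clustering)")
  structure(cfg, class = "iidmr_config")
}

# Beta-scale noise applied on the logit scale: slope correction keeps the
# realized beta-scale sd ~ sd at any mean, with no boundary truncation.
squash_noise <- function(mu, sd, z) {
  plogis(qlogis(mu) + z * sd / (mu * (1 - mu)))
}

#' Simulate a complete twin cohort
#'
#' Generates the manifest, sample sheet, beta matrices (dense platform at
#' time point 2 with technical replicates; sparse promoter-biased platform
#' at time point 1) and the ground-truth table for a synthetic monozygotic
#' twin cohort. Epialleles are planted at time point 1 and persist to time
#' point 2 with probability `temporal_stability`.
#'
#' @param config A configuration from [cohort_config()].
#' @return A list of class `iidmr_cohort`: `manifest`, `sheet`, `beta`
#'   (named list `dense`, `sparse` of wide beta tibbles), `tss` (promoter
#'   TSS intervals), `truth` (list: `epialleles`, `promoters`, `genetic`,
#'   `clusters`), `mu` (underlying per-individual methylation means), and
#'   `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "iidmr_config"))
  cfg <- config

  ## ---- probe layout -----------------------------------------------------
  layout <- withr::with_seed(derive_seed(cfg$seed, "layout"), {
    n_clusters <- ceiling(cfg$n_probes / cfg$cgi_cluster_size)
    sizes <- rep(cfg$cgi_cluster_size, n_clusters)
    sizes[n_clusters] <- cfg$n_probes - sum(sizes[-n_clusters])
    on_x <- runif(n_clusters) < cfg$sex_chromosome_rate
    block <- ceiling(seq_len(n_clusters) / (n_clusters / 5))
    chrom <- paste0("chr", pmin(block, 5))
    chrom[on_x] <- "chrX"
    p_other <- 1 - cfg$promoter_fraction
    feature <- sample(.feature_levels, n_clusters, replace = TRUE,
                      prob = c(cfg$promoter_fraction,
                               p_other * c(0.2, 0.2, 0.3, 0.3)))
    cluster_id <- seq_len(n_clusters)
    probes <- tibble(
      cluster_id = rep(cluster_id, sizes),
      within = unlist(lapply(sizes, seq_len), use.names = FALSE))
    probes$chromosome <- chrom[probes$cluster_id]
    span <- cfg$cgi_cluster_size * cfg$probe_spacing_bp + cfg$cgi_spacing_bp
    idx_in_chrom <- stats::ave(probes$cluster_id, probes$chromosome,
                               FUN = function(x) match(x, unique(x)))
    probes$position <- as.integer(
      (idx_in_chrom - 1) * span + (probes$within - 1) * cfg$probe_spacing_bp)
    probes$probe_id <- sprintf("cg%07d", seq_len(nrow(probes)))
    probes$feature_class <- feature[probes$cluster_id]
    probes$multi_mapped <- runif(nrow(probes)) < cfg$multi_mapped_rate
    probes$snp_overlap <- runif(nrow(probes)) < cfg$snp_overlap_rate
    probes$sex_chromosome <- probes$chromosome %in% c("chrX", "chrY")
    sz <- sizes[probes$cluster_id]
    edge <- probes$within == 1L | probes$within == sz
    probes$cgi_relation <- ifelse(
      probes$feature_class %in% c("promoter", "regulatory", "exon"),
      ifelse(edge, "shore", "island"), "open_sea")
    list(probes = probes, feature = feature, sizes = sizes,
         n_clusters = n_clusters)
  })
  probes <- layout$probes
  n_clusters <- layout$n_clusters
  promoter_clusters <- which(layout$feature == "promoter")

  ## promoter anchors: position of the middle probe of each promoter cluster
  anchor <- vapply(promoter_clusters, function(cl) {
    pos <- probes$position[probes$cluster_id == cl]
    pos[ceiling(length(pos) / 2)]
  }, double(1))
  tss_id <- sprintf("TSS%05d", promoter_clusters)
  tss_of_cluster <- setNames(rep(NA_character_, n_clusters),
                             seq_len(n_clusters))
  tss_of_cluster[promoter_clusters] <- tss_id
  anchor_of_cluster <- setNames(rep(NA_real_, n_clusters),
                                seq_len(n_clusters))
  anchor_of_cluster[promoter_clusters] <- anchor

  probes$nearest_tss_id <- tss_of_cluster[probes$cluster_id]
  probes$tss_distance <- as.integer(
    probes$position - anchor_of_cluster[probes$cluster_id])
  probes$tss_distance[is.na(probes$nearest_tss_id)] <- NA_integer_

  ## ---- promoter truth: methylation mode, expression tier, chromatin state
  prom <- withr::with_seed(derive_seed(cfg$seed, "promoter_truth"), {
    meth_mode <- runif(length(promoter_clusters)) < 0.5
    p_low <- ifelse(meth_mode, cfg$p_low_given_meth, cfg$p_low_given_unmeth)
    tier <- ifelse(runif(length(p_low)) < p_low, "low", "high")
    state <- ifelse(
      tier == "high",
      ifelse(runif(length(tier)) < cfg$p_bivalent_given_high,
             "K4hi/K27hi", "K4hi/K27lo"),
      ifelse(runif(length(tier)) < cfg$p_k27_given_low,
             "K4lo/K27hi", "K4lo/K27lo"))
    tibble(tss_id = tss_id, cluster_id = promoter_clusters,
           chromosome = layout$probes$chromosome[
             match(promoter_clusters, layout$probes$cluster_id)],
           anchor = as.integer(anchor), strand = "+",
           meth_mode = ifelse(meth_mode, "methylated", "unmethylated"),
           tier = tier, state = state)
  })

  ## ---- planted epialleles ----------------------------------------------
  individuals <- sprintf("ind%02d%d", rep(seq_len(cfg$n_pairs), each = 2),
                         rep(1:2, cfg$n_pairs))
  pair_of <- rep(sprintf("P%02d", seq_len(cfg$n_pairs)), each = 2)
  eligible <- prom$cluster_id[!prom$chromosome %in% c("chrX", "chrY")]
  n_epi <- round(cfg$epiallele_rate * length(eligible))
  if (cfg$epiallele_rate > 0 && n_epi < 1)
    n_epi <- 1L
  if (n_epi > length(eligible))
    abort("n_probes too small to host the requested epialleles")

  epi <- withr::with_seed(derive_seed(cfg$seed, "epialleles"), {
    if (n_epi == 0) {
      list(table = tibble(epiallele_id = character(), probe_id = character(),
                          cluster_id = integer(), tss_id = character(),
                          individual_id = character(), direction = integer(),
                          delta = double(), persists_t2 = logical()),
           clusters = integer(0), dev = NULL)
    } else {
      tier_of <- prom$tier[match(eligible, prom$cluster_id)]
      want_low <- runif(n_epi) < cfg$lowexpr_targeting
      pool_low <- sample(eligible[tier_of == "low"])
      pool_high <- sample(eligible[tier_of == "high"])
      chosen <- integer(n_epi)
      i_low <- i_high <- 0L
      for (i in seq_len(n_epi)) {
        take_low <- if (want_low[i]) i_low < length(pool_low)
                    else i_high >= length(pool_high)
        if (take_low) {
          i_low <- i_low + 1L; chosen[i] <- pool_low[i_low]
        } else {
          i_high <- i_high + 1L; chosen[i] <- pool_high[i_high]
        }
      }
      rows <- lapply(seq_len(n_epi), function(i) {
        cl <- chosen[i]
        ids <- probes$probe_id[probes$cluster_id == cl]
        len <- sample(seq(cfg$epiallele_run_range[1],
                          min(cfg$epiallele_run_range[2], length(ids))), 1)
        start <- sample(length(ids) - len + 1L, 1)
        run <- ids[start:(start + len - 1L)]
        tibble(epiallele_id = sprintf("epi%04d", i),
               probe_id = run,
               cluster_id = cl,
               tss_id = tss_of_cluster[[cl]],
               individual_id = sample(individuals, 1),
               direction = sample(c(-1L, 1L), 1),
               delta = cfg$epiallele_delta,
               persists_t2 = runif(1) < cfg$temporal_stability)
      })
      table <- dplyr::bind_rows(rows)
      dev <- NULL
      if (cfg$variability_mode == "cohort") {
        dev <- matrix(rnorm(nrow(table) * length(individuals), 0,
                            cfg$epiallele_delta / sqrt(2)),
                      nrow = nrow(table),
                      dimnames = list(table$probe_id, individuals))
      }
      list(table = table, clusters = chosen, dev = dev)
    }
  })

  ## ---- pair-shared (genetic) shifts ------------------------------------
  genetic <- withr::with_seed(derive_seed(cfg$seed, "genetic"), {
    candidates <- setdiff(which(!layout$feature %in% "none"), epi$clusters)
    candidates <- candidates[!probes$chromosome[
      match(candidates, probes$cluster_id)] %in% c("chrX", "chrY")]
    gen_cl <- candidates[runif(length(candidates)) < cfg$genetic_rate]
    if (!length(gen_cl) || cfg$genetic_delta == 0) {
      tibble(cluster_id = integer(), pair_id = character(), shift = double())
    } else {
      tidyr::expand_grid(cluster_id = gen_cl,
                         pair_id = sprintf("P%02d", seq_len(cfg$n_pairs))) |>
        mutate(shift = rnorm(dplyr::n(), 0, cfg$genetic_delta))
    }
  })

  ## ---- baseline and per-individual means -------------------------------
  baseline <- withr::with_seed(derive_seed(cfg$seed, "baseline"), {
    meth_of_cluster <- rep(NA, n_clusters)
    meth_of_cluster[prom$cluster_id] <- prom$meth_mode == "methylated"
    other <- which(is.na(meth_of_cluster))
    meth_of_cluster[other] <- runif(length(other)) < 0.5
    mode_val <- ifelse(meth_of_cluster[probes$cluster_id],
                       cfg$baseline_beta_modes[2], cfg$baseline_beta_modes[1])
    cl_eff <- rnorm(n_clusters, 0, cfg$cluster_baseline_sd)
    b <- pmin(0.95, pmax(0.05, mode_val + cl_eff[probes$cluster_id] +
                           rnorm(nrow(probes), 0, cfg$baseline_jitter_sd)))
    planted <- probes$cluster_id %in% epi$clusters
    b[planted] <- runif(sum(planted), 0.35, 0.65)
    b
  })

  n_ind <- length(individuals)
  mu1 <- matrix(baseline, nrow(probes), n_ind,
                dimnames = list(probes$probe_id, individuals))
  if (nrow(genetic)) {
    for (i in seq_len(n_ind)) {
      g <- genetic[genetic$pair_id == pair_of[i], ]
      idx <- probes$cluster_id %in% g$cluster_id
      mu1[idx, i] <- mu1[idx, i] +
        g$shift[match(probes$cluster_id[idx], g$cluster_id)]
    }
  }
  mu2 <- mu1
  if (nrow(epi$table)) {
    if (cfg$variability_mode == "owner") {
      rows <- match(epi$table$probe_id, probes$probe_id)
      cols <- match(epi$table$individual_id, individuals)
      shift <- epi$table$direction * epi$table$delta
      mu1[cbind(rows, cols)] <- mu1[cbind(rows, cols)] + shift
      keep2 <- epi$table$persists_t2
      mu2[cbind(rows[keep2], cols[keep2])] <-
        mu2[cbind(rows[keep2], cols[keep2])] + shift[keep2]
    } else {
      rows <- match(rownames(epi$dev), probes$probe_id)
      mu1[rows, ] <- mu1[rows, ] + epi$dev
      mu2[rows, ] <- mu2[rows, ] + epi$dev
    }
  }
  mu1 <- pmax(pmin(mu1, 0.98), 0.02)
  mu2 <- pmax(pmin(mu2, 0.98), 0.02)

  ## ---- sample sheet -----------------------------------------------------
  reps <- ifelse(rep(seq_len(cfg$n_pairs), each = 2) <= cfg$tech_rep_pairs,
                 cfg$n_tech_replicates, 1L)
  dense_rows <- tibble(
    individual_id = rep(individuals, reps),
    pair_id = rep(pair_of, reps),
    replicate_id = unlist(lapply(reps, function(r) sprintf("r%d", seq_len(r))),
                          use.names = FALSE),
    time_point = 2L, platform = "dense")
  sparse_rows <- tibble(individual_id = individuals, pair_id = pair_of,
                        replicate_id = "r1", time_point = 1L,
                        platform = "sparse")
  sheet <- bind_rows(dense_rows, sparse_rows) |>
    mutate(sample_id = sprintf("%s_t%d_%s_%s", .data$individual_id,
                               .data$time_point, .data$replicate_id,
                               .data$platform)) |>
    select("sample_id", "individual_id", "pair_id", "replicate_id",
           "time_point", "platform")

  ## ---- measured beta values --------------------------------------------
  sparse_idx <- probes$feature_class == "promoter" |
    (seq_len(nrow(probes)) %% 13L == 0L)
  betas <- withr::with_seed(derive_seed(cfg$seed, "measurement"), {
    measure <- function(mu_col, n) {
      z <- rnorm(n)
      b <- squash_noise(mu_col, cfg$tech_noise_sd, z)
      if (cfg$missing_rate > 0)
        b[runif(n) < cfg$missing_rate] <- NA_real_
      b
    }
    dense <- tibble(probe_id = probes$probe_id)
    for (k in which(sheet$platform == "dense")) {
      mu_col <- mu2[, sheet$individual_id[k]]
      dense[[sheet$sample_id[k]]] <- measure(mu_col, nrow(probes))
    }
    sparse <- tibble(probe_id = probes$probe_id[sparse_idx])
    for (k in which(sheet$platform == "sparse")) {
      mu_col <- mu1[sparse_idx, sheet$individual_id[k]]
      sparse[[sheet$sample_id[k]]] <- measure(mu_col, sum(sparse_idx))
    }
    list(dense = dense, sparse = sparse)
  })

  manifest <- probes |>
    select("probe_id", "chromosome", "position", "multi_mapped",
           "snp_overlap", "sex_chromosome", "feature_class", "cgi_relation",
           "nearest_tss_id", "tss_distance") |>
    sort_by_coord() |>
    as_tibble()
  sparse_manifest <- manifest[manifest$probe_id %in%
                                probes$probe_id[sparse_idx], ]

  structure(
    list(manifest = manifest,
         sparse_manifest = sparse_manifest,
         sheet = sheet,
         beta = betas,
         tss = tibble(chromosome = prom$chromosome, start = prom$anchor,
                      end = prom$anchor + 1L, name = prom$tss_id,
                      score = 0L, strand = prom$strand),
         truth = list(epialleles = epi$table,
                      promoters = prom,
                      genetic = genetic,
                      clusters = tibble(
                        cluster_id = seq_len(n_clusters),
                        feature_class = layout$feature,
                        planted = seq_len(n_clusters) %in% epi$clusters)),
         probe_clusters = probes |> select("probe_id", "cluster_id"),
         mu = list(t1 = mu1, t2 = mu2, baseline = baseline),
         individuals = tibble(individual_id = individuals,
                              pair_id = pair_of),
         config = cfg),
    class = "iidmr_cohort")
}

#' @export
print.iidmr_cohort <- function(x, ...) {
  cat("<iidmr synthetic cohort>\n")
  cat(sprintf("  %d probes, %d pairs, %d samples (%d dense / %d sparse)\n",
              nrow(x$manifest), x$config$n_pairs, nrow(x$sheet),
              sum(x$sheet$platform == "dense"),
              sum(x$sheet$platform == "sparse")))
  cat(sprintf("  planted epialleles: %d (%d probes), seed %d\n",
              length(unique(x$truth$epialleles$epiallele_id)),
              nrow(x$truth$epialleles), x$config$seed))
  invisible(x)
}

#' Simulate ChIP count tracks for a cohort
#'
#' H2A.Z counts are drawn per promoter probe from an overdispersed
#' (negative-binomial) model coupled to the given individual's promoter
#' methylation through a Gaussian copula, so the realized Spearman
#' correlation approximates `meth_chip_coupling`. H3K4me3/H3K27me3 counts
#' are drawn per promoter from the hi/lo mean dictated by the promoter's
#' true chromatin state.
#'
#' @param cohort A cohort from [simulate_cohort()].
#' @param mark `"H2A.Z"`, `"H3K4me3"` or `"H3K27me3"`.
#' @param individual Individual id for H2A.Z (default: first individual);
#'   ignored for the ES-cell-like K4/K27 marks.
#' @return A count-track tibble: `region_id` (probe for H2A.Z, TSS for
#'   K4/K27), `raw_count`, `norm_score` (counts per 1e7), `mark`,
#'   `sample_id`.
#' @export
simulate_chip_counts <- function(cohort, mark = c("H2A.Z", "H3K4me3",
                                                  "H3K27me3"),
                                 individual = NULL) {
  stopifnot(inherits(cohort, "iidmr_cohort"))
  mark <- match.arg(mark)
  cfg <- cohort$config
  prom <- cohort$truth$promoters
  size <- 1 / cfg$chip_dispersion

  if (mark == "H2A.Z") {
    individual <- individual %||% cohort$individuals$individual_id[1]
    prom_probes <- cohort$probe_clusters[
      cohort$probe_clusters$cluster_id %in% prom$cluster_id, ]
    track <- withr::with_seed(
      derive_seed(cfg$seed, paste0("chip_H2A.Z_", individual)), {
        mu_ind <- cohort$mu$t2[prom_probes$probe_id, individual]
        prom_beta <- tapply(mu_ind, prom_probes$cluster_id, mean)
        np <- length(prom_beta)
        r <- 2 * sin(pi * cfg$meth_chip_coupling / 6)
        z_x <- qnorm((rank(prom_beta, ties.method = "average") - 0.5) / np)
        z_y <- r * z_x + sqrt(1 - r^2) * rnorm(np)
        a <- cfg$chip_probe_corr
        z_probe <- a * z_y[match(prom_probes$cluster_id,
                                 as.integer(names(prom_beta)))] +
          sqrt(1 - a^2) * rnorm(nrow(prom_probes))
        counts <- qnbinom(pnorm(z_probe), size = size, mu = cfg$chip_mean)
        tibble(region_id = prom_probes$probe_id, raw_count = counts,
               mark = mark, sample_id = individual)
      })
  } else {
    key <- if (mark == "H3K4me3") "K4" else "K27"
    hi <- if (key == "K4") grepl("^K4hi", prom$state)
          else grepl("K27hi$", prom$state)
    track <- withr::with_seed(derive_seed(cfg$seed, paste0("chip_", mark)), {
      counts <- rnbinom(nrow(prom), size = size,
                        mu = ifelse(hi, cfg$mark_mean_hi, cfg$mark_mean_lo))
      tibble(region_id = prom$tss_id, raw_count = counts,
             mark = mark, sample_id = "hES")
    })
  }
  normalize_counts(track, library_total = max(1, sum(track$raw_count)))
}

#' Simulate a tiered FPKM expression table
#'
#' Each promoter's FPKM is drawn per individual from a truncated log-normal
#' within its true expression tier: low tier in (0, 1) FPKM, high tier in
#' `[1, Inf)` (1 FPKM is the low/high expression boundary). When
#' `expr_coupling > 0`, an individual's log-FPKM is additionally depressed
#' in proportion to their methylation deviation at the promoter.
#'
#' @param cohort A cohort from [simulate_cohort()].
#' @return A wide tibble: `tss_id` plus one FPKM column per individual.
#' @export
simulate_expression <- function(cohort) {
  stopifnot(inherits(cohort, "iidmr_cohort"))
  cfg <- cohort$config
  prom <- cohort$truth$promoters
  inds <- cohort$individuals$individual_id
  withr::with_seed(derive_seed(cfg$seed, "expression"), {
    out <- tibble(tss_id = prom$tss_id)
    low <- prom$tier == "low"
    rtrunc_lnorm <- function(n, meanlog, sdlog, lo, hi) {
      u <- runif(n, stats::plnorm(lo, meanlog, sdlog),
                 stats::plnorm(hi, meanlog, sdlog))
      stats::qlnorm(u, meanlog, sdlog)
    }
    prom_probes <- cohort$probe_clusters[
      cohort$probe_clusters$cluster_id %in% prom$cluster_id, ]
    for (ind in inds) {
      f <- numeric(nrow(prom))
      f[low] <- rtrunc_lnorm(sum(low), cfg$expr_low_meanlog,
                             cfg$expr_low_sdlog, 0, 1)
      f[!low] <- rtrunc_lnorm(sum(!low), cfg$expr_high_meanlog,
                              cfg$expr_high_sdlog, 1, Inf)
      if (cfg$expr_coupling != 0) {
        ridx <- match(prom_probes$probe_id, rownames(cohort$mu$t2))
        dev <- tapply(cohort$mu$t2[ridx, ind] - cohort$mu$baseline[ridx],
                      prom_probes$cluster_id, mean)
        dev <- dev[match(prom$cluster_id, as.integer(names(dev)))]
        f <- exp(log(f) - cfg$expr_coupling * dev)
      }
      out[[ind]] <- f
    }
    out
  })
}

#' Simulate per-probe methylation-ageing correlation scores
#'
#' A designated set of probes receives high ageing-correlation scores
#' (uniform on 0.5-0.9); all other probes score near zero. With
#' `overlap = 1` the designated set is drawn from planted, persisting
#' epiallele probes (age-associated probes coincide with variable probes);
#' with `overlap = NULL` it is drawn uniformly from all probes (independent
#' designation); intermediate values mix the two pools.
#'
#' @param cohort A cohort from [simulate_cohort()].
#' @param n_designated Size of the designated top set (default 500).
#' @param overlap Fraction of the designated set drawn from planted probes,
#'   or `NULL` for uniform designation.
#' @return A tibble: `probe_id`, `age_score`, `designated`.
#' @export
simulate_age_scores <- function(cohort, n_designated = 500L,
                                overlap = 1) {
  stopifnot(inherits(cohort, "iidmr_cohort"))
  cfg <- cohort$config
  all_ids <- cohort$manifest$probe_id
  planted <- unique(cohort$truth$epialleles$probe_id[
    cohort$truth$epialleles$persists_t2])
  withr::with_seed(derive_seed(cfg$seed, "age_scores"), {
    if (is.null(overlap)) {
      designated <- sample(all_ids, n_designated)
    } else {
      n_from_planted <- round(overlap * n_designated)
      if (n_from_planted > length(planted))
        abort(sprintf(
          "requested %d designated probes from only %d planted probes",
          n_from_planted, length(planted)))
      designated <- c(sample(planted, n_from_planted),
                      sample(setdiff(all_ids, planted),
                             n_designated - n_from_planted))
    }
    score <- rnorm(length(all_ids), 0, 0.08)
    score <- pmin(0.3, pmax(-0.3, score))
    score[match(designated, all_ids)] <- runif(n_designated, 0.5, 0.9)
    tibble(probe_id = all_ids, age_score = score,
           designated = all_ids %in% designated)
  })
}
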