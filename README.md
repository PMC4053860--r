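# iidmr

Analysis of inter-individual differentially methylated regions (iiDMRs) in
twin methylome studies.

Monozygotic (MZ) twins are genetically matched, so stable methylation
differences between co-twins — epialleles — cannot be explained by local
genotype. `iidmr` implements the computational side of such a study for
Illumina-style methylation arrays: it calls iiDMRs from beta-value
matrices, asks whether biological variation exceeds technical replicate
noise, whether inter-individual differences persist across years and array
platforms, how they relate to chromatin (H2A.Z, H3K4me3/H3K27me3) and gene
expression (FPKM), and which genomic features and embryonic-stem-cell
chromatin states they concentrate in. Everything is exercised on a
synthetic twin cohort with a machine-readable truth table, so the whole
pipeline is testable offline.

## The core rule and statistics

* **iiDMR call.** For a pair of samples A and B, let
  `Δβ_i = β_A(i) − β_B(i)` at probe *i*. An iiDMR is a maximal run of
  `≥ 2` consecutive probes (in the kept, coordinate-sorted probe list)
  with `|Δβ_i| ≥ 0.05`, all of one sign, successive members `≤ 500 bp`
  apart on one chromosome. Missing values, sign changes, chromosome
  changes and larger gaps terminate a run (`call_iidmrs()`).
* **Probe QC.** Probes that map to multiple genomic locations, overlap
  known SNPs, or lie on chrX/chrY are excluded (`filter_probes()`).
* **Biological vs technical variation.** The ratio of mean iiDMR call
  counts in co-twin comparisons versus technical-replicate comparisons,
  with a permutation p-value obtained by relabelling comparisons
  (`technical_vs_biological_test()`).
* **Temporal stability.** For probes whose current difference exceeds 5%
  (strict), a 1-df goodness-of-fit χ² tests whether the historic
  difference has the same sign more often than the 50% expected by chance
  (`direction_consistency_test()`).
* **Variability profile.** Per-probe RMS co-twin difference
  `rms_intra(i) = sqrt(mean_pairs Δβ_i²)` and the analogous `rms_inter`
  on derangement-permuted pairs (`rms_profile()`, `permute_pairs()`).
* **Integration.** Probes are assigned to their nearest TSS within 1 kb;
  promoters are TSS ± 1 kb; ChIP fragments are counted per probe region
  and normalized to counts per 10⁷; Spearman correlations, binned means
  with percentile-bootstrap 95% intervals, expression log-ratio series,
  and a rank-sum test for the low-expression shift of DMR genes.
* **Enrichment.** Fraction of category probes called as iiDMRs with
  Clopper–Pearson 95% intervals against the overall iiDMR fraction;
  K4/K27 chromatin-state quadrants by per-mark 75th-percentile cuts;
  housekeeping-gene depletion by 2×2 χ²; ageing-associated (aDMR) probe
  variability versus random controls with bootstrap intervals.

## Worked example

```r
library(iidmr)
library(dplyr)

co <- simulate_cohort(cohort_config(seed = 1, n_probes = 20000,
                                    epiallele_rate = 0.2))
co
#> <iidmr synthetic cohort>
#>   20000 probes, 5 pairs, 28 samples (18 dense / 10 sparse)
#>   planted epialleles: 244 (856 probes), seed 1

kept <- filter_probes(co$manifest)
qc_report(kept)
#> # A tibble: 3 × 2
#>   reason         n_removed
#>   <chr>              <int>
#> 1 multi_mapped         199
#> 2 snp_overlap          403
#> 3 sex_chromosome       337

plan <- comparison_plan(co$sheet)   # 5 intra-pair + 10 inter-pair + 12 technical
d <- compute_deltas(co$beta$dense, plan$sample_a[1], plan$sample_b[1], kept)
calls <- call_iidmrs(d, comparison_id = plan$comparison_id[1])
calls |> select(chromosome, start, end, n_probes, direction, mean_delta)
#> # A tibble: 43 × 6
#>   chromosome start   end n_probes direction mean_delta
#>   <chr>      <int> <int>    <int> <chr>          <dbl>
#> 1 chr1       22800 23102        4 gain           0.139
#> 2 chr1       39300 39702        5 loss          -0.154
#> 3 chr1       72900 73202        4 gain           0.155

technical_vs_biological_test(co$beta$dense, co$sheet, kept,
                             n_perm = 999, seed = 1)
#> <iidmr test> biological/technical iiDMR call ratio
#>   statistic: 14.26   p-value: 0.001
#>   mean_biological = 45.167, mean_technical =  3.167, p_resolution =  0.001
```

The first co-twin comparison yields 43 iiDMRs, most of them the planted
epiallele runs (4–5 probes, mean |Δβ| ≈ 0.15 as configured); the
co-twin/replicate call ratio of ~14 with p = 0.001 (the resolution of 999
permutations) says biological variation far exceeds technical noise in
this cohort. Downstream, `rms_profile()`, `direction_consistency_test()`,
`binned_mean_ci()`, `category_enrichment()` and friends take the same
tibbles; `autoplot()` methods draw the binned series and enrichment bars,
and `tidy()`/`glance()` return broom-style summaries.

`run_pipeline(pipeline_config(...))` chains every stage on one cohort and
writes per-stage TSV/BED outputs plus a `summary.json`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the full pipeline from scratch on the default synthetic cohort
(probe QC → iiDMR calling over all pairwise comparisons → permutation,
variability, temporal, integration and enrichment analyses) and writes the
acceptance JSON to `--out`.
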