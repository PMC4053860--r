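---
title: "Methods: calling and characterising inter-individual DMRs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling and characterising inter-individual DMRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iidmr)
```

## Scope and model

`iidmr` analyses inter-individual DNA methylation variability in
monozygotic-twin designs profiled on Illumina-style beta-value arrays.
Because co-twins are genetically identical, a methylation difference
between them that is reproducible across technical replicates and stable
over years is a *non-genetically determined epiallele*. The package
covers: probe quality filtering, the windowed iiDMR caller, permutation
and bootstrap inference, cross-platform temporal comparison, integration
with ChIP fragment counts (H2A.Z, H3K4me3, H3K27me3) and FPKM expression
tables, and enrichment analyses over genomic features, chromatin-state
quadrants, housekeeping genes and ageing-associated probes. Array
preprocessing (IDAT parsing, normalisation), read mapping and expression
estimation are out of scope: the pipeline consumes beta matrices, fragment
intervals and FPKM tables.

### The caller

For samples A and B the per-probe difference is
$\Delta\beta_i = \beta_A(i) - \beta_B(i)$. A probe *qualifies* when
$|\Delta\beta_i| \ge$ `min_delta` (default 0.05; the comparison uses raw
floating-point values, no rounding). An iiDMR is a **maximal run** of at
least `min_probes` (default 2) consecutive qualifying probes of identical
sign, where *consecutive* means adjacent in the kept, coordinate-sorted
probe list and successive members lie at most `max_gap` (default 500) bp
apart on the same chromosome. A missing beta, a sign change, a chromosome
change or a larger gap terminates a run. Design choices worth stating:

* *Adjacency is array adjacency, not genomic adjacency*: an intervening
  masked probe removed by QC does not break a run, but an intervening
  measured, non-qualifying probe does. This makes the rule decidable from
  the manifest alone.
* *One call per maximal run*, not one per qualifying pair; call counts are
  counts of maximal runs, with member-probe counts reported alongside
  (`count_dmr_probes()`).
* The reported interval runs from the first member's position to the last
  member's position + 2, covering the final CpG dinucleotide; coordinates
  are 0-based half-open everywhere, matching BED natively.
* The caller is verified exactly against a brute-force oracle that
  enumerates candidate runs and tests the definition directly.

### Inference machinery

**Biological vs technical variation.** The test statistic is the mean
iiDMR call count over co-twin comparisons (replicate-matched twin
contrasts) divided by the mean count over within-individual replicate
contrasts. The null distribution permutes the biological/technical labels
over the set of comparisons; `p = (1 + #{null ≥ observed})/(n_perm + 1)`
(add-one estimator, never exactly zero, resolution `1/(n_perm+1)`). The
permutation unit is a deliberate reconstruction — label exchange over
comparisons is the minimal exchangeable null for this design — and the
count and seed are exposed.

**Temporal direction consistency.** Probes are selected when the current
(dense-platform) difference exceeds the threshold *strictly* (`> 0.05`,
deliberately strict where the caller is inclusive, matching how the two
rules are stated); among selected probes with a non-missing, non-zero
historic delta, a 1-df goodness-of-fit χ² compares the same-direction
count with the equiprobable null (n/2 each). The 50% null is exposed
(`null_prop`) for sensitivity analysis; no continuity correction by
default (n is large in intended use; a flag enables it).

**RMS variability.** `rms_intra(probe) = sqrt(mean_pairs Δβ²)`, dropping
pairs with missingness at that probe; probes usable in fewer than two
pairs are omitted. `rms_inter` applies the same measure to permuted
pairings in which twin 1 of pair *i* meets twin 2 of pair σ(*i*) for a
random derangement σ, so no individual ever meets their co-twin. By
default 20 seeded permutations are pooled (a single permutation is
recoverable with `n_pair_perm = 1`); pooling is strictly more stable and
changes nothing in expectation.

**Bootstrap and binomial intervals.** Binned series use percentile
bootstrap intervals over `n_boot` resamples per bin, deterministic given
the seed; bins with fewer than 3 observations are flagged and get no
interval. Enrichment fractions get exact Clopper–Pearson intervals
(Wilson available by flag). Raw p-values are reported throughout; no
multiple-testing correction is applied anywhere, and users comparing many
categories should correct downstream.

### Integration conventions

Promoters are TSS ± 1000 bp around the strand-aware anchor (interval end
− 1 for minus-strand genes), clipped at zero. Probes are assigned to the
nearest TSS anchor iff within 1000 bp, ties broken by smaller anchor
coordinate then lexicographic id. Fragment counts use half-open overlap
(≥ 1 bp, one count per fragment per region) and are normalised to counts
per 10⁷ fragments — the normalisation method and the Figure-style binning
are reconstructions and both are exposed as parameters. Expression ratios
use `log(FPKM + 1)` (pseudo-count 1 guards FPKM = 0; a ratio of logs is
base-invariant up to scale); 1 FPKM is the low/high expression boundary.
Chromatin-state quadrants call a mark "hi" when its normalised score
strictly exceeds the per-mark `hi_quantile` (default 0.75) quantile over
promoters — an operational reconstruction of a bivalency call, matched to
the synthetic truth where 25% of promoters are hi for each mark.

### The comparison plan

`comparison_plan()` enumerates co-twin (`intra_pair`), cross-pair
(`inter_pair`) and replicate (`technical`) contrasts. The default
`inter_mode = "representative"` takes one cross-pair comparison per
unordered pair of twin pairs, so the classic five-individual design (two
full pairs plus an unpaired co-twin) yields exactly five pairwise
comparisons; `"exhaustive"` enumerates every cross-pair individual
pairing (12 for three full pairs) when a deterministic superset is
preferred. Singleton pairs are accepted in the sample sheet precisely to
support that design, and are skipped by intra-pair statistics.

## The synthetic cohort: what it emulates, and what it does not

`simulate_cohort()` generates the full stated world from one seed, with
per-component derived sub-seeds so regenerating one component never
perturbs another; identical configuration gives bit-identical output.

* **Layout.** Probes fall in CpG-island-like clusters (default 8 probes
  spaced 100 bp) separated by 2 kb, across five autosomes plus a small
  chrX fraction; cluster-edge probes are annotated as shores. Half the
  clusters are promoters with a TSS at the middle probe.
* **Baselines.** Cluster methylation is bimodal (modes 0.15/0.85) with a
  per-cluster spread (sd 0.05) and per-probe jitter (sd 0.02). The
  cluster-level spread matters: it is what lets a probe's rank carry its
  promoter's methylation signal into the ChIP copula below.
* **Noise.** Measurement noise is applied on the logit scale with a slope
  correction, `plogis(qlogis(μ) + z·σ/(μ(1−μ)))`, so the realized
  beta-scale sd approximates `tech_noise_sd` at any methylation level with
  no boundary truncation.
* **Epialleles.** Planted as contiguous runs of 2–5 probes (so the caller
  is exercised on both sides of its window limit) at autosomal promoter
  clusters, shifted by ±`epiallele_delta` for one owner individual,
  landing at low-expression promoters with probability
  `lowexpr_targeting`. Planted clusters are re-based to intermediate
  methylation (uniform 0.35–0.65) so a 0.15 shift is never truncated at
  the beta boundary — biologically, variable epialleles sit at
  intermediate methylation. Epialleles exist at time point 1 and persist
  to time point 2 (the dense, replicated platform) with probability
  `temporal_stability`; recovery is therefore scored against persisting
  truth rows.
* **Cohort variability mode.** `variability_mode = "cohort"` replaces
  owner-specific shifts with independent per-individual deviations of sd
  `epiallele_delta/√2` at planted loci, making the intra-pair difference
  SD equal `epiallele_delta` in every pair — the world needed to verify
  the RMS recovery identity `mean rms_intra ≈ sqrt(s² + 2σ²)` at 30
  pairs, where an owner-specific epiallele would be diluted 30-fold.
* **Pair-shared ("genetic") shifts** of sd `genetic_delta` at a fraction
  of clusters make co-twins more correlated than unrelated individuals
  and cancel exactly in co-twin contrasts.
* **Platforms.** The sparse (27K-like) platform is a deterministic,
  promoter-biased strict subset of the dense probe set, measured at the
  historic time point.
* **ChIP counts.** H2A.Z counts are negative-binomial (dispersion 0.2)
  linked to the individual's promoter methylation through a Gaussian
  copula with latent correlation `2·sin(π·ρ/6)` for target Spearman ρ
  (`meth_chip_coupling`, default −0.6), shared across a promoter's probes
  with correlation 0.9. K4/K27 counts are drawn per promoter from hi/lo
  means (100/5) dictated by the true chromatin state; state frequencies
  put 25% of promoters hi per mark, matching the 0.75 classification
  quantile.
* **Expression.** FPKM is truncated log-normal within tier: low tier in
  (0, 1), high in [1, ∞). Methylated-mode promoters are low-tier with
  probability 0.95 (unmethylated: 0.55), which induces the negative
  methylation–expression and positive H2A.Z–expression correlations.
  Per-individual draws are independent by default (`expr_coupling = 0`,
  reflecting the negligible methylation–expression coupling the package's
  motivating analyses observe); a coupling slope can be switched on.
* **Ageing scores.** A designated set of probes receives high
  ageing-correlation scores, drawn from planted persisting probes
  (`overlap = 1`), uniformly from all probes (`overlap = NULL`), or a
  mixture.

What the generator does **not** emulate: cell-type composition and its
confounding, probe chemistry (type I/II) effects, spatial correlation of
noise, realistic LD or genetic architecture, batch effects across
platforms, and any sequence-level process. A green test therefore
establishes that the machinery is correct and calibrated under the stated
statistical structure — not that a particular biological dataset would
yield particular numbers.

## Calibration worlds and numerical choices

* The permutation-test *calibration* world uses `tech_noise_sd = 0.04`:
  the stated noise-only world at sd 0.015 produces essentially zero calls
  in every comparison and a 0/0 ratio. The value was chosen once, before
  measurement, to give non-degenerate technical call counts; the *power*
  world uses the stated sd 0.015 with planted epialleles (rate 0.05,
  delta 0.15).
* Recovery and enrichment checks use planting rates of 0.15–0.2 so the
  signal mass (not the per-locus effect) is large enough for stable
  probe-level precision/recall and category fractions; the per-locus
  effect size stays at the stated delta 0.15 / noise 0.015.
* Heavy simulation loops in the test suite are scaled (e.g. 40 power
  replicates instead of 200) to keep the default run inside a desk-scale
  budget; calibration loops that check rejection *rates* keep the full
  200.
* Degenerate inputs are errors, not silent results: empty kept probe set,
  unsorted delta tracks, constant vectors in Spearman, all-zero count
  tracks, degenerate 2×2 margins, `n_perm = 0`. Two deliberate
  exceptions: constant expression in the shift test returns p = 1 (no
  shift is detectable), and a fully call-free comparison set yields an
  undefined ratio with a warning.
* Ties at the aDMR rank boundary are broken by probe id; all stochastic
  steps (permutations, bootstrap, control sampling) derive their streams
  from one seed.

## Known limitations

The permutation unit for the biological-vs-technical test and the exact
construction of several figure-style analyses (binning, ChIP
normalisation, bivalency thresholds) are documented reconstructions with
exposed parameters rather than fixed conventions. The temporal comparison
assumes two time points and ignores platform batch effects beyond probe
matching. Enrichment is computed at probe level with DMR membership
meaning "member of ≥ 1 call", so probe-dense regions weigh more than
sparse ones.
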