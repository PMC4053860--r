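# Readers/writers for the plain-text formats the pipeline consumes:
# tab-separated manifests, beta matrices, sample sheets and expression
# tables, plus BED3/BED6+ interval files. All coordinates are 0-based
# half-open internally and on disk (BED-native); "NA" and empty cells are
# the missing-value tokens and are never imputed.

.feature_levels <- c("promoter", "regulatory", "exon", "intron", "other")
.cgi_levels <- c("island", "shore", "open_sea")

validate_manifest <- function(manifest) {
  req <- c("probe_id", "chromosome", "position", "multi_mapped",
           "snp_overlap", "sex_chromosome", "feature_class", "cgi_relation")
  missing_cols <- setdiff(req, names(manifest))
  if (length(missing_cols))
    abort(paste0("manifest is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  dup <- manifest$probe_id[duplicated(manifest$probe_id)]
  if (length(dup))
    abort(sprintf("duplicate probe_id in manifest: '%s'", dup[1]))
  if (any(is.na(manifest$position)) || any(manifest$position < 0))
    abort("manifest positions must be non-negative integers")
  sexy <- manifest$chromosome %in% c("chrX", "chrY", "X", "Y")
  if (any(manifest$sex_chromosome != sexy))
    abort("sex_chromosome flag inconsistent with chromosome label")
  if (!all(manifest$feature_class %in% .feature_levels))
    abort("feature_class must be one of promoter/regulatory/exon/intron/other")
  if (!all(manifest$cgi_relation %in% .cgi_levels))
    abort("cgi_relation must be one of island/shore/open_sea")
  if ("nearest_tss_id" %in% names(manifest)) {
    has_tss <- !is.na(manifest$nearest_tss_id)
    if (!"tss_distance" %in% names(manifest) ||
        any(has_tss != !is.na(manifest$tss_distance)))
      abort("tss_distance must be present exactly where nearest_tss_id is")
  }
  invisible(manifest)
}

#' Read a probe manifest
#'
#' Reads a tab-separated probe manifest (one row per array probe: genomic
#' anchor, mask flags, feature and CpG-island annotation, nearest-TSS link),
#' validates its invariants and returns it sorted by genomic coordinate.
#'
#' @param path Path to a TSV file with a header row naming at least
#'   `probe_id`, `chromosome`, `position`, `multi_mapped`, `snp_overlap`,
#'   `sex_chromosome`, `feature_class`, `cgi_relation` and optionally
#'   `nearest_tss_id`, `tss_distance`. `position` is the 0-based coordinate
#'   of the interrogated CpG cytosine.
#' @return A tibble of probe records sorted by `(chromosome, position)`.
#' @export
read_probe_manifest <- function(path) {
  manifest <- readr::read_tsv(
    path, show_col_types = FALSE, progress = FALSE, na = c("NA", ""),
    col_types = readr::cols(
      probe_id = readr::col_character(),
      chromosome = readr::col_character(),
      position = readr::col_integer(),
      multi_mapped = readr::col_logical(),
      snp_overlap = readr::col_logical(),
      sex_chromosome = readr::col_logical(),
      .default = readr::col_guess()))
  probs <- readr::problems(manifest)
  if (nrow(probs))
    abort(sprintf("malformed manifest value at line %d: expected %s",
                  probs$row[1] + 1L, probs$expected[1]))
  validate_manifest(manifest)
  as_tibble(sort_by_coord(manifest))
}

#' Read a beta-value matrix
#'
#' Reads a probes-by-samples table of methylation beta values in `[0, 1]`.
#' The first column must be `probe_id`; every other column is one sample.
#' `"NA"` and empty cells are treated as missing and preserved. Probes not
#' present in `manifest` are dropped with a message.
#'
#' @param path Path to a TSV file.
#' @param manifest A validated probe manifest tibble; rows of the matrix are
#'   restricted to its probes.
#' @return A wide tibble: `probe_id` plus one numeric column per sample.
#' @export
read_beta_matrix <- function(path, manifest) {
  beta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                          na = c("NA", ""))
  if (names(beta)[1] != "probe_id")
    abort("first column of a beta matrix must be 'probe_id'")
  if (ncol(beta) < 2) abort("beta matrix has an empty sample set")
  if (!all(vapply(beta[-1], is.numeric, logical(1))))
    abort("non-numeric beta value encountered")
  validate_beta_values(beta_matrix(beta))
  unknown <- !beta$probe_id %in% manifest$probe_id
  if (any(unknown)) {
    inform(sprintf("dropping %d probe(s) absent from the manifest",
                   sum(unknown)))
    beta <- beta[!unknown, , drop = FALSE]
  }
  as_tibble(beta)
}

#' Read a sample sheet
#'
#' @param path TSV with columns `sample_id`, `individual_id`, `pair_id`,
#'   `replicate_id`, `time_point`, `platform` (`dense` or `sparse`).
#' @return A validated tibble.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(
                             time_point = readr::col_integer(),
                             .default = readr::col_character()))
  validate_sample_sheet(sheet)
}

validate_sample_sheet <- function(sheet) {
  req <- c("sample_id", "individual_id", "pair_id", "replicate_id",
           "time_point", "platform")
  if (length(setdiff(req, names(sheet))))
    abort(paste("sample sheet is missing column(s):",
                paste(setdiff(req, names(sheet)), collapse = ", ")))
  if (anyDuplicated(sheet$sample_id))
    abort("sample_ids must be unique")
  if (!all(sheet$platform %in% c("dense", "sparse")))
    abort("platform must be 'dense' or 'sparse'")
  sizes <- tapply(sheet$individual_id, sheet$pair_id,
                  function(x) length(unique(x)))
  if (any(sizes > 2))
    abort("a pair_id maps to more than two individuals")
  as_tibble(sheet)
}

#' Read an expression table
#'
#' @param path TSV whose first column is `tss_id`; remaining columns are
#'   per-sample FPKM values (non-negative).
#' @return A wide tibble.
#' @export
read_expression_table <- function(path) {
  expr <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                          na = c("NA", ""))
  if (names(expr)[1] != "tss_id")
    abort("first column of an expression table must be 'tss_id'")
  vals <- as.matrix(expr[-1])
  if (any(!is.na(vals) & vals < 0)) abort("FPKM values must be >= 0")
  as_tibble(expr)
}

#' Read genomic intervals from a BED file
#'
#' Accepts BED3 and BED6+ (0-based, half-open). Extra columns beyond the
#' six standard ones are kept as `extra1`, `extra2`, ...
#'
#' @param path Path to a BED file (no header).
#' @return A tibble with `chromosome`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`, sorted within each chromosome.
#' @export
read_intervals <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE, comment = "#")
  if (!nrow(bed)) {
    return(tibble(chromosome = character(), start = integer(),
                  end = integer()))
  }
  std <- c("chromosome", "start", "end", "name", "score", "strand")
  k <- min(ncol(bed), 6L)
  names(bed)[seq_len(k)] <- std[seq_len(k)]
  if (ncol(bed) > 6L)
    names(bed)[7:ncol(bed)] <- paste0("extra", seq_len(ncol(bed) - 6L))
  bed$start <- as.integer(bed$start)
  bed$end <- as.integer(bed$end)
  if (any(is.na(bed$start)) || any(is.na(bed$end)))
    abort("malformed BED coordinates")
  if (any(bed$start < 0)) abort("BED start must be >= 0")
  if (any(bed$start >= bed$end))
    abort(sprintf("BED interval with start >= end at line %d",
                  which(bed$start >= bed$end)[1]))
  if ("strand" %in% names(bed) && !all(bed$strand %in% c("+", "-", ".")))
    abort("BED strand must be '+', '-' or '.'")
  as_tibble(bed[order(chrom_order(bed$chromosome), bed$start, bed$end), ])
}

#' Write iiDMR calls as BED6+
#'
#' One row per call: `chrom start end name score strand n_probes direction
#' mean_delta`. `name` is `<comparison_id>_<index>`; `score` is
#' `1000 * mean_abs_delta` capped at 1000 (browser convention); strand is
#' `"."`. The file round-trips through [read_intervals()].
#'
#' @param calls A tibble of iiDMR calls from [call_iidmrs()].
#' @param path Output path.
#' @export
write_dmr_bed <- function(calls, path) {
  if (!nrow(calls)) {
    readr::write_lines(character(), path)
    return(invisible(path))
  }
  comparison <- col_or(calls, "comparison_id", rep("dmr", nrow(calls)))
  comparison[is.na(comparison)] <- "dmr"
  bed <- tibble(
    chromosome = calls$chromosome,
    start = calls$start,
    end = calls$end,
    name = sprintf("%s_%d", comparison, seq_len(nrow(calls))),
    score = pmin(1000L, as.integer(round(1000 * calls$mean_abs_delta))),
    strand = ".",
    n_probes = calls$n_probes,
    direction = calls$direction,
    mean_delta = calls$mean_delta)
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read iiDMR calls written by [write_dmr_bed()]
#'
#' @param path Path to a BED6+ file produced by [write_dmr_bed()].
#' @return A tibble with interval columns plus `n_probes`, `direction`,
#'   `mean_delta`.
#' @export
read_dmr_bed <- function(path) {
  bed <- read_intervals(path)
  if (!nrow(bed)) return(bed)
  stopifnot(ncol(bed) >= 9)
  names(bed)[7:9] <- c("n_probes", "direction", "mean_delta")
  bed$n_probes <- as.integer(bed$n_probes)
  bed
}
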