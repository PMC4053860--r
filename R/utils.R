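# Internal helpers shared across modules.

# Deterministic sub-stream seeds: one global seed, stable offsets per
# component so regenerating one component never perturbs another.
# Result kept within 32-bit integer range.
derive_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629) + 1L
}

# Order chromosome labels naturally (chr1 < chr2 < ... < chr10 < chrX).
chrom_order <- function(chromosome) {
  stripped <- sub("^chr", "", chromosome)
  num <- suppressWarnings(as.integer(stripped))
  num[is.na(num)] <- 1000L + match(stripped[is.na(num)],
                                   sort(unique(stripped[is.na(num)])))
  num
}

sort_by_coord <- function(df) {
  df[order(chrom_order(df$chromosome), df$position), , drop = FALSE]
}

# Extract the numeric beta matrix (probes x samples) from a wide beta tibble.
beta_matrix <- function(beta) {
  stopifnot(is.data.frame(beta), "probe_id" %in% names(beta))
  m <- as.matrix(beta[setdiff(names(beta), "probe_id")])
  storage.mode(m) <- "double"
  rownames(m) <- beta$probe_id
  m
}

validate_beta_values <- function(m) {
  bad <- !is.na(m) & (m < 0 | m > 1)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf("beta value %.4g outside [0, 1] at probe '%s', sample '%s'",
                  m[idx[1], idx[2]], rownames(m)[idx[1]], colnames(m)[idx[2]]))
  }
  invisible(m)
}

is_flag <- function(x) is.logical(x) && length(x) == 1 && !is.na(x)

# Column if present, default otherwise (tibbles warn on missing `$`).
col_or <- function(df, col, default) {
  if (col %in% names(df)) df[[col]] else default
}

# Stat-result container used by every test in the package.
new_iidmr_test <- function(statistic_name, statistic, p_value,
                           ci_low = NA_real_, ci_high = NA_real_,
                           estimate = NULL, n_resamples = NA_integer_,
                           seed = NA_integer_, details = NULL) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(
    list(statistic_name = statistic_name,
         statistic = statistic,
         p_value = p_value,
         ci_low = ci_low, ci_high = ci_high,
         estimate = estimate,
         n_resamples = n_resamples,
         seed = seed,
         details = details),
    class = "iidmr_test")
}

#' @export
print.iidmr_test <- function(x, ...) {
  cat("<iidmr test>", x$statistic_name, "\n")
  cat("  statistic:", format(x$statistic, digits = 4),
      "  p-value:", format.pval(x$p_value, digits = 3), "\n")
  if (!is.na(x$ci_low) || !is.na(x$ci_high))
    cat("  95% CI: [", format(x$ci_low, digits = 4), ",",
        format(x$ci_high, digits = 4), "]\n")
  if (!is.null(x$estimate) && length(x$estimate))
    cat("  ", paste(names(x$estimate), format(unlist(x$estimate), digits = 4),
                    sep = " = ", collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Percentile bootstrap CI for the mean of a numeric vector; deterministic
# given the current RNG state.
boot_mean_ci <- function(x, n_boot, conf = 0.95) {
  n <- length(x)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  means <- rowMeans(matrix(x[idx], nrow = n_boot))
  alpha <- (1 - conf) / 2
  unname(quantile(means, c(alpha, 1 - alpha), type = 7))
}
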