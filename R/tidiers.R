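# broom-style tidiers for the package's result objects.

#' Tidy an iidmr test result
#'
#' @param x An `iidmr_test`.
#' @param ... Unused.
#' @return A one-row tibble: `statistic_name`, `statistic`, `p_value`,
#'   `ci_low`, `ci_high`, `n_resamples`, `seed`.
#' @exportS3Method generics::tidy
#' @export
tidy.iidmr_test <- function(x, ...) {
  tibble(statistic_name = x$statistic_name,
         statistic = x$statistic,
         p_value = x$p_value,
         ci_low = x$ci_low, ci_high = x$ci_high,
         n_resamples = x$n_resamples, seed = x$seed)
}

#' @rdname tidy.iidmr_test
#' @exportS3Method generics::glance
#' @export
glance.iidmr_test <- function(x, ...) {
  out <- tidy(x)
  if (!is.null(x$estimate) && length(x$estimate))
    out <- bind_cols(out, as_tibble(x$estimate))
  out
}

#' Tidy an enrichment table
#'
#' @param x An `iidmr_enrichment` tibble.
#' @param ... Unused.
#' @return The enrichment tibble (one row per category).
#' @exportS3Method generics::tidy
#' @export
tidy.iidmr_enrichment <- function(x, ...) as_tibble(x)

#' @rdname tidy.iidmr_enrichment
#' @exportS3Method generics::glance
#' @export
glance.iidmr_enrichment <- function(x, ...) {
  tibble(background_fraction = attr(x, "background_fraction"),
         method = attr(x, "method"), n_categories = nrow(x))
}
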