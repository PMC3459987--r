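#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an enrichment test into a one-row tibble
#'
#' @param x An `enrichment_test`.
#' @param ... Unused.
#' @return A tibble with `name`, `n`, `k`, `p`, `p_value`,
#'   `empirical_fdr`, `fdr_label`.
#' @export
tidy.enrichment_test <- function(x, ...) {
  tibble(
    name = x$name, n = x$n, k = x$k, p = x$p, p_value = x$p_value,
    empirical_fdr = x$empirical_fdr, fdr_label = x$fdr_label
  )
}

#' One-row summary of an enrichment test
#'
#' @param x An `enrichment_test`.
#' @param ... Unused.
#' @return A tibble with the test result plus the randomisation settings.
#' @export
glance.enrichment_test <- function(x, ...) {
  tibble(
    name = x$name, n = x$n, k = x$k, p = x$p, p_value = x$p_value,
    empirical_fdr = x$empirical_fdr, n_random_sets = x$n_random_sets,
    degenerate = x$degenerate
  )
}

#' Combine enrichment tests into a results table
#'
#' @param tests A list of `enrichment_test` objects.
#' @return A tibble with one row per test ([tidy.enrichment_test()]).
#' @export
enrichment_table <- function(tests) {
  dplyr::bind_rows(lapply(tests, tidy))
}
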