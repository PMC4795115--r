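#' Tidy a population comparison
#'
#' Returns the comparison table as a plain tibble, one row per test.
#'
#' @param x A [compare_populations()] result.
#' @param ... Unused.
#' @return A tibble.
#' @export
#' @exportS3Method generics::tidy
tidy.population_comparison <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "population_comparison")
  out
}

#' Glance at a population comparison
#'
#' One-row summary of the comparison batch.
#'
#' @param x A [compare_populations()] result.
#' @param ... Unused.
#' @return One-row tibble: `n_comparisons`, `alpha`, `alpha_corrected`,
#'   `n_significant`.
#' @export
#' @exportS3Method generics::glance
glance.population_comparison <- function(x, ...) {
  tibble::tibble(
    n_comparisons = x$n_comparisons[1],
    alpha = attr(x, "alpha"),
    alpha_corrected = x$alpha_corrected[1],
    n_significant = sum(x$significant)
  )
}

#' Tidy an average profile
#'
#' @param x An `average_profile`.
#' @param ... Unused.
#' @return Tibble with `position`, `mean`, `sd`, `n`.
#' @export
#' @exportS3Method generics::tidy
tidy.average_profile <- function(x, ...) {
  tibble::tibble(position = x$position, mean = x$mean, sd = x$sd,
                 n = attr(x, "n"))
}
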