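#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a group comparison
#'
#' @param x A `stereo_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return Tibble of pairwise comparisons: `group1`, `group2`, `estimate`,
#'   `statistic`, `df`, `p_value`, `p_adjusted`, plus the quantity and the
#'   test actually used.
#' @export
tidy.stereo_comparison <- function(x, ...) {
  dplyr::mutate(x$pairwise, quantity = x$quantity, method = x$method_used,
                .before = 1)
}

#' One-row summary of a group comparison
#'
#' @param x A `stereo_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return One-row tibble: omnibus statistic and p-value, the
#'   variance-homogeneity diagnostic, and the test used.
#' @export
glance.stereo_comparison <- function(x, ...) {
  tibble::tibble(
    quantity = x$quantity,
    method = x$method_used,
    statistic = x$omnibus$statistic,
    df1 = x$omnibus$df1,
    df2 = x$omnibus$df2,
    p_value = x$omnibus$p_value,
    homogeneity_p = x$homogeneity$p_value,
    n_groups = length(x$groups)
  )
}
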