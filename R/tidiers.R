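#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy methods for package result objects
#'
#' `tidy()` on a [compare_groups()] result gives the one-row
#' statistic/p-value table; on an [inhibition_profile()] it gives the kinetic
#' mixture with the pharmacological quantities attached. `glance()` gives
#' one-row summaries.
#'
#' @param x A `group_comparison` or `inhibition_profile`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble::tibble(
    estimate = x$mean_a - x$mean_b,
    statistic = x$statistic,
    p.value = x$p_value,
    method = x$test
  )
}

#' @rdname tidy.group_comparison
#' @export
glance.group_comparison <- function(x, ...) tibble::as_tibble(unclass(x))

#' @rdname tidy.group_comparison
#' @export
tidy.inhibition_profile <- function(x, ...) x$mixture

#' @rdname tidy.group_comparison
#' @export
glance.inhibition_profile <- function(x, ...) {
  tibble::tibble(
    fraction_glycinergic = x$fractions[["glycinergic"]],
    fraction_gabaergic = x$fractions[["gabaergic"]],
    fraction_mixed = x$fractions[["mixed"]],
    tonic_glycine_pa = x$tonic_glycine_pa,
    tonic_gaba_pa = x$tonic_gaba_pa,
    strychnine_block_fraction = x$strychnine_block_fraction,
    bicuculline_block_fraction = x$bicuculline_block_fraction
  )
}

#' @export
print.inhibition_profile <- function(x, ...) {
  cat("Inhibition profile\n")
  cat(sprintf("  kinetic fractions: %.0f%% glycinergic / %.0f%% gabaergic / %.0f%% mixed\n",
              100 * x$fractions[["glycinergic"]],
              100 * x$fractions[["gabaergic"]],
              100 * x$fractions[["mixed"]]))
  cat(sprintf("  tonic currents: glycine %.1f pA, GABA %.1f pA\n",
              x$tonic_glycine_pa, x$tonic_gaba_pa))
  cat(sprintf("  frequency blockade: strychnine %.0f%%, bicuculline %.0f%%\n",
              100 * x$strychnine_block_fraction,
              100 * x$bicuculline_block_fraction))
  invisible(x)
}

#' @export
print.tone_report <- function(x, ...) {
  cat("Pipeline report:", x$experiment,
      sprintf("(seed %d)\n", x$provenance$seed))
  str(x$results, max.level = 1, give.attr = FALSE)
  invisible(x)
}
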