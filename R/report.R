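#' Render the category-effect summary table
#'
#' Builds the per-subsample table of posterior-predictive means and 90%
#' credibility intervals by factor category and outcome, categories in the
#' reporting order (stress, bedtime, weather, physical, exercise, dietary,
#' AR(1)) and one column per outcome target (`y1=1`, `y2=1`, `y2=3`,
#' `y3=1`, `y3=3`).  Every number is taken from the `dmpm_contrast`
#' summaries — nothing is recomputed at render time.  A category missing
#' from a result is marked `"absent"` rather than dropped.
#'
#' @param results A `dmpm_contrast` or a named list of them (one per
#'   subsample).
#' @param digits Digits used when formatting cells.
#' @return A tibble with columns `subsample`, `category` and one formatted
#'   `mean [low, high]` column per outcome.
#' @export
render_summary <- function(results, digits = 3) {
  if (inherits(results, "dmpm_contrast")) {
    results <- list(all = results)
  }
  if (!is.list(results) || length(results) == 0 ||
      !all(vapply(results, inherits, logical(1), "dmpm_contrast"))) {
    abort_sleepdmpm("`results` must be one or more dmpm_contrast objects.",
                    "sleepdmpm_contract_error")
  }
  if (is.null(names(results)) || any(names(results) == "")) {
    names(results) <- paste0("subsample", seq_along(results))
  }
  cats <- c(sleep_categories(), "ar1")
  fmt <- function(m, lo, hi) {
    sprintf(paste0("%.", digits, "f [%.", digits, "f, %.", digits, "f]"),
            m, lo, hi)
  }
  purrr::imap_dfr(results, function(res, nm) {
    grid <- tidyr::expand_grid(category = cats, outcome = contrast_outcomes())
    tab <- dplyr::left_join(
      grid,
      dplyr::mutate(res$summary, category = as.character(.data$category)),
      by = c("category", "outcome")) |>
      dplyr::mutate(cell = dplyr::if_else(
        is.na(.data$mean), "absent",
        fmt(.data$mean, .data$ci_low, .data$ci_high))) |>
      dplyr::select("category", "outcome", "cell") |>
      tidyr::pivot_wider(names_from = "outcome", values_from = "cell")
    tab$subsample <- nm
    tab$category <- factor(tab$category, levels = cats)
    dplyr::relocate(tab, "subsample")
  })
}

#' Forest-style plot of category effects
#'
#' One panel per outcome target; categories on the vertical axis in
#' reporting order, posterior-predictive means as points with 90%
#' credibility-interval bars.
#'
#' @param object A `dmpm_contrast`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.dmpm_contrast <- function(object, ...) {
  df <- object$summary |>
    dplyr::mutate(category = factor(.data$category,
                                    levels = rev(c(sleep_categories(), "ar1"))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$category)) +
    ggplot2::geom_point(shape = 1, size = 2) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2) +
    ggplot2::facet_wrap(~outcome, nrow = 1) +
    ggplot2::labs(x = "|change in outcome probability| per interquartile improvement",
                  y = NULL) +
    ggplot2::theme_bw()
}

#' @export
plot.dmpm_contrast <- function(x, ...) print(autoplot(x, ...))

#' Forest plot across subsamples
#'
#' @param results Named list of `dmpm_contrast` objects (one per
#'   subsample).
#' @return A ggplot object faceted subsample x outcome.
#' @export
plot_contrast_panels <- function(results) {
  df <- purrr::imap_dfr(results, function(res, nm) {
    dplyr::mutate(res$summary, subsample = nm)
  }) |>
    dplyr::mutate(category = factor(.data$category,
                                    levels = rev(c(sleep_categories(), "ar1"))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$category)) +
    ggplot2::geom_point(shape = 1, size = 1.8) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2) +
    ggplot2::facet_grid(subsample ~ outcome) +
    ggplot2::labs(x = "|change in outcome probability| per interquartile improvement",
                  y = NULL) +
    ggplot2::theme_bw()
}
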