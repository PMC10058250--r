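#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_col geom_tile
#'   geom_abline labs scale_fill_gradient theme_minimal
#' @export
ggplot2::autoplot

#' Plot an isolation-by-distance fit
#'
#' Bin mean similarities against distance-bin midpoints, with dropped bins
#' greyed out and the fitted line overlaid.
#'
#' @param object A `decay_fit` from [bin_and_fit()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decay_fit <- function(object, ...) {
  ggplot(object$bins,
         aes(x = .data$midpoint_km, y = .data$mean_similarity,
             alpha = .data$retained)) +
    geom_point(aes(size = .data$n_pairs)) +
    geom_abline(slope = object$slope, intercept = object$intercept,
                colour = "steelblue") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.25),
                                guide = "none") +
    labs(x = "Geographic distance (km, bin midpoint)",
         y = "Mean genetic similarity (1 - TVD)",
         size = "Pairs",
         title = sprintf("Isolation by distance (%s): slope %.2g/km, R² = %.2f",
                         object$variant, object$slope, object$r_squared)) +
    theme_minimal()
}

#' Plot a minor-allele-frequency histogram
#'
#' @param object A `maf_histogram` from [maf_histogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.maf_histogram <- function(object, ...) {
  ggplot(object, aes(x = (.data$bin_low + .data$bin_high) / 2,
                     y = .data$count)) +
    geom_col(width = (object$bin_high[1] - object$bin_low[1]) * 0.92,
             fill = "grey35") +
    labs(x = "Minor allele frequency", y = "Variants",
         title = "MAF spectrum (0.05-wide bins)") +
    theme_minimal()
}

#' Heatmap of pairwise distinguishability p-values
#'
#' Tiles the p-value for each ordered group pair (row = the group whose
#' intragroup similarity is tested), marking the two conventional
#' significance levels.
#'
#' @param results Tibble from [all_pairs_tests()].
#' @param alpha Significance levels annotated (default `c(0.01, 0.001)`).
#' @return A ggplot object.
#' @export
plot_pvalue_matrix <- function(results, alpha = c(0.01, 0.001)) {
  long <- dplyr::bind_rows(
    tibble(test_group = results$group_a, other = results$group_b,
           p = results$p_a),
    tibble(test_group = results$group_b, other = results$group_a,
           p = results$p_b))
  long$mark <- dplyr::case_when(
    long$p < min(alpha) ~ "strong", long$p < max(alpha) ~ "moderate",
    TRUE ~ "ns")
  ggplot(long, aes(x = .data$other, y = .data$test_group,
                   fill = log10(.data$p))) +
    geom_tile() +
    geom_point(data = long[long$mark != "ns", ],
               aes(shape = .data$mark), size = 2, colour = "white") +
    ggplot2::scale_shape_manual(
      values = c(moderate = 16, strong = 8),
      labels = c(moderate = paste0("p < ", max(alpha)),
                 strong = paste0("p < ", min(alpha))),
      name = NULL) +
    labs(x = "Compared against", y = "Test group",
         fill = "log10 p") +
    theme_minimal()
}
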