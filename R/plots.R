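#' Plot a MARS rating
#'
#' Bar chart of structure-wise CMB counts, coloured by MARS region.
#'
#' @param object A `mars_rating` from [rate_subject()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mars_rating <- function(object, ...) {
  df <- object$structure_counts |>
    mutate(structure = factor(.data$structure, levels = rev(.data$structure)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count, y = .data$structure,
                                   fill = .data$region)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "CMB count", y = NULL, fill = "MARS region",
                  title = sprintf("MARS rating: %s (%d CMBs)",
                                  object$subject_id, object$total)) +
    ggplot2::theme_minimal()
}

#' Plot an evaluation
#'
#' Heatmap of the region-level confusion matrix (manual rows, automated
#' columns) with per-cell counts.
#'
#' @param object A `region_evaluation` from [evaluate_subject()].
#' @param level `"region"` or `"structure"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.region_evaluation <- function(object, level = c("region", "structure"), ...) {
  level <- match.arg(level)
  m <- if (level == "region") object$confusion_region else object$confusion_structure
  df <- as.data.frame.table(as.table(m), responseName = "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$automated, y = .data$manual,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = sprintf("Confusion (%s level, matched lesions)", level)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Histogram of lesion size errors
#'
#' @param ev A `region_evaluation`.
#' @param binwidth Bin width in mm.
#' @return A ggplot object.
#' @export
plot_size_errors <- function(ev, binwidth = 0.5) {
  if (!inherits(ev, "region_evaluation")) abort_validation("not a region_evaluation.")
  ggplot2::ggplot(ev$size_abs_errors, ggplot2::aes(x = .data$abs_error_mm)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "absolute size error (mm)", y = "lesions",
                  title = sprintf("Size errors (MAE %.1f mm)", ev$size_mae)) +
    ggplot2::theme_minimal()
}
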