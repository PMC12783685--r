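# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_histogram geom_tile geom_line
#'   geom_point geom_vline facet_wrap labs scale_fill_gradient theme_minimal
#' @export
ggplot2::autoplot

#' Overlay a treatment mAP distribution on the DMSO null
#'
#' @param compound_dist,null_dist `map_distribution` objects.
#' @param bins Histogram bins (default 40).
#' @return A ggplot: the two resampled AP distributions.
#' @export
plot_map_distributions <- function(compound_dist, null_dist, bins = 40) {
  df <- dplyr::bind_rows(
    dplyr::mutate(tidy(compound_dist), which = "treatment"),
    dplyr::mutate(tidy(null_dist), which = "DMSO null")
  )
  ggplot(df, aes(x = .data$average_precision, fill = .data$which)) +
    geom_histogram(bins = bins, alpha = 0.6, position = "identity") +
    labs(x = "average precision", y = "resamples", fill = NULL) +
    theme_minimal()
}

#' @rdname plot_map_distributions
#' @param object A `map_distribution`.
#' @param ... Unused.
#' @export
autoplot.map_distribution <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$average_precision)) +
    geom_histogram(bins = 40) +
    labs(x = "average precision", y = "resamples") +
    theme_minimal()
}

#' Heatmap of mAP effect sizes across doses and timepoints
#'
#' @param calls Output of [activity_map()].
#' @return A ggplot: compound-by-timepoint tiles of mAP-ES, faceted by dose.
#' @export
plot_activity_heatmap <- function(calls) {
  ggplot(dplyr::filter(calls, .data$status == "ok"),
         aes(x = factor(.data$timepoint_h), y = .data$compound,
             fill = .data$map_es)) +
    geom_tile() +
    facet_wrap(~dose_uM, nrow = 1, labeller = ggplot2::label_both) +
    scale_fill_gradient(low = "white", high = "firebrick") +
    labs(x = "timepoint (h)", y = NULL, fill = "mAP-ES") +
    theme_minimal()
}

#' Sensitivity of activity calls per dose and timepoint
#'
#' @param calls Output of [activity_map()].
#' @param truth Ground-truth tibble from [generate_dataset()].
#' @return A ggplot: sensitivity by timepoint, one line per dose.
#' @export
plot_sensitivity <- function(calls, truth) {
  df <- calls |>
    dplyr::filter(.data$status == "ok") |>
    dplyr::inner_join(
      dplyr::select(truth, compound = "compound_id", "dose_uM",
                    "timepoint_h", truth_active = "is_active"),
      by = c("compound", "dose_uM", "timepoint_h")
    ) |>
    dplyr::filter(.data$truth_active) |>
    dplyr::group_by(.data$dose_uM, .data$timepoint_h) |>
    dplyr::summarise(sensitivity = mean(.data$is_active), .groups = "drop")
  ggplot(df, aes(x = .data$timepoint_h, y = .data$sensitivity,
                 colour = factor(.data$dose_uM))) +
    geom_line() + geom_point() +
    labs(x = "timepoint (h)", y = "sensitivity", colour = "dose (uM)") +
    theme_minimal()
}

#' Confusion-matrix heatmap of a MoA report
#'
#' @param object A `moa_report`.
#' @param ... Unused.
#' @return A ggplot tile map of the confusion matrix.
#' @export
autoplot.moa_report <- function(object, ...) {
  cm <- object$confusion_matrix
  df <- tibble::as_tibble(as.table(cm), .name_repair = "minimal")
  names(df) <- c("truth", "predicted", "n")
  ggplot(df, aes(x = .data$predicted, y = .data$truth, fill = .data$n)) +
    geom_tile() +
    ggplot2::geom_text(aes(label = .data$n), size = 3) +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(x = "predicted MoA", y = "true MoA", fill = "compounds") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
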