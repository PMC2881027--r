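# ggplot2 views of the main result types.

#' Physicochemical contrast between protein classes
#'
#' GRAVY against aliphatic index, one point per protein, coloured by
#' class — the standard view of the physicochemical separation between
#' organellar and cell-envelope proteins.
#'
#' @param physchem Output of [physchem_profile()] with a grouping column.
#' @param label Name of the grouping column.
#' @return A ggplot object.
#' @export
plot_physchem <- function(physchem, label = "truth_label") {
  ggplot2::ggplot(physchem,
                  ggplot2::aes(x = .data$gravy, y = .data$aliphatic_index,
                               colour = .data[[label]])) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "GRAVY (Kyte-Doolittle mean hydropathy)",
                  y = "Aliphatic index", colour = "class") +
    ggplot2::theme_minimal()
}

#' Plot per-round metrics of a protocol fit
#'
#' Distribution of pooled accuracy over the randomization rounds, with the
#' selected round marked.
#'
#' @param object An `rf_protocol` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rf_protocol <- function(object, ...) {
  runs <- object$runs
  best <- object$selection
  ggplot2::ggplot(runs, ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = best$accuracy, colour = "red",
                        linetype = "dashed") +
    ggplot2::labs(x = "pooled two-class accuracy (OOB)", y = "rounds",
                  subtitle = sprintf("best round %d: accuracy %.3f, recall(A) %.3f",
                                     best$best_run, best$accuracy, best$recall_A)) +
    ggplot2::theme_minimal()
}

#' Plot the input-type comparison
#'
#' @param comparison Output of [compare_input_types()].
#' @return A ggplot object (accuracy and class-A recall per input type).
#' @export
plot_input_types <- function(comparison) {
  long <- comparison |>
    dplyr::mutate(input_type = paste0(.data$region, ":", .data$order)) |>
    tidyr::pivot_longer(c("accuracy", "recall_A"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$input_type, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "input type (region:order)", y = "best-model metric") +
    ggplot2::theme_minimal()
}

#' Heatmap of a position frequency matrix
#'
#' @param pfm Output of [position_frequency_matrix()].
#' @return A ggplot object (residues by alignment column).
#' @export
plot_pfm <- function(pfm) {
  long <- tibble::as_tibble(pfm, rownames = "residue") |>
    tidyr::pivot_longer(-"residue", names_to = "position",
                        values_to = "frequency") |>
    dplyr::mutate(position = factor(.data$position,
                                    levels = colnames(pfm)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$residue,
                                     fill = .data$frequency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkblue") +
    ggplot2::labs(x = "position relative to anchor", y = NULL) +
    ggplot2::theme_minimal()
}
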