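#' Plot the MDVs of a dataset
#'
#' Bar chart of the mass isotopomer fractions per fragment, one bar group per
#' chromatogram, faceted by fragment.
#'
#' @param object An `mdv_dataset` (typically corrected fractions).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mdv_dataset <- function(object, ...) {
  long <- tidy.mdv_dataset(object)
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$weight),
                                     y = .data$value,
                                     fill = .data$chromatogram)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$fragment), scales = "free_x") +
    ggplot2::labs(x = "mass shift (M+i)", y = "fraction",
                  fill = "chromatogram")
}

#' Plot an average-labeling summary
#'
#' Per-MDV average labeling by chromatogram, with one panel per analyte;
#' unlabeled control samples should sit near zero.
#'
#' @param object A `labeling_summary` from [summarize_labeling()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.labeling_summary <- function(object, ...) {
  ggplot2::ggplot(object$per_mdv,
                  ggplot2::aes(x = .data$chromatogram, y = .data$labeling,
                               colour = .data$fragment)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$analyte)) +
    ggplot2::labs(x = NULL, y = "average labeling") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a QC feedback mask
#'
#' Tile map of the flagged cells, mirroring the TSV overlay: rows are
#' analyte/mass, columns chromatograms.
#'
#' @param object A `qc_mask`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qc_mask <- function(object, ...) {
  long <- qc_flags(object)
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$chromatogram,
                               y = paste(.data$analyte, .data$mass),
                               fill = .data$flag)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = NULL, y = NULL, fill = "flag")
}
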