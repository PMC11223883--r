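#' Plot a disorder profile
#'
#' Per-residue disorder score with the calling threshold and shaded IDR
#' segments.
#'
#' @param object A `disorder_profile`.
#' @param min_len Minimum IDR length used for shading (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot disorder_profile
#' @export
autoplot.disorder_profile <- function(object, min_len = 10L, ...) {
  idrs <- segment_idrs(object, min_len = min_len)
  thr <- attr(object, "threshold")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$score))
  if (nrow(idrs) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = idrs,
      ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "grey85"
    )
  }
  p +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed", color = "firebrick") +
    ggplot2::labs(
      x = "residue position", y = "disorder score",
      title = paste0("Disorder profile (", attr(object, "mode"), ", threshold ", thr, ")")
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Map degron matches along a protein
#'
#' Draws each match as a segment at its sequence position, grouped by
#' location class, for one protein.
#'
#' @param matches Match tibble from [scan_degrons()].
#' @param protein Optional one-row protein tibble (sets the x-axis limit).
#' @return A ggplot object.
#' @export
plot_degron_map <- function(matches, protein = NULL) {
  stopifnot(is.data.frame(matches))
  if (nrow(matches) == 0L) stop("no matches to plot")
  p <- ggplot2::ggplot(matches, ggplot2::aes(
    x = .data$start, xend = .data$end,
    y = .data$motif_id, yend = .data$motif_id,
    color = .data$location_class
  )) +
    ggplot2::geom_segment(linewidth = 3) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(
      x = "residue position", y = NULL, color = "location",
      title = paste("Degron matches:", paste(unique(matches$protein_id), collapse = ", "))
    ) +
    ggplot2::theme_minimal()
  if (!is.null(protein)) {
    p <- p + ggplot2::xlim(1, nchar(protein$sequence))
  }
  p
}

#' Plot held-out predictions of a PSI model
#'
#' Observed versus predicted PSI on the held-out test split.
#'
#' @param object A `psi_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot psi_model
#' @export
autoplot.psi_model <- function(object, ...) {
  ggplot2::ggplot(object$test, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.4, color = "steelblue") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "observed PSI", y = "predicted PSI",
      title = sprintf("PSI model (%s): held-out R² = %.3f, RMSE = %.3f",
        object$terminus, object$metrics$r2_test, object$metrics$rmse_test)
    ) +
    ggplot2::theme_minimal()
}
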