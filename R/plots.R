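#' Plot a shuffle-null count distribution
#'
#' Histogram of motif counts over the shuffled sequences with the observed
#' count marked; the further the observed count sits in the right tail, the
#' less the hit is explained by residue composition alone.
#'
#' @param object A [shuffle_null()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shuffle_null <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count)) +
    ggplot2::geom_bar(fill = "grey65") +
    ggplot2::geom_vline(xintercept = object$observed_count,
                        colour = "firebrick", linetype = "dashed") +
    ggplot2::labs(
      x = "motif count in shuffled sequence",
      y = "shuffles",
      title = sprintf("%s: observed %d, empirical p = %.3g",
                      object$protein_id, object$observed_count,
                      object$empirical_p)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-ortholog motif conservation
#'
#' One point per ortholog row at its best hit's column distance from the
#' reference motif column; rows without any hit are shown at the top
#' margin. The dashed line marks the tolerance window.
#'
#' @param object A [conservation_score()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.conservation_result <- function(object, ...) {
  df <- tidy(object) |>
    mutate(column_distance = ifelse(is.na(.data$column_distance),
                                    Inf, .data$column_distance))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$species, y = pmin(.data$column_distance, object$window * 2),
    colour = .data$conserved
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = object$window, linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "forestgreen", `FALSE` = "firebrick")
    ) +
    ggplot2::labs(
      x = NULL, y = "column distance to reference motif",
      title = sprintf("Conserved fraction %.2f (window %d columns)",
                      object$conserved_fraction, object$window)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot two ensembles' RMSD distributions
#'
#' Jittered per-model RMSDs for both constructs with the tandem threshold
#' marked; the tandem fraction of each construct is the share of points
#' below the line.
#'
#' @param object An [compare_ensembles()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ensemble_comparison <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$construct, y = .data$rmsd,
                                   colour = .data$tandem)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, size = 2) +
    ggplot2::geom_hline(yintercept = object$threshold,
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "forestgreen", `FALSE` = "grey40")
    ) +
    ggplot2::labs(
      x = NULL, y = "RMSD to reference region (Å)",
      title = sprintf(
        "Tandem fractions %.2f vs %.2f (Welch p = %.3g)",
        object$fraction_tandem_a, object$fraction_tandem_b, object$p_value
      )
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
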