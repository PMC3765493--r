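#' Plot corrected versus standard-alignment allelic ratios
#'
#' Scatter of paired |log10| folded ratios with the fitted correction line
#' and the identity line; the gap between the two shows how much standard
#' alignment inflates allelic ratios.
#'
#' @param object An `aei_lm` fit from [compare_alignment_methods()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aei_lm <- function(object, ...) {
  d <- object$lm$model
  ggplot2::ggplot(d, ggplot2::aes(.data$log10_standard, .data$log10_corrected)) +
    ggplot2::geom_point(alpha = 0.4, size = 1) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "#2166ac") +
    ggplot2::labs(
      x = "standard alignment, log10 folded ratio",
      y = "corrected alignment, log10 folded ratio",
      title = sprintf("slope %.2f, r² %.2f (identity dotted)",
                      object$slope, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot gene-level AEI calls for one sample set
#'
#' Mean folded ratio per gene with +/- 2 SD bars where defined, coloured by
#' call, with the calling threshold drawn.
#'
#' @param calls Output of [call_aei()].
#' @param threshold Threshold line to draw (default 2).
#' @return A ggplot object.
#' @export
plot_gene_aei <- function(calls, threshold = 2) {
  d <- as_tibble(calls) %>%
    mutate(gene_label = stats::reorder(paste(.data$gene, .data$sample_id),
                                       .data$mean_folded))
  ggplot2::ggplot(d, ggplot2::aes(.data$gene_label, .data$mean_folded,
                                  colour = .data$aei_call)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(1, .data$mean_folded - 2 * dplyr::coalesce(.data$sd_folded, 0)),
      ymax = .data$mean_folded + 2 * dplyr::coalesce(.data$sd_folded, 0)
    ), linewidth = 0.3, size = 0.3) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean folded allelic ratio (≥ 1)",
                  colour = "AEI call") +
    ggplot2::theme_minimal()
}

#' Plot editing levels across two conditions
#'
#' Per-site mean editing percentage in condition A against condition B with
#' SEM bars and the identity line; tightly correlated sites fall on the
#' diagonal.
#'
#' @param panel A tibble with columns `pct_a`, `sem_a`, `pct_b`, `sem_b`
#'   and optionally `gene`; [brain_editing_sites()] output can be renamed
#'   into this shape.
#' @param labels Axis labels, length 2.
#' @return A ggplot object.
#' @export
plot_editing_comparison <- function(panel,
                                    labels = c("condition A", "condition B")) {
  ggplot2::ggplot(as_tibble(panel), ggplot2::aes(.data$pct_a, .data$pct_b)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$pct_b - .data$sem_b,
                                        ymax = .data$pct_b + .data$sem_b),
                           width = 0, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$pct_a - .data$sem_a,
                                         xmax = .data$pct_a + .data$sem_a),
                            height = 0, colour = "grey60") +
    ggplot2::geom_point(size = 2, colour = "#b2182b") +
    ggplot2::labs(x = paste0("% edited, ", labels[1]),
                  y = paste0("% edited, ", labels[2])) +
    ggplot2::lims(x = c(0, 100), y = c(0, 100)) +
    ggplot2::theme_minimal()
}
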