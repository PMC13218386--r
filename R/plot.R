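#' Manhattan plot of a genome scan
#'
#' Markers in map order, \eqn{-\log_{10} p} on the vertical axis, alternating
#' chromosome shading and the Bonferroni threshold as a dashed line.
#'
#' @param object a [psr_scan()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot psr_scan
#' @export
autoplot.psr_scan <- function(object, ...) {
  thr <- attr(object, "threshold")
  df <- dplyr::mutate(tibble::as_tibble(object),
    index = dplyr::row_number(),
    chrom = factor(.data$chrom, levels = unique(.data$chrom))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$index, .data$neglog10p, colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::geom_hline(
      yintercept = thr$neglog10p_crit, linetype = "dashed", colour = "grey30"
    ) +
    ggplot2::scale_colour_manual(
      values = rep(c("#2c7fb8", "#636363"), length.out = nlevels(df$chrom))
    ) +
    ggplot2::labs(
      x = "marker index", y = expression(-log[10] ~ p),
      title = paste0("Genome scan (", attr(object, "method"), ", ",
        attr(object, "family")$name, ")")
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.psr_scan
#' @param scan a [psr_scan()] result.
#' @export
plot_manhattan <- function(scan) autoplot.psr_scan(scan)

#' ROC curves of a power study
#'
#' One panel per QTL effect size, one curve per scan method.
#'
#' @param object a [run_power_study()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot psr_power
#' @export
autoplot.psr_power <- function(object, ...) {
  ggplot2::ggplot(
    object$roc,
    ggplot2::aes(.data$fpr, .data$tpr, colour = .data$method)
  ) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(~effect, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
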