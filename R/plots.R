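#' PCA scatter of samples
#'
#' @param scores tibble from [pca_plot_data()].
#' @return A ggplot: PC1 vs PC2, colored by group, axis labels carrying the
#'   percentage of variance explained.
#' @export
plot_pca_scores <- function(scores) {
  ve <- attr(scores, "var_explained")
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                       colour = .data$group)) +
    ggplot2::geom_point(size = 2, alpha = 0.85) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", ve[1]),
                  y = sprintf("PC2 (%.1f%%)", ve[2]),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential abundance
#'
#' @param results tibble from [run_differential()].
#' @param cfg a [pipeline_config()] supplying the dual-criterion thresholds
#'   drawn as guides.
#' @return A ggplot of log2 fold change against -log10 q.
#' @export
plot_volcano <- function(results, cfg = pipeline_config()) {
  df <- dplyr::mutate(results, log2_fc = log2(.data$fold_change),
                      neglog_q = -log10(pmax(.data$q_value, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fc, y = .data$neglog_q,
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1.2) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(cfg$fc_threshold),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(cfg$fdr_threshold),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (pregnant / non-pregnant)",
                  y = "-log10 FDR", colour = "significant") +
    ggplot2::theme_minimal()
}

#' Gestational-age trend plot for one metabolite
#'
#' Log2 abundance against gestational age among pregnant samples with the
#' least-squares trend line; non-pregnant samples are shown as a reference
#' strip left of the gestational-age axis.
#'
#' @param x an `abund` (typically the adjusted matrix).
#' @param meta sample metadata.
#' @param metabolite_id the metabolite to plot.
#' @return A ggplot.
#' @export
plot_ga_trend <- function(x, meta, metabolite_id) {
  stopifnot(metabolite_id %in% rownames(x$values))
  meta <- align_meta(x, meta)
  keep <- meta$group %in% c("pregnant", "non_pregnant")
  df <- tibble::tibble(
    group = meta$group[keep],
    ga = meta$gestational_age[keep],
    log2_abund = log2(x$values[metabolite_id, meta$sample_id[keep]])
  )
  ga_min <- min(df$ga, na.rm = TRUE)
  df$ga[df$group == "non_pregnant"] <- ga_min - 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ga, y = .data$log2_abund,
                                   colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_smooth(data = df[df$group == "pregnant", ],
                         method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6, colour = "black") +
    ggplot2::labs(title = metabolite_id, x = "gestational age (weeks)",
                  y = "log2 abundance", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Autoplot methods
#'
#' `autoplot()` on a `gravidmet_run` draws the PCA scatter
#' (`type = "pca"`, on the adjusted matrix) or the volcano plot
#' (`type = "volcano"`, unadjusted branch).
#'
#' @param object a `gravidmet_run`.
#' @param type `"pca"` or `"volcano"`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot gravidmet_run
#' @export
autoplot.gravidmet_run <- function(object, type = c("pca", "volcano"), ...) {
  type <- match.arg(type)
  if (type == "pca") {
    keep <- object$metadata$group %in% c("pregnant", "non_pregnant")
    sub <- abund_subset_samples(object$adjusted,
                                object$metadata$sample_id[keep])
    plot_pca_scores(pca_plot_data(sub, object$metadata[keep, ]))
  } else {
    headline <- if (!is.null(object$diff_raw)) object$diff_raw else
      object$diff_adjusted
    plot_volcano(headline, object$config)
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
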