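#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of each result type:
#' stability statistics per gene, the comprehensive ranking, a fitted
#' standard curve with its dilution points, group-wise fold changes with SEM
#' error bars, and location-wise Ct box plots.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot.
#' @name refstab-plots
NULL

#' @rdname refstab-plots
#' @export
autoplot.stability_result <- function(object, ...) {
  d <- dplyr::arrange(object$per_gene, .data$statistic)
  d$gene <- factor(d$gene, levels = d$gene)
  ylab <- switch(object$method,
                 delta_ct = "Mean pairwise dCt SD (cycles)",
                 genorm = "geNorm M value",
                 normfinder = "NormFinder stability value",
                 bestkeeper = "BestKeeper Ct dispersion (cycles)")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gene, y = .data$statistic)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = ylab,
                  title = paste0("Reference-gene stability (", object$method, ")"),
                  subtitle = "lower = more stable") +
    ggplot2::theme_minimal()
}

#' @rdname refstab-plots
#' @export
autoplot.comprehensive_ranking <- function(object, ...) {
  d <- tidy.comprehensive_ranking(object)
  d$gene <- factor(d$gene, levels = d$gene)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gene, y = .data$geomean)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = NULL, y = "Geometric mean of method ranks",
                  title = "Comprehensive reference-gene ranking") +
    ggplot2::theme_minimal()
}

#' @rdname refstab-plots
#' @export
autoplot.standard_curve <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$log10_dilution, y = .data$ct)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "grey40") +
    ggplot2::labs(x = "log10 dilution", y = "Ct",
                  title = sprintf("Standard curve: slope %.3f, E = %.1f%%, R2 = %.3f",
                                  object$slope, object$efficiency_pct,
                                  object$r_squared)) +
    ggplot2::theme_minimal()
}

#' @rdname refstab-plots
#' @export
autoplot.expression_result <- function(object, ...) {
  ggplot2::ggplot(object$per_group,
                  ggplot2::aes(x = .data$group, y = .data$mean_fold)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_fold,
                                        ymax = .data$mean_fold + .data$sem_fold),
                           width = 0.3) +
    ggplot2::labs(x = NULL, y = "Relative expression (fold change)",
                  title = sprintf("%s normalized to %s (2^-ddCt, mean + SEM)",
                                  object$goi,
                                  paste(object$refs, collapse = "+"))) +
    ggplot2::theme_minimal()
}

#' Box plots of a gene's Ct by group and location
#'
#' @param ct A `ct_tbl` with `group` and `location` columns.
#' @param gene Gene to plot.
#' @return A ggplot of Ct distributions, one box per group x location arm.
#' @export
plot_location_ct <- function(ct, gene) {
  ct <- validate_ct_tbl(as_ct_tbl(ct))
  d <- ct[ct$gene == gene & !is.na(ct$ct), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$ct,
                                  fill = .data$location)) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::scale_fill_manual(values = c("white", "grey70")) +
    ggplot2::labs(x = NULL, y = "Ct", title = paste0(gene, " Ct by location")) +
    ggplot2::theme_minimal()
}
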