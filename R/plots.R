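module_fill_scale <- function(modules) {
  known <- grDevices::colors()
  vals <- ifelse(modules %in% known, modules, "grey30")
  ggplot2::scale_fill_manual(values = setNames(vals, modules), guide = "none")
}

#' Soft-threshold diagnostic plot
#'
#' Scale-free fit index and mean connectivity as a function of the candidate
#' soft-thresholding power.
#'
#' @param report Tibble from [soft_threshold_report()].
#' @return A ggplot object.
#' @export
plot_soft_threshold <- function(report) {
  long <- tidyr::pivot_longer(report,
    c("scale_free_r2", "mean_connectivity"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$power, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "soft-threshold power", y = NULL) +
    ggplot2::theme_bw()
}

#' @describeIn fit_coexpression_modules Eigengene profiles per module as
#'   per-sample bars.
#' @param object A `coex_fit` object.
#' @export
autoplot.coex_fit <- function(object, ...) {
  if (is.null(object$eigengenes)) abort("fit has no modules to plot")
  long <- tidyr::pivot_longer(object$eigengenes, -"sample_id",
                              names_to = "module", values_to = "eigengene")
  long$sample_id <- factor(long$sample_id,
                           levels = object$eigengenes$sample_id)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id,
                                     y = .data$eigengene,
                                     fill = .data$module)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~module, ncol = 1) +
    module_fill_scale(unique(long$module)) +
    ggplot2::labs(x = NULL, y = "module eigengene") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 5))
}

#' Plot standardized eigengene contrasts per module
#'
#' @param contrasts Tibble from [eigengene_contrast()].
#' @param effect_threshold Reference line for the selection cutoff.
#' @return A ggplot object.
#' @export
plot_module_contrast <- function(contrasts, effect_threshold = 1) {
  ggplot2::ggplot(contrasts, ggplot2::aes(x = .data$module,
                                          y = .data$effect,
                                          fill = .data$module)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-1, 1) * effect_threshold,
                        linetype = "dashed") +
    module_fill_scale(unique(contrasts$module)) +
    ggplot2::labs(x = NULL, y = "standardized eigengene contrast") +
    ggplot2::theme_bw()
}

#' Plot log2 fold changes of selected proteins over conditions
#'
#' @param log2fc A fold-change tibble from [log2fc_invitro()] or
#'   [log2fc_biopsy()].
#' @param proteins Accessions to display (default: all rows).
#' @return A ggplot object.
#' @export
plot_log2fc <- function(log2fc, proteins = NULL) {
  if (!is.null(proteins)) {
    log2fc <- dplyr::filter(log2fc, .data$accession %in% proteins)
  }
  long <- tidyr::pivot_longer(log2fc, -"accession",
                              names_to = "condition", values_to = "log2fc")
  long$condition <- factor(long$condition,
                           levels = setdiff(names(log2fc), "accession"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$log2fc,
                                     group = .data$accession,
                                     colour = .data$accession)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "log2 fold change vs control") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @describeIn build_induced_network Degree distribution of a PPI graph,
#'   with the hub threshold marked.
#' @param object A `ppi_graph` object.
#' @param hub_min_degree Hub threshold to mark (default 30).
#' @param ... Unused.
#' @export
autoplot.ppi_graph <- function(object, hub_min_degree = 30, ...) {
  ggplot2::ggplot(object$nodes, ggplot2::aes(x = .data$degree)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "steelblue") +
    ggplot2::geom_vline(xintercept = hub_min_degree, linetype = "dashed") +
    ggplot2::labs(x = "degree", y = "proteins") +
    ggplot2::theme_bw()
}
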