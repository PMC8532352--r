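# broom-style tidiers and plots -------------------------------------------

#' Tidy a differential-expression result
#'
#' @param x A `tx_de`.
#' @param ... Unused.
#' @return Tibble with one row per tested EC; `members` flattened to a
#'   comma-joined id string.
#' @export
tidy.tx_de <- function(x, ...) {
  res <- x$results
  tibble(ec = vapply(res$members, function(m) paste(x$ids[m], collapse = ","),
                     character(1)),
         case_count = res$case_count, case_cpm = res$case_cpm,
         logFC = res$logFC, lrt_stat = res$lrt_stat, p_value = res$p_value,
         fdr = res$fdr, significant = res$significant)
}

#' @rdname tidy.tx_de
#' @export
glance.tx_de <- function(x, ...) {
  tibble(n_ecs = x$n_input_ecs, n_tested = nrow(x$results),
         n_significant = sum(x$results$significant),
         dispersion = x$params$dispersion, fdr_max = x$params$fdr_max,
         logfc_min = x$params$logfc_min)
}

#' Tidy a benchmark evaluation
#'
#' @param x A `tx_eval`.
#' @param ... Unused.
#' @return Per-type recall tibble.
#' @export
tidy.tx_eval <- function(x, ...) x$per_type

#' @rdname tidy.tx_eval
#' @export
glance.tx_eval <- function(x, ...) {
  tibble(recall = x$overall, n_detected = x$n_detected, n_truth = x$n_truth,
         fusion_recall = group_recall(x, "fusion"),
         tsv_recall = group_recall(x, "tsv"),
         nsv_recall = group_recall(x, "nsv"),
         classification_consistency = x$classification_consistency,
         fp_background = x$fp_background, fp_outside = x$fp_outside)
}

#' Volcano-style plot of a differential-expression result
#'
#' @param object A `tx_de`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tx_de <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$logFC,
                                  y = -log10(pmax(.data$fdr, 1e-300)),
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = object$params$logfc_min, linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(object$params$fdr_max), linetype = 2) +
    ggplot2::labs(x = "log2 fold change (case vs controls)",
                  y = "-log10 FDR", colour = "significant") +
    ggplot2::theme_minimal()
}

#' Per-type recall barplot for a benchmark evaluation
#'
#' @param object A `tx_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tx_eval <- function(object, ...) {
  d <- tidy(object)
  d$vtype <- factor(d$vtype, levels = VARIANT_TYPES)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$vtype, y = .data$recall,
                                  fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(limits = c(0, 1), labels = function(x) sprintf("%d%%", round(100 * x))) +
    ggplot2::labs(x = NULL, y = "recall (gene-hit rule)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
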