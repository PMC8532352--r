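# Benchmark evaluation -----------------------------------------------------

#' Evaluate variant calls against a benchmark truth table
#'
#' Applies the gene-hit counting rule: a truth variant counts as detected
#' when any call's gene set intersects its gene set (either partner suffices
#' for fusions; classifications are ignored for recall). Classification
#' consistency is computed over calls inside simulated variant genes: the
#' fraction whose class belongs to the plausible class set of a truth
#' variant in that gene. False positives are split into calls in background
#' genes and calls outside all simulated genes.
#'
#' @param calls Tibble of variant calls (from [run_pipeline()] or
#'   [refine_and_classify()]).
#' @param benchmark A `tx_benchmark` (supplies truth and background genes).
#' @return Object of class `tx_eval` with `per_type` (tibble: `vtype`,
#'   `group`, `n`, `detected`, `recall`), `overall` recall, `n_detected`,
#'   `fp_background`, `fp_outside` and `classification_consistency`.
#' @export
evaluate_calls <- function(calls, benchmark) {
  truth <- benchmark$truth
  call_genes <- unique(setdiff(unlist(calls$genes), "intergenic"))
  known <- unique(c(unlist(truth$genes), benchmark$background_genes,
                    benchmark$annotation$genes$gene_id))
  unknown <- setdiff(call_genes, known)
  if (length(unknown)) {
    abort(sprintf("call gene id(s) not in the benchmark annotation: %s",
                  paste(head(unknown, 3), collapse = ", ")))
  }
  detected <- vapply(truth$genes, function(g) any(g %in% call_genes), logical(1))
  per_type <- truth |>
    mutate(detected = detected) |>
    group_by(.data$vtype, .data$group) |>
    summarise(n = n(), detected = sum(.data$detected), .groups = "drop") |>
    mutate(recall = .data$detected / .data$n) |>
    arrange(match(.data$vtype, VARIANT_TYPES))

  variant_genes <- unique(unlist(truth$genes))
  classes_by_gene <- list()
  for (i in seq_len(nrow(truth))) {
    for (g in truth$genes[[i]]) {
      classes_by_gene[[g]] <- union(classes_by_gene[[g]], truth$expected_classes[[i]])
    }
  }
  in_gene <- vapply(calls$genes, function(g) any(g %in% variant_genes), logical(1))
  consistent <- vapply(which(in_gene), function(i) {
    gs <- intersect(calls$genes[[i]], variant_genes)
    any(calls$vclass[i] %in% unlist(classes_by_gene[gs]))
  }, logical(1))
  fp_background <- sum(vapply(calls$genes, function(g)
    !any(g %in% variant_genes) && any(g %in% benchmark$background_genes), logical(1)))
  fp_outside <- sum(vapply(calls$genes, function(g)
    !any(g %in% c(variant_genes, benchmark$background_genes)), logical(1)))

  structure(list(
    per_type = per_type,
    overall = sum(detected) / nrow(truth),
    n_detected = sum(detected),
    n_truth = nrow(truth),
    fp_background = fp_background,
    fp_outside = fp_outside,
    classification_consistency = if (sum(in_gene)) mean(consistent) else NA_real_,
    n_calls_in_gene = sum(in_gene)
  ), class = "tx_eval")
}

#' @export
print.tx_eval <- function(x, ...) {
  cat(sprintf("<tx_eval> overall recall %.1f%% (%d/%d); consistency %.1f%%; FP bg/out %d/%d\n",
              100 * x$overall, x$n_detected, x$n_truth,
              100 * x$classification_consistency, x$fp_background, x$fp_outside))
  print(as.data.frame(x$per_type))
  invisible(x)
}

# group-level recalls used by the benchmark report
group_recall <- function(eval, grp) {
  pt <- eval$per_type[eval$per_type$group == grp, ]
  sum(pt$detected) / sum(pt$n)
}
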