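# Pipeline orchestration ---------------------------------------------------

#' Pipeline configuration
#'
#' Collects every tunable of the quantification, differential-expression and
#' annotation stages with the method's default thresholds: k = 31,
#' dispersion 0.1, case CPM > 0.1, FDR < 0.05, logFC > 2, indel gap >= 7 bp,
#' clips >= 20 bp, novel blocks >= 20 bp, aligned >= 30 bp and 30%, minimum
#' contig length 150 bp.
#'
#' @param k K-mer length.
#' @param min_contig_len Contigs shorter than this are dropped on input.
#' @param de A `de_params`.
#' @param ann An `annotate_params`.
#' @param min_frac Minimum present-k-mer fraction per read orientation.
#' @param seed Top-level seed; per-stage seeds derive from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(k = 31L, min_contig_len = 150L, de = de_params(),
                            ann = annotate_params(), min_frac = 0.5,
                            seed = 1L) {
  structure(list(k = as.integer(k), min_contig_len = as.integer(min_contig_len),
                 de = de, ann = ann, min_frac = min_frac,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as flat key=value text
#'
#' @param config A `pipeline_config`.
#' @param path File path.
#' @return `path` (write) or a `pipeline_config` (read).
#' @export
write_config <- function(config, path) {
  flat <- c(k = config$k, min_contig_len = config$min_contig_len,
            min_frac = config$min_frac, seed = config$seed,
            setNames(unlist(config$de), paste0("de.", names(config$de))),
            setNames(unlist(config$ann), paste0("ann.", names(config$ann))))
  writeLines(sprintf("%s=%s", names(flat), as.character(flat)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  vals <- setNames(vapply(kv, `[[`, character(1), 2),
                   vapply(kv, `[[`, character(1), 1))
  num <- function(x) as.numeric(x)
  de_names <- sub("^de\\.", "", grep("^de\\.", names(vals), value = TRUE))
  de <- do.call(de_params, as.list(setNames(num(vals[paste0("de.", de_names)]), de_names)))
  an_raw <- vals[grep("^ann\\.", names(vals))]
  names(an_raw) <- sub("^ann\\.", "", names(an_raw))
  an <- annotate_params(
    gap_min = num(an_raw[["gap_min"]]), clip_min = num(an_raw[["clip_min"]]),
    block_min = num(an_raw[["block_min"]]),
    min_aligned_bp = num(an_raw[["min_aligned_bp"]]),
    min_aligned_frac = num(an_raw[["min_aligned_frac"]]),
    motif_check = an_raw[["motif_check"]] %in% c("TRUE", "true", "1"),
    motif_tolerance = num(an_raw[["motif_tolerance"]]))
  pipeline_config(k = num(vals[["k"]]), min_contig_len = num(vals[["min_contig_len"]]),
                  de = de, ann = an, min_frac = num(vals[["min_frac"]]),
                  seed = num(vals[["seed"]]))
}

#' Run the full detection pipeline
#'
#' Quantifies case and control reads against contigs merged with the
#' reference transcriptome, matches equivalence classes across samples,
#' keeps the contig-only (novel) classes, tests them for case
#' over-expression (or applies the CPM-only selection when no controls are
#' given), and classifies the retained contigs from their spliced genome
#' alignments.
#'
#' @param case_reads `list(r1, r2)` or two FASTQ paths for the case sample.
#' @param control_reads_list List of the same, one entry per control (may be
#'   empty for the no-control mode).
#' @param contigs Assembled contigs (named vector, `DNAStringSet` or FASTA
#'   path).
#' @param ref_tx Reference transcriptome (same forms).
#' @param genome Genome sequences (for motif checks; may be `NULL` when
#'   motif checking is off).
#' @param annotation A `tx_annotation` (or GTF path).
#' @param sam Spliced contig alignments: a SAM path or a record tibble as
#'   produced by [truth_alignments()].
#' @param config A `pipeline_config`.
#' @return Object of class `tx_pipeline_result`: `calls` tibble, `de`
#'   (`tx_de` or `NULL`), `retained_contigs`, `matrix` (full matched EC
#'   matrix) and a `summary` tibble of per-stage counts.
#' @export
run_pipeline <- function(case_reads, control_reads_list, contigs, ref_tx,
                         genome, annotation, sam,
                         config = pipeline_config()) {
  if (is.character(annotation)) annotation <- read_gtf(annotation)
  contigs <- as_named_seqs(contigs)
  n_contigs_in <- length(contigs)
  contigs <- contigs[nchar(contigs) >= config$min_contig_len]
  if (length(contigs) == 0) {
    warn("no contigs pass the length filter; returning empty results")
    return(empty_pipeline_result(n_contigs_in))
  }
  index <- build_ec_index(contigs, ref_tx, k = config$k)

  tables <- list(count_ecs(index, case_reads, "case", config$min_frac))
  for (i in seq_along(control_reads_list)) {
    tables[[i + 1]] <- count_ecs(index, control_reads_list[[i]],
                                 sprintf("control%d", i), config$min_frac)
  }
  mat <- match_ecs(tables, "case")
  novel <- filter_novel_ecs(mat)

  controls_present <- length(control_reads_list) > 0
  de <- NULL
  if (controls_present) {
    de <- run_diffexp(novel, config$de)
    retained <- select_significant_contigs(de, novel, config$de, TRUE)
  } else {
    retained <- select_significant_contigs(NULL, novel, config$de, FALSE)
  }

  records <- if (is.character(sam)) load_alignments(sam) else {
    tibble(contig_id = sam$qname, chrom = sam$rname, pos = sam$pos - 1L,
           strand = ifelse(bitwAnd(sam$flag, 16L) > 0L, "-", "+"),
           cigar = sam$cigar,
           is_supplementary = bitwAnd(sam$flag, 2048L) > 0L,
           contig_length = nchar(sam$seq))
  }
  records <- records[records$contig_id %in% retained, ]
  kept <- filter_alignments(records, annotation, config$ann)
  records <- records[records$contig_id %in% kept, ]
  cand <- detect_raw_variants(records, annotation, config$ann)
  calls <- refine_and_classify(cand, records, annotation, genome, config$ann)
  calls <- estimate_vaf(calls, mat, annotation)
  calls <- attach_de_stats(calls, de, mat)

  summary <- tibble(
    stage = c("contigs_in", "contigs_len_ok", "ecs_matched", "ecs_novel",
              "ecs_significant", "contigs_retained", "contigs_aligned_ok", "calls"),
    n = c(n_contigs_in, length(contigs), nrow(mat$counts), nrow(novel$counts),
          if (is.null(de)) NA_integer_ else sum(de$results$significant),
          length(retained), length(kept), nrow(calls)))
  structure(list(calls = calls, de = de, retained_contigs = retained,
                 matrix = mat, summary = summary, config = config),
            class = "tx_pipeline_result")
}

empty_pipeline_result <- function(n_in) {
  structure(list(
    calls = tibble(contig_id = character(), vclass = character(), genes = list(),
                   chrom = character(), start = integer(), end = integer(),
                   size_bp = integer(), junction = character(),
                   motif_valid = logical(), vaf = numeric(), logFC = numeric(),
                   fdr = numeric(), case_cpm = numeric()),
    de = NULL, retained_contigs = character(), matrix = NULL,
    summary = tibble(stage = "contigs_in", n = n_in)), class = "tx_pipeline_result")
}

# carry the best (lowest-FDR) DE statistics of any significant EC containing
# each called contig
attach_de_stats <- function(calls, de, mat) {
  if (nrow(calls) == 0) {
    calls$logFC <- numeric(0); calls$fdr <- numeric(0); calls$case_cpm <- numeric(0)
    return(calls)
  }
  if (is.null(de)) {
    calls$logFC <- NA_real_; calls$fdr <- NA_real_; calls$case_cpm <- NA_real_
    return(calls)
  }
  res <- de$results
  per_contig <- res |>
    filter(.data$significant) |>
    tidyr::unnest_longer(col = "members", values_to = "member") |>
    mutate(contig_id = de$ids[.data$member]) |>
    group_by(.data$contig_id) |>
    arrange(.data$fdr) |>
    summarise(logFC = .data$logFC[1], fdr = .data$fdr[1],
              case_cpm = .data$case_cpm[1], .groups = "drop")
  calls |>
    left_join(per_contig, by = "contig_id")
}

#' @export
print.tx_pipeline_result <- function(x, ...) {
  cat("<tx_pipeline_result>\n")
  s <- x$summary
  cat(paste0(sprintf("  %-20s %s", s$stage, s$n), collapse = "\n"), "\n")
  invisible(x)
}
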