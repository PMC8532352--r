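# Benchmark construction --------------------------------------------------

#' Build a heterozygous case/control variant benchmark
#'
#' Draws `per_type` variants of each of the 15 types from distinct eligible
#' genes of a synthetic genome, plus `n_background` unaltered background
#' genes. The case reference holds, per variant, the variant sequence AND its
#' unaltered wild-type transcript (heterozygous design: with equal
#' per-sequence coverage the gene is expressed at twice the variant
#' coverage); the control reference holds the wild-type sequences only.
#' Background genes appear unaltered in both, at the same total coverage as
#' variant genes (coverage scale 2).
#'
#' @param sg A `synthetic_genome` from [generate_synthetic_genome()].
#' @param per_type Variants per type (15 types total).
#' @param n_background Number of unaltered background genes in the case.
#' @param seed Integer seed; the benchmark is deterministic given the seed.
#' @return An object of class `tx_benchmark`: `truth` tibble (one row per
#'   variant with plan, sequence, genes and expected classes),
#'   `case_reference` / `control_reference` named sequence vectors with
#'   `case_scale` / `control_scale` per-sequence coverage multipliers,
#'   `background_genes`, and the annotation/genome.
#' @export
build_benchmark <- function(sg, per_type = 100L, n_background = 100L, seed = 1L) {
  stopifnot(inherits(sg, "synthetic_genome"))
  annotation <- sg$annotation
  genome <- sg$genome
  set.seed(seed)
  elig <- select_eligible_transcripts(annotation)
  # partnered fusion subtypes consume two genes each
  need <- per_type * 19L + n_background
  if (nrow(elig) < need) {
    abort(sprintf("need %d eligible single-isoform genes, found %d (short by %d)",
                  need, nrow(elig), need - nrow(elig)))
  }
  pool <- sample(elig$transcript_id)
  ptr <- 0L
  take_tx <- function() { ptr <<- ptr + 1L; pool[[ptr]] }

  desert_cursor <- setNames(sg$deserts$start + 1000L, sg$deserts$chrom)
  desert_end <- setNames(sg$deserts$end, sg$deserts$chrom)

  rows <- vector("list", per_type * 15L)
  ri <- 0L
  for (vtype in VARIANT_TYPES) {
    group <- variant_types()$group[match(vtype, VARIANT_TYPES)]
    for (i in seq_len(per_type)) {
      tx_a <- take_tx()
      truth <- if (group == "fusion") {
        if (vtype == "fusion_unpartnered") {
          chrom <- annotation$transcripts$chrom[match(tx_a, annotation$transcripts$transcript_id)]
          base <- desert_cursor[[chrom]]
          if (base + 2000L > desert_end[[chrom]]) {
            abort("intergenic desert exhausted; increase desert_len")
          }
          desert_cursor[[chrom]] <- base + 2000L
          make_fusion(annotation, genome, vtype, tx_a,
                      desert_base = list(chrom = chrom, base = base))
        } else {
          make_fusion(annotation, genome, vtype, tx_a, tx_b = take_tx())
        }
      } else if (group == "tsv") {
        make_tsv(annotation, genome, vtype, tx_a)
      } else {
        make_splice_variant(annotation, genome, vtype, tx_a)
      }
      ri <- ri + 1L
      rows[[ri]] <- tibble(
        variant_id = sprintf("%s_%03d", vtype, i),
        vtype = vtype, group = group,
        genes = list(truth$genes), transcripts = list(truth$transcripts),
        size_bp = truth$size_bp,
        variant_sequence = truth$variant_sequence,
        plan = list(truth$plan),
        expected_classes = list(truth$expected_classes)
      )
    }
  }
  truth <- bind_rows(rows)

  bg_tx <- sort(pool[ptr + seq_len(n_background)])
  primary_tx <- vapply(truth$transcripts, `[[`, character(1), 1L)
  wt_ids <- sort(primary_tx)
  tx_seqs <- transcript_sequences(annotation, genome, c(wt_ids, bg_tx))

  case_reference <- c(setNames(truth$variant_sequence, truth$variant_id),
                      tx_seqs[wt_ids], tx_seqs[bg_tx])
  case_scale <- c(rep(1, nrow(truth)), rep(1, length(wt_ids)), rep(2, length(bg_tx)))
  control_reference <- c(tx_seqs[wt_ids], tx_seqs[bg_tx])
  control_scale <- rep(2, length(control_reference))

  bg_genes <- annotation$transcripts$gene_id[match(bg_tx, annotation$transcripts$transcript_id)]
  structure(list(truth = truth,
                 case_reference = case_reference, case_scale = case_scale,
                 control_reference = control_reference, control_scale = control_scale,
                 background_genes = sort(bg_genes),
                 annotation = annotation, genome = genome, seed = seed),
            class = "tx_benchmark")
}

#' @export
print.tx_benchmark <- function(x, ...) {
  cat(sprintf("<tx_benchmark> %d variants (%d types), %d background genes\n",
              nrow(x$truth), dplyr::n_distinct(x$truth$vtype),
              length(x$background_genes)))
  invisible(x)
}

#' Ground-truth contigs for a benchmark
#'
#' One contig per simulated variant, equal to the variant transcript
#' sequence - the output a perfect assembler would produce. Used to study the
#' method independently of assembly quality.
#'
#' @param benchmark A `tx_benchmark`.
#' @return Named character vector of contig sequences (names are variant
#'   ids).
#' @export
perfect_contigs <- function(benchmark) {
  setNames(benchmark$truth$variant_sequence, benchmark$truth$variant_id)
}

#' Ground-truth spliced alignments for benchmark contigs
#'
#' Derives SAM records for each perfect contig from the simulator's segment
#' plans (see segment-plan alignment semantics in the package vignette): the stand-in
#' for running a spliced aligner on the contigs.
#'
#' @param benchmark A `tx_benchmark`.
#' @param max_intron Gaps larger than this split the alignment into
#'   supplementary records.
#' @return Tibble of SAM records (`qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`, `seq`), suitable for [write_sam()].
#' @export
truth_alignments <- function(benchmark, max_intron = 10000L) {
  purrr::map2_dfr(benchmark$truth$plan, seq_len(nrow(benchmark$truth)), function(p, i) {
    plan_to_sam(p, benchmark$truth$variant_id[i],
                benchmark$truth$variant_sequence[i],
                annotation = benchmark$annotation, max_intron = max_intron)
  })
}

#' Write a benchmark truth table to TSV
#'
#' @param benchmark A `tx_benchmark`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(benchmark, path) {
  t <- benchmark$truth
  out <- tibble(
    variant_id = t$variant_id, vtype = t$vtype, group = t$group,
    genes = vapply(t$genes, paste, character(1), collapse = ","),
    transcripts = vapply(t$transcripts, paste, character(1), collapse = ","),
    size_bp = t$size_bp,
    expected_classes = vapply(t$expected_classes, paste, character(1), collapse = ","),
    breakpoints = vapply(t$plan, function(p) {
      bp <- plan_breakpoints(p)
      paste(sprintf("%s:%d", bp$chrom, bp$pos), collapse = ",")
    }, character(1))
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
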