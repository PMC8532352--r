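# Variant construction and the benchmark ----------------------------------

test_that("eligibility excludes overlapping genes and <3-exon transcripts", {
  ann <- annotation_index(tibble::tibble(
    chrom = "chr1",
    start = c(10L, 100L, 200L, 400L, 500L, 600L, 630L, 720L, 800L, 1000L, 1100L),
    end = c(60L, 160L, 260L, 450L, 550L, 650L, 680L, 770L, 850L, 1050L, 1150L),
    strand = "+",
    gene_id = c(rep("gClean", 3), rep("gOvA", 3), rep("gOvB", 3), rep("gTwoExon", 2)),
    transcript_id = c(rep("tClean", 3), rep("tOvA", 3), rep("tOvB", 3), rep("tTwoExon", 2))))
  elig <- select_eligible_transcripts(ann)
  expect_identical(elig$transcript_id, "tClean")
  sg <- small_genome()
  expect_equal(nrow(select_eligible_transcripts(sg$annotation)), 60L)
})

test_that("canonical fusion joins the first two and last two exons", {
  sg <- small_genome()
  ann <- sg$annotation
  elig <- select_eligible_transcripts(ann)
  set.seed(21)
  tx_a <- elig$transcript_id[1]; tx_b <- elig$transcript_id[2]
  tr <- make_fusion(ann, sg$genome, "fusion_canonical", tx_a, tx_b)
  seq_of <- function(tx) transcript_sequence(ann, sg$genome, tx)
  ex_a <- ann$exons[ann$exons$transcript_id == tx_a, ]
  ex_b <- ann$exons[ann$exons$transcript_id == tx_b, ]
  tx_exon_seqs <- function(tx) {
    # exon sequences in transcription order
    full <- seq_of(tx)
    ex <- ann$exons[ann$exons$transcript_id == tx, ]
    w <- ex$end - ex$start
    if (ex$strand[1] == "-") w <- rev(w)
    ends <- cumsum(w)
    substring(full, c(1, utils::head(ends, -1) + 1), ends)
  }
  ea <- tx_exon_seqs(tx_a); eb <- tx_exon_seqs(tx_b)
  expect_identical(tr$variant_sequence,
                   paste0(ea[1], ea[2], eb[length(eb) - 1], eb[length(eb)]))
  expect_setequal(tr$genes, c(txsv:::tx_gene(ann, tx_a), txsv:::tx_gene(ann, tx_b)))
  # same-gene partners are rejected
  expect_error(make_fusion(ann, sg$genome, "fusion_canonical", tx_a, tx_a),
               "different genes")
})

test_that("fusion subtypes respect their insert size vocabularies", {
  sg <- small_genome()
  elig <- select_eligible_transcripts(sg$annotation)
  set.seed(31)
  for (i in 1:20) {
    txs <- sample(elig$transcript_id, 2)
    fi <- make_fusion(sg$annotation, sg$genome, "fusion_insertion", txs[1], txs[2])
    expect_true(fi$size_bp >= 7 && fi$size_bp <= 49)
    fe <- make_fusion(sg$annotation, sg$genome, "fusion_extended_exon", txs[1], txs[2])
    expect_true(fe$size_bp >= 30 && fe$size_bp <= 199)
    fn <- make_fusion(sg$annotation, sg$genome, "fusion_novel_exon", txs[1], txs[2])
    expect_true(fn$size_bp >= 30 && fn$size_bp <= 199)
  }
})

test_that("small TSVs edit within one exon: deletion length, tandem ITD, PTD layout", {
  sg <- small_genome()
  ann <- sg$annotation
  elig <- select_eligible_transcripts(ann)
  set.seed(41)
  for (i in 1:15) {
    tx <- sample(elig$transcript_id, 1)
    wt <- transcript_sequence(ann, sg$genome, tx)
    del <- make_tsv(ann, sg$genome, "del", tx)
    expect_equal(nchar(del$variant_sequence), nchar(wt) - del$size_bp)
    ins <- make_tsv(ann, sg$genome, "ins", tx)
    expect_equal(nchar(ins$variant_sequence), nchar(wt) + ins$size_bp)
    itd <- make_tsv(ann, sg$genome, "itd", tx)
    expect_equal(nchar(itd$variant_sequence), nchar(wt) + itd$size_bp)
    # the duplicated segment occurs twice in tandem: the ITD sequence
    # contains a doubled block absent from the wild type
    p <- itd$plan
    dup <- p$ins_seq[!is.na(p$ins_seq)]
    expect_length(dup, 1)
    expect_true(grepl(paste0(dup, dup), itd$variant_sequence, fixed = TRUE))
    expect_false(grepl(paste0(dup, dup), wt, fixed = TRUE))
  }
  # PTD of exons 2-3 of a 4-exon transcript = e1 e2 e3 e2 e3 e4
  tx4 <- ann$transcripts$transcript_id[ann$transcripts$n_exons == 4][1]
  wt_plan <- txsv:::wt_plan(ann, tx4)
  seg_seq <- function(rows) txsv:::plan_sequence(rows, sg$genome)
  e <- vapply(1:4, function(k) seg_seq(wt_plan[k, ]), character(1))
  found <- FALSE
  set.seed(17)
  for (i in 1:60) {
    ptd <- make_tsv(ann, sg$genome, "ptd", tx4)
    if (identical(ptd$variant_sequence, paste0(e[1], e[2], e[3], e[2], e[3], e[4]))) {
      found <- TRUE; break
    }
  }
  expect_true(found)
  # inversion reverse-complements the selected run in place
  set.seed(18)
  inv <- make_tsv(ann, sg$genome, "inv", tx4)
  expect_equal(nchar(inv$variant_sequence),
               nchar(transcript_sequence(ann, sg$genome, tx4)))
})

test_that("splice variants honour their constraints", {
  sg <- small_genome()
  ann <- sg$annotation
  elig <- select_eligible_transcripts(ann)
  set.seed(51)
  for (i in 1:15) {
    tx <- sample(elig$transcript_id, 1)
    wt <- transcript_sequence(ann, sg$genome, tx)
    ee <- make_splice_variant(ann, sg$genome, "ee", tx)
    expect_equal(nchar(ee$variant_sequence), nchar(wt) + ee$size_bp)
    # novel-exon block overlaps no annotated exon
    ne <- make_splice_variant(ann, sg$genome, "ne", tx)
    ins_row <- ne$plan[!is.na(ne$plan$start) &
                         !paste(ne$plan$start, ne$plan$end) %in%
                           paste(txsv:::wt_plan(ann, tx)$start, txsv:::wt_plan(ann, tx)$end), ]
    expect_equal(nrow(ins_row), 1)
    ov <- ann$exons$start < ins_row$end & ann$exons$end > ins_row$start &
      ann$exons$chrom == ins_row$chrom
    expect_false(any(ov))
    tr <- make_splice_variant(ann, sg$genome, "trunc", tx)
    expect_equal(nchar(tr$variant_sequence), nchar(wt) - tr$size_bp)
    ri <- make_splice_variant(ann, sg$genome, "ri", tx)
    expect_true(ri$size_bp > 30)
    expect_equal(nchar(ri$variant_sequence), nchar(wt) + ri$size_bp)
    # skipped exon drops at least one exon and creates an unannotated junction
    nj <- make_splice_variant(ann, sg$genome, "nj", tx)
    expect_lt(nchar(nj$variant_sequence), nchar(wt))
  }
})

test_that("edit sizes stay in their legal ranges over many draws", {
  sg <- small_genome()
  ann <- sg$annotation
  elig <- select_eligible_transcripts(ann)
  set.seed(61)
  small_sizes <- integer(0); exon_sizes <- integer(0)
  for (i in 1:350) {
    tx <- sample(elig$transcript_id, 1)
    small_sizes <- c(small_sizes,
                     make_tsv(ann, sg$genome, sample(c("ins", "del", "itd"), 1), tx)$size_bp)
    sub <- sample(c("ee", "ne"), 1)
    exon_sizes <- c(exon_sizes, make_splice_variant(ann, sg$genome, sub, tx)$size_bp)
  }
  expect_true(all(small_sizes >= 7 & small_sizes <= 49))
  expect_true(all(exon_sizes >= 30 & exon_sizes <= 199))
})

test_that("benchmark counts, heterozygosity, control purity and background integrity hold", {
  bm <- small_benchmark()
  expect_equal(nrow(bm$truth), 30L)
  expect_equal(sort(unique(bm$truth$vtype)), sort(txsv:::VARIANT_TYPES))
  # per variant: exactly one variant and one wild-type sequence in the case
  expect_equal(length(bm$case_reference), 2 * 30 + 10)
  expect_true(all(bm$truth$variant_id %in% names(bm$case_reference)))
  primary <- vapply(bm$truth$transcripts, `[[`, character(1), 1)
  expect_true(all(primary %in% names(bm$case_reference)))
  expect_equal(length(bm$control_reference), 30 + 10)
  # control purity: no variant sequence occurs inside any control sequence
  for (v in bm$truth$variant_sequence) {
    expect_false(any(vapply(bm$control_reference, grepl, logical(1),
                            pattern = v, fixed = TRUE)))
  }
  # background genes identical between case and control references
  bg_tx <- setdiff(names(bm$control_reference), primary)
  expect_identical(bm$case_reference[bg_tx], bm$control_reference[bg_tx])
  # deterministic given the seed
  bm2 <- build_benchmark(bench_genome(), per_type = 2, n_background = 10, seed = 7)
  expect_identical(bm$truth$variant_sequence, bm2$truth$variant_sequence)
  # per-type = 1 gives one truth record per type
  bm1 <- build_benchmark(bench_genome(), per_type = 1, n_background = 2, seed = 8)
  expect_equal(nrow(bm1$truth), 15L)
  # insufficient genes raise a shortfall error
  expect_error(build_benchmark(small_genome(), per_type = 10, n_background = 10),
               "short by")
})

test_that("read simulator hits target coverage, is exact at zero error and deterministic", {
  set.seed(71)
  ref <- c(s1 = txsv:::random_dna(3000L))
  rd <- simulate_reads(ref, coverage = 50, read_len = 100, fragment_len = 300,
                       error_rate = 0, seed = 3)
  expect_equal(length(rd$r1), 750L, tolerance = 0.002)
  expect_equal(length(rd$r1), length(rd$r2))
  # every mate is an exact substring (mate 2 after reverse complement)
  expect_true(all(vapply(rd$r1[1:50], grepl, logical(1), x = ref, fixed = TRUE)))
  expect_true(all(vapply(revcomp(rd$r2[1:50]), grepl, logical(1), x = ref, fixed = TRUE)))
  rd2 <- simulate_reads(ref, coverage = 50, error_rate = 0, seed = 3)
  expect_identical(rd$r1, rd2$r1)
  # FASTQ round trip preserves reads byte-for-byte, plain and gzipped
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq.gz")
  write_fastq(rd, f1, f2)
  back <- read_fastq_pair(f1, f2)
  expect_identical(unname(back$r1), unname(rd$r1))
  expect_identical(unname(back$r2), unname(rd$r2))
  # short sequences are skipped with a warning
  expect_warning(simulate_reads(c(tiny = "ACGTACGT"), coverage = 10, seed = 1),
                 "skipped")
  expect_error(simulate_reads(ref, coverage = 10, error_rate = 0.2), "error_rate")
  # substitution errors appear at roughly the requested rate
  rde <- simulate_reads(ref, coverage = 50, error_rate = 0.01, seed = 4)
  mism <- sum(vapply(rde$r1[1:200], function(r) !grepl(r, ref, fixed = TRUE), logical(1)))
  expect_gt(mism, 50)  # 1 - (1-.01)^100 ~ 63% of reads carry an error
})
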