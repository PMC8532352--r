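# Alignment loading, candidate detection and classification ---------------

write_toy_sam <- function(lines, genome = toy_genome()) {
  f <- tempfile(fileext = ".sam")
  hdr <- sprintf("@SQ\tSN:%s\tLN:%d", names(genome), nchar(genome))
  writeLines(c("@HD\tVN:1.6", hdr, lines), f)
  f
}

test_that("SAM loading converts coordinates and walks CIGARs correctly", {
  g <- toy_genome()
  f <- write_toy_sam(c(
    sprintf("c1\t0\tchrT\t1\t60\t100M\t*\t0\t0\t%s\t*", strrep("A", 100)),
    sprintf("c2\t0\tchrT\t11\t60\t50M1000N50M\t*\t0\t0\t%s\t*", strrep("A", 100)),
    sprintf("c3\t0\tchrT\t1\t60\t40M20S\t*\t0\t0\t%s\t*", strrep("A", 60)),
    sprintf("c3\t2048\tchr2\t1\t60\t40S20M\t*\t0\t0\t%s\t*", strrep("A", 60))
  ), g)
  rec <- load_alignments(f)
  # POS 1 (1-based) -> 0; single block [0,100)
  r1 <- rec[rec$contig_id == "c1", ]
  expect_equal(r1$pos, 0L)
  w <- txsv:::walk_cigar("100M", 0L)
  expect_equal(w$blocks$rstart, 0L)
  expect_equal(w$blocks$rend, 100L)
  # spliced CIGAR: two blocks separated by a 1,000 bp junction
  w2 <- txsv:::walk_cigar("50M1000N50M", 10L)
  expect_equal(w2$blocks$rstart, c(10L, 1060L))
  expect_equal(w2$blocks$rend, c(60L, 1110L))
  jx <- w2$events[w2$events$kind == "junction", ]
  expect_equal(jx$rstart, 60L)
  expect_equal(jx$rend, 1060L)
  # primary + supplementary on different chromosomes group under one contig
  expect_equal(sum(rec$contig_id == "c3"), 2L)
  expect_setequal(rec$chrom[rec$contig_id == "c3"], c("chrT", "chr2"))
  expect_true(any(rec$is_supplementary[rec$contig_id == "c3"]))
  # CIGAR/sequence length mismatch is a record-level error naming the contig
  bad <- write_toy_sam(sprintf("cx\t0\tchrT\t1\t60\t100M\t*\t0\t0\t%s\t*",
                               strrep("A", 60)), g)
  expect_error(load_alignments(bad), "cx")
})

test_that("alignment filter enforces 30 bp, 30% and exon overlap", {
  ann <- toy_annotation()
  mk <- function(cigar, pos, len, id = "c") {
    tibble::tibble(contig_id = id, chrom = "chrT", pos = pos, strand = "+",
                   cigar = cigar, is_supplementary = FALSE,
                   contig_length = len)
  }
  # 200 bp contig with 59 aligned bp (29.5%): below the 30% fraction
  expect_length(filter_alignments(mk("59M141S", 110L, 200L), ann), 0)
  # 100 bp contig fully aligned but intergenic: discarded
  expect_length(filter_alignments(mk("100M", 700L, 100L), ann), 0)
  # 100 bp contig with 40 bp aligned over an exon: both thresholds met
  expect_equal(filter_alignments(mk("40M60S", 120L, 100L), ann), "c")
  # aligned bases pool across supplementary records of one contig
  two <- dplyr::bind_rows(mk("20M80S", 120L, 100L), mk("80S20M", 320L, 100L))
  expect_equal(filter_alignments(two, ann), "c")
})

test_that("raw candidates: indel/clip thresholds and junction novelty", {
  ann <- toy_annotation()
  mk <- function(cigar, pos = 100L) {
    tibble::tibble(contig_id = "c", chrom = "chrT", pos = pos, strand = "+",
                   cigar = cigar, is_supplementary = FALSE, contig_length = 500L)
  }
  # 40M10D40M inside one exon -> deletion candidate of size 10
  cand <- detect_raw_variants(mk("40M10D40M", 105L), ann)
  del <- cand[cand$kind == "del", ]
  expect_equal(nrow(del), 1)
  expect_equal(del$size, 10L)
  expect_equal(del$start, 145L)
  expect_equal(del$end, 155L)
  # gap_min boundary: 6 bp deletion ignored at default 7
  cand6 <- detect_raw_variants(mk("40M6D40M", 105L), ann)
  expect_false(any(cand6$kind == "del"))
  # clip threshold boundary: 20S flags, 19S does not
  expect_true(any(detect_raw_variants(mk("80M20S"), ann)$kind == "clip"))
  expect_false(any(detect_raw_variants(mk("80M19S"), ann)$kind == "clip"))
  # insertion >= 7 bp
  ins <- detect_raw_variants(mk("40M8I40M", 105L), ann)
  expect_true(any(ins$kind == "ins"))
  # N junction matching an annotated junction produces no candidate
  known <- detect_raw_variants(mk("100M100N100M", 100L), ann)  # 200->300 annotated
  expect_false(any(known$kind == "novel_junction"))
  novel <- detect_raw_variants(mk("100M110N90M", 100L), ann)
  expect_true(any(novel$kind == "novel_junction"))
  # aligned block of >= 20 bp outside every exon
  blk <- detect_raw_variants(mk("100M", 650L), ann)
  expect_true(any(blk$kind == "novel_block"))
  expect_false(any(detect_raw_variants(mk("100M", 100L), ann)$kind == "novel_block"))
})

test_that("splice motifs validate GT/AG-class dinucleotides with tolerance", {
  g <- c(chr1 = "AAAAAGTCCCCCCCCCCAGAAAAA")
  # intron [5,19): starts GT, ends AG
  expect_true(check_motif(g, "chr1", 5L, 19L, tolerance = 0L))
  expect_false(check_motif(g, "chr1", 6L, 19L, tolerance = 0L))
  g2 <- c(chr1 = "AAAAAAACCCCCCCCCCAAAAAAA")
  expect_false(check_motif(g2, "chr1", 5L, 19L, tolerance = 0L))
  # one mismatch at the donor allowed at tolerance 1
  g3 <- c(chr1 = "AAAAAGACCCCCCCCCCAGAAAAA")
  expect_false(check_motif(g3, "chr1", 5L, 19L, tolerance = 0L))
  expect_true(check_motif(g3, "chr1", 5L, 19L, tolerance = 1L))
  # minus-strand convention (CT..AC) accepted
  g4 <- c(chr1 = "AAAAACTCCCCCCCCCCACAAAAA")
  expect_true(check_motif(g4, "chr1", 5L, 19L, tolerance = 0L))
  expect_error(check_motif(g, "chr2", 5L, 19L), "chromosome")
})

test_that("a contig reproducing a reference transcript yields zero calls", {
  sg <- small_genome()
  ann <- sg$annotation
  tx <- ann$transcripts$transcript_id[1]
  plan <- txsv:::wt_plan(ann, tx)
  seq <- txsv:::plan_sequence(plan, sg$genome)
  sam <- txsv:::plan_to_sam(plan, "ref_like", seq, annotation = ann)
  rec <- tibble::tibble(contig_id = sam$qname, chrom = sam$rname,
                        pos = sam$pos - 1L,
                        strand = ifelse(bitwAnd(sam$flag, 16L) > 0, "-", "+"),
                        cigar = sam$cigar, is_supplementary = FALSE,
                        contig_length = nchar(seq))
  expect_equal(filter_alignments(rec, ann), "ref_like")
  cand <- detect_raw_variants(rec, ann)
  expect_equal(nrow(cand), 0)
  calls <- refine_and_classify(cand, rec, ann, sg$genome)
  expect_equal(nrow(calls), 0)
})

test_that("consolidation rules classify blocks, junctions and record pairs", {
  ann <- toy_annotation()
  g <- toy_genome()
  prm <- annotate_params(motif_check = FALSE)
  mkrec <- function(cigar, pos, strand = "+", id = "c", supp = FALSE, len = 400L) {
    tibble::tibble(contig_id = id, chrom = "chrT", pos = pos, strand = strand,
                   cigar = cigar, is_supplementary = supp, contig_length = len)
  }
  classify <- function(rec) {
    refine_and_classify(detect_raw_variants(rec, ann, prm), rec, ann, g, prm)
  }
  # novel block downstream of an exon + flanking novel junction ->
  # novel/extended exon (exon [100,200) extended 50 bp, then splice to 300)
  rec <- mkrec("150M50N100M", 100L, len = 250L)
  calls <- classify(rec)
  expect_true("novel_extended_exon" %in% calls$vclass)
  expect_identical(calls$genes[[which(calls$vclass == "novel_extended_exon")]], "geneA")
  # same block with no novel junction: no novel-exon call
  rec2 <- mkrec("250M", 100L, len = 250L)
  calls2 <- classify(rec2)
  expect_false("novel_extended_exon" %in% calls2$vclass)
  # full intron between annotated boundaries -> retained intron
  rec3 <- mkrec("300M", 100L, len = 300L)  # spans exon1+intron+exon2
  calls3 <- classify(rec3)
  expect_identical(calls3$vclass, "retained_intron")
  expect_equal(calls3$start, 200L)
  expect_equal(calls3$end, 300L)
  # exon truncated by >= 20 bp at a novel junction -> novel exon junction
  rec4 <- mkrec("70M170N100M", 100L, len = 170L)  # donor at 170, 30 bp short
  calls4 <- classify(rec4)
  expect_true("novel_exon_junction" %in% calls4$vclass)
  # junction joining annotated exon boundaries (skipped exon)
  rec5 <- mkrec("100M300N150M", 100L, len = 250L)  # 200 -> 500: skips exon 2
  calls5 <- classify(rec5)
  expect_identical(calls5$vclass, "novel_exon_junction")
  # two records in different genes -> fusion
  rec6 <- dplyr::bind_rows(mkrec("100M100S", 100L, id = "f"),
                           mkrec("100S100M", 1000L, id = "f", supp = TRUE, len = 200L))
  calls6 <- classify(rec6)
  expect_identical(calls6$vclass, "fusion")
  expect_setequal(calls6$genes[[1]], c("geneA", "geneB"))
  # gene plus far intergenic block -> fusion with an intergenic side
  rec7 <- dplyr::bind_rows(mkrec("100M100S", 100L, id = "u"),
                           mkrec("100S100M", 1750L, id = "u", supp = TRUE, len = 200L))
  calls7 <- classify(rec7)
  expect_identical(calls7$vclass, "fusion")
  expect_true("intergenic" %in% calls7$genes[[1]])
  # overlapping same-gene records -> intragenic rearrangement
  rec8 <- dplyr::bind_rows(mkrec("120M100S", 100L, id = "p", len = 220L),
                           mkrec("120S100M", 100L, id = "p", supp = TRUE, len = 220L))
  calls8 <- classify(rec8)
  expect_identical(calls8$vclass, "intragenic_rearrangement")
  # strand-discordant same-gene records -> intragenic rearrangement
  rec9 <- dplyr::bind_rows(mkrec("100M100S", 100L, id = "v", len = 200L),
                           mkrec("100M100S", 300L, id = "v", strand = "-",
                                 supp = TRUE, len = 200L))
  expect_identical(classify(rec9)$vclass, "intragenic_rearrangement")
  # unexplained >= 20 bp clip on a single-record contig -> unknown
  rec10 <- mkrec("100M60S", 100L, len = 160L)
  expect_identical(classify(rec10)$vclass, "unknown")
  # insertions and deletions pass through with their sizes
  rec11 <- mkrec("40M12I40M9D20M", 105L, len = 112L)
  calls11 <- classify(rec11)
  expect_setequal(calls11$vclass, c("insertion", "deletion"))
  expect_setequal(calls11$size_bp, c(12L, 9L))
})

test_that("motif checking gates novel/extended exon calls", {
  ann <- toy_annotation()
  set.seed(12)
  g <- c(chrT = txsv:::random_dna(2000L))
  rec <- tibble::tibble(contig_id = "c", chrom = "chrT", pos = 100L,
                        strand = "+", cigar = "150M50N100M",
                        is_supplementary = FALSE, contig_length = 250L)
  # random genome: junction motif almost surely invalid at tolerance 0
  prm_strict <- annotate_params(motif_check = TRUE, motif_tolerance = 0L)
  g_bad <- g
  substr(g_bad[["chrT"]], 251, 252) <- "AA"  # donor after the extension
  substr(g_bad[["chrT"]], 299, 300) <- "AA"
  cand <- detect_raw_variants(rec, ann, prm_strict)
  calls <- refine_and_classify(cand, rec, ann, g_bad, prm_strict)
  expect_false("novel_extended_exon" %in% calls$vclass)
  # valid GT..AG at the junction passes
  g_ok <- g
  substr(g_ok[["chrT"]], 251, 252) <- "GT"
  substr(g_ok[["chrT"]], 299, 300) <- "AG"
  calls_ok <- refine_and_classify(cand, rec, ann, g_ok, prm_strict)
  expect_true("novel_extended_exon" %in% calls_ok$vclass)
})

test_that("raising gap_min or clip_min never increases the number of calls", {
  bm <- small_benchmark()
  sam <- truth_alignments(bm)
  rec <- tibble::tibble(contig_id = sam$qname, chrom = sam$rname,
                        pos = sam$pos - 1L,
                        strand = ifelse(bitwAnd(sam$flag, 16L) > 0, "-", "+"),
                        cigar = sam$cigar,
                        is_supplementary = bitwAnd(sam$flag, 2048L) > 0,
                        contig_length = nchar(sam$seq))
  ann <- bm$annotation
  n_calls <- function(gap_min, clip_min) {
    prm <- annotate_params(gap_min = gap_min, clip_min = clip_min,
                           motif_check = FALSE)
    nrow(refine_and_classify(detect_raw_variants(rec, ann, prm), rec, ann,
                             bm$genome, prm))
  }
  base <- n_calls(7, 20)
  expect_lte(n_calls(15, 20), base)
  expect_lte(n_calls(50, 20), n_calls(15, 20))
  expect_lte(n_calls(7, 40), base)
  expect_lte(n_calls(7, 200), n_calls(7, 40))
})

test_that("VAF is the contig-only share of the gene's case expression", {
  mk_mat <- function(members, case_counts, ids, is_contig) {
    counts <- cbind(case = case_counts)
    structure(list(
      ec = tibble::tibble(ec_id = as.character(seq_along(members)),
                          members = members,
                          all_contig = vapply(members, function(m) all(is_contig[m]), logical(1))),
      counts = counts, lib_sizes = c(case = 1e6), case = "case",
      ids = ids, is_contig = setNames(is_contig, ids)
    ), class = "ec_matrix")
  }
  ann <- toy_annotation()
  ids <- c("ctg", "txA", "txB")
  calls <- tibble::tibble(contig_id = "ctg", vclass = "deletion",
                          genes = list("geneA"), chrom = "chrT",
                          start = 150L, end = 160L, size_bp = 10L,
                          junction = NA_character_, motif_valid = NA)
  # U = 50 (contig-only), W = 50 (txA without contig) -> 0.5
  m <- mk_mat(list(1L, 2L), c(50, 50), ids, c(TRUE, FALSE, FALSE))
  expect_equal(estimate_vaf(calls, m, ann)$vaf, 0.5)
  # W = 0 -> 1.0
  m2 <- mk_mat(list(1L), 50, ids, c(TRUE, FALSE, FALSE))
  expect_equal(estimate_vaf(calls, m2, ann)$vaf, 1.0)
  # mixed ECs (contig + reference) count toward neither U nor W
  m3 <- mk_mat(list(1L, c(1L, 2L), 2L), c(30, 100, 10), ids, c(TRUE, FALSE, FALSE))
  expect_equal(estimate_vaf(calls, m3, ann)$vaf, 30 / 40)
  # other genes' transcripts do not contribute to W
  m4 <- mk_mat(list(1L, 3L), c(20, 80), ids, c(TRUE, FALSE, FALSE))
  expect_equal(estimate_vaf(calls, m4, ann)$vaf, 1.0)
  # U + W = 0 -> missing
  m5 <- mk_mat(list(2L), 0, ids, c(TRUE, FALSE, FALSE))
  expect_true(is.na(estimate_vaf(calls, m5, ann)$vaf))
})

test_that("variant call TSV output is deterministic and deduplicated", {
  calls <- tibble::tibble(
    contig_id = c("b", "a", "a"), vclass = c("deletion", "insertion", "insertion"),
    genes = list("g2", "g1", "g1"), chrom = "chr1",
    start = c(5L, 9L, 9L), end = c(10L, 10L, 10L), size_bp = c(5L, 7L, 7L),
    junction = NA_character_, motif_valid = NA)
  f <- tempfile(fileext = ".tsv")
  write_variant_calls(calls, f)
  out <- utils::read.delim(f)
  expect_equal(nrow(out), 2)           # duplicates collapsed
  expect_equal(out$contig_id, c("a", "b"))  # sorted
  # empty call set -> header-only file
  f2 <- tempfile(fileext = ".tsv")
  write_variant_calls(calls[0, ], f2)
  expect_equal(nrow(utils::read.delim(f2)), 0)
  expect_equal(length(readLines(f2)), 1)
})
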