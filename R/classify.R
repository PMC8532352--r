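# Contig alignment filtering, candidate detection and classification ------
#
# Retained contigs are classified from their spliced genome alignments
# against the reference annotation into eight classes: fusion, intragenic
# rearrangement, deletion, insertion, novel/extended exon, novel exon
# junction, retained intron, and unknown (unexplained soft clips).

VARIANT_CLASSES <- c("fusion", "intragenic_rearrangement", "deletion",
                     "insertion", "novel_extended_exon", "novel_exon_junction",
                     "retained_intron", "unknown")

#' Annotation-stage parameters
#'
#' @param gap_min Minimum insertion/deletion size in bp (default 7).
#' @param clip_min Minimum soft/hard clip length in bp (default 20).
#' @param block_min Minimum unannotated aligned block in bp (default 20).
#' @param min_aligned_bp,min_aligned_frac Contig retention thresholds: at
#'   least this many bases and this fraction of the contig must align
#'   (defaults 30 bp and 30%).
#' @param motif_check Require a valid splice motif for novel/extended exon
#'   calls (default `TRUE`; benchmark runs on simulated variants disable it
#'   because simulated junctions carry no motifs).
#' @param motif_tolerance Mismatches tolerated per junction end (default 1).
#' @return List of class `annotate_params`.
#' @export
annotate_params <- function(gap_min = 7L, clip_min = 20L, block_min = 20L,
                            min_aligned_bp = 30L, min_aligned_frac = 0.3,
                            motif_check = TRUE, motif_tolerance = 1L) {
  stopifnot(gap_min >= 1, clip_min >= 1, block_min >= 1,
            min_aligned_bp >= 0, min_aligned_frac >= 0, min_aligned_frac <= 1)
  structure(list(gap_min = as.integer(gap_min), clip_min = as.integer(clip_min),
                 block_min = as.integer(block_min),
                 min_aligned_bp = as.integer(min_aligned_bp),
                 min_aligned_frac = min_aligned_frac,
                 motif_check = isTRUE(motif_check),
                 motif_tolerance = as.integer(motif_tolerance)),
            class = "annotate_params")
}

# Walk every CIGAR once (vectorised explode, plain-R accumulation). Returns
# aligned blocks and I/D/N/S/H events for all records, plus per-record
# summaries.
walk_records <- function(records) {
  n <- nrow(records)
  ops_l <- GenomicAlignments::explodeCigarOps(records$cigar)
  lens_l <- GenomicAlignments::explodeCigarOpLengths(records$cigar)
  blocks <- vector("list", n)
  events <- vector("list", n)
  aligned <- numeric(n)
  spliced <- logical(n)
  qstart0 <- numeric(n)  # query start of aligned span in contig orientation
  for (i in seq_len(n)) {
    ops <- ops_l[[i]]; lens <- lens_l[[i]]
    ref <- records$pos[i]; q <- 0L
    bs <- integer(0); be <- integer(0); qs <- integer(0)
    ek <- character(0); es <- integer(0); ee <- integer(0)
    ez <- integer(0); eq <- integer(0)
    for (j in seq_along(ops)) {
      op <- ops[j]; len <- lens[j]
      if (op == "M" || op == "=" || op == "X") {
        bs <- c(bs, ref); be <- c(be, ref + len); qs <- c(qs, q)
        ref <- ref + len; q <- q + len
      } else if (op == "I") {
        ek <- c(ek, "ins"); es <- c(es, ref); ee <- c(ee, ref)
        ez <- c(ez, len); eq <- c(eq, q); q <- q + len
      } else if (op == "D") {
        ek <- c(ek, "del"); es <- c(es, ref); ee <- c(ee, ref + len)
        ez <- c(ez, len); eq <- c(eq, q); ref <- ref + len
      } else if (op == "N") {
        ek <- c(ek, "junction"); es <- c(es, ref); ee <- c(ee, ref + len)
        ez <- c(ez, len); eq <- c(eq, q); ref <- ref + len
      } else if (op == "S" || op == "H") {
        ek <- c(ek, "clip"); es <- c(es, ref); ee <- c(ee, ref)
        ez <- c(ez, len); eq <- c(eq, q)
        if (op == "S") q <- q + len
      }
    }
    left <- if (ops[1] %in% c("S", "H")) lens[1] else 0L
    right <- if (ops[length(ops)] %in% c("S", "H")) lens[length(ops)] else 0L
    qstart0[i] <- if (records$strand[i] == "-") right else left
    aligned[i] <- sum(be - bs)
    spliced[i] <- any(ek == "junction")
    blocks[[i]] <- tibble(record = i, contig_id = records$contig_id[i],
                          chrom = records$chrom[i], rstart = bs, rend = be,
                          qstart = qs)
    if (length(ek)) {
      events[[i]] <- tibble(record = i, contig_id = records$contig_id[i],
                            chrom = records$chrom[i], kind = ek, rstart = es,
                            rend = ee, size = ez, qpos = eq,
                            spliced = NA)
    }
  }
  ev <- if (length(events) && any(!vapply(events, is.null, logical(1)))) {
    bind_rows(events)
  } else {
    tibble(record = integer(), contig_id = character(), chrom = character(),
           kind = character(), rstart = integer(), rend = integer(),
           size = integer(), qpos = integer(), spliced = logical())
  }
  if (nrow(ev)) ev$spliced <- spliced[ev$record]
  list(blocks = bind_rows(blocks), events = ev,
       per_record = tibble(record = seq_len(n), contig_id = records$contig_id,
                           chrom = records$chrom, strand = records$strand,
                           aligned = aligned, spliced = spliced,
                           qstart = qstart0,
                           contig_length = records$contig_length))
}

#' Filter contig alignments
#'
#' A contig is retained when its aligned (M) bases total at least
#' `min_aligned_bp` AND at least `min_aligned_frac` of the contig length,
#' AND at least one aligned block overlaps a reference exon.
#'
#' @param records Alignment tibble from [load_alignments()].
#' @param annotation A `tx_annotation`.
#' @param params An `annotate_params`.
#' @return Character vector of retained contig ids.
#' @export
filter_alignments <- function(records, annotation, params = annotate_params()) {
  if (nrow(records) == 0) return(character(0))
  w <- walk_records(records)
  per <- w$per_record |>
    group_by(.data$contig_id) |>
    summarise(aligned = sum(.data$aligned),
              contig_length = max(.data$contig_length), .groups = "drop")
  enough <- per$contig_id[per$aligned >= params$min_aligned_bp &
                          per$aligned >= params$min_aligned_frac * per$contig_length]
  b <- w$blocks
  hits <- GenomicRanges::findOverlaps(gr0(b$chrom, b$rstart, b$rend),
                                      annotation$exon_gr)
  exonic <- unique(b$contig_id[unique(S4Vectors::queryHits(hits))])
  sort(intersect(enough, exonic))
}

# subtract disjoint sorted merged intervals from one block
subtract_intervals <- function(bs, be, ms, me) {
  idx <- which(me > bs & ms < be)
  if (!length(idx)) return(cbind(bs, be))
  out <- NULL
  cur <- bs
  for (i in idx) {
    if (ms[i] > cur) out <- rbind(out, c(cur, ms[i]))
    cur <- max(cur, me[i])
    if (cur >= be) break
  }
  if (cur < be) out <- rbind(out, c(cur, be))
  out
}

#' Detect raw variant candidates on contig alignments
#'
#' Emits candidate records for: insertions and deletions of at least
#' `gap_min` bp; soft/hard clips of at least `clip_min` bp; splice junctions
#' (N ops) absent from the reference junction set; and aligned blocks of at
#' least `block_min` bp outside every reference exon.
#'
#' @inheritParams filter_alignments
#' @return Tibble of candidates: `contig_id`, `kind` (`ins`, `del`, `clip`,
#'   `novel_junction`, `novel_block`), `chrom`, `start`, `end`, `size`,
#'   `record`, `spliced`, `genes` (list).
#' @export
detect_raw_variants <- function(records, annotation, params = annotate_params()) {
  empty <- tibble(contig_id = character(), kind = character(), chrom = character(),
                  start = integer(), end = integer(), size = integer(),
                  record = integer(), spliced = logical(), genes = list())
  if (nrow(records) == 0) return(empty)
  w <- walk_records(records)
  ev <- w$events
  out <- list()
  take <- function(d, kind) {
    if (nrow(d)) out[[length(out) + 1]] <<- tibble(
      contig_id = d$contig_id, kind = kind, chrom = d$chrom,
      start = d$rstart, end = d$rend, size = d$size,
      record = d$record, spliced = d$spliced)
  }
  take(ev[ev$kind == "ins" & ev$size >= params$gap_min, ], "ins")
  take(ev[ev$kind == "del" & ev$size >= params$gap_min, ], "del")
  take(ev[ev$kind == "clip" & ev$size >= params$clip_min, ], "clip")
  jx <- ev[ev$kind == "junction", ]
  jx <- jx[!paste(jx$chrom, jx$rstart, jx$rend) %in% annotation$junction_keys, ]
  take(jx, "novel_junction")

  # aligned sub-blocks outside every reference exon, per record
  b <- w$blocks
  nb <- list()
  for (ch in unique(b$chrom)) {
    m <- annotation$exon_merged[[ch]]
    ms <- if (is.null(m)) integer(0) else m$start
    me <- if (is.null(m)) integer(0) else m$end
    bb <- b[b$chrom == ch, ]
    for (i in seq_len(nrow(bb))) {
      seg <- subtract_intervals(bb$rstart[i], bb$rend[i], ms, me)
      if (is.null(seg)) next
      keep <- (seg[, 2] - seg[, 1]) >= params$block_min
      if (any(keep)) nb[[length(nb) + 1]] <- tibble(
        contig_id = bb$contig_id[i], kind = "novel_block", chrom = ch,
        start = as.integer(seg[keep, 1]), end = as.integer(seg[keep, 2]),
        size = as.integer(seg[keep, 2] - seg[keep, 1]),
        record = bb$record[i], spliced = w$per_record$spliced[bb$record[i]])
    }
  }
  out <- c(out, nb)
  if (!length(out)) return(empty)
  cand <- bind_rows(out)
  # merge novel-block pieces of the same record split only by D ops
  cand$genes <- genes_overlapping_batch(annotation, cand$chrom, cand$start, cand$end)
  cand
}

#' Check a splice junction for a valid donor/acceptor motif
#'
#' Valid when the intron-start dinucleotide matches `GT` or `CT` and the
#' intron-end dinucleotide matches `AG` or `AC` (both orientations of the
#' canonical pair), each within `tolerance` mismatches.
#'
#' @param genome Named chromosome sequence vector.
#' @param chrom Chromosome.
#' @param donor_end Intron start (0-based; first intronic base).
#' @param acceptor_start Intron end (0-based exclusive).
#' @param tolerance Mismatches tolerated per end (default 1).
#' @return Logical flag.
#' @export
check_motif <- function(genome, chrom, donor_end, acceptor_start, tolerance = 1L) {
  if (acceptor_start - donor_end < 4) return(FALSE)
  don <- genome_substr(genome, chrom, donor_end, donor_end + 2L)
  acc <- genome_substr(genome, chrom, acceptor_start - 2L, acceptor_start)
  ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  don_ok <- min(ham(don, "GT"), ham(don, "CT")) <= tolerance
  acc_ok <- min(ham(acc, "AG"), ham(acc, "AC")) <= tolerance
  don_ok && acc_ok
}

#' Consolidate candidates into classified variant calls
#'
#' Applies, per contig: novel junctions linking two genes (or a gene and an
#' intergenic locus) become fusions, as do record pairs doing the same;
#' novel blocks supported by a flanking novel junction (with a valid donor
#' or acceptor motif when motif checking is on) become novel/extended exon
#' calls, and unsupported blocks whose edges coincide with the flanking exon
#' boundaries become retained introns; novel junctions truncating an exon
#' end by at least 20 bp, or joining two annotated exon boundaries, become
#' novel exon junction calls; same-gene record pairs that overlap, run out
#' of transcriptional order or disagree in strand become intragenic
#' rearrangements; insertions and deletions pass through as their class;
#' clips with no other explanation become unknown calls. Non-fusion calls
#' must overlap a reference gene.
#'
#' @param candidates Output of [detect_raw_variants()].
#' @param records Alignment tibble (all records of the candidate contigs).
#' @param annotation A `tx_annotation`.
#' @param genome Genome sequences (for motif checks; may be `NULL` when
#'   `motif_check` is off).
#' @param params An `annotate_params`.
#' @return Tibble of variant calls: `contig_id`, `vclass`, `genes` (list),
#'   `chrom`, `start`, `end`, `size_bp`, `junction`, `motif_valid`.
#' @export
refine_and_classify <- function(candidates, records, annotation, genome = NULL,
                                params = annotate_params()) {
  empty <- tibble(contig_id = character(), vclass = character(), genes = list(),
                  chrom = character(), start = integer(), end = integer(),
                  size_bp = integer(), junction = character(),
                  motif_valid = logical())
  if (nrow(candidates) == 0 && nrow(records) < 2) return(empty)
  calls <- list()
  emit <- function(contig_id, vclass, genes, chrom, start, end, size = NA_integer_,
                   junction = NA_character_, motif_valid = NA) {
    calls[[length(calls) + 1]] <<- tibble(
      contig_id = contig_id, vclass = vclass,
      genes = list(if (length(genes)) genes else "intergenic"),
      chrom = chrom, start = as.integer(start), end = as.integer(end),
      size_bp = as.integer(size), junction = junction,
      motif_valid = motif_valid)
  }
  junction_motif <- function(ch, ds, as_) {
    if (!params$motif_check || is.null(genome)) return(NA)
    check_motif(genome, ch, ds, as_, params$motif_tolerance)
  }

  # batched gene lookups for junction flanks and record spans
  is_jx <- candidates$kind == "novel_junction"
  jx_all <- candidates[is_jx, ]
  jx_don_genes <- genes_overlapping_batch(annotation, jx_all$chrom,
                                          jx_all$start - 1L, jx_all$start)
  jx_acc_genes <- genes_overlapping_batch(annotation, jx_all$chrom,
                                          jx_all$end, jx_all$end + 1L)
  rw <- if (nrow(records)) walk_records(records) else NULL
  rec_span <- if (!is.null(rw)) {
    rw$blocks |>
      group_by(.data$record) |>
      summarise(rstart = min(.data$rstart), rend = max(.data$rend),
                .groups = "drop")
  } else tibble(record = integer(), rstart = integer(), rend = integer())
  rec_genes <- genes_overlapping_batch(annotation, records$chrom[rec_span$record],
                                       rec_span$rstart, rec_span$rend)

  ex <- annotation$exons
  for (cid in unique(c(candidates$contig_id, records$contig_id[duplicated(records$contig_id)]))) {
    cc <- candidates[candidates$contig_id == cid, ]
    rr_idx <- which(records$contig_id == cid)
    jx_idx <- which(is_jx & candidates$contig_id == cid)  # rows of jx_all space
    jx_rows <- match(jx_idx, which(is_jx))
    jx <- candidates[jx_idx, ]
    used_jx <- rep(FALSE, nrow(jx))
    fusion_jx <- rep(FALSE, nrow(jx))

    # novel junctions linking two genes -> fusion
    for (j in seq_len(nrow(jx))) {
      gd <- jx_don_genes[[jx_rows[j]]]
      ga <- jx_acc_genes[[jx_rows[j]]]
      if (length(gd) && length(ga) && !length(intersect(gd, ga))) {
        fusion_jx[j] <- TRUE
        used_jx[j] <- TRUE
        emit(cid, "fusion", union(gd, ga), jx$chrom[j], jx$start[j], jx$end[j],
             junction = sprintf("%s:%d-%d", jx$chrom[j], jx$start[j], jx$end[j]),
             motif_valid = junction_motif(jx$chrom[j], jx$start[j], jx$end[j]))
      }
    }

    # novel blocks: flanked by a novel junction -> novel/extended exon;
    # otherwise a full intron between annotated boundaries -> retained intron
    blocks <- cc[cc$kind == "novel_block", ]
    for (b in seq_len(nrow(blocks))) {
      bl <- blocks[b, ]
      flank <- if (nrow(jx)) which(!fusion_jx &
                                   (jx$end == bl$start | jx$start == bl$end)) else integer(0)
      if (length(flank)) {
        motifs <- vapply(flank, function(j)
          junction_motif(jx$chrom[j], jx$start[j], jx$end[j]), NA)
        if (!params$motif_check || isTRUE(any(motifs))) {
          emit(cid, "novel_extended_exon", bl$genes[[1]], bl$chrom, bl$start,
               bl$end, size = bl$size,
               junction = sprintf("%s:%d-%d", jx$chrom[flank[1]],
                                  jx$start[flank[1]], jx$end[flank[1]]),
               motif_valid = if (params$motif_check) isTRUE(any(motifs)) else NA)
          used_jx[flank] <- TRUE
        }
      } else if (paste(bl$chrom, bl$start) %in% annotation$exon_end_keys &&
                 paste(bl$chrom, bl$end) %in% annotation$exon_start_keys) {
        emit(cid, "retained_intron", bl$genes[[1]], bl$chrom, bl$start, bl$end,
             size = bl$size)
      }
    }

    # truncations (>= 20 bp into an exon) and annotated-boundary junctions
    for (j in seq_len(nrow(jx))) {
      if (fusion_jx[j] || used_jx[j]) next
      ch <- jx$chrom[j]; ds <- jx$start[j]; as_ <- jx$end[j]
      don_exon <- ex[ex$chrom == ch & ex$start < ds & ex$end > ds, ]
      acc_exon <- ex[ex$chrom == ch & ex$start < as_ & ex$end > as_, ]
      trunc_don <- nrow(don_exon) > 0 && any(don_exon$end - ds >= 20)
      trunc_acc <- nrow(acc_exon) > 0 && any(as_ - acc_exon$start >= 20)
      boundary <- paste(ch, ds) %in% annotation$exon_end_keys &&
        paste(ch, as_) %in% annotation$exon_start_keys
      if (trunc_don || trunc_acc || boundary) {
        emit(cid, "novel_exon_junction", jx$genes[[j]], ch, ds, as_,
             junction = sprintf("%s:%d-%d", ch, ds, as_),
             motif_valid = junction_motif(ch, ds, as_))
        used_jx[j] <- TRUE
      }
    }

    # multi-record contigs: fusions / intragenic rearrangements
    if (length(rr_idx) >= 2) {
      ord <- rr_idx[order(rw$per_record$qstart[rr_idx])]
      for (p in seq_len(length(ord) - 1)) {
        a <- ord[p]; b2 <- ord[p + 1]
        ga <- rec_genes[[match(a, rec_span$record)]]
        gb <- rec_genes[[match(b2, rec_span$record)]]
        sa <- rec_span[match(a, rec_span$record), ]
        sb <- rec_span[match(b2, rec_span$record), ]
        cross <- records$chrom[a] != records$chrom[b2] ||
          !length(intersect(ga, gb))
        if (cross) {
          genes <- union(if (length(ga)) ga else "intergenic",
                         if (length(gb)) gb else "intergenic")
          emit(cid, "fusion", genes, records$chrom[a], sa$rend - 1L, sa$rend)
        } else if (records$strand[a] != records$strand[b2] ||
                   sb$rstart < sa$rend) {
          emit(cid, "intragenic_rearrangement", intersect(ga, gb),
               records$chrom[a], min(sa$rstart, sb$rstart),
               max(sa$rend, sb$rend))
        }
      }
    }

    # insertions / deletions pass through
    for (k in which(cc$kind == "ins")) {
      emit(cid, "insertion", cc$genes[[k]], cc$chrom[k], cc$start[k],
           cc$start[k] + 1L, size = cc$size[k])
    }
    for (k in which(cc$kind == "del")) {
      emit(cid, "deletion", cc$genes[[k]], cc$chrom[k], cc$start[k], cc$end[k],
           size = cc$size[k],
           motif_valid = junction_motif(cc$chrom[k], cc$start[k], cc$end[k]))
    }

    # unexplained clips -> unknown
    if (length(rr_idx) < 2) {
      for (k in which(cc$kind == "clip")) {
        emit(cid, "unknown", cc$genes[[k]], cc$chrom[k], cc$start[k],
             max(cc$start[k] + 1L, cc$end[k]), size = cc$size[k])
      }
    }
  }
  if (!length(calls)) return(empty)
  out <- bind_rows(calls)
  # non-fusion calls must overlap a reference gene (fusions may have one
  # intergenic side)
  keep <- out$vclass == "fusion" |
    vapply(out$genes, function(g) any(g != "intergenic"), logical(1))
  out <- out[keep, ]
  out$gene_key <- vapply(out$genes, paste, character(1), collapse = ",")
  out <- distinct(out, .data$contig_id, .data$vclass, .data$gene_key,
                  .data$chrom, .data$start, .data$end, .keep_all = TRUE)
  out$gene_key <- NULL
  arrange(out, .data$contig_id, .data$chrom, .data$start)
}

#' Estimate the expressed variant allele frequency of a call
#'
#' `vaf = U / (U + W)` where `U` is the case count of contig-only ECs
#' containing the call's contig and `W` is the case count of ECs containing
#' at least one reference transcript of the call's gene(s) and no contig.
#' `NA` when `U + W = 0`.
#'
#' @param calls Tibble of variant calls.
#' @param matrix The full (pre-novel-filter) `ec_matrix`.
#' @param annotation A `tx_annotation`.
#' @return `calls` with a `vaf` column added.
#' @export
estimate_vaf <- function(calls, matrix, annotation) {
  if (nrow(calls) == 0) { calls$vaf <- numeric(0); return(calls) }
  case_counts <- matrix$counts[, matrix$case]
  members <- matrix$ec$members
  all_contig <- matrix$ec$all_contig
  any_contig <- vapply(members, function(m) any(matrix$is_contig[m]), logical(1))
  # member index -> rows of the matrix containing it
  rows_by_member <- split(rep(seq_along(members), lengths(members)),
                          unlist(members))
  tx_of_gene <- split(annotation$transcripts$transcript_id,
                      annotation$transcripts$gene_id)
  calls$vaf <- vapply(seq_len(nrow(calls)), function(i) {
    ci <- match(calls$contig_id[i], matrix$ids)
    u_rows <- rows_by_member[[as.character(ci)]]
    u_rows <- u_rows[all_contig[u_rows]]
    U <- sum(case_counts[u_rows])
    ref_tx <- unlist(tx_of_gene[setdiff(calls$genes[[i]], "intergenic")])
    ref_idx <- match(ref_tx, matrix$ids)
    ref_idx <- ref_idx[!is.na(ref_idx)]
    w_rows <- unique(unlist(rows_by_member[as.character(ref_idx)]))
    w_rows <- w_rows[!any_contig[w_rows]]
    W <- sum(case_counts[w_rows])
    if (U + W == 0) NA_real_ else U / (U + W)
  }, numeric(1))
  calls
}

#' Write variant calls to TSV
#'
#' Deterministic ordering (contig, locus); duplicate identical calls are
#' collapsed.
#'
#' @param calls Tibble of variant calls (optionally with `vaf`, `logFC`,
#'   `fdr`, `case_cpm` columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_calls <- function(calls, path) {
  cols <- c("contig_id", "vclass", "genes", "chrom", "start", "end", "size_bp",
            "junction", "motif_valid", "vaf", "logFC", "fdr", "case_cpm")
  out <- calls
  for (col in setdiff(cols, names(out))) out[[col]] <- NA
  out$genes <- vapply(out$genes, paste, character(1), collapse = ",")
  out <- distinct(out[, cols]) |> arrange(.data$contig_id, .data$chrom, .data$start)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
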