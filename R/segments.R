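# Segment plans -----------------------------------------------------------
#
# A variant transcript is represented internally as a "plan": a tibble of
# segments in transcription (query) order. Reference segments carry genomic
# coordinates (0-based half-open) and an rc flag (sequence contribution is
# reverse-complemented); insertion segments carry literal sequence. The plan
# is the single source of truth for both the variant sequence and its
# ground-truth spliced genome alignment.

seg_ref <- function(chrom, start, end, rc = FALSE) {
  tibble(chrom = chrom, start = as.integer(start), end = as.integer(end),
         rc = rc, ins_seq = NA_character_)
}

seg_ins <- function(seq) {
  tibble(chrom = NA_character_, start = NA_integer_, end = NA_integer_,
         rc = FALSE, ins_seq = seq)
}

seg_is_ins <- function(plan) !is.na(plan$ins_seq)

seg_widths <- function(plan) {
  ifelse(seg_is_ins(plan), nchar(plan$ins_seq), plan$end - plan$start)
}

plan_sequence <- function(plan, genome) {
  pieces <- character(nrow(plan))
  for (i in seq_len(nrow(plan))) {
    if (!is.na(plan$ins_seq[i])) {
      pieces[i] <- plan$ins_seq[i]
    } else {
      s <- genome_substr(genome, plan$chrom[i], plan$start[i], plan$end[i])
      pieces[i] <- if (plan$rc[i]) revcomp(s) else s
    }
  }
  paste0(pieces, collapse = "")
}

# wild-type plan: exon segments in transcription order
wt_plan <- function(annotation, tx_id) {
  ex <- filter(annotation$exons, .data$transcript_id == tx_id) |>
    arrange(.data$start)
  if (nrow(ex) == 0) abort(sprintf("unknown transcript '%s'", tx_id))
  minus <- ex$strand[1] == "-"
  if (minus) ex <- ex[rev(seq_len(nrow(ex))), ]
  seg_ref(ex$chrom, ex$start, ex$end, rc = minus)
}

# split a reference segment after q query bases (0 < q < width)
split_seg <- function(seg, q) {
  stopifnot(is.na(seg$ins_seq), q > 0, q < seg$end - seg$start)
  if (seg$rc) {
    bind_rows(seg_ref(seg$chrom, seg$end - q, seg$end, TRUE),
              seg_ref(seg$chrom, seg$start, seg$end - q, TRUE))
  } else {
    bind_rows(seg_ref(seg$chrom, seg$start, seg$start + q, FALSE),
              seg_ref(seg$chrom, seg$start + q, seg$end, FALSE))
  }
}

# extend the transcription-downstream end of a reference segment
extend_downstream <- function(seg, ext) {
  if (seg$rc) seg$start <- seg$start - as.integer(ext)
  else seg$end <- seg$end + as.integer(ext)
  seg
}

# genomic interval of the gap between segment k and k+1 of a same-strand plan
downstream_gap <- function(plan, k) {
  a <- plan[k, ]; b <- plan[k + 1, ]
  if (a$rc) c(b$end, a$start) else c(a$end, b$start)
}

# a reference segment at a transcription-downstream offset from segment seg
offset_block <- function(seg, gap, size) {
  if (seg$rc) seg_ref(seg$chrom, seg$start - gap - size, seg$start - gap, TRUE)
  else seg_ref(seg$chrom, seg$end + gap, seg$end + gap + size, FALSE)
}

# genomic breakpoint loci: query-adjacent segment pairs that are not
# genomically contiguous, reported as (chrom, pos) points
plan_breakpoints <- function(plan) {
  out <- list()
  for (i in seq_len(nrow(plan) - 1)) {
    a <- plan[i, ]; b <- plan[i + 1, ]
    if (!is.na(a$ins_seq) || !is.na(b$ins_seq)) {
      ref <- if (is.na(a$ins_seq)) a else if (is.na(b$ins_seq)) b else NULL
      if (!is.null(ref)) {
        pos <- if (identical(ref, a)) (if (a$rc) a$start else a$end) else (if (b$rc) b$end else b$start)
        out[[length(out) + 1]] <- tibble(chrom = ref$chrom, pos = as.integer(pos))
      }
      next
    }
    contiguous <- a$chrom == b$chrom && a$rc == b$rc &&
      ((!a$rc && b$start == a$end) || (a$rc && b$end == a$start))
    if (!contiguous) {
      out[[length(out) + 1]] <- tibble(
        chrom = c(a$chrom, b$chrom),
        pos = as.integer(c(if (a$rc) a$start else a$end,
                           if (b$rc) b$end else b$start)))
    }
  }
  if (length(out)) distinct(bind_rows(out)) else tibble(chrom = character(), pos = integer())
}

# Ground-truth alignment --------------------------------------------------
#
# Convert a plan into SAM-style spliced alignment records, emulating what a
# spliced aligner reports for a perfectly assembled contig: colinear
# same-chromosome/strand segments merge into one record (gaps inside a single
# annotated exon become D ops, intronic/other gaps up to max_intron become N
# ops), insertion segments between genomically adjacent segments become I
# ops, and chromosome changes, strand flips, non-colinear jumps or gaps
# beyond max_intron split the alignment into supplementary records.

plan_to_sam <- function(plan, contig_id, contig_seq, annotation = NULL,
                        min_intron = 70L, max_intron = 10000L) {
  w <- seg_widths(plan)
  qstart <- cumsum(c(0L, head(w, -1)))
  qend <- qstart + w
  is_ins <- seg_is_ins(plan)
  n <- nrow(plan)

  gap_inside_exon <- function(chrom, lo, hi) {
    if (is.null(annotation)) return(hi - lo < min_intron)
    h <- GenomicRanges::findOverlaps(gr0(chrom, lo, hi), annotation$exon_gr,
                                     type = "within")
    length(h) > 0
  }

  # group reference segments into colinear runs
  groups <- list()
  cur <- integer(0)     # row indices in query order (refs + interior ins)
  pending_ins <- integer(0)
  last_ref <- NA_integer_
  flush <- function() {
    if (length(cur)) groups[[length(groups) + 1]] <<- cur
    cur <<- integer(0); last_ref <<- NA_integer_
  }
  for (i in seq_len(n)) {
    if (is_ins[i]) { pending_ins <- c(pending_ins, i); next }
    if (is.na(last_ref)) {
      flushed <- length(cur) > 0
      if (flushed) flush()
      pending_ins <- integer(0)  # leading insertions become clips
      cur <- i; last_ref <- i
      next
    }
    a <- plan[last_ref, ]; b <- plan[i, ]
    g <- if (!a$rc) b$start - a$end else a$start - b$end
    colinear <- a$chrom == b$chrom && a$rc == b$rc && !is.na(g) && g >= 0 &&
      g <= max_intron && (length(pending_ins) == 0 || g == 0)
    if (colinear) {
      cur <- c(cur, pending_ins, i)
    } else {
      flush()
      cur <- i
    }
    pending_ins <- integer(0)
    last_ref <- i
  }
  flush()

  contig_len <- nchar(contig_seq)
  recs <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    rows <- groups[[gi]]
    rc <- plan$rc[rows[!is_ins[rows]][1]]
    elements <- if (rc) rev(rows) else rows  # genomic order
    ops <- character(0); lens <- integer(0)
    push <- function(op, len) {
      if (len <= 0) return()
      if (op == "M" && length(ops) && ops[length(ops)] == "M") {
        lens[length(ops)] <<- lens[length(ops)] + len
      } else {
        ops <<- c(ops, op); lens <<- c(lens, as.integer(len))
      }
    }
    prev_ref <- NA_integer_
    for (e in elements) {
      if (is_ins[e]) { push("I", w[e]); next }
      if (!is.na(prev_ref)) {
        # elements are genomically ascending for either orientation
        g <- plan$start[e] - plan$end[prev_ref]
        gap_lo <- plan$end[prev_ref]
        if (g > 0) {
          op <- if (gap_inside_exon(plan$chrom[e], gap_lo, gap_lo + g)) "D" else "N"
          push(op, g)
        }
      }
      push("M", w[e])
      prev_ref <- e
    }
    q0 <- min(qstart[rows]); q1 <- max(qend[rows])
    clip_left_q <- q0; clip_right_q <- contig_len - q1
    sl <- if (rc) clip_right_q else clip_left_q
    sr <- if (rc) clip_left_q else clip_right_q
    cigar_parts <- character(0)
    if (sl > 0) cigar_parts <- c(cigar_parts, paste0(sl, "S"))
    cigar_parts <- c(cigar_parts, paste0(lens, ops))
    if (sr > 0) cigar_parts <- c(cigar_parts, paste0(sr, "S"))
    ref_rows <- rows[!is_ins[rows]]
    flag <- (if (rc) 16L else 0L) + (if (gi > 1) 2048L else 0L)
    recs[[gi]] <- tibble(
      qname = contig_id,
      flag = flag,
      rname = plan$chrom[ref_rows[1]],
      pos = min(plan$start[ref_rows]) + 1L,  # SAM 1-based
      mapq = 60L,
      cigar = paste0(cigar_parts, collapse = ""),
      seq = if (rc) revcomp(contig_seq) else contig_seq
    )
  }
  bind_rows(recs)
}
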