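# Variant simulator -------------------------------------------------------
#
# Implements the 15-class benchmark: 5 fusion subtypes, 5 transcribed
# structural variants (TSVs) and 5 novel splice variants (NSVs), built by
# editing segment plans of randomly chosen eligible transcripts. Small TSV
# edits (ins/del/ITD) are 7-49 bp and sit at least 10 bp inside an exon;
# exon-scale features (extensions, novel exons, truncations, gaps) are
# 30-199 bp; retained introns require an intron > 30 bp.

VARIANT_TYPES <- c("fusion_canonical", "fusion_extended_exon", "fusion_novel_exon",
                   "fusion_insertion", "fusion_unpartnered",
                   "ins", "del", "itd", "ptd", "inv",
                   "ee", "ne", "trunc", "nj", "ri")

#' The 15 simulated variant types
#'
#' Returns the variant-type vocabulary grouped into fusions, transcribed
#' structural variants and novel splice variants (5/5/5).
#'
#' @return Tibble with columns `vtype` and `group`.
#' @export
variant_types <- function() {
  tibble(vtype = VARIANT_TYPES,
         group = rep(c("fusion", "tsv", "nsv"), each = 5L))
}

# plausible output classes for each simulated type (used by the
# classification-consistency metric)
expected_classes_for <- function(vtype) {
  switch(vtype,
    fusion_canonical = ,
    fusion_extended_exon = ,
    fusion_novel_exon = ,
    fusion_insertion = ,
    fusion_unpartnered = c("fusion", "unknown"),
    itd = c("insertion", "unknown", "intragenic_rearrangement"),
    ptd = ,
    inv = c("intragenic_rearrangement", "unknown"),
    ins = "insertion",
    del = "deletion",
    ee = ,
    ne = "novel_extended_exon",
    nj = ,
    trunc = "novel_exon_junction",
    ri = "retained_intron",
    abort(sprintf("unknown variant type '%s'", vtype))
  )
}

#' Transcripts eligible for simulation
#'
#' A transcript is eligible when its gene overlaps no other gene and it has
#' at least 3 exons. Returned in deterministic (transcript id) order.
#'
#' @param annotation A `tx_annotation`.
#' @return Tibble of eligible transcripts (subset of
#'   `annotation$transcripts`).
#' @export
select_eligible_transcripts <- function(annotation) {
  self <- GenomicRanges::findOverlaps(annotation$gene_gr, annotation$gene_gr)
  ov <- S4Vectors::queryHits(self) != S4Vectors::subjectHits(self)
  overlapping <- annotation$genes$gene_id[unique(S4Vectors::queryHits(self)[ov])]
  out <- annotation$transcripts |>
    filter(!.data$gene_id %in% overlapping, .data$n_exons >= 3) |>
    arrange(.data$transcript_id)
  if (nrow(out) == 0) abort("no eligible transcripts: simulation infeasible")
  out
}

sample_range <- function(lo, hi) {
  if (hi < lo) abort("infeasible sampling range")
  if (lo == hi) return(as.integer(lo))
  sample(seq.int(lo, hi), 1L)
}

tx_gene <- function(annotation, tx_id) {
  annotation$transcripts$gene_id[match(tx_id, annotation$transcripts$transcript_id)]
}

new_truth <- function(vtype, genes, transcripts, size_bp, plan, genome) {
  list(vtype = vtype, genes = genes, transcripts = transcripts,
       size_bp = size_bp, plan = plan,
       variant_sequence = plan_sequence(plan, genome),
       expected_classes = expected_classes_for(vtype))
}

#' Simulate a fusion variant
#'
#' Joins the first two exons of `tx_a` to the last two exons of `tx_b`
#' (canonical), optionally with an extended exon (30-199 bp of intronic
#' sequence appended after the second exon of `tx_a`), a novel exon (a
#' 30-199 bp intronic block 30-199 bp downstream), or a 7-49 bp random
#' insertion between the partners. Unpartnered fusions join the first two
#' exons of `tx_a` to a cryptic two-exon block in intergenic sequence at
#' least 10 kb from any gene (`desert_base` names the locus).
#'
#' @param annotation A `tx_annotation`.
#' @param genome Named character vector of chromosome sequences.
#' @param subtype One of `fusion_canonical`, `fusion_extended_exon`,
#'   `fusion_novel_exon`, `fusion_insertion`, `fusion_unpartnered`.
#' @param tx_a,tx_b Transcript ids of the 5' and 3' partners (`tx_b` ignored
#'   for unpartnered fusions).
#' @param desert_base List `(chrom, base)` locating the intergenic block for
#'   unpartnered fusions.
#' @return A truth record (list) with the variant plan, sequence, genes and
#'   expected classification set.
#' @export
make_fusion <- function(annotation, genome, subtype, tx_a, tx_b = NULL,
                        desert_base = NULL) {
  stopifnot(subtype %in% VARIANT_TYPES[1:5])
  plan_a <- wt_plan(annotation, tx_a)[1:2, ]
  gene_a <- tx_gene(annotation, tx_a)
  if (subtype == "fusion_unpartnered") {
    if (is.null(desert_base)) abort("unpartnered fusion needs a desert_base locus")
    b1 <- sample_range(30L, 199L); gap <- sample_range(100L, 500L)
    b2 <- sample_range(30L, 199L)
    base <- as.integer(desert_base$base)
    blocks <- bind_rows(
      seg_ref(desert_base$chrom, base, base + b1),
      seg_ref(desert_base$chrom, base + b1 + gap, base + b1 + gap + b2))
    plan <- bind_rows(plan_a, blocks)
    return(new_truth(subtype, gene_a, tx_a, NA_integer_, plan, genome))
  }
  if (is.null(tx_b)) abort("partnered fusion needs tx_b")
  gene_b <- tx_gene(annotation, tx_b)
  if (identical(gene_a, gene_b)) abort("fusion partners must come from different genes")
  pb <- wt_plan(annotation, tx_b)
  plan_b <- pb[(nrow(pb) - 1):nrow(pb), ]
  size <- NA_integer_
  mid <- NULL
  if (subtype == "fusion_extended_exon") {
    full_a <- wt_plan(annotation, tx_a)
    giv <- diff(downstream_gap(full_a, 2L))
    size <- sample_range(30L, min(199L, giv - 1L))
    plan_a[2, ] <- extend_downstream(plan_a[2, ], size)
  } else if (subtype == "fusion_novel_exon") {
    full_a <- wt_plan(annotation, tx_a)
    giv <- diff(downstream_gap(full_a, 2L))
    repeat {
      gap <- sample_range(30L, 199L); size <- sample_range(30L, 199L)
      if (gap + size < giv) break
    }
    mid <- offset_block(plan_a[2, ], gap, size)
  } else if (subtype == "fusion_insertion") {
    size <- sample_range(7L, 49L)
    mid <- seg_ins(random_dna(size))
  }
  plan <- bind_rows(plan_a, mid, plan_b)
  new_truth(subtype, c(gene_a, gene_b), c(tx_a, tx_b), size, plan, genome)
}

#' Simulate a transcribed structural variant
#'
#' `ins`, `del` and `itd` edit 7-49 bp within one random exon, with both edit
#' endpoints at least 10 bp from the exon ends; `itd` duplicates the segment
#' in tandem. `ptd` duplicates, and `inv` reverse-complements, a run of 1-3
#' random exons in place.
#'
#' @inheritParams make_fusion
#' @param subtype One of `ins`, `del`, `itd`, `ptd`, `inv`.
#' @param tx_id Source transcript.
#' @return A truth record (list); see [make_fusion()].
#' @export
make_tsv <- function(annotation, genome, subtype, tx_id) {
  stopifnot(subtype %in% c("ins", "del", "itd", "ptd", "inv"))
  plan <- wt_plan(annotation, tx_id)
  n <- nrow(plan)
  gene <- tx_gene(annotation, tx_id)
  w <- seg_widths(plan)
  if (subtype %in% c("ins", "del", "itd")) {
    size <- sample_range(7L, 49L)
    ok <- which(w >= (if (subtype == "ins") 20L else 20L + size))
    if (!length(ok)) abort("no exon long enough for the edit: infeasible")
    k <- ok[sample.int(length(ok), 1L)]
    if (subtype == "ins") {
      p <- sample_range(10L, w[k] - 10L)
      parts <- split_seg(plan[k, ], p)
      newk <- bind_rows(parts[1, ], seg_ins(random_dna(size)), parts[2, ])
    } else {
      q <- sample_range(10L, w[k] - 10L - size)
      parts <- split_seg(plan[k, ], q)
      sub <- split_seg(parts[2, ], size)
      dup <- sub[1, ]
      if (subtype == "del") {
        newk <- bind_rows(parts[1, ], sub[2, ])
      } else {
        dup_seq <- plan_sequence(dup, genome)
        newk <- bind_rows(parts[1, ], dup, seg_ins(dup_seq), sub[2, ])
      }
    }
    plan <- bind_rows(plan[seq_len(k - 1), ], newk,
                      if (k < n) plan[(k + 1):n, ])
    return(new_truth(subtype, gene, tx_id, size, plan, genome))
  }
  # ptd / inv: run of 1-3 exons, never the whole transcript
  j <- sample_range(1L, min(3L, n - 1L))
  a <- sample_range(1L, n - j + 1L)
  run <- a:(a + j - 1L)
  size <- sum(w[run])
  if (subtype == "ptd") {
    plan <- bind_rows(plan[seq_len(a + j - 1L), ], plan[run, ],
                      if (a + j <= n) plan[(a + j):n, ])
  } else {
    inv <- plan[rev(run), ]
    inv$rc <- !inv$rc
    plan <- bind_rows(plan[seq_len(a - 1L), ], inv,
                      if (a + j <= n) plan[(a + j):n, ])
  }
  new_truth(subtype, gene, tx_id, size, plan, genome)
}

#' Simulate a novel splice variant
#'
#' `ee` appends 30-199 bp of immediately-downstream intronic sequence to a
#' random exon; `ne` inserts a 30-199 bp intronic block 30-199 bp downstream
#' of a random exon (verified to overlap no annotated exon); `trunc` shortens
#' two neighbouring exons at their facing ends by 30-199 bp each; `nj` joins
#' a random non-adjacent exon pair whose junction is not annotated (skipped
#' exon); `ri` retains one full intron longer than 30 bp.
#'
#' @inheritParams make_tsv
#' @param subtype One of `ee`, `ne`, `trunc`, `nj`, `ri`.
#' @return A truth record (list); see [make_fusion()].
#' @export
make_splice_variant <- function(annotation, genome, subtype, tx_id) {
  stopifnot(subtype %in% c("ee", "ne", "trunc", "nj", "ri"))
  plan <- wt_plan(annotation, tx_id)
  n <- nrow(plan)
  gene <- tx_gene(annotation, tx_id)
  w <- seg_widths(plan)
  if (subtype == "ee") {
    k <- sample_range(1L, n - 1L)
    giv <- diff(downstream_gap(plan, k))
    size <- sample_range(30L, min(199L, giv - 1L))
    plan[k, ] <- extend_downstream(plan[k, ], size)
    return(new_truth(subtype, gene, tx_id, size, plan, genome))
  }
  if (subtype == "ne") {
    for (try in 1:50) {
      k <- sample_range(1L, n - 1L)
      giv <- diff(downstream_gap(plan, k))
      if (giv < 62L) next
      gap <- sample_range(30L, 199L); size <- sample_range(30L, 199L)
      if (gap + size >= giv) next
      blk <- offset_block(plan[k, ], gap, size)
      hit <- GenomicRanges::findOverlaps(gr0(blk$chrom, blk$start, blk$end),
                                         annotation$exon_gr)
      if (length(hit)) next
      newplan <- bind_rows(plan[seq_len(k), ], blk, plan[(k + 1):n, ])
      return(new_truth(subtype, gene, tx_id, size, newplan, genome))
    }
    abort("could not place a novel exon: infeasible for this transcript")
  }
  if (subtype == "trunc") {
    k <- sample_range(1L, n - 1L)
    if (w[k] < 50L || w[k + 1] < 50L) {
      ok <- which(head(w, -1) >= 50L & tail(w, -1) >= 50L)
      if (!length(ok)) abort("no exon pair long enough to truncate")
      k <- ok[sample.int(length(ok), 1L)]
    }
    t1 <- sample_range(30L, min(199L, w[k] - 20L))
    t2 <- sample_range(30L, min(199L, w[k + 1] - 20L))
    a <- plan[k, ]; b <- plan[k + 1, ]
    if (a$rc) a$start <- a$start + t1 else a$end <- a$end - t1
    if (b$rc) b$end <- b$end - t2 else b$start <- b$start + t2
    plan[k, ] <- a; plan[k + 1, ] <- b
    return(new_truth(subtype, gene, tx_id, t1 + t2, plan, genome))
  }
  if (subtype == "nj") {
    if (n < 3) abort("skipped-exon variant needs >= 3 exons")
    for (try in 1:50) {
      i <- sample_range(1L, n - 2L)
      j <- sample_range(i + 2L, n)
      a <- plan[i, ]; b <- plan[j, ]
      key <- if (a$rc) paste(a$chrom, b$end, a$start) else paste(a$chrom, a$end, b$start)
      if (key %in% annotation$junction_keys) next
      newplan <- bind_rows(plan[seq_len(i), ], plan[j:n, ])
      return(new_truth(subtype, gene, tx_id, NA_integer_, newplan, genome))
    }
    abort("could not find an unannotated exon pair to join")
  }
  # ri: retain a full intron > 30 bp
  cand <- which(vapply(seq_len(n - 1L), function(k) diff(downstream_gap(plan, k)) > 30L,
                       logical(1)))
  if (!length(cand)) abort("no intron > 30 bp: retained intron infeasible")
  k <- cand[sample.int(length(cand), 1L)]
  a <- plan[k, ]; b <- plan[k + 1, ]
  size <- diff(downstream_gap(plan, k))
  merged <- if (a$rc) seg_ref(a$chrom, b$start, a$end, TRUE)
            else seg_ref(a$chrom, a$start, b$end, FALSE)
  plan <- bind_rows(plan[seq_len(k - 1L), ], merged,
                    if (k + 2L <= n) plan[(k + 2L):n, ])
  new_truth("ri", gene, tx_id, as.integer(size), plan, genome)
}
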