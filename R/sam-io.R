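# SAM reading/writing ------------------------------------------------------

#' Write alignment records to SAM
#'
#' Minimal SAM writer for contig alignments: a sorted `@SQ` header followed
#' by the records in (qname, rname, pos) order so output is deterministic.
#'
#' @param records Tibble with `qname`, `flag`, `rname`, `pos` (1-based),
#'   `mapq`, `cigar`, `seq`.
#' @param genome Named sequence vector (or `DNAStringSet`) providing `@SQ`
#'   lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, genome, path) {
  genome <- as_seq_store(genome)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", sort(names(genome)),
                   nchar(genome)[order(names(genome))]))
  records <- arrange(records, .data$qname, .data$rname, .data$pos)
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                  records$qname, records$flag, records$rname, records$pos,
                  records$mapq, records$cigar, records$seq)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Load contig alignments from SAM
#'
#' Reads a (headered or headerless) SAM text file and groups records by
#' contig. 1-based positions are converted to the package's 0-based
#' convention; soft/hard clip lengths and the contig length implied by the
#' CIGAR are recorded. Unmapped records are dropped.
#'
#' @param sam_path Path to a SAM file.
#' @return Tibble with one row per alignment record: `contig_id`, `chrom`,
#'   `pos` (0-based leftmost), `strand`, `cigar`, `is_supplementary`,
#'   `contig_length`.
#' @export
load_alignments <- function(sam_path) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    return(tibble(contig_id = character(), chrom = character(), pos = integer(),
                  strand = character(), cigar = character(),
                  is_supplementary = logical(), contig_length = integer()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11)) abort(sprintf("malformed SAM record at line %d", which(nf < 11)[1]))
  flag <- as.integer(vapply(f, `[[`, character(1), 2))
  rec <- tibble(
    contig_id = vapply(f, `[[`, character(1), 1),
    flag = flag,
    chrom = vapply(f, `[[`, character(1), 3),
    pos = as.integer(vapply(f, `[[`, character(1), 4)) - 1L,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    cigar = vapply(f, `[[`, character(1), 6),
    seq = vapply(f, `[[`, character(1), 10)
  )
  rec <- rec[bitwAnd(rec$flag, 4L) == 0L & rec$cigar != "*", ]
  ops <- GenomicAlignments::explodeCigarOps(rec$cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(rec$cigar)
  qlen <- mapply(function(o, l) sum(l[o %in% c("M", "I", "S", "=", "X", "H")]),
                 ops, lens)
  seq_len_ok <- rec$seq == "*" |
    nchar(rec$seq) == mapply(function(o, l) sum(l[o %in% c("M", "I", "S", "=", "X")]),
                             ops, lens)
  if (!all(seq_len_ok)) {
    abort(sprintf("CIGAR/sequence length mismatch for contig '%s'",
                  rec$contig_id[!seq_len_ok][1]))
  }
  rec$is_supplementary <- bitwAnd(rec$flag, 2048L) > 0L
  rec$contig_length <- as.integer(qlen)
  select(rec, "contig_id", "chrom", "pos", "strand", "cigar",
         "is_supplementary", "contig_length")
}

# Walk one CIGAR from a 0-based leftmost position. Returns aligned blocks
# (ref and query 0-based half-open intervals) and events (I/D/N/S/H with
# genomic position). Query coordinates are in SEQ orientation.
walk_cigar <- function(cigar, pos0) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  ref <- pos0
  q <- 0L
  blocks <- list(); events <- list()
  for (i in seq_along(ops)) {
    op <- ops[i]; len <- lens[i]
    if (op %in% c("M", "=", "X")) {
      blocks[[length(blocks) + 1]] <- tibble(rstart = ref, rend = ref + len,
                                             qstart = q, qend = q + len)
      ref <- ref + len; q <- q + len
    } else if (op == "I") {
      events[[length(events) + 1]] <- tibble(kind = "ins", rstart = ref,
                                             rend = ref, size = len, qpos = q)
      q <- q + len
    } else if (op == "D") {
      events[[length(events) + 1]] <- tibble(kind = "del", rstart = ref,
                                             rend = ref + len, size = len, qpos = q)
      ref <- ref + len
    } else if (op == "N") {
      events[[length(events) + 1]] <- tibble(kind = "junction", rstart = ref,
                                             rend = ref + len, size = len, qpos = q)
      ref <- ref + len
    } else if (op %in% c("S", "H")) {
      events[[length(events) + 1]] <- tibble(kind = "clip", rstart = ref,
                                             rend = ref, size = len, qpos = q)
      if (op == "S") q <- q + len
    }
  }
  if (!length(blocks)) {
    blocks <- list(tibble(rstart = integer(), rend = integer(),
                          qstart = integer(), qend = integer()))
  }
  list(blocks = bind_rows(blocks),
       events = if (length(events)) bind_rows(events) else
         tibble(kind = character(), rstart = integer(), rend = integer(),
                size = integer(), qpos = integer()))
}
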