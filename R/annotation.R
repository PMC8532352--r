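#' Build an annotation index from an exon table
#'
#' The annotation index is the reference against which novelty is defined: it
#' holds per-transcript exon structure, the set of annotated splice junctions,
#' gene extents and fast interval lookup structures. All coordinates are
#' 0-based half-open; conversion from GTF's 1-based inclusive convention
#' happens in [read_gtf()] only.
#'
#' @param exons Tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `gene_id`, `transcript_id` (0-based half-open).
#' @return An object of class `tx_annotation` with elements `exons`,
#'   `transcripts`, `genes`, `junctions` and internal lookup indexes.
#' @export
annotation_index <- function(exons) {
  exons <- as_tibble(exons)
  need <- c("chrom", "start", "end", "strand", "gene_id", "transcript_id")
  miss <- setdiff(need, names(exons))
  if (length(miss)) abort(paste0("exon table lacks column(s): ", paste(miss, collapse = ", ")))
  if (any(exons$start < 0) || any(exons$start >= exons$end)) {
    abort("exon intervals must satisfy 0 <= start < end")
  }
  exons <- arrange(exons, .data$chrom, .data$start, .data$end, .data$transcript_id)
  # per-transcript consistency + genomic exon order
  chk <- exons |>
    group_by(.data$transcript_id) |>
    summarise(one_chrom = dplyr::n_distinct(.data$chrom) == 1,
              one_strand = dplyr::n_distinct(.data$strand) == 1,
              sorted_disjoint = all(diff(.data$start) > 0) && all(head(.data$end, -1) <= tail(.data$start, -1)),
              .groups = "drop")
  bad <- chk$transcript_id[!(chk$one_chrom & chk$one_strand & chk$sorted_disjoint)]
  if (length(bad)) {
    abort(paste0("transcript(s) with inconsistent or overlapping exons: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  exons <- exons |>
    group_by(.data$transcript_id) |>
    mutate(genomic_rank = row_number(),
           exon_rank = if (.data$strand[1] == "-") rev(row_number()) else row_number()) |>
    ungroup()

  transcripts <- exons |>
    group_by(.data$transcript_id) |>
    summarise(gene_id = .data$gene_id[1], chrom = .data$chrom[1],
              strand = .data$strand[1], n_exons = n(),
              start = min(.data$start), end = max(.data$end),
              length = sum(.data$end - .data$start), .groups = "drop") |>
    arrange(.data$transcript_id)

  genes <- exons |>
    group_by(.data$gene_id) |>
    summarise(chrom = .data$chrom[1], start = min(.data$start),
              end = max(.data$end), strand = .data$strand[1], .groups = "drop") |>
    arrange(.data$gene_id)

  # junctions from consecutive exons (genomic order) of each transcript
  junctions <- exons |>
    group_by(.data$transcript_id) |>
    dplyr::reframe(chrom = .data$chrom[1], strand = .data$strand[1],
                   donor_end = head(.data$end, -1),
                   acceptor_start = tail(.data$start, -1)) |>
    filter(!is.na(.data$donor_end)) |>
    distinct(.data$chrom, .data$donor_end, .data$acceptor_start, .data$strand) |>
    arrange(.data$chrom, .data$donor_end, .data$acceptor_start)

  merged <- GenomicRanges::reduce(gr0(exons$chrom, exons$start, exons$end))
  exon_merged <- split(
    tibble(start = GenomicRanges::start(merged) - 1L,
           end = GenomicRanges::end(merged)),
    as.character(GenomicRanges::seqnames(merged)))

  structure(list(
    exons = exons,
    transcripts = transcripts,
    genes = genes,
    junctions = junctions,
    exon_merged = exon_merged,
    exon_gr = gr0(exons$chrom, exons$start, exons$end),
    gene_gr = gr0(genes$chrom, genes$start, genes$end),
    junction_keys = paste(junctions$chrom, junctions$donor_end, junctions$acceptor_start),
    exon_start_keys = unique(paste(exons$chrom, exons$start)),
    exon_end_keys = unique(paste(exons$chrom, exons$end))
  ), class = "tx_annotation")
}

#' @export
print.tx_annotation <- function(x, ...) {
  cat(sprintf("<tx_annotation> %d genes, %d transcripts, %d exons, %d junctions\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons), nrow(x$junctions)))
  invisible(x)
}

#' Read a GTF annotation into an annotation index
#'
#' Only `exon` features are used; `gene_id` and `transcript_id` attributes are
#' required. GTF 1-based inclusive coordinates are converted to the package's
#' 0-based half-open convention at parse time.
#'
#' @param path Path to a GTF file.
#' @param sequence_store Optional genome (named character vector or
#'   `DNAStringSet`); when supplied, exons outside chromosome bounds raise an
#'   error.
#' @return A `tx_annotation`.
#' @export
read_gtf <- function(path, sequence_store = NULL) {
  g <- rtracklayer::import(path, format = "gtf")
  g <- g[g$type == "exon"]
  if (length(g) == 0) abort("GTF contains no exon features")
  for (attr in c("gene_id", "transcript_id")) {
    v <- S4Vectors::mcols(g)[[attr]]
    if (is.null(v) || anyNA(v) || any(v == "")) {
      bad <- if (is.null(v)) seq_along(g) else which(is.na(v) | v == "")
      abort(sprintf("GTF exon record(s) missing %s attribute (e.g. exon record %d)",
                    attr, bad[1]))
    }
  }
  exons <- tibble(
    chrom = as.character(GenomicRanges::seqnames(g)),
    start = GenomicRanges::start(g) - 1L,
    end = GenomicRanges::end(g),
    strand = as.character(GenomicRanges::strand(g)),
    gene_id = g$gene_id,
    transcript_id = g$transcript_id
  )
  if (!is.null(sequence_store)) {
    store <- as_seq_store(sequence_store)
    lens <- setNames(nchar(store), names(store))
    if (!all(exons$chrom %in% names(store))) {
      abort("GTF references chromosomes absent from the sequence store")
    }
    if (any(exons$end > lens[exons$chrom])) {
      abort("exon(s) extend beyond chromosome sequence bounds")
    }
  }
  annotation_index(exons)
}

#' Write an annotation index to GTF
#'
#' Emits one `exon` feature per exon with `gene_id` and `transcript_id`
#' attributes, 1-based inclusive coordinates, sorted deterministically.
#'
#' @param annotation A `tx_annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  ex <- arrange(annotation$exons, .data$chrom, .data$gene_id, .data$transcript_id, .data$start)
  lines <- sprintf(
    '%s\ttxsv\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    ex$chrom, ex$start + 1L, ex$end, ex$strand, ex$gene_id, ex$transcript_id
  )
  writeLines(lines, path)
  invisible(path)
}

#' Spliced transcript sequences
#'
#' Concatenates exon sequences in transcription order: exons are stored in
#' genomic order and the concatenation is reverse-complemented for
#' minus-strand transcripts.
#'
#' @param annotation A `tx_annotation`.
#' @param genome Named character vector or `DNAStringSet` of chromosome
#'   sequences.
#' @param transcript_ids Transcripts to extract (default: all).
#' @return Named character vector of spliced sequences.
#' @export
transcript_sequences <- function(annotation, genome, transcript_ids = NULL) {
  genome <- as_seq_store(genome)
  ids <- transcript_ids %||% annotation$transcripts$transcript_id
  ex <- filter(annotation$exons, .data$transcript_id %in% ids)
  lens <- setNames(nchar(genome), names(genome))
  if (any(ex$end > lens[ex$chrom]) || any(ex$start < 0)) {
    abort("exon(s) out of bounds of the supplied genome")
  }
  pieces <- substr(rep(genome[ex$chrom], 1L), ex$start + 1L, ex$end)
  out <- vapply(split(seq_len(nrow(ex)), ex$transcript_id)[ids], function(i) {
    s <- paste0(pieces[i], collapse = "")
    if (ex$strand[i[1]] == "-") revcomp(s) else s
  }, character(1))
  setNames(out, ids)
}

#' @rdname transcript_sequences
#' @param transcript_id A single transcript id.
#' @export
transcript_sequence <- function(annotation, genome, transcript_id) {
  stopifnot(length(transcript_id) == 1)
  unname(transcript_sequences(annotation, genome, transcript_id))
}

#' Transcripts overlapping a genomic point
#'
#' Interval lookup into the exon index: returns the transcripts having an
#' exon that covers `pos` (0-based) on `chrom`.
#'
#' @param annotation A `tx_annotation`.
#' @param chrom Chromosome name.
#' @param pos 0-based position.
#' @return Character vector of transcript ids.
#' @export
exon_lookup <- function(annotation, chrom, pos) {
  hits <- GenomicRanges::findOverlaps(gr0(chrom, pos, pos + 1L), annotation$exon_gr)
  sort(unique(annotation$exons$transcript_id[S4Vectors::subjectHits(hits)]))
}

# gene ids whose extent overlaps the 0-based interval [start,end)
genes_overlapping <- function(annotation, chrom, start, end) {
  hits <- GenomicRanges::findOverlaps(gr0(chrom, start, end), annotation$gene_gr)
  sort(unique(annotation$genes$gene_id[S4Vectors::subjectHits(hits)]))
}

# vectorised form: one findOverlaps for many query intervals; returns a list
# of gene-id vectors parallel to the inputs
genes_overlapping_batch <- function(annotation, chrom, start, end) {
  n <- length(chrom)
  res <- rep(list(character(0)), n)
  if (n == 0) return(res)
  gr <- gr0(chrom, start, pmax(end, start + 1L))
  hits <- GenomicRanges::findOverlaps(gr, annotation$gene_gr)
  sp <- split(annotation$genes$gene_id[S4Vectors::subjectHits(hits)],
              S4Vectors::queryHits(hits))
  res[as.integer(names(sp))] <- lapply(sp, function(x) sort(unique(x)))
  res
}
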