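#' Generate a synthetic genome with clean multi-exon genes
#'
#' Builds a random genome whose genes are pairwise non-overlapping, carry one
#' multi-exon transcript each, and whose introns all start `GT` and end `AG`
#' on the transcribed strand (the canonical splice motif), so downstream
#' motif checks can pass. Each chromosome ends in a gene "desert" - an
#' intergenic stretch at least 10 kb from any gene - used by the simulator to
#' place unpartnered fusion partners. The generator emits in-memory objects;
#' use [write_genome()] to materialise FASTA + GTF for external tools.
#'
#' @param n_genes Number of genes (>= 1).
#' @param exons_per_gene Integer range `c(min, max)` of exons per gene
#'   (min >= 3 so every transcript is eligible for simulation).
#' @param exon_len Range of exon lengths in bp.
#' @param intron_len Range of intron lengths in bp.
#' @param intergenic_gap Minimum gap between neighbouring genes in bp.
#' @param desert_len Length of the intergenic desert at each chromosome end.
#' @param genes_per_chrom Genes placed per chromosome.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A list of class `synthetic_genome` with elements `genome` (named
#'   character vector of chromosome sequences), `annotation`
#'   (`tx_annotation`) and `deserts` (tibble of intergenic desert intervals).
#' @export
generate_synthetic_genome <- function(n_genes,
                                      exons_per_gene = c(4L, 7L),
                                      exon_len = c(120L, 300L),
                                      intron_len = c(400L, 800L),
                                      intergenic_gap = 2000L,
                                      desert_len = 120000L,
                                      genes_per_chrom = 250L,
                                      seed = 1L) {
  if (n_genes < 1) abort("n_genes must be >= 1")
  rng_ok <- function(r) length(r) == 2 && r[1] <= r[2] && r[1] > 0
  if (!rng_ok(exons_per_gene) || exons_per_gene[1] < 3) {
    abort("exons_per_gene must be a positive range with min >= 3")
  }
  if (!rng_ok(exon_len) || !rng_ok(intron_len) || intergenic_gap < 1 || desert_len < 1) {
    abort("infeasible length configuration")
  }
  set.seed(seed)
  n_chrom <- ceiling(n_genes / genes_per_chrom)
  gene_chrom <- rep(seq_len(n_chrom), each = genes_per_chrom)[seq_len(n_genes)]
  gid <- sprintf("GENE%05d", seq_len(n_genes))
  txid <- sprintf("TX%05d", seq_len(n_genes))

  exon_rows <- vector("list", n_genes)
  intron_rows <- vector("list", n_genes)
  chrom_cursor <- setNames(rep(1000L, n_chrom), paste0("chr", seq_len(n_chrom)))
  for (i in seq_len(n_genes)) {
    chrom <- paste0("chr", gene_chrom[i])
    n_ex <- sample(seq(exons_per_gene[1], exons_per_gene[2]), 1L)
    ex_lens <- sample(seq(exon_len[1], exon_len[2]), n_ex, replace = TRUE)
    in_lens <- sample(seq(intron_len[1], intron_len[2]), n_ex - 1L, replace = TRUE)
    strand <- sample(c("+", "-"), 1L)
    pos <- chrom_cursor[[chrom]]
    starts <- integer(n_ex); ends <- integer(n_ex)
    istarts <- integer(n_ex - 1L); iends <- integer(n_ex - 1L)
    for (j in seq_len(n_ex)) {
      starts[j] <- pos
      ends[j] <- pos + ex_lens[j]
      pos <- ends[j]
      if (j < n_ex) {
        istarts[j] <- pos
        iends[j] <- pos + in_lens[j]
        pos <- iends[j]
      }
    }
    chrom_cursor[[chrom]] <- pos + intergenic_gap
    exon_rows[[i]] <- tibble(chrom = chrom, start = starts, end = ends,
                             strand = strand, gene_id = gid[i], transcript_id = txid[i])
    intron_rows[[i]] <- tibble(chrom = chrom, start = istarts, end = iends, strand = strand)
  }
  exons <- bind_rows(exon_rows)
  introns <- bind_rows(intron_rows)

  deserts <- tibble(
    chrom = names(chrom_cursor),
    start = unname(chrom_cursor) + 10000L,
    end = unname(chrom_cursor) + 10000L + desert_len
  )
  chrom_len <- setNames(deserts$end + 1000L, deserts$chrom)

  genome <- vapply(names(chrom_len), function(ch) {
    raw <- charToRaw("ACGT")[sample.int(4L, chrom_len[[ch]], replace = TRUE)]
    ii <- introns[introns$chrom == ch, ]
    if (nrow(ii)) {
      plus <- ii$strand == "+"
      # transcribed-strand GT..AG: plus introns GT..AG genomically, minus CT..AC
      if (any(plus)) {
        raw[ii$start[plus] + 1L] <- charToRaw("G")
        raw[ii$start[plus] + 2L] <- charToRaw("T")
        raw[ii$end[plus] - 1L] <- charToRaw("A")
        raw[ii$end[plus]] <- charToRaw("G")
      }
      if (any(!plus)) {
        raw[ii$start[!plus] + 1L] <- charToRaw("C")
        raw[ii$start[!plus] + 2L] <- charToRaw("T")
        raw[ii$end[!plus] - 1L] <- charToRaw("A")
        raw[ii$end[!plus]] <- charToRaw("C")
      }
    }
    rawToChar(raw)
  }, character(1))

  structure(list(genome = genome,
                 annotation = annotation_index(exons),
                 deserts = deserts),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("<synthetic_genome> %d chromosome(s) (%.1f Mb), %d genes\n",
              length(x$genome), sum(nchar(x$genome)) / 1e6, nrow(x$annotation$genes)))
  invisible(x)
}

#' Write a synthetic genome to FASTA + GTF
#'
#' @param x A `synthetic_genome`.
#' @param fasta,gtf Output paths.
#' @return Invisibly, a named list of the two paths.
#' @export
write_genome <- function(x, fasta, gtf) {
  write_fasta_seqs(x$genome, fasta)
  write_gtf(x$annotation, gtf)
  invisible(list(fasta = fasta, gtf = gtf))
}
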