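#' Reverse-complement nucleotide strings
#'
#' Thin vectorised wrapper over [Biostrings::reverseComplement()].
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# uniform random DNA string(s); uses the current RNG stream
random_dna <- function(len) {
  vapply(len, function(l) {
    rawToChar(charToRaw("ACGT")[sample.int(4L, l, replace = TRUE)])
  }, character(1))
}

# 0-based half-open interval -> GRanges (1-based internally to Bioconductor)
gr0 <- function(chrom, start, end, strand = "*") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end), strand = strand)
}

# substring of a genome (named character vector), 0-based half-open
genome_substr <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) {
    abort(sprintf("chromosome '%s' not present in genome", chrom))
  }
  s <- genome[[chrom]]
  if (start < 0 || end > nchar(s)) {
    abort(sprintf("interval [%d,%d) out of bounds for %s (length %d)",
                  start, end, chrom, nchar(s)))
  }
  substr(s, start + 1L, end)
}

# normalise a genome / sequence set to a named character vector, mapping
# non-ACGTN characters to N with a warning
as_seq_store <- function(x) {
  if (methods::is(x, "DNAStringSet")) x <- as.character(x)
  if (is.list(x)) x <- unlist(x)
  if (is.character(x) && length(x) == 0) return(setNames(character(0), character(0)))
  stopifnot(is.character(x), !is.null(names(x)))
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    warn(sprintf("%d sequence(s) contain non-ACGTN characters; mapped to N", sum(bad)))
    x[bad] <- gsub("[^ACGTN]", "N", x[bad])
  }
  x
}

#' Read a genome or transcript FASTA into a named sequence vector
#'
#' Sequences are upper-cased and any non-ACGTN character is replaced by `N`
#' with a warning. FASTA descriptions are truncated at the first whitespace.
#'
#' @param path Path to a FASTA file (plain or gzipped).
#' @return Named character vector of sequences.
#' @export
read_fasta_seqs <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  as_seq_store(x)
}

#' Write sequences to FASTA
#'
#' Records are written in name order so output is deterministic.
#'
#' @param seqs Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @param sort Sort records by name first (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_fasta_seqs <- function(seqs, path, sort = TRUE) {
  seqs <- as_seq_store(seqs)
  if (sort) seqs <- seqs[order(names(seqs))]
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
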