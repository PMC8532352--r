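# Paired-end read simulation ----------------------------------------------

#' Simulate paired-end reads from a set of sequences
#'
#' Fragments of fixed length are sampled uniformly along each sequence to
#' reach the target per-sequence coverage; mate 1 is the fragment 5' end,
#' mate 2 the reverse complement of the 3' end. Substitution errors are
#' applied independently per base. Sequences shorter than the fragment
#' length are skipped with a warning.
#'
#' @param reference Named character vector (or `DNAStringSet`) of source
#'   sequences.
#' @param coverage Target per-sequence coverage; scalar or one value per
#'   sequence.
#' @param read_len Read length in bp (default 100).
#' @param fragment_len Fragment length in bp (default 300, fixed).
#' @param error_rate Per-base substitution probability (default 0.001; must
#'   be < 0.05).
#' @param seed Optional integer seed; given a seed the output is
#'   deterministic.
#' @return List with named character vectors `r1` and `r2` (same names, one
#'   entry per pair).
#' @export
simulate_reads <- function(reference, coverage = 50, read_len = 100L,
                           fragment_len = 300L, error_rate = 0.001,
                           seed = NULL) {
  reference <- as_seq_store(reference)
  if (read_len > fragment_len) abort("read_len must be <= fragment_len")
  if (any(coverage <= 0)) abort("coverage must be positive")
  if (error_rate < 0 || error_rate >= 0.05) abort("error_rate must be in [0, 0.05)")
  if (!is.null(seed)) set.seed(seed)
  coverage <- rep_len(coverage, length(reference))
  lens <- nchar(reference)
  short <- lens < fragment_len
  if (any(short)) {
    warn(sprintf("%d sequence(s) shorter than fragment_len skipped", sum(short)))
  }
  r1 <- vector("list", length(reference))
  r2 <- vector("list", length(reference))
  for (i in which(!short)) {
    L <- lens[i]
    n_pairs <- round(L * coverage[i] / (2 * read_len))
    if (n_pairs < 1) next
    st <- sample.int(L - fragment_len + 1L, n_pairs, replace = TRUE)  # 1-based
    s <- reference[[i]]
    m1 <- substring(s, st, st + read_len - 1L)
    m2 <- revcomp(substring(s, st + fragment_len - read_len, st + fragment_len - 1L))
    nm <- sprintf("%s_%d", names(reference)[i], seq_len(n_pairs))
    r1[[i]] <- setNames(m1, nm)
    r2[[i]] <- setNames(m2, nm)
  }
  r1 <- unlist(r1); r2 <- unlist(r2)
  if (is.null(r1)) r1 <- setNames(character(0), character(0))
  if (is.null(r2)) r2 <- setNames(character(0), character(0))
  if (error_rate > 0 && length(r1)) {
    r1 <- add_substitution_errors(r1, error_rate)
    r2 <- add_substitution_errors(r2, error_rate)
  }
  list(r1 = r1, r2 = r2)
}

# independent per-base substitutions at `rate`
add_substitution_errors <- function(reads, rate) {
  lens <- nchar(reads)
  n_err <- rbinom(length(reads), lens, rate)
  bases <- c("A", "C", "G", "T")
  for (i in which(n_err > 0)) {
    s <- reads[[i]]
    pos <- sample.int(lens[i], n_err[i])
    for (p in pos) {
      cur <- substr(s, p, p)
      substr(s, p, p) <- sample(setdiff(bases, cur), 1L)
    }
    reads[[i]] <- s
  }
  reads
}

#' Write paired reads to FASTQ
#'
#' Constant quality (`I`, Phred 40). Paths ending in `.gz` are compressed.
#'
#' @param reads List with `r1` and `r2` from [simulate_reads()].
#' @param path_r1,path_r2 Output paths.
#' @return Invisibly, the two paths.
#' @export
write_fastq <- function(reads, path_r1, path_r2) {
  wr <- function(x, path) {
    q <- Biostrings::BStringSet(strrep("I", nchar(x)))
    fq <- ShortRead::ShortReadQ(sread = Biostrings::DNAStringSet(unname(x)),
                                quality = ShortRead::FastqQuality(q),
                                id = Biostrings::BStringSet(names(x)))
    if (file.exists(path)) file.remove(path)
    ShortRead::writeFastq(fq, path, mode = "w", compress = grepl("\\.gz$", path))
  }
  wr(reads$r1, path_r1)
  wr(reads$r2, path_r2)
  invisible(c(path_r1, path_r2))
}

#' Read a FASTQ pair into memory
#'
#' @param path_r1,path_r2 FASTQ paths (plain or gzipped).
#' @return List with character vectors `r1` and `r2`.
#' @export
read_fastq_pair <- function(path_r1, path_r2) {
  rd <- function(p) {
    fq <- ShortRead::readFastq(p)
    setNames(as.character(ShortRead::sread(fq)),
             as.character(ShortRead::id(fq)))
  }
  list(r1 = rd(path_r1), r2 = rd(path_r2))
}

# accept either an in-memory read-pair list or c(fq1, fq2) paths
load_read_pairs <- function(x) {
  if (is.list(x) && all(c("r1", "r2") %in% names(x))) return(x)
  if (is.character(x) && length(x) == 2) return(read_fastq_pair(x[1], x[2]))
  abort("reads must be a list(r1, r2) or a character vector of two FASTQ paths")
}
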