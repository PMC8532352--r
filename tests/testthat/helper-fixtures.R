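# Shared fixtures, built in code and cached for the session ---------------

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixture_env)) assign(name, build(), .fixture_env)
  get(name, .fixture_env)
}

# small synthetic genome used across module tests
small_genome <- function() {
  fixture("small_genome", function() generate_synthetic_genome(60, seed = 13))
}

# a 2-per-type benchmark on the small genome
small_benchmark <- function() {
  fixture("small_benchmark", function() {
    sg <- fixture("bench_genome", function() generate_synthetic_genome(120, seed = 3))
    build_benchmark(sg, per_type = 2, n_background = 10, seed = 7)
  })
}

bench_genome <- function() {
  small_benchmark()
  get("bench_genome", .fixture_env)
}

# a hand-built two-gene annotation on a toy chromosome:
#   geneA/txA (+): exons [100,200) [300,400) [500,650)
#   geneB/txB (-): exons [1000,1120) [1300,1400) [1600,1700)
toy_annotation <- function() {
  annotation_index(tibble::tibble(
    chrom = "chrT",
    start = c(100L, 300L, 500L, 1000L, 1300L, 1600L),
    end = c(200L, 400L, 650L, 1120L, 1400L, 1700L),
    strand = rep(c("+", "-"), each = 3),
    gene_id = rep(c("geneA", "geneB"), each = 3),
    transcript_id = rep(c("txA", "txB"), each = 3)))
}

toy_genome <- function() {
  set.seed(99)
  c(chrT = txsv:::random_dna(2000L))
}

# deterministic random reads drawn from given sequences (error-free)
exact_reads_from <- function(seqs, n_per_seq = 5, read_len = 40, seed = 5) {
  set.seed(seed)
  unlist(lapply(names(seqs), function(nm) {
    s <- seqs[[nm]]
    st <- sample.int(nchar(s) - read_len + 1L, n_per_seq, replace = TRUE)
    substring(s, st, st + read_len - 1L)
  }))
}

# exhaustive substring-match oracle: ids of sequences containing the read in
# either orientation
substring_match_oracle <- function(read, seqs) {
  hitF <- vapply(seqs, function(s) grepl(read, s, fixed = TRUE), logical(1))
  hitR <- vapply(seqs, function(s) grepl(revcomp(read), s, fixed = TRUE), logical(1))
  sort(names(seqs)[hitF | hitR])
}
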