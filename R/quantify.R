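# K-mer pseudo-alignment and equivalence-class counting -------------------

as_named_seqs <- function(x) {
  if (is.character(x) && length(x) == 1 && is.null(names(x)) && file.exists(x)) {
    return(read_fasta_seqs(x))
  }
  as_seq_store(x)
}

#' Build a joint contig + reference k-mer index
#'
#' Assembled contigs are merged with the reference transcriptome and every
#' k-mer of every sequence is indexed against the set of sequences containing
#' it. Contigs are flagged so that equivalence classes can later be tested
#' for novelty (no reference member).
#'
#' @param contigs Named character vector, `DNAStringSet`, or FASTA path of
#'   assembled contigs.
#' @param ref_tx Reference transcriptome in the same forms.
#' @param k Odd k-mer length, 11-31 (default 31).
#' @return An `ec_index` (holds an external pointer; rebuild rather than
#'   serialise).
#' @export
build_ec_index <- function(contigs, ref_tx, k = 31L) {
  if (k %% 2 == 0 || k < 11 || k > 31) abort("k must be odd and within 11..31")
  contigs <- as_named_seqs(contigs)
  ref_tx <- as_named_seqs(ref_tx)
  ids <- c(names(contigs), names(ref_tx))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    abort(sprintf("duplicate sequence id(s) across contigs and reference: %s",
                  paste(head(unique(dup), 3), collapse = ", ")))
  }
  seqs <- c(unname(contigs), unname(ref_tx))
  is_contig <- c(rep(TRUE, length(contigs)), rep(FALSE, length(ref_tx)))
  if (any(nchar(seqs) < k)) {
    warn(sprintf("%d sequence(s) shorter than k=%d contribute no k-mers",
                 sum(nchar(seqs) < k), k))
  }
  ptr <- .cpp_build_index(ids, seqs, is_contig, as.integer(k))
  structure(list(ptr = ptr, ids = ids, is_contig = setNames(is_contig, ids),
                 lengths = setNames(nchar(seqs), ids), k = as.integer(k)),
            class = "ec_index")
}

#' @export
print.ec_index <- function(x, ...) {
  info <- .cpp_index_info(x$ptr)
  cat(sprintf("<ec_index> k=%d, %d sequences (%d contigs), %.0f k-mers\n",
              x$k, length(x$ids), sum(x$is_contig), info$n_kmers))
  invisible(x)
}

# sequence ids stored in an index (1-based positions map to this vector)
index_ids <- function(index) index$ids

#' Assign a single read to an equivalence class
#'
#' For each orientation (forward, reverse complement) the id-sets of the
#' read's k-mers that are present in the index are intersected; k-mers absent
#' from the index are skipped so isolated substitution errors do not destroy
#' the assignment. An orientation is valid when at least `min_frac` of the
#' read's k-mers are present and the intersection is non-empty; the
#' orientation with more present k-mers wins; a read equally compatible with
#' both orientations (the norm for reverse reads of an unstranded library)
#' gets the union of the two compatible sets.
#'
#' @param read_sequence A single read sequence.
#' @param index An `ec_index`.
#' @param min_frac Minimum fraction of the read's k-mers that must be present
#'   (default 0.5).
#' @return Sorted character vector of member ids, or `NULL` when unassigned.
#' @export
assign_read <- function(read_sequence, index, min_frac = 0.5) {
  res <- .cpp_assign_reads(index$ptr, read_sequence, min_frac)[[1]]
  if (is.null(res)) NULL else index$ids[res]
}

#' Count equivalence classes for one sample
#'
#' Both mates of each pair are assigned independently (single-end semantics,
#' so short contigs are still counted) and counts are aggregated per
#' equivalence class. The library size is the number of assigned read ends,
#' recorded before any filtering.
#'
#' @param index An `ec_index`.
#' @param reads A `list(r1, r2)` of read vectors or a character vector of two
#'   FASTQ paths.
#' @param sample_id Sample name.
#' @param min_frac See [assign_read()].
#' @return An `ec_counts` tibble with list-column `members` (integer indexes
#'   into `index$ids`) and `count`; attributes `sample_id`, `n_assigned`,
#'   `n_unassigned` and `library_size`.
#' @export
count_ecs <- function(index, reads, sample_id, min_frac = 0.5) {
  reads <- load_read_pairs(reads)
  all_reads <- c(unname(reads$r1), unname(reads$r2))
  res <- .cpp_count_ecs(index$ptr, all_reads, min_frac)
  out <- tibble(members = res$members, count = as.numeric(res$count))
  structure(out, class = c("ec_counts", class(out)),
            sample_id = sample_id,
            n_assigned = res$n_assigned, n_unassigned = res$n_unassigned,
            library_size = res$n_assigned,
            index_ids = index$ids, index_is_contig = index$is_contig)
}

#' Match equivalence classes across samples
#'
#' ECs are matched by membership: an EC composed of the same sequence ids in
#' two samples is the same row of the resulting matrix, with zero counts
#' where a sample lacks it. Library sizes are carried over unmodified.
#'
#' @param tables List of `ec_counts` from [count_ecs()] (one per sample).
#' @param case_sample_id Which sample is the case.
#' @return An `ec_matrix`: list with `ec` (tibble: `ec_id`, `members`,
#'   `all_contig`), `counts` (EC x sample matrix), `lib_sizes`, `case`,
#'   `ids`, `is_contig`.
#' @export
match_ecs <- function(tables, case_sample_id) {
  sample_ids <- vapply(tables, attr, character(1), "sample_id")
  if (anyDuplicated(sample_ids)) abort("duplicate sample ids")
  if (!case_sample_id %in% sample_ids) abort("case sample not among tables")
  ids <- attr(tables[[1]], "index_ids")
  is_contig <- attr(tables[[1]], "index_is_contig")
  long <- purrr::map2_dfr(tables, sample_ids, function(tb, sid) {
    tibble(ec_id = vapply(tb$members, paste, character(1), collapse = ","),
           members = tb$members, count = tb$count, sample = sid)
  })
  wide <- long |>
    select("ec_id", "sample", "count") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "count",
                       values_fill = 0) |>
    arrange(.data$ec_id)
  members <- long[!duplicated(long$ec_id), c("ec_id", "members")]
  members <- members[match(wide$ec_id, members$ec_id), ]
  counts <- as.matrix(wide[, sample_ids, drop = FALSE])
  rownames(counts) <- wide$ec_id
  all_contig <- vapply(members$members, function(m) all(is_contig[m]), logical(1))
  structure(list(
    ec = tibble(ec_id = wide$ec_id, members = members$members,
                all_contig = all_contig),
    counts = counts,
    lib_sizes = setNames(vapply(tables, attr, numeric(1), "library_size"), sample_ids),
    case = case_sample_id,
    ids = ids, is_contig = is_contig
  ), class = "ec_matrix")
}

#' @export
print.ec_matrix <- function(x, ...) {
  cat(sprintf("<ec_matrix> %d ECs x %d samples (case: %s), %d novel\n",
              nrow(x$counts), ncol(x$counts), x$case, sum(x$ec$all_contig)))
  invisible(x)
}

#' Keep only novel equivalence classes
#'
#' Retains the rows whose every member is an assembled contig (no reference
#' transcript). Library sizes keep their pre-filter values so CPM stays
#' interpretable.
#'
#' @param matrix An `ec_matrix`.
#' @return The filtered `ec_matrix`.
#' @export
filter_novel_ecs <- function(matrix) {
  keep <- matrix$ec$all_contig
  matrix$ec <- matrix$ec[keep, ]
  matrix$counts <- matrix$counts[keep, , drop = FALSE]
  matrix
}

# member indexes -> sequence ids
ec_member_ids <- function(matrix, members) matrix$ids[members]

#' Write / read a matched EC matrix as TSV
#'
#' Column `members` holds comma-joined sequence ids; header comment lines
#' carry the library sizes and case sample so the matrix round-trips.
#'
#' @param matrix An `ec_matrix`.
#' @param path File path.
#' @return `path` (write) or an `ec_matrix` (read).
#' @export
write_ec_matrix <- function(matrix, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#lib_sizes\t", paste(sprintf("%s=%g", names(matrix$lib_sizes),
                                         matrix$lib_sizes), collapse = "\t")),
    paste0("#case\t", matrix$case)
  ), con)
  df <- data.frame(
    members = vapply(matrix$ec$members, function(m) paste(matrix$ids[m], collapse = ","),
                     character(1)),
    matrix$counts, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ec_matrix
#' @param is_contig Named logical vector flagging contig ids (taken from the
#'   index); ids absent from this catalog raise an error.
#' @export
read_ec_matrix <- function(path, is_contig) {
  hdr <- readLines(path, n = 2)
  libs_kv <- strsplit(sub("^#lib_sizes\t", "", hdr[1]), "\t")[[1]]
  lib_sizes <- vapply(strsplit(libs_kv, "="), function(p) as.numeric(p[2]), numeric(1))
  names(lib_sizes) <- vapply(strsplit(libs_kv, "="), `[[`, character(1), 1)
  case <- sub("^#case\t", "", hdr[2])
  df <- utils::read.delim(path, skip = 2, check.names = FALSE)
  ids <- names(is_contig)
  member_ids <- strsplit(df$members, ",", fixed = TRUE)
  unknown <- setdiff(unique(unlist(member_ids)), ids)
  if (length(unknown)) {
    abort(sprintf("EC member id(s) missing from catalog: %s",
                  paste(head(unknown, 3), collapse = ", ")))
  }
  members <- lapply(member_ids, function(m) sort(match(m, ids)))
  counts <- as.matrix(df[, names(lib_sizes), drop = FALSE])
  rownames(counts) <- vapply(members, paste, character(1), collapse = ",")
  structure(list(
    ec = tibble(ec_id = rownames(counts), members = members,
                all_contig = vapply(members, function(m) all(is_contig[m]), logical(1))),
    counts = counts, lib_sizes = lib_sizes, case = case,
    ids = ids, is_contig = is_contig
  ), class = "ec_matrix")
}
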