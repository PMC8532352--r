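# Case-vs-controls differential expression on novel ECs -------------------
#
# One case against N controls, tested per EC with a negative binomial GLM
# likelihood-ratio test at fixed dispersion (no estimation: a single case
# sample gives nothing to estimate from; the benchmark's own
# dispersion-sensitivity analysis shows results are stable for dispersion
# well above the 0.1 default). Model: log link with log(library size) offset;
# the alternative fits separate rates for the case (group of one) and the
# controls, the null one shared rate; the LRT statistic is referred to
# chi-square with 1 df.

#' Differential-expression parameters
#'
#' @param dispersion Fixed negative binomial dispersion (default 0.1).
#' @param cpm_min Case CPM must strictly exceed this to be tested
#'   (default 0.1).
#' @param fdr_max Significance requires FDR strictly below this
#'   (default 0.05).
#' @param logfc_min Significance requires logFC strictly above this
#'   (default 2; large cohort screens typically use 5).
#' @param prior_count Pseudo-count added to both groups when computing logFC
#'   (default 0.5).
#' @return List of class `de_params`.
#' @export
de_params <- function(dispersion = 0.1, cpm_min = 0.1, fdr_max = 0.05,
                      logfc_min = 2, prior_count = 0.5) {
  stopifnot(dispersion > 0, cpm_min > 0, fdr_max > 0, fdr_max <= 1,
            logfc_min > 0, prior_count > 0)
  structure(list(dispersion = dispersion, cpm_min = cpm_min, fdr_max = fdr_max,
                 logfc_min = logfc_min, prior_count = prior_count),
            class = "de_params")
}

#' Counts per million
#'
#' @param count Read (end) count.
#' @param library_size Assigned read ends in the sample (pre-filter).
#' @return `count * 1e6 / library_size`.
#' @export
ec_cpm <- function(count, library_size) {
  if (any(library_size <= 0)) abort("library_size must be positive")
  count * 1e6 / library_size
}

#' Drop ECs with low case expression
#'
#' Keeps rows whose case CPM strictly exceeds `cpm_min`; library sizes are
#' untouched.
#'
#' @param matrix An `ec_matrix`.
#' @param params A `de_params`.
#' @return The filtered `ec_matrix`.
#' @export
filter_low_expression <- function(matrix, params = de_params()) {
  case_cpm <- ec_cpm(matrix$counts[, matrix$case], matrix$lib_sizes[[matrix$case]])
  keep <- case_cpm > params$cpm_min
  matrix$ec <- matrix$ec[keep, ]
  matrix$counts <- matrix$counts[keep, , drop = FALSE]
  matrix
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment (via [stats::p.adjust()]).
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @return FDR values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    abort("p-values must be in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

# MLE of a shared NB rate (log link, library-size offsets) for each row of Y.
# Returns rates and per-row log-likelihoods. Closed form (total/total) when
# library sizes are equal; Newton iterations on the log-rate otherwise.
nb_group_fit <- function(Y, libs, phi) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  tot <- rowSums(Y)
  rate <- tot / sum(libs)
  nz <- tot > 0
  if (ncol(Y) > 1 && length(unique(libs)) > 1 && any(nz)) {
    beta <- log(rate[nz])
    Ln <- matrix(libs, nrow = sum(nz), ncol = ncol(Y), byrow = TRUE)
    Yn <- Y[nz, , drop = FALSE]
    for (it in 1:60) {
      mu <- exp(beta) * Ln
      score <- rowSums((Yn - mu) / (1 + phi * mu))
      info <- rowSums(mu / (1 + phi * mu))
      step <- score / pmax(info, 1e-12)
      beta <- beta + step
      if (max(abs(step)) < 1e-10) break
    }
    rate[nz] <- exp(beta)
  }
  mu <- outer(rate, libs)
  ll <- rowSums(dnbinom(Y, size = 1 / phi, mu = mu, log = TRUE))
  ll[!nz] <- 0  # all-zero rows: saturated at rate 0
  list(rate = rate, ll = ll)
}

# vectorised fixed-dispersion NB LRT; Y has samples in columns
nb_lrt_core <- function(Y, libs, case_index, params) {
  Y <- as.matrix(Y)
  phi <- params$dispersion
  y_case <- Y[, case_index]
  L_case <- libs[[case_index]]
  Yc <- Y[, -case_index, drop = FALSE]
  Lc <- libs[-case_index]
  alt_case <- nb_group_fit(cbind(y_case), L_case, phi)
  alt_ctrl <- nb_group_fit(Yc, Lc, phi)
  null <- nb_group_fit(Y, libs, phi)
  lrt <- pmax(0, 2 * (alt_case$ll + alt_ctrl$ll - null$ll))
  p <- pchisq(lrt, df = 1, lower.tail = FALSE)
  # prior count added per sample so equal per-sample rates give logFC 0
  logFC <- log2((y_case + params$prior_count) / L_case) -
    log2((rowSums(Yc) + params$prior_count * ncol(Yc)) / sum(Lc))
  allzero <- rowSums(Y) == 0
  lrt[allzero] <- 0
  p[allzero] <- 1
  logFC[allzero] <- 0
  tibble(logFC = logFC, lrt_stat = lrt, p_value = p)
}

#' Fixed-dispersion negative binomial likelihood-ratio test for one EC
#'
#' @param ec_counts Counts for one EC, one value per sample.
#' @param library_sizes Library sizes per sample.
#' @param case_index Which entry is the case sample.
#' @param params A `de_params`.
#' @return One-row tibble with `logFC`, `lrt_stat`, `p_value`.
#' @export
nb_lrt_test <- function(ec_counts, library_sizes, case_index,
                        params = de_params()) {
  if (any(!is.finite(ec_counts)) || any(!is.finite(library_sizes))) {
    abort("counts and library sizes must be finite")
  }
  if (any(ec_counts < 0)) abort("counts must be non-negative")
  if (length(ec_counts) < 2) abort("need at least one control sample")
  nb_lrt_core(matrix(ec_counts, nrow = 1), library_sizes, case_index, params)
}

#' Differential expression over a matched EC matrix
#'
#' Applies the case-CPM filter then the fixed-dispersion NB LRT to every
#' remaining EC; FDR by Benjamini-Hochberg. An EC is significant when
#' FDR < `fdr_max` and logFC > `logfc_min` (strict inequalities).
#'
#' @param matrix An `ec_matrix` (typically after [filter_novel_ecs()]).
#' @param params A `de_params`.
#' @return An object of class `tx_de` whose `results` tibble has one row per
#'   tested EC (`ec_id`, `members`, `case_count`, `case_cpm`, `logFC`,
#'   `lrt_stat`, `p_value`, `fdr`, `significant`).
#' @export
run_diffexp <- function(matrix, params = de_params()) {
  if (ncol(matrix$counts) < 2) {
    abort("differential expression needs at least one control; see select_significant_contigs(controls_present = FALSE)")
  }
  filtered <- filter_low_expression(matrix, params)
  case_index <- match(filtered$case, colnames(filtered$counts))
  if (nrow(filtered$counts) == 0) {
    res <- tibble(ec_id = character(), members = list(), case_count = numeric(),
                  case_cpm = numeric(), logFC = numeric(), lrt_stat = numeric(),
                  p_value = numeric(), fdr = numeric(), significant = logical())
  } else {
    stats <- nb_lrt_core(filtered$counts, filtered$lib_sizes, case_index, params)
    case_count <- filtered$counts[, case_index]
    res <- bind_cols(
      tibble(ec_id = filtered$ec$ec_id, members = filtered$ec$members,
             case_count = unname(case_count),
             case_cpm = unname(ec_cpm(case_count, filtered$lib_sizes[[case_index]]))),
      stats)
    res$fdr <- bh_adjust(res$p_value)
    res$significant <- res$fdr < params$fdr_max & res$logFC > params$logfc_min
  }
  structure(list(results = res, params = params, case = matrix$case,
                 lib_sizes = matrix$lib_sizes, ids = matrix$ids,
                 is_contig = matrix$is_contig,
                 n_input_ecs = nrow(matrix$counts)),
            class = "tx_de")
}

#' @export
print.tx_de <- function(x, ...) {
  cat(sprintf("<tx_de> %d ECs tested (of %d), %d significant (FDR<%g, logFC>%g)\n",
              nrow(x$results), x$n_input_ecs, sum(x$results$significant),
              x$params$fdr_max, x$params$logfc_min))
  invisible(x)
}

#' Contigs retained after differential expression
#'
#' Union of the contig members of significant ECs. Without controls no test
#' is run: novel ECs passing the case-CPM filter select their contigs
#' directly.
#'
#' @param de A `tx_de` (required when `controls_present`).
#' @param matrix The novel-EC `ec_matrix` the test ran on.
#' @param params A `de_params`.
#' @param controls_present Set `FALSE` for the no-control mode.
#' @return Sorted character vector of contig ids.
#' @export
select_significant_contigs <- function(de, matrix, params = de_params(),
                                       controls_present = TRUE) {
  if (controls_present) {
    members <- de$results$members[de$results$significant]
    ids <- de$ids
    is_contig <- de$is_contig
  } else {
    filtered <- filter_low_expression(matrix, params)
    members <- filtered$ec$members
    ids <- matrix$ids
    is_contig <- matrix$is_contig
  }
  m <- unique(unlist(members))
  sort(ids[m[is_contig[m]]])
}
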