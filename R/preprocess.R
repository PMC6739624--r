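#' Filter minimal-variance loci
#'
#' Removes loci whose beta values barely vary across samples — they carry
#' no information for tumour/normal discrimination and only inflate the
#' feature:sample ratio. The filter never looks at class labels. Variance
#' is the unbiased sample variance over non-missing entries; ties are
#' broken by lexicographic locus id so the retained set is deterministic.
#'
#' @param mat loci x samples beta matrix.
#' @param mode `"top_k"` keeps the `threshold` most variable loci;
#'   `"min_variance"` keeps loci with variance >= `threshold`.
#' @param threshold positive count (`top_k`) or nonnegative variance bound.
#' @return the matrix restricted to retained loci (sample axis untouched).
#' @export
variance_filter <- function(mat, mode = c("top_k", "min_variance"),
                            threshold) {
  mode <- match.arg(mode)
  validate_beta_matrix(mat)
  if (nrow(mat) == 0L) stop_("matrix has no loci")
  v <- apply(mat, 1L, stats::var, na.rm = TRUE)
  v[is.na(v)] <- 0
  if (mode == "top_k") {
    k <- check_count(threshold, "threshold", min = 1L)
    if (k > nrow(mat))
      stop_("top_k threshold (%d) exceeds locus count (%d)", k, nrow(mat))
    ord <- order(-v, rownames(mat))
    keep <- sort(ord[seq_len(k)])
  } else {
    threshold <- check_number(threshold, "threshold", min = 0)
    keep <- which(v >= threshold)
  }
  mat[keep, , drop = FALSE]
}

#' Drop high-missingness loci and impute the remainder
#'
#' Loci with more than `max_missing` missing entries are removed; remaining
#' missing beta values are imputed with the per-locus median across all
#' samples (class-agnostic, so imputation cannot leak label information
#' into the selectors, which require complete matrices).
#'
#' @param mat loci x samples beta matrix.
#' @param max_missing maximum tolerated missing fraction per locus.
#' @return complete beta matrix.
#' @export
impute_missing <- function(mat, max_missing = 0.2) {
  validate_beta_matrix(mat)
  max_missing <- check_number(max_missing, "max_missing", 0, 1)
  frac <- rowMeans(is.na(mat))
  mat <- mat[frac <= max_missing, , drop = FALSE]
  na_rows <- which(rowSums(is.na(mat)) > 0)
  for (i in na_rows) {
    med <- stats::median(mat[i, ], na.rm = TRUE)
    mat[i, is.na(mat[i, ])] <- med
  }
  mat
}

#' Flag loci overlapping known polymorphisms
#'
#' SNP-overlapping probes are marked, not removed: the appropriate
#' stringency depends on the downstream analysis, so flags travel with the
#' results (all the way into BED output) and users decide.
#'
#' @param annotation locus annotation data.frame.
#' @param snp_loci character vector of locus ids to flag.
#' @return the annotation with `snp_flag` set for the listed loci.
#' @export
flag_snp_loci <- function(annotation, snp_loci) {
  annotation <- validate_annotation(annotation)
  annotation$snp_flag <- annotation$snp_flag |
    annotation$locus_id %in% as.character(snp_loci)
  annotation
}

#' Read a SNP locus list (one locus id per line)
#' @param path plain-text file.
#' @return character vector of locus ids.
#' @export
read_snp_list <- function(path) {
  x <- readLines(path)
  x[nzchar(trimws(x))]
}

#' Preprocess a beta matrix for ensemble selection
#'
#' Applies, in order: an optional normalization hook (identity by default —
#' probe-type normalization and batch correction are expected to have been
#' done upstream by dedicated tools), missingness filtering with median
#' imputation, and minimal-variance filtering.
#'
#' @param mat loci x samples beta matrix.
#' @param max_missing per-locus missing fraction above which a locus is
#'   dropped.
#' @param variance_mode,variance_threshold passed to [variance_filter()];
#'   `variance_threshold = NULL` skips the variance filter.
#' @param normalize_hook optional `function(mat) -> mat` applied first.
#' @return complete, filtered beta matrix.
#' @export
preprocess_beta <- function(mat, max_missing = 0.2,
                            variance_mode = "top_k",
                            variance_threshold = NULL,
                            normalize_hook = NULL) {
  if (!is.null(normalize_hook)) {
    mat <- normalize_hook(mat)
    validate_beta_matrix(mat)
  }
  mat <- impute_missing(mat, max_missing = max_missing)
  if (!is.null(variance_threshold))
    mat <- variance_filter(mat, mode = variance_mode,
                           threshold = variance_threshold)
  mat
}
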