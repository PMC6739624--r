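#' Validate a beta-value methylation matrix
#'
#' A methylation matrix is an ordinary numeric matrix with loci as rows and
#' samples as columns, row names holding locus identifiers (e.g. `cg...`
#' probe ids) and column names holding sample identifiers. Every non-missing
#' entry must be a beta value in \[0, 1\].
#'
#' @param mat numeric matrix, loci x samples, dimnames set.
#' @return `mat`, invisibly, after validation.
#' @export
validate_beta_matrix <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop_("methylation matrix must be a numeric matrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop_("methylation matrix must carry locus row names and sample column names")
  if (anyDuplicated(rownames(mat)))
    stop_("duplicate locus identifiers: %s",
          paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "))
  if (anyDuplicated(colnames(mat)))
    stop_("duplicate sample identifiers: %s",
          paste(unique(colnames(mat)[duplicated(colnames(mat))]), collapse = ", "))
  bad <- which(!is.na(mat) & (mat < 0 | mat > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1L, ]
    stop_("beta value out of [0,1] at locus '%s', sample '%s': %g",
          rownames(mat)[i[1L]], colnames(mat)[i[2L]], mat[i[1L], i[2L]])
  }
  invisible(mat)
}

#' Read a beta-value matrix from delimited text
#'
#' @param path file with an identifier header row and identifier first
#'   column; `NA` marks missing values.
#' @param orientation `"loci"` if rows are loci (the default on disk
#'   layout), `"samples"` if rows are samples; the returned matrix always
#'   has loci as rows.
#' @param sep field delimiter, tab by default.
#' @return validated numeric matrix (loci x samples).
#' @export
read_beta_matrix <- function(path, orientation = c("loci", "samples"),
                             sep = "\t") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop_("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "")
  mat <- matrix(NA_real_, nrow(df), ncol(df),
                dimnames = list(rownames(df), colnames(df)))
  for (j in seq_len(ncol(df))) {
    v <- df[[j]]
    miss <- is.na(v) | v == "NA" | v == ""
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!miss & is.na(num))
    if (length(bad) > 0)
      stop_("malformed numeric field at row '%s', column '%s': '%s'",
            rownames(df)[bad[1L]], colnames(df)[j], v[bad[1L]])
    mat[, j] <- num
  }
  if (orientation == "samples") mat <- t(mat)
  validate_beta_matrix(mat)
  mat
}

#' Write a beta-value matrix as delimited text
#'
#' @param mat loci x samples matrix.
#' @param path output file.
#' @param sep field delimiter.
#' @param digits significant digits retained in the text representation.
#' @export
write_beta_matrix <- function(mat, path, sep = "\t", digits = 10) {
  validate_beta_matrix(mat)
  df <- data.frame(locus_id = rownames(mat),
                   signif(mat, digits), check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read binary sample labels
#'
#' Expects a two-column table `sample_id`, `label` with labels 0 (normal)
#' and 1 (tumour).
#'
#' @param path label file.
#' @param sep field delimiter.
#' @return named integer vector of 0/1 labels.
#' @export
read_labels <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, comment.char = "")
  if (!all(c("sample_id", "label") %in% names(df)))
    stop_("label file must have columns 'sample_id' and 'label'")
  validate_labels(stats::setNames(as.integer(df$label),
                                  as.character(df$sample_id)))
}

validate_labels <- function(labels, mat = NULL) {
  if (!all(labels %in% c(0L, 1L)))
    stop_("labels must be 0 (normal) or 1 (tumour)")
  if (anyDuplicated(names(labels)))
    stop_("duplicate sample identifiers in labels")
  if (!is.null(mat)) {
    if (!identical(names(labels), colnames(mat)))
      stop_("labels must match the matrix sample ids in the same order")
  }
  labels
}

#' Write sample labels
#' @param labels named 0/1 integer vector.
#' @param path output file.
#' @param sep field delimiter.
#' @export
write_labels <- function(labels, path, sep = "\t") {
  utils::write.table(
    data.frame(sample_id = names(labels), label = as.integer(labels)),
    path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a locus annotation table
#'
#' Columns: `locus_id`, `chrom`, `pos` (1-based), `strand` (`+`, `-` or
#' `*` for unknown), `cpg_island` (0/1), `snp_flag` (0/1), optional
#' `gene_id`.
#'
#' @param path annotation file.
#' @param sep field delimiter.
#' @return data.frame with one row per locus.
#' @export
read_annotation <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, comment.char = "")
  validate_annotation(df)
}

validate_annotation <- function(df) {
  need <- c("locus_id", "chrom", "pos", "strand", "cpg_island", "snp_flag")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop_("annotation missing columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$locus_id))
    stop_("duplicate locus_id in annotation")
  if (any(df$pos < 1)) stop_("annotation positions must be >= 1")
  if (!all(df$strand %in% c("+", "-", "*")))
    stop_("annotation strand must be '+', '-' or '*'")
  df$locus_id <- as.character(df$locus_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$cpg_island <- as.logical(as.integer(df$cpg_island))
  df$snp_flag <- as.logical(as.integer(df$snp_flag))
  if (is.null(df$gene_id)) df$gene_id <- NA_character_
  df
}

#' Read a gene-model table
#'
#' Columns: `gene_id`, `chrom`, `strand` (`+`/`-`), `tss`, `start`, `end`
#' (1-based inclusive, `start <= end`, `tss` within the span).
#'
#' @param path gene model file.
#' @param sep field delimiter.
#' @return data.frame of gene models.
#' @export
read_gene_models <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, comment.char = "")
  validate_gene_models(df)
}

validate_gene_models <- function(df) {
  need <- c("gene_id", "chrom", "strand", "tss", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop_("gene model missing columns: %s", paste(miss, collapse = ", "))
  if (any(df$start > df$end)) stop_("gene model with start > end")
  if (any(df$tss < df$start | df$tss > df$end))
    stop_("gene model with TSS outside [start, end]")
  df$gene_id <- as.character(df$gene_id)
  df$chrom <- as.character(df$chrom)
  df$strand <- as.character(df$strand)
  df
}

#' Construct a DML set
#'
#' A DML set is a named collection of locus identifiers, optionally with an
#' occurrence count (across iterations or cancers) and a selection weight
#' per locus.
#'
#' @param loci character vector of locus ids (de-duplicated, order kept).
#' @param name label for the set (e.g. a cancer type).
#' @param counts optional nonnegative integer vector, one per locus.
#' @param weights optional nonnegative numeric vector, one per locus.
#' @return object of class `dml_set`.
#' @export
dml_set <- function(loci, name = "dml", counts = NULL, weights = NULL) {
  loci <- as.character(loci)
  if (anyDuplicated(loci)) {
    keep <- !duplicated(loci)
    loci <- loci[keep]
    if (!is.null(counts)) counts <- counts[keep]
    if (!is.null(weights)) weights <- weights[keep]
  }
  for (v in list(counts, weights)) {
    if (!is.null(v)) {
      if (length(v) != length(loci))
        stop_("counts/weights must be keyed exactly by the loci")
      if (any(v < 0)) stop_("counts/weights must be nonnegative")
    }
  }
  structure(list(name = name, loci = loci,
                 counts = if (!is.null(counts))
                   stats::setNames(as.integer(counts), loci),
                 weights = if (!is.null(weights))
                   stats::setNames(as.numeric(weights), loci)),
            class = "dml_set")
}

#' @export
print.dml_set <- function(x, ...) {
  cat(sprintf("DML set '%s': %d loci\n", x$name, length(x$loci)))
  if (length(x$loci) > 0) {
    show <- utils::head(x$loci, 5L)
    cat("  ", paste(show, collapse = ", "),
        if (length(x$loci) > 5L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.dml_set <- function(x) length(x$loci)

#' Write a DML set as a three-column TSV
#' @param dml a `dml_set`.
#' @param path output file.
#' @param sep field delimiter.
#' @export
write_dml_set <- function(dml, path, sep = "\t") {
  n <- length(dml$loci)
  df <- data.frame(
    locus_id = dml$loci,
    count = if (is.null(dml$counts)) rep(NA_integer_, n) else
      unname(dml$counts),
    weight = if (is.null(dml$weights)) rep(NA_real_, n) else
      signif(unname(dml$weights), 10))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a DML set written by [write_dml_set()]
#' @param path input file.
#' @param name name for the set; defaults to the file base name.
#' @param sep field delimiter.
#' @return a `dml_set`.
#' @export
read_dml_set <- function(path, name = NULL, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, comment.char = "")
  if (!"locus_id" %in% names(df))
    stop_("DML set file must have a 'locus_id' column")
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  counts <- if ("count" %in% names(df) && !all(is.na(df$count))) df$count
  weights <- if ("weight" %in% names(df) && !all(is.na(df$weight))) df$weight
  dml_set(as.character(df$locus_id), name = name,
          counts = counts, weights = weights)
}

#' Export a DML set to BED
#'
#' Writes BED6 plus a trailing `snp` column: `chrom`, 0-based start,
#' half-open end (start + 1 for single-CpG loci), locus id, an integer
#' score in 0-1000 scaled from the set's weights (or counts when no
#' weights are present), strand, and `SNP` for loci flagged as overlapping
#' a polymorphism (kept, never dropped — downstream stringency is the
#' user's call).
#'
#' @param dml a `dml_set`.
#' @param annotation locus annotation data.frame (see [read_annotation()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dml_bed <- function(dml, annotation, path) {
  annotation <- validate_annotation(annotation)
  idx <- match(dml$loci, annotation$locus_id)
  if (anyNA(idx))
    stop_("loci missing from annotation: %s",
          paste(dml$loci[is.na(idx)], collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track name=%s", dml$name), con)
  if (length(dml$loci) == 0L) return(invisible(path))
  ann <- annotation[idx, ]
  sc <- dml$weights %||% dml$counts
  score <- if (is.null(sc)) rep(0L, length(dml$loci)) else {
    m <- max(sc)
    if (m > 0) as.integer(round(1000 * sc / m)) else rep(0L, length(sc))
  }
  strand <- ifelse(ann$strand == "*", ".", ann$strand)
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%s",
                     ann$chrom, ann$pos - 1L, ann$pos, dml$loci, score,
                     strand, ifelse(ann$snp_flag, "SNP", ".")), con)
  invisible(path)
}
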