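#' Pan-cancer consensus loci
#'
#' A locus is a pan-cancer DML (pDML) when it occurs in at least
#' `min_cancers` of the per-cancer DML sets ("no less than" — the bound
#' is inclusive).
#'
#' @param dml_sets named list of [dml_set()]s or character vectors, one
#'   per cancer.
#' @param min_cancers minimum number of sets a locus must appear in.
#' @return a [dml_set()] with per-locus occurrence counts.
#' @export
pdml_select <- function(dml_sets, min_cancers) {
  min_cancers <- check_count(min_cancers, "min_cancers", min = 1L)
  if (min_cancers > length(dml_sets))
    stop_("min_cancers (%d) exceeds the number of sets (%d)",
          min_cancers, length(dml_sets))
  sets <- lapply(dml_sets, function(s)
    if (inherits(s, "dml_set")) s$loci else unique(as.character(s)))
  tab <- table(unlist(sets, use.names = FALSE))
  keep <- sort(names(tab)[tab >= min_cancers])
  dml_set(keep, name = "pdml", counts = as.integer(tab[keep]))
}

#' Methylation direction of loci
#'
#' Calls a locus hypermethylated when the tumour median beta exceeds the
#' normal median by more than `delta`, hypomethylated when it is lower by
#' more than `delta`, and `none` otherwise.
#'
#' @param mat loci x samples beta matrix.
#' @param labels 0/1 vector aligned with the columns.
#' @param loci locus ids to call (default: all rows).
#' @param delta nonnegative median-difference margin.
#' @return named character vector with values `"hyper"`, `"hypo"`,
#'   `"none"`.
#' @export
direction_call <- function(mat, labels, loci = rownames(mat), delta = 0) {
  labels <- as.integer(labels)
  check_two_classes(labels)
  delta <- check_number(delta, "delta", min = 0)
  loci <- as.character(loci)
  missing <- setdiff(loci, rownames(mat))
  if (length(missing) > 0)
    stop_("loci absent from matrix: %s",
          paste(utils::head(missing, 5L), collapse = ", "))
  sub <- mat[loci, , drop = FALSE]
  med_t <- apply(sub[, labels == 1L, drop = FALSE], 1L, stats::median,
                 na.rm = TRUE)
  med_n <- apply(sub[, labels == 0L, drop = FALSE], 1L, stats::median,
                 na.rm = TRUE)
  d <- med_t - med_n
  stats::setNames(ifelse(d > delta, "hyper",
                         ifelse(d < -delta, "hypo", "none")), loci)
}

#' Genomic-region category of loci
#'
#' Assigns each locus exactly one of `promoter`, `gene_body`,
#' `intergenic`. The promoter is the strand-aware window from 2,000 bp
#' upstream of a gene's TSS to the TSS (inclusive at both ends) and takes
#' precedence over the gene body; the gene body is any position inside a
#' gene span outside all promoter windows; everything else is intergenic.
#' Genes with unknown strand are treated as `+` with a warning.
#'
#' @param annotation locus annotation data.frame (needs `locus_id`,
#'   `chrom`, `pos`).
#' @param genes gene-model data.frame (see [read_gene_models()]).
#' @param promoter_width upstream window width in bp.
#' @return named character vector of region categories per locus.
#' @export
annotate_region <- function(annotation, genes, promoter_width = 2000) {
  annotation <- validate_annotation(annotation)
  genes <- validate_gene_models(genes)
  bad <- !genes$strand %in% c("+", "-")
  if (any(bad)) {
    warning(sprintf("%d gene(s) with unknown strand treated as '+'",
                    sum(bad)), call. = FALSE)
    genes$strand[bad] <- "+"
  }
  prom_start <- ifelse(genes$strand == "+", genes$tss - promoter_width,
                       genes$tss)
  prom_end <- ifelse(genes$strand == "+", genes$tss,
                     genes$tss + promoter_width)
  out <- rep("intergenic", nrow(annotation))
  names(out) <- annotation$locus_id
  for (ch in unique(annotation$chrom)) {
    li <- which(annotation$chrom == ch)
    gi <- which(genes$chrom == ch)
    if (length(gi) == 0L) next
    pos <- annotation$pos[li]
    in_prom <- vapply(pos, function(p)
      any(p >= prom_start[gi] & p <= prom_end[gi]), logical(1L))
    in_body <- vapply(pos, function(p)
      any(p >= genes$start[gi] & p <= genes$end[gi]), logical(1L))
    out[li] <- ifelse(in_prom, "promoter",
                      ifelse(in_body, "gene_body", "intergenic"))
  }
  out
}

#' Per-chromosome DML density
#'
#' For every chromosome present in the background annotation, the ratio
#' of the number of DML to the number of array CpG loci on that
#' chromosome. A chromosome with zero background loci would be undefined
#' and is reported as `NA`, never as 0.
#'
#' @param dml a [dml_set()] or character vector of locus ids.
#' @param background locus annotation data.frame covering (at least) all
#'   DML loci.
#' @return data.frame with `chrom`, `n_dml`, `n_background`, `density`.
#' @export
chromosome_density <- function(dml, background) {
  background <- validate_annotation(background)
  loci <- if (inherits(dml, "dml_set")) dml$loci else
    unique(as.character(dml))
  missing <- setdiff(loci, background$locus_id)
  if (length(missing) > 0)
    stop_("DML loci absent from background: %s",
          paste(utils::head(missing, 5L), collapse = ", "))
  chroms <- unique(background$chrom)
  n_bg <- vapply(chroms, function(ch)
    sum(background$chrom == ch), integer(1L))
  is_dml <- background$locus_id %in% loci
  n_dml <- vapply(chroms, function(ch)
    sum(is_dml & background$chrom == ch), integer(1L))
  data.frame(chrom = chroms, n_dml = n_dml, n_background = n_bg,
             density = ifelse(n_bg > 0, n_dml / n_bg, NA_real_),
             row.names = NULL)
}

#' Cross-cancer similarity clustering of DML sets
#'
#' Computes the pairwise Jaccard similarity matrix between the per-cancer
#' DML sets and clusters the cancers by average-linkage agglomeration on
#' distance `1 - Jaccard`. Sets are ordered lexicographically by name
#' first so merge order is deterministic under ties.
#'
#' @param dml_sets named list (>= 2) of [dml_set()]s or character
#'   vectors.
#' @return list of class `cancer_cluster`: `similarity` matrix, `hclust`
#'   tree, and a `newick` serialization.
#' @export
cancer_similarity_cluster <- function(dml_sets) {
  if (length(dml_sets) < 2L) stop_("need at least 2 sets")
  nm <- names(dml_sets)
  if (is.null(nm) || any(!nzchar(nm))) stop_("sets must be named")
  dml_sets <- dml_sets[order(nm)]
  sets <- lapply(dml_sets, function(s)
    if (inherits(s, "dml_set")) s$loci else unique(as.character(s)))
  k <- length(sets)
  m <- diag(1, k)
  dimnames(m) <- list(names(sets), names(sets))
  for (i in seq_len(k - 1L))
    for (j in (i + 1L):k)
      m[i, j] <- m[j, i] <- jaccard(sets[[i]], sets[[j]])
  hc <- stats::hclust(stats::as.dist(1 - m), method = "average")
  newick <- ape::write.tree(ape::as.phylo(hc))
  structure(list(similarity = m, hclust = hc, newick = newick),
            class = "cancer_cluster")
}

#' @export
print.cancer_cluster <- function(x, ...) {
  cat(sprintf("Cross-cancer clustering of %d DML sets (average linkage, 1 - Jaccard)\n",
              nrow(x$similarity)))
  cat(x$newick, "\n")
  invisible(x)
}

#' Combined pan-cancer analysis
#'
#' Applies the pDML rule, calls hyper/hypo direction per (locus, cancer)
#' where cohort matrices are supplied, and clusters the cancers by DML
#' similarity.
#'
#' @param dml_sets named list of per-cancer [dml_set()]s.
#' @param min_cancers pDML occurrence bound.
#' @param cohorts optional named list (same names) of
#'   `list(mat = , labels = )` cohorts for direction calls.
#' @param delta margin for [direction_call()].
#' @return list of class `pancancer_result`: `pdml`, `direction`
#'   (loci x cancers character matrix or `NULL`), `cluster`.
#' @export
pancancer_analysis <- function(dml_sets, min_cancers = 10,
                               cohorts = NULL, delta = 0) {
  pdml <- pdml_select(dml_sets, min_cancers)
  direction <- NULL
  if (!is.null(cohorts) && length(pdml) > 0) {
    direction <- matrix(NA_character_, length(pdml), length(dml_sets),
                        dimnames = list(pdml$loci, names(dml_sets)))
    for (cn in names(dml_sets)) {
      set_loci <- if (inherits(dml_sets[[cn]], "dml_set"))
        dml_sets[[cn]]$loci else dml_sets[[cn]]
      co <- cohorts[[cn]]
      # direction is defined only for loci in that cancer's own DML set
      loci <- intersect(pdml$loci, intersect(set_loci, rownames(co$mat)))
      if (length(loci) > 0)
        direction[loci, cn] <- direction_call(co$mat, co$labels, loci,
                                              delta = delta)
    }
  }
  structure(list(pdml = pdml, direction = direction,
                 cluster = cancer_similarity_cluster(dml_sets)),
            class = "pancancer_result")
}

#' @export
print.pancancer_result <- function(x, ...) {
  cat(sprintf("pDML: %d loci\n", length(x$pdml)))
  if (!is.null(x$direction)) {
    hyper <- sum(x$direction == "hyper", na.rm = TRUE)
    hypo <- sum(x$direction == "hypo", na.rm = TRUE)
    cat(sprintf("direction calls: %d hyper, %d hypo\n", hyper, hypo))
  }
  print(x$cluster)
  invisible(x)
}
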