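# Fixtures built in code: tiny matrices, annotations and gene models used
# across the test files.

# deterministic little beta matrix with named axes
toy_matrix <- function(n_loci = 6, n_samples = 8, seed = 1) {
  hydml:::with_seed(seed, {
    m <- matrix(runif(n_loci * n_samples), n_loci, n_samples,
                dimnames = list(sprintf("cg%08d", seq_len(n_loci)),
                                sprintf("S%02d", seq_len(n_samples))))
    m
  })
}

# balanced labels: first half 0, second half 1
split_labels <- function(n) {
  stats::setNames(rep(c(0L, 1L), each = n %/% 2), sprintf("S%02d", seq_len(n)))
}

toy_annotation <- function(locus_ids,
                           chrom = rep("chr1", length(locus_ids)),
                           pos = seq(100L, by = 100L,
                                     length.out = length(locus_ids)),
                           strand = rep("+", length(locus_ids)),
                           snp = rep(FALSE, length(locus_ids))) {
  data.frame(locus_id = locus_ids, chrom = chrom, pos = pos,
             strand = strand, cpg_island = FALSE, snp_flag = snp,
             gene_id = NA_character_)
}

toy_genes <- function(gene_id = "g1", chrom = "chr1", strand = "+",
                      tss = 10000L, start = 10000L, end = 20000L) {
  data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
             tss = tss, start = start, end = end)
}

# a cohort in which `n_signal` loci separate the classes perfectly and the
# rest are uniform noise
separable_cohort <- function(n_loci = 20, n_per_class = 10, n_signal = 2,
                             seed = 1) {
  hydml:::with_seed(seed, {
    n <- 2L * n_per_class
    mat <- matrix(runif(n_loci * n, 0.2, 0.8), n_loci, n,
                  dimnames = list(sprintf("cg%08d", seq_len(n_loci)),
                                  sprintf("S%02d", seq_len(n))))
    labels <- stats::setNames(rep(c(0L, 1L), each = n_per_class),
                              colnames(mat))
    for (i in seq_len(n_signal)) {
      mat[i, labels == 0L] <- runif(n_per_class, 0.05, 0.15)
      mat[i, labels == 1L] <- runif(n_per_class, 0.85, 0.95)
    }
    list(mat = mat, labels = labels,
         signal = rownames(mat)[seq_len(n_signal)])
  })
}
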