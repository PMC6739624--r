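# Reproducible pipeline runs: flat YAML configuration, artifact writing,
# and the functions behind the command-line entry points (inst/cli).

config_schema <- function() {
  list(
    schema_version = 1L,
    seed = 1L,
    n_folds = 10L, n_iterations = 10L, tau = 0.01, bag_min = 5L,
    selectors = c("elastic_net", "info_gain", "mc_subspace"),
    alpha = 0.5, lambda = "auto", en_family = "gaussian",
    n_bins = 10L, ig_sig = 0.05, ig_adjust = "bonferroni",
    s_mc = 300L, m_mc = NULL, t_mc = 1L, mc_depth = 2L,
    mc_min_node = 5L, mc_null_quantile = 0.999,
    svm_cost = 1, svm_class_weights = FALSE,
    max_missing = 0.2, variance_mode = "top_k",
    variance_threshold = NULL,
    keep_snp = TRUE)
}

#' Default pipeline configuration
#'
#' All tunables of a pipeline run as a flat key-value list; defaults
#' follow the method's stated constants (10 folds, 10 iterations,
#' weight threshold 0.01, bagging minimum 5).
#'
#' @param ... overrides of schema keys (unknown keys are rejected).
#' @return named list of class `hydml_config`.
#' @export
default_config <- function(...) {
  cfg <- config_schema()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop_("unknown configuration key(s): %s",
          paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "hydml_config"
  cfg
}

#' Read a pipeline configuration file
#'
#' Flat YAML with the keys of [default_config()]; unknown keys are an
#' error (they usually mean a typo that would otherwise silently fall
#' back to a default).
#'
#' @param path YAML file.
#' @return validated `hydml_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(default_config, raw)
}

#' Write a pipeline configuration file
#' @param config a `hydml_config`.
#' @param path output YAML file.
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(config)
  cfg <- cfg[!vapply(cfg, is.null, logical(1L))]
  yaml::write_yaml(cfg, path)
  invisible(path)
}

config_to_control <- function(cfg) {
  hydml_control(
    n_folds = cfg$n_folds, n_iterations = cfg$n_iterations,
    tau = cfg$tau, bag_min = cfg$bag_min, selectors = cfg$selectors,
    seed = cfg$seed,
    selector = selector_control(
      alpha = cfg$alpha, lambda = cfg$lambda, en_family = cfg$en_family,
      n_bins = cfg$n_bins, ig_sig = cfg$ig_sig,
      ig_adjust = cfg$ig_adjust, s_mc = cfg$s_mc, m_mc = cfg$m_mc,
      t_mc = cfg$t_mc, mc_depth = cfg$mc_depth,
      mc_min_node = cfg$mc_min_node,
      mc_null_quantile = cfg$mc_null_quantile, svm_cost = cfg$svm_cost,
      svm_class_weights = cfg$svm_class_weights, seed = cfg$seed))
}

log_line <- function(con, fmt, ...) {
  msg <- sprintf(fmt, ...)
  writeLines(sprintf("[%s] %s",
                     format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg), con)
}

#' Run the full DML identification pipeline on files
#'
#' Reads a beta matrix and labels, preprocesses (missingness +
#' variance filter per the configuration), runs [hydml()], and writes
#' all artifacts to `out_dir`: `final_dml.tsv`, per-iteration
#' `iteration_NN.tsv`, `fold_accuracy.tsv`, a `manifest.yaml`
#' reproducibility record (configuration, seed, package version) and a
#' structured `run.log`. With an annotation, also `final_dml.bed` (SNP
#' flags marked, and optionally dropped from the TSV/BED when
#' `keep_snp` is `FALSE`).
#'
#' @param matrix_path,labels_path input TSVs (see [read_beta_matrix()],
#'   [read_labels()]).
#' @param out_dir output directory (created if needed).
#' @param config a `hydml_config` (see [default_config()]).
#' @param snp_path optional SNP locus list (one id per line).
#' @param annotation_path optional locus annotation TSV.
#' @return the `hydml` fit, invisibly.
#' @export
run_dml_pipeline <- function(matrix_path, labels_path, out_dir,
                             config = default_config(),
                             snp_path = NULL, annotation_path = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(out_dir, "run.log"), "w")
  on.exit(close(logcon))
  mat <- read_beta_matrix(matrix_path)
  labels <- read_labels(labels_path)
  if (!setequal(names(labels), colnames(mat)))
    stop_("label sample ids do not match the matrix columns")
  labels <- labels[colnames(mat)]
  log_line(logcon, "input: %d loci x %d samples, seed %d", nrow(mat),
           ncol(mat), config$seed)
  mat <- preprocess_beta(mat, max_missing = config$max_missing,
                         variance_mode = config$variance_mode,
                         variance_threshold = config$variance_threshold)
  log_line(logcon, "preprocessed: %d loci retained", nrow(mat))
  annotation <- NULL
  if (!is.null(annotation_path)) {
    annotation <- read_annotation(annotation_path)
    if (!is.null(snp_path))
      annotation <- flag_snp_loci(annotation, read_snp_list(snp_path))
  }
  control <- config_to_control(config)
  fit <- hydml(mat, labels, control = control)
  for (row in seq_len(nrow(fit$accuracy)))
    log_line(logcon, "iteration %d fold %d selector %s acc %.4f (%d loci)",
             fit$accuracy$iteration[row], fit$accuracy$fold[row],
             fit$accuracy$selector[row], fit$accuracy$accuracy[row],
             fit$accuracy$n_loci[row])
  final <- fit$dml
  if (!is.null(annotation) && !config$keep_snp) {
    snp_ids <- annotation$locus_id[annotation$snp_flag]
    keep <- !final$loci %in% snp_ids
    final <- dml_set(final$loci[keep], name = final$name,
                     counts = final$counts[keep],
                     weights = final$weights[keep])
    log_line(logcon, "dropped %d SNP-flagged loci", sum(!keep))
  }
  write_dml_set(final, file.path(out_dir, "final_dml.tsv"))
  for (t in seq_along(fit$iterations))
    write_dml_set(fit$iterations[[t]],
                  file.path(out_dir, sprintf("iteration_%02d.tsv", t)))
  utils::write.table(fit$accuracy,
                     file.path(out_dir, "fold_accuracy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotation)) {
    idx <- match(final$loci, annotation$locus_id)
    if (!anyNA(idx))
      write_dml_bed(final, annotation,
                    file.path(out_dir, "final_dml.bed"))
  }
  manifest <- unclass(config)
  manifest <- manifest[!vapply(manifest, is.null, logical(1L))]
  manifest$package_version <-
    as.character(utils::packageVersion("hydml"))
  manifest$n_loci_input <- nrow(mat)
  manifest$n_final_dml <- length(final)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  log_line(logcon, "final DML set: %d loci", length(final))
  invisible(fit)
}

#' Write a simulated cohort to files
#'
#' @param out_dir output directory; writes `beta.tsv`, `labels.tsv`,
#'   `truth.tsv`.
#' @param ... passed to [simulate_cohort()].
#' @return the cohort, invisibly.
#' @export
write_simulated_cohort <- function(out_dir, ...) {
  co <- simulate_cohort(...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_beta_matrix(co$mat, file.path(out_dir, "beta.tsv"))
  write_labels(co$labels, file.path(out_dir, "labels.tsv"))
  write_truth(co$truth, file.path(out_dir, "truth.tsv"))
  invisible(co)
}

#' Pan-cancer consensus on DML set files
#'
#' @param dml_paths paths of per-cancer DML set TSVs (named by file).
#' @param min_cancers pDML occurrence bound.
#' @param out_dir output directory; writes `pdml.tsv`,
#'   `similarity.tsv`, `cancer_tree.nwk`.
#' @return the [pancancer_analysis()] result, invisibly.
#' @export
run_pancancer <- function(dml_paths, min_cancers, out_dir) {
  sets <- lapply(dml_paths, read_dml_set)
  names(sets) <- vapply(sets, `[[`, character(1L), "name")
  res <- pancancer_analysis(sets, min_cancers = min_cancers)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_dml_set(res$pdml, file.path(out_dir, "pdml.tsv"))
  utils::write.table(
    data.frame(cancer = rownames(res$cluster$similarity),
               res$cluster$similarity, check.names = FALSE),
    file.path(out_dir, "similarity.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  writeLines(res$cluster$newick, file.path(out_dir, "cancer_tree.nwk"))
  invisible(res)
}

#' Evaluate a DML set on a test cohort
#'
#' Mirrors the independent-test-set protocol: an SVM is trained on the
#' training cohort restricted to the DML set and verified on the test
#' cohort; the full metric table (TPR, FPR, ACC, AUC, Precision,
#' Recall, F1) is written as TSV.
#'
#' @param dml_path DML set TSV.
#' @param train_matrix_path,train_labels_path training cohort files.
#' @param test_matrix_path,test_labels_path test cohort files.
#' @param out_path output metrics TSV.
#' @return the metrics, invisibly.
#' @export
run_evaluate <- function(dml_path, train_matrix_path, train_labels_path,
                         test_matrix_path, test_labels_path, out_path) {
  dml <- read_dml_set(dml_path)
  tr <- read_beta_matrix(train_matrix_path)
  ltr <- read_labels(train_labels_path)[colnames(tr)]
  te <- read_beta_matrix(test_matrix_path)
  lte <- read_labels(test_labels_path)[colnames(te)]
  m <- evaluate_signature(impute_missing(tr, 1), ltr,
                          impute_missing(te, 1), lte, dml$loci)
  df <- data.frame(set = dml$name, tpr = m$tpr, fpr = m$fpr,
                   acc = m$acc, auc = m$auc, precision = m$precision,
                   recall = m$recall, f1 = m$f1)
  utils::write.table(df, out_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(m)
}

#' Run the stability experiment on files
#'
#' @param matrix_path,labels_path cohort files.
#' @param methods,sizes,n_subsamples,seed see [stability_experiment()].
#' @param config a `hydml_config`.
#' @param out_path output tidy TSV (`method`, `signature_size`,
#'   `replicate`, `metric`, `value`).
#' @return the tidy data.frame, invisibly.
#' @export
run_stability <- function(matrix_path, labels_path, methods, sizes,
                          n_subsamples = 5, seed = 1,
                          config = default_config(), out_path) {
  mat <- read_beta_matrix(matrix_path)
  labels <- read_labels(labels_path)[colnames(mat)]
  mat <- preprocess_beta(mat, max_missing = config$max_missing)
  df <- stability_experiment(mat, labels, methods = methods,
                             sizes = sizes,
                             n_subsamples = n_subsamples,
                             control = config_to_control(config),
                             seed = seed)
  utils::write.table(df, out_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(df)
}
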