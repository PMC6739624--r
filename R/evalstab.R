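#' Jaccard similarity of two locus sets
#'
#' `|a n b| / |a u b|`. Two empty signatures are defined as identical
#' (similarity 1); empty versus non-empty is 0.
#'
#' @param a,b character vectors of locus ids.
#' @return similarity in \[0,1\].
#' @export
jaccard <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

#' Overall selection stability of a collection of signatures
#'
#' The mean of all pairwise Jaccard similarities,
#' `S_tot = 2 * sum_{i<j} S(f_i, f_j) / (k (k - 1))`. Higher values mean
#' the selection reproduces better under instance perturbation.
#'
#' @param signatures list of >= 2 character vectors.
#' @return scalar in \[0,1\].
#' @export
stability_total <- function(signatures) {
  k <- length(signatures)
  if (k < 2L) stop_("need at least 2 signatures")
  s <- 0
  for (i in seq_len(k - 1L))
    for (j in (i + 1L):k)
      s <- s + jaccard(signatures[[i]], signatures[[j]])
  2 * s / (k * (k - 1L))
}

#' Pairwise Jaccard matrix and overall stability
#'
#' @param signatures named list of character vectors.
#' @return list of class `stability_report`: `pairwise` (symmetric
#'   similarity matrix with unit diagonal) and `s_tot`.
#' @export
stability_report <- function(signatures) {
  k <- length(signatures)
  if (k < 2L) stop_("need at least 2 signatures")
  nm <- names(signatures) %||% paste0("signature_", seq_len(k))
  m <- diag(1, k)
  dimnames(m) <- list(nm, nm)
  for (i in seq_len(k - 1L))
    for (j in (i + 1L):k)
      m[i, j] <- m[j, i] <- jaccard(signatures[[i]], signatures[[j]])
  structure(list(pairwise = m, s_tot = stability_total(signatures),
                 signatures = signatures), class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Stability over %d signatures: S_tot = %.4f\n",
              length(x$signatures), x$s_tot))
  invisible(x)
}

#' Confusion-matrix classification metrics
#'
#' The positive class is tumour (1). Degenerate ratios (0/0) are defined
#' as 0.
#'
#' @param truth,predicted 0/1 vectors of equal length.
#' @return list of class `confusion_metrics` with `tp`, `tn`, `fp`,
#'   `fn`, `tpr`, `fpr`, `acc`, `precision`, `recall`, `f1`.
#' @export
confusion_metrics <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop_("truth and predicted must have equal length")
  truth <- as.integer(truth)
  predicted <- as.integer(predicted)
  if (!all(c(truth, predicted) %in% c(0L, 1L)))
    stop_("labels must be 0/1")
  tp <- sum(truth == 1L & predicted == 1L)
  tn <- sum(truth == 0L & predicted == 0L)
  fp <- sum(truth == 0L & predicted == 1L)
  fn <- sum(truth == 1L & predicted == 0L)
  div <- function(a, b) if (b == 0) 0 else a / b
  precision <- div(tp, tp + fp)
  recall <- div(tp, tp + fn)
  structure(list(
    tp = tp, tn = tn, fp = fp, fn = fn,
    tpr = recall,
    fpr = div(fp, fp + tn),
    acc = div(tp + tn, length(truth)),
    precision = precision,
    recall = recall,
    f1 = if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)),
    class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf(
    "TP %d  TN %d  FP %d  FN %d\nTPR %.3f  FPR %.3f  ACC %.3f  Prec %.3f  Rec %.3f  F1 %.3f\n",
    x$tp, x$tn, x$fp, x$fn, x$tpr, x$fpr, x$acc, x$precision, x$recall,
    x$f1))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Computed exactly as the Mann-Whitney probability
#' `P(score_pos > score_neg) + 0.5 P(tie)` over all positive x negative
#' sample pairs (via midranks), which is invariant under strictly
#' monotone transformations of the scores.
#'
#' @param truth 0/1 vector, both classes present.
#' @param scores numeric scores, larger meaning more tumour-like.
#' @return AUC in \[0,1\].
#' @export
auc_score <- function(truth, scores) {
  if (length(truth) != length(scores))
    stop_("truth and scores must have equal length")
  truth <- as.integer(truth)
  n1 <- sum(truth == 1L)
  n0 <- sum(truth == 0L)
  if (n1 == 0L || n0 == 0L) stop_("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a locus signature on an independent test set
#'
#' Trains a linear SVM on the training cohort restricted to the
#' signature and reports the full confusion-metric suite plus AUC (from
#' SVM decision values) on the test cohort.
#'
#' @param mat_train,mat_test loci x samples beta matrices.
#' @param labels_train,labels_test 0/1 vectors.
#' @param loci signature locus ids.
#' @param cfg a [selector_control()].
#' @return `confusion_metrics` with an additional `auc` field.
#' @export
evaluate_signature <- function(mat_train, labels_train, mat_test,
                               labels_test, loci,
                               cfg = selector_control()) {
  fit <- svm_fit(mat_train, labels_train, loci, cfg)
  pred <- svm_predict(fit, mat_test, decision = TRUE)
  out <- confusion_metrics(labels_test, pred$class)
  out$auc <- auc_score(labels_test, pred$score)
  out
}

# Ranker registry used by the stability experiment: maps a method name to
# a function(mat, labels, cfg, seed) -> feature_ranking. "hydml" ranks by
# one iteration of the ensemble (fold-aggregated weights summed across
# folds).
stability_ranker <- function(method, control) {
  if (is.function(method)) return(method)
  if (method %in% c("elastic_net", "info_gain", "mc_subspace"))
    return(ranker_fun(method))
  if (method == "hydml") {
    return(function(mat, labels, cfg, seed) {
      k <- control$n_folds
      seeds <- derive_seeds(seed, k + 1L)
      folds <- stratified_folds(labels, k, seed = seeds[k + 1L])
      total <- stats::setNames(numeric(nrow(mat)), rownames(mat))
      for (i in seq_len(k)) {
        test <- folds[[i]]
        train <- setdiff(seq_along(labels), test)
        mat_tr <- mat[, train, drop = FALSE]
        rankings <- list()
        accs <- numeric(0)
        for (sel in control$selectors) {
          r <- ranker_fun(sel)(mat_tr, labels[train], cfg, seeds[i])
          own <- names(r$weights)[r$weights >= control$tau]
          accs[sel] <- if (length(own) == 0L) 0 else
            svm_accuracy(mat_tr, labels[train],
                         mat[, test, drop = FALSE], labels[test], own,
                         cfg)
          rankings[[sel]] <- r
        }
        total <- total + aggregate_fold(rankings, accs)
      }
      feature_ranking("hydml", max_normalize(total), raw = total)
    })
  }
  stop_("unknown method '%s'", method)
}

#' Selection stability and classification performance under subsampling
#'
#' For each method and signature size: draws `n_subsamples` stratified
#' 90% subsamples of the cohort, ranks loci on each subsample, truncates
#' the ranking to the signature size, and reports (i) the overall
#' stability `S_tot` of the resulting signatures and (ii) the mean AUC
#' of a linear SVM trained on each subsample's signature and scored on
#' the held-out 10%.
#'
#' @param mat loci x samples beta matrix (complete).
#' @param labels 0/1 vector.
#' @param methods character vector of ranker names (`"elastic_net"`,
#'   `"info_gain"`, `"mc_subspace"`, `"hydml"`), or a named list whose
#'   elements are such names or custom
#'   `function(mat, labels, cfg, seed) -> feature_ranking` rankers.
#' @param sizes integer signature sizes (each <= locus count).
#' @param n_subsamples number of perturbed draws per method.
#' @param control a [hydml_control()]; supplies the selector settings
#'   and, for the `"hydml"` ranker, the fold count and threshold.
#' @param seed master seed.
#' @return data.frame in tidy form: `method`, `signature_size`,
#'   `replicate` (`NA` for `S_tot`, which is computed across
#'   subsamples), `metric` (`"s_tot"` or `"auc"`), `value`.
#' @export
stability_experiment <- function(mat, labels, methods, sizes,
                                 n_subsamples = 5,
                                 control = hydml_control(), seed = 1) {
  labels <- as.integer(labels)
  sizes <- vapply(sizes, check_count, integer(1L), nm = "sizes")
  if (any(sizes > nrow(mat)))
    stop_("signature size exceeds locus count (%d)", nrow(mat))
  n_subsamples <- check_count(n_subsamples, "n_subsamples", min = 2L)
  sub_seeds <- derive_seeds(seed, n_subsamples)
  # common subsample draws so all methods see identical perturbations
  splits <- lapply(sub_seeds, function(s) {
    folds <- stratified_folds(labels, 10L, seed = s)
    holdout <- folds[[1L]]
    list(train = setdiff(seq_along(labels), holdout), holdout = holdout)
  })
  rows <- list()
  method_names <- names(methods) %||%
    vapply(methods, function(m) if (is.character(m)) m else "custom",
           character(1L))
  for (mi in seq_along(methods)) {
    rk <- stability_ranker(methods[[mi]], control)
    rankings <- vector("list", n_subsamples)
    for (r in seq_len(n_subsamples)) {
      tr <- splits[[r]]$train
      rankings[[r]] <- rk(mat[, tr, drop = FALSE], labels[tr],
                          control$selector, sub_seeds[r])
    }
    for (q in sizes) {
      sigs <- lapply(rankings, top_loci, size = q)
      rows[[length(rows) + 1L]] <-
        data.frame(method = method_names[mi], signature_size = q,
                   replicate = NA_integer_, metric = "s_tot",
                   value = stability_total(sigs))
      for (r in seq_len(n_subsamples)) {
        tr <- splits[[r]]$train
        ho <- splits[[r]]$holdout
        auc <- evaluate_signature(mat[, tr, drop = FALSE], labels[tr],
                                  mat[, ho, drop = FALSE], labels[ho],
                                  sigs[[r]], control$selector)$auc
        rows[[length(rows) + 1L]] <-
          data.frame(method = method_names[mi], signature_size = q,
                     replicate = r, metric = "auc", value = auc)
      }
    }
  }
  do.call(rbind, rows)
}
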