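#' Ensemble configuration
#'
#' @param n_folds number of stratified cross-validation folds per
#'   iteration (`k`).
#' @param n_iterations number of resampling iterations (`T`), each with a
#'   fresh fold assignment.
#' @param tau aggregated-weight threshold: loci with fold-aggregated
#'   weight below `tau` are dropped in that fold (kept when `>= tau`).
#' @param bag_min bagging consensus count: a locus enters the final set
#'   when it appears in at least `bag_min` of the `n_iterations`
#'   iteration sets.
#' @param selectors character vector naming the base rankers to ensemble;
#'   any of `"elastic_net"`, `"info_gain"`, `"mc_subspace"`.
#' @param selector a [selector_control()].
#' @param seed master seed; every stochastic step derives its own seed
#'   from it.
#' @return a list of class `hydml_control`.
#' @export
hydml_control <- function(n_folds = 10, n_iterations = 10, tau = 0.01,
                          bag_min = 5,
                          selectors = c("elastic_net", "info_gain",
                                        "mc_subspace"),
                          selector = selector_control(), seed = 1) {
  selectors <- match.arg(selectors, several.ok = TRUE)
  ctrl <- list(
    n_folds = check_count(n_folds, "n_folds", min = 2L),
    n_iterations = check_count(n_iterations, "n_iterations", min = 1L),
    tau = check_number(tau, "tau", min = 0),
    bag_min = check_count(bag_min, "bag_min", min = 1L),
    selectors = selectors,
    selector = selector,
    seed = check_count(seed, "seed", min = 0L))
  if (ctrl$bag_min > ctrl$n_iterations)
    stop_("bag_min (%d) cannot exceed n_iterations (%d)",
          ctrl$bag_min, ctrl$n_iterations)
  class(ctrl) <- "hydml_control"
  ctrl
}

ranker_fun <- function(name) {
  switch(name,
         elastic_net = function(mat, labels, cfg, seed)
           elastic_net_rank(mat, labels, cfg),
         info_gain = function(mat, labels, cfg, seed)
           info_gain_rank(mat, labels, cfg),
         mc_subspace = function(mat, labels, cfg, seed)
           mc_subspace_rank(mat, labels, cfg, seed = seed),
         stop_("unknown selector '%s'", name))
}

#' Stratified cross-validation folds
#'
#' Partitions sample indices into `k` folds whose sizes differ by at most
#' one, preserving the class proportions within rounding in every fold.
#'
#' @param labels 0/1 vector.
#' @param k number of folds.
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @return list of `k` disjoint integer index vectors covering all
#'   samples.
#' @export
stratified_folds <- function(labels, k, seed = NULL) {
  k <- check_count(k, "k", min = 2L)
  if (!is.null(seed)) return(with_seed(seed, stratified_folds(labels, k)))
  tab <- table(labels)
  short <- names(tab)[tab < k]
  if (length(short) > 0)
    stop_("class %s has fewer samples (%d) than folds (%d)",
          short[1L], tab[short[1L]], k)
  folds <- vector("list", k)
  load <- integer(k)
  for (cls in names(tab)) {
    idx <- sample(which(labels == as.integer(cls)))
    n_c <- length(idx)
    base <- n_c %/% k
    extra <- n_c %% k
    # remainder goes to the currently lightest folds (ties by fold index)
    recv <- order(load, seq_len(k))[seq_len(extra)]
    sizes <- rep(base, k)
    sizes[recv] <- sizes[recv] + 1L
    at <- 1L
    for (i in seq_len(k)) {
      if (sizes[i] > 0) {
        folds[[i]] <- c(folds[[i]], idx[at:(at + sizes[i] - 1L)])
        at <- at + sizes[i]
      }
    }
    load <- load + sizes
  }
  lapply(folds, sort)
}

#' Accuracy-weighted aggregation of selector rankings
#'
#' Implements the first-level aggregation `f_j = sum_i acc_i * f_ij` over
#' the selectors' max-normalized weights; the result is deliberately not
#' re-normalized, since the downstream weight threshold applies on this
#' scale.
#'
#' @param rankings list of `feature_ranking` objects on the same locus
#'   axis.
#' @param accs per-selector held-out accuracies in \[0,1\].
#' @return named numeric vector of aggregated weights.
#' @export
aggregate_fold <- function(rankings, accs) {
  if (length(rankings) != length(accs))
    stop_("need one accuracy per ranking")
  if (length(rankings) == 0L) stop_("no rankings to aggregate")
  ids <- names(rankings[[1L]]$weights)
  f <- numeric(length(ids))
  for (i in seq_along(rankings)) {
    if (!identical(names(rankings[[i]]$weights), ids))
      stop_("rankings disagree on the locus axis")
    f <- f + accs[[i]] * rankings[[i]]$weights
  }
  stats::setNames(f, ids)
}

#' Keep loci whose aggregated weight reaches the threshold
#'
#' @param f named aggregated weight vector.
#' @param tau nonnegative threshold; loci with `f >= tau` are kept.
#' @return character vector of surviving locus ids.
#' @export
threshold_filter <- function(f, tau) {
  tau <- check_number(tau, "tau", min = 0)
  names(f)[f >= tau]
}

#' Union the surviving locus sets of all folds
#'
#' Second-level aggregation: the iteration's locus set is the union of
#' the per-fold surviving sets; each locus's weight is the sum of its
#' fold-aggregated weights over the folds where it survived, and its
#' count is the number of such folds.
#'
#' @param sets list of character vectors (per-fold surviving loci).
#' @param weights optional list of named numeric vectors (per-fold
#'   aggregated weights) matching `sets`.
#' @param name name for the resulting set.
#' @return a [dml_set()].
#' @export
union_folds <- function(sets, weights = NULL, name = "iteration") {
  if (length(sets) == 0L) stop_("need at least one fold set")
  loci <- sort(unique(unlist(sets, use.names = FALSE)))
  counts <- integer(length(loci))
  wsum <- numeric(length(loci))
  names(counts) <- names(wsum) <- loci
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    counts[s] <- counts[s] + 1L
    if (!is.null(weights)) wsum[s] <- wsum[s] + weights[[i]][s]
  }
  dml_set(loci, name = name, counts = counts,
          weights = if (!is.null(weights)) wsum)
}

#' Bagging consensus across iterations
#'
#' Keeps loci appearing in at least `min_count` of the iteration sets;
#' the final weight of a locus is the mean of its iteration weights over
#' the iterations that contain it.
#'
#' @param iteration_sets list of [dml_set()]s, one per iteration.
#' @param min_count minimum number of iterations a locus must appear in.
#' @param name name for the final set.
#' @return a [dml_set()] with occurrence counts and mean weights.
#' @export
bagging_select <- function(iteration_sets, min_count, name = "final") {
  t_total <- length(iteration_sets)
  min_count <- check_count(min_count, "min_count", min = 1L)
  if (min_count > t_total)
    stop_("min_count (%d) exceeds the number of iteration sets (%d)",
          min_count, t_total)
  all_loci <- sort(unique(unlist(lapply(iteration_sets, `[[`, "loci"),
                                 use.names = FALSE)))
  counts <- integer(length(all_loci))
  wsum <- numeric(length(all_loci))
  has_w <- FALSE
  names(counts) <- names(wsum) <- all_loci
  for (s in iteration_sets) {
    counts[s$loci] <- counts[s$loci] + 1L
    if (!is.null(s$weights)) {
      has_w <- TRUE
      wsum[s$loci] <- wsum[s$loci] + s$weights[s$loci]
    }
  }
  keep <- counts >= min_count
  dml_set(all_loci[keep], name = name, counts = counts[keep],
          weights = if (has_w) wsum[keep] / counts[keep])
}

#' Hybrid ensemble identification of differentially methylated loci
#'
#' Runs the full hybrid ensemble: `n_iterations` times, the cohort is
#' split into `n_folds` stratified folds; in each fold the base selectors
#' rank all loci on the training split, a linear SVM trained on each
#' selector's surviving loci is scored on the held-out fold, rankings are
#' aggregated with those accuracies as weights, thresholded at `tau`, and
#' unioned across folds into an iteration set; the final DML set is the
#' bagging consensus of the iteration sets. The entire run is
#' reproducible from the master seed.
#'
#' @param x loci x samples beta matrix, complete (see
#'   [preprocess_beta()]).
#' @param labels 0/1 vector (0 = normal, 1 = tumour) aligned with the
#'   columns of `x`.
#' @param control a [hydml_control()].
#' @param keep_fold_detail store per-fold aggregated weight vectors in the
#'   returned object (memory grows with `n_iterations * n_folds * p`).
#' @return an object of class `hydml` with components `dml` (final
#'   [dml_set()]), `iterations` (per-iteration sets), `accuracy`
#'   (per-fold selector accuracy table), `control`, `seed`, and the
#'   training data for [predict.hydml()].
#' @seealso [predict.hydml()], [coef.hydml()], [summary.hydml()]
#' @export
hydml <- function(x, labels, control = hydml_control(),
                  keep_fold_detail = FALSE) {
  validate_beta_matrix(x)
  labels <- as.integer(labels)
  if (length(labels) != ncol(x))
    stop_("need one label per sample column")
  if (!all(labels %in% c(0L, 1L))) stop_("labels must be 0/1")
  check_two_classes(labels)
  if (anyNA(x))
    stop_("matrix has missing values; run preprocess_beta() first")
  t_total <- control$n_iterations
  k <- control$n_folds
  iter_seeds <- derive_seeds(control$seed, t_total)
  iterations <- vector("list", t_total)
  fold_detail <- if (keep_fold_detail) vector("list", t_total)
  acc_rows <- list()
  for (t in seq_len(t_total)) {
    seeds <- derive_seeds(iter_seeds[t], k + 1L)
    folds <- stratified_folds(labels, k, seed = seeds[k + 1L])
    fold_sets <- vector("list", k)
    fold_weights <- vector("list", k)
    for (i in seq_len(k)) {
      test <- folds[[i]]
      train <- setdiff(seq_along(labels), test)
      mat_tr <- x[, train, drop = FALSE]
      mat_te <- x[, test, drop = FALSE]
      rankings <- list()
      accs <- numeric(0)
      for (sel in control$selectors) {
        r <- ranker_fun(sel)(mat_tr, labels[train], control$selector,
                             seeds[i])
        own <- names(r$weights)[r$weights >= control$tau]
        acc <- if (length(own) == 0L) 0 else
          svm_accuracy(mat_tr, labels[train], mat_te, labels[test], own,
                       control$selector)
        rankings[[sel]] <- r
        accs[sel] <- acc
        acc_rows[[length(acc_rows) + 1L]] <-
          data.frame(iteration = t, fold = i, selector = sel,
                     accuracy = acc, n_loci = length(own))
      }
      f <- aggregate_fold(rankings, accs)
      surv <- threshold_filter(f, control$tau)
      if (length(surv) == 0L)
        warning(sprintf(
          "iteration %d fold %d: no locus reached tau = %g", t, i,
          control$tau), call. = FALSE)
      fold_sets[[i]] <- surv
      fold_weights[[i]] <- f
      if (keep_fold_detail)
        fold_detail[[t]][[i]] <- list(f = f, surviving = surv,
                                      accuracy = accs)
    }
    iterations[[t]] <- union_folds(fold_sets, fold_weights,
                                   name = sprintf("iteration_%02d", t))
  }
  final <- bagging_select(iterations, control$bag_min, name = "hydml")
  if (length(final) == 0L)
    warning("final DML set is empty", call. = FALSE)
  structure(list(
    dml = final,
    iterations = iterations,
    accuracy = do.call(rbind, acc_rows),
    control = control,
    seed = control$seed,
    fold_detail = fold_detail,
    x = x, labels = labels,
    call = match.call()), class = "hydml")
}

#' @export
print.hydml <- function(x, ...) {
  cat("Hybrid ensemble DML selection\n")
  cat(sprintf("  %d loci x %d samples (%d normal / %d tumour)\n",
              nrow(x$x), ncol(x$x), sum(x$labels == 0L),
              sum(x$labels == 1L)))
  cat(sprintf(
    "  %d iterations x %d folds, selectors: %s, tau = %g, bag_min = %d\n",
    x$control$n_iterations, x$control$n_folds,
    paste(x$control$selectors, collapse = ", "), x$control$tau,
    x$control$bag_min))
  cat(sprintf("  final DML set: %d loci\n", length(x$dml)))
  invisible(x)
}

#' Summarize a hydml fit
#' @param object a `hydml` fit.
#' @param ... unused.
#' @return a `summary.hydml` list with selector accuracy summaries,
#'   per-iteration set sizes and the top final loci.
#' @export
summary.hydml <- function(object, ...) {
  acc <- stats::aggregate(accuracy ~ selector, data = object$accuracy,
                          FUN = mean)
  sizes <- vapply(object$iterations, length, integer(1L))
  w <- object$dml$weights
  top <- if (!is.null(w)) utils::head(sort(w, decreasing = TRUE), 10L)
  structure(list(n_final = length(object$dml),
                 iteration_sizes = sizes,
                 mean_accuracy = acc,
                 top_loci = top,
                 control = object$control), class = "summary.hydml")
}

#' @export
print.summary.hydml <- function(x, ...) {
  cat(sprintf("Final DML set: %d loci\n", x$n_final))
  cat("Per-iteration set sizes:\n  ")
  cat(x$iteration_sizes, sep = " ")
  cat("\nMean held-out selector accuracy:\n")
  for (i in seq_len(nrow(x$mean_accuracy)))
    cat(sprintf("  %-12s %.3f\n", x$mean_accuracy$selector[i],
                x$mean_accuracy$accuracy[i]))
  if (!is.null(x$top_loci)) {
    cat("Top loci by consensus weight:\n")
    for (nm in names(x$top_loci))
      cat(sprintf("  %s  %.4f\n", nm, x$top_loci[[nm]]))
  }
  invisible(x)
}

#' Final consensus weights of a hydml fit
#' @param object a `hydml` fit.
#' @param all_loci return a weight for every input locus (0 when not
#'   selected) instead of only the selected ones.
#' @param ... unused.
#' @return named numeric vector of consensus weights.
#' @export
coef.hydml <- function(object, all_loci = FALSE, ...) {
  w <- object$dml$weights
  if (is.null(w))
    w <- stats::setNames(rep(1, length(object$dml)), object$dml$loci)
  if (!all_loci) return(w)
  out <- stats::setNames(numeric(nrow(object$x)), rownames(object$x))
  out[names(w)] <- w
  out
}

#' Classify new samples with the selected loci
#'
#' Trains a linear SVM on the fit's training cohort restricted to the
#' final DML set and applies it to new samples.
#'
#' @param object a `hydml` fit with a non-empty final set.
#' @param newdata loci x samples beta matrix containing the selected
#'   loci.
#' @param type `"class"` for 0/1 predictions, `"score"` for decision
#'   values oriented so that larger means tumour.
#' @param ... unused.
#' @return integer or numeric vector, one value per sample.
#' @export
predict.hydml <- function(object, newdata, type = c("class", "score"),
                          ...) {
  type <- match.arg(type)
  if (length(object$dml) == 0L)
    stop_("final DML set is empty; nothing to predict with")
  fit <- svm_fit(object$x, object$labels, object$dml$loci,
                 object$control$selector)
  if (type == "class") return(svm_predict(fit, newdata))
  svm_predict(fit, newdata, decision = TRUE)$score
}

#' Plot a hydml fit
#'
#' Left: held-out accuracy of each base selector across all folds.
#' Right: occurrence counts of the final loci across iterations.
#'
#' @param x a `hydml` fit.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.hydml <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::boxplot(accuracy ~ selector, data = x$accuracy,
                    ylab = "held-out accuracy", xlab = "",
                    main = "Selector accuracy", las = 2, ...)
  if (length(x$dml) > 0 && !is.null(x$dml$counts)) {
    graphics::hist(x$dml$counts,
                   breaks = seq(0.5, x$control$n_iterations + 0.5, 1),
                   xlab = "iterations containing locus",
                   main = "Final set consensus", col = "grey80")
  }
  invisible(x)
}
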