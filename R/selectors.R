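#' Selector configuration
#'
#' Tuning parameters of the three base rankers and the fold classifier.
#'
#' @param alpha elastic-net mixing in \[0,1\]: 1 = lasso, 0 = ridge.
#' @param lambda elastic-net penalty (on the un-scaled penalized
#'   least-squares objective, see [elastic_net_rank()]) or `"auto"` for
#'   internal 5-fold cross-validation with the one-standard-error rule.
#' @param en_family `"gaussian"` fits the squared-loss objective on 0/1
#'   labels; `"binomial"` switches to logistic loss (then a numeric
#'   `lambda` is interpreted on glmnet's own scale).
#' @param n_bins number of equal-width bins on \[0,1\] for the
#'   information-gain ranker.
#' @param ig_sig,ig_adjust significance level and [stats::p.adjust()]
#'   method for the G-test mask applied to information-gain weights: loci
#'   whose gain is indistinguishable from the finite-sample chance level
#'   are zeroed before normalization so the downstream weight threshold
#'   has a meaningful zero point.
#' @param s_mc number of random subspaces for the Monte Carlo ranker.
#' @param m_mc subspace size; `NULL` for the default
#'   `min(p, 5 * ceiling(sqrt(p)))`.
#' @param t_mc trees per subspace.
#' @param mc_depth,mc_min_node tree depth limit and minimum node size.
#' @param mc_null_quantile quantile of the label-permuted null
#'   importances used to zero chance-level Monte Carlo scores.
#' @param svm_cost soft-margin cost of the linear SVM.
#' @param svm_class_weights balance SVM class weights inversely to class
#'   frequency (off by default).
#' @param seed seed used for internal cross-validation fold assignment in
#'   `lambda = "auto"` mode (the Monte Carlo ranker takes its seed per
#'   call).
#' @return a list of class `selector_control`.
#' @export
selector_control <- function(alpha = 0.5, lambda = "auto",
                             en_family = c("gaussian", "binomial"),
                             n_bins = 10, ig_sig = 0.05,
                             ig_adjust = "bonferroni",
                             s_mc = 300, m_mc = NULL, t_mc = 1,
                             mc_depth = 2, mc_min_node = 5,
                             mc_null_quantile = 0.999,
                             svm_cost = 1, svm_class_weights = FALSE,
                             seed = 1) {
  cfg <- list(
    alpha = check_number(alpha, "alpha", 0, 1),
    lambda = if (identical(lambda, "auto")) "auto"
             else check_number(lambda, "lambda", min = 0),
    en_family = match.arg(en_family),
    n_bins = check_count(n_bins, "n_bins", min = 2L),
    ig_sig = check_number(ig_sig, "ig_sig", 0, 1),
    ig_adjust = ig_adjust,
    s_mc = check_count(s_mc, "s_mc"),
    m_mc = if (!is.null(m_mc)) check_count(m_mc, "m_mc"),
    t_mc = check_count(t_mc, "t_mc"),
    mc_depth = check_count(mc_depth, "mc_depth"),
    mc_min_node = check_count(mc_min_node, "mc_min_node", min = 2L),
    mc_null_quantile = check_number(mc_null_quantile, "mc_null_quantile",
                                    0, 1),
    svm_cost = check_number(svm_cost, "svm_cost", min = 1e-12),
    svm_class_weights = check_flag(svm_class_weights, "svm_class_weights"),
    seed = check_count(seed, "seed", min = 0L))
  class(cfg) <- "selector_control"
  cfg
}

# A feature ranking: nonnegative per-locus weights max-normalized to [0,1]
# (all-zero allowed), plus the raw selector scores kept for tie-breaking
# when a ranking is truncated to a fixed signature size.
feature_ranking <- function(selector, weights, raw = weights) {
  structure(list(selector = selector,
                 weights = weights,
                 raw = raw),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("<feature_ranking: %s, %d loci, %d with positive weight>\n",
              x$selector, length(x$weights), sum(x$weights > 0)))
  invisible(x)
}

# Locus ids of the top `size` loci of a ranking (weight desc, raw score
# desc, then lexicographic id — fully deterministic).
top_loci <- function(ranking, size) {
  ids <- names(ranking$weights)
  ord <- order(-ranking$weights, -ranking$raw, ids)
  ids[ord][seq_len(min(size, length(ids)))]
}

check_two_classes <- function(labels) {
  if (length(unique(labels)) < 2L)
    stop_("both classes (0 and 1) must be present")
}

#' Rank loci with a penalized linear model (elastic net)
#'
#' Fits the penalized least-squares objective
#' `sum_i (y_i - b0 - w'x_i)^2 + lambda * (alpha * sum|w_j| +
#' (1 - alpha) * sum w_j^2)` on standardized beta values with 0/1 labels
#' (the unpenalized intercept absorbs the class base rate) and ranks each
#' locus by `|w_j|`, max-normalized. The penalty is applied exactly on
#' this scale — no `1/m` or `1/2` factors — and is mapped internally to
#' glmnet's parameterization.
#'
#' @param mat loci x samples beta matrix (complete).
#' @param labels 0/1 vector aligned with the matrix columns.
#' @param cfg a [selector_control()].
#' @return a `feature_ranking`.
#' @export
elastic_net_rank <- function(mat, labels, cfg = selector_control()) {
  check_two_classes(labels)
  x <- standardize_cols(t(mat))
  y <- as.numeric(labels)
  m <- nrow(x)
  p <- ncol(x)
  if (p < 2L) stop_("elastic_net_rank needs at least 2 loci")
  if (identical(cfg$lambda, "auto")) {
    nf <- min(5L, min(table(labels)))
    if (nf < 2L) stop_("too few samples per class for internal CV")
    folds <- stratified_folds(labels, nf, seed = cfg$seed)
    foldid <- integer(m)
    for (i in seq_along(folds)) foldid[folds[[i]]] <- i
    fit <- glmnet::cv.glmnet(x, y, family = cfg$en_family,
                             alpha = cfg$alpha, foldid = foldid,
                             standardize = FALSE,
                             grouped = min(table(foldid)) >= 3L)
    w <- as.numeric(stats::coef(fit, s = "lambda.1se"))[-1L]
  } else {
    if (cfg$lambda == 0 && p > m)
      stop_("lambda = 0 with more loci than samples is underdetermined")
    lam_glmnet <- if (cfg$en_family == "gaussian") cfg$lambda / (2 * m)
                  else cfg$lambda
    fit <- glmnet::glmnet(x, y, family = cfg$en_family, alpha = cfg$alpha,
                          lambda = lam_glmnet, standardize = FALSE,
                          thresh = 1e-14, maxit = 1e7)
    w <- as.numeric(stats::coef(fit))[-1L]
  }
  w <- abs(w)
  names(w) <- rownames(mat)
  feature_ranking("elastic_net", max_normalize(w), raw = w)
}

# Raw per-locus information gain (bits) of the class given the equal-width
# binned beta value, plus the G-test p-value of independence.
info_gain_table <- function(mat, labels, n_bins) {
  n <- ncol(mat)
  bins <- pmin(floor(mat * n_bins), n_bins - 1L)
  cls1 <- labels == 1L
  n1 <- sum(cls1)
  n0 <- n - n1
  h_y <- ent2(c(n0, n1) / n)
  ig <- numeric(nrow(mat))
  occupied <- integer(nrow(mat))
  hx <- numeric(nrow(mat))
  hxy <- numeric(nrow(mat))
  for (b in seq_len(n_bins) - 1L) {
    cb0 <- rowSums(bins[, !cls1, drop = FALSE] == b)
    cb1 <- rowSums(bins[, cls1, drop = FALSE] == b)
    cb <- cb0 + cb1
    occupied <- occupied + (cb > 0L)
    hx <- hx + plogp(cb / n)
    hxy <- hxy + plogp(cb0 / n) + plogp(cb1 / n)
  }
  ig <- h_y + hx - hxy  # H(Y) + H(X) - H(X,Y), entropies as -sum p log p
  ig[ig < 0] <- 0       # clip tiny negative rounding noise
  df <- pmax(occupied - 1L, 0L)
  g <- 2 * n * log(2) * ig
  pval <- ifelse(df > 0, stats::pchisq(g, df, lower.tail = FALSE), 1)
  list(ig = stats::setNames(ig, rownames(mat)), pval = pval)
}

# -sum p log2 p accumulator helpers
ent2 <- function(p) -sum(ifelse(p > 0, p * log2(p), 0))
plogp <- function(p) ifelse(p > 0, -p * log2(p), 0)

#' Rank loci by information gain
#'
#' Discretizes each locus into equal-width bins on \[0,1\] and scores it
#' by the information gain of the class: `IG = H(class) -
#' H(class | binned beta)` in bits (`0 * log 0 = 0`). Because the plug-in
#' gain of an uninformative locus is positive in finite samples, gains
#' that a G-test cannot distinguish from independence (at `ig_sig` after
#' `ig_adjust` multiplicity correction across loci) are set to zero before
#' max-normalization; the raw gain is kept in the ranking's `raw` field.
#'
#' @inheritParams elastic_net_rank
#' @return a `feature_ranking`.
#' @export
info_gain_rank <- function(mat, labels, cfg = selector_control()) {
  check_two_classes(labels)
  tab <- info_gain_table(mat, labels, cfg$n_bins)
  padj <- stats::p.adjust(tab$pval, method = cfg$ig_adjust)
  w <- ifelse(padj <= cfg$ig_sig, tab$ig, 0)
  names(w) <- rownames(mat)
  feature_ranking("info_gain", max_normalize(w), raw = tab$ig)
}

#' Rank loci with Monte Carlo random-subspace decision trees
#'
#' Draws `s_mc` random subspaces of `m_mc` loci; in each, grows `t_mc`
#' depth-limited CART trees on bootstrap resamples. Every locus
#' accumulates (tree out-of-bag balanced accuracy) x (its share of the
#' tree's impurity decrease); its relative importance is the accumulated
#' score divided by the number of subspaces containing it. The whole
#' scorer is then re-run with permuted class labels on the same
#' subspaces, and a locus's importance is kept only in excess of the
#' `mc_null_quantile` quantile of the permuted-run importances — label
#' permutation is the only null that reproduces how strongly the
#' luckiest uninformative locus can score consistently within one
#' cohort, so chance-level loci score exactly zero. Fully reproducible
#' given `seed`; the raw (uncalibrated) importances are kept in the
#' ranking's `raw` field.
#'
#' @inheritParams elastic_net_rank
#' @param seed RNG seed for subspace draws, shadow permutations and
#'   bootstrap resamples.
#' @return a `feature_ranking`.
#' @export
mc_subspace_rank <- function(mat, labels, cfg = selector_control(),
                             seed = cfg$seed) {
  check_two_classes(labels)
  p <- nrow(mat)
  m_mc <- cfg$m_mc %||% min(p, 5L * ceiling(sqrt(p)))
  if (m_mc > p)
    stop_("subspace size m_mc (%d) exceeds locus count (%d)", m_mc, p)
  x <- t(mat)
  y <- as.integer(labels)
  res <- with_seed(seed, {
    subspaces <- lapply(seq_len(cfg$s_mc),
                        function(i) sort(sample.int(p, m_mc)))
    real <- .mc_subspace_score(x, y, subspaces, cfg$t_mc, cfg$mc_depth,
                               cfg$mc_min_node)
    perm <- .mc_subspace_score(x, sample(y), subspaces, cfg$t_mc,
                               cfg$mc_depth, cfg$mc_min_node)
    list(real = real, perm = perm)
  })
  avg <- ifelse(res$real$count > 0,
                res$real$score / pmax(res$real$count, 1L), 0)
  avg_perm <- ifelse(res$perm$count > 0,
                     res$perm$score / pmax(res$perm$count, 1L), 0)
  cutoff <- stats::quantile(avg_perm, cfg$mc_null_quantile,
                            names = FALSE)
  masked <- pmax(0, avg - cutoff)
  names(masked) <- names(avg) <- rownames(mat)
  feature_ranking("mc_subspace", max_normalize(masked), raw = avg)
}

#' Held-out accuracy of a linear SVM on a locus subset
#'
#' Trains a linear-kernel soft-margin SVM on the training samples
#' restricted to `loci` (features standardized by training-set statistics)
#' and returns the fraction of correctly classified test samples.
#'
#' @param mat_train,mat_test loci x samples beta matrices.
#' @param labels_train,labels_test 0/1 vectors.
#' @param loci locus ids to use as features.
#' @param cfg a [selector_control()] (cost and class-weight settings).
#' @return accuracy in \[0,1\].
#' @export
svm_accuracy <- function(mat_train, labels_train, mat_test, labels_test,
                         loci, cfg = selector_control()) {
  fit <- svm_fit(mat_train, labels_train, loci, cfg)
  pred <- svm_predict(fit, mat_test)
  mean(pred == as.integer(labels_test))
}

# Internal: fit the linear SVM on a locus subset; returns model + scaling.
svm_fit <- function(mat_train, labels_train, loci, cfg = selector_control()) {
  loci <- as.character(loci)
  if (length(loci) == 0L) stop_("empty locus subset")
  missing <- setdiff(loci, rownames(mat_train))
  if (length(missing) > 0)
    stop_("loci absent from matrix: %s",
          paste(utils::head(missing, 5L), collapse = ", "))
  check_two_classes(labels_train)
  xtr <- standardize_cols(t(mat_train[loci, , drop = FALSE]))
  y <- factor(as.integer(labels_train), levels = c(0L, 1L))
  cw <- if (cfg$svm_class_weights) {
    tb <- table(y)
    stats::setNames(as.numeric(sum(tb) / (2 * tb)), names(tb))
  }
  model <- e1071::svm(xtr, y, kernel = "linear", cost = cfg$svm_cost,
                      scale = FALSE, class.weights = cw,
                      probability = FALSE)
  list(model = model, loci = loci,
       center = attr(xtr, "center"), scale = attr(xtr, "scale"))
}

svm_predict <- function(fit, mat, decision = FALSE) {
  x <- standardize_cols(t(mat[fit$loci, , drop = FALSE]),
                        center = fit$center, scale = fit$scale)
  pred <- stats::predict(fit$model, x, decision.values = decision)
  if (!decision) return(as.integer(as.character(pred)))
  dv <- attr(pred, "decision.values")
  # orient decision values so larger means class 1 (tumour)
  score <- dv[, 1L]
  if (startsWith(colnames(dv)[1L], "0/")) score <- -score
  list(class = as.integer(as.character(pred)), score = unname(score))
}
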