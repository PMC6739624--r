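# ---- stratified folds ------------------------------------------------------

test_that("stratified folds partition samples with balanced classes", {
  lab <- rep(c(0L, 1L), each = 10)
  folds <- stratified_folds(lab, 10, seed = 1)
  expect_length(folds, 10)
  expect_true(all(lengths(folds) == 2))
  for (f in folds) expect_setequal(lab[f], c(0L, 1L))
  expect_setequal(unlist(folds), seq_along(lab))

  # uneven totals: sizes differ by at most one, still a partition
  lab2 <- rep(c(0L, 1L), c(11, 10))
  folds2 <- stratified_folds(lab2, 10, seed = 2)
  expect_setequal(unlist(folds2), seq_along(lab2))
  expect_identical(anyDuplicated(unlist(folds2)), 0L)
  expect_lte(diff(range(lengths(folds2))), 1)

  expect_error(stratified_folds(rep(c(0L, 1L), c(5, 20)), 10),
               "class 0 has fewer")
})

test_that("every fold's class fraction stays within one sample of global", {
  for (seed in 1:100) {
    n <- sample(20:60, 1)
    n1 <- sample(10:(n - 10), 1)
    lab <- sample(rep(c(0L, 1L), c(n - n1, n1)))
    k <- sample(2:8, 1)
    if (min(n1, n - n1) < k) next
    folds <- stratified_folds(lab, k, seed = seed)
    expect_setequal(unlist(folds), seq_len(n))
    expect_lte(diff(range(lengths(folds))), 1)
    for (f in folds) {
      expected <- length(f) * n1 / n
      expect_lte(abs(sum(lab[f]) - expected), 1)
    }
  }
})

# ---- aggregation, thresholding, union, bagging -----------------------------

rank_of <- function(w, ids = paste0("l", seq_along(w))) {
  hydml:::feature_ranking("toy", stats::setNames(w, ids))
}

test_that("fold aggregation implements the accuracy-weighted sum", {
  r1 <- rank_of(c(1, 0))
  r2 <- rank_of(c(0, 1))
  expect_equal(aggregate_fold(list(r1, r2), c(0.9, 0.6)),
               c(l1 = 0.9, l2 = 0.6))
  # single selector with unit accuracy is the identity
  expect_equal(aggregate_fold(list(r1), 1), r1$weights)
  # a zero-accuracy selector contributes nothing
  expect_equal(aggregate_fold(list(r1, r2), c(1, 0)), c(l1 = 1, l2 = 0))
  expect_error(aggregate_fold(list(r1, rank_of(c(1, 0), c("a", "b"))),
                              c(1, 1)), "locus axis")
  expect_error(aggregate_fold(list(r1), c(1, 1)), "one accuracy")
})

test_that("aggregation is monotone in each selector accuracy", {
  for (i in 1:20) {
    w1 <- rank_of(runif(5))
    w2 <- rank_of(runif(5))
    a <- runif(2)
    f_lo <- aggregate_fold(list(w1, w2), a)
    f_hi <- aggregate_fold(list(w1, w2), c(a[1] + 0.1, a[2]))
    expect_true(all(f_hi >= f_lo))
  }
})

test_that("threshold filter keeps loci at or above tau", {
  f <- c(a = 0.9, b = 0.005, c = 0.01)
  expect_identical(threshold_filter(f, 0.01), c("a", "c"))
  expect_identical(threshold_filter(f, 0), c("a", "b", "c"))
  expect_identical(threshold_filter(f, 1), character(0))
})

test_that("fold union sums weights and counts occurrences", {
  sets <- list(c("a", "b"), c("b", "c"))
  weights <- list(c(a = 0.5, b = 0.5, c = 0.001),
                  c(a = 0.002, b = 0.3, c = 0.7))
  u <- union_folds(sets, weights)
  expect_setequal(u$loci, c("a", "b", "c"))
  expect_equal(u$weights[["b"]], 0.8)
  expect_equal(u$weights[["a"]], 0.5)   # only folds where it survived
  expect_identical(u$counts[["b"]], 2L)
  # identical fold sets: counts = k
  u2 <- union_folds(list(c("x"), c("x"), c("x")))
  expect_identical(u2$counts[["x"]], 3L)
  # disjoint sets: sizes add, counts all 1
  u3 <- union_folds(list(c("a"), c("b"), c("c")))
  expect_length(u3$loci, 3)
  expect_true(all(u3$counts == 1L))
})

test_that("bagging keeps loci meeting the occurrence count", {
  mk <- function(...) dml_set(c(...))
  sets <- lapply(seq_len(10), function(t) {
    loci <- "A"
    if (t <= 5) loci <- c(loci, "B")
    if (t <= 4) loci <- c(loci, "C")
    dml_set(loci, weights = stats::setNames(seq_along(loci) / 10, loci))
  })
  f <- bagging_select(sets, 5)
  expect_setequal(f$loci, c("A", "B"))
  expect_identical(f$counts[["A"]], 10L)
  # T = 1, c = 1 reduces to the single iteration set
  single <- bagging_select(list(mk("x", "y")), 1)
  expect_setequal(single$loci, c("x", "y"))
  # all-empty iterations give an empty final set
  expect_length(bagging_select(list(mk(), mk()), 1)$loci, 0)
  expect_error(bagging_select(list(mk()), 2), "exceeds")
  # final weight is the mean over iterations containing the locus
  expect_equal(f$weights[["B"]], 0.2)
})

test_that("bagging and union are invariant to input order and monotone in c", {
  sets <- lapply(1:6, function(i)
    dml_set(sample(letters[1:8], sample(2:6, 1))))
  f1 <- bagging_select(sets, 3)
  f2 <- bagging_select(rev(sets), 3)
  expect_identical(f1, f2)
  for (c_lo in 1:5)
    expect_true(all(bagging_select(sets, c_lo + 1)$loci %in%
                      bagging_select(sets, c_lo)$loci))
})

# ---- full ensemble ---------------------------------------------------------

test_that("the ensemble is reproducible and confined to the input loci", {
  co <- simulate_cohort(n_normal = 12, n_tumor = 12, n_loci = 120,
                        n_dml = 8, effect_size = 0.4, seed = 60)
  ctrl <- hydml_control(n_folds = 3, n_iterations = 2, bag_min = 2,
                        selector = selector_control(s_mc = 60),
                        seed = 7)
  fit1 <- hydml(co$mat, co$labels, control = ctrl)
  fit2 <- hydml(co$mat, co$labels, control = ctrl)
  expect_identical(fit1$dml, fit2$dml)
  expect_identical(fit1$accuracy, fit2$accuracy)
  expect_true(all(fit1$dml$loci %in% rownames(co$mat)))
  expect_true(all(vapply(fit1$iterations, function(s)
    all(s$loci %in% rownames(co$mat)), logical(1))))
  # per-iteration surviving weights respect tau on the aggregated scale
  expect_identical(nrow(fit1$accuracy),
                   3L * 2L * length(ctrl$selectors))
  expect_s3_class(summary(fit1), "summary.hydml")
  expect_identical(predict(fit1, co$mat),
                   unname(predict(fit1, co$mat)))
  expect_length(predict(fit1, co$mat, type = "score"), ncol(co$mat))
})

test_that("ensemble errors are informative", {
  co <- simulate_cohort(n_normal = 8, n_tumor = 8, n_loci = 40,
                        n_dml = 4, seed = 61)
  expect_error(hydml(co$mat, rep(1L, 16)), "both classes")
  bad <- co$mat
  bad[1, 1] <- NA
  expect_error(hydml(bad, co$labels), "missing values")
  expect_error(hydml_control(bag_min = 6, n_iterations = 5),
               "cannot exceed")
})

test_that("reduced pipeline (one selector, two folds, one iteration) matches a brute-force reference", {
  # independent 20-line reimplementation of the degenerate pipeline
  brute <- function(mat, labels, tau, master_seed) {
    iter_seed <- hydml:::derive_seeds(master_seed, 1)[1]
    seeds <- hydml:::derive_seeds(iter_seed, 3)
    folds <- stratified_folds(labels, 2, seed = seeds[3])
    sets <- list()
    weights <- list()
    for (i in 1:2) {
      train <- setdiff(seq_along(labels), folds[[i]])
      r <- info_gain_rank(mat[, train, drop = FALSE], labels[train])
      own <- names(r$weights)[r$weights >= tau]
      acc <- if (length(own) == 0) 0 else
        svm_accuracy(mat[, train, drop = FALSE], labels[train],
                     mat[, folds[[i]], drop = FALSE], labels[folds[[i]]],
                     own)
      f <- acc * r$weights
      sets[[i]] <- names(f)[f >= tau]
      weights[[i]] <- f
    }
    u <- union_folds(sets, weights)
    bagging_select(list(u), 1)$loci
  }
  for (seed in 1:10) {
    co <- simulate_cohort(n_normal = 6, n_tumor = 6, n_loci = 30,
                          n_dml = if (seed %% 2) 3 else 0,
                          effect_size = 0.45, seed = seed)
    ctrl <- hydml_control(n_folds = 2, n_iterations = 1, bag_min = 1,
                          tau = 0.05, selectors = "info_gain",
                          seed = seed + 100)
    fit <- suppressWarnings(hydml(co$mat, co$labels, control = ctrl))
    expect_identical(fit$dml$loci,
                     suppressWarnings(brute(co$mat, co$labels, 0.05,
                                            seed + 100)))
  }
})
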