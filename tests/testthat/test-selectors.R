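# ---- elastic net ----------------------------------------------------------

# closed-form ridge solution for the fitted objective:
# sum(y - b0 - w'x)^2 + lambda * sum(w^2) on standardized x (intercept
# unpenalized => y centred)
ridge_oracle <- function(mat, labels, lambda) {
  xs <- scale(t(mat))
  yc <- as.numeric(labels) - mean(labels)
  drop(solve(t(xs) %*% xs + lambda * diag(ncol(xs)), t(xs) %*% yc))
}

test_that("pure-ridge elastic net matches the closed-form solution", {
  co <- separable_cohort(n_loci = 3, n_per_class = 3, n_signal = 1,
                         seed = 10)
  for (lambda in c(0.5, 2.5, 10)) {
    cfg <- selector_control(alpha = 0, lambda = lambda)
    r <- elastic_net_rank(co$mat, co$labels, cfg)
    expect_lt(max(abs(r$raw - abs(ridge_oracle(co$mat, co$labels,
                                               lambda)))), 1e-6)
  }
})

test_that("lasso nulls all weights above the brute-force lambda_max", {
  co <- separable_cohort(n_loci = 4, n_per_class = 4, n_signal = 1,
                         seed = 11)
  xs <- scale(t(co$mat))
  yc <- as.numeric(co$labels) - mean(co$labels)
  # at w = 0 the subgradient condition gives lambda_max = 2 max |x_j' yc|
  lambda_max <- 2 * max(abs(t(xs) %*% yc))
  above <- elastic_net_rank(co$mat, co$labels,
                            selector_control(alpha = 1,
                                             lambda = lambda_max * 1.01))
  expect_true(all(above$weights == 0))
  below <- elastic_net_rank(co$mat, co$labels,
                            selector_control(alpha = 1,
                                             lambda = lambda_max * 0.8))
  expect_gt(sum(below$weights > 0), 0)
})

test_that("elastic net zeroes constant loci and refuses underdetermined fits", {
  co <- separable_cohort(n_loci = 5, n_per_class = 4, seed = 12)
  co$mat[5, ] <- 0.7
  r <- elastic_net_rank(co$mat, co$labels,
                        selector_control(alpha = 0.5, lambda = 1))
  expect_identical(unname(r$weights["cg00000005"]), 0)
  expect_equal(max(r$weights), 1)
  big <- separable_cohort(n_loci = 30, n_per_class = 4, seed = 13)
  expect_error(elastic_net_rank(big$mat, big$labels,
                                selector_control(lambda = 0)),
               "underdetermined")
})

test_that("elastic net ranking is deterministic and sample-order invariant", {
  co <- separable_cohort(n_loci = 10, n_per_class = 6, seed = 14)
  cfg <- selector_control(alpha = 0.5, lambda = 2)
  r1 <- elastic_net_rank(co$mat, co$labels, cfg)
  r2 <- elastic_net_rank(co$mat, co$labels, cfg)
  expect_identical(r1, r2)
  perm <- sample(ncol(co$mat))
  r3 <- elastic_net_rank(co$mat[, perm], co$labels[perm], cfg)
  expect_equal(r1$weights, r3$weights, tolerance = 1e-8)
  # auto-lambda mode runs and stays deterministic given the config seed
  a1 <- elastic_net_rank(co$mat, co$labels, selector_control())
  a2 <- elastic_net_rank(co$mat, co$labels, selector_control())
  expect_identical(a1$weights, a2$weights)
})

# ---- information gain -----------------------------------------------------

# brute-force entropy oracle on the binned contingency table
ig_oracle <- function(values, labels, n_bins) {
  bins <- pmin(floor(values * n_bins), n_bins - 1)
  n <- length(values)
  ent <- function(counts) {
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log2(p))
  }
  h_y <- ent(table(labels))
  h_cond <- 0
  for (b in unique(bins)) {
    sel <- bins == b
    h_cond <- h_cond + mean(sel) * ent(table(labels[sel]))
  }
  h_y - h_cond
}

test_that("information gain matches direct entropy enumeration", {
  labels <- rep(c(0L, 1L), each = 4)
  # perfectly separating feature on balanced labels: exactly 1 bit
  mat <- rbind(sep = c(rep(0.1, 4), rep(0.9, 4)),
               const = rep(0.5, 8),
               mixed = c(0.05, 0.45, 0.72, 0.95, 0.12, 0.61, 0.33, 0.88))
  r <- info_gain_rank(mat, labels, selector_control(n_bins = 2))
  expect_equal(unname(r$raw["sep"]), 1)
  expect_equal(unname(r$raw["const"]), 0)
  expect_equal(unname(r$raw["mixed"]),
               ig_oracle(mat["mixed", ], labels, 2))

  # randomized cross-check over bin counts
  for (seed in 1:5) {
    m <- toy_matrix(8, 12, seed = seed)
    lab <- split_labels(12)
    for (nb in c(2, 5, 10)) {
      r <- info_gain_rank(m, lab, selector_control(n_bins = nb))
      expected <- apply(m, 1, ig_oracle, labels = lab, n_bins = nb)
      expect_equal(unname(r$raw), unname(expected), tolerance = 1e-12)
    }
  }
})

test_that("information gain weights mask chance-level loci", {
  co <- separable_cohort(n_loci = 40, n_per_class = 15, n_signal = 2,
                         seed = 20)
  r <- info_gain_rank(co$mat, co$labels)
  expect_true(all(r$weights[co$signal] > 0))
  # pure-noise loci carry positive raw gain but zero ranking weight
  noise <- setdiff(names(r$weights), co$signal)
  expect_gt(mean(r$raw[noise] > 0), 0.5)
  expect_identical(sum(r$weights[noise] > 0), 0L)
})

test_that("information gain is invariant to sample and locus order", {
  m <- toy_matrix(12, 10, seed = 21)
  lab <- split_labels(10)
  r <- info_gain_rank(m, lab)
  sperm <- sample(ncol(m))
  lperm <- sample(nrow(m))
  r2 <- info_gain_rank(m[lperm, sperm], lab[sperm])
  expect_equal(r$weights[rownames(m)[lperm]], r2$weights)
})

# ---- Monte Carlo subspace ranker ------------------------------------------

test_that("Monte Carlo ranker is reproducible and finds a separating locus", {
  co <- separable_cohort(n_loci = 50, n_per_class = 10, n_signal = 1,
                         seed = 30)
  cfg <- selector_control(s_mc = 200)
  r1 <- mc_subspace_rank(co$mat, co$labels, cfg, seed = 99)
  r2 <- mc_subspace_rank(co$mat, co$labels, cfg, seed = 99)
  expect_identical(r1, r2)
  # the perfectly separating locus attains the maximum weight
  expect_equal(unname(r1$weights[co$signal]), 1)
  expect_true(all(r1$weights[setdiff(names(r1$weights), co$signal)] < 1))
})

test_that("Monte Carlo ranker zeroes constant matrices and validates sizes", {
  m <- matrix(0.5, 10, 12,
              dimnames = list(sprintf("cg%02d", 1:10),
                              sprintf("S%02d", 1:12)))
  lab <- split_labels(12)
  r <- mc_subspace_rank(m, lab, selector_control(s_mc = 30), seed = 1)
  expect_true(all(r$weights == 0))
  expect_error(mc_subspace_rank(m, lab, selector_control(m_mc = 11),
                                seed = 1),
               "exceeds")
})

# ---- SVM accuracy ----------------------------------------------------------

test_that("svm accuracy matches direct prediction counting", {
  co <- separable_cohort(n_loci = 6, n_per_class = 10, n_signal = 2,
                         seed = 40)
  acc <- svm_accuracy(co$mat, co$labels, co$mat, co$labels, co$signal)
  expect_equal(acc, 1)
  flipped <- 1L - co$labels
  expect_equal(svm_accuracy(co$mat, co$labels, co$mat, flipped,
                            co$signal), 0)

  # counting oracle on a 20-sample toy with noisy features
  noisy <- toy_matrix(4, 20, seed = 41)
  lab <- split_labels(20)
  fit <- hydml:::svm_fit(noisy, lab, rownames(noisy))
  pred <- hydml:::svm_predict(fit, noisy)
  expect_equal(svm_accuracy(noisy, lab, noisy, lab, rownames(noisy)),
               sum(pred == lab) / 20)

  expect_error(svm_accuracy(co$mat, rep(1L, 20), co$mat, co$labels,
                            co$signal), "both classes")
  expect_error(svm_accuracy(co$mat, co$labels, co$mat, co$labels,
                            character(0)), "empty")
  expect_error(svm_accuracy(co$mat, co$labels, co$mat, co$labels,
                            "nope"), "absent")
})

test_that("selectors rank planted loci above the null on synthetic data", {
  co <- simulate_cohort(n_normal = 30, n_tumor = 30, n_loci = 300,
                        n_dml = 10, effect_size = 0.3, seed = 50)
  null_loci <- setdiff(rownames(co$mat), co$truth$planted)
  for (fn in list(elastic_net_rank, info_gain_rank,
                  function(m, l, cfg) mc_subspace_rank(m, l, cfg, seed = 5))) {
    r <- fn(co$mat, co$labels, selector_control())
    # rank position: weight first, raw selector score breaks ties
    ids <- names(r$weights)
    pos <- stats::setNames(order(order(-r$weights, -r$raw, ids)), ids)
    med_planted <- median(pos[co$truth$planted])
    # the median planted locus outranks 95% of the null loci
    expect_lt(med_planted, unname(quantile(pos[null_loci], 0.05)))
  }
})
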