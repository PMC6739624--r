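#' Simulate a methylation cohort with planted differential loci
#'
#' Emulates the statistical structure of array-style beta-value data:
#' each locus has a baseline mean drawn from a three-mode mixture (low
#' ~0.1, mid ~0.5, high ~0.9 — the characteristic multi-modal beta-value
#' landscape of methylation arrays), both classes sample from a beta
#' distribution with that mean and a common concentration, and a minority
#' of planted loci shift the tumour-class mean by `effect_size` (hyper /
#' hypo directions assigned alternately). Class sizes may be unbalanced
#' and the feature:sample ratio is typically extreme.
#'
#' @param n_normal,n_tumor samples per class.
#' @param n_loci number of loci.
#' @param n_dml number of planted differential loci (`<= n_loci`).
#' @param effect_size difference between tumour and normal class means on
#'   the beta scale, in (0,1); planted means are clipped away from the
#'   boundaries so the full shift is realized.
#' @param concentration beta-distribution concentration (shape1 + shape2);
#'   larger gives tighter per-locus spread.
#' @param missing_rate fraction of entries masked missing, in \[0,1).
#' @param seed RNG seed; the cohort is fully reproducible from it.
#' @param truth optional truth object from a previous call: re-uses its
#'   planted loci, directions and baseline means to draw an independent
#'   cohort from the same ground-truth model (e.g. a test set).
#' @return list of class `methylation_cohort`: `mat` (loci x samples),
#'   `labels` (named 0/1), `truth` (`synthetic_truth`: `planted` ids,
#'   `direction`, `effect_size`, baseline means and the generator
#'   parameters).
#' @export
simulate_cohort <- function(n_normal = 30, n_tumor = 30, n_loci = 2000,
                            n_dml = 50, effect_size = 0.35,
                            concentration = 20, missing_rate = 0,
                            seed = 1, truth = NULL) {
  n_normal <- check_count(n_normal, "n_normal")
  n_tumor <- check_count(n_tumor, "n_tumor")
  n_loci <- check_count(n_loci, "n_loci")
  n_dml <- check_count(n_dml, "n_dml", min = 0L)
  if (n_dml > n_loci) stop_("n_dml cannot exceed n_loci")
  if (n_dml > 0L)
    effect_size <- check_number(effect_size, "effect_size", min = 1e-6,
                                max = 1 - 1e-6)
  concentration <- check_number(concentration, "concentration",
                                min = 1e-6)
  missing_rate <- check_number(missing_rate, "missing_rate", 0,
                               1 - 1e-9)
  loci <- sprintf("cg%08d", seq_len(n_loci))
  samples <- c(sprintf("N%03d", seq_len(n_normal)),
               sprintf("T%03d", seq_len(n_tumor)))
  labels <- stats::setNames(rep(c(0L, 1L), c(n_normal, n_tumor)),
                            samples)
  with_seed(seed, {
    if (is.null(truth)) {
      mode <- sample(c(0.1, 0.5, 0.9), n_loci, replace = TRUE,
                     prob = c(0.4, 0.2, 0.4))
      mu <- pmin(pmax(mode + stats::rnorm(n_loci, 0, 0.04), 0.02), 0.98)
      planted <- if (n_dml > 0L) sort(sample.int(n_loci, n_dml))
                 else integer(0)
      direction <- rep(c("hyper", "hypo"),
                       length.out = length(planted))
      # keep the shifted tumour mean inside (0,1)
      mu[planted] <- ifelse(
        direction == "hyper",
        pmin(mu[planted], 1 - effect_size - 0.02),
        pmax(mu[planted], effect_size + 0.02))
      truth <- structure(list(
        planted = loci[planted],
        direction = stats::setNames(direction, loci[planted]),
        effect_size = stats::setNames(
          rep(effect_size, length(planted)), loci[planted]),
        mu = stats::setNames(mu, loci),
        params = list(n_normal = n_normal, n_tumor = n_tumor,
                      n_loci = n_loci, n_dml = n_dml,
                      effect_size = if (n_dml > 0L) effect_size else NA,
                      concentration = concentration,
                      missing_rate = missing_rate, seed = seed)),
        class = "synthetic_truth")
    } else {
      if (length(truth$mu) != n_loci)
        stop_("supplied truth was generated for %d loci",
              length(truth$mu))
      mu <- unname(truth$mu)
      planted <- match(truth$planted, loci)
      direction <- unname(truth$direction)
    }
    mu_t <- mu
    if (length(planted) > 0) {
      shift <- unname(truth$effect_size)
      mu_t[planted] <- mu[planted] +
        ifelse(direction == "hyper", shift, -shift)
    }
    draw <- function(mu_vec, n) {
      a <- mu_vec * concentration
      b <- (1 - mu_vec) * concentration
      matrix(stats::rbeta(length(mu_vec) * n, a, b), nrow =
               length(mu_vec))
    }
    mat <- cbind(draw(mu, n_normal), draw(mu_t, n_tumor))
    # guard against numerically degenerate draws; values stay in (0,1)
    mat <- pmin(pmax(mat, 1e-6), 1 - 1e-6)
    dimnames(mat) <- list(loci, samples)
    if (missing_rate > 0)
      mat[stats::runif(length(mat)) < missing_rate] <- NA_real_
    structure(list(mat = mat, labels = labels, truth = truth),
              class = "methylation_cohort")
  })
}

#' @export
print.methylation_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic methylation cohort: %d loci x %d samples (%d/%d), %d planted DML\n",
    nrow(x$mat), ncol(x$mat), sum(x$labels == 0L), sum(x$labels == 1L),
    length(x$truth$planted)))
  invisible(x)
}

#' Write a synthetic truth table
#' @param truth a `synthetic_truth`.
#' @param path output TSV.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(
    data.frame(locus_id = truth$planted,
               direction = unname(truth$direction),
               effect_size = unname(truth$effect_size)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate a pan-cancer collection of cohorts
#'
#' Generates `n_cancers` cohorts in which a `shared_dml_frac` fraction of
#' each cohort's planted loci is a common pan-cancer core (same locus
#' ids, same directions in every cancer) and the remainder is
#' cancer-private. The returned truth records which loci should satisfy
#' a pDML occurrence rule.
#'
#' @param n_cancers number of cohorts (>= 2).
#' @param shared_dml_frac fraction of planted loci shared by all
#'   cancers, in \[0,1\].
#' @param n_normal,n_tumor,n_loci,n_dml,effect_size,concentration,missing_rate
#'   per-cancer generator parameters (see [simulate_cohort()]).
#' @param seed master seed.
#' @return list of class `pan_cancer_sim`: `cohorts` (named list of
#'   cohorts), `shared` (locus ids planted in every cancer), `private`
#'   (named list of cancer-private planted ids).
#' @export
simulate_pan_cancer <- function(n_cancers = 13, shared_dml_frac = 0.5,
                                n_normal = 30, n_tumor = 30,
                                n_loci = 2000, n_dml = 50,
                                effect_size = 0.35, concentration = 20,
                                missing_rate = 0, seed = 1) {
  n_cancers <- check_count(n_cancers, "n_cancers", min = 2L)
  shared_dml_frac <- check_number(shared_dml_frac, "shared_dml_frac",
                                  0, 1)
  n_shared <- round(n_dml * shared_dml_frac)
  n_private <- n_dml - n_shared
  if (n_shared + n_cancers * n_private > n_loci)
    stop_(paste0("n_loci (%d) too small for %d shared plus %d disjoint ",
                 "private loci per cancer"),
          n_loci, n_shared, n_private)
  cancer_names <- sprintf("cancer_%02d", seq_len(n_cancers))
  seeds <- derive_seeds(seed, n_cancers + 1L)
  loci <- sprintf("cg%08d", seq_len(n_loci))
  # shared core plus disjoint private blocks: a private locus can never
  # occur in a second cancer, so occurrence counts reflect the design
  plan <- with_seed(seeds[n_cancers + 1L], {
    picks <- sample.int(n_loci, n_shared + n_cancers * n_private)
    list(shared = sort(picks[seq_len(n_shared)]),
         private = split(picks[-seq_len(n_shared)],
                         rep(seq_len(n_cancers), each = n_private)))
  })
  shared_idx <- plan$shared
  shared <- loci[shared_idx]
  shared_dir <- rep(c("hyper", "hypo"), length.out = n_shared)
  cohorts <- list()
  private <- list()
  for (ci in seq_len(n_cancers)) {
    co <- with_seed(seeds[ci], {
      priv_idx <- if (n_private > 0) sort(plan$private[[ci]])
                  else integer(0)
      planted_idx <- sort(c(shared_idx, priv_idx))
      direction <- character(length(planted_idx))
      direction[match(shared_idx, planted_idx)] <- shared_dir
      free <- direction == ""
      direction[free] <- rep(c("hyper", "hypo"), length.out = sum(free))
      mode <- sample(c(0.1, 0.5, 0.9), n_loci, replace = TRUE,
                     prob = c(0.4, 0.2, 0.4))
      mu <- pmin(pmax(mode + stats::rnorm(n_loci, 0, 0.04), 0.02), 0.98)
      mu[planted_idx] <- ifelse(
        direction == "hyper",
        pmin(mu[planted_idx], 1 - effect_size - 0.02),
        pmax(mu[planted_idx], effect_size + 0.02))
      truth <- structure(list(
        planted = loci[planted_idx],
        direction = stats::setNames(direction, loci[planted_idx]),
        effect_size = stats::setNames(
          rep(effect_size, length(planted_idx)), loci[planted_idx]),
        mu = stats::setNames(mu, loci),
        params = list(n_normal = n_normal, n_tumor = n_tumor,
                      n_loci = n_loci, n_dml = n_dml,
                      effect_size = effect_size,
                      concentration = concentration,
                      missing_rate = missing_rate, seed = seeds[ci])),
        class = "synthetic_truth")
      simulate_cohort(n_normal, n_tumor, n_loci, n_dml, effect_size,
                      concentration, missing_rate, seed = seeds[ci],
                      truth = truth)
    })
    cohorts[[cancer_names[ci]]] <- co
    private[[cancer_names[ci]]] <- setdiff(co$truth$planted, shared)
  }
  structure(list(cohorts = cohorts, shared = shared, private = private),
            class = "pan_cancer_sim")
}
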