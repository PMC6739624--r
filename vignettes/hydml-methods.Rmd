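---
title: "Hybrid ensemble selection of differentially methylated loci: models and methods"
author: "hydml"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid ensemble selection of differentially methylated loci: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydml)
```

## The problem

Infinium-style methylation arrays report, for each of ~450,000 CpG loci,
a *beta value* in $[0,1]$ — the fraction of methylated signal at that
locus. Comparing tumour against normal tissue, one wants the loci whose
methylation distinguishes the two classes (differentially methylated
loci, DML). The statistical difficulty is the extreme feature:sample
ratio (order $10^3$ loci per sample): ordinary feature selection on such
data is unstable, and an unstable locus list is of little use to anyone
planning follow-up experiments on it.

`hydml` addresses this with a *hybrid ensemble*: instability is averaged
out over both **instance perturbation** (repeated stratified
cross-validation splits of the samples) and **function diversity**
(three heterogeneous base rankers run on every split), followed by a
bagging consensus that only retains loci recurring across repeated
runs.

## The procedure

Let $D$ be the cohort (loci $\times$ samples, labels $y_i \in \{0,1\}$,
1 = tumour). With defaults $k = 10$ folds, $T = 10$ iterations,
threshold $\tau = 0.01$, bagging minimum $c = 5$:

1. For each iteration $t = 1, \dots, T$: split the samples into $k$
   stratified folds.
2. For each fold: the other $k - 1$ folds form a training split. Each
   base selector $F_i$ produces a nonnegative per-locus weight vector
   $f_i$, max-normalized to $[0,1]$. A linear SVM trained on selector
   $i$'s surviving loci (normalized weight $\ge \tau$) is scored on the
   held-out fold, giving $acc_i$. The fold's aggregated ranking is
   $$f \;=\; \sum_{i=1}^{s} acc_i \, f_i ,$$
   and loci with $f < \tau$ are dropped (the comparison is
   "keep if $\ge \tau$").
3. The iteration's set $F_t$ is the union of the fold sets; each
   locus's weight is the sum of its fold-aggregated weights over the
   folds where it survived (the second-level aggregation
   $f = \sum_i f_i$ over data subsets).
4. The final set $F$ keeps loci appearing in at least $c$ of the $T$
   iteration sets; its weight is the mean over the iterations
   containing it.

Every stochastic step draws its seed deterministically from the master
seed, so a run is exactly reproducible and two runs with the same seed
write byte-identical outputs.

On the threshold comparison and the bagging count, the procedure's two
textual sources disagree in small ways ("less than five" versus "more
than five"); the package follows the more precise pseudocode reading —
drop $f < \tau$, keep count $\ge c$ — and both $\tau$ and $c$ are
configurable for users who prefer the stricter variant.

## The three base rankers

**Elastic net** (`elastic_net_rank`). The penalized least-squares
objective is used exactly as printed, on standardized features with 0/1
labels and an unpenalized intercept:
$$\arg\min_w \Big\{ \sum_i (y_i - b_0 - w^\top x_i)^2 +
\lambda\big[\alpha \|w\|_1 + (1-\alpha)\|w\|_2^2\big] \Big\}.$$
The fit is delegated to `glmnet`; because glmnet scales its loss by
$1/(2m)$ and halves its ridge term internally, the package maps
$\lambda_{\text{glmnet}} = \lambda / (2m)$ with $\alpha$ unchanged — a
mapping verified numerically against direct optimization of the printed
objective, and against the ridge closed form
$(X^\top X + \lambda I)^{-1} X^\top y_c$ in the tests. A squared-error
loss on binary labels is unusual but deliberate (it is the objective as
printed); a logistic variant is available via
`selector_control(en_family = "binomial")`. With `lambda = "auto"`
(default), $\lambda$ is chosen by internal 5-fold cross-validation on
the training split only, with the one-standard-error rule; the CV folds
are derived from the configuration seed so the ranking is
deterministic. Default $\alpha = 0.5$. The ranking weight is $|w_j|$,
max-normalized; zero-variance loci are standardized to zero and can
never attract weight.

**Information gain** (`info_gain_rank`). Each locus is discretized into
`n_bins = 10` equal-width bins on $[0,1]$ (beta values are naturally
bounded, so the bin edges are data-independent and reproducible), and
scored by $IG = H(\text{class}) - H(\text{class} \mid \text{bin})$ in
bits, with $0 \log 0 = 0$. The plug-in estimator of $IG$ is biased
upward in finite samples — with ~54 training samples a completely
uninformative locus still scores ~0.04–0.12 bits, i.e. 5–15% of the
maximum after normalization. Left uncorrected this defeats the
$\tau = 0.01$ filter entirely (every locus passes every fold).
The package therefore applies the standard G-test of independence
($G = 2N \ln 2 \cdot IG \sim \chi^2$ with
$(\text{occupied bins}-1)(\text{classes}-1)$ degrees of freedom) and
zeroes gains that are not significant at `ig_sig = 0.05` after
Bonferroni correction across loci — the same information-theoretic
significance filtering the IG-based selection tools in this field
perform. The raw gain is kept alongside the masked weights and is used
to break ties when a ranking is truncated to a fixed signature size.

**Monte Carlo random subspaces** (`mc_subspace_rank`). `s_mc = 300`
random subspaces of $m_{mc} = \min(p, 5\lceil\sqrt{p}\rceil)$ loci are
drawn; in each, `t_mc = 1` CART trees (gini impurity, depth limit 2,
minimum node size 5) are grown on bootstrap resamples, so
interdependencies between loci inside a subspace can be exploited by
the tree. Each locus accumulates (out-of-bag balanced accuracy of the
tree) $\times$ (its share of the tree's impurity decrease), and its
relative importance is the accumulated score divided by the number of
subspaces containing it. Because the importance scale is relative, the
"luckiest" uninformative loci in a 60-sample cohort score consistently
across subspaces and folds; the only null that reproduces this
within-cohort consistency is label permutation. The scorer is therefore
re-run once with permuted labels on the same subspaces, and importances
are kept only in excess of the `mc_null_quantile = 0.999` quantile of
the permuted run (permutation-calibrated cutoffs are also how the
Monte-Carlo feature-selection tools in this field set their
significance threshold). This makes the ranker deliberately
conservative: it contributes high-confidence loci and leaves moderate
effects to the other two selectors. The trees are implemented in
compiled code (`src/mc_tree.cpp`) because a run visits on the order of
$3 \times 10^4$ subspace-trees and per-call overhead of a generic tree
package would dominate the runtime; all randomness is drawn from R's
RNG so `set.seed` governs reproducibility bitwise.

**Fold classifier.** `svm_accuracy` trains a linear-kernel soft-margin
SVM (`e1071`, cost 1, features standardized by training-split
statistics) and reports held-out accuracy. Class weighting is off by
default — class imbalance is handled only by stratification, matching
the method's description — and can be enabled with
`selector_control(svm_class_weights = TRUE)`. If a selector's surviving
set is empty its accuracy is defined as 0, so it contributes nothing to
the aggregation of that fold.

## Stability and performance measures

Selection stability over $k$ signatures is the mean pairwise Jaccard
similarity
$$S_{tot} = \frac{2}{k(k-1)} \sum_{i<j} \frac{|f_i \cap f_j|}{|f_i \cup f_j|}.$$
Two empty signatures count as identical (similarity 1), empty versus
non-empty as 0 — chosen so that identical pipelines always score 1.
`stability_experiment` perturbs the cohort by stratified 90%
subsampling without replacement (mirroring the 10-fold flavour of the
method's own instance perturbation; the exact perturbation scheme
behind the original robustness figures is not documented, so this is
the package's own choice), ranks loci on each subsample, truncates to a
signature size, and reports $S_{tot}$ together with the held-out AUC of
an SVM per signature.

Classification metrics are the usual confusion-matrix suite (positive
class = tumour; 0/0 ratios defined as 0). AUC is computed exactly as
the Mann–Whitney pair-counting probability with ties counted half —
unambiguous, oracle-checkable, and invariant under monotone score
transformations; the tests cross-check it against trapezoidal ROC
integration on tie-free instances.

## Pan-cancer consensus

`pdml_select` keeps loci occurring in at least `min_cancers` of the
per-cancer DML sets (inclusive bound, default 10 — "no less than 10 in
13 cancers"). Direction is called from class medians:
hyper(-methylated) when median(tumour) − median(normal) exceeds a
margin `delta` (default 0), hypo when below −`delta`. Region annotation
assigns each locus exactly one of promoter / gene body / intergenic,
with the promoter the strand-aware window from 2,000 bp upstream of the
TSS to the TSS, inclusive at both ends, taking precedence over gene
body ("gene body excluding promoter"); the source only says
"upstream", so strand awareness is this package's reading, and a locus
inside any gene's promoter window is promoter regardless of other
overlapping genes. Cross-cancer similarity clustering uses
average-linkage agglomeration on $1 -$ Jaccard (the linkage behind the
original clustering is unstated; average linkage — UPGMA — is the
conventional choice for similarity matrices of this kind), with sets
ordered lexicographically for deterministic tie-breaking, and a Newick
serialization for interoperability.

## The synthetic cohort generator

`simulate_cohort` emulates the features of array data the method
actually relies on:

* per-locus baseline means drawn from a three-mode mixture (low ≈ 0.1,
  mid ≈ 0.5, high ≈ 0.9 with probabilities 0.4/0.2/0.4) — the
  characteristic multi-modal beta-value landscape;
* beta-distributed values with a common `concentration = 20`
  (mean-concentration parameterization; at concentration 20 a
  mid-methylated locus has standard deviation ≈ 0.11, a realistic
  array-level spread);
* a minority of planted loci whose tumour-class mean is shifted by
  `effect_size` (default 0.35), hyper/hypo assigned alternately for
  balance, baselines clipped so the full shift stays inside $(0,1)$;
* optional missingness (`missing_rate`), unbalanced class sizes, and
  feature:sample ratios of order $10^3$.

It does **not** simulate probe-type chemistry, genomic spatial
correlation between neighbouring CpGs, batch effects (off by default;
batch correction is out of scope and expected upstream), or realistic
effect-size heterogeneity — planted effects share one magnitude.
Passing tests therefore demonstrate correctness of the machinery and
calibrated behaviour under the generator's assumptions, not performance
on real arrays. `simulate_pan_cancer` plants a shared core of DML
(identical ids and directions in every cancer) plus per-cancer private
blocks that are disjoint across cancers, so pan-cancer occurrence
counts reflect the design exactly.

## Numerical choices and degenerate inputs

* Missing beta values: loci with more than 20% missing entries are
  dropped; the rest are imputed with the class-agnostic per-locus
  median (the original preprocessing is silent on missingness; the
  selectors require complete matrices, and class-agnostic imputation
  cannot leak labels).
* Variance filtering is computed from unbiased sample variance over
  non-missing entries, never touches labels, breaks ties
  lexicographically by locus id, and is idempotent. No default cutoff
  is claimed to match the original preprocessing (its rule is
  unstated); `top_k` is the default mode.
* Fold assignment: per class, shuffled indices are dealt into folds
  whose sizes differ by at most one, remainders going to the currently
  lightest folds; a class with fewer samples than folds is an error.
* All-zero weight vectors stay all-zero under max-normalization; an
  empty fold survivor set or an empty final set is a warning, not an
  error.
* glmnet is run with `thresh = 1e-14` for fixed-$\lambda$ fits so the
  ridge-limit matches its closed form to $10^{-6}$.
* Ties in tree splits resolve to the first-scanned feature; subspace
  draws, bootstrap draws and the label permutation all come from R's
  RNG inside one seeded block.

## Problem sizes used in tests and the acceptance script

The packaged experiments run on generator defaults (30 + 30 samples,
2,000 loci, 50 planted DML at effect 0.35) for recovery and null
calibration; the stability comparison uses 5 subsamples per replicate,
10 replicates, signature size 50 and 5-fold ensembles; the pan-cancer
experiment uses 13 cohorts of 20 + 20 samples and 400 loci with a
5-iteration/5-fold/consensus-3 configuration. These sizes were chosen
as the smallest at which the statistical claims are comfortably
measurable; all scale linearly if users want larger studies.

## Known limitations

* The squared-loss elastic net on 0/1 labels is a linear probability
  model; its coefficient magnitudes are a ranking device, not effect
  estimates.
* The permutation-calibrated Monte Carlo ranker trades sensitivity for
  specificity; on weak effects it abstains and the ensemble leans on
  the other two selectors.
* Probe-type normalization and batch correction are out of scope — the
  pipeline accepts normalized input and exposes only a pass-through
  hook (`preprocess_beta(normalize_hook = )`).
* With very small cohorts (fewer than ~5 samples per class per fold)
  the held-out accuracies $acc_i$ are coarse (steps of $1/|$fold$|$),
  which adds variance to the aggregation exactly as it would in the
  original procedure.
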