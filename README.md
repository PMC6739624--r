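# hydml — hybrid ensemble selection of robust differentially methylated loci

`hydml` identifies differentially methylated loci (DML) from array-style
DNA-methylation beta-value matrices (loci × samples, values in [0, 1])
with tumour/normal labels. The regime it targets is the hard one:
hundreds of thousands of CpG loci against a few dozen samples
(feature:sample ratios of order 10³), where single feature-selection
methods return locus lists that barely reproduce between runs — and a
non-reproducible locus list is useless as a biomarker candidate set.

## The method

The package combines two sources of ensemble diversity:

* **Instance perturbation** — the cohort is split into *k* = 10
  stratified folds, *T* = 10 times with fresh splits;
* **Function diversity** — on every training split, three heterogeneous
  base rankers score all loci: an elastic-net linear model
  (arg min<sub>w</sub> { Σ<sub>i</sub> (y<sub>i</sub> − w<sup>T</sup>x<sub>i</sub>)² +
  λ[α‖w‖₁ + (1−α)‖w‖₂²] }), an information-gain ranker on binned beta
  values (IG = H(class) − H(class | bin), with a G-test mask for
  finite-sample chance gain), and a Monte Carlo random-subspace
  decision-tree ranker with a label-permutation-calibrated cutoff.

Per fold, the rankings **f**<sub>i</sub> (max-normalized to [0, 1]) are
aggregated with the held-out accuracy of an SVM trained on each
selector's own surviving loci:

&nbsp;&nbsp;&nbsp;&nbsp;**f** = Σ<sub>i</sub> acc<sub>i</sub> · **f**<sub>i</sub>

Loci with aggregated weight below τ = 0.01 are dropped, the fold sets
are unioned per iteration (weights summed over the folds where a locus
survived), and the final DML set **F** keeps loci appearing in at least
*c* = 5 of the 10 iteration sets (bagging consensus). Selection
stability is quantified as the mean pairwise Jaccard similarity of
signatures, S<sub>tot</sub> = 2 Σ<sub>i&lt;j</sub> S(f<sub>i</sub>, f<sub>j</sub>) / (k(k−1)).

Pan-cancer utilities select consensus loci occurring in ≥ 10 of 13
per-cancer DML sets (pDML), call hyper/hypo direction from class
medians, annotate promoter (2 kb upstream of TSS, strand-aware) /
gene-body / intergenic categories, compute per-chromosome DML density,
and cluster cancers by Jaccard similarity of their DML sets. A
synthetic-cohort generator with planted effects makes every stage
testable without any data download.

## A worked example

```r
library(hydml)

# a cohort with known ground truth: 30 normal + 30 tumour samples,
# 2,000 loci, 50 planted DML shifted by 0.35 on the beta scale
cohort <- simulate_cohort(n_normal = 30, n_tumor = 30, n_loci = 2000,
                          n_dml = 50, effect_size = 0.35, seed = 101)
fit <- hydml(cohort$mat, cohort$labels, control = hydml_control(seed = 1))
fit
#> Hybrid ensemble DML selection
#>   2000 loci x 60 samples (30 normal / 30 tumour)
#>   10 iterations x 10 folds, selectors: elastic_net, info_gain, mc_subspace, tau = 0.01, bag_min = 5
#>   final DML set: 51 loci

mean(cohort$truth$planted %in% fit$dml$loci)   # recovery of planted DML
#> [1] 1
mean(!fit$dml$loci %in% cohort$truth$planted)  # contamination of F
#> [1] 0.01960784
```

The fit object carries per-fold selector accuracies (`fit$accuracy`,
also `plot(fit)`), the per-iteration sets, and consensus weights
(`coef(fit)`); `predict(fit, newdata)` classifies new samples with a
linear SVM on the selected loci, and `summary(fit)` prints the top
consensus loci. Direction calls and an occurrence-count breakdown:

```r
table(direction_call(cohort$mat, cohort$labels, fit$dml$loci))
#> hyper  hypo
#>    26    25
```

File-based pipelines (`run_dml_pipeline`, `run_stability`,
`run_pancancer`, `run_evaluate`) write TSV/BED/YAML artifacts and a
reproducibility manifest; `inst/cli/hydml.R` exposes them as
`simulate` / `run` / `stability` / `pancancer` / `evaluate`
subcommands.

## Scope

Probe-type (SWAN-style) normalization and batch correction are
deliberately out of scope: the pipeline accepts normalized input and
provides only a pass-through hook. SNP-overlapping loci are flagged and
carried through to the outputs, never silently dropped — downstream
stringency is the user's decision. See the methods vignette
(`vignettes/hydml-methods.Rmd`) for the model details, parameter
meanings, design rationale and known limitations.
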