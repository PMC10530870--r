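---
title: "Ensemble feature selection by rank aggregation and weighted voting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble feature selection by rank aggregation and weighted voting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efsvote)
```

## The model

`efsvote` addresses classification of expression tables where genes far
outnumber samples and most genes are uninformative. Its premise is that a
gene repeatedly chosen by *different kinds* of selectors — a variance
filter, a redundancy filter, an embedded linear model, a wrapper, and a
projection method — is more trustworthy than a gene any single method
favours. The aggregation statistic is deliberately crude: the rank

$$R_i = \#\{\, s : \text{selector } s \text{ chose gene } i \,\},
\qquad R_i \in \{0, \dots, 5\},$$

thresholded into nested consensus subsets
$E_k = \{ i : R_i \ge t_k \}$ with strictly increasing $t_1 < t_2 < t_3$.
No selector-specific scores are blended, so no cross-method score
calibration is needed; ties within a rank level keep original column order
rather than inventing a sub-ranking.

Classification is a weighted hard vote over an RBF-kernel SVM, KNN
($k = 3$) and a depth-2 decision tree. Each member's validation accuracy is
ranked and the members get integer weights 3, 2, 1 from best to worst (ties
broken by the fixed declaration order svm, knn, dt). A sample's predicted
class maximises the summed weights of the members voting for it; a tied
class goes to the vote of the heaviest member among the tied classes, then
to the lowest class index. Every rule here is deterministic by
construction: identical data, configuration and seed reproduce reports byte
for byte.

## Data flow and leakage

The pipeline order is clean → encode → split → scale → select → classify.
Scaling parameters and all five selectors see **only the training split**;
the test split is touched exactly once, for the reported metrics. This is
the methodologically sound default, but feature selection before splitting
is common in the applied literature, so `select_on_all = TRUE` (CLI
`--select-on-all`) reproduces that ordering — the two can differ
noticeably at these sample sizes, which is the point of keeping both.

The same concern drives the weighting policy. Weighting members by their
accuracy *on the final test set* leaks test information into the ensemble;
the default policy is therefore stratified 5-fold cross-validation on the
training split (`"cv"`), with `"holdout"` (a carved-out quarter of the
training data) and `"test_leaky"` available, the latter named for what it
does and retained only to replicate published workflows.

The train fraction is `floor(ratio * n)`: with the 70:30 default this
reproduces the canonical benchmark splits 72 → 50/22, 62 → 43/19 and
174 → 121/53 exactly, which is the reason this rounding rule (and not
`round` or `ceiling`) is used. Splits are stratified by default because
class imbalance in multi-tumour panels is severe (minority classes of a few
samples); plain random splitting remains available.

## Parameters and defaults

| parameter | default | meaning and rationale |
|---|---|---|
| `scaling` | `minmax` | per-gene map to [0, 1]; bounded range keeps the variance threshold interpretable; constant genes map to 0 |
| `variance_t` | 0.1 | minimum population variance (divisor *n*) on scaled data; on min-max data this is strict — near the theoretical maximum of 0.25 — so it often selects few or no genes and the pipeline must (and does) tolerate empty selections |
| `pearson_cutoff` | 0.9 | drop the later of two genes with \|r\| above the cutoff; 0.6 is the common choice for many-class panels |
| `ridge_alpha` | 0.3 | L2 penalty weight in `RSS + α·Σβ²`; selection keeps \|β\| ≥ mean \|β\|, a central threshold since ridge never zeroes coefficients |
| `rfe_n_keep` | `ceiling(p/2)` | target gene count; published per-dataset choices range from ~44% to ~77% of p, so half is the neutral default |
| `rfe_step` | 1 if p ≤ 200 else 10% | genes dropped per elimination round |
| `pca_k`, `pca_m` | 0.95, 1 | components to reach 95% variance; top-`m` absolute loadings per component become gene identifiers |
| `ensemble_thresholds` | (2, 3, 4) | "at least two / three / four of five selectors"; the laxer (1, 2, 3) variant — where E1 is the plain union — is one configuration away |
| `weight_policy` | `cv` | see above |

Numerical choices worth noting: the ridge solve implements the stated
objective exactly (primal `(XᵀX + αI)⁻¹Xᵀy` when p ≤ n, the equivalent dual
`Xᵀ(XXᵀ + αI)⁻¹y` when p > n, intercept handled by centring), with a
relative tolerance of 1e−8 on the mean-threshold comparison so that exactly
tied coefficients (duplicated genes) fall consistently on the "keep" side.
Zero-variance genes are defined to have correlation 0 with everything.
KNN prediction is implemented in-package with deterministic tie-breaks
(distance ties by training-sample order, vote ties by lowest class index);
a randomized tie-break would break the byte-identical-reports guarantee.
The decision tree (rpart, `maxdepth = 2`, `minsplit = 2`, `minbucket = 1`,
`cp = 0`) is deterministic, so the `dt_seed` parameter exists only for
interface symmetry. RFE uses a linear-kernel SVM because margin weights per
feature only exist for the linear kernel; multiclass RFE ranks by the sum
of squared one-vs-rest weights.

Because the voter is a *hard* voter it emits no probabilities; the ROC is
drawn from normalized vote shares (member weight fraction per class), which
take at most `total weight + 1` distinct values. Base classifiers are
scored with one-hot indicators of their hard predictions, so their AUROCs
are coarse by construction; the macro average is one-vs-rest over the
classes present in the truth, with absent classes excluded and flagged.
Precision and recall with empty denominators are defined as 0 and flagged
in the report rather than propagating NaN.

## What the synthetic generator emulates — and what it does not

`synth_spec()`/`generate_dataset()` produce the structure the method is
designed for: tens–hundreds of samples, thousands of genes, 2–11 classes, a
small informative block whose class-conditional means step by
`effect × noise_sd` per class index, optional redundant genes built as
`ρ·source + √(1−ρ²)·noise`, and a dominant majority of pure Gaussian noise
genes. Every base selector has predictable behaviour under this model,
which is what makes the tests interpretable: ridge and RFE should find the
mean-shifted genes, the redundancy filter should drop correlated copies
(laid out after their sources, so the keep-the-earlier rule keeps the
source), and PCA's leading components should align with the class
structure.

Real expression data are harsher in ways the generator does not imitate:
heavy-tailed and skewed intensities, gene–gene correlation blocks not tied
to class labels, batch effects, and label noise. Passing the synthetic
recovery study therefore shows the machinery is sound and the consensus
beats chance under a Gaussian shift model — not that any particular
accuracy will transfer to a given real dataset.

Generator defaults (100 samples, 1000 genes, 20 informative, effect 3,
uniform classes) are the study conditions for the acceptance analyses: the
10-seed recovery comparison against a size-matched random subset and the
voter-vs-worst-base comparison both run at this size, roughly a minute of
CPU. Test fixtures elsewhere use smaller instances (tens of samples,
hundreds of genes) purely to keep the suite brisk.

## Known limitations

* With min-max scaling and the default `variance_t = 0.1`, the variance
  selector frequently selects nothing; the rank aggregation then
  effectively runs on four selectors. This mirrors how strict published
  variance thresholds behave on rescaled data; lower `variance_t` (or
  z-score scaling with a threshold near 1) to make it contribute.
* The Pearson filter is O(p²) in memory for the correlation matrix;
  at p ≳ 20,000 use the relevance mode or pre-filter by variance first.
* Weights are a permutation of {1, 2, 3}: the voter can never fully
  out-vote two agreeing members, so it inherits mistakes the majority
  shares — visible on the smallest (E3) subsets where individual
  classifiers diverge most.
* `test_leaky` weighting and `select_on_all` exist for reproducing
  published numbers; neither should be used for honest evaluation.
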