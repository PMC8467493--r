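---
title: "Marker genes and classification rules from labeled single-cell expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker genes and classification rules from labeled single-cell expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scMarkerRules)
```

## The problem

Annotated single-cell RNA-seq atlases assign every cell a class tag — here a
tissue-by-cell-type combination such as "tumor-lung epithelial cells" — and
report expression as normalized log2(TPM+1). Two questions follow naturally:
which genes carry the information that separates the classes (qualitative
biomarkers), and what quantitative thresholds on those genes discriminate one
class from another (classification rules)? scMarkerRules answers both with a
fixed chain of standard machine-learning components, each exposed as its own
function and orchestrated by `marker_pipeline()`.

The chain is:

1. **Class-size filter.** Classes with no more than `min_cells` members
   (strictly `> min_cells` survive; default 100 in the file-based runner) are
   removed, since rare classes cannot support stable cross-validation.
2. **Shadow-attribute (Boruta) selection** — all-relevant filtering.
3. **mRMR ranking** of the confirmed genes by mutual information.
4. **Incremental feature selection (IFS)** over nested prefixes of the
   ranking, scored by SMOTE-balanced stratified 10-fold cross-validation of a
   CART tree and a random forest, using the multi-class Matthews correlation
   coefficient (MCC).
5. **Rule extraction** from a fully grown tree on the CART-optimum genes,
   plus per-class **exclusive genes**.
6. Optional **over-representation analysis** of the random-forest-optimum
   genes against user-supplied gene sets.

## The components and their assumptions

### Shadow-attribute selection

Each iteration copies every gene still in play into a permuted "shadow"
column, fits a random forest (impurity importance, 100 trees by default) on
originals plus shadows, and credits a *hit* to every gene whose importance
exceeds the best shadow. Hit counts are tested against Binomial(n, 1/2): a
two-sided binomial test at `alpha = 0.05`, Bonferroni-corrected over the
currently undecided genes, confirms genes significantly above the fair-coin
null and rejects those significantly below, removing them from later
forests. The classical stopping phrase "repeat until every attribute is
confirmed" cannot terminate on noise attributes, so the iteration budget
(`max_iter = 100`) is the real stopping rule and whatever is still undecided
is reported `tentative`. Only `important` genes continue downstream; with
the default budget a gene with zero hits is rejected after roughly a dozen
iterations, so the loop usually ends long before the budget.

### mRMR ranking

Mutual information is estimated by the plug-in formula over empirical
contingency tables, in bits, after the three-state discretization
`value < mean − sd → −1`, `value > mean + sd → +1`, else `0` — the default
scheme of the classical mRMR program for continuous inputs. Ranking is
greedy forward selection under the difference (MID) criterion: the first
gene maximizes MI(gene, label); each later pick maximizes
MI(gene, label) − mean MI(gene, selected). The mean-over-selected form is
the standard greedy surrogate of the set-level objective (relevance minus
1/|S|² pairwise redundancy); the two give identical greedy picks. Ties are
broken by input gene order. Log base 2 is presentational: ranking is
base-invariant.

### SMOTE

Class balance is restored by interpolation: a synthetic cell is
`c = a + r (b − a)` with `r ~ U(0, 1)`, `a` a random minority cell, `b` one
of its `k = 5` (the conventional default) nearest same-class neighbors by
Euclidean distance on the feature set in use. Every class is raised to the
majority-class count. Because interpolation is convex, synthetic cells
inherit non-negativity and stay inside their parents' coordinate-wise
bounding box; the object records parent identities so tests can check this
directly.

**Where balancing happens matters.** The default (`smote_policy =
"within"`) oversamples *inside each training fold only*. Balancing the whole
dataset before splitting (`"before"`) puts near-duplicates of test cells
into training folds: on pure-noise data (planted effect size 0) the default
policy yields an optimum MCC near 0, while pre-balancing yields MCC above
0.9 — an entirely spurious signal. The `"before"` mode is kept only for
fidelity with workflows that balance first; the package's tests assert the
hazard explicitly.

### Cross-validation and the multi-class MCC

Folds are stratified (class proportions preserved): with dozens of classes
and minority sizes in the low hundreds, unstratified folds can lose classes
entirely. Held-out predictions are pooled into a single confusion over all
folds and summarized once — matching the convention of reporting one MCC
per classifier — rather than averaging per-fold scores. The multi-class MCC
is the R_K statistic: with X and Y the one-hot indicator matrices of
predictions and truth, MCC = cov(X, Y) / sqrt(cov(X, X) cov(Y, Y)) with
column-centered covariances. It is 1 exactly at perfect prediction, −1 for
the binary complement, near 0 for label-independent predictions, and
reduces to the classical binary MCC at K = 2; the degenerate all-one-class
case (zero variance) is defined as 0, mirroring the binary convention.

### Incremental feature selection

Prefixes of the ranking grow in steps of 10 (plus a final prefix with all
genes when the total is not a multiple of 10); each prefix is evaluated
independently with a seed derived from its size, so the curve does not
depend on evaluation order and subsets could be evaluated in parallel
without changing results. The optimum is the maximal-MCC row, ties going to
the smaller gene count. CART uses Gini splits without a complexity penalty;
the random forest uses 100 Gini trees with sqrt-mtry sampling. Both are
pinned in the run manifest because "default parameters" differ across
library versions.

### Rules and exclusive genes

The interpretable output comes from one CART tree grown to purity (no
complexity penalty, minimum node size 1, depth capped at 30 by the tree
implementation) on the original — unbalanced — cells restricted to the
CART-optimum genes; training on balanced data is available but synthetic
interpolated cells would then appear as rule support. Each leaf yields one
rule: the root-to-leaf conjunction of threshold conditions (`<=` left,
`>` right), the leaf's majority class, its support and purity. The rules of
one tree partition the training cells exactly — every cell satisfies
exactly one rule and supports sum to N — which the tests verify by direct
evaluation.

A gene is *exclusive* to a class when it occurs in at least one rule
predicting that class and in none predicting another (occurrence is by
gene, not by condition direction). One structural caveat deserves emphasis:
in a tree whose leaves are all pure, every split node is label-mixed, so
its descendant leaves cover at least two classes and every split gene
occurs in rules of at least two classes — the exclusive-gene report of a
single purity-grown tree is therefore empty, provably. Non-empty reports
arise only when leaves are impure (depth cap reached, duplicate feature
vectors with conflicting labels — both common at atlas scale, where a
180,000-cell tree has tens of thousands of leaves) or when rule sets are
filtered or pooled before counting. The package implements the definition
faithfully, asserts the structural emptiness on purity-grown trees as a
property test, and leaves exclusivity analysis meaningful for large or
depth-limited trees and for externally supplied rule lists.

### Over-representation analysis

A plain one-sided hypergeometric upper-tail test per gene set
(`P(X >= k)`), with the universe an explicit required argument — there is
no defensible default universe, and the choice (all genes vs. all
selection-eligible genes) materially changes p-values. The significance
threshold defaults to raw p < 0.001; Benjamini–Hochberg adjustment is
optional. Gene-set hierarchies (the GO DAG, decorrelation algorithms) are
out of scope; gene sets arrive as GMT files.

## The synthetic generator

`synthetic_config()` / `simulate_cells()` produce the ground-truth datasets
the tests rely on. Baseline expression is Normal(1, `noise_sd`) truncated
at zero on the log2(TPM+1) scale; markers gain `effect_size` (default 2
log2 units) in their class; `dropout_rate` zeroes entries independently
after the shift. Defaults encode the study conditions used throughout the
tests: 3 classes of sizes 200/50/50 (imbalanced, as real atlases are), 100
noise genes, 5 private markers per class, noise sd 0.5, dropout 0. Dropout
defaults to 0 so that the planted in-class minus out-of-class mean equals
`effect_size` exactly in expectation (with dropout d it converges to
`effect_size * (1 − d)`, which the tests verify at d = 0.3). Gene names
encode their role (`noise_0001`, `mk_A_01`, `pv_B_03`) so recovery can be
asserted without carrying the truth object around.

What the generator does *not* emulate: library-size variation, batch
effects, count noise (negative binomial), gene–gene correlation beyond the
planted shifts, or trajectory structure. Passing tests therefore show the
pipeline recovers planted mean-shift structure under realistic imbalance
and sparsity — not that it handles every pathology of real single-cell
data.

## Problem sizes and numerical choices

The test suite and examples run the full chain on datasets of roughly
130–300 cells and 40–115 genes with 3–4 classes — large enough that Boruta,
mRMR, IFS and rule extraction all exercise their real code paths and the
planted markers are recovered essentially perfectly, small enough that the
whole suite completes in about a minute. Determinism is taken seriously:
every stochastic stage takes a seed, stage seeds derive from one global
seed by name hashing so stages can be rerun in isolation, forests run
single-threaded, and rerunning any stage with the same inputs is asserted
byte-identical. Ties are broken deterministically everywhere (input order
for mRMR and argmax picks, cell order for neighbor ties). The mRMR MID
criterion can tie exactly between candidates on discrete data; which gene
wins then depends on floating-point summation order, which is why the test
oracle accepts any pick attaining the maximal criterion within 1e-12.

## Limitations

- Boruta confirmation depends on random-forest importance; genes informative
  only through interactions invisible to 100-tree forests on small samples
  may stay tentative.
- The discretization (mean ± sd) discards within-band variation; genes whose
  signal is sub-threshold shift rank lower than a continuous estimator would
  place them.
- Exclusive genes from a single purity-grown tree are structurally empty
  (see above); the report is informative only for impure or pooled trees.
- The file-based runner re-reads artifacts on resume; evaluation records of
  per-class accuracy are restored from the written tables, not recomputed.
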