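---
title: "Predicting multiple antigen epitopes by meta-classifier integration and spatial clustering"
author: "epimeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting multiple antigen epitopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimeta)
```

## The problem

Antibodies bind antigens at epitopes. About 90% of known epitopes are
conformational: their residues are close in the folded 3D structure but
discontinuous in sequence, so they can only be identified in the context
of the whole antigen structure. Experimental mapping (crystallography,
NMR, cryo-EM of antibody-antigen complexes) is slow and costly, and a
single antigen frequently carries several distinct epitopes targeted by
different antibodies, of which experiments typically reveal only one.

`epimeta` addresses partner-independent, multi-epitope prediction: given
only the unbound antigen structure and per-residue interface-likelihood
scores from several base classifiers, it produces a consensus per-residue
epitope score, calls an antigen-specific number of epitopal residues, and
partitions them into spatially distinct putative epitopes.

## The model

### Meta-integration

Base interface predictors (feature-based, template-based and docking-based
methods each exploit different structural signals) emit a per-residue
likelihood $P \in [0,1]$. Each one fails on some antigens; integrating
them recovers the best signal per case. The integration model is a
gradient-boosted ensemble of decision trees over the normalised score
columns, fit to the binary epitope label with logistic loss. Because no
boosted-tree package is available in the target environment, the learner
is implemented in the package (`R/gbt.R`): second-order boosting, exact
greedy splits, leaf weights $-G/(H+\lambda)$, and a split accepted only
when its loss reduction exceeds the pruning parameter $\alpha$. Training
uses no row or column subsampling, so a fixed configuration is
bit-for-bit reproducible; the recorded seed only drives the inner tuning
folds.

Scores are min-max normalised per antigen and per classifier
(`normalize_scores()`), because base classifiers' score scales drift
between queries; global normalisation is available as an option. Missing
classifier scores are imputed as 0, read as "no interface evidence".
Class imbalance (epitopes are a small minority of residues) is handled by
weighting positives with the training-fold negative/positive ratio.

Defaults: 200 trees, learning rate 0.1, depth 3, $\alpha = 0$,
$\lambda = 1$. With `tune = TRUE` depth and $\alpha$ are selected over
$\{3,4,5\} \times \{0, 0.5, 1\}$ by antigen-wise inner cross-validation
maximising ROC-AUC. The mention that per-classifier cutoff values could
also be optimised is left unresolved in the source method description;
this package uses the raw normalised scores as features.

### Dynamic threshold

The number of residues called epitopal adapts to the antigen surface:

$$N = \mathrm{round}(6.1 \cdot R^{0.3})$$

where $R$ is the number of surface-exposed residues. Surface exposure is
computed by Shrake-Rupley rolling-probe accessibility (probe 1.4 Å, 92
lattice points per atom), normalised by the Tien theoretical maximum ASA
per residue type, with RSA ≥ 5% defining "surface". The 5% convention and
the rounding mode (nearest) are not pinned by the method description;
both are exposed as arguments (`rsa_threshold`, `rounding`). For a
protein with $R \approx 96$ the threshold is 24, and the formula is
monotone in $R$, so more exposed surface always admits more calls.

### Multi-epitope partitioning

The $N$ called residues are clustered by agglomerative hierarchical
clustering with Ward linkage on Euclidean distances between residue
geometric centers (the unweighted mean over all heavy atoms — the least
arbitrary reading of "geometric center"; Cα-only is a coarser
alternative). The cluster count is chosen by the dendrogram maximum-gap
rule: for each candidate $k$, the gap is the vertical distance a
horizontal line cutting $k$ branches can travel without crossing a merge,
$\mathrm{gap}(k) = h_{n-k+1} - h_{n-k}$; the selected $k$ maximises the
gap. Ties break toward smaller $k$ (parsimony); $k = 1$ is not a
candidate because the rule requires a cut below the final merge — a known
limitation: one spatially spread-out epitope may be split in two.
`k_max` defaults to 8; observed optima on real antigens are 2 or 3.

## Ground-truth machinery

`extract_epitope()` annotates an antigen residue as epitopal when any of
its heavy atoms lies within 4.0 Å of any antibody heavy atom. This is
the distance component of contact-analysis annotation only; contact-type
legitimacy classification is out of scope, and hydrogen- or
water-mediated contacts are not counted. `transfer_annotation()` maps
annotations from bound complexes onto unbound structures through global
pairwise alignment (BLOSUM62, gap open 11 / extend 1), refusing pairs
under 95% identity and dropping positions that align to gaps.
`epitope_overlap()` reports the percentage of identical residues between
two epitopes; the denominator is not fixed by convention, so the
Jaccard-style union is the default with the min-set-size variant as an
option (the 0% and 100% endpoints are invariant to the choice).
`redundancy_filter()` is a greedy longest-first clustering at a 30%
identity cutoff, standing in for an unspecified clustering procedure;
`complex_filter()` applies the resolution (< 3 Å, strict) and antigen
size (100-450 residues inclusive, or > 60 for the bound-set variant)
curation windows.

## Evaluation conventions

- Confusion counts are taken over the full residue set of the antigen by
  default; restricting the universe to surface residues is supported,
  since the published convention is ambiguous.
- $F1 = 2TP/(2TP+FP+FN)$ and MCC both return 0 on a zero denominator.
- ROC-AUC is Mann-Whitney concordance with mean-rank tie handling;
  PR-AUC uses step-wise integration (no trapezoid), avoiding optimistic
  bias at low prevalence.
- %TP at rank $k$ is pooled: summed TPs inside each antigen's top-$k$,
  divided by the total annotated residues over the test set.
- Per-cluster F1 treats each putative epitope in turn as the entire
  predicted set — the quantity that improves when a spatially distinct
  novel epitope is separated from the experimentally annotated one.
- Kolmogorov-Smirnov one- and two-sample comparisons flag significance
  at $p < 0.05$.
- Reported averages are unweighted means over antigens.

## Fold construction

`make_folds()` builds one test set plus three training sets, stratified
by antigen-size tertile: within each tertile, group quotas are
proportional to group targets (largest-remainder rounding capped by
remaining capacity), so every group's tertile composition is within one
antigen of proportional. Group sizes default to as-equal-as-possible;
`test_size` is an explicit argument because the published 111-antigen
split (29 test + 28/27/27 training) is not an equal split and its
test-set size is therefore treated as an input, not derivable from a
rule.

## The synthetic world

`make_synthetic_antigen()` emulates exactly the statistical structure the
method assumes, and nothing more: residues are single pseudo-atoms along
a self-avoiding 3.8 Å random walk (a Cα-like trace); each epitope patch
is a spatially contiguous ball of residues; classifier tracks are
`clip(base + sensitivity * [covered] + N(0, noise_sd), 0, 1)`.

Stated defaults, chosen once: antigen sizes uniform in 100-450 residues
(the curation window); 2 patches for ~90% of antigens, 3 otherwise
(matching the observed prevalence of two- vs three-epitope calls); patch
size 14 (reported epitope sizes span 6-29 residues with mean 15); patch
centroid separation ≥ 25 Å (spatially distinct by construction); three
classifiers with sensitivity 0.6, noise SD 0.12, baseline 0.15; each
classifier sees each patch with probability 0.7 (every patch seen by at
least one), which is what makes the tracks complementary and all three
necessary — the synthetic analogue of the observation that dropping any
one base classifier hurts the integrated model.

What the generator does *not* emulate: real backbone geometry and side
chains, sequence realism, correlated classifier errors, antigen-specific
difficulty, or conformational change on binding. A green synthetic test
therefore establishes that the pipeline's machinery is correct and that
integration helps when tracks carry complementary signal; it does not
establish real-data accuracy figures. Fixture residues are treated as
fully surface-exposed ($R = n$) unless a surface profile is computed
explicitly.

## Numerical choices and degenerate inputs

- Top-$N$ boundary ties break by residue (file) order — deterministic.
- Constant score columns normalise to all-zeros with a warning.
- Ward clustering of a single residue returns a degenerate one-cluster
  call; collinear geometry executes without error.
- Unknown residue types fall back to a generic 200 Å² maximum ASA with a
  warning; alternate locations keep the first conformer; only the first
  NMR model is read.
- Parsing keeps author numbering and insertion codes; residue identity is
  the triple (chain, seqnum, icode) throughout.

## Known limitations

- The SASA routine is $O(\text{atoms}^2)$ per structure; adequate for
  antigens in the 100-450 residue window, not for very large complexes.
- Annotation transfer is sequence-global; domain rearrangements between
  bound and unbound forms would need local alignment.
- The gap rule never returns $k = 1$, so single-epitope antigens are
  always split at least in two; per-cluster evaluation absorbs this.
- Base classifiers themselves are inputs: the package emulates their
  statistical behaviour but does not reimplement them.
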