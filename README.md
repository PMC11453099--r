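# epimeta

Partner-independent prediction of **multiple conformational B-cell
epitopes** on antigen 3D structures.

Most epitopes are conformational — spatially compact in the folded
antigen but discontinuous in sequence — and a single antigen often
carries several of them, while experiments usually characterise only one
antibody complex. `epimeta` is for structural immunologists and method
developers who have an unbound antigen structure plus per-residue
interface-likelihood scores from several base predictors and want (a) a
consensus per-residue epitope score, (b) an antigen-specific set of
called epitopal residues, and (c) that set partitioned into spatially
distinct putative epitopes, including ones with no experimental evidence
yet.

## Method

1. **Meta-integration.** Base classifiers emit per-residue interface
   likelihoods *P* ∈ [0,1]. After per-antigen min–max normalisation, a
   gradient-boosted tree ensemble (logistic loss, second-order boosting;
   implemented in the package) is trained on labelled antigens to produce
   a consensus score per residue. Tunable: tree depth, pruning parameter
   α, 200 trees, learning rate 0.1, positive-class weighting by the
   training imbalance ratio.
2. **Dynamic threshold.** The number of residues called epitopal is
   *N* = round(6.1 · *R*^0.3), where *R* is the count of surface-exposed
   residues (Shrake–Rupley RSA ≥ 5%, probe 1.4 Å).
3. **Multi-epitope partitioning.** The *N* top-scoring residues are
   clustered by Ward-linkage agglomerative clustering on Euclidean
   distances between residue geometric centers; the cluster count *k*
   maximises the dendrogram gap — the vertical distance a horizontal cut
   through *k* branches can travel without crossing a merge,
   gap(*k*) = *h*(*n*−*k*+1) − *h*(*n*−*k*).

Ground-truth tooling (4.0 Å heavy-atom contact annotation from
antibody–antigen complexes, alignment-based transfer to unbound
structures, redundancy and resolution/size curation filters), a full
evaluation suite (F1, MCC, ROC-AUC, PR-AUC, pooled %TP at fixed ranks,
per-cluster F1, KS tests) and a synthetic antigen generator with planted
epitope patches are included, so the whole pipeline runs and is tested
fully offline.

## Worked example

```r
library(epimeta)

# 8 synthetic antigens with planted epitope patches and 3 score tracks
bench <- make_benchmark_set(n_antigens = 8, size_range = c(100, 300), seed = 11)
tab   <- normalize_scores(bench$table)
folds <- make_folds(bench$sizes, n_folds = 3, seed = 11)
model <- fit_meta(tab[tab$antigen_id %in% unlist(folds$training), ])
print(model)
#> meta_model: boosted trees over 3 base classifiers
#>   features: sppider_like, ispred_like, dockpred_like
#>   config: 200 trees, depth 3, alpha 0, eta 0.1
#>   trained on 6 antigens / 1287 residues (182 epitopal)

# score a held-out antigen and call its epitopes
id   <- folds$test[1]
ag   <- bench$antigens[[id]]
sc   <- predict(model, tab[tab$antigen_id == id, ])
call <- call_epitopes(ag$structure, nrow(ag$structure$residues), sc)
print(call)
#> epitope_call: ag005
#>   R = 212 surface residues -> dynamic threshold N = 30
#>   2 putative epitope(s); sizes: 15, 15
```

The antigen has 212 (pseudo-)surface residues, so the dynamic threshold
calls N = 30 residues, and the gap rule splits them into k = 2 putative
epitopes of 15 residues each. Scoring each cluster against the planted
patches (each cluster treated in turn as the full predicted set):

```r
uni <- paste(ag$structure$residues$chain, ag$structure$residues$seqnum,
             ag$structure$residues$icode, sep = "|")
for (p in seq_along(ag$patches)) {
  pk <- paste(ag$patches[[p]]$chain, ag$patches[[p]]$seqnum,
              ag$patches[[p]]$icode, sep = "|")
  cat(sprintf("planted patch %d: best-matching cluster F1 = %.2f\n",
              p, max(cluster_level_f1(call, pk, uni))))
}
#> planted patch 1: best-matching cluster F1 = 0.97
#> planted patch 2: best-matching cluster F1 = 0.97
```

Each of the two planted epitopes is recovered almost exactly by one of
the two called clusters — the multi-epitope behaviour the package exists
for.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end benchmark from scratch: it generates
a 24-antigen synthetic corpus, builds size-stratified training folds,
trains the meta-model, compares the consensus ROC-AUC on held-out
antigens against every individual score track, calls multi-epitope
predictions per test antigen and prints the evaluation report
(mean F1/MCC, ROC/PR-AUC, pooled %TP at ranks 10–50, cluster counts),
then writes its JSON output to `--out`. All randomness derives from
`--seed`.

## Documentation

`vignettes/multi-epitope-prediction.Rmd` describes the model and its
assumptions, every tunable parameter with units and defaults, what the
synthetic generator does and does not emulate, numerical conventions and
known limitations.
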