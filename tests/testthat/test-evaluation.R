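test_that("confusion counts follow the set definitions", {
  uni <- paste0("r", 1:50)
  pred <- uni[1:10]; ann <- uni[6:20]
  cm <- confusion(pred, ann, uni)
  expect_equal(unclass(cm), c(TP = 5, FP = 5, FN = 10, TN = 30))
  expect_equal(sum(cm), 50)

  same <- confusion(pred, pred, uni)
  expect_equal(unname(same[c("FP", "FN")]), c(0, 0))
  disj <- confusion(uni[1:5], uni[40:45], uni)
  expect_equal(unname(disj["TP"]), 0)
  expect_error(confusion(c(pred, "zz"), ann, uni), "universe")
})

test_that("f1_score reproduces hand-computed fractions", {
  expect_equal(f1_score(TP = 7, FP = 4, FN = 33), 14 / 51)
  expect_equal(f1_score(TP = 10, FP = 3, FN = 30), 20 / 53)
  expect_equal(f1_score(TP = 0, FP = 8, FN = 0), 0)
  expect_equal(f1_score(TP = 0, FP = 0, FN = 0), 0)  # zero-denominator
  uni <- paste0("r", 1:30)
  expect_equal(f1_score(confusion(uni[1:10], uni[1:10], uni)), 1)
})

test_that("mcc_score matches the Pearson-correlation identity", {
  expect_equal(mcc_score(TP = 10, FP = 0, FN = 0, TN = 10), 1)
  expect_equal(mcc_score(TP = 5, FP = 5, FN = 5, TN = 5), 0)
  expect_equal(mcc_score(TP = 0, FP = 0, FN = 3, TN = 7), 0)  # degenerate

  set.seed(3)
  for (rep in 1:50) {
    pred <- rbinom(200, 1, runif(1, 0.1, 0.9))
    lab <- rbinom(200, 1, runif(1, 0.1, 0.9))
    cm <- c(TP = sum(pred & lab), FP = sum(pred & !lab),
            FN = sum(!pred & lab), TN = sum(!pred & !lab))
    r <- suppressWarnings(cor(pred, lab))
    expect_equal(mcc_score(cm), if (is.na(r)) 0 else r, tolerance = 1e-12)
  }
})

test_that("roc_auc matches the all-pairs concordance oracle", {
  expect_equal(roc_auc(1:10, c(rep(0, 5), rep(1, 5))), 1)
  expect_equal(roc_auc(10:1, c(rep(0, 5), rep(1, 5))), 0)
  set.seed(7)
  for (rep in 1:20) {
    scores <- sample(seq(0, 1, by = 0.05), 50, replace = TRUE)  # with ties
    labels <- rbinom(50, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels), auc_pairs_oracle(scores, labels))
    # complement identity for tie-free scores
    s2 <- runif(50)
    expect_equal(roc_auc(s2, labels) + roc_auc(-s2, labels), 1)
  }
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("pr_auc integrates stepwise precision-recall", {
  # perfect ranking: PR-AUC 1
  expect_equal(pr_auc(1:10, c(rep(0, 5), rep(1, 5))), 1)
  # a single positive ranked worst: precision 1/n at recall 1
  expect_equal(pr_auc(10:1, c(rep(0, 9), 1)), 0.1)
  # chance level approximates prevalence
  set.seed(15)
  s <- runif(4000); y <- rbinom(4000, 1, 0.2)
  expect_lt(abs(pr_auc(s, y) - mean(y)), 0.05)
})

test_that("percent_tp_at_k pools hits over the test set", {
  # two antigens: annotations of 4 and 6; 2 and 3 hits inside the top 10
  rank1 <- c(paste0("a", 1:2), paste0("x", 1:18))
  ann1 <- c(paste0("a", 1:2), paste0("m", 1:2))
  rank2 <- c(paste0("b", 1:3), paste0("y", 1:17))
  ann2 <- c(paste0("b", 1:3), paste0("n", 1:3))
  expect_equal(percent_tp_at_k(list(rank1, rank2), list(ann1, ann2), 10), 50)

  # all annotated residues inside every top-k: 100%
  expect_equal(percent_tp_at_k(list(ann1, ann2), list(ann1, ann2), 10), 100)
  # no hits: 0%
  expect_equal(percent_tp_at_k(list(paste0("z", 1:10)), list(ann1), 5), 0)
  # non-decreasing in k
  ptp <- vapply(c(2, 5, 10, 20),
                function(k) percent_tp_at_k(list(rank1, rank2),
                                            list(ann1, ann2), k),
                numeric(1))
  expect_true(all(diff(ptp) >= 0))
})

test_that("ks_compare wraps one- and two-sample tests with a 0.05 flag", {
  x <- seq(0.01, 0.99, length.out = 40)
  same <- ks_compare(x, x)
  expect_equal(same$D, 0)
  expect_equal(same$kind, "two-sample")
  expect_false(same$significant)

  disjoint <- ks_compare(seq(0, 1, length.out = 30),
                         seq(10, 11, length.out = 30))
  expect_equal(disjoint$D, 1)
  expect_true(disjoint$significant)

  one <- ks_compare(rnorm(25), "pnorm")
  expect_equal(one$kind, "one-sample")
  expect_error(ks_compare(numeric(0), x), "empty")
})

test_that("cluster-level F1 treats each cluster as the predicted set", {
  uni <- paste0("r", 1:100)
  ann <- uni[1:14]
  # a cluster of 11 with 4 true positives against 14 annotated: 8/25
  cl1 <- c(uni[1:4], uni[50:56])
  cl2 <- uni[70:80]          # disjoint from the annotation
  f1s <- cluster_level_f1(list(cl1, cl2), ann, uni)
  expect_equal(f1s, c(8 / 25, 0))
  expect_equal(cluster_level_f1(list(ann), ann, uni), 1)
})

test_that("evaluate_predictions assembles a coherent report", {
  bench <- make_benchmark_set(n_antigens = 4, size_range = c(100, 160),
                              seed = 11)
  tab <- normalize_scores(bench$table)
  model <- fit_meta(tab, config = meta_config(n_trees = 60))
  calls <- list(); anns <- list(); unis <- list()
  for (id in names(bench$antigens)) {
    ag <- bench$antigens[[id]]
    sub <- tab[tab$antigen_id == id, , drop = FALSE]
    sc <- predict(model, sub)
    calls[[id]] <- with_call_keys(
      call_epitopes(ag$structure, nrow(ag$structure$residues), sc),
      ag$structure)
    anns[[id]] <- ag$annotation
    unis[[id]] <- res_keys(ag$structure$residues)
  }
  rep_ <- evaluate_predictions(calls, anns, unis)
  expect_s3_class(rep_, "evaluation_report")
  expect_equal(nrow(rep_$per_antigen), 4)
  expect_true(all(rep_$per_antigen$F1 >= 0 & rep_$per_antigen$F1 <= 1))
  expect_true(all(rep_$per_antigen$MCC >= -1 & rep_$per_antigen$MCC <= 1))
  expect_true(all(diff(rep_$percent_tp) >= 0))
  # confusion rows account for every residue of each antigen
  tots <- rowSums(rep_$per_antigen[, c("TP", "FP", "FN", "TN")])
  expect_equal(tots, lengths(unis)[rep_$per_antigen$antigen_id],
               ignore_attr = TRUE)
})
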