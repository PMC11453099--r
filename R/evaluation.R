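# Per-residue binary-classification evaluation: confusion counts, F1,
# MCC, ROC-AUC, PR-AUC, pooled %TP at fixed ranks, per-cluster F1 and
# Kolmogorov-Smirnov comparisons.

#' Confusion counts of a predicted residue set against an annotation
#'
#' @param predicted,annotated Character vectors of residue keys (or any
#'   comparable identifiers), both subsets of `universe`.
#' @param universe All evaluated residues (e.g. every residue of the
#'   antigen, or only the surface residues).
#' @return A `confusion` object: named integer vector TP, FP, FN, TN.
#' @export
confusion <- function(predicted, annotated, universe) {
  predicted <- unique(predicted); annotated <- unique(annotated)
  universe <- unique(universe)
  if (!all(predicted %in% universe)) stop("predicted set not in universe")
  if (!all(annotated %in% universe)) stop("annotated set not in universe")
  tp <- length(intersect(predicted, annotated))
  counts <- c(TP = tp,
              FP = length(predicted) - tp,
              FN = length(annotated) - tp,
              TN = length(universe) - length(union(predicted, annotated)))
  class(counts) <- "confusion"
  counts
}

#' @export
print.confusion <- function(x, ...) {
  cat(sprintf("confusion: TP=%d FP=%d FN=%d TN=%d\n",
              x["TP"], x["FP"], x["FN"], x["TN"]))
  invisible(x)
}

as_counts <- function(counts, TP, FP, FN, TN) {
  if (!missing(counts) && !is.null(counts)) {
    return(c(TP = unname(counts["TP"]), FP = unname(counts["FP"]),
             FN = unname(counts["FN"]), TN = unname(counts["TN"])))
  }
  c(TP = TP, FP = FP, FN = FN, TN = TN)
}

#' F1 score from confusion counts
#'
#' F1 = 2TP / (2TP + FP + FN); defined as 0 when the denominator is 0.
#'
#' @param counts A `confusion` object, or leave missing and supply counts.
#' @param TP,FP,FN,TN Individual counts (TN unused by F1).
#' @return F1 in [0, 1].
#' @examples
#' f1_score(TP = 7, FP = 4, FN = 33)   # 14/51 = 0.27 (2 d.p.)
#' @export
f1_score <- function(counts = NULL, TP = 0, FP = 0, FN = 0, TN = 0) {
  k <- as_counts(counts, TP, FP, FN, TN)
  den <- 2 * k["TP"] + k["FP"] + k["FN"]
  if (den == 0) return(0)
  unname(2 * k["TP"] / den)
}

#' Matthews correlation coefficient from confusion counts
#'
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)); defined as
#' 0 when any factor of the denominator is 0.  Equals the Pearson
#' correlation of the binary prediction and label vectors.
#'
#' @inheritParams f1_score
#' @return MCC in [-1, 1].
#' @export
mcc_score <- function(counts = NULL, TP = 0, FP = 0, FN = 0, TN = 0) {
  k <- as.numeric(as_counts(counts, TP, FP, FN, TN))
  den <- (k[1] + k[2]) * (k[1] + k[3]) * (k[4] + k[2]) * (k[4] + k[3])
  if (den == 0) return(0)
  (k[1] * k[4] - k[2] * k[3]) / sqrt(den)
}

#' Area under the ROC curve
#'
#' Mann-Whitney concordance with tie correction (equivalent to
#' trapezoidal integration of the ROC curve).
#'
#' @param scores Numeric scores, higher = more likely positive.
#' @param labels Binary labels (0/1 or logical).
#' @return ROC-AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)  # mean ranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise integration: thresholds descend through the distinct scores,
#' and each recall increment contributes at the precision reached at that
#' threshold (no trapezoid interpolation, avoiding optimistic bias).
#'
#' @inheritParams roc_auc
#' @return PR-AUC in [0, 1].
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  if (n1 == 0 || all(labels == 1)) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  last <- c(diff(s) != 0, TRUE)   # block ends of tied scores
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Pooled percentage of true positives within the top k ranks
#'
#' Over a test set: TPs within each antigen's k top-ranked residues are
#' summed and divided by the total number of annotated residues, x100.
#'
#' @param rankings List (one element per antigen) of residue keys in
#'   descending score order.
#' @param annotations List (same antigens) of annotated residue keys.
#' @param k Rank cutoff (>= 1).
#' @return Percentage in [0, 100].
#' @export
percent_tp_at_k <- function(rankings, annotations, k) {
  stopifnot(length(rankings) == length(annotations), k >= 1)
  tp <- sum(mapply(function(rk, ann) {
    length(intersect(utils::head(rk, k), ann))
  }, rankings, annotations))
  total <- sum(lengths(annotations))
  if (total == 0) stop("no annotated residues")
  100 * tp / total
}

#' Kolmogorov-Smirnov comparison of score distributions
#'
#' Two-sample when `y` is numeric; one-sample against a reference
#' cumulative distribution function when `y` is a function or a
#' distribution name (e.g. `"pnorm"`).  Significance is flagged at
#' p < 0.05.
#'
#' @param x Numeric sample.
#' @param y Second sample, or reference CDF for the one-sample test.
#' @param ... Passed to the reference CDF (one-sample case).
#' @return A `ks_result`: list with `D`, `p_value`, `kind`, `significant`.
#' @export
ks_compare <- function(x, y, ...) {
  if (length(x) == 0) stop("empty sample")
  two <- is.numeric(y)
  if (two && length(y) == 0) stop("empty sample")
  ht <- suppressWarnings(stats::ks.test(x, y, ...))
  structure(list(D = unname(ht$statistic), p_value = ht$p.value,
                 kind = if (two) "two-sample" else "one-sample",
                 significant = ht$p.value < 0.05),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("%s KS test: D = %.4f, p = %.4g%s\n", x$kind, x$D, x$p_value,
              if (x$significant) " (significant at 0.05)" else ""))
  invisible(x)
}

#' Per-cluster F1 against an annotation
#'
#' Each putative epitope cluster is treated in turn as the full predicted
#' positive set; one predicted cluster typically matches the (single)
#' experimentally annotated epitope while the others are novel calls.
#'
#' @param clusters List of residue-key character vectors (or an
#'   `epitope_call`, whose clusters are keyed automatically).
#' @param annotated Annotated residue keys.
#' @param universe All evaluated residue keys.
#' @return Numeric vector: F1 per cluster.
#' @export
cluster_level_f1 <- function(clusters, annotated, universe) {
  if (inherits(clusters, "epitope_call"))
    clusters <- lapply(clusters$clusters, residue_keys)
  vapply(clusters, function(cl) {
    f1_score(confusion(cl, annotated, universe))
  }, numeric(1))
}

#' Evaluate predictions over a set of antigens
#'
#' For each antigen: confusion of the called top-N set against the
#' annotation, F1, MCC, score-based ROC-AUC and PR-AUC, and per-cluster
#' F1; plus unweighted means and pooled %TP at ranks 10..50.
#'
#' @param calls Named list of `epitope_call` objects.
#' @param annotations Named list (same antigens) of `epitope_annotation`
#'   objects or residue-key vectors.
#' @param universes Named list of residue-key vectors defining the
#'   evaluation universe per antigen (all residues, or surface only).
#' @param ks_at Ranks for the pooled %TP curve (default c(10,20,30,40,50)).
#' @return An `evaluation_report`: list with `per_antigen` (data.frame),
#'   `means`, `percent_tp` and `per_cluster_f1`.
#' @export
evaluate_predictions <- function(calls, annotations, universes,
                                 ks_at = c(10, 20, 30, 40, 50)) {
  ids <- names(calls)
  stopifnot(!is.null(ids), setequal(ids, names(annotations)),
            setequal(ids, names(universes)))
  ann_keys <- lapply(annotations, function(a) {
    if (is.data.frame(a)) residue_keys(a) else a
  })

  rows <- lapply(ids, function(id) {
    call <- calls[[id]]
    uni <- universes[[id]]
    ann <- ann_keys[[id]]
    pred <- residue_keys(call$top)
    cm <- confusion(pred, ann, uni)
    lab <- uni %in% ann
    sc <- call$scores[match(uni, residue_keys_of_call(call))]
    data.frame(antigen_id = id, N = call$N, k = call$k,
               TP = cm["TP"], FP = cm["FP"], FN = cm["FN"], TN = cm["TN"],
               F1 = f1_score(cm), MCC = mcc_score(cm),
               ROC_AUC = roc_auc(sc, lab), PR_AUC = pr_auc(sc, lab),
               best_cluster_F1 = max(cluster_level_f1(call, ann, uni)),
               row.names = NULL)
  })
  per_antigen <- do.call(rbind, rows)

  rankings <- lapply(calls, function(call) {
    keys <- residue_keys_of_call(call)
    keys[order(-call$scores, seq_along(call$scores))]
  })
  ptp <- vapply(ks_at, function(k) {
    percent_tp_at_k(rankings, ann_keys, k)
  }, numeric(1))
  names(ptp) <- paste0("top", ks_at)

  structure(list(
    per_antigen = per_antigen,
    means = colMeans(per_antigen[, c("F1", "MCC", "ROC_AUC", "PR_AUC",
                                     "best_cluster_F1")]),
    percent_tp = ptp,
    per_cluster_f1 = lapply(ids, function(id) {
      cluster_level_f1(calls[[id]], ann_keys[[id]], universes[[id]])
    })
  ), class = "evaluation_report")
}

# residue keys of the full scored residue set of a call; calls made by
# call_epitopes() carry scores in structure order, so the caller supplies
# the structure-derived universe in that same order.
residue_keys_of_call <- function(call) {
  attr(call, "universe_keys") %||% stop(
    "call lacks residue keys; attach them with call_keys<- or evaluate ",
    "against the originating structure")
}

#' Attach the scored residues' keys to an epitope call
#'
#' `evaluate_predictions()` needs to know which residue each score row
#' refers to; calls built straight from a structure get the keys attached
#' here.
#'
#' @param call An `epitope_call`.
#' @param structure The `antigen_structure` the call was made on.
#' @return The call with a `universe_keys` attribute.
#' @export
with_call_keys <- function(call, structure) {
  attr(call, "universe_keys") <- residue_keys(structure$residues)
  call
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report over", nrow(x$per_antigen), "antigens\n")
  cat(sprintf("  mean F1 %.3f | mean MCC %.3f | mean ROC-AUC %.3f | mean PR-AUC %.3f\n",
              x$means["F1"], x$means["MCC"], x$means["ROC_AUC"],
              x$means["PR_AUC"]))
  cat("  pooled %TP:",
      paste(sprintf("%s %.1f%%", names(x$percent_tp), x$percent_tp),
            collapse = ", "), "\n")
  invisible(x)
}
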