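# Meta-classifier: gradient-boosted tree integration of base-classifier
# interface likelihood scores into consensus per-residue epitope scores.

#' Meta-model configuration
#'
#' @param max_depth Maximum tree depth (default 3).
#' @param alpha Pruning parameter: minimum split loss reduction
#'   (default 0).
#' @param n_trees Number of boosting rounds (default 200).
#' @param learning_rate Shrinkage per round (default 0.1).
#' @param lambda L2 regularisation on leaf weights (default 1).
#' @param seed Integer seed recorded with the model (training itself is
#'   deterministic — no subsampling — so the seed only matters for the
#'   inner tuning folds).
#' @return A `meta_config` list.
#' @export
meta_config <- function(max_depth = 3, alpha = 0, n_trees = 200,
                        learning_rate = 0.1, lambda = 1, seed = 42) {
  stopifnot(max_depth >= 1, alpha >= 0, n_trees >= 1, learning_rate > 0)
  structure(list(max_depth = max_depth, alpha = alpha, n_trees = n_trees,
                 learning_rate = learning_rate, lambda = lambda, seed = seed),
            class = "meta_config")
}

#' Fit the epitope meta-classifier
#'
#' Trains a gradient-boosted tree ensemble on normalised base-classifier
#' score columns against per-residue epitope labels.  Class imbalance is
#' handled by weighting positives with (#negative / #positive) computed on
#' the training data.  With `tune = TRUE`, `max_depth` and `alpha` are
#' selected by an inner grid search (antigen-wise cross-validation
#' maximising ROC-AUC) over `depth_grid` x `alpha_grid`.
#'
#' @param table A `score_table` containing a logical/binary `label`
#'   column; rows from several antigens may be stacked (column
#'   `antigen_id` distinguishes them).
#' @param classifiers Feature columns to use (default: all classifier
#'   columns of the table).
#' @param config A [meta_config()].
#' @param tune Run the inner hyperparameter grid search (default FALSE).
#' @param depth_grid,alpha_grid Grids for tuning (defaults {3,4,5} and
#'   {0, 0.5, 1}).
#' @param inner_folds Number of inner CV folds when tuning (default 3).
#' @return A `meta_model` with methods [predict.meta_model()],
#'   `print`, `summary` and `plot` (feature importance).
#' @export
fit_meta <- function(table, classifiers = NULL, config = meta_config(),
                     tune = FALSE, depth_grid = c(3, 4, 5),
                     alpha_grid = c(0, 0.5, 1), inner_folds = 3) {
  if (is.null(table$label)) stop("score table carries no 'label' column")
  classifiers <- classifiers %||% score_classifiers(table)
  X <- as.matrix(table[, classifiers, drop = FALSE])
  y <- as.integer(table$label)
  if (length(unique(y)) < 2) stop("labels contain a single class")

  spw <- sum(y == 0) / sum(y == 1)
  w <- ifelse(y == 1, spw, 1)

  tuning <- NULL
  if (tune) {
    grid <- expand.grid(max_depth = depth_grid, alpha = alpha_grid)
    antigens <- unique(table$antigen_id)
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()))
    set.seed(config$seed)
    fold_of <- sample(rep_len(seq_len(inner_folds), length(antigens)))
    names(fold_of) <- antigens
    grid$auc <- vapply(seq_len(nrow(grid)), function(i) {
      aucs <- vapply(seq_len(inner_folds), function(k) {
        hold <- fold_of[table$antigen_id] == k
        if (length(unique(y[hold])) < 2 || length(unique(y[!hold])) < 2)
          return(NA_real_)
        fit <- gbt_fit(X[!hold, , drop = FALSE], y[!hold], w[!hold],
                       n_trees = config$n_trees,
                       learning_rate = config$learning_rate,
                       max_depth = grid$max_depth[i], alpha = grid$alpha[i],
                       lambda = config$lambda)
        roc_auc(gbt_predict(fit, X[hold, , drop = FALSE]), y[hold])
      }, numeric(1))
      mean(aucs, na.rm = TRUE)
    }, numeric(1))
    best <- which.max(grid$auc)
    config$max_depth <- grid$max_depth[best]
    config$alpha <- grid$alpha[best]
    tuning <- grid
  }

  fit <- gbt_fit(X, y, w, n_trees = config$n_trees,
                 learning_rate = config$learning_rate,
                 max_depth = config$max_depth, alpha = config$alpha,
                 lambda = config$lambda)

  structure(list(
    fit = fit,
    features = classifiers,
    config = config,
    scale_pos_weight = spw,
    tuning = tuning,
    training = list(antigens = unique(table$antigen_id),
                    n_residues = length(y), n_positive = sum(y))
  ), class = "meta_model")
}

#' Consensus scores from a fitted meta-model
#'
#' @param object A `meta_model`.
#' @param newdata A `score_table` (or data.frame) holding the model's
#'   feature columns.
#' @param ... Ignored.
#' @return Numeric vector of consensus epitope scores in [0, 1], one per
#'   row of `newdata`; deterministic.
#' @export
predict.meta_model <- function(object, newdata, ...) {
  missing <- setdiff(object$features, names(newdata))
  if (length(missing) > 0)
    stop("newdata lacks feature column(s): ", paste(missing, collapse = ", "))
  gbt_predict(object$fit,
              as.matrix(newdata[, object$features, drop = FALSE]))
}

#' @export
print.meta_model <- function(x, ...) {
  cat("meta_model: boosted trees over",
      length(x$features), "base classifiers\n")
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  cat(sprintf("  config: %d trees, depth %d, alpha %.2g, eta %.2g\n",
              x$config$n_trees, x$config$max_depth, x$config$alpha,
              x$config$learning_rate))
  cat(sprintf("  trained on %d antigens / %d residues (%d epitopal)\n",
              length(x$training$antigens), x$training$n_residues,
              x$training$n_positive))
  invisible(x)
}

#' @export
summary.meta_model <- function(object, ...) {
  imp <- gbt_importance(object$fit, object$features)
  out <- list(model = object,
              importance = sort(imp, decreasing = TRUE),
              tuning = object$tuning)
  class(out) <- "summary.meta_model"
  out
}

#' @export
print.summary.meta_model <- function(x, ...) {
  print(x$model)
  cat("  feature importance (total split gain):\n")
  imp <- x$importance / max(sum(x$importance), .Machine$double.eps)
  for (f in names(imp)) cat(sprintf("    %-12s %6.1f%%\n", f, 100 * imp[f]))
  if (!is.null(x$tuning)) {
    cat("  tuning grid (inner-CV ROC-AUC):\n")
    print(x$tuning, row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.meta_model <- function(x, ...) {
  imp <- gbt_importance(x$fit, x$features)
  graphics::barplot(sort(imp), horiz = TRUE, las = 1,
                    xlab = "total split gain",
                    main = "meta-model feature importance", ...)
  invisible(x)
}
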