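# Gradient-boosted decision trees for binary classification.
#
# Second-order boosting with logistic loss: each tree is fit to the
# gradient/hessian statistics of the current margin by exact greedy
# splitting; leaf weight = -G / (H + lambda), split gain
#   0.5 * (GL^2/(HL+lambda) + GR^2/(HR+lambda) - G^2/(H+lambda))
# and a split is kept only when the gain exceeds the pruning parameter
# `alpha` (minimum loss reduction).  Deterministic: no row or column
# subsampling, so a fixed configuration reproduces bit-for-bit.

sigmoid <- function(x) 1 / (1 + exp(-x))

# Recursively grow one regression tree on (g, h) statistics.
# Returns nested list nodes: leaf  = list(leaf = weight)
#                            split = list(feature, threshold, left, right, gain)
grow_tree <- function(X, g, h, idx, depth, max_depth, alpha, lambda,
                      min_child_weight) {
  G <- sum(g[idx]); H <- sum(h[idx])
  leaf <- function() list(leaf = -G / (H + lambda))
  if (depth >= max_depth || length(idx) < 2) return(leaf())

  parent_score <- G^2 / (H + lambda)
  best <- list(gain = 0)
  for (f in seq_len(ncol(X))) {
    x <- X[idx, f]
    o <- order(x)
    xs <- x[o]
    gs <- cumsum(g[idx][o])
    hs <- cumsum(h[idx][o])
    # candidate cuts between distinct consecutive values
    cut <- which(diff(xs) > 0)
    if (length(cut) == 0) next
    GL <- gs[cut]; HL <- hs[cut]
    GR <- G - GL;  HR <- H - HL
    ok <- HL >= min_child_weight & HR >= min_child_weight
    if (!any(ok)) next
    gain <- 0.5 * (GL^2 / (HL + lambda) + GR^2 / (HR + lambda) - parent_score)
    gain[!ok] <- -Inf
    b <- which.max(gain)
    if (gain[b] > best$gain) {
      best <- list(gain = gain[b], feature = f,
                   threshold = (xs[cut[b]] + xs[cut[b] + 1]) / 2)
    }
  }
  if (best$gain <= alpha) return(leaf())

  go_left <- X[idx, best$feature] <= best$threshold
  list(feature = best$feature, threshold = best$threshold, gain = best$gain,
       left = grow_tree(X, g, h, idx[go_left], depth + 1, max_depth,
                        alpha, lambda, min_child_weight),
       right = grow_tree(X, g, h, idx[!go_left], depth + 1, max_depth,
                         alpha, lambda, min_child_weight))
}

# vectorised evaluation of one tree over a data matrix
eval_tree <- function(node, X, idx = seq_len(nrow(X))) {
  out <- numeric(nrow(X))
  rec <- function(node, idx) {
    if (length(idx) == 0) return()
    if (!is.null(node$leaf)) {
      out[idx] <<- node$leaf
      return()
    }
    go_left <- X[idx, node$feature] <= node$threshold
    rec(node$left, idx[go_left])
    rec(node$right, idx[!go_left])
  }
  rec(node, idx)
  out
}

#' Fit a gradient-boosted tree ensemble (internal engine)
#'
#' @param X Numeric feature matrix.
#' @param y Binary labels (0/1).
#' @param weights Per-row observation weights (e.g. positive-class
#'   upweighting on imbalanced data).
#' @param n_trees,learning_rate,max_depth Boosting schedule.
#' @param alpha Minimum split loss reduction (pruning parameter).
#' @param lambda L2 regularisation on leaf weights.
#' @param min_child_weight Minimum hessian sum per child.
#' @return List with `trees`, `base_margin` and the settings; predictions
#'   via [gbt_predict()].
#' @keywords internal
gbt_fit <- function(X, y, weights = rep(1, length(y)), n_trees = 200,
                    learning_rate = 0.1, max_depth = 3, alpha = 0,
                    lambda = 1, min_child_weight = 1) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) stop("labels contain a single class")

  f <- rep(0, length(y))  # logit margin; base score 0.5
  trees <- vector("list", n_trees)
  idx <- seq_along(y)
  for (t in seq_len(n_trees)) {
    p <- sigmoid(f)
    g <- weights * (p - y)
    h <- weights * p * (1 - p)
    tree <- grow_tree(X, g, h, idx, 0L, max_depth, alpha, lambda,
                      min_child_weight)
    trees[[t]] <- tree
    f <- f + learning_rate * eval_tree(tree, X)
  }
  list(trees = trees, learning_rate = learning_rate, n_features = ncol(X))
}

#' Predict probabilities from a fitted ensemble
#' @param fit Result of [gbt_fit()].
#' @param X Feature matrix with the training column layout.
#' @return Numeric vector of probabilities in [0, 1].
#' @keywords internal
gbt_predict <- function(fit, X) {
  X <- as.matrix(X)
  if (ncol(X) != fit$n_features) stop("feature count mismatch")
  f <- rep(0, nrow(X))
  for (tree in fit$trees) f <- f + fit$learning_rate * eval_tree(tree, X)
  sigmoid(f)
}

# total split gain per feature, for importance reporting
gbt_importance <- function(fit, feature_names) {
  imp <- numeric(length(feature_names))
  walk <- function(node) {
    if (!is.null(node$leaf)) return()
    imp[node$feature] <<- imp[node$feature] + node$gain
    walk(node$left); walk(node$right)
  }
  for (tree in fit$trees) walk(tree)
  names(imp) <- feature_names
  imp
}
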