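# Size-stratified partitioning of antigens into a test set and training
# folds for cross-validated meta-model training.

#' Partition antigens into a test set and training folds
#'
#' Builds one held-out test set plus `n_folds` training sets, stratified
#' by antigen-size tertile so that each group's size distribution matches
#' the corpus.  Within every tertile, group quotas are proportional to the
#' group's target size (largest-remainder rounding constrained by
#' remaining capacity), and members are dealt to quotas after a seeded
#' shuffle, so the assignment is deterministic under a fixed seed.
#'
#' Group sizes default to "as equal as possible" with the test set taking
#' `ceiling(n / (n_folds + 1))`; an explicit `test_size` overrides this,
#' e.g. to reproduce a published 111 = 29 + 28 + 27 + 27 split.
#'
#' @param sizes Named integer vector: antigen length (residues) per
#'   antigen id.
#' @param n_folds Number of training sets (default 3).
#' @param seed Integer seed controlling the shuffle.
#' @param test_size Test-set size; `NULL` for the equal-split default.
#' @return A `fold_split`: list with `test` (character vector of antigen
#'   ids), `training` (list of `n_folds` character vectors) and
#'   `assignment` (data.frame antigen_id, size, tertile, group).
#' @export
make_folds <- function(sizes, n_folds = 3, seed = 42, test_size = NULL) {
  n <- length(sizes)
  if (n < n_folds + 1) stop("need at least ", n_folds + 1, " antigens")
  if (is.null(names(sizes))) names(sizes) <- paste0("ag", seq_len(n))
  g <- n_folds + 1

  if (is.null(test_size)) test_size <- ceiling(n / g)
  if (test_size < 1 || test_size > n - n_folds)
    stop("impossible test_size")
  rest <- n - test_size
  base <- rest %/% n_folds
  target <- c(base + (seq_len(n_folds) <= rest %% n_folds))
  target <- c(test_size, target)  # group 1 = test

  # size tertiles by rank, near-equal occupancy
  ord <- order(sizes, names(sizes))
  tertile <- integer(n)
  tertile[ord] <- rep(1:3, times = diff(round(seq(0, n, length.out = 4))))

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  group <- integer(n)
  remaining <- target
  for (t in 1:3) {
    members <- sample(which(tertile == t))
    ns <- length(members)
    # proportional quota with largest remainders, capped by capacity
    exact <- remaining * ns / sum(remaining)
    quota <- floor(exact)
    short <- ns - sum(quota)
    if (short > 0) {
      pr <- order(exact - quota, decreasing = TRUE)
      for (j in pr) {
        if (short == 0) break
        if (quota[j] < remaining[j]) {
          quota[j] <- quota[j] + 1
          short <- short - 1
        }
      }
    }
    group[members] <- rep(seq_len(g), times = quota)
    remaining <- remaining - quota
  }

  assignment <- data.frame(antigen_id = names(sizes),
                           size = as.integer(sizes),
                           tertile = tertile, group = group,
                           stringsAsFactors = FALSE)
  structure(list(
    test = names(sizes)[group == 1],
    training = lapply(seq_len(n_folds) + 1,
                      function(k) names(sizes)[group == k]),
    assignment = assignment
  ), class = "fold_split")
}

#' @export
print.fold_split <- function(x, ...) {
  cat("fold_split: test", length(x$test), "| training",
      paste(vapply(x$training, length, integer(1)), collapse = " + "), "\n")
  invisible(x)
}
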