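# Epitope calling: dynamic top-N threshold, Ward clustering of residue
# geometric centers, and dendrogram maximum-gap cluster-count selection.

#' Dynamic epitope-size threshold
#'
#' Number of top-scoring residues called epitopal on an antigen with `R`
#' surface-exposed residues: N = round(6.1 * R^0.3).  Rounding to nearest
#' is the default; floor/ceiling are available.
#'
#' @param R Surface-residue count (integer >= 1; vectorised).
#' @param rounding `"nearest"` (default), `"floor"` or `"ceiling"`.
#' @return Integer vector of thresholds N.
#' @examples
#' dynamic_threshold(96)   # 24
#' @export
dynamic_threshold <- function(R, rounding = c("nearest", "floor", "ceiling")) {
  rounding <- match.arg(rounding)
  if (any(R < 1)) stop("R must be >= 1")
  raw <- 6.1 * R^0.3
  as.integer(switch(rounding,
                    nearest = floor(raw + 0.5),
                    floor = floor(raw),
                    ceiling = ceiling(raw)))
}

#' Indices of the N top-scoring residues
#'
#' Ties at the boundary are broken by residue order (earlier residue
#' wins), making the call deterministic.  When `n` exceeds the number of
#' scored residues, all are returned.
#'
#' @param scores Numeric score vector (residue/file order).
#' @param n Number of residues to select (>= 1).
#' @return Integer vector of selected indices, in residue order.
#' @export
select_top_n <- function(scores, n) {
  if (length(scores) == 0) stop("empty score vector")
  if (n < 1) stop("n must be >= 1")
  k <- min(n, length(scores))
  sort(order(-scores, seq_along(scores))[seq_len(k)])
}

#' Ward hierarchical clustering of residue geometric centers
#'
#' Agglomerative clustering with Ward minimum-variance linkage on
#' Euclidean distances, no distance threshold.  Merge heights follow the
#' convention in which two singletons merge at their Euclidean distance
#' (`stats::hclust(method = "ward.D2")`).
#'
#' @param centers m x 3 matrix of geometric centers (Angstrom).
#' @return An `hclust` object; with fewer than 2 points, a degenerate
#'   single-cluster object of class `ward_degenerate`.
#' @export
ward_cluster <- function(centers) {
  centers <- rbind(centers)
  if (nrow(centers) < 2)
    return(structure(list(n = nrow(centers)), class = "ward_degenerate"))
  stats::hclust(stats::dist(centers), method = "ward.D2")
}

#' Optimal cluster count by the dendrogram maximum-gap rule
#'
#' For each candidate k, the vertical span a horizontal line cutting the
#' dendrogram into k clusters can travel without crossing a merge is
#' gap(k) = h(n-k+1) - h(n-k), where h(m) is the height of the m-th merge.
#' The selected k maximises the gap; ties break toward smaller k
#' (parsimony).  k = 1 is not a candidate: the rule requires a cut below
#' the final merge.
#'
#' @param dendrogram An `hclust` object (or a numeric vector of
#'   non-decreasing merge heights).
#' @param k_max Largest candidate k (default 8).
#' @return List with `k` and `gap_table` (data.frame k, gap).
#' @examples
#' optimal_cluster_count(c(5, 10, 31, 71, 88))  # k = 3, gap 40
#' @export
optimal_cluster_count <- function(dendrogram, k_max = 8) {
  h <- if (is.numeric(dendrogram)) dendrogram else dendrogram$height
  if (is.unsorted(h)) stop("merge heights must be non-decreasing")
  n <- length(h) + 1
  if (n < 2) stop("need at least 2 leaves")
  if (n == 2)
    return(list(k = 2L, gap_table = data.frame(k = 2L, gap = h[1])))
  ks <- seq(2L, min(k_max, n - 1L))
  gap <- h[n - ks + 1] - h[n - ks]
  k <- ks[which.max(gap)]   # which.max takes the first maximum -> smallest k
  list(k = k, gap_table = data.frame(k = ks, gap = gap))
}

#' Call epitopes: dynamic threshold, top-N selection and spatial clustering
#'
#' Composes the full calling stage: N = [dynamic_threshold()] from the
#' surface-residue count, the N top consensus scores via [select_top_n()],
#' Ward clustering of their geometric centers and the dendrogram
#' maximum-gap rule, yielding k putative epitopes.
#'
#' @param structure An `antigen_structure`.
#' @param surface A `surface_profile`, or directly the integer surface
#'   count R (synthetic fixtures treat every residue as exposed).
#' @param scores Numeric consensus score per residue (structure order).
#' @param k_max Largest candidate cluster count (default 8).
#' @param rounding Rounding mode for the threshold.
#' @return An `epitope_call`: list with `antigen_id`, `scores`, `R`, `N`,
#'   `top` (data.frame of the called residues with their scores and
#'   cluster ids), `top_idx`, `dendrogram`, `k`, `gap_table` and
#'   `clusters` (list of per-cluster residue data.frames).
#' @export
call_epitopes <- function(structure, surface, scores, k_max = 8,
                          rounding = "nearest") {
  if (length(scores) != nrow(structure$residues))
    stop("scores and structure cover different residue sets")
  R <- if (inherits(surface, "surface_profile")) surface$R else as.integer(surface)
  N <- dynamic_threshold(R, rounding)
  idx <- select_top_n(scores, N)

  hc <- ward_cluster(structure$centers[idx, , drop = FALSE])
  if (inherits(hc, "ward_degenerate")) {
    k <- 1L
    gap_table <- data.frame(k = integer(0), gap = numeric(0))
    labels <- rep(1L, length(idx))
  } else {
    opt <- optimal_cluster_count(hc, k_max)
    k <- opt$k
    gap_table <- opt$gap_table
    labels <- as.integer(stats::cutree(hc, k))
  }

  top <- cbind(structure$residues[idx, , drop = FALSE],
               score = scores[idx], cluster = labels)
  rownames(top) <- NULL
  clusters <- split(top, top$cluster)

  structure(list(
    antigen_id = basename(structure$source$path),
    scores = scores, R = R, N = N,
    top = top, top_idx = idx,
    dendrogram = hc, k = k, gap_table = gap_table,
    clusters = clusters
  ), class = "epitope_call")
}

#' @export
print.epitope_call <- function(x, ...) {
  cat("epitope_call:", x$antigen_id, "\n")
  cat(sprintf("  R = %d surface residues -> dynamic threshold N = %d\n",
              x$R, x$N))
  cat(sprintf("  %d putative epitope(s); sizes: %s\n", x$k,
              paste(vapply(x$clusters, nrow, integer(1)), collapse = ", ")))
  invisible(x)
}

#' @export
plot.epitope_call <- function(x, ...) {
  if (inherits(x$dendrogram, "ward_degenerate")) {
    warning("degenerate single-residue call; nothing to plot")
    return(invisible(x))
  }
  graphics::plot(x$dendrogram, labels = FALSE, hang = -1,
                 main = sprintf("%s: k = %d putative epitopes",
                                x$antigen_id, x$k),
                 xlab = "called residues", sub = "", ...)
  h <- x$dendrogram$height
  n <- length(h) + 1
  graphics::abline(h = mean(h[n - x$k + c(0, 1)]), lty = 2, col = "red")
  invisible(x)
}

#' Write a per-residue prediction/call TSV
#'
#' Columns: chain, seqnum, icode, consensus_score, in_top_n, cluster_id
#' (NA outside the called set).
#'
#' @param structure An `antigen_structure`.
#' @param call An `epitope_call` on that structure.
#' @param path Output file path.
#' @export
write_call_tsv <- function(structure, call, path) {
  n <- nrow(structure$residues)
  cluster_id <- rep(NA_integer_, n)
  cluster_id[call$top_idx] <- call$top$cluster
  out <- cbind(structure$residues[, c("chain", "seqnum", "icode")],
               consensus_score = round(call$scores, 6),
               in_top_n = seq_len(n) %in% call$top_idx,
               cluster_id = cluster_id)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
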