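# Thresholded connectivity edge maps, hierarchical clustering of region
# probability patterns, and afferent-vs-efferent comparison.

#' Threshold a connectivity matrix into an edge set
#'
#' Keeps off-diagonal entries whose probability reaches `conn_threshold`.
#' The boundary is inclusive by default (a probability exactly at the cut
#' is kept); `strict_gt = TRUE` restores a strict `>` comparison.
#'
#' @param cm a `connectivity_matrix`.
#' @param config an [analysis_config()] (supplies `conn_threshold`).
#' @param strict_gt use `>` instead of `>=` at the boundary.
#' @return A data.frame of class `"edge_set"` with columns `source` (row
#'   region), `target` (column region) and `probability`, plus attributes
#'   `direction` and `threshold`. The physiological reading of row ->
#'   column depends on `direction` (for an afferent matrix the row is the
#'   receiving region); the edge set preserves the matrix orientation and
#'   carries the direction as metadata.
#' @export
threshold_edges <- function(cm, config = NULL, strict_gt = FALSE) {
  config <- as_config(config)
  stopifnot(inherits(cm, "connectivity_matrix"))
  thr <- config$conn_threshold
  keep <- if (strict_gt) cm$prob > thr else cm$prob >= thr
  diag(keep) <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  out <- data.frame(source = cm$regions[idx[, 1]],
                    target = cm$regions[idx[, 2]],
                    probability = cm$prob[idx], stringsAsFactors = FALSE)
  out <- out[order(out$source, out$target), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "direction") <- cm$direction
  attr(out, "threshold") <- thr
  class(out) <- c("edge_set", "data.frame")
  out
}

# Euclidean distance between region probability patterns (matrix rows),
# ignoring self-connections: for the pair (i, j) the columns i and j are
# left out of both rows.
row_pattern_dist <- function(prob) {
  r <- nrow(prob)
  d <- matrix(0, r, r)
  for (i in seq_len(r - 1)) {
    for (j in (i + 1):r) {
      keep <- setdiff(seq_len(r), c(i, j))
      d[i, j] <- d[j, i] <- sqrt(sum((prob[i, keep] - prob[j, keep])^2))
    }
  }
  rownames(d) <- colnames(d) <- rownames(prob)
  d
}

#' Hierarchical binary cluster tree of region connectivity patterns
#'
#' Agglomerative clustering of the matrix rows — each region's pattern of
#' connection probabilities to all other regions. The distance is
#' Euclidean with the two regions' mutual (and self) entries masked out;
#' linkage is average by default. Deterministic for a given input; equal
#' rows merge first at height 0.
#'
#' @param cm a `connectivity_matrix` with at least 2 regions.
#' @param linkage linkage method passed to [stats::hclust()].
#' @param metric `"euclidean"` (masked, the default) or any method
#'   accepted by [stats::dist()] applied to raw rows (diagonal included).
#' @return An `hclust` object (R-1 merges, labels = regions) with extra
#'   class `"region_cluster_tree"`.
#' @export
cluster_regions <- function(cm, linkage = "average",
                            metric = "euclidean") {
  stopifnot(inherits(cm, "connectivity_matrix"))
  r <- length(cm$regions)
  if (r < 2) stop("need at least 2 regions to cluster")
  d <- if (identical(metric, "euclidean")) {
    stats::as.dist(row_pattern_dist(cm$prob))
  } else {
    stats::dist(cm$prob, method = metric)
  }
  tree <- stats::hclust(d, method = linkage)
  class(tree) <- c("region_cluster_tree", class(tree))
  tree
}

#' Partition regions by cutting the cluster tree
#'
#' @param tree a tree from [cluster_regions()].
#' @param k number of clusters.
#' @return Integer cluster id per region (named).
#' @export
cut_regions <- function(tree, k) {
  stats::cutree(stats::as.hclust(tree), k = k)
}

# TRUE iff two labelled partitions induce the same grouping
same_partition <- function(a, b) {
  stopifnot(length(a) == length(b))
  co_a <- outer(a, a, "==")
  co_b <- outer(b, b, "==")
  all(co_a == co_b)
}

#' Export a cluster tree in Newick format
#'
#' @param tree a tree from [cluster_regions()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  phy <- ape::as.phylo(stats::as.hclust(tree))
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Compare afferent and efferent connectivity structure
#'
#' Reports (i) the Pearson correlation of the two matrices over
#' off-diagonal entries, (ii) the Jaccard agreement of their thresholded
#' edge sets, and (iii) whether the two cluster trees induce the same
#' partition at `k` clusters (default 4, the number of predominant region
#' clusters).
#'
#' @param afferent,efferent `connectivity_matrix` objects over the same
#'   regions in the same order.
#' @param config an [analysis_config()].
#' @param k partition size for the tree comparison.
#' @return A list of class `"direction_comparison"`: `correlation`,
#'   `edge_agreement`, `same_partition`, `k`.
#' @export
compare_directions <- function(afferent, efferent, config = NULL, k = 4L) {
  config <- as_config(config)
  stopifnot(inherits(afferent, "connectivity_matrix"),
            inherits(efferent, "connectivity_matrix"))
  if (!identical(afferent$regions, efferent$regions)) {
    stop("afferent and efferent matrices have different region order")
  }
  off <- row(afferent$prob) != col(afferent$prob)
  correlation <- stats::cor(afferent$prob[off], efferent$prob[off])

  ea <- threshold_edges(afferent, config)
  eb <- threshold_edges(efferent, config)
  key <- function(e) paste(e$source, e$target, sep = "->")
  u <- union(key(ea), key(eb))
  agreement <- if (length(u) == 0) 1 else
    length(intersect(key(ea), key(eb))) / length(u)

  same <- same_partition(cut_regions(cluster_regions(afferent), k),
                         cut_regions(cluster_regions(efferent), k))
  structure(list(correlation = correlation,
                 edge_agreement = agreement,
                 same_partition = same,
                 k = as.integer(k)),
            class = "direction_comparison")
}

#' @export
print.direction_comparison <- function(x, ...) {
  cat(sprintf("Afferent vs efferent: correlation %.3f, edge agreement %.3f, %s partition at k=%d\n",
              x$correlation, x$edge_agreement,
              if (x$same_partition) "same" else "different", x$k))
  invisible(x)
}
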