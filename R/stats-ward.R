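# Agglomerative Ward (minimum-variance) clustering on Euclidean distances.
#
# Implemented directly via the Lance-Williams recurrence on the quantity
# D(A,B) = 2 * |A||B|/(|A|+|B|) * ||mean_A - mean_B||^2, which equals the
# squared Euclidean distance for singletons and twice the increase in
# within-cluster sum of squares (ESS) caused by merging A and B. Reported
# merge heights are D/2, i.e. the ESS increase itself, so they can be
# checked against direct evaluation of the Ward objective. Ward's criterion
# is reducible, hence heights are non-decreasing.
#
# Ties in the merge cost are broken by the lexicographically smallest pair
# of cluster ids, where a cluster's id is the smallest original item index
# it contains. This makes the tree a deterministic function of the input.

#' Ward hierarchical clustering
#'
#' @param x either a numeric matrix (rows are the items to cluster, Euclidean
#'   distances are computed internally) or a `dist` object of Euclidean
#'   distances.
#' @return An object of class `ward_tree`: list with `merge` (n-1 x 2 matrix
#'   in `hclust` convention: negative entries are leaves, positive entries
#'   reference earlier merges), `height` (ESS increase per merge,
#'   non-decreasing), `labels`, and `n`.
#' @examples
#' tr <- ward_cluster(matrix(c(0, 1, 10), ncol = 1))
#' tr$height  # first merge {0,1} at 0.5, then the far point joins
#' @export
ward_cluster <- function(x) {
  if (inherits(x, "dist")) {
    labels <- attr(x, "Labels")
    n <- attr(x, "Size")
    d2 <- as.matrix(x)^2
  } else {
    abort_if(!is.matrix(x) || !is.numeric(x),
             "x must be a numeric matrix or a dist object")
    abort_if(any(!is.finite(x)), "non-finite distances")
    n <- nrow(x)
    labels <- rownames(x)
    d2 <- as.matrix(stats::dist(x))^2
  }
  abort_if(n < 2, "need at least 2 items to cluster")
  abort_if(any(!is.finite(d2)), "non-finite distances")
  if (is.null(labels)) labels <- as.character(seq_len(n))

  # D holds twice the ESS-increase between active clusters.
  D <- d2
  diag(D) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  # cluster id for the merge matrix: negative leaf index, else merge row
  node <- -seq_len(n)
  # lexicographic tie-break key: smallest original member of each cluster
  smallest <- seq_len(n)

  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (step in seq_len(n - 1)) {
    act <- which(active)
    sub <- D[act, act, drop = FALSE]
    best <- min(sub)
    cand <- which(sub <= best + 0, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # break ties by smallest original-member pair
    key_i <- smallest[act[cand[, 1]]]
    key_j <- smallest[act[cand[, 2]]]
    lo <- pmin(key_i, key_j); hi <- pmax(key_i, key_j)
    pick <- order(lo, hi)[1]
    i <- act[cand[pick, 1]]; j <- act[cand[pick, 2]]
    if (smallest[j] < smallest[i]) { tmp <- i; i <- j; j <- tmp }

    height[step] <- D[i, j] / 2
    a <- node[i]; b <- node[j]
    if (abs(a) > abs(b) && sign(a) == sign(b)) { tmp <- a; a <- b; b <- tmp }
    if (a > 0 && b < 0) { tmp <- a; a <- b; b <- tmp }
    merge[step, ] <- c(a, b)

    ni <- size[i]; nj <- size[j]
    others <- act[act != i & act != j]
    if (length(others)) {
      nk <- size[others]
      newd <- ((ni + nk) * D[i, others] + (nj + nk) * D[j, others] -
                 nk * D[i, j]) / (ni + nj + nk)
      D[i, others] <- newd
      D[others, i] <- newd
    }
    size[i] <- ni + nj
    active[j] <- FALSE
    node[i] <- step
    smallest[i] <- min(smallest[i], smallest[j])
    D[j, ] <- Inf; D[, j] <- Inf
  }
  structure(list(merge = merge, height = height, labels = labels, n = n),
            class = "ward_tree")
}

#' @export
print.ward_tree <- function(x, ...) {
  cat(sprintf("Ward tree over %d items; merge heights %.4g .. %.4g\n",
              x$n, min(x$height), max(x$height)))
  invisible(x)
}

#' Convert a `ward_tree` to an `hclust` object
#'
#' Allows use of the standard dendrogram/heat-map machinery. Heights are the
#' ESS increases (monotone).
#'
#' @param x a `ward_tree`.
#' @param ... unused.
#' @return An `hclust` object.
#' @export
as.hclust.ward_tree <- function(x, ...) {
  ord <- tree_leaf_order(x$merge, x$n)
  structure(
    list(merge = x$merge, height = x$height, order = ord,
         labels = x$labels, method = "ward", call = match.call(),
         dist.method = "euclidean"),
    class = "hclust"
  )
}

# Leaf order by left-to-right traversal of the merge matrix.
tree_leaf_order <- function(merge, n) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(n - 1)
}

#' Cut a Ward tree into flat clusters
#'
#' @param tree a `ward_tree`.
#' @param k number of clusters (1..n); exactly one of `k`, `h` must be given.
#' @param h height threshold: clusters are the components left when all
#'   merges with height > `h` are undone.
#' @return An integer label vector (1-based, labeled in order of each
#'   cluster's smallest item index), named by item labels.
#' @examples
#' tr <- ward_cluster(matrix(c(0, 1, 10), ncol = 1))
#' cut_tree(tr, k = 2)
#' @export
cut_tree <- function(tree, k = NULL, h = NULL) {
  abort_if(!inherits(tree, "ward_tree"), "tree must be a ward_tree")
  abort_if(is.null(k) == is.null(h), "supply exactly one of k or h")
  n <- tree$n
  if (!is.null(h)) {
    k <- n - sum(tree$height <= h)
  }
  abort_if(!is_count(k) || k < 1 || k > n, "k must be in 1..n")
  lab <- seq_len(n)
  if (k < n) {
    for (step in seq_len(n - k)) {
      a <- tree$merge[step, 1]; b <- tree$merge[step, 2]
      mem_a <- if (a < 0) -a else which(lab == lab[merge_rep(tree, a)])
      mem_b <- if (b < 0) -b else which(lab == lab[merge_rep(tree, b)])
      lab[c(mem_a, mem_b)] <- min(lab[c(mem_a, mem_b)])
    }
  }
  out <- match(lab, sort(unique(lab)))
  names(out) <- tree$labels
  out
}

# Representative original item of a merge node (its smallest leaf).
merge_rep <- function(tree, node) {
  while (node > 0) node <- tree$merge[node, 1]
  -node
}

# Default flat-cluster count: cut at the largest relative gap between
# consecutive merge heights, considering k in 2..k_max. The gap for k
# clusters compares the first merge that would destroy the k-cluster
# solution (height index n-k+1) with the last merge that built it.
choose_k_by_gap <- function(tree, k_max = 10) {
  n <- tree$n
  ks <- 2:min(k_max, n - 1)
  if (length(ks) == 0) return(2L)
  h <- tree$height
  eps <- 1e-12 + 1e-9 * max(h)
  score <- vapply(ks, function(k) {
    (h[n - k + 1] - h[n - k]) / (h[n - k] + eps)
  }, numeric(1))
  ks[which.max(score)]
}
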