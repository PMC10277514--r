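# Patient subgroup discovery on a transcriptome matrix.
#
# Samples are clustered in the space of a small marker-gene signature
# (Ward/Euclidean); differential expression between the resulting clusters
# is counted gene-wise (Welch two-sample t with BKY FDR); and the counts
# are calibrated against a permutation null of random clusters with the
# same sizes.

#' Cluster samples on a marker-gene signature
#'
#' @param expr samples x genes numeric matrix with dimnames.
#' @param markers character vector of marker gene names, all present in
#'   `expr`.
#' @param k number of flat clusters (`>= 1`).
#' @return A `subgroup_partition`: list with `labels` (integer per sample,
#'   named), `markers`, `tree` (a `ward_tree`, `NULL` for degenerate
#'   constant-marker input), `k`, `sizes`.
#' @export
cluster_samples_on_markers <- function(expr, markers, k) {
  abort_if(!is.matrix(expr) || !is.numeric(expr),
           "expr must be a numeric matrix (samples x genes)")
  missing_m <- setdiff(markers, colnames(expr))
  abort_if(length(missing_m) > 0,
           paste("markers missing from expression matrix:",
                 paste(missing_m, collapse = ", ")))
  abort_if(!is_count(k) || k < 1 || k > nrow(expr), "k out of range")
  sub <- expr[, markers, drop = FALSE]
  if (all(apply(sub, 2, stats::sd) == 0)) {
    warning("all markers constant across samples: single-height tree")
    labels <- stats::setNames(rep(1L, nrow(expr)), rownames(expr))
    return(structure(list(labels = labels, markers = markers, tree = NULL,
                          k = 1L, sizes = nrow(expr)),
                     class = "subgroup_partition"))
  }
  if (k == 1) {
    labels <- stats::setNames(rep(1L, nrow(expr)), rownames(expr))
    tree <- if (nrow(expr) >= 2) ward_cluster(sub) else NULL
    return(structure(list(labels = labels, markers = markers, tree = tree,
                          k = 1L, sizes = nrow(expr)),
                     class = "subgroup_partition"))
  }
  tree <- ward_cluster(sub)
  labels <- cut_tree(tree, k = k)
  structure(
    list(labels = labels, markers = markers, tree = tree, k = k,
         sizes = as.vector(table(labels))),
    class = "subgroup_partition"
  )
}

#' @export
print.subgroup_partition <- function(x, ...) {
  cat(sprintf("subgroup partition: %d clusters on %d markers; sizes %s\n",
              x$k, length(x$markers), paste(x$sizes, collapse = "/")))
  invisible(x)
}

# Vectorized Welch two-sample t over the columns of expr.
welch_t_columns <- function(expr, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- colMeans(expr[idx1, , drop = FALSE])
  m2 <- colMeans(expr[idx2, , drop = FALSE])
  v1 <- apply(expr[idx1, , drop = FALSE], 2, stats::var)
  v2 <- apply(expr[idx2, , drop = FALSE], 2, stats::var)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t_stat), df = df)
  p[se2 == 0] <- 1  # both groups constant and equal -> no evidence
  p[is.na(p)] <- 1
  p
}

#' Pairwise differentially expressed genes between subgroups
#'
#' For every pair of clusters of size `>= min_cluster`, tests each gene
#' with Welch's two-sample t and applies BKY FDR at `q` across genes
#' within the pair.
#'
#' @param expr samples x genes matrix.
#' @param partition a `subgroup_partition` (or a named label vector).
#' @param q FDR level, default 0.05.
#' @param min_cluster smallest cluster size admitted to testing, default 3;
#'   smaller clusters are skipped and listed in `skipped`.
#' @return A `pairwise_deg` object: `counts` (symmetric cluster x cluster
#'   matrix of DEG counts, zero diagonal), `genes` (named list `"i|j"` ->
#'   character vector), `skipped`, `q`.
#' @export
pairwise_deg <- function(expr, partition, q = 0.05, min_cluster = 3) {
  labels <- if (inherits(partition, "subgroup_partition")) partition$labels
            else partition
  abort_if(is.null(names(labels)) ||
             !all(names(labels) %in% rownames(expr)),
           "partition labels must be named by samples present in expr")
  expr <- expr[names(labels), , drop = FALSE]
  sizes <- table(labels)
  eligible <- as.integer(names(sizes)[sizes >= min_cluster])
  skipped <- as.integer(names(sizes)[sizes < min_cluster])
  abort_if(length(eligible) < 2,
           "fewer than 2 clusters meet the minimum size")
  k <- length(eligible)
  counts <- matrix(0L, k, k, dimnames = list(eligible, eligible))
  genes <- list()
  for (a_ix in seq_len(k - 1)) {
    for (b_ix in seq.int(a_ix + 1, k)) {
      ca <- eligible[a_ix]; cb <- eligible[b_ix]
      p <- welch_t_columns(expr, which(labels == ca), which(labels == cb))
      rej <- bky_two_stage(p, q = q)$rejected
      counts[a_ix, b_ix] <- counts[b_ix, a_ix] <- sum(rej)
      genes[[paste(ca, cb, sep = "|")]] <- colnames(expr)[rej]
    }
  }
  structure(list(counts = counts, genes = genes, skipped = skipped, q = q),
            class = "pairwise_deg")
}

#' @export
print.pairwise_deg <- function(x, ...) {
  cat("pairwise DEG counts (BKY q =", x$q, "):\n")
  print(x$counts)
  if (length(x$skipped)) cat("skipped clusters:",
                             paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' Random-cluster permutation null for pairwise DEG counts
#'
#' Repeatedly assigns samples at random to clusters of the given sizes and
#' records the pairwise DEG counts, yielding the null distribution against
#' which observed counts from a marker-derived partition are judged.
#'
#' @param expr samples x genes matrix.
#' @param sizes integer cluster sizes; must sum to at most `nrow(expr)`.
#' @param n_permutations number of random assignments, `>= 1` (use `>= 100`
#'   for stable percentiles).
#' @param q FDR level per pair.
#' @param seed integer RNG seed; the draw is reproducible.
#' @param min_cluster passed to [pairwise_deg()].
#' @return A `deg_null` object: `max_counts` (per permutation, the maximum
#'   pairwise DEG count), `all_counts` (permutations x pairs matrix),
#'   `percentile(p)` helper for the max-count distribution, `sizes`,
#'   `n_genes`.
#' @export
random_cluster_null <- function(expr, sizes, n_permutations = 1000,
                                q = 0.05, seed = 1, min_cluster = 3) {
  abort_if(sum(sizes) > nrow(expr),
           "cluster sizes exceed the number of samples")
  abort_if(any(sizes < 1), "cluster sizes must be positive")
  abort_if(!is_count(n_permutations) || n_permutations < 1,
           "n_permutations must be a positive integer")
  sizes <- as.integer(sizes)
  assign_labels <- rep(seq_along(sizes), sizes)
  with_seed(seed, {
    res <- matrix(NA_integer_, n_permutations,
                  choose(sum(sizes >= min_cluster), 2))
    for (i in seq_len(n_permutations)) {
      pick <- sample(rownames(expr), sum(sizes))
      labels <- stats::setNames(assign_labels, pick)
      pd <- pairwise_deg(expr, labels, q = q, min_cluster = min_cluster)
      res[i, ] <- pd$counts[upper.tri(pd$counts)]
    }
    max_counts <- apply(res, 1, max)
    structure(
      list(max_counts = max_counts, all_counts = res,
           percentile = function(p) unname(stats::quantile(max_counts, p)),
           sizes = sizes, n_genes = ncol(expr), n_permutations = n_permutations),
      class = "deg_null"
    )
  })
}

#' @export
print.deg_null <- function(x, ...) {
  cat(sprintf(
    "random-cluster DEG null: %d permutations, sizes %s; max-count p95 = %g\n",
    x$n_permutations, paste(x$sizes, collapse = "/"), x$percentile(0.95)))
  invisible(x)
}

#' Biotype composition of DEG lists
#'
#' Tabulates the relative frequency of gene categories (e.g.
#' protein-coding vs non-coding) among each cluster pair's DEGs.
#'
#' @param deg_genes named list of gene-id vectors (e.g. the `genes` element
#'   of a [pairwise_deg()] result).
#' @param annotation data.frame with columns `gene` and `biotype`.
#' @return A named list of per-pair frequency tables (proportions); genes
#'   absent from the annotation count as `"unknown"`. Empty DEG lists give
#'   empty tables.
#' @export
deg_compartment_summary <- function(deg_genes, annotation) {
  abort_if(!is.data.frame(annotation) ||
             !all(c("gene", "biotype") %in% names(annotation)),
           "annotation must have columns gene and biotype")
  abort_if(nrow(annotation) == 0, "empty annotation")
  lapply(deg_genes, function(gs) {
    if (length(gs) == 0) return(table(character(0)) / 1)
    bt <- annotation$biotype[match(gs, annotation$gene)]
    bt[is.na(bt)] <- "unknown"
    table(bt) / length(gs)
  })
}
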