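# Differential co-expression via residual correlation matrices.
#
# A group's co-expression structure is its protein x protein Spearman
# matrix; the residual matrix is the element-wise difference between two
# groups' matrices, so entries far from zero mark protein pairs whose
# coupling changes with disease stage. Ward clustering of the residual row
# profiles extracts blocks of co-deregulated proteins.

#' Group-wise Spearman correlation matrix
#'
#' @param x an [npx_matrix()].
#' @param meta a [sample_metadata()].
#' @param group group label; needs at least 4 samples.
#' @return A `group_corr_matrix`: list with `corr` (symmetric, unit
#'   diagonal; constant proteins give `NA` rows/columns), `group`, `n`.
#' @export
group_correlation <- function(x, meta, group) {
  abort_if(!inherits(x, "npx_matrix"), "x must be an npx_matrix")
  meta <- sample_metadata(as.data.frame(meta))
  ids <- intersect(sample_ids(x), meta$sample_id[meta$group == group])
  abort_if(length(ids) < 4,
           sprintf("group '%s' has fewer than 4 samples", group))
  cc <- spearman_matrix(x$values[ids, , drop = FALSE])
  structure(list(corr = cc, group = group, n = length(ids)),
            class = "group_corr_matrix")
}

#' Residual (differential) correlation matrix
#'
#' Element-wise difference `a - b` of two group correlation matrices over
#' the same proteins; `NA` entries (constant proteins) propagate.
#'
#' @param a,b `group_corr_matrix` objects over identical protein sets.
#' @return A `residual_corr_matrix`: list with `residual` (symmetric, zero
#'   diagonal, entries in [-2, 2]), `contrast` (e.g. `"NASH-NAFL"`), the
#'   two group sample sizes, and later `clusters` once clustered.
#' @export
residual_matrix <- function(a, b) {
  abort_if(!inherits(a, "group_corr_matrix") ||
             !inherits(b, "group_corr_matrix"),
           "inputs must come from group_correlation()")
  abort_if(!identical(colnames(a$corr), colnames(b$corr)),
           "protein sets of the two correlation matrices differ")
  res <- a$corr - b$corr
  diag(res)[!is.na(diag(res))] <- 0
  structure(
    list(residual = res,
         contrast = paste0(a$group, "-", b$group),
         n_a = a$n, n_b = b$n, clusters = NULL, tree = NULL),
    class = "residual_corr_matrix"
  )
}

#' Cluster a residual correlation matrix
#'
#' Ward/Euclidean clustering of the residual row profiles (each protein's
#' vector of correlation changes against all proteins). Missing entries
#' are imputed to 0 with a warning — conservative toward the null, since 0
#' means "no change in co-expression". The number of flat clusters
#' defaults to the largest relative merge-height gap in the tree.
#'
#' @param x a `residual_corr_matrix`.
#' @param k number of clusters; `NULL` (default) picks k by the height-gap
#'   heuristic.
#' @param h alternative height cut, passed to [cut_tree()].
#' @return The input with `tree` (a `ward_tree`), `clusters` (integer
#'   labels per protein) and `cluster_members` (list of protein id
#'   vectors, ordered largest cluster first) filled in.
#' @export
cluster_residuals <- function(x, k = NULL, h = NULL) {
  abort_if(!inherits(x, "residual_corr_matrix"),
           "x must come from residual_matrix()")
  prof <- x$residual
  if (anyNA(prof)) {
    warning("missing residual entries imputed to 0 for clustering")
    prof[is.na(prof)] <- 0
  }
  if (all(prof == 0)) {
    warning("all-zero residual matrix: single trivial cluster")
    labs <- stats::setNames(rep(1L, nrow(prof)), rownames(prof))
    x$clusters <- labs
    x$cluster_members <- list(rownames(prof))
    return(x)
  }
  tree <- ward_cluster(prof)
  if (is.null(k) && is.null(h)) k <- choose_k_by_gap(tree)
  labs <- cut_tree(tree, k = k, h = h)
  members <- split(names(labs), labs)
  members <- members[order(-lengths(members))]
  names(members) <- NULL
  x$tree <- tree
  x$clusters <- labs
  x$cluster_members <- members
  x
}

#' Summarize residual clusters
#'
#' For each cluster of a clustered residual matrix: its mean absolute
#' within-cluster residual and the most differentially co-expressed member
#' pairs, each reported with both groups' Spearman coefficients and the
#' permutation-free asymptotic p-value of each coefficient (t
#' approximation), supporting example-pair reporting.
#'
#' @param x a clustered `residual_corr_matrix`.
#' @param a,b the `group_corr_matrix` objects the residual was built from.
#' @param top_pairs how many example pairs per cluster (default 3).
#' @return A list of per-cluster summaries: `members`, `mean_abs_residual`
#'   (mean |residual| over distinct within-cluster pairs; 0 for
#'   singletons), and `pairs` (data.frame with both group coefficients,
#'   their p-values, and the residual).
#' @export
cluster_enrichment_summary <- function(x, a, b, top_pairs = 3) {
  abort_if(is.null(x$clusters), "cluster the residual matrix first")
  abort_if(!identical(colnames(a$corr), colnames(x$residual)) ||
             !identical(colnames(b$corr), colnames(x$residual)),
           "correlation matrices do not match the residual matrix")
  lapply(x$cluster_members, function(members) {
    if (length(members) < 2) {
      return(list(members = members, mean_abs_residual = 0,
                  pairs = data.frame()))
    }
    sub <- x$residual[members, members, drop = FALSE]
    ut <- upper.tri(sub)
    pair_idx <- which(ut, arr.ind = TRUE)
    vals <- sub[ut]
    o <- order(-abs(vals))
    take <- utils::head(o, top_pairs)
    pairs <- do.call(rbind, lapply(take, function(ix) {
      p1 <- members[pair_idx[ix, 1]]; p2 <- members[pair_idx[ix, 2]]
      data.frame(
        protein_1 = p1, protein_2 = p2,
        rho_a = a$corr[p1, p2], p_a = spearman_p(a$corr[p1, p2], a$n),
        rho_b = b$corr[p1, p2], p_b = spearman_p(b$corr[p1, p2], b$n),
        residual = x$residual[p1, p2],
        stringsAsFactors = FALSE
      )
    }))
    list(members = members,
         mean_abs_residual = mean(abs(vals), na.rm = TRUE),
         pairs = pairs)
  })
}

# Asymptotic two-sided p for a Spearman coefficient (t approximation).
spearman_p <- function(rho, n) {
  if (is.na(rho) || n < 3) return(NA_real_)
  if (abs(rho) >= 1) return(0)
  t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(t_stat), df = n - 2)
}
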