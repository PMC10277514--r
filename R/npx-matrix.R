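# The NPX expression container: a samples x proteins numeric matrix on the
# NPX (log2-like) scale plus a same-shaped logical below-LOD mask. Values at
# masked positions hold the per-protein LOD floor (left-censoring), so rank
# tests see ties at the floor rather than missing values.

#' Construct an NPX expression matrix
#'
#' @param values numeric matrix, samples in rows, proteins in columns, with
#'   unique row (sample) and column (protein) names.
#' @param below_lod logical matrix of the same shape flagging values at or
#'   below the limit of detection; default all `FALSE`.
#' @return An object of class `npx_matrix` with elements `values` and
#'   `below_lod`.
#' @export
npx_matrix <- function(values, below_lod = NULL) {
  abort_if(!is.matrix(values) || !is.numeric(values),
           "values must be a numeric matrix")
  abort_if(is.null(rownames(values)) || is.null(colnames(values)),
           "values must have sample (row) and protein (column) names")
  abort_if(anyDuplicated(rownames(values)) > 0, "duplicated sample ids")
  abort_if(anyDuplicated(colnames(values)) > 0, "duplicated protein ids")
  if (is.null(below_lod)) {
    below_lod <- matrix(FALSE, nrow(values), ncol(values),
                        dimnames = dimnames(values))
  }
  abort_if(!is.logical(below_lod) || !identical(dim(below_lod), dim(values)),
           "below_lod must be a logical matrix matching values")
  dimnames(below_lod) <- dimnames(values)
  abort_if(any(!is.finite(values)),
           "NPX values must be finite (censored values carry the LOD floor)")
  structure(list(values = values, below_lod = below_lod),
            class = "npx_matrix")
}

#' @export
print.npx_matrix <- function(x, ...) {
  cat(sprintf("npx_matrix: %d samples x %d proteins; %.1f%% below LOD\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$below_lod)))
  invisible(x)
}

#' @export
dim.npx_matrix <- function(x) dim(x$values)

sample_ids <- function(x) rownames(x$values)
protein_ids <- function(x) colnames(x$values)

# Row/column subsetting that keeps values and mask aligned.
subset_npx <- function(x, samples = NULL, proteins = NULL) {
  v <- x$values; m <- x$below_lod
  if (!is.null(samples)) { v <- v[samples, , drop = FALSE]
                           m <- m[samples, , drop = FALSE] }
  if (!is.null(proteins)) { v <- v[, proteins, drop = FALSE]
                            m <- m[, proteins, drop = FALSE] }
  npx_matrix(v, m)
}

#' Filter proteins by detection rate
#'
#' Quality filter reducing the measured panel to the analyzed panel: a
#' protein is excluded when it is below the limit of detection in strictly
#' more than `max_below_lod_fraction` of samples (i.e. proteins detected in
#' at least `1 - max_below_lod_fraction` of samples are kept; a protein at
#' exactly the boundary is retained). With the default 0.10 this reproduces
#' the "analyzed in >90% of samples" panel-reduction rule.
#'
#' @param x an `npx_matrix`.
#' @param max_below_lod_fraction maximum tolerated below-LOD fraction,
#'   default 0.10.
#' @return A list with `matrix` (the filtered `npx_matrix`, all samples
#'   kept) and `excluded` (character vector of removed protein ids, in
#'   input column order).
#' @examples
#' v <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("s", 1:10), c("A", "B")))
#' m <- v < -10  # nothing censored
#' filter_by_detection(npx_matrix(v, m))
#' @export
filter_by_detection <- function(x, max_below_lod_fraction = 0.10) {
  abort_if(!inherits(x, "npx_matrix"), "x must be an npx_matrix")
  abort_if(nrow(x$values) == 0 || ncol(x$values) == 0, "empty matrix")
  abort_if(!is_proportion(max_below_lod_fraction),
           "max_below_lod_fraction must lie in [0,1]")
  frac <- colMeans(x$below_lod)
  drop <- frac > max_below_lod_fraction
  list(
    matrix = subset_npx(x, proteins = !drop),
    excluded = colnames(x$values)[drop]
  )
}
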