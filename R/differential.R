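# Group-wise differential protein abundance.
#
# One Mann-Whitney test per protein, two-stage BKY FDR across the whole
# comparison family (one volcano = one family), effect reported both as
# the difference of group median NPX (log2-like units) and as its
# linear-scale ratio 2^difference, since volcano "ratio" axes are drawn on
# either convention.

#' Differential protein abundance between two groups
#'
#' @param x a detection-filtered [npx_matrix()].
#' @param meta a [sample_metadata()] covering all samples of `x`.
#' @param group_a,group_b group labels (`"HC"`, `"NAFL"`, `"NASH"`); the
#'   effect is `group_a - group_b` (median NPX difference), so a protein
#'   lower in `group_a` has direction `"down"`.
#' @param q FDR level for the BKY two-stage decision, default 0.05.
#' @param mode test mode passed to [mann_whitney()].
#' @return A `differential_table`: data.frame with one row per protein and
#'   columns `protein`, `effect` (median NPX difference), `ratio`
#'   (`2^effect`), `p_value`, `rejected`, `direction`; attributes `groups`,
#'   `q`, `n_a`, `n_b`.
#' @examples
#' sim <- simulate_cohort(simulation_config(seed = 3))
#' panel <- filter_by_detection(sim$matrix)$matrix
#' head(differential(panel, sim$meta, "NASH", "NAFL"))
#' @export
differential <- function(x, meta, group_a, group_b, q = 0.05,
                         mode = c("auto", "exact", "asymptotic")) {
  mode <- match.arg(mode)
  abort_if(!inherits(x, "npx_matrix"), "x must be an npx_matrix")
  meta <- sample_metadata(as.data.frame(meta))
  abort_if(!all(sample_ids(x) %in% meta$sample_id),
           "metadata does not cover all samples in the matrix")
  for (g in c(group_a, group_b)) {
    abort_if(!g %in% meta$group,
             sprintf("group label '%s' absent from metadata", g))
  }
  ids_a <- meta$sample_id[meta$group == group_a]
  ids_b <- meta$sample_id[meta$group == group_b]
  rows_a <- intersect(sample_ids(x), ids_a)
  rows_b <- intersect(sample_ids(x), ids_b)
  abort_if(length(rows_a) < 2 || length(rows_b) < 2,
           "both groups need at least 2 samples")
  differential_core(x$values[rows_a, , drop = FALSE],
                    x$values[rows_b, , drop = FALSE],
                    group_a, group_b, q, mode)
}

differential_core <- function(va, vb, label_a, label_b, q, mode = "auto") {
  proteins <- colnames(va)
  p_values <- vapply(seq_along(proteins), function(j)
    mann_whitney(va[, j], vb[, j], mode = mode)$p_value, numeric(1))
  effect <- apply(va, 2, stats::median) - apply(vb, 2, stats::median)
  fdr <- bky_two_stage(p_values, q = q)
  out <- data.frame(
    protein = proteins,
    effect = unname(effect),
    ratio = unname(2^effect),
    p_value = p_values,
    rejected = fdr$rejected,
    direction = ifelse(effect < 0, "down", "up"),
    stringsAsFactors = FALSE
  )
  attr(out, "groups") <- c(label_a, label_b)
  attr(out, "q") <- q
  attr(out, "n_a") <- nrow(va)
  attr(out, "n_b") <- nrow(vb)
  class(out) <- c("differential_table", class(out))
  out
}

#' Normalize an NPX matrix for heat-map display
#'
#' Linearizes NPX (2^NPX) and divides each protein by the linear-scale
#' median of a reference group, so the reference group's median maps to 1
#' for every protein.
#'
#' @param x an [npx_matrix()].
#' @param meta a [sample_metadata()].
#' @param reference_group the group whose medians define 1 (e.g. `"NAFL"`).
#' @return A numeric samples x proteins matrix on the linear scale.
#' @export
median_normalize_heatmap <- function(x, meta, reference_group) {
  abort_if(!inherits(x, "npx_matrix"), "x must be an npx_matrix")
  meta <- sample_metadata(as.data.frame(meta))
  ref_ids <- intersect(sample_ids(x),
                       meta$sample_id[meta$group == reference_group])
  abort_if(length(ref_ids) == 0, "reference group has no samples")
  lin <- 2^x$values
  ref_med <- apply(lin[ref_ids, , drop = FALSE], 2, stats::median)
  abort_if(any(ref_med <= 0), "degenerate reference median")
  sweep(lin, 2, ref_med, "/")
}

#' Stratification rules for confounder re-testing
#'
#' Defines the two-stratum split used to re-run the differential machinery
#' on a covariate instead of the disease groups. Built-in rules: `fibrosis`
#' (stage 0-1 vs 2-4), `bmi` (< 25 vs >= 25), `t2d` and `hypertension`
#' (no vs yes), `sex` (F vs M), `age` (below cohort median vs at/above;
#' the median split is an arbitrary but stated convention).
#'
#' @param covariate one of `"fibrosis"`, `"bmi"`, `"t2d"`,
#'   `"hypertension"`, `"sex"`, `"age"`.
#' @param patients_only restrict to NAFL/NASH patients (default `TRUE`,
#'   matching how comorbidity splits are defined on the patient cohort).
#' @return A `stratification_spec` list with `covariate`, `patients_only`
#'   and `rule(meta) -> factor` of two levels.
#' @export
stratification_spec <- function(covariate = c("fibrosis", "bmi", "t2d",
                                              "hypertension", "sex", "age"),
                                patients_only = TRUE) {
  covariate <- match.arg(covariate)
  rule <- switch(covariate,
    fibrosis = function(meta) factor(
      ifelse(meta$fibrosis <= 1, "low (0-1)", "high (2-4)"),
      levels = c("low (0-1)", "high (2-4)")),
    bmi = function(meta) factor(
      ifelse(meta$bmi < 25, "normal (<25)", "high (>=25)"),
      levels = c("normal (<25)", "high (>=25)")),
    t2d = function(meta) factor(
      ifelse(meta$t2d, "T2D", "no T2D"), levels = c("no T2D", "T2D")),
    hypertension = function(meta) factor(
      ifelse(meta$hypertension, "hypertension", "no hypertension"),
      levels = c("no hypertension", "hypertension")),
    sex = function(meta) factor(as.character(meta$sex), levels = c("F", "M")),
    age = function(meta) {
      med <- stats::median(meta$age)
      factor(ifelse(meta$age < med, "below median", "at/above median"),
             levels = c("below median", "at/above median"))
    }
  )
  structure(list(covariate = covariate, patients_only = patients_only,
                 rule = rule),
            class = "stratification_spec")
}

#' Confounder-stratified differential analysis
#'
#' Runs the identical per-protein Mann-Whitney + BKY machinery with the two
#' strata of a covariate split in place of the disease groups. BMI splits
#' cover the whole cohort by construction (controls are the normal-BMI
#' stratum); other comorbidity splits default to patients only.
#'
#' @param x a detection-filtered [npx_matrix()].
#' @param meta a [sample_metadata()].
#' @param spec a [stratification_spec()].
#' @inheritParams differential
#' @return A `differential_table` (effect is stratum 2 minus stratum 1,
#'   e.g. high fibrosis minus low fibrosis) with attribute `stratification`.
#' @export
stratified_differential <- function(x, meta, spec, q = 0.05,
                                    mode = c("auto", "exact", "asymptotic")) {
  mode <- match.arg(mode)
  abort_if(!inherits(spec, "stratification_spec"),
           "spec must come from stratification_spec()")
  meta <- sample_metadata(as.data.frame(meta))
  use <- if (spec$patients_only && spec$covariate != "bmi") {
    meta[meta$group != "HC", , drop = FALSE]
  } else meta
  strata <- spec$rule(use)
  abort_if(nlevels(strata) != 2, "stratification rule must yield two strata")
  ids_1 <- use$sample_id[strata == levels(strata)[1]]
  ids_2 <- use$sample_id[strata == levels(strata)[2]]
  rows_1 <- intersect(sample_ids(x), ids_1)
  rows_2 <- intersect(sample_ids(x), ids_2)
  abort_if(length(rows_1) < 2 || length(rows_2) < 2,
           sprintf("empty or too-small stratum for covariate '%s'",
                   spec$covariate))
  out <- differential_core(x$values[rows_2, , drop = FALSE],
                           x$values[rows_1, , drop = FALSE],
                           levels(strata)[2], levels(strata)[1], q, mode)
  attr(out, "stratification") <- spec$covariate
  out
}
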