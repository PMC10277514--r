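# End-to-end pipeline: filter -> differential -> stratified -> panel ->
# co-expression -> subgroup discovery, each stage writing plain-text
# outputs plus a machine-readable run manifest. All randomness flows from
# one root seed through per-stage derived seeds.

#' Pipeline configuration
#'
#' @param group_case,group_control the disease contrast (defaults NASH vs
#'   NAFL).
#' @param q FDR level used everywhere, default 0.05.
#' @param specificity_targets per-protein thresholding targets, default
#'   `c(0.76, 0.90)`.
#' @param panel_max_size logistic subset-selection size cap, default 6.
#' @param panel_pool optional candidate pool for the combined panel
#'   (default: proteins rejected in the case/control volcano).
#' @param stratifications covariates to re-test, default fibrosis, bmi,
#'   t2d, hypertension, sex, age.
#' @param coexpr_contrasts list of group pairs for residual co-expression,
#'   default NASH-NAFL and NASH-HC.
#' @param subgroup_k flat cluster count for marker-based subgroup
#'   discovery, default 8.
#' @param n_permutations random-cluster null size, default 200.
#' @param seed root RNG seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(group_case = "NASH", group_control = "NAFL",
                            q = 0.05, specificity_targets = c(0.76, 0.90),
                            panel_max_size = 6, panel_pool = NULL,
                            stratifications = c("fibrosis", "bmi", "t2d",
                                                "hypertension", "sex", "age"),
                            coexpr_contrasts = list(c("NASH", "NAFL"),
                                                    c("NASH", "HC")),
                            subgroup_k = 8, n_permutations = 200, seed = 1) {
  abort_if(!is.numeric(q) || q <= 0 || q >= 1, "q must lie in (0,1)")
  abort_if(any(specificity_targets <= 0 | specificity_targets >= 1),
           "specificity targets must lie in (0,1)")
  structure(
    list(group_case = group_case, group_control = group_control, q = q,
         specificity_targets = specificity_targets,
         panel_max_size = panel_max_size, panel_pool = panel_pool,
         stratifications = stratifications,
         coexpr_contrasts = coexpr_contrasts, subgroup_k = subgroup_k,
         n_permutations = n_permutations, seed = seed),
    class = "pipeline_config"
  )
}

write_diff_table <- function(tab, path) {
  df <- as.data.frame(tab)
  df$effect <- fmt_num(df$effect)
  df$ratio <- fmt_num(df$ratio)
  df$p_value <- fmt_num(df$p_value)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the full serum-panel pipeline
#'
#' Executes detection filtering, the case/control volcano, confounder
#' stratifications, the fixed-specificity k-of-n panel with logistic subset
#' selection, residual co-expression clustering, and (when a transcriptome
#' matrix is supplied) marker-based subgroup discovery with its
#' random-cluster null. Per-stage TSV/JSON outputs and a manifest are
#' written under `out_dir`; numeric formatting is deterministic, so a rerun
#' with the same inputs and seed is byte-identical.
#'
#' @param x an [npx_matrix()] (unfiltered measured panel).
#' @param meta a [sample_metadata()].
#' @param config a [pipeline_config()].
#' @param out_dir output directory, created if needed.
#' @param transcriptome optional samples x genes matrix for subgroup
#'   discovery; markers default to the selected panel proteins present in
#'   its columns.
#' @param transcriptome_markers optional explicit marker set.
#' @return Invisibly, a list with every stage result (`filtered`,
#'   `differential`, `stratified`, `panel`, `coexpression`, `subgroups`,
#'   `manifest`).
#' @export
run_pipeline <- function(x, meta, config = pipeline_config(),
                         out_dir, transcriptome = NULL,
                         transcriptome_markers = NULL) {
  abort_if(!inherits(config, "pipeline_config"),
           "config must come from pipeline_config()")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  res <- list()

  res$filtered <- stage("filter", filter_by_detection(x))
  panel <- res$filtered$matrix
  writeLines(res$filtered$excluded,
             file.path(out_dir, "excluded_proteins.txt"))

  res$differential <- stage("differential",
    differential(panel, meta, config$group_case, config$group_control,
                 q = config$q))
  write_diff_table(res$differential,
                   file.path(out_dir, "differential.tsv"))

  res$stratified <- stage("stratified", {
    out <- lapply(config$stratifications, function(cv)
      stratified_differential(panel, meta, stratification_spec(cv),
                              q = config$q))
    names(out) <- config$stratifications
    out
  })
  for (cv in names(res$stratified)) {
    write_diff_table(res$stratified[[cv]],
                     file.path(out_dir, sprintf("stratified_%s.tsv", cv)))
  }

  res$panel <- stage("panel", {
    meta_v <- sample_metadata(as.data.frame(meta))
    use_ids <- meta_v$sample_id[meta_v$group %in%
                                  c(config$group_case, config$group_control)]
    sub <- subset_npx(panel, samples = intersect(sample_ids(panel), use_ids))
    labels <- meta_v$group[match(sample_ids(sub), meta_v$sample_id)] ==
      config$group_case
    pool <- config$panel_pool
    if (is.null(pool)) pool <- res$differential$protein[res$differential$rejected]
    abort_if(length(pool) == 0, "no panel candidates (no rejected proteins)")
    per_target <- lapply(config$specificity_targets, function(tg) {
      tests <- derive_panel_tests(sub, labels, tg, proteins = pool,
                                  diff_table = res$differential)
      evaluate_k_of_n(tests, sub, labels)
    })
    names(per_target) <- sprintf("sp%02.0f", 100 * config$specificity_targets)
    selection <- select_subset_logistic(sub, labels, candidates = pool,
                                        max_size = config$panel_max_size)
    list(rules = per_target, selection = selection, labels = labels,
         samples = sample_ids(sub))
  })
  op <- do.call(rbind, lapply(names(res$panel$rules), function(nm) {
    cbind(target = nm, res$panel$rules[[nm]]$operating_points)
  }))
  op$sensitivity <- fmt_num(op$sensitivity)
  op$specificity <- fmt_num(op$specificity)
  utils::write.table(op, file.path(out_dir, "panel_operating_points.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  panel_json <- list(
    selected = res$panel$selection$selected,
    criterion = res$panel$selection$criterion,
    criterion_value = res$panel$selection$criterion_value,
    separation = res$panel$selection$separation,
    tests = lapply(res$panel$rules, function(rule)
      lapply(rule$tests, function(t)
        t[c("protein", "direction", "threshold", "specificity",
            "sensitivity", "target")]))
  )
  jsonlite::write_json(panel_json, file.path(out_dir, "panel_rule.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  res$coexpression <- stage("coexpression", {
    lapply(config$coexpr_contrasts, function(ct) {
      ca <- group_correlation(panel, meta, ct[1])
      cb <- group_correlation(panel, meta, ct[2])
      rm <- cluster_residuals(residual_matrix(ca, cb))
      list(contrast = rm$contrast, residual = rm,
           summary = cluster_enrichment_summary(rm, ca, cb))
    })
  })
  for (cx in res$coexpression) {
    utils::write.table(
      round(cx$residual$residual, 10),
      file.path(out_dir, sprintf("residual_%s.tsv", cx$contrast)),
      sep = "\t", quote = FALSE)
    jsonlite::write_json(
      cx$residual$cluster_members,
      file.path(out_dir, sprintf("residual_clusters_%s.json", cx$contrast)),
      auto_unbox = FALSE, pretty = TRUE)
  }

  if (!is.null(transcriptome)) {
    res$subgroups <- stage("subgroups", {
      markers <- transcriptome_markers
      if (is.null(markers)) {
        markers <- intersect(res$panel$selection$selected,
                             colnames(transcriptome))
      }
      abort_if(length(markers) == 0,
               "no subgroup markers present in the transcriptome matrix")
      part <- cluster_samples_on_markers(transcriptome, markers,
                                         config$subgroup_k)
      degs <- pairwise_deg(transcriptome, part, q = config$q)
      null <- random_cluster_null(
        transcriptome, part$sizes[part$sizes >= 3],
        n_permutations = config$n_permutations, q = config$q,
        seed = derive_seed(config$seed, "subgroup_null"))
      list(partition = part, degs = degs, null = null)
    })
    jsonlite::write_json(
      as.list(res$subgroups$partition$labels),
      file.path(out_dir, "subgroup_partition.json"),
      auto_unbox = TRUE, pretty = TRUE)
    utils::write.table(
      res$subgroups$degs$counts,
      file.path(out_dir, "subgroup_deg_counts.tsv"),
      sep = "\t", quote = FALSE)
    jsonlite::write_json(
      list(max_count_p95 = res$subgroups$null$percentile(0.95),
           n_permutations = res$subgroups$null$n_permutations),
      file.path(out_dir, "subgroup_null.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
  }

  res$manifest <- list(
    package_version = as.character(utils::packageVersion("serosig")),
    seed = config$seed,
    q = config$q,
    groups = c(config$group_case, config$group_control),
    n_samples = nrow(x$values),
    n_proteins_measured = ncol(x$values),
    n_proteins_analyzed = ncol(panel$values),
    excluded = res$filtered$excluded,
    specificity_targets = config$specificity_targets,
    n_rejected = sum(res$differential$rejected),
    selected_panel = res$panel$selection$selected
  )
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Write simulated data to disk
#'
#' Writes the wide TSV matrix (with its below-LOD sibling), the long CSV,
#' the metadata TSV, and a ground-truth JSON.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_wide_npx(sim$matrix, file.path(dir, "npx_wide.tsv"))
  write_long_npx(sim$matrix, file.path(dir, "npx_long.csv"))
  write_metadata(sim$meta, file.path(dir, "metadata.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Volcano plot of a differential table
#'
#' Effect (median NPX difference, i.e. log2 ratio) against -log10 p, with
#' FDR-rejected proteins highlighted.
#'
#' @param tab a `differential_table`.
#' @param ... passed to [plot()].
#' @return Invisibly, `tab`.
#' @export
plot_volcano <- function(tab, ...) {
  groups <- attr(tab, "groups")
  cols <- ifelse(!tab$rejected, "grey50",
                 ifelse(tab$direction == "up", "firebrick", "forestgreen"))
  plot(tab$effect, -log10(tab$p_value), pch = 19, col = cols,
       xlab = sprintf("median NPX difference (%s - %s)",
                      groups[1], groups[2]),
       ylab = expression(-log[10](p)), ...)
  graphics::abline(h = -log10(0.05), lty = 2, col = "blue")
  invisible(tab)
}
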