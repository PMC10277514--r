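# Synthetic cohort generator.
#
# The generator states a world with the structure the analysis assumes:
# three groups (healthy controls and two patient groups) on a multiplex
# NPX panel, group-wise multivariate normal on the NPX scale with
# block-exchangeable correlation, planted NASH-vs-NAFL mean shifts,
# left-censoring at a per-protein LOD floor, and comorbidity covariates at
# stated prevalences. NPX is log2-like and every downstream test is
# rank-based, so the normal marginal family is a convenience, not a claim.

#' Simulation configuration for the serum-panel cohort
#'
#' Defaults encode the reference cohort design: 15 healthy controls (HC),
#' 35 NAFL and 35 NASH patients on a 92-protein inflammation panel; 13
#' proteins shifted in NASH relative to NAFL and HC (11 down, 2 up); one
#' 5-protein correlation block present only in NASH (rho = 0.6); 25
#' never-detected proteins plus 4 proteins censored in 20% of samples, so
#' the >90% detection filter retains 63 of 92; hypertension prevalence
#' 29/70 and type-2-diabetes prevalence 25/70 among patients (controls are
#' screened healthy); BMI < 25 for controls and > 25 for patients. Planted
#' shift magnitudes are not reported by any reference and default to 1.5
#' NPX (about 2.8-fold), a strong but assay-realistic cytokine effect.
#'
#' @param n_hc,n_nafl,n_nash cohort sizes.
#' @param n_proteins panel width.
#' @param planted_down named numeric vector: protein index -> negative NPX
#'   shift applied to NASH samples.
#' @param planted_up named numeric vector: protein index -> positive shift.
#' @param corr_blocks list of blocks, each `list(group =, proteins = integer
#'   indices, rho = correlation)`.
#' @param lod_censored list of `list(protein = index, fraction = in [0,1])`;
#'   for each, the `round(fraction * n)` smallest values across all samples
#'   are floored at the protein's LOD and flagged.
#' @param covariate_prevalences named numeric vector with entries
#'   `hypertension` and `t2d`, prevalences among patients.
#' @param confounders optional list of `list(covariate =, proteins = indices,
#'   shift = NPX units)`: samples with the covariate get the shift added to
#'   the named proteins (the "confounded mode" used to exercise stratified
#'   re-testing).
#' @param noise_sd per-protein NPX standard deviation, default 1.
#' @param seed integer RNG seed; generation is a pure function of the
#'   configuration including this seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_hc = 15, n_nafl = 35, n_nash = 35,
                              n_proteins = 92,
                              planted_down = stats::setNames(
                                rep(-1.5, 11), 1:11),
                              planted_up = stats::setNames(
                                rep(1.5, 2), 12:13),
                              corr_blocks = list(
                                list(group = "NASH", proteins = 20:24,
                                     rho = 0.6)),
                              lod_censored = c(
                                lapply(64:88, function(i)
                                  list(protein = i, fraction = 1.0)),
                                lapply(89:92, function(i)
                                  list(protein = i, fraction = 0.2))),
                              covariate_prevalences = c(
                                hypertension = 29 / 70, t2d = 25 / 70),
                              confounders = NULL,
                              noise_sd = 1, seed = 1) {
  abort_if(!is_count(n_hc) || !is_count(n_nafl) || !is_count(n_nash),
           "cohort sizes must be nonnegative integers")
  abort_if(!is_count(n_proteins) || n_proteins < 1,
           "n_proteins must be a positive integer")
  down_idx <- as.integer(names(planted_down))
  up_idx <- as.integer(names(planted_up))
  abort_if(length(planted_down) > 0 && any(planted_down >= 0),
           "planted_down shifts must be negative")
  abort_if(length(planted_up) > 0 && any(planted_up <= 0),
           "planted_up shifts must be positive")
  abort_if(length(intersect(down_idx, up_idx)) > 0,
           "planted up/down protein sets must be disjoint")
  abort_if(any(c(down_idx, up_idx) > n_proteins),
           "planted protein index exceeds n_proteins")
  for (blk in corr_blocks) {
    abort_if(!blk$group %in% GROUP_LEVELS, "block group must be HC/NAFL/NASH")
    abort_if(any(blk$proteins > n_proteins), "block protein index out of range")
    abort_if(abs(blk$rho) > 1, "block correlation must lie in [-1,1]")
  }
  for (cen in lod_censored) {
    abort_if(!is_proportion(cen$fraction),
             "censored fraction must lie in [0,1]")
    abort_if(cen$protein > n_proteins, "censored protein index out of range")
  }
  abort_if(!is.numeric(noise_sd) || noise_sd <= 0, "noise_sd must be > 0")
  structure(
    list(n_hc = n_hc, n_nafl = n_nafl, n_nash = n_nash,
         n_proteins = n_proteins, planted_down = planted_down,
         planted_up = planted_up, corr_blocks = corr_blocks,
         lod_censored = lod_censored,
         covariate_prevalences = covariate_prevalences,
         confounders = confounders, noise_sd = noise_sd, seed = seed),
    class = "simulation_config"
  )
}

# Assemble one group's correlation matrix from its blocks; reject a block
# whose addition makes the matrix non-positive-semi-definite.
build_group_correlation <- function(config, group) {
  p <- config$n_proteins
  sigma <- diag(p)
  for (bi in seq_along(config$corr_blocks)) {
    blk <- config$corr_blocks[[bi]]
    if (blk$group != group) next
    idx <- blk$proteins
    sigma[idx, idx] <- blk$rho
    diag(sigma)[idx] <- 1
    ev <- eigen(sigma[idx, idx], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      stop(sprintf(
        "correlation block %d (group %s, rho = %g over %d proteins) is not positive semi-definite",
        bi, group, blk$rho, length(idx)), call. = FALSE)
    }
  }
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  abort_if(min(ev) < -1e-8,
           sprintf("assembled correlation matrix for group %s is not positive semi-definite (overlapping blocks?)",
                   group))
  sigma
}

#' Simulate a serum-panel cohort
#'
#' Draws the cohort described by a [simulation_config()]: group-wise
#' multivariate normal NPX values with planted NASH shifts and correlation
#' blocks, LOD left-censoring (the configured fraction of smallest values
#' per protein is floored at that protein's realized LOD and flagged), and
#' a clinical metadata table with histology scores and comorbidities.
#'
#' @param config a [simulation_config()].
#' @return A list with `matrix` (an [npx_matrix()]), `meta` (a
#'   [sample_metadata()]) and `truth`: list with `true_differential`
#'   (named direction vector, `"down"`/`"up"`, by protein id),
#'   `true_coexpr_blocks` (the planted blocks with protein ids), and
#'   `true_subgroup_labels` (`NULL` here; used by the transcriptome
#'   generator).
#' @examples
#' sim <- simulate_cohort(simulation_config(seed = 7))
#' dim(sim$matrix)
#' @export
simulate_cohort <- function(config) {
  abort_if(!inherits(config, "simulation_config"),
           "config must come from simulation_config()")
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  n_tot <- config$n_hc + config$n_nafl + config$n_nash
  abort_if(n_tot < 1, "empty cohort")
  p <- config$n_proteins
  groups <- rep(GROUP_LEVELS, c(config$n_hc, config$n_nafl, config$n_nash))
  sample_id <- sprintf("S%03d", seq_len(n_tot))
  protein_id <- sprintf("P%02d", seq_len(p))

  baseline <- stats::runif(p, 2, 10)  # per-protein NPX location

  chol_by_group <- lapply(GROUP_LEVELS, function(g)
    chol(build_group_correlation(config, g)))
  names(chol_by_group) <- GROUP_LEVELS

  values <- matrix(NA_real_, n_tot, p, dimnames = list(sample_id, protein_id))
  for (g in GROUP_LEVELS) {
    rows <- which(groups == g)
    if (length(rows) == 0) next
    z <- matrix(stats::rnorm(length(rows) * p), length(rows), p)
    values[rows, ] <- z %*% chol_by_group[[g]] * config$noise_sd
  }
  values <- sweep(values, 2, baseline, "+")

  nash_rows <- which(groups == "NASH")
  for (set in list(config$planted_down, config$planted_up)) {
    if (length(set) == 0) next
    idx <- as.integer(names(set))
    values[nash_rows, idx] <- sweep(values[nash_rows, idx, drop = FALSE],
                                    2, set, "+")
  }

  meta <- simulate_metadata(config, groups, sample_id)

  if (!is.null(config$confounders)) {
    for (cf in config$confounders) {
      abort_if(!cf$covariate %in% names(meta),
               sprintf("unknown confounder covariate '%s'", cf$covariate))
      hit <- which(as.logical(meta[[cf$covariate]]))
      values[hit, cf$proteins] <- values[hit, cf$proteins, drop = FALSE] +
        cf$shift
    }
  }

  mask <- matrix(FALSE, n_tot, p, dimnames = dimnames(values))
  for (cen in config$lod_censored) {
    m <- round(cen$fraction * n_tot)
    if (m == 0) next
    j <- cen$protein
    ord <- order(values[, j])
    lod <- values[ord[m], j]  # realized LOD = m-th smallest value
    values[ord[seq_len(m)], j] <- lod
    mask[ord[seq_len(m)], j] <- TRUE
  }

  truth <- list(
    true_differential = stats::setNames(
      c(rep("down", length(config$planted_down)),
        rep("up", length(config$planted_up))),
      protein_id[as.integer(c(names(config$planted_down),
                              names(config$planted_up)))]),
    true_coexpr_blocks = lapply(config$corr_blocks, function(blk)
      list(group = blk$group, proteins = protein_id[blk$proteins],
           rho = blk$rho)),
    true_subgroup_labels = NULL
  )

  list(matrix = npx_matrix(values, mask), meta = meta, truth = truth)
}

# Clinical covariates. Controls are screened healthy (no T2D, BMI < 25, no
# fibrosis, NAS 0); patient comorbidity prevalences come from the config.
# NASH is defined by NAS >= 5; NAFL draws NAS 1..4. Fibrosis skews higher
# in NASH so that a 0-1 vs 2-4 split lands near half/half over patients.
simulate_metadata <- function(config, groups, sample_id) {
  n <- length(groups)
  patient <- groups != "HC"
  prev <- config$covariate_prevalences
  hyp <- rep(FALSE, n)
  t2d <- rep(FALSE, n)
  hyp[patient] <- stats::runif(sum(patient)) < prev[["hypertension"]]
  t2d[patient] <- stats::runif(sum(patient)) < prev[["t2d"]]
  bmi <- ifelse(patient, stats::runif(n, 25.5, 38), stats::runif(n, 20, 24.9))
  age <- round(stats::runif(n, 30, 70))
  sex <- ifelse(stats::runif(n) < 0.5, "F", "M")
  nas <- integer(n)
  nas[groups == "NAFL"] <- sample(1:4, sum(groups == "NAFL"), replace = TRUE)
  nas[groups == "NASH"] <- sample(5:8, sum(groups == "NASH"), replace = TRUE)
  sub <- t(vapply(nas, split_nas, integer(3)))
  fib <- integer(n)
  fib[groups == "NAFL"] <- sample(0:4, sum(groups == "NAFL"), replace = TRUE,
                                  prob = c(0.35, 0.35, 0.15, 0.10, 0.05))
  fib[groups == "NASH"] <- sample(0:4, sum(groups == "NASH"), replace = TRUE,
                                  prob = c(0.10, 0.20, 0.30, 0.25, 0.15))
  sample_metadata(data.frame(
    sample_id = sample_id, group = groups, fibrosis = fib, nas = nas,
    steatosis = sub[, 1], lobular_inflammation = sub[, 2],
    ballooning = sub[, 3], t2d = t2d, hypertension = hyp, bmi = round(bmi, 1),
    age = age, sex = sex, stringsAsFactors = FALSE
  ))
}

# Random decomposition of a NAS total into steatosis (0-3), lobular
# inflammation (0-3) and ballooning (0-2) subscores summing to it.
split_nas <- function(total) {
  if (total == 0) return(c(0L, 0L, 0L))
  repeat {
    s <- sample(0:3, 1)
    l <- sample(0:3, 1)
    b <- total - s - l
    if (b >= 0 && b <= 2) return(as.integer(c(s, l, b)))
  }
}

#' Simulate a transcriptome cohort with planted patient subgroups
#'
#' Test bed for marker-based subgroup discovery: `n_subgroups` patient
#' subgroups separate in the space of `marker_genes` (subgroup centers are
#' distinct binary patterns scaled by `marker_sep`, so every pair of
#' centers is at least `marker_sep` apart), and each subgroup carries
#' `deg_per_pair / 2` dedicated non-marker genes shifted by `deg_shift`
#' standard deviations, so every subgroup pair differs in exactly
#' `deg_per_pair` non-marker genes. All other genes are exchangeable noise.
#'
#' @param n_samples number of samples (default 104, the size of a typical
#'   NASH liver-biopsy transcriptome re-analysis cohort).
#' @param n_genes total genes including markers (default 2000).
#' @param marker_genes character vector of marker gene names (default six
#'   markers, mirroring a six-protein serum signature).
#' @param n_subgroups number of planted subgroups, `>= 2` and at most
#'   `2^length(marker_genes)`.
#' @param deg_per_pair even count of genes differing between each subgroup
#'   pair (default 50).
#' @param deg_shift planted shift in units of the noise SD (default 2).
#' @param marker_sep marker-space separation scale in SD units. The
#'   generator's contract is that subgroups *separate* in marker space;
#'   the default 6 keeps per-sample assignment ambiguity negligible
#'   (overlap ~ Phi(-3)), which is what "separate" means operationally.
#'   Smaller values deliberately degrade separability for robustness
#'   studies.
#' @param seed integer RNG seed.
#' @return list with `matrix` (samples x genes), `truth`: list with
#'   `true_subgroup_labels` (integer per sample), `true_deg` (named list,
#'   `"i|j"` -> character vector of the planted genes differing between
#'   subgroups i and j), and `subgroup_genes` (per-subgroup planted sets).
#' @export
simulate_subgrouped_transcriptome <- function(n_samples = 104,
                                              n_genes = 2000,
                                              marker_genes = sprintf("MK%d", 1:6),
                                              n_subgroups = 4,
                                              deg_per_pair = 50,
                                              deg_shift = 2,
                                              marker_sep = 6,
                                              seed = 1) {
  abort_if(n_subgroups < 2, "need at least 2 subgroups")
  abort_if(n_subgroups > 2^length(marker_genes),
           "too many subgroups for the marker space")
  abort_if(deg_per_pair %% 2 != 0,
           "deg_per_pair must be even (half planted in each subgroup)")
  n_markers <- length(marker_genes)
  n_noise <- n_genes - n_markers
  abort_if(n_noise < n_subgroups * deg_per_pair / 2,
           "deg_per_pair exceeds available non-marker genes")
  with_seed(seed, {
    genes <- c(marker_genes, sprintf("G%04d", seq_len(n_noise)))
    labels <- rep(seq_len(n_subgroups), length.out = n_samples)
    labels <- sort(labels)
    # subgroup centers in marker space: distinct binary codes * marker_sep
    codes <- t(vapply(seq_len(n_subgroups) - 1L, function(g)
      as.integer(intToBits(g))[seq_len(n_markers)], integer(n_markers)))
    centers <- codes * marker_sep
    x <- matrix(stats::rnorm(n_samples * n_genes), n_samples, n_genes,
                dimnames = list(sprintf("T%03d", seq_len(n_samples)), genes))
    x[, seq_len(n_markers)] <- x[, seq_len(n_markers)] +
      centers[labels, , drop = FALSE]
    per_sub <- deg_per_pair / 2
    sub_genes <- vector("list", n_subgroups)
    if (per_sub > 0) {
      pool <- sample(n_noise)  # dedicated, disjoint planted sets
      for (g in seq_len(n_subgroups)) {
        take <- pool[seq.int((g - 1) * per_sub + 1, g * per_sub)]
        cols <- n_markers + take
        sub_genes[[g]] <- genes[cols]
        x[labels == g, cols] <- x[labels == g, cols] + deg_shift
      }
    } else {
      sub_genes <- replicate(n_subgroups, character(0), simplify = FALSE)
    }
    pairs <- utils::combn(n_subgroups, 2)
    true_deg <- stats::setNames(
      lapply(seq_len(ncol(pairs)), function(ix)
        c(sub_genes[[pairs[1, ix]]], sub_genes[[pairs[2, ix]]])),
      apply(pairs, 2, paste, collapse = "|"))
    list(matrix = x,
         truth = list(true_subgroup_labels = stats::setNames(labels, rownames(x)),
                      true_deg = true_deg,
                      subgroup_genes = sub_genes))
  })
}
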