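# Synthetic-data generator: reproducibility, realized structure, planted
# signal strength.

test_that("default configuration states the reference cohort", {
  sim <- simulate_cohort(simulation_config())
  expect_equal(as.vector(table(sim$meta$group)), c(15, 35, 35))
  expect_equal(dim(sim$matrix), c(85, 92))
  expect_equal(sum(sim$truth$true_differential == "down"), 11)
  expect_equal(sum(sim$truth$true_differential == "up"), 2)
  # controls are screened healthy
  hc <- sim$meta[sim$meta$group == "HC", ]
  expect_true(all(!hc$t2d & hc$bmi < 25 & hc$nas == 0))
  # NASH defined by NAS >= 5
  expect_true(all(sim$meta$nas[sim$meta$group == "NASH"] >= 5))
  expect_true(all(sim$meta$nas[sim$meta$group == "NAFL"] <= 4))
})

test_that("generation is a pure function of config + seed", {
  a <- simulate_cohort(simulation_config(seed = 99))
  b <- simulate_cohort(simulation_config(seed = 99))
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$matrix$below_lod, b$matrix$below_lod)
  expect_identical(as.data.frame(a$meta), as.data.frame(b$meta))
  c <- simulate_cohort(simulation_config(seed = 100))
  expect_false(identical(a$matrix$values, c$matrix$values))
  # simulation does not disturb the caller's RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(simulate_cohort(simulation_config(seed = 3)))
  expect_identical(rnorm(1), before)
})

test_that("planted shifts apply only to NASH rows", {
  cfg <- simulation_config(seed = 17, lod_censored = list())
  sim <- simulate_cohort(cfg)
  cfg0 <- simulation_config(seed = 17, lod_censored = list(),
                            planted_down = setNames(-1e-9, 1),
                            planted_up = setNames(1e-9, 2))
  sim0 <- simulate_cohort(cfg0)
  nash <- sim$meta$group == "NASH"
  # non-NASH rows identical between the shifted and unshifted worlds
  expect_equal(sim$matrix$values[!nash, ], sim0$matrix$values[!nash, ])
  # NASH rows shifted by the configured amount on planted proteins
  expect_equal(sim$matrix$values[nash, "P01"] - sim0$matrix$values[nash, "P01"],
               rep(-1.5, sum(nash)), ignore_attr = TRUE)
})

test_that("censoring floors the configured fraction within one sample", {
  sim <- simulate_cohort(simulation_config(seed = 23))
  n <- nrow(sim$matrix$values)
  frac <- colMeans(sim$matrix$below_lod)
  expect_true(all(abs(frac[sprintf("P%02d", 64:88)] - 1) * n <= 1))
  expect_true(all(abs(frac[sprintf("P%02d", 89:92)] - 0.2) * n <= 1))
  expect_true(all(frac[sprintf("P%02d", 1:63)] == 0))
  # censored entries sit at the per-protein floor
  j <- "P89"
  flags <- sim$matrix$below_lod[, j]
  lod <- unique(sim$matrix$values[flags, j])
  expect_length(lod, 1)
  expect_true(all(sim$matrix$values[!flags, j] >= lod))
})

test_that("realized block correlation approaches the configured value", {
  cfg <- simulation_config(n_hc = 0, n_nafl = 0, n_nash = 1200,
                           planted_down = setNames(numeric(0), integer(0)),
                           planted_up = setNames(numeric(0), integer(0)),
                           n_proteins = 10,
                           corr_blocks = list(list(group = "NASH",
                                                   proteins = 1:4, rho = 0.5)),
                           lod_censored = list(), seed = 31)
  sim <- simulate_cohort(cfg)
  cc <- spearman(sim$matrix$values[, 1], sim$matrix$values[, 2])
  # Spearman of a bivariate normal: 6/pi * asin(rho/2)
  expect_lt(abs(cc - 6 / pi * asin(0.25)), 0.05)
  off <- spearman(sim$matrix$values[, 1], sim$matrix$values[, 5])
  expect_lt(abs(off), 0.05)
})

test_that("non-PSD correlation blocks are rejected by name", {
  cfg <- simulation_config(
    corr_blocks = list(list(group = "NASH", proteins = 1:5, rho = -0.5)),
    seed = 1)
  expect_error(simulate_cohort(cfg), "block 1.*not positive semi-definite")
})

test_that("a large planted shift is essentially always detected", {
  # -3 NPX on one protein, noise 1, n = 35/35: Mann-Whitney p < 1e-6 in
  # at least 95% of 200 seeds (Monte-Carlo power oracle)
  hits <- vapply(1:200, function(s) {
    cfg <- simulation_config(n_hc = 0, n_proteins = 2,
                             planted_down = setNames(-3, 1),
                             planted_up = setNames(numeric(0), integer(0)),
                             corr_blocks = list(), lod_censored = list(),
                             seed = s)
    sim <- simulate_cohort(cfg)
    nafl <- sim$meta$group == "NAFL"
    p <- mann_whitney(sim$matrix$values[!nafl, 1],
                      sim$matrix$values[nafl, 1])$p_value
    p < 1e-6
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("subgrouped transcriptome plants the stated structure", {
  sim <- simulate_subgrouped_transcriptome(seed = 3)
  expect_equal(dim(sim$matrix), c(104, 2000))
  expect_equal(length(unique(sim$truth$true_subgroup_labels)), 4)
  # each pair differs in exactly deg_per_pair dedicated genes
  expect_true(all(lengths(sim$truth$true_deg) == 50))
  expect_equal(length(sim$truth$true_deg), choose(4, 2))
  # planted sets are disjoint across subgroups
  all_genes <- unlist(sim$truth$subgroup_genes)
  expect_equal(anyDuplicated(all_genes), 0)
  # reproducible
  sim2 <- simulate_subgrouped_transcriptome(seed = 3)
  expect_identical(sim$matrix, sim2$matrix)
  # error contracts
  expect_error(simulate_subgrouped_transcriptome(n_genes = 30,
                                                 deg_per_pair = 100),
               "exceeds")
  expect_error(simulate_subgrouped_transcriptome(n_subgroups = 1), "at least 2")
})

test_that("null subgrouped transcriptome yields no spurious DEGs", {
  sim <- simulate_subgrouped_transcriptome(n_samples = 40, n_genes = 400,
                                           n_subgroups = 2, deg_per_pair = 0,
                                           seed = 9)
  part <- cluster_samples_on_markers(sim$matrix, sprintf("MK%d", 1:6), k = 2)
  expect_gte(adjusted_rand_index(part$labels,
                                 sim$truth$true_subgroup_labels), 0.9)
  degs <- pairwise_deg(sim$matrix, part)
  expect_lte(max(degs$counts), 4)  # ~1% of genes
})
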