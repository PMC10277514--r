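# Residual co-expression: group matrices, residuals, clustering,
# summaries.

# moderately sized world with one NASH-specific correlation block, used by
# several tests below (n = 100 per patient group keeps Spearman sampling
# noise ~0.1, well under the planted 0.6 contrast)
coexpr_cfg <- function(seed, n = 100, rho = 0.6) {
  simulation_config(
    n_hc = 0, n_nafl = n, n_nash = n, n_proteins = 45,
    planted_down = stats::setNames(numeric(0), integer(0)),
    planted_up = stats::setNames(numeric(0), integer(0)),
    corr_blocks = list(list(group = "NASH", proteins = 1:5, rho = rho)),
    lod_censored = list(), seed = seed)
}

sim_cx <- simulate_cohort(coexpr_cfg(401))

test_that("group_correlation: structure and estimation", {
  ca <- group_correlation(sim_cx$matrix, sim_cx$meta, "NASH")
  expect_equal(unname(diag(ca$corr)), rep(1, 45))
  expect_equal(ca$corr, t(ca$corr))
  expect_true(all(abs(ca$corr) <= 1))
  # permuting sample order leaves the matrix unchanged
  perm <- sample(nrow(sim_cx$matrix$values))
  x_perm <- npx_matrix(sim_cx$matrix$values[perm, ],
                       sim_cx$matrix$below_lod[perm, ])
  cb <- group_correlation(x_perm, sim_cx$meta, "NASH")
  expect_equal(ca$corr, cb$corr)
  expect_error(group_correlation(sim_cx$matrix, sim_cx$meta, "HC"),
               "fewer than 4")
})

test_that("block correlation is estimated within +-0.05 at n = 1000", {
  sim_big <- simulate_cohort(coexpr_cfg(402, n = 1000))
  cc <- group_correlation(sim_big$matrix, sim_big$meta, "NASH")
  block <- cc$corr[1:5, 1:5][upper.tri(matrix(0, 5, 5))]
  # Gaussian copula: population Spearman of rho = 0.6 is 6/pi*asin(0.3);
  # the realized within-block correlation (block average) is within 0.05
  expect_lt(abs(mean(block) - 6 / pi * asin(0.3)), 0.05)
  expect_true(all(abs(block - 6 / pi * asin(0.3)) < 0.1))
})

test_that("residual_matrix contracts", {
  ca <- group_correlation(sim_cx$matrix, sim_cx$meta, "NASH")
  cb <- group_correlation(sim_cx$matrix, sim_cx$meta, "NAFL")
  r <- residual_matrix(ca, cb)
  expect_equal(unname(diag(r$residual)), rep(0, 45))
  expect_equal(r$residual, t(r$residual))
  expect_true(all(abs(r$residual) <= 2, na.rm = TRUE))
  expect_equal(r$contrast, "NASH-NAFL")
  # same group twice -> all-zero residual
  r0 <- residual_matrix(ca, ca)
  expect_true(all(r0$residual == 0))
  # antisymmetry
  r_ba <- residual_matrix(cb, ca)
  expect_equal(r$residual, -r_ba$residual)
  # planted block entries near the population contrast (residual sampling
  # noise at n = 100 per group is ~0.14 per entry)
  block <- r$residual[1:5, 1:5][upper.tri(matrix(0, 5, 5))]
  expect_lt(abs(mean(block) - 6 / pi * asin(0.3)), 0.15)
  expect_true(all(block > 0.15))
  # protein-set mismatch is an error
  cc <- group_correlation(subset_npx(sim_cx$matrix, proteins = 1:10),
                          sim_cx$meta, "NASH")
  expect_error(residual_matrix(ca, cc), "protein sets")
})

test_that("cluster_residuals recovers the planted block", {
  ca <- group_correlation(sim_cx$matrix, sim_cx$meta, "NASH")
  cb <- group_correlation(sim_cx$matrix, sim_cx$meta, "NAFL")
  res <- cluster_residuals(residual_matrix(ca, cb))
  planted <- sprintf("P%02d", 1:5)
  overlap <- vapply(res$cluster_members, function(m)
    length(intersect(m, planted)), numeric(1))
  best <- res$cluster_members[[which.max(overlap)]]
  expect_gte(length(intersect(best, planted)), 4)
  # clusters are ordered largest first and partition the panel
  expect_true(all(diff(lengths(res$cluster_members)) <= 0))
  expect_setequal(unlist(res$cluster_members), sprintf("P%02d", 1:45))
})

test_that("all-zero residual collapses to one flagged cluster", {
  ca <- group_correlation(sim_cx$matrix, sim_cx$meta, "NASH")
  r0 <- residual_matrix(ca, ca)
  expect_warning(res <- cluster_residuals(r0), "trivial cluster")
  expect_equal(length(res$cluster_members), 1)
})

test_that("clustering is invariant to protein input order", {
  perm <- c(30:45, 1:29)
  x_perm <- subset_npx(sim_cx$matrix, proteins = perm)
  mk <- function(x) {
    ca <- group_correlation(x, sim_cx$meta, "NASH")
    cb <- group_correlation(x, sim_cx$meta, "NAFL")
    cluster_residuals(residual_matrix(ca, cb), k = 4)
  }
  part_a <- mk(sim_cx$matrix)$clusters
  part_b <- mk(x_perm)$clusters
  expect_gte(adjusted_rand_index(part_a[names(part_b)], part_b), 0.999)
})

test_that("antisymmetry of the full clustering pipeline", {
  ca <- group_correlation(sim_cx$matrix, sim_cx$meta, "NASH")
  cb <- group_correlation(sim_cx$matrix, sim_cx$meta, "NAFL")
  p_ab <- cluster_residuals(residual_matrix(ca, cb), k = 4)$clusters
  p_ba <- cluster_residuals(residual_matrix(cb, ca), k = 4)$clusters
  # Euclidean row distances are invariant under global sign flip, so the
  # partitions agree up to label names
  expect_equal(adjusted_rand_index(p_ab, p_ba), 1)
})

test_that("cluster_enrichment_summary reports consistent pairs", {
  ca <- group_correlation(sim_cx$matrix, sim_cx$meta, "NASH")
  cb <- group_correlation(sim_cx$matrix, sim_cx$meta, "NAFL")
  res <- cluster_residuals(residual_matrix(ca, cb), k = 4)
  summ <- cluster_enrichment_summary(res, ca, cb)
  planted <- sprintf("P%02d", 1:5)
  overlap <- vapply(summ, function(s)
    length(intersect(s$members, planted)), numeric(1))
  s_block <- summ[[which.max(overlap)]]
  null_means <- vapply(summ[-which.max(overlap)], function(s)
    s$mean_abs_residual, numeric(1))
  expect_gte(s_block$mean_abs_residual, 3 * max(null_means))
  # reported per-pair coefficients match the group matrices exactly
  for (ix in seq_len(nrow(s_block$pairs))) {
    pr <- s_block$pairs[ix, ]
    expect_identical(pr$rho_a, ca$corr[pr$protein_1, pr$protein_2])
    expect_identical(pr$rho_b, cb$corr[pr$protein_1, pr$protein_2])
    expect_equal(pr$residual, pr$rho_a - pr$rho_b)
  }
  # singleton clusters summarize without pairs
  res_n <- cluster_residuals(residual_matrix(ca, cb), k = 45)
  summ_n <- cluster_enrichment_summary(res_n, ca, cb)
  expect_true(all(vapply(summ_n, function(s)
    nrow(s$pairs) == 0 || length(s$members) > 1, logical(1))))
})
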