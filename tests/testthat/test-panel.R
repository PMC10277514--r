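# ROC thresholding, k-of-n panel rules, McNemar comparisons, subset
# selection.

test_that("roc_curve endpoints and the U-statistic identity", {
  scores <- c(1, 2, 3, 10, 11, 12)
  labels <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  roc <- roc_curve(scores, labels, "greater")
  expect_true(any(roc$sensitivity == 1 & roc$specificity == 1))
  # identical scores collapse to the diagonal endpoints
  roc0 <- roc_curve(rep(5, 6), labels, "greater")
  expect_equal(sort(unique(roc0$sensitivity)), c(0, 1))
  expect_equal(sort(unique(roc0$specificity)), c(0, 1))
  # AUC equals U/(n*m) on a toy with ties
  set.seed(51)
  s <- sample(1:8, 12, replace = TRUE)
  l <- rep(c(TRUE, FALSE), each = 6)
  u <- oracle_u_stat(s[l], s[!l])
  expect_equal(attr(roc_curve(s, l, "greater"), "auc"), u / 36)
  expect_error(roc_curve(1:5, rep(TRUE, 5)), "both classes")
})

test_that("threshold_at_specificity meets its target", {
  # 10 controls at 1..10: target 0.9 -> threshold 9 (positive above),
  # specificity exactly 0.9
  scores <- c(1:10, 8:12)
  labels <- c(rep(FALSE, 10), rep(TRUE, 5))
  t <- threshold_at_specificity(roc_curve(scores, labels, "greater"), 0.9)
  expect_equal(t$specificity, 0.9)
  expect_equal(t$threshold, 9)
  # symmetric well-separated data: moderate target keeps sensitivity 1
  t2 <- threshold_at_specificity(
    roc_curve(c(1:5, 11:15), rep(c(FALSE, TRUE), each = 5), "greater"), 0.5)
  expect_equal(t2$sensitivity, 1)
  # achieved specificity >= target on random instances, both directions
  set.seed(52)
  for (i in 1:100) {
    sc <- rnorm(30)
    lb <- rep(c(TRUE, FALSE), 15)
    tg <- runif(1, 0.05, 0.95)
    dr <- sample(c("greater", "less"), 1)
    tt <- threshold_at_specificity(roc_curve(sc, lb, dr), tg)
    expect_gte(tt$specificity, tg)
  }
})

test_that("k-of-n operating points match exhaustive enumeration", {
  v <- matrix(c(0, 0, 1, 1, 0, 1,
                0, 1, 0, 1, 1, 1,
                1, 0, 0, 1, 1, 0), 6, 3,
              dimnames = list(sprintf("s%d", 1:6), c("A", "B", "C")))
  labels <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  tests <- lapply(c("A", "B", "C"), function(pr)
    structure(list(protein = pr, direction = "greater", threshold = 0.5,
                   specificity = NA, sensitivity = NA, target = NA),
              class = "thresholded_test"))
  rule <- evaluate_k_of_n(tests, npx_matrix(v), labels)
  # brute-force enumeration of positives per sample
  pos_counts <- rowSums(v > 0.5)
  for (k in 0:3) {
    dec <- pos_counts >= k
    expect_equal(rule$operating_points$sensitivity[k + 1],
                 sum(dec & labels) / 3)
    expect_equal(rule$operating_points$specificity[k + 1],
                 sum(!dec & !labels) / 3)
  }
  # k = 0 -> everyone positive
  expect_equal(rule$operating_points$sensitivity[1], 1)
  expect_equal(rule$operating_points$specificity[1], 0)
  # single test at k = 1 reproduces that test's confusion
  rule1 <- evaluate_k_of_n(tests[1], npx_matrix(v), labels)
  dec <- v[, "A"] > 0.5
  expect_equal(rule1$operating_points$sensitivity[2],
               sum(dec & labels) / 3)
  expect_error(evaluate_k_of_n(tests, npx_matrix(v[, 1:2]), labels),
               "missing")
})

test_that("panel monotonicity holds on simulated cohorts", {
  sim <- simulate_cohort(simulation_config(seed = 61))
  panel <- filter_by_detection(sim$matrix)$matrix
  meta <- as.data.frame(sim$meta)
  use <- meta$sample_id[meta$group != "HC"]
  sub_m <- npx_matrix(panel$values[use, ], panel$below_lod[use, ])
  labels <- meta$group[match(use, meta$sample_id)] == "NASH"
  tab <- differential(panel, sim$meta, "NASH", "NAFL")
  for (tg in c(0.76, 0.90)) {
    tests <- derive_panel_tests(sub_m, labels, tg,
                                proteins = tab$protein[tab$rejected],
                                diff_table = tab)
    for (t in tests) expect_gte(t$specificity, tg)
    rule <- evaluate_k_of_n(tests, sub_m, labels)
    expect_true(all(diff(rule$operating_points$sensitivity) <= 1e-12))
    expect_true(all(diff(rule$operating_points$specificity) >= -1e-12))
  }
})

test_that("compare_panels_mcnemar matches the discordant-count contract", {
  labels <- rep(c(TRUE, FALSE), each = 12)
  dec <- labels  # perfect rule
  same <- compare_panels_mcnemar(dec, dec, labels)
  expect_equal(same$p_value, 1)
  # rule A correct on 9 cases B misses, B correct on 1 case A misses
  dec_a <- labels; dec_b <- labels
  dec_b[1:9] <- FALSE   # B misses 9 cases A catches
  dec_a[10] <- FALSE    # A misses 1 case B catches
  r <- compare_panels_mcnemar(dec_a, dec_b, labels, among = "cases")
  expect_equal(r$p_value, 0.021484375)
  # symmetric discordance -> p = 1
  dec_b2 <- labels; dec_b2[1:4] <- FALSE
  dec_a2 <- labels; dec_a2[5:8] <- FALSE
  expect_equal(compare_panels_mcnemar(dec_a2, dec_b2, labels)$p_value, 1)
  expect_error(compare_panels_mcnemar(dec[1:5], dec, labels), "paired")
})

test_that("subset selection: degenerate cases", {
  set.seed(71)
  n <- 40
  v <- cbind(SEP = rep(c(0, 4), each = n / 2) + rnorm(n, sd = 0.1),
             N1 = rnorm(n), N2 = rnorm(n), N3 = rnorm(n))
  rownames(v) <- sprintf("s%d", 1:n)
  labels <- rep(c(FALSE, TRUE), each = n / 2)
  x <- npx_matrix(v)
  sel <- select_subset_logistic(x, labels)
  expect_identical(sel$selected, "SEP")
  expect_true(sel$separation)
  # penalized scores still separate the classes
  expect_gt(min(sel$scores[labels]), max(sel$scores[!labels]))
  # max_size = 0 -> intercept only
  sel0 <- select_subset_logistic(x, labels, max_size = 0)
  expect_length(sel0$selected, 0)
  expect_equal(var(sel0$scores), 0)
  expect_error(select_subset_logistic(x, rep(c(TRUE, FALSE), c(5, 35))),
               "at least 10")
})

test_that("subset selection criterion is minimal over evaluated subsets", {
  set.seed(72)
  sim <- simulate_cohort(simulation_config(seed = 72))
  panel <- filter_by_detection(sim$matrix)$matrix
  meta <- as.data.frame(sim$meta)
  use <- meta$sample_id[meta$group != "HC"]
  sub_m <- npx_matrix(panel$values[use, ], panel$below_lod[use, ])
  labels <- meta$group[match(use, meta$sample_id)] == "NASH"
  cand <- sprintf("P%02d", 1:8)
  sel <- select_subset_logistic(sub_m, labels, candidates = cand,
                                max_size = 3)
  # every subset of size <= 3 must score no better than the selected one
  y <- as.numeric(labels)
  all_scores <- unlist(lapply(0:3, function(sz) {
    combos <- combn(cand, sz, simplify = FALSE)
    vapply(combos, function(set) {
      xm <- cbind(1, sub_m$values[, set, drop = FALSE])
      fit <- suppressWarnings(glm.fit(xm, y, family = binomial()))
      fit$deviance + 2 * (length(set) + 1)
    }, numeric(1))
  }))
  expect_lt(sel$criterion_value, min(all_scores) + 1e-6)
})

test_that("greedy forward selection engages above 20 candidates", {
  set.seed(73)
  n <- 60
  v <- matrix(rnorm(n * 22), n, 22,
              dimnames = list(sprintf("s%d", 1:n), sprintf("C%02d", 1:22)))
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  v[labels, "C05"] <- v[labels, "C05"] + 3
  sel <- select_subset_logistic(npx_matrix(v), labels, max_size = 3)
  expect_true("C05" %in% sel$selected)
  # greedy evaluates far fewer models than the exhaustive count
  expect_lt(sel$n_evaluated, 100)
})

test_that("cross-validated operating points are honest and reproducible", {
  sim <- simulate_cohort(simulation_config(seed = 81))
  panel <- filter_by_detection(sim$matrix)$matrix
  meta <- as.data.frame(sim$meta)
  use <- meta$sample_id[meta$group != "HC"]
  sub_m <- npx_matrix(panel$values[use, ], panel$below_lod[use, ])
  labels <- meta$group[match(use, meta$sample_id)] == "NASH"
  tab <- differential(panel, sim$meta, "NASH", "NAFL")
  pool <- tab$protein[tab$rejected]
  cv <- evaluate_k_of_n_cv(sub_m, labels, 0.76, proteins = pool,
                           diff_table = tab, seed = 5)
  expect_equal(nrow(cv), length(pool) + 1)
  expect_true(all(cv$sensitivity >= 0 & cv$sensitivity <= 1))
  # reproducible under the seed
  cv2 <- evaluate_k_of_n_cv(sub_m, labels, 0.76, proteins = pool,
                            diff_table = tab, seed = 5)
  expect_identical(cv, cv2)
  # held-out sensitivity at mid-k does not beat resubstitution by much
  # (cross-validation removes optimism; allow sampling slack)
  tests <- derive_panel_tests(sub_m, labels, 0.76, proteins = pool,
                              diff_table = tab)
  resub <- evaluate_k_of_n(tests, sub_m, labels)$operating_points
  k_mid <- floor(length(pool) / 2)
  expect_lte(cv$sensitivity[cv$k == k_mid],
             resub$sensitivity[resub$k == k_mid] + 0.15)
  expect_error(evaluate_k_of_n_cv(sub_m, labels, 0.76, n_folds = 100),
               "out of range")
})
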