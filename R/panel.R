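# Multi-marker diagnostic panel machinery.
#
# Single-protein tests are thresholded at a fixed target specificity on the
# derivation set (resubstitution, as is standard when no held-out cohort
# exists); a panel calls a sample positive when at least k of the n
# single-protein tests are positive, which traces a continuum of
# (sensitivity, specificity) operating points as k varies.

#' Empirical ROC curve
#'
#' @param scores numeric marker values, one per sample.
#' @param labels logical (or 0/1) case indicator, both classes present.
#' @param direction `"greater"` if cases have higher scores (positive means
#'   score strictly above the threshold) or `"less"` (positive means score
#'   strictly below).
#' @return A data.frame of class `roc_curve` with columns `threshold`,
#'   `sensitivity`, `specificity`, ordered from the all-positive to the
#'   all-negative rule, plus attribute `auc` (trapezoidal; equals the
#'   Mann-Whitney U statistic of cases vs controls divided by n*m).
#' @export
roc_curve <- function(scores, labels, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  abort_if(anyNA(scores) || anyNA(labels), "scores/labels must not be NA")
  abort_if(!any(labels) || all(labels),
           "both classes must be present for a ROC curve")
  s <- if (direction == "greater") scores else -scores
  thr <- c(-Inf, sort(unique(s)))
  n_case <- sum(labels); n_ctrl <- sum(!labels)
  sens <- vapply(thr, function(t) sum(s[labels] > t) / n_case, numeric(1))
  spec <- vapply(thr, function(t) sum(s[!labels] <= t) / n_ctrl, numeric(1))
  out_thr <- if (direction == "greater") thr else -thr
  out <- data.frame(threshold = out_thr, sensitivity = sens,
                    specificity = spec)
  # trapezoidal AUC over (1 - specificity, sensitivity)
  fpr <- 1 - spec
  o <- order(fpr, sens)
  auc <- sum(diff(fpr[o]) * (utils::head(sens[o], -1) + utils::tail(sens[o], -1)) / 2)
  attr(out, "auc") <- abs(auc)
  attr(out, "direction") <- direction
  class(out) <- c("roc_curve", class(out))
  out
}

#' Threshold a marker at a target specificity
#'
#' Picks the ROC operating point with the smallest achieved specificity
#' that is still `>= target`; ties on specificity are broken by the larger
#' sensitivity. Achieved specificity therefore always meets the target.
#'
#' @param roc a [roc_curve()].
#' @param target target specificity in (0, 1).
#' @param protein optional marker id to record.
#' @return A `thresholded_test` list: `protein`, `direction`, `threshold`,
#'   `specificity`, `sensitivity`, `target`.
#' @export
threshold_at_specificity <- function(roc, target, protein = NA_character_) {
  abort_if(!inherits(roc, "roc_curve"), "roc must come from roc_curve()")
  abort_if(!is.numeric(target) || target <= 0 || target >= 1,
           "target specificity must lie in (0,1)")
  ok <- roc$specificity >= target
  abort_if(!any(ok), "no threshold achieves the target specificity")
  cand <- roc[ok, , drop = FALSE]
  cand <- cand[order(cand$specificity, -cand$sensitivity), , drop = FALSE]
  pick <- cand[1, ]
  structure(
    list(protein = protein, direction = attr(roc, "direction"),
         threshold = pick$threshold, specificity = pick$specificity,
         sensitivity = pick$sensitivity, target = target),
    class = "thresholded_test"
  )
}

#' @export
print.thresholded_test <- function(x, ...) {
  cat(sprintf(
    "test[%s]: positive if %s %.4g (sens %.3f, spec %.3f @ target %.2f)\n",
    x$protein, if (x$direction == "greater") ">" else "<",
    x$threshold, x$sensitivity, x$specificity, x$target))
  invisible(x)
}

# Apply a thresholded test to raw marker values -> logical positivity.
apply_test <- function(test, values) {
  if (test$direction == "greater") values > test$threshold
  else values < test$threshold
}

#' Build per-protein tests at a fixed specificity
#'
#' Convenience wrapper: for each protein, derives the ROC against the case
#' labels and thresholds it at `target` specificity. The positivity
#' direction per protein is taken from a differential table when supplied
#' (proteins lower in cases are positive below threshold), otherwise from
#' the sign of the median difference.
#'
#' @param x an [npx_matrix()] restricted to the derivation samples.
#' @param labels logical case indicator aligned with the rows of `x`.
#' @param target target specificity.
#' @param proteins proteins to use (default all columns).
#' @param diff_table optional `differential_table` (cases vs controls)
#'   supplying per-protein directions.
#' @return A list of `thresholded_test` objects.
#' @export
derive_panel_tests <- function(x, labels, target, proteins = NULL,
                               diff_table = NULL) {
  abort_if(!inherits(x, "npx_matrix"), "x must be an npx_matrix")
  labels <- as.logical(labels)
  if (is.null(proteins)) proteins <- protein_ids(x)
  missing_p <- setdiff(proteins, protein_ids(x))
  abort_if(length(missing_p) > 0,
           paste("proteins absent from matrix:",
                 paste(missing_p, collapse = ", ")))
  lapply(proteins, function(pr) {
    v <- x$values[, pr]
    dir <- if (!is.null(diff_table)) {
      eff <- diff_table$effect[diff_table$protein == pr]
      abort_if(length(eff) != 1,
               sprintf("protein '%s' absent from differential table", pr))
      if (eff < 0) "less" else "greater"
    } else {
      if (stats::median(v[labels]) < stats::median(v[!labels])) "less"
      else "greater"
    }
    threshold_at_specificity(roc_curve(v, labels, dir), target, protein = pr)
  })
}

#' Evaluate the k-of-n combined panel
#'
#' Counts per sample how many single-protein tests call it positive and
#' reports the full operating-point continuum: for each k in 0..n the rule
#' "positive iff at least k tests positive". Sensitivity is non-increasing
#' and specificity non-decreasing in k by construction.
#'
#' @param tests list of `thresholded_test` objects.
#' @param x an [npx_matrix()] holding the evaluation samples.
#' @param labels logical case indicator aligned with rows of `x`.
#' @return A `panel_rule` list: `tests`, `positive_counts` (per sample),
#'   `operating_points` (data.frame k, sensitivity, specificity),
#'   `decisions(k)` helper returning the logical decision vector at a k.
#' @export
evaluate_k_of_n <- function(tests, x, labels) {
  abort_if(!inherits(x, "npx_matrix"), "x must be an npx_matrix")
  labels <- as.logical(labels)
  prs <- vapply(tests, function(t) t$protein, character(1))
  missing_p <- setdiff(prs, protein_ids(x))
  abort_if(length(missing_p) > 0,
           paste("panel proteins missing from matrix:",
                 paste(missing_p, collapse = ", ")))
  pos <- vapply(tests, function(t) apply_test(t, x$values[, t$protein]),
                logical(nrow(x$values)))
  counts <- rowSums(pos)
  n <- length(tests)
  op <- do.call(rbind, lapply(0:n, function(k) {
    dec <- counts >= k
    data.frame(k = k,
               sensitivity = sum(dec & labels) / sum(labels),
               specificity = sum(!dec & !labels) / sum(!labels))
  }))
  structure(
    list(tests = tests, positive_counts = counts, labels = labels,
         operating_points = op,
         decisions = function(k) counts >= k),
    class = "panel_rule"
  )
}

#' @export
print.panel_rule <- function(x, ...) {
  cat(sprintf("k-of-%d panel rule; operating points:\n", length(x$tests)))
  print(x$operating_points, row.names = FALSE)
  invisible(x)
}

#' Compare two paired diagnostic rules with McNemar's test
#'
#' Compares the decision vectors of two rules on the same samples, among
#' cases (a sensitivity comparison) or among controls (specificity). The
#' discordant counts are rule A correct / rule B wrong and vice versa.
#'
#' @param decisions_a,decisions_b logical decision vectors on identical
#'   samples.
#' @param labels logical case indicator.
#' @param among `"cases"` or `"controls"`.
#' @param mode passed to [mcnemar()].
#' @return A `serosig_test`; `note` states the comparison stratum and the
#'   discordant counts.
#' @export
compare_panels_mcnemar <- function(decisions_a, decisions_b, labels,
                                   among = c("cases", "controls"),
                                   mode = c("exact", "asymptotic")) {
  among <- match.arg(among)
  mode <- match.arg(mode)
  abort_if(length(decisions_a) != length(decisions_b) ||
             length(decisions_a) != length(labels),
           "decision vectors and labels must be paired on identical samples")
  labels <- as.logical(labels)
  keep <- if (among == "cases") labels else !labels
  da <- decisions_a[keep]; db <- decisions_b[keep]
  correct_a <- if (among == "cases") da else !da
  correct_b <- if (among == "cases") db else !db
  b <- sum(correct_a & !correct_b)
  c <- sum(!correct_a & correct_b)
  res <- mcnemar(b, c, mode = mode)
  res$note <- sprintf("among %s: A-only correct = %d, B-only correct = %d",
                      among, b, c)
  res
}

#' Logistic-regression marker subset selection
#'
#' Searches candidate marker subsets for the best combination separating
#' cases from controls under a maximum-likelihood logistic model, scored by
#' an information criterion (AIC by default). With at most 20 candidates
#' the search is exhaustive over all subsets of size `<= max_size`;
#' otherwise greedy forward selection is used. Ties in the criterion break
#' to the lexicographically smallest protein set. Perfect separation is
#' detected and flagged, and the reported scores for the selected subset
#' then come from a ridge-penalized fit.
#'
#' @param x an [npx_matrix()].
#' @param labels logical case indicator aligned with rows of `x`; both
#'   classes need >= 10 samples.
#' @param candidates candidate protein ids (default all columns).
#' @param max_size maximum subset size, default 6.
#' @param criterion `"aic"` or `"bic"`.
#' @return A list of class `panel_selection`: `selected` (protein ids,
#'   sorted), `criterion_value`, `scores` (fitted linear predictor per
#'   sample), `separation` flag, `n_evaluated`.
#' @export
select_subset_logistic <- function(x, labels, candidates = NULL,
                                   max_size = 6,
                                   criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  abort_if(!inherits(x, "npx_matrix"), "x must be an npx_matrix")
  labels <- as.logical(labels)
  abort_if(sum(labels) < 10 || sum(!labels) < 10,
           "need at least 10 samples per class")
  if (is.null(candidates)) candidates <- protein_ids(x)
  missing_p <- setdiff(candidates, protein_ids(x))
  abort_if(length(missing_p) > 0,
           paste("candidate proteins missing:",
                 paste(missing_p, collapse = ", ")))
  abort_if(!is_count(max_size), "max_size must be a nonnegative integer")
  candidates <- sort(candidates)
  y <- as.numeric(labels)
  n <- length(y)
  pen <- if (criterion == "aic") 2 else log(n)

  fit_score <- function(cols) {
    xm <- cbind(1, x$values[, cols, drop = FALSE])
    fit <- suppressWarnings(
      stats::glm.fit(xm, y, family = stats::binomial()))
    mu <- fit$fitted.values
    sep <- any(mu > 1 - 1e-8 & y == 1) && any(mu < 1e-8 & y == 0) &&
      all(abs(mu - y) < 1e-6)
    list(score = fit$deviance + pen * (length(cols) + 1),
         coef = fit$coefficients, separated = sep)
  }

  best <- fit_score(character(0))
  best_set <- character(0)
  n_eval <- 1L

  if (length(candidates) <= 20) {
    sizes <- seq_len(min(max_size, length(candidates)))
    for (sz in sizes) {
      combos <- utils::combn(candidates, sz, simplify = FALSE)
      for (set in combos) {
        res <- fit_score(set)
        n_eval <- n_eval + 1L
        if (res$score < best$score - 1e-9) {
          best <- res; best_set <- set
        }
      }
    }
  } else {
    current <- character(0)
    repeat {
      if (length(current) >= max_size) break
      remaining <- setdiff(candidates, current)
      trial <- lapply(remaining, function(pr) fit_score(c(current, pr)))
      n_eval <- n_eval + length(trial)
      scores <- vapply(trial, `[[`, numeric(1), "score")
      ix <- which.min(scores)
      if (scores[ix] < best$score - 1e-9) {
        current <- c(current, remaining[ix])
        best <- trial[[ix]]
        best_set <- current
      } else break
    }
  }

  separated <- isTRUE(best$separated)
  scores <- if (length(best_set) == 0) {
    rep(stats::qlogis(mean(y)), n)
  } else if (separated) {
    ridge_logistic_scores(x$values[, best_set, drop = FALSE], y)
  } else {
    cbind(1, x$values[, best_set, drop = FALSE]) %*% best$coef
  }
  structure(
    list(selected = sort(best_set), criterion = criterion,
         criterion_value = best$score, scores = as.vector(scores),
         separation = separated, n_evaluated = n_eval),
    class = "panel_selection"
  )
}

#' @export
print.panel_selection <- function(x, ...) {
  cat(sprintf("selected %d marker(s): %s (%s = %.2f%s)\n",
              length(x$selected), paste(x$selected, collapse = ", "),
              toupper(x$criterion), x$criterion_value,
              if (x$separation) "; perfect separation, penalized fit" else ""))
  invisible(x)
}

#' Cross-validated k-of-n panel operating points
#'
#' Honesty check on the resubstitution operating points: stratified k-fold
#' cross-validation in which thresholds are derived at the target
#' specificity on each training split and the k-of-n rule is evaluated on
#' the held-out samples. Off the default path (resubstitution matches the
#' reference design); use this to gauge optimism.
#'
#' @param x an [npx_matrix()].
#' @param labels logical case indicator aligned with rows of `x`.
#' @param target target specificity for the per-protein thresholds.
#' @param proteins panel proteins (default all columns).
#' @param diff_table optional differential table supplying directions.
#' @param n_folds number of stratified folds, default 5.
#' @param seed RNG seed for the fold assignment.
#' @return A data.frame (k, sensitivity, specificity) of pooled held-out
#'   operating points, with attribute `folds`.
#' @export
evaluate_k_of_n_cv <- function(x, labels, target, proteins = NULL,
                               diff_table = NULL, n_folds = 5, seed = 1) {
  abort_if(!inherits(x, "npx_matrix"), "x must be an npx_matrix")
  labels <- as.logical(labels)
  if (is.null(proteins)) proteins <- protein_ids(x)
  abort_if(n_folds < 2 || n_folds > min(sum(labels), sum(!labels)),
           "n_folds out of range for the class sizes")
  folds <- with_seed(seed, {
    f <- integer(length(labels))
    f[labels] <- sample(rep_len(seq_len(n_folds), sum(labels)))
    f[!labels] <- sample(rep_len(seq_len(n_folds), sum(!labels)))
    f
  })
  n <- length(proteins)
  counts <- integer(length(labels))
  for (fold in seq_len(n_folds)) {
    train <- folds != fold
    tests <- derive_panel_tests(subset_npx(x, samples = which(train)),
                                labels[train], target, proteins = proteins,
                                diff_table = diff_table)
    pos <- vapply(tests, function(t)
      apply_test(t, x$values[!train, t$protein]), logical(sum(!train)))
    counts[!train] <- rowSums(pos)
  }
  out <- do.call(rbind, lapply(0:n, function(k) {
    dec <- counts >= k
    data.frame(k = k,
               sensitivity = sum(dec & labels) / sum(labels),
               specificity = sum(!dec & !labels) / sum(!labels))
  }))
  attr(out, "folds") <- folds
  out
}

# Minimal ridge-penalized logistic IRLS, used only when the ML fit is
# perfectly separating (coefficients diverge); lambda small so the linear
# predictor ordering is preserved.
ridge_logistic_scores <- function(xmat, y, lambda = 1e-3, iter = 50) {
  xm <- cbind(1, scale(xmat))
  beta <- rep(0, ncol(xm))
  pen <- diag(c(0, rep(lambda, ncol(xm) - 1)))
  for (i in seq_len(iter)) {
    eta <- as.vector(xm %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(xm * sqrt(w)) + pen, crossprod(xm, w * z))
    if (max(abs(beta_new - beta)) < 1e-10) { beta <- beta_new; break }
    beta <- beta_new
  }
  as.vector(xm %*% beta)
}
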