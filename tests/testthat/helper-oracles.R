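# Independent brute-force oracles. Each recomputes a quantity by a route
# different from the package implementation, so agreement is evidence.

# Mann-Whitney U by direct pair counting (no ranks).
oracle_u_stat <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# Exact two-sided MW p by enumerating every assignment of the pooled values
# into a group of size length(x), computing U by pair counting each time.
oracle_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x); nt <- length(pooled)
  centre <- n * (nt - n) / 2
  u_obs <- oracle_u_stat(x, y)
  combos <- utils::combn(nt, n, simplify = FALSE)
  us <- vapply(combos, function(ix)
    oracle_u_stat(pooled[ix], pooled[-ix]), numeric(1))
  mean(abs(us - centre) >= abs(u_obs - centre) - 1e-9)
}

# Literal two-stage BKY definition, written as explicit loops.
oracle_bky_reject <- function(p, q) {
  m <- length(p)
  bh <- function(p, level) {
    o <- order(p)
    r <- 0
    for (i in seq_len(m)) if (p[o][i] <= level * i / m) r <- i
    rej <- rep(FALSE, m)
    if (r > 0) rej[o[1:r]] <- TRUE
    rej
  }
  qp <- q / (1 + q)
  r1 <- sum(bh(p, qp))
  if (r1 == 0) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  bh(p, qp * m / (m - r1))
}

# Exact McNemar p as an explicit binomial tail sum.
oracle_mcnemar_exact <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  k <- min(b, c)
  min(1, 2 * sum(stats::dbinom(0:k, n, 0.5)))
}

# Greedy Ward agglomeration evaluating the ESS objective directly from the
# raw observations at every step (no Lance-Williams recurrence). Same
# deterministic tie-break as the implementation: smallest pair of
# smallest-original-member ids. Returns merges as sets of original items
# plus the ESS increase of each merge.
oracle_ward <- function(xmat) {
  ess <- function(rows) {
    if (length(rows) == 1) return(0)
    centered <- sweep(xmat[rows, , drop = FALSE], 2,
                      colMeans(xmat[rows, , drop = FALSE]))
    sum(centered^2)
  }
  clusters <- as.list(seq_len(nrow(xmat)))
  merges <- list(); heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; pick <- NULL
    nc <- length(clusters)
    for (i in seq_len(nc - 1)) for (j in seq.int(i + 1, nc)) {
      delta <- ess(c(clusters[[i]], clusters[[j]])) -
        ess(clusters[[i]]) - ess(clusters[[j]])
      key <- c(min(clusters[[i]]), min(clusters[[j]]))
      key <- sort(key)
      if (delta < best - 1e-12 ||
          (abs(delta - best) <= 1e-12 && !is.null(pick) &&
           (key[1] < pick$key[1] ||
            (key[1] == pick$key[1] && key[2] < pick$key[2])))) {
        best <- delta
        pick <- list(i = i, j = j, key = key)
      }
    }
    merged <- sort(c(clusters[[pick$i]], clusters[[pick$j]]))
    merges <- c(merges, list(list(a = sort(clusters[[pick$i]]),
                                  b = sort(clusters[[pick$j]]))))
    heights <- c(heights, best)
    clusters <- c(clusters[-c(pick$i, pick$j)], list(merged))
  }
  list(merges = merges, heights = heights)
}

# Expand a ward_tree merge row into its sorted original-leaf members.
tree_merge_members <- function(tree, step) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(tree$merge[node, 1]), expand(tree$merge[node, 2]))
  }
  list(a = sort(expand(tree$merge[step, 1])),
       b = sort(expand(tree$merge[step, 2])))
}

# The merged set {a union b} at each step, order-insensitive comparison key.
merge_set_signature <- function(pairs) {
  lapply(pairs, function(p) {
    sides <- list(p$a, p$b)
    sides <- sides[order(vapply(sides, min, numeric(1)))]
    sides
  })
}
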