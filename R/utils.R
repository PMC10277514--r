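#' @keywords internal
"_PACKAGE"

# Internal assertion helper: stop with the caller-supplied message.
abort_if <- function(cond, msg) {
  if (isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(NULL)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == floor(x)
}

is_proportion <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
}

# Mid-ranks (average ranks for ties), the tie convention used throughout.
midrank <- function(x) rank(x, ties.method = "average")

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items, used
#' to score recovery of planted subgroups by clustering. 1 means identical
#' partitions (up to label names), 0 is the expectation under random labeling.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return A single number in (-1, 1].
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y"))
#' @export
adjusted_rand_index <- function(a, b) {
  abort_if(length(a) != length(b), "label vectors must have equal length")
  abort_if(length(a) < 2, "need at least 2 items")
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

# Derive a per-stage 32-bit seed from a root seed and a stage tag, so all
# pipeline randomness flows from one root without stages sharing streams.
derive_seed <- function(seed, tag) {
  abort_if(!is_count(abs(seed)), "seed must be an integer")
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 69069 + h * 1013 + 1) %% 2147483647)
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so simulation functions are pure in their seed argument.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Format numbers for file output deterministically (byte-identical reruns).
fmt_num <- function(x, digits = 12) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "g"))
}
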