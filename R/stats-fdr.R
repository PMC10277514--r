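# False discovery rate control.
#
# The primary procedure is the two-stage sharpened linear step-up of
# Benjamini, Krieger & Yekutieli (2006): stage 1 runs the linear step-up
# (Benjamini-Hochberg) at q' = q / (1 + q); the number of stage-1
# rejections r1 estimates the number of true nulls as m0 = m - r1; stage 2
# reruns the linear step-up at level q' * m / m0. Edge cases: r1 = 0
# rejects nothing, r1 = m rejects everything.
#
# Plain BH and the Benjamini-Yekutieli (dependency-robust) variants are
# available behind `method` because figure-level text and methods text of
# typical PEA studies name them interchangeably.

# Linear step-up (BH) rejection indicator at level q; denom = optional
# extra denominator term (BY uses sum(1/i)).
step_up_reject <- function(p, q, c_m = 1) {
  m <- length(p)
  o <- order(p)
  thresh <- q * seq_len(m) / (m * c_m)
  ok <- p[o] <= thresh
  r <- if (any(ok)) max(which(ok)) else 0L
  rej <- logical(m)
  if (r > 0) rej[o[seq_len(r)]] <- TRUE
  rej
}

#' Two-stage Benjamini-Krieger-Yekutieli FDR control
#'
#' Sharpened false discovery rate control via the two-stage linear step-up
#' procedure, the multiplicity correction applied to every protein-wise
#' comparison family in this package (default Q = 5\%).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param q target FDR level in (0, 1); default 0.05.
#' @param method `"bky"` (two-stage, default), `"bh"` (plain linear
#'   step-up) or `"by"` (Benjamini-Yekutieli, arbitrary dependence).
#' @return An object of class `fdr_decision`: list with `p`, `q`, `method`,
#'   logical `rejected`, `n_rejected`, `m0` (estimated true nulls, BKY
#'   only) and `adjusted` (monotone step-up adjusted values such that
#'   `adjusted <= q` matches `rejected`; for BKY with r1 = m the adjusted
#'   values are all set to 0 to preserve that equivalence).
#' @examples
#' bky_two_stage(c(0.001, 0.008, 0.039, 0.041, 0.5))
#' @export
bky_two_stage <- function(p, q = 0.05, method = c("bky", "bh", "by")) {
  method <- match.arg(method)
  abort_if(!is.numeric(p) || length(p) == 0, "p must be a nonempty numeric")
  abort_if(anyNA(p) || any(p < 0 | p > 1), "p-values must lie in [0,1]")
  abort_if(!is.numeric(q) || length(q) != 1 || q <= 0 || q >= 1,
           "q must lie in (0,1)")
  m <- length(p)

  adjust_step_up <- function(p, scale) {
    # monotone step-up adjusted values: min over i >= rank of p(i)*scale/i
    o <- order(p)
    adj <- p[o] * scale / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(1, adj)[order(o)]
  }

  if (method == "bh") {
    rej <- step_up_reject(p, q)
    adj <- adjust_step_up(p, m)
    m0 <- NA_real_
  } else if (method == "by") {
    c_m <- sum(1 / seq_len(m))
    rej <- step_up_reject(p, q, c_m = c_m)
    adj <- adjust_step_up(p, m * c_m)
    m0 <- NA_real_
  } else {
    qp <- q / (1 + q)
    r1 <- sum(step_up_reject(p, qp))
    if (r1 == 0L) {
      rej <- logical(m)
      m0 <- m
      adj <- adjust_step_up(p, m * (1 + q))
    } else if (r1 == m) {
      rej <- rep(TRUE, m)
      m0 <- 0
      adj <- rep(0, m)
    } else {
      m0 <- m - r1
      rej <- step_up_reject(p, qp * m / m0)
      adj <- adjust_step_up(p, m0 * (1 + q))
    }
  }
  structure(
    list(p = p, q = q, method = method, rejected = rej,
         n_rejected = sum(rej), m0 = m0, adjusted = adj),
    class = "fdr_decision"
  )
}

#' @export
print.fdr_decision <- function(x, ...) {
  cat(sprintf("FDR decision (%s, q = %g): %d / %d rejected\n",
              toupper(x$method), x$q, x$n_rejected, length(x$p)))
  invisible(x)
}
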