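#' Benjamini-Hochberg false discovery rate control
#'
#' Literal step-up implementation: with `m` p-values sorted ascending,
#' `q_(i) = min_{j >= i} min(1, m * p_(j) / j)`, mapped back to the input
#' order. Monotone in the p-value ranks and bounded in \[0, 1\].
#'
#' @param p Numeric vector of p-values in \[0, 1\] (`NA` allowed; propagated).
#' @return Vector of q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p)) stop_subloc("`p` must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop_subloc("p-values must lie in [0, 1]")
  }
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0L) return(q)
  o <- order(pv)
  adj <- pmin(1, pv[o] * m / seq_len(m))
  # enforce monotonicity from the largest p downwards (step-up)
  adj <- rev(cummin(rev(adj)))
  qv <- numeric(m)
  qv[o] <- adj
  q[ok] <- qv
  q
}
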