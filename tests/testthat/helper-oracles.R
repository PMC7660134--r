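# Independent naive oracles, kept deliberately separate from the package
# implementations: explicit loops, direct sums, no shared helpers.

# BH step-up computed from the definition: q_i is the smallest value of
# m * p_(j) / j over all p_(j) >= p_i, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "max") # number of p-values <= p_i
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- Inf
    for (j in seq_len(m)) {
      if (p[j] >= p[i]) {
        cand <- min(cand, m * p[j] / r[j])
      }
    }
    q[i] <- min(1, cand)
  }
  q
}

# Exact MWU null by full enumeration of all C(n, n1) member assignments,
# midranks for ties; two-sided p = 2 * min(tails) capped at 1.
oracle_mwu_enum <- function(values, members_idx) {
  n <- length(values)
  n1 <- length(members_idx)
  r <- rank(values)
  u_obs <- sum(r[members_idx]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n, n1)
  u_null <- apply(combos, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  eps <- 1e-9
  lo <- mean(u_null <= u_obs + eps)
  hi <- mean(u_null >= u_obs - eps)
  list(U = u_obs, p = min(1, 2 * min(lo, hi)),
       score_s = 2 * u_obs / (n1 * (n - n1)) - 1)
}

# One-sided hypergeometric upper tail by direct summation of the pmf.
oracle_hyper_upper <- function(k, K, N, n) {
  total <- 0
  for (x in k:min(K, n)) {
    total <- total + choose(K, x) * choose(N - K, n - x) / choose(N, n)
  }
  total
}

# Naive recursive enumeration of the nested density-cluster family for one
# chromosome/strand: at each node, every gap between consecutive positions
# is scored with its two boundary densities (prefix side and suffix side)
# recomputed by direct sums; the node is cut at every gap attaining the
# minimal score, and the resulting segments recurse.
oracle_paraclu_family <- function(pos, cnt) {
  rec <- function(p, v, min_density) {
    n <- length(p)
    if (n == 0) return(NULL)
    if (n == 1) {
      return(data.frame(start = p, end = p + 1, n_positions = 1L,
                        sum = v, min_density = min_density,
                        max_density = Inf))
    }
    gap_score <- numeric(n - 1)
    for (g in 1:(n - 1)) { # gap between elements g and g+1
      d_left <- sum(v[1:g]) / (p[g + 1] - p[1])
      d_right <- sum(v[(g + 1):n]) / (p[n] - p[g])
      gap_score[g] <- min(d_left, d_right)
    }
    brk <- min(gap_score)
    self <- data.frame(start = p[1], end = p[n] + 1, n_positions = n,
                       sum = sum(v), min_density = min_density,
                       max_density = brk)
    cuts <- which(gap_score == brk)
    pieces <- list()
    lo <- 1
    for (g in cuts) {
      pieces[[length(pieces) + 1]] <- lo:g
      lo <- g + 1
    }
    pieces[[length(pieces) + 1]] <- lo:n
    for (idx in pieces) {
      self <- rbind(self, rec(p[idx], v[idx], brk))
    }
    self
  }
  fam <- rec(pos, cnt, 0)
  fam$fold <- ifelse(fam$min_density <= 0, Inf,
                     fam$max_density / fam$min_density)
  fam[order(fam$start, fam$end), ]
}

# Literal filter + nested-overlap resolution on the oracle family.
oracle_paraclu_report <- function(pos, cnt, min_sum = 10, max_len = 200,
                                  min_fold = 2) {
  fam <- oracle_paraclu_family(pos, cnt)
  keep <- fam$sum >= min_sum & (fam$end - fam$start) <= max_len &
    fam$fold >= min_fold
  surv <- fam[keep, , drop = FALSE]
  if (nrow(surv) == 0) return(surv)
  surv <- surv[order(-surv$max_density, surv$end - surv$start,
                     surv$start), , drop = FALSE]
  picked <- surv[0, , drop = FALSE]
  for (i in seq_len(nrow(surv))) {
    overlaps <- FALSE
    for (j in seq_len(nrow(picked))) {
      if (surv$start[i] < picked$end[j] && surv$end[i] > picked$start[j]) {
        overlaps <- TRUE
        break
      }
    }
    if (!overlaps) picked <- rbind(picked, surv[i, ])
  }
  picked[order(picked$start), ]
}

random_track <- function(seed, max_positions = 50, max_count = 20,
                         span = 500) {
  set.seed(seed)
  n <- sample.int(max_positions, 1)
  pos <- sort(sample.int(span, n)) - 1L
  cnt <- sample.int(max_count, n, replace = TRUE)
  tibble::tibble(chrom = "chr1", position = pos, strand = "+",
                 count = cnt)
}
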