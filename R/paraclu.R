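# Parametric density clustering of crosslink tracks.
#
# For one chromosome/strand the crosslink track is a sparse vector of
# deduplicated counts at positions p_1 < ... < p_n. Scanning a density
# threshold d upward, the maximal clusters form a nested family: each
# cluster is born when its parent splits (min_density) and splits itself at
# its weakest internal prefix/suffix boundary (max_density). The stability
# fold max_density/min_density measures how long a cluster persists across
# thresholds. Reported peaks satisfy the published filter set: in-cluster
# sum >= min_sum (10), genomic length <= max_len (200 nt), fold >=
# min_density_increase (2).

#' Paraclu density clusters of a crosslink track
#'
#' Enumerates the nested family of maximal-density clusters of a
#' deduplicated crosslink track, then reports the clusters passing the
#' published filters (`sum >= min_sum`, `length <= max_len`,
#' `max_density / min_density >= min_density_increase`). Overlapping
#' survivors (which are always nested) are resolved by keeping the cluster
#' with the higher stability ceiling `max_density` (ties: shorter, then
#' leftmost), so the densest stable peak represents each locus.
#'
#' @param track Tibble with `chrom`, `position` (0-based), `strand`,
#'   `count` (e.g. from [dedup_umi()]).
#' @param min_sum Minimum total count inside a reported cluster
#'   (default 10).
#' @param max_len Maximum cluster length in nucleotides (default 200).
#' @param min_density_increase Minimum stability fold (default 2).
#' @return Tibble of clusters: `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `n_positions`, `sum`, `min_density`, `max_density`, `fold`.
#' @seealso [paraclu_family()] for the unfiltered nested family.
#' @export
paraclu <- function(track, min_sum = 10, max_len = 200,
                    min_density_increase = 2) {
  check_number(min_sum, "min_sum", lower = 0, strict_lower = TRUE)
  check_number(max_len, "max_len", lower = 0, strict_lower = TRUE)
  check_number(min_density_increase, "min_density_increase", lower = 0,
               strict_lower = TRUE)
  fam <- paraclu_family(track)
  if (nrow(fam) == 0L) return(fam)
  keep <- fam$sum >= min_sum &
    (fam$end - fam$start) <= max_len &
    fam$fold >= min_density_increase
  surv <- fam[keep, , drop = FALSE]
  if (nrow(surv) == 0L) return(surv)
  surv <- surv[order(-surv$max_density, surv$end - surv$start, surv$start), ]
  chosen <- logical(nrow(surv))
  for (grp in split(seq_len(nrow(surv)),
                    paste(surv$chrom, surv$strand))) {
    taken_start <- integer(0)
    taken_end <- integer(0)
    for (i in grp) {
      if (!any(surv$start[i] < taken_end & surv$end[i] > taken_start)) {
        chosen[i] <- TRUE
        taken_start <- c(taken_start, surv$start[i])
        taken_end <- c(taken_end, surv$end[i])
      }
    }
  }
  out <- surv[chosen, , drop = FALSE]
  out[order(out$chrom, out$start, out$strand), , drop = FALSE]
}

#' @rdname paraclu
#' @export
paraclu_family <- function(track) {
  x <- as_tibble(track)
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), n_positions = integer(),
                  sum = double(), min_density = double(),
                  max_density = double(), fold = double())
  if (nrow(x) == 0L) return(empty)
  need <- c("chrom", "position", "strand", "count")
  if (!all(need %in% names(x))) {
    stop_subloc("track needs columns: %s", paste(need, collapse = ", "))
  }
  if (any(x$count <= 0)) stop_subloc("track counts must be positive")
  parts <- split(x, paste(x$chrom, x$strand, sep = "\r"))
  res <- purrr::map(parts, function(part) {
    part <- part[order(part$position), ]
    cl <- paraclu_segment(part$position, part$count)
    cl$chrom <- part$chrom[1]
    cl$strand <- part$strand[1]
    cl
  }) |> list_rbind()
  res$fold <- ifelse(res$min_density <= 0, Inf,
                     res$max_density / res$min_density)
  res <- res[, names(empty)]
  res[order(res$chrom, res$start, res$end, res$strand), , drop = FALSE]
}

# Iterative top-down splitting for one chrom/strand. `pos` strictly
# increasing, `cnt` positive. Range sums via cumsum; the weakest boundary
# search is vectorized per node. Each gap g (between consecutive observed
# positions g and g+1) carries two candidate boundary densities: the
# prefix side sum(beg..g)/(pos[g+1]-pos[beg]) and the suffix side
# sum(g+1..end)/(pos[end]-pos[g]). The node splits at every gap attaining
# the minimal candidate density; cutting all tied gaps at once keeps the
# procedure exactly covariant under strand mirroring, where prefix and
# suffix candidates exchange roles.
paraclu_segment <- function(pos, cnt) {
  n <- length(pos)
  cs <- c(0, cumsum(cnt))
  out_start <- integer(0); out_end <- integer(0)
  out_np <- integer(0); out_sum <- double(0)
  out_min <- double(0); out_max <- double(0)
  stack <- list(list(beg = 1L, end = n, min_density = 0))
  while (length(stack) > 0L) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    beg <- node$beg; end <- node$end
    if (beg > end) next
    if (beg == end) {
      brk <- Inf
      cuts <- integer(0)
    } else {
      g <- beg:(end - 1L)
      d_left <- (cs[g + 1L] - cs[beg]) / (pos[g + 1L] - pos[beg])
      d_right <- (cs[end + 1L] - cs[g + 1L]) / (pos[end] - pos[g])
      gap_min <- pmin(d_left, d_right)
      brk <- min(gap_min)
      cuts <- g[gap_min == brk]
    }
    out_start <- c(out_start, pos[beg])
    out_end <- c(out_end, pos[end] + 1L)
    out_np <- c(out_np, end - beg + 1L)
    out_sum <- c(out_sum, cs[end + 1L] - cs[beg])
    out_min <- c(out_min, node$min_density)
    out_max <- c(out_max, brk)
    if (length(cuts) > 0L) {
      bounds <- c(beg - 1L, cuts, end)
      for (ci in seq_len(length(bounds) - 1L)) {
        stack[[length(stack) + 1L]] <-
          list(beg = bounds[ci] + 1L, end = bounds[ci + 1L],
               min_density = brk)
      }
    }
  }
  tibble(start = out_start, end = out_end, n_positions = out_np,
         sum = out_sum, min_density = out_min, max_density = out_max)
}
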