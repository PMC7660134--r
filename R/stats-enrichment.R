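#' One-dimensional annotation enrichment
#'
#' Runs the category rank test ([mwu_category_test()]) for every annotation
#' set against a single ranked value vector (e.g. per-gene log2
#' protrusion/body ratios) and controls the FDR across the tested sets by
#' Benjamini-Hochberg. Sets with fewer than `min_members` members inside the
#' value universe are skipped and listed in the `"skipped"` attribute.
#'
#' @param values Named numeric vector; names define the analysis universe.
#' @param sets Named list of character vectors (annotation categories).
#' @param fdr FDR threshold used for the `significant` flag (default 0.02,
#'   the published cut-off for annotation enrichment).
#' @param min_members Minimum category size inside the universe (default 5).
#' @param keep_all If `FALSE` (default) only sets with `q < fdr` are
#'   returned; if `TRUE` the full table is returned with a `significant`
#'   column.
#' @return A tibble (class `subloc_enrichment`) with one row per tested set:
#'   `set_name`, `n_members`, `score_s`, `statistic_U`, `p`, `q`,
#'   `significant`.
#' @export
annotation_enrichment_1d <- function(values, sets, fdr = 0.02,
                                     min_members = 5L, keep_all = FALSE) {
  check_universe(values)
  check_sets(sets)
  prepared <- prepare_sets(values, sets, min_members)
  res <- purrr::imap(prepared$sets, function(mem, nm) {
    out <- mwu_category_test(values, mem)
    out$set_name <- nm
    out
  }) |> list_rbind()
  if (nrow(res) == 0L) {
    res <- tibble(set_name = character(), n_members = integer(),
                  score_s = double(), statistic_U = double(), p = double(),
                  q = double(), significant = logical())
  } else {
    res$q <- bh_fdr(res$p)
    res$significant <- res$q < fdr
    res <- res[order(res$q, res$p), c("set_name", "n_members", "score_s",
                                      "statistic_U", "p", "q", "significant")]
  }
  if (!keep_all) res <- res[res$significant %in% TRUE, , drop = FALSE]
  structure(res, skipped = prepared$skipped, fdr = fdr,
            class = c("subloc_enrichment", class(tibble())))
}

check_universe <- function(values) {
  if (length(values) == 0L || all(is.na(values))) {
    stop_subloc("empty universe: no non-missing values")
  }
  if (is.null(names(values))) stop_subloc("`values` must be named")
  invisible(values)
}

check_sets <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop_subloc("`sets` must be a named list of feature-id vectors")
  }
  if (any(lengths(sets) == 0L)) stop_subloc("annotation sets must be non-empty")
  invisible(sets)
}

prepare_sets <- function(values, sets, min_members) {
  universe <- names(values)[!is.na(values)]
  memberships <- purrr::map(sets, ~ intersect(unique(.x), universe))
  sizes <- lengths(memberships)
  usable <- sizes >= min_members & sizes < length(universe)
  skipped <- tibble(set_name = names(sets)[!usable],
                    n_members = unname(sizes[!usable]),
                    reason = ifelse(sizes[!usable] < min_members,
                                    "below min_members", "covers universe"))
  list(sets = memberships[usable], skipped = skipped)
}

#' Two-dimensional annotation enrichment
#'
#' Scores every annotation set independently in two value dimensions (e.g.
#' NT/KD ratio change in protrusions on x and in cell bodies on y). A set is
#' significant when either dimension passes BH control at `fdr`. The sign
#' pattern of the two scores places each significant set in a quadrant:
#' same-sign quadrants are interpreted as an expression change throughout
#' the cell, opposite-sign quadrants as a mislocalization candidate.
#'
#' @inheritParams annotation_enrichment_1d
#' @param values_x,values_y Named numeric vectors over an identical universe.
#' @return Tibble (class `subloc_enrichment2d`): `set_name`, `n_members`,
#'   `score_x`, `score_y`, `q_x`, `q_y`, `joint_q`, `significant`,
#'   `quadrant`, `call`.
#' @export
annotation_enrichment_2d <- function(values_x, values_y, sets, fdr = 0.02,
                                     min_members = 5L, keep_all = FALSE) {
  check_universe(values_x)
  check_universe(values_y)
  if (!setequal(names(values_x), names(values_y))) {
    stop_subloc("x and y universes differ")
  }
  values_y <- values_y[names(values_x)]
  rx <- annotation_enrichment_1d(values_x, sets, fdr = fdr,
                                 min_members = min_members, keep_all = TRUE)
  ry <- annotation_enrichment_1d(values_y, sets, fdr = fdr,
                                 min_members = min_members, keep_all = TRUE)
  xy <- inner_join(
    rename(as_tibble(rx), score_x = "score_s", q_x = "q"),
    rename(as_tibble(ry)[, c("set_name", "score_s", "q")],
           score_y = "score_s", q_y = "q"),
    by = "set_name")
  res <- xy |>
    mutate(joint_q = pmin(.data$q_x, .data$q_y),
           significant = .data$q_x < fdr | .data$q_y < fdr,
           quadrant = dplyr::case_when(
             .data$score_x >= 0 & .data$score_y >= 0 ~ "correlated_up",
             .data$score_x < 0 & .data$score_y < 0 ~ "correlated_down",
             .data$score_x >= 0 & .data$score_y < 0 ~ "anti_correlated_x_up",
             TRUE ~ "anti_correlated_y_up"),
           call = if_else(startsWith(.data$quadrant, "anti"),
                          "mislocalization candidate", "expression change")) |>
    select("set_name", "n_members", "score_x", "score_y", "q_x", "q_y",
           "joint_q", "significant", "quadrant", "call") |>
    arrange(.data$joint_q)
  if (!keep_all) res <- res[res$significant %in% TRUE, , drop = FALSE]
  structure(res, fdr = fdr,
            class = c("subloc_enrichment2d", class(tibble())))
}

#' Per-feature one-sample t meta-analysis across samples
#'
#' For each feature, tests whether its log2 ratios across independent
#' samples (cell lines, replicates) differ from zero with a two-sided
#' one-sample Student t-test, then controls the FDR across features by
#' Benjamini-Hochberg. Features with fewer than 3 non-missing values are
#' reported `untested`; zero-variance rows are flagged `degenerate` with
#' p = 0 when the mean is nonzero and p = 1 otherwise.
#'
#' @param ratio_matrix Tibble with `feature_id` plus one numeric column per
#'   sample (missing values allowed), or a numeric matrix with rownames.
#' @return Tibble (class `subloc_meta`): `feature_id`, `n_used`, `mean`,
#'   `t`, `df`, `p`, `q`, `status` in `{tested, degenerate, untested}`.
#' @export
one_sample_t_meta <- function(ratio_matrix) {
  m <- ratio_matrix_to_matrix(ratio_matrix)
  stats_tbl <- purrr::map(seq_len(nrow(m)), function(i) {
    v <- m[i, ]
    v <- v[!is.na(v)]
    n <- length(v)
    if (n < 3L) {
      return(tibble(n_used = n, mean = if (n > 0) mean(v) else NA_real_,
                    t = NA_real_, df = NA_real_, p = NA_real_,
                    status = "untested"))
    }
    mu <- mean(v)
    s <- sd(v)
    if (s == 0) {
      return(tibble(n_used = n, mean = mu, t = NA_real_, df = n - 1,
                    p = if (mu != 0) 0 else 1, status = "degenerate"))
    }
    tstat <- mu / (s / sqrt(n))
    tibble(n_used = n, mean = mu, t = tstat, df = n - 1,
           p = 2 * pt(-abs(tstat), df = n - 1), status = "tested")
  }) |> list_rbind()
  res <- bind_cols(tibble(feature_id = rownames(m)), stats_tbl)
  res$q <- NA_real_
  tested <- res$status != "untested"
  res$q[tested] <- bh_fdr(res$p[tested])
  res <- res[, c("feature_id", "n_used", "mean", "t", "df", "p", "q",
                 "status")]
  structure(res, class = c("subloc_meta", class(tibble())))
}

ratio_matrix_to_matrix <- function(ratio_matrix) {
  if (is.matrix(ratio_matrix)) {
    if (is.null(rownames(ratio_matrix))) {
      stop_subloc("ratio matrix needs rownames")
    }
    return(ratio_matrix)
  }
  x <- as_tibble(ratio_matrix)
  if (!"feature_id" %in% names(x)) stop_subloc("need a feature_id column")
  num_cols <- names(x)[vapply(x, is.numeric, logical(1))]
  m <- as.matrix(x[, num_cols, drop = FALSE])
  rownames(m) <- x$feature_id
  m
}

#' Fisher over-representation of annotation sets in a target list
#'
#' One-sided hypergeometric test per set: the probability of observing at
#' least the attained overlap between the target list and the set, given the
#' universe. BH control runs across the tested sets; categories disjoint
#' from the universe are excluded.
#'
#' @param target Character vector of feature ids (must be a subset of
#'   `universe`, non-empty).
#' @param universe Character vector of all analyzed feature ids.
#' @param sets Named list of character vectors.
#' @param fdr FDR threshold for the `significant` flag (default 0.02).
#' @return Tibble: `set_name`, `n_set`, `n_overlap`, `expected`, `p`, `q`,
#'   `significant`.
#' @export
fisher_over_representation <- function(target, universe, sets, fdr = 0.02) {
  if (length(target) == 0L) stop_subloc("`target` must be non-empty")
  universe <- unique(universe)
  target <- unique(target)
  if (!all(target %in% universe)) {
    stop_subloc("`target` must be a subset of `universe`")
  }
  check_sets(sets)
  N <- length(universe)
  n <- length(target)
  rows <- purrr::imap(sets, function(s, nm) {
    s <- intersect(unique(s), universe)
    K <- length(s)
    if (K == 0L) return(NULL)
    k <- length(intersect(s, target))
    tibble(set_name = nm, n_set = K, n_overlap = k,
           expected = n * K / N,
           p = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  }) |> list_rbind()
  if (is.null(rows) || nrow(rows) == 0L) {
    return(tibble(set_name = character(), n_set = integer(),
                  n_overlap = integer(), expected = double(), p = double(),
                  q = double(), significant = logical()))
  }
  rows$q <- bh_fdr(rows$p)
  rows$significant <- rows$q < fdr
  arrange(rows, .data$q, .data$p)
}
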