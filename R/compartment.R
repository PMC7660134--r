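#' Log2 compartment ratio table from paired counts
#'
#' Converts paired protrusion/cell-body raw counts into per-gene log2 ratios:
#' each library is scaled to counts per million, a pseudocount is added to
#' both compartments, and the ratio `log2((P + pc) / (B + pc))` is computed
#' per sample. Genes whose summed raw count over the pair falls below
#' `min_count` are dropped for that sample (recorded in the `"dropped"`
#' attribute); genes dropped in every sample are removed. With
#' `median_center = TRUE` each sample's median log2 ratio is subtracted,
#' the normalization-by-median-subtraction step standard for this assay.
#'
#' @param counts A `subloc_counts` tibble from [read_count_table()] (or any
#'   tibble with `feature_id` and count columns plus a design attribute /
#'   `design` argument pairing a protrusion and a body column per sample).
#' @param pseudocount Added to both CPM-scaled compartments (default 1).
#' @param min_count Minimum summed raw count of the pair (default 10).
#' @param median_center Subtract each sample's median ratio (default TRUE).
#' @param design Optional design tibble overriding the attached attribute.
#' @return Tibble with `feature_id` and one `log2_ratio` column per sample
#'   (named by `sample_id`), class `subloc_ratios`; attribute `dropped`
#'   counts genes dropped per sample.
#' @export
log2_ratio_table <- function(counts, pseudocount = 1, min_count = 10L,
                             median_center = TRUE, design = NULL) {
  check_number(pseudocount, "pseudocount", lower = 0)
  check_number(min_count, "min_count", lower = 0)
  check_flag(median_center, "median_center")
  des <- design %||% attr(counts, "design")
  if (is.null(des)) stop_subloc("counts carry no design; pass `design`")
  tab <- as_tibble(counts)
  pairs <- tidyr::pivot_wider(as_tibble(des)[, c("column", "sample_id",
                                                 "compartment")],
                              names_from = "compartment",
                              values_from = "column")
  if (!all(c("protrusion", "body") %in% names(pairs)) ||
      any(is.na(pairs$protrusion)) || any(is.na(pairs$body))) {
    stop_subloc("each sample needs exactly one protrusion and one body column")
  }
  out <- tibble(feature_id = tab$feature_id)
  dropped <- tibble(sample_id = character(), n_dropped = integer())
  for (i in seq_len(nrow(pairs))) {
    pcol <- tab[[pairs$protrusion[i]]]
    bcol <- tab[[pairs$body[i]]]
    p_cpm <- pcol / sum(pcol) * 1e6
    b_cpm <- bcol / sum(bcol) * 1e6
    ratio <- log2((p_cpm + pseudocount) / (b_cpm + pseudocount))
    low <- (pcol + bcol) < min_count
    ratio[low] <- NA_real_
    if (median_center) {
      ratio <- ratio - median(ratio, na.rm = TRUE)
    }
    out[[pairs$sample_id[i]]] <- ratio
    dropped <- bind_rows(dropped, tibble(sample_id = pairs$sample_id[i],
                                         n_dropped = sum(low)))
  }
  keep <- rowSums(!is.na(as.matrix(out[, -1, drop = FALSE]))) > 0
  out <- out[keep, , drop = FALSE]
  structure(out, dropped = dropped, pseudocount = pseudocount,
            min_count = min_count, median_center = median_center,
            class = c("subloc_ratios", class(tibble())))
}

#' Category localization shift test on one ratio column
#'
#' Asks whether an annotated gene category (e.g. the ribosomal proteins)
#' shifts as a block within one sample's ranked log2 compartment ratios.
#' Thin wrapper over [mwu_category_test()]; the shift direction is the sign
#' of the rank-biserial score.
#'
#' @param ratios A `subloc_ratios` tibble, a named numeric vector, or a
#'   tibble with `feature_id` plus one numeric column.
#' @param category Character vector of member feature ids.
#' @param sample Sample column to use when `ratios` has several.
#' @return One-row tibble: `set_name`, `n_members`, `score_s`,
#'   `statistic_U`, `p`, `direction`.
#' @export
category_shift_test <- function(ratios, category, sample = NULL) {
  values <- ratio_values(ratios, sample)
  members <- intersect(unique(category), names(values)[!is.na(values)])
  if (length(members) == 0L) stop_subloc("category outside the universe")
  res <- mwu_category_test(values, members)
  tibble(set_name = "category", n_members = res$n_members,
         score_s = res$score_s, statistic_U = res$statistic_U, p = res$p,
         direction = sign(res$score_s))
}

ratio_values <- function(ratios, sample = NULL) {
  if (is.numeric(ratios) && !is.null(names(ratios))) return(ratios)
  x <- as_tibble(ratios)
  if (!"feature_id" %in% names(x)) stop_subloc("need feature_id column")
  num_cols <- names(x)[vapply(x, is.numeric, logical(1))]
  col <- sample %||% num_cols[1]
  if (length(num_cols) > 1L && is.null(sample)) {
    warn(sprintf("multiple sample columns; using '%s'", col))
  }
  if (!col %in% num_cols) stop_subloc("no sample column '%s'", col)
  setNames(x[[col]], x$feature_id)
}

#' Knockdown mislocalization analysis (2D enrichment)
#'
#' Compares category behaviour between two knockdown-response dimensions —
#' NT/KD log2 ratios measured in protrusions (x) and in cell bodies (y) —
#' via [annotation_enrichment_2d()]. Significant categories moving in
#' opposite directions in the two compartments are mislocalization
#' candidates; same-direction categories are expression changes.
#'
#' @param ratios_protrusion,ratios_body Named numeric vectors of NT/KD
#'   log2 ratios over a shared gene universe.
#' @inheritParams annotation_enrichment_1d
#' @return See [annotation_enrichment_2d()].
#' @export
knockdown_shift_analysis <- function(ratios_protrusion, ratios_body, sets,
                                     fdr = 0.02, min_members = 5L,
                                     keep_all = FALSE) {
  if (length(intersect(names(ratios_protrusion),
                       names(ratios_body))) == 0L) {
    stop_subloc("protrusion and body universes are disjoint")
  }
  annotation_enrichment_2d(ratios_protrusion, ratios_body, sets, fdr = fdr,
                           min_members = min_members, keep_all = keep_all)
}

#' Meta-analysis volcano table for protrusion-enriched RBPs
#'
#' One-sample t meta-analysis of per-protein log2 protrusion/body ratios
#' across independent cell lines, flagging proteins that are significantly
#' protrusion-enriched (q < `fdr`, positive mean) and annotated as
#' RNA-binding.
#'
#' @param ratio_panel Tibble `feature_id` + one log2-ratio column per line.
#' @param rbp_set Character vector of RNA-binding protein ids.
#' @param fdr Enrichment flag threshold (default 0.05, the published
#'   volcano cut-off).
#' @return Tibble: meta-analysis columns plus `is_rbp` and
#'   `is_enriched_rbp`.
#' @export
rbp_meta_volcano <- function(ratio_panel, rbp_set, fdr = 0.05) {
  meta <- one_sample_t_meta(ratio_panel)
  res <- as_tibble(meta) |>
    mutate(is_rbp = .data$feature_id %in% rbp_set,
           is_enriched_rbp = .data$is_rbp & !is.na(.data$q) &
             .data$q < fdr & .data$mean > 0)
  structure(res, fdr = fdr,
            class = c("subloc_volcano", class(tibble())))
}
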