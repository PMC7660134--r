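# Pulsed-SILAC translation accounting.
#
# Triplet tables carry one row per (protein, compartment, replicate) with
# L/M/H intensities and a per-replicate `label_scheme` saying which of the
# two pulse labels (M or H) marks the open-pore (protrusion-forming)
# condition; the other pulse label is the closed-pore control and L is the
# pre-pulse ("old") proteome.

validate_triplets <- function(triplets) {
  x <- as_tibble(triplets)
  need <- c("protein_id", "intensity_L", "intensity_M", "intensity_H",
            "compartment", "replicate_id", "label_scheme")
  if (!all(need %in% names(x))) {
    stop_subloc("triplets need columns: %s", paste(need, collapse = ", "))
  }
  ints <- c("intensity_L", "intensity_M", "intensity_H")
  for (cc in ints) {
    if (any(x[[cc]] < 0, na.rm = TRUE)) stop_subloc("negative intensity in %s", cc)
  }
  if (!all(x$label_scheme %in% c("H_open", "M_open"))) {
    stop_subloc("label_scheme must be 'H_open' or 'M_open'")
  }
  x
}

#' Translation-rate ratios from reciprocally labeled pulsed SILAC
#'
#' Computes per-protein log2(open/closed) translation-rate ratios from
#' whole-cell pulsed-SILAC H/M intensities, harmonizing the label
#' orientation of reciprocally labeled replicates via each replicate's
#' `label_scheme`. Zero intensity in either condition propagates to a
#' missing ratio (never +/-Inf). Proteins quantified in both replicates
#' form the returned ratio matrix; singletons go to the `"singletons"`
#' attribute for side reporting.
#'
#' @param triplets Whole-cell SILAC triplet tibble (see
#'   [gen_pulsed_silac()] for the column contract).
#' @return Tibble `protein_id` + one `log2 open/closed` column per
#'   replicate, class `subloc_ratios`.
#' @export
translation_rate_ratios <- function(triplets) {
  x <- validate_triplets(triplets)
  x <- x[x$compartment == "whole", , drop = FALSE]
  if (nrow(x) == 0L) stop_subloc("no whole-cell rows in triplets")
  x <- x |>
    mutate(open = if_else(.data$label_scheme == "H_open",
                          .data$intensity_H, .data$intensity_M),
           closed = if_else(.data$label_scheme == "H_open",
                            .data$intensity_M, .data$intensity_H),
           log2_ratio = if_else(.data$open > 0 & .data$closed > 0,
                                log2(.data$open / .data$closed), NA_real_))
  wide <- tidyr::pivot_wider(x[, c("protein_id", "replicate_id",
                                   "log2_ratio")],
                             names_from = "replicate_id",
                             values_from = "log2_ratio")
  rep_cols <- setdiff(names(wide), "protein_id")
  complete <- stats::complete.cases(wide[, rep_cols, drop = FALSE])
  structure(wide[complete, , drop = FALSE],
            singletons = wide[!complete, , drop = FALSE],
            class = c("subloc_ratios", class(tibble())))
}

#' Percent of each SILAC label per subcellular compartment
#'
#' For each protein and label (L = old, M/H = nascent), expresses the iBAQ
#' intensity in each compartment as a percentage of that label's summed
#' intensity across all measured compartments. Labels with zero total
#' intensity for a protein are flagged undefined. Fractions are computed
#' independently per label, so each (protein, label) row set sums to 100.
#'
#' @param triplets SILAC triplet tibble restricted to one replicate's
#'   compartment fractionation (compartments among nucleus, cytosol,
#'   membrane).
#' @return Tibble: `protein_id`, `label`, `compartment`, `percent`,
#'   `defined`.
#' @export
compartment_fractions <- function(triplets) {
  x <- validate_triplets(triplets)
  x <- x[x$compartment != "whole", , drop = FALSE]
  if (nrow(x) == 0L) stop_subloc("no compartment rows in triplets")
  long <- tidyr::pivot_longer(
    x[, c("protein_id", "compartment", "intensity_L", "intensity_M",
          "intensity_H")],
    cols = dplyr::starts_with("intensity_"), names_to = "label",
    names_prefix = "intensity_", values_to = "intensity")
  long |>
    group_by(.data$protein_id, .data$label) |>
    mutate(total = sum(.data$intensity),
           defined = .data$total > 0,
           percent = if_else(.data$defined,
                             100 * .data$intensity / .data$total,
                             NA_real_)) |>
    ungroup() |>
    select("protein_id", "label", "compartment", "percent", "defined")
}

#' Nascent versus old compartment distribution of a protein set
#'
#' Summarizes, for an annotated protein set (typically the ribosomal
#' proteins), the per-label distribution of compartment percentages
#' (median, quartiles, min-max, box-plot ready) and tests whether the
#' nascent labels (M, H) occupy the nucleus differently from the old
#' proteome (L) with two-tailed two-sample Student t-tests (homoscedastic),
#' reported both pooled across proteins and paired within proteins.
#'
#' @param fractions Output of [compartment_fractions()].
#' @param protein_set Character vector of protein ids (>= 3 required with
#'   defined fractions; otherwise the tests are reported untested).
#' @param test_compartment Compartment whose percentages are tested
#'   (default `"nucleus"`).
#' @return List with `summary` (per label x compartment) and `tests`
#'   (comparisons `L_vs_M`, `L_vs_H`, pooled and paired p-values).
#' @export
nascent_vs_old_summary <- function(fractions, protein_set,
                                   test_compartment = "nucleus") {
  f <- as_tibble(fractions)
  f <- f[f$protein_id %in% protein_set & f$defined %in% TRUE, , drop = FALSE]
  summary_tbl <- f |>
    group_by(.data$label, .data$compartment) |>
    summarise(n = dplyr::n_distinct(.data$protein_id),
              median = median(.data$percent),
              q1 = quantile(.data$percent, 0.25),
              q3 = quantile(.data$percent, 0.75),
              min = min(.data$percent), max = max(.data$percent),
              .groups = "drop")
  nuc <- f[f$compartment == test_compartment, , drop = FALSE]
  wide <- tidyr::pivot_wider(nuc[, c("protein_id", "label", "percent")],
                             names_from = "label", values_from = "percent")
  tests <- purrr::map(c(M = "M", H = "H"), function(lab) {
    if (!all(c("L", lab) %in% names(wide))) {
      return(tibble(comparison = paste0("L_vs_", lab), n = 0L,
                    p_pooled = NA_real_, p_paired = NA_real_,
                    status = "untested"))
    }
    ok <- stats::complete.cases(wide[, c("L", lab)])
    a <- wide$L[ok]
    b <- wide[[lab]][ok]
    if (length(a) < 3L) {
      return(tibble(comparison = paste0("L_vs_", lab), n = length(a),
                    p_pooled = NA_real_, p_paired = NA_real_,
                    status = "untested"))
    }
    tibble(comparison = paste0("L_vs_", lab), n = length(a),
           p_pooled = t.test(a, b, var.equal = TRUE)$p.value,
           p_paired = t.test(a, b, paired = TRUE)$p.value,
           status = "tested")
  }) |> list_rbind()
  list(summary = summary_tbl, tests = tests)
}

#' Category shift of protein levels after knockdown (spike-in SILAC)
#'
#' Given per-protein heavy-reference ratios for the knockdown and control
#' mixes (each referenced to the same heavy spike-in), derives the
#' per-protein abundance change `log2(KD/NT) = log2((H/L)_NT / (H/L)_KD)`
#' and tests annotated categories for a block shift with the rank-based
#' enrichment kernel.
#'
#' @param hl_ratios Tibble with `protein_id`, `hl_nt`, `hl_kd` (raw H/L
#'   ratios, > 0 when measured; missing or non-positive entries drop the
#'   protein, reported in the `"dropped"` attribute).
#' @inheritParams annotation_enrichment_1d
#' @return An [annotation_enrichment_1d()] table over `log2(KD/NT)`.
#' @export
kd_proteome_shift <- function(hl_ratios, sets, fdr = 0.05,
                              min_members = 5L, keep_all = FALSE) {
  x <- as_tibble(hl_ratios)
  need <- c("protein_id", "hl_nt", "hl_kd")
  if (!all(need %in% names(x))) {
    stop_subloc("hl_ratios needs columns: %s", paste(need, collapse = ", "))
  }
  ok <- !is.na(x$hl_nt) & !is.na(x$hl_kd) & x$hl_nt > 0 & x$hl_kd > 0
  values <- setNames(log2(x$hl_nt[ok] / x$hl_kd[ok]), x$protein_id[ok])
  res <- annotation_enrichment_1d(values, sets, fdr = fdr,
                                  min_members = min_members,
                                  keep_all = keep_all)
  attr(res, "dropped") <- x$protein_id[!ok]
  res
}
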