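# broom-style accessors for the classed result tables.

#' @export
tidy.subloc_enrichment <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' @export
glance.subloc_enrichment <- function(x, ...) {
  d <- as_tibble(unclass_result(x))
  tibble(n_sets = nrow(d),
         n_significant = sum(d$significant %in% TRUE),
         n_skipped = nrow(attr(x, "skipped") %||% tibble()),
         fdr = attr(x, "fdr") %||% NA_real_)
}

#' @export
tidy.subloc_enrichment2d <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' @export
glance.subloc_enrichment2d <- function(x, ...) {
  d <- as_tibble(unclass_result(x))
  tibble(n_sets = nrow(d),
         n_significant = sum(d$significant %in% TRUE),
         n_mislocalization = sum(d$significant %in% TRUE &
                                   d$call == "mislocalization candidate"),
         fdr = attr(x, "fdr") %||% NA_real_)
}

#' @export
tidy.subloc_meta <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' @export
glance.subloc_meta <- function(x, ...) {
  d <- as_tibble(unclass_result(x))
  tibble(n_features = nrow(d),
         n_tested = sum(d$status == "tested"),
         n_untested = sum(d$status == "untested"),
         n_degenerate = sum(d$status == "degenerate"))
}

unclass_result <- function(x) {
  class(x) <- setdiff(class(x), c("subloc_enrichment",
                                  "subloc_enrichment2d", "subloc_meta",
                                  "subloc_volcano", "subloc_ratios",
                                  "subloc_track", "subloc_metaprofile"))
  x
}
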