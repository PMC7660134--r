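# ggplot2 views of the main result types.

#' Volcano plot of the meta-analysis table
#'
#' Mean log2 ratio against -log10 q, highlighting flagged
#' protrusion-enriched RBPs when present.
#'
#' @param x A `subloc_meta` or `subloc_volcano` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_volcano <- function(x, ...) {
  d <- as_tibble(x)
  d <- d[!is.na(d$q), , drop = FALSE]
  d$neglog_q <- -log10(pmax(d$q, 1e-300))
  p <- ggplot(d, aes(x = .data$mean, y = .data$neglog_q)) +
    geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    labs(x = "mean log2 ratio", y = "-log10 q") +
    theme_bw()
  if ("is_enriched_rbp" %in% names(d)) {
    p <- p + geom_point(aes(colour = .data$is_enriched_rbp), size = 0.8) +
      scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red"),
                          name = "enriched RBP")
  } else {
    p <- p + geom_point(size = 0.8, colour = "grey40")
  }
  p
}

#' @export
autoplot.subloc_volcano <- function(object, ...) plot_volcano(object, ...)

#' @export
autoplot.subloc_meta <- function(object, ...) plot_volcano(object, ...)

#' Quadrant plot of 2D annotation enrichment
#'
#' Category scores in the two dimensions; anti-correlated significant
#' categories (mislocalization candidates) separate from correlated ones
#' (expression changes).
#'
#' @param x A `subloc_enrichment2d` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_enrichment_2d <- function(x, ...) {
  d <- as_tibble(x)
  ggplot(d, aes(x = .data$score_x, y = .data$score_y,
                colour = .data$call)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    geom_point() +
    labs(x = "enrichment score (x)", y = "enrichment score (y)") +
    theme_bw()
}

#' @export
autoplot.subloc_enrichment2d <- function(object, ...) {
  plot_enrichment_2d(object, ...)
}

#' Metaprofile line plot
#'
#' Library-normalized crosslink counts against the strand-oriented offset
#' from the aligned landmarks.
#'
#' @param x A `subloc_metaprofile` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_metaprofile <- function(x, ...) {
  ggplot(as_tibble(x), aes(x = .data$offset, y = .data$value)) +
    geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    geom_line() +
    labs(x = "offset from landmark (nt)",
         y = "crosslinks per million") +
    theme_bw()
}

#' @export
autoplot.subloc_metaprofile <- function(object, ...) {
  plot_metaprofile(object, ...)
}
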