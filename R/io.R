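#' Read a gene-level count table for paired subcellular compartments
#'
#' Parses a TSV of raw counts from compartment-fractionated 3' mRNA-seq
#' (one row per gene, one column per library). Compartment labels for each
#' column come either from a sidecar design file or, failing that, from a
#' `<sample>_<compartment>` column-name suffix where the compartment is
#' `protrusion` or `body`.
#'
#' @param path Path to a tab-separated file whose first column holds gene
#'   identifiers and whose remaining columns hold non-negative integer counts.
#' @param design Optional path to (or tibble of) a design table with columns
#'   `column`, `sample_id`, `compartment` (and optionally `condition`).
#'
#' @return A tibble with a `feature_id` column and one count column per
#'   library, carrying the design as the `"design"` attribute and class
#'   `subloc_counts`.
#' @export
read_count_table <- function(path, design = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(tab) == 0L || ncol(tab) < 2L) {
    stop_subloc("no features in count table '%s'", path)
  }
  names(tab)[1] <- "feature_id"
  tab$feature_id <- as.character(tab$feature_id)
  dup <- unique(tab$feature_id[duplicated(tab$feature_id)])
  if (length(dup) > 0L) {
    stop_subloc("duplicate feature id(s) in '%s': %s", path,
                paste(head(dup, 5L), collapse = ", "))
  }
  count_cols <- names(tab)[-1]
  for (cc in count_cols) {
    v <- tab[[cc]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0) || any(v != floor(v))) {
      stop_subloc("column '%s' contains negative or non-integer counts", cc)
    }
    tab[[cc]] <- as.integer(v)
  }
  des <- resolve_design(design, count_cols)
  structure(tab, design = des, class = c("subloc_counts", class(tab)))
}

resolve_design <- function(design, count_cols) {
  if (is.null(design)) {
    m <- stringr::str_match(count_cols, "^(.*)_(protrusion|body)$")
    if (any(is.na(m[, 1]))) {
      stop_subloc(paste0(
        "cannot infer compartments: column(s) %s lack a _protrusion/_body ",
        "suffix and no design file was given"),
        paste(count_cols[is.na(m[, 1])], collapse = ", "))
    }
    des <- tibble(column = count_cols, sample_id = m[, 2],
                  compartment = m[, 3])
  } else {
    des <- if (is.character(design)) {
      readr::read_tsv(design, show_col_types = FALSE, progress = FALSE)
    } else {
      as_tibble(design)
    }
    need <- c("column", "sample_id", "compartment")
    if (!all(need %in% names(des))) {
      stop_subloc("design must have columns: %s", paste(need, collapse = ", "))
    }
    missing_cols <- setdiff(count_cols, des$column)
    if (length(missing_cols) > 0L) {
      stop_subloc("design does not label column(s): %s",
                  paste(missing_cols, collapse = ", "))
    }
    des <- des[des$column %in% count_cols, , drop = FALSE]
  }
  bad <- setdiff(unique(des$compartment), c("protrusion", "body"))
  if (length(bad) > 0L) {
    stop_subloc("unknown compartment label(s): %s", paste(bad, collapse = ", "))
  }
  as_tibble(des)
}

#' Write/read count tables
#'
#' `write_count_table()` writes the counts as TSV and, when a design is
#' attached, a `<path>.design` sidecar; `read_count_table()` round-trips it.
#'
#' @param counts A `subloc_counts` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  readr::write_tsv(as_tibble(counts), path, progress = FALSE)
  des <- attr(counts, "design")
  if (!is.null(des)) {
    readr::write_tsv(des, paste0(path, ".design"), progress = FALSE)
  }
  invisible(path)
}

# ---- BED ------------------------------------------------------------------

bed_cols <- c("chrom", "start", "end", "name", "score", "strand")
cluster_extra_cols <- c("sum", "max_density", "min_density")

validate_intervals <- function(x) {
  x <- as_tibble(x)
  if (!all(bed_cols[c(1, 2, 3, 6)] %in% names(x))) {
    stop_subloc("intervals need columns chrom, start, end, strand")
  }
  if (!"name" %in% names(x)) x$name <- "."
  if (!"score" %in% names(x)) x$score <- 0
  if (any(x$end <= x$start)) {
    stop_subloc("interval with end <= start (0-based half-open required)")
  }
  if (any(x$start < 0)) stop_subloc("negative interval start")
  if (!all(x$strand %in% c("+", "-"))) {
    stop_subloc("strand must be '+' or '-'")
  }
  x
}

#' Write genomic intervals as BED6 (optionally BED6+3 for clusters)
#'
#' Coordinates are 0-based half-open, the package-wide internal convention.
#' Output lines are sorted by (chrom, start, end, strand). Cluster tables
#' carrying `sum`, `max_density` and `min_density` columns are written as
#' BED6+3 with those three extra columns.
#'
#' @param intervals Tibble with `chrom`, `start`, `end`, `strand` and
#'   optionally `name`, `score` plus the three cluster columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  x <- validate_intervals(intervals)
  extra <- intersect(cluster_extra_cols, names(x))
  keep <- c(bed_cols, if (length(extra) == 3L) cluster_extra_cols)
  x <- x[order(x$chrom, x$start, x$end, x$strand), keep, drop = FALSE]
  readr::write_tsv(x, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @return `read_bed()` returns the interval tibble (BED6 or BED6+3).
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       progress = FALSE,
                       col_types = readr::cols(X1 = readr::col_character(),
                                               X4 = readr::col_character(),
                                               X6 = readr::col_character()))
  if (ncol(x) == 0L || nrow(x) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = double(), strand = character()))
  }
  if (!ncol(x) %in% c(6L, 9L)) {
    stop_subloc("expected BED6 or BED6+3, got %d columns", ncol(x))
  }
  names(x) <- c(bed_cols, if (ncol(x) == 9L) cluster_extra_cols)
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  validate_intervals(x)
}

# ---- GTF-lite transcript annotation ---------------------------------------

region_roles <- c("five_prime_utr", "orf", "three_prime_utr", "intron")

#' Read/write the flat transcript-region annotation
#'
#' The annotation is a tab format with columns `gene_id`, `region_role`
#' (`five_prime_utr`, `orf`, `three_prime_utr`, `intron`), `chrom`, `start`,
#' `end`, `strand`; coordinates 0-based half-open. Regions of one gene must
#' be non-overlapping and strand-consistent. The transcription start site
#' (TSS) and ORF start used as metaprofile landmarks are derived from the
#' strand-wise extremes of the annotated regions.
#'
#' @param path Annotation file path.
#' @return A tibble with the columns above, classed `subloc_annotation`.
#' @export
read_annotation <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_annotation(x)
}

#' @rdname read_annotation
#' @param annotation Annotation tibble.
#' @export
write_annotation <- function(annotation, path) {
  readr::write_tsv(as_tibble(annotation), path, progress = FALSE)
  invisible(path)
}

validate_annotation <- function(x) {
  x <- as_tibble(x)
  need <- c("gene_id", "region_role", "chrom", "start", "end", "strand")
  if (!all(need %in% names(x))) {
    stop_subloc("annotation needs columns: %s", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(x$region_role), region_roles)
  if (length(bad) > 0L) {
    stop_subloc("unknown region_role(s): %s", paste(bad, collapse = ", "))
  }
  if (any(x$end <= x$start)) stop_subloc("annotation interval with end <= start")
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  # strand consistency and non-overlap within each gene
  by_gene <- split(x, x$gene_id)
  for (g in by_gene) {
    if (length(unique(g$strand)) != 1L) {
      stop_subloc("gene '%s' mixes strands", g$gene_id[1])
    }
    g <- g[order(g$start), ]
    if (nrow(g) > 1L && any(g$start[-1] < g$end[-nrow(g)] &
                            g$chrom[-1] == g$chrom[-nrow(g)])) {
      stop_subloc("gene '%s' has overlapping regions", g$gene_id[1])
    }
  }
  structure(x, class = c("subloc_annotation", class(x)))
}

#' Strand-oriented landmarks from an annotation
#'
#' `annotation_landmarks()` extracts per-gene landmark positions for
#' metaprofiles: the TSS (5' end of the gene span) or the ORF start
#' (5' end of the ORF region), honouring strand orientation.
#'
#' @param annotation A `subloc_annotation` tibble.
#' @param landmark `"tss"` or `"orf_start"`.
#' @return Tibble with `gene_id`, `chrom`, `position` (0-based), `strand`.
#' @export
annotation_landmarks <- function(annotation, landmark = c("tss", "orf_start")) {
  landmark <- match.arg(landmark)
  x <- as_tibble(annotation)
  if (landmark == "orf_start") x <- x[x$region_role == "orf", , drop = FALSE]
  x |>
    group_by(.data$gene_id, .data$chrom, .data$strand) |>
    summarise(position = if (first(.data$strand) == "+") min(.data$start)
              else max(.data$end) - 1L, .groups = "drop") |>
    select("gene_id", "chrom", "position", "strand")
}

# ---- Run configuration ----------------------------------------------------

#' Pipeline run configuration
#'
#' Bundles the seed and the analysis thresholds. Defaults reproduce the
#' published parameter set: Paraclu minimum in-cluster sum 10, maximum
#' cluster length 200 nt, minimum density increase 2; enrichment FDR 0.02;
#' meta-analysis FDR 0.05; CPM pseudocount 1; minimum summed raw count 10;
#' 5'TOP window 15 nt.
#'
#' @param seed Integer RNG seed recorded in every output header.
#' @param ... Named overrides of the defaults listed above.
#' @return A named list of class `subloc_config`.
#' @export
subloc_config <- function(seed = 1L, ...) {
  cfg <- list(seed = as.integer(seed), fdr = 0.02, meta_fdr = 0.05,
              min_members = 5L, pseudocount = 1, min_count = 10L,
              min_sum = 10, max_len = 200L, min_fold = 2,
              top_window = 15L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    stop_subloc("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  cfg <- modifyList(cfg, dots)
  structure(cfg, class = "subloc_config")
}

#' @rdname subloc_config
#' @param path Flat `key: value` text file (YAML-compatible subset).
#' @export
read_config <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- stringr::str_match(lines, "^\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$")
  if (any(is.na(kv[, 1]))) {
    stop_subloc("malformed config line: '%s'", lines[is.na(kv[, 1])][1])
  }
  vals <- lapply(kv[, 3], function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  do.call(subloc_config, setNames(vals, kv[, 2]))
}

#' @rdname subloc_config
#' @param config A `subloc_config` object.
#' @export
write_config <- function(config, path) {
  lines <- purrr::imap_chr(unclass(config),
                           function(v, k) sprintf("%s: %s", k, format(v)))
  readr::write_lines(lines, path)
  invisible(path)
}
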