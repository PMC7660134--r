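# iCLIP processing: reads -> demultiplexed samples -> truncation-site
# crosslink events -> UMI-deduplicated tracks -> Paraclu peaks -> specific
# binding sites, targets, region distributions and metaprofiles.

#' Read/write FASTQ
#'
#' Minimal FASTQ support for the synthetic iCLIP pipeline. Reading goes
#' through Biostrings; writing emits plain 4-line records with constant
#' quality.
#'
#' @param path FASTQ path (uncompressed).
#' @return `read_fastq()`: tibble with `read_id`, `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(read_id = names(x), seq = unname(as.character(x)))
}

#' @rdname read_fastq
#' @param reads Tibble with `read_id`, `seq`.
#' @export
write_fastq <- function(reads, path) {
  x <- as_tibble(reads)
  if (!all(c("read_id", "seq") %in% names(x))) {
    stop_subloc("reads need columns read_id, seq")
  }
  qual <- vapply(nchar(x$seq), function(n) strrep("I", n), character(1))
  lines <- as.vector(rbind(paste0("@", x$read_id), x$seq, "+", qual))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Barcode scheme for iCLIP read prefixes
#'
#' The read prefix is 12 nt: 3 random nt (W-degenerate, A/T), a 5-nt
#' experimental barcode, then 4 random nt. The UMI is the concatenation of
#' the two random parts (7 nt).
#'
#' @param barcodes Named character vector mapping 5-nt barcode sequences to
#'   sample ids; barcodes must be pairwise distinct.
#' @return A list of class `subloc_barcode_scheme`.
#' @export
barcode_scheme <- function(barcodes) {
  if (is.null(names(barcodes)) || any(!nzchar(names(barcodes)))) {
    stop_subloc("`barcodes` must be named barcode -> sample pairs")
  }
  if (any(nchar(names(barcodes)) != 5L)) {
    stop_subloc("barcodes must be 5 nt")
  }
  if (anyDuplicated(names(barcodes))) {
    stop_subloc("barcodes must be pairwise distinct")
  }
  structure(list(barcode_len = 5L, lead_random = 3L, tail_random = 4L,
                 prefix_len = 12L,
                 map = setNames(as.character(barcodes), names(barcodes))),
            class = "subloc_barcode_scheme")
}

#' Demultiplex iCLIP reads and extract UMIs
#'
#' Assigns each read to a sample by exact match of the 5-nt experimental
#' barcode at prefix positions 4-8, extracts the 7-nt UMI from positions
#' 1-3 and 9-12, and trims the full 12-nt prefix from the emitted read.
#' Reads shorter than the prefix or without a matching barcode go to the
#' unassigned bin with a reason.
#'
#' @param reads Tibble with `read_id`, `seq`, or a FASTQ path.
#' @param scheme A [barcode_scheme()] (or its named-vector shorthand).
#' @return List with `assigned` (tibble `read_id`, `sample_id`, `umi`,
#'   `seq`) and `unassigned` (tibble `read_id`, `reason`).
#' @export
demultiplex <- function(reads, scheme) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  if (!inherits(scheme, "subloc_barcode_scheme")) {
    scheme <- barcode_scheme(scheme)
  }
  x <- as_tibble(reads)
  too_short <- nchar(x$seq) < scheme$prefix_len
  ok <- x[!too_short, , drop = FALSE]
  bc <- substr(ok$seq, scheme$lead_random + 1L,
               scheme$lead_random + scheme$barcode_len)
  sample_id <- unname(scheme$map[bc])
  umi <- paste0(substr(ok$seq, 1L, scheme$lead_random),
                substr(ok$seq, scheme$lead_random + scheme$barcode_len + 1L,
                       scheme$prefix_len))
  assigned <- tibble(read_id = ok$read_id,
                     sample_id = sample_id,
                     umi = umi,
                     seq = substr(ok$seq, scheme$prefix_len + 1L,
                                  nchar(ok$seq)))
  unassigned <- bind_rows(
    tibble(read_id = x$read_id[too_short],
           reason = "shorter than 12-nt prefix"),
    tibble(read_id = assigned$read_id[is.na(assigned$sample_id)],
           reason = "no exact barcode match"))
  list(assigned = assigned[!is.na(assigned$sample_id), , drop = FALSE],
       unassigned = unassigned)
}

#' Crosslink events from insert alignments
#'
#' The crosslink site is the nucleotide immediately 5' of the cDNA insert,
#' where reverse transcription truncated: on the + strand, `start - 1` of
#' the 0-based half-open insert; on the - strand, `end`. Events falling
#' before the chromosome start (or past its end, when `chrom_sizes` is
#' given) are dropped and counted in the `"n_dropped"` attribute.
#'
#' @param alignments Tibble with `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, plus carried-through `umi` and `sample_id`.
#' @param chrom_sizes Optional named vector of chromosome lengths.
#' @return Tibble of crosslink events: `chrom`, `position`, `strand`,
#'   `umi`, `sample_id`.
#' @export
assign_crosslinks <- function(alignments, chrom_sizes = NULL) {
  x <- as_tibble(alignments)
  need <- c("chrom", "start", "end", "strand")
  if (!all(need %in% names(x))) {
    stop_subloc("alignments need columns: %s", paste(need, collapse = ", "))
  }
  position <- if_else(x$strand == "+", x$start - 1L, x$end)
  keep <- position >= 0L
  if (!is.null(chrom_sizes)) {
    lim <- unname(chrom_sizes[x$chrom])
    keep <- keep & !is.na(lim) & position < lim
  }
  out <- tibble(chrom = x$chrom, position = as.integer(position),
                strand = x$strand)
  if ("umi" %in% names(x)) out$umi <- x$umi
  if ("sample_id" %in% names(x)) out$sample_id <- x$sample_id
  structure(out[keep, , drop = FALSE], n_dropped = sum(!keep))
}

#' Collapse PCR duplicates into a crosslink track
#'
#' Reads mapping to the same crosslink position (chrom, position, strand)
#' with the same UMI are one ligation event; the track count at a position
#' is the number of distinct UMIs observed there. Order-independent.
#'
#' @param events Crosslink events from [assign_crosslinks()] (one sample).
#' @return Track tibble `chrom`, `position`, `strand`, `count`, with the
#'   summed `library_size` attribute.
#' @export
dedup_umi <- function(events) {
  x <- as_tibble(events)
  need <- c("chrom", "position", "strand", "umi")
  if (!all(need %in% names(x))) {
    stop_subloc("events need columns: %s", paste(need, collapse = ", "))
  }
  track <- x |>
    distinct(.data$chrom, .data$position, .data$strand, .data$umi) |>
    dplyr::count(.data$chrom, .data$position, .data$strand,
                 name = "count") |>
    arrange(.data$chrom, .data$position, .data$strand)
  structure(track, library_size = sum(track$count),
            class = c("subloc_track", class(tibble())))
}

#' Merge replicate crosslink tracks
#'
#' Position-wise sum of deduplicated counts across replicate tracks of one
#' condition; the merged library size is the sum of the parts.
#'
#' @param tracks List of track tibbles (from [dedup_umi()]).
#' @return A merged track tibble.
#' @export
merge_tracks <- function(tracks) {
  if (!is.list(tracks) || length(tracks) == 0L) {
    stop_subloc("`tracks` must be a non-empty list")
  }
  merged <- purrr::map(tracks, as_tibble) |>
    list_rbind() |>
    group_by(.data$chrom, .data$position, .data$strand) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    arrange(.data$chrom, .data$position, .data$strand)
  structure(merged, library_size = sum(merged$count),
            class = c("subloc_track", class(tibble())))
}

#' Subtract control peaks to reveal specific binding sites
#'
#' Removes every peak that overlaps a control peak by at least 1 nt on the
#' same strand and chromosome (bedtools `intersect -v` semantics). The
#' number removed is recorded in the `"n_removed"` attribute.
#'
#' @param peaks,control_peaks Cluster/peak tibbles with `chrom`, `start`,
#'   `end`, `strand`.
#' @return The specific peaks.
#' @export
subtract_control <- function(peaks, control_peaks) {
  p <- as_tibble(peaks)
  ctl <- as_tibble(control_peaks)
  if (nrow(p) == 0L || nrow(ctl) == 0L) {
    return(structure(p, n_removed = 0L))
  }
  hit <- vapply(seq_len(nrow(p)), function(i) {
    any(ctl$chrom == p$chrom[i] & ctl$strand == p$strand[i] &
          ctl$start < p$end[i] & ctl$end > p$start[i])
  }, logical(1))
  structure(p[!hit, , drop = FALSE], n_removed = sum(hit))
}

#' Call target genes from specific peaks
#'
#' A gene is a target when at least one specific peak overlaps any of its
#' annotated regions (exonic or intronic) on the same strand. Peaks hitting
#' regions of two or more genes call all of them and are flagged ambiguous;
#' peaks overlapping no annotated region are counted intergenic.
#'
#' @param specific_peaks Peak tibble (`chrom`, `start`, `end`, `strand`).
#' @param annotation A `subloc_annotation` tibble.
#' @return Tibble `gene_id`, `n_peaks`, `n_ambiguous`; attributes
#'   `n_intergenic` and `peak_assignments`.
#' @export
call_targets <- function(specific_peaks, annotation) {
  p <- as_tibble(specific_peaks)
  a <- as_tibble(annotation)
  assignments <- purrr::map(seq_len(nrow(p)), function(i) {
    hits <- a[a$chrom == p$chrom[i] & a$strand == p$strand[i] &
                a$start < p$end[i] & a$end > p$start[i], , drop = FALSE]
    genes <- unique(hits$gene_id)
    tibble(peak = i,
           gene_id = if (length(genes) == 0L) NA_character_ else genes,
           ambiguous = length(genes) > 1L)
  }) |> list_rbind()
  if (is.null(assignments) || nrow(assignments) == 0L) {
    assignments <- tibble(peak = integer(), gene_id = character(),
                          ambiguous = logical())
  }
  n_intergenic <- sum(is.na(assignments$gene_id[!duplicated(assignments$peak)]))
  called <- assignments[!is.na(assignments$gene_id), , drop = FALSE] |>
    group_by(.data$gene_id) |>
    summarise(n_peaks = dplyr::n(), n_ambiguous = sum(.data$ambiguous),
              .groups = "drop") |>
    arrange(dplyr::desc(.data$n_peaks), .data$gene_id)
  structure(called, n_intergenic = n_intergenic,
            peak_assignments = assignments)
}

#' Distribution of binding sites across transcript regions
#'
#' Assigns each peak to one region by its midpoint: the 5'TOP window (the
#' first `top_window` nt downstream of the TSS, default 15, covering the
#' 6-12-pyrimidine tract), else the annotated region role containing the
#' midpoint (5'UTR, ORF, 3'UTR, intron). Fractions are over the assigned
#' peaks and sum to 1; midpoints outside any annotated region are counted
#' in the `"n_unassigned"` attribute.
#'
#' @param specific_peaks Peak tibble.
#' @param annotation A `subloc_annotation` tibble.
#' @param top_window 5'TOP window length in nt (default 15).
#' @return Tibble `region`, `n_peaks`, `fraction` over regions
#'   `five_prime_top`, `five_prime_utr`, `orf`, `three_prime_utr`,
#'   `intron`.
#' @export
region_distribution <- function(specific_peaks, annotation,
                                top_window = 15L) {
  check_number(top_window, "top_window", lower = 1)
  p <- as_tibble(specific_peaks)
  a <- as_tibble(annotation)
  tss <- annotation_landmarks(annotation, "tss")
  regions <- c("five_prime_top", "five_prime_utr", "orf",
               "three_prime_utr", "intron")
  assign_one <- function(i) {
    mid <- (p$start[i] + p$end[i]) %/% 2L
    in_top <- tss$chrom == p$chrom[i] & tss$strand == p$strand[i] &
      ((tss$strand == "+" & mid >= tss$position &
          mid < tss$position + top_window) |
         (tss$strand == "-" & mid <= tss$position &
            mid > tss$position - top_window))
    if (any(in_top)) return("five_prime_top")
    hit <- a[a$chrom == p$chrom[i] & a$strand == p$strand[i] &
               a$start <= mid & mid < a$end, , drop = FALSE]
    if (nrow(hit) == 0L) return(NA_character_)
    hit$region_role[1]
  }
  assigned <- vapply(seq_len(nrow(p)), assign_one, character(1))
  counts <- table(factor(assigned, levels = regions))
  n_assigned <- sum(counts)
  out <- tibble(region = regions, n_peaks = as.integer(counts),
                fraction = if (n_assigned > 0) {
                  as.numeric(counts) / n_assigned
                } else {
                  rep(NA_real_, length(regions))
                })
  structure(out, n_unassigned = sum(is.na(assigned)))
}

#' Metaprofile of crosslink counts around aligned landmarks
#'
#' Sums track counts in strand-oriented offset coordinates around a set of
#' genomic landmarks (TSS, ORF start, gene end, ...), at 1-nt resolution,
#' and normalizes to crosslinks per million of the track's library size.
#' On the - strand, offsets run against the genome axis so that positive
#' offsets always point downstream of the landmark. Landmarks closer than
#' `window` to a contig edge are truncated and flagged.
#'
#' @param track Crosslink track tibble (attribute `library_size` used when
#'   present, else the track sum).
#' @param landmarks Tibble `chrom`, `position`, `strand`.
#' @param window Half-window in nt; offsets span `-window..window`.
#' @param chrom_sizes Optional named contig lengths for edge flagging.
#' @return Tibble `offset`, `count`, `value` (counts per million);
#'   attribute `n_truncated`.
#' @export
metaprofile <- function(track, landmarks, window = 50L, chrom_sizes = NULL) {
  check_number(window, "window", lower = 1)
  lm <- as_tibble(landmarks)
  if (nrow(lm) == 0L) stop_subloc("need at least one landmark")
  tr <- as_tibble(track)
  lib <- attr(track, "library_size") %||% sum(tr$count)
  offsets <- seq(-window, window)
  acc <- setNames(numeric(length(offsets)), offsets)
  n_trunc <- 0L
  for (i in seq_len(nrow(lm))) {
    if (lm$position[i] < window ||
        (!is.null(chrom_sizes) &&
         lm$position[i] + window >= chrom_sizes[lm$chrom[i]])) {
      n_trunc <- n_trunc + 1L
    }
    sel <- tr$chrom == lm$chrom[i] & tr$strand == lm$strand[i] &
      abs(tr$position - lm$position[i]) <= window
    if (!any(sel)) next
    sub <- tr[sel, , drop = FALSE]
    off <- if (lm$strand[i] == "+") {
      sub$position - lm$position[i]
    } else {
      lm$position[i] - sub$position
    }
    idx <- match(off, offsets)
    acc[idx] <- acc[idx] + sub$count
  }
  structure(tibble(offset = offsets, count = unname(acc),
                   value = unname(acc) / lib * 1e6),
            n_truncated = n_trunc, library_size = lib,
            class = c("subloc_metaprofile", class(tibble())))
}
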