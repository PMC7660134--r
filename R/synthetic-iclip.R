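# Synthetic iCLIP reads on a desk-scale pseudo-genome: planted crosslink
# clusters over uniform background, barcoded/UMI-tagged read prefixes, and
# optional PCR-duplicate injection by resampling existing (position, UMI)
# pairs.

#' Simulate iCLIP reads with planted crosslink clusters
#'
#' Generates, per sample, `n_reads` reads on one pseudo-chromosome. Each
#' fresh read samples a crosslink site: with probability `background_rate`
#' uniformly over the genome (random strand), otherwise inside a planted
#' cluster (uniformly within its interval, on the cluster strand, clusters
#' weighted by `rate * width`). The cDNA insert starts one position
#' downstream of the crosslink site on the read's strand, so the standard
#' truncation rule recovers the site exactly. The read sequence is the
#' 12-nt prefix — 3 random W (A/T) nt, the 5-nt sample barcode, 4 random
#' nt — followed by the insert; the 7-nt UMI is the concatenation of the
#' two random parts. With probability `duplicate_rate` a read is a PCR
#' duplicate: it resamples a previously generated (position, strand, UMI)
#' event of the same sample.
#'
#' @param clusters Tibble of planted clusters: `start`, `end` (0-based
#'   half-open), `strand`, `rate` (relative weight; optional, default 1).
#' @param background_rate Probability in \[0, 1\] that a fresh read is
#'   background.
#' @param barcodes Named character vector barcode -> sample id (5-nt,
#'   pairwise distinct).
#' @param n_reads Reads per sample.
#' @param genome_length Pseudo-chromosome length (default 10000).
#' @param insert_len cDNA insert length (default 30).
#' @param duplicate_rate PCR duplicate injection probability (default 0).
#' @param chrom Chromosome name (default `"chr1"`).
#' @param seed Integer seed.
#' @return List: `reads` (tibble `read_id`, `sample_id`, `seq`, `chrom`,
#'   `start`, `end`, `strand`, `umi`, `crosslink`, `is_duplicate`,
#'   `is_background`), `genome` (character), `truth` (planted cluster
#'   tibble in BED-compatible columns), `params`.
#' @export
gen_iclip_reads <- function(clusters, background_rate, barcodes, n_reads,
                            genome_length = 10000L, insert_len = 30L,
                            duplicate_rate = 0, chrom = "chr1",
                            seed = 1L) {
  check_number(background_rate, "background_rate", 0, 1)
  check_number(duplicate_rate, "duplicate_rate", 0, 1)
  check_number(n_reads, "n_reads", lower = 1)
  check_number(genome_length, "genome_length", lower = insert_len + 2)
  scheme <- barcode_scheme(barcodes)
  cl <- as_tibble(clusters)
  if (nrow(cl) > 0L) {
    if (!all(c("start", "end", "strand") %in% names(cl))) {
      stop_subloc("clusters need columns start, end, strand")
    }
    if (!"rate" %in% names(cl)) cl$rate <- 1
    if (any(cl$end <= cl$start)) stop_subloc("cluster with end <= start")
  }
  with_seed(seed, {
    genome <- paste(sample(c("A", "C", "G", "T"), genome_length,
                           replace = TRUE), collapse = "")
    samples <- unname(scheme$map)
    all_reads <- purrr::map(seq_along(samples), function(si) {
      sim_sample_reads(cl, background_rate, duplicate_rate, n_reads,
                       genome, genome_length, insert_len, chrom,
                       sample_id = samples[si],
                       barcode = names(scheme$map)[si])
    }) |> list_rbind()
    truth <- if (nrow(cl) > 0L) {
      tibble(chrom = chrom, start = as.integer(cl$start),
             end = as.integer(cl$end), name = sprintf(
               "planted_%02d", seq_len(nrow(cl))),
             score = cl$rate, strand = cl$strand)
    } else {
      tibble(chrom = character(), start = integer(), end = integer(),
             name = character(), score = double(), strand = character())
    }
    list(reads = all_reads, genome = genome, truth = truth,
         params = list(background_rate = background_rate,
                       duplicate_rate = duplicate_rate,
                       n_reads = n_reads, genome_length = genome_length,
                       insert_len = insert_len, chrom = chrom,
                       seed = seed))
  })
}

sim_sample_reads <- function(cl, background_rate, duplicate_rate, n_reads,
                             genome, genome_length, insert_len, chrom,
                             sample_id, barcode) {
  # crosslink positions must leave room for the insert on either strand
  lo <- insert_len # valid for - strand: xl in [insert_len, genome_length]
  hi_plus <- genome_length - insert_len - 1L
  pos <- integer(n_reads); strand <- character(n_reads)
  umi <- character(n_reads); is_dup <- logical(n_reads)
  is_bg <- logical(n_reads)
  for (i in seq_len(n_reads)) {
    if (i > 1L && runif(1) < duplicate_rate) {
      j <- sample.int(i - 1L, 1L)
      pos[i] <- pos[j]; strand[i] <- strand[j]; umi[i] <- umi[j]
      is_bg[i] <- is_bg[j]; is_dup[i] <- TRUE
    } else {
      bg <- nrow(cl) == 0L || runif(1) < background_rate
      if (bg) {
        strand[i] <- sample(c("+", "-"), 1L)
        pos[i] <- if (strand[i] == "+") sample(0:hi_plus, 1L) else
          sample(lo:genome_length, 1L)
      } else {
        w <- cl$rate * (cl$end - cl$start)
        j <- sample.int(nrow(cl), 1L, prob = w)
        strand[i] <- cl$strand[j]
        p <- sample(cl$start[j]:(cl$end[j] - 1L), 1L)
        pos[i] <- min(max(p, if (strand[i] == "-") lo else 0L),
                      if (strand[i] == "+") hi_plus else genome_length)
      }
      umi[i] <- paste0(
        paste(sample(c("A", "T"), 3L, replace = TRUE), collapse = ""),
        paste(sample(c("A", "C", "G", "T"), 4L, replace = TRUE),
              collapse = ""))
      is_bg[i] <- bg
    }
  }
  ins_start <- if_else(strand == "+", pos + 1L, pos - insert_len)
  ins_end <- ins_start + insert_len
  insert_seq <- substring(genome, ins_start + 1L, ins_end)
  minus <- strand == "-"
  if (any(minus)) {
    insert_seq[minus] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(
        insert_seq[minus])))
  }
  seq <- paste0(substr(umi, 1L, 3L), barcode, substr(umi, 4L, 7L),
                insert_seq)
  tibble(read_id = sprintf("%s_read_%06d", sample_id, seq_len(n_reads)),
         sample_id = sample_id, seq = seq, chrom = chrom,
         start = as.integer(ins_start), end = as.integer(ins_end),
         strand = strand, umi = umi, crosslink = as.integer(pos),
         is_duplicate = is_dup, is_background = is_bg)
}
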