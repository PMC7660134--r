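test_that("demultiplex extracts barcode and UMI by construction", {
  insert <- "ACGTACGTACGTACGTACGT"
  reads <- tibble::tibble(
    read_id = c("r1", "r2", "r3"),
    seq = c(paste0("ATA", "GGCTA", "ACGT", insert), # -> s1, UMI ATAACGT
            paste0("ATA", "GGCTT", "ACGT", insert), # 1 mismatch
            "ATAGGC")) # too short
  dmx <- demultiplex(reads, c(GGCTA = "s1"))
  expect_equal(dmx$assigned$sample_id, "s1")
  expect_equal(dmx$assigned$umi, "ATAACGT")
  expect_equal(dmx$assigned$seq, insert) # prefix trimmed
  expect_setequal(dmx$unassigned$read_id, c("r2", "r3"))
  expect_match(dmx$unassigned$reason[dmx$unassigned$read_id == "r2"],
               "barcode")
  # partition invariant
  expect_equal(nrow(dmx$assigned) + nrow(dmx$unassigned), nrow(reads))
})

test_that("fastq round trip preserves ids and sequences", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "reads.fastq")
  reads <- tibble::tibble(read_id = c("a", "b"),
                          seq = c("ACGT", "GGGTTTT"))
  write_fastq(reads, path)
  back <- read_fastq(path)
  expect_equal(back, reads)
})

test_that("crosslink assignment implements the truncation rule", {
  # + strand insert starting at 0-based 999 -> crosslink 998
  aln <- tibble::tibble(chrom = "chr1", start = 999L, end = 1049L,
                        strand = "+", umi = "AAAACCC", sample_id = "s1")
  ev <- assign_crosslinks(aln)
  expect_equal(ev$position, 998L)
  # - strand insert occupying [2000, 2050) -> crosslink 2050
  aln2 <- tibble::tibble(chrom = "chr1", start = 2000L, end = 2050L,
                         strand = "-", umi = "AAAACCC", sample_id = "s1")
  expect_equal(assign_crosslinks(aln2)$position, 2050L)
  # insert at position 0 on + strand is dropped and counted
  aln3 <- tibble::tibble(chrom = "chr1", start = 0L, end = 30L,
                         strand = "+", umi = "AAAACCC", sample_id = "s1")
  ev3 <- assign_crosslinks(aln3)
  expect_equal(nrow(ev3), 0L)
  expect_equal(attr(ev3, "n_dropped"), 1L)
  # chromosome bound applies to the - strand end rule
  aln4 <- tibble::tibble(chrom = "chr1", start = 70L, end = 100L,
                         strand = "-", umi = "AAAACCC", sample_id = "s1")
  ev4 <- assign_crosslinks(aln4, chrom_sizes = c(chr1 = 100L))
  expect_equal(nrow(ev4), 0L)
})

test_that("UMI dedup counts distinct molecules, order independent", {
  ev <- tibble::tibble(
    chrom = "chr1",
    position = c(100L, 100L, 100L, 101L),
    strand = "+",
    umi = c("AAAACCC", "AAAACCC", "AAAACCG", "AAAACCC"),
    sample_id = "s1")
  track <- dedup_umi(ev)
  expect_equal(track$count[track$position == 100L], 2L)
  expect_equal(track$count[track$position == 101L], 1L)
  expect_equal(attr(track, "library_size"), 3L)

  # no duplicates: counts equal read counts
  ev2 <- ev[c(1, 3, 4), ]
  expect_equal(attr(dedup_umi(ev2), "library_size"), 3L)

  # permutation invariance
  set.seed(1)
  shuffled <- ev[sample(nrow(ev)), ]
  expect_identical(dedup_umi(shuffled), track)
})

test_that("merging tracks sums positionwise and adds library sizes", {
  ev <- tibble::tibble(chrom = "chr1", position = c(5L, 9L), strand = "+",
                       umi = c("AAAAAAA", "TTTTTTT"), sample_id = "s1")
  tr <- dedup_umi(ev)
  dbl <- merge_tracks(list(tr, tr))
  expect_equal(dbl$count, tr$count * 2)
  expect_equal(attr(dbl, "library_size"),
               2 * attr(tr, "library_size"))
  empty <- tr[0, ]
  ident <- merge_tracks(list(tr, empty))
  expect_equal(ident$count, tr$count)
})

test_that("control subtraction removes any-overlap peaks", {
  peaks <- tibble::tibble(chrom = "chr1",
                          start = c(10L, 100L, 200L),
                          end = c(60L, 150L, 260L),
                          strand = c("+", "+", "-"))
  ctl <- tibble::tibble(chrom = "chr1", start = c(59L, 100L),
                        end = c(70L, 150L), strand = c("+", "-"))
  # peak 1: 1-nt overlap -> removed; peak 2: same interval other strand
  # in control -> kept; peak 3 untouched
  specific <- subtract_control(peaks, ctl)
  expect_equal(specific$start, c(100L, 200L))
  expect_equal(attr(specific, "n_removed"), 1L)
  # postcondition: no output peak overlaps a control peak on its strand
  for (i in seq_len(nrow(specific))) {
    expect_false(any(ctl$chrom == specific$chrom[i] &
                       ctl$strand == specific$strand[i] &
                       ctl$start < specific$end[i] &
                       ctl$end > specific$start[i]))
  }
  # disjoint sets unchanged
  far <- tibble::tibble(chrom = "chr1", start = 1000L, end = 1100L,
                        strand = "+")
  expect_equal(nrow(subtract_control(peaks, far)), 3L)
})

toy_annotation <- function() {
  ann <- tibble::tibble(
    gene_id = c("g1", "g1", "g1", "g1", "g2", "g3"),
    region_role = c("five_prime_utr", "orf", "intron",
                    "three_prime_utr", "orf", "orf"),
    chrom = "chr1",
    start = c(100L, 140L, 300L, 400L, 480L, 950L),
    end = c(140L, 300L, 400L, 500L, 600L, 1000L),
    strand = c("+", "+", "+", "+", "+", "-"))
  structure(ann, class = c("subloc_annotation", class(ann)))
}

test_that("target calling overlaps peaks with gene regions, flags
           ambiguity and intergenic peaks", {
  ann <- toy_annotation()
  peaks <- tibble::tibble(
    chrom = "chr1",
    start = c(150L, 700L, 490L, 960L),
    end = c(170L, 720L, 510L, 980L),
    strand = c("+", "+", "+", "+"))
  # peak1 in g1 ORF; peak2 intergenic; peak3 spans g1 3'UTR + g2 ORF;
  # peak4 overlaps g3 interval but wrong strand
  res <- call_targets(peaks, ann)
  expect_setequal(res$gene_id, c("g1", "g2"))
  expect_equal(res$n_peaks[res$gene_id == "g1"], 2L)
  expect_equal(attr(res, "n_intergenic"), 2L)
  pa <- attr(res, "peak_assignments")
  expect_true(all(pa$ambiguous[pa$peak == 3]))
})

test_that("region distribution uses midpoints and the 5'TOP window", {
  ann <- toy_annotation()
  peaks <- tibble::tibble(
    chrom = "chr1",
    start = c(101L, 120L, 200L, 350L, 450L),
    end = c(106L, 130L, 220L, 360L, 470L),
    strand = "+")
  # midpoints: 103 (TSS+3 -> TOP), 125 (5'UTR), 210 (ORF), 355 (intron),
  # 460 (3'UTR)
  res <- region_distribution(peaks, ann, top_window = 15L)
  got <- setNames(res$n_peaks, res$region)
  expect_equal(unname(got[c("five_prime_top", "five_prime_utr", "orf",
                            "intron", "three_prime_utr")]),
               c(1L, 1L, 1L, 1L, 1L))
  expect_equal(sum(res$fraction), 1)
  expect_equal(attr(res, "n_unassigned"), 0L)

  # the TOP window is strand oriented: for g3 (- strand, TSS at 999)
  minus_peak <- tibble::tibble(chrom = "chr1", start = 993L, end = 998L,
                               strand = "-") # midpoint 995, TSS-4
  res_m <- region_distribution(minus_peak, ann, top_window = 15L)
  expect_equal(res_m$n_peaks[res_m$region == "five_prime_top"], 1L)
})

test_that("metaprofile normalizes to library size and mirrors strand", {
  ev <- tibble::tibble(chrom = "chr1", position = c(500L, 520L),
                       strand = "+",
                       umi = c("AAAAAAA", "TTTTTTT"), sample_id = "s1")
  track <- dedup_umi(ev)
  lm <- tibble::tibble(chrom = "chr1", position = 500L, strand = "+")
  prof <- metaprofile(track, lm, window = 10L)
  expect_equal(prof$value[prof$offset == 0],
               1e6 / attr(track, "library_size"))
  expect_equal(sum(prof$value > 0), 1L) # 520 outside the window

  # a - strand landmark sees upstream positions at positive offsets
  ev_m <- tibble::tibble(chrom = "chr1", position = c(495L, 505L),
                         strand = "-",
                         umi = c("AAAAAAA", "TTTTTTT"), sample_id = "s1")
  track_m <- dedup_umi(ev_m)
  lm_m <- tibble::tibble(chrom = "chr1", position = 500L, strand = "-")
  prof_m <- metaprofile(track_m, lm_m, window = 10L)
  expect_equal(prof_m$count[prof_m$offset == 5], 1)
  expect_equal(prof_m$count[prof_m$offset == -5], 1)
  # mirrored relative to the same positions on the + strand
  track_p <- dedup_umi(dplyr::mutate(ev_m, strand = "+"))
  prof_p <- metaprofile(track_p,
                        dplyr::mutate(lm_m, strand = "+"), window = 10L)
  expect_equal(prof_m$count, rev(prof_p$count))

  # edge landmark flagged
  lm_edge <- tibble::tibble(chrom = "chr1", position = 3L, strand = "+")
  prof_e <- metaprofile(track, lm_edge, window = 10L)
  expect_equal(attr(prof_e, "n_truncated"), 1L)
  expect_error(metaprofile(track, lm[0, ], window = 10), "landmark")
})

test_that("a noiseless planted cluster is recovered exactly", {
  planted <- tibble::tibble(start = 2000L, end = 2050L, strand = "+",
                            rate = 10)
  g <- gen_iclip_reads(planted, background_rate = 0,
                       barcodes = c(GGCTA = "s1"), n_reads = 400,
                       genome_length = 5000L, seed = 16)
  track <- dedup_umi(assign_crosslinks(g$reads))
  # the filtered cluster family contains the planted interval itself
  fam <- paraclu_family(track)
  surv <- fam[fam$sum >= 10 & (fam$end - fam$start) <= 200 &
                fam$fold >= 2, ]
  expect_true(any(surv$start == 2000L & surv$end == 2050L))
  # and every reported peak lies inside it (no noise, no spill-over)
  peaks <- paraclu(track)
  expect_gte(nrow(peaks), 1L)
  expect_true(all(peaks$start >= 2000L & peaks$end <= 2050L))
})

test_that("the read-level pipeline is invariant to input order", {
  clusters <- tibble::tibble(start = c(300L, 700L), end = c(350L, 740L),
                             strand = c("+", "-"))
  ic <- gen_iclip_reads(clusters, background_rate = 0.3,
                        barcodes = c(GGCTA = "s1"), n_reads = 400,
                        genome_length = 1500L, duplicate_rate = 0.2,
                        seed = 30)
  run <- function(reads) {
    dmx <- demultiplex(reads[, c("read_id", "seq")], c(GGCTA = "s1"))
    ev <- assign_crosslinks(
      dplyr::inner_join(dmx$assigned[, c("read_id", "sample_id", "umi")],
                        ic$reads[, c("read_id", "chrom", "start", "end",
                                     "strand")],
                        by = "read_id"))
    paraclu(dedup_umi(ev), min_sum = 5, max_len = 200,
            min_density_increase = 1.5)
  }
  set.seed(99)
  shuffled <- ic$reads[sample(nrow(ic$reads)), ]
  expect_identical(run(ic$reads), run(shuffled))
})
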