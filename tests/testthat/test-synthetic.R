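test_that("generators are deterministic given the seed", {
  a <- gen_compartment_counts(200, 20, delta = 1, seed = 5)
  b <- gen_compartment_counts(200, 20, delta = 1, seed = 5)
  expect_identical(a, b)
  c <- gen_compartment_counts(200, 20, delta = 1, seed = 6)
  expect_false(identical(a$counts, c$counts))

  r1 <- gen_ratio_panel(100, 4, 10, delta = 0.5, seed = 2)
  r2 <- gen_ratio_panel(100, 4, 10, delta = 0.5, seed = 2)
  expect_identical(r1, r2)

  s1 <- gen_pulsed_silac(50, 10, rate_delta = 0.3, seed = 3)
  s2 <- gen_pulsed_silac(50, 10, rate_delta = 0.3, seed = 3)
  expect_identical(s1, s2)

  i1 <- gen_iclip_reads(tibble::tibble(start = 100L, end = 150L,
                                       strand = "+"),
                        background_rate = 0.2, barcodes = c(GGCTA = "s1"),
                        n_reads = 50, genome_length = 1000L, seed = 4)
  i2 <- gen_iclip_reads(tibble::tibble(start = 100L, end = 150L,
                                       strand = "+"),
                        background_rate = 0.2, barcodes = c(GGCTA = "s1"),
                        n_reads = 50, genome_length = 1000L, seed = 4)
  expect_identical(i1, i2)

  f1 <- gen_spot_field(50, c(2, 0), 1, seed = 8)
  f2 <- gen_spot_field(50, c(2, 0), 1, seed = 8)
  expect_identical(f1, f2)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(gen_ratio_panel(50, 3, 5, delta = 1, seed = 1))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("count generator validates arguments and records truth", {
  expect_error(gen_compartment_counts(100, 10, delta = 1, dispersion = 0),
               "dispersion")
  expect_error(gen_compartment_counts(1, 2, delta = 1), "n_genes")
  cc <- gen_compartment_counts(500, 40, delta = 1, seed = 1)
  expect_equal(sum(cc$truth$in_category), 40L)
  expect_equal(unique(cc$truth$delta[cc$truth$in_category]), 1)
  expect_equal(unique(cc$truth$delta[!cc$truth$in_category]), 0)
  expect_equal(attr(cc$counts, "design")$compartment,
               c("protrusion", "body"))
})

test_that("planted category shift is recovered with positive sign", {
  cc <- gen_compartment_counts(5000, 80, delta = 1.0, seed = 42)
  ratios <- log2_ratio_table(cc$counts)
  values <- setNames(ratios$s1, ratios$feature_id)
  res <- category_shift_test(values,
                             cc$truth$feature_id[cc$truth$in_category])
  expect_gt(res$score_s, 0)
  expect_lt(res$p, 0.01)
})

test_that("null category shift is calibrated at alpha = 0.01", {
  # delta = 0: the category test should be non-significant at alpha=0.01
  # in at least 95% of seeds
  hits <- vapply(1:100, function(s) {
    cc <- gen_compartment_counts(400, 30, delta = 0, seed = s)
    ratios <- log2_ratio_table(cc$counts)
    values <- setNames(ratios$s1, ratios$feature_id)
    res <- category_shift_test(values,
                               cc$truth$feature_id[cc$truth$in_category])
    res$p < 0.01
  }, logical(1))
  expect_lte(mean(hits), 0.05)
})

test_that("ratio panel power and calibration match the stated world", {
  expect_error(gen_ratio_panel(100, 1, 10, delta = 1), "n_samples")
  expect_error(gen_ratio_panel(100, 4, 10, delta = 1, noise_sd = 0),
               "noise_sd")

  # power: delta=1, sd=0.3, 6 samples -> >= 90% of the enriched set at
  # FDR < 0.05 (expected fraction estimated over seeds; the long-run
  # value is 0.912 +/- 0.005 over 40 seeds)
  frac <- vapply(1:20, function(s) {
    rp <- gen_ratio_panel(2000, 6, 100, delta = 1, noise_sd = 0.3,
                          seed = s)
    enr <- rp$truth$feature_id[rp$truth$enriched]
    meta <- one_sample_t_meta(rp$ratios)
    flagged <- meta$feature_id[!is.na(meta$q) & meta$q < 0.05 &
                                 meta$mean > 0]
    mean(enr %in% flagged)
  }, numeric(1))
  expect_gte(mean(frac), 0.9)

  # calibration: delta=0 -> observed FDR among flagged <= nominal within
  # Monte-Carlo error (flagging anything at all is already rare)
  n_false <- vapply(1:20, function(s) {
    rp <- gen_ratio_panel(500, 6, 50, delta = 0, noise_sd = 0.3,
                          seed = 100 + s)
    meta <- one_sample_t_meta(rp$ratios)
    sum(!is.na(meta$q) & meta$q < 0.05)
  }, numeric(1))
  expect_lte(mean(n_false > 0), 0.05 + 3 * sqrt(0.05 * 0.95 / 20))
})

test_that("pulsed SILAC generator plants reciprocal labels and fractions", {
  expect_error(gen_pulsed_silac(50, 10, 0.3, compartments = character(0)),
               "empty")
  ps <- gen_pulsed_silac(200, 30, rate_delta = 0.3, seed = 10)
  schemes <- unique(ps$triplets[ps$triplets$compartment == "whole",
                                c("replicate_id", "label_scheme")])
  expect_setequal(schemes$label_scheme, c("H_open", "M_open"))

  # degenerate planting: nuclear_frac_nascent = 1 -> nascent RPs 100%
  # nuclear
  ps1 <- gen_pulsed_silac(100, 20, rate_delta = 0,
                          nuclear_frac_nascent = 1, seed = 11)
  fr <- compartment_fractions(ps1$triplets)
  rp_ids <- ps1$truth$protein_id[ps1$truth$is_rp]
  nasc_nuc <- fr$percent[fr$protein_id %in% rp_ids & fr$label == "H" &
                           fr$compartment == "nucleus"]
  expect_equal(nasc_nuc, rep(100, length(nasc_nuc)))

  # membrane fraction of RPs planted ~ 0
  mem <- fr$percent[fr$protein_id %in% rp_ids & fr$compartment == "membrane"]
  expect_true(all(mem == 0))
})

test_that("reciprocal replicate harmonization is symmetric", {
  ps <- gen_pulsed_silac(100, 10, rate_delta = 0.4, ratio_sd = 1e-9,
                         seed = 12)
  rates <- translation_rate_ratios(ps$triplets)
  # both replicates carry the same planted ratio despite swapped labels
  expect_equal(rates$rep1, rates$rep2, tolerance = 1e-6)
  rp_ids <- ps$truth$protein_id[ps$truth$is_rp]
  expect_equal(mean(rates$rep1[rates$protein_id %in% rp_ids]), 0.4,
               tolerance = 1e-6)
})

test_that("iCLIP generator enforces the barcode contract and plants
           duplicates at the stated rate", {
  expect_error(gen_iclip_reads(tibble::tibble(start = 1L, end = 5L,
                                              strand = "+"),
                               0.1, c(GGCTA = "a", GGCTA = "b"), 10),
               "distinct")
  expect_error(gen_iclip_reads(tibble::tibble(start = 1L, end = 5L,
                                              strand = "+"),
                               0.1, c(GGC = "a"), 10), "5 nt")

  n <- 2000L
  ic <- gen_iclip_reads(tibble::tibble(start = 300L, end = 400L,
                                       strand = "+"),
                        background_rate = 0.1, barcodes = c(GGCTA = "s1"),
                        n_reads = n, genome_length = 2000L,
                        duplicate_rate = 0.5, seed = 13)
  dmx <- demultiplex(ic$reads[, c("read_id", "seq")], c(GGCTA = "s1"))
  ev <- assign_crosslinks(
    dplyr::inner_join(dmx$assigned[, c("read_id", "sample_id", "umi")],
                      ic$reads[, c("read_id", "chrom", "start", "end",
                                   "strand")],
                      by = "read_id"))
  track <- dedup_umi(ev)
  removed <- n - attr(track, "library_size")
  # binomial expectation n/2 within 3 SD (UMI collisions add a few)
  sd3 <- 3 * sqrt(n * 0.5 * 0.5)
  expect_gt(removed, n * 0.5 - sd3)
  expect_lt(removed, n * 0.5 + sd3 + 0.02 * n) # small collision allowance
})

test_that("two samples with distinct barcodes partition reads exactly", {
  ic <- gen_iclip_reads(tibble::tibble(start = 100L, end = 160L,
                                       strand = "+"),
                        background_rate = 0.2,
                        barcodes = c(GGCTA = "s1", TTAGC = "s2"),
                        n_reads = 300, genome_length = 1500L, seed = 14)
  dmx <- demultiplex(ic$reads[, c("read_id", "seq")],
                     c(GGCTA = "s1", TTAGC = "s2"))
  expect_equal(nrow(dmx$unassigned), 0L)
  got <- dmx$assigned[order(dmx$assigned$read_id), ]
  want <- ic$reads[order(ic$reads$read_id), ]
  expect_equal(got$sample_id, want$sample_id)
  expect_equal(got$umi, want$umi)
})

test_that("crosslink truth is recovered exactly from the read coordinates", {
  ic <- gen_iclip_reads(tibble::tibble(start = c(200L, 600L),
                                       end = c(260L, 650L),
                                       strand = c("+", "-")),
                        background_rate = 0, barcodes = c(GGCTA = "s1"),
                        n_reads = 200, genome_length = 1200L, seed = 15)
  ev <- assign_crosslinks(ic$reads)
  expect_equal(ev$position, ic$reads$crosslink)
  # cluster reads fall inside the planted intervals
  plus <- ev$position[ic$reads$strand == "+"]
  expect_true(all(plus >= 200 & plus < 260))
  minus <- ev$position[ic$reads$strand == "-"]
  expect_true(all(minus >= 600 & minus < 650))
})

test_that("spot field generator behaves at limits and validates", {
  expect_error(gen_spot_field(0, c(0, 0), 1), "n_spots")
  expect_error(gen_spot_field(10, c(0, 0), -1), "spread")

  # displaced cloud polarizes more than a centered one (Monte-Carlo)
  pis <- function(d, seeds) {
    vapply(seeds, function(s) {
      f <- gen_spot_field(60, c(d, 0), 1, seed = s)
      polarization_index(f$field)$pi
    }, numeric(1))
  }
  expect_lt(mean(pis(0, 1:40)), mean(pis(3, 1:40)))

  # single far spot with tiny spread: PI -> 1
  f <- gen_spot_field(1, c(5, 0), 1e-9, seed = 1)
  expect_equal(polarization_index(f$field)$pi, 1, tolerance = 1e-6)
})
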