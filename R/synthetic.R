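# Synthetic-data generators with planted, recorded ground truth. Every
# generator is deterministic given `seed` and returns the dataset together
# with a truth record sufficient to score recovery.

resolve_category <- function(category, ids, what = "category") {
  if (is.numeric(category) && length(category) == 1L) {
    if (category > length(ids)) {
      stop_subloc("%s size %d exceeds number of features %d", what,
                  category, length(ids))
    }
    sample(ids, as.integer(category))
  } else {
    category <- as.character(category)
    if (!all(category %in% ids)) {
      stop_subloc("%s members outside the generated feature ids", what)
    }
    if (length(category) > length(ids)) {
      stop_subloc("%s larger than the feature universe", what)
    }
    category
  }
}

#' Simulate paired protrusion/cell-body counts with a planted category shift
#'
#' Draws negative-binomial counts for two subcellular libraries of one
#' sample. Genes carry lognormal baseline expression; genes in the planted
#' category get an expected log2(protrusion/body) ratio of `delta`
#' (split symmetrically across the two compartments), all others 0. Library
#' sizes are matched to `lib_sizes` in expectation.
#'
#' @param n_genes Number of genes.
#' @param category Planted category: character ids or an integer size (a
#'   random subset is drawn).
#' @param delta Planted log2 protrusion/body shift of the category.
#' @param dispersion Negative-binomial overdispersion (> 0; variance
#'   `mu + dispersion * mu^2`).
#' @param lib_sizes Length-2 expected library totals (protrusion, body).
#' @param mean_count Mean baseline expression per gene before library
#'   scaling (default 200, typical of 3' tag counting).
#' @param seed Integer seed.
#' @return List: `counts` (a `subloc_counts` tibble, columns
#'   `s1_protrusion`, `s1_body`), `truth` (tibble `feature_id`,
#'   `in_category`, `delta`), `params`.
#' @export
gen_compartment_counts <- function(n_genes, category, delta,
                                   dispersion = 0.2,
                                   lib_sizes = c(1e6, 1e6),
                                   mean_count = 200, seed = 1L) {
  check_number(n_genes, "n_genes", lower = 2)
  check_number(delta, "delta")
  check_number(dispersion, "dispersion", lower = 0, strict_lower = TRUE)
  if (length(lib_sizes) != 2L || any(lib_sizes <= 0)) {
    stop_subloc("`lib_sizes` must be two positive totals")
  }
  with_seed(seed, {
    ids <- sprintf("gene_%05d", seq_len(n_genes))
    members <- resolve_category(category, ids)
    mu <- stats::rlnorm(n_genes, meanlog = log(mean_count), sdlog = 1)
    shift <- ifelse(ids %in% members, delta, 0)
    mu_p <- mu * 2^(shift / 2)
    mu_b <- mu * 2^(-shift / 2)
    mu_p <- mu_p / sum(mu_p) * lib_sizes[1]
    mu_b <- mu_b / sum(mu_b) * lib_sizes[2]
    counts <- tibble(
      feature_id = ids,
      s1_protrusion = rnbinom(n_genes, mu = mu_p, size = 1 / dispersion),
      s1_body = rnbinom(n_genes, mu = mu_b, size = 1 / dispersion))
    design <- tibble(column = c("s1_protrusion", "s1_body"),
                     sample_id = "s1",
                     compartment = c("protrusion", "body"))
    counts <- structure(counts, design = design,
                        class = c("subloc_counts", class(tibble())))
    truth <- tibble(feature_id = ids, in_category = ids %in% members,
                    delta = shift)
    list(counts = counts, truth = truth,
         params = list(n_genes = n_genes, delta = delta,
                       dispersion = dispersion, lib_sizes = lib_sizes,
                       mean_count = mean_count, seed = seed))
  })
}

#' Simulate a multi-sample log2 ratio panel with a planted enriched set
#'
#' Emulates per-feature log2 compartment ratios measured across independent
#' samples/cell lines: features in `enriched_set` are drawn from
#' `Normal(delta, noise_sd)` in every sample, all others from
#' `Normal(0, noise_sd)`.
#'
#' @param n_features,n_samples Panel dimensions (`n_samples >= 2`).
#' @param enriched_set Character ids or an integer size.
#' @param delta Planted mean log2 ratio of the enriched set.
#' @param noise_sd Per-sample noise SD (> 0).
#' @param seed Integer seed.
#' @return List: `ratios` (tibble `feature_id` + `line_1..line_k`),
#'   `truth`, `params`.
#' @export
gen_ratio_panel <- function(n_features, n_samples, enriched_set, delta,
                            noise_sd = 0.3, seed = 1L) {
  check_number(n_samples, "n_samples", lower = 2)
  check_number(noise_sd, "noise_sd", lower = 0, strict_lower = TRUE)
  check_number(delta, "delta")
  with_seed(seed, {
    ids <- sprintf("feat_%05d", seq_len(n_features))
    members <- resolve_category(enriched_set, ids, "enriched_set")
    mu <- ifelse(ids %in% members, delta, 0)
    m <- matrix(rnorm(n_features * n_samples, mean = mu, sd = noise_sd),
                nrow = n_features)
    colnames(m) <- sprintf("line_%d", seq_len(n_samples))
    ratios <- bind_cols(tibble(feature_id = ids), as_tibble(m))
    truth <- tibble(feature_id = ids, enriched = ids %in% members,
                    delta = mu)
    list(ratios = ratios, truth = truth,
         params = list(n_features = n_features, n_samples = n_samples,
                       delta = delta, noise_sd = noise_sd, seed = seed))
  })
}

#' Simulate pulsed-SILAC triplets with planted translation and
#' localization effects
#'
#' Emits (i) whole-cell H/M triplets for two reciprocally labeled
#' replicates in which the planted protein set (the "ribosomal proteins")
#' carries a log2 open/closed translation-rate shift of `rate_delta`, and
#' (ii) per-compartment iBAQ triplets for one fractionation replicate in
#' which the nascent labels (M, H) of the planted set place
#' `nuclear_frac_nascent` of their signal in the nucleus versus
#' `nuclear_frac_old` for the pre-existing (L) pool; the planted set's
#' membrane fraction is ~0, and background proteins keep one common
#' distribution for all labels.
#'
#' @param n_proteins Number of proteins.
#' @param rp_set Planted set: character ids or an integer size.
#' @param rate_delta Planted log2 open/closed translation shift.
#' @param compartments Non-empty subset of
#'   `c("nucleus", "cytosol", "membrane")`.
#' @param nuclear_frac_nascent,nuclear_frac_old Nuclear fraction of the
#'   planted set's nascent (M/H) and old (L) signal (defaults 0.8 / 0.4).
#' @param ratio_sd Replicate noise SD on log2 ratios (default 0.25).
#' @param frac_noise Lognormal sdlog of compartment intensity noise
#'   (default 0.1).
#' @param seed Integer seed.
#' @return List: `triplets` (SILAC triplet tibble with whole-cell and
#'   compartment rows), `truth`, `params`.
#' @export
gen_pulsed_silac <- function(n_proteins, rp_set, rate_delta,
                             compartments = c("nucleus", "cytosol",
                                              "membrane"),
                             nuclear_frac_nascent = 0.8,
                             nuclear_frac_old = 0.4,
                             ratio_sd = 0.25, frac_noise = 0.1,
                             seed = 1L) {
  if (length(compartments) == 0L) stop_subloc("`compartments` is empty")
  bad <- setdiff(compartments, c("nucleus", "cytosol", "membrane"))
  if (length(bad) > 0L) stop_subloc("unknown compartment(s): %s",
                                    paste(bad, collapse = ", "))
  check_number(nuclear_frac_nascent, "nuclear_frac_nascent", 0, 1)
  check_number(nuclear_frac_old, "nuclear_frac_old", 0, 1)
  check_number(rate_delta, "rate_delta")
  with_seed(seed, {
    ids <- sprintf("prot_%05d", seq_len(n_proteins))
    members <- resolve_category(rp_set, ids, "rp_set")
    is_rp <- ids %in% members
    base <- stats::rlnorm(n_proteins, meanlog = log(1e6), sdlog = 1)
    shift <- ifelse(is_rp, rate_delta, 0)
    whole <- purrr::map(1:2, function(rep_i) {
      lr <- rnorm(n_proteins, mean = shift, sd = ratio_sd)
      open <- base * 2^(lr / 2)
      closed <- base * 2^(-lr / 2)
      scheme <- if (rep_i == 1L) "H_open" else "M_open"
      tibble(protein_id = ids,
             intensity_L = base,
             intensity_M = if (scheme == "H_open") closed else open,
             intensity_H = if (scheme == "H_open") open else closed,
             compartment = "whole",
             replicate_id = sprintf("rep%d", rep_i),
             label_scheme = scheme)
    }) |> list_rbind()
    frac_for <- function(label) {
      nuc <- ifelse(is_rp,
                    if (label == "L") nuclear_frac_old
                    else nuclear_frac_nascent,
                    0.3)
      mem <- ifelse(is_rp, 0, 0.05)
      cyt <- pmax(0, 1 - nuc - mem)
      cbind(nucleus = nuc, cytosol = cyt, membrane = mem)
    }
    comp_rows <- purrr::map(c("L", "M", "H"), function(label) {
      fr <- frac_for(label)[, compartments, drop = FALSE]
      purrr::map(compartments, function(cc) {
        noisy <- base * fr[, cc] *
          stats::rlnorm(n_proteins, 0, frac_noise)
        tibble(protein_id = ids, label = label, compartment = cc,
               intensity = noisy)
      }) |> list_rbind()
    }) |>
      list_rbind() |>
      tidyr::pivot_wider(names_from = "label", values_from = "intensity",
                         names_prefix = "intensity_") |>
      mutate(replicate_id = "fr1", label_scheme = "H_open") |>
      select("protein_id", "intensity_L", "intensity_M", "intensity_H",
             "compartment", "replicate_id", "label_scheme")
    truth <- tibble(protein_id = ids, is_rp = is_rp, rate_delta = shift,
                    nuclear_frac_nascent = ifelse(is_rp,
                                                  nuclear_frac_nascent,
                                                  0.3),
                    nuclear_frac_old = ifelse(is_rp, nuclear_frac_old,
                                              0.3))
    list(triplets = bind_rows(whole, comp_rows), truth = truth,
         params = list(n_proteins = n_proteins, rate_delta = rate_delta,
                       compartments = compartments,
                       nuclear_frac_nascent = nuclear_frac_nascent,
                       nuclear_frac_old = nuclear_frac_old,
                       ratio_sd = ratio_sd, frac_noise = frac_noise,
                       seed = seed))
  })
}

#' Simulate an RNA-FISH spot field with known displacement
#'
#' Spots are drawn isotropically Normal around
#' `nucleus_centroid + displacement` with SD `spread`; the expected
#' polarization index grows with `|displacement| / spread`. Optional
#' rectangular masks provide compartment areas for density ratios.
#'
#' @param n_spots Number of spots (> 0).
#' @param displacement Length-2 displacement vector of the spot cloud.
#' @param spread Isotropic SD (> 0).
#' @param mask_geometry Optional tibble `region`, `xmin`, `xmax`, `ymin`,
#'   `ymax` of rectangular masks.
#' @param nucleus_centroid Length-2 nucleus centroid (default origin).
#' @param seed Integer seed.
#' @return List: `field` (list with `spots`, `nucleus_centroid`, `masks`),
#'   `truth`, `params`.
#' @export
gen_spot_field <- function(n_spots, displacement = c(0, 0), spread = 1,
                           mask_geometry = NULL,
                           nucleus_centroid = c(0, 0), seed = 1L) {
  check_number(n_spots, "n_spots", lower = 1)
  check_number(spread, "spread", lower = 0, strict_lower = TRUE)
  if (length(displacement) != 2L || any(!is.finite(displacement))) {
    stop_subloc("`displacement` must be a finite length-2 vector")
  }
  with_seed(seed, {
    spots <- tibble(
      x = rnorm(n_spots, nucleus_centroid[1] + displacement[1], spread),
      y = rnorm(n_spots, nucleus_centroid[2] + displacement[2], spread),
      intensity = stats::rlnorm(n_spots, 0, 0.25),
      frame = 1L)
    field <- spot_field(spots, nucleus_centroid, masks = mask_geometry)
    truth <- tibble(dx = displacement[1], dy = displacement[2],
                    spread = spread, n_spots = n_spots,
                    expected_ordering = sqrt(sum(displacement^2)) / spread)
    list(field = field, truth = truth,
         params = list(n_spots = n_spots, displacement = displacement,
                       spread = spread, seed = seed))
  })
}
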