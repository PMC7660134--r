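# Localization statistics on spot/pixel tables and compartment masks.
# Inputs are detected spots (x, y, intensity, frame), not raw images;
# segmentation and spot detection are upstream concerns.

#' Construct a spot field
#'
#' Bundles a spot table with the nucleus centroid and optional rectangular
#' compartment masks (tibble `region`, `xmin`, `xmax`, `ymin`, `ymax`).
#'
#' @param spots Tibble with `x`, `y`, positive `intensity`, optional
#'   `frame`.
#' @param nucleus_centroid Length-2 numeric.
#' @param masks Optional mask tibble as above.
#' @return List of class `subloc_spot_field`.
#' @export
spot_field <- function(spots, nucleus_centroid = c(0, 0), masks = NULL) {
  x <- as_tibble(spots)
  if (!all(c("x", "y") %in% names(x))) {
    stop_subloc("spots need columns x, y")
  }
  if (!"intensity" %in% names(x)) x$intensity <- 1
  if (any(x$intensity <= 0)) stop_subloc("spot intensities must be > 0")
  if (!"frame" %in% names(x)) x$frame <- 1L
  if (length(nucleus_centroid) != 2L || any(!is.finite(nucleus_centroid))) {
    stop_subloc("`nucleus_centroid` must be a finite length-2 vector")
  }
  if (!is.null(masks)) {
    masks <- as_tibble(masks)
    need <- c("region", "xmin", "xmax", "ymin", "ymax")
    if (!all(need %in% names(masks))) {
      stop_subloc("masks need columns: %s", paste(need, collapse = ", "))
    }
  }
  structure(list(spots = x, nucleus_centroid = as.numeric(nucleus_centroid),
                 masks = masks),
            class = "subloc_spot_field")
}

as_spot_field <- function(field) {
  if (inherits(field, "subloc_spot_field")) return(field)
  if (is.list(field) && !is.null(field$spots)) {
    return(spot_field(field$spots,
                      field$nucleus_centroid %||% c(0, 0),
                      field$masks))
  }
  spot_field(field)
}

#' Polarization index of a spot field
#'
#' PI = ||centroid of the transcript signal - nucleus centroid|| / Rg,
#' where the signal centroid is intensity-weighted by default and Rg is the
#' radius of gyration: the root-mean-square (intensity-weighted) distance
#' of all spots from the nucleus centroid. PI lies in \[0, 1\]: 0 for a
#' balanced (unpolarized) distribution, approaching 1 when the whole signal
#' is displaced to one side. Invariant under rigid translation/rotation and
#' under uniform unit change.
#'
#' @param field A `subloc_spot_field` (or list/tibble coercible to one).
#' @param weighted Intensity-weight the centroid and Rg (default TRUE).
#' @return One-row tibble: `pi`, `n_spots`, `rg`, `defined`. When all
#'   spots coincide with the nucleus centroid, Rg = 0 and the index is
#'   undefined (`defined = FALSE`, `pi = NA`).
#' @export
polarization_index <- function(field, weighted = TRUE) {
  f <- as_spot_field(field)
  s <- f$spots
  if (nrow(s) == 0L) stop_subloc("need at least one spot")
  w <- if (weighted) s$intensity else rep(1, nrow(s))
  w <- w / sum(w)
  cx <- sum(w * s$x)
  cy <- sum(w * s$y)
  dx <- s$x - f$nucleus_centroid[1]
  dy <- s$y - f$nucleus_centroid[2]
  rg <- sqrt(sum(w * (dx^2 + dy^2)))
  if (rg == 0) {
    return(tibble(pi = NA_real_, n_spots = nrow(s), rg = 0,
                  defined = FALSE))
  }
  num <- sqrt((cx - f$nucleus_centroid[1])^2 +
                (cy - f$nucleus_centroid[2])^2)
  tibble(pi = num / rg, n_spots = nrow(s), rg = rg, defined = TRUE)
}

mask_area <- function(masks, region) {
  m <- masks[masks$region == region, , drop = FALSE]
  if (nrow(m) == 0L) stop_subloc("mask '%s' missing", region)
  sum((m$xmax - m$xmin) * (m$ymax - m$ymin))
}

in_mask <- function(spots, masks, region) {
  m <- masks[masks$region == region, , drop = FALSE]
  hit <- rep(FALSE, nrow(spots))
  for (i in seq_len(nrow(m))) {
    hit <- hit | (spots$x >= m$xmin[i] & spots$x <= m$xmax[i] &
                    spots$y >= m$ymin[i] & spots$y <= m$ymax[i])
  }
  hit
}

#' Log2 protrusion/cell-body signal density ratio
#'
#' Sums the spot (or thresholded-pixel) intensity falling inside the
#' protrusion and body masks, normalizes each by its mask area, and
#' returns `log2((signal_P / area_P) / (signal_B / area_B))`. Zero body
#' signal is capped at `cap` with a flag instead of returning infinity.
#'
#' @param field A `subloc_spot_field` with `protrusion` and `body` masks.
#' @param cap Cap for the absolute log2 ratio on zero signal (default 10).
#' @return One-row tibble: `log2_ratio`, `signal_protrusion`,
#'   `signal_body`, `area_protrusion`, `area_body`, `capped`.
#' @export
compartment_signal_ratio <- function(field, cap = 10) {
  f <- as_spot_field(field)
  if (is.null(f$masks)) stop_subloc("field carries no masks")
  s <- f$spots
  a_p <- mask_area(f$masks, "protrusion")
  a_b <- mask_area(f$masks, "body")
  if (a_p <= 0 || a_b <= 0) stop_subloc("mask areas must be positive")
  sig_p <- sum(s$intensity[in_mask(s, f$masks, "protrusion")])
  sig_b <- sum(s$intensity[in_mask(s, f$masks, "body")])
  capped <- FALSE
  if (sig_p == 0 && sig_b == 0) {
    stop_subloc("no signal in either mask")
  } else if (sig_b == 0) {
    lr <- cap; capped <- TRUE
  } else if (sig_p == 0) {
    lr <- -cap; capped <- TRUE
  } else {
    lr <- log2((sig_p / a_p) / (sig_b / a_b))
  }
  tibble(log2_ratio = lr, signal_protrusion = sig_p, signal_body = sig_b,
         area_protrusion = a_p, area_body = a_b, capped = capped)
}

#' Percent co-localization of spot set A with spot set B
#'
#' Greedy nearest-neighbour matching: candidate pairs within `radius` are
#' taken in order of increasing distance (ties broken by A index, then B
#' index), each A and each B spot used at most once. Returns the percentage
#' of A spots matched. Deterministic and invariant to input row order.
#'
#' @param spots_a,spots_b Tibbles with `x`, `y`.
#' @param radius Maximum matching distance (> 0), in the spots' units.
#' @return One-row tibble: `percent`, `n_matched`, `n_a`, `n_b`.
#' @export
spot_colocalization <- function(spots_a, spots_b, radius) {
  check_number(radius, "radius", lower = 0, strict_lower = TRUE)
  a <- as_tibble(spots_a)
  b <- as_tibble(spots_b)
  if (nrow(a) == 0L) stop_subloc("spot set A is empty")
  # canonical order so matching ignores input row order
  ord_a <- order(a$x, a$y)
  ord_b <- order(b$x, b$y)
  a <- a[ord_a, , drop = FALSE]
  b <- b[ord_b, , drop = FALSE]
  if (nrow(b) == 0L) {
    return(tibble(percent = 0, n_matched = 0L, n_a = nrow(a), n_b = 0L))
  }
  d <- outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j) {
    sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2)
  })
  cand <- which(d <= radius, arr.ind = TRUE)
  if (nrow(cand) > 0L) {
    cand <- cand[order(d[cand], cand[, 1], cand[, 2]), , drop = FALSE]
  }
  used_a <- logical(nrow(a))
  used_b <- logical(nrow(b))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE
      used_b[j] <- TRUE
    }
  }
  n_matched <- sum(used_a)
  tibble(percent = 100 * n_matched / nrow(a), n_matched = n_matched,
         n_a = nrow(a), n_b = nrow(b))
}

#' Particle density in a compartment over frames
#'
#' Mean over frames of (number of spots inside the mask) / mask area, for
#' per-frame particle quantification in protrusions.
#'
#' @param spots Tibble with `x`, `y`, `frame`.
#' @param area Mask area (> 0) in squared spot units; alternatively pass
#'   `mask` (a rectangle tibble as in [spot_field()]) to derive the area
#'   and restrict spots to it.
#' @param mask Optional mask tibble with a `protrusion` region.
#' @param n_frames Number of frames; defaults to the distinct `frame`
#'   values present (frames with zero spots must be counted — pass
#'   `n_frames` when some frames are empty).
#' @return One-row tibble: `density`, `n_frames`, `mean_count`, `area`.
#' @export
particle_density <- function(spots, area = NULL, mask = NULL,
                             n_frames = NULL) {
  s <- as_tibble(spots)
  if (!"frame" %in% names(s)) s$frame <- 1L
  if (!is.null(mask)) {
    mask <- as_tibble(mask)
    area <- mask_area(mask, "protrusion")
    s <- s[in_mask(s, mask, "protrusion"), , drop = FALSE]
  }
  if (is.null(area)) stop_subloc("provide `area` or `mask`")
  check_number(area, "area", lower = 0, strict_lower = TRUE)
  nf <- n_frames %||% length(unique(s$frame))
  if (nf == 0L) stop_subloc("zero frames")
  mean_count <- nrow(s) / nf
  tibble(density = mean_count / area, n_frames = as.integer(nf),
         mean_count = mean_count, area = area)
}

#' Normalized stain intensity
#'
#' Ratio of a signal's mean intensity to a reference stain's mean
#' intensity (e.g. puromycin analog signal normalized to the DAPI channel
#' of the same image).
#'
#' @param signal_mean,reference_mean Mean intensities; `reference_mean`
#'   must be > 0.
#' @return The ratio.
#' @export
normalized_stain_intensity <- function(signal_mean, reference_mean) {
  check_number(signal_mean, "signal_mean", lower = 0)
  check_number(reference_mean, "reference_mean", lower = 0,
               strict_lower = TRUE)
  signal_mean / reference_mean
}
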