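#' A patch expressed as cone catches
#'
#' The per-pixel chromatic catches and double-cone (luminance) catches of
#' one body region of one specimen, the common currency of all plumage
#' metrics. An optional 2-D luminance grid (the patch embedded in its
#' bounding box) carries the spatial arrangement needed for pattern
#' analysis.
#'
#' @param catches Matrix (pixels x chromatic receptors) of positive
#'   catches.
#' @param luminance Positive double-cone catch per pixel.
#' @param region Region label.
#' @param grid Optional numeric matrix: luminance image over the patch
#'   bounding box (fill values outside the mask are ignored by statistics).
#' @param grid_mask Optional logical matrix marking in-patch cells of
#'   `grid`.
#' @return Object of class `"cone_catch_patch"`.
#' @export
cone_catch_patch <- function(catches, luminance, region,
                             grid = NULL, grid_mask = NULL) {
  catches <- as.matrix(catches)
  if (nrow(catches) != length(luminance))
    stop("chromatic and luminance pixel counts differ")
  if (nrow(catches) < 1) stop("empty patch")
  if (nrow(catches) > 2000)
    stop("patch exceeds the 2000-pixel analysis budget; downsample first")
  if (any(catches <= 0) || any(luminance <= 0))
    stop("cone catches must be positive")
  structure(list(region = region, catches = catches,
                 luminance = as.numeric(luminance),
                 n_pixels = nrow(catches),
                 grid = grid, grid_mask = grid_mask),
            class = "cone_catch_patch")
}

#' Most abundant perceived colour of a patch
#'
#' The single pixel colour with more other pixels within `radius_jnd` of
#' chromatic distance than any other — the patch's modal colour as seen by
#' the receiver, robust to glare and shadow pixels. The count is exhaustive
#' over all pixel pairs (quadratic, hence the 2000-pixel budget); the
#' comparison is strict (`< radius_jnd`) and ties are broken by the lowest
#' pixel index.
#'
#' @param patch A [cone_catch_patch()].
#' @param e Weber fractions of the chromatic receptors.
#' @param radius_jnd Neighbourhood radius in JNDs, default 2.
#' @return Named numeric catch vector of the winning pixel, with
#'   attributes `pixel` (its index) and `count` (neighbours within radius).
#' @export
abundant_colour <- function(patch, e, radius_jnd = 2.0) {
  stopifnot(inherits(patch, "cone_catch_patch"))
  if (radius_jnd <= 0)
    stop("radius_jnd must be positive: a zero radius gives every pixel ",
         "zero neighbours and no meaningful modal colour")
  Q <- patch$catches
  n <- nrow(Q)
  # blockwise to bound memory at the full 2000-pixel budget
  block <- 512L
  counts <- integer(n)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    J <- chromatic_jnd_matrix(Q[rows, , drop = FALSE], Q, e)
    counts[rows] <- as.integer(rowSums(J < radius_jnd)) - 1L  # self excluded
  }
  best <- which.max(counts)
  out <- Q[best, ]
  attr(out, "pixel") <- best
  attr(out, "count") <- counts[best]
  out
}

#' Luminance histogram of a patch
#'
#' Proportions of patch pixels in 32 equal luminance levels spanning
#' 0-100% of the normalized double-cone catch. Catches are clipped to
#' \[0, 1\] (values above 1 arise from specular highlights on calibrated
#' photographs; the clipped count is attached as attribute
#' `"n_clipped"`). Bins are half-open \[lo, hi) with the last bin closed.
#'
#' @param patch A [cone_catch_patch()].
#' @param n_bins Number of levels, default 32.
#' @return Object of class `"luminance_histogram"`: proportions plus bin
#'   edges.
#' @export
luminance_histogram <- function(patch, n_bins = 32) {
  stopifnot(inherits(patch, "cone_catch_patch"))
  v <- patch$luminance
  n_clipped <- sum(v > 1)
  v <- pmin(pmax(v, 0), 1)
  idx <- pmin(floor(v * n_bins) + 1L, n_bins)
  p <- tabulate(idx, nbins = n_bins) / length(v)
  structure(list(proportions = p,
                 breaks = seq(0, 1, length.out = n_bins + 1)),
            class = "luminance_histogram", n_clipped = n_clipped)
}

#' Luminance-distribution difference (L_diff)
#'
#' Sum of absolute differences between two luminance histograms'
#' proportions: twice the total-variation distance, in \[0, 2\]. Captures
#' differences in perceived brightness distribution, including non-normal
#' distributions created by plumage patterns.
#'
#' @param a,b [luminance_histogram()] objects on the same bins.
#' @return Dimensionless value in \[0, 2\].
#' @export
l_diff <- function(a, b) {
  stopifnot(inherits(a, "luminance_histogram"),
            inherits(b, "luminance_histogram"))
  if (length(a$proportions) != length(b$proportions))
    stop("histograms have different bin counts")
  sum(abs(a$proportions - b$proportions))
}

# Signed frequency grid of an n-point DFT, cycles per pixel.
fft_freq <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n %/% 2, k, k - n) / n
}

#' Granularity (pattern-energy) spectrum of a luminance image
#'
#' Classic granularity analysis: the image is Fourier transformed, passed
#' through a series of annular bandpass filters, and the "energy" at each
#' spatial scale is the standard deviation of the band-filtered pixel
#' values. Scales form a geometric series from 2 px to the shorter image
#' dimension; the band at scale s passes spatial wavelengths in
#' \[s/sqrt(2), s*sqrt(2)\] (half-octave edges). The DC component belongs
#' to no band, so energies ignore the image mean.
#'
#' Masked patches should be embedded in their bounding box with mean fill
#' outside the mask (see [patch_luminance_grid()]); statistics are then
#' computed over in-mask pixels only.
#'
#' @param img Numeric matrix of luminance values, at least 8 x 8.
#' @param mask Optional logical matrix: cells over which the energy
#'   statistic is computed (default: all).
#' @param n_scales Number of scales, default 33.
#' @return Object of class `"pattern_spectrum"`: `scales` (px) and
#'   `energy` (luminance units).
#' @export
pattern_energy <- function(img, mask = NULL, n_scales = 33) {
  img <- as.matrix(img)
  nr <- nrow(img); nc <- ncol(img)
  if (nr < 8 || nc < 8)
    stop(sprintf("image %dx%d too small: need at least 8x8 so scales 2..%d px are resolvable",
                 nr, nc, min(nr, nc)))
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  s_max <- min(nr, nc)
  scales <- 2 * (s_max / 2)^(seq(0, 1, length.out = n_scales))
  F <- stats::fft(img)
  fr <- sqrt(outer(fft_freq(nr)^2, fft_freq(nc)^2, "+"))
  energy <- vapply(scales, function(s) {
    lo <- 1 / (s * sqrt(2)); hi <- sqrt(2) / s
    band <- fr >= lo & fr <= hi
    if (!any(band)) return(0)
    filtered <- Re(stats::fft(F * band, inverse = TRUE)) / (nr * nc)
    stats::sd(filtered[mask])
  }, numeric(1))
  structure(list(scales = scales, energy = energy),
            class = "pattern_spectrum")
}

#' Pattern-energy difference (S_diff)
#'
#' Sum over spatial scales of absolute differences in pattern energy
#' between two granularity spectra: sensitive to any mismatch in marking
#' size, spacing or contrast, without reducing the spectrum to a single
#' peak descriptor.
#'
#' @param a,b [pattern_energy()] spectra on identical scale grids.
#' @return Non-negative value in luminance-energy units.
#' @export
s_diff <- function(a, b) {
  stopifnot(inherits(a, "pattern_spectrum"), inherits(b, "pattern_spectrum"))
  if (length(a$scales) != length(b$scales) ||
      max(abs(a$scales - b$scales)) > 1e-9 * max(a$scales))
    stop("pattern spectra are on different scale grids")
  sum(abs(a$energy - b$energy))
}

#' Mean-luminance JND between two patches
#'
#' Achromatic discriminability of two regions, computed from the mean
#' double-cone catch of each.
#'
#' @param a,b [cone_catch_patch()] objects.
#' @param e_D Achromatic Weber fraction, default 0.05.
#' @return Non-negative JND.
#' @export
region_luminance_jnd <- function(a, b, e_D = 0.05) {
  stopifnot(inherits(a, "cone_catch_patch"), inherits(b, "cone_catch_patch"))
  luminance_jnd(mean(a$luminance), mean(b$luminance), e_D)
}

#' Embed masked patch luminance in its bounding box
#'
#' Prepares a masked pixel set for Fourier pattern analysis: pixels are
#' placed at their coordinates within the mask bounding box and cells
#' outside the mask are filled with the in-mask mean (minimizing edge
#' ringing without inventing texture).
#'
#' @param coords Integer matrix (pixels x 2) of row/col coordinates.
#' @param lum Luminance value per pixel.
#' @return List with `grid` (numeric matrix) and `mask` (logical matrix).
#' @export
patch_luminance_grid <- function(coords, lum) {
  coords <- as.matrix(coords)
  r <- coords[, 1] - min(coords[, 1]) + 1L
  cc <- coords[, 2] - min(coords[, 2]) + 1L
  g <- matrix(mean(lum), max(r), max(cc))
  m <- matrix(FALSE, max(r), max(cc))
  g[cbind(r, cc)] <- lum
  m[cbind(r, cc)] <- TRUE
  list(grid = g, mask = m)
}

#' Build a specimen-pair comparison table
#'
#' For every focal specimen x other specimen x body region, computes the
#' four difference statistics: chromatic JND between abundant colours,
#' mean-luminance JND, L_diff and S_diff (with its log transform for
#' modelling). Region-level means per taxon group are attached as the
#' `"summary"` attribute.
#'
#' @param focal List of specimens; each specimen is a list with `id` and
#'   `patches`, a named list of [cone_catch_patch()] by region.
#' @param others Named list of specimen lists, one entry per taxon group
#'   (e.g. `conspecific_male`, `Euplectes`, `Vidua`).
#' @param e Chromatic Weber fractions.
#' @param e_D Achromatic Weber fraction.
#' @param regions Regions to compare, default the nine standard regions.
#' @param radius_jnd Abundant-colour radius, default 2.
#' @param log_offset Offset inside the log for `log_s_diff`, default 1e-3.
#' @return Data frame with one row per focal x other x region
#'   (`focal_id, other_id, taxon_group, region, colour_jnd, luminance_jnd,
#'   l_diff, s_diff, log_s_diff`), with attribute `"summary"` of group x
#'   region means.
#' @export
build_comparison_table <- function(focal, others, e, e_D = 0.05,
                                   regions = BODY_REGIONS,
                                   radius_jnd = 2.0, log_offset = 1e-3) {
  precompute <- function(spec) {
    present <- intersect(regions, names(spec$patches))
    missing <- setdiff(regions, names(spec$patches))
    if (length(missing))
      warning(sprintf("specimen '%s' lacks regions: %s (excluded)",
                      spec$id, paste(missing, collapse = ", ")))
    feats <- lapply(spec$patches[present], function(p) {
      ps <- if (!is.null(p$grid)) pattern_energy(p$grid, p$grid_mask) else NULL
      list(abundant = abundant_colour(p, e, radius_jnd),
           hist = luminance_histogram(p),
           mean_lum = mean(p$luminance),
           pattern = ps)
    })
    list(id = spec$id, feats = feats)
  }
  focal_f <- lapply(focal, precompute)
  others_f <- lapply(others, function(grp) lapply(grp, precompute))

  rows <- list()
  for (f in focal_f) for (grp_name in names(others_f))
    for (o in others_f[[grp_name]]) {
      common <- intersect(names(f$feats), names(o$feats))
      for (rg in common) {
        fa <- f$feats[[rg]]; ob <- o$feats[[rg]]
        sd_val <- if (!is.null(fa$pattern) && !is.null(ob$pattern))
          s_diff(fa$pattern, ob$pattern) else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          focal_id = f$id, other_id = o$id, taxon_group = grp_name,
          region = rg,
          colour_jnd = chromatic_jnd(fa$abundant, ob$abundant, e),
          luminance_jnd = luminance_jnd(fa$mean_lum, ob$mean_lum, e_D),
          l_diff = l_diff(fa$hist, ob$hist),
          s_diff = sd_val,
          stringsAsFactors = FALSE)
      }
    }
  out <- do.call(rbind, rows)
  out$log_s_diff <- log(out$s_diff + log_offset)
  summ <- stats::aggregate(
    out[, c("colour_jnd", "luminance_jnd", "l_diff", "s_diff")],
    by = list(taxon_group = out$taxon_group, region = out$region), mean)
  attr(out, "summary") <- summ
  out
}
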