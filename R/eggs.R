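#' Construct an egg record
#'
#' One egg's measurements: replicate background reflectance spectra, the
#' photographed outline (mm coordinates), and optionally a luminance grid
#' of the shell surface for pattern analysis.
#'
#' @param clutch_id,egg_id Identifiers.
#' @param role `"host"` or `"experimental"`.
#' @param spectra List of replicate [spectrum()] objects (default policy:
#'   5 probe placements per egg, avoiding pattern markings).
#' @param outline Two-column matrix/data frame of ordered boundary points
#'   (mm); closed implicitly (last point joins the first).
#' @param pattern_patch Optional numeric matrix of shell luminance.
#' @param n_replicates Required replicate count, default 5.
#' @return Object of class `"egg_record"`.
#' @export
egg_record <- function(clutch_id, egg_id, role = c("host", "experimental"),
                       spectra, outline = NULL, pattern_patch = NULL,
                       n_replicates = 5) {
  role <- match.arg(role)
  if (length(spectra) != n_replicates)
    stop(sprintf("egg '%s': expected %d replicate spectra, got %d",
                 egg_id, n_replicates, length(spectra)))
  if (!is.null(outline)) {
    outline <- as.matrix(outline[, 1:2])
    if (nrow(outline) < 20) stop("outline needs at least 20 points")
  }
  structure(list(clutch_id = clutch_id, egg_id = egg_id, role = role,
                 spectra = spectra, outline = outline,
                 pattern_patch = pattern_patch),
            class = "egg_record")
}

# Mean spectrum of one egg's replicates (cv attribute retained).
egg_mean_spectrum <- function(egg, grid = NULL) mean_spectrum(egg$spectra, grid)

#' Colour and luminance JNDs between a host clutch and a foreign egg
#'
#' Cone catches are computed from each egg's mean background spectrum
#' under the configured illuminant; the host reference is the mean catch
#' over the clutch's host eggs. Chromatic distance uses the full
#' (tetrachromatic by default) receptor set; luminance uses the double
#' cone.
#'
#' @param clutch List of host [egg_record()]s (at least one).
#' @param foreign The experimental [egg_record()].
#' @param receptors A [receptor_set()] with a double cone; default
#'   [bluetit_uvs()]. Use [peafowl_vs()] for the violet-sensitive variant.
#' @param illuminant Optional illuminant [spectrum()]; default equal
#'   energy.
#' @return Named vector `c(colour_jnd, luminance_jnd)`.
#' @export
egg_colour_luminance_jnd <- function(clutch, foreign,
                                     receptors = bluetit_uvs(),
                                     illuminant = NULL) {
  if (length(clutch) < 1) stop("clutch must contain at least one host egg")
  lam_min <- min(vapply(c(clutch, list(foreign)), function(eg)
    max(vapply(eg$spectra, function(s) min(s$wavelength_nm), numeric(1))),
    numeric(1)))
  peaks <- vapply(receptors$sensitivities, function(s)
    s$wavelength_nm[which.max(s$value)], numeric(1))
  if (any(peaks < lam_min))
    stop(sprintf(
      "missing UV band: reflectance spectra start at %g nm but the '%s' receptor peaks at %g nm",
      lam_min, names(peaks)[which.min(peaks)], min(peaks)))
  catch <- function(eg) cone_catch_from_spectrum(egg_mean_spectrum(eg),
                                                 illuminant, receptors)
  host_q <- lapply(clutch, catch)
  ref <- Reduce(`+`, lapply(host_q, as.numeric)) / length(host_q)
  ref_lum <- mean(vapply(host_q, function(q) attr(q, "luminance"), numeric(1)))
  fq <- catch(foreign)
  e <- weber_fractions(receptors)
  c(colour_jnd = chromatic_jnd(as.numeric(fq), ref, e),
    luminance_jnd = luminance_jnd(attr(fq, "luminance"), ref_lum,
                                  receptors$double_cone_weber))
}

#' Eggshell pattern difference
#'
#' Pattern difference between two shell luminance grids, using the same
#' granularity machinery as plumage pattern: [pattern_energy()] on each
#' grid, then [s_diff()].
#'
#' @param host_patch,foreign_patch Numeric luminance matrices (>= 8 x 8).
#' @param n_scales Number of bandpass scales, default 33.
#' @return Non-negative S_diff value.
#' @export
egg_pattern_diff <- function(host_patch, foreign_patch, n_scales = 33) {
  a <- pattern_energy(host_patch, n_scales = n_scales)
  b <- pattern_energy(foreign_patch, n_scales = n_scales)
  s_diff(a, b)  # errors if the shell grids imply different scale series
}

# TRUE if any two non-adjacent outline segments cross.
outline_self_intersects <- function(pts) {
  n <- nrow(pts)
  seg <- cbind(pts, pts[c(2:n, 1), ])
  cross2 <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    j <- seq(i + 2, n)
    j <- j[!(i == 1 & j == n)]  # skip segments adjacent to i
    if (!length(j)) next
    d1 <- cross2(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
    d2 <- cross2(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
    d3 <- cross2(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
    d4 <- cross2(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Egg volume and shape from an outline
#'
#' Aligns the outline's long axis by principal components, extracts the
#' width profile along the axis, and computes volume as a solid of
#' revolution `V = pi * integral of (w(x)/2)^2 dx` by trapezoid
#' quadrature. Shape is summarized by elongation (length / max width) and
#' asymmetry (offset of the widest section from mid-length, as a fraction
#' of length).
#'
#' @param outline Two-column matrix of ordered boundary points (mm).
#' @param n_profile Number of axial stations for the width profile.
#' @return Named vector: `volume_mm3, length_mm, max_width_mm, elongation,
#'   asymmetry`.
#' @export
egg_volume_shape <- function(outline, n_profile = 400) {
  pts <- as.matrix(outline[, 1:2])
  if (nrow(pts) < 20) stop("outline needs at least 20 points")
  if (all(pts[1, ] == pts[nrow(pts), ])) pts <- pts[-nrow(pts), ]
  if (outline_self_intersects(pts)) stop("outline is self-intersecting")
  ctr <- colMeans(pts)
  pc <- stats::prcomp(pts, center = TRUE, scale. = FALSE)
  xy <- sweep(pts, 2, ctr) %*% pc$rotation  # column 1 = long axis
  x <- xy[, 1]; y <- xy[, 2]
  i_min <- which.min(x); i_max <- which.max(x)
  n <- length(x)
  # split the ordered boundary into the two chains joining the axis ends
  idx <- seq_len(n)
  walk <- function(from, to) {
    if (from <= to) from:to else c(from:n, 1:to)
  }
  chain1 <- walk(i_min, i_max)
  chain2 <- walk(i_max, i_min)
  xs <- seq(min(x), max(x), length.out = n_profile)
  prof <- function(ch) {
    ord <- order(x[ch])
    stats::approx(x[ch][ord], y[ch][ord], xout = xs, rule = 2, ties = mean)$y
  }
  y1 <- prof(chain1); y2 <- prof(chain2)
  w <- abs(y1 - y2)
  r2 <- (w / 2)^2
  dx <- xs[2] - xs[1]
  volume <- pi * sum((r2[-1] + r2[-n_profile]) / 2) * dx
  len <- max(x) - min(x)
  wmax <- max(w)
  x_at <- xs[which.max(w)] - min(x)
  c(volume_mm3 = volume, length_mm = len, max_width_mm = wmax,
    elongation = len / wmax, asymmetry = abs(x_at - len / 2) / len)
}

#' Shape difference between two eggs
#'
#' Euclidean distance between (elongation, asymmetry) descriptor pairs,
#' each standardized by supplied scale factors (typically the population
#' standard deviations from the experiment at hand).
#'
#' @param a,b Results of [egg_volume_shape()].
#' @param scale Positive length-2 vector of standardizing scales for
#'   elongation and asymmetry, default `c(1, 1)`.
#' @return Non-negative dimensionless distance.
#' @export
egg_shape_diff <- function(a, b, scale = c(1, 1)) {
  d <- (c(a["elongation"], a["asymmetry"]) -
        c(b["elongation"], b["asymmetry"])) / scale
  sqrt(sum(d^2))
}

#' Classify an egg-rejection trial from nest checks
#'
#' Applies the field decision rules to post-manipulation nest checks: a
#' single missing egg at any check means the egg was rejected (predators
#' typically take an entire clutch, so partial predation is not assumed);
#' a clutch that stays intact and under active incubation to day 3 or
#' later is accepted; a completely empty nest is depredation and the
#' trial is excluded; anything else is unresolved and excluded.
#'
#' @param checks Data frame with columns `day` (days since manipulation),
#'   `n_eggs`, `incubating` (logical), optionally `experimental_present`
#'   (logical, whether the experimental egg was still in the nest).
#' @param initial_count Clutch size immediately after manipulation.
#' @return One of `"rejected"`, `"accepted"`, `"depredated"`,
#'   `"unresolved"`; for rejections, attribute `"rejected_egg"` is
#'   `"experimental"`, `"own"` or `NA` as identifiable.
#' @export
classify_outcome <- function(checks, initial_count) {
  if (nrow(checks) < 1) stop("need at least one post-manipulation check")
  checks <- checks[order(checks$day), , drop = FALSE]
  prev <- initial_count
  for (i in seq_len(nrow(checks))) {
    nn <- checks$n_eggs[i]
    if (nn > prev)
      stop(sprintf("data error: egg count increased (%d -> %d) at day %g",
                   prev, nn, checks$day[i]))
    if (nn == 0) return("depredated")
    if (nn == initial_count - 1) {
      out <- "rejected"
      which_egg <- NA_character_
      if ("experimental_present" %in% names(checks))
        which_egg <- if (isTRUE(checks$experimental_present[i])) "own"
                     else "experimental"
      attr(out, "rejected_egg") <- which_egg
      return(out)
    }
    if (nn < initial_count - 1) return("unresolved")
    prev <- nn
  }
  last_intact <- checks$n_eggs == initial_count & checks$incubating
  if (any(last_intact & checks$day >= 3)) return("accepted")
  "unresolved"
}
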