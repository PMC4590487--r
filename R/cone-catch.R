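#' Cone quantum catches from a reflectance spectrum
#'
#' Integrates reflectance x illuminant x receptor sensitivity over
#' wavelength and applies von Kries normalization: each receptor's raw
#' catch is divided by its catch from a perfect (unit-reflectance) surface
#' under the same illuminant, modelling chromatic adaptation. A perfectly
#' white surface therefore yields catch 1 in every receptor.
#'
#' @param reflectance A [spectrum()] (reflectance, 0-1.5).
#' @param illuminant A [spectrum()] (irradiance, arbitrary units); default
#'   equal-energy.
#' @param receptors A [receptor_set()].
#' @param include_double_cone If `TRUE` and the set carries a double cone,
#'   attach its normalized catch as attribute `"luminance"`.
#' @return Named numeric vector of normalized catches (class
#'   `"cone_catch"`), one per chromatic receptor.
#' @export
cone_catch_from_spectrum <- function(reflectance, illuminant = NULL,
                                     receptors, include_double_cone = TRUE) {
  stopifnot(is_spectrum(reflectance), inherits(receptors, "receptor_set"))
  grids <- lapply(receptors$sensitivities, function(s) s$wavelength_nm)
  lo <- max(vapply(grids, min, numeric(1)), min(reflectance$wavelength_nm))
  hi <- min(vapply(grids, max, numeric(1)), max(reflectance$wavelength_nm))
  if (is.null(illuminant)) illuminant <- flat_illuminant(seq(lo, hi))
  lo <- max(lo, min(illuminant$wavelength_nm))
  hi <- min(hi, max(illuminant$wavelength_nm))
  if (hi <= lo) stop("no common wavelength range between spectra and receptors")
  grid <- seq(ceiling(lo), floor(hi), by = 1)
  R <- interpolate_spectrum(reflectance, grid)$value
  I <- interpolate_spectrum(illuminant, grid)$value
  w <- c(0.5, rep(1, length(grid) - 2), 0.5)  # trapezoid weights, 1-nm grid
  catch1 <- function(sens) {
    S <- interpolate_spectrum(sens, grid)$value
    denom <- sum(w * I * S)
    if (denom <= 0)
      stop("degenerate catch: illuminant does not overlap a receptor sensitivity")
    sum(w * R * I * S) / denom
  }
  q <- vapply(receptors$sensitivities, catch1, numeric(1))
  q <- stats::setNames(as.numeric(q), receptors$names)
  class(q) <- "cone_catch"
  if (include_double_cone && !is.null(receptors$double_cone))
    attr(q, "luminance") <- catch1(receptors$double_cone)
  q
}

# Build the monomial exponent table for a full polynomial (with all
# interaction terms) of given degree over nc channels, intercept included.
poly_terms <- function(nc, degree) {
  grids <- rep(list(0:degree), nc)
  ex <- as.matrix(expand.grid(grids))
  ex <- ex[rowSums(ex) <= degree, , drop = FALSE]
  # conventional order: intercept, x1, x2, ..., then degree-2 terms, ...
  ex <- ex[order(rowSums(ex),
                 apply(ex, 1, function(r) paste(rev(r), collapse = ","))), ,
           drop = FALSE]
  dimnames(ex) <- NULL
  ex
}

poly_design <- function(X, exponents) {
  n <- nrow(X)
  out <- matrix(1, n, nrow(exponents))
  for (j in seq_len(nrow(exponents)))
    for (k in seq_len(ncol(exponents)))
      if (exponents[j, k] > 0) out[, j] <- out[, j] * X[, k]^exponents[j, k]
  out
}

#' Fit a camera-to-cone polynomial mapping
#'
#' Least-squares fit of each receptor's quantum catch as a polynomial (all
#' interaction terms up to `degree`) in the camera channel catches — the
#' standard calibration step that turns a calibrated photograph into
#' cone-catch images. Needs a training library of spectra for which both
#' camera and cone catches are known.
#'
#' @param training_camera Matrix (spectra x channels) of camera catches.
#' @param training_cones Matrix (spectra x receptors) of cone catches.
#' @param degree Polynomial degree, default 2.
#' @return An object of class `"polynomial_mapping"`: exponent table,
#'   coefficient matrix (terms x receptors) and per-receptor R-squared.
#' @export
fit_camera_to_cone <- function(training_camera, training_cones, degree = 2) {
  X <- as.matrix(training_camera)
  Y <- as.matrix(training_cones)
  if (nrow(X) != nrow(Y)) stop("training sets must have equal rows")
  ex <- poly_terms(ncol(X), degree)
  if (nrow(X) < 3 * nrow(ex))
    stop(sprintf(
      "need at least 3x more training spectra (%d) than polynomial terms (%d)",
      nrow(X), nrow(ex)))
  D <- poly_design(X, ex)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    aliased <- setdiff(seq_len(ncol(D)), qrD$pivot[seq_len(qrD$rank)])
    labs <- apply(ex[aliased, , drop = FALSE], 1, paste, collapse = ",")
    stop("rank-deficient polynomial design; collinear terms (exponents): ",
         paste(labs, collapse = "; "))
  }
  coefs <- qr.coef(qrD, Y)
  fitted <- D %*% coefs
  r2 <- vapply(seq_len(ncol(Y)), function(j) {
    ss_res <- sum((Y[, j] - fitted[, j])^2)
    ss_tot <- sum((Y[, j] - mean(Y[, j]))^2)
    if (ss_tot == 0) 1 else max(0, min(1, 1 - ss_res / ss_tot))
  }, numeric(1))
  structure(list(
    degree = degree,
    exponents = ex,
    coefficients = coefs,
    n_channels = ncol(X),
    receptor_names = colnames(Y) %||% paste0("r", seq_len(ncol(Y))),
    fit_r2 = stats::setNames(r2, colnames(Y))
  ), class = "polynomial_mapping")
}

#' Apply a camera-to-cone mapping to pixel values
#'
#' @param mapping A fitted [fit_camera_to_cone()] mapping.
#' @param pixels Matrix (pixels x channels) of camera values (or a single
#'   pixel as a vector).
#' @param floor Small positive floor applied to predicted catches before
#'   any downstream logarithm, default 1e-6.
#' @return Matrix (pixels x receptors) of predicted catches.
#' @export
apply_camera_to_cone <- function(mapping, pixels, floor = 1e-6) {
  stopifnot(inherits(mapping, "polynomial_mapping"))
  if (is.null(dim(pixels))) pixels <- matrix(pixels, nrow = 1)
  pixels <- as.matrix(pixels)
  if (ncol(pixels) != mapping$n_channels)
    stop(sprintf("mapping expects %d channels, got %d",
                 mapping$n_channels, ncol(pixels)))
  pred <- poly_design(pixels, mapping$exponents) %*% mapping$coefficients
  pred[pred < floor] <- floor
  colnames(pred) <- mapping$receptor_names
  pred
}
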