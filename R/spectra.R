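#' Construct a spectrum
#'
#' A spectrum is a non-negative function of wavelength sampled on a strictly
#' ascending grid, used for reflectances, illuminants and receptor
#' sensitivities alike.
#'
#' @param wavelength_nm Numeric vector of wavelengths (nm), strictly
#'   ascending, within \[300, 700\].
#' @param value Non-negative values at each wavelength. Reflectance spectra
#'   may exceed 1 slightly (up to 1.5) to allow for measurement noise above
#'   a white standard.
#' @return An object of class `"spectrum"`: a data frame with columns
#'   `wavelength_nm` and `value`.
#' @export
spectrum <- function(wavelength_nm, value) {
  wavelength_nm <- as.numeric(wavelength_nm)
  value <- as.numeric(value)
  if (length(wavelength_nm) != length(value))
    stop("wavelength and value must have equal length")
  if (length(wavelength_nm) < 1)
    stop("a spectrum needs at least one sample")
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelength grid must be strictly ascending")
  if (min(wavelength_nm) < 300 || max(wavelength_nm) > 700)
    stop("wavelengths must lie within [300, 700] nm")
  if (any(value < 0))
    stop("spectrum values must be non-negative")
  out <- data.frame(wavelength_nm = wavelength_nm, value = value)
  class(out) <- c("spectrum", "data.frame")
  out
}

is_spectrum <- function(x) inherits(x, "spectrum")

#' Interpolate a spectrum onto a 1-nm grid
#'
#' Linear interpolation onto a regular grid. Extrapolation beyond the
#' sampled range is refused rather than guessed.
#'
#' @param s A [spectrum()].
#' @param grid Target wavelengths (nm); must lie within the range of `s`.
#' @return A [spectrum()] on `grid`.
#' @export
interpolate_spectrum <- function(s, grid) {
  stopifnot(is_spectrum(s))
  grid <- as.numeric(grid)
  if (min(grid) < min(s$wavelength_nm) || max(grid) > max(s$wavelength_nm))
    stop(sprintf(
      "requested grid [%g, %g] extends beyond the sampled range [%g, %g]: refusing to extrapolate",
      min(grid), max(grid), min(s$wavelength_nm), max(s$wavelength_nm)))
  v <- stats::approx(s$wavelength_nm, s$value, xout = grid, method = "linear")$y
  spectrum(grid, v)
}

#' Mean of replicate spectra
#'
#' Pointwise mean of replicate reflectance measurements of the same surface
#' (e.g. repeated probe placements on one egg), after interpolation onto a
#' common 1-nm grid. The replicate coefficient of variation, averaged over
#' wavelengths, is attached as attribute `"cv"` as a per-egg measurement
#' quality figure.
#'
#' @param replicates A list of [spectrum()] objects (at least 2).
#' @param grid Optional common grid; defaults to the 1-nm grid spanning the
#'   intersection of the replicate ranges.
#' @return A [spectrum()] with attribute `cv`.
#' @export
mean_spectrum <- function(replicates, grid = NULL) {
  if (!is.list(replicates) || length(replicates) < 2)
    stop("need at least 2 replicate spectra")
  stopifnot(all(vapply(replicates, is_spectrum, logical(1))))
  if (is.null(grid)) {
    lo <- max(vapply(replicates, function(s) min(s$wavelength_nm), numeric(1)))
    hi <- min(vapply(replicates, function(s) max(s$wavelength_nm), numeric(1)))
    if (hi <= lo) stop("replicate spectra share no wavelength range")
    grid <- seq(ceiling(lo), floor(hi), by = 1)
  }
  vals <- vapply(replicates, function(s) interpolate_spectrum(s, grid)$value,
                 numeric(length(grid)))
  m <- rowMeans(vals)
  sdev <- apply(vals, 1, stats::sd)
  cv <- mean(ifelse(m > 0, sdev / m, 0))
  out <- spectrum(grid, m)
  attr(out, "cv") <- cv
  out
}

#' Flat (equal-energy) illuminant
#'
#' @param grid Wavelength grid (nm), default 300:700.
#' @param value Constant spectral value, default 1.
#' @return A [spectrum()].
#' @export
flat_illuminant <- function(grid = 300:700, value = 1) {
  spectrum(grid, rep(value, length(grid)))
}
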