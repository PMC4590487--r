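#' Visual pigment absorbance template
#'
#' Govardovskii A1 visual-pigment nomogram: the standard parametric template
#' for vertebrate photoreceptor absorbance as a function of wavelength and
#' the pigment's peak wavelength. Used to build default receptor
#' sensitivity sets; any set can instead be loaded from CSV tables via
#' [load_receptor_set()].
#'
#' @param lambda_max Peak absorbance wavelength (nm).
#' @param grid Wavelength grid (nm), default 300:700.
#' @return A [spectrum()] with unit peak.
#' @export
pigment_template <- function(lambda_max, grid = 300:700) {
  x <- lambda_max / grid
  # alpha band
  A <- 69.7; B <- 28; b <- 0.922; C <- -14.9; c_ <- 1.104; D <- 0.674
  a <- 0.8795 + 0.0459 * exp(-((lambda_max - 300)^2) / 11940)
  S_alpha <- 1 / (exp(A * (a - x)) + exp(B * (b - x)) + exp(C * (c_ - x)) + D)
  # beta band
  A_beta <- 0.26
  lmb <- 189 + 0.315 * lambda_max
  bb <- -40.5 + 0.195 * lambda_max
  S_beta <- A_beta * exp(-((grid - lmb) / bb)^2)
  v <- S_alpha + S_beta
  spectrum(grid, v / max(v))
}

#' Assemble a receptor set
#'
#' Bundles the spectral sensitivities, relative abundances and the Weber
#' reference for one model visual system. Chromatic receptors are listed in
#' `names`; an achromatic (double-cone) channel may be attached under
#' `"DBL"`.
#'
#' @param sensitivities Named list of [spectrum()] objects, one per
#'   receptor, in fixed order (short- to long-wave by convention).
#' @param abundances Named positive weights, same names as `sensitivities`
#'   (the achromatic channel may be omitted).
#' @param weber_reference Length-2 list or vector: reference receptor name
#'   and its Weber fraction.
#' @param double_cone Optional [spectrum()] for the achromatic channel.
#' @param double_cone_weber Weber fraction of the achromatic channel.
#' @return An object of class `"receptor_set"`.
#' @export
receptor_set <- function(sensitivities, abundances, weber_reference,
                         double_cone = NULL, double_cone_weber = 0.05) {
  nm <- names(sensitivities)
  if (is.null(nm) || any(nm == ""))
    stop("sensitivities must be a named list")
  if (length(nm) < 2)
    stop("need at least 2 chromatic receptors")
  stopifnot(all(vapply(sensitivities, is_spectrum, logical(1))))
  abundances <- abundances[nm]
  if (any(is.na(abundances)) || any(abundances <= 0))
    stop("abundances must be positive and cover every receptor")
  ref_name <- as.character(weber_reference[[1]])
  ref_e <- as.numeric(weber_reference[[2]])
  if (!ref_name %in% nm)
    stop(sprintf("Weber reference receptor '%s' not in receptor set", ref_name))
  if (ref_e <= 0 || ref_e >= 1) stop("Weber fraction must lie in (0, 1)")
  structure(list(
    names = nm,
    sensitivities = sensitivities,
    abundances = abundances,
    weber_reference = list(receptor = ref_name, e = ref_e),
    double_cone = double_cone,
    double_cone_weber = double_cone_weber
  ), class = "receptor_set")
}

#' @export
print.receptor_set <- function(x, ...) {
  cat("Receptor set:", paste(x$names, collapse = ", "))
  if (!is.null(x$double_cone)) cat(" (+DBL)")
  cat("\n  abundances:", paste(sprintf("%s=%.3g", x$names, x$abundances),
                               collapse = ", "), "\n")
  w <- weber_fractions(x)
  cat("  Weber fractions:", paste(sprintf("%s=%.3g", names(w), w),
                                  collapse = ", "), "\n")
  invisible(x)
}

#' Weber fractions from receptor abundances
#'
#' Receptor-noise scaling: channel noise is taken to fall with the square
#' root of the number of receptors of that class, so
#' `e_i = e_ref * sqrt(eta_ref / eta_i)`.
#'
#' @param abundances Named positive weights per receptor.
#' @param reference Length-2 list/vector: (receptor name, Weber fraction).
#' @return Named numeric vector of Weber fractions.
#' @export
weber_from_abundances <- function(abundances, reference) {
  if (any(abundances <= 0)) stop("abundances must be positive")
  ref_name <- as.character(reference[[1]])
  ref_e <- as.numeric(reference[[2]])
  if (!ref_name %in% names(abundances))
    stop(sprintf("reference receptor '%s' not among abundances", ref_name))
  e <- ref_e * sqrt(abundances[[ref_name]] / abundances)
  stats::setNames(as.numeric(e), names(abundances))
}

#' Weber fractions of a receptor set
#' @param rs A [receptor_set()].
#' @return Named numeric vector.
#' @export
weber_fractions <- function(rs) {
  stopifnot(inherits(rs, "receptor_set"))
  weber_from_abundances(rs$abundances,
                        list(rs$weber_reference$receptor, rs$weber_reference$e))
}

# Default cone abundance ratios for a small passerine UVS retina
# (UVS:SWS:MWS:LWS), a standard choice in avian visual modelling.
.uvs_abundances <- c(UVS = 0.37, SWS = 0.70, MWS = 0.99, LWS = 1.00)
.vs_abundances  <- c(VS = 0.25, SWS = 0.92, MWS = 1.00, LWS = 0.81)

#' Built-in model visual systems
#'
#' `bluetit_uvs()` is an ultraviolet-sensitive four-cone passerine system
#' (template peaks 371, 448, 503, 563 nm; double cone at 563 nm);
#' `peafowl_vs()` is a violet-sensitive alternative (peaks 432, 477, 537,
#' 605 nm). `trichromat_visible()` drops the UV cone for analyses restricted
#' to visible-band photography (420-680 nm). Sensitivities are built from
#' the pigment nomogram; custom tables can replace them via
#' [load_receptor_set()].
#'
#' @param grid Wavelength grid (nm).
#' @param weber_reference_e Weber fraction of the most abundant (reference)
#'   cone, default 0.05.
#' @return A [receptor_set()].
#' @export
bluetit_uvs <- function(grid = 300:700, weber_reference_e = 0.05) {
  peaks <- c(UVS = 371, SWS = 448, MWS = 503, LWS = 563)
  sens <- lapply(peaks, pigment_template, grid = grid)
  receptor_set(sens, .uvs_abundances, list("LWS", weber_reference_e),
               double_cone = pigment_template(563, grid),
               double_cone_weber = weber_reference_e)
}

#' @rdname bluetit_uvs
#' @export
peafowl_vs <- function(grid = 300:700, weber_reference_e = 0.05) {
  peaks <- c(VS = 432, SWS = 477, MWS = 537, LWS = 605)
  sens <- lapply(peaks, pigment_template, grid = grid)
  receptor_set(sens, .vs_abundances, list("MWS", weber_reference_e),
               double_cone = pigment_template(567, grid),
               double_cone_weber = weber_reference_e)
}

#' @rdname bluetit_uvs
#' @export
trichromat_visible <- function(grid = 420:680, weber_reference_e = 0.05) {
  peaks <- c(SWS = 448, MWS = 503, LWS = 563)
  sens <- lapply(peaks, pigment_template, grid = grid)
  receptor_set(sens, .uvs_abundances[c("SWS", "MWS", "LWS")],
               list("LWS", weber_reference_e),
               double_cone = pigment_template(563, grid),
               double_cone_weber = weber_reference_e)
}

#' Visible-band camera sensitivities
#'
#' A three-channel (vR, vG, vB) visible-pass camera model: Gaussian channel
#' sensitivities restricted to 420-680 nm, used for simulating calibrated
#' photographs and for camera-to-cone mapping exercises.
#'
#' @param grid Wavelength grid (nm), default 420:680.
#' @return Named list of [spectrum()] objects (vR, vG, vB).
#' @export
camera_visible <- function(grid = 420:680) {
  gauss <- function(mu, sd) {
    v <- exp(-((grid - mu)^2) / (2 * sd^2))
    spectrum(grid, v / max(v))
  }
  list(vR = gauss(600, 45), vG = gauss(535, 40), vB = gauss(465, 35))
}

#' Load a receptor set from CSV tables
#'
#' Reads a YAML manifest naming, for each receptor, a CSV sensitivity table
#' (`wavelength_nm,value`), plus `abundances` and `weber_reference` blocks.
#'
#' @param manifest_path Path to the YAML manifest; CSV paths are resolved
#'   relative to the manifest directory.
#' @return A [receptor_set()].
#' @export
load_receptor_set <- function(manifest_path) {
  man <- yaml::read_yaml(manifest_path)
  base <- dirname(manifest_path)
  read_sens <- function(p) {
    d <- utils::read.csv(file.path(base, p))
    spectrum(d$wavelength_nm, d$value)
  }
  sens <- lapply(man$receptors, read_sens)
  dbl <- if (!is.null(man$double_cone)) read_sens(man$double_cone) else NULL
  receptor_set(sens,
               unlist(man$abundances)[names(sens)],
               list(man$weber_reference$receptor, man$weber_reference$e),
               double_cone = dbl,
               double_cone_weber = man$double_cone_weber %||% 0.05)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
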