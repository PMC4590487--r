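#' Body regions recognised in plumage analyses
#' @export
BODY_REGIONS <- c("back", "beak", "belly", "breast", "cheek", "eyebrow",
                  "head", "throat", "wing")

#' Construct a linear image
#'
#' A calibrated specimen photograph after linearization: an H x W x C array
#' of non-negative linear sensor values, plus channel labels and a scale
#' flag recording whether the image has been normalized to the grey
#' standard yet.
#'
#' @param pixels Numeric array H x W x C (a matrix is promoted to C = 1).
#' @param channel_names Ordered channel labels, e.g. `c("vR","vG","vB")`.
#' @param scale `"raw-linear"` or `"reflectance-normalized"`.
#' @return Object of class `"linear_image"`.
#' @export
linear_image <- function(pixels, channel_names = NULL,
                         scale = c("raw-linear", "reflectance-normalized")) {
  scale <- match.arg(scale)
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  if (length(dim(pixels)) != 3) stop("pixels must be an H x W x C array")
  if (any(pixels < 0)) stop("linear pixel values must be >= 0")
  C <- dim(pixels)[3]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(C))
  if (length(channel_names) != C)
    stop("channel_names length must match channel count")
  structure(list(pixels = pixels, channel_names = channel_names,
                 scale = scale), class = "linear_image")
}

#' Grey-standard region
#'
#' The region of a photograph covered by the reflectance standard
#' (a 40% Spectralon panel by default) used for exposure normalization.
#'
#' @param mask Logical matrix, `TRUE` over the standard.
#' @param reflectance Known standard reflectance in (0, 1], default 0.40.
#' @return Object of class `"grey_standard"`.
#' @export
grey_standard <- function(mask, reflectance = 0.40) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (!any(mask)) stop("grey-standard mask is empty")
  if (reflectance <= 0 || reflectance > 1)
    stop("standard reflectance must lie in (0, 1]")
  structure(list(mask = mask, reflectance = reflectance),
            class = "grey_standard")
}

#' Normalize an image to its grey standard
#'
#' Scales each channel so that the mean value over the standard region
#' equals the standard's known reflectance, converting arbitrary linear
#' sensor units to reflectance units and equalizing channels to grey.
#'
#' @param img A raw-linear [linear_image()].
#' @param std A [grey_standard()] whose mask lies inside the image.
#' @return A reflectance-normalized [linear_image()].
#' @export
normalize_to_standard <- function(img, std) {
  stopifnot(inherits(img, "linear_image"), inherits(std, "grey_standard"))
  if (img$scale != "raw-linear")
    stop("image is already reflectance-normalized")
  d <- dim(img$pixels)
  if (!identical(dim(std$mask), d[1:2]))
    stop("standard mask does not match image dimensions")
  out <- img$pixels
  for (ch in seq_len(d[3])) {
    plane <- img$pixels[, , ch]
    m <- mean(plane[std$mask])
    if (!is.finite(m) || m <= 0)
      stop(sprintf("calibration error: channel '%s' standard mean is %g",
                   img$channel_names[ch], m))
    out[, , ch] <- plane * (std$reflectance / m)
  }
  linear_image(out, img$channel_names, scale = "reflectance-normalized")
}

#' Extract a labelled body-region patch
#'
#' @param img A [linear_image()].
#' @param mask Logical matrix selecting the region's pixels.
#' @param region One of [BODY_REGIONS] (or any label when `strict = FALSE`,
#'   e.g. for eggshell patches).
#' @param strict Require a recognised body-region label, default `TRUE`.
#' @return Object of class `"patch_image"`: per-pixel channel values
#'   (n_pixels x C), the mask, pixel coordinates and the region label.
#' @export
extract_patch <- function(img, mask, region, strict = TRUE) {
  stopifnot(inherits(img, "linear_image"))
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  d <- dim(img$pixels)
  if (!identical(dim(mask), d[1:2]))
    stop("mask dimensions do not match image")
  if (!any(mask)) stop("patch mask is empty")
  if (strict && !region %in% BODY_REGIONS)
    stop(sprintf("unknown region '%s'; expected one of: %s",
                 region, paste(BODY_REGIONS, collapse = ", ")))
  idx <- which(mask)
  vals <- vapply(seq_len(d[3]), function(ch) img$pixels[, , ch][idx],
                 numeric(length(idx)))
  vals <- matrix(vals, nrow = length(idx),
                 dimnames = list(NULL, img$channel_names))
  coords <- arrayInd(idx, d[1:2])
  structure(list(region = region, values = vals, mask = mask,
                 coords = coords, n_pixels = length(idx),
                 channel_names = img$channel_names, scale = img$scale),
            class = "patch_image")
}

#' Downsample a patch to the analysis pixel budget
#'
#' Exhaustive pairwise colour calculations are quadratic in pixel count, so
#' patches are reduced to a fixed budget (2000 pixels by default) by seeded
#' uniform subsampling without replacement. Patches already within budget
#' are returned unchanged. Subsampling (rather than geometric resizing)
#' preserves the pixel colour multiset; area-averaging resize is available
#' upstream via `method = "resize"` losses being acceptable.
#'
#' @param patch A [extract_patch()] result.
#' @param budget Maximum pixels to keep, default 2000.
#' @param seed Integer seed making the subsample reproducible.
#' @param method `"subsample"` (default) or `"resize"` (area-averaging over
#'   seeded random groups of pixels; smooths the colour distribution).
#' @return A `"patch_image"` with `n_pixels <= budget`.
#' @export
downsample_patch <- function(patch, budget = 2000, seed = 1L,
                             method = c("subsample", "resize")) {
  stopifnot(inherits(patch, "patch_image"))
  method <- match.arg(method)
  if (budget < 1) stop("pixel budget must be >= 1")
  if (patch$n_pixels <= budget) return(patch)
  if (method == "subsample") {
    keep <- withr::with_seed(as.integer(seed),
                             sort(sample.int(patch$n_pixels, budget)))
    patch$values <- patch$values[keep, , drop = FALSE]
    patch$coords <- patch$coords[keep, , drop = FALSE]
  } else {
    grp <- withr::with_seed(as.integer(seed),
                            sample(rep_len(seq_len(budget), patch$n_pixels)))
    patch$values <- apply(patch$values, 2, function(v)
      as.numeric(tapply(v, grp, mean)))
    patch$coords <- NULL
  }
  patch$n_pixels <- budget
  patch$mask <- NULL  # mask no longer describes the retained pixels
  patch
}

#' Read a linear image from TIFF or PNG
#'
#' @param path Image path (.tif/.tiff or .png); values are read as linear
#'   and left unscaled.
#' @param channel_names Optional channel labels.
#' @param drop_alpha Treat a 4th channel as alpha and discard it; defaults
#'   to `TRUE` for PNG (RGBA) and `FALSE` for TIFF, whose 4th sample is a
#'   data channel here.
#' @return A raw-linear [linear_image()].
#' @export
read_linear_image <- function(path, channel_names = NULL, drop_alpha = NULL) {
  ext <- tolower(tools::file_ext(path))
  # multi-sample scientific TIFFs trip a benign photometric-tag warning
  px <- switch(ext,
    tif = , tiff = suppressWarnings(tiff::readTIFF(path)),
    png = png::readPNG(path),
    stop("unsupported image format: ", ext))
  if (is.null(drop_alpha)) drop_alpha <- ext == "png"
  if (drop_alpha && length(dim(px)) == 3 && dim(px)[3] == 4)
    px <- px[, , 1:3]
  linear_image(px, channel_names, scale = "raw-linear")
}

#' Read a binary mask from an 8-bit PNG (0/255)
#' @param path PNG path.
#' @return Logical matrix (`TRUE` where the mask is set).
#' @export
read_mask <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  px > 0.5
}
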