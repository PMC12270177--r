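# H-DAB colour deconvolution and construction of the cleaned binary
# epithelium mask from the DAB channel of a CK AE1/AE3 restained slide.
#
# Brightfield stains follow Beer-Lambert absorbance: for incident intensity
# I0 and transmitted intensity I, the optical density per RGB channel is
# OD = -log10(I / I0), and OD is linear in stain concentration. Unmixing
# solves the 3x3 linear system defined by the unit stain vectors.

#' H-DAB stain vectors
#'
#' The standard published H-DAB reference pair (hematoxylin and DAB optical
#' density vectors), with the residual as their normalized cross product.
#' These are the default vectors brightfield H-DAB deconvolution tools ship
#' with; override per slide if a calibration is available.
#'
#' @param hematoxylin,dab,residual optional 3-vectors of RGB optical-density
#'   components; normalized to unit length.
#' @param background_intensity per-channel incident intensity I0 on the
#'   0..255 scale.
#' @return object of class \code{stain_vectors} containing the 3x3 OD matrix
#'   (rows = stains) and its inverse.
#' @export
hdab_stain_vectors <- function(hematoxylin = c(0.65, 0.70, 0.29),
                               dab = c(0.27, 0.57, 0.78),
                               residual = NULL,
                               background_intensity = c(255, 255, 255)) {
  unit <- function(v) v / sqrt(sum(v^2))
  h <- unit(hematoxylin); d <- unit(dab)
  if (is.null(residual)) {
    r <- c(h[2] * d[3] - h[3] * d[2],
           h[3] * d[1] - h[1] * d[3],
           h[1] * d[2] - h[2] * d[1])
    if (sqrt(sum(r^2)) < 1e-8)
      stop("stain matrix is singular: hematoxylin and DAB vectors are parallel")
  } else r <- residual
  r <- unit(r)
  M <- rbind(hematoxylin = h, dab = d, residual = r)
  if (!all(background_intensity >= 1 & background_intensity <= 255))
    stop("background_intensity must lie in [1, 255] per channel")
  kappa <- kappa(M, exact = TRUE)
  if (!is.finite(kappa) || kappa > 1e6)
    stop("stain matrix is singular or ill-conditioned (condition number ",
         format(kappa), ")")
  structure(list(matrix = M, inverse = solve(M),
                 background_intensity = background_intensity),
            class = "stain_vectors")
}

#' Mask-building parameters
#'
#' Defaults follow the reference pipeline for CK AE1/AE3 restains: Gaussian
#' prefilter sigma 3.0 px and DAB optical-density threshold 0.25 at a working
#' resolution of 0.3448 um/px; nuclear holes below 150 um^2 are filled and
#' fragments below 25 um^2 removed (both strict inequalities).
#'
#' @param gaussian_sigma smoothing sigma in pixels.
#' @param dab_threshold optical-density threshold on the smoothed DAB channel.
#' @param work_mpp working resolution in microns per pixel.
#' @param fill_hole_area_max holes with area strictly below this (um^2) are filled.
#' @param remove_object_area_max objects with area strictly below this (um^2)
#'   are removed.
#' @return list of class \code{mask_params}.
#' @export
mask_params <- function(gaussian_sigma = 3.0, dab_threshold = 0.25,
                        work_mpp = 0.3448, fill_hole_area_max = 150,
                        remove_object_area_max = 25) {
  p <- list(gaussian_sigma = gaussian_sigma, dab_threshold = dab_threshold,
            work_mpp = work_mpp, fill_hole_area_max = fill_hole_area_max,
            remove_object_area_max = remove_object_area_max)
  if (any(unlist(p) <= 0)) stop("all mask parameters must be strictly positive")
  class(p) <- "mask_params"
  p
}

#' Forward Beer-Lambert synthesis of an RGB tile from stain concentrations
#'
#' The inverse of \code{\link{deconvolve_hdab}}; used by the synthetic
#' generator and as the oracle in deconvolution round-trip checks.
#' I_c = I0_c * 10^-(sum_s conc_s * stainvec_s,c).
#'
#' @param conc [H, W, 3] array of concentrations (hematoxylin, dab, residual).
#' @param vectors \code{stain_vectors}.
#' @return [H, W, 3] RGB array in [0, 1].
#' @export
synthesize_hdab <- function(conc, vectors = hdab_stain_vectors()) {
  d <- dim(conc)
  cm <- matrix(conc, d[1] * d[2], 3)
  od <- cm %*% vectors$matrix
  i0 <- vectors$background_intensity
  rgb <- sweep(10^(-od), 2, i0 / 255, `*`)
  array(pmin(1, pmax(0, rgb)), c(d[1], d[2], 3))
}

#' H-DAB colour deconvolution of an RGB tile
#'
#' Converts each channel to optical density OD = -log10(max(I, 1) / I0) on
#' the 8-bit scale and solves the stain linear system per pixel. Negative
#' concentrations are clamped to zero.
#'
#' @param rgb_tile [H, W, 3] array in [0, 1] (8-bit image / 255).
#' @param vectors \code{stain_vectors}.
#' @return list of matrices \code{hematoxylin}, \code{dab}, \code{residual}
#'   holding per-pixel stain optical densities.
#' @export
deconvolve_hdab <- function(rgb_tile, vectors = hdab_stain_vectors()) {
  d <- dim(rgb_tile)
  stopifnot(length(d) == 3L, d[3] == 3L)
  i8 <- pmax(matrix(rgb_tile, d[1] * d[2], 3) * 255, 1)
  od <- -log10(sweep(i8, 2, vectors$background_intensity, `/`))
  conc <- od %*% vectors$inverse
  conc[conc < 0] <- 0
  list(hematoxylin = matrix(conc[, 1], d[1], d[2]),
       dab = matrix(conc[, 2], d[1], d[2]),
       residual = matrix(conc[, 3], d[1], d[2]))
}

#' Threshold the DAB optical-density channel into a raw epithelium mask
#'
#' Gaussian-smooths the DAB channel (reflective borders) and thresholds it.
#'
#' @param dab_od matrix of DAB optical densities at the working resolution.
#' @param params \code{mask_params}.
#' @return \code{binary_mask} at \code{params$work_mpp}.
#' @export
dab_mask <- function(dab_od, params = mask_params()) {
  sm <- gaussian_blur(dab_od, params$gaussian_sigma)
  binary_mask((sm > params$dab_threshold) * 1L, mpp = params$work_mpp)
}

#' Fill nuclear holes and remove small fragments in an epithelium mask
#'
#' CK is a cytoplasmic marker, so thresholding leaves unstained nuclear holes
#' inside epithelial regions. Background holes (4-connected components of the
#' complement not touching the border) with area strictly below
#' \code{fill_hole_area_max} um^2 are filled; then foreground objects
#' (8-connected) with area strictly below \code{remove_object_area_max} um^2
#' are removed. Area thresholds are converted to pixels as
#' \code{round(area / mpp^2)}.
#'
#' @param mask \code{binary_mask} with known mpp.
#' @param params \code{mask_params}.
#' @return cleaned \code{binary_mask}.
#' @export
clean_mask <- function(mask, params = mask_params()) {
  mpp <- if (is.na(mask$mpp)) params$work_mpp else mask$mpp
  if (is.na(mpp) || mpp <= 0) stop("mask mpp unknown; area thresholds undefined")
  m <- mask$raster
  fill_px <- round(params$fill_hole_area_max / mpp^2)
  rm_px <- round(params$remove_object_area_max / mpp^2)

  # holes: 4-connected background components not touching the raster border
  bg <- label_components(m == 0L, connectivity = 4L)
  if (max(bg) > 0L) {
    border_labs <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
    areas <- component_areas(bg)
    fill <- setdiff(which(areas < fill_px), border_labs)
    if (length(fill)) m[bg %in% fill] <- 1L
  }

  # fragments: 8-connected foreground components
  fg <- label_components(m == 1L, connectivity = 8L)
  if (max(fg) > 0L) {
    areas <- component_areas(fg)
    drop <- which(areas < rm_px)
    if (length(drop)) m[fg %in% drop] <- 0L
  }
  binary_mask(m, origin = mask$origin, level_downsample = mask$level_downsample,
              mpp = mpp)
}

#' Full CK tile to cleaned epithelium mask
#'
#' Convenience composition: deconvolve, threshold, clean.
#' @param ck_rgb [H, W, 3] CK tile at the working resolution.
#' @inheritParams dab_mask
#' @param vectors \code{stain_vectors}.
#' @export
ck_epithelium_mask <- function(ck_rgb, params = mask_params(),
                               vectors = hdab_stain_vectors()) {
  dab <- deconvolve_hdab(ck_rgb, vectors)$dab
  clean_mask(dab_mask(dab, params), params)
}
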