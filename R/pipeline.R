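# End-to-end orchestration: from a paired HE/CK slide and its annotations to
# registered per-core HE rasters with four-class ground truths, ready for
# patching (training) or whole-core inference (evaluation).

#' Mask parameters rescaled to a working resolution
#'
#' The canonical mask recipe is stated at 0.3448 um/px with a 3.0 px
#' smoothing sigma. Working at another resolution keeps the physical
#' smoothing scale (sigma in microns) and the um^2 area rules fixed by
#' rescaling sigma to pixels at the new resolution.
#'
#' @param mpp working resolution in microns per pixel.
#' @param base \code{mask_params} to rescale.
#' @export
mask_params_at <- function(mpp, base = mask_params()) {
  mask_params(gaussian_sigma = base$gaussian_sigma * base$work_mpp / mpp,
              dab_threshold = base$dab_threshold, work_mpp = mpp,
              fill_hole_area_max = base$fill_hole_area_max,
              remove_object_area_max = base$remove_object_area_max)
}

#' Process a paired HE/CK slide into per-core ground-truth records
#'
#' Runs the full data-creation path: core detection on the HE slide,
#' exclusion tagging and case grouping from the annotations, HE/CK core
#' pairing by centroid proximity, per-core extraction at the requested
#' magnification, rigid registration of the CK core onto the HE core,
#' DAB-mask construction and cleaning, annotation rasterization in HE
#' coordinates, and four-class ground-truth assembly.
#'
#' @param he,ck \code{pyramidal_image}s of the restained slide pair.
#' @param ann \code{annotation_set} in HE level-0 coordinates.
#' @param magnification extraction magnification (e.g. "x10" for training
#'   cores, "x20" for evaluation cores).
#' @param ex_params \code{extractor_params}.
#' @param reg_params \code{registration_params}.
#' @param base_mask_params \code{mask_params} before rescaling to the
#'   extraction resolution.
#' @param vectors \code{stain_vectors} for the CK deconvolution.
#' @return list of per-core records: \code{core_ref}, \code{he} raster,
#'   \code{ck} (registered), \code{mask} (\code{binary_mask}), \code{gt}
#'   (\code{ground_truth}), \code{shift}, \code{case_id}, \code{bbox}; plus
#'   attributes \code{cores} (the detection tibble) and \code{pairing}.
#' @export
process_slide_pair <- function(he, ck, ann, magnification = "x10",
                               ex_params = extractor_params(),
                               reg_params = registration_params(),
                               base_mask_params = mask_params(),
                               vectors = hdab_stain_vectors()) {
  cores_he <- detect_cores(he, ex_params)
  cores_he <- apply_exclusions(cores_he, ann)
  cores_he <- case_grouping(cores_he, ann)
  cores_ck <- detect_cores(ck, ex_params)
  pairing <- pair_cores(cores_he, cores_ck,
                        max_centroid_dist_um = 500, mpp = he$mpp_x)
  kept <- cores_he[cores_he$kept & cores_he$region %in% pairing$pairs$he_region, ]
  out <- list()
  for (i in seq_len(nrow(kept))) {
    core <- kept[i, ]
    he_core <- extract_core(he, core, magnification, ex_params)
    ck_core <- extract_core(ck, core, magnification, ex_params)
    shift <- suppressWarnings(estimate_shift(he_core$raster, ck_core$raster,
                                             reg_params))
    ck_reg <- apply_shift(ck_core$raster, shift, fill = 1)
    mp <- mask_params_at(he_core$mpp, base_mask_params)
    mask <- ck_epithelium_mask(ck_reg, mp, vectors)
    ds <- he_core$downsample
    win <- c(core$x0, core$y0, core$x1, core$y1)
    # rasterize over the exact extracted window at the extraction level
    lev_win <- c(floor(win[1] / ds), floor(win[2] / ds),
                 floor(win[1] / ds) + ncol(he_core$raster),
                 floor(win[2] / ds) + nrow(he_core$raster))
    ben <- rasterize(ann, "benign", lev_win * ds, downsample = ds, mpp = he_core$mpp)
    ins <- rasterize(ann, "in_situ", lev_win * ds, downsample = ds, mpp = he_core$mpp)
    gt <- build_ground_truth(mask, ben, ins)
    gt$core_ref <- sprintf("%s_region%d", he$slide_id, core$region)
    out[[length(out) + 1L]] <- list(core_ref = gt$core_ref,
                                    he = he_core$raster, ck = ck_reg,
                                    mask = mask, gt = gt, shift = shift,
                                    case_id = core$case_id,
                                    bbox = win, mpp = he_core$mpp)
  }
  attr(out, "cores") <- cores_he
  attr(out, "pairing") <- pairing
  out
}

#' Patch a list of processed cores into sampling-ready records
#'
#' @param records output of \code{\link{process_slide_pair}}.
#' @param params \code{patch_params}.
#' @param second_pass run per-patch registration refinement against the CK
#'   raster.
#' @param reg_params \code{registration_params} for the refinement.
#' @return flat list of patch records (see \code{\link{make_patches}}).
#' @export
patches_from_records <- function(records, params = patch_params(),
                                 second_pass = FALSE,
                                 reg_params = registration_params()) {
  out <- list()
  for (rec in records) {
    p <- make_patches(rec$he, rec$gt, params,
                      ck_core = if (second_pass) rec$ck else NULL,
                      reg_params = reg_params, core_ref = rec$core_ref)
    out <- c(out, p)
  }
  out
}

#' Summarise patch records as a tibble
#' @param patches list of patch records.
#' @export
patch_index <- function(patches) {
  dplyr::bind_rows(lapply(patches, function(p)
    tibble::tibble(core_ref = as.character(p$core_ref %||% NA),
                   set = p$set, x0 = p$origin[1], y0 = p$origin[2],
                   padded = isTRUE(p$padded))))
}
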