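# TMA core detection and extraction: segment tissue on a low-resolution
# overview, flood-fill the regions, filter by size statistics, and cut
# per-core windows at the requested magnification; plus HE/CK core pairing
# for restained slide pairs.

#' TMA extractor parameters
#'
#' @param tissue_threshold a pixel is tissue if min(R, G, B) < this value on
#'   the 0..255 scale (white glass background is bright in all channels).
#' @param min_region_px overview regions strictly below this pixel count are
#'   removed as debris before the size statistics are computed.
#' @param max_rel_deviation regions whose area or equivalent diameter differs
#'   from the respective median by more than this fraction are excluded.
#' @param overview_level pyramid level used for detection; \code{NULL} picks
#'   the lowest-resolution level whose width is still >= 1024 (or the last
#'   level of a small pyramid).
#' @param target_magnification requested output magnification, e.g.
#'   \code{"x10"}; interpreted relative to \code{scan_magnification}.
#' @param scan_magnification magnification of level 0 (default "x40").
#' @return list of class \code{extractor_params}.
#' @export
extractor_params <- function(tissue_threshold = 220, min_region_px = 100L,
                             max_rel_deviation = 0.50, overview_level = NULL,
                             target_magnification = "x10",
                             scan_magnification = "x40") {
  stopifnot(max_rel_deviation > 0, max_rel_deviation < 1, min_region_px >= 1)
  structure(list(tissue_threshold = tissue_threshold,
                 min_region_px = as.integer(min_region_px),
                 max_rel_deviation = max_rel_deviation,
                 overview_level = overview_level,
                 target_magnification = target_magnification,
                 scan_magnification = scan_magnification),
            class = "extractor_params")
}

#' Numeric value of a magnification string like "x10"
#' @keywords internal
mag_value <- function(mag) {
  v <- suppressWarnings(as.numeric(sub("^[xX]", "", mag)))
  if (is.na(v) || v <= 0) stop("bad magnification: ", mag)
  v
}

#' Pick the detection overview level
#' @keywords internal
pick_overview_level <- function(slide, params) {
  if (!is.null(params$overview_level)) return(as.integer(params$overview_level))
  widths <- vapply(slide$levels, ncol, numeric(1))
  ok <- which(widths >= 1024)
  if (length(ok)) max(ok) else length(slide$levels)
}

#' Detect TMA cores on a slide overview
#'
#' Tissue is segmented by colour thresholding on a low-resolution pyramid
#' level; connected regions are labelled by flood fill (8-connectivity).
#' Regions below \code{min_region_px} overview pixels are removed as debris
#' first; the median area and median equivalent-circle diameter are computed
#' over the survivors, and any region deviating more than
#' \code{max_rel_deviation} from either median is excluded (merged or partial
#' cores). Survivors are returned sorted row-major by centroid.
#'
#' @param slide RGB \code{pyramidal_image}.
#' @param params \code{extractor_params}.
#' @return tibble with one row per detected region: bbox (level-0
#'   \code{x0,y0,x1,y1}), centroid (\code{cx,cy}, level 0), \code{area_px} and
#'   \code{diameter_px} at the overview level, \code{kept} and
#'   \code{exclusion_reason}. Rows with \code{kept == TRUE} are the cores.
#' @export
detect_cores <- function(slide, params = extractor_params()) {
  lev <- pick_overview_level(slide, params)
  ds <- slide$level_downsample[lev]
  ov <- slide$levels[[lev]]
  if (length(dim(ov)) == 3L) {
    mins <- pmin(ov[, , 1], ov[, , 2], ov[, , 3])
  } else mins <- ov
  tissue <- mins * 255 < params$tissue_threshold
  labs <- label_components(tissue, connectivity = 8L)
  n <- max(labs)
  if (n == 0L) {
    warning("no tissue regions detected")
    return(empty_core_tibble())
  }
  areas <- component_areas(labs)
  idx <- which(labs > 0L)
  rows <- ((idx - 1L) %% nrow(labs)) + 1L
  cols <- ((idx - 1L) %/% nrow(labs)) + 1L
  lab_v <- labs[idx]
  x0 <- tapply(cols, lab_v, min) - 1L
  x1 <- tapply(cols, lab_v, max)
  y0 <- tapply(rows, lab_v, min) - 1L
  y1 <- tapply(rows, lab_v, max)
  cx <- tapply(cols - 0.5, lab_v, mean)
  cy <- tapply(rows - 0.5, lab_v, mean)
  tb <- tibble::tibble(
    region = seq_len(n),
    area_px = as.numeric(areas),
    diameter_px = 2 * sqrt(areas / pi),
    x0 = as.numeric(x0) * ds, y0 = as.numeric(y0) * ds,
    x1 = as.numeric(x1) * ds, y1 = as.numeric(y1) * ds,
    cx = as.numeric(cx) * ds, cy = as.numeric(cy) * ds,
    overview_level = lev, overview_downsample = ds,
    slide_id = slide$slide_id, stain = slide$stain,
    kept = TRUE, exclusion_reason = NA_character_)

  small <- tb$area_px < params$min_region_px
  tb$kept[small] <- FALSE
  tb$exclusion_reason[small] <- "debris (< min_region_px)"
  surv <- tb[!small, ]
  if (!nrow(surv)) {
    warning("no regions after debris removal")
    return(tb)
  }
  med_a <- stats::median(surv$area_px)
  med_d <- stats::median(surv$diameter_px)
  dev_a <- abs(surv$area_px - med_a) / med_a
  dev_d <- abs(surv$diameter_px - med_d) / med_d
  out <- dev_a > params$max_rel_deviation | dev_d > params$max_rel_deviation
  tb$kept[tb$region %in% surv$region[out]] <- FALSE
  tb$exclusion_reason[tb$region %in% surv$region[out]] <-
    "size deviation (> max_rel_deviation from median)"
  kept <- tb[tb$kept, ]
  # row-major order by centroid: bin rows by median core diameter
  ord <- order(round(kept$cy / (med_d * ds)), kept$cx)
  dplyr::bind_rows(kept[ord, ], tb[!tb$kept, ])
}

empty_core_tibble <- function() {
  tibble::tibble(region = integer(), area_px = numeric(), diameter_px = numeric(),
                 x0 = numeric(), y0 = numeric(), x1 = numeric(), y1 = numeric(),
                 cx = numeric(), cy = numeric(), overview_level = integer(),
                 overview_downsample = numeric(), slide_id = character(),
                 stain = character(), kept = logical(),
                 exclusion_reason = character())
}

#' Extract one core's raster at a requested magnification
#'
#' The raster is cut from the pyramid level whose downsample equals
#' scan magnification / requested magnification; the bbox is padded by
#' \code{margin} level-0 pixels and clamped to the slide bounds.
#'
#' @param slide RGB \code{pyramidal_image}.
#' @param core one row of the \code{\link{detect_cores}} tibble (or a list
#'   with \code{x0,y0,x1,y1}).
#' @param magnification e.g. \code{"x10"}; must not exceed the scan
#'   magnification.
#' @param params \code{extractor_params} (for the scan magnification).
#' @param margin bbox padding in level-0 pixels.
#' @return list of class \code{core_region}: \code{raster}, \code{bbox}
#'   (level-0, possibly clamped), \code{downsample}, \code{mpp},
#'   \code{slide_id}, \code{stain}.
#' @export
extract_core <- function(slide, core, magnification = NULL,
                         params = extractor_params(), margin = 0) {
  mag <- magnification %||% params$target_magnification
  ds_target <- mag_value(params$scan_magnification) / mag_value(mag)
  if (ds_target < 1 - 1e-9)
    stop("requested magnification ", mag, " exceeds scan magnification ",
         params$scan_magnification)
  lev <- which.min(abs(slide$level_downsample - ds_target))
  if (abs(slide$level_downsample[lev] - ds_target) > 0.01 * ds_target)
    stop("no pyramid level matches downsample ", ds_target)
  ds <- slide$level_downsample[lev]
  sz <- slide_size(slide)
  bbox <- c(max(0, core$x0 - margin), max(0, core$y0 - margin),
            min(sz[1], core$x1 + margin), min(sz[2], core$y1 + margin))
  win <- c(floor(bbox[1] / ds), floor(bbox[2] / ds),
           ceiling(bbox[3] / ds), ceiling(bbox[4] / ds))
  lsz <- slide_size(slide, lev)
  win <- c(max(0, win[1]), max(0, win[2]), min(lsz[1], win[3]), min(lsz[2], win[4]))
  raster <- crop_window(slide$levels[[lev]], win)
  structure(list(raster = raster, bbox = win * ds, level = lev, downsample = ds,
                 mpp = level_mpp(slide, lev), slide_id = slide$slide_id,
                 stain = slide$stain,
                 centroid = c(core$cx, core$cy)),
            class = "core_region")
}

#' Pair HE and CK cores by centroid proximity
#'
#' Both detections come from the same physical (restained) slide, so level-0
#' coordinates are comparable. Greedy nearest-centroid matching: the globally
#' closest remaining pair is matched until no pair is within
#' \code{max_centroid_dist_um}.
#'
#' @param he,ck core tibbles from \code{\link{detect_cores}} (kept rows are
#'   used).
#' @param max_centroid_dist_um pairing gate in microns (default 500).
#' @param mpp microns per level-0 pixel used to convert the gate.
#' @return list with \code{pairs} (tibble: he_region, ck_region, dist_um) and
#'   \code{unmatched_he}, \code{unmatched_ck} (region ids).
#' @export
pair_cores <- function(he, ck, max_centroid_dist_um = 500, mpp = 1) {
  he <- he[he$kept, ]; ck <- ck[ck$kept, ]
  if (!nrow(he) || !nrow(ck)) {
    return(list(pairs = tibble::tibble(he_region = integer(), ck_region = integer(),
                                       dist_um = numeric()),
                unmatched_he = he$region, unmatched_ck = ck$region))
  }
  d <- outer(seq_len(nrow(he)), seq_len(nrow(ck)), function(i, j)
    sqrt((he$cx[i] - ck$cx[j])^2 + (he$cy[i] - ck$cy[j])^2) * mpp)
  pairs <- list()
  used_he <- logical(nrow(he)); used_ck <- logical(nrow(ck))
  repeat {
    d_act <- d
    d_act[used_he, ] <- Inf; d_act[, used_ck] <- Inf
    m <- which.min(d_act)
    if (!length(m) || !is.finite(d_act[m]) || d_act[m] > max_centroid_dist_um) break
    i <- ((m - 1L) %% nrow(he)) + 1L
    j <- ((m - 1L) %/% nrow(he)) + 1L
    pairs[[length(pairs) + 1L]] <-
      tibble::tibble(he_region = he$region[i], ck_region = ck$region[j],
                     dist_um = d_act[m])
    used_he[i] <- TRUE; used_ck[j] <- TRUE
  }
  list(pairs = if (length(pairs)) dplyr::bind_rows(pairs) else
         tibble::tibble(he_region = integer(), ck_region = integer(),
                        dist_um = numeric()),
       unmatched_he = he$region[!used_he],
       unmatched_ck = ck$region[!used_ck])
}
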