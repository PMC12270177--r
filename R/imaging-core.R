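# Pyramidal image data model, TIFF I/O, GeoJSON annotation ingestion and
# annotation rasterization. Every other module goes through the containers
# defined here.

#' Construct a pyramidal image
#'
#' The common carrier for slides, masks and annotation rasters: a list of
#' progressively downsampled rasters plus resolution metadata. Level 0 is
#' full resolution with downsample 1.
#'
#' @param levels list of rasters (matrix, or [H, W, 3] array for RGB), finest
#'   first.
#' @param level_downsample numeric vector of per-level downsample factors
#'   relative to level 0; strictly increasing, first element 1.
#' @param mpp_x,mpp_y microns per pixel at level 0 (both > 0).
#' @param slide_id opaque identifier.
#' @param stain one of \code{"HE"}, \code{"CK"}, \code{"MASK"}.
#' @return object of class \code{pyramidal_image}.
#' @export
pyramidal_image <- function(levels, level_downsample = NULL,
                            mpp_x, mpp_y = mpp_x,
                            slide_id = "slide", stain = c("HE", "CK", "MASK")) {
  stain <- match.arg(stain)
  stopifnot(is.list(levels), length(levels) >= 1L)
  if (is.null(level_downsample)) {
    w0 <- ncol(levels[[1]])
    level_downsample <- vapply(levels, function(l) w0 / ncol(l), numeric(1))
  }
  stopifnot(length(level_downsample) == length(levels))
  if (abs(level_downsample[1] - 1) > 1e-9)
    stop("level 0 must have downsample 1")
  if (any(diff(level_downsample) <= 0))
    stop("level_downsample must be strictly increasing")
  if (!(mpp_x > 0 && mpp_y > 0)) stop("mpp values must be > 0")
  for (k in seq_along(levels)) {
    d <- level_downsample[k]
    if (abs(ncol(levels[[k]]) - ncol(levels[[1]]) / d) > 1 ||
        abs(nrow(levels[[k]]) - nrow(levels[[1]]) / d) > 1)
      stop("level ", k - 1L, " size inconsistent with its downsample")
  }
  structure(list(levels = levels,
                 level_downsample = as.numeric(level_downsample),
                 mpp_x = mpp_x, mpp_y = mpp_y,
                 slide_id = slide_id, stain = stain),
            class = "pyramidal_image")
}

#' @export
print.pyramidal_image <- function(x, ...) {
  cat(sprintf("<pyramidal_image '%s' stain=%s  %d levels  %dx%d @ %.4f um/px>\n",
              x$slide_id, x$stain, length(x$levels),
              ncol(x$levels[[1]]), nrow(x$levels[[1]]), x$mpp_x))
  invisible(x)
}

#' Slide width/height at a level (x = columns, y = rows)
#' @keywords internal
slide_size <- function(slide, level = 1L) {
  l <- slide$levels[[level]]
  c(ncol(l), nrow(l))
}

#' Microns per pixel at a given pyramid level
#' @keywords internal
level_mpp <- function(slide, level) slide$mpp_x * slide$level_downsample[level]

#' Pyramid level whose resolution is closest to a target mpp
#' @keywords internal
closest_level <- function(slide, target_mpp) {
  which.min(abs(slide$mpp_x * slide$level_downsample - target_mpp))
}

#' Write a pyramidal image as a multi-page TIFF
#'
#' One TIFF page per pyramid level, finest first, plus a JSON sidecar
#' (\code{<path>.json}) carrying mpp, downsample factors, slide id and stain,
#' which the TIFF container in use cannot store losslessly.
#'
#' @param img \code{pyramidal_image}.
#' @param path output file path (".tif"/".tiff").
#' @param bits bits per sample (8 or 16).
#' @return \code{path}, invisibly.
#' @export
write_pyramidal <- function(img, path, bits = 8L) {
  pages <- lapply(img$levels, function(l) {
    if (bits == 8L) round(l * 255) / 255 else l
  })
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits), reduce = FALSE)
  meta <- list(mpp_x = img$mpp_x, mpp_y = img$mpp_y,
               level_downsample = img$level_downsample,
               slide_id = img$slide_id, stain = img$stain)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pyramidal (multi-page) TIFF
#'
#' Reads all pages of a tiled/multi-page TIFF as pyramid levels. Resolution
#' metadata is taken from the JSON sidecar when present; otherwise
#' \code{default_mpp} is used with a warning. A single-level file is accepted
#' and additional levels are synthesized by repeated 2x block-mean decimation.
#'
#' @param path TIFF file path.
#' @param default_mpp fallback microns per pixel when no metadata is found
#'   (default 0.3448, the canonical mask-creation resolution).
#' @param min_levels synthesize levels by 2x decimation until this many exist.
#' @return \code{pyramidal_image}.
#' @export
read_pyramidal <- function(path, default_mpp = 0.3448, min_levels = 1L) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("failed to read TIFF '", path, "': ",
                                             conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    mpp_x <- meta$mpp_x; mpp_y <- meta$mpp_y
    ds <- meta$level_downsample
    slide_id <- meta$slide_id %||% basename(path)
    stain <- meta$stain %||% "HE"
  } else {
    warning("no resolution metadata for '", path, "'; assuming ",
            default_mpp, " um/px")
    mpp_x <- default_mpp; mpp_y <- default_mpp
    ds <- ncol(pages[[1]]) / vapply(pages, ncol, numeric(1))
    slide_id <- basename(path); stain <- "HE"
  }
  pages <- lapply(pages, unclass)
  while (length(pages) < min_levels) {
    pages[[length(pages) + 1L]] <- block_mean(pages[[length(pages)]], 2L)
    ds <- c(ds, ds[length(ds)] * 2)
  }
  pyramidal_image(pages, ds, mpp_x, mpp_y, slide_id = slide_id, stain = stain)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct an annotation set
#'
#' @param polygons list of entries with \code{$geometry} (a polygon: list with
#'   \code{outer} ring and \code{holes}), \code{$label} (one of "benign",
#'   "in_situ", "exclude_core", "case_group") and optional \code{$case_id}.
#' @return object of class \code{annotation_set}.
#' @export
annotation_set <- function(polygons = list()) {
  labs <- vapply(polygons, function(p) p$label, character(1))
  bad <- setdiff(labs, c("benign", "in_situ", "exclude_core", "case_group"))
  if (length(bad)) stop("unknown annotation labels: ", paste(bad, collapse = ", "))
  structure(list(polygons = polygons), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  labs <- vapply(x$polygons, function(p) p$label, character(1))
  cat("<annotation_set ", length(x$polygons), " polygons: ",
      paste(sprintf("%s=%d", names(table(labs)), table(labs)), collapse = " "),
      ">\n", sep = "")
  invisible(x)
}

# Default mapping from free-text annotation class names (QuPath dialect) to
# the internal label enum; config-overridable in read_annotations().
default_label_map <- c(
  "benign" = "benign", "Benign" = "benign",
  "in situ" = "in_situ", "In situ" = "in_situ", "insitu" = "in_situ",
  "DCIS" = "in_situ", "in_situ" = "in_situ",
  "exclude" = "exclude_core", "Exclude" = "exclude_core",
  "exclude_core" = "exclude_core", "Remove" = "exclude_core",
  "case" = "case_group", "Case" = "case_group", "case_group" = "case_group"
)

#' Read a QuPath-dialect GeoJSON annotation file
#'
#' Expects a FeatureCollection whose features carry the class name under
#' \code{properties.classification.name} (with \code{properties.name} and a
#' bare \code{properties.classification} string accepted as fallbacks).
#' Polygon exteriors are clipped to the slide bounds; interior rings become
#' holes. Self-intersecting rings that cannot be repaired are rejected with
#' their feature index. Unknown class names are collected and reported in the
#' \code{unknown_labels} attribute rather than silently dropped.
#'
#' @param path GeoJSON file.
#' @param slide \code{pyramidal_image} providing the clipping bounds.
#' @param label_map named character vector mapping class names to the label
#'   enum; merged over the built-in defaults.
#' @return \code{annotation_set}; polygons carry level-0 pixel coordinates.
#' @export
read_annotations <- function(path, slide, label_map = NULL) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  lm <- default_label_map
  if (!is.null(label_map)) lm[names(label_map)] <- label_map
  sz <- slide_size(slide)
  rect <- c(0, 0, sz[1], sz[2])
  polys <- list()
  unknown <- character(0)
  for (fi in seq_along(gj$features)) {
    f <- gj$features[[fi]]
    props <- f$properties %||% list()
    cls <- props$classification
    name <- if (is.list(cls)) cls$name else cls
    name <- name %||% props$name
    if (is.null(name)) { unknown <- c(unknown, sprintf("<feature %d: unlabelled>", fi)); next }
    label <- unname(lm[name])
    if (is.na(label)) { unknown <- c(unknown, name); next }
    case_id <- props$case_id %||% props$case %||% NULL
    geom <- f$geometry
    rings_list <- switch(geom$type,
      "Polygon" = list(geom$coordinates),
      "MultiPolygon" = geom$coordinates,
      stop("feature ", fi, ": unsupported geometry type ", geom$type))
    for (rings in rings_list) {
      mats <- lapply(rings, function(r)
        do.call(rbind, lapply(r, function(pt) c(pt[[1]], pt[[2]]))))
      if (!all(is.finite(unlist(mats))))
        stop("feature ", fi, ": non-finite coordinates")
      outer <- repair_ring(mats[[1]], fi)
      outer <- clip_ring_rect(outer, rect)
      if (nrow(outer) < 3L) next
      holes <- lapply(mats[-1], function(h) clip_ring_rect(repair_ring(h, fi), rect))
      holes <- holes[vapply(holes, nrow, integer(1)) >= 3L]
      polys[[length(polys) + 1L]] <-
        list(geometry = list(outer = outer, holes = holes),
             label = label, case_id = case_id)
    }
  }
  out <- annotation_set(polys)
  attr(out, "unknown_labels") <- unique(unknown)
  out
}

#' Reject (or trivially repair) an invalid ring
#'
#' Drops exactly-duplicated consecutive vertices (the zero-buffer equivalent
#' for the degeneracies QuPath exports produce); rings still shorter than 3
#' vertices are rejected with their feature index.
#' @keywords internal
repair_ring <- function(ring, feature_index) {
  if (nrow(ring) >= 2L && all(ring[1, ] == ring[nrow(ring), ]))
    ring <- ring[-nrow(ring), , drop = FALSE]
  dup <- c(FALSE, rowSums(abs(diff(ring))) == 0)
  ring <- ring[!dup, , drop = FALSE]
  if (nrow(ring) < 3L)
    stop("feature ", feature_index, ": degenerate ring (fewer than 3 distinct vertices)")
  ring
}

#' Rasterize annotations of one label over a window
#'
#' A pixel is 1 iff its centre lies inside a polygon of the requested label;
#' polygon holes rasterize as 0. An empty annotation set yields an all-zero
#' mask.
#'
#' @param ann \code{annotation_set} with level-0 coordinates.
#' @param label label to rasterize.
#' @param window c(x0, y0, x1, y1), 0-based half-open, level-0 coordinates.
#' @param level pyramid level at which to rasterize (1-based index into the
#'   slide's downsample table is not needed: pass the downsample factor).
#' @param downsample downsample factor of the output raster relative to
#'   level 0 (default 1).
#' @param mpp microns per pixel of the output raster, stored on the result.
#' @return \code{binary_mask}.
#' @export
rasterize <- function(ann, label, window, downsample = 1, mpp = NA_real_) {
  polys <- lapply(Filter(function(p) p$label == label, ann$polygons),
                  function(p) p$geometry)
  if (downsample != 1) {
    polys <- lapply(polys, function(g) {
      g$outer <- g$outer / downsample
      g$holes <- lapply(g$holes, function(h) h / downsample)
      g
    })
    window <- window / downsample
  }
  m <- rasterize_polygons(polys, window)
  binary_mask(m, origin = c(window[1], window[2]) * downsample,
              level_downsample = downsample, mpp = mpp)
}

#' Construct a binary mask
#'
#' @param raster 0/1 matrix.
#' @param origin level-0 (x, y) offset of the top-left pixel.
#' @param level_downsample downsample of the raster relative to level 0.
#' @param mpp microns per pixel of this raster.
#' @export
binary_mask <- function(raster, origin = c(0, 0), level_downsample = 1,
                        mpp = NA_real_) {
  stopifnot(all(raster %in% c(0L, 1L)))
  storage.mode(raster) <- "integer"
  structure(list(raster = raster, origin = origin,
                 level_downsample = level_downsample, mpp = mpp),
            class = "binary_mask")
}

#' Construct a 4-class label map
#'
#' Classes: 0 background, 1 invasive, 2 benign, 3 in-situ.
#' @inheritParams binary_mask
#' @export
label_map <- function(raster, origin = c(0, 0), level_downsample = 1,
                      mpp = NA_real_) {
  stopifnot(all(raster %in% 0:3))
  storage.mode(raster) <- "integer"
  structure(list(raster = raster, origin = origin,
                 level_downsample = level_downsample, mpp = mpp),
            class = "label_map")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %dx%d, %d positive, mpp=%.4g>\n",
              ncol(x$raster), nrow(x$raster), sum(x$raster), x$mpp))
  invisible(x)
}

#' @export
print.label_map <- function(x, ...) {
  tab <- tabulate(x$raster + 1L, 4L)
  cat(sprintf("<label_map %dx%d  bg=%d inv=%d ben=%d ins=%d>\n",
              ncol(x$raster), nrow(x$raster), tab[1], tab[2], tab[3], tab[4]))
  invisible(x)
}
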