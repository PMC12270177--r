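# Four-class ground truth: combine the cleaned DAB epithelium mask with
# benign / in-situ annotation rasters; core exclusions and case grouping.
#
# Classes: 0 background, 1 invasive, 2 benign, 3 in-situ. The invasive class
# is what remains of CK-stained epithelium after subtracting the manually
# annotated benign and in-situ areas.

GT_CLASSES <- c(background = 0L, invasive = 1L, benign = 2L, in_situ = 3L)

#' Build the four-class ground truth for one core
#'
#' Pixel rules (in-situ takes precedence over benign where annotations
#' overlap): in_situ = dab & insitu; benign = dab & benign & !insitu;
#' invasive = dab & !benign & !insitu; background = !dab.
#'
#' @param dab cleaned epithelium \code{binary_mask} (registered into the HE
#'   frame).
#' @param benign,insitu annotation \code{binary_mask}s of identical size.
#' @return object of class \code{ground_truth}: \code{labels} (a
#'   \code{label_map}) and \code{onehot} ([H, W, 4] 0/1 array).
#' @export
build_ground_truth <- function(dab, benign, insitu) {
  d <- dab$raster; b <- benign$raster; s <- insitu$raster
  if (!all(dim(d) == dim(b)) || !all(dim(d) == dim(s)))
    stop("mask size mismatch: dab ", paste(dim(d), collapse = "x"),
         ", benign ", paste(dim(b), collapse = "x"),
         ", insitu ", paste(dim(s), collapse = "x"))
  lab <- matrix(0L, nrow(d), ncol(d))
  lab[d == 1L] <- 1L                       # invasive by default where epithelium
  lab[d == 1L & b == 1L] <- 2L             # benign where annotated benign
  lab[d == 1L & s == 1L] <- 3L             # in-situ wins over benign
  ground_truth(label_map(lab, origin = dab$origin,
                         level_downsample = dab$level_downsample,
                         mpp = dab$mpp))
}

#' Wrap a label map as a ground-truth object with its one-hot view
#' @param labels \code{label_map} over {0, 1, 2, 3}.
#' @param core_ref optional core identifier.
#' @export
ground_truth <- function(labels, core_ref = NA_character_) {
  structure(list(labels = labels, onehot = onehot_encode(labels$raster),
                 core_ref = core_ref, excluded = FALSE,
                 exclusion_reason = NA_character_),
            class = "ground_truth")
}

#' One-hot encode a {0..K-1} label raster
#' @param lab integer matrix.
#' @param n_classes number of planes (default 4).
#' @return [H, W, n_classes] 0/1 array; planes partition every pixel.
#' @export
onehot_encode <- function(lab, n_classes = 4L) {
  out <- array(0L, c(nrow(lab), ncol(lab), n_classes))
  for (k in seq_len(n_classes)) out[, , k] <- (lab == (k - 1L)) * 1L
  out
}

#' Collapse a one-hot stack back to labels (argmax, ties to lower class)
#' @keywords internal
onehot_decode <- function(onehot) {
  d <- dim(onehot)
  m <- matrix(onehot, d[1] * d[2], d[3])
  matrix(max.col(m, ties.method = "first") - 1L, d[1], d[2])
}

#' @export
print.ground_truth <- function(x, ...) {
  print(x$labels)
  invisible(x)
}

#' Partition cores into kept and excluded by exclusion annotations
#'
#' A core is excluded iff its centroid falls inside a polygon labelled
#' \code{exclude_core} (default), or — in \code{"overlap"} mode — if the
#' fraction of its bbox covered by exclusion polygons exceeds
#' \code{overlap_threshold}.
#'
#' @param cores tibble from \code{\link{detect_cores}} (kept rows are
#'   tested).
#' @param ann \code{annotation_set}.
#' @param mode \code{"centroid"} or \code{"overlap"}.
#' @param overlap_threshold fraction for overlap mode (default 0.5).
#' @return the cores tibble with updated \code{kept} and
#'   \code{exclusion_reason} columns.
#' @export
apply_exclusions <- function(cores, ann, mode = c("centroid", "overlap"),
                             overlap_threshold = 0.5) {
  mode <- match.arg(mode)
  polys <- lapply(Filter(function(p) p$label == "exclude_core", ann$polygons),
                  function(p) p$geometry)
  if (!length(polys)) return(cores)
  act <- which(cores$kept)
  for (i in act) {
    excl <- FALSE
    if (mode == "centroid") {
      for (g in polys)
        if (points_in_polygon(cores$cx[i], cores$cy[i], g)) { excl <- TRUE; break }
    } else {
      win <- c(cores$x0[i], cores$y0[i], cores$x1[i], cores$y1[i])
      m <- rasterize_polygons(polys, win)
      excl <- mean(m) > overlap_threshold
    }
    if (excl) {
      cores$kept[i] <- FALSE
      cores$exclusion_reason[i] <- "tagged for exclusion (insufficient staining)"
    }
  }
  cores
}

#' Assign cores to cases via case-group annotation polygons
#'
#' A core inherits the \code{case_id} of the case polygon containing its
#' centroid; cores outside every case polygon become singleton cases named
#' after their region id. A core whose centroid lies inside two case polygons
#' is an annotation error and is reported.
#'
#' @param cores tibble from \code{\link{detect_cores}}.
#' @param ann \code{annotation_set} with \code{case_group} polygons carrying
#'   \code{case_id}.
#' @return the cores tibble with a \code{case_id} column.
#' @export
case_grouping <- function(cores, ann) {
  polys <- Filter(function(p) p$label == "case_group", ann$polygons)
  case_id <- rep(NA_character_, nrow(cores))
  for (i in seq_len(nrow(cores))) {
    hits <- character(0)
    for (p in polys) {
      if (points_in_polygon(cores$cx[i], cores$cy[i], p$geometry))
        hits <- c(hits, p$case_id %||% "<unnamed>")
    }
    if (length(unique(hits)) > 1L)
      stop("core region ", cores$region[i], " lies inside ",
           length(unique(hits)), " case polygons: ",
           paste(unique(hits), collapse = ", "))
    if (length(hits)) case_id[i] <- hits[1]
  }
  singleton <- is.na(case_id)
  case_id[singleton] <- sprintf("singleton_%s_%d",
                                cores$slide_id[singleton], cores$region[singleton])
  cores$case_id <- case_id
  cores
}
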