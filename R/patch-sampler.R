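# Tiling of registered cores into training patches, tissue filtering,
# benign / in-situ / invasive set assignment, balanced sampling and
# augmentation.

#' Patch parameters
#'
#' @param patch_size training/inference tile side in pixels (default 1024).
#' @param overlap_fraction training tiling overlap: stride =
#'   round(patch_size * (1 - overlap_fraction)) (default 0.25 => stride 768).
#' @param min_tissue_fraction patches with a lower tissue fraction are
#'   excluded from training (default 0.25).
#' @param inference_overlap_fraction overlap used by tiled inference
#'   (default 0.30).
#' @param tissue_threshold colourimetric tissue rule, same convention as the
#'   core extractor: tissue iff min(R, G, B)*255 < threshold.
#' @export
patch_params <- function(patch_size = 1024L, overlap_fraction = 0.25,
                         min_tissue_fraction = 0.25,
                         inference_overlap_fraction = 0.30,
                         tissue_threshold = 220) {
  stopifnot(patch_size >= 64, overlap_fraction >= 0, overlap_fraction < 1,
            inference_overlap_fraction >= 0, inference_overlap_fraction < 1)
  structure(list(patch_size = as.integer(patch_size),
                 overlap_fraction = overlap_fraction,
                 min_tissue_fraction = min_tissue_fraction,
                 inference_overlap_fraction = inference_overlap_fraction,
                 tissue_threshold = tissue_threshold),
            class = "patch_params")
}

#' Enumerate aligned tile windows over a core
#'
#' Windows of side \code{patch_size} starting at 0 and stepping by
#' stride = round(patch_size * (1 - overlap)); the final window on each axis
#' is clamped so it ends at the core edge (no padding beyond the image), and
#' duplicate windows are deduplicated. A core smaller than the patch in an
#' axis yields a single window flagged \code{padded}; the caller pads with
#' background.
#'
#' @param core_dim c(height, width) of the core raster, or the raster itself.
#' @param params \code{patch_params}.
#' @param overlap overlap fraction override (e.g. the inference overlap).
#' @return tibble of 0-based half-open windows: x0, y0, x1, y1, padded.
#' @export
tile_core <- function(core_dim, params = patch_params(), overlap = NULL) {
  if (!is.null(dim(core_dim))) core_dim <- dim(core_dim)[1:2]
  h <- core_dim[1]; w <- core_dim[2]
  ps <- params$patch_size
  ov <- overlap %||% params$overlap_fraction
  stride <- max(1L, as.integer(round(ps * (1 - ov))))
  axis_starts <- function(n) {
    if (n <= ps) return(list(starts = 0L, padded = n < ps))
    s <- seq.int(0L, n - 1L, by = stride)
    s <- s[s < n]            # window starts
    s <- pmin(s, n - ps)     # clamp last windows to end at the edge
    list(starts = unique(s), padded = FALSE)
  }
  xs <- axis_starts(w); ys <- axis_starts(h)
  grid <- expand.grid(x0 = xs$starts, y0 = ys$starts)
  tibble::tibble(x0 = as.integer(grid$x0), y0 = as.integer(grid$y0),
                 x1 = as.integer(pmin(grid$x0 + ps, w)),
                 y1 = as.integer(pmin(grid$y0 + ps, h)),
                 padded = xs$padded || ys$padded)
}

#' Fraction of tissue pixels in an HE patch
#'
#' Same colourimetric rule as core detection: a pixel is tissue iff
#' min(R, G, B) * 255 < threshold.
#' @param he_patch [H, W, 3] array in [0, 1] (or grayscale matrix).
#' @param params \code{patch_params}.
#' @export
tissue_fraction <- function(he_patch, params = patch_params()) {
  mins <- if (length(dim(he_patch)) == 3L)
    pmin(he_patch[, , 1], he_patch[, , 2], he_patch[, , 3]) else he_patch
  mean(mins * 255 < params$tissue_threshold)
}

#' Assign a patch to the benign / in-situ / invasive sampling set
#'
#' The patch joins the in-situ set if it contains any in-situ pixel; else the
#' benign set if it contains any benign pixel; else the invasive set (even
#' when it contains no invasive pixel — the literal assignment rule).
#'
#' @param onehot_patch [H, W, 4] one-hot ground truth.
#' @return \code{"in_situ"}, \code{"benign"} or \code{"invasive"}.
#' @export
assign_set <- function(onehot_patch) {
  if (any(onehot_patch[, , 4] == 1L)) return("in_situ")
  if (any(onehot_patch[, , 3] == 1L)) return("benign")
  "invasive"
}

#' Cut a core pair into filtered, set-assigned patch records
#'
#' Tiles the HE core, drops patches under the tissue threshold, optionally
#' refines registration per patch against the CK core, and assigns each
#' surviving patch to its sampling set.
#'
#' @param he_core [H, W, 3] HE raster.
#' @param gt \code{ground_truth} aligned with the HE core.
#' @param params \code{patch_params}.
#' @param ck_core optional CK raster for second-pass patch registration; when
#'   given, the ground-truth patch is shifted by the refined estimate.
#' @param reg_params \code{registration_params} for the second pass.
#' @param core_ref core identifier stored on the records.
#' @return list of patch records: \code{he}, \code{onehot}, \code{set},
#'   \code{origin}, \code{core_ref}.
#' @export
make_patches <- function(he_core, gt, params = patch_params(), ck_core = NULL,
                         reg_params = registration_params(), core_ref = NA) {
  wins <- tile_core(dim(he_core)[1:2], params)
  ps <- params$patch_size
  out <- list()
  for (i in seq_len(nrow(wins))) {
    win <- c(wins$x0[i], wins$y0[i], wins$x1[i], wins$y1[i])
    he <- crop_window(he_core, win)
    oh <- crop_window(gt$onehot, win)
    if (wins$padded[i]) {
      he_p <- array(1, c(ps, ps, 3))
      he_p[seq_len(dim(he)[1]), seq_len(dim(he)[2]), ] <- he
      oh_p <- array(0L, c(ps, ps, 4)); oh_p[, , 1] <- 1L
      oh_p[seq_len(dim(oh)[1]), seq_len(dim(oh)[2]), ] <- oh
      he <- he_p; oh <- oh_p
    }
    if (tissue_fraction(he, params) < params$min_tissue_fraction) next
    if (!is.null(ck_core)) {
      ck <- crop_window(ck_core, win)
      s <- suppressWarnings(register_patch_pair(he, ck, reg_params))
      if (s$valid && (s$dx != 0L || s$dy != 0L)) {
        lab <- apply_shift(onehot_decode(oh), s, fill = 0L)
        oh <- onehot_encode(lab)
      }
    }
    out[[length(out) + 1L]] <- list(he = he, onehot = oh, set = assign_set(oh),
                                    origin = c(win[1], win[2]),
                                    core_ref = core_ref,
                                    padded = wins$padded[i])
  }
  out
}

#' Balanced sampler over the three patch sets
#'
#' Each draw picks one of the nonempty sets uniformly, then a patch uniformly
#' within it, with replacement; the stream is fully reproducible from the
#' RNG state. Empty sets renormalize the set probabilities with a warning;
#' all-empty input is an error.
#'
#' @param patches list of patch records from \code{\link{make_patches}}.
#' @return function \code{(n)} returning \code{n} sampled patch records.
#' @export
balanced_sampler <- function(patches) {
  sets <- vapply(patches, function(p) p$set, character(1))
  by_set <- split(seq_along(patches), factor(sets, c("benign", "in_situ", "invasive")))
  nonempty <- names(by_set)[vapply(by_set, length, integer(1)) > 0L]
  if (!length(nonempty)) stop("all patch sets are empty")
  if (length(nonempty) < 3L)
    warning("empty patch set(s): ",
            paste(setdiff(c("benign", "in_situ", "invasive"), nonempty),
                  collapse = ", "), "; renormalizing")
  function(n = 1L) {
    chosen <- sample(nonempty, n, replace = TRUE)
    lapply(chosen, function(s) {
      idx <- by_set[[s]]
      patches[[idx[sample.int(length(idx), 1L)]]]
    })
  }
}

#' Augmentation configuration
#'
#' Techniques and enable-probabilities follow the training recipe: each of
#' flip, 90-degree rotation, brightness, hue, saturation and shift is enabled
#' independently with probability 0.5 per patch, blur with probability 0.1.
#' Magnitudes are package defaults.
#'
#' @param enable_prob named numeric vector of per-technique probabilities.
#' @param brightness_delta,hue_delta,saturation_delta,shift_max_px,blur_sigma_range
#'   technique magnitudes.
#' @export
augment_config <- function(enable_prob = c(flip = 0.5, rot90 = 0.5,
                                           brightness = 0.5, hue = 0.5,
                                           saturation = 0.5, shift = 0.5,
                                           blur = 0.1),
                           brightness_delta = 0.2, hue_delta = 0.05,
                           saturation_delta = 0.3, shift_max_px = 32L,
                           blur_sigma_range = c(0.5, 2)) {
  stopifnot(all(enable_prob >= 0 & enable_prob <= 1))
  structure(list(enable_prob = enable_prob, brightness_delta = brightness_delta,
                 hue_delta = hue_delta, saturation_delta = saturation_delta,
                 shift_max_px = as.integer(shift_max_px),
                 blur_sigma_range = blur_sigma_range),
            class = "augment_config")
}

rot90_raster <- function(x, k) {
  k <- k %% 4L
  if (k == 0L) return(x)
  rot1 <- function(m) t(m)[, nrow(m):1, drop = FALSE]  # 90 deg counter-clockwise? keep consistent
  one <- function(m) { for (i in seq_len(k)) m <- rot1(m); m }
  if (length(dim(x)) == 3L) {
    slabs <- lapply(seq_len(dim(x)[3]), function(c) one(x[, , c]))
    out <- array(0, c(dim(slabs[[1]]), length(slabs)))
    for (c in seq_along(slabs)) out[, , c] <- slabs[[c]]
    if (is.integer(x)) storage.mode(out) <- "integer"
    out
  } else one(x)
}

flip_raster <- function(x, axis) {
  if (length(dim(x)) == 3L) {
    if (axis == "h") x[, ncol(x):1, , drop = FALSE] else x[nrow(x):1, , , drop = FALSE]
  } else {
    if (axis == "h") x[, ncol(x):1, drop = FALSE] else x[nrow(x):1, , drop = FALSE]
  }
}

#' Augment one patch record
#'
#' Each technique is enabled independently (Bernoulli with its configured
#' probability). Spatial techniques (flip, rot90, shift) are applied
#' identically to the image and the one-hot ground truth (nearest-neighbour
#' semantics for labels; shift vacates into background), photometric ones
#' (brightness, hue, saturation, blur) to the image only. The one-hot stack
#' remains a valid partition.
#'
#' @param patch patch record (\code{he}, \code{onehot}, ...).
#' @param cfg \code{augment_config}.
#' @return augmented patch record.
#' @export
augment <- function(patch, cfg = augment_config()) {
  on <- stats::runif(length(cfg$enable_prob)) < cfg$enable_prob
  names(on) <- names(cfg$enable_prob)
  he <- patch$he; oh <- patch$onehot
  if (on[["flip"]]) {
    ax <- sample(c("h", "v"), 1L)
    he <- flip_raster(he, ax); oh <- flip_raster(oh, ax)
  }
  if (on[["rot90"]]) {
    k <- sample.int(3L, 1L)
    he <- rot90_raster(he, k); oh <- rot90_raster(oh, k)
  }
  if (on[["shift"]]) {
    s <- sample(seq(-cfg$shift_max_px, cfg$shift_max_px), 2L, replace = TRUE)
    he <- apply_shift(he, s, fill = 1)
    lab <- apply_shift(onehot_decode(oh), s, fill = 0L)
    oh <- onehot_encode(lab)
  }
  if (on[["brightness"]]) {
    he <- pmin(pmax(he + stats::runif(1, -cfg$brightness_delta,
                                      cfg$brightness_delta), 0), 1)
  }
  if (on[["hue"]] || on[["saturation"]]) {
    d <- dim(he)
    hsv <- grDevices::rgb2hsv(rbind(as.vector(he[, , 1]),
                                    as.vector(he[, , 2]),
                                    as.vector(he[, , 3])) * 255, maxColorValue = 255)
    if (on[["hue"]]) hsv[1, ] <- (hsv[1, ] + stats::runif(1, -cfg$hue_delta, cfg$hue_delta)) %% 1
    if (on[["saturation"]])
      hsv[2, ] <- pmin(1, pmax(0, hsv[2, ] * (1 + stats::runif(1, -cfg$saturation_delta,
                                                               cfg$saturation_delta))))
    rgb <- grDevices::hsv(hsv[1, ], hsv[2, ], hsv[3, ])
    cm <- grDevices::col2rgb(rgb) / 255
    he <- array(c(cm[1, ], cm[2, ], cm[3, ]), d)
  }
  if (on[["blur"]]) {
    sg <- stats::runif(1, cfg$blur_sigma_range[1], cfg$blur_sigma_range[2])
    for (c in 1:3) he[, , c] <- gaussian_blur(he[, , c], sg)
  }
  he <- pmin(pmax(he, 0), 1)
  patch$he <- he; patch$onehot <- oh
  patch$set <- assign_set(oh)
  patch
}

#' Which augmentation techniques a single Bernoulli draw enables
#'
#' Exposed so enablement frequencies can be measured without paying for the
#' image transforms.
#' @param cfg \code{augment_config}.
#' @param n number of draws.
#' @return logical matrix n x technique.
#' @export
draw_augment_enables <- function(cfg = augment_config(), n = 1L) {
  p <- cfg$enable_prob
  m <- matrix(stats::runif(n * length(p)) < rep(p, each = n), n, length(p))
  colnames(m) <- names(p)
  m
}
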