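# Synthetic paired HE/CK TMA slides with known ground truth.
#
# The generator emulates the data the pipeline was designed for: a grid of
# roughly circular tissue cores on bright glass, each containing invasive
# nests (solid irregular blobs), benign glands (epithelial rings around an
# empty lumen) and in-situ ducts (large epithelium-filled circles); the CK
# rendering carries DAB-brown cytoplasmic staining with unstained nuclear
# holes, the HE rendering shares the geometry with an H&E palette, and the
# CK image is rigidly translated against the HE image. Optional artifacts
# reproduce the common failure modes: debris specks, merged cores, missing
# cores, background DAB haze and false-negative staining.

#' Synthetic slide-pair configuration
#'
#' Defaults describe the emulated study material: a 3 x 3 core grid with
#' 450 um core radius (about 0.9 mm diameter cores) at 2 um/px level-0
#' resolution, epithelial DAB optical densities 0.5-0.9, nuclear holes of
#' 20-120 um^2 (so hole filling at the 150 um^2 rule is exercised), and a
#' small global HE->CK translation.
#'
#' @param grid c(rows, cols) of cores.
#' @param core_radius_um core radius; jittered per core by
#'   \code{core_radius_jitter} (fractional).
#' @param mpp microns per level-0 pixel.
#' @param n_levels pyramid levels (downsamples 1, 2, 4, ...).
#' @param invasive_nests,benign_glands,insitu_ducts structures per core.
#' @param nest_radius_um,gland_radius_um,duct_radius_um radius ranges.
#' @param gland_lumen_frac lumen radius as a fraction of the gland radius.
#' @param dab_od_range DAB optical density of stained epithelium.
#' @param nuclear_hole_area_um2 area range of unstained nuclear holes.
#' @param nuclear_hole_per_um2 expected holes per um^2 of epithelium.
#' @param global_shift_px rigid (dx, dy) translation of the CK image
#'   relative to HE, in level-0 pixels.
#' @param artifacts list of flags: \code{debris}, \code{merged_cores},
#'   \code{missing_core}, \code{background_dab}, \code{false_negative}.
#' @param seed RNG seed; the generator is deterministic given the config.
#' @export
synth_config <- function(grid = c(3L, 3L), core_radius_um = 450,
                         core_radius_jitter = 0.04, mpp = 2, n_levels = 3L,
                         invasive_nests = 6L, benign_glands = 2L,
                         insitu_ducts = 1L,
                         nest_radius_um = c(40, 80),
                         gland_radius_um = c(60, 100),
                         duct_radius_um = c(80, 120),
                         gland_lumen_frac = 0.55,
                         dab_od_range = c(0.5, 0.9),
                         nuclear_hole_area_um2 = c(20, 120),
                         nuclear_hole_per_um2 = 1 / 900,
                         global_shift_px = c(8L, -12L),
                         artifacts = list(debris = FALSE, merged_cores = FALSE,
                                          missing_core = FALSE,
                                          background_dab = FALSE,
                                          false_negative = FALSE),
                         seed = 7L) {
  stopifnot(all(grid >= 1), core_radius_um > 0, mpp > 0, n_levels >= 1)
  defaults <- list(debris = FALSE, merged_cores = FALSE, missing_core = FALSE,
                   background_dab = FALSE, false_negative = FALSE)
  defaults[names(artifacts)] <- artifacts
  structure(list(grid = as.integer(grid), core_radius_um = core_radius_um,
                 core_radius_jitter = core_radius_jitter, mpp = mpp,
                 n_levels = as.integer(n_levels),
                 invasive_nests = invasive_nests,
                 benign_glands = benign_glands, insitu_ducts = insitu_ducts,
                 nest_radius_um = nest_radius_um,
                 gland_radius_um = gland_radius_um,
                 duct_radius_um = duct_radius_um,
                 gland_lumen_frac = gland_lumen_frac,
                 dab_od_range = dab_od_range,
                 nuclear_hole_area_um2 = nuclear_hole_area_um2,
                 nuclear_hole_per_um2 = nuclear_hole_per_um2,
                 global_shift_px = as.integer(global_shift_px),
                 artifacts = defaults, seed = as.integer(seed)),
            class = "synth_config")
}

# Eosin OD vector for the HE rendering.
EOSIN_VEC <- c(0.07, 0.99, 0.11)

# linear indices of the pixels of a disk, for batched painting of many
# small disks without repeated full-canvas copies
disk_indices <- function(H, W, cx, cy, r) {
  x0 <- max(1L, floor(cx - r)); x1 <- min(W, ceiling(cx + r))
  y0 <- max(1L, floor(cy - r)); y1 <- min(H, ceiling(cy + r))
  if (x1 < x0 || y1 < y0) return(integer(0))
  xs <- x0:x1; ys <- y0:y1
  d2 <- outer((ys - 0.5 - cy)^2, (xs - 0.5 - cx)^2, `+`)
  sel <- which(d2 <= r^2)
  ri <- ((sel - 1L) %% length(ys)) + y0
  ci <- ((sel - 1L) %/% length(ys)) + x0
  ri + (ci - 1L) * H
}

set_disk <- function(canvas, cx, cy, r, value, r_in = 0) {
  h <- nrow(canvas); w <- ncol(canvas)
  x0 <- max(1L, floor(cx - r)); x1 <- min(w, ceiling(cx + r))
  y0 <- max(1L, floor(cy - r)); y1 <- min(h, ceiling(cy + r))
  if (x1 < x0 || y1 < y0) return(canvas)
  xs <- x0:x1; ys <- y0:y1
  d2 <- outer((ys - 0.5 - cy)^2, (xs - 0.5 - cx)^2, `+`)
  sel <- d2 <= r^2 & d2 >= r_in^2
  sub <- canvas[ys, xs, drop = FALSE]
  sub[sel] <- value
  canvas[ys, xs] <- sub
  canvas
}

#' Generate a paired synthetic HE/CK slide with ground truth
#'
#' @param cfg \code{synth_config}.
#' @return list: \code{he}, \code{ck} (\code{pyramidal_image}s),
#'   \code{annotations} (\code{annotation_set} with benign / in-situ /
#'   exclusion / case polygons in level-0 HE coordinates), \code{truth}
#'   (list of per-core \code{ground_truth} over each core's bbox),
#'   \code{manifest} (tibble: core id, centre, radius, bbox, case_id,
#'   artifact tags), and \code{layout} internals (the exact level-0 class
#'   label raster \code{labels0}).
#' @export
generate_slide_pair <- function(cfg = synth_config()) {
  set.seed(cfg$seed)
  r_px <- cfg$core_radius_um / cfg$mpp
  spacing <- 2.3 * r_px
  margin <- 0.75 * spacing
  H <- as.integer(ceiling(2 * margin + (cfg$grid[1] - 1L) * spacing + 2 * r_px))
  W <- as.integer(ceiling(2 * margin + (cfg$grid[2] - 1L) * spacing + 2 * r_px))
  div <- 2^(cfg$n_levels - 1L)
  H <- (H %/% div) * div; W <- (W %/% div) * div

  # --- core layout ---------------------------------------------------------
  cores <- list()
  id <- 0L
  for (gr in seq_len(cfg$grid[1])) for (gc in seq_len(cfg$grid[2])) {
    id <- id + 1L
    cx <- margin + r_px + (gc - 1L) * spacing + stats::runif(1, -0.05, 0.05) * spacing
    cy <- margin + r_px + (gr - 1L) * spacing + stats::runif(1, -0.05, 0.05) * spacing
    r <- r_px * (1 + stats::runif(1, -cfg$core_radius_jitter, cfg$core_radius_jitter))
    cores[[id]] <- list(id = id, row = gr, col = gc, cx = cx, cy = cy, r = r,
                        tags = character(0))
  }
  n_cores <- length(cores)
  if (cfg$artifacts$missing_core) {
    drop <- sample.int(n_cores, 1L)
    cores[[drop]]$tags <- c(cores[[drop]]$tags, "missing")
  }
  if (cfg$artifacts$merged_cores && cfg$grid[2] >= 2L) {
    # pull the first two cores of the last row together until they touch
    pair <- which(vapply(cores, function(k) k$row == cfg$grid[1] & k$col <= 2L,
                         logical(1)))
    if (length(pair) == 2L) {
      mid <- mean(c(cores[[pair[1]]]$cx, cores[[pair[2]]]$cx))
      gap <- 0.85 * (cores[[pair[1]]]$r + cores[[pair[2]]]$r)
      cores[[pair[1]]]$cx <- mid - gap / 2
      cores[[pair[2]]]$cx <- mid + gap / 2
      cores[[pair[1]]]$tags <- c(cores[[pair[1]]]$tags, "merged")
      cores[[pair[2]]]$tags <- c(cores[[pair[2]]]$tags, "merged")
    }
  }

  # --- structures ----------------------------------------------------------
  um <- function(x) x / cfg$mpp
  structures <- list()
  for (k in cores) {
    if ("missing" %in% k$tags) next
    place <- function(n, r_range, min_r_frac = 0.0) {
      out <- list()
      tries <- 0L
      while (length(out) < n && tries < 200L) {
        tries <- tries + 1L
        rr <- min(um(stats::runif(1, r_range[1], r_range[2])), 0.45 * k$r)
        d <- stats::runif(1, min_r_frac, max(min_r_frac + 0.01, 0.78 - rr / k$r)) * k$r
        th <- stats::runif(1, 0, 2 * pi)
        cand <- list(cx = k$cx + d * cos(th), cy = k$cy + d * sin(th), r = rr)
        ok <- TRUE
        for (s in structures) {
          if (s$core != k$id) next
          if ((s$cx - cand$cx)^2 + (s$cy - cand$cy)^2 < (s$r + cand$r + um(15))^2) {
            ok <- FALSE; break
          }
        }
        for (s in out) {
          if ((s$cx - cand$cx)^2 + (s$cy - cand$cy)^2 < (s$r + cand$r + um(15))^2) {
            ok <- FALSE; break
          }
        }
        if (ok) out[[length(out) + 1L]] <- cand
      }
      out
    }
    for (s in place(cfg$benign_glands, cfg$gland_radius_um))
      structures[[length(structures) + 1L]] <-
        c(s, class = "benign", core = k$id, r_in = s$r * cfg$gland_lumen_frac)
    for (s in place(cfg$insitu_ducts, cfg$duct_radius_um))
      structures[[length(structures) + 1L]] <-
        c(s, class = "in_situ", core = k$id, r_in = 0)
    for (s in place(cfg$invasive_nests, cfg$nest_radius_um))
      structures[[length(structures) + 1L]] <-
        c(s, class = "invasive", core = k$id, r_in = 0)
  }

  # --- level-0 label raster and stain OD fields ----------------------------
  tissue <- matrix(0L, H, W)
  for (k in cores) if (!("missing" %in% k$tags))
    tissue <- set_disk(tissue, k$cx, k$cy, k$r, 1L)
  labels0 <- matrix(0L, H, W)
  cls_code <- c(invasive = 1L, benign = 2L, in_situ = 3L)
  for (s in structures)
    labels0 <- set_disk(labels0, s$cx, s$cy, s$r, cls_code[[s$class]],
                        r_in = s$r_in)
  labels0[tissue == 0L] <- 0L
  epith <- labels0 > 0L
  # myoepithelial rim around in-situ ducts: a thin dense ring just outside
  # the epithelium, rendered in both stains but part of the stroma
  rim <- matrix(FALSE, H, W)
  for (s in structures) {
    if (s$class != "in_situ") next
    rim <- set_disk(rim, s$cx, s$cy, s$r + um(8), TRUE, r_in = s$r)
  }
  rim <- rim & tissue == 1L & !epith

  # nuclear holes: unstained in CK, hematoxylin-dense nuclei in HE
  holes <- matrix(FALSE, H, W)
  n_holes <- stats::rpois(1, sum(epith) * cfg$mpp^2 * cfg$nuclear_hole_per_um2)
  ep_idx <- which(epith)
  if (n_holes > 0L && length(ep_idx)) {
    at <- sample(ep_idx, min(n_holes, length(ep_idx)))
    hr <- ((at - 1L) %% H) + 1L; hc <- ((at - 1L) %/% H) + 1L
    ha <- stats::runif(length(at), cfg$nuclear_hole_area_um2[1],
                       cfg$nuclear_hole_area_um2[2])
    # holes must not merge: a merged hole could exceed the fill-area rule,
    # which the construction promises to stay below
    max_r <- sqrt(max(cfg$nuclear_hole_area_um2) / pi) / cfg$mpp
    blocked <- matrix(FALSE, H, W)
    idx <- integer(0)
    for (i in seq_along(at)) {
      if (blocked[hr[i], hc[i]]) next
      idx <- c(idx, disk_indices(H, W, hc[i] - 0.5, hr[i] - 0.5,
                                 sqrt(ha[i] / pi) / cfg$mpp))
      blocked[disk_indices(H, W, hc[i] - 0.5, hr[i] - 0.5,
                           2 * max_r + 1)] <- TRUE
    }
    holes[idx] <- TRUE
    holes <- holes & epith
  }

  # stroma nuclei dots give both stains registration texture
  dots <- matrix(FALSE, H, W)
  st_idx <- which(tissue == 1L & !epith)
  if (length(st_idx)) {
    at <- sample(st_idx, max(1L, length(st_idx) %/% 400L))
    dr <- ((at - 1L) %% H) + 1L; dc <- ((at - 1L) %/% H) + 1L
    idx <- unlist(lapply(seq_along(at), function(i)
      disk_indices(H, W, dc[i] - 0.5, dr[i] - 0.5, um(5))))
    dots[idx] <- TRUE
    dots <- dots & tissue == 1L & !epith
  }

  # spatially correlated multiplicative noise, rendered on a quarter-scale
  # grid and upsampled (the correlation length is several pixels anyway)
  noise <- function(scale = 0.12, sigma = 1.5) {
    hs <- max(2L, H %/% 4L); ws <- max(2L, W %/% 4L)
    n <- gaussian_blur(matrix(stats::rnorm(hs * ws), hs, ws), sigma / 2)
    1 + scale * resize_nn(n, H, W)
  }

  # CK: DAB in epithelial cytoplasm, holes unstained; light hematoxylin
  dab_od <- matrix(0, H, W)
  for (s in structures) {
    od <- stats::runif(1, cfg$dab_od_range[1], cfg$dab_od_range[2])
    if (cfg$artifacts$false_negative && s$core == cores[[1]]$id) od <- 0.05
    dab_od <- set_disk(dab_od, s$cx, s$cy, s$r, od, r_in = s$r_in)
  }
  dab_od[!epith] <- 0
  dab_od[holes] <- 0
  dab_od <- dab_od * noise()
  if (cfg$artifacts$background_dab) {
    k <- cores[[min(2L, n_cores)]]
    haze <- set_disk(matrix(0, H, W), k$cx, k$cy, k$r, 0.15)
    dab_od <- dab_od + haze * noise(0.2)
  }
  # a few sub-threshold-size DAB specks exercise small-object removal
  sp_idx <- sample(which(tissue == 1L & !epith), 6L)
  spk <- unlist(lapply(sp_idx, function(i)
    disk_indices(H, W, ((i - 1L) %/% H) + 0.5, ((i - 1L) %% H) + 0.5, um(2.2))))
  dab_od[spk] <- 0.7
  hema_ck <- matrix(0, H, W)
  hema_ck[tissue == 1L] <- 0.15
  hema_ck[epith] <- 0.28
  hema_ck[rim] <- 0.55
  hema_ck[holes] <- 0.6
  hema_ck[dots] <- 0.5
  hema_ck <- hema_ck * noise()
  conc_ck <- array(0, c(H, W, 3))
  conc_ck[, , 1] <- hema_ck; conc_ck[, , 2] <- dab_od
  ck0 <- synthesize_hdab(conc_ck)
  ck0 <- apply_shift(ck0, cfg$global_shift_px, fill = 1)

  # HE: hematoxylin-dense epithelium and nuclei, eosin stroma
  hema_he <- matrix(0, H, W)
  hema_he[tissue == 1L] <- 0.10
  hema_he[epith] <- 0.62
  hema_he[labels0 == 3L] <- 0.85          # hyperchromatic in-situ epithelium
  hema_he[rim] <- 0.95                    # myoepithelial rim
  hema_he[holes] <- 0.9
  hema_he[dots] <- 0.75
  hema_he <- hema_he * noise()
  eos_he <- matrix(0, H, W)
  eos_he[tissue == 1L] <- 0.38
  eos_he[epith] <- 0.22
  eos_he <- eos_he * noise()
  he_vectors <- hdab_stain_vectors(dab = EOSIN_VEC)  # hematoxylin + eosin pair
  conc_he <- array(0, c(H, W, 3))
  conc_he[, , 1] <- hema_he; conc_he[, , 2] <- eos_he
  he0 <- synthesize_hdab(conc_he, he_vectors)

  if (cfg$artifacts$debris) {
    # a speck between the first two cores, sized to fall under the
    # 100-overview-pixel debris rule
    ov_ds <- 2^(cfg$n_levels - 1L)
    area_ov <- stats::runif(1, 30, 90)
    r_deb <- sqrt(area_ov * ov_ds^2 / pi)
    dx <- (cores[[1]]$cx + cores[[2]]$cx) / 2
    dy <- cores[[1]]$cy - cores[[1]]$r * 1.05
    for (c in 1:3) {
      ch <- he0[, , c]
      ch <- set_disk(ch, dx, dy, r_deb, c(0.45, 0.35, 0.5)[c])
      he0[, , c] <- ch
    }
  }

  build_pyramid <- function(arr0, stain, slide_id) {
    levels <- list(arr0)
    for (l in seq_len(cfg$n_levels - 1L))
      levels[[l + 1L]] <- block_mean(levels[[l]], 2L)
    pyramidal_image(levels, 2^(seq_len(cfg$n_levels) - 1L), mpp_x = cfg$mpp,
                    slide_id = slide_id, stain = stain)
  }
  he <- build_pyramid(he0, "HE", "synthetic_he")
  ck <- build_pyramid(ck0, "CK", "synthetic_ck")

  # --- annotations ---------------------------------------------------------
  polys <- list()
  for (s in structures) {
    if (s$class == "invasive") next
    polys[[length(polys) + 1L]] <- list(
      geometry = list(outer = circle_ring(s$cx, s$cy, s$r * 1.12), holes = list()),
      label = if (s$class == "benign") "benign" else "in_situ",
      case_id = NULL)
  }
  for (k in cores) {
    bad <- cfg$artifacts$false_negative && k$id == cores[[1]]$id
    bad <- bad || (cfg$artifacts$background_dab && k$id == min(2L, n_cores))
    if (bad) {
      polys[[length(polys) + 1L]] <- list(
        geometry = list(outer = circle_ring(k$cx, k$cy, k$r * 1.1), holes = list()),
        label = "exclude_core", case_id = NULL)
      cores[[k$id]]$tags <- c(cores[[k$id]]$tags, "tagged_excluded")
    }
  }
  for (gr in seq_len(cfg$grid[1])) {
    members <- Filter(function(k) k$row == gr && !("missing" %in% k$tags), cores)
    if (!length(members)) next
    xs <- range(vapply(members, function(k) c(k$cx - k$r, k$cx + k$r), numeric(2)))
    ys <- range(vapply(members, function(k) c(k$cy - k$r, k$cy + k$r), numeric(2)))
    pad <- 0.15 * r_px
    rect <- rbind(c(xs[1] - pad, ys[1] - pad), c(xs[2] + pad, ys[1] - pad),
                  c(xs[2] + pad, ys[2] + pad), c(xs[1] - pad, ys[2] + pad))
    polys[[length(polys) + 1L]] <- list(geometry = list(outer = rect, holes = list()),
                                        label = "case_group",
                                        case_id = sprintf("case_%d", gr))
  }
  ann <- annotation_set(polys)

  # --- per-core truth and manifest ----------------------------------------
  manifest <- list()
  truth <- list()
  for (k in cores) {
    if ("missing" %in% k$tags) next
    bbox <- c(max(0, floor(k$cx - k$r - 2)), max(0, floor(k$cy - k$r - 2)),
              min(W, ceiling(k$cx + k$r + 2)), min(H, ceiling(k$cy + k$r + 2)))
    lab <- crop_window(labels0, bbox)
    gt <- ground_truth(label_map(lab, origin = bbox[1:2], mpp = cfg$mpp),
                       core_ref = sprintf("core_%d", k$id))
    truth[[gt$core_ref]] <- gt
    manifest[[length(manifest) + 1L]] <- tibble::tibble(
      core_ref = gt$core_ref, id = k$id, row = k$row, col = k$col,
      cx = k$cx, cy = k$cy, r = k$r,
      x0 = bbox[1], y0 = bbox[2], x1 = bbox[3], y1 = bbox[4],
      case_id = sprintf("case_%d", k$row),
      tags = paste(k$tags, collapse = ";"))
  }
  list(he = he, ck = ck, annotations = ann, truth = truth,
       manifest = dplyr::bind_rows(manifest),
       layout = list(labels0 = labels0, tissue = tissue,
                     shift = cfg$global_shift_px, cfg = cfg))
}

#' Generate a single synthetic HE/CK core pair
#'
#' A lightweight path for registration experiments: one core rendered with
#' the same palettes as \code{\link{generate_slide_pair}}, the CK raster
#' translated by \code{shift_px}.
#'
#' @param cfg \code{synth_config} (grid is ignored; one core is rendered).
#' @param shift_px c(dx, dy) translation applied to the CK raster.
#' @return list: \code{he}, \code{ck} ([H, W, 3] arrays), \code{labels}
#'   (class raster), \code{shift_px}.
#' @export
generate_core_pair <- function(cfg = synth_config(), shift_px = cfg$global_shift_px) {
  sub <- cfg
  sub$grid <- c(1L, 1L)
  sub$global_shift_px <- as.integer(shift_px)
  sub$artifacts <- list(debris = FALSE, merged_cores = FALSE,
                        missing_core = FALSE, background_dab = FALSE,
                        false_negative = FALSE)
  class(sub) <- "synth_config"
  out <- generate_slide_pair(sub)
  list(he = out$he$levels[[1]], ck = out$ck$levels[[1]],
       labels = out$layout$labels0, shift_px = as.integer(shift_px))
}

#' Write annotation and metadata fixtures to disk
#'
#' Produces a QuPath-dialect GeoJSON FeatureCollection (class name under
#' \code{properties.classification.name}) for the annotation set, and a CSV
#' of per-core case metadata with histological subtype drawn from
#' \{NST, lobular, other\} and grade from \{1, 2, 3\}, joinable to cores by
#' \code{core_ref}.
#'
#' @param ann \code{annotation_set}.
#' @param manifest core manifest tibble from \code{\link{generate_slide_pair}}.
#' @param dir output directory (created if needed).
#' @return named list of written paths.
#' @export
generate_annotation_files <- function(ann, manifest, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  label_names <- c(benign = "Benign", in_situ = "DCIS",
                   exclude_core = "Exclude", case_group = "Case")
  features <- lapply(ann$polygons, function(p) {
    ring <- rbind(p$geometry$outer, p$geometry$outer[1, , drop = FALSE])
    coords <- list(lapply(seq_len(nrow(ring)), function(i) as.list(ring[i, ])))
    props <- list(classification = list(name = unname(label_names[[p$label]])))
    if (!is.null(p$case_id)) props$case_id <- p$case_id
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = coords),
         properties = props)
  })
  gj_path <- file.path(dir, "annotations.geojson")
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       gj_path, auto_unbox = TRUE, digits = NA)
  meta <- manifest |>
    dplyr::distinct(.data$case_id) |>
    dplyr::mutate(subtype = sample(c("NST", "lobular", "other"), dplyr::n(),
                                   replace = TRUE, prob = c(0.7, 0.2, 0.1)),
                  grade = sample(1:3, dplyr::n(), replace = TRUE))
  meta <- dplyr::left_join(manifest[, c("core_ref", "case_id")], meta,
                           by = "case_id")
  csv_path <- file.path(dir, "core_metadata.csv")
  utils::write.csv(meta, csv_path, row.names = FALSE)
  list(geojson = gj_path, metadata = csv_path)
}
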