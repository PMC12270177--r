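test_that("the generator is deterministic and satisfies the truth invariants", {
  cfg <- small_synth_config(seed = 5L)
  a <- generate_slide_pair(cfg)
  b <- generate_slide_pair(cfg)
  expect_identical(a$layout$labels0, b$layout$labels0)
  expect_identical(a$he$levels[[1]], b$he$levels[[1]])

  # per-core truths partition every pixel and agree with the layout raster
  for (gt in a$truth) {
    expect_true(all(apply(gt$onehot, c(1, 2), sum) == 1L))
    expect_true(all(gt$labels$raster %in% 0:3))
  }
  expect_equal(nrow(a$manifest), 4L)
  expect_true(all(c("benign", "in_situ", "case_group") %in%
                    vapply(a$annotations$polygons, `[[`, character(1), "label")))
})

test_that("synthetic DAB stays above threshold and holes below the fill rule", {
  out <- cached_slide_pair(small_synth_config())
  cfg <- out$layout$cfg
  ck0 <- out$ck$levels[[1]]
  ck_aligned <- apply_shift(ck0, -cfg$global_shift_px, fill = 1)
  dab <- deconvolve_hdab(ck_aligned)$dab
  p <- mask_params_at(cfg$mpp)
  sm <- ihcseg:::gaussian_blur(dab, p$gaussian_sigma)
  epith <- out$layout$labels0 > 0L

  # the raw mask misses some epithelium (nuclear holes) ...
  raw <- sm > p$dab_threshold
  expect_gt(sum(epith & !raw), 0)
  # ... and every hole is small enough that cleaning fills it
  cleaned <- clean_mask(binary_mask(raw * 1L, mpp = cfg$mpp), p)
  dice <- 2 * sum(cleaned$raster & epith) / (sum(cleaned$raster) + sum(epith))
  expect_gt(dice, 0.95)
  # hole areas are below the 150 um^2 fill rule by construction
  holes <- ihcseg:::label_components(epith & !raw, connectivity = 4L)
  if (max(holes) > 0) {
    areas_um2 <- ihcseg:::component_areas(holes) * cfg$mpp^2
    expect_lt(stats::quantile(areas_um2, 0.99), 150)
  }
})

test_that("the pipeline recovers the generator truth on an unshifted slide", {
  cfg <- small_synth_config(seed = 9L)
  cfg$global_shift_px <- c(0L, 0L)
  out <- generate_slide_pair(cfg)
  recs <- process_slide_pair(out$he, out$ck, out$annotations,
                             magnification = "x40")   # level 0
  expect_equal(length(recs), 4L)
  for (rec in recs) {
    # nearest generator truth, compared over the bbox intersection in
    # absolute slide coordinates (detected and analytic bboxes differ by a
    # few pixels)
    dists <- sapply(out$truth, function(tr)
      sum(abs(tr$labels$origin - rec$bbox[1:2])))
    truth <- out$truth[[which.min(dists)]]
    tx <- truth$labels$origin; rx <- rec$bbox[1:2]
    x0 <- max(tx[1], rx[1]); y0 <- max(tx[2], rx[2])
    x1 <- min(tx[1] + ncol(truth$labels$raster),
              rx[1] + ncol(rec$gt$labels$raster))
    y1 <- min(tx[2] + nrow(truth$labels$raster),
              rx[2] + nrow(rec$gt$labels$raster))
    a_lab <- truth$labels$raster[(y0 - tx[2] + 1):(y1 - tx[2]),
                                 (x0 - tx[1] + 1):(x1 - tx[1])]
    b_lab <- rec$gt$labels$raster[(y0 - rx[2] + 1):(y1 - rx[2]),
                                  (x0 - rx[1] + 1):(x1 - rx[1])]
    for (k in 1:3) {
      a <- a_lab == k; b <- b_lab == k
      if (sum(a) + sum(b) == 0) next
      expect_gt(2 * sum(a & b) / (sum(a) + sum(b)), 0.95)
    }
  }
})

test_that("the global shift is recovered by core registration", {
  out <- cached_slide_pair(small_synth_config())
  cfg <- out$layout$cfg
  recs <- process_slide_pair(out$he, out$ck, out$annotations,
                             magnification = "x40")
  for (rec in recs) {
    expect_lte(abs(rec$shift$dx + cfg$global_shift_px[1]), 4)
    expect_lte(abs(rec$shift$dy + cfg$global_shift_px[2]), 4)
  }
})

test_that("each artifact flag changes exactly its downstream behaviour", {
  base <- small_synth_config(seed = 13L)

  debris <- generate_slide_pair(small_synth_config(seed = 13L,
                                                   artifacts = list(debris = TRUE)))
  cores <- detect_cores(debris$he)
  expect_equal(sum(cores$kept), 4L)
  expect_true(any(grepl("debris", cores$exclusion_reason[!cores$kept])))

  merged <- generate_slide_pair(small_synth_config(seed = 13L,
                                                   artifacts = list(merged_cores = TRUE)))
  cm <- detect_cores(merged$he)
  expect_equal(sum(cm$kept), 2L)
  expect_true(any(grepl("deviation", cm$exclusion_reason[!cm$kept])))

  missing <- generate_slide_pair(small_synth_config(seed = 13L,
                                                    artifacts = list(missing_core = TRUE)))
  expect_equal(nrow(missing$manifest), 3L)
  expect_equal(sum(detect_cores(missing$he)$kept), 3L)

  fneg <- generate_slide_pair(small_synth_config(seed = 13L,
                                                 artifacts = list(false_negative = TRUE)))
  labs <- vapply(fneg$annotations$polygons, `[[`, character(1), "label")
  expect_true("exclude_core" %in% labs)
  cores_f <- detect_cores(fneg$he)
  kept_after <- apply_exclusions(cores_f, fneg$annotations)
  expect_lt(sum(kept_after$kept), sum(cores_f$kept))
})

test_that("annotation files round-trip through the GeoJSON reader", {
  out <- cached_slide_pair(small_synth_config())
  dir <- withr::local_tempdir()
  paths <- generate_annotation_files(out$annotations, out$manifest, dir)
  back <- read_annotations(paths$geojson, out$he)
  labs_orig <- vapply(out$annotations$polygons, `[[`, character(1), "label")
  labs_back <- vapply(back$polygons, `[[`, character(1), "label")
  count <- function(x) {
    t <- table(x)
    stats::setNames(as.integer(t), names(t))[sort(unique(x))]
  }
  expect_identical(count(labs_back), count(labs_orig))
  expect_length(attr(back, "unknown_labels"), 0)

  meta <- utils::read.csv(paths$metadata)
  expect_setequal(meta$core_ref, out$manifest$core_ref)
  expect_true(all(meta$subtype %in% c("NST", "lobular", "other")))
  expect_true(all(meta$grade %in% 1:3))
  # joinable to cores and usable for subgroup summaries
  joined <- dplyr::inner_join(out$manifest, meta,
                              by = c("core_ref", "case_id"))
  expect_equal(nrow(joined), nrow(out$manifest))
})

test_that("a structure-free config still yields a valid annotation file", {
  cfg <- small_synth_config(seed = 17L)
  cfg$benign_glands <- 0L; cfg$insitu_ducts <- 0L
  out <- generate_slide_pair(cfg)
  dir <- withr::local_tempdir()
  paths <- generate_annotation_files(out$annotations, out$manifest, dir)
  gj <- jsonlite::read_json(paths$geojson)
  expect_equal(gj$type, "FeatureCollection")
  labs <- vapply(gj$features, function(f) f$properties$classification$name,
                 character(1))
  expect_false(any(labs %in% c("Benign", "DCIS")))
})

test_that("generate_core_pair renders a registered single-core pair", {
  cp <- generate_core_pair(small_synth_config(seed = 19L),
                           shift_px = c(5L, -3L))
  expect_equal(dim(cp$he)[3], 3L)
  est <- suppressWarnings(
    estimate_shift(cp$he, cp$ck, registration_params()))
  expect_lte(abs(est$dx + 5), 4)
  expect_lte(abs(est$dy - 3), 4)
})
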