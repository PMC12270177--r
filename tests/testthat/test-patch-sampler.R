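test_that("tile_core enumerates stride-768 windows with edge clamping", {
  p <- patch_params()                         # 1024 px, 25% overlap
  expect_equal(nrow(tile_core(c(1024, 1024), p)), 1L)

  t2 <- tile_core(c(1024, 1792), p)           # height x width
  expect_equal(nrow(t2), 2L)
  expect_setequal(t2$x0, c(0L, 768L))
  expect_equal(unique(t2$y0), 0L)

  t3 <- tile_core(c(2000, 2000), p)
  expect_equal(nrow(t3), 9L)
  expect_setequal(unique(t3$x0), c(0L, 768L, 976L))
  expect_setequal(unique(t3$y0), c(0L, 768L, 976L))
  expect_true(all(t3$x1 <= 2000 & t3$y1 <= 2000))

  # a core smaller than the patch yields one flagged window
  t4 <- tile_core(c(500, 2000), p)
  expect_true(all(t4$padded))
})

test_that("tiling covers every pixel, interior pixels by at most 4 windows", {
  p <- patch_params(patch_size = 64L)
  wins <- tile_core(c(200, 150), p)
  cover <- matrix(0L, 200, 150)
  for (i in seq_len(nrow(wins)))
    cover[(wins$y0[i] + 1):wins$y1[i], (wins$x0[i] + 1):wins$x1[i]] <-
      cover[(wins$y0[i] + 1):wins$y1[i], (wins$x0[i] + 1):wins$x1[i]] + 1L
  expect_true(all(cover >= 1L))
  expect_lte(max(cover), 4L)
})

test_that("tissue_fraction applies the colourimetric rule", {
  p <- patch_params(patch_size = 64L)
  white <- array(1, c(64, 64, 3))
  expect_equal(tissue_fraction(white, p), 0)
  tissue <- array(c(0.8, 0.5, 0.6), c(3, 64, 64))
  tissue <- aperm(tissue, c(2, 3, 1))
  expect_equal(tissue_fraction(tissue, p), 1)
  half <- white; half[, 1:32, ] <- rep(c(0.8, 0.5, 0.6), each = 64 * 32)
  expect_equal(tissue_fraction(half, p), 0.5, tolerance = 0.01)
})

test_that("assign_set follows the in-situ > benign > invasive priority", {
  mk <- function(labels) onehot_encode(labels)
  lab <- matrix(1L, 32, 32)                  # heavy invasive
  lab[1, 1] <- 3L                            # one in-situ pixel
  expect_equal(assign_set(mk(lab)), "in_situ")
  lab2 <- matrix(0L, 32, 32); lab2[5, 5] <- 2L
  expect_equal(assign_set(mk(lab2)), "benign")
  expect_equal(assign_set(mk(matrix(0L, 32, 32))), "invasive")

  # exhaustive over presence combinations of (benign, in_situ, invasive)
  for (has_b in 0:1) for (has_s in 0:1) for (has_i in 0:1) {
    lab <- matrix(0L, 4, 4)
    if (has_i) lab[1, 1] <- 1L
    if (has_b) lab[2, 2] <- 2L
    if (has_s) lab[3, 3] <- 3L
    want <- if (has_s) "in_situ" else if (has_b) "benign" else "invasive"
    expect_equal(assign_set(mk(lab)), want)
  }
})

fake_patch <- function(set, seed = 1L) {
  withr::with_seed(seed, {
    he <- array(runif(16 * 16 * 3, 0.2, 0.9), c(16, 16, 3))
    lab <- matrix(0L, 16, 16)
    lab[4:12, 4:12] <- switch(set, invasive = 1L, benign = 2L, in_situ = 3L)
  })
  list(he = he, onehot = onehot_encode(lab), set = set,
       origin = c(0, 0), core_ref = "fake")
}

test_that("balanced_sampler draws sets uniformly and reproducibly", {
  patches <- c(list(fake_patch("benign"), fake_patch("in_situ")),
               replicate(100, fake_patch("invasive"), simplify = FALSE))
  s <- balanced_sampler(patches)
  withr::with_seed(31, draws <- vapply(s(6000), `[[`, character(1), "set"))
  freq <- table(draws) / 6000
  expect_true(all(abs(freq - 1 / 3) < 0.02))

  withr::with_seed(32, a <- vapply(s(50), `[[`, character(1), "set"))
  withr::with_seed(32, b <- vapply(s(50), `[[`, character(1), "set"))
  expect_identical(a, b)

  # an empty set renormalizes over the remaining two
  expect_warning(s2 <- balanced_sampler(patches[-2]), "in_situ")
  withr::with_seed(33, d2 <- vapply(s2(4000), `[[`, character(1), "set"))
  expect_true(all(abs(table(d2) / 4000 - 0.5) < 0.03))
  expect_error(balanced_sampler(list()), "empty")
})

test_that("sampler set frequencies pass a uniformity chi-square test", {
  patches <- list(fake_patch("benign"), fake_patch("in_situ"),
                  fake_patch("invasive"))
  s <- balanced_sampler(patches)
  withr::with_seed(34, draws <- vapply(s(30000), `[[`, character(1), "set"))
  p <- chisq.test(table(draws))$p.value
  expect_gt(p, 0.01)
})

test_that("augmentation with zero probabilities is the identity", {
  patch <- fake_patch("benign")
  cfg <- augment_config(enable_prob = c(flip = 0, rot90 = 0, brightness = 0,
                                        hue = 0, saturation = 0, shift = 0,
                                        blur = 0))
  withr::with_seed(35, out <- augment(patch, cfg))
  expect_identical(out$he, patch$he)
  expect_identical(out$onehot, patch$onehot)
})

test_that("flip is an involution and spatial transforms preserve counts", {
  patch <- fake_patch("in_situ")
  flip_only <- augment_config(enable_prob = c(flip = 1, rot90 = 0,
                                              brightness = 0, hue = 0,
                                              saturation = 0, shift = 0,
                                              blur = 0))
  withr::with_seed(36, once <- augment(patch, flip_only))
  # flipping the flipped patch along the same axis restores the original
  restored <- ihcseg:::flip_raster(once$he,
                                   if (identical(once$he[, 1, ],
                                                 patch$he[, 16, ])) "h" else "v")
  expect_identical(restored, patch$he)

  rot_only <- augment_config(enable_prob = c(flip = 0, rot90 = 1,
                                             brightness = 0, hue = 0,
                                             saturation = 0, shift = 0,
                                             blur = 0))
  withr::with_seed(37, rot <- augment(patch, rot_only))
  for (k in 1:4)
    expect_equal(apply(rot$onehot, 3, sum), apply(patch$onehot, 3, sum))
  expect_true(all(apply(rot$onehot, c(1, 2), sum) == 1L))
})

test_that("photometric augmentation leaves the ground truth untouched", {
  patch <- fake_patch("invasive")
  photo <- augment_config(enable_prob = c(flip = 0, rot90 = 0, brightness = 1,
                                          hue = 1, saturation = 1, shift = 0,
                                          blur = 1))
  withr::with_seed(38, out <- augment(patch, photo))
  expect_identical(out$onehot, patch$onehot)
  expect_false(identical(out$he, patch$he))
  expect_true(all(out$he >= 0 & out$he <= 1))
})

test_that("shift augmentation keeps the one-hot stack a valid partition", {
  patch <- fake_patch("benign")
  shift_only <- augment_config(enable_prob = c(flip = 0, rot90 = 0,
                                               brightness = 0, hue = 0,
                                               saturation = 0, shift = 1,
                                               blur = 0), shift_max_px = 5L)
  withr::with_seed(39, out <- augment(patch, shift_only))
  expect_true(all(apply(out$onehot, c(1, 2), sum) == 1L))
})

test_that("enablement draws follow the configured probabilities", {
  withr::with_seed(40, draws <- draw_augment_enables(augment_config(), 20000))
  freq <- colMeans(draws)
  expect_true(all(abs(freq[c("flip", "rot90", "brightness", "hue",
                             "saturation", "shift")] - 0.5) < 0.012))
  expect_lt(abs(freq[["blur"]] - 0.1), 0.008)
})

test_that("make_patches filters by tissue and assigns sets", {
  sl <- cached_slide_pair(small_synth_config())
  recs <- process_slide_pair(sl$he, sl$ck, sl$annotations,
                             magnification = "x20")
  pp <- patch_params(patch_size = 64L)
  patches <- patches_from_records(recs, pp)
  expect_gt(length(patches), 0)
  idx <- patch_index(patches)
  expect_true(all(idx$set %in% c("benign", "in_situ", "invasive")))
  for (p in patches) {
    expect_gte(tissue_fraction(p$he, pp), pp$min_tissue_fraction)
    expect_equal(assign_set(p$onehot), p$set)
  }
})
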