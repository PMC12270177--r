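mini <- function(...) miniature_config(input_size = c(32L, 32L, 3L),
                                       filters = c(4L, 8L), ...)

rand_patch <- function(seed, n = 32L) {
  withr::with_seed(seed, {
    he <- array(runif(n * n * 3), c(n, n, 3))
    lab <- matrix(0L, n, n)
    lab[(he[, , 1] > 0.6)] <- 1L
    lab[(he[, , 2] > 0.7)] <- 2L
  })
  list(he = he, onehot = onehot_encode(lab), set = "invasive",
       origin = c(0, 0), core_ref = "r")
}

test_that("the model builds with the configured shape and is deterministic", {
  m <- build_agunet(mini(), seed = 7)
  m2 <- build_agunet(mini(), seed = 7)
  expect_identical(m$params, m2$params)
  m3 <- build_agunet(mini(), seed = 8)
  expect_false(identical(m$params, m3$params))

  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  out <- agunet_forward(m, x)
  expect_equal(dim(out$prob), c(32L, 32L, 4L))
  expect_equal(apply(out$prob, c(1, 2), sum),
               matrix(1, 32, 32), tolerance = 1e-9)
})

test_that("config invariants and feature switches are honoured", {
  expect_error(model_config(spatial_levels = 3L,
                            filters_per_level = c(4L, 8L)), "one entry")
  expect_error(miniature_config(input_size = c(60L, 60L, 3L)), "divisible")

  plain <- build_agunet(model_config(spatial_levels = 2L,
                                     filters_per_level = c(4L, 8L),
                                     deep_supervision = FALSE,
                                     attention_gates = FALSE,
                                     multiscale_input = FALSE,
                                     input_size = c(16L, 16L, 3L)), seed = 1)
  expect_false(any(grepl("att", names(plain$params))))
  expect_equal(sum(grepl("^head", names(plain$params))), 2L)  # W and b
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_equal(dim(agunet_forward(plain, x)$prob), c(16L, 16L, 4L))
})

test_that("the learning-rate schedule decays on plateau and stops early", {
  cfg <- train_config()
  st <- lr_state(cfg)
  # monotone improvement: the rate never decays
  for (v in seq(1, 0.5, length.out = 30)) st <- lr_schedule_step(st, v, cfg)
  expect_equal(st$lr, cfg$lr0)
  # frozen validation: halved at the 11th consecutive plateau epoch
  st <- lr_state(cfg)
  lrs <- numeric(11)
  for (e in 1:11) { st <- lr_schedule_step(st, 1.0, cfg); lrs[e] <- st$lr }
  expect_equal(lrs[10], 5e-4)           # still within the patience window
  expect_equal(lrs[11], 5e-4 * 0.5)     # halved after 10 epochs w/o improvement
  # second plateau window halves again
  for (e in 1:10) st <- lr_schedule_step(st, 1.0, cfg)
  expect_equal(st$lr, 5e-4 * 0.25)
  # early stop after the configured patience
  st2 <- lr_state(train_config(lr_patience_epochs = 2L,
                               early_stop_patience = 5L))
  stops <- logical(6)
  for (e in 1:6) {
    st2 <- lr_schedule_step(st2, 1.0, train_config(lr_patience_epochs = 2L,
                                                   early_stop_patience = 5L))
    stops[e] <- st2$stop
  }
  # first epoch improves from Inf; the stop fires 5 plateau epochs later
  expect_equal(which(stops)[1], 6L)
})

test_that("one instrumented epoch performs the configured update counts", {
  patches <- lapply(1:6, rand_patch)
  model <- build_agunet(mini(), seed = 1)
  cfg <- train_config(max_epochs = 1L, batch_size = 1L,
                      train_updates_per_epoch = 20L,
                      val_updates_per_epoch = 5L, seed = 1L)
  set.seed(1)
  trained <- train_agunet(model, balanced_sampler(patches),
                          balanced_sampler(patches), cfg)
  expect_identical(trained$counters$train_steps, 20L)
  expect_identical(trained$counters$val_passes, 5L)
  expect_equal(nrow(trained$history), 1L)
})

test_that("the miniature model overfits a single patch (gradient sanity)", {
  # one dark epithelial square on bright stroma, colour-correlated with the
  # label so the mapping is learnable from appearance
  withr::with_seed(99, he <- array(runif(32 * 32 * 3, 0.6, 1), c(32, 32, 3)))
  lab <- matrix(0L, 32, 32); lab[9:24, 9:24] <- 1L
  for (c in 1:3) {
    pl <- he[, , c]
    pl[lab == 1L] <- pl[lab == 1L] * c(0.5, 0.75, 0.9)[c]
    he[, , c] <- pl
  }
  target <- onehot_encode(lab)
  model <- build_agunet(mini(), seed = 2)
  params <- model$params
  opt <- ihcseg:::adam_new(params)
  loss <- NA_real_
  for (step in 1:200) {
    model$params <- params
    fw <- agunet_forward(model, he, target)
    loss <- fw$loss
    if (loss < 0.05) break
    st <- ihcseg:::adam_step(opt, params, fw$grads, lr = 1e-2)
    opt <- st$state; params <- st$params
  }
  expect_lt(loss, 0.05)
})

test_that("training history is tidy and glance reports the fit", {
  patches <- lapply(1:4, rand_patch)
  model <- build_agunet(mini(), seed = 3)
  cfg <- train_config(max_epochs = 2L, batch_size = 1L,
                      train_updates_per_epoch = 5L,
                      val_updates_per_epoch = 2L, seed = 2L)
  set.seed(2)
  trained <- train_agunet(model, balanced_sampler(patches),
                          balanced_sampler(patches), cfg)
  h <- tidy(trained)
  expect_s3_class(h, "tbl_df")
  expect_named(h, c("epoch", "train_loss", "val_loss", "val_hard_dice",
                    "lr", "improved"))
  g <- glance(trained)
  expect_equal(g$epochs_trained, 2L)
  expect_equal(g$train_steps, 10L)
  expect_s3_class(autoplot(trained), "ggplot")
})

test_that("stitched inference reproduces stub models exactly", {
  pp <- patch_params(patch_size = 64L)
  core <- array(runif(150 * 130 * 3), c(150, 130, 3))

  # constant-prediction stub: stitching must be neutral
  const_stub <- function(tile) {
    p <- array(0, c(dim(tile)[1], dim(tile)[2], 4))
    p[, , 2] <- 1
    p
  }
  out <- predict_core(const_stub, core, pp)
  expect_true(all(out$labels$raster == 1L))

  # deterministic per-pixel stub: stitched output equals the direct
  # full-image prediction (the stub depends only on pixel values)
  value_stub <- function(tile) {
    p <- array(0, c(dim(tile)[1], dim(tile)[2], 4))
    cls <- 1L + (tile[, , 1] > 0.5) + (tile[, , 2] > 0.5)
    for (k in 1:4) p[, , k] <- (cls == k) * 1
    p
  }
  stitched <- predict_core(value_stub, core, pp)
  direct <- ihcseg:::onehot_decode(value_stub(core))
  expect_identical(stitched$labels$raster, direct)

  # ties resolve to the lowest class index
  tie_stub <- function(tile) array(0.25, c(dim(tile)[1], dim(tile)[2], 4))
  ties <- predict_core(tie_stub, core, pp)
  expect_true(all(ties$labels$raster == 0L))

  # a core smaller than the patch is padded and cropped back
  small <- array(runif(40 * 40 * 3), c(40, 40, 3))
  out2 <- predict_core(const_stub, small, pp)
  expect_equal(dim(out2$labels$raster), c(40L, 40L))
})

test_that("trained-model inference stitches at the model input size", {
  model <- build_agunet(mini(), seed = 4)
  core <- array(runif(48 * 70 * 3), c(48, 70, 3))
  out <- predict_core(model, core, patch_params(patch_size = 64L))
  expect_equal(dim(out$prob), c(48L, 70L, 4L))
  expect_equal(apply(out$prob, c(1, 2), sum), matrix(1, 48, 70),
               tolerance = 1e-9)
})
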