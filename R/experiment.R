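# A complete scaled-down experiment on synthetic slides: generate, process,
# train, evaluate. This is the package's reference protocol for checking
# end-to-end recovery of the generator's ground truth on held-out cores.

#' Run the synthetic end-to-end experiment
#'
#' Generates three synthetic slide pairs (training, validation, test) under
#' the default study conditions, runs the full data-creation pipeline
#' (detection, pairing, registration, DAB masking, annotation rasterization,
#' ground-truth assembly) at x20, tiles 64 px patches, trains a miniature
#' attention-gated U-Net (filters 8, 16, 16, 32) on balanced, augmented
#' patches, and evaluates whole-core tiled predictions on the held-out test
#' slide with the per-core metric conventions.
#'
#' All randomness (slide content, initialization, sampling, augmentation)
#' derives from \code{seed}.
#'
#' @param seed master seed.
#' @param epochs training epochs (each 160 train / 40 validation updates).
#' @param batch_size patches per weight update.
#' @param verbose print per-epoch losses.
#' @return list of class \code{ihc_experiment}: \code{model} (trained
#'   \code{agunet}), \code{evaluation} (\code{ihc_evaluation} on test
#'   cores), \code{registration} (tibble of estimated vs true shifts per
#'   slide), \code{n_patches}, \code{seeds}.
#' @export
run_synthetic_experiment <- function(seed = 1L, epochs = 16L, batch_size = 4L,
                                     verbose = FALSE) {
  seed <- as.integer(seed)
  seeds <- list(train = seed * 1000L + 1L, val = seed * 1000L + 2L,
                test = seed * 1000L + 3L)
  pp <- patch_params(patch_size = 64L)
  # slides are generated and processed one at a time: the full pyramids are
  # large and only the per-core records are needed afterwards
  recs <- list()
  reg <- list()
  for (nm in names(seeds)) {
    sl <- generate_slide_pair(synth_config(seed = seeds[[nm]]))
    r <- process_slide_pair(sl$he, sl$ck, sl$annotations, magnification = "x20")
    reg[[nm]] <- tibble::tibble(
      slide = nm,
      dx_est = vapply(r, function(x) x$shift$dx, integer(1)),
      dy_est = vapply(r, function(x) x$shift$dy, integer(1)),
      dx_true = -sl$layout$shift[1], dy_true = -sl$layout$shift[2])
    recs[[nm]] <- lapply(r, function(x) { x$ck <- NULL; x$mask <- NULL; x })
    rm(sl, r)
    gc(FALSE)
  }
  reg <- dplyr::bind_rows(reg)
  p_train <- patches_from_records(recs$train, pp)
  p_val <- patches_from_records(recs$val, pp)

  mc <- miniature_config()
  # single-head miniature: with the short schedule, equal-weight deep
  # supervision starves the full-resolution head (see the methods vignette)
  mc$deep_supervision <- FALSE
  model <- build_agunet(mc, seed = seed)
  cfg <- train_config(max_epochs = as.integer(epochs),
                      batch_size = as.integer(batch_size),
                      selection = "hard_dice", seed = seed)
  set.seed(seed)
  model <- train_agunet(model, balanced_sampler(p_train),
                        balanced_sampler(p_val), cfg,
                        augment_cfg = augment_config(shift_max_px = 8L),
                        verbose = verbose)
  pairs <- lapply(recs$test, function(rec) {
    pred <- predict_core(model, rec$he, pp)
    list(pred = pred$labels, gt = rec$gt$labels, core_ref = rec$core_ref,
         case_id = rec$case_id)
  })
  ev <- evaluate_cores(pairs)
  structure(list(model = model, evaluation = ev, registration = reg,
                 n_patches = c(train = length(p_train), val = length(p_val)),
                 seeds = seeds),
            class = "ihc_experiment")
}

#' @export
print.ihc_experiment <- function(x, ...) {
  cat("<ihc_experiment>\n")
  print(x$evaluation$rows[x$evaluation$rows$row == "III",
                          c("class", "n", "dice_mean", "dice_sd")])
  invisible(x)
}
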