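# Attention-gated U-Net: configurable architecture (the full-size
# configuration or a miniature for CPU-scale work), soft Dice loss, training
# loop with plateau learning-rate decay and early stopping, and tiled
# whole-core inference with probability stitching.

#' AGU-Net architecture configuration
#'
#' The default is the full-size network: seven spatial levels with
#' 16, 32, 32, 64, 64, 128, 128 filters, multiscale input (downscaled copies
#' of the input concatenated at each encoder level), attention-gated skip
#' connections and deep supervision (auxiliary softmax heads at decoder
#' levels, averaged into the loss). \code{miniature_config()} gives a
#' CPU-friendly instance of the same design.
#'
#' @param spatial_levels number of resolution levels.
#' @param filters_per_level integer vector, one entry per level.
#' @param multiscale_input,deep_supervision,attention_gates feature switches.
#' @param n_classes output classes (4).
#' @param input_size c(height, width, channels); height and width must be
#'   divisible by 2^(spatial_levels - 1).
#' @export
model_config <- function(spatial_levels = 7L,
                         filters_per_level = c(16L, 32L, 32L, 64L, 64L, 128L, 128L),
                         multiscale_input = TRUE, deep_supervision = TRUE,
                         attention_gates = TRUE, n_classes = 4L,
                         input_size = c(1024L, 1024L, 3L)) {
  if (length(filters_per_level) != spatial_levels)
    stop("filters_per_level must have one entry per spatial level")
  div <- 2^(spatial_levels - 1L)
  if (input_size[1] %% div != 0 || input_size[2] %% div != 0)
    stop("input size must be divisible by 2^(spatial_levels - 1) = ", div)
  structure(list(spatial_levels = as.integer(spatial_levels),
                 filters_per_level = as.integer(filters_per_level),
                 multiscale_input = multiscale_input,
                 deep_supervision = deep_supervision,
                 attention_gates = attention_gates,
                 n_classes = as.integer(n_classes),
                 input_size = as.integer(input_size)),
            class = "model_config")
}

#' Miniature AGU-Net configuration for CPU-scale training
#' @param input_size input patch size (default 64 x 64 x 3).
#' @param filters filters per level.
#' @export
miniature_config <- function(input_size = c(64L, 64L, 3L),
                             filters = c(4L, 8L, 8L, 16L)) {
  model_config(spatial_levels = length(filters), filters_per_level = filters,
               input_size = as.integer(input_size))
}

#' Training configuration
#'
#' Defaults follow the reference schedule: Adam with initial learning rate
#' 5e-4, halved after every 10 epochs without validation improvement; up to
#' 500 epochs with early-stopping patience 200; an epoch is 160 training and
#' 40 validation weight updates; soft Dice loss over the foreground classes.
#'
#' @param lr0 initial learning rate.
#' @param lr_decay_factor multiplicative decay on plateau.
#' @param lr_patience_epochs epochs without improvement before decay.
#' @param max_epochs,early_stop_patience stopping rule.
#' @param train_updates_per_epoch,val_updates_per_epoch epoch definition.
#' @param batch_size patches per weight update.
#' @param loss_include_background include the background plane in the soft
#'   Dice loss (default FALSE, mirroring the evaluation's disregard of the
#'   background class; config switch).
#' @param selection criterion for which epoch's weights are retained:
#'   \code{"loss"} (lowest validation soft-Dice loss, default) or
#'   \code{"hard_dice"} (highest validation argmax macro-Dice over the
#'   foreground classes — robust when the soft loss is a poor proxy for
#'   argmax quality). The plateau schedule and early stopping always follow
#'   the validation loss.
#' @param seed RNG seed governing initialization, sampling and augmentation.
#' @export
train_config <- function(lr0 = 5e-4, lr_decay_factor = 0.5,
                         lr_patience_epochs = 10L, max_epochs = 500L,
                         early_stop_patience = 200L,
                         train_updates_per_epoch = 160L,
                         val_updates_per_epoch = 40L,
                         batch_size = 8L, loss_include_background = FALSE,
                         selection = c("loss", "hard_dice"),
                         seed = 42L) {
  stopifnot(lr0 > 0, lr_decay_factor > 0, lr_patience_epochs >= 1,
            max_epochs >= 1, early_stop_patience >= 1, batch_size >= 1,
            lr_patience_epochs < early_stop_patience)
  structure(list(lr0 = lr0, lr_decay_factor = lr_decay_factor,
                 lr_patience_epochs = as.integer(lr_patience_epochs),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 train_updates_per_epoch = as.integer(train_updates_per_epoch),
                 val_updates_per_epoch = as.integer(val_updates_per_epoch),
                 batch_size = as.integer(batch_size),
                 loss_include_background = loss_include_background,
                 selection = match.arg(selection),
                 seed = as.integer(seed)),
            class = "train_config")
}

he_init <- function(nin, nout, shape) {
  array(stats::rnorm(prod(shape), sd = sqrt(2 / nin)), shape)
}

#' Build an attention-gated U-Net
#'
#' Initializes all weights (He-normal, deterministic from \code{seed}) for
#' the encoder (two 3x3 conv + ReLU blocks per level, 2x2 max pooling,
#' optional multiscale input concatenation), the additive attention gates
#' (coarser decoder signal gating the skip features through a sigmoid), the
#' decoder (nearest-neighbour upsampling, gated-skip concatenation, two conv
#' blocks) and the 1x1 softmax heads (one per decoder level under deep
#' supervision, else the final head only).
#'
#' @param cfg \code{model_config}.
#' @param seed integer seed for the initialization.
#' @return object of class \code{agunet} holding the parameter list and
#'   config.
#' @export
build_agunet <- function(cfg = model_config(), seed = 42L) {
  set.seed(seed)
  L <- cfg$spatial_levels
  f <- cfg$filters_per_level
  Cin0 <- cfg$input_size[3]
  params <- list()
  add_conv3 <- function(name, cin, cout) {
    params[[paste0(name, "_W")]] <<- he_init(9 * cin, cout, c(9 * cin, cout))
    params[[paste0(name, "_b")]] <<- numeric(cout)
  }
  add_conv1 <- function(name, cin, cout) {
    params[[paste0(name, "_W")]] <<- he_init(cin, cout, c(cin, cout))
    params[[paste0(name, "_b")]] <<- numeric(cout)
  }
  for (i in seq_len(L)) {
    cin <- if (i == 1L) Cin0 else f[i - 1L] + (if (cfg$multiscale_input) Cin0 else 0L)
    add_conv3(sprintf("enc%d_c1", i), cin, f[i])
    add_conv3(sprintf("enc%d_c2", i), f[i], f[i])
  }
  for (i in seq_len(L - 1L)) {
    up_ch <- f[i + 1L]
    if (cfg$attention_gates) {
      fa <- max(4L, f[i] %/% 2L)
      add_conv1(sprintf("att%d_g", i), up_ch, fa)
      add_conv1(sprintf("att%d_x", i), f[i], fa)
      add_conv1(sprintf("att%d_psi", i), fa, 1L)
    }
    add_conv3(sprintf("dec%d_c1", i), up_ch + f[i], f[i])
    add_conv3(sprintf("dec%d_c2", i), f[i], f[i])
  }
  heads <- if (cfg$deep_supervision) seq_len(L - 1L) else 1L
  for (i in heads) add_conv1(sprintf("head%d", i), f[i], cfg$n_classes)
  structure(list(cfg = cfg, params = params, seed = seed,
                 counters = list(train_steps = 0L, val_passes = 0L)),
            class = "agunet")
}

#' @export
print.agunet <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<agunet %d levels [%s]  %s params%s%s%s>\n",
              x$cfg$spatial_levels,
              paste(x$cfg$filters_per_level, collapse = ","),
              format(np, big.mark = ","),
              if (x$cfg$attention_gates) " +attention" else "",
              if (x$cfg$deep_supervision) " +deepsup" else "",
              if (x$cfg$multiscale_input) " +multiscale" else ""))
  invisible(x)
}

# Forward pass on the tape. Returns node ids for the final logits and (when a
# target is given) the averaged deep-supervision loss.
agunet_graph <- function(tp, model, x, target = NULL,
                         include_background = FALSE) {
  cfg <- model$cfg
  L <- cfg$spatial_levels
  P <- lapply(model$params, function(p) tape_leaf(tp, p))
  conv_block <- function(h, name) {
    h <- op_relu(tp, op_conv3x3(tp, h, P[[paste0(name, "_c1_W")]],
                                P[[paste0(name, "_c1_b")]]))
    op_relu(tp, op_conv3x3(tp, h, P[[paste0(name, "_c2_W")]],
                           P[[paste0(name, "_c2_b")]]))
  }
  # multiscale copies of the input
  downs <- list(x)
  if (cfg$multiscale_input && L > 1L)
    for (i in 2:L) downs[[i]] <- block_mean(downs[[i - 1L]], 2L)
  enc <- vector("list", L)
  h <- tape_leaf(tp, x)
  for (i in seq_len(L)) {
    if (i > 1L) {
      h <- op_maxpool2(tp, h)
      if (cfg$multiscale_input)
        h <- op_concat(tp, h, tape_leaf(tp, downs[[i]]))
    }
    h <- conv_block(h, sprintf("enc%d", i))
    enc[[i]] <- h
  }
  dec <- vector("list", L)
  dec[[L]] <- enc[[L]]
  for (i in seq.int(L - 1L, 1L)) {
    up <- op_upnn2(tp, dec[[i + 1L]])
    skip <- enc[[i]]
    if (cfg$attention_gates) {
      g1 <- op_conv1x1(tp, up, P[[sprintf("att%d_g_W", i)]],
                       P[[sprintf("att%d_g_b", i)]])
      x1 <- op_conv1x1(tp, skip, P[[sprintf("att%d_x_W", i)]],
                       P[[sprintf("att%d_x_b", i)]])
      a <- op_sigmoid(tp, op_conv1x1(tp, op_relu(tp, op_add(tp, g1, x1)),
                                     P[[sprintf("att%d_psi_W", i)]],
                                     P[[sprintf("att%d_psi_b", i)]]))
      skip <- op_gate(tp, skip, a)
    }
    dec[[i]] <- conv_block(op_concat(tp, up, skip), sprintf("dec%d", i))
  }
  head_levels <- if (cfg$deep_supervision) seq_len(L - 1L) else 1L
  logits <- list()
  for (i in head_levels)
    logits[[i]] <- op_conv1x1(tp, dec[[i]], P[[sprintf("head%d_W", i)]],
                              P[[sprintf("head%d_b", i)]])
  loss <- NULL
  if (!is.null(target)) {
    losses <- integer(0)
    lab_full <- onehot_decode(target)
    for (i in head_levels) {
      s <- 2L^(i - 1L)
      t_i <- if (s == 1L) target else
        onehot_encode(lab_full[seq.int(1L, nrow(lab_full), s),
                               seq.int(1L, ncol(lab_full), s), drop = FALSE],
                      cfg$n_classes)
      losses <- c(losses, op_dice_loss(tp, logits[[i]], t_i,
                                       include_background = include_background))
    }
    loss <- if (length(losses) > 1L) op_mean_scalars(tp, losses) else losses[1]
  }
  list(P = P, logits_final = logits[[1]], loss = loss)
}

#' Forward pass of an AGU-Net on one patch
#'
#' @param model \code{agunet}.
#' @param x [H, W, C] input patch (intensities in [0, 1]).
#' @param target optional [H, W, K] one-hot ground truth; when given, the
#'   averaged deep-supervision Dice loss and parameter gradients are
#'   returned.
#' @param include_background include the background plane in the loss.
#' @return list with \code{prob} ([H, W, K] softmax output), and, with a
#'   target, \code{loss} and \code{grads}.
#' @export
agunet_forward <- function(model, x, target = NULL,
                           include_background = FALSE) {
  tp <- tape_new()
  g <- agunet_graph(tp, model, x, target, include_background)
  prob <- if (is.null(target)) op_softmax(tp, g$logits_final)
          else attr(tp$val[[if (model$cfg$deep_supervision)
                              tp$parents[[g$loss]][1] else g$loss]], "prob")
  out <- list(prob = prob)
  if (!is.null(target)) {
    tape_backward(tp, g$loss)
    grads <- lapply(g$P, function(id) tp$grad[[id]])
    names(grads) <- names(model$params)
    out$loss <- tp$val[[g$loss]]
    out$grads <- grads
  }
  out
}

#' Soft multiclass Dice loss
#'
#' loss = 1 - mean over (foreground) classes of
#' (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps).
#'
#' @param pred [H, W, K] softmax probabilities (or hard one-hot).
#' @param target [H, W, K] one-hot partition.
#' @param include_background include class 1 in the mean (default FALSE,
#'   matching evaluation's disregard of the background class).
#' @param eps smoothing constant.
#' @export
dice_loss <- function(pred, target, include_background = FALSE, eps = 1e-6) {
  if (!all(dim(pred) == dim(target))) stop("pred/target shape mismatch")
  K <- dim(pred)[3]
  p <- matrix(pred, ncol = K); t <- matrix(target, ncol = K)
  fg <- if (include_background) seq_len(K) else 2:K
  num <- 2 * colSums(p * t)[fg] + eps
  den <- (colSums(p) + colSums(t))[fg] + eps
  1 - mean(num / den)
}

#' One plateau-scheduler step
#'
#' Pure schedule logic, exposed for instrumentation: strict improvement
#' resets the counters; \code{lr_patience_epochs} consecutive epochs without
#' improvement halve the learning rate (factor \code{lr_decay_factor});
#' \code{early_stop_patience} epochs without improvement request a stop.
#'
#' @param state list with \code{best}, \code{lr}, \code{since_improve},
#'   \code{since_decay}; create with \code{lr_state(cfg)}.
#' @param val_loss this epoch's validation loss.
#' @param cfg \code{train_config}.
#' @return updated state with \code{improved} and \code{stop} flags.
#' @export
lr_schedule_step <- function(state, val_loss, cfg) {
  state$improved <- val_loss < state$best
  if (state$improved) {
    state$best <- val_loss
    state$since_improve <- 0L
    state$since_decay <- 0L
  } else {
    state$since_improve <- state$since_improve + 1L
    state$since_decay <- state$since_decay + 1L
    if (state$since_decay >= cfg$lr_patience_epochs) {
      state$lr <- state$lr * cfg$lr_decay_factor
      state$since_decay <- 0L
    }
  }
  state$stop <- state$since_improve >= cfg$early_stop_patience
  state
}

#' @rdname lr_schedule_step
#' @export
lr_state <- function(cfg) {
  list(best = Inf, lr = cfg$lr0, since_improve = 0L, since_decay = 0L,
       improved = FALSE, stop = FALSE)
}

#' Train an AGU-Net on balanced patch streams
#'
#' Per epoch: exactly \code{train_updates_per_epoch} Adam steps (each on a
#' batch drawn from \code{train_sampler}, optionally augmented) and
#' \code{val_updates_per_epoch} validation forward passes. The learning rate
#' halves after \code{lr_patience_epochs} epochs without validation
#' improvement; training stops at \code{max_epochs} or after
#' \code{early_stop_patience} epochs without improvement. The
#' best-validation weights are retained.
#'
#' @param model \code{agunet}.
#' @param train_sampler,val_sampler samplers from
#'   \code{\link{balanced_sampler}}.
#' @param cfg \code{train_config}.
#' @param augment_cfg optional \code{augment_config}; \code{NULL} disables
#'   augmentation.
#' @param verbose print one line per epoch.
#' @return the trained model with \code{history} (tibble: epoch, train_loss,
#'   val_loss, lr, improved) and updated step counters; best weights in
#'   \code{$params}.
#' @export
train_agunet <- function(model, train_sampler, val_sampler,
                         cfg = train_config(), augment_cfg = NULL,
                         verbose = FALSE) {
  set.seed(cfg$seed)
  params <- model$params
  opt <- adam_new(params)
  sched <- lr_state(cfg)
  best_params <- params
  best_hard <- -Inf
  hist <- list()
  for (epoch in seq_len(cfg$max_epochs)) {
    tr_losses <- numeric(cfg$train_updates_per_epoch)
    for (step in seq_len(cfg$train_updates_per_epoch)) {
      batch <- train_sampler(cfg$batch_size)
      if (!is.null(augment_cfg)) batch <- lapply(batch, augment, cfg = augment_cfg)
      gsum <- NULL; lsum <- 0
      for (rec in batch) {
        model$params <- params
        fw <- agunet_forward(model, rec$he, rec$onehot,
                             include_background = cfg$loss_include_background)
        if (!is.finite(fw$loss))
          stop("non-finite loss at epoch ", epoch, " step ", step)
        lsum <- lsum + fw$loss
        gsum <- if (is.null(gsum)) fw$grads
                else mapply(`+`, gsum, fw$grads, SIMPLIFY = FALSE)
      }
      grads <- lapply(gsum, `/`, length(batch))
      st <- adam_step(opt, params, grads, lr = sched$lr)
      opt <- st$state; params <- st$params
      tr_losses[step] <- lsum / length(batch)
      model$counters$train_steps <- model$counters$train_steps + 1L
    }
    val_losses <- numeric(cfg$val_updates_per_epoch)
    hd_acc <- c(num = 0, n = 0)
    model$params <- params
    for (step in seq_len(cfg$val_updates_per_epoch)) {
      batch <- val_sampler(cfg$batch_size)
      vl <- vapply(batch, function(rec) {
        fw <- agunet_forward(model, rec$he, rec$onehot,
                             include_background = cfg$loss_include_background)
        if (cfg$selection == "hard_dice") {
          pred <- onehot_decode(fw$prob)
          gt <- onehot_decode(rec$onehot)
          for (k in 1:3) {
            a <- pred == k; b <- gt == k
            if (sum(a) + sum(b) > 0) {
              hd_acc <<- hd_acc + c(2 * sum(a & b) / (sum(a) + sum(b)), 1)
            }
          }
        }
        fw$loss
      }, numeric(1))
      val_losses[step] <- mean(vl)
      model$counters$val_passes <- model$counters$val_passes + 1L
    }
    vloss <- mean(val_losses)
    vhard <- if (hd_acc[["n"]] > 0) hd_acc[["num"]] / hd_acc[["n"]] else 0
    sched <- lr_schedule_step(sched, vloss, cfg)
    if (cfg$selection == "hard_dice") {
      if (vhard > best_hard) { best_hard <- vhard; best_params <- params }
    } else if (sched$improved) best_params <- params
    hist[[epoch]] <- tibble::tibble(epoch = epoch,
                                    train_loss = mean(tr_losses),
                                    val_loss = vloss,
                                    val_hard_dice = vhard,
                                    lr = sched$lr,
                                    improved = sched$improved)
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2e%s",
                      epoch, mean(tr_losses), vloss, sched$lr,
                      if (sched$improved) " *" else ""))
    if (sched$stop) break
  }
  model$params <- best_params
  model$history <- dplyr::bind_rows(hist)
  model$best_val_loss <- sched$best
  model
}

#' Tiled whole-core inference with probability stitching
#'
#' Tiles the core with the inference overlap (default 30%), clamping edge
#' tiles to the image; per-pixel softmax probabilities are averaged over all
#' covering tiles, and the final label is the argmax with ties resolved to
#' the lower class index. A core smaller than the patch size is padded with
#' background and cropped back.
#'
#' @param model trained \code{agunet} (or any function(tile) -> [H, W, K]
#'   probability array, accepted for stitching checks).
#' @param core [H, W, 3] HE raster.
#' @param params \code{patch_params}; the model's input size overrides
#'   \code{patch_size}.
#' @param overlap overlap fraction (default
#'   \code{params$inference_overlap_fraction}).
#' @return list: \code{labels} (\code{label_map}), \code{prob} ([H, W, K]).
#' @export
predict_core <- function(model, core, params = patch_params(), overlap = NULL) {
  is_stub <- is.function(model)
  ps <- if (is_stub) params$patch_size else model$cfg$input_size[1]
  K <- if (is_stub) 4L else model$cfg$n_classes
  ov <- overlap %||% params$inference_overlap_fraction
  h <- dim(core)[1]; w <- dim(core)[2]
  ph <- max(h, ps); pw <- max(w, ps)
  padded <- ph > h || pw > w
  if (padded) {
    cp <- array(1, c(ph, pw, dim(core)[3]))
    cp[seq_len(h), seq_len(w), ] <- core
    core <- cp
  }
  tile_p <- structure(list(patch_size = as.integer(ps),
                           overlap_fraction = ov), class = "patch_params")
  wins <- tile_core(c(ph, pw), tile_p)
  psum <- array(0, c(ph, pw, K))
  cnt <- matrix(0, ph, pw)
  for (i in seq_len(nrow(wins))) {
    win <- c(wins$x0[i], wins$y0[i], wins$x1[i], wins$y1[i])
    tile <- crop_window(core, win)
    prob <- if (is_stub) model(tile) else agunet_forward(model, tile)$prob
    rows <- (win[2] + 1L):win[4]; cols <- (win[1] + 1L):win[3]
    psum[rows, cols, ] <- psum[rows, cols, , drop = FALSE] + prob
    cnt[rows, cols] <- cnt[rows, cols] + 1
  }
  prob <- psum / array(rep(cnt, K), dim(psum))
  prob <- prob[seq_len(h), seq_len(w), , drop = FALSE]
  lab <- onehot_decode(prob)
  list(labels = label_map(lab), prob = prob)
}

#' @method tidy agunet
#' @export
tidy.agunet <- function(x, ...) {
  if (is.null(x$history)) return(tibble::tibble())
  x$history
}

#' @method glance agunet
#' @export
glance.agunet <- function(x, ...) {
  tibble::tibble(
    n_parameters = sum(vapply(x$params, length, numeric(1))),
    spatial_levels = x$cfg$spatial_levels,
    epochs_trained = if (is.null(x$history)) 0L else nrow(x$history),
    best_val_loss = x$best_val_loss %||% NA_real_,
    train_steps = x$counters$train_steps,
    val_passes = x$counters$val_passes)
}
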