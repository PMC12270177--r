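# Reverse-mode differentiation tape over the handful of array operations the
# attention-gated U-Net needs: 3x3 and 1x1 convolutions (im2col + BLAS
# matmul), ReLU/sigmoid, 2x2 max pooling, nearest-neighbour 2x upsampling,
# channel concatenation, broadcast gating, and a fused softmax + soft-Dice
# loss. Tensors are [H, W, C] arrays; gradients mirror values.

.conv_cache <- new.env(parent = emptyenv())

# Linear indices realizing im2col for a 3x3 stencil with zero padding.
# Row order matches R's column-major pixel order; column block for channel c
# spans (c-1)*9 + k, k enumerating offsets so that the flipped stencil is
# k -> 10 - k.
im2col_indices <- function(H, W, C) {
  key <- paste(H, W, C, sep = "x")
  if (!is.null(.conv_cache[[key]])) return(.conv_cache[[key]])
  rr <- rep(seq_len(H), W)
  cc <- rep(seq_len(W), each = H)
  plane <- (H + 2L) * (W + 2L)
  idx <- matrix(0L, H * W, 9L * C)
  k <- 0L
  for (dx in -1:1) for (dy in -1:1) {
    k <- k + 1L
    base <- (rr + 1L + dy) + (cc + dx) * (H + 2L)
    for (ch in seq_len(C)) idx[, (ch - 1L) * 9L + k] <- base + (ch - 1L) * plane
  }
  .conv_cache[[key]] <- idx
  idx
}

im2col <- function(x) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- if (length(d) == 3L) d[3] else 1L
  pz <- array(0, c(H + 2L, W + 2L, C))
  pz[2L:(H + 1L), 2L:(W + 1L), ] <- x
  cols <- pz[im2col_indices(H, W, C)]
  dim(cols) <- c(H * W, 9L * C)
  cols
}

# --- tape ------------------------------------------------------------------

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$val <- list(); tp$grad <- list(); tp$bw <- list(); tp$parents <- list()
  tp$n <- 0L
  tp
}

tape_node <- function(tp, value, parents = integer(0), bw = NULL) {
  tp$n <- tp$n + 1L
  id <- tp$n
  tp$val[[id]] <- value
  tp$grad[id] <- list(NULL)
  tp$bw[id] <- list(bw)
  tp$parents[[id]] <- parents
  id
}

tape_leaf <- function(tp, value) tape_node(tp, value)

tape_backward <- function(tp, loss_id) {
  tp$grad[[loss_id]] <- 1
  for (id in seq.int(loss_id, 1L)) {
    g <- tp$grad[[id]]
    if (is.null(g) || is.null(tp$bw[[id]])) next
    contribs <- tp$bw[[id]](g)
    ps <- tp$parents[[id]]
    for (j in seq_along(ps)) {
      p <- ps[j]
      if (is.null(contribs[[j]])) next
      tp$grad[[p]] <- if (is.null(tp$grad[[p]])) contribs[[j]]
                      else tp$grad[[p]] + contribs[[j]]
    }
  }
  invisible(tp)
}

# --- ops -------------------------------------------------------------------

op_conv3x3 <- function(tp, x, w, b) {
  force(x); force(w); force(b)
  xv <- tp$val[[x]]; wv <- tp$val[[w]]; bv <- tp$val[[b]]
  d <- dim(xv); H <- d[1]; W <- d[2]; Cin <- d[3]
  Cout <- ncol(wv)
  cols <- im2col(xv)
  y <- cols %*% wv
  y <- y + rep(bv, each = H * W)
  dim(y) <- c(H, W, Cout)
  tape_node(tp, y, c(x, w, b), function(g) {
    dim(g) <- c(H * W, Cout)
    dW <- crossprod(cols, g)
    db <- colSums(g)
    # dX = conv of the upstream gradient with the spatially flipped,
    # channel-transposed kernel
    wa <- array(wv, c(9L, Cin, Cout))
    wf <- aperm(wa[9:1, , , drop = FALSE], c(1, 3, 2))
    dim(wf) <- c(9L * Cout, Cin)
    dim(g) <- c(H, W, Cout)
    dX <- im2col(g) %*% wf
    dim(dX) <- c(H, W, Cin)
    list(dX, dW, db)
  })
}

op_conv1x1 <- function(tp, x, w, b) {
  force(x); force(w); force(b)
  xv <- tp$val[[x]]; wv <- tp$val[[w]]; bv <- tp$val[[b]]
  d <- dim(xv); H <- d[1]; W <- d[2]; Cin <- d[3]; Cout <- ncol(wv)
  x2 <- xv
  dim(x2) <- c(H * W, Cin)
  y <- x2 %*% wv
  y <- y + rep(bv, each = H * W)
  dim(y) <- c(H, W, Cout)
  tape_node(tp, y, c(x, w, b), function(g) {
    dim(g) <- c(H * W, Cout)
    dX <- g %*% t(wv)
    dim(dX) <- c(H, W, Cin)
    list(dX, crossprod(x2, g), colSums(g))
  })
}

op_relu <- function(tp, x) {
  force(x)
  xv <- tp$val[[x]]
  m <- xv > 0
  tape_node(tp, xv * m, x, function(g) list(g * m))
}

op_sigmoid <- function(tp, x) {
  force(x)
  s <- 1 / (1 + exp(-tp$val[[x]]))
  tape_node(tp, s, x, function(g) list(g * s * (1 - s)))
}

op_add <- function(tp, a, b) {
  force(a); force(b)
  tape_node(tp, tp$val[[a]] + tp$val[[b]], c(a, b), function(g) list(g, g))
}

# x [H,W,C] gated by a [H,W,1]
op_gate <- function(tp, x, a) {
  force(x); force(a)
  xv <- tp$val[[x]]; av <- tp$val[[a]]
  C <- dim(xv)[3]
  am <- array(rep(av, C), dim(xv))
  tape_node(tp, xv * am, c(x, a), function(g) {
    da <- rowSums(g * xv, dims = 2L)
    list(g * am, array(da, dim(av)))
  })
}

op_maxpool2 <- function(tp, x) {
  force(x)
  xv <- tp$val[[x]]
  d <- dim(xv); H <- d[1]; W <- d[2]; C <- d[3]
  oi <- seq.int(1L, H, 2L); ei <- seq.int(2L, H, 2L)
  oj <- seq.int(1L, W, 2L); ej <- seq.int(2L, W, 2L)
  a11 <- xv[oi, oj, , drop = FALSE]; a21 <- xv[ei, oj, , drop = FALSE]
  a12 <- xv[oi, ej, , drop = FALSE]; a22 <- xv[ei, ej, , drop = FALSE]
  m1 <- pmax(a11, a21); s1 <- a21 > a11
  m2 <- pmax(a12, a22); s2 <- a22 > a12
  y <- pmax(m1, m2); sc <- m2 > m1
  tape_node(tp, y, x, function(g) {
    dx <- array(0, d)
    g1 <- g * !sc; g2 <- g * sc
    dx[oi, oj, ] <- g1 * !s1
    dx[ei, oj, ] <- g1 * s1
    dx[oi, ej, ] <- g2 * !s2
    dx[ei, ej, ] <- g2 * s2
    list(dx)
  })
}

op_upnn2 <- function(tp, x) {
  force(x)
  xv <- tp$val[[x]]
  d <- dim(xv); h <- d[1]; w <- d[2]
  y <- xv[rep(seq_len(h), each = 2L), rep(seq_len(w), each = 2L), , drop = FALSE]
  tape_node(tp, y, x, function(g) {
    oi <- seq.int(1L, 2L * h, 2L); ei <- oi + 1L
    oj <- seq.int(1L, 2L * w, 2L); ej <- oj + 1L
    list(g[oi, oj, , drop = FALSE] + g[ei, oj, , drop = FALSE] +
         g[oi, ej, , drop = FALSE] + g[ei, ej, , drop = FALSE])
  })
}

op_concat <- function(tp, a, b) {
  force(a); force(b)
  av <- tp$val[[a]]; bv <- tp$val[[b]]
  Ca <- dim(av)[3]; Cb <- dim(bv)[3]
  y <- array(c(av, bv), c(dim(av)[1], dim(av)[2], Ca + Cb))
  tape_node(tp, y, c(a, b), function(g) {
    list(g[, , seq_len(Ca), drop = FALSE],
         g[, , Ca + seq_len(Cb), drop = FALSE])
  })
}

# Fused softmax over channels + soft-Dice loss against a one-hot target.
# Stores the softmax probabilities as an attribute for retrieval.
op_dice_loss <- function(tp, logits, target, include_background = FALSE,
                         eps = 1e-6) {
  force(logits)
  zv <- tp$val[[logits]]
  d <- dim(zv); K <- d[3]
  zm <- zv
  dim(zm) <- c(d[1] * d[2], K)
  mx <- zm[, 1]
  for (k in 2:K) mx <- pmax(mx, zm[, k])
  e <- exp(zm - mx)
  p <- e / rowSums(e)
  tm <- target
  dim(tm) <- c(d[1] * d[2], K)
  fg <- if (include_background) seq_len(K) else 2:K
  num <- 2 * colSums(p * tm)[fg] + eps
  den <- (colSums(p) + colSums(tm))[fg] + eps
  loss <- 1 - mean(num / den)
  id <- tape_node(tp, loss, logits, function(g) {
    dLdp <- matrix(0, nrow(p), K)
    for (j in seq_along(fg)) {
      c <- fg[j]
      dLdp[, c] <- -(2 * tm[, c] * den[j] - num[j]) / (den[j]^2 * length(fg))
    }
    dz <- p * (dLdp - rowSums(p * dLdp))
    list(array(g * dz, d))
  })
  attr(tp$val[[id]], "prob") <- array(p, d)
  id
}

op_softmax <- function(tp, logits) {
  zv <- tp$val[[logits]]
  d <- dim(zv); K <- d[3]
  zm <- zv
  dim(zm) <- c(d[1] * d[2], K)
  mx <- zm[, 1]
  for (k in 2:K) mx <- pmax(mx, zm[, k])
  e <- exp(zm - mx)
  p <- e / rowSums(e)
  dim(p) <- d
  p                              # value only; inference path, no grad needed
}

op_mean_scalars <- function(tp, ids) {
  force(ids)
  vals <- vapply(ids, function(i) tp$val[[i]], numeric(1))
  n <- length(ids)
  tape_node(tp, mean(vals), ids, function(g) as.list(rep(g / n, n)))
}

# --- Adam ------------------------------------------------------------------

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(state = state, params = params)
}
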