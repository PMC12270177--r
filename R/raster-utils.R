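# Low-level raster helpers shared across the pipeline.
#
# Conventions (global to the package): rasters are numeric matrices [row, col]
# or arrays [row, col, channel]; x = column, y = row, origin top-left; windows
# are 0-based half-open [x0, x1) x [y0, y1) at pyramid level 0 unless a level
# is stated. Image intensities live in [0, 1] (8-bit scale / 255).

#' Connected-component labelling of a binary matrix
#'
#' Run-based two-pass labelling with union-find, supporting both 4- and
#' 8-connectivity. Used for hole filling (4-connectivity) and small-object
#' removal (8-connectivity) in mask cleaning, and for flood-fill region
#' extraction during TMA core detection.
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of the same shape; 0 = background, components
#'   labelled 1..n in first-encounter order.
#' @keywords internal
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4L, 8L))
  m <- mask > 0
  nr <- nrow(m); nc <- ncol(m)
  if (!any(m)) return(matrix(0L, nr, nc))

  # Runs of consecutive foreground pixels within each column-major "row" would
  # complicate indexing; work row-wise on the transposed view so runs are
  # contiguous in memory.
  mt <- t(m)                                  # [col, row] => rows of the image are columns here
  v <- as.vector(mt)                          # image row-major order
  n <- length(v)
  d <- diff(c(FALSE, v, FALSE))
  starts <- which(d == 1L)
  ends <- which(d == -1L) - 1L
  # Split runs that span image-row boundaries
  row_of <- function(i) (i - 1L) %/% nc       # 0-based image row
  keep_s <- starts; keep_e <- ends
  # A run crossing a row boundary must be cut at every multiple of nc.
  cut_s <- integer(0); cut_e <- integer(0)
  cross <- which(row_of(keep_s) != row_of(keep_e))
  if (length(cross)) {
    for (i in cross) {
      s <- keep_s[i]; e <- keep_e[i]
      b <- seq.int(row_of(s) + 1L, row_of(e)) * nc  # first index of each later row
      ss <- c(s, b + 1L); ee <- c(b, e)
      cut_s <- c(cut_s, ss); cut_e <- c(cut_e, ee)
    }
    keep_s <- keep_s[-cross]; keep_e <- keep_e[-cross]
  }
  rs <- c(keep_s, cut_s); re <- c(keep_e, cut_e)
  o <- order(rs)
  rs <- rs[o]; re <- re[o]
  nruns <- length(rs)
  run_row <- row_of(rs)
  run_c0 <- (rs - 1L) %% nc                   # 0-based start col
  run_c1 <- (re - 1L) %% nc                   # 0-based end col

  parent <- seq_len(nruns)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  slack <- if (connectivity == 8L) 1L else 0L
  # Union runs on adjacent rows whose column spans touch.
  by_row <- split(seq_len(nruns), run_row)
  rows_present <- as.integer(names(by_row))
  idx_of_row <- function(r) {
    k <- match(r, rows_present)
    if (is.na(k)) integer(0) else by_row[[k]]
  }
  for (r in rows_present) {
    cur <- idx_of_row(r); prev <- idx_of_row(r - 1L)
    if (!length(prev)) next
    for (i in cur) {
      for (j in prev) {
        if (run_c0[i] <= run_c1[j] + slack && run_c1[i] >= run_c0[j] - slack) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  root <- vapply(seq_len(nruns), find, integer(1))
  lab_of_root <- integer(nruns)
  nxt <- 0L
  run_lab <- integer(nruns)
  for (i in seq_len(nruns)) {
    r <- root[i]
    if (lab_of_root[r] == 0L) { nxt <- nxt + 1L; lab_of_root[r] <- nxt }
    run_lab[i] <- lab_of_root[r]
  }
  out_v <- integer(n)
  for (i in seq_len(nruns)) out_v[rs[i]:re[i]] <- run_lab[i]
  t(matrix(out_v, nc, nr))
}

#' Separable Gaussian smoothing with reflective borders
#'
#' @param x numeric matrix.
#' @param sigma standard deviation in pixels; the kernel is truncated at
#'   \code{ceiling(4 * sigma)}.
#' @return smoothed matrix of the same shape.
#' @keywords internal
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_reflect <- function(m, r, dim) {
    if (dim == 1L) {
      n <- nrow(m)
      ri <- pmin(pmax(c(rev(seq_len(r) + 1L), seq_len(n), n - seq_len(r)), 1L), n)
      m[ri, , drop = FALSE]
    } else {
      n <- ncol(m)
      ci <- pmin(pmax(c(rev(seq_len(r) + 1L), seq_len(n), n - seq_len(r)), 1L), n)
      m[, ci, drop = FALSE]
    }
  }
  conv_rows <- function(m) {
    p <- pad_reflect(m, r, 1L)
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) out <- out + k[i] * p[i:(i + nrow(m) - 1L), , drop = FALSE]
    out
  }
  conv_rows(t(conv_rows(t(x))))
}

#' Block-mean downsampling by an integer factor
#'
#' Trailing rows/columns that do not fill a whole block are dropped.
#' @param x matrix or [H, W, C] array.
#' @param factor integer >= 1.
#' @keywords internal
block_mean <- function(x, factor) {
  f <- as.integer(factor)
  if (f <= 1L) return(x)
  if (length(dim(x)) == 3L) {
    out <- vapply(seq_len(dim(x)[3]),
                  function(c) block_mean(x[, , c], f),
                  matrix(0, nrow(x) %/% f, ncol(x) %/% f))
    return(out)
  }
  nr <- (nrow(x) %/% f) * f
  nc <- (ncol(x) %/% f) * f
  x <- x[seq_len(nr), seq_len(nc), drop = FALSE]
  # average f rows, then f cols
  dim(x) <- c(f, nr %/% f, nc)
  x <- colMeans(x)
  x <- t(x)
  dim(x) <- c(f, nc %/% f, nr %/% f)
  t(colMeans(x))
}

#' Nearest-neighbour resize of a matrix to a target shape
#' @keywords internal
resize_nn <- function(x, nr, nc) {
  ri <- pmin(nrow(x), pmax(1L, ceiling(seq_len(nr) * nrow(x) / nr)))
  ci <- pmin(ncol(x), pmax(1L, ceiling(seq_len(nc) * ncol(x) / nc)))
  x[ri, ci, drop = FALSE]
}

#' Luminance grayscale of an RGB array
#' @param rgb [H, W, 3] array in [0, 1].
#' @keywords internal
to_gray <- function(rgb) {
  if (is.matrix(rgb)) return(rgb)
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

#' Histogram equalization of a grayscale raster
#'
#' Maps intensities through their empirical CDF on a 256-bin quantization;
#' used to lift contrast in weakly stained CK cores before registration.
#' @keywords internal
equalize_hist <- function(x) {
  q <- pmin(255L, pmax(0L, as.integer(round(x * 255))))
  tab <- tabulate(q + 1L, nbins = 256L)
  cdf <- cumsum(tab) / length(q)
  out <- cdf[q + 1L]
  matrix(out, nrow(x), ncol(x))
}

#' Crop a raster by a 0-based half-open window
#' @param x matrix or [H, W, C] array.
#' @param window c(x0, y0, x1, y1), 0-based half-open.
#' @keywords internal
crop_window <- function(x, window) {
  x0 <- window[1]; y0 <- window[2]; x1 <- window[3]; y1 <- window[4]
  stopifnot(x1 > x0, y1 > y0)
  rows <- (y0 + 1L):y1
  cols <- (x0 + 1L):x1
  if (length(dim(x)) == 3L) x[rows, cols, , drop = FALSE] else x[rows, cols, drop = FALSE]
}

#' Component areas of a labelled matrix
#' @keywords internal
component_areas <- function(labels) {
  pos <- labels[labels > 0L]
  if (!length(pos)) return(integer(0))
  tabulate(pos, nbins = max(pos))
}
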