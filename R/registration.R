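# Rigid translation between an HE core and its restained CK counterpart,
# estimated by integer-pixel phase cross-correlation at reduced scale and
# upscaled to full resolution.

#' Registration parameters
#'
#' @param downsample_factor block-mean downsampling applied before the
#'   correlation (memory saving; the estimated shift is multiplied back).
#' @param equalize_ck histogram-equalize the CK core first (lifts contrast in
#'   weakly stained tissue).
#' @param max_shift_frac sanity bound: shifts larger than this fraction of
#'   the core width (at full resolution) are rejected as registration
#'   failures and replaced by a zero shift with a warning.
#' @export
registration_params <- function(downsample_factor = 4L, equalize_ck = TRUE,
                                max_shift_frac = 0.10) {
  stopifnot(downsample_factor >= 1, max_shift_frac > 0)
  structure(list(downsample_factor = as.integer(downsample_factor),
                 equalize_ck = equalize_ck, max_shift_frac = max_shift_frac),
            class = "registration_params")
}

#' Integer-pixel phase cross-correlation peak
#'
#' Returns the translation (dx, dy) that moves \code{b} onto \code{a}.
#' @keywords internal
phase_correlate <- function(a, b) {
  fa <- stats::fft(a)
  fb <- stats::fft(b)
  cp <- fa * Conj(fb)
  mag <- Mod(cp)
  cp <- cp / pmax(mag, 1e-12)
  r <- Re(stats::fft(cp, inverse = TRUE))
  m <- which.max(r)
  i <- ((m - 1L) %% nrow(r))        # 0-based row lag
  j <- ((m - 1L) %/% nrow(r))       # 0-based col lag
  dy <- if (i > nrow(r) / 2) i - nrow(r) else i
  dx <- if (j > ncol(r) / 2) j - ncol(r) else j
  c(dx = dx, dy = dy)
}

#' Estimate the HE->CK shift of a core pair
#'
#' Both rasters are converted to luminance grayscale (if RGB); the CK core is
#' optionally histogram-equalized; both are block-mean downsampled; the
#' integer-pixel phase cross-correlation peak gives the shift at reduced
#' scale, which is multiplied back by the downsample factor. The returned
#' shift is the correction to apply to the CK raster so it aligns with HE
#' (\code{apply_shift(ck, shift)}).
#'
#' Degenerate (featureless) input yields a zero shift with a warning, as does
#' an estimate beyond the sanity bound.
#'
#' @param he,ck equal-size rasters (matrix or [H, W, 3]); a smaller raster is
#'   padded with background (white) to match.
#' @param params \code{registration_params}.
#' @return list of class \code{shift}: \code{dx}, \code{dy} at full
#'   resolution, plus \code{valid}.
#' @export
estimate_shift <- function(he, ck, params = registration_params()) {
  g_he <- to_gray(he); g_ck <- to_gray(ck)
  nr <- max(nrow(g_he), nrow(g_ck)); nc <- max(ncol(g_he), ncol(g_ck))
  pad_to <- function(m, nr, nc, fill = 1) {
    if (nrow(m) == nr && ncol(m) == nc) return(m)
    out <- matrix(fill, nr, nc)
    out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    out
  }
  g_he <- pad_to(g_he, nr, nc); g_ck <- pad_to(g_ck, nr, nc)
  if (stats::sd(g_he) < 1e-9 || stats::sd(g_ck) < 1e-9) {
    warning("featureless input; returning zero shift")
    return(new_shift(0, 0, valid = FALSE))
  }
  if (params$equalize_ck) g_ck <- equalize_hist(g_ck)
  f <- params$downsample_factor
  a <- block_mean(g_he, f); b <- block_mean(g_ck, f)
  s <- phase_correlate(a, b) * f
  max_shift <- params$max_shift_frac * nc
  if (abs(s["dx"]) > max_shift || abs(s["dy"]) > max_shift) {
    warning(sprintf("estimated shift (%d, %d) exceeds bound %.0f px; using (0, 0)",
                    s["dx"], s["dy"], max_shift))
    return(new_shift(0, 0, valid = FALSE))
  }
  new_shift(s[["dx"]], s[["dy"]])
}

new_shift <- function(dx, dy, valid = TRUE) {
  structure(list(dx = as.integer(round(dx)), dy = as.integer(round(dy)),
                 valid = valid), class = "shift")
}

#' @export
print.shift <- function(x, ...) {
  cat(sprintf("<shift dx=%d dy=%d%s>\n", x$dx, x$dy,
              if (x$valid) "" else " (invalid -> zero)"))
  invisible(x)
}

#' Apply an integer-pixel translation to a raster
#'
#' Content moves by (+dx, +dy) (columns, rows); vacated borders are filled
#' with \code{fill} (white 1 for images, 0 for masks / label maps). Output
#' size is unchanged.
#'
#' @param raster matrix or [H, W, C] array.
#' @param shift \code{shift} object (or c(dx, dy)).
#' @param fill border fill value; default 1 for double input, 0 for integer.
#' @export
apply_shift <- function(raster, shift, fill = NULL) {
  if (inherits(shift, "shift")) shift <- c(shift$dx, shift$dy)
  dx <- as.integer(shift[1]); dy <- as.integer(shift[2])
  if (is.null(fill)) fill <- if (is.integer(raster)) 0L else 1
  if (dx == 0L && dy == 0L) return(raster)
  d <- dim(raster)
  nr <- d[1]; nc <- d[2]
  shift_idx <- function(n, s) {
    src <- seq_len(n) - s
    ok <- src >= 1L & src <= n
    list(src = src[ok], dst = seq_len(n)[ok])
  }
  ri <- shift_idx(nr, dy); ci <- shift_idx(nc, dx)
  if (length(d) == 3L) {
    out <- array(fill, d)
    out[ri$dst, ci$dst, ] <- raster[ri$src, ci$src, , drop = FALSE]
  } else {
    out <- matrix(fill, nr, nc)
    out[ri$dst, ci$dst] <- raster[ri$src, ci$src, drop = FALSE]
  }
  if (is.integer(raster)) storage.mode(out) <- "integer"
  out
}

#' Second-pass refinement shift between an HE patch and its CK patch
#'
#' Identical contract to \code{\link{estimate_shift}}, applied at patch scale
#' after cores were registered, to absorb residual local displacement.
#' @inheritParams estimate_shift
#' @export
register_patch_pair <- function(he_patch, ck_patch,
                                params = registration_params()) {
  estimate_shift(he_patch, ck_patch, params)
}
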