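# Shared fixtures, built in code. Slide pairs are cached per config so the
# generator runs once per test session for each condition.

.fixture_cache <- new.env(parent = emptyenv())

small_synth_config <- function(seed = 3L, ...) {
  # 2x2 grid of 150 um cores with structures scaled to fit them
  synth_config(grid = c(2L, 2L), core_radius_um = 150,
               invasive_nests = 4L, benign_glands = 1L, insitu_ducts = 1L,
               nest_radius_um = c(20, 32), gland_radius_um = c(30, 45),
               duct_radius_um = c(38, 55), seed = seed, ...)
}

cached_slide_pair <- function(cfg) {
  key <- paste0("slide_", rlang::hash(unclass(cfg)))
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_slide_pair(cfg)
  .fixture_cache[[key]]
}

# a smooth random grayscale texture with enough structure for registration
textured_raster <- function(n = 128L, seed = 1L) {
  withr::with_seed(seed, {
    x <- matrix(stats::runif(n * n), n, n)
    ihcseg:::gaussian_blur(x, 2)
  })
}

# square polygon helper (counter-clockwise ring)
square_ring <- function(x0, y0, x1, y1) {
  rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
}

make_annotation <- function(ring, label, case_id = NULL, holes = list()) {
  list(geometry = list(outer = ring, holes = holes), label = label,
       case_id = case_id)
}

# brute-force pixel-centre rasterization oracle (independent of the scanline
# implementation): tests every pixel centre against every ring by winding
brute_rasterize <- function(polys, window) {
  w <- window[3] - window[1]; h <- window[4] - window[2]
  out <- matrix(0L, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    px <- window[1] + c - 0.5; py <- window[2] + r - 0.5
    for (p in polys) {
      if (ihcseg:::points_in_polygon(px, py, p)) { out[r, c] <- 1L; break }
    }
  }
  out
}
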