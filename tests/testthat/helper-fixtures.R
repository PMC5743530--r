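# Fixture builders and independent oracles shared across test files.

# Flat two-tone RGB raster: sky-coloured where `sky` is 1, canopy elsewhere.
two_tone_rgb <- function(sky, sky_col = c(0.45, 0.65, 0.9),
                         canopy_col = c(0.05, 0.15, 0.05)) {
  sky <- as.matrix(sky)
  arr <- array(0, dim = c(nrow(sky), ncol(sky), 3))
  for (ch in 1:3) {
    arr[, , ch] <- ifelse(sky != 0, sky_col[ch], canopy_col[ch])
  }
  arr
}

# Independent HSL -> RGB converter (standard bi-hexcone inverse), used to
# probe the membership score along controlled colour paths.
hsl_to_rgb <- function(h, s, l) {
  c <- (1 - abs(2 * l - 1)) * s
  x <- c * (1 - abs((h / 60) %% 2 - 1))
  m <- l - c / 2
  hp <- floor(h / 60) %% 6
  rgb1 <- switch(as.character(hp),
    "0" = c(c, x, 0), "1" = c(x, c, 0), "2" = c(0, c, x),
    "3" = c(0, x, c), "4" = c(x, 0, c), "5" = c(c, 0, x))
  pmin(1, pmax(0, rgb1 + m))
}

# Per-pixel solid-angle integration of canopy openness for a hemisphere
# raster: weight each in-disk pixel by sin(zenith) / r (equidistant
# area element), independent of the grid-based path.
pixel_openness_oracle <- function(h) {
  field <- direction_field(h$projection, dim(h$sky_mask))
  idx <- which(field$inside & field$zenith <= 90)
  zen <- field$zenith[idx]
  r <- zen / h$projection$max_zenith * h$projection$radius_px
  w <- ifelse(r > 0, sin(zen * pi / 180) / r, 0)
  sum(w * (h$sky_mask[idx] == 1)) / sum(w)
}

# Build a segmented hemisphere raster straight from a circular render's
# ground truth (bypassing thresholding).
truth_raster <- function(render) {
  hemisphere_raster(render$truth_sky, render$coverage, render$projection)
}

# A small open-sky circular raster with its projection.
open_sky_raster <- function(size = 200) {
  proj <- projection_model(c(size / 2, size / 2), size / 2)
  field <- direction_field(proj, c(size, size))
  hemisphere_raster(field$inside * 1L, field$inside * 1L, proj)
}
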