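#' Sky-grid container
#'
#' Per-cell gap fraction on a polar grid of azimuth sectors by zenith
#' annuli (default 24 x 18: 15-degree sectors, 5-degree equal-angle
#' annuli). Rows index annuli from the zenith outward, columns index
#' sectors clockwise from North. Annulus weights are the hemisphere
#' surface-area fractions `w_i = cos(theta_lower) - cos(theta_upper)`,
#' which sum to 1; each sector carries `w_i / n_azimuth`.
#'
#' @param gap_fraction `n_zenith x n_azimuth` matrix in `[0, 1]`.
#' @param pixel_count Matrix of the same shape; cells with zero pixels must
#'   carry gap fraction 0.
#' @param n_azimuth,n_zenith Grid dimensions.
#' @return An object of class `sky_grid` with fields `gap_fraction`,
#'   `pixel_count`, `weights`, `zenith_edges`, `azimuth_edges`.
#' @export
sky_grid <- function(gap_fraction, pixel_count = NULL, n_azimuth = 24,
                     n_zenith = 18) {
  gf <- as.matrix(gap_fraction)
  if (!identical(dim(gf), c(as.integer(n_zenith), as.integer(n_azimuth)))) {
    stop("'gap_fraction' must be an n_zenith x n_azimuth matrix")
  }
  if (any(gf < -1e-12) || any(gf > 1 + 1e-12)) {
    stop("gap fractions must lie in [0, 1]")
  }
  if (is.null(pixel_count)) pixel_count <- matrix(1L, n_zenith, n_azimuth)
  pc <- as.matrix(pixel_count)
  gf[pc == 0] <- 0
  zenith_edges <- seq(0, 90, length.out = n_zenith + 1)
  azimuth_edges <- seq(0, 360, length.out = n_azimuth + 1)
  weights <- cos(zenith_edges[-(n_zenith + 1)] * pi / 180) -
    cos(zenith_edges[-1] * pi / 180)
  structure(list(gap_fraction = pmax(pmin(gf, 1), 0), pixel_count = pc,
                 weights = weights, zenith_edges = zenith_edges,
                 azimuth_edges = azimuth_edges),
            class = "sky_grid")
}

#' @export
print.sky_grid <- function(x, ...) {
  cat(sprintf("<sky_grid> %d annuli x %d sectors; CO = %.4f\n",
              nrow(x$gap_fraction), ncol(x$gap_fraction), canopy_openness(x)))
  invisible(x)
}

#' Plot a sky grid as a polar gap-fraction map
#'
#' @param x A [sky_grid()].
#' @param ... Passed to [graphics::image()].
#' @export
plot.sky_grid <- function(x, ...) {
  graphics::image(x = x$zenith_edges, y = x$azimuth_edges,
                  z = x$gap_fraction, zlim = c(0, 1),
                  col = grDevices::gray.colors(64, start = 0, end = 1),
                  xlab = "zenith (deg)", ylab = "azimuth (deg)", ...)
  invisible(x)
}

# zenith/azimuth (degrees) -> annulus and sector indices; boundary values
# fall in the lower-index bin.
bin_direction <- function(zenith, azimuth, n_azimuth = 24, n_zenith = 18) {
  zstep <- 90 / n_zenith
  astep <- 360 / n_azimuth
  zi <- pmin(n_zenith, pmax(1L, ceiling(zenith / zstep)))
  ai <- pmin(n_azimuth, pmax(1L, ceiling((azimuth %% 360) / astep)))
  list(zenith_bin = as.integer(zi), azimuth_bin = as.integer(ai))
}

#' Gap fraction on the sky grid from a segmented hemisphere raster
#'
#' Assigns every pixel inside the 90-degree disk to the grid cell containing
#' its direction and computes per-cell gap fractions. By default
#' (`denominator = "all"`) the denominator counts all disk pixels of the
#' cell, covered or not, so regions of the hemisphere not observed by any
#' camera depress the gap fraction as obstructed area. The alternative
#' `"covered"` renormalises over observed pixels only.
#'
#' @param h A [hemisphere_raster()].
#' @param n_azimuth,n_zenith Grid dimensions (defaults 24 and 18).
#' @param denominator `"all"` (uncovered counts as obstructed; default) or
#'   `"covered"`.
#' @return A [sky_grid()].
#' @export
grid_gap_fraction <- function(h, n_azimuth = 24, n_zenith = 18,
                              denominator = c("all", "covered")) {
  stopifnot(inherits(h, "hemisphere_raster"))
  denominator <- match.arg(denominator)
  field <- direction_field(h$projection, dim(h$sky_mask))
  in_disk <- field$inside & field$zenith <= 90
  if (!any(in_disk)) stop("empty hemisphere: no pixel maps inside the sky disk")
  idx <- which(in_disk)
  b <- bin_direction(field$zenith[idx], field$azimuth[idx],
                     n_azimuth, n_zenith)
  cell <- (b$azimuth_bin - 1L) * n_zenith + b$zenith_bin
  ncell <- n_azimuth * n_zenith
  if (denominator == "all") {
    tot <- tabulate(cell, nbins = ncell)
  } else {
    tot <- tabulate(cell[h$coverage_mask[idx] == 1], nbins = ncell)
  }
  sky <- tabulate(cell[h$sky_mask[idx] == 1], nbins = ncell)
  gf <- ifelse(tot > 0, sky / pmax(tot, 1L), 0)
  sky_grid(matrix(gf, n_zenith, n_azimuth),
           pixel_count = matrix(tot, n_zenith, n_azimuth),
           n_azimuth = n_azimuth, n_zenith = n_zenith)
}

#' Total gap fraction of a rectangular frame
#'
#' The unweighted ratio of sky pixels to all pixels of a (non-masked)
#' rectangular image -- the simple protocol used for single diagonal
#' frames. No hemisphere weighting or circular mask is involved.
#'
#' @param x A `segmentation_result`, or a binary sky matrix.
#' @return Total gap in `[0, 1]`.
#' @export
total_gap <- function(x) {
  sky <- if (inherits(x, "segmentation_result")) x$sky_mask else as.matrix(x)
  if (length(sky) == 0) stop("empty raster")
  mean(sky != 0)
}

#' Average the total gap of a frame pair
#'
#' Arithmetic mean of the total gap from the north-south and east-west
#' frames taken at the same point.
#'
#' @param tg_ns,tg_ew Total gap values in `[0, 1]`.
#' @return Their mean.
#' @export
average_total_gap <- function(tg_ns, tg_ew) {
  stopifnot(is.finite(tg_ns), is.finite(tg_ew),
            tg_ns >= 0, tg_ns <= 1, tg_ew >= 0, tg_ew <= 1)
  (tg_ns + tg_ew) / 2
}

#' Canopy openness from a sky grid
#'
#' The unobstructed fraction of hemisphere surface area: gap fractions
#' weighted by each cell's share of hemisphere area,
#' `CO = sum(gap_fraction * w_annulus / n_azimuth)`. Sky near the horizon
#' occupies more surface area per solid angle of image than sky at the
#' zenith, which the annulus weights account for.
#'
#' @param grid A [sky_grid()].
#' @return Canopy openness in `[0, 1]`.
#' @export
canopy_openness <- function(grid) {
  stopifnot(inherits(grid, "sky_grid"))
  n_az <- ncol(grid$gap_fraction)
  sum(grid$gap_fraction * grid$weights / n_az)
}

#' Restrict a sky grid to a narrower field of view
#'
#' Emulates a narrower lens by forcing the gap fraction to zero for annuli
#' beyond `max_zenith` (default 75 degrees, i.e. a 150-degree FOV).
#' Annulus weights are unchanged: the masked area remains on the hemisphere
#' as obstructed surface, so openness and site factors can only decrease.
#'
#' @param grid A [sky_grid()].
#' @param max_zenith Masking limit in degrees; must coincide with an
#'   annulus boundary unless `snap = TRUE`.
#' @param snap If `TRUE`, snap `max_zenith` to the nearest annulus boundary
#'   with a warning instead of failing.
#' @return The masked [sky_grid()].
#' @export
apply_fov_mask <- function(grid, max_zenith = 75, snap = FALSE) {
  stopifnot(inherits(grid, "sky_grid"))
  edges <- grid$zenith_edges
  if (!any(abs(edges - max_zenith) < 1e-9)) {
    if (!snap) {
      stop("'max_zenith' must lie on an annulus boundary (or use snap = TRUE)")
    }
    max_zenith <- edges[which.min(abs(edges - max_zenith))]
    warning(sprintf("'max_zenith' snapped to annulus boundary %g", max_zenith))
  }
  gf <- grid$gap_fraction
  mask_rows <- which(edges[-length(edges)] >= max_zenith - 1e-9)
  gf[mask_rows, ] <- 0
  out <- grid
  out$gap_fraction <- gf
  out
}

#' Export a sky grid to CSV
#'
#' Writes the gap-fraction matrix with annulus zenith bounds as row labels
#' and sector azimuth bounds as column names, for interchange with external
#' gap-fraction tools.
#'
#' @param grid A [sky_grid()].
#' @param path Output file path.
#' @export
write_sky_grid_csv <- function(grid, path) {
  stopifnot(inherits(grid, "sky_grid"))
  nz <- nrow(grid$gap_fraction); na <- ncol(grid$gap_fraction)
  ze <- grid$zenith_edges; ae <- grid$azimuth_edges
  df <- data.frame(
    zenith_lower = ze[-(nz + 1)], zenith_upper = ze[-1],
    grid$gap_fraction, check.names = FALSE)
  names(df)[-(1:2)] <- sprintf("az_%g_%g", ae[-(na + 1)], ae[-1])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Import a sky grid from CSV
#'
#' Reads a file written by [write_sky_grid_csv()].
#'
#' @param path CSV file path.
#' @return A [sky_grid()].
#' @export
read_sky_grid_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  gf <- as.matrix(df[, -(1:2), drop = FALSE])
  dimnames(gf) <- NULL
  sky_grid(gf, n_azimuth = ncol(gf), n_zenith = nrow(gf))
}
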