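#' Azimuthal-equidistant projection model
#'
#' Describes how pixels of an upward-looking fisheye raster map onto the sky
#' hemisphere. Under the equidistant law the angular distance from the optical
#' axis is proportional to the pixel distance from the image centre:
#' `zenith = (r / radius_px) * max_zenith`.
#'
#' Continuous pixel coordinates place the raster origin at the top-left
#' corner, so the centre of the pixel in row `i`, column `j` (1-based) is at
#' `(i - 0.5, j - 0.5)`.
#'
#' Lenses with a field of view wider than 180 degrees (e.g. a 183-degree
#' converter) are handled by calibrating `radius_px` to the radius at which
#' the zenith angle reaches 90 degrees; `max_zenith` itself never exceeds 90.
#'
#' @param center Numeric length-2, continuous `(row, col)` of the optical axis.
#' @param radius_px Pixel distance from `center` at which the zenith angle
#'   equals `max_zenith`. Must be positive.
#' @param max_zenith Zenith angle (degrees) at `radius_px`; 90 for a full
#'   hemisphere circle, 75 for a 150-degree diagonal frame.
#' @param north_offset Degrees added to map image-up to compass North.
#' @param mirror Logical. `FALSE` (default) for an as-captured upward view,
#'   where East appears on the image left; `TRUE` for images that have been
#'   flipped left-right beforehand.
#' @return An object of class `hemi_projection`.
#' @seealso [pixel_to_direction()], [direction_to_pixel()],
#'   [diagonal_projection()]
#' @export
#' @examples
#' proj <- projection_model(center = c(512, 512), radius_px = 512)
#' pixel_to_direction(c(512, 512), proj)  # optical axis: zenith 0
projection_model <- function(center, radius_px, max_zenith = 90,
                             north_offset = 0, mirror = FALSE) {
  stopifnot(is.numeric(center), length(center) == 2, all(is.finite(center)))
  if (!is.numeric(radius_px) || length(radius_px) != 1 || !is.finite(radius_px) ||
      radius_px <= 0) {
    stop("'radius_px' must be a positive finite number")
  }
  if (!is.numeric(max_zenith) || length(max_zenith) != 1 ||
      max_zenith <= 0 || max_zenith > 90) {
    stop("'max_zenith' must lie in (0, 90]")
  }
  structure(
    list(kind = "equidistant",
         center = as.numeric(center),
         radius_px = as.numeric(radius_px),
         max_zenith = as.numeric(max_zenith),
         north_offset = as.numeric(north_offset) %% 360,
         mirror = isTRUE(mirror)),
    class = "hemi_projection")
}

#' @export
print.hemi_projection <- function(x, ...) {
  cat(sprintf(
    "<hemi_projection> equidistant; center (%.1f, %.1f), radius %.1f px -> %g deg, north offset %g, mirror %s\n",
    x$center[1], x$center[2], x$radius_px, x$max_zenith, x$north_offset,
    x$mirror))
  invisible(x)
}

#' Map pixel coordinates to sky directions
#'
#' Inverts the fisheye projection for one or more continuous pixel
#' coordinates. Directions use sky (compass) convention: zenith 0 at the
#' optical axis, azimuth 0 = North increasing clockwise, East = 90.
#'
#' Pixels beyond `radius_px` (zenith beyond `max_zenith`) are out of field
#' and returned with `NA` zenith/azimuth. At the exact optical axis the
#' azimuth is undefined and reported as 0.
#'
#' @param pixel Numeric length-2 `(row, col)` or an n x 2 matrix of
#'   continuous pixel coordinates.
#' @param proj A [projection_model()].
#' @return A data frame with columns `zenith`, `azimuth` (degrees; `NA` when
#'   outside the field of view).
#' @export
pixel_to_direction <- function(pixel, proj) {
  stopifnot(inherits(proj, "hemi_projection"))
  px <- if (is.matrix(pixel)) pixel else matrix(as.numeric(pixel), ncol = 2)
  if (ncol(px) != 2) stop("'pixel' must be (row, col) pairs")
  if (any(!is.finite(px))) stop("non-finite pixel coordinates are invalid")
  dr <- px[, 1] - proj$center[1]
  dc <- px[, 2] - proj$center[2]
  r <- sqrt(dr^2 + dc^2)
  zen <- r / proj$radius_px * proj$max_zenith
  bearing <- atan2(dc, -dr) * 180 / pi   # clockwise from image-up, in image coords
  az <- if (proj$mirror) proj$north_offset + bearing else proj$north_offset - bearing
  az <- az %% 360
  az[r == 0] <- 0
  outside <- zen > proj$max_zenith
  zen[outside] <- NA_real_
  az[outside] <- NA_real_
  data.frame(zenith = zen, azimuth = az)
}

#' Map sky directions to pixel coordinates
#'
#' Exact inverse of [pixel_to_direction()] for directions within the
#' projection's field of view.
#'
#' @param d A data frame (or list) with `zenith` and `azimuth` in degrees.
#' @param proj A [projection_model()].
#' @return An n x 2 matrix of continuous `(row, col)` coordinates.
#' @export
direction_to_pixel <- function(d, proj) {
  stopifnot(inherits(proj, "hemi_projection"))
  zen <- as.numeric(d$zenith)
  az <- as.numeric(d$azimuth) %% 360
  if (any(!is.finite(zen)) || any(!is.finite(az))) {
    stop("non-finite direction is invalid")
  }
  if (any(zen < 0) || any(zen > proj$max_zenith)) {
    stop("zenith beyond 'max_zenith' is out of field")
  }
  r <- zen / proj$max_zenith * proj$radius_px
  bearing <- if (proj$mirror) az - proj$north_offset else proj$north_offset - az
  b <- bearing * pi / 180
  cbind(row = proj$center[1] - r * cos(b),
        col = proj$center[2] + r * sin(b))
}

#' Per-pixel direction field of a raster under a projection
#'
#' Evaluates the projection at every pixel centre of an `nrow x ncol` raster.
#'
#' @param proj A [projection_model()].
#' @param dims Integer length-2, `(nrow, ncol)` of the raster.
#' @return A list with matrices `zenith`, `azimuth` (degrees, `NA` outside
#'   the field) and logical `inside`.
#' @export
direction_field <- function(proj, dims) {
  stopifnot(inherits(proj, "hemi_projection"), length(dims) == 2, all(dims > 0))
  nr <- as.integer(dims[1]); nc <- as.integer(dims[2])
  rows <- matrix(seq_len(nr) - 0.5, nr, nc)
  cols <- matrix(rep(seq_len(nc) - 0.5, each = nr), nr, nc)
  dr <- rows - proj$center[1]
  dc <- cols - proj$center[2]
  r <- sqrt(dr^2 + dc^2)
  zen <- r / proj$radius_px * proj$max_zenith
  bearing <- atan2(dc, -dr) * 180 / pi
  az <- if (proj$mirror) proj$north_offset + bearing else proj$north_offset - bearing
  az <- az %% 360
  az[r == 0] <- 0
  inside <- zen <= proj$max_zenith
  zen[!inside] <- NA_real_
  az[!inside] <- NA_real_
  list(zenith = zen, azimuth = az, inside = inside)
}

#' Projection model of a rectangular diagonal fisheye frame
#'
#' A diagonal frame's image diagonal spans the lens field of view, so the
#' half-diagonal in pixels corresponds to `fov_diagonal / 2` degrees of
#' zenith; corner pixels sit exactly at that zenith angle. The frame's long
#' (width) axis is aligned to the compass bearing `orientation` via the
#' projection's north offset.
#'
#' @param width,height Frame pixel dimensions; `width >= height`.
#' @param fov_diagonal Lens field of view along the diagonal, degrees in
#'   (0, 180]. Default 150.
#' @param orientation Compass bearing of the long axis in degrees
#'   (0 = N-S, 90 = E-W).
#' @param mirror See [projection_model()].
#' @return A `hemi_projection` centred on the frame.
#' @export
diagonal_projection <- function(width, height, fov_diagonal = 150,
                                orientation = 0, mirror = FALSE) {
  stopifnot(width > 0, height > 0)
  if (width < height) stop("diagonal frames must satisfy width >= height")
  if (fov_diagonal <= 0 || fov_diagonal > 180) {
    stop("'fov_diagonal' must lie in (0, 180]")
  }
  projection_model(center = c(height / 2, width / 2),
                   radius_px = sqrt(width^2 + height^2) / 2,
                   max_zenith = fov_diagonal / 2,
                   north_offset = orientation + 90,
                   mirror = mirror)
}

#' Direction field over a diagonal frame footprint
#'
#' Convenience wrapper building the frame's projection model and the
#' per-pixel [direction_field()] in one call. Every frame pixel maps to a
#' direction with zenith at most `fov_diagonal / 2`.
#'
#' @inheritParams diagonal_projection
#' @param frame_dims Integer length-2 `(width, height)` in pixels.
#' @return A list with `projection` and the direction-field matrices
#'   `zenith`, `azimuth`, `inside` (row/col indexed as `height x width`).
#' @export
diagonal_footprint <- function(frame_dims, fov_diagonal = 150,
                               orientation = 0, mirror = FALSE) {
  proj <- diagonal_projection(frame_dims[1], frame_dims[2], fov_diagonal,
                              orientation, mirror)
  field <- direction_field(proj, dims = c(frame_dims[2], frame_dims[1]))
  c(list(projection = proj), field)
}

#' A diagonal smartphone fisheye frame
#'
#' Bundles the RGB raster of a rectangular diagonal-fisheye photograph with
#' its compass orientation and lens field of view.
#'
#' @param rgb A `height x width x 3` numeric array with channels in `[0, 1]`.
#' @param orientation Long-axis compass bearing, degrees.
#' @param fov_diagonal Lens FOV along the diagonal, degrees. Default 150.
#' @param mirror See [projection_model()].
#' @return An object of class `diagonal_frame`.
#' @export
diagonal_frame <- function(rgb, orientation, fov_diagonal = 150,
                           mirror = FALSE) {
  stopifnot(is.array(rgb), length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  if (w < h) stop("diagonal frames must satisfy width >= height")
  structure(
    list(rgb = rgb, orientation = as.numeric(orientation) %% 360,
         fov_diagonal = fov_diagonal,
         projection = diagonal_projection(w, h, fov_diagonal, orientation,
                                          mirror)),
    class = "diagonal_frame")
}

#' @export
print.diagonal_frame <- function(x, ...) {
  d <- dim(x$rgb)
  cat(sprintf("<diagonal_frame> %d x %d px, orientation %g deg, FOV %g deg\n",
              d[2], d[1], x$orientation, x$fov_diagonal))
  invisible(x)
}

#' Segmented hemisphere raster
#'
#' Container joining a binary sky mask, a coverage mask recording which
#' pixels were actually observed by a camera, and the projection model that
#' places each pixel on the hemisphere. Sky can only be claimed where the
#' hemisphere was observed, so `sky_mask` is forced to 0 wherever
#' `coverage_mask` is 0.
#'
#' @param sky_mask Binary (0/1 or logical) matrix, 1 = sky.
#' @param coverage_mask Binary matrix of identical dimensions, 1 = observed.
#' @param projection A [projection_model()].
#' @return An object of class `hemisphere_raster`.
#' @export
hemisphere_raster <- function(sky_mask, coverage_mask, projection) {
  stopifnot(inherits(projection, "hemi_projection"))
  sky <- (as.matrix(sky_mask) != 0) * 1L
  cov <- (as.matrix(coverage_mask) != 0) * 1L
  if (!identical(dim(sky), dim(cov))) {
    stop("'sky_mask' and 'coverage_mask' must share dimensions")
  }
  sky <- sky * cov  # uncovered pixels are never sky
  structure(list(sky_mask = sky, coverage_mask = cov, projection = projection),
            class = "hemisphere_raster")
}

#' @export
print.hemisphere_raster <- function(x, ...) {
  cat(sprintf(
    "<hemisphere_raster> %d x %d px; coverage %.1f%%, sky %.1f%% of covered\n",
    nrow(x$sky_mask), ncol(x$sky_mask), 100 * mean(x$coverage_mask),
    100 * sum(x$sky_mask) / max(1, sum(x$coverage_mask))))
  invisible(x)
}

#' Coverage mask of the image circle of a circular photograph
#'
#' Builds the coverage mask selecting pixels inside the projected hemisphere
#' (zenith at most 90 degrees). For lenses calibrated beyond 180 degrees the
#' outer ring past zenith 90 is excluded.
#'
#' @param rgb A `height x width x 3` array (or any matrix/array whose first
#'   two dimensions give the raster size).
#' @param proj A [projection_model()] whose 90-degree circle must fit inside
#'   the raster.
#' @return A list with the binary `coverage` matrix and `projection`.
#' @export
apply_circular_mask <- function(rgb, proj) {
  stopifnot(inherits(proj, "hemi_projection"))
  d <- dim(rgb)
  dims <- d[1:2]
  r90 <- proj$radius_px * 90 / proj$max_zenith
  if (proj$center[1] - r90 < 0 || proj$center[1] + r90 > dims[1] ||
      proj$center[2] - r90 < 0 || proj$center[2] + r90 > dims[2]) {
    stop("projection circle exceeds raster bounds: check calibration")
  }
  field <- direction_field(proj, dims)
  coverage <- (field$inside) * 1L
  list(coverage = coverage, projection = proj)
}

#' Merge an orthogonal pair of diagonal frames into a pseudo-hemisphere
#'
#' Places two diagonal frames with (approximately) orthogonal compass
#' orientations onto a common full-hemisphere circle by their recorded
#' orientations. The output circle represents the full 180-degree sky: its
#' diameter, measured in source-frame pixel units, equals the frame diagonal
#' multiplied by `ratio` (default `180 / 150`), so the frame diagonals span
#' 150 degrees inside a larger 180-degree disk. Pixels covered by the
#' east-west frame take its values (it is the reference image); pixels
#' covered only by the north-south frame take that frame's values; disk
#' pixels outside both footprints have coverage 0.
#'
#' @param frame_ew,frame_ns [diagonal_frame()] objects sharing the same
#'   `fov_diagonal`, with orientations differing by 90 degrees within
#'   `orientation_tol`.
#' @param out_size Side length in pixels of the square output raster.
#' @param ratio Output disk diameter as a multiple of the frame diagonal.
#' @param orientation_tol Tolerated deviation (degrees) from orthogonality.
#' @return A list with `rgb` (out_size^3 array), binary `coverage` matrix,
#'   `projection` (full-hemisphere model) and `source` (matrix of 0 =
#'   uncovered, 1 = east-west, 2 = north-south).
#' @export
merge_diagonal_pair <- function(frame_ew, frame_ns, out_size = 1024,
                                ratio = 180 / 150, orientation_tol = 15) {
  stopifnot(inherits(frame_ew, "diagonal_frame"),
            inherits(frame_ns, "diagonal_frame"))
  if (!isTRUE(all.equal(frame_ew$fov_diagonal, frame_ns$fov_diagonal))) {
    stop("incompatible frames: 'fov_diagonal' differs between the pair")
  }
  dor <- (frame_ew$orientation - frame_ns$orientation) %% 180
  if (abs(dor - 90) > orientation_tol) {
    stop("incompatible frames: orientations are not orthogonal within tolerance")
  }
  max_zen_out <- frame_ew$fov_diagonal / 2 * ratio
  if (max_zen_out > 90 + 1e-9) max_zen_out <- 90
  proj_out <- projection_model(center = c(out_size / 2, out_size / 2),
                               radius_px = out_size / 2,
                               max_zenith = 90,
                               north_offset = 0,
                               mirror = frame_ew$projection$mirror)
  # the output radius spans zenith (fov/2)*ratio; re-express as max_zenith 90
  # by scaling radius so zenith 90 sits at radius * 90 / max_zen_out
  proj_out$radius_px <- out_size / 2 * 90 / max_zen_out

  field <- direction_field(proj_out, dims = c(out_size, out_size))
  rgb_out <- array(0, dim = c(out_size, out_size, 3))
  coverage <- matrix(0L, out_size, out_size)
  source <- matrix(0L, out_size, out_size)

  in_disk <- which(field$inside)
  zen <- field$zenith[in_disk]
  az <- field$azimuth[in_disk]

  sample_frame <- function(frame) {
    pr <- frame$projection
    ok <- zen <= pr$max_zenith
    px <- matrix(NA_real_, length(zen), 2)
    if (any(ok)) {
      px[ok, ] <- direction_to_pixel(list(zenith = zen[ok], azimuth = az[ok]), pr)
    }
    h <- dim(frame$rgb)[1]; w <- dim(frame$rgb)[2]
    ri <- ceiling(px[, 1]); ci <- ceiling(px[, 2])
    ri[ri == 0] <- 1L; ci[ci == 0] <- 1L
    inside <- ok & !is.na(ri) & ri >= 1 & ri <= h & ci >= 1 & ci <= w
    list(inside = inside, ri = ri, ci = ci)
  }

  sew <- sample_frame(frame_ew)
  sns <- sample_frame(frame_ns)
  use_ew <- sew$inside
  use_ns <- sns$inside & !use_ew

  n <- out_size
  for (ch in 1:3) {
    plane <- matrix(0, n, n)
    if (any(use_ew)) {
      plane[in_disk[use_ew]] <- frame_ew$rgb[, , ch][
        cbind(sew$ri[use_ew], sew$ci[use_ew])]
    }
    if (any(use_ns)) {
      plane[in_disk[use_ns]] <- frame_ns$rgb[, , ch][
        cbind(sns$ri[use_ns], sns$ci[use_ns])]
    }
    rgb_out[, , ch] <- plane
  }
  coverage[in_disk[use_ew | use_ns]] <- 1L
  source[in_disk[use_ew]] <- 1L
  source[in_disk[use_ns]] <- 2L

  list(rgb = rgb_out, coverage = coverage, projection = proj_out,
       source = source)
}
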