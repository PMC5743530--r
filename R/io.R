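#' Read an image file as an RGB array
#'
#' Reads PNG or TIFF (and JPEG when the optional \pkg{jpeg} package is
#' installed) into a `height x width x 3` numeric array in `[0, 1]`.
#' 16-bit images are rescaled to `[0, 1]` by the underlying readers;
#' greyscale images are replicated across channels; alpha channels are
#' dropped.
#'
#' @param path Image file path; format detected from the extension.
#' @return A `height x width x 3` array.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    jpg = , jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE)) {
        stop("reading JPEG requires the 'jpeg' package")
      }
      jpeg::readJPEG(path)
    },
    stop("unsupported image format: '", ext,
         "' (supported: png, tiff, jpeg)"))
  if (is.matrix(img)) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write a binary sky mask
#'
#' Writes a segmentation mask as an 8-bit greyscale PNG or TIFF with sky =
#' white (255) and canopy = black (0).
#'
#' @param mask Binary matrix (or `segmentation_result`).
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @export
write_mask <- function(mask, path) {
  if (inherits(mask, "segmentation_result")) mask <- mask$sky_mask
  m <- (as.matrix(mask) != 0) * 1
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(m, path),
    tif = , tiff = tiff::writeTIFF(m, path),
    stop("unsupported mask format: '", ext, "'"))
  invisible(path)
}

#' Segment an image with a chosen method
#'
#' Dispatches to [classify_blue_isodata()] or [classify_enhanced()].
#'
#' @param rgb RGB array.
#' @param coverage Optional binary coverage mask.
#' @param method `"isodata_blue"` or `"enhanced"`.
#' @return A `segmentation_result`.
#' @export
segment_image <- function(rgb, coverage = NULL,
                          method = c("isodata_blue", "enhanced")) {
  method <- match.arg(method)
  if (method == "isodata_blue") classify_blue_isodata(rgb, coverage)
  else classify_enhanced(rgb, coverage)
}

#' Analyse a circular photograph end to end
#'
#' Circular-protocol pipeline: build the image-circle coverage, segment,
#' assemble the [hemisphere_raster()] and run [analyze_hemisphere()].
#'
#' @param rgb RGB array of the circular photograph.
#' @param proj Its [projection_model()]; by default an inscribed full
#'   hemisphere circle centred on the raster.
#' @param latitude Degrees.
#' @param method Segmentation method, see [segment_image()].
#' @param ... Passed to [analyze_hemisphere()].
#' @return A [site_estimates()].
#' @export
analyze_circular_image <- function(rgb, proj = NULL, latitude = 53,
                                   method = "enhanced", ...) {
  d <- dim(rgb)
  if (is.null(proj)) {
    proj <- projection_model(center = c(d[1] / 2, d[2] / 2),
                             radius_px = min(d[1], d[2]) / 2)
  }
  msk <- apply_circular_mask(rgb, proj)
  seg <- segment_image(rgb, msk$coverage, method)
  h <- hemisphere_raster(seg$sky_mask, msk$coverage, proj)
  analyze_hemisphere(h, latitude, provenance = "circular", ...)
}

#' Analyse a merged diagonal pair end to end
#'
#' Merged-protocol pipeline: geometrically merge the east-west and
#' north-south frames into a pseudo-hemisphere, segment the merged raster
#' over its covered footprint, and run [analyze_hemisphere()] with
#' uncovered regions counted as obstructed.
#'
#' @param frame_ew,frame_ns [diagonal_frame()] objects.
#' @param latitude Degrees.
#' @param method Segmentation method.
#' @param out_size Merged raster side length in pixels.
#' @param ... Passed to [analyze_hemisphere()].
#' @return A [site_estimates()] with provenance `"smartphone_merged"`.
#' @export
analyze_merged_pair <- function(frame_ew, frame_ns, latitude = 53,
                                method = "enhanced", out_size = 1024, ...) {
  merged <- merge_diagonal_pair(frame_ew, frame_ns, out_size = out_size)
  seg <- segment_image(merged$rgb, merged$coverage, method)
  h <- hemisphere_raster(seg$sky_mask, merged$coverage, merged$projection)
  analyze_hemisphere(h, latitude, provenance = "smartphone_merged", ...)
}

#' Averaged total gap of a diagonal pair
#'
#' Single-frame smartphone protocol: segment each rectangular frame whole
#' (no mask) and average the two total-gap values.
#'
#' @param frame_ew,frame_ns [diagonal_frame()] objects.
#' @param method Segmentation method.
#' @return The averaged total gap, with attribute `"per_frame"`.
#' @export
average_pair_total_gap <- function(frame_ew, frame_ns, method = "enhanced") {
  tg_ew <- total_gap(segment_image(frame_ew$rgb, method = method))
  tg_ns <- total_gap(segment_image(frame_ns$rgb, method = method))
  out <- average_total_gap(tg_ns, tg_ew)
  attr(out, "per_frame") <- c(ew = tg_ew, ns = tg_ns)
  out
}
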