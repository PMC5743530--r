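#' Iterative-selection (IsoData) threshold
#'
#' Ridler-Calvard iterative selection: starting from the global mean, the
#' threshold is repeatedly replaced by the mean of the two class means it
#' induces, `t <- (mean(values <= t) + mean(values > t)) / 2`, until the
#' update falls below `tol` or `max_iter` iterations are reached. If all
#' values are equal the common value is returned.
#'
#' @param values Numeric vector of intensities (at least one finite value).
#' @param initial Optional starting threshold; defaults to the global mean.
#' @param tol Convergence tolerance on the threshold update. The default,
#'   0.5, suits 8-bit (0-255) intensities; use `0.5 / 255` for unit-scale
#'   scores.
#' @param max_iter Iteration cap.
#' @return The scalar threshold.
#' @export
#' @examples
#' isodata_threshold(c(10, 10, 10, 200, 200))  # 105
#' isodata_threshold(c(0, 255))                # 127.5
isodata_threshold <- function(values, initial = NULL, tol = 0.5,
                              max_iter = 100) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("'values' must contain at least one finite value")
  if (max(values) == min(values)) return(values[1])
  t <- if (is.null(initial)) mean(values) else as.numeric(initial)
  for (i in seq_len(max_iter)) {
    lo <- values[values <= t]
    hi <- values[values > t]
    if (length(hi) == 0 || length(lo) == 0) break
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t) < tol) {
      t <- t_new
      break
    }
    t <- t_new
  }
  t
}

#' Blue-channel IsoData sky segmentation
#'
#' Classifies each pixel as sky or vegetation by thresholding the blue
#' channel, where the contrast between sky and vegetation is strongest, with
#' the iterative-selection method. Intensities are treated on the 8-bit
#' (0-255) scale. Pixels strictly above the threshold become sky; pixels at
#' or below it (ties included) become canopy; pixels outside `coverage` are
#' always canopy. A uniform covered image carries no contrast to threshold
#' and is classified wholesale: all sky when its value exceeds mid-scale
#' (a uniform overcast sky), all canopy otherwise (degenerate rule).
#'
#' @param rgb A `height x width x 3` array with channels in `[0, 1]`.
#' @param coverage Optional binary matrix restricting which pixels are
#'   observed; the threshold is computed from covered pixels only.
#' @return A list of class `segmentation_result` with `sky_mask` (binary
#'   matrix), `threshold` (8-bit intensity units) and `method`.
#' @export
classify_blue_isodata <- function(rgb, coverage = NULL) {
  stopifnot(is.array(rgb), length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  blue <- rgb[, , 3] * 255
  if (is.null(coverage)) coverage <- matrix(1L, nrow(blue), ncol(blue))
  cov <- as.matrix(coverage) != 0
  if (!any(cov)) stop("'coverage' selects no pixels")
  vals <- blue[cov]
  if (max(vals) == min(vals)) {
    # degenerate uniform image: all sky when brighter than mid-scale
    # (a uniform overcast sky), all canopy otherwise (a closed canopy)
    thr <- vals[1]
    sky <- if (thr > 255 / 2) cov * 1L else 0L * cov
  } else {
    thr <- isodata_threshold(vals)
    sky <- (blue > thr & cov) * 1L
  }
  structure(list(sky_mask = sky, threshold = thr, method = "isodata_blue"),
            class = "segmentation_result")
}

# Hue (degrees), lightness and chroma of the bi-hexcone (HSL-family)
# transform of RGB in [0, 1]. Vectorised over equal-length channel vectors.
rgb_to_hlc <- function(r, g, b) {
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  chroma <- mx - mn
  light <- (mx + mn) / 2
  hue <- numeric(length(r))
  nz <- chroma > 0
  is_r <- nz & mx == r
  is_g <- nz & !is_r & mx == g
  is_b <- nz & !is_r & !is_g
  hue[is_r] <- ((g[is_r] - b[is_r]) / chroma[is_r]) %% 6 * 60
  hue[is_g] <- ((b[is_g] - r[is_g]) / chroma[is_g] + 2) * 60
  hue[is_b] <- ((r[is_b] - g[is_b]) / chroma[is_b] + 4) * 60
  list(hue = hue %% 360, lightness = light, chroma = chroma)
}

#' Fuzzy sky-membership score of RGB pixels
#'
#' Scores each pixel's resemblance to open sky from the colour attributes
#' hue, lightness and chroma (bi-hexcone HSL transform). The score is a
#' weighted sum of three trapezoidal memberships:
#'
#' * lightness: rising ramp on lightness 0.1-0.6 (sky is bright);
#' * hue: 1 on the blue sector (180-300 degrees), 0.1 on the green/yellow
#'   sector (60-180 degrees), 0.3 elsewhere; near-achromatic pixels
#'   (chroma < 0.05) take a lightness-dependent fallback instead (0 for
#'   black, 0.5 at mid lightness, 1 for white) so bright white sky scores
#'   fully and dark shadow scores nothing;
#' * chroma: rewards low chroma at high lightness (washed-out sky),
#'   `max(0, 1 - chroma / 0.3) * lightness`.
#'
#' with weights 0.35 (lightness), 0.5 (hue) and 0.15 (chroma). The score is
#' monotone nondecreasing in lightness, favours blue hues over green/yellow
#' at equal lightness and chroma, approaches 1 for bright achromatic pixels
#' and 0 for dark ones.
#'
#' @param rgb Either a `height x width x 3` array or an n x 3 matrix of RGB
#'   values in `[0, 1]`.
#' @return Scores in `[0, 1]`, shaped as a matrix for array input or a
#'   vector for matrix input.
#' @export
#' @examples
#' sky_membership_score(matrix(c(0.2, 0.4, 1.0), 1))  # bright blue: high
#' sky_membership_score(matrix(c(0.1, 0.3, 0.1), 1))  # dark green: low
sky_membership_score <- function(rgb) {
  if (is.array(rgb) && length(dim(rgb)) == 3) {
    d <- dim(rgb)
    r <- as.vector(rgb[, , 1]); g <- as.vector(rgb[, , 2])
    b <- as.vector(rgb[, , 3])
    out_dim <- d[1:2]
  } else {
    m <- as.matrix(rgb)
    if (ncol(m) != 3) stop("'rgb' must have three channels")
    r <- m[, 1]; g <- m[, 2]; b <- m[, 3]
    out_dim <- NULL
  }
  if (any(!is.finite(c(r, g, b))) || any(c(r, g, b) < 0) ||
      any(c(r, g, b) > 1)) {
    stop("RGB channels must be finite and within [0, 1]")
  }
  hlc <- rgb_to_hlc(r, g, b)
  f_light <- pmin(1, pmax(0, (hlc$lightness - 0.1) / 0.5))
  g_hue <- rep(0.3, length(r))
  g_hue[hlc$hue >= 180 & hlc$hue <= 300] <- 1
  g_hue[hlc$hue >= 60 & hlc$hue < 180] <- 0.1
  achrom <- hlc$chroma < 0.05
  la <- hlc$lightness[achrom]
  g_hue[achrom] <- 0.5 * pmin(1, la / 0.2) +
    0.5 * pmin(1, pmax(0, (la - 0.5) / 0.5))
  h_chroma <- pmax(0, 1 - hlc$chroma / 0.3) * hlc$lightness
  score <- 0.35 * f_light + 0.5 * g_hue + 0.15 * h_chroma
  if (is.null(out_dim)) score else matrix(score, out_dim[1], out_dim[2])
}

#' Enhanced colour-attribute sky segmentation
#'
#' Computes the fuzzy [sky_membership_score()] for every pixel and applies
#' the iterative-selection threshold to the score field (tolerance scaled to
#' the unit score range). Compared with plain blue-channel thresholding this
#' demotes bright but yellow/green vegetation ("bright leaf" artifacts)
#' whose blue intensity alone resembles sky. Tie and coverage rules match
#' [classify_blue_isodata()].
#'
#' @inheritParams classify_blue_isodata
#' @return A `segmentation_result` with the threshold in score units and
#'   `method = "enhanced"`.
#' @export
classify_enhanced <- function(rgb, coverage = NULL) {
  stopifnot(is.array(rgb), length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  score <- sky_membership_score(rgb)
  if (is.null(coverage)) coverage <- matrix(1L, nrow(score), ncol(score))
  cov <- as.matrix(coverage) != 0
  if (!any(cov)) stop("'coverage' selects no pixels")
  vals <- score[cov]
  if (max(vals) == min(vals)) {
    thr <- vals[1]
    sky <- if (thr > 0.5) cov * 1L else 0L * cov
  } else {
    thr <- isodata_threshold(vals, tol = 0.5 / 255)
    sky <- (score > thr & cov) * 1L
  }
  structure(list(sky_mask = sky, threshold = thr, method = "enhanced"),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> method %s, threshold %.4g, sky %.1f%%\n",
              x$method, x$threshold, 100 * mean(x$sky_mask)))
  invisible(x)
}
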