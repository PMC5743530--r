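# Run expr with a temporary RNG state seeded by `seed`, restoring any
# pre-existing state afterwards.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  expr
}

# Derive a deterministic sub-seed (for independent named streams) staying
# within 32-bit integer range.
sub_seed <- function(seed, k) {
  if (is.na(seed)) seed <- 0
  as.integer((as.double(seed) %% 1000003) * 2039 + 7 * k) %% 2147483646L + 1L
}

# Render palette: linear RGB of the three scene materials.
.scene_palette <- list(
  sky = c(0.45, 0.65, 1.00),     # scaled by the sky brightness model
  canopy = c(0.05, 0.15, 0.05),  # dark foliage
  artifact = c(0.85, 0.90, 0.55) # sunlit "bright leaf": yellow hue, high blue
)

#' Construct a synthetic canopy scene
#'
#' A canopy scene is a set of opaque angular disks on the sky sphere plus an
#' artifact fraction; a direction is sky when no disk covers it, giving an
#' exact analytic ground-truth gap function. Disk centres may have zenith
#' beyond 90 degrees (below the horizon) so that e.g. a single large disk
#' centred at the nadir can occlude everything beyond a chosen zenith angle.
#'
#' @param zenith,azimuth,radius Equal-length numeric vectors of disk centre
#'   coordinates (degrees; zenith in `[0, 180]`) and angular radii
#'   (degrees, positive).
#' @param zenith_exponent,artifact_fraction,seed Metadata recorded with the
#'   scene (see [generate_scene()]).
#' @return An object of class `canopy_scene`.
#' @export
canopy_scene <- function(zenith, azimuth, radius, zenith_exponent = NA_real_,
                         artifact_fraction = 0, seed = NA_integer_) {
  stopifnot(length(zenith) == length(azimuth),
            length(zenith) == length(radius))
  if (length(radius) && any(radius <= 0)) stop("'radius' must be positive")
  if (artifact_fraction < 0 || artifact_fraction > 1) {
    stop("'artifact_fraction' must lie in [0, 1]")
  }
  structure(list(zenith = as.numeric(zenith), azimuth = as.numeric(azimuth),
                 radius = as.numeric(radius),
                 zenith_exponent = zenith_exponent,
                 artifact_fraction = artifact_fraction, seed = seed),
            class = "canopy_scene")
}

#' @export
print.canopy_scene <- function(x, ...) {
  cat(sprintf(
    "<canopy_scene> %d disks, zenith exponent %s, artifact fraction %g, seed %s\n",
    length(x$zenith), format(x$zenith_exponent), x$artifact_fraction,
    format(x$seed)))
  invisible(x)
}

#' Generate a random canopy scene
#'
#' Draws `n_disks` opaque angular disks whose centre zenith density is
#' proportional to `sin(theta) * (theta / 90)^zenith_exponent`: a positive
#' exponent concentrates obstruction toward the horizon, emulating the
#' longer canopy path length at grazing view angles. Azimuths are uniform
#' and radii uniform within `radius_range`. Generation is deterministic
#' given `seed`.
#'
#' The defaults (300 disks of 1-6 degrees, exponent 1.5, 3% bright-leaf
#' artifacts) define the package's reference study conditions for
#' validation and bias experiments.
#'
#' @param seed Integer random seed for the scene stream.
#' @param n_disks Number of obstruction disks (>= 0).
#' @param radius_range Length-2 range of angular radii, degrees.
#' @param zenith_exponent Horizon-loading exponent (0 = uniform density on
#'   the hemisphere).
#' @param artifact_fraction Share of canopy pixels rendered as bright
#'   leaves by the renderers.
#' @return A [canopy_scene()].
#' @export
generate_scene <- function(seed, n_disks = 300, radius_range = c(1, 6),
                           zenith_exponent = 1.5, artifact_fraction = 0.03) {
  stopifnot(n_disks >= 0, length(radius_range) == 2,
            all(radius_range > 0), radius_range[1] <= radius_range[2])
  if (n_disks == 0) {
    return(canopy_scene(numeric(0), numeric(0), numeric(0),
                        zenith_exponent, artifact_fraction, seed))
  }
  with_seed(sub_seed(seed, 1), {
    zen <- numeric(0)
    while (length(zen) < n_disks) {
      cand <- acos(stats::runif(4 * n_disks)) * 180 / pi   # density sin(theta)
      keep <- stats::runif(length(cand)) <= (cand / 90)^zenith_exponent
      zen <- c(zen, cand[keep])
    }
    zen <- zen[seq_len(n_disks)]
    az <- stats::runif(n_disks, 0, 360)
    rad <- stats::runif(n_disks, radius_range[1], radius_range[2])
    canopy_scene(zen, az, rad, zenith_exponent, artifact_fraction, seed)
  })
}

# Vectorised gap query: 1 where no disk covers the direction. Disks are
# pruned by the zenith band |theta - theta_c| <= r before the great-circle
# test cos(d) >= cos(r).
scene_sky <- function(scene, zenith, azimuth) {
  n <- length(zenith)
  sky <- rep(TRUE, n)
  if (length(scene$zenith) == 0 || n == 0) return(as.integer(sky))
  zr <- zenith * pi / 180
  ar <- azimuth * pi / 180
  sz <- sin(zr); cz <- cos(zr)
  for (i in seq_along(scene$zenith)) {
    zc <- scene$zenith[i]; rc <- scene$radius[i]
    cand <- which(sky & abs(zenith - zc) <= rc)
    if (length(cand) == 0) next
    zcr <- zc * pi / 180
    cosd <- cos(zcr) * cz[cand] +
      sin(zcr) * sz[cand] * cos(ar[cand] - scene$azimuth[i] * pi / 180)
    sky[cand[cosd >= cos(rc * pi / 180)]] <- FALSE
  }
  as.integer(sky)
}

#' Ground-truth gap indicator of a scene
#'
#' Returns 1 for directions not covered by any obstruction disk (sky) and 0
#' otherwise; a direction exactly on a disk rim counts as obstructed.
#'
#' @param scene A [canopy_scene()].
#' @param d A data frame (or list) with `zenith` and `azimuth` in degrees,
#'   or a length-2 numeric `(zenith, azimuth)`.
#' @return Integer vector of 0/1.
#' @export
is_sky_direction <- function(scene, d) {
  stopifnot(inherits(scene, "canopy_scene"))
  if (is.numeric(d) && length(d) == 2) d <- list(zenith = d[1], azimuth = d[2])
  zen <- as.numeric(d$zenith); az <- as.numeric(d$azimuth)
  if (any(!is.finite(zen)) || any(!is.finite(az)) || any(zen < 0) ||
      any(zen > 90)) {
    stop("directions must have finite zenith in [0, 90]")
  }
  scene_sky(scene, zen, az)
}

# Colour a set of pixels given their zenith angle and truth sky flag.
# Returns list(r, g, b, artifact_flag); randomness (artifact placement,
# channel noise) comes from the noise stream.
shade_pixels <- function(scene, zenith, sky, sky_model, noise_sd, noise_seed) {
  n <- length(zenith)
  bright <- if (sky_model == "uniform") rep(1, n) else {
    0.55 + 0.45 * soc_relative_radiance(pmin(90, zenith))
  }
  pal <- .scene_palette
  r <- ifelse(sky == 1, pal$sky[1] * bright, pal$canopy[1])
  g <- ifelse(sky == 1, pal$sky[2] * bright, pal$canopy[2])
  b <- ifelse(sky == 1, pal$sky[3] * bright, pal$canopy[3])
  artifact <- rep(FALSE, n)
  with_seed(noise_seed, {
    canopy_idx <- which(sky == 0)
    n_art <- round(scene$artifact_fraction * length(canopy_idx))
    if (n_art > 0) {
      pick <- sample(canopy_idx, n_art)
      r[pick] <- pal$artifact[1]
      g[pick] <- pal$artifact[2]
      b[pick] <- pal$artifact[3]
      artifact[pick] <- TRUE
    }
    if (noise_sd > 0) {
      r <- r + stats::rnorm(n, 0, noise_sd)
      g <- g + stats::rnorm(n, 0, noise_sd)
      b <- b + stats::rnorm(n, 0, noise_sd)
    }
  })
  list(r = pmin(1, pmax(0, r)), g = pmin(1, pmax(0, g)),
       b = pmin(1, pmax(0, b)), artifact = artifact)
}

#' Render a circular hemispherical photograph of a scene
#'
#' Maps every pixel of a square raster to its sky direction under a
#' full-hemisphere equidistant projection and colours it: sky pixels in
#' blue graded by the Standard Overcast Sky brightness (or uniform), canopy
#' pixels dark green, a configurable fraction of canopy pixels as bright
#' yellow-green leaves, plus Gaussian channel noise. Pixels outside the
#' image circle are black.
#'
#' @param scene A [canopy_scene()].
#' @param size_px Raster side length (>= 64).
#' @param sky_model `"soc"` (zenith brighter than horizon) or `"uniform"`.
#' @param noise_sd Gaussian channel noise standard deviation.
#' @param noise_seed Seed of the noise/artifact stream; defaults to a
#'   stream derived from the scene seed.
#' @return A list of class `hemi_render`: `rgb`, `projection`, `coverage`,
#'   ground-truth `truth_sky` and `truth_artifact` masks.
#' @export
render_circular <- function(scene, size_px = 1024,
                            sky_model = c("soc", "uniform"), noise_sd = 0.01,
                            noise_seed = NULL) {
  stopifnot(inherits(scene, "canopy_scene"), size_px >= 64)
  sky_model <- match.arg(sky_model)
  if (is.null(noise_seed)) noise_seed <- sub_seed(scene$seed, 2)
  proj <- projection_model(center = c(size_px / 2, size_px / 2),
                           radius_px = size_px / 2, max_zenith = 90)
  field <- direction_field(proj, c(size_px, size_px))
  idx <- which(field$inside)
  zen <- field$zenith[idx]; az <- field$azimuth[idx]
  sky <- scene_sky(scene, zen, az)
  px <- shade_pixels(scene, zen, sky, sky_model, noise_sd, noise_seed)
  rgb <- array(0, dim = c(size_px, size_px, 3))
  plane <- matrix(0, size_px, size_px)
  for (ch in 1:3) {
    plane[] <- 0
    plane[idx] <- list(px$r, px$g, px$b)[[ch]]
    rgb[, , ch] <- plane
  }
  truth <- matrix(0L, size_px, size_px); truth[idx] <- sky
  truth_art <- matrix(0L, size_px, size_px); truth_art[idx] <- px$artifact
  coverage <- matrix(0L, size_px, size_px); coverage[idx] <- 1L
  structure(list(rgb = rgb, projection = proj, coverage = coverage,
                 truth_sky = truth, truth_artifact = truth_art),
            class = "hemi_render")
}

#' Render a diagonal smartphone frame of a scene
#'
#' As [render_circular()] but over the rectangular diagonal-fisheye
#' footprint of a frame with a given long-axis compass orientation.
#' Optional handheld jitter tilts the optical axis and perturbs the
#' azimuth before sampling the scene (deterministic given the jitter
#' seed); directions tilted below the horizon are rendered as canopy.
#'
#' @param scene A [canopy_scene()].
#' @param orientation Long-axis compass bearing, degrees.
#' @param frame_dims `(width, height)` pixels; default matches a 3264 x
#'   1836 smartphone sensor.
#' @param fov_diagonal Lens FOV, degrees.
#' @param jitter List with `tilt_sd`, `azimuth_sd` (degrees) and optional
#'   `seed` for the jitter stream.
#' @inheritParams render_circular
#' @return A [diagonal_frame()] carrying extra fields `truth_sky`,
#'   `truth_artifact` and `jitter_applied`.
#' @export
render_diagonal <- function(scene, orientation = 0,
                            frame_dims = c(3264, 1836), fov_diagonal = 150,
                            jitter = list(tilt_sd = 0, azimuth_sd = 0),
                            sky_model = c("soc", "uniform"), noise_sd = 0.01,
                            noise_seed = NULL) {
  stopifnot(inherits(scene, "canopy_scene"), all(frame_dims > 0))
  sky_model <- match.arg(sky_model)
  if (is.null(noise_seed)) noise_seed <- sub_seed(scene$seed, 3)
  jseed <- if (!is.null(jitter$seed)) jitter$seed else sub_seed(scene$seed, 4)
  tilt_sd <- if (!is.null(jitter$tilt_sd)) jitter$tilt_sd else 0
  az_sd <- if (!is.null(jitter$azimuth_sd)) jitter$azimuth_sd else 0
  jit <- with_seed(jseed, list(tilt_n = stats::rnorm(1, 0, max(0, tilt_sd)),
                               tilt_e = stats::rnorm(1, 0, max(0, tilt_sd)),
                               dazimuth = stats::rnorm(1, 0, max(0, az_sd))))
  if (tilt_sd == 0) jit$tilt_n <- jit$tilt_e <- 0
  if (az_sd == 0) jit$dazimuth <- 0

  w <- frame_dims[1]; h <- frame_dims[2]
  proj <- diagonal_projection(w, h, fov_diagonal,
                              orientation + jit$dazimuth)
  field <- direction_field(proj, c(h, w))
  zen <- pmin(as.vector(field$zenith), proj$max_zenith)
  az <- as.vector(field$azimuth)

  if (jit$tilt_n != 0 || jit$tilt_e != 0) {
    zr <- zen * pi / 180; ar <- az * pi / 180
    x <- sin(zr) * sin(ar)   # east
    y <- sin(zr) * cos(ar)   # north
    z <- cos(zr)
    a <- jit$tilt_e * pi / 180   # rotation about the east axis
    y2 <- y * cos(a) - z * sin(a); z2 <- y * sin(a) + z * cos(a)
    b <- jit$tilt_n * pi / 180   # rotation about the north axis
    x2 <- x * cos(b) + z2 * sin(b); z3 <- -x * sin(b) + z2 * cos(b)
    zen_s <- acos(pmin(1, pmax(-1, z3))) * 180 / pi
    az_s <- (atan2(x2, y2) * 180 / pi) %% 360
  } else {
    zen_s <- zen; az_s <- az
  }

  below <- zen_s > 90
  sky <- integer(length(zen_s))
  if (any(!below)) {
    sky[!below] <- scene_sky(scene, zen_s[!below], az_s[!below])
  }
  sky[below] <- 0L
  px <- shade_pixels(scene, pmin(zen_s, 90), sky, sky_model, noise_sd,
                     noise_seed)
  rgb <- array(c(px$r, px$g, px$b), dim = c(h, w, 3))
  frame <- diagonal_frame(rgb, orientation, fov_diagonal)
  frame$truth_sky <- matrix(sky, h, w)
  frame$truth_artifact <- matrix(px$artifact * 1L, h, w)
  frame$jitter_applied <- jit
  frame
}

#' Analytic ground-truth grid and site estimates of a scene
#'
#' Evaluates the scene's exact gap function on a dense direction lattice,
#' aggregates it (solid-angle weighted) to the 24 x 18 sky grid, and
#' computes ground-truth canopy openness and site factors with the same
#' radiative formulas as the imaging pipeline -- bypassing rendering and
#' segmentation entirely.
#'
#' @param scene A [canopy_scene()].
#' @param latitude Degrees; used for the direct site factor sun track.
#' @param resolution Lattice step in degrees (<= 1).
#' @param track Optional precomputed [build_sun_track()].
#' @param gsf_weights Passed to [global_site_factor()].
#' @return A list of class `scene_truth` with `grid` (a [sky_grid()]) and
#'   `estimates` (a [site_estimates()]).
#' @export
truth_site_estimates <- function(scene, latitude = 53, resolution = 0.5,
                                 track = NULL, gsf_weights = c(0.65, 0.35)) {
  stopifnot(inherits(scene, "canopy_scene"), resolution <= 1, resolution > 0)
  zmid <- seq(resolution / 2, 90 - resolution / 2 + 1e-12, by = resolution)
  amid <- seq(resolution / 2, 360 - resolution / 2 + 1e-12, by = resolution)
  zz <- rep(zmid, times = length(amid))
  aa <- rep(amid, each = length(zmid))
  g <- scene_sky(scene, zz, aa)
  wt <- sin(zz * pi / 180)
  b <- bin_direction(zz, aa)
  cell <- (b$azimuth_bin - 1L) * 18L + b$zenith_bin
  agg <- rowsum(cbind(wt, wt * g, 1), group = cell)
  ncell <- 18L * 24L
  gf <- numeric(ncell); cnt <- numeric(ncell)
  ci <- as.integer(rownames(agg))
  gf[ci] <- agg[, 2] / agg[, 1]
  cnt[ci] <- agg[, 3]
  grid <- sky_grid(matrix(gf, 18, 24), pixel_count = matrix(cnt, 18, 24))
  if (is.null(track)) track <- build_sun_track(latitude)
  isf <- indirect_site_factor(grid)
  dsf <- direct_site_factor(grid, track)
  est <- site_estimates(co = canopy_openness(grid), isf = isf, dsf = dsf,
                        gsf = global_site_factor(isf, dsf, gsf_weights),
                        provenance = "truth")
  structure(list(grid = grid, estimates = est, latitude = latitude,
                 resolution = resolution),
            class = "scene_truth")
}
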