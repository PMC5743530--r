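#' Standard Overcast Sky relative radiance
#'
#' Radiance of the Standard Overcast Sky relative to its zenith value,
#' `L(theta) / L(0) = (1 + 2 cos(theta)) / 3` (Moon-Spencer gradation): the
#' zenith is three times brighter than the horizon.
#'
#' @param zenith Zenith angle(s) in degrees, within `[0, 90]`.
#' @return Relative radiance in `[1/3, 1]`.
#' @export
#' @examples
#' soc_relative_radiance(c(0, 60, 90))  # 1, 2/3, 1/3
soc_relative_radiance <- function(zenith) {
  if (any(!is.finite(zenith)) || any(zenith < 0) || any(zenith > 90)) {
    stop("'zenith' must lie within [0, 90]")
  }
  (1 + 2 * cos(zenith * pi / 180)) / 3
}

#' Indirect site factor (annual diffuse transmittance)
#'
#' Transmittance of diffuse skylight through the canopy onto a horizontal
#' sensor, relative to open sky, under the Standard Overcast Sky. Each grid
#' cell contributes its gap fraction weighted by the sky radiance at the
#' annulus midpoint, the cosine of incidence and the cell's solid-angle
#' share:
#' `ISF = sum(GF * L * cos * w) / sum(L * cos * w)`.
#' An open sky gives exactly 1; the ISF depends only on the zenith angles of
#' the gaps, not on their azimuth.
#'
#' @param grid A [sky_grid()].
#' @return ISF in `[0, 1]`.
#' @export
indirect_site_factor <- function(grid) {
  stopifnot(inherits(grid, "sky_grid"))
  ze <- grid$zenith_edges
  mid <- (ze[-length(ze)] + ze[-1]) / 2
  lw <- soc_relative_radiance(mid) * cos(mid * pi / 180) * grid$weights
  n_az <- ncol(grid$gap_fraction)
  sum(grid$gap_fraction * (lw / n_az)) / sum(lw)
}

#' Solar declination
#'
#' Cooper's approximation `delta = 23.45 sin(360 (284 + n) / 365)` degrees
#' for day of year `n` (non-leap year).
#'
#' @param day_of_year Integer day 1-365.
#' @return Declination in degrees, within about +/-23.45.
#' @export
solar_declination <- function(day_of_year) {
  if (any(day_of_year < 1) || any(day_of_year > 365)) {
    stop("'day_of_year' must lie in 1..365")
  }
  23.45 * sin(2 * pi * (284 + day_of_year) / 365)
}

#' Solar position in local solar time
#'
#' Spherical-triangle solar geometry: with latitude `phi`, declination
#' `delta` and hour angle `H = 15 (t - 12)` degrees,
#' `cos(zenith) = sin(phi) sin(delta) + cos(phi) cos(delta) cos(H)`.
#' Azimuth is measured from North, clockwise (East = 90). Longitude and the
#' equation of time are deliberately ignored: annual site factors are
#' ratios over the whole year in solar time.
#'
#' @param latitude Degrees, `[-90, 90]`.
#' @param day_of_year Integer day 1-365.
#' @param solar_time Hours (vectorised with `day_of_year`).
#' @return Data frame with `zenith`, `azimuth` (degrees) and logical
#'   `above_horizon`.
#' @export
solar_position <- function(latitude, day_of_year, solar_time) {
  stopifnot(abs(latitude) <= 90)
  delta <- solar_declination(day_of_year) * pi / 180
  phi <- latitude * pi / 180
  H <- (solar_time - 12) * 15 * pi / 180
  cosz <- sin(phi) * sin(delta) + cos(phi) * cos(delta) * cos(H)
  cosz <- pmin(1, pmax(-1, cosz))
  zen <- acos(cosz) * 180 / pi
  az <- atan2(-cos(delta) * sin(H),
              cos(phi) * sin(delta) - sin(phi) * cos(delta) * cos(H))
  data.frame(zenith = zen, azimuth = (az * 180 / pi) %% 360,
             above_horizon = cosz > 0)
}

#' Annual sun track with direct-beam weights
#'
#' Samples the sun's position over one 365-day year on a regular grid of
#' days and solar times, keeping above-horizon samples. Each sample carries
#' a relative direct-beam weight on a horizontal surface,
#' `E0(n) * cos(zenith) * tau^(1 / cos(zenith))`, combining the
#' eccentricity factor `E0 = 1 + 0.033 cos(360 n / 365)`, the cosine of
#' incidence, and a simple atmospheric-transmittance path-length law.
#' Because the direct site factor is a ratio, any constant factor cancels.
#'
#' @param latitude Degrees.
#' @param day_step Days between sampled days (default 1).
#' @param time_step Minutes between samples within a day (default 4).
#' @param atmospheric_transmittance Zenith-path transmittance `tau` in
#'   (0, 1]; default 0.6.
#' @return Data frame of class `sun_track` with columns `day_of_year`,
#'   `solar_time`, `zenith`, `azimuth`, `weight`.
#' @export
build_sun_track <- function(latitude, day_step = 1, time_step = 4,
                            atmospheric_transmittance = 0.6) {
  stopifnot(day_step > 0, time_step > 0)
  tau <- atmospheric_transmittance
  if (tau <= 0 || tau > 1) stop("'atmospheric_transmittance' must lie in (0, 1]")
  days <- seq(1L, 365L, by = day_step)
  times <- seq(time_step / 2, 24 * 60, by = time_step) / 60
  dd <- rep(days, each = length(times))
  tt <- rep(times, times = length(days))
  pos <- solar_position(latitude, dd, tt)
  keep <- pos$above_horizon & pos$zenith < 90
  if (!any(keep)) stop("empty sun track: the sun never rises at this latitude")
  cosz <- cos(pos$zenith[keep] * pi / 180)
  e0 <- 1 + 0.033 * cos(2 * pi * dd[keep] / 365)
  track <- data.frame(day_of_year = dd[keep], solar_time = tt[keep],
                      zenith = pos$zenith[keep], azimuth = pos$azimuth[keep],
                      weight = e0 * cosz * tau^(1 / cosz))
  class(track) <- c("sun_track", "data.frame")
  track
}

#' Direct site factor (annual direct-beam transmittance)
#'
#' Overlays the annual sun track on the gap grid: each sun sample looks up
#' the gap fraction of the cell containing the sun's direction, and the DSF
#' is the beam-weighted average,
#' `DSF = sum(GF(cell_t) * w_t) / sum(w_t)`.
#'
#' @param grid A [sky_grid()].
#' @param track A [build_sun_track()] result (non-empty).
#' @return DSF in `[0, 1]`.
#' @export
direct_site_factor <- function(grid, track) {
  stopifnot(inherits(grid, "sky_grid"))
  if (is.null(track) || nrow(track) == 0) stop("'track' must be non-empty")
  b <- bin_direction(track$zenith, track$azimuth,
                     n_azimuth = ncol(grid$gap_fraction),
                     n_zenith = nrow(grid$gap_fraction))
  gf <- grid$gap_fraction[cbind(b$zenith_bin, b$azimuth_bin)]
  sum(gf * track$weight) / sum(track$weight)
}

#' Global site factor
#'
#' Combines the indirect and direct site factors with fixed weights,
#' `GSF = 0.65 ISF + 0.35 DSF` by default (UK Met Office guidance for the
#' diffuse/direct split of annual radiation; adjust `weights` for other
#' climates).
#'
#' @param isf,dsf Site factors in `[0, 1]`.
#' @param weights Length-2 numeric `(w_isf, w_dsf)` summing to 1.
#' @return GSF in `[0, 1]`.
#' @export
#' @examples
#' global_site_factor(1, 0)  # 0.65
#' global_site_factor(0, 1)  # 0.35
global_site_factor <- function(isf, dsf, weights = c(0.65, 0.35)) {
  stopifnot(isf >= 0, isf <= 1, dsf >= 0, dsf <= 1, length(weights) == 2)
  weights[1] * isf + weights[2] * dsf
}

#' Site estimates container
#'
#' Scalar canopy/light outputs of one analysed photograph (or protocol):
#' canopy openness, total gap, indirect/direct/global site factors and
#' their 150-degree-FOV variants, with a provenance label.
#'
#' @param co,isf,dsf,gsf,tg Estimates in `[0, 1]` (`NA` allowed for `tg`).
#' @param co150,isf150,dsf150,gsf150 Optional FOV-150 variants.
#' @param provenance One of `"circular"`, `"smartphone_single"`,
#'   `"smartphone_merged"` or another protocol label.
#' @return An object of class `site_estimates`.
#' @export
site_estimates <- function(co = NA_real_, isf = NA_real_, dsf = NA_real_,
                           gsf = NA_real_, tg = NA_real_,
                           co150 = NA_real_, isf150 = NA_real_,
                           dsf150 = NA_real_, gsf150 = NA_real_,
                           provenance = "circular") {
  vals <- c(co, isf, dsf, gsf, tg, co150, isf150, dsf150, gsf150)
  if (any(!is.na(vals) & (vals < -1e-9 | vals > 1 + 1e-9))) {
    stop("site estimates must lie in [0, 1]")
  }
  structure(list(CO = co, ISF = isf, DSF = dsf, GSF = gsf, TG = tg,
                 CO150 = co150, ISF150 = isf150, DSF150 = dsf150,
                 GSF150 = gsf150, provenance = provenance),
            class = "site_estimates")
}

#' @export
print.site_estimates <- function(x, ...) {
  cat(sprintf("<site_estimates> [%s]\n", x$provenance))
  v <- unlist(x[c("CO", "ISF", "DSF", "GSF", "TG",
                  "CO150", "ISF150", "DSF150", "GSF150")])
  v <- v[!is.na(v)]
  if (length(v)) print(round(v, 4))
  invisible(x)
}

#' @export
as.data.frame.site_estimates <- function(x, ...) {
  data.frame(provenance = x$provenance, CO = x$CO, ISF = x$ISF, DSF = x$DSF,
             GSF = x$GSF, TG = x$TG, CO150 = x$CO150, ISF150 = x$ISF150,
             DSF150 = x$DSF150, GSF150 = x$GSF150)
}

#' Full hemisphere analysis
#'
#' Orchestrates the standard pipeline for a segmented hemisphere raster:
#' gap-fraction grid, canopy openness, indirect/direct/global site factors,
#' and (optionally) the 150-degree-FOV variants obtained by masking the
#' 75-90-degree annuli as obstructed.
#'
#' @param h A [hemisphere_raster()].
#' @param latitude Site latitude in degrees.
#' @param fov150 If `TRUE`, also compute CO150/ISF150/DSF150/GSF150.
#' @param track Optional precomputed [build_sun_track()] for `latitude`
#'   (rebuilt when `NULL`).
#' @param gsf_weights Passed to [global_site_factor()].
#' @param provenance Label stored in the result.
#' @param ... Passed to [grid_gap_fraction()].
#' @return A [site_estimates()] object with attribute `"grid"` holding the
#'   [sky_grid()].
#' @export
analyze_hemisphere <- function(h, latitude, fov150 = FALSE, track = NULL,
                               gsf_weights = c(0.65, 0.35),
                               provenance = "circular", ...) {
  grid <- grid_gap_fraction(h, ...)
  if (is.null(track)) track <- build_sun_track(latitude)
  co <- canopy_openness(grid)
  isf <- indirect_site_factor(grid)
  dsf <- direct_site_factor(grid, track)
  gsf <- global_site_factor(isf, dsf, gsf_weights)
  if (fov150) {
    g150 <- apply_fov_mask(grid, 75)
    isf150 <- indirect_site_factor(g150)
    dsf150 <- direct_site_factor(g150, track)
    est <- site_estimates(co = co, isf = isf, dsf = dsf, gsf = gsf,
                          co150 = canopy_openness(g150), isf150 = isf150,
                          dsf150 = dsf150,
                          gsf150 = global_site_factor(isf150, dsf150,
                                                      gsf_weights),
                          provenance = provenance)
  } else {
    est <- site_estimates(co = co, isf = isf, dsf = dsf, gsf = gsf,
                          provenance = provenance)
  }
  attr(est, "grid") <- grid
  est
}
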