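#' Parameter-recovery study on synthetic circular photographs
#'
#' For each of `n_scenes` random canopy scenes, renders a circular
#' photograph, runs the full circular pipeline (segmentation, sky grid,
#' openness and site factors) and compares the estimates with the scene's
#' analytic ground truth.
#'
#' @param n_scenes Number of scenes.
#' @param seed Master seed; per-scene seeds are derived from it.
#' @param size_px Circular render side length.
#' @param latitude Degrees.
#' @param method Segmentation method.
#' @param artifact_fraction Share of bright-leaf canopy pixels (0 for a
#'   clean recovery experiment).
#' @param ... Further arguments to [generate_scene()].
#' @return Data frame with truth and estimated CO/ISF/DSF/GSF per scene.
#' @export
recovery_study <- function(n_scenes = 20, seed = 1, size_px = 1024,
                           latitude = 53, method = "isodata_blue",
                           artifact_fraction = 0, ...) {
  track <- build_sun_track(latitude)
  out <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    scene <- generate_scene(sub_seed(seed, 100 + i),
                            artifact_fraction = artifact_fraction, ...)
    truth <- truth_site_estimates(scene, latitude, track = track)$estimates
    ren <- render_circular(scene, size_px = size_px)
    est <- analyze_circular_image(ren$rgb, ren$projection, latitude,
                                  method = method, track = track)
    out[[i]] <- data.frame(
      scene = i,
      truth_co = truth$CO, est_co = est$CO,
      truth_isf = truth$ISF, est_isf = est$ISF,
      truth_dsf = truth$DSF, est_dsf = est$DSF,
      truth_gsf = truth$GSF, est_gsf = est$GSF)
  }
  do.call(rbind, out)
}

#' Merged-protocol fidelity study
#'
#' For each scene, compares estimates from the circular pipeline with those
#' from the merged orthogonal diagonal pair of the same scene (the
#' desk-scale analogue of comparing the two camera protocols in the field).
#'
#' @inheritParams recovery_study
#' @param frame_dims Diagonal frame `(width, height)` in pixels.
#' @param out_size Merged raster side length.
#' @param circular_px Circular render side length.
#' @return Data frame with circular and merged CO/ISF/DSF/GSF per scene.
#' @export
merged_fidelity_study <- function(n_scenes = 20, seed = 1,
                                  frame_dims = c(1152, 648), out_size = 1024,
                                  circular_px = 1024, latitude = 53,
                                  method = "isodata_blue",
                                  artifact_fraction = 0, ...) {
  track <- build_sun_track(latitude)
  out <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    scene <- generate_scene(sub_seed(seed, 200 + i),
                            artifact_fraction = artifact_fraction, ...)
    ren <- render_circular(scene, size_px = circular_px)
    circ <- analyze_circular_image(ren$rgb, ren$projection, latitude,
                                   method = method, track = track)
    few <- render_diagonal(scene, orientation = 90, frame_dims = frame_dims)
    fns <- render_diagonal(scene, orientation = 0, frame_dims = frame_dims)
    mrg <- analyze_merged_pair(few, fns, latitude, method = method,
                               out_size = out_size, track = track)
    out[[i]] <- data.frame(
      scene = i,
      circ_co = circ$CO, merged_co = mrg$CO,
      circ_isf = circ$ISF, merged_isf = mrg$ISF,
      circ_dsf = circ$DSF, merged_dsf = mrg$DSF,
      circ_gsf = circ$GSF, merged_gsf = mrg$GSF)
  }
  do.call(rbind, out)
}

#' Diagonal-frame total-gap bias study
#'
#' On horizon-loaded scenes, the rectangular diagonal footprint excludes
#' much of the image periphery where obstruction concentrates, so the
#' averaged total gap of a diagonal pair systematically exceeds the canopy
#' openness of the full circular image. This study measures that bias
#' direction scene by scene.
#'
#' @inheritParams merged_fidelity_study
#' @param zenith_exponent Horizon-loading exponent of the generated scenes.
#' @return Data frame with `tg_avg` (diagonal pair), `co_circ` (circular
#'   pipeline) and `truth_co` per scene.
#' @export
diagonal_bias_study <- function(n_scenes = 40, seed = 1,
                                frame_dims = c(640, 360), circular_px = 512,
                                method = "isodata_blue",
                                zenith_exponent = 1.5, ...) {
  out <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    scene <- generate_scene(sub_seed(seed, 300 + i),
                            zenith_exponent = zenith_exponent, ...)
    few <- render_diagonal(scene, orientation = 90, frame_dims = frame_dims)
    fns <- render_diagonal(scene, orientation = 0, frame_dims = frame_dims)
    tg <- average_pair_total_gap(few, fns, method = method)
    ren <- render_circular(scene, size_px = circular_px)
    msk <- apply_circular_mask(ren$rgb, ren$projection)
    seg <- segment_image(ren$rgb, msk$coverage, method)
    h <- hemisphere_raster(seg$sky_mask, msk$coverage, ren$projection)
    co <- canopy_openness(grid_gap_fraction(h))
    truth <- truth_site_estimates(scene, resolution = 1,
                                  track = .empty_track())$estimates
    out[[i]] <- data.frame(scene = i, tg_avg = as.numeric(tg), co_circ = co,
                           truth_co = truth$CO)
  }
  do.call(rbind, out)
}

# A single-sample placeholder track for studies that only need CO/ISF.
.empty_track <- function() {
  structure(data.frame(day_of_year = 172L, solar_time = 12,
                       zenith = 30, azimuth = 180, weight = 1),
            class = c("sun_track", "data.frame"))
}

#' Bright-leaf artifact segmentation study
#'
#' Renders artifact-bearing diagonal frames and compares blue-channel
#' IsoData with the enhanced colour-attribute segmentation: total gap per
#' method and pixel accuracy against the rendered ground truth.
#'
#' @inheritParams diagonal_bias_study
#' @param artifact_fraction Share of canopy pixels rendered as bright
#'   leaves.
#' @return Data frame with `tg_iso`, `tg_enh`, `acc_iso`, `acc_enh`.
#' @export
artifact_segmentation_study <- function(n_scenes = 20, seed = 1,
                                        frame_dims = c(640, 360),
                                        artifact_fraction = 0.03, ...) {
  out <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    scene <- generate_scene(sub_seed(seed, 400 + i),
                            artifact_fraction = artifact_fraction, ...)
    frame <- render_diagonal(scene, orientation = 0, frame_dims = frame_dims)
    seg_iso <- classify_blue_isodata(frame$rgb)
    seg_enh <- classify_enhanced(frame$rgb)
    truth <- frame$truth_sky
    out[[i]] <- data.frame(
      scene = i,
      tg_iso = total_gap(seg_iso), tg_enh = total_gap(seg_enh),
      acc_iso = mean(seg_iso$sky_mask == truth),
      acc_enh = mean(seg_enh$sky_mask == truth))
  }
  do.call(rbind, out)
}

# Simulate one paired-record dataset with per-overstory slopes.
simulate_calibration_records <- function(n, intercept, slope_base,
                                         slope_offsets, noise_sd,
                                         x_range = c(0.05, 0.65)) {
  ovs <- c("broadleaves", "douglas", "sitka", "larch", "pine")
  ov <- rep(ovs, length.out = n)
  x <- stats::runif(n, x_range[1], x_range[2])
  off <- c(broadleaves = 0, slope_offsets)[ov]
  y <- intercept + (slope_base + off) * x + stats::rnorm(n, 0, noise_sd)
  data.frame(point_id = seq_len(n), OV = ov, x = x, y = y)
}

#' Calibration coefficient-recovery study
#'
#' Simulates paired datasets from a known straight-line transformation and
#' measures the bias of the refitted intercept and slope.
#'
#' @param n_rep Number of replicate datasets.
#' @param n Records per dataset.
#' @param noise_sd Residual noise SD.
#' @param seed Master seed.
#' @param intercept,slope Generating coefficients.
#' @return Data frame of fitted `intercept` and `slope` per replicate, with
#'   attribute `truth`.
#' @export
calibration_bias_study <- function(n_rep = 100, n = 200, noise_sd = 0.03,
                                   seed = 1, intercept = 0.05, slope = 0.6) {
  out <- with_seed(sub_seed(seed, 500), {
    res <- matrix(NA_real_, n_rep, 2)
    for (r in seq_len(n_rep)) {
      df <- simulate_calibration_records(n, intercept, slope,
                                         slope_offsets = c(
                                           douglas = 0, sitka = 0,
                                           larch = 0, pine = 0),
                                         noise_sd = noise_sd)
      fit <- fit_linear_structure(df, "y", "x", "y~x")
      res[r, ] <- fit$coefficients[1:2]
    }
    res
  })
  df <- data.frame(intercept = out[, 1], slope = out[, 2])
  attr(df, "truth") <- c(intercept = intercept, slope = slope)
  df
}

#' AIC structure-selection study
#'
#' Simulates replicate paired datasets either from a homogeneous
#' straight-line model (no overstory effect) or from a model with strong
#' overstory-specific slopes, runs [compare_structures_aic()] on each, and
#' records which structure ranks first.
#'
#' @inheritParams calibration_bias_study
#' @param heterogeneous If `TRUE`, generate overstory-specific slopes
#'   (pattern: larch and pine steepest, douglas and sitka intermediate,
#'   broadleaves the baseline).
#' @return Data frame per replicate: `best` (structure id),
#'   `aic_interaction_beats_base` (logical) and, for heterogeneous runs,
#'   whether the fitted slope ordering larch/pine above broadleaves was
#'   recovered.
#' @export
aic_selection_study <- function(n_rep = 100, n = 200, noise_sd = 0.03,
                                seed = 1, heterogeneous = FALSE) {
  offsets <- if (heterogeneous) {
    c(douglas = 0.197, sitka = 0.228, larch = 0.398, pine = 0.267)
  } else {
    c(douglas = 0, sitka = 0, larch = 0, pine = 0)
  }
  with_seed(sub_seed(seed, 600 + heterogeneous), {
    out <- vector("list", n_rep)
    for (r in seq_len(n_rep)) {
      df <- simulate_calibration_records(n, 0.025, 0.275, offsets, noise_sd)
      tab <- compare_structures_aic(df, "y", "x",
                                    structures = calibration_structures[1:4])
      aic <- stats::setNames(tab$AIC, tab$structure)
      ord <- NA
      if (heterogeneous) {
        fit <- attr(tab, "models")[["y~x+x:OV"]]
        cf <- fit$coefficients
        lar <- cf[grep("larch", names(cf))]
        pin <- cf[grep("pine", names(cf))]
        ord <- length(lar) == 1 && length(pin) == 1 && lar > 0 && pin > 0
      }
      out[[r]] <- data.frame(
        rep = r, best = tab$structure[1],
        aic_interaction_beats_base = aic["y~x+x:OV"] < aic["y~x"],
        ordering_recovered = ord)
    }
    do.call(rbind, out)
  })
}
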