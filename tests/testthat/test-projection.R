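test_that("pixel-to-direction honours the equidistant law and compass convention", {
  proj <- projection_model(center = c(500, 500), radius_px = 400,
                           max_zenith = 90)
  d <- pixel_to_direction(rbind(
    c(500, 500),      # optical axis
    c(100, 500),      # straight up-image at full radius
    c(300, 500),      # half radius up-image
    c(500, 100)),     # full radius image-left
    proj)
  expect_equal(d$zenith, c(0, 90, 45, 90))
  expect_equal(d$azimuth[1], 0)              # azimuth undefined -> 0
  expect_equal(d$azimuth[2], 0)              # image-up = North
  expect_equal(d$azimuth[4], 90)             # image-left = East (as-captured)

  proj75 <- projection_model(c(500, 500), 400, max_zenith = 75)
  expect_equal(pixel_to_direction(c(300, 500), proj75)$zenith, 37.5)

  # outside the field of view
  expect_true(is.na(pixel_to_direction(c(500, 950), proj75)$zenith))
  expect_error(pixel_to_direction(c(NaN, 1), proj), "non-finite")
})

test_that("mirror flag flips East/West while keeping North", {
  proj <- projection_model(c(500, 500), 400, mirror = TRUE)
  d <- pixel_to_direction(rbind(c(100, 500), c(500, 900)), proj)
  expect_equal(d$azimuth, c(0, 90))  # East now on image-right
})

test_that("direction_to_pixel inverts pixel_to_direction within half a pixel", {
  set.seed(42)
  for (proj in list(projection_model(c(400, 420), 390),
                    projection_model(c(300, 300), 280, max_zenith = 75,
                                     north_offset = 137, mirror = TRUE))) {
    d <- data.frame(zenith = runif(1000) * proj$max_zenith,
                    azimuth = runif(1000) * 360)
    px <- direction_to_pixel(d, proj)
    back <- pixel_to_direction(px, proj)
    px2 <- direction_to_pixel(back, proj)
    expect_lt(max(sqrt(rowSums((px - px2)^2))), 0.5)
    expect_lt(max(abs(back$zenith - d$zenith)), 1e-9)
  }
  proj <- projection_model(c(400, 400), 390)
  expect_equal(direction_to_pixel(list(zenith = 0, azimuth = 123), proj),
               cbind(row = 400, col = 400))
  expect_equal(direction_to_pixel(list(zenith = 90, azimuth = 0), proj),
               cbind(row = 10, col = 400))
  expect_error(direction_to_pixel(list(zenith = 80, azimuth = 0),
                                  projection_model(c(1, 1), 1, 75)),
               "out of field")
})

test_that("diagonal footprint maps corners to half the diagonal FOV", {
  fp <- diagonal_footprint(c(3264, 1836), fov_diagonal = 150)
  expect_equal(fp$projection$max_zenith, 75)
  # true frame corner (continuous coordinate) sits exactly at 75 degrees
  corner <- pixel_to_direction(c(0, 0), fp$projection)
  expect_equal(corner$zenith, 75)
  centre <- pixel_to_direction(c(1836 / 2, 3264 / 2), fp$projection)
  expect_equal(centre$zenith, 0)
  # halfway along the half-diagonal: linearity
  mid <- pixel_to_direction(c(1836 * 0.25, 3264 * 0.25), fp$projection)
  expect_equal(mid$zenith, 37.5)
  # every pixel centre is inside the field
  expect_true(all(fp$inside))
  expect_lte(max(fp$zenith), 75)
  # discrete field agrees with the analytic law
  proj <- fp$projection
  i <- 100; j <- 200
  r <- sqrt((i - 0.5 - proj$center[1])^2 + (j - 0.5 - proj$center[2])^2)
  expect_lt(abs(fp$zenith[i, j] - r / proj$radius_px * 75), 1e-9)
  expect_error(diagonal_projection(100, 200), "width >= height")
})

test_that("apply_circular_mask isolates the image circle", {
  size <- 400
  rgb <- array(0.5, dim = c(size, size, 3))
  proj <- projection_model(c(size / 2, size / 2), size / 2)
  msk <- apply_circular_mask(rgb, proj)
  expect_equal(mean(msk$coverage), pi / 4, tolerance = 0.01)
  expect_equal(msk$coverage[1, 1], 0L)
  expect_equal(msk$coverage[1, size], 0L)
  expect_equal(msk$coverage[size, 1], 0L)
  expect_equal(msk$coverage[size, size], 0L)

  # 183-degree lens: radius calibrated so zenith 90 sits inside the rim
  r_image <- size / 2
  proj183 <- projection_model(c(size / 2, size / 2), r_image * 90 / 91.5)
  msk183 <- apply_circular_mask(rgb, proj183)
  field <- direction_field(projection_model(c(size / 2, size / 2), r_image),
                           c(size, size))
  # oracle: pixels whose angle under the full-rim scaling exceeds 90 * (90/91.5)
  zen_lens <- field$zenith * 91.5 / 90   # zenith under the 183-degree lens
  oracle <- sum(!is.na(zen_lens) & zen_lens <= 90 &
                  field$inside)
  expect_equal(sum(msk183$coverage),
               sum(zen_lens <= 90, na.rm = TRUE))

  expect_error(apply_circular_mask(rgb, projection_model(c(10, 10), 300)),
               "calibration")
})

test_that("merging an orthogonal pair builds the documented pseudo-hemisphere", {
  open <- canopy_scene(numeric(0), numeric(0), numeric(0))
  few <- render_diagonal(open, orientation = 90, frame_dims = c(816, 459),
                         noise_sd = 0)
  fns <- render_diagonal(open, orientation = 0, frame_dims = c(816, 459),
                         noise_sd = 0)
  m <- merge_diagonal_pair(few, fns, out_size = 601)
  field <- direction_field(m$projection, dim(m$coverage))

  # pixel-count coverage fraction matches the closed-form union area
  w <- 816; h <- 459
  rho2 <- (w^2 + h^2) / 4 * (90 / 75)^2
  expected <- (2 * w * h - h^2) / (pi * rho2)
  got <- sum(m$coverage) / sum(field$inside)
  expect_equal(got, expected, tolerance = 0.005 / expected)

  # no pixel outside the union footprint is covered, and none outside the disk
  expect_true(all(m$coverage[!field$inside] == 0))
  # the reference (E-W) frame wins in the central overlap
  expect_equal(m$source[301, 301], 1L)

  expect_error(merge_diagonal_pair(few, render_diagonal(open, 0,
                 frame_dims = c(816, 459), fov_diagonal = 140)),
               "incompatible")
  expect_error(merge_diagonal_pair(few, few), "orthogonal")
})

test_that("E-W frame is the reference where the footprints overlap", {
  sky <- matrix(1, 90, 160)
  few <- diagonal_frame(two_tone_rgb(sky), orientation = 90)       # all sky
  fns <- diagonal_frame(two_tone_rgb(0 * sky), orientation = 0)    # all canopy
  m <- merge_diagonal_pair(few, fns, out_size = 301)
  seg <- classify_blue_isodata(m$rgb, m$coverage)
  # central overlap must be classified sky (E-W values)
  expect_equal(seg$sky_mask[151, 151], 1L)
  expect_true(all(seg$sky_mask[m$source == 1L] == 1L))
  expect_true(all(seg$sky_mask[m$source == 2L] == 0L))
})

test_that("rotating both orientations by 90 degrees rotates the merged coverage", {
  open <- canopy_scene(numeric(0), numeric(0), numeric(0))
  f1 <- render_diagonal(open, orientation = 90, frame_dims = c(320, 180),
                        noise_sd = 0)
  f2 <- render_diagonal(open, orientation = 0, frame_dims = c(320, 180),
                        noise_sd = 0)
  f3 <- render_diagonal(open, orientation = 180, frame_dims = c(320, 180),
                        noise_sd = 0)
  m12 <- merge_diagonal_pair(f1, f2, out_size = 200)
  m23 <- merge_diagonal_pair(f3, f1, out_size = 200)
  # coverage rotated by 90 degrees = transpose + reverse of the raster
  rot90 <- t(m12$coverage)[, nrow(m12$coverage):1]
  expect_equal(sum(abs(m23$coverage - rot90)), 0)
})

test_that("hemisphere raster forbids sky outside coverage", {
  proj <- projection_model(c(50, 50), 50)
  sky <- matrix(1, 100, 100)
  cov <- matrix(0, 100, 100); cov[30:70, 30:70] <- 1
  h <- hemisphere_raster(sky, cov, proj)
  expect_true(all(h$sky_mask[cov == 0] == 0))
  expect_error(hemisphere_raster(sky, cov[1:50, ], proj), "dimensions")
})
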