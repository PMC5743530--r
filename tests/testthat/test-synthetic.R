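test_that("scene generation is deterministic and zenith-loaded", {
  s1 <- generate_scene(42)
  s2 <- generate_scene(42)
  expect_identical(s1, s2)
  expect_length(s1$zenith, 300)
  expect_true(all(s1$radius >= 1 & s1$radius <= 6))
  expect_false(identical(generate_scene(43)$zenith, s1$zenith))
  # positive exponent pushes disk centres toward the horizon
  lo <- generate_scene(1, n_disks = 2000, zenith_exponent = 0)
  hi <- generate_scene(1, n_disks = 2000, zenith_exponent = 3)
  expect_gt(mean(hi$zenith), mean(lo$zenith) + 5)
  # empty scene is fully open
  s0 <- generate_scene(1, n_disks = 0)
  tr0 <- truth_site_estimates(s0, resolution = 1)
  expect_equal(tr0$estimates$CO, 1)
  expect_equal(tr0$estimates$GSF, 1)
})

test_that("denser scenes strictly reduce ground-truth openness", {
  for (s in 1:10) {
    co50 <- truth_site_estimates(generate_scene(s, n_disks = 50),
                                 resolution = 1)$estimates$CO
    co500 <- truth_site_estimates(generate_scene(s, n_disks = 500),
                                  resolution = 1)$estimates$CO
    expect_lt(co500, co50)
  }
})

test_that("the gap indicator obeys disk geometry", {
  scene <- canopy_scene(zenith = c(30, 120), azimuth = c(90, 0),
                        radius = c(10, 40))
  expect_equal(is_sky_direction(scene, c(30, 90)), 0L)   # at a disk centre
  expect_equal(is_sky_direction(scene, c(30, 270)), 1L)
  # the below-horizon disk (centre zenith 120, radius 40) reaches up to
  # zenith 80 on its own azimuth
  expect_equal(is_sky_direction(scene, c(85, 0)), 0L)
  expect_equal(is_sky_direction(scene, c(75, 0)), 1L)
  empty <- canopy_scene(numeric(0), numeric(0), numeric(0))
  expect_true(all(is_sky_direction(empty,
    list(zenith = runif(50) * 90, azimuth = runif(50) * 360)) == 1L))
  expect_error(is_sky_direction(scene, c(100, 0)), "zenith in \\[0, 90\\]")
})

test_that("rendered circular images agree with the analytic gap function", {
  scene <- generate_scene(7, artifact_fraction = 0)
  ren <- render_circular(scene, size_px = 384, noise_sd = 0)
  field <- direction_field(ren$projection, dim(ren$truth_sky))
  idx <- which(field$inside)
  truth <- is_sky_direction(scene, list(zenith = field$zenith[idx],
                                        azimuth = field$azimuth[idx]))
  expect_gte(mean(ren$truth_sky[idx] == truth), 0.995)
  # noise-free, artifact-free render segments exactly to the truth mask
  msk <- apply_circular_mask(ren$rgb, ren$projection)
  seg <- classify_blue_isodata(ren$rgb, msk$coverage)
  expect_identical(seg$sky_mask, ren$truth_sky)
  # same seed renders identically
  ren2 <- render_circular(scene, size_px = 384, noise_sd = 0)
  expect_identical(ren$rgb, ren2$rgb)
})

test_that("diagonal renders are consistent with circular renders of the same scene", {
  scene <- generate_scene(19, artifact_fraction = 0)
  frame <- render_diagonal(scene, orientation = 0, frame_dims = c(320, 180),
                           noise_sd = 0)
  field <- direction_field(frame$projection, dim(frame$truth_sky))
  truth <- is_sky_direction(scene, list(zenith = as.vector(field$zenith),
                                        azimuth = as.vector(field$azimuth)))
  expect_equal(as.vector(frame$truth_sky), truth)
  # an azimuthally asymmetric scene renders differently under rotation
  f90 <- render_diagonal(scene, orientation = 90, frame_dims = c(320, 180),
                         noise_sd = 0)
  expect_false(identical(frame$truth_sky, f90$truth_sky))
})

test_that("handheld jitter is seeded, bounded and degrades estimates gracefully", {
  scene <- generate_scene(23)
  j <- list(tilt_sd = 2, azimuth_sd = 3, seed = 99)
  f1 <- render_diagonal(scene, 0, frame_dims = c(320, 180), jitter = j)
  f2 <- render_diagonal(scene, 0, frame_dims = c(320, 180), jitter = j)
  expect_identical(f1$rgb, f2$rgb)
  expect_identical(f1$jitter_applied, f2$jitter_applied)
  f0 <- render_diagonal(scene, 0, frame_dims = c(320, 180))
  expect_equal(f0$jitter_applied$tilt_e, 0)
  expect_false(identical(f0$truth_sky, f1$truth_sky))

  # TG error vs the zero-jitter frame grows with tilt, averaged over scenes
  err <- sapply(c(0, 2, 5), function(tsd) {
    mean(sapply(1:8, function(s) {
      sc <- generate_scene(500 + s)
      base <- total_gap(render_diagonal(sc, 0, frame_dims = c(256, 144),
                                        noise_sd = 0)$truth_sky)
      jit <- total_gap(render_diagonal(sc, 0, frame_dims = c(256, 144),
                                       noise_sd = 0,
                                       jitter = list(tilt_sd = tsd,
                                                     azimuth_sd = 0,
                                                     seed = 7000 + s))$truth_sky)
      abs(jit - base)
    }))
  })
  expect_true(all(diff(err) >= 0))
})

test_that("ground-truth site estimates hit closed forms and the GSF identity", {
  # sky only inside the 60-degree cap: one nadir-centred disk occludes the rest
  cap <- canopy_scene(zenith = 180, azimuth = 0, radius = 120)
  tr <- truth_site_estimates(cap, latitude = 53)
  expect_equal(tr$estimates$ISF, 0.8214, tolerance = 0.005)
  expect_equal(tr$estimates$CO, 0.5, tolerance = 0.002)
  expect_equal(tr$estimates$GSF,
               0.65 * tr$estimates$ISF + 0.35 * tr$estimates$DSF,
               tolerance = 1e-12)
  # truth grid equals direct analytic evaluation cell by cell
  gf <- tr$grid$gap_fraction
  expect_true(all(abs(gf[1:12, ] - 1) < 1e-3))
  expect_true(all(gf[13:18, ] < 1e-3))
})

test_that("end-to-end circular pipeline recovers truth on small scenes", {
  study <- recovery_study(n_scenes = 4, seed = 5, size_px = 512)
  expect_lt(max(abs(study$est_co - study$truth_co)), 0.03)
  expect_lt(max(abs(study$est_isf - study$truth_isf)), 0.03)
  expect_lt(max(abs(study$est_gsf - study$truth_gsf)), 0.03)
  expect_lt(max(abs(study$est_dsf - study$truth_dsf)), 0.05)
})
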