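test_that("every generator is deterministic under a fixed seed", {
  acq <- acquisition_model(seed = 42)
  g1 <- make_guv_scene(radius_um = 6, acq = acq)
  g2 <- make_guv_scene(radius_um = 6, acq = acq)
  expect_identical(g1$stack$data, g2$stack$data)

  e1 <- make_er_scene(er_phantom("mixed", n_objects = 20), acq = acq)
  e2 <- make_er_scene(er_phantom("mixed", n_objects = 20), acq = acq)
  expect_identical(e1$stack$data, e2$stack$data)
  expect_identical(nrow(e1$truth$objects), nrow(e2$truth$objects))

  c1 <- simulate_binding_curve(1, 100, 2, c(0, 50, 100, 500), 0.05, seed = 9)
  c2 <- simulate_binding_curve(1, 100, 2, c(0, 50, 100, 500), 0.05, seed = 9)
  expect_identical(c1, c2)

  t1 <- simulate_rate_timeseries(noise_sd = 0.05, seed = 4)
  t2 <- simulate_rate_timeseries(noise_sd = 0.05, seed = 4)
  expect_identical(t1$ratio, t2$ratio)
})

test_that("noiseless GUV shells hit rim amplitude plus background exactly", {
  sc <- make_guv_scene(radius_um = 5, rim_amp = 100, interior_amp = 5,
                       acq = acquisition_clean(background_level = 7))
  v <- frame_volume(sc$stack, 1, 1)
  z <- sc$truth$middle_slice
  expect_equal(max(v[, , z]), 107) # rim + background
  # ground-truth labels align with the rendered shell: rim voxels carry the
  # maximal shell intensity on the noiseless image
  expect_true(all(v[sc$truth$labels == 0] <= 7))
  expect_error(make_guv_scene(radius_um = 0.3), "resolvable")
})

test_that("PSF blur lowers the shell peak in line with a direct convolution", {
  clean <- make_guv_scene(radius_um = 5, rim_amp = 100, interior_amp = 0,
                          acq = acquisition_clean())
  blurred <- make_guv_scene(
    radius_um = 5, rim_amp = 100, interior_amp = 0,
    acq = acquisition_model(psf_sigma_px = 2, gaussian_noise_sd = 0,
                            poisson_scale = 0, background_level = 0, seed = 1)
  )
  v0 <- frame_volume(clean$stack, 1, 1)
  vb <- frame_volume(blurred$stack, 1, 1)
  expect_lt(max(vb), 100)

  # oracle: direct (triple-loop) Gaussian-weighted sum at the blurred peak
  peak <- which(vb == max(vb), arr.ind = TRUE)[1, ]
  cal <- clean$stack$calibration
  sig_xy <- 2
  sig_z <- 2 * cal$dx / cal$dz
  half <- 7L
  acc <- 0; wsum <- 0
  d <- dim(v0)
  for (dy in -half:half) for (dx in -half:half) for (dz in -2:2) {
    w <- exp(-(dy^2 + dx^2) / (2 * sig_xy^2)) * exp(-dz^2 / (2 * max(sig_z, 1e-6)^2))
    yy <- peak[1] + dy; xx <- peak[2] + dx; zz <- peak[3] + dz
    if (yy >= 1 && yy <= d[1] && xx >= 1 && xx <= d[2] && zz >= 1 && zz <= d[3]) {
      acc <- acc + w * v0[yy, xx, zz]
      wsum <- wsum + w
    }
  }
  expected_peak <- acc / wsum
  expect_equal(max(vb), expected_peak, tolerance = 0.15)
})

test_that("nucleus time lapses carry exact ground-truth ratio ramps and labels", {
  ph <- nucleus_phantom(c(8, 8, 3.5), c(4, 4, 2),
                        rim_intensity = seq(100, 300, length.out = 10),
                        interior_intensity = 100)
  scn <- make_nucleus_timelapse(ph, n_frames = 10, acq = acquisition_clean(),
                                img_px = c(100, 100), n_z = 5)
  expect_equal(scn$truth$ratio[1, ], seq(1, 3, length.out = 10))

  three <- list(
    nucleus_phantom(c(6, 6, 3.5), c(3, 3, 2)),
    nucleus_phantom(c(6, 18, 3.5), c(3, 3, 2)),
    nucleus_phantom(c(18, 12, 3.5), c(3, 3, 2))
  )
  s3 <- make_nucleus_timelapse(three, n_frames = 2, acq = acquisition_clean(),
                               img_px = c(160, 160), n_z = 5)
  for (t in 1:2) {
    expect_setequal(setdiff(unique(as.integer(s3$truth$labels[[t]])), 0L), 1:3)
  }

  # a drifting nucleus stays within the 50 um tracking bound over 10 frames
  drift <- nucleus_phantom(c(8, 8, 3.5), c(3, 3, 2),
                           drift_um_per_frame = c(0, 2))
  sd10 <- make_nucleus_timelapse(drift, n_frames = 10,
                                 acq = acquisition_clean(),
                                 img_px = c(100, 260), n_z = 5)
  disp <- sd10$truth$centers_um[[10]][1, ] - sd10$truth$centers_um[[1]][1, ]
  expect_equal(sqrt(sum(disp^2)), 18) # 2 um/frame over 9 inter-frame steps
  expect_lt(sqrt(sum(disp^2)), 50)

  overlapping <- list(
    nucleus_phantom(c(8, 8, 3.5), c(4, 4, 2)),
    nucleus_phantom(c(8, 10, 3.5), c(4, 4, 2))
  )
  expect_error(
    make_nucleus_timelapse(overlapping, n_frames = 1,
                           acq = acquisition_clean(), img_px = c(100, 100),
                           n_z = 5),
    "overlap"
  )
})

test_that("ER ground truth is analytic and orders the two modes correctly", {
  # one disc: circularity exactly 1 by construction
  ves <- make_er_scene(er_phantom("vesiculated", n_objects = 1,
                                  vesicle_radius_um = c(3.2, 3.2)),
                       acq = acquisition_clean(), img_px = c(96, 96))
  expect_equal(nrow(ves$truth$objects), 1)
  expect_equal(ves$truth$objects$circularity, 1)

  # the analytic rectangle identity the circularity formula must satisfy
  expect_equal(circularity(400, 208), 4 * pi * 400 / 208^2)
  expect_equal(circularity(400, 208), 0.1161832, tolerance = 1e-6)

  # vesiculated true median circularity exceeds tubular, every seed
  for (seed in 1:5) {
    tub <- make_er_scene(er_phantom("tubular", n_objects = 10),
                         acq = acquisition_model(seed = seed))
    vv <- make_er_scene(er_phantom("vesiculated", n_objects = 30),
                        acq = acquisition_model(seed = seed + 50))
    expect_gt(median(vv$truth$objects$circularity),
              median(tub$truth$objects$circularity))
  }
})

test_that("binding-curve simulator satisfies the isotherm identities", {
  # half-saturation at c = kd
  out <- simulate_binding_curve(2, 100, 1.7, c(0, 100), noise_sd = 0)
  expect_equal(out$bound, c(0, 1))
  # frozen direct evaluation: 500^2 / (500^2 + 100^2)
  out2 <- simulate_binding_curve(1, 100, 2, 500, noise_sd = 0)
  expect_equal(out2$bound, 0.961538461538, tolerance = 1e-10)
  expect_error(simulate_binding_curve(1, 100, 2, c(-5, 10)), "non-negative")
})

test_that("rate time-series generator follows its breakpoints", {
  flat <- simulate_rate_timeseries(baseline = 2, slope = 0,
                                   t_linear_start = 3, t_plateau = 10,
                                   n_frames = 15, noise_sd = 0)
  expect_true(all(flat$ratio == 2))

  ts <- simulate_rate_timeseries(baseline = 1, slope = 0.1,
                                 t_linear_start = 5, t_plateau = 15,
                                 n_frames = 20, noise_sd = 0)
  expect_equal(ts$ratio[ts$time == 15], 2.0) # 1 + 0.1 * 10
  expect_equal(ts$ratio[ts$time == 19], 2.0) # plateau
  expect_equal(attr(ts, "true_slope"), 0.1)
  expect_error(simulate_rate_timeseries(t_linear_start = 10, t_plateau = 5),
               "breakpoints")
})
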