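test_that("rolling-ball background subtraction behaves on flat and shaded input", {
  expect_true(all(rolling_ball(matrix(7.7, 80, 80)) == 0))

  # linear shading gradient, ball radius much larger than any object:
  # the residual amplitude away from the image border drops >= 10x
  ramp <- matrix(rep(seq(0, 10, length.out = 200), each = 200), 200, 200)
  res <- rolling_ball(ramp, 50)
  interior <- res[60:140, 60:140]
  expect_lt(diff(range(interior)), diff(range(ramp)) / 10)

  # phantom nucleus: rim/interior contrast survives preprocessing
  scn <- ramp_scene(acquisition_model(seed = 8, psf_sigma_px = 0,
                                      gaussian_noise_sd = 0,
                                      poisson_scale = 0,
                                      background_level = 20), n_frames = 1)
  pp <- preprocess_nuclei(scn$stack)
  v <- frame_volume(pp, 1, 1)
  truth <- scn$truth$labels[[1]] == 1
  raw <- frame_volume(scn$stack, 1, 1)
  rim_mask <- truth & raw == max(raw)
  int_mask <- truth & raw == 150 + 20
  contrast_pp <- median(v[rim_mask]) / median(v[int_mask])
  expect_equal(contrast_pp, 1, tolerance = 0.1) # ramp frame 1: rim = interior
})

test_that("well-separated phantom nuclei segment to the right count with high IoU", {
  phs <- list(nucleus_phantom(c(9, 9, 6), c(5, 5, 2.8)),
              nucleus_phantom(c(9, 28, 6), c(5, 5, 2.8)),
              nucleus_phantom(c(28, 18, 6), c(5, 5, 2.8)))
  scn <- make_nucleus_timelapse(phs, n_frames = 1,
                                acq = acquisition_model(seed = 1,
                                                        gaussian_noise_sd = 3,
                                                        background_level = 5),
                                img_px = c(232, 232), n_z = 9)
  lab <- segment_scene(scn)[[1]]
  expect_equal(max(lab), 3)
  for (i in 1:3) {
    expect_gte(best_iou(lab, scn$truth$labels[[1]], i), 0.9)
  }
})

test_that("touching nuclei with distinct peaks are split by the watershed markers", {
  p1 <- nucleus_phantom(c(12.8, 8.6, 6), c(5, 5, 2.8),
                        rim_intensity = 260, interior_intensity = 220)
  p2 <- nucleus_phantom(c(12.8, 18.85, 6), c(5, 5, 2.8),
                        rim_intensity = 150, interior_intensity = 120)
  scn <- make_nucleus_timelapse(list(p1, p2), n_frames = 1,
                                acq = acquisition_model(seed = 3,
                                                        gaussian_noise_sd = 2,
                                                        background_level = 5),
                                img_px = c(160, 176), n_z = 9)
  pp <- preprocess_nuclei(scn$stack)
  v <- frame_volume(pp, 1, 1)
  mask <- v > rimquant:::otsu_threshold(v)
  expect_equal(max(label3d(mask)), 1) # genuinely merged in the raw mask
  lab <- segment_nuclei(pp)
  expect_equal(max(lab), 2)
})

test_that("blank frames segment to zero labels", {
  blank <- array(0, c(64, 64, 5))
  expect_equal(max(segment_nuclei(blank)), 0)
})

test_that("segmentation recovers the phantom count across 20 random seeds", {
  cal <- pixel_calibration(dx = 0.25)
  for (seed in 1:20) {
    phs <- list(nucleus_phantom(c(9, 9, 6), c(4.5, 4.5, 2.8)),
                nucleus_phantom(c(24, 28, 6), c(4.5, 4.5, 2.8)))
    scn <- make_nucleus_timelapse(phs, n_frames = 1,
                                  acq = acquisition_model(seed = seed,
                                                          gaussian_noise_sd = 3,
                                                          background_level = 5),
                                  calibration = cal,
                                  img_px = c(140, 150), n_z = 9)
    lab <- segment_nuclei(preprocess_nuclei(scn$stack))
    expect_equal(max(lab), 2)
  }
})

test_that("tracking links stationary and drifting objects and splits long jumps", {
  cal <- pixel_calibration(dx = 0.32, dy = 0.32)

  stationary <- replicate(10, cube_labels(50, 50), simplify = FALSE)
  tr <- track_nuclei(stationary, cal)
  expect_equal(length(unique(tr$track)), 1)
  expect_equal(nrow(tr), 10)

  # 2 um/frame drift: 6.25 px/frame, one unbroken track
  drifting <- lapply(0:9, function(t) cube_labels(50, 50 + round(t * 2 / 0.32)))
  trd <- track_nuclei(drifting, cal)
  expect_equal(length(unique(trd$track)), 1)

  # 60 um jump exceeds the 50 um bound: two tracks
  jump <- c(replicate(3, cube_labels(50, 50), simplify = FALSE),
            replicate(3, cube_labels(50, 50 + round(60 / 0.32)), simplify = FALSE))
  trj <- track_nuclei(jump, cal)
  expect_equal(length(unique(trj$track)), 2)

  expect_equal(nrow(track_nuclei(list(), cal)), 0)
})

test_that("tracking survives segmentation end-to-end for a drifting nucleus", {
  ph <- nucleus_phantom(c(10, 8, 6), c(4, 4, 2.8), drift_um_per_frame = c(0, 2))
  scn <- make_nucleus_timelapse(ph, n_frames = 6,
                                acq = acquisition_model(seed = 6,
                                                        gaussian_noise_sd = 3,
                                                        background_level = 5),
                                img_px = c(128, 200), n_z = 9)
  labels <- segment_scene(scn)
  tr <- track_nuclei(labels, scn$stack$calibration)
  expect_equal(length(unique(tr$track)), 1)
  expect_equal(nrow(tr), 6)
})

test_that("binding ratios reproduce phantom ground truth", {
  # defining identity: rim 300 / interior 150 -> ratio 2 (noiseless)
  ph <- nucleus_phantom(c(12.8, 12.8, 6), c(6, 6, 3),
                        rim_intensity = 300, interior_intensity = 150)
  scn <- make_nucleus_timelapse(ph, n_frames = 1, acq = acquisition_clean(),
                                img_px = c(160, 160), n_z = 9)
  labels <- segment_scene(scn)
  tracks <- track_nuclei(labels, scn$stack$calibration, min_length = 1)
  ts <- measure_nm_binding(tracks, scn$stack, labels)
  expect_equal(ts$ratio, 2, tolerance = 0.02)

  # uniform nucleus -> ratio exactly 1
  phu <- nucleus_phantom(c(12.8, 12.8, 6), c(6, 6, 3),
                         rim_intensity = 200, interior_intensity = 200)
  scu <- make_nucleus_timelapse(phu, n_frames = 1, acq = acquisition_clean(),
                                img_px = c(160, 160), n_z = 9)
  labu <- segment_scene(scu)
  tsu <- measure_nm_binding(track_nuclei(labu, scu$stack$calibration,
                                         min_length = 1),
                            scu$stack, labu)
  expect_equal(tsu$ratio, 1)
})

test_that("ratio_norm is the ratio divided by its first frame, exactly 1 at t0", {
  scn <- ramp_scene(acquisition_model(seed = 5, psf_sigma_px = 0,
                                      gaussian_noise_sd = 3,
                                      poisson_scale = 0, background_level = 5))
  labels <- segment_scene(scn)
  ts <- measure_nm_binding(track_nuclei(labels, scn$stack$calibration),
                           scn$stack, labels)
  expect_identical(ts$ratio_norm[1], 1)
  expect_equal(ts$ratio_norm, ts$ratio / ts$ratio[1])
})

test_that("a falling nucleoplasm raises ratio but leaves the ratiometric readout flat", {
  # the stated caveat: constant rim, decreasing interior
  ph <- nucleus_phantom(c(12.8, 12.8, 6), c(6, 6, 3),
                        rim_intensity = rep(300, 6),
                        interior_intensity = seq(150, 75, length.out = 6))
  scn <- make_nucleus_timelapse(ph, n_frames = 6, acq = acquisition_clean(),
                                img_px = c(160, 160), n_z = 9,
                                lamin_rim_amp = 200)
  labels <- segment_scene(scn)
  tracks <- track_nuclei(labels, scn$stack$calibration)
  ts <- measure_nm_binding(tracks, scn$stack, labels,
                           lamin_channel = "lamin")
  expect_gt(ts$ratio[6], 1.5 * ts$ratio[1])
  expect_equal(ts$ratiometric[6], ts$ratiometric[1], tolerance = 0.02)
})

test_that("line profiles sample endpoints inclusively with bilinear interpolation", {
  img <- matrix(9, 40, 40)
  lp <- line_profile(img, c(20, 5), c(20, 25))
  expect_equal(nrow(lp), 21)
  expect_true(all(lp$intensity == 9))
  expect_equal(max(lp$distance_um), 20 * 0.16)

  # across a phantom nucleus diameter: two rim peaks flank the interior
  ph <- nucleus_phantom(c(12.8, 12.8, 6), c(6, 6, 3),
                        rim_intensity = 300, interior_intensity = 150)
  scn <- make_nucleus_timelapse(ph, n_frames = 1, acq = acquisition_clean(),
                                img_px = c(160, 160), n_z = 9)
  sl <- frame_volume(scn$stack, 1, 1)[, , 5]
  prof <- line_profile(sl, c(81, 20), c(81, 140))
  n <- nrow(prof)
  first_half <- prof$intensity[1:floor(n / 2)]
  second_half <- prof$intensity[(floor(n / 2) + 1):n]
  mid <- prof$intensity[round(n / 2)]
  expect_equal(max(first_half), 300)
  expect_equal(max(second_half), 300)
  expect_equal(mid, 150)

  expect_error(line_profile(img, c(5, 5), c(5, 5)), "zero-length")
})
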