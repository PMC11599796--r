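test_that("interpolation fills gaps and smoothing preserves low-order polynomials", {
  # constant track with interior and edge gaps comes back identical
  rec <- static_recording(frames = 60)
  rec$coords[1, 1, c(1, 2, 10, 30, 59, 60), ] <- NA
  sm <- interpolate_and_smooth(rec)
  expect_false(anyNA(sm$coords))
  expect_equal(sm$coords[1, 1, , 1], rep(10, 60), tolerance = 1e-9)
  expect_equal(sm$coords[1, 1, , 2], rep(40, 60), tolerance = 1e-9)

  # exactly linear track is invariant (the filter fits cubics locally)
  rec2 <- static_recording(frames = 60)
  rec2$coords[2, 5, , 1] <- seq(0, 118, by = 2)
  sm2 <- interpolate_and_smooth(rec2)
  expect_equal(sm2$coords[2, 5, , 1], seq(0, 118, by = 2), tolerance = 1e-9)

  # a single missing frame between linear neighbors interpolates linearly:
  # values ..., 10, NA, 12, ... on a linear track -> 11 (and the linear
  # track then passes through smoothing unchanged)
  rec3 <- static_recording(frames = 31)
  rec3$coords[1, 5, , 2] <- 0:30
  rec3$coords[1, 5, 11, 2] <- NA # true value 10 ... 12 gap at 11
  sm3 <- interpolate_and_smooth(rec3)
  expect_equal(sm3$coords[1, 5, 11, 2], 10, tolerance = 1e-9)

  # all-missing tracks are named in the error
  rec4 <- static_recording(frames = 40)
  rec4$coords[2, 3, , ] <- NA
  expect_error(interpolate_and_smooth(rec4), "left_ear")
})

test_that("short recordings shrink the smoothing window with a warning", {
  rec <- static_recording(frames = 10)
  expect_warning(sm <- interpolate_and_smooth(rec), "shrunk")
  expect_false(anyNA(sm$coords))
  expect_error(interpolate_and_smooth(static_recording(10), window = 24),
               "odd")
  expect_error(interpolate_and_smooth(static_recording(10), window = 3,
                                      polyorder = 3), "exceed")
})

test_that("orientation angle is the folded port-thorax-nose angle", {
  expect_equal(orientation_angle(c(0, 0), c(1, 0), c(0.5, 0)), 0)
  expect_equal(orientation_angle(c(0, 0), c(1, 0), c(2, 0)), 180)
  expect_equal(orientation_angle(c(0, 0), c(1, 0), c(1, 1)), 90)
  expect_equal(orientation_angle(c(0, 0), c(1, 0), c(1, -1)), 90)
  expect_equal(orientation_angle(c(0, 0), c(2, 0), c(3, 1)), 135)
  # degenerate geometry returns NA for later imputation
  expect_true(is.na(orientation_angle(c(0, 0), c(1, 0), c(1, 0))))
})

test_that("feature values match hand-constructed geometry", {
  # nose distances 40 and 100 px from the port
  rec <- static_recording(port = c(10, 0), nose1 = c(10, 40), thorax1 = c(10, 65),
                          nose2 = c(110, 0), thorax2 = c(135, 0))
  ft <- compute_features(rec)
  expect_equal(ft$port_nose_dist_sum, rep(140, 10))
  expect_equal(ft$port_nose_dist_absdiff, rep(60, 10))
  # both animals face the port exactly: angles 0
  expect_equal(ft$angle_sum, rep(0, 10), tolerance = 1e-9)
  expect_equal(ft$angle_absdiff, rep(0, 10), tolerance = 1e-9)
  # stationary animals: zero velocity everywhere (first frame backfilled)
  expect_equal(ft$velocity_sum, rep(0, 10))
  expect_equal(ft$velocity_absdiff, rep(0, 10))
  expect_equal(ft$thorax_thorax_dist,
               rep(sqrt((135 - 10)^2 + 65^2), 10))
  expect_error(compute_features(static_recording(frames = 1)), "2 frames")
})

test_that("features are invariant to swapping the two animals", {
  set.seed(14)
  for (i in 1:5) {
    cfg <- pose_sim_config(frames = 120, noise_sd = 3, missing_frac = 0.05,
                           seed = 100 + i)
    rec <- interpolate_and_smooth(generate_pose(cfg))
    ft <- compute_features(rec)
    ft_swapped <- compute_features(swap_animals(rec))
    expect_equal(ft_swapped, ft, tolerance = 1e-12)
  }
})

test_that("features are translation invariant; distances scale and angles do not", {
  cfg <- pose_sim_config(frames = 90, noise_sd = 2, missing_frac = 0, seed = 8)
  rec <- interpolate_and_smooth(generate_pose(cfg))
  ft <- compute_features(rec)

  shift <- c(37, -12)
  rec_t <- rec
  rec_t$coords[, , , 1] <- rec$coords[, , , 1] + shift[1]
  rec_t$coords[, , , 2] <- rec$coords[, , , 2] + shift[2]
  rec_t$port <- rec$port + shift
  expect_equal(compute_features(rec_t), ft, tolerance = 1e-9)

  s <- 2.5
  rec_s <- rec
  rec_s$coords <- rec$coords * s
  rec_s$port <- rec$port * s
  ft_s <- compute_features(rec_s)
  for (col in c("velocity_sum", "velocity_absdiff", "port_nose_dist_sum",
                "port_nose_dist_absdiff", "thorax_thorax_dist")) {
    expect_equal(ft_s[[col]], s * ft[[col]], tolerance = 1e-9)
  }
  expect_equal(ft_s$angle_sum, ft$angle_sum, tolerance = 1e-9)
  expect_equal(ft_s$angle_absdiff, ft$angle_absdiff, tolerance = 1e-9)
})

test_that("reflecting a nose across its thorax-port axis leaves angle features unchanged", {
  rec <- static_recording(port = c(0, 0), nose1 = c(30, 25), thorax1 = c(50, 0),
                          nose2 = c(80, 90), thorax2 = c(60, 70))
  ft <- compute_features(rec)
  # port and thorax1 lie on the x-axis: reflect nose1 across it
  rec_r <- static_recording(port = c(0, 0), nose1 = c(30, -25), thorax1 = c(50, 0),
                            nose2 = c(80, 90), thorax2 = c(60, 70))
  ft_r <- compute_features(rec_r)
  expect_equal(ft_r$angle_sum, ft$angle_sum, tolerance = 1e-9)
  expect_equal(ft_r$angle_absdiff, ft$angle_absdiff, tolerance = 1e-9)
})

test_that("pooling subsamples every step-th frame and z-scores the pool", {
  cfg <- pose_sim_config(frames = 100, noise_sd = 1, missing_frac = 0, seed = 2)
  ft1 <- compute_features(interpolate_and_smooth(generate_pose(cfg)))
  cfg2 <- pose_sim_config(frames = 70, noise_sd = 1, missing_frac = 0, seed = 3)
  ft2 <- compute_features(interpolate_and_smooth(generate_pose(cfg2)))
  fm <- pool_zscore_subsample(list(r1 = ft1, r2 = ft2), step = 3)
  expect_equal(sum(fm$provenance$recording == "r1"), length(seq(1, 100, 3)))
  expect_equal(fm$provenance$frame[fm$provenance$recording == "r1"],
               seq(1, 100, by = 3))
  expect_equal(unname(colMeans(fm$x)), rep(0, 7), tolerance = 1e-8)
  expect_equal(unname(apply(fm$x, 2, sd)), rep(1, 7), tolerance = 1e-6)
  # a single affine transform preserves orderings within and across recordings
  ord_before <- order(c(ft1$thorax_thorax_dist[seq(1, 100, 3)],
                        ft2$thorax_thorax_dist[seq(1, 70, 3)]))
  expect_equal(order(fm$x[, "thorax_thorax_dist"]), ord_before)
  # determinism: identical inputs give bit-identical matrices
  fm2 <- pool_zscore_subsample(list(r1 = ft1, r2 = ft2), step = 3)
  expect_identical(fm$x, fm2$x)
})

test_that("zero-variance features are zeroed with a warning", {
  ft <- compute_features(static_recording(frames = 30))
  expect_warning(fm <- pool_zscore_subsample(list(r1 = ft)), "zero-variance")
  expect_true(all(fm$x[, "velocity_sum"] == 0))
})

test_that("pose recordings round-trip through long-format CSV", {
  cfg <- pose_sim_config(frames = 40, noise_sd = 2, missing_frac = 0.1, seed = 6)
  rec <- generate_pose(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pose_csv(rec, path)
  back <- read_pose_csv(path)
  expect_equal(back$coords, rec$coords, tolerance = 1e-9)
  expect_equal(back$port, rec$port)
  expect_equal(back$fps, rec$fps)
})

test_that("SLEAP-style HDF5 track files load into pose recordings", {
  cfg <- pose_sim_config(frames = 30, noise_sd = 1, missing_frac = 0, seed = 9)
  rec <- generate_pose(cfg)
  path <- withr::local_tempfile(fileext = ".h5")
  # animal x xy x node x frame, the analysis-export layout
  tracks <- aperm(rec$coords, c(1, 4, 2, 3))
  node_names <- c("nose", "forehead", "left_ear", "right_ear", "thorax",
                  "tail_base")
  rhdf5::h5createFile(path)
  rhdf5::h5write(tracks, path, "tracks")
  rhdf5::h5write(node_names, path, "node_names")
  rhdf5::H5close()
  back <- read_pose_h5(path, port = rec$port, fps = rec$fps)
  expect_equal(unname(back$coords), unname(rec$coords), tolerance = 1e-9)
  expect_equal(back$port, rec$port)
})
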