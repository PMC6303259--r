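test_that("network construction validates geometry", {
  expect_error(vessel_segment(c(0, 0), c(10, 0), radius = 0), "radius")
  expect_error(vessel_segment(c(5, 5), c(5, 5), radius = 3), "zero length")
  expect_error(vessel_segment(c(0, 0), c(10, 0), radius = 3, flattening = 1.2),
               "flattening")
  # self-crossing polyline
  expect_error(vessel_segment(path = rbind(c(0, 0), c(10, 0), c(10, 5),
                                           c(5, -5)), radius = 2),
               "self-intersecting")
  # does not fit inside the frame
  expect_error(vessel_network(list(
    vessel_segment(c(2, 10), c(30, 10), radius = 5)), width = 32, height = 20),
    "fit inside")
})

test_that("rendered mask of a straight segment has the analytic thick-line area", {
  seg <- vessel_segment(c(20, 30), c(80, 30), radius = 5)
  net <- vessel_network(list(seg), width = 100, height = 60)
  area <- sum(vessel_mask(net))
  # length x 2 radius, up to the one-pixel discretization band of
  # counting pixel centers inside the closed region
  expect_equal(area, 60 * 10, tolerance = 0.15)
})

test_that("a Y-bifurcation yields three segments sharing one node", {
  net <- vessel_network(list(
    vessel_segment(c(15, 30), c(50, 30), radius = 4),
    vessel_segment(c(50, 30), c(80, 16), radius = 3),
    vessel_segment(c(50, 30), c(80, 44), radius = 3)),
    width = 100, height = 60)
  expect_length(net$segments, 3)
  shared <- c(net$segment_nodes)
  expect_equal(max(table(shared)), 3)  # one node common to all three
})

test_that("generation is fully seeded", {
  expect_identical(vessel_network_tree(7), vessel_network_tree(7))
  net <- vessel_network(list(vessel_segment(c(12, 20), c(50, 20), radius = 4)),
                        width = 64, height = 40)
  m1 <- render_movie(net, motion_model(seed = 9), n_frames = 12)
  m2 <- render_movie(net, motion_model(seed = 9), n_frames = 12)
  expect_identical(m1$stack$frames, m2$stack$frames)
  expect_identical(m1$truth$tracers, m2$truth$tracers)
  m3 <- render_movie(net, motion_model(seed = 10), n_frames = 12)
  expect_false(identical(m1$stack$frames, m3$stack$frames))
})

test_that("zero tracers leave the bare background", {
  net <- vessel_network(list(vessel_segment(c(12, 20), c(50, 20), radius = 4)),
                        width = 64, height = 40)
  mov <- render_movie(net, still_motion(seed = 2), n_frames = 5,
                      tracer_density = 0, noise_sd = 0,
                      static_attenuation = 0, background_texture = 0)
  for (t in 2:5)
    expect_equal(mov$stack$frames[, , t], mov$stack$frames[, , 1])
  expect_gt(min(mov$stack$frames), 0.75)
})

test_that("a single static tracer survives the minima projection unchanged", {
  net <- vessel_network(list(vessel_segment(c(12, 20), c(52, 20), radius = 4,
                                            speed = 0)),
                        width = 64, height = 40)
  mov <- render_movie(net, still_motion(seed = 3), n_frames = 6,
                      tracer_density = 2.5, noise_sd = 0)  # one tracer
  expect_equal(nrow(mov$truth$tracers) / 6, 1)
  mins <- project(mov$stack, "minima")
  expect_equal(mins$image, mov$stack$frames[, , 1])
})

test_that("tracers visit essentially the whole lumen over a long movie", {
  mov <- fix_pipeline_movie()
  tk <- mov$truth$tracers
  H <- nrow(mov$truth$vessel_mask); W <- ncol(mov$truth$vessel_mask)
  visited <- capiflow:::.stamp_counts(tk$x, tk$y,
                                      mov$truth$params$cell_radius_px, H, W) > 0
  frac <- sum(visited & mov$truth$vessel_mask) / sum(mov$truth$vessel_mask)
  expect_gte(frac, 0.99)
})

test_that("undoing the ground-truth transforms reproduces the still minima image", {
  net <- vessel_network(list(vessel_segment(c(16, 22), c(60, 22), radius = 5,
                                            speed = 1.4)),
                        width = 80, height = 44)
  still <- render_movie(net, still_motion(seed = 6), n_frames = 30,
                        noise_sd = 0)
  moving <- render_movie(net, motion_model(seed = 6, blur_fraction = 0,
                                           aberrant_frame_rate = 0),
                         n_frames = 30, noise_sd = 0)
  tr <- moving$truth$transforms
  aligned <- moving$stack$frames
  for (t in seq_len(30))
    aligned[, , t] <- capiflow:::.resample_rigid(
      moving$stack$frames[, , t], tr$dx[t], tr$dy[t], 0,
      fill = 1, inverse = TRUE)$image
  # compare inside the region that stays in frame for every transform
  core_y <- 8:36; core_x <- 12:68
  m_moving <- apply(aligned[core_y, core_x, ], c(1, 2), min)
  m_still <- apply(still$stack$frames[core_y, core_x, ], c(1, 2), min)
  expect_lt(mean(abs(m_moving - m_still)), 0.02 * diff(range(m_still)))
})

test_that("ground truth sidecar files round-trip through disk", {
  mov <- fix_small_movie()
  dir <- withr::local_tempdir()
  write_ground_truth(mov$truth, dir)
  expect_true(file.exists(file.path(dir, "vessel_mask.tif")))
  tr <- read.csv(file.path(dir, "transforms.csv"))
  expect_equal(nrow(tr), 40)
  tk <- read.csv(file.path(dir, "tracers.csv"))
  expect_equal(tk$x[1], mov$truth$tracers$x[1] - 1)  # 0-based on disk
})
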