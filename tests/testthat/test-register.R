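# Textured static scene used for controlled-shift registration tests.
make_scene <- function(seed = 8, H = 72, W = 96) {
  set.seed(seed)
  capiflow:::.gauss_blur(matrix(runif(H * W), H, W), 1.5)
}

test_that("known rigid shifts up to +/-8 px are recovered to subpixel precision", {
  scene <- make_scene()
  shifts <- rbind(c(0, 0), c(3, -2), c(-8, 5), c(6.4, -3.7), c(-1.2, 7.9))
  frames <- array(0, c(72, 96, nrow(shifts)))
  for (t in seq_len(nrow(shifts)))
    frames[, , t] <- capiflow:::.bilinear_shift_matrix(
      scene, shifts[t, 1], shifts[t, 2], fill = median(scene))
  reg <- register_stack(frame_stack(frames), reference_slot = 1)
  err <- sqrt((reg$result$dx - shifts[, 1])^2 + (reg$result$dy - shifts[, 2])^2)
  expect_lt(max(err), 0.5)
  expect_equal(reg$result$dx[1], 0)
  expect_equal(reg$result$theta, rep(0, 5))
})

test_that("a pre-aligned stack stays put and a single frame is the identity", {
  scene <- make_scene(9)
  st <- frame_stack(array(rep(scene, 6), c(72, 96, 6)))
  reg <- register_stack(st)
  expect_lt(max(abs(reg$result$dx)), 0.1)
  expect_lt(max(abs(reg$result$dy)), 0.1)
  one <- register_stack(frame_stack(scene))
  expect_equal(one$result$dx, 0)
  expect_equal(one$result$dy, 0)
})

test_that("featureless frames fall back to the identity and are flagged", {
  scene <- make_scene(10)
  frames <- array(0, c(72, 96, 3))
  frames[, , 1] <- scene
  frames[, , 2] <- 0.5                   # zero variance
  frames[, , 3] <- capiflow:::.bilinear_shift_matrix(scene, 2, 1,
                                                     fill = median(scene))
  reg <- register_stack(frame_stack(frames), reference_slot = 1, passes = 1)
  expect_true(reg$result$low_confidence[2])
  expect_equal(reg$result$dx[2], 0)
  expect_false(reg$result$low_confidence[3])
})

test_that("the rigid model recovers a small rotation with its translation", {
  scene <- make_scene(11)
  theta <- 1.6 * pi / 180
  moved <- capiflow:::.resample_rigid(scene, 4, -3, theta,
                                      fill = median(scene))$image
  frames <- array(c(scene, moved), c(72, 96, 2))
  reg <- register_stack(frame_stack(frames), reference_slot = 1,
                        model = "rigid")
  expect_lt(abs(reg$result$theta[2] - theta), 0.3 * pi / 180)
  expect_lt(abs(reg$result$dx[2] - 4), 0.5)
  expect_lt(abs(reg$result$dy[2] + 3), 0.5)
  expect_error(register_stack(frame_stack(frames), model = "rigid",
                              reference = "previous"), "translation model")
})

test_that("out-of-frame pixels are marked invalid after alignment", {
  scene <- make_scene(12)
  frames <- array(0, c(72, 96, 2))
  frames[, , 1] <- scene
  frames[, , 2] <- capiflow:::.bilinear_shift_matrix(scene, 10, 0,
                                                     fill = median(scene))
  reg <- register_stack(frame_stack(frames), reference_slot = 1, passes = 1)
  v <- reg$stack$valid[, , 2]
  # aligning a frame whose content moved +10 px in x resamples its right
  # edge from outside the frame
  expect_false(any(v[, 88:96]))
  expect_true(all(v[, 5:80]))
})
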