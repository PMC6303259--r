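test_that("projections of identical frames reproduce the frame", {
  m <- matrix(runif(48), 6, 8)
  st <- frame_stack(array(rep(m, 5), c(6, 8, 5)))
  expect_equal(project(st, "minima")$image, m)
  expect_equal(project(st, "average")$image, m)
  expect_error(project(frame_stack(array(0, c(4, 4, 0)))), "empty")
})

test_that("minima is a pixelwise lower bound, order-invariant and concatenation-stable", {
  st <- fix_small_movie()$stack
  mins <- project(st, "minima")$image
  for (t in c(1, 17, 40)) expect_true(all(mins <= st$frames[, , t] + 1e-12))
  sh <- shuffle_decorrelate(st)
  expect_equal(project(sh$stack, "minima")$image, mins)
  a <- capiflow:::stack_subset(st, 1:15)
  b <- capiflow:::stack_subset(st, 16:40)
  expect_equal(pmin(project(a, "minima")$image, project(b, "minima")$image),
               mins)
})

test_that("average projection is linear in the frames", {
  st <- fix_small_movie()$stack
  avg <- project(st, "average")$image
  a <- capiflow:::stack_subset(st, 1:15)
  b <- capiflow:::stack_subset(st, 16:40)
  expect_equal((15 * project(a, "average")$image +
                25 * project(b, "average")$image) / 40, avg)
  expect_equal(mean(avg), mean(st$frames))
})

test_that("projections respect validity masks", {
  frames <- array(0.8, c(6, 8, 3))
  frames[1, 1, 2] <- 0.1
  valid <- array(TRUE, c(6, 8, 3))
  valid[1, 1, 2] <- FALSE          # the dark excursion is marked invalid
  st <- frame_stack(frames, valid = valid)
  mins <- project(st, "minima")
  expect_equal(mins$image[1, 1], 0.8)
  expect_equal(mins$count_map[1, 1], 2)
  avg <- project(st, "average")
  expect_equal(avg$image[1, 1], 0.8)
})

test_that("background flattening removes smooth illumination and little else", {
  grad <- outer(seq(0, 0.2, length.out = 60), seq(0, 0.1, length.out = 80), "+")
  vessel <- matrix(0, 60, 80); vessel[28:32, ] <- 0.3
  img <- 0.7 + grad - vessel
  out <- flatten_background(img, radius = 15)
  fitplane <- function(m) {
    d <- data.frame(z = as.vector(m), y = as.vector(row(m)),
                    x = as.vector(col(m)))
    coef(lm(z ~ x + y, d))[2:3]
  }
  expect_lt(sum(abs(fitplane(out))), sum(abs(fitplane(img))) / 10)
  # vessel contrast survives
  expect_lt(mean(out[30, ]) - mean(out[10, ]), -0.25)
  # idempotence
  out2 <- flatten_background(out, radius = 15)
  expect_lt(max(abs(out2 - out)), 0.01 * diff(range(out)))
  # flat input: changed by at most a constant
  flat <- matrix(0.6, 40, 40); flat[20, 20] <- 0.2
  res <- flatten_background(flat, radius = 10) - flat
  expect_lt(diff(range(res)), 1e-6)
  expect_warning(flatten_background(img, radius = 4, vessel_width = 5),
                 "vessel")
})

test_that("Otsu masking separates dark vessels from the bright field", {
  mov <- fix_small_movie()
  mask <- otsu_mask(project(mov$stack, "minima"))
  expect_gte(dice(mask, mov$truth$vessel_mask), 0.85)
})
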