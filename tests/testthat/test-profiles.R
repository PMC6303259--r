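# Analytic profiles (closed-form oracles for the estimators).
chord_profile <- function(R = 10, step = 0.25, c0 = 0.1) {
  x <- seq(-R - 4, R + 4, by = step)
  structure(list(position = x, intensity = exp(-c0 * 2 * sqrt(pmax(R^2 - x^2, 0))),
                 od = c0 * 2 * sqrt(pmax(R^2 - x^2, 0)),
                 width = NA, fwhm = NA,
                 peak_od = c0 * 2 * R, empty = FALSE),
            class = "vessel_profile")
}
rect_profile <- function(half = 8, step = 0.25, od0 = 1) {
  x <- seq(-half - 4, half + 4, by = step)
  od <- ifelse(abs(x) <= half, od0, 0)
  structure(list(position = x, intensity = exp(-od), od = od, width = NA,
                 fwhm = NA, peak_od = od0, empty = FALSE),
            class = "vessel_profile")
}

test_that("saturated cylinder minima profile follows the chord law", {
  bench <- fix_profile_movie()
  minima <- fix_profile_minima()
  p <- extract_profile(minima, bench$round_line, average_px = 30)
  R <- bench$radius
  keep <- abs(p$position) <= 0.8 * R
  od <- p$od[keep]; x <- p$position[keep]
  fit <- lm(od^2 ~ I(x^2))           # od^2 linear in x^2 under the chord model
  A <- coef(fit)[1]; B <- -coef(fit)[2]
  model <- sqrt(pmax(A - B * x^2, 0))
  rel_rms <- sqrt(mean((od - model)^2)) / sqrt(mean(model^2))
  expect_lt(rel_rms, 0.10)
  expect_gt(summary(lm(od ~ model))$r.squared, 0.95)  # "well circular"
})

test_that("profiles are invariant under intensity rescaling and flag empty lines", {
  minima <- fix_profile_minima()
  bench <- fix_profile_movie()
  p1 <- extract_profile(minima, bench$round_line)
  p2 <- extract_profile(minima$image * 0.43, bench$round_line)
  expect_equal(p1$od, p2$od, tolerance = 1e-8)
  expect_equal(p1$width, p2$width)
  flatimg <- matrix(0.8, 60, 60)
  pe <- extract_profile(flatimg, profile_line(10, 30, 50, 30))
  expect_true(pe$empty)
  expect_error(flatness_score(pe), "empty")
  expect_error(extract_profile(flatimg, profile_line(10, 30, 80, 30)),
               "outside")
  expect_error(profile_line(5, 5, 5, 5), "distinct")
})

test_that("flatness score matches closed forms and orders flat above round", {
  # semicircular chord: plateau fraction sqrt(1 - 0.81) / sqrt(1 - 0.25)
  expect_equal(flatness_score(chord_profile()), sqrt(0.19) / sqrt(0.75),
               tolerance = 0.03)
  expect_gte(flatness_score(rect_profile()), 0.95)
  # rendered benchmark: flat terminal segment vs cylindrical vessel
  minima <- fix_profile_minima()
  bench <- fix_profile_movie()
  pf <- extract_profile(minima, bench$flat_line, average_px = 30)
  pr <- extract_profile(minima, bench$round_line, average_px = 30)
  expect_gte(flatness_score(pf), 0.8)
  expect_gt(flatness_score(pf), flatness_score(pr))
  # degenerate narrow profile
  narrow <- rect_profile(half = 0.2, step = 0.25)
  expect_error(flatness_score(narrow), "3 samples")
})

test_that("flat and round segments separate perfectly across the benchmark", {
  minima <- fix_profile_minima()
  xs <- c(50, 70, 90)
  round_sc <- vapply(xs, function(x0) flatness_score(
    extract_profile(minima, profile_line(x0, 8, x0, 52), average_px = 25)),
    numeric(1))
  flat_sc <- vapply(xs, function(x0) flatness_score(
    extract_profile(minima, profile_line(x0, 48, x0, 92), average_px = 25)),
    numeric(1))
  # complete separation = AUC 1 over the 3 + 3 profiles
  expect_gt(min(flat_sc), max(round_sc))
})

test_that("width ratio recovers the geometric widening of a flattened tip", {
  minima <- fix_profile_minima()
  bench <- fix_profile_movie()
  pf <- extract_profile(minima, bench$flat_line, average_px = 30)
  pr <- extract_profile(minima, bench$round_line, average_px = 30)
  geom <- (pi * (1 - 0.25) / 2 + 0.25)  # width/D of the gap = D/4 stadium
  expect_equal(width_ratio(pf, pr), geom, tolerance = 0.1)
  expect_equal(width_ratio(pr, pr), 1)
  expect_lt(width_ratio(pr, pf), 1)
  empty <- extract_profile(matrix(0.8, 60, 60), profile_line(10, 30, 50, 30))
  expect_error(width_ratio(empty, pr), "empty")
})

test_that("apparent width grows monotonically under dilation", {
  widths <- vapply(c(5, 8, 12), function(R) {
    p <- chord_profile(R = R)
    p$width <- capiflow:::.peak_span(p$position, p$od, which.max(p$od),
                                     0.1 * p$peak_od)
    p$width
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})
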