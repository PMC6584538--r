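test_that("phase projection follows the optical path integral", {
  tom <- ri_tomogram(array(1.337, c(8, 8, 8)), 0.1, 1.337)
  pm <- project_phase(tom)
  expect_true(all(pm$phase == 0))
  # slab: t = 2 um, dn = 0.01, lambda = 0.532 -> 0.2362 rad
  vals <- array(1.337, c(8, 8, 30)); vals[, , 6:25] <- 1.347
  pm2 <- project_phase(ri_tomogram(vals, 0.1, 1.337), wavelength = 0.532)
  expect_equal(pm2$phase[4, 4], 2 * pi * 0.01 * 2 / 0.532,
               tolerance = 1e-9)
  expect_identical(pm2$source, "projected-from-tomogram")
})

test_that("2D morphometry recovers the designed HO dimensions within 2%", {
  m <- measure_2d(ho_phase())
  expect_equal(m$head_length, 9.053, tolerance = 0.02)
  expect_equal(m$head_width, 4.954, tolerance = 0.02)
  expect_equal(m$midpiece_length, 13.926, tolerance = 0.02)
  expect_equal(m$tail_length, 46.415, tolerance = 0.02)
})

test_that("2D morphometry recovers the designed KN dimensions within 2%", {
  m <- measure_2d(project_phase(build_phantom(design_kn(), 0.1)))
  expect_equal(m$head_length, 9.229, tolerance = 0.02)
  expect_equal(m$head_width, 5.241, tolerance = 0.02)
  expect_equal(m$midpiece_length, 13.245, tolerance = 0.02)
  expect_equal(m$tail_length, 47.750, tolerance = 0.02)
})

test_that("head-only circular silhouette measures its diameter", {
  d <- sperm_design(head_length = 4, head_width = 4, head_thickness = 4,
                    midpiece_length = 0, tail_length = 0)
  m <- measure_2d(project_phase(build_phantom(d, 0.1)))
  expect_equal(m$head_length, 4, tolerance = 0.2 / 4) # 2 px quantization
  expect_equal(m$head_width, 4, tolerance = 0.2 / 4)
  expect_equal(m$midpiece_length, 0)
  expect_equal(m$tail_length, 0)
})

test_that("curved tails are measured by arclength, not chord", {
  dc <- design_ho(curvature = 0.02)   # bend radius 50 um
  m <- measure_2d(project_phase(build_phantom(dc, 0.1)))
  expect_equal(m$tail_length, 46.415, tolerance = 0.03)
  # the chord of this arc is noticeably shorter than the arclength
  chord <- 2 * (1 / 0.02) * sin(0.02 * 46.415 / 2)
  expect_gt(m$tail_length, chord + 2 * (46.415 - chord) / 3)
})

test_that("measurements are rotation invariant to about a pixel", {
  pm0 <- ho_phase()
  m0 <- unlist(measure_2d(pm0))
  rot <- EBImage::rotate(EBImage::Image(pm0$phase), 27, filter = "none",
                         bg.col = 0)
  mr <- unlist(measure_2d(phase_map(EBImage::imageData(rot), 0.1)))
  expect_true(all(abs(mr - m0) < 0.15))
})

test_that("halving the pixel size changes lengths by less than 1%", {
  a <- unlist(measure_2d(ho_phase()))
  b <- unlist(measure_2d(project_phase(
    build_phantom(design_ho(), c(0.05, 0.05, 0.1)))))
  expect_true(all(abs(b / a - 1) < 0.01))
})

test_that("empty and multi-cell frames raise explicit errors", {
  expect_error(measure_2d(phase_map(matrix(0, 40, 40), 0.1)), "empty")
  ph <- matrix(0, 60, 120)
  ph[20:40, 10:40] <- 0.5
  ph[20:40, 80:110] <- 0.5
  expect_error(measure_2d(phase_map(ph, 0.1)), "multiple cells")
})

test_that("phase map container validates inputs", {
  expect_error(phase_map(matrix(NA_real_, 2, 2), 0.1), "finite")
  expect_error(phase_map(matrix(0, 2, 2), -0.1), "positive")
})
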