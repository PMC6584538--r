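plan_default <- illumination_plan()

slab_tomogram <- function(dn, t_um = 2, n = 64, vx = 0.1) {
  vals <- array(1.337, c(n, n, n))
  iz0 <- n / 2 - t_um / vx / 2 + 1
  vals[, , iz0:(iz0 + t_um / vx - 1)] <- 1.337 + dn
  ri_tomogram(vals, vx, 1.337)
}

test_that("pure medium gives the undisturbed tilted plane wave", {
  tom <- ri_tomogram(array(1.337, c(32, 32, 32)), 0.1, 1.337)
  dir <- illumination_directions(plan_default, 1.337)[1, ]
  f <- scattered_field(tom, dir, plan_default)
  expect_lt(max(abs(f$amplitude - 1)), 1e-10)
  expect_lt(max(abs(f$phase)), 1e-10)
  # the total phase is exactly the illumination ramp
  km <- 2 * pi / 0.532 * 1.337
  x <- (0:31) * 0.1
  ramp <- km * (outer(x, rep(1, 32)) * dir[2] + outer(rep(1, 32), x) * dir[1])
  expect_equal(total_phase(f), ramp, tolerance = 1e-10)
})

test_that("thin slab phase matches the optical path length", {
  f <- scattered_field(slab_tomogram(0.01), c(0, 0, 1), plan_default)
  expect_equal(f$phase[32, 32], 2 * pi * 0.01 * 2 / 0.532, tolerance = 0.05)
})

test_that("Rytov phase is linear in the scattering contrast", {
  p1 <- scattered_field(slab_tomogram(0.0025), c(0, 0, 1),
                        plan_default)$phase[32, 32]
  p2 <- scattered_field(slab_tomogram(0.005), c(0, 0, 1),
                        plan_default)$phase[32, 32]
  expect_equal(p2 / p1, 2, tolerance = 0.05)
})

test_that("a 30-angle scan produces 30 fields and 30 holograms", {
  tom <- make_analytic_shape("sphere", list(radius = 0.6), ri = 1.342,
                             voxel_size = 0.1, pad = 0.9)
  hs <- simulate_holograms(tom, plan_default)
  expect_length(hs$frames, 30)
  expect_equal(nrow(hs$illum_dirs), 30)
  expect_length(attr(hs, "fields"), 30)
  expect_equal(unname(sqrt(rowSums(hs$illum_dirs^2))), rep(1, 30),
               tolerance = 1e-9)
})

test_that("unit field on a zero-carrier reference gives I = |1+1|^2 = 4", {
  n <- 16
  f <- complex_field(matrix(1, n, n), matrix(0, n, n), 0.1, c(0, 0, 1),
                     0.532, 1.337)
  plan0 <- illumination_plan(na_detection = 0.4,
                             carrier_frequency = c(0, 0))
  I <- synthesize_hologram(f, plan0)
  expect_equal(max(abs(I - 4)), 0, tolerance = 1e-12)
})

test_that("hologram noise is seeded and intensities stay non-negative", {
  tom <- make_analytic_shape("sphere", list(radius = 0.6), ri = 1.342,
                             voxel_size = 0.1, pad = 0.9)
  f <- scattered_field(tom, illumination_directions(plan_default, 1.337)[1, ],
                       plan_default)
  I1 <- synthesize_hologram(f, plan_default, noise_snr = 10, seed = 7)
  I2 <- synthesize_hologram(f, plan_default, noise_snr = 10, seed = 7)
  I3 <- synthesize_hologram(f, plan_default, noise_snr = 10, seed = 8)
  expect_identical(unclass(I1), unclass(I2))
  expect_false(identical(unclass(I1), unclass(I3)))
  expect_true(min(I1) >= 0)
})

test_that("carrier aliasing and NA violations raise errors", {
  f <- complex_field(matrix(1, 16, 16), matrix(0, 16, 16), 0.1, c(0, 0, 1),
                     0.532, 1.337)
  plan_bad <- illumination_plan(carrier_frequency = c(4.9, 4.9))
  expect_error(synthesize_hologram(f, plan_bad), "aliasing")
  tom <- ri_tomogram(array(1.337, c(8, 8, 8)), 0.1, 1.337)
  plan_na <- illumination_plan(na_detection = 1.4)
  expect_error(scattered_field(tom, c(0, 0, 1), plan_na), "medium")
})

test_that("excessive contrast triggers the validity warning", {
  vals <- array(1.337, c(16, 16, 16)); vals[8, 8, 8] <- 1.45
  tom <- ri_tomogram(vals, 0.1, 1.337)
  expect_warning(scattered_field(tom, c(0, 0, 1), plan_default),
                 "validity")
})

test_that("illumination patterns lie on the prescribed cone", {
  dirs <- illumination_directions(plan_default, 1.337)
  sin_t <- sqrt(dirs[, 1]^2 + dirs[, 2]^2)
  expect_equal(sin_t, rep(1.2 / 1.337, 30), tolerance = 1e-12)
  plan_sp <- illumination_plan(angle_pattern = "spiral", n_angles = 12)
  dsp <- illumination_directions(plan_sp, 1.337)
  expect_true(all(sqrt(dsp[, 1]^2 + dsp[, 2]^2) <= 1.2 / 1.337 + 1e-12))
  expect_equal(unname(sqrt(rowSums(dsp^2))), rep(1, 12), tolerance = 1e-12)
})
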