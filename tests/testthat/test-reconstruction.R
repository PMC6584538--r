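plan_default <- illumination_plan()

test_that("least-squares unwrapping recovers a smooth wrapped phase", {
  n <- 96
  y <- outer(seq(-3, 3, length.out = n), rep(1, n)); x <- t(y)
  true <- 9 * exp(-(x^2 + y^2) / 2)
  uw <- unwrap_phase(odtmorph:::wrap_pi(true))
  expect_lt(max(abs(uw - true)), 1e-9)
})

test_that("plane-wave hologram demodulates to unit amplitude, zero phase", {
  n <- 64
  dir <- odtmorph:::snap_directions(
    illumination_directions(plan_default, 1.337)[1, , drop = FALSE],
    1.337, 0.532, c(n, n), c(0.1, 0.1))[1, ]
  f <- complex_field(matrix(1, n, n), matrix(0, n, n), 0.1, dir,
                     0.532, 1.337)
  H <- synthesize_hologram(f, plan_default)
  fr <- demodulate_hologram(H, plan_default, medium_ri = 1.337)
  expect_lt(max(abs(fr$amplitude - 1)), 1e-6)
  expect_lt(max(abs(fr$phase)), 1e-6)
})

test_that("synthesis then demodulation round-trips the field", {
  # weak-phase regime: the off-axis round trip is first-order exact and
  # second-order harmonics fall outside the sideband crop
  sp <- make_analytic_shape("sphere", list(radius = 1.2), ri = 1.338,
                            voxel_size = 0.1, pad = 1.3)
  dirs <- odtmorph:::snap_directions(
    illumination_directions(plan_default, 1.337), 1.337, 0.532,
    dim(sp$values)[1:2], c(0.1, 0.1))
  for (k in c(1, 11)) {
    fs <- scattered_field(sp, dirs[k, ], plan_default)
    H <- synthesize_hologram(fs, plan_default)
    fr <- demodulate_hologram(H, plan_default, medium_ri = 1.337)
    u1 <- fs$amplitude * exp(1i * fs$phase)
    u2 <- fr$amplitude * exp(1i * fr$phase)
    expect_lt(sqrt(sum(Mod(u2 - u1)^2) / sum(Mod(u1)^2)), 1e-3)
  }
})

test_that("DC-overlapping carrier is rejected with a clear message", {
  H <- matrix(1, 32, 32)
  attr(H, "pixel_size") <- c(0.1, 0.1)
  attr(H, "carrier_frequency") <- c(0.5, 0.5)
  attr(H, "illum_dir") <- c(0, 0, 1)
  expect_error(demodulate_hologram(H, plan_default), "overlaps the DC")
})

test_that("a single normal-incidence field fills a cap through the origin", {
  sp <- make_analytic_shape("sphere", list(radius = 0.15), ri = 1.347,
                            voxel_size = 0.1, pad = 2.4)
  f <- scattered_field(sp, c(0, 0, 1), plan_default)
  fs <- map_to_frequency_space(list(f), plan_default, nz = dim(sp$values)[3])
  expect_true(fs$support[1, 1, 1])      # DC voxel measured
  expect_gt(sum(fs$support), 0)
  # a cap is a 2D surface: far fewer voxels than the full grid
  expect_lt(mean(fs$support), 0.05)
})

test_that("30-angle support anisotropy matches the printed resolution ratio", {
  sp <- make_analytic_shape("sphere", list(radius = 0.15), ri = 1.347,
                            voxel_size = 0.1, pad = 2.4)
  d <- dim(sp$values)
  dirs <- odtmorph:::snap_directions(
    illumination_directions(plan_default, 1.337), 1.337, 0.532,
    d[1:2], c(0.1, 0.1))
  fields <- lapply(seq_len(nrow(dirs)), function(k)
    scattered_field(sp, dirs[k, ], plan_default))
  fsup <- symmetrize_support(
    map_to_frequency_space(fields, plan_default, nz = d[3]))
  w <- which(fsup$support, arr.ind = TRUE)
  fy <- odtmorph:::freq_rad(d[1], 0.1)
  fz <- odtmorph:::freq_rad(d[3], 0.1)
  ratio <- diff(range(fy[w[, 1]])) / diff(range(fz[w[, 3]]))
  expect_equal(ratio, 360 / 110, tolerance = 0.15)
})

test_that("naive reconstruction of a point-like scatterer is axially elongated", {
  sp <- make_analytic_shape("sphere", list(radius = 0.15), ri = 1.347,
                            voxel_size = 0.1, pad = 2.4)
  d <- dim(sp$values)
  dirs <- odtmorph:::snap_directions(
    illumination_directions(plan_default, 1.337), 1.337, 0.532,
    d[1:2], c(0.1, 0.1))
  fields <- lapply(seq_len(nrow(dirs)), function(k)
    scattered_field(sp, dirs[k, ], plan_default))
  fsup <- map_to_frequency_space(fields, plan_default, nz = d[3])
  tom <- regularize_missing_cone(fsup, reconstruction_settings(iterations = 0))
  cc <- (d + 1) / 2
  fwhm <- function(p) { i <- which(p / max(p) > 0.5); diff(range(i)) + 1 }
  lat <- fwhm(tom$values[cc[1], , cc[3]] - 1.337)
  axi <- fwhm(tom$values[cc[1], cc[2], ] - 1.337)
  expect_gt(axi / lat, 1.5)
})

test_that("non-negativity iterations improve a weak sphere and preserve data", {
  sp <- make_analytic_shape("sphere", list(radius = 1.2), ri = 1.347,
                            voxel_size = 0.1, pad = 2.0)
  d <- dim(sp$values)
  dirs <- odtmorph:::snap_directions(
    illumination_directions(plan_default, 1.337), 1.337, 0.532,
    d[1:2], c(0.1, 0.1))
  fields <- lapply(seq_len(nrow(dirs)), function(k)
    scattered_field(sp, dirs[k, ], plan_default))
  fsup <- map_to_frequency_space(fields, plan_default, nz = d[3])
  rr <- radial_distance(sp)
  inside <- rr <= 1.2
  t0 <- regularize_missing_cone(fsup, reconstruction_settings(iterations = 0))
  t1 <- regularize_missing_cone(fsup, reconstruction_settings(iterations = 30))
  rmse <- function(t) sqrt(mean((t$values[inside] - 1.347)^2))
  expect_lt(rmse(t1), rmse(t0))          # monotone benefit
  expect_equal(mean(t1$values[inside]), 1.347, tolerance = 0.002 / 1.347)

  # support preservation: the final spectrum equals the (symmetrized)
  # measured data on the support
  sym <- symmetrize_support(fsup)
  vs <- fsup$voxel_size
  V <- (2 * pi / 0.532)^2 * (t1$values^2 - 1.337^2)
  nz <- d[3]
  zshift <- exp(-1i * odtmorph:::freq_rad(nz, vs[3]) * floor(nz / 2) * vs[3])
  S <- sweep(fft(V) * prod(vs), 3, 1 / zshift, "*")
  num <- sqrt(sum(Mod(S[sym$support] - sym$spectrum[sym$support])^2))
  den <- sqrt(sum(Mod(sym$spectrum[sym$support])^2))
  expect_lt(num / den, 1e-6)
})

test_that("zero iterations equals the naive inverse transform", {
  sp <- make_analytic_shape("sphere", list(radius = 0.5), ri = 1.342,
                            voxel_size = 0.1, pad = 1.1)
  d <- dim(sp$values)
  f <- scattered_field(sp, c(0, 0, 1), plan_default)
  fsup <- map_to_frequency_space(list(f), plan_default, nz = d[3])
  t0 <- regularize_missing_cone(fsup, reconstruction_settings(
    iterations = 0, hermitian = FALSE))
  expect_length(attr(t0, "trace"), 0)
  expect_equal(attr(t0, "iterations"), 0)
})

test_that("wrapped phase is rejected by the frequency mapper", {
  ph <- matrix(0, 32, 32); ph[, 17:32] <- 6
  f <- complex_field(matrix(1, 32, 32), ph, 0.1, c(0, 0, 1), 0.532, 1.337)
  expect_error(map_to_frequency_space(list(f), plan_default, nz = 32),
               "unwrap")
})

test_that("Lauer resolution metadata behaves and hits the printed pair", {
  res <- lauer_resolution(illumination_plan(), 1.337)
  expect_equal(unname(res[1]), 110, tolerance = 0.15)
  expect_equal(unname(res[2]), 360, tolerance = 0.15)
  # no illumination scan: lateral limit set by detection alone
  r0 <- lauer_resolution(illumination_plan(na_illumination = 0), 1.337)
  expect_equal(unname(r0[1]), 0.532 / (2 * 1.2) * 1000, tolerance = 1e-9)
  # doubling the wavelength doubles both
  r2 <- lauer_resolution(illumination_plan(wavelength = 1.064), 1.337)
  expect_equal(unname(r2), unname(2 * res), tolerance = 1e-9)
  expect_error(lauer_resolution(illumination_plan(na_detection = 1.4), 1.337),
               "medium")
})

test_that("reconstruction settings are validated", {
  expect_error(reconstruction_settings(iterations = -1), "iterations")
  expect_error(reconstruction_settings(tol = 0), "tol")
})
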