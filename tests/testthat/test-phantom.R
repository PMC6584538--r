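test_that("calibrate_head_axes returns exact volumes and ratios", {
  expect_equal(unname(calibrate_head_axes(4 / 3 * pi, 1, 1)), c(1, 1, 1),
               tolerance = 1e-10)
  ax <- calibrate_head_axes(94.18, 9.053 / 4.954, 2)
  expect_equal(4 / 3 * pi * prod(ax), 94.18, tolerance = 1e-12)
  expect_equal(unname(ax[1] / ax[2]), 9.053 / 4.954, tolerance = 1e-12)
  expect_equal(unname(ax[2] / ax[3]), 2, tolerance = 1e-12)
  # closed-form round trip for arbitrary targets
  for (v in c(0.5, 20, 145.3)) {
    ax <- calibrate_head_axes(v, 1.7, 1.3)
    expect_equal(4 / 3 * pi * prod(ax), v, tolerance = 1e-12)
  }
  expect_error(calibrate_head_axes(-1, 1, 1), "positive")
  expect_error(calibrate_head_axes(1, 0.5, 1), "ratios")
})

test_that("zero-contrast design voxelizes to pure background", {
  d <- sperm_design(head_ri = 1.337, midpiece_ri = 1.337,
                    midpiece_core_ri = 1.337, tail_ri = 1.337,
                    head_length = 5, head_width = 3,
                    midpiece_length = 4, tail_length = 10)
  tom <- build_phantom(d, voxel_size = 0.2, medium_ri = 1.337)
  expect_true(all(tom$values == 1.337))
})

test_that("sphere-only degenerate design recovers the analytic volume", {
  d <- sperm_design(head_length = 4, head_width = 4, head_thickness = 4,
                    midpiece_length = 0, tail_length = 0)
  tom <- build_phantom(d, voxel_size = 0.1)
  v <- region_volume(attr(tom, "labels") == 1L, tom$voxel_size)
  expect_equal(v, 4 / 3 * pi * 8, tolerance = 0.02)
})

test_that("analytic shapes carry correct metadata and voxelize accurately", {
  cube <- make_analytic_shape("cube", list(side = 1), voxel_size = 0.05)
  expect_equal(attr(cube, "analytic")$volume, 1)
  expect_equal(attr(cube, "analytic")$surface_area, 6)
  expect_equal(region_volume(cube$values > 1.34, 0.05), 1, tolerance = 1e-9)

  sph <- weak_sphere()
  expect_equal(attr(sph, "analytic")$surface_area, 4 * pi * 4,
               tolerance = 1e-12)
  expect_equal(region_volume(sph$values > 1.34, 0.1), 4 / 3 * pi * 8,
               tolerance = 0.02)

  ax <- calibrate_head_axes(94.18, 9.053 / 4.954, 2)
  ell <- make_analytic_shape("ellipsoid", list(semi_axes = unname(ax)),
                             voxel_size = 0.1)
  expect_equal(attr(ell, "analytic")$volume, 94.18, tolerance = 1e-9)
  expect_equal(region_volume(ell$values > 1.34, 0.1), 94.18,
               tolerance = 0.02)

  expect_error(make_analytic_shape("torus", list(radius = 1)))
})

test_that("compartments partition the cell and masks are exclusive", {
  tom <- ho_phantom()
  lab <- attr(tom, "labels")
  cell <- tom$values > tom$medium_ri
  expect_identical(lab > 0L, cell)
  vox <- tabulate(lab[lab > 0L], 3)
  expect_equal(sum(vox), sum(cell))
  # voxelized compartment volumes close to the analytic design volumes
  dv <- odtmorph:::design_volumes(attr(tom, "design"))
  expect_equal(vox * voxel_volume(tom), unname(dv), tolerance = 0.04)
})

test_that("explicit undersized extent raises a sizing error", {
  expect_error(
    build_phantom(design_ho(), voxel_size = 0.2,
                  extent = list(y = c(-2, 2), x = c(-1, 30), z = c(-2, 2))),
    "grid too small")
})

test_that("non-physical designs are rejected", {
  expect_error(build_phantom(design_ho(head_ri = 1.30)), "non-physical")
  expect_error(sperm_design(head_width = 2, head_thickness = 3),
               "flattened")
  expect_error(sperm_design(tail_base_radius = 0.1, tail_tip_radius = 0.2),
               "tip")
  expect_error(sperm_design(head_length = -1), "positive")
})

test_that("population sampling is seeded, truncated and unbiased", {
  spec <- ho_kn_population_spec(n_per_group = 30, seed = 11)
  pop1 <- sample_population(spec)
  pop2 <- sample_population(spec)
  expect_identical(pop1, pop2)
  expect_length(pop1, 60)
  expect_setequal(unique(vapply(pop1, attr, "", "group")), c("HO", "KN"))

  hw <- vapply(pop1[seq_len(30)], function(d) d$head_width, 0)
  expect_lt(abs(mean(hw) - 4.954), 3 * 0.268 / sqrt(30))
  expect_true(all(hw >= 4.954 - 4 * 0.268 & hw <= 4.954 + 4 * 0.268))

  # zero SD collapses to the mean design
  s0 <- breed_population_spec(
    list(G = list(mean = design_ho(), sd = c(head_length = 0))),
    n_per_group = 3, seed = 1)
  p0 <- sample_population(s0)
  expect_true(all(vapply(p0, function(d) d$head_length, 0) == 9.053))

  expect_error(breed_population_spec(
    list(G = list(mean = design_ho())), n_per_group = 1), "n_per_group")

  # sampling leaves the caller's RNG stream untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(sample_population(spec)); after <- rnorm(1)
  expect_identical(before, after)
})
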