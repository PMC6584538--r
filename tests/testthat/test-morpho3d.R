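test_that("RI-band segmentation quantizes, bands and filters debris", {
  expect_equal(ri_bands()$lo, c(1.3451, 1.3521, 1.3641))
  expect_equal(ri_bands()$hi, c(1.3520, 1.3640, 1.3820))
  # uniform medium: empty mask is a valid result
  tom <- ri_tomogram(array(1.337, c(10, 10, 10)), 0.1, 1.337)
  expect_false(any(segment_cell(tom)))
  # two disjoint spheres: only the larger survives the component filter
  vals <- array(1.337, c(20, 44, 20))
  Y <- array(seq_len(20), c(20, 44, 20))
  X <- array(rep(seq_len(44), each = 20), c(20, 44, 20))
  Z <- array(rep(seq_len(20), each = 20 * 44), c(20, 44, 20))
  big <- (Y - 10)^2 + (X - 12)^2 + (Z - 10)^2 <= 64
  small <- (Y - 10)^2 + (X - 34)^2 + (Z - 10)^2 <= 16
  vals[big | small] <- 1.36
  m <- segment_cell(ri_tomogram(vals, 0.1, 1.337))
  expect_identical(m, big)
  # band intervals closed at the printed 4-decimal endpoints
  v2 <- array(1.337, c(4, 4, 4))
  v2[1, 1, 1] <- 1.35201   # rounds to 1.3520, inside RI-I
  v2[2, 1, 1] <- 1.35206   # rounds to 1.3521, inside RI-II
  t2 <- ri_tomogram(v2, 0.1, 1.337)
  b <- ri_bands()
  m1 <- segment_cell(t2, c(b$lo[1], b$hi[1]), largest_only = FALSE)
  m2 <- segment_cell(t2, c(b$lo[2], b$hi[2]), largest_only = FALSE)
  expect_true(m1[1, 1, 1] && !m1[2, 1, 1])
  expect_true(m2[2, 1, 1] && !m2[1, 1, 1])
})

test_that("voxel volumes and scale equivariance are exact", {
  expect_equal(region_volume(array(FALSE, c(3, 3, 3)), 0.1), 0)
  sph <- weak_sphere()
  m <- sph$values > 1.34
  expect_equal(region_volume(m, 0.1), 4 / 3 * pi * 8, tolerance = 0.02)
  # scaling the grid spacing by s multiplies V by s^3 and A by s^2
  expect_equal(region_volume(m, 0.2), 8 * region_volume(m, 0.1),
               tolerance = 1e-12)
  expect_equal(region_surface_area(m, 0.2), 4 * region_surface_area(m, 0.1),
               tolerance = 1e-9)
})

test_that("mesh areas match analytic oracles", {
  sph <- weak_sphere()
  a <- region_surface_area(sph$values > 1.34, 0.1)
  expect_equal(a, 4 * pi * 4, tolerance = 0.03)
  cube <- make_analytic_shape("cube", list(side = 1), voxel_size = 0.05)
  expect_equal(region_surface_area(cube$values > 1.34, 0.05), 6,
               tolerance = 0.05)
  cyl <- make_analytic_shape("cylinder", list(radius = 1, length = 3),
                             voxel_size = 0.05)
  expect_equal(region_surface_area(cyl$values > 1.34, 0.05), 8 * pi,
               tolerance = 0.05)
  expect_error(region_surface_area(array(FALSE, c(3, 3, 3)), 0.1), "empty")
})

test_that("hollow shell reports the outermost surface only", {
  sph <- weak_sphere()
  m <- sph$values > 1.34
  rr <- radial_distance(sph)
  shell <- m & rr > 1
  expect_equal(region_surface_area(shell, 0.1),
               region_surface_area(m, 0.1), tolerance = 1e-9)
  # without cavity filling, the inner surface (4*pi*1^2) adds to the total
  expect_equal(region_surface_area(shell, 0.1, fill_cavities = FALSE),
               4 * pi * 4 + 4 * pi, tolerance = 0.05)
})

test_that("sphere area error shrinks monotonically with voxel refinement", {
  errs <- vapply(c(0.2, 0.1, 0.05), function(vx) {
    s <- make_analytic_shape("sphere", list(radius = 2), voxel_size = vx)
    abs(region_surface_area(s$values > 1.34, vx) / (16 * pi) - 1)
  }, 0)
  expect_true(all(diff(errs) < 0.002))  # decreasing, small slack for ripple
})

test_that("sphericity follows the closed form and validates inputs", {
  expect_equal(sphericity(1, 6), pi^(1 / 3) * 6^(2 / 3) / 6,
               tolerance = 1e-12)
  expect_equal(sphericity(1, 6), 0.80600, tolerance = 1e-4)
  r <- 2
  expect_equal(sphericity(4 / 3 * pi * r^3, 4 * pi * r^2), 1,
               tolerance = 1e-12)
  sph <- weak_sphere()
  m <- sph$values > 1.34
  psi <- sphericity(region_volume(m, 0.1), region_surface_area(m, 0.1))
  expect_equal(psi, 1, tolerance = 0.02)
  expect_error(sphericity(0, 1), "positive")
})

test_that("concentration and dry mass follow the RI-increment relation", {
  vals <- array(1.337, c(8, 8, 8))
  m <- array(FALSE, c(8, 8, 8)); m[3:6, 3:6, 3:6] <- TRUE
  tom <- ri_tomogram(vals, 0.1, 1.337)
  expect_equal(region_concentration(tom, m), 0)
  vals[m] <- 1.35078
  tom <- ri_tomogram(vals, 0.1, 1.337)
  expect_equal(region_concentration(tom, m, ri_increment = 0.19), 72.5,
               tolerance = 1e-3)
  expect_equal(region_dry_mass(0, 99), 0)
  expect_equal(region_dry_mass(72.5, 145.3), 10.53425, tolerance = 1e-9)
  expect_error(region_concentration(tom, m & FALSE), "empty")
  expect_error(region_dry_mass(-1, 1), "non-negative")
})

test_that("compartment partition recovers designed boundaries and lengths", {
  tom <- ho_phantom()
  mask <- segment_cell(tom)
  seg <- partition_compartments(mask, tom)
  truth <- attr(tom, "boundaries")
  expect_lt(abs(seg$boundaries[[1]] - truth[[1]]), 0.5)
  expect_lt(abs(seg$boundaries[[2]] - truth[[2]]), 0.5)
  len <- compartment_lengths(seg)
  expect_equal(unname(len), c(9.053, 13.926, 46.415), tolerance = 0.03)
  # labels partition the mask
  expect_identical(seg$labels > 0L, mask)
  # voxel assignment close to the generator's ground truth
  agree <- mean(seg$labels[mask] == attr(tom, "labels")[mask])
  expect_gt(agree, 0.98)
})

test_that("degenerate shapes partition sensibly or fail loudly", {
  d <- sperm_design(head_length = 8, head_width = 4, midpiece_length = 0,
                    tail_length = 0)
  tom <- build_phantom(d, voxel_size = 0.1)
  mask <- segment_cell(tom)
  seg <- partition_compartments(mask, tom)
  expect_true(all(seg$labels[mask] == 1L))
  len <- compartment_lengths(seg)
  # zero up to the half-pixel quantization of the boundary walk
  expect_lt(max(unname(len[2:3])), 0.1)
  # a sphere cannot be oriented
  sph <- weak_sphere()
  m <- sph$values > 1.34
  expect_error(partition_compartments(m, sph), "orient")
})

test_that("band decomposition mirrors the table structure", {
  tom <- ho_phantom()
  seg <- partition_compartments(segment_cell(tom), tom)
  rec <- band_decomposition(tom, seg)
  expect_s3_class(rec, "morphometric_record")
  # tail holds no RI-III material: undetectable
  t3 <- rec[rec$region == "tail" & rec$band == "RI-III", ]
  expect_false(t3$detectable)
  expect_true(is.na(t3$volume_um3))
  # midpiece core is RI-III: detectable with the designed core RI
  m3 <- rec[rec$region == "midpiece" & rec$band == "RI-III", ]
  expect_true(m3$detectable)
  expect_equal(m3$concentration_fg_um3, (1.3731 - 1.337) / 1.9e-4,
               tolerance = 1e-3)
  # zero-width bands: everything undetectable
  zb <- data.frame(name = "Z", lo = 1.35, hi = 1.35)
  rz <- band_decomposition(tom, seg, bands = zb)
  expect_true(all(!rz$detectable[rz$band == "Z"]))
  # compartment volumes sum exactly to the whole-cell volume
  allr <- rec[rec$band == "all", ]
  expect_equal(sum(allr$volume_um3[allr$region != "cell"]),
               allr$volume_um3[allr$region == "cell"], tolerance = 1e-12)
  # band volumes within a region never exceed the region volume
  for (rg in c("head", "midpiece", "tail")) {
    sub <- rec[rec$region == rg & rec$detectable, ]
    expect_lte(sum(sub$volume_um3[sub$band != "all"]),
               sub$volume_um3[sub$band == "all"] + 1e-9)
  }
})

test_that("dry mass is additive over bands that tile the cell range", {
  tom <- ho_phantom()
  seg <- partition_compartments(segment_cell(tom), tom)
  tiling <- data.frame(name = c("low", "mid", "high"),
                       lo = c(1.3400, 1.3521, 1.3641),
                       hi = c(1.3520, 1.3640, 1.3850))
  rec <- band_decomposition(tom, seg, bands = tiling, min_voxels = 1)
  for (rg in unique(rec$region)) {
    sub <- rec[rec$region == rg, ]
    whole <- sub$dry_mass_pg[sub$band == "all"]
    parts <- sum(sub$dry_mass_pg[sub$band != "all"], na.rm = TRUE)
    expect_equal(parts, whole, tolerance = 1e-6)
  }
})

test_that("measure_3d wraps segmentation, partition and decomposition", {
  tom <- ho_phantom()
  rec <- measure_3d(tom, cell_id = "c1", group = "HO")
  expect_true(all(c("cell_id", "group", "region", "band", "volume_um3",
                    "surface_area_um2", "concentration_fg_um3",
                    "dry_mass_pg", "sphericity", "detectable")
                  %in% names(rec)))
  expect_true(all(rec$cell_id == "c1"))
  expect_false(is.na(rec$sphericity[rec$region == "head" &
                                      rec$band == "all"]))
  expect_s3_class(attr(rec, "segmentation"), "compartment_segmentation")
})
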