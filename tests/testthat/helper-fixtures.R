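# Shared fixtures, built once per test run and memoized. All fixtures are
# generated in code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# Holstein phantom at the default 0.1 um grid (the main 2D/3D fixture)
ho_phantom <- function() memo("ho", function() {
  build_phantom(design_ho(), voxel_size = 0.1)
})

ho_phase <- function() memo("ho_phase", function() {
  project_phase(ho_phantom())
})

# weak sphere (r = 2 um, dn = 0.01) voxelized at 0.1 um
weak_sphere <- function(pad = 2.4) {
  memo(paste0("sph", pad), function()
    make_analytic_shape("sphere", list(radius = 2), ri = 1.347,
                        voxel_size = 0.1, pad = pad))
}

# radial distance array (um) about the centre of a cubic tomogram grid
radial_distance <- function(tom) {
  d <- dim(tom$values)
  cc <- (d + 1) / 2
  Y <- array(seq_len(d[1]), d)
  X <- array(rep(seq_len(d[2]), each = d[1]), d)
  Z <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  sqrt(((Y - cc[1])^2 + (X - cc[2])^2 + (Z - cc[3])^2)) * tom$voxel_size[1]
}

# exact two-sided permutation p-value for the difference in means
permutation_p <- function(a, b) {
  obs <- abs(mean(a) - mean(b))
  pool <- c(a, b)
  idx <- utils::combn(length(pool), length(a))
  stats <- apply(idx, 2, function(i)
    abs(mean(pool[i]) - mean(pool[-i])))
  mean(stats >= obs - 1e-12)
}
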