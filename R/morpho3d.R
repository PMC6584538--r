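#' Refractive-index bands
#'
#' The three RI bands used to decompose intracellular material: RI-I
#' (1.3451-1.3520), RI-II (1.3521-1.3640) and RI-III (1.3641-1.3820),
#' intervals closed at both printed endpoints. RI values are quantized to
#' four decimals before banding so every in-range value falls in exactly
#' one band.
#'
#' @return data.frame with columns `name`, `lo`, `hi`.
#' @export
ri_bands <- function() {
  data.frame(name = c("RI-I", "RI-II", "RI-III"),
             lo = c(1.3451, 1.3521, 1.3641),
             hi = c(1.3520, 1.3640, 1.3820))
}

#' Whole-cell RI window
#'
#' The RI interval treated as cell material when segmenting whole cells.
#' `"standard"` is 1.3400-1.3850; `"wide"` (1.3350-1.3850) extends the
#' lower edge and captures more low-contrast halo.
#'
#' @param variant `"standard"` or `"wide"`.
#' @return numeric `c(lo, hi)`.
#' @export
whole_cell_band <- function(variant = c("standard", "wide")) {
  switch(match.arg(variant),
         standard = c(1.3400, 1.3850),
         wide = c(1.3350, 1.3850))
}

#' Segment cell material by RI band
#'
#' Voxels whose RI (quantized to 4 decimals) lies in `[lo, hi]`,
#' restricted to the largest 26-connected component (floating debris and
#' reconstruction speckle are dropped). An empty mask is a valid result.
#'
#' @param tom an `ri_tomogram`.
#' @param band numeric `c(lo, hi)`.
#' @param largest_only keep only the largest connected component.
#' @return logical array of `dim(tom$values)`.
#' @export
segment_cell <- function(tom, band = whole_cell_band(),
                         largest_only = TRUE) {
  v <- round(tom$values, 4)
  mask <- v >= band[1] & v <= band[2]
  if (!any(mask) || !largest_only) return(mask)
  lab <- cpp_label_components(mask, 26L)
  counts <- tabulate(lab[lab > 0L])
  lab == which.max(counts)
}

#' Voxel-counting volume of a region
#'
#' Volume as the number of voxels in the mask times the unit voxel volume.
#'
#' @param mask logical array.
#' @param voxel_size voxel spacing (scalar or length 3), µm.
#' @return volume in µm³.
#' @export
region_volume <- function(mask, voxel_size) {
  sum(mask) * voxel_volume(voxel_size)
}

# separable Gaussian smoothing of a 3D numeric array; sigma in voxels,
# scalar or per-axis. Edges are replicated so boundary values stay flat.
gauss_smooth_3d <- function(a, sigma) {
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  smooth_first <- function(a, sg) {
    if (sg <= 0) return(a)
    r <- ceiling(3 * sg)
    kern <- exp(-0.5 * ((-r:r) / sg)^2)
    kern <- kern / sum(kern)
    d <- dim(a)
    m <- matrix(a, nrow = d[1])
    m <- rbind(m[rep(1, r), , drop = FALSE], m,
               m[rep(d[1], r), , drop = FALSE])
    f <- stats::filter(m, kern, sides = 2)
    array(f[(r + 1):(r + d[1]), ], dim = d)
  }
  a <- smooth_first(a, sigma[1])
  a <- aperm(smooth_first(aperm(a, c(2, 1, 3)), sigma[2]), c(2, 1, 3))
  aperm(smooth_first(aperm(a, c(3, 1, 2)), sigma[3]), c(2, 3, 1))
}

# signed Euclidean distance field of a mask (negative inside), physical
# units, from the voxel-centre distance transforms of both phases
signed_distance_3d <- function(mask, voxel_size) {
  d_in <- sqrt(cpp_sq_edt(mask, voxel_size[1], voxel_size[2],
                          voxel_size[3]))
  d_out <- sqrt(cpp_sq_edt(!mask, voxel_size[1], voxel_size[2],
                           voxel_size[3]))
  d_in - d_out  # 0 midway between opposite-phase voxel centres
}

# fill interior cavities of a 3D mask: background components not connected
# to the array border become foreground
fill_cavities_3d <- function(mask) {
  lab <- cpp_label_components(!mask, 6L)
  d <- dim(mask)
  border <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
                     lab[, , 1], lab[, , d[3]]))
  border <- border[border > 0L]
  cavity <- lab > 0L & !(lab %in% border)
  mask | cavity
}

#' Surface area of a voxel region
#'
#' Area of the triangulated mid-surface of the (optionally cavity-filled)
#' binary mask. The mask is converted to a signed Euclidean distance
#' field (zero midway between opposite-phase voxel centres), lightly
#' Gaussian-smoothed to suppress lattice ripple — the level-set position
#' of a distance field is insensitive to symmetric smoothing, unlike that
#' of a smoothed binary indicator — and the zero isosurface is meshed by
#' marching tetrahedra with physical voxel spacing. With
#' `fill_cavities = TRUE` only the outermost surface counts, so a hollow
#' shell has the area of the solid shape with the same outer boundary.
#'
#' @param mask logical array.
#' @param voxel_size voxel spacing (scalar or length 3), µm.
#' @param fill_cavities remove internal cavities before meshing.
#' @param smooth_sigma Gaussian sigma (voxels) applied to the distance
#'   field before meshing.
#' @param taubin_iters Taubin smoothing passes applied to the mesh.
#' @return surface area in µm².
#' @export
region_surface_area <- function(mask, voxel_size, fill_cavities = TRUE,
                                smooth_sigma = 0.5, taubin_iters = 40) {
  if (!any(mask)) stop("cannot mesh an empty mask")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  # crop to the occupied bounding box; the surface only depends on a
  # neighbourhood of the mask
  w <- which(mask, arr.ind = TRUE)
  lo <- apply(w, 2, min); hi <- apply(w, 2, max)
  mask <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  if (fill_cavities) mask <- fill_cavities_3d(mask)
  marg <- 4L
  d <- dim(mask)
  big <- array(FALSE, dim = d + 2 * marg)
  big[marg + seq_len(d[1]), marg + seq_len(d[2]), marg + seq_len(d[3])] <-
    mask
  f <- signed_distance_3d(big, voxel_size)
  if (smooth_sigma > 0) f <- gauss_smooth_3d(f, smooth_sigma)
  cpp_isosurface_area(-f, 0, voxel_size[1], voxel_size[2], voxel_size[3],
                      as.integer(taubin_iters), 0.5, -0.53)
}

#' Sphericity index
#'
#' `psi = pi^(1/3) * (6 V)^(2/3) / A`: 1 for a sphere, smaller for
#' flattened or elongated shapes.
#'
#' @param volume volume, µm³.
#' @param surface_area surface area, µm².
#' @return dimensionless sphericity.
#' @export
sphericity <- function(volume, surface_area) {
  if (any(volume <= 0) || any(surface_area <= 0))
    stop("volume and surface_area must be positive")
  pi^(1 / 3) * (6 * volume)^(2 / 3) / surface_area
}

#' Dry-mass concentration of a region
#'
#' Mean RI elevation over the medium divided by the refractive-index
#' increment. With the increment in mL/g the result is in fg/µm³
#' (numerically equal to g/L): `c = (RI - medium_ri) / (alpha * 1e-3)`.
#'
#' @param tom an `ri_tomogram`.
#' @param mask logical array selecting the region.
#' @param ri_increment refractive-index increment, mL/g (default 0.19,
#'   the common protein/nucleic-acid value).
#' @param medium_ri medium RI (defaults to the tomogram's).
#' @return mean concentration in fg/µm³.
#' @export
region_concentration <- function(tom, mask, ri_increment = 0.19,
                                 medium_ri = tom$medium_ri) {
  if (!any(mask)) stop("cannot compute concentration of an empty mask")
  if (ri_increment <= 0) stop("ri_increment must be positive")
  mean(tom$values[mask] - medium_ri) / (ri_increment * 1e-3)
}

#' Dry mass of a region
#'
#' Concentration times volume, converted fg to pg.
#'
#' @param concentration fg/µm³.
#' @param volume µm³.
#' @return dry mass in pg.
#' @export
region_dry_mass <- function(concentration, volume) {
  if (any(concentration < 0) || any(volume < 0))
    stop("concentration and volume must be non-negative")
  concentration * volume / 1000
}

#' Split a cell mask into head, midpiece and tail
#'
#' Extracts the medial axis from the z-projection of the mask (thinning,
#' longest skeleton path, smoothing spline, tip extension; z from the
#' per-column centre of mass), orders it thick end first, and places the
#' two compartment boundaries: head/midpiece by the shared width-profile
#' rule and midpiece/tail at the end of the high-RI (RI-III) core, or at a
#' fixed fallback arclength when the cell carries no such core. Voxels are
#' assigned to the compartment of their nearest axis sample.
#'
#' @param mask logical array, a single connected elongated cell.
#' @param tom the `ri_tomogram` the mask came from.
#' @param head_frac width fraction for the head/midpiece neck.
#' @param core_ri_min lower RI edge of the high-RI core band.
#' @param midpiece_fallback midpiece length (µm) assumed when no high-RI
#'   core is present.
#' @param min_aspect minimum bounding-box aspect ratio; below it the cell
#'   cannot be oriented and an error is raised.
#' @return object of class `compartment_segmentation`: list with `labels`
#'   (0 background, 1 head, 2 midpiece, 3 tail), `medial_axis` (matrix
#'   with columns `s`, `y`, `x`, `z` in µm), `boundaries` (two
#'   arclengths), `widths` (per-sample silhouette width).
#' @export
partition_compartments <- function(mask, tom, head_frac = 0.25,
                                   core_ri_min = 1.3641,
                                   midpiece_fallback = 13.9,
                                   min_aspect = 1.5) {
  if (!any(mask)) stop("empty mask")
  proj <- rowSums(mask, dims = 2) > 0
  pix <- which(proj, arr.ind = TRUE)
  ry <- diff(range(pix[, 1])) + 1
  rx <- diff(range(pix[, 2])) + 1
  if (max(ry, rx) / min(ry, rx) < min_aspect)
    stop("cannot orient cell: silhouette aspect ratio below ", min_aspect)

  vs <- tom$voxel_size
  ax <- extract_axis_2d(proj, vs[1:2])
  smax <- max(ax$s)
  b1 <- boundary_from_width(ax$s, ax$width, frac = head_frac)

  # arclength of every mask voxel via its (y, x) column's assignment
  sgrid <- matrix(NA_real_, nrow(proj), ncol(proj))
  sgrid[ax$pixels] <- ax$pixel_s
  d <- dim(mask)
  svox <- array(sgrid, dim = d)  # recycles the (y, x) map along z
  svals <- svox[mask]

  if (b1 >= smax - mean(vs[1:2])) {
    b2 <- smax
  } else {
    core <- mask & round(tom$values, 4) >= core_ri_min
    s_core <- svox[core]
    s_core <- s_core[is.finite(s_core) & s_core > b1]
    b2 <- if (length(s_core) > 0) max(s_core) + mean(vs[1:2]) / 2
      else min(b1 + midpiece_fallback, smax)
  }

  lab <- array(0L, dim = d)
  lab[mask] <- ifelse(svals <= b1, 1L, ifelse(svals <= b2, 2L, 3L))

  # z-coordinate of the axis from the mask centre of mass per column
  zc <- axis_coords(tom)$z
  zw <- rowSums(sweep(mask, 3, zc, "*"), dims = 2)
  zn <- rowSums(mask, dims = 2)
  zmap <- ifelse(zn > 0, zw / pmax(zn, 1), NA_real_)
  iy <- pmin(pmax(round(ax$y / vs[1]) + 1, 1), d[1])
  ix <- pmin(pmax(round(ax$x / vs[2]) + 1, 1), d[2])
  az <- zmap[cbind(iy, ix)]
  if (anyNA(az)) {
    ok <- which(!is.na(az))
    az <- approx(ax$s[ok], az[ok], xout = ax$s, rule = 2)$y
  }

  structure(list(
    labels = lab,
    medial_axis = cbind(s = ax$s, y = ax$y, x = ax$x, z = az),
    boundaries = c(head_mid = b1, mid_tail = b2),
    widths = ax$width),
    class = "compartment_segmentation")
}

#' Compartment lengths along the medial axis
#' @param seg a `compartment_segmentation`.
#' @return named numeric: head, midpiece, tail lengths (µm).
#' @export
compartment_lengths <- function(seg) {
  s <- seg$medial_axis[, "s"]
  b <- seg$boundaries
  c(head = b[[1]] - min(s), midpiece = b[[2]] - b[[1]],
    tail = max(s) - b[[2]])
}

#' Per-region, per-band morphometrics
#'
#' For every compartment (head, midpiece, tail, plus the whole cell) and
#' every RI band (plus `"all"`) computes voxel volume, surface area, mean
#' dry-mass concentration and dry mass. Whole-region rows use the
#' outermost surface (cavities filled); band rows mesh the band mask
#' itself, internal surfaces included, since band material is typically a
#' shell or scattered inclusions. Bands occupying fewer than `min_voxels`
#' voxels are reported undetectable (`detectable = FALSE`, measurements
#' `NA`). Sphericity is reported for the head region.
#'
#' @param tom an `ri_tomogram`.
#' @param seg a [partition_compartments()] result.
#' @param bands data.frame as [ri_bands()].
#' @param ri_increment refractive-index increment, mL/g.
#' @param min_voxels detectability threshold in voxels.
#' @return data.frame (class `morphometric_record`) with columns `region`,
#'   `band`, `volume_um3`, `surface_area_um2`, `concentration_fg_um3`,
#'   `dry_mass_pg`, `sphericity`, `detectable`.
#' @export
band_decomposition <- function(tom, seg, bands = ri_bands(),
                               ri_increment = 0.19, min_voxels = 10) {
  vs <- tom$voxel_size
  q <- round(tom$values, 4)
  regions <- list(cell = seg$labels > 0L, head = seg$labels == 1L,
                  midpiece = seg$labels == 2L, tail = seg$labels == 3L)
  rows <- list()
  for (rn in names(regions)) {
    rmask <- regions[[rn]]
    if (!any(rmask)) next
    vol <- region_volume(rmask, vs)
    area <- region_surface_area(rmask, vs, fill_cavities = TRUE)
    conc <- region_concentration(tom, rmask, ri_increment)
    rows[[length(rows) + 1L]] <- data.frame(
      region = rn, band = "all", volume_um3 = vol,
      surface_area_um2 = area, concentration_fg_um3 = conc,
      dry_mass_pg = region_dry_mass(conc, vol),
      sphericity = if (rn == "head") sphericity(vol, area) else NA_real_,
      detectable = TRUE)
    for (bi in seq_len(nrow(bands))) {
      bmask <- rmask & q >= bands$lo[bi] & q <= bands$hi[bi]
      nvx <- sum(bmask)
      if (nvx < min_voxels) {
        rows[[length(rows) + 1L]] <- data.frame(
          region = rn, band = bands$name[bi], volume_um3 = NA_real_,
          surface_area_um2 = NA_real_, concentration_fg_um3 = NA_real_,
          dry_mass_pg = NA_real_, sphericity = NA_real_,
          detectable = FALSE)
      } else {
        bvol <- region_volume(bmask, vs)
        barea <- region_surface_area(bmask, vs, fill_cavities = FALSE)
        bconc <- region_concentration(tom, bmask, ri_increment)
        rows[[length(rows) + 1L]] <- data.frame(
          region = rn, band = bands$name[bi], volume_um3 = bvol,
          surface_area_um2 = barea, concentration_fg_um3 = bconc,
          dry_mass_pg = region_dry_mass(bconc, bvol),
          sphericity = NA_real_, detectable = TRUE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("morphometric_record", class(out))
  out
}

#' Full 3D morphometry of one tomogram
#'
#' Convenience wrapper: whole-cell segmentation, compartment partition and
#' band decomposition, with identification columns prepended.
#'
#' @param tom an `ri_tomogram`.
#' @param cell_id,group identifiers carried into the output.
#' @param band whole-cell RI window for segmentation.
#' @param bands RI band table for decomposition.
#' @param ... passed to [partition_compartments()].
#' @return a `morphometric_record` data.frame; the segmentation is
#'   attached as attribute `segmentation`.
#' @export
measure_3d <- function(tom, cell_id = "cell", group = NA_character_,
                       band = whole_cell_band(), bands = ri_bands(), ...) {
  mask <- segment_cell(tom, band)
  if (!any(mask)) stop("no cell material in the whole-cell RI window")
  seg <- partition_compartments(mask, tom, ...)
  rec <- band_decomposition(tom, seg, bands)
  rec <- cbind(cell_id = cell_id, group = group, rec)
  class(rec) <- c("morphometric_record", "data.frame")
  attr(rec, "segmentation") <- seg
  rec
}
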