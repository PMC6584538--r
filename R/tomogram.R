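#' 3D refractive-index tomogram
#'
#' The central container of the pipeline: a 3D voxel grid of refractive
#' index (RI) values together with its physical voxel spacing and the RI of
#' the immersion medium. Values are stored as a numeric array with
#' dimensions `(ny, nx, nz)` so that `values[, , k]` is the k-th z-slice;
#' world coordinates are in micrometres, voxel-centre convention, with
#' `origin` the world coordinate of voxel `[1, 1, 1]`.
#'
#' @param values numeric 3D array of RI values, dim `(ny, nx, nz)`.
#' @param voxel_size voxel spacing in µm: scalar (isotropic) or length-3
#'   `(dy, dx, dz)` matching `dim(values)`.
#' @param medium_ri refractive index of the immersion medium.
#' @param origin world coordinate (µm) of the centre of voxel `[1, 1, 1]`,
#'   length-3 `(y, x, z)`.
#' @param tol tolerance below `medium_ri` allowed for noise/ringing.
#' @return An object of class `ri_tomogram`.
#' @export
ri_tomogram <- function(values, voxel_size, medium_ri, origin = c(0, 0, 0),
                        tol = 5e-3) {
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array (ny, nx, nz)")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be a positive scalar or length-3 (dy, dx, dz)")
  if (!all(is.finite(values)))
    stop("tomogram values must be finite")
  if (min(values) < medium_ri - tol)
    stop(sprintf(
      "tomogram contains RI %.4f more than %.4f below the medium (%.4f)",
      min(values), tol, medium_ri))
  structure(
    list(values = values,
         voxel_size = as.numeric(voxel_size),
         medium_ri = medium_ri,
         origin = as.numeric(origin)),
    class = "ri_tomogram")
}

#' @export
print.ri_tomogram <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<ri_tomogram> %d x %d x %d voxels @ (%.3g, %.3g, %.3g) um, medium RI %.4f\n",
    d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
    x$medium_ri))
  cat(sprintf("  RI range [%.4f, %.4f]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Physical volume of one voxel in µm³
#' @param tom an `ri_tomogram`, or a numeric voxel-size vector.
#' @export
voxel_volume <- function(tom) {
  vs <- if (inherits(tom, "ri_tomogram")) tom$voxel_size else tom
  if (length(vs) == 1L) vs <- rep(vs, 3L)
  prod(vs)
}

#' World coordinates of voxel centres
#'
#' @param tom an `ri_tomogram`.
#' @return list with numeric vectors `y`, `x`, `z` (µm).
#' @export
axis_coords <- function(tom) {
  d <- dim(tom$values)
  list(y = tom$origin[1] + (seq_len(d[1]) - 1) * tom$voxel_size[1],
       x = tom$origin[2] + (seq_len(d[2]) - 1) * tom$voxel_size[2],
       z = tom$origin[3] + (seq_len(d[3]) - 1) * tom$voxel_size[3])
}

#' RI contrast relative to the medium
#' @param tom an `ri_tomogram`.
#' @return numeric array `values - medium_ri`.
#' @export
ri_contrast <- function(tom) tom$values - tom$medium_ri
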