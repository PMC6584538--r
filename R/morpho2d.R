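#' 2D optical phase map
#'
#' Quantitative phase image: optical phase delay in radians on a 2D pixel
#' grid. Phase delay is the path integral of RI contrast along the optical
#' axis scaled by 2*pi/lambda.
#'
#' @param phase numeric matrix, radians.
#' @param pixel_size pixel pitch in µm (scalar or `(dy, dx)`).
#' @param source `"measured"` or `"projected-from-tomogram"`.
#' @param wavelength wavelength in µm (metadata).
#' @return object of class `phase_map`.
#' @export
phase_map <- function(phase, pixel_size, source = "measured",
                      wavelength = NA_real_) {
  if (!is.matrix(phase) || !all(is.finite(phase)))
    stop("`phase` must be a finite numeric matrix")
  if (length(pixel_size) == 1L) pixel_size <- rep(pixel_size, 2L)
  if (any(pixel_size <= 0)) stop("pixel_size must be positive")
  structure(list(phase = phase, pixel_size = as.numeric(pixel_size),
                 source = source, wavelength = wavelength),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("<phase_map> %d x %d px @ (%.3g, %.3g) um, range [%.3f, %.3f] rad (%s)\n",
              nrow(x$phase), ncol(x$phase), x$pixel_size[1], x$pixel_size[2],
              min(x$phase), max(x$phase), x$source))
  invisible(x)
}

#' Project a tomogram to a phase map
#'
#' Integrates RI contrast along z: `phase(y, x) = (2*pi/lambda) *
#' sum_z (RI - medium_ri) * dz`, the ideal-imaging phase delay of the
#' sample.
#'
#' @param tom an `ri_tomogram`.
#' @param wavelength wavelength in µm.
#' @return a [phase_map()] with source `"projected-from-tomogram"`.
#' @export
project_phase <- function(tom, wavelength = 0.532) {
  dz <- tom$voxel_size[3]
  opd <- rowSums(ri_contrast(tom), dims = 2) * dz
  phase_map(2 * pi / wavelength * opd, tom$voxel_size[1:2],
            source = "projected-from-tomogram", wavelength = wavelength)
}

#' Measure 2D sperm morphometry from a phase map
#'
#' Segments the cell (Otsu threshold on phase with hysteresis extension so
#' the dim tail is retained), extracts the medial axis, and measures the
#' four standard 2D parameters: head length, head width, midpiece length
#' and tail length (all µm, disjoint segments along the axis).
#'
#' Segmentation: pixels above the Otsu threshold seed the cell; the mask
#' is the connected component of pixels above `lo_frac` times that
#' threshold containing the seed, so the low-phase tail stays attached.
#' The head/midpiece boundary uses the shared width-profile rule
#' (width below `head_frac` of the maximal head width, advanced to the
#' neck); the midpiece/tail boundary is the largest downward step of the
#' axial phase profile, reflecting the drop in optical density at the end
#' of the mitochondria-rich midpiece.
#'
#' @param pm a [phase_map()].
#' @param lo_frac hysteresis low threshold as a fraction of the Otsu
#'   threshold.
#' @param head_frac width fraction defining the head/midpiece neck.
#' @param min_seed_px minimum seed size (px) for a component to count as a
#'   cell (smaller bright specks are ignored).
#' @return object of class `morphometry_2d`: list with `head_length`,
#'   `head_width`, `midpiece_length`, `tail_length` (µm) and attributes
#'   `boundaries` and `axis`.
#' @export
measure_2d <- function(pm, lo_frac = 0.15, head_frac = 0.25,
                       min_seed_px = 50) {
  stopifnot(inherits(pm, "phase_map"))
  ph <- pmax(pm$phase, 0)
  if (max(ph) <= 0) stop("empty frame: no positive phase signal")
  thr <- EBImage::otsu(EBImage::Image(ph / max(ph))) * max(ph)
  seed <- ph > thr
  lo <- ph > lo_frac * thr
  # label a one-pixel dilation so hair-thin necks (e.g. the head-midpiece
  # junction) cannot split the cell, then restrict to the original mask
  lo_d <- EBImage::imageData(EBImage::dilate(
    EBImage::Image(lo * 1), EBImage::makeBrush(3, "box"))) > 0
  lab <- cpp_label_components(array(lo_d, dim = c(dim(lo_d), 1L)), 26L)
  lab <- lab[, , 1]
  lab[!lo] <- 0L
  seed_labs <- lab[seed & lab > 0]
  if (length(seed_labs) == 0) stop("empty frame: no cell above threshold")
  counts <- table(seed_labs)
  counts <- counts[counts >= min_seed_px]
  if (length(counts) == 0) stop("empty frame: no cell above threshold")
  if (length(counts) > 1)
    stop(sprintf("multiple cells in frame (%d candidate components); expected exactly one",
                 length(counts)))
  mask <- lab == as.integer(names(counts)[1])
  # close hair-thin gaps (sub-threshold pinch at the head-midpiece neck)
  mask <- EBImage::imageData(EBImage::closing(
    EBImage::Image(mask * 1), EBImage::makeBrush(3, "box"))) > 0

  ax <- extract_axis_2d(mask, pm$pixel_size)
  smax <- max(ax$s)
  b1 <- boundary_from_width(ax$s, ax$width, frac = head_frac)
  head_length <- b1
  head_region <- ax$s <= b1
  head_width <- max(ax$width[head_region])

  if (b1 >= smax - mean(pm$pixel_size)) {
    # degenerate head-only cell
    out <- list(head_length = smax, head_width = head_width,
                midpiece_length = 0, tail_length = 0)
    b2 <- smax
  } else {
    # centre-line (per-sample maximum) phase: insensitive to the pixel
    # quantization of the silhouette width, so the optical-density step at
    # the end of the midpiece stands out against the tail taper
    prof_vals <- ph[ax$pixels]
    prof <- rep(NA_real_, length(ax$s))
    pm_max <- tapply(prof_vals, ax$assign, max)
    prof[as.integer(names(pm_max))] <- pm_max
    if (anyNA(prof)) {
      ok <- which(!is.na(prof))
      prof <- approx(ax$s[ok], prof[ok], xout = ax$s, rule = 2)$y
    }
    b2 <- boundary_from_profile(ax$s, prof, from = b1 + 1)
    out <- list(head_length = head_length, head_width = head_width,
                midpiece_length = b2 - b1, tail_length = smax - b2)
  }
  structure(out, class = "morphometry_2d",
            boundaries = c(head_mid = b1, mid_tail = b2), axis = ax)
}

#' @export
print.morphometry_2d <- function(x, ...) {
  cat(sprintf(
    "<morphometry_2d> head %.3f x %.3f um, midpiece %.3f um, tail %.3f um\n",
    x$head_length, x$head_width, x$midpiece_length, x$tail_length))
  invisible(x)
}
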