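#' Parametric description of a sperm-cell phantom
#'
#' Geometry and refractive-index (RI) parameters of a single spermatozoon
#' phantom. The cell is modelled as three compartments joined along a
#' medial axis: a triaxial ellipsoidal head flattened in z (thickness
#' below width, reflecting the bilateral symmetry of bovine sperm), a
#' cylindrical midpiece carrying a coaxial high-RI core (the
#' mitochondria-rich band), and a linearly tapered filament tail. The
#' compartments occupy disjoint intervals of the axis:
#' head `[0, head_length]`, midpiece `(head_length, head_length +
#' midpiece_length]`, tail up to the total length, so designed boundary
#' arclengths are exact ground truth for segmentation tests.
#'
#' All lengths and radii are in µm; RI values are dimensionless.
#' `curvature` (1/µm) bends the tail in-plane along a circular arc of that
#' curvature; 0 keeps the cell straight.
#'
#' @param head_length,head_width,head_thickness head ellipsoid diameters.
#'   `head_thickness` defaults to half the width (flattened head).
#' @param midpiece_length,midpiece_radius,midpiece_core_radius midpiece
#'   cylinder and inner core geometry. Zero midpiece length gives a
#'   head-only (degenerate) design.
#' @param tail_length,tail_base_radius,tail_tip_radius tapered tail.
#' @param head_ri,midpiece_ri,midpiece_core_ri,tail_ri compartment RI.
#' @param curvature tail curvature in 1/µm.
#' @return object of class `sperm_design` (named list).
#' @export
sperm_design <- function(head_length = 9.0, head_width = 5.0,
                         head_thickness = head_width / 2,
                         midpiece_length = 13.0, midpiece_radius = 0.4,
                         midpiece_core_radius = 0.25,
                         tail_length = 45, tail_base_radius = 0.35,
                         tail_tip_radius = 0.1,
                         head_ri = 1.3514, midpiece_ri = 1.3564,
                         midpiece_core_ri = 1.3731, tail_ri = 1.3600,
                         curvature = 0) {
  d <- list(head_length = head_length, head_width = head_width,
            head_thickness = head_thickness,
            midpiece_length = midpiece_length,
            midpiece_radius = midpiece_radius,
            midpiece_core_radius = midpiece_core_radius,
            tail_length = tail_length, tail_base_radius = tail_base_radius,
            tail_tip_radius = tail_tip_radius,
            head_ri = head_ri, midpiece_ri = midpiece_ri,
            midpiece_core_ri = midpiece_core_ri, tail_ri = tail_ri,
            curvature = curvature)
  validate_sperm_design(d)
  structure(d, class = "sperm_design")
}

validate_sperm_design <- function(d) {
  if (d$head_length <= 0 || d$head_width <= 0 || d$head_thickness <= 0)
    stop("head dimensions must be positive")
  if (d$midpiece_length < 0 || d$tail_length < 0)
    stop("midpiece and tail lengths must be non-negative")
  if (d$midpiece_length > 0 && d$midpiece_radius <= 0)
    stop("midpiece radius must be positive")
  if (d$tail_length > 0 &&
      (d$tail_base_radius <= 0 || d$tail_tip_radius <= 0))
    stop("tail radii must be positive")
  if (d$head_width < d$head_thickness)
    stop("head must be flattened: head_width >= head_thickness")
  if (d$tail_tip_radius > d$tail_base_radius)
    stop("tail_tip_radius must not exceed tail_base_radius")
  if (d$curvature < 0) stop("curvature must be >= 0")
  if (d$curvature > 0 && d$curvature * d$tail_length >= pi)
    stop("tail arc exceeds a half turn; reduce curvature or tail length")
  invisible(d)
}

#' @export
print.sperm_design <- function(x, ...) {
  cat(sprintf(
    "<sperm_design> head %.3f x %.3f x %.3f um, midpiece %.3f um (r %.2f), tail %.3f um\n",
    x$head_length, x$head_width, x$head_thickness, x$midpiece_length,
    x$midpiece_radius, x$tail_length))
  invisible(x)
}

#' Preset designs for the two bovine breeds
#'
#' `design_ho()` and `design_kn()` carry the measured mean 2D dimensions of
#' Holstein (HO) and Kongsberg/Korean native (KN) bovine spermatozoa: head
#' length x width 9.053 x 4.954 µm vs 9.229 x 5.241 µm, midpiece 13.926 vs
#' 13.245 µm, tail 46.415 vs 47.750 µm. Head thickness defaults to half
#' the head width. Compartment RI values are placed inside the RI-I/II/III
#' bands so that compartment mean concentrations under the default
#' refractive-index increment fall in the measured ranges; the midpiece
#' core sits in the RI-III band and the tail contains no RI-III material.
#'
#' @param ... overrides passed on to [sperm_design()].
#' @return a `sperm_design`.
#' @export
design_ho <- function(...) {
  args <- modifyList(
    list(head_length = 9.053, head_width = 4.954, head_thickness = 4.954 / 2,
         midpiece_length = 13.926, tail_length = 46.415,
         head_ri = 1.3514, midpiece_ri = 1.3564, midpiece_core_ri = 1.3731,
         tail_ri = 1.3600),
    list(...))
  do.call(sperm_design, args)
}

#' @rdname design_ho
#' @export
design_kn <- function(...) {
  args <- modifyList(
    list(head_length = 9.229, head_width = 5.241, head_thickness = 5.241 / 2,
         midpiece_length = 13.245, tail_length = 47.750,
         head_ri = 1.3507, midpiece_ri = 1.3490, midpiece_core_ri = 1.3728,
         tail_ri = 1.3600),
    list(...))
  do.call(sperm_design, args)
}

#' Volume-calibrated whole-cell design
#'
#' Builds a design whose analytic compartment volumes are calibrated to
#' measured volumetric data rather than to the 2D silhouette: the head
#' ellipsoid axes come from [calibrate_head_axes()] at `head_volume` with
#' the measured head length/width aspect ratio, and the midpiece/tail
#' radii are solved so that the three compartments sum exactly to
#' `total_volume`. When the target total exceeds the sum of the given part
#' volumes (as happens when the whole cell is segmented with a wider RI
#' window than the parts), the midpiece and tail volumes are scaled up
#' proportionally to absorb the difference.
#'
#' @param total_volume target whole-cell volume, µm³.
#' @param head_volume,midpiece_volume,tail_volume per-part volumes, µm³.
#' @param length_to_width,width_to_thickness head aspect ratios.
#' @param midpiece_length,tail_length,tail_tip_radius geometry carried over.
#' @param ... further overrides passed to [sperm_design()].
#' @return a `sperm_design` with attribute `analytic_volume` equal to
#'   `total_volume`.
#' @export
design_calibrated <- function(total_volume = 145.3, head_volume = 94.18,
                              midpiece_volume = 20.61, tail_volume = 8.94,
                              length_to_width = 9.053 / 4.954,
                              width_to_thickness = 2,
                              midpiece_length = 13.926, tail_length = 46.415,
                              tail_tip_radius = 0.1, ...) {
  if (total_volume < head_volume)
    stop("total_volume must be at least head_volume")
  ax <- calibrate_head_axes(head_volume, length_to_width, width_to_thickness)
  scale <- (total_volume - head_volume) / (midpiece_volume + tail_volume)
  v_mid <- midpiece_volume * scale
  v_tail <- tail_volume * scale
  r_mid <- sqrt(v_mid / (pi * midpiece_length))
  # frustum: V = pi L / 3 * (R^2 + R r + r^2), solve for base radius R
  cc <- 3 * v_tail / (pi * tail_length)
  r <- tail_tip_radius
  R <- (-r + sqrt(r^2 - 4 * (r^2 - cc))) / 2
  d <- sperm_design(head_length = 2 * ax[1], head_width = 2 * ax[2],
                    head_thickness = 2 * ax[3],
                    midpiece_length = midpiece_length,
                    midpiece_radius = r_mid,
                    midpiece_core_radius = min(0.25, 0.6 * r_mid),
                    tail_length = tail_length, tail_base_radius = R,
                    tail_tip_radius = tail_tip_radius, ...)
  attr(d, "analytic_volume") <- total_volume
  d
}

#' Ellipsoid semi-axes with a prescribed volume and aspect ratios
#'
#' Returns semi-axes `(a, b, c)` with `a/b = length_to_width`,
#' `b/c = width_to_thickness` and `4/3 pi a b c = target_volume` exactly.
#'
#' @param target_volume ellipsoid volume, µm³.
#' @param length_to_width,width_to_thickness aspect ratios, both >= 1.
#' @return numeric semi-axes `c(a, b, c)` in µm.
#' @export
calibrate_head_axes <- function(target_volume, length_to_width = 1,
                                width_to_thickness = 1) {
  if (target_volume <= 0) stop("target_volume must be positive")
  if (length_to_width < 1 || width_to_thickness < 1)
    stop("aspect ratios must be >= 1")
  b <- (3 * target_volume * width_to_thickness /
          (4 * pi * length_to_width))^(1 / 3)
  c(a = length_to_width * b, b = b, c = b / width_to_thickness)
}

# Analytic compartment volumes of a design (µm³).
design_volumes <- function(d) {
  v_head <- pi / 6 * d$head_length * d$head_width * d$head_thickness
  v_mid <- pi * d$midpiece_radius^2 * d$midpiece_length
  R <- d$tail_base_radius; r <- d$tail_tip_radius
  v_tail <- if (d$tail_length > 0)
    pi * d$tail_length / 3 * (R^2 + R * r + r^2) else 0
  c(head = v_head, midpiece = if (d$midpiece_length > 0) v_mid else 0,
    tail = v_tail)
}

#' Voxelize a sperm design into an RI tomogram
#'
#' Renders the design on a voxel grid by voxel-centre sampling: a voxel
#' belongs to a compartment when its centre lies inside that compartment's
#' solid. The background is the immersion medium. The returned tomogram
#' carries the compartment label array (0 background, 1 head, 2 midpiece,
#' 3 tail), the design, and the ground-truth boundary arclengths as
#' attributes.
#'
#' @param design a [sperm_design()].
#' @param voxel_size voxel spacing, µm (scalar or `(dy, dx, dz)`).
#' @param medium_ri immersion-medium RI.
#' @param pad clearance between cell and grid edge, µm.
#' @param extent optional explicit grid extent, a list with numeric ranges
#'   `y`, `x`, `z` (µm). An extent too small to contain the cell plus
#'   `pad` is an error.
#' @return an `ri_tomogram` with attributes `labels`, `design`,
#'   `boundaries` (the two axis arclengths separating head/midpiece and
#'   midpiece/tail).
#' @export
build_phantom <- function(design, voxel_size = 0.1, medium_ri = 1.337,
                          pad = 1.0, extent = NULL) {
  validate_sperm_design(design)
  ris <- c(design$head_ri, design$midpiece_ri, design$midpiece_core_ri,
           design$tail_ri)
  if (any(ris < medium_ri))
    stop("non-physical design: compartment RI below the medium RI")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)

  L_h <- design$head_length
  L_m <- design$midpiece_length
  L_t <- design$tail_length
  x_t0 <- L_h + L_m
  total <- x_t0 + L_t
  r_max <- max(design$head_width / 2, design$midpiece_radius,
               design$tail_base_radius)

  # bounding box of the (possibly bent) tail
  y_lo <- -r_max; y_hi <- r_max; x_hi <- total
  if (design$curvature > 0 && L_t > 0) {
    R_arc <- 1 / design$curvature
    phi <- L_t / R_arc
    x_hi <- x_t0 + R_arc * sin(min(phi, pi / 2))
    y_hi <- max(y_hi, R_arc * (1 - cos(phi)) + design$tail_base_radius)
  }
  need <- list(y = c(y_lo - pad, y_hi + pad),
               x = c(0 - pad, x_hi + pad),
               z = c(-(max(design$head_thickness / 2, r_max)) - pad,
                     max(design$head_thickness / 2, r_max) + pad))
  if (is.null(extent)) {
    extent <- need
  } else {
    for (ax in c("y", "x", "z"))
      if (extent[[ax]][1] > need[[ax]][1] || extent[[ax]][2] < need[[ax]][2])
        stop(sprintf(
          "grid too small: %s extent [%.2f, %.2f] um cannot contain the cell plus pad (needs [%.2f, %.2f])",
          ax, extent[[ax]][1], extent[[ax]][2], need[[ax]][1], need[[ax]][2]))
  }
  yc <- seq(extent$y[1], extent$y[2], by = voxel_size[1])
  xc <- seq(extent$x[1], extent$x[2], by = voxel_size[2])
  zc <- seq(extent$z[1], extent$z[2], by = voxel_size[3])
  ny <- length(yc); nx <- length(xc); nz <- length(zc)

  Y <- array(yc, dim = c(ny, nx, nz))
  X <- array(rep(xc, each = ny), dim = c(ny, nx, nz))
  Z <- array(rep(zc, each = ny * nx), dim = c(ny, nx, nz))

  a <- L_h / 2; b <- design$head_width / 2; cth <- design$head_thickness / 2
  in_head <- ((X - a) / a)^2 + (Y / b)^2 + (Z / cth)^2 <= 1

  in_mid <- in_core <- array(FALSE, dim = c(ny, nx, nz))
  if (L_m > 0) {
    span <- X > L_h & X <= x_t0
    rho2 <- Y^2 + Z^2
    in_mid <- span & rho2 <= design$midpiece_radius^2
    in_core <- span & rho2 <= design$midpiece_core_radius^2
  }

  in_tail <- array(FALSE, dim = c(ny, nx, nz))
  if (L_t > 0) {
    rb <- design$tail_base_radius; rt <- design$tail_tip_radius
    if (design$curvature == 0) {
      s_t <- X - x_t0
      ok <- s_t > 0 & s_t <= L_t
      r_here <- rb + (rt - rb) * pmin(pmax(s_t, 0), L_t) / L_t
      in_tail <- ok & (Y^2 + Z^2) <= r_here^2
    } else {
      R_arc <- 1 / design$curvature
      dx0 <- X - x_t0; dy0 <- Y - R_arc
      phi <- atan2(dx0, -dy0)            # 0 at the tail base, grows along arc
      s_t <- R_arc * phi
      rho <- sqrt(dx0^2 + dy0^2)
      d2 <- (rho - R_arc)^2 + Z^2
      ok <- s_t > 0 & s_t <= L_t
      r_here <- rb + (rt - rb) * pmin(pmax(s_t, 0), L_t) / L_t
      in_tail <- ok & d2 <= r_here^2
    }
  }

  labels <- array(0L, dim = c(ny, nx, nz))
  labels[in_tail] <- 3L
  labels[in_mid] <- 2L
  labels[in_head] <- 1L

  vals <- array(medium_ri, dim = c(ny, nx, nz))
  vals[in_tail] <- design$tail_ri
  vals[in_mid] <- design$midpiece_ri
  vals[in_core] <- design$midpiece_core_ri
  vals[in_head] <- design$head_ri

  tom <- ri_tomogram(vals, voxel_size, medium_ri,
                     origin = c(extent$y[1], extent$x[1], extent$z[1]))
  attr(tom, "labels") <- labels
  attr(tom, "design") <- design
  attr(tom, "boundaries") <- c(head_mid = L_h, mid_tail = x_t0)
  tom
}

#' Voxelized analytic reference shapes
#'
#' Oracle fixtures with known closed-form volume and surface area attached
#' as metadata: `sphere` (params `radius`), `ellipsoid` (params
#' `semi_axes`, a length-3 vector mapped to x, y, z), `cube` (params
#' `side`) and `cylinder` (params `radius`, `length`, axis along x). The
#' ellipsoid surface area uses the Thomsen approximation (p = 1.6075,
#' error below ~1.1%); all other areas are exact.
#'
#' @param kind one of `"sphere"`, `"ellipsoid"`, `"cube"`, `"cylinder"`.
#' @param params named list of dimensions (µm), see Details.
#' @param ri RI value inside the shape.
#' @param voxel_size voxel spacing, µm.
#' @param medium_ri background RI.
#' @param pad clearance around the shape, µm.
#' @return an `ri_tomogram` with attribute `analytic`, a list with
#'   `volume` (µm³) and `surface_area` (µm²).
#' @export
make_analytic_shape <- function(kind, params, ri = 1.36, voxel_size = 0.1,
                                medium_ri = 1.337, pad = 0.5) {
  kind <- match.arg(kind, c("sphere", "ellipsoid", "cube", "cylinder"))
  if (ri < medium_ri) stop("shape RI must be >= medium RI")
  semi <- switch(kind,
    sphere = {
      r <- params$radius
      if (is.null(r) || r <= 0) stop("sphere needs positive `radius`")
      c(r, r, r)
    },
    ellipsoid = {
      ax <- params$semi_axes
      if (is.null(ax) || length(ax) != 3 || any(ax <= 0))
        stop("ellipsoid needs positive length-3 `semi_axes`")
      as.numeric(ax[c(2, 1, 3)]) # store as (y, x, z) half-extents
    },
    cube = {
      s <- params$side
      if (is.null(s) || s <= 0) stop("cube needs positive `side`")
      c(s, s, s) / 2
    },
    cylinder = {
      if (is.null(params$radius) || is.null(params$length) ||
          params$radius <= 0 || params$length <= 0)
        stop("cylinder needs positive `radius` and `length`")
      c(params$radius, params$length / 2, params$radius)
    })
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  # half-voxel staggered grid: voxel centres never sit exactly on shape
  # boundaries aligned with grid multiples (avoids double-counted faces)
  stag <- function(h, d) {
    n <- 2 * ceiling(h / d)
    ((seq_len(n)) - (n + 1) / 2) * d
  }
  yc <- stag(semi[1] + pad, voxel_size[1])
  xc <- stag(semi[2] + pad, voxel_size[2])
  zc <- stag(semi[3] + pad, voxel_size[3])
  ny <- length(yc); nx <- length(xc); nz <- length(zc)
  Y <- array(yc, dim = c(ny, nx, nz))
  X <- array(rep(xc, each = ny), dim = c(ny, nx, nz))
  Z <- array(rep(zc, each = ny * nx), dim = c(ny, nx, nz))

  inside <- switch(kind,
    sphere = (X^2 + Y^2 + Z^2) <= params$radius^2,
    ellipsoid = {
      ax <- as.numeric(params$semi_axes)
      (X / ax[1])^2 + (Y / ax[2])^2 + (Z / ax[3])^2 <= 1
    },
    cube = pmax(abs(X), abs(Y), abs(Z)) <= params$side / 2,
    cylinder = abs(X) <= params$length / 2 &
      (Y^2 + Z^2) <= params$radius^2)

  analytic <- switch(kind,
    sphere = {
      r <- params$radius
      list(volume = 4 / 3 * pi * r^3, surface_area = 4 * pi * r^2)
    },
    ellipsoid = {
      ax <- as.numeric(params$semi_axes)
      p <- 1.6075
      A <- 4 * pi * ((ax[1]^p * ax[2]^p + ax[1]^p * ax[3]^p +
                        ax[2]^p * ax[3]^p) / 3)^(1 / p)
      list(volume = 4 / 3 * pi * prod(ax), surface_area = A)
    },
    cube = list(volume = params$side^3, surface_area = 6 * params$side^2),
    cylinder = {
      r <- params$radius; h <- params$length
      list(volume = pi * r^2 * h, surface_area = 2 * pi * r * (r + h))
    })

  vals <- array(medium_ri, dim = c(ny, nx, nz))
  vals[inside] <- ri
  tom <- ri_tomogram(vals, voxel_size, medium_ri,
                     origin = c(yc[1], xc[1], zc[1]))
  attr(tom, "analytic") <- analytic
  attr(tom, "kind") <- kind
  tom
}

#' Two-group population specification
#'
#' Per-parameter means and standard deviations of [sperm_design()] fields
#' for each group, used by [sample_population()] to draw cell designs from
#' truncated normal distributions (truncated at +-4 SD and at physical
#' bounds: positive lengths and radii, RI not below 1.337).
#'
#' @param groups named list; each element is a list with `mean` (a
#'   `sperm_design` or named numeric vector of design fields) and `sd`
#'   (named numeric vector; fields not named have SD 0).
#' @param n_per_group number of cells per group (>= 2).
#' @param seed integer seed making the sampling reproducible.
#' @return object of class `breed_population_spec`.
#' @export
breed_population_spec <- function(groups, n_per_group = 30, seed = 1) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("`groups` must be a named list")
  for (g in groups) {
    if (is.null(g$mean)) stop("each group needs a `mean` design")
    if (!is.null(g$sd) && any(g$sd < 0)) stop("SDs must be >= 0")
  }
  structure(list(groups = groups, n_per_group = n_per_group,
                 seed = as.integer(seed)),
            class = "breed_population_spec")
}

#' Default HO/KN population specification
#'
#' Means from [design_ho()]/[design_kn()] with the measured between-cell
#' SDs of the four 2D dimensions (head length 0.310/0.297, head width
#' 0.268/0.297, midpiece 0.547/0.299, tail 1.386/1.373 µm); all other
#' parameters are held fixed. The default n of 30 cells per breed mirrors
#' the study design of five bulls with six cells each.
#'
#' @param n_per_group cells per group.
#' @param seed integer seed.
#' @export
ho_kn_population_spec <- function(n_per_group = 30, seed = 1) {
  breed_population_spec(
    groups = list(
      HO = list(mean = design_ho(),
                sd = c(head_length = 0.310, head_width = 0.268,
                       midpiece_length = 0.547, tail_length = 1.386)),
      KN = list(mean = design_kn(),
                sd = c(head_length = 0.297, head_width = 0.297,
                       midpiece_length = 0.299, tail_length = 1.373))),
    n_per_group = n_per_group, seed = seed)
}

# physical lower bounds for truncated sampling
.design_lower_bounds <- c(
  head_length = 1e-2, head_width = 1e-2, head_thickness = 1e-2,
  midpiece_length = 0, midpiece_radius = 1e-3, midpiece_core_radius = 0,
  tail_length = 0, tail_base_radius = 1e-3, tail_tip_radius = 1e-3,
  head_ri = 1.337, midpiece_ri = 1.337, midpiece_core_ri = 1.337,
  tail_ri = 1.337, curvature = 0)

#' Draw a population of cell designs
#'
#' Draws `n_per_group` designs per group from truncated normal
#' distributions around the group means. Sampling is reproducible: the
#' spec's seed fully determines the output, and the caller's RNG state is
#' left untouched.
#'
#' @param spec a [breed_population_spec()].
#' @return list of `sperm_design` objects, each with attributes `group`
#'   and `cell_id`.
#' @export
sample_population <- function(spec) {
  stopifnot(inherits(spec, "breed_population_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  out <- list()
  for (gname in names(spec$groups)) {
    g <- spec$groups[[gname]]
    mean_d <- if (inherits(g$mean, "sperm_design")) unclass(g$mean)
      else as.list(g$mean)
    sds <- g$sd
    for (i in seq_len(spec$n_per_group)) {
      d <- mean_d
      for (f in names(sds)) {
        if (!f %in% names(d)) stop("unknown design field in sd: ", f)
        s <- sds[[f]]
        if (s == 0) next
        mu <- d[[f]]
        lo <- max(mu - 4 * s, .design_lower_bounds[[f]])
        hi <- mu + 4 * s
        v <- rnorm(1, mu, s)
        tries <- 0
        while ((v < lo || v > hi) && tries < 1000) {
          v <- rnorm(1, mu, s)
          tries <- tries + 1
        }
        d[[f]] <- min(max(v, lo), hi)
      }
      # keep the flattening invariant under independent draws
      d$head_thickness <- min(d$head_thickness, d$head_width)
      dd <- do.call(sperm_design, d)
      attr(dd, "group") <- gname
      attr(dd, "cell_id") <- sprintf("%s_%02d", gname, i)
      out[[length(out) + 1L]] <- dd
    }
  }
  out
}
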