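# ---- least-squares 2D phase unwrapping (DCT Poisson solver) ----

# cached cosine transform matrices
.dct_cache <- new.env(parent = emptyenv())
dct_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.dct_cache[[key]])) return(.dct_cache[[key]])
  C <- cos(pi * outer(0:(n - 1), (0:(n - 1)) + 0.5) / n)
  .dct_cache[[key]] <- C
  C
}
dct2 <- function(m) {
  dct_matrix(nrow(m)) %*% m %*% t(dct_matrix(ncol(m)))
}
idct2 <- function(M) {
  n1 <- nrow(M); n2 <- ncol(M)
  C1 <- dct_matrix(n1); C2 <- dct_matrix(n2)
  # DCT-II inverse: x = (2/N) C' (X - X0-half correction) handled via weights
  w1 <- c(0.5, rep(1, n1 - 1)); w2 <- c(0.5, rep(1, n2 - 1))
  (2 / n1) * t(C1) %*% (M * outer(w1, w2)) %*% C2 * (2 / n2)
}

wrap_pi <- function(x) (x + pi) %% (2 * pi) - pi

#' Least-squares 2D phase unwrapping
#'
#' Unweighted least-squares unwrapping (Poisson equation on the wrapped
#' phase gradients, solved with discrete cosine transforms under Neumann
#' boundary conditions). Exact for phases whose true gradients are below
#' pi per pixel; smooth fields from weak scatterers satisfy this.
#'
#' @param ph wrapped phase matrix, radians.
#' @return unwrapped phase matrix (mean-free up to the wrapped offset of
#'   the input; the output is shifted so its first pixel matches the
#'   wrapped input modulo 2*pi).
#' @export
unwrap_phase <- function(ph) {
  ny <- nrow(ph); nx <- ncol(ph)
  gy <- rbind(wrap_pi(diff(ph)), 0)
  gx <- cbind(wrap_pi(t(diff(t(ph)))), 0)
  rho <- (gy - rbind(0, gy[-ny, , drop = FALSE])) +
    (gx - cbind(0, gx[, -nx, drop = FALSE]))
  R <- dct2(rho)
  D <- 2 * (outer(cos(pi * (0:(ny - 1)) / ny), rep(1, nx)) +
              outer(rep(1, ny), cos(pi * (0:(nx - 1)) / nx)) - 2)
  D[1, 1] <- 1
  Phi <- R / D
  Phi[1, 1] <- 0
  out <- idct2(Phi)
  out - out[1, 1] + ph[1, 1]
}

#' Demodulate an off-axis hologram
#'
#' Retrieves the complex field from a single off-axis intensity hologram:
#' the hologram is mixed down by the conjugate reference (shifting the +1
#' sideband to DC), low-pass filtered with a circular stop of radius
#' `NA_detection / lambda`, and inverse-transformed. The illumination
#' plane-wave ramp is then divided out and the remaining phase is
#' 2D-unwrapped, yielding the relative complex field.
#'
#' @param hologram intensity matrix (e.g. from [synthesize_hologram()]).
#' @param plan an [illumination_plan()].
#' @param pixel_size µm (defaults to the hologram's attribute).
#' @param illum_dir illumination direction (defaults to the attribute).
#' @param medium_ri medium RI.
#' @return a [complex_field()].
#' @export
demodulate_hologram <- function(hologram, plan,
                                pixel_size = attr(hologram, "pixel_size"),
                                illum_dir = attr(hologram, "illum_dir"),
                                medium_ri = 1.337) {
  if (is.null(pixel_size)) stop("pixel_size required")
  if (length(pixel_size) == 1L) pixel_size <- rep(pixel_size, 2L)
  fc <- attr(hologram, "carrier_frequency")
  if (is.null(fc)) fc <- plan$carrier_frequency
  if (is.null(fc)) fc <- default_carrier(pixel_size, plan, dim(hologram))
  if (length(fc) == 1L) fc <- rep(fc, 2L)
  band <- plan$na_detection / plan$wavelength
  if (sqrt(sum(fc^2)) <= band)
    stop(sprintf(
      "sideband overlaps the DC term: |carrier| %.2f cycles/um must exceed NA/lambda = %.2f; raise the carrier or reduce NA",
      sqrt(sum(fc^2)), band))

  ny <- nrow(hologram); nx <- ncol(hologram)
  y <- (seq_len(ny) - 1) * pixel_size[1]
  x <- (seq_len(nx) - 1) * pixel_size[2]
  # select the U * conj(R) sideband: mixing by +carrier brings it to DC
  mix <- hologram * exp(2i * pi * (outer(y, rep(1, nx)) * fc[1] +
                                     outer(rep(1, ny), x) * fc[2]))
  H <- fft(mix)
  qy <- freq_rad(ny, pixel_size[1]) / (2 * pi)
  qx <- freq_rad(nx, pixel_size[2]) / (2 * pi)
  # crop radius: the full detection band plus a small grid margin (the
  # illumination tilt can sit exactly at the aperture edge), bounded away
  # from the DC term
  dq <- 1 / (c(ny, nx) * pixel_size)
  radius <- min(band + 2 * max(dq), sqrt(sum(fc^2)) - 2 * max(dq))
  pass <- outer(qy^2, rep(1, nx)) + outer(rep(1, ny), qx^2) <= radius^2
  U <- fft(H * pass, inverse = TRUE) / (ny * nx)

  fld <- complex_field(amplitude = matrix(1, ny, nx),
                       phase = matrix(0, ny, nx),
                       pixel_size = pixel_size, illum_dir = illum_dir,
                       wavelength = plan$wavelength, medium_ri = medium_ri)
  Urel <- U * exp(-1i * illumination_ramp(fld))
  complex_field(amplitude = Mod(Urel),
                phase = unwrap_phase(Arg(Urel)),
                pixel_size = pixel_size, illum_dir = illum_dir,
                wavelength = plan$wavelength, medium_ri = medium_ri)
}

#' Map complex fields onto the 3D scattering-potential spectrum
#'
#' Fourier diffraction theorem under the Rytov approximation: for each
#' field the 2D spectrum of the complex Rytov phase `psi = log(A) + i phi`
#' is placed on the Ewald-sphere cap
#' `kz = sqrt((n_m k0)^2 - kx^2 - ky^2)` shifted by the illumination
#' wavevector, limited by the detection NA. Frequency voxels hit by
#' several angles are averaged (nearest-voxel gridding with multiplicity
#' averaging).
#'
#' @param fields list of [complex_field()] objects sharing grid and
#'   wavelength.
#' @param plan an [illumination_plan()].
#' @param nz number of axial voxels of the target grid.
#' @param dz axial voxel pitch, µm (defaults to the lateral pitch).
#' @return object of class `frequency_support`: list with `spectrum`
#'   (complex array, ny x nx x nz), `support` (logical array of measured
#'   voxels), `count` (integer multiplicities), plus grid metadata.
#' @export
map_to_frequency_space <- function(fields, plan, nz,
                                   dz = fields[[1]]$pixel_size[1]) {
  f1 <- fields[[1]]
  ny <- nrow(f1$amplitude); nx <- ncol(f1$amplitude)
  dy <- f1$pixel_size[1]; dx <- f1$pixel_size[2]
  lam <- plan$wavelength
  k0 <- 2 * pi / lam
  km <- k0 * f1$medium_ri

  spectrum <- array(0i, dim = c(ny, nx, nz))
  count <- array(0L, dim = c(ny, nx, nz))
  qy <- freq_rad(ny, dy); qx <- freq_rad(nx, dx)
  Qy <- matrix(qy, ny, nx)
  Qx <- matrix(qx, ny, nx, byrow = TRUE)
  dqz <- 2 * pi / (nz * dz)

  for (fld in fields) {
    jump <- max(max(abs(diff(fld$phase))), max(abs(diff(t(fld$phase)))))
    if (jump > pi)
      stop("field phase contains 2*pi jumps; unwrap before mapping")
    psi <- log(pmax(fld$amplitude, 1e-12)) + 1i * fld$phase
    F2 <- fft(psi) * dy * dx
    kx <- Qx + km * fld$illum_dir[1]
    ky <- Qy + km * fld$illum_dir[2]
    kpar2 <- kx^2 + ky^2
    valid <- kpar2 <= (plan$na_detection * k0)^2 & kpar2 < km^2
    idx <- which(valid)
    kz <- sqrt(km^2 - kpar2[idx])
    Kz <- kz - km * fld$illum_dir[3]
    kzi <- round(Kz / dqz) %% nz
    Vhat <- -2i * kz * F2[idx]
    idx3 <- idx + kzi * (ny * nx)
    spectrum[idx3] <- spectrum[idx3] + Vhat
    count[idx3] <- count[idx3] + 1L
  }
  support <- count > 0L
  spectrum[support] <- spectrum[support] / count[support]
  structure(list(spectrum = spectrum, support = support, count = count,
                 voxel_size = c(dy, dx, dz), wavelength = lam,
                 medium_ri = f1$medium_ri),
            class = "frequency_support")
}

#' Hermitian symmetrization of a measured frequency support
#'
#' The scattering potential of a non-absorbing object is real, so its
#' spectrum is Hermitian: `V(-k) = conj(V(k))`. Averaging each measured
#' voxel with the conjugate of its mirrored counterpart (multiplicity
#' weighted) enforces this physical constraint, enlarges the support by
#' its mirror image, and removes the non-Hermitian residue of the Rytov
#' data that otherwise drives a slow background drift of the
#' non-negativity iteration.
#'
#' @param fsup a [map_to_frequency_space()] result.
#' @return a `frequency_support` with symmetrized spectrum, support and
#'   counts.
#' @export
symmetrize_support <- function(fsup) {
  d <- dim(fsup$spectrum)
  rev_idx <- function(n) c(1, rev(seq_len(n)[-1]))
  Srev <- Conj(fsup$spectrum[rev_idx(d[1]), rev_idx(d[2]), rev_idx(d[3])])
  crev <- fsup$count[rev_idx(d[1]), rev_idx(d[2]), rev_idx(d[3])]
  tot <- fsup$count + crev
  S <- fsup$spectrum * fsup$count + Srev * crev
  S[tot > 0L] <- S[tot > 0L] / tot[tot > 0L]
  fsup$spectrum <- S
  fsup$support <- tot > 0L
  fsup$count <- tot
  fsup
}

#' Reconstruction settings
#'
#' @param iterations non-negativity iteration cap (0 = naive inverse).
#' @param tol relative RI-change convergence tolerance.
#' @param enforce_nonnegativity clamp RI contrast at zero in real space.
#' @param hermitian apply [symmetrize_support()] before reconstructing.
#' @return object of class `reconstruction_settings`.
#' @export
reconstruction_settings <- function(iterations = 100, tol = 1e-4,
                                    enforce_nonnegativity = TRUE,
                                    hermitian = TRUE) {
  if (iterations < 0) stop("iterations must be >= 0")
  if (tol <= 0) stop("tol must be positive")
  structure(list(iterations = as.integer(iterations), tol = tol,
                 enforce_nonnegativity = enforce_nonnegativity,
                 hermitian = hermitian),
            class = "reconstruction_settings")
}

#' Iterative non-negativity correction of the missing cone
#'
#' Gerchberg-Papoulis-type iteration on the scattering potential: the
#' real-space step clamps the RI at the medium value (non-negative
#' contrast, discarding the imaginary part), the frequency-space step
#' restores the measured voxels on the support. Stops at the iteration cap
#' or when the relative RI change falls below `tol`; a relative change
#' growing three iterations in a row raises an error carrying the
#' iteration trace. The final spectrum has the measured data restored
#' exactly.
#'
#' @param fsup a [map_to_frequency_space()] result.
#' @param settings a [reconstruction_settings()].
#' @return an `ri_tomogram`; attributes `trace` (relative change per
#'   iteration) and `iterations`.
#' @export
regularize_missing_cone <- function(fsup, settings = reconstruction_settings()) {
  if (isTRUE(settings$hermitian)) fsup <- symmetrize_support(fsup)
  spectrum <- fsup$spectrum; support <- fsup$support
  d <- dim(spectrum)
  ny <- d[1]; nx <- d[2]; nz <- d[3]
  vs <- fsup$voxel_size
  k0 <- 2 * pi / fsup$wavelength
  n_m <- fsup$medium_ri
  ntot <- prod(d); dvol <- prod(vs)

  # the cap z-phases were referenced to the grid centre; convert between
  # the centred spectrum and index-origin FFT conventions per kz plane
  zc_shift <- exp(-1i * freq_rad(nz, vs[3]) * floor(nz / 2) * vs[3])
  inv_trans <- function(S) {
    S <- sweep(S, 3, zc_shift, "*")
    fft(S, inverse = TRUE) / (ntot * dvol)
  }
  fwd_trans <- function(V) {
    S <- fft(V) * dvol
    sweep(S, 3, 1 / zc_shift, "*")
  }

  data <- spectrum[support]
  V <- Re(inv_trans(spectrum))
  trace <- numeric(0)
  if (settings$iterations > 0) {
    grow <- 0L
    for (it in seq_len(settings$iterations)) {
      Vc <- if (settings$enforce_nonnegativity) pmax(V, 0) else V
      S <- fwd_trans(Vc)
      S[support] <- data
      Vn <- Re(inv_trans(S))
      rel <- sqrt(sum((Vn - V)^2)) / max(sqrt(sum(V^2)), 1e-12)
      trace <- c(trace, rel)
      if (length(trace) > 1 && rel > 1.05 * trace[length(trace) - 1]) {
        grow <- grow + 1L
        if (grow >= 3L) {
          err <- simpleError("non-negativity iteration diverging (relative change grew 3 iterations in a row)")
          err$trace <- trace
          stop(err)
        }
      } else grow <- 0L
      V <- Vn
      if (rel < settings$tol) break
    }
  }
  n <- sqrt(pmax(n_m^2 + V / k0^2, 1))
  tom <- ri_tomogram(n, vs, n_m, tol = 0.05)
  attr(tom, "trace") <- trace
  attr(tom, "iterations") <- length(trace)
  tom
}

#' Lateral and axial resolution by the Lauer criterion
#'
#' Resolution implied by the synthetic aperture of angle-scanned
#' tomography: lateral `lambda / (2 (NA_ill + NA_det))` and axial
#' `lambda / (2 n_m - sqrt(n_m^2 - NA_det^2) - sqrt(n_m^2 - NA_ill^2))`,
#' i.e. the reciprocal of the lateral/axial extent of the accessible
#' frequency support (half-period convention laterally, matching how
#' commercial holotomography systems state it). At the shipped defaults
#' (532 nm, both NA 1.2, medium 1.337) this is approximately (111, 356)
#' nm.
#'
#' @param plan an [illumination_plan()].
#' @param medium_ri medium RI.
#' @return named numeric `c(lateral_nm, axial_nm)`.
#' @export
lauer_resolution <- function(plan, medium_ri = 1.337) {
  check_na_vs_medium(plan, medium_ri)
  lam <- plan$wavelength
  lateral <- lam / (2 * (plan$na_illumination + plan$na_detection))
  den <- 2 * medium_ri - sqrt(medium_ri^2 - plan$na_detection^2) -
    sqrt(medium_ri^2 - plan$na_illumination^2)
  axial <- lam / den
  c(lateral_nm = lateral * 1000, axial_nm = axial * 1000)
}

#' Reconstruct a tomogram from a hologram set
#'
#' Full inverse pipeline: per-frame off-axis demodulation and phase
#' unwrapping, Fourier-diffraction-theorem mapping, and iterative
#' non-negativity correction of the missing cone. Lauer-criterion
#' resolution metadata is attached.
#'
#' @param hs a [hologram_set()].
#' @param plan an [illumination_plan()].
#' @param nz axial grid size.
#' @param dz axial pitch (µm).
#' @param settings a [reconstruction_settings()].
#' @param verbose print per-iteration relative change.
#' @return an `ri_tomogram` with attribute `lauer_resolution`.
#' @export
reconstruct_tomogram <- function(hs, plan, nz, dz = hs$pixel_size[1],
                                 settings = reconstruction_settings(),
                                 verbose = FALSE) {
  fields <- lapply(seq_along(hs$frames), function(k)
    demodulate_hologram(hs$frames[[k]], plan,
                        pixel_size = hs$pixel_size,
                        illum_dir = hs$illum_dirs[k, ],
                        medium_ri = hs$medium_ri))
  fsup <- map_to_frequency_space(fields, plan, nz = nz, dz = dz)
  tom <- regularize_missing_cone(fsup, settings)
  if (verbose) {
    tr <- attr(tom, "trace")
    for (i in seq_along(tr))
      message(sprintf("iteration %3d: relative RI change %.3e", i, tr[i]))
  }
  attr(tom, "lauer_resolution") <- lauer_resolution(plan, hs$medium_ri)
  tom
}
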