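# angular spatial frequencies (rad/µm) of an n-point grid with pitch d,
# in FFT layout (DC first, negative frequencies wrapped)
freq_rad <- function(n, d) {
  k <- 0:(n - 1)
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  2 * pi * k / (n * d)
}

#' Illumination and detection settings of the simulated tomographic system
#'
#' Describes the angle-scanned illumination and the detection aperture of
#' a holotomographic microscope. Defaults are instrument-class values for
#' a water-immersion system at 532 nm with matched illumination and
#' detection numerical apertures of 1.2; under the Lauer criterion these
#' give the lateral/axial resolution reported by [lauer_resolution()].
#'
#' @param wavelength vacuum wavelength, µm.
#' @param na_illumination NA of the illumination scan cone.
#' @param na_detection NA of the collection objective.
#' @param n_angles number of illumination angles (default 30).
#' @param angle_pattern `"circle"` (equispaced azimuths on the maximum-NA
#'   cone) or `"spiral"` (golden-angle azimuths with radially growing
#'   polar angle).
#' @param carrier_frequency off-axis reference tilt, cycles/µm `(fy, fx)`;
#'   `NULL` chooses one third of the camera Nyquist frequency per axis at
#'   hologram synthesis time.
#' @return object of class `illumination_plan`.
#' @export
illumination_plan <- function(wavelength = 0.532, na_illumination = 1.2,
                              na_detection = 1.2, n_angles = 30,
                              angle_pattern = c("circle", "spiral"),
                              carrier_frequency = NULL) {
  angle_pattern <- match.arg(angle_pattern)
  if (wavelength <= 0) stop("wavelength must be positive")
  if (na_illumination < 0 || na_detection <= 0)
    stop("numerical apertures must be positive")
  if (n_angles < 1) stop("n_angles must be >= 1")
  structure(list(wavelength = wavelength,
                 na_illumination = na_illumination,
                 na_detection = na_detection,
                 n_angles = as.integer(n_angles),
                 angle_pattern = angle_pattern,
                 carrier_frequency = carrier_frequency),
            class = "illumination_plan")
}

check_na_vs_medium <- function(plan, medium_ri) {
  if (plan$na_illumination >= medium_ri || plan$na_detection >= medium_ri)
    stop(sprintf(
      "numerical aperture (%.2f/%.2f) must be below the medium RI (%.4f)",
      plan$na_illumination, plan$na_detection, medium_ri))
}

#' Unit illumination directions of a plan
#'
#' @param plan an [illumination_plan()].
#' @param medium_ri immersion-medium RI (sets the cone angle via
#'   `sin(theta) = NA / medium_ri`).
#' @return `n_angles` x 3 matrix of unit vectors `(sx, sy, sz)`, z the
#'   optical axis.
#' @export
illumination_directions <- function(plan, medium_ri) {
  check_na_vs_medium(plan, medium_ri)
  n <- plan$n_angles
  smax <- plan$na_illumination / medium_ri
  if (plan$angle_pattern == "circle") {
    sin_t <- rep(smax, n)
    phi <- 2 * pi * (seq_len(n) - 1) / n
  } else {
    sin_t <- smax * sqrt(seq_len(n) / n)
    phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  }
  cbind(sx = sin_t * cos(phi), sy = sin_t * sin(phi),
        sz = sqrt(1 - sin_t^2))
}

#' Complex optical field at the detection plane
#'
#' Relative complex field (illumination plane wave divided out):
#' amplitude and smooth phase in radians. The total phase including the
#' illumination ramp is available via [total_phase()].
#'
#' @param amplitude,phase numeric matrices.
#' @param pixel_size µm, `(dy, dx)` or scalar.
#' @param illum_dir length-3 unit illumination direction.
#' @param wavelength µm.
#' @param medium_ri medium RI.
#' @return object of class `complex_field`.
#' @export
complex_field <- function(amplitude, phase, pixel_size, illum_dir,
                          wavelength, medium_ri) {
  if (any(amplitude < 0)) stop("amplitude must be non-negative")
  if (!all(is.finite(phase))) stop("phase must be finite")
  if (length(pixel_size) == 1L) pixel_size <- rep(pixel_size, 2L)
  structure(list(amplitude = amplitude, phase = phase,
                 pixel_size = as.numeric(pixel_size),
                 illum_dir = as.numeric(illum_dir),
                 wavelength = wavelength, medium_ri = medium_ri),
            class = "complex_field")
}

# illumination plane-wave phase ramp on the field grid (radians)
illumination_ramp <- function(field) {
  km <- 2 * pi / field$wavelength * field$medium_ri
  ny <- nrow(field$amplitude); nx <- ncol(field$amplitude)
  y <- (seq_len(ny) - 1) * field$pixel_size[1]
  x <- (seq_len(nx) - 1) * field$pixel_size[2]
  km * (outer(y, rep(1, nx)) * field$illum_dir[2] +
          outer(rep(1, ny), x) * field$illum_dir[1])
}

#' Total phase of a field including the illumination ramp
#' @param field a `complex_field`.
#' @return numeric matrix, radians.
#' @export
total_phase <- function(field) field$phase + illumination_ramp(field)

# complex values of the relative field
field_complex <- function(field) field$amplitude * exp(1i * field$phase)

#' First-order scattered field of a tomogram
#'
#' Computes the total complex field at the detection plane for one
#' illumination direction under the first-order weak-scattering (Rytov)
#' model: the 2D spectrum of the complex Rytov phase equals the
#' Ewald-sphere cap of the 3D spectrum of the scattering potential
#' `V = k0^2 (n^2 - n_m^2)`, shifted by the illumination wavevector and
#' low-pass limited by the detection NA. The cap is sampled exactly in z
#' (slice-wise discrete Fourier transform), so the model is the forward
#' direction of the Fourier diffraction theorem used in reconstruction.
#' For zero contrast the relative field is exactly unity.
#'
#' @param tom an `ri_tomogram` (weak scatterer: max contrast about 0.05).
#' @param illum_dir length-3 unit illumination direction.
#' @param plan an [illumination_plan()].
#' @return a [complex_field()] (relative field, ramp removed).
#' @export
scattered_field <- function(tom, illum_dir, plan) {
  check_na_vs_medium(plan, tom$medium_ri)
  contrast <- max(abs(ri_contrast(tom)))
  if (contrast > 0.05)
    warning(sprintf(
      "RI contrast %.3f exceeds the first-order validity bound (~0.05)",
      contrast))
  lam <- plan$wavelength
  k0 <- 2 * pi / lam
  km <- k0 * tom$medium_ri
  d <- dim(tom$values)
  ny <- d[1]; nx <- d[2]; nz <- d[3]
  dy <- tom$voxel_size[1]; dx <- tom$voxel_size[2]; dz <- tom$voxel_size[3]

  V <- k0^2 * (tom$values^2 - tom$medium_ri^2)
  A <- array(0i, dim = d)
  for (iz in seq_len(nz)) A[, , iz] <- fft(V[, , iz])

  qy <- freq_rad(ny, dy); qx <- freq_rad(nx, dx)
  Qy <- matrix(qy, ny, nx)
  Qx <- matrix(qx, ny, nx, byrow = TRUE)
  kx <- Qx + km * illum_dir[1]
  ky <- Qy + km * illum_dir[2]
  kpar2 <- kx^2 + ky^2
  valid <- kpar2 <= (plan$na_detection * k0)^2 & kpar2 < km^2
  idx <- which(valid)
  kz <- sqrt(km^2 - kpar2[idx])
  Kz <- kz - km * illum_dir[3]

  zc <- ((seq_len(nz) - 1) - floor(nz / 2)) * dz
  M <- vapply(seq_len(nz), function(iz) A[, , iz][idx],
              complex(length(idx)))
  M <- matrix(M, nrow = length(idx))
  B <- (M * exp(-1i * outer(Kz, zc))) %*% rep(1, nz) * dz

  F2 <- matrix(0i, ny, nx)
  F2[idx] <- 1i / (2 * kz) * B
  psi <- fft(F2, inverse = TRUE) / (ny * nx)

  complex_field(amplitude = exp(Re(psi)), phase = Im(psi),
                pixel_size = c(dy, dx), illum_dir = illum_dir,
                wavelength = lam, medium_ri = tom$medium_ri)
}

# default off-axis carrier: the largest alias-free tilt, one detection
# passband below Nyquist per axis, so the sideband crop can include the
# full aperture (the illumination tilt reaches the aperture edge) while
# staying clear of the DC/autocorrelation terms. Snapped down to the DFT
# frequency grid when the frame size is known, so the reference wave is
# periodic over the frame and its spectrum stays compact.
default_carrier <- function(pixel_size, plan, n = NULL) {
  fc <- 1 / (2 * pixel_size) - plan$na_detection / plan$wavelength
  if (!is.null(n)) {
    df <- 1 / (n * pixel_size)
    fc <- floor(fc / df) * df
  }
  fc
}

# snap illumination directions onto the lateral DFT frequency grid of an
# (n_y x n_x, pixel_size) frame: the tilted plane wave becomes periodic
# over the frame, so synthesis and demodulation are leakage-free. The
# adjustment is below one frequency-grid step (a fraction of a degree).
snap_directions <- function(dirs, medium_ri, wavelength, n, pixel_size) {
  if (length(n) == 1L) n <- rep(n, 2L)
  if (length(pixel_size) == 1L) pixel_size <- rep(pixel_size, 2L)
  km <- 2 * pi / wavelength * medium_ri
  dqy <- 2 * pi / (n[1] * pixel_size[1])
  dqx <- 2 * pi / (n[2] * pixel_size[2])
  out <- dirs
  for (k in seq_len(nrow(dirs))) {
    sx <- round(km * dirs[k, 1] / dqx) * dqx / km
    sy <- round(km * dirs[k, 2] / dqy) * dqy / km
    s2 <- sx^2 + sy^2
    if (s2 >= 1) { sx <- dirs[k, 1]; sy <- dirs[k, 2]; s2 <- sx^2 + sy^2 }
    out[k, ] <- c(sx, sy, sqrt(1 - s2))
  }
  out
}

#' Synthesize an off-axis hologram
#'
#' Interferes the total field with a tilted plane-wave reference at the
#' carrier frequency: `I = |U + R|^2`. Optional additive Gaussian noise at
#' a stated intensity SNR (dB); negative intensities are clipped at zero.
#' Deterministic for a given `seed`; the caller's RNG state is preserved.
#'
#' @param field a [complex_field()].
#' @param plan an [illumination_plan()]; its `carrier_frequency`
#'   (cycles/µm) is used, or the 1/3-Nyquist default.
#' @param noise_snr intensity SNR in dB, or `NULL` for noise-free.
#' @param seed integer seed for the noise.
#' @return numeric intensity matrix with attributes `illum_dir`,
#'   `pixel_size`, `carrier_frequency`.
#' @export
synthesize_hologram <- function(field, plan, noise_snr = NULL, seed = 1L) {
  px <- field$pixel_size
  fc <- plan$carrier_frequency
  if (is.null(fc)) fc <- default_carrier(px, plan, dim(field$amplitude))
  if (length(fc) == 1L) fc <- rep(fc, 2L)
  f_nyq <- 1 / (2 * px)
  band <- plan$na_detection / field$wavelength
  if (any(abs(fc) + band > f_nyq))
    stop(sprintf(
      "carrier aliasing: |carrier| + NA/lambda = (%.2f, %.2f) cycles/um exceeds Nyquist (%.2f, %.2f)",
      abs(fc[1]) + band, abs(fc[2]) + band, f_nyq[1], f_nyq[2]))

  U <- field_complex(field) * exp(1i * illumination_ramp(field))
  ny <- nrow(U); nx <- ncol(U)
  y <- (seq_len(ny) - 1) * px[1]
  x <- (seq_len(nx) - 1) * px[2]
  Rw <- exp(2i * pi * (outer(y, rep(1, nx)) * fc[1] +
                         outer(rep(1, ny), x) * fc[2]))
  I <- Mod(U + Rw)^2
  if (!is.null(noise_snr)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                     envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
    sdn <- sqrt(mean(I^2)) * 10^(-noise_snr / 20)
    I <- pmax(I + matrix(rnorm(length(I), 0, sdn), ny, nx), 0)
  }
  structure(I, illum_dir = field$illum_dir, pixel_size = px,
            carrier_frequency = fc)
}

#' Container for an angle-scanned hologram stack
#'
#' @param frames list of 2D intensity matrices, one per angle.
#' @param illum_dirs matrix of unit illumination directions (rows match
#'   `frames`).
#' @param pixel_size µm.
#' @param wavelength µm.
#' @param medium_ri medium RI.
#' @param carrier_frequency cycles/µm pair used at synthesis.
#' @return object of class `hologram_set`.
#' @export
hologram_set <- function(frames, illum_dirs, pixel_size, wavelength,
                         medium_ri, carrier_frequency) {
  if (length(frames) != nrow(illum_dirs))
    stop("one illumination direction per frame required")
  if (any(vapply(frames, min, 0) < 0))
    stop("hologram intensities must be non-negative")
  nrm <- sqrt(rowSums(illum_dirs^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("illumination directions must be unit vectors")
  if (length(pixel_size) == 1L) pixel_size <- rep(pixel_size, 2L)
  structure(list(frames = frames, illum_dirs = illum_dirs,
                 pixel_size = as.numeric(pixel_size),
                 wavelength = wavelength, medium_ri = medium_ri,
                 carrier_frequency = carrier_frequency),
            class = "hologram_set")
}

#' @export
print.hologram_set <- function(x, ...) {
  cat(sprintf("<hologram_set> %d frames of %d x %d px @ %.3g um, lambda %.3g um\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              x$pixel_size[1], x$wavelength))
  invisible(x)
}

#' Simulate a full angle scan of a phantom
#'
#' Runs [scattered_field()] for every direction of the plan and
#' synthesizes one off-axis hologram per angle.
#'
#' @param tom an `ri_tomogram`.
#' @param plan an [illumination_plan()].
#' @param noise_snr intensity SNR in dB or `NULL`.
#' @param seed base seed; frame k uses `seed + k`.
#' @return a [hologram_set()]; the noise-free fields are attached as
#'   attribute `fields`.
#' @export
simulate_holograms <- function(tom, plan, noise_snr = NULL, seed = 1L) {
  dirs <- illumination_directions(plan, tom$medium_ri)
  d <- dim(tom$values)
  dirs <- snap_directions(dirs, tom$medium_ri, plan$wavelength,
                          d[1:2], tom$voxel_size[1:2])
  fields <- lapply(seq_len(nrow(dirs)), function(k)
    scattered_field(tom, dirs[k, ], plan))
  frames <- lapply(seq_along(fields), function(k)
    synthesize_hologram(fields[[k]], plan, noise_snr = noise_snr,
                        seed = seed + k))
  fc <- attr(frames[[1]], "carrier_frequency")
  hs <- hologram_set(frames, dirs, tom$voxel_size[1:2], plan$wavelength,
                     tom$medium_ri, fc)
  attr(hs, "fields") <- fields
  hs
}
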